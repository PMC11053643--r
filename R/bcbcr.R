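# The BCBCR statistic: in vitro POD (ng/mL) / measured plasma concentration
# (ng/mL), its threshold classification, and the chemical ranking.

#' Compute BCBCR values
#'
#' The Bioactive Concentration to Blood Concentration Ratio is the
#' chemical-level in vitro POD (converted to ng/mL) divided by the measured
#' plasma-equivalent concentration, also in ng/mL, for each population
#' summary record. Values below 1 mean the measured plasma level reaches the
#' in vitro bioactive range. Records with a zero plasma value are skipped
#' with a warning (the ratio is undefined); censoring of the POD (all assay
#' sets inactive up to their top concentrations) is propagated so that
#' ratios built on the sentinel POD can be distinguished from ratios built
#' on observed bioactivity. `halflife_applicable` marks chemicals whose
#' half-life class supports the stable-blood-level assumption behind the
#' ratio (> 2 months).
#'
#' @param plasma Tibble of plasma-equivalent records (see [to_plasma()]).
#' @param chem_pods Tibble of chemical-level PODs (see [pod_chemical()]).
#' @param roster Chemical roster (see [load_roster()]).
#' @param thresholds Strictly increasing classification thresholds; see
#'   [classify_bcbcr()].
#' @return Tibble with one row per plasma record of a chemical that has a
#'   POD: identifiers, `plasma_ngml`, `pod_ngml`, `bcbcr`, `band`,
#'   `censored`, `halflife_applicable`.
#' @export
compute_bcbcr <- function(plasma, chem_pods, roster,
                          thresholds = c(1, 100, 1000, 10000)) {
  plasma <- plasma[, setdiff(names(plasma),
                             c("abbreviation", "halflife_class"))]
  pods <- chem_pods[, c("dtxsid", "pod_chemical_ngml", "driving_set",
                        "censored")]
  if (anyNA(pods$pod_chemical_ngml) || any(pods$pod_chemical_ngml <= 0)) {
    stop("every chemical POD must be a positive ng/mL value", call. = FALSE)
  }
  out <- dplyr::inner_join(plasma, pods, by = "dtxsid")
  zero <- !is.na(out$plasma_value) & out$plasma_value == 0
  if (any(zero)) {
    warning("skipping ", sum(zero),
            " record(s) with plasma concentration 0 (BCBCR undefined)",
            call. = FALSE)
    out <- out[!zero, , drop = FALSE]
  }
  hl <- roster[, c("dtxsid", "abbreviation", "halflife_class")]
  out <- dplyr::left_join(out, hl, by = "dtxsid")
  out$bcbcr <- out$pod_chemical_ngml / out$plasma_value
  tibble::tibble(
    dtxsid = out$dtxsid,
    abbreviation = out$abbreviation,
    snaid = out$snaid,
    population_class = out$population_class,
    matrix = out$matrix,
    metric = out$metric,
    metric_group = out$metric_group,
    plasma_ngml = out$plasma_value,
    pod_ngml = out$pod_chemical_ngml,
    driving_set = out$driving_set,
    bcbcr = out$bcbcr,
    band = classify_bcbcr(out$bcbcr, thresholds),
    censored = out$censored,
    halflife_applicable = !is.na(out$halflife_class) &
      out$halflife_class == "gt_2_months"
  )
}

#' Classify BCBCR values into threshold bands
#'
#' Assigns each ratio the smallest threshold it falls strictly below
#' (`"<1"`, `"<100"`, ...); ratios at or above the largest threshold are
#' `"above_max"`. Strict inequalities throughout, so a ratio exactly at a
#' boundary belongs to the next band up.
#'
#' @param bcbcr Numeric vector of ratios (> 0).
#' @param thresholds Strictly increasing positive thresholds; default
#'   `c(1, 100, 1000, 10000)`.
#' @return Factor with levels `"<1"`, ..., `"above_max"` (for the default
#'   thresholds).
#' @examples
#' classify_bcbcr(c(0.7, 1, 25000))
#' @export
classify_bcbcr <- function(bcbcr, thresholds = c(1, 100, 1000, 10000)) {
  if (length(thresholds) == 0 || any(thresholds <= 0) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing and positive",
         call. = FALSE)
  }
  if (any(bcbcr <= 0, na.rm = TRUE)) {
    stop("bcbcr must be > 0", call. = FALSE)
  }
  labels <- c(paste0("<", format(thresholds, scientific = FALSE,
                                 trim = TRUE, big.mark = "")),
              "above_max")
  idx <- vapply(bcbcr, function(x) {
    i <- which(x < thresholds)
    if (length(i) == 0) length(thresholds) + 1L else min(i)
  }, integer(1))
  factor(labels[idx], levels = labels)
}

#' Rank chemicals by minimum BCBCR
#'
#' Summarises BCBCR results per chemical: the minimum ratio across all
#' population x metric records, the record driving it, and counts of records
#' per threshold band. Chemicals are ordered ascending by minimum BCBCR
#' (highest screening priority first). Chemicals whose POD is censored are
#' retained but flagged: their ratios are built on the sentinel POD, i.e.
#' on absence of observed bioactivity up to the top tested concentration.
#'
#' @param results BCBCR results (see [compute_bcbcr()]).
#' @return Tibble ordered by `min_bcbcr` with one row per chemical:
#'   `dtxsid`, `abbreviation`, `min_bcbcr`, `min_band`,
#'   `driving_population`, `driving_metric`, `driving_snaid`, `n_records`,
#'   `censored_pod` plus one `n_band_*` count column per band.
#' @export
rank_chemicals <- function(results) {
  if (nrow(results) == 0) stop("no BCBCR results to rank", call. = FALSE)
  band_counts <- results |>
    dplyr::count(.data$dtxsid, .data$band) |>
    tidyr::pivot_wider(names_from = "band", values_from = "n",
                       names_prefix = "n_band_", values_fill = 0L,
                       names_expand = TRUE)
  summary <- results |>
    dplyr::group_by(.data$dtxsid) |>
    dplyr::arrange(.data$bcbcr, .by_group = TRUE) |>
    dplyr::summarise(
      abbreviation = .data$abbreviation[1],
      min_bcbcr = .data$bcbcr[1],
      min_band = .data$band[1],
      driving_population = .data$population_class[1],
      driving_metric = .data$metric[1],
      driving_snaid = .data$snaid[1],
      n_records = dplyr::n(),
      censored_pod = any(.data$censored),
      .groups = "drop"
    )
  dplyr::left_join(summary, band_counts, by = "dtxsid") |>
    dplyr::arrange(.data$min_bcbcr)
}

#' Check which chemicals reach bioactive blood levels
#'
#' Given a full BCBCR result table, returns the chemicals having at least
#' one population x metric record with a ratio below `limit` (default 1,
#' i.e. measured plasma levels at or above the in vitro bioactive
#' concentration). With complete biomonitoring and POD tables for the
#' 31-chemical PFAS roster this reproduces the screening headline that only
#' PFOA and PFOS reach ratios below 1, and only in exposed populations;
#' the check runs on any inputs in the documented CSV schemas.
#'
#' @param results BCBCR results (see [compute_bcbcr()]).
#' @param limit Ratio threshold; default 1.
#' @return Tibble of chemicals with any `bcbcr < limit`: `dtxsid`,
#'   `abbreviation`, `min_bcbcr`, `n_below`, `populations` (comma-separated
#'   population classes among the qualifying records).
#' @export
check_low_bcbcr <- function(results, limit = 1) {
  stopifnot(limit > 0)
  hits <- dplyr::filter(results, .data$bcbcr < limit)
  if (nrow(hits) == 0) {
    return(tibble::tibble(dtxsid = character(), abbreviation = character(),
                          min_bcbcr = numeric(), n_below = integer(),
                          populations = character()))
  }
  hits |>
    dplyr::group_by(.data$dtxsid) |>
    dplyr::summarise(
      abbreviation = .data$abbreviation[1],
      min_bcbcr = min(.data$bcbcr),
      n_below = dplyr::n(),
      populations = paste(sort(unique(.data$population_class)),
                          collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$min_bcbcr)
}
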