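# Aggregation of endpoint-level in vitro results into assay-set PODs and a
# chemical-level POD, with the developmental-neurotoxicity curve filters.

HITCALLS <- c("active", "inactive", "undetermined")

#' Default POD aggregation policy
#'
#' Per-technology aggregation of active endpoint potencies into a set-level
#' POD: the default is the lower 5th percentile (`P5`) of active potencies
#' (transcription-factor panels, primary-cell systems, developmental
#' neurotoxicity, transcriptomics, thyroid); the minimum (`MIN`) is used for
#' technologies whose set-level POD is defined as the lowest endpoint value
#' (estrogen-proliferation impedance `ACEA`, phenotypic profiling `HTPP`,
#' `Zebrafish` embryotoxicity). Assay sets are matched by prefix so that
#' e.g. `HTPP_U2OS` and `HTPP_MCF7` are separate sets under the same rule.
#' An all-inactive set receives the sentinel POD (1000 uM by default).
#'
#' @param sentinel_um Sentinel POD in uM for all-inactive sets.
#' @param quantile_type Percentile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @param min_prefixes Assay-set name prefixes aggregated by minimum.
#' @return A policy list consumed by [pod_set()].
#' @export
default_pod_policy <- function(sentinel_um = 1000, quantile_type = 7,
                               min_prefixes = c("ACEA", "HTPP",
                                                "Zebrafish")) {
  stopifnot(sentinel_um > 0, quantile_type %in% 1:9)
  list(sentinel_um = sentinel_um, quantile_type = quantile_type,
       min_prefixes = min_prefixes)
}

# aggregation rule ("P5" or "MIN") for one assay set name
pod_rule_for <- function(assay_set, policy) {
  hits <- vapply(policy$min_prefixes, function(p) startsWith(assay_set, p),
                 logical(1))
  if (any(hits)) "MIN" else "P5"
}

#' Read endpoint-level in vitro assay results
#'
#' @param path CSV with columns `dtxsid`, `assay_set`, `endpoint_id`,
#'   `potency_um`, `potency_kind`, `hitcall` and optionally
#'   `caution_flags`, `model_top`, `cutoff`, `n_concs`, `min_conc_um`,
#'   `max_conc_um`.
#' @return Tibble of validated endpoint results. `hitcall` accepts the
#'   labels `active`/`inactive`/`undetermined` or the numeric codes
#'   1/0/-1.
#' @export
read_assay_results <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("dtxsid", "assay_set", "endpoint_id", "potency_um",
                "potency_kind", "hitcall")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("assay file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("caution_flags", "model_top", "cutoff", "n_concs",
                "min_conc_um", "max_conc_um")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  hit <- df$hitcall
  hit[hit == "1"] <- "active"
  hit[hit == "0"] <- "inactive"
  hit[hit == "-1"] <- "undetermined"
  bad_hit <- setdiff(unique(hit), HITCALLS)
  if (length(bad_hit) > 0) {
    stop("unknown hitcall value(s): ", paste(bad_hit, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    dtxsid = df$dtxsid,
    assay_set = df$assay_set,
    endpoint_id = df$endpoint_id,
    potency_um = suppressWarnings(as.numeric(df$potency_um)),
    potency_kind = df$potency_kind,
    hitcall = hit,
    caution_flags = suppressWarnings(as.integer(df$caution_flags)),
    model_top = suppressWarnings(as.numeric(df$model_top)),
    cutoff = suppressWarnings(as.numeric(df$cutoff)),
    n_concs = suppressWarnings(as.integer(df$n_concs)),
    min_conc_um = suppressWarnings(as.numeric(df$min_conc_um)),
    max_conc_um = suppressWarnings(as.numeric(df$max_conc_um))
  )
  if (any(out$hitcall == "active" & (is.na(out$potency_um) |
                                     out$potency_um <= 0))) {
    stop("active endpoints must have potency > 0", call. = FALSE)
  }
  out
}

#' Filter low-confidence developmental-neurotoxicity curves
#'
#' Applies the three curve-quality criteria used for the developmental
#' neurotoxicity (DNT) battery: a hit is demoted to inactive, and its
#' potency cleared, when (1) the curve carries three or more caution flags;
#' (2) it is a positive curve whose model top is at or below 1.2 times the
#' response cutoff and whose fitted potency falls below the lowest tested
#' concentration; or (3) the hitcall is undetermined (a concentration series
#' with fewer than four concentrations). Non-DNT records pass through
#' unchanged; the filter is idempotent.
#'
#' @param results Tibble of endpoint results (see [read_assay_results()]).
#' @return The input tibble with demoted hitcalls and a logical
#'   `dnt_filtered` column recording which rows were changed.
#' @export
dnt_filter <- function(results) {
  is_dnt <- startsWith(results$assay_set, "DNT")
  flags <- !is.na(results$caution_flags) & results$caution_flags >= 3
  low_top <- results$hitcall == "active" &
    !is.na(results$model_top) & !is.na(results$cutoff) &
    results$model_top <= 1.2 * results$cutoff &
    !is.na(results$potency_um) & !is.na(results$min_conc_um) &
    results$potency_um < results$min_conc_um
  undetermined <- results$hitcall == "undetermined" |
    (!is.na(results$n_concs) & results$n_concs < 4)
  demote <- is_dnt & (flags | low_top | undetermined)
  results$hitcall[demote] <- "inactive"
  results$potency_um[demote] <- NA_real_
  # sticky across repeated application, so the filter is idempotent
  prev <- if ("dnt_filtered" %in% names(results)) results$dnt_filtered
          else FALSE
  results$dnt_filtered <- prev | demote
  results
}

#' Set-level point of departure for one chemical and assay set
#'
#' Aggregates the active endpoint potencies of a single chemical within a
#' single assay set into its set-level POD under the policy's rule for that
#' set (5th percentile or minimum). A set with no active endpoints receives
#' the sentinel POD and is marked censored.
#'
#' @param results Endpoint results for exactly one chemical x assay set.
#' @param policy Aggregation policy from [default_pod_policy()].
#' @return One-row tibble: `dtxsid`, `assay_set`, `pod_set_um`, `n_active`,
#'   `censored`, `max_conc_um` (largest tested concentration seen, for
#'   reporting alongside censored PODs).
#' @export
pod_set <- function(results, policy = default_pod_policy()) {
  if (length(unique(results$dtxsid)) != 1 ||
      length(unique(results$assay_set)) != 1) {
    stop("pod_set() expects results for exactly one chemical and assay set",
         call. = FALSE)
  }
  assay_set <- results$assay_set[1]
  active <- results$hitcall == "active"
  pot <- results$potency_um[active]
  max_conc <- if (all(is.na(results$max_conc_um))) NA_real_ else
    max(results$max_conc_um, na.rm = TRUE)
  if (length(pot) == 0) {
    return(tibble::tibble(dtxsid = results$dtxsid[1], assay_set = assay_set,
                          pod_set_um = policy$sentinel_um, n_active = 0L,
                          censored = TRUE, max_conc_um = max_conc))
  }
  if (any(is.na(pot) | pot <= 0)) {
    stop("active endpoints must have potency > 0", call. = FALSE)
  }
  pod <- switch(pod_rule_for(assay_set, policy),
    MIN = min(pot),
    P5 = unname(stats::quantile(pot, probs = 0.05,
                                type = policy$quantile_type))
  )
  tibble::tibble(dtxsid = results$dtxsid[1], assay_set = assay_set,
                 pod_set_um = pod, n_active = length(pot),
                 censored = FALSE, max_conc_um = max_conc)
}

#' Set-level PODs for a full endpoint table
#'
#' Convenience wrapper applying [pod_set()] to every chemical x assay-set
#' combination present in an endpoint table, after the DNT curve filter.
#'
#' @inheritParams pod_set
#' @param apply_dnt_filter Apply [dnt_filter()] first (default `TRUE`).
#' @return Tibble of set-level PODs, one row per chemical x assay set.
#' @export
pod_set_all <- function(results, policy = default_pod_policy(),
                        apply_dnt_filter = TRUE) {
  if (apply_dnt_filter) results <- dnt_filter(results)
  results |>
    dplyr::group_by(.data$dtxsid, .data$assay_set) |>
    dplyr::group_map(~ pod_set(dplyr::mutate(.x, dtxsid = .y$dtxsid,
                                             assay_set = .y$assay_set),
                               policy = policy)) |>
    dplyr::bind_rows()
}

#' Chemical-level point of departure
#'
#' The chemical-level POD is the minimum over that chemical's set-level
#' PODs; ties are broken by lexicographic assay-set name so the driving set
#' is deterministic. The uM value is converted to ng/mL with the chemical's
#' molecular weight; a chemical is censored only when every contributing
#' set was censored.
#'
#' @param set_pods Tibble of set-level PODs (see [pod_set_all()]).
#' @param roster Chemical roster with an `mw` column (see [load_roster()]).
#' @return Tibble: `dtxsid`, `pod_chemical_um`, `pod_chemical_ngml`
#'   (`NA` with a warning when the roster has no molecular weight),
#'   `driving_set`, `censored`, `n_sets`.
#' @export
pod_chemical <- function(set_pods, roster) {
  if (nrow(set_pods) == 0) stop("no set-level PODs supplied", call. = FALSE)
  out <- set_pods |>
    dplyr::group_by(.data$dtxsid) |>
    dplyr::arrange(.data$pod_set_um, .data$assay_set, .by_group = TRUE) |>
    dplyr::summarise(
      pod_chemical_um = .data$pod_set_um[1],
      driving_set = .data$assay_set[1],
      censored = all(.data$censored),
      n_sets = dplyr::n(),
      .groups = "drop"
    )
  out <- dplyr::left_join(out, roster[, c("dtxsid", "mw")], by = "dtxsid")
  if (anyNA(out$mw)) {
    warning("no molecular weight for: ",
            paste(out$dtxsid[is.na(out$mw)], collapse = ", "),
            "; pod_chemical_ngml left NA", call. = FALSE)
  }
  out$pod_chemical_ngml <- ifelse(is.na(out$mw), NA_real_,
                                  out$pod_chemical_um * out$mw)
  out[, c("dtxsid", "pod_chemical_um", "pod_chemical_ngml", "driving_set",
          "censored", "n_sets")]
}
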