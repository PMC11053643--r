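# Ingest of population-level biomonitoring summary records, matrix-to-plasma
# harmonization, metric grouping and QC flagging.

BCBCR_MATRICES <- c("whole_blood", "serum", "plasma", "cord_blood",
                    "cord_serum", "cord_plasma", "blood_spot")

# matrices quantified on the whole-blood scale: converted to plasma by
# dividing by the blood-to-plasma concentration ratio
BLOOD_LIKE_MATRICES <- c("whole_blood", "cord_blood", "blood_spot")

BCBCR_METRICS <- c("p5", "p10", "p25", "p50", "p75", "p90", "p95", "p98",
                   "p99", "maximum", "minimum", "mean", "median")

#' Normalize a reported concentration-metric label
#'
#' Biomonitoring studies report summary statistics under many spellings.
#' All flavours of mean (arithmetic, geometric, "average") are designated
#' means; percentile spellings such as `"50th percentile"` or `"P50"`
#' collapse to `p50`. Labels that cannot be classified raise an error
#' naming the offending label rather than being silently dropped.
#'
#' @param raw_label Character vector of reported metric labels.
#' @return Character vector of canonical metrics (one of
#'   `r paste(BCBCR_METRICS, collapse = ", ")`).
#' @examples
#' normalize_metric(c("geometric mean", "95th percentile", "Median"))
#' @export
normalize_metric <- function(raw_label) {
  stopifnot(is.character(raw_label), all(nzchar(raw_label)))
  lab <- tolower(trimws(raw_label))
  out <- rep(NA_character_, length(lab))
  out[lab %in% c("mean", "arithmetic mean", "geometric mean", "average",
                 "geomean", "gm")] <- "mean"
  out[lab %in% c("median", "med")] <- "median"
  out[lab %in% c("maximum", "max")] <- "maximum"
  out[lab %in% c("minimum", "min")] <- "minimum"
  pct <- grepl("^([0-9]{1,2})(st|nd|rd|th)?( percentile)?$|^p[0-9]{1,2}$",
               lab)
  num <- suppressWarnings(as.integer(sub("^p", "", sub("(st|nd|rd|th)?( percentile)?$", "", lab))))
  known_pct <- c(5, 10, 25, 50, 75, 90, 95, 98, 99)
  ok <- pct & !is.na(num) & num %in% known_pct
  out[ok] <- paste0("p", num[ok])
  if (anyNA(out)) {
    stop("cannot classify metric label(s): ",
         paste(unique(raw_label[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Group canonical metrics into presentation strata
#'
#' Maps each summary metric into one of five strata used when plotting and
#' summarising: `high` (above the 75th percentile, including the maximum),
#' `p75`, `p50` (50th percentile, mean and median), `p25`, and `low`
#' (below the 25th percentile, including the minimum). The mapping is total
#' over the metric vocabulary.
#'
#' @param metric Character vector of canonical metrics (see
#'   [normalize_metric()]).
#' @return Factor with levels `high`, `p75`, `p50`, `p25`, `low`.
#' @examples
#' group_metric(c("p95", "mean", "minimum"))
#' @export
group_metric <- function(metric) {
  bad <- setdiff(unique(metric), BCBCR_METRICS)
  if (length(bad) > 0) {
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  map <- c(p90 = "high", p95 = "high", p98 = "high", p99 = "high",
           maximum = "high",
           p75 = "p75",
           p50 = "p50", mean = "p50", median = "p50",
           p25 = "p25",
           p5 = "low", p10 = "low", minimum = "low")
  factor(unname(map[metric]), levels = c("high", "p75", "p50", "p25", "low"))
}

#' Read long-format biomonitoring records
#'
#' Reads a CSV of population-level summary concentrations, one statistic per
#' row. Metric labels are normalized via [normalize_metric()] and all
#' concentrations are converted to ng/mL: accepted unit spellings are
#' `ng/mL` and the equivalent `ug/L` (factor 1), and `ug/mL` (factor 1000).
#' Rows whose value is non-numeric (e.g. reported only as "<LOD") are
#' rejected with an error rather than imputed. A missing `population_class`
#' defaults to `general` with a warning.
#'
#' @param path Path to a biomonitoring CSV with columns `snaid`, `dtxsid`,
#'   `matrix`, `metric`, `value` and optionally `location`, `cohort`,
#'   `population_class`, `unit`, `lod`, `loq`, `n_subjects`.
#' @return Tibble of validated records with `value`, `lod`, `loq` in ng/mL.
#' @export
read_biomonitoring <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("snaid", "dtxsid", "matrix", "metric", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("biomonitoring file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("location", "cohort", "population_class", "unit", "lod",
                "loq", "n_subjects")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (any(!nzchar(df$snaid) | is.na(df$snaid))) {
    stop("snaid must be non-empty for every record", call. = FALSE)
  }
  bad_matrix <- setdiff(unique(df$matrix), BCBCR_MATRICES)
  if (length(bad_matrix) > 0) {
    stop("unknown matrix value(s): ", paste(bad_matrix, collapse = ", "),
         call. = FALSE)
  }
  df$metric <- normalize_metric(df$metric)

  value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(value)) {
    bad <- unique(df$value[is.na(value)])
    stop("non-numeric concentration value(s) (e.g. censored '<LOD' ",
         "entries are not imputed): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(value < 0)) stop("concentrations must be >= 0", call. = FALSE)

  unit <- tolower(ifelse(is.na(df$unit), "ng/ml", df$unit))
  unit <- gsub("µ", "u", unit)  # micro sign -> u
  factor <- dplyr::case_when(
    unit %in% c("ng/ml", "ug/l", "ppb") ~ 1,
    unit %in% c("ug/ml", "mg/l", "ppm") ~ 1000,
    TRUE ~ NA_real_
  )
  if (anyNA(factor)) {
    stop("unrecognized concentration unit(s): ",
         paste(unique(df$unit[is.na(factor)]), collapse = ", "),
         call. = FALSE)
  }

  pop <- df$population_class
  if (any(is.na(pop) | !nzchar(pop))) {
    warning("population_class missing for ",
            sum(is.na(pop) | !nzchar(pop)),
            " record(s); defaulting to 'general'", call. = FALSE)
    pop[is.na(pop) | !nzchar(pop)] <- "general"
  }
  bad_pop <- setdiff(unique(pop), c("exposed", "general"))
  if (length(bad_pop) > 0) {
    stop("population_class must be 'exposed' or 'general', got: ",
         paste(bad_pop, collapse = ", "), call. = FALSE)
  }

  tibble::tibble(
    snaid = df$snaid,
    dtxsid = df$dtxsid,
    location = df$location,
    cohort = df$cohort,
    population_class = pop,
    matrix = df$matrix,
    metric = df$metric,
    metric_group = group_metric(df$metric),
    value = value * factor,
    lod = suppressWarnings(as.numeric(df$lod)) * factor,
    loq = suppressWarnings(as.numeric(df$loq)) * factor,
    n_subjects = suppressWarnings(as.integer(df$n_subjects))
  )
}

#' Convert biomonitoring records to plasma-equivalent concentrations
#'
#' Serum and plasma matrices (including cord serum/plasma) are taken as
#' plasma directly (factor 1). Whole blood, cord blood and blood spots are
#' divided by the chemical's blood-to-plasma concentration ratio (Rb2p):
#' `c(plasma) = c(whole blood) / Rb2p`. The ratio is looked up in the
#' roster; a measured in vivo ratio takes precedence over an in vitro
#' prediction when the roster distinguishes them via `rb2p_source`, and
#' chemicals with no ratio at all fall back to `default_rb2p` (0.5, typical
#' of the measured range for PFAS). Every record yields exactly one output
#' row; duplicates in the input are deliberately retained.
#'
#' @param records Tibble of biomonitoring records (see
#'   [read_biomonitoring()]).
#' @param roster Chemical roster tibble (see [load_roster()]).
#' @param default_rb2p Blood-to-plasma ratio applied when the roster has
#'   none for a chemical. Default 0.5.
#' @return The input records with added columns `plasma_value` (ng/mL),
#'   `conversion_factor` and `rb2p_source` (`measured_in_vivo`,
#'   `in_vitro_predicted` or `default`).
#' @export
to_plasma <- function(records, roster, default_rb2p = 0.5) {
  stopifnot(default_rb2p > 0)
  if (any(records$value < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  lk <- roster[, c("dtxsid", "rb2p", "rb2p_source")]
  out <- dplyr::left_join(records, lk, by = "dtxsid")
  if (any(!is.na(out$rb2p) & out$rb2p <= 0)) {
    stop("rb2p must be > 0", call. = FALSE)
  }
  blood_like <- out$matrix %in% BLOOD_LIKE_MATRICES
  rb2p_eff <- ifelse(is.na(out$rb2p), default_rb2p, out$rb2p)
  source_eff <- dplyr::case_when(
    !blood_like ~ NA_character_,
    is.na(out$rb2p) ~ "default",
    !is.na(out$rb2p_source) ~ out$rb2p_source,
    TRUE ~ "in_vitro_predicted"
  )
  out$conversion_factor <- ifelse(blood_like, 1 / rb2p_eff, 1)
  out$plasma_value <- out$value * out$conversion_factor
  out$rb2p_source <- source_eff
  out$rb2p <- NULL
  out
}

#' Flag plasma concentrations above a QC review threshold
#'
#' Records with a plasma-equivalent value strictly above `threshold` are
#' returned for manual review against their source documents; high values
#' dominate the screening ratio, so transcription errors there matter most.
#' The input is not mutated and no record is dropped.
#'
#' @param records Tibble with a `plasma_value` column (see [to_plasma()]).
#' @param threshold QC threshold in ng/mL; default 100.
#' @return The subset of `records` with `plasma_value > threshold`, with a
#'   `qc_flag` column set to `"review"`.
#' @export
qc_flag <- function(records, threshold = 100) {
  stopifnot(threshold > 0)
  flagged <- records[!is.na(records$plasma_value) &
                       records$plasma_value > threshold, , drop = FALSE]
  flagged$qc_flag <- rep("review", nrow(flagged))
  flagged
}
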