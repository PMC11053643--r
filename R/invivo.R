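# In vivo PODs from the 28-day rat study table (lowest effect levels per
# chemical and sex, with plasma concentration at the lowest LEL) and the
# comparison of in vitro set-level PODs against those internal
# concentrations.

INVIVO_PHENOTYPES <- c("liver_weight", "relative_liver_weight",
                       "kidney_weight", "relative_kidney_weight",
                       "decreased_hematocrit", "decreased_cholesterol",
                       "decreased_t3", "decreased_free_t4",
                       "decreased_total_t4")

#' Load the in vivo lowest-effect-level table
#'
#' Reads the packaged (or a same-schema) table of 28-day oral rat study
#' results: one row per chemical x sex, nine phenotype columns holding
#' lowest effect levels (LELs) in mg/kg-day (`NA` when the phenotype showed
#' no significant change at any dose), and the measured plasma
#' concentration (ng/mL) at the lowest LEL dose.
#'
#' @param path CSV path; defaults to the packaged table covering PFBS,
#'   PFDA, PFHxA, PFHxSK, PFNA, PFOA and PFOS in both sexes.
#' @return Tibble with columns `name`, `sex`, the nine phenotype LELs and
#'   `plasma_at_lowest_lel`.
#' @export
load_invivo <- function(path = system.file("extdata", "ntp_invivo_lel.csv",
                                           package = "bcbcr",
                                           mustWork = TRUE)) {
  df <- readr::read_csv(path, col_types = readr::cols(
    name = "c", sex = "c", .default = "d"), progress = FALSE,
    na = c("", "NA"))
  missing_cols <- setdiff(c("name", "sex", INVIVO_PHENOTYPES,
                            "plasma_at_lowest_lel"), names(df))
  if (length(missing_cols) > 0) {
    stop("in vivo table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("sex must be male or female, got: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  lels <- as.matrix(df[, INVIVO_PHENOTYPES])
  if (any(rowSums(!is.na(lels)) == 0)) {
    stop("every row must have at least one non-missing LEL", call. = FALSE)
  }
  if (any(lels <= 0, na.rm = TRUE)) {
    stop("LELs must be > 0", call. = FALSE)
  }
  df
}

#' Lowest effect level per chemical and sex
#'
#' For each row (chemical x sex) returns the minimum over the non-missing
#' phenotype LELs — the in vivo POD — together with every phenotype
#' attaining it.
#'
#' @param invivo Tibble from [load_invivo()].
#' @return Tibble: `name`, `sex`, `lowest_lel` (mg/kg-day), `phenotypes`
#'   (comma-separated names attaining the minimum), `plasma_at_lowest_lel`
#'   (ng/mL).
#' @examples
#' lowest_lel(load_invivo())
#' @export
lowest_lel <- function(invivo) {
  lels <- as.matrix(invivo[, INVIVO_PHENOTYPES])
  if (any(rowSums(!is.na(lels)) == 0)) {
    stop("every row must have at least one non-missing LEL", call. = FALSE)
  }
  mins <- apply(lels, 1, min, na.rm = TRUE)
  phen <- vapply(seq_len(nrow(lels)), function(i) {
    paste(INVIVO_PHENOTYPES[!is.na(lels[i, ]) & lels[i, ] == mins[i]],
          collapse = ",")
  }, character(1))
  tibble::tibble(name = invivo$name, sex = invivo$sex, lowest_lel = mins,
                 phenotypes = phen,
                 plasma_at_lowest_lel = invivo$plasma_at_lowest_lel)
}

#' Compare in vitro set-level PODs with in vivo internal concentrations
#'
#' For each chemical present in both inputs, forms the closed interval
#' spanned by the male and female plasma concentrations at the lowest LEL
#' and flags every in vitro set-level POD (converted to ng/mL) as
#' `below_range`, `in_range` or `above_range`. A POD equal to an interval
#' endpoint counts as in range. The summary counts chemicals whose in vitro
#' POD range (min to max over assay sets) overlaps the in vivo interval.
#'
#' @param set_pods Tibble of set-level PODs with a `pod_set_ngml` column
#'   (uM PODs converted via the chemical's molecular weight) and an
#'   `abbreviation` or `name` column matching the in vivo `name`.
#' @param invivo Tibble from [load_invivo()].
#' @return List with `table` (one row per chemical x assay set:
#'   `name`, `assay_set`, `pod_set_ngml`, `invivo_lo`, `invivo_hi`,
#'   `flag`) and `summary` (per chemical overlap indicator plus the count
#'   `n_overlap`).
#' @export
compare_invitro_invivo <- function(set_pods, invivo) {
  name_col <- if ("name" %in% names(set_pods)) "name" else "abbreviation"
  if (!name_col %in% names(set_pods)) {
    stop("set_pods needs a 'name' or 'abbreviation' column", call. = FALSE)
  }
  if (!"pod_set_ngml" %in% names(set_pods)) {
    stop("set_pods needs a 'pod_set_ngml' column (PODs in ng/mL)",
         call. = FALSE)
  }
  ranges <- lowest_lel(invivo) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(invivo_lo = min(.data$plasma_at_lowest_lel),
                     invivo_hi = max(.data$plasma_at_lowest_lel),
                     .groups = "drop")
  tab <- set_pods |>
    dplyr::rename(name = dplyr::all_of(name_col)) |>
    dplyr::inner_join(ranges, by = "name")
  if (nrow(tab) == 0) {
    stop("no chemical is present in both inputs", call. = FALSE)
  }
  tab$flag <- dplyr::case_when(
    tab$pod_set_ngml < tab$invivo_lo ~ "below_range",
    tab$pod_set_ngml > tab$invivo_hi ~ "above_range",
    TRUE ~ "in_range"
  )
  summary <- tab |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      pod_min = min(.data$pod_set_ngml),
      pod_max = max(.data$pod_set_ngml),
      invivo_lo = .data$invivo_lo[1],
      invivo_hi = .data$invivo_hi[1],
      .groups = "drop"
    )
  summary$overlaps <- summary$pod_min <= summary$invivo_hi &
    summary$pod_max >= summary$invivo_lo
  list(
    table = tab[, c("name", "assay_set", "pod_set_ngml", "invivo_lo",
                    "invivo_hi", "flag")],
    summary = summary,
    n_overlap = sum(summary$overlaps)
  )
}
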