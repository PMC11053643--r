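# End-to-end orchestration: read the three inputs, harmonize, aggregate,
# compute and classify BCBCR values, rank, and write tables and figures.

#' Run the full BCBCR screening pipeline
#'
#' Reads a roster, a long-format biomonitoring table and an endpoint-level
#' assay table; converts all concentrations to plasma-equivalent ng/mL;
#' aggregates endpoint potencies into set-level and chemical-level PODs
#' (after the DNT curve filter); computes BCBCR values per chemical x
#' population x metric; classifies and ranks; and writes the result tables
#' (`bcbcr_results.csv`, `ranking.csv`, `set_pods.csv`, `qc_flags.csv`)
#' plus four figures to `output_dir`. The pipeline is a pure function of
#' its inputs and configuration: identical reruns produce identical CSVs.
#'
#' @param roster_path,biomonitoring_path,assays_path Input CSV paths in the
#'   documented ingest schemas.
#' @param output_dir Directory for outputs (created if needed).
#' @param default_rb2p Blood-to-plasma ratio fallback, default 0.5.
#' @param qc_threshold_ngml Plasma QC review threshold, default 100.
#' @param thresholds BCBCR classification thresholds.
#' @param policy POD aggregation policy, see [default_pod_policy()].
#' @param write_figures Write the four PNG figures (default `TRUE`).
#' @return Invisibly, a result bundle: `plasma`, `set_pods`, `chem_pods`,
#'   `results`, `ranking`, `qc_flags`, `files` (paths written).
#' @export
run_bcbcr_pipeline <- function(roster_path, biomonitoring_path, assays_path,
                               output_dir,
                               default_rb2p = 0.5,
                               qc_threshold_ngml = 100,
                               thresholds = c(1, 100, 1000, 10000),
                               policy = default_pod_policy(),
                               write_figures = TRUE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  roster <- load_roster(roster_path)
  records <- read_biomonitoring(biomonitoring_path)
  assays <- read_assay_results(assays_path)

  plasma <- to_plasma(records, roster, default_rb2p = default_rb2p)
  flags <- qc_flag(plasma, threshold = qc_threshold_ngml)
  set_pods <- pod_set_all(assays, policy = policy)
  chem_pods <- pod_chemical(set_pods, roster)
  results <- compute_bcbcr(plasma, chem_pods, roster,
                           thresholds = thresholds)
  ranking <- rank_chemicals(results)

  files <- list(
    results = file.path(output_dir, "bcbcr_results.csv"),
    ranking = file.path(output_dir, "ranking.csv"),
    set_pods = file.path(output_dir, "set_pods.csv"),
    qc_flags = file.path(output_dir, "qc_flags.csv")
  )
  readr::write_csv(results, files$results, na = "")
  readr::write_csv(ranking, files$ranking, na = "")
  readr::write_csv(set_pods, files$set_pods, na = "")
  readr::write_csv(flags, files$qc_flags, na = "")

  if (write_figures) {
    set_pods_ngml <- dplyr::left_join(
      set_pods, roster[, c("dtxsid", "abbreviation", "mw")], by = "dtxsid")
    set_pods_ngml$pod_set_ngml <-
      set_pods_ngml$pod_set_um * set_pods_ngml$mw
    figs <- list(
      chemical_summary = plot_chemical_summary(
        dplyr::left_join(plasma, roster[, c("dtxsid", "abbreviation")],
                         by = "dtxsid"),
        set_pods_ngml),
      bcbcr_ranking = plot_bcbcr_ranking(results),
      chain_length = if (any(!is.na(chain_length(roster$smiles)))) {
        plot_chain_length(plasma, roster)
      },
      invitro_invivo = NULL
    )
    for (nm in names(figs)) {
      if (is.null(figs[[nm]])) next
      path <- file.path(output_dir, paste0("fig_", nm, ".png"))
      ggplot2::ggsave(path, figs[[nm]], width = 9, height = 6, dpi = 150)
      files[[paste0("fig_", nm)]] <- path
    }
  }
  invisible(list(plasma = plasma, set_pods = set_pods,
                 chem_pods = chem_pods, results = results,
                 ranking = ranking, qc_flags = flags, files = files))
}

# exposed = orange, general = blue, throughout the figures
POP_COLOURS <- c(exposed = "#E69F00", general = "#0072B2")

#' Per-chemical biomonitoring summary figure
#'
#' Boxplots of plasma-equivalent concentrations by metric group (High,
#' 75th, 50th, 25th, Low) for each chemical, points coloured by population
#' class, with vertical lines at the set-level PODs. Log10 concentration
#' axis.
#'
#' @param plasma Plasma records joined with an `abbreviation` column.
#' @param set_pods_ngml Set-level PODs with `abbreviation` and
#'   `pod_set_ngml` columns; censored sets are dropped from the overlay.
#' @return A ggplot object.
#' @export
plot_chemical_summary <- function(plasma, set_pods_ngml) {
  pods <- set_pods_ngml[!set_pods_ngml$censored &
                          !is.na(set_pods_ngml$pod_set_ngml), , drop = FALSE]
  ggplot2::ggplot(plasma,
                  ggplot2::aes(x = .data$plasma_value,
                               y = .data$metric_group)) +
    ggplot2::geom_boxplot(outlier.shape = 1, fill = "grey92") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$population_class),
                         height = 0.15, size = 0.9, alpha = 0.7) +
    ggplot2::geom_vline(data = pods,
                        ggplot2::aes(xintercept = .data$pod_set_ngml,
                                     linetype = .data$assay_set),
                        linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = POP_COLOURS) +
    ggplot2::facet_wrap(~abbreviation, scales = "free_x") +
    ggplot2::labs(x = "plasma concentration (ng/mL)", y = "metric group",
                  colour = "population", linetype = "assay set POD")
}

#' BCBCR ranking figure
#'
#' One row per chemical (ordered by minimum BCBCR), each point one
#' population x metric ratio, boxes summarising the distribution, log10
#' ratio axis with a reference line at 1.
#'
#' @param results BCBCR results (see [compute_bcbcr()]).
#' @return A ggplot object.
#' @export
plot_bcbcr_ranking <- function(results) {
  ord <- rank_chemicals(results)
  results$abbreviation <- factor(results$abbreviation,
                                 levels = rev(ord$abbreviation))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$bcbcr,
                                        y = .data$abbreviation)) +
    ggplot2::geom_boxplot(outlier.shape = 1, fill = "grey92") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$population_class),
                         height = 0.15, size = 0.9, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = POP_COLOURS) +
    ggplot2::labs(x = "BCBCR (in vitro POD / plasma concentration)",
                  y = NULL, colour = "population")
}

#' Plasma concentration by perfluorinated chain length
#'
#' Boxplots of plasma-equivalent concentrations grouped by the chain length
#' computed from each chemical's structure; chemicals without structures
#' are excluded (their chain length is missing, not zero).
#'
#' @param plasma Plasma records (see [to_plasma()]).
#' @param roster Roster with a `smiles` column.
#' @return A ggplot object.
#' @export
plot_chain_length <- function(plasma, roster) {
  cl <- tibble::tibble(
    dtxsid = roster$dtxsid,
    chain_length = chain_length(roster$smiles)
  )
  df <- dplyr::inner_join(plasma, cl, by = "dtxsid")
  df <- df[!is.na(df$chain_length), , drop = FALSE]
  df$chain_length <- factor(df$chain_length,
                            levels = sort(unique(df$chain_length)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chain_length,
                                   y = .data$plasma_value)) +
    ggplot2::geom_boxplot(outlier.shape = 1, fill = "grey92") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$population_class),
                         width = 0.15, size = 0.9, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = POP_COLOURS) +
    ggplot2::labs(x = "maximum contiguous fully fluorinated carbons",
                  y = "plasma concentration (ng/mL)", colour = "population")
}

#' In vitro vs in vivo comparison figure
#'
#' For each chemical with 28-day rat data, plots the in vitro set-level
#' PODs (points, one per assay set) against vertical lines at the male and
#' female plasma concentrations at the lowest in vivo effect level.
#'
#' @param comparison Output of [compare_invitro_invivo()].
#' @param invivo Tibble from [load_invivo()] (for the per-sex lines).
#' @return A ggplot object.
#' @export
plot_invitro_invivo <- function(comparison, invivo) {
  lines <- lowest_lel(invivo)
  ggplot2::ggplot(comparison$table,
                  ggplot2::aes(x = .data$pod_set_ngml,
                               y = .data$name)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$assay_set), size = 2) +
    ggplot2::geom_segment(
      data = lines,
      ggplot2::aes(x = .data$plasma_at_lowest_lel,
                   xend = .data$plasma_at_lowest_lel,
                   y = as.numeric(factor(.data$name)) - 0.35,
                   yend = as.numeric(factor(.data$name)) + 0.35,
                   linetype = .data$sex),
      inherit.aes = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (ng/mL)", y = NULL,
                  colour = "assay set",
                  linetype = "plasma at lowest LEL")
}

#' @importFrom rlang .data %||%
NULL
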