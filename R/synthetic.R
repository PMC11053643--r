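# Synthetic biomonitoring, assay and roster inputs with known ground truth,
# so every pipeline stage can be validated end to end without external data.

# Stable 32-bit seed fan-out: one global seed plus a string key gives each
# spec its own stream, so adding a spec does not perturb the others.
fanout_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Specify a synthetic biomonitoring population
#'
#' One population summary extract: log-normal plasma concentrations with
#' geometric mean `gm` (ng/mL) and geometric standard deviation `gsd`,
#' reported in a given matrix. For blood-like matrices the individual
#' plasma values are moved to the whole-blood scale with the true
#' blood-to-plasma ratio `rb2p_true` before summarizing, so that the
#' pipeline's matrix conversion can be checked against known truth.
#'
#' @param dtxsid Chemical identifier.
#' @param snaid Study/data-set code.
#' @param population_class `"exposed"` or `"general"`.
#' @param gm Geometric mean plasma concentration, ng/mL (> 0).
#' @param gsd Geometric standard deviation (> 1).
#' @param n_subjects Number of simulated subjects (>= 5).
#' @param matrix Reporting matrix (see `BCBCR_MATRICES`).
#' @param lod Limit of detection, ng/mL.
#' @param rb2p_true True blood-to-plasma ratio used when reporting in a
#'   blood-like matrix.
#' @return A population spec (list) consumed by [simulate_population()].
#' @export
population_spec <- function(dtxsid, snaid, population_class = "general",
                            gm = 5, gsd = 2, n_subjects = 500,
                            matrix = "serum", lod = 0.05, rb2p_true = 0.5) {
  stopifnot(gm > 0, gsd >= 1, n_subjects >= 5,
            matrix %in% BCBCR_MATRICES,
            population_class %in% c("exposed", "general"),
            rb2p_true > 0)
  list(dtxsid = dtxsid, snaid = snaid,
       population_class = population_class, gm = gm, gsd = gsd,
       n_subjects = n_subjects, matrix = matrix, lod = lod,
       rb2p_true = rb2p_true)
}

#' Simulate one population's biomonitoring summary records
#'
#' Draws `n_subjects` individual plasma concentrations from
#' LogNormal(log gm, log gsd), converts them to the reporting matrix scale
#' (multiplying by the true blood-to-plasma ratio for blood-like matrices),
#' and emits one record per summary metric (percentiles 5-99, minimum,
#' maximum, mean, median) in the long-format ingest schema. Deterministic
#' given `seed`: the global seed is fanned out per spec by a stable string
#' hash.
#'
#' @param spec Population spec from [population_spec()].
#' @param seed Global integer seed.
#' @return Tibble of biomonitoring records (ingest schema, values ng/mL).
#' @export
simulate_population <- function(spec, seed = 1) {
  # the reporting matrix is not part of the key: the same cohort reported
  # in plasma and in whole blood shares its underlying individuals, so
  # matrix conversion can be checked for exact recovery
  local_seed <- fanout_seed(seed, paste(spec$dtxsid, spec$snaid,
                                        spec$population_class, sep = "|"))
  plasma <- withr::with_seed(local_seed,
    stats::rlnorm(spec$n_subjects, meanlog = log(spec$gm),
                  sdlog = log(spec$gsd)))
  scale <- if (spec$matrix %in% BLOOD_LIKE_MATRICES) spec$rb2p_true else 1
  x <- plasma * scale
  pct <- c(5, 10, 25, 50, 75, 90, 95, 98, 99)
  values <- c(stats::quantile(x, probs = pct / 100, type = 7, names = FALSE),
              max(x), min(x), mean(x), stats::median(x))
  tibble::tibble(
    snaid = spec$snaid,
    dtxsid = spec$dtxsid,
    location = "synthetic",
    cohort = paste0("synthetic ", spec$population_class, " cohort"),
    population_class = spec$population_class,
    matrix = spec$matrix,
    metric = c(paste0("p", pct), "maximum", "minimum", "mean", "median"),
    value = values,
    unit = "ng/mL",
    lod = spec$lod,
    loq = NA_real_,
    n_subjects = spec$n_subjects
  )
}

#' Simulate endpoint-level assay results with known true PODs
#'
#' For each assay set with an active true POD, draws `n_endpoints` i.i.d.
#' log-normal endpoint potencies whose aggregation statistic recovers the
#' truth: under the 5th-percentile rule the population 5th percentile
#' equals the true POD, and under the minimum rule the sampling median of
#' the minimum equals it (the minimum of n i.i.d. draws has its median at
#' quantile 1 - 0.5^(1/n)). With `noise = 0` every draw equals the truth
#' exactly. Inactive sets emit all-inactive endpoints. For DNT sets three
#' additional low-confidence curves are injected, one per filter criterion
#' (>= 3 caution flags; low model top with potency below the tested range;
#' undetermined hitcall), each carrying a potency far below the truth so
#' that an unfiltered pipeline would visibly corrupt the POD.
#'
#' @param dtxsid Chemical identifier.
#' @param true_pods Named numeric vector or list, assay set -> true POD in
#'   uM, with `NA` marking an inactive set.
#' @param noise Log-scale standard deviation of endpoint potencies
#'   (natural log), default 0.2.
#' @param n_endpoints Active endpoints per set, default 20.
#' @param seed Global integer seed.
#' @param policy Aggregation policy (determines the calibration rule per
#'   set), default [default_pod_policy()].
#' @param max_conc_um Top tested concentration recorded on each endpoint.
#' @return Tibble of endpoint results in the assay ingest schema.
#' @export
simulate_assays <- function(dtxsid, true_pods, noise = 0.2,
                            n_endpoints = 20, seed = 1,
                            policy = default_pod_policy(),
                            max_conc_um = 100) {
  stopifnot(length(true_pods) > 0, noise >= 0, n_endpoints >= 1)
  sets <- names(true_pods)
  if (is.null(sets) || any(!nzchar(sets))) {
    stop("true_pods must be named by assay set", call. = FALSE)
  }
  rows <- lapply(sets, function(set) {
    truth <- true_pods[[set]]
    local_seed <- fanout_seed(seed, paste(dtxsid, set, sep = "|"))
    if (is.na(truth)) {
      return(tibble::tibble(
        dtxsid = dtxsid, assay_set = set,
        endpoint_id = sprintf("%s_ep%03d", set, seq_len(n_endpoints)),
        potency_um = NA_real_, potency_kind = "AC50",
        hitcall = "inactive", caution_flags = 0L, model_top = NA_real_,
        cutoff = NA_real_, n_concs = 8L, min_conc_um = 0.1,
        max_conc_um = max_conc_um))
    }
    rule <- pod_rule_for(set, policy)
    meanlog <- if (rule == "MIN") {
      # median of the sample minimum sits at quantile 1 - 0.5^(1/n)
      log(truth) - noise * stats::qnorm(1 - 0.5^(1 / n_endpoints))
    } else {
      log(truth) - noise * stats::qnorm(0.05)
    }
    pot <- withr::with_seed(local_seed,
      stats::rlnorm(n_endpoints, meanlog = meanlog, sdlog = noise))
    active <- tibble::tibble(
      dtxsid = dtxsid, assay_set = set,
      endpoint_id = sprintf("%s_ep%03d", set, seq_len(n_endpoints)),
      potency_um = pot, potency_kind = "AC50", hitcall = "active",
      caution_flags = 0L, model_top = 3, cutoff = 1, n_concs = 8L,
      min_conc_um = 0.1, max_conc_um = max_conc_um)
    if (!startsWith(set, "DNT")) return(active)
    bad_pot <- truth / 10
    lures <- tibble::tibble(
      dtxsid = dtxsid, assay_set = set,
      endpoint_id = sprintf("%s_lure%d", set, 1:3),
      potency_um = c(bad_pot, 0.01, bad_pot),
      potency_kind = "AC50",
      hitcall = c("active", "active", "undetermined"),
      caution_flags = c(3L, 0L, 0L),
      model_top = c(3, 1.1, 3),
      cutoff = 1, n_concs = c(8L, 8L, 3L),
      min_conc_um = 0.1, max_conc_um = max_conc_um)
    dplyr::bind_rows(active, lures)
  })
  dplyr::bind_rows(rows)
}

#' Write a complete synthetic scenario to disk
#'
#' Generates the three pipeline inputs (roster, biomonitoring records,
#' assay results) for a list of chemicals with known ground truth and
#' writes them as CSVs in the ingest schemas. Each chemical entry carries a
#' `dtxsid`, `abbreviation`, `formula`, optional `smiles` and `rb2p`, a
#' list of population specs, and a named `true_pods` vector in uM.
#'
#' @param chemicals List of chemical scenario entries (see Details).
#' @param dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param noise,n_endpoints Passed to [simulate_assays()].
#' @return Invisibly, a named list of the three file paths.
#' @export
simulate_scenario <- function(chemicals, dir, seed = 1, noise = 0.2,
                              n_endpoints = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roster <- dplyr::bind_rows(lapply(chemicals, function(ch) {
    tibble::tibble(
      dtxsid = ch$dtxsid,
      casrn = ch$casrn %||% NA_character_,
      name = ch$name %||% ch$abbreviation,
      abbreviation = ch$abbreviation,
      formula = ch$formula %||% NA_character_,
      smiles = ch$smiles %||% NA_character_,
      rb2p = ch$rb2p %||% NA_real_,
      rb2p_source = ch$rb2p_source %||% NA_character_,
      halflife_class = ch$halflife_class %||% "gt_2_months")
  }))
  biomon <- dplyr::bind_rows(lapply(chemicals, function(ch) {
    dplyr::bind_rows(lapply(ch$populations, simulate_population,
                            seed = seed))
  }))
  assays <- dplyr::bind_rows(lapply(chemicals, function(ch) {
    simulate_assays(ch$dtxsid, ch$true_pods, noise = noise,
                    n_endpoints = n_endpoints, seed = seed)
  }))
  paths <- list(roster = file.path(dir, "roster.csv"),
                biomonitoring = file.path(dir, "biomonitoring.csv"),
                assays = file.path(dir, "assays.csv"))
  readr::write_csv(roster, paths$roster, na = "")
  readr::write_csv(biomon, paths$biomonitoring, na = "")
  readr::write_csv(assays, paths$assays, na = "")
  invisible(paths)
}
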