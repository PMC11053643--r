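# Shared builders and independent oracles for the test suite. Oracles are
# deliberately written without reusing the package's internal code paths.

# Independent type-7 percentile oracle: sort and linearly interpolate
# between order statistics at h = (n - 1) * p.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Independent qualifying-carbon + exhaustive path enumeration oracle for
# chain length, parsing the SMILES on its own via ChemmineR.
oracle_chain_length <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  sym <- sub("_.*$", "", rownames(ab))
  n <- length(sym)
  adj <- matrix(FALSE, n, n)
  osum <- rep(0, n)
  for (i in seq_len(nrow(bb))) {
    a <- bb[i, 1]; b <- bb[i, 2]; o <- bb[i, 3]
    adj[a, b] <- TRUE; adj[b, a] <- TRUE
    osum[a] <- osum[a] + o; osum[b] <- osum[b] + o
  }
  ok <- vapply(seq_len(n), function(i) {
    if (sym[i] != "C" || osum[i] < 4) return(FALSE)
    nb <- which(adj[i, ])
    !any(sym[nb] == "H") && any(sym[nb] == "F")
  }, logical(1))
  keep <- which(ok)
  if (length(keep) == 0) return(0L)
  best <- 0L
  extend <- function(path) {
    best <<- max(best, length(path))
    tail_node <- path[length(path)]
    for (nxt in keep) {
      if (!nxt %in% path && adj[tail_node, nxt]) extend(c(path, nxt))
    }
  }
  for (s in keep) extend(s)
  best
}

# Minimal roster tibble for unit tests.
mini_roster <- function() {
  tibble::tibble(
    dtxsid = c("DTX_A", "DTX_B", "DTX_C"),
    casrn = c("1-1-1", "2-2-2", "3-3-3"),
    name = c("chem A", "chem B", "chem C"),
    abbreviation = c("A", "B", "C"),
    formula = c("C8HF15O2", "C8HF17O3S", NA),
    smiles = NA_character_,
    mw = c(414.07, 500.13, NA),
    rb2p = c(NA, 0.5, 0.8),
    rb2p_source = c(NA, "measured_in_vivo", NA),
    halflife_class = c("gt_2_months", "gt_2_months", "lt_1_week")
  )
}

# One biomonitoring record row in the ingest (post-read) schema.
biomon_record <- function(dtxsid = "DTX_A", matrix = "serum",
                          metric = "median", value = 10,
                          population_class = "general",
                          snaid = "SNA1") {
  tibble::tibble(
    snaid = snaid, dtxsid = dtxsid, location = "here", cohort = "test",
    population_class = population_class, matrix = matrix, metric = metric,
    metric_group = group_metric(metric), value = value,
    lod = 0.05, loq = NA_real_, n_subjects = 100L
  )
}

# One endpoint-level assay result row.
assay_row <- function(dtxsid = "DTX_A", assay_set = "ATG",
                      endpoint_id = "ep1", potency_um = 10,
                      hitcall = "active", caution_flags = 0L,
                      model_top = 3, cutoff = 1, n_concs = 8L,
                      min_conc_um = 0.1, max_conc_um = 100) {
  tibble::tibble(
    dtxsid = dtxsid, assay_set = assay_set, endpoint_id = endpoint_id,
    potency_um = potency_um, potency_kind = "AC50", hitcall = hitcall,
    caution_flags = caution_flags, model_top = model_top, cutoff = cutoff,
    n_concs = n_concs, min_conc_um = min_conc_um,
    max_conc_um = max_conc_um
  )
}

# Scenario entry used by simulate_scenario() in pipeline-level tests.
scenario_chemical <- function(dtxsid, abbreviation, formula, true_pods,
                              populations, rb2p = NA_real_, smiles = NA) {
  list(dtxsid = dtxsid, abbreviation = abbreviation, formula = formula,
       smiles = smiles, rb2p = rb2p, true_pods = true_pods,
       populations = populations)
}
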