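# DNT curve filters and POD aggregation.

test_that("dnt_filter demotes each low-confidence criterion", {
  # truth table over the three criteria
  base <- function(...) assay_row(assay_set = "DNT_MEA", ...)
  cases <- dplyr::bind_rows(
    base(caution_flags = 3L),                              # (1) flags >= 3
    base(caution_flags = 4L),
    base(model_top = 1.1, cutoff = 1, potency_um = 0.05,
         min_conc_um = 0.1),                               # (2) low top
    base(model_top = 1.2, cutoff = 1, potency_um = 0.05),  # boundary <=
    base(hitcall = "undetermined"),                        # (3) hitcall -1
    base(n_concs = 3L),                                    # (3) < 4 concs
    base(caution_flags = 2L, model_top = 2, potency_um = 50),  # clean hit
    base(model_top = 1.1, cutoff = 1, potency_um = 50)     # potency in range
  )
  out <- dnt_filter(cases)
  expect_identical(out$dnt_filtered,
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$hitcall[1:6], rep("inactive", 6))
  expect_true(all(is.na(out$potency_um[1:6])))
  expect_identical(out$hitcall[7:8], c("active", "active"))
})

test_that("dnt_filter leaves non-DNT records alone and is idempotent", {
  rows <- dplyr::bind_rows(
    assay_row(assay_set = "ATG", caution_flags = 5L),  # non-DNT: untouched
    assay_row(assay_set = "DNT_HCI", caution_flags = 3L),
    assay_row(assay_set = "DNT_MEA", model_top = 2, potency_um = 10))
  once <- dnt_filter(rows)
  expect_identical(once$hitcall[1], "active")
  twice <- dnt_filter(once)
  expect_identical(twice, once)
})

test_that("pod_set applies the sentinel, P5 and MIN rules", {
  # all inactive -> sentinel, censored
  inact <- dplyr::bind_rows(
    assay_row(hitcall = "inactive", potency_um = NA),
    assay_row(hitcall = "inactive", potency_um = NA, endpoint_id = "ep2"))
  out <- pod_set(inact)
  expect_identical(out$pod_set_um, 1000)
  expect_true(out$censored)
  expect_identical(out$n_active, 0L)

  # singleton active under P5 -> that potency
  one <- assay_row(potency_um = 2)
  expect_equal(pod_set(one)$pod_set_um, 2)

  # P5 of 1..100 matches the independent sort-and-interpolate oracle
  pots <- dplyr::bind_rows(lapply(1:100, function(i)
    assay_row(potency_um = i, endpoint_id = paste0("ep", i))))
  expect_equal(pod_set(pots)$pod_set_um, oracle_percentile(1:100, 0.05))

  # MIN rule for impedance / phenotypic profiling / zebrafish sets
  for (set in c("ACEA", "HTPP_U2OS", "HTPP_MCF7", "Zebrafish")) {
    rows <- dplyr::bind_rows(
      assay_row(assay_set = set, potency_um = 5),
      assay_row(assay_set = set, potency_um = 2, endpoint_id = "ep2"))
    expect_equal(pod_set(rows)$pod_set_um, 2)
  }
  # BSK primary-cell systems use the default P5 within a system
  bsk <- dplyr::bind_rows(lapply(1:10, function(i)
    assay_row(assay_set = "BSK_3C", potency_um = i * 10,
              endpoint_id = paste0("ep", i))))
  expect_equal(pod_set(bsk)$pod_set_um,
               oracle_percentile((1:10) * 10, 0.05))

  mixed <- dplyr::bind_rows(assay_row(assay_set = "ATG"),
                            assay_row(assay_set = "ACEA"))
  expect_error(pod_set(mixed), "exactly one")
})

test_that("P5 aggregation lies within the active potency range", {
  set.seed(7)
  for (i in 1:50) {
    pots <- rlnorm(sample(2:40, 1), log(10), 1)
    rows <- dplyr::bind_rows(lapply(seq_along(pots), function(j)
      assay_row(potency_um = pots[j], endpoint_id = paste0("ep", j))))
    p <- pod_set(rows)$pod_set_um
    expect_gte(p, min(pots))
    expect_lte(p, max(pots))
  }
})

test_that("pod_chemical is the minimum over sets with deterministic ties", {
  roster <- mini_roster()
  sets <- tibble::tibble(
    dtxsid = "DTX_A",
    assay_set = c("ATG", "BSK_3C", "Zebrafish"),
    pod_set_um = c(5, 0.8, 1000),
    n_active = c(3L, 2L, 0L),
    censored = c(FALSE, FALSE, TRUE))
  out <- pod_chemical(sets, roster)
  expect_equal(out$pod_chemical_um, 0.8)
  expect_identical(out$driving_set, "BSK_3C")
  expect_false(out$censored)
  expect_equal(out$pod_chemical_ngml, 0.8 * 414.07, tolerance = 1e-6)

  # tie broken lexicographically by assay set name
  tie <- sets; tie$pod_set_um <- c(0.8, 0.8, 1000)
  expect_identical(pod_chemical(tie, roster)$driving_set, "ATG")

  # all censored -> sentinel propagated with the censored flag
  cens <- sets; cens$pod_set_um <- 1000; cens$censored <- TRUE
  cens$n_active <- 0L
  out <- pod_chemical(cens, roster)
  expect_identical(out$pod_chemical_um, 1000)
  expect_true(out$censored)

  # missing molecular weight: uM kept, ng/mL NA with a warning
  sets_c <- sets; sets_c$dtxsid <- "DTX_C"
  expect_warning(out <- pod_chemical(sets_c, roster), "molecular weight")
  expect_equal(out$pod_chemical_um, 0.8)
  expect_true(is.na(out$pod_chemical_ngml))
})

test_that("chemical POD never exceeds any set POD and adding sets is
           monotone", {
  roster <- mini_roster()
  set.seed(13)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    sets <- tibble::tibble(
      dtxsid = "DTX_A",
      assay_set = paste0("SET_", seq_len(n)),
      pod_set_um = rlnorm(n, log(10), 1.5),
      n_active = 1L, censored = FALSE)
    out <- pod_chemical(sets, roster)
    expect_equal(out$pod_chemical_um, min(sets$pod_set_um))  # brute min
    expect_true(all(out$pod_chemical_um <= sets$pod_set_um))
    more <- dplyr::bind_rows(sets, tibble::tibble(
      dtxsid = "DTX_A", assay_set = "SET_EXTRA",
      pod_set_um = rlnorm(1, log(10), 1.5), n_active = 1L,
      censored = FALSE))
    expect_lte(pod_chemical(more, roster)$pod_chemical_um,
               out$pod_chemical_um)
  }
})

test_that("pod_set_all aggregates a whole endpoint table after filtering", {
  tab <- dplyr::bind_rows(
    assay_row(dtxsid = "DTX_A", assay_set = "ATG", potency_um = 3),
    assay_row(dtxsid = "DTX_A", assay_set = "DNT_MEA", potency_um = 0.01,
              caution_flags = 3L),
    assay_row(dtxsid = "DTX_A", assay_set = "DNT_MEA", potency_um = 10,
              endpoint_id = "ep2"),
    assay_row(dtxsid = "DTX_B", assay_set = "Zebrafish",
              hitcall = "inactive", potency_um = NA))
  out <- pod_set_all(tab)
  expect_identical(nrow(out), 3L)
  expect_equal(out$pod_set_um[out$dtxsid == "DTX_A" &
                                out$assay_set == "DNT_MEA"], 10)
  expect_true(out$censored[out$dtxsid == "DTX_B"])
})
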