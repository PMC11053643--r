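# Metric normalization/grouping, matrix-to-plasma conversion, QC flagging.

test_that("metric labels normalize across reporting dialects", {
  expect_identical(
    normalize_metric(c("mean", "arithmetic mean", "geometric mean",
                       "average")),
    rep("mean", 4))
  expect_identical(normalize_metric(c("median", "Median")),
                   c("median", "median"))
  expect_identical(
    normalize_metric(c("50th percentile", "P50", "p50", "95th percentile",
                       "5th percentile", "Maximum", "min")),
    c("p50", "p50", "p50", "p95", "p5", "maximum", "minimum"))
  expect_error(normalize_metric("mode"), "cannot classify.*mode")
  expect_error(normalize_metric("63rd percentile"), "cannot classify")
})

test_that("metric grouping is total and matches the five strata", {
  g <- group_metric(BCBCR_METRICS)
  expect_false(anyNA(g))
  expect_identical(as.character(group_metric(c("p90", "p95", "p98", "p99",
                                               "maximum"))),
                   rep("high", 5))
  expect_identical(as.character(group_metric(c("p50", "mean", "median"))),
                   rep("p50", 3))
  expect_identical(as.character(group_metric(c("p5", "p10", "minimum"))),
                   rep("low", 3))
  expect_identical(as.character(group_metric("p75")), "p75")
  expect_identical(as.character(group_metric("p25")), "p25")
  expect_error(group_metric("p42"), "unknown metric")
})

test_that("matrix conversion applies the blood-to-plasma ratio correctly", {
  roster <- mini_roster()
  # whole blood, chemical without rb2p -> default 0.5 doubles the value
  rec <- biomon_record(dtxsid = "DTX_A", matrix = "whole_blood", value = 10)
  out <- to_plasma(rec, roster)
  expect_equal(out$plasma_value, 20)
  expect_identical(out$rb2p_source, "default")
  # serum passes through untouched
  out <- to_plasma(biomon_record(matrix = "serum", value = 7.3), roster)
  expect_equal(out$plasma_value, 7.3)
  expect_equal(out$conversion_factor, 1)
  expect_true(is.na(out$rb2p_source))
  # cord blood treated as whole blood; measured rb2p = 0.5 doubles
  rec <- biomon_record(dtxsid = "DTX_B", matrix = "cord_blood", value = 5)
  out <- to_plasma(rec, roster)
  expect_equal(out$plasma_value, 10)
  expect_identical(out$rb2p_source, "measured_in_vivo")
  # cord serum / cord plasma / plasma are plasma-scale already
  for (m in c("cord_serum", "cord_plasma", "plasma")) {
    out <- to_plasma(biomon_record(matrix = m, value = 3), roster)
    expect_equal(out$plasma_value, 3)
  }
  bad <- roster; bad$rb2p[2] <- -1
  expect_error(to_plasma(biomon_record(dtxsid = "DTX_B",
                                       matrix = "whole_blood"), bad),
               "> 0")
})

test_that("conversion is linear, count-preserving and keeps duplicates", {
  roster <- mini_roster()
  recs <- dplyr::bind_rows(
    biomon_record(value = 1), biomon_record(value = 1),  # deliberate dupes
    biomon_record(dtxsid = "DTX_C", matrix = "blood_spot", value = 4))
  out <- to_plasma(recs, roster)
  expect_identical(nrow(out), nrow(recs))
  expect_equal(out$plasma_value[1], out$plasma_value[2])
  # blood spot for DTX_C uses its rb2p 0.8
  expect_equal(out$plasma_value[3], 4 / 0.8)
  # linearity in the reported value for fixed chemistry
  k <- 7.5
  scaled <- recs; scaled$value <- scaled$value * k
  expect_equal(to_plasma(scaled, roster)$plasma_value,
               k * out$plasma_value)
  # whole-blood conversion with rb2p in (0, 1] never decreases the value
  expect_true(all(out$plasma_value >= recs$value))
})

test_that("whole-blood summaries convert back to the plasma-side summaries", {
  spec_p <- population_spec("DTX_B", "SNA_P", gm = 12, gsd = 2,
                            n_subjects = 400, matrix = "plasma")
  spec_b <- population_spec("DTX_B", "SNA_P", gm = 12, gsd = 2,
                            n_subjects = 400, matrix = "whole_blood",
                            rb2p_true = 0.5)
  plasma_side <- simulate_population(spec_p, seed = 9)
  blood_side <- simulate_population(spec_b, seed = 9)
  out <- to_plasma(blood_side, mini_roster())  # DTX_B rb2p = 0.5
  expect_equal(out$plasma_value, plasma_side$value, tolerance = 1e-12)
})

test_that("ingest validates schema, units and censored values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "snaid,dtxsid,matrix,metric,value,unit,population_class",
    "S1,DTX_A,serum,geometric mean,5,ng/mL,general",
    "S1,DTX_A,serum,95th percentile,12,ug/L,exposed",
    "S2,DTX_A,whole_blood,median,0.004,ug/mL,general"), f)
  out <- read_biomonitoring(f)
  expect_identical(nrow(out), 3L)
  expect_identical(out$metric, c("mean", "p95", "median"))
  expect_equal(out$value, c(5, 12, 4))  # ug/L = ng/mL; ug/mL x1000

  writeLines(c("snaid,dtxsid,matrix,metric,value",
               "S1,DTX_A,serum,mean,<LOD"), f)
  expect_error(read_biomonitoring(f), "non-numeric")

  writeLines(c("snaid,dtxsid,matrix,metric,value,unit",
               "S1,DTX_A,serum,mean,5,mol/L"), f)
  expect_error(read_biomonitoring(f), "unrecognized.*unit")

  writeLines(c("snaid,dtxsid,matrix,metric,value",
               "S1,DTX_A,saliva,mean,5"), f)
  expect_error(read_biomonitoring(f), "unknown matrix")

  writeLines(c("snaid,dtxsid,matrix,metric,value",
               "S1,DTX_A,serum,mean,5"), f)
  expect_warning(out <- read_biomonitoring(f), "population_class")
  expect_identical(out$population_class, "general")
})

test_that("qc_flag returns exactly the records above the threshold", {
  recs <- to_plasma(dplyr::bind_rows(
    biomon_record(value = 50), biomon_record(value = 100),
    biomon_record(value = 150)), mini_roster())
  flagged <- qc_flag(recs, threshold = 100)
  expect_identical(nrow(flagged), 1L)        # strictly greater only
  expect_equal(flagged$plasma_value, 150)
  expect_identical(flagged$qc_flag, "review")
  expect_identical(nrow(qc_flag(recs[0, ])), 0L)

  set.seed(31)
  big <- biomon_record(value = 1)[rep(1, 1000), ]
  big$value <- rlnorm(1000, log(60), 1)
  conv <- to_plasma(big, mini_roster())
  expect_identical(nrow(qc_flag(conv, 100)),
                   sum(conv$plasma_value > 100))  # brute-force filter count
})
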