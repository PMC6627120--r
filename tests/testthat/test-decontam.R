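spiked_fixture <- function() {
  counts <- rbind(
    OTU_A = c(100, 200, 0, 0),
    OTU_B = c(50, 60, 0, 0),
    OTU_C = c(40, 12, 10, 20),
    OTU_D = c(30, 25, 8, 0),
    OTU_spike = c(0, 0, 500, 400)
  )
  make_table(counts, samples = c("S1", "S2", "NTC1", "NTC2"),
             roles = c("biological", "biological", "ntc_spiked", "ntc_spiked"))
}

test_that("background catalog averages NTC counts with zeros in the denominator", {
  tb <- spiked_fixture()
  cat <- identify_background(tb, "OTU_spike")
  expect_s3_class(cat, "background_catalog")
  expect_setequal(cat$background_features, c("OTU_C", "OTU_D"))
  expect_equal(unname(cat$mean_reads["OTU_C"]), 15)  # (10 + 20) / 2
  expect_equal(unname(cat$mean_reads["OTU_D"]), 4)   # (8 + 0) / 2
  expect_false("OTU_spike" %in% cat$background_features)
  expect_equal(cat$n_ntc_used, 2)
})

test_that("clean NTCs (spike only) yield an empty catalog and identity cleaning", {
  counts <- rbind(OTU_A = c(10, 0), OTU_spike = c(0, 300))
  tb <- make_table(counts, samples = c("S1", "NTC1"),
                   roles = c("biological", "ntc_spiked"))
  cat <- identify_background(tb, "OTU_spike")
  expect_length(cat$background_features, 0)
  clean <- subtract_background(tb, cat)
  expect_identical(clean$counts[, "S1"], tb$counts[, "S1"])
  expect_false("NTC1" %in% sample_ids(clean))
})

test_that("catalog construction fails without NTCs or without the spike", {
  tb <- make_table(rbind(OTU_A = c(1, 2)))
  expect_error(identify_background(tb, "OTU_A"), "no spiked-NTC")
  tb2 <- spiked_fixture()
  expect_error(identify_background(tb2, "OTU_missing"), "absent")
})

test_that("subtraction removes the rounded mean, floors at zero, drops NTCs", {
  tb <- spiked_fixture()
  cat <- identify_background(tb, "OTU_spike")
  clean <- subtract_background(tb, cat)
  expect_equal(unname(clean$counts["OTU_C", c("S1", "S2")]), c(25, 0))  # 40-15, 12-15 -> 0
  expect_equal(unname(clean$counts["OTU_D", c("S1", "S2")]), c(26, 21)) # 30-4, 25-4
  # features absent from the NTCs are untouched (over-compensation guard)
  expect_identical(clean$counts[c("OTU_A", "OTU_B"), ],
                   tb$counts[c("OTU_A", "OTU_B"), c("S1", "S2")])
  expect_setequal(sample_ids(clean), c("S1", "S2"))
  expect_true(all(clean$counts <= tb$counts[, c("S1", "S2")]))
  expect_true(all(clean$counts >= 0))
})

test_that("rounding modes agree on their definitions", {
  # two NTCs at 5 and 6 reads give a fractional mean of 5.5
  counts2 <- rbind(OTU_C = c(40, 11, 5, 6), OTU_spike = c(0, 0, 100, 90))
  tb2 <- make_table(counts2, samples = c("S1", "S2", "NTC1", "NTC2"),
                    roles = c("biological", "biological", "ntc_spiked", "ntc_spiked"))
  cat2 <- identify_background(tb2, "OTU_spike")
  expect_equal(unname(cat2$mean_reads["OTU_C"]), 5.5)
  expect_equal(unname(subtract_background(tb2, cat2, "half_up")$counts["OTU_C", "S1"]), 34)   # 40 - 6
  expect_equal(unname(subtract_background(tb2, cat2, "floor")$counts["OTU_C", "S1"]), 35)     # 40 - 5
  expect_equal(unname(subtract_background(tb2, cat2, "none")$counts["OTU_C", "S1"]), 34)      # floor(34.5)
})

test_that("catalog features missing from the table are skipped with a warning", {
  tb <- spiked_fixture()
  cat <- identify_background(tb, "OTU_spike")
  cat$background_features <- c(cat$background_features, "OTU_ghost")
  cat$mean_reads <- c(cat$mean_reads, OTU_ghost = 3)
  expect_warning(clean <- subtract_background(tb, cat), "OTU_ghost")
  expect_equal(unname(clean$counts["OTU_C", "S1"]), 25)
})

test_that("subtraction moves compositions toward the contamination-free truth", {
  improved <- logical(0)
  untouched <- logical(0)
  for (s in 1:6) {
    sp <- cohort_spec(n_samples = c(10, 10, 10), contamination_fraction = 0.1,
                      n_ntc = 4)
    co <- generate_cohort(sp, seed = s)
    cat <- identify_background(co$table, sp$spike_feature)
    clean <- subtract_background(co$table, cat)
    bio <- biological_samples(clean)
    truth <- co$truth$true_composition[, bio]
    pre <- to_relative(subset_samples(co$table, bio))$proportions
    post <- to_relative(clean)$proportions
    improved <- c(improved, mean(abs(post - truth)) < mean(abs(pre - truth)))
    non_bg <- setdiff(feature_ids(co$table), cat$background_features)
    untouched <- c(untouched,
                   identical(clean$counts[non_bg, ], co$table$counts[non_bg, bio]))
  }
  expect_true(all(improved))
  expect_true(all(untouched))
})

test_that("per-run NTC means are used when run labels are supplied", {
  counts <- rbind(OTU_C = c(40, 40, 10, 30), OTU_spike = c(0, 0, 500, 400))
  tb <- make_table(counts, samples = c("S1", "S2", "NTC1", "NTC2"),
                   roles = c("biological", "biological",
                             "ntc_spiked", "ntc_spiked"))
  runs <- c(S1 = "run1", S2 = "run2", NTC1 = "run1", NTC2 = "run2")
  cat_runs <- identify_background(tb, "OTU_spike", runs = runs)
  expect_equal(unname(cat_runs$mean_reads["OTU_C"]), 20)   # pooled (10+30)/2
  expect_equal(unname(cat_runs$run_means$run1["OTU_C"]), 10)
  expect_equal(unname(cat_runs$run_means$run2["OTU_C"]), 30)
  clean <- subtract_background(tb, cat_runs, runs = runs)
  expect_equal(unname(clean$counts["OTU_C", ]), c(30, 10))  # 40-10, 40-30
  # pooled fallback without run labels
  pooled <- subtract_background(tb, cat_runs)
  expect_equal(unname(pooled$counts["OTU_C", ]), c(20, 20))
  # a catalog without run means refuses run-wise subtraction
  cat_pooled <- identify_background(tb, "OTU_spike")
  expect_error(subtract_background(tb, cat_pooled, runs = runs), "per-run")
})

test_that("sequence-identity matching re-keys the catalog onto table features", {
  tb <- spiked_fixture()
  cat0 <- identify_background(tb, "OTU_spike")
  # catalog keyed by control-run feature IDs; sequences tie them to the table
  names(cat0$mean_reads) <- cat0$background_features <- c("ctl_1", "ctl_2")
  catalog_seqs <- c(ctl_1 = "ACGTACGT", ctl_2 = "GGGGCCCC")
  table_seqs <- c(OTU_A = "TTTTTTTT", OTU_C = "acgtacgt", OTU_D = "GGGGCCCC")
  mapped <- match_background_sequences(cat0, catalog_seqs, table_seqs)
  expect_setequal(mapped$background_features, c("OTU_C", "OTU_D"))
  expect_equal(unname(mapped$mean_reads["OTU_C"]), 15)
  clean <- subtract_background(tb, mapped)
  expect_equal(unname(clean$counts["OTU_C", "S1"]), 25)
  # unmatched sequences are dropped with a warning
  expect_warning(
    match_background_sequences(cat0, c(ctl_1 = "AAAA", ctl_2 = "GGGGCCCC"),
                               table_seqs),
    "ctl_1")
})
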