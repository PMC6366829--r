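test_that("ploidy-group bands are inclusive at 24-34 and 47-57", {
  expect_equal(classify_ploidy_group(30), "hyperhaploid")
  expect_equal(classify_ploidy_group(50), "hyperdiploid")
  expect_equal(classify_ploidy_group(46), "other")
  # exact boundary behavior
  expect_equal(classify_ploidy_group(24), "hyperhaploid")
  expect_equal(classify_ploidy_group(34), "hyperhaploid")
  expect_equal(classify_ploidy_group(47), "hyperdiploid")
  expect_equal(classify_ploidy_group(57), "hyperdiploid")
  expect_equal(classify_ploidy_group(23), "other")
  expect_equal(classify_ploidy_group(35), "other")
  expect_equal(classify_ploidy_group(58), "other")
  expect_error(classify_ploidy_group(-1), "non-negative")
})

test_that("monosomy counting respects no-calls and partitions autosomes", {
  calls <- data.frame(chrom = 1:22,
                      cn = ifelse(1:22 %in% c(3, 5, 7, 9, 11, 15, 18, 19,
                                              21), 2L, 1L),
                      loh = FALSE, no_call = FALSE)
  mono <- count_monosomies(calls)
  expect_equal(mono$count, 13)

  dip <- data.frame(chrom = 1:22, cn = 2L, loh = FALSE, no_call = FALSE)
  expect_equal(count_monosomies(dip)$count, 0)

  # no-call chromosomes never count as monosomic
  calls$no_call[1] <- TRUE
  mono2 <- count_monosomies(calls)
  expect_equal(mono2$count, 12)
  expect_equal(mono2$no_call_count, 1)
  expect_true(is.na(mono2$indicator$monosomic[1]))
  # partition: monosomic + disomic + other + no-call = 22
  n_di <- sum(!calls$no_call & calls$cn == 2)
  expect_equal(mono2$count + n_di + 0 + mono2$no_call_count, 22)
})

test_that("per-chromosome monosomy frequencies recover the generator's design", {
  sizes <- c(8, 9, 10)
  full <- c(3, 5, 7, 9, 11, 15, 18, 19, 21, 4)
  reports <- list()
  truth_mono <- matrix(0L, nrow = 0, ncol = 22)
  for (i in 1:8) {
    retained <- full[seq_len(sizes[(i %% 3) + 1])]
    s <- make_sample("direct_loss", seed = 100 + i,
                     retained_set = retained)
    reports[[paste0("s", i)]] <- run_pipeline(pipeline_config(), s$counts)
    truth_mono <- rbind(truth_mono, as.integer(!(1:22 %in% retained)))
  }
  freq <- monosomy_frequency(reports)
  expect_equal(freq$frequency, colMeans(truth_mono))
})

test_that("heterodisomy summaries expose each mechanism's LOH fraction", {
  s <- make_sample("direct_loss", seed = 111)
  rep <- run_pipeline(pipeline_config(), s$counts)
  het <- heterodisomy_summary(rep$ploidy)
  expect_equal(het$n_disomic, 9)
  expect_equal(het$disomic_loh_fraction, 0)

  hd <- make_sample("haploid_duplication", seed = 111)
  het_hd <- heterodisomy_summary(run_pipeline(pipeline_config(),
                                              hd$counts)$ploidy)
  expect_equal(het_hd$disomic_loh_fraction, 1)

  # no disomic chromosomes -> undefined flag, not an error
  all_mono <- data.frame(chrom = 1:22, cn = 1L, loh = TRUE,
                         no_call = FALSE)
  het_none <- heterodisomy_summary(all_mono)
  expect_true(het_none$undefined)
  expect_true(is.na(het_none$disomic_loh_fraction))
})

test_that("karyotype summaries classify simulated samples correctly", {
  s <- make_sample("direct_loss", seed = 121)
  k <- summarize_karyotype(run_pipeline(pipeline_config(), s$counts)$ploidy)
  expect_equal(k$group, "hyperhaploid")
  expect_equal(k$total_count, 31 + 2)
  expect_equal(k$monosomy_count, 13)

  dip <- make_sample("none", seed = 121)
  kd <- summarize_karyotype(run_pipeline(pipeline_config(),
                                         dip$counts)$ploidy)
  expect_equal(kd$group, "other")
  expect_equal(kd$total_count, 46)

  # > 4 uncallable autosomes make a sample unclassifiable
  calls <- data.frame(chrom = 1:22, cn = c(rep(NA, 5), rep(2L, 17)),
                      loh = FALSE, no_call = c(rep(TRUE, 5), rep(FALSE, 17)))
  expect_equal(summarize_karyotype(calls)$group, "unclassifiable")
})

test_that("serial comparison reports losses, swaps on reversal", {
  a <- data.frame(chrom = 1:22, cn = 2L, loh = FALSE, no_call = FALSE)
  b <- a
  b$cn[b$chrom == 15] <- 1L
  cmp <- compare_serial(a, b)
  expect_equal(cmp$lost, 15)
  expect_length(cmp$gained, 0)
  expect_length(cmp$unchanged, 21)

  rev <- compare_serial(b, a)
  expect_equal(rev$gained, 15)
  expect_length(rev$lost, 0)

  same <- compare_serial(a, a)
  expect_length(same$unchanged, 22)

  b$no_call[1] <- TRUE
  expect_equal(compare_serial(a, b)$incomparable, 1)
  expect_error(compare_serial(a, a[-1, ]), "different chromosomes")
})

test_that("a simulated serial pair round-trips through the pipeline", {
  s <- make_sample("direct_loss", seed = 131,
                   retained_set = c(3, 5, 6, 7, 9, 11, 15, 18, 19, 21))
  pair <- derive_serial_pair(s, c(6, 15), seed = 7)
  cfg <- pipeline_config()
  r1 <- run_pipeline(cfg, pair$t1$counts)
  r2 <- run_pipeline(cfg, pair$t2$counts)
  cmp <- compare_serial(r1$ploidy$calls, r2$ploidy$calls)
  expect_equal(sort(cmp$lost), c(6, 15))
  expect_length(cmp$gained, 0)
})
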