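test_that("expected BAF matches the purity-mixture model", {
  expect_equal(expected_baf(1, 2, 0.9), 0.5)
  expect_equal(expected_baf(1, 2, 0.3), 0.5)
  expect_equal(expected_baf(0, 1, 0.9), 0.1 / 1.1)
  expect_equal(expected_baf(1, 1, 0.9), 1 / 1.1)
  expect_equal(expected_baf(2, 3, 0), 0.5)  # pure-normal limit
  expect_error(expected_baf(3, 2, 0.9), "exceeds")
  expect_error(expected_baf(0, 0, 1), "undefined")
})

test_that("expected BAF is allele-symmetric: f(n_b) + f(cn - n_b) = 1", {
  for (cn in 1:4) for (nb in 0:cn) for (p in c(0.2, 0.5, 0.9, 1)) {
    expect_equal(expected_baf(nb, cn, p) + expected_baf(cn - nb, cn, p), 1)
  }
})

test_that("BAF profiles mirror, filter by depth, and flag no-calls", {
  s <- make_sample("direct_loss", seed = 41)
  prof <- compute_baf_profile(s$counts, min_depth = 10)
  expect_true(all(prof$snps$mirrored_baf >= 0.5 &
                  prof$snps$mirrored_baf <= 1))
  bc <- prof$chromosomes
  cn <- truth_cn(s$karyotype)
  het_med <- bc$median_mirrored_baf[cn == 2]
  mono_med <- bc$median_mirrored_baf[cn == 1]
  expect_true(all(abs(het_med - 0.5) < 0.1))
  expect_true(all(abs(mono_med - 1 / 1.1) < 0.05))

  # impossible depth filter -> every chromosome no-call
  prof_hi <- compute_baf_profile(s$counts, min_depth = 10000)
  expect_true(all(prof_hi$chromosomes$no_call))
  expect_equal(sum(prof_hi$chromosomes$n_excluded), nrow(s$counts))

  expect_error(compute_baf_profile(s$counts[0, ]), "empty")
})

test_that("LOH threshold is the heterodisomy/monosomy midpoint", {
  expect_equal(loh_threshold(1), 0.75)
  expect_equal(loh_threshold(0.9), (0.5 + 1 / 1.1) / 2)

  # a median mirrored BAF of 0.70 sits just below the purity-0.9
  # threshold of ~0.705 and must not be called LOH
  fake <- structure(list(chromosomes = data.frame(
    chrom = 1L, median_mirrored_baf = 0.70, n_snps = 50L,
    n_excluded = 0L, no_call = FALSE)), class = "baf_profile")
  call <- call_chromosome_loh(fake, purity = 0.9)
  expect_false(call$loh)
  fake$chromosomes$median_mirrored_baf <- 0.71
  expect_true(call_chromosome_loh(fake, purity = 0.9)$loh)

  # too few SNPs -> no-call, not a verdict
  fake$chromosomes$n_snps <- 5L
  expect_true(is.na(call_chromosome_loh(fake, purity = 0.9)$loh))
})

test_that("LOH calls on simulated samples hit exactly the lost chromosomes", {
  s <- make_sample("direct_loss", seed = 51)
  prof <- compute_baf_profile(s$counts)
  calls <- call_chromosome_loh(prof, purity = 0.9)
  expect_identical(calls$loh, unname(truth_loh(s$karyotype)))
  expect_equal(sum(calls$loh), 13)

  dip <- make_sample("none", seed = 51)
  dip_calls <- call_chromosome_loh(compute_baf_profile(dip$counts), 0.9)
  expect_equal(sum(dip_calls$loh), 0)
})

test_that("depth ratios separate monosomy from disomy in proportion", {
  s <- make_sample("direct_loss", seed = 61, purity = 1)
  ratios <- estimate_relative_cn(s$counts)
  cn <- truth_cn(s$karyotype)
  mono <- median(ratios$depth_ratio[cn == 1])
  di <- median(ratios$depth_ratio[cn == 2])
  expect_lt(abs(di / mono - 2), 0.1)

  # at purity 0.9 the contrast shrinks to 2 : 1.1
  s9 <- make_sample("direct_loss", seed = 61, purity = 0.9)
  r9 <- estimate_relative_cn(s9$counts)
  mono9 <- median(r9$depth_ratio[cn == 1])
  di9 <- median(r9$depth_ratio[cn == 2])
  expect_lt(abs(mono9 / di9 - 0.55), 0.05)

  dip <- make_sample("none", seed = 61)
  rd <- estimate_relative_cn(dip$counts)
  expect_lt(max(rd$depth_ratio) - min(rd$depth_ratio), 0.2)
})

test_that("ploidy renormalization anchors LOH chromosomes at copy one", {
  s <- make_sample("direct_loss", seed = 71)
  sol <- call_chromosomes(s$counts, purity = 0.9)
  expect_true(sol$renormalized)
  expect_identical(sol$calls$cn[sol$calls$loh], rep(1L, 13))
  expect_identical(sol$calls$cn[!sol$calls$loh], rep(2L, 9))
  expect_false(any(sol$calls$discordant))

  # haploidization-then-duplication: retained chromosomes are CN 2 with
  # LOH and surface as discordant under the CN-1 mapping
  hd <- make_sample("haploid_duplication", seed = 71)
  sol_hd <- call_chromosomes(hd$counts, purity = 0.9)
  retained <- truth_cn(hd$karyotype) == 2
  expect_true(all(sol_hd$calls$loh))
  expect_identical(sol_hd$calls$cn[retained], rep(2L, 9))
  expect_true(all(sol_hd$calls$discordant[retained]))

  # no LOH and no anchor is an error; an anchor resolves it
  dip <- make_sample("none", seed = 71)
  ratios <- estimate_relative_cn(dip$counts)
  loh <- call_chromosome_loh(compute_baf_profile(dip$counts), 0.9)
  expect_error(renormalize_ploidy(ratios, loh), "anchor")
  sol_dip <- renormalize_ploidy(ratios, loh, anchor_cn = 2)
  expect_true(all(sol_dip$calls$cn == 2L))
  expect_false(sol_dip$renormalized)
})

test_that("renormalization is scale-invariant and idempotent", {
  s <- make_sample("direct_loss", seed = 81)
  ratios <- estimate_relative_cn(s$counts)
  loh <- call_chromosome_loh(compute_baf_profile(s$counts), 0.9)
  sol <- renormalize_ploidy(ratios, loh)

  doubled <- ratios
  doubled$depth_ratio <- doubled$depth_ratio * 2
  sol2 <- renormalize_ploidy(doubled, loh)
  expect_identical(sol$calls$cn, sol2$calls$cn)
  expect_equal(sol$calls$scaled_ratio, sol2$calls$scaled_ratio)

  rescaled <- ratios
  rescaled$depth_ratio <- sol$calls$scaled_ratio
  sol3 <- renormalize_ploidy(rescaled, loh)
  expect_identical(sol3$calls$cn, sol$calls$cn)
  expect_equal(sol3$scale_factor, 1)
})

test_that("call confidence grows with SNP support", {
  s <- make_sample("direct_loss", seed = 91)
  sol_full <- call_chromosomes(s$counts, purity = 0.9)
  thin <- s$counts[seq(1, nrow(s$counts), by = 2), ]
  class(thin) <- class(s$counts)
  sol_thin <- call_chromosomes(thin, purity = 0.9)
  expect_true(all(sol_full$calls$confidence > sol_thin$calls$confidence))
})
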