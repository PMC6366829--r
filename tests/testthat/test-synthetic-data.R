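test_that("germline panels are sized, sorted, unique and deterministic", {
  empty <- make_germline_panel(0, seed = 1)
  expect_equal(nrow(empty), 0)

  p1 <- make_germline_panel(50, seed = 1)
  p2 <- make_germline_panel(50, seed = 1)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 22 * 50)
  expect_setequal(unique(p1$chrom), 1:22)
  expect_true(all(p1$ref != p1$alt))  # heterozygous by construction
  for (ch in 1:22) {
    pos <- p1$pos[p1$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_false(identical(p1, make_germline_panel(50, seed = 2)))
  expect_error(make_germline_panel(-1, seed = 1), "non-negative")
})

test_that("seeded operations do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_germline_panel(10, seed = 7))
  invisible(evolve_karyotype("hyperdiploid_loss", seed = 7))
  expect_equal(runif(1), before)
})

test_that("karyotype evolution matches each mechanism's copy-state signature", {
  none <- evolve_karyotype("none", seed = 1)
  expect_true(all(truth_cn(none) == 2))
  expect_true(all(!truth_loh(none)))
  expect_length(none$event_log, 0)

  dl <- evolve_karyotype("direct_loss", seed = 3)
  cn <- truth_cn(dl)
  expect_equal(sum(cn == 1), 13)
  expect_equal(sum(cn == 2), 9)
  # every disomic chromosome retains heterodisomy
  expect_true(all(!truth_loh(dl)[cn == 2]))
  # conservation: k retained -> total 2k + (22 - k)
  expect_equal(sum(cn), 2 * 9 + 13)

  hd <- evolve_karyotype("haploid_duplication", seed = 3)
  expect_true(all(truth_loh(hd)))  # LOH genome-wide
  expect_equal(sum(truth_cn(hd) == 2), 9)

  hl <- evolve_karyotype("hyperdiploid_loss", seed = 3)
  cn_hl <- truth_cn(hl)
  expect_true(all(cn_hl[hl$states$chrom %in% c(3, 5, 7, 9, 11, 15, 18, 19, 21)] == 2))
  expect_true(all(cn_hl[!hl$states$chrom %in% c(3, 5, 7, 9, 11, 15, 18, 19, 21)] == 1))

  expect_error(evolve_karyotype("fission", seed = 1), "mechanism")
})

test_that("event logs replay from diploid to the stored copy states", {
  for (mech in c("none", "direct_loss", "haploid_duplication",
                 "hyperdiploid_loss")) {
    for (seed in 1:5) {
      k <- evolve_karyotype(mech, seed = seed)
      expect_identical(replay_event_log(k$event_log), k$states)
    }
  }
})

test_that("simulated allele counts follow the purity-scaled BAF model", {
  panel <- default_panel
  # monosomy everywhere that lost the B homolog at purity 1: alt reads
  # can only arise from retained B copies
  k <- evolve_karyotype("direct_loss", seed = 11)
  counts <- simulate_allele_counts(k, panel, purity = 1, mean_depth = 100,
                                   seed = 5)
  b_parent <- attr(counts, "b_allele_parent")
  st <- k$states
  lost_b <- st$chrom[ifelse(b_parent[as.character(st$chrom)] == "m",
                            st$n_m, st$n_p) == 0]
  expect_true(length(lost_b) > 0)
  expect_true(all(counts$tumor_alt[counts$chrom %in% lost_b] == 0))

  # heterodisomic chromosomes concentrate at BAF 0.5
  het <- st$chrom[st$n_m == 1 & st$n_p == 1]
  baf <- with(counts[counts$chrom %in% het, ],
              tumor_alt / (tumor_alt + tumor_ref))
  expect_lt(abs(mean(baf) - 0.5), 0.02)

  # monosomy retaining the B homolog at purity 0.9: mean alt fraction
  # near (0.1 + 0.9) / (0.2 + 0.9)
  counts9 <- simulate_allele_counts(k, panel, purity = 0.9,
                                    mean_depth = 200, seed = 6)
  bp9 <- attr(counts9, "b_allele_parent")
  kept_b <- st$chrom[st$n_m + st$n_p == 1 &
                     ifelse(bp9[as.character(st$chrom)] == "m",
                            st$n_m, st$n_p) == 1]
  baf9 <- with(counts9[counts9$chrom %in% kept_b, ],
               tumor_alt / (tumor_alt + tumor_ref))
  expect_lt(abs(mean(baf9) - 1 / 1.1), 0.02)

  expect_error(simulate_allele_counts(k, panel, purity = 0), "purity")
  empty <- simulate_allele_counts(k, make_germline_panel(0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("spiked mutations carry the requested multiplicity and CCF", {
  s <- make_sample("direct_loss", seed = 21)
  # clonal hemizygous limit: ccf 1, purity 1, CN_t 1, m 1 -> VAF 1
  s_pure <- make_sample("direct_loss", seed = 21, purity = 1)
  s_pure <- spike_somatic_mutation(s_pure, "TP53", 17, 7674220,
                                   m = 1, ccf = 1, seed = 1)
  expect_equal(s_pure$somatic_mutations$vaf, 1)

  # expected VAF ccf * pi * m / (pi * CN_t + (1 - pi) * 2) at pi = 0.9
  vafs <- vapply(1:200, function(i) {
    sp <- spike_somatic_mutation(s, "TP53", 17, 7674220, m = 1, ccf = 1,
                                 seed = i)
    sp$somatic_mutations$vaf
  }, numeric(1))
  expect_lt(abs(mean(vafs) - 0.9 / 1.1), 0.02)

  # m > CN_t on a monosomic chromosome is rejected
  expect_error(spike_somatic_mutation(s, "TP53", 17, 1, m = 2, ccf = 1),
               "exceeds tumor copy number")
  expect_true("true_ccf" %in% names(
    spike_somatic_mutation(s, "TP53", 17, 1, m = 1, ccf = 0.5,
                           seed = 2)$somatic_mutations))
})

test_that("serial pairs lose exactly the requested chromosomes", {
  s <- make_sample("direct_loss", seed = 31)
  pair <- derive_serial_pair(s, 15, seed = 2)
  expect_equal(sum(truth_cn(pair$t1$karyotype) == 1), 13)
  expect_equal(sum(truth_cn(pair$t2$karyotype) == 1), 14)
  expect_equal(truth_cn(pair$t2$karyotype)[15], 1)

  same <- derive_serial_pair(s, integer(), seed = 2)
  expect_identical(same$t1$karyotype$states, same$t2$karyotype$states)

  # chromosome 17 is already monosomic in a direct_loss karyotype
  expect_error(derive_serial_pair(s, 17, seed = 2), "not disomic")
})
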