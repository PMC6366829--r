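# Shared builders for simulated samples used across the test files.

default_panel <- make_germline_panel(50, seed = 42)

# One full simulated sample: karyotype + allele counts at defaults.
make_sample <- function(mechanism = "direct_loss", seed = 1L,
                        purity = 0.9, mean_depth = 100,
                        panel = default_panel,
                        retained_set = c(3, 5, 7, 9, 11, 15, 18, 19, 21)) {
  k <- evolve_karyotype(mechanism, retained_set = retained_set, seed = seed)
  simulate_sample(k, panel, purity = purity, mean_depth = mean_depth,
                  seed = seed + 500000L)
}

# Ground-truth per-chromosome CN / LOH vectors from a karyotype.
truth_cn <- function(karyotype) {
  with(karyotype$states, n_m + n_p)
}
truth_loh <- function(karyotype) {
  with(karyotype$states, pmin(n_m, n_p) == 0 & (n_m + n_p) >= 1)
}

table1_path <- system.file("extdata", "table1_tp53_synthetic_loci.tsv",
                           package = "hyperhaploidy")
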