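#!/usr/bin/env Rscript
# Simulate the study cohort: eight hyperhaploid tumor/normal sample
# pairs generated by direct sequential chromosome loss (the mechanism
# the karyotype data support), one diploid control, and one serial pair
# losing chromosome 15 at the second timepoint. Every sample carries a
# spiked TP53 mutation on its monosomic chromosome 17; two are
# subclonal, mirroring the published clonality split.
#
# Outputs under results/cohort/: per-sample allele-count TSVs, a
# mutation TSV + minimal VCF per sample, and a ground-truth JSON.

suppressPackageStartupMessages(library(hyperhaploidy))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20260928L
base_retained <- c(3, 5, 7, 9, 11, 15, 18, 19, 21)
# retained-set sizes 8-10 give the observed 12-14 monosomies; one
# sample drops chromosome 18 from the retained set (it is disomic in
# only 7 of 8 samples)
retained_sets <- list(
  base_retained, base_retained, setdiff(base_retained, 18),
  c(base_retained, 4), base_retained, c(base_retained, 6),
  setdiff(base_retained, 15), base_retained)
tp53_ccf <- c(1, 1, 0.45, 1, 1, 0.6, 1, 1)

truth <- list()
for (i in seq_along(retained_sets)) {
  id <- sprintf("HH%02d", i)
  k <- evolve_karyotype("direct_loss", retained_set = retained_sets[[i]],
                        seed = seed + i)
  s <- simulate_sample(k, make_germline_panel(50, seed = seed),
                       purity = 0.9, mean_depth = 100, seed = seed + 100 + i)
  s <- spike_somatic_mutation(s, "TP53", 17, 7674220L, m = 1,
                              ccf = tp53_ccf[i], seed = seed + 200 + i)
  write_allele_counts(s$counts, file.path(out_dir, paste0(id, "_counts.tsv")))
  write.table(s$somatic_mutations,
              file.path(out_dir, paste0(id, "_mutations.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_mutations_vcf(s$somatic_mutations,
                      file.path(out_dir, paste0(id, "_mutations.vcf")),
                      sample_name = id)
  truth[[id]] <- list(mechanism = "direct_loss",
                      retained_set = retained_sets[[i]],
                      monosomies = sum(k$states$n_m + k$states$n_p == 1),
                      tp53_ccf = tp53_ccf[i])
  message(id, ": ", truth[[id]]$monosomies, " monosomies, TP53 ccf ",
          tp53_ccf[i])
}

# diploid control
dip <- simulate_sample(evolve_karyotype("none", seed = seed),
                       make_germline_panel(50, seed = seed),
                       purity = 0.9, mean_depth = 100, seed = seed + 300)
write_allele_counts(dip$counts, file.path(out_dir, "DIPLOID_counts.tsv"))
truth$DIPLOID <- list(mechanism = "none", monosomies = 0)

# serial pair: second timepoint loses chromosome 15
serial_base <- simulate_sample(
  evolve_karyotype("direct_loss", retained_set = base_retained,
                   seed = seed + 50),
  make_germline_panel(50, seed = seed), purity = 0.9, mean_depth = 100,
  seed = seed + 400)
pair <- derive_serial_pair(serial_base, 15, seed = seed + 401)
write_allele_counts(pair$t1$counts, file.path(out_dir, "SERIAL_t1_counts.tsv"))
write_allele_counts(pair$t2$counts, file.path(out_dir, "SERIAL_t2_counts.tsv"))
truth$SERIAL <- list(lost_at_t2 = 15)

write_report_json(truth, file.path(out_dir, "ground_truth.json"))
message("cohort written to ", out_dir)
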