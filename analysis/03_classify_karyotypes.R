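#!/usr/bin/env Rscript
# Classify each sample's karyotype group (hyperhaploid 24-34 /
# hyperdiploid 47-57 / other), count monosomies, summarize heterodisomy
# and compare the serial pair.
#
# Reads results/calls/*_calls.tsv; writes results/karyotypes/
# cohort_summary.tsv, monosomy_frequency.tsv and serial_comparison.json.

suppressPackageStartupMessages(library(hyperhaploidy))

in_dir <- "results/calls"
out_dir <- "results/karyotypes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

call_files <- list.files(in_dir, pattern = "_calls\\.tsv$",
                         full.names = TRUE)
stopifnot(length(call_files) > 0)
calls <- lapply(call_files, read_chromosome_calls)
names(calls) <- sub("_calls\\.tsv$", "", basename(call_files))

summaries <- lapply(calls, summarize_karyotype)
cohort <- do.call(rbind, lapply(names(summaries), function(id) {
  k <- summaries[[id]]
  data.frame(sample = id, group = k$group, total_count = k$total_count,
             monosomy_count = k$monosomy_count,
             disomic_loh_fraction = k$disomic_loh_fraction)
}))
write.table(cohort, file.path(out_dir, "cohort_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("karyotype groups: ",
        paste(names(table(cohort$group)), table(cohort$group),
              sep = "=", collapse = ", "))
hh <- cohort[cohort$group == "hyperhaploid", ]
message("monosomies in hyperhaploid samples: median ",
        median(hh$monosomy_count), " (range ", min(hh$monosomy_count),
        "-", max(hh$monosomy_count), ")")

# per-chromosome monosomy frequency over the hyperhaploid samples
hh_calls <- calls[cohort$sample[cohort$group == "hyperhaploid"]]
ind <- lapply(hh_calls, function(cl) count_monosomies(cl)$indicator)
freq <- do.call(rbind, lapply(1:22, function(ch) {
  v <- unlist(lapply(ind, function(i) i$monosomic[i$chrom == ch]))
  data.frame(chrom = ch, n_monosomic = sum(v, na.rm = TRUE),
             n_called = sum(!is.na(v)),
             frequency = mean(v, na.rm = TRUE))
}))
write.table(freq, file.path(out_dir, "monosomy_frequency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
chr18 <- freq[freq$chrom == 18, ]
message("chromosome 18 disomic in ", chr18$n_called - chr18$n_monosomic,
        "/", chr18$n_called, " hyperhaploid samples; least-monosomic ",
        "chromosomes: ",
        paste(freq$chrom[order(freq$frequency)][1:9], collapse = ", "))

# serial pair: which chromosomes were lost between timepoints?
if (all(c("SERIAL_t1", "SERIAL_t2") %in% names(calls))) {
  cmp <- compare_serial(calls$SERIAL_t1, calls$SERIAL_t2)
  write_report_json(cmp, file.path(out_dir, "serial_comparison.json"))
  message("serial pair: chromosome(s) ",
          paste(cmp$lost, collapse = ", "), " lost at the second timepoint")
}
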