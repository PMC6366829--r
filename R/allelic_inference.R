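# Whole-chromosome allele-specific inference: mirrored B-allele
# frequency profiles, LOH calls, relative copy number from depth ratios,
# and ploidy renormalization anchored on LOH chromosomes.

#' Expected B-allele frequency under an allele-specific copy state
#'
#' The expectation behind tumor BAF plots: a tumor with purity `purity`
#' carrying `n_b` copies of the B (alt) allele out of `cn_t` total copies,
#' mixed with diploid heterozygous normal cells, has expected alt-read
#' fraction `((1 - purity) + purity * n_b) / ((1 - purity) * 2 + purity *
#' cn_t)`.
#'
#' @param n_b B-allele copy number in the tumor (0 <= `n_b` <= `cn_t`).
#' @param cn_t Total tumor copy number at the locus.
#' @param purity Tumor purity in \[0, 1\].
#' @return Expected BAF in \[0, 1\].
#' @examples
#' expected_baf(1, 2, 0.9)  # 0.5, balanced heterodisomy
#' expected_baf(0, 1, 0.9)  # 0.0909..., monosomy that lost the B homolog
#' @export
expected_baf <- function(n_b, cn_t, purity) {
  check_fraction(purity, "purity")
  if (n_b < 0 || cn_t < 0) stop("copy numbers must be non-negative",
                                call. = FALSE)
  if (n_b > cn_t) {
    stop("n_b = ", n_b, " exceeds cn_t = ", cn_t, call. = FALSE)
  }
  if (purity == 1 && cn_t == 0) {
    stop("expected BAF is undefined for a pure tumor with zero copies",
         call. = FALSE)
  }
  ((1 - purity) + purity * n_b) / ((1 - purity) * 2 + purity * cn_t)
}

mirror_baf <- function(baf) pmax(baf, 1 - baf)

#' Compute a mirrored B-allele frequency profile
#'
#' Per-SNP tumor BAF (`tumor_alt / tumor depth`) and mirrored BAF
#' `max(BAF, 1 - BAF)`, with per-chromosome median mirrored BAF. SNPs
#' below `min_depth` in either the tumor or the normal are excluded and
#' counted; a chromosome whose SNPs are all excluded is marked no-call.
#'
#' @param counts A `read_count_table` (see [simulate_allele_counts()] or
#'   [read_allele_counts()]).
#' @param min_depth Minimum tumor and normal depth per SNP (default 10).
#' @return A list of class `baf_profile`: `$snps` (retained SNPs with
#'   `baf`, `mirrored_baf`) and `$chromosomes` (`chrom`,
#'   `median_mirrored_baf`, `n_snps`, `n_excluded`, `no_call`).
#' @export
compute_baf_profile <- function(counts, min_depth = 10L) {
  if (nrow(counts) == 0L) {
    stop("`counts` is empty; at least one chromosome must have SNPs",
         call. = FALSE)
  }
  tumor_depth <- counts$tumor_ref + counts$tumor_alt
  normal_depth <- counts$normal_ref + counts$normal_alt
  keep <- tumor_depth >= min_depth & normal_depth >= min_depth
  snps <- counts[keep, , drop = FALSE]
  baf <- snps$tumor_alt / (snps$tumor_ref + snps$tumor_alt)
  snps$baf <- baf
  snps$mirrored_baf <- mirror_baf(baf)
  chroms <- sort(unique(counts$chrom))
  med <- vapply(chroms, function(ch) {
    v <- snps$mirrored_baf[snps$chrom == ch]
    if (length(v) == 0L) NA_real_ else median(v)
  }, numeric(1))
  n_snps <- vapply(chroms, function(ch) sum(snps$chrom == ch), integer(1))
  n_all <- vapply(chroms, function(ch) sum(counts$chrom == ch), integer(1))
  by_chrom <- data.frame(chrom = chroms,
                         median_mirrored_baf = med,
                         n_snps = n_snps,
                         n_excluded = n_all - n_snps,
                         no_call = n_snps == 0L)
  structure(list(snps = snps, chromosomes = by_chrom, min_depth = min_depth),
            class = "baf_profile")
}

#' Threshold for calling whole-chromosome LOH from mirrored BAF
#'
#' The midpoint between the heterodisomic expectation (mirrored BAF 0.5)
#' and the purity-adjusted monosomy expectation
#' `mirror(expected_baf(0, 1, purity))`. Reduces to 0.75 at purity 1.
#'
#' @inheritParams expected_baf
#' @return The decision threshold in (0.5, 0.75\].
#' @export
loh_threshold <- function(purity) {
  (0.5 + mirror_baf(expected_baf(0L, 1L, purity))) / 2
}

#' Call whole-chromosome loss of heterozygosity
#'
#' A chromosome is called LOH when its median mirrored BAF is at or above
#' [loh_threshold()] (minus `tolerance`) and it has at least `min_snps`
#' usable SNPs; chromosomes with fewer SNPs are no-call, never an error.
#'
#' @param profile A [compute_baf_profile()] result.
#' @param purity Tumor purity (a config input, not estimated).
#' @param min_snps Minimum SNPs per chromosome to call (default 20).
#' @param tolerance Slack subtracted from the threshold (default 0).
#' @return A `data.frame` with `chrom`, `loh` (logical, NA for no-call),
#'   `median_mirrored_baf`, `n_snps`, `no_call`, `threshold`.
#' @export
call_chromosome_loh <- function(profile, purity, min_snps = 20L,
                                tolerance = 0) {
  thr <- loh_threshold(purity)
  bc <- profile$chromosomes
  callable <- !bc$no_call & bc$n_snps >= min_snps
  loh <- ifelse(callable, bc$median_mirrored_baf >= thr - tolerance, NA)
  data.frame(chrom = bc$chrom, loh = loh,
             median_mirrored_baf = bc$median_mirrored_baf,
             n_snps = bc$n_snps, no_call = !callable, threshold = thr)
}

#' Estimate relative copy number from tumor/normal depth ratios
#'
#' Per-SNP ratio of tumor to normal depth, summarized as a per-chromosome
#' median and normalized so the genome-wide median SNP ratio maps to
#' `anchor` (default 1; the absolute scale is fixed later by
#' [renormalize_ploidy()]). SNPs with zero normal depth are excluded.
#'
#' @param counts A `read_count_table`.
#' @param anchor Value the genome-wide median ratio is mapped to.
#' @return A `data.frame` with `chrom`, `depth_ratio` (NA for chromosomes
#'   with no usable SNPs), `n_snps`.
#' @export
estimate_relative_cn <- function(counts, anchor = 1) {
  tumor_depth <- counts$tumor_ref + counts$tumor_alt
  normal_depth <- counts$normal_ref + counts$normal_alt
  keep <- normal_depth > 0
  ratio <- tumor_depth[keep] / normal_depth[keep]
  chrom <- counts$chrom[keep]
  genome_median <- median(ratio)
  ratio <- ratio / genome_median * anchor
  chroms <- sort(unique(counts$chrom))
  med <- vapply(chroms, function(ch) {
    v <- ratio[chrom == ch]
    if (length(v) == 0L) NA_real_ else median(v)
  }, numeric(1))
  n <- vapply(chroms, function(ch) sum(chrom == ch), integer(1))
  data.frame(chrom = chroms, depth_ratio = med, n_snps = n)
}

#' Renormalize ploidy so LOH chromosomes have copy number one
#'
#' Where consistent whole-chromosome LOH is seen, the sample's ploidy is
#' rescaled so the median depth ratio of LOH chromosomes maps to copy
#' number one; every chromosome is then assigned the nearest integer copy
#' number (half rounds up). LOH chromosomes whose scaled ratio deviates
#' from 1 by more than `tolerance` are flagged discordant rather than
#' silently overwritten -- under the haploidization-then-duplication
#' mechanism, duplicated LOH chromosomes surface exactly this way.
#'
#' @param ratios An [estimate_relative_cn()] result.
#' @param loh_calls A [call_chromosome_loh()] result.
#' @param tolerance Maximum |scaled ratio - 1| for an LOH chromosome to be
#'   concordant (default 0.25).
#' @param anchor_cn Fallback copy number assigned to the genome-wide
#'   median ratio when no chromosome shows LOH (e.g. 2 for a diploid
#'   sample). Required in that case; unused otherwise.
#' @return A list of class `ploidy_solution`: `$calls` (`chrom`, `cn`,
#'   `loh`, `n_snps`, `confidence`, `depth_ratio`, `scaled_ratio`,
#'   `discordant`, `no_call`), `$scale_factor`, `$renormalized`.
#' @export
renormalize_ploidy <- function(ratios, loh_calls, tolerance = 0.25,
                               anchor_cn = NULL) {
  m <- merge(ratios, loh_calls[, c("chrom", "loh", "n_snps", "no_call")],
             by = "chrom", suffixes = c("", "_baf"))
  m <- m[order(m$chrom), ]
  loh_known <- !is.na(m$loh) & m$loh & !is.na(m$depth_ratio)
  if (any(loh_known)) {
    scale_factor <- 1 / median(m$depth_ratio[loh_known])
    renormalized <- TRUE
  } else if (!is.null(anchor_cn)) {
    scale_factor <- anchor_cn / median(m$depth_ratio, na.rm = TRUE)
    renormalized <- FALSE
  } else {
    stop("no LOH chromosomes found; supply `anchor_cn` (assumed copy ",
         "number of the genome-wide median ratio) to fix the scale",
         call. = FALSE)
  }
  scaled <- m$depth_ratio * scale_factor
  cn <- as.integer(round_half_up(scaled))
  cn[!is.na(cn) & cn < 0L] <- 0L
  discordant <- loh_known & abs(scaled - 1) > tolerance
  # confidence saturates with SNP support: crude but monotone in n_snps
  confidence <- m$n_snps / (m$n_snps + 10)
  confidence[m$no_call | is.na(m$depth_ratio)] <- 0
  calls <- data.frame(chrom = m$chrom, cn = cn, loh = m$loh,
                      n_snps = m$n_snps, confidence = confidence,
                      depth_ratio = m$depth_ratio, scaled_ratio = scaled,
                      discordant = discordant,
                      no_call = m$no_call | is.na(m$depth_ratio))
  structure(list(calls = calls, scale_factor = scale_factor,
                 renormalized = renormalized, tolerance = tolerance),
            class = "ploidy_solution")
}

#' @export
print.ploidy_solution <- function(x, ...) {
  cat("<ploidy_solution>", if (x$renormalized) "renormalized on LOH" else
    "anchored", "| scale factor:", signif(x$scale_factor, 4), "\n")
  print(x$calls, row.names = FALSE)
  invisible(x)
}

#' Run the whole-chromosome inference chain on one sample
#'
#' Convenience wrapper: BAF profile, LOH calls, depth ratios and ploidy
#' renormalization in one step.
#'
#' @param counts A `read_count_table`.
#' @param purity Tumor purity.
#' @param min_depth,min_snps,loh_tolerance,cn_tolerance,anchor_cn Passed
#'   to the component steps.
#' @return A `ploidy_solution` (see [renormalize_ploidy()]).
#' @export
call_chromosomes <- function(counts, purity, min_depth = 10L,
                             min_snps = 20L, loh_tolerance = 0,
                             cn_tolerance = 0.25, anchor_cn = 2) {
  profile <- compute_baf_profile(counts, min_depth = min_depth)
  loh <- call_chromosome_loh(profile, purity, min_snps = min_snps,
                             tolerance = loh_tolerance)
  ratios <- estimate_relative_cn(counts)
  renormalize_ploidy(ratios, loh, tolerance = cn_tolerance,
                     anchor_cn = anchor_cn)
}
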