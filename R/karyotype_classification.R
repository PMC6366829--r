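# Karyotype-group classification, monosomy bookkeeping, heterodisomy
# summaries and serial-sample comparison over per-chromosome calls.

#' Classify a total chromosome count into a ploidy group
#'
#' Hyperhaploid karyotypes carry 24-34 chromosomes; hyperdiploid
#' karyotypes carry 47-57 (both inclusive). Everything else, including
#' the normal diploid 46, is `"other"`.
#'
#' @param total_count Total chromosome count (autosomes + sex
#'   chromosomes), a non-negative integer.
#' @return `"hyperhaploid"`, `"hyperdiploid"` or `"other"`.
#' @examples
#' classify_ploidy_group(30)  # hyperhaploid
#' classify_ploidy_group(50)  # hyperdiploid
#' classify_ploidy_group(46)  # other
#' @export
classify_ploidy_group <- function(total_count) {
  if (!is.numeric(total_count) || length(total_count) != 1L ||
      is.na(total_count) || total_count < 0) {
    stop("`total_count` must be a non-negative integer", call. = FALSE)
  }
  if (total_count >= 24 && total_count <= 34) return("hyperhaploid")
  if (total_count >= 47 && total_count <= 57) return("hyperdiploid")
  "other"
}

#' Count monosomic autosomes
#'
#' @param calls A per-chromosome call table with columns `chrom`, `cn`
#'   and `no_call` (a `ploidy_solution$calls`, or any data.frame with
#'   those columns). No-call chromosomes are reported separately and
#'   never counted as monosomic.
#' @return A list: `count` (autosomes with CN 1), `no_call_count`, and
#'   `indicator` (`chrom`, `monosomic`, NA where no-call).
#' @export
count_monosomies <- function(calls) {
  calls <- as_call_table(calls)
  mono <- ifelse(calls$no_call, NA, calls$cn == 1L)
  list(count = sum(mono, na.rm = TRUE),
       no_call_count = sum(calls$no_call),
       indicator = data.frame(chrom = calls$chrom, monosomic = mono))
}

#' Summarize heterodisomy over disomic chromosomes
#'
#' The fraction of called CN-2 chromosomes flagged LOH -- the statistic
#' that discriminates the three hyperhaploidy-generating mechanisms
#' (see [classify_mechanism()]). With no disomic chromosomes the fraction
#' is undefined and flagged, not an error.
#'
#' @param calls A per-chromosome call table (needs `chrom`, `cn`, `loh`,
#'   `no_call`).
#' @return A list: `n_disomic`, `k_loh`, `disomic_loh_fraction` (NA when
#'   undefined), `undefined` flag, and the per-chromosome `table`.
#' @export
heterodisomy_summary <- function(calls) {
  calls <- as_call_table(calls)
  disomic <- !calls$no_call & calls$cn == 2L & !is.na(calls$loh)
  n <- sum(disomic)
  k <- sum(calls$loh[disomic])
  list(n_disomic = n, k_loh = k,
       disomic_loh_fraction = if (n > 0L) k / n else NA_real_,
       undefined = n == 0L,
       table = data.frame(chrom = calls$chrom[disomic],
                          loh = calls$loh[disomic]))
}

#' Summarize one sample's karyotype
#'
#' Aggregates per-chromosome calls into a karyotype-level summary: total
#' chromosome count (autosomal CN sum plus the configured sex-chromosome
#' copies), ploidy group, monosomy count and disomic-LOH fraction. The
#' pipeline is autosome-only, so the sex contribution is an explicit
#' assumption, not an inference. Samples with more than
#' `max_no_calls` uncallable autosomes are labeled `"unclassifiable"`.
#'
#' @param solution A `ploidy_solution` or its `$calls` table.
#' @param sex_chromosome_copies Copies of sex chromosomes added to the
#'   autosomal CN sum (default 2).
#' @param max_no_calls No-call budget before the sample is unclassifiable
#'   (default 4, the width of the gap below the hyperhaploid band).
#' @return A list of class `karyotype_call`: `group`, `total_count`,
#'   `monosomy_count`, `no_call_count`, `disomic_loh_fraction`,
#'   `disomic_loh_undefined`, `calls`.
#' @export
summarize_karyotype <- function(solution, sex_chromosome_copies = 2L,
                                max_no_calls = 4L) {
  calls <- as_call_table(solution)
  called <- !calls$no_call
  total <- sum(calls$cn[called]) + sex_chromosome_copies
  mono <- count_monosomies(calls)
  het <- heterodisomy_summary(calls)
  group <- if (mono$no_call_count > max_no_calls) "unclassifiable" else
    classify_ploidy_group(total)
  structure(list(group = group, total_count = total,
                 monosomy_count = mono$count,
                 no_call_count = mono$no_call_count,
                 disomic_loh_fraction = het$disomic_loh_fraction,
                 disomic_loh_undefined = het$undefined,
                 calls = calls),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat("<karyotype_call> group:", x$group,
      "| total count:", x$total_count,
      "| monosomies:", x$monosomy_count,
      "| disomic-LOH fraction:",
      if (x$disomic_loh_undefined) "undefined" else
        signif(x$disomic_loh_fraction, 3), "\n")
  invisible(x)
}

#' Compare per-chromosome calls between two serial samples
#'
#' Reports chromosomes whose copy number decreased (lost), increased
#' (gained) or stayed the same between two timepoints; chromosomes
#' uncallable at either timepoint are incomparable.
#'
#' @param calls_t1,calls_t2 Call tables covering the same autosomes.
#' @return A list of integer chromosome vectors: `lost`, `gained`,
#'   `unchanged`, `incomparable`.
#' @export
compare_serial <- function(calls_t1, calls_t2) {
  a <- as_call_table(calls_t1)
  b <- as_call_table(calls_t2)
  if (!identical(sort(a$chrom), sort(b$chrom))) {
    stop("serial call sets cover different chromosomes", call. = FALSE)
  }
  a <- a[order(a$chrom), ]
  b <- b[order(b$chrom), ]
  comparable <- !a$no_call & !b$no_call
  delta <- b$cn - a$cn
  list(lost = a$chrom[comparable & delta < 0],
       gained = a$chrom[comparable & delta > 0],
       unchanged = a$chrom[comparable & delta == 0],
       incomparable = a$chrom[!comparable])
}

# Accept a ploidy_solution, karyotype_call, or bare calls data.frame.
as_call_table <- function(x) {
  if (inherits(x, "ploidy_solution")) x <- x$calls
  if (inherits(x, "karyotype_call")) x <- x$calls
  if (!is.data.frame(x) || !all(c("chrom", "cn") %in% names(x))) {
    stop("expected a ploidy_solution or a call table with `chrom`, `cn`",
         call. = FALSE)
  }
  if (is.null(x$no_call)) x$no_call <- is.na(x$cn)
  if (is.null(x$loh)) x$loh <- NA
  x
}
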