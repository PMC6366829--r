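# Cancer cell fraction, clonality, bi-allelic ("double-hit") gene
# inactivation calls and deletion-vs-mutation event ordering.

# Built-in gene -> chromosome map for the loci this analysis reasons
# about; extend per sample set via the `gene_table` arguments.
DEFAULT_GENE_TABLE <- c(TP53 = 17L, CYLD = 16L, TRAF3 = 14L)

#' Convert a variant allele frequency to a cancer cell fraction
#'
#' The standard purity/copy-number correction:
#' `CCF = VAF * (purity * CN_t + (1 - purity) * CN_n) / (purity * m)`,
#' where `CN_t`/`CN_n` are tumor/normal copy number at the locus and `m`
#' the mutation multiplicity. Raw values above 1 (sampling noise,
#' multiplicity misassignment) are capped at 1 with the raw value
#' retained.
#'
#' @param vaf Variant allele frequency in \[0, 1\].
#' @param purity Tumor purity in (0, 1\].
#' @param cn_t Tumor copy number at the locus.
#' @param cn_n Normal copy number at the locus (default 2).
#' @param m Mutation multiplicity (mutated copies per tumor cell, >= 1).
#' @param clonal_threshold CCF at or above which a mutation is clonal
#'   (default 0.8).
#' @return A list of class `ccf_estimate`: `ccf` (capped), `raw`,
#'   `clonality`, and the `inputs` used.
#' @examples
#' compute_ccf(0.5, purity = 1, cn_t = 2, m = 1)$ccf   # 1
#' compute_ccf(0.42, purity = 1, cn_t = 1, m = 1)$ccf  # 0.42, subclonal
#' @export
compute_ccf <- function(vaf, purity, cn_t, cn_n = 2L, m = 1L,
                        clonal_threshold = 0.8) {
  check_fraction(vaf, "vaf")
  check_fraction(purity, "purity", lower = 0, upper = 1, lower_open = TRUE)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (m > max(cn_t, 1)) {
    stop("multiplicity m = ", m, " exceeds tumor copy number ", cn_t,
         call. = FALSE)
  }
  raw <- vaf * (purity * cn_t + (1 - purity) * cn_n) / (purity * m)
  ccf <- min(raw, 1)
  structure(list(ccf = ccf, raw = raw,
                 clonality = classify_clonality(ccf, clonal_threshold),
                 inputs = list(vaf = vaf, purity = purity, cn_t = cn_t,
                               cn_n = cn_n, m = m)),
            class = "ccf_estimate")
}

#' Classify a cancer cell fraction as clonal or subclonal
#'
#' @param ccf A capped CCF in \[0, 1\] or a `ccf_estimate`.
#' @param threshold Clonality threshold (default 0.8); `ccf >= threshold`
#'   is clonal.
#' @return `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(ccf, threshold = 0.8) {
  if (inherits(ccf, "ccf_estimate")) ccf <- ccf$ccf
  if (ccf >= threshold) "clonal" else "subclonal"
}

#' Assign mutation multiplicity by binomial likelihood
#'
#' Chooses the multiplicity `m` in `1..CN_t` whose expected VAF under a
#' fully clonal mutation, `purity * m / (purity * CN_t + (1 - purity) *
#' 2)`, maximizes the binomial likelihood of the observed alt counts.
#' With `CN_t = 1` the only option is `m = 1`.
#'
#' @param vaf Observed variant allele frequency.
#' @param purity Tumor purity.
#' @param cn_t Tumor copy number at the locus (>= 1).
#' @param alt,depth Observed alt and total read counts; when absent they
#'   are reconstructed from `vaf` at a nominal depth of 100.
#' @return The maximum-likelihood multiplicity (integer).
#' @export
assign_multiplicity <- function(vaf, purity, cn_t, alt = NULL,
                                depth = NULL) {
  if (cn_t < 1) {
    stop("a mutation on a fully deleted locus (CN_t = 0) is inconsistent",
         call. = FALSE)
  }
  if (cn_t == 1L) return(1L)
  if (is.null(depth)) depth <- 100L
  if (is.null(alt)) alt <- round(vaf * depth)
  ll <- vapply(seq_len(cn_t), function(m) {
    p <- min(purity * m / (purity * cn_t + (1 - purity) * 2), 1)
    dbinom(alt, depth, p, log = TRUE)
  }, numeric(1))
  which.max(ll)
}

#' Call bi-allelic ("double-hit") inactivation of a gene
#'
#' Combines mutation and whole-chromosome copy-number evidence at a gene
#' locus. The verdict is `"biallelic"` when two independent hits cover
#' both alleles: a mutation on a monosomic (CN 1, LOH) chromosome, two or
#' more mutations on an LOH chromosome at CN >= 2, or homozygous deletion
#' (CN 0). A single hit (mutation on a heterodisomic background, or a
#' deletion alone) is `"monoallelic"`; no hits is `"wild-type"`. Event
#' order is inferred from mutation vs deletion clonality via
#' [infer_event_order()] when a mutation is present.
#'
#' @param gene Gene symbol.
#' @param mutations A mutation table (`gene`, `chrom`, `pos`, `vaf`, ...)
#'   for the sample; rows for other genes are ignored.
#' @param chromosome_call A one-row call for the gene's chromosome
#'   (needs `cn`, `loh`), or a full call table from which it is selected
#'   via `gene_table`.
#' @param purity Tumor purity used for CCF computation.
#' @param clonal_threshold Clonality threshold on CCF.
#' @param deletion_clonality Clonality of the chromosome loss; whole-
#'   chromosome monosomies called from median BAF shifts are clonal-level
#'   events, so the default is `"clonal"`.
#' @param gene_table Named integer vector mapping genes to chromosomes
#'   (default TP53/CYLD/TRAF3).
#' @return A list of class `double_hit_call`: `gene`, `verdict`,
#'   `evidence`, `order`, `n_mutations`, `cn`, `loh`, `ccf` (list of
#'   `ccf_estimate`s, one per mutation).
#' @export
call_double_hit <- function(gene, mutations, chromosome_call,
                            purity = 1, clonal_threshold = 0.8,
                            deletion_clonality = "clonal",
                            gene_table = DEFAULT_GENE_TABLE) {
  call <- resolve_gene_call(gene, chromosome_call, gene_table)
  cn <- call$cn
  loh <- isTRUE(call$loh)
  muts <- mutations[!is.na(mutations$gene) & mutations$gene == gene, ,
                    drop = FALSE]
  n_mut <- nrow(muts)
  if (cn == 0L && n_mut > 0L) {
    stop("gene ", gene, " has mutations but CN 0 at its locus; ",
         "inconsistent input", call. = FALSE)
  }
  ccfs <- lapply(seq_len(n_mut), function(i) {
    m <- assign_multiplicity(muts$vaf[i], purity, max(cn, 1L),
                             alt = muts$tumor_alt[i],
                             depth = muts$tumor_alt[i] + muts$tumor_ref[i])
    compute_ccf(muts$vaf[i], purity, max(cn, 1L), m = m,
                clonal_threshold = clonal_threshold)
  })
  verdict <- "wild-type"
  evidence <- NA_character_
  if (cn == 0L) {
    verdict <- "biallelic"
    evidence <- "homozygous_deletion"
  } else if (n_mut >= 1L && cn == 1L && loh) {
    verdict <- "biallelic"
    evidence <- "mutation+monosomy"
  } else if (n_mut >= 2L && loh && cn >= 2L) {
    verdict <- "biallelic"
    evidence <- "two_mutations_with_LOH"
  } else if (n_mut >= 1L || cn == 1L) {
    verdict <- "monoallelic"
    evidence <- if (n_mut >= 1L) "mutation_only" else "deletion_only"
  }
  order <- "undetermined"
  if (n_mut >= 1L && cn <= 1L && verdict == "biallelic") {
    mut_clon <- ccfs[[which.max(vapply(ccfs, `[[`, 0, "ccf"))]]$clonality
    order <- infer_event_order(mut_clon, deletion_clonality)
  }
  structure(list(gene = gene, verdict = verdict, evidence = evidence,
                 order = order, n_mutations = n_mut, cn = cn, loh = loh,
                 ccf = ccfs),
            class = "double_hit_call")
}

#' @export
print.double_hit_call <- function(x, ...) {
  cat("<double_hit_call>", x$gene, "->", x$verdict,
      if (!is.na(x$evidence)) paste0("(", x$evidence, ")") else "",
      "| order:", x$order, "\n")
  invisible(x)
}

#' Infer whether deletion or mutation came first
#'
#' A subclonal mutation on the background of a clonal deletion implies
#' the deletion preceded the mutation, and vice versa; when both events
#' have the same clonality there is no ordering signal.
#'
#' @param mutation_clonality,deletion_clonality `"clonal"` or
#'   `"subclonal"`.
#' @return `"deletion_first"`, `"mutation_first"` or `"undetermined"`.
#' @export
infer_event_order <- function(mutation_clonality, deletion_clonality) {
  stopifnot(mutation_clonality %in% c("clonal", "subclonal"),
            deletion_clonality %in% c("clonal", "subclonal"))
  if (mutation_clonality == "subclonal" && deletion_clonality == "clonal") {
    "deletion_first"
  } else if (mutation_clonality == "clonal" &&
             deletion_clonality == "subclonal") {
    "mutation_first"
  } else {
    "undetermined"
  }
}

resolve_gene_call <- function(gene, chromosome_call, gene_table) {
  if (is.data.frame(chromosome_call) && nrow(chromosome_call) > 1L ||
      inherits(chromosome_call, "ploidy_solution")) {
    calls <- as_call_table(chromosome_call)
    if (!gene %in% names(gene_table)) {
      stop("no chromosome mapping for gene ", gene,
           "; extend `gene_table`", call. = FALSE)
    }
    chrom <- gene_table[[gene]]
    row <- calls[calls$chrom == chrom, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("call table does not cover chromosome ", chrom, call. = FALSE)
    }
    return(row)
  }
  chromosome_call
}
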