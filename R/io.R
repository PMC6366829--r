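# Readers and writers for the pipeline's plain-text formats. All
# coordinates are 1-based inclusive (VCF convention); chromosome labels
# are accepted with or without a "chr" prefix and normalized to 1..22.

COUNT_COLUMNS <- c("chrom", "pos", "ref", "alt",
                   "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")

#' Write a tumor/normal allele-count table as TSV
#'
#' @param counts A `read_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  write.table(counts[, COUNT_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tumor/normal allele-count table from TSV
#'
#' Expects the 8-column header written by [write_allele_counts()]:
#' `chrom pos ref alt normal_ref normal_alt tumor_ref tumor_alt`, with
#' 1-based positions sorted within chromosomes.
#'
#' @param path Input TSV path.
#' @return A validated `read_count_table`.
#' @export
read_allele_counts <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(COUNT_COLUMNS, header)
  if (length(missing_cols) > 0L) {
    stop("allele-count file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "integer", "character",
                                 "character", rep("integer", 4L)))
  if (nrow(x) == 0L) {
    warning("allele-count file ", path, " has a header but no records",
            call. = FALSE)
  } else {
    x$chrom <- normalize_chrom(x$chrom)
    counts <- x[, c("normal_ref", "normal_alt", "tumor_ref", "tumor_alt")]
    if (anyNA(counts) || any(counts < 0)) {
      bad <- which(apply(is.na(counts) | counts < 0, 1L, any))
      stop("non-integer or negative counts at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    key <- paste(x$chrom, x$pos)
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      stop("duplicate (chrom, pos) records at line(s) ",
           paste(dup + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    unsorted <- unlist(lapply(split(seq_len(nrow(x)), x$chrom), function(i) {
      i[c(FALSE, diff(x$pos[i]) <= 0)]
    }), use.names = FALSE)
    if (length(unsorted) > 0L) {
      stop("positions not strictly increasing at line(s) ",
           paste(sort(unsorted) + 1L, collapse = ", "), " of ", path,
           call. = FALSE)
    }
  }
  class(x) <- c("read_count_table", "data.frame")
  x
}

#' Read somatic mutations from TSV or minimal VCF
#'
#' TSV needs columns `gene chrom pos` plus either `vaf` or read counts
#' `tumor_ref`/`tumor_alt` (VAF is computed from counts when absent; when
#' both are given they must agree to 0.005). VCF must be v4.x with an
#' `AD` (ref,alt depths) FORMAT field in the first sample column and a
#' `GENE` INFO tag; multi-allelic records are not supported.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return A `data.frame` with columns `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `tumor_ref`, `tumor_alt`, `vaf`, `source_line`.
#' @export
read_mutations <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_mutations_vcf(path) else read_mutations_tsv(path)
}

read_mutations_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("mutation TSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_counts <- all(c("tumor_ref", "tumor_alt") %in% names(x))
  if (!("vaf" %in% names(x)) && !has_counts) {
    stop("mutation TSV ", path, " needs a `vaf` column or ",
         "`tumor_ref`/`tumor_alt` counts", call. = FALSE)
  }
  if (nrow(x) > 0L) x$chrom <- normalize_chrom(x$chrom)
  if (!("vaf" %in% names(x))) {
    x$vaf <- x$tumor_alt / (x$tumor_alt + x$tumor_ref)
  } else if (has_counts) {
    count_vaf <- x$tumor_alt / (x$tumor_alt + x$tumor_ref)
    off <- which(abs(x$vaf - count_vaf) > 0.005)
    if (length(off) > 0L) {
      stop("VAF disagrees with read counts at line(s) ",
           paste(off + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
  }
  if (!has_counts) x$tumor_ref <- x$tumor_alt <- NA_integer_
  if (is.null(x$ref)) x$ref <- NA_character_
  if (is.null(x$alt)) x$alt <- NA_character_
  x$source_line <- seq_len(nrow(x)) + 1L
  x[, c("gene", "chrom", "pos", "ref", "alt", "tumor_ref", "tumor_alt",
        "vaf", "source_line")]
}

read_mutations_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)  # single-record VCF
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(read_mutations_tsv_empty())
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported; normalize the VCF ",
         "to one ALT allele per record first", call. = FALSE)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF ", path, " has no AD field; cannot compute VAF", call. = FALSE)
  }
  if (is.null(dim(ad))) ad <- matrix(ad, ncol = 1L)
  ad1 <- ad[, 1L]
  parts <- strsplit(ad1, ",", fixed = TRUE)
  ref_n <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
  alt_n <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  gene <- vcfR::extract.info(vcf, element = "GENE")
  data.frame(gene = gene, chrom = normalize_chrom(fix$CHROM),
             pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
             tumor_ref = ref_n, tumor_alt = alt_n,
             vaf = alt_n / (alt_n + ref_n),
             source_line = seq_len(nrow(fix)))
}

read_mutations_tsv_empty <- function() {
  data.frame(gene = character(), chrom = integer(), pos = integer(),
             ref = character(), alt = character(), tumor_ref = integer(),
             tumor_alt = integer(), vaf = numeric(),
             source_line = integer())
}

#' Write somatic mutations as a minimal VCF 4.2
#'
#' One sample column with `AD` (ref,alt) and a `GENE` INFO tag --
#' re-readable by [read_mutations()].
#'
#' @param mutations A mutation table with `gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `tumor_ref`, `tumor_alt`.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(mutations, path, sample_name = "TUMOR") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  ref <- ifelse(is.na(mutations$ref), "N", mutations$ref)
  alt <- ifelse(is.na(mutations$alt), "N", mutations$alt)
  body <- paste(mutations$chrom, mutations$pos, ".", ref, alt, ".",
                "PASS", paste0("GENE=", mutations$gene), "GT:AD",
                paste0("0/1:", mutations$tumor_ref, ",",
                       mutations$tumor_alt),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write per-chromosome calls as TSV
#'
#' @param solution A `ploidy_solution` or call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromosome_calls <- function(solution, path) {
  calls <- as_call_table(solution)
  out <- calls[, intersect(c("chrom", "cn", "loh", "n_snps", "confidence",
                             "depth_ratio", "discordant", "no_call"),
                           names(calls))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-chromosome calls from TSV
#'
#' @param path A TSV written by [write_chromosome_calls()].
#' @return A call table usable by [summarize_karyotype()] etc.
#' @export
read_chromosome_calls <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t")
  x$chrom <- normalize_chrom(x$chrom)
  x
}

#' Write a ploidy solution (or any pipeline report) as JSON
#'
#' @param x A `ploidy_solution`, `mechanism_posterior`, or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
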