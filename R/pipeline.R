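# Pipeline configuration and the end-to-end per-sample analysis.

#' Build a validated pipeline configuration
#'
#' All tunable parameters of the analysis in one validated list. Unknown
#' names are rejected; the result round-trips losslessly through JSON or
#' YAML.
#'
#' @param purity Tumor purity in (0, 1\] (default 0.9).
#' @param min_depth Minimum per-SNP depth (default 10).
#' @param min_snps Minimum SNPs per chromosome for an LOH call
#'   (default 20).
#' @param loh_tolerance Slack on the LOH BAF threshold (default 0).
#' @param cn_tolerance Concordance band for LOH chromosomes around copy
#'   number 1 (default 0.25).
#' @param clonal_threshold CCF clonality threshold (default 0.8).
#' @param epsilon Per-chromosome LOH call-error rate for mechanism
#'   likelihoods (default 0.01).
#' @param sex_chromosome_copies Sex-chromosome copies added to total
#'   counts (default 2).
#' @param anchor_cn Copy number assumed for the genome-median depth ratio
#'   when no LOH chromosome anchors the scale (default 2).
#' @param retained_set Autosomes the simulator keeps disomic.
#' @param seed Default seed for stochastic stages.
#' @param gene_table Named gene-to-chromosome map for double-hit calls.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(purity = 0.9, min_depth = 10L, min_snps = 20L,
                            loh_tolerance = 0, cn_tolerance = 0.25,
                            clonal_threshold = 0.8, epsilon = 0.01,
                            sex_chromosome_copies = 2L, anchor_cn = 2L,
                            retained_set = DEFAULT_RETAINED_SET,
                            seed = 1L, gene_table = DEFAULT_GENE_TABLE) {
  check_fraction(purity, "purity", lower = 0, upper = 1, lower_open = TRUE)
  check_fraction(clonal_threshold, "clonal_threshold")
  check_fraction(epsilon, "epsilon", lower = 0, upper = 0.5,
                 lower_open = TRUE, upper_open = TRUE)
  stopifnot(min_depth >= 0, min_snps >= 0, loh_tolerance >= 0,
            cn_tolerance >= 0, sex_chromosome_copies >= 0, anchor_cn >= 1)
  structure(list(purity = purity, min_depth = as.integer(min_depth),
                 min_snps = as.integer(min_snps),
                 loh_tolerance = loh_tolerance,
                 cn_tolerance = cn_tolerance,
                 clonal_threshold = clonal_threshold, epsilon = epsilon,
                 sex_chromosome_copies = as.integer(sex_chromosome_copies),
                 anchor_cn = as.integer(anchor_cn),
                 retained_set = as.integer(retained_set),
                 seed = as.integer(seed),
                 # stored as a named list so the config serializes with
                 # gene names intact
                 gene_table = as.list(gene_table)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path A `.json`, `.yaml` or `.yml` file whose keys are
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$gene_table)) raw$gene_table <- unlist(raw$gene_table)
  do.call(pipeline_config, raw)
}

#' Run the full per-sample analysis
#'
#' Chains the whole pipeline on one sample: BAF profile, LOH calls, depth
#' ratios, ploidy renormalization, karyotype summary, mechanism
#' inference, and (when mutations are supplied) CCF and double-hit calls
#' per gene in the config's gene table. Deterministic given config and
#' inputs.
#'
#' @param config A [pipeline_config()].
#' @param counts A `read_count_table` for the sample.
#' @param mutations Optional somatic mutation table
#'   (see [read_mutations()]).
#' @return A list of class `sample_report`: `ploidy` (the
#'   `ploidy_solution`), `karyotype` (the `karyotype_call`), `mechanism`
#'   (the `mechanism_posterior`), `double_hit` (named list of
#'   `double_hit_call`s), `config`.
#' @export
run_pipeline <- function(config, counts, mutations = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  ploidy <- stage("allelic_inference", call_chromosomes(
    counts, purity = config$purity, min_depth = config$min_depth,
    min_snps = config$min_snps, loh_tolerance = config$loh_tolerance,
    cn_tolerance = config$cn_tolerance, anchor_cn = config$anchor_cn))
  karyotype <- stage("karyotype_classification", summarize_karyotype(
    ploidy, sex_chromosome_copies = config$sex_chromosome_copies))
  mechanism <- stage("mechanism_inference", classify_mechanism_from_calls(
    ploidy, epsilon = config$epsilon))
  double_hit <- list()
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    genes <- intersect(unique(mutations$gene), names(config$gene_table))
    double_hit <- stage("clonality_doublehit", setNames(lapply(
      genes, call_double_hit, mutations = mutations,
      chromosome_call = ploidy, purity = config$purity,
      clonal_threshold = config$clonal_threshold,
      gene_table = config$gene_table), genes))
  }
  structure(list(ploidy = ploidy, karyotype = karyotype,
                 mechanism = mechanism, double_hit = double_hit,
                 config = config),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  print(x$karyotype)
  print(x$mechanism)
  for (dh in x$double_hit) print(dh)
  invisible(x)
}

#' Summarize a cohort of sample reports as a table
#'
#' One row per sample: group, total chromosome count, monosomy count and
#' disomic-LOH fraction -- the cohort view of the karyotype analysis.
#'
#' @param reports A named list of [run_pipeline()] results.
#' @return A `data.frame` with one row per sample.
#' @export
cohort_summary <- function(reports) {
  rows <- lapply(names(reports), function(id) {
    k <- reports[[id]]$karyotype
    data.frame(sample = id, group = k$group, total_count = k$total_count,
               monosomy_count = k$monosomy_count,
               disomic_loh_fraction = k$disomic_loh_fraction,
               mechanism = reports[[id]]$mechanism$winner)
  })
  do.call(rbind, rows)
}

#' Per-chromosome monosomy frequency across a cohort
#'
#' @param reports A named list of [run_pipeline()] results.
#' @return A `data.frame` with `chrom`, `n_monosomic`, `n_called`,
#'   `frequency`.
#' @export
monosomy_frequency <- function(reports) {
  ind <- lapply(reports, function(r) count_monosomies(r$ploidy)$indicator)
  chroms <- sort(unique(unlist(lapply(ind, `[[`, "chrom"))))
  rows <- lapply(chroms, function(ch) {
    v <- unlist(lapply(ind, function(i) i$monosomic[i$chrom == ch]))
    data.frame(chrom = ch, n_monosomic = sum(v, na.rm = TRUE),
               n_called = sum(!is.na(v)),
               frequency = sum(v, na.rm = TRUE) / max(sum(!is.na(v)), 1L))
  })
  do.call(rbind, rows)
}
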