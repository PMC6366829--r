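# Synthetic cohort generator: ground-truth karyotypes under three
# whole-chromosome loss mechanisms, plus tumor/normal SNP allele counts
# and spiked somatic mutations with known multiplicity and CCF.

MECHANISMS <- c("haploid_duplication", "hyperdiploid_loss", "direct_loss")

#' Generate a germline heterozygous SNP panel
#'
#' Builds a panel of germline-heterozygous SNPs across all 22 autosomes,
#' the raw coordinate system on which allele counts are simulated. All
#' SNPs are heterozygous by construction (the matched normal is expected
#' to show B-allele frequency 0.5 at every site).
#'
#' @param n_snps_per_chrom Number of SNPs per autosome (>= 0).
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A `data.frame` of class `snp_panel` with columns `chrom`
#'   (integer 1-22), `pos` (1-based, strictly increasing within a
#'   chromosome), `ref` and `alt` (distinct nucleotides).
#' @examples
#' panel <- make_germline_panel(50, seed = 1)
#' nrow(panel)  # 1100
#' @export
make_germline_panel <- function(n_snps_per_chrom, seed) {
  if (!is.numeric(n_snps_per_chrom) || length(n_snps_per_chrom) != 1L ||
      is.na(n_snps_per_chrom) || n_snps_per_chrom < 0) {
    stop("`n_snps_per_chrom` must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n_snps_per_chrom)
  nts <- c("A", "C", "G", "T")
  panel <- with_seed(seed, {
    rows <- lapply(AUTOSOMES, function(chrom) {
      if (n == 0L) {
        return(data.frame(chrom = integer(), pos = integer(),
                          ref = character(), alt = character()))
      }
      pos <- sort(sample.int(100000000L, n))
      ref <- sample(nts, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), "")
      data.frame(chrom = rep(chrom, n), pos = pos, ref = ref, alt = alt)
    })
    do.call(rbind, rows)
  })
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

new_karyotype <- function(states, mechanism, event_log) {
  structure(list(states = states, mechanism = mechanism,
                 event_log = event_log),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cn <- x$states$n_m + x$states$n_p
  cat("<karyotype> mechanism:", x$mechanism,
      "| total autosomal CN:", sum(cn),
      "| monosomies:", sum(cn == 1L),
      "| events:", length(x$event_log), "\n")
  invisible(x)
}

#' Evolve a karyotype under one of three hyperhaploidy mechanisms
#'
#' Starting from a fully heterodisomic diploid state (one maternal and one
#' paternal copy of each autosome), applies one of three whole-chromosome
#' mechanisms that can generate a hyperhaploid karyotype:
#'
#' * `haploid_duplication`: the genome is reduced to a single random
#'   homolog of each chromosome, then the retained set duplicates that
#'   homolog -- every chromosome ends with LOH.
#' * `hyperdiploid_loss`: the retained set first gains a duplicate of one
#'   random homolog (a hyperdiploid intermediate), then every chromosome
#'   loses one uniformly random copy -- retained chromosomes end disomic
#'   with LOH with probability 1/3.
#' * `direct_loss`: non-retained chromosomes each lose one random homolog
#'   directly from the diploid state -- all disomic chromosomes retain
#'   heterodisomy.
#' * `none`: no events; a diploid control.
#'
#' @param mechanism One of `"haploid_duplication"`, `"hyperdiploid_loss"`,
#'   `"direct_loss"`, `"none"`.
#' @param retained_set Autosomes kept disomic (default the odd-numbered
#'   hyperdiploidy set plus chromosome 18).
#' @param seed Integer seed for the random homolog choices.
#' @return A `karyotype`: per-autosome maternal/paternal copy counts
#'   (`$states`), the mechanism label, and an `$event_log` whose replay
#'   from diploid reproduces the copy states exactly
#'   (see [replay_event_log()]).
#' @examples
#' k <- evolve_karyotype("direct_loss", seed = 1)
#' sum(k$states$n_m + k$states$n_p == 1)  # 13 monosomies
#' @export
evolve_karyotype <- function(mechanism,
                             retained_set = DEFAULT_RETAINED_SET,
                             seed = 1L) {
  if (!is.character(mechanism) || length(mechanism) != 1L ||
      !(mechanism %in% c(MECHANISMS, "none"))) {
    stop("`mechanism` must be one of: ",
         paste(c(MECHANISMS, "none"), collapse = ", "), call. = FALSE)
  }
  retained_set <- sort(unique(normalize_chrom(retained_set)))
  n_m <- rep(1L, 22L)
  n_p <- rep(1L, 22L)
  events <- list()
  apply_event <- function(type, chrom, parent) {
    delta <- if (type == "gain") 1L else -1L
    if (parent == "m") n_m[chrom] <<- n_m[chrom] + delta
    else n_p[chrom] <<- n_p[chrom] + delta
    events[[length(events) + 1L]] <<- list(type = type, chrom = chrom,
                                           parent = parent)
  }
  with_seed(seed, {
    if (mechanism == "direct_loss") {
      for (chrom in setdiff(AUTOSOMES, retained_set)) {
        apply_event("loss", chrom, sample(c("m", "p"), 1L))
      }
    } else if (mechanism == "haploid_duplication") {
      kept <- sample(c("m", "p"), 22L, replace = TRUE)
      for (chrom in AUTOSOMES) {
        apply_event("loss", chrom, if (kept[chrom] == "m") "p" else "m")
      }
      for (chrom in retained_set) {
        apply_event("gain", chrom, kept[chrom])
      }
    } else if (mechanism == "hyperdiploid_loss") {
      for (chrom in retained_set) {
        apply_event("gain", chrom, sample(c("m", "p"), 1L))
      }
      for (chrom in AUTOSOMES) {
        # choose one physical copy uniformly among those present
        parent <- sample(rep(c("m", "p"), c(n_m[chrom], n_p[chrom])), 1L)
        apply_event("loss", chrom, parent)
      }
    }
  })
  new_karyotype(data.frame(chrom = AUTOSOMES, n_m = n_m, n_p = n_p),
                mechanism, events)
}

#' Replay a karyotype event log from a diploid start
#'
#' Applies a `karyotype`'s gain/loss events, in order, to a fully
#' heterodisomic diploid genome. The result must equal the karyotype's
#' stored copy states (a conservation check used by the tests).
#'
#' @param event_log The `$event_log` of a [evolve_karyotype()] result.
#' @return A `data.frame` with columns `chrom`, `n_m`, `n_p`.
#' @export
replay_event_log <- function(event_log) {
  states <- data.frame(chrom = AUTOSOMES, n_m = 1L, n_p = 1L)
  for (ev in event_log) {
    i <- which(states$chrom == ev$chrom)
    col <- if (ev$parent == "m") "n_m" else "n_p"
    delta <- if (ev$type == "gain") 1L else -1L
    states[i, col] <- states[i, col] + delta
    if (states[i, col] < 0L) stop("event log drives a copy count below zero")
  }
  states
}

# Summaries of the true allele-specific state, used throughout the tests.
karyotype_cn <- function(karyotype) {
  with(karyotype$states, setNames(n_m + n_p, chrom))
}
karyotype_loh <- function(karyotype) {
  with(karyotype$states,
       setNames(pmin(n_m, n_p) == 0L & (n_m + n_p) >= 1L, chrom))
}

#' Simulate tumor and normal SNP allele counts for a karyotype
#'
#' Emulates exome-style read counts at germline-heterozygous SNPs. Per
#' chromosome, the alternate (B) allele is assigned to one parental
#' homolog at random. Normal depth is Poisson at `mean_depth` with
#' alt-fraction 0.5; tumor depth is Poisson at `mean_depth` scaled by
#' `((1 - purity) * 2 + purity * CN_t) / 2`, with alt counts binomial at
#' [expected_baf()] for the B-homolog's copy number.
#'
#' @param karyotype A [evolve_karyotype()] result.
#' @param panel A [make_germline_panel()] SNP panel.
#' @param purity Tumor purity in (0, 1].
#' @param mean_depth Expected reads per SNP (> 0).
#' @param seed Integer seed.
#' @return A `data.frame` of class `read_count_table` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `normal_ref`, `normal_alt`, `tumor_ref`,
#'   `tumor_alt`, plus an attribute `b_allele_parent` (named "m"/"p" per
#'   chromosome) recording the simulation truth.
#' @export
simulate_allele_counts <- function(karyotype, panel, purity = 0.9,
                                   mean_depth = 100, seed = 1L) {
  check_fraction(purity, "purity", lower = 0, upper = 1, lower_open = TRUE)
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop("`mean_depth` must be positive", call. = FALSE)
  }
  empty <- data.frame(chrom = integer(), pos = integer(),
                      ref = character(), alt = character(),
                      normal_ref = integer(), normal_alt = integer(),
                      tumor_ref = integer(), tumor_alt = integer())
  if (nrow(panel) == 0L) {
    class(empty) <- c("read_count_table", "data.frame")
    return(empty)
  }
  st <- karyotype$states
  out <- with_seed(seed, {
    b_parent <- setNames(sample(c("m", "p"), 22L, replace = TRUE), AUTOSOMES)
    idx <- match(panel$chrom, st$chrom)
    cn_t <- st$n_m[idx] + st$n_p[idx]
    n_b <- ifelse(b_parent[as.character(panel$chrom)] == "m",
                  st$n_m[idx], st$n_p[idx])
    normal_depth <- rpois(nrow(panel), mean_depth)
    normal_alt <- rbinom(nrow(panel), normal_depth, 0.5)
    tumor_scale <- ((1 - purity) * 2 + purity * cn_t) / 2
    tumor_depth <- rpois(nrow(panel), mean_depth * tumor_scale)
    p_alt <- vapply(seq_along(cn_t), function(i) {
      if (tumor_depth[i] == 0L) return(0)
      expected_baf(n_b[i], cn_t[i], purity)
    }, numeric(1))
    tumor_alt <- rbinom(nrow(panel), tumor_depth, p_alt)
    counts <- data.frame(chrom = panel$chrom, pos = panel$pos,
                         ref = panel$ref, alt = panel$alt,
                         normal_ref = normal_depth - normal_alt,
                         normal_alt = normal_alt,
                         tumor_ref = tumor_depth - tumor_alt,
                         tumor_alt = tumor_alt)
    attr(counts, "b_allele_parent") <- b_parent
    counts
  })
  class(out) <- c("read_count_table", "data.frame")
  out
}

#' Build a fully simulated tumor/normal sample
#'
#' Convenience constructor bundling a karyotype, its simulated allele
#' counts and an (initially empty) somatic mutation table.
#'
#' @inheritParams simulate_allele_counts
#' @param panel A SNP panel; defaults to 50 SNPs per autosome.
#' @return A list of class `simulated_sample` with elements `karyotype`,
#'   `purity`, `mean_depth`, `counts`, `somatic_mutations`.
#' @export
simulate_sample <- function(karyotype, panel = make_germline_panel(50, seed),
                            purity = 0.9, mean_depth = 100, seed = 1L) {
  counts <- simulate_allele_counts(karyotype, panel, purity, mean_depth,
                                   seed = seed)
  structure(list(karyotype = karyotype, purity = purity,
                 mean_depth = mean_depth, counts = counts,
                 somatic_mutations = empty_mutation_table()),
            class = "simulated_sample")
}

empty_mutation_table <- function() {
  data.frame(gene = character(), chrom = integer(), pos = integer(),
             ref = character(), alt = character(),
             tumor_ref = integer(), tumor_alt = integer(),
             vaf = numeric(), true_m = integer(), true_ccf = numeric())
}

#' Spike a somatic mutation into a simulated sample
#'
#' Adds a somatic point mutation with chosen multiplicity `m` (mutated
#' copies per tumor cell) and cancer cell fraction `ccf`. Observed alt
#' counts are binomial around the expected variant allele frequency
#' `ccf * purity * m / (purity * CN_t + (1 - purity) * 2)` at the locus,
#' at Poisson depth matching the chromosome's tumor copy state. Ground
#' truth `m` and `ccf` are recorded for recovery tests.
#'
#' @param sample A [simulate_sample()] result.
#' @param gene Gene symbol (e.g. `"TP53"`).
#' @param chrom,pos Locus of the mutation (autosome, 1-based position).
#' @param m Multiplicity, a positive integer `<=` the chromosome's tumor
#'   copy number.
#' @param ccf Cancer cell fraction in (0, 1].
#' @param seed Integer seed.
#' @return The sample with one row appended to `$somatic_mutations`.
#' @export
spike_somatic_mutation <- function(sample, gene, chrom, pos, m = 1L,
                                   ccf = 1, seed = 1L) {
  chrom <- normalize_chrom(chrom)
  check_fraction(ccf, "ccf", lower = 0, upper = 1, lower_open = TRUE)
  st <- sample$karyotype$states
  cn_t <- st$n_m[st$chrom == chrom] + st$n_p[st$chrom == chrom]
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != as.integer(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (m > cn_t) {
    stop("multiplicity m = ", m, " exceeds tumor copy number CN_t = ", cn_t,
         " on chromosome ", chrom, call. = FALSE)
  }
  purity <- sample$purity
  exp_vaf <- ccf * purity * m / (purity * cn_t + (1 - purity) * 2)
  row <- with_seed(seed, {
    depth_scale <- ((1 - purity) * 2 + purity * cn_t) / 2
    depth <- rpois(1L, sample$mean_depth * depth_scale)
    alt <- rbinom(1L, depth, exp_vaf)
    data.frame(gene = gene, chrom = chrom, pos = as.integer(pos),
               ref = "C", alt = "T",
               tumor_ref = depth - alt, tumor_alt = alt,
               vaf = if (depth > 0) alt / depth else NA_real_,
               true_m = as.integer(m), true_ccf = ccf)
  })
  sample$somatic_mutations <- rbind(sample$somatic_mutations, row)
  sample
}

#' Derive a serial sample pair differing by additional chromosome losses
#'
#' Models a later sample from the same patient in which listed chromosomes
#' have each lost one random homolog (gradual loss over time). Allele
#' counts for the second timepoint are regenerated from its karyotype.
#'
#' @param sample A [simulate_sample()] result; every chromosome in
#'   `chroms_to_lose` must be disomic in it.
#' @param chroms_to_lose Autosomes to drop to monosomy (may be empty).
#' @param seed Integer seed.
#' @return A list `list(t1 = , t2 = )` of two `simulated_sample`s.
#' @export
derive_serial_pair <- function(sample, chroms_to_lose, seed = 1L) {
  chroms_to_lose <- if (length(chroms_to_lose) == 0L) integer() else
    normalize_chrom(chroms_to_lose)
  k2 <- sample$karyotype
  st <- k2$states
  for (chrom in chroms_to_lose) {
    i <- which(st$chrom == chrom)
    if (st$n_m[i] + st$n_p[i] != 2L) {
      stop("chromosome ", chrom, " is not disomic and cannot be lost",
           call. = FALSE)
    }
  }
  k2 <- with_seed(seed, {
    for (chrom in chroms_to_lose) {
      i <- which(st$chrom == chrom)
      present <- rep(c("m", "p"), c(st$n_m[i], st$n_p[i]))
      parent <- sample(present, 1L)
      col <- if (parent == "m") "n_m" else "n_p"
      st[i, col] <- st[i, col] - 1L
      k2$event_log[[length(k2$event_log) + 1L]] <-
        list(type = "loss", chrom = chrom, parent = parent)
    }
    k2$states <- st
    k2
  })
  panel <- sample$counts[, c("chrom", "pos", "ref", "alt")]
  class(panel) <- c("snp_panel", "data.frame")
  t2 <- simulate_sample(k2, panel, purity = sample$purity,
                        mean_depth = sample$mean_depth,
                        seed = seed + 1000L)
  t2$somatic_mutations <- sample$somatic_mutations
  list(t1 = sample, t2 = t2)
}
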