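# Discriminating the three hyperhaploidy-generating mechanisms from the
# LOH pattern on disomic chromosomes. Each mechanism predicts a distinct
# disomic-LOH fraction (1, 1/3, 0); observed counts are scored with a
# binomial likelihood under a small per-chromosome call-error rate.

#' Predicted fraction of disomic chromosomes with LOH per mechanism
#'
#' Haploidization followed by duplication leaves LOH on every chromosome;
#' a hyperdiploid intermediate that loses a haploid set leaves LOH on one
#' third of disomic chromosomes (the duplicated homolog survives the
#' random loss with probability 2/3); direct sequential loss from a
#' diploid state preserves heterodisomy on every disomic chromosome.
#'
#' @param mechanism One of `"haploid_duplication"`, `"hyperdiploid_loss"`,
#'   `"direct_loss"`.
#' @return 1, 1/3 (exact) or 0.
#' @export
expected_loh_fraction <- function(mechanism) {
  switch(mechanism,
         haploid_duplication = 1,
         hyperdiploid_loss = 1 / 3,
         direct_loss = 0,
         stop("unknown mechanism: ", mechanism, call. = FALSE))
}

#' Binomial log-likelihood of a disomic-LOH count under a mechanism
#'
#' Observing `k_loh` LOH chromosomes among `n_disomic` disomic
#' chromosomes is scored as binomial with success probability
#' `p' = p (1 - epsilon) + (1 - p) epsilon`, where `p` is the mechanism's
#' predicted LOH fraction and `epsilon` a per-chromosome call-error rate
#' that keeps the likelihood finite at the deterministic predictions 0
#' and 1.
#'
#' @param k_loh Disomic chromosomes called LOH (0 <= `k_loh` <=
#'   `n_disomic`).
#' @param n_disomic Number of disomic chromosomes.
#' @param mechanism See [expected_loh_fraction()].
#' @param epsilon Call-error rate in (0, 0.5).
#' @return The binomial log-likelihood.
#' @export
mechanism_loglik <- function(k_loh, n_disomic, mechanism, epsilon = 0.01) {
  if (k_loh < 0 || k_loh > n_disomic) {
    stop("`k_loh` must lie in [0, n_disomic]", call. = FALSE)
  }
  check_fraction(epsilon, "epsilon", lower = 0, upper = 0.5,
                 lower_open = TRUE, upper_open = TRUE)
  p <- expected_loh_fraction(mechanism)
  p_err <- p * (1 - epsilon) + (1 - p) * epsilon
  dbinom(k_loh, n_disomic, p_err, log = TRUE)
}

#' Classify the hyperhaploidy-generating mechanism by maximum likelihood
#'
#' Evaluates all three mechanisms' binomial log-likelihoods for the
#' observed disomic-LOH count and reports the maximum-likelihood winner.
#' Ties and the empty case `n_disomic = 0` give `"undetermined"`.
#'
#' @inheritParams mechanism_loglik
#' @return A list of class `mechanism_posterior`: `$loglik` (named per
#'   mechanism), `$winner`, `$lr` (likelihood ratios of the winner over
#'   each alternative), `$k_loh`, `$n_disomic`, `$epsilon`, `$note`.
#' @examples
#' classify_mechanism(0, 9)$winner  # "direct_loss"
#' classify_mechanism(3, 9)$winner  # "hyperdiploid_loss"
#' @export
classify_mechanism <- function(k_loh, n_disomic, epsilon = 0.01) {
  if (n_disomic == 0L) {
    return(structure(list(loglik = setNames(rep(NA_real_, 3), MECHANISMS),
                          winner = "undetermined", lr = NULL,
                          k_loh = k_loh, n_disomic = n_disomic,
                          epsilon = epsilon,
                          note = "no disomic chromosomes to score"),
                     class = "mechanism_posterior"))
  }
  ll <- vapply(MECHANISMS, mechanism_loglik, numeric(1),
               k_loh = k_loh, n_disomic = n_disomic, epsilon = epsilon)
  best <- max(ll)
  top <- names(ll)[abs(ll - best) < 1e-12]
  winner <- if (length(top) == 1L) top else "undetermined"
  structure(list(loglik = ll, winner = winner,
                 lr = exp(best - ll),
                 k_loh = as.integer(k_loh), n_disomic = as.integer(n_disomic),
                 epsilon = epsilon, note = NULL),
            class = "mechanism_posterior")
}

#' @export
print.mechanism_posterior <- function(x, ...) {
  cat("<mechanism_posterior> winner:", x$winner,
      sprintf("(k = %d LOH of n = %d disomic, epsilon = %g)\n",
              x$k_loh, x$n_disomic, x$epsilon))
  if (!all(is.na(x$loglik))) {
    print(round(x$loglik, 4))
  } else if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Classify the mechanism from a sample's chromosome calls
#'
#' Extracts the disomic-LOH count with [heterodisomy_summary()] and
#' scores it with [classify_mechanism()]. Chromosomes with no-call LOH
#' status are excluded from the disomic denominator; a warning is raised
#' when more than two are dropped.
#'
#' @param solution A `ploidy_solution` or call table.
#' @param epsilon Call-error rate.
#' @return A `mechanism_posterior`.
#' @export
classify_mechanism_from_calls <- function(solution, epsilon = 0.01) {
  calls <- as_call_table(solution)
  dropped <- sum(!calls$no_call & calls$cn == 2L & is.na(calls$loh))
  if (dropped > 2L) {
    warning(dropped, " disomic chromosomes had no LOH call and were ",
            "excluded from mechanism inference", call. = FALSE)
  }
  het <- heterodisomy_summary(calls)
  classify_mechanism(het$k_loh, het$n_disomic, epsilon = epsilon)
}

#' Monte-Carlo oracle for the mechanisms' disomic-LOH fractions
#'
#' Repeatedly evolves karyotypes under a mechanism, pools all disomic
#' chromosomes, and returns the fraction carrying LOH with its binomial
#' standard error -- an independent simulation check of the closed-form
#' predictions in [expected_loh_fraction()].
#'
#' @param mechanism See [expected_loh_fraction()].
#' @param reps Number of simulated karyotypes (>= 1).
#' @param seed Integer seed.
#' @param retained_set Passed to [evolve_karyotype()].
#' @return A list: `fraction`, `se`, `n_disomic` (pooled), `reps`.
#' @export
monte_carlo_oracle <- function(mechanism, reps = 10000L, seed = 1L,
                               retained_set = DEFAULT_RETAINED_SET) {
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  k_loh <- 0L
  n_disomic <- 0L
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, reps)
    for (r in seq_len(reps)) {
      k <- evolve_karyotype(mechanism, retained_set = retained_set,
                            seed = sub_seeds[r])
      cn <- karyotype_cn(k)
      loh <- karyotype_loh(k)
      disomic <- cn == 2L
      n_disomic <- n_disomic + sum(disomic)
      k_loh <- k_loh + sum(loh[disomic])
    }
  })
  p <- k_loh / n_disomic
  list(fraction = p, se = sqrt(p * (1 - p) / n_disomic),
       n_disomic = n_disomic, reps = as.integer(reps))
}
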