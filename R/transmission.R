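# Mendelian transmission of hemizygous transgene loci.
#
# A transposon founder carries k unlinked hemizygous insertion loci; crossed
# to wild type, each locus transmits independently with probability 1/2, so
# the expected transgene-positive fraction of a litter is 1 - (1/2)^k.
# Repeated backcrossing with selection reduces k until the litter ratio
# settles at 50%, the signature of a single remaining locus.

#' Expected transgene-positive offspring fraction
#'
#' For a hemizygous carrier of `k` unlinked loci crossed to wild type, an
#' offspring is positive when it inherits at least one locus:
#' `1 - (1/2)^k`. At `k = 1` this is the familiar 50% litter ratio.
#'
#' @param k non-negative integer locus count (vectorised).
#' @return probability of a transgene-positive offspring.
#' @examples
#' expected_positive_fraction(0:3)
#' @export
expected_positive_fraction <- function(k) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  1 - 0.5^k
}

#' Simulate offspring locus sets of a hemizygous carrier x wild-type cross
#'
#' Each of the sire's `k` loci transmits independently with probability 1/2;
#' the dam contributes none.
#'
#' @param k sire locus count (>= 0).
#' @param n number of offspring (>= 1).
#' @param seed optional integer seed.
#' @return list of integer vectors, one per offspring, each the set of
#'   inherited locus indices (possibly empty).
#' @export
simulate_offspring <- function(k, n, seed = NULL) {
  stopifnot(k >= 0, k == floor(k), n >= 1)
  with_seed_or_not(seed, {
    if (k == 0) return(rep(list(integer(0)), n))
    tx <- matrix(runif(n * k) < 0.5, nrow = n)
    lapply(seq_len(n), function(i) which(tx[i, ]))
  })
}

#' Fraction of carriers among simulated offspring
#' @param offspring output of [simulate_offspring()].
#' @return fraction of offspring carrying at least one locus.
#' @export
carrier_fraction <- function(offspring) {
  mean(lengths(offspring) > 0)
}

#' Exact binomial segregation test
#'
#' Tests an observed litter against a null positive fraction (e.g. the 50%
#' single-locus expectation) with an exact binomial test, two-sided by
#' summing the probabilities of all outcomes no more likely than the
#' observation.
#'
#' @param n_positive number of transgene-positive offspring.
#' @param n_offspring litter size (> 0).
#' @param null_fraction null positive fraction in (0, 1); default 0.5.
#' @return list `p_value, estimate, n_positive, n_offspring, null_fraction`.
#' @examples
#' segregation_test(5, 10)$p_value    # the mode: p = 1
#' segregation_test(0, 10)$p_value    # 2/1024
#' @export
segregation_test <- function(n_positive, n_offspring, null_fraction = 0.5) {
  stopifnot(n_offspring > 0, n_positive >= 0, n_positive <= n_offspring,
            null_fraction > 0, null_fraction < 1)
  bt <- binom.test(n_positive, n_offspring, p = null_fraction,
                   alternative = "two.sided")
  list(p_value = bt$p.value, estimate = n_positive / n_offspring,
       n_positive = n_positive, n_offspring = n_offspring,
       null_fraction = null_fraction)
}

#' Maximum-likelihood locus count from an observed litter
#'
#' Profiles the binomial likelihood of the observed positive count over
#' locus counts `k = 1..k_max` with success probability `1 - (1/2)^k`.
#' Because the expected fraction saturates towards 1, the likelihood is
#' nearly flat for large `k`; a maximum at `k_max` is flagged as saturated.
#' With zero positives there is no carrier evidence and the estimate is
#' undefined.
#'
#' @param n_positive,n_offspring observed litter.
#' @param k_max largest locus count profiled (default 10).
#' @return list `k_hat` (NA when undefined), `log_lik` (named vector over
#'   k), `saturated` (logical).
#' @examples
#' infer_locus_count(25, 50)$k_hat   # 1
#' infer_locus_count(37, 50)$k_hat   # 2
#' @export
infer_locus_count <- function(n_positive, n_offspring, k_max = 10L) {
  stopifnot(n_offspring >= 1, n_positive >= 0, n_positive <= n_offspring,
            k_max >= 1)
  ks <- seq_len(k_max)
  ll <- dbinom(n_positive, n_offspring, expected_positive_fraction(ks),
               log = TRUE)
  names(ll) <- ks
  if (n_positive == 0)
    return(list(k_hat = NA_integer_, log_lik = ll, saturated = FALSE))
  k_hat <- ks[which.max(ll)]
  list(k_hat = k_hat, log_lik = ll, saturated = k_hat == k_max)
}

#' Breeding-scheme configuration
#'
#' @param founder_locus_count k0, insertion loci in the founder sire (>= 1).
#' @param generations number of backcross generations to simulate.
#' @param litter_size offspring per cross.
#' @param selection_policy `"random_carrier"` (uniform among carriers) or
#'   `"max_locus_carrier"` (most loci, ties random) -- the latter models
#'   selecting the strongest-expressing pup under an
#'   expression-proportional-to-copy-number assumption.
#' @param seed optional integer seed.
#' @return A `pedigree_config` list.
#' @export
pedigree_config <- function(founder_locus_count = 4L, generations = 6L,
                            litter_size = 10L,
                            selection_policy = c("random_carrier",
                                                 "max_locus_carrier"),
                            seed = NULL) {
  selection_policy <- match.arg(selection_policy)
  stopifnot(founder_locus_count >= 1, generations >= 1, litter_size >= 1)
  structure(list(founder_locus_count = as.integer(founder_locus_count),
                 generations = as.integer(generations),
                 litter_size = as.integer(litter_size),
                 selection_policy = selection_policy, seed = seed),
            class = "pedigree_config")
}

#' Simulate a multi-generation backcross breeding trajectory
#'
#' Each generation, the selected sire (starting from the founder) is crossed
#' to wild type; every locus transmits independently with probability 1/2;
#' the next sire is chosen among the litter's carriers by the selection
#' policy. A litter with no carriers terminates the trajectory early.
#'
#' @param config a [pedigree_config()].
#' @return list with `trajectory` (data.frame `generation,
#'   sire_locus_count, litter_carrier_fraction`; generation 0 is the
#'   founder) and `terminated_early` (logical).
#' @export
simulate_breeding <- function(config) {
  stopifnot(inherits(config, "pedigree_config"))
  with_seed_or_not(config$seed, {
    k <- config$founder_locus_count
    rows <- list(data.frame(generation = 0L, sire_locus_count = k,
                            litter_carrier_fraction = NA_real_))
    terminated <- FALSE
    for (g in seq_len(config$generations)) {
      litter <- simulate_offspring(k, config$litter_size)
      counts <- lengths(litter)
      frac <- mean(counts > 0)
      carriers <- which(counts > 0)
      if (!length(carriers)) {
        rows[[length(rows) + 1L]] <- data.frame(
          generation = g, sire_locus_count = NA_integer_,
          litter_carrier_fraction = frac)
        terminated <- TRUE
        break
      }
      pick <- switch(config$selection_policy,
        random_carrier = carriers[sample.int(length(carriers), 1L)],
        max_locus_carrier = {
          top <- carriers[counts[carriers] == max(counts[carriers])]
          top[sample.int(length(top), 1L)]
        })
      k <- counts[pick]
      rows[[length(rows) + 1L]] <- data.frame(
        generation = g, sire_locus_count = k,
        litter_carrier_fraction = frac)
    }
    list(trajectory = do.call(rbind, rows), terminated_early = terminated)
  })
}
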