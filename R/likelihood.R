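#' Recombination and mutation rate parameters
#'
#' Bundles the per-interval recombination rates \eqn{\theta} (length n-1)
#' and per-marker mutation rates \eqn{\mu} (length n). Estimation constrains
#' both to (0, 0.5]; the likelihood itself also accepts the boundary value 0
#' (useful for exact no-mutation tests).
#'
#' @param theta numeric vector of n-1 recombination rates in [0, 0.5].
#' @param mu numeric vector of n mutation rates in [0, 0.5].
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(theta, mu) {
  theta <- as.numeric(theta); mu <- as.numeric(mu)
  if (any(theta < 0) || any(theta > 0.5) || any(mu < 0) || any(mu > 0.5)) {
    stop("rates must lie in [0, 0.5]")
  }
  structure(list(theta = theta, mu = mu), class = "rate_params")
}

check_params <- function(params, n) {
  if (!inherits(params, "rate_params")) stop("params must be rate_params")
  if (length(params$theta) != max(n - 1L, 0L) || length(params$mu) != n) {
    stop("rate vector lengths do not match the panel (need n-1 theta, n mu)")
  }
  params
}

# --- mutation kernels (public, on natural allele representations) ---------

#' Stepwise STR mutation kernel
#'
#' Single-step mutation probability between STR alleles: `1 - mu` when the
#' repeat counts match, `mu` for a change of exactly one repeat unit, and 0
#' otherwise (multi-repeat and partial-repeat changes are far rarer than
#' single steps and are excluded by the model). Fractional repeat counts with
#' one decimal digit are compared exactly, so `|9.3 - 10.3|` is one step.
#'
#' @param a,b STR alleles (positive rationals, repeat counts). Vectorized.
#' @param mu per-meiosis mutation rate.
#' @return Numeric vector of probabilities.
#' @export
mut_prob_str <- function(a, b, mu) {
  d <- abs(round(10 * a) - round(10 * b))
  ifelse(d == 0, 1 - mu, ifelse(d == 10, mu, 0))
}

#' Transition/transversion mutation kernel for non-STR markers
#'
#' Mutation probability between non-STR alleles given as strings: `1 - mu`
#' on a match; transitions (single-base A<->G or C<->T) are weighted 9/10 of
#' `mu`, all other changes (transversions, indels, complex alleles) 1/10,
#' reflecting the strong excess of transitions among single-base
#' substitutions.
#'
#' @param a,b allele strings (e.g. `"A"`, `"G"`, or longer indel alleles).
#'   Vectorized.
#' @param mu per-meiosis mutation rate.
#' @return Numeric vector of probabilities.
#' @export
mut_prob_poly <- function(a, b, mu) {
  same <- as.character(a) == as.character(b)
  trans <- is_transition_class(base_class(a), base_class(b))
  ifelse(same, 1 - mu, ifelse(trans, 0.9 * mu, 0.1 * mu))
}

# Scalar kernel on internal numeric codes (STR decimal repeat counts, POLY
# negative integers), mirroring the C++ `pstar`. Missing -> factor 1.
pstar_code <- function(m, c, mu, type, bc) {
  if (is.na(m) || is.na(c)) return(1)
  if (type == "STR") {
    d <- abs(round(10 * m) - round(10 * c))
    if (d == 0) 1 - mu else if (d == 10) mu else 0
  } else {
    if (m == c) {
      1 - mu
    } else if (is_transition_class(bc[-m], bc[-c])) {
      0.9 * mu
    } else {
      0.1 * mu
    }
  }
}

# --- direct (enumeration) engine ------------------------------------------

.direct_cap <- 20L

# Sum over all 2^n inheritance vectors, vectorized over the enumeration.
# Reference implementation: O(n 2^n) time, practical only for small panels;
# serves as the oracle for the dynamic engine.
child_lik_direct_codes <- function(child, m1, m2, theta, mu, panel) {
  n <- length(child)
  if (n > .direct_cap) {
    stop("direct engine refused for n = ", n, " markers (cap ", .direct_cap,
         "); use the dynamic engine")
  }
  P <- matrix(0, 2L, n)
  for (i in seq_len(n)) {
    P[1L, i] <- pstar_code(m1[i], child[i], mu[i], panel$types[i],
                           panel$bclass[[i]])
    P[2L, i] <- pstar_code(m2[i], child[i], mu[i], panel$types[i],
                           panel$bclass[[i]])
  }
  V <- as.matrix(expand.grid(rep(list(1:2), n)))
  acc <- rep(1, nrow(V))
  for (i in seq_len(n)) acc <- acc * P[, i][V[, i]]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      acc <- acc * ifelse(V[, i] == V[, i + 1L], 1 - theta[i], theta[i])
    }
  }
  sum(acc)
}

#' Child likelihood by direct enumeration of inheritance vectors
#'
#' Computes the probability of observing a child's maternal haplotype from a
#' phased mother by summing, over all `2^n` inheritance vectors `v` in
#' `{1,2}^n`, the product of recombination factors
#' `theta_i + (1 - 2 theta_i) * delta(v_i, v_{i+1})` between adjacent markers
#' and mutation-kernel factors `p*(m_i^{v_i}, c_i)` at each marker. Markers
#' missing in the child contribute mutation factor 1. Exponential in `n`;
#' refused above 20 markers. Kept as the readable reference implementation
#' against which the dynamic engine is validated.
#'
#' @param child numeric vector of the child's maternal allele codes.
#' @param mother a [phased_mother()].
#' @param params a [rate_params()].
#' @param panel the [marker_panel()].
#' @param log return the log-likelihood instead of the likelihood.
#' @return The (log-)likelihood, a scalar.
#' @export
child_likelihood_direct <- function(child, mother, params, panel,
                                    log = FALSE) {
  n <- panel$n_markers
  if (length(child) != n || length(mother$hap1) != n) {
    stop("length mismatch between child, mother and panel")
  }
  check_params(params, n)
  l <- child_lik_direct_codes(child, mother$hap1, mother$hap2,
                              params$theta, params$mu, panel)
  if (log) base::log(l) else l
}

#' Child likelihood by the forward (dynamic-programming) recursion
#'
#' Same value as [child_likelihood_direct()], computed in O(n) by the
#' forward recurrence `f_1(s) = p*_1(m_1^s, c_1)`,
#' `f_{i+1}(s') = p*_{i+1}(m_{i+1}^{s'}, c_{i+1}) *
#'  sum_s f_i(s) (theta_i if s != s' else 1 - theta_i)`, result
#' `sum_s f_n(s)`. The pass rescales at every marker and accumulates log
#' scale factors, so panels of 10,000 markers neither underflow nor overflow
#' (request `log = TRUE` at that scale; the linear-scale value itself is
#' below double precision).
#'
#' @inheritParams child_likelihood_direct
#' @return The (log-)likelihood, a scalar.
#' @export
child_likelihood_dynamic <- function(child, mother, params, panel,
                                     log = FALSE) {
  n <- panel$n_markers
  if (length(child) != n || length(mother$hap1) != n) {
    stop("length mismatch between child, mother and panel")
  }
  check_params(params, n)
  pl <- panel_ll(panel)
  ll <- cpp_child_loglik(encode_internal(child, panel),
                         encode_internal(mother$hap1, panel),
                         encode_internal(mother$hap2, panel),
                         params$theta, params$mu, pl$type, pl$bclass)
  if (log) ll else exp(ll)
}

child_matrix <- function(fam) {
  do.call(rbind, lapply(fam$children, encode_internal, panel = fam$panel))
}

#' Likelihood of a type I family
#'
#' Children are independent recombination events given the phased mother, so
#' the family likelihood is the product of the per-child likelihoods.
#'
#' @param fam an [informative_family()] of kind `"typeI"`.
#' @param params a [rate_params()].
#' @param engine `"dynamic"` (forward recursion, default) or `"direct"`
#'   (enumeration; small panels only).
#' @param log return the log-likelihood.
#' @return The (log-)likelihood, a scalar.
#' @export
family_likelihood_typeI <- function(fam, params, engine = c("dynamic", "direct"),
                                    log = FALSE) {
  engine <- match.arg(engine)
  if (fam$kind != "typeI") stop("family is not type I")
  if (length(fam$children) == 0L) stop("type I family with no children")
  check_params(params, fam$panel$n_markers)
  if (engine == "dynamic") {
    pl <- panel_ll(fam$panel)
    ll <- cpp_typeI_loglik(child_matrix(fam),
                           encode_internal(fam$mother$hap1, fam$panel),
                           encode_internal(fam$mother$hap2, fam$panel),
                           params$theta, params$mu, pl$type, pl$bclass)
  } else {
    ll <- sum(vapply(fam$children, function(c) {
      base::log(child_lik_direct_codes(c, fam$mother$hap1, fam$mother$hap2,
                                       params$theta, params$mu, fam$panel))
    }, 0))
  }
  if (log) ll else exp(ll)
}

# Enumerate the 2^(h-1) anchored (unordered) phasings of an unphased mother:
# the first heterozygous marker keeps its stored order, every later
# heterozygous marker is free. Returns a list of (hap1, hap2) pairs.
enumerate_phasings <- function(mother) {
  g <- mother$genotype
  het <- which(mother$het_mask)
  free <- het[-1]
  n <- ncol(g)
  base1 <- g[1L, ]; base2 <- g[2L, ]
  if (length(free) == 0L) return(list(list(base1, base2)))
  out <- vector("list", 2^length(free))
  for (b in seq_len(2^length(free)) - 1L) {
    h1 <- base1; h2 <- base2
    bits <- bitwAnd(bitwShiftR(b, seq_along(free) - 1L), 1L)
    sw <- free[bits == 1L]
    h1[sw] <- base2[sw]; h2[sw] <- base1[sw]
    out[[b + 1L]] <- list(h1, h2)
  }
  out
}

#' Likelihood of a type II family
#'
#' The mother's phase is unknown, so the likelihood sums the type I
#' likelihood over all `2^(h-1)` distinct maternal phasings compatible with
#' her genotype (`h` = heterozygous markers; the phase is anchored at the
#' first heterozygous marker since relabeling the two haplotypes leaves every
#' child likelihood unchanged). The dynamic engine branches depth-first
#' through the heterozygous markers, sharing partial forward states between
#' phasings and pruning branches whose partial likelihood is already zero for
#' some child; the result is identical to exhaustive enumeration. Cost is
#' exponential in `h`, hence the marker cap.
#'
#' @inheritParams family_likelihood_typeI
#' @param fam an [informative_family()] of kind `"typeII"`.
#' @param marker_cap refuse panels larger than this (default 25): the
#'   phasing sum doubles per additional heterozygous marker.
#' @return The (log-)likelihood, a scalar.
#' @export
family_likelihood_typeII <- function(fam, params,
                                     engine = c("dynamic", "direct"),
                                     log = FALSE, marker_cap = 25L) {
  engine <- match.arg(engine)
  if (fam$kind != "typeII") stop("family is not type II")
  if (length(fam$children) < 2L) stop("type II family needs >= 2 children")
  n <- fam$panel$n_markers
  check_params(params, n)
  if (n > marker_cap) {
    stop("type II likelihood refused for n = ", n, " markers (cap ",
         marker_cap, "): cost doubles per heterozygous marker. ",
         "Raise marker_cap to override.")
  }
  if (engine == "dynamic") {
    pl <- panel_ll(fam$panel)
    g <- fam$mother$genotype
    ll <- cpp_typeII_loglik(child_matrix(fam),
                            encode_internal(g[1L, ], fam$panel),
                            encode_internal(g[2L, ], fam$panel),
                            params$theta, params$mu, pl$type, pl$bclass)
  } else {
    tot <- 0
    for (ph in enumerate_phasings(fam$mother)) {
      lk <- 1
      for (c in fam$children) {
        lk <- lk * child_lik_direct_codes(c, ph[[1]], ph[[2]],
                                          params$theta, params$mu, fam$panel)
        if (lk == 0) break
      }
      tot <- tot + lk
    }
    ll <- base::log(tot)
  }
  if (log) ll else exp(ll)
}

family_loglik <- function(fam, params, engine = "dynamic", marker_cap = 25L) {
  if (fam$kind == "typeI") {
    family_likelihood_typeI(fam, params, engine, log = TRUE)
  } else {
    family_likelihood_typeII(fam, params, engine, log = TRUE,
                             marker_cap = marker_cap)
  }
}

#' Negative log-likelihood of a dataset of informative families
#'
#' Families are independent, so the dataset likelihood is the product of the
#' family likelihoods; this returns the negative sum of their logs — the
#' objective minimized by [estimate_rates()]. A family whose likelihood is
#' exactly zero (data incompatible with the single-step mutation model, e.g.
#' a multi-repeat change) is an error naming the family.
#'
#' @param families list of [informative_family()].
#' @param params a [rate_params()].
#' @param engine `"dynamic"` or `"direct"`.
#' @param marker_cap passed to [family_likelihood_typeII()].
#' @return Non-negative scalar.
#' @export
dataset_negloglik <- function(families, params,
                              engine = c("dynamic", "direct"),
                              marker_cap = 25L) {
  engine <- match.arg(engine)
  if (length(families) == 0L) stop("no families supplied")
  lls <- vapply(families, family_loglik, 0, params = params,
                engine = engine, marker_cap = marker_cap)
  if (any(!is.finite(lls))) {
    bad <- which(!is.finite(lls))
    ids <- vapply(families[bad], function(f) {
      if (is.null(f$provenance)) "<unknown>"
      else paste0(f$provenance$family_id, "/", f$provenance$mother_id)
    }, "")
    stop("zero likelihood for ", length(bad), " family(ies): ",
         paste(ids, collapse = ", "),
         " — data incompatible with the single-step mutation model")
  }
  -sum(lls)
}
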