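#' Maximum-likelihood estimation of recombination and mutation rates
#'
#' Minimizes [dataset_negloglik()] over the recombination vector (length
#' n-1) and, depending on `mu_mode`, the mutation rates, using bounded
#' L-BFGS-B. Rates live in (0, 0.5]; the lower box bound is a small epsilon
#' rather than 0 so the log-likelihood stays finite.
#'
#' Mutation-rate modes: `"per_marker"` (one rate per marker, the default),
#' `"shared"` (a single rate for all markers — useful when per-marker event
#' counts are tiny), `"fixed"` (held at `fix_mu`, not estimated).
#'
#' Non-convergence is reported, never silently accepted: the result carries
#' `converged = FALSE` plus the optimizer message. After fitting, each free
#' parameter is probed for likelihood flatness (e.g. a recombination interval
#' with no informative meioses); flat parameters sit at their initial value
#' and are reported with a warning.
#'
#' @param families list of [informative_family()] sharing one panel.
#' @param engine likelihood engine, `"dynamic"` (default) or `"direct"`.
#' @param mu_mode `"per_marker"`, `"shared"` or `"fixed"`.
#' @param fix_mu mutation rate used when `mu_mode = "fixed"`.
#' @param theta_init,mu_init initial values (scalars, broadcast).
#' @param lower,upper box bounds for all rates.
#' @param maxit iteration cap for L-BFGS-B.
#' @param marker_cap passed to [family_likelihood_typeII()].
#' @param flat_check probe for flat directions after the fit.
#' @return An object of class `xrecomb_fit` with elements `theta_hat`,
#'   `mu_hat` (`NULL` when `mu_mode = "fixed"`), `mu_mode`, `converged`,
#'   `final_negloglik`, `initial_negloglik`, `n_iterations`, `diagnostics`
#'   and `panel`.
#' @export
estimate_rates <- function(families,
                           engine = c("dynamic", "direct"),
                           mu_mode = c("per_marker", "shared", "fixed"),
                           fix_mu = 0,
                           theta_init = 0.1, mu_init = 0.001,
                           lower = 1e-8, upper = 0.5,
                           maxit = 15000L, marker_cap = 25L,
                           flat_check = TRUE) {
  engine <- match.arg(engine)
  mu_mode <- match.arg(mu_mode)
  if (length(families) == 0L) stop("no families to estimate from")
  panel <- families[[1]]$panel
  for (f in families) {
    if (!identical(f$panel$names, panel$names)) {
      stop("families do not share a marker panel")
    }
  }
  n <- panel$n_markers
  if (n < 2L && mu_mode == "fixed") {
    stop("nothing to estimate: one marker and fixed mutation rates")
  }
  if (!(lower > 0 && upper <= 0.5 && lower < upper)) {
    stop("invalid bounds: need 0 < lower < upper <= 0.5")
  }
  n_theta <- n - 1L
  n_mu <- switch(mu_mode, per_marker = n, shared = 1L, fixed = 0L)
  par0 <- c(rep(min(max(theta_init, lower), upper), n_theta),
            rep(min(max(mu_init, lower), upper), n_mu))
  if (mu_mode == "fixed" && (fix_mu < 0 || fix_mu > 0.5)) {
    stop("fix_mu must lie in [0, 0.5]")
  }

  unpack <- function(par) {
    theta <- par[seq_len(n_theta)]
    mu <- switch(mu_mode,
                 per_marker = par[n_theta + seq_len(n)],
                 shared = rep(par[n_theta + 1L], n),
                 fixed = rep(fix_mu, n))
    rate_params(theta, mu)
  }
  nll <- function(par) {
    dataset_negloglik(families, unpack(par), engine = engine,
                      marker_cap = marker_cap)
  }

  nll0 <- nll(par0)  # errors early on all-zero-likelihood datasets
  # finite-difference steps: optim's default ndeps (1e-3) is coarser than
  # the mutation-rate scale and derails the line search when a rate sits
  # near its bound
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit,
                                     ndeps = rep(1e-6, length(par0))))

  flat <- integer(0)
  if (flat_check) {
    eps <- 1e-5
    for (j in seq_along(opt$par)) {
      up <- opt$par; up[j] <- min(up[j] + eps, upper)
      dn <- opt$par; dn[j] <- max(dn[j] - eps, lower)
      if (abs(nll(up) - opt$value) < 1e-11 &&
          abs(nll(dn) - opt$value) < 1e-11) {
        flat <- c(flat, j)
      }
    }
    if (length(flat)) {
      nm <- c(if (n_theta) paste0("theta_", seq_len(n_theta)),
              if (n_mu) paste0("mu_", seq_len(n_mu)))
      warning("likelihood is flat in: ", paste(nm[flat], collapse = ", "),
              " (no informative meioses); estimates sit at initial values")
    }
  }

  est <- unpack(opt$par)
  structure(list(
    theta_hat = est$theta,
    mu_hat = if (mu_mode == "fixed") NULL else est$mu,
    mu_mode = mu_mode,
    fix_mu = if (mu_mode == "fixed") fix_mu else NULL,
    converged = opt$convergence == 0L,
    final_negloglik = opt$value,
    initial_negloglik = nll0,
    n_iterations = unname(opt$counts[1]),
    diagnostics = list(message = opt$message,
                       convergence_code = opt$convergence,
                       flat_params = flat),
    panel = panel
  ), class = "xrecomb_fit")
}

#' @export
print.xrecomb_fit <- function(x, ...) {
  cat("X-chromosome rate estimates (", length(x$theta_hat) + 1L,
      " markers)\n", sep = "")
  if (!x$converged) {
    cat("*** WARNING: optimizer did NOT converge (",
        x$diagnostics$message, ") ***\n", sep = "")
  }
  cat("theta_hat:", format(x$theta_hat, digits = 4), "\n")
  if (!is.null(x$mu_hat)) {
    cat("mu_hat (", x$mu_mode, "):",
        format(unique(round(x$mu_hat, 8)), digits = 4), "\n")
  } else {
    cat("mu fixed at", x$fix_mu, "\n")
  }
  cat("negative log-likelihood:", format(x$final_negloglik), "\n")
  invisible(x)
}
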