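#' von Bertalanffy growth model parameters
#'
#' Container for the three parameters of the von Bertalanffy growth model
#' (VBGM) in its length-at-birth parameterization,
#' \deqn{E[L(a)] = L_\infty - (L_\infty - L_0) e^{-k a},}
#' where \eqn{L_\infty} is the asymptotic length (cm), \eqn{k} Brody's growth
#' coefficient (1/year) and \eqn{L_0} the length at birth (cm).
#'
#' @param L_inf asymptotic length, cm; must exceed `L0`.
#' @param k Brody's growth coefficient, 1/year; must be positive.
#' @param L0 length at birth, cm; non-negative.
#' @return An object of class `vbgm_params`.
#' @examples
#' vbgm_params(87, 0.124, 1.7)
#' @export
vbgm_params <- function(L_inf, k, L0) {
  stopifnot(is.numeric(L_inf), is.numeric(k), is.numeric(L0),
            length(L_inf) == 1, length(k) == 1, length(L0) == 1)
  if (!is.finite(L_inf) || !is.finite(k) || !is.finite(L0))
    stop("VBGM parameters must be finite")
  if (L0 < 0) stop("L0 must be >= 0")
  if (L_inf <= L0) stop("L_inf must exceed L0")
  if (k <= 0) stop("k must be > 0")
  structure(list(L_inf = L_inf, k = k, L0 = L0), class = "vbgm_params")
}

#' @export
print.vbgm_params <- function(x, ...) {
  cat(sprintf("VBGM parameters: L_inf = %g cm, k = %g /y, L0 = %g cm\n",
              x$L_inf, x$k, x$L0))
  invisible(x)
}

#' Expected length at age under the von Bertalanffy growth model
#'
#' @param params a [vbgm_params()] object (or list with `L_inf`, `k`, `L0`).
#' @param age age in years; vectorized; must be non-negative.
#' @return expected length(s), cm.
#' @examples
#' vbgm_length(vbgm_params(87, 0.124, 1.7), 0:5)
#' @export
vbgm_length <- function(params, age) {
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be finite and >= 0")
  params$L_inf - (params$L_inf - params$L0) * exp(-params$k * age)
}

# cumulative day count at the start of each month, 365-day calendar
.cum_month_days <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)

#' Fractional age of a fish at capture
#'
#' Converts an age in completed years plus a capture date into a fractional
#' age, assuming a June 1 birthday and a 365-day year (leap days are ignored:
#' February 29 counts as February 28). The fraction is the number of days
#' since the most recent June 1 divided by 365, so the result always lies in
#' `[completed_years, completed_years + 1)`.
#'
#' @param completed_years non-negative integer age in completed years.
#' @param capture_date a `Date` (or string coercible via [as.Date()]).
#' @return fractional age in years; vectorized over both arguments.
#' @examples
#' fractional_age(3, as.Date("2010-06-01"))   # 3.0
#' fractional_age(0, as.Date("2010-08-13"))   # 73/365 = 0.2
#' @export
fractional_age <- function(completed_years, capture_date) {
  capture_date <- as.Date(capture_date)
  if (any(is.na(capture_date))) stop("invalid capture_date")
  if (any(completed_years < 0) || any(completed_years != floor(completed_years)))
    stop("completed_years must be a non-negative integer")
  lt <- as.POSIXlt(capture_date)
  mon <- lt$mon + 1L          # 1..12
  mday <- pmin(lt$mday, ifelse(mon == 2L, 28L, 31L))
  doy <- .cum_month_days[mon] + mday                  # 1..365
  june1 <- .cum_month_days[6L] + 1L                   # 152
  completed_years + ((doy - june1) %% 365L) / 365
}

#' Lognormal log-likelihood of length-at-age data under the VBGM
#'
#' The length at fractional age \eqn{a_t} is modelled as
#' \eqn{L_t \sim \mathrm{Lognormal}(\mu_t, \sigma)} with location
#' \eqn{\mu_t = \ln E[L_t] - \sigma^2/2}, so that the mean of the lognormal
#' equals the VBGM expectation.
#'
#' @param data a data.frame with columns `fractional_age` and `length_cm`.
#' @param params a [vbgm_params()] object.
#' @param sigma lognormal shape parameter, > 0.
#' @return scalar log-likelihood.
#' @export
loglik_lognormal <- function(data, params, sigma) {
  stopifnot(is.data.frame(data), sigma > 0)
  if (any(data$length_cm <= 0)) stop("all lengths must be > 0")
  if (any(data$fractional_age < 0)) stop("all ages must be >= 0")
  mu <- log(vbgm_length(params, data$fractional_age)) - sigma^2 / 2
  sum(stats::dlnorm(data$length_cm, meanlog = mu, sdlog = sigma, log = TRUE))
}

#' Uniform prior bounds for the Bayesian VBGM
#'
#' @param L_inf,k,L0,sigma length-2 numeric vectors `c(lower, upper)`.
#'   Collapsed bounds (`lower == upper`) fix the parameter at that value,
#'   which is also how `L0` can be pinned to a literature value.
#' @return An object of class `prior_bounds`: a 4 x 2 matrix.
#' @export
prior_bounds <- function(L_inf = c(5, 150), k = c(0.01, 2), L0 = c(0, 5),
                         sigma = c(0.005, 1)) {
  m <- rbind(L_inf = L_inf, k = k, L0 = L0, sigma = sigma)
  colnames(m) <- c("lower", "upper")
  if (any(m[, 1] > m[, 2])) stop("each lower bound must be <= its upper bound")
  if (any(m[, 1] < 0)) stop("all lower bounds must be >= 0")
  structure(m, class = c("prior_bounds", class(m)))
}

#' Default prior bounds per focal species
#'
#' Wide uniform boxes spanning the population-level posterior-mean estimates
#' for the two focal species (pikeperch-like piscivore, vendace-like
#' planktivore), leaving room on both sides.
#'
#' @param species `"pikeperch"` or `"vendace"`.
#' @export
default_prior_bounds <- function(species = c("pikeperch", "vendace")) {
  species <- match.arg(species)
  switch(species,
    pikeperch = prior_bounds(L_inf = c(40, 150), k = c(0.02, 0.8),
                             L0 = c(0, 5), sigma = c(0.005, 1)),
    vendace   = prior_bounds(L_inf = c(5, 40), k = c(0.05, 2),
                             L0 = c(0, 3), sigma = c(0.005, 1)))
}

#' Fit the Bayesian von Bertalanffy growth model
#'
#' Samples the posterior of \eqn{(L_\infty, k, L_0, \sigma)} under uniform
#' priors and the lognormal likelihood of [loglik_lognormal()], using an
#' adaptive random-walk Metropolis sampler (diagonal scaling during the first
#' half of warmup, empirical-covariance proposals thereafter; adaptation is
#' frozen after warmup). Split-chain potential scale reduction (Rhat) and
#' effective sample sizes are reported; non-convergence is flagged with a
#' warning, never silently ignored.
#'
#' @param data data.frame with columns `fractional_age`, `length_cm`.
#' @param prior a [prior_bounds()] object.
#' @param n_chains number of chains (>= 2 for diagnostics; default 4).
#' @param warmup warmup iterations per chain (discarded; default 1000).
#' @param draws retained iterations per chain (default 4000).
#' @param seed integer seed; the fit is reproducible bit-for-bit.
#' @param rhat_threshold flag non-convergence above this value.
#' @return An object of class `vbgm_posterior`: list with `draws`
#'   (array `draws x 4 x n_chains`), `diagnostics` (per-parameter Rhat and
#'   ESS), `converged`, and the call configuration.
#' @export
fit_bvbgm <- function(data, prior = prior_bounds(), n_chains = 4,
                      warmup = 1000, draws = 4000, seed = 1,
                      rhat_threshold = 1.05) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (any(data$length_cm <= 0)) stop("all lengths must be > 0")
  bounds <- unclass(prior)
  pn <- rownames(bounds)
  free <- which(bounds[, 2] > bounds[, 1])
  nfree <- length(free)
  set.seed(as.integer(seed))

  age <- data$fractional_age
  len <- data$length_cm
  logpost <- function(theta) {
    if (any(theta < bounds[, 1]) || any(theta > bounds[, 2])) return(-Inf)
    if (theta[1] <= theta[3]) return(-Inf)
    mu <- log(theta[1] - (theta[1] - theta[3]) * exp(-theta[2] * age)) - theta[4]^2 / 2
    sum(stats::dlnorm(len, meanlog = mu, sdlog = theta[4], log = TRUE))
  }

  out <- array(NA_real_, dim = c(draws, 4L, n_chains),
               dimnames = list(NULL, pn, paste0("chain", seq_len(n_chains))))
  if (nfree == 0L) {                      # fully degenerate prior: a point
    for (c in seq_len(n_chains)) out[, , c] <- matrix(bounds[, 1], draws, 4, byrow = TRUE)
    diag_df <- data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_)
    return(structure(list(draws = out, diagnostics = diag_df, converged = TRUE,
                          n_chains = n_chains, warmup = warmup, prior = prior),
                     class = "vbgm_posterior"))
  }

  # chain starts: the best of a batch of prior draws, jittered, so short
  # warmups begin near the posterior mass rather than deep in the tails
  n0 <- 256L
  cand <- matrix(bounds[, 1], n0, 4, byrow = TRUE) +
    matrix(stats::runif(4 * n0), n0, 4) *
    matrix(bounds[, 2] - bounds[, 1], n0, 4, byrow = TRUE)
  lp0 <- apply(cand, 1, logpost)
  best <- cand[which.max(lp0), ]
  # polish towards the posterior mode so chains start on the ridge, not at
  # its far end (the L_inf-k ridge is long and slow to traverse)
  if (nfree > 0) {
    opt <- stats::optim(best[free], function(th) {
      full <- best; full[free] <- th
      -logpost(full)
    }, method = "Nelder-Mead", control = list(maxit = 400))
    if (is.finite(opt$value)) best[free] <- opt$par
  }

  for (c in seq_len(n_chains)) {
    repeat {
      theta <- best
      theta[free] <- theta[free] + stats::rnorm(nfree) *
        (bounds[free, 2] - bounds[free, 1]) / 100
      theta <- pmin(pmax(theta, bounds[, 1]), bounds[, 2])
      lp <- logpost(theta)
      if (is.finite(lp)) break
    }
    sd0 <- (bounds[free, 2] - bounds[free, 1]) / 50
    hist <- matrix(NA_real_, warmup + draws, nfree)
    scale <- 1
    chol_prop <- diag(sd0, nfree, nfree)
    total <- warmup + draws
    for (i in seq_len(total)) {
      adapt <- i <= warmup
      if (adapt && i > max(50, warmup / 4) && i %% 50 == 0) {
        S <- stats::cov(hist[seq(floor(i / 2), i - 1), , drop = FALSE])
        S <- S + diag(1e-10 + 1e-6 * diag(S), nfree)
        chol_prop <- t(chol(2.38^2 / nfree * S))
      }
      prop <- theta
      prop[free] <- theta[free] + scale * as.vector(chol_prop %*% stats::rnorm(nfree))
      lp_prop <- logpost(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc <- 1
      } else acc <- 0
      if (adapt) scale <- exp(log(scale) + (acc - 0.3) / sqrt(i) * 2)
      hist[i, ] <- theta[free]
      if (i > warmup) out[i - warmup, , c] <- theta
    }
  }

  diag_df <- .mcmc_diagnostics(out)
  converged <- all(is.na(diag_df$rhat) | diag_df$rhat < rhat_threshold)
  if (!converged)
    warning(sprintf("MCMC may not have converged: max split-Rhat = %.3f",
                    max(diag_df$rhat, na.rm = TRUE)))
  structure(list(draws = out, diagnostics = diag_df, converged = converged,
                 n_chains = n_chains, warmup = warmup, prior = prior),
            class = "vbgm_posterior")
}

# split-chain Rhat and a Geyer initial-monotone ESS, per parameter
.mcmc_diagnostics <- function(draws_arr) {
  pn <- dimnames(draws_arr)[[2]]
  n <- dim(draws_arr)[1]; nc <- dim(draws_arr)[3]
  half <- floor(n / 2)
  res <- data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_)
  for (p in seq_along(pn)) {
    chains <- lapply(seq_len(nc), function(c) draws_arr[, p, c])
    splits <- unlist(lapply(chains, function(x)
      list(x[seq_len(half)], x[(n - half + 1):n])), recursive = FALSE)
    m <- length(splits)
    means <- vapply(splits, mean, 0); vars <- vapply(splits, stats::var, 0)
    W <- mean(vars); B <- half * stats::var(means)
    if (W < .Machine$double.eps * max(abs(means), 1)^2) {
      res$rhat[p] <- 1; res$ess[p] <- n * nc; next
    }
    var_plus <- (half - 1) / half * W + B / half
    res$rhat[p] <- sqrt(var_plus / W)
    ess <- 0
    for (ch in chains) {
      ac <- stats::acf(ch, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
      s <- 0; k <- 1
      while (k < length(ac)) {             # Geyer: sum positive pairs
        pair <- ac[k] + ifelse(k + 1 <= length(ac), ac[k + 1], 0)
        if (pair < 0) break
        s <- s + pair; k <- k + 2
      }
      ess <- ess + n / (1 + 2 * s)
    }
    res$ess[p] <- ess
  }
  res
}

#' Summarize a VBGM posterior
#'
#' @param posterior a `vbgm_posterior` object.
#' @param mass central credible-interval probability mass (default 0.9).
#' @return data.frame with posterior mean, median and central interval per
#'   parameter, pooled across chains.
#' @export
posterior_summary <- function(posterior, mass = 0.9) {
  stopifnot(inherits(posterior, "vbgm_posterior"), mass > 0, mass < 1)
  pn <- dimnames(posterior$draws)[[2]]
  a <- (1 - mass) / 2
  res <- lapply(seq_along(pn), function(p) {
    x <- as.vector(posterior$draws[, p, ])
    q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE)
    data.frame(parameter = pn[p], mean = mean(x), median = q[2],
               lower = q[1], upper = q[3])
  })
  out <- do.call(rbind, res)
  attr(out, "mass") <- mass
  out
}

#' @export
print.vbgm_posterior <- function(x, ...) {
  cat(sprintf("Bayesian VBGM posterior: %d chains x %d draws (warmup %d)\n",
              x$n_chains, dim(x$draws)[1], x$warmup))
  print(cbind(posterior_summary(x), x$diagnostics[, c("rhat", "ess")]))
  if (!x$converged) cat("WARNING: convergence diagnostics exceeded threshold\n")
  invisible(x)
}

#' Read / write length-at-age records
#'
#' CSV with header `fractional_age,length_cm`.
#' @param path file path.
#' @param data data.frame with columns `fractional_age`, `length_cm`.
#' @export
read_length_at_age <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("fractional_age", "length_cm") %in% names(d)))
  d
}

#' @rdname read_length_at_age
#' @export
write_length_at_age <- function(data, path) {
  utils::write.csv(data[, c("fractional_age", "length_cm")], path, row.names = FALSE)
  invisible(path)
}

#' Export posterior draws as CSV
#' @param posterior a `vbgm_posterior`.
#' @param path file path.
#' @export
write_posterior_draws <- function(posterior, path) {
  pn <- dimnames(posterior$draws)[[2]]
  nc <- dim(posterior$draws)[3]
  d <- do.call(rbind, lapply(seq_len(nc), function(c) {
    df <- as.data.frame(posterior$draws[, , c])
    names(df) <- pn
    df$chain <- c
    df
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
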