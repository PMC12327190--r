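#' Bell-shaped gear selectivity curve
#'
#' Size selectivity of a fishing gear is modelled with a bell-shaped
#' (Gaussian-bell) curve,
#' \deqn{\hat S(L \mid \mu, \sigma, \delta) =
#'   \frac{\delta}{\sqrt{2\pi}\,\sigma} e^{-(L-\mu)^2 / (2\sigma^2)},}
#' where \eqn{\mu} (cm) is the modal length, \eqn{\sigma} (cm) the width and
#' \eqn{\delta} a scaling parameter in catch-biomass units per length class.
#'
#' @param mu modal length, cm.
#' @param sigma width, cm; > 0.
#' @param delta scaling; > 0 (default 1).
#' @return An object of class `selectivity_curve`.
#' @examples
#' gillnet <- selectivity_curve(46.72, 3.44)
#' trawl <- selectivity_curve(12.21, 1.71)
#' @export
selectivity_curve <- function(mu, sigma, delta = 1) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(delta))
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(delta))
    stop("selectivity parameters must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  if (delta <= 0) stop("delta must be > 0")
  structure(list(mu = mu, sigma = sigma, delta = delta),
            class = "selectivity_curve")
}

#' @export
print.selectivity_curve <- function(x, ...) {
  cat(sprintf("Selectivity curve: mu = %g cm, sigma = %g cm, delta = %g\n",
              x$mu, x$sigma, x$delta))
  invisible(x)
}

#' Evaluate a selectivity curve
#'
#' @param curve a [selectivity_curve()].
#' @param L length(s), cm; >= 0.
#' @return selectivity in the curve's units; maximal at `L == mu`.
#' @export
selectivity_eval <- function(curve, L) {
  if (any(L < 0)) stop("L must be >= 0")
  curve$delta / (sqrt(2 * pi) * curve$sigma) *
    exp(-(L - curve$mu)^2 / (2 * curve$sigma^2))
}

#' Normalized selectivity in [0, 1]
#'
#' The curve divided by its peak value, i.e.
#' \eqn{\exp(-(L-\mu)^2/(2\sigma^2))}; equals 1 at the modal length and is
#' independent of the scaling \eqn{\delta}. Used to scale the peak
#' instantaneous fishing mortality E across lengths.
#'
#' @inheritParams selectivity_eval
#' @export
normalized_selectivity <- function(curve, L) {
  exp(-(L - curve$mu)^2 / (2 * curve$sigma^2))
}

#' Aggregate individual catch records into 1-cm length classes
#'
#' Bins are `[c, c + 1)` keyed by the integer floor of the length, matching
#' the convention that e.g. the 20 cm class covers lengths 20 to 20.9 cm.
#'
#' @param records data.frame with columns `length_cm` (>= 0) and `mass_g`.
#' @return data.frame with columns `class_lower_cm`, `biomass_g`, one row per
#'   non-empty class, sorted by class; total mass is preserved.
#' @export
aggregate_catch <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(data.frame(class_lower_cm = integer(0), biomass_g = numeric(0)))
  if (any(records$length_cm < 0)) stop("lengths must be >= 0")
  if (any(records$mass_g < 0)) stop("negative mass in catch records")
  cls <- floor(records$length_cm)
  agg <- tapply(records$mass_g, cls, sum)
  data.frame(class_lower_cm = as.integer(names(agg)),
             biomass_g = as.numeric(agg), row.names = NULL)
}

.class_midpoints <- function(class_lower) class_lower + 0.5

#' Fit a selectivity curve to catch-by-length-class data
#'
#' Minimizes the sum of squared residuals between class biomasses and the
#' curve evaluated at class midpoints (`class_lower + 0.5` for the 1-cm
#' classes `[c, c + 1)`), using derivative-free Nelder-Mead simplex search
#' from multiple starts. Default starts are seeded from data moments (the
#' maximal class for mu, the biomass-weighted SD for sigma) plus
#' perturbations; the best converged start is reported. Starts yielding a
#' non-finite objective are rejected.
#'
#' @param catch data.frame with columns `class_lower_cm`, `biomass_g`;
#'   at least 3 classes with positive biomass are required.
#' @param starts optional list of numeric `c(mu, sigma, delta)` start values
#'   replacing the defaults.
#' @param n_starts number of moment-seeded starts when `starts` is NULL
#'   (minimum 5).
#' @return list with `curve` (the fitted [selectivity_curve()]), `rss`
#'   (residual sum of squares) and `n_starts_used`.
#' @export
fit_selectivity <- function(catch, starts = NULL, n_starts = 5) {
  stopifnot(is.data.frame(catch))
  b <- catch$biomass_g
  mids <- .class_midpoints(catch$class_lower_cm)
  if (sum(b > 0) < 3) stop("need at least 3 classes with positive biomass")
  obj <- function(par) {            # par = (mu, log sigma, log delta)
    s <- exp(par[2]); d <- exp(par[3])
    pred <- d / (sqrt(2 * pi) * s) * exp(-(mids - par[1])^2 / (2 * s^2))
    sum((b - pred)^2)
  }
  if (is.null(starts)) {
    n_starts <- max(5L, as.integer(n_starts))
    mu0 <- mids[which.max(b)]
    w <- b / sum(b)
    sd0 <- sqrt(max(sum(w * (mids - sum(w * mids))^2), 0.25))
    d0 <- max(b) * sqrt(2 * pi) * sd0
    starts <- list(c(mu0, sd0, d0))
    fac <- cbind(mu = c(-1, 1, 0, -2, 2, 0, 0),
                 sig = c(0.5, 2, 1.5, 1, 1, 0.75, 3),
                 del = c(1, 1, 2, 0.5, 2, 1, 1))
    for (i in seq_len(n_starts - 1L)) {
      j <- ((i - 1L) %% nrow(fac)) + 1L
      starts[[i + 1L]] <- c(mu0 + fac[j, 1] * sd0, sd0 * fac[j, 2], d0 * fac[j, 3])
    }
  }
  best <- NULL
  used <- 0L
  for (s0 in starts) {
    if (s0[2] <= 0 || s0[3] <= 0) next
    par0 <- c(s0[1], log(s0[2]), log(s0[3]))
    if (!is.finite(obj(par0))) next      # reject this start
    used <- used + 1L
    fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    # polish: restart the simplex once from the optimum
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("no usable start for the selectivity fit")
  list(curve = selectivity_curve(best$par[1], exp(best$par[2]), exp(best$par[3])),
       rss = best$value, n_starts_used = used)
}

#' Read / write catch-by-length-class data
#'
#' CSV with header `class_lower_cm,biomass_g`.
#' @param path file path.
#' @param catch data.frame with columns `class_lower_cm`, `biomass_g`.
#' @export
read_catch_by_length <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("class_lower_cm", "biomass_g") %in% names(d)))
  d
}

#' @rdname read_catch_by_length
#' @export
write_catch_by_length <- function(catch, path) {
  utils::write.csv(catch[, c("class_lower_cm", "biomass_g")], path, row.names = FALSE)
  invisible(path)
}
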