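#' Discrete trait grid for evolving von Bertalanffy parameters
#'
#' The evolving life-history traits (asymptotic length \eqn{L_\infty} and
#' Brody's growth coefficient \eqn{k}) live on a fixed rectangular grid of
#' `n_L x n_k` cells ("genotype groups"). Cell edges partition the rectangle
#' exactly; grid bounds are the hard limits for trait values in the
#' simulation.
#'
#' @param L_inf_bounds length-2 numeric, cm (e.g. `c(70, 90)` for a
#'   pikeperch-like piscivore, `c(10, 20)` for a vendace-like planktivore).
#' @param k_bounds length-2 numeric, 1/year.
#' @param n_L,n_k number of cells per axis. The full-scale configuration is
#'   100 x 100 (10,000 genotype groups); 40 x 40 is the default working
#'   resolution.
#' @return An object of class `trait_grid` with cell edges and centres.
#' @export
trait_grid <- function(L_inf_bounds, k_bounds, n_L = 40, n_k = 40) {
  stopifnot(length(L_inf_bounds) == 2, length(k_bounds) == 2,
            all(is.finite(L_inf_bounds)), all(is.finite(k_bounds)),
            n_L >= 1, n_k >= 1)
  if (L_inf_bounds[1] >= L_inf_bounds[2] || k_bounds[1] >= k_bounds[2])
    stop("grid bounds must satisfy low < high")
  n_L <- as.integer(n_L); n_k <- as.integer(n_k)
  edges_L <- seq(L_inf_bounds[1], L_inf_bounds[2], length.out = n_L + 1)
  edges_k <- seq(k_bounds[1], k_bounds[2], length.out = n_k + 1)
  structure(list(
    L_inf_bounds = as.numeric(L_inf_bounds), k_bounds = as.numeric(k_bounds),
    n_L = n_L, n_k = n_k, G = n_L * n_k,
    edges_L = edges_L, edges_k = edges_k,
    centers_L = (edges_L[-1] + edges_L[-(n_L + 1)]) / 2,
    centers_k = (edges_k[-1] + edges_k[-(n_k + 1)]) / 2,
    h_L = diff(L_inf_bounds) / n_L, h_k = diff(k_bounds) / n_k),
    class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf(
    "Trait grid: L_inf in [%g, %g] cm x k in [%g, %g] /y, %d x %d = %d cells\n",
    x$L_inf_bounds[1], x$L_inf_bounds[2], x$k_bounds[1], x$k_bounds[2],
    x$n_L, x$n_k, x$G))
  invisible(x)
}

# per-cell trait vectors in the flat (column-major, L_inf fastest) cell order
grid_cell_traits <- function(grid) {
  list(L_inf = rep(grid$centers_L, grid$n_k),
       k = rep(grid$centers_k, each = grid$n_L))
}

#' Reproduction-kernel parameters
#'
#' Parameters of the multivariate normal inheritance kernel: `cV` scales the
#' genotypic variance component (the two-point variance of each parent pair),
#' `sigma_L_inf` and `sigma_k` are the additive phenotypic standard
#' deviations, `rho` the correlation between \eqn{L_\infty} and \eqn{k}
#' (negative in the baseline scenarios), and `u` the efficiency converting
#' allocated reproductive biomass into larvae biomass.
#'
#' @param cV genotypic variance control, >= 0 (sensitivity levels 0.125,
#'   0.25, 0.5; medium 0.25).
#' @param sigma_L_inf additive phenotypic SD for `L_inf`, cm.
#' @param sigma_k additive phenotypic SD for `k`, 1/year.
#' @param rho trait correlation, |rho| <= 1 (scenarios use 0, -0.35, -0.7).
#' @param u larvae conversion efficiency in (0, 1]; default 0.8.
#' @export
reproduction_params <- function(cV = 0.25, sigma_L_inf, sigma_k, rho = -0.7,
                                u = 0.8) {
  stopifnot(cV >= 0, sigma_L_inf >= 0, sigma_k >= 0, abs(rho) <= 1,
            u > 0, u <= 1)
  structure(list(cV = cV, sigma_L_inf = sigma_L_inf, sigma_k = sigma_k,
                 rho = rho, u = u), class = "reproduction_params")
}

#' Default reproduction parameters per focal species (medium levels)
#' @param species `"pikeperch"` or `"vendace"`.
#' @param rho trait correlation (default -0.7, the baseline scenario).
#' @export
default_reproduction_params <- function(species = c("pikeperch", "vendace"),
                                        rho = -0.7) {
  species <- match.arg(species)
  switch(species,
    pikeperch = reproduction_params(0.25, 3.0, 0.030, rho),
    vendace   = reproduction_params(0.25, 1.0, 0.020, rho))
}

#' Initial trait distribution on a grid
#'
#' A bivariate normal truncated to the grid rectangle and discretized to cell
#' masses. By default it is centred at the middle of the grid, where the
#' neutral (unfished) dynamics leave the distribution mean stationary.
#'
#' @param grid a [trait_grid()].
#' @param center length-2 `c(L_inf, k)`; default the grid middle.
#' @param sd length-2 SDs; default one tenth of each axis span.
#' @param rho correlation of the initial distribution (default 0).
#' @return `n_L x n_k` matrix of cell probabilities summing to 1.
#' @export
initial_trait_distribution <- function(grid, center = NULL, sd = NULL,
                                       rho = 0) {
  if (is.null(center))
    center <- c(mean(grid$L_inf_bounds), mean(grid$k_bounds))
  if (is.null(sd))
    sd <- c(diff(grid$L_inf_bounds), diff(grid$k_bounds)) / 10
  m <- cpp_bvn_cell_masses(grid$edges_L, grid$edges_k, center[1], center[2],
                           sd[1], sd[2], rho)
  s <- sum(m)
  if (s <= 0) stop("initial distribution has no mass on the grid")
  m / s
}

#' Mean and marginal variances of a trait distribution
#'
#' @param dist `n_L x n_k` probability matrix.
#' @param grid the matching [trait_grid()].
#' @return list with `mean` (named `L_inf`, `k`) and `var` (named the same),
#'   computed over cell centres.
#' @export
trait_moments <- function(dist, grid) {
  pL <- rowSums(dist); pk <- colSums(dist)
  mL <- sum(pL * grid$centers_L); mk <- sum(pk * grid$centers_k)
  list(mean = c(L_inf = mL, k = mk),
       var = c(L_inf = sum(pL * (grid$centers_L - mL)^2),
               k = sum(pk * (grid$centers_k - mk)^2)))
}
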