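#' Parent trait distribution from reproductive pools
#'
#' Sums the end-of-season reproductive pools of each genotype lineage across
#' age guilds and normalizes by the grand total.
#'
#' @param pools matrix `G x n_ages` of reproductive-pool biomass (mg C), one
#'   column per age guild, rows in the flat cell order of the grid.
#' @param grid the [trait_grid()] (supplies the cell layout).
#' @return `n_L x n_k` probability matrix summing to 1.
#' @export
parent_distribution <- function(pools, grid) {
  lineage <- if (is.matrix(pools)) rowSums(pools) else as.numeric(pools)
  tot <- sum(lineage)
  if (tot <= 0)
    stop(structure(class = c("atne_reproduction_failure", "error", "condition"),
                   list(message = "total reproductive pool is zero: no larvae this year",
                        call = sys.call(-1))))
  matrix(lineage / tot, grid$n_L, grid$n_k)
}

#' Inheritance kernel for one parent pair
#'
#' The larvae trait vector conditioned on a parent pair is bivariate normal
#' with mean the pair midpoint and covariance
#' \eqn{\Sigma = \Omega^{1/2} \Lambda \Omega^{1/2}} where
#' \eqn{\Omega = \Omega_G + \Omega_A}, \eqn{\Omega_G = c_V\,
#' \mathrm{diag}((t_1 - t_2)^2/2)} (the two-point variance of the pair, per
#' trait), \eqn{\Omega_A = \mathrm{diag}(\tilde\sigma^2_{L_\infty},
#' \tilde\sigma^2_k)}, and \eqn{\Lambda} the correlation matrix with
#' off-diagonal \eqn{\rho}.
#'
#' @param tp1,tp2 length-2 parent trait vectors `c(L_inf, k)`; must lie
#'   inside the grid rectangle.
#' @param params a [reproduction_params()].
#' @param grid the [trait_grid()].
#' @return list with `mean` (length 2) and `Sigma` (2 x 2 covariance).
#' @export
pair_kernel <- function(tp1, tp2, params, grid) {
  stopifnot(length(tp1) == 2, length(tp2) == 2)
  inside <- function(tp)
    tp[1] >= grid$L_inf_bounds[1] && tp[1] <= grid$L_inf_bounds[2] &&
    tp[2] >= grid$k_bounds[1] && tp[2] <= grid$k_bounds[2]
  if (!inside(tp1) || !inside(tp2))
    stop("parent trait vectors must lie inside the grid rectangle")
  omega_G <- params$cV * c((tp1[1] - tp2[1])^2, (tp1[2] - tp2[2])^2) / 2
  omega_A <- c(params$sigma_L_inf^2, params$sigma_k^2)
  om <- omega_G + omega_A                       # diagonal of Omega
  s <- sqrt(om)                                 # elementwise square root
  Sigma <- diag(s, 2) %*% matrix(c(1, params$rho, params$rho, 1), 2) %*% diag(s, 2)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev >= -1e-12 * max(abs(ev), 1)))  # PSD for |rho| <= 1
  list(mean = (tp1 + tp2) / 2, Sigma = Sigma)
}

#' Kernel cache for repeated larvae-distribution evaluations
#'
#' The mixing engine caches per-lag kernel templates; reusing one cache
#' across the years of a simulation makes repeated spawns much faster. A
#' cache is bound to one (grid, kernel-parameter) combination on first use.
#'
#' @return an external pointer to pass as `cache` to [larvae_distribution()].
#' @export
mix_cache <- function() cpp_mix_cache_new()

#' Larvae trait distribution from a parent distribution
#'
#' Mixes the [pair_kernel()] over all parent-cell pairs weighted
#' \eqn{P(t_1) P(t_2)} (random mating with independent parents), truncates
#' each kernel to the grid, renormalizes it to its in-grid mass (so spawned
#' biomass is conserved), and discretizes via the bivariate normal CDF over
#' cell rectangles. Parent cells holding less than `eps_P` probability mass
#' are pruned from the pair sum; `eps_P = 0` gives the exact full double
#' sum, and the pruned result differs from it by at most ~`eps_P * G` in
#' total variation.
#'
#' @param parents `n_L x n_k` parent probability matrix (see
#'   [parent_distribution()]).
#' @param params a [reproduction_params()].
#' @param grid the [trait_grid()].
#' @param eps_P parent-cell pruning threshold (default 1e-8 of the parent
#'   mass).
#' @param cache optional [mix_cache()] reused across calls.
#' @param component `"phenotype"` (full kernel) or `"genotype"`
#'   (\eqn{\Omega_A = 0}, genotypic component only; used for heritability).
#' @return `n_L x n_k` probability matrix summing to 1.
#' @export
larvae_distribution <- function(parents, params, grid, eps_P = 1e-8,
                                cache = NULL,
                                component = c("phenotype", "genotype")) {
  component <- match.arg(component)
  stopifnot(is.matrix(parents), nrow(parents) == grid$n_L,
            ncol(parents) == grid$n_k, all(parents >= 0))
  tot <- sum(parents)
  if (tot <= 0) stop("parent distribution has no mass")
  parents <- parents / tot
  if (eps_P > 0) {
    parents[parents < eps_P] <- 0
    if (sum(parents) <= 0)
      stop("all parent cells were pruned; no larvae mass left")
  }
  if (is.null(cache)) cache <- cpp_mix_cache_new()
  sA2L <- if (component == "phenotype") params$sigma_L_inf^2 else 0
  sA2K <- if (component == "phenotype") params$sigma_k^2 else 0
  cpp_larvae_mix(parents, grid$h_L, grid$h_k, params$cV, sA2L, sA2K,
                 params$rho, 0, cache)
}

#' Genotypic and phenotypic variances of the larvae distribution
#'
#' Computes the larvae trait distribution with (phenotype) and without
#' (genotype) the additive phenotypic variance component and returns the
#' marginal variances of both discretized, truncated distributions.
#'
#' @inheritParams larvae_distribution
#' @param caches optional list with elements `phenotype` and `genotype`,
#'   each a [mix_cache()].
#' @return list with `V_G` and `V_P` (each named `c(L_inf, k)`) and the two
#'   distributions (`dist_G`, `dist_P`).
#' @export
genotype_phenotype_variances <- function(parents, params, grid, eps_P = 1e-8,
                                         caches = NULL) {
  dP <- larvae_distribution(parents, params, grid, eps_P,
                            cache = caches$phenotype, component = "phenotype")
  dG <- larvae_distribution(parents, params, grid, eps_P,
                            cache = caches$genotype, component = "genotype")
  list(V_G = trait_moments(dG, grid)$var, V_P = trait_moments(dP, grid)$var,
       dist_G = dG, dist_P = dP)
}

#' Heritability of the evolving traits
#'
#' Defined as the genotypic variance divided by the phenotypic variance,
#' \eqn{H = V_G / V_P}, per trait. Because both variances come from
#' grid-truncated distributions, values above one can occur near the grid
#' boundaries (truncation shrinks the wider phenotype distribution more).
#'
#' @param V_G,V_P named numeric vectors as returned by
#'   [genotype_phenotype_variances()].
#' @return named numeric vector `c(L_inf, k)`.
#' @export
heritability <- function(V_G, V_P) {
  if (any(V_P <= 0)) stop("phenotypic variance is zero: heritability undefined")
  V_G / V_P
}
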