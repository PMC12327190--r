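# Independent oracles and small fixtures shared across tests.

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  E <- eigen(J, symmetric = TRUE)
  list(x = E$values, w = 2 * E$vectors[1, ]^2)
}
.GL48 <- gauss_legendre(48)

# Rectangle masses of one bivariate normal over grid cells, by quadrature
# over the first axis and exact conditional normal CDFs on the second;
# independent of the package's bivariate-CDF code.
oracle_bvn_masses <- function(grid, mu, Sigma) {
  sL <- sqrt(Sigma[1, 1]); sK <- sqrt(Sigma[2, 2])
  r <- Sigma[1, 2] / (sL * sK)
  out <- matrix(0, grid$n_L, grid$n_k)
  for (i in seq_len(grid$n_L)) {
    a <- (grid$edges_L[i] - mu[1]) / sL
    b <- (grid$edges_L[i + 1] - mu[1]) / sL
    x <- (a + b) / 2 + (b - a) / 2 * .GL48$x
    w <- (b - a) / 2 * .GL48$w * stats::dnorm(x)
    for (j in seq_len(grid$n_k)) {
      yl <- ((grid$edges_k[j] - mu[2]) / sK - r * x) / sqrt(1 - r^2)
      yh <- ((grid$edges_k[j + 1] - mu[2]) / sK - r * x) / sqrt(1 - r^2)
      out[i, j] <- sum(w * (stats::pnorm(yh) - stats::pnorm(yl)))
    }
  }
  out
}

# Full double-sum larvae distribution over all parent pairs (no pruning),
# mirroring the inheritance-kernel definition directly.
oracle_larvae <- function(P, params, grid, phenotype = TRUE) {
  cl <- rep(grid$centers_L, grid$n_k)
  ck <- rep(grid$centers_k, each = grid$n_L)
  p <- as.vector(P)
  occ <- which(p > 0)
  out <- matrix(0, grid$n_L, grid$n_k)
  sA <- if (phenotype) c(params$sigma_L_inf^2, params$sigma_k^2) else c(0, 0)
  place1d <- function(mu1, edges, n) {
    v <- numeric(n)
    hit <- which(abs(edges - mu1) < 1e-9)
    if (length(hit) && hit[1] > 1 && hit[1] < n + 1) {
      v[hit[1] - 1] <- 0.5; v[hit[1]] <- 0.5
    } else v[findInterval(mu1, edges, rightmost.closed = TRUE)] <- 1
    v
  }
  for (a in occ) for (b in occ) {
    w <- p[a] * p[b]
    om <- params$cV * c((cl[a] - cl[b])^2, (ck[a] - ck[b])^2) / 2 + sA
    mu <- c((cl[a] + cl[b]) / 2, (ck[a] + ck[b]) / 2)
    if (all(om > 0)) {
      s <- sqrt(om)
      Sigma <- diag(s) %*% matrix(c(1, params$rho, params$rho, 1), 2) %*%
        diag(s)
      m <- oracle_bvn_masses(grid, mu, Sigma)
    } else {
      mL <- if (om[1] > 0)
        diff(stats::pnorm((grid$edges_L - mu[1]) / sqrt(om[1])))
      else place1d(mu[1], grid$edges_L, grid$n_L)
      mK <- if (om[2] > 0)
        diff(stats::pnorm((grid$edges_k - mu[2]) / sqrt(om[2])))
      else place1d(mu[2], grid$edges_k, grid$n_k)
      m <- outer(mL, mK)
    }
    tot <- sum(m)
    if (tot > 0) out <- out + w * m / tot
  }
  out / sum(out)
}

# a tiny evolving toy web for fast driver tests
tiny_web <- function(grid_n = 5, rho = -0.7)
  toy_foodweb(grid_n = grid_n, rho = rho)

# one annual cycle (growth season -> spawn -> ageing -> off-season)
annual_cycle <- function(state, web, E = 0, ...) {
  state <- integrate_growth_season(state, web, E = E)
  state <- spawn(state, web, ...)
  state <- age_guilds(state, web)
  off_season_step(state, web)
}

# memoised store for expensive shared computations (built on first use)
.acceptance_cache <- new.env(parent = emptyenv())
with_cache <- function(key, expr) {
  if (is.null(.acceptance_cache[[key]]))
    assign(key, expr, envir = .acceptance_cache)
  .acceptance_cache[[key]]
}
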