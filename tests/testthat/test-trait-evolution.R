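test_that("trait grid partitions the rectangle exactly", {
  g <- trait_grid(c(70, 90), c(0.10, 0.20), 40, 40)
  expect_equal(g$G, 1600L)
  expect_equal(length(g$edges_L), 41)
  expect_equal(diff(range(g$edges_L)), 20)
  expect_equal(g$centers_L, (g$edges_L[-41] + g$edges_L[-1]) / 2)
  expect_equal(g$h_L, 0.5)
  expect_error(trait_grid(c(90, 70), c(0.1, 0.2)), "low < high")
})

test_that("parent_distribution pools lineages across age guilds", {
  g <- trait_grid(c(10, 20), c(0.45, 0.65), 2, 2)
  # all pool mass in one cell -> point mass
  pools <- matrix(0, 4, 3); pools[3, 2] <- 7
  expect_equal(as.vector(parent_distribution(pools, g)),
               c(0, 0, 1, 0))
  # two guilds with equal pools in two cells -> (0.5, 0.5)
  pools2 <- matrix(0, 4, 2); pools2[1, 1] <- 3; pools2[4, 2] <- 3
  expect_equal(as.vector(parent_distribution(pools2, g)),
               c(0.5, 0, 0, 0.5))
  # hand-summed 3-guild x 4-cell table
  pools3 <- matrix(c(1, 0, 2, 1,
                     0, 3, 1, 0,
                     2, 0, 0, 2), 4, 3)
  expect_equal(as.vector(parent_distribution(pools3, g)),
               c(3, 3, 3, 3) / 12)
  expect_error(parent_distribution(matrix(0, 4, 2), g),
               class = "atne_reproduction_failure")
})

test_that("pair_kernel builds the documented covariance", {
  g <- trait_grid(c(70, 90), c(0.10, 0.20), 10, 10)
  pr <- reproduction_params(cV = 0.25, sigma_L_inf = 3, sigma_k = 0.03,
                            rho = -0.7)
  # identical parents: zero pair variance, Sigma from Omega_A alone
  k1 <- pair_kernel(c(80, 0.15), c(80, 0.15), pr, g)
  expect_equal(k1$mean, c(80, 0.15))
  expect_equal(k1$Sigma, matrix(c(9, -0.7 * 3 * 0.03,
                                  -0.7 * 3 * 0.03, 0.03^2), 2))
  # rho = 0: diagonal Sigma equal to Omega
  pr0 <- reproduction_params(0.25, 3, 0.03, 0)
  k2 <- pair_kernel(c(75, 0.12), c(85, 0.18), pr0, g)
  expect_equal(k2$mean, c(80, 0.15))
  expect_equal(k2$Sigma,
               diag(c(0.25 * 100 / 2 + 9, 0.25 * 0.06^2 / 2 + 0.03^2)))
  # rho = -0.7: off-diagonal from the 2x2 product, by hand
  k3 <- pair_kernel(c(75, 0.12), c(85, 0.18), pr, g)
  sL <- sqrt(0.25 * 100 / 2 + 9); sk <- sqrt(0.25 * 0.06^2 / 2 + 0.03^2)
  expect_equal(k3$Sigma[1, 2], -0.7 * sL * sk)
  expect_equal(k3$Sigma[1, 2], k3$Sigma[2, 1])
  expect_error(pair_kernel(c(60, 0.15), c(80, 0.15), pr, g), "inside")
})

test_that("larvae_distribution handles degenerate kernels and symmetry", {
  g <- trait_grid(c(0, 10), c(0, 1), 5, 5)
  # point-mass parents with a vanishing kernel stay in the parent cell
  P <- matrix(0, 5, 5); P[3, 3] <- 1
  d <- larvae_distribution(P, reproduction_params(0, 0, 0, 0), g, eps_P = 0)
  expect_equal(d[3, 3], 1)
  expect_equal(sum(d), 1)
  # symmetric two-cell parents on a symmetric grid, rho = 0: the larvae
  # distribution is invariant under the cell-swap reflection
  P2 <- matrix(0, 5, 5); P2[2, 2] <- 0.5; P2[4, 4] <- 0.5
  d2 <- larvae_distribution(P2, reproduction_params(0.25, 1, 0.1, 0), g,
                            eps_P = 0)
  expect_equal(d2, d2[5:1, 5:1], tolerance = 1e-12)
  expect_equal(sum(d2), 1, tolerance = 1e-10)
})

test_that("larvae_distribution equals the exact double sum (oracle)", {
  set.seed(31)
  g <- trait_grid(c(70, 90), c(0.10, 0.20), 9, 7)
  pr <- reproduction_params(0.25, 3, 0.03, -0.7)
  P <- matrix(rexp(63), 9, 7); P <- P / sum(P)
  mine <- larvae_distribution(P, pr, g, eps_P = 0)
  orc <- oracle_larvae(P, pr, g)
  expect_lt(0.5 * sum(abs(mine - orc)), 1e-12)
  # genotype component too (includes degenerate same-cell kernels)
  mineG <- larvae_distribution(P, pr, g, eps_P = 0, component = "genotype")
  orcG <- oracle_larvae(P, pr, g, phenotype = FALSE)
  expect_lt(0.5 * sum(abs(mineG - orcG)), 1e-12)
})

test_that("pair pruning changes the mixture by at most eps_P * G", {
  set.seed(5)
  g <- trait_grid(c(10, 20), c(0.45, 0.65), 12, 12)
  pr <- reproduction_params(0.25, 1, 0.02, -0.7)
  P <- matrix(rexp(144)^3, 12, 12); P <- P / sum(P)
  exact <- larvae_distribution(P, pr, g, eps_P = 0)
  for (eps in c(1e-8, 1e-5)) {
    pruned <- larvae_distribution(P, pr, g, eps_P = eps)
    expect_lt(0.5 * sum(abs(exact - pruned)), eps * g$G + 1e-12)
  }
})

test_that("kernel caches reproduce uncached results and reject reuse", {
  g <- trait_grid(c(10, 20), c(0.45, 0.65), 8, 8)
  pr <- reproduction_params(0.25, 1, 0.02, -0.35)
  P <- initial_trait_distribution(g)
  cache <- mix_cache()
  d1 <- larvae_distribution(P, pr, g, cache = cache)
  d2 <- larvae_distribution(P, pr, g, cache = cache)  # cached templates
  d3 <- larvae_distribution(P, pr, g)                 # fresh cache
  expect_identical(d1, d2)
  expect_identical(d1, d3)
  pr2 <- reproduction_params(0.5, 1, 0.02, -0.35)
  expect_error(larvae_distribution(P, pr2, g, cache = cache), "cache")
})

test_that("spawn conserves u x pooled biomass and clears pools", {
  web <- tiny_web()
  st <- initial_state(web, default_initial_biomass(web))
  st <- integrate_growth_season(st, web)
  for (nm in names(web$species)) {
    tot <- sum(st$pools[[nm]])
    expect_gt(tot, 0)
  }
  pooled <- lapply(st$pools, sum)
  sp_state <- spawn(st, web)
  for (nm in names(web$species)) {
    u <- web$species[[nm]]$repro$u
    expect_lt(abs(sum(sp_state$larvae[[nm]]) - u * pooled[[nm]]),
              1e-12 * max(1, pooled[[nm]]))
    expect_equal(sum(sp_state$pools[[nm]]), 0)
  }
})

test_that("a stocked species bypasses reproduction at fixed input biomass", {
  stocked <- fish_species("trout", vbgm_params(83, 0.198, 1.7), ages = 0:3,
                          mature_from = 3, stocked = TRUE, stock_age = 2,
                          stock_biomass = 137.3)
  web <- toy_foodweb(grid_n = 3)
  # hand the stocked species the zooplankton food chain
  link <- data.frame(resource = c("zoo1", "zoo2"),
                     consumer = rep(paste0("trout_a", 0:3), each = 2),
                     w = 1, e = 0.85)
  web2 <- foodweb_config(
    producers = web$guilds[web$guilds$role == "producer",
                           c("id", "mass_mgC", "r", "group")],
    consumers = web$guilds[web$guilds$role == "consumer",
                           c("id", "mass_mgC", "x", "y", "fm", "group", "B0")],
    species = c(web$species, list(stocked)),
    links = rbind(web$links, link), globals = web$globals)
  st <- initial_state(web2, default_initial_biomass(web2))
  st <- integrate_growth_season(st, web2)
  st <- spawn(st, web2)
  expect_equal(sum(st$larvae$trout), 0)
  expect_equal(st$last_spawn$trout$status, "stocked")
  st <- age_guilds(st, web2)
  expect_equal(unname(st$cells$trout[1, "trout_a2"]), 137.3)
})

test_that("ageing shifts cohorts, accumulates the plus group, conserves mass", {
  web <- tiny_web()
  st <- initial_state(web, default_initial_biomass(web))
  # single cohort pulse in prey age 1
  st$cells$prey[] <- 0
  d0 <- initial_trait_distribution(web$species$prey$grid)
  st$cells$prey[, 2] <- 5 * as.vector(d0)
  st$larvae <- list(prey = numeric(25), pred = numeric(25))
  st1 <- age_guilds(st, web)
  expect_equal(st1$cells$prey[, 3], 5 * as.vector(d0))   # moved up, per cell
  expect_equal(sum(st1$cells$prey[, c(1, 2, 4, 5)]), 0)
  # plus group accumulates two successive cohorts
  st$cells$prey[] <- 0
  st$cells$prey[, 4] <- 3 * as.vector(d0)   # age 3
  st$cells$prey[, 5] <- 2 * as.vector(d0)   # age 4+ (plus group)
  st2 <- age_guilds(st, web)
  expect_equal(st2$cells$prey[, 5], 5 * as.vector(d0))
  # conservation excluding larvae
  web3 <- tiny_web()
  s <- initial_state(web3, default_initial_biomass(web3))
  s <- integrate_growth_season(s, web3)
  s <- spawn(s, web3)
  before <- vapply(s$cells, sum, 0)
  aged <- age_guilds(s, web3)
  after <- vapply(names(aged$cells), function(nm)
    sum(aged$cells[[nm]]) - sum(aged$cells[[nm]][, 1]), 0)
  expect_equal(unname(after), unname(before), tolerance = 1e-12)
  expect_error(age_guilds(initial_state(web3, default_initial_biomass(web3)),
                          web3), "spawn")
})

test_that("variance decomposition obeys the heritability laws", {
  g <- trait_grid(c(70, 90), c(0.10, 0.20), 8, 8)
  # Omega_A = 0: genotype and phenotype distributions coincide, H = 1
  P <- initial_trait_distribution(g)
  pr0 <- reproduction_params(0.25, 0, 0, -0.7)
  gv0 <- genotype_phenotype_variances(P, pr0, g, eps_P = 0)
  expect_equal(gv0$V_G, gv0$V_P)
  expect_equal(unname(heritability(gv0$V_G, gv0$V_P)), c(1, 1))
  # interior kernels with Omega_A > 0: V_P > V_G, H < 1
  pr1 <- reproduction_params(0.25, 1.0, 0.01, -0.7)
  gv1 <- genotype_phenotype_variances(P, pr1, g, eps_P = 0)
  expect_true(all(gv1$V_P >= gv1$V_G))
  expect_true(all(heritability(gv1$V_G, gv1$V_P) < 1))
  # moment oracle: variances agree with a brute-force loop over cell centres
  for (comp in c("dist_G", "dist_P")) {
    d <- gv1[[comp]]
    mL <- 0; vL <- 0
    for (i in 1:8) for (j in 1:8) mL <- mL + d[i, j] * g$centers_L[i]
    for (i in 1:8) for (j in 1:8)
      vL <- vL + d[i, j] * (g$centers_L[i] - mL)^2
    key <- if (comp == "dist_G") "V_G" else "V_P"
    expect_equal(unname(gv1[[key]]["L_inf"]), vL, tolerance = 1e-12)
  }
  # grid-corner construction: truncation shrinks the wide phenotype kernel
  # more than the bimodal genotype mixture, so H exceeds one
  Pc <- matrix(0, 8, 8); Pc[1, 1] <- 0.5; Pc[8, 8] <- 0.5
  prc <- reproduction_params(0.5, 20, 0.2, 0)
  gvc <- genotype_phenotype_variances(Pc, prc, g, eps_P = 0)
  expect_true(all(heritability(gvc$V_G, gvc$V_P) > 1))
  expect_error(heritability(c(L_inf = 1, k = 1), c(L_inf = 0, k = 1)),
               "undefined")
})
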