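# minimal diagnostic configurations ------------------------------------------

empty_links <- data.frame(resource = character(0), consumer = character(0),
                          w = numeric(0), e = numeric(0))

single_producer_web <- function(r = 0.5, K = 100)
  foodweb_config(
    producers = data.frame(id = "p", mass_mgC = 1e-7, r = r),
    consumers = data.frame(id = character(0), mass_mgC = numeric(0),
                           x = numeric(0), y = numeric(0), fm = numeric(0)),
    species = list(), links = empty_links,
    globals = list(K = K), check_connected = FALSE)

# an isolated fish species with constant length (k ~ 0 keeps L at L0 so
# within-season growth does not move it across the selectivity curve)
lone_fish_web <- function(ax = 0.1, fm = 0.1, ra = 0, gear = NULL,
                          mature_from = 2, vb = vbgm_params(100, 1e-9, 12))
  foodweb_config(
    producers = data.frame(id = "p", mass_mgC = 1e-7, r = 0.1),
    consumers = data.frame(id = character(0), mass_mgC = numeric(0),
                           x = numeric(0), y = numeric(0), fm = numeric(0)),
    species = list(fish_species("f", vb, ages = 0:2,
                                mature_from = mature_from, gear = gear,
                                ra = ra)),
    links = empty_links,
    globals = list(K = 100, ax_fish = ax, fm_fish = fm),
    check_connected = FALSE)

lone_fish_state <- function(web, b = c(p = 1, f_a0 = 10, f_a1 = 10, f_a2 = 10))
  initial_state(web, b)

test_that("a lone producer follows the closed-form logistic solution", {
  web <- single_producer_web(r = 0.5, K = 100)
  st <- initial_state(web, c(p = 5))
  expect_equal(producer_gain(web, "p", st), 0.5 * 5 * (1 - 5 / 100))
  # absorbing at zero and at capacity
  expect_equal(producer_gain(web, "p", initial_state(web, c(p = 0))), 0)
  expect_equal(producer_gain(web, "p", initial_state(web, c(p = 100))), 0)
  out <- integrate_growth_season(st, web, rtol = 1e-10, atol = 1e-12)
  closed <- 100 * 5 * exp(0.5 * 90) / (100 + 5 * (exp(0.5 * 90) - 1))
  expect_equal(unname(out$B["p"]), closed, tolerance = 1e-7)
})

test_that("consumption flux has the Hill functional-response shape", {
  web <- toy_foodweb(grid_n = 3)
  st <- initial_state(web, default_initial_biomass(web))
  # zero resource biomass -> zero flux
  st0 <- st; st0$B["prod1"] <- 0
  expect_equal(consumption_flux(web, "prod1", "zoo1", st0)$gain, 0)
  # saturation: a single huge resource drives the flux to x*y*B
  stS <- st
  stS$B["prod1"] <- 1e9; stS$B["prod2"] <- 0
  g1 <- consumption_flux(web, "prod1", "zoo1", stS)$gain
  i <- match("zoo1", web$guilds$id)
  xyB <- web$guilds$x[i] * web$guilds$y[i] * stS$B[["zoo1"]]
  expect_equal(g1, xyB, tolerance = 1e-3)
  # two identical resources at equal biomass and preference: equal fluxes
  stE <- st; stE$B["prod1"] <- stE$B["prod2"] <- 40
  f1 <- consumption_flux(web, "prod1", "zoo1", stE)
  f2 <- consumption_flux(web, "prod2", "zoo1", stE)
  expect_equal(f1$gain, f2$gain)
  # resource-side accounting: loss = gain / e
  expect_equal(f1$resource_loss, f1$gain / 0.45)
  expect_error(consumption_flux(web, "prey_a0", "zoo1", st), "link")
})

test_that("maintenance drives exponential decay of a starving fish guild", {
  web <- lone_fish_web(ax = 0.1, fm = 0.2)
  st <- lone_fish_state(web)
  i <- match("f_a1", web$guilds$id)
  fmx <- web$guilds$fm[i] * web$guilds$x[i]
  expect_equal(maintenance_loss(web, "f_a1", st), fmx * 10)
  out <- integrate_growth_season(st, web, rtol = 1e-10, atol = 1e-12)
  for (a in 0:2) {
    j <- match(paste0("f_a", a), web$guilds$id)
    expect_equal(sum(out$cells$f[, a + 1]),
                 10 * exp(-web$guilds$fm[j] * web$guilds$x[j] * 90),
                 tolerance = 1e-7)
  }
  # fm = 0: no maintenance loss
  web0 <- lone_fish_web(fm = 0)
  expect_equal(maintenance_loss(web0, "f_a1", lone_fish_state(web0)), 0)
  expect_error(maintenance_loss(web, "p", st), "guild")
})

test_that("fishing at the gear mode yields exp(-E) season survival", {
  gear <- selectivity_curve(12, 3)   # fish length is pinned at ~12 cm
  web <- lone_fish_web(ax = 0, fm = 0, gear = gear)   # all other dynamics off
  st <- lone_fish_state(web)
  # E = 0: no loss
  expect_equal(unname(fishing_loss(web, "f", 1, st, day = 0, E = 0)), 0)
  out0 <- integrate_growth_season(st, web, E = 0)
  out1 <- integrate_growth_season(st, web, E = 1)
  expect_equal(unname(colSums(out0$cells$f)), rep(10, 3))
  expect_equal(unname(colSums(out1$cells$f)), rep(10 * exp(-1), 3),
               tolerance = 1e-6)
  # far tail: fishing loss is negligible, season matches the unfished run
  webT <- lone_fish_web(ax = 0, fm = 0, gear = selectivity_curve(80, 2))
  outT <- integrate_growth_season(lone_fish_state(webT), webT, E = 1)
  expect_equal(colSums(outT$cells$f), colSums(out0$cells$f), tolerance = 1e-9)
  webNG <- lone_fish_web()
  expect_error(fishing_loss(webNG, "f", 1, lone_fish_state(webNG), E = 1),
               "gear")
})

test_that("reproduction allocation debits biomass and credits pools", {
  web <- lone_fish_web(ax = 0, fm = 0, ra = 0.01, mature_from = 1)
  st <- lone_fish_state(web)
  expect_equal(reproduction_allocation(web, "f", 1, st), st$cells$f[, 2] * 0.01)
  expect_error(reproduction_allocation(web, "f", 0, st), "immature")
  out <- integrate_growth_season(st, web)
  # allocation conserves cells + pools against this term
  expect_equal(sum(out$cells$f[, 2]) + sum(out$pools$f[, 2]), 10,
               tolerance = 1e-7)
  expect_equal(sum(out$cells$f[, 2]), 10 * exp(-0.01 * 90), tolerance = 1e-7)
  # with fishing on, pools deplete proportionally to B+/B
  gear <- selectivity_curve(12, 3)
  webF <- lone_fish_web(ax = 0, fm = 0, ra = 0.01, mature_from = 1,
                        gear = gear)
  outF <- integrate_growth_season(lone_fish_state(webF), webF, E = 1)
  # two-compartment closed form: dB = -(ra+f)B, dP = ra*B - f*P with
  # f = E/t_end constant at the mode
  f <- 1 / 90; ra <- 0.01; t <- 90
  B_cl <- 10 * exp(-(ra + f) * t)
  P_cl <- 10 * ra / ((ra + f) - f) * (exp(-f * t) - exp(-(ra + f) * t))
  expect_equal(sum(outF$cells$f[, 2]), B_cl, tolerance = 1e-5)
  expect_equal(sum(outF$pools$f[, 2]), P_cl, tolerance = 1e-4)
  # ra = 0: no allocation anywhere
  web0 <- lone_fish_web(ax = 0, fm = 0, ra = 0, mature_from = 1)
  out0 <- integrate_growth_season(lone_fish_state(web0), web0)
  expect_equal(sum(out0$pools$f), 0)
})

test_that("the assembled rhs balances a double-entry term audit", {
  web <- toy_foodweb(grid_n = 3)
  st <- initial_state(web, default_initial_biomass(web))
  E <- 1.5
  d <- foodweb_rhs(st, web, E = E, day = 0)
  lk <- web$links
  for (gid in web$guilds$id) {
    role <- web$guilds$role[web$guilds$id == gid]
    gains <- sum(vapply(lk$resource[lk$consumer == gid], function(r)
      consumption_flux(web, r, gid, st)$gain, 0))
    consumed <- sum(vapply(lk$consumer[lk$resource == gid], function(cns)
      consumption_flux(web, gid, cns, st)$resource_loss, 0))
    if (role == "producer") {
      expect_equal(unname(d$B[gid]), producer_gain(web, gid, st) - consumed,
                   tolerance = 1e-10, label = gid)
    } else if (role == "consumer") {
      expect_equal(unname(d$B[gid]),
                   gains - maintenance_loss(web, gid, st) - consumed,
                   tolerance = 1e-10, label = gid)
    } else {
      sp <- web$species[[web$guilds$species[web$guilds$id == gid]]]
      age <- web$guilds$age[web$guilds$id == gid]
      fl <- sum(fishing_loss(web, sp$name, age, st, day = 0, E = E))
      rp <- if (age >= sp$mature_from)
        sum(reproduction_allocation(web, sp$name, age, st)) else 0
      expect_equal(sum(d$cells[[sp$name]][, age + 1]),
                   gains - maintenance_loss(web, gid, st) - consumed - fl - rp,
                   tolerance = 1e-9, label = gid)
    }
  }
  # all-zero biomass is a fixed point
  z <- st
  z$B[] <- 0
  for (nm in names(z$cells)) { z$cells[[nm]][] <- 0; z$pools[[nm]][] <- 0 }
  dz <- foodweb_rhs(z, web)
  expect_equal(max(abs(dz$B)), 0)
  expect_equal(max(abs(dz$cells$prey)), 0)
})

test_that("unfished mass balance: growth minus unassimilated minus maintenance", {
  web <- toy_foodweb(grid_n = 3)
  st <- initial_state(web, default_initial_biomass(web))
  d <- foodweb_rhs(st, web, E = 0)
  total_change <- sum(d$B) + sum(vapply(d$cells, sum, 0)) +
    sum(vapply(d$pools, sum, 0))
  growth <- sum(vapply(web$guilds$id[web$guilds$role == "producer"],
                       function(g) producer_gain(web, g, st), 0))
  lk <- web$links
  unassim <- sum(vapply(seq_len(nrow(lk)), function(i) {
    fl <- consumption_flux(web, lk$resource[i], lk$consumer[i], st)
    fl$resource_loss - fl$gain
  }, 0))
  maint <- sum(vapply(web$guilds$id[web$guilds$role != "producer"],
                      function(g) maintenance_loss(web, g, st), 0))
  expect_equal(total_change, growth - unassim - maint, tolerance = 1e-8)
})

test_that("season integration is tolerance-convergent and non-negative", {
  web <- toy_foodweb(grid_n = 5)
  st <- initial_state(web, default_initial_biomass(web))
  a <- integrate_growth_season(st, web, rtol = 1e-6, atol = 1e-8)
  b <- integrate_growth_season(st, web, rtol = 5e-7, atol = 5e-9)
  ga <- guild_biomass(a, web); gb <- guild_biomass(b, web)
  expect_lt(max(abs(ga - gb) / pmax(gb, 1e-6)), 1e-3)
  expect_true(all(ga >= 0))
  # t_end = 0 is the identity
  web0 <- toy_foodweb(grid_n = 3)
  web0$globals$t_end <- 0
  attr(web0, "engine_env") <- new.env(parent = emptyenv())
  st0 <- initial_state(web0, default_initial_biomass(web0))
  expect_identical(integrate_growth_season(st0, web0), st0)
  # E = 0 is invariant to the presence of gear configuration
  webNG <- toy_foodweb(grid_n = 5)
  webNG$species$prey$gear <- NULL
  webNG$species$pred$gear <- NULL
  attr(webNG, "engine_env") <- new.env(parent = emptyenv())
  c2 <- integrate_growth_season(initial_state(webNG,
                                              default_initial_biomass(webNG)),
                                webNG, E = 0)
  expect_equal(guild_biomass(c2, webNG), ga, tolerance = 1e-12)
})

test_that("off-season decay applies half-rate maintenance to fish only", {
  web <- lone_fish_web(ax = 0.1, fm = 0.1)
  # engineered so fm * x = 2/275 per day: multiplier is exactly exp(-1)
  web$guilds$x[web$guilds$role == "fish"] <- (2 / 275) / 0.1
  st <- lone_fish_state(web)
  out <- off_season_step(st, web)
  expect_equal(unname(colSums(out$cells$f)), rep(10 * exp(-1), 3),
               tolerance = 1e-12)
  expect_equal(out$B[["p"]], st$B[["p"]])          # non-fish unchanged
  expect_equal(out$year, st$year + 1L)
  # fm = 0: identity on fish biomass
  web0 <- lone_fish_web(fm = 0)
  out0 <- off_season_step(lone_fish_state(web0), web0)
  expect_equal(colSums(out0$cells$f), c(f_a0 = 10, f_a1 = 10, f_a2 = 10))
})

test_that("within-season length accrues one growth-year over the season", {
  p <- vbgm_params(16, 0.555, 0.9)
  expect_equal(fish_length_at(16, 0.555, 0.9, age = 2, day = 0),
               vbgm_length(p, 2))
  expect_equal(fish_length_at(16, 0.555, 0.9, age = 2, day = 90),
               vbgm_length(p, 3))
  L <- sapply(seq(0, 90, 5), function(d) fish_length_at(16, 0.555, 0.9, 2, d))
  expect_true(all(diff(L) > 0))
  expect_error(fish_length_at(16, 0.555, 0.9, 2, day = 91), "day")
})

test_that("length-to-carbon-mass conversion multiplies through", {
  lw <- c(a = 0.01, b = 3, dry = 0.2, carbon = 0.4)
  expect_equal(length_to_carbon_mass(2, lw) / length_to_carbon_mass(1, lw), 8)
  # chain of conversions by hand: 0.01*10^3 g * 0.2 * 0.4 * 1000 mg
  expect_equal(length_to_carbon_mass(10, lw), 0.01 * 1000 * 0.2 * 0.4 * 1000)
  L <- seq(1, 90, 1)
  expect_true(all(diff(length_to_carbon_mass(L, lw)) > 0))
  expect_error(length_to_carbon_mass(0), "L")
  expect_error(length_to_carbon_mass(5, c(a = -1, b = 3, dry = 0.2,
                                          carbon = 0.4)), "positive")
})
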