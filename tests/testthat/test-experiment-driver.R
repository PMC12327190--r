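# a fast scenario on the 5x5-grid toy web
fast_sc <- function(burn = 4, fish = 0, E = 1, H = FALSE)
  scenario_config(burn_in_years = burn, fishing_years = fish, E = E,
                  record_heritability = H)

test_that("runs are deterministic and zero fishing years equal pure burn-in", {
  web <- tiny_web()
  r1 <- run_scenario(web, fast_sc(4, 0))
  r2 <- run_scenario(web, fast_sc(4, 0))
  expect_identical(r1$biomass, r2$biomass)           # bit-identical repeat
  expect_identical(r1$traits, r2$traits)
  # E = 0 "fishing" phase continues the burn-in exactly
  r3 <- run_scenario(web, fast_sc(2, 2, E = 0))
  expect_equal(r3$biomass, r1$biomass, tolerance = 1e-12)
  expect_equal(r3$traits$mean_L_inf, r1$traits$mean_L_inf, tolerance = 1e-12)
  expect_equal(r1$status, "completed")
  expect_match(r1$manifest$config_hash, "^[0-9a-f]+$")
})

test_that("fishing with the trawl shifts the prey trait distribution", {
  web <- tiny_web()
  base <- run_scenario(web, fast_sc(6, 0))
  web9 <- web
  web9$species$prey$gear <- selectivity_curve(16.5, 2.0)  # above mean length
  web9$species$pred$gear <- NULL
  attr(web9, "engine_env") <- new.env(parent = emptyenv())
  fished <- run_scenario(web9, fast_sc(0, 6, E = 2), state = base$final_state)
  ctrl <- run_scenario(web, fast_sc(6, 0), state = base$final_state)
  mfin <- function(r) {
    d <- r$traits[r$traits$species == "prey", ]
    d$mean_L_inf[which.max(d$year)]
  }
  expect_lt(mfin(fished), mfin(ctrl))
})

test_that("heritability recording adds the variance columns", {
  web <- tiny_web()
  r <- run_scenario(web, fast_sc(3, 0, H = TRUE))
  expect_true(all(c("V_G_L_inf", "V_P_L_inf", "H_L_inf", "H_k") %in%
                    names(r$traits)))
  expect_true(all(r$traits$V_P_L_inf >= r$traits$V_G_L_inf - 1e-12))
  expect_true(all(r$traits$H_L_inf > 0))
})

test_that("sensitivity suite enumerates combinations reproducibly", {
  web <- tiny_web()
  lv <- list(E = c(0.5, 1), cV = c(0.125, 0.25),
             sigma_L_inf = c(0.5, 1), sigma_k = c(0.01, 0.02))
  sc <- scenario_config(burn_in_years = 1, fishing_years = 1, E = 1,
                        record_heritability = FALSE)
  out <- sensitivity_suite(web, "prey", levels = lv, rho_levels = -0.7,
                           scenario = sc)
  expect_equal(nrow(out), 16)                       # 2^4 in test mode
  expect_equal(anyDuplicated(out[, c("combo", "rho")]), 0)
  expect_true(all(out$status == "completed"))
  # shuffled execution order gives identical outputs (order independence)
  set.seed(1)
  out2 <- sensitivity_suite(web, "prey", levels = lv, rho_levels = -0.7,
                            scenario = sc, order = sample(16))
  expect_equal(out, out2)
  # full mode enumerates 3^4 = 81 combinations per rho (not run here)
  combos <- expand.grid(E = c(0.5, 1, 2), cV = c(0.125, 0.25, 0.5),
                        s1 = c(0.5, 1, 2), s2 = c(0.01, 0.02, 0.04))
  expect_equal(nrow(combos), 81)
})

test_that("sensitivity suite resumes from written results", {
  web <- tiny_web()
  lv <- list(E = c(0.5, 1), cV = c(0.25, 0.5),
             sigma_L_inf = c(0.5, 1), sigma_k = c(0.01, 0.02))
  sc <- scenario_config(1, 1, record_heritability = FALSE)
  dir <- tempfile("suite")
  out1 <- sensitivity_suite(web, "prey", levels = lv, rho_levels = 0,
                            scenario = sc, out_dir = dir)
  files <- list.files(dir)
  expect_equal(length(files), 16)
  # drop half the files: only the missing runs are recomputed, results equal
  unlink(file.path(dir, files[1:8]))
  out2 <- sensitivity_suite(web, "prey", levels = lv, rho_levels = 0,
                            scenario = sc, out_dir = dir)
  expect_equal(out1$mean_L_inf_final, out2$mean_L_inf_final)
  unlink(dir, recursive = TRUE)
})

test_that("relative biomass change reports group aggregates", {
  web <- tiny_web()
  r <- run_scenario(web, fast_sc(4, 0))
  groups <- foodweb_groups(web)
  # identical runs: zero change everywhere
  z <- relative_biomass_change(r, r, groups, window = 3)
  expect_equal(z$change_pct, rep(0, nrow(z)))
  expect_true(all(z$defined))
  # plain arithmetic: reference 200, fished 150 -> -25%
  mk <- function(b) data.frame(year = rep(1:3, each = 1), guild = "g",
                               biomass = b)
  out <- relative_biomass_change(mk(c(150, 150, 150)), mk(c(200, 200, 200)),
                                 groups = list(all = "g"), window = 3)
  expect_equal(out$change_pct, -25)
  # group assignment covers the reporting partition
  expect_setequal(names(groups),
                  c("phytoplankton", "zooplankton", "prey", "pred"))
  expect_setequal(unlist(groups, use.names = FALSE), web$guilds$id)
  # zero reference flagged undefined
  out0 <- relative_biomass_change(mk(c(1, 1, 1)), mk(c(0, 0, 0)),
                                  groups = list(all = "g"), window = 3)
  expect_false(out0$defined)
  expect_true(is.na(out0$change_pct))
})

test_that("equilibrium_check computes CV and trend", {
  b <- data.frame(year = rep(1:10, 2),
                  guild = rep(c("flat", "ramp"), each = 10),
                  biomass = c(rep(5, 10), 1:10))
  ec <- equilibrium_check(b, window = 10, cv_threshold = 0.05)
  flat <- ec[ec$guild == "flat", ]; ramp <- ec[ec$guild == "ramp", ]
  expect_equal(flat$cv, 0); expect_equal(flat$slope, 0)
  expect_true(flat$pass)
  expect_equal(ramp$slope, 1)                        # the ramp coefficient
  expect_false(ramp$pass)
  expect_error(equilibrium_check(b, window = 11), "window")
})

test_that("extinction terminates a run with a labelled status", {
  web <- tiny_web()
  st <- initial_state(web, default_initial_biomass(web))
  st$cells$prey[] <- 0      # prey absent from the start
  r <- run_scenario(web, fast_sc(3, 0), state = st)
  expect_match(r$status, "^extinct:prey")
  expect_lte(max(r$biomass$year), 3)                 # partial outputs kept
})
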