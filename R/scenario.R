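#' Scenario configuration
#'
#' @param burn_in_years unfished years to reach dynamic equilibrium
#'   (default 100).
#' @param fishing_years fished years following burn-in (default 100).
#' @param E peak instantaneous fishing mortality, 1/year, shared by all
#'   fished species within a scenario (study levels 0.5, 1.0, 2.0).
#' @param eps_P inheritance-kernel pair-pruning threshold.
#' @param seed integer seed, recorded in the run manifest (the annual cycle
#'   itself is deterministic).
#' @param rtol,atol season-integrator tolerances.
#' @param record_heritability track V_G, V_P and H of each spawn.
#' @param record_dist_years years at which full trait distributions are
#'   stored (e.g. `c(100, 200)`); `"final"` stores the last year only.
#' @param terminal_window years used for equilibrium averaging in reports.
#' @export
scenario_config <- function(burn_in_years = 100, fishing_years = 100, E = 1.0,
                            eps_P = 1e-8, seed = 1, rtol = 1e-6, atol = 1e-8,
                            record_heritability = TRUE,
                            record_dist_years = "final",
                            terminal_window = 20) {
  stopifnot(burn_in_years >= 0, fishing_years >= 0,
            burn_in_years + fishing_years >= 1, E >= 0)
  structure(list(burn_in_years = burn_in_years, fishing_years = fishing_years,
                 E = E, eps_P = eps_P, seed = as.integer(seed), rtol = rtol,
                 atol = atol, record_heritability = record_heritability,
                 record_dist_years = record_dist_years,
                 terminal_window = terminal_window),
            class = "scenario_config")
}

# polynomial rolling hash of a serialized object, for run manifests
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one burn-in / fishing scenario
#'
#' Executes the annual cycle (growth-season ODE, spawn, ageing, off-season)
#' for `burn_in_years` unfished years followed by `fishing_years` years with
#' fishing mortality `E` on the geared species. The run is deterministic
#' given the configuration and tolerances. If a focal species goes extinct
#' the run terminates with a labelled status and partial outputs are kept.
#'
#' @param web a [foodweb_config()].
#' @param scenario a [scenario_config()].
#' @param state optional initial `system_state` (default:
#'   [default_initial_biomass()] with the default initial trait
#'   distributions); passing the end state of a previous run continues it.
#' @return list of class `atne_run`: `biomass` (data.frame year x guild),
#'   `traits` (annual oldest-guild trait moments and larvae V_G/V_P/H per
#'   evolving species), `dists` (stored trait distributions), `final_state`,
#'   `status` (`"completed"` or `"extinct:<species>"`), and `manifest`.
#' @export
run_scenario <- function(web, scenario = scenario_config(), state = NULL) {
  stopifnot(inherits(web, "foodweb_config"),
            inherits(scenario, "scenario_config"))
  if (is.null(state))
    state <- initial_state(web, default_initial_biomass(web))
  caches <- lapply(web$species, function(sp)
    if (sp$evolving) list(phenotype = mix_cache(), genotype = mix_cache()))
  years_total <- scenario$burn_in_years + scenario$fishing_years
  ev_sp <- names(web$species)[vapply(web$species, `[[`, TRUE, "evolving")]
  biomass <- vector("list", years_total)
  traits <- vector("list", years_total)
  dists <- list()
  rec_years <- if (identical(scenario$record_dist_years, "final"))
    years_total else scenario$record_dist_years
  status <- "completed"
  for (yr in seq_len(years_total)) {
    E_y <- if (yr > scenario$burn_in_years) scenario$E else 0
    state <- integrate_growth_season(state, web, E = E_y,
                                     rtol = scenario$rtol,
                                     atol = scenario$atol)
    tot <- guild_biomass(state, web)
    biomass[[yr]] <- data.frame(year = yr, guild = names(tot),
                                biomass = unname(tot), row.names = NULL)
    tr <- lapply(ev_sp, function(nm) {
      sp <- web$species[[nm]]
      oldest <- state$cells[[nm]][, ncol(state$cells[[nm]])]
      if (sum(oldest) > 0) {
        d <- matrix(oldest / sum(oldest), sp$grid$n_L, sp$grid$n_k)
        mo <- trait_moments(d, sp$grid)
      } else mo <- list(mean = c(L_inf = NA, k = NA), var = c(L_inf = NA, k = NA))
      data.frame(year = yr, species = nm,
                 mean_L_inf = mo$mean[["L_inf"]], mean_k = mo$mean[["k"]],
                 var_L_inf = mo$var[["L_inf"]], var_k = mo$var[["k"]])
    })
    if (any(tot[!is.na(web$guilds$species) &
               web$guilds$species %in% ev_sp] < 0)) stop("negative biomass")
    extinct <- ev_sp[vapply(ev_sp, function(nm)
      sum(state$cells[[nm]]) <= 0, TRUE)]
    if (length(extinct)) {
      status <- paste0("extinct:", paste(extinct, collapse = ","))
      traits[[yr]] <- do.call(rbind, tr)
      break
    }
    state <- spawn(state, web, eps_P = scenario$eps_P, caches = caches,
                   record_variance = scenario$record_heritability)
    tr <- Map(function(df, nm) {
      info <- state$last_spawn[[nm]]
      if (scenario$record_heritability && !is.null(info$H)) {
        df$V_G_L_inf <- info$V_G[["L_inf"]]; df$V_G_k <- info$V_G[["k"]]
        df$V_P_L_inf <- info$V_P[["L_inf"]]; df$V_P_k <- info$V_P[["k"]]
        df$H_L_inf <- info$H[["L_inf"]]; df$H_k <- info$H[["k"]]
      }
      df
    }, tr, ev_sp)
    traits[[yr]] <- do.call(rbind, tr)
    if (yr %in% rec_years)
      dists[[as.character(yr)]] <- lapply(
        stats::setNames(ev_sp, ev_sp),
        function(nm) state$last_spawn[[nm]]$larvae_dist)
    state <- age_guilds(state, web)
    state <- off_season_step(state, web)
  }
  structure(list(
    biomass = do.call(rbind, biomass[!vapply(biomass, is.null, TRUE)]),
    traits = do.call(rbind, traits[!vapply(traits, is.null, TRUE)]),
    dists = dists, final_state = state, status = status,
    scenario = scenario,
    manifest = list(config_hash = config_hash(list(web, scenario)),
                    seed = scenario$seed,
                    package_version = as.character(utils::packageVersion("atne")))),
    class = "atne_run")
}

#' @export
print.atne_run <- function(x, ...) {
  cat(sprintf("ATNE run: %d years, status %s (config %s)\n",
              max(x$biomass$year), x$status, x$manifest$config_hash))
  invisible(x)
}

#' Table-4 sensitivity levels
#'
#' The low/medium/high parameter levels of the sensitivity analysis:
#' shared fishing mortality E and genotypic-variance control cV, plus the
#' species-specific phenotypic SDs.
#'
#' @param species `"pikeperch"` (piscivore) or `"vendace"` (planktivore).
#' @return named list of length-3 sorted level vectors for `E`, `cV`,
#'   `sigma_L_inf`, `sigma_k`.
#' @export
sensitivity_levels <- function(species = c("pikeperch", "vendace")) {
  species <- match.arg(species)
  common <- list(E = c(0.5, 1.0, 2.0), cV = c(0.125, 0.25, 0.5))
  c(common, switch(species,
    pikeperch = list(sigma_L_inf = c(1.5, 3.0, 6.0),
                     sigma_k = c(0.015, 0.030, 0.060)),
    vendace   = list(sigma_L_inf = c(0.5, 1.0, 2.0),
                     sigma_k = c(0.01, 0.02, 0.04))))
}

# replace one species' reproduction kernel (resets nothing the season
# engine depends on, so the memoised engine stays valid)
set_species_repro <- function(web, species, repro) {
  web$species[[species]]$repro <- repro
  web
}

#' Run the sensitivity suite
#'
#' Enumerates all combinations of the varied species' (E, cV, sigma_L_inf,
#' sigma_k) levels — 3^4 = 81 in full mode, 2^4 = 16 with two levels per
#' parameter — at each correlation level, holding the other species at its
#' medium values. E is shared by both fished species. Runs are tagged with
#' their combination, seeded deterministically from the master seed and the
#' combination index (so execution order does not matter), and optionally
#' written to `out_dir` so an interrupted suite resumes by skipping
#' completed runs. A failing run is recorded with its error message and the
#' suite continues.
#'
#' @param web a [foodweb_config()] with two evolving species.
#' @param species name of the species whose parameters are varied.
#' @param levels named list of level vectors (`E`, `cV`, `sigma_L_inf`,
#'   `sigma_k`), e.g. [sensitivity_levels()]; medium = the middle (or for
#'   even lengths, `ceiling(n/2)`-th) sorted level.
#' @param rho_levels correlation levels (default the three study levels).
#' @param scenario base [scenario_config()]; E is overridden per run.
#' @param other_medium named list of the non-varied species' medium
#'   parameters (default [sensitivity_levels()] mediums for its matching
#'   defaults).
#' @param out_dir optional directory for per-run CSV results (resumable).
#' @param order optional permutation of the run index for execution order
#'   (results are identical for any order).
#' @return data.frame, one row per (combination, rho): the levels, seed,
#'   status and final-year summary metrics.
#' @export
sensitivity_suite <- function(web, species, levels = NULL,
                              rho_levels = c(0, -0.35, -0.7),
                              scenario = scenario_config(),
                              other_medium = NULL, out_dir = NULL,
                              order = NULL) {
  ev <- names(web$species)[vapply(web$species, `[[`, TRUE, "evolving")]
  stopifnot(species %in% ev)
  other <- setdiff(ev, species)
  if (is.null(levels))
    levels <- sensitivity_levels(
      if (web$species[[species]]$grid$L_inf_bounds[2] > 50) "pikeperch"
      else "vendace")
  for (l in levels) stopifnot(length(l) >= 2, !is.unsorted(l))
  med <- function(v) v[ceiling(length(v) / 2)]
  combos <- expand.grid(E = levels$E, cV = levels$cV,
                        sigma_L_inf = levels$sigma_L_inf,
                        sigma_k = levels$sigma_k,
                        KEEP.OUT.ATTRS = FALSE)
  grid_rows <- expand.grid(combo = seq_len(nrow(combos)),
                           rho = rho_levels, KEEP.OUT.ATTRS = FALSE)
  if (is.null(order)) order <- seq_len(nrow(grid_rows))
  stopifnot(sort(order) == seq_len(nrow(grid_rows)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- vector("list", nrow(grid_rows))
  for (idx in order) {
    ci <- grid_rows$combo[idx]; rho <- grid_rows$rho[idx]
    cmb <- combos[ci, ]
    run_seed <- scenario$seed + 131L * ci +
      17L * match(rho, rho_levels)
    tag <- sprintf("%s_rho%+.2f_c%03d", species, rho, ci)
    f <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
    if (!is.null(f) && file.exists(f)) {
      results[[idx]] <- utils::read.csv(f)
      next
    }
    u_sp <- web$species[[species]]$repro$u
    w <- set_species_repro(web, species,
      reproduction_params(cmb$cV, cmb$sigma_L_inf, cmb$sigma_k, rho, u_sp))
    if (length(other)) {
      om <- other_medium
      if (is.null(om)) {
        lv <- sensitivity_levels(
          if (web$species[[other]]$grid$L_inf_bounds[2] > 50) "pikeperch"
          else "vendace")
        om <- lapply(lv, med)
      }
      w <- set_species_repro(w, other,
        reproduction_params(om$cV, om$sigma_L_inf, om$sigma_k, rho,
                            web$species[[other]]$repro$u))
    }
    sc <- scenario
    sc$E <- cmb$E
    sc$seed <- run_seed
    row <- data.frame(species_varied = species, combo = ci, rho = rho,
                      E = cmb$E, cV = cmb$cV,
                      sigma_L_inf = cmb$sigma_L_inf, sigma_k = cmb$sigma_k,
                      seed = run_seed, status = NA_character_,
                      mean_L_inf_final = NA_real_, mean_k_final = NA_real_,
                      H_L_inf_final = NA_real_, H_k_final = NA_real_,
                      biomass_final = NA_real_)
    res <- tryCatch(run_scenario(w, sc), error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- paste0("error:", conditionMessage(res))
    } else {
      row$status <- res$status
      tf <- res$traits[res$traits$species == species, ]
      tf <- tf[tf$year == max(tf$year), ]
      if (nrow(tf)) {
        row$mean_L_inf_final <- tf$mean_L_inf
        row$mean_k_final <- tf$mean_k
        if (!is.null(tf$H_L_inf)) {
          row$H_L_inf_final <- tf$H_L_inf
          row$H_k_final <- tf$H_k
        }
      }
      bf <- res$biomass[res$biomass$year == max(res$biomass$year), ]
      ids <- fish_guild_ids(web$species[[species]])
      row$biomass_final <- sum(bf$biomass[bf$guild %in% ids])
    }
    if (!is.null(f)) utils::write.csv(row, f, row.names = FALSE)
    results[[idx]] <- row
  }
  out <- do.call(rbind, results)
  out[order(out$rho, out$combo), , drop = FALSE]
}

#' Reporting groups of a food web
#'
#' @param config a [foodweb_config()].
#' @return named list mapping each reporting group label (from the guild
#'   table's `group` column) to its guild ids.
#' @export
foodweb_groups <- function(config)
  split(config$guilds$id, config$guilds$group)

#' Relative biomass change against an unfished reference
#'
#' Compares equilibrium biomasses between a fished run and an unfished
#' reference: per aggregate group, 100 * (mean fished - mean reference) /
#' mean reference, with means taken over the terminal `window` years of each
#' run.
#'
#' @param run,reference `atne_run` objects (or their `$biomass` tables).
#' @param groups named list mapping group labels to guild-id vectors; by
#'   default the configuration's reporting groups via [foodweb_groups()]
#'   must be supplied explicitly.
#' @param window terminal averaging window, years.
#' @return data.frame with columns `group`, `reference`, `fished`,
#'   `change_pct`, `defined` (FALSE where the reference biomass is zero).
#' @export
relative_biomass_change <- function(run, reference, groups, window = 20) {
  btab <- function(r) if (inherits(r, "atne_run")) r$biomass else r
  term_mean <- function(b) {
    yrs <- sort(unique(b$year))
    if (window > length(yrs)) stop("terminal window longer than the run")
    keep <- b$year %in% utils::tail(yrs, window)
    tapply(b$biomass[keep], b$guild[keep], mean)
  }
  mf <- term_mean(btab(run)); mr <- term_mean(btab(reference))
  rows <- lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], names(mr))
    r <- sum(mr[ids]); f <- sum(mf[ids])
    data.frame(group = g, reference = r, fished = f,
               change_pct = if (r > 0) 100 * (f - r) / r else NA_real_,
               defined = r > 0)
  })
  do.call(rbind, rows)
}

#' Stationarity diagnostic over a terminal window
#'
#' Per guild, the coefficient of variation and the linear-trend slope of
#' biomass over the last `window` years, with pass/fail against the
#' thresholds. A guild extinct throughout the window counts as stationary.
#'
#' @param run an `atne_run` (or its `$biomass` table).
#' @param window window length, years (must not exceed the series).
#' @param cv_threshold maximum coefficient of variation to pass.
#' @param slope_threshold maximum |slope| / mean (per year) to pass;
#'   default `Inf` bases the verdict on CV only.
#' @return data.frame with `guild`, `mean`, `cv`, `slope`, `pass`.
#' @export
equilibrium_check <- function(run, window = 20, cv_threshold = 0.05,
                              slope_threshold = Inf) {
  b <- if (inherits(run, "atne_run")) run$biomass else run
  yrs <- sort(unique(b$year))
  if (window > length(yrs)) stop("window longer than the series")
  keep <- b$year %in% utils::tail(yrs, window)
  bb <- b[keep, ]
  rows <- lapply(split(bb, bb$guild), function(d) {
    m <- mean(d$biomass)
    cv <- if (m > 0) stats::sd(d$biomass) / m else 0
    slope <- if (length(unique(d$year)) > 1)
      unname(stats::coef(stats::lm(biomass ~ year, data = d))[2]) else 0
    rel_slope <- if (m > 0) abs(slope) / m else 0
    data.frame(guild = d$guild[1], mean = m, cv = cv, slope = slope,
               pass = cv <= cv_threshold && rel_slope <= slope_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
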