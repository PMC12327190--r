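#' Generate synthetic length-at-age records
#'
#' Draws lengths from the lognormal observation model of the Bayesian VBGM:
#' at fractional age \eqn{a_t}, \eqn{L_t \sim \mathrm{Lognormal}(\mu_t,
#' \sigma)} with \eqn{\mu_t = \ln E[L_t] - \sigma^2/2}, so the sample mean at
#' each age converges to the VBGM expectation [vbgm_length()] and the median
#' to \eqn{\exp(\mu_t)}.
#'
#' Default ages are drawn uniformly from the quarter-year grid
#' `{0.25, 0.5, ..., age_max}` plus a uniform within-quarter jitter, giving
#' broad age coverage for parameter-recovery experiments.
#'
#' @param truth a [vbgm_params()] object (the generating truth).
#' @param sigma lognormal shape, > 0.
#' @param n number of records, >= 1.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param ages optional fixed vector of fractional ages (recycled to `n`),
#'   replacing the default age sampler.
#' @param age_max upper end of the default age grid, years.
#' @return data.frame with columns `fractional_age`, `length_cm`.
#' @export
gen_length_at_age <- function(truth, sigma, n, seed = 1, ages = NULL,
                              age_max = 12) {
  stopifnot(inherits(truth, "vbgm_params"), n >= 1)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  set.seed(as.integer(seed))
  if (is.null(ages)) {
    grid <- seq(0.25, age_max, by = 0.25)
    ages <- sample(grid, n, replace = TRUE) + stats::runif(n, 0, 0.25)
  } else {
    ages <- rep_len(ages, n)
  }
  if (any(ages < 0)) stop("ages must be >= 0")
  mu <- log(vbgm_length(truth, ages)) - sigma^2 / 2
  data.frame(fractional_age = ages,
             length_cm = stats::rlnorm(n, meanlog = mu, sdlog = sigma))
}

#' Generate synthetic catch-by-length-class records
#'
#' Evaluates a selectivity curve at the 1-cm class midpoints and adds
#' Gaussian noise (the matched generator for a least-squares selectivity
#' fit), clipping at zero.
#'
#' @param truth a [selectivity_curve()] (the generating truth).
#' @param classes integer vector of class lower edges, cm (class `c` covers
#'   `[c, c + 1)`); must be non-empty.
#' @param noise_sd Gaussian noise SD on class biomass, >= 0.
#' @param seed integer seed.
#' @return data.frame with columns `class_lower_cm`, `biomass_g`.
#' @export
gen_catch_by_length <- function(truth, classes, noise_sd = 0, seed = 1) {
  stopifnot(inherits(truth, "selectivity_curve"), noise_sd >= 0)
  if (length(classes) == 0) stop("class list must be non-empty")
  set.seed(as.integer(seed))
  mids <- classes + 0.5
  b <- selectivity_eval(truth, mids)
  if (noise_sd > 0) b <- b + stats::rnorm(length(b), 0, noise_sd)
  data.frame(class_lower_cm = as.integer(classes), biomass_g = pmax(b, 0))
}

#' Reduced toy food web with two evolving fish species
#'
#' A connected fixture web with the trophic structure producers ->
#' zooplankton -> planktivorous fish age guilds -> piscivorous fish age
#' guilds. The planktivorous level comprises all age guilds of the
#' vendace-like prey species plus the young predator guilds; the older
#' predator guilds are piscivores feeding on the prey species and (weakly)
#' on young conspecifics. Both focal species carry evolving (L_inf, k)
#' trait grids with bounds, reproduction-kernel medium levels and fitted
#' gear parameters matching the study species (gillnet on the piscivore,
#' trawl on the planktivore). All other constants are fixture values chosen
#' for a persistent, stationary unfished equilibrium; they are documented
#' defaults, not estimates of any real lake.
#'
#' @param n_producers number of producer guilds (>= 1).
#' @param n_zooplankton number of zooplankton guilds (>= 1).
#' @param grid_n trait-grid resolution per axis for both species (the
#'   full-scale configuration is 100).
#' @param rho trait correlation used in both species' reproduction kernels.
#' @param prey,predator optional [fish_species()] overrides (each must have
#'   >= 3 age guilds).
#' @param seed integer seed; with `jitter > 0` it drives a reproducible
#'   perturbation of masses and preferences, otherwise the fixture is fully
#'   deterministic (identical for equal seeds).
#' @param jitter relative lognormal jitter on non-fish masses and link
#'   preferences (default 0).
#' @return a [foodweb_config()] whose guild table carries reporting groups
#'   (phytoplankton, zooplankton, focal prey/predator).
#' @export
toy_foodweb <- function(n_producers = 2, n_zooplankton = 2, grid_n = 40,
                        rho = -0.7, prey = NULL, predator = NULL, seed = 1,
                        jitter = 0) {
  stopifnot(n_producers >= 1, n_zooplankton >= 1)
  set.seed(as.integer(seed))
  jit <- function(n) if (jitter > 0) stats::rlnorm(n, 0, jitter) else rep(1, n)
  if (is.null(prey))
    prey <- fish_species(
      name = "prey", vbgm = vbgm_params(16, 0.555, 0.9), ages = 0:4,
      mature_from = 2,
      grid = trait_grid(c(10, 20), c(0.45, 0.65), grid_n, grid_n),
      repro = default_reproduction_params("vendace", rho),
      gear = selectivity_curve(12.21, 1.71), ra = 0.01, B0 = 40)
  if (is.null(predator))
    predator <- fish_species(
      name = "pred", vbgm = vbgm_params(87, 0.124, 1.7), ages = 0:6,
      mature_from = 4,
      grid = trait_grid(c(70, 90), c(0.10, 0.20), grid_n, grid_n),
      repro = default_reproduction_params("pikeperch", rho),
      gear = selectivity_curve(46.72, 3.44), ra = 0.002, y = 2,
      B0 = c(1500, 1500, 1500, rep(40, length(0:6) - 3)))
  for (sp in list(prey, predator))
    if (length(sp$ages) < 3) stop("focal species need >= 3 age guilds")

  producers <- data.frame(
    id = paste0("prod", seq_len(n_producers)),
    mass_mgC = 1e-7 * 4^(seq_len(n_producers) - 1) * jit(n_producers),
    r = 1.0 * 0.9^(seq_len(n_producers) - 1),
    group = "phytoplankton")
  zoo <- data.frame(
    id = paste0("zoo", seq_len(n_zooplankton)),
    mass_mgC = 1e-4 * 10^(seq_len(n_zooplankton) - 1) * jit(n_zooplankton),
    x = 0.10 * 0.6^(seq_len(n_zooplankton) - 1), y = 8, fm = 0.1,
    group = "zooplankton")

  link <- function(res, con, w, e)
    data.frame(resource = res, consumer = con, w = w, e = e)
  links <- list()
  for (z in zoo$id)                        # zooplankton graze all producers
    links <- c(links, list(link(producers$id, z,
                                jit(n_producers), 0.45)))
  prey_ids <- fish_guild_ids(prey)
  pred_ids <- fish_guild_ids(predator)
  plankt_pred <- pred_ids[predator$ages <= 2]    # young predators eat zoo
  for (f in c(prey_ids, plankt_pred))
    links <- c(links, list(link(zoo$id, f, jit(n_zooplankton), 0.85)))
  pisc <- pred_ids[predator$ages >= 3]
  juv_pred <- pred_ids[predator$ages <= 1]
  for (f in pisc)
    links <- c(links, list(link(c(prey_ids, juv_pred), f,
                                c(rep(1, length(prey_ids)),
                                  rep(0.1, length(juv_pred))), 0.85)))
  foodweb_config(producers, zoo, list(prey, predator),
                 do.call(rbind, links),
                 globals = list(K = 500, B0 = 350, q = 1.2, t_end = 90,
                                eps_B = 1e-6, ax_fish = 0.12, y_fish = 3,
                                fm_fish = 0.1))
}

#' Default initial biomasses for a food web
#'
#' Heuristic starting point: producers share half the carrying capacity,
#' zooplankton start at K/25 each, fish age guilds at a geometric series
#' declining with age (older guilds hold less biomass).
#'
#' @param config a [foodweb_config()].
#' @return named biomass vector (mg C) over all guilds.
#' @export
default_initial_biomass <- function(config) {
  gdf <- config$guilds
  b <- stats::setNames(numeric(nrow(gdf)), gdf$id)
  np <- sum(gdf$role == "producer")
  b[gdf$role == "producer"] <- config$globals$K / (2 * np)
  b[gdf$role == "consumer"] <- config$globals$K / 25
  for (sp in config$species) {
    ids <- fish_guild_ids(sp)
    b[ids] <- 20 * 0.6^sp$ages
    if (sp$stocked) {
      b[ids] <- 0
      b[ids[sp$ages >= sp$stock_age]] <-
        sp$stock_biomass * 0.6^(sp$ages[sp$ages >= sp$stock_age] - sp$stock_age)
    }
  }
  b
}

#' Write / read a food-web configuration as YAML
#'
#' Serializes the guild table, links, global constants and fish species
#' specifications (including trait grids, reproduction kernels and gears) to
#' a structured YAML file, and reconstructs the validated configuration.
#'
#' @param config a [foodweb_config()].
#' @param path file path.
#' @export
write_foodweb_config <- function(config, path) {
  gdf <- config$guilds
  sp_ser <- lapply(config$species, function(sp) {
    list(name = sp$name, vbgm = unclass(sp$vbgm)[c("L_inf", "k", "L0")],
         amax = sp$amax, mature_from = sp$mature_from,
         grid = if (sp$evolving)
           list(L_inf_bounds = sp$grid$L_inf_bounds,
                k_bounds = sp$grid$k_bounds,
                n_L = sp$grid$n_L, n_k = sp$grid$n_k),
         repro = if (!is.null(sp$repro)) unclass(sp$repro),
         gear = if (!is.null(sp$gear)) unclass(sp$gear),
         ra = sp$ra, lw = as.list(sp$lw), stocked = sp$stocked,
         stock_age = sp$stock_age, stock_biomass = sp$stock_biomass,
         u = sp$u, B0 = sp$B0, y = sp$y)
  })
  pr <- gdf[gdf$role == "producer", c("id", "mass_mgC", "r", "group")]
  cs <- gdf[gdf$role == "consumer",
            c("id", "mass_mgC", "x", "y", "fm", "group")]
  yaml::write_yaml(list(
    producers = lapply(seq_len(nrow(pr)), function(i) as.list(pr[i, ])),
    consumers = if (nrow(cs)) lapply(seq_len(nrow(cs)),
                                     function(i) as.list(cs[i, ])),
    species = unname(sp_ser),
    links = lapply(seq_len(nrow(config$links)),
                   function(i) as.list(config$links[i, ])),
    globals = config$globals), path, precision = 12)
  invisible(path)
}

#' @rdname write_foodweb_config
#' @export
read_foodweb_config <- function(path) {
  y <- yaml::read_yaml(path)
  df_from <- function(l) do.call(rbind, lapply(l, as.data.frame))
  species <- lapply(y$species, function(s) {
    fish_species(
      name = s$name,
      vbgm = vbgm_params(s$vbgm$L_inf, s$vbgm$k, s$vbgm$L0),
      ages = 0:s$amax, mature_from = s$mature_from,
      grid = if (!is.null(s$grid))
        trait_grid(unlist(s$grid$L_inf_bounds), unlist(s$grid$k_bounds),
                   s$grid$n_L, s$grid$n_k),
      repro = if (!is.null(s$repro))
        reproduction_params(s$repro$cV, s$repro$sigma_L_inf, s$repro$sigma_k,
                            s$repro$rho, s$repro$u),
      gear = if (!is.null(s$gear))
        selectivity_curve(s$gear$mu, s$gear$sigma, s$gear$delta),
      ra = s$ra, lw = unlist(s$lw), stocked = isTRUE(s$stocked),
      stock_age = s$stock_age, stock_biomass = s$stock_biomass, u = s$u,
      B0 = if (!is.null(s$B0)) unlist(s$B0), y = s$y)
  })
  foodweb_config(df_from(y$producers),
                 if (!is.null(y$consumers)) df_from(y$consumers) else
                   data.frame(id = character(0), mass_mgC = numeric(0),
                              x = numeric(0), y = numeric(0),
                              fm = numeric(0), group = character(0)),
                 species, df_from(y$links), y$globals)
}

#' Tidy snapshot of a system state
#'
#' @param state a `system_state`.
#' @param config the [foodweb_config()].
#' @return data.frame with columns `year`, `guild`, `genotype_cell`,
#'   `biomass` (non-fish guilds have `genotype_cell = NA`).
#' @export
state_to_df <- function(state, config) {
  out <- list(data.frame(year = state$year, guild = names(state$B),
                         genotype_cell = NA_integer_,
                         biomass = as.numeric(state$B)))
  for (sp in config$species) {
    m <- state$cells[[sp$name]]
    out <- c(out, list(data.frame(
      year = state$year, guild = rep(colnames(m), each = nrow(m)),
      genotype_cell = rep(seq_len(nrow(m)), ncol(m)),
      biomass = as.vector(m))))
  }
  do.call(rbind, out)
}
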