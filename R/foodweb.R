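#' Length-weight-carbon conversion
#'
#' Converts fish length to carbon body mass through the length-weight
#' relationship \eqn{W = a L^b} (fresh weight, g) and multiplicative
#' fresh-to-dry and dry-to-carbon fractions.
#'
#' @param L length, cm (> 0); vectorized.
#' @param lw named numeric vector `c(a, b, dry, carbon)`: length-weight
#'   coefficient (g/cm^b), exponent, dry-weight fraction of fresh weight and
#'   carbon fraction of dry weight. All must be positive.
#' @return carbon body mass, mg C.
#' @export
length_to_carbon_mass <- function(L, lw = c(a = 0.01, b = 3, dry = 0.2,
                                            carbon = 0.4)) {
  if (any(L <= 0)) stop("L must be > 0")
  if (any(lw <= 0)) stop("length-weight constants must be positive")
  lw[["a"]] * L^lw[["b"]] * lw[["dry"]] * lw[["carbon"]] * 1000
}

#' Fish length within a growth season
#'
#' Fish grow along their von Bertalanffy curves during the growth season:
#' one VBGM-year of growth is accrued over the `t_end`-day season (there is
#' no growth off-season), so the effective age at day `d` of the season is
#' `age + d / t_end`.
#'
#' @param L_inf,k cell trait values (vectors).
#' @param L0 species length at birth, cm.
#' @param age age guild age, years (>= 0).
#' @param day day within the season, in `[0, t_end]`.
#' @param t_end season length, days.
#' @return length(s), cm.
#' @export
fish_length_at <- function(L_inf, k, L0, age, day = 0, t_end = 90) {
  if (age < 0) stop("age must be >= 0")
  if (day < 0 || day > t_end) stop("day must lie in [0, t_end]")
  a_eff <- age + if (t_end > 0) day / t_end else 0
  L_inf - (L_inf - L0) * exp(-k * a_eff)
}

#' Fish species specification for the food web
#'
#' @param name species tag.
#' @param vbgm species-mean [vbgm_params()] (drives guild body masses and,
#'   for non-evolving species, the deterministic growth curve).
#' @param ages integer vector of age guilds, `0:amax`; the oldest guild is a
#'   plus group.
#' @param mature_from first mature age guild (allocates to reproduction).
#' @param grid a [trait_grid()] for an evolving (focal) species, else NULL
#'   (single "average individual" genotype).
#' @param repro a [reproduction_params()] (required when `grid` is given).
#' @param gear a [selectivity_curve()] if the species is fished, else NULL.
#' @param ra reproduction allocation rate for mature guilds, 1/day.
#' @param lw length-weight-carbon constants, see [length_to_carbon_mass()].
#' @param stocked if TRUE the species bypasses reproduction and a fixed
#'   biomass is placed into `stock_age` each year.
#' @param stock_age,stock_biomass stocking target age guild and biomass
#'   (mg C); the default biomass matches the brown-trout stocking input.
#' @param u larvae conversion efficiency for a non-evolving species
#'   (evolving species take it from their [reproduction_params()]).
#' @param B0 optional per-species half-saturation density overriding the
#'   global (fish feed on much sparser resources than grazers).
#' @param y optional per-species maximum consumption factor overriding the
#'   global `y_fish` (piscivores are slower feeders than planktivores).
#' @export
fish_species <- function(name, vbgm, ages = 0:4, mature_from = 2, grid = NULL,
                         repro = NULL, gear = NULL, ra = 0.005,
                         lw = c(a = 0.01, b = 3, dry = 0.2, carbon = 0.4),
                         stocked = FALSE, stock_age = 2,
                         stock_biomass = 137.3, u = 0.8, B0 = NULL,
                         y = NULL) {
  stopifnot(inherits(vbgm, "vbgm_params"), length(ages) >= 2,
            all(diff(ages) == 1), ages[1] == 0)
  if (!is.null(grid) && is.null(repro))
    stop("an evolving species needs reproduction_params")
  if (mature_from > max(ages)) stop("mature_from beyond the oldest age guild")
  structure(list(name = name, vbgm = vbgm, ages = ages, amax = max(ages),
                 mature_from = mature_from, grid = grid, repro = repro,
                 gear = gear, ra = ra, lw = lw, evolving = !is.null(grid),
                 G = if (is.null(grid)) 1L else grid$G,
                 stocked = stocked, stock_age = stock_age,
                 stock_biomass = stock_biomass, u = u, B0 = B0, y = y),
            class = "fish_species")
}

fish_guild_ids <- function(sp) paste0(sp$name, "_a", sp$ages)

#' Assemble a food-web configuration
#'
#' Builds the guild table, trophic links and global constants of an
#' allometric trophic network. Non-fish guilds are supplied as data frames
#' with explicit rates; fish age guilds are generated from the species
#' specifications with allometric metabolic rates
#' \eqn{x = a_x M^{-1/4}} computed from the species-mean carbon body mass at
#' mid-season guild age. Feeding preferences are renormalized to sum to one
#' per consumer.
#'
#' @param producers data.frame: `id`, `mass_mgC`, `r` (intrinsic growth,
#'   1/day), optional `group`.
#' @param consumers data.frame: `id`, `mass_mgC`, `x`, `y`, `fm`, optional
#'   `group` (non-fish consumers, e.g. zooplankton) and optional `B0`
#'   (per-consumer half-saturation overriding the global).
#' @param species list of [fish_species()].
#' @param links data.frame: `resource`, `consumer` (guild ids), `w`
#'   (preference), `e` (assimilation efficiency in (0, 1]).
#' @param globals named list; defaults
#'   `K` (shared producer carrying capacity), `B0` (half-saturation),
#'   `q` (Hill exponent), `t_end = 90` (season days), `eps_B = 1e-6`
#'   (extinction threshold), `ax_fish` (fish metabolic allometry constant),
#'   `y_fish` (max consumption factor), `fm_fish` (maintenance coefficient).
#' @param check_connected validate that the web is connected (disable only
#'   for single-guild diagnostic set-ups).
#' @return An object of class `foodweb_config`.
#' @export
foodweb_config <- function(producers, consumers, species, links,
                           globals = list(), check_connected = TRUE) {
  g <- utils::modifyList(list(K = 1000, B0 = 50, q = 1.2, t_end = 90,
                              eps_B = 1e-6, ax_fish = 0.3, y_fish = 4,
                              fm_fish = 0.15, year_days = 365), globals)
  pr <- producers; cs <- consumers
  if (is.null(pr$group)) pr$group <- "phytoplankton"
  if (is.null(cs$group) && nrow(cs)) cs$group <- "zooplankton"
  if (is.null(cs$B0) && nrow(cs)) cs$B0 <- NA_real_
  rows <- list(
    data.frame(id = pr$id, role = "producer", species = NA, age = NA,
               group = pr$group, mass_mgC = pr$mass_mgC, x = 0, y = 0,
               fm = 0, r = pr$r, B0 = NA_real_, stringsAsFactors = FALSE))
  if (nrow(cs))
    rows <- c(rows, list(
      data.frame(id = cs$id, role = "consumer", species = NA, age = NA,
                 group = cs$group, mass_mgC = cs$mass_mgC, x = cs$x, y = cs$y,
                 fm = cs$fm, r = 0, B0 = cs$B0, stringsAsFactors = FALSE)))
  for (sp in species) {
    L_mid <- vbgm_length(sp$vbgm, sp$ages + 0.5)
    m <- length_to_carbon_mass(L_mid, sp$lw)
    rows <- c(rows, list(
      data.frame(id = fish_guild_ids(sp), role = "fish", species = sp$name,
                 age = sp$ages, group = sp$name, mass_mgC = m,
                 x = g$ax_fish * m^(-0.25),
                 y = if (is.null(sp$y)) g$y_fish else sp$y, fm = g$fm_fish,
                 r = 0,
                 B0 = if (is.null(sp$B0)) NA_real_ else
                   rep_len(sp$B0, length(sp$ages)),
                 stringsAsFactors = FALSE)))
  }
  rows <- lapply(rows, function(d) {
    d$B0[is.na(d$B0)] <- g$B0
    d
  })
  guilds <- do.call(rbind, rows)
  if (anyDuplicated(guilds$id)) stop("duplicate guild ids")
  if (any(guilds$r[guilds$role != "producer"] > 0) ||
      any(guilds$r[guilds$role == "producer"] <= 0))
    stop("exactly the producer guilds must have r > 0")
  if (any(guilds$x < 0) || any(guilds$y < 0)) stop("x and y must be >= 0")

  stopifnot(all(c("resource", "consumer", "w", "e") %in% names(links)))
  bad <- setdiff(c(links$resource, links$consumer), guilds$id)
  if (length(bad)) stop("links refer to unknown guilds: ",
                        paste(bad, collapse = ", "))
  if (any(links$e <= 0 | links$e > 1)) stop("assimilation e must be in (0, 1]")
  if (any(links$w <= 0)) stop("preferences w must be > 0")
  for (j in unique(links$consumer)) {     # preferences sum to 1 per consumer
    i <- links$consumer == j
    links$w[i] <- links$w[i] / sum(links$w[i])
  }
  non_prod <- guilds$id[guilds$role != "producer"]
  no_res <- setdiff(non_prod, unique(links$consumer))
  if (check_connected) {
    if (length(no_res))
      stop("guilds without any resource: ", paste(no_res, collapse = ", "))
    # undirected connectivity over the link graph
    adj <- rbind(links[, c("resource", "consumer")],
                 stats::setNames(links[, c("consumer", "resource")],
                                 c("resource", "consumer")))
    seen <- guilds$id[1]; frontier <- seen
    while (length(frontier)) {
      nxt <- unique(adj$consumer[adj$resource %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    if (length(setdiff(guilds$id, seen)))
      stop("food web is disconnected: ",
           paste(setdiff(guilds$id, seen), collapse = ", "))
  }
  names(species) <- vapply(species, `[[`, "", "name")
  cfg <- structure(list(guilds = guilds, links = links, species = species,
                        globals = g), class = "foodweb_config")
  attr(cfg, "engine_env") <- new.env(parent = emptyenv())
  cfg
}

#' @export
print.foodweb_config <- function(x, ...) {
  cat(sprintf("Food web: %d guilds (%d producers, %d consumers, %d fish), %d links\n",
              nrow(x$guilds), sum(x$guilds$role == "producer"),
              sum(x$guilds$role == "consumer"), sum(x$guilds$role == "fish"),
              nrow(x$links)))
  for (sp in x$species)
    cat(sprintf("  %s: ages 0-%d%s, %s, %s\n", sp$name, sp$amax,
                if (sp$amax >= 0) "+" else "",
                if (sp$evolving) sprintf("%dx%d trait grid", sp$grid$n_L,
                                         sp$grid$n_k) else "average individual",
                if (is.null(sp$gear)) "unfished" else "fished"))
  invisible(x)
}

# ---- state ----------------------------------------------------------------

#' Initial system state
#'
#' @param config a [foodweb_config()].
#' @param biomass named vector of initial guild biomasses (mg C); fish entries
#'   give the total per age guild, spread over genotype cells according to the
#'   initial trait distribution.
#' @param trait_init optional named list per evolving species: probability
#'   matrix from [initial_trait_distribution()]; default is that function's
#'   default (grid-middle centred truncated normal).
#' @return An object of class `system_state`.
#' @export
initial_state <- function(config, biomass, trait_init = NULL) {
  gdf <- config$guilds
  stopifnot(all(gdf$id %in% names(biomass)))
  b <- biomass[gdf$id]
  if (any(b < 0)) stop("biomasses must be >= 0")
  cells <- list(); pools <- list()
  for (sp in config$species) {
    ids <- fish_guild_ids(sp)
    if (sp$evolving) {
      d0 <- trait_init[[sp$name]]
      if (is.null(d0)) d0 <- initial_trait_distribution(sp$grid)
      cells[[sp$name]] <- outer(as.vector(d0), as.numeric(b[ids]))
    } else {
      cells[[sp$name]] <- matrix(as.numeric(b[ids]), 1, length(ids))
    }
    colnames(cells[[sp$name]]) <- ids
    pools[[sp$name]] <- matrix(0, sp$G, length(ids), dimnames = list(NULL, ids))
  }
  nf <- gdf$id[gdf$role != "fish"]
  structure(list(B = stats::setNames(as.numeric(b[nf]), nf), cells = cells,
                 pools = pools, larvae = NULL, year = 0L),
            class = "system_state")
}

#' Guild biomass totals of a state
#'
#' @param state a `system_state`.
#' @param config the matching [foodweb_config()].
#' @return named vector over all guilds (fish totals summed over genotype
#'   cells).
#' @export
guild_biomass <- function(state, config) {
  tot <- stats::setNames(numeric(nrow(config$guilds)), config$guilds$id)
  tot[names(state$B)] <- state$B
  for (sp in config$species)
    tot[colnames(state$cells[[sp$name]])] <- colSums(state$cells[[sp$name]])
  tot
}

# ---- engine ---------------------------------------------------------------

# Precomputed index structure for the season ODE; memoised on the config.
build_engine <- function(config) {
  env <- attr(config, "engine_env")
  if (!is.null(env$eng)) return(env$eng)
  gdf <- config$guilds; g <- config$globals
  n <- nrow(gdf)
  gid <- stats::setNames(seq_len(n), gdf$id)
  cons_ids <- unique(config$links$consumer)
  cons <- lapply(cons_ids, function(j) {
    lk <- config$links[config$links$consumer == j, ]
    list(j = gid[[j]], res = unname(gid[lk$resource]), w = lk$w, e = lk$e,
         B0q = gdf$B0[gid[[j]]]^g$q)
  })
  nf_ids <- gdf$id[gdf$role != "fish"]
  nf <- unname(gid[nf_ids])
  off <- length(nf)
  spl <- list()
  for (sp in config$species) {
    ids <- fish_guild_ids(sp)
    na <- length(ids); G <- sp$G
    if (sp$evolving) {
      tr <- grid_cell_traits(sp$grid)
      Linf_c <- tr$L_inf; k_c <- tr$k
    } else {
      Linf_c <- sp$vbgm$L_inf; k_c <- sp$vbgm$k
    }
    spl[[sp$name]] <- list(
      name = sp$name, G = G, na = na, ages = sp$ages,
      gidx = unname(gid[ids]),
      cell_off = off, pool_off = off + G * na,
      mature = sp$ages >= sp$mature_from,
      ra = sp$ra, gear = sp$gear, Linf_c = Linf_c, k_c = k_c,
      L0 = sp$vbgm$L0, x = gdf$x[gid[ids]])
    off <- off + 2 * G * na
  }
  eng <- list(n = n, ids = gdf$id, role = gdf$role,
              is_prod = gdf$role == "producer",
              is_cons = gdf$role == "consumer",
              x = gdf$x, y = gdf$y, fm = gdf$fm, r = gdf$r,
              prod_idx = which(gdf$role == "producer"),
              cons = cons, nf = nf, n_nf = length(nf), sp = spl, ny = off,
              K = g$K, B0q = g$B0^g$q, q = g$q, t_end = g$t_end,
              eps_B = g$eps_B)
  env$eng <- eng
  eng
}

pack_state <- function(state, eng) {
  y <- numeric(eng$ny)
  y[seq_len(eng$n_nf)] <- state$B
  for (s in eng$sp) {
    y[s$cell_off + seq_len(s$G * s$na)] <- state$cells[[s$name]]
    y[s$pool_off + seq_len(s$G * s$na)] <- state$pools[[s$name]]
  }
  y
}

unpack_state <- function(y, eng, state) {
  state$B[] <- y[seq_len(eng$n_nf)]
  for (s in eng$sp) {
    state$cells[[s$name]][] <- y[s$cell_off + seq_len(s$G * s$na)]
    state$pools[[s$name]][] <- y[s$pool_off + seq_len(s$G * s$na)]
  }
  state
}

# guild totals from the packed state
eng_totals <- function(y, eng) {
  tot <- numeric(eng$n)
  tot[eng$nf] <- y[seq_len(eng$n_nf)]
  for (s in eng$sp)
    tot[s$gidx] <- .colSums(y[s$cell_off + seq_len(s$G * s$na)], s$G, s$na)
  tot
}

# fishing mortality rate (1/day) per genotype cell for one age guild
fishing_rate_cells <- function(s, age, day, t_end, E) {
  if (E <= 0 || is.null(s$gear)) return(0)
  L <- s$Linf_c - (s$Linf_c - s$L0) * exp(-s$k_c * (age + day / t_end))
  (E / t_end) * exp(-(L - s$gear$mu)^2 / (2 * s$gear$sigma^2))
}

# right-hand side over the packed state; E is the peak instantaneous fishing
# mortality (1/year), delivered over the season
rhs_core <- function(t, y, eng, E) {
  if (any(is.nan(y))) stop("NaN in state during integration")
  y <- pmax(y, 0)
  tot <- eng_totals(y, eng)
  gain_unit <- numeric(eng$n)      # consumption gain per unit consumer biomass
  consumed <- numeric(eng$n)       # biomass loss rate to predation, per guild
  for (cn in eng$cons) {
    num <- cn$w * tot[cn$res]^eng$q
    den <- cn$B0q + sum(num)
    xy <- eng$x[cn$j] * eng$y[cn$j]
    gain_unit[cn$j] <- xy * sum(num) / den
    consumed[cn$res] <- consumed[cn$res] + (xy * tot[cn$j] / den) * (num / cn$e)
  }
  dy <- numeric(length(y))
  # non-fish guilds
  B_nf <- tot[eng$nf]
  prod_nf <- eng$is_prod[eng$nf]
  growth <- ifelse(prod_nf,
                   eng$r[eng$nf] * B_nf * (1 - sum(tot[eng$prod_idx]) / eng$K),
                   (gain_unit[eng$nf] - eng$fm[eng$nf] * eng$x[eng$nf]) * B_nf)
  dy[seq_len(eng$n_nf)] <- growth - consumed[eng$nf]
  # fish guilds, per genotype cell
  for (s in eng$sp) {
    gi <- s$gidx
    crate <- ifelse(tot[gi] > 0, consumed[gi] / tot[gi], 0)
    unit <- gain_unit[gi] - eng$fm[gi] * s$x - crate -
            ifelse(s$mature, s$ra, 0)
    for (a in seq_len(s$na)) {
      seg <- s$cell_off + (a - 1) * s$G + seq_len(s$G)
      pseg <- s$pool_off + (a - 1) * s$G + seq_len(s$G)
      f <- fishing_rate_cells(s, s$ages[a], t, eng$t_end, E)
      dy[seg] <- (unit[a] - f) * y[seg]
      if (s$mature[a]) dy[pseg] <- s$ra * y[seg] - f * y[pseg]
    }
  }
  list(dy)
}

# Reduced right-hand side over guild totals only, valid when no fishing is
# active: within a guild every genotype cell then has the same per-biomass
# rate, so cell shares are constant through the season and the full system
# factorizes exactly into guild totals (plus per-guild pool accumulators).
rhs_reduced <- function(t, y, eng) {
  if (any(is.nan(y))) stop("NaN in state during integration")
  y <- pmax(y, 0)
  n_nf <- eng$n_nf
  tot <- numeric(eng$n)
  tot[eng$nf] <- y[seq_len(n_nf)]
  off <- n_nf
  for (s in eng$sp) {
    tot[s$gidx] <- y[off + seq_len(s$na)]
    off <- off + 2 * s$na
  }
  gain_unit <- numeric(eng$n); consumed <- numeric(eng$n)
  for (cn in eng$cons) {
    num <- cn$w * tot[cn$res]^eng$q
    den <- cn$B0q + sum(num)
    xy <- eng$x[cn$j] * eng$y[cn$j]
    gain_unit[cn$j] <- xy * sum(num) / den
    consumed[cn$res] <- consumed[cn$res] + (xy * tot[cn$j] / den) * (num / cn$e)
  }
  dy <- numeric(length(y))
  B_nf <- tot[eng$nf]
  prod_nf <- eng$is_prod[eng$nf]
  growth <- ifelse(prod_nf,
                   eng$r[eng$nf] * B_nf * (1 - sum(tot[eng$prod_idx]) / eng$K),
                   (gain_unit[eng$nf] - eng$fm[eng$nf] * eng$x[eng$nf]) * B_nf)
  dy[seq_len(n_nf)] <- growth - consumed[eng$nf]
  off <- n_nf
  for (s in eng$sp) {
    gi <- s$gidx
    B <- tot[gi]
    crate <- ifelse(B > 0, consumed[gi] / B, 0)
    unit <- gain_unit[gi] - eng$fm[gi] * s$x - crate - ifelse(s$mature, s$ra, 0)
    dy[off + seq_len(s$na)] <- unit * B
    dy[off + s$na + seq_len(s$na)] <- ifelse(s$mature, s$ra, 0) * B
    off <- off + 2 * s$na
  }
  list(dy)
}

integrate_season_reduced <- function(state, eng, rtol, atol, method) {
  y0 <- numeric(eng$n_nf + 2 * sum(vapply(eng$sp, `[[`, 0L, "na")))
  y0[seq_len(eng$n_nf)] <- state$B
  off <- eng$n_nf
  for (s in eng$sp) {
    y0[off + seq_len(s$na)] <- .colSums(state$cells[[s$name]], s$G, s$na)
    off <- off + 2 * s$na
  }
  if (is.null(method)) method <- "lsoda"
  sol <- deSolve::ode(y = y0, times = c(0, eng$t_end),
                      func = function(t, y, p) rhs_reduced(t, y, eng),
                      parms = NULL, method = method, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1])))
    stop(sprintf("season integration failed (istate = %d, t reached = %g)",
                 attr(sol, "istate")[1], sol[nrow(sol), 1]))
  y1 <- pmax(sol[nrow(sol), -1], 0)
  state$B[] <- y1[seq_len(eng$n_nf)]
  state$B[state$B < eng$eps_B] <- 0
  off <- eng$n_nf
  for (s in eng$sp) {
    old <- .colSums(state$cells[[s$name]], s$G, s$na)
    newt <- y1[off + seq_len(s$na)]
    pool_acc <- y1[off + s$na + seq_len(s$na)]
    ratio <- ifelse(old > 0, newt / old, 0)
    share <- sweep(state$cells[[s$name]], 2,
                   ifelse(old > 0, old, 1), "/")
    state$cells[[s$name]] <- sweep(state$cells[[s$name]], 2, ratio, "*")
    pools <- state$pools[[s$name]] + sweep(share, 2, pool_acc, "*")
    pools[pools < eng$eps_B] <- 0
    state$pools[[s$name]] <- pools
    cells <- state$cells[[s$name]]
    cells[cells < eng$eps_B] <- 0
    state$cells[[s$name]] <- cells
    off <- off + 2 * s$na
  }
  state
}

# ---- exported dynamics operations -----------------------------------------

#' Right-hand side of the growth-season ODE system
#'
#' Assembles, for every guild (and genotype cell of the focal species), the
#' gain and loss terms: producers gain logistic growth and lose to
#' consumption; consumers gain consumption and lose maintenance and
#' predation; fish additionally lose fishing mortality and (mature guilds)
#' reproduction allocation, which is credited to the reproductive pools.
#'
#' @param state a `system_state`.
#' @param config the [foodweb_config()].
#' @param E peak instantaneous fishing mortality, 1/year (0 = no fishing).
#' @param day day within the season (selectivity follows within-season
#'   growth).
#' @return a list like `state` holding time derivatives (mg C / day).
#' @export
foodweb_rhs <- function(state, config, E = 0, day = 0) {
  eng <- build_engine(config)
  dy <- rhs_core(day, pack_state(state, eng), eng, E)[[1]]
  unpack_state(dy, eng, state)
}

#' Logistic gain of a producer guild
#'
#' \eqn{r_i B_i (1 - \sum_{producers} B_j / K)} with shared carrying
#' capacity K.
#'
#' @inheritParams foodweb_rhs
#' @param guild_id a producer guild id.
#' @return rate, mg C/day.
#' @export
producer_gain <- function(config, guild_id, state) {
  gdf <- config$guilds
  i <- match(guild_id, gdf$id)
  if (is.na(i) || gdf$role[i] != "producer") stop("not a producer guild")
  tot <- guild_biomass(state, config)
  sumP <- sum(tot[gdf$id[gdf$role == "producer"]])
  unname(gdf$r[i] * tot[[guild_id]] * (1 - sumP / config$globals$K))
}

#' Consumption flux along one trophic link
#'
#' Multi-species functional response with Hill exponent q and
#' half-saturation B0: the flux gained by consumer j from resource i is
#' \eqn{x_j y_j B_j w_{ji} B_i^q / (B_0^q + \sum_m w_{jm} B_m^q)}; the
#' resource loses flux divided by the assimilation efficiency e.
#'
#' @inheritParams foodweb_rhs
#' @param resource_id,consumer_id guild ids of an existing link.
#' @return list with `gain` (to the consumer) and `resource_loss`, mg C/day.
#' @export
consumption_flux <- function(config, resource_id, consumer_id, state) {
  lk <- config$links
  row <- which(lk$resource == resource_id & lk$consumer == consumer_id)
  if (!length(row)) stop("no such trophic link")
  tot <- guild_biomass(state, config)
  g <- config$globals
  all_res <- lk[lk$consumer == consumer_id, ]
  num <- all_res$w * tot[all_res$resource]^g$q
  j0 <- match(consumer_id, config$guilds$id)
  den <- config$guilds$B0[j0]^g$q + sum(num)
  j <- match(consumer_id, config$guilds$id)
  xy <- config$guilds$x[j] * config$guilds$y[j]
  fl <- unname(xy * tot[[consumer_id]] *
               num[match(resource_id, all_res$resource)] / den)
  list(gain = fl, resource_loss = fl / lk$e[row[1]])
}

#' Maintenance loss of a consumer or fish guild
#'
#' \eqn{f_m x_i B_i}: the maintenance coefficient times the mass-specific
#' metabolic rate times biomass.
#'
#' @inheritParams producer_gain
#' @export
maintenance_loss <- function(config, guild_id, state) {
  gdf <- config$guilds
  i <- match(guild_id, gdf$id)
  if (is.na(i) || gdf$role[i] == "producer") stop("not a consumer/fish guild")
  tot <- guild_biomass(state, config)
  unname(gdf$fm[i] * gdf$x[i] * tot[[guild_id]])
}

#' Fishing loss rates per genotype cell
#'
#' The annual peak instantaneous fishing mortality E is delivered uniformly
#' over the `t_end`-day season, scaled by the normalized gear selectivity at
#' each cell's current length: rate `(E / t_end) * S_norm(L)` per day, so a
#' guild held at the gear mode loses exactly `exp(-E)` of its biomass over a
#' season with no other dynamics.
#'
#' @inheritParams foodweb_rhs
#' @param species species name (must carry a gear).
#' @param age age guild.
#' @return vector over genotype cells, mg C/day.
#' @export
fishing_loss <- function(config, species, age, state, day = 0, E = 0) {
  sp <- config$species[[species]]
  if (is.null(sp)) stop("unknown species")
  if (is.null(sp$gear)) stop("species has no gear configured")
  eng <- build_engine(config)
  s <- eng$sp[[species]]
  f <- fishing_rate_cells(s, age, day, eng$t_end, E)
  f * state$cells[[species]][, paste0(species, "_a", age)]
}

#' Reproduction allocation of a mature fish guild
#'
#' Rate `ra * B` per genotype cell, debited from guild biomass and credited
#' to the reproductive pools (the season ODE does both simultaneously, so
#' the sum of guild biomass and pool is conserved against this term).
#'
#' @inheritParams fishing_loss
#' @return vector over genotype cells, mg C/day.
#' @export
reproduction_allocation <- function(config, species, age, state) {
  sp <- config$species[[species]]
  if (is.null(sp)) stop("unknown species")
  if (age < sp$mature_from)
    stop("reproduction allocation requested from an immature guild")
  sp$ra * state$cells[[species]][, paste0(species, "_a", age)]
}

#' Integrate one growth season
#'
#' Advances the system from day 0 to day `t_end` of the season with an
#' adaptive-step integrator (deSolve); genotype-resolved states use the
#' Adams method, small guild-only webs lsoda. Non-negativity is enforced and
#' biomasses below the extinction threshold `eps_B` are clamped to zero at
#' season end.
#'
#' When no fishing is active, all genotype cells of a guild share the same
#' per-biomass rate, so the system factorizes exactly into guild totals;
#' large genotype-resolved states then integrate the reduced guild-level
#' system and rescale the (constant) cell shares, which is much faster and
#' equal to the full integration up to integrator tolerance.
#'
#' @inheritParams foodweb_rhs
#' @param rtol,atol integrator tolerances.
#' @param method deSolve method; default `"lsoda"` for states of dimension
#'   <= 2000, `"adams"` otherwise.
#' @return the end-of-season `system_state`.
#' @export
integrate_growth_season <- function(state, config, E = 0, rtol = 1e-6,
                                    atol = 1e-8, method = NULL) {
  eng <- build_engine(config)
  if (eng$t_end == 0) return(state)
  if (E == 0 && eng$ny > 2000)
    return(integrate_season_reduced(state, eng, rtol, atol, method))
  y0 <- pack_state(state, eng)
  if (is.null(method)) method <- if (eng$ny <= 2000) "lsoda" else "adams"
  sol <- deSolve::ode(y = y0, times = c(0, eng$t_end),
                      func = function(t, y, p) rhs_core(t, y, eng, E),
                      parms = NULL, method = method, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1])))
    stop(sprintf("season integration failed (istate = %d, t reached = %g)",
                 attr(sol, "istate")[1], sol[nrow(sol), 1]))
  y1 <- pmax(sol[nrow(sol), -1], 0)
  y1[y1 < eng$eps_B] <- 0
  unpack_state(y1, eng, state)
}

#' Off-season step
#'
#' Fish guild biomasses are reduced by off-season maintenance respiration at
#' half the in-season coefficient, `exp(-(fm/2) * x * (365 - t_end))`;
#' non-fish guilds start the next season at their season-end biomass.
#'
#' @inheritParams foodweb_rhs
#' @return the next-season initial `system_state` (year incremented).
#' @export
off_season_step <- function(state, config) {
  g <- config$globals
  gdf <- config$guilds
  for (sp in config$species) {
    ids <- fish_guild_ids(sp)
    i <- match(ids, gdf$id)
    mult <- exp(-(gdf$fm[i] / 2) * gdf$x[i] * (g$year_days - g$t_end))
    state$cells[[sp$name]] <-
      state$cells[[sp$name]] * rep(mult, each = sp$G)
  }
  state$year <- state$year + 1L
  state
}
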