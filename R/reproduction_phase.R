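#' Spawn: convert reproductive pools into larvae biomass
#'
#' For each fish species the end-of-season reproductive pools are summed
#' over age guilds and genotype lineages; the total is converted into larvae
#' biomass with efficiency u and distributed over the genotype cells
#' according to the larvae trait distribution of [larvae_distribution()]
#' (random mating of the pool-weighted parent distribution). Pools are
#' cleared. A stocked species bypasses reproduction entirely: its larvae are
#' zero and a fixed biomass is placed into its stocking age guild during
#' [age_guilds()]. A species whose total pool is zero produces no larvae
#' this year (reproduction failure, recorded in the spawn log).
#'
#' @param state end-of-season `system_state`.
#' @param config the [foodweb_config()].
#' @param eps_P pair-pruning threshold passed to [larvae_distribution()].
#' @param caches optional named list per evolving species, each a list with
#'   [mix_cache()] entries `phenotype` and `genotype`.
#' @param record_variance also compute the genotypic/phenotypic variance
#'   decomposition and heritability of the larvae distribution.
#' @return the state with `larvae` set per species, pools cleared, and a
#'   `last_spawn` log (status, parent distribution, larvae distribution,
#'   V_G, V_P, H).
#' @export
spawn <- function(state, config, eps_P = 1e-8, caches = NULL,
                  record_variance = FALSE) {
  state$larvae <- list()
  state$last_spawn <- list()
  for (sp in config$species) {
    nm <- sp$name
    pools <- state$pools[[nm]]
    tot <- sum(pools)
    info <- list(status = "ok", pool_total = tot)
    if (sp$stocked) {
      larvae <- numeric(sp$G)
      info$status <- "stocked"
    } else if (tot <= 0) {
      larvae <- numeric(sp$G)
      info$status <- "no_reproduction"
    } else if (sp$evolving) {
      parents <- parent_distribution(pools, sp$grid)
      dist <- larvae_distribution(parents, sp$repro, sp$grid, eps_P,
                                  cache = caches[[nm]]$phenotype,
                                  component = "phenotype")
      larvae <- sp$repro$u * tot * as.vector(dist)
      info$parents <- parents
      info$larvae_dist <- dist
      if (record_variance) {
        dG <- larvae_distribution(parents, sp$repro, sp$grid, eps_P,
                                  cache = caches[[nm]]$genotype,
                                  component = "genotype")
        info$V_P <- trait_moments(dist, sp$grid)$var
        info$V_G <- trait_moments(dG, sp$grid)$var
        info$H <- heritability(info$V_G, info$V_P)
      }
    } else {
      u <- if (!is.null(sp$repro)) sp$repro$u else sp$u
      larvae <- u * tot
    }
    state$larvae[[nm]] <- larvae
    state$pools[[nm]][] <- 0
    state$last_spawn[[nm]] <- info
  }
  state
}

#' Ageing: shift age guilds and recruit larvae
#'
#' Biomass moves up one age guild per year, retaining genotype-cell
#' assignments; the oldest guild is a plus group accumulating its own
#' survivors plus the incoming cohort. Larvae produced by [spawn()] enter
#' age 0. Total fish biomass (excluding the new larvae) is conserved
#' exactly. For a stocked species, the stocking age guild is then set to the
#' configured stocking biomass.
#'
#' @param state a post-[spawn()] `system_state` (with `larvae` present).
#' @param config the [foodweb_config()].
#' @return the aged `system_state` (larvae consumed).
#' @export
age_guilds <- function(state, config) {
  if (is.null(state$larvae))
    stop("age_guilds requires a post-spawn state (larvae missing)")
  for (sp in config$species) {
    nm <- sp$name
    cells <- state$cells[[nm]]
    na <- ncol(cells)
    new <- cells
    new[, na] <- cells[, na] + cells[, na - 1]          # plus group
    if (na > 2) new[, 2:(na - 1)] <- cells[, 1:(na - 2)]
    new[, 1] <- state$larvae[[nm]]
    if (sp$stocked)
      new[, sp$stock_age + 1] <- sp$stock_biomass / sp$G
    state$cells[[nm]] <- new
    state$pools[[nm]][] <- 0
  }
  state$larvae <- NULL
  state
}
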