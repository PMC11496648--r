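## Mesocosm-style community simulator with known ground truth.
##
## Discrete-time Gompertz/Ricker dynamics on the log(density + 1) scale:
##   lnp_i(t+1) = lnp_i(t) + r_i(season) - s_i z_i(t)
##                + sum_d J_{i<-d}(t) z_d(t) + press_i + eps_proc
## where z_i = (lnp_i - mu_i) / sd_i is the density on a fixed reference
## standardized scale (so interaction effects live on the same scale as
## S-map coefficients from empirically standardized data, up to a positive
## rescaling), and the realized per-capita effect of donor d on recipient
## i is density-dependent:
##   J_{i<-d}(t) = a_dr + b_dr * z_i(t) + eps_int(t).
## b_dr < 0 gives negative (stabilizing) interaction density-dependence,
## b_dr > 0 positive (destabilizing), b_dr = 0 density-independent
## variability carried by eps_int alone.

#' Default synthetic interaction web
#'
#' Eight directed links among the ten functional groups, mixing
#' predator-prey and resource links with negative, positive and zero
#' recipient-density-dependence.
#'
#' @return Data frame: `donor`, `recipient`, `a` (baseline per-capita
#'   effect), `b` (IDD slope on the recipient's standardized density).
#' @export
default_web <- function() {
  data.frame(
    donor = c("phytoplankton", "rotifers", "rotifers",
              "phytophilous_pred", "macrophytes", "benthic_pred",
              "neustonic_pred", "phytoplankton"),
    recipient = c("rotifers", "phytoplankton", "crust_zoopl",
                  "rotifers", "herbivores", "molluscs",
                  "molluscs", "crust_zoopl"),
    a = c(0.4, -0.4, 0.35, -0.35, 0.4, -0.4, -0.3, 0.3),
    b = c(0.2, -0.2, 0, 0.2, -0.2, -0.25, 0, 0.15),
    stringsAsFactors = FALSE)
}

#' Synthetic community configuration
#'
#' Defaults emulate the mesocosm design: 2 replicate tanks per treatment
#' (C, I, H, IH), 3 years, 10 fortnightly censuses, 10 functional groups
#' on a 10-census seasonal cycle, with selective press disturbances
#' mimicking an arthropod-targeting insecticide (suppressing predatory and
#' detritivorous insects) and a macrophyte-targeting herbicide.
#'
#' @param web Interaction links (see [default_web()]).
#' @param sigma_int Density-independent interaction noise SD (default
#'   0.05).
#' @param process_sd Process noise SD on log growth (default 0.05).
#' @param season_amp Seasonal forcing amplitude per taxon on log growth
#'   (recycled; default 0.3 for plankton groups, 0.15 otherwise).
#' @param season_phase Per-taxon phase (radians) of the sinusoidal
#'   10-census cycle, staggered by trophic position.
#' @param self_reg Self-regulation strength per taxon (default 0.5).
#' @param carrying Carrying density per taxon (count scale; macrophytes
#'   are mapped to a coverage proportion instead).
#' @param disturbance Named list of per-treatment multiplicative
#'   suppression factors per taxon, applied as a press (log factor added
#'   at every census transition).
#' @param tanks_per_treatment,years,censuses Design shape (2, 3, 10).
#' @param init_sd SD of the initial log-density deviation per fragment.
#' @param density_cap Hard cap on simulated densities; exceeding it stops
#'   the simulation with advice to use smaller effects.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(web = default_web(),
                             sigma_int = 0.05,
                             process_sd = 0.05,
                             season_amp = NULL,
                             season_phase = NULL,
                             self_reg = 0.5,
                             carrying = NULL,
                             disturbance = NULL,
                             tanks_per_treatment = 2L,
                             years = 3L,
                             censuses = 10L,
                             init_sd = 0.5,
                             density_cap = 1e6) {
  taxa <- default_taxa()
  if (is.null(season_amp)) {
    season_amp <- ifelse(taxa %in% c("phytoplankton", "rotifers",
                                     "crust_zoopl"), 0.3, 0.15)
  }
  if (is.null(season_phase)) {
    season_phase <- c(phytoplankton = 0, rotifers = 0.6, crust_zoopl = 1.2,
                      macrophytes = 0, detritivores = 1.2, herbivores = 1.2,
                      phytophilous_pred = 1.8, benthic_pred = 1.8,
                      neustonic_pred = 1.8, molluscs = 1.8)[taxa]
  }
  if (is.null(carrying)) {
    carrying <- c(phytoplankton = 200, rotifers = 100, crust_zoopl = 50,
                  macrophytes = NA, detritivores = 20, herbivores = 15,
                  phytophilous_pred = 10, benthic_pred = 10,
                  neustonic_pred = 10, molluscs = 15)[taxa]
  }
  if (is.null(disturbance)) {
    insecticide <- c(phytophilous_pred = 0.45, benthic_pred = 0.45,
                     detritivores = 0.75, neustonic_pred = 1.15,
                     molluscs = 1.1)
    herbicide <- c(macrophytes = 0.55, phytoplankton = 0.85)
    both <- c(insecticide, herbicide)
    both[names(insecticide)] <- insecticide
    both[names(herbicide)] <- herbicide
    disturbance <- list(C = numeric(0), I = insecticide, H = herbicide,
                        IH = both)
  }
  stopifnot(all(web$donor %in% taxa), all(web$recipient %in% taxa),
            censuses %% 10L == 0L || censuses == 10L,
            sigma_int >= 0, process_sd >= 0, init_sd >= 0)
  structure(list(taxa = taxa, web = web, sigma_int = sigma_int,
                 process_sd = process_sd,
                 season_amp = rep_len(season_amp, length(taxa)),
                 season_phase = rep_len(season_phase, length(taxa)),
                 self_reg = rep_len(self_reg, length(taxa)),
                 carrying = carrying,
                 disturbance = disturbance,
                 tanks_per_treatment = as.integer(tanks_per_treatment),
                 years = as.integer(years), censuses = as.integer(censuses),
                 init_sd = init_sd, density_cap = density_cap,
                 period = 10L, sd_ref = 1),
            class = "synthetic_config")
}

## state z -> observed raw density (macrophytes are a coverage proportion)
state_to_density <- function(z, taxon, cfg) {
  if (taxon == "macrophytes") {
    pmin(1, pmax(0, 0.5 + 0.15 * z))
  } else {
    pmax(0, exp(log(cfg$carrying[[taxon]] + 1) + cfg$sd_ref * z) - 1)
  }
}

#' Simulate a synthetic mesocosm community with known Jacobians
#'
#' Runs the density-dependent interaction model (see the package vignette)
#' over the full experimental design and returns both the observation
#' panel and the generator's ground truth: the state trajectory, the
#' realized per-capita interaction effect `J` of every link at every time
#' point, the true link list with IDD directions, and the configured press
#' log-effects.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed; the same (config, seed) reproduces the panel
#'   bit-identically.
#' @return List: `panel` (a `community_panel`), `truth` (list with
#'   `states`, `jacobian`, `web`, `idd_direction`, `press`).
#' @export
simulate_community <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  taxa <- config$taxa
  n_tx <- length(taxa)
  web <- config$web
  trts <- treatment_levels()
  tanks <- unlist(lapply(seq_along(trts), function(i) {
    sprintf("%s%d", trts[i], seq_len(config$tanks_per_treatment))
  }))
  tank_trt <- rep(trts, each = config$tanks_per_treatment)
  names(tank_trt) <- tanks

  panel_rows <- list()
  state_rows <- list()
  jac_rows <- list()
  with_seed(seed, {
    for (tk in tanks) {
      trt <- tank_trt[[tk]]
      press <- rep(0, n_tx)
      names(press) <- taxa
      dist <- config$disturbance[[trt]]
      if (length(dist) > 0L) press[names(dist)] <- log(dist)
      for (yr in seq_len(config$years)) {
        z <- stats::rnorm(n_tx, 0, config$init_sd)
        names(z) <- taxa
        for (cs in seq_len(config$censuses)) {
          dens <- vapply(taxa, function(tx)
            state_to_density(z[[tx]], tx, config), numeric(1))
          if (any(dens > config$density_cap)) {
            stop("explosive divergence (density above cap); ",
                 "use smaller interaction effects or stronger self-regulation")
          }
          panel_rows[[length(panel_rows) + 1L]] <-
            data.frame(tank_id = tk, treatment = trt, year = yr,
                       census = cs, taxon = taxa, raw_density = unname(dens),
                       stringsAsFactors = FALSE)
          state_rows[[length(state_rows) + 1L]] <-
            data.frame(tank_id = tk, treatment = trt, year = yr,
                       census = cs, taxon = taxa, z = unname(z),
                       stringsAsFactors = FALSE)
          ## realized per-capita effects at this state (used in the t -> t+1
          ## transition; recorded for every census including the last)
          eps_int <- stats::rnorm(nrow(web), 0, config$sigma_int)
          J <- web$a + web$b * z[web$recipient] + eps_int
          if (nrow(web) > 0L) {
            jac_rows[[length(jac_rows) + 1L]] <-
              data.frame(tank_id = tk, treatment = trt, year = yr,
                         census = cs, donor = web$donor,
                         recipient = web$recipient, J = J,
                         stringsAsFactors = FALSE)
          }
          if (cs < config$censuses) {
            season <- config$season_amp *
              sin(2 * pi * (cs - 1) / config$period + config$season_phase)
            inter <- rep(0, n_tx)
            names(inter) <- taxa
            contrib <- J * z[web$donor]
            for (l in seq_len(nrow(web))) {
              inter[web$recipient[l]] <- inter[web$recipient[l]] + contrib[l]
            }
            dz <- (season - config$self_reg * z + inter + press +
                     stats::rnorm(n_tx, 0, config$process_sd)) / config$sd_ref
            z <- z + dz
            ## extinction floor: counts cannot drop below zero density
            lnp <- log(config$carrying + 1) + config$sd_ref * z
            flo <- !is.na(config$carrying) & lnp < 0
            z[flo] <- -log(config$carrying[flo] + 1) / config$sd_ref
          }
        }
      }
    }
  })
  panel <- community_panel(do.call(rbind, panel_rows))
  states <- do.call(rbind, c(state_rows, list(make.row.names = FALSE)))
  jac <- do.call(rbind, c(jac_rows, list(make.row.names = FALSE)))
  idd_dir <- ifelse(web$b < 0, "negative",
                    ifelse(web$b > 0, "positive", "density_independent"))
  truth <- list(states = states, jacobian = jac,
                web = cbind(web, idd_direction = idd_dir),
                press = lapply(config$disturbance, log),
                config = config, seed = seed)
  list(panel = panel, truth = truth)
}

#' Look up the realized per-capita interaction effect
#'
#' Returns `J_{recipient<-donor}(t)` exactly as used in the simulator's
#' state update at the given key.
#'
#' @param truth The `truth` component of [simulate_community()].
#' @param donor,recipient Link endpoints.
#' @param tank_id,year,census Time key.
#' @return The realized per-capita effect (numeric scalar).
#' @export
analytic_jacobian <- function(truth, donor, recipient, tank_id, year, census) {
  j <- truth$jacobian
  hit <- j$donor == donor & j$recipient == recipient & j$tank_id == tank_id &
    j$year == year & j$census == census
  if (sum(hit) != 1L) {
    stop(sprintf("unknown key (%s->%s, tank=%s, year=%s, census=%s)",
                 donor, recipient, tank_id, year, census))
  }
  j$J[hit]
}

#' Simulate unidirectionally coupled logistic maps as composites
#'
#' The classic cross-mapping test system: `x` evolves autonomously with
#' growth rate `rx`; `y` is forced by `x` with the given coupling.
#' A single trajectory is split into equal-length fragments so the
#' composite machinery (within-fragment embedding) is exercised.
#'
#' @param n_points Total points (default 240).
#' @param rx,ry Logistic growth rates (defaults 3.8 and 3.5).
#' @param coupling Forcing of x on y (default 0.32).
#' @param frag_len Fragment length (default 10).
#' @param obs_sd Observation noise SD added before standardization.
#' @param burn Burn-in steps discarded.
#' @param seed Integer seed.
#' @return List of two `composite_series`: `x` (the driver) and `y` (the
#'   forced variable).
#' @export
simulate_coupled_logistic <- function(n_points = 240L, rx = 3.8, ry = 3.5,
                                      coupling = 0.32, frag_len = 10L,
                                      obs_sd = 0, burn = 100L, seed = 1L) {
  stopifnot(n_points %% frag_len == 0L)
  n <- n_points + burn
  x <- numeric(n); y <- numeric(n)
  with_seed(seed, {
    x[1L] <- stats::runif(1, 0.2, 0.8)
    y[1L] <- stats::runif(1, 0.2, 0.8)
    for (t in seq_len(n - 1L)) {
      x[t + 1L] <- x[t] * (rx - rx * x[t])
      y[t + 1L] <- y[t] * (ry - ry * y[t] - coupling * x[t])
    }
    x <- x[(burn + 1L):n]
    y <- y[(burn + 1L):n]
    if (obs_sd > 0) {
      x <- x + stats::rnorm(n_points, 0, obs_sd)
      y <- y + stats::rnorm(n_points, 0, obs_sd)
    }
  })
  split_frag <- function(v) split(v, rep(seq_len(n_points / frag_len),
                                         each = frag_len))
  list(x = as_composite(unname(split_frag(x)), taxon = "x"),
       y = as_composite(unname(split_frag(y)), taxon = "y"))
}

#' Simulate a link-property / sensitivity experiment with known effects
#'
#' Generates the link-by-year table the sensitivity regression consumes,
#' from a known linear mixed model in which density-independent temporal
#' variability is constructed to destabilize (a dominant positive effect
#' on `ln(1 + |LRR|)`), with weaker effects for the other interaction
#' properties and random intercepts for link and year. Used for parameter
#' recovery checks of [sensitivity_regression()].
#'
#' @param n_links Number of interaction links (default 23).
#' @param years Number of years (default 3).
#' @param beta Named list of true fixed effects: `intercept`, `tv`
#'   (temporal variability), `ms` (mean strength), `idd` (ln IDD
#'   magnitude), `dir` (direction code: negative = +1, positive = -1),
#'   `idd_dir` (interaction), `fn_producer`, `fn_predator` (offsets from
#'   prey).
#' @param sd_link,sd_year,sd_resid Random-effect and residual SDs.
#' @param prop_positive Proportion of links with positive IDD (default
#'   1/3: negative slopes about twice as frequent).
#' @param seed Integer seed.
#' @return List: `data` (for [sensitivity_regression()]) and `beta` (the
#'   generating effects).
#' @export
simulate_property_sensitivity <- function(n_links = 23L, years = 3L,
                                          beta = list(intercept = 0.5,
                                                      tv = 1.5, ms = 0.2,
                                                      idd = -0.05,
                                                      dir = 0.02,
                                                      idd_dir = 0.1,
                                                      fn_producer = 0.05,
                                                      fn_predator = -0.05),
                                          sd_link = 0.15, sd_year = 0.08,
                                          sd_resid = 0.15,
                                          prop_positive = 1 / 3,
                                          seed = 1L) {
  with_seed(seed, {
    tv <- exp(stats::rnorm(n_links, -1.8, 0.8))
    ms <- exp(stats::rnorm(n_links, -2.0, 0.7))
    log_idd <- stats::rnorm(n_links, -2.0, 0.9)
    dir <- ifelse(stats::runif(n_links) < prop_positive, "positive",
                  "negative")
    dircode <- ifelse(dir == "negative", 1, -1)   # sum-to-zero coding
    fn <- sample(c("producer", "prey", "predator"), n_links, replace = TRUE,
                 prob = c(0.2, 0.5, 0.3))
    fneff <- ifelse(fn == "producer", beta$fn_producer,
                    ifelse(fn == "predator", beta$fn_predator, 0))
    u_link <- stats::rnorm(n_links, 0, sd_link)
    u_year <- stats::rnorm(years, 0, sd_year)
    rows <- expand.grid(link = seq_len(n_links), year = seq_len(years))
    i <- rows$link; j <- rows$year
    mu <- beta$intercept + beta$tv * tv[i] + beta$ms * ms[i] +
      beta$idd * log_idd[i] + beta$dir * dircode[i] +
      beta$idd_dir * log_idd[i] * dircode[i] + fneff[i] +
      u_link[i] + u_year[j]
    resp <- mu + stats::rnorm(nrow(rows), 0, sd_resid)
    dat <- data.frame(link = sprintf("L%02d", i),
                      recipient = sprintf("L%02d", i), year = j,
                      response = resp, mean_strength = ms[i],
                      temporal_variability = tv[i], log_idd = log_idd[i],
                      idd_direction = dir[i], recipient_function = fn[i],
                      stringsAsFactors = FALSE)
    list(data = dat, beta = beta)
  })
}
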