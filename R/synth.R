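#' Configuration for the synthetic respirometry dataset
#'
#' Describes the statistical structure of a multi-species, multi-stream
#' respirometry study: species-level random intercepts and slopes around the
#' fixed effects of the plasticity rate model, lognormal body masses, acute
#' exposure temperatures drawn from a fixed set, chronic temperatures
#' spanning a stream gradient, and Gaussian residual noise on log rate.
#' Defaults mirror the field design the package models: 16 species, 9
#' streams spanning 5--20 degrees C, acute exposures at
#' \{5, 10, 15, 20, 25\} degrees C, about 35% species-by-stream occupancy
#' (so not every species occurs in every stream) and ~31 individuals per
#' population, giving roughly 1400 individuals in total.
#'
#' @param n_species,n_streams study dimensions.
#' @param stream_temp_range_C chronic temperature span (degrees C).
#' @param acute_temps_C acute exposure temperatures (degrees C).
#' @param occupancy probability a species occurs in a stream (each species
#'   is guaranteed at least one stream).
#' @param individuals_per_population individuals per species x stream.
#' @param mass_logmean_range span of species mean log body masses (log mg).
#' @param mass_logsd within-species SD of log body mass.
#' @param coefficients generating fixed effects, a
#'   [metabolic_coefficients()] object (default: the packaged plasticity
#'   set).
#' @param sd_intercept,sd_ln_mass,sd_TA,sd_TC species-level random-effect
#'   SDs. Slope SDs default to 25% of the corresponding fixed effect; the
#'   intercept SD defaults to 0.3 log units (25% of an intercept near -11
#'   would imply orders-of-magnitude species scatter).
#' @param re_correlation common pairwise correlation of the random effects.
#' @param residual_sd residual SD of log rate.
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return a list of class `metabolic_sim_config`.
#' @export
metabolic_sim_config <- function(n_species = 16, n_streams = 9,
                                 stream_temp_range_C = c(5, 20),
                                 acute_temps_C = c(5, 10, 15, 20, 25),
                                 occupancy = 0.35,
                                 individuals_per_population = 31,
                                 mass_logmean_range = c(-2, 4),
                                 mass_logsd = 0.5,
                                 coefficients = default_coefficients("plasticity"),
                                 sd_intercept = 0.3,
                                 sd_ln_mass = 0.25 * abs(coefficients$b),
                                 sd_TA = 0.25 * abs(coefficients$E_A),
                                 sd_TC = 0.25 * abs(coefficients$E_C),
                                 re_correlation = 0,
                                 residual_sd = 0.3,
                                 seed = 1L) {
  sds <- c(sd_intercept, sd_ln_mass, sd_TA, sd_TC)
  if (any(sds < 0)) stop("random-effect SDs must be non-negative")
  if (abs(re_correlation) > 1) stop("correlation must lie in [-1, 1]")
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  structure(list(n_species = n_species, n_streams = n_streams,
                 stream_temp_range_C = stream_temp_range_C,
                 acute_temps_C = acute_temps_C, occupancy = occupancy,
                 individuals_per_population = individuals_per_population,
                 mass_logmean_range = mass_logmean_range,
                 mass_logsd = mass_logsd, coefficients = coefficients,
                 re_sds = sds, re_correlation = re_correlation,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "metabolic_sim_config")
}

#' Simulate a respirometry dataset
#'
#' Draws species-level random effects from a multivariate normal around the
#' configured fixed effects, assigns species to streams with the configured
#' occupancy, draws lognormal body masses and acute temperatures, and
#' computes log rates from the plasticity rate model plus species effects
#' and residual noise. The generating truth (fixed effects, realised random
#' effects, assignment) is attached for recovery experiments.
#'
#' @param cfg a [metabolic_sim_config()].
#' @return a data frame of individual measurements (`species`, `stream`,
#'   `mass_mg`, `T_acute_C`, `T_acute_K`, `T_chronic_C`, `T_chronic_K`,
#'   `rate_J_per_h`) with attribute `truth`.
#' @export
simulate_metabolic_dataset <- function(cfg = metabolic_sim_config()) {
  stopifnot(inherits(cfg, "metabolic_sim_config"))
  set.seed(cfg$seed)
  co <- cfg$coefficients
  ns <- cfg$n_species; nw <- cfg$n_streams
  stream_temps <- seq(cfg$stream_temp_range_C[1], cfg$stream_temp_range_C[2],
                      length.out = nw)
  # unstructured random-effect covariance with common correlation
  R <- matrix(cfg$re_correlation, 4, 4); diag(R) <- 1
  Sigma <- diag(cfg$re_sds) %*% R %*% diag(cfg$re_sds)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("random-effect covariance is not positive semi-definite")
  u <- MASS::mvrnorm(ns, mu = rep(0, 4), Sigma = Sigma)
  occ <- matrix(runif(ns * nw) < cfg$occupancy, ns, nw)
  none <- rowSums(occ) == 0
  occ[cbind(which(none), sample.int(nw, sum(none), replace = TRUE))] <- TRUE
  mass_mu <- runif(ns, cfg$mass_logmean_range[1], cfg$mass_logmean_range[2])
  rows <- list()
  for (s in seq_len(ns)) for (w in which(occ[s, ])) {
    ni <- cfg$individuals_per_population
    ln_mass <- rnorm(ni, mass_mu[s], cfg$mass_logsd)
    T_acute_C <- sample(cfg$acute_temps_C, ni, replace = TRUE)
    TA <- arrhenius_temp(celsius_to_kelvin(T_acute_C))
    TC <- arrhenius_temp(celsius_to_kelvin(stream_temps[w]))
    ln_rate <- predict_ln_rate(co, ln_mass, TA, TC) +
      u[s, 1] + u[s, 2] * ln_mass + u[s, 3] * TA + u[s, 4] * TC +
      rnorm(ni, 0, cfg$residual_sd)
    rows[[length(rows) + 1]] <- data.frame(
      species = sprintf("sp%02d", s), stream = sprintf("st%02d", w),
      mass_mg = exp(ln_mass), T_acute_C = T_acute_C,
      T_acute_K = celsius_to_kelvin(T_acute_C),
      T_chronic_C = stream_temps[w],
      T_chronic_K = celsius_to_kelvin(stream_temps[w]),
      rate_J_per_h = exp(ln_rate))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(coefficients = co, random_effects = u,
                             occupancy = occ, stream_temps_C = stream_temps,
                             config = cfg)
  out
}

#' Configuration for synthetic food webs
#'
#' Niche-ordered webs with basal plants and detritus, consumers feeding on
#' lower-ranked nodes, body mass increasing with niche position and
#' biomass declining with body mass by a power law. Stands in for empirical
#' stream webs in tests and simulation experiments.
#'
#' @param n_nodes number of nodes.
#' @param basal_fraction fraction of nodes that are basal (at least one
#'   plant and one detritus pool are always present).
#' @param connectance probability that a candidate (lower-ranked) node is a
#'   resource of a consumer.
#' @param mass_range_log10 span of log10 body masses (mg) across the niche
#'   axis.
#' @param biomass_exponent power-law exponent of biomass against body mass
#'   (negative: large organisms are rarer).
#' @param biomass_scale biomass (mg m^-2) of a 1 mg node.
#' @param fish_top make the highest-ranked consumer a fish.
#' @param seed integer seed.
#' @return a list of class `web_sim_config`.
#' @export
web_sim_config <- function(n_nodes = 20, basal_fraction = 0.3,
                           connectance = 0.3, mass_range_log10 = c(-3, 1),
                           biomass_exponent = -0.25, biomass_scale = 100,
                           fish_top = TRUE, seed = 1L) {
  if (connectance <= 0 || connectance >= 1) stop("connectance must lie in (0, 1)")
  n_basal <- max(2, round(basal_fraction * n_nodes))
  if (n_basal >= n_nodes) stop("no consumers left; lower basal_fraction")
  structure(list(n_nodes = n_nodes, n_basal = n_basal,
                 connectance = connectance,
                 mass_range_log10 = mass_range_log10,
                 biomass_exponent = biomass_exponent,
                 biomass_scale = biomass_scale, fish_top = fish_top,
                 seed = as.integer(seed)),
            class = "web_sim_config")
}

#' Simulate a solvable food web
#'
#' Generates a niche-ordered acyclic web per the configuration and
#' rejection-samples (up to `max_attempts`) until the flux balance is
#' feasible at reference conditions with the packaged plasticity
#' coefficients. Deterministic given the seed.
#'
#' @param cfg a [web_sim_config()].
#' @param max_attempts rejection-sampling budget.
#' @return a [food_web()].
#' @export
simulate_web <- function(cfg = web_sim_config(), max_attempts = 1000) {
  stopifnot(inherits(cfg, "web_sim_config"))
  set.seed(cfg$seed)
  for (attempt in seq_len(max_attempts)) {
    web <- try(build_web_once(cfg), silent = TRUE)
    if (inherits(web, "try-error")) next
    feasible <- tryCatch({
      Z <- metabolic_losses(web, default_coefficients("plasticity"), 0, 0)
      e <- assimilation_efficiencies(web, T_REF_K)
      w <- biomass_preferences(web)
      sol <- solve_fluxes(web, flux_parameters(web, Z, e, w))
      TRUE
    }, error = function(err) FALSE)
    if (feasible) return(web)
  }
  stop("no feasible web found in ", max_attempts,
       " attempts; adjust the configuration (connectance or basal fraction)")
}

build_web_once <- function(cfg) {
  n <- cfg$n_nodes; nb <- cfg$n_basal
  niche <- sort(runif(n))
  lg10 <- cfg$mass_range_log10
  body_mass <- 10^(lg10[1] + (lg10[2] - lg10[1]) * niche + rnorm(n, 0, 0.2))
  biomass <- cfg$biomass_scale * body_mass^cfg$biomass_exponent *
    exp(rnorm(n, 0, 0.3))
  type <- rep("invertebrate", n)
  type[seq_len(nb)] <- rep(c("plant", "detritus"), length.out = nb)
  if (cfg$fish_top) type[n] <- "fish"
  A <- matrix(0, n, n)
  for (j in (nb + 1):n) {
    cand <- seq_len(j - 1)
    links <- cand[runif(length(cand)) < cfg$connectance]
    if (!length(links)) links <- sample(cand, 1)
    A[links, j] <- 1
  }
  nodes <- data.frame(label = sprintf("n%02d", seq_len(n)),
                      resource_type = type,
                      biomass_mg_m2 = biomass, body_mass_mg = body_mass)
  food_web(nodes, A)
}

#' Simulate a paired animal/control oxygen trace
#'
#' 330-sample 1 Hz dissolved-oxygen traces: the animal chamber declines at
#' `true_rate` (plus any shared sensor drift), the control carries the drift
#' alone, and Gaussian noise is added to both.
#'
#' @param true_rate_umol_h true oxygen consumption, umol O2 h^-1 (>= 0).
#' @param volume_L chamber volume (litres).
#' @param noise_sd Gaussian noise SD on concentration (umol L^-1).
#' @param drift_umol_L_s shared linear drift of concentration per second.
#' @param o2_init initial concentration (umol L^-1).
#' @param n_samples trace length (default 330).
#' @param seed optional integer seed.
#' @return list with `animal` and `control` [oxygen_trace()] objects.
#' @export
simulate_o2_trace <- function(true_rate_umol_h, volume_L, noise_sd = 0,
                              drift_umol_L_s = 0, o2_init = 300,
                              n_samples = 330, seed = NULL) {
  if (true_rate_umol_h < 0) stop("true rate must be non-negative")
  if (volume_L <= 0) stop("volume must be positive")
  if (!is.null(seed)) set.seed(seed)
  t_s <- seq_len(n_samples) - 1
  decline <- true_rate_umol_h / volume_L / 3600   # umol L^-1 s^-1
  animal <- o2_init - (decline - drift_umol_L_s) * t_s + rnorm(n_samples, 0, noise_sd)
  control <- o2_init + drift_umol_L_s * t_s + rnorm(n_samples, 0, noise_sd)
  list(animal = oxygen_trace(t_s, animal, volume_L, is_control = FALSE),
       control = oxygen_trace(t_s, control, volume_L, is_control = TRUE))
}
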