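# small synthetic dataset for fast mixed-model tests
small_sim <- function(seed = 1, n_species = 8, ipp = 20, residual_sd = 0.3) {
  simulate_metabolic_dataset(metabolic_sim_config(
    n_species = n_species, n_streams = 6, individuals_per_population = ipp,
    occupancy = 0.6, residual_sd = residual_sd, seed = seed))
}

test_that("fixed-structure enumeration matches a brute-force marginality filter", {
  cands <- enumerate_fixed_structures()
  terms_all <- c("ln_mass", "TA", "TC",
                 "ln_mass:TA", "ln_mass:TC", "TA:TC", "ln_mass:TA:TC")
  # independent brute force over all 2^7 subsets: a term is admissible only
  # when every non-empty strict subset of its factors is also present
  subterms <- function(tm) {
    parts <- strsplit(tm, ":")[[1]]
    if (length(parts) == 1) return(character(0))
    unlist(lapply(seq_len(length(parts) - 1), function(k)
      apply(combn(parts, k), 2, paste, collapse = ":")))
  }
  count <- 0
  kept <- list()
  for (mask in 0:127) {
    terms <- terms_all[bitwAnd(mask, 2^(0:6)) > 0]
    if (all(unlist(lapply(terms, subterms)) %in% terms)) {
      count <- count + 1
      kept[[count]] <- terms
    }
  }
  expect_equal(length(cands), count)
  # the classical count for three factors under full marginality is 19
  expect_equal(count, 19)
  expect_true(all(vapply(cands, function(x)
    plastflux:::terms_respect_marginality(x), logical(1))))
  expect_error(fit_lmm(small_sim(), c("ln_mass:TC")), "marginality")
})

test_that("the AIC identity holds exactly for every candidate fit", {
  d <- prepare_lmm_data(small_sim(2))
  for (rt in list(NULL, c("intercept"), c("intercept", "ln_mass"))) {
    f <- fit_lmm(d, c("ln_mass", "TA", "TC"), rt, method = "ML")
    expect_equal(f$aic, -2 * f$logLik + 2 * f$n_params, tolerance = 1e-12)
    expect_equal(f$aic, AIC(f$model), tolerance = 1e-8)
    expect_true(all(f$coefficients$se > 0))
  }
})

test_that("zero-noise data without random effects are recovered to numerical precision", {
  d <- small_sim(3, residual_sd = 0)
  cfg <- attr(d, "truth")$config
  # strip the species effects by regenerating with zero random SDs
  d0 <- simulate_metabolic_dataset(metabolic_sim_config(
    n_species = 8, n_streams = 6, individuals_per_population = 20,
    occupancy = 0.6, residual_sd = 0, sd_intercept = 0, sd_ln_mass = 0,
    sd_TA = 0, sd_TC = 0, seed = 3))
  f <- suppressWarnings(fit_lmm(prepare_lmm_data(d0),
               c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"), NULL))
  co <- as_metabolic_coefficients(f)
  truth <- default_coefficients("plasticity")
  for (nm in c("ln_I0", "b", "E_A", "E_C", "b_C", "E_AC")) {
    expect_equal(co[[nm]], truth[[nm]], tolerance = 1e-8)
  }
})

test_that("single-species data cannot support a species random effect", {
  d <- small_sim(4)
  d1 <- d[d$species == d$species[1], ]
  expect_error(fit_lmm(prepare_lmm_data(d1), c("ln_mass", "TA"), c("intercept")),
               "at least 2 species")
})

test_that("ML AIC ordering is invariant to rescaling the response units", {
  d <- prepare_lmm_data(small_sim(5))
  cands <- list(c("ln_mass", "TA"), c("ln_mass", "TA", "TC"),
                c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"))
  aic1 <- vapply(cands, function(ft)
    fit_lmm(d, ft, c("intercept"), "ML")$aic, 0)
  d2 <- d
  d2$ln_rate <- d2$ln_rate + log(1000)   # e.g. mJ instead of J
  aic2 <- vapply(cands, function(ft)
    fit_lmm(d2, ft, c("intercept"), "ML")$aic, 0)
  expect_equal(order(aic1), order(aic2))
  expect_equal(aic1, aic2, tolerance = 1e-6)
})

test_that("random-structure selection finds strong species effects and rejects absent ones", {
  d_strong <- simulate_metabolic_dataset(metabolic_sim_config(
    n_species = 12, n_streams = 6, individuals_per_population = 25,
    occupancy = 0.6, sd_intercept = 0.8, sd_ln_mass = 0.3, sd_TA = 0.4,
    sd_TC = 0.15, residual_sd = 0.2, seed = 6))
  sel <- select_random_structure(prepare_lmm_data(d_strong))
  expect_setequal(sel$random_terms, c("intercept", "ln_mass", "TA", "TC"))
  d_none <- simulate_metabolic_dataset(metabolic_sim_config(
    n_species = 12, n_streams = 6, individuals_per_population = 25,
    occupancy = 0.6, sd_intercept = 0, sd_ln_mass = 0, sd_TA = 0,
    sd_TC = 0, residual_sd = 0.3, seed = 7))
  sel0 <- select_random_structure(prepare_lmm_data(d_none))
  tab <- sel0$table
  expect_lt(tab$aic[tab$random_terms == ""] - min(tab$aic), 3)
})

test_that("fixed-structure selection recovers the generating term set and refits with REML", {
  d <- simulate_metabolic_dataset(metabolic_sim_config(seed = 8))
  sel <- select_fixed_structure(prepare_lmm_data(d),
                                c("intercept", "ln_mass", "TA", "TC"))
  expect_setequal(sel$fixed_terms,
                  c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"))
  expect_identical(sel$fit$method, "REML")
  expect_equal(nrow(sel$table), length(enumerate_fixed_structures()))
  # estimates near the generating values (strong design)
  co <- as_metabolic_coefficients(sel$fit)
  truth <- default_coefficients("plasticity")
  est <- unlist(co[c("b", "E_A", "E_C", "b_C", "E_AC")])
  se <- sel$fit$coefficients$se[match(c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"),
                                      sel$fit$coefficients$term)]
  tru <- unlist(truth[c("b", "E_A", "E_C", "b_C", "E_AC")])
  expect_true(all(abs(est - tru) < 4 * se))
})

test_that("AIC ties are broken towards the fewest parameters", {
  tab <- data.frame(aic = c(100.0, 99.8, 103.5), k_params = c(5, 7, 4))
  expect_equal(plastflux:::aic_winner(tab), 1)   # within 2 of min, fewer params
  tab2 <- data.frame(aic = c(100.0, 96.0), k_params = c(5, 7))
  expect_equal(plastflux:::aic_winner(tab2), 2)  # clear winner stands
})

test_that("partial residuals isolate the requested term", {
  d0 <- simulate_metabolic_dataset(metabolic_sim_config(
    n_species = 6, n_streams = 5, individuals_per_population = 15,
    occupancy = 0.8, residual_sd = 0, sd_intercept = 0, sd_ln_mass = 0,
    sd_TA = 0, sd_TC = 0, seed = 9))
  dd <- prepare_lmm_data(d0)
  f <- suppressWarnings(
    fit_lmm(dd, c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"), NULL))
  co <- as_metabolic_coefficients(f)
  pr <- partial_residuals(f, "ln_mass")
  # zero noise: partial residuals sit exactly on the mass effect line
  expect_equal(pr, co$b * dd$ln_mass + co$b_C * dd$ln_mass * dd$TC,
               tolerance = 1e-8)
  expect_error(partial_residuals(f, "ln_mass:TA"), "not in the fitted model")
  # full-model residuals sum to ~0
  expect_lt(abs(sum(residuals(f$model))), 1e-6)
})

test_that("partial residual slopes are invariant to intercept shifts of the response", {
  d <- prepare_lmm_data(small_sim(10))
  f1 <- fit_lmm(d, c("ln_mass", "TA"), c("intercept"))
  d2 <- d
  d2$ln_rate <- d2$ln_rate + 2.5
  f2 <- fit_lmm(d2, c("ln_mass", "TA"), c("intercept"))
  pr1 <- partial_residuals(f1, "ln_mass")
  pr2 <- partial_residuals(f2, "ln_mass")
  expect_equal(pr1, pr2, tolerance = 1e-6)
})

test_that("fixed-effect bias shrinks as the sample grows", {
  # species effects limited to the intercept so the slope error is
  # residual-driven and must shrink roughly as 1/sqrt(n)
  sizes <- c(200, 800, 3200)
  err <- vapply(sizes, function(n) {
    ipp <- max(4, round(n / (16 * 9 * 0.35)))
    d <- simulate_metabolic_dataset(metabolic_sim_config(
      individuals_per_population = ipp, sd_ln_mass = 0, sd_TA = 0, sd_TC = 0,
      seed = 1000 + n))
    f <- fit_lmm(prepare_lmm_data(d),
                 c("ln_mass", "TA", "TC", "ln_mass:TC", "TA:TC"),
                 c("intercept"))
    co <- as_metabolic_coefficients(f)
    abs(co$E_A - 0.7217)
  }, 0)
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.02)
})
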