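test_that("biomass preferences are proportional shares that sum to one", {
  nodes <- data.frame(label = c("a", "b", "c"),
                      resource_type = c("plant", "detritus", "invertebrate"),
                      biomass_mg_m2 = c(30, 70, 5), body_mass_mg = c(NA, NA, 2))
  A <- matrix(0, 3, 3); A[1, 3] <- 1; A[2, 3] <- 1
  w <- biomass_preferences(food_web(nodes, A))
  expect_equal(w[1, 3], 0.3)
  expect_equal(w[2, 3], 0.7)
  # single-resource consumer gets weight 1
  sol_web <- chain_web()
  w1 <- biomass_preferences(sol_web)
  expect_equal(w1[1, 2], 1)
  # random webs: per-consumer sums are exactly 1
  for (s in 1:5) {
    web <- random_feasible_web(100 + s)
    wr <- biomass_preferences(web)
    cons <- !web$nodes$is_basal
    expect_equal(unname(colSums(wr)[cons]), rep(1, sum(cons)), tolerance = 1e-12)
  }
})

test_that("food web validation enforces structure", {
  nodes <- data.frame(label = c("a", "b"),
                      resource_type = c("plant", "invertebrate"),
                      biomass_mg_m2 = c(10, 5), body_mass_mg = c(NA, 1))
  A0 <- matrix(0, 2, 2)
  expect_error(food_web(nodes, A0), "without any resource")
  A_self <- A0; A_self[2, 2] <- 1
  expect_error(food_web(nodes, A_self), "self-loop")
  A <- A0; A[1, 2] <- 1
  nodes_bad <- nodes; nodes_bad$biomass_mg_m2[1] <- -1
  expect_error(food_web(nodes_bad, A), "biomass")
  nodes_bad2 <- nodes; nodes_bad2$resource_type[1] <- "algae"
  expect_error(food_web(nodes_bad2, A), "resource_type")
})

test_that("assimilation efficiencies respond to temperature through the logit link", {
  web <- chain_web()
  cfg <- efficiency_config()
  # zero sensitivity: base values at any temperature
  e_flat <- assimilation_efficiencies(web, 300, efficiency_config(E_eff = 0))
  expect_equal(e_flat[1, 2], 0.545)
  expect_equal(e_flat[2, 3], 0.906)
  # positive sensitivity: strictly increasing in T on every link
  temps <- seq(275, 300, by = 5)
  es <- vapply(temps, function(Tk) assimilation_efficiencies(web, Tk, cfg)[1, 2], 0)
  expect_true(all(diff(es) > 0))
  expect_true(all(es > 0 & es < 1))
  # configured ordering animal > plant > detritus preserved at all temperatures
  for (Tk in temps) {
    e <- stats::plogis(stats::qlogis(cfg$base) + cfg$E_eff * arrhenius_temp(Tk, cfg$T0))
    expect_true(e[["invertebrate"]] > e[["plant"]])
    expect_true(e[["plant"]] > e[["detritus"]])
  }
})

test_that("metabolic losses scale rate-at-mean-mass by areal density", {
  nodes <- data.frame(label = c("p", "c"),
                      resource_type = c("plant", "invertebrate"),
                      biomass_mg_m2 = c(10, 1), body_mass_mg = c(NA, 1))
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  web <- food_web(nodes, A)
  co <- default_coefficients("plasticity")
  Z <- metabolic_losses(web, co, 0, 0)
  expect_equal(unname(Z["c"]), exp(-11.03), tolerance = 1e-12)
  expect_equal(unname(Z["p"]), 0)
  # doubling biomass doubles Z
  nodes2 <- nodes; nodes2$biomass_mg_m2[2] <- 2
  Z2 <- metabolic_losses(food_web(nodes2, A), co, 0, 0)
  expect_equal(unname(Z2["c"]), 2 * unname(Z["c"]))
  # zeroed plasticity terms match the plain model
  a <- metabolic_coefficients(-11, 0.6, 0.7, 0, 0, 0, plasticity = TRUE)
  b <- metabolic_coefficients(-11, 0.6, 0.7, plasticity = FALSE)
  expect_equal(metabolic_losses(web, a, 0.5, 1.2), metabolic_losses(web, b, 0.5, 1.2))
})

test_that("the 3-node chain solves to the hand-computed fluxes", {
  web <- chain_web()
  sol <- solve_fluxes(web, chain_params())
  # x_C = 0.5 / 0.9; x_H = (1 + x_C) / 0.5
  expect_equal(unname(sol$x["C"]), 0.5 / 0.9, tolerance = 1e-12)
  expect_equal(unname(sol$x["H"]), (1 + 0.5 / 0.9) / 0.5, tolerance = 1e-12)
  expect_equal(total_flux(sol), 0.5 * (1 + 0.5 / 0.9) / 0.5 + 0.9 * 0.5 / 0.9,
               tolerance = 1e-12)
  expect_equal(total_flux(sol), 2.0556, tolerance = 1e-4)
  dec <- trophic_decomposition(sol)
  expect_equal(unname(dec["F_H"]), 1.5556, tolerance = 1e-4)
  expect_equal(unname(dec["F_D"]), 0)
  expect_equal(unname(dec["F_P"]), 0.5, tolerance = 1e-12)
})

test_that("a top consumer with no predators balances exactly at Z / ebar", {
  nodes <- data.frame(label = c("p", "c"),
                      resource_type = c("plant", "invertebrate"),
                      biomass_mg_m2 = c(10, 1), body_mass_mg = c(NA, 1))
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  web <- food_web(nodes, A)
  e <- matrix(0, 2, 2); e[1, 2] <- 0.5
  params <- flux_parameters(web, c(0, 2), e, biomass_preferences(web))
  sol <- solve_fluxes(web, params)
  expect_equal(unname(sol$x["c"]), 2 / 0.5, tolerance = 1e-12)
  # assimilated gain balances the loss exactly: F = Z
  expect_equal(total_flux(sol), 2, tolerance = 1e-12)
})

test_that("random feasible webs agree with the fixed-point oracle and conserve energy", {
  for (s in 1:20) {
    web <- random_feasible_web(200 + s)
    params <- default_flux_params(web)
    sol <- solve_fluxes(web, params)
    cons <- !web$nodes$is_basal
    # energy balance residuals
    expect_lt(max(abs(sol$residual[cons])), 1e-8 * max(params$Z, 1))
    # independent damped fixed-point solution
    x_fp <- fixed_point_fluxes(web, params)
    expect_equal(unname(sol$x), x_fp, tolerance = 1e-6)
    # partition identity
    dec <- trophic_decomposition(sol)
    expect_equal(sum(dec), total_flux(sol), tolerance = 1e-10)
    # total flux equals summed consumer gains
    expect_equal(total_flux(sol), sum(sol$gain), tolerance = 1e-10)
    expect_true(all(sol$F >= 0))
  }
})

test_that("fluxes are scale-equivariant and monotone in consumer losses", {
  web <- random_feasible_web(42, n_nodes = 10)
  params <- default_flux_params(web)
  sol <- solve_fluxes(web, params)
  # scaling all Z by c scales all fluxes by c
  c_scale <- 3.7
  params2 <- flux_parameters(web, c_scale * params$Z, params$e, params$w)
  sol2 <- solve_fluxes(web, params2)
  expect_equal(sol2$F, c_scale * sol$F, tolerance = 1e-10)
  expect_equal(total_flux(sol2), c_scale * total_flux(sol), tolerance = 1e-10)
  # raising one consumer's Z never lowers total flux
  cons <- which(!web$nodes$is_basal)
  for (i in cons[1:min(3, length(cons))]) {
    Z3 <- params$Z
    Z3[i] <- Z3[i] * 1.5
    sol3 <- solve_fluxes(web, flux_parameters(web, Z3, params$e, params$w))
    expect_gte(total_flux(sol3), total_flux(sol) - 1e-12)
  }
})

test_that("webs with only detritivores have zero herbivory and predation flux", {
  nodes <- data.frame(label = c("d", "x", "y"),
                      resource_type = c("detritus", "invertebrate", "invertebrate"),
                      biomass_mg_m2 = c(100, 5, 5), body_mass_mg = c(NA, 1, 2))
  A <- matrix(0, 3, 3); A[1, 2] <- 1; A[1, 3] <- 1
  web <- food_web(nodes, A)
  sol <- solve_fluxes(web, default_flux_params(web))
  dec <- trophic_decomposition(sol)
  expect_equal(unname(dec["F_H"]), 0)
  expect_equal(unname(dec["F_P"]), 0)
  expect_gt(unname(dec["F_D"]), 0)
})

test_that("infeasible and invalid parameterisations fail loudly", {
  web <- chain_web()
  e <- matrix(0, 3, 3); e[1, 2] <- 0.5; e[2, 3] <- 0.9
  w <- biomass_preferences(web)
  expect_error(flux_parameters(web, c(0, 0, 0.5), e, w), "zero loss")
  expect_error(flux_parameters(web, c(0, -1, 0.5), e, w), "non-negative")
  e_bad <- e; e_bad[1, 2] <- 1.5
  expect_error(flux_parameters(web, c(0, 1, 0.5), e_bad, w), "\\(0, 1\\]")
  w_bad <- w; w_bad[1, 2] <- 0.5
  expect_error(flux_parameters(web, c(0, 1, 0.5), e, w_bad), "sum to 1")
})

test_that("a mutual-predation loop with weak assimilation has no steady state", {
  # a eats p and b; b eats a; tiny efficiencies make the cycle demand exceed
  # what the cycle can supply, so the balance solution turns negative
  nodes <- data.frame(label = c("p", "a", "b"),
                      resource_type = c("plant", "invertebrate", "invertebrate"),
                      biomass_mg_m2 = c(1, 1, 1), body_mass_mg = c(NA, 1, 1))
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1; A[3, 2] <- 1; A[2, 3] <- 1
  web <- food_web(nodes, A)
  e <- A * 0.05
  w <- biomass_preferences(web)
  expect_error(solve_fluxes(web, flux_parameters(web, c(0, 0.1, 0.1), e, w)),
               "no feasible steady state")
})
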