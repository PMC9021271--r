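# shared fixtures: the 3-node chain web, its hand-solved parameters, and an
# independent damped fixed-point flux solver used as an oracle

chain_web <- function() {
  nodes <- data.frame(
    label = c("P", "H", "C"),
    resource_type = c("plant", "invertebrate", "invertebrate"),
    biomass_mg_m2 = c(100, 50, 10),
    body_mass_mg = c(NA, 1, 10))
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1  # plant -> herbivore
  A[2, 3] <- 1  # herbivore -> consumer
  food_web(nodes, A)
}

chain_params <- function(web = chain_web(), Z_H = 1, Z_C = 0.5,
                         e_plant = 0.5, e_animal = 0.9) {
  e <- matrix(0, 3, 3)
  e[1, 2] <- e_plant
  e[2, 3] <- e_animal
  flux_parameters(web, Z = c(0, Z_H, Z_C), e = e, w = biomass_preferences(web))
}

# damped fixed-point iteration on x_i = (Z_i + sum_j w_ij x_j) / ebar_i,
# independent of the package's direct linear solve
fixed_point_fluxes <- function(web, params, damping = 0.5,
                               tol = 1e-12, max_iter = 100000) {
  A <- web$adjacency
  cons <- which(!web$nodes$is_basal)
  e <- params$e; w <- params$w; Z <- params$Z
  ebar <- colSums(e * w)[cons]
  Wcc <- w[cons, cons, drop = FALSE] * A[cons, cons, drop = FALSE]
  x <- Z[cons] / ebar
  for (i in seq_len(max_iter)) {
    x_new <- (Z[cons] + as.numeric(Wcc %*% x)) / ebar
    x_next <- (1 - damping) * x + damping * x_new
    if (max(abs(x_next - x)) < tol * max(1, max(abs(x_next)))) {
      x <- x_next
      break
    }
    x <- x_next
  }
  xall <- numeric(nrow(A))
  xall[cons] <- x
  xall
}

# brute-force exact signed-rank null: literally enumerate all 2^n sign
# assignments of the given ranks
brute_force_signrank_p <- function(V, ranks, alternative = "less") {
  n <- length(ranks)
  stopifnot(n <= 14)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% ranks)
  switch(alternative,
         less = mean(Vs <= V + 1e-12),
         greater = mean(Vs >= V - 1e-12))
}

random_feasible_web <- function(seed, n_nodes = NULL) {
  cfg <- web_sim_config(n_nodes = if (is.null(n_nodes)) sample(4:12, 1) else n_nodes,
                        seed = seed)
  simulate_web(cfg)
}

default_flux_params <- function(web, TA = 0, TC = 0) {
  Z <- metabolic_losses(web, default_coefficients("plasticity"), TA, TC)
  e <- assimilation_efficiencies(web, 283.15)
  w <- biomass_preferences(web)
  flux_parameters(web, Z, e, w)
}
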