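RESOURCE_TYPES <- c("plant", "detritus", "invertebrate", "fish")

#' Construct and validate a food web
#'
#' A food web couples a node table (one row per species or resource pool)
#' with a binary adjacency matrix whose entry (i, j) is 1 when node i is a
#' resource of consumer j. Plants and detritus are basal (they consume
#' nothing here); every non-basal node must have at least one resource;
#' self-loops are not allowed.
#'
#' @param nodes data frame with columns `label`, `resource_type` (one of
#'   `plant`, `detritus`, `invertebrate`, `fish`), `biomass_mg_m2` (> 0) and
#'   `body_mass_mg` (> 0 for consumers).
#' @param adjacency binary matrix, rows = resources, columns = consumers,
#'   dimnames matching `nodes$label` (a numeric matrix without dimnames is
#'   accepted when its order matches the node table).
#' @return an object of class `food_web` with elements `nodes` (including a
#'   derived `is_basal` column) and `adjacency`.
#' @export
food_web <- function(nodes, adjacency) {
  need <- c("label", "resource_type", "biomass_mg_m2", "body_mass_mg")
  missing <- setdiff(need, names(nodes))
  if (length(missing)) stop("node table lacks columns: ", paste(missing, collapse = ", "))
  n <- nrow(nodes)
  nodes$label <- as.character(nodes$label)
  if (anyDuplicated(nodes$label)) stop("duplicated node labels")
  bad_type <- !nodes$resource_type %in% RESOURCE_TYPES
  if (any(bad_type)) {
    stop("unknown resource_type at node row(s) ",
         paste(which(bad_type), collapse = ", "), " (",
         paste(unique(nodes$resource_type[bad_type]), collapse = ", "), ")")
  }
  bad_b <- !is.finite(nodes$biomass_mg_m2) | nodes$biomass_mg_m2 <= 0
  if (any(bad_b)) stop("non-positive biomass at node row(s) ",
                       paste(which(bad_b), collapse = ", "))
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == n)) stop("adjacency must be ", n, " x ", n)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (is.null(dimnames(adjacency))) {
    dimnames(adjacency) <- list(nodes$label, nodes$label)
  } else {
    if (!identical(rownames(adjacency), nodes$label) ||
        !identical(colnames(adjacency), nodes$label)) {
      adjacency <- adjacency[nodes$label, nodes$label]
    }
  }
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  nodes$is_basal <- nodes$resource_type %in% c("plant", "detritus")
  if (any(colSums(adjacency)[nodes$is_basal] > 0)) {
    stop("basal nodes (plants, detritus) cannot have resources")
  }
  no_res <- !nodes$is_basal & colSums(adjacency) == 0
  if (any(no_res)) {
    stop("consumer(s) without any resource: ",
         paste(nodes$label[no_res], collapse = ", "))
  }
  bad_m <- !nodes$is_basal & (!is.finite(nodes$body_mass_mg) | nodes$body_mass_mg <= 0)
  if (any(bad_m)) stop("non-positive body mass on consumer(s): ",
                       paste(nodes$label[bad_m], collapse = ", "))
  structure(list(nodes = nodes, adjacency = adjacency), class = "food_web")
}

#' @exportS3Method base::print
print.food_web <- function(x, ...) {
  cat(sprintf("Food web: %d nodes (%d basal), %d links\n",
              nrow(x$nodes), sum(x$nodes$is_basal), sum(x$adjacency)))
  print(table(x$nodes$resource_type))
  invisible(x)
}

#' Biomass-proportional feeding preferences
#'
#' Each consumer's preference for a resource is that resource's share of the
#' summed biomass of all its resources: `w_ij = B_i / sum(B_k, k in R_j)`.
#' Preferences of every consumer sum to one.
#'
#' @param web a [food_web()].
#' @return matrix of the same shape as the adjacency, zero off the links.
#' @export
biomass_preferences <- function(web) {
  stopifnot(inherits(web, "food_web"))
  A <- web$adjacency
  B <- web$nodes$biomass_mg_m2
  w <- A * B            # column j holds resource biomasses of consumer j
  tot <- colSums(w)
  consumers <- colSums(A) > 0
  w[, consumers] <- sweep(w[, consumers, drop = FALSE], 2, tot[consumers], "/")
  w
}

#' Assimilation-efficiency configuration
#'
#' Base efficiencies per resource type at the reference temperature plus a
#' thermal sensitivity on the logit scale. Defaults follow the published
#' syntheses conventionally used for flux models (animal prey assimilated
#' most efficiently, detritus least); they are not package estimates and are
#' fully overridable.
#'
#' @param e_plant,e_detritus,e_invertebrate,e_fish base efficiencies in
#'   (0, 1] at the reference temperature.
#' @param E_eff thermal sensitivity (eV) of logit efficiency against
#'   standardised temperature.
#' @param T0 reference temperature (kelvin) at which the bases apply.
#' @return a list of class `efficiency_config`.
#' @export
efficiency_config <- function(e_plant = 0.545, e_detritus = 0.158,
                              e_invertebrate = 0.906, e_fish = 0.906,
                              E_eff = 0.164, T0 = T_REF_K) {
  e <- c(plant = e_plant, detritus = e_detritus,
         invertebrate = e_invertebrate, fish = e_fish)
  if (any(e <= 0 | e > 1)) stop("base efficiencies must lie in (0, 1]")
  structure(list(base = e, E_eff = E_eff, T0 = T0), class = "efficiency_config")
}

#' Temperature-dependent assimilation efficiencies
#'
#' The efficiency of a trophic link depends only on the resource's type and
#' on temperature, through a logit-linear Arrhenius response:
#' `logit(e) = logit(e_base[type]) + E_eff * (T - T0)/(k T T0)`. The logistic
#' back-transform keeps efficiencies inside (0, 1) and preserves the ordering
#' of the configured bases at every temperature.
#'
#' @param web a [food_web()].
#' @param temp_K temperature in kelvin at which links operate.
#' @param config an [efficiency_config()].
#' @return matrix of per-link efficiencies (zero off the links).
#' @export
assimilation_efficiencies <- function(web, temp_K, config = efficiency_config()) {
  stopifnot(inherits(web, "food_web"), inherits(config, "efficiency_config"))
  types <- web$nodes$resource_type
  missing <- setdiff(unique(types), names(config$base))
  if (length(missing)) stop("efficiency config lacks type(s): ",
                            paste(missing, collapse = ", "))
  Tstd <- arrhenius_temp(temp_K, T0 = config$T0)
  e_node <- plogis(qlogis(config$base[types]) + config$E_eff * Tstd)
  web$adjacency * e_node   # recycles down rows: resource i sets its links
}

#' Per-node metabolic losses
#'
#' The population-level energy loss of each consumer node, taking the
#' individual metabolic rate predicted at the node's mean body mass and
#' scaling it to areal density: `Z = exp(ln I) * biomass / body_mass`
#' (J h^-1 m^-2). Basal nodes get zero. The alternative mass-specific
#' convention (`per_mg = TRUE`) multiplies the per-mg rate at the mean body
#' mass by the biomass instead.
#'
#' @param web a [food_web()].
#' @param coeffs a [metabolic_coefficients()] object.
#' @param TA,TC standardised acute and chronic temperatures (scalars).
#' @param per_mg use the mass-specific convention (default `FALSE`).
#' @return named vector of per-node losses Z.
#' @export
metabolic_losses <- function(web, coeffs, TA, TC, per_mg = FALSE) {
  stopifnot(inherits(web, "food_web"))
  nodes <- web$nodes
  Z <- numeric(nrow(nodes))
  cons <- !nodes$is_basal
  ln_I <- predict_ln_rate(coeffs, log(nodes$body_mass_mg[cons]), TA, TC)
  Z[cons] <- if (per_mg) {
    exp(ln_I) / nodes$body_mass_mg[cons] * nodes$biomass_mg_m2[cons]
  } else {
    exp(ln_I) * nodes$biomass_mg_m2[cons] / nodes$body_mass_mg[cons]
  }
  setNames(Z, nodes$label)
}

#' Bundle and validate flux parameters
#'
#' @param web a [food_web()].
#' @param Z per-node losses (J h^-1 m^-2); zero allowed only on basal nodes.
#' @param e per-link assimilation efficiencies in (0, 1].
#' @param w per-link preferences; each consumer's column must sum to 1
#'   within 1e-12.
#' @return a list of class `flux_parameters`.
#' @export
flux_parameters <- function(web, Z, e, w) {
  stopifnot(inherits(web, "food_web"))
  A <- web$adjacency
  cons <- !web$nodes$is_basal
  if (length(Z) != nrow(A)) stop("Z must have one entry per node")
  if (any(Z < 0)) stop("losses Z must be non-negative")
  if (any(Z[cons] == 0)) stop("zero loss on consumer node(s): ",
                              paste(web$nodes$label[cons & Z == 0], collapse = ", "))
  if (any((e[A == 1] <= 0) | (e[A == 1] > 1))) stop("link efficiencies must lie in (0, 1]")
  wsum <- colSums(w)[cons]
  if (any(abs(wsum - 1) > 1e-12)) {
    stop("preferences of consumer(s) do not sum to 1: ",
         paste(web$nodes$label[cons][abs(wsum - 1) > 1e-12], collapse = ", "))
  }
  structure(list(Z = Z, e = e, w = w), class = "flux_parameters")
}

#' Solve the steady-state energy-flux balance
#'
#' At energetic steady state every consumer's assimilated gain equals its
#' metabolic loss plus its losses to predation. Writing `x_j` for consumer
#' j's total ingoing feeding rate, each link's feeding rate is
#' `F_ij = w_ij x_j` and the balance for consumer i reads
#' `ebar_i x_i - sum(w_ij x_j, j in C_i) = Z_i` with
#' `ebar_i = sum(e_ki w_ki, k in R_i)`. This linear system is solved
#' directly; a solution with any negative flux means no steady state exists
#' for the given parameters and is reported as an infeasibility error naming
#' the offending nodes.
#'
#' @param web a [food_web()].
#' @param params a [flux_parameters()] bundle.
#' @return an object of class `flux_solution`: per-link feeding rates `F`
#'   and assimilated fluxes `ewF` (matrices), per-node `gain`, `loss` and
#'   `residual`, the per-consumer total influx `x`, and the inputs.
#' @export
solve_fluxes <- function(web, params) {
  stopifnot(inherits(web, "food_web"), inherits(params, "flux_parameters"))
  A <- web$adjacency
  cons <- which(!web$nodes$is_basal)
  nc <- length(cons)
  if (nc == 0) stop("web has no consumers")
  e <- params$e; w <- params$w; Z <- params$Z
  ebar <- colSums(e * w)[cons]                 # mean efficiency per consumer
  M <- diag(ebar, nc, nc)
  # subtract predation losses: consumer i (row) preyed on by consumer j (col)
  M <- M - (w[cons, cons, drop = FALSE] * A[cons, cons, drop = FALSE])
  x <- tryCatch(solve(M, Z[cons]),
                error = function(err) stop("flux balance system is singular: ",
                                           conditionMessage(err)))
  tol <- 1e-10 * max(abs(x), 1)
  if (any(x < -tol)) {
    stop("no feasible steady state: negative influx for node(s) ",
         paste(web$nodes$label[cons][x < -tol], collapse = ", "))
  }
  x <- pmax(x, 0)
  xall <- numeric(nrow(A)); xall[cons] <- x
  Fmat <- sweep(w * A, 2, xall, "*")
  ewF <- e * Fmat
  gain <- colSums(ewF)
  pred_loss <- rowSums(Fmat)
  loss <- Z + pred_loss
  residual <- gain - loss
  residual[web$nodes$is_basal] <- NA_real_   # basal balance is implicit
  structure(list(F = Fmat, ewF = ewF, x = setNames(xall, web$nodes$label),
                 gain = setNames(gain, web$nodes$label),
                 loss = setNames(loss, web$nodes$label),
                 residual = setNames(residual, web$nodes$label),
                 params = params, web = web),
            class = "flux_solution")
}

#' @exportS3Method base::print
print.flux_solution <- function(x, ...) {
  cat(sprintf("Flux solution: %d links, total flux %.4g J h^-1 m^-2, max |residual| %.2e\n",
              sum(x$F > 0), total_flux(x), max(abs(x$residual), na.rm = TRUE)))
  invisible(x)
}

#' Total energy flux through a web
#'
#' The sum of assimilated fluxes `e * w * F` over all links -- a whole-web
#' measure of multitrophic functioning, expected to track ecosystem
#' respiration.
#'
#' @param sol a [solve_fluxes()] solution.
#' @return total flux (J h^-1 m^-2).
#' @export
total_flux <- function(sol) {
  stopifnot(inherits(sol, "flux_solution"))
  sum(sol$ewF)
}

#' Decompose total flux by trophic group
#'
#' Partitions the assimilated link fluxes by the resource's type: fluxes out
#' of plants feed herbivory (`F_H`), out of detritus feed detritivory
#' (`F_D`), and out of animal resources feed predation (`F_P`). The three
#' components sum exactly to the total flux.
#'
#' @param sol a [solve_fluxes()] solution.
#' @return named vector `c(F_H, F_D, F_P)`.
#' @export
trophic_decomposition <- function(sol) {
  stopifnot(inherits(sol, "flux_solution"))
  types <- sol$web$nodes$resource_type
  out_by_node <- rowSums(sol$ewF)
  c(F_H = sum(out_by_node[types == "plant"]),
    F_D = sum(out_by_node[types == "detritus"]),
    F_P = sum(out_by_node[types %in% c("invertebrate", "fish")]))
}
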