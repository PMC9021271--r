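#' Warming-scenario comparison for one food web
#'
#' Solves the flux balance at baseline and under a warming scenario for two
#' metabolic models. The no-plasticity model responds to warming through the
#' acute temperature only (`TA + dT`); the plasticity model additionally
#' experiences the warmed chronic temperature (`TC + dT`), engaging its
#' chronic-temperature terms. Assimilation efficiencies are evaluated at the
#' baseline acute temperature by default (the scenario perturbs the
#' metabolic equations); set `warm_efficiencies = TRUE` for a sensitivity
#' variant where link efficiencies also feel the warming.
#'
#' @param web a [food_web()].
#' @param coeffs_plastic,coeffs_fixed coefficient sets for the plasticity and
#'   no-plasticity models, see [metabolic_coefficients()].
#' @param T_acute_K,T_chronic_K baseline acute and chronic temperatures
#'   (kelvin).
#' @param dT_C warming increment in degrees C (= kelvin), default 2.
#' @param eff_config an [efficiency_config()].
#' @param warm_efficiencies re-evaluate efficiencies at the warmed
#'   temperature (default `FALSE`).
#' @param per_mg passed to [metabolic_losses()].
#' @return an object of class `warming_comparison`: a data frame with one
#'   row per model (`plastic`, `fixed`) holding `F_baseline`, `F_warmed`,
#'   `dF`, and trophic components `dF_H`, `dF_D`, `dF_P`; the scenario
#'   settings are attached as attributes.
#' @export
warming_scenario <- function(web, coeffs_plastic, coeffs_fixed,
                             T_acute_K, T_chronic_K, dT_C = 2,
                             eff_config = efficiency_config(),
                             warm_efficiencies = FALSE, per_mg = FALSE) {
  stopifnot(inherits(web, "food_web"))
  TA0 <- arrhenius_temp(T_acute_K)
  TC0 <- arrhenius_temp(T_chronic_K)
  TA1 <- arrhenius_temp(T_acute_K + dT_C)
  TC1 <- arrhenius_temp(T_chronic_K + dT_C)
  e0 <- assimilation_efficiencies(web, T_acute_K, eff_config)
  e1 <- if (warm_efficiencies) {
    assimilation_efficiencies(web, T_acute_K + dT_C, eff_config)
  } else e0
  w <- biomass_preferences(web)

  solve_at <- function(coeffs, TA, TC, e, stage, model) {
    Z <- metabolic_losses(web, coeffs, TA, TC, per_mg = per_mg)
    tryCatch(solve_fluxes(web, flux_parameters(web, Z, e, w)),
             error = function(err) {
               stop("flux solve failed for the ", model, " model at the ",
                    stage, " temperature: ", conditionMessage(err))
             })
  }
  specs <- list(
    plastic = list(coeffs = coeffs_plastic, TC_base = TC0, TC_warm = TC1),
    fixed   = list(coeffs = coeffs_fixed,   TC_base = TC0, TC_warm = TC0))
  out <- do.call(rbind, lapply(names(specs), function(m) {
    sp <- specs[[m]]
    base <- solve_at(sp$coeffs, TA0, sp$TC_base, e0, "baseline", m)
    warm <- solve_at(sp$coeffs, TA1, sp$TC_warm, e1, "warmed", m)
    tb <- trophic_decomposition(base)
    tw <- trophic_decomposition(warm)
    data.frame(model = m,
               F_baseline = total_flux(base), F_warmed = total_flux(warm),
               dF = total_flux(warm) - total_flux(base),
               dF_H = tw[["F_H"]] - tb[["F_H"]],
               dF_D = tw[["F_D"]] - tb[["F_D"]],
               dF_P = tw[["F_P"]] - tb[["F_P"]])
  }))
  rownames(out) <- NULL
  structure(out, class = c("warming_comparison", "data.frame"),
            dT_C = dT_C, T_acute_K = T_acute_K, T_chronic_K = T_chronic_K)
}

# exact null counts of the signed-rank statistic for the given ranks: the
# distribution over all 2^n sign assignments, accumulated rank by rank
# (identical to brute-force enumeration, organised as a convolution);
# ranks are doubled internally so that midranks (.5) stay integral
signrank_null_counts <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  counts <- rep(0, sum(r2) + 1)   # index v+1 holds count of 2V == v
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Computes the signed-rank statistic V (sum of the ranks of positive
#' differences) and its exact one-sided or two-sided p-value from the full
#' enumeration of all `2^n` sign assignments of the ranks. Zero differences
#' are dropped before ranking (classical convention; the count is reported);
#' tied absolute differences receive midranks, in which case the enumeration
#' is conditional on the observed midranks and the result is flagged
#' `exact = FALSE` with a warning. For `n > 25` a normal approximation with
#' continuity correction is used instead.
#'
#' Alternatively, pass a precomputed statistic via `V` and `n` (tie-free
#' ranks 1..n assumed).
#'
#' @param differences numeric vector of paired differences, or `NULL` when
#'   `V` and `n` are given.
#' @param alternative `"less"` (small V; default), `"greater"` or
#'   `"two.sided"`.
#' @param V,n optional: the statistic and pair count in place of raw
#'   differences.
#' @return an object of class `wilcoxon_exact`: list with `V`, `n`, `p`,
#'   `alternative`, `exact`, `n_zero_dropped`.
#' @export
wilcoxon_exact <- function(differences = NULL,
                           alternative = c("less", "greater", "two.sided"),
                           V = NULL, n = NULL) {
  alternative <- match.arg(alternative)
  n_zero <- 0L
  if (is.null(differences)) {
    if (is.null(V) || is.null(n)) stop("supply either differences or both V and n")
    if (n < 1) stop("n must be at least 1")
    if (V < 0 || V > n * (n + 1) / 2) stop("V outside [0, n(n+1)/2]")
    ranks <- seq_len(n)
    exact_ok <- TRUE
  } else {
    d <- differences[!is.na(differences)]
    n_zero <- sum(d == 0)
    d <- d[d != 0]
    if (!length(d)) stop("all paired differences are zero")
    ranks <- rank(abs(d))
    ties <- anyDuplicated(ranks) > 0
    V <- sum(ranks[d > 0])
    n <- length(d)
    exact_ok <- !ties
    if (ties) warning("ties in |differences|: midranks used, p-value is not exact")
  }
  maxV <- n * (n + 1) / 2
  if (n <= 25) {
    counts <- signrank_null_counts(ranks)
    total <- 2^n
    v2 <- round(2 * V)
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p_ge <- sum(counts[(v2 + 1):length(counts)]) / total
  } else {
    mu <- maxV / 2
    sigma <- sqrt(sum(ranks^2) / 4)
    p_le <- pnorm((V + 0.5 - mu) / sigma)
    p_ge <- pnorm((V - 0.5 - mu) / sigma, lower.tail = FALSE)
    exact_ok <- FALSE
  }
  p <- switch(alternative,
              less = p_le, greater = p_ge,
              two.sided = min(1, 2 * min(p_le, p_ge)))
  structure(list(V = V, n = n, p = p, alternative = alternative,
                 exact = exact_ok && n <= 25, n_zero_dropped = n_zero),
            class = "wilcoxon_exact")
}

#' @exportS3Method base::print
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank test (%s): V = %g, n = %d, p = %.4g%s\n",
              x$alternative, x$V, x$n, x$p,
              if (x$exact) " (exact)" else " (approximate)"))
  if (x$n_zero_dropped > 0) cat("  zero differences dropped:", x$n_zero_dropped, "\n")
  invisible(x)
}

#' Relative amplification of the warming response by plasticity
#'
#' For each web, the warming-induced flux change of the plasticity model
#' relative to the no-plasticity model,
#' `a = 100 * (dF_plastic - dF_fixed) / dF_fixed` (percent), summarised as
#' mean and standard error across webs. Webs where the no-plasticity change
#' is not positive have undefined amplification; they are excluded and
#' reported.
#'
#' @param comparisons a list of [warming_scenario()] results.
#' @return list with `mean`, `se`, `n`, per-web `amplification`, and
#'   `excluded` (indices of webs with non-positive fixed-model response).
#' @export
amplification_summary <- function(comparisons) {
  if (length(comparisons) < 2) stop("need at least 2 webs")
  dF <- t(vapply(comparisons, function(cmp) {
    stopifnot(inherits(cmp, "warming_comparison"))
    c(plastic = cmp$dF[cmp$model == "plastic"], fixed = cmp$dF[cmp$model == "fixed"])
  }, c(plastic = 0, fixed = 0)))
  bad <- dF[, "fixed"] <= 0
  a <- 100 * (dF[!bad, "plastic"] - dF[!bad, "fixed"]) / dF[!bad, "fixed"]
  if (length(a) < 2) stop("fewer than 2 webs with a positive no-plasticity response")
  list(mean = mean(a), se = sd(a) / sqrt(length(a)), n = length(a),
       amplification = a, excluded = which(bad))
}

#' Compare warming responses across an ensemble of webs
#'
#' Assembles per-web flux changes for both models, tests whether the
#' plasticity model's change exceeds the no-plasticity model's (one-sided
#' paired Wilcoxon on the differences `fixed - plastic`, alternative
#' `"less"`) for total flux and each trophic component, and summarises the
#' relative amplification.
#'
#' @param comparisons a list of [warming_scenario()] results.
#' @return list with `deltas` (per-web data frame), `tests` (named list of
#'   [wilcoxon_exact()] results for `total`, `herbivory`, `detritivory`,
#'   `predation`) and `amplification` ([amplification_summary()]).
#' @export
compare_warming <- function(comparisons) {
  grab <- function(cmp, col) {
    c(plastic = cmp[[col]][cmp$model == "plastic"],
      fixed = cmp[[col]][cmp$model == "fixed"])
  }
  cols <- c(total = "dF", herbivory = "dF_H", detritivory = "dF_D",
            predation = "dF_P")
  deltas <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    data.frame(web = i, model = cmp$model, dF = cmp$dF, dF_H = cmp$dF_H,
               dF_D = cmp$dF_D, dF_P = cmp$dF_P)
  }))
  tests <- lapply(cols, function(col) {
    d <- vapply(comparisons, function(cmp) {
      v <- grab(cmp, col); v[["fixed"]] - v[["plastic"]]
    }, 0)
    wilcoxon_exact(d, alternative = "less")
  })
  list(deltas = deltas, tests = tests,
       amplification = amplification_summary(comparisons))
}
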