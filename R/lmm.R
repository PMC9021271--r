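FIXED_TERMS_ALL <- c("ln_mass", "TA", "TC",
                     "ln_mass:TA", "ln_mass:TC", "TA:TC", "ln_mass:TA:TC")
RANDOM_TERMS_ALL <- c("intercept", "ln_mass", "TA", "TC")

#' Prepare individual measurements for mixed-effects modelling
#'
#' Adds the modelling columns: `ln_rate` (log J h^-1), `ln_mass` (log mg),
#' and the standardised Arrhenius temperatures `TA` (acute) and `TC`
#' (chronic), and coerces `species` and `stream` to factors. Idempotent.
#'
#' @param data a data frame with columns `species`, `stream`, `mass_mg`,
#'   `T_acute_K`, `T_chronic_K`, `rate_J_per_h`.
#' @param T0,k Arrhenius standardisation constants, see [arrhenius_temp()].
#' @return the data frame with modelling columns appended.
#' @export
prepare_lmm_data <- function(data, T0 = T_REF_K, k = BOLTZMANN_EV) {
  need <- c("species", "stream", "mass_mg", "T_acute_K", "T_chronic_K",
            "rate_J_per_h")
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("data lacks columns: ", paste(missing, collapse = ", "))
  if (any(data$mass_mg <= 0) || any(data$rate_J_per_h <= 0)) {
    stop("masses and rates must be positive")
  }
  data$species <- factor(data$species)
  data$stream <- factor(data$stream)
  data$ln_rate <- log(data$rate_J_per_h)
  data$ln_mass <- log(data$mass_mg)
  data$TA <- arrhenius_temp(data$T_acute_K, T0, k)
  data$TC <- arrhenius_temp(data$T_chronic_K, T0, k)
  data
}

# marginality principle: every interaction requires all of its lower-order
# terms (main effects, and for the three-way also the three two-ways)
terms_respect_marginality <- function(terms) {
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      for (k in seq_len(length(parts) - 1)) {
        subs <- utils::combn(parts, k, paste, collapse = ":")
        if (!all(subs %in% terms)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Enumerate candidate fixed-effect structures
#'
#' All subsets of the seven candidate terms (three main effects of log mass,
#' acute and chronic temperature, their three two-way interactions, and the
#' three-way interaction) that respect the marginality principle: an
#' interaction never enters without all of its lower-order terms. The
#' intercept is always included.
#'
#' @return a list of character vectors of term labels.
#' @export
enumerate_fixed_structures <- function() {
  n <- length(FIXED_TERMS_ALL)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    terms <- FIXED_TERMS_ALL[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (terms_respect_marginality(terms)) out[[length(out) + 1]] <- terms
  }
  out
}

build_formula <- function(fixed_terms, random_terms, diagonal = FALSE) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  if (length(random_terms)) {
    ri <- if ("intercept" %in% random_terms) "1" else "0"
    slopes <- setdiff(random_terms, "intercept")
    rterms <- paste(c(ri, slopes), collapse = " + ")
    bar <- if (diagonal) "||" else "|"
    rhs <- paste0(rhs, " + (", rterms, " ", bar, " species)")
  }
  as.formula(paste("ln_rate ~", rhs))
}

#' Fit a (mixed) model of log metabolic rate
#'
#' Fits a Gaussian linear mixed-effects model of `ln_rate` with the requested
#' fixed terms and species-level random terms. With no random terms an
#' ordinary least-squares fit is used (the generalised-least-squares baseline
#' of the random-structure comparison). Mixed fits go through
#' \pkg{lme4}/\pkg{lmerTest}; a singular random-effects covariance is
#' reported as a warning flag on the result, and an optimiser failure is an
#' error carrying the optimiser's own message.
#'
#' @param data prepared data, see [prepare_lmm_data()] (the preparation is
#'   applied automatically when the modelling columns are absent).
#' @param fixed_terms character vector from the candidate set `ln_mass`,
#'   `TA`, `TC`, `ln_mass:TA`, `ln_mass:TC`, `TA:TC`, `ln_mass:TA:TC`; must
#'   respect marginality.
#' @param random_terms character vector from `intercept`, `ln_mass`, `TA`,
#'   `TC` (species-grouped, unstructured covariance), or `NULL`/empty for no
#'   random effects.
#' @param method `"ML"` or `"REML"`.
#' @param satterthwaite compute Satterthwaite p-values for REML fits via
#'   \pkg{lmerTest} (default); disable for speed in simulation loops, in
#'   which case p-values use the normal approximation.
#' @param diagonal_covariance constrain the species-level random-effect
#'   covariance to be diagonal (independent intercept and slopes). The
#'   default is the unstructured covariance the grouped random-effects
#'   formula implies; the diagonal option stabilises hard datasets where
#'   many weakly identified correlations push the fit to the boundary.
#' @return an object of class `plastflux_lmm`: a list with the underlying
#'   `model`, a `coefficients` table (estimate, SE, t, p), `logLik`,
#'   `n_params`, `aic`, `residual_sd`, `singular` flag and the structure
#'   descriptors.
#' @export
fit_lmm <- function(data, fixed_terms = FIXED_TERMS_ALL[1:2],
                    random_terms = NULL, method = c("ML", "REML"),
                    satterthwaite = TRUE, diagonal_covariance = FALSE) {
  method <- match.arg(method)
  if (!all(fixed_terms %in% FIXED_TERMS_ALL)) {
    stop("unknown fixed terms: ",
         paste(setdiff(fixed_terms, FIXED_TERMS_ALL), collapse = ", "))
  }
  if (!terms_respect_marginality(fixed_terms)) {
    stop("fixed terms violate marginality (interaction without its main effects)")
  }
  if (length(random_terms) && !all(random_terms %in% RANDOM_TERMS_ALL)) {
    stop("unknown random terms: ",
         paste(setdiff(random_terms, RANDOM_TERMS_ALL), collapse = ", "))
  }
  if (!all(c("ln_rate", "ln_mass", "TA", "TC") %in% names(data))) {
    data <- prepare_lmm_data(data)
  }
  if (length(random_terms) && nlevels(factor(data$species)) < 2) {
    stop("species-level random effects need at least 2 species")
  }
  fml <- build_formula(fixed_terms, random_terms, diagonal_covariance)
  singular <- FALSE
  if (!length(random_terms)) {
    model <- lm(fml, data = data)
    sm <- summary(model)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        t = sm[, 3], p = sm[, 4], row.names = NULL)
    resid_sd <- summary(model)$sigma
  } else {
    # ML fits feed AIC scans where only the likelihood matters, so the cheap
    # lme4 fit with normal-approximation p-values is used; the REML
    # reporting fit carries Satterthwaite p-values via lmerTest
    fitter <- if (method == "REML" && satterthwaite) lmerTest::lmer else lme4::lmer
    model <- withCallingHandlers(
      fitter(fml, data = data, REML = (method == "REML"),
             control = lme4::lmerControl(
               calc.derivs = FALSE,
               check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("singular", conditionMessage(w), ignore.case = TRUE)) {
          invokeRestart("muffleWarning")
        }
      })
    conv <- model@optinfo$conv$opt
    if (!is.null(conv) && conv != 0) {
      stop("mixed-model optimiser failed to converge (code ", conv, "): ",
           paste(unlist(model@optinfo$message), collapse = "; "))
    }
    singular <- lme4::isSingular(model)
    sm <- if (method == "REML" && satterthwaite) {
      tryCatch({
        s <- summary(model)$coefficients
        if (ncol(s) < 5) NULL else s[, c(1, 2, 4, 5), drop = FALSE]
      }, error = function(e) NULL)
    } else NULL
    if (is.null(sm)) {
      s0 <- if (inherits(model, "lmerModLmerTest")) {
        summary(model, ddf = "lme4")$coefficients
      } else {
        summary(model)$coefficients
      }
      sm <- cbind(s0[, 1:3, drop = FALSE], 2 * pnorm(-abs(s0[, 3])))
    }
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        t = sm[, 3], p = sm[, 4], row.names = NULL)
    resid_sd <- stats::sigma(model)
  }
  ll <- logLik(model)
  k <- attr(ll, "df")
  structure(list(model = model,
                 fixed_terms = fixed_terms,
                 random_terms = random_terms %||% character(0),
                 method = method,
                 coefficients = coefs,
                 logLik = as.numeric(ll),
                 n_params = k,
                 aic = -2 * as.numeric(ll) + 2 * k,
                 residual_sd = resid_sd,
                 singular = singular,
                 n = nrow(data)),
            class = "plastflux_lmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.plastflux_lmm <- function(x, ...) {
  cat(sprintf("Log metabolic rate model (%s), n = %d\n", x$method, x$n))
  cat("  fixed:  ~", paste(c("1", x$fixed_terms), collapse = " + "), "\n")
  cat("  random:",
      if (length(x$random_terms)) paste0("~ ", paste(x$random_terms, collapse = " + "),
                                         " | species") else "none", "\n")
  cat(sprintf("  logLik %.2f, k = %d, AIC %.2f%s\n", x$logLik, x$n_params,
              x$aic, if (x$singular) " [singular random covariance]" else ""))
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), t = round(t, 3), p = signif(p, 3)))
  invisible(x)
}

# AIC table with the tie rule: among candidates within `tie_window` AIC of the
# minimum, prefer the fewest parameters (a competitor that cannot improve the
# fit by ~2 AIC per extra parameter is not worth its complexity)
aic_winner <- function(table, tie_window = 2) {
  near <- which(table$aic - min(table$aic) < tie_window)
  near[order(table$k_params[near], table$aic[near])][1]
}

#' Select the random-effects structure by AIC
#'
#' Holds the fixed structure constant (by default the full candidate set) and
#' compares, by maximum-likelihood AIC, a no-random-effect baseline against
#' every subset of the species-level structure
#' `~ 1 + ln_mass + TA + TC | species` that retains the random intercept.
#' Candidates whose fit fails are recorded and dropped from the comparison.
#' Ties within 2 AIC are resolved towards the fewest parameters.
#'
#' @param data see [fit_lmm()].
#' @param fixed_terms fixed structure held constant during the comparison.
#' @param ... further arguments passed to [fit_lmm()] (e.g.
#'   `diagonal_covariance`).
#' @return a list with `random_terms` (winning structure), `table` (the AIC
#'   comparison: structure, k_params, logLik, AIC, dAIC, error) and `fits`.
#' @export
select_random_structure <- function(data, fixed_terms = FIXED_TERMS_ALL, ...) {
  slopes <- c("ln_mass", "TA", "TC")
  cands <- list(character(0))
  for (m in 0:7) {
    cands[[length(cands) + 1]] <- c("intercept", slopes[bitwAnd(m, c(1, 2, 4)) > 0])
  }
  fits <- lapply(cands, function(rt) {
    tryCatch(fit_lmm(data, fixed_terms, rt, method = "ML", ...),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  table <- data.frame(
    random_terms = vapply(cands, function(x) paste(x, collapse = "+"), ""),
    k_params = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else as.numeric(f$n_params), 0),
    logLik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$logLik, 0),
    aic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic, 0),
    error = vapply(fits, function(f) if (inherits(f, "error")) conditionMessage(f) else "", ""))
  if (!any(ok)) stop("no random-structure candidate could be fitted")
  sub <- table[ok, ]
  sub$dAIC <- sub$aic - min(sub$aic)
  win <- aic_winner(sub)
  list(random_terms = cands[ok][[win]], table = sub, fits = fits[ok])
}

#' Select the fixed-effect structure by AIC and refit the winner with REML
#'
#' Enumerates every marginality-respecting combination of the candidate fixed
#' terms (see [enumerate_fixed_structures()]), fits each by maximum
#' likelihood with the given random structure, compares by AIC (ties within
#' 2 AIC resolved to the fewest parameters), and refits the winner with REML
#' for coefficient reporting.
#'
#' @param data see [fit_lmm()].
#' @param random_terms random structure, typically from
#'   [select_random_structure()].
#' @param candidates optional list of term vectors to compare (defaults to
#'   the full marginality-respecting enumeration).
#' @param ... further arguments passed to [fit_lmm()] (e.g.
#'   `diagonal_covariance`, `satterthwaite`).
#' @return a list with `fit` (the REML-refitted winner, a `plastflux_lmm`),
#'   `fixed_terms`, and `table` (model_id, fixed_terms, k_params, logLik,
#'   AIC, dAIC, error).
#' @export
select_fixed_structure <- function(data, random_terms,
                                   candidates = enumerate_fixed_structures(),
                                   ...) {
  if (!all(c("ln_rate", "ln_mass", "TA", "TC") %in% names(data))) {
    data <- prepare_lmm_data(data)
  }
  fits <- lapply(candidates, function(ft) {
    tryCatch(fit_lmm(data, ft, random_terms, method = "ML", ...),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  table <- data.frame(
    model_id = seq_along(candidates),
    fixed_terms = vapply(candidates, function(x) paste(c("1", x), collapse = "+"), ""),
    k_params = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else as.numeric(f$n_params), 0),
    logLik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$logLik, 0),
    aic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic, 0),
    error = vapply(fits, function(f) if (inherits(f, "error")) conditionMessage(f) else "", ""))
  if (!any(ok)) stop("no fixed-structure candidate could be fitted")
  table$dAIC <- NA_real_
  table$dAIC[ok] <- table$aic[ok] - min(table$aic[ok])
  win_ok <- aic_winner(table[ok, ])
  winner_terms <- candidates[ok][[win_ok]]
  fit <- fit_lmm(data, winner_terms, random_terms, method = "REML", ...)
  list(fit = fit, fixed_terms = winner_terms, table = table)
}

#' Write a model comparison table to CSV
#'
#' @param table the `table` element of [select_fixed_structure()] or
#'   [select_random_structure()].
#' @param path output file.
#' @export
write_comparison_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Partial residuals for one model term
#'
#' Observed log rate minus every fitted component except those involving the
#' requested variable, with the species random effects removed -- the
#' quantity plotted when visualising a single effect of the mixed model free
#' of species-level noise. Equivalently the model's conditional residuals
#' plus the fitted contribution of all fixed terms involving `wrt`.
#'
#' @param fit a `plastflux_lmm` from [fit_lmm()].
#' @param wrt variable whose effect is retained: one of `ln_mass`, `TA`,
#'   `TC` (or an interaction label present in the model).
#' @return numeric vector, one value per observation.
#' @export
partial_residuals <- function(fit, wrt) {
  stopifnot(inherits(fit, "plastflux_lmm"))
  X <- model.matrix(fit$model)
  labels <- attr(terms(fit$model), "term.labels")
  assign <- attr(X, "assign")
  involves <- vapply(labels, function(lb) {
    wrt %in% strsplit(lb, ":", fixed = TRUE)[[1]] || identical(lb, wrt)
  }, logical(1))
  if (!any(involves)) stop("term '", wrt, "' is not in the fitted model")
  keep_cols <- assign %in% which(involves)
  beta <- if (inherits(fit$model, "lm")) coef(fit$model) else lme4::fixef(fit$model)
  as.numeric(residuals(fit$model) + X[, keep_cols, drop = FALSE] %*% beta[keep_cols])
}

#' Coefficient set from a fitted model
#'
#' Maps a fitted model's fixed effects onto a [metabolic_coefficients()]
#' object (the exchange format the prediction and flux machinery consumes).
#' Only models whose terms are a subset of the six-term plasticity model can
#' be represented.
#'
#' @param fit a `plastflux_lmm`.
#' @return a [metabolic_coefficients()] object.
#' @export
as_metabolic_coefficients <- function(fit) {
  stopifnot(inherits(fit, "plastflux_lmm"))
  map <- c("(Intercept)" = "ln_I0", "ln_mass" = "b", "TA" = "E_A", "TC" = "E_C",
           "ln_mass:TC" = "b_C", "TA:TC" = "E_AC")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  extra <- setdiff(names(est), names(map))
  if (length(extra)) {
    stop("model terms not representable as metabolic coefficients: ",
         paste(extra, collapse = ", "))
  }
  get <- function(nm) if (nm %in% names(est)) unname(est[[nm]]) else 0
  metabolic_coefficients(
    ln_I0 = get("(Intercept)"), b = get("ln_mass"), E_A = get("TA"),
    E_C = get("TC"), b_C = get("ln_mass:TC"), E_AC = get("TA:TC"))
}
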