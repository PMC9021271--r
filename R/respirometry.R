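#' Closed-chamber oxygen trace
#'
#' A single respirometry recording: dissolved-oxygen concentration sampled at
#' (nominally) 1 Hz over about 330 s in a sealed glass chamber, either holding
#' one animal or animal-free (the drift control).
#'
#' @param t_s sample times in seconds, strictly increasing, length >= 2.
#' @param o2_umol_L dissolved oxygen concentration, umol L^-1.
#' @param volume_L chamber volume in litres (> 0).
#' @param is_control logical; `TRUE` for the animal-free control chamber.
#' @return an object of class `oxygen_trace`.
#' @export
oxygen_trace <- function(t_s, o2_umol_L, volume_L, is_control = FALSE) {
  if (length(t_s) < 2) stop("an oxygen trace needs at least 2 samples")
  if (length(o2_umol_L) != length(t_s)) stop("t_s and o2_umol_L lengths differ")
  if (any(diff(t_s) <= 0)) stop("timestamps must be strictly increasing")
  if (!is.numeric(volume_L) || length(volume_L) != 1 || volume_L <= 0) {
    stop("chamber volume must be a single positive number (litres)")
  }
  structure(list(t_s = as.numeric(t_s), o2_umol_L = as.numeric(o2_umol_L),
                 volume_L = volume_L, is_control = isTRUE(is_control)),
            class = "oxygen_trace")
}

#' @exportS3Method base::print
print.oxygen_trace <- function(x, ...) {
  cat(sprintf("Oxygen trace: %d samples over %.0f s, %.4g L chamber%s\n",
              length(x$t_s), diff(range(x$t_s)), x$volume_L,
              if (x$is_control) " (control)" else ""))
  invisible(x)
}

# OLS slope of oxygen concentration against time, umol L^-1 s^-1
trace_slope <- function(trace) {
  fit <- lm(o2_umol_L ~ t_s, data = trace[c("t_s", "o2_umol_L")])
  unname(coef(fit)[2])
}

#' Oxygen trace to individual metabolic rate
#'
#' Oxygen consumption is the slope of the OLS regression of concentration on
#' time through all samples of the animal chamber, scaled by chamber volume
#' and corrected by the volume-scaled slope of the paired animal-free control
#' (sensor drift and microbial background). Output is per hour.
#'
#' A `low_oxygen` flag is attached when the animal trace falls below 70% of
#' its initial concentration (measurements are normally stopped before that
#' to avoid oxygen limitation), and a warning is emitted when the control
#' background exceeds 5% of the animal signal, which suggests chamber
#' contamination.
#'
#' @param animal an [oxygen_trace()] with `is_control = FALSE`.
#' @param control the paired control [oxygen_trace()] with
#'   `is_control = TRUE`.
#' @return oxygen consumption rate, umol O2 h^-1, with attributes
#'   `low_oxygen` (logical) and `background_fraction`.
#' @export
trace_to_rate <- function(animal, control) {
  stopifnot(inherits(animal, "oxygen_trace"), inherits(control, "oxygen_trace"))
  if (animal$is_control) stop("'animal' trace is flagged as a control")
  if (!control$is_control) stop("'control' trace is not flagged as a control")
  slope_a <- trace_slope(animal) * animal$volume_L    # umol s^-1
  slope_c <- trace_slope(control) * control$volume_L
  rate <- -(slope_a - slope_c) * 3600                 # consumption, umol h^-1
  low_o2 <- min(animal$o2_umol_L) < 0.7 * animal$o2_umol_L[1]
  bg <- if (slope_a != 0) abs(slope_c) / abs(slope_a) else Inf
  if (is.finite(bg) && bg > 0.05 && abs(slope_c) > 0) {
    warning(sprintf("control background is %.1f%% of the animal signal (> 5%%)",
                    100 * bg))
  }
  structure(rate, low_oxygen = low_o2, background_fraction = bg)
}

#' Per-population mass-temperature regressions
#'
#' Fits, for every population (species x stream combination), the ordinary
#' least squares regression of log metabolic rate on log body mass and
#' standardised acute temperature -- the log form of the classical
#' Boltzmann--Arrhenius model. The fits feed the quality-control filter
#' ([qc_filter()]); populations with fewer than 3 usable rows cannot be fitted
#' and are reported with `NA` statistics.
#'
#' @param data a data frame of individual measurements with columns `species`,
#'   `stream`, `mass_mg`, `T_acute_K` and `rate_J_per_h` (the layout produced
#'   by [read_measurements()] and [simulate_metabolic_dataset()]).
#' @param T0,k Arrhenius standardisation constants, see [arrhenius_temp()].
#' @return a data frame with one row per population: `species`, `stream`,
#'   `n`, `r2`, `p_mass`, `p_temp`, `worst_p`.
#' @export
population_regressions <- function(data, T0 = T_REF_K, k = BOLTZMANN_EV) {
  need <- c("species", "stream", "mass_mg", "T_acute_K", "rate_J_per_h")
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("data lacks columns: ", paste(missing, collapse = ", "))
  key <- interaction(data$species, data$stream, drop = TRUE, sep = "\r")
  out <- lapply(split(data, key), function(d) {
    res <- data.frame(species = d$species[1], stream = d$stream[1],
                      n = nrow(d), r2 = NA_real_,
                      p_mass = NA_real_, p_temp = NA_real_, worst_p = NA_real_)
    if (nrow(d) < 3) return(res)
    df <- data.frame(ln_rate = log(d$rate_J_per_h),
                     ln_mass = log(d$mass_mg),
                     TA = arrhenius_temp(d$T_acute_K, T0, k))
    # a population measured at a single acute temperature has no estimable
    # temperature slope; treat as unfittable under the two-term model
    if (length(unique(df$TA)) < 2 || length(unique(df$ln_mass)) < 2) return(res)
    fit <- lm(ln_rate ~ ln_mass + TA, data = df)
    sm <- summary(fit)
    pv <- sm$coefficients[c("ln_mass", "TA"), "Pr(>|t|)"]
    res$r2 <- sm$r.squared
    res$p_mass <- pv[["ln_mass"]]
    res$p_temp <- pv[["TA"]]
    res$worst_p <- max(pv)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Population-level quality-control filter
#'
#' Excludes poor-quality populations before mixed-effects modelling. The
#' criteria are: fewer than 10 individuals, regression r-squared below 0.5,
#' or any slope term (log mass, acute temperature) with p above 0.05. By
#' default a population failing ANY criterion is excluded (`rule = "any"`);
#' `rule = "all"` excludes only populations failing all three. Unfittable
#' populations (`NA` statistics) always fail the r2/p criteria.
#'
#' @param fits output of [population_regressions()] on `data`.
#' @param data the individual-level data the fits were computed from.
#' @param rule `"any"` (default) or `"all"`; how the three criteria combine.
#' @param n_min,r2_min,p_max criterion thresholds.
#' @return a list with `kept` (the filtered individual-level data) and
#'   `report` (per-population data frame with `excluded` and `reasons`).
#' @export
qc_filter <- function(fits, data, rule = c("any", "all"),
                      n_min = 10, r2_min = 0.5, p_max = 0.05) {
  rule <- match.arg(rule)
  fail_n <- fits$n < n_min
  fail_r2 <- is.na(fits$r2) | fits$r2 < r2_min
  fail_p <- is.na(fits$worst_p) | fits$worst_p > p_max
  excluded <- if (rule == "any") fail_n | fail_r2 | fail_p else fail_n & fail_r2 & fail_p
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "n" else NULL, if (b) "r2" else NULL, if (c) "p" else NULL),
          collapse = "+")
  }, fail_n, fail_r2, fail_p)
  report <- cbind(fits, excluded = excluded,
                  reasons = ifelse(excluded, reasons, ""))
  bad <- paste(fits$species, fits$stream, sep = "\r")[excluded]
  keep <- !(paste(data$species, data$stream, sep = "\r") %in% bad)
  list(kept = data[keep, , drop = FALSE], report = report)
}

#' Write a QC exclusion report to CSV
#'
#' @param report the `report` element of [qc_filter()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
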