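#' Great-circle distance matrix from site coordinates
#'
#' Spherical-earth (haversine) distances between sites, equatorial radius
#' 6378.137 km.
#'
#' @param coords data frame with columns `site`, `lat`, `lon` (decimal
#'   degrees).
#' @return symmetric distance matrix in km with zero diagonal, dimnames from
#'   `site`.
#' @export
great_circle_matrix <- function(coords) {
  need <- c("site", "lat", "lon")
  missing <- setdiff(need, names(coords))
  if (length(missing)) stop("coords lacks columns: ", paste(missing, collapse = ", "))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)")
  }
  R <- 6378.137
  lat <- coords$lat * pi / 180
  lon <- coords$lon * pi / 180
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(coords$site, coords$site))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      h <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      D[i, j] <- D[j, i] <- 2 * R * asin(pmin(1, sqrt(h)))
    }
  }
  D
}

upper_vec <- function(D) D[upper.tri(D)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a one-sided
#' permutation p-value: rows and columns of the second matrix are permuted
#' jointly and p is the proportion of permutations (the observed arrangement
#' included) whose correlation is at least the observed one. With
#' `exhaustive = TRUE` all `n!` permutations are enumerated (n <= 8) and the
#' p-value is the exact proportion.
#'
#' @param D1,D2 symmetric matrices of equal size, n >= 4.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed for the permutation draw.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with `r`, `p`, `n_perm`, `exhaustive`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (n < 4) stop("need at least 4 sites")
  if (!all(dim(D1) == dim(D2))) stop("matrices differ in size")
  if (!isSymmetric(unname(D1)) || !isSymmetric(unname(D2))) {
    stop("matrices must be symmetric")
  }
  v1 <- upper_vec(D1)
  if (sd(v1) == 0 || sd(upper_vec(D2)) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  r_obs <- cor(v1, upper_vec(D2))
  perm_r <- function(idx) cor(v1, upper_vec(D2[idx, idx]))
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, 0)
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) perm_r(sample(n)), 0)
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1
    out[[k]] <- append(p, n, after = i - 1)
  }
  out
}

#' Inverse-distance spatial weights
#'
#' `w_ij = 1 / d_ij` off the diagonal, zero on it, optionally row
#' standardised to sum to one.
#'
#' @param D distance matrix (positive off-diagonal entries).
#' @param row_standardise divide each row by its sum.
#' @return weight matrix.
#' @export
inverse_distance_weights <- function(D, row_standardise = FALSE) {
  D <- as.matrix(D)
  if (any(D[upper.tri(D)] <= 0)) stop("off-diagonal distances must be positive")
  W <- 1 / D
  diag(W) <- 0
  if (row_standardise) W <- W / rowSums(W)
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' The classical statistic
#' `I = (n / sum(W)) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param weights non-negative weight matrix, zero diagonal, not all zero.
#' @return Moran's I (scalar). Under spatial randomness its expectation is
#'   `-1/(n-1)`.
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  W <- as.matrix(weights)
  if (!all(dim(W) == n)) stop("weights must be ", n, " x ", n)
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("weight diagonal must be zero")
  if (sum(W) == 0) stop("weights are all zero")
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("constant values: Moran's I undefined")
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Permutation test for Moran's I
#'
#' Permutes the values over the sites and reports the one-sided (greater)
#' permutation p-value, observed arrangement included in the null set.
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `I`, `expectation` (`-1/(n-1)`), `p`, `n_perm`.
#' @export
morans_i_test <- function(values, weights, n_perm = 999, seed = NULL) {
  I_obs <- morans_i(values, weights)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  Is <- vapply(seq_len(n_perm), function(i) morans_i(sample(values), weights), 0)
  list(I = I_obs, expectation = -1 / (n - 1),
       p = (1 + sum(Is >= I_obs - 1e-12)) / (n_perm + 1), n_perm = n_perm)
}

#' Empirical semivariogram cloud
#'
#' For every unordered pair of sites, half the squared difference of their
#' residuals against their separation distance. No variogram model is
#' fitted; the cloud is a visual diagnostic for spatial structure in model
#' residuals.
#'
#' @param residuals numeric vector aligned with the rows of `distances`.
#' @param distances symmetric distance matrix.
#' @return data frame with columns `i`, `j`, `distance`, `semivariance`
#'   (`n(n-1)/2` rows).
#' @export
semivariogram_cloud <- function(residuals, distances) {
  D <- as.matrix(distances)
  n <- length(residuals)
  if (!all(dim(D) == n)) stop("residuals and distance matrix sizes differ")
  idx <- which(upper.tri(D), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             distance = D[idx],
             semivariance = 0.5 * (residuals[idx[, 1]] - residuals[idx[, 2]])^2)
}

#' Stream-level residuals of a fitted rate model
#'
#' Conditional residuals of the mixed model (species random effects removed)
#' averaged per stream, for use in the spatial diagnostics where residuals
#' must map one-to-one onto sites.
#'
#' @param fit a `plastflux_lmm` from [fit_lmm()].
#' @param data the data the model was fitted to (for the `stream` column).
#' @return named numeric vector, one mean residual per stream.
#' @export
stream_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "plastflux_lmm"))
  r <- residuals(fit$model)
  tapply(r, data$stream, mean)
}
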