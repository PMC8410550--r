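#' Gaussian kernel
#'
#' The standard-normal density \eqn{K(u) = (2\pi)^{-1/2} e^{-u^2/2}} used as
#' the smoothing kernel throughout.
#'
#' @param u Numeric vector.
#' @return Kernel weights, same length as `u`.
#' @export
gaussian_kernel <- function(u) {
  exp(-0.5 * u^2) / sqrt(2 * pi)
}

# log-kernel weights for query ages q against reference ages x, bandwidth h,
# stabilised per query row by subtracting the row maximum before
# exponentiation. Rows where even the largest raw weight underflows are an
# out-of-support (extrapolation) condition, signalled by the caller.
# Returns list(w = |q| x |x| matrix, ok = logical per row).
kernel_weights <- function(q, x, h) {
  e <- -0.5 * (outer(q, x, "-") / h)^2
  emax <- apply(e, 1L, max)
  ok <- emax > log(.Machine$double.xmin) + 1
  w <- exp(e - ifelse(is.finite(emax), emax, 0))
  list(w = w, ok = ok)
}

stop_extrapolation <- function(age) {
  abort(sprintf(
    "normative model cannot be evaluated at age %.3g: all kernel weights underflow (out of reference support)",
    age[1]), class = "nd_extrapolation_error")
}

#' Construct a normative curve object
#'
#' A fitted reference for one (ROI, modality, sex) stratum: the reference
#' ages and values of the sex-matched controls together with the selected
#' bandwidth. Evaluated lazily at any age via [nw_mean()] and [nw_sd()].
#'
#' @param ages,values Reference ages (years) and measure values (same length).
#' @param bandwidth Kernel bandwidth in years, > 0.
#' @param roi,modality,sex Stratum labels.
#' @param sd_floor Lower bound for the returned SD (modality units); guards
#'   against division by zero for degenerate strata.
#' @return An object of class `nd_curve`.
#' @export
normative_curve <- function(ages, values, bandwidth,
                            roi = NA_character_, modality = NA_character_,
                            sex = NA_character_, sd_floor = 1e-6) {
  stopifnot(length(ages) == length(values), length(ages) >= 1,
            bandwidth > 0, sd_floor > 0)
  structure(
    list(ages = as.numeric(ages), values = as.numeric(values),
         bandwidth = bandwidth, roi = roi, modality = modality, sex = sex,
         sd_floor = sd_floor),
    class = "nd_curve"
  )
}

#' @export
print.nd_curve <- function(x, ...) {
  cat(sprintf("<nd_curve> %s / %s / sex %s: n = %d, h = %.3g years\n",
              x$roi, x$modality, x$sex, length(x$ages), x$bandwidth))
  invisible(x)
}

#' Kernel-weighted normative mean at an age
#'
#' The Nadaraya-Watson estimate
#' \eqn{\hat m_h(x) = \sum_i y_i K((x - x_i)/h) / \sum_i K((x - x_i)/h)},
#' a convex combination of the reference values.
#'
#' @param x Query age(s) in years.
#' @param curve An `nd_curve`.
#' @return Numeric vector of conditional means, one per query age.
#' @export
nw_mean <- function(x, curve) {
  kw <- kernel_weights(x, curve$ages, curve$bandwidth)
  if (!all(kw$ok)) stop_extrapolation(x[!kw$ok])
  drop(kw$w %*% curve$values) / rowSums(kw$w)
}

#' Kernel-weighted normative standard deviation at an age
#'
#' The conditional SD from
#' \eqn{\hat\sigma_h^2(x) = \sum_i (y_i - \hat m_h(x))^2 K((x - x_i)/h) /
#' \sum_i K((x - x_i)/h)}, where the squared deviations use the mean at the
#' same query age. The returned value is floored at `curve$sd_floor`.
#'
#' @inheritParams nw_mean
#' @return Numeric vector of conditional SDs, one per query age.
#' @export
nw_sd <- function(x, curve) {
  kw <- kernel_weights(x, curve$ages, curve$bandwidth)
  if (!all(kw$ok)) stop_extrapolation(x[!kw$ok])
  denom <- rowSums(kw$w)
  m <- drop(kw$w %*% curve$values) / denom
  v <- drop(kw$w %*% (curve$values^2)) / denom - m^2
  pmax(sqrt(pmax(v, 0)), curve$sd_floor)
}

#' Evaluate a normative curve on an age grid
#'
#' @param object An `nd_curve`.
#' @param newdata Numeric vector of ages (default: a 100-point grid spanning
#'   the reference ages).
#' @param ... Unused.
#' @return Tibble with columns `age`, `mean`, `sd`.
#' @export
predict.nd_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- seq(min(object$ages), max(object$ages), length.out = 100)
  }
  tibble::tibble(age = newdata,
                 mean = nw_mean(newdata, object),
                 sd = nw_sd(newdata, object))
}

# leave-one-out CV errors for every column of Y at each bandwidth in grid.
# Y: n x p matrix sharing the age vector; returns |grid| x p matrix of CV(h).
# Terms whose leave-one-out weights all vanish fall back to the mean of the
# remaining values, keeping CV finite at very small bandwidths.
cv_score_matrix <- function(ages, Y, grid) {
  n <- length(ages)
  p <- ncol(Y)
  out <- matrix(NA_real_, length(grid), p)
  d2 <- outer(ages, ages, "-")^2
  colsums <- colSums(Y)
  for (g in seq_along(grid)) {
    e <- -0.5 * d2 / grid[g]^2
    diag(e) <- -Inf
    emax <- apply(e, 1L, max)
    ok <- emax > log(.Machine$double.xmin) + 1
    w <- exp(e - ifelse(is.finite(emax), emax, 0))
    denom <- rowSums(w)
    pred <- (w %*% Y) / denom
    if (any(!ok)) {
      # fallback: mean of the other n-1 values
      fb <- (matrix(colsums, sum(!ok), p, byrow = TRUE) - Y[!ok, , drop = FALSE]) / (n - 1)
      pred[!ok, ] <- fb
    }
    out[g, ] <- colMeans((Y - pred)^2)
  }
  out
}

#' Leave-one-out cross-validation error of the kernel regression
#'
#' \eqn{CV(h) = n^{-1} \sum_j (y_j - \hat m_{h,-j}(x_j))^2}, where
#' \eqn{\hat m_{h,-j}} is the Nadaraya-Watson mean fitted on all reference
#' points except the j-th, evaluated at \eqn{x_j}.
#'
#' @param h Bandwidth (> 0).
#' @param ages,values Reference ages and values (length >= 2).
#' @return The mean squared leave-one-out prediction error.
#' @export
cv_score <- function(h, ages, values) {
  stopifnot(length(ages) >= 2, h > 0)
  drop(cv_score_matrix(ages, cbind(as.numeric(values)), h))
}

#' Default bandwidth search grid
#'
#' 40 log-spaced bandwidths from 0.5 to 50 years, covering under- to
#' over-smoothing for human age ranges.
#'
#' @param n Number of grid points.
#' @param from,to Grid endpoints in years.
#' @return Increasing numeric vector of bandwidths.
#' @export
bandwidth_grid <- function(n = 40, from = 0.5, to = 50) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Select the bandwidth minimising the leave-one-out CV error
#'
#' Exhaustive search over a fixed grid; ties are broken toward the smallest
#' bandwidth. Deterministic given its inputs.
#'
#' @param ages,values Reference ages and values (length >= 3).
#' @param grid Candidate bandwidths (positive; sorted internally).
#' @return The selected bandwidth.
#' @export
select_bandwidth <- function(ages, values, grid = bandwidth_grid()) {
  stopifnot(length(grid) >= 1, all(grid > 0), length(ages) >= 3)
  grid <- sort(grid)
  cv <- drop(cv_score_matrix(ages, cbind(as.numeric(values)), grid))
  if (all(!is.finite(cv))) abort("bandwidth selection failed: CV(h) non-finite on the whole grid")
  grid[which.min(cv)]
}

# grid selection for many ROIs sharing one age vector; returns named vector
select_bandwidth_matrix <- function(ages, Y, grid = bandwidth_grid()) {
  grid <- sort(grid)
  cv <- cv_score_matrix(ages, Y, grid)
  hs <- apply(cv, 2L, function(col) {
    if (all(!is.finite(col))) abort("bandwidth selection failed: CV(h) non-finite on the whole grid")
    grid[which.min(col)]
  })
  stats::setNames(hs, colnames(Y))
}
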