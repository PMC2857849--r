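#' Per-animal quadratic regression of breeding values on time
#'
#' Fits, for every animal, ordinary least squares of EBV on `(1, t, t^2)`
#' over the fitted time points. Internally time is centred and scaled
#' (`u = (t - c)/s`, `c` = mid-range, `s` = half-range) because raw `t^2`
#' values up to ~280,900 give an ill-conditioned design; coefficients are
#' mapped back to the raw-time basis for reporting, so `beta0 + beta1 t +
#' beta2 t^2` reproduces the fit.
#'
#' @param ebv Long-format data frame with columns `id`, `time`, `ebv` (one
#'   row per animal and time point; every animal needs at least 3 distinct
#'   times).
#' @return Tibble with columns `id`, `beta0`, `beta1`, `beta2`.
#' @export
fit_quadratic <- function(ebv) {
  times <- sort(unique(ebv$time))
  if (length(times) < 3) {
    stop("at least 3 distinct time points are required for a quadratic fit",
         call. = FALSE)
  }
  if (anyDuplicated(ebv[, c("id", "time")])) {
    stop("duplicated (id, time) records in the EBV table", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(ebv[, c("id", "time", "ebv")],
                             names_from = "time", values_from = "ebv")
  wide <- wide[, c("id", as.character(times))]
  Y <- as.matrix(wide[, -1]) # animals x times
  if (anyNA(Y)) {
    bad <- wide$id[apply(Y, 1, anyNA)]
    stop("animals without an EBV at every time point: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ctr <- mean(range(times))
  scl <- diff(range(times)) / 2
  u <- (times - ctr) / scl
  X <- cbind(1, u, u^2)
  # scaled-basis coefficients for all animals at once: (X'X)^-1 X' Y'
  Bs <- t(solve(crossprod(X), crossprod(X, t(Y)))) # animals x 3
  # map y = b0 + b1 u + b2 u^2, u = (t - c)/s back to powers of t
  b0 <- Bs[, 1] - Bs[, 2] * ctr / scl + Bs[, 3] * ctr^2 / scl^2
  b1 <- Bs[, 2] / scl - 2 * ctr * Bs[, 3] / scl^2
  b2 <- Bs[, 3] / scl^2
  tibble::tibble(id = wide$id, beta0 = unname(b0), beta1 = unname(b1),
                 beta2 = unname(b2))
}

#' Extrapolate breeding values to a later time point
#'
#' Evaluates each animal's quadratic trajectory at `t_star`:
#' `pred = beta0 + beta1 t_star + beta2 t_star^2`.
#'
#' @param coeffs Tibble from [fit_quadratic()].
#' @param t_star Target time (default 600).
#' @return Tibble with columns `id`, `time`, `pred_bv`.
#' @export
extrapolate <- function(coeffs, t_star = 600) {
  tibble::tibble(
    id = coeffs$id,
    time = t_star,
    pred_bv = coeffs$beta0 + coeffs$beta1 * t_star + coeffs$beta2 * t_star^2
  )
}
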