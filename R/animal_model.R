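#' Estimate variance components by EM-REML under an animal model
#'
#' Fits `y = mu + a + e` with `var(a) = G sigma2_a`, `var(e) = I sigma2_e`,
#' intercept as the only fixed effect, by expectation-maximisation REML. The
#' relationship matrix is reduced to the phenotyped individuals and
#' eigendecomposed once, which makes every EM iteration O(n); the restricted
#' log-likelihood is evaluated exactly at each iterate and is non-decreasing
#' (a property of EM used as an internal check).
#'
#' @param phenotypes Data frame with columns `id` and `value` (one record per
#'   individual; use [fit_time_points()] for a long table with several time
#'   points).
#' @param G A [relmat] covering every phenotyped id; must be positive
#'   definite (apply [bend_to_pd()] first for marker matrices).
#' @param tolerance Relative change in both variance components below which
#'   iteration stops.
#' @param max_iter Maximum EM iterations; hitting it flags non-convergence
#'   and returns the last iterate.
#' @return An object of class `snpblup_reml`: list with `sigma2_a`,
#'   `sigma2_e`, `h2`, `loglik`, `n_iter`, `converged`, `boundary`,
#'   `loglik_trace`, `n` and the data/matrix needed by [solve_blup()].
#' @export
fit_reml <- function(phenotypes, G, tolerance = 1e-6, max_iter = 500L) {
  stopifnot(inherits(G, "snpblup_relmat"))
  ids <- as.character(phenotypes$id)
  if (anyDuplicated(ids)) {
    stop("one record per individual is required (duplicated ids)",
         call. = FALSE)
  }
  if (!all(ids %in% rownames(G))) {
    stop("phenotyped ids absent from the relationship matrix: ",
         paste(utils::head(setdiff(ids, rownames(G)), 5), collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(phenotypes$value)
  n <- length(y)
  if (n < 10) stop("at least 10 phenotyped individuals are required",
                   call. = FALSE)
  Gobs <- unclass_relmat(G)[ids, ids]
  eg <- eigen(Gobs, symmetric = TRUE)
  d <- eg$values
  if (min(d) <= 0) {
    stop("relationship matrix (phenotyped block) is not positive definite ",
         "(min eigenvalue ", format(min(d)), "); bend it first",
         call. = FALSE)
  }
  yt <- crossprod(eg$vectors, y)[, 1]
  xt <- colSums(eg$vectors) # U' 1

  vy <- stats::var(y)
  s2a <- vy / 2
  s2e <- vy / 2
  floor_a <- 1e-10 * vy
  boundary <- FALSE
  ll_trace <- numeric(0)

  reml_parts <- function(s2a, s2e) {
    w <- 1 / (s2a * d + s2e)
    xwx <- sum(w * xt^2)
    xwy <- sum(w * xt * yt)
    beta <- xwy / xwx
    pt <- w * (yt - xt * beta) # transformed Py
    ypy <- sum(yt * pt)
    ll <- -0.5 * ((n - 1) * log(2 * pi) +
                    sum(log(s2a * d + s2e)) + log(xwx) + ypy)
    list(w = w, xwx = xwx, beta = beta, pt = pt, ypy = ypy, ll = ll)
  }

  converged <- FALSE
  iter <- 0L
  parts <- reml_parts(s2a, s2e)
  ll_trace <- parts$ll
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- parts$w
    pt <- parts$pt
    # tr(PG) and tr(P) with P = V^-1 - V^-1 x (x'V^-1 x)^-1 x'V^-1
    tr_pg <- sum(d * w) - sum(d * w^2 * xt^2) / parts$xwx
    tr_p <- sum(w) - sum(w^2 * xt^2) / parts$xwx
    ypgpy <- sum(d * pt^2)
    yppy <- sum(pt^2)
    s2a_new <- s2a + (s2a^2 / n) * (ypgpy - tr_pg)
    s2e_new <- s2e + (s2e^2 / n) * (yppy - tr_p)
    if (s2a_new < floor_a) {
      s2a_new <- floor_a
      boundary <- TRUE
    }
    if (s2e_new <= 0) {
      s2e_new <- 1e-10 * vy
      boundary <- TRUE
    }
    rel <- max(abs(s2a_new - s2a) / max(s2a, floor_a),
               abs(s2e_new - s2e) / s2e)
    s2a <- s2a_new
    s2e <- s2e_new
    parts <- reml_parts(s2a, s2e)
    ll_trace <- c(ll_trace, parts$ll)
    if (rel < tolerance) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      sigma2_a = s2a, sigma2_e = s2e,
      h2 = s2a / (s2a + s2e),
      loglik = parts$ll,
      n_iter = iter, converged = converged, boundary = boundary,
      loglik_trace = ll_trace,
      n = n, ids = ids, y = y, mu = parts$beta,
      tolerance = tolerance
    ),
    class = "snpblup_reml"
  )
}

#' @export
print.snpblup_reml <- function(x, ...) {
  cat(sprintf(
    "<EM-REML animal model fit> n = %d\n  sigma2_a = %.4f  sigma2_e = %.4f  h2 = %.3f\n  logLik = %.3f  (%d iterations, %s)\n",
    x$n, x$sigma2_a, x$sigma2_e, x$h2, x$loglik, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param sigma2_a Additive genetic variance, or a `snpblup_reml` fit.
#' @param sigma2_e Residual variance (ignored when a fit is given).
#' @return Heritability in `[0, 1)`.
#' @export
heritability <- function(sigma2_a, sigma2_e = NULL) {
  if (inherits(sigma2_a, "snpblup_reml")) {
    return(sigma2_a$h2)
  }
  if (any(sigma2_a < 0) || any(sigma2_e < 0)) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  tot <- sigma2_a + sigma2_e
  if (any(tot == 0)) {
    stop("heritability undefined when both components are zero",
         call. = FALSE)
  }
  sigma2_a / tot
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_reml
#' @param x A `snpblup_reml` fit.
#' @param ... Unused.
#' @method tidy snpblup_reml
#' @export
tidy.snpblup_reml <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2_a", "sigma2_e", "mu"),
    estimate = c(x$sigma2_a, x$sigma2_e, x$mu)
  )
}

#' @rdname fit_reml
#' @method glance snpblup_reml
#' @export
glance.snpblup_reml <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
    logLik = x$loglik, n = x$n, n_iter = x$n_iter,
    converged = x$converged, boundary = x$boundary
  )
}

#' Solve the mixed model equations for breeding values of all animals
#'
#' Henderson's mixed model equations for `y = X mu + Z a + e` with `X` a
#' column of ones over phenotyped records, `Z` the incidence of records onto
#' the animals in `G`, and shrinkage `lambda = sigma2_e / sigma2_a`:
#' breeding values are returned for every animal in `G`, including
#' non-phenotyped ones (their information flows through the off-diagonals of
#' `G`). The solution is verified against the right-hand side to a relative
#' residual below 1e-8.
#'
#' @param phenotypes Data frame with columns `id`, `value` (one record per
#'   individual).
#' @param G A positive-definite [relmat] (all animals to be evaluated).
#' @param vc A `snpblup_reml` fit, or a list with `sigma2_a` and `sigma2_e`.
#' @return Tibble with columns `id`, `ebv`, `phenotyped`; the intercept is
#'   attached as attribute `mu`.
#' @export
solve_blup <- function(phenotypes, G, vc) {
  ids_all <- rownames(G)
  ids_ph <- as.character(phenotypes$id)
  if (anyDuplicated(ids_ph)) {
    stop("one record per individual is required (duplicated ids)",
         call. = FALSE)
  }
  if (!all(ids_ph %in% ids_all)) {
    stop("phenotyped ids absent from the relationship matrix", call. = FALSE)
  }
  y <- as.numeric(phenotypes$value)
  n <- length(y)
  N <- length(ids_all)
  s2a <- vc$sigma2_a
  s2e <- vc$sigma2_e
  if (s2a <= 1e-12 * (s2a + s2e)) {
    # infinite shrinkage limit: all breeding values zero
    out <- tibble::tibble(id = ids_all, ebv = 0,
                          phenotyped = ids_all %in% ids_ph)
    attr(out, "mu") <- mean(y)
    return(out)
  }
  lambda <- s2e / s2a
  V <- unclass_relmat(G)
  Ginv <- tryCatch(chol2inv(chol(V)), error = function(e) {
    stop("relationship matrix is singular; bend it first (",
         conditionMessage(e), ")", call. = FALSE)
  })
  obs <- match(ids_ph, ids_all)
  # coefficient matrix: [ n      1'Z       ]
  #                     [ Z'1    Z'Z + λG⁻¹ ]
  C <- matrix(0, N + 1, N + 1)
  C[1, 1] <- n
  zt1 <- numeric(N)
  zt1[obs] <- 1
  C[1, -1] <- zt1
  C[-1, 1] <- zt1
  ZtZ <- diag(zt1)
  C[-1, -1] <- ZtZ + lambda * Ginv
  rhs <- c(sum(y), {
    zy <- numeric(N)
    zy[obs] <- y
    zy
  })
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("mixed model equations are singular (condition estimate ",
         format(1 / rcond(C)), "); check variance components and G",
         call. = FALSE)
  })
  resid <- C %*% sol - rhs
  if (sqrt(sum(resid^2)) > 1e-8 * max(1, sqrt(sum(rhs^2)))) {
    stop("mixed model solution failed the residual check", call. = FALSE)
  }
  out <- tibble::tibble(id = ids_all, ebv = sol[-1],
                        phenotyped = ids_all %in% ids_ph)
  attr(out, "mu") <- sol[1]
  out
}

#' Fit animal models at every time point of a longitudinal phenotype table
#'
#' For each time point, estimates variance components by [fit_reml()] on the
#' phenotyped records and solves for breeding values of all animals in `G`
#' by [solve_blup()].
#'
#' @param phenotypes Long-format data frame with columns `id`, `time`,
#'   `value`.
#' @param G A positive-definite [relmat].
#' @param tolerance,max_iter Passed to [fit_reml()].
#' @return List with `variance_components` (tibble: time, sigma2_a,
#'   sigma2_e, h2, loglik, n_iter, converged, n) and `ebv` (tibble: id,
#'   time, ebv, phenotyped), plus `fits` (named list of `snpblup_reml`).
#' @export
fit_time_points <- function(phenotypes, G, tolerance = 1e-6,
                            max_iter = 500L) {
  times <- sort(unique(phenotypes$time))
  fits <- list()
  vc_rows <- list()
  ebv_rows <- list()
  for (tp in times) {
    ph <- phenotypes[phenotypes$time == tp, c("id", "value")]
    fit <- fit_reml(ph, G, tolerance = tolerance, max_iter = max_iter)
    bv <- solve_blup(ph, G, fit)
    key <- as.character(tp)
    fits[[key]] <- fit
    vc_rows[[key]] <- tibble::tibble(
      time = tp, sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
      h2 = fit$h2, loglik = fit$loglik, n_iter = fit$n_iter,
      converged = fit$converged, n = fit$n
    )
    ebv_rows[[key]] <- tibble::tibble(
      id = bv$id, time = tp, ebv = bv$ebv, phenotyped = bv$phenotyped
    )
  }
  list(
    variance_components = dplyr::bind_rows(vc_rows),
    ebv = dplyr::bind_rows(ebv_rows),
    fits = fits
  )
}
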