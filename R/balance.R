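#' Knight-Ruiz matrix balancing
#'
#' Finds a positive diagonal scaling `diag(s) %*% M %*% diag(s)` under which
#' every unmasked row (and, by symmetry, column) sums to 1. The primary solver
#' is the Knight-Ruiz inner-outer Newton scheme (an inexact Newton method with
#' a conjugate-gradient inner iteration on the balancing fixed-point
#' `x * (A x) = 1`); if it fails to converge or leaves the positive cone, the
#' solver falls back to the damped symmetric Sinkhorn iteration
#' `x <- x / sqrt(x * (A x))`.
#'
#' Rows with zero unmasked sum cannot be balanced and are masked before
#' iteration. No coverage-based filtering is applied beyond that: masking is
#' driven only by zero rows and the matrix's own mask.
#'
#' @param m A `contact_matrix` of raw counts.
#' @param tol Convergence tolerance on the maximum deviation of unmasked row
#'   sums from 1.
#' @param max_iter Maximum outer iterations (shared between the Newton scheme
#'   and the Sinkhorn fallback).
#' @return A list with elements
#'   * `matrix`: the balanced `contact_matrix` (units `"balanced"`),
#'   * `result`: a one-row tibble with `scale` (list column holding the
#'     per-bin multiplier, `NA` at masked bins), `converged`, `iterations`,
#'     and `residual` (max row-sum deviation from 1).
#' @examples
#' g <- bin_grid("chr1", 2e4, 1e4)
#' kr_balance(contact_matrix(g, matrix(c(2, 1, 1, 2), 2)))$result
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$grid$n_bins
  v <- m$values
  rs <- rowSums(v, na.rm = TRUE)
  mask <- m$mask | rs == 0
  if (all(mask)) abort("matrix is fully zero or masked; nothing to balance.")
  A <- v[!mask, !mask, drop = FALSE]
  A[is.na(A)] <- 0
  fit <- kr_newton(A, tol, max_iter)
  if (!fit$converged || any(fit$x <= 0)) {
    fit <- sinkhorn_sym(A, tol, max_iter, warm = fit$x)
  }
  x <- fit$x
  bal <- A * tcrossprod(x)
  scale <- rep(NA_real_, n)
  scale[!mask] <- x
  out <- matrix(NA_real_, n, n)
  out[!mask, !mask] <- bal
  res <- max(abs(rowSums(bal) - 1))
  list(
    matrix = contact_matrix(m$grid, out, mask = mask, units = "balanced"),
    result = tibble(
      scale = list(scale),
      converged = fit$converged && res <= tol * 10,
      iterations = fit$iterations,
      residual = res
    )
  )
}

# Knight & Ruiz inner-outer Newton scheme on x * (A x) = e.
# Follows the published bnewt algorithm: CG inner solves of the Jacobian
# system, with step limiting to keep the iterate in a cone around e.
kr_newton <- function(A, tol, max_iter, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  if (n == 1L) {
    return(list(x = 1 / sqrt(A[1, 1]), converged = TRUE, iterations = 1L))
  }
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  mvp <- 0L
  i <- 0L
  while (rout > rt && i < max_iter) {
    i <- i + 1L
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      mvp <- mvp + 1L
      if (k > 50L) break
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) {
      return(list(x = x, converged = FALSE, iterations = i))
    }
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # adaptive forcing term (Eisenstat-Walker style safeguard)
    rat <- rout / rold
    rold <- rout
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- min(max(eta, rt / rout), etamax)
  }
  list(x = x, converged = rout <= rt, iterations = i)
}

# damped symmetric Sinkhorn fixed-point fallback
sinkhorn_sym <- function(A, tol, max_iter, warm = NULL) {
  n <- nrow(A)
  x <- if (!is.null(warm) && all(is.finite(warm)) && all(warm > 0)) warm
       else rep(1, n)
  for (i in seq_len(max_iter)) {
    r <- x * drop(A %*% x)
    if (max(abs(r - 1)) <= tol) {
      return(list(x = x, converged = TRUE, iterations = i))
    }
    x <- x / sqrt(r)
  }
  list(x = x, converged = FALSE, iterations = max_iter)
}
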