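## Equilibria of the loop under constant drive, with stability classification.
##
## The marker variable C_a does not feed back on (C_I, C_P), so equilibria are
## found in the 2-D (C_I, C_P) subsystem by damped Newton iteration with the
## analytic Jacobian, from a regular grid of starts; C_a is then slaved via its
## own closed form and stability read off the block-triangular 3x3 Jacobian.

fp_residual2 <- function(ci, cp, S, F, uI, uP, p) {
  c((1 - uI) * (p$k1f * S + F * hill(cp, p$n)) * (1 - ci) - p$k1r * ci,
    (1 - uP) * (p$k2f * S + F * hill(ci, p$n)) * (1 - cp) - p$k2r * cp)
}

fp_jacobian2 <- function(ci, cp, S, F, uI, uP, p) {
  aI <- (1 - uI) * (p$k1f * S + F * hill(cp, p$n))
  aP <- (1 - uP) * (p$k2f * S + F * hill(ci, p$n))
  matrix(c(-aI - p$k1r,
           (1 - uP) * F * hill_deriv(ci, p$n) * (1 - cp),
           (1 - uI) * F * hill_deriv(cp, p$n) * (1 - ci),
           -aP - p$k2r), 2, 2)
}

slaved_ca <- function(ci, cp, p) {
  prod3 <- p$k3f * (ci + cp)
  if (prod3 == 0 && p$k3r == 0) return(0)
  prod3 / (prod3 + p$k3r)
}

#' Find all equilibria of the loop under a constant drive
#'
#' Runs damped Newton iterations on the `(C_I, C_P)` subsystem from a regular
#' `starts x starts` grid over \[0, 1\]^2, deduplicates converged roots, slaves
#' `C_a` through its closed form, and classifies stability from the eigenvalues
#' of the (block-triangular) Jacobian. Eigenvalues with `|Re| < 1e-9` are
#' reported as marginal.
#'
#' @param params A [pfl_params] object.
#' @param drive A [pfl_drive] (constant).
#' @param starts Number of Newton starts per axis (default 21).
#' @param tol Residual norm below which a root is accepted (default 1e-9).
#' @return An object of class `pfl_fixed_points`: a data frame with columns
#'   `C_I, C_P, C_a, stability, residual, marginal`, ordered by `C_a`.
#' @examples
#' find_fixed_points(pfl_params(), pfl_drive(S = 0, F = 1))
#' @export
find_fixed_points <- function(params = pfl_params(), drive = pfl_drive(),
                              starts = 21, tol = 1e-9) {
  drive <- as_pfl_drive(drive)
  p <- params
  S <- drive$S; F <- drive$F; uI <- drive$u_I; uP <- drive$u_P
  grid <- seq(0, 1, length.out = starts)
  roots <- NULL
  for (ci0 in grid) for (cp0 in grid) {
    x <- c(ci0, cp0)
    ok <- FALSE
    for (it in 1:60) {
      f <- fp_residual2(x[1], x[2], S, F, uI, uP, p)
      if (max(abs(f)) < 1e-13) { ok <- TRUE; break }
      J <- fp_jacobian2(x[1], x[2], S, F, uI, uP, p)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lam <- 1
      repeat {
        xn <- x - lam * step
        xn <- pmin(pmax(xn, -0.05), 1.05)
        fn <- fp_residual2(xn[1], xn[2], S, F, uI, uP, p)
        if (sum(fn^2) < sum(f^2) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (max(abs(x - xn)) < 1e-15) { ok <- max(abs(fn)) < 1e-11; x <- xn; break }
      x <- xn
    }
    if (!ok) next
    if (any(x < -1e-9) || any(x > 1 + 1e-9)) next
    x <- pmin(pmax(x, 0), 1)
    if (is.null(roots)) roots <- matrix(x, 1, 2)
    else if (all(sqrt(rowSums((roots - matrix(x, nrow(roots), 2,
                                              byrow = TRUE))^2)) > 1e-6))
      roots <- rbind(roots, x)
  }
  if (is.null(roots))
    stop("no equilibrium found (root search failed from all starts)", call. = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(roots)), function(i) {
    ci <- roots[i, 1]; cp <- roots[i, 2]
    ca <- slaved_ca(ci, cp, p)
    J2 <- fp_jacobian2(ci, cp, S, F, uI, uP, p)
    ev <- c(eigen(J2, only.values = TRUE)$values,
            -(p$k3f * (ci + cp) + p$k3r))
    re <- Re(ev)
    marginal <- any(abs(re) < 1e-9)
    npos <- sum(re > 1e-9)
    stability <- if (npos == 0) "stable" else if (npos == 1) "saddle" else "unstable"
    resid <- max(abs(pfl_rhs_raw(c(ci, cp, ca), S, F, uI, uP, p)))
    data.frame(C_I = ci, C_P = cp, C_a = ca, stability = stability,
               residual = resid, marginal = marginal)
  }))
  res <- res[res$residual < tol, , drop = FALSE]
  res <- res[order(res$C_a), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pfl_fixed_points", "data.frame"),
            params = params, drive = drive)
}

#' @export
print.pfl_fixed_points <- function(x, ...) {
  d <- attr(x, "drive")
  cat(sprintf("Equilibria at S=%g F=%g u_I=%g u_P=%g:\n", d$S, d$F, d$u_I, d$u_P))
  print(data.frame(C_I = signif(x$C_I, 6), C_P = signif(x$C_P, 6),
                   C_a = signif(x$C_a, 6), stability = x$stability),
        row.names = FALSE)
  invisible(x)
}

#' Classify the dynamical regime at a constant drive
#'
#' Counts stable equilibria: two or more gives `"bistable"`; a single stable
#' state is `"monostable_low"` or `"monostable_high"` according to whether its
#' marker level `C_a` is below or at/above the activation threshold.
#'
#' @inheritParams find_fixed_points
#' @param threshold Activation threshold on `C_a` (default 0.5).
#' @return One of `"monostable_low"`, `"bistable"`, `"monostable_high"`.
#' @examples
#' classify_regime(pfl_params(), pfl_drive(S = 0, F = 1))
#' @export
classify_regime <- function(params = pfl_params(), drive = pfl_drive(),
                            threshold = 0.5, starts = 21) {
  fps <- find_fixed_points(params, drive, starts = starts)
  st <- fps[fps$stability == "stable", , drop = FALSE]
  if (nrow(st) >= 2) return("bistable")
  if (nrow(st) == 0)
    stop("no stable equilibrium found", call. = FALSE)
  if (st$C_a[1] >= threshold) "monostable_high" else "monostable_low"
}
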