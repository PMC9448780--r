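## Parameter sweeps: bifurcation diagrams with fold refinement, and
## quasi-static hysteresis loops.

#' Sweep a control parameter and record all equilibria
#'
#' Enumerates equilibria (via [find_fixed_points]) over a grid of the swept
#' parameter (`"F"` or `"S"`), holding the other drive fields fixed, and
#' locates fold (saddle-node) values by bisection on the number of stable
#' equilibria. (Counting stable states, rather than all equilibria, keeps
#' degenerate exchanges of stability — e.g. the transcritical point of the
#' origin at `n = 1`, `S = 0` — from being misreported as folds.)
#'
#' @param params A [pfl_params] object.
#' @param drive A [pfl_drive] supplying the non-swept fields.
#' @param axis `"F"` or `"S"`.
#' @param range Length-2 numeric range of the swept parameter
#'   (within \[0, 1\] for `F`, `>= 0` for `S`).
#' @param n Number of grid points (`>= 3`).
#' @param starts Newton starts per axis passed to [find_fixed_points].
#' @return An object of class `pfl_bifurcation`: list with `axis`, `values`,
#'   `points` (data frame `param, C_I, C_P, C_a, stability`) and `folds`
#'   (refined fold parameter values).
#' @examples
#' bd <- bifurcation_sweep(pfl_params(), pfl_drive(S = 0), axis = "F",
#'                         range = c(0, 1), n = 21, starts = 7)
#' bd$folds
#' @export
bifurcation_sweep <- function(params = pfl_params(), drive = pfl_drive(),
                              axis = c("F", "S"), range, n = 51, starts = 21) {
  axis <- match.arg(axis)
  if (n < 3) stop("sweep needs at least 3 grid points", call. = FALSE)
  if (length(range) != 2 || range[1] >= range[2])
    stop("'range' must be an increasing length-2 vector", call. = FALSE)
  if (axis == "F" && (range[1] < 0 || range[2] > 1))
    stop("F range must lie within [0, 1]", call. = FALSE)
  if (axis == "S" && range[1] < 0)
    stop("S range must be >= 0", call. = FALSE)
  vals <- seq(range[1], range[2], length.out = n)
  at <- function(v) {
    d <- drive
    d[[axis]] <- v
    find_fixed_points(params, d, starts = starts)
  }
  fps <- lapply(vals, at)
  counts <- vapply(fps, function(f) sum(f$stability == "stable"), 0L)
  points <- do.call(rbind, lapply(seq_along(vals), function(i) {
    data.frame(param = vals[i], C_I = fps[[i]]$C_I, C_P = fps[[i]]$C_P,
               C_a = fps[[i]]$C_a, stability = fps[[i]]$stability)
  }))
  folds <- numeric(0)
  for (i in seq_len(n - 1)) {
    if (counts[i] != counts[i + 1]) {
      lo <- vals[i]; hi <- vals[i + 1]
      clo <- counts[i]
      while ((hi - lo) > 1e-6 * max(abs(hi), 1)) {
        mid <- (lo + hi) / 2
        fm <- at(mid)
        if (sum(fm$stability == "stable") == clo) lo <- mid else hi <- mid
      }
      folds <- c(folds, (lo + hi) / 2)
    }
  }
  structure(list(axis = axis, values = vals, points = points, folds = folds,
                 params = params, drive = drive),
            class = "pfl_bifurcation")
}

#' @export
print.pfl_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation sweep over %s in [%g, %g] (%d points)\n",
              x$axis, min(x$values), max(x$values), length(x$values)))
  if (length(x$folds)) cat("  folds at:", signif(x$folds, 6), "\n")
  else cat("  no folds detected\n")
  invisible(x)
}

#' @export
plot.pfl_bifurcation <- function(x, ...) {
  st <- x$points$stability == "stable"
  graphics::plot(x$points$param, x$points$C_a, pch = ifelse(st, 16, 1),
                 col = ifelse(st, "black", "grey50"),
                 xlab = x$axis, ylab = "equilibrium C_a", ...)
  if (length(x$folds)) graphics::abline(v = x$folds, lty = 3)
  invisible(x)
}

#' Quasi-static hysteresis sweep of the stiffness drive
#'
#' Follows the attained stable state along a stiffness path (typically up and
#' back down), relaxing to steady state at each step by long-time integration
#' warm-started from the previous state. The loop is flagged open when the
#' first and last attained states differ by more than `1e-3` in `C_a`.
#'
#' @param params A [pfl_params] object.
#' @param S_path Numeric stiffness-drive path; must start and end at the same
#'   value.
#' @param F Constant feedback strength during the sweep.
#' @param t_relax Integration time per relaxation step (days).
#' @param init Starting state (default quiescent).
#' @return An object of class `pfl_hysteresis`: list with `S_path`, `states`
#'   (matrix of attained states), `loop_open`.
#' @examples
#' hy <- hysteresis_sweep(pfl_params(), c(0, 3e-3, 6e-3, 3e-3, 0), F = 1)
#' hy$loop_open
#' @export
hysteresis_sweep <- function(params = pfl_params(), S_path, F = 1,
                             t_relax = 400, init = c(0, 0, 0)) {
  if (length(S_path) < 2 || abs(S_path[1] - S_path[length(S_path)]) > 1e-12)
    stop("'S_path' must start and end at the same value", call. = FALSE)
  if (any(S_path < 0)) stop("'S_path' must be >= 0", call. = FALSE)
  y <- as.numeric(init)
  states <- matrix(NA_real_, length(S_path), 3,
                   dimnames = list(NULL, c("C_I", "C_P", "C_a")))
  for (i in seq_along(S_path)) {
    fun <- function(t, y, parms) list(pfl_rhs_raw(y, S_path[i], F, 0, 0, params))
    converged <- FALSE
    for (round in 1:5) {
      sol <- deSolve::lsoda(y, c(0, t_relax), fun, parms = NULL,
                            rtol = 1e-10, atol = 1e-12)
      y <- pmin(pmax(sol[nrow(sol), 2:4], 0), 1)
      if (max(abs(pfl_rhs_raw(y, S_path[i], F, 0, 0, params))) < 1e-9) {
        converged <- TRUE; break
      }
    }
    if (!converged)
      stop(sprintf("relaxation did not converge at sweep step %d (S=%g)",
                   i, S_path[i]), call. = FALSE)
    states[i, ] <- y
  }
  loop_open <- unname(abs(states[1, "C_a"] - states[nrow(states), "C_a"]) > 1e-3)
  structure(list(S_path = S_path, states = states, loop_open = loop_open,
                 F = F, params = params),
            class = "pfl_hysteresis")
}

#' @export
print.pfl_hysteresis <- function(x, ...) {
  cat(sprintf("Hysteresis sweep (%d steps, F=%g): loop %s\n",
              length(x$S_path), x$F, if (x$loop_open) "OPEN" else "closed"))
  invisible(x)
}
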