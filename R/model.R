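## Core ODE system of the integrin/Piezo1 positive feedback loop.

hill <- function(c, n) c^n / (1 + c^n)
hill_deriv <- function(c, n) {
  ifelse(c == 0 & n > 1, 0, n * c^(n - 1) / (1 + c^n)^2)
}

#' Right-hand side of the feedback-loop ODE system
#'
#' Evaluates the instantaneous derivatives of the three state variables under a
#' given drive:
#' \deqn{dC_I/dt = (1-u_I)[k_{1f} S + F\,C_P^n/(1+C_P^n)](1-C_I) - k_{1r} C_I}
#' \deqn{dC_P/dt = (1-u_P)[k_{2f} S + F\,C_I^n/(1+C_I^n)](1-C_P) - k_{2r} C_P}
#' \deqn{dC_a/dt = k_{3f}(C_I+C_P)(1-C_a) - k_{3r} C_a}
#' The `(1-C)` factors confine each activity to \[0, 1\]; the inhibitor
#' occupancies scale the whole activation bracket of their target species.
#'
#' @param state Numeric length-3 vector `(C_I, C_P, C_a)`, each in \[0, 1\].
#' @param drive A [pfl_drive] (or list coercible to one).
#' @param params A [pfl_params] object.
#' @return Numeric length-3 vector of derivatives, named
#'   `c("C_I", "C_P", "C_a")`.
#' @examples
#' pfl_rhs(c(0, 0, 0), pfl_drive(S = 0, F = 0), pfl_params())
#' @export
pfl_rhs <- function(state, drive, params = pfl_params()) {
  if (length(state) != 3 || any(!is.finite(state)))
    stop("'state' must be a finite numeric vector (C_I, C_P, C_a)", call. = FALSE)
  if (any(state < -1e-9) || any(state > 1 + 1e-9))
    stop("'state' components must lie in [0, 1]", call. = FALSE)
  drive <- as_pfl_drive(drive)
  d <- pfl_rhs_raw(state, drive$S, drive$F, drive$u_I, drive$u_P, params)
  names(d) <- c("C_I", "C_P", "C_a")
  d
}

## unvalidated fast path used by the integrator and root finder
pfl_rhs_raw <- function(y, S, F, uI, uP, p) {
  c((1 - uI) * (p$k1f * S + F * hill(y[2], p$n)) * (1 - y[1]) - p$k1r * y[1],
    (1 - uP) * (p$k2f * S + F * hill(y[1], p$n)) * (1 - y[2]) - p$k2r * y[2],
    p$k3f * (y[1] + y[2]) * (1 - y[3]) - p$k3r * y[3])
}

#' Closed-form fixed point of the loop without feedback
#'
#' With the feedback strength held at zero the system decouples and its unique
#' equilibrium has the closed form
#' `C_I* = k1f S / (k1f S + k1r)`, `C_P* = k2f S / (k2f S + k2r)`,
#' `C_a* = k3f (C_I*+C_P*) / (k3f (C_I*+C_P*) + k3r)`. This serves as an
#' analytic oracle for the integrator and the root finder.
#'
#' @param params A [pfl_params] object.
#' @param S Dimensionless stiffness drive, `>= 0`.
#' @return Named numeric vector `(C_I, C_P, C_a)`.
#' @examples
#' closed_form_fixed_point(pfl_params(), S = 0.1)
#' @export
closed_form_fixed_point <- function(params = pfl_params(), S) {
  if (!is.finite(S) || S < 0) stop("'S' must be finite and >= 0", call. = FALSE)
  ci <- params$k1f * S / (params$k1f * S + params$k1r)
  cp <- params$k2f * S / (params$k2f * S + params$k2r)
  prod3 <- params$k3f * (ci + cp)
  ca <- if (prod3 == 0 && params$k3r == 0) 0 else prod3 / (prod3 + params$k3r)
  c(C_I = ci, C_P = cp, C_a = ca)
}

#' Integrate the feedback-loop model under a schedule
#'
#' Solves the three-variable ODE system with `deSolve::lsoda`, segment by
#' segment over the piecewise structure of the schedule (stiffness and
#' inhibitor occupancies are constant and the feedback strength is linear in
#' time within each compiled piece). States are renormalized into \[0, 1\] when
#' the solver's excursion is below `clamp_tol`; larger excursions raise an
#' error.
#'
#' @param params A [pfl_params] object.
#' @param schedule A [pfl_schedule] object.
#' @param times Strictly increasing numeric vector of output times within the
#'   schedule span. Defaults to a grid of step `dt` spanning the schedule.
#' @param init Initial state `(C_I, C_P, C_a)` in \[0, 1\]^3. Default
#'   `c(0, 0, 0)` (fully quiescent).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param dt Output grid step (days) when `times` is not given.
#' @param clamp_tol Largest tolerated excursion outside \[0, 1\].
#' @return A `pfl_trajectory`: a data frame with columns
#'   `t, C_I, C_P, C_a, S, F, u_I, u_P`, carrying the parameters, schedule and
#'   solver settings as attributes.
#' @examples
#' sch <- constant_schedule(stiffness_kpa = 15, duration = 50)
#' tr <- pfl_simulate(pfl_params(), sch, dt = 1)
#' tail(tr, 2)
#' @export
pfl_simulate <- function(params, schedule, times = NULL, init = c(0, 0, 0),
                         rtol = 1e-8, atol = 1e-10, dt = 0.25,
                         clamp_tol = 1e-6) {
  stopifnot(inherits(params, "pfl_params"), inherits(schedule, "pfl_schedule"))
  if (length(init) != 3 || any(!is.finite(init)) || any(init < 0) || any(init > 1))
    stop("'init' must lie in [0, 1]^3", call. = FALSE)
  pieces <- compile_schedule(schedule)
  span <- c(pieces$t0[1], pieces$t1[nrow(pieces)])
  if (is.null(times)) times <- seq(span[1], span[2], by = dt)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (times[1] < span[1] - 1e-12 || times[length(times)] > span[2] + 1e-12)
    stop(sprintf("'times' must lie within the schedule span [%g, %g]",
                 span[1], span[2]), call. = FALSE)

  y <- as.numeric(init)
  out_t <- numeric(0); out_y <- NULL
  for (i in seq_len(nrow(pieces))) {
    pc <- pieces[i, ]
    sel <- times >= pc$t0 - 1e-12 & times <= pc$t1 + 1e-12
    t_req <- times[sel]
    t_int <- sort(unique(c(pc$t0, t_req, pc$t1)))
    if (length(t_int) < 2) t_int <- c(pc$t0, pc$t1)
    fun <- function(t, y, parms) {
      Ft <- min(pc$Fhi, pc$F0 + pc$Fslope * (t - pc$t0))
      list(pfl_rhs_raw(y, pc$S, Ft, pc$uI, pc$uP, params))
    }
    sol <- tryCatch(
      deSolve::lsoda(y, t_int, fun, parms = NULL, rtol = rtol, atol = atol),
      warning = function(w) stop(sprintf(
        "ODE solver failed on interval [%g, %g]: %s", pc$t0, pc$t1,
        conditionMessage(w)), call. = FALSE))
    states <- sol[, 2:4, drop = FALSE]
    if (any(states < -clamp_tol) || any(states > 1 + clamp_tol))
      stop(sprintf("state left [0,1]^3 by more than %g on interval [%g, %g]",
                   clamp_tol, pc$t0, pc$t1), call. = FALSE)
    states <- pmin(pmax(states, 0), 1)
    keep <- sol[, 1] %in% t_req
    if (any(keep)) {
      out_t <- c(out_t, sol[keep, 1])
      out_y <- rbind(out_y, states[keep, , drop = FALSE])
    }
    y <- states[nrow(states), ]
  }
  ## drop duplicated boundary points (a time can fall in two adjacent pieces)
  dup <- duplicated(out_t)
  out_t <- out_t[!dup]; out_y <- out_y[!dup, , drop = FALSE]
  dr <- drive_at(schedule, out_t)
  res <- data.frame(t = out_t, C_I = out_y[, 1], C_P = out_y[, 2],
                    C_a = out_y[, 3], S = dr$S, F = dr$F,
                    u_I = dr$u_I, u_P = dr$u_P)
  structure(res, class = c("pfl_trajectory", "data.frame"),
            params = params, schedule = schedule,
            solver = list(rtol = rtol, atol = atol, clamp_tol = clamp_tol))
}

#' @export
print.pfl_trajectory <- function(x, ...) {
  cat(sprintf("PFL trajectory: %d time points over [%g, %g] days\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  final state: C_I=%.4f C_P=%.4f C_a=%.4f\n",
              x$C_I[nrow(x)], x$C_P[nrow(x)], x$C_a[nrow(x)]))
  invisible(x)
}

#' @export
plot.pfl_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$C_I, x$C_P, x$C_a), type = "l", lty = 1,
                    col = c("steelblue", "darkorange", "firebrick"),
                    xlab = "time (days)", ylab = "normalized activity", ...)
  graphics::legend("topleft", c("C_I", "C_P", "C_a"), lty = 1, bty = "n",
                   col = c("steelblue", "darkorange", "firebrick"))
  invisible(x)
}
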