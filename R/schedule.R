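## Time-dependent culture schedules: piecewise stiffness/inhibitor segments
## plus a feedback-strength rule, compiled to pieces the integrator can use.

.pfl_soft_kpa <- 4
.pfl_stiff_kpa <- 15

#' Feedback-strength rules
#'
#' The feedback strength `F(t)` represents the gradual establishment of the
#' mutual integrin/Piezo1 activation loop. Under the ramp rule it rises
#' piecewise-linearly at rate `1/tau_F` whenever the stiffness drive is at or
#' above `S_threshold`, is frozen at its attained value otherwise, and
#' saturates at `F_max`. With the default `tau_F` of 14 days, 7 days of stiff
#' priming yields `F = 0.5` and 14 days yields `F = 1`. `S_threshold = NULL`
#' resolves, when the schedule is compiled, to the midpoint of the mapped
#' drives of the conventional soft (4 kPa) and stiff (15 kPa) substrates.
#'
#' `feedback_explicit()` instead interpolates `F(t)` piecewise-linearly through
#' user-supplied breakpoints (constant beyond the first/last breakpoint);
#' `feedback_constant()` is the degenerate single-breakpoint case.
#'
#' @param tau_F Ramp time constant in days, `> 0`.
#' @param F_max Saturation level in \[0, 1\].
#' @param S_threshold Stiffness drive at or above which `F` ramps, or `NULL`.
#' @return An object of class `pfl_feedback`.
#' @export
feedback_ramp <- function(tau_F = 14, F_max = 1, S_threshold = NULL) {
  if (!is.finite(tau_F) || tau_F <= 0) stop("'tau_F' must be > 0", call. = FALSE)
  if (!is.finite(F_max) || F_max < 0 || F_max > 1)
    stop("'F_max' must lie in [0, 1]", call. = FALSE)
  if (!is.null(S_threshold) && (!is.finite(S_threshold) || S_threshold < 0))
    stop("'S_threshold' must be >= 0 or NULL", call. = FALSE)
  structure(list(mode = "ramp", tau_F = tau_F, F_max = F_max,
                 S_threshold = S_threshold), class = "pfl_feedback")
}

#' @rdname feedback_ramp
#' @param times,values Breakpoint times and feedback values (same length,
#'   times strictly increasing, values in \[0, 1\]).
#' @export
feedback_explicit <- function(times, values) {
  if (length(times) != length(values) || length(times) < 1)
    stop("'times' and 'values' must be non-empty and of equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("feedback values must lie in [0, 1]", call. = FALSE)
  structure(list(mode = "explicit", times = times, values = values),
            class = "pfl_feedback")
}

#' @rdname feedback_ramp
#' @param F Constant feedback strength in \[0, 1\].
#' @export
feedback_constant <- function(F) feedback_explicit(0, F)

#' Build a culture schedule
#'
#' A schedule is an ordered list of contiguous segments, each with a constant
#' substrate stiffness (kPa) and inhibitor occupancies, together with a
#' feedback rule and a stiffness-transduction mapping.
#'
#' @param segments Data frame with columns `t_start`, `t_end`,
#'   `stiffness_kpa` and optionally `u_I`, `u_P` (default 0). Segments must be
#'   contiguous, non-overlapping and have `t_start < t_end`.
#' @param feedback A `pfl_feedback` rule (see [feedback_ramp]).
#' @param mapping A [stiffness_mapping].
#' @return An object of class `pfl_schedule`.
#' @examples
#' segs <- data.frame(t_start = c(0, 14), t_end = c(14, 21),
#'                    stiffness_kpa = c(15, 4))
#' pfl_schedule(segs)
#' @export
pfl_schedule <- function(segments, feedback = feedback_ramp(),
                         mapping = stiffness_mapping()) {
  req <- c("t_start", "t_end", "stiffness_kpa")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("'segments' needs columns t_start, t_end, stiffness_kpa", call. = FALSE)
  if (is.null(segments$u_I)) segments$u_I <- 0
  if (is.null(segments$u_P)) segments$u_P <- 0
  if (nrow(segments) < 1) stop("schedule needs at least one segment", call. = FALSE)
  if (any(segments$t_end <= segments$t_start))
    stop("each segment needs t_start < t_end", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(abs(segments$t_start[-1] - segments$t_end[-nrow(segments)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  if (any(segments$stiffness_kpa < 0))
    stop("stiffness must be >= 0 kPa", call. = FALSE)
  if (any(segments$u_I < 0 | segments$u_I > 1 | segments$u_P < 0 | segments$u_P > 1))
    stop("inhibitor occupancies must lie in [0, 1]", call. = FALSE)
  if (!inherits(feedback, "pfl_feedback")) stop("invalid 'feedback'", call. = FALSE)
  if (!inherits(mapping, "pfl_mapping")) stop("invalid 'mapping'", call. = FALSE)
  structure(list(segments = segments[, c(req, "u_I", "u_P")],
                 feedback = feedback, mapping = mapping),
            class = "pfl_schedule")
}

#' @export
print.pfl_schedule <- function(x, ...) {
  cat(sprintf("PFL schedule: %d segment(s), span [%g, %g] days, feedback mode '%s'\n",
              nrow(x$segments), x$segments$t_start[1],
              x$segments$t_end[nrow(x$segments)], x$feedback$mode))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' One-segment schedule with a fixed drive
#'
#' Convenience constructor used for relaxation runs and equilibrium checks.
#' Exactly one of `stiffness_kpa` or `S` must be given; a raw drive `S` is
#' converted to the equivalent modulus through the inverse mapping so that the
#' compiled schedule reproduces it exactly.
#'
#' @param stiffness_kpa Substrate modulus in kPa.
#' @param S Raw dimensionless stiffness drive.
#' @param duration Span of the schedule in days.
#' @param F Constant feedback strength in \[0, 1\].
#' @param u_I,u_P Constant inhibitor occupancies.
#' @param mapping A [stiffness_mapping].
#' @return A [pfl_schedule].
#' @export
constant_schedule <- function(stiffness_kpa = NULL, S = NULL, duration,
                              F = 0, u_I = 0, u_P = 0,
                              mapping = stiffness_mapping()) {
  if (is.null(stiffness_kpa) == is.null(S))
    stop("give exactly one of 'stiffness_kpa' or 'S'", call. = FALSE)
  if (is.null(stiffness_kpa))
    stiffness_kpa <- (S / mapping$sigma)^(1 / mapping$exponent)
  segs <- data.frame(t_start = 0, t_end = duration,
                     stiffness_kpa = stiffness_kpa, u_I = u_I, u_P = u_P)
  pfl_schedule(segs, feedback = feedback_constant(F), mapping = mapping)
}

## Compile a schedule into integrator-ready pieces: constant S, u and linear F.
compile_schedule <- function(schedule) {
  segs <- schedule$segments
  fb <- schedule$feedback
  S <- stiffness_to_drive(segs$stiffness_kpa, schedule$mapping)
  pieces <- NULL
  if (fb$mode == "ramp") {
    thr <- fb$S_threshold
    if (is.null(thr))
      thr <- mean(stiffness_to_drive(c(.pfl_soft_kpa, .pfl_stiff_kpa),
                                     schedule$mapping))
    Fcur <- 0
    for (i in seq_len(nrow(segs))) {
      t0 <- segs$t_start[i]; t1 <- segs$t_end[i]
      if (S[i] >= thr && Fcur < fb$F_max) {
        t_sat <- t0 + (fb$F_max - Fcur) * fb$tau_F
        if (t_sat < t1 - 1e-12) {
          pieces <- rbind(pieces, data.frame(
            t0 = t0, t1 = t_sat, S = S[i], uI = segs$u_I[i], uP = segs$u_P[i],
            F0 = Fcur, Fslope = 1 / fb$tau_F, Fhi = fb$F_max))
          pieces <- rbind(pieces, data.frame(
            t0 = t_sat, t1 = t1, S = S[i], uI = segs$u_I[i], uP = segs$u_P[i],
            F0 = fb$F_max, Fslope = 0, Fhi = fb$F_max))
          Fcur <- fb$F_max
        } else {
          pieces <- rbind(pieces, data.frame(
            t0 = t0, t1 = t1, S = S[i], uI = segs$u_I[i], uP = segs$u_P[i],
            F0 = Fcur, Fslope = 1 / fb$tau_F, Fhi = fb$F_max))
          Fcur <- min(fb$F_max, Fcur + (t1 - t0) / fb$tau_F)
        }
      } else {
        pieces <- rbind(pieces, data.frame(
          t0 = t0, t1 = t1, S = S[i], uI = segs$u_I[i], uP = segs$u_P[i],
          F0 = Fcur, Fslope = 0, Fhi = fb$F_max))
      }
    }
  } else {
    ## explicit piecewise-linear breakpoints; constant beyond the ends
    bt <- fb$times; bv <- fb$values
    span0 <- segs$t_start[1]; span1 <- segs$t_end[nrow(segs)]
    cuts <- sort(unique(c(segs$t_start, segs$t_end,
                          bt[bt > span0 & bt < span1])))
    Fat <- function(t) {
      if (length(bt) == 1) return(bv)
      stats::approx(bt, bv, xout = t, rule = 2)$y
    }
    for (j in seq_len(length(cuts) - 1)) {
      t0 <- cuts[j]; t1 <- cuts[j + 1]
      i <- findInterval(t0 + 1e-12, segs$t_start)
      F0 <- Fat(t0); F1 <- Fat(t1)
      pieces <- rbind(pieces, data.frame(
        t0 = t0, t1 = t1, S = S[i], uI = segs$u_I[i], uP = segs$u_P[i],
        F0 = F0, Fslope = (F1 - F0) / (t1 - t0), Fhi = Inf))
    }
  }
  pieces
}

#' Evaluate the drive of a schedule at given times
#'
#' @param schedule A [pfl_schedule].
#' @param t Numeric vector of times within the schedule span.
#' @return Data frame with columns `t, S, F, u_I, u_P`.
#' @export
drive_at <- function(schedule, t) {
  pieces <- compile_schedule(schedule)
  span <- c(pieces$t0[1], pieces$t1[nrow(pieces)])
  if (any(t < span[1] - 1e-9) || any(t > span[2] + 1e-9))
    stop("'t' outside the schedule span", call. = FALSE)
  idx <- findInterval(pmin(pmax(t, span[1]), span[2] - 1e-12), pieces$t0)
  Fv <- pmin(pieces$Fhi[idx], pieces$F0[idx] + pieces$Fslope[idx] * (t - pieces$t0[idx]))
  data.frame(t = t, S = pieces$S[idx], F = Fv,
             u_I = pieces$uI[idx], u_P = pieces$uP[idx])
}

#' Mechanical-dose protocols ("St.. So..")
#'
#' A dose protocol primes cells on a stiff substrate for `priming_days`, then
#' transfers them to a soft substrate for `recovery_days`. The conventional
#' label is `St<d1>So<d2>`, with `So` omitted when there is no recovery phase:
#' `"St14So7"` is 14 days stiff then 7 days soft, `"St21"` is 21 days stiff.
#'
#' @param label Protocol label to parse, e.g. `"St14So7"`; alternatively give
#'   the durations directly.
#' @param priming_days,recovery_days Non-negative durations in days.
#' @param stiff_kpa,soft_kpa Substrate moduli in kPa (defaults 15 and 4).
#' @return An object of class `dose_protocol`.
#' @examples
#' dose_protocol("St14So7")
#' format(dose_protocol(priming_days = 7, recovery_days = 7))
#' @export
dose_protocol <- function(label = NULL, priming_days = NULL, recovery_days = 0,
                          stiff_kpa = .pfl_stiff_kpa, soft_kpa = .pfl_soft_kpa) {
  if (!is.null(label)) {
    m <- regmatches(label, regexec("^St([0-9]+)(So([0-9]+))?$", label))[[1]]
    if (length(m) == 0)
      stop(sprintf("cannot parse protocol label '%s' (expected St<d1>[So<d2>])",
                   label), call. = FALSE)
    priming_days <- as.numeric(m[2])
    recovery_days <- if (m[4] == "") 0 else as.numeric(m[4])
  }
  if (is.null(priming_days) || priming_days < 0 || recovery_days < 0)
    stop("durations must be >= 0", call. = FALSE)
  structure(list(priming_days = priming_days, recovery_days = recovery_days,
                 stiff_kpa = stiff_kpa, soft_kpa = soft_kpa),
            class = "dose_protocol")
}

#' @export
format.dose_protocol <- function(x, ...) {
  lab <- paste0("St", format(x$priming_days, trim = TRUE))
  if (x$recovery_days > 0)
    lab <- paste0(lab, "So", format(x$recovery_days, trim = TRUE))
  lab
}

#' @export
print.dose_protocol <- function(x, ...) {
  cat(sprintf("Dose protocol %s: %g d at %g kPa, then %g d at %g kPa\n",
              format(x), x$priming_days, x$stiff_kpa,
              x$recovery_days, x$soft_kpa))
  invisible(x)
}

#' Turn a dose protocol into a schedule
#'
#' @param protocol A [dose_protocol] or protocol label string.
#' @param feedback,mapping Feedback rule and stiffness mapping (see
#'   [feedback_ramp], [stiffness_mapping]).
#' @param extend_recovery Extra days appended to the recovery phase (used to
#'   follow the relaxation beyond the nominal protocol end).
#' @return A [pfl_schedule] with one segment per protocol phase.
#' @examples
#' make_dose_schedule("St14So7")
#' @export
make_dose_schedule <- function(protocol, feedback = feedback_ramp(),
                               mapping = stiffness_mapping(),
                               extend_recovery = 0) {
  if (is.character(protocol)) protocol <- dose_protocol(protocol)
  stopifnot(inherits(protocol, "dose_protocol"))
  d1 <- protocol$priming_days
  d2 <- protocol$recovery_days + extend_recovery
  segs <- NULL
  if (d1 > 0)
    segs <- rbind(segs, data.frame(t_start = 0, t_end = d1,
                                   stiffness_kpa = protocol$stiff_kpa))
  if (d2 > 0)
    segs <- rbind(segs, data.frame(t_start = d1, t_end = d1 + d2,
                                   stiffness_kpa = protocol$soft_kpa))
  if (is.null(segs))
    stop("protocol has zero total duration", call. = FALSE)
  pfl_schedule(segs, feedback = feedback, mapping = mapping)
}
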