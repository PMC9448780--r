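## Mechanical-memory protocols, inhibitor treatment scenarios and the two
## phase diagrams (inhibitor composition, treatment timing).

#' Classify the reversibility of activation along a schedule
#'
#' Simulates the schedule and labels the outcome from the marker trajectory
#' `C_a(t)`:
#' \itemize{
#'   \item `reversible` — final `C_a` below the activation threshold;
#'   \item `reactivated` — final `C_a` at/above threshold although `C_a`
#'     dipped below it within the assessment window (treatment suppressed
#'     activation, which then returned);
#'   \item `partially_reversible` — final `C_a` at/above threshold but reduced
#'     by at least `partial_frac` from its pre-window peak;
#'   \item `irreversible` — otherwise.
#' }
#' The assessment window starts at `assess_from` (by default the start of the
#' schedule's last segment, i.e. the recovery phase).
#'
#' @param params A [pfl_params] object.
#' @param schedule A [pfl_schedule]; its span after `assess_from` should be at
#'   least one day.
#' @param threshold Activation threshold on `C_a` (default 0.5).
#' @param assess_from Start of the assessment window (days), or `NULL`.
#' @param partial_frac Fractional reduction from the pre-window peak that
#'   counts as partial reversal (default 0.25).
#' @param dt Output grid step for the underlying simulation.
#' @param init Initial state.
#' @return An object of class `pfl_outcome`: list with `label`, `final_Ca`,
#'   `min_Ca` (within the window), `peak_Ca` (before the window),
#'   `threshold`, `assess_from` and the `trajectory`.
#' @examples
#' out <- reversibility_assay(pfl_params(), make_dose_schedule("St7So7"))
#' out$label
#' @export
reversibility_assay <- function(params = pfl_params(), schedule,
                                threshold = 0.5, assess_from = NULL,
                                partial_frac = 0.25, dt = 0.25,
                                init = c(0, 0, 0)) {
  stopifnot(inherits(schedule, "pfl_schedule"))
  segs <- schedule$segments
  if (is.null(assess_from)) assess_from <- segs$t_start[nrow(segs)]
  span_end <- segs$t_end[nrow(segs)]
  if (span_end - assess_from < 1)
    stop("assessment window must cover at least 1 day", call. = FALSE)
  tr <- pfl_simulate(params, schedule, init = init, dt = dt)
  final <- tr$C_a[nrow(tr)]
  w <- tr$t >= assess_from
  min_Ca <- min(tr$C_a[w])
  peak_Ca <- max(tr$C_a[tr$t <= assess_from])
  label <- if (final < threshold) "reversible"
  else if (min_Ca < threshold) "reactivated"
  else if (final <= (1 - partial_frac) * peak_Ca) "partially_reversible"
  else "irreversible"
  structure(list(label = label, final_Ca = final, min_Ca = min_Ca,
                 peak_Ca = peak_Ca, threshold = threshold,
                 assess_from = assess_from, trajectory = tr),
            class = "pfl_outcome")
}

#' @export
print.pfl_outcome <- function(x, ...) {
  cat(sprintf("Outcome: %s (final C_a=%.3f, window min=%.3f, pre-window peak=%.3f)\n",
              x$label, x$final_Ca, x$min_Ca, x$peak_Ca))
  invisible(x)
}

.scenario_ids <- c(line1 = "line1_no_memory", line2 = "line2_soften_only",
                   line3 = "line3_soften_plus_inhibitors",
                   line4 = "line4_inhibitors_only", untreated = "untreated")

#' Treatment plan for an in-silico intervention
#'
#' The four canonical intervention lines (plus the untreated control) against
#' a stiff-primed, feedback-locked activated state:
#' \itemize{
#'   \item `line1_no_memory` — feedback held at zero throughout (the
#'     no-memory reference): priming then soft recovery;
#'   \item `line2_soften_only` — transfer to soft substrate, no inhibitors;
#'   \item `line3_soften_plus_inhibitors` — transfer to soft substrate and
#'     both inhibitors applied during `[T1, T1 + T2]`;
#'   \item `line4_inhibitors_only` — substrate stays stiff, inhibitors during
#'     `[T1, T1 + T2]`;
#'   \item `untreated` — substrate stays stiff, no inhibitors.
#' }
#'
#' @param scenario Scenario id (long form as above, or `"line1"`..`"line4"`).
#' @param u_I,u_P Inhibitor occupancies in \[0, 1\] (default 0.6).
#' @param T1 Treatment start time in days (`NULL`: at transfer).
#' @param T2 Treatment duration in days (default 28).
#' @return An object of class `treatment_plan`.
#' @export
treatment_plan <- function(scenario, u_I = 0.6, u_P = 0.6, T1 = NULL, T2 = 28) {
  if (scenario %in% names(.scenario_ids)) scenario <- .scenario_ids[[scenario]]
  if (!scenario %in% .scenario_ids)
    stop(sprintf("unknown scenario id '%s'", scenario), call. = FALSE)
  if (any(c(u_I, u_P) < 0) || any(c(u_I, u_P) > 1))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  if (!is.null(T1) && T1 < 0) stop("'T1' must be >= 0", call. = FALSE)
  if (T2 < 0) stop("'T2' must be >= 0", call. = FALSE)
  structure(list(scenario = scenario, u_I = u_I, u_P = u_P, T1 = T1, T2 = T2),
            class = "treatment_plan")
}

## Build the schedule a plan implies on top of a dose protocol.
build_treatment_schedule <- function(plan, protocol, horizon,
                                     feedback = feedback_ramp(),
                                     mapping = stiffness_mapping()) {
  if (is.character(protocol)) protocol <- dose_protocol(protocol)
  d1 <- protocol$priming_days
  T1 <- if (is.null(plan$T1)) d1 else plan$T1
  t_on <- min(T1, horizon)
  t_off <- min(T1 + plan$T2, horizon)
  scen <- plan$scenario
  soften <- scen %in% c("line1_no_memory", "line2_soften_only",
                        "line3_soften_plus_inhibitors")
  treated <- scen %in% c("line3_soften_plus_inhibitors", "line4_inhibitors_only")
  stiff_until <- if (soften) min(d1, horizon) else horizon
  cuts <- sort(unique(c(0, stiff_until, if (treated) c(t_on, t_off), horizon)))
  cuts <- cuts[cuts <= horizon]
  segs <- data.frame(t_start = cuts[-length(cuts)], t_end = cuts[-1])
  segs <- segs[segs$t_end > segs$t_start, , drop = FALSE]
  mid <- (segs$t_start + segs$t_end) / 2
  segs$stiffness_kpa <- ifelse(mid < stiff_until, protocol$stiff_kpa,
                               protocol$soft_kpa)
  inwin <- treated & mid >= t_on & mid < t_off
  segs$u_I <- ifelse(inwin, plan$u_I, 0)
  segs$u_P <- ifelse(inwin, plan$u_P, 0)
  fb <- if (scen == "line1_no_memory") feedback_constant(0) else feedback
  pfl_schedule(segs, feedback = fb, mapping = mapping)
}

#' Run the canonical treatment scenarios against a priming protocol
#'
#' Simulates each requested scenario (see [treatment_plan]) on top of the
#' priming protocol and classifies the outcome with [reversibility_assay].
#' The assessment window starts at the treatment start (`T1`), or at transfer
#' for untreated scenarios.
#'
#' @param params A [pfl_params] object.
#' @param protocol Priming [dose_protocol] or label (default `"St14"`, which
#'   produces irreversible activation untreated).
#' @param scenarios Character vector of scenario ids.
#' @param u Inhibitor occupancy applied to both arms (default 0.6).
#' @param T1 Treatment start (`NULL`: at transfer).
#' @param T2 Treatment duration in days (default 28).
#' @param horizon Total simulated span (`NULL`: priming + 56 days).
#' @param threshold Activation threshold.
#' @param feedback,mapping Model plumbing as elsewhere.
#' @return An object of class `pfl_scenarios`: named list of [pfl_outcome]s
#'   with a summary `print` method.
#' @examples
#' \donttest{
#' sc <- run_treatment_scenarios(pfl_params(), "St14",
#'                               scenarios = c("line1", "line3", "untreated"))
#' sc
#' }
#' @export
run_treatment_scenarios <- function(params = pfl_params(), protocol = "St14",
                                    scenarios = names(.scenario_ids),
                                    u = 0.6, T1 = NULL, T2 = 28,
                                    horizon = NULL, threshold = 0.5,
                                    feedback = feedback_ramp(),
                                    mapping = stiffness_mapping()) {
  if (is.character(protocol)) protocol <- dose_protocol(protocol)
  d1 <- protocol$priming_days
  if (is.null(horizon)) horizon <- d1 + 56
  if (is.null(T1)) T1 <- d1
  out <- lapply(scenarios, function(sc) {
    plan <- treatment_plan(sc, u_I = u, u_P = u, T1 = T1, T2 = T2)
    sch <- build_treatment_schedule(plan, protocol, horizon,
                                    feedback = feedback, mapping = mapping)
    reversibility_assay(params, sch, threshold = threshold, assess_from = T1)
  })
  names(out) <- vapply(scenarios, function(sc)
    if (sc %in% names(.scenario_ids)) .scenario_ids[[sc]] else sc, "")
  structure(out, class = "pfl_scenarios",
            meta = list(protocol = format(protocol), u = u, T1 = T1, T2 = T2,
                        horizon = horizon))
}

#' @export
print.pfl_scenarios <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Treatment scenarios on %s (u=%g, T1=%g, T2=%g, horizon=%g d):\n",
              m$protocol, m$u, m$T1, m$T2, m$horizon))
  df <- data.frame(scenario = names(x),
                   final_Ca = vapply(x, function(o) o$final_Ca, 0),
                   label = vapply(x, function(o) o$label, ""))
  print(df, row.names = FALSE)
  invisible(x)
}

new_phase_diagram <- function(x_name, y_name, x_values, y_values,
                              labels, final_Ca, meta) {
  structure(list(x_name = x_name, y_name = y_name,
                 x_values = x_values, y_values = y_values,
                 labels = labels, final_Ca = final_Ca, meta = meta),
            class = "pfl_phase")
}

#' @export
print.pfl_phase <- function(x, ...) {
  cat(sprintf("Phase diagram %s x %s (%d x %d cells)\n", x$x_name, x$y_name,
              length(x$x_values), length(x$y_values)))
  print(table(factor(x$labels)))
  invisible(x)
}

#' @export
plot.pfl_phase <- function(x, ...) {
  levs <- c("reversible", "partially_reversible", "reactivated", "irreversible")
  cols <- c("#2b83ba", "#abdda4", "#fdae61", "#d7191c")
  z <- matrix(match(x$labels, levs), nrow(x$labels), ncol(x$labels))
  graphics::image(x$x_values, x$y_values, z, zlim = c(1, 4),
                  col = cols, xlab = x$x_name, ylab = x$y_name, ...)
  present <- sort(unique(as.vector(z)))
  graphics::legend("topright", legend = levs[present], fill = cols[present],
                   bg = "white", cex = 0.8)
  invisible(x)
}

#' Phase diagram over the two inhibitor occupancies
#'
#' Classifies the treatment outcome on a grid of integrin-arm (`u_I`) and
#' Piezo1-arm (`u_P`) inhibitor occupancies. Treatment starts at `T1`, well
#' after the activated state has consolidated, lasts `T2` days, and by default
#' is combined with transfer to the soft substrate at the end of priming (set
#' `recovery = "stiff"` to keep the substrate stiff instead).
#'
#' @param params A [pfl_params] object.
#' @param protocol Priming protocol (default `"St14"`).
#' @param u_I,u_P Occupancy grids in \[0, 1\], at least 5 points each.
#' @param T1 Treatment start in days (default 56).
#' @param T2 Treatment duration in days (default 28).
#' @param horizon Total span (`NULL`: `T1 + T2 + 28`).
#' @param recovery `"soft"` or `"stiff"` substrate after priming.
#' @param threshold Activation threshold.
#' @param feedback,mapping Model plumbing.
#' @return A `pfl_phase` object; `labels` and `final_Ca` are matrices with
#'   rows indexed by `u_I` and columns by `u_P`.
#' @export
inhibitor_phase_diagram <- function(params = pfl_params(), protocol = "St14",
                                    u_I = seq(0, 1, length.out = 11),
                                    u_P = seq(0, 1, length.out = 11),
                                    T1 = 56, T2 = 28, horizon = NULL,
                                    recovery = c("soft", "stiff"),
                                    threshold = 0.5,
                                    feedback = feedback_ramp(),
                                    mapping = stiffness_mapping()) {
  recovery <- match.arg(recovery)
  if (length(u_I) < 5 || length(u_P) < 5)
    stop("occupancy grids need at least 5 points", call. = FALSE)
  if (any(c(u_I, u_P) < 0) || any(c(u_I, u_P) > 1))
    stop("occupancy grids must lie in [0, 1]", call. = FALSE)
  if (is.null(horizon)) horizon <- T1 + T2 + 28
  base <- if (recovery == "soft") "line3_soften_plus_inhibitors"
          else "line4_inhibitors_only"
  labs <- matrix("", length(u_I), length(u_P))
  fin <- matrix(NA_real_, length(u_I), length(u_P))
  for (i in seq_along(u_I)) for (j in seq_along(u_P)) {
    plan <- treatment_plan(base, u_I = u_I[i], u_P = u_P[j], T1 = T1, T2 = T2)
    sch <- build_treatment_schedule(plan, protocol, horizon,
                                    feedback = feedback, mapping = mapping)
    out <- reversibility_assay(params, sch, threshold = threshold,
                               assess_from = T1)
    labs[i, j] <- out$label
    fin[i, j] <- out$final_Ca
  }
  new_phase_diagram("u_I", "u_P", u_I, u_P, labs, fin,
                    meta = list(protocol = if (is.character(protocol)) protocol
                                else format(protocol),
                                T1 = T1, T2 = T2, horizon = horizon,
                                recovery = recovery, threshold = threshold))
}

#' Phase diagram over treatment start time and duration
#'
#' Classifies the outcome on a grid of treatment start times `T1` (measured
#' from the start of stiff priming) and durations `T2`, with both inhibitors
#' applied at occupancy `u` and transfer to the soft substrate at the end of
#' priming. Cells with `T2 = 0` are evaluated as untreated. At the defaults,
#' early but brief treatment merely delays consolidation of the loop and the
#' marker re-escapes after withdrawal ("reactivated").
#'
#' @param params A [pfl_params] object.
#' @param protocol Priming protocol (default `"St14"`).
#' @param T1,T2 Grids in days, at least 5 points each, `>= 0`.
#' @param u Occupancy of both inhibitors, in (0, 1\].
#' @param horizon Total span in days (default 42).
#' @param threshold Activation threshold.
#' @param feedback,mapping Model plumbing.
#' @return A `pfl_phase` object; rows of `labels` are indexed by `T1`,
#'   columns by `T2`.
#' @export
timing_phase_diagram <- function(params = pfl_params(), protocol = "St14",
                                 T1 = seq(0, 20, length.out = 11),
                                 T2 = seq(0, 40, length.out = 11),
                                 u = 0.6, horizon = 42, threshold = 0.5,
                                 feedback = feedback_ramp(),
                                 mapping = stiffness_mapping()) {
  if (length(T1) < 5 || length(T2) < 5)
    stop("timing grids need at least 5 points", call. = FALSE)
  if (any(c(T1, T2) < 0)) stop("T1 and T2 must be >= 0", call. = FALSE)
  if (u <= 0 || u > 1) stop("'u' must lie in (0, 1]", call. = FALSE)
  if (is.character(protocol)) protocol <- dose_protocol(protocol)
  d1 <- protocol$priming_days
  labs <- matrix("", length(T1), length(T2))
  fin <- matrix(NA_real_, length(T1), length(T2))
  for (i in seq_along(T1)) for (j in seq_along(T2)) {
    if (T2[j] == 0) {
      plan <- treatment_plan("line2_soften_only", T1 = d1, T2 = 0)
      assess <- d1
    } else {
      plan <- treatment_plan("line3_soften_plus_inhibitors", u_I = u, u_P = u,
                             T1 = T1[i], T2 = T2[j])
      assess <- T1[i]
    }
    sch <- build_treatment_schedule(plan, protocol, horizon,
                                    feedback = feedback, mapping = mapping)
    out <- reversibility_assay(params, sch, threshold = threshold,
                               assess_from = assess)
    labs[i, j] <- out$label
    fin[i, j] <- out$final_Ca
  }
  new_phase_diagram("T1", "T2", T1, T2, labs, fin,
                    meta = list(protocol = format(protocol), u = u,
                                horizon = horizon, threshold = threshold))
}
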