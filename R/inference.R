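## Parameter recovery from marker time courses: multi-start bounded
## least squares (Levenberg-Marquardt via minpack.lm), Latin-hypercube starts.

.free_param_names <- c("F_max", "n", "sigma", "tau_F")

apply_free_params <- function(params, schedule, theta) {
  for (nm in names(theta)) {
    switch(nm,
           F_max = { schedule$feedback$F_max <- theta[[nm]] },
           n     = { params$n <- theta[[nm]] },
           sigma = { schedule$mapping$sigma <- theta[[nm]] },
           tau_F = { schedule$feedback$tau_F <- theta[[nm]] },
           stop(sprintf("unknown free parameter '%s'", nm), call. = FALSE))
  }
  list(params = params, schedule = schedule)
}

#' Fit model parameters to a marker time course
#'
#' Recovers a subset of model parameters from observations of the activation
#' marker `C_a(t)` by bounded least squares: candidate parameters are applied
#' to the schedule skeleton, the model is simulated on the observation time
#' grid, and the sum of squared residuals is minimized with
#' Levenberg-Marquardt (`minpack.lm::nls.lm`) from `n_starts` Latin-hypercube
#' starting points. The best converged start is reported; if no start
#' converges the result is flagged rather than an error raised.
#'
#' Free parameters (with their natural bounds) are any subset of:
#' `F_max` (feedback plateau, \[0, 1\]), `n` (Hill coefficient, `>= 1`),
#' `sigma` (stiffness-transduction scale, `> 0`) and `tau_F` (feedback ramp
#' time constant, `> 0`).
#'
#' @param data Data frame with columns `t` and `value` (observed `C_a`);
#'   replicate rows at the same `t` are allowed. At least 10 rows.
#' @param schedule Schedule skeleton (a [pfl_schedule]); free parameters
#'   override its feedback/mapping fields.
#' @param params Fixed model parameters (a [pfl_params]).
#' @param free Named list of length-2 bound vectors, e.g.
#'   `list(F_max = c(0, 1), n = c(1, 6))`.
#' @param n_starts Number of Latin-hypercube multistarts (default 8).
#' @param seed Integer seed fixing the starts (and any bootstrap).
#' @param init Initial state for the simulations.
#' @return An object of class `pfl_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' sch <- make_dose_schedule("St14So7")
#' obs <- noisy_timecourse(pfl_params(), sch, times = seq(0, 21, length.out = 40),
#'                         noise = noise_model(sigma = 0, replicates = 1))
#' fit <- pfl_fit(obs[, c("t", "value")], sch, free = list(F_max = c(0, 1)),
#'                n_starts = 4, seed = 1)
#' coef(fit)
#' }
#' @export
pfl_fit <- function(data, schedule, params = pfl_params(),
                    free = list(F_max = c(0, 1), n = c(1, 6)),
                    n_starts = 8, seed = 1, init = c(0, 0, 0)) {
  if (!is.data.frame(data) || !all(c("t", "value") %in% names(data)))
    stop("'data' needs columns t and value", call. = FALSE)
  if (nrow(data) < 10)
    stop("need at least 10 observations", call. = FALSE)
  if (length(free) < 1) stop("need at least one free parameter", call. = FALSE)
  if (!all(names(free) %in% .free_param_names))
    stop("free parameters must be among: ",
         paste(.free_param_names, collapse = ", "), call. = FALSE)
  bounds <- do.call(rbind, free)
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("each bound must be a finite increasing length-2 vector", call. = FALSE)

  ## order-invariant internal representation of the data
  ord <- order(data$t)
  tt <- data$t[ord]; vv <- data$value[ord]
  ut <- sort(unique(tt))
  idx <- match(tt, ut)

  model_at <- function(theta) {
    names(theta) <- names(free)
    ap <- apply_free_params(params, schedule, as.list(theta))
    tr <- pfl_simulate(ap$params, ap$schedule, times = ut, init = init)
    tr$C_a[idx]
  }
  residfun <- function(theta) model_at(theta) - vv

  k <- length(free)
  set.seed(seed)
  u01 <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(u01, 2, bounds[, 2] - bounds[, 1], "*"),
                  2, bounds[, 1], "+")
  colnames(starts) <- names(free)
  runs <- lapply(seq_len(n_starts), function(i) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = residfun,
                         lower = bounds[, 1], upper = bounds[, 2],
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(start = starts[i, ], par = fit$par, loss = fit$deviance,
         converged = fit$info %in% 1:4)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0)
    stop("all optimizer starts failed to evaluate", call. = FALSE)
  losses <- vapply(runs, function(r) r$loss, 0)
  best <- runs[[which.min(losses)]]
  est <- best$par
  names(est) <- names(free)
  starts_df <- do.call(rbind, lapply(runs, function(r) {
    data.frame(t(r$start), t(stats::setNames(r$par, paste0("est_", names(free)))),
               loss = r$loss, converged = r$converged)
  }))
  structure(list(coefficients = est, loss = best$loss,
                 converged = any(vapply(runs, function(r) r$converged, TRUE)),
                 starts = starts_df, free = free, bounds = bounds,
                 data = data.frame(t = tt, value = vv),
                 schedule = schedule, params = params, seed = seed,
                 init = init, nobs = length(vv)),
            class = "pfl_fit")
}

#' @export
print.pfl_fit <- function(x, ...) {
  cat("PFL model fit (multi-start least squares)\n")
  cat("  estimates:", paste(sprintf("%s=%.5g", names(x$coefficients),
                                    x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  loss=%.6g over %d observations; converged: %s\n",
              x$loss, x$nobs, x$converged))
  invisible(x)
}

#' @export
coef.pfl_fit <- function(object, ...) object$coefficients

#' @export
summary.pfl_fit <- function(object, ...) {
  k <- length(object$coefficients)
  sigma_hat <- sqrt(object$loss / max(object$nobs - k, 1))
  structure(list(coefficients = object$coefficients, loss = object$loss,
                 sigma = sigma_hat, nobs = object$nobs,
                 converged = object$converged, starts = object$starts),
            class = "summary.pfl_fit")
}

#' @export
print.summary.pfl_fit <- function(x, ...) {
  cat("PFL model fit summary\n")
  print(data.frame(estimate = x$coefficients))
  cat(sprintf("residual sd %.5g on %d observations (loss %.6g)\n",
              x$sigma, x$nobs, x$loss))
  cat(sprintf("%d multistart run(s); converged: %s\n",
              nrow(x$starts), x$converged))
  invisible(x)
}

#' @export
predict.pfl_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$data$t))
  ap <- apply_free_params(object$params, object$schedule,
                          as.list(object$coefficients))
  tr <- pfl_simulate(ap$params, ap$schedule, times = times,
                     init = object$init)
  stats::setNames(tr$C_a, times)
}

#' @export
fitted.pfl_fit <- function(object, ...) {
  pr <- predict(object, times = sort(unique(object$data$t)))
  unname(pr[match(object$data$t, sort(unique(object$data$t)))])
}

#' @export
residuals.pfl_fit <- function(object, ...) {
  object$data$value - fitted(object)
}

#' @export
plot.pfl_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$value, pch = 16, col = "grey50",
                 xlab = "time (days)", ylab = "C_a", ...)
  ts <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(ts, predict(x, times = ts), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.pfl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  k <- length(object$coefficients)
  sigma_hat <- sqrt(object$loss / max(object$nobs - k, 1))
  out <- replicate(nsim, pmin(pmax(mu + stats::rnorm(length(mu), 0, sigma_hat),
                                   0), 1))
  as.data.frame(out)
}

#' Summarize parameter-recovery quality across repeated fits
#'
#' @param truth Named numeric vector of true parameter values.
#' @param fits List of [pfl_fit] objects (or a matrix/data frame of estimates
#'   with matching column names), length/rows `>= 2`.
#' @return Data frame with one row per parameter: `truth`, `mean_estimate`,
#'   `bias`, `rmse`, `median_rel_err`.
#' @export
recovery_report <- function(truth, fits) {
  est <- if (is.list(fits) && !is.data.frame(fits))
    do.call(rbind, lapply(fits, function(f) {
      if (inherits(f, "pfl_fit")) coef(f) else unlist(f)
    }))
  else as.matrix(fits)
  if (nrow(est) < 2) stop("need at least 2 fits", call. = FALSE)
  if (!setequal(colnames(est), names(truth)))
    stop("parameter sets of truth and fits do not match", call. = FALSE)
  est <- est[, names(truth), drop = FALSE]
  out <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    median_rel_err = apply(abs(sweep(est, 2, truth)) /
                             matrix(abs(truth), nrow(est), ncol(est),
                                    byrow = TRUE), 2, stats::median))
  rownames(out) <- NULL
  out
}
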