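#' Model parameters for the mechanical positive feedback loop
#'
#' The model tracks three normalized activities: integrin beta-1 (`C_I`),
#' Piezo1 (`C_P`) and a lumped downstream fibrotic-marker level (`C_a`), each
#' confined to \[0, 1\]. Integrin and Piezo1 activate each other through a Hill
#' term with coefficient `n`, and both are additionally activated linearly by
#' the dimensionless substrate-stiffness drive `S`. The marker pool is produced
#' in proportion to `C_I + C_P`.
#'
#' Rates are expressed per model time unit; by package convention one time unit
#' is one day (protocol durations in the literature this model addresses are
#' day-scale, and the qualitative conclusions are insensitive to the absolute
#' rate scale).
#'
#' @param k1f,k2f,k3f Non-negative basal activation (production) rate
#'   constants for integrin, Piezo1 and the marker pool. Default 1.
#' @param k1r,k2r,k3r Non-negative deactivation rate constants. Default 0.1.
#' @param n Hill coefficient of the mutual-activation terms, `n >= 1`.
#'   Default 2, the smallest integer value that supports bistability at the
#'   default rate constants.
#'
#' @return An object of class `pfl_params`.
#' @examples
#' p <- pfl_params()
#' p$n
#' @export
pfl_params <- function(k1f = 1, k2f = 1, k3f = 1,
                       k1r = 0.1, k2r = 0.1, k3r = 0.1,
                       n = 2) {
  rates <- c(k1f = k1f, k2f = k2f, k3f = k3f,
             k1r = k1r, k2r = k2r, k3r = k3r)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (!is.finite(n) || n < 1)
    stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  structure(list(k1f = k1f, k2f = k2f, k3f = k3f,
                 k1r = k1r, k2r = k2r, k3r = k3r, n = n),
            class = "pfl_params")
}

#' @export
print.pfl_params <- function(x, ...) {
  cat("PFL model parameters (per day):\n")
  cat(sprintf("  activation  k1f=%g k2f=%g k3f=%g\n", x$k1f, x$k2f, x$k3f))
  cat(sprintf("  deactivation k1r=%g k2r=%g k3r=%g\n", x$k1r, x$k2r, x$k3r))
  cat(sprintf("  Hill coefficient n=%g\n", x$n))
  invisible(x)
}

#' Instantaneous drive acting on the loop
#'
#' Bundles the time-local external inputs of the model: the dimensionless
#' stiffness drive `S`, the feedback strength `F` and the inhibitor occupancies
#' `u_I` (integrin arm) and `u_P` (Piezo1 arm). An occupancy `u` multiplies the
#' whole activation bracket of its target species by `1 - u`, so `u = 1` fully
#' silences activation of that species while leaving its decay untouched.
#'
#' @param S Dimensionless stiffness drive, `S >= 0`.
#' @param F Feedback strength in \[0, 1\].
#' @param u_I,u_P Inhibitor occupancies in \[0, 1\].
#' @return An object of class `pfl_drive`.
#' @examples
#' pfl_drive(S = 0.01, F = 1)
#' @export
pfl_drive <- function(S = 0, F = 0, u_I = 0, u_P = 0) {
  if (!is.finite(S) || S < 0)
    stop("stiffness drive 'S' must be finite and >= 0", call. = FALSE)
  if (!is.finite(F) || F < 0 || F > 1)
    stop("feedback strength 'F' must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(c(u_I, u_P))) || any(c(u_I, u_P) < 0) || any(c(u_I, u_P) > 1))
    stop("inhibitor occupancies must lie in [0, 1]", call. = FALSE)
  structure(list(S = S, F = F, u_I = u_I, u_P = u_P), class = "pfl_drive")
}

#' @export
print.pfl_drive <- function(x, ...) {
  cat(sprintf("PFL drive: S=%g F=%g u_I=%g u_P=%g\n", x$S, x$F, x$u_I, x$u_P))
  invisible(x)
}

as_pfl_drive <- function(x) {
  if (inherits(x, "pfl_drive")) return(x)
  do.call(pfl_drive, as.list(x))
}

#' Stiffness transduction from elastic modulus to model drive
#'
#' Maps a substrate elastic modulus in kPa onto the dimensionless stiffness
#' drive `S` used by the model, as `S = sigma * E^exponent`. The default is
#' supralinear (`exponent = 2`): mechanosensing through adhesion growth is
#' cooperative, and a supralinear map is also required for the model to place
#' soft substrates (4 kPa) inside the bistable window while stiff substrates
#' (15 kPa) activate the loop within one to two weeks. See the package
#' vignette for the calibration analysis.
#'
#' @param sigma Scale factor (drive per kPa^exponent), `> 0`. Default `5e-5`.
#' @param exponent Power applied to the modulus, `> 0`. Default 2.
#' @return An object of class `pfl_mapping`.
#' @examples
#' m <- stiffness_mapping()
#' stiffness_to_drive(c(4, 15), m)
#' @export
stiffness_mapping <- function(sigma = 5e-5, exponent = 2) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (!is.finite(exponent) || exponent <= 0) stop("'exponent' must be > 0", call. = FALSE)
  structure(list(sigma = sigma, exponent = exponent), class = "pfl_mapping")
}

#' @rdname stiffness_mapping
#' @param E_kpa Elastic modulus in kPa (vectorized).
#' @param mapping A `pfl_mapping` object.
#' @export
stiffness_to_drive <- function(E_kpa, mapping = stiffness_mapping()) {
  if (any(!is.finite(E_kpa)) || any(E_kpa < 0))
    stop("elastic modulus must be finite and >= 0", call. = FALSE)
  mapping$sigma * E_kpa^mapping$exponent
}
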