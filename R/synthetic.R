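## Seeded synthetic-data generators: noisy marker time courses, ellipse-based
## cell-image fixtures with known nuclear/cytoplasmic ratio, and fold-change
## panels. Every generator is bit-reproducible given its seed.

#' Measurement-noise model
#'
#' @param kind `"additive_gaussian"` (noise added to the normalized marker,
#'   observations clamped to \[0, 1\]) or `"lognormal"` (multiplicative
#'   `exp(eps)` noise, natural for fold changes).
#' @param sigma Noise dispersion, `>= 0`. Defaults: 0.05 on the normalized
#'   marker scale; use ~0.2 for lognormal fold changes.
#' @param replicates Number of replicate series, `>= 1`.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("additive_gaussian", "lognormal"),
                        sigma = 0.05, replicates = 3, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, replicates = replicates,
                 seed = seed), class = "noise_model")
}

#' Noisy synthetic marker time course
#'
#' Simulates the model under a schedule, samples the marker `C_a` at the given
#' times and perturbs it by the noise model, emulating replicate activation-
#' marker readouts along a transfer protocol. The noiseless truth is attached
#' as an attribute for testing.
#'
#' @param params A [pfl_params] object.
#' @param schedule A [pfl_schedule].
#' @param times Sample times within the schedule span.
#' @param noise A [noise_model].
#' @param init Initial state.
#' @return Data frame `t, replicate, value` with attribute `"truth"` (data
#'   frame `t, C_a`).
#' @examples
#' sch <- make_dose_schedule("St7So7")
#' obs <- noisy_timecourse(pfl_params(), sch, times = 0:14,
#'                         noise = noise_model(sigma = 0.05, seed = 1))
#' head(obs)
#' @export
noisy_timecourse <- function(params = pfl_params(), schedule, times,
                             noise = noise_model(), init = c(0, 0, 0)) {
  tr <- pfl_simulate(params, schedule, times = sort(unique(times)),
                     init = init)
  truth <- data.frame(t = tr$t, C_a = tr$C_a)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  out <- do.call(rbind, lapply(seq_len(noise$replicates), function(r) {
    eps <- stats::rnorm(nrow(truth), 0, noise$sigma)
    v <- if (noise$kind == "additive_gaussian")
      pmin(pmax(truth$C_a + eps, 0), 1)
    else truth$C_a * exp(eps)
    data.frame(t = truth$t, replicate = r, value = v)
  }))
  attr(out, "truth") <- truth
  out
}

#' Synthetic cell-image fixture with known nuclear/cytoplasmic ratio
#'
#' Paints a cell as an axis-aligned ellipse containing a concentric nuclear
#' ellipse, assigns constant mean intensities to the two compartments plus
#' optional Gaussian pixel noise (floored at zero), and returns the image, the
#' 0/1/2 label mask, and the ground-truth ratio implied by the noiseless
#' means.
#'
#' @param size Image size in pixels, length-2 `(rows, cols)`.
#' @param center Ellipse center `(row, col)`; default image center.
#' @param cell_radii,nucleus_radii Semi-axes in pixels; the nuclear ellipse
#'   must be strictly inside the cell ellipse.
#' @param nuclear_mean,cyto_mean Mean intensities of the compartments, `>= 0`.
#' @param noise_sd Gaussian pixel-noise standard deviation, `>= 0`.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return List with elements `image` (numeric matrix), `mask` (integer
#'   matrix) and `truth` (list with `R_nc`, the compartment means and areas).
#' @examples
#' fx <- yap_image_fixture(nuclear_mean = 200, cyto_mean = 100, seed = 1)
#' fx$truth$R_nc  # 2
#' @export
yap_image_fixture <- function(size = c(96, 96), center = NULL,
                              cell_radii = c(36, 28), nucleus_radii = c(14, 11),
                              nuclear_mean = 200, cyto_mean = 100,
                              noise_sd = 0, seed = NULL) {
  if (any(nucleus_radii >= cell_radii))
    stop("nucleus ellipse must be strictly inside the cell ellipse",
         call. = FALSE)
  if (nuclear_mean < 0 || cyto_mean < 0 || noise_sd < 0)
    stop("intensities and noise must be >= 0", call. = FALSE)
  if (is.null(center)) center <- (size + 1) / 2
  rows <- matrix(seq_len(size[1]), size[1], size[2])
  cols <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  inside <- function(radii)
    ((rows - center[1]) / radii[1])^2 + ((cols - center[2]) / radii[2])^2 <= 1
  cell <- inside(cell_radii)
  nuc <- inside(nucleus_radii)
  mask <- matrix(0L, size[1], size[2])
  mask[cell] <- 1L
  mask[nuc] <- 2L
  img <- matrix(0, size[1], size[2])
  img[mask == 1L] <- cyto_mean
  img[mask == 2L] <- nuclear_mean
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                             size[1], size[2]), 0)
  }
  truth <- list(R_nc = nuclear_mean / cyto_mean,
                nuclear_mean = nuclear_mean, cyto_mean = cyto_mean,
                A_nucleus = sum(mask == 2L), A_cell = sum(mask >= 1L))
  list(image = img, mask = mask, truth = truth)
}

#' Synthetic activation-marker fold-change panel
#'
#' Emulates an RT-PCR style fold-change table across transfer protocols:
#' the true fold of each protocol is its simulated final marker level `C_a`
#' relative to the control protocol, replicated per gene with lognormal
#' noise.
#'
#' @param params A [pfl_params] object.
#' @param protocols Character vector of protocol labels (see [dose_protocol]).
#' @param control Control protocol label.
#' @param genes Marker gene names attached to the rows.
#' @param noise A [noise_model] (lognormal recommended).
#' @param feedback,mapping Model plumbing.
#' @return Data frame `protocol, gene, replicate, fold` with attribute
#'   `"truth"` (data frame `protocol, fold`).
#' @export
marker_foldchange_fixture <- function(params = pfl_params(),
                                      protocols = c("St7So7", "St14So7", "St21"),
                                      control = "St0So7",
                                      genes = c("Acta2", "Col1a1", "Pdgfra"),
                                      noise = noise_model("lognormal",
                                                          sigma = 0.2),
                                      feedback = feedback_ramp(),
                                      mapping = stiffness_mapping()) {
  final_ca <- function(lab) {
    sch <- make_dose_schedule(lab, feedback = feedback, mapping = mapping)
    tr <- pfl_simulate(params, sch, dt = 0.5)
    tr$C_a[nrow(tr)]
  }
  ca0 <- final_ca(control)
  truth <- data.frame(protocol = protocols,
                      fold = vapply(protocols, final_ca, 0) / ca0)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  out <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    do.call(rbind, lapply(genes, function(g) {
      eps <- stats::rnorm(noise$replicates, 0, noise$sigma)
      data.frame(protocol = truth$protocol[i], gene = g,
                 replicate = seq_len(noise$replicates),
                 fold = truth$fold[i] * exp(eps))
    }))
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
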