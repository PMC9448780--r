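## Closed-form quantification formulas used alongside the wet experiments:
## nuclear/cytoplasmic intensity ratio, rheometry-derived elastic modulus,
## hydrogel swelling ratio, and relative expression by the 2^-ddCt method.

#' Nuclear-to-cytoplasmic intensity ratio measurement
#'
#' Bundles the summed fluorescence intensities and pixel counts of the nucleus
#' and whole-cell masks of one cell. The ratio is
#' \deqn{R_{nc} = \frac{I_{nucleus}/A_{nucleus}}
#'                     {(I_{cell}-I_{nucleus})/(A_{cell}-A_{nucleus})}}
#' i.e. mean nuclear intensity over mean cytoplasmic intensity, with the
#' cytoplasm taken as the cell mask minus the nucleus mask.
#'
#' @param I_nucleus,I_cell Summed intensities within the nucleus and cell
#'   masks (`I_cell >= I_nucleus >= 0`).
#' @param A_nucleus,A_cell Pixel counts of the masks
#'   (`A_cell > A_nucleus > 0`).
#' @return An object of class `yap_measurement`.
#' @examples
#' m <- yap_measurement(I_nucleus = 50, A_nucleus = 10,
#'                      I_cell = 110, A_cell = 40)
#' yap_nc_ratio(m)  # 2.5
#' @export
yap_measurement <- function(I_nucleus, A_nucleus, I_cell, A_cell) {
  if (A_nucleus <= 0 || A_cell <= A_nucleus)
    stop("need A_cell > A_nucleus > 0 (nucleus strictly inside cell)",
         call. = FALSE)
  if (I_nucleus < 0 || I_cell < I_nucleus)
    stop("need I_cell >= I_nucleus >= 0", call. = FALSE)
  structure(list(I_nucleus = I_nucleus, A_nucleus = A_nucleus,
                 I_cell = I_cell, A_cell = A_cell),
            class = "yap_measurement")
}

#' @rdname yap_measurement
#' @param m A `yap_measurement`.
#' @export
yap_nc_ratio <- function(m) {
  stopifnot(inherits(m, "yap_measurement"))
  if (m$I_cell == m$I_nucleus)
    stop("zero cytoplasmic signal: I_cell equals I_nucleus", call. = FALSE)
  (m$I_nucleus / m$A_nucleus) /
    ((m$I_cell - m$I_nucleus) / (m$A_cell - m$A_nucleus))
}

#' Measure the nuclear/cytoplasmic ratio from an image and label mask
#'
#' The mask uses label conventions 0 = background, 1 = cell (cytoplasm
#' extent), 2 = nucleus; the nucleus is part of the cell, so the cell mask is
#' `mask >= 1`. An optional constant background offset is subtracted per pixel
#' before summation.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Integer matrix of the same shape with labels 0/1/2.
#' @param background Constant per-pixel offset subtracted before summing.
#' @return A [yap_measurement].
#' @export
yap_measure_image <- function(image, mask, background = 0) {
  if (!all(dim(image) == dim(mask)))
    stop("'image' and 'mask' must have the same shape", call. = FALSE)
  if (!all(mask %in% 0:2))
    stop("'mask' labels must be 0 (background), 1 (cell), 2 (nucleus)",
         call. = FALSE)
  img <- image - background
  cell <- mask >= 1
  nuc <- mask == 2
  if (!any(nuc) || sum(cell) <= sum(nuc))
    stop("mask must contain a nucleus strictly inside the cell", call. = FALSE)
  yap_measurement(I_nucleus = sum(img[nuc]), A_nucleus = sum(nuc),
                  I_cell = sum(img[cell]), A_cell = sum(cell))
}

#' Elastic modulus from rheometry
#'
#' Combines the storage and loss moduli into the complex-modulus magnitude
#' \eqn{G = \sqrt{G'^2 + G''^2}} and converts to Young's modulus
#' \eqn{E = 2G(1+\nu)}. For an incompressible gel (\eqn{\nu = 0.5}),
#' \eqn{E = 3G}.
#'
#' @param G_storage,G_loss Storage and loss moduli in kPa, `>= 0`.
#' @param nu Poisson ratio in \[0, 0.5\] (default 0.5).
#' @return Named list with `G` and `E` (kPa).
#' @examples
#' elastic_modulus_from_rheometry(3, 4)  # G = 5, E = 15
#' @export
elastic_modulus_from_rheometry <- function(G_storage, G_loss, nu = 0.5) {
  if (any(c(G_storage, G_loss) < 0))
    stop("moduli must be >= 0", call. = FALSE)
  if (nu < 0 || nu > 0.5)
    stop("Poisson ratio must lie in [0, 0.5]", call. = FALSE)
  G <- sqrt(G_storage^2 + G_loss^2)
  list(G = G, E = 2 * G * (1 + nu))
}

#' Hydrogel swelling ratio
#'
#' @param Ws Swollen weight, `>= Wd`.
#' @param Wd Dry weight, `> 0`.
#' @return `Ws / Wd`.
#' @examples
#' swelling_ratio(10, 2)  # 5
#' @export
swelling_ratio <- function(Ws, Wd) {
  if (Wd <= 0) stop("dry weight must be > 0", call. = FALSE)
  if (Ws < Wd) stop("swollen weight must be >= dry weight", call. = FALSE)
  Ws / Wd
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and sample, computes
#' `fold = 2^-((Ct_gene - Ct_ref)_sample - (Ct_gene - Ct_ref)_control)`,
#' normalizing to a reference (housekeeping) gene and a control sample. The
#' control sample maps to fold 1 for every gene.
#'
#' @param table Data frame with columns `gene`, `sample`, `ct`.
#' @param reference_gene Reference gene id present in every sample.
#' @param control_sample Control sample id present for every gene.
#' @return Data frame `gene, sample, ddct, fold` (reference gene excluded).
#' @examples
#' tab <- data.frame(gene = c("Acta2", "Gapdh", "Acta2", "Gapdh"),
#'                   sample = c("stiff", "stiff", "ctrl", "ctrl"),
#'                   ct = c(20, 15, 22, 15))
#' delta_delta_ct(tab, "Gapdh", "ctrl")  # Acta2/stiff: fold 4
#' @export
delta_delta_ct <- function(table, reference_gene, control_sample) {
  req <- c("gene", "sample", "ct")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop("'table' needs columns gene, sample, ct", call. = FALSE)
  if (any(!is.finite(table$ct))) stop("Ct values must be finite", call. = FALSE)
  samples <- unique(table$sample)
  genes <- setdiff(unique(table$gene), reference_gene)
  ref <- table[table$gene == reference_gene, ]
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref))
    stop("missing reference gene Ct for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ctrl <- table[table$sample == control_sample, ]
  missing_ctrl <- setdiff(genes, ctrl$gene)
  if (!control_sample %in% samples || length(missing_ctrl))
    stop("missing control-sample Ct for gene(s): ",
         paste(if (control_sample %in% samples) missing_ctrl else genes,
               collapse = ", "), call. = FALSE)
  ct_of <- function(g, s) {
    v <- table$ct[table$gene == g & table$sample == s]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- expand.grid(gene = genes, sample = samples,
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$ddct <- mapply(function(g, s) {
    dct <- ct_of(g, s) - ct_of(reference_gene, s)
    dct0 <- ct_of(g, control_sample) - ct_of(reference_gene, control_sample)
    dct - dct0
  }, out$gene, out$sample)
  out <- out[is.finite(out$ddct), , drop = FALSE]
  out$fold <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}
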