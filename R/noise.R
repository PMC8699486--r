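#' Interferometric noise metrology
#'
#' Spatial and temporal OPD noise statistics of a quantitative phase imaging
#' system: the spatial noise level is the standard deviation across one OPD
#' map; the temporal noise level is the standard deviation per single
#' diffraction-limited spot across the frames of a recorded stack.
#'
#' @name noise
NULL

#' Diffraction-limited spot size in pixels
#'
#' Spot diameter `1.22 * lambda / NA` converted to pixels (rounded up, at
#' least 1). With the 633 nm HeNe line and a 0.66 NA objective the spot is
#' about 1.17 um across.
#'
#' @param wavelength wavelength in nm.
#' @param numerical_aperture objective NA (dimensionless).
#' @param pixel_size um/px in the sample plane.
#' @return spot size in pixels (integer >= 1).
#' @export
spot_size <- function(wavelength = 633, numerical_aperture = 0.66,
                      pixel_size = 0.16) {
  if (wavelength <= 0 || numerical_aperture <= 0 || pixel_size <= 0)
    stop("all spot_size inputs must be > 0")
  d_um <- 1.22 * (wavelength / 1000) / numerical_aperture
  max(1L, as.integer(ceiling(d_um / pixel_size)))
}

#' Temporal noise per diffraction-limited spot
#'
#' Each frame is block-averaged over non-overlapping `spot_px` x `spot_px`
#' tiles; the standard deviation of each tile's mean across frames is the
#' per-spot temporal noise, and their average is the temporal noise level.
#' For iid per-pixel noise of std sigma the block mean has std `sigma /
#' spot_px`.
#'
#' @param stack an [opd_stack()] (or 3-D array `[row, col, frame]`).
#' @param spot_px spot size in pixels (see [spot_size()]).
#' @return list with `temporal_std_map` (matrix of per-tile stds, nm) and
#'   `temporal_std_avg` (nm).
#' @export
temporal_noise <- function(stack, spot_px = 1) {
  a <- unclass(stack)
  stopifnot(length(dim(a)) == 3)
  nf <- dim(a)[3]
  if (nf < 2) stop("temporal noise needs at least 2 frames")
  spot_px <- as.integer(spot_px)
  stopifnot(spot_px >= 1)
  nr <- dim(a)[1] %/% spot_px
  nc <- dim(a)[2] %/% spot_px
  if (nr < 1 || nc < 1) stop("spot larger than the frame")
  a <- a[seq_len(nr * spot_px), seq_len(nc * spot_px), , drop = FALSE]
  # block means: collapse each spot_px x spot_px tile
  dim(a) <- c(spot_px, nr, spot_px * nc * nf)
  m <- colMeans(a)                       # (nr, spot_px * nc * nf)
  dim(m) <- c(nr, spot_px, nc * nf)
  m <- aperm(m, c(2, 1, 3))              # (spot_px, nr, nc*nf)
  tiles <- colMeans(m)                   # (nr, nc * nf)
  dim(tiles) <- c(nr * nc, nf)
  mu <- rowMeans(tiles)
  v <- (rowSums(tiles^2) - nf * mu^2) / (nf - 1)
  stds <- sqrt(pmax(v, 0))
  list(temporal_std_map = matrix(stds, nr, nc),
       temporal_std_avg = mean(stds))
}

#' Spatial noise of one OPD map
#'
#' Standard deviation across the (optionally masked) pixels of a single map.
#'
#' @param opd an [opd_map] or matrix, nm.
#' @param mask optional logical matrix of pixels to include.
#' @return std in nm.
#' @export
spatial_noise <- function(opd, mask = NULL) {
  x <- as_plain_matrix(opd)
  v <- if (is.null(mask)) as.numeric(x) else x[mask]
  if (length(v) < 2) stop("spatial noise needs at least 2 pixels")
  stats::sd(v)
}

#' Fold change between two noise levels
#'
#' @param a,b noise levels in the same units; `b > 0`.
#' @return `a / b`.
#' @export
noise_ratio <- function(a, b) {
  if (b == 0) stop("reference noise level must be non-zero")
  a / b
}

#' Full noise report for an OPD stack
#'
#' Computes the per-frame spatial stds and their average, the per-spot
#' temporal std map and its average, and Freedman-Diaconis histograms of both
#' distributions (bin edges recorded for reproducibility).
#'
#' @param stack an [opd_stack()].
#' @param spot_px spot size in px; computed from `numerical_aperture` and the
#'   stack calibration when omitted.
#' @param numerical_aperture objective NA used when `spot_px` is omitted.
#' @param mask optional mask for the spatial stds.
#' @return object of class `noise_report`: list with `spatial_std_per_frame`,
#'   `spatial_std_avg`, `temporal_std_map`, `temporal_std_avg`,
#'   `spot_size_px`, `histograms` (each with `breaks`, `counts`, `mids`).
#' @export
noise_report <- function(stack, spot_px = NULL, numerical_aperture = 0.66,
                         mask = NULL) {
  stopifnot(inherits(stack, "opd_stack"))
  if (is.null(spot_px))
    spot_px <- spot_size(wavelength(stack), numerical_aperture,
                         pixel_size(stack))
  nf <- dim(stack)[3]
  spf <- vapply(seq_len(nf), function(f)
    spatial_noise(unclass(stack)[, , f], mask), numeric(1))
  tn <- temporal_noise(stack, spot_px)
  fd_hist <- function(v) {
    # Freedman-Diaconis, falling back to Sturges when the FD bin width
    # degenerates (near-identical values)
    bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    br <- if (bw > 0 && diff(range(v)) / bw < 1e4) "FD" else "Sturges"
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids)
  }
  structure(list(
    spatial_std_per_frame = spf,
    spatial_std_avg = mean(spf),
    temporal_std_map = tn$temporal_std_map,
    temporal_std_avg = tn$temporal_std_avg,
    spot_size_px = spot_px,
    n_frames = nf,
    histograms = list(spatial = fd_hist(spf),
                      temporal = fd_hist(as.numeric(tn$temporal_std_map)))),
    class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> %d frames, spot %d px\n", x$n_frames,
              x$spot_size_px))
  cat(sprintf("  average spatial std  %.3f nm\n", x$spatial_std_avg))
  cat(sprintf("  average temporal std %.3f nm\n", x$temporal_std_avg))
  invisible(x)
}
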