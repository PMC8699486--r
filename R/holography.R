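#' Off-axis hologram reconstruction
#'
#' Reconstruction of quantitative OPD maps from single-exposure off-axis
#' interferograms: Fourier transform, selection (crop) of one cross-correlation
#' term, inverse transform, two-dimensional phase unwrapping of the complex
#' wavefront's argument, conversion to optical path delay, and polynomial
#' background flattening.
#'
#' @name holography
NULL

# wrapped DFT frequency axis in cycles/pixel for n samples
freq_axis <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

#' Estimate the off-axis carrier frequency
#'
#' Locates the strongest Fourier-magnitude peak outside a DC exclusion disc and
#' refines it to sub-pixel precision by a local 3x3 magnitude centroid. The
#' peak is searched in the half-plane `fx >= 0` (the two cross-correlation
#' terms are complex conjugates, so one representative suffices).
#'
#' @param ig an [interferogram] (or plain matrix) with visible fringes.
#' @param exclude_radius radius (cycles/pixel) of the DC disc excluded from the
#'   search; default 0.05.
#' @param k detection threshold: the peak must exceed `k` times the median
#'   Fourier magnitude outside the DC disc; default 5.
#' @return numeric vector `c(fx, fy)` in cycles/pixel (`fx` along columns,
#'   `fy` along rows).
#' @export
estimate_carrier <- function(ig, exclude_radius = 0.05, k = 5) {
  x <- as_plain_matrix(ig)
  nr <- nrow(x); nc <- ncol(x)
  F <- stats::fft(x)
  mag <- Mod(F)
  fy <- freq_axis(nr)          # row frequencies
  fx <- freq_axis(nc)          # column frequencies
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  ok <- (FX^2 + FY^2) > exclude_radius^2 & (FX > 0 | (FX == 0 & FY > 0))
  bg <- stats::median(mag[(FX^2 + FY^2) > exclude_radius^2])
  cand <- mag
  cand[!ok] <- -Inf
  pk <- which.max(cand)
  if (!is.finite(cand[pk]) || cand[pk] <= k * bg)
    stop("no carrier detected")
  pi0 <- (pk - 1) %% nr + 1
  pj0 <- (pk - 1) %/% nr + 1
  # 3x3 centroid with periodic indexing
  ii <- ((pi0 - 2):(pi0)) %% nr + 1
  jj <- ((pj0 - 2):(pj0)) %% nc + 1
  w <- mag[ii, jj]
  off_i <- sum(rowSums(w) * (-1:1)) / sum(w)
  off_j <- sum(colSums(w) * (-1:1)) / sum(w)
  f_row <- fy[pi0] + off_i / nr
  f_col <- fx[pj0] + off_j / nc
  c(fx = f_col, fy = f_row)
}

#' Demodulate one cross-correlation term
#'
#' Shifts the interferogram spectrum so the selected cross-correlation term is
#' centered at zero frequency (by multiplying with a complex carrier
#' exponential, which is exact for sub-pixel carriers), applies a circular
#' low-pass crop of the given radius, and inverse transforms. The argument of
#' the result is the wrapped sample phase; its modulus is proportional to the
#' fringe amplitude.
#'
#' @param ig an [interferogram].
#' @param carrier `c(fx, fy)` in cycles/pixel.
#' @param crop_radius crop radius in cycles/pixel; default 0.7 times the
#'   carrier magnitude (see the methods vignette for the choice).
#' @return complex matrix with `pixel_size`/`wavelength` attributes.
#' @export
demodulate_sideband <- function(ig, carrier, crop_radius = NULL) {
  x <- as_plain_matrix(ig)
  nr <- nrow(x); nc <- ncol(x)
  cm <- sqrt(sum(carrier^2))
  if (is.null(crop_radius)) crop_radius <- 0.7 * cm
  if (crop_radius <= 0) stop("crop_radius must be > 0")
  if (cm <= crop_radius) stop("orders overlap")
  X0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  Y0 <- matrix(0:(nr - 1), nr, nc)
  demod <- x * exp(-2i * pi * (carrier[1] * X0 + carrier[2] * Y0))
  F <- stats::fft(demod)
  FY <- matrix(freq_axis(nr), nr, nc)
  FX <- matrix(freq_axis(nc), nr, nc, byrow = TRUE)
  F[FX^2 + FY^2 > crop_radius^2] <- 0
  field <- stats::fft(F, inverse = TRUE) / (nr * nc)
  attr(field, "pixel_size") <- attr(ig, "pixel_size")
  attr(field, "wavelength") <- attr(ig, "wavelength")
  field
}

#' Two-dimensional phase unwrapping
#'
#' Restores a continuous phase surface from values wrapped into `(-pi, pi]`.
#' The default `"reliability"` method is a reliability-sorting unwrapper
#' (second-difference quality, edges merged in decreasing reliability with a
#' union-find over pixel groups), robust on low-residue fields. `"itoh"` is a
#' simple row/column cumulative method kept as a debugging fallback.
#'
#' The output is congruent to the input modulo 2*pi at every pixel; smooth
#' fields are restored up to a single global multiple of 2*pi.
#'
#' @param wrapped matrix of wrapped phase in radians.
#' @param method `"reliability"` (default) or `"itoh"`.
#' @return matrix of unwrapped phase in radians.
#' @export
unwrap_phase <- function(wrapped, method = c("reliability", "itoh")) {
  method <- match.arg(method)
  x <- as_plain_matrix(wrapped)
  out <- switch(method,
    reliability = unwrap_reliability_cpp(x),
    itoh = unwrap_itoh(x))
  attributes(out) <- attributes(x)[c("dim")]
  dimnames(out) <- NULL
  out
}

wrap_to_pi <- function(x) x - 2 * pi * floor(x / (2 * pi) + 0.5)

unwrap_itoh <- function(x) {
  # unwrap first column, then each row from its first element
  col1 <- x[, 1]
  col1 <- cumsum(c(col1[1], wrap_to_pi(diff(col1))))
  dx <- wrap_to_pi(t(diff(t(x))))               # wrapped row differences
  out <- cbind(col1, col1 + t(apply(dx, 1, cumsum)))
  dimnames(out) <- NULL
  out
}

#' Convert phase to optical path delay
#'
#' `OPD = phase * wavelength / (2 * pi)`, elementwise, OPD in the units of
#' `wavelength` (nanometers throughout this package).
#'
#' @param phase matrix (or scalar) of phase in radians.
#' @param wavelength wavelength in nanometers.
#' @return same shape as `phase`, OPD in nanometers.
#' @export
phase_to_opd <- function(phase, wavelength) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  phase * wavelength / (2 * pi)
}

#' Flatten the OPD background
#'
#' Fits a 2D polynomial of the given order to background pixels and subtracts
#' it, then shifts so the background median is zero. Background pixels are
#' either supplied as a mask or identified robustly: pixels below the 75th
#' percentile seed the fit, and two re-fits trim pixels whose residual exceeds
#' 3 robust standard deviations (cells and other objects are thereby
#' excluded).
#'
#' @param opd an [opd_map] (or matrix).
#' @param order polynomial order (>= 0); default 2.
#' @param mask optional logical matrix marking background pixels.
#' @param max_points background pixels are subsampled to at most this many for
#'   the least-squares fit; default 20000.
#' @return flattened map of the same class as the input.
#' @export
flatten_background <- function(opd, order = 2, mask = NULL, max_points = 20000) {
  if (order < 0) stop("polynomial order must be >= 0")
  x <- as_plain_matrix(opd)
  nr <- nrow(x); nc <- ncol(x)
  U <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  V <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  terms <- list()
  for (p in 0:order) for (q in 0:(order - p)) terms[[length(terms) + 1]] <- c(p, q)
  design <- function(idx) {
    vapply(terms, function(t) U[idx]^t[1] * V[idx]^t[2], numeric(length(idx)))
  }
  if (is.null(mask)) {
    bg <- which(x <= stats::quantile(x, 0.75))
  } else {
    stopifnot(identical(dim(mask), dim(x)))
    bg <- which(mask)
  }
  if (length(bg) < length(terms)) stop("not enough background pixels")
  fit_idx <- if (length(bg) > max_points) sort(sample(bg, max_points)) else bg
  coef <- NULL
  for (iter in 1:3) {
    A <- design(fit_idx)
    coef <- qr.coef(qr(A), x[fit_idx])
    coef[is.na(coef)] <- 0
    if (iter < 3 && is.null(mask)) {
      r_all <- x[bg] - design(bg) %*% coef
      s <- stats::mad(r_all)
      if (s == 0) break
      keep <- bg[abs(r_all) < 3 * s]
      if (length(keep) >= length(terms)) {
        fit_idx <- if (length(keep) > max_points) sort(sample(keep, max_points)) else keep
      }
    }
  }
  full <- matrix(design(seq_along(x)) %*% coef, nr, nc)
  out <- x - full
  out <- out - stats::median(out[bg])
  if (inherits(opd, "opd_map"))
    opd_map(out, pixel_size(opd), wavelength(opd))
  else out
}

#' Reconstruct an OPD map from an off-axis interferogram
#'
#' Full chain: carrier estimation (unless supplied), sideband demodulation,
#' 2D phase unwrapping, phase-to-OPD conversion, and polynomial background
#' flattening. Deterministic for a fixed input and configuration.
#'
#' Because only one of the two conjugate cross-correlation terms is cropped,
#' the sign of the recovered phase depends on which term the carrier estimate
#' picked; with `assume_nonnegative = TRUE` (default) the map is negated when
#' its strong features are predominantly negative, which is correct for cells
#' (positive OPD objects on a flat background).
#'
#' @param ig an [interferogram].
#' @param carrier optional `c(fx, fy)` override (cycles/pixel).
#' @param crop_radius optional crop radius override (cycles/pixel).
#' @param flatten_order background polynomial order; default 2.
#' @param unwrap_method passed to [unwrap_phase()].
#' @param assume_nonnegative flip sign if the dominant features are negative.
#' @return an [opd_map] in nanometers.
#' @export
reconstruct <- function(ig, carrier = NULL, crop_radius = NULL,
                        flatten_order = 2,
                        unwrap_method = c("reliability", "itoh"),
                        assume_nonnegative = TRUE) {
  stopifnot(inherits(ig, "interferogram"))
  if (is.null(carrier)) carrier <- estimate_carrier(ig)
  field <- demodulate_sideband(ig, carrier, crop_radius)
  ph <- unwrap_phase(Arg(field), method = match.arg(unwrap_method))
  opd <- phase_to_opd(ph, wavelength(ig))
  if (assume_nonnegative) {
    md <- stats::median(opd)
    hi <- stats::quantile(opd, 0.999) - md
    lo <- md - stats::quantile(opd, 0.001)
    if (lo > hi) opd <- -opd
  }
  out <- opd_map(opd, pixel_size(ig), wavelength(ig))
  flatten_background(out, order = flatten_order)
}
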