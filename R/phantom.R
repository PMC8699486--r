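#' Sperm phantom specification
#'
#' Describes a ground-truthed synthetic scene: an elliptical sperm head with a
#' reduced-OPD anterior (acrosomal) region, a midpiece capsule continuing the
#' head axis (optionally offset by a few degrees), a thin faint tail, optional
#' vacuole depressions and a residual-cytoplasm blob at the neck, on an
#' optionally non-flat background of hexagonally tiled residual droplet
#' curvature. All physical coordinates are in micrometers, OPD in nanometers.
#'
#' The default geometry encodes a morphologically normal cell: a 5 x 3 um
#' head (width-to-length ratio 3:5), an acrosome occupying 55% of the head
#' area at 0.6 times the head OPD, and a midpiece as long as the head. The
#' head OPD peak (300 nm) is a plausible value for a flattened sperm head at
#' 633 nm; it keeps the phase below the wrapping limit of half a wavelength.
#' The whole scene is low-pass smoothed with a Gaussian of `edge_sigma_um`
#' (default 0.2 um, well below the ~1.2 um diffraction-limited spot of a
#' 0.66 NA objective), which anti-aliases the rasterization and keeps the
#' scene's spectrum inside the demodulation passband of the default off-axis
#' carrier.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param head_major,head_minor full head length and width in um
#'   (`head_major > head_minor > 0`).
#' @param head_opd_peak OPD of the posterior head plateau in nm.
#' @param acrosome_fraction fraction of head area occupied by the acrosome,
#'   in `[0, 1]`.
#' @param acrosome_opd_scale multiplier (< 1 for contrast) applied to the head
#'   OPD in the acrosomal region; a value of 1 renders no contrast and is
#'   flagged in the ground truth.
#' @param midpiece_length_um midpiece length in um (0 disables the midpiece).
#' @param midpiece_axis_offset_deg angle between the head major axis and the
#'   midpiece axis, degrees.
#' @param vacuoles vacuole list: a data frame (or list of length-4 vectors)
#'   with columns `du_um`, `dv_um` (center offset from the head center in the
#'   cell frame, `du` anterior-positive), `radius_um`, `depth_nm`. Vacuoles
#'   must lie inside the head and be shallower than the local OPD level.
#' @param residual_cytoplasm_fraction area of the residual-cytoplasm blob as a
#'   fraction of head area (0 disables it).
#' @param droplet_pitch hexagonal droplet-rug center spacing in um.
#' @param droplet_residual_opd amplitude (max minus min) of the leftover
#'   droplet curvature in nm; 0 (default) reflects the flattened, oil-covered
#'   rug in which droplet curvature is not visible in the OPD map.
#' @param midpiece_width_um,midpiece_opd_scale,tail_length_um,tail_opd_scale,
#'   cytoplasm_opd_scale secondary rendering levels (see vignette).
#' @param edge_sigma_um Gaussian smoothing of the final scene, um.
#' @param center_um cell center `c(x, y)` in um; default image center.
#' @param orientation_deg head major-axis orientation (anterior direction),
#'   degrees counter-clockwise from +x.
#' @param seed integer seed controlling any stochastic rendering.
#' @return object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(image_shape = c(512, 512), pixel_size = 0.16,
                         head_major = 5, head_minor = 3, head_opd_peak = 300,
                         acrosome_fraction = 0.55, acrosome_opd_scale = 0.6,
                         midpiece_length_um = 5, midpiece_axis_offset_deg = 0,
                         vacuoles = NULL, residual_cytoplasm_fraction = 0,
                         droplet_pitch = 40, droplet_residual_opd = 0,
                         midpiece_width_um = 1, midpiece_opd_scale = 0.4,
                         tail_length_um = 20, tail_opd_scale = 0.08,
                         cytoplasm_opd_scale = 0.35,
                         edge_sigma_um = 0.2,
                         center_um = NULL, orientation_deg = 0, seed = 1L) {
  if (!(head_major > head_minor && head_minor > 0))
    stop("need head_major > head_minor > 0")
  if (acrosome_fraction < 0 || acrosome_fraction > 1)
    stop("acrosome_fraction must be in [0, 1]")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (head_opd_peak < 0 || droplet_residual_opd < 0)
    stop("all OPD levels must be >= 0")
  if (droplet_pitch <= 0) stop("droplet_pitch must be > 0")
  vacuoles <- normalize_vacuoles(vacuoles)
  a <- head_major / 2; b <- head_minor / 2
  if (nrow(vacuoles)) {
    r <- vacuoles$radius_um
    inside <- r < b &
      (vacuoles$du_um / pmax(a - r, 1e-9))^2 +
      (vacuoles$dv_um / pmax(b - r, 1e-9))^2 <= 1
    if (!all(inside)) stop("vacuole outside head")
    if (any(vacuoles$depth_nm >= head_opd_peak * min(1, acrosome_opd_scale)))
      stop("vacuole depth exceeds local head OPD")
  }
  if (is.null(center_um))
    center_um <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2) * pixel_size
  spec <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    head_major = head_major, head_minor = head_minor,
    head_opd_peak = head_opd_peak,
    acrosome_fraction = acrosome_fraction,
    acrosome_opd_scale = acrosome_opd_scale,
    midpiece_length_um = midpiece_length_um,
    midpiece_axis_offset_deg = midpiece_axis_offset_deg,
    vacuoles = vacuoles,
    residual_cytoplasm_fraction = residual_cytoplasm_fraction,
    droplet_pitch = droplet_pitch,
    droplet_residual_opd = droplet_residual_opd,
    midpiece_width_um = midpiece_width_um,
    midpiece_opd_scale = midpiece_opd_scale,
    tail_length_um = tail_length_um, tail_opd_scale = tail_opd_scale,
    cytoplasm_opd_scale = cytoplasm_opd_scale,
    edge_sigma_um = edge_sigma_um,
    center_um = center_um, orientation_deg = orientation_deg,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

normalize_vacuoles <- function(v) {
  if (is.null(v) || (is.data.frame(v) && nrow(v) == 0))
    return(data.frame(du_um = numeric(0), dv_um = numeric(0),
                      radius_um = numeric(0), depth_nm = numeric(0)))
  if (is.data.frame(v)) {
    stopifnot(all(c("du_um", "dv_um", "radius_um", "depth_nm") %in% names(v)))
    return(v[c("du_um", "dv_um", "radius_um", "depth_nm")])
  }
  if (is.numeric(v)) v <- list(v)
  m <- do.call(rbind, lapply(v, function(x) {
    stopifnot(length(x) == 4)
    as.numeric(x)
  }))
  data.frame(du_um = m[, 1], dv_um = m[, 2], radius_um = m[, 3],
             depth_nm = m[, 4])
}

# area fraction of an ellipse with normalized major-axis coordinate > t
ellipse_cap_fraction <- function(t) (acos(t) - t * sqrt(1 - t^2)) / pi

# normalized cut position realizing an anterior cap of area fraction f
acrosome_cut <- function(f) {
  if (f <= 0) return(1)
  if (f >= 1) return(-1)
  stats::uniroot(function(t) ellipse_cap_fraction(t) - f,
                 c(-1, 1), tol = 1e-10)$root
}

# min distance from point p (cell frame, um) to the head ellipse boundary
dist_to_ellipse <- function(p, a, b) {
  t <- seq(0, 2 * pi, length.out = 721)
  min(sqrt((a * cos(t) - p[1])^2 + (b * sin(t) - p[2])^2))
}

# Gaussian low-pass via FFT (exact Gaussian transfer function, periodic)
gaussian_smooth <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  FY <- matrix(freq_axis(nr), nr, nc)
  FX <- matrix(freq_axis(nc), nr, nc, byrow = TRUE)
  H <- exp(-2 * pi^2 * sigma_px^2 * (FX^2 + FY^2))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / (nr * nc)
}

# rasterize one cell into the full-size OPD canvas (nm); returns the canvas
# contribution and the resolved cytoplasm center (um, lab frame) or NULL
rasterize_cell <- function(spec, center_um, orientation_deg) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size
  a <- spec$head_major / 2; b <- spec$head_minor / 2
  th <- orientation_deg * pi / 180
  reach <- a + spec$midpiece_length_um + spec$tail_length_um + 3
  # bounding box in pixels
  cx <- center_um[1]; cy <- center_um[2]
  j0 <- max(1, floor((cx - reach) / ps) + 1); j1 <- min(nc, ceiling((cx + reach) / ps) + 1)
  i0 <- max(1, floor((cy - reach) / ps) + 1); i1 <- min(nr, ceiling((cy + reach) / ps) + 1)
  if (j0 > j1 || i0 > i1) return(list(canvas = matrix(0, nr, nc), cyto = NULL))
  xs <- ((j0:j1) - 1) * ps - cx
  ys <- ((i0:i1) - 1) * ps - cy
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  U <- cos(th) * X + sin(th) * Y        # anterior-positive axis coordinate
  V <- -sin(th) * X + cos(th) * Y
  P <- spec$head_opd_peak
  lv <- matrix(0, length(ys), length(xs))
  # analytic soft edges one pixel wide: a cubic smoothstep makes the raster a
  # C1 function of the cell position, so sub-pixel motion translates the
  # scene faithfully (no aliasing jitter in downstream centroids); the
  # profile is antisymmetric about the nominal edge, so half-level contours
  # and areas are unbiased
  w_um <- ps
  soft <- function(signed_d) {
    t <- pmin(1, pmax(0, signed_d / w_um + 0.5))
    t * t * (3 - 2 * t)
  }

  # structures are layered by coverage blending, lv <- lv*(1-c) + level*c,
  # so the composite stays C1 (no pmax creases) under sub-pixel motion
  blend <- function(lv, cov, level) lv * (1 - cov) + level * cov
  beta <- spec$midpiece_axis_offset_deg * pi / 180
  dir <- c(-cos(beta), sin(beta))       # posterior direction, offset to +v
  S <- c(-a, 0)
  if (spec$midpiece_length_um > 0) {
    E <- S + spec$midpiece_length_um * dir
    if (spec$tail_length_um > 0) {
      Et <- E + spec$tail_length_um * dir
      dt <- dist_to_segment(U, V, E, Et)
      lv <- blend(lv, soft(ps - dt), spec$tail_opd_scale * P)
    }
    d <- dist_to_segment(U, V, S, E)
    lv <- blend(lv, soft(spec$midpiece_width_um / 2 - d),
                spec$midpiece_opd_scale * P)
  }
  cyto_lab <- NULL
  if (spec$residual_cytoplasm_fraction > 0) {
    rc <- sqrt(spec$residual_cytoplasm_fraction * a * b)
    cen <- c(-a, rc + 0.8)
    while (dist_to_ellipse(cen, a, b) < rc + 0.05) cen[2] <- cen[2] + 0.1
    dcy <- sqrt((U - cen[1])^2 + (V - cen[2])^2)
    lv <- blend(lv, soft(rc - dcy), spec$cytoplasm_opd_scale * P)
    cyto_lab <- center_um +
      c(cos(th) * cen[1] - sin(th) * cen[2], sin(th) * cen[1] + cos(th) * cen[2])
  }

  # head with acrosome contrast, vacuole depressions subtracted;
  # (1 - sqrt(E)) * b approximates the signed distance to the ellipse
  Eq <- (U / a)^2 + (V / b)^2
  head_cov <- soft((1 - sqrt(Eq)) * b)
  u_cut <- a * acrosome_cut(spec$acrosome_fraction)
  frac_acr <- soft(U - u_cut)
  head_lv <- P * (spec$acrosome_opd_scale * frac_acr + (1 - frac_acr))
  vac <- spec$vacuoles
  if (nrow(vac)) for (k in seq_len(nrow(vac))) {
    dv <- sqrt((U - vac$du_um[k])^2 + (V - vac$dv_um[k])^2)
    head_lv <- head_lv - soft(vac$radius_um[k] - dv) * vac$depth_nm[k]
  }
  lv <- blend(lv, head_cov, pmax(head_lv, 0))
  canvas <- matrix(0, nr, nc)
  canvas[i0:i1, j0:j1] <- lv
  list(canvas = canvas, cyto = cyto_lab)
}

# distance from grid points to segment [S, E] (all in the same frame)
dist_to_segment <- function(U, V, S, E) {
  d <- E - S
  L2 <- sum(d^2)
  if (L2 == 0) return(sqrt((U - S[1])^2 + (V - S[2])^2))
  t <- pmin(1, pmax(0, ((U - S[1]) * d[1] + (V - S[2]) * d[2]) / L2))
  sqrt((U - (S[1] + t * d[1]))^2 + (V - (S[2] + t * d[2]))^2)
}

# analytic ground-truth morphometrics of one spec
truth_row <- function(spec, cell_id, center_um, orientation_deg) {
  a <- spec$head_major / 2; b <- spec$head_minor / 2
  tibble::tibble(
    cell_id = cell_id,
    x_um = center_um[1], y_um = center_um[2],
    orientation_deg = orientation_deg,
    head_major_um = spec$head_major, head_minor_um = spec$head_minor,
    radii_ratio = spec$head_minor / spec$head_major,
    acrosome_head_ratio_pct = 100 * spec$acrosome_fraction,
    midpiece_length_um = spec$midpiece_length_um,
    midpiece_head_ratio = spec$midpiece_length_um / spec$head_major,
    axis_offset_deg = spec$midpiece_axis_offset_deg,
    vacuole_count = nrow(spec$vacuoles),
    vacuole_area_fraction = sum(spec$vacuoles$radius_um^2) / (a * b),
    residual_cytoplasm_fraction = spec$residual_cytoplasm_fraction,
    head_opd_peak_nm = spec$head_opd_peak,
    acrosome_contrast = spec$acrosome_opd_scale < 1)
}

#' Generate a ground-truthed sperm phantom scene
#'
#' Rasterizes one or more sperm-shaped phase objects onto a common OPD canvas
#' (plus the residual droplet rug when `droplet_residual_opd > 0`) and records
#' the analytic ground-truth morphometrics of every cell. Ground-truth values
#' are exact functions of the specification, not measurements.
#'
#' @param spec a [phantom_spec()], or a list of them (one per cell).
#' @param centers_um optional n x 2 matrix of cell centers (um); default: the
#'   spec's `center_um`.
#' @param orientations_deg optional vector of head orientations (degrees).
#' @return `list(opd = opd_map, truth = list(morphometrics, cell_centers,
#'   injected_noise_sigma))`.
#' @export
generate_sperm_phantom <- function(spec, centers_um = NULL,
                                   orientations_deg = NULL) {
  specs <- if (inherits(spec, "phantom_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "phantom_spec")))
  s1 <- specs[[1]]
  if (is.null(centers_um))
    centers_um <- do.call(rbind, lapply(specs, function(s) s$center_um))
  centers_um <- matrix(centers_um, ncol = 2)
  n <- nrow(centers_um)
  if (length(specs) == 1 && n > 1) specs <- rep(specs, n)
  if (is.null(orientations_deg))
    orientations_deg <- vapply(specs, function(s) s$orientation_deg, numeric(1))
  stopifnot(length(specs) == n, length(orientations_deg) == n)
  canvas <- matrix(0, s1$image_shape[1], s1$image_shape[2])
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    rc <- rasterize_cell(specs[[k]], centers_um[k, ], orientations_deg[k])
    canvas <- pmax(canvas, rc$canvas)
    rows[[k]] <- truth_row(specs[[k]], k, centers_um[k, ], orientations_deg[k])
  }
  if (s1$droplet_residual_opd > 0)
    canvas <- canvas + as_plain_matrix(generate_droplet_rug(s1))
  canvas <- gaussian_smooth(canvas, s1$edge_sigma_um / s1$pixel_size)
  list(opd = opd_map(canvas, s1$pixel_size),
       truth = list(morphometrics = do.call(rbind, rows),
                    cell_centers = centers_um,
                    injected_noise_sigma = 0))
}

#' Generate the residual droplet-rug background
#'
#' Smooth background of hexagonally tiled low-amplitude OPD bumps emulating
#' leftover curvature of the self-assembled, flattened droplet rug. The bump
#' amplitude (max minus min of the background) equals `droplet_residual_opd`.
#'
#' @param spec a [phantom_spec()]; uses `droplet_pitch`,
#'   `droplet_residual_opd`, `image_shape` and `pixel_size`.
#' @return an [opd_map] of the background alone.
#' @export
generate_droplet_rug <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size
  p <- spec$droplet_pitch
  if (p < 2 * ps) stop("droplet_pitch smaller than 2 pixels")
  amp <- spec$droplet_residual_opd
  canvas <- matrix(0, nr, nc)
  if (amp == 0) return(opd_map(canvas, ps))
  R <- p / 2
  W <- (nc - 1) * ps; H <- (nr - 1) * ps
  centers <- hex_lattice(p, W, H)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    j0 <- max(1, floor((cx - R) / ps) + 1); j1 <- min(nc, ceiling((cx + R) / ps) + 1)
    i0 <- max(1, floor((cy - R) / ps) + 1); i1 <- min(nr, ceiling((cy + R) / ps) + 1)
    if (j0 > j1 || i0 > i1) next
    xs <- ((j0:j1) - 1) * ps - cx
    ys <- ((i0:i1) - 1) * ps - cy
    rho <- sqrt(outer(ys^2, xs^2, `+`))
    bump <- amp * cos(pmin(rho / R, 1) * pi / 2)^2
    canvas[i0:i1, j0:j1] <- canvas[i0:i1, j0:j1] + bump
  }
  opd_map(canvas, ps)
}

#' Hexagonal lattice centers inside a field
#'
#' Centers of a hexagonal lattice of the given pitch covering the rectangle
#' `[0, width] x [0, height]` (um), rows offset by half a pitch.
#'
#' @param pitch lattice spacing (um).
#' @param width,height field extent (um).
#' @return n x 2 matrix of `(x, y)` centers.
#' @export
hex_lattice <- function(pitch, width, height) {
  dy <- pitch * sqrt(3) / 2
  rows <- seq(0, height + dy, by = dy)
  out <- list()
  for (r in seq_along(rows)) {
    off <- if ((r - 1) %% 2 == 1) pitch / 2 else 0
    xs <- seq(off, width + pitch, by = pitch)
    out[[r]] <- cbind(xs, rows[r])
  }
  m <- do.call(rbind, out)
  m[m[, 1] <= width & m[, 2] <= height, , drop = FALSE]
}

#' Off-axis carrier specification
#'
#' @param fx,fy carrier spatial frequency in cycles/pixel; the default
#'   `(0.25, 0.25)` separates the cross-correlation term maximally from DC
#'   while staying below Nyquist.
#' @param mean_intensity mean camera intensity (arbitrary units > 0).
#' @param fringe_contrast fringe visibility in `[0, 1]`.
#' @param detector_noise_sigma additive zero-mean Gaussian detection noise,
#'   same units as intensity.
#' @return object of class `carrier_spec`.
#' @export
carrier_spec <- function(fx = 0.25, fy = 0.25, mean_intensity = 1,
                         fringe_contrast = 0.8, detector_noise_sigma = 0) {
  if (mean_intensity <= 0) stop("mean_intensity must be > 0")
  if (fringe_contrast < 0 || fringe_contrast > 1)
    stop("fringe_contrast must be in [0, 1]")
  if (detector_noise_sigma < 0) stop("detector_noise_sigma must be >= 0")
  structure(list(fx = fx, fy = fy, mean_intensity = mean_intensity,
                 fringe_contrast = fringe_contrast,
                 detector_noise_sigma = detector_noise_sigma),
            class = "carrier_spec")
}

#' Render an off-axis interferogram of an OPD map
#'
#' Forward model of single-exposure off-axis recording:
#' `I(x, y) = A * (1 + C * cos(2*pi*(fx*x + fy*y) + phi(x, y))) + n(x, y)`
#' with `phi = 2*pi*OPD/lambda`, `A` the mean intensity, `C` the fringe
#' contrast and `n` zero-mean Gaussian detector noise. Negative intensities
#' after noise are clipped at zero; the clip count is reported in the
#' `n_clipped` attribute. Reproducible under a fixed seed.
#'
#' @param opd an [opd_map] in nm (its `wavelength` attribute sets lambda).
#' @param carrier a [carrier_spec()].
#' @param seed integer seed for the detector noise (ignored when
#'   `detector_noise_sigma = 0`).
#' @return an [interferogram].
#' @export
render_interferogram <- function(opd, carrier = carrier_spec(), seed = NULL) {
  stopifnot(inherits(opd, "opd_map"), inherits(carrier, "carrier_spec"))
  nr <- nrow(opd); nc <- ncol(opd)
  lam <- wavelength(opd)
  phi <- 2 * pi * as_plain_matrix(opd) / lam
  X0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  Y0 <- matrix(0:(nr - 1), nr, nc)
  I <- carrier$mean_intensity *
    (1 + carrier$fringe_contrast *
       cos(2 * pi * (carrier$fx * X0 + carrier$fy * Y0) + phi))
  if (carrier$detector_noise_sigma > 0) {
    I <- I + with_seed(seed,
      matrix(stats::rnorm(nr * nc, 0, carrier$detector_noise_sigma), nr, nc))
  }
  n_clipped <- sum(I < 0)
  I[I < 0] <- 0
  out <- interferogram(I, pixel_size(opd), lam)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate a swimming sequence of OPD frames
#'
#' Generates `n_frames` OPD maps of one or more cells following either free
#' progressive motion (constant speed along a heading with optional angular
#' jitter) or droplet-confined motion (the head stays in contact with the
#' droplet edge and drifts tangentially along it). Ground-truth tracks hold
#' the exact head-center coordinates.
#'
#' @param spec a [phantom_spec()] (or list, one per cell).
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval in seconds (> 0).
#' @param mode `"free_progressive"` or `"droplet_confined"`.
#' @param speeds_um_s per-cell swimming speed (um/s); recycled.
#' @param centers_um n x 2 start positions (free) or droplet centers
#'   (confined); default from the spec.
#' @param headings_deg initial headings (free) or angular start positions on
#'   the droplet edge (confined), degrees.
#' @param jitter_sd_deg per-step heading jitter standard deviation, degrees.
#' @param droplet_radius_um confinement radius; default `droplet_pitch / 2`.
#' @param seed integer seed for the jitter.
#' @return `list(frames = list of opd_map, truth = list(tracks = tibble,
#'   speeds_um_s, mode))`; tracks columns: `cell_id, frame, t_s, x_um, y_um`.
#' @export
simulate_motion <- function(spec, n_frames, dt,
                            mode = c("free_progressive", "droplet_confined"),
                            speeds_um_s = 0.15, centers_um = NULL,
                            headings_deg = NULL, jitter_sd_deg = 0,
                            droplet_radius_um = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (dt <= 0) stop("dt must be > 0")
  specs <- if (inherits(spec, "phantom_spec")) list(spec) else spec
  s1 <- specs[[1]]
  if (is.null(centers_um))
    centers_um <- do.call(rbind, lapply(specs, function(s) s$center_um))
  centers_um <- matrix(centers_um, ncol = 2)
  n_cells <- nrow(centers_um)
  if (length(specs) == 1 && n_cells > 1) specs <- rep(specs, n_cells)
  speeds <- rep_len(speeds_um_s, n_cells)
  width_um <- (s1$image_shape[2] - 1) * s1$pixel_size
  if (any(speeds * dt > width_um)) stop("per-frame displacement exceeds image width")
  if (is.null(headings_deg)) headings_deg <- rep(0, n_cells)
  headings_deg <- rep_len(headings_deg, n_cells)
  if (is.null(droplet_radius_um)) droplet_radius_um <- s1$droplet_pitch / 2

  pos <- array(NA_real_, c(n_cells, 2, n_frames))
  orient <- matrix(NA_real_, n_cells, n_frames)
  jit <- with_seed(seed, matrix(stats::rnorm(n_cells * n_frames, 0,
                                             jitter_sd_deg), n_cells))
  for (k in seq_len(n_cells)) {
    if (mode == "free_progressive") {
      h <- headings_deg[k] + cumsum(c(0, jit[k, -1]))
      hr <- h * pi / 180
      steps <- cbind(cos(hr), sin(hr)) * speeds[k] * dt
      p <- apply(rbind(centers_um[k, ], steps[-n_frames, , drop = FALSE]), 2, cumsum)
      pos[k, , ] <- t(p)
      orient[k, ] <- h            # anterior points along the heading
    } else {
      re <- max(droplet_radius_um - specs[[k]]$head_major / 2, 0.1)
      om <- speeds[k] / re        # rad/s tangential drift
      tt <- (seq_len(n_frames) - 1) * dt
      ang <- headings_deg[k] * pi / 180 + om * tt +
        cumsum(c(0, jit[k, -1])) * pi / 180
      pos[k, 1, ] <- centers_um[k, 1] + re * cos(ang)
      pos[k, 2, ] <- centers_um[k, 2] + re * sin(ang)
      orient[k, ] <- ang * 180 / pi + 90   # tangential heading
    }
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sc <- generate_sperm_phantom(specs, centers_um = matrix(pos[, , f], ncol = 2),
                                 orientations_deg = orient[, f])
    frames[[f]] <- sc$opd
  }
  tracks <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
    tibble::tibble(cell_id = k, frame = seq_len(n_frames),
                   t_s = (seq_len(n_frames) - 1) * dt,
                   x_um = pos[k, 1, ], y_um = pos[k, 2, ])
  }))
  list(frames = frames,
       truth = list(tracks = tracks, speeds_um_s = speeds, mode = mode))
}

#' Generate a parameter-sweep of validation phantoms
#'
#' Draws `n` single-cell phantom specifications whose generative parameters
#' sample both the pass and fail side of every selection criterion, with a
#' margin to each decision boundary of at least the corresponding measurement
#' tolerance (so that measured and generative classifications are expected to
#' agree; within a tolerance of a boundary, disagreement would be expected
#' and recovery could not be scored). Radii ratios are kept at or above 0.36:
#' heads narrower than that are under ~12 px across at the default pixel size
#' and below the validity domain of the acrosome-cap estimator (see the
#' methods vignette). Vacuoles are placed clear of the acrosome boundary and
#' of the head margin, where depressions are not reliably countable.
#'
#' @param n number of phantoms.
#' @param seed integer seed.
#' @param image_shape per-phantom field size in pixels.
#' @return list of [phantom_spec()] objects.
#' @export
phantom_parameter_sweep <- function(n = 50, seed = 1,
                                    image_shape = c(256, 256)) {
  with_seed(seed, {
    pick <- function(ints) {
      i <- sample.int(length(ints), 1)
      stats::runif(1, ints[[i]][1], ints[[i]][2])
    }
    specs <- vector("list", n)
    for (k in seq_len(n)) {
      f <- pick(list(c(0.25, 0.35), c(0.45, 0.65), c(0.75, 0.85)))
      rr <- pick(list(c(0.36, 0.42), c(0.54, 0.66), c(0.78, 0.90)))
      mr <- pick(list(c(0.45, 0.60), c(0.95, 1.25), c(1.60, 1.75)))
      cy <- pick(list(c(0, 0), c(0.12, 0.20), c(0.47, 0.57)))
      off <- stats::runif(1, 0, 12)
      scale <- stats::runif(1, 0.55, 0.7)
      a <- 2.5; b <- 2.5 * rr
      u_cut <- a * acrosome_cut(f)
      nv <- sample(0:3, 1)
      vd <- NULL
      if (nv > 0 && b > 1.45) {
        rows <- list()
        for (tries in 1:200) {
          if (length(rows) == nv) break
          r <- stats::runif(1, sqrt(0.03 * a * b), sqrt(0.06 * a * b))
          du <- stats::runif(1, -a, a); dv <- stats::runif(1, -b, b)
          if ((du / max(a - r - 0.75, 0.01))^2 +
              (dv / max(b - r - 0.75, 0.01))^2 > 1) next
          if (abs(du - u_cut) < r + 0.65) next
          ok <- TRUE
          for (p in rows)
            if (sqrt((p[1] - du)^2 + (p[2] - dv)^2) < p[3] + r + 0.4) ok <- FALSE
          if (!ok) next
          rows[[length(rows) + 1]] <- c(du, dv, r, stats::runif(1, 60, 100))
        }
        if (length(rows) > 0) {
          m <- do.call(rbind, rows)
          vd <- data.frame(du_um = m[, 1], dv_um = m[, 2],
                           radius_um = m[, 3], depth_nm = m[, 4])
        }
      }
      specs[[k]] <- phantom_spec(image_shape = image_shape, head_major = 5,
        head_minor = 5 * rr, acrosome_fraction = f,
        acrosome_opd_scale = scale, midpiece_length_um = 5 * mr,
        midpiece_axis_offset_deg = off, vacuoles = vd,
        residual_cytoplasm_fraction = cy,
        orientation_deg = stats::runif(1, 0, 360), seed = k)
    }
    specs
  })
}

#' Simulate a population of cell tracks without rendering
#'
#' Light-weight kinematic generator for motile-fraction studies: a population
#' in which a known proportion of cells swim progressively at speeds drawn
#' from `speed_range` while the rest are immotile (sub-threshold positional
#' jitter only). No images are rendered; the output is the track table alone.
#'
#' @param n_cells number of cells.
#' @param p_motile proportion of motile cells in `[0, 1]`.
#' @param speed_range motile speed range (um/s), default the observed
#'   free-medium range `c(0.05, 0.25)`.
#' @param immotile_jitter_um positional noise sd of immotile cells (um).
#' @param n_frames,dt frames and frame interval (default 10 frames, 50 ms).
#' @param seed integer seed.
#' @return `list(tracks = tibble(cell_id, frame, t_s, x_um, y_um),
#'   motile = logical vector, speeds_um_s = numeric vector)`.
#' @export
simulate_track_population <- function(n_cells, p_motile,
                                      speed_range = c(0.05, 0.25),
                                      immotile_jitter_um = 2e-4,
                                      n_frames = 10, dt = 0.05, seed = NULL) {
  with_seed(seed, {
    motile <- stats::runif(n_cells) < p_motile
    speeds <- ifelse(motile,
                     stats::runif(n_cells, speed_range[1], speed_range[2]), 0)
    headings <- stats::runif(n_cells, 0, 2 * pi)
    tt <- (seq_len(n_frames) - 1) * dt
    tracks <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
      x <- speeds[k] * tt * cos(headings[k])
      y <- speeds[k] * tt * sin(headings[k])
      if (!motile[k]) {
        x <- x + stats::rnorm(n_frames, 0, immotile_jitter_um)
        y <- y + stats::rnorm(n_frames, 0, immotile_jitter_um)
      }
      tibble::tibble(cell_id = k, frame = seq_len(n_frames), t_s = tt,
                     x_um = x, y_um = y)
    }))
    list(tracks = tracks, motile = motile, speeds_um_s = speeds)
  })
}
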