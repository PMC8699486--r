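#' Stain-free sperm morphometrics from OPD maps
#'
#' Segmentation of sperm cells in flattened OPD maps and extraction of the
#' morphological parameters used for fertilization-suitability screening:
#' acrosome-head area ratio, head radii ratio (width/length), midpiece-head
#' length ratio, vacuole content, and residual-cytoplasm content.
#'
#' @name morphometrics
NULL

# ---- small mask utilities ---------------------------------------------------

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# centroid / principal axes of a binary mask, in 0-based pixel (x, y) coords
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("degenerate mask: fewer than 3 pixels")
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  mu <- colMeans(xy)
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= 1e-9) stop("degenerate mask: collinear pixels")
  list(centroid = mu, values = ev$values,
       e1 = ev$vectors[, 1], e2 = ev$vectors[, 2],
       area = nrow(idx), xy = xy)
}

# Otsu threshold of a numeric vector (maximal between-class variance)
otsu_threshold <- function(v, n_bins = 256) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, 1 + floor((v - r[1]) / diff(r) * n_bins)), n_bins)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w <- cumsum(h)
  m <- cumsum(h * mids)
  wt <- w[n_bins]; mt <- m[n_bins]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# two-level step fit of OPD against the head-axis coordinate t (px).
# Returns c(cut, r2): the sub-pixel cut position and the fraction of the
# binned-profile variance the step model explains, or NA when no step is
# found. A low r2 means the low-OPD class is not an anterior cap (for
# example an enclosed depression), so no acrosome cut exists.
step_cut <- function(t, v) {
  br <- seq(floor(min(t)), ceiling(max(t)) + 1, by = 1)
  bin <- findInterval(t, br)
  K <- max(bin)
  # two per-bin summaries: the upper quantile resists boundary-taper pixels
  # (needed for plateau levels on narrow heads), while the median is centered
  # within the bin (needed for an unbiased crossing in the transition)
  qbin <- function(p) vapply(seq_len(K), function(k) {
    x <- v[bin == k]
    if (length(x) >= 2) stats::quantile(x, p, names = FALSE) else NA_real_
  }, numeric(1))
  med <- qbin(0.7)
  cen <- qbin(0.5)
  # abscissa = actual mean coordinate of each bin's pixels: for cells nearly
  # aligned with the pixel lattice the pixels cluster within the bin and the
  # nominal bin center would misplace the profile by up to half a pixel
  ctr <- vapply(seq_len(K), function(k) mean(t[bin == k]), numeric(1))
  keep <- !is.na(med)
  med <- med[keep]; cen <- cen[keep]; ctr <- ctr[keep]
  K <- length(med)
  if (K < 4) return(c(cut = NA_real_, r2 = NA_real_))
  best <- NULL
  for (k in 2:(K - 2)) {
    l1 <- stats::median(med[1:k]); l2 <- stats::median(med[(k + 1):K])
    err <- sum((med[1:k] - l1)^2) + sum((med[(k + 1):K] - l2)^2)
    if (is.null(best) || err < best$err) best <- list(k = k, err = err, l1 = l1, l2 = l2)
  }
  tot <- sum((med - mean(med))^2)
  r2 <- if (tot > 0) 1 - best$err / tot else 0
  # refine: crossing of the mid level between the two bins around the split.
  # The two levels are re-read from the bins flanking the transition (the
  # widest, taper-free part of the head) rather than from whole-side medians,
  # which a short cap at the eroded tip would bias.
  k <- best$k
  lA <- med[max(1, k - 4):max(1, k - 1)]
  lB <- med[min(K, k + 2):min(K, k + 5)]
  mid <- (stats::median(lA) + stats::median(lB)) / 2
  lo <- max(1, k - 2); hi <- min(K, k + 3)
  tt <- ctr[lo:hi]; mm <- cen[lo:hi]
  cut <- ctr[k] + 0.5
  for (i in seq_len(length(mm) - 1)) {
    if ((mm[i] - mid) * (mm[i + 1] - mid) <= 0 && mm[i] != mm[i + 1]) {
      cut <- tt[i] + (mid - mm[i]) / (mm[i + 1] - mm[i]) * (tt[i + 1] - tt[i])
      break
    }
  }
  c(cut = cut, r2 = r2)
}

# ---- segmentation -----------------------------------------------------------

#' Segment sperm cells in a flattened OPD map
#'
#' Connected components above a threshold are split per cell into a head
#' (compact high-OPD blob, refined with class-adaptive boundary thresholds), a
#' midpiece (elongated appendage continuing the head axis from the neck), and
#' any residual-cytoplasm blob beside the neck. The acrosome/post-acrosome
#' OPD levels and the anterior cut position are estimated during segmentation
#' and cached on each cell record for the measurement functions.
#'
#' The default threshold follows the noise-calibrated rule: background median
#' plus five times the background robust standard deviation, with a 15 nm
#' floor for effectively noiseless maps.
#'
#' @param opd an [opd_map] (flattened; see [flatten_background()]).
#' @param min_area_um2 components smaller than this are discarded (um^2).
#' @param opd_threshold_nm detection threshold override (nm).
#' @param contrast_floor_nm minimum acrosome/post-acrosome class contrast for
#'   a determinate acrosome partition (nm).
#' @return list of `sperm_cell` records with elements `cell_id`, `head_mask`,
#'   `midpiece_mask`, `cytoplasm_mask`, `neck_point` (0-based px, `c(x, y)`),
#'   `centroid_um`, `axis` (unit vector, anterior direction), `cut_t_px`,
#'   `levels` (acrosome / post-acrosome class means, nm), `contrast_ok`,
#'   `component_mask`, `pixel_size`; empty list when no cells are found.
#' @export
segment_cells <- function(opd, min_area_um2 = 3, opd_threshold_nm = NULL,
                          contrast_floor_nm = 15) {
  x <- as_plain_matrix(opd)
  ps <- pixel_size(opd)
  if (is.null(opd_threshold_nm)) {
    bgv <- x[x <= stats::quantile(x, 0.75)]
    opd_threshold_nm <- stats::median(bgv) + max(5 * stats::mad(bgv), 15)
  }
  bw <- x > opd_threshold_nm
  lab <- EBImage::bwlabel(bw * 1)
  n <- max(lab)
  if (n == 0) return(list())
  min_px <- max(10, round(min_area_um2 / ps^2))
  cells <- list()
  for (id in seq_len(n)) {
    comp <- lab == id
    if (sum(comp) < min_px) next
    rec <- tryCatch(analyze_component(x, comp, ps, contrast_floor_nm),
                    error = function(e) NULL)
    if (!is.null(rec)) {
      rec$cell_id <- length(cells) + 1L
      cells[[length(cells) + 1]] <- rec
    }
  }
  cells
}

analyze_component <- function(x, comp, ps, contrast_floor) {
  vals <- x[comp]
  P_est <- stats::quantile(vals, 0.98, names = FALSE)
  core <- largest_component(EBImage::fillHull((comp & x >= 0.5 * P_est) * 1) > 0)
  if (sum(core) < 20) stop("head too small")
  mm <- mask_moments(core)
  # anterior = lower-OPD side of the major axis
  tproj <- (mm$xy[, 1] - mm$centroid[1]) * mm$e1[1] +
           (mm$xy[, 2] - mm$centroid[2]) * mm$e1[2]
  ov <- x[core]
  e1 <- if (mean(ov[tproj > 0]) <= mean(ov[tproj < 0])) mm$e1 else -mm$e1

  # class levels on an eroded core (boundary taper excluded); narrow heads
  # get a smaller erosion radius so the eroded set keeps both classes
  erode_core <- function(mask) {
    semi_minor <- 2 * sqrt(mask_moments(mask)$values[2])
    r_e <- max(1, min(3, floor(semi_minor / 2.5)))
    out <- EBImage::erode(mask * 1, EBImage::makeBrush(2 * r_e + 1, "disc")) > 0
    if (sum(out) < 30) mask else out
  }
  er <- erode_core(core)
  T0 <- otsu_threshold(x[er])
  lo <- x[er][x[er] < T0]; hi <- x[er][x[er] >= T0]
  # medians: plateau levels must not be dragged by vacuole pixels or taper
  contrast_ok <- length(lo) > 5 && length(hi) > 5 &&
    (stats::median(hi) - stats::median(lo)) >= contrast_floor
  mu_lo <- if (contrast_ok) stats::median(lo) else stats::median(x[er])
  mu_hi <- if (contrast_ok) stats::median(hi) else stats::median(x[er])

  # anterior direction from the OPD class geometry: vector from the head
  # centroid to the low-class (acrosome) centroid; robust for round heads
  # whose mask axis is degenerate
  e_acr <- NULL
  if (contrast_ok) {
    exy <- which(er, arr.ind = TRUE)
    exy <- cbind(exy[, 2] - 1, exy[, 1] - 1)
    lo_px <- x[er] < T0
    d <- colMeans(exy[lo_px, , drop = FALSE]) - colMeans(exy)
    if (sqrt(sum(d^2)) > 0.5) e_acr <- d / sqrt(sum(d^2))
  }
  head <- core
  cut <- NA_real_
  ax <- e1
  for (pass in 1:2) {
    hm <- mask_moments(head)
    e1 <- hm$e1
    if (!is.null(e_acr)) {
      if (sum(e1 * e_acr) < 0) e1 <- -e1
    } else {
      tp <- (hm$xy[, 1] - hm$centroid[1]) * e1[1] +
            (hm$xy[, 2] - hm$centroid[2]) * e1[2]
      hv <- x[head]
      if (mean(hv[tp > 0]) > mean(hv[tp < 0])) e1 <- -e1
    }
    # near-circular heads: project along the class direction itself
    ax <- if (!is.null(e_acr) && sqrt(hm$values[1] / hm$values[2]) < 1.2)
      e_acr else e1
    if (!contrast_ok) break
    # sub-pixel anterior cut from a two-level step fit along the axis
    src <- erode_core(head)
    sm <- mask_moments(src)
    ts <- (sm$xy[, 1] - hm$centroid[1]) * ax[1] +
          (sm$xy[, 2] - hm$centroid[2]) * ax[2]
    sc <- step_cut(ts, x[src])
    cut <- unname(sc["cut"])
    if (is.na(cut) || sc["r2"] < 0.75) {
      contrast_ok <- FALSE; cut <- NA_real_; break
    }
    if (pass == 2) break
    # refine the head boundary with class-adaptive half-level thresholds
    idx_all <- which(comp, arr.ind = TRUE)
    t_all <- (idx_all[, 2] - 1 - hm$centroid[1]) * ax[1] +
             (idx_all[, 1] - 1 - hm$centroid[2]) * ax[2]
    v_all <- x[comp]
    keep <- ifelse(t_all > cut, v_all > 0.5 * mu_lo, v_all > 0.5 * mu_hi)
    head2 <- comp & FALSE
    head2[which(comp)[keep]] <- TRUE
    head2 <- largest_component(EBImage::fillHull(head2 * 1) > 0)
    if (sum(head2) < 20) break
    head <- head2
  }
  finish_mask <- function(head) {
    hm <- mask_moments(head)
    if (hm$values[2] <= 1e-6) stop("degenerate head")
    semi_major_px <- 2 * sqrt(hm$values[1])
    neck <- hm$centroid - ax * semi_major_px        # 0-based (x, y) px
    head_excl <- EBImage::dilate(head * 1, EBImage::makeBrush(7, "disc")) > 0
    app <- comp & !head_excl & x > 0.22 * mu_hi
    idx <- which(app, arr.ind = TRUE)
    mid_mask <- cyto_mask <- comp & FALSE
    if (nrow(idx) > 0) {
      dx <- idx[, 2] - 1 - neck[1]
      dy <- idx[, 1] - 1 - neck[2]
      post <- -ax
      cosang <- (dx * post[1] + dy * post[2]) / pmax(sqrt(dx^2 + dy^2), 1e-9)
      is_mid <- cosang >= cos(50 * pi / 180)
      mid_mask[app][is_mid] <- TRUE
      cyto_mask[app][!is_mid] <- TRUE
    }
    list(hm = hm, neck = neck, head_excl = head_excl,
         mid_mask = mid_mask, cyto_mask = cyto_mask)
  }
  fin <- finish_mask(head)

  # neck correction: at the head/midpiece junction the head boundary
  # half-level sits over the midpiece plateau, not over zero background, so
  # the plain posterior threshold lets the mask bulge ~1 px into the
  # midpiece; re-threshold that corridor at the head/midpiece mid level
  if (sum(fin$mid_mask) > 5) {
    L_m <- stats::median(x[fin$mid_mask])
    thr_neck <- (mu_hi + L_m) / 2
    corridor <- EBImage::dilate(fin$mid_mask * 1,
                                EBImage::makeBrush(9, "disc")) > 0
    drop <- head & corridor & x < thr_neck
    if (any(drop)) {
      head2 <- largest_component(head & !drop)
      if (sum(head2) >= 20) {
        head <- head2
        # the centroid moved: re-estimate the cut in the new frame
        if (contrast_ok && !is.na(cut)) {
          hm2 <- mask_moments(head)
          src <- erode_core(head)
          sm <- mask_moments(src)
          ts <- (sm$xy[, 1] - hm2$centroid[1]) * ax[1] +
                (sm$xy[, 2] - hm2$centroid[2]) * ax[2]
          sc2 <- step_cut(ts, x[src])
          if (!is.na(sc2["cut"]) && sc2["r2"] >= 0.75)
            cut <- unname(sc2["cut"])
        }
        fin <- finish_mask(head)
      }
    }
  }
  hm <- fin$hm
  neck <- fin$neck
  head_excl <- fin$head_excl
  mid_mask <- fin$mid_mask
  cyto_mask <- fin$cyto_mask

  # final class levels re-estimated positionally on either side of the cut
  # (vacuole floors or an eroded-away cap must not bias the plateaus)
  if (contrast_ok && !is.na(cut)) {
    erh <- erode_core(head)
    em <- mask_moments(erh)
    te <- (em$xy[, 1] - hm$centroid[1]) * ax[1] +
          (em$xy[, 2] - hm$centroid[2]) * ax[2]
    alo <- x[erh][te > cut + 3]
    ahi <- x[erh][te < cut - 3]
    if (length(alo) >= 5) mu_lo <- stats::quantile(alo, 0.7, names = FALSE)
    if (length(ahi) >= 5) mu_hi <- stats::quantile(ahi, 0.7, names = FALSE)
  }
  structure(list(
    cell_id = NA_integer_,
    head_mask = head, head_excl_mask = head_excl,
    midpiece_mask = mid_mask, cytoplasm_mask = cyto_mask,
    component_mask = comp,
    neck_point = neck, centroid_um = hm$centroid * ps,
    axis = ax, cut_t_px = cut,
    levels = c(acrosome = mu_lo, postacrosome = mu_hi, peak = P_est),
    contrast_ok = contrast_ok, pixel_size = ps), class = "sperm_cell")
}

# ---- measurements -----------------------------------------------------------

#' Fit the moment-equivalent head ellipse
#'
#' Second-moment (moment-equivalent) ellipse of the head mask. The radii
#' ratio is head width over length (minor/major), in `(0, 1]`.
#'
#' @param cell a `sperm_cell` record from [segment_cells()].
#' @param pixel_size um/px; defaults to the cell record's value.
#' @return list with `major_um`, `minor_um` (full axis lengths),
#'   `orientation_deg`, `radii_ratio`.
#' @export
fit_head_ellipse <- function(cell, pixel_size = cell$pixel_size) {
  if (sum(cell$head_mask) < 20) stop("head area below 20 px")
  mm <- mask_moments(cell$head_mask)
  major <- 4 * sqrt(mm$values[1]) * pixel_size
  minor <- 4 * sqrt(mm$values[2]) * pixel_size
  list(major_um = major, minor_um = minor,
       orientation_deg = atan2(mm$e1[2], mm$e1[1]) * 180 / pi,
       radii_ratio = minor / major)
}

#' Partition the head into acrosomal and post-acrosomal regions
#'
#' Splits the head by the OPD bimodality within it: a two-class intensity
#' split estimates the class levels, and a step fit of OPD against the
#' head-axis coordinate locates the anterior cut, so the acrosome is the
#' contiguous anterior region by construction. When the class contrast is
#' below the noise floor the ratio is indeterminate.
#'
#' @param cell a `sperm_cell` record.
#' @param opd the [opd_map] the cell was segmented from.
#' @return list with `acrosome_mask`, `acrosome_head_ratio` (percent) and
#'   `indeterminate` flag.
#' @export
partition_acrosome <- function(cell, opd) {
  if (!isTRUE(cell$contrast_ok) || is.na(cell$cut_t_px))
    return(list(acrosome_mask = cell$head_mask & FALSE,
                acrosome_head_ratio = NA_real_, indeterminate = TRUE))
  hm <- mask_moments(cell$head_mask)
  tproj <- (hm$xy[, 1] - hm$centroid[1]) * cell$axis[1] +
           (hm$xy[, 2] - hm$centroid[2]) * cell$axis[2]
  amask <- cell$head_mask & FALSE
  amask[which(cell$head_mask)[tproj > cell$cut_t_px]] <- TRUE
  list(acrosome_mask = amask,
       acrosome_head_ratio = 100 * sum(amask) / sum(cell$head_mask),
       indeterminate = FALSE)
}

#' Measure the midpiece
#'
#' Re-thresholds the midpiece at half its median OPD level, takes its
#' principal axis, and measures its length from the neck to the farthest
#' projection (minus half the midpiece width, compensating the rounded distal
#' cap). The axis offset is the angle between the midpiece axis and the
#' continuation of the head major axis.
#'
#' @param cell a `sperm_cell` record.
#' @param opd the source [opd_map].
#' @param pixel_size um/px.
#' @param head_major_um head length used for the ratio; measured from the
#'   cell when omitted.
#' @return list with `midpiece_length_um`, `midpiece_head_ratio`,
#'   `axis_offset_deg`, `flag` (`""` or `"no_midpiece"`).
#' @export
measure_midpiece <- function(cell, opd, pixel_size = cell$pixel_size,
                             head_major_um = NULL) {
  x <- as_plain_matrix(opd)
  if (is.null(head_major_um))
    head_major_um <- fit_head_ellipse(cell, pixel_size)$major_um
  m0 <- cell$midpiece_mask
  if (sum(m0) < 5)
    return(list(midpiece_length_um = 0, midpiece_head_ratio = 0,
                axis_offset_deg = NA_real_, flag = "no_midpiece"))
  L_m <- stats::median(x[m0])
  # re-threshold at half level within the same angular sector of the component
  mm <- cell$component_mask & !cell$head_excl_mask & x >= 0.5 * L_m
  idx <- which(mm, arr.ind = TRUE)
  dx <- idx[, 2] - 1 - cell$neck_point[1]
  dy <- idx[, 1] - 1 - cell$neck_point[2]
  post <- -cell$axis
  cosang <- (dx * post[1] + dy * post[2]) / pmax(sqrt(dx^2 + dy^2), 1e-9)
  sel <- cosang >= cos(50 * pi / 180)
  if (sum(sel) < 5)
    return(list(midpiece_length_um = 0, midpiece_head_ratio = 0,
                axis_offset_deg = NA_real_, flag = "no_midpiece"))
  xy <- cbind(dx[sel], dy[sel])
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE)
  e_m <- ev$vectors[, 1]
  if (mean(xy %*% e_m) < 0) e_m <- -e_m
  proj <- as.numeric(xy %*% e_m)
  width_px <- sqrt(12 * max(ev$values[2], 0))
  len_px <- max(proj) - 0.5 * width_px
  len_um <- max(len_px, 0) * pixel_size
  off <- acos(pmin(1, abs(sum(e_m * post)))) * 180 / pi
  list(midpiece_length_um = len_um,
       midpiece_head_ratio = len_um / head_major_um,
       axis_offset_deg = off, flag = "")
}

#' Detect vacuoles in the head
#'
#' Vacuoles are closed local OPD depressions inside the head: the deficit of
#' each interior pixel below its class level (acrosomal or post-acrosomal) is
#' thresholded, candidate depressions smaller than a minimum area are
#' discarded, and each vacuole's area is measured at half its maximum depth
#' (which is insensitive to the exact depth threshold). A band around the
#' acrosome boundary is excluded because the class transition itself would
#' register as a spurious depression there.
#'
#' @param cell a `sperm_cell` record.
#' @param opd the source [opd_map].
#' @param depth_threshold_nm minimum depression depth (nm); the
#'   noise-calibrated choice is 3x the temporal noise std, with a 20 nm
#'   default floor.
#' @param min_area_fraction minimum vacuole area as a fraction of head area.
#' @param large_vacuole_fraction a single vacuole larger than this fraction
#'   of the head is "large".
#' @param cut_margin_px half-width of the excluded band around the acrosome
#'   boundary (px).
#' @return list with `vacuole_count`, `vacuole_area_fraction`, `any_large`,
#'   `areas_px`.
#' @export
detect_vacuoles <- function(cell, opd, depth_threshold_nm = 20,
                            min_area_fraction = 0.005,
                            large_vacuole_fraction = 0.20,
                            cut_margin_px = 3) {
  x <- as_plain_matrix(opd)
  head_area <- sum(cell$head_mask)
  # erode past the boundary taper so edge pixels cannot register as deficits
  interior <- EBImage::erode(cell$head_mask * 1, EBImage::makeBrush(9, "disc")) > 0
  idx <- which(interior, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(vacuole_count = 0L, vacuole_area_fraction = 0,
                any_large = FALSE, areas_px = integer(0)))
  hm <- mask_moments(cell$head_mask)
  tproj <- (idx[, 2] - 1 - hm$centroid[1]) * cell$axis[1] +
           (idx[, 1] - 1 - hm$centroid[2]) * cell$axis[2]
  lev <- cell$levels
  # without an acrosome cut the plateau reference is an upper quantile, so a
  # depression covering most of the interior cannot drag it down
  ref <- if (isTRUE(cell$contrast_ok) && !is.na(cell$cut_t_px))
    ifelse(tproj > cell$cut_t_px, lev["acrosome"], lev["postacrosome"])
  else rep(stats::quantile(x[interior], 0.85, names = FALSE), nrow(idx))
  deficit <- matrix(0, nrow(x), ncol(x))
  deficit[interior] <- pmax(ref - x[interior], 0)
  cand <- deficit > depth_threshold_nm
  if (isTRUE(cell$contrast_ok) && !is.na(cell$cut_t_px)) {
    near_cut <- abs(tproj - cell$cut_t_px) <= cut_margin_px
    cand[interior][near_cut] <- FALSE
  }
  lab <- EBImage::bwlabel(cand * 1)
  nlab <- max(lab)
  if (nlab == 0)
    return(list(vacuole_count = 0L, vacuole_area_fraction = 0,
                any_large = FALSE, areas_px = integer(0)))
  min_px <- max(2, min_area_fraction * head_area)
  areas <- integer(0)
  for (id in seq_len(nlab)) {
    blob <- lab == id
    if (sum(blob) < min_px) next
    d_i <- max(deficit[blob])
    half <- deficit >= d_i / 2
    hl <- EBImage::bwlabel(half * 1)
    peak <- which(blob & deficit == d_i)[1]
    areas <- c(areas, sum(hl == hl[peak]))
  }
  list(vacuole_count = length(areas),
       vacuole_area_fraction = sum(areas) / head_area,
       any_large = any(areas > large_vacuole_fraction * head_area),
       areas_px = areas)
}

#' Measure residual cytoplasm at the neck
#'
#' Area of the extra-head OPD blob adjacent to the neck (outside the midpiece
#' sector), re-thresholded at half its median level, as a fraction of head
#' area.
#'
#' @param cell a `sperm_cell` record.
#' @param opd the source [opd_map].
#' @return residual cytoplasm area as a fraction of head area.
#' @export
detect_residual_cytoplasm <- function(cell, opd) {
  x <- as_plain_matrix(opd)
  c0 <- cell$cytoplasm_mask
  if (sum(c0) < 5) return(0)
  L_c <- stats::median(x[c0])
  mm <- cell$component_mask & !cell$head_excl_mask & x >= 0.5 * L_c
  idx <- which(mm, arr.ind = TRUE)
  dx <- idx[, 2] - 1 - cell$neck_point[1]
  dy <- idx[, 1] - 1 - cell$neck_point[2]
  post <- -cell$axis
  cosang <- (dx * post[1] + dy * post[2]) / pmax(sqrt(dx^2 + dy^2), 1e-9)
  sum(cosang < cos(50 * pi / 180)) / sum(cell$head_mask)
}

#' Measure all morphological parameters of one cell
#'
#' Composes the head-ellipse fit, acrosome partition, midpiece measurement,
#' vacuole detection and residual-cytoplasm measurement into one record with
#' per-field flags.
#'
#' @param cell a `sperm_cell` record.
#' @param opd the source [opd_map].
#' @param pixel_size um/px.
#' @param ... passed to [detect_vacuoles()].
#' @return one-row [tibble::tibble] with columns `cell_id`, `x_um`, `y_um`,
#'   `acrosome_head_ratio_pct`, `radii_ratio`, `head_major_um`,
#'   `head_minor_um`, `midpiece_length_um`, `midpiece_head_ratio`,
#'   `axis_offset_deg`, `vacuole_count`, `vacuole_area_fraction`,
#'   `any_large_vacuole`, `residual_cytoplasm_fraction`, `flags`.
#' @export
measure_cell <- function(cell, opd, pixel_size = cell$pixel_size, ...) {
  if (sum(cell$head_mask) == 0) stop("blank cell mask")
  ell <- fit_head_ellipse(cell, pixel_size)
  acr <- partition_acrosome(cell, opd)
  mid <- measure_midpiece(cell, opd, pixel_size, head_major_um = ell$major_um)
  vac <- detect_vacuoles(cell, opd, ...)
  cyt <- detect_residual_cytoplasm(cell, opd)
  flags <- c(if (acr$indeterminate) "acrosome_indeterminate",
             if (mid$flag != "") mid$flag)
  tibble::tibble(
    cell_id = cell$cell_id,
    x_um = cell$centroid_um[1], y_um = cell$centroid_um[2],
    acrosome_head_ratio_pct = acr$acrosome_head_ratio,
    radii_ratio = ell$radii_ratio,
    head_major_um = ell$major_um, head_minor_um = ell$minor_um,
    midpiece_length_um = mid$midpiece_length_um,
    midpiece_head_ratio = mid$midpiece_head_ratio,
    axis_offset_deg = mid$axis_offset_deg,
    vacuole_count = vac$vacuole_count,
    vacuole_area_fraction = vac$vacuole_area_fraction,
    any_large_vacuole = vac$any_large,
    residual_cytoplasm_fraction = cyt,
    flags = paste(flags, collapse = ";"))
}

#' Segment and measure every cell in an OPD map
#'
#' @param opd an [opd_map].
#' @param ... passed to [segment_cells()].
#' @return tibble with one row per detected cell (see [measure_cell()]);
#'   zero rows when the map is blank.
#' @export
measure_cells <- function(opd, ...) {
  cells <- segment_cells(opd, ...)
  if (length(cells) == 0) {
    return(measure_cell_prototype())
  }
  do.call(rbind, lapply(cells, measure_cell, opd = opd))
}

measure_cell_prototype <- function() {
  tibble::tibble(
    cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
    acrosome_head_ratio_pct = numeric(0), radii_ratio = numeric(0),
    head_major_um = numeric(0), head_minor_um = numeric(0),
    midpiece_length_um = numeric(0), midpiece_head_ratio = numeric(0),
    axis_offset_deg = numeric(0), vacuole_count = integer(0),
    vacuole_area_fraction = numeric(0), any_large_vacuole = logical(0),
    residual_cytoplasm_fraction = numeric(0), flags = character(0))
}
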