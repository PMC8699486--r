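# shared fixtures: all synthetic, built in code at test time

# a small default cell phantom on a 256^2 field (fast)
small_spec <- function(...) {
  phantom_spec(image_shape = c(256, 256), ...)
}

# brute-force rasterization oracle: pixel-center masks of the generative
# head / vacuole geometry (cell frame, orientation 0), independent of the
# package's rasterizer
raster_oracle <- function(spec) {
  ps <- spec$pixel_size
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  cx <- spec$center_um[1]; cy <- spec$center_um[2]
  a <- spec$head_major / 2; b <- spec$head_minor / 2
  X <- matrix(((1:nc) - 1) * ps - cx, nr, nc, byrow = TRUE)
  Y <- matrix(((1:nr) - 1) * ps - cy, nr, nc)
  head <- (X / a)^2 + (Y / b)^2 <= 1
  vac <- matrix(FALSE, nr, nc)
  v <- spec$vacuoles
  if (nrow(v)) for (k in seq_len(nrow(v)))
    vac <- vac | (sqrt((X - v$du_um[k])^2 + (Y - v$dv_um[k])^2) <= v$radius_um[k])
  list(head = head, vacuole = vac & head)
}

rmse <- function(a, b, margin = 0) {
  a <- unclass(a); b <- unclass(b)
  if (margin > 0) {
    ii <- (margin + 1):(nrow(a) - margin)
    jj <- (margin + 1):(ncol(a) - margin)
    a <- a[ii, jj]; b <- b[ii, jj]
  }
  sqrt(mean((a - b)^2))
}

# run expr under a fixed seed without disturbing the session RNG
with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# reference wrap to (-pi, pi], independent of the package internals
wrap_to_pi_test <- function(x) x - 2 * pi * floor(x / (2 * pi) + 0.5)

# brute-force optimal frame-to-frame assignment by permutation enumeration
brute_force_assignment <- function(prev, curr) {
  n <- nrow(prev)
  stopifnot(nrow(curr) == n, n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(sqrt(rowSums((prev - curr[p, , drop = FALSE])^2)))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}
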