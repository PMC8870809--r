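# Small in-code fixtures shared across the suite.

# PET volume from an array of SUVs (4 mm grid unless stated).
make_pet <- function(vals, spacing = c(4, 4, 4)) {
  volume_grid(vals, spacing, modality = "PET_SUV")
}

# PET volume whose first voxels along x carry `suvs`, rest background.
line_pet <- function(suvs, background = 0, dim = c(length(suvs), 1, 1)) {
  a <- array(background, dim)
  a[seq_along(suvs)] <- suvs
  make_pet(a)
}

full_roi <- function(pet) array(TRUE, dim(pet$values))

# One flat 10 mm-radius sphere, configurable grid spacing.
sphere_phantom_spec <- function(spacing_mm, peak_suv = 8, noise_sd = 0,
                                seed = 1, extent_mm = c(96, 96, 96)) {
  shape <- round(extent_mm / spacing_mm) + 1
  phantom_spec(shape, rep(spacing_mm, 3),
               lesions = list(lesion_spec(extent_mm / 2, 10, peak_suv, "flat")),
               background_suv = 1, noise_sd = noise_sd, seed = seed)
}

# Brute-force Otsu oracle: scan every candidate bin-edge threshold and
# maximize between-class variance computed directly from the raw values.
otsu_oracle <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cands <- edges[2:n_bins]
  best_t <- NA_real_
  best_v <- -Inf
  # bin values as the histogram does, then score every split on bin mids
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  binned <- mids[bin]
  for (t in cands) {
    lo <- binned[binned <= t]; hi <- binned[binned > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}
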