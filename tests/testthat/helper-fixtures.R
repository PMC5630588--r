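# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# channel_binary from a plain matrix of thresholded intensities
cb <- function(m) channel_binary(as.matrix(m))

# Brute-force Manders oracle: explicit double loop over pixels, straight from
# the definition. Kept deliberately independent of the package's vectorized
# implementation.
manders_oracle <- function(G, R, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(G), ncol(G))
  sg <- 0; sr <- 0; sgc <- 0; src <- 0
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    if (!mask[i, j]) next
    g <- G[i, j]; r <- R[i, j]
    sg <- sg + g; sr <- sr + r
    if (r > 0) sgc <- sgc + g
    if (g > 0) src <- src + r
  }
  c(M1 = if (sg > 0) sgc / sg else NA_real_,
    M2 = if (sr > 0) src / sr else NA_real_)
}

# Exhaustive-search Otsu oracle: tries every bin-edge threshold and maximizes
# between-class variance computed naively on the raw values.
otsu_oracle <- function(v, nbins = 256) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  best <- -Inf; best_t <- NA
  for (t in breaks[2:nbins]) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; best_t <- t }
  }
  best_t
}

# A small noiseless field with well-separated foci; everything downstream is
# exactly recoverable from it.
tiny_field <- function(seed = 1, n_nuclei = 2, colocal_fraction = 1,
                       foci = 3, noise_sd = 0, psf = 0) {
  simulate_field(field_spec(
    image_height_px = 140, image_width_px = 140, n_nuclei = n_nuclei,
    nucleus_radius_px = 22, foci_per_nucleus_green = foci,
    foci_per_nucleus_red = foci, colocal_fraction = colocal_fraction,
    focus_radius_px = 3, psf_sigma_px = psf, background_level = 50,
    focus_amplitude = 1000, noise_sd = noise_sd, seed = seed))
}

# Match segmented nuclei back to ground-truth nuclei by nearest centroid;
# returns truth-table row indices aligned with `nuclei`.
match_truth <- function(nuclei, truth_nuclei) {
  vapply(nuclei, function(nuc) {
    which.min((truth_nuclei$center_x_px - nuc$centroid["x"])^2 +
              (truth_nuclei$center_y_px - nuc$centroid["y"])^2)
  }, integer(1))
}
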