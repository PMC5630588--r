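#' Specify a synthetic nuclear-foci field
#'
#' Collects and validates the parameters of the synthetic two-channel
#' focus-field generator used by [simulate_field()]. The generated scene
#' emulates interphase cells spread on a slide: disjoint disk-shaped nuclei
#' (blue channel), with punctate foci in a green channel (telomere marker,
#' e.g. TRF1) and a red channel (DNA-damage marker, e.g. 53BP1). A controlled
#' fraction of the green foci are placed exactly coincident with red foci,
#' providing unambiguous co-localization ground truth.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param n_nuclei number of nuclei to place (pairwise center distance is
#'   forced to exceed twice the nucleus radius, so nuclei never touch).
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param foci_per_nucleus_green,foci_per_nucleus_red foci per nucleus in
#'   each channel.
#' @param colocal_fraction fraction in `[0, 1]` of green foci rendered at the
#'   exact center of a red focus; `round(colocal_fraction *
#'   foci_per_nucleus_green)` pairs per nucleus are the true TIFs.
#' @param focus_radius_px radius of the rendered focus disk before blurring.
#' @param psf_sigma_px standard deviation of the isotropic Gaussian blur
#'   emulating the microscope point-spread function (kernel truncated at
#'   3 sigma); 0 disables blurring.
#' @param background_level,focus_amplitude background intensity and the
#'   additive amplitude of a focus (and of the nuclear stain), in arbitrary
#'   intensity units.
#' @param noise_sd standard deviation of additive Gaussian noise; negative
#'   intensities are clipped to zero.
#' @param min_focus_sep_px minimum center-to-center distance enforced between
#'   foci that are not a co-localized pair (within and across channels).
#'   Defaults to `2 * (focus_radius_px + 3 * psf_sigma_px) + 2`, so rendered
#'   footprints of distinct foci cannot touch. Set a small value to place
#'   foci (near-)independently.
#' @param focus_margin_px margin between a focus center and the nucleus
#'   boundary. Defaults to `focus_radius_px + 3 * psf_sigma_px + 1`, which
#'   keeps each focus's rendered footprint entirely inside its nucleus
#'   (exact count recovery). Set 0 to draw focus centers uniformly over the
#'   whole nucleus disk — the appropriate regime for calibration studies
#'   under spatial randomness, at the cost of a little blur energy spilling
#'   past the nuclear boundary.
#' @param seed integer seed; identical specs produce bit-identical fields.
#' @return an object of class `field_spec`.
#' @seealso [simulate_field()]
#' @export
field_spec <- function(image_height_px = 256, image_width_px = 256,
                       n_nuclei = 4, nucleus_radius_px = 40,
                       foci_per_nucleus_green = 4, foci_per_nucleus_red = 4,
                       colocal_fraction = 0.5,
                       focus_radius_px = 3, psf_sigma_px = 1,
                       background_level = 200, focus_amplitude = 1000,
                       noise_sd = 50, min_focus_sep_px = NULL,
                       focus_margin_px = NULL, seed = 1L) {
  stopifnot_scalar(image_height_px, "image_height_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar(image_width_px, "image_width_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar(n_nuclei, "n_nuclei", integer = TRUE)
  if (n_nuclei < 0) stop("'n_nuclei' must be non-negative")
  stopifnot_scalar(nucleus_radius_px, "nucleus_radius_px", positive = TRUE)
  stopifnot_scalar(foci_per_nucleus_green, "foci_per_nucleus_green", integer = TRUE)
  stopifnot_scalar(foci_per_nucleus_red, "foci_per_nucleus_red", integer = TRUE)
  if (foci_per_nucleus_green < 0 || foci_per_nucleus_red < 0)
    stop("foci counts must be non-negative")
  stopifnot_scalar(colocal_fraction, "colocal_fraction")
  if (colocal_fraction < 0 || colocal_fraction > 1)
    stop("'colocal_fraction' must lie in [0, 1]")
  stopifnot_scalar(focus_radius_px, "focus_radius_px", positive = TRUE)
  stopifnot_scalar(psf_sigma_px, "psf_sigma_px")
  if (psf_sigma_px < 0) stop("'psf_sigma_px' must be non-negative")
  stopifnot_scalar(background_level, "background_level")
  stopifnot_scalar(focus_amplitude, "focus_amplitude")
  if (background_level < 0 || focus_amplitude < 0)
    stop("intensity parameters must be non-negative")
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(min_focus_sep_px))
    min_focus_sep_px <- 2 * (focus_radius_px + 3 * psf_sigma_px) + 2
  stopifnot_scalar(min_focus_sep_px, "min_focus_sep_px", positive = TRUE)
  if (is.null(focus_margin_px))
    focus_margin_px <- focus_radius_px + 3 * psf_sigma_px + 1
  stopifnot_scalar(focus_margin_px, "focus_margin_px")
  if (focus_margin_px < 0) stop("'focus_margin_px' must be non-negative")
  stopifnot_scalar(seed, "seed", integer = TRUE)
  n_coloc <- round(colocal_fraction * foci_per_nucleus_green)
  if (n_coloc > foci_per_nucleus_red)
    stop("round(colocal_fraction * foci_per_nucleus_green) exceeds foci_per_nucleus_red; ",
         "cannot pair every co-localized green focus with a distinct red focus")
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_px = nucleus_radius_px,
    foci_per_nucleus_green = as.integer(foci_per_nucleus_green),
    foci_per_nucleus_red = as.integer(foci_per_nucleus_red),
    colocal_fraction = colocal_fraction,
    focus_radius_px = focus_radius_px,
    psf_sigma_px = psf_sigma_px,
    background_level = background_level,
    focus_amplitude = focus_amplitude,
    noise_sd = noise_sd,
    min_focus_sep_px = min_focus_sep_px,
    focus_margin_px = focus_margin_px,
    seed = as.integer(seed)
  ), class = "field_spec")
}

# Rejection-sample `n` points in a disk of radius `r_inner` around (cy, cx),
# each at distance >= min_sep from every point in `existing` (2-col y,x).
place_points <- function(n, cy, cx, r_inner, min_sep, existing = NULL,
                         max_attempts = 10000L) {
  pts <- matrix(numeric(0), 0, 2)
  all_pts <- if (is.null(existing)) pts else existing
  attempts <- 0L
  while (nrow(pts) < n) {
    if (attempts >= max_attempts)
      stop("focus placement failed: could not fit ", n,
           " foci with min separation ", min_sep,
           " inside a disk of radius ", r_inner,
           "; reduce foci count or min_focus_sep_px", call. = FALSE)
    attempts <- attempts + 1L
    th <- runif(1, 0, 2 * pi); rr <- r_inner * sqrt(runif(1))
    p <- c(cy + rr * sin(th), cx + rr * cos(th))
    if (nrow(all_pts) == 0 ||
        min(sqrt((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
      all_pts <- rbind(all_pts, p)
    }
  }
  pts
}

# Add disks of given radius and amplitude at centers (2-col y,x) to `img`.
render_disks <- function(img, centers, radius, amplitude) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    r0 <- max(1L, floor(cy - radius)); r1 <- min(h, ceiling(cy + radius))
    c0 <- max(1L, floor(cx - radius)); c1 <- min(w, ceiling(cx + radius))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
    img[rows, cols] <- img[rows, cols] + amplitude * (d2 <= radius^2)
  }
  img
}

gaussian_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  x <- (-half):half
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Simulate a two-channel nuclear-foci field with known ground truth
#'
#' Renders the scene described by a [field_spec()]: nuclei as filled disks in
#' the blue channel, and Gaussian-blurred punctate foci in the green and red
#' channels, with a known fraction of green foci exactly coincident with red
#' foci (the true TIFs). Additive Gaussian noise is applied to all channels
#' and intensities are clipped at zero.
#'
#' Nucleus centers are rejection-sampled so that pairwise center distances
#' exceed twice the nucleus radius and every disk lies fully inside the
#' frame. Focus centers are sampled inside a concentric disk shrunk by the
#' rendered focus footprint, so all focus signal stays within its nucleus,
#' and non-paired foci respect `min_focus_sep_px`.
#'
#' @param spec a [field_spec()].
#' @return an object of class `telo_field`: a list with intensity matrices
#'   `green`, `red`, `blue` (rows = y, columns = x), the `spec`, and `truth`,
#'   itself a list with `foci` (data frame: `nucleus_id`, `channel`, `x_px`,
#'   `y_px`, `colocal_pair_id`) and `nuclei` (data frame: `nucleus_id`,
#'   `center_x_px`, `center_y_px`, `n_green`, `n_red`, `n_tif`).
#' @export
#' @examples
#' f <- simulate_field(field_spec(n_nuclei = 2, seed = 7))
#' f$truth$nuclei
simulate_field <- function(spec) {
  if (!inherits(spec, "field_spec")) stop("'spec' must be a field_spec")
  with_seed(spec$seed, simulate_field_impl(spec))
}

simulate_field_impl <- function(spec) {
  h <- spec$image_height_px; w <- spec$image_width_px
  r <- spec$nucleus_radius_px
  if (spec$n_nuclei > 0 && (h < 2 * r + 2 || w < 2 * r + 2))
    stop("nucleus placement failed: image too small for nucleus radius ", r)

  # nuclei: centers pairwise > 2r apart, disks fully inside the frame
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < spec$n_nuclei) {
    if (attempts >= 10000L)
      stop("nucleus placement failed: could not place ", spec$n_nuclei,
           " non-overlapping nuclei of radius ", r, " in a ",
           h, "x", w, " frame", call. = FALSE)
    attempts <- attempts + 1L
    p <- c(runif(1, r + 1, h - r), runif(1, r + 1, w - r))
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) > 2 * r)
      centers <- rbind(centers, p)
  }

  # foci: co-localized green foci share red centers exactly
  r_inner <- r - spec$focus_margin_px
  ng <- spec$foci_per_nucleus_green; nr <- spec$foci_per_nucleus_red
  if ((ng > 0 || nr > 0) && r_inner <= 0)
    stop("focus placement failed: focus footprint does not fit inside the nucleus")
  n_coloc <- round(spec$colocal_fraction * ng)

  foci <- list(); pair_id <- 0L
  nuc_rows <- list()
  for (i in seq_len(spec$n_nuclei)) {
    red <- if (nr > 0)
      place_points(nr, centers[i, 1], centers[i, 2], r_inner, spec$min_focus_sep_px)
    else matrix(numeric(0), 0, 2)
    n_free <- ng - n_coloc
    green_free <- if (n_free > 0)
      place_points(n_free, centers[i, 1], centers[i, 2], r_inner,
                   spec$min_focus_sep_px, existing = red)
    else matrix(numeric(0), 0, 2)
    green <- rbind(red[seq_len(n_coloc), , drop = FALSE], green_free)
    pair_ids_red <- rep(NA_integer_, nr)
    pair_ids_green <- rep(NA_integer_, ng)
    if (n_coloc > 0) {
      ids <- pair_id + seq_len(n_coloc); pair_id <- pair_id + n_coloc
      pair_ids_red[seq_len(n_coloc)] <- ids
      pair_ids_green[seq_len(n_coloc)] <- ids
    }
    foci[[length(foci) + 1L]] <- data.frame(
      nucleus_id = rep(i, ng + nr),
      channel = rep(c("green", "red"), c(ng, nr)),
      x_px = c(green[, 2], red[, 2]),
      y_px = c(green[, 1], red[, 1]),
      colocal_pair_id = c(pair_ids_green, pair_ids_red)
    )
    nuc_rows[[i]] <- data.frame(
      nucleus_id = i, center_x_px = centers[i, 2], center_y_px = centers[i, 1],
      n_green = ng, n_red = nr, n_tif = n_coloc
    )
  }
  foci_df <- if (length(foci)) do.call(rbind, c(foci, make.row.names = FALSE)) else
    data.frame(nucleus_id = integer(), channel = character(),
               x_px = numeric(), y_px = numeric(), colocal_pair_id = integer())
  nuclei_df <- if (length(nuc_rows)) do.call(rbind, c(nuc_rows, make.row.names = FALSE)) else
    data.frame(nucleus_id = integer(), center_x_px = numeric(),
               center_y_px = numeric(), n_green = integer(),
               n_red = integer(), n_tif = integer())

  # render
  blank <- matrix(0, h, w)
  blue <- render_disks(blank, centers, r, spec$focus_amplitude)
  gmap <- blank; rmap <- blank
  gc_centers <- as.matrix(foci_df[foci_df$channel == "green", c("y_px", "x_px")])
  rc_centers <- as.matrix(foci_df[foci_df$channel == "red", c("y_px", "x_px")])
  gmap <- render_disks(gmap, gc_centers, spec$focus_radius_px, spec$focus_amplitude)
  rmap <- render_disks(rmap, rc_centers, spec$focus_radius_px, spec$focus_amplitude)
  if (spec$psf_sigma_px > 0) {
    k <- gaussian_kernel(spec$psf_sigma_px)
    gmap <- matrix(EBImage::filter2(gmap, k, boundary = 0), h, w)
    rmap <- matrix(EBImage::filter2(rmap, k, boundary = 0), h, w)
  }
  addnoise <- function(x) {
    x <- x + spec$background_level
    if (spec$noise_sd > 0) x <- x + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    pmax(x, 0)
  }
  structure(list(
    green = addnoise(gmap), red = addnoise(rmap), blue = addnoise(blue),
    spec = spec,
    truth = list(foci = foci_df, nuclei = nuclei_df)
  ), class = "telo_field")
}

#' @export
print.telo_field <- function(x, ...) {
  cat(sprintf("Synthetic focus field: %dx%d px, %d nuclei\n",
              nrow(x$green), ncol(x$green), nrow(x$truth$nuclei)))
  cat(sprintf("  foci per nucleus: %d green / %d red, true TIFs per nucleus: %s\n",
              x$spec$foci_per_nucleus_green, x$spec$foci_per_nucleus_red,
              paste(unique(x$truth$nuclei$n_tif), collapse = ", ")))
  cat(sprintf("  seed %d, noise sd %.3g, PSF sigma %.3g px\n",
              x$spec$seed, x$spec$noise_sd, x$spec$psf_sigma_px))
  invisible(x)
}

#' Simulate a limiting-dilution dose-response table
#'
#' Samples transplantation outcomes under the single-hit Poisson model: a
#' recipient of `dose` cells fails to respond (e.g. shows no long-term
#' engraftment) with probability `exp(-f * dose)`, where `f` is the true
#' frequency of active cells. Responders are drawn binomially per dose.
#'
#' @param true_frequency active-cell frequency `f` in `(0, 1]` (active cells
#'   per cell transplanted).
#' @param doses vector of positive integer cell doses per recipient.
#' @param n_per_dose number of recipients per dose (single value or one per
#'   dose).
#' @param seed integer seed; identical arguments reproduce the table.
#' @param group_label label written to the `group` column.
#' @return data frame with columns `group`, `dose`, `n_tested`,
#'   `n_responding`.
#' @seealso [lda_fit()]
#' @export
#' @examples
#' simulate_lda_table(0.01, doses = c(20, 50), n_per_dose = 24, seed = 3)
simulate_lda_table <- function(true_frequency, doses, n_per_dose, seed = 1L,
                               group_label = "group") {
  stopifnot_scalar(true_frequency, "true_frequency", positive = TRUE)
  if (true_frequency > 1) stop("'true_frequency' must lie in (0, 1]")
  if (!is.numeric(doses) || !length(doses) || any(doses <= 0) ||
      any(doses != round(doses)))
    stop("'doses' must be positive integers")
  if (any(n_per_dose <= 0) || any(n_per_dose != round(n_per_dose)))
    stop("'n_per_dose' must be positive integers")
  n_tested <- rep_len(as.integer(n_per_dose), length(doses))
  stopifnot_scalar(seed, "seed", integer = TRUE)
  p_resp <- 1 - exp(-true_frequency * doses)
  n_resp <- with_seed(seed, rbinom(length(doses), n_tested, p_resp))
  data.frame(group = group_label, dose = as.integer(doses),
             n_tested = n_tested, n_responding = n_resp)
}
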