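#' Construct a thresholded-channel object
#'
#' Low-level constructor for the container produced by [otsu_threshold()]:
#' a binary foreground map together with the retained (above-threshold)
#' intensities. Useful for feeding pre-thresholded data into
#' [manders_coefficients()], [coloc_test()] or the focus-counting functions.
#'
#' @param values numeric matrix of thresholded intensities: the original
#'   intensity where a pixel is foreground and 0 elsewhere.
#' @param threshold the threshold that produced `values`.
#' @param channel_name label, e.g. `"green"` or `"red"`.
#' @return object of class `channel_binary` with elements `binary` (logical
#'   matrix, `values > 0`), `values`, `threshold`, `channel_name`.
#' @export
channel_binary <- function(values, threshold = 0, channel_name = "channel") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (any(values < 0)) stop("thresholded intensities must be non-negative")
  structure(list(binary = values > 0, values = values,
                 threshold = threshold, channel_name = channel_name),
            class = "channel_binary")
}

#' @export
print.channel_binary <- function(x, ...) {
  cat(sprintf("Thresholded channel '%s': %dx%d px, %d foreground px, threshold %.6g\n",
              x$channel_name, nrow(x$values), ncol(x$values),
              sum(x$binary), x$threshold))
  invisible(x)
}

#' Otsu threshold a channel within a mask
#'
#' Computes the threshold that maximizes between-class intensity variance
#' over a 256-bin histogram of the intensities inside `mask` (bins uniform
#' over the observed min-max range), and returns the channel binarized at
#' that threshold. Foreground is defined strictly: pixels inside the mask
#' with intensity greater than the threshold. Pixels outside the mask are
#' always background.
#'
#' @param channel numeric intensity matrix.
#' @param mask logical matrix of the same dimensions restricting the
#'   histogram and the foreground, or `NULL` for the whole image.
#' @param nbins number of histogram bins.
#' @param channel_name label carried into the result.
#' @return a [channel_binary()] object.
#' @export
#' @examples
#' x <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' cb <- otsu_threshold(x)
#' sum(cb$binary)  # exactly the 50 bright pixels
otsu_threshold <- function(channel, mask = NULL, nbins = 256L,
                           channel_name = "channel") {
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("'channel' must be a numeric matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel), ncol(channel))
  if (!identical(dim(mask), dim(channel)))
    stop("'mask' dimensions must match 'channel'")
  mask <- mask & TRUE
  v <- channel[mask]
  if (!length(v)) stop("mask is empty")
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate region: constant intensities in '", channel_name,
         "' within the mask; no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  n <- length(v)
  w0 <- cumsum(counts) / n          # class-0 weight after bin k
  mu <- cumsum(counts * mids) / n   # unnormalized class-0 mean
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  sigma_b2 <- rep(-Inf, nbins)
  sigma_b2[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b2)          # first maximum: deterministic tie-break
  thr <- breaks[k + 1]
  binary <- mask & (channel > thr)
  values <- ifelse(binary, channel, 0)
  structure(list(binary = binary, values = values, threshold = thr,
                 channel_name = channel_name, nbins = nbins),
            class = "channel_binary")
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Otsu-binarizes the nuclear channel over the whole image, fills holes,
#' labels connected components with 8-connectivity and drops components
#' smaller than `min_nucleus_area`. Analysis downstream (thresholding,
#' focus counting, co-localization) is restricted to these masks.
#'
#' @param blue numeric intensity matrix of the nuclear stain (TOTO3/DAPI).
#' @param min_nucleus_area minimum component area in pixels.
#' @return list of `nucleus_mask` objects, each with `nucleus_id`, `mask`
#'   (logical matrix), `area_px` and `centroid` (`c(x, y)` in pixels),
#'   ordered by raster position of the centroid. A constant channel yields
#'   an empty list with a warning. Touching nuclei merge into one component
#'   (no watershed splitting is attempted).
#' @export
segment_nuclei <- function(blue, min_nucleus_area = 50L) {
  stopifnot_scalar(min_nucleus_area, "min_nucleus_area", positive = TRUE, integer = TRUE)
  cb <- tryCatch(otsu_threshold(blue, channel_name = "nuclear"),
                 error = function(e) NULL)
  if (is.null(cb)) {
    warning("nuclear channel is constant; no nuclei segmented")
    return(list())
  }
  filled <- EBImage::fillHull(matrix(as.numeric(cb$binary), nrow(blue), ncol(blue)))
  lab <- label_components(matrix(as.numeric(filled), nrow(blue), ncol(blue)))
  nl <- max(lab)
  if (nl == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nl)
  keep <- which(areas >= min_nucleus_area)
  if (!length(keep)) return(list())
  rows <- row(lab); cols <- col(lab)
  out <- lapply(keep, function(l) {
    m <- lab == l
    list(mask = m, area_px = areas[l],
         centroid = c(x = mean(cols[m]), y = mean(rows[m])))
  })
  # raster order of centroid: top-to-bottom, then left-to-right
  cy <- vapply(out, function(o) o$centroid["y"], numeric(1))
  cx <- vapply(out, function(o) o$centroid["x"], numeric(1))
  out <- out[order(cy, cx)]
  for (i in seq_along(out)) {
    out[[i]] <- structure(c(list(nucleus_id = i), out[[i]]),
                          class = "nucleus_mask")
  }
  out
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("Nucleus %d: area %d px, centroid (%.1f, %.1f)\n",
              x$nucleus_id, x$area_px, x$centroid["x"], x$centroid["y"]))
  invisible(x)
}

# Union of nucleus masks as one logical matrix.
nuclei_union <- function(nuclei) {
  if (!length(nuclei)) stop("no nuclei")
  Reduce(`|`, lapply(nuclei, `[[`, "mask"))
}

#' Per-nucleus relative focus area
#'
#' For each nucleus, the foreground area of a thresholded channel inside the
#' nucleus divided by the nucleus area. Optionally also expressed relative
#' to a reference group mean, reproducing "relative area" measurements
#' normalized so that a control group averages 1.0.
#'
#' @param cb a [channel_binary()].
#' @param nuclei list of nucleus masks from [segment_nuclei()].
#' @param reference_mean optional positive reference value; when given, the
#'   column `relative_to_reference` is `relative_area / reference_mean`.
#' @return data frame with one row per nucleus: `nucleus_id`,
#'   `focus_area_px`, `nucleus_area_px`, `relative_area`, and
#'   `relative_to_reference` (NA when no reference is supplied).
#' @export
relative_focus_area <- function(cb, nuclei, reference_mean = NULL) {
  if (!inherits(cb, "channel_binary")) stop("'cb' must be a channel_binary")
  if (!length(nuclei)) stop("at least one nucleus is required")
  if (!is.null(reference_mean))
    stopifnot_scalar(reference_mean, "reference_mean", positive = TRUE)
  rows <- lapply(nuclei, function(nuc) {
    fa <- sum(cb$binary & nuc$mask)
    data.frame(nucleus_id = nuc$nucleus_id, focus_area_px = fa,
               nucleus_area_px = nuc$area_px,
               relative_area = fa / nuc$area_px)
  })
  out <- do.call(rbind, rows)
  out$relative_to_reference <-
    if (is.null(reference_mean)) NA_real_ else out$relative_area / reference_mean
  out
}
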