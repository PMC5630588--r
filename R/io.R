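#' Write a field to a multi-page TIFF
#'
#' Writes the three channels as one 16-bit page each (order green, red,
#' blue). Intensities are non-negative reals; they are scaled into `[0, 1]`
#' by a single common factor before quantization, and the factor plus the
#' channel order are recorded in a JSON sidecar (`<path>.json`) so that
#' [read_field_tiff()] restores the original scale (up to 16-bit
#' quantization).
#'
#' @param field a `telo_field` (or any list with numeric matrices `green`,
#'   `red`, `blue` of equal dimensions).
#' @param path output file path.
#' @return the scale factor, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  chans <- list(green = field$green, red = field$red, blue = field$blue)
  if (any(!vapply(chans, is.matrix, logical(1))))
    stop("field must carry matrices green, red, blue")
  mx <- max(vapply(chans, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(chans, function(m) m / mx), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(channels = c("green", "red", "blue"), scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(mx)
}

#' Read a field from a multi-page TIFF
#'
#' Reads a three-page TIFF written by [write_field_tiff()] (or any
#' three-page TIFF, assumed green/red/blue in page order when no metadata
#' is present) and restores the intensity scale recorded in the JSON
#' sidecar, when one exists next to the file.
#'
#' @param path TIFF file path.
#' @return list of class `telo_field` with matrices `green`, `red`, `blue`
#'   and the file `path` as provenance (no ground truth).
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected a 3-page TIFF (green, red, blue)")
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  out <- lapply(pages[1:3], function(p) {
    m <- if (length(dim(p)) == 3) p[, , 1] else p
    m * scale
  })
  structure(list(green = out[[1]], red = out[[2]], blue = out[[3]],
                 spec = NULL, truth = NULL, provenance = path),
            class = "telo_field")
}

#' Write the ground-truth focus table of a synthetic field
#'
#' @param field a `telo_field` from [simulate_field()].
#' @param path output CSV path (columns `nucleus_id`, `channel`, `x_px`,
#'   `y_px`, `colocal_pair_id`).
#' @export
write_ground_truth <- function(field, path) {
  if (is.null(field$truth)) stop("field carries no ground truth")
  write.csv(field$truth$foci, path, row.names = FALSE)
  invisible(path)
}
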