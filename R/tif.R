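#' Count foci in a nucleus
#'
#' Counts connected components (8-connectivity) of the channel's foreground
#' within a nucleus mask, keeping components of at least `min_focus_px`
#' pixels. The size filter suppresses isolated noise pixels.
#'
#' @param cb a [channel_binary()].
#' @param nucleus a nucleus mask from [segment_nuclei()], or a logical
#'   matrix.
#' @param min_focus_px minimum component area in pixels.
#' @return non-negative integer focus count.
#' @export
count_foci <- function(cb, nucleus, min_focus_px = 1L) {
  stopifnot_scalar(min_focus_px, "min_focus_px", positive = TRUE, integer = TRUE)
  m <- if (inherits(nucleus, "nucleus_mask")) nucleus$mask else nucleus
  if (!identical(dim(m), dim(cb$binary))) stop("dimensions differ")
  fg <- cb$binary & m
  lab <- label_components(fg)
  nl <- max(lab)
  if (nl == 0L) return(0L)
  sum(tabulate(lab[lab > 0L], nl) >= min_focus_px)
}

#' Count TIFs (co-stained foci) in a nucleus
#'
#' A telomere dysfunction-induced focus (TIF) is identified as a focus in
#' the telomere-marker channel (green, e.g. TRF1) that is co-stained by the
#' damage-marker channel (red, e.g. 53BP1): a green connected component
#' whose pixel overlap with the red foreground is at least
#' `min_overlap_px`, evaluated within the nucleus. The count of such
#' components is the per-cell TIF number.
#'
#' @param green_cb,red_cb [channel_binary()] objects.
#' @param nucleus nucleus mask (object or logical matrix).
#' @param min_overlap_px minimum overlap in pixels for a green component to
#'   count as co-stained (inclusive).
#' @param min_focus_px minimum component area for a green component to count
#'   as a focus at all; components below it (e.g. single noise pixels) are
#'   not TIF candidates. Use the same value as in [count_foci()] so that
#'   the TIF count can never exceed the focus count.
#' @return non-negative integer TIF count.
#' @export
count_tifs <- function(green_cb, red_cb, nucleus, min_overlap_px = 1L,
                       min_focus_px = 1L) {
  stopifnot_scalar(min_overlap_px, "min_overlap_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar(min_focus_px, "min_focus_px", positive = TRUE, integer = TRUE)
  m <- if (inherits(nucleus, "nucleus_mask")) nucleus$mask else nucleus
  if (!identical(dim(m), dim(green_cb$binary)) ||
      !identical(dim(m), dim(red_cb$binary))) stop("dimensions differ")
  gfg <- green_cb$binary & m
  rfg <- red_cb$binary & m
  lab <- label_components(gfg)
  nl <- max(lab)
  if (nl == 0L || !any(rfg)) return(0L)
  areas <- tabulate(lab[lab > 0L], nl)
  overlap <- tabulate(lab[lab > 0L & rfg], nl)
  sum(areas >= min_focus_px & overlap >= min_overlap_px)
}

#' Run the per-cell quantification pipeline on one field
#'
#' Segments nuclei from the blue channel, Otsu-thresholds the green and red
#' channels within the union of the nuclear masks, and tabulates per-nucleus
#' focus counts, TIF counts and relative focus area.
#'
#' @param field a `telo_field` from [simulate_field()], or a list with
#'   numeric matrices `green`, `red`, `blue`.
#' @param min_nucleus_area minimum nucleus component area (pixels).
#' @param min_focus_px minimum focus component area (pixels).
#' @param min_overlap_px minimum green/red overlap for a TIF (pixels).
#' @param image_id,group_label identifiers copied into the table.
#' @param area_channel channel whose relative focus area is tabulated.
#' @param return_details also return the nucleus masks and thresholded
#'   channels.
#' @return a per-cell table (data frame) with columns `image_id`,
#'   `nucleus_id`, `n_green_foci`, `n_red_foci`, `n_tifs`,
#'   `relative_focus_area`, `group_label`; with `return_details = TRUE`, a
#'   list `(cells, nuclei, green_cb, red_cb)`.
#' @export
#' @examples
#' f <- simulate_field(field_spec(n_nuclei = 2, colocal_fraction = 1, seed = 2))
#' analyze_field(f)$n_tifs  # equals the planted TIF counts
analyze_field <- function(field, min_nucleus_area = 50L, min_focus_px = 4L,
                          min_overlap_px = 1L, image_id = "image1",
                          group_label = NA_character_,
                          area_channel = c("green", "red"),
                          return_details = FALSE) {
  area_channel <- match.arg(area_channel)
  nuclei <- segment_nuclei(field$blue, min_nucleus_area = min_nucleus_area)
  empty <- data.frame(image_id = character(), nucleus_id = integer(),
                      n_green_foci = integer(), n_red_foci = integer(),
                      n_tifs = integer(), relative_focus_area = numeric(),
                      group_label = character())
  if (!length(nuclei)) {
    return(if (return_details) list(cells = empty, nuclei = nuclei,
                                    green_cb = NULL, red_cb = NULL) else empty)
  }
  um <- nuclei_union(nuclei)
  green_cb <- otsu_threshold(field$green, um, channel_name = "green")
  red_cb <- otsu_threshold(field$red, um, channel_name = "red")
  area_cb <- if (area_channel == "green") green_cb else red_cb
  area <- relative_focus_area(area_cb, nuclei)
  cells <- do.call(rbind, lapply(nuclei, function(nuc) {
    data.frame(
      image_id = image_id, nucleus_id = nuc$nucleus_id,
      n_green_foci = count_foci(green_cb, nuc, min_focus_px),
      n_red_foci = count_foci(red_cb, nuc, min_focus_px),
      n_tifs = count_tifs(green_cb, red_cb, nuc, min_overlap_px, min_focus_px),
      group_label = group_label
    )
  }))
  cells$relative_focus_area <-
    area$relative_area[match(cells$nucleus_id, area$nucleus_id)]
  cells <- cells[, c("image_id", "nucleus_id", "n_green_foci", "n_red_foci",
                     "n_tifs", "relative_focus_area", "group_label")]
  if (return_details)
    list(cells = cells, nuclei = nuclei, green_cb = green_cb, red_cb = red_cb)
  else cells
}

#' Compare a per-cell measurement between groups
#'
#' Two groups are compared with a two-tailed two-sample Student's t-test
#' (pooled variance); more than two groups with one-way ANOVA followed by
#' Tukey's HSD over all pairs. Group means and standard deviations are
#' reported as in figure legends (mean +/- SD, n = cells).
#'
#' @param table a per-cell data frame (e.g. from [analyze_field()], rows
#'   from several images/groups bound together).
#' @param response name of the response column (default `"n_tifs"`).
#' @param group name of the grouping column.
#' @param var_equal use the pooled-variance Student's t for two groups
#'   (default); `FALSE` switches to Welch's t.
#' @return object of class `group_comparison`: per-group summary
#'   (`group`, `n`, `mean`, `sd`), the test name, statistic and p-value,
#'   and for >2 groups the Tukey pair table (`pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`). Two groups that both have zero variance yield statistic 0 /
#'   p 1 when their means agree, otherwise an infinite statistic with a
#'   degeneracy note — never an error.
#' @export
compare_groups <- function(table, response = "n_tifs", group = "group_label",
                           var_equal = TRUE) {
  if (!response %in% names(table)) stop("no column '", response, "'")
  if (!group %in% names(table)) stop("no column '", group, "'")
  y <- table[[response]]
  g <- factor(table[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  lv <- levels(g)
  if (length(lv) < 2) stop("at least 2 groups are required")
  ns <- tapply(y, g, length)
  if (any(ns < 2)) stop("each group needs at least 2 cells")
  summ <- data.frame(group = lv, n = as.integer(ns[lv]),
                     mean = as.numeric(tapply(y, g, mean)[lv]),
                     sd = as.numeric(tapply(y, g, sd)[lv]))
  note <- NULL; pairs <- NULL
  if (length(lv) == 2) {
    ya <- y[g == lv[1]]; yb <- y[g == lv[2]]
    if (sd(ya) == 0 && sd(yb) == 0) {
      delta <- mean(ya) - mean(yb)
      statistic <- if (delta == 0) 0 else sign(delta) * Inf
      p <- if (delta == 0) 1 else .Machine$double.xmin
      note <- "degenerate: zero within-group variance in both groups"
      test <- if (var_equal) "Student's t (two-tailed)" else "Welch's t (two-tailed)"
    } else {
      tt <- t.test(ya, yb, var.equal = var_equal)
      statistic <- unname(tt$statistic); p <- tt$p.value
      test <- if (var_equal) "Student's t (two-tailed)" else "Welch's t (two-tailed)"
    }
  } else {
    fit <- aov(y ~ g)
    an <- anova(fit)
    statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
    test <- "one-way ANOVA + Tukey HSD"
    tk <- TukeyHSD(fit)$g
    pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(response = response, test = test, groups = summ,
                 statistic = statistic, p_value = p, pairs = pairs,
                 note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s)\n", x$response, x$test))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", x$groups$group[i],
                x$groups$mean[i], x$groups$sd[i], x$groups$n[i]))
  cat(sprintf("  statistic = %.4g, p = %s\n", x$statistic, format.pval(x$p_value)))
  if (!is.null(x$pairs)) {
    cat("  Tukey pairs:\n")
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("    %s: diff %.3f [%.3f, %.3f], p_adj = %s\n",
                  x$pairs$pair[i], x$pairs$diff[i], x$pairs$lwr[i],
                  x$pairs$upr[i], format.pval(x$pairs$p_adj[i])))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
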