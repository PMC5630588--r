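test_that("focus counting recovers planted counts in noiseless fields", {
  f <- tiny_field(seed = 61, n_nuclei = 2, colocal_fraction = 0, foci = 3)
  det <- analyze_field(f, return_details = TRUE, min_nucleus_area = 100)
  idx <- match_truth(det$nuclei, f$truth$nuclei)
  for (k in seq_along(det$nuclei)) {
    expect_equal(count_foci(det$green_cb, det$nuclei[[k]], 4),
                 f$truth$nuclei$n_green[idx[k]])
    expect_equal(count_foci(det$red_cb, det$nuclei[[k]], 4),
                 f$truth$nuclei$n_red[idx[k]])
  }
})

test_that("focus counting edge cases: empty foreground and the size filter", {
  nucleus <- matrix(TRUE, 10, 10)
  expect_equal(count_foci(cb(matrix(0, 10, 10)), nucleus), 0L)
  speck <- matrix(0, 10, 10); speck[4:5, 4] <- 8       # 2-px component
  expect_equal(count_foci(cb(speck), nucleus, min_focus_px = 3), 0L)
  expect_equal(count_foci(cb(speck), nucleus, min_focus_px = 2), 1L)
})

test_that("TIF counting: full co-localization, empty red, overlap boundary", {
  f <- tiny_field(seed = 62, n_nuclei = 2, colocal_fraction = 1, foci = 3)
  det <- analyze_field(f, return_details = TRUE, min_nucleus_area = 100)
  for (nuc in det$nuclei)
    expect_equal(count_tifs(det$green_cb, det$red_cb, nuc), 3L)
  # red empty
  none <- cb(matrix(0, 10, 10))
  blob <- matrix(0, 10, 10); blob[3:5, 3:5] <- 9
  expect_equal(count_tifs(cb(blob), none, matrix(TRUE, 10, 10)), 0L)
  # overlap of exactly min_overlap_px - 1 fails; min_overlap_px succeeds
  g <- matrix(0, 10, 10); g[3:5, 3:5] <- 9             # 9-px green focus
  r <- matrix(0, 10, 10); r[5:7, 5:7] <- 9             # overlaps g in 1 px
  m <- matrix(TRUE, 10, 10)
  expect_equal(count_tifs(cb(g), cb(r), m, min_overlap_px = 2), 0L)
  expect_equal(count_tifs(cb(g), cb(r), m, min_overlap_px = 1), 1L)
})

test_that("TIF count never exceeds either channel's focus count", {
  set.seed(603)
  for (seed in 1:6) {
    f <- simulate_field(field_spec(
      image_height_px = 160, image_width_px = 160, n_nuclei = 3,
      nucleus_radius_px = 24, foci_per_nucleus_green = 4,
      foci_per_nucleus_red = 3, colocal_fraction = runif(1, 0, 0.75),
      psf_sigma_px = 1, noise_sd = 100, min_focus_sep_px = 8, seed = seed))
    cells <- analyze_field(f, min_nucleus_area = 200)
    expect_true(all(cells$n_tifs <= pmin(cells$n_green_foci, cells$n_red_foci)))
  }
})

test_that("two identical groups give a null comparison and clean summaries", {
  tab <- data.frame(n_tifs = rep(c(1, 2, 3), 2),
                    group_label = rep(c("a", "b"), each = 3))
  res <- compare_groups(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$groups$mean, c(2, 2))
  expect_equal(res$groups$n, c(3L, 3L))
})

test_that("zero-variance groups degrade gracefully, never crash", {
  same <- data.frame(n_tifs = c(2, 2, 2, 2),
                     group_label = rep(c("a", "b"), each = 2))
  res <- compare_groups(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  diff <- data.frame(n_tifs = c(2, 2, 5, 5),
                     group_label = rep(c("a", "b"), each = 2))
  res2 <- compare_groups(diff)
  expect_true(is.infinite(res2$statistic))
  expect_lte(res2$p_value, .Machine$double.xmin)
  expect_match(res2$note, "degenerate")
})

test_that("the two-group test holds its nominal size", {
  set.seed(601)
  rej <- mean(vapply(1:1000, function(i) {
    tab <- data.frame(n_tifs = rnorm(20), group_label = rep(c("a", "b"), 10))
    compare_groups(tab)$p_value < 0.05
  }, logical(1)))
  band <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rej, 0.05 - band)
  expect_lt(rej, 0.05 + band)
})

test_that("Tukey flags exactly the pairs involving a shifted group", {
  set.seed(602)
  tab <- data.frame(
    n_tifs = c(rnorm(30, 0, 1), rnorm(30, 0, 1), rnorm(30, 10, 1)),
    group_label = rep(c("a", "b", "c"), each = 30))
  res <- compare_groups(tab)
  expect_equal(res$test, "one-way ANOVA + Tukey HSD")
  sig <- res$pairs$pair[res$pairs$p_adj < 0.01]
  expect_setequal(sig, c("c-a", "c-b"))
})

test_that("the full pipeline separates cohorts differing in co-localization", {
  cohort <- function(frac, seeds, label) do.call(rbind, lapply(seeds, function(i) {
    f <- simulate_field(field_spec(
      image_height_px = 160, image_width_px = 160, n_nuclei = 3,
      nucleus_radius_px = 24, foci_per_nucleus_green = 4,
      foci_per_nucleus_red = 4, colocal_fraction = frac, focus_radius_px = 3,
      psf_sigma_px = 1, noise_sd = 100, min_focus_sep_px = 8, seed = i))
    analyze_field(f, min_nucleus_area = 200,
                  image_id = sprintf("%s_%02d", label, i), group_label = label)
  }))
  tab <- rbind(cohort(0.2, 1:18, "low"), cohort(0.8, 101:118, "high"))
  expect_gte(min(table(tab$group_label)), 50)
  res <- compare_groups(tab)
  expect_lt(res$p_value, 0.01)
  means <- setNames(res$groups$mean, res$groups$group)
  expect_gt(means["high"], means["low"])
})
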