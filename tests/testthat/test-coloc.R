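test_that("Manders coefficients match the hand-worked 3x3 case", {
  g <- matrix(0, 3, 3); g[1, 2] <- 5; g[2, 2] <- 5
  r <- matrix(0, 3, 3); r[1, 2] <- 5; r[3, 2] <- 5
  expect_equal(manders_coefficients(cb(g), cb(r)),
               c(M1 = 0.5, M2 = 0.5))
})

test_that("Manders limits: identical, disjoint and empty channels", {
  x <- matrix(0, 6, 6); x[2:3, 2:3] <- 10
  expect_equal(manders_coefficients(cb(x), cb(x)), c(M1 = 1, M2 = 1))
  y <- matrix(0, 6, 6); y[5:6, 5:6] <- 4
  expect_equal(manders_coefficients(cb(x), cb(y)), c(M1 = 0, M2 = 0))
  none <- matrix(0, 6, 6)
  res <- manders_coefficients(cb(none), cb(x))
  expect_true(is.na(res["M1"]))   # undefined, not 0
  expect_equal(unname(res["M2"]), 0)
})

test_that("vectorized Manders equals the double-loop oracle on random grids", {
  set.seed(501)
  for (i in 1:200) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    G <- matrix(rbinom(h * w, 1, 0.4) * runif(h * w, 1, 100), h, w)
    R <- matrix(rbinom(h * w, 1, 0.4) * runif(h * w, 1, 100), h, w)
    mask <- matrix(runif(h * w) < 0.8, h, w)
    if (!any(mask)) next
    expect_identical(manders_coefficients(cb(G), cb(R), mask),
                     manders_oracle(G, R, mask))
  }
})

test_that("block partition tiles exactly: counts, shapes, full coverage", {
  p <- block_partition(c(64, 64), 8, offset = c(0, 0))
  expect_equal(max(p$id), 64)
  expect_true(all(tabulate(as.vector(p$id)) == 64))
  # block size 1: every pixel its own block
  p1 <- block_partition(c(5, 7), 1)
  expect_equal(max(p1$id), 35)
  # ragged case: 10x10, block 8, offset (3,3) still a bijection onto pixels
  p2 <- block_partition(c(10, 10), 8, offset = c(3, 3))
  idv <- as.vector(p2$id)
  expect_equal(length(idv), 100)
  expect_equal(sum(tabulate(idv)), 100)           # every pixel exactly once
  expect_setequal(unique(idv), seq_len(max(idv)))
  # blocks are contiguous rectangles of the advertised shapes
  for (b in unique(idv)) {
    px <- which(p2$id == b, arr.ind = TRUE)
    expect_equal(nrow(px),
                 length(unique(px[, 1])) * length(unique(px[, 2])))
    expect_true(all(diff(sort(unique(px[, 1]))) == 1))
    expect_true(all(diff(sort(unique(px[, 2]))) == 1))
  }
})

test_that("block scrambling conserves content and fixes the zero grid", {
  zero <- matrix(0, 12, 12)
  p <- block_partition(c(12, 12), 4)
  expect_identical(block_scramble(zero, p), zero)
  set.seed(502)
  for (i in 1:20) {
    x <- matrix(rbinom(144, 1, 0.3), 12, 12)
    p <- block_partition(c(12, 12), sample(1:5, 1))
    y <- block_scramble(x, p)
    expect_equal(sum(y), sum(x))                  # conservation, exactly
    expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  }
})

test_that("two-block scramble is a fair coin over many draws", {
  x <- matrix(0, 8, 16); x[, 1:8] <- 1            # one all-ones 8x8 block
  p <- block_partition(c(8, 16), 8, offset = c(0, 0))
  set.seed(503)
  swapped <- vapply(1:10000, function(i) block_scramble(x, p)[1, 9] == 1,
                    logical(1))
  expect_lt(abs(mean(swapped) - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("scrambling permutes contents only within a shape class", {
  set.seed(504)
  p <- block_partition(c(10, 13), 4, offset = c(2, 1))  # ragged edges
  x <- matrix(runif(130), 10, 13)
  y <- block_scramble(x, p)
  shape_of <- function(b) {
    px <- which(p$id == b, arr.ind = TRUE)
    paste(length(unique(px[, 1])), length(unique(px[, 2])))
  }
  shapes <- vapply(seq_len(max(p$id)), shape_of, character(1))
  for (s in unique(shapes)) {
    sel <- as.vector(p$id) %in% which(shapes == s)
    expect_equal(sort(as.vector(y)[sel]), sort(as.vector(x)[sel]))
  }
})

test_that("identical dense channels give the floor p-value 1/(n_perm+1)", {
  f <- tiny_field(seed = 41, n_nuclei = 2, colocal_fraction = 1, foci = 3,
                  noise_sd = 20, psf = 1)
  det <- analyze_field(f, return_details = TRUE, min_nucleus_area = 100)
  um <- Reduce(`|`, lapply(det$nuclei, `[[`, "mask"))
  res <- coloc_test(det$green_cb, det$green_cb, um, n_perm = 999,
                    block_size_px = 7, seed = 11, scope = "mask")
  expect_equal(res$M1, 1)
  expect_equal(res$M2, 1)
  expect_equal(res$p_M1, 1 / 1000)  # no scramble can beat M = 1; ties count
  expect_equal(res$p_M2, 1 / 1000)
})

test_that("empty green channel propagates missing M1 and p_M1", {
  r <- matrix(0, 20, 20); r[5:6, 5:6] <- 10
  res <- coloc_test(cb(matrix(0, 20, 20)), cb(r), n_perm = 19,
                    block_size_px = 4, seed = 3)
  expect_true(is.na(res$M1))
  expect_true(is.na(res$p_M1))
  expect_equal(res$M2, 0)
  expect_false(is.na(res$p_M2))
})

test_that("the permutation test is seed-deterministic", {
  f <- tiny_field(seed = 42, colocal_fraction = 0.5, noise_sd = 30, psf = 1)
  det <- analyze_field(f, return_details = TRUE, min_nucleus_area = 100)
  um <- Reduce(`|`, lapply(det$nuclei, `[[`, "mask"))
  a <- coloc_test(det$green_cb, det$red_cb, um, n_perm = 99,
                  block_size_px = 7, seed = 99, keep_null = TRUE)
  b <- coloc_test(det$green_cb, det$red_cb, um, n_perm = 99,
                  block_size_px = 7, seed = 99, keep_null = TRUE)
  expect_identical(a$null_samples, b$null_samples)
  expect_identical(a$p_M1, b$p_M1)
})

test_that("channel scrambles are independent across iterations", {
  # with two channels scrambled independently, their null overlap indicators
  # across iterations should be uncorrelated with each channel's own motion
  x <- matrix(0, 16, 16); x[1:4, 1:4] <- 1
  y <- matrix(0, 16, 16); y[1:4, 1:4] <- 1
  p <- block_partition(c(16, 16), 4, offset = c(0, 0))
  set.seed(505)
  pos <- t(vapply(1:2000, function(i) {
    xs <- block_scramble(x, p); ys <- block_scramble(y, p)
    c(which(xs == 1)[1], which(ys == 1)[1])
  }, numeric(2)))
  # 16 equally likely blocks each; independence => correlation near 0
  expect_lt(abs(cor(pos[, 1], pos[, 2])), 0.06)
})

test_that("cohort comparison handles exact and degenerate difference patterns", {
  obs <- data.frame(M1 = c(0.5, 0.6, 0.7), M2 = c(0.4, 0.5, 0.6))
  out0 <- cohort_welch(obs, obs)             # all differences exactly zero
  expect_equal(out0$paired_t, c(0, 0))
  expect_equal(out0$paired_p, c(1, 1))
  shift <- obs; shift$M1 <- shift$M1 - 0.2; shift$M2 <- shift$M2 - 0.2
  outc <- cohort_welch(obs, shift)           # constant positive difference
  expect_true(all(is.infinite(outc$paired_t)))
  expect_true(all(outc$paired_p <= .Machine$double.xmin))
  expect_error(cohort_welch(obs[1, , drop = FALSE], shift[1, , drop = FALSE]),
               "at least 2")
})

test_that("cohort paired p-values are uniform under the null", {
  # observed and per-image null means drawn from the same distribution
  set.seed(506)
  ps <- vapply(1:200, function(i) {
    obs <- data.frame(M1 = runif(20, 0.2, 0.4), M2 = runif(20, 0.2, 0.4))
    nul <- data.frame(M1 = runif(20, 0.2, 0.4), M2 = runif(20, 0.2, 0.4))
    cohort_welch(obs, nul)$paired_p[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
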