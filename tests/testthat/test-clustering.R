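orthogonal_maps <- function(n_maps = 4L, n_ch = 12L) {
  # zero-mean, unit-norm, mutually orthogonal topographies
  set.seed(99)
  basis <- rbind(rep(1, n_ch), matrix(rnorm((n_maps) * n_ch), n_maps, n_ch))
  Q <- qr.Q(qr(t(basis)))[, -1, drop = FALSE]
  t(Q)[seq_len(n_maps), , drop = FALSE]
}

# piecewise amplitude so every sample has a well-defined GFP peak pattern
toy_record <- function(maps, labels, amp = NULL, fs = 100) {
  n <- length(labels)
  if (is.null(amp)) amp <- 1 + abs(sin(seq_len(n) / 2))
  eeg_record(amp * maps[labels + 1L, , drop = FALSE], fs = fs)
}

test_that("noiseless orthogonal clusters are recovered exactly with total GEV 1", {
  maps <- orthogonal_maps(4, 12)
  set.seed(1)
  labels <- sample(0:3, 600, replace = TRUE)
  signs <- sample(c(-1, 1), 600, replace = TRUE)
  rec <- toy_record(maps * 1, labels)
  rec$data <- rec$data * signs                # polarity must not matter
  seg <- modified_kmeans(rec, n_maps = 4, n_runs = 5, seed = 42)
  expect_equal(sum(seg$gev), 1, tolerance = 1e-9)
  cc <- match_corr(seg$maps, maps)
  expect_true(all(cc >= 0.999))
  expect_equal(seg$cv, 0, tolerance = 1e-12)
})

test_that("maps survive white spatial noise at SNR 5 with matched |corr| >= 0.95", {
  maps <- orthogonal_maps(4, 30)
  set.seed(7)
  n <- 4000
  labels <- sample(0:3, n, replace = TRUE)
  amp <- 1 + abs(sin(seq_len(n) / 2))
  clean <- amp * maps[labels + 1L, ]
  noise_sd <- sqrt(mean(clean^2) / 5)
  rec <- eeg_record(clean + matrix(rnorm(n * 30, sd = noise_sd), n, 30),
                    fs = 100)
  seg <- modified_kmeans(rec, n_maps = 4, n_runs = 10, seed = 11)
  expect_true(all(match_corr(seg$maps, maps) >= 0.95))
})

test_that("modified_kmeans validates its configuration", {
  rec <- toy_record(orthogonal_maps(4, 12), rep(0:3, 50))
  expect_error(modified_kmeans(rec, n_maps = 1), ">= 2")
  expect_error(modified_kmeans(rec, n_maps = 4, maxerr = 0), "configuration")
  tiny <- eeg_record(matrix(rnorm(3 * 12), 3, 12), fs = 100)
  expect_error(modified_kmeans(tiny, n_maps = 4), "GFP peaks|at least 3")
})

test_that("backfit assigns by squared correlation, polarity-blind, ties to lowest index", {
  maps <- orthogonal_maps(3, 10)
  expect_identical(backfit_labels(maps, maps[3, , drop = FALSE]), 2L)
  expect_identical(backfit_labels(maps, -maps[3, , drop = FALSE]), 2L)
  # exact tie (identical dot products in floating point) -> lowest index
  m_exact <- rbind(c(1, -1, 0, 0) / sqrt(2), c(0, 0, 1, -1) / sqrt(2))
  tie <- c(1, -1, 1, -1)
  expect_identical(backfit_labels(m_exact, matrix(tie, 1)), 0L)
  expect_error(backfit_labels(maps, matrix(0, 5, 4)), "same number of channels")
})

test_that("label assignment is scale- and polarity-invariant", {
  maps <- orthogonal_maps(4, 12)
  set.seed(3)
  x <- matrix(rnorm(200 * 12), 200, 12)
  l0 <- backfit_labels(maps, x)
  expect_identical(backfit_labels(maps, 5.5 * x), l0)
  flip <- sample(c(-1, 1), 200, replace = TRUE)
  expect_identical(backfit_labels(maps, flip * x), l0)
})

test_that("GEV is 1 for pure one-map data, 0 for orthogonal data, additive over label splits", {
  maps <- orthogonal_maps(2, 10)
  amp <- 1 + abs(sin(1:100))
  one <- amp * matrix(maps[1, ], 100, 10, byrow = TRUE)
  expect_equal(global_explained_variance(maps[1, , drop = FALSE], one,
                                         rep(0L, 100)),
               1, tolerance = 1e-12)
  # data built entirely from map 2 but labeled as map 1: orthogonal -> 0
  two <- amp * matrix(maps[2, ], 100, 10, byrow = TRUE)
  expect_equal(sum(global_explained_variance(maps[1, , drop = FALSE], two,
                                             rep(0L, 100))),
               0, tolerance = 1e-12)
  # additivity: total GEV invariant to how samples are split across labels
  set.seed(8)
  x <- matrix(rnorm(300 * 10), 300, 10)
  la <- sample(0:1, 300, replace = TRUE)
  dup <- rbind(maps[1, ], maps[1, ])
  expect_equal(sum(global_explained_variance(dup, x, la)),
               sum(global_explained_variance(dup, x, rep(0L, 300))),
               tolerance = 1e-12)
})

test_that("cv criterion matches its closed form and scales linearly", {
  expect_equal(cv_criterion(0, 30, 4), 0)
  expect_equal(cv_criterion(2.2, 30, 4), 2 * cv_criterion(1.1, 30, 4))
  expect_equal(cv_criterion(1, 30, 4), (29 / 25)^2)
  expect_equal(cv_criterion(1, 30, 4), 1.3456)
  expect_error(cv_criterion(1, 5, 4), "n_ch > n_maps")
  # strictly increasing in n_maps at fixed residual variance
  expect_gt(cv_criterion(1, 30, 5), cv_criterion(1, 30, 4))
})

test_that("reorder_maps permutes maps, gev, labels consistently", {
  maps <- orthogonal_maps(3, 12)
  rec <- toy_record(maps, rep(0:2, 80))
  seg <- modified_kmeans(rec, n_maps = 3, n_runs = 4, seed = 5)
  expect_identical(reorder_maps(seg, 0:2)$labels, seg$labels)
  perm <- c(1L, 0L, 2L)
  out <- reorder_maps(seg, perm)
  expect_equal(out$maps[2, ], seg$maps[1, ])
  expect_equal(out$gev[c(2, 1, 3)], seg$gev)
  expect_identical(out$labels, perm[seg$labels + 1L])
  # back-fitting the reordered maps reproduces the permuted labels
  expect_identical(backfit_labels(out$maps, rec$data), out$labels)
  expect_error(reorder_maps(seg, c(0L, 0L, 1L)), "bijection")
})

test_that("segmentation is deterministic given a seed and polarity-invariant", {
  maps <- orthogonal_maps(4, 12)
  set.seed(21)
  labels <- sample(0:3, 500, replace = TRUE)
  rec <- toy_record(maps, labels)
  noise <- matrix(rnorm(500 * 12, sd = 0.05), 500, 12)
  rec$data <- rec$data + noise
  a <- modified_kmeans(rec, n_maps = 4, n_runs = 3, seed = 77)
  b <- modified_kmeans(rec, n_maps = 4, n_runs = 3, seed = 77)
  expect_identical(a$labels, b$labels)
  expect_equal(a$maps, b$maps)
  expect_equal(a$cv, b$cv)
  # sign-flipping input topographies leaves labels and |maps| unchanged
  flip <- sample(c(-1, 1), 500, replace = TRUE)
  rec2 <- rec
  rec2$data <- flip * rec$data
  c_ <- modified_kmeans(rec2, n_maps = 4, n_runs = 3, seed = 77)
  expect_identical(c_$labels, a$labels)
  expect_equal(abs(c_$maps %*% t(a$maps)) |> diag() |> unname(),
               rep(1, 4), tolerance = 1e-9)
})

test_that("total GEV does not decrease with more maps", {
  maps <- orthogonal_maps(5, 16)
  set.seed(31)
  labels <- sample(0:4, 800, replace = TRUE)
  rec <- toy_record(maps, labels)
  rec$data <- rec$data + matrix(rnorm(800 * 16, sd = 0.3), 800, 16)
  gev2 <- sum(modified_kmeans(rec, n_maps = 2, n_runs = 6, seed = 1)$gev)
  gev3 <- sum(modified_kmeans(rec, n_maps = 3, n_runs = 6, seed = 1)$gev)
  gev5 <- sum(modified_kmeans(rec, n_maps = 5, n_runs = 6, seed = 1)$gev)
  expect_lte(gev2, gev3 + 1e-9)
  expect_lte(gev3, gev5 + 1e-9)
})

test_that("template matching yields a canonical ordering", {
  lay <- demo_layout(30)
  tpl <- template_maps(lay)
  # shuffle the templates, then recover each row's template index
  ord <- c(3L, 1L, 4L, 2L)
  shuffled <- tpl[ord, ]
  expect_identical(match_maps(shuffled, tpl), ord - 1L)
  # reorder_maps with that permutation restores template order
  restored <- shuffled[order(ord - 1L), ]
  expect_equal(unname(restored), unname(tpl))
})
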