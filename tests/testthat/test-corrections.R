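test_that("parameter estimation pools mean and population sd", {
  v <- vol3d(c(100, 150))
  p <- estimate_fd_params(v, exclude_zeros = FALSE)
  expect_equal(p$epsilon_F, 125)
  expect_equal(p$epsilon_b, -25)

  # pooled across volumes at dataset scope; brute-force pool as oracle
  set.seed(11)
  vols <- list(random_volume(c(3, 4, 5)), random_volume(c(2, 3, 4)))
  p2 <- estimate_fd_params(vols, exclude_zeros = FALSE)
  pool <- c(vols[[1]], vols[[2]])
  expect_equal(p2$epsilon_F, mean(pool))
  expect_equal(p2$epsilon_b, -sqrt(mean((pool - mean(pool))^2)))

  # volume scope returns one estimate per volume
  pv <- estimate_fd_params(vols, stats_scope = "volume",
                           exclude_zeros = FALSE)
  expect_length(pv, 2)
  expect_equal(pv[[2]]$epsilon_F, mean(vols[[2]]))
})

test_that("zero-exclusion drops skull-stripped background from the pool", {
  v <- vol3d(c(0, 0, 0, 100, 150, 0))
  p <- estimate_fd_params(v, exclude_zeros = TRUE)
  expect_equal(p$epsilon_F, 125)
  expect_equal(p$n_voxels, 2L)
  expect_error(estimate_fd_params(vol3d(rep(0, 8)), exclude_zeros = TRUE),
               "no foreground voxels")
  expect_error(estimate_fd_params(vol3d(rep(7, 5)), exclude_zeros = FALSE),
               "degenerate intensity distribution")
})

test_that("FD corrections match the closed sigmoid forms", {
  p <- fd_params(epsilon_F = 125, epsilon_b = -25)
  at <- function(x, ...) fd_correct(vol3d(x), p, ...)[1]

  expect_identical(at(125, variant = "FD1"), 0.5)      # value at the mean
  expect_identical(at(125, variant = "FD2"), 0.5)
  expect_equal(at(125 + log(3), variant = "FD1"), 0.75)
  p1 <- fd_params(125, -1)
  expect_equal(fd_correct(vol3d(126), p1, "FD2")[1], 1 / (exp(-1) + 1),
               tolerance = 1e-12)

  # FD1 ignores epsilon_b entirely; FD2 with |eb| = 1 equals FD1 exactly
  set.seed(3)
  v <- random_volume()
  expect_identical(fd_correct(v, p, "FD1"), fd_correct(v, p1, "FD1"))
  expect_identical(fd_correct(v, p1, "FD2"), fd_correct(v, p1, "FD1"))
})

test_that("FD outputs are strictly inside (0,1) and increasing in intensity", {
  p <- fd_params(epsilon_F = 125, epsilon_b = -40)
  # FD1's unit-width kernel saturates in double precision beyond ~eF +/- 36,
  # so probe it on a narrower band; FD2 is scaled by |eb| and covers 0..300
  ranges <- list(FD1 = c(105, 150), FD2 = c(0, 300))
  for (variant in c("FD1", "FD2")) {
    set.seed(7)
    for (i in 1:5) {
      v <- random_volume(lo = ranges[[variant]][1], hi = ranges[[variant]][2])
      out <- fd_correct(v, p, variant)
      expect_true(all(out > 0 & out < 1))
      o <- order(v)
      expect_true(all(diff(out[o]) >= 0))
    }
    # strictly increasing on an evenly spaced intensity ramp
    ramp <- vol3d(seq(ranges[[variant]][1], ranges[[variant]][2],
                      length.out = 100))
    expect_true(all(diff(fd_correct(ramp, p, variant)) > 0))
  }
  expect_error(fd_correct(vol3d(c(1, NA, 3)), p), "non-finite")
  expect_error(fd_correct(vol3d(1:3), fd_params(2, 0), "FD2"),
               "requires \\|epsilon_b\\| > 0")
})

test_that("FD2 is the sigmoid of the z-score, voxelwise", {
  set.seed(21)
  v <- random_volume(c(5, 6, 7))
  p <- estimate_fd_params(v, exclude_zeros = FALSE)
  expect_equal(fd_correct(v, p, "FD2"),
               array(plogis(zscore_normalize(v, p)), dim = dim(v)),
               tolerance = 1e-15)
})

test_that("z-score normalization standardizes and is shift invariant", {
  v <- vol3d(c(1, 2, 3))
  p <- estimate_fd_params(v, exclude_zeros = FALSE)
  z <- zscore_normalize(v, p)
  expect_equal(z[3], (3 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
  expect_identical(zscore_normalize(vol3d(2), p)[1], 0)    # centering at eF

  # shifting input and params together leaves the output unchanged
  shift <- 42
  p_shift <- fd_params(p$epsilon_F + shift, p$epsilon_b)
  expect_equal(zscore_normalize(v + shift, p_shift), z, tolerance = 1e-12)
})

test_that("BE and MB transforms follow the occupation forms and limits", {
  p <- fd_params(epsilon_F = 100, epsilon_b = -10)
  # kernel k = (x - eF)/eb; choose x so k = log(2): BE = 1/(2-1) = 1
  x_log2 <- 100 + (-10) * log(2)
  expect_equal(be_transform(vol3d(x_log2), p)[1], 1, tolerance = 1e-12)
  expect_equal(mb_transform(vol3d(x_log2), p)[1], 0.5, tolerance = 1e-12)
  expect_equal(mb_transform(vol3d(100), p)[1], 1)  # e^0 at the mean

  expect_error(be_transform(vol3d(c(5, 100)), p), "BE pole at mean intensity")

  # classical limit: at kernel 10 all three forms agree within 1e-3 relative
  x10 <- 100 + (-10) * 10
  fd <- fd_correct(vol3d(x10), p, "FD2")[1]
  be <- be_transform(vol3d(x10), p)[1]
  mb <- mb_transform(vol3d(x10), p)[1]
  expect_equal(mb, exp(-10), tolerance = 1e-12)
  expect_lt(abs(fd - mb) / mb, 1e-3)
  expect_lt(abs(be - mb) / mb, 1e-3)
})

test_that("gamma correction normalizes then exponentiates, preserving order", {
  v <- vol3d(c(0, 5, 10))
  expect_equal(gamma_correct(v, 1), vol3d(c(0, 0.5, 1)))
  expect_equal(gamma_correct(v, 0.6)[2], 0.5^0.6, tolerance = 1e-12)
  g <- gamma_correct(v, 3.7)
  expect_identical(g[1], 0); expect_identical(g[3], 1)  # fixed points
  set.seed(5)
  r <- random_volume()
  out <- gamma_correct(r, 0.3)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(order(out), order(r))
  expect_error(gamma_correct(vol3d(rep(2, 4)), 0.6),
               "cannot normalize constant volume")
  expect_error(gamma_correct(v, -1), "'gamma' must be > 0")
})

test_that("gamma sweep picks the argmax with smallest-gamma tie-break", {
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5, 2)
  vols <- list(vol3d(c(0, 1, 2)))
  labs <- list(NULL)

  const <- gamma_sweep(vols, labs, function(v, l) 1, grid = grid)
  expect_equal(const$best_gamma, 0.2)

  # evaluator cannot see gamma directly; reconstruct it from the output:
  # gamma_correct maps normalized 0.5 to 0.5^gamma, so invert the middle voxel
  peak <- gamma_sweep(vols, labs,
                      function(v, l) -abs(log(v[[1]][2]) / log(0.5) - 0.6),
                      grid = grid)
  expect_equal(peak$best_gamma, 0.6)
  expect_equal(peak$scores$gamma, grid)

  expect_error(
    gamma_sweep(vols, labs, function(v, l) stop("boom"), grid = c(0.4)),
    "evaluator failed at gamma=0.4")
})

test_that("gamma sweep on a phantom equals brute-force grid argmax", {
  spec <- phantom_spec(shape = c(8, 20, 20), n_cases = 2, noise_sigma = 4,
                       seed = 99)
  cases <- lapply(1:2, generate_case, spec = spec)
  vols <- lapply(cases, `[[`, "channels")
  labs <- lapply(cases, `[[`, "labels")
  evaluator <- function(pre, labels) {
    counts <- pool_counts(Map(function(chs, lab) {
      confusion_counts(threshold_segmenter(chs, 0.5),
                       label_decompose(lab)$WT)
    }, pre, labels))
    2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn)
  }
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5, 2)
  res <- gamma_sweep(vols, labs, evaluator, grid = grid)
  # independent exhaustive evaluation of the same grid
  brute <- vapply(grid, function(g) {
    evaluator(lapply(vols, function(ch) lapply(ch, gamma_correct, gamma = g)),
              labs)
  }, numeric(1))
  expect_equal(res$scores$score, brute)
  expect_equal(res$best_gamma, min(grid[brute == max(brute)]))
})

test_that("3D histogram equalization maps through the global CDF", {
  # 30 voxels at a < 70 voxels at b: CDF sends a -> 0.3 and b -> 1.0
  v <- vol3d(c(rep(10, 30), rep(200, 70)), dim = c(10, 10, 1))
  out <- histogram_equalize_3d(v, exclude_zeros = FALSE)
  expect_equal(unique(out[v == 10]), 0.3)
  expect_equal(unique(out[v == 200]), 1.0)

  # constant participating volume collapses to 1; zeros stay 0
  cz <- vol3d(c(0, 0, 7, 7, 7))
  outz <- histogram_equalize_3d(cz, exclude_zeros = TRUE)
  expect_equal(as.vector(outz), c(0, 0, 1, 1, 1))
  expect_error(histogram_equalize_3d(vol3d(rep(0, 4)), exclude_zeros = TRUE),
               "no participating voxels")

  # rank order among participating voxels is preserved; range is [0, 1]
  set.seed(13)
  for (i in 1:5) {
    r <- random_volume(c(6, 7, 8))
    eq <- histogram_equalize_3d(r, n_bins = 64, exclude_zeros = FALSE)
    expect_true(all(eq >= 0 & eq <= 1))
    o <- order(r)
    expect_true(all(diff(eq[o]) >= 0))
  }
})

test_that("apply_correction dispatches and preserves the zero background", {
  set.seed(31)
  v <- random_volume(c(4, 6, 6), lo = 50, hi = 200)
  v[1:20] <- 0  # carve a background
  p <- estimate_fd_params(v, exclude_zeros = TRUE)

  expect_identical(apply_correction(v, "null"), v)
  for (m in c("zscore", "gamma", "histeq3d", "fd1", "fd2", "mb")) {
    out <- apply_correction(v, m, params = p, exclude_zeros = TRUE)
    expect_identical(dim(out), dim(v))
    expect_true(all(out[v == 0] == 0), label = paste(m, "background"))
  }
  fd2 <- apply_correction(v, "fd2", params = p, exclude_zeros = TRUE)
  expect_true(all(fd2[v != 0] > 0 & fd2[v != 0] < 1))
  expect_error(apply_correction(v, "sharpen"), "'arg' should be one of")
})
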