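test_that("centroid_size is the root summed squared centroid deviation", {
  sq <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2))
  expect_equal(centroid_size(sweep(sq, 2L, c(100, -4), "+")), sqrt(2))
  expect_error(centroid_size(matrix(1, 4L, 2L)), "identical")
})

test_that("superimpose_pair removes similarity transforms", {
  set.seed(3)
  a <- matrix(rnorm(8L), 4L, 2L)
  expect_equal(superimpose_pair(a, a)$distance, 0, tolerance = 1e-12)
  rot <- matrix(c(0, -1, 1, 0), 2L, 2L)  # 90 degrees
  b <- 3 * a %*% rot + matrix(c(5, -2), 4L, 2L, byrow = TRUE)
  expect_lt(superimpose_pair(b, a)$distance, 1e-10)
  expect_error(superimpose_pair(matrix(0.5, 4L, 2L), a), "identical")
})

test_that("superimpose_pair matches a brute-force rotation search", {
  set.seed(8)
  m <- matrix(rnorm(8L), 4L, 2L)
  t_ <- matrix(rnorm(8L), 4L, 2L)
  got <- superimpose_pair(m, t_)$distance
  cs <- function(p) {
    p <- sweep(p, 2L, colMeans(p))
    p / sqrt(sum(p^2))
  }
  mc <- cs(m); tc <- cs(t_)
  grid <- seq(0, 2 * pi, by = 1e-5)
  best <- min(vapply(grid, function(th) {
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
    sqrt(sum((mc %*% r - tc)^2))
  }, numeric(1)))
  expect_equal(got, best, tolerance = 1e-4)
  expect_lte(got, best + 1e-12)  # analytic solution can only be better
})

test_that("gpa aligns copies exactly and satisfies its contracts", {
  base <- matrix(rnorm(16L, sd = 2), 8L, 2L)
  set.seed(4)
  arr <- array(0, c(8L, 2L, 5L))
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
    arr[, , i] <- runif(1, 0.5, 3) * base %*% r +
      matrix(rnorm(2L, sd = 4), 8L, 2L, byrow = TRUE)
  }
  fit <- gpa(arr)
  expect_true(fit$converged)
  for (i in 1:5)
    expect_equal(fit$aligned[, , i], fit$aligned[, , 1L], tolerance = 1e-8)
  expect_lt(tail(fit$q_history, 1L), 1e-15)

  # Q equals the summed squared distances to the consensus
  arr2 <- toy_array(7L, k = 9L, seed = 5L)
  fit2 <- gpa(arr2)
  q_direct <- sum(apply(fit2$aligned, 3L, function(a)
    sum((a - fit2$consensus)^2)))
  expect_equal(tail(fit2$q_history, 1L), q_direct, tolerance = 1e-12)
  expect_true(all(diff(fit2$q_history) < 1e-10))

  # unit size and centred at origin
  for (i in 1:7) {
    expect_lt(max(abs(colMeans(fit2$aligned[, , i]))), 1e-9)
    expect_equal(sum(fit2$aligned[, , i]^2), 1, tolerance = 1e-9)
  }

  # consensus is a fixed point: re-running changes Q negligibly
  fit3 <- gpa(fit2$aligned)
  expect_lt(abs(tail(fit3$q_history, 1L) - tail(fit2$q_history, 1L)), 1e-8)
})

test_that("gpa output is invariant to a global similarity transform", {
  arr <- toy_array(6L, k = 10L, seed = 11L)
  f1 <- gpa(arr)
  f2 <- gpa(similarity_transform(arr, angle = 1.1, scale = 0.37,
                                 shift = c(-3, 8)))
  expect_equal(f1$aligned, f2$aligned, tolerance = 1e-8)
  expect_equal(f1$consensus, f2$consensus, tolerance = 1e-8)
})

test_that("bending energy annihilates affine fields and is PSD", {
  set.seed(21)
  ref <- matrix(rnorm(20L), 10L, 2L)
  be <- bending_energy(ref)
  aff <- cbind(1, ref) %*% matrix(rnorm(6L), 3L, 2L)
  expect_lt(abs(toothdisp:::displacement_energy(be, ref + aff)), 1e-8)
  expect_equal(be$energy_matrix, t(be$energy_matrix))
  expect_gt(min(eigen(be$energy_matrix, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
  expect_error(bending_energy(rbind(ref, ref[1L, ])), "coincident")
})

test_that("bending energy agrees with an independent full TPS fit", {
  set.seed(22)
  ref <- matrix(rnorm(16L), 8L, 2L)
  be <- bending_energy(ref)
  target <- ref
  target[4L, ] <- target[4L, ] + c(0.3, -0.2)  # single-point perturbation
  # oracle: fit the interpolating TPS and evaluate w' K w directly
  coefs <- toothdisp:::tps_coefficients(ref, target)
  d <- as.matrix(dist(ref))
  K <- d^2 * log(d + (d == 0))
  w <- coefs[1:8, ]
  oracle <- sum(w[, 1L] * (K %*% w[, 1L])) + sum(w[, 2L] * (K %*% w[, 2L]))
  expect_equal(toothdisp:::displacement_energy(be, target), oracle,
               tolerance = 1e-8)
})

test_that("sliding reduces bending energy and handles zero variation", {
  # zero shape variation: sliding leaves everything in place
  cfg <- make_tooth(tooth_params(crown_height = 1.8), k = 30L)
  arr <- array(rep(cfg$points, 4L), c(30L, 2L, 4L))
  fit <- slide_semilandmarks(arr, make_slider_table(30L))
  for (i in 1:4)
    expect_equal(fit$aligned[, , i], fit$consensus, tolerance = 1e-8)

  # energy to the pre-slide consensus never increases for any specimen
  teeth <- toy_teeth(8L, k = 30L, seed = 2L, noise_sd = 0.02)
  arr <- toothdisp:::configs_to_array(teeth)
  g0 <- gpa(arr)
  bem <- bending_energy(g0$consensus)
  sl <- make_slider_table(30L)
  for (i in 1:8) {
    before <- toothdisp:::displacement_energy(bem, g0$aligned[, , i])
    slid <- toothdisp:::slide_one(g0$aligned[, , i], g0$consensus,
                                  bem$energy_matrix, sl)
    expect_lte(toothdisp:::displacement_energy(bem, slid), before + 1e-12)
  }

  # full sliding run is invariant to a global similarity transform
  f1 <- slide_semilandmarks(arr, sl)
  f2 <- slide_semilandmarks(similarity_transform(arr, 0.8, 2.5, c(1, -9)),
                            sl)
  expect_equal(f1$aligned, f2$aligned, tolerance = 1e-8)
  expect_true(isTRUE(f1$slid))
})

test_that("single-slider optimum matches a dense 1-D grid search", {
  # 5-point toy with one slider (index 3), neighbours 2 and 4
  set.seed(30)
  ref <- cbind(seq(0, 1, length.out = 5L), c(0, 0.3, 0.5, 0.3, 0))
  spec <- ref + matrix(rnorm(10L, sd = 0.05), 5L, 2L)
  be <- bending_energy(ref)
  sliders <- validate_slider_table(
    data.frame(before = 2L, slider = 3L, after = 4L))
  slid <- toothdisp:::slide_one(spec, ref, be$energy_matrix, sliders,
                                clamp_factor = 1e6)
  got_t <- sum((slid[3L, ] - spec[3L, ]) *
                 (spec[4L, ] - spec[2L, ])) /
    sqrt(sum((spec[4L, ] - spec[2L, ])^2))
  u <- (spec[4L, ] - spec[2L, ]) / sqrt(sum((spec[4L, ] - spec[2L, ])^2))
  grid <- seq(-0.5, 0.5, by = 1e-4)
  energies <- vapply(grid, function(tt) {
    s2 <- spec
    s2[3L, ] <- s2[3L, ] + tt * u
    toothdisp:::displacement_energy(be, s2)
  }, numeric(1))
  expect_equal(got_t, grid[which.min(energies)], tolerance = 1e-3)
})

test_that("tangent projection is idempotent and preserves small shapes", {
  teeth <- toy_teeth(9L, k = 24L, seed = 6L, noise_sd = 0.0005,
                     crown_sd = 0.002)
  fit <- gpa(toothdisp:::configs_to_array(teeth))
  X <- project_to_tangent_space(fit)
  mu <- attr(X, "consensus_vec")
  # consensus projects to itself; row mean ~ consensus
  expect_equal(as.vector(X %*% mu), rep(1, nrow(X)), tolerance = 1e-9)
  expect_equal(colMeans(X), mu, tolerance = 1e-5)
  # idempotence: re-projecting the projected rows changes nothing
  X2 <- X - (X %*% mu) %*% t(mu) +
    matrix(mu, nrow(X), length(mu), byrow = TRUE)
  expect_equal(X2, X, tolerance = 1e-12, ignore_attr = TRUE)
  # near-consensus: projected vs raw inter-specimen distances almost equal
  raw <- t(apply(fit$aligned, 3L, as.vector))
  expect_equal(as.vector(dist(X)), as.vector(dist(raw)), tolerance = 1e-6)
})
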