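test_that("procrustes_lm decomposes SS exactly with sequential terms", {
  set.seed(51)
  n <- 36L
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 12L)),
                  h = factor(rep(c("u", "v"), 18L)))
  Y <- matrix(rnorm(n * 4L), n, 4L)
  Y[d$g == "b", 1L] <- Y[d$g == "b", 1L] + 2
  an <- procrustes_lm(Y, ~ g + h, d, n_perm = 99L, seed = 1L)
  tab <- an$table
  terms <- tab[!(tab$term %in% c("Residuals", "Total")), ]
  expect_equal(sum(terms$SS) + tab$SS[tab$term == "Residuals"],
               tab$SS[tab$term == "Total"], tolerance = 1e-9)
  expect_equal(terms$Rsq, terms$SS / tab$SS[tab$term == "Total"])
  # strong designed effect detected
  expect_lt(terms$p[terms$term == "g"], 0.05)
  expect_gt(terms$F[terms$term == "g"], terms$F[terms$term == "h"])
  # determinism
  an2 <- procrustes_lm(Y, ~ g + h, d, n_perm = 99L, seed = 1L)
  expect_identical(an$table, an2$table)
})

test_that("procrustes_lm flags degenerate and aliased designs", {
  set.seed(52)
  d <- data.frame(one = factor(rep("x", 12L)),
                  g = factor(rep(c("a", "b"), each = 6L)))
  d$alias <- d$g
  Y <- matrix(rnorm(24L), 12L, 2L)
  # single-level factor: SS = 0, Rsq = 0 row, no error
  an <- procrustes_lm(Y, ~ one, d, n_perm = 49L)
  expect_equal(an$table$SS[1L], 0)
  expect_equal(an$table$Rsq[1L], 0)
  expect_error(procrustes_lm(Y, ~ g + alias, d, n_perm = 49L), "aliased")
})

test_that("procrustes_lm null p-values are uniform", {
  # 120 null replicates of a 3-level factor with no effect
  set.seed(53)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 8L)))
  ps <- vapply(1:120, function(r) {
    Y <- matrix(rnorm(24L * 2L), 24L, 2L)
    procrustes_lm(Y, ~ g, d, n_perm = 59L, seed = r)$table$p[1L]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pairwise_mean_tests: null, power, and enumeration oracle", {
  set.seed(61)
  X <- matrix(rnorm(20L * 3L), 20L, 3L)
  dup <- rbind(X, X)
  p0 <- pairwise_mean_tests(dup, rep(c("a", "b"), each = 20L),
                            n_perm = 199L, seed = 1L)
  expect_gt(p0$p_raw, 0.95)

  # large designed offset: decisive at n = 50
  Y <- rbind(matrix(rnorm(50L * 3L), 50L, 3L),
             matrix(rnorm(50L * 3L, mean = 2), 50L, 3L))
  p1 <- pairwise_mean_tests(Y, rep(c("a", "b"), each = 50L),
                            n_perm = 999L, seed = 2L)
  expect_lte(p1$p_raw, 0.01)

  # n = 3 + 3: compare to exhaustive enumeration of assignments
  set.seed(62)
  Z <- matrix(rnorm(6L * 2L), 6L, 2L)
  g <- rep(c("a", "b"), each = 3L)
  pt <- pairwise_mean_tests(Z, g, n_perm = 2000L, seed = 3L)
  dmean <- function(idx) sqrt(sum((colMeans(Z[idx, , drop = FALSE]) -
                                     colMeans(Z[-idx, , drop = FALSE]))^2))
  obs <- dmean(1:3)
  exact <- mean(apply(combn(6L, 3L), 2L, function(idx)
    dmean(idx) >= obs - 1e-15))
  expect_lt(abs(pt$p_raw - exact), 0.05)

  expect_warning(
    p_small <- pairwise_mean_tests(Z, c("a", "a", "a", "b", "b", "c"),
                                   n_perm = 19L),
    "n < 2")
  expect_identical(nrow(p_small), 1L)   # group c excluded
})

test_that("dip statistic reproduces exact closed-form cases", {
  # two points: dip = 1/4 (derived from the band-feasibility argument)
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  expect_equal(dip_statistic(c(-3, 7)), 0.25)
  # n equally spaced points: a linear cdf fits to within 1/(2n)
  for (n in c(3L, 5L, 10L, 40L))
    expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  # two tight pairs approach the two-atom limit 1/4
  expect_gt(dip_statistic(c(0, 1e-6, 1, 1 + 1e-6)), 0.2499)
  # location-scale invariance and bounds
  set.seed(71)
  x <- rnorm(87L)
  expect_equal(dip_statistic(3.2 * x - 17), dip_statistic(x),
               tolerance = 1e-12)
  expect_gte(dip_statistic(x), 1 / (2 * length(x)))
  expect_lte(dip_statistic(x), 0.25)
})

test_that("dip test separates unimodal from bimodal samples", {
  set.seed(72)
  # well-separated mixture rejects with high power (scaled-down n)
  rej <- vapply(1:25, function(r) {
    x <- c(rnorm(100L, -2, 0.5), rnorm(100L, 2, 0.5))
    dip_test(x, n_mc = 99L, seed = r)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
  # unimodal normal sample is not rejected wholesale
  rej0 <- vapply(1:25, function(r)
    dip_test(rnorm(200L), n_mc = 99L, seed = r)$p_value <= 0.05,
    logical(1))
  expect_lte(mean(rej0), 0.2)
})

test_that("hz_test matches an independent reference implementation", {
  # expected values computed with pingouin.multivariate_normality
  # (Henze-Zirkler) on this exact LCG-generated matrix
  lcg <- function(n, seed = 1234) {
    m <- 2^31 - 1; a <- 16807; st <- seed
    out <- numeric(n)
    for (i in seq_len(n)) { st <- (a * st) %% m; out[i] <- st / m }
    out
  }
  X <- matrix(lcg(60L), 20L, 3L, byrow = TRUE)
  hz <- hz_test(X)
  expect_equal(hz$statistic, 0.6377899421514416, tolerance = 1e-9)
  expect_equal(hz$p_value, 0.28775701060506886, tolerance = 1e-7)
  # grossly non-normal data rejected
  set.seed(73)
  bad <- matrix(rlnorm(200L * 3L, sdlog = 1.5), 200L, 3L)
  expect_lt(hz_test(bad)$p_value, 1e-4)
  expect_error(hz_test(matrix(rnorm(6L), 2L, 3L)), "n > p")
  expect_error(hz_test(cbind(1:20, 1:20)), "singular")
})

test_that("distribution_summary computes moments, modes and dip", {
  set.seed(74)
  x <- rnorm(1250L)
  sym <- c(x, -x)
  sc <- cbind(sym, rnorm(2500L))
  ds <- distribution_summary(sc, rep("all", 2500L), dip_n_mc = 49L)
  expect_equal(ds$skew_g1[1L], 0, tolerance = 1e-9)   # exactly symmetric
  expect_lt(abs(ds$kurtosis[1L] - 3), 0.2)
  expect_true(all(ds$iqr >= 0))
  expect_false(anyNA(ds$dip))
  expect_true(is.list(attr(ds, "hz")))
  # tiny groups flagged with NA, not errors
  ds2 <- distribution_summary(cbind(rnorm(5L)), rep(c("a", "b"), c(3L, 2L)),
                              dip_n_mc = 19L)
  expect_true(all(is.na(ds2$skew_g1)))
  expect_true(all(is.na(ds2$dip)))
})

test_that("two_block_pls: identity, hand SVD, and invariance", {
  set.seed(81)
  X <- matrix(rnorm(30L), 10L, 3L)
  self <- two_block_pls(X, X, n_perm = 49L)
  expect_equal(self$r_pls, 1, tolerance = 1e-10)

  # 2-variable toy blocks against a hand-computed cross-covariance SVD
  A <- matrix(c(1, 2, 3, 4, 2, 1, 0, 2), 4L, 2L)
  B <- matrix(c(0, 1, 1, 3, 5, 2, 4, 1), 4L, 2L)
  got <- two_block_pls(A, B, n_perm = 19L)
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  s <- svd(crossprod(Ac, Bc) / 3)
  oracle <- abs(cor(Ac %*% s$u[, 1L], Bc %*% s$v[, 1L]))
  expect_equal(got$r_pls, as.vector(oracle), tolerance = 1e-12)
  expect_equal(got$singular_values, s$d, tolerance = 1e-12)

  # r_pls invariant to separate orthogonal rotations of each block
  th1 <- 0.6; th2 <- -1.2
  R1 <- matrix(c(cos(th1), -sin(th1), sin(th1), cos(th1)), 2L, 2L)
  R2 <- matrix(c(cos(th2), -sin(th2), sin(th2), cos(th2)), 2L, 2L)
  got_rot <- two_block_pls(A %*% R1, B %*% R2, n_perm = 19L)
  expect_equal(got_rot$r_pls, got$r_pls, tolerance = 1e-10)

  # strongly covarying blocks: small p
  set.seed(82)
  Z <- matrix(rnorm(40L), 20L, 2L)
  W <- Z + matrix(rnorm(40L, sd = 0.1), 20L, 2L)
  expect_lte(two_block_pls(Z, W, n_perm = 199L, seed = 1L)$p_value, 0.01)
  expect_error(two_block_pls(Z[1:2, ], W[1:2, ]), "N >= 3")
})

test_that("measurement_error recovers designed variance components", {
  # identical replicates: zero error
  teeth <- toy_teeth(6L, k = 20L, seed = 91L, noise_sd = 0)
  reps <- c(teeth, teeth)
  spec <- factor(rep(seq_len(6L), 2L))
  me0 <- measurement_error(reps, spec)
  expect_lt(me0$error_percent, 1e-6)
  expect_gt(me0$icc_percent, 100 - 1e-6)

  # replicate noise comparable to between-specimen spread: ~50% error.
  # Built directly in aligned space to keep the designed components exact.
  set.seed(92)
  n_spec <- 40L
  mu <- matrix(rnorm(n_spec * 10L, sd = 1), n_spec, 10L)
  X <- rbind(mu + rnorm(n_spec * 10L), mu + rnorm(n_spec * 10L))
  fit <- structure(list(aligned = array(t(X), c(5L, 2L, 2L * n_spec)),
                        consensus = matrix(0, 5L, 2L)),
                   class = "gpa_fit")
  me <- measurement_error(fit, factor(rep(seq_len(n_spec), 2L)))
  expect_lt(abs(me$error_percent - 50), 10)

  # error percentage decreases monotonically with replicate noise
  errs <- vapply(c(1, 0.5, 0.25, 0.1), function(sd_rep) {
    set.seed(93)
    X <- rbind(mu + rnorm(n_spec * 10L, sd = sd_rep),
               mu + rnorm(n_spec * 10L, sd = sd_rep))
    fit <- structure(list(aligned = array(t(X), c(5L, 2L, 2L * n_spec)),
                          consensus = matrix(0, 5L, 2L)),
                     class = "gpa_fit")
    measurement_error(fit, factor(rep(seq_len(n_spec), 2L)))$error_percent
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(measurement_error(toy_teeth(4L, k = 20L), factor(1:4)),
               "replicates")
})

test_that("find_outliers flags by the box-plot fence", {
  teeth <- toy_teeth(15L, k = 20L, seed = 95L, noise_sd = 0.005)
  fit <- gpa(toothdisp:::configs_to_array(teeth))
  out <- find_outliers(fit)
  expect_false(any(out$outlier))   # homogeneous sample

  # deform one specimen far from the consensus (a translation would be
  # absorbed by the superimposition, so bend half the outline instead)
  arr <- fit$aligned
  arr[1:10, 1L, 5L] <- arr[1:10, 1L, 5L] + 0.3
  fit2 <- gpa(arr)
  out2 <- find_outliers(fit2)
  expect_identical(out2$specimen[1L], "tooth_05")
  expect_true(out2$outlier[1L])
  # fence equals the direct quantile computation
  d <- sqrt(apply(fit2$aligned, 3L, function(a)
    sum((a - fit2$consensus)^2)))
  expect_equal(attr(out2, "threshold"),
               unname(quantile(d, 0.75) + 1.5 * IQR(d)))
})
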