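#' Principal component analysis of aligned shapes
#'
#' Ordinates vectorized shape coordinates (rows = specimens) by singular
#' value decomposition of the column-centred data matrix, equivalent to an
#' eigendecomposition of the (1/(N-1)-normalized) covariance matrix. A
#' deterministic sign convention orients every eigenvector so that its
#' largest-magnitude loading is positive.
#'
#' @param x N x p matrix of tangent-space coordinates (see
#'   [project_to_tangent_space()]), or a `gpa_fit` (projected first).
#' @param tangent if `x` is a `gpa_fit`, project to tangent space (default)
#'   or use raw Procrustes coordinates.
#' @return object of class `shape_pca`: rotation (p x q), scores (N x q),
#'   eigenvalues, percent_variance, reference_mean, k, m.
#' @export
shape_pca <- function(x, tangent = TRUE) {
  if (inherits(x, "gpa_fit")) {
    X <- if (tangent) project_to_tangent_space(x)
         else t(apply(x$aligned, 3L, as.vector))
  } else X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  pos <- s$d > max(s$d[1L], 0) * 1e-10
  if (!any(pos)) stop("rank-0 input: no shape variation to ordinate")
  q <- sum(pos)
  rot <- s$v[, seq_len(q), drop = FALSE]
  # sign convention: largest-|loading| entry of each PC positive
  flip <- vapply(seq_len(q), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- Xc %*% rot
  rownames(scores) <- rownames(X)
  eig <- (s$d[seq_len(q)]^2) / (n - 1L)
  structure(
    list(rotation = rot, scores = scores, eigenvalues = eig,
         percent_variance = 100 * eig / sum(eig), reference_mean = mu,
         k = length(mu) %/% 2L, m = 2L),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  q <- min(4L, length(x$eigenvalues))
  cat(sprintf("<shape_pca> %d specimens, %d PCs; PC1-%d explain %s%%\n",
              nrow(x$scores), length(x$eigenvalues), q,
              format(round(cumsum(x$percent_variance)[q], 2))))
  invisible(x)
}

#' Reconstruct a shape from PC scores
#'
#' Returns the configuration at the given position in morphospace:
#' the reference mean plus the score-weighted sum of eigenvectors,
#' reshaped to k x 2. A zero score vector reproduces the consensus shape.
#'
#' @param pca a `shape_pca`.
#' @param scores numeric vector of scores on PC1..PCj (length <= number of
#'   PCs).
#' @return k x 2 coordinate matrix.
#' @export
backtransform <- function(pca, scores) {
  q <- length(pca$eigenvalues)
  if (length(scores) > q)
    stop("score vector longer than the number of PCs (", q, ")")
  v <- pca$reference_mean
  if (length(scores))
    v <- v + pca$rotation[, seq_along(scores), drop = FALSE] %*% scores
  matrix(v, ncol = 2L, dimnames = list(NULL, c("x", "y")))
}

#' Modal shape along a principal component
#'
#' Estimates the mode of the score distribution on axis `j` as the argmax
#' of a Gaussian kernel density (Silverman's bandwidth, 512-point grid
#' spanning the score range with a 5% margin) and reconstructs the shape at
#' that position: consensus + mode x eigenvector.
#'
#' @param pca a `shape_pca`.
#' @param j PC axis index.
#' @param scores optional score subset (defaults to all specimens' scores
#'   on axis j); at least 10 values.
#' @return list of class `shape_reconstruction`: kind = "mode", axis,
#'   location_value (the modal score), shape (k x 2).
#' @export
modal_shape <- function(pca, j = 1L, scores = NULL) {
  if (is.null(scores)) scores <- pca$scores[, j]
  scores <- as.numeric(scores)
  if (length(scores) < 10L)
    stop("mode estimation is unstable below 10 scores (got ",
         length(scores), ")")
  if (stats::sd(scores) < .Machine$double.eps) {
    moc <- scores[1L]
  } else {
    margin <- 0.05 * diff(range(scores))
    d <- stats::density(scores, bw = "nrd0", n = 512L,
                        from = min(scores) - margin,
                        to = max(scores) + margin)
    moc <- d$x[which.max(d$y)]
  }
  sc <- rep(0, j)
  sc[j] <- moc
  structure(list(kind = "mode", axis = j, location_value = moc,
                 shape = backtransform(pca, sc)),
            class = "shape_reconstruction")
}

# TPS coefficients mapping `reference` landmarks onto `target`.
tps_coefficients <- function(reference, target) {
  ref <- as.matrix(reference)
  k <- nrow(ref)
  d <- as.matrix(stats::dist(ref))
  K <- d^2 * log(d + (d == 0))
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- rbind(as.matrix(target), matrix(0, 3L, 2L))
  coefs <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  coefs  # (k+3) x 2: w_1..w_k, a0, ax, ay per output coordinate
}

# Evaluate the TPS map (and optionally its Jacobian) at points `p` (n x 2).
tps_eval <- function(reference, coefs, p, jacobian = FALSE) {
  ref <- as.matrix(reference)
  p <- as.matrix(p)
  k <- nrow(ref)
  dx <- outer(p[, 1L], ref[, 1L], "-")
  dy <- outer(p[, 2L], ref[, 2L], "-")
  r2 <- dx^2 + dy^2
  U <- r2 * log(r2 + (r2 == 0)) / 2      # r^2 log r
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[k + 1:3, , drop = FALSE]
  val <- cbind(1, p) %*% a + U %*% w
  if (!jacobian) return(val)
  fac <- log(r2 + (r2 == 0)) + 1         # dU/dx = (x-xi)(2 log r + 1)
  Ux <- dx * fac
  Uy <- dy * fac
  list(value = val,
       j11 = a[2L, 1L] + Ux %*% w[, 1L], j12 = a[3L, 1L] + Uy %*% w[, 1L],
       j21 = a[2L, 2L] + Ux %*% w[, 2L], j22 = a[3L, 2L] + Uy %*% w[, 2L])
}

#' Thin-plate-spline deformation grid
#'
#' Fits the TPS interpolant that maps the reference landmarks exactly onto
#' the target landmarks and evaluates it on a rectangular grid spanning the
#' reference bounding box with a proportional margin.
#'
#' @param reference,target k x 2 matrices (or [landmark_config()]s) in
#'   correspondence.
#' @param grid_resolution points per grid side (default 24).
#' @param margin bounding-box margin as a fraction of its span (default 0.1).
#' @return object of class `tps_warp`: reference, target, coefs, grid_x,
#'   grid_y (evaluation lattice), warped (n_grid x 2 deformed positions).
#' @export
tps_warp <- function(reference, target, grid_resolution = 24L, margin = 0.1) {
  ref <- if (inherits(reference, "landmark_config")) reference$points
         else as.matrix(reference)
  tgt <- if (inherits(target, "landmark_config")) target$points
         else as.matrix(target)
  coefs <- tps_coefficients(ref, tgt)
  rx <- range(ref[, 1L]); ry <- range(ref[, 2L])
  mx <- margin * max(diff(rx), .Machine$double.eps)
  my <- margin * max(diff(ry), .Machine$double.eps)
  gx <- seq(rx[1L] - mx, rx[2L] + mx, length.out = grid_resolution)
  gy <- seq(ry[1L] - my, ry[2L] + my, length.out = grid_resolution)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  structure(
    list(reference = ref, target = tgt, coefs = coefs,
         grid_x = gx, grid_y = gy, grid = grid,
         warped = tps_eval(ref, coefs, grid)),
    class = "tps_warp")
}

#' Predict deformed positions under a fitted TPS warp
#' @param object a `tps_warp`.
#' @param newdata n x 2 matrix of positions (defaults to the warp grid).
#' @param ... unused.
#' @return n x 2 matrix of deformed positions.
#' @export
predict.tps_warp <- function(object, newdata = object$grid, ...) {
  tps_eval(object$reference, object$coefs, as.matrix(newdata))
}

#' Log area-expansion field of a TPS warp
#'
#' Computes log |det J| of the thin-plate-spline map at every grid node
#' from the analytic derivatives of the kernel; 0 everywhere for the
#' identity warp, log(s^2) for a uniform scaling by s. Suitable for isoline
#' contouring as a deformation "heat map".
#'
#' @param warp a `tps_warp`.
#' @return matrix (grid_resolution x grid_resolution) of log-Jacobian
#'   values, x varying over rows.
#' @export
deformation_heatmap <- function(warp) {
  stopifnot(inherits(warp, "tps_warp"))
  ev <- tps_eval(warp$reference, warp$coefs, warp$grid, jacobian = TRUE)
  detj <- ev$j11 * ev$j22 - ev$j12 * ev$j21
  field <- log(pmax(abs(detj), .Machine$double.xmin))
  matrix(field, nrow = length(warp$grid_x),
         dimnames = list(NULL, NULL))
}

#' Per-group central-tendency shapes and score summaries
#'
#' For each group and each requested PC axis: the mean, median, and modal
#' score with the corresponding reconstructed shapes, plus nonparametric
#' bootstrap confidence intervals (percentile, 1,000 resamples by default)
#' on the mean and median.
#'
#' @param pca a `shape_pca`.
#' @param groups factor/character vector, one entry per specimen.
#' @param axes PC axes to summarize (default 1:2).
#' @param n_boot bootstrap resamples for the CIs.
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `stats` (data.frame: group, axis, n, mean, median,
#'   mode, mean_ci_low/high, median_ci_low/high) and `shapes` (nested list
#'   of k x 2 reconstructions by group, axis and kind).
#' @export
group_shape_summaries <- function(pca, groups, axes = 1:2, n_boot = 1000L,
                                  conf = 0.95, seed = 1L) {
  groups <- factor(groups)
  if (length(groups) != nrow(pca$scores))
    stop("groups length does not match number of specimens")
  if (any(table(groups) == 0L)) groups <- droplevels(groups)
  set.seed(seed)
  alpha <- (1 - conf) / 2
  rows <- list()
  shapes <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    shapes[[g]] <- list()
    for (j in axes) {
      x <- pca$scores[idx, j]
      n <- length(x)
      ci <- matrix(NA_real_, 2L, 2L)
      if (n >= 2L) {
        bm <- matrix(x[sample.int(n, n * n_boot, replace = TRUE)],
                     nrow = n_boot)
        means <- rowMeans(bm)
        meds <- apply(bm, 1L, stats::median)
        ci <- rbind(stats::quantile(means, c(alpha, 1 - alpha)),
                    stats::quantile(meds, c(alpha, 1 - alpha)))
      } else {
        warning("group '", g, "' has n < 2; CIs omitted")
      }
      mode_val <- if (n >= 10L) modal_shape(pca, j, scores = x)$location_value
                  else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, axis = j, n = n, mean = mean(x),
        median = stats::median(x), mode = mode_val,
        mean_ci_low = ci[1L, 1L], mean_ci_high = ci[1L, 2L],
        median_ci_low = ci[2L, 1L], median_ci_high = ci[2L, 2L])
      sc <- function(v) { s <- rep(0, j); s[j] <- v; s }
      shapes[[g]][[paste0("PC", j)]] <- list(
        mean = backtransform(pca, sc(mean(x))),
        median = backtransform(pca, sc(stats::median(x))),
        mode = if (is.na(mode_val)) NULL else backtransform(pca, sc(mode_val)))
    }
  }
  list(stats = do.call(rbind, rows), shapes = shapes)
}
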