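#' Procrustes linear model with residual-randomization inference
#'
#' Fits an ordinary least-squares linear model to multivariate shape data
#' (vectorized Procrustes coordinates or PC scores) with Type I
#' (sequential) sums of squares, and evaluates each term by the residual
#' randomization permutation procedure (RRPP): the residuals of the
#' reduced model preceding a term are randomized across specimens,
#' the term's F statistic is recomputed, and the p-value is the add-one
#' corrected proportion of permuted F values at or above the observed.
#' Effect sizes Z are the observed log-F standardized against the
#' permutation distribution of log-F.
#'
#' @param shapes N x p response matrix (`gpa_fit`, array, or matrix).
#' @param formula one-sided formula of grouping factors/covariates, e.g.
#'   `~ clade` or `~ tooth_position + bin`.
#' @param data data.frame holding the model variables, N rows.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return object of class `procrustes_anova` with `table` (term rows with
#'   df, SS, MS, Rsq, F, Z, p, plus Residuals and Total rows), n_perm, seed.
#' @export
procrustes_lm <- function(shapes, formula, data, n_perm = 999L, seed = 1L) {
  Y <- as_shape_matrix(shapes)
  n <- nrow(Y)
  if (nrow(data) != n) stop("data rows != number of specimens")
  tf <- stats::terms(formula)
  labels <- attr(tf, "term.labels")
  if (!length(labels)) stop("formula has no terms")
  # single-level factors contribute nothing; keep a 0-df row for them
  degenerate <- vapply(labels, function(lb) {
    vars <- all.vars(stats::reformulate(lb))
    any(vapply(vars, function(v) {
      x <- data[[v]]
      (is.factor(x) || is.character(x)) && length(unique(x)) < 2L
    }, logical(1)))
  }, logical(1))
  live <- labels[!degenerate]
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- sum(Yc^2)
  make_row <- function(term) data.frame(
    term = term, df = 0L, SS = 0, MS = NA_real_, Rsq = 0,
    F = NA_real_, Z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (!length(live)) {
    tab <- do.call(rbind, lapply(labels, make_row))
    tab <- rbind(tab,
                 data.frame(term = "Residuals", df = n - 1L, SS = ss_total,
                            MS = ss_total / (n - 1L), Rsq = NA_real_,
                            F = NA_real_, Z = NA_real_, p = NA_real_),
                 data.frame(term = "Total", df = n - 1L, SS = ss_total,
                            MS = NA_real_, Rsq = NA_real_, F = NA_real_,
                            Z = NA_real_, p = NA_real_))
    return(structure(list(table = tab, n_perm = n_perm, seed = seed),
                     class = "procrustes_anova"))
  }
  mm <- stats::model.matrix(stats::reformulate(live), data = data)
  qr_full <- qr(mm)
  if (qr_full$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_full$pivot[(qr_full$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (n <= qr_full$rank) stop("more model parameters than specimens")
  asgn <- attr(mm, "assign")
  # cumulative orthonormal bases Q_0 (intercept) .. Q_T (full model)
  n_terms <- length(live)
  Qs <- vector("list", n_terms + 1L)
  ranks <- integer(n_terms + 1L)
  for (i in 0:n_terms) {
    cols <- which(asgn <= i)
    qri <- qr(mm[, cols, drop = FALSE])
    Qs[[i + 1L]] <- qr.Q(qri)[, seq_len(qri$rank), drop = FALSE]
    ranks[i + 1L] <- qri$rank
  }
  fit_ss <- vapply(Qs, function(Q) sum(crossprod(Q, Y)^2), numeric(1))
  ss_term <- diff(fit_ss)
  df_term <- diff(ranks)
  df_res <- n - ranks[n_terms + 1L]
  ss_res <- sum(Y^2) - fit_ss[n_terms + 1L]
  ms_res <- ss_res / df_res
  f_obs <- (ss_term / df_term) / ms_res
  # RRPP: permute reduced-model residuals, shared permutations per term
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  p_val <- z_val <- numeric(n_terms)
  Qf <- Qs[[n_terms + 1L]]
  for (i in seq_len(n_terms)) {
    Qr <- Qs[[i]]
    Qi <- Qs[[i + 1L]]
    fitted_r <- Qr %*% crossprod(Qr, Y)
    resid_r <- Y - fitted_r
    f_perm <- vapply(seq_len(n_perm), function(b) {
      Yp <- fitted_r + resid_r[perms[, b], , drop = FALSE]
      ssb <- sum(crossprod(Qi, Yp)^2) - sum(crossprod(Qr, Yp)^2)
      rss <- sum(Yp^2) - sum(crossprod(Qf, Yp)^2)
      (ssb / df_term[i]) / (rss / df_res)
    }, numeric(1))
    null_f <- c(f_obs[i], f_perm)
    p_val[i] <- mean(null_f >= f_obs[i] - 1e-12)
    lf <- log(pmax(null_f, .Machine$double.xmin))
    z_val[i] <- (lf[1L] - mean(lf)) / stats::sd(lf)
  }
  live_rows <- data.frame(term = live, df = df_term, SS = ss_term,
                          MS = ss_term / df_term, Rsq = ss_term / ss_total,
                          F = f_obs, Z = z_val, p = p_val,
                          stringsAsFactors = FALSE)
  rows <- lapply(labels, function(lb)
    if (lb %in% live) live_rows[live_rows$term == lb, ] else make_row(lb))
  tab <- rbind(do.call(rbind, rows),
               data.frame(term = "Residuals", df = df_res, SS = ss_res,
                          MS = ms_res, Rsq = NA_real_, F = NA_real_,
                          Z = NA_real_, p = NA_real_),
               data.frame(term = "Total", df = n - 1L, SS = ss_total,
                          MS = NA_real_, Rsq = NA_real_, F = NA_real_,
                          Z = NA_real_, p = NA_real_))
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("<procrustes_anova> RRPP with %d permutations (seed %d)\n",
              x$n_perm, x$seed))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Permutation tests of pairwise group mean-shape differences
#'
#' Euclidean distances between group mean vectors, tested by full
#' randomization of specimens across group labels (residuals from the
#' grand mean), with Benjamini-Hochberg adjustment across pairs.
#'
#' @param x shapes or scores (N x p).
#' @param groups factor/character group labels; groups with n < 2 are
#'   excluded with a warning.
#' @param axes optional column subset (e.g. `1:4` for PC1-PC4).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: group_1, group_2, distance, p_raw, p_fdr.
#' @export
pairwise_mean_tests <- function(x, groups, axes = NULL, n_perm = 999L,
                                seed = 1L) {
  X <- as_shape_matrix(x)
  if (!is.null(axes)) X <- X[, axes, drop = FALSE]
  groups <- factor(groups)
  small <- names(which(table(groups) < 2L))
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    X <- X[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups with n >= 2")
  g <- as.integer(groups)
  ns <- tabulate(g, nlevels(groups))
  n <- nrow(X)
  gm <- rowsum(X, g, reorder = TRUE) / ns
  obs <- as.vector(stats::dist(gm))
  set.seed(seed)
  lab <- vapply(seq_len(n_perm), function(b) g[sample.int(n)], integer(n))
  prs <- utils::combn(nlevels(groups), 2L)
  means <- lapply(seq_len(nlevels(groups)), function(lv)
    crossprod(X, (lab == lv) * 1) / ns[lv])        # p x n_perm per group
  count <- integer(length(obs))
  for (pp in seq_len(ncol(prs))) {
    d_perm <- sqrt(colSums((means[[prs[1L, pp]]] -
                              means[[prs[2L, pp]]])^2))
    count[pp] <- sum(d_perm >= obs[pp] - 1e-15)
  }
  p_raw <- (1 + count) / (1 + n_perm)
  data.frame(group_1 = levels(groups)[prs[1L, ]],
             group_2 = levels(groups)[prs[2L, ]],
             distance = obs, p_raw = p_raw, p_fdr = fdr_adjust(p_raw))
}

# ---- Hartigan dip statistic ------------------------------------------------

# Lower convex hull ("greatest convex minorant") touch indices of the
# points (x_i, y_i), x nondecreasing. Collinear points are dropped.
lower_hull_idx <- function(x, y) {
  h <- integer(0)
  for (i in seq_along(x)) {
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]; b <- h[length(h)]
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

upper_hull_idx <- function(x, y) {
  h <- integer(0)
  for (i in seq_along(x)) {
    while (length(h) >= 2L) {
      a <- h[length(h) - 1L]; b <- h[length(h)]
      if ((y[b] - y[a]) * (x[i] - x[a]) <= (y[i] - y[a]) * (x[b] - x[a]))
        h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

# Piecewise-linear hull curve through (x[touch], y[touch]) evaluated at
# the points x[at]; vertical runs (tied x) take the touchpoint value.
hull_curve_at <- function(x, y, touch, at) {
  vapply(at, function(i) {
    j <- findInterval(i, touch)                 # touches are indices
    if (j == 0L) return(y[touch[1L]])
    if (j >= length(touch)) return(y[touch[length(touch)]])
    a <- touch[j]; b <- touch[j + 1L]
    dx <- x[b] - x[a]
    if (dx <= 0) return(y[a])
    y[a] + (y[b] - y[a]) * (x[i] - x[a]) / dx
  }, numeric(1))
}

#' Hartigan dip statistic for unimodality
#'
#' The dip is the smallest attainable supremum distance between the
#' empirical distribution function and any unimodal (convex-then-concave)
#' distribution function. Computed by iteratively narrowing a candidate
#' modal interval: the greatest convex minorant of the lower step corners
#' and the least concave majorant of the upper step corners are fitted on
#' the current interval, their maximal separation located, and the
#' deviation of the empirical cdf from the hulls on the discarded flanks
#' accumulated; the dip is half the final maximal gap. Exact closed-form
#' cases (two points: 1/4; n equally spaced points: 1/(2n)) are preserved.
#'
#' @param x numeric sample (n >= 2).
#' @return the dip statistic, in [1/(2n), 1/4].
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2L) stop("dip needs at least 2 observations")
  lo <- (seq_len(n) - 1) / n      # F just left of each point
  hi <- seq_len(n) / n            # F at each point
  low <- 1L; high <- n
  gap <- 1 / n
  for (it in seq_len(n)) {
    idx <- low:high
    gt <- idx[lower_hull_idx(x[idx], lo[idx])]   # gcm touches
    lt <- idx[upper_hull_idx(x[idx], hi[idx])]   # lcm touches
    d_g <- hull_curve_at(x, hi, lt, gt) - lo[gt] # lcm curve over gcm touches
    d_l <- hi[lt] - hull_curve_at(x, lo, gt, lt) # gcm curve under lcm touches
    d <- max(d_g, d_l)
    if (d <= gap + 1e-15) break
    if (max(d_g) >= max(d_l)) {
      ig <- gt[which.max(d_g)]
      cand <- lt[lt > ig]
      ih <- if (length(cand)) min(cand) else high
    } else {
      ih <- lt[which.max(d_l)]
      cand <- gt[gt < ih]
      ig <- if (length(cand)) max(cand) else low
    }
    if (ig <= low && ih >= high) break
    if (ig > low) {
      fl <- low:ig
      gap <- max(gap, max(hi[fl] - hull_curve_at(x, lo, gt, fl)))
    }
    if (ih < high) {
      fr <- ih:high
      gap <- max(gap, max(hull_curve_at(x, hi, lt, fr) - lo[fr]))
    }
    low <- ig; high <- ih
  }
  gap / 2
}

#' Monte-Carlo dip test of unimodality
#'
#' The null distribution of the dip is simulated from uniform samples of
#' the same size (the least favourable unimodal case); the p-value uses
#' the add-one correction.
#'
#' @param x numeric sample, n >= 8 recommended.
#' @param n_mc null Monte-Carlo draws (default 10000).
#' @param seed integer seed.
#' @return list(statistic, p_value, n_mc).
#' @export
dip_test <- function(x, n_mc = 10000L, seed = 1L) {
  n <- length(x)
  stat <- dip_statistic(x)
  set.seed(seed)
  null <- vapply(seq_len(n_mc), function(b) dip_statistic(stats::runif(n)),
                 numeric(1))
  list(statistic = stat,
       p_value = (1 + sum(null >= stat - 1e-15)) / (1 + n_mc),
       n_mc = n_mc)
}

# ---- Henze-Zirkler ---------------------------------------------------------

#' Henze-Zirkler test of multivariate normality
#'
#' Computes the HZ statistic from scaled pairwise Mahalanobis distances
#' (ML covariance) with the standard smoothing parameter
#' \eqn{\beta = ((n(2p+1))/4)^{1/(p+4)} / \sqrt 2} and a p-value from the
#' usual lognormal approximation to the null distribution. The covariance
#' must be non-singular: for rank-deficient shape data, test a PC-score
#' subset instead.
#'
#' @param X numeric n x p matrix, n > p.
#' @return list(statistic, p_value, beta, n, p).
#' @export
hz_test <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("HZ needs n > p; reduce to a PC-score subset")
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < max(ev$values) * 1e-10)
    stop("singular covariance; test a PC-score subset instead")
  W <- Xc %*% (ev$vectors %*% (t(ev$vectors) / sqrt(ev$values)))
  Dij <- as.matrix(stats::dist(W))^2
  Di <- rowSums(W^2)
  b2 <- (((2 * p + 1) * n / 4)^(2 / (p + 4))) / 2      # beta^2
  a <- 1 + 2 * b2
  hz <- n * (mean(exp(-b2 / 2 * Dij)) -
             2 * (1 + b2)^(-p / 2) * mean(exp(-b2 / (2 * (1 + b2)) * Di)) +
             (1 + 2 * b2)^(-p / 2))
  wb <- (1 + b2) * (1 + 3 * b2)
  mu <- 1 - a^(-p / 2) * (1 + p * b2 / a + p * (p + 2) * b2^2 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b2^2 / a^2 + 3 * p * (p + 2) * b2^4 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b2^2 / (2 * wb) +
                         p * (p + 2) * b2^4 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  list(statistic = hz,
       p_value = stats::plnorm(hz, pmu, psi, lower.tail = FALSE),
       beta = sqrt(b2), n = n, p = p)
}

# ---- descriptive summaries -------------------------------------------------

# third standardized moment (no small-sample correction)
skewness_g1 <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= .Machine$double.eps) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

# raw Pearson kurtosis (normal = 3)
kurtosis_raw <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= .Machine$double.eps) return(NA_real_)
  mean((x - m)^4) / s2^2
}

#' Per-group distribution diagnostics of ordination scores
#'
#' For each group and score axis: mean, median, KDE mode, skewness g1
#' (third standardized moment), raw kurtosis (normal = 3, values below 3
#' platykurtic), IQR, and the Hartigan dip statistic with its Monte-Carlo
#' uniform-null p-value. Moments need n >= 4 and the dip n >= 8; smaller
#' groups are flagged with NA. A Henze-Zirkler test of joint multivariate
#' normality over all supplied axes (whole dataset) is attached as
#' `attr(, "hz")`.
#'
#' @param scores N x q score matrix (or vector).
#' @param groups factor/character of group labels.
#' @param axes columns to summarize (default all).
#' @param dip_n_mc Monte-Carlo draws for the dip p-value (default 10000).
#' @param seed integer seed.
#' @return data.frame: group, axis, n, mean, median, mode, skew_g1,
#'   kurtosis, iqr, dip, dip_p.
#' @export
distribution_summary <- function(scores, groups, axes = NULL,
                                 dip_n_mc = 10000L, seed = 1L) {
  X <- as.matrix(scores)
  if (is.null(axes)) axes <- seq_len(ncol(X))
  groups <- droplevels(factor(groups))
  rows <- list()
  for (g in levels(groups)) {
    for (j in axes) {
      x <- X[groups == g, j]
      n <- length(x)
      mode_val <- if (n >= 10L && stats::sd(x) > .Machine$double.eps) {
        margin <- 0.05 * diff(range(x))
        d <- stats::density(x, bw = "nrd0", n = 512L,
                            from = min(x) - margin, to = max(x) + margin)
        d$x[which.max(d$y)]
      } else NA_real_
      dip <- dip_p <- NA_real_
      if (n >= 8L) {
        dt <- dip_test(x, n_mc = dip_n_mc, seed = seed)
        dip <- dt$statistic; dip_p <- dt$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, axis = j, n = n, mean = mean(x),
        median = stats::median(x), mode = mode_val,
        skew_g1 = if (n >= 4L) skewness_g1(x) else NA_real_,
        kurtosis = if (n >= 4L) kurtosis_raw(x) else NA_real_,
        iqr = stats::IQR(x), dip = dip, dip_p = dip_p)
    }
  }
  out <- do.call(rbind, rows)
  hz <- tryCatch(hz_test(X[, axes, drop = FALSE]), error = function(e) {
    warning("HZ test not computed: ", conditionMessage(e))
    NULL
  })
  attr(out, "hz") <- hz
  out
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-block covariance of two
#' centred blocks; r-PLS is the Pearson correlation of the first pair of
#' singular scores, with a permutation p-value from row shuffling of the
#' second block and a standardized effect size Z.
#'
#' @param block_x,block_y N x p / N x q matrices, equal N >= 3.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return object of class `pls_result`: r_pls, Z, p_value, n_perm,
#'   singular_values, scores_x, scores_y.
#' @export
two_block_pls <- function(block_x, block_y, n_perm = 999L, seed = 1L) {
  X <- as_shape_matrix(block_x)
  Y <- as_shape_matrix(block_y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks differ in row count")
  if (n < 3L) stop("2B-PLS needs N >= 3")
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  first_pair <- function(Yp) {
    s <- svd(crossprod(Xc, Yp) / (n - 1L), nu = 1L, nv = 1L)
    as.vector(stats::cor(Xc %*% s$u[, 1L], Yp %*% s$v[, 1L]))
  }
  s <- svd(crossprod(Xc, Yc) / (n - 1L))
  r_obs <- as.vector(stats::cor(Xc %*% s$u[, 1L], Yc %*% s$v[, 1L]))
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b)
    abs(first_pair(Yc[sample.int(n), , drop = FALSE])), numeric(1))
  null_r <- c(abs(r_obs), r_perm)
  structure(
    list(r_pls = as.vector(abs(r_obs)),
         Z = (abs(r_obs) - mean(null_r)) / stats::sd(null_r),
         p_value = mean(null_r >= abs(r_obs) - 1e-15),
         n_perm = n_perm, singular_values = s$d,
         scores_x = Xc %*% s$u[, 1L], scores_y = Yc %*% s$v[, 1L]),
    class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> r-PLS = %.4f, Z = %.3f, p = %.4g (%d perms)\n",
              x$r_pls, x$Z, x$p_value, x$n_perm))
  invisible(x)
}

#' Digitization measurement error from replicated landmark sets
#'
#' Aligns all digitization replicates together, then partitions coordinate
#' variance by one-way ANOVA over specimens: s2_within = MS_within,
#' s2_among = (MS_among - MS_within) / n0 with n0 the (mean) replicate
#' count. The error percentage is 100 * s2_within / (s2_within + s2_among);
#' repeatability (the intraclass correlation) is its complement.
#'
#' @param configs all replicate configurations (list, array, or `gpa_fit`
#'   of already-aligned data).
#' @param specimen factor identifying which specimen each replicate
#'   belongs to; every specimen needs >= 2 replicates.
#' @return object of class `measurement_error_report`: icc_percent
#'   (repeatability), error_percent, ms_among, ms_within, n_specimens,
#'   n_replicates (mean).
#' @export
measurement_error <- function(configs, specimen) {
  fit <- if (inherits(configs, "gpa_fit")) configs else gpa(configs)
  X <- as_shape_matrix(fit)
  specimen <- droplevels(factor(specimen))
  a <- nlevels(specimen)
  ni <- as.integer(table(specimen))
  if (any(ni < 2L)) stop("every specimen needs >= 2 digitization replicates")
  n <- nrow(X)
  g <- as.integer(specimen)
  gm <- rowsum(X, g, reorder = TRUE) / ni
  grand <- colMeans(X)
  ss_among <- sum(ni * rowSums(sweep(gm, 2L, grand)^2))
  ss_within <- sum((X - gm[g, , drop = FALSE])^2)
  ms_among <- ss_among / (a - 1L)
  ms_within <- ss_within / (n - a)
  n0 <- (n - sum(ni^2) / n) / (a - 1L)   # balanced: the replicate count
  s2_within <- ms_within
  s2_among <- max((ms_among - ms_within) / n0, 0)
  err <- if (s2_within + s2_among <= 0) 0 else
    100 * s2_within / (s2_within + s2_among)
  structure(list(icc_percent = 100 - err, error_percent = err,
                 ms_among = ms_among, ms_within = ms_within,
                 n_specimens = a, n_replicates = mean(ni)),
            class = "measurement_error_report")
}

#' @export
print.measurement_error_report <- function(x, ...) {
  cat(sprintf(paste0("<measurement_error_report> %d specimens x %.3g ",
                     "replicates: error = %.3g%%, repeatability = %.3g%%\n"),
              x$n_specimens, x$n_replicates, x$error_percent, x$icc_percent))
  invisible(x)
}

#' Rank specimens by Procrustes distance to the consensus
#'
#' Flags specimens whose distance to the consensus exceeds
#' Q3 + 1.5 IQR of the distance distribution (the usual box-plot fence),
#' for morphospace outlier screening.
#'
#' @param fit a `gpa_fit`.
#' @return data.frame sorted by decreasing distance: specimen, distance,
#'   outlier (logical); the fence is in `attr(, "threshold")`.
#' @export
find_outliers <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  d <- sqrt(apply(fit$aligned, 3L, function(a) sum((a - fit$consensus)^2)))
  ids <- dimnames(fit$aligned)[[3L]]
  if (is.null(ids)) ids <- sprintf("specimen_%d", seq_along(d))
  thr <- stats::quantile(d, 0.75) + 1.5 * stats::IQR(d)
  out <- data.frame(specimen = ids, distance = d,
                    outlier = d > thr)[order(-d), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- unname(thr)
  out
}
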