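# Coerce shapes to an N x p matrix of vectorized aligned coordinates.
as_shape_matrix <- function(x) {
  if (inherits(x, "gpa_fit")) {
    n <- dim(x$aligned)[3L]
    X <- t(apply(x$aligned, 3L, as.vector))
    if (n == 1L) X <- matrix(as.vector(x$aligned[, , 1L]), nrow = 1L)
    rownames(X) <- dimnames(x$aligned)[[3L]]
    return(X)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    n <- dim(x)[3L]
    if (n == 0L) return(matrix(numeric(0), 0L, prod(dim(x)[1:2])))
    X <- t(apply(x, 3L, as.vector))
    if (n == 1L) X <- matrix(as.vector(x[, , 1L]), nrow = 1L)
    rownames(X) <- dimnames(x)[[3L]]
    return(X)
  }
  as.matrix(x)
}

#' Per-specimen sum of squared deviations from a reference shape
#'
#' For specimen n with coordinates \eqn{(x_k, y_k)} and reference
#' \eqn{(\bar x_k, \bar y_k)}:
#' \eqn{SSW_n = \sum_k (x_k - \bar x_k)^2 + (y_k - \bar y_k)^2}.
#' The reference may be the grand mean or a group mean.
#'
#' @param x aligned shapes: `gpa_fit`, k x 2 x N array, or N x p matrix.
#' @param reference reference shape: k x 2 matrix or length-p vector;
#'   defaults to the column mean of `x`.
#' @return numeric vector of length N.
#' @export
ssw <- function(x, reference = NULL) {
  X <- as_shape_matrix(x)
  ref <- if (is.null(reference)) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X))
    stop("reference dimension ", length(ref), " != shape dimension ", ncol(X))
  rowSums(sweep(X, 2L, ref)^2)
}

#' Procrustes variance of a group of aligned shapes
#'
#' The disparity metric: the summed squared deviations of every specimen
#' from the group mean shape, divided by the group sample size
#' (\eqn{PV_t = \sum_n SSW_n / N_t}).
#'
#' @param x aligned shapes (see [ssw()]).
#' @param group label for the estimate.
#' @param denominator "n" (the printed definition, default) or "n_minus_1"
#'   (the unbiased variant used by the additive partial-disparity
#'   decomposition).
#' @return object of class `disparity_estimate`: list(group, n, pv,
#'   denominator).
#' @export
procrustes_variance <- function(x, group = "all",
                                denominator = c("n", "n_minus_1")) {
  denominator <- match.arg(denominator)
  X <- as_shape_matrix(x)
  n <- nrow(X)
  if (n < 1L) stop("empty group")
  den <- if (denominator == "n") n else n - 1L
  if (den < 1L) stop("n_minus_1 denominator needs n >= 2")
  structure(list(group = group, n = n, pv = sum(ssw(X)) / den,
                 denominator = denominator),
            class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  cat(sprintf("<disparity_estimate> %s: PV = %.6g (n = %d%s)\n", x$group,
              x$pv, x$n,
              if (!is.null(x$ci_low))
                sprintf(", 95%% CI [%.6g, %.6g], %d bootstraps",
                        x$ci_low, x$ci_high, x$n_boot) else ""))
  invisible(x)
}

# Fast grouped PV (denominator n) from a shape matrix; groups is a factor
# with no empty levels. Uses PV_g = mean ||x||^2 - ||mean x||^2 per group.
group_pv <- function(X, groups) {
  g <- as.integer(groups)
  ns <- tabulate(g, nbins = nlevels(groups))
  gm <- rowsum(X, g, reorder = TRUE) / ns
  tot <- rowsum(rowSums(X^2), g, reorder = TRUE)
  as.vector(tot) / ns - rowSums(gm^2)
}

#' Partial disparity of subgroups within a time bin
#'
#' Decomposes a bin's disparity into per-group contributions. Under the
#' default `grand_mean` convention (Foote-style) each specimen's squared
#' deviation is measured from the bin grand mean and
#' \eqn{PV_{i|t} = \sum_{n \in i} SSW_n / (N - 1)}, so the group partials
#' sum exactly to the total (1/(N-1)-normalized) bin disparity. The
#' `group_mean` convention measures deviations from each group's own mean
#' with the same \eqn{n_i/(N-1)} weighting; it is generally not additive,
#' and the residual discrepancy is reported.
#'
#' @param x aligned shapes for one bin.
#' @param groups factor/character vector of group labels (clade, basin).
#' @param convention "grand_mean" (default) or "group_mean".
#' @return object of class `partial_disparity_table` with fields rows
#'   (data.frame: group, n, pv_partial), convention, total_pv (1/(N-1)
#'   total), additivity_gap.
#' @export
partial_disparity <- function(x, groups,
                              convention = c("grand_mean", "group_mean")) {
  convention <- match.arg(convention)
  X <- as_shape_matrix(x)
  groups <- factor(groups)
  if (length(groups) != nrow(X))
    stop("groups length does not match number of specimens")
  n <- nrow(X)
  if (n < 2L) stop("partial disparity needs N >= 2")
  total_pv <- sum(ssw(X)) / (n - 1L)
  dev <- if (convention == "grand_mean") {
    ssw(X)                         # deviations from the bin grand mean
  } else {
    gm <- rowsum(X, groups) / tabulate(groups, nlevels(groups))
    rowSums((X - gm[as.integer(groups), , drop = FALSE])^2)
  }
  pv_i <- as.vector(rowsum(dev, groups)) / (n - 1L)
  rows <- data.frame(group = levels(groups),
                     n = as.integer(table(groups)),
                     pv_partial = pv_i)
  structure(list(rows = rows, convention = convention, total_pv = total_pv,
                 additivity_gap = sum(pv_i) - total_pv),
            class = "partial_disparity_table")
}

#' @export
print.partial_disparity_table <- function(x, ...) {
  cat(sprintf("<partial_disparity_table> (%s convention), total PV = %.6g\n",
              x$convention, x$total_pv))
  print(x$rows, row.names = FALSE)
  if (abs(x$additivity_gap) > 1e-9)
    cat(sprintf("  non-additive: partials sum - total = %.3g\n",
                x$additivity_gap))
  invisible(x)
}

#' Permutation test of pairwise Procrustes-variance differences
#'
#' Tests, for every pair of groups, the null that the absolute difference
#' of their Procrustes variances is zero. The null distribution randomizes
#' specimens' residual vectors (deviations from the grand mean shape)
#' across group labels; p-values use the add-one correction
#' \eqn{p = (1 + \#\{|\Delta PV^*| \ge |\Delta PV|\}) / (1 + n_{perm})}
#' and are adjusted across pairs by the Benjamini-Hochberg FDR step-up.
#'
#' @param x aligned shapes.
#' @param groups factor/character of group (time-bin) labels, >= 2 levels,
#'   each with n >= 2.
#' @param n_perm permutations (default 1000, minimum 10).
#' @param seed integer seed.
#' @return object of class `pv_test`: data.frame `pairs` (group_1, group_2,
#'   pv_1, pv_2, observed_abs_diff, p_raw, p_fdr), plus pv (named observed
#'   PVs), n_perm, seed.
#' @export
pv_permutation_test <- function(x, groups, n_perm = 1000L, seed = 1L) {
  if (n_perm < 10L) stop("n_perm must be at least 10")
  X <- as_shape_matrix(x)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  R <- sweep(X, 2L, colMeans(X))       # grand-mean residual vectors
  obs_pv <- group_pv(R, groups)        # PV is translation-invariant
  names(obs_pv) <- levels(groups)
  prs <- utils::combn(nlevels(groups), 2L)
  obs_diff <- abs(obs_pv[prs[1L, ]] - obs_pv[prs[2L, ]])
  set.seed(seed)
  n <- nrow(R)
  g <- as.integer(groups)
  ns <- tabulate(g, nlevels(groups))
  # all permuted label columns at once; PV per group via indicator algebra:
  # PV_g = mean_i ||r_i||^2 - ||mean_i r_i||^2 over i assigned to g
  lab <- vapply(seq_len(n_perm), function(b) g[sample.int(n)], integer(n))
  s_i <- rowSums(R^2)
  pv_perm <- vapply(seq_len(nlevels(groups)), function(lv) {
    M <- (lab == lv) * 1
    means2 <- colSums((crossprod(R, M) / ns[lv])^2)
    as.vector(crossprod(s_i, M)) / ns[lv] - means2
  }, numeric(n_perm))                  # n_perm x G
  diff_perm <- abs(pv_perm[, prs[1L, ], drop = FALSE] -
                     pv_perm[, prs[2L, ], drop = FALSE])
  count <- colSums(sweep(diff_perm, 2L, obs_diff - 1e-15, ">="))
  p_raw <- (1 + count) / (1 + n_perm)
  pairs <- data.frame(group_1 = levels(groups)[prs[1L, ]],
                      group_2 = levels(groups)[prs[2L, ]],
                      pv_1 = obs_pv[prs[1L, ]], pv_2 = obs_pv[prs[2L, ]],
                      observed_abs_diff = unname(obs_diff),
                      p_raw = p_raw, p_fdr = fdr_adjust(p_raw),
                      row.names = NULL)
  structure(list(pairs = pairs, pv = obs_pv, n_perm = n_perm, seed = seed),
            class = "pv_test")
}

#' @export
print.pv_test <- function(x, ...) {
  cat(sprintf("<pv_test> %d pair(s), %d permutations (seed %d)\n",
              nrow(x$pairs), x$n_perm, x$seed))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bootstrap confidence interval for Procrustes variance
#'
#' Resamples specimens with replacement, recomputing the group's PV (about
#' the resampled mean) each time; percentile 2.5/97.5 bounds by default.
#'
#' @param x aligned shapes of one group.
#' @param group label.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return a `disparity_estimate` with ci_low, ci_high, n_boot added.
#' @export
bootstrap_pv <- function(x, group = "all", n_boot = 1000L, conf = 0.95,
                         seed = 1L) {
  X <- as_shape_matrix(x)
  n <- nrow(X)
  if (n < 2L) stop("bootstrap needs n >= 2")
  est <- procrustes_variance(X, group = group)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    Xi <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
    sum(ssw(Xi)) / n
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  est$ci_low <- ci[1L]
  est$ci_high <- ci[2L]
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Rarefy Procrustes variance to a common sample size
#'
#' For each bin, repeatedly subsamples `target_n` specimens without
#' replacement (999 iterations by default), recomputes the PV, and reports
#' the rarefied mean with a 95% percentile prediction interval. At
#' `target_n` equal to the bin size every iteration reproduces the
#' observed PV exactly.
#'
#' @param x aligned shapes.
#' @param bins factor/character of bin labels.
#' @param target_n common subsample size, 2 <= target_n <= min bin size
#'   (defaults to the minimum bin size).
#' @param n_iter iterations (default 999).
#' @param conf prediction-interval level.
#' @param seed integer seed.
#' @return object of class `rarefaction_result`: data.frame `table` (bin,
#'   n, observed_pv, target_n, mean_rarefied_pv, pi_low, pi_high),
#'   n_iter, seed.
#' @export
rarefy_pv <- function(x, bins, target_n = NULL, n_iter = 999L, conf = 0.95,
                      seed = 1L) {
  X <- as_shape_matrix(x)
  bins <- droplevels(factor(bins))
  sizes <- table(bins)
  if (is.null(target_n)) target_n <- min(sizes)
  if (target_n < 2L) stop("target_n must be at least 2")
  if (target_n > min(sizes))
    stop("target_n (", target_n, ") exceeds smallest bin size (",
         min(sizes), ")")
  set.seed(seed)
  alpha <- (1 - conf) / 2
  rows <- lapply(levels(bins), function(b) {
    Xi <- X[bins == b, , drop = FALSE]
    pvs <- vapply(seq_len(n_iter), function(it) {
      Xs <- Xi[sample.int(nrow(Xi), target_n), , drop = FALSE]
      sum(ssw(Xs)) / target_n
    }, numeric(1))
    pi <- unname(stats::quantile(pvs, c(alpha, 1 - alpha)))
    data.frame(bin = b, n = nrow(Xi),
               observed_pv = sum(ssw(Xi)) / nrow(Xi),
               target_n = target_n, mean_rarefied_pv = mean(pvs),
               pi_low = pi[1L], pi_high = pi[2L])
  })
  structure(list(table = do.call(rbind, rows), n_iter = n_iter, seed = seed),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("<rarefaction_result> target_n = %d, %d iterations\n",
              x$table$target_n[1L], x$n_iter))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
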