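#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the size measure removed during superimposition.
#'
#' @param x a [landmark_config()] or a k x 2 coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(x) {
  pts <- if (inherits(x, "landmark_config")) x$points else as.matrix(x)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  cs <- sqrt(sum(scale(pts, scale = FALSE)^2))
  if (cs <= .Machine$double.eps)
    stop("degenerate configuration: all points identical")
  cs
}

# Center at origin and scale to unit centroid size.
center_scale <- function(pts) {
  pts <- sweep(pts, 2L, colMeans(pts))
  pts / sqrt(sum(pts^2))
}

# Optimal proper rotation of centered `moving` onto centered `target`
# (Kabsch with reflection disallowed).
optimal_rotation <- function(moving, target) {
  s <- svd(crossprod(target, moving))
  d <- sign(det(s$u %*% t(s$v)))
  s$v %*% diag(c(1, d)) %*% t(s$u)
}

#' Superimpose one configuration onto another
#'
#' Translates the moving configuration to the origin, scales it to unit
#' centroid size, and applies the optimal proper rotation onto the
#' (likewise centred and unit-scaled) target. Reflections are never used:
#' left/right identity is handled upstream by [normalize_orientation()].
#'
#' @param moving,target k x 2 matrices or [landmark_config()] objects with
#'   equal k.
#' @return list(aligned, distance): the aligned moving coordinates and the
#'   root summed squared difference to the normalized target (partial
#'   Procrustes distance).
#' @export
superimpose_pair <- function(moving, target) {
  m <- if (inherits(moving, "landmark_config")) moving$points
       else as.matrix(moving)
  t_ <- if (inherits(target, "landmark_config")) target$points
        else as.matrix(target)
  if (!identical(dim(m), dim(t_)))
    stop("configurations differ in dimension: ",
         paste(dim(m), collapse = "x"), " vs ", paste(dim(t_), collapse = "x"))
  centroid_size(m); centroid_size(t_)  # degenerate input errors here
  m <- center_scale(m)
  t_ <- center_scale(t_)
  rot <- optimal_rotation(m, t_)
  aligned <- m %*% rot
  list(aligned = aligned, distance = sqrt(sum((aligned - t_)^2)))
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all configurations onto an evolving consensus
#' (the normalized arithmetic mean of the aligned set) until the Procrustes
#' sum of squares Q -- the summed squared distances of aligned specimens to
#' the consensus -- changes by less than `tol`, or `max_iter` is reached.
#' Partial Procrustes: specimens are fixed at unit centroid size and only
#' rotated during the fit.
#'
#' @param x k x 2 x N array or list of [landmark_config()] objects (N >= 2).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the change in Q (default 1e-10).
#' @return object of class `gpa_fit`: list(aligned = k x 2 x N array,
#'   consensus = k x 2 matrix, centroid_sizes, q_history, iterations,
#'   converged).
#' @export
gpa <- function(x, max_iter = 100L, tol = 1e-10) {
  arr <- if (is.array(x) && length(dim(x)) == 3L) x else configs_to_array(x)
  n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  sizes <- apply(arr, 3L, centroid_size)
  aligned <- arr
  for (i in seq_len(n)) aligned[, , i] <- center_scale(arr[, , i])
  consensus <- aligned[, , 1L]
  q_history <- numeric(0)
  q_prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*%
        optimal_rotation(aligned[, , i], consensus)
    consensus <- center_scale(apply(aligned, c(1L, 2L), mean))
    q <- sum(apply(aligned, 3L, function(a) sum((a - consensus)^2)))
    q_history <- c(q_history, q)
    if (is.finite(q_prev) && abs(q_prev - q) < tol) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  can <- canonical_rotation(consensus)
  consensus <- consensus %*% can
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% can
  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = sizes,
         q_history = q_history, iterations = iter, converged = converged),
    class = "gpa_fit")
}

# Rotation taking a centred configuration to a canonical orientation:
# principal axes on the coordinate axes, with the 180-degree ambiguity
# resolved by making the third moment of the x (then y) coordinates
# non-negative. Removes the rotational gauge freedom of GPA so that a
# global similarity transform of all inputs leaves the output unchanged.
canonical_rotation <- function(consensus) {
  V <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 2L] <- -V[, 2L]
  rot <- consensus %*% V
  s <- sum(rot[, 1L]^3)
  if (abs(s) < 1e-12) s <- sum(rot[, 2L]^3)
  if (s < 0) V <- -V                      # rotate by pi, still det +1
  V
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf(paste0("<gpa_fit> %d specimens, %d landmarks; Q = %.6g ",
                     "after %d iteration(s)%s%s\n"),
              d[3L], d[1L], utils::tail(x$q_history, 1L), x$iterations,
              if (x$converged) " (converged)" else " (NOT converged)",
              if (is.null(x$slid) || !x$slid) "" else "; semilandmarks slid"))
  invisible(x)
}

#' Thin-plate-spline bending energy of a reference configuration
#'
#' Builds the k x k bending-energy quadratic form of the 2D thin-plate
#' spline anchored at the reference landmarks (radial kernel
#' \eqn{U(r) = r^2 \log r}, affine part annihilated). The bending energy of
#' a displacement field given per-coordinate as vectors dx, dy is
#' \eqn{dx' B dx + dy' B dy}.
#'
#' @param reference k x 2 matrix or [landmark_config()]; points must not be
#'   all collinear or coincident.
#' @return object of class `bending_energy_model`: list(reference,
#'   energy_matrix).
#' @export
bending_energy <- function(reference) {
  ref <- if (inherits(reference, "landmark_config")) reference$points
         else as.matrix(reference)
  k <- nrow(ref)
  d <- as.matrix(stats::dist(ref))
  if (any(d[upper.tri(d)] < 1e-12))
    stop("coincident reference points make the TPS kernel singular; ",
         "jitter the duplicates or drop one of each pair")
  K <- d^2 * log(d + (d == 0))  # U(0) = 0 by continuity
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system (collinear reference?): ", conditionMessage(e)))
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(reference = ref, energy_matrix = B),
            class = "bending_energy_model")
}

# Bending energy of the displacement field taking `ref_model$reference`
# onto `target` (k x 2).
displacement_energy <- function(ref_model, target) {
  dxy <- as.matrix(target) - ref_model$reference
  sum(dxy[, 1L] * (ref_model$energy_matrix %*% dxy[, 1L])) +
    sum(dxy[, 2L] * (ref_model$energy_matrix %*% dxy[, 2L]))
}

# One bending-energy sliding pass for a single aligned specimen against
# `consensus` using precomputed energy matrix B. Tangents are normalized
# chords between each slider's neighbours; all slide amounts are solved
# jointly, clamped to +/- `clamp_factor` x mean adjacent spacing, with an
# exact line search to guarantee the energy never increases.
slide_one <- function(pts, consensus, B, sliders, clamp_factor = 2) {
  s <- sliders$slider
  u <- pts[sliders$after, , drop = FALSE] - pts[sliders$before, , drop = FALSE]
  u <- u / pmax(sqrt(rowSums(u^2)), .Machine$double.eps)
  dxy <- pts - consensus
  Bd <- B %*% dxy                              # k x 2
  g <- rowSums(u * Bd[s, , drop = FALSE])      # t(T) B vec(d)
  A <- B[s, s, drop = FALSE] * tcrossprod(u)   # t(T) B T
  t_hat <- tryCatch(as.vector(solve(A, -g)), error = function(e) NULL)
  if (is.null(t_hat)) return(NULL)
  spacing <- (sqrt(rowSums((pts[s, , drop = FALSE] -
                            pts[sliders$before, , drop = FALSE])^2)) +
              sqrt(rowSums((pts[sliders$after, , drop = FALSE] -
                            pts[s, , drop = FALSE])^2))) / 2
  lim <- clamp_factor * spacing
  t_cl <- pmin(pmax(t_hat, -lim), lim)
  # exact minimizer along the clamped direction: E(a t) quadratic in a
  qa <- sum(t_cl * (A %*% t_cl))
  qb <- sum(t_cl * g)
  alpha <- if (qa > .Machine$double.eps) min(max(-qb / qa, 0), 1) else 0
  out <- pts
  out[s, ] <- out[s, ] + (alpha * t_cl) * u
  out
}

#' GPA with bending-energy sliding of semilandmarks
#'
#' Alternates (a) generalized Procrustes alignment and (b) per-specimen
#' displacement of every sliding semilandmark along its local tangent (the
#' chord between its curve neighbours) by the jointly solved amounts that
#' minimize the thin-plate-spline bending energy of the specimen-to-
#' consensus deformation. Slides are clamped to twice the local inter-point
#' spacing to prevent curve fold-over. Iterates until the consensus
#' stabilizes or `max_outer_iter` is reached.
#'
#' @param x k x 2 x N array or list of [landmark_config()] objects.
#' @param sliders a `slider_table` (see [make_slider_table()]).
#' @param max_outer_iter outer GPA-slide cycles (default 5).
#' @param tol convergence tolerance on root-mean-square consensus change.
#' @param gpa_max_iter,gpa_tol passed to the inner [gpa()] calls.
#' @return a `gpa_fit` with elements `slid = TRUE`, `outer_iterations` and
#'   `energy` (per-specimen bending energy to the final consensus).
#' @export
slide_semilandmarks <- function(x, sliders, max_outer_iter = 5L, tol = 1e-7,
                                gpa_max_iter = 100L, gpa_tol = 1e-10) {
  arr <- if (is.array(x) && length(dim(x)) == 3L) x else configs_to_array(x)
  k <- dim(arr)[1L]
  sliders <- validate_slider_table(sliders, k = k)
  fit <- gpa(arr, max_iter = gpa_max_iter, tol = gpa_tol)
  sizes <- fit$centroid_sizes
  n <- dim(arr)[3L]
  outer <- 0L
  repeat {
    outer <- outer + 1L
    bem <- bending_energy(fit$consensus)
    slid <- fit$aligned
    ok <- TRUE
    for (i in seq_len(n)) {
      new_pts <- slide_one(fit$aligned[, , i], fit$consensus,
                           bem$energy_matrix, sliders)
      if (is.null(new_pts)) { ok <- FALSE; break }
      slid[, , i] <- new_pts
    }
    if (!ok) {
      warning("singular sliding system; returning unslid GPA result")
      fit$slid <- FALSE
      return(fit)
    }
    old_consensus <- fit$consensus
    fit2 <- gpa(slid, max_iter = gpa_max_iter, tol = gpa_tol)
    fit2$centroid_sizes <- sizes
    delta <- sqrt(mean((fit2$consensus - old_consensus)^2))
    fit <- fit2
    if (delta < tol || outer >= max_outer_iter) break
  }
  bem <- bending_energy(fit$consensus)
  fit$energy <- apply(fit$aligned, 3L, function(a)
    displacement_energy(bem, a))
  fit$slid <- TRUE
  fit$outer_iterations <- outer
  fit
}

#' Project aligned shapes to the tangent space at the consensus
#'
#' Vectorizes each aligned configuration (all x coordinates, then all y)
#' and orthogonally projects it onto the tangent plane of the unit
#' pre-shape sphere at the consensus. The projection is idempotent and
#' leaves the consensus itself unchanged.
#'
#' @param fit a `gpa_fit`.
#' @return N x (2k) matrix with `attr(,"consensus_vec")` set.
#' @export
project_to_tangent_space <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3L]
  X <- t(apply(fit$aligned, 3L, as.vector))
  if (n == 1L) X <- matrix(as.vector(fit$aligned[, , 1L]), nrow = 1L)
  mu <- as.vector(center_scale(fit$consensus))
  proj <- X - (X %*% mu) %*% t(mu) + matrix(mu, n, length(mu), byrow = TRUE)
  rownames(proj) <- dimnames(fit$aligned)[[3L]]
  attr(proj, "consensus_vec") <- mu
  proj
}
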