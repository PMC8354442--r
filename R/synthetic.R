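#' Parameters of a synthetic tooth outline
#'
#' The generator spans the principal directions of real tooth-shape
#' variation: apicobasally tall/narrow versus mesiodistally broad/low
#' crowns (crown_height), distal recurvature of the apex, a basal distal
#' heel, and lateral cusplets.
#'
#' @param crown_height apex height as a fraction of base width (> 0);
#'   tall-narrow teeth ~2-3, broad-low crowns ~0.5.
#' @param recurvature horizontal apex offset as a fraction of the
#'   half-base, in [-1, 1]; positive = distally recurved.
#' @param heel_depth depth of the basal distal heel notch (>= 0, same
#'   units as the unit base width).
#' @param cusplet_count sinusoidal lateral cusplets per side (integer >= 0).
#' @param cusplet_amplitude cusplet height (>= 0); keep below crown_height
#'   so the apex stays the highest point.
#' @param noise_sd isotropic Gaussian digitization noise per landmark.
#' @return list of class `tooth_params`.
#' @export
tooth_params <- function(crown_height = 1.5, recurvature = 0,
                         heel_depth = 0, cusplet_count = 0L,
                         cusplet_amplitude = 0, noise_sd = 0) {
  if (crown_height <= 0) stop("crown_height must be > 0")
  if (abs(recurvature) > 1) stop("recurvature must lie in [-1, 1]")
  if (heel_depth < 0 || cusplet_amplitude < 0 || noise_sd < 0)
    stop("heel_depth, cusplet_amplitude and noise_sd must be >= 0")
  structure(list(crown_height = crown_height, recurvature = recurvature,
                 heel_depth = heel_depth,
                 cusplet_count = as.integer(cusplet_count),
                 cusplet_amplitude = cusplet_amplitude, noise_sd = noise_sd),
            class = "tooth_params")
}

# Smooth outline of one crown edge from `from` to `to`: a cubic spline
# through 5 control points bulged outward by `bulge` along the side normal,
# with sinusoidal cusplets and an optional Gaussian heel notch near the
# base (position `heel_at` in curve parameter).
edge_curve <- function(from, to, side_normal, bulge, cusplets, cusplet_amp,
                       heel_depth = 0, heel_at = NULL, n_dense = 400L) {
  tt <- seq(0, 1, length.out = 5L)
  base <- cbind(from[1L] + tt * (to[1L] - from[1L]),
                from[2L] + tt * (to[2L] - from[2L]))
  ctrl <- base + outer(bulge * sin(pi * tt), side_normal)
  td <- seq(0, 1, length.out = n_dense)
  sx <- stats::spline(tt, ctrl[, 1L], xout = td, method = "natural")$y
  sy <- stats::spline(tt, ctrl[, 2L], xout = td, method = "natural")$y
  offset <- numeric(n_dense)
  if (cusplets > 0L && cusplet_amp > 0)
    offset <- offset + cusplet_amp * sin(2 * pi * cusplets * td) *
      sin(pi * td)^2
  if (heel_depth > 0 && !is.null(heel_at))
    offset <- offset - heel_depth * exp(-((td - heel_at) / 0.08)^2)
  cbind(sx, sy) + outer(offset, side_normal)
}

# TRUE if the closed polygon through `pts` (decimated) self-intersects.
outline_self_intersects <- function(pts, n_check = 80L) {
  idx <- unique(round(seq(1L, nrow(pts), length.out = min(n_check,
                                                          nrow(pts)))))
  p <- pts[idx, , drop = FALSE]
  n <- nrow(p)
  seg_a <- p
  seg_b <- p[c(2:n, 1L), , drop = FALSE]
  crosses <- function(a1, a2, b1, b2) {
    d1 <- (a2[1L] - a1[1L]) * (b1[2L] - a1[2L]) -
          (a2[2L] - a1[2L]) * (b1[1L] - a1[1L])
    d2 <- (a2[1L] - a1[1L]) * (b2[2L] - a1[2L]) -
          (a2[2L] - a1[2L]) * (b2[1L] - a1[1L])
    d3 <- (b2[1L] - b1[1L]) * (a1[2L] - b1[2L]) -
          (b2[2L] - b1[2L]) * (a1[1L] - b1[1L])
    d4 <- (b2[1L] - b1[1L]) * (a2[2L] - b1[2L]) -
          (b2[2L] - b1[2L]) * (a2[1L] - b1[1L])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (crosses(seg_a[i, ], seg_b[i, ], seg_a[j, ], seg_b[j, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Generate one synthetic tooth landmark configuration
#'
#' Builds a tooth outline with crown-root junctions at (-0.5, 0) and
#' (0.5, 0) and the apex at (recurvature/2, crown_height); the mesial and
#' distal crown edges are smooth splines with optional cusplets and a
#' distal heel notch, resampled to the standard semilandmark partition
#' (79 mesial / 78 distal at k = 160) and perturbed by isotropic Gaussian
#' landmark noise.
#'
#' @param params a [tooth_params()].
#' @param k total landmark count (default 160).
#' @param specimen_id identifier.
#' @param seed optional seed for the noise draw (uses the current RNG
#'   state when NULL, so assemblage-level seeding controls everything).
#' @return a [landmark_config()]; the noise-free dense outline curves are
#'   attached as `attr(, "curves")`.
#' @export
make_tooth <- function(params, k = 160L, specimen_id = "tooth",
                       seed = NULL) {
  stopifnot(inherits(params, "tooth_params"))
  if (!is.null(seed)) set.seed(seed)
  mesial_j <- c(-0.5, 0)
  distal_j <- c(0.5, 0)
  apex <- c(0.5 * params$recurvature, params$crown_height)
  bulge <- 0.06
  mesial <- edge_curve(mesial_j, apex, side_normal = c(-1, 0),
                       bulge = bulge, cusplets = params$cusplet_count,
                       cusplet_amp = params$cusplet_amplitude)
  distal <- edge_curve(apex, distal_j, side_normal = c(1, 0),
                       bulge = bulge, cusplets = params$cusplet_count,
                       cusplet_amp = params$cusplet_amplitude,
                       heel_depth = params$heel_depth, heel_at = 0.85)
  outline <- rbind(mesial, distal[-1L, , drop = FALSE])
  if (outline_self_intersects(outline))
    stop("parameters produce a self-intersecting outline; reduce ",
         "cusplet_amplitude or heel_depth")
  cfg <- assemble_configuration(rbind(mesial_j, apex, distal_j),
                                mesial_curve = mesial,
                                distal_curve = distal, k = k,
                                specimen_id = specimen_id)
  if (params$noise_sd > 0)
    cfg$points <- cfg$points +
      matrix(stats::rnorm(2L * nrow(cfg$points), sd = params$noise_sd),
             ncol = 2L)
  attr(cfg, "curves") <- list(mesial = mesial, distal = distal,
                              params = params)
  cfg
}

#' Design of a synthetic grouped tooth assemblage
#'
#' @param groups data.frame with one row per group: columns label, clade,
#'   bin, n, the mean tooth parameters (crown_height, recurvature,
#'   heel_depth, cusplet_count, cusplet_amplitude, noise_sd) and their
#'   between-specimen standard deviations (columns suffixed `_sd`,
#'   optional, default 0). An optional `tooth_position` column labels
#'   monognathic position groups.
#' @param k landmark count (default 160).
#' @param seed integer seed governing every stochastic draw.
#' @return list of class `assemblage_design`.
#' @export
assemblage_design <- function(groups, k = 160L, seed = 1L) {
  groups <- as.data.frame(groups)
  need <- c("label", "clade", "bin", "n", "crown_height")
  miss <- setdiff(need, names(groups))
  if (length(miss)) stop("groups lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(groups$n < 1L)) stop("every group needs n >= 1")
  defaults <- c(recurvature = 0, heel_depth = 0, cusplet_count = 0,
                cusplet_amplitude = 0, noise_sd = 0)
  for (nm in names(defaults))
    if (is.null(groups[[nm]])) groups[[nm]] <- defaults[[nm]]
  for (nm in c("crown_height", "recurvature", "heel_depth",
               "cusplet_amplitude")) {
    sd_col <- paste0(nm, "_sd")
    if (is.null(groups[[sd_col]])) groups[[sd_col]] <- 0
  }
  structure(list(groups = groups, k = as.integer(k), seed = as.integer(seed)),
            class = "assemblage_design")
}

# Truncated-normal draw by rejection; errors after `max_try` rejections.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_try = 1000L) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper))
      stop("degenerate draw outside validity bounds")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in seq_len(max_try)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lower && x <= upper) break
      if (tries == max_try)
        stop("infeasible truncation: >", max_try, " rejections for mean=",
             mean, ", sd=", sd)
    }
    out[i] <- x
  }
  out
}

#' Sample a synthetic tooth assemblage
#'
#' Draws per-specimen tooth parameters from independent normals truncated
#' to their validity ranges, generates the teeth, and assembles specimen
#' metadata (clade, time bin, labial view, synthetic basin).
#'
#' @param design an [assemblage_design()].
#' @return list of class `tooth_assemblage`: configs (list of
#'   [landmark_config()]), metadata (data.frame), design.
#' @export
sample_assemblage <- function(design) {
  stopifnot(inherits(design, "assemblage_design"))
  set.seed(design$seed)
  configs <- list()
  meta <- list()
  counter <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    g <- design$groups[gi, ]
    ch <- rtrunc_norm(g$n, g$crown_height, g$crown_height_sd, lower = 0.05)
    rc <- rtrunc_norm(g$n, g$recurvature, g$recurvature_sd, -1, 1)
    hd <- rtrunc_norm(g$n, g$heel_depth, g$heel_depth_sd, lower = 0)
    ca <- rtrunc_norm(g$n, g$cusplet_amplitude, g$cusplet_amplitude_sd,
                      lower = 0)
    for (i in seq_len(g$n)) {
      counter <- counter + 1L
      id <- sprintf("%s_%03d", g$label, i)
      pars <- tooth_params(crown_height = ch[i], recurvature = rc[i],
                           heel_depth = hd[i],
                           cusplet_count = g$cusplet_count,
                           cusplet_amplitude = ca[i],
                           noise_sd = g$noise_sd)
      configs[[counter]] <- make_tooth(pars, k = design$k, specimen_id = id)
      meta[[counter]] <- data.frame(
        specimen_id = id, group = g$label, order_clade = g$clade,
        age_label = g$bin, basin = "synthetic", view = "labial",
        tooth_position = if (is.null(g$tooth_position) ||
                             is.na(g$tooth_position)) "unknown"
                         else g$tooth_position,
        jaw = "unknown", stringsAsFactors = FALSE)
    }
  }
  structure(list(configs = configs, metadata = do.call(rbind, meta),
                 design = design),
            class = "tooth_assemblage")
}

#' Write an assemblage to TPS + sliders + metadata files
#'
#' Emits the three file kinds every downstream module consumes, so the
#' whole pipeline can be exercised through its file interface.
#'
#' @param assemblage a `tooth_assemblage`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_assemblage <- function(assemblage, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tps = file.path(dir, "landmarks.tps"),
             sliders = file.path(dir, "sliders.txt"),
             metadata = file.path(dir, "metadata.csv"))
  write_tps(assemblage$configs, paths[["tps"]])
  write_sliders(make_slider_table(assemblage$design$k), paths[["sliders"]])
  utils::write.csv(assemblage$metadata, paths[["metadata"]],
                   row.names = FALSE)
  paths
}

#' Preset assemblage designs with known ground truth
#'
#' \describe{
#'   \item{null_equal_disparity}{two time bins drawn from one identical
#'     generative population (no disparity or mean-shape difference).}
#'   \item{disparity_shift}{two bins with identical mean shape whose
#'     landmark noise sd differs by a factor sqrt(2), i.e. a designed 2:1
#'     Procrustes-variance ratio; no parameter-level variation.}
#'   \item{selective_loss}{a pre-extinction bin mixing tall-narrow and
#'     broad-low (blade-like) morphotypes, and a post-extinction bin from
#'     which the broad-low region of morphospace has been removed.}
#'   \item{heterodonty_gradient}{a single bin with a monognathic
#'     recurvature gradient across anterior, lateroposterior, and
#'     posterior tooth positions.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed stored in the design.
#' @param k landmark count (default 160).
#' @return an [assemblage_design()].
#' @export
scenario <- function(name, seed = 1L, k = 160L) {
  presets <- c("null_equal_disparity", "disparity_shift", "selective_loss",
               "heterodonty_gradient")
  if (!name %in% presets)
    stop("unknown scenario '", name, "'; available: ",
         paste(presets, collapse = ", "))
  base <- data.frame(crown_height = 1.5, crown_height_sd = 0.2,
                     recurvature = 0.2, recurvature_sd = 0.1,
                     heel_depth = 0.05, heel_depth_sd = 0.02,
                     cusplet_count = 0L, cusplet_amplitude = 0,
                     cusplet_amplitude_sd = 0, noise_sd = 0.02)
  groups <- switch(name,
    null_equal_disparity = cbind(
      data.frame(label = c("binA", "binB"), clade = "Lamniformes",
                 bin = c("Campanian", "Maastrichtian"), n = 60L),
      rbind(base, base)),
    disparity_shift = {
      g <- cbind(
        data.frame(label = c("binA", "binB"), clade = "Lamniformes",
                   bin = c("Maastrichtian", "Danian"), n = 100L),
        rbind(base, base))
      g$crown_height_sd <- 0; g$recurvature_sd <- 0
      g$heel_depth_sd <- 0
      g$noise_sd <- c(0.02 * sqrt(2), 0.02)   # PV ratio 2:1
      g
    },
    selective_loss = {
      tall <- base; tall$crown_height <- 2.5
      broad <- base; broad$crown_height <- 0.6
      cbind(
        data.frame(label = c("pre_tall", "pre_broad", "post_tall"),
                   clade = c("Lamniformes", "Carcharhiniformes",
                             "Lamniformes"),
                   bin = c("Maastrichtian", "Maastrichtian", "Danian"),
                   n = c(30L, 30L, 60L)),
        rbind(tall, broad, tall))
    },
    heterodonty_gradient = {
      g <- cbind(
        data.frame(label = c("ant", "latpost", "post"),
                   clade = "Carcharhiniformes", bin = "Danian", n = 30L,
                   tooth_position = c("anterior", "lateroposterior",
                                      "posterior")),
        rbind(base, base, base))
      g$recurvature <- c(0, 0.4, 0.8)
      g$recurvature_sd <- 0.05
      g$crown_height_sd <- 0.1   # nuisance variance kept below the gradient
      g
    })
  assemblage_design(groups, k = k, seed = seed)
}
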