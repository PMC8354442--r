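#' Landmark configuration for a single specimen
#'
#' Bundles the ordered \eqn{k \times 2} coordinate matrix of one digitized
#' tooth outline with its identifier, the indices of the three fixed
#' anchor landmarks (mesial crown-root junction, apex, distal crown-root
#' junction) and an optional digitizing scale factor.
#'
#' Under the standard traversal convention the points run: mesial junction,
#' mesial semilandmarks (junction towards apex), apex, distal
#' semilandmarks (apex towards distal junction), distal junction. For the
#' canonical k = 160 scheme this gives 79 mesial and 78 distal sliding
#' semilandmarks.
#'
#' @param points numeric k x 2 matrix of planar coordinates.
#' @param specimen_id character scalar identifier.
#' @param fixed integer vector of length 3: indices of mesial junction,
#'   apex, distal junction. Defaults to the standard scheme for `nrow(points)`.
#' @param scale optional positive scalar, units per pixel.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, specimen_id = "unnamed", fixed = NULL,
                            scale = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must have 2 columns, got ", ncol(points))
  if (!all(is.finite(points)))
    stop("non-finite coordinate in configuration '", specimen_id, "'")
  storage.mode(points) <- "double"
  k <- nrow(points)
  if (is.null(fixed) && k >= 5L) fixed <- standard_fixed_indices(k)
  if (!is.null(fixed)) {
    fixed <- as.integer(fixed)
    if (length(fixed) != 3L || anyDuplicated(fixed) ||
        any(fixed < 1L) || any(fixed > k))
      stop("`fixed` must be 3 distinct in-range indices")
  }
  structure(
    list(points = points, specimen_id = as.character(specimen_id),
         fixed = fixed, scale = scale),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> '%s': %d landmarks (anchors at %s)%s\n",
              x$specimen_id, nrow(x$points),
              paste(x$fixed, collapse = ", "),
              if (is.null(x$scale)) "" else sprintf(", scale=%g", x$scale)))
  invisible(x)
}

#' Standard anchor indices for a k-point tooth scheme
#'
#' Splits the k - 3 semilandmarks between the two curves with the smaller
#' partition on the distal curve, so that k = 160 yields the 79 (mesial) /
#' 78 (distal) split.
#'
#' @param k total landmark count, at least 5.
#' @return integer vector: indices of (mesial junction, apex, distal junction).
#' @export
standard_fixed_indices <- function(k) {
  k <- as.integer(k)
  if (k < 5L) stop("standard scheme needs k >= 5, got ", k)
  n_semi <- k - 3L
  n_mesial <- as.integer(ceiling(n_semi / 2))
  c(1L, 2L + n_mesial, k)
}

#' Number of mesial/distal semilandmarks under the standard scheme
#' @param k total landmark count.
#' @return named integer vector with elements `mesial` and `distal`.
#' @export
semilandmark_partition <- function(k) {
  fx <- standard_fixed_indices(k)
  c(mesial = fx[2L] - 2L, distal = as.integer(k) - 1L - fx[2L])
}

#' Slider table for a configuration's semilandmarks
#'
#' Every non-anchor point slides between its two curve neighbours. Rows are
#' (before, slider, after) with 1-based indices; this is also the on-disk
#' dialect of the 3-column sliders file.
#'
#' @param k landmark count.
#' @param fixed anchor indices; defaults to [standard_fixed_indices()].
#' @return data.frame of class `slider_table` with columns before, slider,
#'   after.
#' @export
make_slider_table <- function(k, fixed = standard_fixed_indices(k)) {
  sliders <- setdiff(seq_len(k), fixed)
  tab <- data.frame(before = sliders - 1L, slider = sliders,
                    after = sliders + 1L)
  validate_slider_table(tab, k = k, fixed = fixed)
}

#' Validate a slider table
#'
#' @param tab data.frame with integer columns before, slider, after.
#' @param k optional landmark count for range checking.
#' @param fixed optional anchor indices that must not appear as sliders.
#' @return the validated table, classed `slider_table`.
#' @export
validate_slider_table <- function(tab, k = NULL, fixed = NULL) {
  tab <- as.data.frame(tab)
  if (!all(c("before", "slider", "after") %in% names(tab)))
    stop("slider table needs columns before, slider, after")
  tab <- tab[c("before", "slider", "after")]
  for (nm in names(tab)) tab[[nm]] <- as.integer(tab[[nm]])
  if (anyNA(tab)) stop("non-integer entry in slider table")
  if (any(tab$slider == tab$before | tab$slider == tab$after))
    stop("slider equal to its own neighbour in row(s) ",
         paste(which(tab$slider == tab$before | tab$slider == tab$after),
               collapse = ", "))
  if (anyDuplicated(tab$slider))
    stop("slider index appears more than once: ",
         paste(unique(tab$slider[duplicated(tab$slider)]), collapse = ", "))
  if (!is.null(k) && any(unlist(tab) < 1L | unlist(tab) > k))
    stop("slider table index out of range 1..", k)
  if (!is.null(fixed) && any(tab$slider %in% fixed))
    stop("fixed landmark listed as slider: ",
         paste(intersect(tab$slider, fixed), collapse = ", "))
  class(tab) <- c("slider_table", "data.frame")
  tab
}

#' Read a TPS landmark file
#'
#' Parses the classic tpsDig dialect: `LM=<n>` followed by n coordinate
#' lines, with optional `ID=`, `IMAGE=` and `SCALE=` keys per record.
#' Unrecognized keys are ignored.
#'
#' @param path file path.
#' @return list of [landmark_config()] objects, one per record.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L && length(lines) > 0L)
    stop("no LM= records in ", path)
  configs <- vector("list", length(starts))
  ends <- c(starts[-1L] - 1L, length(lines))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                            ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1L)
      stop("malformed LM count in record ", r, " of ", path)
    if (length(block) < 1L + n_lm)
      stop("record ", r, ": LM=", n_lm, " but only ",
           length(block) - 1L, " lines follow")
    coord_lines <- block[2L:(1L + n_lm)]
    coords <- suppressWarnings(
      do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric)))
    if (anyNA(coords) || ncol(coords) != 2L)
      stop("non-numeric or non-2D coordinate in record ", r, " of ", path)
    rest <- if (length(block) > 1L + n_lm) block[(2L + n_lm):length(block)]
            else character()
    get_key <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), rest, ignore.case = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", rest[hit[1L]],
                           ignore.case = TRUE) else NULL
    }
    id <- get_key("ID")
    if (is.null(id)) id <- sprintf("record_%d", r)
    scale <- get_key("SCALE")
    scale <- if (is.null(scale)) NULL else as.numeric(scale)
    configs[[r]] <- landmark_config(coords, specimen_id = id, scale = scale)
  }
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate specimen IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  message(sprintf("read_tps: %d record(s) from %s", length(configs), path))
  configs
}

#' Write configurations to a TPS landmark file
#'
#' @param configs list of [landmark_config()] objects.
#' @param path output file path.
#' @param digits decimal places for fixed-format coordinates.
#' @param allow_ragged permit configurations of unequal landmark counts.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, digits = 10L, allow_ragged = FALSE) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  ks <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(ks) > 1L && !allow_ragged && length(unique(ks)) > 1L)
    stop("ragged landmark counts; pass allow_ragged = TRUE to permit")
  out <- character(0)
  for (cf in configs) {
    if (!all(is.finite(cf$points)))
      stop("non-finite coordinate in '", cf$specimen_id, "'")
    rec <- c(sprintf("LM=%d", nrow(cf$points)),
             sprintf(paste0("%.", digits, "f %.", digits, "f"),
                     cf$points[, 1L], cf$points[, 2L]),
             sprintf("ID=%s", cf$specimen_id))
    if (!is.null(cf$scale)) rec <- c(rec, sprintf("SCALE=%g", cf$scale))
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a 3-column sliders file
#'
#' Whitespace-delimited (before, slider, after) integer triples with an
#' optional non-numeric header line; 1-based indices.
#'
#' @param path file path.
#' @param k optional landmark count for validation.
#' @param fixed optional anchor indices for validation.
#' @return a `slider_table`.
#' @export
read_sliders <- function(path, k = NULL, fixed = NULL) {
  if (!file.exists(path)) stop("sliders file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1L], "\\s+|,")[[1L]]
  if (any(is.na(suppressWarnings(as.integer(first))))) lines <- lines[-1L]
  cells <- strsplit(lines, "\\s+|,")
  bad <- which(lengths(cells) != 3L)
  if (length(bad)) stop("sliders row(s) without 3 fields: ",
                        paste(bad, collapse = ", "))
  m <- suppressWarnings(matrix(as.integer(unlist(cells)), ncol = 3L,
                               byrow = TRUE))
  if (anyNA(m)) stop("non-integer entry in sliders file ", path)
  tab <- validate_slider_table(
    data.frame(before = m[, 1L], slider = m[, 2L], after = m[, 3L]),
    k = k, fixed = fixed)
  message(sprintf("read_sliders: %d slider row(s) from %s", nrow(tab), path))
  tab
}

#' Write a slider table to a 3-column text file
#' @param tab a `slider_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sliders <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[c("before", "slider", "after")],
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resample an open polyline to equidistant points
#'
#' Places `n` points at equal arc-length spacing along the piecewise-linear
#' curve through the input points; the first and last output points
#' coincide with the input endpoints.
#'
#' @param points ordered matrix of 2D points (at least 2 distinct).
#' @param n number of output points, at least 2.
#' @return n x 2 matrix.
#' @export
resample_open_curve <- function(points, n) {
  points <- as.matrix(points)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (nrow(points) < 2L) stop("need at least 2 input points")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("zero-length curve cannot be resampled")
  s <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n)
  # segment index for each target arc length; clamp to last segment
  idx <- pmin(findInterval(target, s, rightmost.closed = TRUE),
              nrow(points) - 1L)
  frac <- (target - s[idx]) / pmax(seg[idx], .Machine$double.eps)
  out <- points[idx, , drop = FALSE] +
    frac * (points[idx + 1L, , drop = FALSE] - points[idx, , drop = FALSE])
  out[1L, ] <- points[1L, ]
  out[n, ] <- points[nrow(points), ]
  out
}

#' Assemble a standard tooth configuration from anchors and curves
#'
#' Resamples the mesial (mesial junction to apex) and distal (apex to distal
#' junction) outline curves to the standard semilandmark partition for `k`
#' total landmarks and concatenates them in the canonical traversal order.
#'
#' @param anchors 3 x 2 matrix: mesial junction, apex, distal junction.
#' @param mesial_curve ordered points from mesial junction to apex.
#' @param distal_curve ordered points from apex to distal junction.
#' @param k total landmark count (default 160).
#' @param specimen_id identifier for the new configuration.
#' @return a [landmark_config()].
#' @export
assemble_configuration <- function(anchors, mesial_curve, distal_curve,
                                   k = 160L, specimen_id = "assembled") {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 3L || ncol(anchors) != 2L)
    stop("`anchors` must be a 3 x 2 matrix")
  part <- semilandmark_partition(k)   # errors for k < 5
  mes <- resample_open_curve(rbind(anchors[1L, ], as.matrix(mesial_curve),
                                   anchors[2L, ]), part[["mesial"]] + 2L)
  dis <- resample_open_curve(rbind(anchors[2L, ], as.matrix(distal_curve),
                                   anchors[3L, ]), part[["distal"]] + 2L)
  pts <- rbind(anchors[1L, , drop = FALSE],
               mes[-c(1L, nrow(mes)), , drop = FALSE],
               anchors[2L, , drop = FALSE],
               dis[-c(1L, nrow(dis)), , drop = FALSE],
               anchors[3L, , drop = FALSE])
  landmark_config(pts, specimen_id = specimen_id,
                  fixed = standard_fixed_indices(k))
}

# Mirror about the vertical axis, reversing traversal so mesial/distal
# labels keep their anatomical identity; anchor indices are remapped.
mirror_config <- function(config) {
  pts <- config$points
  pts[, 1L] <- -pts[, 1L]
  k <- nrow(pts)
  pts <- pts[k:1L, , drop = FALSE]
  fixed <- sort(k + 1L - config$fixed)
  landmark_config(pts, specimen_id = config$specimen_id, fixed = fixed,
                  scale = config$scale)
}

#' Normalize a configuration to the canonical apex-left orientation
#'
#' Lingual-view specimens are first reflected about the vertical axis (with
#' traversal order reversed so the mesial/distal identity of the curves is
#' preserved), making them comparable to labial views. The configuration is
#' then rigidly rotated so the axis from the junction midpoint to the apex
#' points in the negative x direction, which guarantees the apex
#' x-coordinate does not exceed either junction's.
#'
#' @param config a [landmark_config()].
#' @param view "labial" or "lingual".
#' @return the normalized [landmark_config()].
#' @export
normalize_orientation <- function(config, view = c("labial", "lingual")) {
  view <- match.arg(view)
  if (is.null(config$fixed))
    stop("configuration has no anchor indices; orientation undefined")
  if (view == "lingual") config <- mirror_config(config)
  fx <- config$fixed
  pts <- config$points
  mid <- (pts[fx[1L], ] + pts[fx[3L], ]) / 2
  v <- pts[fx[2L], ] - mid
  nv <- sqrt(sum(v^2))
  if (nv > 1e-12) {
    # proper rotation (as a right-multiplied matrix for row vectors)
    # taking the junction-midpoint-to-apex vector v onto (-|v|, 0)
    rot <- matrix(c(-v[1L], -v[2L], v[2L], -v[1L]) / nv, 2L, 2L)
    pts <- sweep(pts, 2L, mid) %*% rot
    pts <- sweep(pts, 2L, mid, "+")
  }
  landmark_config(pts, specimen_id = config$specimen_id, fixed = fx,
                  scale = config$scale)
}

#' Built-in time-binning schemes
#'
#' Returns a binning scheme mapping geochronological age labels to analysis
#' bins with numeric midpoints (Ma, ICS v2020/03 boundaries). Available:
#' \describe{
#'   \item{five_age}{Campanian, Maastrichtian, Danian, Selandian, Thanetian.}
#'   \item{four_age}{as five_age but Danian and Selandian (and specimens
#'     already labelled "Danian-Selandian") pooled into one bin.}
#'   \item{sub_age}{early/late Campanian and Maastrichtian plus
#'     early/middle/late Danian.}
#'   \item{regional_three_bin}{late Maastrichtian, early Danian, middle
#'     Danian (the K/Pg boundary-section succession).}
#' }
#'
#' @param name scheme name.
#' @return object of class `binning_scheme`: list(name, mapping, bin_order,
#'   bin_mid_ma).
#' @export
binning_scheme <- function(name = c("five_age", "four_age",
                                    "regional_three_bin", "sub_age")) {
  name <- match.arg(name)
  # ICS v2020/03 stage boundaries (Ma): Campanian 83.6-72.1,
  # Maastrichtian 72.1-66.0, Danian 66.0-61.6, Selandian 61.6-59.2,
  # Thanetian 59.2-56.0. Sub-ages split stages evenly (Danian in thirds).
  sch <- switch(name,
    five_age = list(
      mapping = c(Campanian = "Campanian", Maastrichtian = "Maastrichtian",
                  Danian = "Danian", Selandian = "Selandian",
                  Thanetian = "Thanetian"),
      bin_order = c("Campanian", "Maastrichtian", "Danian", "Selandian",
                    "Thanetian"),
      bin_mid_ma = c(77.85, 69.05, 63.8, 60.4, 57.6)),
    four_age = list(
      mapping = c(Campanian = "Campanian", Maastrichtian = "Maastrichtian",
                  Danian = "Danian-Selandian", Selandian = "Danian-Selandian",
                  `Danian-Selandian` = "Danian-Selandian",
                  Thanetian = "Thanetian"),
      bin_order = c("Campanian", "Maastrichtian", "Danian-Selandian",
                    "Thanetian"),
      bin_mid_ma = c(77.85, 69.05, 62.6, 57.6)),
    sub_age = list(
      mapping = c(`early Campanian` = "early Campanian",
                  `late Campanian` = "late Campanian",
                  `early Maastrichtian` = "early Maastrichtian",
                  `late Maastrichtian` = "late Maastrichtian",
                  `early Danian` = "early Danian",
                  `middle Danian` = "middle Danian",
                  `late Danian` = "late Danian"),
      bin_order = c("early Campanian", "late Campanian",
                    "early Maastrichtian", "late Maastrichtian",
                    "early Danian", "middle Danian", "late Danian"),
      bin_mid_ma = c(80.73, 74.98, 70.58, 67.53, 65.27, 63.8, 62.33)),
    regional_three_bin = list(
      mapping = c(`late Maastrichtian` = "late Maastrichtian",
                  `early Danian` = "early Danian",
                  `middle Danian` = "middle Danian"),
      bin_order = c("late Maastrichtian", "early Danian", "middle Danian"),
      bin_mid_ma = c(67.53, 65.27, 63.8)))
  structure(c(list(name = name), sch), class = "binning_scheme")
}

#' Assign specimens to time bins
#'
#' @param metadata data.frame with at least an `age_label` column.
#' @param scheme a [binning_scheme()] or scheme name.
#' @param strict error on unmapped labels (default); otherwise drop them
#'   with a warning.
#' @return `metadata` restricted to mapped rows, with `bin` (factor in
#'   chronological order) and `bin_mid_ma` columns added; per-bin counts in
#'   `attr(, "bin_counts")`.
#' @export
assign_bins <- function(metadata, scheme = "five_age", strict = TRUE) {
  if (is.character(scheme)) scheme <- binning_scheme(scheme)
  if (!"age_label" %in% names(metadata))
    stop("metadata lacks an `age_label` column")
  lab <- as.character(metadata$age_label)
  bin <- unname(scheme$mapping[lab])
  if (anyNA(bin)) {
    offenders <- sort(unique(lab[is.na(bin)]))
    if (strict)
      stop("age label(s) not covered by scheme '", scheme$name, "': ",
           paste(offenders, collapse = ", "))
    warning("dropping ", sum(is.na(bin)), " specimen(s) with unmapped ",
            "label(s): ", paste(offenders, collapse = ", "))
    metadata <- metadata[!is.na(bin), , drop = FALSE]
    bin <- bin[!is.na(bin)]
  }
  metadata$bin <- factor(bin, levels = scheme$bin_order)
  metadata$bin_mid_ma <- scheme$bin_mid_ma[match(bin, scheme$bin_order)]
  attr(metadata, "bin_counts") <- table(metadata$bin)
  metadata
}

#' Read a specimen occurrence table (CSV)
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping internal field
#'   names (e.g. `specimen_id`, `age_label`, `view`) to file column names.
#' @return data.frame of specimen metadata.
#' @export
read_metadata <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(md))
    if (length(missing_cols))
      stop("mapped column(s) absent from file: ",
           paste(missing_cols, collapse = ", "))
    names(md)[match(column_map, names(md))] <- names(column_map)
  }
  message(sprintf("read_metadata: %d specimen row(s) from %s", nrow(md), path))
  md
}

# Stack a list of landmark_configs into a k x 2 x N array.
configs_to_array <- function(configs) {
  ks <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(unique(ks)) != 1L)
    stop("configurations have unequal landmark counts")
  arr <- array(unlist(lapply(configs, function(cf) cf$points)),
               dim = c(ks[1L], 2L, length(configs)))
  dimnames(arr) <- list(NULL, c("x", "y"),
                        vapply(configs, function(cf) cf$specimen_id,
                               character(1)))
  arr
}
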