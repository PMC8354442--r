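#' Pipeline configuration
#'
#' Exactly one input source must be given: either the three file paths
#' (tps, sliders, metadata) or a [scenario()] preset name.
#'
#' @param tps,sliders,metadata input file paths.
#' @param scenario preset name for synthetic input.
#' @param scheme binning scheme name (see [binning_scheme()]).
#' @param exclude_clades clade labels dropped before analysis (the
#'   sensitivity-analysis switch, e.g. "Synechodontiformes").
#' @param basin optional basin label to subset to.
#' @param n_perm,n_boot,n_rarefaction,dip_n_mc stochastic-procedure sizes.
#' @param partial_convention partial-disparity convention.
#' @param k landmark count for scenario-generated data (default 160).
#' @param strict_bins error on unmapped age labels (otherwise drop).
#' @param seed global seed; each stage derives a child seed from it.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(tps = NULL, sliders = NULL, metadata = NULL,
                            scenario = NULL, scheme = "five_age",
                            exclude_clades = character(), basin = NULL,
                            n_perm = 999L, n_boot = 1000L,
                            n_rarefaction = 999L, dip_n_mc = 999L,
                            partial_convention = "grand_mean",
                            k = 160L, strict_bins = TRUE, seed = 1L,
                            out_dir = "toothdisp_out") {
  has_paths <- !is.null(tps) || !is.null(sliders) || !is.null(metadata)
  if (has_paths && !is.null(scenario))
    stop("give either input paths or a scenario, not both")
  if (!has_paths && is.null(scenario))
    stop("one of (tps, sliders, metadata) paths or scenario is required")
  if (has_paths && (is.null(tps) || is.null(metadata)))
    stop("file input needs at least tps and metadata paths")
  counts <- c(n_perm = n_perm, n_boot = n_boot,
              n_rarefaction = n_rarefaction, dip_n_mc = dip_n_mc)
  if (any(counts < 1L)) stop("all iteration counts must be positive")
  structure(list(tps = tps, sliders = sliders, metadata = metadata,
                 scenario = scenario, scheme = scheme,
                 exclude_clades = exclude_clades, basin = basin,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 n_rarefaction = as.integer(n_rarefaction),
                 dip_n_mc = as.integer(dip_n_mc),
                 partial_convention = partial_convention,
                 k = as.integer(k),
                 strict_bins = isTRUE(strict_bins), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Deterministic per-stage child seed below 2^31.
child_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L + sum(utf8ToInt(stage)) %% 9973L
}

log_line <- function(config, ...) {
  cat(sprintf(...), "\n", sep = "",
      file = file.path(config$out_dir, "log.txt"), append = TRUE)
}

write_table <- function(df, config, name) {
  path <- file.path(config$out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank lines
#' ignored; unknown keys are an error. List-valued keys
#' (exclude_clades) take comma-separated values.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("unparseable config line(s): ",
                        paste(lines[bad], collapse = " | "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate config key(s): ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  ints <- c("n_perm", "n_boot", "n_rarefaction", "dip_n_mc", "seed", "k")
  for (nm in intersect(ints, keys)) args[[nm]] <- as.integer(args[[nm]])
  if ("strict_bins" %in% keys)
    args$strict_bins <- toupper(args$strict_bins) %in% c("TRUE", "YES", "1")
  if ("exclude_clades" %in% keys)
    args$exclude_clades <- trimws(strsplit(args$exclude_clades, ",")[[1L]])
  do.call(pipeline_config, args)
}

# ---- stages ----------------------------------------------------------------

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  if (is.null(config$scenario)) return(invisible(config))
  design <- scenario(config$scenario,
                     seed = child_seed(config$seed, "simulate"),
                     k = config$k)
  asm <- sample_assemblage(design)
  paths <- write_assemblage(asm, file.path(config$out_dir, "sim"))
  config$tps <- paths[["tps"]]
  config$sliders <- paths[["sliders"]]
  config$metadata <- paths[["metadata"]]
  log_line(config, "simulate: scenario=%s n=%d seed=%d", config$scenario,
           length(asm$configs), design$seed)
  invisible(config)
}

#' @rdname run_pipeline
#' @export
stage_align <- function(config) {
  if (is.null(config$tps)) stop("align: no tps input; run simulate first ",
                                "or give file paths")
  configs <- read_tps(config$tps)
  md <- read_metadata(config$metadata)
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  if (!all(ids %in% md$specimen_id))
    stop("align: specimens missing from metadata: ",
         paste(utils::head(setdiff(ids, md$specimen_id)), collapse = ", "))
  md <- md[match(ids, md$specimen_id), , drop = FALSE]
  view <- if ("view" %in% names(md)) md$view else rep("labial", length(ids))
  configs <- Map(function(cf, v) normalize_orientation(cf, v), configs, view)
  k <- nrow(configs[[1L]]$points)
  sliders <- if (!is.null(config$sliders))
    read_sliders(config$sliders, k = k) else make_slider_table(k)
  fit <- slide_semilandmarks(configs, sliders)
  write_tps(Map(function(i) landmark_config(fit$aligned[, , i], ids[i]),
                seq_along(ids)),
            file.path(config$out_dir, "aligned.tps"), digits = 12L)
  utils::write.csv(data.frame(x = fit$consensus[, 1L],
                              y = fit$consensus[, 2L]),
                   file.path(config$out_dir, "consensus.csv"),
                   row.names = FALSE)
  write_table(data.frame(n = length(ids), k = k,
                         q = utils::tail(fit$q_history, 1L),
                         gpa_iterations = fit$iterations,
                         outer_iterations = fit$outer_iterations,
                         converged = fit$converged),
              config, "alignment_summary")
  log_line(config, "align: n=%d k=%d Q=%.6g", length(ids), k,
           utils::tail(fit$q_history, 1L))
  invisible(config)
}

# Rebuild a minimal gpa_fit from the align stage's serialized outputs.
read_alignment <- function(config) {
  configs <- read_tps(file.path(config$out_dir, "aligned.tps"))
  arr <- configs_to_array(configs)
  cons <- utils::read.csv(file.path(config$out_dir, "consensus.csv"))
  structure(list(aligned = arr, consensus = as.matrix(cons),
                 centroid_sizes = rep(1, dim(arr)[3L]),
                 q_history = NA_real_, iterations = NA_integer_,
                 converged = TRUE),
            class = "gpa_fit")
}

#' @rdname run_pipeline
#' @export
stage_ordinate <- function(config) {
  fit <- read_alignment(config)
  pca <- shape_pca(fit)
  scores <- data.frame(specimen_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE)
  names(scores)[-1L] <- paste0("PC", seq_len(ncol(pca$scores)))
  write_table(scores, config, "scores")
  write_table(data.frame(PC = seq_along(pca$eigenvalues),
                         eigenvalue = pca$eigenvalues,
                         percent = pca$percent_variance,
                         cumulative = cumsum(pca$percent_variance)),
              config, "percent_variance")
  utils::write.csv(cbind(mean = pca$reference_mean, pca$rotation),
                   file.path(config$out_dir, "pca_basis.csv"),
                   row.names = FALSE)
  log_line(config, "ordinate: %d PCs, PC1 = %.2f%%",
           length(pca$eigenvalues), pca$percent_variance[1L])
  invisible(config)
}

# Metadata joined to the aligned specimens, binned and subset per config.
binned_metadata <- function(config, fit) {
  md <- read_metadata(config$metadata)
  ids <- dimnames(fit$aligned)[[3L]]
  md <- md[match(ids, md$specimen_id), , drop = FALSE]
  md <- assign_bins(md, config$scheme, strict = config$strict_bins)
  keep <- rep(TRUE, nrow(md))
  if (length(config$exclude_clades) && "order_clade" %in% names(md))
    keep <- keep & !(md$order_clade %in% config$exclude_clades)
  if (!is.null(config$basin) && "basin" %in% names(md))
    keep <- keep & md$basin == config$basin
  list(md = md[keep, , drop = FALSE], keep = keep)
}

#' @rdname run_pipeline
#' @export
stage_disparity <- function(config) {
  fit <- read_alignment(config)
  bm <- binned_metadata(config, fit)
  X <- as_shape_matrix(fit)[bm$keep, , drop = FALSE]
  md <- bm$md
  bins <- droplevels(md$bin)
  seed <- child_seed(config$seed, "disparity")
  by_bin <- do.call(rbind, lapply(levels(bins), function(b) {
    Xb <- X[bins == b, , drop = FALSE]
    if (nrow(Xb) >= 2L) {
      est <- bootstrap_pv(Xb, group = b, n_boot = config$n_boot, seed = seed)
      data.frame(bin = b, n = est$n, pv = est$pv, ci_low = est$ci_low,
                 ci_high = est$ci_high)
    } else data.frame(bin = b, n = nrow(Xb),
                      pv = if (nrow(Xb)) 0 else NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_)
  }))
  write_table(by_bin, config, "disparity_by_bin")
  ok <- levels(bins)[table(bins) >= 2L]
  if (length(ok) >= 2L) {
    sel <- bins %in% ok
    pt <- pv_permutation_test(X[sel, , drop = FALSE],
                              droplevels(bins[sel]),
                              n_perm = config$n_perm, seed = seed)
    write_table(pt$pairs, config, "pairwise_bins")
  }
  for (grouping in c("order_clade", "family", "basin")) {
    if (!grouping %in% names(md)) next
    if (length(unique(md[[grouping]])) < 2L && grouping != "order_clade")
      next
    pd <- do.call(rbind, lapply(levels(bins), function(b) {
      sel <- bins == b
      if (sum(sel) < 2L) return(NULL)
      tab <- partial_disparity(X[sel, , drop = FALSE], md[[grouping]][sel],
                               convention = config$partial_convention)
      cbind(bin = b, tab$rows, total_pv = tab$total_pv,
            convention = tab$convention)
    }))
    if (!is.null(pd))
      write_table(pd, config, paste0("partial_disparity_",
                                     sub("order_clade", "order", grouping)))
  }
  sizes <- table(bins)
  if (length(sizes) >= 2L && min(sizes) >= 2L) {
    rar <- rarefy_pv(X, bins, n_iter = config$n_rarefaction, seed = seed)
    write_table(rar$table, config, "rarefaction")
  }
  log_line(config, "disparity: %d bin(s), seed=%d", nlevels(bins), seed)
  invisible(config)
}

#' @rdname run_pipeline
#' @export
stage_stats <- function(config) {
  fit <- read_alignment(config)
  bm <- binned_metadata(config, fit)
  X <- as_shape_matrix(fit)[bm$keep, , drop = FALSE]
  md <- bm$md
  md$bin <- droplevels(md$bin)
  seed <- child_seed(config$seed, "stats")
  run_anova <- function(form, name) {
    an <- procrustes_lm(X, form, md, n_perm = config$n_perm, seed = seed)
    write_table(an$table, config, name)
    an
  }
  if ("order_clade" %in% names(md))
    run_anova(~order_clade, "anova_clades")
  if (nlevels(md$bin) >= 2L) run_anova(~bin, "anova_bins")
  if ("tooth_position" %in% names(md) &&
      length(unique(md$tooth_position)) >= 2L)
    run_anova(~tooth_position + bin, "anova_position")
  if ("view" %in% names(md) && length(unique(md$view)) >= 2L)
    run_anova(~view, "anova_view")
  scores <- utils::read.csv(file.path(config$out_dir, "scores.csv"))
  sc <- as.matrix(scores[match(md$specimen_id, scores$specimen_id),
                         -1L, drop = FALSE])
  axes <- seq_len(min(2L, ncol(sc)))
  ds <- distribution_summary(sc[, axes, drop = FALSE], md$bin,
                             dip_n_mc = config$dip_n_mc, seed = seed)
  write_table(ds, config, "distribution_summary")
  hz <- attr(ds, "hz")
  if (!is.null(hz))
    write_table(data.frame(statistic = hz$statistic, p_value = hz$p_value,
                           n = hz$n, p = hz$p),
                config, "henze_zirkler")
  log_line(config, "stats: seed=%d", seed)
  invisible(config)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(config) {
  out <- config$out_dir
  figures <- character(0)
  if (capabilities("png")) {
    scores <- utils::read.csv(file.path(out, "scores.csv"))
    pv <- utils::read.csv(file.path(out, "percent_variance.csv"))
    basis <- utils::read.csv(file.path(out, "pca_basis.csv"))
    pca <- list(rotation = as.matrix(basis[, -1L, drop = FALSE]),
                reference_mean = basis$mean,
                eigenvalues = pv$eigenvalue)
    class(pca) <- "shape_pca"
    fig <- function(name, code) {
      path <- file.path(out, paste0(name, ".png"))
      grDevices::png(path, width = 1000, height = 800, res = 120)
      on.exit(grDevices::dev.off(), add = TRUE)
      code()
      figures <<- c(figures, path)
    }
    fig("morphospace", function() {
      plot(scores$PC1, scores$PC2, pch = 19,
           col = grDevices::adjustcolor("steelblue", 0.6),
           xlab = sprintf("PC1 (%.1f%%)", pv$percent[1L]),
           ylab = sprintf("PC2 (%.1f%%)", pv$percent[2L]),
           main = "Morphospace with backtransform shapes")
      if (ncol(pca$rotation) >= 2L) {
        gx <- stats::quantile(scores$PC1, c(0.05, 0.5, 0.95))
        gy <- stats::quantile(scores$PC2, c(0.05, 0.5, 0.95))
        sc <- 0.12 * diff(range(scores$PC1))
        for (a in gx) for (b in gy) {
          sh <- backtransform(pca, c(a, b))
          sh <- sh - matrix(colMeans(sh), nrow(sh), 2L, byrow = TRUE)
          graphics::lines(a + sc * sh[, 1L], b + sc * sh[, 2L],
                          col = "grey60")
        }
        graphics::points(scores$PC1, scores$PC2, pch = 19,
                         col = grDevices::adjustcolor("steelblue", 0.6))
      }
    })
    disp_path <- file.path(out, "disparity_by_bin.csv")
    if (file.exists(disp_path)) {
      disp <- utils::read.csv(disp_path)
      fig("disparity_trajectory", function() {
        xi <- seq_len(nrow(disp))
        plot(xi, disp$pv, type = "b", pch = 19, xaxt = "n",
             ylim = range(c(disp$ci_low, disp$ci_high, disp$pv),
                          na.rm = TRUE),
             xlab = "time bin", ylab = "Procrustes variance",
             main = "Disparity through time (bootstrap 95% CI)")
        graphics::axis(1, at = xi, labels = disp$bin, cex.axis = 0.8)
        graphics::arrows(xi, disp$ci_low, xi, disp$ci_high, angle = 90,
                         code = 3, length = 0.04)
      })
    }
  } else {
    warning("png device unavailable; figures skipped")
  }
  files <- list.files(out, recursive = TRUE)
  manifest <- data.frame(file = files,
                         bytes = file.size(file.path(out, files)))
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  log_line(config, "report: %d file(s) in manifest", nrow(manifest))
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (for scenario input), align, ordinate, disparity,
#' stats, and report in order, writing CSV tables and figures to the
#' configured output directory. Each stage reads its predecessor's
#' serialized outputs, so stage-wise and monolithic execution produce
#' identical files; all stochastic routines derive per-stage child seeds
#' from the global seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a result bundle: list(config, tables, manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cat(sprintf("toothdisp %s run, seed %d\n",
              as.character(utils::packageVersion("toothdisp")), config$seed),
      file = file.path(config$out_dir, "log.txt"))
  for (stage in list(stage_simulate, stage_align, stage_ordinate,
                     stage_disparity, stage_stats, stage_report)) {
    config <- tryCatch(stage(config), error = function(e)
      stop("pipeline stage failed: ", conditionMessage(e), call. = FALSE))
  }
  tables <- list.files(config$out_dir, pattern = "\\.csv$")
  bundle <- list(config = config,
                 tables = stats::setNames(
                   lapply(tables, function(f)
                     utils::read.csv(file.path(config$out_dir, f))),
                   sub("\\.csv$", "", tables)),
                 manifest = utils::read.csv(file.path(config$out_dir,
                                                      "manifest.csv")))
  invisible(bundle)
}

#' Command-line interface
#'
#' `Rscript inst/cli/toothdisp.R <subcommand> --config FILE [--seed INT]
#' [--out DIR]` with subcommands simulate, align, ordinate, disparity,
#' stats, report, or run (all stages).
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0 on success (invisibly).
#' @export
toothdisp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- list(simulate = stage_simulate, align = stage_align,
                 ordinate = stage_ordinate, disparity = stage_disparity,
                 stats = stage_stats, report = stage_report,
                 run = run_pipeline)
  if (!length(args) || !args[1L] %in% names(stages))
    stop("usage: toothdisp <", paste(names(stages), collapse = "|"),
         "> --config FILE [--seed INT] [--out DIR]")
  sub <- args[1L]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) stop("--config FILE is required")
  config <- read_pipeline_config(cfg_path)
  if (!is.null(opt("--seed"))) config$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--out"))) config$out_dir <- opt("--out")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (sub != "run" && !file.exists(file.path(config$out_dir, "log.txt")))
    cat("", file = file.path(config$out_dir, "log.txt"))
  stages[[sub]](config)
  invisible(0L)
}
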