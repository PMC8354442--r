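test_that("read_tps parses minimal and multi-record files", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=t1"), f)
  got <- read_tps(f)
  expect_length(got, 1L)
  expect_identical(got[[1L]]$specimen_id, "t1")
  expect_equal(got[[1L]]$points, matrix(c(0, 1, 0, 0, 0, 1), 3L, 2L),
               ignore_attr = TRUE)

  # two 160-point records, built programmatically
  cfgs <- lapply(1:2, function(i)
    make_tooth(tooth_params(crown_height = 1 + i / 2), k = 160L,
               specimen_id = paste0("s", i)))
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(cfgs, f2)
  expect_identical(readLines(f2)[1L], "LM=160")
  back <- read_tps(f2)
  expect_length(back, 2L)
  expect_true(all(vapply(back, function(cf) nrow(cf$points), integer(1)) ==
                    160L))
})

test_that("tps round trip preserves coordinates, ids and scale", {
  cfgs <- toy_configs(30L, k = 12L, seed = 7L)
  cfgs[[3L]]$scale <- 0.042
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(cfgs, f)
  back <- read_tps(f)
  for (i in seq_along(cfgs)) {
    expect_equal(back[[i]]$points, cfgs[[i]]$points, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
  }
  expect_equal(back[[3L]]$scale, 0.042)
  # empty list -> empty file
  f0 <- withr::local_tempfile(fileext = ".tps")
  write_tps(list(), f0)
  expect_identical(readLines(f0), character(0))
})

test_that("malformed TPS input errors name the problem", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=5", "0 0", "1 1", "ID=t"), f)
  expect_error(read_tps(f), "LM=5")
  writeLines(c("LM=2", "0 0", "a b", "ID=t"), f)
  expect_error(read_tps(f), "non-numeric")
  writeLines(c("LM=1", "0 0", "ID=t", "LM=1", "1 1", "ID=t"), f)
  expect_error(read_tps(f), "duplicate")
  expect_error(write_tps(list(landmark_config(matrix(0, 3, 2))), f),
               NA)  # fine
  bad <- landmark_config(matrix(0.5, 3, 2))
  bad$points[2L, 1L] <- NA_real_
  expect_error(write_tps(list(bad), f), "non-finite")
})

test_that("read_sliders validates triples and the standard scheme", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "2 3 4"), f)
  tab <- read_sliders(f)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$slider, c(2L, 3L))

  # standard 160-point scheme: 157 slider rows
  f160 <- withr::local_tempfile(fileext = ".txt")
  write_sliders(make_slider_table(160L), f160)
  tab160 <- read_sliders(f160, k = 160L, fixed = standard_fixed_indices(160L))
  expect_equal(nrow(tab160), 157L)

  writeLines(c("before slider after", "5 5 6"), f)
  expect_error(read_sliders(f), "neighbour")
  writeLines(c("1 2 3", "1 2 3"), f)
  expect_error(read_sliders(f), "more than once")
  writeLines("1 2 9", f)
  expect_error(read_sliders(f, k = 5L), "out of range")
})

test_that("resample_open_curve spaces points by arc length", {
  seg <- resample_open_curve(rbind(c(0, 0), c(0, 9)), 4L)
  expect_equal(seg, rbind(c(0, 0), c(0, 3), c(0, 6), c(0, 9)),
               ignore_attr = TRUE)

  # idempotence on an already-equidistant curve
  eq <- cbind(seq(0, 1, length.out = 11L), 0)
  expect_equal(resample_open_curve(eq, 11L), eq, tolerance = 1e-12,
               ignore_attr = TRUE)

  # dense unit semicircle -> arc angles {0, pi/4, ..., pi}
  th <- seq(0, pi, length.out = 4000L)
  semi <- cbind(cos(th), sin(th))
  out <- resample_open_curve(semi, 5L)
  expect_equal(atan2(out[, 2L], out[, 1L]), seq(0, pi, by = pi / 4),
               tolerance = 1e-3)

  # equal consecutive arc-length spacing for random polylines (property);
  # arc positions recomputed independently by walking the input polyline
  arc_position <- function(crv, pts) {
    seg <- sqrt(rowSums(diff(crv)^2))
    cum <- c(0, cumsum(seg))
    vapply(seq_len(nrow(pts)), function(i) {
      p <- pts[i, ]
      best <- Inf; pos <- NA_real_
      for (s in seq_len(nrow(crv) - 1L)) {
        a <- crv[s, ]; b <- crv[s + 1L, ]
        tt <- sum((p - a) * (b - a)) / max(sum((b - a)^2), 1e-300)
        tt <- min(max(tt, 0), 1)
        d2 <- sum((a + tt * (b - a) - p)^2)
        if (d2 < best) { best <- d2; pos <- cum[s] + tt * seg[s] }
      }
      pos
    }, numeric(1))
  }
  for (s in 1:5) {
    set.seed(s)
    crv <- apply(matrix(rnorm(20L), 10L, 2L), 2L, cumsum)
    out <- resample_open_curve(crv, 23L)
    d <- diff(arc_position(crv, out))
    expect_lt(diff(range(d)) / mean(d), 1e-9)
  }
  expect_error(resample_open_curve(rbind(c(1, 1), c(1, 1)), 3L),
               "zero-length")
})

test_that("assemble_configuration reproduces the standard partition", {
  expect_identical(semilandmark_partition(160L),
                   c(mesial = 79L, distal = 78L))
  expect_identical(semilandmark_partition(7L), c(mesial = 2L, distal = 2L))
  th <- seq(0, 1, length.out = 50L)
  anchors <- rbind(c(-0.5, 0), c(0, 1.5), c(0.5, 0))
  mes <- cbind(-0.5 + 0.5 * th, 1.5 * th)
  dis <- cbind(0.5 * th, 1.5 * (1 - th))
  for (k in c(40L, 60L, 80L, 100L, 120L, 140L, 160L)) {
    cfg <- assemble_configuration(anchors, mes, dis, k = k)
    expect_equal(nrow(cfg$points), k)
    expect_identical(cfg$fixed, standard_fixed_indices(k))
  }
  expect_error(assemble_configuration(anchors, mes, dis, k = 4L), "k >= 5")
})

test_that("normalize_orientation mirrors and is idempotent", {
  cfg <- make_tooth(tooth_params(crown_height = 2, recurvature = 0.3),
                    k = 20L)
  norm1 <- normalize_orientation(cfg, "labial")
  fx <- norm1$fixed
  expect_lte(norm1$points[fx[2L], 1L], norm1$points[fx[1L], 1L] + 1e-12)
  expect_lte(norm1$points[fx[2L], 1L], norm1$points[fx[3L], 1L] + 1e-12)
  # idempotent
  norm2 <- normalize_orientation(norm1, "labial")
  expect_equal(norm2$points, norm1$points, tolerance = 1e-9)
  # a lingual tooth and its labial mirror twin coincide after normalization
  lingual <- toothdisp:::mirror_config(cfg)
  expect_equal(normalize_orientation(lingual, "lingual")$points,
               norm1$points, tolerance = 1e-9)
})

test_that("assign_bins applies schemes and partitions the sample", {
  md <- data.frame(specimen_id = sprintf("s%d", 1:6),
                   age_label = c("Campanian", "Maastrichtian", "Danian",
                                 "Selandian", "Thanetian", "Danian"))
  b5 <- assign_bins(md, "five_age")
  expect_identical(as.character(b5$bin[3L]), "Danian")
  b4 <- assign_bins(md, "four_age")
  expect_identical(as.character(b4$bin[3L]), "Danian-Selandian")
  expect_identical(as.character(b4$bin[4L]), "Danian-Selandian")
  expect_identical(as.character(b4$bin[1L]), "Campanian")
  expect_identical(as.character(b5$bin[1L]), "Campanian")
  # partition: per-bin counts sum to retained total
  expect_equal(sum(attr(b4, "bin_counts")), nrow(md))
  # chronological midpoints strictly decrease with bin order
  sch <- binning_scheme("five_age")
  expect_true(all(diff(sch$bin_mid_ma) < 0))

  md$age_label[2L] <- "Jurassic"
  expect_error(assign_bins(md, "five_age"), "Jurassic")
  expect_warning(b <- assign_bins(md, "five_age", strict = FALSE),
                 "Jurassic")
  expect_equal(nrow(b), 5L)
})
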