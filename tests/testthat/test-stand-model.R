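test_that("plot geometry derives area and enforces quadrat divisibility", {
  g <- plot_geometry(800, 320)
  expect_equal(g$area_ha, 25.6)
  expect_error(plot_geometry(810, 320), "integer multiples")
  expect_error(plot_geometry(-10, 320), "positive")
  expect_error(plot_geometry(100, 100, 0), "positive")
})

test_that("diameter classification uses an inclusive large threshold", {
  stems <- data.frame(tag = c("t1", "t2", "t3"),
                      dbh_cm = c(99.9, 100.0, 100.1))
  cl <- classify_diameter(stems)
  expect_equal(cl$small$tag, "t1")
  expect_equal(sort(cl$large$tag), c("t2", "t3"))
  # degenerate threshold: everything is large
  expect_equal(nrow(classify_diameter(stems, 1)$large), 3)
  expect_error(classify_diameter(stems, -5), "parameter error")
})

test_that("diameter partition is exhaustive and disjoint at any threshold", {
  set.seed(11)
  stems <- data.frame(tag = as.character(1:500),
                      dbh_cm = 1 + rexp(500, 0.05))
  for (thr in c(1, 10, 50, 100, 500)) {
    cl <- classify_diameter(stems, thr)
    expect_equal(nrow(cl$large) + nrow(cl$small), nrow(stems))
    expect_length(intersect(cl$large$tag, cl$small$tag), 0)
    expect_true(all(cl$large$dbh_cm >= thr))
    expect_true(all(cl$small$dbh_cm < thr))
  }
})

test_that("quadrat summaries conserve counts and basal area", {
  expect_equal(nrow(quadratize(stand_dataset(plot_geometry(800, 320)))), 640)

  st <- tiny_stand()
  q <- quadratize(st)
  expect_equal(nrow(q), 5 * 4)
  expect_equal(sum(q$n_stems), nrow(st$stems))
  expect_equal(sum(q$basal_area_m2), sum(basal_area_m2(st$stems$dbh_cm)))
  # stem at the origin sits in quadrat (0, 0)
  expect_equal(q$n_stems[q$qx == 0 & q$qy == 0], 1)

  # far-boundary stem is mapped into the last quadrat, not rejected
  geom <- plot_geometry(100, 80, 20)
  edge <- stand_dataset(geom, stems = data.frame(
    tag = "e", species = "ABCO", dbh_cm = 10, x_m = 100, y_m = 80,
    status = "live", stringsAsFactors = FALSE))
  qe <- quadratize(edge)
  expect_equal(qe$n_stems[qe$qx == 4 & qe$qy == 3], 1)

  # conservation on a generated stand
  stand <- generate_stand(small_config(3L))
  qs <- quadratize(stand)
  expect_equal(sum(qs$n_stems), nrow(stand$stems))
  expect_equal(sum(qs$basal_area_m2),
               sum(basal_area_m2(stand$stems$dbh_cm)))
})

test_that("validation rejects out-of-window and undersized records by tag", {
  geom <- plot_geometry(100, 80, 20)
  bad_coord <- data.frame(tag = c("x1", "x2", "x3"), species = "ABCO",
                          dbh_cm = 10, x_m = c(5, -1, 20), y_m = 5,
                          status = "live", stringsAsFactors = FALSE)
  expect_error(stand_dataset(geom, stems = bad_coord), "x2")
  small_live <- data.frame(tag = "s1", species = "ABCO", dbh_cm = 0.5,
                           x_m = 5, y_m = 5, status = "live",
                           stringsAsFactors = FALSE)
  expect_error(stand_dataset(geom, stems = small_live), "dbh < 1")
  dup <- data.frame(tag = c("d", "d"), species = "ABCO", dbh_cm = 10,
                    x_m = 5, y_m = 5, status = "live",
                    stringsAsFactors = FALSE)
  expect_error(stand_dataset(geom, stems = dup), "duplicated")
  bad_snag <- data.frame(tag = "n1", species = "ABCO", dbh_cm = 20,
                         height_m = 10, top_diameter_cm = 30,
                         decay_class = 2, x_m = 5, y_m = 5,
                         stringsAsFactors = FALSE)
  expect_error(stand_dataset(geom, snags = bad_snag), "top diameter")
})

test_that("an empty stems layer round-trips as zero records", {
  dir <- withr::local_tempdir()
  write_stand(stand_dataset(plot_geometry(100, 80, 20)), dir)
  back <- read_stand(dir)
  expect_equal(nrow(back$stems), 0)
  expect_equal(back$geometry$area_ha, 0.8)
})

test_that("write/read round-trip is lossless for all layers", {
  stand <- generate_stand(small_config(5L))
  dir <- withr::local_tempdir()
  write_stand(stand, dir)
  back <- read_stand(dir)
  for (layer in c("stems", "snags", "demography", "transects",
                  "intercepts")) {
    expect_equal(back[[layer]], stand[[layer]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(back$shrub_patches$area_m2, stand$shrub_patches$area_m2,
               tolerance = 1e-9)
  expect_equal(back$shrub_patches$polygon[[3]],
               unname(stand$shrub_patches$polygon[[3]]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("malformed numeric cells are reported with line numbers", {
  dir <- withr::local_tempdir()
  write_stand(generate_stand(small_config(5L)), dir)
  lines <- readLines(file.path(dir, "stems.csv"))
  parts <- strsplit(lines[3], ",")[[1]]
  parts[3] <- "notanumber"
  lines[3] <- paste(parts, collapse = ",")
  writeLines(lines, file.path(dir, "stems.csv"))
  expect_error(read_stand(dir), "line")
})
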