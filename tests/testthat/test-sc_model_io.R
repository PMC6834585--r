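# Point-file and JSON model I/O, calibration, scaling, validation.

make_point_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

role_map4 <- c(`1` = "LE_left", `2` = "LE_right", `3` = "CE", `4` = "TF")

basic_lines <- c(
  "1 1 0 0 0",  "1 1 1 0 0",  "1 1 0 1 0",  "1 1 0 0 1",
  "2 1 10 0 0", "2 1 11 0 0", "2 1 10 1 0", "2 1 10 0 1",
  "3 1 5 0 0",  "3 1 6 0 0",  "3 1 5 1 0",  "3 1 5 0 1",
  "4 1 1 2 3",  "4 1 4 5 6",  "4 1 7 8 9",
  "4 2 1 1 1",  "4 2 2 2 2")

test_that("point files parse with grouping and counts conserved", {
  path <- make_point_file(basic_lines)
  m <- read_point_model(path, role_map4)
  expect_s3_class(m, "sc_model")
  expect_equal(m$units, "px")
  expect_length(m$tfs, 2)
  expect_equal(nrow(m$tfs[[1]]$points), 3)
  expect_equal(unname(m$tfs[[1]]$points[2, ]), c(4, 5, 6))
  expect_equal(nrow(m$le_left$points), 4)
  expect_equal(unname(m$le_left$points[1, ]), c(0, 0, 0))
})

test_that("malformed and incomplete point files are rejected with context", {
  expect_error(read_point_model(make_point_file(c("1 1 10 20 5", "1 1 3")),
                                role_map4),
               "line 2.*expected 5")
  expect_error(read_point_model(make_point_file("1 1 10 abc 5"), role_map4),
               "line 1.*non-numeric")
  # 3-column files (no object grouping) are ambiguous, never guessed
  expect_error(read_point_model(make_point_file("10 20 5"), role_map4),
               "expected 5")
  expect_error(read_point_model(make_point_file(basic_lines),
                                c(`1` = "LE_left")),
               "missing from role_map")
  no_tf <- basic_lines[1:12]
  expect_error(read_point_model(make_point_file(no_tf), role_map4),
               "no TF objects")
})

test_that("write/read round trip is lossless, including slab regions", {
  g <- gen_quiet(generator_config(sc_length_nm = 300), seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_point_model(g$model, path)
  m2 <- read_point_model(path)
  expect_equal(m2$units, "nm")
  expect_length(m2$tfs, length(g$model$tfs))
  for (i in seq_along(m2$tfs))
    expect_identical(unname(m2$tfs[[i]]$points),
                     unname(g$model$tfs[[i]]$points))
  expect_equal(m2$ce$variant, "slab")
  expect_identical(m2$ce$half_extents, g$model$ce$half_extents)
  # write -> read -> write reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_point_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
  # writing a TF-free model is a content error
  m_bad <- g$model
  m_bad$tfs <- list()
  expect_error(write_point_model(m_bad, path2), "no TFs")
})

test_that("native JSON model round trip is exact for both region variants", {
  for (style in c("slab", "cloud")) {
    g <- gen_quiet(generator_config(sc_length_nm = 200,
                                    region_style = style), seed = 4)
    path <- withr::local_tempfile(fileext = ".json")
    write_sc_json(g$model, path)
    m2 <- read_sc_json(path)
    expect_equal(m2$ce$variant,
                 if (style == "slab") "slab" else "point_cloud")
    for (i in seq_along(m2$tfs))
      expect_identical(unname(m2$tfs[[i]]$points),
                       unname(g$model$tfs[[i]]$points))
    if (style == "cloud")
      expect_identical(unname(m2$le_left$points),
                       unname(g$model$le_left$points))
  }
})

test_that("z-factor follows thickness over reconstructed extent", {
  expect_equal(compute_z_factor(250, 250 / 0.287, 0.287), 1.0)
  expect_equal(compute_z_factor(250, 600, 0.287), 250 / 172.2)
  expect_equal(compute_z_factor(125, 600, 0.287),
               compute_z_factor(250, 600, 0.287) / 2)
  expect_error(compute_z_factor(0, 600, 0.287), "positive")
})

test_that("scaling converts px to nm, stretching z by the z-factor", {
  pts <- rbind(c(100, 200, 50), c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))
  m <- sc_model(sc_region_cloud("LE_left", pts),
                sc_region_cloud("LE_right", pts + 10),
                sc_region_cloud("CE", pts + 5),
                list(sc_polyline(rbind(c(100, 200, 50), c(0, 0, 0)))),
                scale = sc_scale(0.287, z_factor = 1), units = "px")
  m1 <- apply_scaling(m)
  expect_equal(unname(m1$tfs[[1]]$points[1, ]), c(28.7, 57.4, 14.35))
  expect_equal(m1$units, "nm")
  m2 <- apply_scaling(m, sc_scale(0.287, z_factor = 2))
  expect_equal(unname(m2$tfs[[1]]$points[1, ]), c(28.7, 57.4, 28.7))
  expect_equal(unname(m2$tfs[[1]]$points[1, 1:2]),
               unname(m1$tfs[[1]]$points[1, 1:2]))
  # structure preserved; already-scaled models refuse a second pass
  expect_length(m1$tfs, 1)
  expect_equal(nrow(m1$le_left$points), 4)
  expect_error(apply_scaling(m1), "already scaled")
  # invertibility
  back <- sweep(m2$tfs[[1]]$points, 2, c(0.287, 0.287, 0.287 * 2), `/`)
  expect_equal(unname(back), unname(m$tfs[[1]]$points), tolerance = 1e-9)
})

test_that("validate_model reports without raising", {
  g <- gen_quiet(generator_config(sc_length_nm = 300), seed = 2)
  expect_equal(nrow(validate_model(g$model)), 0)

  m <- g$model
  # a degenerate single-point TF cannot be built via sc_polyline; inject
  m$tfs[[1]]$points <- m$tfs[[1]]$points[1, , drop = FALSE]
  iss <- validate_model(m)
  expect_true("degenerate_tf" %in% iss$kind)

  px_big <- sc_model(
    sc_region_cloud("LE_left", matrix(runif(12, 2e4, 3e4), 4)),
    sc_region_cloud("LE_right", matrix(runif(12, 2e4, 3e4), 4)),
    sc_region_cloud("CE", matrix(runif(12, 2e4, 3e4), 4)),
    list(sc_polyline(rbind(c(2e4, 2e4, 2e4), c(3e4, 3e4, 3e4)))),
    units = "px")
  expect_true("scale_warning" %in% validate_model(px_big)$kind)
})
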