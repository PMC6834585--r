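# Morphometrics: segment lengths, widths, nearest neighbors, pairing,
# asymmetry, densities, rank-sum test and cohort pooling.

# one-TF model around the canonical straight-filament scene
scene_model <- function() {
  sc <- straight_tf_scene()
  le_right <- slab("LE_right", c(250, 0, 0), c(30, 50, 50))
  sc_model(le_left = sc$le, le_right = le_right, ce = sc$ce,
           tfs = list(sc$tf), units = "nm")
}

test_that("segment metrics reconstruct the embedded-portion geometry", {
  tm <- compute_tf_metrics(scene_model())
  expect_equal(tm$side, "left")
  expect_equal(tm$le_indent, 21, tolerance = 1e-7)
  expect_equal(tm$midsection, 53, tolerance = 1e-7)
  expect_equal(tm$ce_indent, 14, tolerance = 1e-7)
  expect_equal(tm$len_total, 88)
})

test_that("sides match ground truth on synthetic cohorts", {
  coh <- suppressWarnings(
    generate_cohort(generator_config(sc_length_nm = 1000), 2, seed = 21))
  match_rate <- vapply(coh, function(g) {
    sides <- assign_tf_sides(g$model)
    mean(sides$side == g$truth$tf$side)
  }, numeric(1))
  expect_gte(min(match_rate), 0.99)
})

test_that("zero-noise slab models reproduce ground truth per TF exactly", {
  g <- generate_sc(identity_config(), seed = 13)
  tm <- compute_tf_metrics(g$model)
  expect_equal(tm$le_indent, g$truth$tf$le_indent, tolerance = 1e-7)
  expect_equal(tm$ce_indent, g$truth$tf$ce_indent, tolerance = 1e-7)
  expect_equal(tm$midsection, g$truth$tf$midsection, tolerance = 1e-7)
  expect_equal(tm$len_total, g$truth$tf$len_total, tolerance = 1e-9)
})

test_that("cloud and slab regions give matching metrics", {
  cfgS <- generator_config(sc_length_nm = 300, endpoint_jitter_sd_nm = 1)
  cfgC <- generator_config(sc_length_nm = 300, endpoint_jitter_sd_nm = 1,
                           region_style = "cloud")
  gs <- gen_quiet(cfgS, seed = 7)
  gc <- gen_quiet(cfgC, seed = 7)
  expect_identical(gs$model$tfs, gc$model$tfs)
  ms <- compute_tf_metrics(gs$model)
  mc <- compute_tf_metrics(gc$model)
  tol <- generator_config()$element_cloud_spacing_nm + 0.01
  expect_lt(max(abs(ms$le_indent - mc$le_indent), na.rm = TRUE), tol)
  expect_lt(max(abs(ms$ce_indent - mc$ce_indent), na.rm = TRUE), tol)
})

test_that("width samples follow nearest-neighbor geometry", {
  # perpendicular zero-noise SC with directly opposing TFs
  g <- generate_sc(identity_config(), seed = 14)
  w <- compute_region_widths(compute_tf_metrics(g$model))
  expect_equal(mean(w$cr_width), 114, tolerance = 1e-6)
  expect_equal(mean(w$ce_width), 29, tolerance = 1e-6)
  expect_equal(mean(w$le_ce), 42.5, tolerance = 1e-6)

  # two lone TFs offset laterally: closed-form hypotenuse
  tf_l <- sc_polyline(rbind(c(0, -60, 0), c(0, -10, 0)))
  tf_r <- sc_polyline(rbind(c(10, 60, 0), c(10, 10, 0)))
  m <- sc_model(slab("LE_left", c(0, -77, 0), c(100, 20, 50)),
                slab("LE_right", c(0, 77, 0), c(100, 20, 50)),
                slab("CE", c(0, 0, 0), c(100, 14.5, 50)),
                list(tf_l, tf_r), units = "nm")
  w2 <- compute_region_widths(compute_tf_metrics(m))
  expect_equal(w2$cr_width, rep(sqrt(114^2 + 10^2), 2), tolerance = 1e-6)

  # estimator bias: measured CR width never undershoots the planted gap
  for (s in 1:5) {
    g <- gen_quiet(generator_config(sc_length_nm = 400), seed = 30 + s)
    w3 <- compute_region_widths(compute_tf_metrics(g$model))
    expect_gte(min(w3$cr_width), 114 - 6 * 2)  # allow endpoint jitter only
    expect_gte(mean(w3$cr_width), 114)
  }
})

test_that("CE and LE nearest neighbors match brute force", {
  g <- gen_quiet(generator_config(sc_length_nm = 3200), seed = 15)
  tm <- compute_le_nn(compute_ce_nn(compute_tf_metrics(g$model)))
  expect_gte(nrow(tm), 250)
  ce <- cbind(tm$ce_end_x, tm$ce_end_y, tm$ce_end_z)
  le <- cbind(tm$le_end_x, tm$le_end_y, tm$le_end_z)
  for (i in seq(1, nrow(tm), by = 17)) {
    same <- which(tm$side == tm$side[i])
    opp <- which(tm$side == setdiff(c("left", "right"), tm$side[i]))
    expect_identical(tm$nn_opposite[i],
                     brute_nn(ce[i, ], ce[opp, , drop = FALSE])$distance)
    expect_identical(tm$nn_parallel[i],
                     brute_nn(ce[i, ], ce[same, , drop = FALSE],
                              exclude_self = TRUE)$distance)
    expect_identical(tm$nn_le[i],
                     brute_nn(le[i, ], le[same, , drop = FALSE],
                              exclude_self = TRUE)$distance)
  }
})

test_that("lone TFs yield NA nearest neighbors, not errors", {
  m <- scene_model()  # single left-side TF
  tm <- compute_le_nn(compute_ce_nn(compute_tf_metrics(m)))
  expect_true(is.na(tm$nn_opposite))
  expect_true(is.na(tm$nn_parallel))
  expect_true(is.na(tm$nn_le))
})

test_that("pairing classification follows the threshold rule", {
  tm <- data.frame(side = c("left", "left", "right", "left"),
                   nn_opposite = c(8, 30, 25, NA),
                   nn_parallel = c(3, 10, 40, NA))
  out <- classify_pairings(tm, threshold = 15)
  expect_equal(out$pairing, c("opposite", "parallel", "single", "single"))
  # planted-mixture recovery on a default synthetic cohort
  g <- gen_quiet(generator_config(sc_length_nm = 2000), seed = 16)
  tm2 <- classify_pairings(compute_ce_nn(compute_tf_metrics(g$model)))
  expect_gte(mean(tm2$pairing == g$truth$tf$pairing), 0.9)
})

test_that("asymmetry is the count difference over the larger side", {
  expect_equal(compute_asymmetry(100, 79), 21)
  expect_equal(compute_asymmetry(50, 50), 0)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(1:200, 2)
    expect_equal(compute_asymmetry(n[1], n[2]),
                 compute_asymmetry(n[2], n[1]))
  }
  expect_error(compute_asymmetry(0, 10), "no TFs")
})

test_that("densities derive from the projected bounding rectangle", {
  g <- generate_sc(identity_config(), seed = 18)
  tm <- compute_tf_metrics(g$model)
  d <- compute_density(tm, g$model)
  expect_equal(d$rect$length, 2000, tolerance = 1e-6)
  expect_equal(d$tfs_per_um, 79, tolerance = 1e-6)
  expect_equal(d$tfs_per_um2, 79 / 0.0755, tolerance = 1e-6)
  # doubling the TFs at a fixed rectangle doubles both densities
  m2 <- g$model
  m2$tfs <- c(m2$tfs, m2$tfs)
  tm2 <- compute_tf_metrics(m2)
  d2 <- compute_density(tm2, m2)
  expect_equal(d2$tfs_per_um, 2 * d$tfs_per_um, tolerance = 1e-6)
  expect_equal(d2$tfs_per_um2, 2 * d$tfs_per_um2, tolerance = 1e-6)
})

test_that("rank-sum test matches full enumeration and handles modes", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, enum_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(rank_sum_test(1, 1)$p_value, 1)

  set.seed(19)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    expect_equal(rank_sum_test(x, y)$p_value, enum_rank_sum_p(x, y))
  }

  x <- rnorm(20); y <- rnorm(20, 0.1)
  pe <- rank_sum_test(x, y, mode = "exact")$p_value
  pn <- rank_sum_test(x, y, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.01)
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("cohort pooling concatenates samples rather than averaging means", {
  coh <- suppressWarnings(
    generate_cohort(generator_config(sc_length_nm = 700), 2, seed = 20))
  results <- lapply(coh, function(g) sc_quantify_model(g$model))
  pooled1 <- summarize_cohort(results[1])$pooled
  expect_equal(pooled1$tf_len_mean, results[[1]]$summary$tf_len_mean)
  expect_equal(pooled1$cr_width_sd, results[[1]]$summary$cr_width_sd)

  pooled <- summarize_cohort(results)$pooled
  all_len <- c(results[[1]]$tf$len_total, results[[2]]$tf$len_total)
  expect_equal(pooled$tf_len_mean, mean(all_len))
  expect_equal(pooled$tf_len_sd, sd(all_len))
  all_cr <- c(results[[1]]$widths$cr_width, results[[2]]$widths$cr_width)
  expect_equal(pooled$cr_width_mean, mean(all_cr))
  expect_equal(pooled$cr_width_sd, sd(all_cr))
})
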