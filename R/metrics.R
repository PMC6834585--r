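# Per-tomogram morphometrics: filament segment lengths via region
# intersections, width samples via nearest neighbors between intersection
# points, CE/LE nearest-neighbor statistics, pairing classes, asymmetry,
# densities from projected bounding rectangles, and cohort pooling.

#' Quantification configuration
#'
#' @param delta_nm membership radius for point-cloud element regions (nm).
#' @param pairing_threshold_nm nearest-neighbor threshold below which a
#'   CE endpoint counts as paired; opposite takes precedence over
#'   parallel. Default 15 nm, below both reported CE NN means (17, 20 nm)
#'   so only markedly close neighbors count as pairs.
#' @param density_site `"CE"` (CE intersection points; the reported
#'   densities are measured at the CE insertion site), `"LE_left"` or
#'   `"LE_right"` (LE endpoints of that side).
#' @param min_tf_points minimum vertices for a TF to be quantified.
#' @return list of class `sc_quant_config`.
#' @export
quant_config <- function(delta_nm = 4, pairing_threshold_nm = 15,
                         density_site = c("CE", "LE_left", "LE_right"),
                         min_tf_points = 2) {
  if (delta_nm <= 0 || pairing_threshold_nm <= 0 || min_tf_points < 2)
    stop("config error: quantification parameters must be positive")
  structure(list(delta_nm = delta_nm,
                 pairing_threshold_nm = pairing_threshold_nm,
                 density_site = match.arg(density_site),
                 min_tf_points = min_tf_points),
            class = "sc_quant_config")
}

#' Assign each transverse filament to a lateral element side
#'
#' The endpoint closer to a lateral element is taken as the LE end; the
#' filament's side is that element's. A trace whose putative CE end also
#' lies inside the same LE is flagged `unresolved` (suspect segmentation)
#' and excluded from side-specific statistics downstream.
#'
#' @param model scaled `sc_model` (units nm).
#' @param config a [quant_config()].
#' @return data.frame: `tf`, `label`, `side` (`left`/`right`/`unresolved`),
#'   `le_end` (`first`/`last`).
#' @export
assign_tf_sides <- function(model, config = quant_config()) {
  if (model$units != "nm") stop("model must be scaled to nm first")
  les <- list(left = model$le_left, right = model$le_right)
  rows <- lapply(seq_along(model$tfs), function(i) {
    pts <- model$tfs[[i]]$points
    ends <- pts[c(1, nrow(pts)), , drop = FALSE]
    d <- vapply(les, function(le)
      c(point_region_distance(ends[1, ], le),
        point_region_distance(ends[2, ], le)), numeric(2))
    le_end_i <- which.min(c(min(d[1, ]), min(d[2, ])))
    side <- names(les)[which.min(d[le_end_i, ])]
    other <- 3 - le_end_i
    if (is_member(ends[other, ], les[[side]], config$delta_nm))
      side <- "unresolved"
    data.frame(tf = i, label = model$tfs[[i]]$label, side = side,
               le_end = c("first", "last")[le_end_i])
  })
  do.call(rbind, rows)
}

#' Per-filament segment metrics
#'
#' For each TF: the intersection point with its own-side lateral element
#' (walking from the LE end) and with the central element (walking from
#' the CE end); the LE indent (LE endpoint to LE intersection), the CE
#' indent (CE endpoint to CE intersection), the midsection (between the
#' two intersections) and the total length (endpoint to endpoint), all
#' Euclidean. Filaments missing an intersection keep `NA` in the affected
#' fields and are excluded from the affected summaries only.
#'
#' @inheritParams assign_tf_sides
#' @return data.frame with one row per TF: side, endpoint and
#'   intersection coordinates, and `len_total`, `le_indent`, `ce_indent`,
#'   `midsection` in nm.
#' @export
compute_tf_metrics <- function(model, config = quant_config()) {
  sides <- assign_tf_sides(model, config)
  les <- list(left = model$le_left, right = model$le_right)
  rows <- lapply(seq_along(model$tfs), function(i) {
    poly <- model$tfs[[i]]
    pts <- poly$points
    out <- data.frame(tf = i, label = poly$label, side = sides$side[i],
                      le_end = sides$le_end[i])
    skip <- nrow(pts) < config$min_tf_points || sides$side[i] == "unresolved"
    idx <- if (sides$le_end[i] == "first") c(1, nrow(pts)) else c(nrow(pts), 1)
    p_le <- pts[idx[1], ]; p_ce <- pts[idx[2], ]
    out[, c("le_end_x", "le_end_y", "le_end_z")] <- as.list(p_le)
    out[, c("ce_end_x", "ce_end_y", "ce_end_z")] <- as.list(p_ce)
    out$len_total <- vnorm(p_le - p_ce)
    xle <- xce <- c(NA_real_, NA_real_, NA_real_)
    if (!skip) {
      hit <- polyline_region_intersection(poly, les[[sides$side[i]]],
                                          delta = config$delta_nm,
                                          from_end = sides$le_end[i])
      if (!is.null(hit$point) && !hit$interior) xle <- hit$point
      hit <- polyline_region_intersection(poly, model$ce,
                                          delta = config$delta_nm,
                                          from_end = if (sides$le_end[i] == "first") "last" else "first")
      if (!is.null(hit$point) && !hit$interior) xce <- hit$point
    }
    out[, c("x_le_x", "x_le_y", "x_le_z")] <- as.list(xle)
    out[, c("x_ce_x", "x_ce_y", "x_ce_z")] <- as.list(xce)
    out$le_indent <- if (anyNA(xle)) NA_real_ else vnorm(p_le - xle)
    out$ce_indent <- if (anyNA(xce)) NA_real_ else vnorm(p_ce - xce)
    out$midsection <- if (anyNA(xle) || anyNA(xce)) NA_real_
                      else vnorm(xle - xce)
    out
  })
  do.call(rbind, rows)
}

# rows of `tm` with complete coordinates for prefix (e.g. "x_le")
coord_mat <- function(tm, prefix) {
  m <- as.matrix(tm[, paste0(prefix, c("_x", "_y", "_z"))])
  colnames(m) <- c("x", "y", "z")
  m
}

# Per-row nearest-neighbor distance from A into B, computed with the
# plain difference form so results are bit-identical to a direct
# per-pair evaluation.
nn_to_set <- function(A, B, exclude_same_index = FALSE) {
  if (nrow(A) == 0) return(numeric(0))
  if (nrow(B) == 0) return(rep(NA_real_, nrow(A)))
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                (B[, 3] - A[i, 3])^2)
    if (exclude_same_index) d[i] <- Inf
    m <- min(d)
    out[i] <- if (is.finite(m)) m else NA_real_
  }
  out
}

#' Width samples from intersection points
#'
#' Central-region width: for every LE intersection point, the shortest
#' distance to an LE intersection point of the opposing side. LE-to-CE
#' distance: shortest distance from an LE intersection to a same-side CE
#' intersection. CE width: shortest distance from a CE intersection to an
#' opposite-side CE intersection.
#'
#' @param tf_metrics output of [compute_tf_metrics()].
#' @return list with sample vectors `cr_width`, `le_ce`, `ce_width` and
#'   their `mean`/`sd` (sample sd) under `summary`.
#' @export
compute_region_widths <- function(tf_metrics) {
  tm <- tf_metrics
  out <- list(cr_width = numeric(0), le_ce = numeric(0),
              ce_width = numeric(0))
  for (s in c("left", "right")) {
    own <- tm$side == s & !is.na(tm$x_le_x)
    opp <- tm$side == setdiff(c("left", "right"), s) & !is.na(tm$x_le_x)
    own_ce <- tm$side == s & !is.na(tm$x_ce_x)
    opp_ce <- tm$side == setdiff(c("left", "right"), s) & !is.na(tm$x_ce_x)
    out$cr_width <- c(out$cr_width,
                      nn_to_set(coord_mat(tm[own, ], "x_le"),
                                coord_mat(tm[opp, ], "x_le")))
    out$le_ce <- c(out$le_ce,
                   nn_to_set(coord_mat(tm[own, ], "x_le"),
                             coord_mat(tm[own_ce, ], "x_ce")))
    out$ce_width <- c(out$ce_width,
                      nn_to_set(coord_mat(tm[own_ce, ], "x_ce"),
                                coord_mat(tm[opp_ce, ], "x_ce")))
  }
  out <- lapply(out, function(v) v[!is.na(v)])
  out$summary <- data.frame(
    metric = c("cr_width", "le_ce", "ce_width"),
    mean = vapply(out[1:3], function(v) mean(v), numeric(1)),
    sd = vapply(out[1:3], function(v) stats::sd(v), numeric(1)),
    n = vapply(out[1:3], length, integer(1)))
  out
}

#' Nearest-neighbor distances between CE endpoints
#'
#' For each TF's CE endpoint: the minimum distance to a CE endpoint of
#' the opposing side (`nn_opposite`) and of the same side excluding
#' itself (`nn_parallel`).
#'
#' @param tf_metrics output of [compute_tf_metrics()].
#' @return `tf_metrics` with `nn_opposite` and `nn_parallel` columns
#'   (`NA` where the relevant group is empty or the side unresolved).
#' @export
compute_ce_nn <- function(tf_metrics) {
  tm <- tf_metrics
  tm$nn_opposite <- NA_real_
  tm$nn_parallel <- NA_real_
  for (s in c("left", "right")) {
    own <- which(tm$side == s)
    opp <- which(tm$side == setdiff(c("left", "right"), s))
    if (length(own) == 0) next
    A <- coord_mat(tm[own, ], "ce_end")
    tm$nn_opposite[own] <- nn_to_set(A, coord_mat(tm[opp, ], "ce_end"))
    if (length(own) >= 2)
      tm$nn_parallel[own] <- nn_to_set(A, A, exclude_same_index = TRUE)
  }
  tm
}

#' Nearest-neighbor distances between LE endpoints
#'
#' Minimum distance from each TF's LE endpoint to the LE endpoints of the
#' other TFs of the same side.
#'
#' @param tf_metrics output of [compute_tf_metrics()].
#' @return `tf_metrics` with an `nn_le` column.
#' @export
compute_le_nn <- function(tf_metrics) {
  tm <- tf_metrics
  tm$nn_le <- NA_real_
  for (s in c("left", "right")) {
    own <- which(tm$side == s)
    if (length(own) < 2) next
    A <- coord_mat(tm[own, ], "le_end")
    tm$nn_le[own] <- nn_to_set(A, A, exclude_same_index = TRUE)
  }
  tm
}

#' Classify TF pairings in the central element
#'
#' A TF is `opposite` when its CE endpoint has an opposing-side neighbor
#' within the threshold, else `parallel` when it has a same-side neighbor
#' within the threshold, else `single` (opposite takes precedence).
#'
#' @param tf_metrics output of [compute_ce_nn()].
#' @param threshold pairing threshold in nm.
#' @return `tf_metrics` with a `pairing` column plus an attribute
#'   `proportions` (over classified TFs).
#' @export
classify_pairings <- function(tf_metrics,
                              threshold = quant_config()$pairing_threshold_nm) {
  tm <- tf_metrics
  tm$pairing <- ifelse(tm$side == "unresolved", "unresolved",
                ifelse(!is.na(tm$nn_opposite) & tm$nn_opposite <= threshold,
                       "opposite",
                ifelse(!is.na(tm$nn_parallel) & tm$nn_parallel <= threshold,
                       "parallel", "single")))
  cl <- tm$pairing[tm$pairing != "unresolved"]
  attr(tm, "proportions") <-
    prop.table(table(factor(cl, c("parallel", "opposite", "single"))))
  tm
}

#' Side asymmetry of TF counts
#'
#' @param n_left,n_right TF counts per side (both positive).
#' @return `100 * |n_left - n_right| / max(n_left, n_right)`.
#' @export
compute_asymmetry <- function(n_left, n_right) {
  if (n_left <= 0 || n_right <= 0)
    stop("asymmetry undefined: a side has no TFs")
  100 * abs(n_left - n_right) / max(n_left, n_right)
}

#' TF densities from a projected bounding rectangle
#'
#' Projects the site points (CE intersection points, or the LE endpoints
#' of one side) onto their best-fit plane, fits an axis-aligned rectangle
#' to the projected extrema, and derives TFs per micrometer of SC length
#' (total TF count over rectangle length) and per square micrometer
#' (site-point count over rectangle area).
#'
#' @param tf_metrics output of [compute_tf_metrics()].
#' @param model the `sc_model` (for the total TF count).
#' @param config a [quant_config()]; `density_site` selects the site.
#' @return list: `tfs_per_um`, `tfs_per_um2`, `rect` (an `sc_rect`),
#'   `n_sites`.
#' @export
compute_density <- function(tf_metrics, model, config = quant_config()) {
  site <- config$density_site
  pts <- if (site == "CE") {
    coord_mat(tf_metrics[!is.na(tf_metrics$x_ce_x), ], "x_ce")
  } else {
    s <- if (site == "LE_left") "left" else "right"
    coord_mat(tf_metrics[tf_metrics$side == s, ], "le_end")
  }
  if (nrow(pts) < 3) stop("density undefined: fewer than 3 site points")
  plane <- fit_plane(pts)
  rect <- bounding_rectangle(project_to_plane(pts, plane))
  list(tfs_per_um = length(model$tfs) / (rect$length / 1000),
       tfs_per_um2 = nrow(pts) / (rect$area / 1e6),
       rect = rect, n_sites = nrow(pts))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration when `n1 + n2 <= 16` and the data are tie-free
#' (mode `"auto"`), otherwise a normal approximation with midranks and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list of class `sc_test`: `statistic` (Mann-Whitney U of `x`),
#'   `p_value`, `method`, `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = length(x) + length(y) <= 16 && !ties,
                  exact = TRUE, normal = FALSE)
  if (exact && ties)
    stop("exact mode requires tie-free data")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate case: zero rank variance
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 method = if (exact) "exact" else "normal_approx",
                 n1 = length(x), n2 = length(y)),
            class = "sc_test")
}

#' Quantify one SC model
#'
#' Runs the full per-tomogram pipeline: side assignment, segment metrics,
#' CE/LE nearest neighbors, pairing classes, width samples, asymmetry and
#' densities.
#'
#' @inheritParams assign_tf_sides
#' @return list of class `sc_metrics`: `tf` (per-TF data.frame), `widths`,
#'   `density`, `summary` (one-row data.frame), `exclusions`.
#' @export
sc_quantify_model <- function(model, config = quant_config()) {
  tm <- compute_tf_metrics(model, config)
  tm <- compute_ce_nn(tm)
  tm <- compute_le_nn(tm)
  tm <- classify_pairings(tm, config$pairing_threshold_nm)
  widths <- compute_region_widths(tm)
  density <- compute_density(tm, model, config)
  n_left <- sum(tm$side == "left"); n_right <- sum(tm$side == "right")
  props <- attr(tm, "proportions")
  msd <- function(v) {
    v <- v[!is.na(v)]
    c(mean(v), stats::sd(v))
  }
  su <- data.frame(
    n_total = nrow(tm), n_left = n_left, n_right = n_right,
    n_unresolved = sum(tm$side == "unresolved"),
    asymmetry_pct = if (n_left > 0 && n_right > 0)
      compute_asymmetry(n_left, n_right) else NA_real_,
    tf_len_mean = msd(tm$len_total)[1], tf_len_sd = msd(tm$len_total)[2],
    le_indent_mean = msd(tm$le_indent)[1],
    le_indent_sd = msd(tm$le_indent)[2],
    ce_indent_mean = msd(tm$ce_indent)[1],
    ce_indent_sd = msd(tm$ce_indent)[2],
    midsection_mean = msd(tm$midsection)[1],
    midsection_sd = msd(tm$midsection)[2],
    cr_width_mean = mean(widths$cr_width), cr_width_sd = stats::sd(widths$cr_width),
    le_ce_mean = mean(widths$le_ce), le_ce_sd = stats::sd(widths$le_ce),
    ce_width_mean = mean(widths$ce_width),
    ce_width_sd = stats::sd(widths$ce_width),
    nn_opposite_mean = msd(tm$nn_opposite)[1],
    nn_opposite_sd = msd(tm$nn_opposite)[2],
    nn_parallel_mean = msd(tm$nn_parallel)[1],
    nn_parallel_sd = msd(tm$nn_parallel)[2],
    nn_le_mean = msd(tm$nn_le)[1], nn_le_sd = msd(tm$nn_le)[2],
    tfs_per_um = density$tfs_per_um, tfs_per_um2 = density$tfs_per_um2,
    prop_parallel = unname(props["parallel"]),
    prop_opposite = unname(props["opposite"]),
    prop_single = unname(props["single"]))
  exclusions <- data.frame(
    unresolved_side = sum(tm$side == "unresolved"),
    missing_le_intersection = sum(is.na(tm$x_le_x)),
    missing_ce_intersection = sum(is.na(tm$x_ce_x)))
  structure(list(tf = tm, widths = widths, density = density,
                 summary = su, exclusions = exclusions,
                 source = model$source),
            class = "sc_metrics")
}

#' Pool metrics across tomograms
#'
#' Pooled statistics are computed over the concatenated per-TF and
#' per-point samples (all tomograms treated as one data set), not as
#' means of per-tomogram means; densities and asymmetry, which are
#' per-tomogram quantities, are summarized as mean and sd across
#' tomograms.
#'
#' @param results list of [sc_quantify_model()] results.
#' @return list of class `sc_cohort`: `pooled` (one-row data.frame),
#'   `per_tomogram` (data.frame of per-tomogram summaries), `tf`
#'   (concatenated per-TF table with a `tomogram` column).
#' @export
summarize_cohort <- function(results) {
  if (length(results) < 1) stop("need at least one tomogram")
  tf_all <- do.call(rbind, lapply(seq_along(results), function(i) {
    tm <- results[[i]]$tf
    tm$tomogram <- i
    tm
  }))
  widths <- list(
    cr_width = unlist(lapply(results, function(r) r$widths$cr_width)),
    le_ce = unlist(lapply(results, function(r) r$widths$le_ce)),
    ce_width = unlist(lapply(results, function(r) r$widths$ce_width)))
  per <- do.call(rbind, lapply(results, function(r) r$summary))
  per$tomogram <- seq_along(results)
  msd <- function(v) {
    v <- v[!is.na(v)]
    c(mean(v), stats::sd(v))
  }
  cl <- tf_all$pairing[tf_all$pairing != "unresolved"]
  props <- prop.table(table(factor(cl, c("parallel", "opposite", "single"))))
  pooled <- data.frame(
    n_tomograms = length(results),
    n_total = nrow(tf_all),
    n_left = sum(tf_all$side == "left"),
    n_right = sum(tf_all$side == "right"),
    tf_len_mean = msd(tf_all$len_total)[1],
    tf_len_sd = msd(tf_all$len_total)[2],
    le_indent_mean = msd(tf_all$le_indent)[1],
    le_indent_sd = msd(tf_all$le_indent)[2],
    ce_indent_mean = msd(tf_all$ce_indent)[1],
    ce_indent_sd = msd(tf_all$ce_indent)[2],
    midsection_mean = msd(tf_all$midsection)[1],
    midsection_sd = msd(tf_all$midsection)[2],
    cr_width_mean = msd(widths$cr_width)[1],
    cr_width_sd = msd(widths$cr_width)[2],
    le_ce_mean = msd(widths$le_ce)[1], le_ce_sd = msd(widths$le_ce)[2],
    ce_width_mean = msd(widths$ce_width)[1],
    ce_width_sd = msd(widths$ce_width)[2],
    nn_opposite_mean = msd(tf_all$nn_opposite)[1],
    nn_opposite_sd = msd(tf_all$nn_opposite)[2],
    nn_parallel_mean = msd(tf_all$nn_parallel)[1],
    nn_parallel_sd = msd(tf_all$nn_parallel)[2],
    nn_le_mean = msd(tf_all$nn_le)[1], nn_le_sd = msd(tf_all$nn_le)[2],
    tfs_per_um_mean = msd(per$tfs_per_um)[1],
    tfs_per_um_sd = msd(per$tfs_per_um)[2],
    tfs_per_um2_mean = msd(per$tfs_per_um2)[1],
    tfs_per_um2_sd = msd(per$tfs_per_um2)[2],
    asymmetry_mean_pct = msd(per$asymmetry_pct)[1],
    asymmetry_max_pct = max(per$asymmetry_pct, na.rm = TRUE),
    prop_parallel = unname(props["parallel"]),
    prop_opposite = unname(props["opposite"]),
    prop_single = unname(props["single"]))
  structure(list(pooled = pooled, per_tomogram = per, tf = tf_all,
                 widths = widths),
            class = "sc_cohort")
}

#' @export
print.sc_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("sc_metrics: %d TFs (L %d / R %d), TF %.1f +/- %.1f nm, CR %.1f nm, %.1f TFs/um\n",
              s$n_total, s$n_left, s$n_right, s$tf_len_mean, s$tf_len_sd,
              s$cr_width_mean, s$tfs_per_um))
  invisible(x)
}

#' @export
print.sc_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}
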