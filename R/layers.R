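# Layered-arrangement test of the transverse filaments: a lateral-view
# projection of the CE intersection points (depth coordinates), and a
# two-plane fit to the CE endpoints of each side with a
# monolayer/bilayer verdict.

#' Layer-test configuration
#'
#' A bilayer verdict requires (1) near-parallel fitted planes, (2) a
#' plane separation clearly exceeding the within-layer scatter (and a
#' minimum absolute separation), and (3) longitudinally overlapping
#' clusters — a split along the course of the SC is an artifact of SC
#' curvature or tilt through the section, not a layered arrangement.
#'
#' @param max_angle_deg maximum angle between the two plane normals.
#' @param gap_rms_mult required ratio of plane separation to pooled
#'   within-cluster rms. An optimal two-way split of unimodal Gaussian
#'   scatter already yields a ratio near 2.7 (uniform scatter: 3.5), so
#'   the default 4 demands separation beyond any unimodal artifact.
#' @param min_gap_nm minimum absolute separation (guards noise-free and
#'   near-degenerate fits).
#' @param min_overlap minimum longitudinal overlap fraction of the two
#'   clusters.
#' @param endpoint which TF endpoints to fit: `"CE"` (default) or
#'   `"both"` (sensitivity option).
#' @param n_restarts,max_iter passed to [fit_two_planes()].
#' @return list of class `sc_layer_config`.
#' @export
layer_config <- function(max_angle_deg = 20, gap_rms_mult = 4,
                         min_gap_nm = 5, min_overlap = 0.5,
                         endpoint = c("CE", "both"),
                         n_restarts = 10, max_iter = 100) {
  structure(list(max_angle_deg = max_angle_deg,
                 gap_rms_mult = gap_rms_mult, min_gap_nm = min_gap_nm,
                 min_overlap = min_overlap,
                 endpoint = match.arg(endpoint),
                 n_restarts = n_restarts, max_iter = max_iter),
            class = "sc_layer_config")
}

#' Lateral-view projection of CE intersection points
#'
#' Projects the CE intersection points into the (long axis, depth) frame:
#' the width axis is the direction between the two LE centroids, the long
#' axis is the principal direction of the intersection points orthogonal
#' to it, and depth completes the right-handed frame. In this view a
#' bilayer shows as a bimodal depth distribution with modes near
#' +/- gap/2.
#'
#' @param model the `sc_model` (supplies the LE centroids).
#' @param tf_metrics output of [compute_tf_metrics()].
#' @return list: `coords` (n x 2, columns `long` and `depth`), `axes`
#'   (2 x 3 matrix), `center`.
#' @export
ce_projection <- function(model, tf_metrics) {
  pts <- coord_mat(tf_metrics[!is.na(tf_metrics$x_ce_x), ], "x_ce")
  if (nrow(pts) < 3) stop("need at least 3 CE intersection points")
  w <- colMeans(region_points(model$le_right)) -
    colMeans(region_points(model$le_left))
  w <- w / vnorm(w)
  centered <- sweep(pts, 2, colMeans(pts))
  inplane <- centered - (centered %*% w) %*% t(w)
  M <- crossprod(inplane) / nrow(pts)
  long <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (long[which.max(abs(long))] < 0) long <- -long
  depth <- c(w[2] * long[3] - w[3] * long[2],
             w[3] * long[1] - w[1] * long[3],
             w[1] * long[2] - w[2] * long[1])
  depth <- depth / vnorm(depth)
  coords <- cbind(long = as.numeric(centered %*% long),
                  depth = as.numeric(centered %*% depth))
  list(coords = coords, axes = rbind(long = long, depth = depth),
       center = colMeans(pts))
}

overlap_fraction <- function(proj, assign) {
  ra <- range(proj[assign == 1L]); rb <- range(proj[assign == 2L])
  inter <- min(ra[2], rb[2]) - max(ra[1], rb[1])
  shorter <- min(diff(ra), diff(rb))
  if (shorter <= 0) return(as.numeric(inter >= 0))
  max(0, min(1, inter / shorter))
}

#' Monolayer/bilayer verdict from a two-plane fit
#'
#' Fits one and two planes to a set of TF endpoints and applies the
#' [layer_config()] criteria: `bilayer` only when the two planes are
#' near-parallel, separated well beyond the within-cluster scatter, and
#' longitudinally overlapping; `monolayer` when a converged fit fails any
#' criterion; `inconclusive` when the two-plane fit is degenerate.
#'
#' @param points n x 3 matrix of endpoints (n >= 8).
#' @param config a [layer_config()].
#' @param seed seed for the two-plane restarts.
#' @return list of class `sc_layer_result`: `verdict`, `single_fit`,
#'   `two_fit`, `angle_deg`, `gap_nm`, `pooled_within_rms_nm`,
#'   `longitudinal_overlap_fraction`, `criteria` (named logicals).
#' @export
layer_verdict <- function(points, config = layer_config(), seed = 1) {
  pts <- as_points(points)
  if (nrow(pts) < 8) stop("need at least 8 endpoints")
  single <- fit_plane(pts)
  two <- tryCatch(fit_two_planes(pts, n_restarts = config$n_restarts,
                                 max_iter = config$max_iter, seed = seed),
                  error = function(e) NULL)
  if (is.null(two)) {
    return(structure(list(verdict = "inconclusive", single_fit = single,
                          two_fit = NULL, angle_deg = NA_real_,
                          gap_nm = NA_real_,
                          pooled_within_rms_nm = NA_real_,
                          longitudinal_overlap_fraction = NA_real_,
                          criteria = NULL),
                     class = "sc_layer_result"))
  }
  centered <- sweep(pts, 2, colMeans(pts))
  long_axis <- eigen(crossprod(centered) / nrow(pts),
                     symmetric = TRUE)$vectors[, 1]
  ov <- overlap_fraction(as.numeric(centered %*% long_axis),
                         two$assignments)
  crit <- c(parallel = two$angle_deg <= config$max_angle_deg,
            separated = two$gap_nm >=
              max(config$gap_rms_mult * two$pooled_within_rms,
                  config$min_gap_nm),
            overlapping = ov >= config$min_overlap)
  structure(list(verdict = if (all(crit)) "bilayer" else "monolayer",
                 single_fit = single, two_fit = two,
                 angle_deg = two$angle_deg, gap_nm = two$gap_nm,
                 pooled_within_rms_nm = two$pooled_within_rms,
                 longitudinal_overlap_fraction = ov,
                 criteria = crit),
            class = "sc_layer_result")
}

#' Full layer analysis of one SC model
#'
#' Evaluates each side's TF endpoints independently (the two sets of
#' filaments on either side of the CE), plus a combined report and the
#' lateral-view depth coordinates of the CE intersection points.
#'
#' @param model scaled `sc_model`.
#' @param quant a [quant_config()].
#' @param config a [layer_config()].
#' @param seed seed for the two-plane restarts.
#' @return list of class `sc_layer_analysis`: `left`, `right`
#'   (`sc_layer_result` or `NULL` if a side has too few endpoints),
#'   `combined_verdict` (`bilayer`/`monolayer` when the evaluated sides
#'   agree, else `inconclusive`), `depth` (from [ce_projection()]).
#' @export
sc_layer_analysis <- function(model, quant = quant_config(),
                              config = layer_config(), seed = 1) {
  tm <- compute_tf_metrics(model, quant)
  res <- list()
  for (s in c("left", "right")) {
    rows <- tm[tm$side == s, ]
    pts <- if (config$endpoint == "CE") coord_mat(rows, "ce_end")
           else rbind(coord_mat(rows, "ce_end"), coord_mat(rows, "le_end"))
    res[[s]] <- if (nrow(pts) >= 8)
      layer_verdict(pts, config, seed = seed) else NULL
  }
  verdicts <- unique(vapply(Filter(Negate(is.null), res),
                            function(r) r$verdict, character(1)))
  combined <- if (length(verdicts) == 1 && verdicts != "inconclusive")
    verdicts else "inconclusive"
  depth <- tryCatch(ce_projection(model, tm), error = function(e) NULL)
  structure(list(left = res$left, right = res$right,
                 combined_verdict = combined, depth = depth),
            class = "sc_layer_analysis")
}

#' @export
print.sc_layer_result <- function(x, ...) {
  cat(sprintf("layer verdict: %s (angle %.1f deg, gap %.1f nm, within-rms %.1f nm, overlap %.2f)\n",
              x$verdict, x$angle_deg, x$gap_nm, x$pooled_within_rms_nm,
              x$longitudinal_overlap_fraction))
  invisible(x)
}
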