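#' @keywords internal
"_PACKAGE"

# Point sets are plain numeric matrices with columns x, y, z (nm or px).
# An sc_model is a list: regions le_left / le_right / ce, a list of TF
# polylines, calibration (sc_scale), a units flag and a source tag.

as_points <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("point set must have 3 columns (x, y, z)")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  if (!all(is.finite(m))) stop("point coordinates must be finite")
  m
}

#' Create a transverse-filament polyline
#'
#' A polyline is an ordered trace of at least two distinct 3D points, as
#' produced by manual segmentation of a transverse filament.
#'
#' @param points numeric matrix (n x 3) of ordered coordinates.
#' @param label text identifier.
#' @return An object of class `sc_polyline`.
#' @export
sc_polyline <- function(points, label = "tf") {
  pts <- as_points(points)
  if (nrow(pts) < 2) stop("polyline needs at least 2 points")
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d == 0)) stop("polyline has identical consecutive points")
  structure(list(points = pts, label = as.character(label)),
            class = "sc_polyline")
}

#' Create an element region (lateral or central element)
#'
#' Two representations are supported: a `point_cloud` (the segmented points
#' themselves; membership is distance-to-cloud below a radius `delta`
#' supplied at analysis time) and a `slab` (an oriented box given by a
#' center, three orthonormal axes and three half-extents, used by the
#' synthetic generator where exact boundaries are known).
#'
#' @param role one of `"LE_left"`, `"LE_right"`, `"CE"`.
#' @param points for a point cloud: matrix (>= 4 points).
#' @param delta optional membership radius in nm (usually supplied later).
#' @param center,axes,half_extents for a slab: center point, 3x3 matrix of
#'   orthonormal row axes, and positive half-extents along those axes.
#' @return An object of class `sc_region`.
#' @export
sc_region_cloud <- function(role, points, delta = NULL) {
  role <- match.arg(role, c("LE_left", "LE_right", "CE"))
  pts <- as_points(points)
  if (nrow(pts) < 4) stop("point-cloud region needs at least 4 points")
  if (!is.null(delta) && (!is.finite(delta) || delta <= 0))
    stop("delta must be positive")
  structure(list(variant = "point_cloud", role = role, points = pts,
                 delta = delta),
            class = "sc_region")
}

#' @rdname sc_region_cloud
#' @export
sc_region_slab <- function(role, center, axes, half_extents) {
  role <- match.arg(role, c("LE_left", "LE_right", "CE"))
  center <- as.numeric(center)
  axes <- as.matrix(axes)
  he <- as.numeric(half_extents)
  if (length(center) != 3 || !all(dim(axes) == c(3, 3)) || length(he) != 3)
    stop("slab needs a 3-vector center, 3x3 axes and 3 half-extents")
  if (any(he <= 0)) stop("slab half-extents must be positive")
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-9)
    stop("slab axes must be orthonormal")
  structure(list(variant = "slab", role = role, center = center,
                 axes = axes, half_extents = he),
            class = "sc_region")
}

#' Calibration of a tomogram model
#'
#' Holds the pixel size, the nominal section thickness, and the z-scale
#' factor that compensates section thinning (the ratio of nominal section
#' thickness to the z-extent of the reconstructed volume).
#'
#' @param pixel_size_nm pixel size in nm (tomogram default 0.287).
#' @param section_thickness_nm nominal section thickness in nm (default 250).
#' @param z_extent_px z-extent of the reconstructed volume in pixels, used
#'   to derive `z_factor` when that is not given.
#' @param z_factor explicit z-scale factor; derived from the other fields
#'   when `NULL`, and 1 when underivable.
#' @return An object of class `sc_scale`.
#' @export
sc_scale <- function(pixel_size_nm = 0.287, section_thickness_nm = 250,
                     z_extent_px = NULL, z_factor = NULL) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (is.null(z_factor)) {
    z_factor <- if (!is.null(z_extent_px)) {
      compute_z_factor(section_thickness_nm, z_extent_px, pixel_size_nm)
    } else 1
  }
  if (z_factor <= 0) stop("z_factor must be positive")
  structure(list(pixel_size_nm = pixel_size_nm,
                 section_thickness_nm = section_thickness_nm,
                 z_extent_px = z_extent_px, z_factor = z_factor),
            class = "sc_scale")
}

#' Assemble an annotated SC model
#'
#' @param le_left,le_right,ce element regions with matching roles.
#' @param tfs list of `sc_polyline` transverse filaments (>= 1).
#' @param scale an [sc_scale()] record.
#' @param units `"px"` or `"nm"`; whether scaling has been applied.
#' @param source free-text provenance tag.
#' @return An object of class `sc_model`.
#' @export
sc_model <- function(le_left, le_right, ce, tfs, scale = sc_scale(),
                     units = c("px", "nm"), source = "") {
  units <- match.arg(units)
  for (r in list(le_left, le_right, ce))
    if (!inherits(r, "sc_region")) stop("regions must be sc_region objects")
  if (le_left$role != "LE_left" || le_right$role != "LE_right" ||
      ce$role != "CE")
    stop("region roles must match their slots")
  if (length(tfs) < 1) stop("model needs at least one transverse filament")
  if (!all(vapply(tfs, inherits, logical(1), "sc_polyline")))
    stop("tfs must be a list of sc_polyline objects")
  structure(list(le_left = le_left, le_right = le_right, ce = ce,
                 tfs = tfs, scale = scale, units = units,
                 source = as.character(source)),
            class = "sc_model")
}

region_points <- function(region) {
  if (region$variant == "point_cloud") return(region$points)
  # slab: its 8 corners, for extent checks only
  s <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  corners <- t(apply(s, 1, function(sg)
    region$center + colSums(region$axes * (sg * region$half_extents))))
  as_points(corners)
}

#' @export
print.sc_model <- function(x, ...) {
  cat(sprintf("sc_model (%s): %d TFs, regions %s; pixel %.3f nm, z-factor %.4f\n",
              x$units, length(x$tfs),
              paste(vapply(list(x$le_left, x$le_right, x$ce), function(r)
                sprintf("%s[%s]", r$role, r$variant), character(1)),
                collapse = ", "),
              x$scale$pixel_size_nm, x$scale$z_factor))
  invisible(x)
}

#' Report structural issues in a model
#'
#' Pure report (never raises): degenerate filaments, sparse element
#' regions, filaments whose both ends sit inside the same lateral element
#' (suspect traces), and px-flagged models whose coordinates look like
#' nanometer-scale values were never converted.
#'
#' @param model an `sc_model`.
#' @param delta membership radius (nm) used for the suspect-trace check.
#' @return data.frame with columns `kind`, `what`, `detail` (zero rows when
#'   the model is clean).
#' @export
validate_model <- function(model, delta = 4) {
  issues <- list()
  add <- function(kind, what, detail)
    issues[[length(issues) + 1]] <<- data.frame(kind = kind, what = what,
                                                detail = detail)
  for (i in seq_along(model$tfs)) {
    np <- nrow(model$tfs[[i]]$points)
    if (np < 2) add("degenerate_tf", model$tfs[[i]]$label,
                    sprintf("%d point(s)", np))
  }
  for (r in list(model$le_left, model$le_right, model$ce)) {
    if (r$variant == "point_cloud" && nrow(r$points) < 4)
      add("sparse_element", r$role, sprintf("%d points", nrow(r$points)))
  }
  for (le in list(model$le_left, model$le_right)) {
    for (i in seq_along(model$tfs)) {
      pts <- model$tfs[[i]]$points
      if (nrow(pts) < 2) next
      ends <- pts[c(1, nrow(pts)), , drop = FALSE]
      if (is_member(ends[1, ], le, delta) && is_member(ends[2, ], le, delta))
        add("suspect_trace", model$tfs[[i]]$label,
            sprintf("both endpoints inside %s", le$role))
    }
  }
  if (model$units == "px") {
    allp <- do.call(rbind, c(lapply(model$tfs, function(tf) tf$points),
                             list(region_points(model$le_left),
                                  region_points(model$le_right),
                                  region_points(model$ce))))
    if (max(abs(allp)) > 1e4)
      add("scale_warning", "model",
          "coordinates exceed 10^4 while flagged as pixels")
  }
  if (length(issues) == 0)
    return(data.frame(kind = character(), what = character(),
                      detail = character()))
  do.call(rbind, issues)
}
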