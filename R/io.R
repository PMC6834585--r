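# Reading and writing annotated point models.
#
# Text dialect: 5 whitespace-delimited columns `object contour x y z`, one
# point per line, as emitted by `model2point -object` on a segmented IMOD
# model. Grouping into SC roles is supplied by a role map; a JSON sidecar
# (written next to the file) carries calibration, roles and units so that
# a written model round-trips without external information.

ROLES <- c("LE_left", "LE_right", "CE")

sidecar_path <- function(path) paste0(path, ".json")

#' Read a model2point-style point file into an SC model
#'
#' @param path point-file path (columns `object contour x y z`).
#' @param role_map named character vector mapping object indices (names,
#'   e.g. `"1"`) to `"LE_left"`, `"LE_right"`, `"CE"` or `"TF"`. When
#'   `NULL`, the role map is taken from the JSON sidecar written by
#'   [write_point_model()].
#' @param scale an [sc_scale()]; overridden by a sidecar when present.
#' @return An `sc_model`. Units are `"px"` unless a sidecar says otherwise.
#'   Element objects sharing a role are merged into one point-cloud region;
#'   each TF contour becomes one polyline, ordered as in the file.
#' @export
read_point_model <- function(path, role_map = NULL, scale = sc_scale()) {
  if (!file.exists(path)) stop("no such file: ", path)
  units <- "px"
  source <- basename(path)
  slabs <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (is.null(role_map)) role_map <- unlist(side$role_map)
    if (length(side$slabs) > 0) slabs <- side$slabs
    if (!is.null(side$scale))
      scale <- sc_scale(pixel_size_nm = side$scale$pixel_size_nm,
                        section_thickness_nm = side$scale$section_thickness_nm,
                        z_extent_px = side$scale$z_extent_px,
                        z_factor = side$scale$z_factor)
    if (!is.null(side$units)) units <- side$units
    if (!is.null(side$source)) source <- side$source
  }
  if (is.null(role_map)) stop("role_map is required (no sidecar found)")

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty point file: ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop(sprintf("parse error at line %d of %s: expected 5 columns, got %d",
                 bad, path, nf[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 5, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 bad, path))
  }
  obj <- as.integer(m[, 1]); contour <- as.integer(m[, 2])

  seen <- as.character(sort(unique(obj)))
  missing <- setdiff(seen, names(role_map))
  if (length(missing) > 0)
    stop("objects missing from role_map: ", paste(missing, collapse = ", "))

  regions <- list()
  tfs <- list()
  for (o in sort(unique(obj))) {
    role <- role_map[[as.character(o)]]
    rows <- obj == o
    if (role %in% ROLES) {
      regions[[role]] <- rbind(regions[[role]], m[rows, 3:5, drop = FALSE])
    } else if (identical(role, "TF")) {
      for (ct in unique(contour[rows])) {
        sel <- rows & contour == ct
        tfs[[length(tfs) + 1]] <-
          sc_polyline(m[sel, 3:5, drop = FALSE],
                      label = sprintf("obj%d_c%d", o, ct))
      }
    } else {
      stop("unknown role in role_map for object ", o, ": ", role)
    }
  }
  if (length(tfs) == 0) stop("content error: no TF objects in ", path)
  for (r in ROLES) if (is.null(regions[[r]]))
    stop("content error: role ", r, " not present in ", path)

  mk_region <- function(role) {
    # a slab region written by write_point_model round-trips exactly via
    # its sidecar parameters; segmented data stay point clouds
    if (!is.null(slabs) && role %in% names(slabs)) {
      sl <- slabs[[role]]
      sc_region_slab(role, unlist(sl$center),
                     matrix(unlist(sl$axes), ncol = 3, byrow = FALSE),
                     unlist(sl$half_extents))
    } else sc_region_cloud(role, regions[[role]])
  }
  sc_model(le_left = mk_region("LE_left"), le_right = mk_region("LE_right"),
           ce = mk_region("CE"),
           tfs = tfs, scale = scale, units = units, source = source)
}

#' Write an SC model as a point file plus JSON sidecar
#'
#' Emits the same 5-column dialect read by [read_point_model()]. Element
#' regions become objects 1 (LE_left), 2 (LE_right), 3 (CE); TFs become
#' contours of object 4. Slab regions are written as their corner points;
#' the sidecar (`<path>.json`) records roles, units, calibration and the
#' full slab parameters so geometry is not lost.
#'
#' @param model an `sc_model` with at least one TF.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_point_model <- function(model, path) {
  if (length(model$tfs) == 0) stop("content error: model has no TFs")
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(o, ct, pts)
    writeLines(sprintf("%d %d %.17g %.17g %.17g",
                       o, ct, pts[, 1], pts[, 2], pts[, 3]), con)
  regs <- list(model$le_left, model$le_right, model$ce)
  for (i in 1:3) emit(i, 1L, region_points(regs[[i]]))
  for (j in seq_along(model$tfs)) emit(4L, j, model$tfs[[j]]$points)

  slabs <- list()
  for (r in regs) if (r$variant == "slab")
    slabs[[r$role]] <- list(center = r$center, axes = r$axes,
                            half_extents = r$half_extents)
  side <- list(role_map = list(`1` = "LE_left", `2` = "LE_right",
                               `3` = "CE", `4` = "TF"),
               units = model$units, source = model$source,
               scale = model$scale[c("pixel_size_nm", "section_thickness_nm",
                                     "z_extent_px", "z_factor")],
               slabs = slabs)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Write / read the native JSON model format
#'
#' Full-fidelity serialization of an `sc_model`, including slab regions,
#' per-TF labels, calibration and units, in one self-describing file.
#'
#' @param model an `sc_model`.
#' @param path file path.
#' @return `read_sc_json` returns an `sc_model`; `write_sc_json` returns
#'   `path` invisibly.
#' @export
write_sc_json <- function(model, path) {
  ser_region <- function(r) {
    if (r$variant == "point_cloud")
      list(variant = "point_cloud", role = r$role,
           points = unname(r$points), delta = r$delta)
    else
      list(variant = "slab", role = r$role, center = r$center,
           axes = unname(r$axes), half_extents = r$half_extents)
  }
  obj <- list(format = "scquant-model", version = 1,
              units = model$units, source = model$source,
              scale = model$scale[c("pixel_size_nm", "section_thickness_nm",
                                    "z_extent_px", "z_factor")],
              regions = lapply(list(model$le_left, model$le_right, model$ce),
                               ser_region),
              tfs = lapply(model$tfs, function(tf)
                list(label = tf$label, points = unname(tf$points))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_sc_json
#' @export
read_sc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "scquant-model"))
    stop("not a scquant model file: ", path)
  de_region <- function(r) {
    if (identical(r$variant, "point_cloud"))
      sc_region_cloud(r$role, matrix(unlist(r$points), ncol = 3,
                                     byrow = FALSE),
                      delta = r$delta)
    else
      sc_region_slab(r$role, unlist(r$center),
                     matrix(unlist(r$axes), ncol = 3, byrow = FALSE),
                     unlist(r$half_extents))
  }
  regions <- if (is.data.frame(obj$regions)) {
    lapply(seq_len(nrow(obj$regions)), function(i)
      de_region(lapply(obj$regions, function(col) col[[i]])))
  } else lapply(obj$regions, de_region)
  roles <- vapply(regions, function(r) r$role, character(1))
  tfs <- if (is.data.frame(obj$tfs)) {
    lapply(seq_len(nrow(obj$tfs)), function(i)
      sc_polyline(obj$tfs$points[[i]], label = obj$tfs$label[[i]]))
  } else lapply(obj$tfs, function(tf) sc_polyline(tf$points, tf$label))
  sc_model(le_left = regions[[which(roles == "LE_left")]],
           le_right = regions[[which(roles == "LE_right")]],
           ce = regions[[which(roles == "CE")]],
           tfs = tfs,
           scale = sc_scale(pixel_size_nm = obj$scale$pixel_size_nm,
                            section_thickness_nm = obj$scale$section_thickness_nm,
                            z_extent_px = obj$scale$z_extent_px,
                            z_factor = obj$scale$z_factor),
           units = obj$units, source = obj$source)
}

#' z-scale factor compensating section thinning
#'
#' The reconstructed volume of a resin section is thinner than the nominal
#' cut thickness; the model's z coordinates are stretched by the ratio of
#' the nominal thickness to the reconstructed z-extent.
#'
#' @param section_thickness_nm nominal section thickness (nm).
#' @param z_extent_px z-extent of the reconstructed volume (pixels).
#' @param pixel_size_nm pixel size (nm).
#' @return `section_thickness_nm / (z_extent_px * pixel_size_nm)`.
#' @export
compute_z_factor <- function(section_thickness_nm, z_extent_px,
                             pixel_size_nm) {
  if (any(c(section_thickness_nm, z_extent_px, pixel_size_nm) <= 0))
    stop("all arguments must be positive")
  section_thickness_nm / (z_extent_px * pixel_size_nm)
}

#' Convert a pixel-space model to nanometers
#'
#' x and y are multiplied by the pixel size; z additionally by the z-scale
#' factor (thinning compensation applied after pixel conversion).
#'
#' @param model an `sc_model` with `units == "px"`.
#' @param scale an [sc_scale()]; defaults to the model's own.
#' @return The model in nm (`units == "nm"`).
#' @export
apply_scaling <- function(model, scale = model$scale) {
  if (model$units != "px")
    stop("state error: model is already scaled (units = ", model$units, ")")
  f <- c(scale$pixel_size_nm, scale$pixel_size_nm,
         scale$pixel_size_nm * scale$z_factor)
  sc_pts <- function(p) sweep(p, 2, f, `*`)
  sc_region <- function(r) {
    if (r$variant == "point_cloud") r$points <- sc_pts(r$points)
    else {
      # axis-aligned scaling of an oriented box is exact only for boxes
      # aligned with the coordinate axes; reject otherwise
      if (max(abs(abs(r$axes) - diag(3))) > 1e-9)
        stop("cannot scale a slab not aligned with the coordinate axes")
      r$center <- r$center * f
      r$half_extents <- r$half_extents * f[apply(abs(r$axes), 1, which.max)]
    }
    r
  }
  model$le_left <- sc_region(model$le_left)
  model$le_right <- sc_region(model$le_right)
  model$ce <- sc_region(model$ce)
  model$tfs <- lapply(model$tfs, function(tf) {
    tf$points <- sc_pts(tf$points); tf
  })
  model$scale <- scale
  model$units <- "nm"
  model
}
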