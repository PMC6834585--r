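# Synthetic SC generator.
#
# Coordinate frame: x = SC long axis, y = width axis (lateral elements at
# +/- cr_width/2 .. +/- (cr_width/2 + le_thickness)), z = section depth.
# Transverse filaments are straight segments anchored at their CE
# endpoint, tilted (obliquity) so that the drawn midsection chord spans
# the fixed LE-to-CE gap, with the LE- and CE-embedded portions continuing
# along the same direction.

#' Configuration of the synthetic SC generator
#'
#' Defaults emulate the measured geometry of murine pachytene SCs: central
#' region 114 nm wide, central element 29 nm, TF length 88 +/- 14 nm with
#' 21 +/- 9 nm embedded in the LE and 14 +/- 7 nm in the CE, 79 TFs per
#' micrometer of SC (both sides pooled), and a TF depth extent of 75.5 nm
#' (the value implied by 79 TFs/um against 1046 TFs/um^2).
#'
#' @param sc_length_nm SC length along its axis.
#' @param course_amplitude_nm,course_period_nm sinusoidal bend of the SC
#'   course through the section depth (z); amplitude 0 = straight.
#' @param cr_width_mean_nm,cr_width_sd_nm central-region width (inner LE
#'   edge to inner LE edge). The sd is recorded but the element faces are
#'   kept planar; measured CR spread arises from filament obliquity and
#'   jitter.
#' @param ce_width_nm,le_thickness_nm central-element width and LE
#'   thickness along y.
#' @param tf_per_um_total TFs per micrometer, both sides pooled.
#' @param asymmetry_fraction fraction by which the right side's TF count
#'   exceeds the left's (|nL - nR| / max), in `[0, 1)`.
#' @param tf_total_len_mean_nm,tf_total_len_sd_nm total TF length draw.
#' @param le_indent_mean_nm,le_indent_sd_nm,ce_indent_mean_nm,ce_indent_sd_nm
#'   embedded-portion draws.
#' @param pairing_weights length-3 non-negative weights for the
#'   (parallel, opposite, single) arrangement classes.
#' @param pair_offset_max_nm maximum 3D offset between the CE endpoints of
#'   a planted pair (parallel or opposite).
#' @param single_exclusion_nm minimum distance from a planted single TF's
#'   CE endpoint to every other CE endpoint.
#' @param layer_mode `"single"` or `"bilayer"`.
#' @param bilayer_gap_nm spacing between the two TF layers in z.
#' @param tf_depth_range_nm depth extent over which TF CE-endpoints are
#'   spread in single-layer mode.
#' @param endpoint_jitter_sd_nm Gaussian noise added to every TF point.
#' @param position_jitter_frac positional jitter of anchor sites as a
#'   fraction of the inter-site spacing (0 = regular grid).
#' @param points_per_tf vertices per TF polyline.
#' @param element_cloud_spacing_nm grid spacing of point-cloud regions.
#' @param cloud_delta_nm erosion applied when sampling cloud regions so
#'   that the delta-offset surface of the cloud reproduces the slab
#'   surface (use the same value as the analysis membership radius).
#' @param region_style `"slab"` (exact boundaries) or `"cloud"`.
#' @param seed default seed used when [generate_sc()] is called without one.
#' @return list of class `sc_generator_config`.
#' @export
generator_config <- function(sc_length_nm = 2000,
                             course_amplitude_nm = 0,
                             course_period_nm = 1000,
                             cr_width_mean_nm = 114, cr_width_sd_nm = 17,
                             ce_width_nm = 29, le_thickness_nm = 40,
                             tf_per_um_total = 79,
                             asymmetry_fraction = 0,
                             tf_total_len_mean_nm = 88,
                             tf_total_len_sd_nm = 14,
                             le_indent_mean_nm = 21, le_indent_sd_nm = 9,
                             ce_indent_mean_nm = 14, ce_indent_sd_nm = 7,
                             pairing_weights = c(parallel = 0.3,
                                                 opposite = 0.4,
                                                 single = 0.3),
                             pair_offset_max_nm = 5,
                             single_exclusion_nm = 25,
                             layer_mode = c("single", "bilayer"),
                             bilayer_gap_nm = 30,
                             tf_depth_range_nm = 75.5,
                             endpoint_jitter_sd_nm = 2,
                             position_jitter_frac = 0.45,
                             points_per_tf = 5,
                             element_cloud_spacing_nm = 3,
                             cloud_delta_nm = 4,
                             region_style = c("slab", "cloud"),
                             seed = 1) {
  cfg <- list(sc_length_nm = sc_length_nm,
              course_amplitude_nm = course_amplitude_nm,
              course_period_nm = course_period_nm,
              cr_width_mean_nm = cr_width_mean_nm,
              cr_width_sd_nm = cr_width_sd_nm,
              ce_width_nm = ce_width_nm,
              le_thickness_nm = le_thickness_nm,
              tf_per_um_total = tf_per_um_total,
              asymmetry_fraction = asymmetry_fraction,
              tf_total_len_mean_nm = tf_total_len_mean_nm,
              tf_total_len_sd_nm = tf_total_len_sd_nm,
              le_indent_mean_nm = le_indent_mean_nm,
              le_indent_sd_nm = le_indent_sd_nm,
              ce_indent_mean_nm = ce_indent_mean_nm,
              ce_indent_sd_nm = ce_indent_sd_nm,
              pairing_weights = pairing_weights,
              pair_offset_max_nm = pair_offset_max_nm,
              single_exclusion_nm = single_exclusion_nm,
              layer_mode = match.arg(layer_mode),
              bilayer_gap_nm = bilayer_gap_nm,
              tf_depth_range_nm = tf_depth_range_nm,
              endpoint_jitter_sd_nm = endpoint_jitter_sd_nm,
              position_jitter_frac = position_jitter_frac,
              points_per_tf = points_per_tf,
              element_cloud_spacing_nm = element_cloud_spacing_nm,
              cloud_delta_nm = cloud_delta_nm,
              region_style = match.arg(region_style),
              seed = seed)
  lens <- c(cfg$sc_length_nm, cfg$course_period_nm, cfg$cr_width_mean_nm,
            cfg$ce_width_nm, cfg$le_thickness_nm, cfg$tf_per_um_total,
            cfg$tf_total_len_mean_nm, cfg$le_indent_mean_nm,
            cfg$ce_indent_mean_nm, cfg$bilayer_gap_nm,
            cfg$single_exclusion_nm)
  if (any(lens <= 0)) stop("config error: lengths and rates must be positive")
  if (any(c(cfg$cr_width_sd_nm, cfg$tf_total_len_sd_nm, cfg$le_indent_sd_nm,
            cfg$ce_indent_sd_nm, cfg$endpoint_jitter_sd_nm,
            cfg$course_amplitude_nm, cfg$tf_depth_range_nm,
            cfg$position_jitter_frac, cfg$pair_offset_max_nm) < 0))
    stop("config error: sds, amplitudes and fractions must be non-negative")
  if (cfg$asymmetry_fraction < 0 || cfg$asymmetry_fraction >= 1)
    stop("config error: asymmetry_fraction must be in [0, 1)")
  if (length(cfg$pairing_weights) != 3 || any(cfg$pairing_weights < 0) ||
      sum(cfg$pairing_weights) <= 0)
    stop("config error: pairing_weights must be 3 non-negative weights, sum > 0")
  if (cfg$points_per_tf < 2) stop("config error: points_per_tf must be >= 2")
  if (cfg$ce_width_nm >= cfg$cr_width_mean_nm)
    stop("config error: ce_width_nm must be smaller than cr_width_mean_nm")
  gap <- (cfg$cr_width_mean_nm - cfg$ce_width_nm) / 2
  mid_mean <- cfg$tf_total_len_mean_nm - cfg$le_indent_mean_nm -
    cfg$ce_indent_mean_nm
  if (mid_mean < gap)
    stop(sprintf(paste("config error: implied midsection mean %.1f nm cannot",
                       "span the %.1f nm LE-to-CE gap"), mid_mean, gap))
  class(cfg) <- "sc_generator_config"
  cfg
}

# Truncated-normal draw (inverse-cdf; exact for sd = 0).
rtnorm <- function(n, mean, sd, lo = 1, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

runif_jitter <- function(n, half) {
  if (half == 0) rep(0, n) else stats::runif(n, -half, half)
}

# Draw one TF anchored at its CE endpoint on side `sgn` (+1 right).
draw_tf <- function(cfg, sgn, x, z, gap) {
  le <- rtnorm(1, cfg$le_indent_mean_nm, cfg$le_indent_sd_nm)
  ce <- rtnorm(1, cfg$ce_indent_mean_nm, cfg$ce_indent_sd_nm)
  tot <- rtnorm(1, cfg$tf_total_len_mean_nm, cfg$tf_total_len_sd_nm)
  mid <- tot - le - ce
  clamped <- mid < gap
  if (clamped) mid <- gap
  cos_t <- gap / mid
  sin_t <- sqrt(max(0, 1 - cos_t^2))
  # keep embedded portions inside their elements
  ce_max <- 0.9 * cfg$ce_width_nm / cos_t
  le_max <- 0.9 * cfg$le_thickness_nm / cos_t
  ce <- min(max(ce, 1), ce_max)
  le <- min(le, le_max)
  phi <- stats::runif(1, 0, 2 * pi)
  u <- c(sin_t * cos(phi), sgn * cos_t, sin_t * sin(phi))  # CE end -> LE end
  y_ce <- sgn * (cfg$ce_width_nm / 2 - ce * cos_t)
  p_ce <- c(x, y_ce, z)
  list(side = if (sgn > 0) "right" else "left",
       p_ce_end = p_ce,
       x_ce = p_ce + ce * u,
       x_le = p_ce + (ce + mid) * u,
       p_le_end = p_ce + (ce + mid + le) * u,
       len_total = ce + mid + le, le_indent = le, ce_indent = ce,
       midsection = mid, tilt_deg = acos(cos_t) * 180 / pi,
       clamped = clamped)
}

# Pair partner: enters the CE at the anchor's (x, z) locus plus a small
# offset; its own indent draw is accepted when the 3D endpoint
# separation stays below the pairing scale (14 nm), so planted pairs are
# recoverable while the indent distribution is preserved. If the
# geometry makes that condition rare (narrow central regions), the first
# unconditioned draw is kept rather than biasing the draws.
draw_partner <- function(cfg, sgn, anchor, off, gap) {
  sep <- function(tt) vnorm(tt$p_ce_end - anchor$p_ce_end)
  first <- draw_tf(cfg, sgn, anchor$p_ce_end[1] + off[1],
                   anchor$p_ce_end[3] + off[3], gap)
  t2 <- first
  k <- 1
  while (sep(t2) > 14 && k < 40) {
    t2 <- draw_tf(cfg, sgn, anchor$p_ce_end[1] + off[1],
                  anchor$p_ce_end[3] + off[3], gap)
    k <- k + 1
  }
  if (sep(t2) > 14) first else t2
}

curve_z <- function(cfg, x) {
  if (cfg$course_amplitude_nm == 0) return(0)
  cfg$course_amplitude_nm * sin(2 * pi * x / cfg$course_period_nm)
}

# Split n TFs into sides and arrangement-class slots.
plan_slots <- function(cfg, n_total) {
  a <- cfg$asymmetry_fraction
  n_right <- round(n_total / (2 - a))
  n_left <- n_total - n_right
  w <- cfg$pairing_weights / sum(cfg$pairing_weights)
  n_opp <- min(round(w[2] * n_total / 2), n_left, n_right)
  rl <- n_left - n_opp; rr <- n_right - n_opp
  fp <- if (w[1] + w[3] > 0) w[1] / (w[1] + w[3]) else 0
  pl <- floor(fp * rl / 2); pr <- floor(fp * rr / 2)
  sl <- rl - 2 * pl; sr <- rr - 2 * pr
  types <- c(rep("opp", n_opp),
             rep("par_left", pl), rep("par_right", pr),
             rep("sing_left", sl), rep("sing_right", sr))
  list(types = types, n_left = n_left, n_right = n_right)
}

#' Generate one synthetic SC model with ground truth
#'
#' Builds an SC of the configured geometry: two lateral-element slabs and
#' a central-element slab (or eroded point-cloud equivalents), and
#' straight, tilted transverse filaments whose CE endpoints are placed in
#' planted arrangement classes — opposite pairs share a CE locus across
#' sides, parallel pairs share one on the same side, singles keep an
#' exclusion radius — and, in bilayer mode, on two z-layers. Gaussian
#' jitter is added to every TF vertex; the returned ground truth records
#' all quantities before jitter.
#'
#' @param config an [generator_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `model` (an `sc_model`, units nm) and `truth` (class
#'   `sc_ground_truth`: per-TF data.frame `tf`, realized `aggregates`,
#'   realized config, placement warnings).
#' @export
generate_sc <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sc_generator_config"))
  with_seed(seed, generate_sc_impl(config, seed))
}

generate_sc_impl <- function(cfg, seed) {
  L <- cfg$sc_length_nm
  half_cr <- cfg$cr_width_mean_nm / 2
  gap <- half_cr - cfg$ce_width_nm / 2
  n_total <- max(2, round(cfg$tf_per_um_total * L / 1000))
  plan <- plan_slots(cfg, n_total)
  types <- plan$types
  m <- length(types)

  type_order <- sample.int(m)
  xs <- if (m > 1) seq(0, L, length.out = m) else L / 2
  d <- cfg$tf_depth_range_nm
  if (m == 1 || d == 0) {
    zs <- rep(0, m)
  } else if (cfg$position_jitter_frac == 0) {
    # noise-free placement: depth levels symmetric about the SC midpoint,
    # so the sample x-z covariance vanishes and the projected bounding
    # rectangle recovers length and depth spans exactly
    k <- max(2, floor(m / 2))
    levels <- seq(-d / 2, d / 2, length.out = k)
    half <- rep_len(levels, floor(m / 2))
    zs <- numeric(m)
    zs[seq_len(floor(m / 2))] <- half
    zs[m + 1 - seq_len(floor(m / 2))] <- half
    if (m %% 2 == 1) zs[(m + 1) / 2] <- 0
  } else {
    zs <- sample(seq(-d / 2, d / 2, length.out = m))
  }
  dx <- if (m > 1) L / (m - 1) else L
  dz <- if (m > 1) d / (m - 1) else 0
  xs <- xs + runif_jitter(m, cfg$position_jitter_frac * dx / 2)
  zs <- zs + runif_jitter(m, cfg$position_jitter_frac * dz / 2)
  layers <- if (cfg$layer_mode == "bilayer")
    sample(c(-1, 1), m, replace = TRUE) else rep(0, m)

  excl <- cfg$single_exclusion_nm
  buffer <- 2
  placed <- matrix(numeric(0), ncol = 3)   # CE endpoints placed so far
  placed_kind <- character(0)              # single / parallel / other
  placed_side <- character(0)
  warnings_n <- 0
  tf_rows <- list()
  tf_geoms <- list()

  pair_offset <- function() {
    if (cfg$pair_offset_max_nm == 0) return(c(0, 0, 0))
    v <- stats::rnorm(3)
    v / vnorm(v) * stats::runif(1, min(0.5, cfg$pair_offset_max_nm / 2),
                                cfg$pair_offset_max_nm)
  }

  ok_placement <- function(pts, kind, sides) {
    if (nrow(placed) > 0) {
      for (i in seq_len(nrow(pts))) {
        d <- sqrt(colSums((t(placed) - pts[i, ])^2))
        lim <- rep(0, length(d))
        lim[placed_kind == "single"] <- excl + buffer
        lim[placed_kind == "parallel" & placed_side != sides[i]] <-
          15 + buffer
        if (kind == "single") lim <- pmax(lim, excl + buffer)
        if (kind == "parallel")
          lim <- pmax(lim, ifelse(placed_side != sides[i], 15 + buffer, 0))
        if (any(d < lim)) return(FALSE)
      }
    }
    if (nrow(pts) > 1 && kind == "single") return(FALSE)
    TRUE
  }

  slot_id <- 0
  for (j in seq_len(m)) {
    type <- types[type_order[j]]
    slot_id <- slot_id + 1
    x0 <- xs[j]
    kind <- switch(type, opp = "pair", par_left = "parallel",
                   par_right = "parallel", sing_left = "single",
                   sing_right = "single")
    pairing <- switch(type, opp = "opposite", par_left = "parallel",
                      par_right = "parallel", sing_left = "single",
                      sing_right = "single")
    accepted <- FALSE
    for (try in 1:60) {
      z0 <- if (try == 1) zs[j] else
        stats::runif(1, -cfg$tf_depth_range_nm / 2,
                     cfg$tf_depth_range_nm / 2)
      if (cfg$layer_mode == "bilayer") z0 <- layers[j] * cfg$bilayer_gap_nm / 2
      zc <- z0 + curve_z(cfg, x0)
      if (type == "opp") {
        t1 <- draw_tf(cfg, +1, x0, zc, gap)
        members <- list(t1, draw_partner(cfg, -1, t1, pair_offset(), gap))
      } else if (kind == "parallel") {
        sgn <- if (type == "par_left") -1 else +1
        t1 <- draw_tf(cfg, sgn, x0, zc, gap)
        members <- list(t1, draw_partner(cfg, sgn, t1, pair_offset(), gap))
      } else {
        sgn <- if (type == "sing_left") -1 else +1
        members <- list(draw_tf(cfg, sgn, x0, zc, gap))
      }
      pts <- do.call(rbind, lapply(members, function(tt) tt$p_ce_end))
      sides <- vapply(members, function(tt) tt$side, character(1))
      check_kind <- if (kind == "pair") "other" else kind
      if (ok_placement(pts, check_kind, sides)) { accepted <- TRUE; break }
      if (cfg$layer_mode == "bilayer" && cfg$position_jitter_frac == 0 &&
          cfg$tf_depth_range_nm == 0) break   # nothing to resample
    }
    if (!accepted) warnings_n <- warnings_n + 1
    for (tt in members) {
      tf_geoms[[length(tf_geoms) + 1]] <- tt
      tf_rows[[length(tf_rows) + 1]] <- data.frame(
        tf = length(tf_geoms), slot = slot_id, side = tt$side,
        pairing = pairing,
        layer = if (cfg$layer_mode == "bilayer") layers[j] else 0,
        le_end_x = tt$p_le_end[1], le_end_y = tt$p_le_end[2],
        le_end_z = tt$p_le_end[3],
        ce_end_x = tt$p_ce_end[1], ce_end_y = tt$p_ce_end[2],
        ce_end_z = tt$p_ce_end[3],
        x_le_x = tt$x_le[1], x_le_y = tt$x_le[2], x_le_z = tt$x_le[3],
        x_ce_x = tt$x_ce[1], x_ce_y = tt$x_ce[2], x_ce_z = tt$x_ce[3],
        len_total = tt$len_total, le_indent = tt$le_indent,
        ce_indent = tt$ce_indent, midsection = tt$midsection,
        tilt_deg = tt$tilt_deg, mid_clamped = tt$clamped)
    }
    placed <- rbind(placed, do.call(rbind,
                                    lapply(members, function(tt) tt$p_ce_end)))
    placed_kind <- c(placed_kind,
                     rep(if (kind == "pair") "other" else kind,
                         length(members)))
    placed_side <- c(placed_side,
                     vapply(members, function(tt) tt$side, character(1)))
  }
  truth_tf <- do.call(rbind, tf_rows)

  # polylines with vertex jitter
  tfs <- lapply(seq_along(tf_geoms), function(i) {
    tt <- tf_geoms[[i]]
    s <- seq(0, 1, length.out = cfg$points_per_tf)
    pts <- outer(1 - s, tt$p_le_end) + outer(s, tt$p_ce_end)
    pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                     cfg$endpoint_jitter_sd_nm),
                        ncol = 3)
    sc_polyline(pts, label = sprintf("tf%04d", i))
  })

  model <- sc_model(le_left = build_region(cfg, "LE_left", truth_tf),
                    le_right = build_region(cfg, "LE_right", truth_tf),
                    ce = build_region(cfg, "CE", truth_tf),
                    tfs = tfs,
                    scale = sc_scale(pixel_size_nm = 0.287,
                                     section_thickness_nm = 250,
                                     z_factor = 1),
                    units = "nm",
                    source = sprintf("synthetic seed=%d", seed))

  truth <- structure(list(tf = truth_tf,
                          aggregates = truth_aggregates(cfg, truth_tf),
                          config = cfg, seed = seed,
                          placement_warnings = warnings_n),
                     class = "sc_ground_truth")
  if (warnings_n > 0)
    warning(sprintf("pairing quota not fully satisfiable: %d slot(s) placed best-effort",
                    warnings_n))
  list(model = model, truth = truth)
}

region_box <- function(cfg, role, truth_tf) {
  L <- cfg$sc_length_nm
  half_cr <- cfg$cr_width_mean_nm / 2
  allz <- c(truth_tf$le_end_z, truth_tf$ce_end_z)
  allx <- c(truth_tf$le_end_x, truth_tf$ce_end_x)
  zc <- mean(range(allz)); zh <- diff(range(allz)) / 2 + 30
  xc <- mean(range(c(allx, 0, L))); xh <- diff(range(c(allx, 0, L))) / 2 + 30
  if (role == "CE") {
    list(center = c(xc, 0, zc),
         half = c(xh, cfg$ce_width_nm / 2, zh))
  } else {
    s <- if (role == "LE_left") -1 else 1
    list(center = c(xc, s * (half_cr + cfg$le_thickness_nm / 2), zc),
         half = c(xh, cfg$le_thickness_nm / 2, zh))
  }
}

build_region <- function(cfg, role, truth_tf) {
  box <- region_box(cfg, role, truth_tf)
  if (cfg$region_style == "slab")
    return(sc_region_slab(role, box$center, diag(3), box$half))
  # point cloud: regular grid over the box eroded by cloud_delta, so the
  # delta-offset surface of the cloud reproduces the slab surface
  d <- cfg$cloud_delta_nm
  s <- cfg$element_cloud_spacing_nm
  he <- box$half - d
  if (any(he <= 0)) stop("config error: cloud_delta too large for region")
  ax <- lapply(1:3, function(k)
    seq(box$center[k] - he[k], box$center[k] + he[k],
        length.out = max(2, ceiling(2 * he[k] / s) + 1)))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  if (nrow(g) > 2e6)
    stop("cloud region too large; increase element_cloud_spacing_nm or shrink the model")
  if (cfg$course_amplitude_nm > 0)
    g[, 3] <- g[, 3] + cfg$course_amplitude_nm *
      sin(2 * pi * g[, 1] / cfg$course_period_nm)
  sc_region_cloud(role, g, delta = d)
}

# Realized (pre-jitter) aggregates: the generative counterparts of the
# measured summary quantities, computed from the true per-TF records.
truth_aggregates <- function(cfg, tf) {
  xle <- cbind(tf$x_le_x, tf$x_le_y, tf$x_le_z)
  xce <- cbind(tf$x_ce_x, tf$x_ce_y, tf$x_ce_z)
  pce <- cbind(tf$ce_end_x, tf$ce_end_y, tf$ce_end_z)
  ple <- cbind(tf$le_end_x, tf$le_end_y, tf$le_end_z)
  left <- tf$side == "left"
  cr <- c(cross_nn(xle[left, , drop = FALSE], xle[!left, , drop = FALSE]),
          cross_nn(xle[!left, , drop = FALSE], xle[left, , drop = FALSE]))
  lece <- c(cross_nn(xle[left, , drop = FALSE], xce[left, , drop = FALSE]),
            cross_nn(xle[!left, , drop = FALSE], xce[!left, , drop = FALSE]))
  cew <- c(cross_nn(xce[left, , drop = FALSE], xce[!left, , drop = FALSE]),
           cross_nn(xce[!left, , drop = FALSE], xce[left, , drop = FALSE]))
  nn_opp <- c(cross_nn(pce[left, , drop = FALSE], pce[!left, , drop = FALSE]),
              cross_nn(pce[!left, , drop = FALSE], pce[left, , drop = FALSE]))
  nn_par <- c(self_nn(pce[left, , drop = FALSE]),
              self_nn(pce[!left, , drop = FALSE]))
  nn_le <- c(self_nn(ple[left, , drop = FALSE]),
             self_nn(ple[!left, , drop = FALSE]))
  # densities via the same projected-rectangle construction the
  # estimator uses, evaluated on the pre-jitter intersection points
  n <- nrow(tf)
  rect <- tryCatch(bounding_rectangle(
    project_to_plane(xce, fit_plane(xce))), error = function(e) NULL)
  nl <- sum(left); nr <- n - nl
  list(n_total = n, n_left = nl, n_right = nr,
       asymmetry_pct = 100 * abs(nl - nr) / max(nl, nr),
       pairing_counts = c(table(factor(tf$pairing,
                                       c("parallel", "opposite", "single")))),
       tf_len_mean = mean(tf$len_total), tf_len_sd = stats::sd(tf$len_total),
       le_indent_mean = mean(tf$le_indent),
       le_indent_sd = stats::sd(tf$le_indent),
       ce_indent_mean = mean(tf$ce_indent),
       ce_indent_sd = stats::sd(tf$ce_indent),
       midsection_mean = mean(tf$midsection),
       midsection_sd = stats::sd(tf$midsection),
       cr_width_mean = mean(cr), cr_width_sd = stats::sd(cr),
       le_ce_mean = mean(lece), le_ce_sd = stats::sd(lece),
       ce_width_mean = mean(cew), ce_width_sd = stats::sd(cew),
       nn_opposite_mean = mean(nn_opp), nn_opposite_sd = stats::sd(nn_opp),
       nn_parallel_mean = mean(nn_par), nn_parallel_sd = stats::sd(nn_par),
       nn_le_mean = mean(nn_le), nn_le_sd = stats::sd(nn_le),
       tfs_per_um = if (!is.null(rect)) n / (rect$length / 1000)
                    else NA_real_,
       tfs_per_um2 = if (!is.null(rect) && rect$area > 0)
                       n / (rect$area / 1e6) else NA_real_,
       clamped_fraction = mean(tf$mid_clamped))
}

# per-row nearest neighbor from A to B (possibly the same matrix)
cross_nn <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(numeric(0))
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

self_nn <- function(A) {
  if (nrow(A) < 2) return(numeric(0))
  d2 <- outer(rowSums(A^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(A)), rowSums(A^2)) - 2 * A %*% t(A)
  diag(d2) <- Inf
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Generate a cohort of independent synthetic tomogram models
#'
#' @param config an [generator_config()], shared by all tomograms.
#' @param n_tomograms number of models (the source study used six).
#' @param seed master seed; tomogram i uses `seed + i - 1`.
#' @return list of `generate_sc()` results.
#' @export
generate_cohort <- function(config, n_tomograms, seed = config$seed) {
  if (n_tomograms < 1) stop("n_tomograms must be >= 1")
  lapply(seq_len(n_tomograms), function(i)
    generate_sc(config, seed = seed + i - 1))
}

#' @export
print.sc_ground_truth <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("sc_ground_truth: %d TFs (%d left / %d right), TF length %.1f nm, %.1f TFs/um\n",
              a$n_total, a$n_left, a$n_right, a$tf_len_mean, a$tfs_per_um))
  invisible(x)
}
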