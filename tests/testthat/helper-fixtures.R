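# Shared fixtures and independent oracles. Everything is built in code;
# no fixture files.

# Axis-aligned slab helper
slab <- function(role, center, half) sc_region_slab(role, center, diag(3), half)

# The canonical straight-filament scene: an 88 nm TF running along x from
# inside an LE (occupying x <= 21) to inside the CE (occupying x >= 74),
# so the embedded portions are 21 and 14 nm and the midsection is 53 nm.
straight_tf_scene <- function() {
  list(tf = sc_polyline(cbind(seq(0, 88, length.out = 5), 0, 0)),
       le = slab("LE_left", c(-39.5, 0, 0), c(60.5, 50, 50)),   # x in [-100, 21]
       ce = slab("CE", c(104, 0, 0), c(30, 50, 50)))            # x in [74, 134]
}

# Generator config with every noise source off and a perpendicular-TF
# geometry (total = le_indent + ce_indent + gap), all TFs in opposite
# pairs: every measured summary equals its configured value exactly.
identity_config <- function(...) {
  generator_config(
    tf_total_len_mean_nm = 21 + 14 + (114 - 29) / 2,
    tf_total_len_sd_nm = 0, le_indent_sd_nm = 0, ce_indent_sd_nm = 0,
    cr_width_sd_nm = 0, endpoint_jitter_sd_nm = 0,
    position_jitter_frac = 0, pair_offset_max_nm = 0,
    course_amplitude_nm = 0,
    pairing_weights = c(parallel = 0, opposite = 1, single = 0),
    ...)
}

# Derived values the identity config must reproduce
identity_expect <- function(cfg) {
  gap <- (cfg$cr_width_mean_nm - cfg$ce_width_nm) / 2
  c(tf_len_mean = cfg$le_indent_mean_nm + cfg$ce_indent_mean_nm + gap,
    le_indent_mean = cfg$le_indent_mean_nm,
    ce_indent_mean = cfg$ce_indent_mean_nm,
    midsection_mean = gap,
    cr_width_mean = cfg$cr_width_mean_nm,
    le_ce_mean = gap,
    ce_width_mean = cfg$ce_width_nm,
    tfs_per_um = cfg$tf_per_um_total,
    tfs_per_um2 = cfg$tf_per_um_total / (cfg$tf_depth_range_nm / 1000))
}

# O(n^2) nearest-neighbor oracle (fixed left-to-right accumulation so
# distances are bit-identical to the implementation's arithmetic)
brute_nn <- function(p, candidates, exclude_self = FALSE) {
  d <- apply(candidates, 1, function(q)
    sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2))
  if (exclude_self) {
    z <- which(d == 0)
    if (length(z) > 0) d[z[1]] <- Inf
  }
  list(distance = min(d), index = which.min(d))
}

# Full-enumeration two-sided rank-sum oracle (tie-free data)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  allr <- seq_len(n1 + n2)
  Us <- apply(utils::combn(n1 + n2, n1), 2,
              function(idx) sum(allr[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= obs), mean(Us >= obs)))
}

gen_quiet <- function(cfg, seed) suppressWarnings(generate_sc(cfg, seed))
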