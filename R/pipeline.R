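# Orchestration: simulate / quantify / layers / report, file-based, used
# by the inst/cli/scquant.R command-line script. All tables are written
# as CSV with a header row; structured results as JSON. Outputs carry no
# timestamps, so identical inputs and seeds give byte-identical files.

read_generator_yaml <- function(path) {
  vals <- yaml::yaml.load_file(path)
  if (!is.list(vals)) stop("config error: YAML must be a mapping")
  bad <- setdiff(names(vals), names(formals(generator_config)))
  if (length(bad) > 0)
    stop("config error: unknown generator fields: ",
         paste(bad, collapse = ", "))
  if (!is.null(vals$pairing_weights))
    vals$pairing_weights <- unlist(vals$pairing_weights)
  do.call(generator_config, vals)
}

write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(tf = truth$tf,
                            aggregates = truth$aggregates,
                            config = unclass(truth$config),
                            seed = truth$seed,
                            placement_warnings = truth$placement_warnings),
                       path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Simulate a cohort of synthetic SC models to disk
#'
#' Writes `model_XX.txt` point files (with JSON sidecars) and
#' `truth_XX.json` ground-truth files.
#'
#' @param out_dir output directory (created if needed).
#' @param config an [generator_config()] or a path to a YAML file of
#'   generator fields.
#' @param n_tomograms number of models.
#' @param seed master seed.
#' @return data.frame of written `model` and `truth` paths, invisibly.
#' @export
sc_simulate <- function(out_dir, config = generator_config(),
                        n_tomograms = 6, seed = config$seed) {
  if (is.character(config)) config <- read_generator_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, n_tomograms, seed = seed)
  files <- lapply(seq_along(cohort), function(i) {
    mp <- file.path(out_dir, sprintf("model_%02d.txt", i))
    tp <- file.path(out_dir, sprintf("truth_%02d.json", i))
    write_point_model(cohort[[i]]$model, mp)
    write_ground_truth(cohort[[i]]$truth, tp)
    data.frame(model = mp, truth = tp)
  })
  invisible(do.call(rbind, files))
}

load_model_any <- function(path, role_map = NULL) {
  model <- if (grepl("\\.json$", path)) read_sc_json(path)
           else read_point_model(path, role_map = role_map)
  if (model$units == "px") model <- apply_scaling(model)
  model
}

#' Quantify SC models from disk
#'
#' Reads each model (point file or native JSON), scales pixel models to
#' nm, quantifies it, and writes per-model `metrics_XX.csv` and
#' `summary_XX.json` plus the cohort-pooled `summary_pooled.json` and
#' `per_tomogram.csv`.
#'
#' @param model_paths character vector of model files.
#' @param out_dir output directory.
#' @param quant a [quant_config()].
#' @param role_map passed to [read_point_model()] for sidecar-less files.
#' @return the [summarize_cohort()] result, invisibly.
#' @export
sc_quantify <- function(model_paths, out_dir, quant = quant_config(),
                        role_map = NULL) {
  if (length(model_paths) == 0) stop("no input models")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- lapply(seq_along(model_paths), function(i) {
    model <- load_model_any(model_paths[i], role_map)
    res <- sc_quantify_model(model, quant)
    utils::write.csv(res$tf,
                     file.path(out_dir, sprintf("metrics_%02d.csv", i)),
                     row.names = FALSE)
    jsonlite::write_json(c(list(source = res$source), as.list(res$summary),
                           list(exclusions = as.list(res$exclusions))),
                         file.path(out_dir, sprintf("summary_%02d.json", i)),
                         auto_unbox = TRUE, digits = I(17), null = "null")
    excl <- res$exclusions
    if (sum(unlist(excl)) > 0)
      message(sprintf("model %d: excluded %d unresolved side(s), %d/%d missing LE/CE intersections",
                      i, excl$unresolved_side, excl$missing_le_intersection,
                      excl$missing_ce_intersection))
    res
  })
  cohort <- summarize_cohort(results)
  jsonlite::write_json(as.list(cohort$pooled),
                       file.path(out_dir, "summary_pooled.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  utils::write.csv(cohort$per_tomogram,
                   file.path(out_dir, "per_tomogram.csv"), row.names = FALSE)
  invisible(cohort)
}

#' Layer analysis of SC models from disk
#'
#' @inheritParams sc_quantify
#' @param layer a [layer_config()].
#' @param seed seed for the two-plane restarts.
#' @return list of [sc_layer_analysis()] results, invisibly; writes
#'   `layers.json`.
#' @export
sc_layers <- function(model_paths, out_dir, quant = quant_config(),
                      layer = layer_config(), role_map = NULL, seed = 1) {
  if (length(model_paths) == 0) stop("no input models")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analyses <- lapply(model_paths, function(p) {
    model <- load_model_any(p, role_map)
    sc_layer_analysis(model, quant, layer, seed = seed)
  })
  ser_side <- function(r) {
    if (is.null(r)) return(NULL)
    list(verdict = r$verdict, angle_deg = r$angle_deg, gap_nm = r$gap_nm,
         pooled_within_rms_nm = r$pooled_within_rms_nm,
         longitudinal_overlap_fraction = r$longitudinal_overlap_fraction)
  }
  jsonlite::write_json(
    lapply(seq_along(analyses), function(i)
      list(model = model_paths[i],
           left = ser_side(analyses[[i]]$left),
           right = ser_side(analyses[[i]]$right),
           combined_verdict = analyses[[i]]$combined_verdict)),
    file.path(out_dir, "layers.json"),
    auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(analyses)
}

#' SYCP1 molecules per micrometer implied by the TF density
#'
#' Each TF is an SYCP1 dimer, so a density of `mean +/- sd` TFs/um
#' implies `2 * (mean - sd)` to `2 * (mean + sd)` SYCP1 molecules per
#' micrometer of SC (79 +/- 8 TFs/um gives 142 to 174).
#'
#' @param tfs_per_um_mean,tfs_per_um_sd TF density statistics.
#' @return named numeric `c(low, high)`.
#' @export
sycp1_per_um_range <- function(tfs_per_um_mean, tfs_per_um_sd) {
  c(low = 2 * (tfs_per_um_mean - tfs_per_um_sd),
    high = 2 * (tfs_per_um_mean + tfs_per_um_sd))
}

#' Report tables from a pooled summary
#'
#' Produces a central-region width table (CR width, LE-CE distance, CE
#' width), a TF table (total length, LE/CE indents, midsection, counts
#' per um and um^2), and the implied SYCP1-per-micrometer range.
#'
#' @param pooled one-row pooled summary data.frame (from
#'   [summarize_cohort()]) or the path of a `summary_pooled.json`.
#' @param out_dir optional; when given, writes `report_widths.csv`,
#'   `report_tf.csv` and `report.txt`.
#' @return list of class `sc_report`: `widths`, `tf`, `sycp1_per_um`.
#' @export
sc_report <- function(pooled, out_dir = NULL) {
  if (is.character(pooled))
    pooled <- as.data.frame(jsonlite::read_json(pooled,
                                                simplifyVector = TRUE))
  need <- function(f) if (f %in% names(pooled)) pooled[[f]] else NA_real_
  widths <- data.frame(
    metric = c("CR-width", "LE-CE", "CE-width"),
    mean = c(need("cr_width_mean"), need("le_ce_mean"),
             need("ce_width_mean")),
    sd = c(need("cr_width_sd"), need("le_ce_sd"), need("ce_width_sd")))
  dens_mean <- if ("tfs_per_um_mean" %in% names(pooled))
    pooled$tfs_per_um_mean else need("tfs_per_um")
  dens_sd <- if ("tfs_per_um_sd" %in% names(pooled))
    pooled$tfs_per_um_sd else 0
  dens2_mean <- if ("tfs_per_um2_mean" %in% names(pooled))
    pooled$tfs_per_um2_mean else need("tfs_per_um2")
  tf <- data.frame(
    metric = c("TF total", "LE-indent", "CE-indent", "CR-midsection",
               "TFs per um", "TFs per um^2"),
    mean = c(need("tf_len_mean"), need("le_indent_mean"),
             need("ce_indent_mean"), need("midsection_mean"),
             dens_mean, dens2_mean),
    sd = c(need("tf_len_sd"), need("le_indent_sd"), need("ce_indent_sd"),
           need("midsection_sd"), dens_sd,
           if ("tfs_per_um2_sd" %in% names(pooled))
             pooled$tfs_per_um2_sd else NA_real_))
  if (anyNA(widths$mean) || anyNA(tf$mean))
    warning("missing fields: report is partial")
  sycp1 <- sycp1_per_um_range(dens_mean, dens_sd)
  rep <- structure(list(widths = widths, tf = tf, sycp1_per_um = sycp1),
                   class = "sc_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(widths, file.path(out_dir, "report_widths.csv"),
                     row.names = FALSE)
    utils::write.csv(tf, file.path(out_dir, "report_tf.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(rep)),
               file.path(out_dir, "report.txt"))
  }
  rep
}

#' @export
print.sc_report <- function(x, ...) {
  cat("Central region [nm]\n")
  for (i in seq_len(nrow(x$widths)))
    cat(sprintf("  %-14s %6.1f +/- %.1f\n", x$widths$metric[i],
                x$widths$mean[i], x$widths$sd[i]))
  cat("Transverse filaments\n")
  for (i in seq_len(nrow(x$tf)))
    cat(sprintf("  %-14s %6.1f +/- %.1f\n", x$tf$metric[i],
                x$tf$mean[i], x$tf$sd[i]))
  cat(sprintf("SYCP1 per um of SC: %.0f to %.0f molecules\n",
              x$sycp1_per_um["low"], x$sycp1_per_um["high"]))
  invisible(x)
}
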