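#' Run the synthetic analysis pipeline from a config
#'
#' Orchestrates the stages named in the config in dependency order and
#' writes all outputs, a log, and a provenance record to \code{out_dir}.
#' Runs are idempotent: two runs with the same config and seed produce
#' byte-identical outputs (no timestamps are written).
#'
#' The config is a list (or a path to a YAML/JSON file) with an integer
#' \code{seed} and any of:
#' \describe{
#'   \item{caps}{\code{spec}: arguments for \code{\link{cap_field_spec}}
#'     (synthetic input), or \code{input_image} + \code{pixel_size_um} to
#'     segment an existing TIFF; \code{segmentation}: arguments for
#'     \code{\link{segmentation_params}}; \code{small_threshold_um2}
#'     (default 80).}
#'   \item{binding}{\code{spec}: arguments for
#'     \code{\link{binding_sim_spec}}, or \code{input_table}: path to a
#'     densitometry CSV; \code{plateau_mode}; \code{n_boot} (default 200).}
#'   \item{tirf}{\code{spec}: arguments for \code{\link{tirf_field_spec}};
#'     \code{metric_mode}; \code{control_condition} (default
#'     \code{"filament"}).}
#' }
#' Stage seeds are derived deterministically from the top-level seed unless
#' a spec supplies its own.
#'
#' @param config list or path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a path to one")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # canonical config + provenance
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["config"] <- cfg_path

  if (!is.null(config$caps)) {
    cc <- config$caps
    if (!is.null(cc$input_image)) {
      if (!file.exists(cc$input_image))
        stop("caps stage: input image not found: ", cc$input_image)
      img <- read_image_tiff(cc$input_image, cc$pixel_size_um)
      if (!inherits(img, "image2d"))
        stop("caps stage: input_image must be an intensity image, not a label map")
      truth <- NULL
      note("caps: read %s", cc$input_image)
    } else {
      spec_args <- if (is.null(cc$spec)) list() else cc$spec
      if (is.null(spec_args$seed)) spec_args$seed <- seed
      spec <- do.call(cap_field_spec, spec_args)
      field <- generate_cap_field(spec)
      img <- field$image; truth <- field$truth
      p <- write_cap_field(field, out_dir, "caps")
      paths <- c(paths, p)
      note("caps: simulated %d caps (seed %d)", truth$n_caps, spec$seed)
    }
    sp_args <- if (is.null(cc$segmentation)) list() else cc$segmentation
    params <- do.call(segmentation_params, sp_args)
    lm <- segment_caps(img, params)
    tab <- cap_table(lm)
    p_lab <- file.path(out_dir, "caps_labels.tif")
    p_tab <- file.path(out_dir, "caps_table.csv")
    write_image_tiff(lm, p_lab)
    write.csv(tab, p_tab, row.names = FALSE)
    thr <- if (is.null(cc$small_threshold_um2)) 80 else cc$small_threshold_um2
    s <- cap_statistics(tab, thr)
    field_area <- prod(dim(img$pixels)) * img$pixel_size_um^2
    summ <- data.frame(n_caps = s$n_caps,
                       mean_cap_area_um2 = s$mean_cap_area_um2,
                       small_cap_fraction = s$small_cap_fraction,
                       nuclear_density_per_um2 =
                         nuclear_density(s$n_caps, field_area))
    p_sum <- file.path(out_dir, "caps_summary.csv")
    write.csv(summ, p_sum, row.names = FALSE)
    paths <- c(paths, labels_out = p_lab, table_out = p_tab, summary = p_sum)
    note("caps: segmented %d regions", s$n_caps)
  }

  if (!is.null(config$binding)) {
    bc <- config$binding
    if (!is.null(bc$input_table)) {
      if (!file.exists(bc$input_table))
        stop("binding stage: input table not found: ", bc$input_table)
      ds <- read.csv(bc$input_table)
      note("binding: read %s", bc$input_table)
    } else {
      spec_args <- if (is.null(bc$spec)) list() else bc$spec
      if (is.null(spec_args$seed)) spec_args$seed <- seed + 1L
      bspec <- do.call(binding_sim_spec, spec_args)
      ds <- generate_binding_table(bspec)
      note("binding: simulated %d reactions (seed %d)", nrow(ds), bspec$seed)
    }
    p_ds <- file.path(out_dir, "binding_table.csv")
    write.csv(ds, p_ds, row.names = FALSE)
    fb <- fraction_bound(ds)
    p_fb <- file.path(out_dir, "fraction_bound.csv")
    write.csv(fb, p_fb, row.names = FALSE)
    mode <- if (is.null(bc$plateau_mode)) "fixed_1" else bc$plateau_mode
    nb <- if (is.null(bc$n_boot)) 200 else bc$n_boot
    fit <- fit_hill(fb$actin_conc_um, fb$fraction_bound,
                    plateau_mode = mode, n_boot = nb, seed = seed + 2L)
    p_fit <- file.path(out_dir, "hill_fit.json")
    fit_out <- list(kd_um = fit$kd_um, h = fit$h, plateau = fit$plateau,
                    rss = fit$rss, plateau_mode = fit$plateau_mode,
                    n_boot = fit$n_boot,
                    ci = if (is.null(fit$ci)) NULL else
                      as.data.frame(cbind(parameter = rownames(fit$ci),
                                          as.data.frame(fit$ci))))
    jsonlite::write_json(fit_out, p_fit, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, binding_table = p_ds, fraction_bound = p_fb,
               hill_fit = p_fit)
    note("binding: Kd = %.4g uM, h = %.3g", fit$kd_um, fit$h)
  }

  if (!is.null(config$tirf)) {
    tc <- config$tirf
    spec_args <- if (is.null(tc$spec)) list() else tc$spec
    if (is.null(spec_args$seed)) spec_args$seed <- seed + 3L
    tspec <- do.call(tirf_field_spec, spec_args)
    gen <- generate_tirf_profiles(tspec)
    mode <- if (is.null(tc$metric_mode)) "amplitude" else tc$metric_mode
    ctrl <- if (is.null(tc$control_condition)) "filament" else tc$control_condition
    fits <- lapply(gen$profiles, fit_gaussian)
    metrics <- vapply(fits, bundle_intensity_metric, numeric(1), mode = mode)
    cond <- vapply(gen$profiles, function(p) p$condition, character(1))
    if (!any(cond == ctrl)) stop("tirf stage: no profiles in control condition ", ctrl)
    res <- data.frame(condition = cond,
                      true_filament_count = gen$true_counts,
                      amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
                      fwhm_px = vapply(fits, `[[`, numeric(1), "fwhm"),
                      metric = metrics,
                      normalized_intensity =
                        normalize_to_control(metrics, metrics[cond == ctrl]))
    p_tirf <- file.path(out_dir, "tirf_metrics.csv")
    write.csv(res, p_tirf, row.names = FALSE)
    paths <- c(paths, tirf_metrics = p_tirf)
    note("tirf: %d profiles, control mean normalized to 1", nrow(res))
  }

  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               seed = seed,
               package = "syncap",
               package_version = as.character(utils::packageVersion("syncap")),
               r_version = R.version.string)
  p_prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, p_prov, auto_unbox = TRUE, pretty = TRUE)
  p_log <- file.path(out_dir, "log.txt")
  writeLines(log_lines, p_log)
  paths <- c(paths, provenance = p_prov, log = p_log)
  invisible(paths)
}
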