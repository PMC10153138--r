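#' Cooperative Hill binding curve
#'
#' f(A) = plateau * A^h / (kd^h + A^h); the fraction of binder co-pelleting
#' with F-actin at concentration A. At A = kd (with plateau 1) the fraction
#' is 0.5; h controls cooperativity.
#'
#' @param conc_um F-actin concentration(s), um.
#' @param kd_um half-saturation constant, um.
#' @param h Hill coefficient.
#' @param plateau saturating fraction (default 1).
#' @return numeric vector of bound fractions.
#' @export
hill_fraction <- function(conc_um, kd_um, h, plateau = 1) {
  if (kd_um <= 0 || h <= 0) stop("kd_um and h must be > 0")
  out <- plateau * conc_um^h / (kd_um^h + conc_um^h)
  out[conc_um == 0] <- 0
  out
}

#' Specification of a synthetic co-sedimentation experiment
#'
#' Emulates a high-speed pelleting assay in which a fixed amount of binder
#' is incubated with variable F-actin and the supernatant/pellet split is
#' quantified by densitometry. Defaults are the assay's study conditions:
#' F-actin at 0, 0.1, 0.25, 0.5, 1, 2 and 4 um, three replicates, and the
#' reported binding parameters kd = 0.45 um, h = 2.9.
#'
#' @param true_kd_um,true_h,true_plateau ground-truth Hill parameters.
#' @param concentrations_um F-actin concentrations; must include 0 (the
#'   nonspecific-pelleting control reaction).
#' @param nonspecific_pellet_fraction fraction of binder pelleting without
#'   F-actin (default 0.05).
#' @param noise_sd additive Gaussian noise on the pellet fraction (< 0.2).
#' @param n_replicates replicates per concentration.
#' @param seed integer RNG seed.
#' @return list of class \code{binding_sim_spec}.
#' @export
binding_sim_spec <- function(true_kd_um = 0.45, true_h = 2.9,
                             true_plateau = 1,
                             concentrations_um = c(0, 0.1, 0.25, 0.5, 1, 2, 4),
                             nonspecific_pellet_fraction = 0.05,
                             noise_sd = 0.02, n_replicates = 3, seed = 1L) {
  if (true_kd_um <= 0 || true_h <= 0) stop("true_kd_um and true_h must be > 0")
  if (true_plateau <= 0 || true_plateau > 1) stop("true_plateau must be in (0,1]")
  if (!any(concentrations_um == 0))
    stop("concentrations_um must include 0 (nonspecific control)")
  if (any(concentrations_um < 0)) stop("concentrations must be >= 0")
  if (nonspecific_pellet_fraction < 0 || nonspecific_pellet_fraction >= 1)
    stop("nonspecific_pellet_fraction must be in [0,1)")
  if (noise_sd < 0 || noise_sd >= 0.2) stop("noise_sd must be in [0, 0.2)")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(true_kd_um = true_kd_um, true_h = true_h,
                 true_plateau = true_plateau,
                 concentrations_um = concentrations_um,
                 nonspecific_pellet_fraction = nonspecific_pellet_fraction,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "binding_sim_spec")
}

#' Generate a synthetic binding densitometry table
#'
#' For each concentration A and replicate the pellet fraction is
#' ns + plateau * A^h / (kd^h + A^h) * (1 - ns) + noise, clipped to [0, 1]
#' (ns = nonspecific pellet fraction). The supernatant fraction is its
#' complement; both are converted to band intensities with a fixed total of
#' 1000 densitometry units per reaction.
#'
#' @param spec \code{binding_sim_spec}.
#' @param condition condition label stored in the table.
#' @return data frame with columns \code{actin_conc_um}, \code{replicate},
#'   \code{supernatant_intensity}, \code{pellet_intensity},
#'   \code{condition}.
#' @export
generate_binding_table <- function(spec, condition = "binder") {
  stopifnot(inherits(spec, "binding_sim_spec"))
  withr::with_seed(spec$seed, {
    grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                        actin_conc_um = spec$concentrations_um)
    spec_frac <- hill_fraction(grid$actin_conc_um, spec$true_kd_um,
                               spec$true_h, spec$true_plateau)
    p <- spec$nonspecific_pellet_fraction +
      spec_frac * (1 - spec$nonspecific_pellet_fraction)
    if (spec$noise_sd > 0) p <- p + rnorm(nrow(grid), 0, spec$noise_sd)
    p <- pmin(pmax(p, 0), 1)
    total <- 1000
    data.frame(actin_conc_um = grid$actin_conc_um,
               replicate = grid$replicate,
               supernatant_intensity = (1 - p) * total,
               pellet_intensity = p * total,
               condition = condition)
  })
}

#' Generate a synthetic low-speed pelleting table
#'
#' Emulates the bundling assay: at low centrifugal force only large actin
#' assemblies pellet, so the pelleted fraction of the actin band shifts up
#' when a bundler is present. One row per condition and replicate.
#'
#' @param fraction_by_condition named numeric vector of true mean pelleted
#'   fractions, e.g. \code{c(actin_only = 0.1, plus_binder = 0.6)}.
#' @param noise_sd Gaussian noise on the fraction, clipped to [0,1].
#' @param n_replicates replicates per condition.
#' @param actin_conc_um actin concentration recorded in the table
#'   (default 2).
#' @param seed integer RNG seed.
#' @return data frame in the same densitometry layout as
#'   \code{\link{generate_binding_table}}.
#' @export
generate_lowspeed_table <- function(fraction_by_condition,
                                    noise_sd = 0.03, n_replicates = 3,
                                    actin_conc_um = 2, seed = 1L) {
  if (is.null(names(fraction_by_condition)) ||
      any(!nzchar(names(fraction_by_condition))))
    stop("fraction_by_condition must be a named vector")
  if (any(fraction_by_condition < 0 | fraction_by_condition > 1))
    stop("fractions must be in [0,1]")
  withr::with_seed(seed, {
    rows <- lapply(names(fraction_by_condition), function(cond) {
      p <- fraction_by_condition[[cond]] + rnorm(n_replicates, 0, noise_sd)
      p <- pmin(pmax(p, 0), 1)
      data.frame(actin_conc_um = actin_conc_um,
                 replicate = seq_len(n_replicates),
                 supernatant_intensity = (1 - p) * 1000,
                 pellet_intensity = p * 1000,
                 condition = cond)
    })
    do.call(rbind, rows)
  })
}
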