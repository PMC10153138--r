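check_binding_dataset <- function(ds) {
  need <- c("actin_conc_um", "replicate", "supernatant_intensity",
            "pellet_intensity")
  miss <- setdiff(need, names(ds))
  if (length(miss) > 0)
    stop("binding dataset lacks columns: ", paste(miss, collapse = ", "))
  if (any(ds$actin_conc_um < 0)) stop("actin concentrations must be >= 0")
  tot <- ds$supernatant_intensity + ds$pellet_intensity
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("supernatant + pellet intensity must be positive in every row")
  invisible(ds)
}

#' Fraction of binder bound to F-actin, with nonspecific correction
#'
#' Per reaction the raw pellet fraction is p = pellet / (pellet +
#' supernatant). The binder that pellets nonspecifically is estimated as
#' p0, the mean raw pellet fraction of the zero-actin control reactions,
#' and subtracted: with \code{renormalize = TRUE} (default) the corrected
#' fraction is (p - p0) / (1 - p0), so full binding maps to 1; with
#' \code{renormalize = FALSE} it is the plain difference p - p0. Either way
#' the result is clipped to [0, 1] and the zero-concentration control rows
#' are dropped from the output used for curve fitting.
#'
#' @param ds binding dataset (see \code{\link{generate_binding_table}} for
#'   the column layout); must contain at least one zero-concentration row.
#' @param renormalize divide by (1 - p0) after subtraction (default TRUE).
#' @return data frame: \code{actin_conc_um}, \code{replicate},
#'   \code{fraction_bound}.
#' @export
fraction_bound <- function(ds, renormalize = TRUE) {
  check_binding_dataset(ds)
  p <- ds$pellet_intensity / (ds$pellet_intensity + ds$supernatant_intensity)
  zero <- ds$actin_conc_um == 0
  if (!any(zero)) stop("no zero-concentration control rows for nonspecific correction")
  p0 <- mean(p[zero])
  if (p0 >= 1) stop("nonspecific pellet fraction is 1; dataset degenerate")
  fb <- if (renormalize) (p - p0) / (1 - p0) else p - p0
  fb <- pmin(pmax(fb, 0), 1)
  out <- data.frame(actin_conc_um = ds$actin_conc_um,
                    replicate = ds$replicate, fraction_bound = fb)
  out[!zero, , drop = FALSE]
}

#' Fit the cooperative Hill binding model
#'
#' Nonlinear least squares for f(A) = plateau * A^h / (kd^h + A^h), with the
#' plateau either fixed at 1 (\code{plateau_mode = "fixed_1"}, the default:
#' fraction bound saturates at 1) or floated in (0, 1.5]. Because Hill fits
#' are multimodal at small n, fitting is multi-start: kd from \{min,
#' geometric mean, max\} of the concentrations crossed with h in \{1, 2,
#' 4\}; the lowest-RSS converged fit wins. Confidence intervals are
#' percentile bootstrap over resampled points (seeded; resamples with fewer
#' than 4 distinct concentrations are redrawn).
#'
#' @param conc_um concentrations (> 0), at least 4 distinct values.
#' @param fraction_bound fractions in [0, 1], same length.
#' @param plateau_mode \code{"fixed_1"} or \code{"free"}.
#' @param n_boot bootstrap resamples for CIs (default 1000; 0 disables).
#' @param conf_level CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return object of class \code{hill_fit}: \code{kd_um}, \code{h},
#'   \code{plateau}, \code{rss}, \code{converged}, \code{ci} (matrix or
#'   NULL), \code{n_boot}, \code{plateau_mode}, \code{data}.
#' @export
fit_hill <- function(conc_um, fraction_bound,
                     plateau_mode = c("fixed_1", "free"),
                     n_boot = 1000, conf_level = 0.95, seed = 1L) {
  plateau_mode <- match.arg(plateau_mode)
  if (length(conc_um) != length(fraction_bound))
    stop("conc_um and fraction_bound must have equal length")
  keep <- is.finite(conc_um) & is.finite(fraction_bound)
  conc_um <- conc_um[keep]; fraction_bound <- fraction_bound[keep]
  if (length(unique(conc_um)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(conc_um <= 0)) stop("concentrations must be > 0 for fitting")
  if (any(fraction_bound < 0 | fraction_bound > 1))
    stop("fractions must be in [0, 1]")
  if (sd(fraction_bound) == 0)
    stop("degenerate data: all fractions equal")

  est <- hill_nls_multistart(conc_um, fraction_bound, plateau_mode)
  if (is.null(est)) stop("Hill fit did not converge from any start")

  ci <- NULL
  if (n_boot > 0) {
    boots <- hill_bootstrap(conc_um, fraction_bound, plateau_mode, est,
                            n_boot, seed)
    if (nrow(boots) > 0) {
      a <- (1 - conf_level) / 2
      ci <- t(apply(boots, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
      colnames(ci) <- c("lower", "upper")
    }
  }
  structure(list(kd_um = est$kd, h = est$h, plateau = est$plateau,
                 rss = est$rss, converged = TRUE, ci = ci,
                 n_boot = n_boot, plateau_mode = plateau_mode,
                 data = data.frame(actin_conc_um = conc_um,
                                   fraction_bound = fraction_bound)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Kd = %.4g uM, h = %.3g, plateau = %.3g (%s), RSS = %.3g\n",
              x$kd_um, x$h, x$plateau, x$plateau_mode, x$rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %d x, 95%% CI: Kd [%.3g, %.3g], h [%.3g, %.3g]\n",
                x$n_boot, x$ci["kd", 1], x$ci["kd", 2],
                x$ci["h", 1], x$ci["h", 2]))
  }
  invisible(x)
}

#' Predict from a Hill fit
#'
#' @param object \code{hill_fit}.
#' @param conc_um concentrations at which to evaluate the fitted curve.
#' @param ... unused.
#' @return fitted bound fractions.
#' @export
predict.hill_fit <- function(object, conc_um, ...) {
  hill_fraction(conc_um, object$kd_um, object$h, object$plateau)
}

hill_nls_multistart <- function(conc, fb, plateau_mode, starts = NULL) {
  lower_kd <- 1e-6; upper_kd <- 1e4
  lower_h <- 0.05; upper_h <- 20
  if (is.null(starts)) {
    kd0 <- unique(c(min(conc), exp(mean(log(conc))), max(conc)))
    h0 <- c(1, 2, 4)
    starts <- expand.grid(kd = kd0, h = h0)
  }
  fixed <- plateau_mode == "fixed_1"
  model <- function(p) {
    pl <- if (fixed) 1 else p["plateau"]
    pl * conc^p["h"] / (p["kd"]^p["h"] + conc^p["h"])
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(kd = starts$kd[i], h = starts$h[i])
    lo <- c(kd = lower_kd, h = lower_h)
    up <- c(kd = upper_kd, h = upper_h)
    if (!fixed) {
      p0["plateau"] <- if (!is.null(starts$plateau)) starts$plateau[i] else
        min(max(max(fb), 0.1), 1.5)
      lo["plateau"] <- 1e-3; up["plateau"] <- 1.5
    }
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = up,
                         fn = function(p) fb - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      cf <- fit$par
      best <- list(kd = unname(cf["kd"]), h = unname(cf["h"]),
                   plateau = if (fixed) 1 else unname(cf["plateau"]),
                   rss = rss)
    }
  }
  best
}

hill_bootstrap <- function(conc, fb, plateau_mode, est, n_boot, seed) {
  n <- length(conc)
  start1 <- data.frame(kd = est$kd, h = est$h)
  if (plateau_mode == "free") start1$plateau <- est$plateau
  withr::with_seed(seed, {
    rows <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(conc[idx])) >= 4) break
      }
      fit <- hill_nls_multistart(conc[idx], fb[idx], plateau_mode, start1)
      rows[[b]] <- if (is.null(fit)) c(kd = NA_real_, h = NA_real_)
                   else c(kd = fit$kd, h = fit$h)
    }
    do.call(rbind, rows)
  })
}

#' Low-speed pelleting: fraction of actin pelleted per condition
#'
#' At low centrifugal force single actin filaments stay in the supernatant
#' while bundles pellet, so the pelleted fraction of the actin band reports
#' bundling. Per replicate the fraction pelleted is pellet / (pellet +
#' supernatant); replicates are aggregated per condition.
#'
#' @param ds binding dataset with a \code{condition} column.
#' @return data frame: \code{condition}, \code{n}, \code{mean_fraction_pelleted},
#'   \code{sd_fraction_pelleted}.
#' @export
lowspeed_fraction_pelleted <- function(ds) {
  check_binding_dataset(ds)
  if (is.null(ds$condition)) stop("dataset needs a condition column")
  if (any(is.na(ds$condition))) stop("empty condition labels")
  p <- ds$pellet_intensity / (ds$pellet_intensity + ds$supernatant_intensity)
  sp <- split(p, ds$condition)
  out <- data.frame(condition = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean_fraction_pelleted = vapply(sp, mean, numeric(1)),
                    sd_fraction_pelleted = vapply(sp, function(v)
                      if (length(v) > 1) sd(v) else 0, numeric(1)))
  rownames(out) <- NULL
  out
}
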