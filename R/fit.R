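#' Mean percentage error between a profile and a contour model
#'
#' The fit criterion
#' `epsilon = (100/k) * sum(|v1 - v2| / |v1|)` over the profile's own
#' axial positions, where `v1` is the measured half-breadth and `v2` the
#' model half-breadth at the same `x`. Points with `|v1| < 1e-9 * B`
#' (the tips, where the relative error is undefined) are excluded from
#' the sum, and `k` counts the included points. The metric is invariant
#' under uniform rescaling of both contours.
#'
#' @param profile an [egg_profile].
#' @param spec an [egg_spec] evaluated at the profile's (normalized,
#'   centered) `x` values.
#' @return `epsilon` in percent, with attributes `k_used` and `excluded`.
#' @examples
#' spec <- egg_spec("SM_MA", L = 398, B = 298, w = 20)
#' egg_epsilon(synth_profile(spec, 398), spec)   # 0: the model matches
#' @export
egg_epsilon <- function(profile, spec) {
  stopifnot(inherits(profile, "egg_profile"), inherits(spec, "egg_spec"))
  p <- .normalize_profile(profile)
  L <- spec$dims$L
  x <- pmin(pmax(p$x, -L / 2), L / 2)
  rep <- .epsilon_report(p$y, egg_contour(spec, x), spec$dims$B)
  structure(rep$epsilon, k_used = rep$k_used, excluded = rep$excluded)
}

.epsilon_report <- function(v1, v2, B) {
  keep <- abs(v1) >= 1e-9 * B
  if (!any(keep)) stop("undefined metric: every point was excluded")
  list(epsilon = 100 * mean(abs((v1[keep] - v2[keep]) / v1[keep])),
       k_used = sum(keep), excluded = sum(!keep))
}

# build a spec for `variant` from measured parameters
.spec_from_measure <- function(variant, m, profile = NULL) {
  tt <- NULL
  if (variant == "SM") {
    if (is.null(profile))
      stop("variant 'SM' needs the profile to refit tan theta")
    tt <- refit_tan_theta(profile, m$dims)
  }
  egg_spec(variant, dims = m$dims, B0 = m$B0, r = m$r, R = m$R,
           tan_theta = tt)
}

#' Fit a Smart-family contour model to a digitized profile
#'
#' The central modelling function: measures the profile's parameters
#' ([measure_profile]), resolves the requested variant's slope parameter
#' from them, and evaluates the resulting contour against the profile
#' with the mean-percentage-error criterion ([egg_epsilon]) and the
#' Main-Axiom residuals ([axiom_residual]). The raw `"SM"` variant has no
#' fixed-point estimator for `tan theta` and uses the least-squares
#' refit ([refit_tan_theta]) instead.
#'
#' @param profile an [egg_profile].
#' @param variant one of [SM_VARIANTS].
#' @param measure optionally a precomputed [measure_profile] result
#'   (reused across variants by [compare_variants]).
#' @return An object of class `"egg_fit"` with components `variant`,
#'   `spec`, `measure`, `epsilon`, `k_used`, `excluded`, `axiom`, `x`,
#'   `observed`, `fitted`, and methods `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' p <- standard_fixtures(seed = 1)$ovoid
#' fit <- egg_fit(p, "SM_r")
#' coef(fit)
#' @export
egg_fit <- function(profile, variant = "SM_r", measure = NULL) {
  stopifnot(inherits(profile, "egg_profile"))
  variant <- match.arg(variant, SM_VARIANTS)
  if (is.null(measure)) measure <- measure_profile(profile)
  stopifnot(inherits(measure, "egg_measure"))
  spec <- .spec_from_measure(variant, measure, profile)
  p <- .normalize_profile(profile)
  L <- spec$dims$L
  x <- pmin(pmax(p$x, -L / 2), L / 2)
  yhat <- egg_contour(spec, x)
  rep <- .epsilon_report(p$y, yhat, spec$dims$B)
  structure(list(variant = variant, spec = spec, measure = measure,
                 epsilon = rep$epsilon, k_used = rep$k_used,
                 excluded = rep$excluded,
                 axiom = axiom_residual(spec),
                 x = x, observed = p$y, fitted = yhat,
                 units = p$units),
            class = "egg_fit")
}

#' @export
print.egg_fit <- function(x, ...) {
  cat(sprintf("Egg contour fit, variant %s (%s measured parameters)\n",
              x$variant,
              ifelse(is.na(variant_n_params(x$variant)), "refit",
                     variant_n_params(x$variant))))
  print(x$measure$dims)
  cat(sprintf("  tan theta = %.6g\n", x$spec$tan_theta))
  cat(sprintf("  mean percentage error = %.4g%% over %d points (%d excluded)\n",
              x$epsilon, x$k_used, x$excluded))
  print(x$axiom)
  invisible(x)
}

#' @export
summary.egg_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 res_quartiles = stats::quantile(res),
                 max_abs_res = max(abs(res)),
                 nonphysical = any(object$fitted < 0),
                 volume = tryCatch(egg_volume(object$spec),
                                   error = function(e) NULL)),
            class = "summary.egg_fit")
}

#' @export
print.summary.egg_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residuals (%s): max |r| = %.4g\n",
              x$fit$units, x$max_abs_res))
  print(signif(x$res_quartiles, 4))
  if (x$nonphysical)
    cat("  warning: fitted contour goes negative near a tip\n")
  if (!is.null(x$volume)) print(x$volume)
  invisible(x)
}

#' @export
coef.egg_fit <- function(object, ...) {
  m <- object$measure
  c(L = m$dims$L, B = m$dims$B, w = m$dims$w,
    B0 = m$B0, r = m$r, R = m$R,
    tan_theta = object$spec$tan_theta,
    P = object$spec$P, Q = object$spec$Q)
}

#' @export
predict.egg_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$fitted)
  egg_contour(object$spec, x)
}

#' @export
fitted.egg_fit <- function(object, ...) object$fitted

#' @export
residuals.egg_fit <- function(object, ...) object$observed - object$fitted

#' @export
plot.egg_fit <- function(x, ...) {
  graphics::plot(x$x, x$observed, pch = 16, cex = 0.4, asp = 1,
                 xlab = sprintf("x (%s)", x$units),
                 ylab = sprintf("half-breadth (%s)", x$units),
                 main = sprintf("%s fit, epsilon = %.3g%%",
                                x$variant, x$epsilon), ...)
  graphics::points(x$x, -x$observed, pch = 16, cex = 0.4)
  xx <- seq(min(x$x), max(x$x), length.out = 512)
  yy <- egg_contour(x$spec, xx)
  graphics::lines(xx, yy, col = "red3")
  graphics::lines(xx, -yy, col = "red3")
  graphics::abline(v = x$spec$dims$w, lty = 3)
  invisible(x)
}

#' @export
simulate.egg_fit <- function(object, nsim = 1, seed = NULL,
                             n_points = NULL, quantize = TRUE,
                             noise_sd = 0, ...) {
  if (is.null(n_points)) n_points <- length(object$x)
  base <- if (is.null(seed)) sample.int(1e6, 1) else seed
  lapply(seq_len(nsim), function(i)
    synth_profile(object$spec, n_points = n_points, quantize = quantize,
                  noise_sd = noise_sd, seed = base + i - 1L,
                  units = object$units))
}

#' Fit and rank every model variant on one profile
#'
#' Measures the profile once, fits each requested variant, and reports
#' accuracy (mean percentage error) and geometric compliance (Main-Axiom
#' residuals) side by side — a model is judged on the combination of the
#' two, not on either alone. Variants are ranked by ascending error.
#'
#' @param profile an [egg_profile].
#' @param variants character vector of variants to fit (default: the six
#'   field-measurable ones).
#' @return An object of class `"egg_fit_set"`: list with `table` (one row
#'   per variant: `variant`, `n_params`, `epsilon`, `value_residual`,
#'   `slope_residual`, `compliant`, sorted by `epsilon`), `fits` (named
#'   list of [egg_fit] objects) and `measure`.
#' @examples
#' compare_variants(standard_fixtures(seed = 1)$pyriform)
#' @export
compare_variants <- function(profile,
                             variants = c("SM_r", "SM_B0", "SM_U",
                                          "SM_B02", "SM_r2", "SM_MA")) {
  variants <- match.arg(variants, SM_VARIANTS, several.ok = TRUE)
  m <- measure_profile(profile)
  fits <- lapply(variants, function(v)
    tryCatch(egg_fit(profile, v, measure = m), error = function(e) {
      warning("variant ", v, " could not be configured: ",
              conditionMessage(e))
      NULL
    }))
  names(fits) <- variants
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]; variants <- variants[keep]
  if (!length(fits)) stop("no variant could be fitted to this profile")
  tab <- data.frame(
    variant = variants,
    n_params = variant_n_params(variants),
    epsilon = vapply(fits, `[[`, numeric(1), "epsilon"),
    value_residual = vapply(fits, function(f) f$axiom$value_residual,
                            numeric(1)),
    slope_residual = vapply(fits, function(f) f$axiom$slope_residual,
                            numeric(1)),
    compliant = vapply(fits, function(f) f$axiom$compliant, logical(1)),
    row.names = NULL)
  o <- order(tab$epsilon)
  structure(list(table = tab[o, ], fits = fits[o], measure = m),
            class = "egg_fit_set")
}

#' @export
print.egg_fit_set <- function(x, ...) {
  cat("Model-variant comparison (ranked by mean percentage error):\n")
  tab <- x$table
  tab$epsilon <- signif(tab$epsilon, 4)
  tab$value_residual <- signif(tab$value_residual, 3)
  tab$slope_residual <- signif(tab$slope_residual, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
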