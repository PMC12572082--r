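#' Main-Axiom residuals of a contour model
#'
#' The Main Axiom of an egg contour formula requires the function's
#' interior extremum to sit exactly at the measured maximum-breadth
#' section: `y(w) = B/2` and `y'(w) = 0`. Because every variant is
#' anchored through `(w, B/2)` by construction, the value residual is zero
#' up to rounding; the slope residual
#' `y'(w) = Q*sqrt(L^2 - 4*w^2) - 2*B*w/(L^2 - 4*w^2)` is the informative
#' part and vanishes only for Axiom-compatible parameter combinations
#' (always for variant `"SM_MA"`).
#'
#' @param spec an [egg_spec] object.
#' @param tol_value tolerance on `|y(w) - B/2|`, relative to `B`.
#' @param tol_slope absolute tolerance on the dimensionless slope.
#' @return An object of class `"egg_axiom"`: list with `value_residual`
#'   (length units), `slope_residual` (dimensionless), `compliant`.
#' @examples
#' axiom_residual(egg_spec("SM_MA", L = 60, B = 45, w = 3))$compliant
#' @export
axiom_residual <- function(spec, tol_value = 1e-12, tol_slope = 1e-9) {
  stopifnot(inherits(spec, "egg_spec"))
  d <- spec$dims
  vr <- egg_contour(spec, d$w) - d$B / 2
  sr <- spec$Q * .rad(d$L, d$w) - 2 * d$B * d$w / (d$L^2 - 4 * d$w^2)
  structure(list(value_residual = vr, slope_residual = sr,
                 compliant = abs(vr) <= tol_value * d$B &&
                             abs(sr) <= tol_slope),
            class = "egg_axiom")
}

#' @export
print.egg_axiom <- function(x, ...) {
  cat(sprintf("Main Axiom: %s  (y(w) - B/2 = %.3g, y'(w) = %.3g)\n",
              if (x$compliant) "compliant" else "violated",
              x$value_residual, x$slope_residual))
  invisible(x)
}

#' Slope parameter enforcing the Main Axiom
#'
#' The unique `tan theta` for which the canonical contour's extremum falls
#' at `(w, B/2)`:
#' `tan theta = 2*B*L*w / ((L^2 - 4*w^2) * sqrt(L^2 - 4*w^2))`.
#' Identical to `tan_theta_resolve("SM_MA", dims)`.
#'
#' @param dims an [egg_dims] object.
#' @return `tan theta` (dimensionless).
#' @export
axiom_tan_theta <- function(dims) tan_theta_resolve("SM_MA", dims)

#' Pointed quarter-radius required for SM_r Axiom compliance
#'
#' Differentiating the five-parameter model and forcing its extremum to
#' `x = w` ties the two quarter-length radii (half-breadths) together:
#' `r = R - sqrt(3)*L^2*B*w / (2*(L^2 - 4*w^2)*sqrt(L^2 - 4*w^2))`.
#'
#' @param dims an [egg_dims] object.
#' @param R blunt-side quarter-length radius (half-breadth) (`> 0`).
#' @return The required `r`, same units. May be non-positive for extreme
#'   inputs, in which case a warning flags the combination as
#'   non-physical.
#' @export
axiom_required_r <- function(dims, R) {
  stopifnot(inherits(dims, "egg_dims"), is.numeric(R), all(R > 0))
  L <- dims$L; B <- dims$B; w <- dims$w
  r <- R - sqrt(3) * L^2 * B * w / (2 * (L^2 - 4 * w^2) * .rad(L, w))
  if (any(r <= 0))
    warning("required r <= 0: no physical egg satisfies the Axiom here")
  r
}

#' Axiom-compatible r/B ratio as a function of elongation
#'
#' Combining the compliance condition on `r` with the universal ovoid
#' expression for the blunt-side radius `R` leaves a one-variable curve
#' in `t = w/L`:
#' `r/B = (sqrt(3)/2) * (1/(2*sqrt(1 - 2t + 4t^2))
#'        - 1/((1 - 4t^2)*sqrt(t^-2 - 4)))`,
#' with the `t = 0` value taken as the analytic limit `sqrt(3)/4`. Over
#' the empirical band `t` in `[0, 0.2]` the ratio spans roughly
#' 0.27 to 0.43.
#'
#' @param t `w/L` values, `0 <= t < 0.5` (warning above 0.2).
#' @return `r/B` values (dimensionless).
#' @export
axiom_r_curve <- function(t) {
  stopifnot(is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0) || any(t >= 0.5))
    stop("'t' = w/L must lie in [0, 0.5)")
  if (any(t > 0.2))
    warning("t = w/L above the empirical band [0, 0.2]")
  out <- numeric(length(t))
  z <- t == 0
  out[z] <- sqrt(3) / 4                 # limit: second term vanishes
  tt <- t[!z]
  out[!z] <- sqrt(3) / 2 *
    (1 / (2 * sqrt(1 - 2 * tt + 4 * tt^2)) -
     1 / ((1 - 4 * tt^2) * sqrt(tt^-2 - 4)))
  out
}

#' Boundary-shape ratio table
#'
#' Dimensionless bounds on the shape ratios as functions of `t = w/L`:
#' the mid-length breadth ratio `B0/B` between its parabolic minimum,
#' ovoid (Huegelschaeffer) maximum and their mean; the pointed
#' quarter-radius ratio `r/B` under the same three pointed-end rules;
#' the universal blunt-side ratio `R/B`; and the Axiom-compatible `r/B`
#' curve of [axiom_r_curve].
#'
#' @param t `w/L` values in `[0, 0.5)`.
#' @return A data frame with one row per `t`: columns `t`,
#'   `b0_over_B_min`, `b0_over_B_avg`, `b0_over_B_max`,
#'   `r_over_B_parabola`, `r_over_B_avg`, `r_over_B_huegel`, `R_over_B`,
#'   `r_over_B_axiom`.
#' @export
ratio_bounds <- function(t) {
  stopifnot(is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0) || any(t >= 0.5))
    stop("'t' = w/L must lie in [0, 0.5)")
  b0_min <- 1 / sqrt(1 + 2 * t)
  b0_max <- 1 / sqrt(1 + 4 * t^2)
  r_par  <- 1 / (2 * sqrt(2 * (1 + 2 * t)))
  r_hue  <- 1 / 4 * sqrt(3 / (1 + 2 * t + 4 * t^2))
  R_ovr  <- 1 / 4 * sqrt(3 / (1 - 2 * t + 4 * t^2))
  data.frame(t = t,
             b0_over_B_min = b0_min,
             b0_over_B_avg = (b0_min + b0_max) / 2,
             b0_over_B_max = b0_max,
             r_over_B_parabola = r_par,
             r_over_B_avg = (r_par + r_hue) / 2,
             r_over_B_huegel = r_hue,
             R_over_B = R_ovr,
             r_over_B_axiom = suppressWarnings(axiom_r_curve(t)))
}

# auxiliary measurements implied by a ratio rule at elongation t (units B)
.rule_aux <- function(variant, rule, t) {
  rb <- ratio_bounds(t)
  if (variant == "SM_B0") {
    b0 <- switch(rule, parabola = rb$b0_over_B_min,
                 average = rb$b0_over_B_avg,
                 huegelschaeffer = rb$b0_over_B_max)
    list(B0 = b0)
  } else {
    r <- switch(rule, parabola = rb$r_over_B_parabola,
                average = rb$r_over_B_avg,
                huegelschaeffer = rb$r_over_B_huegel)
    list(r = r, R = rb$R_over_B)
  }
}

#' Atlas of normalized theoretical egg profiles
#'
#' Reconstructs the families of dimensionless profiles (`x/L` against
#' `y/B`) obtained by sweeping the elongation `t = w/L` over its empirical
#' band and filling the auxiliary measurements of the four- and
#' five-parameter models from one of the boundary-shape rules: the
#' parabolic lower bound, the Huegelschaeffer ovoid upper bound, or their
#' arithmetic mean ([ratio_bounds]). For every `t > 0` the resulting
#' contours overshoot `y/B = 0.5` and place their maximum away from
#' `x/L = t` — the geometric defect that motivates the Main Axiom.
#'
#' @param variant `"SM_B0"` (mid-breadth rule) or `"SM_r"`
#'   (quarter-radius rules).
#' @param ratio_rule `"huegelschaeffer"`, `"parabola"` or `"average"`.
#' @param t_grid elongation grid, subset of `[0, 0.2]` by default the
#'   five-step grid `0, 0.05, ..., 0.20`.
#' @param n points per profile.
#' @return An object of class `"egg_atlas"`: list with `profiles` (long
#'   data frame: `t`, `x_over_L`, `y_over_B`), `summary` (per `t`: maximum
#'   `y/B` and its location, found by optimization of the smooth contour),
#'   `variant`, `ratio_rule`.
#' @export
egg_atlas <- function(variant = c("SM_B0", "SM_r"),
                      ratio_rule = c("huegelschaeffer", "parabola", "average"),
                      t_grid = seq(0, 0.2, by = 0.05), n = 401) {
  variant <- match.arg(variant)
  ratio_rule <- match.arg(ratio_rule)
  stopifnot(is.numeric(t_grid), all(t_grid >= 0), all(t_grid <= 0.2),
            n >= 21)
  xg <- seq(-0.5, 0.5, length.out = n)
  prof <- list(); summ <- list()
  for (t in t_grid) {
    aux <- .rule_aux(variant, ratio_rule, t)
    spec <- egg_spec(variant, L = 1, B = 1, w = t,
                     B0 = aux$B0, r = aux$r, R = aux$R)
    y <- egg_contour(spec, xg)
    prof[[length(prof) + 1L]] <-
      data.frame(t = t, x_over_L = xg, y_over_B = y)
    opt <- stats::optimize(function(x) egg_contour(spec, x),
                           interval = c(-0.5, 0.5), maximum = TRUE,
                           tol = 1e-12)
    summ[[length(summ) + 1L]] <-
      data.frame(t = t, y_max_over_B = opt$objective,
                 x_at_max_over_L = opt$maximum)
  }
  structure(list(profiles = do.call(rbind, prof),
                 summary = do.call(rbind, summ),
                 variant = variant, ratio_rule = ratio_rule),
            class = "egg_atlas")
}

#' @export
print.egg_atlas <- function(x, ...) {
  cat(sprintf("Normalized %s profile atlas (%s rule)\n",
              x$variant, x$ratio_rule))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.egg_atlas <- function(x, ...) {
  pr <- x$profiles
  ts <- unique(pr$t)
  cols <- grDevices::hcl.colors(length(ts), "Zissou 1")
  graphics::plot(NA, xlim = c(-0.5, 0.5),
                 ylim = c(0, max(pr$y_over_B) * 1.05),
                 xlab = "x / L", ylab = "y / B",
                 main = sprintf("%s atlas, %s rule", x$variant,
                                x$ratio_rule), ...)
  graphics::abline(h = 0.5, lty = 3)
  for (i in seq_along(ts)) {
    p <- pr[pr$t == ts[i], ]
    graphics::lines(p$x_over_L, p$y_over_B, col = cols[i])
  }
  graphics::legend("bottomright", legend = sprintf("w/L = %.2f", ts),
                   col = cols, lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
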