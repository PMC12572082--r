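#' Measure the model parameters of a digitized profile
#'
#' Extracts the full Smart-family parameter set from a digitized outline:
#' length `L` (tip-to-tip span), maximum breadth `B` and its axial offset
#' `w`, the mid-length breadth `B0`, and the quarter-length radii `r`
#' (the half-breadth at `x = -L/4`, pointed side) and `R` (at `x = +L/4`,
#' blunt side). Note `B` and `B0` are full breadths while `r` and `R` are
#' half-breadths — the convention of the slope formulas, under which an
#' ellipse has `r = R = sqrt(3)/4 * B`. The profile is first normalized to
#' the pointed-end-at-negative-x convention with `x = 0` at the midpoint
#' of the two tips.
#'
#' `B` and `w` are taken from the interior extremum of a smooth
#' whole-profile fit: weighted linear least squares of `y` on the family
#' `(A + C*x) * sqrt(L^2 - 4*x^2)`, whose extremum is located by
#' optimization. Averaging over the full outline makes the estimate
#' robust to pixel quantization, which flattens the discrete maximum into
#' a plateau many pixels wide and defeats purely local refinement.
#' `B0`, `r` and `R` use piecewise-linear interpolation of the raw points
#' at `x = 0` and `x = -L/4`, `+L/4`.
#'
#' @param profile an [egg_profile].
#' @return An object of class `"egg_measure"`: list with `dims`
#'   ([egg_dims]), `B0`, `r`, `R`, `units`, `scale`, `provenance`
#'   (character notes on the estimators used).
#' @examples
#' p <- synth_profile(egg_spec("SM_MA", L = 398, B = 298, w = 20),
#'                    n_points = 398)
#' measure_profile(p)
#' @export
measure_profile <- function(profile) {
  stopifnot(inherits(profile, "egg_profile"))
  notes <- character()
  if (profile$orientation == "pointed_positive_x")
    notes <- c(notes, "orientation flipped to pointed_negative_x")
  p <- .normalize_profile(profile)
  x <- p$x; y <- p$y; n <- p$n
  if (which.max(y) %in% c(1L, n))
    stop("degenerate profile: the maximum breadth sits at an endpoint")
  if (min(y[c(1L, n)]) > min(y[-c(1L, n)]) + 1e-9 * max(y))
    warning("profile endpoints are not the smallest breadths; ",
            "are the tips included?")
  L <- x[n] - x[1L]

  # smooth fit y ~ (A + C x) sqrt(L^2 - 4 x^2); tips contribute zero rows
  rad <- .rad(L, x)
  fit <- stats::lm.fit(cbind(A = rad, C = x * rad), y)
  A <- fit$coefficients[["A"]]; C <- fit$coefficients[["C"]]
  f <- function(xx) (A + C * xx) * .rad(L, xx)
  opt <- stats::optimize(f, interval = c(-L / 2, L / 2), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * L)
  w <- opt$maximum
  if (abs(w) < 1e-6 * L) w <- 0          # symmetric within resolution
  if (w < 0) {
    # widest section toward the labelled pointed end: orientation mislabel
    notes <- c(notes, "negative breadth offset: profile re-flipped")
    return(measure_profile(flip_profile(profile)))
  }
  if (w >= L / 2 * 0.999)
    stop("degenerate profile: fitted maximum at the tip")
  B <- 2 * f(w)
  notes <- c(notes,
             "B, w from least-squares contour smoother (interior extremum)",
             "B0, r, R from piecewise-linear interpolation")
  at <- function(x0) stats::approx(x, y, xout = x0, rule = 2)$y
  m <- list(dims = egg_dims(L, B, w),
            B0 = 2 * at(0), r = at(-L / 4), R = at(L / 4),
            units = p$units, scale = p$scale, provenance = notes)
  structure(m, class = "egg_measure")
}

#' @export
print.egg_measure <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "Measured egg parameters (%s):\n  L = %.6g, B = %.6g, w = %.6g (w/L = %.4f)\n  B0 = %.6g, r = %.6g, R = %.6g\n",
    x$units, d$L, d$B, d$w, d$w / d$L, x$B0, x$r, x$R))
  invisible(x)
}

#' Least-squares slope parameter given the measured dimensions
#'
#' With `L`, `B`, `w` fixed, the canonical contour is linear in
#' `Q = tan theta / L`: minimizing the summed squared residuals of
#' `y` against `(P + Q*(x - w)) * sqrt(L^2 - 4*x^2)` over the interior
#' points has the closed-form solution
#' `Q = sum(R_i u_i (y_i - P R_i)) / sum(R_i^2 u_i^2)` with
#' `u = x - w` and `R_i` the radical. This recovers the generating
#' `tan theta` exactly on noiseless dense samples of any family member
#' and serves as a diagnostic slope estimate beyond the fixed-point
#' variant formulas.
#'
#' @param profile an [egg_profile].
#' @param dims an [egg_dims] object (typically from [measure_profile]).
#' @return `tan theta` (dimensionless).
#' @export
refit_tan_theta <- function(profile, dims) {
  stopifnot(inherits(profile, "egg_profile"), inherits(dims, "egg_dims"))
  p <- .normalize_profile(profile)
  L <- dims$L; w <- dims$w
  P <- dims$B / (2 * .rad(L, w))
  x <- pmin(pmax(p$x, -L / 2), L / 2)
  rad <- .rad(L, x)
  u <- x - w
  denom <- sum(rad^2 * u^2)
  if (denom <= 0) stop("degenerate profile: no interior leverage for Q")
  Q <- sum(rad * u * (p$y - P * rad)) / denom
  Q * L
}
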