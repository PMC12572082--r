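#' Evaluate the canonical egg contour
#'
#' The upper half-contour of every model variant in one canonical form,
#' `y(x) = (P + Q*(x - w)) * sqrt(L^2 - 4*x^2)` on `x` in `[-L/2, L/2]`
#' (pointed end at negative `x`). The full outline is `+/- y`. By
#' construction `y(w) = B/2` exactly and `y(+/- L/2) = 0`.
#'
#' For extreme parameter combinations the linear factor can become
#' negative near a tip; the signed value is returned unchanged (no
#' clamping) so that non-physical fits remain visible to diagnostics.
#'
#' @param spec an [egg_spec] object.
#' @param x axial coordinates within `[-L/2, L/2]`.
#' @return Numeric vector of signed half-breadths.
#' @export
egg_contour <- function(spec, x) {
  stopifnot(inherits(spec, "egg_spec"))
  L <- spec$dims$L
  x <- .check_x_domain(x, L)
  (spec$P + spec$Q * (x - spec$dims$w)) * .rad(L, x)
}

#' Analytic slope of the canonical contour
#'
#' `y'(x) = Q*sqrt(L^2 - 4*x^2) - (P + Q*(x - w)) * 4*x / sqrt(L^2 - 4*x^2)`.
#' Undefined at the tips (vertical tangent).
#'
#' @inheritParams egg_contour
#' @return Numeric vector of slopes `dy/dx`.
#' @export
egg_contour_slope <- function(spec, x) {
  stopifnot(inherits(spec, "egg_spec"))
  L <- spec$dims$L
  x <- .check_x_domain(x, L)
  s <- .rad(L, x)
  if (any(s == 0)) stop("slope is undefined at the tips x = +/- L/2")
  spec$Q * s - (spec$P + spec$Q * (x - spec$dims$w)) * 4 * x / s
}

#' Parabolic bound of the pointed-end continuum
#'
#' The lower boundary of the admissible pointed-end shapes,
#' `y = (B/2) * sqrt((L - 2*x) / (L + 2*w))`. NOTE: this classical form is
#' written in the opposite orientation to the canonical family — the
#' pointed end sits at positive `x` and the maximum breadth near
#' `x = -w`.
#'
#' @param dims an [egg_dims] object.
#' @param x axial coordinates in `[-L/2, L/2]`.
#' @return Half-breadth values.
#' @export
parabola_contour <- function(dims, x) {
  stopifnot(inherits(dims, "egg_dims"))
  x <- .check_x_domain(x, dims$L)
  dims$B / 2 * sqrt(pmax(dims$L - 2 * x, 0) / (dims$L + 2 * dims$w))
}

#' Huegelschaeffer ovoid contour
#'
#' The upper boundary of the pointed-end continuum and the universal model
#' of the blunt half:
#' `y = (B/2) * sqrt((L^2 - 4*x^2) / (L^2 + 8*w*x + 4*w^2))`. Same
#' orientation as [parabola_contour] (pointed end at positive `x`); its
#' interior extremum lies exactly at `x = -w` with value `B/2`, so in its
#' own frame this model satisfies the Main Axiom.
#'
#' @inheritParams parabola_contour
#' @return Half-breadth values.
#' @export
huegelschaeffer_contour <- function(dims, x) {
  stopifnot(inherits(dims, "egg_dims"))
  L <- dims$L; w <- dims$w
  x <- .check_x_domain(x, L)
  dims$B / 2 * sqrt(pmax(L^2 - 4 * x^2, 0) / (L^2 + 8 * w * x + 4 * w^2))
}
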