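#' Basic axial measurements of an egg
#'
#' The three measurements shared by every model variant: overall length `L`,
#' maximum breadth `B`, and the signed axial offset `w` of the
#' maximum-breadth cross-section from the mid-length point. The package
#' orientation convention places the pointed end at negative `x` and the
#' blunt end at positive `x`, so an ordinary egg has `w >= 0` (the widest
#' section sits toward the blunt end).
#'
#' Admissibility requires `0 <= w < L/2` so that the recurring factor
#' `sqrt(L^2 - 4*w^2)` is real and nonzero. Empirically eggs satisfy
#' `w/L <= 0.2`; values above that band are accepted with a warning to
#' allow super-elongated shapes.
#'
#' @param L egg length (px or mm), `> 0`.
#' @param B maximum breadth, same units as `L`, `> 0`.
#' @param w axial offset of the maximum-breadth section, same units,
#'   `0 <= w < L/2`.
#' @return An object of class `"egg_dims"`: a list with elements `L`, `B`,
#'   `w`.
#' @examples
#' egg_dims(L = 60, B = 45, w = 3)
#' @export
egg_dims <- function(L, B, w = 0) {
  stopifnot(is.numeric(L), is.numeric(B), is.numeric(w),
            length(L) == 1L, length(B) == 1L, length(w) == 1L)
  if (!is.finite(L) || L <= 0) stop("'L' must be a positive finite number")
  if (!is.finite(B) || B <= 0) stop("'B' must be a positive finite number")
  if (!is.finite(w)) stop("'w' must be finite")
  if (w < 0)
    stop("'w' must be >= 0 in the pointed-end-at-negative-x convention; ",
         "flip the profile orientation instead of passing a negative offset")
  if (w >= L / 2)
    stop("'w' must be < L/2 (the breadth section cannot reach the tip)")
  if (w / L > 0.2)
    warning("w/L = ", signif(w / L, 3),
            " exceeds the empirical band [0, 0.2] for real eggs")
  structure(list(L = L, B = B, w = w), class = "egg_dims")
}

#' @export
print.egg_dims <- function(x, ...) {
  cat(sprintf("Egg dimensions: L = %g, B = %g, w = %g (w/L = %.4f)\n",
              x$L, x$B, x$w, x$w / x$L))
  invisible(x)
}

# shared radical sqrt(L^2 - 4 t^2); t may be x or w
.rad <- function(L, t) sqrt(pmax(L^2 - 4 * t^2, 0))

.check_x_domain <- function(x, L) {
  tol <- 1e-9 * L
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (any(x < -L / 2 - tol | x > L / 2 + tol))
    stop("'x' outside the contour domain [-L/2, L/2]")
  pmin(pmax(x, -L / 2), L / 2)
}
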