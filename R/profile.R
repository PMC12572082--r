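#' Digitized egg profile
#'
#' An ordered sample of an egg outline: axial positions `x` (strictly
#' increasing) and non-negative half-breadths `y`, in pixels or
#' millimetres. A closed outline (both branches, `y` of either sign or
#' duplicated `x`) is folded to a half-profile by averaging `|y|` of the
#' two branches at matched `x`.
#'
#' @param x axial coordinates (strictly increasing after folding).
#' @param y half-breadths; signed values allowed only with
#'   `closed = TRUE`.
#' @param units `"px"` or `"mm"`.
#' @param scale optional mm-per-px conversion factor.
#' @param orientation `"pointed_negative_x"` (package convention) or
#'   `"pointed_positive_x"`.
#' @param closed logical; `TRUE` if `x`, `y` trace a closed outline.
#' @return An object of class `"egg_profile"`: list with `x`, `y`, `n`,
#'   `units`, `scale`, `orientation`.
#' @examples
#' x <- seq(-1, 1, length.out = 51)
#' p <- egg_profile(x, 0.5 * sqrt(pmax(1 - x^2, 0)))
#' @export
egg_profile <- function(x, y, units = c("px", "mm"), scale = NULL,
                        orientation = c("pointed_negative_x",
                                        "pointed_positive_x"),
                        closed = FALSE) {
  units <- match.arg(units)
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("profile coordinates must be finite")
  if (closed) {
    o <- order(x)
    x <- x[o]; y <- abs(y[o])
    ux <- unique(x)
    y <- vapply(ux, function(xi) mean(y[x == xi]), numeric(1))
    x <- ux
  } else {
    if (any(y < 0))
      stop("half-profile 'y' must be non-negative (use closed = TRUE ",
           "for full outlines)")
    if (is.unsorted(x, strictly = TRUE))
      stop("'x' must be strictly increasing in a half-profile")
  }
  n <- length(x)
  if (n < 7L)
    stop("insufficient data: at least 7 points are needed to place ",
         "L, B, w, B0, r and R")
  structure(list(x = x, y = y, n = n, units = units, scale = scale,
                 orientation = orientation),
            class = "egg_profile")
}

#' @export
print.egg_profile <- function(x, ...) {
  cat(sprintf(
    "Digitized egg profile: %d points, x in [%g, %g] %s, %s%s\n",
    x$n, min(x$x), max(x$x), x$units, x$orientation,
    if (!is.null(x$scale)) sprintf(", scale %g mm/px", x$scale) else ""))
  invisible(x)
}

#' @export
plot.egg_profile <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "p", pch = 16, cex = 0.4, asp = 1,
                 xlab = sprintf("x (%s)", x$units),
                 ylab = sprintf("half-breadth (%s)", x$units), ...)
  graphics::points(x$x, -x$y, pch = 16, cex = 0.4)
  invisible(x)
}

#' Flip a profile between the two orientation conventions
#'
#' Maps `x -> -x` (reversing the point order) and toggles the orientation
#' tag. In parameter terms the flip swaps the roles of the quarter-length
#' radii `r` and `R` and negates `w` before re-normalization.
#'
#' @param profile an [egg_profile].
#' @return The flipped [egg_profile].
#' @export
flip_profile <- function(profile) {
  stopifnot(inherits(profile, "egg_profile"))
  profile$x <- rev(-profile$x)
  profile$y <- rev(profile$y)
  profile$orientation <-
    if (profile$orientation == "pointed_negative_x") "pointed_positive_x"
    else "pointed_negative_x"
  profile
}

# bring profile to pointed_negative_x with x centered on the tip midpoint
.normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "egg_profile"))
  if (profile$orientation == "pointed_positive_x")
    profile <- flip_profile(profile)
  mid <- (profile$x[1L] + profile$x[profile$n]) / 2
  profile$x <- profile$x - mid
  profile
}
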