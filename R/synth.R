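#' Blend specification for the pointed-end shape continuum
#'
#' Real pointed ends lie between two boundary figures: the parabola
#' (lower bound) and the Huegelschaeffer ovoid (upper bound). A blend
#' takes the pointed side as the convex combination
#' `(1 - lambda) * parabola + lambda * ovoid` while the blunt half is
#' always the ovoid, which models it for every pointed-end shape. Both
#' components pass through `B/2` at the junction, so the blend is
#' continuous there and keeps `B` and `w` exact by construction.
#'
#' The blend lives in the classical orientation of its two components:
#' pointed end at positive `x`, maximum breadth at `x = -w`.
#'
#' @param L,B,w basic measurements as in [egg_dims].
#' @param lambda pointed-end mix in `[0, 1]`: 0 = parabola, 1 = ovoid.
#' @return An object of class `"egg_blend"`.
#' @export
egg_blend <- function(L, B, w = 0, lambda = 1) {
  dims <- egg_dims(L, B, w)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single number in [0, 1]")
  structure(list(dims = dims, lambda = lambda), class = "egg_blend")
}

#' Evaluate a blended contour
#'
#' @param blend an [egg_blend] object.
#' @param x axial coordinates in `[-L/2, L/2]` (pointed end at positive
#'   `x`).
#' @return Half-breadth values.
#' @export
blend_contour <- function(blend, x) {
  stopifnot(inherits(blend, "egg_blend"))
  d <- blend$dims
  x <- .check_x_domain(x, d$L)
  hue <- huegelschaeffer_contour(d, x)
  par <- parabola_contour(d, x)
  lam <- blend$lambda
  ifelse(x >= -d$w, (1 - lam) * par + lam * hue, hue)
}

# restore RNG state on exit so seeded generation does not disturb callers
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic digitized profile
#'
#' Samples a contour model (an [egg_spec] or [egg_blend]) at `n_points`
#' uniformly spaced axial positions spanning tip to tip, emulating
#' outlines digitized from photographs in 1-pixel increments. Optional
#' additive Gaussian noise (truncated at zero) models tracing error;
#' optional quantization emulates the pixel grid by rounding full
#' breadths `2*y` to whole pixels after a seeded sub-pixel offset
#' `delta ~ U(-0.5, 0.5)` representing the egg's arbitrary placement on
#' the grid — so distinct seeds yield distinct quantized profiles even
#' without noise.
#'
#' @param source an [egg_spec] (pointed end at negative `x`) or
#'   [egg_blend] (pointed end at positive `x`; the profile carries the
#'   matching orientation tag).
#' @param n_points number of samples (`>= 7`).
#' @param quantize logical; round full breadths to the integer pixel
#'   grid.
#' @param noise_sd standard deviation of additive noise on `y`, in the
#'   profile units.
#' @param seed integer; fixes the output exactly. The caller's RNG state
#'   is left untouched.
#' @param units,scale forwarded to [egg_profile].
#' @return An [egg_profile].
#' @examples
#' p <- synth_profile(egg_spec("SM_MA", L = 398, B = 298, w = 20),
#'                    n_points = 398, quantize = TRUE, seed = 1)
#' @export
synth_profile <- function(source, n_points = 398, quantize = FALSE,
                          noise_sd = 0, seed = NULL, units = "px",
                          scale = NULL) {
  stopifnot(n_points >= 7L, is.numeric(noise_sd), noise_sd >= 0)
  if (inherits(source, "egg_spec")) {
    L <- source$dims$L
    fy <- function(x) egg_contour(source, x)
    orientation <- "pointed_negative_x"
  } else if (inherits(source, "egg_blend")) {
    L <- source$dims$L
    fy <- function(x) blend_contour(source, x)
    orientation <- "pointed_positive_x"
  } else stop("'source' must be an egg_spec or egg_blend")
  .with_seed(seed, {
    x <- seq(-L / 2, L / 2, length.out = n_points)
    y <- fy(x)
    if (noise_sd > 0) y <- pmax(y + stats::rnorm(n_points, 0, noise_sd), 0)
    if (quantize) {
      delta <- stats::runif(1, -0.5, 0.5)
      y <- pmax(round(2 * y + delta), 0) / 2
    }
    egg_profile(x, y, units = units, scale = scale,
                orientation = orientation)
  })
}

# fixed fixture parameters: chosen once as realistic stand-ins for the three
# characteristic shapes (true parameters of the source eggs are unpublished)
.fixture_table <- data.frame(
  name     = c("ovoid", "conical", "pyriform"),
  n_points = c(398L, 215L, 215L),
  L        = c(398, 215, 215),          # px
  B_over_L = c(0.74, 0.72, 0.66),
  w_over_L = c(0.05, 0.10, 0.15),
  lambda   = c(0.90, 0.50, 0.15),
  scale    = c(NA, 57 / 215, 57 / 215)  # mm per px where known
)

#' Standard synthetic fixtures: ovoid, conical and pyriform eggs
#'
#' Three digitized profiles with the sampling structure of the package's
#' reference shapes: an ovoid (chicken-like) egg sampled at 398 points
#' with `L` = 398 px; a conical (sandpiper-like) and a pyriform
#' (razorbill-like) egg at 215 points each with `L` = 215 px scaled to
#' 57 mm. Shapes are drawn from the parabola-to-ovoid blend continuum
#' with elongations `w/L` of 0.05, 0.10 and 0.15 and pointed-end mixes
#' `lambda` of 0.90, 0.50 and 0.15; the exact values are fixed in the
#' package.
#'
#' @param seed integer seed controlling the quantization placement (one
#'   derived seed per fixture).
#' @param quantize logical; pixel-quantize the profiles (default `TRUE`).
#' @return Named list of three [egg_profile] objects: `ovoid`, `conical`,
#'   `pyriform`.
#' @export
standard_fixtures <- function(seed = 1, quantize = TRUE) {
  ft <- .fixture_table
  out <- lapply(seq_len(nrow(ft)), function(i) {
    b <- egg_blend(L = ft$L[i], B = ft$B_over_L[i] * ft$L[i],
                   w = ft$w_over_L[i] * ft$L[i], lambda = ft$lambda[i])
    synth_profile(b, n_points = ft$n_points[i], quantize = quantize,
                  seed = if (is.null(seed)) NULL else seed + i - 1L,
                  units = "px",
                  scale = if (is.na(ft$scale[i])) NULL else ft$scale[i])
  })
  names(out) <- ft$name
  out
}
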