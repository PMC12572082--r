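#' Closed-form volumes of the egg as a solid of revolution
#'
#' Rotating the original Smart contour (parameterized by the length `L`,
#' the mid-length breadth `B0` and the slope `tan theta`) about its long
#' axis and integrating `pi * y^2` over each half gives closed forms
#' for the pointed-half, blunt-half and total volumes:
#' \deqn{V_p = (\pi L/4)(B_0^2/3 - B_0 L \tan\theta/4 + L^2\tan^2\theta/15)}
#' \deqn{V_b = (\pi L/4)(B_0^2/3 + B_0 L \tan\theta/4 + L^2\tan^2\theta/15)}
#' \deqn{V   = (\pi L/6)(B_0^2 + L^2\tan^2\theta/5)}
#' The report also carries the volume-equivalent ellipsoid: `V` equals the
#' ellipsoid volume at length `L` only when `tan theta = 0`; otherwise the
#' equal-volume ellipsoid is longer, with length given by
#' [ellipsoid_equiv_length].
#'
#' Callers holding the `(L, B, w)` measurements convert through
#' [b0_from_dims] first (or pass an [egg_spec] to [egg_volume]).
#'
#' @param L egg length (`> 0`).
#' @param B0 mid-length breadth (`> 0`), same units.
#' @param tan_theta slope parameter (dimensionless).
#' @return An object of class `"egg_volume"`: list with `V_p`, `V_b`, `V`
#'   (length^3), `L_el` (length of the equal-volume ellipsoid) and `V_el`
#'   (its volume, equal to `V` by construction).
#' @examples
#' volume_parts(L = 2, B0 = 2, tan_theta = 0)$V   # sphere: 4*pi/3
#' @export
volume_parts <- function(L, B0, tan_theta = 0) {
  stopifnot(is.numeric(L), is.numeric(B0), is.numeric(tan_theta),
            L > 0, B0 > 0, is.finite(tan_theta))
  Vp <- pi * L / 4 * (B0^2 / 3 - B0 * L * tan_theta / 4 +
                      L^2 * tan_theta^2 / 15)
  Vb <- pi * L / 4 * (B0^2 / 3 + B0 * L * tan_theta / 4 +
                      L^2 * tan_theta^2 / 15)
  V  <- pi * L / 6 * (B0^2 + L^2 * tan_theta^2 / 5)
  Lel <- ellipsoid_equiv_length(L, B0, tan_theta)
  structure(list(V_p = Vp, V_b = Vb, V = V,
                 L_el = Lel, V_el = ellipsoid_volume(Lel, B0)),
            class = "egg_volume")
}

#' @export
print.egg_volume <- function(x, ...) {
  cat(sprintf("Egg volume: V = %.6g (pointed %.6g + blunt %.6g)\n",
              x$V, x$V_p, x$V_b))
  cat(sprintf("  equal-volume ellipsoid: L_el = %.6g, V_el = %.6g\n",
              x$L_el, x$V_el))
  invisible(x)
}

#' Volume of a prolate ellipsoid of revolution
#'
#' `V_el = pi * L_el * B0^2 / 6` for length `L_el` and equatorial breadth
#' `B0`.
#'
#' @param L_el ellipsoid length (`> 0`).
#' @param B0 equatorial breadth (`> 0`).
#' @return Volume, length^3.
#' @export
ellipsoid_volume <- function(L_el, B0) {
  stopifnot(is.numeric(L_el), is.numeric(B0), all(L_el > 0), all(B0 > 0))
  pi * L_el * B0^2 / 6
}

#' Length of the ellipsoid with the same volume as the egg
#'
#' `L_el = L * (1 + (1/5) * (L/B0)^2 * tan_theta^2)`; always `>= L`, with
#' equality exactly when `tan theta = 0`. The excess length quantifies how
#' much an ellipsoid must be stretched to store the ovoid's volume — the
#' reason an egg's length cannot stay constant while it deforms from an
#' equal-volume ellipsoid.
#'
#' @inheritParams volume_parts
#' @return `L_el`, units of `L`.
#' @export
ellipsoid_equiv_length <- function(L, B0, tan_theta = 0) {
  stopifnot(is.numeric(L), is.numeric(B0), all(L > 0), all(B0 > 0))
  L * (1 + (L / B0)^2 * tan_theta^2 / 5)
}

#' Does the egg conserve the volume of the same-length ellipsoid?
#'
#' Tests the identity `V = V_el(L)` between the egg volume and the
#' ellipsoid of identical length and mid-breadth. The discrepancy has the
#' closed form `V - V_el = pi * L^3 * tan_theta^2 / 30`, so equality holds
#' exactly when `tan theta = 0` (the egg *is* the ellipsoid).
#'
#' @inheritParams volume_parts
#' @param tol relative tolerance on the volume discrepancy.
#' @return List with `conserved` (logical) and `discrepancy`
#'   (`V - V_el`, length^3, always `>= 0`).
#' @export
conservation_check <- function(L, B0, tan_theta = 0, tol = 1e-12) {
  v <- volume_parts(L, B0, tan_theta)
  disc <- v$V - ellipsoid_volume(L, B0)
  list(conserved = abs(disc) <= tol * v$V, discrepancy = disc)
}

#' Volume report for a fitted or specified contour model
#'
#' Converts the model's `(L, B, w, tan theta)` parameterization to the
#' `(L, B0, tan theta)` frame in which the volume integrals are taken
#' (via [b0_from_dims]) and returns the closed-form [volume_parts] report.
#'
#' @param object an [egg_spec] or [egg_fit] object.
#' @param ... unused.
#' @return An `"egg_volume"` object.
#' @export
egg_volume <- function(object, ...) UseMethod("egg_volume")

#' @export
egg_volume.egg_spec <- function(object, ...) {
  B0 <- b0_from_dims(object$dims, object$tan_theta)
  if (B0 <= 0) stop("implied B0 <= 0: no solid of revolution to measure")
  volume_parts(object$dims$L, B0, object$tan_theta)
}

#' @export
egg_volume.egg_fit <- function(object, ...) egg_volume(object$spec, ...)
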