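#' Model variants of the Smart egg-shape family
#'
#' Tags of the supported contour models. All of them share one canonical
#' form `y = (P + Q*(x - w)) * sqrt(L^2 - 4*x^2)` and differ only in how
#' the slope parameter `tan theta = Q*L` is obtained from measurements:
#'
#' * `"SM"` — `tan theta` supplied directly (Smart's original form).
#' * `"SM_r"` — from the quarter-length radii (half-breadths) `r` (pointed side) and
#'   `R` (blunt side): `tan theta = (4/sqrt(3)) * (R - r) / L`. Five
#'   measured parameters (`L`, `B`, `w`, `r`, `R`).
#' * `"SM_B0"` — from the mid-length breadth `B0`. Four parameters.
#' * `"SM_B02"` — `SM_B0` with `B0` replaced by its ovoid (Huegelschaeffer)
#'   upper bound, leaving three parameters (`L`, `B`, `w`).
#' * `"SM_r2"` — `SM_r` with `r` and `R` replaced by their ovoid-bound
#'   ratios; three parameters.
#' * `"SM_MA"` — the Main-Axiom-compliant member: `tan theta` chosen so the
#'   contour's interior extremum falls exactly at `(w, B/2)`. Three
#'   parameters.
#' * `"SM_U"` — the "universal" hybrid using `L`, `B`, `w` and the pointed
#'   quarter-radius `r`; four parameters.
#'
#' @format A character vector of the seven variant tags.
#' @export
SM_VARIANTS <- c("SM", "SM_r", "SM_B0", "SM_B02", "SM_r2", "SM_MA", "SM_U")

# measured parameters each variant consumes (beyond L, B, w)
.variant_n_params <- c(SM = NA_integer_, SM_r = 5L, SM_B0 = 4L, SM_B02 = 3L,
                       SM_r2 = 3L, SM_MA = 3L, SM_U = 4L)

#' Number of measured parameters used by each variant
#'
#' @param variant character vector of variant tags.
#' @return Integer vector: 3, 4 or 5 (NA for the raw `"SM"` form, whose
#'   `tan theta` is not a field measurement).
#' @export
variant_n_params <- function(variant) {
  variant <- match.arg(variant, SM_VARIANTS, several.ok = TRUE)
  unname(.variant_n_params[variant])
}

#' Resolve the slope parameter tan(theta) for a model variant
#'
#' Each variant defines `tan theta` from a different subset of
#' measurements; see [SM_VARIANTS]. The `w = 0` cases of `SM_B0` and
#' `SM_B02` are evaluated as their analytic limits (0; for `SM_B0` the
#' mid-length breadth must then equal `B` up to measurement precision —
#' 0.5% relative — since the geometry forces `B0 = B` at `w = 0`).
#'
#' @param variant one of [SM_VARIANTS].
#' @param dims an [egg_dims] object.
#' @param B0,r,R,tan_theta auxiliary measurements, required per variant.
#' @return The dimensionless slope `tan theta`.
#' @export
tan_theta_resolve <- function(variant, dims, B0 = NULL, r = NULL, R = NULL,
                              tan_theta = NULL) {
  variant <- match.arg(variant, SM_VARIANTS)
  stopifnot(inherits(dims, "egg_dims"))
  L <- dims$L; B <- dims$B; w <- dims$w
  s <- .rad(L, w)                       # sqrt(L^2 - 4 w^2)
  need <- function(val, name)
    if (is.null(val) || !is.finite(val))
      stop(sprintf("variant '%s' requires a finite '%s'", variant, name))
  tt <- switch(variant,
    SM = {
      need(tan_theta, "tan_theta")
      tan_theta
    },
    SM_r = {
      need(r, "r"); need(R, "R")
      4 / sqrt(3) * (R - r) / L
    },
    SM_B0 = {
      need(B0, "B0")
      if (B0 <= 0) stop("'B0' must be positive")
      if (w == 0) {
        # the limit exists only when B0 -> B; allow measurement precision
        if (abs(B0 - B) > 5e-3 * B)
          stop("at w = 0 the geometry forces B0 = B; got B0 = ", B0)
        0
      } else {
        (B * L - B0 * s) / (2 * w * s)
      }
    },
    SM_B02 = {
      # B0 replaced by its ovoid upper bound B*L/sqrt(L^2 + 4 w^2)
      if (w == 0) 0
      else B * L * (sqrt(L^2 + 4 * w^2) - s) /
             (2 * w * s * sqrt(L^2 + 4 * w^2))
    },
    SM_r2 = {
      B * (1 / sqrt(L^2 - 2 * w * L + 4 * w^2) -
           1 / sqrt(L^2 + 2 * w * L + 4 * w^2))
    },
    SM_MA = 2 * B * L * w / ((L^2 - 4 * w^2) * s),
    SM_U = {
      need(r, "r")
      B / sqrt(L^2 - 2 * w * L + 4 * w^2) - 4 * r / (sqrt(3) * L)
    })
  if (!is.finite(tt)) stop("resolved tan theta is not finite")
  tt
}

#' Build a fully resolved model specification
#'
#' Resolves the variant's `tan theta` from the supplied measurements and
#' the canonical coefficients `P = B / (2*sqrt(L^2 - 4*w^2))` (so every
#' variant passes through the measured point `(w, B/2)`) and
#' `Q = tan theta / L`.
#'
#' @param variant one of [SM_VARIANTS].
#' @param L,B,w basic measurements, or pass `dims`.
#' @param dims optionally an [egg_dims] object instead of `L`, `B`, `w`.
#' @param B0,r,R,tan_theta auxiliary measurements as required by the
#'   variant (see [tan_theta_resolve]).
#' @return An object of class `"egg_spec"`: list with `variant`, `dims`,
#'   `aux`, `tan_theta`, `P`, `Q`.
#' @examples
#' spec <- egg_spec("SM_MA", L = 60, B = 45, w = 3)
#' egg_contour(spec, c(-30, 0, 3, 30))
#' @export
egg_spec <- function(variant, L = NULL, B = NULL, w = 0, dims = NULL,
                     B0 = NULL, r = NULL, R = NULL, tan_theta = NULL) {
  variant <- match.arg(variant, SM_VARIANTS)
  if (is.null(dims)) dims <- egg_dims(L, B, w)
  stopifnot(inherits(dims, "egg_dims"))
  tt <- tan_theta_resolve(variant, dims, B0 = B0, r = r, R = R,
                          tan_theta = tan_theta)
  P <- dims$B / (2 * .rad(dims$L, dims$w))
  Q <- tt / dims$L
  if (!is.finite(P) || !is.finite(Q))
    stop("non-finite canonical coefficients; check the measurements")
  structure(list(variant = variant, dims = dims,
                 aux = list(B0 = B0, r = r, R = R),
                 tan_theta = tt, P = P, Q = Q),
            class = "egg_spec")
}

#' @export
print.egg_spec <- function(x, ...) {
  cat(sprintf("Egg contour model %s\n", x$variant))
  cat(sprintf("  L = %g, B = %g, w = %g  (w/L = %.4f)\n",
              x$dims$L, x$dims$B, x$dims$w, x$dims$w / x$dims$L))
  aux <- x$aux[!vapply(x$aux, is.null, logical(1))]
  if (length(aux))
    cat("  aux:", paste(sprintf("%s = %g", names(aux), unlist(aux)),
                        collapse = ", "), "\n")
  cat(sprintf("  tan theta = %.6g   (P = %.6g, Q = %.6g)\n",
              x$tan_theta, x$P, x$Q))
  invisible(x)
}

#' Mid-length breadth implied by (L, B, w, tan theta)
#'
#' Inverts the breadth-offset substitution: the breadth of the canonical
#' contour at the mid-length point `x = 0` is
#' `B0 = B*L/sqrt(L^2 - 4*w^2) - 2*w*tan_theta`. This is the exact inverse
#' of the `SM_B0` slope resolver, so composing the two round-trips any
#' admissible `B0`.
#'
#' @param dims an [egg_dims] object.
#' @param tan_theta slope parameter.
#' @return `B0` in the units of `L`. A non-positive result (geometrically
#'   impossible egg) triggers a warning and is returned as-is for
#'   diagnostics.
#' @export
b0_from_dims <- function(dims, tan_theta) {
  stopifnot(inherits(dims, "egg_dims"), is.numeric(tan_theta))
  B0 <- dims$B * dims$L / .rad(dims$L, dims$w) - 2 * dims$w * tan_theta
  if (any(B0 <= 0))
    warning("non-physical parameter combination: implied B0 <= 0")
  B0
}
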