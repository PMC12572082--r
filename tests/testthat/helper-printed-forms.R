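# Independent transcriptions of the published closed-form contour equations,
# written directly from the printed per-variant formulas (not via the
# canonical P/Q coefficients). They serve as oracles for the canonical
# evaluation path and must stay independent of the package internals.

sm_printed <- function(L, B, w, tan_theta, x)
  (B / (2 * sqrt(L^2 - 4 * w^2)) + tan_theta * (x - w) / L) *
    sqrt(L^2 - 4 * x^2)

sm_r_printed <- function(L, B, w, r, R, x)
  (B / (2 * sqrt(L^2 - 4 * w^2)) +
     4 * (R - r) / (sqrt(3) * L^2) * (x - w)) * sqrt(L^2 - 4 * x^2)

sm_b0_printed <- function(L, B, w, B0, x)
  (1 / L) * ((B * L - B0 * sqrt(L^2 - 4 * w^2)) /
               (2 * w * sqrt(L^2 - 4 * w^2)) * x + B0 / 2) *
    sqrt(L^2 - 4 * x^2)

sm_b02_printed <- function(L, B, w, x)
  B / (2 * sqrt(L^2 + 4 * w^2)) *
    ((sqrt(L^2 + 4 * w^2) - sqrt(L^2 - 4 * w^2)) /
       (w * sqrt(L^2 - 4 * w^2)) * x + 1) * sqrt(L^2 - 4 * x^2)

sm_r2_printed <- function(L, B, w, x)
  B * (1 / (2 * sqrt(L^2 - 4 * w^2)) +
         (1 / sqrt(L^2 - 2 * w * L + 4 * w^2) -
            1 / sqrt(L^2 + 2 * w * L + 4 * w^2)) * (x - w) / L) *
    sqrt(L^2 - 4 * x^2)

sm_ma_printed <- function(L, B, w, x)
  B / 2 * (1 + 4 * w / (L^2 - 4 * w^2) * (x - w)) *
    sqrt((L^2 - 4 * x^2) / (L^2 - 4 * w^2))

sm_u_printed <- function(L, B, w, r, x)
  B * (1 / (2 * sqrt(L^2 - 4 * w^2)) +
         (1 / sqrt(L^2 - 2 * w * L + 4 * w^2) -
            4 * r / (sqrt(3) * B * L)) * (x - w) / L) *
    sqrt(L^2 - 4 * x^2)

# printed derivative of the canonical contour
sm_slope_printed <- function(L, B, w, tan_theta, x)
  tan_theta / L * sqrt(L^2 - 4 * x^2) -
    (B / (2 * sqrt(L^2 - 4 * w^2)) + tan_theta * (x - w) / L) *
      4 * x / sqrt(L^2 - 4 * x^2)
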