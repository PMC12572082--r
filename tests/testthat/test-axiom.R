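test_that("the Axiom-constrained variant is compliant on a random dims grid", {
  set.seed(42)
  for (i in 1:200) {
    a <- axiom_residual(egg_spec("SM_MA", dims = rand_dims()))
    expect_true(a$compliant)
  }
})

test_that("slope residual of the zero-slope model matches its closed form", {
  set.seed(5)
  for (i in 1:25) {
    d <- rand_dims()
    s <- egg_spec("SM", dims = d, tan_theta = 0)
    a <- axiom_residual(s)
    expect_equal(a$slope_residual, -2 * d$B * d$w / (d$L^2 - 4 * d$w^2),
                 tolerance = 1e-12)
    # cross-check the analytic derivative with central finite differences
    h <- 1e-6 * d$L
    fd <- (egg_contour(s, d$w + h) - egg_contour(s, d$w - h)) / (2 * h)
    expect_equal(a$slope_residual, fd, tolerance = 1e-5)
    # and with the printed derivative formula
    expect_equal(egg_contour_slope(s, d$w),
                 sm_slope_printed(d$L, d$B, d$w, 0, d$w), tolerance = 1e-12)
  }
})

test_that("Axiom slope parameter is increasing in the breadth offset", {
  tts <- sapply(seq(0, 29, length.out = 50),
                function(w) axiom_tan_theta(suppressWarnings(
                  egg_dims(60, 45, w))))
  expect_true(all(diff(tts) > 0))
  expect_equal(axiom_tan_theta(egg_dims(60, 45, 0)), 0)
})

test_that("required pointed radius closes the compliance loop", {
  expect_equal(axiom_required_r(egg_dims(60, 45, 0), R = 19), 19)
  set.seed(9)
  for (i in 1:50) {
    d <- rand_dims()
    R <- d$B * runif(1, 0.38, 0.46)
    r <- axiom_required_r(d, R)
    if (r <= 0) next
    fit <- egg_spec("SM_r", dims = d, r = r, R = R)
    expect_true(axiom_residual(fit)$compliant)
    # any other r breaks compliance
    off <- egg_spec("SM_r", dims = d, r = r * 0.98, R = R)
    expect_false(axiom_residual(off)$compliant)
  }
})

test_that("the two derivations of the compatible r/B curve agree", {
  for (t in seq(0.001, 0.2, by = 0.004)) {
    d <- egg_dims(100, 70, 100 * t)
    R <- 70 * ratio_bounds(t)$R_over_B
    expect_lt(rel_err(axiom_r_curve(t) * 70, axiom_required_r(d, R)),
              1e-12)
  }
})

test_that("compatible r/B curve: limit, frozen value and printed range", {
  expect_equal(axiom_r_curve(0), sqrt(3) / 4)
  # frozen arbitrary-precision substitution at t = 0.2
  expect_equal(axiom_r_curve(0.2), 0.27172078091770855, tolerance = 1e-14)
  expect_error(axiom_r_curve(0.6), "0.5")
  expect_warning(axiom_r_curve(0.21), "band")
  rb <- axiom_r_curve(seq(0, 0.2, by = 1e-3))
  expect_equal(round(min(rb), 2), 0.27)
  expect_equal(round(max(rb), 2), 0.43)
})

test_that("ratio table: anchors at t = 0, mean identities and bracketing", {
  r0 <- ratio_bounds(0)
  expect_equal(r0$b0_over_B_min, 1)
  expect_equal(r0$b0_over_B_max, 1)
  expect_equal(r0$R_over_B, sqrt(3) / 4)
  expect_equal(r0$r_over_B_huegel, sqrt(3) / 4)
  t <- seq(0, 0.49, by = 0.01)
  rb <- ratio_bounds(t)
  expect_equal(rb$b0_over_B_avg, (rb$b0_over_B_min + rb$b0_over_B_max) / 2)
  expect_equal(rb$r_over_B_avg,
               (rb$r_over_B_parabola + rb$r_over_B_huegel) / 2)
  expect_true(all(rb$b0_over_B_min <= rb$b0_over_B_avg + 1e-15))
  expect_true(all(rb$b0_over_B_avg <= rb$b0_over_B_max + 1e-15))
  expect_true(all(rb$b0_over_B_max <= 1))
})

test_that("atlas: default grid, ellipse limit and overshoot diagnostics", {
  at <- egg_atlas("SM_B0", "huegelschaeffer")
  expect_equal(unique(at$profiles$t), seq(0, 0.2, by = 0.05))
  s0 <- at$summary[at$summary$t == 0, ]
  expect_equal(s0$y_max_over_B, 0.5, tolerance = 1e-10)
  expect_equal(s0$x_at_max_over_L, 0, tolerance = 1e-6)
  expect_error(egg_atlas("SM_B0", "circle"))
  # the parabola and average rules exist and produce full atlases too
  for (rule in c("parabola", "average")) {
    a <- egg_atlas("SM_r", rule, t_grid = c(0, 0.1))
    expect_equal(nrow(a$summary), 2L)
  }
})

test_that("normalized atlases overshoot B/2 and displace the breadth axis", {
  for (v in c("SM_B0", "SM_r")) {
    at <- egg_atlas(v, "huegelschaeffer", t_grid = seq(0.05, 0.2, 0.05))
    expect_true(all(at$summary$y_max_over_B > 0.5))
    expect_true(all(abs(at$summary$x_at_max_over_L - at$summary$t) > 1e-4))
  }
})
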