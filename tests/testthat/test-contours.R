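test_that("canonical contour hits the anchor points exactly", {
  set.seed(11)
  for (i in 1:25) {
    d <- rand_dims()
    tt <- runif(1, -0.1, 0.4)
    s <- egg_spec("SM", dims = d, tan_theta = tt)
    expect_identical(egg_contour(s, c(-d$L / 2, d$L / 2)), c(0, 0))
    expect_equal(egg_contour(s, d$w), d$B / 2, tolerance = 1e-14)
  }
})

test_that("zero slope parameter degenerates to the ellipse", {
  s <- egg_spec("SM", L = 2, B = 1, w = 0, tan_theta = 0)
  expect_equal(egg_contour(s, 0), 0.5)
  x <- seq(-1, 1, length.out = 101)
  expect_equal(egg_contour(s, x), 0.5 * sqrt(pmax(1 - x^2, 0)),
               tolerance = 1e-15)
})

test_that("canonical contour matches high-precision direct substitution", {
  s <- egg_spec("SM", L = 60, B = 45, w = 3, tan_theta = 0.15)
  # frozen value from arbitrary-precision symbolic substitution
  expect_equal(egg_contour(s, 15), 21.142582021827996, tolerance = 1e-15)
})

test_that("x outside the half-length domain is rejected", {
  s <- egg_spec("SM_MA", L = 60, B = 45, w = 3)
  expect_error(egg_contour(s, 30.001), "domain")
  expect_error(egg_contour(s, -31), "domain")
})

test_that("every variant reproduces its printed closed form", {
  set.seed(101)
  n_draws <- 1000
  worst <- 0
  for (i in seq_len(n_draws)) {
    d <- rand_dims()
    x <- rand_x(d)
    L <- d$L; B <- d$B; w <- d$w
    r <- B * runif(1, 0.25, 0.45)
    R <- B * runif(1, 0.35, 0.48)
    tt <- runif(1, 0, 0.35)
    B0 <- b0_from_dims(d, tt)
    pairs <- list(
      list(egg_spec("SM_r", dims = d, r = r, R = R),
           sm_r_printed(L, B, w, r, R, x)),
      list(egg_spec("SM_B0", dims = d, B0 = B0),
           sm_b0_printed(L, B, w, B0, x)),
      list(egg_spec("SM_B02", dims = d),
           sm_b02_printed(L, B, w, x)),
      list(egg_spec("SM_r2", dims = d),
           sm_r2_printed(L, B, w, x)),
      list(egg_spec("SM_MA", dims = d),
           sm_ma_printed(L, B, w, x)),
      list(egg_spec("SM_U", dims = d, r = r),
           sm_u_printed(L, B, w, r, x)))
    for (p in pairs)
      worst <- max(worst, rel_err(egg_contour(p[[1]], x), p[[2]]))
  }
  expect_lt(worst, 1e-12)
})

test_that("three-parameter variants collapse to the ellipse as w -> 0", {
  x <- seq(-30, 30, length.out = 201)
  ell <- 45 / 2 * sqrt(pmax(1 - (x / 30)^2, 0))
  for (v in c("SM_B02", "SM_r2", "SM_MA")) {
    s <- egg_spec(v, L = 60, B = 45, w = 0)
    expect_equal(egg_contour(s, x), ell, tolerance = 1e-14)
    expect_equal(s$tan_theta, 0)
  }
})

test_that("mid-breadth conversion and its slope resolver are inverses", {
  set.seed(7)
  for (i in 1:50) {
    d <- rand_dims()
    tt <- runif(1, 0, 0.35)
    B0 <- b0_from_dims(d, tt)
    expect_lt(rel_err(tan_theta_resolve("SM_B0", d, B0 = B0), tt), 1e-11)
    # and the reverse composition round-trips B0
    B0b <- b0_from_dims(d, tan_theta_resolve("SM_B0", d, B0 = B0))
    expect_lt(rel_err(B0b, B0), 1e-12)
  }
  # closed-form spot checks
  d0 <- egg_dims(60, 45, 0)
  expect_equal(b0_from_dims(d0, 0.3), 45)          # w = 0: B0 = B
  d1 <- egg_dims(60, 45, 6)
  expect_gt(b0_from_dims(d1, 0), 45)               # tan theta = 0: B0 > B
})

test_that("slope resolver degenerate and error cases", {
  d <- egg_dims(60, 45, 3)
  expect_equal(tan_theta_resolve("SM_r", d, r = 20, R = 20), 0)
  expect_equal(tan_theta_resolve("SM_MA", egg_dims(60, 45, 0)), 0)
  expect_equal(tan_theta_resolve("SM_B02", egg_dims(60, 45, 0)), 0)
  expect_error(tan_theta_resolve("SM_r", d, r = 20), "requires")
  expect_error(tan_theta_resolve("SM_B0", d), "requires")
  expect_error(tan_theta_resolve("SM_U", d), "requires")
  expect_error(tan_theta_resolve("SM_B0", egg_dims(60, 45, 0), B0 = 40),
               "B0 = B")
})

test_that("the Axiom slope value matches its closed form at the reference egg", {
  # frozen arbitrary-precision value of 2*B*L*w / (L^2-4w^2)^(3/2)
  expect_equal(axiom_tan_theta(egg_dims(60, 45, 3)),
               0.076139228428728188, tolerance = 1e-15)
  expect_equal(tan_theta_resolve("SM_MA", egg_dims(60, 45, 3)),
               2 * 45 * 60 * 3 / (60^2 - 4 * 3^2)^1.5, tolerance = 1e-15)
})

test_that("boundary models: tips, breadth anchor and mid-length ratios", {
  d <- egg_dims(60, 45, 6)
  expect_equal(parabola_contour(d, 30), 0)
  expect_equal(parabola_contour(d, -6), 45 / 2)
  expect_equal(parabola_contour(d, 0),
               45 / 2 / sqrt(1 + 2 * 6 / 60))         # parabolic B0/B bound
  expect_equal(huegelschaeffer_contour(d, c(-30, 30)), c(0, 0))
  expect_equal(huegelschaeffer_contour(d, 0),
               45 / 2 / sqrt(1 + 4 * (6 / 60)^2))     # ovoid B0/B bound
})

test_that("ovoid contour has its interior extremum exactly at x = -w", {
  # d(y^2)/dx factorizes as -2 B^2 (L^2 + 4 w x)(w + x) / (...)^2,
  # so the interior root is x = -w with value B/2
  set.seed(21)
  for (i in 1:20) {
    d <- rand_dims()
    opt <- optimize(function(x) huegelschaeffer_contour(d, x),
                    c(-d$L / 2, d$L / 2), maximum = TRUE, tol = 1e-12)
    expect_equal(opt$maximum, -d$w, tolerance = 1e-6 * d$L)
    expect_equal(huegelschaeffer_contour(d, -d$w), d$B / 2,
                 tolerance = 1e-13)
  }
})

test_that("slope formula via quarter radii agrees with the ovoid-ratio variant", {
  # feeding the ovoid-bound r/B and R/B back through the radii formula
  # reproduces the three-parameter ovoid-ratio slope (substitution chain)
  for (t in seq(0, 0.2, by = 0.01)) {
    d <- egg_dims(100, 75, 100 * t)
    rb <- ratio_bounds(t)
    via_radii <- tan_theta_resolve("SM_r", d, r = 75 * rb$r_over_B_huegel,
                                   R = 75 * rb$R_over_B)
    expect_lt(rel_err(via_radii, tan_theta_resolve("SM_r2", d)), 1e-12)
  }
})

test_that("extreme slope parameters yield signed (unclamped) contours", {
  s <- egg_spec("SM", L = 60, B = 40, w = 10, tan_theta = 1.2)
  y <- egg_contour(s, seq(-29.9, -25, length.out = 20))
  expect_true(any(y < 0))   # visible to diagnostics, not silently clamped
})

test_that("inadmissible dimensions are rejected, wide offsets only warned", {
  expect_error(egg_dims(-1, 1, 0))
  expect_error(egg_dims(10, 5, -1), "flip")
  expect_error(egg_dims(10, 5, 5), "L/2")
  expect_warning(egg_dims(10, 7, 2.3), "0.2")
})
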