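test_that("logistic solution matches numerical integration and fixed points", {
  p <- c(lam = 1.21, Rmax = 316)
  tr <- solve_logistic(p, R0 = 10, grid21)
  ## independent oracle: direct numerical integration of the ODE
  num <- deSolve::ode(c(R = 10), 0:21, function(t, y, q)
    list(p[["lam"]] / 3 * y * (1 - y / p[["Rmax"]])), NULL,
    rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$radius, unname(num[, 2]), tolerance = 1e-8)
  expect_equal(tr$radius[22],
               logistic_oracle(1.21, 316, 10, 21), tolerance = 1e-12)
  ## fixed point and zero growth
  expect_equal(solve_logistic(c(lam = 1, Rmax = 100), 100, 0:5)$radius,
               rep(100, 6))
  expect_equal(solve_logistic(c(lam = 0, Rmax = 316), 10, 0:5)$radius,
               rep(10, 6))
  expect_error(solve_logistic(c(lam = 1, Rmax = -1), 10, 0:5), "Rmax")
  expect_error(solve_logistic(c(lam = 1, Rmax = 100), -5, 0:5), "R0")
})

test_that("bounded Gompertz is exponential below Rmax/e and C1 at the switch", {
  lam <- 1; Rmax <- 300; R0 <- 10
  tsw <- (3 / lam) * log(Rmax / (exp(1) * R0))
  tt <- time_grid(seq(0, 0.9 * tsw, length.out = 8))
  tr <- solve_bounded_gompertz(c(lam = lam, Rmax = Rmax), R0, tt)
  expect_equal(tr$radius, R0 * exp(lam * as.numeric(tt) / 3),
               tolerance = 1e-12)
  ## continuity of the value and the derivative across the switch
  h <- 1e-5
  four <- solve_bounded_gompertz(c(lam = lam, Rmax = Rmax), R0,
                                 tsw + c(-2 * h, -h, h, 2 * h))$radius
  expect_equal(four[2], four[3], tolerance = 1e-4)
  slope_l <- (four[2] - four[1]) / h
  slope_r <- (four[4] - four[3]) / h
  expect_equal(slope_l, slope_r, tolerance = 1e-3)
  ## fixed point
  expect_equal(solve_bounded_gompertz(c(lam = 2, Rmax = 50), 50,
                                      0:4)$radius, rep(50, 5),
               tolerance = 1e-12)
})

test_that("Richards nests the logistic model and limits to Gompertz", {
  p <- c(lam = 1.3, Rmax = 280)
  lg <- solve_logistic(p, 10, grid21)$radius
  rc <- solve_richards(c(p, beta = 1), 10, grid21)$radius
  expect_lt(max(abs(rc - lg)), 1e-8 * p[["Rmax"]])
  ## beta -> 0+ approaches the standard Gompertz closed form under the
  ## usual rate rescaling lam -> lam/beta (at fixed lam the Richards
  ## right-hand side degenerates to zero growth as beta -> 0)
  gs <- gompertz_std_oracle(1.3, 280, 10, 0:21)
  err <- sapply(c(1e-2, 1e-3, 1e-4), function(b)
    max(abs(solve_richards(c(lam = 1.3 / b, Rmax = 280, beta = b), 10,
                           grid21)$radius - gs)))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
  expect_equal(solve_richards(c(lam = 1, Rmax = 90, beta = 2), 90,
                              0:3)$radius, rep(90, 4))
  expect_error(solve_richards(c(lam = 1, Rmax = 100, beta = 0), 10, 0:3),
               "beta")
})

test_that("radial-death model: exponential rim phase, steady state, monotonicity", {
  p <- radial_death_params(lam = 1, zeta = 1, Rd = 150)
  tsw <- 3 * log(150 / 10)            # R reaches Rd
  tt <- time_grid(seq(0, 0.95 * tsw, length.out = 7))
  tr <- solve_radial_death(p, 10, tt)
  expect_equal(tr$radius, 10 * exp(as.numeric(tt) / 3), tolerance = 1e-10)
  ## steady state: (R - Rd)^3 / R^3 = 1/(1 + gamma); oracle by bisection
  Rstar <- bisect(function(R) (R - 150)^3 / R^3 - 0.5, 151, 3000)
  expect_equal(Rstar, 150 / (1 - 2^(-1 / 3)), tolerance = 1e-8)
  late <- solve_radial_death(p, 10, c(0, 250, 300))$radius
  expect_equal(late[2], Rstar, tolerance = 1e-5)
  expect_equal(late[3], Rstar, tolerance = 1e-5)
  ## zeta = 0: monotone non-decreasing
  r0 <- solve_radial_death(c(lam = 1, zeta = 0, Rd = 100), 10,
                           seq(0, 40, by = 0.5))$radius
  expect_true(all(diff(r0) >= 0))
})

test_that("Greenspan inner radii satisfy the phase system", {
  ## phase 1 and the closed-form phase 2
  expect_equal(greenspan_inner_radii(100, p1),
               list(Ri = 0, Rn = 0, phase = 1L))
  ir2 <- greenspan_inner_radii(130, p1)
  expect_equal(ir2$Ri, 50)            # sqrt(130^2 - 120^2)
  expect_identical(ir2$phase, 2L)
  ## phase 3 against an independent bisection oracle
  R <- 200; Q <- 0.8; Rd <- 150
  Rn_o <- bisect(function(x) R^3 - Rd^2 * R - 3 * R * x^2 + 2 * x^3, 0, R)
  ir3 <- greenspan_inner_radii(R, p1)
  expect_equal(ir3$Rn, Rn_o, tolerance = 1e-9)
  Ri_o <- bisect(function(x) Q^2 * Rd^2 * R * x + R * x^3 +
                   2 * R * Rn_o^3 - R^3 * x - 2 * x * Rn_o^3, Rn_o, R)
  expect_equal(ir3$Ri, Ri_o, tolerance = 1e-9)
  ## residuals of both algebraic equations
  expect_lt(abs(R^3 - Rd^2 * R - 3 * R * ir3$Rn^2 + 2 * ir3$Rn^3),
            1e-10 * R^3)
  expect_lt(abs(Q^2 * Rd^2 * R * ir3$Ri + R * ir3$Ri^3 +
                  2 * R * ir3$Rn^3 - R^3 * ir3$Ri - 2 * ir3$Ri * ir3$Rn^3),
            1e-10 * R^4)
  ## ordering and phase thresholds across a sweep of radii
  for (R in seq(20, 400, by = 20)) {
    ir <- greenspan_inner_radii(R, p1)
    expect_true(0 <= ir$Rn && ir$Rn <= ir$Ri && ir$Ri <= R)
    expect_identical(ir$Rn > 0, R > p1[["Rd"]])
    expect_identical(ir$Ri > 0, R > p1[["Q"]] * p1[["Rd"]])
  }
})

test_that("Greenspan trajectory: exponential phase, plateau, refinement", {
  tr <- solve_greenspan(p1, 10, grid21)
  tsw <- 3 * log(0.8 * 150 / 10)
  early <- as.numeric(grid21) < tsw
  expect_equal(tr$radius[early], 10 * exp(as.numeric(grid21)[early] / 3),
               tolerance = 1e-10)
  expect_true(all(tr$necrotic_radius <= tr$inner_radius + 1e-8))
  ## long-time plateau of the reference parameter set (320 um)
  plateau <- solve_greenspan(p1, 10, c(0, 200))$radius[2]
  expect_equal(plateau, 320, tolerance = 1e-2)
  ## output-grid refinement: dense re-integration agrees at shared times
  dense <- solve_greenspan(p1, 10, seq(0, 21, by = 0.25))
  at <- match(0:21, as.numeric(dense$times))
  expect_equal(dense$radius[at], tr$radius, tolerance = 1e-6)
  ## slope continuity across the necrosis onset (R crossing Rd): the
  ## one-sided slopes on a tight stencil around the crossing time agree
  t_rd <- approx(dense$radius, as.numeric(dense$times), xout = 150)$y
  h <- 1e-4
  st <- solve_greenspan(p1, 10, t_rd + c(-2 * h, -h, h, 2 * h))$radius
  slope_l <- (st[2] - st[1]) / h
  slope_r <- (st[4] - st[3]) / h
  expect_equal(slope_l, slope_r, tolerance = 1e-3)
})

test_that("crowding functions match each model's right-hand side", {
  expect_equal(crowding_function("logistic", c(lam = 1, Rmax = 300),
                                 c(150, 300))$f, c(0.5, 0))
  expect_equal(crowding_function("gompertz", c(lam = 1, Rmax = 300),
                                 c(50, 200))$f,
               c(1, log(300 / 200)))
  expect_equal(crowding_function("richards",
                                 c(lam = 1, Rmax = 300, beta = 2),
                                 300)$f, 0)
  ## Greenspan phase 1 is exponential growth: f = 1
  expect_equal(crowding_function("greenspan", p1, c(50, 100))$f, c(1, 1))
  ## radial-death below Rd has no necrotic loss
  expect_equal(crowding_function("radial_death",
                                 radial_death_params(), c(100, 150))$f,
               c(1, 1))
  cf <- crowding_function("greenspan", p1, seq(20, 400, by = 10))
  expect_true(all(cf$f <= 1 + 1e-12))
  expect_error(crowding_function("ward_king", wk_params(), 100),
               "empirical")
  expect_error(crowding_function("nope", c(a = 1), 100), "unknown")
})

test_that("time grids and trajectories validate their invariants", {
  expect_error(time_grid(c(1, 1, 2)), "increasing")
  expect_error(time_grid(c(-1, 2)), "t >= 0")
  expect_error(time_grid(c(0, NA)), "finite")
  expect_error(trajectory(0:2, c(1, -1, 2)), "positive")
  expect_error(trajectory(0:1, c(10, 20), inner_radius = c(5, 5),
                          necrotic_radius = c(6, 6)), "Rn <= Ri")
})
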