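test_that("Greenspan-to-surrogate maps reproduce the reported fits", {
  mp <- greenspan_logistic_map()
  expect_equal(mp$target_params[["lam"]], 1.21, tolerance = 0.01)
  expect_equal(mp$target_params[["Rmax"]], 316, tolerance = 0.005)
  expect_equal(mp$r_squared, 0.998, tolerance = 1e-3)
  mg <- fit_map("greenspan", p1, "gompertz", grid21)
  expect_equal(mg$target_params[["lam"]], 1.00, tolerance = 0.01)
  expect_equal(mg$target_params[["Rmax"]], 317, tolerance = 0.005)
  expect_equal(mg$r_squared, 0.99997, tolerance = 1e-5)
  ## the bounded Gompertz surrogate matches the Greenspan model better
  ## than the logistic surrogate, and its growth-rate estimate is closer
  expect_gt(mg$r_squared, mp$r_squared)
  expect_lt(abs(mg$target_params[["lam"]] - 1),
            abs(mp$target_params[["lam"]] - 1))
})

test_that("self-map is the identity with unit R-squared", {
  pl <- c(lam = 1.2, Rmax = 310)
  mp <- fit_map("logistic", pl, "logistic", grid21)
  expect_equal(mp$target_params, pl, tolerance = 1e-6)
  expect_gt(mp$r_squared, 1 - 1e-10)
  J <- map_jacobian("logistic", pl, "logistic", grid21)
  expect_equal(unclass(J$matrix), diag(2), ignore_attr = TRUE,
               tolerance = 1e-4)
  S <- sensitivity_matrix(J)
  expect_equal(unclass(S), diag(2), ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("analytic rescaled-model map has the exact Jacobian", {
  ## target predicts 2*rate2*t, so f(rate) = rate/2 and df/drate = 1/2
  mp <- fit_map("test_linear", c(rate = 3), "test_linear_scaled",
                time_grid(1:8))
  expect_equal(mp$target_params[["rate2"]], 1.5, tolerance = 1e-8)
  J <- map_jacobian("test_linear", c(rate = 3), "test_linear_scaled",
                    time_grid(1:8))
  expect_equal(J$matrix[1, 1], 0.5, tolerance = 1e-6)
})

test_that("nested-model map recovers the generating parameters", {
  mp <- fit_map("richards", c(lam = 1.1, Rmax = 280, beta = 1),
                "logistic", grid21)
  expect_equal(mp$target_params[["lam"]], 1.1, tolerance = 1e-5)
  expect_equal(mp$target_params[["Rmax"]], 280, tolerance = 1e-5)
  expect_gt(mp$r_squared, 1 - 1e-12)
})

test_that("relative sensitivities match the reported matrix entries", {
  S <- sensitivity_matrix(greenspan_logistic_jacobian())
  ## entries printed for the Greenspan-to-logistic map (lam row entry for
  ## Q is checked in the acceptance suite)
  expect_equal(S["lam", "lam"], 0.989, tolerance = 0.02)
  expect_equal(S["lam", "gamma"], 0.105, tolerance = 0.02)
  expect_equal(S["Rmax", "Q"], 0.901, tolerance = 0.02)
  expect_equal(S["Rmax", "Rd"], 1.01, tolerance = 0.02)
  expect_equal(S["Rmax", "gamma"], -0.304, tolerance = 0.02)
  ## printed-orientation convention is the reciprocal scaling
  J <- greenspan_logistic_jacobian()
  Sp <- sensitivity_matrix(J, convention = "printed")
  pj <- J$anchor$target_params; pi_ <- J$anchor$source_params
  expect_equal(Sp["lam", "Q"],
               J$matrix["lam", "Q"] * pj[["lam"]] / pi_[["Q"]])
  expect_error(sensitivity_matrix(J$matrix, p_i = c(Q = 0, Rd = 1,
                                                    gamma = 1, lam = 1),
                                  p_j = pj), "nonzero")
})

test_that("constant-feature manifolds pass through the anchor and recertify", {
  slice <- list(free = c("Q", "gamma"), solve_for = "Rd",
                ranges = list(Q = c(0.7, 0.9), gamma = c(0.6, 1.4)),
                bracket = c(60, 400))
  for (feat in c("lam", "Rmax")) {
    mf <- feature_manifold("greenspan", p1, "logistic", grid21, feat,
                           slice, resolution = 3, feature_tol = 0.005)
    expect_gt(nrow(mf$points), 4)
    expect_true(all(abs(mf$points$residual) <= 0.005))
    ## the centre gridline is the anchor (Q = 0.8, gamma = 1): both the
    ## constant-lam and constant-Rmax surfaces must pass through Rd = 150
    ctr <- mf$points[abs(mf$points$Q - 0.8) < 1e-9 &
                       abs(mf$points$gamma - 1) < 1e-9, ]
    expect_equal(ctr$Rd, 150, tolerance = 0.01)
  }
})

test_that("tangent-plane cross product aligns with the sloppy direction", {
  ## synthetic 3-d check: orthogonal unit rows give their cross product
  Jfake <- structure(list(matrix = rbind(c(1, 0, 0), c(0, 1, 0))),
                     class = "sg_map_jacobian")
  colnames(Jfake$matrix) <- c("a", "b", "c")
  rownames(Jfake$matrix) <- c("f1", "f2")
  ## columns ordered by descending eigenvalue, so v1 = e3 = cross(e1, e2)
  ffake <- structure(list(eigenvalues = c(3, 2, 1),
                          eigenvectors = diag(3),
                          param_names = c("a", "b", "c")),
                     class = "sg_fim")
  tn <- tangent_normal_check(Jfake, ffake, c("a", "b", "c"))
  expect_equal(tn$cosine, 1)
  ## invariance under positive row rescaling
  Jscaled <- Jfake; Jscaled$matrix <- Jfake$matrix * c(7, 0.1)
  expect_equal(tangent_normal_check(Jscaled, ffake,
                                    c("a", "b", "c"))$cosine, 1)
  ## parallel rows degenerate
  Jpar <- Jfake; Jpar$matrix[2, ] <- 2 * Jpar$matrix[1, ]
  expect_error(tangent_normal_check(Jpar, ffake, c("a", "b", "c")),
               "parallel")
  ## the real Greenspan slice (Q, Rd, gamma): cross product of the map
  ## Jacobian rows aligns with the sloppiest FIM eigenvector
  tn <- tangent_normal_check(greenspan_logistic_jacobian(),
                             greenspan_fim(), c("Q", "Rd", "gamma"))
  expect_gt(tn$cosine, 0.99)
})

test_that("orthogonality report bounds and aligned-vector extremes", {
  rep <- orthogonality_report(greenspan_fim(),
                              greenspan_logistic_jacobian())
  expect_true(all(abs(rep$dot_u1) <= 1 + 1e-12))
  expect_true(all(abs(rep$dot_u2) <= 1 + 1e-12))
  expect_true(all(diff(rep$eigenvalue_rel) >= 0))   # ascending order
  ## synthetic: an eigenvector parallel to u1 gives |dot| = 1
  Jfake <- structure(list(matrix = rbind(c(2, 0), c(0, 3))),
                     class = "sg_map_jacobian")
  ffake <- structure(list(eigenvalues = c(5, 1), eigenvectors = diag(2),
                          normalised_spectrum = c(1, 0.2),
                          param_names = c("a", "b")), class = "sg_fim")
  rf <- orthogonality_report(ffake, Jfake)
  expect_equal(abs(rf$dot_u1[2]), 1)   # largest-eigenvalue vector is e1
  expect_equal(abs(rf$dot_u2[1]), 1)
})

test_that("steering achieves targeted relative feature changes", {
  J <- greenspan_logistic_jacobian()
  S <- sensitivity_matrix(J)
  expect_identical(steer(p1, S, "lam", 0), p1)
  before <- J$anchor$target_params
  ## plain move along the lam row changes lam by ~10%
  p_plain <- steer(p1, S, "lam", 0.10)
  after_plain <- fit_map("greenspan", p_plain, "logistic", grid21,
                         init = before)$target_params
  dlam_plain <- after_plain[["lam"]] / before[["lam"]] - 1
  expect_gt(dlam_plain, 0.05)
  expect_lt(dlam_plain, 0.15)
  ## orthogonalised move: lam changes, Rmax held (>= 3x smaller change)
  p_orth <- steer(p1, S, "lam", 0.10, orthogonalize = TRUE)
  after <- fit_map("greenspan", p_orth, "logistic", grid21,
                   init = before)$target_params
  dlam <- abs(after[["lam"]] / before[["lam"]] - 1)
  dRmax <- abs(after[["Rmax"]] / before[["Rmax"]] - 1)
  expect_gt(dlam, 0.03)
  expect_lt(dRmax, dlam / 3)
})
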