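#' Observation time grid
#'
#' Validates a vector of observation times (days). Times must be finite,
#' non-negative and strictly increasing.
#'
#' @param times Numeric vector of observation times in days.
#' @return The validated numeric vector, classed `sg_time_grid`.
#' @export
time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1 || any(!is.finite(times)))
    stop_domain("times must be finite numeric")
  if (times[1] < 0) stop_domain("times must start at t >= 0")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_domain("times must be strictly increasing")
  structure(as.numeric(times), class = "sg_time_grid")
}

#' Model trajectory
#'
#' A radius trajectory \eqn{R(t)} on a time grid, optionally carrying the
#' Greenspan inhibited radius \eqn{R_i(t)} and necrotic radius \eqn{R_n(t)}.
#'
#' @param times Time grid (days).
#' @param radius Spheroid radius at each time (\eqn{\mu}m).
#' @param inner_radius Optional inhibited-region radius (\eqn{\mu}m).
#' @param necrotic_radius Optional necrotic-core radius (\eqn{\mu}m).
#' @return An object of class `sg_trajectory`.
#' @export
trajectory <- function(times, radius, inner_radius = NULL,
                       necrotic_radius = NULL) {
  times <- time_grid(times)
  if (length(radius) != length(times))
    stop_domain("radius length must match times")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop_domain("radius must be finite and positive")
  if (!is.null(inner_radius) || !is.null(necrotic_radius)) {
    Ri <- if (is.null(inner_radius)) rep(0, length(times)) else inner_radius
    Rn <- if (is.null(necrotic_radius)) rep(0, length(times)) else necrotic_radius
    tol <- 1e-8 * max(radius)
    if (any(Rn < -tol) || any(Ri < Rn - tol) || any(radius < Ri - tol))
      stop_domain("inner radii must satisfy 0 <= Rn <= Ri <= R")
  }
  structure(list(times = times, radius = as.numeric(radius),
                 inner_radius = inner_radius,
                 necrotic_radius = necrotic_radius),
            class = "sg_trajectory")
}

#' @export
print.sg_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<sg_trajectory> ", n, " times on [", x$times[1], ", ",
      x$times[n], "] d; R in [", signif(min(x$radius), 5), ", ",
      signif(max(x$radius), 5), "] um",
      if (!is.null(x$necrotic_radius)) " (with inner radii)", "\n", sep = "")
  invisible(x)
}

.check_solver_inputs <- function(p, R0, grid) {
  check_finite_positive(R0, "R0")
  if (!inherits(grid, "sg_time_grid")) grid <- time_grid(grid)
  if (any(!is.finite(unlist(p)))) stop_domain("parameters must be finite")
  grid
}

#' Logistic growth of spheroid radius
#'
#' Solves \eqn{dR/dt = (\lambda/3) R (1 - R/R_{max})}, \eqn{R(0) = R_0},
#' using the closed-form solution (logistic in \eqn{R} with rate
#' \eqn{\lambda/3}). The factor 1/3 converts the volumetric growth rate
#' \eqn{\lambda} to a radial rate.
#'
#' @param p Named vector/list with `lam` (volumetric growth rate, 1/d, > 0)
#'   and `Rmax` (maximum radius, um, > 0).
#' @param R0 Initial radius, um (default 10).
#' @param grid Observation times, days.
#' @return An [trajectory()] object.
#' @export
solve_logistic <- function(p, R0 = 10, grid) {
  grid <- .check_solver_inputs(p, R0, grid)
  lam <- p[["lam"]]; Rmax <- p[["Rmax"]]
  if (lam < 0 || Rmax <= 0) stop_domain("require lam >= 0, Rmax > 0")
  R <- if (lam == 0) rep(R0, length(grid)) else
    Rmax / (1 + (Rmax / R0 - 1) * exp(-lam * grid / 3))
  trajectory(grid, R)
}

#' Bounded Gompertz growth of spheroid radius
#'
#' Solves \eqn{dR/dt = (\lambda/3) R \min(\log(R_{max}/R), 1)}: growth is
#' exactly exponential at volumetric rate \eqn{\lambda} while
#' \eqn{R < R_{max}/e}, and Gompertzian thereafter. Both regimes have closed
#' forms, joined continuously at the switch radius.
#'
#' @inheritParams solve_logistic
#' @export
solve_bounded_gompertz <- function(p, R0 = 10, grid) {
  grid <- .check_solver_inputs(p, R0, grid)
  lam <- p[["lam"]]; Rmax <- p[["Rmax"]]
  if (lam < 0 || Rmax <= 0) stop_domain("require lam >= 0, Rmax > 0")
  if (lam == 0) return(trajectory(grid, rep(R0, length(grid))))
  Rsw <- Rmax / exp(1)
  gomp <- function(Rstart, t) Rmax * exp(log(Rstart / Rmax) * exp(-lam * t / 3))
  if (R0 >= Rsw) {
    R <- gomp(R0, grid)
  } else {
    tsw <- (3 / lam) * log(Rsw / R0)  # R reaches Rmax/e
    R <- ifelse(grid < tsw, R0 * exp(lam * grid / 3),
                gomp(Rsw, grid - tsw))
  }
  trajectory(grid, R)
}

#' Richards growth of spheroid radius
#'
#' Solves \eqn{dR/dt = (\lambda/3) R (1 - (R/R_{max})^\beta)} via the
#' substitution \eqn{u = (R/R_{max})^\beta}, which is logistic with rate
#' \eqn{\lambda\beta/3}. \eqn{\beta = 1} recovers the logistic model and
#' \eqn{\beta \to 0^+} the standard Gompertz model.
#'
#' @param p Named vector/list with `lam` (1/d), `Rmax` (um), `beta`
#'   (dimensionless shape, > 0).
#' @inheritParams solve_logistic
#' @export
solve_richards <- function(p, R0 = 10, grid) {
  grid <- .check_solver_inputs(p, R0, grid)
  lam <- p[["lam"]]; Rmax <- p[["Rmax"]]; beta <- p[["beta"]]
  if (is.null(beta) || beta <= 0) stop_domain("require beta > 0")
  if (lam < 0 || Rmax <= 0) stop_domain("require lam >= 0, Rmax > 0")
  if (lam == 0) return(trajectory(grid, rep(R0, length(grid))))
  u0 <- (R0 / Rmax)^beta
  u <- u0 / (u0 + (1 - u0) * exp(-lam * beta * grid / 3))
  trajectory(grid, Rmax * u^(1 / beta))
}

#' Radial-death model for spheroid radius
#'
#' Compartment model in which nutrient penetrates a constant distance `Rd`
#' from the periphery; the volume balance \eqn{dV/dt = \lambda V_1 - \zeta N}
#' with necrotic volume \eqn{N = (4\pi/3)\max(0, R - R_d)^3} reduces to
#' \deqn{dR/dt = (\lambda/3) R [1 - (1 + \zeta/\lambda)\max(0, R-R_d)^3/R^3].}
#' Growth is exactly exponential while \eqn{R \le R_d} (closed form used);
#' the necrotic regime is integrated with an adaptive stepper.
#'
#' @param p Named vector/list with `lam` (1/d, > 0), `zeta` (necrotic loss
#'   rate, 1/d, >= 0) and `Rd` (viable rim thickness, um, > 0).
#' @inheritParams solve_logistic
#' @export
solve_radial_death <- function(p, R0 = 10, grid) {
  grid <- .check_solver_inputs(p, R0, grid)
  lam <- p[["lam"]]; zeta <- p[["zeta"]]; Rd <- p[["Rd"]]
  if (lam <= 0 || zeta < 0 || Rd <= 0)
    stop_domain("require lam > 0, zeta >= 0, Rd > 0")
  gam <- zeta / lam
  rhs <- function(t, y, parms) {
    R <- y[1]
    core <- max(0, R - Rd)
    list((lam / 3) * R * (1 - (1 + gam) * core^3 / R^3))
  }
  R <- .solve_exp_then_ode(grid, R0, lam, Rswitch = Rd, rhs)
  trajectory(grid, R)
}

## exponential closed form while R <= Rswitch, then lsoda from the switch;
## keeps the max(0, .)-type kinks away from the adaptive stepper
.solve_exp_then_ode <- function(grid, R0, lam, Rswitch, rhs) {
  tsw <- if (R0 < Rswitch) (3 / lam) * log(Rswitch / R0) else 0
  out <- numeric(length(grid))
  early <- grid <= tsw
  out[early] <- R0 * exp(lam * grid[early] / 3)
  if (any(!early)) {
    tt <- c(tsw, grid[!early])
    Rstart <- if (tsw > 0) Rswitch else R0
    sol <- deSolve::ode(c(R = Rstart), tt, rhs, NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, 2])))
      stop("ODE integration failed", call. = FALSE)
    out[!early] <- sol[-1, 2]
  }
  out
}

#' Greenspan inhibited and necrotic radii
#'
#' Given the outer radius `R`, returns the inhibited radius \eqn{R_i}, the
#' necrotic radius \eqn{R_n} and the growth phase. Phase 1
#' (\eqn{R < Q R_d}): \eqn{R_i = R_n = 0}. Phase 2
#' (\eqn{Q R_d \le R < R_d}): \eqn{R_n = 0},
#' \eqn{R_i = \sqrt{R^2 - Q^2 R_d^2}}. Phase 3 (\eqn{R \ge R_d}):
#' \eqn{R_n} is the root in \eqn{(0, R)} of
#' \deqn{0 = R^3 - R_d^2 R - 3 R R_n^2 + 2 R_n^3,}
#' and \eqn{R_i} the root in \eqn{(R_n, R)} of
#' \deqn{0 = Q^2 R_d^2 R R_i + R R_i^3 + 2 R R_n^3 - R^3 R_i - 2 R_i R_n^3.}
#' Both follow from the quasi-steady nutrient profile of a sphere with an
#' inert core and Heaviside nutrient thresholds; roots are found by a
#' guaranteed-bracketing method to relative tolerance 1e-12.
#'
#' @param R Outer radius, um (scalar, > 0).
#' @param p Named vector/list with `Q` in (0,1), `Rd` (um), `gamma` (>= 0),
#'   `lam` (1/d). Only `Q` and `Rd` enter the algebraic system.
#' @return List with `Ri`, `Rn`, `phase`.
#' @export
greenspan_inner_radii <- function(R, p) {
  check_finite_positive(R, "R")
  Q <- p[["Q"]]; Rd <- p[["Rd"]]
  if (Q <= 0 || Q >= 1 || Rd <= 0) stop_domain("require 0 < Q < 1, Rd > 0")
  if (R < Q * Rd) return(list(Ri = 0, Rn = 0, phase = 1L))
  if (R < Rd)
    return(list(Ri = sqrt(max(0, R^2 - Q^2 * Rd^2)), Rn = 0, phase = 2L))
  ## monotone in Rn on (0, R): d/dRn = 6 Rn (Rn - R) < 0
  fn <- function(Rn) R^3 - Rd^2 * R - 3 * R * Rn^2 + 2 * Rn^3
  Rn <- root_bracketed(fn, 0, R, tol = 1e-12 * R)
  fi <- function(Ri) Q^2 * Rd^2 * R * Ri + R * Ri^3 + 2 * R * Rn^3 -
    R^3 * Ri - 2 * Ri * Rn^3
  Ri <- root_bracketed(fi, Rn, R, tol = 1e-12 * R)
  list(Ri = Ri, Rn = Rn, phase = 3L)
}

## fast path for the phase-3 algebraic system: warm-started Newton on the
## same equations as greenspan_inner_radii(), falling back to the
## guaranteed bracketing solve; used inside the ODE right-hand side where
## successive calls are at nearby radii
.greenspan_inner_fast <- function(R, Q, Rd, cache) {
  if (R < Q * Rd) return(c(0, 0))
  if (R < Rd) return(c(sqrt(max(0, R^2 - Q^2 * Rd^2)), 0))
  R3 <- R^3
  cn <- R3 - Rd^2 * R                 # constant term of the Rn equation
  x <- cache$Rn
  if (is.null(x) || x <= 0 || x >= R)
    x <- sqrt(max(R^2 - Rd^2, 1e-12) / 3)
  x <- min(x, 0.999 * R)
  Rn <- NA_real_
  for (i in 1:40) {
    fx <- cn - 3 * R * x^2 + 2 * x^3
    if (abs(fx) < 1e-12 * R3) { Rn <- x; break }
    x2 <- x - fx / (6 * x * (x - R))
    if (!is.finite(x2) || x2 <= 0 || x2 >= R) break
    x <- x2
  }
  if (!is.finite(Rn))
    Rn <- root_bracketed(function(z) cn - 3 * R * z^2 + 2 * z^3, 0, R,
                         tol = 1e-12 * R)
  a1 <- Q^2 * Rd^2 * R - R3 - 2 * Rn^3  # fi = a1 x + R x^3 + c0
  c0 <- 2 * R * Rn^3
  x <- cache$Ri
  if (is.null(x) || x <= Rn || x >= R)
    x <- sqrt(max(R^2 - Q^2 * Rd^2, 1e-12))
  x <- min(max(x, 1.001 * Rn), 0.999 * R)
  Ri <- NA_real_
  for (i in 1:40) {
    fx <- a1 * x + R * x^3 + c0
    if (abs(fx) < 1e-12 * R3 * R) { Ri <- x; break }
    x2 <- x - fx / (a1 + 3 * R * x^2)
    if (!is.finite(x2) || x2 <= Rn || x2 >= R) break
    x <- x2
  }
  if (!is.finite(Ri))
    Ri <- root_bracketed(function(z) a1 * z + R * z^3 + c0, Rn, R,
                         tol = 1e-12 * R)
  cache$Rn <- Rn; cache$Ri <- Ri
  c(Ri, Rn)
}

#' Greenspan model for spheroid radius
#'
#' Nutrient-limited growth with an inhibited shell and necrotic core:
#' \deqn{dR/dt = (\lambda/3) R (1 - R_i^3/R^3 - \gamma R_n^3/R^3),}
#' with \eqn{(R_i, R_n)} recomputed from [greenspan_inner_radii()] at every
#' right-hand-side evaluation. Phase 1 (pure exponential growth while
#' \eqn{R < Q R_d}) is evaluated in closed form; the remaining phases are
#' integrated with `deSolve::lsoda` at rtol 1e-8 / atol 1e-10, starting
#' exactly at the phase-1 boundary so the stepper never straddles the
#' switch.
#'
#' @param p Named vector/list with `Q` (relative nutrient-threshold
#'   composite, dimensionless, in (0,1)), `Rd` (radius at necrosis onset,
#'   um), `gamma` (\eqn{\zeta/\lambda}, dimensionless, >= 0) and `lam`
#'   (volumetric growth rate, 1/d).
#' @inheritParams solve_logistic
#' @return A [trajectory()] with `inner_radius` and `necrotic_radius`.
#' @export
solve_greenspan <- function(p, R0 = 10, grid) {
  grid <- .check_solver_inputs(p, R0, grid)
  Q <- p[["Q"]]; Rd <- p[["Rd"]]; gam <- p[["gamma"]]; lam <- p[["lam"]]
  if (Q <= 0 || Q >= 1 || Rd <= 0 || gam < 0 || lam <= 0)
    stop_domain("require 0 < Q < 1, Rd > 0, gamma >= 0, lam > 0")
  cache <- new.env(parent = emptyenv())
  rhs <- function(t, y, parms) {
    ir <- .greenspan_inner_fast(y[1], Q, Rd, cache)
    list((lam / 3) * y[1] *
           (1 - ir[1]^3 / y[1]^3 - gam * ir[2]^3 / y[1]^3))
  }
  R <- .solve_exp_then_ode(grid, R0, lam, Rswitch = Q * Rd, rhs)
  inner <- vapply(R, function(r) {
    ir <- greenspan_inner_radii(r, p)
    c(ir$Ri, ir$Rn)
  }, numeric(2))
  trajectory(grid, R, inner_radius = inner[1, ], necrotic_radius = inner[2, ])
}

#' Crowding functions of the growth-model hierarchy
#'
#' Evaluates \eqn{f(R) = (3/(\lambda R)) dR/dt} from each model's
#' right-hand side, i.e. the factor multiplying \eqn{(\lambda/3) R} in the
#' generalised logistic form of the model.
#'
#' @param model_id One of `"logistic"`, `"gompertz"`, `"richards"`,
#'   `"radial_death"`, `"greenspan"`. The Ward-King model has no closed-form
#'   crowding function; use [wk_empirical_crowding()].
#' @param params Named parameter vector for the model.
#' @param radii Radii (um, > 0) at which to evaluate.
#' @return List of class `sg_crowding` with `radius` and `f` (f <= 1).
#' @export
crowding_function <- function(model_id, params, radii) {
  check_finite_positive(radii, "radii")
  f <- switch(model_id,
    logistic = 1 - radii / params[["Rmax"]],
    gompertz = pmin(log(params[["Rmax"]] / radii), 1),
    richards = 1 - (radii / params[["Rmax"]])^params[["beta"]],
    radial_death = {
      gam <- params[["zeta"]] / params[["lam"]]
      1 - (1 + gam) * pmax(0, radii - params[["Rd"]])^3 / radii^3
    },
    greenspan = vapply(radii, function(r) {
      ir <- greenspan_inner_radii(r, params)
      1 - ir$Ri^3 / r^3 - params[["gamma"]] * ir$Rn^3 / r^3
    }, numeric(1)),
    ward_king = stop_domain(
      "ward_king has no closed-form crowding function; ",
      "use wk_empirical_crowding() on a solved trajectory"),
    stop_domain("unknown model_id: ", model_id)
  )
  structure(list(radius = radii, f = f), class = "sg_crowding")
}
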