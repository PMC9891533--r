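#' Ward-King model parameters
#'
#' Parameters for the simplified Ward-King multiphase model. The Hill
#' exponents `m1`, `m2` are fixed at 10 to emulate Heaviside-like nutrient
#' switches, and `n0` is the initial (spatially uniform) cell volume
#' fraction. The defaults are a synthetic reference set chosen to produce
#' sigmoid growth from 10 um to a few hundred um over three weeks with
#' nutrient-limited saturation; they are a package choice, not a literature
#' value.
#'
#' Units: `lam`, `delta` 1/d; `c1`, `c2`, `p0`, `n0` dimensionless in
#' (0, 1); `alpha` d/um^2 (nutrient consumed at rate
#' \eqn{k(c) = \alpha k_m(c)} per unit cell density, with the radial
#' coordinate in um); `Dp` um^2/d; `Qp` um/d.
#'
#' @param lam Maximum volumetric growth rate, 1/d.
#' @param delta Maximum death rate, 1/d.
#' @param c1 Nutrient level of half-maximal growth.
#' @param c2 Nutrient level of half-maximal death.
#' @param alpha Nutrient consumption scale, d/um^2.
#' @param Dp Cellular-material diffusivity, um^2/d.
#' @param Qp Boundary material inflow rate, um/d.
#' @param p0 Material concentration in the surrounding medium.
#' @param m1,m2 Hill exponents (fixed at 10 unless overridden).
#' @param n0 Initial cell density in (0, 1].
#' @return Named numeric vector of class use in [solve_ward_king()].
#' @export
wk_params <- function(lam = 1, delta = 1.5, c1 = 0.4, c2 = 0.3,
                      alpha = 5e-5, Dp = 3e4, Qp = 300, p0 = 0.1,
                      m1 = 10, m2 = 10, n0 = 1) {
  p <- c(lam = lam, delta = delta, c1 = c1, c2 = c2, alpha = alpha,
         Dp = Dp, Qp = Qp, p0 = p0, m1 = m1, m2 = m2, n0 = n0)
  if (any(!is.finite(p)) || any(p[c("lam", "delta", "Dp", "Qp")] < 0))
    stop_domain("rates and diffusivities must be finite and non-negative")
  if (alpha < 0) stop_domain("alpha must be >= 0")
  if (any(p[c("c1", "c2")] <= 0) || any(p[c("c1", "c2")] >= 1))
    stop_domain("c1, c2 must be in (0, 1)")
  if (p0 < 0 || p0 > 1 || n0 < 0 || n0 > 1)
    stop_domain("p0, n0 must be in [0, 1]")
  p
}

.wk_full <- function(p) {
  ## accept an 8-parameter registry vector; fill fixed exponents and n0
  if (!"m1" %in% names(p))
    p <- c(p, m1 = 10, m2 = 10, n0 = 1)
  p
}

#' Nutrient-dependent growth and death rates
#'
#' Hill-type rates of the Ward-King model:
#' \eqn{k_m(c) = \lambda c^{m_1}/(c_1^{m_1} + c^{m_1})} (increasing in c)
#' and \eqn{k_d(c) = \delta(1 - c^{m_2}/(c_2^{m_2} + c^{m_2}))}
#' (decreasing in c). At \eqn{c = c_1} the growth rate is half-maximal; at
#' \eqn{c = c_2} the death rate is half-maximal.
#'
#' @param c Nutrient concentration(s) in `[0, 1]`.
#' @param p A [wk_params()] vector.
#' @export
wk_growth_rate <- function(c, p) {
  p <- .wk_full(p)
  p[["lam"]] * c^p[["m1"]] / (p[["c1"]]^p[["m1"]] + c^p[["m1"]])
}

#' @rdname wk_growth_rate
#' @export
wk_death_rate <- function(c, p) {
  p <- .wk_full(p)
  p[["delta"]] * (1 - c^p[["m2"]] / (p[["c2"]]^p[["m2"]] + c^p[["m2"]]))
}

## quasi-steady nutrient profile on the unit rho-grid by damped Newton.
## (1/rho^2)(rho^2 c')' = R^2 alpha km(c) n,  c'(0) = 0, c(1) = 1.
## Discretised with second-order central differences; tridiagonal Newton
## systems solved by the Thomas algorithm.
.wk_nutrient <- function(n, R, p, rho, cinit = NULL) {
  M <- length(rho)
  h <- rho[2] - rho[1]
  src_scale <- R^2 * p[["alpha"]]
  if (src_scale == 0 || all(n <= 0)) return(rep(1, M))
  cvec <- if (is.null(cinit)) rep(1, M) else cinit
  km <- function(c) wk_growth_rate(pmax(c, 0), p)
  dkm <- function(c) {
    c <- pmax(c, 1e-14)
    m <- p[["m1"]]; c1m <- p[["c1"]]^m
    p[["lam"]] * m * c^(m - 1) * c1m / (c1m + c^m)^2
  }
  resid <- function(cv) {
    r <- numeric(M)
    ## centre node: spherical symmetry limit, Laplacian = 6 (c2 - c1)/h^2
    r[1] <- 6 * (cv[2] - cv[1]) / h^2 - src_scale * km(cv[1]) * n[1]
    i <- 2:(M - 1)
    rp <- (rho[i] + rho[i + 1]) / 2
    rm <- (rho[i] + rho[i - 1]) / 2
    lap <- (rp^2 * (cv[i + 1] - cv[i]) - rm^2 * (cv[i] - cv[i - 1])) /
      (h^2 * rho[i]^2)
    r[i] <- lap - src_scale * km(cv[i]) * n[i]
    r[M] <- cv[M] - 1
    r
  }
  thomas <- function(a, b, d, rhs) {
    ## a sub, b diag, d super
    m <- length(b)
    cp <- numeric(m); dp <- numeric(m)
    cp[1] <- d[1] / b[1]; dp[1] <- rhs[1] / b[1]
    for (i in 2:m) {
      den <- b[i] - a[i] * cp[i - 1]
      cp[i] <- if (i < m) d[i] / den else 0
      dp[i] <- (rhs[i] - a[i] * dp[i - 1]) / den
    }
    x <- numeric(m)
    x[m] <- dp[m]
    for (i in (m - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  r <- resid(cvec)
  for (iter in 1:60) {
    if (max(abs(r)) < 1e-10 * max(1, src_scale)) break
    ## tridiagonal Jacobian of resid
    a <- numeric(M); b <- numeric(M); d <- numeric(M)
    b[1] <- -6 / h^2 - src_scale * dkm(cvec[1]) * n[1]
    d[1] <- 6 / h^2
    i <- 2:(M - 1)
    rp <- (rho[i] + rho[i + 1]) / 2
    rm <- (rho[i] + rho[i - 1]) / 2
    a[i] <- rm^2 / (h^2 * rho[i]^2)
    d[i] <- rp^2 / (h^2 * rho[i]^2)
    b[i] <- -(rp^2 + rm^2) / (h^2 * rho[i]^2) -
      src_scale * dkm(cvec[i]) * n[i]
    a[M] <- 0; b[M] <- 1; d[M] <- 0
    step <- thomas(a, b, d, -r)
    lambda <- 1
    for (half in 1:25) {
      cnew <- cvec + lambda * step
      rnew <- resid(cnew)
      if (max(abs(rnew)) < max(abs(r))) break
      lambda <- lambda / 2
    }
    cvec <- cnew; r <- rnew
  }
  if (max(abs(r)) > 1e-6 * max(1, src_scale))
    stop("nutrient boundary-value problem did not converge", call. = FALSE)
  pmin(pmax(cvec, 0), 1)
}

#' Solve the simplified Ward-King multiphase model
#'
#' Moving-boundary method-of-lines solver for the coupled system of cell
#' density \eqn{n(r,t)}, cellular material \eqn{p = 1 - n} (no voids),
#' quasi-steady nutrient \eqn{c(r,t)} and velocity \eqn{v(r,t)} on
#' \eqn{0 \le r \le R(t)}. The no-voids volume balance gives
#' \eqn{v = -D_p \partial n/\partial r}, so the boundary condition
#' \eqn{-D_p \partial n/\partial r = -Q_p(1 - p_0 - n)} at \eqn{r = R}
#' drives boundary motion \eqn{dR/dt = v(R, t)}.
#'
#' Numerics: Landau transformation \eqn{\rho = r/R(t)} to the fixed domain
#' `[0, 1]`; second-order central differences with first-order upwinding of
#' the advective term; the nutrient two-point boundary value problem
#' re-solved by damped Newton at every right-hand-side evaluation (warm
#' started from the previous profile); time stepping by `deSolve::lsoda`.
#' The coordinate singularity at \eqn{\rho = 0} uses the spherical symmetry
#' limit (Laplacian \eqn{\to 3\,\partial^2/\partial r^2}).
#'
#' @param p A [wk_params()] vector (8 fitted parameters plus `m1`, `m2`,
#'   `n0`; an 8-parameter vector is completed with the defaults).
#' @param R0 Initial radius, um.
#' @param grid Observation times, days.
#' @param n_rho Number of radial grid nodes (>= 20; default 101).
#' @param rtol,atol Integration tolerances.
#' @return List with `trajectory` (an [trajectory()]) and `states`, a list
#'   of per-time snapshots with fields `t`, `R`, `rho`, `n`, `p`, `c`, `v`.
#' @export
solve_ward_king <- function(p, R0 = 10, grid, n_rho = 101,
                            rtol = 1e-6, atol = 1e-8) {
  p <- .wk_full(p)
  grid <- .check_solver_inputs(p, R0, grid)
  if (n_rho < 20) stop_domain("n_rho must be >= 20")
  M <- as.integer(n_rho)
  rho <- seq(0, 1, length.out = M)
  h <- rho[2] - rho[1]
  Dp <- p[["Dp"]]; Qp <- p[["Qp"]]; p0 <- p[["p0"]]
  env <- new.env(); env$clast <- NULL

  derivs <- function(t, y, parms) {
    n <- y[1:M]; R <- y[M + 1]
    cprof <- .wk_nutrient(n, R, p, rho, env$clast)
    env$clast <- cprof
    km <- wk_growth_rate(cprof, p)
    kd <- wk_death_rate(cprof, p)
    ## one-sided gradient at the boundary comes from the flux condition
    dn_b <- (Qp * R / Dp) * (1 - p0 - n[M])
    ## central first derivative with ghost node at rho = 1
    ghost <- n[M - 1] + 2 * h * dn_b
    np <- c(n[2:M], ghost)
    nm <- c(n[2], n[1:(M - 1)])       # symmetry ghost at rho = 0
    dndr <- (np - nm) / (2 * h)
    dndr[1] <- 0
    lap <- (np - 2 * n + nm) / h^2 + (2 / pmax(rho, h)) * dndr
    lap[1] <- 6 * (n[2] - n[1]) / h^2
    v <- -(Dp / R) * dndr             # um/d, velocity profile
    Rdot <- v[M]
    ## advection n_t = a n_rho + ..., a = (rho Rdot - v)/R; upwind on a
    a <- (rho * Rdot - v) / R
    fwd <- c(n[2:M] - n[1:(M - 1)], ghost - n[M]) / h
    bwd <- c(n[2] - n[1], n[2:M] - n[1:(M - 1)]) / h
    adv <- ifelse(a >= 0, a * fwd, a * bwd)
    adv[1] <- 0
    dn <- adv + (n * Dp / R^2) * lap + (km - kd) * n
    list(c(dn, Rdot))
  }

  tt <- grid
  if (tt[1] > 0) tt <- c(0, tt)
  y0 <- c(rep(p[["n0"]], M), R0)
  sol <- deSolve::ode(y0, tt, derivs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, M + 2])))
    stop("Ward-King integration failed; state dump in attr('state')",
         call. = FALSE)
  keep <- match(round(grid, 10), round(sol[, 1], 10))
  Rout <- unname(sol[keep, M + 2])
  states <- lapply(keep, function(i) {
    n <- unname(sol[i, 2:(M + 1)]); R <- unname(sol[i, M + 2])
    cprof <- .wk_nutrient(n, R, p, rho)
    dn_b <- (Qp * R / Dp) * (1 - p0 - n[M])
    ghost <- n[M - 1] + 2 * h * dn_b
    dndr <- (c(n[2:M], ghost) - c(n[2], n[1:(M - 1)])) / (2 * h)
    dndr[1] <- 0
    list(t = sol[i, 1], R = R, rho = rho, n = n, p = 1 - n, c = cprof,
         v = -(Dp / R) * dndr)
  })
  list(trajectory = trajectory(grid, Rout), states = states)
}

#' Empirical crowding function from a trajectory
#'
#' Computes \eqn{f(R) = (3/(\lambda R)) dR/dt} by centred finite
#' differences of a solved trajectory; used for models (such as Ward-King)
#' that cannot be written as a generalised logistic model in closed form.
#'
#' @param traj An [trajectory()].
#' @param lam Volumetric growth rate used for normalisation, 1/d.
#' @export
wk_empirical_crowding <- function(traj, lam) {
  t <- as.numeric(traj$times); R <- traj$radius
  n <- length(t)
  if (n < 3) stop_domain("need at least 3 points to differentiate")
  dRdt <- numeric(n)
  dRdt[2:(n - 1)] <- (R[3:n] - R[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dRdt[1] <- (R[2] - R[1]) / (t[2] - t[1])
  dRdt[n] <- (R[n] - R[n - 1]) / (t[n] - t[n - 1])
  structure(list(radius = R, f = 3 * dRdt / (lam * R)),
            class = "sg_crowding")
}
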