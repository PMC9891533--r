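#' Model registry
#'
#' The registry ties each model identifier to its parameter names, default
#' (true-value) parameters, fitting bounds, fitting transforms and solver.
#' Identifiers: `"logistic"`, `"gompertz"` (bounded Gompertz),
#' `"richards"`, `"radial_death"`, `"greenspan"`, `"ward_king"`.
#'
#' Transforms are used by every optimisation routine so that searches cover
#' several orders of magnitude: positive parameters are optimised on the log
#' scale and (0,1)-bounded parameters (Q, c1, c2, p0, n0) on the logit
#' scale.
#'
#' @return Named list of model descriptors.
#' @export
model_registry <- function() {
  if (!is.null(.sg_cache$registry)) return(.sg_cache$registry)
  lg <- function(n) stats::setNames(rep("log", length(n)), n)
  reg <- list(
    logistic = list(
      id = "logistic", k = 2L, params = c("lam", "Rmax"),
      default = c(lam = 1, Rmax = 320),
      lower = c(lam = 1e-3, Rmax = 1), upper = c(lam = 1e3, Rmax = 1e5),
      transform = lg(c("lam", "Rmax")),
      solve = function(p, R0, grid, ...) solve_logistic(p, R0, grid)),
    gompertz = list(
      id = "gompertz", k = 2L, params = c("lam", "Rmax"),
      default = c(lam = 1, Rmax = 320),
      lower = c(lam = 1e-3, Rmax = 1), upper = c(lam = 1e3, Rmax = 1e5),
      transform = lg(c("lam", "Rmax")),
      solve = function(p, R0, grid, ...) solve_bounded_gompertz(p, R0, grid)),
    richards = list(
      id = "richards", k = 3L, params = c("lam", "Rmax", "beta"),
      default = c(lam = 1, Rmax = 320, beta = 1),
      lower = c(lam = 1e-3, Rmax = 1, beta = 1e-3),
      upper = c(lam = 1e3, Rmax = 1e5, beta = 1e3),
      transform = lg(c("lam", "Rmax", "beta")),
      solve = function(p, R0, grid, ...) solve_richards(p, R0, grid)),
    radial_death = list(
      id = "radial_death", k = 3L, params = c("lam", "zeta", "Rd"),
      default = c(lam = 1, zeta = 1, Rd = 150),
      lower = c(lam = 1e-3, zeta = 1e-6, Rd = 1),
      upper = c(lam = 1e3, zeta = 1e3, Rd = 1e4),
      transform = lg(c("lam", "zeta", "Rd")),
      solve = function(p, R0, grid, ...) solve_radial_death(p, R0, grid)),
    greenspan = list(
      id = "greenspan", k = 4L, params = c("Q", "Rd", "gamma", "lam"),
      default = c(Q = 0.8, Rd = 150, gamma = 1, lam = 1),
      lower = c(Q = 1e-4, Rd = 1, gamma = 1e-6, lam = 1e-3),
      upper = c(Q = 1 - 1e-4, Rd = 1e4, gamma = 1e3, lam = 1e3),
      transform = c(Q = "logit", Rd = "log", gamma = "log", lam = "log"),
      solve = function(p, R0, grid, ...) solve_greenspan(p, R0, grid)),
    ward_king = list(
      id = "ward_king", k = 8L,
      params = c("lam", "delta", "c1", "c2", "alpha", "Dp", "Qp", "p0"),
      default = wk_params(),
      lower = c(lam = 1e-3, delta = 1e-3, c1 = 1e-3, c2 = 1e-3,
                alpha = 1e-9, Dp = 1, Qp = 1e-2, p0 = 1e-3),
      upper = c(lam = 1e3, delta = 1e3, c1 = 1 - 1e-3, c2 = 1 - 1e-3,
                alpha = 1, Dp = 1e7, Qp = 1e5, p0 = 1 - 1e-3),
      transform = c(lam = "log", delta = "log", c1 = "logit", c2 = "logit",
                    alpha = "log", Dp = "log", Qp = "log", p0 = "logit"),
      solve = function(p, R0, grid, ...) {
        solve_ward_king(p, R0, grid, ...)$trajectory
      }),
    ## analytic test models (m = rate * t and a rescaled twin); used by the
    ## test suite as exact oracles for Jacobian and map machinery
    test_linear = list(
      id = "test_linear", k = 1L, params = "rate",
      default = c(rate = 1),
      lower = c(rate = 1e-6), upper = c(rate = 1e6),
      transform = c(rate = "log"),
      solve = function(p, R0, grid, ...)
        trajectory(grid, p[["rate"]] * as.numeric(grid))),
    test_linear_scaled = list(
      id = "test_linear_scaled", k = 1L, params = "rate2",
      default = c(rate2 = 1),
      lower = c(rate2 = 1e-6), upper = c(rate2 = 1e6),
      transform = c(rate2 = "log"),
      solve = function(p, R0, grid, ...)
        trajectory(grid, 2 * p[["rate2"]] * as.numeric(grid)))
  )
  .sg_cache$registry <- reg
  reg
}

#' @rdname model_registry
#' @param model_id Model identifier.
#' @export
model_info <- function(model_id) {
  reg <- model_registry()
  if (!model_id %in% names(reg))
    stop_domain("unknown model_id: ", model_id)
  reg[[model_id]]
}

#' @rdname model_registry
#' @export
list_models <- function() names(model_registry())

#' Model predictions on a time grid
#'
#' Returns the prediction vector \eqn{m_i(p)} of radius values for a
#' registered model.
#'
#' @param model_id Model identifier (see [model_registry()]).
#' @param p Named parameter vector.
#' @param grid Observation times, days.
#' @param R0 Initial radius, um.
#' @param ... Passed to the solver (e.g. `n_rho` for `ward_king`).
#' @export
model_predict <- function(model_id, p, grid, R0 = 10, ...) {
  info <- model_info(model_id)
  p <- p[info$params]
  if (any(is.na(names(p))) || length(p) != info$k)
    stop_domain(model_id, " needs parameters: ",
                paste(info$params, collapse = ", "))
  info$solve(p, R0, grid, ...)$radius
}

## parameter <-> unconstrained internal coordinates for the optimisers
.to_internal <- function(p, info) {
  tr <- info$transform[names(p)]
  ifelse(tr == "logit", stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)),
         log(p))
}

.from_internal <- function(th, info) {
  tr <- info$transform[names(th)]
  out <- ifelse(tr == "logit", stats::plogis(th), exp(th))
  names(out) <- names(th)
  out
}

#' Parameter constructors
#'
#' Convenience constructors returning validated named parameter vectors for
#' each model.
#'
#' @param lam Volumetric growth rate, 1/d.
#' @param Rmax Maximum radius, um.
#' @name params
NULL

#' @rdname params
#' @export
logistic_params <- function(lam = 1, Rmax = 320) {
  check_finite_positive(c(lam, Rmax), "lam, Rmax")
  c(lam = lam, Rmax = Rmax)
}

#' @rdname params
#' @export
gompertz_params <- function(lam = 1, Rmax = 320) {
  check_finite_positive(c(lam, Rmax), "lam, Rmax")
  c(lam = lam, Rmax = Rmax)
}

#' @rdname params
#' @param beta Richards shape parameter, dimensionless.
#' @export
richards_params <- function(lam = 1, Rmax = 320, beta = 1) {
  check_finite_positive(c(lam, Rmax, beta), "lam, Rmax, beta")
  c(lam = lam, Rmax = Rmax, beta = beta)
}

#' @rdname params
#' @param zeta Necrotic loss rate, 1/d.
#' @param Rd Viable rim thickness / radius at necrosis onset, um.
#' @export
radial_death_params <- function(lam = 1, zeta = 1, Rd = 150) {
  check_finite_positive(c(lam, Rd), "lam, Rd")
  if (zeta < 0) stop_domain("zeta must be >= 0")
  c(lam = lam, zeta = zeta, Rd = Rd)
}

#' @rdname params
#' @param Q Relative nutrient-threshold composite, in (0, 1).
#' @param gamma Necrotic loss rate relative to growth rate, zeta/lam.
#' @export
greenspan_params <- function(Q = 0.8, Rd = 150, gamma = 1, lam = 1) {
  check_finite_positive(c(Rd, lam), "Rd, lam")
  if (Q <= 0 || Q >= 1) stop_domain("Q must be in (0, 1)")
  if (gamma < 0) stop_domain("gamma must be >= 0")
  c(Q = Q, Rd = Rd, gamma = gamma, lam = lam)
}
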