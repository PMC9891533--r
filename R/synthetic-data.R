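#' Synthetic dataset of noisy radius observations
#'
#' @param times Observation times, days.
#' @param y Observed radii, um.
#' @param sigma Noise standard deviation, um (> 0 for likelihood work).
#' @return Object of class `sg_dataset`.
#' @export
dataset <- function(times, y, sigma) {
  times <- time_grid(times)
  if (length(y) != length(times) || any(!is.finite(y)))
    stop_domain("y must be finite and match times")
  if (!is.finite(sigma) || sigma < 0) stop_domain("sigma must be >= 0")
  structure(list(times = times, y = as.numeric(y), sigma = sigma),
            class = "sg_dataset")
}

#' @export
print.sg_dataset <- function(x, ...) {
  cat("<sg_dataset> n =", length(x$y), " sigma =", x$sigma, "um\n")
  invisible(x)
}

#' Scenario configurations
#'
#' Named study scenarios for the synthetic-data generator:
#' * `"main"` - Greenspan generator at (Q, Rd, gamma, lam) =
#'   (0.8, 150, 1, 1), R0 = 10 um, daily observations t = 0..21 d,
#'   sigma = 20 um, one replicate.
#' * `"noise_sweep"` - as `"main"` but sigma in \{5, 10, 20, 40\} um with
#'   100 replicates per sigma (the exact sigma grid is configurable since
#'   only its qualitative span is documented).
#' * `"early_time"` - 22 equally spaced observations on 0..5 d with
#'   sigma = 2 um.
#'
#' @param name Scenario name.
#' @return A list of class `sg_scenario` with fields `generator_model`,
#'   `generator_params`, `R0`, `grid`, `sigma` (possibly a vector),
#'   `replicates`.
#' @export
scenario <- function(name) {
  base <- list(generator_model = "greenspan",
               generator_params = greenspan_params(),
               R0 = 10, grid = time_grid(0:21), sigma = 20, replicates = 1)
  cfg <- switch(name,
    main = base,
    noise_sweep = utils::modifyList(base, list(sigma = c(5, 10, 20, 40),
                                               replicates = 100)),
    early_time = utils::modifyList(base, list(
      grid = time_grid(seq(0, 5, length.out = 22)), sigma = 2)),
    stop_domain("unknown scenario: ", name))
  structure(c(cfg, list(name = name)), class = "sg_scenario")
}

## deterministic sub-seed for replicate r of a base seed (kept < 2^31)
.sub_seed <- function(seed, r) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(r) %% 1000003L
}

#' Generate noisy synthetic radius datasets
#'
#' Observations follow \eqn{y^{(k)} = m^{(k)}(p) + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma^2)} i.i.d. Noise can produce
#' non-physical values (e.g. negative radii at small R0 and large sigma);
#' values are kept as generated, since clipping would bias the noise model.
#' Replicate `r` uses a sub-seed derived deterministically from
#' `(seed, r)`, so individual replicates are reproducible in isolation.
#'
#' @param cfg An `sg_scenario` (or compatible list). If `cfg$sigma` has
#'   length > 1 the first value is used; see [aic_sweep()] for sweeps.
#' @param seed Integer seed.
#' @param replicate Replicate index (default 1).
#' @return An `sg_dataset`.
#' @export
generate_dataset <- function(cfg, seed = 1, replicate = 1) {
  m <- model_predict(cfg$generator_model, cfg$generator_params,
                     cfg$grid, R0 = cfg$R0)
  sigma <- cfg$sigma[1]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(.sub_seed(seed, replicate))
  y <- m + stats::rnorm(length(m), 0, sigma)
  dataset(cfg$grid, y, sigma)
}
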