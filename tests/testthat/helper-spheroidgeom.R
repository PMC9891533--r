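## shared fixtures and independent closed-form oracles

grid21 <- time_grid(0:21)
p1 <- greenspan_params()          # (Q, Rd, gamma, lam) = (0.8, 150, 1, 1)

## closed forms written independently of the solver implementations
logistic_oracle <- function(lam, Rmax, R0, t)
  Rmax / (1 + (Rmax / R0 - 1) * exp(-lam * t / 3))

gompertz_std_oracle <- function(lam, Rmax, R0, t)
  Rmax * exp(log(R0 / Rmax) * exp(-lam * t / 3))

## plain bisection, used as the independent root oracle
bisect <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

noise_free_data <- function(model_id, p, grid = grid21, sigma = 20,
                            R0 = 10)
  dataset(grid, model_predict(model_id, p, grid, R0), sigma)

## memoised expensive fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

greenspan_logistic_map <- function() {
  if (is.null(.fixtures$map))
    .fixtures$map <- fit_map("greenspan", p1, "logistic", grid21)
  .fixtures$map
}

greenspan_logistic_jacobian <- function() {
  if (is.null(.fixtures$J))
    .fixtures$J <- map_jacobian("greenspan", p1, "logistic", grid21,
                                anchor = greenspan_logistic_map())
  .fixtures$J
}

greenspan_fim <- function() {
  if (is.null(.fixtures$fim))
    .fixtures$fim <- fim(model_jacobian("greenspan", p1, grid21), 20)
  .fixtures$fim
}
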