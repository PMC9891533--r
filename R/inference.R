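#' Gaussian log-likelihood of a model at given parameters
#'
#' For additive i.i.d. normal noise with known sigma,
#' \deqn{\ell(p) = -n \log(\sigma\sqrt{2\pi}) - \|y - m(p)\|^2/(2\sigma^2).}
#' If the solver fails at `p` the function returns `-Inf` with a warning.
#'
#' @param data An [dataset()].
#' @param model_id Registered model identifier.
#' @param p Named parameter vector.
#' @param R0 Initial radius, um.
#' @export
log_likelihood <- function(data, model_id, p, R0 = 10) {
  n <- length(data$y)
  s <- tryCatch(sse(data, model_id, p, R0),
                error = function(e) {
                  warning("solver failed at p: ", conditionMessage(e),
                          call. = FALSE)
                  Inf
                })
  -n * log(data$sigma * sqrt(2 * pi)) - s / (2 * data$sigma^2)
}

#' Sum-of-squares error of a model at given parameters
#'
#' \eqn{e(p) = \sum_k (y^{(k)} - m^{(k)}(p))^2} (um^2). Minimising `sse` is
#' equivalent to maximising [log_likelihood()] for known sigma.
#'
#' @inheritParams log_likelihood
#' @export
sse <- function(data, model_id, p, R0 = 10) {
  m <- model_predict(model_id, p, data$times, R0 = R0)
  sum((data$y - m)^2)
}

## deterministic multi-start design: registry default plus log-scale
## perturbations drawn with a fixed private RNG stream (user RNG untouched)
.default_starts <- function(info, n_starts) {
  p0 <- pmin(pmax(info$default, info$lower * 1.01), info$upper * 0.99)
  starts <- list(p0)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(194703L)
    for (s in seq_len(n_starts - 1)) {
      f <- stats::runif(length(p0), -1, 1)          # +- one decade
      ps <- pmin(pmax(p0 * 10^f, info$lower * 1.01), info$upper * 0.99)
      starts[[s + 1]] <- ps
    }
  }
  starts
}

.bounded_objective <- function(fun, info) {
  function(th) {
    names(th) <- info$params
    p <- .from_internal(th, info)
    if (any(p < info$lower) || any(p > info$upper)) {
      excess <- sum(pmax(0, info$lower / p - 1) + pmax(0, p / info$upper - 1))
      return(1e10 * (1 + excess))
    }
    v <- tryCatch(fun(p), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
}

.run_nm <- function(obj, th0, reltol = 1e-8, maxit = 3000, restarts = 1,
                    polish = TRUE) {
  if (length(th0) == 1)  # simplex is unreliable in 1-D; bracketed search
    return(stats::optim(th0, obj, method = "Brent", lower = th0 - 25,
                        upper = th0 + 25))
  o <- stats::optim(th0, obj, method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = maxit))
  for (r in seq_len(restarts))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  if (polish) {
    ## quasi-Newton sharpening of the simplex result; keep only if better
    pol <- tryCatch(stats::optim(o$par, obj, method = "BFGS",
                                 control = list(reltol = 1e-13,
                                                maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(pol) && pol$value <= o$value) o <- pol
  }
  o
}

#' Maximum likelihood fit of a registered model
#'
#' Maximises the Gaussian log-likelihood (equivalently minimises the
#' sum-of-squares error) by multi-start Nelder-Mead on transformed
#' parameters (log scale for positive parameters, logit for (0,1)-bounded
#' ones) so that the search covers several orders of magnitude. Starts
#' default to the registry default plus deterministic log-scale
#' perturbations within +-1 decade. Ties between starts are broken by the
#' highest log-likelihood, then the smallest parameter norm.
#'
#' @inheritParams log_likelihood
#' @param starts Optional list of named start vectors; overrides the
#'   default design.
#' @param n_starts Number of default starts (>= 1).
#' @param bounds Optional list with `lower`/`upper` named vectors
#'   overriding the registry fitting box.
#' @return Object of class `sg_fit` with fields `model_id`, `p_hat`,
#'   `loglik`, `sse`, `k`, `aic` (= 2k - 2 loglik), `n_starts`,
#'   `converged`, `R0`.
#' @export
fit_mle <- function(data, model_id, starts = NULL, n_starts = 5,
                    bounds = NULL, R0 = 10) {
  info <- model_info(model_id)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) info$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) info$upper[names(bounds$upper)] <- bounds$upper
  }
  if (is.null(starts)) starts <- .default_starts(info, n_starts)
  obj <- .bounded_objective(function(p) sse(data, model_id, p, R0), info)
  best <- NULL
  n_ok <- 0L
  for (st in starts) {
    th0 <- .to_internal(st[info$params], info)
    o <- tryCatch(.run_nm(obj, th0), error = function(e) NULL)
    if (is.null(o)) next
    n_ok <- n_ok + 1L
    p <- .from_internal(stats::setNames(o$par, info$params), info)
    cand <- list(p = p, sse = o$value, conv = o$convergence == 0)
    if (is.null(best) || cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 &&
         sum(cand$p^2) < sum(best$p^2)))
      best <- cand
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  n <- length(data$y)
  ll <- -n * log(data$sigma * sqrt(2 * pi)) - best$sse / (2 * data$sigma^2)
  structure(list(model_id = model_id, p_hat = best$p, loglik = ll,
                 sse = best$sse, k = info$k, aic = 2 * info$k - 2 * ll,
                 n_starts = length(starts), converged = best$conv, R0 = R0),
            class = "sg_fit")
}

#' @export
print.sg_fit <- function(x, ...) {
  cat("<sg_fit> ", x$model_id, ": loglik = ", signif(x$loglik, 6),
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  print(signif(x$p_hat, 4))
  invisible(x)
}

## shared profiling engine; `objective(p) -> value to minimise`,
## `to_report(value)` converts the per-point minimum to the stored profile
.profile_engine <- function(model_id, param_name, grid_values, p_centre,
                            objective, info) {
  eta_names <- setdiff(info$params, param_name)
  prof <- rep(NA_real_, length(grid_values))
  eta_store <- vector("list", length(grid_values))
  eta_hat <- p_centre[eta_names]
  eta_default <- .default_starts(info, 1)[[1]][eta_names]
  inner <- function(phi0, eta_starts) {
    sub <- info
    sub$params <- eta_names
    sub$lower <- info$lower[eta_names]; sub$upper <- info$upper[eta_names]
    sub$transform <- info$transform[eta_names]
    obj <- .bounded_objective(function(eta) {
      p <- c(phi0, eta)[info$params]
      names(p) <- info$params
      objective(p)
    }, sub)
    best <- NULL
    for (eta0 in eta_starts) {
      th0 <- .to_internal(eta0[eta_names], sub)
      o <- if (length(eta_names) == 1) {
        lo <- .to_internal(sub$lower, sub); up <- .to_internal(sub$upper, sub)
        tryCatch(stats::optim(th0, obj, method = "Brent", lower = lo,
                              upper = up), error = function(e) NULL)
      } else {
        tryCatch(.run_nm(obj, th0, reltol = 1e-9, maxit = 4000,
                         restarts = 1), error = function(e) NULL)
      }
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) {
        best <- o
        best$eta <- .from_internal(stats::setNames(o$par, eta_names), sub)
      }
    }
    best
  }
  i0 <- which.min(abs(log(grid_values) - log(p_centre[[param_name]])))
  for (half in list(seq(i0, length(grid_values)), seq(i0, 1))) {
    eta_prev <- eta_hat
    for (i in half) {
      phi0 <- stats::setNames(grid_values[i], param_name)
      ## three starts: MLE, previously profiled point, initial guess
      res <- inner(phi0, list(c(phi0, eta_hat), c(phi0, eta_prev),
                              c(phi0, eta_default)))
      if (is.null(res)) next
      prof[i] <- res$value
      eta_store[[i]] <- res$eta
      eta_prev <- res$eta
    }
  }
  list(values = prof, eta = eta_store)
}

#' Profile log-likelihood of one parameter
#'
#' For each grid value \eqn{\varphi_0} of the profiled parameter, maximises
#' the log-likelihood over the remaining (nuisance) parameters and reports
#' \eqn{PLL(\varphi_0) = \sup_\eta \ell(\varphi_0, \eta) - \ell(\hat p)}.
#' Profiling proceeds sequentially outward from the grid point closest to
#' the MLE; each inner optimisation is started from three points (the MLE,
#' the previously profiled point, and the default initial guess) and the
#' best result kept. The 95% confidence threshold is
#' \eqn{-\Delta_{1,0.95}/2 = -\chi^2_1(0.95)/2 \approx -1.92}; the
#' confidence interval is the grid region with `pll >= threshold`, and the
#' parameter is classified `identifiable`, `one_sided` or
#' `non_identifiable` by the number of threshold crossings (see
#' [classify_identifiability()]).
#'
#' @inheritParams log_likelihood
#' @param param_name Name of the profiled parameter.
#' @param fit An `sg_fit` from [fit_mle()].
#' @param grid Optional explicit grid of profiled values. By default 41
#'   log-spaced points on `span` times the MLE, clipped to the registry
#'   bounds.
#' @param n_grid,span Grid resolution and relative range (default
#'   `c(0.01, 100)`).
#' @param conf Confidence level for the threshold (default 0.95).
#' @return Object of class `sg_profile`.
#' @export
profile_parameter <- function(data, model_id, param_name, fit, grid = NULL,
                              n_grid = 41, span = c(0.01, 100),
                              conf = 0.95, R0 = 10) {
  info <- model_info(model_id)
  if (!param_name %in% info$params)
    stop_domain("unknown parameter: ", param_name)
  if (!isTRUE(fit$converged))
    warning("profiling from a non-converged fit", call. = FALSE)
  phat <- fit$p_hat[[param_name]]
  if (is.null(grid)) {
    lo <- max(info$lower[[param_name]], phat * span[1])
    up <- min(info$upper[[param_name]], phat * span[2])
    grid <- exp(seq(log(lo), log(up), length.out = n_grid))
  }
  eng <- .profile_engine(model_id, param_name, grid, fit$p_hat,
                         function(p) sse(data, model_id, p, R0), info)
  n <- length(data$y)
  ll <- -n * log(data$sigma * sqrt(2 * pi)) - eng$values / (2 * data$sigma^2)
  ## normalise so the best point (MLE or better, if profiling found better)
  ## is at zero; pll <= 0 everywhere by construction
  ll_ref <- max(fit$loglik, ll, na.rm = TRUE)
  pll <- ll - ll_ref
  threshold <- -stats::qchisq(conf, df = 1) / 2
  out <- structure(list(param_name = param_name, grid = grid, pll = pll,
                        threshold = threshold, model_id = model_id,
                        mle = phat, conf = conf),
                   class = "sg_profile")
  cls <- classify_identifiability(out)
  out$classification <- cls$classification
  out$ci_lower <- cls$ci_lower
  out$ci_upper <- cls$ci_upper
  out
}

#' Profile of the error function on noise-free data
#'
#' The same profiling machinery as [profile_parameter()] applied directly
#' to the sum-of-squares error \eqn{e(p)} of noise-free data (sigma plays
#' no role): per grid value the error is minimised over the nuisance
#' parameters and reported normalised so the global minimum is zero.
#'
#' @inheritParams profile_parameter
#' @param centre Optional parameter vector the profile grid is centred on
#'   (defaults to a least-squares fit of the data).
#' @return Object of class `sg_error_profile` with fields `grid` and
#'   `profile` (normalised minimum error per grid point, >= 0).
#' @export
profile_error_function <- function(data, model_id, param_name, grid = NULL,
                                   n_grid = 41, span = c(0.01, 100),
                                   centre = NULL, R0 = 10) {
  info <- model_info(model_id)
  if (!param_name %in% info$params)
    stop_domain("unknown parameter: ", param_name)
  if (is.null(centre)) {
    f <- fit_mle(dataset(data$times, data$y, max(data$sigma, 1)),
                 model_id, R0 = R0)
    centre <- f$p_hat
  }
  phat <- centre[[param_name]]
  if (is.null(grid)) {
    lo <- max(info$lower[[param_name]], phat * span[1])
    up <- min(info$upper[[param_name]], phat * span[2])
    grid <- exp(seq(log(lo), log(up), length.out = n_grid))
  }
  eng <- .profile_engine(model_id, param_name, grid, centre,
                         function(p) sse(data, model_id, p, R0), info)
  structure(list(param_name = param_name, grid = grid,
                 profile = eng$values - min(eng$values, na.rm = TRUE),
                 model_id = model_id, centre = phat),
            class = "sg_error_profile")
}

#' Classify practical identifiability from a profile
#'
#' A parameter is `identifiable` when the profile log-likelihood crosses
#' the chi-squared threshold on both sides of its maximiser within the
#' grid, `one_sided` with exactly one crossing, and `non_identifiable`
#' with none.
#'
#' @param profile An `sg_profile`.
#' @return List with `classification`, `ci_lower`, `ci_upper` (threshold
#'   crossings by linear interpolation; `-Inf`/`Inf` when unbounded within
#'   the grid).
#' @export
classify_identifiability <- function(profile) {
  g <- profile$grid; pll <- profile$pll; thr <- profile$threshold
  ok <- is.finite(pll)
  if (sum(ok) < 3) stop_domain("degenerate profile grid")
  imax <- which(pll == max(pll[ok]))[1]
  cross_at <- function(i, j) {      # interpolate between grid i and j
    w <- (thr - pll[i]) / (pll[j] - pll[i])
    exp(log(g[i]) + w * (log(g[j]) - log(g[i])))
  }
  lower <- -Inf; upper <- Inf
  left <- FALSE; right <- FALSE
  if (imax > 1) for (i in seq(imax - 1, 1)) {
    if (!ok[i]) next
    if (pll[i] < thr) { left <- TRUE; lower <- cross_at(i, i + 1); break }
  }
  if (imax < length(g)) for (i in seq(imax + 1, length(g))) {
    if (!ok[i]) next
    if (pll[i] < thr) { right <- TRUE; upper <- cross_at(i, i - 1); break }
  }
  cls <- if (left && right) "identifiable" else
    if (left || right) "one_sided" else "non_identifiable"
  list(classification = cls, ci_lower = lower, ci_upper = upper)
}

#' AIC comparison sweep over noise levels
#'
#' Repeats the synthetic-data experiment: for each noise level and each
#' replicate, a dataset is generated from the generator model and every
#' candidate model is fitted by maximum likelihood; AIC = 2k - 2 loglik is
#' recorded and summarised as mean and standard deviation per model and
#' noise level.
#'
#' @param generator_model,generator_params Generating model and its
#'   parameters.
#' @param sigmas Noise standard deviations, um.
#' @param reps Replicates per sigma (>= 1; >= 2 for a standard deviation).
#' @param candidate_models Character vector of model ids to fit.
#' @param seed Base seed; replicate r of a sweep uses a deterministic
#'   sub-seed.
#' @param grid Observation times (default daily 0..21 d).
#' @param n_starts Starts per fit.
#' @param R0 Initial radius, um.
#' @return Data frame with columns `sigma`, `model`, `mean_aic`, `sd_aic`,
#'   `n_ok`.
#' @export
aic_sweep <- function(generator_model, generator_params, sigmas, reps,
                      candidate_models, seed = 1, grid = 0:21,
                      n_starts = 3, R0 = 10) {
  if (reps < 1) stop_domain("reps must be >= 1")
  grid <- time_grid(grid)
  rows <- list()
  for (sg in sigmas) {
    cfg <- list(generator_model = generator_model,
                generator_params = generator_params,
                R0 = R0, grid = grid, sigma = sg)
    aics <- matrix(NA_real_, reps, length(candidate_models),
                   dimnames = list(NULL, candidate_models))
    for (r in seq_len(reps)) {
      d <- generate_dataset(cfg, seed = seed + round(1000 * sg), replicate = r)
      for (m in candidate_models) {
        f <- tryCatch(fit_mle(d, m, n_starts = n_starts, R0 = R0),
                      error = function(e) NULL)
        if (!is.null(f)) aics[r, m] <- f$aic
      }
    }
    for (m in candidate_models)
      rows[[length(rows) + 1]] <- data.frame(
        sigma = sg, model = m,
        mean_aic = mean(aics[, m], na.rm = TRUE),
        sd_aic = if (reps > 1) stats::sd(aics[, m], na.rm = TRUE) else NA_real_,
        n_ok = sum(is.finite(aics[, m])))
  }
  do.call(rbind, rows)
}
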