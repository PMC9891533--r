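#' Parameter sensitivity matrix (model Jacobian)
#'
#' The n x k matrix of partial derivatives of the model predictions with
#' respect to each parameter, \eqn{J_{kj} = \partial R(t^{(k)})/\partial
#' p_j}, computed by central finite differences with per-parameter relative
#' step `rel_step` (default 1e-4) and optional one-level Richardson
#' extrapolation.
#'
#' @param model_id Registered model identifier.
#' @param p Named parameter vector.
#' @param grid Observation times, days.
#' @param R0 Initial radius, um.
#' @param rel_step Relative finite-difference step.
#' @param richardson If `TRUE`, combine steps h and h/2 by Richardson
#'   extrapolation.
#' @param ... Passed to the solver.
#' @return Object of class `sg_jacobian` with fields `matrix` (n x k),
#'   `param_names`, `times`.
#' @export
model_jacobian <- function(model_id, p, grid, R0 = 10, rel_step = 1e-4,
                           richardson = FALSE, ...) {
  info <- model_info(model_id)
  p <- p[info$params]
  grid <- if (inherits(grid, "sg_time_grid")) grid else time_grid(grid)
  central <- function(k, h) {
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    (model_predict(model_id, pp, grid, R0, ...) -
       model_predict(model_id, pm, grid, R0, ...)) / (2 * h)
  }
  cols <- lapply(seq_along(p), function(k) {
    h <- rel_step * max(abs(p[k]), 1e-8)
    d1 <- central(k, h)
    if (!richardson) return(d1)
    d2 <- central(k, h / 2)
    (4 * d2 - d1) / 3
  })
  J <- do.call(cbind, cols)
  colnames(J) <- info$params
  if (any(!is.finite(J))) stop("non-finite Jacobian entries", call. = FALSE)
  structure(list(matrix = J, param_names = info$params, times = grid),
            class = "sg_jacobian")
}

#' Fisher information matrix and sloppiness spectrum
#'
#' For additive Gaussian noise the observed FIM is
#' \eqn{F = J^\top J / \sigma^2}, where J is the sensitivity Jacobian.
#' (The 1/sigma^2 scaling makes F the true information matrix; the
#' normalised spectrum, eigenvectors, rank and condition number are
#' unaffected by it.) Eigenvalues are returned in descending order with
#' matching eigenvector columns; the normalised spectrum is scaled so the
#' spectral radius is unity.
#'
#' @param J An `sg_jacobian` (or plain n x k matrix).
#' @param sigma Noise standard deviation, um.
#' @return Object of class `sg_fim` with fields `fim`, `eigenvalues`,
#'   `eigenvectors`, `condition_number`, `normalised_spectrum`, `sigma`.
#' @export
fim <- function(J, sigma = 1) {
  M <- if (inherits(J, "sg_jacobian")) J$matrix else as.matrix(J)
  F <- crossprod(M) / sigma^2
  e <- eigen((F + t(F)) / 2, symmetric = TRUE)
  structure(list(fim = F, eigenvalues = e$values,
                 eigenvectors = e$vectors,
                 condition_number = e$values[1] / e$values[length(e$values)],
                 normalised_spectrum = e$values / e$values[1],
                 param_names = colnames(M), sigma = sigma),
            class = "sg_fim")
}

#' @export
print.sg_fim <- function(x, ...) {
  cat("<sg_fim> k =", length(x$eigenvalues),
      " condition number =", signif(x$condition_number, 4), "\n")
  cat("normalised spectrum:", signif(x$normalised_spectrum, 3), "\n")
  invisible(x)
}

#' Normalised FIM spectra for a set of models
#'
#' Computes the FIM eigen-spectrum for each (model, parameters) pair,
#' normalised so the spectral radius is unity, and counts "sloppy"
#' eigenvalues: those separated from the leading group by a spectral gap
#' of at least `gap_decades` decades.
#'
#' @param models_and_params Named list: each element a named parameter
#'   vector, names of the list giving model ids; or a list of
#'   `list(model_id=, p=)`.
#' @param grid Observation times.
#' @param sigma Noise standard deviation, um.
#' @param gap_decades Sloppy-gap threshold in decades (default 3).
#' @param ... Passed to [model_jacobian()].
#' @return Data frame with one row per eigenvalue: `model`, `index`,
#'   `normalised_eigenvalue`, `log10_normalised`, `sloppy`.
#' @export
spectrum_report <- function(models_and_params, grid, sigma = 20,
                            gap_decades = 3, ...) {
  rows <- lapply(seq_along(models_and_params), function(i) {
    el <- models_and_params[[i]]
    if (is.list(el) && !is.null(el$model_id)) {
      id <- el$model_id; p <- el$p
    } else {
      id <- names(models_and_params)[i]; p <- el
    }
    f <- fim(model_jacobian(id, p, grid, ...), sigma)
    lg <- log10(pmax(f$normalised_spectrum, .Machine$double.xmin))
    gaps <- -diff(lg)
    sloppy <- rep(FALSE, length(lg))
    big <- which(gaps >= gap_decades)
    if (length(big)) sloppy[(min(big) + 1):length(lg)] <- TRUE
    data.frame(model = id, index = seq_along(lg),
               normalised_eigenvalue = f$normalised_spectrum,
               log10_normalised = lg, sloppy = sloppy)
  })
  do.call(rbind, rows)
}

## smallest-eigenvalue unit eigenvector with deterministic sign: first
## component of magnitude > tol positive, or aligned with `prev`
.sloppy_vector <- function(f, prev = NULL) {
  v <- f$eigenvectors[, length(f$eigenvalues)]
  v <- v / sqrt(sum(v^2))
  if (!is.null(prev)) {
    if (sum(v * prev) < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-10)[1]
    if (length(nz) && v[nz] < 0) v <- -v
  }
  v
}

#' Follow the sloppy direction through parameter space
#'
#' Integrates \eqn{dp/ds = v_1(p)}, where \eqn{v_1(p)} is the unit
#' eigenvector of the smallest FIM eigenvalue, by fixed-step fourth-order
#' Runge-Kutta in scaled coordinates (parameters divided by `p_start`,
#' since the arclength parameterisation is arbitrary). Sign continuity is
#' enforced by flipping \eqn{v_1} whenever its dot product with the
#' previous direction is negative. The log-likelihood along the path is
#' recorded against `data` (by default the noise-free generating data with
#' the supplied sigma).
#'
#' @param model_id Registered model identifier.
#' @param p_start Named starting parameter vector.
#' @param sigma Noise standard deviation used in the FIM and likelihood.
#' @param grid Observation times.
#' @param span Scaled arclength to integrate in each direction
#'   (default 0.25).
#' @param step RK4 step in scaled coordinates (default 0.01).
#' @param data Optional `sg_dataset` for the likelihood record.
#' @param R0 Initial radius, um.
#' @return Object of class `sg_sloppy_path` with `arclength` (signed),
#'   `points` (matrix, one row per path point), `loglik_along`.
#' @export
sloppy_path <- function(model_id, p_start, sigma, grid, span = 0.25,
                        step = 0.01, data = NULL, R0 = 10) {
  info <- model_info(model_id)
  p_start <- p_start[info$params]
  grid <- if (inherits(grid, "sg_time_grid")) grid else time_grid(grid)
  if (is.null(data))
    data <- dataset(grid, model_predict(model_id, p_start, grid, R0),
                    sigma)
  scale <- abs(p_start)
  dirfun <- function(q, prev) {
    p <- q * scale
    f <- fim(model_jacobian(model_id, p, grid, R0), sigma)
    v <- .sloppy_vector(f, prev)
    w <- v / scale                    # tangent in scaled coordinates
    w / sqrt(sum(w^2))
  }
  march <- function(sgn) {
    n_steps <- max(1L, ceiling(span / step))
    q <- p_start / scale
    prev <- sgn * dirfun(q, NULL)
    pts <- matrix(NA_real_, n_steps + 1, length(q))
    pts[1, ] <- q * scale
    s <- numeric(n_steps + 1)
    for (i in seq_len(n_steps)) {
      k1 <- dirfun(q, prev)
      k2 <- dirfun(q + step / 2 * k1, k1)
      k3 <- dirfun(q + step / 2 * k2, k2)
      k4 <- dirfun(q + step * k3, k3)
      q <- q + step * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      prev <- k4
      pts[i + 1, ] <- q * scale
      s[i + 1] <- s[i] + sgn * step
    }
    list(pts = pts, s = s)
  }
  fwd <- march(1)
  bwd <- march(-1)
  pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))[-1]), , drop = FALSE],
               fwd$pts)
  s <- c(rev(bwd$s[-1]), fwd$s)
  colnames(pts) <- info$params
  ll <- apply(pts, 1, function(p)
    log_likelihood(data, model_id, stats::setNames(p, info$params), R0))
  structure(list(arclength = s, points = pts, loglik_along = ll,
                 model_id = model_id, sigma = sigma),
            class = "sg_sloppy_path")
}
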