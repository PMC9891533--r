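## default initial guess for fitting a target model to a radius curve:
## early-time slope for lam, curve maximum for Rmax-like scales
.map_init <- function(target_model, m, grid, R0) {
  t <- as.numeric(grid)
  pos <- which(m > 0 & t > t[1])
  lam0 <- if (length(pos)) {
    i <- pos[1]
    max(1e-2, min(1e2, 3 * log(m[i] / max(m[1], R0 / 2)) / (t[i] - t[1])))
  } else 1
  top <- 1.1 * max(m)
  switch(target_model,
    logistic = c(lam = lam0, Rmax = top),
    gompertz = c(lam = lam0, Rmax = top),
    richards = c(lam = lam0, Rmax = top, beta = 1),
    radial_death = c(lam = lam0, zeta = lam0, Rd = 0.5 * max(m)),
    greenspan = c(Q = 0.8, Rd = 0.5 * max(m), gamma = 1, lam = lam0),
    test_linear = c(rate = max(m) / max(t)),
    test_linear_scaled = c(rate2 = max(m) / (2 * max(t))),
    ward_king = stop_domain(
      "ward_king target requires an explicit init (its printed initial ",
      "guess is under-determined); pass init = wk_params(...)"),
    stop_domain("unknown model_id: ", target_model))
}

#' Least-squares map between model parameter spaces
#'
#' Computes \eqn{f_{ij}(p_i) = \arg\min_{p_j} \|m_i(p_i) - m_j(p_j)\|}:
#' the parameters of the surrogate (target) model j that best reproduce
#' the noise-free predictions of the source model i at `p_i`, i.e. the
#' maximum-likelihood estimate for model j if noise-free data from model i
#' were observed. Goodness of correspondence is summarised by
#' \deqn{R^2 = 1 - \|m_i - m_j(f_{ij})\|^2 / \|m_i - \bar m_i\|^2.}
#'
#' The minimisation runs multi-start Nelder-Mead on transformed target
#' parameters, followed by a quasi-Newton polish of the best start (the
#' map is defined by the argmin, so the polish only sharpens it; it also
#' makes finite differences of the map smooth enough for
#' [map_jacobian()]).
#'
#' @param source_model,p_i Source model id and its named parameters.
#' @param target_model Target (surrogate) model id.
#' @param grid Observation times used to compare the models (the
#'   reference scenario uses daily times 0..21 d).
#' @param init Optional named start for the target parameters (required
#'   for a `ward_king` target).
#' @param n_starts Number of Nelder-Mead starts (the initial guess plus
#'   deterministic log-scale perturbations).
#' @param R0 Initial radius, um (shared by both models).
#' @param m_source Optional precomputed source prediction vector.
#' @return Object of class `sg_map` with `source_model`, `source_params`,
#'   `target_model`, `target_params`, `r_squared`, `residual_norm` (um),
#'   `sse`.
#' @export
fit_map <- function(source_model, p_i, target_model, grid, init = NULL,
                    n_starts = 3, R0 = 10, m_source = NULL) {
  grid <- if (inherits(grid, "sg_time_grid")) grid else time_grid(grid)
  if (is.null(m_source))
    m_source <- model_predict(source_model, p_i, grid, R0)
  info <- model_info(target_model)
  if (is.null(init)) init <- .map_init(target_model, m_source, grid, R0)
  init <- pmin(pmax(init[info$params], info$lower * 1.01),
               info$upper * 0.99)
  obj <- .bounded_objective(function(p)
    sum((m_source - model_predict(target_model, p, grid, R0))^2), info)
  starts <- list(init)
  if (n_starts > 1) {
    fac <- list(c(0.3, 1), c(3, 1), c(1, 0.5), c(1, 2))
    for (s in seq_len(n_starts - 1)) {
      f <- rep(1, info$k)
      f[seq_along(fac[[1 + (s - 1) %% length(fac)]])] <-
        fac[[1 + (s - 1) %% length(fac)]]
      starts[[s + 1]] <- pmin(pmax(init * f, info$lower * 1.01),
                              info$upper * 0.99)
    }
  }
  best <- NULL
  for (st in starts) {
    th0 <- .to_internal(st, info)
    o <- tryCatch(.run_nm(obj, th0, reltol = 1e-12, restarts = 1),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("map optimisation failed", call. = FALSE)
  p_j <- .from_internal(stats::setNames(best$par, info$params), info)
  tss <- sum((m_source - mean(m_source))^2)
  structure(list(source_model = source_model, source_params = p_i,
                 target_model = target_model, target_params = p_j,
                 r_squared = 1 - best$value / tss,
                 residual_norm = sqrt(best$value), sse = best$value),
            class = "sg_map")
}

#' @export
print.sg_map <- function(x, ...) {
  cat("<sg_map> ", x$source_model, " -> ", x$target_model,
      "  (R^2 = ", signif(x$r_squared, 5), ")\n", sep = "")
  print(signif(x$target_params, 4))
  invisible(x)
}

#' Jacobian of the model map
#'
#' Central finite differences of \eqn{f_{ij}} with per-column relative
#' steps and Richardson extrapolation: for each source parameter the
#' derivative is extrapolated from steps (h, h/2) and (h/2, h/4); if the
#' two extrapolants disagree beyond `tol` (relative) the step is halved
#' and the test repeated. Every perturbed map evaluation is warm-started
#' from the anchor's fitted target parameters, which suppresses optimiser
#' noise and makes the columns smooth.
#'
#' Rows correspond to target parameters (the gradients
#' \eqn{u_k = \nabla p_j^{(k)}}), columns to source parameters.
#'
#' @inheritParams fit_map
#' @param fd_step Initial relative step (default 1e-3).
#' @param tol Column-norm-relative agreement required between Richardson
#'   levels (default 2e-3, near the optimiser-noise floor of the inner
#'   fits).
#' @param max_shrink Maximum number of step halvings.
#' @param anchor Optional precomputed `sg_map` at `p_i`.
#' @return Object of class `sg_map_jacobian` with `matrix`
#'   (k_j x k_i), `anchor`, `fd_steps`.
#' @export
map_jacobian <- function(source_model, p_i, target_model, grid,
                         fd_step = 1e-3, tol = 2e-3, max_shrink = 3,
                         anchor = NULL, R0 = 10) {
  grid <- if (inherits(grid, "sg_time_grid")) grid else time_grid(grid)
  src_info <- model_info(source_model)
  p_i <- p_i[src_info$params]
  if (is.null(anchor))
    anchor <- fit_map(source_model, p_i, target_model, grid, R0 = R0)
  warm <- anchor$target_params
  f_eval <- function(p) {
    fit_map(source_model, p, target_model, grid, init = warm,
            n_starts = 1, R0 = R0)$target_params
  }
  central <- function(k, h) {
    pp <- p_i; pp[k] <- p_i[k] + h
    pm <- p_i; pm[k] <- p_i[k] - h
    (f_eval(pp) - f_eval(pm)) / (2 * h)
  }
  steps <- numeric(length(p_i))
  cols <- vector("list", length(p_i))
  for (k in seq_along(p_i)) {
    h <- fd_step * max(abs(p_i[k]), 1e-8)
    ## keep (0,1)-bounded source parameters inside their domain
    if (src_info$transform[k] == "logit")
      h <- min(h, 0.25 * min(p_i[k], 1 - p_i[k]))
    best <- NULL
    for (shrink in 0:max_shrink) {
      d1 <- central(k, h); d2 <- central(k, h / 2); d4 <- central(k, h / 4)
      e1 <- (4 * d2 - d1) / 3
      e2 <- (4 * d4 - d2) / 3
      ## column-norm-relative agreement: small entries are dominated by
      ## optimiser noise and should not force step shrinkage
      disagree <- max(abs(e2 - e1)) / max(abs(e2), 1e-12)
      if (is.null(best) || disagree < best$disagree)
        best <- list(e = e2, disagree = disagree, h = h)
      if (disagree < tol) break
      h <- h / 2
    }
    if (best$disagree >= tol)
      warning("map Jacobian column '", names(p_i)[k],
              "' reached Richardson agreement ",
              signif(best$disagree, 2), " (requested ", tol, ")",
              call. = FALSE)
    cols[[k]] <- best$e
    steps[k] <- best$h
  }
  Jm <- do.call(cbind, cols)
  dimnames(Jm) <- list(names(warm), names(p_i))
  structure(list(matrix = Jm, anchor = anchor, fd_steps = steps),
            class = "sg_map_jacobian")
}

#' Relative sensitivity matrix of the model map
#'
#' Rescales the map Jacobian into dimensionless %-per-% sensitivities:
#' \deqn{S^{(k_1,k_2)} = (p_i^{(k_2)} / p_j^{(k_1)}) J^{(k_1,k_2)},}
#' interpreted as the relative change of target parameter \eqn{k_1} per
#' relative change of source parameter \eqn{k_2} (so an entry of -0.016 in
#' row lam, column Q means a 1% increase in Q decreases the surrogate lam
#' by 0.016%). `convention = "printed"` gives the transposed scaling
#' \eqn{(p_j^{(k_1)}/p_i^{(k_2)}) J^{(k_1,k_2)}}.
#'
#' @param J An `sg_map_jacobian` (or plain k_j x k_i matrix).
#' @param p_i,p_j Source and target parameter vectors (taken from the
#'   Jacobian's anchor when omitted).
#' @param convention `"target_per_source"` (default) or `"printed"`.
#' @return Matrix of class `sg_sensitivity` (rows = target parameters,
#'   columns = source parameters).
#' @export
sensitivity_matrix <- function(J, p_i = NULL, p_j = NULL,
                               convention = c("target_per_source",
                                              "printed")) {
  convention <- match.arg(convention)
  if (inherits(J, "sg_map_jacobian")) {
    if (is.null(p_i)) p_i <- J$anchor$source_params
    if (is.null(p_j)) p_j <- J$anchor$target_params
    Jm <- J$matrix
  } else Jm <- as.matrix(J)
  p_i <- p_i[colnames(Jm)]; p_j <- p_j[rownames(Jm)]
  if (any(p_i == 0) || any(p_j == 0))
    stop_domain("relative sensitivities require nonzero parameters")
  S <- if (convention == "target_per_source")
    diag(1 / p_j, nrow = length(p_j)) %*% Jm %*% diag(p_i, nrow = length(p_i))
  else
    diag(p_j, nrow = length(p_j)) %*% Jm %*% diag(1 / p_i, nrow = length(p_i))
  dimnames(S) <- dimnames(Jm)
  structure(S, class = c("sg_sensitivity", "matrix"))
}

## a scalar feature of the source parameters: a fitted target parameter,
## or the final-time necrotic radius for a Greenspan source
.feature_value <- function(source_model, p, target_model, grid,
                           feature_name, init, R0) {
  if (feature_name == "necrotic_final") {
    if (source_model != "greenspan")
      stop_domain("necrotic_final is only defined for a greenspan source")
    tr <- solve_greenspan(p, R0, grid)
    return(tr$necrotic_radius[length(tr$necrotic_radius)])
  }
  fit_map(source_model, p, target_model, grid, init = init,
          n_starts = 1, R0 = R0)$target_params[[feature_name]]
}

#' Constant-feature manifold in source parameter space
#'
#' Traces the level set \{p : feature(f_ij(p)) = level\} over a 2- or
#' 3-dimensional slice of the source parameter space: the feature level is
#' taken from the anchor point, and for every gridline of the free
#' parameters the remaining slice parameter is solved by bracketed 1-D
#' root-finding on the feature residual. Every returned point therefore
#' carries a residual certificate; gridlines where the root is not
#' bracketed are omitted (with a message).
#'
#' Features are target parameter names (e.g. `"lam"`, `"Rmax"`) or
#' `"necrotic_final"` (Greenspan necrotic radius at the final observation
#' time, which needs no surrogate).
#'
#' @inheritParams fit_map
#' @param p_anchor Source parameters on the manifold.
#' @param feature_name Feature to hold constant.
#' @param slice_spec List with `free` (1 or 2 free source parameter
#'   names), `solve_for` (the parameter solved per gridline), `ranges`
#'   (named list of c(lo, hi) for the free parameters) and `bracket`
#'   (c(lo, hi) search interval for `solve_for`). Parameters not in the
#'   slice stay at their anchor values.
#' @param resolution Gridline count per free parameter.
#' @param feature_tol Relative tolerance of the root solve.
#' @return Object of class `sg_manifold`: `feature_name`, `level`,
#'   `points` (data frame of slice coordinates plus achieved feature and
#'   residual), `slice_spec`.
#' @export
feature_manifold <- function(source_model, p_anchor, target_model, grid,
                             feature_name, slice_spec, resolution = 5,
                             feature_tol = 0.005, R0 = 10) {
  grid <- if (inherits(grid, "sg_time_grid")) grid else time_grid(grid)
  info <- model_info(source_model)
  p_anchor <- p_anchor[info$params]
  anchor_fit <- fit_map(source_model, p_anchor, target_model, grid, R0 = R0)
  warm <- anchor_fit$target_params
  level <- .feature_value(source_model, p_anchor, target_model, grid,
                          feature_name, warm, R0)
  free <- slice_spec$free; sfor <- slice_spec$solve_for
  axes <- lapply(free, function(nm)
    seq(slice_spec$ranges[[nm]][1], slice_spec$ranges[[nm]][2],
        length.out = resolution))
  names(axes) <- free
  gridpts <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  bracket <- slice_spec$bracket
  rows <- list()
  for (i in seq_len(nrow(gridpts))) {
    p <- p_anchor
    p[free] <- as.numeric(gridpts[i, ])
    resfun <- function(x) {
      p[sfor] <- x
      .feature_value(source_model, p, target_model, grid, feature_name,
                     warm, R0) - level
    }
    x <- tryCatch(
      root_bracketed(resfun, bracket[1], bracket[2],
                     tol = 1e-6 * (bracket[2] - bracket[1])),
      error = function(e) {
        message("gridline ", i, " skipped: ", conditionMessage(e))
        NA_real_
      })
    if (!is.finite(x)) next
    p[sfor] <- x
    achieved <- .feature_value(source_model, p, target_model, grid,
                               feature_name, warm, R0)
    if (abs(achieved - level) > feature_tol * abs(level)) {
      message("gridline ", i, " dropped: residual above feature_tol")
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(c(as.list(p[c(free, sfor)]),
                   list(feature = achieved,
                        residual = (achieved - level) / level)))
  }
  structure(list(feature_name = feature_name, level = level,
                 points = do.call(rbind, rows), slice_spec = slice_spec,
                 anchor = anchor_fit),
            class = "sg_manifold")
}

#' Tangent-plane cross product versus the sloppy direction
#'
#' In a 3-parameter slice, the rows u1, u2 of the model-map Jacobian are
#' normal to the constant-feature manifolds, so the intersection of the
#' two tangent planes is the cross product u1 x u2. This diagnostic
#' restricts u1, u2 and the sloppiest FIM eigenvector v1 to the slice and
#' reports the absolute cosine between u1 x u2 and v1 (close to 1 when the
#' sloppy direction runs along the manifold intersection).
#'
#' @param J An `sg_map_jacobian` with at least two rows.
#' @param fim_result An `sg_fim` for the source model.
#' @param slice Character vector of 3 source parameter names.
#' @return List with `cross`, `v1`, `cosine`.
#' @export
tangent_normal_check <- function(J, fim_result, slice) {
  if (length(slice) != 3) stop_domain("slice must name 3 parameters")
  idx <- match(slice, colnames(J$matrix))
  if (any(is.na(idx))) stop_domain("slice names not in Jacobian columns")
  u1 <- J$matrix[1, idx]; u2 <- J$matrix[2, idx]
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr < 1e-14 * sqrt(sum(u1^2)) * sqrt(sum(u2^2)))
    stop_domain("Jacobian rows are parallel; cross product degenerate")
  fidx <- match(slice, fim_result$param_names)
  v1 <- fim_result$eigenvectors[fidx, length(fim_result$eigenvalues)]
  v1 <- v1 / sqrt(sum(v1^2))
  list(cross = cr / ncr, v1 = v1,
       cosine = abs(sum(cr / ncr * v1)))
}

#' Orthogonality of FIM eigenvectors and model-map directions
#'
#' For each FIM eigenvector (ordered by ascending eigenvalue) reports the
#' dot products with the unit vectors along the model-map Jacobian rows
#' u1 (target feature 1, typically lam) and u2 (feature 2, typically
#' Rmax), together with the eigenvalue relative to the largest. Sloppy
#' eigenvectors orthogonal to both rows indicate directions that leave
#' all surrogate features unchanged.
#'
#' @param fim_result An `sg_fim` for the source model.
#' @param J An `sg_map_jacobian` from the same source model.
#' @return Data frame with `eigenvalue_rel`, `dot_u1`, `dot_u2`.
#' @export
orthogonality_report <- function(fim_result, J) {
  Jm <- J$matrix
  if (ncol(Jm) != length(fim_result$eigenvalues))
    stop_domain("dimension mismatch between FIM and map Jacobian")
  u1 <- Jm[1, ] / sqrt(sum(Jm[1, ]^2))
  u2 <- Jm[2, ] / sqrt(sum(Jm[2, ]^2))
  k <- length(fim_result$eigenvalues)
  ord <- seq(k, 1)                     # ascending eigenvalue
  data.frame(
    eigenvalue_rel = fim_result$normalised_spectrum[ord],
    dot_u1 = apply(fim_result$eigenvectors[, ord, drop = FALSE], 2,
                   function(v) sum(v * u1)),
    dot_u2 = apply(fim_result$eigenvectors[, ord, drop = FALSE], 2,
                   function(v) sum(v * u2)))
}

#' Steer source parameters toward a relative feature change
#'
#' Uses a row of the relative sensitivity matrix as a direction of
#' multiplicative parameter updates: \eqn{p \leftarrow p (1 + d)} with
#' \eqn{d \propto s_{row}} scaled so the linear prediction of the targeted
#' feature's relative change equals `rel_change`. With
#' `orthogonalize = TRUE` the direction is first projected orthogonal to
#' the other row, changing the targeted feature while approximately
#' holding the other feature fixed.
#'
#' @param p_i Source parameter vector.
#' @param S An `sg_sensitivity` matrix (rows = target features).
#' @param target_row Row name or index of the feature to change.
#' @param rel_change Desired relative change (recommended |.| <= 0.2 for
#'   the linearisation to hold).
#' @param orthogonalize Project the move orthogonal to `other_row`.
#' @param other_row Row held fixed when orthogonalising (defaults to the
#'   other row of a two-row matrix).
#' @return Adjusted parameter vector.
#' @export
steer <- function(p_i, S, target_row, rel_change,
                  orthogonalize = FALSE, other_row = NULL) {
  S <- unclass(S)
  if (is.character(target_row)) target_row <- match(target_row, rownames(S))
  st <- S[target_row, ]
  if (all(st == 0)) stop_domain("target sensitivity row is zero")
  d <- st
  if (orthogonalize) {
    if (is.null(other_row))
      other_row <- setdiff(seq_len(nrow(S)), target_row)[1]
    if (is.character(other_row)) other_row <- match(other_row, rownames(S))
    so <- S[other_row, ]
    d <- st - sum(st * so) / sum(so^2) * so
    if (sqrt(sum(d^2)) < 1e-12 * sqrt(sum(st^2)))
      stop_domain("sensitivity rows are parallel; cannot orthogonalise")
  }
  if (rel_change == 0) return(p_i)
  pred <- sum(st * d)                 # predicted relative feature change
  delta <- d * (rel_change / pred)
  p_i * (1 + delta[names(p_i)])
}
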