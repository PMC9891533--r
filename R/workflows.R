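#' End-to-end analysis workflows
#'
#' Reproduces the computations behind the study's figure panels as
#' delimited-text artifacts in an output directory. Workflows (scaled-down
#' defaults in parentheses are overridable through `cfg`):
#'
#' * `"aic"` - AIC indistinguishability sweep over noise levels
#'   (sigma grid from the `noise_sweep` scenario, `reps = 5`).
#' * `"spectra"` - normalised FIM sloppiness spectra of the model
#'   hierarchy at the reference parameters.
#' * `"profiles"` - profile likelihoods for the logistic, radial-death
#'   and Greenspan models on the main scenario, plus noise-free error
#'   profiles for the Greenspan model.
#' * `"geometry"` - constant-lam and constant-Rmax manifolds of the
#'   Greenspan-to-logistic map plus the sloppy-direction path.
#' * `"early_time"` - profile likelihoods under the early-time scenario.
#' * `"steer"` - sensitivity-row steering demonstration.
#'
#' @param name Workflow name.
#' @param cfg List of overrides: `out_dir` (default `"sg-output"`),
#'   `seed` (default 1), `scenario`, `reps`, `n_grid`, `resolution`,
#'   `models`.
#' @return Invisibly, the vector of files written.
#' @export
run_workflow <- function(name, cfg = list()) {
  out <- cfg$out_dir %||% "sg-output"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1
  t0 <- Sys.time()
  files <- switch(name,
    aic = .wf_aic(out, seed, cfg),
    spectra = .wf_spectra(out, cfg),
    profiles = .wf_profiles(out, seed, cfg),
    geometry = .wf_geometry(out, cfg),
    early_time = .wf_early(out, seed, cfg),
    steer = .wf_steer(out, cfg),
    stop_domain("unknown workflow: ", name))
  message(sprintf("workflow '%s' wrote %d file(s) in %.1f s", name,
                  length(files),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.wf_meta <- function(seed = NULL) {
  m <- list(tool = paste0("spheroidgeom ",
                          as.character(utils::packageVersion("spheroidgeom"))))
  if (!is.null(seed)) m$seed <- seed
  m
}

.wf_aic <- function(out, seed, cfg) {
  sc <- scenario("noise_sweep")
  tab <- aic_sweep("greenspan", sc$generator_params, sc$sigma,
                   reps = cfg$reps %||% 5,
                   candidate_models = cfg$models %||%
                     c("logistic", "gompertz", "richards", "radial_death",
                       "greenspan"),
                   seed = seed, grid = sc$grid)
  f <- file.path(out, "aic_sweep.tsv")
  write_sg_table(tab, f, .wf_meta(seed))
  f
}

.wf_spectra <- function(out, cfg) {
  grid <- time_grid(0:21)
  sets <- cfg$models_and_params %||% list(
    logistic = c(lam = 1.21, Rmax = 316),
    gompertz = c(lam = 1.00, Rmax = 317),
    radial_death = radial_death_params(),
    greenspan = greenspan_params())
  tab <- spectrum_report(sets, grid, sigma = 20)
  f <- file.path(out, "fim_spectra.tsv")
  write_sg_table(tab, f, .wf_meta())
  f
}

.wf_profiles <- function(out, seed, cfg) {
  sc <- scenario(cfg$scenario %||% "main")
  d <- generate_dataset(sc, seed = seed)
  n_grid <- cfg$n_grid %||% 21
  files <- file.path(out, "dataset_main.tsv")
  write_dataset(d, files[1], .wf_meta(seed))
  for (m in cfg$models %||% c("logistic", "radial_death", "greenspan")) {
    fit <- fit_mle(d, m)
    for (pn in model_info(m)$params) {
      pr <- profile_parameter(d, m, pn, fit, n_grid = n_grid)
      f <- file.path(out, sprintf("profile_%s_%s.tsv", m, pn))
      write_sg_table(data.frame(value = pr$grid, pll = pr$pll),
                     f, c(.wf_meta(seed),
                          list(threshold = pr$threshold,
                               classification = pr$classification)))
      files <- c(files, f)
    }
  }
  if (!isTRUE(cfg$error_profiles %||% TRUE)) return(files)
  ## noise-free error profiles for the Greenspan model
  mfree <- model_predict(sc$generator_model, sc$generator_params, sc$grid)
  dfree <- dataset(sc$grid, mfree, 0)
  for (pn in c("Q", "gamma")) {
    pr <- profile_error_function(dfree, "greenspan", pn,
                                 centre = sc$generator_params,
                                 n_grid = n_grid)
    f <- file.path(out, sprintf("error_profile_greenspan_%s.tsv", pn))
    write_sg_table(data.frame(value = pr$grid, error = pr$profile), f,
                   .wf_meta())
    files <- c(files, f)
  }
  files
}

.wf_geometry <- function(out, cfg) {
  grid <- time_grid(0:21)
  p1 <- greenspan_params()
  res <- cfg$resolution %||% 4
  slice <- list(free = c("Q", "gamma"), solve_for = "Rd",
                ranges = list(Q = c(0.65, 0.92), gamma = c(0.5, 2)),
                bracket = c(60, 400))
  files <- character()
  for (feat in c("lam", "Rmax")) {
    mf <- feature_manifold("greenspan", p1, "logistic", grid, feat, slice,
                           resolution = res)
    f <- file.path(out, sprintf("manifold_const_%s.tsv", feat))
    write_sg_table(mf$points, f, c(.wf_meta(), list(level = mf$level)))
    files <- c(files, f)
  }
  sp <- sloppy_path("greenspan", p1, sigma = 20, grid,
                    span = cfg$span %||% 0.1, step = cfg$step %||% 0.02)
  f <- file.path(out, "sloppy_path.tsv")
  write_sg_table(data.frame(arclength = sp$arclength, sp$points,
                            loglik = sp$loglik_along), f, .wf_meta())
  c(files, f)
}

.wf_early <- function(out, seed, cfg) {
  cfg$scenario <- "early_time"
  cfg$models <- cfg$models %||% c("logistic", "radial_death")
  cfg$error_profiles <- cfg$error_profiles %||% FALSE
  .wf_profiles(out, seed, cfg)
}

.wf_steer <- function(out, cfg) {
  grid <- time_grid(0:21)
  p1 <- greenspan_params()
  J <- map_jacobian("greenspan", p1, "logistic", grid)
  S <- sensitivity_matrix(J)
  rows <- list()
  for (orth in c(FALSE, TRUE)) {
    p_new <- steer(p1, S, "lam", 0.1, orthogonalize = orth)
    after <- fit_map("greenspan", p_new, "logistic", grid,
                     init = J$anchor$target_params)$target_params
    before <- J$anchor$target_params
    rows[[length(rows) + 1]] <- data.frame(
      orthogonalized = orth,
      dlam_rel = after[["lam"]] / before[["lam"]] - 1,
      dRmax_rel = after[["Rmax"]] / before[["Rmax"]] - 1)
  }
  f <- file.path(out, "steering.tsv")
  write_sg_table(do.call(rbind, rows), f, .wf_meta())
  f
}
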