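#' Read and write trajectories and datasets as delimited text
#'
#' Trajectories serialise with columns `time_d`, `radius_um` and, when
#' present, `inner_radius_um`, `necrotic_radius_um`. Datasets serialise
#' with columns `time_d`, `radius_obs_um` and carry sigma and generator
#' metadata as `#`-prefixed comment lines.
#'
#' @param traj An `sg_trajectory`.
#' @param file Path to a tab-delimited text file.
#' @param meta Optional named list written as comment headers.
#' @export
write_trajectory <- function(traj, file, meta = NULL) {
  df <- data.frame(time_d = as.numeric(traj$times), radius_um = traj$radius)
  if (!is.null(traj$inner_radius)) {
    df$inner_radius_um <- traj$inner_radius
    df$necrotic_radius_um <- traj$necrotic_radius
  }
  write_sg_table(df, file, meta)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- read_sg_table(file)
  trajectory(df$time_d, df$radius_um,
             inner_radius = df$inner_radius_um,
             necrotic_radius = df$necrotic_radius_um)
}

#' @rdname write_trajectory
#' @param data An `sg_dataset`.
#' @export
write_dataset <- function(data, file, meta = NULL) {
  write_sg_table(data.frame(time_d = as.numeric(data$times),
                            radius_obs_um = data$y),
                 file, c(list(sigma_um = data$sigma), meta))
}

#' @rdname write_trajectory
#' @export
read_dataset <- function(file) {
  hdr <- grep("^#", readLines(file, n = 20), value = TRUE)
  sig <- sub(".*sigma_um = ", "", grep("sigma_um", hdr, value = TRUE)[1])
  df <- read_sg_table(file)
  dataset(df$time_d, df$radius_obs_um, as.numeric(sig))
}

#' Serialise Ward-King state snapshots
#'
#' Writes per-time blocks of columns `t_d`, `rho`, `n`, `p`, `c`,
#' `v_um_d`.
#'
#' @param states List of state snapshots from [solve_ward_king()].
#' @param file Output path.
#' @export
write_wk_states <- function(states, file) {
  df <- do.call(rbind, lapply(states, function(s)
    data.frame(t_d = s$t, rho = s$rho, n = s$n, p = s$p, c = s$c,
               v_um_d = s$v)))
  write_sg_table(df, file)
}
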