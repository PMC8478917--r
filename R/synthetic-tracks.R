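# Correlated-random-walk track generator with tracking noise. Stands in for
# manually tracked nuclear positions: the analysis stages assume nothing
# about the generator beyond what these parameters state.

#' Parameters of the correlated-random-walk generator
#'
#' The walk draws per-frame step speeds from a lognormal distribution with
#' the stated arithmetic mean/sd (speeds are positive and right-skewed, as
#' per-cell speed distributions are) and evolves the heading as
#' `theta[t+1] = theta[t] + vonMises(0, kappa)`; `kappa = 0` is an
#' uncorrelated walk and `kappa >= 1e6` a straight path. Observed positions
#' are the true positions plus i.i.d. Gaussian noise of sd `noise_sd` per
#' coordinate, modelling manual-tracking positional error.
#'
#' @param n_frames number of observed frames (>= 2)
#' @param frame_interval minutes between frames (> 0)
#' @param speed_mean mean step speed, um/min (> 0)
#' @param speed_sd sd of step speeds, um/min (>= 0; 0 = constant speed)
#' @param kappa von Mises turning-angle concentration (>= 0)
#' @param noise_sd positional error sd per coordinate, um (>= 0)
#' @param seed integer RNG seed
#' @return a validated parameter list of class `crw_params`
#' @export
crw_params <- function(n_frames = 48L, frame_interval = 5, speed_mean = 0.4,
                       speed_sd = 0.2, kappa = 1, noise_sd = 0, seed = 1L) {
  check_scalar(n_frames, "n_frames", lower = 2, integer = TRUE)
  check_scalar(frame_interval, "frame_interval", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(speed_mean, "speed_mean", lower = 0, allow_equal_lower = FALSE)
  check_scalar(speed_sd, "speed_sd", lower = 0)
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, speed_mean = speed_mean,
                 speed_sd = speed_sd, kappa = kappa, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "crw_params")
}

#' Simulate a correlated random walk
#'
#' @param params a [crw_params()]
#' @param cell_id identifier for the generated track
#' @return an observed [track()] (true positions + positional noise) whose
#'   [ground_truth()] carries the noise-free track, the parameters, the true
#'   headings and the true mean step speed
#' @export
#' @examples
#' tr <- simulate_crw(crw_params(n_frames = 20, kappa = 4, seed = 7))
#' ground_truth(tr)$true_mean_speed
simulate_crw <- function(params, cell_id = "sim") {
  stopifnot(inherits(params, "crw_params"))
  set.seed(params$seed)
  n_steps <- params$n_frames - 1L
  step_mean <- params$speed_mean * params$frame_interval
  step_sd <- params$speed_sd * params$frame_interval
  lp <- lognormal_from_moments(step_mean, step_sd)
  steps <- if (lp$sigma == 0) rep(step_mean, n_steps) else
    stats::rlnorm(n_steps, lp$mu, lp$sigma)
  turns <- c(stats::runif(1, -pi, pi), rvonmises(n_steps - 1L, params$kappa))
  if (params$kappa >= 1e6) turns[1] <- 0       # degenerate: straight along +x
  headings <- cumsum(turns)
  x_true <- c(0, cumsum(steps * cos(headings)))
  y_true <- c(0, cumsum(steps * sin(headings)))
  times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  x_obs <- x_true + stats::rnorm(params$n_frames, sd = params$noise_sd)
  y_obs <- y_true + stats::rnorm(params$n_frames, sd = params$noise_sd)
  tr <- track(cell_id, times, x_obs, y_obs)
  set_ground_truth(tr, "simulate_crw", params,
                   true_track = track(paste0(cell_id, "_true"), times,
                                      x_true, y_true),
                   headings = headings,
                   true_mean_speed = mean(steps) / params$frame_interval)
}

#' Replicate noisy observations of one true track
#'
#' Emulates tracking the same cell several times, blinded: each replicate is
#' the true track plus independent Gaussian positional noise. Used to drive
#' [usable_time_interval()].
#'
#' @param truth a noise-free [track()]
#' @param noise_sd positional error sd per coordinate, um
#' @param n_replicates number of independent observations (>= 2)
#' @param seed integer RNG seed
#' @return list of [track()]s sharing `truth`'s timestamps
#' @export
replicate_observations <- function(truth, noise_sd, n_replicates, seed = 1L) {
  stopifnot(inherits(truth, "track"))
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(n_replicates, "n_replicates", lower = 2, integer = TRUE)
  set.seed(seed)
  n <- n_frames(truth)
  lapply(seq_len(n_replicates), function(i) {
    tr <- track(sprintf("%s_rep%d", truth$cell_id, i), truth$times,
                truth$x + stats::rnorm(n, sd = noise_sd),
                truth$y + stats::rnorm(n, sd = noise_sd))
    set_ground_truth(tr, "replicate_observations",
                     list(noise_sd = noise_sd, n_replicates = n_replicates,
                          seed = seed, replicate = i),
                     true_track = truth)
  })
}
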