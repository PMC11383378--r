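# Synthetic arena videos: a moving Gaussian blob with a programmed speed
# profile, optional hypoactivity onset, and brief head-twitch jitter events.

#' Speed profiles for the behavior generator
#'
#' `control` keeps a constant programmed speed; `hypoactive` switches from
#' `speed_pre` to the strictly lower `speed_post` at `switch_time_s`
#' (emulating the abrupt drop in cage exploration after psychedelic
#' dosing).
#'
#' @param speed,speed_pre,speed_post Blob speeds (px/s).
#' @param switch_time_s Hypoactivity onset time (s).
#' @return A profile list consumed by [simulate_behavior_video()].
#' @export
behavior_profile_control <- function(speed = 20) {
  list(type = "control", speed = speed)
}

#' @rdname behavior_profile_control
#' @export
behavior_profile_hypoactive <- function(switch_time_s = 600,
                                        speed_pre = 20, speed_post = 3) {
  if (speed_post >= speed_pre)
    stop("hypoactive profile needs `speed_post` < `speed_pre`")
  list(type = "hypoactive", switch_time_s = switch_time_s,
       speed_pre = speed_pre, speed_post = speed_post)
}

#' Head-twitch rate profiles
#'
#' `htr_rate_decaying()` is an exponentially decaying rate with a hard
#' cutoff (default: gone by 10 min), matching the reported head-twitch
#' time-course after psilocybin; `htr_rate_constant()` is a homogeneous
#' (possibly zero) rate for control-like videos.
#'
#' @param peak_rate_hz Initial (or constant) event rate (events/s).
#' @param tau_s Exponential decay constant (s).
#' @param cutoff_s Time after which the rate is exactly zero (s).
#' @return A rate-profile list consumed by [simulate_behavior_video()].
#' @export
htr_rate_decaying <- function(peak_rate_hz = 0.15, tau_s = 150,
                              cutoff_s = 600) {
  list(type = "decaying", peak_rate_hz = peak_rate_hz, tau_s = tau_s,
       cutoff_s = cutoff_s)
}

#' @rdname htr_rate_decaying
#' @export
htr_rate_constant <- function(peak_rate_hz = 0.005) {
  list(type = "constant", peak_rate_hz = peak_rate_hz)
}

htr_rate_at <- function(profile, t) {
  switch(profile$type,
         decaying = ifelse(t < profile$cutoff_s,
                           profile$peak_rate_hz * exp(-t / profile$tau_s), 0),
         constant = rep(profile$peak_rate_hz, length(t)),
         stop("unknown HTR rate profile"))
}

# Inhomogeneous Poisson event times on [0, duration) by thinning.
draw_htr_times <- function(profile, duration_s) {
  lmax <- max(htr_rate_at(profile, seq(0, duration_s, by = 1)))
  if (lmax <= 0) return(numeric(0))
  n <- stats::rpois(1, lmax * duration_s)
  cand <- sort(stats::runif(n, 0, duration_s))
  keep <- stats::runif(n) < htr_rate_at(profile, cand) / lmax
  cand[keep]
}

# Reflect a free path into [lo, hi] (triangle-wave folding).
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}

#' Simulate an arena video of a moving animal
#'
#' A Gaussian blob performs a persistent random walk (reflecting at the
#' arena walls) whose per-frame displacement follows the programmed speed
#' profile. Head-twitch events are rendered as brief (`htr_duration_s`,
#' default 0.15 s <= 0.2 s) high-amplitude positional jitter. The
#' programmed speed and event times are recorded as ground truth.
#'
#' @param duration_s Video duration (s); sessions are 40--60 min at full
#'   scale.
#' @param fps Frames per second (analysis runs at 30 fps at full scale).
#' @param shape Frame shape `c(height, width)` in px.
#' @param profile A [behavior_profile_control()] or
#'   [behavior_profile_hypoactive()] speed profile.
#' @param htr_profile A [htr_rate_decaying()] / [htr_rate_constant()] rate
#'   profile, or `NULL` for no events.
#' @param bout_mean_on_s,bout_mean_off_s Mean durations (s) of movement
#'   bouts and of the still intervals between them (exponentially
#'   distributed). Real mice locomote intermittently, and this burstiness
#'   is what makes the Hilbert-envelope movement trace informative; set
#'   `bout_mean_off_s = 0` for uninterrupted gliding at the programmed
#'   speed.
#' @param blob_sd_px Gaussian blob SD (px).
#' @param blob_amplitude,background Peak blob intensity and background
#'   level.
#' @param htr_jitter_px,htr_duration_s Jitter amplitude (px) and event
#'   duration (s).
#' @param noise_sd Additive per-pixel sensor noise SD (0 disables).
#' @param seed Integer seed, or `NULL`.
#' @return A `behavior_video`: `frames` (height x width x frames), `fps`,
#'   `truth_speed` (px/s per frame), `htr_times_s`, `switch_time_s`
#'   (`NA` for control), and the generator parameters.
#' @export
simulate_behavior_video <- function(duration_s = 2400, fps = 30,
                                    shape = c(64, 64),
                                    profile = behavior_profile_control(),
                                    htr_profile = NULL,
                                    bout_mean_on_s = 2,
                                    bout_mean_off_s = 2,
                                    blob_sd_px = max(2, min(shape) / 20),
                                    blob_amplitude = 1, background = 0.1,
                                    htr_jitter_px = 2 * blob_sd_px,
                                    htr_duration_s = 0.15,
                                    noise_sd = 0, seed = NULL) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(fps, "fps", positive = TRUE)
  h <- shape[1]; w <- shape[2]
  n_frames <- round(duration_s * fps)
  t_s <- (seq_len(n_frames) - 1) / fps

  truth_speed <- switch(profile$type,
    control = rep(profile$speed, n_frames),
    hypoactive = ifelse(t_s < profile$switch_time_s, profile$speed_pre,
                        profile$speed_post),
    stop("unknown speed profile"))

  sim <- with_local_seed(seed, {
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n_frames - 1, 0, 0.3)))
    moving <- rep(TRUE, n_frames)
    if (bout_mean_off_s > 0) {
      t_edge <- 0; state <- stats::runif(1) <
        bout_mean_on_s / (bout_mean_on_s + bout_mean_off_s)
      moving <- logical(n_frames)
      while (t_edge < duration_s) {
        len <- stats::rexp(1, 1 / (if (state) bout_mean_on_s else
                                     bout_mean_off_s))
        idx <- which(t_s >= t_edge & t_s < t_edge + len)
        moving[idx] <- state
        t_edge <- t_edge + len
        state <- !state
      }
    }
    step <- truth_speed / fps * moving
    margin <- 3 * blob_sd_px
    cx <- reflect_into(w / 2 + cumsum(step * cos(heading)), margin,
                       w - margin)
    cy <- reflect_into(h / 2 + cumsum(step * sin(heading)), margin,
                       h - margin)
    htr_times <- if (is.null(htr_profile)) numeric(0) else
      draw_htr_times(htr_profile, duration_s)
    jitter <- numeric(n_frames)
    for (ev in htr_times) {
      idx <- which(t_s >= ev & t_s < ev + htr_duration_s)
      jitter[idx] <- htr_jitter_px * (-1)^(seq_along(idx))
    }
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(h * w * n_frames, sd = noise_sd), h * w, n_frames)
    else NULL
    list(cx = cx + jitter, cy = cy, htr_times = htr_times, noise = noise)
  })

  # separable rendering: frame = gy %o% gx, expanded over all frames at once
  two_s2 <- 2 * blob_sd_px^2
  gx <- exp(-(outer(seq_len(w), sim$cx, "-"))^2 / two_s2)  # w x frames
  gy <- exp(-(outer(seq_len(h), sim$cy, "-"))^2 / two_s2)  # h x frames
  flat <- background +
    blob_amplitude * gy[rep(seq_len(h), w), ] * gx[rep(seq_len(w), each = h), ]
  if (!is.null(sim$noise)) flat <- flat + sim$noise
  flat[flat < 0] <- 0

  structure(
    list(frames = array(flat, c(h, w, n_frames)), fps = fps,
         truth_speed = truth_speed, htr_times_s = sim$htr_times,
         switch_time_s = if (profile$type == "hypoactive")
           profile$switch_time_s else NA_real_,
         profile = profile, htr_profile = htr_profile,
         blob_sd_px = blob_sd_px, seed = seed),
    class = "behavior_video"
  )
}

#' Write / read head-twitch event times as CSV (column `t_s`)
#' @param times_s Numeric event times (s).
#' @param path CSV path.
#' @export
write_htr_csv <- function(times_s, path) {
  utils::write.csv(data.frame(t_s = times_s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_htr_csv
#' @export
read_htr_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"t_s" %in% names(df)) stop("HTR CSV must have column t_s")
  df$t_s
}
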