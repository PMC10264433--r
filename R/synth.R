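# Synthetic bipolar-forceps force recordings.
#
# A recording alternates idle (OFF) gaps, where both prongs read only sensor
# noise, with active (ON) force segments drawn from a five-task vocabulary.
# Per-task duration laws are lognormal, moment-matched to operating-room
# duration statistics; Coagulation segments average 12.1 s (SD 7.2 s),
# roughly 58% longer than the other tasks.

TASKS <- c("Coagulation", "Manipulating", "Pulling", "Retracting", "Dissecting")
SKILLS <- c("Expert", "Novice")

#' Configuration of the synthetic force-recording generator
#'
#' Defaults encode the operating-room dataset statistics the generator is
#' calibrated to: the task mix is the normalized published segment census
#' (1170/323/316/149/127), Coagulation durations average 12.1 s with SD
#' 7.2 s, and the remaining tasks average 12.1/1.58 ~= 7.66 s so that
#' Coagulation runs ~58% longer. Skill effects perturb the force waveform
#' only -- never segment durations -- so Expert and Novice duration
#' distributions coincide by construction.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param recording_minutes Length of a generated recording, minutes.
#' @param task_mix Named probabilities over the five tasks; must sum to 1.
#' @param duration_params Named list per task: `c(mean, sd)` of segment
#'   duration in seconds (arithmetic moments of the lognormal law).
#' @param amplitude_params Named list per task: `c(lo, hi)` force plateau
#'   range in newtons.
#' @param off_noise_sd Sensor noise SD (N) during idle periods.
#' @param off_gap_mean_s Mean idle-gap length, seconds (exponential law).
#' @param prong_correlation Target Pearson correlation between the left and
#'   right prong forces within a segment, in [0, 1]; 1 makes the channels
#'   identical.
#' @param skill_effects Per-skill list of `variance_multiplier`,
#'   `broadband_noise_sd` (N) and `transient_rate` (events/s).
#' @param seed Default seed used by generators when none is supplied.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 20,
                         recording_minutes = 10,
                         task_mix = c(Coagulation = 1170, Manipulating = 323,
                                      Pulling = 316, Retracting = 149,
                                      Dissecting = 127) / 2085,
                         duration_params = list(
                           Coagulation  = c(mean = 12.1, sd = 7.2),
                           Manipulating = c(mean = 12.1 / 1.58, sd = 4.0),
                           Pulling      = c(mean = 12.1 / 1.58, sd = 4.0),
                           Retracting   = c(mean = 12.1 / 1.58, sd = 4.0),
                           Dissecting   = c(mean = 12.1 / 1.58, sd = 4.0)),
                         amplitude_params = list(
                           Coagulation  = c(0.8, 2.5),
                           Manipulating = c(0.2, 1.0),
                           Pulling      = c(0.5, 2.0),
                           Retracting   = c(0.4, 1.5),
                           Dissecting   = c(0.5, 2.0)),
                         off_noise_sd = 0.02,
                         off_gap_mean_s = 8,
                         prong_correlation = 0.9,
                         skill_effects = list(
                           Expert = list(variance_multiplier = 1,
                                         broadband_noise_sd = 0,
                                         transient_rate = 0),
                           Novice = list(variance_multiplier = 1.35,
                                         broadband_noise_sd = 0.04,
                                         transient_rate = 0.25)),
                         seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate,
              recording_minutes = recording_minutes,
              task_mix = task_mix,
              duration_params = duration_params,
              amplitude_params = amplitude_params,
              off_noise_sd = off_noise_sd,
              off_gap_mean_s = off_gap_mean_s,
              prong_correlation = prong_correlation,
              skill_effects = skill_effects,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (!setequal(names(cfg$task_mix), TASKS))
    stop_labeled("config_error", "task_mix must name exactly the five tasks")
  if (abs(sum(cfg$task_mix) - 1) > 1e-9)
    stop_labeled("config_error", "task_mix must sum to 1 (got %.12f)",
                 sum(cfg$task_mix))
  for (tk in TASKS) {
    dp <- cfg$duration_params[[tk]]
    if (is.null(dp) || dp[["mean"]] <= 0 || dp[["sd"]] < 0)
      stop_labeled("config_error",
                   "duration_params[%s] needs mean > 0 and sd >= 0", tk)
    ap <- cfg$amplitude_params[[tk]]
    if (is.null(ap) || any(ap <= 0) || ap[2] < ap[1])
      stop_labeled("config_error", "amplitude_params[%s] invalid", tk)
  }
  if (cfg$off_noise_sd < 0 || cfg$off_gap_mean_s <= 0)
    stop_labeled("config_error", "off-noise SD and gap mean must be valid")
  if (cfg$prong_correlation < 0 || cfg$prong_correlation > 1)
    stop_labeled("config_error", "prong_correlation must lie in [0, 1]")
  invisible(cfg)
}

# lognormal (mu, sigma) with prescribed arithmetic mean m and SD s
lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Sample force-segment durations for one task
#'
#' Durations are i.i.d. lognormal with arithmetic mean and SD set by the
#' configuration (analytic moment matching), then clipped to at least 1 s.
#' A configured SD of 0 degenerates to the constant mean.
#'
#' @param task One of the five task labels.
#' @param n Number of draws.
#' @param config A [synth_config()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of durations, seconds.
#' @export
sample_segment_duration <- function(task, n, config = synth_config(),
                                    seed = NULL) {
  if (!task %in% TASKS)
    stop_labeled("unknown_task", "unknown task label '%s'", task)
  stopifnot(is_count(n))
  dp <- config$duration_params[[task]]
  with_seed(seed, {
    if (dp[["sd"]] == 0) {
      rep(max(dp[["mean"]], 1), n)
    } else {
      lp <- lognormal_params(dp[["mean"]], dp[["sd"]])
      pmax(stats::rlnorm(n, lp$mu, lp$sigma), 1)
    }
  })
}

# Smooth taper used at segment boundaries (raised cosine over m samples).
edge_taper <- function(n, frac = 0.15, min_ramp = 2L) {
  m <- max(min_ramp, round(n * frac))
  m <- min(m, floor(n / 2))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  env[seq_len(m)] <- ramp
  env[n + 1 - seq_len(m)] <- ramp
  env
}

# low-pass filtered gaussian noise via moving-average smoothing
smooth_noise <- function(n, width) {
  z <- stats::rnorm(n + width)
  stats::filter(z, rep(1 / width, width), sides = 2)[
    seq.int(width %/% 2 + 1, length.out = n)]
}

#' Synthesize the per-task force waveform of one segment
#'
#' Each task has a characteristic shape: Coagulation is a smooth
#' rise/plateau/fall grasp carrying a low-amplitude 8-9.5 Hz tremor;
#' Pulling ramps and holds; Retracting is a long low-variance hold;
#' Dissecting is a series of short spiky bursts; Manipulating wanders
#' irregularly at low force. The two prongs share the common waveform plus
#' independent noise scaled so their Pearson correlation approaches
#' `prong_correlation` (1 yields identical channels). Forces are
#' non-negative.
#'
#' @param task Task label.
#' @param n_points Segment length in samples (>= 20).
#' @param amplitude Plateau force, newtons.
#' @param config A [synth_config()] (sampling rate, prong correlation).
#' @param seed Optional seed.
#' @return `n_points` x 2 matrix (left, right prong force in N).
#' @export
synth_task_waveform <- function(task, n_points, amplitude,
                                config = synth_config(), seed = NULL) {
  if (!task %in% TASKS)
    stop_labeled("unknown_task", "unknown task label '%s'", task)
  if (!is_count(n_points, 20L))
    stop_labeled("segment_too_short", "n_points must be >= 20")
  fs <- config$sampling_rate
  with_seed(seed, {
    t_s <- (seq_len(n_points) - 1) / fs
    base <- switch(task,
      Coagulation = {
        f_trem <- stats::runif(1, 8, 9.5)       # below the 10 Hz Nyquist
        plateau <- amplitude *
          (1 + 0.04 * sin(2 * pi * f_trem * t_s + stats::runif(1, 0, 2 * pi)))
        plateau * edge_taper(n_points, 0.15)
      },
      Pulling = {
        ramp_n <- max(2L, round(0.3 * n_points))
        env <- c(seq(0, 1, length.out = ramp_n),
                 rep(1, n_points - ramp_n))
        amplitude * env * edge_taper(n_points, 0.05)
      },
      Retracting = {
        slow <- 1 + 0.03 * sin(2 * pi * 0.1 * t_s + stats::runif(1, 0, 2 * pi))
        amplitude * slow * edge_taper(n_points, 0.08)
      },
      Dissecting = {
        x <- rep(0.15 * amplitude, n_points)
        n_bursts <- max(1L, stats::rpois(1, n_points / 30))
        for (b in seq_len(n_bursts)) {
          w <- sample(3:8, 1)
          at <- sample.int(max(1L, n_points - w), 1)
          bump <- amplitude * stats::runif(1, 0.6, 1) *
            sin(pi * seq_len(w) / (w + 1))
          idx <- at:(at + w - 1)
          x[idx] <- pmax(x[idx], bump)
        }
        x * edge_taper(n_points, 0.05)
      },
      Manipulating = {
        w <- smooth_noise(n_points, max(5L, round(fs / 2)))
        w <- w - min(w)
        if (max(w) > 0) w <- w / max(w)
        amplitude * (0.2 + 0.6 * w) * edge_taper(n_points, 0.05)
      })
    rho <- config$prong_correlation
    if (rho >= 1) {
      left <- right <- base
    } else {
      # cor(base + e, base + e') = var(base) / (var(base) + sd_e^2)
      sd_e <- stats::sd(base) * sqrt((1 - rho) / max(rho, 1e-6))
      left <- base + stats::rnorm(n_points, 0, sd_e)
      right <- base + stats::rnorm(n_points, 0, sd_e)
    }
    cbind(left = pmax(left, 0), right = pmax(right, 0))
  })
}

#' Apply skill-dependent perturbations to a segment trace
#'
#' Novice traces receive a variance multiplier about the channel mean, added
#' broadband noise, and randomly-placed short force transients; Expert traces
#' pass through unchanged under the default effect sizes. Durations are never
#' altered: the output has exactly the input's number of samples.
#'
#' @param trace n x 2 force matrix (N).
#' @param skill `"Expert"` or `"Novice"`.
#' @param effects Per-skill effect list (see [synth_config()]).
#' @param fs Sampling rate, Hz.
#' @param seed Optional seed.
#' @return Perturbed n x 2 force matrix.
#' @export
apply_skill_effects <- function(trace, skill,
                                effects = synth_config()$skill_effects,
                                fs = 20, seed = NULL) {
  if (!skill %in% SKILLS)
    stop_labeled("unknown_skill", "skill must be Expert or Novice")
  ef <- effects[[skill]]
  n <- nrow(trace)
  with_seed(seed, {
    out <- trace
    if (ef$variance_multiplier != 1) {
      for (j in 1:2) {
        m <- mean(out[, j])
        out[, j] <- m + (out[, j] - m) * sqrt(ef$variance_multiplier)
      }
    }
    if (ef$broadband_noise_sd > 0)
      out <- out + matrix(stats::rnorm(2 * n, 0, ef$broadband_noise_sd), n, 2)
    if (ef$transient_rate > 0) {
      k <- stats::rpois(1, ef$transient_rate * n / fs)
      for (i in seq_len(k)) {
        w <- sample(3:7, 1)
        at <- sample.int(max(1L, n - w), 1)
        bump <- stats::runif(1, 0.2, 0.6) * sin(pi * seq_len(w) / (w + 1))
        out[at:(at + w - 1), ] <- out[at:(at + w - 1), ] + bump
      }
    }
    pmax(out, 0)
  })
}

new_force_segment <- function(trace, task, skill, surgeon_id,
                              start_idx = NA_integer_, end_idx = NA_integer_,
                              fs = 20) {
  structure(list(left = trace[, 1], right = trace[, 2], task = task,
                 skill = skill, surgeon_id = surgeon_id,
                 start_idx = start_idx, end_idx = end_idx, fs = fs),
            class = "force_segment")
}

#' @export
print.force_segment <- function(x, ...) {
  cat(sprintf("<force_segment> %s / %s, %d samples (%.1f s at %g Hz)\n",
              x$task, x$skill, length(x$left), length(x$left) / x$fs, x$fs))
  invisible(x)
}

# draw one ON segment's metadata + trace
draw_segment <- function(config, task = NULL, skill = NULL,
                         surgeon_id = NULL) {
  if (is.null(task))
    task <- sample(TASKS, 1, prob = config$task_mix[TASKS])
  if (is.null(skill)) skill <- sample(SKILLS, 1)
  dur <- sample_segment_duration(task, 1, config)
  n <- max(20L, round(dur * config$sampling_rate))
  amp <- stats::runif(1, config$amplitude_params[[task]][1],
                      config$amplitude_params[[task]][2])
  tr <- synth_task_waveform(task, n, amp, config)
  tr <- apply_skill_effects(tr, skill, config$skill_effects,
                            config$sampling_rate)
  new_force_segment(tr, task, skill,
                    surgeon_id %||% paste0("S", match(skill, SKILLS)),
                    fs = config$sampling_rate)
}

#' Generate a full synthetic force recording with ground truth
#'
#' Alternates exponential-length idle gaps (near-zero force plus sensor
#' noise) with ON segments drawn from the configured task mix, until the
#' requested duration is filled. Reproducible: identical (config, seed)
#' yield bit-identical output.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param skill Optional fixed skill for the whole recording; default samples
#'   a skill per segment.
#' @param surgeon_id Identifier recorded in the ground-truth segment table.
#' @return A list with `recording` (a `force_recording`, see
#'   [force_recording()]) and `truth` (point labels + segment table, class
#'   `ground_truth`).
#' @export
generate_recording <- function(config = synth_config(), seed = config$seed,
                               skill = NULL, surgeon_id = "S01") {
  fs <- config$sampling_rate
  n_total <- round(config$recording_minutes * 60 * fs)
  with_seed(seed, {
    left <- right <- numeric(n_total)
    labels <- integer(n_total)           # 0 = OFF, 1 = ON
    segs <- list()
    pos <- 0L
    repeat {
      gap <- max(1L, round(stats::rexp(1, 1 / config$off_gap_mean_s) * fs))
      pos_after_gap <- pos + gap
      seg <- draw_segment(config, skill = skill, surgeon_id = surgeon_id)
      n_seg <- length(seg$left)
      if (pos_after_gap + n_seg > n_total) break
      idx <- (pos_after_gap + 1):(pos_after_gap + n_seg)
      left[idx] <- seg$left
      right[idx] <- seg$right
      labels[idx] <- 1L
      seg$start_idx <- pos_after_gap        # 0-based, half-open
      seg$end_idx <- pos_after_gap + n_seg
      segs[[length(segs) + 1L]] <- seg
      pos <- pos_after_gap + n_seg
    }
    if (length(segs) == 0L)
      stop_labeled("recording_too_short",
                   "recording of %.1f min cannot fit one segment",
                   config$recording_minutes)
    if (config$off_noise_sd > 0) {
      off <- labels == 0L
      left[off] <- pmax(stats::rnorm(sum(off), 0, config$off_noise_sd), 0)
      right[off] <- pmax(stats::rnorm(sum(off), 0, config$off_noise_sd), 0)
    }
    rec <- force_recording(left, right, fs = fs,
                           label = ifelse(labels == 1L, "ON", "OFF"))
    truth <- structure(
      list(point_labels = ifelse(labels == 1L, "ON", "OFF"),
           segments = data.frame(
             segment_id = seq_along(segs),
             start_idx = vapply(segs, `[[`, 0, "start_idx"),
             end_idx = vapply(segs, `[[`, 0, "end_idx"),
             task = vapply(segs, `[[`, "", "task"),
             skill = vapply(segs, `[[`, "", "skill"),
             surgeon_id = vapply(segs, `[[`, "", "surgeon_id"))),
      class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Generate a labeled dataset of force segments
#'
#' Draws `n_segments` independent ON segments from the configured task mix.
#' Skill labels are balanced by construction (|Novice - Expert| <= 1) unless
#' `skill_balance = FALSE`, in which case skills are sampled uniformly.
#' The manifest records the configuration hash, seed and class census.
#'
#' @param config A [synth_config()].
#' @param n_segments Number of segments.
#' @param seed Integer seed.
#' @param skill_balance Balance skill labels exactly (default TRUE).
#' @param tasks Optional fixed task label(s) recycled over segments,
#'   bypassing the task mix (used for calibration studies).
#' @return List with `segments` (list of `force_segment`) and `manifest`.
#' @export
generate_dataset <- function(config = synth_config(), n_segments, seed = config$seed,
                             skill_balance = TRUE, tasks = NULL) {
  stopifnot(is_count(n_segments))
  with_seed(seed, {
    skills <- if (skill_balance) {
      sample(rep_len(SKILLS, n_segments))
    } else sample(SKILLS, n_segments, replace = TRUE)
    task_vec <- if (is.null(tasks)) {
      sample(TASKS, n_segments, replace = TRUE, prob = config$task_mix[TASKS])
    } else rep_len(tasks, n_segments)
    segs <- vector("list", n_segments)
    for (i in seq_len(n_segments))
      segs[[i]] <- draw_segment(config, task = task_vec[i], skill = skills[i],
                                surgeon_id = sprintf("S%02d", 1L + (i %% 8L)))
    manifest <- dataset_manifest(segs, config, seed)
    list(segments = segs, manifest = manifest)
  })
}

#' @rdname generate_dataset
#' @param segments List of `force_segment` objects.
#' @export
dataset_manifest <- function(segments, config, seed) {
  task <- vapply(segments, `[[`, "", "task")
  skill <- vapply(segments, `[[`, "", "skill")
  list(schema_version = "1.0",
       n_recordings = 0L,
       n_segments = length(segments),
       class_counts = list(
         task = as.list(table(factor(task, TASKS))),
         skill = as.list(table(factor(skill, SKILLS)))),
       config_hash = config_hash(config),
       seed = as.integer(seed))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2)  # scratch file only
  unname(tools::md5sum(f))
}
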