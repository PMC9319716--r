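#' Gait profile for the synthetic insole-recording generator
#'
#' A profile fixes how one limb loads the insole: the stance duration, the
#' per-limb step rate, the fraction of the peak body force routed to the
#' hindfoot / midfoot / forefoot loading centers, and an asymmetry factor.
#' The patterns mirror the sagittal gait patterns commonly described in
#' spastic cerebral palsy:
#'
#' * `typical`: balanced heel-to-toe loading;
#' * `true_equinus`: plantarflexed ankle, forefoot-dominant loading with a
#'   suppressed heel (hindfoot weight strictly below forefoot weight);
#' * `drop_foot`: reduced heel-strike loading in swing-to-stance
#'   transition;
#' * `apparent_equinus`: toe-walking appearance with moderately reduced
#'   heel loading.
#'
#' @param pattern one of `"typical"`, `"true_equinus"`, `"drop_foot"`,
#'   `"apparent_equinus"`.
#' @param stance_duration stance-phase duration in seconds (> 0).
#' @param cadence per-limb step rate in steps/minute (> 0); the stance must
#'   fit inside the step period `60 / cadence`.
#' @param regional_load_weights length-3 non-negative vector (hindfoot,
#'   midfoot, forefoot) of body-force fractions; defaults depend on the
#'   pattern.
#' @param peak_body_force peak vertical force in N (default 170, a child of
#'   about 18 kg).
#' @param asymmetry_factor unitless overall scaling between limbs.
#' @return an object of class `gait_profile`.
#' @examples
#' gait_profile("true_equinus")
#' @export
gait_profile <- function(pattern = c("typical", "true_equinus", "drop_foot",
                                     "apparent_equinus"),
                         stance_duration = 0.67, cadence = 40,
                         regional_load_weights = NULL,
                         peak_body_force = 170, asymmetry_factor = 1) {
  pattern <- match.arg(pattern)
  if (is.null(regional_load_weights)) {
    regional_load_weights <- switch(pattern,
      typical          = c(0.40, 0.20, 0.40),
      true_equinus     = c(0.15, 0.20, 0.65),
      drop_foot        = c(0.28, 0.22, 0.50),
      apparent_equinus = c(0.22, 0.23, 0.55))
  }
  w <- as.numeric(regional_load_weights)
  if (length(w) != 3L || any(w < 0)) {
    stop("'regional_load_weights' must be 3 non-negative values (hindfoot, midfoot, forefoot)",
         call. = FALSE)
  }
  if (pattern == "true_equinus" && !(w[1L] < w[3L])) {
    stop("true_equinus requires hindfoot weight strictly below forefoot weight",
         call. = FALSE)
  }
  check_scalar(stance_duration, "stance_duration", lower = 0, strict_lower = TRUE)
  check_scalar(cadence, "cadence", lower = 0, strict_lower = TRUE)
  if (stance_duration >= 60 / cadence) {
    stop("stance_duration must be shorter than the step period 60/cadence",
         call. = FALSE)
  }
  check_scalar(peak_body_force, "peak_body_force", lower = 0, strict_lower = TRUE)
  check_scalar(asymmetry_factor, "asymmetry_factor", lower = 0, strict_lower = TRUE)
  structure(list(pattern = pattern, stance_duration = stance_duration,
                 cadence = cadence, regional_load_weights = w,
                 peak_body_force = peak_body_force,
                 asymmetry_factor = asymmetry_factor),
            class = "gait_profile")
}

#' Variance components of the two-way test-retest model
#'
#' The model behind the paired-measurements generator:
#' `X[i, j] = mu + r_i + c_j + e_ij` with independent normal components
#' `r_i ~ N(0, sigma_r^2)` (stable limb trait), `c_j ~ N(0, sigma_c^2)`
#' (session effect) and `e_ij ~ N(0, sigma_e^2)` (residual).
#'
#' @param mu mean on the variable's scale.
#' @param sigma_r,sigma_c,sigma_e non-negative SDs of the limb, session and
#'   residual components.
#' @param n_units number of limbs (>= 2; default 16, i.e. both limbs of
#'   eight participants).
#' @param k_sessions number of sessions (>= 2; default 2).
#' @return an object of class `variance_components`.
#' @seealso [theoretical_icc()], [simulate_paired_measurements()]
#' @export
variance_components <- function(mu, sigma_r, sigma_c, sigma_e,
                                n_units = 16L, k_sessions = 2L) {
  check_scalar(mu, "mu")
  check_scalar(sigma_r, "sigma_r", lower = 0)
  check_scalar(sigma_c, "sigma_c", lower = 0)
  check_scalar(sigma_e, "sigma_e", lower = 0)
  n_units <- as.integer(n_units); k_sessions <- as.integer(k_sessions)
  if (n_units < 2L) stop("'n_units' must be >= 2", call. = FALSE)
  if (k_sessions < 2L) stop("'k_sessions' must be >= 2", call. = FALSE)
  structure(list(mu = mu, sigma_r = sigma_r, sigma_c = sigma_c,
                 sigma_e = sigma_e, n_units = n_units,
                 k_sessions = k_sessions),
            class = "variance_components")
}

#' Population (closed-form) average-measures agreement ICC
#'
#' `ICC(A,k) = sigma_r^2 / (sigma_r^2 + (sigma_c^2 + sigma_e^2) / k)`,
#' the reliability of the mean of `k` sessions under the two-way model.
#'
#' @param vc a [variance_components()] object.
#' @return the population ICC in `[0, 1]` (0 when all SDs are zero).
#' @export
theoretical_icc <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$sigma_r^2 + (vc$sigma_c^2 + vc$sigma_e^2) / vc$k_sessions
  if (denom == 0) return(0)
  vc$sigma_r^2 / denom
}

#' Simulate a paired-measurements matrix from variance components
#'
#' @param vc a [variance_components()] object.
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @param variable,region optional labels for the result.
#' @return a [paired_measurements()] matrix (`n_units x k_sessions`).
#' @examples
#' vc <- variance_components(5, 0, 0, 0, n_units = 4, k_sessions = 2)
#' simulate_paired_measurements(vc, seed = 1)
#' @export
simulate_paired_measurements <- function(vc, seed,
                                         variable = NA_character_,
                                         region = NA_character_) {
  stopifnot(inherits(vc, "variance_components"))
  set.seed(derive_seed(seed, "paired_measurements"))
  n <- vc$n_units; k <- vc$k_sessions
  r <- stats::rnorm(n, 0, vc$sigma_r)
  cj <- stats::rnorm(k, 0, vc$sigma_c)
  e <- matrix(stats::rnorm(n * k, 0, vc$sigma_e), nrow = n)
  x <- vc$mu + outer(r, rep(1, k)) + outer(rep(1, n), cj) + e
  paired_measurements(x, variable = variable, region = region)
}

# raised-cosine activation envelope on the stance-fraction span [a, b]
raised_cosine <- function(tau, a, b) {
  env <- numeric(length(tau))
  inside <- tau >= a & tau <= b
  env[inside] <- 0.5 * (1 - cos(2 * pi * (tau[inside] - a) / (b - a)))
  env
}

# spatial Gaussian blob over grid cells, centered at a length fraction;
# returns a vector over cells, max ~1 at the blob center
blob_gaussian <- function(grid, center_frac, sigma_long = 0.07, sigma_lat = 0.18) {
  rows_f <- grid$row_centroid_fraction[grid_cell_rows(grid)]
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  cols_f <- (cols - 0.5) / grid$n_cols
  exp(-((rows_f - center_frac)^2 / (2 * sigma_long^2) +
          (cols_f - 0.5)^2 / (2 * sigma_lat^2)))
}

# temporal envelope spans (fractions of stance) for the three loading centers
envelope_spans <- function() {
  list(hindfoot = c(0.00, 0.55), midfoot = c(0.15, 0.80), forefoot = c(0.35, 1.00))
}
blob_centers <- function() c(hindfoot = 0.15, midfoot = 0.45, forefoot = 0.80)

#' Simulate an insole recording for one limb and session
#'
#' Renders each stance phase as the sum of three spatial Gaussian pressure
#' blobs (hindfoot / midfoot / forefoot loading centers at 15%, 45% and
#' 80% of the insole length), each modulated by a raised-cosine temporal
#' envelope ordered heel-early to forefoot-late.  Blob amplitudes are
#' scaled so that the regional peak force equals the profile's regional
#' load weight times the peak body force.  Steps are separated by swing
#' intervals carrying only a uniform sensor-noise floor (below the cell
#' activation threshold by construction).
#'
#' @param profile a [gait_profile()].
#' @param grid a [sensor_grid()].
#' @param n_steps number of steps to render (>= 1).
#' @param session_effects optional list with `weight_multipliers`
#'   (length 3), `force_multiplier`, `stance_multiplier`; the hook used by
#'   [simulate_cohort()] to impose between-session variation.
#' @param seed integer seed; fully determines the output.
#' @param noise_floor upper bound (kPa) of the uniform swing-phase sensor
#'   noise (default 1; set 0 for a noiseless recording).
#' @param step_noise_sd log-scale SD of per-step amplitude jitter.
#' @param timing_jitter_sd SD of per-step onset jitter, as a fraction of
#'   the step period.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param participant,limb,session metadata passed to
#'   [insole_recording()].
#' @return an [insole_recording()]; the programmed stance intervals and
#'   rendering parameters are attached as attribute `ground_truth`.
#' @examples
#' rec <- simulate_recording(gait_profile("typical"), n_steps = 3, seed = 1)
#' nrow(detect_steps(rec))
#' @export
simulate_recording <- function(profile, grid = sensor_grid(), n_steps = 15,
                               session_effects = NULL, seed = 1,
                               noise_floor = 1, step_noise_sd = 0.02,
                               timing_jitter_sd = 0.02, sampling_rate = 100,
                               participant = "P01", limb = "L", session = 1L) {
  stopifnot(inherits(profile, "gait_profile"), inherits(grid, "sensor_grid"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  check_scalar(noise_floor, "noise_floor", lower = 0)
  se <- list(weight_multipliers = c(1, 1, 1), force_multiplier = 1,
             stance_multiplier = 1)
  if (!is.null(session_effects)) se[names(session_effects)] <- session_effects

  set.seed(derive_seed(seed, "recording", participant, limb, session))
  rate <- sampling_rate
  dt <- 1 / rate
  pad <- 0.3
  stride <- 60 / profile$cadence
  stance <- profile$stance_duration * se$stance_multiplier
  if (stance >= stride - 0.1) {
    stop("effective stance duration leaves no swing interval", call. = FALSE)
  }
  weights <- profile$regional_load_weights * se$weight_multipliers
  force_scale <- profile$peak_body_force * profile$asymmetry_factor *
    se$force_multiplier

  n_frames <- ceiling((2 * pad + n_steps * stride) * rate)
  n_cells <- grid_n_cells(grid)
  frames <- matrix(stats::runif(n_frames * n_cells, 0, noise_floor),
                   nrow = n_frames)

  centers <- blob_centers()
  spans <- envelope_spans()
  blobs <- lapply(centers, function(cf) blob_gaussian(grid, cf))
  blob_sums <- vapply(blobs, sum, numeric(1))

  intervals <- data.frame(step = seq_len(n_steps),
                          frame_start = NA_integer_, frame_end = NA_integer_)
  for (s in seq_len(n_steps)) {
    onset <- pad + (s - 1L) * stride +
      clamp(stats::rnorm(1, 0, timing_jitter_sd * stride),
            -0.2 * stride, 0.2 * stride)
    amp_jit <- exp(stats::rnorm(3, 0, step_noise_sd))
    i0 <- floor(onset * rate) + 1L
    i1 <- min(floor((onset + stance) * rate) + 1L, n_frames)
    idx <- i0:i1
    tau <- ((idx - 1L) * dt - onset) / stance
    for (r in seq_along(centers)) {
      amp <- weights[r] * amp_jit[r] * force_scale /
        (0.1 * grid$cell_area * blob_sums[[r]])
      env <- raised_cosine(tau, spans[[r]][1L], spans[[r]][2L])
      frames[idx, ] <- frames[idx, ] + amp * outer(env, blobs[[r]])
    }
    intervals$frame_start[s] <- i0
    intervals$frame_end[s] <- i1 + 1L     # half-open
  }

  rec <- insole_recording(grid = grid, frames = frames, sampling_rate = rate,
                          participant = participant, limb = limb,
                          session = session)
  attr(rec, "ground_truth") <- list(step_intervals = intervals,
                                    profile = profile,
                                    session_effects = se,
                                    noise_floor = noise_floor)
  rec
}

#' Corrupt selected steps of a recording into "amiss" footprints
#'
#' Three corruption modes are applied in rotation over the selected steps:
#'
#' * `truncated`: only the first 300 ms of the stance are kept;
#' * `partial`: only rows with centroid in `[0.65, 0.95)` stay loaded, as
#'   when just the forefoot lands on the insole;
#' * `low_force`: stance pressures are scaled to 15%, as in a grazing or
#'   turning contact.
#'
#' All modes remain detectable by [detect_steps()] at default thresholds
#' but are removed by [clean_footprints()] at default criteria, so the
#' returned step labels are a checkable ground truth for the cleaning
#' stage.  (Which criterion fires first for a given corrupted step depends
#' on the gait profile, because the cleaning measures are taken over the
#' force-thresholded detected interval; the contract is the removal set,
#' not the reason.)
#'
#' @param recording a recording from [simulate_recording()] (the
#'   `ground_truth` attribute is required).
#' @param n_amiss number of steps to corrupt (0 returns the input
#'   unchanged); must not exceed the step count.
#' @param seed integer seed for the selection.
#' @return a list with `recording` (modified) and `amiss`, a data.frame
#'   with columns `step` and `type`.
#' @export
inject_amiss_footprints <- function(recording, n_amiss, seed = 1) {
  stopifnot(inherits(recording, "insole_recording"))
  gt <- attr(recording, "ground_truth")
  if (is.null(gt)) {
    stop("recording has no ground_truth attribute (not from simulate_recording)",
         call. = FALSE)
  }
  n_steps <- nrow(gt$step_intervals)
  n_amiss <- as.integer(n_amiss)
  if (n_amiss < 0L) stop("'n_amiss' must be >= 0", call. = FALSE)
  if (n_amiss > n_steps) {
    stop(sprintf("'n_amiss' (%d) exceeds the step count (%d)", n_amiss, n_steps),
         call. = FALSE)
  }
  empty <- data.frame(step = integer(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (n_amiss == 0L) return(list(recording = recording, amiss = empty))

  set.seed(derive_seed(seed, "amiss", recording$participant,
                       recording$limb, recording$session))
  idx <- sort(sample.int(n_steps, n_amiss))
  types <- c("truncated", "partial", "low_force")[((seq_along(idx) - 1L) %% 3L) + 1L]
  rate <- recording$sampling_rate
  frames <- recording$frames
  nf <- rep(gt$noise_floor %||% 1, 1)
  cell_rows <- grid_cell_rows(recording$grid)
  row_f <- recording$grid$row_centroid_fraction

  for (a in seq_along(idx)) {
    s <- idx[a]
    i0 <- gt$step_intervals$frame_start[s]
    i1 <- gt$step_intervals$frame_end[s] - 1L
    if (types[a] == "truncated") {
      cut <- min(i0 + round(0.3 * rate), i1)
      kill <- (cut + 1L):i1
      if (length(kill) > 0L && kill[1L] <= i1) {
        frames[kill, ] <- stats::runif(length(kill) * ncol(frames), 0, nf)
      }
    } else if (types[a] == "partial") {
      keep_rows <- which(row_f >= 0.65 & row_f < 0.95)
      kill_cells <- which(!(cell_rows %in% keep_rows))
      frames[i0:i1, kill_cells] <- stats::runif(length(i0:i1) * length(kill_cells), 0, nf)
    } else {
      frames[i0:i1, ] <- frames[i0:i1, ] * 0.15
    }
  }
  out <- recording
  out$frames <- frames
  amiss <- data.frame(step = idx, type = types, stringsAsFactors = FALSE)
  gt$amiss <- amiss
  attr(out, "ground_truth") <- gt
  list(recording = out, amiss = amiss)
}

#' Configuration of a synthetic test-retest cohort
#'
#' Defaults emulate the study design the package targets: 8 children, both
#' limbs recorded (16 analysis units), two sessions 7-14 days apart, at
#' least 15 valid steps per limb, a mix of cerebral-palsy sagittal gait
#' patterns on the affected side(s), and a limb x session x step variance
#' structure (stable limb trait + common session effect + limb-session
#' interaction + per-step noise), all multiplicative on the log scale.
#'
#' @param n_participants number of participants (default 8).
#' @param n_steps number of valid steps per recording (default 15).
#' @param n_amiss number of additional corrupted steps injected per
#'   recording (default 2; rendered steps = `n_steps + n_amiss`).
#' @param grid a [sensor_grid()].
#' @param seed master seed; fully determines the cohort.
#' @param patterns character vector (recycled over participants) of
#'   affected-side gait patterns.
#' @param affected_side character vector (recycled), `"L"`, `"R"` or
#'   `"both"`; the unaffected limb of a unilateral participant walks with
#'   the `typical` profile.
#' @param sigma named list of log-scale SDs: `limb_weight`, `limb_force`,
#'   `limb_stance` (stable limb traits), `session_weight`, `session_force`,
#'   `session_stance` (day effects common to all limbs), `inter_weight`,
#'   `inter_force`, `inter_stance` (limb x session interaction).
#' @param noise_floor,step_noise_sd,timing_jitter_sd,sampling_rate passed
#'   to [simulate_recording()].
#' @param session_interval_days nominal days between sessions (metadata
#'   only).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 8L, n_steps = 15L, n_amiss = 2L,
                          grid = sensor_grid(), seed = 1L,
                          patterns = c("drop_foot", "true_equinus",
                                       "true_equinus", "apparent_equinus",
                                       "true_equinus", "true_equinus",
                                       "true_equinus", "true_equinus"),
                          affected_side = c("R", "L", "R", "both",
                                            "R", "R", "R", "R"),
                          sigma = list(limb_weight = 0.20, limb_force = 0.15,
                                       limb_stance = 0.06,
                                       session_weight = 0.03,
                                       session_force = 0.03,
                                       session_stance = 0.03,
                                       inter_weight = 0.05,
                                       inter_force = 0.04,
                                       inter_stance = 0.03),
                          noise_floor = 1, step_noise_sd = 0.02,
                          timing_jitter_sd = 0.02, sampling_rate = 100,
                          session_interval_days = 8) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("'n_participants' must be >= 1", call. = FALSE)
  stopifnot(inherits(grid, "sensor_grid"))
  defaults <- list(limb_weight = 0.20, limb_force = 0.15, limb_stance = 0.06,
                   session_weight = 0.03, session_force = 0.03,
                   session_stance = 0.03, inter_weight = 0.05,
                   inter_force = 0.04, inter_stance = 0.03)
  defaults[names(sigma)] <- sigma
  bad <- vapply(defaults, function(s) !is.numeric(s) || s < 0, logical(1))
  if (any(bad)) stop("all sigma components must be non-negative numbers", call. = FALSE)
  structure(list(
    n_participants = n_participants, n_steps = as.integer(n_steps),
    n_amiss = as.integer(n_amiss), grid = grid, seed = as.integer(seed),
    patterns = rep_len(patterns, n_participants),
    affected_side = rep_len(affected_side, n_participants),
    sigma = defaults, noise_floor = noise_floor,
    step_noise_sd = step_noise_sd, timing_jitter_sd = timing_jitter_sd,
    sampling_rate = sampling_rate,
    session_interval_days = session_interval_days
  ), class = "cohort_config")
}

# internal: lognormal multiplier(s) from a derived seed
ln_mult <- function(n, sd, seed) {
  set.seed(seed)
  exp(stats::rnorm(n, 0, sd))
}

#' Simulate a full test-retest cohort of insole recordings
#'
#' One recording per limb per session (default: 8 participants x 2 limbs x
#' 2 sessions = 32 recordings).  Each limb carries stable latent traits
#' (regional weight, overall force and stance-duration multipliers); each
#' session adds a common day effect plus a limb-session interaction; each
#' step adds small residual jitter.  The stance multiplier product is
#' clamped to `[0.85, 1.2]` (physiological bounds).  Per-recording amiss
#' steps are injected for the cleaning stage to find.
#'
#' @param config a [cohort_config()].
#' @return an object of class `insole_cohort`: a list with `recordings`
#'   (list of [insole_recording()]), `ground_truth` (latent multipliers per
#'   limb and session, amiss labels, programmed valid step count) and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sg <- config$sigma
  seed <- config$seed

  session_mult <- lapply(1:2, function(j) {
    list(weight = ln_mult(3, sg$session_weight, derive_seed(seed, "sess_w", j)),
         force = ln_mult(1, sg$session_force, derive_seed(seed, "sess_f", j)),
         stance = ln_mult(1, sg$session_stance, derive_seed(seed, "sess_s", j)))
  })

  recordings <- list()
  latent <- list()
  amiss_all <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    side <- config$affected_side[p]
    for (limb in c("L", "R")) {
      affected <- side == "both" || side == limb
      pattern <- if (affected) config$patterns[p] else "typical"
      profile <- gait_profile(pattern)
      limb_w <- ln_mult(3, sg$limb_weight, derive_seed(seed, "limb_w", pid, limb))
      limb_f <- ln_mult(1, sg$limb_force, derive_seed(seed, "limb_f", pid, limb))
      limb_s <- ln_mult(1, sg$limb_stance, derive_seed(seed, "limb_s", pid, limb))
      for (j in 1:2) {
        inter_w <- ln_mult(3, sg$inter_weight, derive_seed(seed, "int_w", pid, limb, j))
        inter_f <- ln_mult(1, sg$inter_force, derive_seed(seed, "int_f", pid, limb, j))
        inter_s <- ln_mult(1, sg$inter_stance, derive_seed(seed, "int_s", pid, limb, j))
        sm <- session_mult[[j]]
        eff <- list(
          weight_multipliers = limb_w * sm$weight * inter_w,
          force_multiplier = limb_f * sm$force * inter_f,
          stance_multiplier = clamp(limb_s * sm$stance * inter_s, 0.85, 1.2)
        )
        rec <- simulate_recording(
          profile, grid = config$grid,
          n_steps = config$n_steps + config$n_amiss,
          session_effects = eff,
          seed = derive_seed(seed, "rec", pid, limb, j),
          noise_floor = config$noise_floor,
          step_noise_sd = config$step_noise_sd,
          timing_jitter_sd = config$timing_jitter_sd,
          sampling_rate = config$sampling_rate,
          participant = pid, limb = limb, session = j)
        inj <- inject_amiss_footprints(rec, config$n_amiss,
                                       seed = derive_seed(seed, "inj", pid, limb, j))
        key <- sprintf("%s_%s_s%d", pid, limb, j)
        recordings[[key]] <- inj$recording
        latent[[key]] <- data.frame(
          participant = pid, limb = limb, session = j, pattern = pattern,
          force_multiplier = eff$force_multiplier,
          stance_multiplier = eff$stance_multiplier,
          weight_hindfoot = eff$weight_multipliers[1L],
          weight_midfoot = eff$weight_multipliers[2L],
          weight_forefoot = eff$weight_multipliers[3L],
          stringsAsFactors = FALSE)
        if (nrow(inj$amiss) > 0L) {
          amiss_all[[key]] <- cbind(data.frame(participant = pid, limb = limb,
                                               session = j), inj$amiss)
        }
      }
    }
  }
  ground_truth <- list(
    latent = do.call(rbind, c(latent, list(make.row.names = FALSE))),
    amiss = if (length(amiss_all) > 0L)
      do.call(rbind, c(amiss_all, list(make.row.names = FALSE))) else NULL,
    n_valid_steps = config$n_steps
  )
  structure(list(recordings = recordings, ground_truth = ground_truth,
                 config = config),
            class = "insole_cohort")
}

#' @export
print.insole_cohort <- function(x, ...) {
  cat(sprintf("<insole_cohort> %d recordings (%d participants x 2 limbs x 2 sessions), %d+%d steps each\n",
              length(x$recordings), x$config$n_participants,
              x$config$n_steps, x$config$n_amiss))
  invisible(x)
}
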