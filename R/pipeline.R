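#' Process every recording of a cohort into limb-session summaries
#'
#' @param cohort an `insole_cohort` from [simulate_cohort()], or a plain
#'   list of [insole_recording()] objects.
#' @param ... processing options passed to [summarize_limb_session()].
#' @return stacked long-format data.frame of limb-session means.
#' @export
process_cohort <- function(cohort, ...) {
  recs <- if (inherits(cohort, "insole_cohort")) cohort$recordings else cohort
  out <- lapply(recs, summarize_limb_session, ...)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# internal: latent (ground-truth) ICC per region x variable, computed by
# applying the same ANOVA/ICC machinery to the simulated latent multipliers
latent_icc_table <- function(cohort) {
  lat <- cohort$ground_truth$latent
  lat$unit <- paste(lat$participant, lat$limb, sep = ":")
  units <- sort(unique(lat$unit))
  pick <- function(col) {
    m <- matrix(NA_real_, nrow = length(units), ncol = 2L)
    for (j in 1:2) {
      sj <- lat[lat$session == j, ]
      m[, j] <- log(sj[[col]][match(units, sj$unit)])
    }
    m
  }
  latent_col <- c(whole = "force_multiplier", hindfoot = "weight_hindfoot",
                  midfoot = "weight_midfoot", forefoot = "weight_forefoot")
  out <- list()
  for (region in region_levels()) {
    amp <- pick(latent_col[[region]])
    if (region != "whole") {
      amp <- amp + pick("force_multiplier")   # log scale: regional x overall
    }
    tim <- pick("stance_multiplier")
    for (variable in variable_levels()) {
      m <- if (variable == "contact_time") tim else amp
      icc <- tryCatch(icc_absolute_agreement_averaged(two_way_mean_squares(m)),
                      error = function(e) NA_real_)
      out[[paste(region, variable)]] <- data.frame(
        region = region, variable = variable, latent_icc = icc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full simulate-process-reliability pipeline
#'
#' Simulates a cohort, extracts and cleans footprints, computes the
#' limb-session means of the six variables in the four regions, assembles
#' the 24-row reliability table, and compares the estimated ICCs with the
#' ICCs of the simulated latent limb-session multipliers (amplitude-scale
#' latents for the force/pressure/area variables, stance-duration latents
#' for contact time).  Deterministic given the seed in `config`.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory; when given, writes
#'   `summaries.csv`, `reliability.csv` + `reliability.json`,
#'   `icc_recovery.csv`, `ground_truth.json`, `config.yaml`, `run_log.txt`
#'   and (if `write_recordings`) one `.ppr` file per recording.
#' @param alpha type-I level for ICC confidence intervals.
#' @param processing named list of options for [summarize_limb_session()].
#' @param write_recordings write the simulated `.ppr` files (default
#'   FALSE).
#' @return invisibly, a list with `cohort`, `summaries`, `reliability`,
#'   `icc_recovery` (estimated vs latent ICC per region x variable) and
#'   `paths`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         alpha = 0.05, processing = list(),
                         write_recordings = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- stage("simulate", simulate_cohort(config))
  summaries <- stage("process",
                     do.call(process_cohort, c(list(cohort), processing)))
  reliability <- stage("reliability", reliability_table(summaries, alpha = alpha))
  recovery <- stage("recovery", {
    lat <- latent_icc_table(cohort)
    merged <- merge(reliability[, c("region", "variable", "icc")], lat,
                    by = c("region", "variable"), sort = FALSE)
    merged$delta <- merged$icc - merged$latent_icc
    merged
  })
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      summaries = file.path(out_dir, "summaries.csv"),
      reliability = file.path(out_dir, "reliability.csv"),
      recovery = file.path(out_dir, "icc_recovery.csv"),
      ground_truth = file.path(out_dir, "ground_truth.json"),
      config = file.path(out_dir, "config.yaml"),
      log = file.path(out_dir, "run_log.txt")
    )
    utils::write.csv(summaries, paths$summaries, row.names = FALSE)
    write_reliability_table(reliability, paths$reliability)
    utils::write.csv(recovery, paths$recovery, row.names = FALSE)
    jsonlite::write_json(cohort$ground_truth, paths$ground_truth,
                         dataframe = "rows", digits = NA, na = "null")
    write_pipeline_config(config, paths$config)
    steps <- unique(summaries[, c("participant", "limb", "session",
                                  "n_steps_retained")])
    log_lines <- c(
      sprintf("recordings: %d", length(cohort$recordings)),
      sprintf("steps retained per limb-session: %s",
              paste(steps$n_steps_retained, collapse = " ")),
      sprintf("amiss steps injected: %d",
              if (is.null(cohort$ground_truth$amiss)) 0L
              else nrow(cohort$ground_truth$amiss)),
      sprintf("ANOVA df per variable: rows %d, cols 1, error %d",
              nrow(steps) / 2 - 1, nrow(steps) / 2 - 1)
    )
    writeLines(log_lines, paths$log)
    if (write_recordings) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (key in names(cohort$recordings)) {
        write_recording(cohort$recordings[[key]],
                        file.path(rec_dir, paste0(key, ".ppr")))
      }
    }
  }
  invisible(list(cohort = cohort, summaries = summaries,
                 reliability = reliability, icc_recovery = recovery,
                 paths = paths))
}

#' Serialize a cohort configuration to YAML
#'
#' @param config a [cohort_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  lst <- unclass(config)
  lst$grid <- list(n_rows = config$grid$n_rows, n_cols = config$grid$n_cols,
                   cell_area = config$grid$cell_area,
                   insole_length = config$grid$insole_length)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' @param path path to a file written by [write_pipeline_config()].
#' @return a [cohort_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  grid <- do.call(sensor_grid, lst$grid)
  cohort_config(
    n_participants = lst$n_participants, n_steps = lst$n_steps,
    n_amiss = lst$n_amiss, grid = grid, seed = lst$seed,
    patterns = unlist(lst$patterns),
    affected_side = unlist(lst$affected_side), sigma = lst$sigma,
    noise_floor = lst$noise_floor, step_noise_sd = lst$step_noise_sd,
    timing_jitter_sd = lst$timing_jitter_sd,
    sampling_rate = lst$sampling_rate,
    session_interval_days = lst$session_interval_days
  )
}

#' Verify the SEM/MDC/LOA arithmetic of a published reliability table
#'
#' Reads a transcription of a published test-retest reliability table
#' (printed Mean, Mean_diff, SD_diff, LOA, SEM and MDC per region and
#' variable), recomputes SEM, MDC and both limits of agreement from the
#' printed Mean_diff and SD_diff, and reports the absolute deviation of
#' every recomputed cell from its printed value.  Published tables round
#' intermediates to 2 decimals, so deviations up to ~0.02 are expected
#' from rounding alone.
#'
#' The packaged fixture transcribes a published whole-foot plus three-zone
#' table (24 rows) from a test-retest study of pressure-insole gait
#' variables in children with cerebral palsy.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @param tolerance maximum absolute deviation to pass (default 0.02).
#' @return a data.frame with one row per table row and the per-cell
#'   deviations (`dev_sem`, `dev_mdc`, `dev_loa_low`, `dev_loa_high`),
#'   with attributes `pass` (logical) and `max_dev`.
#' @export
verify_published_table <- function(path = NULL, tolerance = 0.02) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_reliability_table.csv",
                        package = "pedreli")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("region", "variable", "mean", "mean_diff", "sd_diff",
              "loa_low", "loa_high", "sem", "mdc")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  sem_c <- sem_from_sd_diff(tab$sd_diff)
  mdc_c <- mdc_from_sem(sem_c)
  loa_low_c <- tab$mean_diff - 1.96 * tab$sd_diff
  loa_high_c <- tab$mean_diff + 1.96 * tab$sd_diff
  out <- data.frame(
    region = tab$region, variable = tab$variable,
    sem_recomputed = sem_c, mdc_recomputed = mdc_c,
    loa_low_recomputed = loa_low_c, loa_high_recomputed = loa_high_c,
    dev_sem = abs(sem_c - tab$sem),
    dev_mdc = abs(mdc_c - tab$mdc),
    dev_loa_low = abs(loa_low_c - tab$loa_low),
    dev_loa_high = abs(loa_high_c - tab$loa_high),
    stringsAsFactors = FALSE
  )
  devs <- as.matrix(out[, c("dev_sem", "dev_mdc", "dev_loa_low", "dev_loa_high")])
  out$pass <- apply(devs, 1L, max) <= tolerance
  attr(out, "max_dev") <- max(devs)
  attr(out, "pass") <- all(out$pass)
  out
}
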