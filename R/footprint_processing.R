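#' Build the whole-foot and three-zone region masks
#'
#' The segmentation follows the common three-zone length mask: cells whose
#' row centroid lies in `[0, 0.30)` of the insole length form the hindfoot,
#' `[0.30, 0.60)` the midfoot, and `[0.60, 1.00]` the forefoot.  The
#' half-open intervals ensure each cell lands in exactly one zone, and the
#' three zones partition the whole-foot mask.
#'
#' @param grid a [sensor_grid()].
#' @return a named list of four masks (`whole`, `hindfoot`, `midfoot`,
#'   `forefoot`); each mask is a list with `label`, `cells` (integer cell
#'   indices), `rows` (integer row indices) and `length_bounds`.
#' @examples
#' masks <- build_masks(sensor_grid())
#' vapply(masks, function(m) length(m$cells), integer(1))
#' @export
build_masks <- function(grid) {
  stopifnot(inherits(grid, "sensor_grid"))
  f <- grid$row_centroid_fraction
  zone_rows <- list(
    hindfoot = which(f < 0.30),
    midfoot  = which(f >= 0.30 & f < 0.60),
    forefoot = which(f >= 0.60)
  )
  bounds <- list(whole = c(0, 1), hindfoot = c(0, 0.30),
                 midfoot = c(0.30, 0.60), forefoot = c(0.60, 1.00))
  cell_rows <- grid_cell_rows(grid)
  mask <- function(label, rows) {
    list(label = label,
         cells = which(cell_rows %in% rows),
         rows = as.integer(rows),
         length_bounds = bounds[[label]])
  }
  list(whole    = mask("whole", seq_len(grid$n_rows)),
       hindfoot = mask("hindfoot", zone_rows$hindfoot),
       midfoot  = mask("midfoot", zone_rows$midfoot),
       forefoot = mask("forefoot", zone_rows$forefoot))
}

#' Total force time series over a region mask
#'
#' Converts summed cell pressures to force with 1 kPa x 1 cm^2 = 0.1 N:
#' `F(t) = sum(p_cell(t)) * cell_area * 0.1`.
#'
#' @param recording an [insole_recording()].
#' @param mask one element of [build_masks()]; defaults to the whole foot.
#' @return numeric vector of forces in N, one per frame.
#' @export
total_force_series <- function(recording, mask = NULL) {
  stopifnot(inherits(recording, "insole_recording"))
  if (is.null(mask)) mask <- build_masks(recording$grid)$whole
  if (length(mask$cells) == 0L) stop("mask contains no cells", call. = FALSE)
  if (any(mask$cells > ncol(recording$frames))) {
    stop("mask cells outside the recording grid", call. = FALSE)
  }
  rowSums(recording$frames[, mask$cells, drop = FALSE]) *
    recording$grid$cell_area * 0.1
}

#' Detect stance-phase footprints in a recording
#'
#' A footprint is a maximal run of frames whose whole-foot total force is
#' at or above `force_threshold`, lasting at least `min_contact_ms`.
#' Intervals are half-open: `frame_start` is the first loaded frame,
#' `frame_end` one past the last.
#'
#' @param recording an [insole_recording()].
#' @param force_threshold force threshold in N (default 10).
#' @param min_contact_ms minimum duration in ms for a run to count as a
#'   footprint (default 150).
#' @return a data.frame with columns `step`, `frame_start`, `frame_end`,
#'   `valid`, `exclusion_reason`; zero rows if nothing is detected.
#' @export
detect_steps <- function(recording, force_threshold = 10, min_contact_ms = 150) {
  stopifnot(inherits(recording, "insole_recording"))
  check_scalar(force_threshold, "force_threshold", lower = 0)
  check_scalar(min_contact_ms, "min_contact_ms", lower = 0)
  force <- total_force_series(recording)
  above <- force >= force_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    (r$lengths - 1L) / recording$sampling_rate * 1000 >= min_contact_ms
  n_kept <- sum(keep)
  data.frame(
    step = seq_len(n_kept),
    frame_start = starts[keep],
    frame_end = ends[keep] + 1L,          # half-open
    valid = rep(TRUE, n_kept),
    exclusion_reason = rep(NA_character_, n_kept),
    stringsAsFactors = FALSE
  )
}

#' Cleaning criteria for detected footprints
#'
#' A footprint is removed (flagged invalid) if it fails any enabled
#' criterion, with reasons assigned in the order below:
#'
#' * `too_short`: activation-based contact time below `min_contact_ms`
#'   (default 450 ms; genuine paediatric stance phases are well above it,
#'   truncated or clipped footprints well below);
#' * `partial_loading`: the span of rows ever loaded above
#'   `activation_threshold` is below `min_row_span` (default 6 rows), as
#'   when only part of the foot lands on the insole;
#' * `low_force`: peak whole-foot force below `min_peak_fraction` (default
#'   0.5) of the median step peak of the recording, as in grazing contacts
#'   or turning steps.
#'
#' Set a component to `NULL` to disable that criterion.
#'
#' @param min_contact_ms minimum contact time in ms, or `NULL`.
#' @param min_peak_fraction minimum fraction of the median step peak force,
#'   or `NULL`.
#' @param min_row_span minimum number of distinct loaded rows, or `NULL`.
#' @param activation_threshold cell activation threshold in kPa used for
#'   the contact-time and row-span criteria (default 5).
#' @return a list of class `clean_criteria`.
#' @export
clean_criteria <- function(min_contact_ms = 450, min_peak_fraction = 0.5,
                           min_row_span = 6, activation_threshold = 5) {
  if (!is.null(min_contact_ms)) check_scalar(min_contact_ms, "min_contact_ms", lower = 0)
  if (!is.null(min_peak_fraction)) check_scalar(min_peak_fraction, "min_peak_fraction", lower = 0, upper = 1)
  if (!is.null(min_row_span)) check_scalar(min_row_span, "min_row_span", lower = 1)
  check_scalar(activation_threshold, "activation_threshold", lower = 0)
  structure(list(min_contact_ms = min_contact_ms,
                 min_peak_fraction = min_peak_fraction,
                 min_row_span = min_row_span,
                 activation_threshold = activation_threshold),
            class = "clean_criteria")
}

#' Flag amiss footprints for removal
#'
#' Applies the [clean_criteria()] to every detected footprint and fills the
#' `valid` / `exclusion_reason` columns.  Footprints listed in `flag_steps`
#' are removed with reason `user_flagged` (manual review, e.g. directional
#' changes at the end of a walkway).
#'
#' @param recording the [insole_recording()] the footprints came from.
#' @param footprints data.frame from [detect_steps()].
#' @param criteria a [clean_criteria()] object.
#' @param flag_steps integer vector of step numbers to remove manually.
#' @return the annotated footprint data.frame; retained footprints are the
#'   rows with `valid == TRUE`.
#' @export
clean_footprints <- function(recording, footprints,
                             criteria = clean_criteria(),
                             flag_steps = integer(0)) {
  stopifnot(inherits(recording, "insole_recording"), is.data.frame(footprints))
  if (nrow(footprints) == 0L) return(footprints)
  stopifnot(inherits(criteria, "clean_criteria"))
  dt_ms <- 1000 / recording$sampling_rate
  whole <- build_masks(recording$grid)$whole
  force <- total_force_series(recording, whole)
  cell_rows <- grid_cell_rows(recording$grid)
  thr <- criteria$activation_threshold

  n <- nrow(footprints)
  contact <- peak <- span <- numeric(n)
  for (i in seq_len(n)) {
    idx <- footprints$frame_start[i]:(footprints$frame_end[i] - 1L)
    sub <- recording$frames[idx, , drop = FALSE]
    active_frames <- rowSums(sub >= thr) > 0L
    contact[i] <- max(sum(active_frames) - 1L, 0L) * dt_ms
    peak[i] <- max(force[idx])
    loaded_rows <- unique(cell_rows[colSums(sub >= thr) > 0L])
    span[i] <- length(loaded_rows)
  }
  median_peak <- stats::median(peak)

  reason <- rep(NA_character_, n)
  if (length(flag_steps) > 0L) {
    reason[footprints$step %in% flag_steps] <- "user_flagged"
  }
  if (!is.null(criteria$min_contact_ms)) {
    hit <- is.na(reason) & contact < criteria$min_contact_ms
    reason[hit] <- "too_short"
  }
  if (!is.null(criteria$min_row_span)) {
    hit <- is.na(reason) & span < criteria$min_row_span
    reason[hit] <- "partial_loading"
  }
  if (!is.null(criteria$min_peak_fraction) && median_peak > 0) {
    hit <- is.na(reason) & peak < criteria$min_peak_fraction * median_peak
    reason[hit] <- "low_force"
  }
  footprints$valid <- is.na(reason)
  footprints$exclusion_reason <- reason
  footprints
}

#' Compute the six pedobarographic variables for one footprint and mask
#'
#' Over the frames of the footprint and the cells of the mask:
#'
#' * `maximum_force` (N): maximum of the regional total force;
#' * `peak_pressure` (kPa): maximum cell pressure;
#' * `force_time_integral` (N s): trapezoidal integral of regional force;
#' * `pressure_time_integral` (kPa s): trapezoidal integral of the regional
#'   instantaneous maximum pressure (vendor-style convention; see
#'   `pti_mode = "cell_mean"` for the per-cell alternative);
#' * `contact_area` (cm^2): maximum instantaneous area of cells at or above
#'   `activation_threshold`;
#' * `contact_time` (ms): time from the first to the last frame with any
#'   active cell, counted as (active frames - 1) x dt so that a constant
#'   1 s signal yields exactly 1000 ms, consistent with the trapezoidal
#'   integrals.
#'
#' The PTI convention is not standardized across vendors; the default
#' integrates the regional instantaneous maximum.  `"cell_mean"` instead
#' averages the per-cell time integrals over cells that are ever active.
#'
#' @param recording an [insole_recording()].
#' @param footprint one row of the data.frame from [detect_steps()] (a list
#'   or data.frame row with `frame_start` and `frame_end`).
#' @param mask one element of [build_masks()].
#' @param activation_threshold cell activation threshold in kPa (default 5).
#' @param pti_mode `"regional_peak"` (default) or `"cell_mean"`.
#' @return named numeric vector with the six variables.
#' @export
step_variables <- function(recording, footprint, mask,
                           activation_threshold = 5,
                           pti_mode = c("regional_peak", "cell_mean")) {
  stopifnot(inherits(recording, "insole_recording"))
  pti_mode <- match.arg(pti_mode)
  check_scalar(activation_threshold, "activation_threshold", lower = 0)
  fs <- footprint$frame_start
  fe <- footprint$frame_end
  if (is.null(fs) || is.null(fe) || fe <= fs) {
    stop("footprint must have frame_end > frame_start", call. = FALSE)
  }
  idx <- fs:(fe - 1L)
  sub <- recording$frames[idx, mask$cells, drop = FALSE]
  dt <- 1 / recording$sampling_rate
  area <- recording$grid$cell_area

  force <- rowSums(sub) * area * 0.1
  trapz <- function(y) if (length(y) < 2L) 0 else sum((y[-1L] + y[-length(y)]) / 2) * dt

  pmax_t <- row_max(sub)
  pti <- if (pti_mode == "regional_peak") {
    trapz(pmax_t)
  } else {
    ever_active <- colSums(sub >= activation_threshold) > 0L
    if (!any(ever_active)) 0 else {
      mean(apply(sub[, ever_active, drop = FALSE], 2L, trapz))
    }
  }
  active <- sub >= activation_threshold
  n_active_frames <- sum(rowSums(active) > 0L)

  c(force_time_integral = trapz(force),
    pressure_time_integral = pti,
    maximum_force = max(force),
    peak_pressure = max(sub),
    contact_area = max(rowSums(active)) * area,
    contact_time = max(n_active_frames - 1L, 0L) * dt * 1000)
}

#' Per-limb-per-session means of the six variables in all four regions
#'
#' Runs detection, cleaning and per-footprint variable extraction, then
#' averages each variable over the retained footprints, separately for the
#' whole foot and the three zones.
#'
#' @param recording an [insole_recording()].
#' @param force_threshold,detect_min_contact_ms detection parameters, see
#'   [detect_steps()].
#' @param criteria a [clean_criteria()] object.
#' @param activation_threshold,pti_mode see [step_variables()].
#' @return a data.frame in long format with columns `participant`, `limb`,
#'   `session`, `region`, `variable`, `value`, `n_steps_retained`
#'   (4 regions x 6 variables = 24 rows).
#' @export
summarize_limb_session <- function(recording, force_threshold = 10,
                                   detect_min_contact_ms = 150,
                                   criteria = clean_criteria(),
                                   activation_threshold = 5,
                                   pti_mode = "regional_peak") {
  stopifnot(inherits(recording, "insole_recording"))
  fp <- detect_steps(recording, force_threshold, detect_min_contact_ms)
  fp <- clean_footprints(recording, fp, criteria)
  kept <- fp[fp$valid, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no valid footprints", call. = FALSE)
  masks <- build_masks(recording$grid)
  rows <- list()
  for (region in names(masks)) {
    vals <- vapply(seq_len(nrow(kept)), function(i) {
      step_variables(recording, kept[i, ], masks[[region]],
                     activation_threshold = activation_threshold,
                     pti_mode = pti_mode)
    }, numeric(6))
    means <- rowMeans(vals)
    rows[[region]] <- data.frame(
      participant = recording$participant,
      limb = recording$limb,
      session = recording$session,
      region = region,
      variable = names(means),
      value = as.numeric(means),
      n_steps_retained = nrow(kept),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# canonical orders used by reliability_table and the writers
region_levels <- function() c("whole", "hindfoot", "midfoot", "forefoot")
variable_levels <- function() c("force_time_integral", "pressure_time_integral",
                                "maximum_force", "peak_pressure",
                                "contact_area", "contact_time")
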