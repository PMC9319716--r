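test_that("three-zone masks partition the grid by row-centroid fraction", {
  # 10 equal rows: centroids 0.05 ... 0.95
  g10 <- sensor_grid(n_rows = 10, n_cols = 2)
  m10 <- build_masks(g10)
  expect_equal(m10$hindfoot$rows, 1:3)
  expect_equal(m10$midfoot$rows, 4:6)
  expect_equal(m10$forefoot$rows, 7:10)

  # default 16-row grid: centroids (r - 0.5)/16 give 5/5/6 rows
  m16 <- build_masks(sensor_grid())
  expect_equal(lengths(list(m16$hindfoot$rows, m16$midfoot$rows,
                            m16$forefoot$rows)), c(5L, 5L, 6L))

  for (m in list(m10, m16)) {
    zone_cells <- c(m$hindfoot$cells, m$midfoot$cells, m$forefoot$cells)
    expect_equal(sort(zone_cells), m$whole$cells)   # disjoint union
    expect_equal(anyDuplicated(zone_cells), 0L)
  }
})

test_that("force conversion follows 1 kPa x 1 cm^2 = 0.1 N over any mask", {
  rec <- constant_cell_recording(pressure = 100, n_frames = 5)
  masks <- build_masks(rec$grid)
  expect_equal(total_force_series(rec, masks$whole), rep(10, 5))
  zero <- constant_cell_recording(pressure = 0, n_frames = 3)
  expect_equal(total_force_series(zero), rep(0, 3))
  empty_mask <- list(label = "x", cells = integer(0))
  expect_error(total_force_series(rec, empty_mask), "no cells")
})

test_that("whole-foot force is the sum of the three regional forces at every frame", {
  rec <- simulate_recording(gait_profile("drop_foot"), n_steps = 4, seed = 31)
  masks <- build_masks(rec$grid)
  whole <- total_force_series(rec, masks$whole)
  parts <- total_force_series(rec, masks$hindfoot) +
    total_force_series(rec, masks$midfoot) +
    total_force_series(rec, masks$forefoot)
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("step detection is empty on silent input and monotone in the threshold", {
  grid <- sensor_grid()
  silent <- insole_recording(grid, matrix(0, 100, grid$n_rows * grid$n_cols))
  expect_equal(nrow(detect_steps(silent)), 0L)

  rec <- simulate_recording(gait_profile(), n_steps = 6, seed = 13)
  n_lo <- nrow(detect_steps(rec, force_threshold = 10))
  n_hi <- nrow(detect_steps(rec, force_threshold = 60))
  n_over <- nrow(detect_steps(rec, force_threshold = 1e5))
  expect_gte(n_lo, n_hi)
  expect_equal(n_over, 0L)
})

test_that("constant single-cell signal reproduces all six variables in closed form", {
  # one cell at 100 kPa for exactly 1 s (101 frames at 100 Hz)
  rec <- constant_cell_recording(pressure = 100, n_frames = 101)
  fp <- list(frame_start = 1L, frame_end = 102L)
  sv <- step_variables(rec, fp, build_masks(rec$grid)$whole)
  expect_equal(sv[["force_time_integral"]], 10)     # N s
  expect_equal(sv[["pressure_time_integral"]], 100) # kPa s
  expect_equal(sv[["maximum_force"]], 10)           # N
  expect_equal(sv[["peak_pressure"]], 100)          # kPa
  expect_equal(sv[["contact_area"]], 1)             # cm^2
  expect_equal(sv[["contact_time"]], 1000)          # ms
})

test_that("regional variables respect partition conservation and threshold monotonicity", {
  rec <- simulate_recording(gait_profile("true_equinus"), n_steps = 3, seed = 17)
  masks <- build_masks(rec$grid)
  fp <- detect_steps(rec)
  for (i in seq_len(nrow(fp))) {
    sv <- lapply(masks, function(m) step_variables(rec, fp[i, ], m))
    expect_equal(sv$whole[["force_time_integral"]],
                 sv$hindfoot[["force_time_integral"]] +
                   sv$midfoot[["force_time_integral"]] +
                   sv$forefoot[["force_time_integral"]],
                 tolerance = 1e-12)
    expect_equal(sv$whole[["peak_pressure"]],
                 max(sv$hindfoot[["peak_pressure"]],
                     sv$midfoot[["peak_pressure"]],
                     sv$forefoot[["peak_pressure"]]))
    # regional contact time can never exceed the whole-foot contact time
    for (z in c("hindfoot", "midfoot", "forefoot")) {
      expect_lte(sv[[z]][["contact_time"]], sv$whole[["contact_time"]])
    }
  }
  # raising the activation threshold never increases area or contact time
  sv5 <- step_variables(rec, fp[1, ], masks$whole, activation_threshold = 5)
  sv20 <- step_variables(rec, fp[1, ], masks$whole, activation_threshold = 20)
  expect_lte(sv20[["contact_area"]], sv5[["contact_area"]])
  expect_lte(sv20[["contact_time"]], sv5[["contact_time"]])
})

test_that("per-frame active area of the whole foot sums over the zones", {
  rec <- simulate_recording(gait_profile(), n_steps = 2, seed = 23)
  masks <- build_masks(rec$grid)
  thr <- 5
  area <- function(m) rowSums(rec$frames[, m$cells, drop = FALSE] >= thr) *
    rec$grid$cell_area
  expect_equal(area(masks$whole),
               area(masks$hindfoot) + area(masks$midfoot) + area(masks$forefoot))
})

test_that("each cleaning criterion fires on its designed violation", {
  rec <- handmade_cleaning_recording()
  fp <- detect_steps(rec)
  expect_equal(nrow(fp), 5L)
  cleaned <- clean_footprints(rec, fp)
  expect_equal(cleaned$valid, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cleaned$exclusion_reason[3:5],
               c("too_short", "partial_loading", "low_force"))

  # manual flags take precedence
  flagged <- clean_footprints(rec, fp, flag_steps = 1L)
  expect_equal(flagged$exclusion_reason[1], "user_flagged")

  # all criteria disabled: identity
  off <- clean_criteria(min_contact_ms = NULL, min_peak_fraction = NULL,
                        min_row_span = NULL)
  expect_true(all(clean_footprints(rec, fp, off)$valid))
})

test_that("uncorrupted recordings keep every footprint after cleaning", {
  rec <- simulate_recording(gait_profile(), n_steps = 8, seed = 19)
  fp <- clean_footprints(rec, detect_steps(rec))
  expect_equal(sum(fp$valid), 8L)
})

test_that("limb-session summary averages the retained footprints", {
  # three identical steps: the mean equals any single step's variables
  rec <- handmade_cleaning_recording()
  template <- rec$frames[51:120, ]   # one valid step block
  gap <- matrix(0, 50, ncol(rec$frames))
  frames <- rbind(gap, template, gap, template, gap, template, gap)
  rep3 <- insole_recording(rec$grid, frames, sampling_rate = 100)
  s <- summarize_limb_session(rep3)
  expect_equal(unique(s$n_steps_retained), 3L)
  fp <- detect_steps(rep3)
  one <- step_variables(rep3, fp[1, ], build_masks(rep3$grid)$whole)
  whole <- s[s$region == "whole", ]
  expect_equal(whole$value[match(names(one), whole$variable)], unname(one),
               tolerance = 1e-12)

  silent <- insole_recording(rep3$grid, matrix(0, 50, ncol(frames)))
  expect_error(summarize_limb_session(silent), "no valid footprints")
})

test_that("the default 15-step simulation retains all 15 steps", {
  rec <- simulate_recording(gait_profile(), n_steps = 15, seed = 29)
  s <- summarize_limb_session(rec)
  expect_equal(unique(s$n_steps_retained), 15L)
  expect_equal(nrow(s), 24L)   # 4 regions x 6 variables
})
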