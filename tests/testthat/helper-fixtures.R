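# Shared fixture builders: tiny recordings constructed directly in code.

# A recording holding a single cell at a constant pressure, surrounded by
# otherwise silent frames.  Used for closed-form variable checks.
constant_cell_recording <- function(pressure = 100, n_frames = 101,
                                    cell = 1L, rate = 100) {
  grid <- sensor_grid(n_rows = 4, n_cols = 2, cell_area = 1, insole_length = 10)
  frames <- matrix(0, nrow = n_frames, ncol = grid_n_cells_test(grid))
  frames[, cell] <- pressure
  insole_recording(grid, frames, sampling_rate = rate)
}

grid_n_cells_test <- function(grid) grid$n_rows * grid$n_cols

# A hand-built multi-step recording on the default 16 x 6 grid exercising
# each cleaning criterion exactly once:
#   step 1, 2: valid (all rows loaded at 50 kPa, 70 frames)
#   step 3: short (same loading, 30 frames)            -> too_short
#   step 4: narrow (only rows 1-4 loaded, 70 frames)   -> partial_loading
#   step 5: weak (all rows at 8 kPa, 70 frames)        -> low_force
handmade_cleaning_recording <- function() {
  grid <- sensor_grid()
  n_cols <- grid$n_cols
  cell_of <- function(row) (row - 1L) * n_cols + 1L
  block <- function(rows, pressure, n_frames) {
    fr <- matrix(0, nrow = n_frames, ncol = grid$n_rows * n_cols)
    fr[, vapply(rows, cell_of, integer(1))] <- pressure
    fr
  }
  gap <- matrix(0, nrow = 50, ncol = grid$n_rows * n_cols)
  frames <- rbind(
    gap,
    block(1:16, 50, 70), gap,   # valid
    block(1:16, 50, 70), gap,   # valid
    block(1:16, 50, 30), gap,   # too short
    block(1:4, 50, 70), gap,    # partial loading
    block(1:16, 8, 70), gap     # low force
  )
  insole_recording(grid, frames, sampling_rate = 100)
}

# Random two-way matrix with a genuine unit effect (for ANOVA/ICC checks)
random_paired_matrix <- function(n = 16, k = 2, unit_sd = 8, noise_sd = 10) {
  matrix(stats::rnorm(n * k, 50, noise_sd) + rep(stats::rnorm(n, 0, unit_sd), k),
         nrow = n, ncol = k)
}
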