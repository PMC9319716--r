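#' Describe an insole sensor grid
#'
#' The insole is modelled as a rectangular grid of pressure cells:
#' `n_rows` longitudinal rows (row 1 at the heel) by `n_cols` mediolateral
#' columns.  Each row has a longitudinal centroid position expressed as a
#' fraction of the insole length; the three-zone mask assigns cells to
#' hindfoot / midfoot / forefoot by this fraction.
#'
#' The default geometry (16 x 6 cells of 1 cm^2 on a 20 cm insole) mimics
#' a paediatric pressure insole at reduced resolution.
#'
#' @param n_rows number of longitudinal rows (>= 4); row 1 is the heel end.
#' @param n_cols number of mediolateral columns (>= 2).
#' @param cell_area area of one cell in cm^2.
#' @param insole_length insole length in cm.
#' @param row_centroid_fraction optional numeric vector of per-row
#'   longitudinal centroid positions as fractions of `insole_length`
#'   (strictly increasing, in `[0, 1]`); defaults to uniformly spaced rows.
#' @return an object of class `sensor_grid`.
#' @examples
#' g <- sensor_grid()
#' g$n_rows * g$n_cols
#' @export
sensor_grid <- function(n_rows = 16L, n_cols = 6L, cell_area = 1.0,
                        insole_length = 20.0, row_centroid_fraction = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 4L) stop("'n_rows' must be >= 4", call. = FALSE)
  if (n_cols < 2L) stop("'n_cols' must be >= 2", call. = FALSE)
  check_scalar(cell_area, "cell_area", lower = 0, strict_lower = TRUE)
  check_scalar(insole_length, "insole_length", lower = 0, strict_lower = TRUE)
  if (is.null(row_centroid_fraction)) {
    row_centroid_fraction <- (seq_len(n_rows) - 0.5) / n_rows
  }
  if (length(row_centroid_fraction) != n_rows ||
      any(row_centroid_fraction < 0) || any(row_centroid_fraction > 1) ||
      any(diff(row_centroid_fraction) <= 0)) {
    stop("'row_centroid_fraction' must be strictly increasing in [0, 1], one per row",
         call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_area = cell_area,
         insole_length = insole_length,
         row_centroid_fraction = as.numeric(row_centroid_fraction)),
    class = "sensor_grid"
  )
}

#' @export
print.sensor_grid <- function(x, ...) {
  cat(sprintf("<sensor_grid> %d x %d cells, %.3g cm^2/cell, insole %.3g cm\n",
              x$n_rows, x$n_cols, x$cell_area, x$insole_length))
  invisible(x)
}

# internal: number of cells; cell index = (row - 1) * n_cols + col
grid_n_cells <- function(grid) grid$n_rows * grid$n_cols

# internal: row index of each cell, length n_cells
grid_cell_rows <- function(grid) rep(seq_len(grid$n_rows), each = grid$n_cols)

# internal: TRUE if rows are uniformly spaced (required by the text format)
grid_uniform_rows <- function(grid) {
  isTRUE(all.equal(grid$row_centroid_fraction,
                   (seq_len(grid$n_rows) - 0.5) / grid$n_rows,
                   tolerance = 1e-12))
}

#' Construct an insole pressure recording
#'
#' A recording is a time series of per-cell pressure frames (kPa) on a
#' [sensor_grid()], sampled at a fixed rate, for one limb of one
#' participant in one session.
#'
#' @param grid a [sensor_grid()].
#' @param frames numeric matrix, one row per frame, one column per cell
#'   (cell index `(row - 1) * n_cols + col`); pressures in kPa, all >= 0.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param participant participant identifier (single string, no whitespace).
#' @param limb `"L"` or `"R"`.
#' @param session session number, 1 or 2.
#' @return an object of class `insole_recording`.
#' @export
insole_recording <- function(grid, frames, sampling_rate = 100,
                             participant = "P01", limb = "L", session = 1L) {
  stopifnot(inherits(grid, "sensor_grid"))
  frames <- as.matrix(frames)
  if (nrow(frames) < 1L) stop("recording must contain at least one frame", call. = FALSE)
  if (ncol(frames) != grid_n_cells(grid)) {
    stop(sprintf("frames have %d cells but the grid has %d",
                 ncol(frames), grid_n_cells(grid)), call. = FALSE)
  }
  if (any(frames < 0)) stop("pressure values must be >= 0", call. = FALSE)
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (!is.character(participant) || length(participant) != 1L ||
      grepl("\\s", participant)) {
    stop("'participant' must be a single string without whitespace", call. = FALSE)
  }
  limb <- match.arg(limb, c("L", "R"))
  session <- as.integer(session)
  if (!session %in% c(1L, 2L)) stop("'session' must be 1 or 2", call. = FALSE)
  dimnames(frames) <- NULL
  structure(
    list(grid = grid, frames = frames, sampling_rate = sampling_rate,
         participant = participant, limb = limb, session = session),
    class = "insole_recording"
  )
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> %s limb %s session %d: %d frames @ %g Hz on %d x %d grid\n",
              x$participant, x$limb, x$session, nrow(x$frames),
              x$sampling_rate, x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# internal: one-line .ppr header
ppr_header <- function(rec) {
  g <- rec$grid
  sprintf("# rows=%d cols=%d cell_area_cm2=%.6g insole_length_cm=%.6g rate_hz=%.6g participant=%s limb=%s session=%d",
          g$n_rows, g$n_cols, g$cell_area, g$insole_length,
          rec$sampling_rate, rec$participant, rec$limb, rec$session)
}

#' Write an insole recording to a plain-text `.ppr` file
#'
#' The format is one `#`-prefixed header line carrying the grid geometry,
#' sampling rate and metadata, followed by one comma-separated row of kPa
#' values per frame.  Numbers are serialized with 6 significant digits, so
#' two writes of the same recording are byte-identical and the text
#' representation is a fixpoint of read-then-write.  The format assumes
#' uniformly spaced sensor rows.
#'
#' @param recording an [insole_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "insole_recording"))
  if (!grid_uniform_rows(recording$grid)) {
    stop("the .ppr text format only supports uniformly spaced rows", call. = FALSE)
  }
  fr <- recording$frames
  txt <- vapply(seq_len(nrow(fr)), function(i) {
    paste(sprintf("%.6g", fr[i, ]), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(ppr_header(recording), txt), con = con, sep = "\n")
  invisible(path)
}

# internal: parse "key=value" tokens of the header line
parse_ppr_header <- function(line) {
  body <- sub("^#\\s*", "", line)
  tokens <- strsplit(trimws(body), "\\s+")[[1]]
  kv <- strsplit(tokens, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (length(tokens) == 0L || any(bad)) {
    stop("line 1: malformed header", call. = FALSE)
  }
  vals <- vapply(kv, `[`, character(1), 2L)
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  needed <- c("rows", "cols", "cell_area_cm2", "insole_length_cm",
              "rate_hz", "participant", "limb", "session")
  missing <- setdiff(needed, names(vals))
  if (length(missing) > 0L) {
    stop(sprintf("line 1: header is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals
}

#' Read an insole recording from a `.ppr` file
#'
#' @param path path to a file written by [write_recording()] (or following
#'   the same documented format).
#' @return an [insole_recording()].
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#")) {
    stop("line 1: expected a '#' header line", call. = FALSE)
  }
  h <- parse_ppr_header(lines[[1L]])
  grid <- sensor_grid(n_rows = as.integer(h[["rows"]]),
                      n_cols = as.integer(h[["cols"]]),
                      cell_area = as.numeric(h[["cell_area_cm2"]]),
                      insole_length = as.numeric(h[["insole_length_cm"]]))
  n_cells <- grid_n_cells(grid)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no frames", call. = FALSE)
  frames <- matrix(NA_real_, nrow = length(body), ncol = n_cells)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(strsplit(body[[i]], ",", fixed = TRUE)[[1L]]))
    line_no <- i + 1L
    if (length(vals) != n_cells) {
      stop(sprintf("line %d: expected %d values, found %d",
                   line_no, n_cells, length(vals)), call. = FALSE)
    }
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric pressure value", line_no), call. = FALSE)
    }
    if (any(vals < 0)) {
      stop(sprintf("line %d: negative pressure value", line_no), call. = FALSE)
    }
    frames[i, ] <- vals
  }
  insole_recording(grid = grid, frames = frames,
                   sampling_rate = as.numeric(h[["rate_hz"]]),
                   participant = h[["participant"]],
                   limb = h[["limb"]],
                   session = as.integer(h[["session"]]))
}

#' Write a reliability results table to CSV (display) plus JSON (full precision)
#'
#' The CSV mirrors the layout of published test-retest reliability tables
#' for pedobarography: one row per (region, variable) with ICC, its 95% CI,
#' qualitative band, Mean, Mean_diff, SD_diff, limits of agreement, SEM,
#' MDC, SEM%, MDC% and the MDC% band.  Display values are rounded
#' half-to-even to 2 decimals and negative CI lower bounds are clamped to 0
#' for display only; a companion `.json` file preserves full precision and
#' unclamped bounds.
#'
#' @param results a data.frame from [reliability_table()].
#' @param path output CSV path; the JSON companion replaces the extension
#'   with `.json` (or appends it).
#' @return invisibly, a list with elements `csv` and `json` (the two paths).
#' @export
write_reliability_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("'results' must be a non-empty data.frame of reliability results",
         call. = FALSE)
  }
  disp <- results
  disp$ci_low <- pmax(disp$ci_low, 0)
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, digits = 2L)
  utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
  json_path <- if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path) else paste0(path, ".json")
  jsonlite::write_json(results, json_path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(list(csv = path, json = json_path))
}
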