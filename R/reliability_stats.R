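#' Construct a paired-measurements matrix
#'
#' The ANOVA input for one variable in one region: an `n x k` matrix of
#' limb-session means, rows = analysis units (limbs), columns = sessions.
#'
#' @param values numeric matrix, `n >= 2` rows, `k >= 2` columns, no
#'   missing cells.
#' @param variable,region optional labels carried through to results.
#' @return a matrix of class `paired_measurements` with attributes
#'   `variable` and `region`.
#' @export
paired_measurements <- function(values, variable = NA_character_,
                                region = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("paired measurements need at least 2 units and 2 sessions", call. = FALSE)
  }
  if (anyNA(values)) stop("paired measurements must have no missing cells", call. = FALSE)
  storage.mode(values) <- "double"
  structure(values, variable = variable, region = region,
            class = c("paired_measurements", class(values)))
}

#' Mean squares of the two-way crossed ANOVA without replication
#'
#' Decomposes the total sum of squares of an `n x k` table into rows
#' (units), columns (sessions) and error: `SS_total = SS_R + SS_C + SS_E`
#' with `df = n - 1`, `k - 1`, `(n - 1)(k - 1)`.  These mean squares are
#' the ingredients of the absolute-agreement intraclass correlation.
#'
#' @param pm a [paired_measurements()] matrix (or any `n x k` matrix with
#'   `n, k >= 2`).
#' @return a list of class `anova_mean_squares` with `ms_rows`, `ms_cols`,
#'   `ms_error`, the three degrees of freedom, and `n`, `k`.
#' @examples
#' two_way_mean_squares(cbind(c(1, 2, 3), c(1, 2, 3)))
#' @export
two_way_mean_squares <- function(pm) {
  x <- unclass(as.matrix(pm))
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 units and 2 sessions", call. = FALSE)
  if (anyNA(x)) stop("matrix must have no missing cells", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ss_error <- max(ss_error, 0)          # guard against negative round-off
  structure(list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_error / ((n - 1) * (k - 1)),
    df_rows = n - 1L, df_cols = k - 1L, df_error = (n - 1L) * (k - 1L),
    n = n, k = k
  ), class = "anova_mean_squares")
}

#' Intraclass correlation: two-way model, absolute agreement, average measures
#'
#' The reliability of the mean of `k` repeated sessions under a two-way
#' model with absolute agreement (often written ICC(A,k) or ICC(2,k)):
#'
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#'
#' where `MS_R` is the between-unit (between-limb) mean square, `MS_C` the
#' between-session mean square, `MS_E` the error mean square, and `n` the
#' number of units.  The value can be negative in pathological data; it is
#' returned as computed (display clamping, if any, is a presentation
#' concern).
#'
#' @param ms an [two_way_mean_squares()] result.
#' @param n number of analysis units; defaults to the `n` stored in `ms`.
#' @return the ICC point estimate.
#' @export
icc_absolute_agreement_averaged <- function(ms, n = ms$n) {
  stopifnot(inherits(ms, "anova_mean_squares"))
  denom <- ms$ms_rows + (ms$ms_cols - ms$ms_error) / n
  if (denom == 0) stop("degenerate data: zero ICC denominator", call. = FALSE)
  (ms$ms_rows - ms$ms_error) / denom
}

#' Exact F-based confidence interval for the average-measures agreement ICC
#'
#' McGraw-Wong interval for ICC(A,k): the single-measure bounds are
#' obtained from F quantiles with a Satterthwaite-approximated denominator
#' df, then stepped up to average measures via the Spearman-Brown relation
#' `k * L / (1 + (k - 1) * L)`.  Bounds are returned as computed (possibly
#' negative); clamp for display only.
#'
#' In the fully degenerate noiseless case (`MS_C = MS_E = 0` with
#' `MS_R > 0`) the interval collapses to `(1, 1)`.  For pathological data
#' (very small `n` together with vanishing between-unit variance, i.e. a
#' meaningless negative ICC) the F-based construction itself can
#' degenerate; this announces itself through inverted (`ci_low > ci_high`)
#' or non-finite bounds, which are returned as computed rather than
#' silently repaired.
#'
#' @param ms an [two_way_mean_squares()] result.
#' @param n,k dimensions; default to those stored in `ms`.
#' @param alpha two-sided type-I level (default 0.05 for a 95% CI).
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
icc_confidence_interval <- function(ms, n = ms$n, k = ms$k, alpha = 0.05) {
  stopifnot(inherits(ms, "anova_mean_squares"))
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  msr <- ms$ms_rows; msj <- ms$ms_cols; mse <- ms$ms_error
  if (n < 2L || k < 2L) stop("degenerate degrees of freedom", call. = FALSE)
  if (mse == 0 && msj == 0) {
    if (msr > 0) return(c(1, 1))
    stop("degenerate data: all mean squares are zero", call. = FALSE)
  }
  if (mse == 0) mse <- .Machine$double.xmin  # avoid 0/0 in fj; limit is exact
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msj - mse) / n)
  fj <- msj / mse
  vn <- (n - 1) * (k - 1) * (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
  vd <- (n - 1) * k^2 * icc1^2 * fj^2 + (n * (1 + (k - 1) * icc1) - k * icc1)^2
  v <- vn / vd
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_u * mse) / (f_u * (k * msj + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_l * msr - mse) / (k * msj + (k * n - k - n) * mse + n * f_l * msr)
  c(l1 * k / (1 + l1 * (k - 1)), u1 * k / (1 + u1 * (k - 1)))
}

#' Qualitative agreement band for an ICC value
#'
#' Bands: poor (`ICC < 0.40`), fair (`0.40 <= ICC < 0.60`), good
#' (`0.60 <= ICC < 0.75`), excellent (`0.75 <= ICC <= 1`).  Negative
#' estimates are floored at 0 for banding, which lands them in `poor`.
#'
#' @param icc numeric vector of ICC values.
#' @return character vector of bands.
#' @examples
#' classify_icc(c(0.37, 0.44, 0.60, 0.75))
#' @export
classify_icc <- function(icc) {
  x <- pmax(icc, 0)
  out <- character(length(x))
  out[x < 0.40] <- "poor"
  out[x >= 0.40 & x < 0.60] <- "fair"
  out[x >= 0.60 & x < 0.75] <- "good"
  out[x >= 0.75] <- "excellent"
  out
}

#' Bland-Altman agreement statistics for two sessions
#'
#' Differences are oriented session 1 minus session 2.  Returns the grand
#' mean of all `2n` values (the "Mean" column of reliability tables, used
#' as the denominator of SEM% and MDC%), the mean difference with its
#' t-based 95% CI, the sample SD of the differences (`n - 1` denominator),
#' and the 95% limits of agreement `mean_diff +/- 1.96 * sd_diff`.
#'
#' @param session1,session2 numeric vectors of equal length (>= 2), one
#'   value per analysis unit.
#' @param conf_level confidence level for the mean-difference CI.
#' @return a list with `n`, `mean`, `mean_diff`, `mean_diff_ci`, `sd_diff`,
#'   `loa_low`, `loa_high`.
#' @examples
#' bland_altman(c(10, 12, 9), c(11, 11, 10))
#' @export
bland_altman <- function(session1, session2, conf_level = 0.95) {
  if (length(session1) != length(session2)) {
    stop("sessions must have equal length", call. = FALSE)
  }
  n <- length(session1)
  if (n < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- session1 - session2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * sd_diff / sqrt(n)
  list(n = n,
       mean = mean(c(session1, session2)),
       mean_diff = mean_diff,
       mean_diff_ci = c(mean_diff - half, mean_diff + half),
       sd_diff = sd_diff,
       loa_low = mean_diff - 1.96 * sd_diff,
       loa_high = mean_diff + 1.96 * sd_diff)
}

#' Standard error of measurement from the SD of differences
#'
#' `SEM = SD_diff / sqrt(2)`: the within-subject measurement noise implied
#' by the between-session differences of a test-retest design.
#'
#' @param sd_diff standard deviation of the between-session differences
#'   (>= 0).
#' @return the SEM, in the variable's units.
#' @examples
#' sem_from_sd_diff(18.57)
#' @export
sem_from_sd_diff <- function(sd_diff) {
  if (any(sd_diff < 0)) stop("'sd_diff' must be >= 0", call. = FALSE)
  sd_diff / sqrt(2)
}

#' Minimal detectable change from the SEM
#'
#' `MDC = 1.96 * sqrt(2) * SEM`: the smallest between-session change
#' exceeding measurement error with 95% confidence.  When the SEM came
#' from [sem_from_sd_diff()] this is algebraically `1.96 * SD_diff`.
#'
#' @param sem standard error of measurement (>= 0).
#' @return the MDC, in the variable's units.
#' @examples
#' mdc_from_sem(sem_from_sd_diff(25))
#' @export
mdc_from_sem <- function(sem) {
  if (any(sem < 0)) stop("'sem' must be >= 0", call. = FALSE)
  1.96 * sqrt(2) * sem
}

#' Qualitative band for an MDC percentage
#'
#' `< 10%` excellent, `10` to `30%` (inclusive) acceptable, `> 30%` poor.
#'
#' @param mdc_pct numeric vector of MDC percentages.
#' @return character vector of bands.
#' @export
classify_mdc_pct <- function(mdc_pct) {
  out <- character(length(mdc_pct))
  out[mdc_pct < 10] <- "excellent"
  out[mdc_pct >= 10 & mdc_pct <= 30] <- "acceptable"
  out[mdc_pct > 30] <- "poor"
  out
}

#' SEM and MDC as percentages of the variable mean
#'
#' `SEM% = 100 * SEM / Mean`, `MDC% = 100 * MDC / Mean`, with the MDC%
#' band of [classify_mdc_pct()].  The mean must be strictly positive.
#'
#' @param sem,mdc absolute SEM and MDC.
#' @param mean the variable's grand mean over both sessions (> 0).
#' @return a list with `sem_pct`, `mdc_pct`, `mdc_pct_band`.
#' @export
percent_metrics <- function(sem, mdc, mean) {
  check_scalar(mean, "mean", lower = 0, strict_lower = TRUE)
  sem_pct <- 100 * sem / mean
  mdc_pct <- 100 * mdc / mean
  list(sem_pct = sem_pct, mdc_pct = mdc_pct,
       mdc_pct_band = classify_mdc_pct(mdc_pct))
}

#' Full reliability statistics for one paired-measurements matrix
#'
#' @param pm a [paired_measurements()] `n x 2` matrix (columns = sessions).
#' @param alpha type-I level for the ICC confidence interval.
#' @return a one-row data.frame with region, variable, n_units, icc,
#'   ci_low/ci_high (unclamped), icc_band, mean, mean_diff, sd_diff,
#'   loa_low/loa_high, sem, mdc, sem_pct, mdc_pct, mdc_pct_band.
#' @export
reliability_result <- function(pm, alpha = 0.05) {
  x <- unclass(as.matrix(pm))
  if (ncol(x) != 2L) {
    stop("reliability_result expects exactly 2 sessions", call. = FALSE)
  }
  ms <- two_way_mean_squares(x)
  icc <- icc_absolute_agreement_averaged(ms)
  ci <- icc_confidence_interval(ms, alpha = alpha)
  ba <- bland_altman(x[, 1L], x[, 2L])
  sem <- sem_from_sd_diff(ba$sd_diff)
  mdc <- mdc_from_sem(sem)
  pct <- if (ba$mean > 0) {
    percent_metrics(sem, mdc, ba$mean)
  } else {
    list(sem_pct = NA_real_, mdc_pct = NA_real_, mdc_pct_band = NA_character_)
  }
  data.frame(
    region = attr(pm, "region") %||% NA_character_,
    variable = attr(pm, "variable") %||% NA_character_,
    n_units = nrow(x),
    icc = icc, ci_low = ci[1L], ci_high = ci[2L],
    icc_band = classify_icc(icc),
    mean = ba$mean, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    sem = sem, mdc = mdc,
    sem_pct = pct$sem_pct, mdc_pct = pct$mdc_pct,
    mdc_pct_band = pct$mdc_pct_band,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the 24-row reliability table from limb-session summaries
#'
#' For each of the 4 regions x 6 variables, builds the `n x 2` matrix of
#' limb-session means (one row per limb, columns = sessions 1 and 2) and
#' computes the full set of reliability statistics.
#'
#' @param summaries long-format data.frame as returned by
#'   [summarize_limb_session()] (rows from all limbs and both sessions,
#'   stacked).
#' @param alpha type-I level for the ICC confidence intervals.
#' @return a data.frame with one row per (region, variable), regions
#'   ordered whole, hindfoot, midfoot, forefoot.
#' @export
reliability_table <- function(summaries, alpha = 0.05) {
  stopifnot(is.data.frame(summaries))
  needed <- c("participant", "limb", "session", "region", "variable", "value")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols) > 0L) {
    stop(sprintf("summaries are missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  summaries$unit <- paste(summaries$participant, summaries$limb, sep = ":")
  units <- sort(unique(summaries$unit))
  have <- unique(summaries[, c("unit", "session")])
  missing_pairs <- character(0)
  for (u in units) {
    s <- have$session[have$unit == u]
    for (need in c(1L, 2L)) {
      if (!need %in% s) missing_pairs <- c(missing_pairs, sprintf("%s session %d", u, need))
    }
  }
  if (length(missing_pairs) > 0L) {
    stop(sprintf("unmatched limb-session pairs: %s",
                 paste(missing_pairs, collapse = "; ")), call. = FALSE)
  }
  out <- list()
  for (region in region_levels()) {
    for (variable in variable_levels()) {
      sub <- summaries[summaries$region == region & summaries$variable == variable, ]
      if (nrow(sub) == 0L) next
      m <- matrix(NA_real_, nrow = length(units), ncol = 2L)
      for (j in c(1L, 2L)) {
        sj <- sub[sub$session == j, ]
        m[, j] <- sj$value[match(units, sj$unit)]
      }
      pm <- paired_measurements(m, variable = variable, region = region)
      out[[paste(region, variable)]] <- reliability_result(pm, alpha = alpha)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
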