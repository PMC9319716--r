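# Independent ICC oracle: pingouin's two-way absolute-agreement
# average-measures ICC (ICC(A,k)) with its F-based 95% CI, run through a
# single python process over a stack of matrices.
pingouin_icc_aak <- function(mats) {
  stopifnot(length(mats) >= 1L)
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(seq_along(mats), function(b) {
    m <- mats[[b]]
    data.frame(rep = b,
               unit = rep(seq_len(nrow(m)), ncol(m)),
               session = rep(seq_len(ncol(m)), each = nrow(m)),
               y = as.vector(m))
  }))
  utils::write.csv(df, in_csv, row.names = FALSE)
  script <- c(
    "import warnings",
    "warnings.filterwarnings('ignore')",
    "import pandas as pd, pingouin as pg",
    "pg.options['round.column.CI95'] = None",
    sprintf("df = pd.read_csv(%s)", deparse(in_csv)),
    "rows = []",
    "for b, g in df.groupby('rep'):",
    "    res = pg.intraclass_corr(data=g, targets='unit', raters='session', ratings='y')",
    "    r = res[res['Type'] == 'ICC(A,k)'].iloc[0]",
    "    rows.append({'rep': b, 'icc': r['ICC'], 'lo': r['CI95'][0], 'hi': r['CI95'][1]})",
    sprintf("pd.DataFrame(rows).to_csv(%s, index=False)", deparse(out_csv))
  )
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out_csv)) {
    stop("pingouin oracle invocation failed")
  }
  out <- utils::read.csv(out_csv)
  out[order(out$rep), ]
}
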