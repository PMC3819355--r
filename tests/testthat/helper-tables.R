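# Published reference grids (block, event-related, contrast), stored as the
# printed strings so that each entry's printed precision is known.  Columns:
# psc, sigma_N, def1..def6, power.

parseTable <- function(rows) {
  toks <- lapply(strsplit(rows, "\\s+"), function(x) x[nzchar(x)])
  vals <- t(vapply(toks, as.numeric, numeric(9)))
  dec <- t(vapply(toks, function(r) {
    vapply(r, function(s) {
      dot <- regexpr(".", s, fixed = TRUE)
      if (dot < 0) 0L else nchar(s) - dot
    }, integer(1))
  }, integer(9)))
  colnames(vals) <- colnames(dec) <-
    c("psc", "sigma_N", paste0("def", 1:6), "power")
  list(values = as.data.frame(vals), halfUlp = 0.5 * 10^(-dec))
}

printedBlockTable <- parseTable(c(
  "1 0.1 1003 10 20 4.46 19.85 12.98 1.00",
  "1 0.2 502 5 14 2.23 4.96 6.96 1.00",
  "1 0.5 201 2 6 0.89 0.79 -1.00 1.00",
  "1 1 100 1 0 0.45 0.20 -7.02 0.99",
  "1 2 50 0.5 -6 0.22 0.050 -13.04 0.58",
  "1 5 20 0.2 -14 0.089 0.0079 -21.00 0.14",
  "1 10 10 0.1 -20 0.045 0.0020 -27.02 0.07",
  "2 0.1 1007 20 26 8.91 79.42 19.00 1.00",
  "2 0.2 503 10 20 4.46 19.85 12.97 1.00",
  "2 0.5 201 4 12 1.78 3.18 5.02 1.00",
  "2 1 101 2 6 0.89 0.79 -1.00 1.00",
  "2 2 50 1 0 0.45 0.20 -7.02 0.99",
  "2 5 20 0.4 -8 0.18 0.032 -14.98 0.42",
  "2 10 10 0.2 -14 0.089 0.0079 -21.00 0.15",
  "5 0.1 1017 50 34 22.28 496.35 26.96 1.00",
  "5 0.2 508 25 28 11.14 124.09 20.94 1.00",
  "5 0.5 203 10 20 4.46 19.85 12.98 1.00",
  "5 1 102 5 14 2.23 4.96 6.96 1.00",
  "5 2 51 2.5 8 1.11 1.24 0.94 1.00",
  "5 5 20 1 0 0.45 0.1985 -7.02 0.99",
  "5 10 10 0.5 -6 0.22 0.0496 -13.04 0.59"))

printedErTable <- parseTable(c(
  "1 0.1 1002 10 20 3.07 9.41 9.74 1.00",
  "1 0.2 501 5 14 1.53 2.35 3.72 1.00",
  "1 0.5 200 2 6 0.61 0.38 -4.24 0.99",
  "1 1 100 1 0 0.31 0.094 -10.26 0.67",
  "1 2 50 0.5 -6 0.15 0.024 -16.28 0.22",
  "1 5 20 0.2 -14 0.06 0.0038 -24.24 0.08",
  "1 10 10 0.1 -20 0.03 0.00094 -30.26 0.06",
  "2 0.1 1004 20 26 6.14 37.64 15.76 1.00",
  "2 0.2 502 10 20 3.07 9.41 9.74 1.00",
  "2 0.5 201 4 12 1.23 1.51 1.78 1.00",
  "2 1 100 2 6 0.61 0.38 -4.24 0.99",
  "2 2 50 1 0 0.31 0.094 -10.26 0.75",
  "2 5 20 0.4 -8 0.13 0.015 -18.23 0.17",
  "2 10 10 0.2 -14 0.06 0.0038 -24.24 0.08",
  "5 0.1 1010 50 34 15.34 235.26 23.72 1.00",
  "5 0.2 505 25 28 7.67 58.81 17.69 1.00",
  "5 0.5 202 10 20 3.07 9.41 9.74 1.00",
  "5 1 101 5 14 1.54 2.35 3.72 1.00",
  "5 2 51 2.5 8 0.77 0.59 -2.31 0.99",
  "5 5 20 1 0 0.31 0.15 -10.26 0.64",
  "5 10 10 0.5 -6 0.15 0.024 -16.28 0.21"))

printedContrastTable <- parseTable(c(
  "1 0.1 1001 10.56 20.47 3.02 9.14 9.61 1.00",
  "1 0.2 501 5.28 14.45 1.51 2.28 3.59 1.00",
  "1 0.5 200 2.11 6.49 0.60 0.37 -4.37 0.96",
  "1 1 100 1.06 0.47 0.30 0.09 -10.39 0.46",
  "1 2 50 0.53 -5.55 0.15 0.02 -16.41 0.15",
  "1 5 20 0.21 -13.51 0.06 0.0037 -24.37 0.07",
  "1 10 10 0.11 -19.53 0.03 0.0009 -30.39 0.05",
  "2 0.1 1003 21.12 26.49 6.05 36.56 15.63 1.00",
  "2 0.2 501 10.56 20.47 3.02 9.14 9.61 1.00",
  "2 0.5 201 4.22 12.51 1.21 1.46 1.65 1.00",
  "2 1 100 2.11 6.49 0.60 0.37 -4.37 1.00",
  "2 2 50 1.06 0.47 0.30 0.091 -10.39 0.92",
  "2 5 20 0.42 -7.49 0.12 0.015 -18.35 0.27",
  "2 10 10 0.21 -13.51 0.06 0.004 -24.37 0.10",
  "5 0.1 1007 52.79 34.45 15.12 228.50 23.59 1.00",
  "5 0.2 504 26.40 28.43 7.56 57.12 17.57 1.00",
  "5 0.5 201 10.56 20.47 3.02 9.14 9.61 1.00",
  "5 1 101 5.28 14.45 1.51 2.28 3.59 1.00",
  "5 2 50 2.64 8.43 0.76 0.57 -2.43 0.99",
  "5 5 20 1.06 0.47 0.30 0.09 -10.39 0.47",
  "5 10 10 0.53 -5.55 0.15 0.02 -16.41 0.16"))

# Metric columns of a computed reference grid for comparison against a
# printed table: returns character vector of cells violating the tolerance
# rel * |printed| plus the printed half-ULP (the printed value itself is
# rounded).  The decibel columns are logarithms of the linear ratios, so
# the same relative tolerance is applied on the log scale: a fraction rel
# on a linear ratio is 20*log10(1 + rel) dB, absolutely.
metricViolations <- function(computed, printed, rel,
                             cols = paste0("def", 1:6)) {
  bad <- character()
  for (cl in cols) {
    tol <- if (cl %in% c("def3", "def6"))
      20 * log10(1 + rel) + printed$halfUlp[, cl]
    else rel * abs(printed$values[[cl]]) + printed$halfUlp[, cl]
    dev <- abs(computed[[cl]] - printed$values[[cl]])
    idx <- which(dev > tol)
    if (length(idx))
      bad <- c(bad, sprintf("%s psc=%g sigma=%g: %.4g vs %.4g", cl,
                            printed$values$psc[idx],
                            printed$values$sigma_N[idx],
                            computed[[cl]][idx],
                            printed$values[[cl]][idx]))
  }
  bad
}
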