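# Post-WGD fractionation statistics: loss-run spectra with geometric fits,
# sliding-window retention, window-difference testing, and the P-index.

#' Extract loss runs from an alignment-table column
#'
#' Maximal runs of consecutive absence marks along the reference gene
#' order; runs never span chromosome boundaries.
#'
#' @param tab an [AlignmentTable-class].
#' @param column name of the query subgenome column.
#' @return list of class `RunLengthSpectrum`: `counts` (named integer,
#'   run length -> number of runs), `n_runs`, `runs` (data.frame `chrom`,
#'   `start`, `length`), plus `p_hat`/`chisq`/`df`/`p_value` filled by
#'   [fitGeometric()].
#' @export
lossRuns <- function(tab, column) {
  tt <- tab@table
  if (!column %in% names(tt)) stop("no column '", column, "' in the table")
  runs <- list()
  for (ch in unique(tt$chrom)) {
    sub <- tt[tt$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    r <- rle(sub[[column]] == ".")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = ch, start = sub$ordinal[starts[k]], length = r$lengths[k],
        stringsAsFactors = FALSE)
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(chrom = character(), start = integer(), length = integer())
  counts <- table(factor(runs$length,
                         levels = seq_len(max(c(runs$length, 0L)))))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n_runs = nrow(runs), runs = runs,
                 p_hat = NA_real_, chisq = NA_real_, df = NA_integer_,
                 p_value = NA_real_),
            class = "RunLengthSpectrum")
}

#' Run-length spectrum from explicit run lengths
#'
#' Convenience constructor (e.g. for simulator truth ledgers).
#' @param lengths integer vector of run lengths (all >= 1).
#' @return a `RunLengthSpectrum` as in [lossRuns()].
#' @export
runSpectrum <- function(lengths) {
  stopifnot(all(lengths >= 1))
  counts <- table(factor(lengths, levels = seq_len(max(c(lengths, 0L)))))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n_runs = length(lengths),
                 runs = data.frame(chrom = NA_character_, start = NA_integer_,
                                   length = as.integer(lengths)),
                 p_hat = NA_real_, chisq = NA_real_, df = NA_integer_,
                 p_value = NA_real_),
            class = "RunLengthSpectrum")
}

#' @export
print.RunLengthSpectrum <- function(x, ...) {
  cat("RunLengthSpectrum:", x$n_runs, "runs,",
      sum(x$counts * as.integer(names(x$counts))), "lost genes\n")
  if (is.finite(x$p_hat))
    cat(sprintf("  geometric fit: p_hat = %.3f, chi-square %.2f (df %d), p = %.3g\n",
                x$p_hat, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Fit a geometric distribution to a run-length spectrum
#'
#' Maximum-likelihood estimate on support \{1, 2, ...\}:
#' `p_hat = n_runs / total lost genes` (the reciprocal mean run length).
#' A chi-square goodness-of-fit statistic is computed after pooling tail
#' cells to an expected count of at least 5 (df = cells - 2, one parameter
#' estimated).
#'
#' @param spectrum a `RunLengthSpectrum` with at least 10 runs.
#' @return the spectrum with `p_hat`, `expected`, `chisq`, `df`, `p_value`
#'   filled in.
#' @export
fitGeometric <- function(spectrum) {
  if (spectrum$n_runs < 10)
    stop("insufficient data: need >= 10 runs for a geometric fit")
  L <- as.integer(names(spectrum$counts))
  cnt <- spectrum$counts
  n <- spectrum$n_runs
  total <- sum(L * cnt)
  p <- n / total
  spectrum$p_hat <- p
  # expected counts over 1..Lmax with the tail mass beyond Lmax pooled in
  expect <- n * p * (1 - p)^(L - 1)
  expect[length(expect)] <- expect[length(expect)] +
    n * (1 - p)^max(L)                      # tail beyond the observed max
  # pool cells from the tail until every cell expects >= 5
  obs <- as.numeric(cnt); exp <- expect
  while (length(exp) > 1 && exp[length(exp)] < 5) {
    k <- length(exp)
    exp[k - 1] <- exp[k - 1] + exp[k]; exp <- exp[-k]
    obs[k - 1] <- obs[k - 1] + obs[k]; obs <- obs[-k]
  }
  spectrum$expected <- expect
  if (length(exp) > 2) {
    spectrum$chisq <- sum((obs - exp)^2 / exp)
    spectrum$df <- length(exp) - 2L
    spectrum$p_value <- stats::pchisq(spectrum$chisq, spectrum$df,
                                      lower.tail = FALSE)
  } else {
    spectrum$chisq <- NA_real_; spectrum$df <- 0L; spectrum$p_value <- NA_real_
  }
  spectrum
}

#' Sliding-window retention rates for two homoeologous subgenome columns
#'
#' Windows of `M` reference genes advanced by `step` genes within each
#' reference chromosome; `A` and `B` are the fractions of the window's
#' reference positions with a retained colinear gene in the respective
#' subgenome column. Chromosomes shorter than `M` are skipped with a
#' warning.
#'
#' @param tab an [AlignmentTable-class].
#' @param columnA,columnB the two subgenome column names.
#' @param M window size in genes (default 100).
#' @param step step in genes (default 1).
#' @return list of class `RetentionWindows`: `windows` (data.frame
#'   `chrom`, `start`, `A`, `B`), `M`, `step`, `columns`.
#' @export
retentionWindows <- function(tab, columnA, columnB, M = 100, step = 1) {
  tt <- tab@table
  stopifnot(columnA %in% names(tt), columnB %in% names(tt), M >= 1, step >= 1)
  res <- list()
  for (ch in unique(tt$chrom)) {
    sub <- tt[tt$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    n <- nrow(sub)
    if (n < M) {
      warning("chromosome '", ch, "' spans ", n, " genes < window M = ", M,
              "; skipped")
      next
    }
    a <- cumsum(c(0L, sub[[columnA]] != "."))
    b <- cumsum(c(0L, sub[[columnB]] != "."))
    starts <- seq(1L, n - M + 1L, by = step)
    res[[ch]] <- data.frame(
      chrom = ch, start = sub$ordinal[starts],
      A = (a[starts + M] - a[starts]) / M,
      B = (b[starts + M] - b[starts]) / M,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no chromosome spans the window size M = ", M)
  structure(list(windows = do.call(rbind, res), M = as.integer(M),
                 step = as.integer(step), columns = c(columnA, columnB)),
            class = "RetentionWindows")
}

#' @export
print.RetentionWindows <- function(x, ...) {
  cat("RetentionWindows:", nrow(x$windows), "windows of", x$M,
      "genes (step", x$step, ") over",
      length(unique(x$windows$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Fraction of windows without a significant retention difference
#'
#' A window counts as "not significantly different" when the absolute
#' retention difference is below `delta` (default 5 percentage points) or
#' the two-proportion chi-square test on the retained counts (out of M) is
#' not significant at `alpha`. Both criteria are also reported separately.
#'
#' @param rw a [retentionWindows()] result.
#' @param delta absolute retention-difference threshold (default 0.05).
#' @param alpha significance level (default 0.05).
#' @return list: `fraction` (overall), `per_chrom` (named), `n_windows`,
#'   `fraction_delta_only`, `fraction_test_only`.
#' @export
windowDifferenceTest <- function(rw, delta = 0.05, alpha = 0.05) {
  w <- rw$windows
  M <- rw$M
  xa <- round(w$A * M); xb <- round(w$B * M)
  # two-proportion chi-square (prop.test without continuity correction),
  # vectorized
  phat <- (xa + xb) / (2 * M)
  se2 <- phat * (1 - phat) * (2 / M)
  z2 <- ifelse(se2 > 0, (w$A - w$B)^2 / se2, 0)
  pval <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
  small <- abs(w$A - w$B) < delta
  nsig <- pval >= alpha
  ok <- small | nsig
  list(fraction = mean(ok),
       per_chrom = vapply(split(ok, w$chrom), mean, 0),
       n_windows = nrow(w),
       fraction_delta_only = mean(small),
       fraction_test_only = mean(nsig))
}

#' The P-index: quantifying divergence in subgenome fractionation
#'
#' For window i of a homoeologous chromosome pair with retention rates
#' `A_i`, `B_i`: the relative difference is
#' `d_i = |A_i - B_i| / (0.5 (A_i + B_i))` (0 when both rates are 0), a
#' window is included (`delta_i = 1`) iff `low < d_i < high`, and each
#' chromosome contributes the absolute mean sign of `A_i - B_i` over its
#' included windows, weighted by its share of windows
#' `W_C = N_C / sum(N_c)`. The resulting index lies in \[0, 1\]: 0 means
#' balanced fractionation (autopolyploid-like), 1 a fully dominant
#' subgenome; values above 0.3 diagnose allopolyploidy.
#'
#' @param rw a [retentionWindows()] result covering all homoeologous
#'   chromosome pairs.
#' @param low,high inclusion thresholds on `d_i` (defaults 0.1 and 3; note
#'   `d_i <= 2` by construction, so the upper cutoff is inert at its
#'   default).
#' @return a [PIndexResult-class].
#' @export
pIndex <- function(rw, low = 0.1, high = 3) {
  w <- rw$windows
  rows <- list()
  for (ch in unique(w$chrom)) {
    sub <- w[w$chrom == ch, , drop = FALSE]
    A <- sub$A; B <- sub$B
    d <- ifelse(A + B == 0, 0, abs(A - B) / (0.5 * (A + B)))
    incl <- d > low & d < high
    signs <- sign(A - B)[incl]
    contribution <- if (any(incl)) abs(sum(signs)) / sum(incl) else 0
    rows[[ch]] <- data.frame(
      chrom = ch, n_windows = nrow(sub), included = sum(incl),
      signed_sum = sum(signs), contribution = contribution,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  per$weight <- per$n_windows / sum(per$n_windows)
  p <- sum(per$weight * per$contribution)
  if (all(per$included == 0))
    warning("all windows excluded by the d_i thresholds; P-index is 0")
  new("PIndexResult", p_index = p, per_chrom = per,
      thresholds = c(low = low, high = high))
}
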