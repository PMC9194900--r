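# Loss-run spectra, geometric fits, sliding-window retention, window
# difference testing and the P-index.

# build a tiny AlignmentTable directly from presence patterns
patternTable <- function(..., M = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  tt <- data.frame(chrom = rep("c1", n), ordinal = seq_len(n) - 1L,
                   REF = paste0("r", seq_len(n)), stringsAsFactors = FALSE)
  for (nm in names(cols))
    tt[[nm]] <- ifelse(cols[[nm]], paste0(nm, seq_len(n)), ".")
  new("AlignmentTable", ref_species = "REF", table = tt,
      depths = c(REF = 1L, Q = length(cols)),
      header = paste0(1 + length(cols), "=1+", length(cols)))
}

test_that("loss runs are counted per chromosome along reference order", {
  # pattern G . . G . G -> runs {2:1, 1:1}
  tab <- patternTable(Q.A = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  sp <- lossRuns(tab, "Q.A")
  expect_equal(sp$n_runs, 2L)
  expect_equal(unname(sp$counts[c("1", "2")]), c(1L, 1L))

  full <- patternTable(Q.A = rep(TRUE, 6))
  expect_equal(lossRuns(full, "Q.A")$n_runs, 0L)

  # runs do not span chromosome boundaries
  tt <- patternTable(Q.A = c(TRUE, FALSE, FALSE, TRUE))@table
  tt$chrom <- c("c1", "c1", "c2", "c2")
  tt$ordinal <- c(0L, 1L, 0L, 1L)
  tab2 <- new("AlignmentTable", ref_species = "REF", table = tt,
              depths = c(REF = 1L, Q = 1L), header = "2=1+1")
  sp2 <- lossRuns(tab2, "Q.A")
  expect_equal(sp2$n_runs, 2L)
  expect_true(all(sp2$runs$length == 1L))
})

test_that("loss runs in a simulated column equal the truth ledger exactly", {
  fx <- biasedTableFixture()
  tr <- fx$sim$truth$runs
  for (col in c("N.A", "N.B")) {
    sub <- if (col == "N.A") "NSTA" else "NSTB"
    got <- lossRuns(fx$table, col)
    expect_equal(got$n_runs, sum(tr$subgenome == sub))
    expect_equal(sort(got$runs$length),
                 sort(tr$length[tr$subgenome == sub]))
  }
})

test_that("geometric MLE and goodness of fit behave on closed-form cases", {
  sp1 <- fitGeometric(runSpectrum(rep(1L, 20)))
  expect_equal(sp1$p_hat, 1)

  sp2 <- fitGeometric(runSpectrum(c(1L, 1L, 2L, 4L, rep(1L, 8))))
  expect_equal(sp2$p_hat, 12 / 16)   # 1 / mean run length

  expect_error(fitGeometric(runSpectrum(c(1L, 2L))), "insufficient")

  set.seed(5)
  lens <- rgeom(10000, 0.6) + 1L
  sp3 <- fitGeometric(runSpectrum(lens))
  expect_lt(abs(sp3$p_hat - 0.6), 3 * sqrt(0.6^2 * 0.4 / 10000))
  expect_gt(sp3$p_value, 0.01)
})

test_that("chi-square residuals grow with run length under a non-geometric mix", {
  # long runs over-represented: mixture of geometric and uniform long runs
  set.seed(6)
  lens <- c(rgeom(5000, 0.7) + 1L, sample(4:12, 600, replace = TRUE))
  sp <- fitGeometric(runSpectrum(lens))
  L <- as.integer(names(sp$counts))
  obs <- as.numeric(sp$counts)
  expFull <- sp$n_runs * sp$p_hat * (1 - sp$p_hat)^(L - 1)
  dev <- (obs - expFull) / sqrt(pmax(expFull, 1e-9))
  keep <- expFull > 1
  slope <- stats::coef(stats::lm(dev[keep] ~ L[keep]))[2]
  expect_gt(slope, 0)
})

test_that("retention windows slide within chromosomes", {
  tab <- patternTable(Q.A = rep(TRUE, 120), Q.B = rep(TRUE, 120))
  rw <- retentionWindows(tab, "Q.A", "Q.B", M = 100, step = 1)
  expect_equal(nrow(rw$windows), 21L)   # N_C = span - M + 1
  expect_true(all(rw$windows$A == 1 & rw$windows$B == 1))

  alt <- rep(c(TRUE, FALSE), 60)
  rw2 <- retentionWindows(patternTable(Q.A = alt, Q.B = alt),
                          "Q.A", "Q.B", M = 100)
  expect_true(all(rw2$windows$A == 0.5))

  expect_warning(
    expect_error(retentionWindows(patternTable(Q.A = rep(TRUE, 50),
                                               Q.B = rep(TRUE, 50)),
                                  "Q.A", "Q.B", M = 100),
                 "no chromosome"),
    "skipped")
})

test_that("window difference testing matches prop.test and the 5% rule", {
  tab <- patternTable(Q.A = rep(TRUE, 150), Q.B = rep(TRUE, 150))
  wd <- windowDifferenceTest(retentionWindows(tab, "Q.A", "Q.B"))
  expect_equal(wd$fraction, 1.0)

  opp <- patternTable(Q.A = rep(TRUE, 150), Q.B = rep(FALSE, 150))
  wd0 <- windowDifferenceTest(retentionWindows(opp, "Q.A", "Q.B"))
  expect_equal(wd0$fraction, 0.0)

  # the vectorized two-proportion chi-square equals prop.test
  pt <- stats::prop.test(c(80, 60), c(100, 100), correct = FALSE)$p.value
  phat <- 140 / 200
  z2 <- (0.8 - 0.6)^2 / (phat * (1 - phat) * (2 / 100))
  expect_equal(stats::pchisq(z2, 1, lower.tail = FALSE), pt,
               tolerance = 1e-12)
})

test_that("the P-index formulas evaluate the worked example exactly", {
  rw <- list(windows = data.frame(chrom = "c1", start = 0:3,
                                  A = c(0.8, 0.5, 0.6, 0.6),
                                  B = c(0.4, 0.5, 0.7, 0.3)),
             M = 100L, step = 1L, columns = c("A", "B"))
  class(rw) <- "RetentionWindows"
  res <- pIndex(rw)
  expect_equal(pIndexValue(res), 1 / 3, tolerance = 1e-12)
  expect_equal(res@per_chrom$included, 3L)

  rwEq <- rw; rwEq$windows$B <- rwEq$windows$A
  expect_equal(pIndexValue(suppressWarnings(pIndex(rwEq))), 0)

  rw1 <- rw
  rw1$windows$A <- 0.8; rw1$windows$B <- 0.4
  expect_equal(pIndexValue(pIndex(rw1)), 1)
})

test_that("the P-index stays in [0,1] and is label-symmetric", {
  set.seed(10)
  for (rep in 1:1000) {
    k <- sample(1:3, 1)
    rows <- do.call(rbind, lapply(seq_len(k), function(ci)
      data.frame(chrom = paste0("c", ci), start = 0,
                 A = round(runif(sample(1:8, 1)), 2),
                 B = round(runif(1), 2))))
    rw <- list(windows = rows, M = 100L, step = 1L, columns = c("A", "B"))
    class(rw) <- "RetentionWindows"
    p <- pIndexValue(suppressWarnings(pIndex(rw)))
    expect_gte(p, 0); expect_lte(p, 1)
    rwSwap <- rw
    rwSwap$windows$A <- rw$windows$B; rwSwap$windows$B <- rw$windows$A
    res1 <- suppressWarnings(pIndex(rw))
    res2 <- suppressWarnings(pIndex(rwSwap))
    expect_equal(pIndexValue(res2), p, tolerance = 1e-12)
    expect_equal(res2@per_chrom$signed_sum, -res1@per_chrom$signed_sum)
  }
})

test_that("biased and balanced fractionation separate at the 0.3 threshold", {
  # reduced replicate count here; the full 20+20 study runs in the
  # acceptance suite
  biased <- vapply(1:3, function(s)
    pIndexReplicate(c(0.2, 0.5), seed = s), 0)
  equal <- vapply(4:6, function(s)
    pIndexReplicate(c(0.35, 0.35), seed = s), 0)
  expect_true(all(biased > 0.3))
  expect_true(all(equal < 0.3))

  # window-difference fractions separate the same designs
  fx <- biasedTableFixture()
  rw <- retentionWindows(fx$table, "N.A", "N.B")
  expect_lt(windowDifferenceTest(rw)$fraction, 0.5)
})
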