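# Max-gap chaining against exhaustive enumeration, filter behavior,
# symmetry and monotonicity.

test_that("BLAST tabular reading filters by E-value, best-N and self-hits", {
  fx <- gridFixture(a = 0:4, b = 0:4)
  path <- tempfile(fileext = ".tsv")
  rows <- data.frame(
    q = c("ga0", "ga1", "ga2", "ga2"),
    s = c("gb0", "gb1", "gb2", "gb3"),
    pid = 90, len = 100, mm = 5, go = 0, qs = 1, qe = 100, ss = 1, se = 100,
    ev = c(1e-10, 1e-3, 1e-8, 1e-6), bits = c(200, 180, 150, 120))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  hits <- readBlastHits(path, fx$annA, fx$annB, evalueCutoff = 1e-5)
  expect_equal(nrow(hits), 3L)       # the 1e-3 hit is dropped
  expect_false("gb1" %in% hits$gene_b)

  hits1 <- readBlastHits(path, fx$annA, fx$annB, evalueCutoff = 1e-5,
                         bestN = 1)
  expect_equal(nrow(hits1[hits1$gene_a == "ga2", ]), 1L)
  expect_equal(hits1$gene_b[hits1$gene_a == "ga2"], "gb2")  # higher score

  # malformed file
  writeLines("only\tthree\tcolumns", path)
  expect_error(readBlastHits(path, fx$annA, fx$annB), "malformed")
})

test_that("perfect diagonals chain into one block; short chains filtered", {
  fx <- gridFixture(a = c(0, 2, 4, 6, 8), b = c(0, 2, 4, 6, 8))
  bl <- chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = 50, minAnchors = 4)
  expect_equal(nrow(blocks(bl)), 1L)
  expect_equal(blocks(bl)$orientation, "+")
  expect_equal(blocks(bl)$n_anchors, 5L)

  fx3 <- gridFixture(a = 0:2, b = 0:2)
  bl3 <- chainBlocks(fx3$hits, fx3$annA, fx3$annB, minAnchors = 4)
  expect_equal(length(bl3), 0L)       # "at least four anchor pairs"

  # antidiagonal: one "-" block
  fxm <- gridFixture(a = 0:4, b = 4:0)
  blm <- chainBlocks(fxm$hits, fxm$annA, fxm$annB, minAnchors = 4)
  expect_equal(blocks(blm)$orientation, "-")

  expect_equal(length(chainBlocks(fx$hits[0, ], fx$annA, fx$annB)), 0L)
})

test_that("gap constraint splits chains", {
  fx <- gridFixture(a = c(0:3, 10:13), b = c(0:3, 10:13))
  bl <- chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = 3, minAnchors = 4)
  expect_equal(nrow(blocks(bl)), 2L)
  bl50 <- chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = 50, minAnchors = 4)
  expect_equal(nrow(blocks(bl50)), 1L)
  expect_equal(blocks(bl50)$n_anchors, 8L)
})

test_that("chaining equals exhaustive maximal-chain extraction", {
  for (rep in 1:12) {
    set.seed(100 + rep)
    n <- sample(8:16, 1)
    gridN <- sample(10:15, 1)
    a <- sample(0:(gridN - 1), n, replace = TRUE)
    b <- sample(0:(gridN - 1), n, replace = TRUE)
    dup <- duplicated(paste(a, b))
    a <- a[!dup]; b <- b[!dup]
    maxGap <- sample(c(2, 4, 50), 1)
    fx <- gridFixture(a, b, nA = gridN, nB = gridN)
    bl <- chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = maxGap,
                      minAnchors = 2)
    oracle <- chainOracle(a, b, maxGap, minAnchors = 2)
    got <- list(plus = list(), minus = list())
    for (id in blocks(bl)$block_id) {
      an <- anchors(bl)[anchors(bl)$block_id == id, ]
      ori <- blocks(bl)$orientation[blocks(bl)$block_id == id]
      key <- if (ori == "+") "plus" else "minus"
      got[[key]][[length(got[[key]]) + 1L]] <-
        paste(an$ordinal_a, an$ordinal_b, sep = ",")
    }
    exp <- lapply(oracle, function(side) lapply(side, function(ch)
      paste(a[ch], b[ch], sep = ",")))
    expect_equal(got$plus, exp$plus,
                 info = paste("plus blocks differ, rep", rep))
    expect_equal(got$minus, exp$minus,
                 info = paste("minus blocks differ, rep", rep))
  }
})

test_that("chaining is symmetric under transposition", {
  # the chaining objective (anchor count, then total gap) is symmetric;
  # equal-score ties are broken lexicographically, which is directional,
  # so symmetry is asserted at the level of block summaries
  for (rep in 1:8) {
    set.seed(200 + rep)
    n <- 10
    a <- sample(0:11, n)
    b <- sample(0:11, n)
    fx <- gridFixture(a, b, nA = 12, nB = 12)
    bl1 <- chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = 5, minAnchors = 3)
    hitsT <- data.frame(gene_a = fx$hits$gene_b, gene_b = fx$hits$gene_a,
                        score = 100, evalue = 1e-20)
    bl2 <- chainBlocks(hitsT, fx$annB, fx$annA, maxGap = 5, minAnchors = 3)
    summarySet <- function(bl) {
      blk <- blocks(bl)
      an <- anchors(bl)
      gapOf <- function(id) {
        aa <- an[an$block_id == id, ]
        sum(abs(diff(aa$ordinal_a)) - 1L) + sum(abs(diff(aa$ordinal_b)) - 1L)
      }
      sort(paste(blk$orientation, blk$n_anchors,
                 vapply(blk$block_id, gapOf, 0)))
    }
    expect_equal(summarySet(bl1), summarySet(bl2))
    expect_equal(nrow(anchors(bl1)), nrow(anchors(bl2)))
  }
})

test_that("more permissive parameters never shrink the chains", {
  set.seed(42)
  a <- sample(0:14, 20, replace = TRUE)
  b <- sample(0:14, 20, replace = TRUE)
  dup <- duplicated(paste(a, b)); a <- a[!dup]; b <- b[!dup]
  fx <- gridFixture(a, b, nA = 15, nB = 15)
  nAnchors <- function(maxGap, minAnchors)
    nrow(anchors(chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = maxGap,
                             minAnchors = minAnchors)))
  prev <- -1
  for (g in c(1, 2, 4, 8, 50)) {
    cur <- nAnchors(g, 2)
    expect_gte(cur, prev)
    prev <- cur
  }
  nBlocks <- function(minAnchors)
    nrow(blocks(chainBlocks(fx$hits, fx$annA, fx$annB, maxGap = 4,
                            minAnchors = minAnchors)))
  prevB <- Inf
  for (m in c(2, 3, 4, 6)) {
    cur <- nBlocks(m)
    expect_lte(cur, prevB)
    prevB <- cur
  }
})

test_that("a lossless simulated tetraploid self-comparison anchors every paralog pair", {
  scn <- wgdScenario("(S:10,O:10);",
                     events = list(wgdEvent("W", 2, branch = "S", at = 5,
                                            loss_prob = c(0, 0))),
                     nChromosomes = 2, genesPerChromosome = 120,
                     codonsPerGene = 5, ksPerMyr = 0.001, seed = 11,
                     evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  S <- sim$genomes$S
  hits <- truthHits(S, S)
  bl <- chainBlocks(hits, S, S)
  expect_equal(nrow(anchors(bl)), nrow(hits))   # every pair in some block
  expect_equal(blockCoverage(bl, S), 1.0)
  expect_equal(blockCoverage(chainBlocks(hits[0, ], S, S), S), 0.0)
})

test_that("the identity diagonal is masked in self-comparisons", {
  g <- generateAncestor(1, 60, 5, seed = 12, withCds = FALSE)
  gg <- genes(g)
  # fake hits of every gene against itself plus a shifted paralogy
  hits <- data.frame(gene_a = gg$gene_id, gene_b = gg$gene_id,
                     score = 100, evalue = 1e-30)
  bl <- chainBlocks(hits, g, g)
  expect_equal(length(bl), 0L)        # self-hits dropped entirely
})

test_that("dot plots render to file for empty and non-empty inputs", {
  fx <- gridFixture(a = 0:5, b = 0:5)
  bl <- chainBlocks(fx$hits, fx$annA, fx$annB, minAnchors = 4)
  f1 <- tempfile(fileext = ".png")
  dotplotBlocks(bl, fx$annA, fx$annB, file = f1)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  blEmpty <- chainBlocks(fx$hits[0, ], fx$annA, fx$annB)
  f2 <- tempfile(fileext = ".png")
  dotplotBlocks(blEmpty, fx$annA, fx$annB, file = f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
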