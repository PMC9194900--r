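# Genome-evolution simulator: bookkeeping, determinism, targeted Ks
# divergence, WGD fractionation and scenario truth.

test_that("ancestral genome generation respects counts and determinism", {
  g <- generateAncestor(1, 10, 100, seed = 1)
  expect_equal(length(g), 10L)
  expect_true(all(Biostrings::width(cds(g)) == 300))
  expect_true(all(startsWith(as.character(cds(g)), "ATG")))

  g2 <- generateAncestor(7, 200, 150, seed = 2)
  expect_equal(length(g2), 1400L)

  expect_identical(generateAncestor(2, 20, 50, seed = 9),
                   generateAncestor(2, 20, 50, seed = 9))
  expect_error(generateAncestor(0, 10, 10, seed = 1), "counts")
})

test_that("generated CDS have no internal stop codons", {
  g <- generateAncestor(1, 50, 80, seed = 3)
  aa <- as.character(Biostrings::translate(cds(g)))
  expect_false(any(grepl("\\*", aa)))
})

test_that("lineage divergence hits its Ks target and preserves gene order", {
  g <- generateAncestor(1, 1000, 100, seed = 5)
  expect_identical(evolveLineage(g, 0), g)
  expect_error(evolveLineage(g, 2.5), "saturation")

  codsp <- function(s) substring(s, 3 * (1:100) - 2, 3 * (1:100))
  for (target in c(0.1, 0.5, 1.0)) {
    g2 <- evolveLineage(g, target, seed = 7)
    expect_identical(genes(g2), genes(g))
    ks <- vapply(seq_len(1000), function(i)
      neiGojobori(list(a = codsp(as.character(cds(g)[[i]])),
                       b = codsp(as.character(cds(g2)[[i]]))))$ks, 0)
    m <- mean(ks, na.rm = TRUE)
    se <- stats::sd(ks, na.rm = TRUE) / sqrt(sum(is.finite(ks)))
    expect_lt(abs(m - target), 3 * se)
    # the spec bands for the frozen examples
    if (target == 0.5) expect_true(m > 0.45 && m < 0.55)
    if (target == 1.0) expect_true(m > 0.9 && m < 1.1)
  }
})

test_that("whole-genome duplication duplicates and fractionates exactly", {
  g <- generateAncestor(2, 200, 10, seed = 4)
  res0 <- applyWgd(g, wgdEvent("W", 2, branch = "x", at = 10,
                               loss_prob = c(0, 0)), seed = 1)
  expect_equal(length(res0$genome), 2L * length(g))

  res <- applyWgd(g, wgdEvent("W", 2, branch = "x", at = 10,
                              loss_prob = c(0.3, 0.3)), seed = 1)
  # gene-count conservation: after = multiplicity x before - recorded losses
  expect_equal(length(res$genome),
               2L * length(g) - nrow(res$truth$losses))
  # recorded run lengths partition the losses
  expect_equal(sum(res$truth$runs$length), nrow(res$truth$losses))
})

test_that("per-subgenome retention matches the loss budgets", {
  g <- generateAncestor(2, 5000, 1, seed = 6, withCds = FALSE)
  res <- applyWgd(g, wgdEvent("W", 2, branch = "x", at = 10, mode = "allo",
                              loss_prob = c(0.3, 0.3)), seed = 2)
  par <- res$truth$parents
  kept <- tapply(par$retained, par$subgenome, mean)
  expect_true(all(abs(kept - 0.7) < 0.02))

  res2 <- applyWgd(g, wgdEvent("W", 2, branch = "x", at = 10, mode = "allo",
                               loss_prob = c(0.2, 0.5)), seed = 3)
  par2 <- res2$truth$parents
  kept2 <- tapply(par2$retained, par2$subgenome, mean)
  # subgenome retention ranks follow the loss probabilities
  expect_gt(kept2[["WA"]], kept2[["WB"]])
})

test_that("simulator loss runs are geometric and non-adjacent", {
  g <- generateAncestor(1, 30000, 1, seed = 8, withCds = FALSE)
  res <- applyWgd(g, wgdEvent("W", 2, branch = "x", at = 10,
                              loss_prob = c(0.4, 0), run_p = 0.6), seed = 9)
  sp <- fitGeometric(runSpectrum(res$truth$runs$length))
  expect_gt(sum(res$truth$runs$length), 10000)
  expect_lt(abs(sp$p_hat - 0.6), 3 * sqrt(0.6^2 * 0.4 / sp$n_runs))
  expect_gt(sp$p_value, 0.01)
})

test_that("scenario composition yields correct homolog counts and truth", {
  # two species, one shared tetraploidy, no loss: every ancestral gene has
  # exactly two descendants per species
  scn <- wgdScenario("((A:10,B:10)anc:5);",
                     events = list(wgdEvent("SH", 2, branch = "anc", at = 12,
                                            loss_prob = c(0, 0))),
                     nChromosomes = 1, genesPerChromosome = 50,
                     codonsPerGene = 5, ksPerMyr = 0.001, seed = 2)
  sim <- simulateScenario(scn)
  for (sp in c("A", "B")) {
    cnt <- table(table(genes(sim$genomes[[sp]])$ancestor_id))
    expect_equal(names(cnt), "2")
  }

  # true peak arithmetic: tetraploidy at 62 Mya, terminal rate 0.7,
  # ksPerMyr chosen so the expected paralog peak is 0.49
  sim2 <- simulateScenario(scenarioPreset("nst_like", seed = 3,
                                          genesPerChromosome = 30,
                                          evolveSequences = FALSE))
  ev <- sim2$truth$events
  expect_equal(ev$true_peak[ev$event == "NST"], 0.49, tolerance = 1e-9)
  # hexaploidy multiplies gene content by 3 before loss
  scn3 <- wgdScenario("(H:10,D:10);",
                      events = list(wgdEvent("HX", 3, branch = "H", at = 5,
                                             loss_prob = c(0, 0, 0))),
                      nChromosomes = 1, genesPerChromosome = 40,
                      codonsPerGene = 5, ksPerMyr = 0.001, seed = 4)
  sim3 <- simulateScenario(scn3)
  expect_equal(length(sim3$genomes$H), 120L)
  expect_equal(length(sim3$genomes$D), 40L)
})

test_that("scenarios are deterministic and reject unknown branches", {
  scn <- scenarioPreset("nst_like", seed = 5, genesPerChromosome = 40,
                        codonsPerGene = 10)
  s1 <- simulateScenario(scn)
  s2 <- simulateScenario(scn)
  expect_identical(lapply(s1$genomes, genes), lapply(s2$genomes, genes))
  expect_identical(lapply(s1$genomes, function(g) as.character(cds(g))),
                   lapply(s2$genomes, function(g) as.character(cds(g))))

  expect_error(
    wgdScenario("(A:10,B:10);",
                events = list(wgdEvent("W", 2, branch = "nope", at = 5))),
    "unknown branch")
})

test_that("realized paralog Ks matches the recorded true peak", {
  sim <- nstFixture()
  gs <- sim$genomes
  bl <- chainBlocks(truthHits(gs$N, gs$N), gs$N, gs$N)
  bl <- blockKs(bl, cds(gs$N))
  ks <- anchors(bl)$ks
  ks <- ks[is.finite(ks)]
  expect_gt(length(ks), 1000)
  truePeak <- sim$truth$events$true_peak[sim$truth$events$event == "NST"]
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - truePeak), 3 * se + 0.01)
})
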