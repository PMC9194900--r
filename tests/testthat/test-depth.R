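# Colinear depth ratios, subgenome assignment and the multi-genome
# alignment table.

test_that("depth ratios reproduce the polyploidy algebra", {
  simE <- simulateScenario(scenarioPreset("ech_like", seed = 3,
                                          evolveSequences = FALSE))
  gs <- simE$genomes
  bl <- chainBlocks(truthHits(gs$T2, gs$H3), gs$T2, gs$H3)
  dr <- depthRatio(bl, gs$T2, gs$H3)
  expect_equal(unname(dr$ratio), c(2L, 3L))   # tetraploid vs hexaploid

  simD <- simulateScenario(scenarioPreset("double_tetra", seed = 4,
                                          evolveSequences = FALSE))
  gd <- simD$genomes
  bl2 <- chainBlocks(truthHits(gd$S, gd$D), gd$S, gd$D)
  dr2 <- depthRatio(bl2, gd$S, gd$D)
  expect_equal(unname(dr2$ratio), c(2L, 4L))  # tetra vs double tetra
  # ratio symmetry
  bl2r <- chainBlocks(truthHits(gd$D, gd$S), gd$D, gd$S)
  dr2r <- depthRatio(bl2r, gd$D, gd$S)
  expect_equal(unname(dr2r$ratio), rev(unname(dr2$ratio)))

  simN <- simulateScenario(scenarioPreset("nst_like", seed = 5,
                                          evolveSequences = FALSE))
  gn <- simN$genomes
  blS <- chainBlocks(truthHits(gn$N, gn$N), gn$N, gn$N)
  drS <- depthRatio(blS, gn$N, gn$N)
  expect_equal(unname(drS$ratio), c(1L, 1L))  # one WGD, losses < 50%
})

test_that("an unshared hexaploidy shows as 1:3 against the outgroup", {
  scn <- wgdScenario("(H:40,D:40);",
                     events = list(wgdEvent("HX", 3, branch = "H", at = 20,
                                            loss_prob = c(0.1, 0.1, 0.1))),
                     nChromosomes = 2, genesPerChromosome = 300,
                     codonsPerGene = 5, ksPerMyr = 0.002, seed = 6,
                     evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  bl <- chainBlocks(truthHits(sim$genomes$D, sim$genomes$H),
                    sim$genomes$D, sim$genomes$H)
  dr <- depthRatio(bl, sim$genomes$D, sim$genomes$H)
  expect_equal(unname(dr$ratio), c(1L, 3L))
})

test_that("subgenome assignment recovers dominance from biased loss", {
  scn <- wgdScenario("(Q:100,R:100);",
                     events = list(wgdEvent("W", 2, branch = "Q", at = 60,
                                            mode = "allo",
                                            loss_prob = c(0.2, 0.5),
                                            run_p = 0.6)),
                     nChromosomes = 2, genesPerChromosome = 2500,
                     codonsPerGene = 5, ksPerMyr = 0.004, seed = 13,
                     evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  gs <- sim$genomes
  bl <- chainBlocks(truthHits(gs$Q, gs$R), gs$Q, gs$R)
  asg <- assignSubgenomes(bl, gs$R, gs$Q, m = 2)
  expect_false(asg$ties)
  # map every anchored query gene to its assigned subgenome and compare
  # with the simulator's truth labels
  an <- anchors(bl)
  an$sub <- asg$fragments$subgenome[match(an$block_id,
                                          asg$fragments$block_id)]
  qg <- genes(gs$Q)
  truthSub <- qg$subgenome[match(an$gene_a, qg$gene_id)]
  # subgenome "A" (dominant) should be the low-loss truth label WA
  agree <- mean((an$sub == "A") == (truthSub == "WA"))
  expect_gte(agree, 0.95)
  # dominance classes present
  expect_setequal(unique(asg$summary$class), c("dominant", "sensitive"))
})

test_that("a hexaploid query is partitioned into three subgenomes", {
  scn <- wgdScenario("(H:40,D:40);",
                     events = list(wgdEvent("HX", 3, branch = "H", at = 20,
                                            loss_prob = c(0.1, 0.2, 0.3))),
                     nChromosomes = 1, genesPerChromosome = 800,
                     codonsPerGene = 5, ksPerMyr = 0.002, seed = 7,
                     evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  bl <- chainBlocks(truthHits(sim$genomes$H, sim$genomes$D),
                    sim$genomes$H, sim$genomes$D)
  asg <- assignSubgenomes(bl, sim$genomes$D, sim$genomes$H, m = 3)
  expect_equal(sort(unique(asg$fragments$subgenome)), c("A", "B", "C"))
})

test_that("lossless tables have no absence marks and full cell counts", {
  scn <- wgdScenario("(Q:50,R:50);",
                     events = list(wgdEvent("W", 2, branch = "Q", at = 25,
                                            loss_prob = c(0, 0))),
                     nChromosomes = 2, genesPerChromosome = 200,
                     codonsPerGene = 5, ksPerMyr = 0.002, seed = 8,
                     evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  gs <- sim$genomes
  bl <- chainBlocks(truthHits(gs$Q, gs$R), gs$Q, gs$R)
  tab <- buildAlignmentTable(gs$R, list(list(ann = gs$Q, blocks = bl,
                                             depth = 2)))
  tt <- alignmentCells(tab)
  expect_equal(sum(tt$Q.A == "."), 0L)
  expect_equal(sum(tt$Q.B == "."), 0L)
  expect_equal(nrow(tt), 400L)
  expect_equal(tab@header, "3=1+2")
})

test_that("absence marks equal the simulated losses exactly", {
  fx <- biasedTableFixture()
  tt <- alignmentCells(fx$table)
  led <- fx$sim$truth$ledger
  lostPerSub <- tapply(!led$retained, led$subgenome, sum)
  absences <- c(sum(tt$N.A == "."), sum(tt$N.B == "."))
  # column A is the dominant (low-loss) subgenome
  expect_equal(sort(absences), sort(unname(lostPerSub)))
  # table conservation: non-absent cells = retained genes in the ledger
  expect_equal(sum(tt$N.A != ".") + sum(tt$N.B != "."),
               sum(led$retained))
})

test_that("the alignment-table header records the expected column arithmetic", {
  scn <- wgdScenario(
    "(Q1:100,Q2:100,Q3:100,Q4:100,P1:100,P2:100,R:100);",
    events = list(
      wgdEvent("T1", 2, branch = "Q1", at = 50, loss_prob = c(0.05, 0.1)),
      wgdEvent("T2", 2, branch = "Q2", at = 50, loss_prob = c(0.05, 0.1)),
      wgdEvent("T3", 2, branch = "Q3", at = 50, loss_prob = c(0.05, 0.1)),
      wgdEvent("T4", 2, branch = "Q4", at = 50, loss_prob = c(0.05, 0.1)),
      wgdEvent("PA", 2, branch = "P1", at = 70, loss_prob = c(0.05, 0.1)),
      wgdEvent("PB", 2, branch = "P1", at = 30, loss_prob = c(0.05, 0.1)),
      wgdEvent("PC", 2, branch = "P2", at = 70, loss_prob = c(0.05, 0.1)),
      wgdEvent("PD", 2, branch = "P2", at = 30, loss_prob = c(0.05, 0.1)),
      wgdEvent("HX", 3, branch = "R", at = 60,
               loss_prob = c(0.05, 0.1, 0.1))),
    nChromosomes = 2, genesPerChromosome = 150, codonsPerGene = 5,
    ksPerMyr = 0.002, seed = 9, evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  gs <- sim$genomes
  mkBl <- function(a, b) chainBlocks(truthHits(a, b), a, b)
  queries <- list(
    list(ann = gs$Q1, blocks = mkBl(gs$Q1, gs$R), depth = 2),
    list(ann = gs$Q2, blocks = mkBl(gs$Q2, gs$R), depth = 2),
    list(ann = gs$Q3, blocks = mkBl(gs$Q3, gs$R), depth = 2),
    list(ann = gs$Q4, blocks = mkBl(gs$Q4, gs$R), depth = 2),
    list(ann = gs$P1, blocks = mkBl(gs$P1, gs$R), depth = 4),
    list(ann = gs$P2, blocks = mkBl(gs$P2, gs$R), depth = 4))
  tab <- buildAlignmentTable(gs$R, queries,
                             selfBlocks = mkBl(gs$R, gs$R), refDepth = 3)
  expect_equal(tab@header, "19=3+2+2+2+2+4+4")
  expect_equal(ncol(alignmentCells(tab)) - 2L, 19L)
  expect_equal(sum(expectedDepths(tab)), 19L)
})

test_that("local alignment views render", {
  fx <- biasedTableFixture()
  f <- tempfile(fileext = ".png")
  localAlignmentView(fx$table, chrom = "chr01", from = 0, to = 80, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
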