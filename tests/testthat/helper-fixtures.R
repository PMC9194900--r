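# Shared simulation fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# lineage-specific tetraploidy with biased loss and a slow lineage,
# sequences evolved; true paralog peak 0.49, >= 1000 retained anchor pairs
nstFixture <- function() {
  if (is.null(.fixtures$nst)) {
    scn <- scenarioPreset("nst_like", seed = 42, genesPerChromosome = 1000,
                          nChromosomes = 2, codonsPerGene = 100)
    .fixtures$nst <- simulateScenario(scn)
  }
  .fixtures$nst
}

# gene-order-only tetraploid vs diploid, used by table/fractionation tests
biasedTableFixture <- function() {
  if (is.null(.fixtures$btab)) {
    sim <- simulateScenario(scenarioPreset(
      "nst_like", seed = 7, genesPerChromosome = 600, nChromosomes = 2,
      evolveSequences = FALSE))
    gs <- sim$genomes
    bl <- chainBlocks(truthHits(gs$N, gs$V), gs$N, gs$V)
    tab <- buildAlignmentTable(gs$V, list(list(ann = gs$N, blocks = bl,
                                               depth = 2)))
    .fixtures$btab <- list(sim = sim, blocks = bl, table = tab)
  }
  .fixtures$btab
}

# one allo/auto-style P-index replicate at the package's separation design
pIndexReplicate <- function(lossProb, seed, genesPerChromosome = 6000,
                            nChromosomes = 6) {
  scn <- wgdScenario(
    "(Q:100,R:100);",
    events = list(wgdEvent("W", 2, branch = "Q", at = 60,
                           mode = if (diff(range(lossProb)) > 0) "allo"
                                  else "auto",
                           loss_prob = lossProb, run_p = 0.6)),
    nChromosomes = nChromosomes, genesPerChromosome = genesPerChromosome,
    codonsPerGene = 10, ksPerMyr = 0.004, seed = seed,
    evolveSequences = FALSE)
  sim <- simulateScenario(scn)
  gs <- sim$genomes
  bl <- chainBlocks(truthHits(gs$Q, gs$R), gs$Q, gs$R)
  tab <- buildAlignmentTable(gs$R, list(list(ann = gs$Q, blocks = bl,
                                             depth = 2)))
  rw <- retentionWindows(tab, "Q.A", "Q.B")
  pIndexValue(pIndex(rw))
}
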