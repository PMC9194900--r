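# Genome-evolution simulator: ancestral genome generation, sequence
# divergence targeted in Ks units, whole-genome duplication with run-length
# fractionation, and scenario composition along a dated species tree.
# Every stochastic step feeds from the R RNG so a single seed fixes a run.

#' Describe a whole-genome duplication event for simulation
#'
#' @param name event label (e.g. `"NST"`).
#' @param multiplicity integer >= 2; 2 = tetraploidy, 3 = hexaploidy.
#' @param branch label of the species-tree branch carrying the event
#'   (the tip or internal-node label at the branch's descendant end).
#' @param at age of the event in Mya; must lie on the branch.
#' @param mode `"auto"` or `"allo"` (bookkeeping label; the loss
#'   probabilities, not the mode, drive biased fractionation).
#' @param loss_prob per-subgenome per-gene loss probabilities in \[0,1),
#'   one per copy set.
#' @param run_p geometric parameter in (0,1\] for loss run lengths
#'   (mean run length 1/run_p).
#' @return a `WgdEvent` (list).
#' @export
wgdEvent <- function(name, multiplicity, branch, at, mode = c("auto", "allo"),
                     loss_prob = rep(0, multiplicity), run_p = 0.6) {
  mode <- match.arg(mode)
  multiplicity <- as.integer(multiplicity)
  stopifnot(multiplicity >= 2L,
            length(loss_prob) == multiplicity,
            all(loss_prob >= 0 & loss_prob < 1),
            run_p > 0, run_p <= 1,
            is.numeric(at), at > 0)
  structure(list(name = name, multiplicity = multiplicity, branch = branch,
                 at = at, mode = mode, loss_prob = loss_prob, run_p = run_p),
            class = "WgdEvent")
}

#' Generate a random ancestral genome
#'
#' Genes are laid out in ordinal order on each chromosome; each CDS starts
#' with ATG followed by random non-stop codons (in frame, no internal stops).
#'
#' @param nChromosomes,genesPerChromosome,codonsPerGene positive integers.
#' @param seed integer seed; same seed gives byte-identical output.
#' @param species label for the genome (default `"ancestor"`).
#' @param withCds generate coding sequences (disable for gene-order-only
#'   studies).
#' @return a [GenomeAnnotation-class] with CDS.
#' @export
generateAncestor <- function(nChromosomes, genesPerChromosome, codonsPerGene,
                             seed, species = "ancestor", withCds = TRUE) {
  if (nChromosomes < 1 || genesPerChromosome < 1 || codonsPerGene < 1)
    stop("all counts must be >= 1")
  set.seed(seed)
  tab <- codonTables()
  nonStop <- setdiff(seq_len(64L), tab$stops)
  ng <- nChromosomes * genesPerChromosome
  chrom <- rep(sprintf("chr%02d", seq_len(nChromosomes)),
               each = genesPerChromosome)
  ordinal <- rep(seq_len(genesPerChromosome) - 1L, nChromosomes)
  gid <- sprintf("anc_%s_g%05d", chrom, ordinal + 1L)
  cds <- Biostrings::DNAStringSet()
  if (withCds) {
    atg <- codonIndex("ATG")
    idx <- matrix(sample(nonStop, ng * codonsPerGene, replace = TRUE),
                  nrow = ng)
    idx[, 1] <- atg
    seqs <- apply(idx, 1L, function(i) paste0(tab$codons[i], collapse = ""))
    cds <- Biostrings::DNAStringSet(seqs)
    names(cds) <- gid
  }
  g <- data.frame(gene_id = gid, chrom = chrom, ordinal = ordinal,
                  strand = "+", ancestor_id = gid, subgenome = "",
                  stringsAsFactors = FALSE)
  GenomeAnnotation(species, g, cds)
}

# Jukes-Cantor inversion: expected substitutions per site -> per-site
# difference probability.
.jcP <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Diverge a genome's coding sequences by a target Ks
#'
#' Applies synonymous and nonsynonymous single-nucleotide substitutions,
#' codon position by codon position, so that the expected pairwise
#' Nei-Gojobori Ks between input and output equals `ksTarget` (the
#' Jukes-Cantor inversion converts the target into a per-synonymous-site
#' change probability; nonsynonymous changes are applied analogously at
#' `kaKsRatio * ksTarget` and never create stop codons). Gene order is
#' untouched.
#'
#' @param genome a [GenomeAnnotation-class] with CDS.
#' @param ksTarget expected Ks between input and output, in \[0, 2\];
#'   larger values are refused as saturated.
#' @param seed optional integer; when `NULL` the current RNG stream is used
#'   (as inside [simulateScenario()]).
#' @param kaKsRatio target Ka/Ks (default 0.3).
#' @return the diverged [GenomeAnnotation-class].
#' @export
evolveLineage <- function(genome, ksTarget, seed = NULL, kaKsRatio = 0.3) {
  if (ksTarget < 0) stop("ksTarget must be >= 0")
  if (ksTarget > 2) stop("ksTarget beyond saturation guard (Ks > 2)")
  if (ksTarget == 0) return(genome)
  if (!is.null(seed)) set.seed(seed)
  tab <- codonTables()
  ps <- .jcP(ksTarget)
  pn <- .jcP(kaKsRatio * ksTarget)

  s <- as.character(genome@cds)
  ncod <- nchar(s) %/% 3L
  big <- paste0(s, collapse = "")
  tot <- sum(ncod)
  starts <- 3L * (seq_len(tot) - 1L) + 1L
  idx <- codonIndex(substring(big, starts, starts + 2L))

  # synonymous pass: at each position, change to a random synonymous
  # alternative with probability ps x (synonymous site fraction), so the
  # expected synonymous difference count per codon is ps x s exactly
  synChanged <- rep(FALSE, tot)
  for (p in 1:3) {
    fs <- tab$synAltCount[cbind(idx, p)] / 3
    doSyn <- stats::runif(tot) < ps * fs
    if (any(doSyn)) {
      k <- tab$synAltCount[cbind(idx[doSyn], rep(p, sum(doSyn)))]
      pick <- ceiling(stats::runif(sum(doSyn)) * k)
      idx[doSyn] <- tab$synAlt[cbind(idx[doSyn], rep(p, sum(doSyn)), pick)]
      synChanged <- synChanged | doSyn
    }
  }
  # nonsynonymous pass, restricted to codons without a synonymous change:
  # mixed codons would push the estimator's minimal-path averaging away
  # from the generating counts and bias Ks downward
  for (p in 1:3) {
    fn <- tab$nsynAltCount[cbind(idx, p)] / 3
    doNsyn <- !synChanged & stats::runif(tot) < pn * fn
    if (any(doNsyn)) {
      k <- tab$nsynAltCount[cbind(idx[doNsyn], rep(p, sum(doNsyn)))]
      pick <- ceiling(stats::runif(sum(doNsyn)) * k)
      idx[doNsyn] <- tab$nsynAlt[cbind(idx[doNsyn], rep(p, sum(doNsyn)), pick)]
    }
  }

  codStr <- tab$codons[idx]
  gene <- rep.int(seq_along(ncod), ncod)
  newSeq <- vapply(split(codStr, gene), paste0, "", collapse = "")
  out <- Biostrings::DNAStringSet(unname(newSeq))
  names(out) <- names(genome@cds)
  initialize(genome, cds = out)
}

# Sample loss runs for one copy set: geometric lengths, uniform placement
# among starts whose run (plus a one-gene retained buffer on both sides)
# fits in currently retained genes of one chromosome. Placement draws a
# uniform start and rejects invalid ones (uniform over valid starts); a
# rare exhaustive fallback handles dense endgames. Returns list(lost, runs).
.sampleLossRuns <- function(geneChrom, budget, run_p) {
  n <- length(geneChrom)
  chromLev <- unique(geneChrom)
  chromI <- match(geneChrom, chromLev)
  chromStart <- stats::setNames(match(seq_along(chromLev), chromI), chromLev)
  retained <- rep(TRUE, n)
  runChrom <- character(0); runStart <- integer(0); runLen <- integer(0)
  lost <- 0L
  validAt <- function(s, L) {
    if (chromI[s] != chromI[s + L - 1L]) return(FALSE)
    if (!all(retained[s:(s + L - 1L)])) return(FALSE)
    if (s > 1L && chromI[s - 1L] == chromI[s] && !retained[s - 1L])
      return(FALSE)
    if (s + L <= n && chromI[s + L] == chromI[s] && !retained[s + L])
      return(FALSE)
    TRUE
  }
  allValid <- function(L) {
    ok <- logical(n - L + 1L)
    for (s in seq_len(n - L + 1L)) ok[s] <- validAt(s, L)
    which(ok)
  }
  place <- function(s, L) {
    retained[s:(s + L - 1L)] <<- FALSE
    ch <- chromLev[chromI[s]]
    runChrom <<- c(runChrom, ch)
    runStart <<- c(runStart, s - chromStart[[ch]])   # 0-based ordinal
    runLen <<- c(runLen, L)
    lost <<- lost + L
  }
  while (lost < budget) {
    L <- stats::rgeom(1L, run_p) + 1L
    if (lost + L > budget) L <- budget - lost        # trim final run
    placed <- FALSE
    while (L >= 1L && !placed) {
      for (try in seq_len(200L)) {
        s <- sample.int(n - L + 1L, 1L)
        if (validAt(s, L)) { place(s, L); placed <- TRUE; break }
      }
      if (!placed) {                                 # exhaustive fallback
        cand <- allValid(L)
        if (!length(cand)) { L <- L - 1L; next }
        place(cand[sample.int(length(cand), 1L)], L)
        placed <- TRUE
      }
    }
    if (!placed) break                               # genome too dense to place
  }
  list(lost = which(!retained),
       runs = data.frame(chrom = runChrom, start_ordinal = runStart,
                         length = runLen, stringsAsFactors = FALSE))
}

#' Apply a whole-genome duplication with run-length fractionation
#'
#' Every chromosome is duplicated into `multiplicity` copy sets carrying
#' subgenome labels; each copy set then loses genes in runs of
#' geometric(`run_p`) consecutive genes until its loss budget
#' (`loss_prob * genes`) is met (the final run is trimmed to the budget).
#' Runs are placed with a one-gene retained buffer so recorded runs and the
#' loss pattern visible in downstream alignment columns coincide exactly.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param event a [wgdEvent()].
#' @param seed optional integer (see [evolveLineage()]).
#' @return list with elements `genome` (the post-event annotation) and
#'   `truth` (list: `losses` data.frame, `runs` data.frame, `parents`
#'   data.frame mapping every new gene id to its pre-event parent id and
#'   subgenome).
#' @export
applyWgd <- function(genome, event, seed = NULL) {
  stopifnot(inherits(event, "WgdEvent"))
  if (length(genome) == 0) stop("genome is empty")
  if (!is.null(seed)) set.seed(seed)
  m <- event$multiplicity
  g0 <- genome@genes
  hasCds <- length(genome@cds) > 0

  parents <- list(); newGenes <- list(); newCds <- list()
  losses <- list(); runsAll <- list()
  for (s in seq_len(m)) {
    lab <- paste0(event$name, LETTERS[s])
    gs <- g0
    if (s > 1L) {
      gs$gene_id <- paste0(g0$gene_id, ".", lab)
      gs$chrom <- paste0(g0$chrom, ".", lab)
    }
    gs$subgenome <- ifelse(g0$subgenome == "", lab,
                           paste(g0$subgenome, lab, sep = ";"))
    loss <- .sampleLossRuns(gs$chrom,
                            budget = as.integer(round(event$loss_prob[s] * nrow(gs))),
                            run_p = event$run_p)
    keep <- setdiff(seq_len(nrow(gs)), loss$lost)
    if (length(loss$lost))
      losses[[s]] <- data.frame(gene_id = gs$gene_id[loss$lost],
                                parent_id = g0$gene_id[loss$lost],
                                chrom = gs$chrom[loss$lost],
                                subgenome = lab, event = event$name,
                                stringsAsFactors = FALSE)
    if (nrow(loss$runs)) {
      loss$runs$event <- event$name
      loss$runs$subgenome <- lab
      runsAll[[s]] <- loss$runs
    }
    parents[[s]] <- data.frame(gene_id = gs$gene_id, parent_id = g0$gene_id,
                               subgenome = lab, event = event$name,
                               retained = seq_len(nrow(gs)) %in% keep,
                               stringsAsFactors = FALSE)
    gs <- gs[keep, , drop = FALSE]
    newGenes[[s]] <- gs
    if (hasCds) {
      cc <- genome@cds[g0$gene_id[keep]]
      names(cc) <- gs$gene_id
      newCds[[s]] <- cc
    }
  }
  gg <- do.call(rbind, newGenes)
  # recompute dense 0-based ordinals per chromosome
  gg <- gg[order(gg$chrom, gg$ordinal), , drop = FALSE]
  gg$ordinal <- unlist(lapply(split(gg$ordinal, gg$chrom), seq_along),
                       use.names = FALSE) - 1L
  cdsOut <- if (hasCds) do.call(c, newCds) else Biostrings::DNAStringSet()
  ann <- GenomeAnnotation(genome@species, gg, cdsOut)
  list(genome = ann,
       truth = list(
         losses = if (length(losses)) do.call(rbind, losses) else NULL,
         runs = if (length(runsAll)) do.call(rbind, runsAll) else NULL,
         parents = do.call(rbind, parents)))
}

#' Define a simulation scenario
#'
#' @param tree newick string, rooted, branch lengths in Myr (ultrametric);
#'   internal nodes that carry events or rates must be labelled.
#' @param events list of [wgdEvent()].
#' @param rates named numeric of per-branch rate multipliers, keyed by the
#'   branch's descendant tip/node label; unlisted branches multiply by 1.
#' @param nChromosomes,genesPerChromosome,codonsPerGene ancestral genome
#'   dimensions.
#' @param ksPerMyr baseline synonymous substitutions per site per Myr per
#'   lineage (so a pair diverged T Myr ago peaks at `2 * rate * T * ksPerMyr`).
#' @param seed integer master seed.
#' @param evolveSequences simulate CDS divergence (disable for analyses that
#'   need gene orders only, e.g. fractionation statistics).
#' @return a `WgdScenario` (list).
#' @export
wgdScenario <- function(tree, events = list(), rates = numeric(),
                        nChromosomes = 2, genesPerChromosome = 300,
                        codonsPerGene = 120, ksPerMyr = 0.004, seed = 1,
                        evolveSequences = TRUE) {
  stopifnot(nChromosomes >= 1, genesPerChromosome >= 1, codonsPerGene >= 1,
            ksPerMyr > 0)
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse the species tree")
  labels <- c(phy$tip.label, phy$node.label)
  for (ev in events)
    if (!ev$branch %in% labels)
      stop("WGD event '", ev$name, "' placed on unknown branch '",
           ev$branch, "'")
  structure(list(tree = phy, events = events, rates = rates,
                 nChromosomes = as.integer(nChromosomes),
                 genesPerChromosome = as.integer(genesPerChromosome),
                 codonsPerGene = as.integer(codonsPerGene),
                 ksPerMyr = ksPerMyr, seed = as.integer(seed),
                 evolveSequences = isTRUE(evolveSequences)),
            class = "WgdScenario")
}

# label of the node at the descendant end of the edge into `node`
.nodeLabel <- function(phy, node) {
  nt <- length(phy$tip.label)
  if (node <= nt) phy$tip.label[node]
  else if (!is.null(phy$node.label) && nzchar(phy$node.label[node - nt]))
    phy$node.label[node - nt]
  else paste0("node", node)
}

#' Simulate a full scenario along a species tree
#'
#' Walks the dated species tree from the root, diverging sequences on every
#' branch segment (Ks increment = rate x ksPerMyr x segment length) and
#' applying the scenario's WGD events at their placed ages. Each tip yields
#' one genome; the returned truth records, per event and tip, the expected
#' paralog Ks peak (twice the rate-weighted path length from the event to
#' the tip, times ksPerMyr), the expected divergence Ks for every tip pair,
#' the full gene-fate ledger and all loss runs.
#'
#' @param scenario a [wgdScenario()].
#' @return list: `genomes` (named list of [GenomeAnnotation-class]),
#'   `truth` (list: `events`, `divergences`, `ledger`, `runs`), `scenario`.
#' @export
simulateScenario <- function(scenario) {
  stopifnot(inherits(scenario, "WgdScenario"))
  set.seed(scenario$seed)
  phy <- scenario$tree
  nt <- length(phy$tip.label)
  root <- nt + 1L
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(nt)])
  age <- height - depth                      # Mya before present per node

  anc <- generateAncestor(scenario$nChromosomes, scenario$genesPerChromosome,
                          scenario$codonsPerGene,
                          seed = sample.int(.Machine$integer.max, 1L),
                          withCds = scenario$evolveSequences)

  genomes <- list()
  eventRows <- list(); ledger <- list(); runRows <- list()
  markerStore <- list()                      # tip -> named acc vector

  walk <- function(node, ann, acc) {
    acc[paste0("node:", node)] <- 0
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (!length(kids)) return(NULL)
    for (child in kids) {
      lab <- .nodeLabel(phy, child)
      rate <- if (lab %in% names(scenario$rates)) scenario$rates[[lab]] else 1
      t0 <- age[node]; t1 <- age[child]
      evs <- Filter(function(e) e$branch == lab, scenario$events)
      for (e in evs)
        if (e$at > t0 + 1e-9 || e$at < t1 - 1e-9)
          stop("event '", e$name, "' at ", e$at,
               " Mya lies outside branch '", lab, "' [", t1, ", ", t0, "]")
      evs <- evs[order(vapply(evs, `[[`, 0, "at"), decreasing = TRUE)]
      curAnn <- ann; curAcc <- acc; tCur <- t0
      segment <- function(tEnd) {
        dt <- tCur - tEnd
        if (dt > 1e-9) {
          if (length(curAnn@cds))
            curAnn <<- evolveLineage(curAnn, rate * scenario$ksPerMyr * dt)
          curAcc <<- curAcc + rate * dt
        }
        tCur <<- tEnd
      }
      for (e in evs) {
        segment(e$at)
        res <- applyWgd(curAnn, e)
        curAnn <- res$genome
        curAcc[paste0("event:", e$name)] <- 0
        if (!is.null(res$truth$runs)) {
          res$truth$runs$branch <- lab
          runRows[[length(runRows) + 1L]] <<- res$truth$runs
        }
        res$truth$parents$branch <- lab
        ledger[[length(ledger) + 1L]] <<- res$truth$parents
      }
      segment(t1)
      if (child <= nt) {
        sp <- phy$tip.label[child]
        # species-qualified gene ids: copy-1 genes keep their ancestral id
        # through duplications, so tips must be disambiguated for
        # cross-genome comparisons
        gg <- curAnn@genes
        gg$gene_id <- paste0(sp, "_", gg$gene_id)
        cc <- curAnn@cds
        if (length(cc)) names(cc) <- paste0(sp, "_", names(cc))
        genomes[[sp]] <<- GenomeAnnotation(sp, gg, cc)
        markerStore[[sp]] <<- curAcc
        for (nm in names(curAcc)) {
          if (startsWith(nm, "event:")) {
            evName <- sub("^event:", "", nm)
            e <- Filter(function(x) x$name == evName, scenario$events)[[1]]
            eventRows[[length(eventRows) + 1L]] <<- data.frame(
              event = evName, species = sp, age_mya = e$at,
              true_peak = 2 * scenario$ksPerMyr * curAcc[[nm]],
              stringsAsFactors = FALSE)
          }
        }
      } else {
        walk(child, curAnn, curAcc)
      }
    }
  }
  walk(root, anc, c())

  tips <- phy$tip.label
  div <- list()
  if (length(tips) > 1) {
    for (i in seq_len(length(tips) - 1L)) for (j in (i + 1L):length(tips)) {
      mrca <- ape::getMRCA(phy, c(tips[i], tips[j]))
      key <- paste0("node:", mrca)
      div[[length(div) + 1L]] <- data.frame(
        species_a = tips[i], species_b = tips[j],
        true_ks = scenario$ksPerMyr *
          (markerStore[[tips[i]]][[key]] + markerStore[[tips[j]]][[key]]),
        age_mya = age[mrca], stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes,
       truth = list(
         events = if (length(eventRows)) do.call(rbind, eventRows) else NULL,
         divergences = if (length(div)) do.call(rbind, div) else NULL,
         ledger = if (length(ledger)) do.call(rbind, ledger) else NULL,
         runs = if (length(runRows)) do.call(rbind, runRows) else NULL),
       scenario = scenario)
}

#' Homolog hits implied by simulation ground truth
#'
#' Pairs every gene of `a` with every gene of `b` that descends from the
#' same ancestral gene — the idealized (noise-free) counterpart of a BLAST
#' hit table, in the same `gene_a`/`gene_b`/`score`/`evalue` layout that
#' [readBlastHits()] produces. For a self-comparison pass the same genome
#' twice; each unordered pair is reported once and self-pairs are dropped.
#'
#' @param a,b [GenomeAnnotation-class] objects carrying `ancestor_id`.
#' @return data.frame of homolog pairs.
#' @export
truthHits <- function(a, b) {
  ga <- a@genes; gb <- b@genes
  if (is.null(ga$ancestor_id) || is.null(gb$ancestor_id))
    stop("truthHits needs simulated annotations with ancestor ids")
  same <- identical(a@species, b@species)
  mrg <- merge(ga[, c("gene_id", "ancestor_id")],
               gb[, c("gene_id", "ancestor_id")],
               by = "ancestor_id", suffixes = c("_a", "_b"))
  if (same) mrg <- mrg[mrg$gene_id_a < mrg$gene_id_b, , drop = FALSE]
  data.frame(gene_a = mrg$gene_id_a, gene_b = mrg$gene_id_b,
             score = rep(200, nrow(mrg)), evalue = rep(1e-180, nrow(mrg)),
             stringsAsFactors = FALSE)
}
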