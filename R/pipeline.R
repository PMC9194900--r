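# End-to-end orchestration: configuration handling, bundled simulation
# scenario presets, and a staged pipeline runner with a run manifest.

#' Bundled simulation scenario presets
#'
#' Three study designs covering the depth-ratio algebra exercised by the
#' pipeline: `"nst_like"` (a lineage-specific tetraploidy with biased
#' fractionation and a slower lineage, self depth 1:1), `"ech_like"`
#' (tetraploid vs hexaploid descendants of a shared ancestor, depth 2:3)
#' and `"double_tetra"` (tetraploid vs double-tetraploid, depth 2:4).
#'
#' @param name preset name.
#' @param seed master seed.
#' @param genesPerChromosome,nChromosomes,codonsPerGene,evolveSequences
#'   overrides of the preset sizes.
#' @return a [wgdScenario()].
#' @export
scenarioPreset <- function(name = c("nst_like", "ech_like", "double_tetra"),
                           seed = 1, genesPerChromosome = 300,
                           nChromosomes = 2, codonsPerGene = 120,
                           evolveSequences = TRUE) {
  name <- match.arg(name)
  mk <- function(tree, events, rates, ksPerMyr)
    wgdScenario(tree, events = events, rates = rates,
                nChromosomes = nChromosomes,
                genesPerChromosome = genesPerChromosome,
                codonsPerGene = codonsPerGene, ksPerMyr = ksPerMyr,
                seed = seed, evolveSequences = evolveSequences)
  switch(name,
    nst_like = mk(
      "(N:100,V:100);",
      list(wgdEvent("NST", 2, branch = "N", at = 62, mode = "allo",
                    loss_prob = c(0.2, 0.35), run_p = 0.6)),
      rates = c(N = 0.7),
      ksPerMyr = 0.49 / (2 * 0.7 * 62)),
    ech_like = mk(
      "(T2:100,H3:100);",
      list(wgdEvent("TT", 2, branch = "T2", at = 70, mode = "auto",
                    loss_prob = c(0.12, 0.18), run_p = 0.6),
           wgdEvent("HH", 3, branch = "H3", at = 70, mode = "allo",
                    loss_prob = c(0.10, 0.15, 0.25), run_p = 0.6)),
      rates = numeric(),
      ksPerMyr = 0.004),
    double_tetra = mk(
      "(D:100,S:100);",
      list(wgdEvent("OLD", 2, branch = "D", at = 80, mode = "auto",
                    loss_prob = c(0.12, 0.18), run_p = 0.6),
           wgdEvent("RECENT", 2, branch = "D", at = 30, mode = "auto",
                    loss_prob = c(0.08, 0.12), run_p = 0.6),
           wgdEvent("SGL", 2, branch = "S", at = 70, mode = "auto",
                    loss_prob = c(0.12, 0.18), run_p = 0.6)),
      rates = numeric(),
      ksPerMyr = 0.004))
}

.defaultParams <- function() {
  list(max_gap = 50, min_anchors = 4, evalue = 1e-5,
       window_m = 100, step = 1, d_low = 0.1, d_high = 3,
       bs_threshold = 50, pindex_threshold = 0.3,
       ks_domain = c(0.02, 2))
}

#' Read (or normalize) a pipeline configuration
#'
#' YAML on disk or an R list; missing stage parameters are filled with the
#' documented defaults. The configuration round-trips through
#' [writePipelineConfig()].
#'
#' @param x path to a YAML file, or a list.
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  params <- utils::modifyList(.defaultParams(), cfg$params %||% list())
  cfg$params <- params
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$scenario))
    stop("config needs a 'scenario' (preset name or specification)")
  structure(cfg, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a pipeline configuration to YAML
#' @param cfg a `PipelineConfig`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.stageOrder <- c("simulate", "hits", "blocks", "ks", "peaks", "depth",
                 "table", "fractionate", "pindex")

#' Run the analysis pipeline on a simulated scenario
#'
#' Executes the requested stages in dependency order
#' (simulate -> hits -> blocks -> ks -> peaks; blocks -> depth -> table ->
#' fractionate -> pindex), writing text artifacts and a YAML manifest to
#' the output directory. Rerunning with the same configuration reproduces
#' the deterministic artifacts bit for bit. A stage whose upstream artifact
#' is missing from `state` raises an error naming the stage to run first.
#'
#' @param config a `PipelineConfig` (see [readPipelineConfig()]); its
#'   `scenario` is a [scenarioPreset()] name (with optional
#'   `scenario_args`) or an inline specification accepted by
#'   [wgdScenario()].
#' @param stages character vector of stages (default: all).
#' @param outdir output directory (default: `config$outdir` or tempdir).
#' @param state result of a previous [runPipeline()] call to continue from.
#' @return list of class `PipelineState` with the stage artifacts and
#'   `manifest`.
#' @export
runPipeline <- function(config, stages = .stageOrder, outdir = NULL,
                        state = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else readPipelineConfig(config)
  outdir <- outdir %||% cfg$outdir %||% file.path(tempdir(), "wgdtrace_run")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
  st <- state %||% list()
  p <- cfg$params
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  needs <- function(what, from) {
    if (is.null(st[[what]]))
      stop("stage needs '", what, "': run stage '", from, "' first")
    st[[what]]
  }

  if ("simulate" %in% stages) {
    scn <- if (is.character(cfg$scenario))
      do.call(scenarioPreset,
              c(list(name = cfg$scenario, seed = cfg$seed),
                cfg$scenario_args %||% list()))
    else do.call(wgdScenario, utils::modifyList(cfg$scenario,
                                                list(seed = cfg$seed)))
    st$sim <- simulateScenario(scn)
    for (sp in names(st$sim$genomes)) {
      gp <- file.path(outdir, paste0(sp, ".gff3"))
      fp <- file.path(outdir, paste0(sp, ".cds.fasta"))
      writeGenomeGff3(st$sim$genomes[[sp]], gp,
                      if (length(cds(st$sim$genomes[[sp]]))) fp)
      note(gp)
      if (length(cds(st$sim$genomes[[sp]]))) note(fp)
    }
    writeTruthLedger(st$sim$truth, file.path(outdir, "truth"))
    note(file.path(outdir, "truth"))
  }

  if ("hits" %in% stages) {
    sim <- needs("sim", "simulate")
    gs <- sim$genomes
    sp <- names(gs)
    st$hits <- list()
    for (i in seq_along(sp)) for (j in i:length(sp)) {
      key <- paste(sp[i], sp[j], sep = "~")
      st$hits[[key]] <- truthHits(gs[[sp[i]]], gs[[sp[j]]])
      hp <- file.path(outdir, paste0("hits_", sp[i], "_", sp[j], ".tsv"))
      writeBlastTable(st$hits[[key]], hp)
      note(hp)
    }
  }

  if ("blocks" %in% stages) {
    sim <- needs("sim", "simulate")
    hits <- needs("hits", "hits")
    gs <- sim$genomes
    st$blocks <- list()
    for (key in names(hits)) {
      ab <- strsplit(key, "~", fixed = TRUE)[[1]]
      st$blocks[[key]] <- chainBlocks(hits[[key]], gs[[ab[1]]], gs[[ab[2]]],
                                      maxGap = p$max_gap,
                                      minAnchors = p$min_anchors)
      bp <- file.path(outdir, paste0("blocks_", ab[1], "_", ab[2], ".tsv"))
      writeBlocksTsv(st$blocks[[key]], bp)
      note(bp)
    }
  }

  if ("ks" %in% stages) {
    sim <- needs("sim", "simulate")
    bls <- needs("blocks", "blocks")
    gs <- sim$genomes
    if (!length(cds(gs[[1]])))
      stop("ks stage needs simulated sequences (evolveSequences = TRUE)")
    for (key in names(bls)) {
      ab <- strsplit(key, "~", fixed = TRUE)[[1]]
      bls[[key]] <- blockKs(bls[[key]], cds(gs[[ab[1]]]), cds(gs[[ab[2]]]))
      kp <- file.path(outdir, paste0("ks_", ab[1], "_", ab[2], ".tsv"))
      utils::write.table(anchors(bls[[key]]), kp, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      note(kp)
    }
    st$blocks <- bls
  }

  if ("peaks" %in% stages) {
    bls <- needs("blocks", "ks")
    st$mixtures <- list()
    for (key in names(bls)) {
      ks <- anchors(bls[[key]])$ks
      ks <- ks[is.finite(ks)]
      if (length(ks) >= 50) {
        st$mixtures[[key]] <- fitKsMixture(ks, seed = cfg$seed,
                                           domain = p$ks_domain)
        mp <- file.path(outdir, paste0("mixture_", gsub("~", "_", key), ".tsv"))
        utils::write.table(components(st$mixtures[[key]]), mp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        note(mp)
      }
    }
  }

  if ("depth" %in% stages) {
    sim <- needs("sim", "simulate")
    bls <- needs("blocks", "blocks")
    gs <- sim$genomes
    st$depth <- list()
    for (key in names(bls)) {
      ab <- strsplit(key, "~", fixed = TRUE)[[1]]
      st$depth[[key]] <- depthRatio(bls[[key]], gs[[ab[1]]], gs[[ab[2]]])
    }
    dp <- file.path(outdir, "depth_ratios.tsv")
    utils::write.table(
      data.frame(pair = names(st$depth),
                 ratio = vapply(st$depth, function(d)
                   paste0(d$ratio[1], ":", d$ratio[2]), "")),
      dp, sep = "\t", row.names = FALSE, quote = FALSE)
    note(dp)
  }

  if ("table" %in% stages) {
    sim <- needs("sim", "simulate")
    bls <- needs("blocks", "blocks")
    gs <- sim$genomes
    ref <- cfg$reference %||% names(gs)[length(gs)]
    queries <- list()
    for (q in cfg$queries %||% lapply(setdiff(names(gs), ref), function(s)
      list(species = s, depth = 2))) {
      key <- if (paste(q$species, ref, sep = "~") %in% names(bls))
        paste(q$species, ref, sep = "~") else paste(ref, q$species, sep = "~")
      queries[[length(queries) + 1L]] <-
        list(ann = gs[[q$species]], blocks = bls[[key]],
             depth = q$depth, ksBand = q$ksBand)
    }
    refDepth <- cfg$ref_depth %||% 1L
    selfKey <- paste(ref, ref, sep = "~")
    st$table <- buildAlignmentTable(gs[[ref]], queries,
                                    selfBlocks = bls[[selfKey]],
                                    refDepth = refDepth,
                                    minAnchors = p$min_anchors)
    tp <- file.path(outdir, "alignment_table.csv")
    writeAlignmentCsv(st$table, tp)
    note(tp)
  }

  if ("fractionate" %in% stages) {
    tab <- needs("table", "table")
    cols <- setdiff(colnames(alignmentCells(tab)),
                    c("chrom", "ordinal", tab@ref_species))
    st$spectra <- lapply(stats::setNames(cols, cols), function(cl)
      tryCatch(fitGeometric(lossRuns(tab, cl)), error = function(e)
        lossRuns(tab, cl)))
    fp <- file.path(outdir, "loss_runs.tsv")
    utils::write.table(
      do.call(rbind, lapply(cols, function(cl)
        data.frame(column = cl, length = as.integer(names(st$spectra[[cl]]$counts)),
                   count = st$spectra[[cl]]$counts))),
      fp, sep = "\t", row.names = FALSE, quote = FALSE)
    note(fp)
  }

  if ("pindex" %in% stages) {
    tab <- needs("table", "table")
    qs <- setdiff(names(expectedDepths(tab)), tab@ref_species)
    st$pindex <- list()
    for (q in qs) {
      colA <- paste0(q, ".A"); colB <- paste0(q, ".B")
      if (!all(c(colA, colB) %in% colnames(alignmentCells(tab)))) next
      rw <- retentionWindows(tab, colA, colB, M = p$window_m, step = p$step)
      st$pindex[[q]] <- pIndex(rw, low = p$d_low, high = p$d_high)
    }
    pp <- file.path(outdir, "pindex.tsv")
    utils::write.table(
      data.frame(query = names(st$pindex),
                 p_index = vapply(st$pindex, pIndexValue, 0),
                 call = ifelse(vapply(st$pindex, pIndexValue, 0) >
                                 p$pindex_threshold, "allo", "auto")),
      pp, sep = "\t", row.names = FALSE, quote = FALSE)
    note(pp)
  }

  manifest <- list(seed = cfg$seed, stages = stages, params = p,
                   artifacts = sort(unique(artifacts)),
                   package_version = as.character(utils::packageVersion("wgdtrace")))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  st$manifest <- manifest
  st$outdir <- outdir
  class(st) <- "PipelineState"
  st
}
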