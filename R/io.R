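# Plain-text interchange: GFF3 gene lists, CDS FASTA, truth ledgers,
# block/anchor TSV, alignment-table CSV.

#' Write a genome annotation as GFF3 (+ CDS FASTA)
#'
#' Gene features only, 1-based coordinates derived from the ordinal layout
#' (each gene occupies a 1 kb slot); attributes carry `ID=`, and
#' `subgenome=` / `ancestor=` when the annotation is simulated.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param gffPath output GFF3 path.
#' @param fastaPath optional CDS FASTA path (ids match GFF3 IDs).
#' @return invisibly, `gffPath`.
#' @export
writeGenomeGff3 <- function(ann, gffPath, fastaPath = NULL) {
  g <- ann@genes
  start <- g$ordinal * 1000L + 1L
  attrs <- paste0("ID=", g$gene_id)
  if (!is.null(g$subgenome))
    attrs <- paste0(attrs, ";subgenome=", ifelse(g$subgenome == "", ".",
                                                 g$subgenome))
  if (!is.null(g$ancestor_id))
    attrs <- paste0(attrs, ";ancestor=", g$ancestor_id)
  lines <- paste(g$chrom, "wgdtrace", "gene", start, start + 899L, ".",
                 g$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), gffPath)
  if (!is.null(fastaPath) && length(ann@cds))
    Biostrings::writeXStringSet(ann@cds, fastaPath)
  invisible(gffPath)
}

#' Read a gene-list GFF3 (as written by [writeGenomeGff3()])
#'
#' Gene features are ordered by start within each chromosome and assigned
#' 0-based ordinals.
#'
#' @param gffPath GFF3 path.
#' @param species species label for the annotation.
#' @param fastaPath optional CDS FASTA.
#' @return a [GenomeAnnotation-class].
#' @export
readGenomeGff3 <- function(gffPath, species, fastaPath = NULL) {
  ln <- readLines(gffPath)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in '", gffPath, "'")
  f <- do.call(rbind, f)
  f <- f[f[, 3] == "gene", , drop = FALSE]
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  g <- data.frame(gene_id = attr1(f[, 9], "ID"), chrom = f[, 1],
                  start = as.integer(f[, 4]), strand = f[, 7],
                  stringsAsFactors = FALSE)
  sg <- attr1(f[, 9], "subgenome")
  if (!all(is.na(sg))) g$subgenome <- ifelse(is.na(sg) | sg == ".", "", sg)
  anc <- attr1(f[, 9], "ancestor")
  if (!all(is.na(anc))) g$ancestor_id <- anc
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  g$ordinal <- unlist(lapply(split(seq_len(nrow(g)), g$chrom), seq_along),
                      use.names = FALSE) - 1L
  g$start <- NULL
  cds <- if (!is.null(fastaPath)) Biostrings::readDNAStringSet(fastaPath)
  else Biostrings::DNAStringSet()
  if (length(cds)) names(cds) <- sub("\\s.*$", "", names(cds))
  GenomeAnnotation(species, g, cds)
}

#' Write simulation truth as TSV files
#'
#' @param truth the `truth` element of a [simulateScenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeTruthLedger <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) if (!is.null(df))
    utils::write.table(df, file.path(dir, nm), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  wr(truth$ledger, "gene_fates.tsv")
  wr(truth$runs, "loss_runs.tsv")
  wr(truth$events, "event_peaks.tsv")
  wr(truth$divergences, "divergence_peaks.tsv")
  invisible(dir)
}

#' Write homolog hits as 12-column BLAST tabular
#'
#' Dummy alignment coordinates; intended to exercise the BLAST-tabular
#' reading path on simulated hits.
#'
#' @param hits data.frame from [truthHits()] (or compatible).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBlastTable <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(hits$gene_a, hits$gene_b, rep(95, n), rep(300, n),
                   rep(10, n), rep(0, n), rep(1, n), rep(300, n), rep(1, n),
                   rep(300, n), hits$evalue, hits$score)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write colinear blocks as TSV
#'
#' One row per block with a compact anchor list
#' (`geneA:geneB` pairs separated by commas).
#'
#' @param bl a [CollinearBlocks-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBlocksTsv <- function(bl, path) {
  blk <- bl@blocks
  an <- bl@anchors
  blk$anchors <- vapply(blk$block_id, function(id) {
    a <- an[an$block_id == id, ]
    paste(paste0(a$gene_a, ":", a$gene_b), collapse = ",")
  }, "")
  utils::write.table(blk, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an alignment table as CSV
#'
#' Header row holds genome.subgenome column labels; absence is `"."`.
#'
#' @param tab an [AlignmentTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAlignmentCsv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns ", tab@header), con)
  utils::write.csv(tab@table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Homology dot plot
#'
#' Scatter of anchor ordinals per chromosome pair, optionally colored by
#' block Ks-median bands derived from a fitted mixture model (band
#' boundaries at the midpoints between component means).
#'
#' @param bl a [CollinearBlocks-class] (run [blockKs()] first for Ks
#'   coloring).
#' @param annA,annB the two annotations (axis layout).
#' @param mixture optional [KsMixtureModel-class] for color banding.
#' @param file output PNG/SVG path; `NULL` draws on the current device.
#' @return invisibly, `file`.
#' @export
dotplotBlocks <- function(bl, annA, annB, mixture = NULL, file = NULL) {
  if (!is.null(file)) {
    if (grepl("[.]svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  ga <- annA@genes; gb <- annB@genes
  offA <- c(0, cumsum(table(factor(ga$chrom, unique(ga$chrom)))))
  offB <- c(0, cumsum(table(factor(gb$chrom, unique(gb$chrom)))))
  names(offA) <- c(unique(ga$chrom), "end")
  names(offB) <- c(unique(gb$chrom), "end")
  an <- bl@anchors
  blk <- bl@blocks
  graphics::plot(NULL, xlim = c(0, max(offA)), ylim = c(0, max(offB)),
                 xlab = annA@species, ylab = annB@species,
                 main = "colinear anchors")
  graphics::abline(v = offA, h = offB, col = "gray85")
  if (nrow(an)) {
    ca <- blk$chrom_a[match(an$block_id, blk$block_id)]
    cb <- blk$chrom_b[match(an$block_id, blk$block_id)]
    x <- offA[ca] + an$ordinal_a
    y <- offB[cb] + an$ordinal_b
    col <- "gray30"
    if (!is.null(mixture)) {
      mu <- ksPeaks(mixture)
      breaks <- c(-Inf, if (length(mu) > 1) (mu[-1] + mu[-length(mu)]) / 2,
                  Inf)
      med <- blk$ks_median[match(an$block_id, blk$block_id)]
      band <- cut(med, breaks, labels = FALSE)
      pal <- grDevices::hcl.colors(max(length(mu), 2), "Dark 3")
      col <- ifelse(is.na(band), "gray70", pal[band])
    }
    graphics::points(x, y, pch = 16, cex = 0.4, col = col)
  }
  invisible(file)
}
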