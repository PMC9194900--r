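#' @import methods
NULL

#' GenomeAnnotation: ordered gene models of one genome
#'
#' Holds the gene order of a genome (one row per gene, 0-based ordinal per
#' chromosome), optionally its coding sequences, and — for simulated genomes —
#' the per-gene ancestry (ancestral gene id and subgenome labels per
#' polyploidy event) that serves as ground truth downstream.
#'
#' @slot species single species label.
#' @slot genes data.frame with columns `gene_id`, `chrom`, `ordinal`
#'   (0-based within chromosome), `strand`, and optionally `ancestor_id`,
#'   `subgenome`.
#' @slot cds [Biostrings::DNAStringSet] of coding sequences named by
#'   `gene_id`, or an empty set when sequences are not tracked.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(species = "character", genes = "data.frame", cds = "ANY"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character(0)
  need <- c("gene_id", "chrom", "ordinal", "strand")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("genes must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicated gene ids")
    bad <- unlist(lapply(split(g$ordinal, g$chrom), function(o)
      !identical(sort(o), seq_along(o) - 1L)))
    if (any(bad)) msg <- c(msg, "ordinals must be 0..n-1 within each chromosome")
  }
  if (length(object@species) != 1) msg <- c(msg, "species must be length 1")
  if (length(object@cds) && !all(names(object@cds) %in% g$gene_id))
    msg <- c(msg, "cds names must be gene ids")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param species species label.
#' @param genes gene table (see [GenomeAnnotation-class]).
#' @param cds optional `DNAStringSet` named by gene id.
#' @return a [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(species, genes, cds = Biostrings::DNAStringSet()) {
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$ordinal <- as.integer(genes$ordinal)
  if (is.null(genes$strand)) genes$strand <- "+"
  genes <- genes[order(genes$chrom, genes$ordinal), , drop = FALSE]
  rownames(genes) <- NULL
  new("GenomeAnnotation", species = species, genes = genes, cds = cds)
}

#' @describeIn GenomeAnnotation-class number of genes
#' @param x,object a `GenomeAnnotation`
#' @export
setMethod("length", "GenomeAnnotation", function(x) nrow(x@genes))

#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @describeIn GenomeAnnotation-class species label
#' @export
setMethod("species", "GenomeAnnotation", function(x) x@species)

#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @describeIn GenomeAnnotation-class the gene table
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @export
setGeneric("cds", function(x) standardGeneric("cds"))
#' @describeIn GenomeAnnotation-class coding sequences
#' @export
setMethod("cds", "GenomeAnnotation", function(x) x@cds)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", object@species, "\n")
  cat(" ", nrow(object@genes), "genes on",
      length(unique(object@genes$chrom)), "chromosomes;",
      length(object@cds), "CDS\n")
})

#' CollinearBlocks: colinear (syntenic) blocks between two gene orders
#'
#' Result of max-gap chaining ([chainBlocks()]): a table of blocks and the
#' anchor gene pairs composing them. Sides `a` and `b` refer to the two
#' genomes compared (identical labels for a self-comparison).
#'
#' @slot genome_a,genome_b species labels of the two sides.
#' @slot blocks data.frame: `block_id`, `chrom_a`, `chrom_b`, `orientation`
#'   (`"+"`/`"-"`), `n_anchors`, `ks_median` (NA until [blockKs()]).
#' @slot anchors data.frame: `block_id`, `gene_a`, `gene_b`, `ordinal_a`,
#'   `ordinal_b`, `ks` (NA until [blockKs()]).
#' @slot params list of chaining parameters (`max_gap`, `min_anchors`).
#' @exportClass CollinearBlocks
setClass("CollinearBlocks",
  representation(genome_a = "character", genome_b = "character",
                 blocks = "data.frame", anchors = "data.frame",
                 params = "list"))

setValidity("CollinearBlocks", function(object) {
  b <- object@blocks; a <- object@anchors
  msg <- character(0)
  if (nrow(b) && !all(a$block_id %in% b$block_id))
    msg <- c(msg, "anchors reference unknown block ids")
  if (nrow(b) && !all(b$orientation %in% c("+", "-")))
    msg <- c(msg, "orientation must be + or -")
  for (id in b$block_id) {
    oa <- a$ordinal_a[a$block_id == id]
    ob <- a$ordinal_b[a$block_id == id]
    if (is.unsorted(oa, strictly = TRUE)) { msg <- c(msg, "ordinal_a not strictly increasing"); break }
    ori <- b$orientation[b$block_id == id]
    obo <- if (ori == "+") ob else rev(ob)
    if (is.unsorted(obo, strictly = TRUE)) { msg <- c(msg, "ordinal_b not monotone for orientation"); break }
  }
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @describeIn CollinearBlocks-class the block table
#' @param x,object a `CollinearBlocks`
#' @export
setMethod("blocks", "CollinearBlocks", function(x) x@blocks)

#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @describeIn CollinearBlocks-class the anchor table
#' @export
setMethod("anchors", "CollinearBlocks", function(x) x@anchors)

#' @describeIn CollinearBlocks-class number of blocks
#' @export
setMethod("length", "CollinearBlocks", function(x) nrow(x@blocks))

setMethod("show", "CollinearBlocks", function(object) {
  cat("CollinearBlocks:", object@genome_a, "vs", object@genome_b, "\n")
  cat(" ", nrow(object@blocks), "blocks,", nrow(object@anchors),
      "anchors (max_gap =", object@params$max_gap,
      ", min_anchors =", object@params$min_anchors, ")\n")
})

#' KsMixtureModel: normal mixture decomposition of a Ks sample
#'
#' Each component's mean is read as the Ks peak of one evolutionary event
#' (polyploidy or speciation); the component sd is the "+/-" spread reported
#' alongside a peak.
#'
#' @slot components data.frame with columns `weight`, `mean`, `sd`, ordered
#'   by mean.
#' @slot domain numeric(2), the fitted Ks interval.
#' @slot n sample size used in the fit.
#' @slot bandwidth kernel bandwidth used for initialization.
#' @slot loglik,bic fit diagnostics.
#' @exportClass KsMixtureModel
setClass("KsMixtureModel",
  representation(components = "data.frame", domain = "numeric", n = "integer",
                 bandwidth = "numeric", loglik = "numeric", bic = "numeric"))

setValidity("KsMixtureModel", function(object) {
  cm <- object@components
  msg <- character(0)
  if (abs(sum(cm$weight) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (any(cm$sd <= 0)) msg <- c(msg, "component sd must be positive")
  if (any(cm$mean < object@domain[1] - 1e-9 | cm$mean > object@domain[2] + 1e-9))
    msg <- c(msg, "component means must lie in the fit domain")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @describeIn KsMixtureModel-class the component table
#' @param x,object a `KsMixtureModel`
#' @export
setMethod("components", "KsMixtureModel", function(x) x@components)

#' @export
setGeneric("ksPeaks", function(x) standardGeneric("ksPeaks"))
#' @describeIn KsMixtureModel-class component means (event peaks), ascending
#' @export
setMethod("ksPeaks", "KsMixtureModel", function(x) x@components$mean)

setMethod("show", "KsMixtureModel", function(object) {
  cat("KsMixtureModel:", nrow(object@components), "components, n =", object@n, "\n")
  for (i in seq_len(nrow(object@components)))
    cat(sprintf("  peak %.3f (+/- %.3f), weight %.2f\n",
                object@components$mean[i], object@components$sd[i],
                object@components$weight[i]))
})

#' AlignmentTable: event-related multi-genome alignment
#'
#' Rows follow the reference gene order; the first column block holds the
#' reference gene and its polyploidy-produced paralogs, then each query
#' genome contributes one column per expected orthologous subgenome. Absent
#' genes (lost, translocated or unassembled) carry the reserved mark `"."`.
#'
#' @slot ref_species reference species label.
#' @slot table data.frame of gene ids / absence marks; first two columns are
#'   `chrom` and `ordinal` of the reference gene.
#' @slot depths named integer: expected depth per genome (reference first).
#' @slot header the column-arithmetic string, e.g. `"19=3+2+2+2+2+4+4"`.
#' @exportClass AlignmentTable
setClass("AlignmentTable",
  representation(ref_species = "character", table = "data.frame",
                 depths = "integer", header = "character"))

setValidity("AlignmentTable", function(object) {
  msg <- character(0)
  if (ncol(object@table) - 2L != sum(object@depths))
    msg <- c(msg, "column count must equal the sum of expected depths")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("alignmentCells", function(x) standardGeneric("alignmentCells"))
#' @describeIn AlignmentTable-class the cell table (gene ids / `"."`)
#' @param x,object an `AlignmentTable`
#' @export
setMethod("alignmentCells", "AlignmentTable", function(x) x@table)

#' @export
setGeneric("expectedDepths", function(x) standardGeneric("expectedDepths"))
#' @describeIn AlignmentTable-class expected depth per genome
#' @export
setMethod("expectedDepths", "AlignmentTable", function(x) x@depths)

setMethod("show", "AlignmentTable", function(object) {
  cat("AlignmentTable (reference:", object@ref_species, ")\n")
  cat("  columns:", object@header, ";", nrow(object@table), "reference genes\n")
})

#' PIndexResult: the P-index allo/autopolyploidy diagnostic
#'
#' Windowed divergence in fractionation between two subgenomes, aggregated
#' over homoeologous chromosome pairs; values near 0 indicate balanced
#' (auto-like) fractionation, values near 1 a fully dominant subgenome.
#' Values above 0.3 are read as evidence of allopolyploidy.
#'
#' @slot p_index the scalar statistic in \[0,1\].
#' @slot per_chrom data.frame: `chrom`, `n_windows`, `included`, `signed_sum`,
#'   `contribution`, `weight`.
#' @slot thresholds numeric(2): the (low, high) inclusion cutoffs on the
#'   relative retention difference d_i.
#' @exportClass PIndexResult
setClass("PIndexResult",
  representation(p_index = "numeric", per_chrom = "data.frame",
                 thresholds = "numeric"))

setValidity("PIndexResult", function(object) {
  msg <- character(0)
  if (object@p_index < -1e-9 || object@p_index > 1 + 1e-9)
    msg <- c(msg, "p_index must lie in [0,1]")
  w <- object@per_chrom$weight
  if (length(w) && abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "chromosome weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("pIndexValue", function(x) standardGeneric("pIndexValue"))
#' @describeIn PIndexResult-class the scalar P-index
#' @param x,object a `PIndexResult`
#' @export
setMethod("pIndexValue", "PIndexResult", function(x) x@p_index)

setMethod("show", "PIndexResult", function(object) {
  cat(sprintf("PIndexResult: P-index = %.3f over %d chromosome pair(s)\n",
              object@p_index, nrow(object@per_chrom)))
})
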