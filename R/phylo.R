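# Gene-tree topology classification for WGD placement and bootstrap
# support counting. External (e.g. maximum-likelihood) trees enter as
# newick with bootstrap values on internal nodes; a neighbor-joining +
# bootstrap stand-in is provided for end-to-end simulation tests.

#' Select collinearity-based orthogroups from an alignment table
#'
#' Rows whose non-absent cell counts satisfy a per-genome copy-count
#' pattern; each selected row yields the group of gene ids with their
#' (genome, subgenome) tags.
#'
#' @param tab an [AlignmentTable-class].
#' @param pattern named integer: required copy count per genome (matched as
#'   "at least this many non-absent cells"; a pattern above the genome's
#'   expected depth is a configuration error).
#' @return list of data.frames (`gene`, `genome`, `subgenome`), one per
#'   selected row.
#' @export
selectOrthogroups <- function(tab, pattern) {
  depths <- tab@depths
  if (!all(names(pattern) %in% names(depths)))
    stop("pattern names must be genomes of the table: ",
         paste(setdiff(names(pattern), names(depths)), collapse = ", "))
  over <- pattern > depths[names(pattern)]
  if (any(over))
    stop("pattern exceeds expected depth for: ",
         paste(names(pattern)[over], collapse = ", "))
  tt <- tab@table
  cellCols <- setdiff(names(tt), c("chrom", "ordinal"))
  genomeOf <- ifelse(cellCols == tab@ref_species, tab@ref_species,
                     sub("[.][A-Z]$", "", cellCols))
  subOf <- ifelse(grepl("[.][A-Z]$", cellCols),
                  sub("^.*[.]", "", cellCols), "A")
  groups <- list()
  for (r in seq_len(nrow(tt))) {
    cells <- unlist(tt[r, cellCols], use.names = FALSE)
    present <- cells != "."
    counts <- tapply(present, genomeOf, sum)
    if (all(counts[names(pattern)] >= pattern)) {
      groups[[length(groups) + 1L]] <- data.frame(
        gene = cells[present], genome = genomeOf[present],
        subgenome = subOf[present], stringsAsFactors = FALSE)
    }
  }
  groups
}

.nodeSupport <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(NA_real_)
  lab <- if (is.null(tree$node.label)) "" else tree$node.label[node - nt]
  val <- suppressWarnings(as.numeric(lab))
  if (is.na(val)) {
    warning("missing bootstrap label at key node; treated as 0")
    val <- 0
  }
  val
}

.cladeTips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  tree$tip.label[.tipDescendants(tree, node)]
}

.tipDescendants <- function(tree, node) {
  nt <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= nt) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  out
}

#' Classify a gene-tree topology for WGD placement
#'
#' A paralog pair supports a lineage-specific WGD when it forms an
#' exclusive clade (the MRCA of the pair contains only genes of the pair's
#' genome) with bootstrap support at the key node at or above the
#' threshold; it supports a shared WGD when the two children of the pair's
#' MRCA each contain one paralog together with at least one gene of the
#' putatively sharing genome (key node = the pair's MRCA), again at or
#' above the threshold. Anything else is unresolved.
#'
#' @param tree an [ape::phylo] with bootstrap values as internal node
#'   labels, or a newick string.
#' @param tags named character: genome label per gene (tip) id.
#' @param paralogPair character(2): the two paralogous gene ids under test.
#' @param sharedWith genome label whose copies would join the paralogs
#'   under a shared WGD.
#' @param outgroup genome label used to root the tree (required when the
#'   tree is unrooted); tips of this genome must be present.
#' @param threshold bootstrap threshold at the key node (default 50).
#' @return list of class `TopologyCall`: `label` (one of
#'   `"lineage_specific_wgd"`, `"shared_wgd"`, `"unresolved"`),
#'   `key_node_support`, `passes`.
#' @export
classifyTopology <- function(tree, tags, paralogPair, sharedWith,
                             outgroup = NULL, threshold = 50) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length(paralogPair) == 2)
  if (!all(paralogPair %in% tree$tip.label))
    stop("paralog pair not in the tree")
  if (!ape::is.rooted(tree)) {
    og <- names(tags)[tags == outgroup]
    og <- intersect(og, tree$tip.label)
    if (!length(og)) stop("unrooted tree and no outgroup tip present")
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  genome <- tags[[paralogPair[1]]]
  mrca <- ape::getMRCA(tree, paralogPair)
  tipsUnder <- .cladeTips(tree, mrca)
  exclusive <- all(tags[tipsUnder] == genome)
  label <- "unresolved"
  support <- 0
  if (exclusive) {
    # key node: the exclusive paralog clade itself
    support <- .nodeSupport(tree, mrca)
    if (support >= threshold) label <- "lineage_specific_wgd"
  } else {
    kids <- tree$edge[tree$edge[, 1] == mrca, 2]
    sides <- lapply(kids, function(k) .cladeTips(tree, k))
    hasP <- vapply(sides, function(s)
      sum(paralogPair %in% s), 0L)
    hasShared <- vapply(sides, function(s)
      any(tags[s] == sharedWith), logical(1))
    if (length(kids) == 2 && all(hasP == 1L) && all(hasShared)) {
      # key nodes: the two clades pairing each paralog with a copy of the
      # sharing genome; the call's support is their minimum
      nt <- length(tree$tip.label)
      supp <- vapply(kids[kids > nt], function(k) .nodeSupport(tree, k), 0)
      support <- if (length(supp)) min(supp) else 0
      if (support >= threshold) label <- "shared_wgd"
    } else {
      support <- .nodeSupport(tree, mrca)
    }
  }
  structure(list(label = label, key_node_support = support,
                 passes = support >= threshold),
            class = "TopologyCall")
}

#' @export
print.TopologyCall <- function(x, ...) {
  cat(sprintf("TopologyCall: %s (key node BS %s)\n", x$label,
              format(x$key_node_support)))
  invisible(x)
}

#' Tally topology calls into a support frequency table
#'
#' @param calls list of `TopologyCall`s.
#' @param denominator `"all"` (all trees) or `"passing"` (trees whose key
#'   node meets the bootstrap threshold).
#' @return data.frame: `label`, `count`, `percent` (2 decimals); empty for
#'   no calls.
#' @export
countSupport <- function(calls, denominator = c("all", "passing")) {
  denominator <- match.arg(denominator)
  if (!length(calls))
    return(data.frame(label = character(), count = integer(),
                      percent = numeric()))
  lab <- vapply(calls, `[[`, "", "label")
  pass <- vapply(calls, `[[`, logical(1), "passes")
  denom <- if (denominator == "all") length(calls) else sum(pass)
  tb <- table(lab)
  data.frame(label = names(tb), count = as.integer(tb),
             percent = round(100 * as.integer(tb) / max(denom, 1L), 2),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining gene tree with bootstrap support
#'
#' Jukes-Cantor distances on the (gap-free) nucleotide alignment, NJ
#' topology, and nonparametric bootstrap by resampling alignment columns;
#' internal node labels carry bootstrap percentages. A lightweight
#' stand-in for externally inferred maximum-likelihood trees, intended for
#' simulated data.
#'
#' @param seqs named character vector or `DNAStringSet` of aligned
#'   sequences (>= 4, equal lengths).
#' @param bootstrapReps bootstrap replicates (default 100).
#' @param seed integer seed (same seed, same newick).
#' @return an [ape::phylo] with `node.label` bootstrap percentages.
#' @export
njTree <- function(seqs, bootstrapReps = 100, seed = 1) {
  s <- if (is.character(seqs)) seqs else as.character(seqs)
  if (length(s) < 4) stop("need >= 4 sequences")
  if (length(unique(nchar(s))) != 1) stop("sequences must be aligned")
  set.seed(seed)
  mat <- do.call(rbind, strsplit(tolower(s), ""))
  rownames(mat) <- names(s)
  bin <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  tr <- ape::nj(d)
  boot <- ape::boot.phylo(tr, mat, function(m) {
    b <- ape::as.DNAbin(m)
    dd <- ape::dist.dna(b, model = "JC69", pairwise.deletion = TRUE)
    if (any(!is.finite(dd))) dd[!is.finite(dd)] <- max(dd[is.finite(dd)], 1) * 2
    ape::nj(dd)
  }, B = bootstrapReps, quiet = TRUE)
  boot[is.na(boot)] <- 0
  tr$node.label <- as.character(round(100 * boot / bootstrapReps))
  tr
}
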