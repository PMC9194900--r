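# Colinear (syntenic) block detection by max-gap chaining of homolog hits.
#
# For each chromosome pair and orientation, anchors are chained by dynamic
# programming maximizing anchor count; the best chain (ties: smaller total
# ordinal gap, then lexicographically first anchor sequence) is extracted,
# its anchors removed, and the search repeated until no chain reaches
# min_anchors. Gaps are counted as intervening gene ordinals on each
# chromosome independently and both must stay within max_gap.

#' Read homolog hits from BLAST tabular output
#'
#' Parses 12-column BLAST outfmt-6 files, filters by E-value, keeps the
#' `bestN` highest-scoring hits per query and drops self-hits. Hits whose
#' gene ids are not in the annotations are skipped with a warning.
#'
#' @param path BLAST tabular file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param annA,annB [GenomeAnnotation-class] of query and subject genomes.
#' @param evalueCutoff keep hits with E-value <= cutoff (default 1e-5).
#' @param bestN maximum hits kept per query gene, by descending bit score
#'   (default 5; `Inf` keeps all).
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, `evalue`.
#' @export
readBlastHits <- function(path, annA, annB, evalueCutoff = 1e-5, bestN = 5) {
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c("character", "character",
                                     rep("numeric", 10))),
    error = function(e) stop("malformed BLAST tabular file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(raw) != 12)
    stop("malformed BLAST tabular file '", path, "': expected 12 columns, got ",
         ncol(raw))
  hits <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                     score = raw[[12]], evalue = raw[[11]],
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalueCutoff & hits$gene_a != hits$gene_b, ,
               drop = FALSE]
  known <- hits$gene_a %in% annA@genes$gene_id &
    hits$gene_b %in% annB@genes$gene_id
  if (any(!known)) {
    warning(sum(!known), " hit(s) with unresolvable gene ids skipped")
    hits <- hits[known, , drop = FALSE]
  }
  if (is.finite(bestN) && nrow(hits)) {
    hits <- hits[order(hits$gene_a, -hits$score), , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$gene_a),
                          function(i) i[seq_len(min(bestN, length(i)))]),
                   use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

# DP chain extraction on an anchor table (columns a, b = ordinals) for the
# "+" orientation (both strictly increasing). Returns row indices of the
# best chain, or integer(0).
.bestChain <- function(a, b, maxGap) {
  n <- length(a)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  # successor candidates of i lie in a contiguous index range (a sorted)
  hiIdx <- findInterval(a + maxGap + 1L, a)
  len <- integer(n); gap <- numeric(n); nxt <- integer(n)
  # backward DP: best chain starting at i
  for (i in n:1) {
    len[i] <- 1L; gap[i] <- 0; nxt[i] <- 0L
    if (i == n || hiIdx[i] <= i) next
    rng <- (i + 1L):hiIdx[i]
    js <- rng[a[rng] > a[i] & b[rng] > b[i] & b[rng] <= b[i] + maxGap + 1L]
    for (j in js) {
      g <- gap[j] + (a[j] - a[i] - 1L) + (b[j] - b[i] - 1L)
      better <- (len[j] + 1L > len[i]) ||
        (len[j] + 1L == len[i] && nxt[i] != 0L &&
           (g < gap[i] || (g == gap[i] &&
                           (a[j] < a[nxt[i]] ||
                            (a[j] == a[nxt[i]] && b[j] < b[nxt[i]])))))
      if (better) { len[i] <- len[j] + 1L; gap[i] <- g; nxt[i] <- j }
    }
  }
  best <- order(-len, gap, a, b)[1L]
  chain <- integer(0); i <- best
  while (i != 0L) { chain <- c(chain, i); i <- nxt[i] }
  ord[chain]
}

#' Chain homolog hits into colinear blocks
#'
#' @param hits data.frame of homolog pairs (`gene_a`, `gene_b`, optionally
#'   `score`, `evalue`), e.g. from [readBlastHits()] or [truthHits()].
#' @param annA,annB the two [GenomeAnnotation-class] objects; pass the same
#'   object twice for a self-comparison (self-hits are dropped and, on a
#'   chromosome against itself, anchors within `maxGap` of the identity
#'   diagonal are masked).
#' @param maxGap maximum number of intervening genes between consecutive
#'   anchors on either chromosome (default 50).
#' @param minAnchors minimum anchors per reported block (default 4).
#' @return a [CollinearBlocks-class].
#' @export
chainBlocks <- function(hits, annA, annB, maxGap = 50, minAnchors = 4) {
  ga <- annA@genes; gb <- annB@genes
  same <- identical(annA@species, annB@species)
  empty <- new("CollinearBlocks", genome_a = annA@species,
               genome_b = annB@species,
               blocks = data.frame(block_id = integer(), chrom_a = character(),
                                   chrom_b = character(),
                                   orientation = character(),
                                   n_anchors = integer(),
                                   ks_median = numeric()),
               anchors = data.frame(block_id = integer(), gene_a = character(),
                                    gene_b = character(),
                                    ordinal_a = integer(),
                                    ordinal_b = integer(), ks = numeric()),
               params = list(max_gap = maxGap, min_anchors = minAnchors))
  if (!nrow(hits)) return(empty)
  ia <- match(hits$gene_a, ga$gene_id)
  ib <- match(hits$gene_b, gb$gene_id)
  ok <- !is.na(ia) & !is.na(ib) & hits$gene_a != hits$gene_b
  tab <- data.frame(gene_a = hits$gene_a[ok], gene_b = hits$gene_b[ok],
                    chrom_a = ga$chrom[ia[ok]], chrom_b = gb$chrom[ib[ok]],
                    ordinal_a = ga$ordinal[ia[ok]],
                    ordinal_b = gb$ordinal[ib[ok]],
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab[, c("gene_a", "gene_b")]), , drop = FALSE]
  if (same && nrow(tab)) {
    # orient each pair once: (chrom_a, ordinal_a) <= (chrom_b, ordinal_b)
    flip <- tab$chrom_a > tab$chrom_b |
      (tab$chrom_a == tab$chrom_b & tab$ordinal_a > tab$ordinal_b)
    tab[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                "ordinal_a", "ordinal_b")] <-
      tab[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a",
                  "ordinal_b", "ordinal_a")]
    tab <- tab[!duplicated(tab[, c("gene_a", "gene_b")]), , drop = FALSE]
    diag <- tab$chrom_a == tab$chrom_b &
      abs(tab$ordinal_a - tab$ordinal_b) <= maxGap
    tab <- tab[!diag, , drop = FALSE]
  }
  if (!nrow(tab)) return(empty)

  blockRows <- list(); anchorRows <- list(); bid <- 0L
  for (key in sort(unique(paste(tab$chrom_a, tab$chrom_b, sep = "\r")))) {
    sub <- tab[paste(tab$chrom_a, tab$chrom_b, sep = "\r") == key, ,
               drop = FALSE]
    for (ori in c("+", "-")) {
      pool <- sub
      bsign <- if (ori == "+") pool$ordinal_b else -pool$ordinal_b
      repeat {
        if (!nrow(pool)) break
        chain <- .bestChain(pool$ordinal_a, bsign, maxGap)
        if (length(chain) < minAnchors) break
        bid <- bid + 1L
        cc <- pool[chain, , drop = FALSE]
        blockRows[[bid]] <- data.frame(
          block_id = bid, chrom_a = cc$chrom_a[1], chrom_b = cc$chrom_b[1],
          orientation = ori, n_anchors = nrow(cc), ks_median = NA_real_,
          stringsAsFactors = FALSE)
        anchorRows[[bid]] <- data.frame(
          block_id = bid, gene_a = cc$gene_a, gene_b = cc$gene_b,
          ordinal_a = cc$ordinal_a, ordinal_b = cc$ordinal_b, ks = NA_real_,
          stringsAsFactors = FALSE)
        pool <- pool[-chain, , drop = FALSE]
        bsign <- bsign[-chain]
      }
    }
  }
  if (!length(blockRows)) return(empty)
  new("CollinearBlocks", genome_a = annA@species, genome_b = annB@species,
      blocks = do.call(rbind, blockRows),
      anchors = do.call(rbind, anchorRows),
      params = list(max_gap = maxGap, min_anchors = minAnchors))
}

#' Fraction of a genome's genes anchored in colinear blocks
#'
#' @param bl a [CollinearBlocks-class].
#' @param ann the annotation whose coverage is wanted (must be one of the
#'   two sides; for a self-comparison both sides are counted).
#' @return fraction in \[0,1\].
#' @export
blockCoverage <- function(bl, ann) {
  an <- bl@anchors
  sameSelf <- identical(bl@genome_a, bl@genome_b)
  covered <- character(0)
  if (identical(ann@species, bl@genome_a)) covered <- c(covered, an$gene_a)
  if (identical(ann@species, bl@genome_b)) covered <- c(covered, an$gene_b)
  if (!length(covered) && !sameSelf)
    stop("annotation '", ann@species, "' is not a side of this comparison")
  length(intersect(unique(covered), ann@genes$gene_id)) / length(ann)
}
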