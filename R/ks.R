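# Nei-Gojobori (1986, unweighted-pathway) Ka/Ks estimation on codon
# alignments, with a protein-guided pairwise aligner in front and per-block
# Ks summaries behind.

#' Codon-align two coding sequences
#'
#' Equal-length in-frame sequences are paired codon by codon without gaps.
#' Otherwise (or when `proteinGuided = TRUE` is forced) the translated
#' proteins are globally aligned (BLOSUM62, affine gaps: open 10, extend
#' 0.5) and the alignment is back-translated to codons; gap codons are
#' written as `"---"` and excluded from counting downstream.
#'
#' @param cdsA,cdsB coding sequences (character or `DNAString`); trailing
#'   bases beyond a multiple of 3 are dropped with a warning.
#' @param proteinGuided force the protein-guided path even for equal-length
#'   input.
#' @return list with character vectors `a` and `b` of aligned codons
#'   (equal length).
#' @export
alignCodons <- function(cdsA, cdsB, proteinGuided = FALSE) {
  a <- toupper(as.character(cdsA)); b <- toupper(as.character(cdsB))
  if (nchar(a) < 3 || nchar(b) < 3) stop("sequences must be >= 3 nt")
  trim <- function(s) {
    r <- nchar(s) %% 3
    if (r) {
      warning("sequence length not a multiple of 3; trailing bases dropped")
      s <- substr(s, 1, nchar(s) - r)
    }
    s
  }
  a <- trim(a); b <- trim(b)
  codSplit <- function(s) {
    st <- 3L * (seq_len(nchar(s) %/% 3L) - 1L) + 1L
    substring(s, st, st + 2L)
  }
  if (!proteinGuided && nchar(a) == nchar(b))
    return(list(a = codSplit(a), b = codSplit(b)))
  pa <- Biostrings::translate(Biostrings::DNAString(a), if.fuzzy.codon = "X")
  pb <- Biostrings::translate(Biostrings::DNAString(b), if.fuzzy.codon = "X")
  aln <- Biostrings::pairwiseAlignment(pa, pb, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- codSplit(a); cb <- codSplit(b)
  ia <- ib <- 0L
  outA <- outB <- character(length(pat))
  for (k in seq_along(pat)) {
    if (pat[k] != "-") { ia <- ia + 1L; outA[k] <- ca[ia] } else outA[k] <- "---"
    if (sbj[k] != "-") { ib <- ib + 1L; outB[k] <- cb[ib] } else outB[k] <- "---"
  }
  list(a = outA, b = outB)
}

#' Nei-Gojobori Ka/Ks on a codon alignment
#'
#' Synonymous site fractions follow the Nei-Gojobori site definition
#' (changes to stop codons count as nonsynonymous opportunities) and are
#' averaged over the two sequences; codons differing at several positions
#' average the synonymous/nonsynonymous difference counts over all minimal
#' substitution paths with equal weights (steps through stop codons count
#' as nonsynonymous). The Jukes-Cantor correction maps proportions to
#' rates; a proportion >= 3/4 is reported as saturated (`ks`/`ka` = `NA`
#' with the corresponding flag set). The estimate is symmetric in its
#' arguments.
#'
#' @param aln a codon alignment from [alignCodons()], or a list with
#'   character codon vectors `a` and `b`.
#' @return list: `S`, `N` (site counts), `sd`, `nd` (difference counts),
#'   `ps`, `pn`, `ks`, `ka`, `ks_saturated`, `ka_saturated`,
#'   `codons_used`, `codons_excluded`.
#' @export
neiGojobori <- function(aln) {
  tab <- codonTables()
  ia <- codonIndex(aln$a)
  ib <- codonIndex(aln$b)
  drop <- is.na(ia) | is.na(ib)
  stopA <- !is.na(ia) & ia %in% tab$stops
  stopB <- !is.na(ib) & ib %in% tab$stops
  if (any(stopA | stopB)) {
    warning(sum((stopA | stopB) & !drop),
            " codon pair(s) with stop codons excluded")
    drop <- drop | stopA | stopB
  }
  ia <- ia[!drop]; ib <- ib[!drop]
  if (!length(ia)) stop("no comparable codon pairs")
  S <- sum((tab$synSites[ia] + tab$synSites[ib]) / 2)
  N <- 3 * length(ia) - S
  sd <- sum(tab$sdTab[cbind(ia, ib)])
  nd <- sum(tab$ndTab[cbind(ia, ib)])
  ps <- sd / S
  pn <- nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn),
       ks_saturated = ps >= 0.75, ka_saturated = pn >= 0.75,
       codons_used = length(ia), codons_excluded = sum(drop))
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param cdsA,cdsB `DNAStringSet`s holding the sequences (named by gene
#'   id); pass the same set twice for a within-genome comparison.
#' @param proteinGuided see [alignCodons()].
#' @return `pairs` with columns `ka`, `ks`, `S`, `N` appended (NA where
#'   saturated).
#' @export
pairKs <- function(pairs, cdsA, cdsB = cdsA, proteinGuided = FALSE) {
  n <- nrow(pairs)
  ka <- ks <- S <- N <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sa <- cdsA[[pairs$gene_a[i]]]
    sb <- cdsB[[pairs$gene_b[i]]]
    est <- neiGojobori(alignCodons(sa, sb, proteinGuided = proteinGuided))
    ka[i] <- est$ka; ks[i] <- est$ks; S[i] <- est$S; N[i] <- est$N
  }
  cbind(pairs, ka = ka, ks = ks, S = S, N = N)
}

#' Attach anchor Ks values and medians to colinear blocks
#'
#' `ks_median` is the median of the finite anchor Ks values; saturated
#' anchors are excluded from the median but counted. A block whose anchors
#' are all saturated keeps `ks_median = NA`.
#'
#' @param bl a [CollinearBlocks-class].
#' @param cdsA,cdsB CDS sets for the two sides (same set twice for a
#'   self-comparison).
#' @param proteinGuided see [alignCodons()].
#' @return the [CollinearBlocks-class] with `ks` per anchor and
#'   `ks_median` per block filled in.
#' @export
blockKs <- function(bl, cdsA, cdsB = cdsA, proteinGuided = FALSE) {
  an <- bl@anchors
  if (!nrow(an)) return(bl)
  est <- pairKs(an[, c("gene_a", "gene_b")], cdsA, cdsB,
                proteinGuided = proteinGuided)
  an$ks <- est$ks
  blk <- bl@blocks
  med <- vapply(blk$block_id, function(id) {
    v <- an$ks[an$block_id == id]
    v <- v[is.finite(v)]
    if (length(v)) stats::median(v) else NA_real_
  }, 0)
  blk$ks_median <- med
  initialize(bl, blocks = blk, anchors = an)
}
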