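# Genetic-code tables shared by the simulator and the Nei-Gojobori estimator.
#
# Everything here is precomputed once per session into `.codon_env`:
#   - codon <-> index maps (1..64, TCAG order)
#   - per-codon synonymous site counts (Nei-Gojobori site definition)
#   - per-codon, per-position synonymous / nonsynonymous single-nucleotide
#     alternatives (stop codons count as nonsynonymous targets and are never
#     offered as mutation targets by the simulator)
#   - a 64 x 64 table of (syn diffs, nonsyn diffs) averaged over all minimal
#     substitution paths between two codons, which makes pairwise counting a
#     vectorized table lookup.

.codon_env <- new.env(parent = emptyenv())

.bases <- c("T", "C", "A", "G")

#' @noRd
codonStrings <- function() {
  as.vector(outer(outer(.bases, .bases, paste0), .bases, paste0))
}

#' @noRd
codonIndex <- function(codons) {
  match(codons, codonStrings())
}

# amino acid per codon; "*" for stops (treated as a 21st residue: any step
# into or out of a stop is a nonsynonymous difference)
.codonAA <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codonStrings()])
  aa
}

.initCodonTables <- function() {
  if (!is.null(.codon_env$ready)) return(invisible(NULL))
  codons <- codonStrings()
  aa <- .codonAA()
  n <- length(codons)

  # neighbour structure: for codon i, position p, base b -> codon index
  mat <- do.call(rbind, strsplit(codons, ""))
  neighbour <- array(NA_integer_, dim = c(n, 3L, 4L))
  for (p in 1:3) {
    for (b in 1:4) {
      alt <- mat
      alt[, p] <- .bases[b]
      neighbour[, p, b] <- codonIndex(paste0(alt[, 1], alt[, 2], alt[, 3]))
    }
  }

  # Nei-Gojobori fractional synonymous sites per codon position:
  # fraction of the 3 possible changes at that position that are synonymous.
  synAltCount <- matrix(0L, n, 3L)    # synonymous alternatives (none are stops)
  nsynAltCount <- matrix(0L, n, 3L)   # nonsynonymous alternatives excluding stops
  synAlt <- array(NA_integer_, dim = c(n, 3L, 3L))
  nsynAlt <- array(NA_integer_, dim = c(n, 3L, 3L))
  for (i in seq_len(n)) {
    for (p in 1:3) {
      alts <- setdiff(neighbour[i, p, ], i)
      syn <- alts[aa[alts] == aa[i] & aa[alts] != "*"]
      nsyn <- alts[aa[alts] != aa[i] & aa[alts] != "*"]
      synAltCount[i, p] <- length(syn)
      nsynAltCount[i, p] <- length(nsyn)
      if (length(syn)) synAlt[i, p, seq_along(syn)] <- syn
      if (length(nsyn)) nsynAlt[i, p, seq_along(nsyn)] <- nsyn
    }
  }
  # site fractions: stop-codon targets count as nonsynonymous opportunities,
  # so the synonymous fraction at a position is (#syn alternatives)/3.
  synSites <- rowSums(synAltCount) / 3

  # minimal-path averaged difference counts for every ordered codon pair
  sdTab <- matrix(0, n, n)
  ndTab <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffPos <- which(mat[i, ] != mat[j, ])
      paths <- .permutations(diffPos)
      sd <- nd <- 0
      for (k in seq_len(nrow(paths))) {
        cur <- i
        for (p in paths[k, ]) {
          nxt <- neighbour[cur, p, match(mat[j, p], .bases)]
          if (aa[cur] == aa[nxt] && aa[cur] != "*") sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
      }
      sdTab[i, j] <- sd / nrow(paths)
      ndTab[i, j] <- nd / nrow(paths)
    }
  }

  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$synSites <- synSites
  .codon_env$synAltCount <- synAltCount
  .codon_env$nsynAltCount <- nsynAltCount
  .codon_env$synAlt <- synAlt
  .codon_env$nsynAlt <- nsynAlt
  .codon_env$sdTab <- sdTab
  .codon_env$ndTab <- ndTab
  .codon_env$stops <- which(aa == "*")
  .codon_env$ready <- TRUE
  invisible(NULL)
}

# all orderings of a short vector (<= 3 elements here)
.permutations <- function(x) {
  if (length(x) <= 1) return(matrix(x, nrow = 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' @noRd
codonTables <- function() {
  .initCodonTables()
  .codon_env
}

# split an in-frame DNA string into codon index vector (NA for codons with
# gaps or ambiguity codes)
#' @noRd
codonIndices <- function(x) {
  s <- as.character(x)
  nc <- nchar(s)
  if (nc < 3) return(integer(0))
  n <- nc %/% 3
  cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  codonIndex(cods)
}
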