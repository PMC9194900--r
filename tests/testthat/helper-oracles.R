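# Independent oracles used by the tests only. They re-derive everything
# from first principles (Biostrings' genetic code, exhaustive enumeration)
# and share no code with the package internals they check.

# --- Nei-Gojobori by direct path enumeration on codon strings -----------

.oracleAA <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

.oracleSynSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- .oracleAA(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (.oracleAA(alt) == aa && .oracleAA(alt) != "*") s <- s + 1 / 3
    }
  }
  s
}

.oraclePerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .oraclePerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# average (syn, nonsyn) difference counts over all minimal paths
.oracleDiffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  tot <- c(0, 0)
  perms <- .oraclePerms(pos)
  for (path in perms) {
    cur <- ca
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (.oracleAA(cur) == .oracleAA(nxt) && .oracleAA(cur) != "*")
        tot[1] <- tot[1] + 1
      else tot[2] <- tot[2] + 1
      cur <- nxt
    }
  }
  tot / length(perms)
}

# full oracle estimate on two equal-length in-frame CDS strings
ngOracle <- function(a, b) {
  n <- nchar(a) %/% 3
  S <- 0; sd <- 0; nd <- 0
  for (i in seq_len(n)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    S <- S + (.oracleSynSites(ca) + .oracleSynSites(cb)) / 2
    d <- .oracleDiffs(ca, cb)
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  N <- 3 * n - S
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn))
}

# random in-frame CDS without stop codons
randomCds <- function(nCodons, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  paste0(sample(ok, nCodons, replace = TRUE), collapse = "")
}

# mutate a CDS at random positions (may create any non-stop codon)
mutateCds <- function(cdsStr, nMut, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  cods <- substring(cdsStr, 3 * (1:(nchar(cdsStr) %/% 3)) - 2,
                    3 * (1:(nchar(cdsStr) %/% 3)))
  idx <- sample(seq_along(cods), min(nMut, length(cods)))
  cods[idx] <- sample(ok, length(idx), replace = TRUE)
  paste0(cods, collapse = "")
}

# --- exhaustive max-gap chain extraction --------------------------------

# all chains (index sequences) with strictly increasing a and b and both
# gaps <= maxGap; returns every chain, the caller picks the best
.allChains <- function(a, b, maxGap) {
  res <- list()
  extend <- function(chain) {
    res[[length(res) + 1L]] <<- chain
    last <- chain[length(chain)]
    succ <- which(a > a[last] & a - a[last] - 1L <= maxGap &
                  b > b[last] & b - b[last] - 1L <= maxGap)
    for (j in succ) extend(c(chain, j))
  }
  for (i in seq_along(a)) extend(i)
  res
}

# key for "smaller is better" chain comparison: longer, then smaller total
# gap, then lexicographically first (a, b) sequence
.chainBetter <- function(a, b, c1, c2) {
  if (length(c1) != length(c2)) return(length(c1) > length(c2))
  g <- function(ch) sum(diff(a[ch]) - 1L) + sum(abs(diff(b[ch])) - 1L)
  g1 <- g(c1); g2 <- g(c2)
  if (g1 != g2) return(g1 < g2)
  s1 <- c(rbind(a[c1], b[c1])); s2 <- c(rbind(a[c2], b[c2]))
  d <- which(s1 != s2)
  if (!length(d)) return(FALSE)
  s1[d[1]] < s2[d[1]]
}

# greedy best-chain extraction by exhaustive search, one orientation
chainOracleOneOri <- function(a, b, maxGap, minAnchors) {
  blocks <- list()
  idx <- seq_along(a)
  repeat {
    if (!length(idx)) break
    chains <- .allChains(a[idx], b[idx], maxGap)
    best <- NULL
    for (ch in chains)
      if (is.null(best) || .chainBetter(a[idx], b[idx], ch, best)) best <- ch
    if (length(best) < minAnchors) break
    blocks[[length(blocks) + 1L]] <- idx[best]
    idx <- idx[-best]
  }
  blocks
}

# full oracle over both orientations, mirroring chainBlocks' conventions
chainOracle <- function(a, b, maxGap, minAnchors) {
  list(plus = chainOracleOneOri(a, b, maxGap, minAnchors),
       minus = chainOracleOneOri(a, -b, maxGap, minAnchors))
}

# turn a one-chromosome-pair hit set into annotations + hits for chainBlocks
gridFixture <- function(a, b, nA = max(a) + 1L, nB = max(b) + 1L) {
  annA <- GenomeAnnotation("gA", data.frame(
    gene_id = paste0("ga", seq_len(nA) - 1L), chrom = "c1",
    ordinal = seq_len(nA) - 1L, strand = "+"))
  annB <- GenomeAnnotation("gB", data.frame(
    gene_id = paste0("gb", seq_len(nB) - 1L), chrom = "c1",
    ordinal = seq_len(nB) - 1L, strand = "+"))
  hits <- data.frame(gene_a = paste0("ga", a), gene_b = paste0("gb", b),
                     score = 100, evalue = 1e-20, stringsAsFactors = FALSE)
  list(annA = annA, annB = annB, hits = hits)
}
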