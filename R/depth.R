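# Colinear depth profiles, subgenome assignment against a reference, and
# the event-related multi-genome alignment table.

# re-orient a CollinearBlocks object so that `refSpecies` is side a
.orientBlocks <- function(bl, refSpecies) {
  if (identical(bl@genome_a, refSpecies)) return(bl)
  if (!identical(bl@genome_b, refSpecies))
    stop("reference '", refSpecies, "' is not a side of this comparison")
  an <- bl@anchors
  an[, c("gene_a", "gene_b", "ordinal_a", "ordinal_b")] <-
    an[, c("gene_b", "gene_a", "ordinal_b", "ordinal_a")]
  blk <- bl@blocks
  blk[, c("chrom_a", "chrom_b")] <- blk[, c("chrom_b", "chrom_a")]
  # re-sort anchors so ordinal_a increases within each block
  an <- an[order(an$block_id, an$ordinal_a), , drop = FALSE]
  new("CollinearBlocks", genome_a = bl@genome_b, genome_b = bl@genome_a,
      blocks = blk, anchors = an, params = bl@params)
}

# per-gene colinear depth on one side of a block set
.sideDepth <- function(bl, ann, side = c("a", "b"), minAnchors) {
  side <- match.arg(side)
  g <- ann@genes
  depth <- setNames(integer(nrow(g)), g$gene_id)
  blk <- bl@blocks[bl@blocks$n_anchors >= minAnchors, , drop = FALSE]
  an <- bl@anchors
  chromCol <- paste0("chrom_", side)
  ordCol <- paste0("ordinal_", side)
  for (i in seq_len(nrow(blk))) {
    o <- an[an$block_id == blk$block_id[i], ordCol]
    hit <- g$chrom == blk[[chromCol]][i] &
      g$ordinal >= min(o) & g$ordinal <= max(o)
    depth[hit] <- depth[hit] + 1L
  }
  depth
}

.modalDepth <- function(depth) {
  d <- depth[depth >= 1L]
  if (!length(d)) return(NA_integer_)
  tb <- table(d)
  as.integer(names(tb)[which.max(tb)])
}

#' Colinear depth profile and depth ratio between two genomes
#'
#' Per gene, the depth is the number of colinear blocks (with at least
#' `minAnchors` anchors) whose span on that gene's side covers its ordinal.
#' The summary ratio is modal-depth : modal-depth, oriented so that the
#' first number is the copy count of genome a (i.e. the modal depth
#' observed on b-side genes) — e.g. tetraploid vs hexaploid descendants
#' give 2:3. Modes are taken over covered genes only (depth >= 1). Ratios
#' are reported as modal depths, unreduced (2:4 stays 2:4).
#'
#' @param bl a [CollinearBlocks-class].
#' @param annA,annB the two annotations (same object twice for a
#'   self-comparison, in which case both sides are pooled and the ratio is
#'   symmetric).
#' @param minAnchors block size filter (defaults to the chaining value).
#' @return list of class `DepthProfile`: `depth_a`, `depth_b` (named per
#'   gene), `modal_a`, `modal_b`, `ratio` (c(a, b), NA when no blocks).
#' @export
depthRatio <- function(bl, annA, annB, minAnchors = bl@params$min_anchors) {
  self <- identical(annA@species, annB@species)
  da <- .sideDepth(bl, annA, "a", minAnchors)
  db <- .sideDepth(bl, annB, "b", minAnchors)
  if (self) {
    pooled <- da + db
    m <- .modalDepth(pooled)
    out <- list(depth_a = pooled, depth_b = pooled,
                modal_a = m, modal_b = m, ratio = c(a = m, b = m))
  } else {
    ma <- .modalDepth(da); mb <- .modalDepth(db)
    out <- list(depth_a = da, depth_b = db, modal_a = ma, modal_b = mb,
                ratio = c(a = mb, b = ma))
  }
  class(out) <- "DepthProfile"
  out
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat("DepthProfile: depth ratio",
      paste0(x$ratio[1], ":", x$ratio[2]), "\n")
  invisible(x)
}

# fragments of a block set against the reference side: one row per block,
# with the reference span
.refFragments <- function(bl, minAnchors) {
  blk <- bl@blocks[bl@blocks$n_anchors >= minAnchors, , drop = FALSE]
  an <- bl@anchors
  if (!nrow(blk))
    return(data.frame(block_id = integer(), ref_chrom = character(),
                      lo = integer(), hi = integer(), n_anchors = integer(),
                      ks_median = numeric()))
  lo <- vapply(blk$block_id, function(id)
    min(an$ordinal_a[an$block_id == id]), 0L)
  hi <- vapply(blk$block_id, function(id)
    max(an$ordinal_a[an$block_id == id]), 0L)
  data.frame(block_id = blk$block_id, ref_chrom = blk$chrom_a,
             lo = lo, hi = hi, n_anchors = blk$n_anchors,
             ks_median = blk$ks_median, stringsAsFactors = FALSE)
}

# greedy interval-partitioning of fragments into m groups per ref chromosome
.groupFragments <- function(frags, m) {
  frags$group <- NA_integer_
  for (ch in unique(frags$ref_chrom)) {
    idx <- which(frags$ref_chrom == ch)
    idx <- idx[order(frags$lo[idx], -frags$n_anchors[idx], frags$block_id[idx])]
    ends <- numeric(0)                     # current max end per group
    for (i in idx) {
      placed <- FALSE
      for (gp in seq_along(ends)) {
        if (frags$lo[i] > ends[gp]) {      # no overlap with group gp
          frags$group[i] <- gp
          ends[gp] <- max(ends[gp], frags$hi[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        ends <- c(ends, frags$hi[i])
        frags$group[i] <- length(ends)
      }
    }
  }
  frags
}

#' Assign polyploidy-produced subgenomes against a reference
#'
#' The reference genome (side a, assumed unaffected by the event under
#' study) defines the coordinate system; the covering query fragments
#' (blocks) of each reference chromosome are partitioned into `m` groups so
#' that no group overlaps itself on the reference, then ranked by retained
#' gene (anchor) count: the highest-retention group is the dominant
#' subgenome (`"A"`), the lowest the sensitive one. Ties are resolved
#' arbitrarily (stable order) and flagged.
#'
#' @param bl a [CollinearBlocks-class]; side a must be the reference (use
#'   [depthRatio()] semantics; re-oriented automatically when the reference
#'   is side b).
#' @param refAnn,queryAnn reference and query annotations.
#' @param m event multiplicity (expected number of subgenomes).
#' @param minAnchors block size filter.
#' @return list of class `SubgenomeAssignment`: `fragments` (per block:
#'   `block_id`, `ref_chrom`, `subgenome`, `rank`, `n_anchors`), `summary`
#'   (per ref chromosome x subgenome: anchors, retention rate vs the
#'   reference span, dominance class), `ties` (logical), `overflow`
#'   (fraction of reference genes with depth > m).
#' @export
assignSubgenomes <- function(bl, refAnn, queryAnn, m,
                             minAnchors = bl@params$min_anchors) {
  bl <- .orientBlocks(bl, refAnn@species)
  frags <- .refFragments(bl, minAnchors)
  frags <- .groupFragments(frags, m)
  depth <- .sideDepth(bl, refAnn, "a", minAnchors)
  overflow <- mean(depth > m)
  if (overflow > 0.05)
    warning(sprintf(paste0("%.1f%% of reference genes have colinear depth > %d; ",
                           "the event multiplicity may be wrong"),
                    100 * overflow, m))
  refGenes <- refAnn@genes
  out <- list(); ties <- FALSE
  for (ch in unique(frags$ref_chrom)) {
    f <- frags[frags$ref_chrom == ch, , drop = FALSE]
    sizes <- tapply(f$n_anchors, f$group, sum)
    o <- order(-sizes, as.integer(names(sizes)))
    if (any(duplicated(sizes[o]))) ties <- TRUE
    rankOf <- setNames(seq_along(o), names(sizes)[o])
    f$rank <- rankOf[as.character(f$group)]
    f$subgenome <- LETTERS[f$rank]
    out[[ch]] <- f
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  summ <- NULL
  if (!is.null(frags) && nrow(frags)) {
    agg <- stats::aggregate(n_anchors ~ ref_chrom + subgenome + rank,
                            data = frags, FUN = sum)
    nGroups <- stats::aggregate(rank ~ ref_chrom, data = frags,
                                FUN = function(r) length(unique(r)))
    names(nGroups)[2] <- "n_groups"
    agg <- merge(agg, nGroups, by = "ref_chrom")
    span <- vapply(agg$ref_chrom, function(ch)
      sum(refGenes$chrom == ch), 0L)
    agg$retention <- agg$n_anchors / span
    agg$class <- ifelse(agg$rank == 1L, "dominant",
                        ifelse(agg$rank == agg$n_groups, "sensitive",
                               "intermediate"))
    summ <- agg[order(agg$ref_chrom, agg$rank),
                c("ref_chrom", "subgenome", "rank", "n_anchors",
                  "retention", "class")]
    rownames(summ) <- NULL
  }
  structure(list(fragments = frags, summary = summ, ties = ties,
                 overflow = overflow, m = m, query = queryAnn@species,
                 reference = refAnn@species),
            class = "SubgenomeAssignment")
}

#' @export
print.SubgenomeAssignment <- function(x, ...) {
  cat("SubgenomeAssignment:", x$query, "onto", x$reference,
      sprintf("(m = %d%s)\n", x$m, if (x$ties) ", ties" else ""))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

# choose, for every query gene, its single best fragment (event-layer
# gating): larger blocks first, then ks_median closest to ksBand center,
# then block id; returns anchor table restricted to winning fragments
.gateAnchors <- function(bl, frags, ksBand = NULL) {
  an <- bl@anchors[bl@anchors$block_id %in% frags$block_id, , drop = FALSE]
  f <- frags[match(an$block_id, frags$block_id), ]
  ksDist <- if (!is.null(ksBand) && all(is.finite(f$ks_median)))
    abs(f$ks_median - mean(ksBand)) else rep(0, nrow(an))
  o <- order(-f$n_anchors, ksDist, f$block_id)
  an <- an[o, , drop = FALSE]
  an[!duplicated(an$gene_b), , drop = FALSE]
}

#' Build the event-related multi-genome alignment table
#'
#' Rows follow the reference gene order. The reference contributes its gene
#' column plus `refDepth - 1` paralog columns (from the reference
#' self-comparison blocks); every query genome contributes `depth` columns,
#' one per expected orthologous subgenome, filled with the colinear query
#' gene at each reference position or the absence mark `"."` (gene lost,
#' translocated, or unassembled — not distinguished). The header records
#' the column arithmetic, e.g. `"19=3+2+2+2+2+4+4"`.
#'
#' Each query gene is placed at most once (fragments are gated to the best
#' event layer first — larger blocks, then `ks_median` closest to the
#' query's `ksBand`); a duplicated placement after gating raises an
#' integrity error.
#'
#' @param refAnn reference [GenomeAnnotation-class].
#' @param queries list of query specifications: each a list with `ann`
#'   (annotation), `blocks` ([CollinearBlocks-class] vs the reference),
#'   `depth` (expected subgenome count), optional `ksBand` (numeric(2)).
#' @param selfBlocks optional reference self-comparison
#'   [CollinearBlocks-class] (required when `refDepth > 1`).
#' @param refDepth expected reference depth (1 + paralog columns).
#' @param minAnchors block size filter.
#' @return an [AlignmentTable-class].
#' @export
buildAlignmentTable <- function(refAnn, queries, selfBlocks = NULL,
                                refDepth = 1, minAnchors = 4) {
  rg <- refAnn@genes
  rg <- rg[order(rg$chrom, rg$ordinal), , drop = FALSE]
  tabl <- data.frame(chrom = rg$chrom, ordinal = rg$ordinal,
                     stringsAsFactors = FALSE)
  tabl[[refAnn@species]] <- rg$gene_id
  rowOf <- setNames(seq_len(nrow(rg)), rg$gene_id)

  fillColumns <- function(bl, ann, depth, ksBand, label) {
    frags <- .refFragments(bl, minAnchors)
    frags <- frags[order(-frags$n_anchors, frags$block_id), , drop = FALSE]
    grouped <- .groupFragments(frags, depth)
    # rank groups per chromosome by anchors (dominant first)
    cols <- matrix(".", nrow = nrow(rg), ncol = depth)
    colnames(cols) <- paste0(label, ".", LETTERS[seq_len(depth)])
    gated <- .gateAnchors(bl, grouped, ksBand)
    for (ch in unique(grouped$ref_chrom)) {
      f <- grouped[grouped$ref_chrom == ch, , drop = FALSE]
      sizes <- tapply(f$n_anchors, f$group, sum)
      o <- order(-sizes, as.integer(names(sizes)))
      rankOf <- setNames(seq_along(o), names(sizes)[o])
      for (i in seq_len(nrow(f))) {
        rk <- rankOf[as.character(f$group[i])]
        if (rk > depth) next                       # overflow layer dropped
        an <- gated[gated$block_id == f$block_id[i], , drop = FALSE]
        if (!nrow(an)) next
        rows <- rowOf[an$gene_a]
        prev <- cols[rows, rk]
        dupPos <- prev != "." & prev != an$gene_b
        if (any(dupPos)) next                      # later (smaller) fragment loses
        cols[rows, rk] <- an$gene_b
      }
    }
    dup <- duplicated(cols[cols != "."])
    if (any(dup))
      stop("integrity error: query gene(s) mapped to two cells: ",
           paste(unique(cols[cols != "."][dup]), collapse = ", "))
    cols
  }

  depths <- as.integer(refDepth)
  names(depths) <- refAnn@species
  if (refDepth > 1) {
    if (is.null(selfBlocks))
      stop("refDepth > 1 needs the reference self-comparison blocks")
    # symmetrize the self blocks: each block contributes both directions
    sb <- selfBlocks
    an <- sb@anchors
    anSym <- rbind(an,
                   transform(an,
                             gene_a = an$gene_b, gene_b = an$gene_a,
                             ordinal_a = an$ordinal_b,
                             ordinal_b = an$ordinal_a,
                             block_id = an$block_id + max(an$block_id)))
    blk <- sb@blocks
    blkSym <- rbind(blk,
                    transform(blk, chrom_a = blk$chrom_b,
                              chrom_b = blk$chrom_a,
                              block_id = blk$block_id + max(an$block_id)))
    anSym <- anSym[order(anSym$block_id, anSym$ordinal_a), , drop = FALSE]
    blSym <- new("CollinearBlocks", genome_a = sb@genome_a,
                 genome_b = sb@genome_b, blocks = blkSym, anchors = anSym,
                 params = sb@params)
    paraCols <- fillColumns(blSym, refAnn, refDepth - 1L, NULL,
                            refAnn@species)
    colnames(paraCols) <- paste0(refAnn@species, ".",
                                 LETTERS[1 + seq_len(refDepth - 1L)])
    tabl <- cbind(tabl, paraCols, stringsAsFactors = FALSE)
  }
  for (q in queries) {
    bl <- .orientBlocks(q$blocks, refAnn@species)
    depth <- as.integer(q$depth)
    stopifnot(depth >= 1)
    cols <- fillColumns(bl, q$ann, depth, q$ksBand, q$ann@species)
    tabl <- cbind(tabl, cols, stringsAsFactors = FALSE)
    depths[q$ann@species] <- as.integer(depth)
  }
  header <- paste0(sum(depths), "=", paste(depths, collapse = "+"))
  new("AlignmentTable", ref_species = refAnn@species, table = tabl,
      depths = depths, header = header)
}

#' Render a local region of an alignment table
#'
#' Stacked gene tracks (reference on top, then every subgenome column) with
#' gray links joining each reference gene to its colinear genes.
#'
#' @param tab an [AlignmentTable-class].
#' @param chrom reference chromosome.
#' @param from,to reference ordinal range (default: whole chromosome).
#' @param file output file (PNG or SVG by extension); `NULL` draws on the
#'   current device.
#' @return invisibly, the file path (or `NULL`).
#' @export
localAlignmentView <- function(tab, chrom, from = NULL, to = NULL,
                               file = NULL) {
  tt <- tab@table
  tt <- tt[tt$chrom == chrom, , drop = FALSE]
  if (!nrow(tt)) stop("no reference genes on chromosome '", chrom, "'")
  if (is.null(from)) from <- min(tt$ordinal)
  if (is.null(to)) to <- max(tt$ordinal)
  tt <- tt[tt$ordinal >= from & tt$ordinal <= to, , drop = FALSE]
  cols <- setdiff(names(tt), c("chrom", "ordinal"))
  if (!is.null(file)) {
    if (grepl("[.]svg$", file)) grDevices::svg(file, width = 8, height = 4)
    else grDevices::png(file, width = 900, height = 420)
    on.exit(grDevices::dev.off())
  }
  nT <- length(cols)
  graphics::plot(NULL, xlim = c(from - 1, to + 1), ylim = c(0.5, nT + 0.5),
                 xlab = paste("gene ordinal on", chrom),
                 ylab = "", yaxt = "n", bty = "n",
                 main = paste("local alignment:", tab@ref_species, chrom))
  graphics::axis(2, at = rev(seq_len(nT)), labels = cols, las = 2,
                 cex.axis = 0.7)
  for (j in seq_along(cols)) {
    y <- nT - j + 1
    present <- tt[[cols[j]]] != "."
    graphics::rect(tt$ordinal[present] - 0.4, y - 0.15,
                   tt$ordinal[present] + 0.4, y + 0.15,
                   col = if (j == 1) "steelblue" else "darkseagreen",
                   border = NA)
    if (j > 1)
      graphics::segments(tt$ordinal[present], nT - 0.15,
                         tt$ordinal[present], y + 0.15,
                         col = grDevices::adjustcolor("gray40", 0.35))
  }
  invisible(file)
}
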