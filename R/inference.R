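# One-step derivability of an observed circular gene order under the DRRL
# (and, for comparison, TDRL) model. The criterion is the two-increasing-run
# decomposition of the rearranged block: after a duplication of the genes
# between two replication origins and loss of one copy of each gene, the
# surviving copy-1 genes form one run and the surviving copy-2 genes a
# second run, each preserving the ancestral relative order; hence the block,
# read off the observed order, must contain at most one descent in ancestral
# rank.

.rot <- function(x, i) {
  if (i <= 1L || !length(x)) x else c(x[i:length(x)], x[seq_len(i - 1L)])
}

#' Descents of an index sequence
#'
#' Positions \code{i} at which \code{seq[i + 1] < seq[i]}.
#'
#' @param seq numeric vector (typically ancestral ranks).
#' @return increasing integer vector of descent positions.
#' @examples
#' descents(c(3, 2, 1))  # 1 2
#' @export
descents <- function(seq) {
  if (length(seq) < 2L) return(integer(0))
  which(diff(seq) < 0)
}

#' Valid splits of a sequence into two increasing runs
#'
#' Positions \code{s} (0 to \code{length(seq)}) such that both
#' \code{seq[1..s]} and \code{seq[(s+1)..n]} are strictly increasing: with
#' two or more descents there is none, with exactly one descent the split is
#' unique (at the descent), and with none every position is valid.
#'
#' @param seq numeric vector with distinct values.
#' @return integer vector of valid split positions.
#' @export
twoIncreasingSplit <- function(seq) {
  d <- descents(seq)
  if (length(d) >= 2L) return(integer(0))
  if (length(d) == 1L) return(d)
  0:length(seq)
}

# --- shared checks --------------------------------------------------------

.geneView <- function(order) {
  el <- order@elements
  g <- el$class %in% GENE_CLASSES
  list(el = el, tok = .formatToken(el$label, el$copy)[g],
       strand = el$strand[g], gene = g)
}

.checkComparable <- function(ancestral, observed) {
  if (!ancestral@circular || !observed@circular) {
    stop("derivability analysis requires circular orders")
  }
  av <- .geneView(ancestral); ov <- .geneView(observed)
  missing <- setdiff(av$tok, ov$tok)
  extra <- setdiff(ov$tok, av$tok)
  if (length(missing) || length(extra) || length(av$tok) != length(ov$tok)) {
    stop("gene content mismatch; missing: [",
         paste(missing, collapse = " "), "], extra: [",
         paste(extra, collapse = " "), "]")
  }
  astr <- stats::setNames(av$strand, av$tok)
  inv <- ov$tok[astr[ov$tok] != ov$strand]
  if (length(inv)) {
    warning("strand inversion detected for: ", paste(inv, collapse = ", "),
            "; duplication-loss models cannot invert strands")
    return(inv)
  }
  character(0)
}

# gaps of an observed order, rotated to start at a given gene token: the
# gene-token sequence plus, per gene j, the non-gene elements (class, token)
# sitting between gene j and gene j+1 (gap N wraps to gene 1)
.gapView <- function(order, startTok) {
  el <- order@elements
  tok <- .formatToken(el$label, el$copy)
  g <- el$class %in% GENE_CLASSES
  at <- which(tok == startTok & g)
  idx <- .rot(seq_len(nrow(el)), at)
  genes <- character(0)
  gaps <- list()
  cur <- 0L
  for (i in idx) {
    if (g[i]) {
      cur <- cur + 1L
      genes[cur] <- tok[i]
      gaps[[cur]] <- data.frame(class = character(0), tok = character(0))
    } else {
      gaps[[cur]] <- rbind(gaps[[cur]],
                           data.frame(class = el$class[i], tok = tok[i]))
    }
  }
  list(genes = genes, gaps = gaps)
}

# cyclic site placement: which of the gaps after genes 1..N hold the CRI,
# CRII, CRIII sites for survivor counts (m upstream, s copy1, k-s copy2)
.sitesPerGap <- function(m, s, k) {
  N <- m + k
  gs <- rep(list(character(0)), N)
  pre <- character(0)
  lastGene <- 0L
  emit <- function(counts) lastGene + counts
  walk <- c(rep("G", m), "CRI", rep("G", s), "CRII", rep("G", k - s), "CRIII")
  for (item in walk) {
    if (item == "G") lastGene <- lastGene + 1L
    else if (lastGene == 0L) pre <- c(pre, item)
    else gs[[lastGene]] <- c(gs[[lastGene]], item)
  }
  gs[[N]] <- c(gs[[N]], pre)
  gs
}

# match observed non-gene elements onto predicted CR sites; returns the
# implied fates (named over CRI/CRII/CRIII) or NULL if inconsistent
.matchSites <- function(gaps, siteGaps) {
  fates <- c(CRI = "lost", CRII = "lost", CRIII = "lost")
  for (j in seq_along(siteGaps)) {
    o <- gaps[[j]]
    e <- siteGaps[[j]]
    if (nrow(o) > length(e)) return(NULL)
    for (i in seq_len(nrow(o))) {
      fates[[e[i]]] <- if (o$class[i] == "CR") "functional" else "remnant"
    }
  }
  if (!any(fates == "functional")) return(NULL)
  fates
}

.edgeBlocks <- function(ancestral) {
  el <- ancestral@elements
  if (sum(el$class == "CR") != 1L) {
    stop("ancestral order must contain exactly one CR")
  }
  if (any(el$class == "remnant")) {
    stop("ancestral order may not contain remnant elements")
  }
  n <- nrow(el)
  tok <- .formatToken(el$label, el$copy)
  crPos <- which(el$class == "CR")
  walk <- function(from, to) {
    out <- integer(0)
    i <- if (from < n) from + 1L else 1L
    while (i != to) { out <- c(out, i); i <- if (i < n) i + 1L else 1L }
    out
  }
  lapply(seq_len(n), function(e) {
    b <- if (e < n) e + 1L else 1L
    blockRows <- if (b == crPos) integer(0) else walk(e, crPos)
    upRows <- if (e == crPos) integer(0) else walk(crPos, b)
    list(edge = e, edgeTok = c(tok[e], tok[b]), block = tok[blockRows],
         upstream = tok[upRows])
  })
}

#' Enumerate one-step DRRL explanations of an observed order
#'
#' Decides whether \code{observed} is derivable from \code{ancestral} by a
#' single DRRL event and enumerates every explanation. For each candidate
#' insertion edge on the ancestral circle, the implied duplicated block is
#' the run of genes from the insertion point forward to the ancestral CR;
#' the observed arrangement of those genes must decompose into two
#' increasing runs (\code{\link{twoIncreasingSplit}}), and observed CR,
#' remnant and noncoding elements must sit at the positions where the event
#' places CRI, CRII and CRIII (a CR implies fate \code{functional}, a
#' remnant/NC element fate \code{remnant}, an empty position fate
#' \code{lost}). One explanation is emitted per valid (edge, split),
#' sorted by edge then split.
#'
#' @param ancestral circular \code{GeneOrder} with exactly one CR.
#' @param observed circular \code{GeneOrder} over the same genes; may carry
#'   CR, remnant and NC elements.
#' @param requireRemnants discard explanations whose predicted CRII/CRIII
#'   positions lack an observed CR/remnant/NC element (default FALSE).
#' @return list of \code{\link{Explanation}}s; empty (with a warning and
#'   attribute \code{inversion}) when the observed order inverts a strand.
#' @export
explainDrrl <- function(ancestral, observed, requireRemnants = FALSE) {
  inv <- .checkComparable(ancestral, observed)
  if (length(inv)) {
    out <- list()
    attr(out, "inversion") <- inv
    return(out)
  }
  ov <- .geneView(observed)
  obsG <- ov$tok
  res <- list()
  keys <- character(0)
  ord <- NULL
  for (eb in .edgeBlocks(ancestral)) {
    m <- length(eb$upstream)
    k <- length(eb$block)
    if (m + k == 0L) next
    if (m > 0L) {
      rotG <- .rot(obsG, match(eb$upstream[1L], obsG))
      if (!identical(rotG[seq_len(m)], eb$upstream)) next
      starts <- eb$upstream[1L]
    } else {
      starts <- obsG
    }
    for (startTok in starts) {
      gv <- .gapView(observed, startTok)
      arr <- if (k > 0L) gv$genes[(m + 1L):(m + k)] else character(0)
      if (m > 0L && !identical(gv$genes[seq_len(m)], eb$upstream)) next
      ranks <- match(arr, eb$block)
      if (anyNA(ranks)) next
      for (s in twoIncreasingSplit(ranks)) {
        fates <- .matchSites(gv$gaps, .sitesPerGap(m, s, k))
        if (is.null(fates)) next
        support <- fates[["CRII"]] != "lost" && fates[["CRIII"]] != "lost"
        if (requireRemnants && !support) next
        copy1 <- arr[seq_len(s)]
        copy2 <- if (s < k) arr[(s + 1L):k] else character(0)
        key <- paste(eb$edge, paste(sort(copy1), collapse = ","), sep = "|")
        if (key %in% keys) next
        keys <- c(keys, key)
        ev <- new("DrrlEvent", insertionEdge = eb$edgeTok, block = eb$block,
                  lossAssignment = stats::setNames(
                    as.character(ifelse(eb$block %in% copy1, "copy1", "copy2")), eb$block),
                  crFates = fates, seed = NA_integer_)
        res[[length(res) + 1L]] <- new("Explanation", mechanism = "DRRL",
                                       event = ev, splitPosition = s,
                                       remnantSupport = support,
                                       copy1 = copy1, copy2 = copy2)
        ord <- rbind(ord, c(eb$edge, s))
      }
    }
  }
  if (length(res)) res <- res[order(ord[, 1L], ord[, 2L])]
  res
}

#' Enumerate one-step TDRL explanations of an observed order
#'
#' Analogous enumeration over contiguous ancestral blocks: a one-step TDRL
#' explanation exists iff the genes of some block occupy the block's slot in
#' the observed order as two increasing runs. CR and remnant elements are
#' ignored on both sides (TDRL carries no CR bookkeeping), so TDRL
#' explanations never carry remnant support.
#'
#' @param ancestral,observed circular \code{GeneOrder}s over the same genes.
#' @return list of \code{\link{Explanation}}s with mechanism \code{"TDRL"}.
#' @export
explainTdrl <- function(ancestral, observed) {
  inv <- .checkComparable(ancestral, observed)
  if (length(inv)) {
    out <- list()
    attr(out, "inversion") <- inv
    return(out)
  }
  ancG <- .geneView(ancestral)$tok
  obsG <- .geneView(observed)$tok
  n <- length(ancG)
  res <- list()
  keys <- character(0)
  for (p in seq_len(n)) {
    for (L in seq_len(n)) {
      block <- .rot(ancG, p)[seq_len(L)]
      if (L < n) {
        others <- .rot(ancG, p)[(L + 1L):n]
        rotG <- .rot(obsG, match(others[1L], obsG))
        if (!identical(rotG[seq_len(n - L)], others)) next
        arrs <- list(rotG[(n - L + 1L):n])
      } else {
        arrs <- lapply(seq_len(n), function(r) .rot(obsG, r))
      }
      for (arr in arrs) {
        ranks <- match(arr, block)
        if (anyNA(ranks)) next
        for (s in twoIncreasingSplit(ranks)) {
          copy1 <- arr[seq_len(s)]
          key <- paste(paste(block, collapse = ","),
                       paste(sort(copy1), collapse = ","), sep = "|")
          if (key %in% keys) next
          keys <- c(keys, key)
          ev <- new("TdrlEvent", block = block,
                    lossAssignment = stats::setNames(
                      as.character(ifelse(block %in% copy1, "copy1", "copy2")), block),
                    seed = NA_integer_)
          res[[length(res) + 1L]] <- new("Explanation", mechanism = "TDRL",
                                         event = ev, splitPosition = s,
                                         remnantSupport = FALSE,
                                         copy1 = copy1,
                                         copy2 = setdiff(arr, copy1))
        }
      }
    }
  }
  res
}

#' Reduce recent segment duplications
#'
#' Finds maximal repeated segments of an observed order (runs whose label
#' sequences are identical up to copy tags, e.g. CR-trnC-trnY vs
#' CR-trnC'-trnY') and emits both possible reductions (removing either
#' copy); the caller scores reductions by downstream one-step derivability.
#' Copy tags of the surviving occurrence are cleared when that leaves the
#' label unique.
#'
#' @param observed a circular \code{GeneOrder}.
#' @return list of entries with components \code{segment} (tokens of the
#'   first occurrence), \code{removed} (\code{"second"} or \code{"first"})
#'   and \code{order} (the reduced \code{GeneOrder}); empty when the order
#'   has no repeats.
#' @export
reduceRecentDuplications <- function(observed) {
  ord <- canonicalRotation(observed)
  el <- ord@elements
  n <- nrow(el)
  lab <- el$label
  segs <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (i >= j || lab[i] != lab[j]) next
      if (i > 1L && lab[i - 1L] == lab[j - 1L]) next  # not left-maximal
      len <- 1L
      while (i + len < j && j + len <= n && lab[i + len] == lab[j + len]) {
        len <- len + 1L
      }
      segs[[length(segs) + 1L]] <- c(i = i, j = j, len = len)
    }
  }
  out <- list()
  for (sg in segs) {
    first <- sg[["i"]]:(sg[["i"]] + sg[["len"]] - 1L)
    second <- sg[["j"]]:(sg[["j"]] + sg[["len"]] - 1L)
    segTok <- .formatToken(el$label[first], el$copy[first])
    for (which in c("second", "first")) {
      drop <- if (which == "second") second else first
      red <- el[-drop, , drop = FALSE]
      for (l in unique(el$label[drop])) {
        at <- which(red$label == l)
        if (length(at) == 1L && red$copy[at] != "") red$copy[at] <- ""
      }
      rownames(red) <- NULL
      out[[length(out) + 1L]] <- list(
        segment = segTok, removed = which,
        order = new("GeneOrder", elements = red, circular = ord@circular))
    }
  }
  out
}

#' Exhaustive one-step DRRL oracle
#'
#' Brute-force enumeration used as an independent oracle for
#' \code{\link{explainDrrl}}: every insertion edge, every of the \code{2^k}
#' loss assignments of its block, and every CR fate combination is replayed
#' and compared element-wise (genes with strands, CRs, remnants) against the
#' observed order.
#'
#' @param ancestral,observed circular \code{GeneOrder}s as in
#'   \code{\link{explainDrrl}}.
#' @param maxBlock refuse enumeration when the largest block exceeds this
#'   many genes (the search costs edges x 2^block).
#' @return list of \code{\link{Explanation}}s.
#' @export
bruteForceExplanations <- function(ancestral, observed, maxBlock = 12L) {
  inv <- .checkComparable(ancestral, observed)
  if (length(inv)) {
    out <- list()
    attr(out, "inversion") <- inv
    return(out)
  }
  av <- .geneView(ancestral)
  ov <- .geneView(observed)
  nGenes <- length(av$tok)
  if (nGenes > maxBlock) {
    stop(sprintf("largest enumerated block (%d genes) exceeds maxBlock (%d)",
                 nGenes, maxBlock))
  }
  strandOf <- stats::setNames(paste0(av$strand, av$tok), av$tok)
  anchor <- sort(av$tok)[1L]
  # observed full token sequence, rotated to the anchor gene
  oel <- observed@elements
  otok <- .formatToken(oel$label, oel$copy)
  og <- oel$class %in% GENE_CLASSES
  full <- ifelse(og, paste0(oel$strand, otok),
                 ifelse(oel$class == "CR", "CR", "*"))
  at <- which(og & otok == anchor)
  obsFull <- .rot(full, at)
  obsGRot <- unname(strandOf[.rot(ov$tok, match(anchor, ov$tok))])
  fateGrid <- expand.grid(CRI = c("functional", "remnant", "lost"),
                          CRII = c("functional", "remnant", "lost"),
                          CRIII = c("functional", "remnant", "lost"),
                          stringsAsFactors = FALSE)
  fateGrid <- fateGrid[rowSums(fateGrid == "functional") >= 1L, , drop = FALSE]
  mat <- function(f) switch(f, functional = "CR", remnant = "*", lost = NULL)
  res <- list()
  keys <- character(0)
  for (eb in .edgeBlocks(ancestral)) {
    k <- length(eb$block)
    upS <- unname(strandOf[eb$upstream])
    blockS <- unname(strandOf[eb$block])
    for (S in 0:(2^k - 1)) {
      bits <- bitwAnd(S, bitwShiftL(1L, seq_len(max(k, 1L)) - 1L)) > 0L
      if (!k) bits <- logical(0)
      candG <- c(upS, blockS[bits], blockS[!bits])
      p <- match(strandOf[[anchor]], candG)
      if (!identical(unname(.rot(candG, p)), obsGRot)) next
      copy1 <- eb$block[bits]
      copy2 <- eb$block[!bits]
      for (fi in seq_len(nrow(fateGrid))) {
        f <- fateGrid[fi, ]
        candFull <- c(upS, mat(f$CRI), blockS[bits], mat(f$CRII),
                      blockS[!bits], mat(f$CRIII))
        if (length(candFull) != length(obsFull)) next
        pp <- match(strandOf[[anchor]], candFull)
        if (!identical(unname(.rot(candFull, pp)), obsFull)) next
        key <- paste(eb$edge, paste(sort(copy1), collapse = ","), sep = "|")
        if (!key %in% keys) {
          keys <- c(keys, key)
          ev <- new("DrrlEvent", insertionEdge = eb$edgeTok, block = eb$block,
                    lossAssignment = stats::setNames(
                      as.character(ifelse(eb$block %in% copy1, "copy1", "copy2")), eb$block),
                    crFates = c(CRI = f$CRI, CRII = f$CRII, CRIII = f$CRIII),
                    seed = NA_integer_)
          res[[length(res) + 1L]] <- new("Explanation", mechanism = "DRRL",
                                         event = ev,
                                         splitPosition = length(copy1),
                                         remnantSupport =
                                           f$CRII != "lost" && f$CRIII != "lost",
                                         copy1 = copy1, copy2 = copy2)
        }
        break
      }
    }
  }
  res
}

#' Comparable identity keys of a list of explanations
#'
#' A canonical "edge | copy-1 survivor set" (DRRL) or "block | copy-1 set"
#' (TDRL) key per explanation, for set comparison between
#' \code{\link{explainDrrl}} and \code{\link{bruteForceExplanations}}.
#'
#' @param explanations list of \code{\link{Explanation}}s.
#' @return sorted character vector.
#' @export
explanationKeys <- function(explanations) {
  sort(vapply(explanations, function(x) {
    left <- if (is(x@event, "DrrlEvent")) {
      paste(x@event@insertionEdge, collapse = ">")
    } else {
      paste(x@event@block, collapse = ",")
    }
    paste(left, paste(sort(x@copy1), collapse = ","), sep = "|")
  }, character(1)))
}
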