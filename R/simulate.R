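# Forward simulators for control-region duplication/translocation, double
# replication between two origins, random loss with CR fate assignment, and
# classic TDRL. The replication direction of a double replication is fixed
# as the direction in which the genes follow the first origin (CRI), which
# is the convention that reproduces the duplicated layout
# [upstream, CRI, block copy 1, CRII, block copy 2, CRIII].

.tokenRow <- function(order, token) {
  r <- .resolveToken(token)
  hit <- which(order@elements$label == r$label & order@elements$copy == r$copy)
  if (length(hit) != 1L) {
    stop(sprintf("element '%s' %s in order", token,
                 if (length(hit)) "is ambiguous" else "not found"))
  }
  hit
}

#' Duplicate a contiguous segment and translocate the copy
#'
#' Copies a contiguous run of elements and inserts the copy (each element
#' tagged with an extra \code{'}) at the given edge; the original segment is
#' untouched. Inserting at an edge adjacent to the segment end yields a
#' tandem duplication.
#'
#' @param order a \code{GeneOrder}.
#' @param segment character vector of element tokens forming a contiguous run
#'   in \code{order} (in order).
#' @param edge ordered pair of adjacent element tokens; the copy is inserted
#'   between them. The edge must not lie inside the segment.
#' @return the enlarged \code{GeneOrder}.
#' @examples
#' b <- duplicateTranslocate(canonicalVertebrateOrder(), "CR",
#'                           c("trnQ", "trnM"))
#' length(b)  # 39
#' @export
duplicateTranslocate <- function(order, segment, edge) {
  el <- order@elements
  n <- nrow(el)
  seg <- vapply(segment, function(t) .tokenRow(order, t), integer(1))
  nxt <- function(i) if (i < n) i + 1L else 1L
  if (length(seg) > 1L) {
    for (j in seq_len(length(seg) - 1L)) {
      if (nxt(seg[j]) != seg[j + 1L]) stop("segment is not contiguous in order")
    }
  }
  e1 <- .tokenRow(order, edge[1L])
  e2 <- .tokenRow(order, edge[2L])
  if (nxt(e1) != e2) stop("insertion edge elements are not adjacent")
  if (e1 %in% seg && e2 %in% seg) stop("insertion edge lies inside the segment")
  copy <- el[seg, , drop = FALSE]
  copy$copy <- paste0(copy$copy, "'")
  out <- rbind(el[seq_len(e1), , drop = FALSE], copy,
               if (e1 < n) el[(e1 + 1L):n, , drop = FALSE])
  rownames(out) <- NULL
  new("GeneOrder", elements = out, circular = order@circular)
}

#' Double replication between two control regions
#'
#' Simulates two successive replications launched from the heavy-strand
#' origins housed in two control regions of one genome: the first replication
#' starts at the origin in CRI, passes through the origin in CRII, and both
#' replications terminate back at CRI. The net product duplicates every gene
#' strictly between CRI and CRII (in the direction in which genes follow
#' CRI) and creates a third control region at the distal end of the second
#' copy, i.e. at the position the original CR occupied. Genes upstream of
#' CRI (between CRII and CRI) stay single-copy.
#'
#' @param order a \code{GeneOrder} containing exactly two CR elements.
#' @param origin1,origin2 tokens of the CRs acting as first and second
#'   origin. By default the most recently copied CR (non-empty copy tag) is
#'   the first origin.
#' @return a \code{\link{DuplicatedState}}.
#' @export
doubleReplication <- function(order, origin1 = NULL, origin2 = NULL) {
  el <- order@elements
  crs <- which(el$class == "CR")
  if (length(crs) != 2L) {
    stop(sprintf("double replication needs exactly 2 CRs, found %d", length(crs)))
  }
  if (is.null(origin1)) {
    tagged <- crs[el$copy[crs] != ""]
    if (length(tagged) != 1L) {
      stop("cannot infer origin1: pass the CR tokens explicitly")
    }
    p1 <- tagged
    p2 <- setdiff(crs, p1)
  } else {
    p1 <- .tokenRow(order, origin1)
    p2 <- if (is.null(origin2)) setdiff(crs, p1) else .tokenRow(order, origin2)
    if (!all(c(p1, p2) %in% crs) || p1 == p2) stop("origins must be the two CRs")
  }
  n <- nrow(el)
  walk <- function(from, to) {  # rows strictly between, moving forward
    out <- integer(0)
    i <- if (from < n) from + 1L else 1L
    while (i != to) {
      out <- c(out, i)
      i <- if (i < n) i + 1L else 1L
    }
    out
  }
  block <- walk(p1, p2)
  upstream <- walk(p2, p1)
  if (any(el$class[block] == "CR")) stop("block may not contain a CR")
  mkCR <- function(tag) data.frame(label = "CR", copy = tag,
                                   strand = el$strand[p1], class = "CR",
                                   index = el$index[p1],
                                   stringsAsFactors = FALSE)
  tagCopy <- function(rows, tag) {
    b <- el[rows, , drop = FALSE]
    if (nrow(b)) b$copy <- paste0(b$copy, tag)
    b
  }
  out <- rbind(el[upstream, , drop = FALSE], mkCR("I"), tagCopy(block, "1"),
               mkCR("II"), tagCopy(block, "2"), mkCR("III"))
  rownames(out) <- NULL
  new("DuplicatedState", elements = out, circular = order@circular,
      blockLabels = el$label[block], blockCopies = el$copy[block])
}

.defaultFates <- c(CRI = "functional", CRII = "remnant", CRIII = "remnant")

#' Random loss of duplicated gene copies
#'
#' Resolves a \code{\link{DuplicatedState}}: for each duplicated gene the
#' copy named by \code{lossAssignment} survives (or, when the assignment is
#' absent, the surviving copy is drawn by an independent fair coin per gene
#' using \code{seed}); lost copies are removed. Control regions follow their
#' assigned fate: \code{functional} CRs stay (the copy tag is cleared when a
#' single CR remains functional), \code{remnant} CRs degenerate into
#' noncoding remnant elements (\code{CRII-remnant} / \code{CRIII-remnant}),
#' and \code{lost} CRs are removed.
#'
#' @param state a \code{DuplicatedState}.
#' @param lossAssignment named character vector over the original block
#'   tokens with values \code{"copy1"}/\code{"copy2"}; \code{NULL} to draw
#'   randomly.
#' @param seed integer seed, required when \code{lossAssignment} is NULL.
#' @param crFates named character over CRI/CRII/CRIII; default
#'   \code{c(CRI = "functional", CRII = "remnant", CRIII = "remnant")}.
#' @return list with components \code{order} (the resolved \code{GeneOrder})
#'   and \code{event} (the \code{\link{DrrlEvent}} recording everything).
#' @export
randomLoss <- function(state, lossAssignment = NULL, seed = NULL,
                       crFates = .defaultFates) {
  stopifnot(is(state, "DuplicatedState"))
  blockTok <- .formatToken(state@blockLabels, state@blockCopies)
  k <- length(blockTok)
  if (is.null(lossAssignment)) {
    if (is.null(seed)) stop("a seed is required for a random loss draw")
    lossAssignment <- withr::with_seed(seed,
      stats::setNames(sample(c("copy1", "copy2"), k, replace = TRUE), blockTok))
  } else {
    if (!setequal(names(lossAssignment), blockTok) ||
        length(lossAssignment) != k) {
      stop("loss assignment must cover exactly the duplicated block: ",
           paste(blockTok, collapse = " "))
    }
    lossAssignment <- lossAssignment[blockTok]
  }
  if (!setequal(names(crFates), c("CRI", "CRII", "CRIII"))) {
    stop("crFates must name CRI, CRII and CRIII")
  }
  if (!any(crFates == "functional")) stop("at least one CR must stay functional")

  el <- state@elements
  nFunctional <- sum(crFates == "functional")
  crRow <- function(tag) which(el$class == "CR" & el$copy == tag)
  upstreamRows <- seq_len(min(crRow("I")) - 1L)
  survivors <- function(tag, want) {
    rows <- which(el$class %in% GENE_CLASSES & endsWith(el$copy, tag))
    keep <- lossAssignment == want
    sub <- el[rows[keep], , drop = FALSE]
    sub$copy <- substr(sub$copy, 1L, nchar(sub$copy) - 1L)  # restore identity
    sub
  }
  fateRows <- function(name, tag) {
    f <- crFates[[name]]
    if (f == "lost") return(NULL)
    row <- el[crRow(tag), , drop = FALSE]
    if (f == "functional") {
      if (nFunctional == 1L) row$copy <- ""
      return(row)
    }
    data.frame(label = paste0("CR", tag, "-remnant"), copy = "", strand = "H",
               class = "remnant", index = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- rbind(el[upstreamRows, , drop = FALSE],
               fateRows("CRI", "I"), survivors("1", "copy1"),
               fateRows("CRII", "II"), survivors("2", "copy2"),
               fateRows("CRIII", "III"))
  rownames(out) <- NULL
  prev <- if (length(upstreamRows)) {
    .formatToken(el$label[max(upstreamRows)], el$copy[max(upstreamRows)])
  } else "CR"
  nxt <- if (k) blockTok[1L] else "CR"
  event <- new("DrrlEvent", insertionEdge = c(prev, nxt), block = blockTok,
               lossAssignment = lossAssignment,
               crFates = stats::setNames(as.character(crFates[c("CRI", "CRII", "CRIII")]),
                                         c("CRI", "CRII", "CRIII")),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(order = new("GeneOrder", elements = out, circular = state@circular),
       event = event)
}

#' Simulate one full DRRL event
#'
#' Composition of \code{\link{duplicateTranslocate}} (of the single CR, to
#' \code{insertionEdge}), \code{\link{doubleReplication}} and
#' \code{\link{randomLoss}}.
#'
#' @param order a \code{GeneOrder} with exactly one CR.
#' @param insertionEdge ordered pair of adjacent element tokens receiving the
#'   translocated CR copy.
#' @param lossAssignment,seed,crFates passed to \code{\link{randomLoss}}.
#' @return list with \code{order} and \code{event} as in
#'   \code{\link{randomLoss}}; the event's insertion edge is the one given.
#' @examples
#' res <- simulateDrrl(canonicalVertebrateOrder(), c("trnQ", "trnM"), seed = 1)
#' res$event
#' @export
simulateDrrl <- function(order, insertionEdge, lossAssignment = NULL,
                         seed = NULL, crFates = .defaultFates) {
  crs <- which(order@elements$class == "CR")
  if (length(crs) != 1L) stop("simulateDrrl expects exactly one CR")
  crTok <- .formatToken(order@elements$label[crs], order@elements$copy[crs])
  b <- duplicateTranslocate(order, crTok, insertionEdge)
  st <- doubleReplication(b)
  res <- randomLoss(st, lossAssignment = lossAssignment, seed = seed,
                    crFates = crFates)
  res$event@insertionEdge <- as.character(insertionEdge)
  res
}

#' Simulate one classic TDRL event
#'
#' Tandemly duplicates a contiguous block (the copy immediately follows the
#' block) and deletes one copy of each duplicated element per the loss
#' assignment: the result keeps the copy-1 survivors in place followed by
#' the copy-2 survivors. No control-region bookkeeping is performed.
#'
#' @param order a \code{GeneOrder}.
#' @param block character vector of element tokens forming a contiguous run.
#' @param lossAssignment named character over the block tokens with values
#'   \code{"copy1"}/\code{"copy2"}; \code{NULL} to draw with \code{seed}.
#' @param seed integer seed for a random draw.
#' @return list with \code{order} and \code{event} (a \code{TdrlEvent}).
#' @examples
#' toy <- parseGeneOrder("g1 g2 g3 g4 g5 g6")
#' keep1 <- setNames(c("copy1", "copy2", "copy1", "copy2", "copy1", "copy2"),
#'                   paste0("g", 1:6))
#' formatGeneOrder(simulateTdrl(toy, paste0("g", 1:6), keep1)$order)
#' @export
simulateTdrl <- function(order, block, lossAssignment = NULL, seed = NULL) {
  el <- order@elements
  n <- nrow(el)
  rows <- vapply(block, function(t) .tokenRow(order, t), integer(1))
  nxt <- function(i) if (i < n) i + 1L else 1L
  if (length(rows) > 1L) {
    for (j in seq_len(length(rows) - 1L)) {
      if (nxt(rows[j]) != rows[j + 1L]) stop("block is not contiguous in order")
    }
  }
  blockTok <- .formatToken(el$label[rows], el$copy[rows])
  k <- length(blockTok)
  if (is.null(lossAssignment)) {
    if (is.null(seed)) stop("a seed is required for a random loss draw")
    lossAssignment <- withr::with_seed(seed,
      stats::setNames(sample(c("copy1", "copy2"), k, replace = TRUE), blockTok))
  } else if (!setequal(names(lossAssignment), blockTok) ||
             length(lossAssignment) != k) {
    stop("loss assignment must cover exactly the block: ",
         paste(blockTok, collapse = " "))
  } else {
    lossAssignment <- lossAssignment[blockTok]
  }
  surv1 <- rows[lossAssignment == "copy1"]
  surv2 <- rows[lossAssignment == "copy2"]
  keepOrder <- c(surv1, surv2)
  # place survivors in the block slot, keep everything else fixed
  if (order@circular) {
    lin <- ((rows[1L] - 1L + 0:(n - 1L)) %% n) + 1L
    newRows <- c(keepOrder, lin[!(lin %in% rows)])
  } else {
    newRows <- c(if (rows[1L] > 1L) seq_len(rows[1L] - 1L), keepOrder,
                 if (rows[k] < n) (rows[k] + 1L):n)
  }
  out <- el[newRows, , drop = FALSE]
  rownames(out) <- NULL
  res <- new("GeneOrder", elements = out, circular = order@circular)
  if (order@circular) res <- canonicalRotation(res)
  list(order = res,
       event = new("TdrlEvent", block = blockTok,
                   lossAssignment = lossAssignment,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}
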