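# The six-stage reconstruction of the S. latus rearrangement and the
# residue bookkeeping that links deleted gene copies and degenerated CRs to
# the long intergenic spacers of the observed annotation.

# copy-1 survivors of the duplicated block, by canonical position: the
# 11-gene cluster trnC..trnT; every other block gene (incl. trnP) survived
# in copy 2
.SLATUS_COPY1 <- c(14L, 15L, 17L, 20L, 26L, 30L, 32L, 33L, 34L, 35L, 36L)

#' Six-stage reconstruction of the S. latus rearrangement
#'
#' Replays the inferred event chain that turns the canonical vertebrate
#' order into the observed \emph{S. latus} order: (A) the canonical 37-gene
#' + CR order; (B) the CR is duplicated and the copy translocated between
#' trnQ and trnM; (C) the same order, with the first replication under way;
#' (D) the double replication has duplicated the 29 genes between the two
#' CRs and created a third CR; (E) one copy of each duplicated gene pair is
#' lost (the copy-1 cluster keeps trnC, trnY, trnS1, trnK, trnR, trnS2,
#' ND5, ND6, trnE, CYTB, trnT), CRI stays functional while CRII and CRIII
#' degenerate; (F) the CR-trnC-trnY fragment is duplicated once more and the
#' copy translocated between trnL2 and trnP. At stage F the CRII remnant,
#' reduced to an 86-bp residue, drops below annotation scale; the functional
#' CRs take the observed names CR1/CR2 and the CRIII remnant the name NC.
#' Stage F equals \code{\link{samariscusLatusOrder}}.
#'
#' @return named list of six \code{GeneOrder}s (A--F), with attributes
#'   \code{event} (the \code{\link{DrrlEvent}} of stages B--E),
#'   \code{finalSegment} and \code{finalEdge} (the stage E-to-F duplication).
#' @export
reconstructSlatus <- function() {
  A <- canonicalVertebrateOrder()
  B <- duplicateTranslocate(A, "CR", c("trnQ", "trnM"))
  C <- B
  D <- doubleReplication(B)
  blockTok <- .formatToken(D@blockLabels, D@blockCopies)
  blockIdx <- .vocab$index[match(D@blockLabels, .vocab$label)]
  assign <- stats::setNames(
    ifelse(blockIdx %in% .SLATUS_COPY1, "copy1", "copy2"), blockTok)
  E <- randomLoss(D, lossAssignment = assign,
                  crFates = c(CRI = "functional", CRII = "remnant",
                              CRIII = "remnant"))
  F0 <- duplicateTranslocate(E$order, c("CR", "trnC", "trnY"),
                             c("trnL2", "trnP"))
  el <- F0@elements
  el <- el[el$label != "CRII-remnant", , drop = FALSE]
  el$copy[el$label == "CR" & el$copy == ""] <- "1"
  el$copy[el$label == "CR" & el$copy == "'"] <- "2"
  nc <- el$label == "CRIII-remnant"
  el$label[nc] <- "NC"
  rownames(el) <- NULL
  stageF <- new("GeneOrder", elements = el, circular = TRUE)
  stages <- list(A = A, B = B, C = C, D = D, E = E$order, F = stageF)
  attr(stages, "event") <- E$event
  attr(stages, "finalSegment") <- c("CR", "trnC", "trnY")
  attr(stages, "finalEdge") <- c("trnL2", "trnP")
  stages
}

# Chain of retained elements between the two flanks of a resolved DRRL
# event, with the number of elements (gene copies / lost CRs) deleted at
# each junction. Dropped remnants merge into their junction; a final
# segment duplication splits a junction, both new junctions inheriting its
# scar. Tokens are reported with the final (annotation) names.
.eventChain <- function(event, droppedRemnants = character(),
                        rename = c()) {
  blockTok <- event@block
  k <- length(blockTok)
  assign <- event@lossAssignment
  toks <- character(0)
  dels <- integer(0)     # deletions at the junction before each token
  pending <- 0L
  push <- function(tok) {
    toks[length(toks) + 1L] <<- tok
    dels[length(dels) + 1L] <<- pending
    pending <<- 0L
  }
  pushCR <- function(name, tag) {
    f <- event@crFates[[name]]
    if (f == "lost") { pending <<- pending + 1L; return(invisible()) }
    push(if (f == "functional") "CR" else paste0("CR", tag, "-remnant"))
  }
  # deletions trailing the last survivor count toward the next junction;
  # an all-lost copy collapses onto a single junction
  pushCopyFixed <- function(want) {
    prev <- 0L
    for (r in seq_len(k)) {
      if (assign[[blockTok[r]]] == want) {
        pending <<- pending + (r - prev - 1L)
        push(blockTok[r])
        prev <- r
      }
    }
    pending <<- pending + (k - prev)
  }
  pushCR("CRI", "I")
  pushCopyFixed("copy1")
  pushCR("CRII", "II")
  pushCopyFixed("copy2")
  pushCR("CRIII", "III")
  chain <- data.frame(tok = toks, delBefore = dels, stringsAsFactors = FALSE)
  chain$tail <- 0L
  chain$tail[nrow(chain)] <- pending
  # drop sub-annotation remnants, merging their residue into the junction
  for (d in droppedRemnants) {
    at <- which(chain$tok == d)
    if (!length(at)) next
    if (at < nrow(chain)) {
      chain$delBefore[at + 1L] <- chain$delBefore[at + 1L] +
        chain$delBefore[at] + 1L
    } else {
      chain$tail[at - 1L] <- chain$tail[at] + chain$delBefore[at] + 1L
    }
    chain <- chain[-at, , drop = FALSE]
  }
  for (from in names(rename)) chain$tok[chain$tok == from] <- rename[[from]]
  rownames(chain) <- NULL
  chain
}

#' Residue-bearing adjacencies of the S. latus reconstruction
#'
#' Walks the reconstructed event chain (stages A--F of
#' \code{\link{reconstructSlatus}}) and reports, for every adjacency of the
#' final annotated order between the translocated CR and the NC region, how
#' many element copies were deleted there and whether a degenerated CR
#' remnant sits at (or was absorbed into) the junction. Adjacent pairs with
#' at least one deletion or a remnant are "scarred": the model expects their
#' intergenic spacers to carry residual sequence.
#'
#' @return data.frame with columns upstream, downstream, nDeleted, remnant,
#'   scarred; feature names match the packaged annotation.
#' @export
slatusScars <- function() {
  stages <- reconstructSlatus()
  event <- attr(stages, "event")
  chain <- .eventChain(event, droppedRemnants = "CRII-remnant",
                       rename = c(CR = "CR1", `CRIII-remnant` = "NC"))
  # stage E -> F: the CR1-trnC-trnY fragment is copied between trnL2 and
  # trnP; both junctions created by the insertion inherit the scar of the
  # split junction
  edge <- attr(stages, "finalEdge")
  seg <- c("CR2", "trnC'", "trnY'")
  at <- which(chain$tok == edge[1L])
  stopifnot(length(at) == 1L, chain$tok[at + 1L] == edge[2L])
  d <- chain$delBefore[at + 1L]
  ins <- data.frame(tok = seg, delBefore = c(d, 0L, 0L), tail = 0L)
  chain <- rbind(chain[seq_len(at), ], ins,
                 chain[(at + 1L):nrow(chain), ])
  chain$delBefore[at + 1L + length(seg)] <- d
  # flank the chain with its upstream neighbours on the circle
  up <- data.frame(tok = event@insertionEdge[1L],
                   delBefore = 0L, tail = 0L)
  down <- data.frame(tok = "trnF", delBefore = chain$tail[nrow(chain)],
                     tail = 0L)
  chain <- rbind(up, chain, down)
  n <- nrow(chain)
  rem <- grepl("remnant$", chain$tok) | chain$tok == "NC"
  out <- data.frame(upstream = chain$tok[-n], downstream = chain$tok[-1L],
                    nDeleted = chain$delBefore[-1L],
                    remnant = rem[-n] | rem[-1L],
                    stringsAsFactors = FALSE)
  out$scarred <- out$nDeleted > 0L | out$remnant
  out
}

#' Spacer-residue consistency of the observed annotation
#'
#' Cross-checks the annotated intergenic spacers above a length threshold
#' against the reconstructed event chain: under the model, long spacers are
#' residual sequences of gene copies or control regions that degenerated
#' during the rearrangement, so every spacer above the threshold should lie
#' at a scarred adjacency (\code{\link{slatusScars}}).
#'
#' @param features annotation table; defaults to the packaged
#'   \emph{S. latus} table.
#' @param threshold spacer length threshold in bp (default 50).
#' @return data.frame of the spacers above threshold with a logical
#'   \code{scarred} column.
#' @export
residueConsistency <- function(features = slatusAnnotation(), threshold = 50) {
  sp <- computeSpacers(features, genomeLength = max(features$to))
  long <- sp[sp$length > threshold, , drop = FALSE]
  scars <- slatusScars()
  key <- paste(scars$upstream[scars$scarred], scars$downstream[scars$scarred])
  long$scarred <- paste(long$upstream, long$downstream) %in% key
  rownames(long) <- NULL
  long
}
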