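#' @import methods
NULL

GENE_CLASSES <- c("tRNA", "rRNA", "CDS")
ELEMENT_CLASSES <- c(GENE_CLASSES, "CR", "remnant")
ANNOTATION_CLASSES <- c(GENE_CLASSES, "CR", "NC")

#' Circular gene order
#'
#' A \code{GeneOrder} holds an ordered list of labelled, stranded elements of
#' a (by default circular) mitochondrial genome: genes (tRNA, rRNA,
#' protein-coding), control regions (CR) and noncoding remnants. Elements are
#' stored as a data frame with one row per element and columns \code{label}
#' (compact gene name, e.g. \code{trnF}, \code{ND5}, \code{CR}), \code{copy}
#' (copy tag distinguishing duplicates, \code{""} when single), \code{strand}
#' (\code{H} or \code{L}), \code{class} (one of tRNA, rRNA, CDS, CR, remnant)
#' and \code{index} (position 1--38 in the canonical vertebrate order, or
#' \code{NA} for remnants and non-canonical elements).
#'
#' Two circular orders are considered equal when their canonical rotations
#' (see \code{\link{canonicalRotation}}) are element-wise equal.
#'
#' @slot elements data.frame with columns label, copy, strand, class, index.
#' @slot circular logical; circular genomes compare equal under rotation.
#' @export
setClass("GeneOrder",
  representation(elements = "data.frame", circular = "logical"),
  prototype(circular = TRUE)
)

setValidity("GeneOrder", function(object) {
  el <- object@elements
  msgs <- character(0)
  need <- c("label", "copy", "strand", "class", "index")
  if (!all(need %in% names(el))) {
    return(paste("elements must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@circular) != 1L || is.na(object@circular)) {
    msgs <- c(msgs, "circular must be TRUE or FALSE")
  }
  if (nrow(el)) {
    if (!all(el$class %in% ELEMENT_CLASSES)) {
      msgs <- c(msgs, paste("class must be one of", paste(ELEMENT_CLASSES, collapse = "/")))
    }
    if (!all(el$strand %in% c("H", "L"))) {
      msgs <- c(msgs, "strand must be H or L")
    }
    bad <- !is.na(el$index) & (el$index < 1L | el$index > 38L)
    if (any(bad)) msgs <- c(msgs, "index must be in [1, 38] or NA")
    if (any(el$class == "CR" & el$label != "CR")) {
      msgs <- c(msgs, "elements of class CR must have label CR")
    }
    key <- paste(el$label, el$copy, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- el$label[duplicated(key)][1L]
      msgs <- c(msgs, sprintf("duplicate (label, copy) pair: %s", dup))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Duplicated intermediate state of a double replication
#'
#' The gene order produced by \code{\link{doubleReplication}}: upstream
#' single-copy genes, the first control region (copy tag \code{I}), the
#' duplicated block tagged \code{1}, the second control region (\code{II}),
#' the block again tagged \code{2}, and a third control region (\code{III})
#' created at the distal end of the second copy. The original (label, copy)
#' identity of the duplicated block is kept so that a subsequent
#' \code{\link{randomLoss}} can restore surviving copies.
#'
#' @slot blockLabels,blockCopies original identity of the duplicated genes,
#'   in replication order.
#' @export
setClass("DuplicatedState",
  contains = "GeneOrder",
  representation(blockLabels = "character", blockCopies = "character")
)

setValidity("DuplicatedState", function(object) {
  el <- object@elements
  if (sum(el$class == "CR") != 3L) return("a DuplicatedState carries three CRs")
  k <- length(object@blockLabels)
  if (length(object@blockCopies) != k) return("blockLabels/blockCopies length mismatch")
  c1 <- el[el$class %in% GENE_CLASSES & endsWith(el$copy, "1"), , drop = FALSE]
  c2 <- el[el$class %in% GENE_CLASSES & endsWith(el$copy, "2"), , drop = FALSE]
  if (nrow(c1) != k || nrow(c2) != k) {
    return("every duplicated gene must appear exactly twice, tagged 1 and 2")
  }
  if (k && (!identical(c1$label, object@blockLabels) ||
            !identical(c2$label, object@blockLabels))) {
    return("both copies must keep the replication-order arrangement")
  }
  TRUE
})

#' One DRRL rearrangement event
#'
#' Full parameterization of a double-replication random-loss event: where the
#' translocated control region was inserted, which genes lay between the two
#' replication origins (the duplicated block), which copy of each duplicated
#' gene survived, and the fate of each of the three control regions.
#'
#' @slot insertionEdge ordered pair of element tokens flanking the inserted CR.
#' @slot block element tokens of the duplicated genes, in replication order.
#' @slot lossAssignment named character, \code{"copy1"} or \code{"copy2"} per
#'   block token.
#' @slot crFates named character over CRI/CRII/CRIII with values
#'   functional/remnant/lost; at least one must be functional.
#' @slot seed integer seed used for a random loss draw, or \code{NA}.
#' @export
setClass("DrrlEvent",
  representation(insertionEdge = "character", block = "character",
                 lossAssignment = "character", crFates = "character",
                 seed = "integer"),
  prototype(seed = NA_integer_)
)

setValidity("DrrlEvent", function(object) {
  msgs <- character(0)
  if (length(object@insertionEdge) != 2L) {
    msgs <- c(msgs, "insertionEdge must name the two flanking elements")
  }
  if (!setequal(names(object@lossAssignment), object@block)) {
    msgs <- c(msgs, "lossAssignment must cover exactly the duplicated block")
  }
  if (!all(object@lossAssignment %in% c("copy1", "copy2"))) {
    msgs <- c(msgs, "lossAssignment values must be copy1/copy2")
  }
  if (!setequal(names(object@crFates), c("CRI", "CRII", "CRIII")) ||
      !all(object@crFates %in% c("functional", "remnant", "lost"))) {
    msgs <- c(msgs, "crFates must map CRI/CRII/CRIII to functional/remnant/lost")
  } else if (!any(object@crFates == "functional")) {
    msgs <- c(msgs, "at least one CR must remain functional")
  }
  if (length(msgs)) msgs else TRUE
})

#' One TDRL rearrangement event
#'
#' Parameterization of a classic tandem-duplication random-loss event: the
#' tandemly duplicated contiguous block and the surviving copy of each gene.
#'
#' @slot block element tokens of the duplicated run, in order.
#' @slot lossAssignment named character, \code{"copy1"}/\code{"copy2"} per token.
#' @slot seed integer seed used for a random draw, or \code{NA}.
#' @export
setClass("TdrlEvent",
  representation(block = "character", lossAssignment = "character",
                 seed = "integer"),
  prototype(seed = NA_integer_)
)

#' An inferred explanation of an observed gene order
#'
#' One mechanism + parameter set that maps an ancestral order onto an observed
#' order. \code{splitPosition} is the size of the first increasing run (the
#' copy-1 survivor cluster) in the observed arrangement of the duplicated
#' block; \code{remnantSupport} records whether the positions at which the
#' event predicts degenerated CR remnants carry an observed remnant or
#' noncoding element.
#'
#' @slot mechanism \code{"DRRL"} or \code{"TDRL"}.
#' @slot event the generating \code{DrrlEvent} or \code{TdrlEvent}.
#' @slot splitPosition integer cluster boundary in the observed block.
#' @slot remnantSupport logical.
#' @slot copy1,copy2 element tokens of the two survivor clusters.
#' @export
setClass("Explanation",
  representation(mechanism = "character", event = "ANY",
                 splitPosition = "integer", remnantSupport = "logical",
                 copy1 = "character", copy2 = "character")
)

#' Genome-organization summary of an annotation table
#'
#' Summary statistics of a circular mitogenome annotation: genome length,
#' feature counts by class and strand, the intergenic spacer list (negative
#' lengths are overlaps), the number of strictly positive spacers, the number
#' of spacers above a threshold, the number of overlapping pairs, and the
#' noncoding regions longer than a threshold.
#'
#' @slot genomeLength integer, bp.
#' @slot classCounts,strandCounts,classStrandCounts feature tallies.
#' @slot spacers data.frame upstream/downstream/length.
#' @slot nPositiveSpacers,nSpacersOver,nOverlaps integer counts.
#' @slot spacerThreshold,ncThreshold integer thresholds, bp.
#' @slot ncOver names of noncoding (CR/NC) features above ncThreshold.
#' @export
setClass("AnnotationSummary",
  representation(genomeLength = "integer", classCounts = "integer",
                 strandCounts = "integer", classStrandCounts = "table",
                 spacers = "data.frame", nPositiveSpacers = "integer",
                 nSpacersOver = "integer", nOverlaps = "integer",
                 spacerThreshold = "numeric", ncThreshold = "numeric",
                 ncOver = "character")
)

#' A synthetic ground-truth rearrangement case
#'
#' An (ancestral order, event, derived order, seed) quadruple generated by
#' \code{\link{randomDrrlCase}}. Replaying \code{event} on \code{ancestral}
#' reproduces \code{derived} exactly.
#'
#' @slot ancestral,derived \code{GeneOrder}s.
#' @slot event the generating \code{DrrlEvent}.
#' @slot seed the integer seed.
#' @export
setClass("SyntheticCase",
  representation(ancestral = "GeneOrder", event = "DrrlEvent",
                 derived = "GeneOrder", seed = "integer")
)
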