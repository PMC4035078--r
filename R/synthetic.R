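# Seeded generators of synthetic gene orders, DRRL cases with ground truth,
# and annotation tables. Every stochastic entry point takes an explicit
# seed and leaves the caller's RNG state untouched.

#' Random circular gene order
#'
#' A circular order of \code{nGenes} synthetic genes (labels g1..gn, in a
#' seed-determined arrangement) plus one control region. Pure function of
#' its seed.
#'
#' @param nGenes number of genes (>= 1).
#' @param seed integer seed.
#' @return a circular \code{GeneOrder} of \code{nGenes + 1} elements.
#' @export
randomGeneOrder <- function(nGenes, seed) {
  if (nGenes < 1L) stop("nGenes must be >= 1")
  perm <- withr::with_seed(seed, sample.int(nGenes))
  lab <- c(paste0("g", perm), "CR")
  .newGeneOrder(lab, "", "H", c(rep("CDS", nGenes), "CR"),
                c(rep(NA_integer_, nGenes), 38L), circular = TRUE)
}

#' Random DRRL case with ground truth
#'
#' Draws an ancestral order (\code{\link{randomGeneOrder}}), a uniformly
#' random insertion edge on its circle, an independent fair-coin loss
#' assignment, applies a full DRRL event with CR fates
#' \{functional, remnant, remnant\}, and packages ancestral order, event
#' and derived order. Replaying the event on the ancestral order
#' reproduces the derived order exactly.
#'
#' @param nGenes number of ancestral genes.
#' @param seed integer seed.
#' @return a \code{\link{SyntheticCase}}.
#' @export
randomDrrlCase <- function(nGenes, seed) {
  anc <- randomGeneOrder(nGenes, seed)
  n <- length(anc)
  tok <- orderTokens(anc)
  draws <- withr::with_seed(seed + 1L, list(
    edge = sample.int(n, 1L),
    coins = sample(c("copy1", "copy2"), nGenes, replace = TRUE)))
  e <- draws$edge
  edgeTok <- c(tok[e], tok[if (e < n) e + 1L else 1L])
  # the implied block runs from the insertion point forward to the CR
  eb <- .edgeBlocks(anc)[[e]]
  assign <- stats::setNames(draws$coins[seq_along(eb$block)], eb$block)
  res <- simulateDrrl(anc, edgeTok, lossAssignment = assign,
                      crFates = c(CRI = "functional", CRII = "remnant",
                                  CRIII = "remnant"))
  res$event@seed <- as.integer(seed)
  new("SyntheticCase", ancestral = anc, event = res$event,
      derived = res$order, seed = as.integer(seed))
}

.defaultLengthModel <- list(tRNA = c(66L, 75L), rRNA = c(950L, 1715L),
                            CDS = c(160L, 1840L), CR = c(850L, 900L),
                            remnant = c(300L, 400L))
.defaultSpacerModel <- list(pZero = 0.5, pOverlap = 0.15,
                            posRange = c(1L, 90L), negRange = c(1L, 10L))

#' Synthetic annotation table for a gene order
#'
#' Draws feature sizes per element class and intergenic spacers between
#' consecutive features (with a parameterized overlap probability), and lays
#' the features on a circular genome starting at position 1; the last
#' feature closes the circle flush with the genome end, so the wrap spacer
#' is zero. The result round-trips through \code{\link{computeSpacers}}:
#' the recomputed spacers equal the drawn ones.
#'
#' @param order a \code{GeneOrder}.
#' @param lengthModel named list of \code{c(min, max)} integer ranges per
#'   element class.
#' @param spacerModel either an integer vector of exact spacer lengths (one
#'   per adjacent feature pair, \code{length(order) - 1}) or a list with
#'   \code{pZero}, \code{pOverlap}, \code{posRange}, \code{negRange}.
#' @param seed integer seed.
#' @return data.frame of feature records as from
#'   \code{\link{readAnnotationTable}}.
#' @export
syntheticAnnotation <- function(order, lengthModel = .defaultLengthModel,
                                spacerModel = .defaultSpacerModel, seed = 1L) {
  el <- order@elements
  n <- nrow(el)
  lengths <- withr::with_seed(seed, {
    sizes <- vapply(el$class, function(cl) {
      r <- lengthModel[[cl]]
      if (is.null(r)) r <- c(100L, 1000L)
      as.integer(r[1L] + sample.int(r[2L] - r[1L] + 1L, 1L) - 1L)
    }, integer(1))
    if (is.numeric(spacerModel)) {
      if (length(spacerModel) != n - 1L) {
        stop("spacerModel vector needs one spacer per adjacent pair")
      }
      sp <- as.integer(spacerModel)
    } else {
      sp <- integer(n - 1L)
      for (i in seq_len(n - 1L)) {
        u <- stats::runif(1)
        rint <- function(r) as.integer(r[1L] + sample.int(r[2L] - r[1L] + 1L, 1L) - 1L)
        sp[i] <- if (u < spacerModel$pZero) 0L
        else if (u < spacerModel$pZero + spacerModel$pOverlap) {
          -rint(spacerModel$negRange)
        } else {
          rint(spacerModel$posRange)
        }
      }
    }
    list(sizes = sizes, sp = sp)
  })
  sizes <- lengths$sizes
  sp <- lengths$sp
  # keep overlaps shallow enough that starts stay sorted
  if (n > 1L) sp <- pmax(sp, -(pmin(sizes[-n], sizes[-1L]) - 1L))
  from <- integer(n)
  from[1L] <- 1L
  to <- integer(n)
  to[1L] <- sizes[1L]
  for (i in seq_len(n - 1L)) {
    from[i + 1L] <- to[i] + sp[i] + 1L
    to[i + 1L] <- from[i + 1L] + sizes[i + 1L] - 1L
  }
  data.frame(name = .formatToken(el$label, el$copy), from = from, to = to,
             size = sizes, strand = el$strand,
             class = ifelse(el$class == "remnant", "NC", el$class),
             anticodon = NA_character_, start_codon = NA_character_,
             stop_codon = NA_character_, stringsAsFactors = FALSE)
}
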