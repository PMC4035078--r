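#' Parse a gene order from a token string
#'
#' Tokens are whitespace- or comma-separated element names. A leading
#' \code{-} marks the light strand (otherwise the consensus strand of the
#' vocabulary is used), a trailing \code{'} marks a duplicate copy, and
#' control-region tokens may be numbered (\code{CR1}, \code{CRII}, ...).
#' Unknown labels are kept as elements of class \code{remnant} with a
#' warning. Text after \code{#} is ignored.
#'
#' @param text token string (a single order).
#' @param circular logical; default TRUE.
#' @return a \code{\link{GeneOrder}}.
#' @examples
#' parseGeneOrder("trnQ CR trnC trnY")
#' @export
parseGeneOrder <- function(text, circular = TRUE) {
  text <- sub("#.*$", "", text)
  toks <- strsplit(trimws(text), "[,[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty gene order")
  n <- length(toks)
  label <- copy <- strand <- class <- character(n)
  index <- integer(n)
  unknown <- character(0)
  for (i in seq_len(n)) {
    tok <- toks[i]
    forced <- NA_character_
    if (startsWith(tok, "-")) { forced <- "L"; tok <- substring(tok, 2) }
    else if (startsWith(tok, "+")) { forced <- "H"; tok <- substring(tok, 2) }
    r <- .resolveToken(tok)
    if (!r$known) unknown <- c(unknown, tok)
    label[i] <- r$label; copy[i] <- r$copy; class[i] <- r$class
    index[i] <- r$index
    strand[i] <- if (is.na(forced)) r$strand else forced
  }
  if (length(unknown)) {
    warning("unknown label(s) kept as remnant elements: ",
            paste(unique(unknown), collapse = ", "))
  }
  key <- paste(label, copy, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate element token: ", toks[which(duplicated(key))[1L]])
  }
  .newGeneOrder(label, copy, strand, class, index, circular = circular)
}

#' Format a gene order as a token string
#'
#' Inverse of \code{\link{parseGeneOrder}}: light-strand elements get a
#' \code{-} prefix, copies a \code{'} suffix, CR copies a numeric/roman
#' suffix.
#'
#' @param order a \code{GeneOrder}.
#' @return a single character string.
#' @export
formatGeneOrder <- function(order) {
  el <- order@elements
  tok <- .formatToken(el$label, el$copy)
  tok[el$strand == "L"] <- paste0("-", tok[el$strand == "L"])
  paste(tok, collapse = " ")
}

#' Read gene orders from a text file
#'
#' One order per line; \code{#} starts a comment; blank lines are skipped.
#'
#' @param file path.
#' @param circular logical applied to every order.
#' @return a list of \code{GeneOrder}s.
#' @export
readGeneOrders <- function(file, circular = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parseGeneOrder, circular = circular)
}

#' Write gene orders to a text file
#'
#' @param orders a \code{GeneOrder} or list of them.
#' @param file path.
#' @export
writeGeneOrders <- function(orders, file) {
  if (is(orders, "GeneOrder")) orders <- list(orders)
  writeLines(vapply(orders, formatGeneOrder, character(1)), file)
}

#' Canonical rotation of a circular gene order
#'
#' Rotates a circular order to start at \code{trnF} (untagged) when present,
#' otherwise at the element with the smallest (label, copy) pair. Linear
#' orders are returned unchanged. Two circular orders are equal iff their
#' canonical rotations are element-wise equal.
#'
#' @param order a \code{GeneOrder}.
#' @return the rotated \code{GeneOrder}.
#' @export
canonicalRotation <- function(order) {
  if (!order@circular || nrow(order@elements) <= 1L) return(order)
  el <- order@elements
  at <- which(el$label == "trnF" & el$copy == "")
  if (length(at) != 1L) {
    key <- paste(el$label, el$copy, sep = "\r")
    at <- which.min(rank(key, ties.method = "first"))
  }
  if (at != 1L) {
    el <- el[c(at:nrow(el), seq_len(at - 1L)), , drop = FALSE]
    rownames(el) <- NULL
    order@elements <- el
  }
  order
}

#' Test two gene orders for equality
#'
#' Circular orders are compared after canonical rotation; comparison covers
#' label, copy tag, strand and class.
#'
#' @param a,b \code{GeneOrder}s.
#' @param ignoreCopy drop copy tags before comparing.
#' @param genesOnly drop CR and remnant elements before comparing.
#' @return logical.
#' @export
orderIdentical <- function(a, b, ignoreCopy = FALSE, genesOnly = FALSE) {
  pick <- function(o) {
    el <- o@elements
    if (genesOnly) el <- el[el$class %in% GENE_CLASSES, , drop = FALSE]
    if (ignoreCopy) el$copy <- ""
    o@elements <- el
    rownames(o@elements) <- NULL
    el <- canonicalRotation(o)@elements
    el[, c("label", "copy", "strand", "class")]
  }
  ea <- pick(a); eb <- pick(b)
  if (a@circular != b@circular || nrow(ea) != nrow(eb)) return(FALSE)
  rownames(ea) <- rownames(eb) <- NULL
  isTRUE(all.equal(ea, eb, check.attributes = FALSE))
}

#' Count gene-gene adjacencies shared by two orders
#'
#' CR and remnant elements are ignored; an adjacency is an unordered pair of
#' gene elements that are consecutive on the (circular) order once non-gene
#' elements are removed. For identical circular orders over n genes the
#' count is n.
#'
#' @param a,b \code{GeneOrder}s over a shared label set.
#' @return non-negative integer; symmetric in its arguments.
#' @export
sharedAdjacencies <- function(a, b) {
  adj <- function(o) {
    el <- o@elements
    el <- el[el$class %in% GENE_CLASSES, , drop = FALSE]
    k <- .formatToken(el$label, el$copy)
    n <- length(k)
    if (n < 2L) return(character(0))
    j <- if (o@circular) c(2:n, 1L) else 2:n
    i <- seq_len(length(j))
    pairs <- cbind(k[i], k[j])
    unique(apply(pairs, 1L, function(p) paste(sort(p), collapse = "~")))
  }
  length(intersect(adj(a), adj(b)))
}

#' @describeIn GeneOrder number of elements.
#' @param x a \code{GeneOrder}.
#' @export
setMethod("length", "GeneOrder", function(x) nrow(x@elements))

#' Element table of a gene order
#'
#' @param order a \code{GeneOrder}.
#' @return data.frame with columns label, copy, strand, class, index.
#' @export
orderElements <- function(order) order@elements

#' Element tokens of a gene order
#'
#' @param order a \code{GeneOrder}.
#' @return character vector, e.g. \code{c("trnF", ..., "CR1", "trnC'")}.
#' @export
orderTokens <- function(order) .elementTokens(order)

#' Is the order circular?
#'
#' @param order a \code{GeneOrder}.
#' @export
isCircular <- function(order) order@circular

#' Gene elements (tRNA/rRNA/CDS) of an order
#'
#' @param order a \code{GeneOrder}.
#' @return a \code{GeneOrder} with CR and remnant elements removed.
#' @export
geneElements <- function(order) {
  order@elements <- order@elements[order@elements$class %in% GENE_CLASSES, ,
                                   drop = FALSE]
  rownames(order@elements) <- NULL
  order
}

setMethod("show", "GeneOrder", function(object) {
  el <- object@elements
  cat(sprintf("%s of %d elements (%s)\n", class(object), nrow(el),
              if (object@circular) "circular" else "linear"))
  cat(" ", formatGeneOrder(object), "\n")
  tab <- table(factor(el$class, levels = ELEMENT_CLASSES))
  cat(" ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
})

setMethod("show", "DrrlEvent", function(object) {
  cat("DrrlEvent\n")
  cat("  insertion edge:", paste(object@insertionEdge, collapse = " | "), "\n")
  cat(sprintf("  duplicated block: %d gene(s)%s\n", length(object@block),
              if (length(object@block))
                paste0(" [", paste(object@block, collapse = " "), "]") else ""))
  surv1 <- names(object@lossAssignment)[object@lossAssignment == "copy1"]
  cat(sprintf("  copy-1 survivors: %d, copy-2 survivors: %d\n",
              length(surv1), length(object@block) - length(surv1)))
  cat("  CR fates:", paste(sprintf("%s=%s", names(object@crFates),
                                   object@crFates), collapse = ", "), "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
})

setMethod("show", "TdrlEvent", function(object) {
  cat("TdrlEvent\n")
  cat(sprintf("  block: %d element(s) [%s]\n", length(object@block),
              paste(object@block, collapse = " ")))
  surv1 <- sum(object@lossAssignment == "copy1")
  cat(sprintf("  copy-1 survivors: %d, copy-2 survivors: %d\n",
              surv1, length(object@block) - surv1))
})

setMethod("show", "Explanation", function(object) {
  cat(sprintf("%s explanation (split %d, remnant support: %s)\n",
              object@mechanism, object@splitPosition,
              if (object@remnantSupport) "yes" else "no"))
  if (is(object@event, "DrrlEvent")) {
    cat("  insertion edge:",
        paste(object@event@insertionEdge, collapse = " | "), "\n")
  } else {
    cat("  block:", paste(object@event@block, collapse = " "), "\n")
  }
  cat(sprintf("  clusters: [%s] | [%s]\n",
              paste(object@copy1, collapse = " "),
              paste(object@copy2, collapse = " ")))
})

setMethod("show", "SyntheticCase", function(object) {
  cat("SyntheticCase (seed", object@seed, ")\n ancestral: ",
      formatGeneOrder(object@ancestral), "\n derived:   ",
      formatGeneOrder(object@derived), "\n")
})

#' Serialize a gene order to JSON
#'
#' @param order a \code{GeneOrder}.
#' @return a JSON string (elements array with label/copy/strand/class/index
#'   fields plus a circular flag).
#' @export
geneOrderToJson <- function(order) {
  el <- order@elements
  jsonlite::toJSON(list(circular = order@circular, elements = el),
                   dataframe = "rows", auto_unbox = TRUE, na = "null")
}

#' Deserialize a gene order from JSON
#'
#' @param json string produced by \code{\link{geneOrderToJson}}.
#' @return a \code{GeneOrder}.
#' @export
geneOrderFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  el <- x$elements
  .newGeneOrder(el$label, ifelse(is.na(el$copy), "", el$copy), el$strand,
                el$class, el$index, circular = isTRUE(x$circular))
}

#' Serialize a DRRL event to JSON
#'
#' @param event a \code{DrrlEvent}.
#' @return a JSON string with insertion_edge, block, loss_assignment,
#'   cr_fates and seed fields.
#' @export
drrlEventToJson <- function(event) {
  jsonlite::toJSON(list(
    insertion_edge = event@insertionEdge,
    block = event@block,
    loss_assignment = as.list(event@lossAssignment),
    cr_fates = as.list(event@crFates),
    seed = if (is.na(event@seed)) NULL else event@seed
  ), auto_unbox = TRUE, null = "null")
}

#' Deserialize a DRRL event from JSON
#'
#' @param json string produced by \code{\link{drrlEventToJson}}.
#' @return a \code{DrrlEvent}.
#' @export
drrlEventFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("DrrlEvent",
      insertionEdge = as.character(x$insertion_edge),
      block = as.character(x$block),
      lossAssignment = unlist(x$loss_assignment) %||% setNames(character(0), character(0)),
      crFates = unlist(x$cr_fates),
      seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
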