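# Controlled vocabulary for vertebrate mitochondrial gene orders. The table
# is the single source of truth linking compact labels, the one-letter names
# used in mitogenome figures, the canonical 1-38 position, the consensus
# strand and the element class. trnS1 = Ser(TGA), trnS2 = Ser(GCT),
# trnL1 = Leu(TAA), trnL2 = Leu(TAG).

.vocab <- data.frame(
  index = 1:38,
  label = c("trnF", "rrnS", "trnV", "rrnL", "trnL1", "ND1", "trnI", "trnQ",
            "trnM", "ND2", "trnW", "trnA", "trnN", "trnC", "trnY", "COI",
            "trnS1", "trnD", "COII", "trnK", "ATP8", "ATP6", "COIII", "trnG",
            "ND3", "trnR", "ND4L", "ND4", "trnH", "trnS2", "trnL2", "ND5",
            "ND6", "trnE", "CYTB", "trnT", "trnP", "CR"),
  letter = c("F", "12S", "V", "16S", "L1", "ND1", "I", "Q", "M", "ND2", "W",
             "A", "N", "C", "Y", "COI", "S1", "D", "COII", "K", "ATP8",
             "ATP6", "COIII", "G", "ND3", "R", "ND4L", "ND4", "H", "S2",
             "L2", "ND5", "ND6", "E", "CYTB", "T", "P", "CR"),
  strand = c("H", "H", "H", "H", "H", "H", "H", "L", "H", "H", "H", "L", "L",
             "L", "L", "H", "L", "H", "H", "H", "H", "H", "H", "H", "H", "H",
             "H", "H", "H", "H", "H", "H", "L", "L", "H", "H", "L", "H"),
  class = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA", "CDS", "tRNA", "tRNA",
            "tRNA", "CDS", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "CDS",
            "tRNA", "tRNA", "CDS", "tRNA", "CDS", "CDS", "CDS", "tRNA",
            "CDS", "tRNA", "CDS", "CDS", "tRNA", "tRNA", "tRNA", "CDS",
            "CDS", "tRNA", "CDS", "tRNA", "tRNA", "CR"),
  stringsAsFactors = FALSE
)

#' Gene-name vocabulary
#'
#' The lookup table mapping compact labels (\code{trnF}, \code{rrnS}, ...,
#' \code{CR}) to the one-letter names used in mitogenome diagrams, the
#' canonical vertebrate position 1--38, the consensus strand and the element
#' class.
#'
#' @return data.frame with columns index, label, letter, strand, class.
#' @export
geneVocabulary <- function() .vocab

.newGeneOrder <- function(label, copy, strand, class, index, circular = TRUE) {
  el <- data.frame(label = as.character(label), copy = as.character(copy),
                   strand = as.character(strand), class = as.character(class),
                   index = as.integer(index), stringsAsFactors = FALSE)
  rownames(el) <- NULL
  new("GeneOrder", elements = el, circular = circular)
}

# element token: label + copy tag, with CR copies rendered CR1/CRI/...
.formatToken <- function(label, copy) {
  as.character(ifelse(label == "CR", paste0("CR", copy), paste0(label, copy)))
}

.elementTokens <- function(order) {
  el <- order@elements
  .formatToken(el$label, el$copy)
}

.elementKeys <- function(el) paste(el$label, el$copy, sep = "\r")

#' The canonical vertebrate mitochondrial gene order
#'
#' The typical 37-gene + control-region vertebrate arrangement, numbered
#' consecutively from 1 (\code{trnF}) to 38 (\code{CR}), with the consensus
#' strands (ND6 and the tRNAs Q, A, N, C, Y, S1, E, P on the light strand).
#'
#' @return a circular \code{\link{GeneOrder}} of 38 elements.
#' @examples
#' ord <- canonicalVertebrateOrder()
#' length(ord)
#' @export
canonicalVertebrateOrder <- function() {
  v <- .vocab
  .newGeneOrder(v$label, "", v$strand, v$class, v$index, circular = TRUE)
}

#' The observed Samariscus latus gene order
#'
#' The rearranged mitochondrial gene order of the flatfish
#' \emph{Samariscus latus}: the first eight genes retain the canonical
#' arrangement, a translocated control region (CR1) follows, the genes that
#' lay between the two replication origins form two clusters that each keep
#' the canonical relative order, a second control region with copies of
#' trnC/trnY (CR2, trnC', trnY') sits between trnL2 and trnP, and a 376-bp
#' noncoding region (NC) occupies the typical CR position between trnP and
#' trnF.
#'
#' @return a circular \code{\link{GeneOrder}} of 42 elements.
#' @export
samariscusLatusOrder <- function() {
  tok <- c("trnF", "rrnS", "trnV", "rrnL", "trnL1", "ND1", "trnI", "trnQ",
           "CR1", "trnC", "trnY", "trnS1", "trnK", "trnR", "trnS2", "ND5",
           "ND6", "trnE", "CYTB", "trnT", "trnM", "ND2", "trnW", "trnA",
           "trnN", "COI", "trnD", "COII", "ATP8", "ATP6", "COIII", "trnG",
           "ND3", "ND4L", "ND4", "trnH", "trnL2", "CR2", "trnC'", "trnY'",
           "trnP", "NC")
  parseGeneOrder(paste(tok, collapse = " "))
}

# Resolve one bare token (no strand prefix) to label/copy/class/index.
# Unknown labels become class "remnant" (with a warning upstream).
.resolveToken <- function(tok) {
  copy <- ""
  if (grepl("^CR", tok)) {
    rest <- sub("^CR", "", tok)
    if (rest %in% c("", "1", "2", "3", "I", "II", "III", "'")) {
      return(list(label = "CR", copy = rest, strand = "H", class = "CR",
                  index = 38L, known = TRUE))
    }
  }
  base <- tok
  while (grepl("['′]$", base)) {
    base <- sub("['′]$", "", base)
    copy <- paste0(copy, "'")
  }
  if (base == "NC") {
    return(list(label = "NC", copy = copy, strand = "H", class = "remnant",
                index = NA_integer_, known = TRUE))
  }
  if (base %in% c("CRII-remnant", "CRIII-remnant")) {
    return(list(label = base, copy = copy, strand = "H", class = "remnant",
                index = NA_integer_, known = TRUE))
  }
  hit <- match(base, .vocab$label)
  if (is.na(hit)) hit <- match(base, .vocab$letter)
  if (!is.na(hit)) {
    v <- .vocab[hit, ]
    return(list(label = v$label, copy = copy, strand = v$strand,
                class = v$class, index = v$index, known = TRUE))
  }
  if (grepl("^g[0-9]+$", base)) {
    return(list(label = base, copy = copy, strand = "H", class = "CDS",
                index = NA_integer_, known = TRUE))
  }
  list(label = base, copy = copy, strand = "H", class = "remnant",
       index = NA_integer_, known = FALSE)
}
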