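# Annotation tables use 1-based inclusive coordinates; the intergenic spacer
# between consecutive features is next$from - prev$to - 1 (negative =
# overlap), computed circularly for the last -> first pair. This is the only
# convention that reproduces the printed intergenic column of a mitogenome
# organization table.

#' Read a mitogenome annotation table
#'
#' Reads a tab-separated annotation table with columns \code{name},
#' \code{from}, \code{to}, \code{strand} (H/L) and \code{class} (tRNA, rRNA,
#' CDS, CR, NC); optional columns \code{anticodon}, \code{start_codon},
#' \code{stop_codon} are passed through. If a printed \code{intergenic}
#' column is present it is cross-checked against the recomputed spacers and a
#' warning is raised on any mismatch (the recomputed value wins).
#'
#' Rows must be in coordinate order (features sorted by start), which is also
#' the element order used by \code{\link{orderFromAnnotation}}.
#'
#' @param file path to a TSV file.
#' @return data.frame of feature records, with a derived \code{size} column.
#' @export
readAnnotationTable <- function(file) {
  raw <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "from", "to", "strand", "class")
  if (!all(need %in% names(raw))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(raw)
  if (!n) stop("empty annotation table")
  from <- suppressWarnings(as.integer(raw$from))
  to <- suppressWarnings(as.integer(raw$to))
  for (i in seq_len(n)) {
    if (is.na(from[i]) || is.na(to[i])) {
      stop(sprintf("row %d (%s): non-numeric coordinates", i, raw$name[i]))
    }
    if (from[i] < 1L) stop(sprintf("row %d (%s): start must be >= 1", i, raw$name[i]))
    if (from[i] > to[i]) stop(sprintf("row %d (%s): start > end", i, raw$name[i]))
    if (!raw$strand[i] %in% c("H", "L")) {
      stop(sprintf("row %d (%s): unknown strand '%s'", i, raw$name[i], raw$strand[i]))
    }
    if (!raw$class[i] %in% ANNOTATION_CLASSES) {
      stop(sprintf("row %d (%s): unknown class '%s'", i, raw$name[i], raw$class[i]))
    }
  }
  feats <- data.frame(name = raw$name, from = from, to = to,
                      size = to - from + 1L, strand = raw$strand,
                      class = raw$class, stringsAsFactors = FALSE)
  for (opt in c("anticodon", "start_codon", "stop_codon")) {
    feats[[opt]] <- if (opt %in% names(raw)) raw[[opt]] else NA_character_
  }
  if ("intergenic" %in% names(raw)) {
    printed <- suppressWarnings(as.integer(raw$intergenic))
    sp <- computeSpacers(feats, genomeLength = max(feats$to))
    bad <- which(!is.na(printed) & printed != sp$length)
    if (length(bad)) {
      warning(sprintf(
        "printed intergenic value disagrees with recomputation at row(s) %s; using recomputed values",
        paste(bad, collapse = ", ")))
    }
    feats$intergenic_printed <- printed
  }
  feats
}

#' Intergenic spacers of a circular annotation
#'
#' One spacer per adjacent feature pair, \code{length = next start - previous
#' end - 1}; negative lengths denote overlaps. For a circular genome the
#' wrap-around pair (last feature back to the first) is included, using
#' \code{genomeLength}.
#'
#' @param features data.frame from \code{\link{readAnnotationTable}} (sorted
#'   by start; unsorted input is an error).
#' @param genomeLength genome size in bp; defaults to the last feature end.
#' @param circular include the wrap-around spacer (default TRUE).
#' @return data.frame with columns upstream, downstream, length.
#' @export
computeSpacers <- function(features, genomeLength = max(features$to),
                           circular = TRUE) {
  n <- nrow(features)
  if (is.unsorted(features$from)) {
    stop("features must be sorted by start coordinate")
  }
  if (n < 2L) {
    sp <- data.frame(upstream = character(0), downstream = character(0),
                     length = integer(0))
  } else {
    sp <- data.frame(upstream = features$name[-n],
                     downstream = features$name[-1L],
                     length = features$from[-1L] - features$to[-n] - 1L,
                     stringsAsFactors = FALSE)
  }
  if (circular && n >= 1L) {
    wrap <- data.frame(upstream = features$name[n],
                       downstream = features$name[1L],
                       length = features$from[1L] - features$to[n] - 1L +
                         as.integer(genomeLength),
                       stringsAsFactors = FALSE)
    sp <- rbind(sp, wrap)
  }
  rownames(sp) <- NULL
  sp
}

#' Summarize genome organization of an annotation table
#'
#' Computes genome length, feature counts by class and strand, the full
#' intergenic spacer list, the number of strictly positive spacers, the
#' number of spacers above \code{spacerThreshold}, the number of overlapping
#' pairs (negative spacers), and the noncoding features (CR/NC class) longer
#' than \code{ncThreshold}.
#'
#' @param features data.frame from \code{\link{readAnnotationTable}}.
#' @param genomeLength genome size in bp; defaults to the last feature end.
#' @param spacerThreshold bp threshold for "long" spacers (default 50).
#' @param ncThreshold bp threshold for "large" noncoding regions (default 300).
#' @param circular treat the genome as circular (default TRUE).
#' @return an \code{\link{AnnotationSummary}}.
#' @export
summarizeAnnotation <- function(features, genomeLength = max(features$to),
                                spacerThreshold = 50, ncThreshold = 300,
                                circular = TRUE) {
  sp <- computeSpacers(features, genomeLength = genomeLength,
                       circular = circular)
  cls <- factor(features$class, levels = ANNOTATION_CLASSES)
  strand <- factor(features$strand, levels = c("H", "L"))
  nc <- features$class %in% c("CR", "NC")
  new("AnnotationSummary",
      genomeLength = as.integer(genomeLength),
      classCounts = as.integer(table(cls)) |> stats::setNames(ANNOTATION_CLASSES),
      strandCounts = as.integer(table(strand)) |> stats::setNames(c("H", "L")),
      classStrandCounts = table(class = cls, strand = strand),
      spacers = sp,
      nPositiveSpacers = sum(sp$length > 0L),
      nSpacersOver = sum(sp$length > spacerThreshold),
      nOverlaps = sum(sp$length < 0L),
      spacerThreshold = spacerThreshold,
      ncThreshold = ncThreshold,
      ncOver = features$name[nc & features$size > ncThreshold])
}

setMethod("show", "AnnotationSummary", function(object) {
  cat("Mitogenome annotation summary\n")
  cat(sprintf("  genome length: %d bp\n", object@genomeLength))
  cc <- object@classCounts
  cat("  features:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "),
      sprintf("(H=%d, L=%d)\n", object@strandCounts["H"],
              object@strandCounts["L"]))
  cat(sprintf("  intergenic spacers: %d positive, %d over %g bp, %d overlaps\n",
              object@nPositiveSpacers, object@nSpacersOver,
              object@spacerThreshold, object@nOverlaps))
  cat(sprintf("  noncoding regions over %g bp: %s\n", object@ncThreshold,
              paste(object@ncOver, collapse = ", ")))
})

#' Gene order implied by an annotation table
#'
#' Maps feature names through the gene vocabulary and returns the circular
#' \code{\link{GeneOrder}} given by the file order of the features, with
#' strands taken from the table and canonical positions 1--38 attached where
#' the label matches.
#'
#' @param features data.frame from \code{\link{readAnnotationTable}}.
#' @return a \code{GeneOrder}.
#' @export
orderFromAnnotation <- function(features) {
  ord <- parseGeneOrder(paste(features$name, collapse = " "))
  ord@elements$strand <- features$strand
  validObject(ord)
  ord
}

#' Packaged Samariscus latus annotation
#'
#' The packaged transcription of the \emph{S. latus} mitogenome organization
#' table (42 features, 18,706 bp): coordinates, strands, classes, anticodons,
#' start/stop codons, and the printed intergenic column used for
#' cross-checking.
#'
#' @return \code{slatusAnnotationFile}: the path of the packaged TSV;
#'   \code{slatusAnnotation}: the parsed feature data.frame.
#' @export
slatusAnnotationFile <- function() {
  system.file("extdata", "slatus_mitogenome_annotation.tsv",
              package = "mitoDRRL", mustWork = TRUE)
}

#' @rdname slatusAnnotationFile
#' @export
slatusAnnotation <- function() readAnnotationTable(slatusAnnotationFile())
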