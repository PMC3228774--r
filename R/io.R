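#' Read a labeled peptide dataset from TSV or FASTA
#'
#' The TSV dialect has one record per line: column 1 the peptide sequence,
#' column 2 the label (\code{1/0}, \code{+1/-1} or
#' \code{immunogenic/non-immunogenic}); whitespace- or tab-separated, with
#' an optional header line. FASTA input is parsed with
#' \pkg{Biostrings}, the label taken from a \code{label=} key in the
#' description line. After parsing, sequences are uppercased and
#' normalized: exact duplicate records are collapsed, and sequences
#' annotated with both labels are resolved to immunogenic (+1); both
#' collapse counts are logged.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension and content), \code{"tsv"} or
#'   \code{"fasta"}.
#' @return A \code{\link{PeptideSet}}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("LLFGYPVYV\t1", "GILGFVFTL\t0"), tf)
#' readPeptideSet(tf)
#' @export
readPeptideSet <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa", "fna")) "fasta"
    else if (ext %in% c("tsv", "txt", "csv", "dat")) "tsv"
    else {
      first <- readLines(path, n = 1L)
      if (length(first) && startsWith(first, ">")) "fasta" else "tsv"
    }
  }
  if (format == "fasta") {
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0L) stop("empty FASTA file: ", path)
    lab <- regmatches(names(aas),
                      regexpr("label=[^ \t]+", names(aas)))
    if (length(lab) != length(aas))
      stop("every FASTA header must carry a label= key")
    seqs <- toupper(as.character(aas))
    labels <- normalizeLabels(sub("^label=", "", lab))
  } else {
    lines <- readLines(path)
    keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    if (length(keep) == 0L) stop("empty dataset file: ", path)
    fields <- strsplit(trimws(lines[keep]), "[\t,;[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 2L))
      stop("line ", keep[which(nf < 2L)[1L]],
           ": expected at least 2 columns (sequence, label)")
    seqs <- toupper(vapply(fields, `[[`, character(1L), 1L))
    labs <- vapply(fields, `[[`, character(1L), 2L)
    # optional header: first kept line whose sequence column is not a
    # valid peptide over the canonical alphabet
    isHeader <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs[1L])
    if (isHeader) {
      if (length(seqs) == 1L) stop("no data rows in ", path)
      seqs <- seqs[-1L]; labs <- labs[-1L]; keep <- keep[-1L]
    }
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
    if (any(bad))
      stop("line ", keep[which(bad)[1L]], ": invalid residue in sequence '",
           seqs[which(bad)[1L]], "'")
    labels <- tryCatch(normalizeLabels(labs), error = function(e) {
      i <- as.integer(sub(".*entry ([0-9]+).*", "\\1", conditionMessage(e)))
      stop("line ", keep[i], ": unmappable label '", labs[i], "'",
           call. = FALSE)
    })
    if (length(unique(nchar(seqs))) > 1L) {
      lens <- nchar(seqs)
      stop("line ", keep[which(lens != lens[1L])[1L]],
           ": ragged sequence lengths (", lens[1L], " vs ",
           lens[which(lens != lens[1L])[1L]], ")")
    }
  }
  # resolve contradictory annotations to immunogenic, then deduplicate
  contradictory <- intersect(seqs[labels == 1L], seqs[labels == -1L])
  if (length(contradictory) > 0L) {
    labels[seqs %in% contradictory] <- 1L
    logMsg("warn", length(contradictory),
           " sequence(s) with contradictory labels resolved to immunogenic")
  }
  dup <- duplicated(paste(seqs, labels))
  if (any(dup))
    logMsg("info", sum(dup), " exact duplicate record(s) collapsed")
  PeptideSet(seqs[!dup], labels[!dup])
}

#' Write a labeled peptide dataset
#'
#' TSV output is the package dialect (sequence, label as +1/-1); FASTA
#' output carries \code{label=} keys in the headers. If the dataset was
#' produced by \code{\link{generateDataset}}, its generating configuration
#' is written alongside as a JSON sidecar (\code{<path>.json}) for
#' provenance.
#'
#' @param data a \code{\link{PeptideSet}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @param sidecar write the JSON provenance sidecar when a generating
#'   config is attached (default TRUE).
#' @return The path, invisibly.
#' @export
writePeptideSet <- function(data, path, format = c("tsv", "fasta"),
                            sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(is(data, "PeptideSet"))
  seqs <- as.character(data)
  if (format == "tsv") {
    writeLines(paste(seqs, data@labels, sep = "\t"), path)
  } else {
    headers <- paste0(">pep", seq_along(seqs), " label=", data@labels)
    writeLines(as.vector(rbind(headers, seqs)), path)
  }
  cfg <- attr(data, "config")
  if (sidecar && !is.null(cfg)) {
    cfg$motif$background <- as.list(cfg$motif$background)
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(10),
                                na = "null", force = TRUE),
               paste0(path, ".json"))
  }
  invisible(path)
}
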