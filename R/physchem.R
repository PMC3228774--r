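#' Read an AAindex1 flat file
#'
#' Parses the AAindex1 dialect: records delimited by \code{//}, with an
#' \code{H} line (accession), \code{D} line (description) and an \code{I}
#' line followed by two rows of ten numeric values in the canonical
#' \code{A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V} column order. Values of
#' \code{NA} are allowed; records containing any are parsed but flagged
#' incomplete and excluded from encodings.
#'
#' @param path file path (or connection) to an AAindex1-format file.
#' @return data.frame with columns \code{accession}, \code{description},
#'   \code{complete}, and one numeric column per residue (A..Y, in
#'   alphabetical order).
#' @examples
#' tbl <- defaultPropertyTable()
#' tbl[, c("accession", "complete")]
#' @export
readAAindex <- function(path) {
  lines <- readLines(path)
  recEnds <- grep("^//", lines)
  if (length(recEnds) == 0L) stop("no AAindex records found in ", path)
  start <- 1L
  rows <- list()
  for (end in recEnds) {
    rec <- lines[start:(end - 1L)]
    start <- end + 1L
    rec <- rec[nzchar(trimws(rec))]
    if (length(rec) == 0L) next
    acc <- sub("^H\\s+", "", grep("^H\\s", rec, value = TRUE)[1L])
    if (is.na(acc) || !nzchar(acc))
      stop("malformed AAindex record (missing H line) before line ", end)
    dLines <- grep("^D\\s", rec, value = TRUE)
    desc <- if (length(dLines)) sub("^D\\s+", "", dLines[1L]) else ""
    iPos <- grep("^I\\s", rec)
    if (length(iPos) != 1L || iPos + 2L > length(rec))
      stop("malformed AAindex record '", acc, "': bad I block")
    toks <- unlist(strsplit(trimws(rec[c(iPos + 1L, iPos + 2L)]), "\\s+"))
    if (length(toks) != 20L)
      stop("malformed AAindex record '", acc, "': expected 20 values, got ",
           length(toks))
    vals <- suppressWarnings(as.numeric(toks))
    badTok <- toks != "NA" & is.na(vals)
    if (any(badTok))
      stop("malformed AAindex record '", acc, "': non-numeric value '",
           toks[which(badTok)[1L]], "'")
    names(vals) <- AAINDEX_ORDER
    row <- data.frame(accession = acc, description = desc,
                      complete = !anyNA(vals), stringsAsFactors = FALSE)
    for (aa in AA_ALPHABET20) row[[aa]] <- vals[[aa]]
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$accession))
    stop("duplicate accession(s): ",
         paste(unique(out$accession[duplicated(out$accession)]),
               collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Write a property table in AAindex1 format
#'
#' Inverse of \code{\link{readAAindex}}; a parse-write-parse round trip
#' reproduces all values.
#'
#' @param table a property table as returned by \code{\link{readAAindex}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAAindex <- function(table, path) {
  fmtv <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "g",
                                                     digits = 10))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(table))) {
    vals <- vapply(AAINDEX_ORDER, function(aa) table[[aa]][i], numeric(1L))
    writeLines(c(
      paste("H", table$accession[i]),
      paste("D", table$description[i]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(fmtv(vals[1:10]), collapse = "  ")),
      paste0("  ", paste(fmtv(vals[11:20]), collapse = "  ")),
      "//"), con)
  }
  invisible(path)
}

#' Bundled physicochemical property table
#'
#' A compact selection of classical amino-acid scales shipped with the
#' package in AAindex1 format: hydropathy, hydrophilicity, normalized van
#' der Waals volume, polarity, molecular weight, isoelectric point,
#' secondary-structure propensities, plus synthetic records (accessions
#' starting with X) including one with missing values to exercise
#' completeness handling. It stands in for the full AAindex database, which
#' can be supplied externally through \code{\link{readAAindex}}.
#'
#' @return A property table data.frame (see \code{\link{readAAindex}}).
#' @export
defaultPropertyTable <- function() {
  readAAindex(system.file("extdata", "aaindex_subset.txt",
                          package = "tcreact", mustWork = TRUE))
}

#' Mean physicochemical-property encoding
#'
#' Represents each peptide as the vector of per-property arithmetic means
#' over its residues: for a length-\eqn{L} peptide and each complete
#' property, the \eqn{L} per-residue values are averaged to one number.
#' This encoding is position-independent by construction.
#'
#' @param peptides a \code{\link{PeptideSet}}, character vector, or
#'   \link[Biostrings]{AAStringSet}.
#' @param table property table from \code{\link{readAAindex}}; incomplete
#'   records are excluded.
#' @param properties optional accession subset to encode with.
#' @return Numeric matrix, one row per peptide, one column per property
#'   (column names are accessions).
#' @examples
#' encodeMeanProperties("AAAAAAAAA", defaultPropertyTable())
#' @export
encodeMeanProperties <- function(peptides, table = defaultPropertyTable(),
                                 properties = NULL) {
  seqs <- if (is(peptides, "PeptideSet")) as.character(peptides)
          else toupper(as.character(peptides))
  if (!is.null(properties)) {
    missing <- setdiff(properties, table$accession)
    if (length(missing) > 0L)
      stop("accession(s) not in table: ", paste(missing, collapse = ", "))
    table <- table[table$accession %in% properties, , drop = FALSE]
  }
  table <- table[table$complete, , drop = FALSE]
  if (nrow(table) == 0L) stop("no complete properties available")
  chars <- strsplit(seqs, "", fixed = TRUE)
  used <- unique(unlist(chars))
  out <- matrix(NA_real_, nrow = length(seqs), ncol = nrow(table),
                dimnames = list(NULL, table$accession))
  for (j in seq_len(nrow(table))) {
    vals <- vapply(AA_ALPHABET20, function(aa) table[[aa]][j], numeric(1L))
    if (anyNA(vals[used]))
      stop("property ", table$accession[j],
           " lacks values for residues in the data")
    out[, j] <- vapply(chars, function(cs) mean(vals[cs]), numeric(1L))
  }
  out
}
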