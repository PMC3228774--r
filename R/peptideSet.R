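#' Construct a labeled peptide set
#'
#' @param sequences character vector of equal-length peptide sequences over
#'   the 20 canonical amino acids (uppercased on input), or an
#'   \link[Biostrings]{AAStringSet}.
#' @param labels vector of class labels; accepted encodings are
#'   \code{+1/-1}, \code{1/0}, or \code{"immunogenic"/"non-immunogenic"}.
#' @return A \code{\link{PeptideSet}}.
#' @examples
#' ps <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
#' ps
#' @export
PeptideSet <- function(sequences, labels) {
  if (is(sequences, "AAStringSet")) {
    aas <- sequences
  } else {
    aas <- Biostrings::AAStringSet(toupper(as.character(sequences)))
  }
  new("PeptideSet", peptides = aas, labels = normalizeLabels(labels))
}

# map the accepted label encodings onto integer +1/-1
normalizeLabels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- tolower(trimws(labels))
    out <- rep(NA_integer_, length(lab))
    out[lab %in% c("1", "+1", "immunogenic", "pos", "positive")] <- 1L
    out[lab %in% c("0", "-1", "non-immunogenic", "nonimmunogenic",
                   "neg", "negative")] <- -1L
  } else {
    num <- as.numeric(labels)
    out <- rep(NA_integer_, length(num))
    out[num == 1] <- 1L
    out[num %in% c(0, -1)] <- -1L
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("unmappable label at entry ", bad, ": '", labels[bad], "'")
  }
  out
}

#' @describeIn PeptideSet number of peptides.
#' @param x,object a \code{PeptideSet}.
#' @export
setMethod("length", "PeptideSet", function(x) length(x@peptides))

#' Accessors for PeptideSet
#'
#' \code{peptides} returns the sequences as an
#' \link[Biostrings]{AAStringSet}; \code{labels} the \code{+1/-1} label
#' vector; \code{peptideLength} the common sequence length L.
#'
#' @param x,object a \code{\link{PeptideSet}}.
#' @param ... unused.
#' @return See individual descriptions.
#' @examples
#' ps <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
#' peptides(ps)
#' labels(ps)
#' peptideLength(ps)
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname peptides
#' @export
setMethod("peptides", "PeptideSet", function(x) x@peptides)

#' @rdname peptides
#' @export
setMethod("labels", "PeptideSet", function(object, ...) object@labels)

#' @rdname peptides
#' @export
setGeneric("peptideLength", function(x) standardGeneric("peptideLength"))

#' @rdname peptides
#' @export
setMethod("peptideLength", "PeptideSet", function(x) {
  if (length(x) == 0L) return(NA_integer_)
  Biostrings::width(x@peptides)[1L]
})

#' @describeIn PeptideSet subset peptides and labels together.
#' @param i index vector.
#' @param j,drop ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  new("PeptideSet", peptides = x@peptides[i], labels = x@labels[i])
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  cat("PeptideSet with", n, "peptides of length",
      peptideLength(object), "\n")
  cat("  +1 (immunogenic):    ", sum(object@labels == 1L), "\n")
  cat("  -1 (non-immunogenic):", sum(object@labels == -1L), "\n")
  if (n > 0) {
    k <- min(n, 3L)
    cat("  head:", paste(as.character(object@peptides[seq_len(k)]),
                         collapse = " "),
        if (n > k) "..." else "", "\n")
  }
  invisible(NULL)
})

#' @describeIn PeptideSet sequences as a plain character vector.
#' @export
setMethod("as.character", "PeptideSet",
          function(x) as.character(x@peptides))

# integer residue-code matrix (n x L) used by the compiled kernel routines
peptideCodes <- function(x) {
  seqs <- if (is(x, "PeptideSet")) as.character(x@peptides)
          else toupper(as.character(x))
  if (length(seqs) == 0L) stop("empty peptide set")
  chars <- strsplit(seqs, "", fixed = TRUE)
  L <- unique(lengths(chars))
  if (length(L) != 1L) stop("peptides have unequal lengths")
  m <- matrix(match(unlist(chars), AA_ALPHABET20), ncol = L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("non-canonical residue in peptide ", bad, ": '", seqs[bad], "'")
  }
  m
}

validatePeptides <- function(x) {
  invisible(peptideCodes(x))
}
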