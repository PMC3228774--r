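#' Excise one position from every peptide
#'
#' Shortens every peptide from length \eqn{L} to \eqn{L - 1} by removing the
#' residue at \code{pos} (1-based, as in all reports of this package);
#' labels are unchanged.
#'
#' @param data a \code{\link{PeptideSet}}.
#' @param pos position to remove, \eqn{1 \le pos \le L}.
#' @return A \code{\link{PeptideSet}} of length-\eqn{(L-1)} peptides.
#' @examples
#' ps <- PeptideSet("LLFGYPVYV", 1)
#' as.character(deletePosition(ps, 6))  # "LLFGYVYV"
#' @export
deletePosition <- function(data, pos) {
  stopifnot(is(data, "PeptideSet"))
  L <- peptideLength(data)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > L ||
      pos != round(pos))
    stop("pos must be a single position in 1..", L)
  seqs <- as.character(data)
  left <- if (pos > 1L) substr(seqs, 1L, pos - 1L) else ""
  right <- if (pos < L) substr(seqs, pos + 1L, L) else ""
  PeptideSet(paste0(left, right), data@labels)
}

#' Position importance by deletion (delta-MCC)
#'
#' Estimates how much each peptide position contributes to predictability of
#' T-cell reactivity: the baseline is a nested CV on the full-length data;
#' then, for each position, the same protocol is run on the dataset with
#' that position excised (the degree grid capped at the remaining length
#' \eqn{L - 1}). The importance of a position is the drop in mean MCC,
#' \eqn{\Delta MCC = MCC_{baseline} - MCC_{deleted}}; larger drops mean more
#' important positions. Baseline and deleted runs are seed-matched. A
#' position is flagged \code{important} when its \eqn{\Delta MCC} exceeds
#' twice the across-run sd of the deleted-position MCC (requires
#' \code{nRuns >= 2} for a nonzero sd).
#'
#' @param data a \code{\link{PeptideSet}} with \eqn{L \ge 2}.
#' @param nRuns nested-CV repetitions per dataset (reference protocol: 20).
#' @param seed integer seed, reused for baseline and every deleted run.
#' @param grid \code{\link{gridSpec}}; degrees above \eqn{L} (baseline) or
#'   \eqn{L - 1} (deleted) are dropped automatically.
#' @param ... further arguments passed to \code{\link{nestedCV}}.
#' @return data.frame with one row per position: \code{position},
#'   \code{baselineMCC}, \code{deletedMCC}, \code{deletedSD},
#'   \code{deltaMCC}, \code{important}, \code{nRuns}.
#' @export
positionImportance <- function(data, nRuns = 20, seed = NULL,
                               grid = gridSpec(), ...) {
  stopifnot(is(data, "PeptideSet"))
  L <- peptideLength(data)
  if (is.na(L) || L < 2L) stop("peptide length must be at least 2")
  capGrid <- function(g, maxd) {
    d <- g$d[g$d <= maxd]
    if (length(d) == 0L) d <- maxd
    gridSpec(g$C, d)
  }
  base <- nestedCV(data, capGrid(grid, L), nRuns = nRuns, seed = seed, ...)
  baseMCC <- mean(cvRuns(base)$MCC)
  rows <- lapply(seq_len(L), function(pos) {
    del <- deletePosition(data, pos)
    rep <- nestedCV(del, capGrid(grid, L - 1L), nRuns = nRuns, seed = seed,
                    ...)
    mccs <- cvRuns(rep)$MCC
    data.frame(position = pos, baselineMCC = baseMCC,
               deletedMCC = mean(mccs),
               deletedSD = if (length(mccs) > 1L) sd(mccs) else NA_real_,
               deltaMCC = baseMCC - mean(mccs), nRuns = nRuns)
  })
  out <- do.call(rbind, rows)
  out$important <- !is.na(out$deletedSD) &
    out$deltaMCC > 2 * out$deletedSD
  out[, c("position", "baselineMCC", "deletedMCC", "deletedSD",
          "deltaMCC", "important", "nRuns")]
}

# Welch (or pooled) two-sample t on binary occurrence indicators, computed
# from summary statistics; handles the degenerate zero-variance cases the
# indicators produce (constant and equal -> t = 0, p = 1; constant and
# different -> p = 0).
indicatorTTest <- function(x1, x2, var.equal = FALSE) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (var.equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0)
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    else NA_real_
  }
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sample logo statistics
#'
#' For each position and alphabet symbol, a two-sample t-test compares the
#' per-peptide occurrence indicator (1 if the symbol occupies the position,
#' else 0) between the positive and negative sets. The direction is the
#' sign of the frequency difference (over-/under-represented in positives).
#' Under Bonferroni correction a symbol is flagged significant when its raw
#' p-value falls below \eqn{\alpha / m} with \eqn{m = L \times} alphabet
#' size (all position-symbol tests form one family; \eqn{m} is recorded in
#' the report).
#'
#' @param posSet,negSet \code{\link{PeptideSet}}s or character vectors of
#'   equal-length peptides (labels, if any, are ignored; the two arguments
#'   define the two samples).
#' @param alpha family-wise significance level (default 0.05).
#' @param correction \code{"bonferroni"} (default) or \code{"none"}.
#' @param alphabet symbols to test; defaults to the 20 canonical amino
#'   acids. Pass \code{c("S","M","L")} for property-recoded sequences.
#' @param var.equal use the pooled-variance t-test instead of Welch's
#'   (default FALSE: Welch).
#' @return data.frame of class \code{LogoReport}, one row per
#'   (position, symbol): \code{position}, \code{symbol}, \code{freqPos},
#'   \code{freqNeg}, \code{t}, \code{df}, \code{p}, \code{significant},
#'   \code{direction} ("over"/"under"/"none"). Attributes \code{alpha},
#'   \code{m}, \code{correction}, \code{nPos}, \code{nNeg} record the
#'   testing family.
#' @examples
#' pos <- c("AAAGAAAAA", "CCCGCCCCC", "DDDGDDDDD")
#' neg <- c("AAATAAAAA", "CCCTCCCCC", "DDDTDDDDD")
#' head(twoSampleLogo(pos, neg))
#' @export
twoSampleLogo <- function(posSet, negSet, alpha = 0.05,
                          correction = c("bonferroni", "none"),
                          alphabet = aminoAcids(), var.equal = FALSE) {
  correction <- match.arg(correction)
  seqP <- if (is(posSet, "PeptideSet")) as.character(posSet)
          else toupper(as.character(posSet))
  seqN <- if (is(negSet, "PeptideSet")) as.character(negSet)
          else toupper(as.character(negSet))
  if (length(seqP) == 0L || length(seqN) == 0L)
    stop("both peptide sets must be non-empty")
  L <- unique(nchar(c(seqP, seqN)))
  if (length(L) != 1L)
    stop("all peptides in both sets must share one length")
  mP <- do.call(rbind, strsplit(seqP, "", fixed = TRUE))
  mN <- do.call(rbind, strsplit(seqN, "", fixed = TRUE))
  m <- L * length(alphabet)
  thr <- if (correction == "bonferroni") alpha / m else alpha
  rows <- vector("list", m)
  k <- 0L
  for (pos in seq_len(L)) {
    for (sym in alphabet) {
      iP <- as.numeric(mP[, pos] == sym)
      iN <- as.numeric(mN[, pos] == sym)
      tt <- indicatorTTest(iP, iN, var.equal = var.equal)
      fP <- mean(iP); fN <- mean(iN)
      sig <- tt$p < thr
      k <- k + 1L
      rows[[k]] <- data.frame(
        position = pos, symbol = sym, freqPos = fP, freqNeg = fN,
        t = tt$t, df = tt$df, p = tt$p, significant = sig,
        direction = if (!sig || fP == fN) "none"
                    else if (fP > fN) "over" else "under",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "correction") <- correction
  attr(out, "nPos") <- length(seqP)
  attr(out, "nNeg") <- length(seqN)
  class(out) <- c("LogoReport", "data.frame")
  out
}

#' @describeIn twoSampleLogo split a labeled \code{\link{PeptideSet}} by its
#'   labels and run \code{twoSampleLogo} (+1 peptides vs -1 peptides).
#' @param data a labeled \code{\link{PeptideSet}}.
#' @param ... passed on to \code{twoSampleLogo}.
#' @export
datasetLogo <- function(data, ...) {
  stopifnot(is(data, "PeptideSet"))
  twoSampleLogo(data[data@labels == 1L], data[data@labels == -1L], ...)
}

#' Write a logo report as TSV
#'
#' @param report a \code{LogoReport} from \code{\link{twoSampleLogo}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLogoReport <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot a two-sample logo
#'
#' Residue letters of significantly over-represented symbols are drawn
#' above the axis and under-represented ones below, with heights
#' proportional to the frequency difference between the two sets.
#'
#' @param report a \code{LogoReport} from \code{\link{twoSampleLogo}}.
#' @return A \code{ggplot} object.
#' @export
plotTwoSampleLogo <- function(report) {
  sig <- report[report$significant & report$direction != "none", ,
                drop = FALSE]
  L <- max(report$position)
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = seq_len(L),
                                limits = c(0.5, L + 0.5)) +
    ggplot2::labs(x = "position", y = "frequency difference (pos - neg)",
                  title = "Two-sample logo") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    sig$diff <- sig$freqPos - sig$freqNeg
    # stack letters outward from the axis within each position and side
    sig <- sig[order(sig$position, -abs(sig$diff)), ]
    sig$ymin <- NA_real_
    for (posi in unique(sig$position)) {
      for (side in c(1, -1)) {
        idx <- which(sig$position == posi & sign(sig$diff) == side)
        base <- 0
        for (i in idx) {
          sig$ymin[i] <- base
          base <- base + sig$diff[i]
        }
      }
    }
    sig$y <- sig$ymin + sig$diff / 2
    p <- p + ggplot2::geom_text(
      data = sig,
      ggplot2::aes(x = position, y = y, label = symbol,
                   size = abs(diff), colour = direction)) +
      ggplot2::scale_size_continuous(range = c(3, 8), guide = "none") +
      ggplot2::scale_colour_manual(
        values = c(over = "#1b7837", under = "#762a83"))
  }
  p
}

# per-residue scalar scales used for the coarse S/M/L recoding
RECODING_SCALES <- list(
  hydrophobicity = list(
    # Kyte-Doolittle hydropathy; thresholds 0.5 / 2.5
    values = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2),
    thresholds = c(0.5, 2.5)),
  vdw_volume = list(
    # normalized van der Waals volume; thresholds 2.0 / 6.0
    values = c(A = 1.00, R = 6.13, N = 2.95, D = 2.78, C = 2.43, Q = 3.95,
               E = 3.78, G = 0.00, H = 4.66, I = 4.00, L = 4.00, K = 4.77,
               M = 4.43, F = 5.89, P = 2.72, S = 1.60, T = 2.60, W = 8.08,
               Y = 6.47, V = 3.00),
    thresholds = c(2.0, 6.0)))

#' Recode peptides to the coarse S/M/L property alphabet
#'
#' Each residue is replaced by \code{'S'} (small), \code{'M'} (medium) or
#' \code{'L'} (large) according to a per-residue scalar property: \code{'S'}
#' if the value is below the low threshold, \code{'M'} in [low, high),
#' \code{'L'} at or above the high threshold. Built-in scales:
#' \code{"hydrophobicity"} (Kyte-Doolittle hydropathy, thresholds 0.5 and
#' 2.5) and \code{"vdw_volume"} (normalized van der Waals volume,
#' thresholds 2.0 and 6.0). Length, labels and set size are preserved.
#'
#' @param data a \code{\link{PeptideSet}}.
#' @param property \code{"hydrophobicity"} or \code{"vdw_volume"}, or any
#'   name if \code{values} is supplied.
#' @param values optional named per-residue scalar vector overriding the
#'   built-in scale.
#' @param thresholds optional numeric \code{c(low, high)} overriding the
#'   built-in thresholds.
#' @return A \code{\link{PeptideSet}} over the \{S, M, L\} alphabet, with
#'   attributes \code{property} and \code{thresholds}.
#' @examples
#' ps <- PeptideSet("GILGFVFTL", 1)
#' as.character(recodeAlphabet(ps, "vdw_volume"))
#' @export
recodeAlphabet <- function(data, property = c("hydrophobicity",
                                              "vdw_volume"),
                           values = NULL, thresholds = NULL) {
  stopifnot(is(data, "PeptideSet"))
  if (is.null(values)) {
    property <- match.arg(property)
    scale <- RECODING_SCALES[[property]]
    values <- scale$values
    if (is.null(thresholds)) thresholds <- scale$thresholds
  } else {
    property <- property[1L]
    if (is.null(thresholds))
      stop("thresholds must be supplied with custom values")
  }
  seqs <- as.character(data)
  chars <- strsplit(seqs, "", fixed = TRUE)
  missing <- setdiff(unique(unlist(chars)), names(values))
  if (length(missing) > 0L)
    stop("residue(s) missing from the property table: ",
         paste(missing, collapse = ", "))
  recoded <- vapply(chars, function(cs) {
    v <- values[cs]
    paste(ifelse(v < thresholds[1L], "S",
                 ifelse(v < thresholds[2L], "M", "L")), collapse = "")
  }, character(1L))
  out <- PeptideSet(recoded, data@labels)
  attr(out, "property") <- property
  attr(out, "thresholds") <- thresholds
  out
}

#' Property-recoded two-sample logo
#'
#' Recodes the dataset to the S/M/L alphabet of the chosen property
#' (\code{\link{recodeAlphabet}}) and computes the two-sample logo between
#' immunogenic and non-immunogenic peptides over that 3-letter alphabet
#' (Bonferroni family \eqn{m = L \times 3}).
#'
#' @param data a labeled \code{\link{PeptideSet}}.
#' @param property as in \code{\link{recodeAlphabet}}.
#' @param ... passed to \code{\link{twoSampleLogo}} (e.g. \code{alpha}).
#' @return A \code{LogoReport} over symbols \{S, M, L\}.
#' @export
propertyLogo <- function(data, property = c("hydrophobicity",
                                            "vdw_volume"), ...) {
  recoded <- recodeAlphabet(data, property)
  datasetLogo(recoded, alphabet = c("S", "M", "L"), ...)
}
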