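#' Hyperparameter grid for nested cross-validation
#'
#' Defaults follow the published protocol: cost
#' \eqn{C \in \{2^{-4}, ..., 2^4\}} and kernel degree \eqn{d \in \{1..9\}}.
#'
#' @param C numeric vector of cost values.
#' @param d integer vector of kernel degrees.
#' @return A list with elements \code{C} and \code{d}.
#' @export
gridSpec <- function(C = 2^(-4:4), d = 1:9) {
  if (length(C) == 0L || length(d) == 0L) stop("grid is empty")
  if (any(C <= 0)) stop("all C values must be > 0")
  if (any(d < 1 | d != round(d))) stop("all d values must be integers >= 1")
  list(C = as.numeric(C), d = as.integer(d))
}

# stratified k-fold assignment: indices are shuffled within class and fold
# ids handed out by one rotating counter across classes, so global fold
# sizes differ by at most 1 and class proportions are preserved per fold.
stratifiedFolds <- function(y, k) {
  n <- length(y)
  if (k < 2L || k > n) stop("degenerate folds: k = ", k, ", n = ", n)
  fold <- integer(n)
  counter <- sample.int(k, 1L) - 1L
  for (cls in sort(unique(y), decreasing = TRUE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
    counter <- counter + length(idx)
  }
  fold
}

# fit on K[tr, tr] and return decision scores for rows `te`
.fitScore <- function(K, y, tr, te, C, tol) {
  fit <- cpp_smo(K[tr, tr, drop = FALSE], y[tr], C, tol, 2000000L)
  ay <- fit$alpha * y[tr]
  as.vector(K[te, tr, drop = FALSE] %*% ay) + fit$bias
}

# Generic nested-CV engine over precomputed kernel matrices.
#   Klist  : list of full n x n kernel matrices
#   combos : data.frame of hyperparameter combinations, pre-sorted in
#            tie-break order, with a .kernel column indexing Klist and a
#            C column; remaining columns are reported as selected params
.nestedCVEngine <- function(Klist, combos, y, nRuns, outerFolds, innerFolds,
                            seed, tol) {
  n <- length(y)
  if (n < 2L * outerFolds)
    stop("dataset too small for ", outerFolds, "-fold outer CV")
  if (min(table(y)) < outerFolds)
    stop("each class needs at least ", outerFolds,
         " members for stratified folds")
  paramCols <- setdiff(names(combos), ".kernel")
  rows <- list()
  withSeed(seed, {
    for (run in seq_len(nRuns)) {
      fold <- stratifiedFolds(y, outerFolds)
      for (f in seq_len(outerFolds)) {
        tr <- which(fold != f)
        te <- which(fold == f)
        if (length(unique(y[tr])) < 2L || length(te) == 0L)
          stop("degenerate fold encountered")
        sel <- 1L
        if (nrow(combos) > 1L) {
          inner <- stratifiedFolds(y[tr], innerFolds)
          aucMean <- numeric(nrow(combos))
          for (ci in seq_len(nrow(combos))) {
            K <- Klist[[combos$.kernel[ci]]]
            aucs <- numeric(innerFolds)
            for (g in seq_len(innerFolds)) {
              itr <- tr[inner != g]
              ite <- tr[inner == g]
              s <- .fitScore(K, y, itr, ite, combos$C[ci], tol)
              aucs[g] <- aucScore(s, y[ite])
            }
            aucMean[ci] <- mean(aucs, na.rm = TRUE)
          }
          sel <- which.max(aucMean)  # combos pre-sorted in tie-break order
        }
        K <- Klist[[combos$.kernel[sel]]]
        s <- .fitScore(K, y, tr, te, combos$C[sel], tol)
        met <- computeMetrics(s, y[te])
        row <- data.frame(run = run, fold = f)
        for (pc in paramCols) row[[pc]] <- combos[[pc]][sel]
        row$ACC <- met[["ACC"]]; row$MCC <- met[["MCC"]]
        row$AUC <- met[["AUC"]]
        rows[[length(rows) + 1L]] <- row
      }
    }
  })
  folds <- do.call(rbind, rows)
  runs <- do.call(rbind, lapply(split(folds, folds$run), function(d) {
    data.frame(run = d$run[1L], ACC = mean(d$ACC), MCC = mean(d$MCC),
               AUC = mean(d$AUC))
  }))
  rownames(runs) <- NULL
  summ <- data.frame(
    metric = c("ACC", "MCC", "AUC"),
    mean = c(mean(runs$ACC), mean(runs$MCC), mean(runs$AUC)),
    sd = c(sd(runs$ACC), sd(runs$MCC), sd(runs$AUC)))
  new("CVReport", folds = folds, runs = runs, summary = summ,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      grid = as.list(combos[paramCols]))
}

#' Nested 10-fold cross-validation with grid search
#'
#' The dataset is randomly partitioned into \code{outerFolds} stratified
#' folds. For each outer fold, an inner \code{innerFolds}-fold CV on the
#' remaining data selects the \code{(C, d)} pair maximizing mean inner AUC
#' (ties broken towards smallest \code{d}, then smallest \code{C}); a model
#' trained with the selected pair on the full outer-training portion is then
#' scored on the held-out fold. The whole procedure is repeated
#' \code{nRuns} times with fresh random partitions and summarized as
#' across-run means and standard deviations of ACC, MCC and AUC.
#'
#' @param data a \code{\link{PeptideSet}}, at least 20 peptides with both
#'   classes represented.
#' @param grid hyperparameter grid from \code{\link{gridSpec}}.
#' @param nRuns number of independent repetitions (reference protocol: 20).
#' @param seed integer seed driving all fold randomness; the caller's RNG
#'   state is preserved.
#' @param outerFolds,innerFolds fold counts (default 10/10).
#' @param tol SVM solver tolerance.
#' @return A \code{\link{CVReport}}.
#' @examples
#' \donttest{
#' ds <- generateDataset(nPos = 30, nNeg = 30, mode = "deterministic",
#'                       rule = c(position = 4, residue = "G"), seed = 1)
#' rep <- nestedCV(ds, gridSpec(C = 1, d = 9), nRuns = 1, seed = 1)
#' cvSummary(rep)
#' }
#' @export
nestedCV <- function(data, grid = gridSpec(), nRuns = 20, seed = NULL,
                     outerFolds = 10L, innerFolds = 10L, tol = 1e-3) {
  stopifnot(is(data, "PeptideSet"))
  grid <- gridSpec(grid$C, grid$d)
  L <- peptideLength(data)
  if (any(grid$d > L))
    stop("grid degree(s) exceed peptide length L = ", L)
  counts <- matchCountArray(data)
  ud <- sort(unique(grid$d))
  Klist <- lapply(ud, function(d) gramFromCounts(counts, kernelSpec(d)))
  combos <- expand.grid(C = sort(grid$C), d = ud,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$d, combos$C), , drop = FALSE]
  combos$.kernel <- match(combos$d, ud)
  .nestedCVEngine(Klist, combos, as.numeric(data@labels), nRuns,
                  outerFolds, innerFolds, seed, tol)
}

#' Learning curve under a fixed 50/25/25 split
#'
#' One random stratified split into 50\% training pool, 25\% validation and
#' 25\% test. For each requested size \eqn{s}, a model is trained on
#' \eqn{s} randomly chosen pool samples (with \code{C = 1}, \code{d = 9}
#' unless \code{grid} is supplied, in which case \code{(C, d)} is re-tuned
#' by 10-fold CV on the sampled training set) and evaluated on the
#' validation and test sets.
#'
#' @param data a \code{\link{PeptideSet}}.
#' @param sizes increasing training sizes; default: multiples of 50 up to
#'   the pool size, plus the full pool.
#' @param seed integer seed for the split and sampling.
#' @param C,d parameters used when no grid is supplied.
#' @param grid optional \code{\link{gridSpec}} enabling re-tuning at every
#'   size.
#' @param tol SVM solver tolerance.
#' @return data.frame with one row per size: \code{size}, selected
#'   \code{C}/\code{d}, and \code{ACC}/\code{MCC}/\code{AUC} for the
#'   validation and test sets.
#' @export
learningCurve <- function(data, sizes = NULL, seed = NULL, C = 1, d = 9,
                          grid = NULL, tol = 1e-8) {
  stopifnot(is(data, "PeptideSet"))
  y <- as.numeric(data@labels)
  n <- length(y)
  L <- peptideLength(data)
  d <- min(d, L)
  counts <- matchCountArray(data)
  withSeed(seed, {
    quarter <- stratifiedFolds(y, 4L)
    pool <- which(quarter <= 2L)
    val <- which(quarter == 3L)
    test <- which(quarter == 4L)
    if (is.null(sizes)) {
      sizes <- seq(50L, length.out = max(0L, length(pool) %/% 50L), by = 50L)
      sizes <- unique(c(sizes[sizes < length(pool)], length(pool)))
    }
    if (max(sizes) > length(pool))
      stop("requested size ", max(sizes), " exceeds training pool (",
           length(pool), ")")
    rows <- lapply(sizes, function(s) {
      tr <- pool[sample.int(length(pool), s)]
      if (length(unique(y[tr])) < 2L)
        stop("sampled training set of size ", s, " has a single class")
      selC <- C; selD <- d
      if (!is.null(grid)) {
        sub <- data[tr]
        rep <- nestedCV(sub, grid, nRuns = 1L, seed = NULL,
                        outerFolds = min(10L, length(tr) %/% 2L),
                        innerFolds = 10L, tol = tol)
        # most frequently selected pair across folds, ties to smallest
        tab <- stats::aggregate(list(nsel = rep@folds$run),
                                by = list(C = rep@folds$C, d = rep@folds$d),
                                FUN = length)
        tab <- tab[order(-tab$nsel, tab$d, tab$C), ]
        selC <- tab$C[1L]; selD <- tab$d[1L]
      }
      K <- gramFromCounts(counts, kernelSpec(selD))
      sv <- .fitScore(K, y, tr, val, selC, tol)
      st <- .fitScore(K, y, tr, test, selC, tol)
      mv <- computeMetrics(sv, y[val])
      mt <- computeMetrics(st, y[test])
      data.frame(size = s, C = selC, d = selD,
                 ACC_val = mv[["ACC"]], MCC_val = mv[["MCC"]],
                 AUC_val = mv[["AUC"]],
                 ACC_test = mt[["ACC"]], MCC_test = mt[["MCC"]],
                 AUC_test = mt[["AUC"]])
    })
    do.call(rbind, rows)
  })
}

#' Mean-property RBF-SVM baseline
#'
#' The position-independent baseline: peptides are encoded as vectors of
#' per-property means (see \code{\link{encodeMeanProperties}}), columns are
#' z-scored, and a Gaussian-kernel SVM
#' \eqn{k(x, y) = \exp(-\gamma \|x - y\|^2)} is evaluated with the same
#' nested-CV protocol as \code{\link{nestedCV}}, tuning \eqn{C} and
#' \eqn{\gamma} over the supplied grids (ties broken towards smallest
#' \eqn{\gamma}, then smallest \eqn{C}). Because the encoding averages over
#' positions, this baseline is blind to positional information; the string
#' kernel is not.
#'
#' @param data a \code{\link{PeptideSet}}.
#' @param table a property table from \code{\link{readAAindex}} or
#'   \code{\link{defaultPropertyTable}}; incomplete records are excluded.
#' @param properties optional character vector of accessions to restrict
#'   the encoding to.
#' @param C,gamma numeric grids (defaults \eqn{2^{-4}..2^4}).
#' @param nRuns,seed,outerFolds,innerFolds,tol as in \code{\link{nestedCV}}.
#' @param scale z-score encoding columns before the kernel (default TRUE).
#' @return A \code{\link{CVReport}}.
#' @export
baselinePropertySVM <- function(data, table = defaultPropertyTable(),
                                properties = NULL, C = 2^(-4:4),
                                gamma = 2^(-4:4), nRuns = 20, seed = NULL,
                                outerFolds = 10L, innerFolds = 10L,
                                tol = 1e-3, scale = TRUE) {
  stopifnot(is(data, "PeptideSet"))
  if (any(C <= 0) || any(gamma <= 0)) stop("C and gamma must be > 0")
  enc <- encodeMeanProperties(data, table, properties = properties)
  if (scale) {
    enc <- apply(enc, 2L, function(col) {
      s <- sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  }
  d2 <- as.matrix(stats::dist(enc))^2
  gamma <- sort(as.numeric(gamma))
  Klist <- lapply(gamma, function(g) exp(-g * d2))
  combos <- expand.grid(C = sort(as.numeric(C)), gamma = gamma,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$gamma, combos$C), , drop = FALSE]
  combos$.kernel <- match(combos$gamma, gamma)
  .nestedCVEngine(Klist, combos, as.numeric(data@labels), nRuns,
                  outerFolds, innerFolds, seed, tol)
}

#' Accessors for CVReport
#'
#' @param x a \code{\link{CVReport}}.
#' @return \code{cvFolds}: per-(run, fold) rows with selected parameters and
#'   metrics; \code{cvRuns}: per-run means; \code{cvSummary}: across-run
#'   mean and sd per metric.
#' @export
cvFolds <- function(x) x@folds

#' @rdname cvFolds
#' @export
cvRuns <- function(x) x@runs

#' @rdname cvFolds
#' @export
cvSummary <- function(x) x@summary

setMethod("show", "CVReport", function(object) {
  nr <- max(object@folds$run)
  cat("CVReport:", nr, "run(s) x", max(object@folds$fold),
      "outer folds (seed:", object@seed, ")\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(NULL)
})

#' Write a CVReport to disk
#'
#' Writes \code{<prefix>_folds.tsv} (one row per run per fold: run, fold,
#' selected parameters, ACC, MCC, AUC) and \code{<prefix>_summary.json}
#' (across-run means and sds, the seed and the searched grid).
#'
#' @param report a \code{\link{CVReport}}.
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
writeCVReport <- function(report, prefix) {
  foldsPath <- paste0(prefix, "_folds.tsv")
  summaryPath <- paste0(prefix, "_summary.json")
  write.table(report@folds, foldsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  summ <- list(summary = report@summary, runs = report@runs,
               seed = report@seed, grid = report@grid,
               package_version = as.character(packageVersion("tcreact")))
  writeLines(jsonlite::toJSON(summ, digits = I(10), auto_unbox = TRUE,
                              na = "null"), summaryPath)
  invisible(c(foldsPath, summaryPath))
}
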