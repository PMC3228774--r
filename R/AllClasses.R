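#' Labeled peptide set
#'
#' A set of equal-length amino-acid peptides with binary immunogenicity
#' labels: \code{+1} for immunogenic (T-cell reactive), \code{-1} for
#' non-immunogenic. Sequences are held as a \link[Biostrings]{AAStringSet}.
#' Validity requires equal lengths, labels in \{-1, +1\}, residues drawn from
#' the 20 canonical one-letter codes, and no sequence occurring with both
#' labels (contradictory annotations must be resolved before construction;
#' \code{\link{readPeptideSet}} collapses them to immunogenic).
#'
#' @slot peptides \link[Biostrings]{AAStringSet} of equal-width sequences.
#' @slot labels integer vector of \code{+1}/\code{-1}, one per peptide.
#' @seealso \code{\link{PeptideSet}}, \code{\link{readPeptideSet}}
#' @export
setClass("PeptideSet",
         representation(peptides = "AAStringSet", labels = "integer"))

setValidity("PeptideSet", function(object) {
  msg <- character()
  n <- length(object@peptides)
  if (length(object@labels) != n)
    msg <- c(msg, "number of labels must equal number of peptides")
  if (!all(object@labels %in% c(-1L, 1L)))
    msg <- c(msg, "labels must be +1 or -1")
  if (n > 0) {
    w <- Biostrings::width(object@peptides)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "all peptides must have the same length")
    letters <- Biostrings::uniqueLetters(object@peptides)
    bad <- setdiff(letters, AA_ALPHABET20)
    if (length(bad) > 0L)
      msg <- c(msg, paste0("non-canonical residue(s): ",
                           paste(bad, collapse = ", ")))
    seqs <- as.character(object@peptides)
    if (length(msg) == 0L) {
      both <- intersect(seqs[object@labels == 1L], seqs[object@labels == -1L])
      if (length(both) > 0L)
        msg <- c(msg, paste0("sequence(s) present with both labels: ",
                             paste(head(both, 3L), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Weighted degree kernel specification
#'
#' Degree \eqn{d} and the weight vector \eqn{\beta_1..\beta_d} of the
#' weighted degree string kernel
#' \deqn{k(s_i, s_j) = \sum_{p=1}^{d} \beta_p \sum_{l=1}^{L-p+1}
#'   I(u_{p,l}(s_i) = u_{p,l}(s_j)),}
#' where \eqn{u_{p,l}(s)} is the length-\eqn{p} substring of \eqn{s} starting
#' at position \eqn{l}. The default weights
#' \eqn{\beta_p = 2(d-p+1)/(d(d+1))} decrease with substring length and sum
#' to one. An optional cosine normalization
#' \eqn{k/\sqrt{k_{11} k_{22}}} can be switched on; it is off by default.
#'
#' @slot degree integer, maximal matched-substring length \eqn{d \ge 1}.
#' @slot betas numeric weights \eqn{\beta_1..\beta_d}, non-negative.
#' @slot normalize logical, cosine-normalize kernel values (default FALSE).
#' @seealso \code{\link{kernelSpec}}, \code{\link{betaWeights}}
#' @export
setClass("KernelSpec",
         representation(degree = "integer", betas = "numeric",
                        normalize = "logical"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@degree) != 1L || is.na(object@degree) ||
      object@degree < 1L)
    msg <- c(msg, "degree must be a single integer >= 1")
  else if (length(object@betas) != object@degree)
    msg <- c(msg, "betas must have length equal to degree")
  if (any(!is.finite(object@betas)) || any(object@betas < 0))
    msg <- c(msg, "betas must be finite and non-negative")
  if (length(object@normalize) != 1L || is.na(object@normalize))
    msg <- c(msg, "normalize must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Trained string-kernel SVM model
#'
#' Result of fitting the soft-margin SVM dual on a precomputed weighted
#' degree kernel Gram matrix. Decision scores for a query peptide \eqn{q} are
#' \deqn{f(q) = \sum_i \alpha_i y_i k(x_i, q) + b,} and a peptide is called
#' immunogenic exactly when \eqn{f(q) > 0}. The training peptides are kept
#' because kernel evaluation at prediction time needs them.
#'
#' @slot train \code{\link{PeptideSet}} the model was fitted on.
#' @slot coefficients numeric \eqn{\alpha_i y_i} per training peptide.
#' @slot alpha numeric dual variables \eqn{\alpha_i \in [0, C]}.
#' @slot bias numeric intercept \eqn{b}.
#' @slot cost numeric soft-margin cost \eqn{C}.
#' @slot spec \code{\link{KernelSpec}} used for the Gram matrix.
#' @slot tol numeric duality-gap tolerance the solver stopped at.
#' @slot converged logical, solver reached the tolerance within the
#'   iteration cap.
#' @slot iterations integer, SMO iterations used.
#' @slot objective numeric, dual objective \eqn{0.5 a'Qa - e'a} at the
#'   solution (minimization form).
#' @seealso \code{\link{trainModel}}, \code{\link{predict,WdSvmModel-method}}
#' @export
setClass("WdSvmModel",
         representation(train = "PeptideSet", coefficients = "numeric",
                        alpha = "numeric", bias = "numeric", cost = "numeric",
                        spec = "KernelSpec", tol = "numeric",
                        converged = "logical", iterations = "integer",
                        objective = "numeric"))

setValidity("WdSvmModel", function(object) {
  msg <- character()
  n <- length(object@train)
  if (length(object@coefficients) != n || length(object@alpha) != n)
    msg <- c(msg, "coefficients/alpha must match the training set size")
  if (any(object@alpha < -1e-9) || any(object@alpha > object@cost + 1e-9))
    msg <- c(msg, "alpha outside [0, C]")
  if (length(msg)) msg else TRUE
})

#' Nested cross-validation report
#'
#' Per-fold, per-run, and overall summaries of a repeated nested 10-fold
#' cross-validation. The inner loop selects the hyperparameters maximizing
#' inner-CV AUC; the outer loop estimates generalization performance.
#'
#' @slot folds data.frame, one row per (run, fold): selected hyperparameters
#'   and ACC/MCC/AUC on the held-out fold.
#' @slot runs data.frame, per-run means of each metric.
#' @slot summary data.frame, across-run mean and sd per metric.
#' @slot seed integer seed the report was generated from (NA if none given).
#' @slot grid list describing the searched hyperparameter grid.
#' @seealso \code{\link{nestedCV}}, \code{\link{writeCVReport}}
#' @export
setClass("CVReport",
         representation(folds = "data.frame", runs = "data.frame",
                        summary = "data.frame", seed = "integer",
                        grid = "list"))
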