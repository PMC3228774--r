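#' Train a string-kernel SVM
#'
#' Fits the soft-margin SVM dual
#' \deqn{\min_a \tfrac12 a^\top Q a - e^\top a, \quad Q_{ij} = y_i y_j
#'   k(x_i, x_j), \quad 0 \le a_i \le C, \quad \sum_i a_i y_i = 0}
#' on the precomputed weighted degree kernel Gram matrix, by SMO with
#' second-order working-set selection. The fit is deterministic for a fixed
#' input ordering and satisfies the dual box and equality constraints to
#' solver tolerance.
#'
#' @param data a \code{\link{PeptideSet}} containing both classes.
#' @param spec a \code{\link{KernelSpec}}.
#' @param C soft-margin cost, \eqn{C > 0}.
#' @param tol duality-gap stopping tolerance (default \code{1e-8}).
#' @param maxit iteration cap for the SMO loop.
#' @param gram optional precomputed Gram matrix of \code{data} under
#'   \code{spec} (skips recomputation inside cross-validation loops).
#' @return A \code{\link{WdSvmModel}}.
#' @examples
#' ps <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
#' m <- trainModel(ps, kernelSpec(9), C = 1)
#' predict(m, ps)
#' @export
trainModel <- function(data, spec = kernelSpec(9), C = 1, tol = 1e-8,
                       maxit = 2000000L, gram = NULL) {
  stopifnot(is(data, "PeptideSet"))
  if (length(C) != 1L || !is.finite(C) || C <= 0) stop("C must be > 0")
  y <- as.numeric(data@labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  K <- if (is.null(gram)) gramMatrix(data, spec) else gram
  if (any(!is.finite(K))) stop("non-finite kernel values in Gram matrix")
  fit <- cpp_smo(K, y, C, tol, as.integer(maxit))
  if (!fit$converged)
    warning("SMO did not reach tolerance ", tol, " within ", maxit,
            " iterations (gap ", signif(fit$gap, 3), ")")
  new("WdSvmModel", train = data, coefficients = fit$alpha * y,
      alpha = fit$alpha, bias = fit$bias, cost = as.numeric(C), spec = spec,
      tol = tol, converged = fit$converged,
      iterations = as.integer(fit$iterations),
      objective = fit$objective)
}

#' Train the final whole-dataset model
#'
#' Convenience wrapper fitting the production configuration: cost
#' \eqn{C = 1.0} and degree \eqn{d = 9} on all supplied data, the parameter
#' pair selected by the inner cross-validation loop in every evaluation run.
#'
#' @param data a \code{\link{PeptideSet}} of 9-mers.
#' @param ... passed on to \code{\link{trainModel}}.
#' @return A \code{\link{WdSvmModel}}.
#' @export
trainFinalModel <- function(data, ...) {
  if (!is.na(peptideLength(data)) && peptideLength(data) != 9L)
    warning("peptide length is ", peptideLength(data),
            "; the reference configuration (C = 1, d = 9) targets 9-mers")
  trainModel(data, kernelSpec(min(9L, peptideLength(data))), C = 1, ...)
}

#' Predict immunogenicity of query peptides
#'
#' Decision scores are \eqn{f(q) = \sum_i \alpha_i y_i k(x_i, q) + b}. A
#' peptide is called immunogenic exactly when its score is larger than zero;
#' a score of exactly zero is called non-immunogenic.
#'
#' @param object a \code{\link{WdSvmModel}}.
#' @param newdata \code{\link{PeptideSet}} or character vector of query
#'   peptides with the model's peptide length.
#' @param ... unused.
#' @return data.frame with columns \code{sequence}, \code{score},
#'   \code{label} (+1/-1) and \code{call}
#'   ("immunogenic"/"non-immunogenic").
#' @export
setMethod("predict", "WdSvmModel", function(object, newdata, ...) {
  seqs <- if (is(newdata, "PeptideSet")) as.character(newdata)
          else toupper(as.character(newdata))
  Lq <- unique(nchar(seqs))
  if (length(Lq) != 1L || Lq != peptideLength(object@train))
    stop("query peptides must have the model's peptide length (",
         peptideLength(object@train), ")")
  Kq <- crossGram(seqs, object@train, object@spec)
  score <- as.vector(Kq %*% object@coefficients) + object@bias
  label <- ifelse(score > 0, 1L, -1L)
  data.frame(sequence = seqs, score = score, label = label,
             call = ifelse(label == 1L, "immunogenic", "non-immunogenic"),
             stringsAsFactors = FALSE)
})

#' @describeIn trainModel decision scores only, as a numeric vector.
#' @param model a \code{\link{WdSvmModel}}.
#' @param newdata query peptides.
#' @export
decisionScores <- function(model, newdata) {
  predict(model, newdata)$score
}

#' Accessors for WdSvmModel
#'
#' @param object a \code{\link{WdSvmModel}}.
#' @param ... unused.
#' @return \code{supportCoefficients}: the \eqn{\alpha_i y_i} expansion
#'   coefficients; \code{dualAlpha}: the raw \eqn{\alpha_i};
#'   \code{modelBias}: the intercept; \code{modelCost}: \eqn{C};
#'   \code{modelKernel}: the \code{\link{KernelSpec}};
#'   \code{trainingPeptides}: the training \code{\link{PeptideSet}};
#'   \code{dualObjective}: the attained dual objective (minimization form).
#' @export
supportCoefficients <- function(object) object@coefficients

#' @rdname supportCoefficients
#' @export
dualAlpha <- function(object) object@alpha

#' @rdname supportCoefficients
#' @export
modelBias <- function(object) object@bias

#' @rdname supportCoefficients
#' @export
modelCost <- function(object) object@cost

#' @rdname supportCoefficients
#' @export
modelKernel <- function(object) object@spec

#' @rdname supportCoefficients
#' @export
trainingPeptides <- function(object) object@train

#' @rdname supportCoefficients
#' @export
dualObjective <- function(object) object@objective

setMethod("show", "WdSvmModel", function(object) {
  cat("WdSvmModel: string-kernel SVM\n")
  cat("  training peptides:", length(object@train), "of length",
      peptideLength(object@train), "\n")
  cat("  C =", object@cost, " d =", object@spec@degree,
      " support vectors:", sum(object@alpha > 1e-9), "\n")
  cat("  bias:", signif(object@bias, 6),
      " dual objective:", signif(object@objective, 6), "\n")
  if (!object@converged) cat("  WARNING: solver did not converge\n")
  invisible(NULL)
})

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize / restore a trained model
#'
#' The archive is a single self-describing JSON file holding the training
#' sequences and labels, the dual coefficients, bias, cost, kernel degree
#' and weights, and a format version. Numeric values are written with 17
#' significant digits so that a load-then-predict round trip reproduces
#' decision scores bit-identically.
#'
#' @param model a \code{\link{WdSvmModel}}.
#' @param path file path of the model archive.
#' @return \code{writeModel}: the path, invisibly. \code{readModel}: the
#'   restored \code{\link{WdSvmModel}}.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    format = "tcreact-model",
    version = MODEL_FORMAT_VERSION,
    package_version = as.character(packageVersion("tcreact")),
    sequences = as.character(model@train),
    labels = model@train@labels,
    coefficients = model@coefficients,
    alpha = model@alpha,
    bias = model@bias,
    cost = model@cost,
    degree = model@spec@degree,
    betas = model@spec@betas,
    normalize = model@spec@normalize,
    tol = model@tol,
    converged = model@converged,
    iterations = model@iterations,
    objective = model@objective
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE),
             path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "tcreact-model"))
    stop("not a tcreact model archive: ", path)
  data <- PeptideSet(obj$sequences, obj$labels)
  new("WdSvmModel", train = data,
      coefficients = as.numeric(obj$coefficients),
      alpha = as.numeric(obj$alpha), bias = as.numeric(obj$bias),
      cost = as.numeric(obj$cost),
      spec = kernelSpec(obj$degree, betas = obj$betas,
                        normalize = isTRUE(obj$normalize)),
      tol = as.numeric(obj$tol), converged = isTRUE(obj$converged),
      iterations = as.integer(obj$iterations),
      objective = as.numeric(obj$objective))
}
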