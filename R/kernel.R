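#' Weighted degree kernel weights
#'
#' The fixed substring-length weights \eqn{\beta_p = 2(d-p+1)/(d(d+1))},
#' \eqn{p = 1..d}: strictly decreasing in \eqn{p} and summing to one.
#'
#' @param d integer degree \eqn{\ge 1}.
#' @return Numeric vector of length \code{d}.
#' @examples
#' betaWeights(1)   # 1
#' betaWeights(2)   # 2/3, 1/3
#' betaWeights(9)[1] # 0.2
#' @export
betaWeights <- function(d) {
  if (length(d) != 1L || is.na(d) || d < 1 || d != round(d))
    stop("invalid degree: d must be a single integer >= 1")
  d <- as.integer(d)
  p <- seq_len(d)
  2 * (d - p + 1) / (d * (d + 1))
}

#' Construct a kernel specification
#'
#' @param degree integer degree \eqn{d \ge 1} (maximal substring length).
#' @param betas optional custom weight vector of length \code{degree};
#'   defaults to \code{\link{betaWeights}(degree)}.
#' @param normalize logical; cosine-normalize kernel values
#'   (\eqn{k/\sqrt{k_{11}k_{22}}}). Default \code{FALSE}: raw kernel values
#'   are used.
#' @return A \code{\link{KernelSpec}}.
#' @examples
#' kernelSpec(9)
#' @export
kernelSpec <- function(degree, betas = NULL, normalize = FALSE) {
  if (is.null(betas)) betas <- betaWeights(degree)
  new("KernelSpec", degree = as.integer(degree), betas = as.numeric(betas),
      normalize = isTRUE(normalize))
}

#' @describeIn kernelSpec degree accessor.
#' @param x a \code{KernelSpec}.
#' @export
kernelDegree <- function(x) x@degree

#' @describeIn kernelSpec weight-vector accessor.
#' @export
kernelBetas <- function(x) x@betas

setMethod("show", "KernelSpec", function(object) {
  cat("KernelSpec: weighted degree string kernel, d =", object@degree,
      if (object@normalize) "(normalized)" else "", "\n")
  cat("  betas:", paste(signif(object@betas, 4), collapse = " "), "\n")
  invisible(NULL)
})

# self-kernel value k(s, s) for any L-mer: sum_p beta_p (L - p + 1)
selfKernelValue <- function(L, spec) {
  p <- seq_len(spec@degree)
  sum(spec@betas * (L - p + 1))
}

checkDegree <- function(spec, L) {
  if (spec@degree > L)
    stop("kernel degree d = ", spec@degree,
         " exceeds peptide length L = ", L)
}

#' Weighted degree string kernel between two peptides
#'
#' Counts position-aligned matching substrings of lengths \eqn{1..d},
#' weighted by \eqn{\beta_p}:
#' \eqn{k(s_1, s_2) = \sum_p \beta_p \sum_l I(u_{p,l}(s_1) = u_{p,l}(s_2))}.
#'
#' @param s1,s2 single peptide sequences (character) of equal length.
#' @param spec a \code{\link{KernelSpec}}; default degree 9.
#' @return A single kernel value.
#' @examples
#' wdKernel("LLFGYPVYV", "LLFGYPVYV")            # 19/3
#' wdKernel("LLFGYPVYV", "LLFGYAVYV", kernelSpec(2)) # 22/3
#' @export
wdKernel <- function(s1, s2, spec = kernelSpec(9)) {
  X <- peptideCodes(c(as.character(s1), as.character(s2)))
  if (nrow(X) != 2L) stop("s1 and s2 must be single sequences")
  checkDegree(spec, ncol(X))
  k <- cpp_cross_gram(X[1L, , drop = FALSE], X[2L, , drop = FALSE],
                      spec@betas)[1L, 1L]
  if (spec@normalize) k <- k / selfKernelValue(ncol(X), spec)
  k
}

#' Gram matrix of the weighted degree kernel
#'
#' Batched kernel evaluation over a peptide list; entry \eqn{(i, j)} equals
#' \code{wdKernel(p_i, p_j, spec)}. The result is symmetric and positive
#' semidefinite, with all diagonal entries equal to
#' \eqn{\sum_p \beta_p (L-p+1)}.
#'
#' @param x a \code{\link{PeptideSet}} or character vector of equal-length
#'   peptides.
#' @param spec a \code{\link{KernelSpec}}.
#' @return Numeric \eqn{n \times n} matrix.
#' @examples
#' gramMatrix(c("LLFGYPVYV", "LLFGYAVYV"), kernelSpec(9))
#' @export
gramMatrix <- function(x, spec = kernelSpec(9)) {
  X <- peptideCodes(x)
  checkDegree(spec, ncol(X))
  K <- cpp_gram(X, spec@betas)
  if (spec@normalize) {
    s <- sqrt(diag(K))
    K <- K / outer(s, s)
  }
  K
}

#' Rectangular kernel matrix between two peptide sets
#'
#' Entry \eqn{(i, j)} is the kernel between \code{x[i]} and \code{y[j]};
#' needed to score unseen peptides against a model's training set.
#'
#' @param x,y \code{\link{PeptideSet}}s or character vectors; all peptides
#'   in both sets must share one length.
#' @param spec a \code{\link{KernelSpec}}.
#' @return Numeric \code{length(x)} by \code{length(y)} matrix.
#' @export
crossGram <- function(x, y, spec = kernelSpec(9)) {
  X <- peptideCodes(x)
  Y <- peptideCodes(y)
  if (ncol(X) != ncol(Y))
    stop("peptide length mismatch between the two sets (",
         ncol(X), " vs ", ncol(Y), ")")
  checkDegree(spec, ncol(X))
  K <- cpp_cross_gram(X, Y, spec@betas)
  if (spec@normalize) K <- K / selfKernelValue(ncol(X), spec)
  K
}

# n x n x L array of per-length matched-window counts; any degree-d Gram is
# a beta-weighted sum over the third axis.  Used to make grids over d cheap.
matchCountArray <- function(x) {
  X <- peptideCodes(x)
  cpp_match_count_array(X)
}

# assemble a Gram matrix from a match-count array for a given spec
gramFromCounts <- function(counts, spec) {
  dm <- dim(counts)
  L <- dm[3L]
  checkDegree(spec, L)
  w <- c(spec@betas, rep(0, L - spec@degree))
  K <- matrix(matrix(counts, dm[1L] * dm[2L], L) %*% w, dm[1L], dm[2L])
  if (spec@normalize) K <- K / selfKernelValue(L, spec)
  K
}
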