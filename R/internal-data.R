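#' Construct an internal case-control dataset
#'
#' Bundles the individual-level data of the internal study: a categorical
#' outcome with \code{0} for controls and \code{1..K} for disease subtypes,
#' and a numeric covariate matrix (binary markers, genotype dosages, or any
#' precomputed features). The retrospective empirical likelihood is anchored
#' on the control distribution \eqn{P(X | Y = 0)}, so data without controls
#' are rejected, as are empty subtype classes and missing covariate values.
#'
#' @param x numeric matrix (or data.frame) of covariates, one row per subject.
#' @param y integer outcome vector in \code{0..K}; \code{0} denotes controls.
#' @param K number of non-control classes; defaults to \code{max(y)}.
#' @param allow_empty_classes permit subtype classes with zero subjects
#'   (used for external study datasets that collected only some subtypes;
#'   internal study data must have every class represented).
#' @return An object of class \code{"polygim_internal"} with elements
#'   \code{x}, \code{y}, \code{K}, \code{n}, \code{class_counts} (named
#'   \code{n0..nK}) and \code{rho} (case-control ratios \eqn{n_k/n_0}).
#' @examples
#' d <- internal_data(cbind(x1 = rbinom(50, 1, .5)), rep(0:2, length.out = 50))
#' d$class_counts
#' @export
internal_data <- function(x, y, K = NULL, allow_empty_classes = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  y <- as.integer(y)
  if (nrow(x) != length(y)) {
    pg_stop("schema", "covariate rows (%d) != outcome length (%d)", nrow(x), length(y))
  }
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    pg_stop("schema", "missing covariate values at row(s) %s; resolve missingness upstream",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(y) || any(y < 0)) pg_stop("schema", "outcome labels must be integers in 0..K")
  K <- as.integer(K %||% max(y))
  if (K < 1L) pg_stop("schema", "need at least one non-control class (K >= 1)")
  if (any(y > K)) {
    pg_stop("schema", "outcome label %d exceeds K = %d (first at row %d)",
            max(y), K, which(y > K)[1])
  }
  counts <- tabulate(y + 1L, nbins = K + 1L)
  if (!allow_empty_classes) {
    if (counts[1] == 0L) pg_stop("schema", "no controls (label 0) present; outcome coding is 0 = control")
    if (any(counts == 0L)) {
      pg_stop("schema", "class(es) %s have no subjects",
              paste(which(counts == 0L) - 1L, collapse = ", "))
    }
  }
  names(counts) <- paste0("n", 0:K)
  structure(list(
    x = x, y = y, K = K, n = length(y),
    class_counts = counts,
    rho = counts[-1] / counts[1]
  ), class = "polygim_internal")
}

#' @export
print.polygim_internal <- function(x, ...) {
  cat(sprintf("Internal case-control data: n = %d, K = %d subtypes\n", x$n, x$K))
  cat("  class counts:", paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                               collapse = ", "), "\n")
  cat("  covariates:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

# 0/1 indicator matrix (n x K) of case classes, used throughout the likelihoods.
class_indicators <- function(data) {
  Y <- matrix(0, data$n, data$K)
  idx <- which(data$y > 0L)
  Y[cbind(idx, data$y[idx])] <- 1
  Y
}
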