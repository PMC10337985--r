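#' Specify the target polytomous regression model
#'
#' The target model relates covariates to the odds of each disease subtype
#' versus controls through a shared feature map applied identically in every
#' class: \eqn{\log\{P(Y=k|X)/P(Y=0|X)\} = \omega_k + M_k(X)} with
#' \eqn{M_k(X) = f(X)^\top \theta_k}. Supported feature maps:
#' \describe{
#'   \item{\code{"identity"}}{features are the covariate columns themselves
#'     (optionally a named subset via \code{features}).}
#'   \item{\code{"prs"}}{a single feature, the polygenic risk score
#'     \eqn{S(X)=\sum_i w_i X_i} computed from \code{prs_weights}.}
#'   \item{\code{"prs_quadratic"}}{two features \eqn{\{S(X), S(X)^2\}},
#'     allowing a curvature check on the score effect.}
#' }
#' Feature maps are registered by name so that external working models and
#' the target model can be compared structurally when classifying summary
#' data as regular or irregular.
#'
#' @param K number of non-control outcome classes.
#' @param feature_map one of \code{"identity"}, \code{"prs"},
#'   \code{"prs_quadratic"}.
#' @param features for \code{"identity"}: covariate column names to use
#'   (default: all columns of the data the model is fitted to).
#' @param prs_weights named numeric vector of SNP weights for the PRS maps;
#'   names must match covariate columns.
#' @return An object of class \code{"polygim_target"}.
#' @export
target_model <- function(K, feature_map = c("identity", "prs", "prs_quadratic"),
                         features = NULL, prs_weights = NULL) {
  feature_map <- match.arg(feature_map)
  K <- as.integer(K)
  if (K < 1L) pg_stop("config", "K must be >= 1")
  if (feature_map != "identity" && is.null(prs_weights)) {
    pg_stop("config", "feature map '%s' requires prs_weights", feature_map)
  }
  structure(list(K = K, feature_map = feature_map, features = features,
                 prs_weights = prs_weights),
            class = "polygim_target")
}

#' Compute polygenic risk scores
#'
#' \eqn{S(X) = \sum_i w_i X_i}: the weighted sum of genotype dosages, linear
#' in both the dosages and the weights.
#'
#' @param genotypes numeric dosage matrix (subjects x SNPs).
#' @param weights numeric weight vector, one entry per SNP column.
#' @return numeric vector of one score per subject.
#' @export
prs_score <- function(genotypes, weights) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(weights)) {
    pg_stop("config", "weight length (%d) != genotype columns (%d)",
            length(weights), ncol(genotypes))
  }
  drop(genotypes %*% as.numeric(weights))
}

# Feature matrix f(X) (n x p, no intercept column) for a target spec.
build_features <- function(x, target) {
  switch(target$feature_map,
    identity = {
      feats <- target$features %||% colnames(x)
      missing <- setdiff(feats, colnames(x))
      if (length(missing)) pg_stop("config", "features not in data: %s",
                                   paste(missing, collapse = ", "))
      x[, feats, drop = FALSE]
    },
    prs = {
      w <- target$prs_weights
      s <- prs_score(x[, names(w) %||% colnames(x), drop = FALSE], w)
      matrix(s, ncol = 1, dimnames = list(NULL, "prs"))
    },
    prs_quadratic = {
      w <- target$prs_weights
      s <- prs_score(x[, names(w) %||% colnames(x), drop = FALSE], w)
      cbind(prs = s, prs2 = s^2)
    })
}

# Names of the per-class linear features of the target (used by the
# regular/irregular classifier).
target_feature_names <- function(target, data) {
  switch(target$feature_map,
    identity = target$features %||% colnames(data$x),
    prs = "prs",
    prs_quadratic = c("prs", "prs2"))
}

# Index of theta_{k, j} inside the stacked parameter vector xi = (tau, theta):
# tau occupies 1..K, theta is stacked class-major after it. The layout is a
# bijection onto 1..(K + K*p).
theta_index <- function(K, p, k, j) K + (k - 1L) * p + j

xi_split <- function(xi, K, p) {
  list(tau = xi[seq_len(K)],
       theta = matrix(xi[-seq_len(K)], nrow = K, ncol = p, byrow = TRUE))
}
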