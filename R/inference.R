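# Post-fit inference: Wald summaries and the disease-subtype heterogeneity
# likelihood-ratio test.

#' Extract subtype coefficients and their covariance for one feature
#'
#' Returns \eqn{\hat\theta_{j\cdot} = (\hat\theta_{j1},...,\hat\theta_{jK})}
#' (the coefficients of feature \eqn{j} across subtypes) together with the
#' \eqn{K\times K} covariance block \eqn{\hat W} extracted from the fit's
#' estimated covariance matrix.
#'
#' @param fit a converged \code{"polygim_fit"}.
#' @param feature feature name or index (position in the target feature map).
#' @return list with \code{theta} (length K, named by class) and \code{W}.
#' @export
coefficient_covariance <- function(fit, feature) {
  p <- length(fit$feature_names)
  j <- if (is.character(feature)) match(feature, fit$feature_names) else as.integer(feature)
  if (is.na(j) || j < 1L || j > p) {
    pg_stop("config", "feature '%s' not present in every class's linear predictor", feature)
  }
  K <- fit$K
  idx <- vapply(seq_len(K), function(k) theta_index(K, p, k, j), integer(1))
  W <- fit$cov_xi[idx, idx, drop = FALSE]
  W <- (W + t(W)) / 2
  list(theta = stats::setNames(fit$theta[, j], paste0("class", seq_len(K))), W = W)
}

#' Likelihood-ratio test for disease-subtype heterogeneity
#'
#' Tests \eqn{H_0: \theta_{j1} = ... = \theta_{jK}} using the asymptotic
#' normality of \eqn{\hat\theta_{j\cdot} \sim N(\theta_{j\cdot}, \hat W)}:
#' \deqn{\Lambda = \hat\theta^\top\hat W^{-1}\hat\theta -
#'   (\mathbf 1^\top\hat W^{-1}\hat\theta)^2/(\mathbf 1^\top\hat W^{-1}\mathbf 1),}
#' which is chi-square with \eqn{K-1} degrees of freedom under the null. The
#' common-effect estimate under the null is
#' \eqn{\hat a = (\mathbf 1^\top\hat W^{-1}\hat\theta)/(\mathbf 1^\top\hat
#' W^{-1}\mathbf 1)}.
#'
#' @param theta_vec estimated subtype coefficients for one feature.
#' @param W their covariance matrix (positive definite; a singular matrix is
#'   a hard error, not silently regularized).
#' @return object of class \code{"polygim_het"} with \code{lambda_stat},
#'   \code{df}, \code{p_value}, \code{common_effect}, \code{theta}, \code{W}.
#' @export
heterogeneity_lrt <- function(theta_vec, W) {
  theta_vec <- as.numeric(theta_vec)
  K <- length(theta_vec)
  W <- as.matrix(W)
  if (!all(dim(W) == K)) pg_stop("config", "W must be %d x %d", K, K)
  Winv <- tryCatch(solve((W + t(W)) / 2), error = function(e)
    pg_stop("singular", "covariance W is singular; the fit is degenerate"))
  one <- rep(1, K)
  a_hat <- drop(crossprod(one, Winv %*% theta_vec)) / drop(crossprod(one, Winv %*% one))
  lam <- drop(crossprod(theta_vec, Winv %*% theta_vec)) -
    drop(crossprod(one, Winv %*% theta_vec))^2 / drop(crossprod(one, Winv %*% one))
  lam <- max(lam, 0)
  df <- K - 1L
  p <- if (df == 0L) 1 else stats::pchisq(lam, df, lower.tail = FALSE)
  structure(list(lambda_stat = lam, df = df, p_value = p,
                 common_effect = a_hat, theta = theta_vec, W = W),
            class = "polygim_het")
}

#' @export
print.polygim_het <- function(x, ...) {
  cat(sprintf("Subtype heterogeneity LRT: Lambda = %.4f, df = %d, p = %.4g\n",
              x$lambda_stat, x$df, x$p_value))
  cat(sprintf("  common effect under H0: %.4f\n", x$common_effect))
  invisible(x)
}

#' Global heterogeneity test for a fitted model
#'
#' Convenience wrapper: extracts \eqn{(\hat\theta_{j\cdot},\hat W)} for a
#' feature via [coefficient_covariance()] and applies [heterogeneity_lrt()].
#'
#' @inheritParams coefficient_covariance
#' @export
heterogeneity_test <- function(fit, feature = 1L) {
  cc <- coefficient_covariance(fit, feature)
  heterogeneity_lrt(cc$theta, cc$W)
}

#' Pairwise subtype comparison
#'
#' Tests \eqn{H_0: \theta_{j k_1} = \theta_{j k_2}} for one pair of subtypes
#' (1 degree of freedom); equivalent to the heterogeneity LRT applied to the
#' corresponding 2-subvector.
#'
#' @inheritParams coefficient_covariance
#' @param pair integer vector of two distinct class indices.
#' @export
pairwise_heterogeneity <- function(fit, feature, pair) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2]) {
    pg_stop("config", "pair must be two distinct class indices")
  }
  cc <- coefficient_covariance(fit, feature)
  heterogeneity_lrt(cc$theta[pair], cc$W[pair, pair])
}

#' Coefficient table with Wald tests
#'
#' One row per model parameter: estimate, standard error (square root of the
#' covariance diagonal), z value and two-sided normal p-value. A
#' Bonferroni-adjusted column is appended as a supplementary convenience; the
#' primary p-values are unadjusted.
#'
#' @param fit a converged \code{"polygim_fit"}.
#' @return data.frame with columns \code{term}, \code{estimate}, \code{se},
#'   \code{z}, \code{p_value}, \code{p_bonferroni}.
#' @export
wald_summary <- function(fit) {
  est <- fit$xi
  se <- sqrt(pmax(diag(fit$cov_xi), 0))
  z <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  ntheta <- sum(grepl("^theta", names(est)))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p_value = unname(p),
             p_bonferroni = pmin(unname(p) * ntheta, 1),
             row.names = NULL)
}
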