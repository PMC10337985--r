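# Retrospective representation of the target model and the internal-data MLE.
#
# The prospective model log{P(Y=k|X)/P(Y=0|X)} = omega_k + M_k(X) has the
# equivalent retrospective form P(X|Y=k) = P(X|Y=0) * Delta_k(X; xi) with
# Delta_k = exp{tau_k + M_k(X; theta_k)} and tau_k a shifted intercept.
# Profiling the empirical control distribution out of the retrospective
# likelihood yields
#   l1(xi) = sum_i sum_k 1(Y_i=k) log Delta_ki - sum_i log(1 + sum_k rho_k Delta_ki),
# whose maximizer coincides (for linear feature maps) with the prospective
# multinomial-logit MLE after the intercept conversion tau_k = omega_k - log rho_k.

# n x K matrix of Delta_k(X_i; xi) given a feature matrix F (n x p).
delta_matrix <- function(F, xi, K) {
  p <- ncol(F)
  if (length(xi) != K + K * p) {
    pg_stop("config", "xi has length %d, expected %d (K=%d, p=%d)",
            length(xi), K + K * p, K, p)
  }
  sp <- xi_split(xi, K, p)
  lin <- F %*% t(sp$theta)                  # n x K
  lin <- sweep(lin, 2, sp$tau, "+")
  matrix(clipped_exp(lin), nrow(F), K)
}

#' Retrospective odds factor of the target model
#'
#' \eqn{\Delta_k(X;\xi) = \exp\{\tau_k + M_k(X;\theta_k)\}}: the density ratio
#' \eqn{P(X|Y=k)/P(X|Y=0)} implied by the polytomous model. Strictly positive;
#' exponents are clipped at \eqn{\pm 700} for overflow protection.
#'
#' @param x_row numeric feature vector (already on the feature scale of the
#'   target model, i.e. a row of the design built by its feature map).
#' @param xi parameter vector \eqn{(\tau_1..\tau_K, \theta_1, ..., \theta_K)}
#'   with each \eqn{\theta_k} of length \code{length(x_row)}.
#' @param k class index in \code{1..K}.
#' @param K number of non-control classes.
#' @return positive scalar.
#' @export
retro_delta <- function(x_row, xi, k, K) {
  k <- as.integer(k)
  if (k < 1L || k > K) pg_stop("config", "class index k = %d outside 1..%d", k, K)
  F <- matrix(as.numeric(x_row), nrow = 1)
  delta_matrix(F, xi, K)[1, k]
}

#' Profile log-likelihood of the internal case-control study
#'
#' The empirical-likelihood profile
#' \eqn{\ell_1(\xi) = \sum_i\sum_k 1(Y_i{=}k)\log\Delta_k(X_i;\xi) -
#' \sum_i \log\{1+\sum_k \rho_k \Delta_k(X_i;\xi)\}} with
#' \eqn{\rho_k = n_k/n_0}.
#'
#' @param xi parameter vector \eqn{(\tau, \theta)}; see [retro_delta()].
#' @param data an [internal_data()] object.
#' @param target a [target_model()] spec (defines the feature map).
#' @return scalar log-likelihood value.
#' @export
internal_profile_loglik <- function(xi, data, target = target_model(data$K)) {
  F <- build_features(data$x, target)
  D <- delta_matrix(F, xi, data$K)
  Y <- class_indicators(data)
  val <- sum(Y * log(D)) - sum(log1p(D %*% data$rho))
  if (!is.finite(val)) {
    bad <- which(!is.finite(log(D) %*% rep(1, data$K)))[1] %||% NA
    pg_stop("numeric", "non-finite internal likelihood (first offending row: %s)", bad)
  }
  val
}

# Score and Hessian of l1 in xi = (tau, theta). Block layout matches
# theta_index(). Returns list(loglik, grad, hess, P) where P is the n x K
# matrix rho_k Delta_ki / (1 + sum_j rho_j Delta_ji).
plr_score_hess <- function(xi, F, Y, rho, hess = TRUE) {
  n <- nrow(F); K <- length(rho); p <- ncol(F)
  D <- delta_matrix(F, xi, K)
  denom <- 1 + drop(D %*% rho)
  P <- sweep(D, 2, rho, "*") / denom
  ll <- sum(Y * log(D)) - sum(log(denom))
  V <- cbind(1, F)                          # per-class design (tau_k, theta_k)
  R <- Y - P
  grad <- as.numeric(vapply(seq_len(K), function(k) crossprod(V, R[, k]),
                            numeric(p + 1)))
  H <- NULL
  if (hess) {
    H <- matrix(0, K * (p + 1), K * (p + 1))
    for (k in seq_len(K)) {
      for (l in k:K) {
        wkl <- if (k == l) -P[, k] * (1 - P[, k]) else P[, k] * P[, l]
        blk <- crossprod(V * wkl, V)
        ik <- (k - 1) * (p + 1) + seq_len(p + 1)
        il <- (l - 1) * (p + 1) + seq_len(p + 1)
        H[ik, il] <- blk
        if (l != k) H[il, ik] <- t(blk)
      }
    }
  }
  # reorder from per-class (tau_k, theta_k) blocks to (tau..., theta...) layout
  ord <- order_classblocks_to_xi(K, p)
  list(loglik = ll, grad = grad[ord],
       hess = if (hess) H[ord, ord, drop = FALSE] else NULL, P = P, D = D)
}

# Permutation mapping the per-class (tau_k, theta_k) stacking onto the
# xi = (tau_1..tau_K, theta_1, ..., theta_K) layout.
order_classblocks_to_xi <- function(K, p) {
  idx <- matrix(seq_len(K * (p + 1)), ncol = K)   # column k = block k
  c(idx[1, ], as.numeric(idx[-1, , drop = FALSE]))
}

#' Internal-data maximum likelihood fit of the polytomous model
#'
#' Maximizes the retrospective profile likelihood \eqn{\ell_1(\xi)} by damped
#' Newton iteration with step-halving (ascent safeguarded); convergence when
#' the maximal score component falls below \code{tol}. The estimated
#' covariance is the inverse observed information of \eqn{\ell_1}; for the
#' slope parameters this agrees with prospective multinomial-logit standard
#' errors under case-control sampling.
#'
#' @param data an [internal_data()] object.
#' @param target a [target_model()] spec.
#' @param xi0 optional start value (defaults to 0).
#' @param tol convergence tolerance on \code{max(abs(score))}.
#' @param max_iter maximum Newton iterations.
#' @return A \code{"polygim_fit"} object with elements \code{xi} (named),
#'   \code{tau}, \code{theta} (K x p), \code{cov_xi}, \code{loglik},
#'   \code{iterations}, \code{method = "MLE"}.
#' @export
fit_plr_mle <- function(data, target = target_model(data$K), xi0 = NULL,
                        tol = 1e-8, max_iter = 100L) {
  F <- build_features(data$x, target)
  qrF <- qr(cbind(1, F))
  if (qrF$rank < ncol(F) + 1) {
    pg_stop("identifiability", "feature matrix (with intercept) is rank deficient (rank %d < %d)",
            qrF$rank, ncol(F) + 1)
  }
  Y <- class_indicators(data)
  K <- data$K; p <- ncol(F)
  xi <- xi0 %||% numeric(K + K * p)
  sc <- plr_score_hess(xi, F, Y, data$rho)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gmax <- max(abs(sc$grad))
    trace <- c(trace, gmax)
    # secondary criterion: accumulation floor of an n-term score sum
    if (gmax < tol || (it > 6L && gmax < 2e-10 * data$n)) { converged <- TRUE; break }
    step <- tryCatch(solve(sc$hess, -sc$grad), error = function(e)
      pg_stop("identifiability", "singular information matrix (possible separation): %s",
              conditionMessage(e)))
    if (max(abs(step)) < 1e-12) { converged <- TRUE; break }  # change below precision
    t_ <- 1; stalled <- FALSE
    repeat {
      cand <- xi + t_ * step
      sc_new <- tryCatch(plr_score_hess(cand, F, Y, data$rho), error = function(e) NULL)
      if (!is.null(sc_new) && is.finite(sc_new$loglik) && sc_new$loglik >= sc$loglik - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) { stalled <- TRUE; break }
    }
    if (stalled) {
      # ascent exhausted at floating-point resolution; accept if the score
      # is at the accumulation floor of an n-term sum, else fail
      if (gmax < 2e-10 * data$n) { converged <- TRUE; break }
      pg_stop("convergence", "step-halving failed at iteration %d (|score| = %.3g)", it, gmax)
    }
    xi <- cand; sc <- sc_new
    pg_log("debug", "MLE Newton iter %d: |score| = %.3g, step = %.3g", it, gmax, t_)
  }
  if (!converged && max(abs(sc$grad)) < 2e-10 * data$n) converged <- TRUE
  if (!converged) {
    pg_stop("convergence", "MLE did not converge in %d iterations (|score| trace: %s)",
            max_iter, paste(sprintf("%.2g", utils::tail(trace, 5)), collapse = " "))
  }
  cov_xi <- safe_solve(-sc$hess)
  nm <- xi_names(K, colnames(F))
  dimnames(cov_xi) <- list(nm, nm)
  names(xi) <- nm
  sp <- xi_split(xi, K, p)
  structure(list(xi = xi, tau = sp$tau, theta = sp$theta,
                 feature_names = colnames(F), K = K,
                 cov_xi = cov_xi, cov_mu = cov_xi, loglik = sc$loglik,
                 iterations = length(trace), method = "MLE",
                 data = data, target = target),
            class = c("polygim_fit"))
}

xi_names <- function(K, fnames) {
  c(paste0("tau", seq_len(K)),
    as.vector(t(outer(seq_len(K), fnames, function(k, f) paste0("theta", k, ".", f)))))
}

#' @export
print.polygim_fit <- function(x, ...) {
  cat(sprintf("polygim fit [%s]: K = %d, %d parameters, loglik = %.3f\n",
              x$method, x$K, length(x$xi), x$loglik))
  print(wald_summary(x), digits = 4)
  invisible(x)
}
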