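# Covariance of the external summary statistics.
#
# Each working model's coefficient estimate solves an M-estimating equation
# with per-subject score psi = (D - h) z, h = rho*delta/(1+rho*delta),
# under stratified (outcome-conditional) sampling of the external design.
# Its asymptotic covariance is the sandwich A^{-1} B A^{-1}, where the
# expectations over the stratum covariate distributions P(X|Y=k) are
# estimated on the internal sample by the change of measure p-hat * Delta_k.
# Models fitted on overlapping samples (shared outcome strata within one
# study) get non-zero cross-blocks assembled from shared-stratum covariances
# of their scores; models from distinct studies are independent.

# Core builder: Cov(beta~) for a list of model descriptors.
# models: list of list(wm, Z) as in build_system; gammas: list of current
# (alpha, beta) vectors; phat: empirical control weights; Dm: n x K matrix of
# Delta_k at the current xi.
beta_cov_core <- function(models, gammas, phat, Dm, want_AB = FALSE) {
  M <- length(models)
  dm <- vapply(models, function(m) gamma_dim(m$wm), integer(1))
  off <- c(0L, cumsum(dm))
  Gt <- sum(dm)
  K <- ncol(Dm)
  strata <- lapply(models, function(m) model_strata(m$wm))
  # external count used by model m in stratum s (0 if unused)
  cnt <- matrix(0, M, K + 1L)
  for (m in seq_len(M)) cnt[m, strata[[m]]$s + 1L] <- strata[[m]]$count
  study <- vapply(models, function(m) m$wm$study, character(1))
  # consistency of overlap declarations: two models of one study that both
  # use a stratum must declare the same count there
  for (s in seq_len(K + 1L)) {
    for (st_ in unique(study)) {
      use <- which(study == st_ & cnt[, s] > 0)
      if (length(use) > 1 && diff(range(cnt[use, s])) > 1e-8) {
        pg_stop("config",
                "inconsistent overlap declaration: models of study '%s' declare different counts (%s) in stratum %d",
                st_, paste(unique(cnt[use, s]), collapse = ", "), s - 1L)
      }
    }
  }
  hmat <- matrix(0, nrow(Dm), M)
  Dval <- matrix(NA_real_, M, K + 1L)       # D of model m in stratum s
  for (m in seq_len(M)) {
    wm <- models[[m]]$wm
    delta <- clipped_exp(drop(models[[m]]$Z %*% c(gammas[[m]]$alpha, gammas[[m]]$beta)))
    hmat[, m] <- wm$rho * delta / (1 + wm$rho * delta)
    st_m <- strata[[m]]
    Dval[m, st_m$s + 1L] <- st_m$D
  }
  A <- vector("list", M)
  for (m in seq_len(M)) A[[m]] <- matrix(0, dm[m], dm[m])
  B <- matrix(0, Gt, Gt)
  Nm <- vapply(models, function(m) m$wm$N, numeric(1))
  for (s in seq_len(K + 1L)) {
    use <- which(cnt[, s] > 0)
    if (!length(use)) next
    u <- if (s == 1L) phat else phat * Dm[, s - 1L]
    u <- u / sum(u)
    # A contributions
    for (m in use) {
      wA <- u * hmat[, m] * (1 - hmat[, m])
      A[[m]] <- A[[m]] + (cnt[m, s] / Nm[m]) *
        crossprod(models[[m]]$Z * wA, models[[m]]$Z)
    }
    # B contributions: Cov_s(psi_m, psi_m') over all pairs sharing stratum s;
    # psi_m = (D_m - h_m) z_m with D_m constant in the stratum but z random
    cols <- unlist(lapply(use, function(m) off[m] + seq_len(dm[m])), use.names = FALSE)
    Psi <- do.call(cbind, lapply(use, function(m)
      models[[m]]$Z * (Dval[m, s] - hmat[, m])))
    Es <- crossprod(Psi * u, Psi)
    mu_s <- drop(crossprod(Psi, u))
    Cov_s <- Es - tcrossprod(mu_s)
    # scale each (m, m') block by the shared count (equal by the check above;
    # models from different studies share nothing)
    scl <- matrix(0, length(cols), length(cols))
    pos <- cumsum(c(0L, dm[use]))
    for (a in seq_along(use)) {
      for (b in seq_along(use)) {
        if (study[use[a]] == study[use[b]]) {
          scl[pos[a] + seq_len(dm[use[a]]), pos[b] + seq_len(dm[use[b]])] <-
            min(cnt[use[a], s], cnt[use[b], s])
        }
      }
    }
    B[cols, cols] <- B[cols, cols] + Cov_s * scl
  }
  Ainv <- lapply(A, safe_solve)
  Gamma <- matrix(0, Gt, Gt)                # Cov of stacked gamma~
  for (m in seq_len(M)) {
    im <- off[m] + seq_len(dm[m])
    for (m2 in seq_len(M)) {
      im2 <- off[m2] + seq_len(dm[m2])
      Gamma[im, im2] <- Ainv[[m]] %*% B[im, im2, drop = FALSE] %*% Ainv[[m2]] /
        (Nm[m] * Nm[m2])
    }
  }
  bsl <- unlist(lapply(seq_len(M), function(m) off[m] + beta_slots(models[[m]]$wm)),
                use.names = FALSE)
  cov_beta <- (Gamma[bsl, bsl, drop = FALSE] + t(Gamma[bsl, bsl, drop = FALSE])) / 2
  if (want_AB) list(cov_beta = cov_beta, A = A, B = B, cov_gamma = Gamma) else
    list(cov_beta = cov_beta)
}

#' Sandwich covariance of one working model's summary statistics
#'
#' Estimates \eqn{\hat A}, \eqn{\hat B} and
#' \eqn{\hat\Sigma_0 = N(\hat A^{-1}\hat B\hat A^{-1})_{\beta\beta}} (scaled
#' so that \eqn{Cov(\tilde\beta) = \hat\Sigma_0/N}) for a single working
#' model, with expectations taken under the estimated control distribution.
#'
#' @param fit a \code{"polygim_fit"} (supplies \eqn{\hat\xi}, \eqn{\hat p}).
#' @param entry a [summary_entry()]; its working-model coefficients are taken
#'   from the fit when available, otherwise initialized from the internal
#'   data.
#' @return list with \code{A}, \code{B}, \code{sigma0} (the \eqn{\beta}
#'   block, scaled by \eqn{N}) and \code{cov_beta} (\eqn{=\Sigma_0/N}).
#' @export
estimate_sigma0 <- function(fit, entry) {
  data <- fit$data
  wm <- entry$model
  mod <- list(wm = wm, Z = working_design(wm, data$x))
  gam <- fit$gammas[[wm$id]] %||% init_nuisance(data, wm)
  Dm <- delta_matrix(build_features(data$x, fit$target), fit$xi, data$K)
  phat <- fit$p_hat %||% retrospective_weights(Dm, data)
  out <- beta_cov_core(list(mod), list(gam), phat, Dm, want_AB = TRUE)
  list(A = out$A[[1]], B = out$B, cov_beta = out$cov_beta,
       sigma0 = out$cov_beta * wm$N)
}

#' Joint covariance of summary statistics from multiple working models
#'
#' Assembles \eqn{Cov(\tilde\beta)} across all working models in a summary
#' set: block-diagonal across distinct studies, with cross-blocks for models
#' fitted on overlapping samples (declared via a shared \code{study} label)
#' computed from shared-stratum covariances of their estimating functions.
#'
#' @param fit a \code{"polygim_fit"} supplying \eqn{\hat\xi}, \eqn{\hat p}
#'   and working-model coefficients.
#' @param summaries a [summary_data()] object.
#' @return symmetric covariance matrix of the stacked reported coefficients.
#' @export
build_joint_sigma <- function(fit, summaries) {
  data <- fit$data
  models <- lapply(summaries$entries, function(e)
    list(wm = e$model, Z = working_design(e$model, data$x)))
  gammas <- lapply(summaries$entries, function(e)
    fit$gammas[[e$model$id]] %||% init_nuisance(data, e$model))
  Dm <- delta_matrix(build_features(data$x, fit$target), fit$xi, data$K)
  phat <- fit$p_hat %||% retrospective_weights(Dm, data)
  beta_cov_core(models, gammas, phat, Dm)$cov_beta
}

# Control-distribution weights implied by the internal-only retrospective
# likelihood (lambda at its population value, nu = 0):
# p_i = (1 + sum rho) / (n (1 + sum_k rho_k Delta_ki)).
retrospective_weights <- function(Dm, data) {
  (1 + sum(data$rho)) / (data$n * (1 + drop(Dm %*% data$rho)))
}
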