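# Profiled joint empirical likelihood for regular summary data.
#
# Parameter vector eta = (lambda, nu, tau, theta, gamma_1, ..., gamma_M):
#   lambda  K Lagrange multipliers of the Delta_k normalization constraints,
#   nu      stacked multipliers of the working-model constraints g,
#   (tau, theta) target-model parameters,
#   gamma_m = (alpha0, alpha1, beta) of working model m.
# The profiled objective is
#   lV(eta) = -sum_i log d_i + sum_i sum_k 1(Y_i=k) log Delta_ki - penalty,
#   d_i = 1 + sum_k lambda_k (Delta_ki - 1) + sum_m nu_m' g_m(X_i; mu),
# with a quadratic penalty (1/2)(beta - beta~)' W (beta - beta~) on the
# stacked reported coefficients (W encodes the chosen V matrix policy), plus
# analogous penalties on theta contrasts for irregular blocks handled jointly.
# The empirical control-distribution weights are p_i = 1/(n d_i).
#
# For linear feature maps every g_m factorizes as g_m = z_m * s_m with z_m
# the working design row and s_m a scalar:
#   CC: s = rho (Delta_c1 - delta Delta_c0) / (1 + rho delta)
#   GC: s = rho (sum_k q_k Delta_k - delta) / (1 + rho delta)
# All derivatives below are analytic; the test suite cross-checks them
# against central differences.

# Precompute the static description of the estimating system.
build_system <- function(data, entries_reg, entries_irr, target) {
  F <- build_features(data$x, target)
  K <- data$K; p <- ncol(F); n <- data$n
  models <- lapply(entries_reg, function(e) {
    wm <- e$model
    Z <- working_design(wm, data$x)
    ks <- if (wm$kind == "cc") c(wm$c0, wm$c1) else which(wm$q > 0)
    list(wm = wm, Z = Z, d = gamma_dim(wm), ks = ks,
         beta_tilde = e$beta, se = e$se)
  })
  dm <- vapply(models, `[[`, integer(1), "d")
  G <- sum(dm)
  idx <- local({
    off <- 0L
    lambda <- off + seq_len(K); off <- off + K
    nu <- lapply(dm, function(d) { v <- off + seq_len(d); off <<- off + d; v })
    tau <- off + seq_len(K); off <- off + K
    theta <- off + seq_len(K * p); off <- off + K * p
    gamma <- lapply(dm, function(d) { v <- off + seq_len(d); off <<- off + d; v })
    list(lambda = lambda, nu = nu, tau = tau, theta = theta, gamma = gamma,
         P = off)
  })
  # stacked reported-beta positions in eta, and within the gamma stack
  beta_eta <- unlist(lapply(seq_along(models), function(m)
    idx$gamma[[m]][beta_slots(models[[m]]$wm)]), use.names = FALSE)
  # irregular blocks enter through a theta-contrast penalty only
  irr <- lapply(entries_irr, function(e) {
    wm <- e$model
    C <- matrix(0, p, K + K * p)
    for (j in seq_len(p)) {
      C[j, theta_index(K, p, wm$c1, j)] <- 1
      C[j, theta_index(K, p, wm$c0, j)] <- -1
    }
    list(wm = wm, C = C, beta_tilde = e$beta, se = e$se)
  })
  # concatenated working designs and the model index of each stacked column
  # (used to batch the per-model Hessian blocks into few BLAS calls)
  Zall <- if (length(models)) do.call(cbind, lapply(models, `[[`, "Z")) else NULL
  modidx <- rep(seq_along(models), dm)
  # batched fast path for "simple" working models (single-class GC with one
  # reported covariate and intercept-only nuisance -- the marginal-SNP case):
  # their per-subject state is computed as whole n x Ms matrix operations
  is_simple <- vapply(models, function(m)
    m$wm$kind == "gc" && gamma_dim(m$wm) == 2L && length(m$ks) == 1L, logical(1))
  smp <- NULL
  if (any(is_simple)) {
    si <- which(is_simple)
    smp <- list(
      i = si,
      Xs = do.call(cbind, lapply(models[si], function(m) m$Z[, 2L])),
      cls = vapply(models[si], function(m) m$ks[1L], integer(1)),
      rhoM = matrix(vapply(models[si], function(m) m$wm$rho, numeric(1)),
                    n, length(si), byrow = TRUE),
      nuA = vapply(idx$nu[si], `[`, numeric(1), 1L),
      nuB = vapply(idx$nu[si], `[`, numeric(1), 2L),
      gaA = vapply(idx$gamma[si], `[`, numeric(1), 1L),
      gaB = vapply(idx$gamma[si], `[`, numeric(1), 2L))
  }
  gen_idx <- which(!is_simple)
  list(data = data, target = target, F = F, V1 = cbind(1, F),
       Y = class_indicators(data), K = K, p = p, n = n,
       rho = data$rho, nk = data$class_counts,
       models = models, idx = idx, G = G, beta_eta = beta_eta, irr = irr,
       Zall = Zall, modidx = modidx, smp = smp, gen_idx = gen_idx,
       nu_all = unlist(idx$nu), gamma_all = unlist(idx$gamma),
       xi_idx = c(idx$tau, idx$theta),
       mu_idx = c(idx$tau, idx$theta, unlist(idx$gamma)))
}

# Per-model state at given eta: delta, s and its derivative scalars.
model_state <- function(mod, gam, Dm) {
  wm <- mod$wm; rho <- wm$rho
  delta <- clipped_exp(drop(mod$Z %*% gam))
  u <- 1 + rho * delta
  if (wm$kind == "cc") {
    D0 <- Dm[, wm$c0]; D1 <- Dm[, wm$c1]
    s <- rho * (D1 - delta * D0) / u
    sD <- cbind(-rho * delta / u, rho / u)            # d s / d Delta_{c0,c1}
    sdel <- -rho * (D0 + rho * D1) / u^2
    sDd <- cbind(-rho / u^2, -rho^2 / u^2)            # d2 s / dDelta ddelta
    sdd <- 2 * rho^2 * (D0 + rho * D1) / u^3
  } else {
    qk <- wm$q[mod$ks]
    Tm <- Dm[, mod$ks, drop = FALSE] %*% qk
    s <- drop(rho * (Tm - delta) / u)
    sD <- outer(1 / u, rho * qk)
    sdel <- drop(-rho * (1 + rho * Tm) / u^2)
    sDd <- outer(-1 / u^2, rho^2 * qk)
    sdd <- drop(2 * rho^2 * (1 + rho * Tm) / u^3)
  }
  list(delta = delta, s = s, sD = sD, sdel = sdel, sDd = sDd, sdd = sdd)
}

# Penalty weight matrix W over the stacked reported betas of the regular
# blocks, according to the V policy. cov_beta is Cov(beta~) (joint), needed
# for "optimal"; for "identity" V = I so the penalty is (N/2)|beta-beta~|^2
# per block; for "sigma" the penalty uses reported squared SEs.
penalty_weight <- function(models, policy, cov_beta = NULL) {
  if (policy == "optimal") {
    if (is.null(cov_beta)) pg_stop("config", "optimal policy requires cov_beta")
    return(safe_solve(cov_beta))
  }
  blocks <- lapply(models, function(mod) {
    nb <- length(mod$wm$reported)
    if (policy == "identity") diag(mod$wm$N, nb)
    else {
      if (is.null(mod$se)) pg_stop("config", "V-sigma policy requires reported SEs (model '%s')",
                                   mod$wm$id)
      diag(1 / mod$se^2, nb)
    }
  })
  as_block_diag(blocks)
}

as_block_diag <- function(blocks) {
  dims <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(dims), sum(dims))
  off <- 0L
  for (b in blocks) {
    i <- off + seq_len(nrow(b)); out[i, i] <- b; off <- off + nrow(b)
  }
  out
}

# Evaluate the profiled objective. what: subset of "grad", "hess", "scores".
# W: penalty weight on stacked regular betas; Wirr: list of weights for
# irregular blocks. Returns NULL if eta is infeasible (some d_i <= 0) and
# .feasible_only is TRUE, else errors.
el_eval <- function(eta, sys, W, Wirr = NULL,
                    what = c("grad", "hess"), feas_error = TRUE) {
  idx <- sys$idx; K <- sys$K; n <- sys$n
  lambda <- eta[idx$lambda]
  Dm <- delta_matrix(sys$F, eta[sys$xi_idx], K)
  d <- 1 + drop(Dm %*% lambda) - sum(lambda)
  M <- length(sys$models)
  st <- vector("list", M); nz <- vector("list", M)
  sb <- NULL
  if (!is.null(sys$smp)) {
    sp_ <- sys$smp
    DeltaS <- clipped_exp(sp_$Xs * rep(eta[sp_$gaB], each = n) +
                            rep(eta[sp_$gaA], each = n))
    uS <- 1 + sp_$rhoM * DeltaS
    DkS <- Dm[, sp_$cls, drop = FALSE]
    sS <- sp_$rhoM * (DkS - DeltaS) / uS
    nzS <- rep(eta[sp_$nuA], each = n) + sp_$Xs * rep(eta[sp_$nuB], each = n)
    d <- d + rowSums(nzS * sS)
    sb <- list(DeltaS = DeltaS, uS = uS, DkS = DkS, sS = sS, nzS = nzS)
    for (j in seq_along(sp_$i)) st[[sp_$i[j]]] <- list(s = sS[, j])
  }
  for (m in sys$gen_idx) {
    mod <- sys$models[[m]]
    st[[m]] <- model_state(mod, eta[idx$gamma[[m]]], Dm)
    nz[[m]] <- drop(mod$Z %*% eta[idx$nu[[m]]])
    d <- d + nz[[m]] * st[[m]]$s
  }
  if (any(d <= 1e-12)) {
    if (feas_error) {
      pg_stop("feasibility", "empirical-weight denominator <= 0 at subject %s",
              which(d <= 1e-12)[1])
    }
    return(NULL)
  }
  w <- 1 / d
  # penalty residuals
  beta_stack <- eta[sys$beta_eta]
  bt <- unlist(lapply(sys$models, `[[`, "beta_tilde"), use.names = FALSE)
  r <- beta_stack - bt
  pen <- if (length(r)) 0.5 * drop(crossprod(r, W %*% r)) else 0
  rirr <- list()
  for (j in seq_along(sys$irr)) {
    ir <- sys$irr[[j]]
    rj <- drop(ir$C %*% eta[sys$xi_idx]) - ir$beta_tilde
    rirr[[j]] <- rj
    pen <- pen + 0.5 * drop(crossprod(rj, Wirr[[j]] %*% rj))
  }
  value <- sum(sys$Y * log(Dm)) - sum(log(d)) - pen
  out <- list(value = value, d = d, w = w, phat = w / n, Dm = Dm, st = st)
  if (!length(intersect(c("grad", "hess", "scores"), what))) return(out)

  # c_k(i) = d d_i / d tau_k = lambda_k Delta_k + sum_m nz_m sD_mk Delta_k
  Cmat <- sweep(Dm, 2, lambda, "*")
  if (!is.null(sb)) {
    sp_ <- sys$smp
    sDS <- sp_$rhoM / sb$uS
    T1 <- sb$nzS * sDS * sb$DkS
    for (k in unique(sp_$cls)) {
      Cmat[, k] <- Cmat[, k] + rowSums(T1[, sp_$cls == k, drop = FALSE])
    }
    sb$sDS <- sDS
  }
  for (m in sys$gen_idx) {
    mod <- sys$models[[m]]
    for (a in seq_along(mod$ks)) {
      k <- mod$ks[a]
      Cmat[, k] <- Cmat[, k] + nz[[m]] * st[[m]]$sD[, a] * Dm[, k]
    }
  }
  # dd_i/deta as an n x P matrix
  P <- idx$P
  Md <- matrix(0, n, P)
  Md[, idx$lambda] <- Dm - 1
  Md[, idx$tau] <- Cmat
  for (k in seq_len(K)) {
    Md[, idx$theta[(k - 1) * sys$p + seq_len(sys$p)]] <- sys$F * Cmat[, k]
  }
  if (!is.null(sb)) {
    sp_ <- sys$smp
    sdelS <- -sp_$rhoM * (1 + sp_$rhoM * sb$DkS) / sb$uS^2
    gSc <- sb$nzS * sdelS * sb$DeltaS
    Md[, sp_$nuA] <- sb$sS
    Md[, sp_$nuB] <- sp_$Xs * sb$sS
    Md[, sp_$gaA] <- gSc
    Md[, sp_$gaB] <- sp_$Xs * gSc
    sb$sdelS <- sdelS
  }
  for (m in sys$gen_idx) {
    Md[, idx$nu[[m]]] <- sys$models[[m]]$Z * st[[m]]$s
    Md[, idx$gamma[[m]]] <- sys$models[[m]]$Z * (nz[[m]] * st[[m]]$sdel * st[[m]]$delta)
  }
  # linear part of the score (the indicator sums)
  lin <- numeric(P)
  lin[idx$tau] <- sys$nk[-1]
  for (k in seq_len(K)) {
    lin[idx$theta[(k - 1) * sys$p + seq_len(sys$p)]] <- crossprod(sys$F, sys$Y[, k])
  }
  grad <- lin - drop(crossprod(Md, w))
  if (length(r)) grad[sys$beta_eta] <- grad[sys$beta_eta] - drop(W %*% r)
  for (j in seq_along(sys$irr)) {
    grad[sys$xi_idx] <- grad[sys$xi_idx] -
      drop(crossprod(sys$irr[[j]]$C, Wirr[[j]] %*% rirr[[j]]))
  }
  out$grad <- grad

  if ("scores" %in% what) {
    # per-subject score contributions (penalty excluded; its variability
    # enters through Cov(beta~) separately)
    S <- -(Md * w)
    S[, idx$tau] <- S[, idx$tau] + sys$Y
    for (k in seq_len(K)) {
      S[, idx$theta[(k - 1) * sys$p + seq_len(sys$p)]] <-
        S[, idx$theta[(k - 1) * sys$p + seq_len(sys$p)], drop = FALSE] + sys$F * sys$Y[, k]
    }
    out$scores <- S
  }

  if ("hess" %in% what) {
    H <- crossprod(Md * w)                  # sum w^2 (dd)(dd)'
    # subtract T = sum_i w_i d2 d_i
    V1 <- sys$V1
    for (k in seq_len(K)) {
      tk_idx <- c(idx$tau[k], idx$theta[(k - 1) * sys$p + seq_len(sys$p)])
      wD <- w * Dm[, k]
      # lambda_k x (tau_k, theta_k)
      blk <- drop(crossprod(V1, wD))
      H[idx$lambda[k], tk_idx] <- H[idx$lambda[k], tk_idx] - blk
      H[tk_idx, idx$lambda[k]] <- H[tk_idx, idx$lambda[k]] - blk
      # (tau_k, theta_k)^2 : weight w * c_k
      H[tk_idx, tk_idx] <- H[tk_idx, tk_idx] - crossprod(V1 * (w * Cmat[, k]), V1)
    }
    if (M) {
      # batched per-model blocks: per-model scalar weights are expanded onto
      # the stacked working-design columns, so each block family costs one
      # elementwise scaling plus one BLAS crossprod
      A1 <- matrix(0, n, M); A2 <- matrix(0, n, M)
      if (!is.null(sb)) {
        sp_ <- sys$smp
        sddS <- 2 * sp_$rhoM^2 * (1 + sp_$rhoM * sb$DkS) / sb$uS^3
        A1[, sp_$i] <- w * (sb$sdelS * sb$DeltaS)
        A2[, sp_$i] <- w * (sb$nzS * (sddS * sb$DeltaS^2 + sb$sdelS * sb$DeltaS))
      }
      for (m in sys$gen_idx) {
        sm <- st[[m]]
        A1[, m] <- w * sm$sdel * sm$delta                 # nu_m x gamma_m
        A2[, m] <- w * nz[[m]] * (sm$sdd * sm$delta^2 + sm$sdel * sm$delta)
      }
      Zall2 <- cbind(sys$Zall, sys$Zall)
      B12 <- crossprod(sys$Zall, Zall2 * cbind(A1, A2)[, c(sys$modidx, M + sys$modidx)])
      for (m in seq_len(M)) {
        cols <- which(sys$modidx == m)
        inu <- idx$nu[[m]]; iga <- idx$gamma[[m]]
        blk1 <- B12[cols, cols, drop = FALSE]
        H[inu, iga] <- H[inu, iga] - blk1
        H[iga, inu] <- H[iga, inu] - t(blk1)
        blk2 <- B12[cols, sys$G + cols, drop = FALSE]
        H[iga, iga] <- H[iga, iga] - blk2
      }
      for (k in seq_len(K)) {
        A3 <- matrix(0, n, M); A4 <- matrix(0, n, M)
        touched <- FALSE
        if (!is.null(sb) && any(sys$smp$cls == k)) {
          sp_ <- sys$smp
          loc <- which(sp_$cls == k)
          sDdS <- -sp_$rhoM[, loc, drop = FALSE]^2 / sb$uS[, loc, drop = FALSE]^2
          A3[, sp_$i[loc]] <- w * (sb$sDS[, loc, drop = FALSE] *
                                     sb$DkS[, loc, drop = FALSE])
          A4[, sp_$i[loc]] <- w * (sb$nzS[, loc, drop = FALSE] * sDdS *
                                     sb$DkS[, loc, drop = FALSE] *
                                     sb$DeltaS[, loc, drop = FALSE])
          touched <- TRUE
        }
        for (m in sys$gen_idx) {
          a <- match(k, sys$models[[m]]$ks)
          if (is.na(a)) next
          touched <- TRUE
          sm <- st[[m]]
          A3[, m] <- w * sm$sD[, a] * Dm[, k]             # nu_m x (tau_k, theta_k)
          A4[, m] <- w * nz[[m]] * sm$sDd[, a] * Dm[, k] * sm$delta
        }
        if (!touched) next
        tk_idx <- c(idx$tau[k], idx$theta[(k - 1) * sys$p + seq_len(sys$p)])
        B34 <- crossprod(V1, Zall2 * cbind(A3, A4)[, c(sys$modidx, M + sys$modidx)])
        blk3 <- t(B34[, seq_len(sys$G), drop = FALSE])    # G x (p+1)
        H[sys$nu_all, tk_idx] <- H[sys$nu_all, tk_idx] - blk3
        H[tk_idx, sys$nu_all] <- H[tk_idx, sys$nu_all] - t(blk3)
        blk4 <- B34[, sys$G + seq_len(sys$G), drop = FALSE]  # (p+1) x G
        H[tk_idx, sys$gamma_all] <- H[tk_idx, sys$gamma_all] - blk4
        H[sys$gamma_all, tk_idx] <- H[sys$gamma_all, tk_idx] - t(blk4)
      }
    }
    if (length(r)) H[sys$beta_eta, sys$beta_eta] <- H[sys$beta_eta, sys$beta_eta] - W
    for (j in seq_along(sys$irr)) {
      H[sys$xi_idx, sys$xi_idx] <- H[sys$xi_idx, sys$xi_idx] -
        crossprod(sys$irr[[j]]$C, Wirr[[j]] %*% sys$irr[[j]]$C)
    }
    out$hess <- H
  }
  out
}

# Newton-Raphson on the full score of the profiled objective. The stationary
# point is a saddle (convex in the multipliers, concave in mu), so steps are
# safeguarded by feasibility and score-norm decrease rather than ascent.
# The Hessian is reused across iterations (chord steps) while the score
# contracts fast, and refreshed when contraction slows.
newton_saddle <- function(eta0, sys, W, Wirr = NULL, tol = 1e-8, max_iter = 100L) {
  eta <- eta0
  ev <- el_eval(eta, sys, W, Wirr, what = c("grad", "hess"))
  H <- ev$hess; H_fresh <- TRUE
  for (it in seq_len(max_iter)) {
    gmax <- max(abs(ev$grad))
    pg_log("debug", "Newton iter %d: |score| = %.3g", it, gmax)
    if (gmax < tol || (it > 6L && gmax < 2e-10 * sys$n)) {
      return(list(eta = eta, eval = ev, iterations = it, score_norm = gmax))
    }
    step <- tryCatch(solve(H, -ev$grad), error = function(e)
      pg_stop("convergence", "singular Hessian in Newton solve: %s", conditionMessage(e)))
    if (max(abs(step)) < 1e-12) {           # parameter change below precision
      return(list(eta = eta, eval = ev, iterations = it, score_norm = gmax))
    }
    t_ <- 1; ok <- FALSE
    g0 <- sqrt(sum(ev$grad^2))
    for (h in 1:40) {
      cand <- eta + t_ * step
      ev_new <- el_eval(cand, sys, W, Wirr, what = "grad", feas_error = FALSE)
      if (!is.null(ev_new) && all(is.finite(ev_new$grad)) &&
          sqrt(sum(ev_new$grad^2)) <= (1 - 1e-4 * t_) * g0) {
        ok <- TRUE; break
      }
      t_ <- t_ / 2
    }
    if (!ok) {
      if (!H_fresh) {                       # stale chord Hessian: refresh, retry
        ev <- el_eval(eta, sys, W, Wirr, what = c("grad", "hess"))
        H <- ev$hess; H_fresh <- TRUE
        next
      }
      # score decrease exhausted: accept if at the accumulation floor of an
      # n-term sum, else report failure
      if (gmax < 2e-10 * sys$n) {
        return(list(eta = eta, eval = ev, iterations = it, score_norm = gmax))
      }
      pg_stop("convergence",
              "step-halving lost feasibility/score decrease at iteration %d (|score| = %.3g)",
              it, g0)
    }
    eta <- cand; ev <- ev_new
    if (sqrt(sum(ev$grad^2)) > 0.15 * g0 || t_ < 1) {
      ev <- el_eval(eta, sys, W, Wirr, what = c("grad", "hess"))
      H <- ev$hess; H_fresh <- TRUE
    } else {
      H_fresh <- FALSE
    }
  }
  if (max(abs(ev$grad)) < 2e-10 * sys$n) {
    return(list(eta = eta, eval = ev, iterations = max_iter,
                score_norm = max(abs(ev$grad))))
  }
  pg_stop("convergence", "score equations not solved in %d iterations (last |score| = %.3g)",
          max_iter, max(abs(ev$grad)))
}

#' Empirical control-distribution weights
#'
#' \eqn{\hat p_i = n^{-1} / \{1+\sum_k\lambda_k(\Delta_{ki}-1)+\nu^\top
#' g(X_i;\mu)\}}. At a solution of the score equations these satisfy
#' \eqn{\sum_i \hat p_i = 1}, \eqn{\sum_i \hat p_i\Delta_k = 1} and
#' \eqn{\sum_i \hat p_i g = 0}.
#'
#' @param fit a converged \code{"polygim_fit"} from [fit_polygim()].
#' @return numeric vector of weights over the internal subjects.
#' @export
empirical_weights <- function(fit) fit$p_hat

# Constraint diagnostics at a converged solution.
constraint_check <- function(ev, sys) {
  p <- ev$phat
  out <- c(sum_p = sum(p) - 1,
           vapply(seq_len(sys$K), function(k) sum(p * ev$Dm[, k]) - 1, numeric(1)))
  for (m in seq_along(sys$models)) {
    gm <- sys$models[[m]]$Z * ev$st[[m]]$s
    out <- c(out, drop(crossprod(gm, p)))
  }
  out
}
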