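# PolyGIM estimators: regular integration (profiled EL with Lagrange
# multipliers), irregular integration (penalized internal likelihood on the
# theta contrast), and the restricted-MLE comparator.

polygim_control <- function(tol = 1e-8, max_iter = 100L,
                            vloop_tol = 1e-6, vloop_max = 20L) {
  list(tol = tol, max_iter = max_iter, vloop_tol = vloop_tol, vloop_max = vloop_max)
}

# Within-outcome-stratum empirical covariance of per-subject score
# contributions: the variability matrix of the retrospective (stratified)
# design. Rows of S are subject contributions; y gives the stratum.
stratified_score_cov <- function(S, y) {
  Om <- matrix(0, ncol(S), ncol(S))
  for (k in unique(y)) {
    rows <- S[y == k, , drop = FALSE]
    if (nrow(rows) > 1L) {
      Om <- Om + crossprod(scale(rows, center = TRUE, scale = FALSE))
    }
  }
  Om
}

split_summaries <- function(summaries, target, data) {
  if (is.null(summaries) || !length(summaries$entries)) {
    return(list(regular = list(), irregular = list(), flags = character(0)))
  }
  flags <- vapply(summaries$entries, function(e)
    classify_regularity(e$model, target, data), character(1))
  names(flags) <- vapply(summaries$entries, function(e) e$model$id, character(1))
  list(regular = summaries$entries[flags == "regular"],
       irregular = summaries$entries[flags == "irregular"],
       flags = flags)
}

#' Fit the polytomous model integrating external summary data
#'
#' Implements the integrated empirical-likelihood estimator. Regular summary
#' data (grouped case-control models, and case-case models whose features
#' differ from the target's) enter through Lagrange-multiplier constraints on
#' the estimated control distribution plus a quadratic penalty on the
#' reported coefficients; irregular summary data (case-case models consistent
#' with the target model) enter through a quadratic penalty on the
#' corresponding coefficient contrasts. The penalty matrix \eqn{V} is chosen
#' by \code{policy}:
#' \describe{
#'   \item{\code{"optimal"}}{iteratively replaces \eqn{V} by the estimated
#'     covariance of the summary statistics (the asymptotically efficient
#'     choice), re-solving until the estimate stabilizes.}
#'   \item{\code{"identity"}}{\eqn{V = I}.}
#'   \item{\code{"sigma"}}{diagonal \eqn{V} from the reported squared
#'     standard errors.}
#' }
#'
#' @param data an [internal_data()] object.
#' @param summaries a [summary_data()] object (may be empty or \code{NULL}).
#' @param target a [target_model()] spec.
#' @param policy penalty-matrix policy; see above.
#' @param control solver settings from \code{polygim_control()}.
#' @param mle optional precomputed internal-data MLE (reused for
#'   initialization when several estimators are fitted to the same data).
#' @return A \code{"polygim_fit"} with the fitted \code{xi} (\code{tau},
#'   \code{theta}), working-model coefficients \code{gammas}, multipliers
#'   \code{lambda} and \code{nu}, empirical weights \code{p_hat}, sandwich
#'   covariance \code{cov_mu} (and its \code{cov_xi} block), the covariance
#'   of the summary statistics \code{sigma_beta}, per-model regularity flags,
#'   iteration counts and the method label.
#' @references The estimator maximizes the profiled objective
#'   \eqn{\ell_V(\eta)} combining the retrospective empirical likelihood of
#'   the internal study with the summary-data quasi-likelihood.
#' @export
fit_polygim <- function(data, summaries = NULL, target = target_model(data$K),
                        policy = c("optimal", "identity", "sigma"),
                        control = polygim_control(), mle = NULL) {
  policy <- match.arg(policy)
  parts <- split_summaries(summaries, target, data)
  if (!length(parts$regular)) {
    if (!length(parts$irregular)) {
      # no summary information at all: the estimator reduces to the MLE
      fit <- mle %||% fit_plr_mle(data, target, tol = control$tol, max_iter = control$max_iter)
      fit$method <- method_label(policy)
      fit$regularity <- parts$flags
      Dm <- delta_matrix(build_features(data$x, target), fit$xi, data$K)
      fit$p_hat <- retrospective_weights(Dm, data)
      fit$lambda <- data$class_counts[-1] / data$n
      fit$nu <- numeric(0)
      return(fit)
    }
    fit <- fit_irregular(data, summaries, target = target, policy = policy,
                         control = control, mle = mle)
    fit$regularity <- parts$flags
    return(fit)
  }
  sys <- build_system(data, parts$regular, parts$irregular, target)
  K <- sys$K

  # --- Step 1: initialization -------------------------------------------
  mle <- mle %||% fit_plr_mle(data, target, tol = control$tol, max_iter = control$max_iter)
  eta <- numeric(sys$idx$P)
  eta[sys$idx$lambda] <- data$class_counts[-1] / data$n     # lambda* = rho_k/(1+sum rho)
  eta[sys$xi_idx] <- mle$xi
  for (m in seq_along(sys$models)) {
    ini <- init_nuisance(data, sys$models[[m]]$wm)
    eta[sys$idx$gamma[[m]]] <- c(ini$alpha, ini$beta)
  }

  state_cov <- function(eta_now, phat) {
    # joint Cov(beta~) over regular + irregular models at the current state
    models <- lapply(sys$models, function(m) list(wm = m$wm, Z = m$Z))
    gammas <- lapply(seq_along(sys$models), function(m) {
      gam <- eta_now[sys$idx$gamma[[m]]]
      nb <- length(sys$models[[m]]$wm$reported)
      list(alpha = gam[seq_len(length(gam) - nb)], beta = gam[length(gam) - nb + seq_len(nb)])
    })
    if (length(sys$irr)) {
      for (ir in sys$irr) {
        models <- c(models, list(list(wm = ir$wm, Z = working_design(ir$wm, data$x))))
        gammas <- c(gammas, list(implied_cc_gamma(ir$wm, eta_now[sys$xi_idx], sys, data)))
      }
    }
    Dm <- delta_matrix(sys$F, eta_now[sys$xi_idx], K)
    beta_cov_core(models, gammas, phat, Dm)$cov_beta
  }
  nreg_beta <- length(sys$beta_eta)
  irr_slice <- nreg_beta + seq_len(sum(vapply(sys$irr, function(i) length(i$beta_tilde), integer(1))))

  phat <- retrospective_weights(delta_matrix(sys$F, mle$xi, K), data)
  cov_beta <- state_cov(eta, phat)
  weights_from <- function(cov_beta) {
    if (policy == "optimal") {
      W <- safe_solve(cov_beta[seq_len(nreg_beta), seq_len(nreg_beta), drop = FALSE])
    } else {
      W <- penalty_weight(sys$models, policy)
    }
    Wirr <- NULL
    if (length(sys$irr)) {
      Wirr <- irr_weights(sys$irr, policy, cov_beta, irr_slice)
    }
    list(W = W, Wirr = Wirr)
  }
  ww <- weights_from(cov_beta)

  # --- Steps 2-5: solve; iterate V when optimal --------------------------
  sol <- newton_saddle(eta, sys, ww$W, ww$Wirr, tol = control$tol,
                       max_iter = control$max_iter)
  vhist <- numeric(0)
  if (policy == "optimal") {
    # intermediate re-solves use a relaxed score tolerance; once the V
    # iteration has stabilized the final solve polishes to full precision
    mid_tol <- max(control$tol, 1e-6)
    for (v in seq_len(control$vloop_max)) {
      cov_beta <- state_cov(sol$eta, sol$eval$phat)
      ww <- weights_from(cov_beta)
      sol_new <- newton_saddle(sol$eta, sys, ww$W, ww$Wirr, tol = mid_tol,
                               max_iter = control$max_iter)
      dmax <- max(abs(sol_new$eta - sol$eta))
      vhist <- c(vhist, dmax)
      pg_log("info", "V-loop iteration %d: max|delta eta| = %.3g", v, dmax)
      sol <- sol_new
      if (dmax < control$vloop_tol) break
    }
    if (length(vhist) && utils::tail(vhist, 1) >= control$vloop_tol) {
      pg_stop("convergence", "V iteration did not stabilize in %d rounds (history: %s)",
              control$vloop_max, paste(sprintf("%.2g", vhist), collapse = " "))
    }
    if (sol$score_norm >= control$tol) {
      sol <- newton_saddle(sol$eta, sys, ww$W, ww$Wirr, tol = control$tol,
                           max_iter = control$max_iter)
    }
  }

  # --- covariance: stratified sandwich ----------------------------------
  ev <- el_eval(sol$eta, sys, ww$W, ww$Wirr, what = c("grad", "hess", "scores"))
  Om <- stratified_score_cov(ev$scores, data$y)
  if (nreg_beta) {
    Sb <- cov_beta[seq_len(nreg_beta), seq_len(nreg_beta), drop = FALSE]
    Om[sys$beta_eta, sys$beta_eta] <- Om[sys$beta_eta, sys$beta_eta] +
      ww$W %*% Sb %*% ww$W
  }
  ioff <- 0L
  for (j in seq_along(sys$irr)) {
    nbj <- length(sys$irr[[j]]$beta_tilde)
    slj <- irr_slice[ioff + seq_len(nbj)]; ioff <- ioff + nbj
    Sbj <- cov_beta[slj, slj, drop = FALSE]
    CW <- crossprod(sys$irr[[j]]$C, ww$Wirr[[j]])
    Om[sys$xi_idx, sys$xi_idx] <- Om[sys$xi_idx, sys$xi_idx] + CW %*% Sbj %*% t(CW)
  }
  Hinv <- solve(ev$hess)
  cov_eta <- Hinv %*% Om %*% t(Hinv)
  cov_eta <- (cov_eta + t(cov_eta)) / 2

  finish_fit(sol, ev, sys, cov_eta, cov_beta, ww, parts$flags,
             method_label(policy), vloops = length(vhist), mle = mle)
}

method_label <- function(policy) {
  switch(policy, optimal = "GIM_opt", identity = "GIM_I", sigma = "GIM_Vsigma")
}

# gamma implied for an irregular CC working model by model consistency:
# alpha0 = tau_c1 - tau_c0, coefficients = theta_c1 - theta_c0 (mapped onto
# the working model's nuisance/reported feature order).
implied_cc_gamma <- function(wm, xi, sys, data) {
  sp <- xi_split(xi, sys$K, sys$p)
  fnames <- colnames(sys$F)
  dth <- sp$theta[wm$c1, ] - sp$theta[wm$c0, ]
  names(dth) <- fnames
  list(alpha = c(sp$tau[wm$c1] - sp$tau[wm$c0], unname(dth[wm$nuisance])),
       beta = unname(dth[wm$reported]))
}

irr_weights <- function(irr, policy, cov_beta, irr_slice) {
  # one stacked weight per irregular block from the joint Cov(beta~);
  # cross-block covariance between distinct irregular entries is kept when
  # they come from the same study via the joint matrix ordering
  off <- 0L
  lapply(irr, function(ir) {
    nb <- length(ir$beta_tilde)
    sl <- irr_slice[off + seq_len(nb)]; off <<- off + nb
    if (policy == "optimal") safe_solve(cov_beta[sl, sl, drop = FALSE])
    else if (policy == "identity") diag(ir$wm$N, nb)
    else {
      if (is.null(ir$se)) pg_stop("config", "V-sigma policy requires reported SEs (model '%s')", ir$wm$id)
      diag(1 / ir$se^2, nb)
    }
  })
}

finish_fit <- function(sol, ev, sys, cov_eta, cov_beta, ww, flags, method,
                       vloops, mle = NULL) {
  K <- sys$K; p <- sys$p
  xi <- sol$eta[sys$xi_idx]
  nm <- xi_names(K, colnames(sys$F))
  names(xi) <- nm
  sp <- xi_split(xi, K, p)
  gammas <- list()
  for (m in seq_along(sys$models)) {
    wm <- sys$models[[m]]$wm
    gam <- sol$eta[sys$idx$gamma[[m]]]
    nb <- length(wm$reported)
    gammas[[wm$id]] <- list(alpha = gam[seq_len(length(gam) - nb)],
                            beta = gam[length(gam) - nb + seq_len(nb)])
  }
  mu_idx <- sys$mu_idx
  cov_mu <- cov_eta[mu_idx, mu_idx, drop = FALSE]
  cov_xi <- cov_eta[sys$xi_idx, sys$xi_idx, drop = FALSE]
  dimnames(cov_xi) <- list(nm, nm)
  structure(list(
    xi = xi, tau = sp$tau, theta = sp$theta, feature_names = colnames(sys$F),
    K = K, gammas = gammas,
    lambda = sol$eta[sys$idx$lambda],
    nu = sol$eta[unlist(sys$idx$nu)],
    eta = sol$eta, p_hat = ev$phat,
    cov_mu = cov_mu, cov_xi = cov_xi, sigma_beta = cov_beta,
    v_used = ww$W, loglik = ev$value,
    iterations = sol$iterations, v_iterations = vloops,
    constraints = constraint_check(ev, sys),
    regularity = flags, method = method,
    data = sys$data, target = sys$target, mle = mle),
    class = "polygim_fit")
}

#' Fit with irregular (consistent case-case) summary data
#'
#' For case-case working models consistent with the target model the
#' constraint function vanishes identically and the summary data enter
#' through a quadratic penalty on the coefficient contrast:
#' \eqn{\ell'_V(\xi) = \ell_1(\xi) - \frac{N}{2}(\theta_{c_1}-\theta_{c_0}-
#' \tilde\beta)^\top V^{-1}(\theta_{c_1}-\theta_{c_0}-\tilde\beta)}, maximized
#' by damped Newton with the same iterative optimal-\eqn{V} loop.
#'
#' @inheritParams fit_polygim
#' @export
fit_irregular <- function(data, summaries, target = target_model(data$K),
                          policy = c("optimal", "identity", "sigma"),
                          control = polygim_control(), mle = NULL) {
  policy <- match.arg(policy)
  entries <- summaries$entries
  sys <- build_system(data, list(), entries, target)
  if (!length(sys$irr)) pg_stop("config", "no summary entries supplied")
  F <- sys$F; Y <- sys$Y; K <- sys$K; p <- sys$p
  Cs <- lapply(sys$irr, `[[`, "C")
  bts <- lapply(sys$irr, `[[`, "beta_tilde")

  cov_beta_at <- function(xi) {
    models <- lapply(sys$irr, function(ir) list(wm = ir$wm, Z = working_design(ir$wm, data$x)))
    gammas <- lapply(sys$irr, function(ir) implied_cc_gamma(ir$wm, xi, sys, data))
    Dm <- delta_matrix(F, xi, K)
    beta_cov_core(models, gammas, retrospective_weights(Dm, data), Dm)$cov_beta
  }
  irr_slice_all <- seq_len(sum(lengths(bts)))
  weights_from <- function(cov_beta) irr_weights(sys$irr, policy, cov_beta, irr_slice_all)

  solve_pen <- function(xi0, Wirr) {
    xi <- xi0
    for (it in seq_len(control$max_iter)) {
      sc <- plr_score_hess(xi, F, Y, data$rho)
      g <- sc$grad; H <- sc$hess; penv <- 0
      for (j in seq_along(Cs)) {
        rj <- drop(Cs[[j]] %*% xi) - bts[[j]]
        g <- g - drop(crossprod(Cs[[j]], Wirr[[j]] %*% rj))
        H <- H - crossprod(Cs[[j]], Wirr[[j]] %*% Cs[[j]])
        penv <- penv + 0.5 * drop(crossprod(rj, Wirr[[j]] %*% rj))
      }
      if (max(abs(g)) < max(control$tol, if (it > 3) 2e-10 * data$n else 0)) {
        return(list(xi = xi, grad = g, hess = H, loglik = sc$loglik - penv,
                    iterations = it))
      }
      step <- solve(H, -g)
      obj0 <- sc$loglik - penv
      t_ <- 1
      repeat {
        cand <- xi + t_ * step
        sc2 <- plr_score_hess(cand, F, Y, data$rho, hess = FALSE)
        pen2 <- 0
        for (j in seq_along(Cs)) {
          rj <- drop(Cs[[j]] %*% cand) - bts[[j]]
          pen2 <- pen2 + 0.5 * drop(crossprod(rj, Wirr[[j]] %*% rj))
        }
        if (is.finite(sc2$loglik) && sc2$loglik - pen2 >= obj0 - 1e-12) break
        t_ <- t_ / 2
        if (t_ < 1e-10) pg_stop("convergence", "penalized Newton step-halving failed")
      }
      xi <- cand
    }
    pg_stop("convergence", "irregular fit did not converge in %d iterations", control$max_iter)
  }

  mle <- mle %||% fit_plr_mle(data, target, tol = control$tol, max_iter = control$max_iter)
  cov_beta <- cov_beta_at(mle$xi)
  Wirr <- weights_from(cov_beta)
  sol <- solve_pen(mle$xi, Wirr)
  vloops <- 0L
  if (policy == "optimal") {
    for (v in seq_len(control$vloop_max)) {
      cov_beta <- cov_beta_at(sol$xi)
      Wirr <- weights_from(cov_beta)
      sol_new <- solve_pen(sol$xi, Wirr)
      dmax <- max(abs(sol_new$xi - sol$xi))
      sol <- sol_new; vloops <- v
      pg_log("info", "V-loop iteration %d: max|delta xi| = %.3g", v, dmax)
      if (dmax < control$vloop_tol) break
      if (v == control$vloop_max) {
        pg_stop("convergence", "V iteration did not stabilize in %d rounds", v)
      }
    }
  }
  # stratified sandwich on the penalized score
  S <- plr_score_contribs(sol$xi, F, Y, data$rho)
  Om <- stratified_score_cov(S, data$y)
  off <- 0L
  for (j in seq_along(Cs)) {
    nb <- length(bts[[j]])
    Sbj <- cov_beta[off + seq_len(nb), off + seq_len(nb), drop = FALSE]; off <- off + nb
    CW <- crossprod(Cs[[j]], Wirr[[j]])
    Om <- Om + CW %*% Sbj %*% t(CW)
  }
  Hinv <- solve(sol$hess)
  cov_xi <- Hinv %*% Om %*% t(Hinv)
  cov_xi <- (cov_xi + t(cov_xi)) / 2
  nm <- xi_names(K, colnames(F))
  xi <- sol$xi; names(xi) <- nm
  dimnames(cov_xi) <- list(nm, nm)
  sp <- xi_split(xi, K, p)
  Dm <- delta_matrix(F, xi, K)
  structure(list(
    xi = xi, tau = sp$tau, theta = sp$theta, feature_names = colnames(F),
    K = K, gammas = stats::setNames(
      lapply(sys$irr, function(ir) implied_cc_gamma(ir$wm, xi, sys, data)),
      vapply(sys$irr, function(ir) ir$wm$id, character(1))),
    lambda = data$class_counts[-1] / data$n, nu = numeric(0),
    p_hat = retrospective_weights(Dm, data),
    cov_mu = cov_xi, cov_xi = cov_xi, sigma_beta = cov_beta,
    v_used = Wirr, loglik = sol$loglik,
    iterations = sol$iterations, v_iterations = vloops,
    method = method_label(policy), route = "irregular",
    data = data, target = target, mle = mle),
    class = "polygim_fit")
}

# Per-subject score contributions of l1 (n x dim(xi)), xi layout.
plr_score_contribs <- function(xi, F, Y, rho) {
  K <- length(rho); p <- ncol(F)
  D <- delta_matrix(F, xi, K)
  P <- sweep(D, 2, rho, "*") / (1 + drop(D %*% rho))
  R <- Y - P
  S <- matrix(0, nrow(F), K + K * p)
  S[, seq_len(K)] <- R
  for (k in seq_len(K)) S[, K + (k - 1) * p + seq_len(p)] <- F * R[, k]
  S
}

#' Restricted maximum likelihood under consistent case-case summary data
#'
#' Maximizes the internal profile likelihood \eqn{\ell_1(\xi)} subject to the
#' hard constraints \eqn{\theta_{c_1}-\theta_{c_0} = \tilde\beta} for each
#' irregular case-case block. Because \eqn{\tilde\beta} is itself an
#' estimate, the reported covariance propagates its uncertainty:
#' \eqn{Cov(\hat\xi) = E\,\Omega\,E^\top + Fm\,Cov(\tilde\beta)\,Fm^\top}
#' with \eqn{(E, Fm)} blocks of the inverse KKT matrix. The covariance
#' without the propagation term is stored as \code{cov_xi_noprop} for
#' comparison.
#'
#' @inheritParams fit_polygim
#' @export
fit_rmle <- function(data, summaries, target = target_model(data$K),
                     control = polygim_control(), mle = NULL) {
  entries <- summaries$entries
  sys <- build_system(data, list(), entries, target)
  if (!length(sys$irr)) pg_stop("config", "RMLE requires irregular case-case summary data")
  F <- sys$F; Y <- sys$Y; K <- sys$K; p <- sys$p
  C <- do.call(rbind, lapply(sys$irr, `[[`, "C"))
  bt <- unlist(lapply(sys$irr, `[[`, "beta_tilde"), use.names = FALSE)
  q <- nrow(C); dxi <- K + K * p
  if (q >= dxi) pg_stop("config", "constraint dimension (%d) >= parameter dimension (%d)", q, dxi)
  mle <- mle %||% fit_plr_mle(data, target, tol = control$tol, max_iter = control$max_iter)
  xi <- mle$xi; psi <- numeric(q)
  kkt_res <- function(xi, psi) {
    sc <- plr_score_hess(xi, F, Y, data$rho)
    list(sc = sc, r = c(sc$grad - drop(crossprod(C, psi)), drop(C %*% xi) - bt))
  }
  st <- kkt_res(xi, psi)
  for (it in seq_len(control$max_iter)) {
    if (max(abs(st$r[seq_len(dxi)])) < control$tol &&
        max(abs(st$r[dxi + seq_len(q)])) < 1e-10) break
    Mk <- rbind(cbind(st$sc$hess, -t(C)), cbind(C, matrix(0, q, q)))
    stepv <- solve(Mk, -st$r)
    t_ <- 1; r0 <- sqrt(sum(st$r^2))
    repeat {
      xin <- xi + t_ * stepv[seq_len(dxi)]
      psin <- psi + t_ * stepv[dxi + seq_len(q)]
      stn <- tryCatch(kkt_res(xin, psin), error = function(e) NULL)
      if (!is.null(stn) && all(is.finite(stn$r)) && sqrt(sum(stn$r^2)) <= (1 - 1e-4 * t_) * r0) break
      t_ <- t_ / 2
      if (t_ < 1e-10) pg_stop("convergence", "RMLE step-halving failed at iteration %d", it)
    }
    xi <- xin; psi <- psin; st <- stn
    if (it == control$max_iter) pg_stop("convergence", "RMLE did not converge in %d iterations", it)
  }
  sc <- st$sc
  # covariance via KKT sensitivity: res_g = grad - C'psi, res_c = C xi - beta~;
  # d xi = -E d(grad) + Fm d(beta~) with (E, Fm) blocks of the inverse Jacobian
  Mk <- rbind(cbind(sc$hess, -t(C)), cbind(C, matrix(0, q, q)))
  Minv <- solve(Mk)
  E <- Minv[seq_len(dxi), seq_len(dxi), drop = FALSE]
  Fm <- Minv[seq_len(dxi), dxi + seq_len(q), drop = FALSE]
  S <- plr_score_contribs(xi, F, Y, data$rho)
  Om <- stratified_score_cov(S, data$y)
  models <- lapply(sys$irr, function(ir) list(wm = ir$wm, Z = working_design(ir$wm, data$x)))
  gammas <- lapply(sys$irr, function(ir) implied_cc_gamma(ir$wm, xi, sys, data))
  Dm <- delta_matrix(F, xi, K)
  cov_beta <- beta_cov_core(models, gammas, retrospective_weights(Dm, data), Dm)$cov_beta
  # dxi = E (-d grad) + Fm d beta~ ; the two sources are independent
  cov_core <- E %*% Om %*% t(E)
  cov_xi <- cov_core + Fm %*% cov_beta %*% t(Fm)
  cov_xi <- (cov_xi + t(cov_xi)) / 2
  nm <- xi_names(K, colnames(F))
  names(xi) <- nm; dimnames(cov_xi) <- list(nm, nm)
  sp <- xi_split(xi, K, p)
  structure(list(
    xi = xi, tau = sp$tau, theta = sp$theta, feature_names = colnames(F),
    K = K, lambda = data$class_counts[-1] / data$n, nu = numeric(0),
    p_hat = retrospective_weights(Dm, data),
    cov_mu = cov_xi, cov_xi = cov_xi,
    cov_xi_noprop = (cov_core + t(cov_core)) / 2,
    sigma_beta = cov_beta,
    constraint_gap = drop(C %*% xi) - bt,
    loglik = sc$loglik, iterations = it, method = "RMLE",
    data = data, target = target, mle = mle),
    class = "polygim_fit")
}

#' Profiled joint log-likelihood
#'
#' Evaluates \eqn{\ell_V(\eta)} at a given parameter state, mainly for
#' diagnostics and testing. \code{eta} is a list with components
#' \code{lambda}, \code{nu} (list per regular working model), \code{xi}, and
#' \code{gammas} (list per regular working model, each \code{c(alpha, beta)}).
#'
#' @param eta parameter state list (see details).
#' @param data an [internal_data()] object.
#' @param summaries a [summary_data()] object.
#' @param target a [target_model()] spec.
#' @param policy penalty policy for the weight matrix, or supply \code{W}.
#' @param W optional explicit penalty weight matrix on the stacked reported
#'   coefficients (overrides \code{policy}).
#' @param cov_beta joint Cov of summary statistics (needed for
#'   \code{policy = "optimal"}).
#' @return scalar value of the profiled objective.
#' @export
joint_profile_loglik <- function(eta, data, summaries, target = target_model(data$K),
                                 policy = "identity", W = NULL, cov_beta = NULL) {
  parts <- split_summaries(summaries, target, data)
  sys <- build_system(data, parts$regular, parts$irregular, target)
  ev <- el_eval(flatten_eta(eta, sys), sys,
                W %||% penalty_weight(sys$models, policy, cov_beta),
                Wirr = if (length(sys$irr)) irr_weights(sys$irr, policy, cov_beta,
                                                        seq_len(sum(vapply(sys$irr, function(i) length(i$beta_tilde), integer(1))))),
                what = character(0))
  ev$value
}

#' Solve the score equations of the profiled objective
#'
#' Newton-Raphson on the stationarity system of \eqn{\ell_V(\eta)} from a
#' feasible start, for a fixed penalty weight. Used directly in testing; end
#' users should call [fit_polygim()], which also initializes and iterates
#' \eqn{V}.
#'
#' @inheritParams joint_profile_loglik
#' @param eta0 starting state (list form; see [joint_profile_loglik()]).
#' @param control solver settings.
#' @return the converged state in list form, with attribute
#'   \code{"score_norm"}.
#' @export
solve_score_equations <- function(eta0, data, summaries, target = target_model(data$K),
                                  policy = "identity", W = NULL, cov_beta = NULL,
                                  control = polygim_control()) {
  parts <- split_summaries(summaries, target, data)
  sys <- build_system(data, parts$regular, parts$irregular, target)
  W <- W %||% penalty_weight(sys$models, policy, cov_beta)
  Wirr <- if (length(sys$irr)) irr_weights(sys$irr, policy, cov_beta,
                                           seq_len(sum(vapply(sys$irr, function(i) length(i$beta_tilde), integer(1)))))
  sol <- newton_saddle(flatten_eta(eta0, sys), sys, W, Wirr,
                       tol = control$tol, max_iter = control$max_iter)
  out <- unflatten_eta(sol$eta, sys)
  attr(out, "score_norm") <- sol$score_norm
  out
}

flatten_eta <- function(eta, sys) {
  if (is.numeric(eta)) return(eta)
  v <- numeric(sys$idx$P)
  v[sys$idx$lambda] <- eta$lambda
  v[sys$xi_idx] <- eta$xi
  for (m in seq_along(sys$models)) {
    v[sys$idx$nu[[m]]] <- eta$nu[[m]] %||% numeric(length(sys$idx$nu[[m]]))
    v[sys$idx$gamma[[m]]] <- eta$gammas[[m]]
  }
  v
}

unflatten_eta <- function(v, sys) {
  list(lambda = v[sys$idx$lambda],
       nu = lapply(sys$idx$nu, function(i) v[i]),
       xi = v[sys$xi_idx],
       gammas = lapply(sys$idx$gamma, function(i) v[i]))
}
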