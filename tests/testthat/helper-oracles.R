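# Independent oracles used across the test suite. These deliberately avoid
# the package's internal computation paths: hand-coded IRLS, direct Bayes
# enumeration over the discrete two-marker population, numerical
# differentiation, and a primal (p, mu) constrained optimizer.

# --- hand-coded IRLS for weighted logistic regression ---------------------
irls_logistic <- function(Z, D, w = rep(1, length(D)), tol = 1e-12) {
  beta <- numeric(ncol(Z))
  for (i in 1:100) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    step <- solve(crossprod(Z * W, Z), crossprod(Z, w * (D - mu)))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- central differences --------------------------------------------------
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

fd_jacobian <- function(f, x, h = 1e-6) {
  # rows index f components, columns index x components
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, f(x))
}

# --- exact facts about the two-marker population --------------------------
# Joint cells, prospective truth and implied retrospective quantities,
# written directly from the design's definition.
tm_population <- function(des = two_marker_design()) {
  cells <- des$cells
  lin <- sweep(cells %*% t(des$theta), 2, des$omega, "+")
  e <- exp(lin)
  post <- cbind(1, e) / (1 + rowSums(e))          # P(Y = k | x)
  joint <- post * des$probs                       # P(x, Y = k)
  pk <- colSums(joint)                            # P(Y = k)
  cond <- sweep(joint, 2, pk, "/")                # P(x | Y = k)
  tau_star <- des$omega + log(pk[1] / pk[-1])
  list(cells = cells, probs = des$probs, post = post, cond = cond,
       pk = pk, tau_star = tau_star, theta_star = des$theta,
       xi_star = c(tau_star, t(des$theta)))
}

# Population working-model solution: solves the stochastic constraint
# equation E_{D=0}[phi0] + rho E_{D=1}[phi1] = 0 over the 4 cells by Newton
# with numerical Jacobian. P0/P1 are the covariate distributions in the
# external D = 0 / D = 1 groups; Zc the working design on the cells.
solve_population_gamma <- function(Zc, P0, P1, rho, start = numeric(ncol(Zc))) {
  ee <- function(gam) {
    h <- 1 / (1 + exp(-drop(Zc %*% gam) - log(rho)))  # rho*delta/(1+rho*delta)
    drop(crossprod(Zc, -P0 * h) + rho * crossprod(Zc, P1 * (1 - h))) / rho
  }
  gam <- start
  for (i in 1:100) {
    r <- ee(gam)
    if (max(abs(r)) < 1e-13) break
    J <- fd_jacobian(ee, gam, h = 1e-7)
    gam <- gam - solve(J, r)
  }
  gam
}

# --- primal constrained-optimization oracle -------------------------------
# Solves the integrated-likelihood optimization directly over the empirical
# control masses (one per distinct covariate cell) and mu, with equality
# constraints, by augmented Lagrangian followed by a KKT Newton polish using
# numerical derivatives only. Supports one working model (CC or GC) with the
# identity penalty V = I.
primal_el_oracle <- function(data, entry, target) {
  wm <- entry$model; bt <- entry$beta
  F <- data$x
  K <- data$K
  key <- apply(F, 1, paste, collapse = ",")
  cells <- F[!duplicated(key), , drop = FALSE]
  cid <- match(key, unique(key))
  cnt <- tabulate(cid, nbins = nrow(cells))
  J <- nrow(cells)
  Y <- matrix(0, data$n, K)
  Y[cbind(which(data$y > 0), data$y[data$y > 0])] <- 1
  Zc <- cbind(1, cells[, c(wm$nuisance, wm$reported), drop = FALSE])
  nb <- length(wm$reported)
  dg <- 1 + length(wm$nuisance) + nb
  Dm_at <- function(xi) {
    tau <- xi[1:K]
    th <- matrix(xi[-(1:K)], K, ncol(F), byrow = TRUE)
    exp(sweep(cells %*% t(th), 2, tau, "+"))
  }
  g_at <- function(xi, gam) {
    Dm <- Dm_at(xi)
    delta <- exp(drop(Zc %*% gam))
    u <- 1 + wm$rho * delta
    if (wm$kind == "gc") {
      Zc * (wm$rho * (drop(Dm %*% wm$q) - delta) / u)
    } else {
      Zc * (wm$rho * (Dm[, wm$c1] - delta * Dm[, wm$c0]) / u)
    }
  }
  dxi <- K + K * ncol(F)
  np <- J + dxi + dg
  nc <- 1 + K + dg
  objective <- function(par) {
    lm_ <- par[1:J]; xi <- par[J + (1:dxi)]; gam <- par[J + dxi + (1:dg)]
    tau <- xi[1:K]; th <- matrix(xi[-(1:K)], K, ncol(F), byrow = TRUE)
    DmF <- exp(sweep(F %*% t(th), 2, tau, "+"))
    sum(cnt * lm_) + sum(Y * log(DmF)) -
      (wm$N / 2) * sum((gam[dg - nb + seq_len(nb)] - bt)^2)
  }
  constr <- function(par) {
    m <- exp(par[1:J]); xi <- par[J + (1:dxi)]; gam <- par[J + dxi + (1:dg)]
    Dm <- Dm_at(xi)
    c(sum(cnt * m) - 1, colSums(cnt * m * Dm) - 1,
      drop(crossprod(g_at(xi, gam), cnt * m)))
  }
  # neutral start: uniform masses, internal MLE, weighted-logistic init
  mle <- fit_plr_mle(data, target)
  ini <- init_nuisance(data, wm)
  par <- c(rep(log(1 / data$n), J), unname(mle$xi), ini$alpha, ini$beta)
  lam <- numeric(nc); rho_pen <- 100
  for (outer in 1:2) {
    fn <- function(par) -objective(par) + sum(lam * constr(par)) +
      (rho_pen / 2) * sum(constr(par)^2)
    par <- stats::optim(par, fn, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-10))$par
    cv <- constr(par)
    lam <- lam + rho_pen * cv
    if (max(abs(cv)) < 1e-6) break
  }
  kkt <- function(z) {
    p_ <- z[1:np]; lm <- z[np + (1:nc)]
    c(-fd_grad(objective, p_) + drop(t(fd_jacobian(constr, p_)) %*% lm),
      constr(p_))
  }
  z <- c(par, lam)
  Jk <- NULL
  for (it in 1:60) {
    r <- kkt(z)
    if (max(abs(r)) < 1e-10) break
    # the KKT Jacobian varies slowly; rebuild it only every other iteration
    if (is.null(Jk) || it %% 3 == 1) Jk <- fd_jacobian(kkt, z, h = 1e-6)
    step <- solve(Jk, -r)
    t_ <- 1
    repeat {
      r2 <- kkt(z + t_ * step)
      if (all(is.finite(r2)) && sqrt(sum(r2^2)) <= sqrt(sum(r^2))) break
      t_ <- t_ / 2
      if (t_ < 1e-6) break
    }
    z <- z + t_ * step
  }
  list(mu = z[J + seq_len(dxi + dg)], kkt_resid = max(abs(kkt(z))),
       masses = exp(z[1:J]), cells = cells, cnt = cnt)
}

# Random positive definite matrix
random_psd <- function(k) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(0.1, k)
}
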