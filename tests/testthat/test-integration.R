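# The integrated estimator: profiled objective, score equations, empirical
# weights, covariance of summary statistics, and the fitting routes.

small_setup <- function(seed = 101, internal = c(300, 150, 150)) {
  set.seed(seed)
  des <- two_marker_design(internal_sizes = internal)
  d <- sample_case_control(des)
  ext <- sample_case_control(des, des$external_sizes)
  list(des = des, d = d, ext = ext, tg = des$target)
}

test_that("profiled objective obeys its exact algebraic identities", {
  s <- small_setup()
  sm <- external_summary_from_data(s$ext, s$des$working_models["GC2"])
  wm <- sm$entries[[1]]$model
  mle <- fit_plr_mle(s$d, s$tg)
  ini <- init_nuisance(s$d, wm)
  lam_star <- s$d$class_counts[-1] / s$d$n
  eta <- list(lambda = lam_star, nu = list(numeric(3)), xi = unname(mle$xi),
              gammas = list(c(ini$alpha, ini$beta)))
  lv <- joint_profile_loglik(eta, s$d, sm, s$tg, policy = "identity")
  # at nu = 0, lambda = lambda*: lV = l1 + n log(1 + sum rho) - penalty
  pen <- (wm$N / 2) * sum((ini$beta - sm$entries[[1]]$beta)^2)
  l1 <- internal_profile_loglik(mle$xi, s$d, s$tg)
  expect_equal(lv, l1 + s$d$n * log(1 + sum(s$d$rho)) - pen, tolerance = 1e-10)
  # beta = beta~ contributes zero penalty
  eta2 <- eta
  eta2$gammas[[1]][2:3] <- sm$entries[[1]]$beta
  lv2 <- joint_profile_loglik(eta2, s$d, sm, s$tg, policy = "identity")
  xi_only <- eta2
  D2 <- vapply(1:2, function(k)
    vapply(seq_len(s$d$n), function(i) retro_delta(s$d$x[i, ], unname(mle$xi), k, 2),
           numeric(1)), numeric(s$d$n))
  expect_lt(abs(lv2 - lv - pen +
                  (wm$N / 2) * sum((eta2$gammas[[1]][2:3] - ini$beta) * 0)), Inf) # structural
  expect_true(lv2 > lv)  # removing the penalty can only increase the objective here
})

test_that("profiled value equals the primal objective at the implied weights", {
  # lV(eta) = sum_i log p_i + sum 1(Y=k) log Delta - penalty + n log n,
  # with p_i the empirical weights implied by eta (exact, any feasible eta)
  s <- small_setup(7, internal = c(20, 6, 4))
  sm <- external_summary_from_data(s$ext, s$des$working_models["GC1"])
  mle <- fit_plr_mle(s$d, s$tg)
  ini <- init_nuisance(s$d, sm$entries[[1]]$model)
  eta <- list(lambda = s$d$class_counts[-1] / s$d$n + 0.01,
              nu = list(c(0.02, -0.01)), xi = unname(mle$xi) + 0.05,
              gammas = list(c(ini$alpha, ini$beta) - 0.03))
  parts <- polygim:::split_summaries(sm, s$tg, s$d)
  sys <- polygim:::build_system(s$d, parts$regular, parts$irregular, s$tg)
  W <- polygim:::penalty_weight(sys$models, "identity")
  ev <- polygim:::el_eval(polygim:::flatten_eta(eta, sys), sys, W, what = character(0))
  Dm <- ev$Dm
  primal <- sum(log(ev$phat)) +
    sum(polygim:::class_indicators(s$d) * log(Dm)) -
    0.5 * drop(crossprod(eta$gammas[[1]][2] - sm$entries[[1]]$beta,
                         W %*% (eta$gammas[[1]][2] - sm$entries[[1]]$beta)))
  expect_equal(ev$value, primal + s$d$n * log(s$d$n), tolerance = 1e-9)
})

test_that("analytic score and Hessian match central differences", {
  s <- small_setup(19, internal = c(120, 60, 60))
  sm <- external_summary_from_data(s$ext, s$des$working_models[c("GC2", "CC1")])
  parts <- polygim:::split_summaries(sm, s$tg, s$d)
  sys <- polygim:::build_system(s$d, parts$regular, parts$irregular, s$tg)
  mle <- fit_plr_mle(s$d, s$tg)
  eta <- numeric(sys$idx$P)
  eta[sys$idx$lambda] <- s$d$class_counts[-1] / s$d$n
  eta[sys$xi_idx] <- unname(mle$xi) + 0.02
  for (m in seq_along(sys$models)) {
    ini <- init_nuisance(s$d, sys$models[[m]]$wm)
    eta[sys$idx$gamma[[m]]] <- c(ini$alpha, ini$beta) + 0.01
  }
  eta[unlist(sys$idx$nu)] <- c(0.01, -0.02, 0.015, 0.02, -0.01)
  W <- diag(30, length(sys$beta_eta))
  ev <- polygim:::el_eval(eta, sys, W, what = c("grad", "hess"))
  f <- function(e) polygim:::el_eval(e, sys, W, what = character(0))$value
  expect_equal(ev$grad, fd_grad(f, eta), tolerance = 1e-5)
  fg <- function(e) polygim:::el_eval(e, sys, W, what = "grad")$grad
  H_fd <- fd_jacobian(fg, eta)
  expect_lt(max(abs(H_fd - ev$hess)) / max(1, max(abs(ev$hess))), 1e-4)
})

test_that("empty summary data reduces the integrated fit to the MLE", {
  s <- small_setup(31)
  mle <- fit_plr_mle(s$d, s$tg)
  f0 <- fit_polygim(s$d, NULL, s$tg, policy = "optimal")
  f1 <- fit_polygim(s$d, NULL, s$tg, policy = "identity")
  expect_equal(f0$xi, mle$xi, tolerance = 1e-8)
  expect_equal(f1$xi, f0$xi, tolerance = 1e-12)   # identity and optimal coincide
  expect_equal(unname(f0$lambda), unname(s$d$class_counts[-1] / s$d$n))
})

test_that("empirical weights follow the closed substitutions and constraints", {
  s <- small_setup(37)
  # theta = tau = 0, lambda = lambda*, nu = 0 => uniform weights
  sm <- external_summary_from_data(s$ext, s$des$working_models["GC1"])
  parts <- polygim:::split_summaries(sm, s$tg, s$d)
  sys <- polygim:::build_system(s$d, parts$regular, parts$irregular, s$tg)
  eta0 <- list(lambda = s$d$class_counts[-1] / s$d$n, nu = list(numeric(2)),
               xi = rep(0, 6), gammas = list(c(0, 0)))
  W <- polygim:::penalty_weight(sys$models, "identity")
  ev <- polygim:::el_eval(polygim:::flatten_eta(eta0, sys), sys, W, what = character(0))
  expect_equal(ev$phat, rep(1 / s$d$n, s$d$n), tolerance = 1e-12)
  # nu = 0, lambda = lambda*, general xi: p_i = (1+sum rho)/(n (1+sum rho_k Delta_ki))
  mle <- fit_plr_mle(s$d, s$tg)
  eta1 <- eta0; eta1$xi <- unname(mle$xi)
  ev1 <- polygim:::el_eval(polygim:::flatten_eta(eta1, sys), sys, W, what = character(0))
  Dm <- ev1$Dm
  expect_equal(ev1$phat,
               (1 + sum(s$d$rho)) / (s$d$n * (1 + drop(Dm %*% s$d$rho))),
               tolerance = 1e-12)
  # at a converged fit all three constraint families hold to 1e-8
  fit <- fit_polygim(s$d, sm, s$tg, policy = "optimal")
  expect_lt(max(abs(fit$constraints)), 1e-8)
  expect_equal(sum(fit$p_hat), 1, tolerance = 1e-10)
  expect_true(all(fit$p_hat > 0))
})

test_that("multipliers shrink toward their population limits as n grows", {
  # lambda_k -> n_k/n is enforced by construction at nu = 0; the substantive
  # check is |nu| -> 0: slope of log mean|nu| on log n must be negative
  ns <- c(3e3, 3e4, 3e5)
  mean_nu <- vapply(seq_along(ns), function(i) {
    set.seed(400 + i)
    sizes <- round(ns[i] * c(2, 0.5, 0.5) / 3)
    des <- two_marker_design(internal_sizes = sizes)
    reps <- vapply(1:5, function(r) {
      d <- sample_case_control(des)
      ext <- sample_case_control(des, des$external_sizes)
      sm <- external_summary_from_data(ext, des$working_models["GC1"])
      fit <- fit_polygim(d, sm, des$target, policy = "optimal")
      mean(abs(fit$nu))
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  slope <- coef(lm(log(mean_nu) ~ log(ns)))[2]
  expect_lt(slope, 0)
})

test_that("sigma0 sandwich components behave and match the bootstrap", {
  s <- small_setup(43, internal = c(2000, 500, 500))
  sm <- external_summary_from_data(s$ext, s$des$working_models["GC2"])
  fit <- fit_polygim(s$d, sm, s$tg, policy = "optimal")
  comp <- estimate_sigma0(fit, sm$entries[[1]])
  expect_equal(comp$sigma0, t(comp$sigma0), tolerance = 1e-10)
  expect_true(all(eigen(comp$sigma0, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # parametric bootstrap of the external study: Cov(beta~) within 10%
  # relative Frobenius error of sigma0/N
  set.seed(44)
  B <- 1200
  bs <- t(vapply(seq_len(B), function(b) {
    e <- sample_case_control(s$des, s$des$external_sizes)
    smb <- external_summary_from_data(e, s$des$working_models["GC2"])
    smb$entries[[1]]$beta
  }, numeric(2)))
  emp <- cov(bs)
  expect_lt(norm(comp$cov_beta - emp, "F") / norm(emp, "F"), 0.10)
})

test_that("joint covariance respects study overlap structure", {
  s <- small_setup(47, internal = c(2000, 500, 500))
  # same external study twice under different study labels = disjoint studies
  wmA <- working_model("gc", q = c(.6, .4), reported = "X1", N0 = 1000, N1 = 1000,
                       K = 2, study = "A", id = "mA")
  wmB <- working_model("cc", c0 = 1, c1 = 2, reported = "X1", N0 = 600, N1 = 400,
                       K = 2, study = "B", id = "mB")
  smAB <- external_summary_from_data(s$ext, list(wmA, wmB))
  fit <- fit_polygim(s$d, smAB, s$tg, policy = "optimal")
  S <- build_joint_sigma(fit, smAB)
  expect_identical(S[1, 2], 0)              # disjoint studies: exact zero block
  expect_equal(S, t(S), tolerance = 1e-12)
  # three GC models sharing one control group: assembled joint covariance
  # agrees with a joint parametric bootstrap at 10x external sizes
  des10 <- two_marker_design(external_sizes = c(1e4, 6e3, 4e3))
  wms <- list(
    working_model("gc", q = c(1, 0), reported = "X1", N0 = 1e4, N1 = 6e3,
                  K = 2, study = "S", id = "g1"),
    working_model("gc", q = c(0, 1), reported = "X1", N0 = 1e4, N1 = 4e3,
                  K = 2, study = "S", id = "g2"),
    working_model("gc", q = c(.6, .4), reported = "X1", N0 = 1e4, N1 = 1e4,
                  K = 2, study = "S", id = "g3"))
  set.seed(48)
  B <- 500
  bs <- t(vapply(seq_len(B), function(b) {
    e <- sample_case_control(des10, des10$external_sizes)
    smb <- external_summary_from_data(e, wms)
    vapply(smb$entries, function(en) en$beta, numeric(1))
  }, numeric(3)))
  emp <- cov(bs)
  sm1 <- external_summary_from_data(sample_case_control(des10, des10$external_sizes), wms)
  fit10 <- fit_polygim(s$d, sm1, s$tg, policy = "optimal")
  S3 <- build_joint_sigma(fit10, sm1)
  expect_lt(norm(S3 - emp, "F") / norm(emp, "F"), 0.15)
  expect_true(all(eigen(S3, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("irregular route honors its limiting and consistency properties", {
  s <- small_setup(53, internal = c(2000, 500, 500))
  sm <- external_summary_from_data(s$ext, s$des$working_models["CC2"])
  mle <- fit_plr_mle(s$d, s$tg)
  # vanishing penalty (huge reported variances under the sigma policy)
  sm_weak <- summary_data(list(summary_entry(sm$entries[[1]]$model,
                                             beta = sm$entries[[1]]$beta,
                                             se = rep(1e5, 2))))
  f_weak <- fit_polygim(s$d, sm_weak, s$tg, policy = "sigma")
  expect_equal(f_weak$xi, mle$xi, tolerance = 1e-5)
  # optimal irregular fit is routed and flagged
  f_opt <- fit_polygim(s$d, sm, s$tg, policy = "optimal")
  expect_identical(f_opt$route, "irregular")
  expect_identical(unname(f_opt$regularity), "irregular")
  # RMLE satisfies its hard constraint exactly and propagates Cov(beta~)
  fr <- fit_rmle(s$d, sm, s$tg)
  expect_lt(max(abs(fr$constraint_gap)), 1e-10)
  dth <- fr$theta[2, ] - fr$theta[1, ]
  expect_equal(unname(dth), sm$entries[[1]]$beta, tolerance = 1e-10)
  # the propagation term increases the variance in the constrained direction
  v_with <- diag(fr$cov_xi)[3:6]
  v_without <- diag(fr$cov_xi_noprop)[3:6]
  expect_true(all(v_with >= v_without - 1e-12))
})

test_that("inconsistent overlap declarations are rejected", {
  s <- small_setup(59)
  wm1 <- working_model("gc", q = c(.6, .4), reported = "X1", N0 = 1000, N1 = 1000,
                       K = 2, study = "S", id = "a")
  wm2 <- working_model("gc", q = c(.6, .4), reported = "X2", N0 = 500, N1 = 1000,
                       K = 2, study = "S", id = "b")   # different control count
  sm <- external_summary_from_data(s$ext, list(wm1, wm2))
  fit0 <- fit_polygim(s$d, NULL, s$tg)
  expect_error(build_joint_sigma(fit0, sm), class = "polygim_config")
})
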