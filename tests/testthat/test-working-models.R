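# External working models: retrospective factors, score components,
# constraint functions, regularity classification, initialization.

test_that("working_delta matches direct exponentiated linear predictors", {
  wm <- working_model("cc", c0 = 1, c1 = 2, reported = "X1", N0 = 10, N1 = 10, K = 2)
  expect_equal(working_delta(c(X1 = 0.7), alpha = 0, beta = 0, wm), 1)
  # marginal single-SNP style model: alpha0 = 0.3, beta = 0.2, dosage 1
  expect_equal(working_delta(c(X1 = 1), alpha = 0.3, beta = 0.2, wm), exp(0.5))
  set.seed(11)
  wm2 <- working_model("gc", q = c(.5, .5), reported = c("X1", "X2"),
                       nuisance = "X3", N0 = 5, N1 = 5, K = 2)
  for (i in 1:10) {
    x <- c(X1 = rnorm(1), X2 = rnorm(1), X3 = rnorm(1))
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(working_delta(x, a, b, wm2),
                 exp(a[1] + x["X3"] * a[2] + sum(x[c("X1", "X2")] * b)),
                 ignore_attr = TRUE)
  }
})

test_that("phi components satisfy their algebraic identities", {
  set.seed(2)
  wm <- working_model("gc", q = c(1, 0), reported = "X1", nuisance = "X2",
                      N0 = 100, N1 = 50, K = 2)
  for (i in 1:20) {
    x <- c(X1 = rnorm(1), X2 = rnorm(1))
    a <- rnorm(2); b <- rnorm(1)
    ph <- phi_components(x, a, b, wm)
    d <- working_delta(x, a, b, wm)
    expect_equal(ph$phi0 + wm$rho * d * ph$phi1, rep(0, 3), tolerance = 1e-12)
  }
  # rho = 0 limit: phi0 = 0 and phi1 = dlog delta = z
  ph0 <- phi_components(c(X1 = 1.3, X2 = -0.4), c(0.2, 0.1), 0.5, wm, rho = 0)
  expect_equal(ph0$phi0, rep(0, 3))
  expect_equal(ph0$phi1, c(1, -0.4, 1.3))
})

test_that("fitted working models annihilate the sample estimating equation", {
  # the score of the external logistic likelihood, written in the
  # retrospective parametrization, sums to zero at the glm solution
  set.seed(13)
  des <- two_marker_design()
  ext <- sample_case_control(des, des$external_sizes)
  sm <- external_summary_from_data(ext, des$working_models["GC2"])
  wm <- sm$entries[[1]]$model
  # recover full gamma (incl. nuisance intercept) by refitting with glm
  keep <- ext$y %in% c(0, 1, 2)
  D <- as.integer(ext$y > 0)
  Z <- cbind(1, ext$x)
  gam <- irls_logistic(Z, D)
  a0_retro <- gam[1] - log(wm$rho)
  score <- colSums((D - wm$rho * exp(a0_retro + drop(ext$x %*% gam[2:3])) /
                      (1 + wm$rho * exp(a0_retro + drop(ext$x %*% gam[2:3])))) * Z)
  expect_lt(max(abs(score)), 1e-6 * wm$N)
  # and the reported coefficients agree with the independent IRLS oracle
  expect_equal(sm$entries[[1]]$beta, unname(gam[2:3]), tolerance = 1e-6)
})

test_that("constraint function vanishes where theory says it must", {
  pop <- tm_population()
  des <- two_marker_design()
  d <- sample_case_control(des, c(40, 20, 20))
  # consistent CC working model: g == 0 at alpha0 = tau_c1 - tau_c0,
  # beta = theta_c1 - theta_c0, on the full covariate grid
  wm <- des$working_models$CC2
  mu <- list(xi = pop$xi_star,
             alpha = pop$tau_star[2] - pop$tau_star[1],
             beta = pop$theta_star[2, ] - pop$theta_star[1, ])
  for (cell in 1:4) {
    g <- constraint_g(pop$cells[cell, ],
                      mu, wm, des$target, d)
    expect_equal(g, rep(0, 3), tolerance = 1e-12)
  }
  # GC model: control expectation of g vanishes at the population solution
  # of the external estimating equation (exact 4-cell enumeration)
  wmg <- des$working_models$GC2
  P1mix <- drop(pop$cond[, 2:3] %*% wmg$q)       # P(x | D = 1) for merged cases
  Zc <- cbind(1, pop$cells)
  gam_star <- solve_population_gamma(Zc, pop$cond[, 1], P1mix, wmg$rho)
  mu_g <- list(xi = pop$xi_star, alpha = gam_star[1], beta = gam_star[2:3])
  gbar <- rowSums(vapply(1:4, function(cell)
    pop$cond[cell, 1] * constraint_g(pop$cells[cell, ],
                                     mu_g, wmg, des$target, d),
    numeric(3)))
  expect_lt(max(abs(gbar)), 1e-8)
  # degenerate external design rho = 0: g identically zero for GC models
  wm0 <- wmg; wm0$rho <- 0
  g0 <- constraint_g(c(X1 = 1, X2 = 1), mu_g, wm0, des$target, d)
  expect_equal(g0, rep(0, 3))
})

test_that("Monte-Carlo external fits satisfy the population constraint", {
  # with external data at N = 1e5 the fitted coefficients bring the exact
  # control expectation of g below 3/sqrt(N) in every coordinate
  set.seed(17)
  pop <- tm_population()
  des <- two_marker_design(external_sizes = c(5e4, 3e4, 2e4))
  ext <- sample_case_control(des, des$external_sizes)
  d <- sample_case_control(des, c(40, 20, 20))
  sm <- external_summary_from_data(ext, des$working_models["GC1"])
  wm <- sm$entries[[1]]$model
  # nuisance intercept: refit marginal model to recover it
  D <- as.integer(ext$y > 0)
  Z1 <- cbind(1, ext$x[, "X1"])
  gam <- irls_logistic(Z1, D)
  mu <- list(xi = pop$xi_star, alpha = gam[1] - log(wm$rho), beta = gam[2])
  gbar <- rowSums(vapply(1:4, function(cell)
    pop$cond[cell, 1] * constraint_g(pop$cells[cell, ],
                                     mu, wm, des$target, d),
    numeric(2)))
  expect_lt(max(abs(gbar)), 3 / sqrt(1e5))
})

test_that("regularity classification follows the structural rule", {
  des <- two_marker_design()
  d <- sample_case_control(des, c(20, 10, 10))
  tg <- des$target
  expect_identical(classify_regularity(des$working_models$CC2, tg, d), "irregular")
  expect_identical(classify_regularity(des$working_models$CC1, tg, d), "regular")
  expect_identical(classify_regularity(des$working_models$GC1, tg, d), "regular")
  expect_identical(classify_regularity(des$working_models$GC2, tg, d), "regular")
  # user override wins
  wm <- working_model("cc", c0 = 1, c1 = 2, reported = c("X1", "X2"),
                      N0 = 10, N1 = 10, K = 2, regularity = "regular")
  expect_identical(classify_regularity(wm, tg, d), "regular")
})

test_that("nuisance initializer reduces to the unweighted fit when designs match", {
  set.seed(23)
  des <- two_marker_design(internal_sizes = c(1000, 600, 400))
  d <- sample_case_control(des)
  # external sizes identical to internal class sizes, q matching the case mix
  wm <- working_model("gc", q = c(.6, .4), reported = c("X1", "X2"),
                      N0 = 1000, N1 = 1000, K = 2, study = "e")
  ini <- init_nuisance(d, wm)
  expect_equal(unname(ini$weights), rep(1, d$n))
  gam_unw <- irls_logistic(cbind(1, d$x), as.integer(d$y > 0))
  expect_equal(unname(c(ini$alpha, ini$beta)),
               unname(c(gam_unw[1] - log(wm$rho), gam_unw[2:3])), tolerance = 1e-6)
  # doubling all weights leaves the maximizer unchanged
  gam_w2 <- irls_logistic(cbind(1, d$x), as.integer(d$y > 0), w = rep(2, d$n))
  expect_equal(gam_unw, gam_w2, tolerance = 1e-10)
})

test_that("initializer approaches the population estimating-equation solution", {
  set.seed(29)
  pop <- tm_population()
  des <- two_marker_design(internal_sizes = c(2e5, 5e4, 5e4))
  d <- sample_case_control(des)
  wm <- des$working_models$GC1
  ini <- init_nuisance(d, wm)
  P1mix <- drop(pop$cond[, 2:3] %*% wm$q)
  Zc <- cbind(1, pop$cells[, 1])
  gam_star <- solve_population_gamma(Zc, pop$cond[, 1], P1mix, wm$rho)
  # 3 SEs of a weighted logistic fit at this size are well under 0.05
  expect_lt(max(abs(c(ini$alpha, ini$beta) - gam_star)), 0.05)
})

test_that("working-model and summary validation catches misuse", {
  expect_error(working_model("cc", c0 = 1, c1 = 1, reported = "X1",
                             N0 = 10, N1 = 10, K = 2), class = "polygim_config")
  expect_error(working_model("gc", q = c(0, 0), reported = "X1",
                             N0 = 10, N1 = 10, K = 2), class = "polygim_config")
  expect_error(working_model("gc", q = c(.7, .7), reported = "X1",
                             N0 = 10, N1 = 10, K = 2), class = "polygim_config")
  wm <- working_model("gc", q = c(1, 0), reported = c("X1", "X2"),
                      N0 = 10, N1 = 10, K = 2)
  expect_error(summary_entry(wm, beta = 1), class = "polygim_schema")
  expect_error(summary_entry(wm, beta = c(1, 2), se = c(0.1, -0.1)),
               class = "polygim_schema")
  e <- summary_entry(wm, beta = c(1, 2))
  expect_error(summary_data(list(e, e)), class = "polygim_schema")
})
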