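# Simulation designs, retrospective samplers and the replication harness.

test_that("two-marker design carries the study conditions", {
  des <- two_marker_design()
  expect_equal(sum(des$probs), 1)
  expect_equal(as.numeric(t(des$theta)), c(1.5, -1.0, -0.5, 1.2))
  expect_equal(des$omega, c(-0.2, 0.1))
  expect_equal(des$internal_sizes, c(2000, 500, 500))
  expect_equal(des$external_sizes, c(1000, 600, 400))
  # regularity pattern of the four working-model variants
  d <- sample_case_control(des, c(20, 10, 10))
  flags <- vapply(des$working_models, classify_regularity,
                  character(1), target = des$target, data = d)
  expect_equal(unname(flags[c("CC1", "CC2", "GC1", "GC2")]),
               c("regular", "irregular", "regular", "regular"))
})

test_that("retrospective sampling hits exact counts and exact conditionals", {
  set.seed(71)
  des <- two_marker_design()
  d <- sample_case_control(des, c(2000, 500, 500))
  expect_equal(unname(d$class_counts), c(2000, 500, 500))
  # subtype-1 cell frequencies converge to the exact Bayes conditional
  pop <- tm_population(des)
  n1 <- 1e5
  d1 <- sample_case_control(des, c(10, n1, 10))
  x1 <- d1$x[d1$y == 1, ]
  cellkey <- paste(x1[, 1], x1[, 2])
  freq <- table(factor(cellkey, levels = paste(pop$cells[, 1], pop$cells[, 2]))) / n1
  p <- pop$cond[, 2]
  expect_true(all(abs(as.numeric(freq) - p) < 3 * sqrt(p * (1 - p) / n1)))
  # null design: covariate distribution identical across classes
  des0 <- two_marker_design(theta = rep(0, 4))
  d0 <- sample_case_control(des0, c(5000, 5000, 10))
  tb <- table(paste(d0$x[d0$y < 2, 1], d0$x[d0$y < 2, 2]), d0$y[d0$y < 2])
  expect_gt(suppressWarnings(chisq.test(tb)$p.value), 0.01)
})

test_that("PRS design encodes the null/alternative conditions and shifts", {
  expect_equal(as.numeric(prs_design("null")$theta), rep(0, 4))
  alt <- prs_design("alternative")
  expect_equal(as.numeric(alt$theta), c(0.019, 0.092, -0.12, 0.047))
  expect_equal(alt$omega, rep(-3.8, 4))
  expect_equal(prs_design("null")$omega, c(-3.9, -4.1, -3.6, -3.8))
  # frequency-shift rule: 0.2 lower with floor 0.05
  des7 <- prs_design("alternative", external_subset = c("ext6", "ext7"))
  f <- des7$freq
  expect_equal(unname(des7$externals$ext6$freq[1:10]),
               unname(pmax(f[1:10] - 0.2, 0.05)))
  expect_equal(unname(des7$externals$ext6$freq[11:21]), unname(f[11:21]))
  expect_equal(unname(des7$externals$ext7$freq[11:21]),
               unname(pmax(f[11:21] - 0.2, 0.05)))
  # the multi-study layout records the printed design counts
  lay <- nhl_study_layout()
  expect_equal(unlist(lay[lay$study == "ext1", c("s1", "s2", "s3", "s4", "controls")],
                      use.names = FALSE), c(213, 254, 210, 0, 748))
  expect_equal(unlist(lay[lay$study == "internal", c("s1", "s2", "s3", "s4", "controls")],
                      use.names = FALSE), c(2179, 2661, 2142, 825, 6221))
})

test_that("disease subtypes are rare under the PRS intercepts", {
  set.seed(73)
  # the stated intercepts put every subtype below ~3% prevalence (subtype 3
  # sits at ~2.5% under the null intercepts, so 2% would be unattainable)
  expect_true(all(design_prevalence(prs_design("null"), nsim = 5e4) < 0.03))
  expect_true(all(design_prevalence(prs_design("alternative"), nsim = 5e4) < 0.03))
})

test_that("noisy PRS weights have the declared error law", {
  wt <- prs_weight_table()
  expect_equal(nrow(wt), 21L)
  expect_identical(draw_noisy_weights(wt, 0), setNames(wt$weight, wt$snp))
  set.seed(79)
  draws <- replicate(1e4, draw_noisy_weights(wt, 16)[3])
  expect_equal(var(draws), 16 * wt$weight_se[3]^2, tolerance = 0.05)
  # reproducible under a fixed seed
  set.seed(80); a <- draw_noisy_weights(wt, 1)
  set.seed(80); b <- draw_noisy_weights(wt, 1)
  expect_identical(a, b)
})

test_that("external summaries agree with an independent IRLS oracle", {
  set.seed(83)
  des <- two_marker_design()
  ext <- sample_case_control(des, des$external_sizes)
  sm <- external_summary_from_data(ext, des$working_models[c("GC2", "CC1")])
  # GC2 oracle
  D <- as.integer(ext$y > 0)
  expect_equal(sm$entries[[1]]$beta,
               unname(irls_logistic(cbind(1, ext$x), D)[2:3]), tolerance = 1e-6)
  # CC1 oracle (cases only)
  cc <- ext$y > 0
  expect_equal(sm$entries[[2]]$beta,
               unname(irls_logistic(cbind(1, ext$x[cc, "X1"]),
                                    as.integer(ext$y[cc] == 2))[2]),
               tolerance = 1e-6)
  # a GC model over one subtype records q as a unit vector
  des_prs <- prs_design("null", external_subset = "ext2")
  wms <- polygim:::prs_study_models(des_prs$externals$ext2)
  expect_equal(wms[[1]]$q, c(1, 0, 0, 0))
  # independent covariate: coefficient within 4 SE of zero
  set.seed(84)
  x0 <- cbind(X1 = rbinom(4000, 1, 0.4))
  d0 <- internal_data(x0, rep(0:1, 2000), K = 2, allow_empty_classes = TRUE)
  wm0 <- working_model("gc", q = c(1, 0), reported = "X1", N0 = 2000, N1 = 2000, K = 2)
  sm0 <- external_summary_from_data(d0, list(wm0))
  expect_lt(abs(sm0$entries[[1]]$beta), 4 * sm0$entries[[1]]$se)
})

test_that("the replication harness is deterministic and validates failures", {
  des <- two_marker_design(internal_sizes = c(200, 100, 100))
  runs <- list(list(label = "MLE", method = "mle"),
               list(label = "GIM", method = "gim_opt", models = "GC1"))
  r1 <- run_replication_study(des, runs, R = 3, seed = 5)
  r2 <- run_replication_study(des, runs, R = 3, seed = 5)
  expect_identical(r1$report, r2$report)
  expect_true(all(r1$report$replicates == 3))
  expect_true(all(r1$report$cp >= 0 & r1$report$cp <= 100))
  # replicate seeds are seed + r: a 2-replicate run reproduces the first
  # two replicates of a 3-replicate run
  r3 <- run_replication_study(des, runs, R = 2, seed = 5)
  expect_equal(r3$raw$est[1:2, , ], r1$raw$est[1:2, , ])
  expect_error(run_replication_study(des, list(list(label = "bad", method = "nope")),
                                     R = 2, seed = 1), class = "polygim_harness")
})

test_that("partial-summary validity conditions are checkable", {
  des <- prs_design("alternative", external_subset = c("ext2", "ext6"))
  ok <- check_partial_validity(des, "ext6", paste0("rs_syn", 11:21))
  expect_true(ok$valid)
  bad <- check_partial_validity(des, "ext6", sprintf("rs_syn%02d", 1:10))
  expect_false(bad$same_distribution)
  expect_false(bad$valid)
  expect_error(check_partial_validity(des, "ext6", "rs_unknown"),
               class = "polygim_config")
})
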