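# Synthetic-data engine: retrospective case-control sampling from fully
# specified populations, the two-biomarker three-class design, the 21-SNP
# polygenic-risk-score five-class design with noisy weights, external-study
# summary generation, and the Monte-Carlo replication harness.

#' Two-biomarker, three-class simulation design
#'
#' A population with two correlated binary biomarkers \eqn{(X_1, X_2)} whose
#' joint cell probabilities for \eqn{(0,0),(0,1),(1,0),(1,1)} are
#' \eqn{(0.28, 0.12, 0.18, 0.42)}, and a prospective polytomous model with
#' two disease subtypes: intercepts \eqn{(\omega_1,\omega_2) = (-0.2, 0.1)}
#' and slopes \eqn{(\theta_{11},\theta_{12},\theta_{21},\theta_{22}) =
#' (1.5, -1.0, -0.5, 1.2)}. The internal study samples 2000 controls and
#' 500 cases per subtype; the external study has 1000 controls, 600 subtype-1
#' and 400 subtype-2 cases and supports four working models: CC1/CC2
#' (case-case on \eqn{X_1} / on both markers) and GC1/GC2 (merged-case
#' grouped case-control on \eqn{X_1} / on both markers).
#'
#' @param theta slope vector \eqn{(\theta_{11},\theta_{12},\theta_{21},\theta_{22})}.
#' @param omega prospective intercepts.
#' @param internal_sizes,external_sizes counts \eqn{(n_0, n_1, n_2)}.
#' @return object of class \code{"polygim_design"}.
#' @export
two_marker_design <- function(theta = c(1.5, -1.0, -0.5, 1.2),
                              omega = c(-0.2, 0.1),
                              internal_sizes = c(2000, 500, 500),
                              external_sizes = c(1000, 600, 400)) {
  cells <- cbind(X1 = c(0, 0, 1, 1), X2 = c(0, 1, 0, 1))
  probs <- c(0.28, 0.12, 0.18, 0.42)
  K <- 2L
  th <- matrix(theta, nrow = K, byrow = TRUE,
               dimnames = list(NULL, c("X1", "X2")))
  Ncase <- sum(external_sizes[-1])
  qmix <- external_sizes[-1] / Ncase
  wms <- list(
    CC1 = working_model("cc", c0 = 1, c1 = 2, reported = "X1",
                        N0 = external_sizes[2], N1 = external_sizes[3],
                        K = K, study = "ext1", id = "CC1"),
    CC2 = working_model("cc", c0 = 1, c1 = 2, reported = c("X1", "X2"),
                        N0 = external_sizes[2], N1 = external_sizes[3],
                        K = K, study = "ext1", id = "CC2"),
    GC1 = working_model("gc", q = qmix, reported = "X1",
                        N0 = external_sizes[1], N1 = Ncase,
                        K = K, study = "ext1", id = "GC1"),
    GC2 = working_model("gc", q = qmix, reported = c("X1", "X2"),
                        N0 = external_sizes[1], N1 = Ncase,
                        K = K, study = "ext1", id = "GC2"))
  structure(list(type = "two_marker", K = K,
                 cells = cells, probs = probs,
                 omega = omega, theta = th,
                 internal_sizes = internal_sizes,
                 external_sizes = external_sizes,
                 working_models = wms,
                 target = target_model(K, "identity", features = c("X1", "X2"))),
            class = "polygim_design")
}

#' Study layout of the multi-study lymphoma-style simulation
#'
#' Case counts per disease subtype and control counts for the internal study
#' and seven external studies used by the multi-study simulation designs.
#'
#' @return data.frame with columns \code{study}, \code{s1..s4} (subtype case
#'   counts) and \code{controls}.
#' @export
nhl_study_layout <- function() {
  data.frame(
    study = c("internal", "ext1", "ext2", "ext3", "ext4", "ext5", "ext6", "ext7"),
    s1 = c(2179, 213, 387, 321, 0, 0, 0, 0),
    s2 = c(2661, 254, 0, 0, 393, 0, 549, 0),
    s3 = c(2142, 210, 0, 0, 0, 119, 0, 376),
    s4 = c(825, 0, 0, 0, 0, 0, 0, 0),
    controls = c(6221, 748, 294, 405, 172, 349, 525, 791))
}

#' Load the packaged 21-SNP weight table
#'
#' A synthetic stand-in table with the schema of a published
#' Hodgkin-lymphoma PRS panel: per SNP a GWAS effect estimate (\code{weight}),
#' its reported standard error (\code{weight_se}) and the effect-allele
#' frequency (\code{freq}) in the study population. The values are fabricated
#' with realistic magnitudes; see the file
#' \code{inst/extdata/hl_prs_snps_synthetic.tsv}.
#'
#' @return data.frame with columns \code{snp}, \code{weight},
#'   \code{weight_se}, \code{freq}.
#' @export
prs_weight_table <- function() {
  path <- system.file("extdata", "hl_prs_snps_synthetic.tsv", package = "polygim")
  if (path == "") pg_stop("config", "packaged SNP weight table not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Multi-study polygenic-risk-score simulation design
#'
#' Five outcome classes (controls + four disease subtypes), 21 independent
#' SNPs under Hardy-Weinberg equilibrium, risk acting through the PRS
#' \eqn{S(X)=\sum_i w_i X_i}:
#' \describe{
#'   \item{null}{\eqn{\omega = (-3.9,-4.1,-3.6,-3.8)}, \eqn{\theta = 0}.}
#'   \item{alternative}{\eqn{\omega_k = -3.8},
#'     \eqn{\theta = (0.019, 0.092, -0.12, 0.047)}.}
#' }
#' PRS weights used in the analysis are drawn per replicate from
#' \eqn{N(w_i, c\,se_i^2)} (\code{me_scale} = \eqn{c}), emulating GWAS
#' estimation error. External studies 6 and 7 come from populations whose
#' effect-allele frequency is 0.2 lower (bounded below at 0.05) for the
#' first 10 / last 11 SNPs respectively.
#'
#' @param variant \code{"null"} or \code{"alternative"}.
#' @param me_scale measurement-error factor \eqn{c \ge 0} (0, 1 or 16 in the
#'   study conditions).
#' @param external_subset names of external studies to include
#'   (subset of \code{ext1..ext7}).
#' @param size_multiplier scale factor for external study sizes (scalar or
#'   named per study).
#' @param snp_subsets optional named list restricting which SNPs each study
#'   reports (the partial-summary strategy); default: all 21.
#' @param weight_table SNP table as from [prs_weight_table()].
#' @return object of class \code{"polygim_design"}.
#' @export
prs_design <- function(variant = c("null", "alternative"), me_scale = 0,
                       external_subset = paste0("ext", 1:5),
                       size_multiplier = 1, snp_subsets = NULL,
                       weight_table = prs_weight_table()) {
  variant <- match.arg(variant)
  if (me_scale < 0) pg_stop("config", "me_scale must be >= 0")
  if (nrow(weight_table) != 21L) pg_stop("config", "weight table must have 21 SNPs")
  K <- 4L
  omega <- if (variant == "null") c(-3.9, -4.1, -3.6, -3.8) else rep(-3.8, 4)
  theta <- if (variant == "null") rep(0, 4) else c(0.019, 0.092, -0.12, 0.047)
  lay <- nhl_study_layout()
  snps <- weight_table$snp
  freq <- stats::setNames(weight_table$freq, snps)
  # frequency-shifted external populations (0.2 lower, floored at 0.05)
  study_freq <- list()
  for (st_ in paste0("ext", 1:7)) study_freq[[st_]] <- freq
  study_freq[["ext6"]][1:10] <- pmax(freq[1:10] - 0.2, 0.05)
  study_freq[["ext7"]][11:21] <- pmax(freq[11:21] - 0.2, 0.05)
  mult <- if (length(size_multiplier) == 1L)
    stats::setNames(rep(size_multiplier, 7), paste0("ext", 1:7)) else size_multiplier
  externals <- list()
  for (st_ in external_subset) {
    row <- lay[lay$study == st_, ]
    if (!nrow(row)) pg_stop("config", "unknown external study '%s'", st_)
    m <- mult[[st_]] %||% 1
    sizes <- round(c(row$controls, row$s1, row$s2, row$s3, row$s4) * m)
    use_snps <- (snp_subsets[[st_]] %||% snps)
    externals[[st_]] <- list(name = st_, sizes = sizes,
                             freq = study_freq[[st_]], snps = use_snps)
  }
  internal_sizes <- c(lay$controls[1], lay$s1[1], lay$s2[1], lay$s3[1], lay$s4[1])
  structure(list(type = "prs", K = K,
                 snps = snps, freq = freq,
                 weight_table = weight_table,
                 omega = omega,
                 theta = matrix(theta, ncol = 1, dimnames = list(NULL, "prs")),
                 me_scale = me_scale,
                 internal_sizes = internal_sizes,
                 externals = externals),
            class = "polygim_design")
}

#' @export
print.polygim_design <- function(x, ...) {
  cat(sprintf("Simulation design [%s]: K = %d, internal sizes (%s)\n",
              x$type, x$K, paste(x$internal_sizes, collapse = ", ")))
  invisible(x)
}

#' Perturbed PRS weights
#'
#' Draws \eqn{\tilde w_i \sim N(w_i, c\,se_i^2)}; \code{c = 0} returns the
#' weights unchanged.
#'
#' @param weight_table data.frame with \code{weight} and \code{weight_se}.
#' @param c measurement-error scale factor.
#' @return named numeric vector of perturbed weights.
#' @export
draw_noisy_weights <- function(weight_table, c = 0) {
  w <- weight_table$weight
  if (c > 0) w <- stats::rnorm(length(w), w, sqrt(c) * weight_table$weight_se)
  stats::setNames(w, weight_table$snp)
}

# Class-conditional distribution over the four cells of the two-marker
# population (columns: Y = 0..K), by exact Bayes enumeration.
cell_class_dist <- function(design) {
  lin <- design$cells %*% t(design$theta)
  lin <- sweep(lin, 2, design$omega, "+")
  e <- exp(lin)
  denom <- 1 + rowSums(e)
  post <- cbind(1, e) / denom               # P(Y = k | x)
  cond <- post * design$probs
  sweep(cond, 2, colSums(cond), "/")        # P(x | Y = k)
}

#' Retrospective case-control sampling from a design
#'
#' Draws exactly the requested number of subjects per outcome class from the
#' class-conditional covariate distributions \eqn{P(X|Y=k)} implied by the
#' design's population and true model (exact enumeration for the
#' two-biomarker design; per-SNP exponential tilting with rejection on the
#' outcome denominator for the PRS design, which is exact).
#'
#' @param design a \code{"polygim_design"}.
#' @param sizes counts \eqn{(n_0, ..., n_K)}; defaults to the design's
#'   internal sizes.
#' @param population for PRS designs: allele-frequency vector of the source
#'   population (defaults to the internal study population).
#' @return an [internal_data()] object.
#' @export
sample_case_control <- function(design, sizes = design$internal_sizes,
                                population = NULL) {
  K <- design$K
  if (design$type == "two_marker") {
    cond <- cell_class_dist(design)
    rows <- integer(0); ys <- integer(0)
    for (k in 0:K) {
      if (sizes[k + 1] == 0) next
      if (any(cond[, k + 1] < 0) || all(cond[, k + 1] == 0)) {
        pg_stop("config", "class %d has zero probability under the design", k)
      }
      cnt <- drop(stats::rmultinom(1, sizes[k + 1], cond[, k + 1]))
      rows <- c(rows, rep(seq_len(4), cnt))
      ys <- c(ys, rep(k, sizes[k + 1]))
    }
    internal_data(design$cells[rows, , drop = FALSE], ys, K = K,
                  allow_empty_classes = any(sizes == 0))
  } else {
    freq <- population %||% design$freq
    w <- stats::setNames(design$weight_table$weight, design$snps)
    xs <- vector("list", K + 1L); ys <- integer(0)
    for (k in 0:K) {
      nk <- sizes[k + 1]
      if (nk == 0) next
      xs[[k + 1]] <- sample_prs_class(nk, k, freq, w, design$omega, design$theta[, 1])
      ys <- c(ys, rep(k, nk))
    }
    X <- do.call(rbind, xs)
    colnames(X) <- design$snps
    internal_data(X, ys, K = K, allow_empty_classes = any(sizes == 0))
  }
}

# Exact sampler for P(X | Y = k) in the PRS design: propose from the
# factorized tilted genotype law prod_j Binom(2, f_j) * exp(theta_k w_j x_j)
# and accept with probability 1/(1 + sum_l exp(omega_l + theta_l S(x))) <= 1.
sample_prs_class <- function(n, k, freq, w, omega, theta) {
  J <- length(freq)
  tilt <- if (k == 0) 0 else theta[k]
  # per-SNP dosage probabilities under the tilt
  pr <- vapply(seq_len(J), function(j) {
    f <- freq[j]
    base <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    p <- base * exp(tilt * w[j] * 0:2)
    p / sum(p)
  }, numeric(3))
  out <- matrix(0L, 0, J)
  need <- n
  while (need > 0) {
    m <- max(ceiling(need * 1.15), 50)
    cand <- vapply(seq_len(J), function(j) {
      u <- stats::runif(m)
      findInterval(u, cumsum(pr[1:2, j])) # 0,1,2 dosages
    }, integer(m))
    cand <- matrix(cand, nrow = m)
    S <- drop(cand %*% w)
    acc_p <- 1 / (1 + rowSums(exp(outer(S, theta) +
                                    matrix(omega, m, length(omega), byrow = TRUE))))
    keep <- stats::runif(m) < acc_p
    got <- cand[keep, , drop = FALSE]
    if (nrow(got) > need) got <- got[seq_len(need), , drop = FALSE]
    out <- rbind(out, got)
    need <- n - nrow(out)
  }
  out
}

#' Fit working models on an external dataset and extract summary data
#'
#' Fits each declared working logistic model to the external dataset with
#' standard maximum likelihood (\code{stats::glm.fit}) and records the
#' reported coefficients, their standard errors and the realized design
#' sizes.
#'
#' @param dataset an [internal_data()] object holding the external study's
#'   individual-level records.
#' @param wms list of [working_model()] specs.
#' @return a [summary_data()] object.
#' @export
external_summary_from_data <- function(dataset, wms) {
  entries <- lapply(wms, function(wm) {
    st <- model_strata(wm)
    keep <- dataset$y %in% st$s
    Dv <- st$D[match(dataset$y[keep], st$s)]
    Z <- working_design(wm, dataset$x[keep, , drop = FALSE])
    fit <- tryCatch(fit_logistic(Z, Dv), polygim_convergence = function(e)
      pg_stop("convergence", "working model '%s' did not converge (separation?)", wm$id))
    bsl <- beta_slots(wm)
    summary_entry(wm, beta = unname(fit$coef[bsl]),
                  se = sqrt(diag(fit$vcov))[bsl])
  })
  summary_data(unname(entries))
}

# Working models of one PRS external study: a marginal single-SNP GC model
# per (collected subtype, SNP).
prs_study_models <- function(ext, K = 4L) {
  out <- list()
  for (k in seq_len(K)) {
    nk <- ext$sizes[k + 1]
    if (nk == 0) next
    q <- numeric(K); q[k] <- 1
    for (s in ext$snps) {
      out[[paste(ext$name, "s", k, s, sep = "_")]] <-
        working_model("gc", q = q, reported = s,
                      N0 = ext$sizes[1], N1 = nk, K = K,
                      study = ext$name,
                      id = paste(ext$name, "s", k, s, sep = "_"))
    }
  }
  out
}

# Simulate all external studies of a PRS design and return their pooled
# summary data.
simulate_prs_externals <- function(design) {
  entries <- list()
  for (ext in design$externals) {
    wms <- prs_study_models(ext, design$K)
    if (!length(wms)) next
    ds <- sample_case_control(design, sizes = ext$sizes, population = ext$freq)
    sm <- external_summary_from_data(ds, wms)
    entries <- c(entries, sm$entries)
  }
  summary_data(entries)
}

#' Monte-Carlo prevalence of each subtype under a design
#'
#' Integrates \eqn{P(Y=k|X)} over the population covariate distribution
#' (exactly for the two-marker design, by Monte-Carlo for the PRS design).
#'
#' @param design a \code{"polygim_design"}.
#' @param nsim Monte-Carlo size for PRS designs.
#' @return named vector of subtype prevalences (classes \code{1..K}).
#' @export
design_prevalence <- function(design, nsim = 2e5) {
  if (design$type == "two_marker") {
    lin <- design$cells %*% t(design$theta)
    lin <- sweep(lin, 2, design$omega, "+")
    e <- exp(lin)
    post <- e / (1 + rowSums(e))
    prev <- drop(design$probs %*% post)
  } else {
    X <- vapply(design$freq, function(f) stats::rbinom(nsim, 2, f), numeric(nsim))
    S <- drop(X %*% design$weight_table$weight)
    e <- exp(outer(S, design$theta[, 1]) +
               matrix(design$omega, nsim, design$K, byrow = TRUE))
    prev <- colMeans(e / (1 + rowSums(e)))
  }
  stats::setNames(prev, paste0("class", seq_len(design$K)))
}

#' Validity conditions for the partial-summary strategy
#'
#' Before using only a subset of SNP-level summary statistics from an
#' external study drawn from a shifted population, three conditions should
#' hold: (i) the retained SNPs have the same distribution in both
#' populations, (ii) SNPs are mutually independent, and (iii) the disease is
#' rare in both populations (so control and population genotype
#' distributions agree).
#'
#' @param design a PRS \code{"polygim_design"}.
#' @param study external study name.
#' @param snps SNPs whose summary data would be retained.
#' @param prev_tol rarity threshold on subtype prevalence.
#' @return list of logical conditions and overall \code{valid}.
#' @export
check_partial_validity <- function(design, study, snps, prev_tol = 0.03) {
  ext <- design$externals[[study]]
  if (is.null(ext)) pg_stop("config", "study '%s' not in design", study)
  unknown <- setdiff(snps, names(design$freq))
  if (length(unknown)) pg_stop("config", "unknown SNP(s): %s", paste(unknown, collapse = ", "))
  same_freq <- all(abs(ext$freq[snps] - design$freq[snps]) < 1e-12)
  indep <- TRUE                             # SNPs simulated independently
  rare <- all(design_prevalence(design) < prev_tol)
  list(same_distribution = same_freq, independent = indep, rare_disease = rare,
       valid = same_freq && indep && rare)
}

#' Replicated simulation study
#'
#' Runs \code{R} independent replicates of a design: per replicate the
#' internal study (and, when requested, external studies and their summary
#' data) are simulated and each analysis run is applied. Replicate \code{r}
#' uses seed \code{seed + r} so sub-ranges are independently reproducible.
#'
#' @param design a \code{"polygim_design"}.
#' @param runs list of analysis runs; each a list with \code{label},
#'   \code{method} (\code{"mle"}, \code{"gim_opt"}, \code{"gim_i"},
#'   \code{"gim_sigma"}, \code{"rmle"}) and optionally \code{models}
#'   (character vector of working-model ids to use as summary data; for PRS
#'   designs default all models of the design's external studies).
#' @param R number of replicates.
#' @param seed base seed.
#' @param keep_raw keep the per-replicate estimate/SE arrays.
#' @return object of class \code{"polygim_replication"}: a report data.frame
#'   (per run and coefficient: Bias, SE-Emp, SE-Est, CP, all multiplied by
#'   100), failure counts, and optionally the raw arrays.
#' @export
run_replication_study <- function(design, runs, R = 100, seed = 1,
                                  keep_raw = TRUE) {
  K <- design$K
  coef_names <- if (design$type == "two_marker") {
    as.vector(t(outer(1:K, c("X1", "X2"), function(k, f) paste0("theta", k, ".", f))))
  } else paste0("theta", 1:K, ".prs")
  true_theta <- as.numeric(t(design$theta))
  nr <- length(runs)
  labels <- vapply(runs, `[[`, character(1), "label")
  est <- array(NA_real_, c(R, length(coef_names), nr),
               dimnames = list(NULL, coef_names, labels))
  ses <- est
  fails <- integer(nr); names(fails) <- labels
  needs_ext <- any(vapply(runs, function(r) r$method != "mle", logical(1)))
  for (r in seq_len(R)) {
    set.seed(seed + r)
    if (design$type == "prs") {
      wtilde <- draw_noisy_weights(design$weight_table, design$me_scale)
      target <- target_model(K, "prs", prs_weights = wtilde)
    } else {
      target <- design$target
    }
    internal <- sample_case_control(design)
    summaries <- NULL
    if (needs_ext) {
      summaries <- if (design$type == "two_marker") {
        ext <- sample_case_control(design, sizes = design$external_sizes)
        ids <- unique(unlist(lapply(runs, `[[`, "models")))
        if (!length(ids)) ids <- names(design$working_models)
        external_summary_from_data(ext, design$working_models[ids])
      } else {
        simulate_prs_externals(design)
      }
    }
    mle_fit <- tryCatch(fit_plr_mle(internal, target), error = function(e) e)
    for (ri in seq_len(nr)) {
      run <- runs[[ri]]
      sm <- NULL
      if (run$method != "mle") {
        keep <- if (is.null(run$models)) seq_along(summaries$entries) else {
          which(vapply(summaries$entries, function(e) e$model$id, character(1))
                %in% run$models)
        }
        sm <- summary_data(summaries$entries[keep])
      }
      fit <- if (inherits(mle_fit, "error")) mle_fit else tryCatch(switch(run$method,
        mle = mle_fit,
        gim_opt = fit_polygim(internal, sm, target, policy = "optimal", mle = mle_fit),
        gim_i = fit_polygim(internal, sm, target, policy = "identity", mle = mle_fit),
        gim_sigma = fit_polygim(internal, sm, target, policy = "sigma", mle = mle_fit),
        rmle = fit_rmle(internal, sm, target, mle = mle_fit),
        pg_stop("config", "unknown method '%s'", run$method)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        fails[ri] <- fails[ri] + 1L
        pg_log("info", "replicate %d run '%s' failed: %s", r, run$label,
               conditionMessage(fit))
        next
      }
      ti <- grep("^theta", names(fit$xi))
      est[r, , ri] <- fit$xi[ti]
      ses[r, , ri] <- sqrt(pmax(diag(fit$cov_xi)[ti], 0))
    }
  }
  if (any(fails > 0.05 * R)) {
    pg_stop("harness", "more than 5%% replicate failures for run(s): %s",
            paste(labels[fails > 0.05 * R], collapse = ", "))
  }
  rows <- list()
  for (ri in seq_len(nr)) {
    for (ci in seq_along(coef_names)) {
      e <- est[, ci, ri]; s <- ses[, ci, ri]
      ok <- is.finite(e) & is.finite(s)
      cover <- abs(e[ok] - true_theta[ci]) <= 1.959964 * s[ok]
      rows[[length(rows) + 1L]] <- data.frame(
        run = labels[ri], coef = coef_names[ci], true = true_theta[ci],
        bias = 100 * (mean(e[ok]) - true_theta[ci]),
        se_emp = 100 * stats::sd(e[ok]),
        se_est = 100 * mean(s[ok]),
        cp = 100 * mean(cover),
        replicates = sum(ok))
    }
  }
  report <- do.call(rbind, rows)
  structure(list(report = report, failures = fails, R = R, seed = seed,
                 raw = if (keep_raw) list(est = est, se = ses),
                 coef_names = coef_names, true_theta = true_theta),
            class = "polygim_replication")
}

#' @export
print.polygim_replication <- function(x, ...) {
  cat(sprintf("Replication study: R = %d (seed %d)\n", x$R, x$seed))
  print(x$report, digits = 4, row.names = FALSE)
  if (any(x$failures > 0)) {
    cat("failures:", paste(sprintf("%s=%d", names(x$failures), x$failures),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
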