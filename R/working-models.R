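# External logistic working models and their constraint functions.
#
# An external study reports coefficients beta~ from a logistic working model
# of a binary outcome D derived from the subtype outcome Y:
#   CC (case-case):           D = 0 if Y = c0, D = 1 if Y = c1;
#   GC (grouped case-control): D = 0 if Y = 0, D = 1 if Y in a case group with
#                              known subtype mix q.
# In retrospective form P(X|D=1) = P(X|D=0) delta(X; alpha, beta) with
# delta = exp{alpha0 + m(X; alpha1, beta)}. The reported coefficients satisfy
# a population estimating equation which, mapped to the control distribution
# of the internal study, becomes E_{Y=0}[ g(X; mu*) ] = 0 with
#   CC: g = phi0 * Delta_c0 + rho * phi1 * Delta_c1
#   GC: g = phi0 + rho * phi1 * sum_k q_k Delta_k
# where phi0 = -rho*delta/(1+rho*delta) * dlogdelta, phi1 = dlogdelta/(1+rho*delta)
# and rho = N1/N0 in the external design.

#' Describe an external logistic working model
#'
#' @param kind \code{"cc"} (case-case) or \code{"gc"} (grouped case-control).
#' @param c0,c1 for CC models: the subtype labels compared
#'   (\code{D=0} for \code{Y=c0}, \code{D=1} for \code{Y=c1}).
#' @param q for GC models: length-\code{K} vector of known within-case
#'   subtype proportions (zeros allowed for uncollected subtypes; must sum
#'   to 1). \code{D=0} corresponds to controls.
#' @param reported covariate names whose coefficients are reported as
#'   summary data.
#' @param nuisance covariate names in the working model whose coefficients
#'   are nuisance; the intercept is always nuisance and is implicit.
#' @param N0,N1 external sample sizes in the \code{D=0} and \code{D=1} groups.
#' @param K number of subtype classes of the target outcome.
#' @param study study identifier; models sharing a \code{study} label are
#'   treated as fitted on overlapping samples (shared outcome strata) when the
#'   joint covariance of their summary statistics is assembled.
#' @param id optional model identifier (defaults to a generated label).
#' @param regularity \code{"auto"} (structural classification) or an explicit
#'   \code{"regular"}/\code{"irregular"} override.
#' @return An object of class \code{"polygim_working_model"}.
#' @export
working_model <- function(kind = c("cc", "gc"), c0 = NULL, c1 = NULL, q = NULL,
                          reported, nuisance = character(0), N0, N1, K,
                          study = "external", id = NULL,
                          regularity = c("auto", "regular", "irregular")) {
  kind <- match.arg(kind)
  regularity <- match.arg(regularity)
  K <- as.integer(K)
  if (N0 <= 0 || N1 <= 0) pg_stop("config", "external sizes N0, N1 must be positive")
  if (kind == "cc") {
    if (is.null(c0) || is.null(c1)) pg_stop("config", "CC model needs subtype labels c0, c1")
    if (c0 == c1) pg_stop("config", "CC model requires c0 != c1")
    if (!all(c(c0, c1) %in% seq_len(K))) pg_stop("config", "CC subtypes must be in 1..K")
    q <- NULL
  } else {
    if (is.null(q)) pg_stop("config", "GC model needs the case-mix vector q")
    if (length(q) != K) pg_stop("config", "q must have length K = %d", K)
    if (any(q < 0)) pg_stop("config", "q must be nonnegative")
    if (all(q == 0)) pg_stop("config", "GC model with all q_k = 0 is empty")
    if (abs(sum(q) - 1) > 1e-6) pg_stop("config", "q must sum to 1 (got %.6f)", sum(q))
    q <- q / sum(q)
    c0 <- c1 <- NULL
  }
  if (!length(reported)) pg_stop("config", "at least one reported coefficient is required")
  if (length(intersect(reported, nuisance))) {
    pg_stop("config", "features cannot be both reported and nuisance: %s",
            paste(intersect(reported, nuisance), collapse = ", "))
  }
  structure(list(kind = kind, c0 = c0, c1 = c1, q = q,
                 reported = reported, nuisance = nuisance,
                 N0 = N0, N1 = N1, N = N0 + N1, rho = N1 / N0,
                 K = K, study = study,
                 id = id %||% paste0(kind, "-", paste(reported, collapse = "+")),
                 regularity = regularity),
            class = "polygim_working_model")
}

# Outcome strata (subtype resolution) used by a working model:
# a data.frame with stratum label s in 0..K, external count, and D value.
model_strata <- function(wm) {
  if (wm$kind == "cc") {
    data.frame(s = c(wm$c0, wm$c1), count = c(wm$N0, wm$N1), D = c(0, 1))
  } else {
    used <- which(wm$q > 0)
    data.frame(s = c(0L, used), count = c(wm$N0, wm$N1 * wm$q[used]),
               D = c(0, rep(1, length(used))))
  }
}

# Working-model design matrix on internal covariates: intercept, nuisance
# features, reported features (in that order).
working_design <- function(wm, x) {
  feats <- c(wm$nuisance, wm$reported)
  missing <- setdiff(feats, colnames(x))
  if (length(missing)) pg_stop("config", "working-model feature(s) not in data: %s",
                               paste(missing, collapse = ", "))
  Z <- cbind(1, x[, feats, drop = FALSE])
  colnames(Z) <- c("(Intercept)", feats)
  Z
}

gamma_dim <- function(wm) 1L + length(wm$nuisance) + length(wm$reported)
beta_slots <- function(wm) gamma_dim(wm) - length(wm$reported) + seq_along(wm$reported)

#' Retrospective odds factor of a working model
#'
#' \eqn{\delta(X;\alpha,\beta) = \exp\{\alpha_0 + m(X;\alpha_1,\beta)\}} for a
#' linear working model \eqn{m = X_{nuis}^\top\alpha_1 + X_{rep}^\top\beta}.
#'
#' @param x_row named numeric covariate vector (raw covariates).
#' @param alpha nuisance coefficients \eqn{(\alpha_0, \alpha_1)}.
#' @param beta reported coefficients.
#' @param wm a [working_model()] spec.
#' @return positive scalar (overflow-protected).
#' @export
working_delta <- function(x_row, alpha, beta, wm) {
  gam <- c(alpha, beta)
  if (length(gam) != gamma_dim(wm)) {
    pg_stop("config", "alpha+beta length %d != expected %d", length(gam), gamma_dim(wm))
  }
  z <- c(1, x_row[c(wm$nuisance, wm$reported)])
  drop(clipped_exp(sum(z * gam)))
}

#' Score components of a working model
#'
#' Returns \eqn{\varphi_0 = -\rho\delta/(1+\rho\delta)\,\partial\log\delta} and
#' \eqn{\varphi_1 = \partial\log\delta/(1+\rho\delta)}, each of length
#' \eqn{\dim(\alpha)+\dim(\beta)}. They satisfy
#' \eqn{\varphi_0 + \rho\delta\varphi_1 = 0} identically.
#'
#' @inheritParams working_delta
#' @param rho external case-control ratio \eqn{N_1/N_0} (defaults to the
#'   model's own).
#' @return list with elements \code{phi0} and \code{phi1}.
#' @export
phi_components <- function(x_row, alpha, beta, wm, rho = wm$rho) {
  z <- c(1, as.numeric(x_row[c(wm$nuisance, wm$reported)]))
  d <- working_delta(x_row, alpha, beta, wm)
  list(phi0 = -rho * d / (1 + rho * d) * z,
       phi1 = z / (1 + rho * d))
}

#' Constraint function g of a working model
#'
#' Evaluates the control-distribution constraint function at one covariate
#' row: for CC models \eqn{g = \varphi_0\Delta_{c_0} + \rho\varphi_1\Delta_{c_1}},
#' for GC models \eqn{g = \varphi_0 + \rho\varphi_1\sum_k q_k\Delta_k}. At the
#' true population parameters its expectation over \eqn{P(X|Y=0)} is zero.
#'
#' @param x_row named numeric vector of raw covariates.
#' @param mu full parameter list with components \code{xi} (target
#'   parameters), \code{alpha}, \code{beta} (working-model parameters).
#' @param wm a [working_model()] spec.
#' @param target a [target_model()] spec.
#' @param data an [internal_data()] object supplying covariate naming for the
#'   target feature map.
#' @return numeric vector of length \eqn{\dim(\alpha)+\dim(\beta)}.
#' @export
constraint_g <- function(x_row, mu, wm, target, data) {
  X1 <- matrix(x_row, nrow = 1, dimnames = list(NULL, names(x_row)))
  F <- build_features(X1, target)
  D <- delta_matrix(F, mu$xi, wm$K)[1, ]
  ph <- phi_components(x_row, mu$alpha, mu$beta, wm)
  if (wm$kind == "cc") {
    ph$phi0 * D[wm$c0] + wm$rho * ph$phi1 * D[wm$c1]
  } else {
    ph$phi0 + wm$rho * ph$phi1 * sum(wm$q * D)
  }
}

#' Classify summary data as regular or irregular
#'
#' Grouped case-control summary data is always regular. Case-case summary
#' data is irregular exactly when the working model's named feature set
#' (nuisance plus reported covariates) coincides with the target model's
#' per-class linear features, i.e. the working model is consistent with the
#' underlying risk model, making \eqn{g(\cdot;\mu^*) \equiv 0}. The
#' comparison is structural (named feature sets, not numerical spans); an
#' explicit override on the working model wins.
#'
#' @param wm a [working_model()] spec.
#' @param target a [target_model()] spec.
#' @param data an [internal_data()] object (for default feature naming).
#' @return \code{"regular"} or \code{"irregular"}.
#' @export
classify_regularity <- function(wm, target, data) {
  if (wm$regularity != "auto") return(wm$regularity)
  if (wm$kind == "gc") return("regular")
  wm_feats <- sort(c(wm$nuisance, wm$reported))
  tg_feats <- sort(target_feature_names(target, data))
  if (identical(wm_feats, tg_feats)) "irregular" else "regular"
}

#' Initialize working-model nuisance and reported coefficients
#'
#' Mimics the external design on the internal sample: each internal subject
#' in an outcome stratum used by the working model receives the weight
#' (external stratum count)/(internal stratum count), and a weighted logistic
#' regression of the derived binary outcome D on the working-model features
#' is fitted. The fitted intercept is shifted by \eqn{-\log(N_1/N_0)} to the
#' retrospective (empirical-likelihood) parametrization. For CC models the
#' two compared subtypes play the role of the weighting strata.
#'
#' @param data an [internal_data()] object.
#' @param wm a [working_model()] spec.
#' @return list with \code{alpha} (intercept first), \code{beta}, and the
#'   per-subject \code{weights} used.
#' @export
init_nuisance <- function(data, wm) {
  st <- model_strata(wm)
  if (!all(st$s %in% data$y)) {
    pg_stop("config", "internal data lacks subjects in subtype(s) %s required by working model '%s'",
            paste(setdiff(st$s, unique(data$y)), collapse = ", "), wm$id)
  }
  keep <- data$y %in% st$s
  yv <- data$y[keep]
  Dv <- st$D[match(yv, st$s)]
  wts <- (st$count / data$class_counts[st$s + 1L])[match(yv, st$s)]
  Z <- working_design(wm, data$x[keep, , drop = FALSE])
  gam <- fit_logistic(Z, Dv, wts)$coef
  if (anyNA(gam)) {
    pg_stop("convergence", "weighted logistic initializer failed for model '%s'", wm$id)
  }
  gam[1] <- gam[1] - log(wm$rho)            # retrospective intercept
  nb <- length(wm$reported)
  list(alpha = gam[seq_len(gamma_dim(wm) - nb)],
       beta = gam[gamma_dim(wm) - nb + seq_len(nb)],
       weights = wts)
}

# Weighted logistic regression used for working-model fits. Narrow designs
# (the marginal single-SNP case, ubiquitous in the GWAS setting) go through
# a direct Newton iteration; wider designs through stats::glm.fit.
fit_logistic <- function(Z, D, w = NULL) {
  if (ncol(Z) <= 2L) {
    beta <- numeric(ncol(Z))
    if (is.null(w)) w <- 1
    for (i in 1:60) {
      mu <- 1 / (1 + exp(-drop(Z %*% beta)))
      wt <- w * mu * (1 - mu)
      info <- crossprod(Z * wt, Z)
      step <- tryCatch(drop(solve(info, crossprod(Z, w * (D - mu)))),
                       error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) {
        pg_stop("convergence", "logistic fit failed (separation?)")
      }
      beta <- beta + step
      if (max(abs(step)) < 1e-10) break
    }
    if (max(abs(step)) >= 1e-8) pg_stop("convergence", "logistic fit did not converge")
    mu <- 1 / (1 + exp(-drop(Z %*% beta)))
    list(coef = beta, vcov = solve(crossprod(Z * (w * mu * (1 - mu)), Z)))
  } else {
    fit <- if (is.null(w)) stats::glm.fit(Z, D, family = stats::binomial())
           else stats::glm.fit(Z, D, weights = w, family = stats::quasibinomial())
    if (!fit$converged || anyNA(fit$coefficients)) {
      pg_stop("convergence", "logistic fit did not converge (separation?)")
    }
    list(coef = fit$coefficients,
         vcov = safe_solve(crossprod(Z * fit$weights, Z)))
  }
}

#' Bundle summary data entries
#'
#' @param entries list of entries created by [summary_entry()].
#' @return object of class \code{"polygim_summary"}.
#' @export
summary_data <- function(entries) {
  if (inherits(entries, "polygim_summary_entry")) entries <- list(entries)
  ids <- vapply(entries, function(e) e$model$id, character(1))
  if (anyDuplicated(ids)) pg_stop("schema", "duplicate working-model ids: %s",
                                  paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(entries = entries), class = "polygim_summary")
}

#' One working model's reported coefficients
#'
#' @param model a [working_model()] spec.
#' @param beta numeric vector of reported coefficient estimates (length and
#'   order matching \code{model$reported}).
#' @param se optional strictly positive reported standard errors.
#' @return object of class \code{"polygim_summary_entry"}.
#' @export
summary_entry <- function(model, beta, se = NULL) {
  if (length(beta) != length(model$reported)) {
    pg_stop("schema", "beta length %d != %d reported coefficients of model '%s'",
            length(beta), length(model$reported), model$id)
  }
  if (!is.null(se)) {
    if (length(se) != length(beta) || any(se <= 0)) {
      pg_stop("schema", "reported SEs must be positive and match beta length (model '%s')", model$id)
    }
  }
  structure(list(model = model, beta = as.numeric(beta), se = se),
            class = "polygim_summary_entry")
}

#' @export
print.polygim_summary <- function(x, ...) {
  cat(sprintf("Summary data: %d working model(s)\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s [%s, study %s] N0=%g N1=%g beta~ = (%s)\n",
                e$model$id, toupper(e$model$kind), e$model$study,
                e$model$N0, e$model$N1,
                paste(sprintf("%.4f", e$beta), collapse = ", ")))
  }
  invisible(x)
}
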