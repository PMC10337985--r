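# File formats: delimited internal data, YAML summary-data files, JSON/TSV
# fit reports.

#' Read internal study data from a delimited file
#'
#' Expects a header; one column holds the integer outcome (0 = control), the
#' remaining columns are covariates or genotype dosages.
#'
#' @param path TSV or CSV file path (delimiter inferred from the extension,
#'   override via \code{sep}).
#' @param outcome name of the outcome column.
#' @param K number of non-control classes (default: maximum label).
#' @param sep field separator.
#' @return an [internal_data()] object.
#' @export
read_internal_data <- function(path, outcome = "y", K = NULL, sep = NULL) {
  if (!file.exists(path)) pg_stop("io", "file not found: %s", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!outcome %in% names(df)) pg_stop("schema", "outcome column '%s' not in %s", outcome, path)
  y <- df[[outcome]]
  if (any(y != round(y))) {
    pg_stop("schema", "non-integer outcome label at row %d", which(y != round(y))[1])
  }
  x <- as.matrix(df[setdiff(names(df), outcome)])
  d <- internal_data(x, y, K = K)
  pg_log("info", "read %d subjects (%s) from %s", d$n,
         paste(d$class_counts, collapse = "/"), path)
  d
}

#' Write internal study data to a delimited file
#'
#' @param data an [internal_data()] object.
#' @param path output path.
#' @param sep field separator.
#' @export
write_internal_data <- function(data, path, sep = "\t") {
  df <- data.frame(y = data$y, data$x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PRS weight table
#'
#' TSV with columns \code{snp} (or \code{snp_id}), \code{weight} and
#' optionally \code{weight_se}; returns weights named by SNP id, with the
#' standard errors attached as an attribute when present. The result can be
#' passed to [target_model()] as \code{prs_weights}.
#'
#' @param path TSV file path.
#' @return named numeric vector of weights (attribute \code{"se"} when
#'   standard errors are present).
#' @export
read_prs_weights <- function(path) {
  if (!file.exists(path)) pg_stop("io", "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("snp", "snp_id"), names(df))[1]
  if (is.na(idcol) || !"weight" %in% names(df)) {
    pg_stop("schema", "PRS weight file needs columns snp/snp_id and weight")
  }
  w <- stats::setNames(as.numeric(df$weight), df[[idcol]])
  if ("weight_se" %in% names(df)) {
    if (any(df$weight_se <= 0)) pg_stop("schema", "weight_se must be positive")
    attr(w, "se") <- stats::setNames(as.numeric(df$weight_se), df[[idcol]])
  }
  w
}

#' Read a summary-data file
#'
#' YAML schema: a top-level \code{models} list; each block has \code{id},
#' \code{study}, \code{kind} (\code{cc}|\code{gc}), \code{c0}/\code{c1} (CC)
#' or \code{q} (GC), \code{N0}, \code{N1}, \code{reported} feature names,
#' optional \code{nuisance} feature names, \code{beta} values and optional
#' \code{beta_se}; a top-level \code{K} gives the number of subtype classes.
#'
#' @param path YAML file path.
#' @return a [summary_data()] object.
#' @export
read_summary_file <- function(path) {
  if (!file.exists(path)) pg_stop("io", "file not found: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$models) || !length(doc$models)) {
    pg_stop("schema", "summary file %s has no 'models' blocks", path)
  }
  K <- doc$K %||% pg_stop("schema", "summary file must declare K")
  entries <- lapply(doc$models, function(b) {
    wm <- working_model(kind = b$kind,
                        c0 = b$c0, c1 = b$c1,
                        q = if (!is.null(b$q)) as.numeric(b$q),
                        reported = as.character(b$reported),
                        nuisance = as.character(b$nuisance %||% character(0)),
                        N0 = b$N0, N1 = b$N1, K = K,
                        study = b$study %||% "external",
                        id = b$id %||% NULL)
    summary_entry(wm, beta = as.numeric(b$beta),
                  se = if (!is.null(b$beta_se)) as.numeric(b$beta_se))
  })
  summary_data(entries)
}

#' Write a fit report
#'
#' Emits a JSON file with the full fit state (estimates, standard errors,
#' covariance, multipliers, convergence and provenance metadata) and a TSV
#' coefficient table next to it.
#'
#' @param fit a \code{"polygim_fit"}.
#' @param path output JSON path; the TSV is written with extension
#'   \code{.tsv}.
#' @param het optional list of heterogeneity results to embed.
#' @param seed optional seed recorded for provenance.
#' @return invisibly, the JSON path.
#' @export
write_fit_report <- function(fit, path, het = NULL, seed = NULL) {
  tab <- wald_summary(fit)
  payload <- list(
    package = "polygim",
    version = as.character(utils::packageVersion("polygim")),
    method = fit$method,
    config_hash = config_hash(list(fit$method, fit$K, fit$feature_names,
                                   unname(fit$xi), seed)),
    seed = seed,
    K = fit$K,
    feature_names = fit$feature_names,
    estimates = as.list(fit$xi),
    se = stats::setNames(as.list(tab$se), tab$term),
    cov_xi = fit$cov_xi,
    lambda = fit$lambda,
    nu = fit$nu,
    loglik = fit$loglik,
    iterations = fit$iterations,
    v_iterations = fit$v_iterations %||% 0L,
    constraints = fit$constraints,
    heterogeneity = lapply(het, function(h)
      list(lambda_stat = h$lambda_stat, df = h$df, p_value = h$p_value,
           common_effect = h$common_effect))
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  }, error = function(e) pg_stop("io", "cannot write %s: %s", path, conditionMessage(e)))
  tsv <- sub("\\.json$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  pg_log("info", "fit report written to %s (+ %s)", path, tsv)
  invisible(path)
}

#' Read a fit report back
#'
#' Restores the estimate/covariance content of a JSON fit report written by
#' [write_fit_report()] (sufficient for downstream inference such as
#' heterogeneity tests; the original data are not embedded).
#'
#' @param path JSON report path.
#' @return a \code{"polygim_fit"}-like list.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) pg_stop("io", "file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  xi <- unlist(doc$estimates)
  K <- doc$K
  p <- length(doc$feature_names)
  cov_xi <- matrix(as.numeric(as.matrix(doc$cov_xi)), length(xi), length(xi),
                   dimnames = list(names(xi), names(xi)))
  sp <- xi_split(xi, K, p)
  structure(list(xi = xi, tau = sp$tau, theta = sp$theta,
                 feature_names = doc$feature_names, K = K,
                 cov_xi = cov_xi, cov_mu = cov_xi,
                 lambda = doc$lambda, nu = doc$nu,
                 loglik = doc$loglik, iterations = doc$iterations,
                 method = doc$method),
            class = "polygim_fit")
}
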