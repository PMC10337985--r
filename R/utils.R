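# Small internal helpers shared across modules.

# Exponentials inside the retrospective odds factors are clipped at +-700
# (just inside the double-precision overflow limit for exp) so that extreme
# linear predictors degrade gracefully instead of producing Inf/NaN.
EXP_CLIP <- 700

clipped_exp <- function(x) {
  rng <- range(x)
  if (rng[2] > EXP_CLIP || rng[1] < -EXP_CLIP) {
    clip <- abs(x) > EXP_CLIP
    pg_log("warn", "exponent clipped at +-700 for %d value(s)", sum(clip))
    x <- pmin(pmax(x, -EXP_CLIP), EXP_CLIP)
  }
  exp(x)
}

# Lightweight leveled logging; level set via option polygim.log_level
# (one of "debug", "info", "warn", "none").
pg_log <- function(level = c("info", "debug", "warn"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("polygim.log_level", "warn")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, none = 4L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[polygim:%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

pg_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("polygim_", class), "polygim_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic content hash (multiplicative, exact in doubles) used
# to stamp output files with their generating configuration.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- ((h + b) * 65599) %% 2^32
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Symmetrize and (optionally) ridge a nearly-singular covariance before
# inversion; the ridge is tiny relative to the trace and logged.
safe_solve <- function(m, ridge = 1e-10) {
  m <- (m + t(m)) / 2
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(out)) {
    lam <- ridge * sum(diag(m)) / nrow(m)
    pg_log("warn", "near-singular matrix: adding ridge %.3g before inversion", lam)
    out <- solve(m + diag(lam, nrow(m)))
  }
  (out + t(out)) / 2
}
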