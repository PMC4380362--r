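# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI wrapper) can map failures to
# exit codes: config errors, data errors, numerical degeneracies.
mn_stop <- function(msg, class = "modnet_data_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "modnet_error", "error")))
}

mn_config_error <- function(msg, ...) mn_stop(msg, "modnet_config_error", ...)
mn_data_error <- function(msg, ...) mn_stop(msg, "modnet_data_error", ...)
mn_degenerate_error <- function(msg, ...) mn_stop(msg, "modnet_degenerate_error", ...)

# Evaluate `expr` under a fixed, versioned RNG (Mersenne-Twister /
# Inversion / Rejection), restoring the caller's RNG state afterwards.
# Pinning the generator kinds makes seeds portable across R sessions.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(old)) {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    } else {
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

# Fixed per-generator offsets from a top-level seed, so each synthetic
# generator consumes its own reproducible stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    mn_config_error(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}

check_count <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    mn_config_error(sprintf("%s must be a single integer >= %d", what, min))
  }
  invisible(as.integer(x))
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    mn_data_error(sprintf("%s is missing column(s): %s",
                          what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", ...)
}
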