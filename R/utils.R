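# Internal helpers shared across modules: harmonic sums, seeded RNG scopes,
# deterministic child-seed derivation, and a small provenance hash.

#' Partial harmonic sums used by the diversity estimators
#'
#' `a1(n)` is the (n-1)-th partial harmonic sum and `a2(n)` the corresponding
#' sum of inverse squares; both appear in Watterson's theta, Tajima's D and
#' the HKA moment equations.
#'
#' @param n Sample size (number of sequences), `n >= 2`.
#' @return A numeric scalar.
#' @keywords internal
harmonic_a1 <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' @rdname harmonic_a1
#' @keywords internal
harmonic_a2 <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package go through this so that a global
# seed yields bit-identical reruns without clobbering the user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically derive a child seed from a parent seed and a sequence of
# integer/string tags (multiplicative congruential mix, kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (tag in tags) {
    ks <- if (is.character(tag)) utf8ToInt(tag) else as.numeric(tag)
    for (k in ks) {
      h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483587 + 1)
}

# FNV-1a style hash of a character representation, for provenance headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Shared cache environment (fixed-S null distributions etc.)
.srnapop_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!is.null(.srnapop_cache[[key]])) {
    return(.srnapop_cache[[key]])
  }
  val <- compute()
  .srnapop_cache[[key]] <- val
  val
}

#' Clear srnapop's internal simulation caches
#'
#' Null distributions for the fixed-S Tajima test are cached per
#' `(n, S, n_reps, seed)`; this drops them (mainly useful in long sessions).
#'
#' @return Invisibly, `NULL`.
#' @export
clear_srnapop_cache <- function() {
  rm(list = ls(.srnapop_cache), envir = .srnapop_cache)
  invisible(NULL)
}

# Provenance header lines written at the top of every report TSV (D2: files
# print 1-based inclusive coordinates; internal representation is R 1-based).
provenance_header <- function(seed = NA, extra = NULL) {
  ver <- as.character(utils::packageVersion("srnapop"))
  c(
    sprintf("# srnapop %s", ver),
    sprintf("# seed=%s config_hash=%s", seed, config_hash(list(seed, extra)))
  )
}

write_report_tsv <- function(df, path, seed = NA, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
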