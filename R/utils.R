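# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions
#' do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# assertion helper: stop with a named message when cond is FALSE
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# longest run length in a vector
max_run_length <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

# write a data.frame as the package's canonical tab-delimited format
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
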