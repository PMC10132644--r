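#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# Every generator routes its randomness through this so a call is a pure
# function of (arguments, seed) and never perturbs the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Classed error constructor so callers can distinguish degenerate inputs
# (extinct populations, empty lanes, sigma = 0, ...) from programming errors.
stop_escape <- function(class, message, ...) {
  stop(structure(
    class = c(class, "crisprEscape_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop_escape(
      "non_acgt",
      sprintf("%s contains non-ACGT characters (first offender: %s)",
              what, x[bad][1L])
    )
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute a random different base at `k` random positions of one sequence.
substitute_bases <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), min(k, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Vectorised per-base substitution error process: each base of each sequence
# is independently replaced with a uniformly random different base with
# probability `rate`.
apply_substitution_errors <- function(seqs, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), size = lens, prob = rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    seqs[i] <- substitute_bases(seqs[i], n_err[i])
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
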