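# Shared fixtures and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")

fixture_spec <- function() demo_target_spec("geneJ")

rand_window <- function(L = 24L) {
  paste(sample(BASES, L, replace = TRUE), collapse = "")
}

# mutate exactly one window offset to a different base
mutate_at <- function(seq, offset, to = NULL) {
  base <- substr(seq, offset, offset)
  to <- to %||% sample(setdiff(BASES, base), 1L)
  substr(seq, offset, offset) <- to
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for nucleotide diversity: literal double loop over
# ordered pairs i = 2..n, j = 1..i-1 with the printed factor 2, Hamming
# distance computed character by character.
diversity_oracle <- function(haps, freqs, L) {
  n <- length(haps)
  if (n < 2) return(0)
  total <- 0
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      pij <- 0
      for (k in seq_len(nchar(haps[i]))) {
        if (substr(haps[i], k, k) != substr(haps[j], k, k)) pij <- pij + 1
      }
      total <- total + 2 * freqs[i] * freqs[j] * pij
    }
  }
  total / L
}

# Independent oracle for the positional enrichment Z-score: explicit
# means and an explicitly accumulated pooled sample SD over every
# proportion in every supplied sample.
zscore_oracle <- function(exp_mats, ctl_mats) {
  pos <- exp_mats[[1]]$positions
  all_vals <- c()
  for (m in c(exp_mats, ctl_mats)) all_vals <- c(all_vals, m$proportions)
  mu_all <- sum(all_vals) / length(all_vals)
  sigma <- sqrt(sum((all_vals - mu_all)^2) / (length(all_vals) - 1))
  z <- numeric(length(pos))
  for (p in seq_along(pos)) {
    xbar <- mean(vapply(exp_mats, function(m) m$proportions[[p]], numeric(1)))
    mubar <- mean(vapply(ctl_mats, function(m) m$proportions[[p]], numeric(1)))
    z[p] <- (xbar - mubar) / sigma
  }
  z
}

# Construct a position_matrix with given proportions directly (bypassing
# read classification) for statistics tests.
raw_position_matrix <- function(proportions, positions, sample_id = "s") {
  structure(
    list(sample_id = sample_id, n_accepted = 1000L,
         positions = positions,
         proportions = stats::setNames(proportions, positions),
         by_type = data.frame(index = integer(), type = character(),
                              fraction = numeric())),
    class = "position_matrix"
  )
}

# Independent read-corruption helper (oracle-side, not the package's own
# error process): substitute each base with probability `rate`.
apply_substitution_errors_public <- function(seq, rate, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

random_position_matrices <- function(n_exp = 3L, n_ctl = 2L, L = 24L) {
  positions <- c(-(4:1), 1:20)[seq_len(L)]
  make <- function(id) {
    raw_position_matrix(stats::runif(L, 0, 0.3), positions, id)
  }
  list(experimental = lapply(paste0("e", seq_len(n_exp)), make),
       control = lapply(paste0("c", seq_len(n_ctl)), make))
}
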