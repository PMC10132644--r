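#' Define a phage genotype pool for population simulation
#'
#' Each genotype is a haplotype over the target window (possibly carrying a
#' deletion edit relative to wild type), an initial population frequency,
#' and a nonnegative survival weight: the per-generation relative
#' propagation weight under CRISPR pressure. Weight ratios are a proxy for
#' relative cleavage rates (a genotype cleaved 20x slower propagates with
#' ~20x the weight of wild type).
#'
#' @param haplotype Character vector of target-window haplotypes (ACGT).
#' @param frequency Initial frequencies; must sum to 1 within 1e-9.
#' @param weight Nonnegative survival weights.
#' @return data.frame of class `genotype_pool`.
#' @export
genotype_pool <- function(haplotype, frequency, weight) {
  stopifnot(length(haplotype) == length(frequency),
            length(haplotype) == length(weight))
  haplotype <- toupper(haplotype)
  check_dna(haplotype, "haplotype")
  if (abs(sum(frequency) - 1) > 1e-9) {
    stop("initial frequencies must sum to 1 (got ", sum(frequency), ")")
  }
  if (any(frequency < 0)) stop("frequencies must be nonnegative")
  if (any(weight < 0)) stop("survival weights must be nonnegative")
  if (anyDuplicated(haplotype)) stop("duplicate haplotypes in pool")
  structure(
    data.frame(haplotype = haplotype, frequency = frequency, weight = weight,
               stringsAsFactors = FALSE),
    class = c("genotype_pool", "data.frame")
  )
}

#' Simulate a phage population under CRISPR selection
#'
#' Discrete-generation Wright-Fisher-style resampling: each generation the
#' population of `pop_size` genomes is drawn multinomially with probability
#' proportional to frequency x survival_weight, then a per-base
#' substitution process at `error_rate` converts a binomial number of
#' individuals of each genotype into single-base mutants (PCR and
#' sequencing errors downstream are modelled separately by the read
#' emitter). Novel haplotypes inherit their parent's survival weight;
#' genuinely escaping genotypes should be specified explicitly in the pool
#' with their own weights.
#'
#' @param pool A [genotype_pool()].
#' @param n_generations Number of generations to simulate (>= 1).
#' @param pop_size Population size per generation (>= 1).
#' @param error_rate Per-base substitution probability per generation.
#' @param seed Integer RNG seed; the run is a pure function of
#'   (arguments, seed).
#' @return An object of class `population_series`: list with `timepoints`
#'   (0..n_generations), `frequencies` (haplotype x timepoint matrix, each
#'   column summing to 1), `weights` (named survival weights including any
#'   de novo haplotypes), and `pop_size`.
#' @export
simulate_population <- function(pool, n_generations, pop_size,
                                error_rate = 0, seed) {
  stopifnot(inherits(pool, "genotype_pool"),
            n_generations >= 1, pop_size >= 1,
            error_rate >= 0, error_rate < 1)
  if (all(pool$weight == 0)) {
    stop_escape("population_extinct",
                "all survival weights are zero: the population is extinct")
  }
  L <- nchar(pool$haplotype[1])
  with_seed(seed, {
    freq <- stats::setNames(pool$frequency, pool$haplotype)
    weight <- stats::setNames(pool$weight, pool$haplotype)
    parent <- stats::setNames(pool$haplotype, pool$haplotype)
    traj <- list(`0` = freq)
    for (g in seq_len(n_generations)) {
      w <- freq * weight[names(freq)]
      if (sum(w) <= 0) {
        stop_escape("population_extinct",
                    sprintf("population extinct at generation %d (total selective weight 0)", g))
      }
      counts <- as.vector(stats::rmultinom(1, pop_size, w / sum(w)))
      names(counts) <- names(freq)
      counts <- counts[counts > 0]
      if (error_rate > 0) {
        # probability an individual acquires >=1 substitution this generation;
        # small rates => model one substitution per mutated individual
        p_mut <- 1 - (1 - error_rate)^nchar(names(counts))
        n_mut <- stats::rbinom(length(counts), counts, p_mut)
        for (i in which(n_mut > 0)) {
          hap <- names(counts)[i]
          counts[i] <- counts[i] - n_mut[i]
          for (k in seq_len(n_mut[i])) {
            mut <- substitute_bases(hap, 1L)
            if (!mut %in% names(counts)) {
              counts[mut] <- 0L
              weight[mut] <- weight[[hap]]
              parent[mut] <- hap
            }
            counts[mut] <- counts[mut] + 1L
          }
        }
        counts <- counts[counts > 0]
      }
      freq <- counts / pop_size
      traj[[as.character(g)]] <- freq
    }
    haps <- unique(unlist(lapply(traj, names)))
    mat <- matrix(0, nrow = length(haps), ncol = length(traj),
                  dimnames = list(haps, names(traj)))
    for (j in seq_along(traj)) mat[names(traj[[j]]), j] <- traj[[j]]
    structure(
      list(timepoints = as.integer(names(traj)),
           frequencies = mat,
           weights = weight[haps],
           pop_size = pop_size),
      class = "population_series"
    )
  })
}

#' @export
print.population_series <- function(x, ...) {
  cat("<population_series> ", nrow(x$frequencies), " haplotypes x ",
      length(x$timepoints), " timepoints (pop_size ", x$pop_size, ")\n",
      sep = "")
  invisible(x)
}

#' Draw a finite read sample from one timepoint of a population series
#'
#' @param series A [simulate_population()] result.
#' @param timepoint Which recorded generation to sample.
#' @param n_reads Number of genomes/reads to draw.
#' @param seed Integer RNG seed.
#' @return Named integer vector of counts per haplotype (only nonzero).
#' @export
sample_population <- function(series, timepoint, n_reads, seed) {
  stopifnot(inherits(series, "population_series"))
  j <- match(timepoint, series$timepoints)
  if (is.na(j)) stop("timepoint ", timepoint, " not recorded in series")
  p <- series$frequencies[, j]
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_reads, p))
    names(counts) <- rownames(series$frequencies)
    counts[counts > 0]
  })
}
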