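#' Emit paired-end amplicon reads from a genotype sample
#'
#' Builds, for each genome in `counts`, the sample amplicon (the reference
#' with the target window replaced by the genotype's haplotype) and emits
#' an R1 read from the amplicon's left end and an R2 read from the right
#' end (reverse-complemented), mirroring a MiSeq design in which both
#' mates overlap the entire protospacer + PAM window. Per-base
#' substitution errors are applied independently to each mate. A fraction
#' `discordance_rate` of pairs is made deliberately discordant by mutating
#' one window base of the R2 mate only; these pairs are flagged in the
#' read identifiers and the truth table so concordance filtering can be
#' audited exactly.
#'
#' @param counts Named integer vector: window haplotype -> genome count
#'   (e.g. from [sample_population()]; names must be ACGT strings).
#' @param spec A [target_spec()].
#' @param read_length Read length; must cover the full window from each
#'   primer end for every genotype.
#' @param seq_error_rate Per-base substitution probability per read.
#' @param discordance_rate Fraction of pairs planted as R1/R2-discordant.
#' @param seed Integer RNG seed.
#' @return List with data.frames `r1`, `r2` (columns `id`, `seq`) and
#'   `truth` (columns `read_id`, `haplotype`, `discordant`).
#' @export
emit_amplicon_reads <- function(counts, spec, read_length,
                                seq_error_rate = 0, discordance_rate = 0,
                                seed) {
  stopifnot(inherits(spec, "target_spec"),
            discordance_rate >= 0, discordance_rate <= 1)
  haps <- names(counts)
  check_dna(haps, "haplotype")
  ref <- spec$amplicon_reference
  amplicons <- vapply(haps, function(h) {
    paste0(substr(ref, 1, spec$window_start - 1L), h,
           substr(ref, spec$window_end + 1L, nchar(ref)))
  }, character(1))
  # each mate must span the window plus the flank anchors used to locate it:
  # R1 reads the amplicon prefix, R2 the suffix
  anchor_len <- nchar(spec$anchor_left)
  win_end <- spec$window_start - 1L + nchar(haps)
  need_r1 <- win_end + anchor_len
  need_r2 <- nchar(amplicons) - (spec$window_start - anchor_len) + 1L
  if (any(read_length < need_r1) || any(read_length < need_r2)) {
    stop("read_length ", read_length,
         " does not cover the full target window (plus flank anchors) ",
         "from both primer ends")
  }
  with_seed(seed, {
    hap_idx <- rep(seq_along(haps), times = counts)
    n <- length(hap_idx)
    disc <- stats::rbinom(n, 1L, discordance_rate) == 1L
    amp1 <- amplicons[hap_idx]
    amp2 <- amp1
    for (i in which(disc)) {
      # corrupt one window base on the template seen by R2 only
      pos <- sample.int(nchar(haps[hap_idx[i]]), 1L) + spec$window_start - 1L
      base <- substr(amp2[i], pos, pos)
      substr(amp2[i], pos, pos) <- sample(setdiff(DNA_BASES, base), 1L)
    }
    r1 <- substr(amp1, 1L, read_length)
    r2 <- revcomp(substr(amp2, nchar(amp2) - read_length + 1L, nchar(amp2)))
    r1 <- apply_substitution_errors(r1, seq_error_rate)
    r2 <- apply_substitution_errors(r2, seq_error_rate)
    read_id <- sprintf("sim%06d g=%d disc=%d", seq_len(n), hap_idx,
                       as.integer(disc))
    list(
      r1 = data.frame(id = read_id, seq = r1, stringsAsFactors = FALSE),
      r2 = data.frame(id = read_id, seq = r2, stringsAsFactors = FALSE),
      truth = data.frame(read_id = read_id, haplotype = haps[hap_idx],
                         discordant = disc, stringsAsFactors = FALSE)
    )
  })
}

#' Build a reference that realises requested deletion microhomologies
#'
#' Generates a random reference and, for each planted deletion
#' `[del_start, del_end]` (1-based closed) with requested microhomology
#' `mh`, copies the `mh`-mer starting at the left breakpoint to the
#' position just right of the deleted interval, so the deletion junction
#' carries exactly that homology; flanking bases are then adjusted so the
#' homology does not extend further in either direction and `del_start`
#' is the leftmost equivalent placement.
#'
#' @param ref_length Reference length (nt).
#' @param deletions data.frame with columns `del_start`, `del_end`, `mh`.
#' @param seed Integer RNG seed.
#' @return Reference sequence (character scalar).
#' @export
build_deletion_reference <- function(ref_length, deletions, seed) {
  stopifnot(all(c("del_start", "del_end", "mh") %in% names(deletions)))
  d <- deletions
  if (any(d$del_start < 2L) || any(d$del_end + d$mh + 1L > ref_length)) {
    stop("deletions (plus homology and flank room) must fit inside the reference")
  }
  if (any(d$del_end < d$del_start)) stop("del_end must be >= del_start")
  # keep each deletion's homology-engineering zone disjoint from the others'
  zone <- cbind(d$del_start - 1L, d$del_end + d$mh + 1L)
  ord <- order(zone[, 1])
  if (nrow(d) > 1L && any(zone[ord, 1][-1] <= zone[ord, 2][-nrow(d)])) {
    stop("planted deletions too close: homology zones overlap")
  }
  with_seed(seed, {
    ref <- random_dna(ref_length)
    for (i in seq_len(nrow(d))) {
      l <- d$del_start[i]; r <- d$del_end[i]; m <- d$mh[i]
      len <- r - l + 1L
      if (m > 0L) {
        if (m > len) stop("microhomology longer than the deletion itself")
        substr(ref, r + 1L, r + m) <- substr(ref, l, l + m - 1L)
      }
      # block extension: base after each homology copy must differ
      a <- substr(ref, l + m, l + m)
      b <- substr(ref, r + m + 1L, r + m + 1L)
      if (a == b) {
        substr(ref, r + m + 1L, r + m + 1L) <- sample(setdiff(DNA_BASES, a), 1L)
      }
      # block leftward shift: base before del_start must differ from base
      # before the right junction
      a <- substr(ref, l - 1L, l - 1L)
      b <- substr(ref, r, r)
      if (a == b) {
        substr(ref, l - 1L, l - 1L) <- sample(setdiff(DNA_BASES, b), 1L)
      }
    }
    ref
  })
}

#' Emit long reads with planted large deletions
#'
#' Each read is the full reference, or the reference with one planted
#' deletion excised, drawn multinomially from the requested frequencies;
#' per-base substitution errors are then applied. Deletions use 1-based
#' closed coordinates `[del_start, del_end]`.
#'
#' @param reference Reference sequence (e.g. from
#'   [build_deletion_reference()]).
#' @param deletions data.frame with columns `del_start`, `del_end`,
#'   `frequency`; frequencies plus the implied wild-type remainder must
#'   sum to 1, and intervals must not overlap.
#' @param n_reads Number of reads to emit.
#' @param seq_error_rate Per-base substitution probability.
#' @param seed Integer RNG seed.
#' @return List with `reads` (data.frame `id`, `seq`) and `truth`
#'   (data.frame `read_id`, `deletion` index with 0 = wild type,
#'   `del_start`, `del_end`).
#' @export
emit_long_reads <- function(reference, deletions, n_reads,
                            seq_error_rate = 0, seed) {
  check_dna(reference, "reference")
  d <- deletions
  stopifnot(all(c("del_start", "del_end", "frequency") %in% names(d)))
  if (any(d$del_start < 1L) || any(d$del_end > nchar(reference)) ||
      any(d$del_end < d$del_start)) {
    stop("deletion coordinates out of range")
  }
  if (nrow(d) > 1L) {
    ord <- order(d$del_start)
    if (any(d$del_start[ord][-1] <= d$del_end[ord][-nrow(d)])) {
      stop("planted deletions overlap")
    }
  }
  wt_freq <- 1 - sum(d$frequency)
  if (wt_freq < -1e-9 || any(d$frequency < 0)) {
    stop("deletion frequencies must be nonnegative and sum to <= 1")
  }
  with_seed(seed, {
    p <- c(max(wt_freq, 0), d$frequency)
    idx <- sample.int(length(p), n_reads, replace = TRUE, prob = p) - 1L
    seqs <- vapply(idx, function(i) {
      if (i == 0L) return(reference)
      paste0(substr(reference, 1L, d$del_start[i] - 1L),
             substr(reference, d$del_end[i] + 1L, nchar(reference)))
    }, character(1))
    seqs <- apply_substitution_errors(seqs, seq_error_rate)
    read_id <- sprintf("long%05d del=%d", seq_len(n_reads), idx)
    list(
      reads = data.frame(id = read_id, seq = seqs, stringsAsFactors = FALSE),
      truth = data.frame(
        read_id = read_id, deletion = idx,
        del_start = ifelse(idx == 0L, NA_integer_, d$del_start[idx]),
        del_end = ifelse(idx == 0L, NA_integer_, d$del_end[idx]),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Emit a first-order cleavage time course
#'
#' fraction(t) = plateau * (1 - exp(-k_obs * t)) plus Gaussian noise,
#' clipped to [0, 1]. Default timepoints are the quench times used for
#' plasmid cleavage assays (7 s to 30 min).
#'
#' @param k_obs Observed first-order rate constant (per second, >= 0).
#' @param plateau Amplitude in [0, 1].
#' @param timepoints Seconds, strictly increasing.
#' @param noise_sd Gaussian noise SD on the fraction scale (>= 0).
#' @param seed Integer RNG seed (unused when `noise_sd` is 0).
#' @return data.frame of class `time_course` with columns `time_s`,
#'   `fraction_cleaved`.
#' @export
emit_timecourse <- function(k_obs, plateau = 1,
                            timepoints = c(7, 15, 30, 60, 300, 900, 1800),
                            noise_sd = 0, seed = 1L) {
  stopifnot(k_obs >= 0, plateau >= 0, plateau <= 1,
            all(diff(timepoints) > 0))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  f <- plateau * (1 - exp(-k_obs * timepoints))
  if (noise_sd > 0) {
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  f <- pmin(pmax(f, 0), 1)
  structure(
    data.frame(time_s = timepoints, fraction_cleaved = f),
    class = c("time_course", "data.frame")
  )
}
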