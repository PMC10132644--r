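# Summary statistics over position mutation matrices and haplotype tables:
# positional enrichment Z-scores against a non-targeted control, haplotype
# nucleotide diversity, competition read ratios and time-course summaries.

#' Positional mutation-enrichment Z-scores
#'
#' For each target position p,
#' \deqn{Z(p) = (\bar{x}(p) - \bar{\mu}(p)) / \sigma}
#' where \eqn{\bar{x}} and \eqn{\bar{\mu}} are the cross-replicate mean
#' mutated-read proportions in the experimental and control samples, and
#' \eqn{\sigma} is a single pooled standard deviation of the proportions
#' at all positions in all supplied samples (experimental and control
#' together). Negative Z is permitted.
#'
#' @param experimental,control Lists of [tabulate_variants()] matrices
#'   sharing one position set.
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n)
#'   denominator for the pooled standard deviation.
#' @return Object of class `zscore_matrix`: data.frame with columns
#'   `index` and `z`, with attributes `sigma`, `experimental_ids`,
#'   `control_ids`.
#' @export
zscores <- function(experimental, control,
                    sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  if (inherits(experimental, "position_matrix")) experimental <- list(experimental)
  if (inherits(control, "position_matrix")) control <- list(control)
  stopifnot(length(experimental) >= 1L, length(control) >= 1L)
  all_m <- c(experimental, control)
  pos <- all_m[[1]]$positions
  for (m in all_m) {
    if (!identical(m$positions, pos)) {
      stop("all matrices must share one position set")
    }
  }
  exp_mat <- vapply(experimental, `[[`, numeric(length(pos)), "proportions")
  ctl_mat <- vapply(control, `[[`, numeric(length(pos)), "proportions")
  exp_mat <- matrix(exp_mat, nrow = length(pos))
  ctl_mat <- matrix(ctl_mat, nrow = length(pos))
  pooled <- c(exp_mat, ctl_mat)
  sigma <- if (sd_denominator == "sample") {
    stats::sd(pooled)
  } else {
    sqrt(mean((pooled - mean(pooled))^2))
  }
  if (!is.finite(sigma) || sigma == 0) {
    stop_escape("degenerate_sigma",
                "all per-position proportions are identical: sigma = 0, Z undefined")
  }
  z <- (rowMeans(exp_mat) - rowMeans(ctl_mat)) / sigma
  out <- data.frame(index = pos, z = z)
  attr(out, "sigma") <- sigma
  attr(out, "experimental_ids") <-
    vapply(experimental, `[[`, character(1), "sample_id")
  attr(out, "control_ids") <- vapply(control, `[[`, character(1), "sample_id")
  class(out) <- c("zscore_matrix", "data.frame")
  out
}

#' Haplotype nucleotide diversity of a target window
#'
#' Frequency-weighted mean pairwise difference per site over the
#' PAM+protospacer window:
#' \deqn{D = \frac{1}{L}\sum_{i=2}^{n}\sum_{j=1}^{i-1} 2 x_i x_j \pi_{ij}}
#' with \eqn{\pi_{ij}} the Hamming distance between haplotypes i and j
#' and L the window length (24 for the default window). No sample-size
#' correction is applied.
#'
#' Haplotypes one base shorter than L (single deletions) are compared by
#' expanding them with a gap character at the canonical deletion slot
#' resolved against `reference`; a gap mismatches every base (pairwise
#' difference contribution 1) and matches a gap at the same slot. With
#' `deletions = "exclude"` such haplotypes are dropped and the remaining
#' frequencies renormalised.
#'
#' @param haplotypes Character vector of window haplotypes.
#' @param frequencies Frequencies summing to 1 within 1e-9.
#' @param L Window length; defaults to the longest haplotype length.
#' @param reference Reference window, required to place deletions when
#'   haplotype lengths differ.
#' @param deletions `"canonical"` (default) or `"exclude"`.
#' @return Nonnegative diversity value.
#' @export
nucleotide_diversity <- function(haplotypes, frequencies, L = NULL,
                                 reference = NULL,
                                 deletions = c("canonical", "exclude")) {
  deletions <- match.arg(deletions)
  stopifnot(length(haplotypes) == length(frequencies),
            length(haplotypes) >= 1L)
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1")
  }
  L <- L %||% max(nchar(haplotypes))
  lens <- nchar(haplotypes)
  if (any(lens != L)) {
    short <- lens == L - 1L
    if (!all(short | lens == L)) {
      stop("haplotype lengths other than L or L-1 are not supported")
    }
    if (deletions == "exclude") {
      keep <- lens == L
      if (!any(keep)) {
        stop_escape("empty_sample", "no full-length haplotypes to compare")
      }
      haplotypes <- haplotypes[keep]
      frequencies <- frequencies[keep] / sum(frequencies[keep])
    } else {
      if (is.null(reference)) {
        stop("a reference window is required to place deletion haplotypes")
      }
      haplotypes[short] <- vapply(haplotypes[short], function(h) {
        pl <- deletion_placements(reference, h)
        if (is.null(pl)) {
          stop("haplotype is not a single-base deletion of the reference; ",
               "cannot align for diversity")
        }
        # gap marks the deleted reference slot (rightmost placement, matching
        # the first-mismatch position of the canonical labelling)
        paste0(substr(h, 1, pl$rightmost - 1L), "-",
               substr(h, pl$rightmost, nchar(h)))
      }, character(1), USE.NAMES = FALSE)
    }
  }
  n <- length(haplotypes)
  if (n == 1L) return(0)
  chars <- do.call(rbind, strsplit(haplotypes, ""))
  pi_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(chars[i, ] != chars[j, ])
      pi_mat[i, j] <- d
      pi_mat[j, i] <- d
    }
  }
  x <- frequencies
  sum(pi_mat * outer(x, x)) / L
}

#' Haplotype table from classified reads
#'
#' Collapses the accepted windows of a [classify_reads()] result into a
#' frequency table suitable for [nucleotide_diversity()].
#'
#' @param calls A [classify_reads()] result.
#' @return data.frame with columns `haplotype`, `frequency`, `count`.
#' @export
haplotype_table <- function(calls) {
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  if (!nrow(acc)) stop_escape("empty_sample", "no accepted reads")
  tab <- table(acc$window)
  data.frame(haplotype = names(tab),
             frequency = as.numeric(tab) / nrow(acc),
             count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Seed-to-PAM-distal mutant competition read ratio
#'
#' @param seed_mutant_reads,pam_distal_mutant_reads Nonnegative read
#'   counts for the two mutants in one sample.
#' @return seed count / PAM-distal count.
#' @export
competition_ratio <- function(seed_mutant_reads, pam_distal_mutant_reads) {
  stopifnot(seed_mutant_reads >= 0, pam_distal_mutant_reads >= 0)
  if (pam_distal_mutant_reads == 0) {
    stop_escape("undefined_ratio",
                "PAM-distal mutant read count is zero: ratio undefined")
  }
  seed_mutant_reads / pam_distal_mutant_reads
}

#' Fraction-mutated time course across replicates
#'
#' @param times Numeric vector of sampling times.
#' @param replicate_sets List parallel to `times`; each element a list of
#'   [classify_reads()] results (one per replicate).
#' @return data.frame with columns `time`, `mean_fraction`, `sd_fraction`
#'   (NA for single replicates) and `n_replicates`.
#' @export
timecourse_table <- function(times, replicate_sets) {
  stopifnot(length(times) == length(replicate_sets))
  rows <- lapply(seq_along(times), function(i) {
    fr <- vapply(replicate_sets[[i]], fraction_mutated, numeric(1))
    data.frame(time = times[i],
               mean_fraction = mean(fr),
               sd_fraction = if (length(fr) > 1L) stats::sd(fr) else NA_real_,
               n_replicates = length(fr))
  })
  do.call(rbind, rows)
}
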