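# Large-deletion detection in long amplicon reads by two-piece matching
# against the wild-type reference, with junction microhomology
# characterisation and breakpoint normalisation.

#' Call a single large deletion in a long read
#'
#' Matches the read piecewise to the reference as a prefix aligned at the
#' reference start plus a suffix aligned at the reference end, scanning
#' every junction placement: for a junction after read position l, the
#' cost is the number of mismatches of `read[1..l]` against the reference
#' prefix plus mismatches of the remainder against the reference suffix.
#' The minimum-cost junction set is exact at zero sequencing error (its
#' width equals the junction microhomology) and tolerant of isolated
#' substitution errors. The placement is normalised to the leftmost
#' equivalent breakpoint via [microhomology()].
#'
#' Reads equal in length to the reference carry no deletion (`none`).
#' Reads whose best two-piece interpretation still leaves more than
#' `max_mismatch_rate` mismatches per base, or whose junction is within
#' `min_anchor` bases of either read end, are `unresolved` - inconsistent
#' with a single clean deletion but not deletion-free.
#'
#' @param read Read sequence (ACGT).
#' @param reference Wild-type reference sequence of the amplified region.
#' @param min_anchor Minimum matched bases required on each side of the
#'   junction (default 20).
#' @param max_mismatch_rate Tolerated residual mismatch rate per read
#'   base (default 0.01, i.e. 1 per 100 bases).
#' @return One-row data.frame of class `deletion_event` with columns
#'   `status` (`deletion`/`none`/`unresolved`), `del_start`, `del_end`
#'   (1-based closed deleted interval on the reference), `length`,
#'   `homology_length`, `homology_seq`, `ambiguity_left`,
#'   `ambiguity_right` (range of equivalent leftmost breakpoints) and
#'   `mismatches` (residual mismatch count of the best placement).
#' @export
find_deletion <- function(read, reference, min_anchor = 20L,
                          max_mismatch_rate = 0.01) {
  check_dna(read, "read")
  check_dna(reference, "reference")
  stopifnot(min_anchor >= 1L)
  n <- nchar(read)
  m <- nchar(reference)
  if (n > m) {
    stop("read longer than reference: not a deletion candidate")
  }
  none <- deletion_event_row("none")
  if (n == m) return(none)
  d <- m - n
  rc <- strsplit(read, "")[[1]]
  ref <- strsplit(reference, "")[[1]]
  # A[i]: read base i matches reference base i (prefix frame)
  # B[i]: read base i matches reference base i + d (suffix frame)
  a_mis <- cumsum(rc != ref[seq_len(n)])
  b_mis_vec <- rc != ref[seq_len(n) + d]
  b_tail <- rev(cumsum(rev(b_mis_vec)))          # mismatches in B[i..n]
  # cost of junction after read position l (l = 0..n)
  cost <- c(b_tail, 0) + c(0, a_mis)
  best <- min(cost)
  if (best > max_mismatch_rate * n) {
    return(deletion_event_row("unresolved", mismatches = best))
  }
  arg <- which(cost == best) - 1L               # junction read positions l
  l0 <- min(arg)
  l1 <- max(arg)
  if (l0 < min_anchor || n - l1 < min_anchor) {
    return(deletion_event_row("unresolved", mismatches = best))
  }
  # deletion occupies reference positions l0+1 .. l0+d; normalise leftmost
  mh <- microhomology(reference, l0 + 1L, l0 + d)
  deletion_event_row(
    "deletion",
    del_start = mh$del_start,
    del_end = mh$del_end,
    length = d,
    homology_length = mh$homology_length,
    homology_seq = mh$homology_seq,
    ambiguity_left = mh$ambiguity_left,
    ambiguity_right = mh$ambiguity_right,
    mismatches = best
  )
}

deletion_event_row <- function(status,
                               del_start = NA_integer_,
                               del_end = NA_integer_,
                               length = NA_integer_,
                               homology_length = NA_integer_,
                               homology_seq = NA_character_,
                               ambiguity_left = NA_integer_,
                               ambiguity_right = NA_integer_,
                               mismatches = NA_integer_) {
  structure(
    data.frame(status = status, del_start = del_start, del_end = del_end,
               length = length, homology_length = homology_length,
               homology_seq = homology_seq, ambiguity_left = ambiguity_left,
               ambiguity_right = ambiguity_right,
               mismatches = as.integer(mismatches),
               stringsAsFactors = FALSE),
    class = c("deletion_event", "data.frame")
  )
}

#' Junction microhomology of a deletion
#'
#' Normalises the deleted interval `[del_start, del_end]` (1-based
#' closed) to its leftmost equivalent placement, then measures the
#' maximal homology h for which the h-mer starting at the left breakpoint
#' equals the h-mer starting just right of the deleted interval. All
#' placements shifting the deletion right by 0..h bases excise the same
#' sequence; the ambiguity interval spans those equivalent left
#' breakpoints and its width equals `homology_length`.
#'
#' @param reference Reference sequence.
#' @param del_start,del_end 1-based closed deleted interval.
#' @return List with `del_start`, `del_end` (leftmost placement),
#'   `homology_length`, `homology_seq`, `ambiguity_left`,
#'   `ambiguity_right`.
#' @export
microhomology <- function(reference, del_start, del_end) {
  m <- nchar(reference)
  stopifnot(del_start >= 1L, del_end >= del_start, del_end <= m)
  ref <- strsplit(reference, "")[[1]]
  l <- as.integer(del_start)
  d <- as.integer(del_end - del_start + 1L)
  # shift left while the base entering the deletion equals the one leaving it
  while (l > 1L && ref[l - 1L] == ref[l + d - 1L]) l <- l - 1L
  h <- 0L
  while (l + d + h <= m && ref[l + h] == ref[l + d + h]) h <- h + 1L
  list(
    del_start = l,
    del_end = l + d - 1L,
    homology_length = h,
    homology_seq = if (h > 0L) paste(ref[l:(l + h - 1L)], collapse = "") else "",
    ambiguity_left = l,
    ambiguity_right = l + h
  )
}

#' Call deletions across a set of long reads
#'
#' @param reads data.frame with columns `id`, `seq` (e.g. from
#'   [read_fastq()] or [emit_long_reads()]).
#' @param reference Reference sequence.
#' @inheritParams find_deletion
#' @return data.frame with one row per read: `read_id` plus the
#'   [find_deletion()] columns.
#' @export
find_deletions <- function(reads, reference, min_anchor = 20L,
                           max_mismatch_rate = 0.01) {
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    ev <- find_deletion(reads$seq[i], reference, min_anchor,
                        max_mismatch_rate)
    cbind(read_id = reads$id[i], ev, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate deletion events by canonical breakpoints
#'
#' Events are keyed by their leftmost-normalised breakpoints (events
#' whose equivalent-placement sets overlap share that key), support is
#' summed, and breakpoints are translated to genome coordinates by the
#' amplicon's genomic offset.
#'
#' @param events A [find_deletions()] result (rows with status
#'   `deletion`; other rows are ignored).
#' @param genome_offset Integer offset added to amplicon coordinates.
#' @return data.frame with columns `del_start`, `del_end`, `genome_start`,
#'   `genome_end`, `length`, `homology_length`, `homology_seq`,
#'   `support`, sorted by `del_start`.
#' @export
aggregate_deletions <- function(events, genome_offset = 0L) {
  ev <- events[events$status == "deletion", , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(del_start = integer(), del_end = integer(),
                      genome_start = integer(), genome_end = integer(),
                      length = integer(), homology_length = integer(),
                      homology_seq = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ev$del_start, ev$del_end, sep = ":")
  agg <- lapply(split(ev, key), function(g) {
    data.frame(del_start = g$del_start[1], del_end = g$del_end[1],
               genome_start = g$del_start[1] + genome_offset,
               genome_end = g$del_end[1] + genome_offset,
               length = g$length[1],
               homology_length = g$homology_length[1],
               homology_seq = g$homology_seq[1],
               support = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$del_start, out$del_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write aggregated deletions as a BED track of deleted genome intervals
#'
#' @param agg An [aggregate_deletions()] result.
#' @param path Output path.
#' @param chrom Chromosome/contig name for the BED records.
#' @export
write_deletion_bed <- function(agg, path, chrom = "lambda") {
  bed <- data.frame(chrom = chrom,
                    start = agg$genome_start - 1L,  # BED is 0-based half-open
                    end = agg$genome_end,
                    name = sprintf("del_%d_%d", agg$del_start, agg$del_end),
                    score = agg$support)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
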