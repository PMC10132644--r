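# Target-window extraction, R1/R2 concordance filtering and mutation
# classification for amplicon deep-sequencing read pairs.

#' Extract the target window from a read sequence
#'
#' Locates the window by exact match of the two flank anchors; if either
#' anchor is not found exactly, a fallback search allowing at most one
#' mismatch per anchor (no indels) is attempted. The returned subsequence
#' may be shorter than the reference window when the read carries a
#' deletion. Anchors occurring more than once, or in the wrong order,
#' make the read unalignable.
#'
#' @param read_sequence Read sequence oriented to the amplicon plus strand.
#' @param spec A [target_spec()].
#' @return The window sequence, or `NA_character_` when the window cannot
#'   be located.
#' @export
extract_window <- function(read_sequence, spec) {
  extract_windows(read_sequence, spec)
}

# Vectorised extraction over many reads; exact anchor matching first,
# 1-mismatch fallback (via Biostrings) only on the leftovers.
extract_windows <- function(seqs, spec) {
  out <- rep(NA_character_, length(seqs))
  la <- spec$anchor_left
  ra <- spec$anchor_right
  l_pos <- anchor_position_exact(seqs, la)
  r_pos <- anchor_position_exact(seqs, ra)
  ok <- !is.na(l_pos) & !is.na(r_pos)
  retry <- which(!ok & !is.na(seqs))
  if (length(retry)) {
    l_pos[retry] <- ifelse(is.na(l_pos[retry]),
                           anchor_position_fuzzy(seqs[retry], la),
                           l_pos[retry])
    r_pos[retry] <- ifelse(is.na(r_pos[retry]),
                           anchor_position_fuzzy(seqs[retry], ra),
                           r_pos[retry])
    ok <- !is.na(l_pos) & !is.na(r_pos)
  }
  start <- l_pos + nchar(la)
  end <- r_pos - 1L
  good <- ok & start <= end + 1L & r_pos > l_pos
  out[good] <- substr(seqs[good], start[good], end[good])
  out
}

# Position of a unique exact anchor hit; NA if absent or ambiguous.
anchor_position_exact <- function(seqs, anchor) {
  first <- regexpr(anchor, seqs, fixed = TRUE)
  pos <- ifelse(first == -1L, NA_integer_, as.integer(first))
  hit <- which(!is.na(pos))
  if (length(hit)) {
    # ambiguity check: a second occurrence after the first disqualifies
    rest <- substr(seqs[hit], pos[hit] + 1L, nchar(seqs[hit]))
    again <- regexpr(anchor, rest, fixed = TRUE)
    pos[hit][again != -1L] <- NA_integer_
  }
  pos
}

# Unique anchor hit allowing <=1 mismatch (no indels); NA if 0 or >1 hits.
anchor_position_fuzzy <- function(seqs, anchor) {
  vapply(seqs, function(s) {
    if (is.na(s) || grepl("[^ACGT]", s)) return(NA_integer_)
    m <- Biostrings::matchPattern(anchor, Biostrings::DNAString(s),
                                  max.mismatch = 1)
    if (length(m) == 1L) as.integer(Biostrings::start(m)) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Merge a read pair into a single target-window call
#'
#' Applies the concordance rule used for amplicon pairs designed so both
#' mates overlap the whole protospacer + PAM window: when both mates
#' cover the window, their window sequences must agree exactly or the
#' pair is removed from analysis (`rejected_discordant`); when only one
#' mate covers it (R1 by design; the symmetric R2-only case is handled
#' the same way), that mate's window is used. Pairs in which neither mate
#' yields the window are `rejected_unalignable`.
#'
#' @param r1,r2 Character vectors of R1 and R2 read sequences (raw
#'   orientation; R2 is reverse-complemented internally).
#' @param spec A [target_spec()].
#' @param read_id Optional read identifiers.
#' @param require_concordance If `FALSE`, disagreeing pairs fall back to
#'   the R1 window instead of being rejected (the relaxed behaviour;
#'   default enforces concordance for all samples).
#' @return data.frame with columns `read_id`, `status`
#'   (`accepted`/`rejected_discordant`/`rejected_unalignable`), `window`.
#' @export
merge_pairs <- function(r1, r2, spec, read_id = NULL,
                        require_concordance = TRUE) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  read_id <- read_id %||% sprintf("pair%06d", seq_len(n))
  w1 <- extract_windows(toupper(r1), spec)
  w2 <- extract_windows(revcomp(toupper(r2)), spec)
  status <- rep("rejected_unalignable", n)
  window <- rep(NA_character_, n)
  both <- !is.na(w1) & !is.na(w2)
  agree <- both & w1 == w2
  status[agree] <- "accepted"
  window[agree] <- w1[agree]
  disagree <- both & w1 != w2
  if (require_concordance) {
    status[disagree] <- "rejected_discordant"
  } else {
    status[disagree] <- "accepted"
    window[disagree] <- w1[disagree]
  }
  only1 <- !is.na(w1) & is.na(w2)
  status[only1] <- "accepted"
  window[only1] <- w1[only1]
  only2 <- is.na(w1) & !is.na(w2)
  status[only2] <- "accepted"
  window[only2] <- w2[only2]
  data.frame(read_id = read_id, status = status, window = window,
             stringsAsFactors = FALSE)
}

#' @rdname merge_pairs
#' @export
merge_pair <- function(r1, r2, spec, require_concordance = TRUE) {
  merge_pairs(r1, r2, spec, require_concordance = require_concordance)
}

#' Classify a target-window sequence against the reference
#'
#' Equal-length windows are compared positionwise: 0 differences is
#' `wildtype`, 1 is `single_substitution`, 2 or more is
#' `multiple_substitution`. A window one base short is a
#' `single_deletion`: the excised base is resolved to its leftmost
#' placement within any homopolymer run and reported at the adjacent
#' position to the 3' side (canonical label); the alternative
#' first-mismatch label is stored alongside. Any other length, or a
#' window that cannot be explained by a single deletion, is `complex`.
#' Windows with non-ACGT characters are unalignable.
#'
#' @param window Window sequence (character scalar or vector).
#' @param spec A [target_spec()].
#' @return data.frame with columns `window`, `variant_class`, `n_variants`
#'   and `variants` (list column of per-window variant tables with
#'   `offset`, `index`, `ref`, `alt`, `label`, plus for deletions
#'   `offset_first`, `index_first`, `label_first`).
#' @export
classify_window <- function(window, spec) {
  refwin <- reference_window(spec)
  labels <- position_labels(spec)
  res <- lapply(window, classify_one_window, refwin = refwin,
                labels = labels)
  data.frame(
    window = window,
    variant_class = vapply(res, `[[`, character(1), "class"),
    n_variants = vapply(res, function(x) nrow(x$variants), integer(1)),
    variants = I(lapply(res, `[[`, "variants")),
    stringsAsFactors = FALSE
  )
}

empty_variants <- function() {
  data.frame(offset = integer(), index = integer(), ref = character(),
             alt = character(), label = character(),
             stringsAsFactors = FALSE)
}

classify_one_window <- function(w, refwin, labels) {
  L <- nchar(refwin)
  if (is.na(w) || grepl("[^ACGT]", w)) {
    return(list(class = "unalignable", variants = empty_variants()))
  }
  if (nchar(w) == L) {
    rc <- strsplit(refwin, "")[[1]]
    oc <- strsplit(w, "")[[1]]
    diff <- which(rc != oc)
    if (!length(diff)) {
      return(list(class = "wildtype", variants = empty_variants()))
    }
    v <- data.frame(
      offset = diff,
      index = labels$index[diff],
      ref = rc[diff],
      alt = oc[diff],
      label = variant_label(rc[diff], labels$index[diff], oc[diff]),
      stringsAsFactors = FALSE
    )
    cls <- if (length(diff) == 1L) "single_substitution" else "multiple_substitution"
    return(list(class = cls, variants = v))
  }
  if (nchar(w) == L - 1L) {
    pl <- deletion_placements(refwin, w)
    if (is.null(pl)) {
      return(list(class = "complex", variants = empty_variants()))
    }
    # first positionwise mismatch = rightmost equivalent placement; the
    # canonical label sits one base further, 3' of the homopolymer run
    # (clamped at the window edge)
    first <- pl$rightmost
    canon <- min(pl$rightmost + 1L, L)
    rc <- strsplit(refwin, "")[[1]]
    del_base <- rc[pl$leftmost]
    v <- data.frame(
      offset = canon,
      index = labels$index[canon],
      ref = del_base,
      alt = "del",
      label = variant_label(del_base, labels$index[canon], "del"),
      stringsAsFactors = FALSE
    )
    v$offset_first <- first
    v$index_first <- labels$index[first]
    v$label_first <- variant_label(del_base, labels$index[first], "del")
    return(list(class = "single_deletion", variants = v))
  }
  list(class = "complex", variants = empty_variants())
}

# All reference offsets i such that deleting refwin[i] yields `w`
# (equivalent placements within a homopolymer run); NULL when `w` is not a
# clean single-base deletion of the reference window.
deletion_placements <- function(refwin, w) {
  L <- nchar(refwin)
  stopifnot(nchar(w) == L - 1L)
  rc <- strsplit(refwin, "")[[1]]
  oc <- strsplit(w, "")[[1]]
  p <- 0L
  while (p < L - 1L && rc[p + 1L] == oc[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < L - 1L && rc[L - s] == oc[L - 1L - s]) s <- s + 1L
  if (p + s < L - 1L) return(NULL)
  lo <- max(1L, L - s)
  hi <- min(L, p + 1L)
  if (lo > hi) return(NULL)
  list(leftmost = lo, rightmost = hi, placements = lo:hi)
}

#' Classify merged read pairs
#'
#' Runs [classify_window()] over the accepted windows of a
#' [merge_pairs()] table (memoised over unique windows) and returns the
#' per-read classification. Rejected reads keep their status and carry no
#' class.
#'
#' @param merged A [merge_pairs()] result.
#' @param spec A [target_spec()].
#' @return data.frame of class `classified_reads`: columns `read_id`,
#'   `status`, `window`, `variant_class`, `n_variants`, `variants`
#'   (list column), `labels` (comma-joined canonical variant labels).
#' @export
classify_reads <- function(merged, spec) {
  out <- merged
  out$variant_class <- NA_character_
  out$n_variants <- NA_integer_
  out$variants <- I(vector("list", nrow(out)))
  acc <- which(out$status == "accepted")
  if (length(acc)) {
    uw <- unique(out$window[acc])
    cls <- classify_window(uw, spec)
    m <- match(out$window[acc], uw)
    out$variant_class[acc] <- cls$variant_class[m]
    out$n_variants[acc] <- cls$n_variants[m]
    out$variants[acc] <- cls$variants[m]
    # windows that fail classification (non-ACGT) become unalignable
    bad <- acc[out$variant_class[acc] == "unalignable"]
    if (length(bad)) {
      out$status[bad] <- "rejected_unalignable"
      out$variant_class[bad] <- NA_character_
      out$n_variants[bad] <- NA_integer_
      out$variants[bad] <- list(NULL)
    }
  }
  out$labels <- vapply(out$variants, function(v) {
    if (is.null(v) || !nrow(v)) "" else paste(v$label, collapse = ",")
  }, character(1))
  class(out) <- c("classified_reads", "data.frame")
  out
}

#' Tabulate per-position mutated-read proportions
#'
#' For each PAM-relative position, the proportion of accepted reads
#' carrying any variant at that position; a multiple-substitution read
#' increments every mutated position, and single-base deletions are
#' counted at their canonical (3'-adjacent) label by default. A per-type
#' breakdown (e.g. `A>C`, `del`) is attached.
#'
#' @param calls A [classify_reads()] result.
#' @param spec A [target_spec()].
#' @param sample_id Sample identifier carried into the result.
#' @param deletion_convention `"3prime_adjacent"` (canonical) or
#'   `"first_mismatch"`: which stored deletion label feeds the tabulation.
#' @return Object of class `position_matrix`: list with `sample_id`,
#'   `n_accepted`, `positions` (signed indices), `proportions` (named
#'   numeric) and `by_type` (data.frame `index`, `type`, `fraction`).
#' @export
tabulate_variants <- function(calls, spec, sample_id = "sample",
                              deletion_convention = c("3prime_adjacent",
                                                      "first_mismatch")) {
  deletion_convention <- match.arg(deletion_convention)
  labels <- position_labels(spec)
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  if (!nrow(acc)) {
    stop_escape("empty_sample", "no accepted reads to tabulate")
  }
  n <- nrow(acc)
  counts <- stats::setNames(numeric(nrow(labels)), labels$index)
  type_counts <- list()
  for (v in acc$variants) {
    if (is.null(v) || !nrow(v)) next
    idx <- v$index
    typ <- ifelse(v$alt == "del", "del", paste0(v$ref, ">", v$alt))
    if (deletion_convention == "first_mismatch" && "index_first" %in% names(v)) {
      del <- v$alt == "del"
      idx[del] <- v$index_first[del]
    }
    for (k in seq_along(idx)) {
      key <- as.character(idx[k])
      counts[key] <- counts[key] + 1
      tkey <- paste0(key, "|", typ[k])
      type_counts[[tkey]] <- (type_counts[[tkey]] %||% 0) + 1
    }
  }
  by_type <- if (length(type_counts)) {
    parts <- strsplit(names(type_counts), "|", fixed = TRUE)
    data.frame(
      index = as.integer(vapply(parts, `[[`, character(1), 1L)),
      type = vapply(parts, `[[`, character(1), 2L),
      fraction = unlist(type_counts, use.names = FALSE) / n,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(index = integer(), type = character(), fraction = numeric())
  }
  structure(
    list(sample_id = sample_id,
         n_accepted = n,
         positions = labels$index,
         proportions = counts / n,
         by_type = by_type),
    class = "position_matrix"
  )
}

#' @export
print.position_matrix <- function(x, ...) {
  cat("<position_matrix> sample ", x$sample_id, ": ", x$n_accepted,
      " accepted reads, ", sum(x$proportions > 0),
      " positions with variants\n", sep = "")
  invisible(x)
}

#' Fraction of accepted reads carrying any target mutation
#'
#' @param calls A [classify_reads()] result.
#' @return Fraction in [0, 1].
#' @export
fraction_mutated <- function(calls) {
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  if (!nrow(acc)) {
    stop_escape("empty_sample", "no accepted reads")
  }
  mean(acc$variant_class != "wildtype")
}
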