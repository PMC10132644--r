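#' Describe a protospacer+PAM target window on an amplicon
#'
#' A target spec ties together the amplicon reference sequence, the
#' coordinates of the PAM + protospacer window on it, the PAM geometry
#' (Cas12a-style 5' TTTV PAMs or Cas9-style 3' NGG PAMs), and the short
#' flanking anchor sequences used to locate the window inside reads.
#'
#' Coordinates are 1-based and closed: the window occupies
#' `window_start..window_end` on the amplicon plus strand and its length
#' must equal `pam_length + protospacer_length` (24 for the default
#' 4 nt PAM + 20 nt protospacer used throughout).
#'
#' Position reporting is PAM-relative: PAM positions are negative with -1
#' adjacent to protospacer position 1, and protospacer positions run
#' 1..`protospacer_length` from the PAM-proximal end. Seed/mid/PAM-distal
#' region boundaries are configurable; defaults are seed = 1-6, mid = 7-12,
#' PAM-distal = 13 onwards.
#'
#' @param amplicon_reference Amplicon reference sequence (ACGT string).
#' @param window_start,window_end 1-based closed coordinates of the
#'   PAM+protospacer window on the amplicon.
#' @param pam_side `"5prime"` (Cas12a-like) or `"3prime"` (Cas9-like):
#'   which side of the protospacer carries the PAM, on the amplicon
#'   plus strand as given.
#' @param pam_length PAM length in nt (4 for TTTV-class, 3 for NGG-class).
#' @param protospacer_length Protospacer length in nt (default 20).
#' @param anchor_length Length of the flanking anchors lifted from the
#'   reference immediately outside the window (default 12 nt).
#' @param seed_region,mid_region Integer vectors of protospacer positions
#'   assigned to the seed and mid regions.
#' @param genome_offset Offset added to amplicon coordinates to obtain
#'   genome coordinates (0 if the amplicon frame is not anchored).
#'
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(amplicon_reference,
                        window_start,
                        window_end,
                        pam_side = c("5prime", "3prime"),
                        pam_length = 4L,
                        protospacer_length = 20L,
                        anchor_length = 12L,
                        seed_region = 1:6,
                        mid_region = 7:12,
                        genome_offset = 0L) {
  pam_side <- match.arg(pam_side)
  amplicon_reference <- toupper(amplicon_reference)
  check_dna(amplicon_reference, "amplicon reference")
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  pam_length <- as.integer(pam_length)
  protospacer_length <- as.integer(protospacer_length)
  L <- pam_length + protospacer_length
  if (window_end - window_start + 1L != L) {
    stop("window length must equal pam_length + protospacer_length (",
         L, " nt)")
  }
  if (window_start - anchor_length < 1L ||
      window_end + anchor_length > nchar(amplicon_reference)) {
    stop("amplicon reference too short to provide ", anchor_length,
         " nt flank anchors around the window")
  }
  anchor_left <- substr(amplicon_reference,
                        window_start - anchor_length, window_start - 1L)
  anchor_right <- substr(amplicon_reference,
                         window_end + 1L, window_end + anchor_length)
  for (a in c(anchor_left, anchor_right)) {
    hits <- gregexpr(a, amplicon_reference, fixed = TRUE)[[1]]
    if (length(hits) != 1L || hits[1] == -1L) {
      stop("flank anchor '", a,
           "' does not occur exactly once in the amplicon reference; ",
           "increase anchor_length")
    }
  }
  spec <- structure(
    list(
      amplicon_reference = amplicon_reference,
      window_start = window_start,
      window_end = window_end,
      pam_side = pam_side,
      pam_length = pam_length,
      protospacer_length = protospacer_length,
      anchor_left = anchor_left,
      anchor_right = anchor_right,
      seed_region = as.integer(seed_region),
      mid_region = as.integer(mid_region),
      genome_offset = as.integer(genome_offset)
    ),
    class = "target_spec"
  )
  spec
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec> ", x$pam_length, " nt ", x$pam_side, " PAM + ",
      x$protospacer_length, " nt protospacer; window ",
      x$window_start, "-", x$window_end, " on a ",
      nchar(x$amplicon_reference), " nt amplicon\n", sep = "")
  cat("  reference window:", reference_window(x), "\n")
  invisible(x)
}

#' Reference sequence of the target window
#' @param spec A [target_spec()].
#' @return The PAM+protospacer reference sequence.
#' @export
reference_window <- function(spec) {
  substr(spec$amplicon_reference, spec$window_start, spec$window_end)
}

#' PAM-relative position labels of the target window
#'
#' Maps each offset of the window string (left to right on the amplicon
#' plus strand) to its signed PAM-relative index and region. For a 5' PAM
#' the window reads PAM then protospacer, so indices run
#' -pam_length..-1, 1..N; for a 3' PAM the protospacer comes first with
#' position 1 PAM-proximal (rightmost), so indices run N..1, -1..-pam_length.
#'
#' @param spec A [target_spec()].
#' @return A data.frame with columns `offset` (1-based window offset),
#'   `index` (signed PAM-relative position) and `region`
#'   (`PAM`/`seed`/`mid`/`PAM-distal`).
#' @export
position_labels <- function(spec) {
  n <- spec$protospacer_length
  p <- spec$pam_length
  if (spec$pam_side == "5prime") {
    index <- c(-(p:1), seq_len(n))
  } else {
    index <- c(rev(seq_len(n)), -(1:p))
  }
  region <- ifelse(index < 0, "PAM",
            ifelse(index %in% spec$seed_region, "seed",
            ifelse(index %in% spec$mid_region, "mid", "PAM-distal")))
  data.frame(offset = seq_len(p + n), index = index, region = region,
             stringsAsFactors = FALSE)
}

# Variant label in the field's convention: ref base, signed PAM-relative
# index, alt base -- "T-2C" is PAM position -2 ref T to C; deletions use
# alt "del".
variant_label <- function(ref, index, alt) {
  paste0(ref, index, alt)
}

#' Synthetic lambda-like demonstration targets
#'
#' Builds a reproducible synthetic amplicon and [target_spec()] emulating
#' the geometry of a lambda phage Cas12a target (4 nt TTTV-class 5' PAM +
#' 20 nt protospacer, 24 nt window) embedded in a longer amplicon. The
#' sequences are synthetic stand-ins, not the phage genome.
#'
#' @param target `"geneJ"` (intergenic-style target) or `"geneL"`
#'   (coding-style target); the two differ only in sequence seed.
#' @param amplicon_length Total synthetic amplicon length.
#' @return A [target_spec()].
#' @export
demo_target_spec <- function(target = c("geneJ", "geneL"),
                             amplicon_length = 140L) {
  target <- match.arg(target)
  seed <- if (target == "geneJ") 101L else 202L
  with_seed(seed, {
    amp <- random_dna(amplicon_length)
    start <- 61L
    # plant a TTTA PAM so the window looks like a canonical Cas12a site
    substr(amp, start, start + 3L) <- "TTTA"
    target_spec(amp, window_start = start, window_end = start + 23L,
                pam_side = "5prime", pam_length = 4L,
                protospacer_length = 20L)
  })
}
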