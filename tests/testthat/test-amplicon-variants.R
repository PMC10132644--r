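spec <- fixture_spec()
refwin <- reference_window(spec)
amp <- spec$amplicon_reference

test_that("window extraction recovers the reference window and deletions", {
  expect_equal(extract_window(amp, spec), refwin)
  expect_equal(nchar(extract_window(amp, spec)), 24L)
  # a 1-nt deletion inside the window shortens the extracted sequence
  del_amp <- paste0(substr(amp, 1, spec$window_start + 4),
                    substr(amp, spec$window_start + 6, nchar(amp)))
  expect_equal(nchar(extract_window(del_amp, spec)), 23L)
})

test_that("anchor tolerance is exactly one mismatch per anchor", {
  # enumerate anchor corruption: 1 mismatch in the left anchor still locates
  # the window; 2 mismatches fail it
  anchor_start <- spec$window_start - nchar(spec$anchor_left)
  one <- amp
  substr(one, anchor_start, anchor_start) <-
    setdiff(BASES, substr(amp, anchor_start, anchor_start))[1]
  expect_equal(extract_window(one, spec), refwin)
  two <- one
  p2 <- anchor_start + 2L
  substr(two, p2, p2) <- setdiff(BASES, substr(amp, p2, p2))[1]
  expect_true(is.na(extract_window(two, spec)))
})

test_that("duplicated or out-of-order anchors make a read unalignable", {
  dup <- paste0(amp, spec$anchor_left)
  expect_true(is.na(extract_window(dup, spec)))
  swapped <- paste0(spec$anchor_right, "ACGT", spec$anchor_left)
  expect_true(is.na(extract_window(swapped, spec)))
})

test_that("pair merging enforces the R1/R2 concordance rule", {
  r1 <- substr(amp, 1, 100)
  r2 <- revcomp(substr(amp, nchar(amp) - 99, nchar(amp)))
  m <- merge_pairs(r1, r2, spec)
  expect_equal(m$status, "accepted")
  expect_equal(m$window, refwin)

  # one-base disagreement inside the window is removed from analysis
  amp2 <- amp
  substr(amp2, spec$window_start + 3, spec$window_start + 3) <-
    setdiff(BASES, substr(amp, spec$window_start + 3, spec$window_start + 3))[1]
  r2_bad <- revcomp(substr(amp2, nchar(amp2) - 99, nchar(amp2)))
  m2 <- merge_pairs(r1, r2_bad, spec)
  expect_equal(m2$status, "rejected_discordant")

  # ... unless concordance is relaxed, in which case R1 wins
  m2r <- merge_pairs(r1, r2_bad, spec, require_concordance = FALSE)
  expect_equal(m2r$status, "accepted")
  expect_equal(m2r$window, refwin)

  # R2 truncated before the window: R1's window is used
  r2_short <- revcomp(substr(amp, nchar(amp) - 19, nchar(amp)))
  m3 <- merge_pairs(r1, r2_short, spec)
  expect_equal(m3$status, "accepted")
  expect_equal(m3$window, refwin)

  # neither mate reaches the window
  m4 <- merge_pairs(substr(amp, 1, 20), r2_short, spec)
  expect_equal(m4$status, "rejected_unalignable")
})

test_that("classification partitions equal-length windows by mismatch count", {
  expect_equal(classify_window(refwin, spec)$variant_class, "wildtype")
  one <- mutate_at(refwin, 10)
  expect_equal(classify_window(one, spec)$variant_class, "single_substitution")
  two <- mutate_at(one, 15)
  expect_equal(classify_window(two, spec)$variant_class,
               "multiple_substitution")
  # length L-2 or unexplainable length L-1 windows are complex
  expect_equal(classify_window(substr(refwin, 1, 22), spec)$variant_class,
               "complex")
})

test_that("substitution labels use the PAM-relative naming convention", {
  # protospacer position 2 sits at window offset pam_length + 2
  off <- spec$pam_length + 2L
  ref_base <- substr(refwin, off, off)
  alt <- setdiff(BASES, ref_base)[1]
  v <- classify_window(mutate_at(refwin, off, alt), spec)$variants[[1]]
  expect_equal(v$index, 2L)
  expect_equal(v$label, paste0(ref_base, "2", alt))
  # PAM position -2 is window offset pam_length - 1
  offp <- spec$pam_length - 1L
  refp <- substr(refwin, offp, offp)
  altp <- setdiff(BASES, refp)[1]
  vp <- classify_window(mutate_at(refwin, offp, altp), spec)$variants[[1]]
  expect_equal(vp$index, -2L)
  expect_equal(vp$label, paste0(refp, "-2", altp))
})

test_that("single-deletion labels are stable across homopolymer placements", {
  # build a window with a 3-run and delete each base of the run in turn:
  # every excision yields the same observed window, hence the same canonical
  # (3'-adjacent) and first-mismatch labels
  win <- paste0("TTTA", "GGCCCAT", paste(rep("A", 13), collapse = ""))
  spec_run <- with(list(), {
    base <- fixture_spec()
    a <- base$amplicon_reference
    substr(a, base$window_start, base$window_end) <- win
    target_spec(a, base$window_start, base$window_end,
                pam_side = "5prime", pam_length = 4L,
                protospacer_length = 20L)
  })
  run_offsets <- 7:9  # the CCC run
  observed <- vapply(run_offsets, function(i) {
    paste0(substr(win, 1, i - 1), substr(win, i + 1, nchar(win)))
  }, character(1))
  expect_equal(length(unique(observed)), 1L)
  cls <- classify_window(observed[1], spec_run)
  expect_equal(cls$variant_class, "single_deletion")
  v <- cls$variants[[1]]
  # first mismatch at the last run position, canonical one base 3' of it
  expect_equal(v$offset_first, 9L)
  expect_equal(v$offset, 10L)
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "del")
})

test_that("every single-deletion alignment yields one canonical label", {
  # enumerate all 24 single-base excisions of the reference window; each
  # observed sequence must classify as a single deletion whose canonical
  # offset is one past the rightmost equivalent placement
  set.seed(4)
  for (i in 1:24) {
    obs <- paste0(substr(refwin, 1, i - 1), substr(refwin, i + 1, 24))
    cls <- classify_window(obs, spec)
    expect_equal(cls$variant_class, "single_deletion")
    v <- cls$variants[[1]]
    expect_gte(v$offset_first, i - 0L)  # placement at or 3' of the excised base
    expect_equal(v$offset, min(v$offset_first + 1L, 24L))
  }
})

test_that("tabulation counts reads per position with multi-hit reads at every site", {
  one <- mutate_at(refwin, spec$pam_length + 2L)        # protospacer pos 2
  multi <- mutate_at(mutate_at(refwin, spec$pam_length + 14L),
                     spec$pam_length + 18L)             # positions 14 and 18
  windows <- c(rep(refwin, 8), one, multi)
  calls <- classify_reads(
    data.frame(read_id = paste0("r", 1:10), status = "accepted",
               window = windows, stringsAsFactors = FALSE),
    spec
  )
  pm <- tabulate_variants(calls, spec)
  expect_equal(pm$n_accepted, 10L)
  expect_equal(unname(pm$proportions[["2"]]), 0.1)
  expect_equal(unname(pm$proportions[["14"]]), 0.1)
  expect_equal(unname(pm$proportions[["18"]]), 0.1)
  expect_equal(sum(pm$proportions > 0), 3L)
})

test_that("tabulation equals an independent per-position recount", {
  set.seed(77)
  windows <- vapply(1:300, function(i) {
    w <- refwin
    k <- sample(0:3, 1)
    for (j in sample(1:24, k)) w <- mutate_at(w, j)
    w
  }, character(1))
  calls <- classify_reads(
    data.frame(read_id = paste0("r", seq_along(windows)),
               status = "accepted", window = windows,
               stringsAsFactors = FALSE),
    spec
  )
  pm <- tabulate_variants(calls, spec)
  labels <- position_labels(spec)
  # brute-force recount: compare every window to the reference directly
  for (off in seq_len(24)) {
    expected <- mean(substr(windows, off, off) != substr(refwin, off, off))
    expect_equal(unname(pm$proportions[[as.character(labels$index[off])]]),
                 expected, tolerance = 1e-12)
  }
})

test_that("fraction mutated is the non-wildtype share of accepted reads", {
  windows <- c(rep(refwin, 80), rep(mutate_at(refwin, 5), 20))
  calls <- classify_reads(
    data.frame(read_id = paste0("r", seq_along(windows)),
               status = "accepted", window = windows,
               stringsAsFactors = FALSE),
    spec
  )
  expect_equal(fraction_mutated(calls), 0.2)
  all_wt <- classify_reads(
    data.frame(read_id = "r1", status = "accepted", window = refwin,
               stringsAsFactors = FALSE), spec)
  expect_equal(fraction_mutated(all_wt), 0)
  none <- classify_reads(
    data.frame(read_id = "r1", status = "rejected_unalignable",
               window = NA_character_, stringsAsFactors = FALSE), spec)
  expect_error(fraction_mutated(none), class = "empty_sample")
  expect_error(tabulate_variants(none, spec), class = "empty_sample")
})

test_that("status partition is exhaustive and classes are exclusive", {
  reads <- emit_amplicon_reads(
    stats::setNames(c(400L, 100L),
                    c(refwin, mutate_at(refwin, 9))),
    spec, read_length = 100, seq_error_rate = 0.01,
    discordance_rate = 0.1, seed = 31
  )
  m <- merge_pairs(reads$r1$seq, reads$r2$seq, spec, read_id = reads$r1$id)
  calls <- classify_reads(m, spec)
  expect_equal(nrow(calls), 500L)
  expect_true(all(calls$status %in% c("accepted", "rejected_discordant",
                                      "rejected_unalignable")))
  acc <- calls[calls$status == "accepted", ]
  expect_true(all(acc$variant_class %in%
    c("wildtype", "single_substitution", "multiple_substitution",
      "single_deletion", "complex")))
  expect_true(all(is.na(calls$variant_class[calls$status != "accepted"])))
})
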