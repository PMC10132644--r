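test_that("a clean excision is recovered with exact breakpoints", {
  ref <- build_deletion_reference(2000, data.frame(del_start = 601,
                                                   del_end = 650, mh = 0),
                                  seed = 1)
  read <- paste0(substr(ref, 1, 600), substr(ref, 651, 2000))
  ev <- find_deletion(read, ref)
  expect_equal(ev$status, "deletion")
  expect_equal(ev$del_start, 601L)
  expect_equal(ev$del_end, 650L)
  expect_equal(ev$length, 50L)
  expect_equal(ev$homology_length, 0L)
  expect_equal(ev$ambiguity_right - ev$ambiguity_left, 0L)
})

test_that("an unmutated read yields no deletion call", {
  ref <- with(list(), { set.seed(2); paste(sample(BASES, 500, TRUE), collapse = "") })
  expect_equal(find_deletion(ref, ref)$status, "none")
})

test_that("microhomology widens the placement set and is reported leftmost", {
  ref <- build_deletion_reference(3000, data.frame(del_start = 1001,
                                                   del_end = 1200, mh = 3),
                                  seed = 3)
  # excise at a shifted (non-canonical) placement inside the homology window:
  # the same read results, and the caller must still report the leftmost
  for (shift in 0:3) {
    read <- paste0(substr(ref, 1, 1000 + shift),
                   substr(ref, 1201 + shift, 3000))
    ev <- find_deletion(read, ref)
    expect_equal(ev$status, "deletion")
    expect_equal(ev$del_start, 1001L)
    expect_equal(ev$del_end, 1200L)
    expect_equal(ev$homology_length, 3L)
    expect_equal(ev$ambiguity_left, 1001L)
    expect_equal(ev$ambiguity_right, 1004L)
  }
  # brute force: exactly homology_length + 1 equivalent placements exist
  excised <- paste0(substr(ref, 1, 1000), substr(ref, 1201, 3000))
  valid <- vapply(900:1100, function(l) {
    identical(paste0(substr(ref, 1, l - 1), substr(ref, l + 200, 3000)),
              excised)
  }, logical(1))
  expect_equal(sum(valid), 4L)
  expect_equal((900:1100)[valid], 1001:1004)
})

test_that("engineered 4-mer junction homology is identified exactly", {
  # hand-build a reference where GCTA immediately precedes both breakpoints
  set.seed(9)
  left_flank <- paste(sample(BASES, 96, TRUE), collapse = "")
  mid <- paste(sample(BASES, 146, TRUE), collapse = "")
  right_flank <- paste(sample(BASES, 150, TRUE), collapse = "")
  # guard against accidental homology extension past the planted 4-mer
  if (substr(left_flank, 96, 96) == substr(mid, 146, 146)) {
    substr(left_flank, 96, 96) <-
      setdiff(BASES, substr(mid, 146, 146))[1]
  }
  ref <- paste0(left_flank, "GCTA", mid, "GCTA", right_flank)
  # deleted interval [101, 250]: GCTA at 97-100 and 247-250
  got <- microhomology(ref, 101, 250)
  expect_gte(got$homology_length, 4L)
  canon <- got$del_start
  expect_equal(substr(ref, canon, canon + 3), "GCTA")
  # left-homologous placements excise identical sequence
  expect_identical(
    paste0(substr(ref, 1, got$del_start - 1),
           substr(ref, got$del_end + 1, nchar(ref))),
    paste0(substr(ref, 1, 100), substr(ref, 251, nchar(ref)))
  )
})

test_that("homology calls agree between a construct and its reverse complement", {
  ref <- build_deletion_reference(1500, data.frame(del_start = 501,
                                                   del_end = 700, mh = 5),
                                  seed = 10)
  fwd <- microhomology(ref, 501, 700)
  rc <- revcomp(ref)
  # the deleted interval maps to [1500-700+1, 1500-501+1] on the other strand
  rev_ev <- microhomology(rc, 1500 - 700 + 1, 1500 - 501 + 1)
  expect_equal(rev_ev$homology_length, fwd$homology_length)
  # the excised sequences are reverse complements of each other
  expect_identical(
    revcomp(paste0(substr(ref, 1, fwd$del_start - 1),
                   substr(ref, fwd$del_end + 1, 1500))),
    paste0(substr(rc, 1, rev_ev$del_start - 1),
           substr(rc, rev_ev$del_end + 1, 1500))
  )
})

test_that("reads inconsistent with one clean deletion are unresolved, not dropped", {
  ref <- build_deletion_reference(2000, data.frame(del_start = 501,
                                                   del_end = 700, mh = 0),
                                  seed = 11)
  # two separated deletions in one read
  read2 <- paste0(substr(ref, 1, 300), substr(ref, 351, 500),
                  substr(ref, 701, 2000))
  ev <- find_deletion(read2, ref)
  expect_equal(ev$status, "unresolved")
  # heavily corrupted read
  noisy <- paste0(substr(ref, 1, 500), substr(ref, 701, 2000))
  set.seed(12)
  chars <- strsplit(noisy, "")[[1]]
  idx <- sample(seq_along(chars), 100)
  chars[idx] <- vapply(chars[idx], function(b) sample(setdiff(BASES, b), 1), "")
  expect_equal(find_deletion(paste(chars, collapse = ""), ref)$status,
               "unresolved")
})

test_that("aggregation merges equivalent placements and translates coordinates", {
  ref <- build_deletion_reference(3000, data.frame(del_start = 1001,
                                                   del_end = 1200, mh = 3),
                                  seed = 13)
  reads <- data.frame(
    id = paste0("r", 1:12),
    seq = vapply(c(rep(0, 5), rep(1, 3), rep(3, 4)), function(shift) {
      paste0(substr(ref, 1, 1000 + shift), substr(ref, 1201 + shift, 3000))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  events <- find_deletions(reads, ref)
  agg <- aggregate_deletions(events, genome_offset = 19000L)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$support, 12L)
  expect_equal(agg$del_start, 1001L)
  expect_equal(agg$genome_start, 1001L + 19000L)
  expect_equal(agg$genome_end - agg$genome_start, agg$del_end - agg$del_start)
  # idempotence: aggregating an already-aggregated table changes nothing
  again <- aggregate_deletions(events, genome_offset = 19000L)
  expect_identical(agg, again)
})

test_that("planted deletions are recovered perfectly without error and >=95% at 0.5%", {
  n_del <- 40L
  set.seed(20)
  lens <- sample(50:2000, n_del, replace = TRUE)
  mhs <- sample(0:10, n_del, replace = TRUE)
  ok_clean <- logical(n_del)
  ok_noisy <- logical(n_del)
  for (i in seq_len(n_del)) {
    start <- sample(200:(9800 - lens[i] - 20), 1)
    ref <- build_deletion_reference(
      10000, data.frame(del_start = start, del_end = start + lens[i] - 1,
                        mh = mhs[i]), seed = 1000 + i)
    truth <- microhomology(ref, start, start + lens[i] - 1)
    clean <- paste0(substr(ref, 1, start - 1),
                    substr(ref, start + lens[i], 10000))
    ev <- find_deletion(clean, ref)
    ok_clean[i] <- ev$status == "deletion" &&
      ev$length == lens[i] &&
      ev$del_start >= truth$ambiguity_left &&
      ev$del_start <= truth$ambiguity_right &&
      ev$homology_length == truth$homology_length
    noisy <- apply_substitution_errors_public(clean, 0.005, seed = 2000 + i)
    evn <- find_deletion(noisy, ref)
    ok_noisy[i] <- evn$status == "deletion" &&
      evn$length == lens[i] &&
      evn$del_start >= truth$ambiguity_left &&
      evn$del_start <= truth$ambiguity_right
  }
  expect_true(all(ok_clean))
  expect_gte(mean(ok_noisy), 0.95)
})
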