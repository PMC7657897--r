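alc <- "CAGGTGACTGTGATTATATAGTTCACAGGTG"
nil <- "CAGGTGACTGTGATTATATAGTTCACAGGTT"
inserts <- seq_records(c("A_alcalica", "O_niloticus"), c(alc, nil), "dna")

test_that("IUPAC symbol matching follows the code table, N-subject matches nothing", {
  expect_true(iupac_matches("S", "G"))
  expect_false(iupac_matches("S", "A"))
  expect_true(iupac_matches("N", "T"))
  expect_false(iupac_matches("A", "N"))
  expect_false(iupac_matches("N", "N"))
  expect_error(iupac_matches("J", "A"), "invalid IUPAC")
  # full table against the oracle's sets
  for (sym in names(IUPAC)) {
    for (b in c("A", "C", "G", "T")) {
      expect_equal(iupac_matches(sym, b), b %in% IUPAC[[sym]])
    }
  }
})

test_that("the published 31-mers give a paired MyoD E-box in A. alcalica only", {
  myod <- scan_motifs(inserts, "CAGSTG")
  alc_hits <- dplyr::filter(myod, seq_id == "A_alcalica")
  expect_equal(nrow(alc_hits), 2L)
  expect_equal(alc_hits$start, c(1L, 26L))
  expect_equal(alc_hits$mismatches, c(0L, 0L))

  nil_hits <- dplyr::filter(myod, seq_id == "O_niloticus")
  expect_equal(nrow(nil_hits), 1L) # a single MyoD E-box

  generic <- scan_motifs(inserts[1, ], "CANNTG")
  expect_equal(dplyr::filter(generic, seq_id == "A_alcalica")$start,
               c(1L, 26L)) # brute-force enumeration of all 26 windows
  expect_equal(oracle_window_dist(alc, "CANNTG") == 0L,
               seq_len(26) %in% c(1L, 26L))
})

test_that("near-miss finder reports CAGGTT one substitution from the consensus", {
  nm <- find_near_misses(inserts, "CAGSTG", k = 1)
  nil_nm <- dplyr::filter(nm, seq_id == "O_niloticus")
  expect_equal(nil_nm$matched, "CAGGTT")
  expect_equal(nil_nm$mismatches, 1L)
  expect_equal(nil_nm$edits, "p6:T>G")
  # exact windows are excluded
  expect_false(any(dplyr::filter(nm, seq_id == "A_alcalica")$start == 26L))
  expect_error(find_near_misses(inserts, "CAGSTG", k = 0), "use scan")
  # pattern longer than region -> silently empty
  short <- seq_records("s", "ACGT", "dna")
  expect_equal(nrow(find_near_misses(short, "CAGSTG", 1)), 0L)
})

test_that("pairing uses the strictly-between gap and the presumptive category", {
  myod <- scan_motifs(inserts, "CAGSTG")
  alc_pair <- pair_hits(dplyr::filter(myod, seq_id == "A_alcalica"),
                        max_gap = 25, seqs = inserts)
  expect_equal(nrow(alc_pair), 1L)
  expect_equal(alc_pair$gap, 19L) # 26 - 6 - 1
  expect_equal(alc_pair$composite, alc)
  expect_equal(alc_pair$category, "exact")

  nm <- find_near_misses(inserts, "CAGSTG", 1)
  nil <- dplyr::bind_rows(dplyr::filter(myod, seq_id == "O_niloticus"),
                          dplyr::filter(nm, seq_id == "O_niloticus"))
  expect_equal(nrow(pair_hits(nil, 19)), 0L) # exact-only view
  pres <- pair_hits(nil, 19, allow_near_miss_partner = TRUE)
  expect_equal(pres$category, "presumptive")
  expect_equal(pres$gap, 19L)

  # gap over threshold: two exact hits 30 apart
  far <- scan_motifs(
    seq_records("f", paste0("CAGGTG", strrep("A", 30), "CAGGTG"), "dna"),
    "CAGSTG"
  )
  expect_equal(nrow(pair_hits(far, 25)), 0L)
  expect_equal(nrow(pair_hits(far, 30)), 1L)

  # overlapping hits never pair
  ov <- scan_motifs(seq_records("o", "CACGTG", "dna"), "CANNTG")
  expect_equal(nrow(pair_hits(ov, 19)), 0L)
})

test_that("upstream coordinates follow L - p + 1 and invert exactly", {
  expect_equal(upstream_coords(1, 6, 3500),
               tibble::tibble(distal = 3500L, proximal = 3495L))
  expect_equal(upstream_coords(3495, 3500, 3500),
               tibble::tibble(distal = 6L, proximal = 1L))
  expect_error(upstream_coords(0, 6, 3500), "outside region")
  # a 31-base composite ending 940 bases upstream starts 970 upstream
  expect_equal(upstream_coords(3500 - 970 + 1, 3500 - 940 + 1, 3500)$distal,
               970L)
  # bijection on random spans
  withr::local_seed(11)
  for (i in 1:50) {
    L <- sample(50:5000, 1)
    s <- sample.int(L, 1)
    e <- s + sample.int(L - s + 1L, 1) - 1L
    up <- upstream_coords(s, e, L)
    back <- upstream_to_coords(up$distal, up$proximal, L)
    expect_identical(c(back$start, back$end), c(s, e))
  }
})

test_that("scanner and near-miss finder agree with the concretization oracle", {
  withr::local_seed(101)
  for (i in 1:150) {
    L <- sample(10:50, 1)
    m <- sample(4:8, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    pat <- random_pattern(m)
    k <- sample(0:2, 1)
    dist <- oracle_window_dist(seq, pat)
    seqs <- seq_records("t", seq, "dna")
    got <- scan_motifs(seqs, pat, max_mismatches = k)
    expect_identical(got$start, which(dist <= k),
                     info = paste(seq, pat, k))
    expect_identical(got$mismatches, dist[dist <= k])
    if (k >= 1) {
      nm <- find_near_misses(seqs, pat, k)
      expect_identical(nm$start, which(dist >= 1L & dist <= k))
    }
  }
})

test_that("reverse-complement scanning mirrors forward coordinates", {
  withr::local_seed(77)
  for (i in 1:40) {
    L <- sample(15:50, 1)
    seq <- random_dna(L)
    pat <- random_pattern(6)
    fwd <- scan_motifs(seq_records("t", seq, "dna"), pat,
                       max_mismatches = 1)
    # forward scan of the reverse-complemented region with the
    # reverse-complemented pattern: mirror-image coordinate set
    mirrored <- scan_motifs(seq_records("t", revcomp(seq), "dna"),
                            iupac_rc(pat), max_mismatches = 1)
    expect_setequal(L - mirrored$end + 1L, fwd$start)
    expect_identical(sort(mirrored$mismatches), sort(fwd$mismatches))
    # minus-strand reporting is the same scan seen from the other strand
    both <- scan_motifs(seq_records("t", seq, "dna"), pat,
                        strands = "both", max_mismatches = 1)
    minus <- dplyr::filter(both, strand == "-")
    rc_fwd <- scan_motifs(seq_records("t", revcomp(seq), "dna"), pat,
                          max_mismatches = 1)
    expect_setequal(L - minus$end + 1L, rc_fwd$start)
  }
})

test_that("the two published fragments differ by the single reported edit", {
  a <- strsplit(alc, "")[[1]]
  n <- strsplit(nil, "")[[1]]
  expect_equal(sum(a != n), 1L)
  nm <- dplyr::filter(find_near_misses(inserts, "CAGSTG", 1),
                      seq_id == "O_niloticus")
  # apply the reported edit (position within the matched window)
  edit <- regmatches(nm$edits, regexec("p(\\d+):(.)>(.)", nm$edits))[[1]]
  pos <- nm$start + as.integer(edit[[2]]) - 1L
  n[pos] <- "G" # any base allowed by the consensus at that spot
  expect_equal(paste(n, collapse = ""), alc)
})

test_that("cross-species survey reproduces the published contrast", {
  sv <- compare_regions(inserts)
  expect_equal(sv$n_exact_pairs, c(1L, 0L))
  expect_equal(sv$n_presumptive_pairs, c(0L, 1L))
  expect_equal(sv$n_myod, c(2L, 1L))

  # empty pattern set -> empty survey
  empty <- compare_regions(inserts[1, ], ebox_patterns()[0, ])
  expect_equal(nrow(empty), 0L)

  # duplicated region under two ids -> identical rows
  dup <- seq_records(c("r1", "r2"), c(alc, alc), "dna")
  svd <- compare_regions(dup)
  expect_equal(dplyr::select(as.data.frame(svd[1, ]), -seq_id),
               dplyr::select(as.data.frame(svd[2, ]), -seq_id))
})

test_that("survey tidiers and track plot behave", {
  sv <- compare_regions(inserts)
  expect_s3_class(tidy(sv), "tbl_df")
  expect_gt(nrow(tidy(sv, "pairs")), 0L)
  expect_equal(glance(sv)$n_exact_pairs, 1L)
  p <- ggplot2::autoplot(sv)
  expect_s3_class(p, "ggplot")
})
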