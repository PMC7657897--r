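#' Default E-box motif patterns
#'
#' The generic E-box consensus `CANNTG` and the MyoD-preferred consensus
#' `CAG(G/C)TG`, encoded in IUPAC as `CAGSTG` (`S` = G or C).
#'
#' @return A tibble with columns `label` and `iupac`.
#' @export
#' @examples
#' ebox_patterns()
ebox_patterns <- function() {
  tibble(
    label = c("Ebox_generic", "Ebox_MyoD"),
    iupac = c("CANNTG", "CAGSTG")
  )
}

#' Does an IUPAC symbol match a subject base?
#'
#' Symbol-wise degenerate matching: `TRUE` iff `base` belongs to the
#' symbol's allowed set. A subject base `N` matches nothing — an unknown
#' base never confirms a motif (conservative policy for low-quality
#' assembly regions).
#'
#' @param symbol IUPAC nucleotide code(s) (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`).
#' @param base Subject base(s) in `A,C,G,T,N`. Vectorized, recycled.
#' @return Logical vector.
#' @export
#' @examples
#' iupac_matches("S", c("G", "A")) # TRUE FALSE
iupac_matches <- function(symbol, base) {
  symbol <- str_to_upper(symbol)
  base <- str_to_upper(base)
  if (any(!symbol %in% names(IUPAC_SETS))) {
    abort(paste0("invalid IUPAC symbol: ",
                 paste(setdiff(symbol, names(IUPAC_SETS)), collapse = ", ")))
  }
  if (any(!base %in% DNA_ALPHABET)) {
    abort(paste0("invalid subject base: ",
                 paste(setdiff(base, DNA_ALPHABET), collapse = ", ")))
  }
  n <- max(length(symbol), length(base))
  symbol <- rep_len(symbol, n)
  base <- rep_len(base, n)
  map2(symbol, base, function(s, b) b != "N" && b %in% IUPAC_SETS[[s]]) |>
    unlist()
}

# Normalize a pattern argument (string, named character vector, or tibble
# with label/iupac) into a validated tibble(label, iupac).
as_pattern_tbl <- function(patterns) {
  if (is.character(patterns)) {
    labels <- names(patterns) %||% patterns
    labels[!nzchar(labels)] <- patterns[!nzchar(labels)]
    patterns <- tibble(label = labels, iupac = unname(patterns))
  }
  if (!is.data.frame(patterns) ||
      !all(c("label", "iupac") %in% names(patterns))) {
    abort("patterns must be a character vector or a tibble with label, iupac")
  }
  patterns$iupac <- str_to_upper(patterns$iupac)
  for (p in patterns$iupac) {
    sym <- strsplit(p, "", fixed = TRUE)[[1]]
    if (length(sym) == 0L || any(!sym %in% names(IUPAC_SETS))) {
      abort(paste0("invalid IUPAC pattern: ", p))
    }
  }
  as_tibble(patterns[c("label", "iupac")])
}

# Mismatch count of every window of `chars` against IUPAC `pattern`
# (minimal Hamming distance over pattern concretizations, computed
# symbol-wise; subject N matches nothing). Returns integer vector of
# length length(chars) - m + 1, or integer(0) when the pattern is longer.
window_mismatches <- function(chars, pattern) {
  sym <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(sym)
  L <- length(chars)
  if (m > L) return(integer(0))
  nwin <- L - m + 1L
  mm <- integer(nwin)
  for (j in seq_len(m)) {
    allowed <- DNA_ALPHABET %in% IUPAC_SETS[[sym[[j]]]] &
      DNA_ALPHABET != "N"
    names(allowed) <- DNA_ALPHABET
    mm <- mm + !allowed[chars[seq_len(nwin) + j - 1L]]
  }
  unname(mm)
}

scan_one <- function(id, residues, label, iupac, strands, max_mismatches) {
  L <- str_length(residues)
  if (L == 0L) abort(paste0("empty sequence: ", id))
  m <- str_length(iupac)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  out <- list()
  mm <- window_mismatches(chars, iupac)
  keep <- which(mm <= max_mismatches)
  if (length(keep) > 0L) {
    out$fwd <- tibble(
      seq_id = id, start = keep, end = keep + m - 1L, strand = "+",
      label = label, iupac = iupac,
      matched = str_sub(residues, keep, keep + m - 1L),
      mismatches = mm[keep]
    )
  }
  if (strands == "both") {
    rc <- revcomp(residues)
    mm_rc <- window_mismatches(strsplit(rc, "", fixed = TRUE)[[1]], iupac)
    keep_rc <- which(mm_rc <= max_mismatches)
    if (length(keep_rc) > 0L) {
      out$rev <- tibble(
        seq_id = id,
        start = L - (keep_rc + m - 1L) + 1L, end = L - keep_rc + 1L,
        strand = "-",
        label = label, iupac = iupac,
        matched = str_sub(rc, keep_rc, keep_rc + m - 1L),
        mismatches = mm_rc[keep_rc]
      )
    }
  }
  bind_rows(out)
}

empty_hits <- function() {
  tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), label = character(), iupac = character(),
    matched = character(), mismatches = integer(),
    upstream_distal = integer(), upstream_proximal = integer()
  )
}

#' Scan promoter regions for degenerate motifs
#'
#' Slides every pattern across every sequence and reports each window
#' whose minimal Hamming distance to the degenerate pattern (minimum over
#' concretizations, computed symbol-wise) is at most `max_mismatches`.
#' Overlapping hits are reported. Reverse-strand hits, when requested, are
#' given in forward coordinates with strand `"-"` and `matched` as read on
#' the minus strand. Each hit also carries its TSS-relative upstream span
#' (see [upstream_coords()]), taking the last base of each record to sit
#' immediately 5' of the transcription start site.
#'
#' @param seqs DNA sequence tibble (see [read_fasta()]).
#' @param patterns Pattern tibble (`label`, `iupac`), a named character
#'   vector, or bare IUPAC strings. Defaults to [ebox_patterns()].
#' @param strands `"forward"` (default — promoter annotation is given on
#'   the reported strand) or `"both"`.
#' @param max_mismatches Maximum mismatch count (default 0 = exact).
#' @return A tibble of hits sorted by `seq_id`, `start`, `strand`, `label`:
#'   columns `seq_id`, `start`, `end` (1-based inclusive), `strand`,
#'   `label`, `iupac`, `matched`, `mismatches`, `upstream_distal`,
#'   `upstream_proximal`. A pattern longer than a sequence simply yields no
#'   hits for it.
#' @export
#' @examples
#' seqs <- seq_records("alc", "CAGGTGACTGTGATTATATAGTTCACAGGTG", "dna")
#' scan_motifs(seqs, "CAGSTG")
scan_motifs <- function(seqs, patterns = ebox_patterns(),
                        strands = c("forward", "both"),
                        max_mismatches = 0L) {
  check_seq_tbl(seqs)
  strands <- match.arg(strands)
  patterns <- as_pattern_tbl(patterns)
  if (max_mismatches < 0L) abort("max_mismatches must be >= 0")
  if (nrow(patterns) == 0L || nrow(seqs) == 0L) return(empty_hits())
  hits <- pmap_dfr(
    expand.grid(i = seq_len(nrow(seqs)), p = seq_len(nrow(patterns))),
    function(i, p) {
      scan_one(seqs$id[[i]], seqs$residues[[i]],
               patterns$label[[p]], patterns$iupac[[p]],
               strands, max_mismatches)
    }
  )
  if (nrow(hits) == 0L) return(empty_hits())
  lens <- setNames(str_length(seqs$residues), seqs$id)
  hits <- mutate(hits,
    upstream_distal = unname(lens[.data$seq_id]) - .data$start + 1L,
    upstream_proximal = unname(lens[.data$seq_id]) - .data$end + 1L
  )
  arrange(hits, .data$seq_id, .data$start, .data$strand, .data$label)
}

#' Find near-miss motif occurrences
#'
#' Reports windows at Hamming distance 1..`k` from a degenerate pattern;
#' exact matches are excluded (use [scan_motifs()] for those). Each hit's
#' `edits` column lists, for every mismatching position, the offending base
#' and one allowed replacement, e.g. `"p6:T>G"` for a `CAGGTT` window one
#' substitution away from `CAGSTG`.
#'
#' @param seqs DNA sequence tibble.
#' @param pattern A single IUPAC pattern (string or one-row pattern tibble).
#' @param k Maximum mismatches, at least 1.
#' @param strands `"forward"` or `"both"`.
#' @return A hit tibble as from [scan_motifs()] plus an `edits` column.
#' @export
find_near_misses <- function(seqs, pattern, k = 1L,
                             strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (k == 0L) abort("use scan_motifs for exact matches")
  if (k < 0L) abort("k must be >= 1")
  pattern <- as_pattern_tbl(pattern)
  if (nrow(pattern) != 1L) abort("pattern must be a single pattern")
  hits <- scan_motifs(seqs, pattern, strands, max_mismatches = k)
  hits <- filter(hits, .data$mismatches >= 1L)
  sym <- strsplit(pattern$iupac, "", fixed = TRUE)[[1]]
  hits$edits <- map_chr(hits$matched, function(w) {
    wc <- strsplit(w, "", fixed = TRUE)[[1]]
    bad <- which(!map2(sym, wc, function(s, b) {
      b != "N" && b %in% IUPAC_SETS[[s]]
    }) |> unlist())
    paste(sprintf("p%d:%s>%s", bad, wc[bad],
                  map_chr(bad, function(j) IUPAC_SETS[[sym[[j]]]][[1L]])),
          collapse = ",")
  })
  hits
}

#' Pair motif hits in close proximity
#'
#' Forms every ordered pair of non-overlapping hits on the same sequence
#' and strand separated by at most `max_gap` bases, where the gap counts
#' the bases strictly between the two hits
#' (`second_start - first_end - 1`). Pairs of two exact hits are category
#' `"exact"`; when `allow_near_miss_partner` is `TRUE`, pairs in which
#' exactly one member carries mismatches are reported as `"presumptive"`
#' (pairs of two near-misses are never reported).
#'
#' @param hits Hit tibble from [scan_motifs()] and/or [find_near_misses()],
#'   normally for a single pattern.
#' @param max_gap Largest allowed gap (default 19, the distance separating
#'   the two E-boxes of the paired MyoD site this scanner was built to
#'   find).
#' @param allow_near_miss_partner Report exact/near-miss pairs as
#'   `"presumptive"`.
#' @param seqs Optional sequence tibble; when supplied, each pair carries
#'   the literal composite substring spanning both hits (as read on the
#'   hit strand).
#' @return Tibble with one row per pair: `seq_id`, `strand`, first/second
#'   hit coordinates, `gap`, `category`, `total_mismatches`, `composite`.
#' @export
pair_hits <- function(hits, max_gap = 19L, allow_near_miss_partner = FALSE,
                      seqs = NULL) {
  empty <- tibble(
    seq_id = character(), strand = character(),
    first_start = integer(), first_end = integer(),
    second_start = integer(), second_end = integer(),
    gap = integer(), category = character(),
    total_mismatches = integer(), composite = character()
  )
  if (nrow(hits) == 0L) return(empty)
  hits <- arrange(hits, .data$seq_id, .data$strand, .data$start, .data$end)
  pairs <- hits |>
    group_by(.data$seq_id, .data$strand) |>
    dplyr::group_modify(function(h, key) {
      n <- nrow(h)
      if (n < 2L) return(empty[0L, 3:10])
      idx <- expand.grid(i = seq_len(n), j = seq_len(n))
      idx <- idx[idx$i < idx$j, , drop = FALSE]
      gap <- h$start[idx$j] - h$end[idx$i] - 1L
      keep <- gap >= 0L & gap <= max_gap
      idx <- idx[keep, , drop = FALSE]
      gap <- gap[keep]
      tibble(
        first_start = h$start[idx$i], first_end = h$end[idx$i],
        second_start = h$start[idx$j], second_end = h$end[idx$j],
        gap = gap,
        category = if_else(
          h$mismatches[idx$i] == 0L & h$mismatches[idx$j] == 0L, "exact",
          if_else(xor(h$mismatches[idx$i] > 0L, h$mismatches[idx$j] > 0L),
                  "presumptive", "drop")
        ),
        total_mismatches = h$mismatches[idx$i] + h$mismatches[idx$j],
        composite = NA_character_
      )
    }) |>
    ungroup()
  keep_cat <- if (allow_near_miss_partner) c("exact", "presumptive") else "exact"
  pairs <- filter(pairs, .data$category %in% keep_cat)
  if (!is.null(seqs) && nrow(pairs) > 0L) {
    check_seq_tbl(seqs)
    res <- setNames(seqs$residues, seqs$id)
    fwd <- str_sub(res[pairs$seq_id], pairs$first_start, pairs$second_end)
    pairs$composite <- ifelse(pairs$strand == "+", fwd, revcomp(fwd))
  }
  arrange(pairs, .data$seq_id, .data$first_start, .data$second_start)
}

#' Convert record coordinates to TSS-relative upstream distances
#'
#' The last base of a promoter record is taken to sit immediately 5' of
#' the transcription start site, so the base at 1-based position `p` of a
#' length-`L` record lies `L - p + 1` bases upstream.
#'
#' @param start,end 1-based inclusive record coordinates.
#' @param region_length Record length `L`.
#' @return Tibble with `distal` (`L - start + 1`) and `proximal`
#'   (`L - end + 1`); `distal >= proximal`.
#' @export
#' @examples
#' upstream_coords(1, 6, 3500) # distal 3500, proximal 3495
upstream_coords <- function(start, end, region_length) {
  if (any(start < 1L | end > region_length | start > end)) {
    abort("hit outside region")
  }
  tibble(
    distal = as.integer(region_length - start + 1L),
    proximal = as.integer(region_length - end + 1L)
  )
}

#' Invert [upstream_coords()]
#'
#' @param distal,proximal Upstream distances of the hit's 5'-most and
#'   3'-most base.
#' @param region_length Record length `L`.
#' @return Tibble with 1-based inclusive `start` and `end`.
#' @export
upstream_to_coords <- function(distal, proximal, region_length) {
  if (any(proximal < 1L | distal > region_length | distal < proximal)) {
    abort("span outside region")
  }
  tibble(
    start = as.integer(region_length - distal + 1L),
    end = as.integer(region_length - proximal + 1L)
  )
}

#' Cross-species E-box survey of promoter regions
#'
#' Runs the full comparative analysis on a set of upstream regions: counts
#' generic E-boxes (`CANNTG`) and MyoD-preferred E-boxes (`CAGSTG`), forms
#' exact pairs, and — after scanning for Hamming-`near_miss_k` near-misses
#' of the MyoD consensus — presumptive pairs in which one partner is a
#' near-miss.
#'
#' @param seqs DNA sequence tibble, one promoter region per species.
#' @param patterns Pattern tibble; the labels named by `generic_label` and
#'   `myod_label` drive the counts (a missing label yields `NA` counts).
#'   An empty pattern table yields an empty survey.
#' @param generic_label,myod_label Which pattern labels play the generic
#'   and MyoD roles.
#' @param max_gap Pairing distance passed to [pair_hits()].
#' @param near_miss_k Near-miss radius for presumptive pairs.
#' @param strands Strand policy for all scans.
#' @return An `ebox_survey`: a tibble with one row per sequence
#'   (`seq_id`, `region_length`, `n_generic`, `n_myod`, `n_exact_pairs`,
#'   `n_presumptive_pairs`) carrying the underlying `hits`, `near_misses`
#'   and `pairs` tables as attributes (retrieve with [tidy()]).
#' @export
compare_regions <- function(seqs, patterns = ebox_patterns(),
                            generic_label = "Ebox_generic",
                            myod_label = "Ebox_MyoD",
                            max_gap = 19L, near_miss_k = 1L,
                            strands = c("forward", "both")) {
  check_seq_tbl(seqs)
  strands <- match.arg(strands)
  patterns <- as_pattern_tbl(patterns)
  if (nrow(patterns) == 0L) {
    out <- tibble(seq_id = character(), region_length = integer(),
                  n_generic = integer(), n_myod = integer(),
                  n_exact_pairs = integer(), n_presumptive_pairs = integer())
    return(new_ebox_survey(out, empty_hits(), empty_hits(),
                           pair_hits(empty_hits())))
  }
  hits <- scan_motifs(seqs, patterns, strands)
  myod_row <- filter(patterns, .data$label == myod_label)
  myod_hits <- filter(hits, .data$label == myod_label)
  near <- if (nrow(myod_row) == 1L) {
    find_near_misses(seqs, myod_row, k = near_miss_k, strands = strands)
  } else {
    empty_hits()
  }
  all_pairs <- pair_hits(bind_rows(myod_hits, near), max_gap,
                         allow_near_miss_partner = TRUE, seqs = seqs)
  count_label <- function(lbl) {
    if (!lbl %in% patterns$label) return(rep(NA_integer_, nrow(seqs)))
    map_int(seqs$id, function(s) {
      sum(hits$label == lbl & hits$seq_id == s)
    })
  }
  summary <- tibble(
    seq_id = seqs$id,
    region_length = str_length(seqs$residues),
    n_generic = count_label(generic_label),
    n_myod = count_label(myod_label),
    n_exact_pairs = map_int(seqs$id, function(s) {
      sum(all_pairs$seq_id == s & all_pairs$category == "exact")
    }),
    n_presumptive_pairs = map_int(seqs$id, function(s) {
      sum(all_pairs$seq_id == s & all_pairs$category == "presumptive")
    })
  )
  new_ebox_survey(summary, hits, near, all_pairs)
}

new_ebox_survey <- function(summary, hits, near_misses, pairs) {
  structure(summary,
            hits = hits, near_misses = near_misses, pairs = pairs,
            class = c("ebox_survey", class(summary)))
}
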