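#' Predict PCR amplicons of a primer pair on template sequences
#'
#' Finds every binding site of the forward primer on the plus strand and
#' of the reverse primer on the minus strand (i.e. plus-strand occurrences
#' of its reverse complement), and reports each compatible combination as
#' an amplicon. The product spans from the 5' end of the forward site to
#' the template position complementary to the 5' end of the reverse
#' primer, inclusive of both primer footprints, so
#' `length >= nchar(forward) + nchar(reverse)`. The 3'-terminal base of
#' each primer must match even when mismatches are allowed elsewhere
#' (polymerase extension requires a paired 3' end). Multiple sites yield
#' all products; none is preferred.
#'
#' @param template DNA sequence tibble (one or more templates).
#' @param forward,reverse Primer sequences, 5'→3', over `A,C,G,T`, length
#'   at least 10. The reverse primer anneals to the minus strand.
#' @param max_mismatches Mismatches tolerated per primer site (default 0).
#' @param max_product Optional upper bound on product length.
#' @return Tibble with one row per amplicon: `template_id`, `start`,
#'   `end` (1-based inclusive), `length`, `fwd_mismatches`,
#'   `rev_mismatches`, sorted by template, start, then length.
#' @export
#' @examples
#' tpl <- seq_records("t", paste0("CAGTGGGAGGTCAGATTGC",
#'                                strrep("A", 361),
#'                                revcomp("CTCACAGCGAAGCACAGGG")), "dna")
#' find_amplicons(tpl, "CAGTGGGAGGTCAGATTGC", "CTCACAGCGAAGCACAGGG")
find_amplicons <- function(template, forward, reverse,
                           max_mismatches = 0L, max_product = Inf) {
  check_seq_tbl(template)
  forward <- str_to_upper(forward)
  reverse <- str_to_upper(reverse)
  for (p in c(forward, reverse)) {
    if (str_length(p) < 10L) abort("primers must be at least 10 nt")
    if (str_detect(p, "[^ACGT]")) abort("primers must be over A,C,G,T")
  }
  flen <- str_length(forward)
  rlen <- str_length(reverse)
  rc_rev <- revcomp(reverse)
  out <- map_dfr(seq_len(nrow(template)), function(i) {
    res <- template$residues[[i]]
    if (str_length(res) == 0L) return(NULL)
    chars <- strsplit(res, "", fixed = TRUE)[[1]]
    fwd_mm <- window_mismatches(chars, forward)
    fwd_pos <- which(fwd_mm <= max_mismatches)
    # 3' anchor of the forward primer = last base of its site
    fwd_pos <- fwd_pos[chars[fwd_pos + flen - 1L] ==
                         str_sub(forward, flen, flen)]
    rev_mm <- window_mismatches(chars, rc_rev)
    rev_pos <- which(rev_mm <= max_mismatches)
    # 3' anchor of the reverse primer pairs with the first base of the
    # plus-strand site (the site is the revcomp of the primer)
    rev_pos <- rev_pos[chars[rev_pos] == str_sub(rc_rev, 1L, 1L)]
    if (length(fwd_pos) == 0L || length(rev_pos) == 0L) return(NULL)
    combos <- expand.grid(f = fwd_pos, r = rev_pos)
    combos$len <- combos$r + rlen - 1L - combos$f + 1L
    combos <- combos[combos$len >= flen + rlen &
                       combos$len <= max_product, , drop = FALSE]
    if (nrow(combos) == 0L) return(NULL)
    tibble(
      template_id = template$id[[i]],
      start = as.integer(combos$f),
      end = as.integer(combos$r + rlen - 1L),
      length = as.integer(combos$len),
      fwd_mismatches = fwd_mm[combos$f],
      rev_mismatches = rev_mm[combos$r]
    )
  })
  if (nrow(out) == 0L) {
    return(tibble(template_id = character(), start = integer(),
                  end = integer(), length = integer(),
                  fwd_mismatches = integer(), rev_mismatches = integer()))
  }
  arrange(out, .data$template_id, .data$start, .data$length)
}
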