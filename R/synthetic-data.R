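#' Simulate a promoter region with implanted motifs
#'
#' Draws an i.i.d. background sequence with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`, then overwrites it with the requested
#' implants. The background model has no dinucleotide structure — it is a
#' correctness harness for the scanner, not a promoter model. Chance
#' background occurrences of an implanted motif are not suppressed.
#'
#' @param length Region length in bp (default 3500, the upstream window
#'   the comparative promoter analysis uses).
#' @param gc GC fraction in `[0,1]` (default 0.41, a typical teleost
#'   genome-wide value).
#' @param implants Tibble with columns `seq` (concrete `A,C,G,T` string),
#'   `pos` (1-based start) and optionally `strand` (`"+"` default; a `"-"`
#'   implant is reverse-complemented before insertion). Implants must fit
#'   within `length` and must not overlap one another.
#' @param seed Integer seed; the generator uses its own RNG stream and
#'   records the seed in the record description.
#' @param id Record id.
#' @return List with `sequence` (one-row sequence tibble) and `truth`
#'   (tibble `seq_id`, `start`, `end`, `name`, `strand`) — write it with
#'   [write_bed()]-compatible columns via `truth`.
#' @export
sim_promoter <- function(length = 3500L, gc = 0.41, implants = NULL,
                         seed = 1L, id = "synthetic_promoter") {
  if (length < 1L) abort("length must be >= 1")
  if (gc < 0 || gc > 1) abort("gc must be in [0,1]")
  if (is.null(implants)) {
    implants <- tibble(seq = character(), pos = integer(),
                       strand = character())
  }
  implants <- as_tibble(implants)
  if (!"strand" %in% names(implants)) implants$strand <- "+"
  implants$seq <- str_to_upper(implants$seq)
  if (nrow(implants) > 0L) {
    if (any(str_detect(implants$seq, "[^ACGT]"))) {
      abort("implants must be concrete A,C,G,T sequences")
    }
    ends <- implants$pos + str_length(implants$seq) - 1L
    if (any(implants$pos < 1L | ends > length)) {
      abort("implant does not fit within region")
    }
    ord <- order(implants$pos)
    if (any(implants$pos[ord][-1L] <= ends[ord][-nrow(implants)])) {
      abort("overlapping implants")
    }
  }
  local_seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)
  truth <- tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), strand = character())
  if (nrow(implants) > 0L) {
    for (i in seq_len(nrow(implants))) {
      s <- implants$seq[[i]]
      if (implants$strand[[i]] == "-") s <- revcomp(s)
      w <- str_length(s)
      chars[implants$pos[[i]]:(implants$pos[[i]] + w - 1L)] <-
        strsplit(s, "", fixed = TRUE)[[1]]
    }
    truth <- tibble(
      seq_id = id,
      start = as.integer(implants$pos),
      end = as.integer(implants$pos + str_length(implants$seq) - 1L),
      name = implants$seq,
      strand = implants$strand
    )
  }
  sequence <- seq_records(
    id, paste(chars, collapse = ""), "dna",
    description = sprintf("simulated promoter length=%d gc=%g seed=%d",
                          length, gc, as.integer(seed))
  )
  list(sequence = sequence, truth = truth)
}

#' Simulate a CPS protein family with clamped diagnostic residues
#'
#' Each simulated sequence is the reference with i.i.d. substitutions at
#' non-diagnostic sites (each substituted site is set to a uniformly
#' chosen different amino acid), while the five diagnostic positions are
#' clamped to residues consistent with the sequence's assigned functional
#' class:
#'
#' * `GLN_UTILIZING` — all five expected residues;
#' * `INTERMEDIATE_AMMONIA_PREFERRING` — the second glutamine-binding
#'   residue replaced by `replacement`;
#' * `AMMONIA_OBLIGATE` — the catalytic Cys replaced
#'   (`obligate_mode = "cys"`, default) or both glutamine-binding residues
#'   replaced (`obligate_mode = "gln_both"`, the bullfrog configuration).
#'
#' Because diagnostic sites never receive background noise, the
#' classifier must recover the generating class exactly; the truth table
#' makes that testable.
#'
#' @param ref One-row protein sequence tibble: the ungapped reference the
#'   spec is anchored to (it is included as the first alignment row).
#' @param spec A `diagnostic_spec` anchored to `ref`.
#' @param n_seqs Number of simulated sequences.
#' @param classes Character vector of target classes, recycled to
#'   `n_seqs`.
#' @param sub_prob Per-site background substitution probability.
#' @param replacement Residue used for divergent diagnostic sites; must
#'   differ from every expected residue it replaces.
#' @param obligate_mode `"cys"` or `"gln_both"`.
#' @param seed Integer seed (own RNG stream).
#' @return List with `msa` (alignment tibble, reference first) and
#'   `truth` (tibble `seq_id`, `class`).
#' @export
sim_protein_family <- function(ref, spec, n_seqs = 10L,
                               classes = "GLN_UTILIZING",
                               sub_prob = 0.05, replacement = "A",
                               obligate_mode = c("cys", "gln_both"),
                               seed = 1L) {
  stopifnot(inherits(spec, "diagnostic_spec"))
  obligate_mode <- match.arg(obligate_mode)
  ref <- as_protein_string(ref, "ref")
  if (ref$id != spec$ref_id) {
    abort("ref id must match spec$ref_id")
  }
  if (sub_prob < 0 || sub_prob > 1) abort("sub_prob must be in [0,1]")
  classes <- rep_len(classes, n_seqs)
  bad <- setdiff(classes, setdiff(CPS_CLASSES, "INDETERMINATE"))
  if (length(bad) > 0L) {
    abort(paste0("unknown target class: ", paste(unique(bad), collapse = ", ")))
  }
  replacement <- str_to_upper(replacement)
  if (!replacement %in% AA_LETTERS) abort("replacement must be an amino acid")
  pos_tbl <- spec$positions
  if (any(pos_tbl$expected == replacement)) {
    abort("replacement equals an expected diagnostic residue")
  }
  rc <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  if (any(pos_tbl$pos > length(rc))) {
    abort("diagnostic position beyond reference length")
  }
  local_seed(as.integer(seed))
  background <- setdiff(seq_along(rc), pos_tbl$pos)
  rows <- map_chr(seq_len(n_seqs), function(i) {
    s <- rc
    # clamp diagnostic sites per class
    s[pos_tbl$pos] <- pos_tbl$expected
    cls <- classes[[i]]
    if (cls == "INTERMEDIATE_AMMONIA_PREFERRING") {
      s[pos_tbl$pos[pos_tbl$name == "Gln2"]] <- replacement
    } else if (cls == "AMMONIA_OBLIGATE") {
      if (obligate_mode == "cys") {
        s[pos_tbl$pos[pos_tbl$name == "Cys"]] <- replacement
      } else {
        s[pos_tbl$pos[pos_tbl$role == "gln"]] <- replacement
      }
    }
    hit <- background[stats::runif(length(background)) < sub_prob]
    for (p in hit) {
      s[[p]] <- sample(setdiff(AA_LETTERS, s[[p]]), 1L)
    }
    paste(s, collapse = "")
  })
  ids <- sprintf("sim_%03d", seq_len(n_seqs))
  msa <- seq_records(
    c(ref$id, ids), c(ref$residues, rows), "protein",
    description = c(ref$description,
                    sprintf("simulated class=%s seed=%d", classes,
                            as.integer(seed)))
  )
  list(msa = msa, truth = tibble(seq_id = ids, class = classes))
}
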