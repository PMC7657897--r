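# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Everything here is deliberately naive and
# never calls the code paths it checks.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Every concrete A/C/G/T string a degenerate pattern stands for.
concretize <- function(pattern) {
  sets <- IUPAC[strsplit(pattern, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# Minimal Hamming distance of every window of `seq` to `pattern`,
# enumerating all concretizations. A subject N mismatches every concrete
# base automatically, matching the scanner's N-never-matches policy.
oracle_window_dist <- function(seq, pattern) {
  m <- nchar(pattern)
  L <- nchar(seq)
  if (m > L) return(integer(0))
  cons <- concretize(pattern)
  cons_chars <- strsplit(cons, "")
  chars <- strsplit(seq, "")[[1]]
  vapply(seq_len(L - m + 1L), function(s) {
    w <- chars[s:(s + m - 1L)]
    min(vapply(cons_chars, function(cc) sum(cc != w), integer(1)))
  }, integer(1))
}

# Reverse complement of an IUPAC pattern (oracle-side helper).
iupac_rc <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# Cursor-walk oracle: alignment column of ungapped reference position p.
oracle_ref_column <- function(ref_row, p) {
  chars <- strsplit(ref_row, "")[[1]]
  seen <- 0L
  for (c in seq_along(chars)) {
    if (chars[[c]] != "-") {
      seen <- seen + 1L
      if (seen == p) return(c)
    }
  }
  NA_integer_
}

# Exhaustive global-alignment oracle: enumerates every alignment of two
# short sequences as a move string (D = substitution, Q = gap in query,
# R = gap in ref) and scores it with affine gaps (a maximal run of L equal
# gap moves costs open + L * extend). Returns the best score.
oracle_global_score <- function(q, r, S, open, extend) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i == length(qc) && j == length(rc)) {
      score <- 0
      k <- 1L
      while (k <= length(moves)) {
        if (moves[[k]] == "D") {
          score <- score # substitution scores added below
          k <- k + 1L
        } else {
          run <- k
          while (run <= length(moves) && moves[[run]] == moves[[k]]) {
            run <- run + 1L
          }
          score <- score - (open + extend * (run - k))
          k <- run
        }
      }
      qi <- 0L
      ri <- 0L
      for (mv in moves) {
        if (mv == "D") {
          qi <- qi + 1L
          ri <- ri + 1L
          score <- score + S[qc[[qi]], rc[[ri]]]
        } else if (mv == "Q") {
          ri <- ri + 1L
        } else {
          qi <- qi + 1L
        }
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i < length(qc) && j < length(rc)) recurse(i + 1L, j + 1L, c(moves, "D"))
    if (j < length(rc)) recurse(i, j + 1L, c(moves, "Q"))
    if (i < length(qc)) recurse(i + 1L, j, c(moves, "R"))
  }
  recurse(0L, 0L, character(0))
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_ref <- function(n = 100L, id = "REF") {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  seq_records(id, paste(sample(aa, n, replace = TRUE), collapse = ""),
              "protein")
}

# A spec with positions spread over a length-100 reference.
toy_spec <- function(ref_id = "REF") {
  diagnostic_spec(ref_id, triad = c(Cys = 10, His = 25, Glu = 40),
                  gln_binding = c(55, 70), gln_expected = c("S", "Q"))
}

# Random degenerate pattern biased toward low degeneracy so the
# concretization oracle stays cheap.
random_pattern <- function(m) {
  pool <- list(
    concrete = c("A", "C", "G", "T"),
    twofold = c("R", "Y", "S", "W", "K", "M"),
    any = "N"
  )
  kind <- sample(c("concrete", "twofold", "any"), m, replace = TRUE,
                 prob = c(0.7, 0.25, 0.05))
  paste(vapply(kind, function(k) sample(pool[[k]], 1L), character(1)),
        collapse = "")
}

# Build the long state tibble classify_cps() expects, from five state
# labels, bypassing extract_states().
states_from_labels <- function(tr, gl, seq_id = "s") {
  tibble::tibble(
    seq_id = seq_id,
    role = c(rep("triad", 3), rep("gln", 2)),
    name = c("Cys", "His", "Glu", "Gln1", "Gln2"),
    pos = 1:5, column = 1:5,
    expected = c("C", "H", "E", "S", "Q"),
    observed = "?",
    state = c(tr, gl),
    flag = ""
  )
}
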