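#' Global pairwise protein alignment with affine gap penalties
#'
#' Needleman–Wunsch alignment over the full length of both sequences. A
#' gap of length L costs `gap_open + L * gap_extend`. Traceback is
#' deterministic: on ties a substitution is preferred over a gap, and a
#' gap in the query over a gap in the reference. The dynamic program is
#' plain R; at the few-hundred-residue scale of CPS GAT-domain queries
#' this is instantaneous.
#'
#' @param query,ref Protein sequences: single strings or one-row sequence
#'   tibbles. Must be non-empty and ungapped.
#' @param substitution_matrix A scoring matrix, or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1,
#'   the common protein-search settings).
#' @return A `global_alignment`: list with `msa` (two-row alignment
#'   tibble, query first) and `score`.
#' @export
#' @examples
#' align_global("HEAGAWGHEE", "PAWHEAE")$score
align_global <- function(query, ref, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  q <- as_protein_string(query, "query")
  r <- as_protein_string(ref, "ref")
  S <- resolve_matrix(substitution_matrix)
  qc <- strsplit(q$residues, "", fixed = TRUE)[[1]]
  rc <- strsplit(r$residues, "", fixed = TRUE)[[1]]
  missing <- setdiff(c(qc, rc), rownames(S))
  if (length(missing) > 0L) {
    abort(paste0("residues absent from substitution matrix: ",
                 paste(unique(missing), collapse = ", ")))
  }
  n <- length(qc)
  m <- length(rc)
  NEG <- -1e9
  open1 <- gap_open + gap_extend # cost of the first gapped position
  # state matrices: M substitution, IQ gap in query (consumes ref),
  # IR gap in ref (consumes query); (n+1) x (m+1), index +1
  M <- matrix(NEG, n + 1L, m + 1L)
  IQ <- matrix(NEG, n + 1L, m + 1L)
  IR <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (m > 0L) IQ[1L, 2L:(m + 1L)] <- -(gap_open + gap_extend * seq_len(m))
  if (n > 0L) IR[2L:(n + 1L), 1L] <- -(gap_open + gap_extend * seq_len(n))
  # traceback: which predecessor state fed each cell (1 = M, 2 = IQ, 3 = IR)
  TM <- matrix(0L, n + 1L, m + 1L)
  TQ <- matrix(0L, n + 1L, m + 1L)
  TR <- matrix(0L, n + 1L, m + 1L)
  best3 <- function(a, b, c) { # tie order: M > IQ > IR
    if (a >= b && a >= c) c(a, 1L) else if (b >= c) c(b, 2L) else c(c, 3L)
  }
  for (i in seq_len(n)) {
    srow <- S[qc[[i]], ]
    for (j in seq_len(m)) {
      d <- best3(M[i, j], IQ[i, j], IR[i, j])
      M[i + 1L, j + 1L] <- d[[1L]] + srow[[rc[[j]]]]
      TM[i + 1L, j + 1L] <- d[[2L]]
      g <- best3(M[i + 1L, j] - open1, IQ[i + 1L, j] - gap_extend,
                 IR[i + 1L, j] - open1)
      IQ[i + 1L, j + 1L] <- g[[1L]]
      TQ[i + 1L, j + 1L] <- g[[2L]]
      h <- best3(M[i, j + 1L] - open1, IQ[i, j + 1L] - open1,
                 IR[i, j + 1L] - gap_extend)
      IR[i + 1L, j + 1L] <- h[[1L]]
      TR[i + 1L, j + 1L] <- h[[2L]]
    }
  }
  fin <- best3(M[n + 1L, m + 1L], IQ[n + 1L, m + 1L], IR[n + 1L, m + 1L])
  score <- fin[[1L]]
  # traceback
  state <- fin[[2L]]
  i <- n
  j <- m
  qa <- character(0)
  ra <- character(0)
  while (i > 0L || j > 0L) {
    if (i == 0L) state <- 2L
    if (j == 0L) state <- 3L
    if (state == 1L) {
      qa <- c(qc[[i]], qa)
      ra <- c(rc[[j]], ra)
      state <- TM[i + 1L, j + 1L]
      i <- i - 1L
      j <- j - 1L
    } else if (state == 2L) {
      qa <- c("-", qa)
      ra <- c(rc[[j]], ra)
      prev <- if (i == 0L && j > 1L) 2L else TQ[i + 1L, j + 1L]
      state <- prev
      j <- j - 1L
    } else {
      qa <- c(qc[[i]], qa)
      ra <- c("-", ra)
      prev <- if (j == 0L && i > 1L) 3L else TR[i + 1L, j + 1L]
      state <- prev
      i <- i - 1L
    }
  }
  msa <- seq_records(
    id = c(q$id, r$id),
    residues = c(paste(qa, collapse = ""), paste(ra, collapse = "")),
    alphabet = "protein"
  )
  structure(list(msa = msa, score = score), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat("Global alignment, score ", x$score, "\n", sep = "")
  w <- max(str_length(x$msa$id))
  for (i in seq_len(nrow(x$msa))) {
    cat(formatC(x$msa$id[[i]], width = w), " ", x$msa$residues[[i]], "\n",
        sep = "")
  }
  invisible(x)
}

as_protein_string <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    x <- seq_records(what, x, "protein")
  }
  check_seq_tbl(x)
  if (nrow(x) != 1L) abort(paste0(what, " must be a single sequence"))
  if (str_length(x$residues) == 0L) abort(paste0("empty ", what, " sequence"))
  if (str_detect(x$residues, "-")) {
    abort(paste0(what, " must be ungapped"))
  }
  x
}

resolve_matrix <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  if (is.character(substitution_matrix) &&
      length(substitution_matrix) == 1L) {
    env <- new.env()
    data(list = substitution_matrix, package = "Biostrings", envir = env)
    return(get(substitution_matrix, envir = env))
  }
  abort("substitution_matrix must be a matrix or a Biostrings matrix name")
}
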