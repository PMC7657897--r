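#' Define the diagnostic residue positions of a CPS sequence
#'
#' Carbamoyl-phosphate synthetases are typed by five residues of the
#' glutamine amidotransferase (GAT) domain: the Cys-His-Glu catalytic
#' triad that hydrolyses glutamine, and two further residues required for
#' efficient glutamine binding. Positions are 1-based on the ungapped
#' reference sequence named by `ref_id`; they are mapped through an
#' alignment with [map_ref_positions()].
#'
#' @param ref_id Identifier of the anchor sequence.
#' @param triad Named integer vector `c(Cys = ..., His = ..., Glu = ...)`
#'   of reference positions for the catalytic triad.
#' @param gln_binding Integer vector of length 2: positions of the two
#'   glutamine-binding residues.
#' @param gln_expected Expected residue letters at the glutamine-binding
#'   positions (length 2).
#' @param window Optional `c(from, to)` reference positions bounding the
#'   region of interest.
#' @return A `diagnostic_spec` object: a list with a `positions` tibble
#'   (`role`, `name`, `pos`, `expected`), `ref_id` and `window`.
#' @export
#' @examples
#' diagnostic_spec("ref", triad = c(Cys = 10, His = 25, Glu = 40),
#'                 gln_binding = c(55, 70), gln_expected = c("S", "Q"))
diagnostic_spec <- function(ref_id, triad, gln_binding,
                            gln_expected = c("S", "Q"), window = NULL) {
  if (!is.character(ref_id) || length(ref_id) != 1L || !nzchar(ref_id)) {
    abort("ref_id must be a non-empty string")
  }
  if (length(triad) != 3L ||
      !setequal(names(triad), c("Cys", "His", "Glu"))) {
    abort("triad must be a named vector with entries Cys, His, Glu")
  }
  triad <- triad[c("Cys", "His", "Glu")]
  if (length(gln_binding) != 2L || length(gln_expected) != 2L) {
    abort("gln_binding and gln_expected must have length 2")
  }
  gln_expected <- str_to_upper(gln_expected)
  if (any(!gln_expected %in% AA_LETTERS)) {
    abort("gln_expected must be standard amino-acid letters")
  }
  pos_all <- c(unname(triad), as.integer(gln_binding))
  if (anyDuplicated(pos_all)) abort("diagnostic positions must be distinct")
  if (any(pos_all < 1L)) abort("diagnostic positions must be >= 1")
  positions <- tibble(
    role = c(rep("triad", 3L), rep("gln", 2L)),
    name = c("Cys", "His", "Glu", "Gln1", "Gln2"),
    pos = pos_all,
    expected = c("C", "H", "E", gln_expected)
  )
  if (!is.null(window)) {
    window <- as.integer(window)
    if (length(window) != 2L || window[1L] > window[2L]) {
      abort("window must be c(from, to) with from <= to")
    }
  }
  structure(list(ref_id = ref_id, positions = positions, window = window),
            class = "diagnostic_spec")
}

#' @export
print.diagnostic_spec <- function(x, ...) {
  cat("CPS diagnostic spec anchored to '", x$ref_id, "'\n", sep = "")
  if (!is.null(x$window)) {
    cat("window: residues ", x$window[1L], "-", x$window[2L], "\n", sep = "")
  }
  print(x$positions)
  invisible(x)
}

#' Read or write a diagnostic spec as YAML
#'
#' The on-disk format mirrors the constructor: `ref_id`, a `triad` map of
#' `Cys/His/Glu` positions, `gln_binding` positions, `gln_expected`
#' letters, and an optional `window`.
#'
#' @param path Path to a YAML file.
#' @return For `read_diagnostic_spec()`, a `diagnostic_spec`; for
#'   `write_diagnostic_spec()`, `path` invisibly.
#' @export
read_diagnostic_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  for (f in c("ref_id", "triad", "gln_binding")) {
    if (is.null(y[[f]])) abort(paste0("diagnostic spec missing field: ", f))
  }
  diagnostic_spec(
    ref_id = y$ref_id,
    triad = unlist(y$triad),
    gln_binding = unlist(y$gln_binding),
    gln_expected = y$gln_expected %||% c("S", "Q"),
    window = y$window
  )
}

#' @rdname read_diagnostic_spec
#' @param spec A `diagnostic_spec`.
#' @export
write_diagnostic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "diagnostic_spec"))
  pos <- spec$positions
  yaml::write_yaml(list(
    ref_id = spec$ref_id,
    triad = as.list(setNames(pos$pos[1:3], pos$name[1:3])),
    gln_binding = pos$pos[4:5],
    gln_expected = pos$expected[4:5],
    window = spec$window
  ), path)
  invisible(path)
}

#' Map ungapped reference positions to alignment columns
#'
#' For reference position `p`, returns the alignment column `c` such that
#' the reference row contains exactly `p` non-gap characters in columns
#' `1..c` and column `c` itself is not a gap.
#'
#' @param msa Alignment tibble (see [read_alignment()]).
#' @param spec A `diagnostic_spec`, or an integer vector of reference
#'   positions together with `ref_id`.
#' @param ref_id Reference row id (taken from `spec` when it is a
#'   `diagnostic_spec`).
#' @return Tibble with columns `pos` and `column`.
#' @export
map_ref_positions <- function(msa, spec, ref_id = NULL) {
  check_seq_tbl(msa)
  if (inherits(spec, "diagnostic_spec")) {
    ref_id <- spec$ref_id
    pos <- spec$positions$pos
  } else {
    pos <- as.integer(spec)
    if (is.null(ref_id)) abort("ref_id required when spec is a position vector")
  }
  row <- which(msa$id == ref_id)
  if (length(row) != 1L) {
    abort(paste0("reference row '", ref_id, "' not found in alignment"))
  }
  chars <- strsplit(msa$residues[[row]], "", fixed = TRUE)[[1]]
  nongap <- cumsum(chars != "-")
  ungapped_len <- nongap[length(nongap)]
  if (any(pos > ungapped_len)) {
    abort(sprintf("position %d beyond ungapped reference length %d",
                  max(pos), ungapped_len))
  }
  column <- map_int(pos, function(p) {
    match(TRUE, nongap == p & chars != "-")
  })
  tibble(pos = pos, column = column)
}

#' Extract diagnostic residue states from an alignment
#'
#' Maps the spec's positions through the reference row, then records for
#' every sequence and every diagnostic column whether the residue matches
#' the expected letter, diverges from it, or is a gap. An `X` (unknown
#' residue) is divergent with flag `"ambiguous residue"` — an unknown
#' cannot confirm a match.
#'
#' @param msa Alignment tibble containing the spec's reference row.
#' @param spec A `diagnostic_spec`.
#' @return A long tibble: `seq_id`, `role`, `name`, `pos`, `column`,
#'   `expected`, `observed`, `state` (`match`/`divergent`/`gap`), `flag`.
#' @export
extract_states <- function(msa, spec) {
  stopifnot(inherits(spec, "diagnostic_spec"))
  cols <- map_ref_positions(msa, spec)
  pos_tbl <- mutate(spec$positions, column = cols$column)
  imap_dfr(setNames(msa$residues, msa$id), function(res, id) {
    obs <- str_sub(res, pos_tbl$column, pos_tbl$column)
    mutate(pos_tbl,
      seq_id = id,
      observed = obs,
      state = dplyr::case_when(
        obs == "-" ~ "gap",
        obs == .data$expected ~ "match",
        TRUE ~ "divergent"
      ),
      flag = if_else(obs == "X", "ambiguous residue", "")
    )
  }) |>
    select("seq_id", "role", "name", "pos", "column",
           "expected", "observed", "state", "flag")
}

#' Classify CPS functional type from diagnostic residue states
#'
#' Applies the decision table that separates glutamine-utilizing CPS III
#' from ammonia-obligate CPS I and the intermediate, ammonia-preferring
#' configuration seen in *Alcolapia* (and in tree frog CPS I):
#'
#' * any gap among the five diagnostic positions → `INDETERMINATE`
#'   (absence of evidence, not evidence of loss);
#' * triad intact and both glutamine-binding residues present →
#'   `GLN_UTILIZING`;
#' * triad intact but exactly one glutamine-binding residue divergent →
#'   `INTERMEDIATE_AMMONIA_PREFERRING`;
#' * any triad residue divergent, or both glutamine-binding residues
#'   divergent → `AMMONIA_OBLIGATE`.
#'
#' @param states Long state tibble from [extract_states()].
#' @return A `cps_calls` tibble: `seq_id`, `triad_state`, `gln_state`
#'   (compact summaries), `functional_class`, `rationale`; the input
#'   states are attached as an attribute and recoverable with [tidy()].
#' @export
classify_cps <- function(states) {
  needed <- c("seq_id", "role", "name", "state", "observed")
  if (!all(needed %in% names(states))) {
    abort("states must come from extract_states()")
  }
  calls <- states |>
    group_by(.data$seq_id) |>
    dplyr::group_modify(function(s, key) {
      tr <- s$state[s$role == "triad"]
      gl <- s$state[s$role == "gln"]
      if (length(tr) != 3L || length(gl) != 2L) {
        abort("each sequence needs 3 triad and 2 gln states")
      }
      n_gap <- sum(c(tr, gl) == "gap")
      n_tr_div <- sum(tr == "divergent")
      n_gl_div <- sum(gl == "divergent")
      if (n_gap > 0L) {
        cls <- "INDETERMINATE"
        why <- sprintf("%d diagnostic position(s) gapped", n_gap)
      } else if (n_tr_div == 0L && n_gl_div == 0L) {
        cls <- "GLN_UTILIZING"
        why <- "catalytic triad and both glutamine-binding residues intact"
      } else if (n_tr_div == 0L && n_gl_div == 1L) {
        cls <- "INTERMEDIATE_AMMONIA_PREFERRING"
        why <- "triad intact; one glutamine-binding residue divergent"
      } else {
        cls <- "AMMONIA_OBLIGATE"
        why <- if (n_tr_div > 0L) {
          sprintf("catalytic triad disrupted (%d divergent)", n_tr_div)
        } else {
          "both glutamine-binding residues divergent"
        }
      }
      tibble(
        triad_state = paste(tr, collapse = "/"),
        gln_state = paste(gl, collapse = "/"),
        functional_class = cls,
        rationale = why
      )
    }) |>
    ungroup()
  structure(calls, states = states, class = c("cps_calls", class(calls)))
}

#' Classify every sequence of a CPS alignment
#'
#' Convenience wrapper: [extract_states()] then [classify_cps()].
#'
#' @inheritParams extract_states
#' @return A `cps_calls` tibble.
#' @export
classify_alignment <- function(msa, spec) {
  classify_cps(extract_states(msa, spec))
}

#' Classify an unaligned query against a reference
#'
#' Globally aligns the query to the spec's reference with
#' [align_global()], then classifies the resulting two-row alignment.
#'
#' @param query One-row protein sequence tibble (or a single string).
#' @param ref One-row protein sequence tibble for the spec's reference.
#' @param spec A `diagnostic_spec` anchored to `ref`.
#' @param ... Passed to [align_global()].
#' @return A `cps_calls` tibble for the query (the reference row is
#'   dropped from the result).
#' @export
classify_query <- function(query, ref, spec, ...) {
  stopifnot(inherits(spec, "diagnostic_spec"))
  aln <- align_global(query, ref, ...)
  calls <- classify_alignment(aln$msa, spec)
  filter(calls, .data$seq_id != spec$ref_id)
}

#' Per-column conservation of an alignment
#'
#' For each column, the fraction of rows carrying the modal residue, with
#' gaps excluded from both numerator and denominator (the shading rule of
#' standard alignment figures). An all-gap column has no defined fraction
#' and is reported as `NA`.
#'
#' @param msa Alignment tibble with at least two rows.
#' @param threshold Fraction at or above which a column is labelled
#'   conserved (default 1.0 — strict identity).
#' @return Tibble with `column`, `modal_residue`, `fraction`, `conserved`.
#' @export
column_conservation <- function(msa, threshold = 1.0) {
  check_seq_tbl(msa)
  if (nrow(msa) < 2L) abort("conservation needs at least 2 rows")
  nc <- msa_ncol(msa)
  mat <- do.call(rbind, strsplit(msa$residues, "", fixed = TRUE))
  map_dfr(seq_len(nc), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      return(tibble(column = j, modal_residue = NA_character_,
                    fraction = NA_real_, conserved = NA))
    }
    tab <- sort(table(col), decreasing = TRUE)
    tibble(
      column = j,
      modal_residue = names(tab)[[1L]],
      fraction = unname(tab[[1L]]) / length(col),
      conserved = unname(tab[[1L]]) / length(col) >= threshold
    )
  })
}
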