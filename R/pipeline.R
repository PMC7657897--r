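#' Run the comparative promoter scan end to end
#'
#' Reads one or more promoter FASTA files, runs [compare_regions()], and
#' writes per-species BED files (motif hits plus near-misses), a combined
#' BED of paired sites, and a tab-separated summary table. A `run.log`
#' records the configuration and its hash so reruns are verifiable.
#'
#' @param fasta Path(s) to promoter FASTA file(s), one record per species.
#' @param out_dir Output directory (created if absent).
#' @param patterns,generic_label,myod_label,max_gap,near_miss_k,strands
#'   Passed to [compare_regions()].
#' @return The [compare_regions()] survey, invisibly.
#' @export
run_scan_promoter <- function(fasta, out_dir,
                              patterns = ebox_patterns(),
                              generic_label = "Ebox_generic",
                              myod_label = "Ebox_MyoD",
                              max_gap = 19L, near_miss_k = 1L,
                              strands = "forward") {
  seqs <- bind_rows(map(fasta, read_fasta, alphabet = "dna"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey <- compare_regions(seqs, patterns, generic_label, myod_label,
                            max_gap, near_miss_k, strands)
  hits <- bind_rows(attr(survey, "hits"), attr(survey, "near_misses"))
  for (s in seqs$id) {
    write_bed(filter(hits, .data$seq_id == s),
              file.path(out_dir, paste0(s, ".bed")))
  }
  write_bed(attr(survey, "pairs"), file.path(out_dir, "paired_eboxes.bed"))
  readr::write_tsv(as_tibble(survey), file.path(out_dir, "ebox_summary.tsv"))
  write_run_log(out_dir, list(
    command = "scan-promoter", fasta = fasta,
    patterns = as_pattern_tbl(patterns), max_gap = max_gap,
    near_miss_k = near_miss_k, strands = strands
  ))
  invisible(survey)
}

#' Run the CPS functional classification
#'
#' Classifies either a ready-made multiple alignment or a set of unaligned
#' queries (each globally aligned to the spec's reference). Writes a
#' `cps_calls.tsv` table of per-sequence residue states and functional
#' class.
#'
#' @param spec A `diagnostic_spec` or the path to its YAML file.
#' @param out_dir Output directory.
#' @param alignment Path to an alignment (FASTA or Clustal) containing the
#'   spec's reference row, or an alignment tibble.
#' @param queries,reference Alternative input: unaligned protein FASTA
#'   path (or tibble) of queries plus the reference sequence (path or
#'   one-row tibble). Ignored when `alignment` is given.
#' @param format Alignment format when `alignment` is a path.
#' @return The `cps_calls` tibble, invisibly.
#' @export
run_classify_cps <- function(spec, out_dir, alignment = NULL,
                             queries = NULL, reference = NULL,
                             format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (is.character(spec)) spec <- read_diagnostic_spec(spec)
  stopifnot(inherits(spec, "diagnostic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(alignment)) {
    msa <- if (is.character(alignment)) {
      read_alignment(alignment, format, "protein")
    } else {
      alignment
    }
    calls <- classify_alignment(msa, spec)
  } else {
    if (is.null(queries) || is.null(reference)) {
      abort("provide either an alignment or queries plus a reference")
    }
    qs <- if (is.character(queries)) read_fasta(queries, "protein") else queries
    ref <- if (is.character(reference)) {
      read_fasta(reference, "protein")
    } else {
      reference
    }
    calls <- map_dfr(seq_len(nrow(qs)), function(i) {
      classify_query(qs[i, ], ref, spec)
    })
  }
  readr::write_tsv(as_tibble(calls), file.path(out_dir, "cps_calls.tsv"))
  write_run_log(out_dir, list(command = "classify-cps",
                              ref_id = spec$ref_id,
                              positions = spec$positions))
  invisible(calls)
}

#' Run in-silico PCR
#'
#' @param template Template FASTA path or sequence tibble.
#' @param forward,reverse Primer sequences, 5'→3'.
#' @param out_dir Output directory for `amplicons.tsv`.
#' @param max_mismatches Passed to [find_amplicons()].
#' @return The amplicon tibble, invisibly.
#' @export
run_insilico_pcr <- function(template, forward, reverse, out_dir,
                             max_mismatches = 0L) {
  tpl <- if (is.character(template)) read_fasta(template, "dna") else template
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  amps <- find_amplicons(tpl, forward, reverse, max_mismatches)
  readr::write_tsv(amps, file.path(out_dir, "amplicons.tsv"))
  write_run_log(out_dir, list(command = "insilico-pcr", forward = forward,
                              reverse = reverse,
                              max_mismatches = max_mismatches))
  invisible(amps)
}

write_run_log <- function(out_dir, config) {
  lines <- c(
    paste0("time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("package: cpscan ",
           as.character(utils::packageVersion("cpscan"))),
    paste0("config_hash: ", rlang::hash(config)),
    paste0("config: ", paste(utils::capture.output(utils::str(config)),
                             collapse = " | "))
  )
  writeLines(lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}

#' The study's CPS III RT-PCR primer pair
#'
#' The published primer pair used to detect CPS III transcripts, which
#' amplifies a 399 bp product from the A. alcalica coding sequence.
#'
#' @return Named character vector with `forward` and `reverse`.
#' @export
cps3_primers <- function() {
  c(forward = "CAGTGGGAGGTCAGATTGC", reverse = "CTCACAGCGAAGCACAGGG")
}

#' The published 31-nt paired E-box inserts
#'
#' The two printed upstream fragments compared across species: the
#' A. alcalica paired MyoD E-box and the O. niloticus fragment carrying a
#' single MyoD E-box plus the presumptive `CAGGTT` site. Shipped as
#' `inst/extdata/ebox_insert_31mers.fasta`.
#'
#' @return Sequence tibble with records `A_alcalica` and `O_niloticus`.
#' @export
ebox_inserts <- function() {
  read_fasta(system.file("extdata", "ebox_insert_31mers.fasta",
                         package = "cpscan", mustWork = TRUE), "dna")
}
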