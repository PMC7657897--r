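#' Build a table of sequence records
#'
#' The package's core container is a plain tibble with one row per sequence
#' and columns `id`, `description`, `residues`, `alphabet`. Residues are
#' normalized to upper case; for DNA, `U` is converted to `T`. Characters
#' outside the declared alphabet (`A,C,G,T,N` for DNA; the 20 amino-acid
#' letters plus `X` and the gap character `-` for protein) are an error that
#' names the offending record and offset.
#'
#' @param id Character vector of non-empty record identifiers.
#' @param residues Character vector of sequences, same length as `id`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param description Optional free-text descriptions (default empty).
#'
#' @return A tibble with columns `id`, `description`, `residues`, `alphabet`.
#' @export
#' @examples
#' seq_records("x", "acgtu", "dna")
seq_records <- function(id, residues, alphabet = c("dna", "protein"),
                        description = "") {
  alphabet <- match.arg(alphabet)
  if (length(id) == 0L) abort("no records")
  if (any(!nzchar(id)) || anyNA(id)) abort("record ids must be non-empty")
  if (anyDuplicated(id)) {
    warn(paste0("duplicated record id(s): ",
                paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  residues <- str_to_upper(residues)
  if (alphabet == "dna") residues <- gsub("U", "T", residues, fixed = TRUE)
  allowed <- if (alphabet == "dna") c(DNA_ALPHABET, "-") else PROTEIN_ALPHABET
  for (i in seq_along(residues)) {
    chars <- strsplit(residues[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L) {
      abort(sprintf(
        "illegal %s character '%s' in record '%s' at offset %d",
        alphabet, chars[bad[1L]], id[[i]], bad[1L]
      ))
    }
  }
  tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    alphabet = alphabet
  )
}

#' Read a FASTA file into a sequence table
#'
#' @param path Path to a plain-text FASTA file.
#' @param alphabet `"dna"` or `"protein"`; records are validated and
#'   normalized against it (see [seq_records()]).
#'
#' @return A tibble of records in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("no records")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), alphabet, description)
}

#' Write a sequence table as FASTA
#'
#' Lines are wrapped at 60 residues.
#'
#' @param seqs A sequence tibble (see [seq_records()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_seq_tbl(seqs)
  lines <- unlist(map2(seqs$id, seq_len(nrow(seqs)), function(id, i) {
    desc <- seqs$description[[i]]
    header <- if (nzchar(desc)) paste0(">", id, " ", desc) else paste0(">", id)
    res <- seqs$residues[[i]]
    starts <- seq(1L, max(str_length(res), 1L), by = width)
    c(header, str_sub(res, starts, pmin(starts + width - 1L, str_length(res))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a multiple alignment
#'
#' Reads FASTA or Clustal alignments into a sequence tibble whose rows all
#' have identical width (ragged input is an error).
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @return A tibble of aligned records; width available via [msa_ncol()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           alphabet = c("protein", "dna")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "fasta") {
    msa <- read_fasta(path, alphabet)
  } else {
    aln <- if (alphabet == "protein") {
      Biostrings::readAAMultipleAlignment(path, format = "clustal")
    } else {
      Biostrings::readDNAMultipleAlignment(path, format = "clustal")
    }
    set <- Biostrings::unmasked(aln)
    msa <- seq_records(names(set), as.character(set), alphabet)
  }
  widths <- str_length(msa$residues)
  if (length(unique(widths)) != 1L) abort("unequal alignment lengths")
  msa
}

#' Alignment width of a sequence table
#'
#' @param msa A sequence tibble whose rows all have equal length.
#' @return Integer alignment width.
#' @export
msa_ncol <- function(msa) {
  check_seq_tbl(msa)
  widths <- unique(str_length(msa$residues))
  if (length(widths) != 1L) abort("unequal alignment lengths")
  as.integer(widths)
}

#' Write motif hits or pairs as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention. The `name` field is the pattern label (or the pair
#' category), `score` the mismatch count, and lines are sorted by
#' chromosome then start. An empty hit table produces a file holding only
#' the header comment.
#'
#' @param hits A tibble from [scan_motifs()], [find_near_misses()] or
#'   [pair_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  if (nrow(hits) > 0 && !"seq_id" %in% names(hits)) {
    abort("hits must carry a seq_id column")
  }
  if (nrow(hits) == 0L) {
    writeLines("# chrom\tstart\tend\tname\tscore\tstrand", path)
    return(invisible(path))
  }
  if ("first_start" %in% names(hits)) { # paired-motif table
    bed <- tibble(
      chrom = hits$seq_id,
      start = hits$first_start - 1L,
      end = hits$second_end,
      name = hits$category,
      score = hits$total_mismatches,
      strand = hits$strand
    )
  } else {
    bed <- tibble(
      chrom = hits$seq_id,
      start = hits$start - 1L,
      end = hits$end,
      name = hits$label,
      score = hits$mismatches,
      strand = hits$strand
    )
  }
  bed <- arrange(bed, .data$chrom, .data$start)
  lines <- c(
    "# chrom\tstart\tend\tname\tscore\tstrand",
    sprintf("%s\t%d\t%d\t%s\t%d\t%s",
            bed$chrom, bed$start, bed$end, bed$name, bed$score, bed$strand)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to the BED file.
#' @return Tibble with 1-based inclusive `start`/`end` plus BED fields.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), score = integer(), strand = character()))
  }
  parts <- str_split(lines, "\t")
  tibble(
    seq_id = map_chr(parts, 1L),
    start = as.integer(map_chr(parts, 2L)) + 1L,
    end = as.integer(map_chr(parts, 3L)),
    name = map_chr(parts, 4L),
    score = as.integer(map_chr(parts, 5L)),
    strand = map_chr(parts, 6L)
  )
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over `A,C,G,T,N` (case-insensitive).
#' @return Reverse-complemented upper-case strings.
#' @export
revcomp <- function(x) {
  x <- str_to_upper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  map_chr(strsplit(comp, "", fixed = TRUE),
          function(ch) paste(rev(ch), collapse = ""))
}

check_seq_tbl <- function(seqs, call = rlang::caller_env()) {
  if (!is.data.frame(seqs) ||
      !all(c("id", "residues", "alphabet") %in% names(seqs))) {
    abort("expected a sequence tibble with columns id, residues, alphabet",
          call = call)
  }
  invisible(seqs)
}
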