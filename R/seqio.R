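#' Read a FASTA file of reference sequences
#'
#' Reference (template) sequences are held to a strict contract: non-empty,
#' and over the unambiguous alphabet A/C/G/T only. Lowercase input is
#' uppercased; ambiguity codes are rejected because a plasmid reference with
#' ambiguous bases cannot anchor the verification.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `name`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*$", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble(name = character(), sequence = character(),
                  length = integer()))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    abort(sprintf("malformed FASTA: line %d does not start with '>'",
                  lineno[1]),
          class = "plasmidcons_format_error")
  }
  rec_id <- cumsum(hdr)
  out <- purrr::map_dfr(split(seq_along(lines), rec_id), function(idx) {
    name <- sub("^>\\s*", "", lines[idx[1]])
    name <- sub("\\s.*$", "", name)
    seq <- toupper(paste(lines[idx[-1]], collapse = ""))
    if (!nzchar(seq)) {
      abort(sprintf("malformed FASTA: empty sequence for record at line %d",
                    lineno[idx[1]]),
            class = "plasmidcons_format_error")
    }
    tibble(name = name, sequence = seq, length = nchar(seq))
  })
  validate_dna(out$sequence, allow_n = FALSE, what = "reference sequence")
  out
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `name` and `sequence` (as returned by
#'   [read_fasta()] or [make_reference()]).
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(x, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$name[i]), con)
    seq <- x$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))), con)
  }
  invisible(path)
}

#' Read a FASTQ file of basecalled reads
#'
#' Expects plain 4-line records with Phred+33 quality encoding (the modern
#' basecaller convention). Qualities are decoded to integer scores.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `qualities`
#'   (a list-column of integer vectors).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  qualities = list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4",
                  length(lines)),
          class = "plasmidcons_format_error")
  }
  n <- length(lines) / 4
  at <- function(k) lines[seq.int(k, by = 4, length.out = n)]
  headers <- at(1)
  seqs <- toupper(at(2))
  plus <- at(3)
  quals <- at(4)
  if (any(!startsWith(headers, "@"))) {
    bad <- which(!startsWith(headers, "@"))[1]
    abort(sprintf("malformed FASTQ: record %d header does not start with '@'",
                  bad),
          class = "plasmidcons_format_error")
  }
  if (any(!startsWith(plus, "+"))) {
    bad <- which(!startsWith(plus, "+"))[1]
    abort(sprintf("malformed FASTQ: record %d separator line is not '+'", bad),
          class = "plasmidcons_format_error")
  }
  read_id <- sub("\\s.*$", "", sub("^@", "", headers))
  len_mismatch <- nchar(seqs) != nchar(quals)
  if (any(len_mismatch)) {
    bad <- which(len_mismatch)[1]
    abort(sprintf(
      "malformed FASTQ: sequence/quality length mismatch for read '%s'",
      read_id[bad]),
      class = "plasmidcons_format_error")
  }
  validate_dna(seqs, allow_n = TRUE, what = "read sequence")
  qualities <- purrr::map(quals, phred33_decode)
  neg <- vapply(qualities, function(q) any(q < 0), logical(1))
  if (any(neg)) {
    abort(sprintf("malformed FASTQ: negative quality score in read '%s'",
                  read_id[which(neg)[1]]),
          class = "plasmidcons_format_error")
  }
  tibble(read_id = read_id, sequence = seqs, qualities = qualities)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A reads tibble (`read_id`, `sequence`, `qualities`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(reads$qualities, phred33_encode, character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read alignments from a PAF file
#'
#' Parses the 12 mandatory PAF columns. Strand comes from column 5 and the
#' number of residue matches from column 10, which is the "aligned bases"
#' quantity used for pseudopair qualification, so external alignments behave
#' like internally computed ones. Reads appearing on more than one line are
#' flagged as multi-alignment.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `read_id`, `read_length`, `strand`,
#'   `target`, `match_count`, `aligned_length`, `multi_alignment`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), read_length = integer(),
                  strand = character(), target = character(),
                  match_count = integer(), aligned_length = integer(),
                  multi_alignment = logical()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("malformed PAF: line %d has %d columns (12 required)",
                  which(nf < 12)[1], min(nf)),
          class = "plasmidcons_format_error")
  }
  out <- tibble(
    read_id = vapply(fields, `[[`, character(1), 1),
    read_length = as.integer(vapply(fields, `[[`, character(1), 2)),
    strand = ifelse(vapply(fields, `[[`, character(1), 5) == "+",
                    "forward", "reverse"),
    target = vapply(fields, `[[`, character(1), 6),
    match_count = as.integer(vapply(fields, `[[`, character(1), 10)),
    aligned_length = as.integer(vapply(fields, `[[`, character(1), 11))
  )
  dup <- out$read_id %in% out$read_id[duplicated(out$read_id)]
  out$multi_alignment <- dup
  out
}

#' Write the consensus sequence to FASTA
#'
#' @param consensus A `consensus_result` object.
#' @param path Output path.
#' @param name Record name for the FASTA header.
#' @export
write_consensus_fasta <- function(consensus, path, name = "consensus") {
  if (!nzchar(consensus$sequence)) {
    abort("consensus sequence is empty; nothing to write",
          class = "plasmidcons_validation_error")
  }
  write_fasta(tibble(name = name, sequence = consensus$sequence), path)
}

#' Write the per-position consensus report as TSV
#'
#' One row per pileup column in 5' to 3' traversal order: the 5' terminal
#' junction, every draft base, every between-base junction, and the 3'
#' terminal junction (2L+1 rows for a draft of length L when no junction
#' carries a multi-base insertion). Base columns use 1-based indices;
#' between columns are labelled "i/i+1" for inspection parity with trace
#' viewers. `signal_noise` is written as "inf" when the second count is zero.
#'
#' @param consensus A `consensus_result` object.
#' @param path Output path.
#' @export
write_position_report <- function(consensus, path) {
  calls <- consensus$calls
  if (is.null(calls) || nrow(calls) == 0 || !nzchar(consensus$sequence)) {
    abort("consensus has no position calls; nothing to report",
          class = "plasmidcons_validation_error")
  }
  out <- calls
  out$signal_noise <- ifelse(is.infinite(calls$signal_noise), "inf",
                             format(calls$signal_noise, trim = TRUE))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the JSON run summary for a verification report
#'
#' Serializes the resolved configuration (for provenance), the read-count
#' funnel at each filter stage, the pairing rate, per-pass QC, the verdict
#' and the discrepancy list.
#'
#' @param report A `verification_report` object.
#' @param path Output path.
#' @export
write_run_summary <- function(report, path) {
  summary <- list(
    config = report$config,
    stage_counts = report$stage_counts,
    pairing_rate = report$pairing_rate,
    contamination_flag = report$contamination_flag,
    qc = list(
      forward = list(median_confidence = report$median_confidence[["forward_draft"]],
                     qc_pass = report$qc_pass[["forward_draft"]]),
      reverse = list(median_confidence = report$median_confidence[["reverse_draft"]],
                     qc_pass = report$qc_pass[["reverse_draft"]])
    ),
    agreement = report$agreement,
    verdict = report$verdict,
    discrepancies = report$discrepancies
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
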