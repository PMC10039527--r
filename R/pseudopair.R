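#' Qualify reads for pseudopairing and classify them by strand
#'
#' A read qualifies iff it has a single alignment to the expected reference
#' and its number of aligned bases (identical residues) is no shorter than
#' the reference length minus `slack` bases (inclusive). Qualified reads
#' are partitioned by strand.
#'
#' @param alignments An alignment tibble (from [align_reads()] or
#'   [read_paf()]) computed against the expected reference.
#' @param reference_length Length of the expected reference in bases.
#' @param slack Qualification slack in bases (default 500).
#' @return A list with tibbles `forward` and `reverse`.
#' @export
qualify_reads <- function(alignments, reference_length, slack = 500) {
  ok <- !alignments$multi_alignment &
    alignments$match_count >= reference_length - slack
  q <- alignments[ok, ]
  list(
    forward = q[q$strand == "forward", ],
    reverse = q[q$strand == "reverse", ]
  )
}

#' Pair sense and antisense reads by similar length
#'
#' Both strand lists are sorted ascending by read length (ties broken by
#' read id for reproducibility) and paired index-by-index, preferring pairs
#' of similar length; the shorter list bounds the number of pairs. The
#' pairing rate is the percentage of quality- and length-filtered reads
#' that end up in a pair.
#'
#' @param forward,reverse Tibbles of qualified reads per strand (with
#'   `read_id` and `read_length` columns), as from [qualify_reads()].
#' @param filtered_input_count Number of quality- and length-filtered reads
#'   (the pairing-rate denominator).
#' @return A `pseudopair_set` object.
#' @export
make_pseudopairs <- function(forward, reverse, filtered_input_count) {
  f <- forward[order(forward$read_length, forward$read_id), ]
  r <- reverse[order(reverse$read_length, reverse$read_id), ]
  n_pairs <- min(nrow(f), nrow(r))
  pairs <- tibble(
    forward_read_id = head(f$read_id, n_pairs),
    reverse_read_id = head(r$read_id, n_pairs)
  )
  qualified_count <- nrow(f) + nrow(r)
  pairing_rate <- if (filtered_input_count > 0) {
    100 * (2 * n_pairs) / filtered_input_count
  } else 0
  structure(list(
    pairs = pairs,
    unpaired_forward = if (nrow(f) > n_pairs) {
      f$read_id[(n_pairs + 1):nrow(f)]
    } else character(),
    unpaired_reverse = if (nrow(r) > n_pairs) {
      r$read_id[(n_pairs + 1):nrow(r)]
    } else character(),
    qualified_count = qualified_count,
    filtered_input_count = filtered_input_count,
    pairing_rate = pairing_rate
  ), class = "pseudopair_set")
}

#' @export
print.pseudopair_set <- function(x, ...) {
  cat(sprintf(
    "<pseudopair_set> %d pairs, %d qualified of %d filtered reads, pairing rate %.1f%%\n",
    nrow(x$pairs), x$qualified_count, x$filtered_input_count,
    x$pairing_rate))
  invisible(x)
}

#' Write a pseudopair list as two-column text
#'
#' @param pairs A `pseudopair_set`.
#' @param path Output path.
#' @export
write_pair_list <- function(pairs, path) {
  readr::write_tsv(pairs$pairs, path, col_names = FALSE)
  invisible(path)
}

#' Flag plasmid contamination from the pseudopairing rate
#'
#' Reads from an unrelated plasmid do not align well to the expected
#' reference and therefore fail pseudopair qualification; a pairing rate
#' below the threshold (strict) is evidence of contamination. On a fully
#' wrong reference the rate drops to 0%.
#'
#' @param pairing_rate Pairing rate in percent.
#' @param threshold Flagging threshold in percent (default 90).
#' @return `TRUE` when contamination is suspected.
#' @export
contamination_check <- function(pairing_rate, threshold = 90) {
  pairing_rate < threshold
}

#' Collapse a pseudopair into one higher-accuracy read
#'
#' A sequence-level stand-in for raw-signal duplex basecalling: the reverse
#' read is reverse-complemented and aligned to the forward read; agreeing
#' columns emit the shared base, disagreeing substitution columns emit the
#' higher-quality base (N on a quality tie), and columns where one read has
#' a gap emit the present base only if its quality reaches
#' `indel_quality_threshold` (default 0: always emit). Output qualities are
#' the per-column maximum of the contributing qualities.
#'
#' @param forward,reverse One-row reads tibbles.
#' @param indel_quality_threshold Minimum quality for a one-sided base to
#'   be emitted.
#' @param band_width,scoring Alignment parameters.
#' @return A one-row reads tibble.
#' @export
collapse_pair <- function(forward, reverse, indel_quality_threshold = 0,
                          band_width = 600, scoring = default_scoring()) {
  fseq <- forward$sequence[[1]]
  fq <- forward$qualities[[1]]
  rseq_rc <- reverse_complement(reverse$sequence[[1]])
  rq_rc <- rev(reverse$qualities[[1]])

  aln <- align_read(tibble(read_id = "rev_rc", sequence = rseq_rc,
                           qualities = list(rq_rc)),
                    fseq, band_width = band_width, scoring = scoring)
  ops <- aln$ops
  n_cols <- length(ops$op)
  if (n_cols == 0 || aln$match_count / n_cols < 0.80) {
    abort("pair alignment identity below 80%; reads do not form a pseudopair",
          class = "plasmidcons_pairing_error")
  }
  fchars <- strsplit(fseq, "")[[1]]
  rchars <- strsplit(rseq_rc, "")[[1]]
  out_base <- character(n_cols)
  out_qual <- integer(n_cols)
  keep <- logical(n_cols)
  for (c in seq_len(n_cols)) {
    op <- ops$op[c]
    if (op == 1L) { # agreement
      b <- fchars[ops$ref_pos[c] + 1]
      q <- max(fq[ops$ref_pos[c] + 1], rq_rc[ops$read_pos[c] + 1])
      out_base[c] <- b; out_qual[c] <- q; keep[c] <- TRUE
    } else if (op == 2L) { # substitution disagreement
      qf <- fq[ops$ref_pos[c] + 1]
      qr <- rq_rc[ops$read_pos[c] + 1]
      b <- if (qf > qr) fchars[ops$ref_pos[c] + 1]
           else if (qr > qf) rchars[ops$read_pos[c] + 1]
           else "N"
      out_base[c] <- b; out_qual[c] <- max(qf, qr); keep[c] <- TRUE
    } else if (op == 4L) { # base present only in forward
      q <- fq[ops$ref_pos[c] + 1]
      if (q >= indel_quality_threshold) {
        out_base[c] <- fchars[ops$ref_pos[c] + 1]
        out_qual[c] <- q; keep[c] <- TRUE
      }
    } else { # base present only in reverse
      q <- rq_rc[ops$read_pos[c] + 1]
      if (q >= indel_quality_threshold) {
        out_base[c] <- rchars[ops$read_pos[c] + 1]
        out_qual[c] <- q; keep[c] <- TRUE
      }
    }
  }
  tibble(
    read_id = paste0("pair:", forward$read_id[[1]], "|",
                     reverse$read_id[[1]]),
    sequence = paste(out_base[keep], collapse = ""),
    qualities = list(out_qual[keep])
  )
}
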