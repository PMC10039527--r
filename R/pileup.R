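#' Build the position-array pileup from read alignments
#'
#' The pileup is an array with one column for every draft base and one
#' "between" column for every junction between adjacent draft bases,
#' including the 5' and 3' terminal junctions. Match and mismatch
#' operations increment base counts at base columns; deletions increment
#' the gap count; inserted bases increment between-column sub-columns by
#' insertion offset (first inserted base at offset 0, and so on). Reads
#' aligned straight across a junction with no insertion count as
#' pass-through there. N bases in reads are not counted anywhere.
#'
#' @param alignments An alignment tibble from [align_reads()], computed
#'   against `draft` (reverse-strand reads already contribute their reverse
#'   complement through the aligner).
#' @param draft The draft template the alignments were computed against.
#' @return A `pileup_matrix` object.
#' @export
build_pileup <- function(alignments, draft) {
  draft <- as_template(draft, what = "draft")
  L <- draft$length
  raw <- cpp_pileup(alignments$ops, L)
  base_counts <- raw$base_counts
  rownames(base_counts) <- c("A", "C", "G", "T", "gap")
  depth <- colSums(base_counts)
  pass_through <- pmax(0L, raw$span - raw$with_ins)
  ins <- tibble(
    junction = raw$ins_junction,
    offset = raw$ins_offset,
    base = BASES[raw$ins_base],
    count = raw$ins_count
  )
  structure(list(
    draft = draft,
    draft_length = L,
    base_counts = base_counts,
    depth = depth,
    span = raw$span,
    pass_through = pass_through,
    ins = ins,
    max_coverage = if (L > 0) max(depth) else 0,
    n_reads = nrow(alignments)
  ), class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat(sprintf(
    "<pileup_matrix> draft length %d, %d reads, max coverage %d, %d junctions with insertion evidence\n",
    x$draft_length, x$n_reads, x$max_coverage,
    length(unique(x$ins$junction))))
  invisible(x)
}

# vectorized calling of base columns; cm is the 4 x L A/C/G/T count matrix
call_base_columns <- function(cm, gap, max_coverage, ratio_threshold,
                              coverage_fraction) {
  cm <- unname(cm)
  gap <- unname(gap)
  L <- ncol(cm)
  depth <- colSums(cm) + gap
  top_count <- pmax(cm[1, ], cm[2, ], cm[3, ], cm[4, ])
  top_idx <- max.col(t(cm), ties.method = "first")
  cm2 <- cm
  cm2[cbind(top_idx, seq_len(L))] <- -1L
  second_count <- pmax(cm2[1, ], cm2[2, ], cm2[3, ], cm2[4, ], 0)
  second_idx <- max.col(t(cm2), ties.method = "first")
  status <- ifelse(top_count < coverage_fraction * max_coverage | top_count == 0,
                   "dropped",
                   ifelse(top_count < ratio_threshold * second_count,
                          "N", "base"))
  tibble(
    kind = "base",
    ref_index = seq_len(L),
    offset = NA_integer_,
    status = status,
    base = ifelse(status == "base", BASES[top_idx],
                  ifelse(status == "N", "N", NA_character_)),
    top_base = BASES[top_idx],
    top_count = as.integer(top_count),
    second_base = ifelse(second_count > 0, BASES[second_idx], NA_character_),
    second_count = as.integer(second_count),
    n_A = cm[1, ], n_C = cm[2, ], n_G = cm[3, ], n_T = cm[4, ],
    gap_or_pass = as.integer(gap),
    depth = as.integer(depth),
    confidence = ifelse(depth > 0, 100 * top_count / depth, NA_real_),
    signal_noise = ifelse(second_count == 0,
                          ifelse(top_count > 0, Inf, NA_real_),
                          top_count / second_count)
  )
}

# calling of one between-base junction; ins_j: tibble(offset, base, count)
# for this junction, span_j: reads spanning the junction
call_between_junction <- function(ins_j, span_j, max_coverage,
                                  ratio_threshold, coverage_fraction) {
  rows <- list()
  offsets <- sort(unique(ins_j$offset))
  for (o in offsets) {
    sub <- ins_j[ins_j$offset == o, , drop = FALSE]
    total_ins <- sum(sub$count)
    pass_o <- max(0L, span_j - total_ins)
    bi <- order(-sub$count, sub$base)
    best_count <- sub$count[bi[1]]
    best_base <- sub$base[bi[1]]
    second_ins <- if (nrow(sub) > 1) sub$count[bi[2]] else 0L
    mk <- function(status, base, top_base, top_count, second_base,
                   second_count) {
      tibble(
        kind = "between", ref_index = NA_integer_, offset = o,
        status = status, base = base,
        top_base = top_base, top_count = as.integer(top_count),
        second_base = second_base, second_count = as.integer(second_count),
        n_A = sum(sub$count[sub$base == "A"]),
        n_C = sum(sub$count[sub$base == "C"]),
        n_G = sum(sub$count[sub$base == "G"]),
        n_T = sum(sub$count[sub$base == "T"]),
        gap_or_pass = as.integer(pass_o),
        depth = as.integer(span_j),
        confidence = if (span_j > 0) 100 * top_count / span_j else NA_real_,
        signal_noise = if (second_count == 0) {
          if (top_count > 0) Inf else NA_real_
        } else top_count / second_count
      )
    }
    if (pass_o >= best_count) {
      # pass-through wins the contest at this offset
      if (pass_o >= ratio_threshold * best_count) {
        rows[[length(rows) + 1]] <- mk("no_insertion", NA_character_,
                                       "pass_through", pass_o,
                                       best_base, best_count)
      } else {
        rows[[length(rows) + 1]] <- mk("N", "N", "pass_through", pass_o,
                                       best_base, best_count)
      }
      break
    }
    # an inserted base wins: apply the base-column criteria
    second_count <- max(second_ins, pass_o)
    second_base <- if (pass_o >= second_ins) "pass_through" else
      sub$base[bi[2]]
    if (best_count < coverage_fraction * max_coverage) {
      rows[[length(rows) + 1]] <- mk("dropped", NA_character_, best_base,
                                     best_count, second_base, second_count)
      break
    }
    if (best_count < ratio_threshold * second_count) {
      rows[[length(rows) + 1]] <- mk("N", "N", best_base, best_count,
                                     second_base, second_count)
    } else {
      rows[[length(rows) + 1]] <- mk("base", best_base, best_base,
                                     best_count, second_base, second_count)
    }
  }
  dplyr::bind_rows(rows)
}

#' Apply the consensus calling criteria to a single pileup column
#'
#' Base columns: the top base must be at least `ratio_threshold` times as
#' abundant as the second top base (else N) and its coverage at least
#' `coverage_fraction` of the maximum coverage (else the base is dropped).
#' Gap (deletion) counts do not compete in the ratio contest; they compete
#' only through the coverage criterion, which is what limits deletion
#' sensitivity to very high variant fractions. Between columns: the
#' pass-through count competes against inserted-base counts, which sets the
#' 20% theoretical detection floor for insertions.
#'
#' @param counts For `kind = "base"`: a named numeric vector with entries
#'   among A, C, G, T and optionally `gap`. For `kind = "between"`: a list
#'   with elements `pass_through` (count) and `insertions` (a tibble with
#'   columns `offset`, `base`, `count`).
#' @param max_coverage Maximum base-column depth of the pileup.
#' @param ratio_threshold Top:second abundance ratio required to call
#'   (default 5, inclusive).
#' @param coverage_fraction Minimum top-base coverage as a fraction of
#'   `max_coverage` (default 0.10, inclusive).
#' @param kind "base" or "between".
#' @return A tibble of position calls (a single row for base columns).
#' @export
call_column <- function(counts, max_coverage, ratio_threshold = 5,
                        coverage_fraction = 0.10,
                        kind = c("base", "between")) {
  kind <- match.arg(kind)
  if (kind == "base") {
    cm <- matrix(0L, nrow = 4, ncol = 1, dimnames = list(BASES, NULL))
    for (b in BASES) if (!is.na(counts[b])) cm[b, 1] <- as.integer(counts[b])
    gap <- if ("gap" %in% names(counts)) as.integer(counts[["gap"]]) else 0L
    call_base_columns(cm, gap, max_coverage, ratio_threshold,
                      coverage_fraction)
  } else {
    ins <- counts$insertions
    span_j <- counts$pass_through + sum(ins$count[ins$offset == 0])
    call_between_junction(ins, span_j, max_coverage, ratio_threshold,
                          coverage_fraction)
  }
}

junction_label <- function(j, L) {
  ifelse(j == 0, "5'", ifelse(j == L, "3'", paste0(j, "/", j + 1)))
}

#' Generate the consensus sequence and per-position calls from a pileup
#'
#' Columns are traversed 5' terminal, then base and between columns
#' alternating, then the 3' terminal. Emitted bases and Ns are concatenated
#' into the consensus; dropped columns emit nothing. Per-call confidence is
#' the percent of reads at the position supporting the called base; the
#' run-level QC statistic is the median confidence over called bases, which
#' must exceed `median_confidence_threshold` (strictly) for `qc_pass`.
#'
#' @param pileup A `pileup_matrix`.
#' @param ratio_threshold,coverage_fraction Calling criteria (see
#'   [call_column()]).
#' @param median_confidence_threshold QC threshold in percent (default 99.9).
#' @param pass_label Which pass this consensus belongs to
#'   ("forward_draft" or "reverse_draft").
#' @return A `consensus_result` object.
#' @export
consensus_from_pileup <- function(pileup, ratio_threshold = 5,
                                  coverage_fraction = 0.10,
                                  median_confidence_threshold = 99.9,
                                  pass_label = "forward_draft") {
  L <- pileup$draft_length
  if (L == 0 || pileup$max_coverage == 0) {
    abort("empty pileup: no aligned reads", class = "plasmidcons_validation_error")
  }
  base_calls <- call_base_columns(
    pileup$base_counts[1:4, , drop = FALSE],
    pileup$base_counts[5, ],
    pileup$max_coverage, ratio_threshold, coverage_fraction
  )

  # default between rows (no insertion evidence anywhere)
  junctions <- 0:L
  between_default <- tibble(
    kind = "between", ref_index = NA_integer_, junction = junctions,
    offset = 0L, status = "no_insertion", base = NA_character_,
    top_base = "pass_through",
    top_count = as.integer(pileup$pass_through),
    second_base = NA_character_, second_count = 0L,
    n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L,
    gap_or_pass = as.integer(pileup$pass_through),
    depth = as.integer(pileup$span),
    confidence = NA_real_, signal_noise = NA_real_
  )
  with_ins <- unique(pileup$ins$junction)
  evaluated <- purrr::map(with_ins, function(j) {
    out <- call_between_junction(
      pileup$ins[pileup$ins$junction == j, , drop = FALSE],
      pileup$span[j + 1], pileup$max_coverage,
      ratio_threshold, coverage_fraction
    )
    out$junction <- j
    out
  })
  between_calls <- dplyr::bind_rows(
    between_default[!(junctions %in% with_ins), ],
    dplyr::bind_rows(evaluated)
  )

  base_calls$junction <- NA_integer_
  # traversal order: junction j has key 2j, base i has key 2i - 1
  base_calls$.key <- 2 * base_calls$ref_index - 1
  between_calls$.key <- 2 * between_calls$junction
  calls <- dplyr::bind_rows(base_calls, between_calls)
  calls <- dplyr::arrange(calls, .data$.key, .data$offset)
  calls$.key <- NULL
  calls$kind[!is.na(calls$junction) & calls$junction %in% c(0L, L)] <- "terminal"
  calls$position <- ifelse(calls$kind == "base",
                           as.character(calls$ref_index),
                           junction_label(calls$junction, L))
  calls <- dplyr::relocate(calls, "position", "kind", "ref_index", "junction",
                           "offset", "status", "base")

  emitted <- calls$status %in% c("base", "N")
  sequence <- paste(calls$base[emitted], collapse = "")
  conf_base <- calls$confidence[calls$status == "base"]
  median_confidence <- if (length(conf_base) > 0) median(conf_base) else NA_real_
  structure(list(
    sequence = sequence,
    calls = calls,
    median_confidence = median_confidence,
    qc_pass = isTRUE(median_confidence > median_confidence_threshold),
    pass_label = pass_label,
    draft_length = L,
    max_coverage = pileup$max_coverage
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  n_N <- stringr::str_count(x$sequence, "N")
  cat(sprintf(
    "<consensus_result> pass=%s length=%d N=%d median confidence=%.4g%% qc_pass=%s\n",
    x$pass_label, nchar(x$sequence), n_N, x$median_confidence, x$qc_pass))
  invisible(x)
}

# draft-stage caller: permissive scaffold rules (no Ns, no ratio test).
# Base columns keep the top A/C/G/T base at >= draft_coverage_fraction of
# max coverage; between columns insert on simple majority over pass-through
# OR, to survive homopolymer run-length undercall, when the inserted base
# extends an adjacent run and clears the same coverage floor.
draft_call <- function(pileup, draft_coverage_fraction = 0.05) {
  L <- pileup$draft_length
  cm <- pileup$base_counts[1:4, , drop = FALSE]
  top_count <- pmax(cm[1, ], cm[2, ], cm[3, ], cm[4, ])
  top_idx <- max.col(t(cm), ties.method = "first")
  keep <- top_count >= draft_coverage_fraction * pileup$max_coverage &
    top_count > 0
  base_char <- ifelse(keep, BASES[top_idx], "")

  draft_chars <- strsplit(pileup$draft$sequence, "")[[1]]
  ins_emit <- rep("", L + 1)
  for (j in unique(pileup$ins$junction)) {
    ins_j <- pileup$ins[pileup$ins$junction == j, , drop = FALSE]
    span_j <- pileup$span[j + 1]
    emitted <- character()
    for (o in sort(unique(ins_j$offset))) {
      sub <- ins_j[ins_j$offset == o, , drop = FALSE]
      total_ins <- sum(sub$count)
      pass_o <- max(0L, span_j - total_ins)
      bi <- order(-sub$count, sub$base)
      best_count <- sub$count[bi[1]]
      best_base <- sub$base[bi[1]]
      left <- if (j >= 1) draft_chars[j] else ""
      right <- if (j < L) draft_chars[j + 1] else ""
      extends_run <- best_base == left || best_base == right
      if (best_count > pass_o ||
          (extends_run &&
           best_count >= draft_coverage_fraction * pileup$max_coverage)) {
        emitted <- c(emitted, best_base)
      } else break
    }
    ins_emit[j + 1] <- paste(emitted, collapse = "")
  }
  pieces <- character(2 * L + 1)
  pieces[seq(1, 2 * L + 1, by = 2)] <- ins_emit
  pieces[seq(2, 2 * L, by = 2)] <- base_char
  paste(pieces, collapse = "")
}

#' Build a draft consensus from the reads themselves
#'
#' Subsamples reads deterministically, picks the read whose length is
#' closest to the subsample median as the seed, aligns all subsampled reads
#' to the seed, computes a permissive pileup consensus, and repeats the
#' alignment once against the updated draft (one polish iteration). The
#' draft only needs to be close enough to the truth for banded alignment of
#' the full read set to converge; the final calling criteria are applied
#' against it afterwards on all reads.
#'
#' @param reads A reads tibble (at least 1 read).
#' @param subsample_size Number of reads to subsample (default 500).
#' @param seed Integer seed for the subsample.
#' @param band_width,scoring Alignment parameters (see [align_read()]).
#' @param draft_coverage_fraction Coverage floor for keeping/inserting a
#'   base at the draft stage, as a fraction of max coverage (default 0.05 -
#'   deliberately half the calling threshold so the subsample's sampling
#'   noise cannot pre-empt the full-data coverage decision).
#' @return A one-row template tibble named "draft".
#' @export
build_draft <- function(reads, subsample_size = 500, seed = 1,
                        band_width = 600, scoring = default_scoring(),
                        draft_coverage_fraction = 0.05) {
  n <- nrow(reads)
  if (n < 1) {
    abort("at least one read required", class = "plasmidcons_validation_error")
  }
  idx <- if (n > subsample_size) {
    withr::with_seed(seed, sample.int(n, subsample_size))
  } else seq_len(n)
  sub <- reads[idx, ]
  lens <- nchar(sub$sequence)
  med <- median(lens)
  seed_row <- order(abs(lens - med), sub$read_id)[1]
  draft <- tibble(name = "draft", sequence = sub$sequence[seed_row],
                  length = lens[seed_row])
  for (round in 1:2) {
    alns <- align_reads(sub, draft, band_width = band_width,
                        scoring = scoring)
    pu <- build_pileup(alns, draft)
    seq <- draft_call(pu, draft_coverage_fraction)
    draft <- tibble(name = "draft", sequence = seq, length = nchar(seq))
  }
  draft
}

#' Orient a draft to match an expected reference
#'
#' The draft seed read may come from either strand, so the draft can be
#' built in reverse-complement frame. Aligning it to the expected
#' reference and flipping it when the reverse orientation scores higher
#' puts all downstream coordinates into the expected frame.
#'
#' @param draft The draft template.
#' @param expected The expected reference template.
#' @param band_width,scoring Alignment parameters.
#' @return The draft, reverse-complemented if needed.
#' @export
orient_draft <- function(draft, expected, band_width = 600,
                         scoring = default_scoring()) {
  draft <- as_template(draft, what = "draft")
  expected <- as_template(expected, what = "expected")
  bw <- max(band_width, 2 * abs(draft$length - expected$length) + 32)
  aln <- align_read(draft$sequence, expected, band_width = bw,
                    scoring = scoring)
  if (aln$strand == "reverse") {
    draft$sequence <- reverse_complement(draft$sequence)
  }
  draft
}

# reverse-complement a consensus result back into the draft frame
rc_consensus <- function(cons, L) {
  comp <- function(x) {
    out <- chartr("ACGT", "TGCA", x)
    out
  }
  calls <- cons$calls
  calls$ref_index <- ifelse(calls$kind == "base", L + 1L - calls$ref_index,
                            NA_integer_)
  calls$junction <- ifelse(calls$kind != "base", L - calls$junction,
                           NA_integer_)
  for (col in c("base", "top_base", "second_base")) {
    v <- calls[[col]]
    swap <- !is.na(v) & v %in% BASES
    v[swap] <- comp(v[swap])
    calls[[col]] <- v
  }
  tmp <- calls$n_A; calls$n_A <- calls$n_T; calls$n_T <- tmp
  tmp <- calls$n_C; calls$n_C <- calls$n_G; calls$n_G <- tmp
  calls$.key <- ifelse(calls$kind == "base", 2 * calls$ref_index - 1,
                       2 * calls$junction)
  # multi-base insertions read in the opposite direction after the flip
  calls <- dplyr::arrange(calls, .data$.key, dplyr::desc(.data$offset))
  calls <- dplyr::group_by(calls, .data$.key)
  calls <- dplyr::mutate(calls, offset = ifelse(
    .data$kind == "base", NA_integer_,
    dplyr::row_number() - 1L))
  calls <- dplyr::ungroup(calls)
  calls$.key <- NULL
  calls$kind[!is.na(calls$junction) & calls$junction %in% c(0L, L)] <- "terminal"
  calls$kind[!is.na(calls$junction) & !(calls$junction %in% c(0L, L))] <- "between"
  calls$position <- ifelse(calls$kind == "base",
                           as.character(calls$ref_index),
                           junction_label(calls$junction, L))
  cons$calls <- calls
  cons$sequence <- reverse_complement(cons$sequence)
  cons$pass_label <- "reverse_draft"
  cons
}

#' Dual-pass consensus: against the draft and its reverse complement
#'
#' Because indels are left-aligned, a variant adjacent to a homopolymer can
#' have its support diluted by alignment artefacts in one direction but not
#' the other. The consensus is therefore generated twice - once against the
#' draft, once against its reverse complement (the result mapped back into
#' the draft frame) - and disagreement between the two passes is itself a
#' signal that a variant template may be present.
#'
#' @param reads A reads tibble.
#' @param draft The draft template.
#' @param band_width,scoring Alignment parameters.
#' @param ratio_threshold,coverage_fraction,median_confidence_threshold
#'   Calling criteria (see [consensus_from_pileup()]).
#' @return A list with elements `forward`, `reverse` (both
#'   `consensus_result`, in the draft frame) and `agreement` (logical).
#' @export
dual_pass_consensus <- function(reads, draft, band_width = 600,
                                scoring = default_scoring(),
                                ratio_threshold = 5,
                                coverage_fraction = 0.10,
                                median_confidence_threshold = 99.9) {
  draft <- as_template(draft, what = "draft")
  L <- draft$length
  aln_f <- align_reads(reads, draft, band_width = band_width,
                       scoring = scoring)
  cons_f <- consensus_from_pileup(
    build_pileup(aln_f, draft),
    ratio_threshold = ratio_threshold,
    coverage_fraction = coverage_fraction,
    median_confidence_threshold = median_confidence_threshold,
    pass_label = "forward_draft"
  )
  rc_draft <- tibble(name = "draft_rc",
                     sequence = reverse_complement(draft$sequence),
                     length = L)
  aln_r <- align_reads(reads, rc_draft, band_width = band_width,
                       scoring = scoring)
  cons_r_raw <- consensus_from_pileup(
    build_pileup(aln_r, rc_draft),
    ratio_threshold = ratio_threshold,
    coverage_fraction = coverage_fraction,
    median_confidence_threshold = median_confidence_threshold,
    pass_label = "reverse_draft"
  )
  cons_r <- rc_consensus(cons_r_raw, L)
  list(forward = cons_f, reverse = cons_r,
       agreement = identical(cons_f$sequence, cons_r$sequence))
}
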