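#' Compare a consensus sequence against the expected reference
#'
#' The consensus is globally aligned to the expected sequence (indels
#' left-aligned) and every difference is typed: mismatches become SNVs,
#' consensus-only bases insertions, expected-only bases deletions, and any
#' difference whose observed bases contain N becomes an N call flagged for
#' manual inspection. Maximal runs of adjacent inserted/deleted bases are
#' reported as one discrepancy. Positions are 1-based on the expected
#' reference (insertions are placed after their position). When the
#' consensus carries position calls, the underlying top/second counts and
#' confidence are attached.
#'
#' @param consensus A `consensus_result` object (or a plain character
#'   sequence).
#' @param expected The expected template.
#' @param band_width,scoring Alignment parameters.
#' @return A discrepancy tibble (possibly empty) with columns `kind`,
#'   `position`, `expected_bases`, `observed_bases`, `pass_label`,
#'   `top_count`, `second_count`, `confidence`.
#' @export
compare_to_expected <- function(consensus, expected, band_width = 600,
                                scoring = default_scoring()) {
  expected <- as_template(expected, what = "expected")
  if (is.character(consensus)) {
    consensus <- structure(list(sequence = consensus, calls = NULL,
                                pass_label = "forward_draft"),
                           class = "consensus_result")
  }
  seq <- consensus$sequence
  empty <- tibble(
    kind = character(), position = integer(),
    expected_bases = character(), observed_bases = character(),
    pass_label = character(), top_count = integer(),
    second_count = integer(), confidence = numeric()
  )
  if (identical(seq, expected$sequence)) return(empty)
  bw <- max(band_width, 2 * abs(nchar(seq) - expected$length) + 32)
  aln <- align_read(tibble(read_id = "consensus", sequence = seq,
                           qualities = list(integer())),
                    expected, band_width = bw, scoring = scoring)
  ops <- aln$ops

  # map consensus character index (0-based, oriented) -> call record
  emitted_calls <- NULL
  if (!is.null(consensus$calls)) {
    emitted_calls <- consensus$calls[
      consensus$calls$status %in% c("base", "N"), , drop = FALSE]
  }
  call_info <- function(read_pos) {
    if (is.null(emitted_calls) || is.na(read_pos) || read_pos < 0 ||
        read_pos + 1 > nrow(emitted_calls)) {
      return(list(top = NA_integer_, second = NA_integer_,
                  conf = NA_real_))
    }
    row <- emitted_calls[read_pos + 1, ]
    list(top = row$top_count, second = row$second_count,
         conf = row$confidence)
  }

  exp_chars <- strsplit(expected$sequence, "")[[1]]
  n <- length(ops$op)
  rows <- list()
  c <- 1
  while (c <= n) {
    op <- ops$op[c]
    if (op == 2L) { # mismatch
      obs <- if (ops$base[c] == 0) "N" else BASES[ops$base[c]]
      info <- call_info(ops$read_pos[c])
      rows[[length(rows) + 1]] <- tibble(
        kind = if (obs == "N") "N_call" else "SNV",
        position = ops$ref_pos[c] + 1L,
        expected_bases = exp_chars[ops$ref_pos[c] + 1],
        observed_bases = obs,
        top_count = info$top, second_count = info$second,
        confidence = info$conf
      )
      c <- c + 1
    } else if (op == 3L) { # insertion run
      j <- ops$ref_pos[c]
      e <- c
      while (e + 1 <= n && ops$op[e + 1] == 3L && ops$ref_pos[e + 1] == j) {
        e <- e + 1
      }
      obs <- paste(ifelse(ops$base[c:e] == 0, "N", BASES[ops$base[c:e]]),
                   collapse = "")
      info <- call_info(ops$read_pos[c])
      rows[[length(rows) + 1]] <- tibble(
        kind = if (grepl("N", obs)) "N_call" else "insertion",
        position = j, # insertion after this 1-based expected position
        expected_bases = "",
        observed_bases = obs,
        top_count = info$top, second_count = info$second,
        confidence = info$conf
      )
      c <- e + 1
    } else if (op == 4L) { # deletion run
      e <- c
      while (e + 1 <= n && ops$op[e + 1] == 4L &&
             ops$ref_pos[e + 1] == ops$ref_pos[e] + 1L) {
        e <- e + 1
      }
      rows[[length(rows) + 1]] <- tibble(
        kind = "deletion",
        position = ops$ref_pos[c] + 1L,
        expected_bases = paste(exp_chars[ops$ref_pos[c:e] + 1],
                               collapse = ""),
        observed_bases = "",
        top_count = NA_integer_, second_count = NA_integer_,
        confidence = NA_real_
      )
      c <- e + 1
    } else {
      c <- c + 1
    }
  }
  # bases of the expected reference never covered by the consensus are
  # missing sequence: report them as deletions too
  if (aln$ref_start > 0) {
    rows[[length(rows) + 1]] <- tibble(
      kind = "deletion", position = 1L,
      expected_bases = substr(expected$sequence, 1, aln$ref_start),
      observed_bases = "", top_count = NA_integer_,
      second_count = NA_integer_, confidence = NA_real_
    )
  }
  if (aln$ref_end < expected$length) {
    rows[[length(rows) + 1]] <- tibble(
      kind = "deletion", position = aln$ref_end + 1L,
      expected_bases = substr(expected$sequence, aln$ref_end + 1,
                              expected$length),
      observed_bases = "", top_count = NA_integer_,
      second_count = NA_integer_, confidence = NA_real_
    )
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$pass_label <- consensus$pass_label %||% "forward_draft"
  dplyr::relocate(out, "kind", "position", "expected_bases",
                  "observed_bases", "pass_label")
}

#' Assemble the final verification report
#'
#' Discrepancies from the two passes are unioned (a difference found in
#' either consensus is reported) and deduplicated by kind, position and
#' bases. Verdict precedence: contaminated > qc_fail > variant_detected >
#' inspect_required (only N calls) > verified.
#'
#' @param cmp_forward,cmp_reverse Discrepancy tibbles from
#'   [compare_to_expected()] for the two passes.
#' @param pairing_rate Pairing rate in percent (NA when the pairing stage
#'   was skipped).
#' @param qc_pass Named logical vector for the two passes.
#' @param median_confidence Named numeric vector for the two passes.
#' @param agreement Logical: do the two pass sequences agree?
#' @param pairing_rate_threshold Contamination threshold (default 90).
#' @param stage_counts Optional stage-counter tibble.
#' @param config Optional resolved configuration list for provenance.
#' @return A `verification_report` object.
#' @export
assemble_report <- function(cmp_forward, cmp_reverse, pairing_rate,
                            qc_pass, median_confidence, agreement,
                            pairing_rate_threshold = 90,
                            stage_counts = NULL, config = NULL) {
  both <- dplyr::bind_rows(cmp_forward, cmp_reverse)
  if (nrow(both) > 0) {
    both <- dplyr::group_by(both, .data$kind, .data$position,
                            .data$expected_bases, .data$observed_bases)
    both <- dplyr::summarise(
      both,
      pass_label = paste(sort(unique(.data$pass_label)), collapse = "+"),
      top_count = .data$top_count[1],
      second_count = .data$second_count[1],
      confidence = .data$confidence[1],
      .groups = "drop"
    )
    both <- dplyr::arrange(both, .data$position, .data$kind)
  }
  contaminated <- !is.na(pairing_rate) &&
    contamination_check(pairing_rate, pairing_rate_threshold)
  any_qc_fail <- any(!unlist(qc_pass))
  n_variant <- sum(both$kind %in% c("SNV", "insertion", "deletion"))
  n_ncall <- sum(both$kind == "N_call")
  verdict <- if (contaminated) "contaminated"
  else if (any_qc_fail) "qc_fail"
  else if (n_variant > 0) "variant_detected"
  else if (n_ncall > 0) "inspect_required"
  else "verified"
  structure(list(
    verdict = verdict,
    discrepancies = both,
    pairing_rate = pairing_rate,
    contamination_flag = contaminated,
    qc_pass = qc_pass,
    median_confidence = median_confidence,
    agreement = agreement,
    stage_counts = stage_counts,
    config = config
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> verdict: %s\n", x$verdict))
  if (!is.na(x$pairing_rate)) {
    cat(sprintf("  pairing rate: %.1f%% (contamination %s)\n",
                x$pairing_rate,
                if (x$contamination_flag) "FLAGGED" else "not flagged"))
  }
  cat(sprintf("  median confidence: forward %.4g%%, reverse %.4g%%\n",
              x$median_confidence[["forward_draft"]],
              x$median_confidence[["reverse_draft"]]))
  cat(sprintf("  passes agree: %s\n", x$agreement))
  cat(sprintf("  discrepancies: %d\n", nrow(x$discrepancies)))
  if (nrow(x$discrepancies) > 0) print(x$discrepancies, n = 20)
  invisible(x)
}

# does a discrepancy list hit a mutation site (within a small window that
# absorbs indel-alignment frame shifts)?
detects_mutation <- function(disc, mut, window = 3) {
  if (nrow(disc) == 0) return(FALSE)
  any(abs(disc$position - mut$position) <= window)
}

#' Scan mixtures of wildtype and variant template for detection limits
#'
#' For each variant-read fraction on the grid, simulates a mixed read set
#' at exact counts, runs the consensus pipeline (draft built from the mixed
#' reads, dual-pass calling) and compares both passes to the wildtype
#' expected sequence. A mutation counts as detected at a fraction if either
#' pass shows an N, a changed base, a novel insertion signal or a dropped
#' base at its site. Reports each mutation's minimum detected fraction on
#' the grid.
#'
#' @param wildtype,variant Wildtype and variant templates.
#' @param mutations Mutation tibble describing the wildtype-to-variant
#'   differences (see [mutation()]).
#' @param n_reads Total reads per mixture (default 10000; the detection
#'   thresholds depend on fractions, not absolute depth, for depths well
#'   above 100, so this is configurable downward).
#' @param fractions Variant-read percentages to scan (default 0 to 100 in
#'   5% increments).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param config A [pipeline_config()] for the consensus stages.
#' @return A `mixture_scan` object; its `summary` tibble has one row per
#'   mutation with `min_detected_fraction` (NA when never detected).
#' @export
mixture_scan <- function(wildtype, variant, mutations, n_reads = 10000,
                         fractions = seq(0, 100, by = 5),
                         model = error_model(), seed = 1,
                         config = pipeline_config()) {
  wildtype <- as_template(wildtype, what = "wildtype")
  variant <- as_template(variant, what = "variant")
  if (any(fractions < 0 | fractions > 100)) {
    abort("fractions must be percentages in [0, 100]",
          class = "plasmidcons_parameter_error")
  }
  if (nrow(mutations) == 0) {
    abort("templates identical: no mutations to scan",
          class = "plasmidcons_parameter_error")
  }
  labels <- mutation_label(mutations)
  templates <- dplyr::bind_rows(wildtype, variant)

  detections <- purrr::map_dfr(fractions, function(f) {
    reads <- simulate_mixture(
      templates, c(1 - f / 100, f / 100), n_reads, model = model,
      seed = derive_seed(seed, as.integer(f))
    )
    reads <- filter_reads(reads, wildtype$length,
                          min_qscore = config$min_qscore,
                          length_tolerance = config$length_tolerance)
    draft <- build_draft(reads, subsample_size = config$draft_subsample,
                         seed = derive_seed(seed, 1000L + as.integer(f)),
                         band_width = config$band_width,
                         scoring = config$scoring,
                         draft_coverage_fraction = config$draft_coverage_fraction)
    draft <- orient_draft(draft, wildtype, band_width = config$band_width,
                          scoring = config$scoring)
    passes <- dual_pass_consensus(
      reads, draft, band_width = config$band_width,
      scoring = config$scoring,
      ratio_threshold = config$ratio_threshold,
      coverage_fraction = config$coverage_fraction,
      median_confidence_threshold = config$median_confidence_threshold
    )
    disc <- dplyr::bind_rows(
      compare_to_expected(passes$forward, wildtype,
                          band_width = config$band_width,
                          scoring = config$scoring),
      compare_to_expected(passes$reverse, wildtype,
                          band_width = config$band_width,
                          scoring = config$scoring)
    )
    tibble(
      fraction = f,
      mutation = labels,
      detected = vapply(seq_len(nrow(mutations)), function(k) {
        detects_mutation(disc, mutations[k, ])
      }, logical(1))
    )
  })

  summary <- dplyr::summarise(
    dplyr::group_by(detections, .data$mutation),
    kind = mutations$kind[match(.data$mutation[1], labels)],
    position = mutations$position[match(.data$mutation[1], labels)],
    min_detected_fraction = if (any(.data$detected)) {
      min(.data$fraction[.data$detected])
    } else NA_real_,
    .groups = "drop"
  )
  summary <- summary[match(labels, summary$mutation), ]
  structure(list(
    summary = summary,
    detections = detections,
    fractions = fractions,
    n_reads = n_reads
  ), class = "mixture_scan")
}

#' @export
print.mixture_scan <- function(x, ...) {
  cat(sprintf("<mixture_scan> %d reads per mixture, grid %s%%\n",
              x$n_reads, paste(range(x$fractions), collapse = "-")))
  print(x$summary)
  invisible(x)
}

#' Write mixture-scan results as TSV
#' @param scan A `mixture_scan` object.
#' @param path Output path.
#' @export
write_mixture_scan <- function(scan, path) {
  readr::write_tsv(scan$summary, path)
  invisible(path)
}
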