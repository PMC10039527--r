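#' Pipeline configuration
#'
#' Houses every numeric threshold of the workflow, with the published
#' defaults. The resolved configuration is serialized verbatim into every
#' run summary for provenance.
#'
#' @param min_qscore Per-read minimum base quality (default 12).
#' @param length_tolerance Allowed deviation from the expected template
#'   length in bases (default 250, inclusive).
#' @param pair_qualification_slack Aligned bases may be up to this many
#'   bases shorter than the reference for pseudopair qualification
#'   (default 500).
#' @param ratio_threshold Top:second abundance ratio for calling a base
#'   (default 5).
#' @param coverage_fraction Minimum top-base coverage as a fraction of max
#'   coverage (default 0.10).
#' @param draft_coverage_fraction Coverage floor at the draft stage
#'   (default 0.05).
#' @param median_confidence_threshold Run-level QC threshold in percent
#'   (default 99.9, strict).
#' @param pairing_rate_threshold Contamination flag threshold in percent
#'   (default 90, strict).
#' @param draft_subsample Reads subsampled for the draft (default 500).
#' @param band_width Maximum alignment band breadth in bases (default 600).
#' @param scoring Alignment scoring vector.
#' @param seed Integer seed for all stochastic steps.
#' @param collapse_mode If `TRUE`, pseudopairs are collapsed into single
#'   higher-accuracy sequences before consensus; if `FALSE` (default) the
#'   input reads are treated as already duplex-grade ("pre-collapsed").
#' @export
pipeline_config <- function(min_qscore = 12,
                            length_tolerance = 250,
                            pair_qualification_slack = 500,
                            ratio_threshold = 5,
                            coverage_fraction = 0.10,
                            draft_coverage_fraction = 0.05,
                            median_confidence_threshold = 99.9,
                            pairing_rate_threshold = 90,
                            draft_subsample = 500,
                            band_width = 600,
                            scoring = default_scoring(),
                            seed = 1,
                            collapse_mode = FALSE) {
  stopifnot(min_qscore >= 0, length_tolerance >= 0,
            pair_qualification_slack >= 0, ratio_threshold >= 1,
            coverage_fraction >= 0, coverage_fraction <= 1,
            draft_coverage_fraction >= 0, draft_coverage_fraction <= 1,
            pairing_rate_threshold >= 0, pairing_rate_threshold <= 100,
            draft_subsample >= 1, band_width >= 2)
  structure(list(
    min_qscore = min_qscore,
    length_tolerance = length_tolerance,
    pair_qualification_slack = pair_qualification_slack,
    ratio_threshold = ratio_threshold,
    coverage_fraction = coverage_fraction,
    draft_coverage_fraction = draft_coverage_fraction,
    median_confidence_threshold = median_confidence_threshold,
    pairing_rate_threshold = pairing_rate_threshold,
    draft_subsample = draft_subsample,
    band_width = band_width,
    scoring = scoring,
    seed = seed,
    collapse_mode = collapse_mode
  ), class = "pipeline_config")
}

#' Verify a plasmid read set against its expected sequence
#'
#' Runs the full workflow: quality and length filters, strand
#' classification and pseudopairing against the expected reference
#' (yielding the pairing-rate contamination metric), optional pair
#' collapse, draft consensus from the reads, dual-pass pileup consensus,
#' and comparison of both passes to the expected sequence.
#'
#' @param reads A reads tibble (e.g. from [read_fastq()]).
#' @param expected The expected template (e.g. from [read_fasta()]).
#' @param config A [pipeline_config()].
#' @return A `verification_report`; the two `consensus_result` objects are
#'   attached as `$consensus$forward` / `$consensus$reverse`.
#' @export
verify_plasmid <- function(reads, expected, config = pipeline_config()) {
  expected <- as_template(expected, what = "expected")
  filtered <- filter_reads(reads, expected$length,
                           min_qscore = config$min_qscore,
                           length_tolerance = config$length_tolerance)
  stage_counts <- attr(filtered, "filter_counts")
  if (nrow(filtered) == 0) {
    abort("no reads survived the quality and length filters",
          class = "plasmidcons_insufficient_data")
  }

  aln_exp <- align_reads(filtered, expected, band_width = config$band_width,
                         scoring = config$scoring)
  qualified <- qualify_reads(aln_exp, expected$length,
                             slack = config$pair_qualification_slack)
  pairs <- make_pseudopairs(qualified$forward, qualified$reverse,
                            filtered_input_count = nrow(filtered))
  stage_counts <- dplyr::bind_rows(stage_counts, tibble(
    stage = c("qualified", "paired"),
    n_reads = c(pairs$qualified_count, 2L * nrow(pairs$pairs))
  ))

  cons_reads <- filtered
  if (isTRUE(config$collapse_mode)) {
    if (nrow(pairs$pairs) == 0) {
      abort("collapse mode requested but no pseudopairs were formed",
            class = "plasmidcons_insufficient_data")
    }
    by_id <- setNames(seq_len(nrow(filtered)), filtered$read_id)
    cons_reads <- purrr::map_dfr(seq_len(nrow(pairs$pairs)), function(i) {
      collapse_pair(filtered[by_id[[pairs$pairs$forward_read_id[i]]], ],
                    filtered[by_id[[pairs$pairs$reverse_read_id[i]]], ],
                    band_width = config$band_width,
                    scoring = config$scoring)
    })
  }

  draft <- build_draft(cons_reads, subsample_size = config$draft_subsample,
                       seed = config$seed, band_width = config$band_width,
                       scoring = config$scoring,
                       draft_coverage_fraction = config$draft_coverage_fraction)
  draft <- orient_draft(draft, expected, band_width = config$band_width,
                        scoring = config$scoring)
  passes <- dual_pass_consensus(
    cons_reads, draft, band_width = config$band_width,
    scoring = config$scoring,
    ratio_threshold = config$ratio_threshold,
    coverage_fraction = config$coverage_fraction,
    median_confidence_threshold = config$median_confidence_threshold
  )

  cmp_f <- compare_to_expected(passes$forward, expected,
                               band_width = config$band_width,
                               scoring = config$scoring)
  cmp_r <- compare_to_expected(passes$reverse, expected,
                               band_width = config$band_width,
                               scoring = config$scoring)
  report <- assemble_report(
    cmp_f, cmp_r,
    pairing_rate = pairs$pairing_rate,
    qc_pass = c(forward_draft = passes$forward$qc_pass,
                reverse_draft = passes$reverse$qc_pass),
    median_confidence = c(forward_draft = passes$forward$median_confidence,
                          reverse_draft = passes$reverse$median_confidence),
    agreement = passes$agreement,
    pairing_rate_threshold = config$pairing_rate_threshold,
    stage_counts = stage_counts,
    config = unclass(config)
  )
  report$consensus <- list(forward = passes$forward,
                           reverse = passes$reverse)
  report$pseudopairs <- pairs
  report$draft <- draft
  report
}
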