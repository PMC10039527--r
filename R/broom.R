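#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a consensus result into its per-position calls
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  x$calls
}

#' One-row summary of a consensus result
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  base_rows <- x$calls[x$calls$status == "base", ]
  min_sn <- suppressWarnings(min(base_rows$signal_noise, na.rm = TRUE))
  tibble(
    pass_label = x$pass_label,
    length = nchar(x$sequence),
    n_N = stringr::str_count(x$sequence, "N"),
    n_dropped = sum(x$calls$status == "dropped"),
    median_confidence = x$median_confidence,
    qc_pass = x$qc_pass,
    min_signal_noise = min_sn,
    min_signal_noise_position = if (nrow(base_rows) > 0) {
      base_rows$position[which.min(base_rows$signal_noise)]
    } else NA_character_,
    max_coverage = x$max_coverage
  )
}

#' Tidy a verification report into its discrepancy list
#' @param x A `verification_report`.
#' @param ... Unused.
#' @method tidy verification_report
#' @export
tidy.verification_report <- function(x, ...) {
  x$discrepancies
}

#' One-row summary of a verification report
#' @param x A `verification_report`.
#' @param ... Unused.
#' @method glance verification_report
#' @export
glance.verification_report <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    n_discrepancies = nrow(x$discrepancies),
    pairing_rate = x$pairing_rate,
    contamination_flag = x$contamination_flag,
    agreement = x$agreement,
    median_confidence_forward = x$median_confidence[["forward_draft"]],
    median_confidence_reverse = x$median_confidence[["reverse_draft"]],
    qc_pass_forward = x$qc_pass[["forward_draft"]],
    qc_pass_reverse = x$qc_pass[["reverse_draft"]]
  )
}

#' Tidy a pseudopair set into its pair list
#' @param x A `pseudopair_set`.
#' @param ... Unused.
#' @method tidy pseudopair_set
#' @export
tidy.pseudopair_set <- function(x, ...) {
  x$pairs
}

#' One-row summary of a pseudopair set
#' @param x A `pseudopair_set`.
#' @param ... Unused.
#' @method glance pseudopair_set
#' @export
glance.pseudopair_set <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_unpaired_forward = length(x$unpaired_forward),
    n_unpaired_reverse = length(x$unpaired_reverse),
    qualified_count = x$qualified_count,
    filtered_input_count = x$filtered_input_count,
    pairing_rate = x$pairing_rate
  )
}

#' Tidy a mixture scan into its per-fraction detection table
#' @param x A `mixture_scan`.
#' @param ... Unused.
#' @method tidy mixture_scan
#' @export
tidy.mixture_scan <- function(x, ...) {
  x$detections
}

#' Per-mutation summary of a mixture scan
#' @param x A `mixture_scan`.
#' @param ... Unused.
#' @method glance mixture_scan
#' @export
glance.mixture_scan <- function(x, ...) {
  x$summary
}
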