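#' Filter reads by minimum per-base quality
#'
#' A read is kept iff the minimum over its base qualities is at least
#' `min_qscore` ("all bases at q12 or higher" semantics: the filter is a
#' per-read minimum, not a mean). The number of rejected reads is attached
#' as the `"n_rejected"` attribute.
#'
#' @param reads A reads tibble.
#' @param min_qscore Integer quality threshold (default 12).
#' @return The kept reads (same columns), with attribute `n_rejected`.
#' @export
filter_by_quality <- function(reads, min_qscore = 12) {
  stopifnot(min_qscore >= 0)
  if (nrow(reads) == 0) {
    return(structure(reads, n_rejected = 0L))
  }
  keep <- vapply(reads$qualities, function(q) min(q) >= min_qscore, logical(1))
  structure(reads[keep, ], n_rejected = sum(!keep))
}

#' Filter reads by distance from the expected template length
#'
#' Keeps reads whose length is within `tolerance` bases of
#' `expected_length`, boundary inclusive (|len - expected| <= tolerance).
#'
#' @param reads A reads tibble.
#' @param expected_length Expected template length in bases.
#' @param tolerance Allowed deviation in bases (default 250).
#' @return The kept reads, with attribute `n_rejected`.
#' @export
filter_by_length <- function(reads, expected_length, tolerance = 250) {
  stopifnot(expected_length > 0, tolerance >= 0)
  if (nrow(reads) == 0) {
    return(structure(reads, n_rejected = 0L))
  }
  keep <- abs(nchar(reads$sequence) - expected_length) <= tolerance
  structure(reads[keep, ], n_rejected = sum(!keep))
}

#' Apply the quality and length filters in sequence
#'
#' @param reads A reads tibble.
#' @param expected_length Expected template length in bases.
#' @param min_qscore Minimum per-base quality (default 12).
#' @param length_tolerance Allowed length deviation in bases (default 250).
#' @return The kept reads, with a `"filter_counts"` attribute holding the
#'   stage funnel (input, after quality, after length).
#' @export
filter_reads <- function(reads, expected_length, min_qscore = 12,
                         length_tolerance = 250) {
  n_in <- nrow(reads)
  q <- filter_by_quality(reads, min_qscore)
  l <- filter_by_length(q, expected_length, length_tolerance)
  counts <- tibble(
    stage = c("input", "quality_filter", "length_filter"),
    n_reads = c(n_in, nrow(q), nrow(l))
  )
  structure(l, filter_counts = counts, n_rejected = NULL)
}
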