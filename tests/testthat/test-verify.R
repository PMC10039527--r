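test_that("comparison types discrepancies with exact positions", {
  expected <- make_reference(300, seed = 41)
  expect_equal(nrow(compare_to_expected(expected$sequence, expected)), 0L)

  snv_at <- 120
  s <- expected$sequence
  alt <- setdiff(c("A", "C", "G", "T"),
                 substr(s, snv_at - 1, snv_at + 1) |> strsplit("") |> unlist())[1]
  substr(s, snv_at, snv_at) <- alt
  d <- compare_to_expected(s, expected)
  expect_equal(d$kind, "SNV")
  expect_equal(d$position, snv_at)
  expect_equal(d$observed_bases, alt)

  # a consensus N is typed as an N call carrying the underlying counts
  draft <- pattern_draft(30)
  specs <- c(replicate(8, list(), simplify = FALSE),
             replicate(4, list(sub = list(c(15, "A"))), simplify = FALSE))
  cons <- package_consensus(draft, specs)
  expect_true(grepl("N", cons$sequence))
  dn <- compare_to_expected(cons, draft)
  expect_equal(dn$kind, "N_call")
  expect_equal(dn$top_count, 8L)
  expect_equal(dn$second_count, 4L)
})

test_that("report union covers both passes and verdict precedence holds", {
  d_f <- tibble::tibble(kind = "SNV", position = 10L, expected_bases = "A",
                        observed_bases = "G", pass_label = "forward_draft",
                        top_count = 90L, second_count = 5L,
                        confidence = 94)
  d_r <- d_f
  d_r$pass_label <- "reverse_draft"
  empty <- d_f[0, ]
  qc_ok <- c(forward_draft = TRUE, reverse_draft = TRUE)
  mc <- c(forward_draft = 100, reverse_draft = 100)

  clean <- assemble_report(empty, empty, 95, qc_ok, mc, TRUE)
  expect_equal(clean$verdict, "verified")

  # discrepancy present in only one pass is still reported
  one_pass <- assemble_report(empty, d_r, 95, qc_ok, mc, FALSE)
  expect_equal(one_pass$verdict, "variant_detected")
  expect_equal(nrow(one_pass$discrepancies), 1L)
  expect_equal(one_pass$discrepancies$pass_label, "reverse_draft")

  # the same discrepancy in both passes is deduplicated
  both <- assemble_report(d_f, d_r, 95, qc_ok, mc, TRUE)
  expect_equal(nrow(both$discrepancies), 1L)
  expect_equal(both$discrepancies$pass_label,
               "forward_draft+reverse_draft")

  # contamination trumps everything else
  cont <- assemble_report(d_f, d_r, 0, qc_ok, mc, TRUE)
  expect_equal(cont$verdict, "contaminated")

  qc_bad <- c(forward_draft = TRUE, reverse_draft = FALSE)
  expect_equal(assemble_report(d_f, d_r, 95, qc_bad, mc, TRUE)$verdict,
               "qc_fail")

  n_only <- d_f
  n_only$kind <- "N_call"
  n_only$observed_bases <- "N"
  expect_equal(assemble_report(n_only, empty, 95, qc_ok, mc, TRUE)$verdict,
               "inspect_required")
})

test_that("noiseless mixture detection is monotone on the fraction grid", {
  wt <- make_reference(300, seed = 51)
  at <- function(p) substr(wt$sequence, p, p)
  other <- function(p) setdiff(c("A", "C", "G", "T"),
                               c(at(p - 1), at(p), at(p + 1)))[1]
  muts <- dplyr::bind_rows(
    mutation("SNV", 100, at(100), other(100)),
    mutation("deletion", 200, ref_base = at(200))
  )
  var <- apply_mutations(wt, muts)
  scan <- mixture_scan(wt, var, muts, n_reads = 60,
                       fractions = seq(0, 100, 20),
                       model = perfect_reads(), seed = 52,
                       config = pipeline_config(draft_subsample = 40))
  det <- tidy(scan)
  for (m in unique(det$mutation)) {
    flags <- det$detected[det$mutation == m][order(det$fraction[det$mutation == m])]
    expect_true(all(diff(as.integer(flags)) >= 0),
                info = sprintf("%s detection not monotone", m))
  }
  # nothing is ever detected in a pure wildtype mixture
  expect_false(any(det$detected[det$fraction == 0]))
  # everything is detected at 100%
  expect_true(all(det$detected[det$fraction == 100]))
  expect_error(mixture_scan(wt, var, muts[0, ]),
               class = "plasmidcons_parameter_error")
})

test_that("infer_mutations recovers the designed edits from the two templates", {
  wt <- make_reference(500, seed = 61)
  at <- function(p) substr(wt$sequence, p, p)
  other <- function(p) setdiff(c("A", "C", "G", "T"),
                               c(at(p - 1), at(p), at(p + 1)))[1]
  # deletions report at the leftmost equivalent placement, so pick a
  # deletion site whose base differs from both neighbours
  del_site <- 400
  while (at(del_site) == at(del_site - 1) ||
           at(del_site) == at(del_site + 1)) {
    del_site <- del_site + 1
  }
  muts <- dplyr::bind_rows(
    mutation("SNV", 100, at(100), other(100)),
    mutation("insertion", 250, alt_base = other(250)),
    mutation("deletion", del_site, ref_base = at(del_site))
  )
  var <- apply_mutations(wt, muts)
  got <- infer_mutations(wt, var)
  expect_equal(nrow(got), 3L)
  expect_equal(sort(got$kind), sort(muts$kind))
  expect_equal(sort(got$position), sort(muts$position))
})
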