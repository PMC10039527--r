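test_that("make_reference embeds exact homopolymer runs deterministically", {
  tpl <- make_reference(3000, seed = 5,
                        homopolymer_runs = list(list(1500, "A", 17)))
  expect_equal(tpl$length, 3000L)
  expect_equal(substr(tpl$sequence, 1500, 1516), strrep("A", 17))
  # flanks forced to differ: run is exactly 17
  expect_false(grepl(strrep("A", 18), tpl$sequence))

  tpl18 <- make_reference(3000, seed = 5,
                          homopolymer_runs = list(list(1000, "G", 18)))
  expect_true(grepl(strrep("G", 18), tpl18$sequence))

  expect_identical(make_reference(500, seed = 9), make_reference(500, seed = 9))
  expect_error(make_reference(3000, seed = 1,
                              homopolymer_runs = list(list(100, "A", 10),
                                                      list(105, "C", 10))),
               class = "plasmidcons_parameter_error")
})

test_that("apply_mutations edits right-to-left and validates ref bases", {
  expect_equal(apply_mutations("AAGT", mutation("SNV", 3, "G", "C"))$sequence,
               "AACT")
  muts <- dplyr::bind_rows(mutation("deletion", 2, ref_base = "A"),
                           mutation("insertion", 4, alt_base = "T"))
  expect_equal(apply_mutations("AAGT", muts)$sequence, "AGTT")
  expect_error(apply_mutations("AAGT", mutation("SNV", 3, "C", "T")),
               regexp = "position 3", class = "plasmidcons_validation_error")
})

test_that("a balanced 9-mutation set keeps length and yields 9 alignment differences", {
  wt <- make_reference(2000, seed = 31)
  sites <- c(200, 400, 600, 800, 1000, 1200, 1400, 1600, 1800)
  at <- function(p) substr(wt$sequence, p, p)
  other <- function(p) setdiff(c("A", "C", "G", "T"),
                               c(at(p - 1), at(p), at(p + 1)))[1]
  muts <- dplyr::bind_rows(
    mutation("SNV", sites[1], at(sites[1]), other(sites[1])),
    mutation("SNV", sites[2], at(sites[2]), other(sites[2])),
    mutation("SNV", sites[3], at(sites[3]), other(sites[3])),
    mutation("insertion", sites[4], alt_base = other(sites[4])),
    mutation("insertion", sites[5], alt_base = other(sites[5])),
    mutation("insertion", sites[6], alt_base = other(sites[6])),
    mutation("deletion", sites[7], ref_base = at(sites[7])),
    mutation("deletion", sites[8], ref_base = at(sites[8])),
    mutation("deletion", sites[9], ref_base = at(sites[9]))
  )
  var <- apply_mutations(wt, muts)
  expect_equal(var$length, wt$length)
  # pairwise-alignment oracle: exactly 9 differing columns
  disc <- compare_to_expected(var$sequence, wt)
  expect_equal(nrow(disc), 9L)
  expect_equal(sort(table(disc$kind), decreasing = TRUE),
               sort(table(c(rep("SNV", 3), rep("insertion", 3),
                            rep("deletion", 3))), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("mutation notation parses and round-trips", {
  m <- parse_mutation(c("1886delT", "T2010A", "2205insA"))
  expect_equal(m$kind, c("deletion", "SNV", "insertion"))
  expect_equal(m$position, c(1886L, 2010L, 2205L))
  expect_error(parse_mutation("nonsense"),
               class = "plasmidcons_parameter_error")
})

test_that("zero-error reads are exact template copies and reverse reads invert", {
  tpl <- make_reference(400, seed = 2)
  reads <- simulate_reads(tpl, 20, model = perfect_reads(),
                          fraction_reverse = 0.5, seed = 3)
  fwd <- grepl("_F$", reads$read_id)
  expect_equal(sum(fwd), 10L)
  expect_true(all(reads$sequence[fwd] == tpl$sequence))
  expect_true(all(reverse_complement(reads$sequence[!fwd]) == tpl$sequence))
  expect_identical(reads,
                   simulate_reads(tpl, 20, model = perfect_reads(),
                                  fraction_reverse = 0.5, seed = 3))
})

test_that("strand-bias sites miscall only the designated strand at the stated rate", {
  tpl <- make_reference(300, seed = 4)
  sb <- tibble::tibble(position = 150, strand = "reverse",
                       wrong_base = "T", prob = 0.9)
  model <- error_model(dispersed_error = 0, homopolymer_undercall = NULL,
                       strand_bias_sites = sb)
  n <- 4000
  reads <- simulate_reads(tpl, n, model = model, seed = 6)
  rev <- grepl("_R$", reads$read_id)
  # reverse reads carry the site at rc coordinates, complemented
  rc_pos <- 300 - 150 + 1
  rev_base <- chartr("ACGT", "TGCA",
                     substr(reads$sequence[rev], rc_pos, rc_pos))
  frac <- mean(rev_base == "T")
  # binomial 99% interval around 0.9
  half <- 2.58 * sqrt(0.9 * 0.1 / sum(rev))
  expect_gt(frac, 0.9 - half)
  expect_lt(frac, 0.9 + half)
  fwd_base <- substr(reads$sequence[!rev], 150, 150)
  expect_true(all(fwd_base == substr(tpl$sequence, 150, 150)))
})

test_that("homopolymer undercall calibrated to 17.3% full support is realized", {
  tpl <- make_reference(400, seed = 11,
                        homopolymer_runs = list(list(200, "A", 17)))
  tab <- list(`17` = c(`17` = 0.173, `16` = 0.2757, `15` = 0.2757,
                       `14` = 0.2756))
  model <- error_model(dispersed_error = 0, homopolymer_undercall = tab)
  reads <- simulate_reads(tpl, 6000, model = model, fraction_reverse = 0,
                          seed = 8)
  full <- mean(grepl(strrep("A", 17), reads$sequence))
  expect_gt(full, 0.173 - 0.02)
  expect_lt(full, 0.173 + 0.02)
})

test_that("realized dispersed substitution rate converges to the configured rate", {
  tpl <- make_reference(2000, seed = 13)
  model <- error_model(dispersed_error = 0.01, sub_frac = 1, ins_frac = 0,
                       del_frac = 0, homopolymer_undercall = NULL)
  reads <- simulate_reads(tpl, 500, model = model, fraction_reverse = 0,
                          seed = 14)
  tchars <- strsplit(tpl$sequence, "")[[1]]
  n_sub <- sum(vapply(reads$sequence, function(s) {
    sum(strsplit(s, "")[[1]] != tchars)
  }, numeric(1)))
  rate <- n_sub / (500 * 2000)
  expect_gt(rate, 0.009)
  expect_lt(rate, 0.011)
})

test_that("mixture read counts are exact and provenance is conserved", {
  a <- make_reference(200, seed = 1, name = "wt")
  b <- make_reference(200, seed = 2, name = "var")
  tpls <- dplyr::bind_rows(a, b)
  mix <- simulate_mixture(tpls, c(0.95, 0.05), 1000,
                          model = perfect_reads(), seed = 3)
  prov <- attr(mix, "provenance")
  expect_equal(nrow(mix), 1000L)
  expect_equal(sum(prov$template == "wt"), 950L)
  expect_equal(sum(prov$template == "var"), 50L)

  mix2 <- simulate_mixture(tpls, c(0.5, 0.5), 11, model = perfect_reads(),
                           seed = 3)
  tab <- table(attr(mix2, "provenance")$template)
  expect_equal(sum(tab), 11)
  expect_true(all(tab %in% c(5, 6)))

  mix3 <- simulate_mixture(tpls[1, ], 1, 25, model = perfect_reads(),
                           seed = 4)
  expect_true(all(attr(mix3, "provenance")$template == "wt"))

  expect_error(simulate_mixture(tpls, c(0.6, 0.5), 100),
               class = "plasmidcons_parameter_error")
})
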