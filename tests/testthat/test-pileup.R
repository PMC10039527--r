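test_that("calling criteria match the stated boundary cases exactly", {
  mc <- 1000
  # ratio criterion: 800 vs 200 fails 5x -> N
  r1 <- call_column(c(C = 800, T = 200), mc)
  expect_equal(r1$status, "N")
  # "at least 5x" is inclusive: 500 vs 100 is called
  r2 <- call_column(c(C = 500, T = 100), mc)
  expect_equal(r2$status, "base")
  expect_equal(r2$base, "C")
  # "at least 10% of max coverage" is inclusive: 100/1000 survives a 900 gap
  r3 <- call_column(c(A = 100, gap = 900), mc)
  expect_equal(r3$status, "base")
  expect_equal(r3$base, "A")
  expect_equal(r3$confidence, 10)
  # 9% is dropped
  r4 <- call_column(c(A = 90, gap = 910), mc)
  expect_equal(r4$status, "dropped")
  # between column: pass-through 80 vs inserted 20 fails the ratio -> N
  expect_equal(call_column(list(pass_through = 80,
                                insertions = tibble::tibble(
                                  offset = 0L, base = "A", count = 20L)),
                           mc, kind = "between")$status, "N")
  # pass-through 85 vs 15 clears it -> no insertion
  expect_equal(call_column(list(pass_through = 85,
                                insertions = tibble::tibble(
                                  offset = 0L, base = "A", count = 15L)),
                           mc, kind = "between")$status, "no_insertion")
  # a top-count tie cannot satisfy the ratio -> N
  expect_equal(call_column(c(A = 300, G = 300), mc)$status, "N")
})

test_that("pileup counts are conserved and track insertions by offset", {
  draft <- pattern_draft(12)
  specs <- c(
    replicate(7, list(), simplify = FALSE),
    list(list(del = 5L)),
    list(list(ins = list(c(6, "T")))),
    list(list(ins = list(c(6, "T"), c(6, "T")))) # two-base insertion
  )
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", seq_along(specs)),
    sequence = vapply(specs, function(s) edit_sequence(draft, s),
                      character(1)),
    qualities = purrr::map(specs, ~ list())
  )
  reads$qualities <- lapply(reads$sequence, function(s) rep(20L, nchar(s)))
  pu <- build_pileup(align_reads(reads, draft), draft)

  # every base column: base counts + gap = depth
  expect_true(all(colSums(pu$base_counts) == pu$depth))
  expect_equal(unname(pu$base_counts["gap", 5]), 1L)
  expect_equal(unname(pu$depth[5]), 10)
  # junction 6: one read with 1 insertion, one with 2; pass-through 8
  ins6 <- pu$ins[pu$ins$junction == 6, ]
  expect_equal(ins6$count[ins6$offset == 0], 2L)
  expect_equal(ins6$count[ins6$offset == 1], 1L)
  expect_equal(pu$pass_through[7], 8L)
  expect_equal(pu$span[7], 10L)
  expect_equal(pu$max_coverage, 10)
})

test_that("consensus equals the exhaustive small-instance oracle under the same criteria", {
  withr::with_seed(99, {
    for (case in 1:12) {
      L <- sample(20:40, 1)
      draft <- pattern_draft(L)
      n <- sample(6:10, 1)
      n_var <- sample(0:n, 1)
      site <- sample(5:(L - 5), 1)
      # avoid edits colliding with pattern period at the site boundary
      kind <- sample(c("sub", "del", "ins"), 1)
      mk_spec <- function(variant) {
        if (!variant) return(list())
        if (kind == "sub") {
          cur <- substr(draft, site, site)
          list(sub = list(c(site, setdiff(c("A", "C", "G", "T"),
                                          c(cur,
                                            substr(draft, site - 1, site - 1),
                                            substr(draft, site + 1, site + 1))))))
        } else if (kind == "del") {
          list(del = site)
        } else {
          nb <- setdiff(c("A", "C", "G", "T"),
                        c(substr(draft, site, site),
                          substr(draft, site + 1, site + 1)))[1]
          list(ins = list(c(site, nb)))
        }
      }
      specs <- c(replicate(n - n_var, mk_spec(FALSE), simplify = FALSE),
                 replicate(n_var, mk_spec(TRUE), simplify = FALSE))
      expected <- oracle_consensus(draft, specs)
      got <- package_consensus(draft, specs)
      expect_equal(got$sequence, expected,
                   info = sprintf("case %d (kind %s, %d/%d variant)",
                                  case, kind, n_var, n))
    }
  })
})

test_that("draft building recovers the template from clean and noisy reads", {
  tpl <- make_reference(400, seed = 3)
  clean <- copy_reads(tpl, 30)
  d1 <- build_draft(clean, subsample_size = 500, seed = 1)
  expect_equal(d1$sequence, tpl$sequence)

  # only 3 reads available: all used
  d2 <- build_draft(clean[1:3, ], subsample_size = 500, seed = 1)
  expect_equal(d2$sequence, tpl$sequence)

  noisy <- simulate_reads(tpl, 60, model = error_model(), seed = 4)
  d3 <- build_draft(noisy, subsample_size = 60, seed = 2)
  d3 <- orient_draft(d3, tpl)
  expect_equal(d3$sequence, tpl$sequence)
})

test_that("error-free reads give a perfect dual-pass consensus with full confidence", {
  tpl <- make_reference(300, seed = 6)
  reads <- simulate_reads(tpl, 20, model = perfect_reads(), seed = 7)
  draft <- orient_draft(build_draft(reads, seed = 1), tpl)
  passes <- dual_pass_consensus(reads, draft)
  expect_equal(passes$forward$sequence, tpl$sequence)
  expect_equal(passes$reverse$sequence, tpl$sequence)
  expect_true(passes$agreement)
  expect_true(all(passes$forward$calls$confidence[
    passes$forward$calls$status == "base"] == 100))
  expect_true(passes$forward$qc_pass)
  expect_equal(passes$forward$median_confidence, 100)
})

test_that("signal:noise and confidence arithmetic follow the counts", {
  draft <- pattern_draft(20)
  specs <- c(replicate(24, list(), simplify = FALSE),
             list(list(sub = list(c(10, "T")))))
  cons <- package_consensus(draft, specs)
  row <- cons$calls[cons$calls$kind == "base" & cons$calls$ref_index == 10, ]
  expect_equal(row$top_count, 24L)
  expect_equal(row$second_count, 1L)
  expect_equal(row$confidence, 100 * 24 / 25)
  expect_equal(row$signal_noise, 24)
  clean_row <- cons$calls[cons$calls$kind == "base" &
                            cons$calls$ref_index == 11, ]
  expect_true(is.infinite(clean_row$signal_noise))
})

test_that("the whole module is reverse-complement symmetric", {
  tpl <- make_reference(300, seed = 16,
                        homopolymer_runs = list(list(150, "A", 8)))
  model <- error_model()
  reads <- simulate_reads(tpl, 40, model = model, seed = 17)
  draft <- orient_draft(build_draft(reads, seed = 2), tpl)
  passes <- dual_pass_consensus(reads, draft)

  rc_reads <- reads
  rc_reads$sequence <- reverse_complement(reads$sequence)
  rc_reads$qualities <- lapply(reads$qualities, rev)
  rc_draft <- tibble::tibble(name = "draft",
                             sequence = reverse_complement(draft$sequence),
                             length = draft$length)
  rc_passes <- dual_pass_consensus(rc_reads, rc_draft)
  expect_equal(rc_passes$forward$sequence,
               reverse_complement(passes$forward$sequence))
  expect_equal(rc_passes$agreement, passes$agreement)
})

test_that("a homopolymer base with terminal support above the coverage floor is retained", {
  tpl <- make_reference(500, seed = 21,
                        homopolymer_runs = list(list(250, "A", 17)))
  tab <- list(`17` = c(`17` = 0.173, `16` = 0.2757, `15` = 0.2757,
                       `14` = 0.2756))
  model <- error_model(dispersed_error = 0, homopolymer_undercall = tab)
  reads <- simulate_reads(tpl, 300, model = model, seed = 22)
  draft <- orient_draft(build_draft(reads, subsample_size = 150, seed = 3),
                        tpl)
  passes <- dual_pass_consensus(reads, draft)
  run <- regmatches(passes$forward$sequence,
                    gregexpr("A{5,}", passes$forward$sequence))[[1]]
  expect_true(17 %in% nchar(run))
  expect_equal(passes$forward$sequence, tpl$sequence)
  # terminal run support sits near 17.3% of coverage, well above 10%
  calls <- passes$forward$calls
  run_conf <- calls$confidence[calls$kind == "base" &
                                 calls$ref_index %in% 250:266]
  expect_gt(min(run_conf), 10)
  expect_lt(min(run_conf), 30)
})

test_that("an empty pileup is an explicit error", {
  draft <- pattern_draft(10)
  alns <- align_reads(copy_reads(draft, 1), draft)
  pu <- build_pileup(alns[0, ], draft)
  expect_error(consensus_from_pileup(pu),
               class = "plasmidcons_validation_error")
})
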