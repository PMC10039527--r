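test_that("reverse_complement complements, reverses and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANC"), "GNT")
  expect_equal(reverse_complement(reverse_complement("AACGTTGCA")),
               "AACGTTGCA")
  expect_error(reverse_complement("ACGU"),
               class = "plasmidcons_validation_error")
})

test_that("exact copies align all-match in the correct orientation", {
  ref <- make_reference(300, seed = 1)
  a <- align_read(ref$sequence, ref)
  expect_equal(a$strand, "forward")
  expect_equal(a$match_count, 300L)
  expect_true(all(a$ops$op == 1L))

  a2 <- align_read(reverse_complement(ref$sequence), ref)
  expect_equal(a2$strand, "reverse")
  expect_equal(a2$match_count, 300L)
})

test_that("single edits produce single left-aligned operations", {
  ref <- "ACGTCAAAAAGTCAGGCA"
  # deletion inside the A-run lands on the first A
  a <- align_read("ACGTCAAAAGTCAGGCA", ref)
  expect_equal(sum(a$ops$op == 4L), 1L)
  expect_equal(a$ops$ref_pos[a$ops$op == 4L], 5L)
  # insertion extending the run lands at the run start junction
  b <- align_read("ACGTCAAAAAAGTCAGGCA", ref)
  expect_equal(sum(b$ops$op == 3L), 1L)
  expect_equal(b$ops$ref_pos[b$ops$op == 3L], 5L)
  # substitution: exactly one mismatch, match_count = length - 1
  s <- ref
  substr(s, 15, 15) <- "T"
  c_ <- align_read(s, ref)
  expect_equal(sum(c_$ops$op == 2L), 1L)
  expect_equal(c_$match_count, nchar(ref) - 1L)
})

test_that("banded aligner agrees with the unbanded Biostrings oracle on sequences <= 200 bp", {
  skip_if_not_installed("Biostrings")
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  oracle_score <- function(read, ref) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2))
  }
  withr::with_seed(42, {
    for (k in 1:25) {
      n <- sample(40:200, 1)
      ref <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      read <- if (k %% 3 == 0) {
        paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "") # unrelated
      } else {
        ch <- strsplit(ref, "")[[1]]
        for (i in sample(seq_along(ch), sample(1:6, 1))) {
          ch[i] <- sample(c("A", "C", "G", "T"), 1)
        }
        if (runif(1) < 0.5) ch <- ch[-sample(seq_along(ch), 1)]
        if (runif(1) < 0.3) ch <- append(ch, "A", sample(seq_along(ch), 1))
        paste(ch, collapse = "")
      }
      if (runif(1) < 0.3) read <- reverse_complement(read)
      ours <- align_read(read, ref)
      best <- max(oracle_score(read, ref),
                  oracle_score(reverse_complement(read), ref))
      expect_equal(ours$score, best,
                   info = sprintf("case %d: banded score != oracle", k))
    }
  })
})

test_that("strand symmetry: aligning rc(read) to rc(reference) mirrors the alignment", {
  withr::with_seed(11, {
    ref <- make_reference(250, seed = 21)
    ch <- strsplit(ref$sequence, "")[[1]]
    ch[c(50, 120)] <- c("A", "C")
    ch <- ch[-200]
    read <- paste(ch, collapse = "")
    a <- align_read(read, ref)
    b <- align_read(reverse_complement(read),
                    reverse_complement(ref$sequence))
    expect_equal(a$match_count, b$match_count)
    expect_equal(a$score, b$score)
  })
})

test_that("gaps sit at the leftmost equivalent placement", {
  # oracle enumeration on small cases: any left shift of the reported gap
  # must change alignment columns (i.e. the shifted placement is invalid)
  shifts_ok <- function(ref, read) {
    a <- align_read(read, ref)
    dels <- which(a$ops$op == 4L)
    for (d in dels) {
      p <- a$ops$ref_pos[d] # 0-based position of the deleted ref base
      in_run_tail <- d > 1 && a$ops$op[d - 1] == 4L
      if (p > 0 && !in_run_tail) {
        # shifting the gap one base left would require the base to its
        # left to equal the deleted base; assert that is not the case
        expect_true(substr(ref, p, p) != substr(ref, p + 1, p + 1),
                    info = sprintf("deletion at %d not left-aligned", p))
      }
    }
    invisible(NULL)
  }
  shifts_ok("TTCAAAAGG", "TTCAAAGG")
  shifts_ok("TTCAAAAGGGTT", "TTCAAAGGGTT")
  shifts_ok("AGGGGCTTTTA", "AGGGCTTTA")
})

test_that("a band narrower than the length difference is an explicit error", {
  expect_error(align_read(strrep("ACGT", 100), strrep("ACGT", 10),
                          band_width = 10),
               regexp = "band",
               class = "plasmidcons_band_error")
})
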