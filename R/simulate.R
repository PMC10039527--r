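#' Nanopore-style read error model
#'
#' Describes how synthetic reads are corrupted. Dispersed errors (isolated
#' substitutions, insertions and deletions scattered uniformly along the
#' read) are parameterised by a total rate and a kind split; systematic
#' errors are modelled separately because that is how duplex-grade nanopore
#' data actually misbehaves: run-length undercall inside homopolymers, and
#' optional strand-specific miscalls at fixed template sites.
#'
#' The defaults emulate a duplex-grade read: 0.07% dispersed error
#' (70/15/15 substitution/insertion/deletion) plus homopolymer run-length
#' undercall on runs of 5 or more, which together land near the 0.5%
#' aggregate error typical of pseudopaired basecalls on templates with long
#' homopolymers. Substitutions are deliberately rare and dispersed while
#' indel error concentrates in homopolymers; this is what keeps the median
#' per-base confidence of a deep consensus above 99.9%.
#'
#' Simulated error bases receive quality `error_quality` (default 14), which
#' sits above the default read filter threshold of 12: a per-read-minimum
#' quality filter would otherwise discard every read carrying any simulated
#' error. Deliberately low-quality reads for filter testing are produced by
#' the `n_low_quality` argument of [simulate_reads()] instead.
#'
#' @param dispersed_error Total per-base probability of a dispersed error.
#' @param sub_frac,ins_frac,del_frac Split of `dispersed_error` into
#'   substitutions, insertions and deletions; must sum to 1.
#' @param homopolymer_undercall `NULL` for none, a per-base dropout
#'   probability (see [hp_undercall()]), or a named list mapping run length
#'   to a named probability vector over reported run lengths.
#' @param min_homopolymer Minimum run length subject to undercall.
#' @param strand_bias_sites `NULL` or a tibble with columns `position`,
#'   `strand` ("forward"/"reverse"), `wrong_base`, `prob`: a systematic
#'   miscall applied only to reads of the designated strand.
#' @param end_raggedness Maximum number of bases randomly truncated from
#'   each read end.
#' @param base_quality,error_quality Quality scores assigned to correct and
#'   to simulator-flagged error bases.
#' @return An object of class `error_model`.
#' @export
error_model <- function(dispersed_error = 7e-4,
                        sub_frac = 0.70, ins_frac = 0.15, del_frac = 0.15,
                        homopolymer_undercall = hp_undercall(),
                        min_homopolymer = 5,
                        strand_bias_sites = NULL,
                        end_raggedness = 0,
                        base_quality = 20L,
                        error_quality = 14L) {
  stopifnot(dispersed_error >= 0, dispersed_error <= 1)
  if (abs(sub_frac + ins_frac + del_frac - 1) > 1e-9) {
    abort("sub_frac + ins_frac + del_frac must sum to 1",
          class = "plasmidcons_parameter_error")
  }
  if (!is.null(strand_bias_sites)) {
    stopifnot(all(c("position", "strand", "wrong_base", "prob") %in%
                    names(strand_bias_sites)))
    stopifnot(all(strand_bias_sites$prob >= 0 & strand_bias_sites$prob <= 1))
  }
  structure(list(
    substitution_rate = dispersed_error * sub_frac,
    insertion_rate = dispersed_error * ins_frac,
    deletion_rate = dispersed_error * del_frac,
    homopolymer_undercall = homopolymer_undercall,
    min_homopolymer = min_homopolymer,
    strand_bias_sites = strand_bias_sites,
    end_raggedness = end_raggedness,
    base_quality = as.integer(base_quality),
    error_quality = as.integer(error_quality)
  ), class = "error_model")
}

#' Zero-error model (reads are exact template copies)
#' @export
perfect_reads <- function() {
  error_model(dispersed_error = 0, homopolymer_undercall = NULL,
              end_raggedness = 0)
}

#' Homopolymer run-length undercall model
#'
#' With per-base dropout probability `dropout`, a true run of length r is
#' reported with length drawn from Binomial(r, 1 - dropout). The default
#' dropout 0.098 makes the probability of reporting a full 17-mer about
#' 17.3%, matching the coverage decay seen over long homopolymers in real
#' duplex-grade nanopore data.
#'
#' @param dropout Per-base dropout probability within a qualifying run.
#' @export
hp_undercall <- function(dropout = 0.098) {
  stopifnot(dropout >= 0, dropout <= 1)
  structure(list(dropout = dropout), class = "hp_undercall")
}

# normalize the homopolymer_undercall field to a sampler:
# function(run_length, n_samples) -> integer vector of reported lengths
undercall_sampler <- function(model) {
  hu <- model$homopolymer_undercall
  if (is.null(hu)) return(NULL)
  if (inherits(hu, "hp_undercall")) {
    dropout <- hu$dropout
    return(function(run_length, n) {
      rbinom(n, run_length, 1 - dropout)
    })
  }
  if (is.list(hu)) {
    for (tab in hu) {
      if (abs(sum(tab) - 1) > 1e-9) {
        abort("undercall distributions must sum to 1 per run length",
              class = "plasmidcons_parameter_error")
      }
    }
    return(function(run_length, n) {
      tab <- hu[[as.character(run_length)]]
      if (is.null(tab)) return(rep.int(run_length, n))
      sample(as.integer(names(tab)), n, replace = TRUE, prob = tab)
    })
  }
  abort("homopolymer_undercall must be NULL, hp_undercall(), or a named list",
        class = "plasmidcons_parameter_error")
}

#' Generate a random plasmid reference with embedded homopolymer runs
#'
#' Produces uniform-random DNA of the requested length and plants the
#' requested homopolymer runs verbatim. The bases flanking each run are
#' forced to differ from the run base so that the embedded run has exactly
#' the requested length. Deterministic given the seed.
#'
#' @param length Template length in bases (at least 100).
#' @param seed Integer seed.
#' @param homopolymer_runs `NULL`, or a list of `c(position, base, run
#'   length)` triples (position is the 1-based start of the run).
#' @param name Record name.
#' @return A one-row template tibble (`name`, `sequence`, `length`).
#' @export
make_reference <- function(length, seed, homopolymer_runs = NULL,
                           name = "synthetic_plasmid") {
  if (length < 100) {
    abort("reference length must be at least 100",
          class = "plasmidcons_parameter_error")
  }
  runs <- homopolymer_runs
  if (!is.null(runs)) {
    spans <- purrr::map(runs, function(r) {
      pos <- as.integer(r[[1]]); len <- as.integer(r[[3]])
      if (pos < 2 || pos + len > length) {
        abort("homopolymer run does not fit inside the reference",
              class = "plasmidcons_parameter_error")
      }
      c(pos - 1, pos + len) # include forced flanks
    })
    spans <- spans[order(vapply(spans, `[[`, numeric(1), 1))]
    if (length(spans) > 1) {
      for (i in 2:length(spans)) {
        if (spans[[i]][1] <= spans[[i - 1]][2]) {
          abort("homopolymer runs overlap",
                class = "plasmidcons_parameter_error")
        }
      }
    }
  }
  chars <- withr::with_seed(seed, sample(BASES, length, replace = TRUE))
  if (!is.null(runs)) {
    for (r in runs) {
      pos <- as.integer(r[[1]]); base <- toupper(r[[2]])
      len <- as.integer(r[[3]])
      stopifnot(base %in% BASES)
      chars[pos:(pos + len - 1)] <- base
      other <- setdiff(BASES, base)
      if (chars[pos - 1] == base) chars[pos - 1] <- other[1]
      if (pos + len <= length && chars[pos + len] == base) {
        chars[pos + len] <- other[1]
      }
    }
  }
  tibble(name = name, sequence = paste(chars, collapse = ""),
         length = length)
}

#' Describe a single template mutation
#'
#' @param kind One of "SNV", "insertion", "deletion".
#' @param position 1-based base index on the template. For insertions the
#'   new base is placed after this position.
#' @param ref_base Template base at `position` (SNV and deletion).
#' @param alt_base New base (SNV and insertion).
#' @export
mutation <- function(kind, position, ref_base = "", alt_base = "") {
  kind <- match.arg(kind, c("SNV", "insertion", "deletion"))
  if (kind == "SNV" && (ref_base == alt_base || alt_base == "")) {
    abort("SNV requires ref_base != alt_base",
          class = "plasmidcons_parameter_error")
  }
  tibble(kind = kind, position = as.integer(position),
         ref_base = toupper(ref_base), alt_base = toupper(alt_base))
}

#' Parse compact mutation notation
#'
#' Understands the conventional forms `T2010A` (SNV), `2205insA`
#' (insertion after position 2205) and `1886delT` (deletion at 1886).
#'
#' @param x Character vector of mutation strings.
#' @return A mutation tibble (one row per string).
#' @export
parse_mutation <- function(x) {
  purrr::map_dfr(x, function(s) {
    if (grepl("^[0-9]+ins[ACGT]$", s)) {
      m <- regmatches(s, regexec("^([0-9]+)ins([ACGT])$", s))[[1]]
      mutation("insertion", as.integer(m[2]), alt_base = m[3])
    } else if (grepl("^[0-9]+del[ACGT]$", s)) {
      m <- regmatches(s, regexec("^([0-9]+)del([ACGT])$", s))[[1]]
      mutation("deletion", as.integer(m[2]), ref_base = m[3])
    } else if (grepl("^[ACGT][0-9]+[ACGT]$", s)) {
      m <- regmatches(s, regexec("^([ACGT])([0-9]+)([ACGT])$", s))[[1]]
      mutation("SNV", as.integer(m[3]), ref_base = m[2], alt_base = m[4])
    } else {
      abort(sprintf("cannot parse mutation '%s'", s),
            class = "plasmidcons_parameter_error")
    }
  })
}

mutation_label <- function(mut) {
  dplyr::case_when(
    mut$kind == "SNV" ~ paste0(mut$ref_base, mut$position, mut$alt_base),
    mut$kind == "insertion" ~ paste0(mut$position, "ins", mut$alt_base),
    mut$kind == "deletion" ~ paste0(mut$position, "del", mut$ref_base)
  )
}

#' Apply mutations to a template
#'
#' Edits are applied right-to-left so that earlier positions stay valid.
#' For SNVs and deletions the stated `ref_base` must match the template at
#' that position; a mismatch is an error naming the position.
#'
#' @param template A template (character or one-row tibble).
#' @param mutations A mutation tibble (see [mutation()]).
#' @return A new one-row template tibble.
#' @export
apply_mutations <- function(template, mutations) {
  tpl <- as_template(template)
  chars <- strsplit(tpl$sequence, "")[[1]]
  ord <- order(mutations$position, decreasing = TRUE)
  for (i in ord) {
    kind <- mutations$kind[i]
    pos <- mutations$position[i]
    if (pos < 1 || pos > length(chars)) {
      abort(sprintf("mutation position %d outside template", pos),
            class = "plasmidcons_validation_error")
    }
    if (kind %in% c("SNV", "deletion") &&
        chars[pos] != mutations$ref_base[i]) {
      abort(sprintf(
        "ref_base mismatch at position %d: template has %s, mutation says %s",
        pos, chars[pos], mutations$ref_base[i]),
        class = "plasmidcons_validation_error")
    }
    chars <- switch(kind,
      SNV = { chars[pos] <- mutations$alt_base[i]; chars },
      deletion = chars[-pos],
      insertion = append(chars, mutations$alt_base[i], after = pos)
    )
  }
  tibble(name = paste0(tpl$name, "_variant"),
         sequence = paste(chars, collapse = ""),
         length = length(chars))
}

# template runs of min_len or longer: tibble(start, base, length)
template_runs <- function(sequence, min_len) {
  r <- rle(strsplit(sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  tibble(start = (ends - r$lengths + 1)[keep], base = r$values[keep],
         length = r$lengths[keep])
}

# corrupt one template-frame char vector per the model; returns chars+flags
corrupt_read <- function(chars, flags, model, runs, sampler, is_reverse) {
  # strand-specific systematic miscalls (template frame)
  sb <- model$strand_bias_sites
  if (!is.null(sb)) {
    strand <- if (is_reverse) "reverse" else "forward"
    sb <- sb[sb$strand == strand, , drop = FALSE]
    if (nrow(sb) > 0) {
      hit <- runif(nrow(sb)) < sb$prob
      if (any(hit)) {
        chars[sb$position[hit]] <- toupper(sb$wrong_base[hit])
        flags[sb$position[hit]] <- TRUE
      }
    }
  }
  # homopolymer run-length undercall: reassemble by segments
  if (!is.null(sampler) && nrow(runs) > 0) {
    reported <- vapply(seq_len(nrow(runs)), function(k) {
      sampler(runs$length[k], 1L)
    }, integer(1))
    reported <- pmax(0L, pmin(reported, runs$length))
    drop_idx <- unlist(purrr::map(which(reported < runs$length), function(k) {
      n_drop <- runs$length[k] - reported[k]
      seq.int(runs$start[k], length.out = n_drop)
    }))
    if (length(drop_idx) > 0) {
      chars <- chars[-drop_idx]
      flags <- flags[-drop_idx]
    }
  }
  n <- length(chars)
  # dispersed substitutions
  if (model$substitution_rate > 0) {
    at <- which(runif(n) < model$substitution_rate)
    if (length(at) > 0) {
      chars[at] <- vapply(chars[at], function(b) {
        sample(setdiff(BASES, b), 1)
      }, character(1))
      flags[at] <- TRUE
    }
  }
  # dispersed deletions
  if (model$deletion_rate > 0) {
    at <- which(runif(n) < model$deletion_rate)
    if (length(at) > 0) {
      chars <- chars[-at]
      flags <- flags[-at]
      n <- length(chars)
    }
  }
  # dispersed insertions (after position j, j = 0..n)
  if (model$insertion_rate > 0) {
    at <- which(runif(n + 1) < model$insertion_rate) - 1L
    for (j in rev(at)) {
      chars <- append(chars, sample(BASES, 1), after = j)
      flags <- append(flags, TRUE, after = j)
    }
  }
  # ragged ends
  if (model$end_raggedness > 0) {
    lead <- sample.int(model$end_raggedness + 1L, 1L) - 1L
    trail <- sample.int(model$end_raggedness + 1L, 1L) - 1L
    n <- length(chars)
    if (lead + trail < n) {
      keep <- seq.int(lead + 1L, n - trail)
      chars <- chars[keep]
      flags <- flags[keep]
    }
  }
  list(chars = chars, flags = flags)
}

#' Simulate nanopore-style reads from a template
#'
#' Every read is a full-template-length copy of the template (or of its
#' reverse complement for reverse reads) corrupted according to the error
#' model: strand-specific miscalls first (template frame), then homopolymer
#' run-length resampling for runs of at least `min_homopolymer` bases, then
#' dispersed substitutions/insertions/deletions, then ragged-end truncation.
#' Orientation is recorded as an `_F`/`_R` suffix on the read id for test
#' introspection only; the pipeline itself never reads it.
#'
#' @param template A template (character or one-row tibble).
#' @param n_reads Number of reads (at least 1).
#' @param model An [error_model()].
#' @param fraction_reverse Proportion of reverse-orientation reads; realized
#'   counts are exact (largest remainder).
#' @param seed Integer seed; the same seed reproduces the reads exactly.
#' @param read_id_prefix Prefix for read identifiers.
#' @param n_low_quality Number of additional reads whose bases are all at
#'   quality 10 (deliberate failures for the quality filter).
#' @param n_abnormal_length Number of additional junk reads with grossly
#'   abnormal length (half and double template copies, for the length
#'   filter).
#' @return A reads tibble (`read_id`, `sequence`, `qualities`).
#' @export
simulate_reads <- function(template, n_reads, model = error_model(),
                           fraction_reverse = 0.5, seed = 1,
                           read_id_prefix = "read",
                           n_low_quality = 0, n_abnormal_length = 0) {
  tpl <- as_template(template)
  if (n_reads < 1) {
    abort("n_reads must be at least 1", class = "plasmidcons_parameter_error")
  }
  if (fraction_reverse < 0 || fraction_reverse > 1) {
    abort("fraction_reverse must be in [0, 1]",
          class = "plasmidcons_parameter_error")
  }
  tpl_chars <- strsplit(tpl$sequence, "")[[1]]
  runs <- template_runs(tpl$sequence, model$min_homopolymer)
  sampler <- undercall_sampler(model)

  n_rev <- round(n_reads * fraction_reverse)
  is_rev <- c(rep(FALSE, n_reads - n_rev), rep(TRUE, n_rev))

  withr::with_seed(seed, {
    is_rev <- sample(is_rev)
    recs <- purrr::map(seq_len(n_reads), function(i) {
      cr <- corrupt_read(tpl_chars, rep(FALSE, length(tpl_chars)), model,
                         runs, sampler, is_rev[i])
      chars <- cr$chars
      flags <- cr$flags
      if (is_rev[i]) {
        chars <- rev(chartr("ACGTN", "TGCAN", chars))
        flags <- rev(flags)
      }
      quals <- ifelse(flags, model$error_quality, model$base_quality)
      list(
        read_id = sprintf("%s_%05d_%s", read_id_prefix, i,
                          if (is_rev[i]) "R" else "F"),
        sequence = paste(chars, collapse = ""),
        qualities = as.integer(quals)
      )
    })
    extra <- list()
    if (n_low_quality > 0) {
      for (k in seq_len(n_low_quality)) {
        extra[[length(extra) + 1]] <- list(
          read_id = sprintf("%s_lowq_%03d_F", read_id_prefix, k),
          sequence = tpl$sequence,
          qualities = rep(10L, tpl$length)
        )
      }
    }
    if (n_abnormal_length > 0) {
      for (k in seq_len(n_abnormal_length)) {
        seq <- if (k %% 2 == 1) {
          substr(tpl$sequence, 1, floor(tpl$length / 3))
        } else {
          paste0(tpl$sequence, tpl$sequence)
        }
        extra[[length(extra) + 1]] <- list(
          read_id = sprintf("%s_junk_%03d_F", read_id_prefix, k),
          sequence = seq,
          qualities = rep(model$base_quality, nchar(seq))
        )
      }
    }
    recs <- c(recs, extra)
  })

  tibble(
    read_id = vapply(recs, `[[`, character(1), "read_id"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    qualities = purrr::map(recs, "qualities")
  )
}

#' Simulate a mixture of templates at exact proportions
#'
#' Read counts per template are exact (largest-remainder rounding), the
#' combined set is shuffled deterministically, and per-read provenance is
#' kept in the `"provenance"` attribute for tests; the pipeline never uses
#' it.
#'
#' @param templates A template tibble (one row per template).
#' @param proportions Numeric vector summing to 1, one entry per template.
#' @param n_reads Total number of reads.
#' @param model An [error_model()].
#' @param fraction_reverse Proportion of reverse reads per template.
#' @param seed Integer seed.
#' @return A reads tibble with a `"provenance"` attribute.
#' @export
simulate_mixture <- function(templates, proportions, n_reads,
                             model = error_model(), fraction_reverse = 0.5,
                             seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("proportions must sum to 1", class = "plasmidcons_parameter_error")
  }
  if (length(proportions) != nrow(templates)) {
    abort("one proportion per template required",
          class = "plasmidcons_parameter_error")
  }
  # largest-remainder apportionment
  raw <- proportions * n_reads
  counts <- floor(raw)
  rem <- n_reads - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  counts <- as.integer(counts)

  pieces <- purrr::map(which(counts > 0), function(k) {
    r <- simulate_reads(templates[k, ], counts[k], model = model,
                        fraction_reverse = fraction_reverse,
                        seed = derive_seed(seed, k),
                        read_id_prefix = paste0(templates$name[k], "_read"))
    r$template <- templates$name[k]
    r
  })
  all <- dplyr::bind_rows(pieces)
  ord <- withr::with_seed(derive_seed(seed, 0L), sample.int(nrow(all)))
  all <- all[ord, ]
  prov <- tibble(read_id = all$read_id, template = all$template)
  all$template <- NULL
  attr(all, "provenance") <- prov
  all
}
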