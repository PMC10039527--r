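# Shared fixtures and independent oracles, all built in code.

# a draft with no homopolymer of length >= 2, so single edits have a unique
# alignment placement
pattern_draft <- function(length) {
  paste(rep_len(c("A", "C", "G", "T"), length), collapse = "")
}

# build exact-copy reads of a template as a reads tibble
copy_reads <- function(template, n, q = 20L, prefix = "r") {
  seq <- if (is.character(template)) template else template$sequence
  tibble::tibble(
    read_id = sprintf("%s%03d", prefix, seq_len(n)),
    sequence = seq,
    qualities = replicate(n, rep(q, nchar(seq)), simplify = FALSE)
  )
}

# apply an edit description to a sequence string; edits are applied
# right-to-left and must not collide. spec: list(sub = list(c(pos, "B")),
# del = c(pos...), ins = list(c(junction, "B")))
edit_sequence <- function(seq, spec) {
  chars <- strsplit(seq, "")[[1]]
  ops <- list()
  for (s in spec$sub %||% list()) {
    ops[[length(ops) + 1]] <- list(kind = "sub", pos = as.integer(s[[1]]),
                                   base = s[[2]])
  }
  for (p in spec$del %||% integer()) {
    ops[[length(ops) + 1]] <- list(kind = "del", pos = as.integer(p))
  }
  for (s in spec$ins %||% list()) {
    ops[[length(ops) + 1]] <- list(kind = "ins", pos = as.integer(s[[1]]),
                                   base = s[[2]])
  }
  ord <- order(vapply(ops, `[[`, integer(1), "pos"), decreasing = TRUE)
  for (o in ops[ord]) {
    if (o$kind == "sub") chars[o$pos] <- o$base
    else if (o$kind == "del") chars <- chars[-o$pos]
    else chars <- append(chars, o$base, after = o$pos)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent consensus oracle: given the draft and the per-read edit
# descriptions (the construction truth, not any alignment), tally the
# pileup counts directly and apply the calling criteria. Returns the
# expected consensus sequence. Assumes every read spans the whole draft
# and edits are isolated (unique alignment placement).
oracle_consensus <- function(draft, read_specs, ratio = 5, covfrac = 0.10) {
  L <- nchar(draft)
  dchars <- strsplit(draft, "")[[1]]
  n <- length(read_specs)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "gap"), NULL))
  ins_counts <- list() # key "junction:offset:base"
  ins_reads <- list()  # key junction -> read count with >=1 ins there
  for (r in seq_len(n)) {
    spec <- read_specs[[r]]
    subs <- spec$sub %||% list()
    dels <- spec$del %||% integer()
    inss <- spec$ins %||% list()
    sub_pos <- vapply(subs, function(s) as.integer(s[[1]]), integer(1))
    for (p in seq_len(L)) {
      if (p %in% dels) {
        counts["gap", p] <- counts["gap", p] + 1L
      } else if (p %in% sub_pos) {
        b <- subs[[match(p, sub_pos)]][[2]]
        counts[b, p] <- counts[b, p] + 1L
      } else {
        counts[dchars[p], p] <- counts[dchars[p], p] + 1L
      }
    }
    by_j <- split(inss, vapply(inss, function(s) as.integer(s[[1]]),
                               integer(1)))
    for (jc in names(by_j)) {
      bases <- vapply(by_j[[jc]], `[[`, character(1), 2)
      for (o in seq_along(bases)) {
        key <- paste(jc, o - 1, bases[o], sep = ":")
        ins_counts[[key]] <- (ins_counts[[key]] %||% 0L) + 1L
      }
      ins_reads[[jc]] <- (ins_reads[[jc]] %||% 0L) + 1L
    }
  }
  depth <- colSums(counts)
  max_cov <- max(depth)
  out <- character()
  for (j in 0:L) {
    # between column at junction j
    keys <- grep(paste0("^", j, ":"), names(ins_counts), value = TRUE)
    if (length(keys) > 0) {
      offs <- sort(unique(as.integer(vapply(strsplit(keys, ":"), `[[`,
                                            character(1), 2))))
      for (o in offs) {
        ok <- keys[vapply(strsplit(keys, ":"), function(x)
          as.integer(x[2]) == o, logical(1))]
        cand <- vapply(ok, function(k) ins_counts[[k]], integer(1))
        names(cand) <- vapply(strsplit(ok, ":"), `[[`, character(1), 3)
        total <- sum(cand)
        pass <- n - total
        best <- max(cand)
        best_base <- names(cand)[which.max(cand)]
        if (pass >= best) {
          if (pass < ratio * best) out <- c(out, "N")
          break
        }
        if (best < covfrac * max_cov) break
        second <- max(c(cand[names(cand) != best_base |
                               duplicated(names(cand))], pass, 0))
        second <- max(c(sort(cand, decreasing = TRUE)[-1], pass, 0),
                      na.rm = TRUE)
        if (best < ratio * second) out <- c(out, "N")
        else out <- c(out, best_base)
      }
    }
    if (j == L) break
    # base column j+1
    p <- j + 1
    bc <- counts[1:4, p]
    top <- max(bc)
    top_base <- names(bc)[which.max(bc)]
    second <- max(sort(bc, decreasing = TRUE)[-1], 0)
    if (top < covfrac * max_cov || top == 0) {
      # dropped
    } else if (sum(bc == top) > 1 || top < ratio * second) {
      out <- c(out, "N")
    } else {
      out <- c(out, top_base)
    }
  }
  paste(out, collapse = "")
}

# run the package's own consensus path on constructed reads
package_consensus <- function(draft, read_specs, ratio = 5,
                              covfrac = 0.10) {
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", seq_along(read_specs)),
    sequence = vapply(read_specs, function(s) edit_sequence(draft, s),
                      character(1)),
    qualities = lapply(read_specs, function(s) rep(20L, 1))
  )
  reads$qualities <- lapply(reads$sequence, function(s) rep(20L, nchar(s)))
  alns <- align_reads(reads, draft)
  pu <- build_pileup(alns, draft)
  consensus_from_pileup(pu, ratio_threshold = ratio,
                        coverage_fraction = covfrac)
}
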