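# Independent brute-force oracles and small fixture builders.

# Exhaustive-enumeration optimum for global alignment with affine gaps.
# Walks every alignment path (match/mismatch, gap in either sequence),
# charging gap_open once per maximal gap run plus gap_extend per column —
# independent of any dynamic-programming shortcut.
bf_align_score <- function(a, b, scoring = scoring_scheme()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > na && j > nb) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= na && j <= nb) {
      s <- if (ca[i] == cb[j]) scoring$match else scoring$mismatch
      rec(i + 1L, j + 1L, score + s, "m")
    }
    if (i <= na) {  # consume a; gap opened/extended in b
      pen <- scoring$gap_extend + if (state == "gb") 0 else scoring$gap_open
      rec(i + 1L, j, score + pen, "gb")
    }
    if (j <= nb) {  # consume b; gap in a
      pen <- scoring$gap_extend + if (state == "ga") 0 else scoring$gap_open
      rec(i, j + 1L, score + pen, "ga")
    }
  }
  rec(1L, 1L, 0, "none")
  best
}

# Brute-force microsatellite scanner: tests every (start, unit_len) pair
# by direct base comparison, keeps maximal arrays with a primitive motif,
# then applies the same-unit-length de-duplication rule (later array
# trimmed to start past the previous locus, re-anchored to a unit
# boundary). Primitivity via the classic doubling trick: a motif is a
# nontrivial power iff it occurs inside (motif + motif) minus its ends.
bf_find_repeats <- function(seq, min_unit = 2L, max_unit = 100L,
                            min_repeats = 3L, mono_min_repeats = 12L) {
  s <- toupper(seq)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  primitive <- function(motif) {
    k <- nchar(motif)
    if (k == 1L) return(TRUE)
    doubled <- substr(paste0(motif, motif), 2L, 2L * k - 1L)
    !grepl(motif, doubled, fixed = TRUE)
  }
  out <- list()
  for (k in unique(c(1L, seq_len(min(max_unit, n)))) ) {
    if (k > 1L && (k < min_unit || k > max_unit)) next
    minrep <- if (k == 1L) mono_min_repeats else min_repeats
    prev_end <- -1L
    i <- 1L
    while (i + k - 1L <= n) {
      # maximal array at i: i must not be extendable left
      left_ok <- i == 1L || !ok[i - 1L] ||
        (i - 1L + k <= n && ch[i - 1L] != ch[i - 1L + k]) ||
        (i - 1L + k > n)
      if (!left_ok) { i <- i + 1L; next }
      # extend right while period k holds on certified bases
      e <- i + k - 1L
      while (e + 1L <= n && ok[e + 1L] && ok[e + 1L - k] &&
             ch[e + 1L] == ch[e + 1L - k]) {
        e <- e + 1L
      }
      arr_len <- e - i + 1L
      if (arr_len >= k * minrep && all(ok[i:e])) {
        start0 <- i - 1L
        total <- arr_len
        if (start0 < prev_end) {
          shift <- prev_end - start0
          start0 <- prev_end
          total <- total - shift
        }
        rc <- total %/% k
        motif <- substr(s, start0 + 1L, start0 + k)
        if (rc >= minrep && primitive(motif)) {
          prev_end <- start0 + k * rc
          out[[length(out) + 1L]] <- data.frame(
            start = start0, end = start0 + k * rc, motif = motif,
            unit_len = k, repeat_count = rc, stringsAsFactors = FALSE)
        }
      }
      i <- max(i + 1L, e - k + 2L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      repeat_count = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# pooled two-sample t computed straight from the textbook formula
bf_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# tiny region builders
mk_gene <- function(name, strand, ..., species = "sp") {
  ex <- do.call(rbind, lapply(list(...), function(e) {
    data.frame(start = e[1], end = e[2])
  }))
  gene_model(name, strand, ex, species = species)
}

mk_region <- function(seq, genes = list(), species = "sp", id = "toy",
                      ...) {
  annotated_region(species, id, seq, genes = genes, ...)
}

# substitute given 1-based positions of a sequence to a different base
sub_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (i in positions) {
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  }
  paste(ch, collapse = "")
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
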