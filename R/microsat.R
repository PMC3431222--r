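# Perfect tandem-repeat (microsatellite) detection and census.
#
# A locus is a maximal perfect tandem array: a motif of unit length k
# repeated repeat_count full times, not extendable by one unit in either
# direction, with a primitive motif (unit "ATAT" is reported as "AT").
# Motifs are reported as read on the forward strand starting at the locus
# start (no rotation or reverse-complement merging). N (or any ambiguity
# code) breaks arrays: an unsequenced base cannot certify perfection.
# When two maximal arrays of the same unit length overlap at a phase-shift
# junction (by at most k-1 bases), the later one is trimmed to start at the
# first position past the earlier locus, re-anchored to a full-unit
# boundary, so reported loci of one unit length never overlap.

# is the motif itself periodic with a shorter period that divides it?
is_periodic_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(FALSE)
  for (d in seq_len(k %/% 2)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k %/% d)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Find perfect microsatellite loci
#'
#' Scans for maximal perfect tandem arrays with unit length between
#' `min_unit` and `max_unit` and at least `min_repeats` full repeats.
#' Mononucleotide arrays are additionally reported when their repeat count
#' reaches `mono_min_repeats`. Partial trailing units are not counted, so
#' `end - start = unit_len * repeat_count` for every locus.
#'
#' @param seq nucleotide string.
#' @param min_unit,max_unit unit-length range for multi-base motifs
#'   (defaults 2 and 100).
#' @param min_repeats minimum full repeats for multi-base motifs
#'   (default 3).
#' @param mono_min_repeats minimum repeats for mononucleotide arrays
#'   (default 12).
#' @return a data.frame with one row per locus: `start`, `end` (0-based
#'   half-open), `motif`, `unit_len`, `repeat_count`, `is_long_mer`
#'   (see [long_mer_filter()]), sorted by `start` then `unit_len`.
#' @export
find_perfect_repeats <- function(seq, min_unit = 2L, max_unit = 100L,
                                 min_repeats = 3L, mono_min_repeats = 12L) {
  if (min_unit > max_unit) {
    stop("min_unit must not exceed max_unit", call. = FALSE)
  }
  s <- toupper(seq)
  n <- nchar(s)
  ch <- seq_chars(s)
  ok <- ch %in% c("A", "C", "G", "T")
  units <- unique(c(1L, seq2int(min_unit, min(max_unit, n %/% 2L))))
  loci <- list()
  for (k in units) {
    minrep <- if (k == 1L) mono_min_repeats else min_repeats
    if (n < k * minrep || n <= k) next
    idx <- seq_len(n - k)
    eq <- ch[idx] == ch[idx + k] & ok[idx] & ok[idx + k]
    r <- rle(eq)
    starts <- cumsum(c(1L, r$lengths))
    prev_end0 <- -1L  # end of previous kept locus at this unit length
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      i <- starts[j]               # 1-based start of the perfect array
      total <- r$lengths[j] + k    # array length in bases
      start0 <- i - 1L
      # trim a phase-shift overlap with the previous same-k locus
      if (start0 < prev_end0) {
        shift <- prev_end0 - start0
        start0 <- prev_end0
        total <- total - shift
      }
      rc <- total %/% k
      if (rc < minrep) next
      motif <- substr(s, start0 + 1L, start0 + k)
      if (k > 1L && is_periodic_motif(motif)) next
      prev_end0 <- start0 + k * rc
      loci[[length(loci) + 1L]] <- data.frame(
        start = start0, end = start0 + k * rc, motif = motif,
        unit_len = k, repeat_count = rc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(loci) == 0L) {
    data.frame(start = integer(), end = integer(), motif = character(),
               unit_len = integer(), repeat_count = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, loci)
  }
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out$is_long_mer <- is_long_mer(out)
  out
}

seq2int <- function(from, to) {
  if (to < from) integer(0) else seq.int(from, to)
}

# class-specific long-mer thresholds: mono >= 30, di >= 15, tri >= 10
# repeats; classes without a stated threshold never qualify
is_long_mer <- function(loci) {
  thr <- c(30L, 15L, 10L)
  k <- loci$unit_len
  ifelse(k >= 1L & k <= 3L, loci$repeat_count >= thr[pmin(k, 3L)], FALSE)
}

#' Census of microsatellite loci by unit-length class
#'
#' Counts and proportions of mono-, di-, tri- and tetranucleotide loci.
#' Loci with unit length above 4 are counted under `other` and excluded
#' from the four-class proportions.
#'
#' @param loci a [find_perfect_repeats()] result.
#' @return a list of class `census_report` with `counts` (named: mono, di,
#'   tri, tetra, other), `proportions` (over the four classes) and
#'   `n_total`.
#' @export
classify_and_count <- function(loci) {
  classes <- c("mono", "di", "tri", "tetra")
  k <- loci$unit_len
  counts <- c(mono = sum(k == 1L), di = sum(k == 2L), tri = sum(k == 3L),
              tetra = sum(k == 4L), other = sum(k > 4L))
  four <- counts[classes]
  props <- if (sum(four) > 0L) four / sum(four) else
    stats::setNames(rep(0, 4L), classes)
  structure(list(counts = counts, proportions = props,
                 n_total = nrow(loci)),
            class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("<census_report> %d locus/loci: mono %d, di %d, tri %d, tetra %d, other %d\n",
              x$n_total, x$counts[["mono"]], x$counts[["di"]],
              x$counts[["tri"]], x$counts[["tetra"]], x$counts[["other"]]))
  invisible(x)
}

#' Filter loci to long-mer microsatellites
#'
#' Keeps mononucleotide loci with >= 30 repeats, dinucleotide loci with
#' >= 15 repeats and trinucleotide loci with >= 10 repeats; other unit
#' lengths are never long-mers.
#'
#' @param loci a [find_perfect_repeats()] result.
#' @return the qualifying subset of `loci`.
#' @export
long_mer_filter <- function(loci) {
  out <- loci[is_long_mer(loci), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare microsatellite class densities between two censuses
#'
#' Unpaired pooled Student's t on the two 4-vectors of class proportions
#' (mono, di, tri, tetra).
#'
#' @param census_a,census_b [classify_and_count()] results.
#' @param variant passed to [student_t_two_sample()].
#' @return a `two_sample_t` object.
#' @export
density_compare <- function(census_a, census_b,
                            variant = c("pooled", "welch")) {
  student_t_two_sample(census_a$proportions, census_b$proportions,
                       match.arg(variant))
}
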