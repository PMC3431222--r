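# LTR retrotransposon molecular dating. The two long terminal repeats of
# one element are identical at insertion time; divergence accumulated
# between them since then dates the insertion as T = N / (2 * L * K).

#' Construct an LTR pair
#'
#' @param element_name element identifier.
#' @param seq5,seq3 nucleotide sequences of the 5' and 3' LTR.
#' @param ltr5,ltr3 optional genomic intervals `c(start, end)` (0-based
#'   half-open, 5' before 3').
#' @return a list of class `ltr_pair`.
#' @export
ltr_pair <- function(element_name, seq5, seq3, ltr5 = NULL, ltr3 = NULL) {
  if (!nzchar(seq5) || !nzchar(seq3)) {
    stop(sprintf("LTR element '%s': zero-length LTR sequence", element_name),
         call. = FALSE)
  }
  if (!is.null(ltr5) && !is.null(ltr3) && ltr5[2] > ltr3[1]) {
    stop(sprintf("LTR element '%s': 5' LTR must not overlap or follow the 3' LTR",
                 element_name), call. = FALSE)
  }
  structure(list(element_name = element_name, seq5 = toupper(seq5),
                 seq3 = toupper(seq3), ltr5 = ltr5, ltr3 = ltr3),
            class = "ltr_pair")
}

#' Estimate the insertion age of an LTR element
#'
#' The two LTRs are globally aligned and the age estimated as
#' `T = N / (2 * L * K)` where `N` is the number of base substitutions
#' between them (optionally plus indel events, one event counting as one
#' mutation), `L` is the arithmetic mean of the two LTR lengths and `K`
#' the substitution rate per site per year (default 23e-9).
#'
#' @param pair an [ltr_pair()].
#' @param K substitution rate per site per year (> 0).
#' @param include_indels count internal indel events in `N` (default
#'   `FALSE`: substitutions only).
#' @param scoring alignment [scoring_scheme()].
#' @return a list of class `ltr_age` with `element_name`, `L`, `N`,
#'   `substitutions`, `indel_events`, `indel_columns`, `K`, `age_years`.
#' @export
estimate_insertion_age <- function(pair, K = 23e-9, include_indels = FALSE,
                                   scoring = scoring_scheme()) {
  if (K <= 0) stop("substitution rate K must be positive", call. = FALSE)
  aln <- global_align(pair$seq5, pair$seq3, scoring)
  mut <- count_mutations(aln)
  L <- (nchar(pair$seq5) + nchar(pair$seq3)) / 2
  N <- mut$substitutions + if (include_indels) mut$indel_events else 0L
  structure(list(element_name = pair$element_name, L = L, N = N,
                 substitutions = mut$substitutions,
                 indel_events = mut$indel_events,
                 indel_columns = mut$indel_columns,
                 K = K, age_years = N / (2 * L * K)),
            class = "ltr_age")
}

#' @export
print.ltr_age <- function(x, ...) {
  cat(sprintf("<ltr_age> %s: N = %d over mean LTR length %.1f bp at K = %g -> %.0f years\n",
              x$element_name, x$N, x$L, x$K, x$age_years))
  invisible(x)
}

#' Date every LTR element of a region
#'
#' LTR sequences are taken from the region sequence at the annotated
#' intervals; one row per element, sorted by coordinate.
#'
#' @param region an [annotated_region()] (possibly with zero LTR pairs).
#' @param K substitution rate per site per year.
#' @param include_indels see [estimate_insertion_age()].
#' @param scoring alignment [scoring_scheme()].
#' @return a data.frame with columns `element`, `start`, `end`, `len5`,
#'   `len3`, `substitutions`, `indel_events`, `indel_columns`, `N`,
#'   `age_years`, `K`.
#' @export
batch_date <- function(region, K = 23e-9, include_indels = FALSE,
                       scoring = scoring_scheme()) {
  len <- region$record$length
  rows <- lapply(region$ltr_pairs, function(p) {
    if (p$ltr5[1] < 0L || p$ltr3[2] > len) {
      stop(sprintf("LTR element '%s': interval outside sequence bounds",
                   p$element_name), call. = FALSE)
    }
    seq5 <- substr(region$record$seq, p$ltr5[1] + 1L, p$ltr5[2])
    seq3 <- substr(region$record$seq, p$ltr3[1] + 1L, p$ltr3[2])
    est <- estimate_insertion_age(
      ltr_pair(p$element_name, seq5, seq3, p$ltr5, p$ltr3),
      K = K, include_indels = include_indels, scoring = scoring)
    data.frame(element = p$element_name, start = p$ltr5[1], end = p$ltr3[2],
               len5 = nchar(seq5), len3 = nchar(seq3),
               substitutions = est$substitutions,
               indel_events = est$indel_events,
               indel_columns = est$indel_columns,
               N = est$N, age_years = est$age_years, K = K,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0L) {
    data.frame(element = character(), start = integer(), end = integer(),
               len5 = integer(), len3 = integer(),
               substitutions = integer(), indel_events = integer(),
               indel_columns = integer(), N = integer(),
               age_years = numeric(), K = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect a terminal repeat pair in an element sequence
#'
#' A simplified detector for the two LTRs of a candidate retrotransposon:
#' the best-scoring pair of similar substrings, one within the first
#' `window` bp and one within the last `window` bp, found by local
#' alignment of the two terminal windows. Returns `NULL` when the best
#' pair is shorter than `min_len` or below `min_identity` percent
#' identity (absence of a repeat is a valid result).
#'
#' @param element_seq nucleotide string, longer than `2 * min_len`.
#' @param min_len minimum LTR length (default 100).
#' @param window terminal window size in bp (default 1500).
#' @param min_identity minimum percent identity (default 85).
#' @param scoring alignment [scoring_scheme()].
#' @return `NULL`, or a list with `ltr5` and `ltr3` intervals
#'   (`c(start, end)`, 0-based half-open) and `identity`.
#' @export
detect_terminal_repeats <- function(element_seq, min_len = 100L,
                                    window = 1500L, min_identity = 85,
                                    scoring = scoring_scheme()) {
  n <- nchar(element_seq)
  if (n <= 2L * min_len) {
    stop("element shorter than twice the minimum LTR length", call. = FALSE)
  }
  w <- min(window, n %/% 2L)
  head_seq <- substr(element_seq, 1L, w)
  tail_off <- n - w  # 0-based offset of the tail window
  tail_seq <- substr(element_seq, tail_off + 1L, n)
  aln <- Biostrings::pairwiseAlignment(
    pattern = head_seq, subject = tail_seq, type = "local",
    substitutionMatrix = iupac_submat(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  acc <- align_accounting(as.character(p), as.character(s))
  alen <- acc$trim_end - acc$trim_start + 1L
  if (alen < min_len) return(NULL)
  identity <- 100 * acc$matches / max(1L, alen - acc$ambig_in_trim)
  if (identity < min_identity) return(NULL)
  list(ltr5 = c(IRanges::start(p) - 1L, IRanges::end(p)),
       ltr3 = c(tail_off + IRanges::start(s) - 1L,
                tail_off + IRanges::end(s)),
       identity = identity)
}
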