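# Global pairwise alignment with affine gaps, plus the identity/mutation
# accounting used by the structure comparison and by LTR dating. The
# Needleman-Wunsch optimisation is delegated to Biostrings; all column
# accounting (match/mismatch/gap/ambiguity classification, terminal-gap
# trimming) is done here on the aligned strings.

#' Alignment scoring scheme
#'
#' EMBOSS-needle-like defaults: match +5, mismatch -4, gap open -10, gap
#' extend -0.5. A gap run of length L costs `gap_open + L * gap_extend`.
#' Columns involving N (or any other ambiguity code) score 0 and are
#' excluded from match/mismatch/identity accounting.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores (penalties
#'   negative).
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = -10,
                           gap_extend = -0.5) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

iupac_submat <- function(scoring) {
  n <- length(IUPAC_DNA)
  m <- matrix(scoring$mismatch, n, n, dimnames = list(IUPAC_DNA, IUPAC_DNA))
  diag(m) <- scoring$match
  m[AMBIG_DNA, ] <- 0
  m[, AMBIG_DNA] <- 0
  m
}

# classify alignment columns and trim terminal gap runs
align_accounting <- function(aligned_a, aligned_b) {
  ca <- seq_chars(aligned_a); cb <- seq_chars(aligned_b)
  len <- length(ca)
  gap <- ca == "-" | cb == "-"
  ncol_flag <- !gap & (ca %in% AMBIG_DNA | cb %in% AMBIG_DNA)
  match <- !gap & !ncol_flag & ca == cb
  mismatch <- !gap & !ncol_flag & !match
  # terminal gap runs
  nongap <- which(!gap)
  if (length(nongap) == 0L) {
    trim <- c(1L, 0L)
  } else {
    trim <- c(min(nongap), max(nongap))
  }
  inner <- if (trim[2] >= trim[1]) trim[1]:trim[2] else integer(0)
  gap_runs_in <- function(chars) {
    if (length(inner) == 0L) return(c(events = 0L, cols = 0L))
    r <- rle(chars[inner] == "-")
    c(events = sum(r$values), cols = sum(r$lengths[r$values]))
  }
  ga <- gap_runs_in(ca); gb <- gap_runs_in(cb)
  list(length = len, matches = sum(match), mismatches = sum(mismatch),
       gap_columns = sum(gap), ambig_columns = sum(ncol_flag),
       gap_events = unname(ga["events"] + gb["events"]),
       internal_gap_columns = unname(ga["cols"] + gb["cols"]),
       trim_start = trim[1], trim_end = trim[2],
       ambig_in_trim = sum(ncol_flag[inner]))
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under affine gap scoring. Columns in
#' which either sequence carries an ambiguity code (N and friends) are
#' counted neither as matches nor as mismatches.
#'
#' @param a,b non-empty nucleotide strings.
#' @param scoring a [scoring_scheme()].
#' @return an object of class `pairwise_alignment` with the aligned strings
#'   (`aligned_a`, `aligned_b`, gap symbol `-`), the optimal `score`, and
#'   column counts: `matches`, `mismatches`, `gap_columns` (all gap
#'   columns), `gap_events` and `internal_gap_columns` (after trimming
#'   terminal gap runs), and `ambig_columns`.
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("global_align requires non-empty sequences", call. = FALSE)
  }
  a <- toupper(a); b <- toupper(b)
  validate_dna(a, "sequence a"); validate_dna(b, "sequence b")
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = iupac_submat(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  acc <- align_accounting(aligned_a, aligned_b)
  structure(c(list(aligned_a = unname(aligned_a),
                   aligned_b = unname(aligned_b),
                   score = Biostrings::score(aln), scoring = scoring),
              acc),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> length %d: %d match, %d mismatch, %d gap column(s) (%d internal event(s)); score %.1f\n",
              x$length, x$matches, x$mismatches, x$gap_columns,
              x$gap_events, x$score))
  if (x$length <= 120) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  }
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' 100 x matches / (alignment length after trimming terminal gap runs),
#' where columns involving ambiguity codes are removed from the
#' denominator. Internal gap columns stay in the denominator.
#'
#' @param result a [global_align()] result.
#' @return percent identity (full precision; round at the report layer).
#' @export
percent_identity <- function(result) {
  denom <- (result$trim_end - result$trim_start + 1L) - result$ambig_in_trim
  if (denom <= 0L) {
    stop("percent identity undefined: zero-length trimmed alignment",
         call. = FALSE)
  }
  100 * result$matches / denom
}

#' Mutation counts from a global alignment
#'
#' Substitutions are mismatch columns; indel events are maximal internal
#' gap runs (terminal overhangs are not mutations); indel columns are the
#' internal gap columns.
#'
#' @param result a [global_align()] result.
#' @return a list of class `mutation_count` with `substitutions`,
#'   `indel_events`, `indel_columns`.
#' @export
count_mutations <- function(result) {
  structure(list(substitutions = result$mismatches,
                 indel_events = result$gap_events,
                 indel_columns = result$internal_gap_columns),
            class = "mutation_count")
}

#' @export
print.mutation_count <- function(x, ...) {
  cat(sprintf("<mutation_count> %d substitution(s), %d indel event(s) over %d column(s)\n",
              x$substitutions, x$indel_events, x$indel_columns))
  invisible(x)
}
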