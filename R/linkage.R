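# Two-point linkage analysis for a pseudo-backcross: one parent is
# heterozygous at the scored markers, so offspring codes directly reveal
# recombination and phase is known (no EM). Recombination fractions are
# binomial MLEs; map distances come from the Kosambi (with crossover
# interference) and Haldane (without) mapping functions.

#' Construct a segregation matrix
#'
#' @param genotypes character matrix of codes in `{A, B, NA}`, rows =
#'   markers (rownames), columns = individuals.
#' @return the validated matrix with class `segregation_matrix`.
#' @export
segregation_matrix <- function(genotypes) {
  m <- as.matrix(genotypes)
  if (is.null(rownames(m))) stop("markers must be named (rownames)",
                                 call. = FALSE)
  bad <- !(m %in% c("A", "B") | is.na(m))
  if (any(bad)) {
    stop(sprintf("invalid genotype code(s): %s",
                 paste(unique(m[bad]), collapse = ", ")), call. = FALSE)
  }
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    stop(sprintf("marker(s) with no genotypes: %s",
                 paste(rownames(m)[all_missing], collapse = ", ")),
         call. = FALSE)
  }
  structure(m, class = c("segregation_matrix", "matrix"))
}

#' Read a genotype matrix from TSV
#'
#' Rows are markers (first column holds the marker name), columns are
#' individuals; cells are `A`, `B` or `-` (missing).
#'
#' @param path path to the TSV file.
#' @return a [segregation_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == "-"] <- NA_character_
  segregation_matrix(m)
}

#' Write a genotype matrix as TSV
#'
#' @param seg a [segregation_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(seg, path) {
  m <- unclass(seg)
  m[is.na(m)] <- "-"
  df <- data.frame(marker = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-point recombination fraction between two markers
#'
#' Individuals missing at either marker are excluded pairwise; the
#' recombination fraction is the proportion of informative individuals
#' whose codes differ, with binomial standard error
#' `sqrt(r (1 - r) / n)`. Estimates above 0.5 are capped at 0.5 with a
#' warning. Kosambi and Haldane distances are attached (infinite at
#' r = 0.5).
#'
#' @param seg a [segregation_matrix()].
#' @param m1,m2 marker names.
#' @return a list of class `linkage_estimate` with `markers`,
#'   `n_informative`, `recombinants`, `r`, `se`, `d_kosambi`, `d_haldane`.
#' @export
recombination_fraction <- function(seg, m1, m2) {
  for (m in c(m1, m2)) {
    if (!m %in% rownames(seg)) {
      stop(sprintf("unknown marker '%s'", m), call. = FALSE)
    }
  }
  g1 <- seg[m1, ]; g2 <- seg[m2, ]
  keep <- !is.na(g1) & !is.na(g2)
  n <- sum(keep)
  if (n == 0L) {
    stop(sprintf("no informative individuals for pair %s / %s", m1, m2),
         call. = FALSE)
  }
  rec <- sum(g1[keep] != g2[keep])
  r <- rec / n
  if (r > 0.5) {
    warning(sprintf("estimated r = %.3f > 0.5 for %s / %s; capped at 0.5",
                    r, m1, m2))
    r <- 0.5
  }
  se <- sqrt(r * (1 - r) / n)
  structure(list(markers = c(m1, m2), n_informative = n,
                 recombinants = rec, r = r, se = se,
                 d_kosambi = if (r < 0.5) kosambi(r) else Inf,
                 d_haldane = if (r < 0.5) haldane(r) else Inf),
            class = "linkage_estimate")
}

#' @export
print.linkage_estimate <- function(x, ...) {
  cat(sprintf("<linkage_estimate> %s - %s: r = %.3f +/- %.3f (%d/%d), Kosambi %.2f cM, Haldane %.2f cM\n",
              x$markers[1], x$markers[2], x$r, x$se, x$recombinants,
              x$n_informative, x$d_kosambi, x$d_haldane))
  invisible(x)
}

#' Kosambi and Haldane mapping functions
#'
#' `kosambi(r) = 100 * 0.25 * log((1 + 2r) / (1 - 2r))` cM accounts for
#' crossover interference; `haldane(r) = 100 * (-0.5) * log(1 - 2r)` cM
#' assumes none. Both require `0 <= r < 0.5` and satisfy
#' `kosambi(r) <= haldane(r)`. `inverse_kosambi()` and
#' `inverse_haldane()` are the exact closed-form inverses (cM to r).
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `d >= 0`.
#' @return map distance in cM, or recombination fraction for the inverses.
#' @export
kosambi <- function(r) {
  check_r(r)
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  check_r(r)
  100 * (-0.5) * log(1 - 2 * r)
}

check_r <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must satisfy 0 <= r < 0.5 (map distance diverges at 0.5)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname kosambi
#' @export
inverse_kosambi <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * tanh(2 * d / 100)
}

#' @rdname kosambi
#' @export
inverse_haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' Cosegregation report against an anchor marker
#'
#' One two-point [recombination_fraction()] estimate per non-anchor
#' marker versus the anchor (e.g. the PAR-specific marker ScOPA09 or a
#' pseudoautosomal-boundary pseudo-marker).
#'
#' @param seg a [segregation_matrix()].
#' @param anchor anchor marker name.
#' @return a data.frame with one row per marker: `marker`,
#'   `n_informative`, `recombinants`, `r`, `se`, `d_kosambi`, `d_haldane`.
#' @export
cosegregation_report <- function(seg, anchor) {
  if (!anchor %in% rownames(seg)) {
    stop(sprintf("unknown anchor marker '%s'", anchor), call. = FALSE)
  }
  others <- setdiff(rownames(seg), anchor)
  rows <- lapply(others, function(m) {
    est <- recombination_fraction(seg, m, anchor)
    data.frame(marker = m, anchor = anchor,
               n_informative = est$n_informative,
               recombinants = est$recombinants, r = est$r, se = est$se,
               d_kosambi = est$d_kosambi, d_haldane = est$d_haldane,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0L) {
    data.frame(marker = character(), anchor = character(),
               n_informative = integer(), recombinants = integer(),
               r = numeric(), se = numeric(), d_kosambi = numeric(),
               d_haldane = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
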