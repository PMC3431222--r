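# shared helpers: alphabet checks, reverse complement, report-layer rounding

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

# ambiguity letters (incl. N) are carried through but excluded from
# composition and alignment accounting
AMBIG_DNA <- setdiff(IUPAC_DNA, c("A", "C", "G", "T"))

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

validate_dna <- function(seq, what = "sequence") {
  ch <- unique(seq_chars(seq))
  bad <- setdiff(ch, c(IUPAC_DNA, "-"))
  if (length(bad) > 0L) {
    stop(sprintf("%s contains illegal symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented according to the standard table.
#'
#' @param seq a nucleotide string.
#' @return the reverse complement as a character string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# report-layer rounding conventions: percentages to 1 d.p., t statistics to
# 3 significant figures, ratios to 1 d.p., map distances to the nearest cM
fmt_pct   <- function(x) round(x, 1)
fmt_t     <- function(x) signif(x, 3)
fmt_ratio <- function(x) round(x, 1)
fmt_cm    <- function(x) round(x)

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
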