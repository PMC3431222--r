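# GC and GC3 composition per gene and the cross-species comparison.

#' GC content of a nucleotide string
#'
#' (#G + #C) / (#A + #C + #G + #T). Ambiguity codes (including N) and gap
#' symbols contribute to neither numerator nor denominator.
#'
#' @param seq nucleotide string (gaps `-` allowed).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  s <- Biostrings::DNAString(toupper(seq))
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) {
    stop("GC content undefined: no unambiguous A/C/G/T bases", call. = FALSE)
  }
  unname((f[["G"]] + f[["C"]]) / denom)
}

#' GC content at third codon positions (GC3)
#'
#' Applies [gc_content()] to the third base of every complete codon of a
#' coding sequence. A trailing incomplete codon (1-2 bases) is ignored
#' with a warning.
#'
#' @param cds coding sequence, 5' to 3' (from [extract_cds()]).
#' @return fraction in `[0, 1]`.
#' @export
gc3_content <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) {
    stop("GC3 undefined: coding sequence shorter than one codon",
         call. = FALSE)
  }
  if (n %% 3L != 0L) {
    warning(sprintf("ignoring %d trailing base(s) of an incomplete codon",
                    n %% 3L))
  }
  third <- seq.int(3L, n - n %% 3L, by = 3L)
  gc_content(paste(substring(cds, third, third), collapse = ""))
}

# mutually covered fragment of two CDSs: align, trim terminal gaps, drop
# gap columns; returns per-species base strings and per-species coding
# positions of the retained columns
covered_fragment <- function(cds_a, cds_b, scoring = scoring_scheme()) {
  aln <- global_align(cds_a, cds_b, scoring)
  ca <- seq_chars(aln$aligned_a); cb <- seq_chars(aln$aligned_b)
  pos_a <- cumsum(ca != "-"); pos_b <- cumsum(cb != "-")
  keep <- rep(FALSE, aln$length)
  if (aln$trim_end >= aln$trim_start) {
    keep[aln$trim_start:aln$trim_end] <- TRUE
  }
  keep <- keep & ca != "-" & cb != "-"
  list(a = ca[keep], b = cb[keep], pos_a = pos_a[keep], pos_b = pos_b[keep])
}

gc3_covered <- function(chars, pos, cds_len) {
  third <- pos %% 3L == 0L & pos <= cds_len - cds_len %% 3L
  if (!any(third)) {
    stop("GC3 undefined on covered fragment: no third-codon positions",
         call. = FALSE)
  }
  gc_content(paste(chars[third], collapse = ""))
}

#' Per-gene composition table for a homolog pair set
#'
#' For every paired gene, GC of the exonic (coding) sequence, GC3, and GC
#' of the full gene span, in both species. Only the mutually covered
#' fragment of the two coding sequences is used (the CDSs are aligned,
#' terminal overhangs trimmed and gap columns excluded), so a gene
#' truncated in one species does not bias the comparison. Third-codon
#' positions are taken in each species' own reading frame.
#'
#' @param pairs a [pair_homologs()] result.
#' @param scoring alignment [scoring_scheme()] for the covered-fragment
#'   computation.
#' @return a data.frame of class `composition_table`: one row per gene per
#'   species with columns `gene`, `species`, `exon_bp`, `gc_exon`,
#'   `gc3_exon`, `gc_gene` (percentages at full precision).
#' @export
composition_table <- function(pairs, scoring = scoring_scheme()) {
  region_a <- pairs$region_a; region_b <- pairs$region_b
  rows <- list()
  for (nm in pairs$pairs$name) {
    ga <- region_a$genes[[nm]]; gb <- region_b$genes[[nm]]
    cds_a <- extract_cds(region_a, ga); cds_b <- extract_cds(region_b, gb)
    cov <- covered_fragment(cds_a, cds_b, scoring)
    span_seq <- function(region, g) {
      substr(region$record$seq, min(g$exons$start) + 1L, max(g$exons$end))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = nm, species = region_a$species, exon_bp = exon_total(ga),
      gc_exon = 100 * gc_content(paste(cov$a, collapse = "")),
      gc3_exon = 100 * gc3_covered(cov$a, cov$pos_a, nchar(cds_a)),
      gc_gene = 100 * gc_content(span_seq(region_a, ga)),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = nm, species = region_b$species, exon_bp = exon_total(gb),
      gc_exon = 100 * gc_content(paste(cov$b, collapse = "")),
      gc3_exon = 100 * gc3_covered(cov$b, cov$pos_b, nchar(cds_b)),
      gc_gene = 100 * gc_content(span_seq(region_b, gb)),
      stringsAsFactors = FALSE)
  }
  for (nm in c(pairs$unpaired_a, pairs$unpaired_b)) {
    message(sprintf("composition_table: gene '%s' unpaired, skipped", nm))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("composition_table", class(out))
  out
}

#' Compare composition values between species
#'
#' Unpaired two-sample Student's t-test (pooled variance by default) on
#' two per-gene value vectors, e.g. the GC or GC3 percentages of the two
#' species.
#'
#' @param values_a,values_b numeric vectors, one value per gene.
#' @param variant passed to [student_t_two_sample()].
#' @return a `two_sample_t` object.
#' @export
compare_composition <- function(values_a, values_b,
                                variant = c("pooled", "welch")) {
  student_t_two_sample(values_a, values_b, match.arg(variant))
}
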