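# Cross-species gene-structure and intergenic comparison: homolog pairing,
# collinearity, per-gene size tables and the intergenic-expansion report.

#' Pair homologous genes between two regions
#'
#' Genes are paired by exact name match; genes present in only one region
#' are listed as unpaired.
#'
#' @param region_a,region_b [annotated_region()] objects.
#' @return an object of class `homolog_pairs`: `pairs` (data.frame with
#'   `name`, `order_a`, `order_b`, `strand_a`, `strand_b`), `unpaired_a`,
#'   `unpaired_b`, and the two regions.
#' @export
pair_homologs <- function(region_a, region_b) {
  na <- names(region_a$genes); nb <- names(region_b$genes)
  shared <- intersect(na, nb)
  if (length(shared) == 0L) {
    warning("no shared gene names between regions: 0 pairs")
  }
  span_start <- function(nm, region) {
    min(region$genes[[nm]]$exons$start)
  }
  ord_a <- rank(vapply(na, span_start, integer(1), region = region_a))
  ord_b <- rank(vapply(nb, span_start, integer(1), region = region_b))
  pairs <- data.frame(
    name = shared,
    order_a = as.integer(ord_a[shared]),
    order_b = as.integer(ord_b[shared]),
    strand_a = vapply(shared, function(nm) region_a$genes[[nm]]$strand,
                      character(1)),
    strand_b = vapply(shared, function(nm) region_b$genes[[nm]]$strand,
                      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$order_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unpaired_a = setdiff(na, shared),
                 unpaired_b = setdiff(nb, shared),
                 region_a = region_a, region_b = region_b),
            class = "homolog_pairs")
}

#' @export
print.homolog_pairs <- function(x, ...) {
  cat(sprintf("<homolog_pairs> %s vs %s: %d pair(s)",
              x$region_a$species, x$region_b$species, nrow(x$pairs)))
  if (length(x$unpaired_a) > 0L) {
    cat(sprintf("; unpaired in %s: %s", x$region_a$species,
                paste(x$unpaired_a, collapse = ", ")))
  }
  if (length(x$unpaired_b) > 0L) {
    cat(sprintf("; unpaired in %s: %s", x$region_b$species,
                paste(x$unpaired_b, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Check collinearity of paired genes
#'
#' Gene order is conserved when the paired genes appear in the same order
#' in both regions, or in exactly reversed order with uniformly flipped
#' strands (a whole-segment inversion). Otherwise the number of order
#' breakpoints is reported.
#'
#' @param pairs a [pair_homologs()] result with at least 2 pairs.
#' @return a list with `conserved` (logical) and `inversions` (breakpoint
#'   count, 0 when conserved).
#' @export
collinearity_check <- function(pairs) {
  p <- pairs$pairs
  n <- nrow(p)
  if (n < 2L) {
    stop("collinearity undefined with fewer than 2 gene pairs", call. = FALSE)
  }
  perm <- p$order_b[order(p$order_a)]  # order in B when walking A
  same <- identical(perm, seq_len(n))
  flipped <- identical(perm, rev(seq_len(n))) &&
    all(p$strand_a != p$strand_b)
  if (same || flipped) {
    return(list(conserved = TRUE, inversions = 0L))
  }
  breakpoints <- sum(abs(diff(perm)) != 1L)
  list(conserved = FALSE, inversions = breakpoints)
}

#' Per-gene size table for paired genes
#'
#' For every paired gene and both species: span length, exon count, total
#' exon length and total intron length, plus the intron-length ratio
#' (second species over first). Single-exon genes have no introns and an
#' undefined ratio (NA, printed blank at the report layer).
#'
#' @param pairs a [pair_homologs()] result.
#' @return a data.frame of class `gene_size_table`, one row per gene, with
#'   `_a`/`_b` column pairs and `intron_ratio_b_a`.
#' @export
gene_length_table <- function(pairs) {
  ra <- pairs$region_a; rb <- pairs$region_b
  rows <- lapply(pairs$pairs$name, function(nm) {
    ga <- ra$genes[[nm]]; gb <- rb$genes[[nm]]
    ia <- intron_total(ga); ib <- intron_total(gb)
    data.frame(gene = nm,
               span_a = gene_span(ga), exons_a = nrow(ga$exons),
               exon_bp_a = exon_total(ga), intron_bp_a = ia,
               span_b = gene_span(gb), exons_b = nrow(gb$exons),
               exon_bp_b = exon_total(gb), intron_bp_b = ib,
               intron_ratio_b_a = if (ia > 0L) ib / ia else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "species") <- c(a = ra$species, b = rb$species)
  class(out) <- c("gene_size_table", class(out))
  out
}

#' Compare per-gene exon and intron totals between species
#'
#' Unpaired pooled Student's t on the per-gene exon totals and on the
#' per-gene intron totals (first species minus second in the numerator).
#'
#' @param table a [gene_length_table()] result with >= 2 genes.
#' @param variant passed to [student_t_two_sample()].
#' @return a list with `t_exon` and `t_intron` (`two_sample_t` objects).
#' @export
compare_gene_sizes <- function(table, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (nrow(table) < 2L) {
    stop("need at least 2 paired genes", call. = FALSE)
  }
  list(t_exon = student_t_two_sample(table$exon_bp_a, table$exon_bp_b,
                                     variant),
       t_intron = student_t_two_sample(table$intron_bp_a, table$intron_bp_b,
                                       variant))
}

#' Expansion statistics from intergenic totals
#'
#' Difference, ratio and percent increase of the first total over the
#' second; when per-region genic totals are supplied, a 2x2 Pearson
#' chi-square (genic vs intergenic bp by region, df = 1) tests whether the
#' intergenic share differs between regions.
#'
#' @param total_a,total_b intergenic totals in bp.
#' @param genic_a,genic_b optional genic totals in bp.
#' @return a list of class `expansion_report`.
#' @export
expansion_stats <- function(total_a, total_b, genic_a = NULL,
                            genic_b = NULL) {
  if (total_b <= 0) {
    stop("expansion ratio undefined: zero intergenic total in denominator",
         call. = FALSE)
  }
  out <- list(total_intergenic_a = total_a, total_intergenic_b = total_b,
              difference = total_a - total_b, ratio = total_a / total_b,
              percent_increase = 100 * (total_a / total_b - 1),
              chi2 = NA_real_, chi2_df = NA_integer_, chi2_p = NA_real_)
  if (!is.null(genic_a) && !is.null(genic_b)) {
    tab <- matrix(c(genic_a, total_a, genic_b, total_b), nrow = 2,
                  byrow = TRUE,
                  dimnames = list(c("region_a", "region_b"),
                                  c("genic_bp", "intergenic_bp")))
    cs <- chi_square(tab)
    out$chi2 <- cs$chi2; out$chi2_df <- cs$df; out$chi2_p <- cs$p
  }
  structure(out, class = "expansion_report")
}

#' @export
print.expansion_report <- function(x, ...) {
  cat(sprintf("<expansion_report> intergenic %d vs %d bp: difference %d bp, ratio %.1f, +%d%%\n",
              round(x$total_intergenic_a), round(x$total_intergenic_b),
              round(x$difference), fmt_ratio(x$ratio),
              round(x$percent_increase)))
  if (!is.na(x$chi2)) {
    cat(sprintf("  genic/intergenic-by-region chi2 = %.1f, df = %d, p = %.4g\n",
                x$chi2, x$chi2_df, x$chi2_p))
  }
  invisible(x)
}

#' Intergenic expansion between two regions
#'
#' Intergenic totals are the summed widths of the intervals strictly
#' between the paired genes in each region (flanks excluded); the
#' chi-square uses the 2x2 genic/intergenic-by-region layout with df = 1.
#'
#' @param region_a,region_b the two regions.
#' @param pairs the [pair_homologs()] result for them (>= 2 pairs with
#'   shared order).
#' @return an `expansion_report` (see [expansion_stats()]).
#' @export
intergenic_expansion <- function(region_a, region_b, pairs) {
  if (nrow(pairs$pairs) < 2L) {
    stop("need at least 2 paired genes", call. = FALSE)
  }
  coll <- collinearity_check(pairs)
  if (!coll$conserved) {
    stop("paired gene order differs between regions; intergenic totals are not comparable",
         call. = FALSE)
  }
  nms <- pairs$pairs$name
  ia <- intergenic_intervals(region_a, nms)
  ib <- intergenic_intervals(region_b, nms)
  genic <- function(region) {
    sum(vapply(region$genes[nms], gene_span, integer(1)))
  }
  expansion_stats(sum(ia$width), sum(ib$width),
                  genic_a = genic(region_a), genic_b = genic(region_b))
}
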