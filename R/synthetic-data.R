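# Seeded generators for homologous region pairs and segregation matrices.
# Every planted feature is recorded in a generator ledger so that each
# pipeline stage can be checked against known truth: planted
# microsatellites are recovered exactly, LTR ages exactly (substitutions
# only), the intergenic expansion factor within one TE unit, and
# recombination fractions within binomial error.

default_gene_templates <- function() {
  list(
    list(name = "ESP1", strand = "+",
         exon_lengths = c(240L, rep(225L, 23L)),   # 5415 bp coding
         intron_lengths = rep(87L, 23L)),
    list(name = "BIP1", strand = "+",
         exon_lengths = c(339L, rep(336L, 5L)),    # 2019 bp
         intron_lengths = rep(55L, 5L)),
    list(name = "ACBP1", strand = "+",
         exon_lengths = c(193L, rep(190L, 5L)),    # 1143 bp
         intron_lengths = rep(150L, 5L)),
    list(name = "PAR1", strand = "+",
         exon_lengths = c(297L, rep(292L, 6L)),    # 2049 bp
         intron_lengths = rep(35L, 6L)),
    list(name = "PAR2", strand = "-",
         exon_lengths = rep(170L, 3L),             # 510 bp
         intron_lengths = rep(62L, 2L)))
}

default_microsat_plan <- function() {
  data.frame(
    motif = c("ATC", "AG", "AAT", "T", "ATA", "AAG", "TTA", "AAGT"),
    repeats = c(10L, 6L, 4L, 35L, 16L, 19L, 25L, 4L),
    species = c("B", "B", "B", "A", "A", "A", "A", "A"),
    spacer = c(1L, 2L, 4L, 1L, 2L, 3L, 4L, 3L),
    at = c(0.3, 0.6, 0.4, 0.3, 0.55, 0.35, 0.65, 0.7),
    stringsAsFactors = FALSE)
}

default_ltr_plan <- function() {
  # the youngest element needs a long LTR for its age to be
  # representable as at least one substitution (2 L K T >= 0.5)
  data.frame(
    element = c("LTRsynB1", "LTRsynB2", "LTRsynB3", "LTRsynA1", "LTRsynA2"),
    species = c("B", "B", "B", "A", "A"),
    ltr_len = c(1500L, 800L, 1000L, 700L, 600L),
    age_years = c(17200, 250000, 766000, 100000, 450000),
    internal_len = c(800L, 800L, 1000L, 800L, 800L),
    spacer = c(1L, 2L, 3L, 2L, 4L),
    at = c(0.8, 0.2, 0.8, 0.75, 0.25),
    stringsAsFactors = FALSE)
}

#' Specification for a synthetic homologous region pair
#'
#' Defaults emulate a pseudoautosomal-versus-autosome comparison at desk
#' scale: five collinear genes with near-identical exons (low exon
#' divergence), more divergent introns, intergenic spacers expanded
#' 1.6-fold in the PAR-like species (B) by transposable-element
#' insertion, scattered planted microsatellites including long-mers, and
#' LTR element pairs whose divergence encodes ages of order 1e4-1e6
#' years at K = 23e-9.
#'
#' @param seed root RNG seed; all generator randomness derives from it.
#' @param species labels for the compact (A) and expanded (B) region.
#' @param gene_templates list of per-gene templates (`name`, `strand`,
#'   `exon_lengths`, `intron_lengths`).
#' @param exon_divergence substitution rate applied to exons of B.
#' @param intron_divergence list with `sub` and `indel` rates for introns
#'   of B.
#' @param expansion_factor target intergenic ratio B / A.
#' @param spacer_lengths base spacer lengths (one fewer than genes).
#' @param flank_bp flanking sequence outside the first and last gene.
#' @param te_unit_bp length of one transposable-element unit.
#' @param cds_gc GC fraction used when drawing coding sequence.
#' @param microsat_plan data.frame (`motif`, `repeats`, `species`,
#'   `spacer`, `at`).
#' @param ltr_plan data.frame (`element`, `species`, `ltr_len`,
#'   `age_years`, `internal_len`, `spacer`, `at`); the planted
#'   substitution count is `round(2 * ltr_len * K * age_years)`.
#' @param K substitution rate per site per year for the LTR plan.
#' @param n_padding per-spacer probability of one planted run of N.
#' @return a list of class `synthetic_region_spec`.
#' @export
synthetic_region_spec <- function(seed = 1L,
                                  species = c("S_vulgaris", "S_latifolia"),
                                  gene_templates = default_gene_templates(),
                                  exon_divergence = 0.04,
                                  intron_divergence = list(sub = 0.10,
                                                           indel = 0.02),
                                  expansion_factor = 1.6,
                                  spacer_lengths = c(3000L, 2500L, 3500L,
                                                     3000L),
                                  flank_bp = 500L,
                                  te_unit_bp = 500L,
                                  cds_gc = 0.45,
                                  microsat_plan = default_microsat_plan(),
                                  ltr_plan = default_ltr_plan(),
                                  K = 23e-9,
                                  n_padding = 0) {
  n_genes <- length(gene_templates)
  if (length(spacer_lengths) != n_genes - 1L) {
    stop("spacer_lengths must have one entry per gene gap", call. = FALSE)
  }
  stopifnot(expansion_factor > 0, exon_divergence >= 0,
            exon_divergence <= 1, n_padding >= 0, n_padding <= 1)
  structure(list(seed = as.integer(seed), species = species,
                 gene_templates = gene_templates,
                 exon_divergence = exon_divergence,
                 intron_divergence = intron_divergence,
                 expansion_factor = expansion_factor,
                 spacer_lengths = as.integer(spacer_lengths),
                 flank_bp = as.integer(flank_bp),
                 te_unit_bp = as.integer(te_unit_bp),
                 cds_gc = cds_gc,
                 microsat_plan = microsat_plan, ltr_plan = ltr_plan,
                 K = K, n_padding = n_padding),
            class = "synthetic_region_spec")
}

#' Mutate a sequence with known truth
#'
#' Substitutions are drawn per site (never to the same base); indel
#' events are drawn per site with geometric lengths (mean 3), insertion
#' or deletion with equal probability. True counts are returned so the
#' mutated sequence can serve as an oracle for alignment-based counting.
#'
#' @param seq nucleotide string.
#' @param sub_rate per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site indel-event probability in `[0, 1)`.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return a list with `seq`, `substitutions`, `indel_events`,
#'   `indel_columns`.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  ch <- seq_chars(seq)
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  sub_idx <- which(stats::runif(n) < sub_rate & ch %in% bases)
  for (i in sub_idx) {
    ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  }
  n_events <- 0L; n_cols <- 0L
  if (indel_rate > 0) {
    ev_idx <- which(stats::runif(n) < indel_rate)
    # apply right to left so earlier positions stay valid
    for (i in rev(ev_idx)) {
      len <- stats::rgeom(1L, 1 / 3) + 1L
      if (stats::runif(1L) < 0.5) {          # deletion
        del <- i:min(n, i + len - 1L)
        ch[del] <- NA_character_
        n_cols <- n_cols + length(del)
      } else {                               # insertion after site i
        ins <- sample(bases, len, replace = TRUE)
        ch <- append(ch, ins, after = i)
        n_cols <- n_cols + len
      }
      n_events <- n_events + 1L
    }
    ch <- ch[!is.na(ch)]
  }
  list(seq = paste(ch, collapse = ""),
       substitutions = length(sub_idx),
       indel_events = n_events, indel_columns = n_cols)
}

# exactly m substitutions at distinct sites (used for LTR planting)
apply_exact_substitutions <- function(seq, m) {
  ch <- seq_chars(seq)
  if (m > length(ch)) stop("more substitutions than sites", call. = FALSE)
  idx <- sample(length(ch), m)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# a spacer is built as a list of typed pieces; features become annotation
# when the region is laid out
new_spacer <- function(len, gc = 0.4) {
  list(list(type = "dna", seq = random_dna(len, gc)))
}

spacer_length <- function(pieces) {
  sum(vapply(pieces, function(p) nchar(p$seq), numeric(1)))
}

# insert a typed piece into the i-th spacer at fraction `at` of its first
# large-enough dna piece (features are never split)
insert_piece <- function(pieces, piece, at) {
  dna_idx <- which(vapply(pieces, function(p) p$type == "dna", logical(1)))
  sizes <- vapply(dna_idx, function(i) nchar(pieces[[i]]$seq), numeric(1))
  host <- dna_idx[which.max(sizes)]
  s <- pieces[[host]]$seq
  cut <- max(1L, min(nchar(s) - 1L, round(at * nchar(s))))
  left <- list(type = "dna", seq = substr(s, 1L, cut))
  right <- list(type = "dna", seq = substr(s, cut + 1L, nchar(s)))
  append(pieces[-host], list(left, piece, right), after = host - 1L)
}

# plant a perfect microsatellite with breaker bases so the planted locus
# is a maximal array exactly as specified
msat_piece <- function(motif, repeats) {
  k <- nchar(motif)
  last <- substr(motif, k, k); first <- substr(motif, 1L, 1L)
  breaker_l <- setdiff(c("A", "C", "G", "T"), last)[1]
  breaker_r <- setdiff(c("A", "C", "G", "T"), first)[1]
  list(type = "msat", seq = paste0(breaker_l, strrep(motif, repeats),
                                   breaker_r),
       motif = motif, repeats = repeats, pad_left = 1L, pad_right = 1L)
}

ltr_piece <- function(element, ltr_len, internal_len, age_years, K) {
  ltr <- random_dna(ltr_len, 0.4)
  n_sub <- round(2 * ltr_len * K * age_years)
  ltr3 <- apply_exact_substitutions(ltr, n_sub)
  list(type = "ltr", seq = paste0(ltr, random_dna(internal_len, 0.4), ltr3),
       element = element, ltr_len = ltr_len, internal_len = internal_len,
       n_sub = n_sub, age_programmed = age_years,
       age_realized = n_sub / (2 * ltr_len * K), K = K)
}

#' Generate a synthetic homologous region pair
#'
#' Species A is built gene by gene with intergenic spacers; species B
#' carries the same genes with exon/intron divergence applied, and its
#' spacers are expanded by whole transposable-element units until the
#' intergenic total reaches `expansion_factor` times that of A (within
#' one unit). Planted microsatellites and LTR pairs follow the plans in
#' the spec.
#'
#' @param spec a [synthetic_region_spec()].
#' @return a list with `region_a`, `region_b` ([annotated_region()]
#'   objects) and `ledger` (the generator's truth record).
#' @export
generate_homolog_pair <- function(spec) {
  set.seed(spec$seed)
  n_genes <- length(spec$gene_templates)
  n_spacers <- n_genes - 1L
  ms <- spec$microsat_plan; lp <- spec$ltr_plan
  if (nrow(ms) > 0L && any(ms$spacer > n_spacers | ms$spacer < 1L)) {
    stop("microsat_plan: spacer index out of range", call. = FALSE)
  }
  if (nrow(lp) > 0L && any(lp$spacer > n_spacers | lp$spacer < 1L)) {
    stop("ltr_plan: spacer index out of range", call. = FALSE)
  }

  ## genes ------------------------------------------------------------
  genes_a <- list(); genes_b <- list()
  ledger_genes <- list()
  for (tpl in spec$gene_templates) {
    n_ex <- length(tpl$exon_lengths)
    if (length(tpl$intron_lengths) != n_ex - 1L) {
      stop(sprintf("gene '%s': need one intron length per exon gap",
                   tpl$name), call. = FALSE)
    }
    cds_len <- sum(tpl$exon_lengths)
    cds_a <- random_dna(cds_len, spec$cds_gc)
    coding_genomic <- if (tpl$strand == "-") reverse_complement(cds_a) else
      cds_a
    # split the genomic coding sequence into exons in genomic order
    ends <- cumsum(tpl$exon_lengths)
    exon_seqs_a <- substring(coding_genomic, c(1L, ends[-n_ex] + 1L), ends)
    intron_seqs_a <- vapply(tpl$intron_lengths, random_dna, character(1),
                            gc = 0.35)
    ex_subs <- 0L
    exon_seqs_b <- vapply(exon_seqs_a, function(s) {
      m <- mutate_sequence(s, spec$exon_divergence, 0)
      ex_subs <<- ex_subs + m$substitutions
      m$seq
    }, character(1), USE.NAMES = FALSE)
    in_subs <- 0L; in_indels <- 0L
    intron_seqs_b <- vapply(intron_seqs_a, function(s) {
      m <- mutate_sequence(s, spec$intron_divergence$sub,
                           spec$intron_divergence$indel)
      in_subs <<- in_subs + m$substitutions
      in_indels <<- in_indels + m$indel_events
      m$seq
    }, character(1), USE.NAMES = FALSE)
    cds_b <- local({
      coding_b <- paste(exon_seqs_b, collapse = "")
      if (tpl$strand == "-") reverse_complement(coding_b) else coding_b
    })
    genes_a[[tpl$name]] <- list(tpl = tpl, exon_seqs = exon_seqs_a,
                                intron_seqs = intron_seqs_a)
    genes_b[[tpl$name]] <- list(tpl = tpl, exon_seqs = exon_seqs_b,
                                intron_seqs = intron_seqs_b)
    ledger_genes[[tpl$name]] <- list(
      cds_a = cds_a, cds_b = cds_b, strand = tpl$strand,
      exon_total_a = cds_len,
      exon_total_b = sum(nchar(exon_seqs_b)),
      intron_total_a = sum(tpl$intron_lengths),
      intron_total_b = sum(nchar(intron_seqs_b)),
      exon_substitutions = ex_subs,
      intron_substitutions = in_subs, intron_indel_events = in_indels)
  }

  ## spacers ------------------------------------------------------------
  spacers_a <- lapply(spec$spacer_lengths, new_spacer)
  spacers_b <- lapply(spec$spacer_lengths, new_spacer)
  get_spacers <- function(sp) if (sp == "A") spacers_a else spacers_b
  if (nrow(ms) > 0L) for (i in seq_len(nrow(ms))) {
    piece <- msat_piece(ms$motif[i], ms$repeats[i])
    if (nchar(piece$seq) >= spec$spacer_lengths[ms$spacer[i]]) {
      stop(sprintf("microsat_plan item %d (%s x %d) longer than its spacer",
                   i, ms$motif[i], ms$repeats[i]), call. = FALSE)
    }
    if (ms$species[i] == "A") {
      spacers_a[[ms$spacer[i]]] <- insert_piece(spacers_a[[ms$spacer[i]]],
                                                piece, ms$at[i])
    } else {
      spacers_b[[ms$spacer[i]]] <- insert_piece(spacers_b[[ms$spacer[i]]],
                                                piece, ms$at[i])
    }
  }
  if (nrow(lp) > 0L) for (i in seq_len(nrow(lp))) {
    piece <- ltr_piece(lp$element[i], lp$ltr_len[i], lp$internal_len[i],
                       lp$age_years[i], spec$K)
    if (lp$species[i] == "A") {
      spacers_a[[lp$spacer[i]]] <- insert_piece(spacers_a[[lp$spacer[i]]],
                                                piece, lp$at[i])
    } else {
      spacers_b[[lp$spacer[i]]] <- insert_piece(spacers_b[[lp$spacer[i]]],
                                                piece, lp$at[i])
    }
  }
  if (spec$n_padding > 0) {
    for (j in seq_len(n_spacers)) {
      if (stats::runif(1L) < spec$n_padding) {
        spacers_a[[j]] <- insert_piece(
          spacers_a[[j]], list(type = "dna", seq = strrep("N", 50L)), 0.9)
      }
      if (stats::runif(1L) < spec$n_padding) {
        spacers_b[[j]] <- insert_piece(
          spacers_b[[j]], list(type = "dna", seq = strrep("N", 50L)), 0.9)
      }
    }
  }

  ## expand B by whole TE units until the intergenic ratio is reached ----
  te_unit <- random_dna(spec$te_unit_bp, 0.42)
  total_a <- sum(vapply(spacers_a, spacer_length, numeric(1)))
  total_b <- sum(vapply(spacers_b, spacer_length, numeric(1)))
  target <- spec$expansion_factor * total_a
  te_count <- 0L
  while (total_b < target) {
    j <- sample(n_spacers, 1L)
    te_count <- te_count + 1L
    spacers_b[[j]] <- insert_piece(
      spacers_b[[j]],
      list(type = "te", seq = te_unit,
           te_name = sprintf("TEsyn%03d", te_count)),
      stats::runif(1L))
    total_b <- total_b + spec$te_unit_bp
  }

  ## lay out both regions ------------------------------------------------
  layout_region <- function(species, id, genes, spacers) {
    seq_parts <- character(0)
    offset <- 0L
    gene_models <- list()
    repeats <- empty_repeats()
    ltr_pairs <- list()
    msat_rows <- list()
    push <- function(s) {
      seq_parts[[length(seq_parts) + 1L]] <<- s
      offset <<- offset + nchar(s)
    }
    push(random_dna(spec$flank_bp, 0.4))
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      ex <- data.frame(start = integer(0), end = integer(0))
      for (k in seq_along(g$exon_seqs)) {
        ex <- rbind(ex, data.frame(start = offset,
                                   end = offset + nchar(g$exon_seqs[k])))
        push(g$exon_seqs[k])
        if (k < length(g$exon_seqs)) push(g$intron_seqs[k])
      }
      gene_models[[g$tpl$name]] <- gene_model(g$tpl$name, g$tpl$strand, ex,
                                              species = species)
      if (gi <= length(spacers)) {
        for (p in spacers[[gi]]) {
          p_start <- offset
          if (p$type == "msat") {
            msat_rows[[length(msat_rows) + 1L]] <- data.frame(
              species = species,
              start = p_start + p$pad_left,
              end = p_start + p$pad_left +
                nchar(p$motif) * p$repeats,
              motif = p$motif, unit_len = nchar(p$motif),
              repeat_count = p$repeats, stringsAsFactors = FALSE)
          } else if (p$type == "te") {
            repeats <- rbind(repeats, data.frame(
              start = p_start, end = p_start + nchar(p$seq), strand = "+",
              name = p$te_name, stringsAsFactors = FALSE))
          } else if (p$type == "ltr") {
            repeats <- rbind(repeats, data.frame(
              start = p_start, end = p_start + nchar(p$seq), strand = "+",
              name = p$element, stringsAsFactors = FALSE))
            ltr_pairs[[length(ltr_pairs) + 1L]] <- list(
              element_name = p$element,
              ltr5 = c(p_start, p_start + p$ltr_len),
              ltr3 = c(p_start + p$ltr_len + p$internal_len,
                       p_start + 2L * p$ltr_len + p$internal_len),
              strand = "+")
          }
          push(p$seq)
        }
      }
    }
    push(random_dna(spec$flank_bp, 0.4))
    region <- annotated_region(species, id, paste(seq_parts, collapse = ""),
                               genes = gene_models, repeats = repeats,
                               ltr_pairs = ltr_pairs)
    list(region = region, msats = msat_rows)
  }

  la <- layout_region(spec$species[1], paste0(spec$species[1], "_region"),
                      genes_a, spacers_a)
  lb <- layout_region(spec$species[2], paste0(spec$species[2], "_region"),
                      genes_b, spacers_b)

  msats <- do.call(rbind, c(la$msats, lb$msats,
                            list(data.frame(species = character(),
                                            start = integer(),
                                            end = integer(),
                                            motif = character(),
                                            unit_len = integer(),
                                            repeat_count = integer(),
                                            stringsAsFactors = FALSE))))
  ltr_truth <- do.call(rbind, c(
    lapply(seq_len(nrow(lp)), function(i) {
      data.frame(element = lp$element[i], species = lp$species[i],
                 L = lp$ltr_len[i],
                 N = round(2 * lp$ltr_len[i] * spec$K * lp$age_years[i]),
                 age_programmed = lp$age_years[i],
                 K = spec$K, stringsAsFactors = FALSE)
    }),
    list(data.frame(element = character(), species = character(),
                    L = integer(), N = numeric(),
                    age_programmed = numeric(), K = numeric(),
                    stringsAsFactors = FALSE))))
  ltr_truth$age_realized <- ltr_truth$N / (2 * ltr_truth$L * ltr_truth$K)

  ledger <- list(seed = spec$seed, genes = ledger_genes,
                 microsats = msats, ltr = ltr_truth,
                 intergenic = list(total_a = total_a, total_b = total_b,
                                   ratio = total_b / total_a,
                                   te_units_inserted = te_count,
                                   te_unit_bp = spec$te_unit_bp),
                 expansion_factor = spec$expansion_factor)
  list(region_a = la$region, region_b = lb$region, ledger = ledger)
}

#' Generate a pseudo-backcross segregation matrix
#'
#' Anchor genotypes are Bernoulli(1/2); every other marker flips
#' independently per individual with its recombination probability to the
#' anchor; entries are masked missing at `missing_rate`.
#'
#' @param markers marker names; the first is the anchor.
#' @param r_to_anchor recombination fractions to the anchor for
#'   `markers[-1]` (values in `[0, 0.5]`).
#' @param n number of individuals (default 76).
#' @param missing_rate per-cell missingness probability.
#' @param seed optional seed.
#' @return a list with `seg` (a [segregation_matrix()]) and `ledger`
#'   (true `r` per marker and realized recombinant counts).
#' @export
generate_segregation <- function(markers, r_to_anchor, n = 76L,
                                 missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(r_to_anchor) == length(markers) - 1L,
            all(r_to_anchor >= 0), all(r_to_anchor <= 0.5))
  anchor <- sample(c("A", "B"), n, replace = TRUE)
  m <- matrix(NA_character_, nrow = length(markers), ncol = n,
              dimnames = list(markers,
                              sprintf("ind%02d", seq_len(n))))
  m[1L, ] <- anchor
  realized <- integer(length(markers) - 1L)
  for (i in seq_along(r_to_anchor)) {
    flip <- stats::runif(n) < r_to_anchor[i]
    realized[i] <- sum(flip)
    m[i + 1L, ] <- ifelse(flip, ifelse(anchor == "A", "B", "A"), anchor)
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(m)) < missing_rate, nrow = nrow(m))
    mask[, 1L] <- FALSE  # keep one fully typed individual per marker
    m[mask] <- NA_character_
  }
  list(seg = segregation_matrix(m),
       ledger = list(anchor = markers[1],
                     true_r = stats::setNames(r_to_anchor, markers[-1L]),
                     realized_recombinants = stats::setNames(realized,
                                                             markers[-1L]),
                     n = n, missing_rate = missing_rate))
}

#' Reference values for the five-gene PAR/autosome comparison
#'
#' Published per-gene structure and composition values for the five
#' pseudoautosomal genes (ESP1, BIP1, ACBP1, PAR1, PAR2) shared by the
#' *Silene latifolia* PAR and its *S. vulgaris* autosomal homolog, used
#' as worked-example fixtures: per-species exon counts, exon/intron/span
#' lengths (bp), exon GC and GC3 percentages, exon and whole-gene percent
#' identities, and the two intergenic totals.
#'
#' @return a named list of numeric vectors (one entry per gene, in the
#'   order ESP1, BIP1, ACBP1, PAR1, PAR2) plus `intergenic_bp`.
#' @export
silene_reference_values <- function() {
  genes <- c("ESP1", "BIP1", "ACBP1", "PAR1", "PAR2")
  nm <- function(x) stats::setNames(x, genes)
  list(
    genes = genes,
    sl_span_bp = nm(c(15455, 3401, 4909, 3107, 1127)),
    sl_exons = nm(c(24, 6, 6, 7, 3)),
    sl_exon_bp = nm(c(5416, 2019, 1143, 2049, 510)),
    sl_intron_bp = nm(c(10039, 1382, 3766, 1058, 617)),
    sv_span_bp = nm(c(16677, 3217, 5042, 3043, 1138)),
    sv_exons = nm(c(24, 6, 6, 7, 3)),
    sv_exon_bp = nm(c(5422, 2046, 1143, 2049, 507)),
    sv_intron_bp = nm(c(11255, 1171, 3899, 994, 631)),
    sl_exon_gc = nm(c(42.4, 47.3, 48.3, 42.3, 48.3)),
    sl_exon_gc3 = nm(c(41.2, 53.5, 42.9, 38.1, 49.7)),
    sv_exon_gc = nm(c(42.4, 47.3, 47.7, 42.4, 48.3)),
    sv_exon_gc3 = nm(c(41.1, 53.7, 42.9, 37.3, 49.1)),
    identity_exons = nm(c(96.5, 96.9, 92.9, 97.1, 95.9)),
    identity_gene = nm(c(80.7, 85.6, 73.6, 92.6, 92.8)),
    intergenic_bp = c(sl = 115909, sv = 71866))
}
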