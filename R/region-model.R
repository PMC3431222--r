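# Domain types for annotated genomic regions and their FASTA/GFF3 readers
# and writers. Internal coordinates are 0-based half-open throughout; the
# GFF3 boundary converts to/from the 1-based inclusive convention.

#' Construct a gene model from exon intervals
#'
#' A gene model is an ordered chain of non-overlapping exons on one strand.
#' The gene span runs from the start of the first exon to the end of the
#' last exon; everything in between that is not exonic is intronic (no UTR
#' model is used, so published per-gene "sequence length" values are treated
#' as span lengths).
#'
#' @param name gene name, unique within a region.
#' @param strand `"+"` or `"-"`.
#' @param exons a data.frame with integer columns `start`, `end`
#'   (0-based half-open), one row per exon.
#' @param species species label.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, strand, exons, species = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) stop("gene model needs at least one exon", call. = FALSE)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) {
    stop(sprintf("gene '%s': exon with end <= start", name), call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop(sprintf("gene '%s': overlapping exons", name), call. = FALSE)
  }
  structure(list(name = name, strand = strand, exons = exons,
                 species = species),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s: %d exon(s), span %d bp (exons %d, introns %d)\n",
              x$name, x$species, x$strand, nrow(x$exons), gene_span(x),
              exon_total(x), intron_total(x)))
  invisible(x)
}

#' Gene-model size accessors
#'
#' `exon_total()` is the summed exon length, `intron_total()` the summed
#' intron length and `gene_span()` the distance from first exon start to
#' last exon end, so that `gene_span == exon_total + intron_total`.
#'
#' @param gene a [gene_model()].
#' @return an integer number of base pairs.
#' @export
exon_total <- function(gene) sum(gene$exons$end - gene$exons$start)

#' @rdname exon_total
#' @export
intron_total <- function(gene) gene_span(gene) - exon_total(gene)

#' @rdname exon_total
#' @export
gene_span <- function(gene) {
  max(gene$exons$end) - min(gene$exons$start)
}

empty_repeats <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             name = character(), stringsAsFactors = FALSE)
}

#' Construct an annotated region
#'
#' One species' genomic sequence together with its typed features: gene
#' models, repeat intervals (transposable-element insertions and the like)
#' and paired-LTR elements.
#'
#' @param species species label.
#' @param id sequence identifier.
#' @param seq nucleotide string (upper-cased; IUPAC codes allowed).
#' @param genes list of [gene_model()] objects with unique names.
#' @param repeats data.frame with columns `start`, `end`, `strand`, `name`
#'   (0-based half-open).
#' @param ltr_pairs list of LTR elements; each a list with `element_name`,
#'   `ltr5` and `ltr3` (each `c(start, end)`, 0-based half-open) and
#'   optionally `strand`.
#' @return an object of class `annotated_region`.
#' @export
annotated_region <- function(species, id, seq, genes = list(),
                             repeats = empty_repeats(), ltr_pairs = list()) {
  seq <- toupper(seq)
  validate_dna(seq, sprintf("sequence '%s'", id))
  len <- nchar(seq)
  nm <- vapply(genes, function(g) g$name, character(1))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene name(s) in region '%s': %s", id,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  names(genes) <- nm
  for (g in genes) {
    if (min(g$exons$start) < 0L || max(g$exons$end) > len) {
      stop(sprintf("gene '%s' outside sequence bounds [0, %d)", g$name, len),
           call. = FALSE)
    }
  }
  repeats <- as.data.frame(repeats)
  if (nrow(repeats) > 0L &&
      (any(repeats$start < 0L) || any(repeats$end > len))) {
    stop("repeat feature outside sequence bounds", call. = FALSE)
  }
  for (p in ltr_pairs) {
    if (p$ltr5[1] < 0L || p$ltr3[2] > len || p$ltr5[2] > p$ltr3[1]) {
      stop(sprintf("LTR element '%s': invalid or out-of-bounds intervals",
                   p$element_name), call. = FALSE)
    }
  }
  structure(list(species = species,
                 record = list(id = id, seq = seq, length = len),
                 genes = genes, repeats = repeats, ltr_pairs = ltr_pairs),
            class = "annotated_region")
}

#' @export
print.annotated_region <- function(x, ...) {
  cat(sprintf("<annotated_region> %s [%s]: %d bp, %d gene(s), %d repeat(s), %d LTR element(s)\n",
              x$species, x$record$id, x$record$length, length(x$genes),
              nrow(x$repeats), length(x$ltr_pairs)))
  invisible(x)
}

## ---- FASTA ---------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return a list of records, each a list with `id`, `seq` (upper-cased)
#'   and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  diagnose <- function(fallback) {
    # name the offending symbol/line for a useful message
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">") || !nzchar(ln)) next
      bad <- setdiff(unique(seq_chars(toupper(ln))), IUPAC_DNA)
      if (length(bad) > 0L) {
        stop(sprintf("FASTA format error in '%s', line %d: illegal symbol '%s'",
                     path, i, bad[1]), call. = FALSE)
      }
    }
    stop(sprintf("FASTA format error in '%s': %s", path, fallback),
         call. = FALSE)
  }
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
             error = function(e) diagnose(conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        diagnose(conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("FASTA file '%s': duplicate record id '%s'", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  lapply(seq_along(set), function(i) {
    validate_dna(seqs[i], sprintf("FASTA record '%s'", ids[i]))
    list(id = unname(ids[i]), seq = unname(seqs[i]),
         length = unname(nchar(seqs[i])))
  })
}

#' Write records to a FASTA file
#'
#' Sequences are wrapped at 80 columns.
#'
#' @param records a list of records as returned by [read_fasta()], or a
#'   named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- Map(function(id, s) list(id = id, seq = s),
                   names(records), unname(records))
  }
  seqs <- vapply(records, function(r) r$seq, character(1))
  names(seqs) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

## ---- GFF3 ----------------------------------------------------------------

GFF_TYPES <- c("gene", "exon", "repeat_region", "LTR_retrotransposon",
               "long_terminal_repeat")

#' Read a GFF3 annotation onto a region
#'
#' Recognised feature types are `gene`, `exon` (linked to its gene by the
#' `Parent` attribute), `repeat_region`, `LTR_retrotransposon` and
#' `long_terminal_repeat` (two per retrotransposon, linked by `Parent`).
#' GFF3 columns 4/5 (1-based inclusive) are converted to internal 0-based
#' half-open coordinates.
#'
#' @param path path to a GFF3 file.
#' @param region an [annotated_region()] carrying the sequence the
#'   annotation refers to (its existing features are replaced).
#' @return the region with genes, repeats and LTR pairs attached.
#' @export
read_gff3 <- function(path, region) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df <- df[df$type %in% GFF_TYPES, , drop = FALSE]
  len <- region$record$length

  id_of <- function(i) {
    id <- df$ID[i] %||% NA_character_
    if (is.na(id) || !nzchar(id)) id <- df$Name[i] %||% NA_character_
    if (is.na(id)) id <- sprintf("feature_%d", i)
    id
  }
  first_parent <- function(i) {
    p <- df$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }

  start0 <- df$start - 1L   # 1-based inclusive -> 0-based half-open
  end0 <- df$end
  if (any(end0 <= start0)) {
    bad <- which(end0 <= start0)[1]
    stop(sprintf("GFF3 feature '%s': end < start", id_of(bad)), call. = FALSE)
  }
  if (any(start0 < 0L) || any(end0 > len)) {
    bad <- which(start0 < 0L | end0 > len)[1]
    stop(sprintf("GFF3 feature '%s': interval [%d, %d) outside sequence bounds [0, %d)",
                 id_of(bad), start0[bad], end0[bad], len), call. = FALSE)
  }

  gene_rows <- which(df$type == "gene")
  gene_ids <- vapply(gene_rows, id_of, character(1))
  gene_names <- vapply(gene_rows, function(i) {
    nm <- df$Name[i] %||% NA_character_
    if (is.na(nm) || !nzchar(nm)) id_of(i) else nm
  }, character(1))

  exon_rows <- which(df$type == "exon")
  genes <- list()
  exon_parents <- vapply(exon_rows, first_parent, character(1))
  if (length(exon_rows) > 0L && anyNA(exon_parents)) {
    bad <- exon_rows[which(is.na(exon_parents))[1]]
    stop(sprintf("GFF3 exon '%s' has no Parent attribute", id_of(bad)),
         call. = FALSE)
  }
  for (k in seq_along(gene_rows)) {
    i <- gene_rows[k]
    ex <- exon_rows[exon_parents == gene_ids[k]]
    if (length(ex) == 0L) {
      # a gene without exon children is modelled as a single-exon gene
      ex_df <- data.frame(start = start0[i], end = end0[i])
    } else {
      ex_df <- data.frame(start = start0[ex], end = end0[ex])
    }
    genes[[k]] <- gene_model(gene_names[k], as.character(df$strand[i]),
                             ex_df, species = region$species)
  }

  rep_rows <- which(df$type == "repeat_region")
  repeats <- if (length(rep_rows) > 0L) {
    data.frame(start = start0[rep_rows], end = end0[rep_rows],
               strand = as.character(df$strand[rep_rows]),
               name = vapply(rep_rows, id_of, character(1)),
               stringsAsFactors = FALSE)
  } else empty_repeats()

  ltr_el_rows <- which(df$type == "LTR_retrotransposon")
  ltr_rows <- which(df$type == "long_terminal_repeat")
  ltr_parents <- vapply(ltr_rows, first_parent, character(1))
  ltr_pairs <- lapply(ltr_el_rows, function(i) {
    id <- id_of(i)
    kids <- ltr_rows[ltr_parents == id]
    if (length(kids) != 2L) {
      stop(sprintf("LTR_retrotransposon '%s' must have exactly 2 long_terminal_repeat children (found %d)",
                   id, length(kids)), call. = FALSE)
    }
    kids <- kids[order(start0[kids])]
    list(element_name = id,
         ltr5 = c(start0[kids[1]], end0[kids[1]]),
         ltr3 = c(start0[kids[2]], end0[kids[2]]),
         strand = as.character(df$strand[i]))
  })

  annotated_region(region$species, region$record$id, region$record$seq,
                   genes = genes, repeats = repeats, ltr_pairs = ltr_pairs)
}

#' Write a region's annotation as GFF3
#'
#' @param region an [annotated_region()].
#' @param path output path.
#' @export
write_gff3 <- function(region, path) {
  rows <- list()
  add <- function(type, start0, end0, strand, id, name = NA, parent = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start = start0 + 1L, end = end0, strand = strand,
      ID = id, Name = name, Parent = parent, stringsAsFactors = FALSE)
  }
  for (g in region$genes) {
    gid <- paste0("gene:", g$name)
    add("gene", min(g$exons$start), max(g$exons$end), g$strand, gid, g$name)
    for (j in seq_len(nrow(g$exons))) {
      add("exon", g$exons$start[j], g$exons$end[j], g$strand,
          sprintf("%s.exon%d", gid, j), parent = gid)
    }
  }
  if (nrow(region$repeats) > 0L) {
    for (j in seq_len(nrow(region$repeats))) {
      r <- region$repeats[j, ]
      add("repeat_region", r$start, r$end, r$strand, r$name, r$name)
    }
  }
  for (p in region$ltr_pairs) {
    eid <- p$element_name
    add("LTR_retrotransposon", p$ltr5[1], p$ltr3[2], p$strand %||% "+",
        eid, eid)
    add("long_terminal_repeat", p$ltr5[1], p$ltr5[2], p$strand %||% "+",
        paste0(eid, ".ltr5"), parent = eid)
    add("long_terminal_repeat", p$ltr3[1], p$ltr3[2], p$strand %||% "+",
        paste0(eid, ".ltr3"), parent = eid)
  }
  if (length(rows) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = region$record$id,
      ranges = IRanges::IRanges(start = df$start, end = df$end),
      strand = df$strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$ID <- df$ID
    S4Vectors::mcols(gr)$Name <- df$Name
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- derived sequences and intervals ------------------------------------

#' Extract the coding sequence of a gene
#'
#' Exon substrings are concatenated in genomic order; for minus-strand
#' genes the concatenation is reverse-complemented, so the result reads
#' 5' to 3' on the coding strand.
#'
#' @param region an [annotated_region()].
#' @param gene a [gene_model()] belonging to the region, or a gene name.
#' @return the CDS as a character string.
#' @export
extract_cds <- function(region, gene) {
  if (is.character(gene)) {
    if (!gene %in% names(region$genes)) {
      stop(sprintf("unknown gene '%s' in region '%s'", gene,
                   region$record$id), call. = FALSE)
    }
    gene <- region$genes[[gene]]
  }
  len <- region$record$length
  if (min(gene$exons$start) < 0L || max(gene$exons$end) > len) {
    stop(sprintf("gene '%s': exon outside sequence bounds", gene$name),
         call. = FALSE)
  }
  pieces <- substring(region$record$seq, gene$exons$start + 1L,
                      gene$exons$end)
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds <- reverse_complement(cds)
  cds
}

#' Intervals between consecutive genes
#'
#' Returns the intervals strictly between the spans of consecutive named
#' genes (first exon start to last exon end), in genomic order. Flanking
#' intervals before the first and after the last gene are excluded: only
#' the regions in between the genes count as intergenic.
#'
#' @param region an [annotated_region()].
#' @param gene_names names of the genes to consider (default: all).
#' @return a data.frame with columns `start`, `end`, `width`, `left_gene`,
#'   `right_gene`; `n` genes yield `n - 1` rows.
#' @export
intergenic_intervals <- function(region, gene_names = names(region$genes)) {
  missing <- setdiff(gene_names, names(region$genes))
  if (length(missing) > 0L) {
    stop(sprintf("unknown gene name(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  genes <- region$genes[gene_names]
  spans <- data.frame(
    name = vapply(genes, function(g) g$name, character(1)),
    start = vapply(genes, function(g) min(g$exons$start), integer(1)),
    end = vapply(genes, function(g) max(g$exons$end), integer(1)))
  spans <- spans[order(spans$start), , drop = FALSE]
  n <- nrow(spans)
  if (n > 1L && any(spans$start[-1L] < spans$end[-n])) {
    stop("overlapping gene spans; intergenic intervals undefined",
         call. = FALSE)
  }
  if (n < 2L) {
    return(data.frame(start = integer(), end = integer(), width = integer(),
                      left_gene = character(), right_gene = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(start = spans$end[-n], end = spans$start[-1L],
             width = spans$start[-1L] - spans$end[-n],
             left_gene = spans$name[-n], right_gene = spans$name[-1L],
             row.names = NULL, stringsAsFactors = FALSE)
}
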