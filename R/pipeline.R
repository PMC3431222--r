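# Config-driven orchestration: run every comparison stage on a pair of
# annotated regions (plus an optional genotype matrix) and write a
# comparative report, or write a synthetic dataset to disk.
# Rounding conventions are applied only here, at serialization:
# percentages 1 d.p., t statistics 3 s.f., ratios 1 d.p., map distances
# to the nearest cM.

#' Run configuration for the comparative pipeline
#'
#' @param fasta_a,gff_a,fasta_b,gff_b input paths for the two species.
#' @param species_a,species_b species labels.
#' @param genotypes optional genotype TSV for the linkage stage.
#' @param anchor anchor marker for the cosegregation report.
#' @param out_dir output directory (created if needed).
#' @param K substitution rate per site per year for LTR dating.
#' @param include_indels count indel events in the LTR mutation number N.
#' @param min_unit,max_unit,min_repeats,mono_min_repeats microsatellite
#'   thresholds (see [find_perfect_repeats()]).
#' @param scoring alignment [scoring_scheme()].
#' @param t_variant `"pooled"` or `"welch"`.
#' @param seed seed recorded in the manifest and used for any stochastic
#'   step.
#' @return a list of class `run_config`.
#' @export
run_config <- function(fasta_a, gff_a, fasta_b, gff_b,
                       species_a = "species_a", species_b = "species_b",
                       genotypes = NULL, anchor = NULL,
                       out_dir = "parcomp_out",
                       K = 23e-9, include_indels = FALSE,
                       min_unit = 2L, max_unit = 100L, min_repeats = 3L,
                       mono_min_repeats = 12L,
                       scoring = scoring_scheme(),
                       t_variant = c("pooled", "welch"),
                       seed = 1L) {
  stopifnot(K > 0, min_unit >= 1L, max_unit >= min_unit, min_repeats >= 1L,
            mono_min_repeats >= 1L)
  structure(list(fasta_a = fasta_a, gff_a = gff_a, fasta_b = fasta_b,
                 gff_b = gff_b, species_a = species_a,
                 species_b = species_b, genotypes = genotypes,
                 anchor = anchor, out_dir = out_dir, K = K,
                 include_indels = include_indels, min_unit = min_unit,
                 max_unit = max_unit, min_repeats = min_repeats,
                 mono_min_repeats = mono_min_repeats, scoring = scoring,
                 t_variant = match.arg(t_variant), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a key = value file
#'
#' One `key = value` per line; `#` starts a comment. Keys match the
#' arguments of [run_config()] (scoring as `match`, `mismatch`,
#' `gap_open`, `gap_extend`).
#'
#' @param path path to the configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(x) x[2]),
                          vapply(kv, function(x) x[1], character(1)))
  num_keys <- c("K", "min_unit", "max_unit", "min_repeats",
                "mono_min_repeats", "seed", "match", "mismatch",
                "gap_open", "gap_extend")
  for (k in intersect(names(vals), num_keys)) {
    vals[[k]] <- as.numeric(vals[[k]])
  }
  if ("include_indels" %in% names(vals)) {
    vals$include_indels <- toupper(vals$include_indels) %in%
      c("TRUE", "1", "YES")
  }
  sc_keys <- intersect(names(vals), c("match", "mismatch", "gap_open",
                                      "gap_extend"))
  if (length(sc_keys) > 0L) {
    vals$scoring <- do.call(scoring_scheme, vals[sc_keys])
    vals[sc_keys] <- NULL
  }
  do.call(run_config, vals)
}

add_region_col <- function(df, label) {
  df$region <- rep(label, nrow(df))
  df[, c("region", setdiff(names(df), "region")), drop = FALSE]
}

read_region <- function(fasta, gff, species) {
  recs <- read_fasta(fasta)
  if (length(recs) != 1L) {
    stop(sprintf("expected exactly one FASTA record in '%s' (found %d)",
                 fasta, length(recs)), call. = FALSE)
  }
  region <- annotated_region(species, recs[[1]]$id, recs[[1]]$seq)
  read_gff3(gff, region)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Reads the two annotated regions (and optionally a genotype matrix),
#' runs every comparison stage and writes to `config$out_dir`:
#' `composition.tsv`, `gene_sizes.tsv`, `expansion.json`,
#' `microsat_loci.tsv`, `microsat_census.json`, `ltr_ages.tsv`,
#' `linkage.tsv` (when genotypes are given) and `manifest.json`. Any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config a [run_config()] (or path to a config file).
#' @return invisibly, a list with the in-memory results of every stage
#'   and the output paths.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    set.seed(config$seed)
    stage <- "read_inputs"
    region_a <- read_region(config$fasta_a, config$gff_a, config$species_a)
    region_b <- read_region(config$fasta_b, config$gff_b, config$species_b)

    stage <- "pair_homologs"
    pairs <- pair_homologs(region_a, region_b)
    coll <- collinearity_check(pairs)

    stage <- "composition"
    comp <- composition_table(pairs, scoring = config$scoring)
    comp_out <- comp
    comp_out$gc_exon <- fmt_pct(comp_out$gc_exon)
    comp_out$gc3_exon <- fmt_pct(comp_out$gc3_exon)
    comp_out$gc_gene <- fmt_pct(comp_out$gc_gene)
    written <- c(written, write_tsv(comp_out,
                                    file.path(out_dir, "composition.tsv")))
    spl <- split(comp, comp$species)
    t_gc <- student_t_two_sample(spl[[config$species_a]]$gc_exon,
                                 spl[[config$species_b]]$gc_exon,
                                 config$t_variant)
    t_gc3 <- student_t_two_sample(spl[[config$species_a]]$gc3_exon,
                                  spl[[config$species_b]]$gc3_exon,
                                  config$t_variant)

    stage <- "gene_sizes"
    sizes <- gene_length_table(pairs)
    size_tests <- compare_gene_sizes(sizes, config$t_variant)
    sizes_out <- sizes
    sizes_out$intron_ratio_b_a <- fmt_ratio(sizes_out$intron_ratio_b_a)
    written <- c(written, write_tsv(sizes_out,
                                    file.path(out_dir, "gene_sizes.tsv")))

    stage <- "intergenic_expansion"
    expansion <- intergenic_expansion(region_a, region_b, pairs)
    exp_json <- c(unclass(expansion),
                  list(ratio_rounded = fmt_ratio(expansion$ratio),
                       percent_increase_rounded =
                         round(expansion$percent_increase),
                       chi2_note = paste("2x2 genic/intergenic-by-region",
                                         "contingency chi-square, df = 1"),
                       collinear = coll$conserved,
                       t_gc = fmt_t(t_gc$t), p_gc = t_gc$p,
                       t_gc3 = fmt_t(t_gc3$t), p_gc3 = t_gc3$p,
                       t_exon = fmt_t(size_tests$t_exon$t),
                       p_exon = size_tests$t_exon$p,
                       t_intron = fmt_t(size_tests$t_intron$t),
                       p_intron = size_tests$t_intron$p))
    exp_path <- file.path(out_dir, "expansion.json")
    jsonlite::write_json(exp_json, exp_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, exp_path)

    stage <- "microsatellites"
    loci_a <- find_perfect_repeats(region_a$record$seq, config$min_unit,
                                   config$max_unit, config$min_repeats,
                                   config$mono_min_repeats)
    loci_b <- find_perfect_repeats(region_b$record$seq, config$min_unit,
                                   config$max_unit, config$min_repeats,
                                   config$mono_min_repeats)
    loci <- rbind(add_region_col(loci_a, config$species_a),
                  add_region_col(loci_b, config$species_b))
    written <- c(written, write_tsv(loci,
                                    file.path(out_dir,
                                              "microsat_loci.tsv")))
    census_a <- classify_and_count(loci_a)
    census_b <- classify_and_count(loci_b)
    t_density <- density_compare(census_a, census_b, config$t_variant)
    census_path <- file.path(out_dir, "microsat_census.json")
    jsonlite::write_json(
      list(species_a = unclass(census_a), species_b = unclass(census_b),
           long_mers_a = nrow(long_mer_filter(loci_a)),
           long_mers_b = nrow(long_mer_filter(loci_b)),
           t_density = fmt_t(t_density$t), p_density = t_density$p),
      census_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, census_path)

    stage <- "ltr_dating"
    ages <- rbind(add_region_col(batch_date(region_a, config$K,
                                            config$include_indels,
                                            config$scoring),
                                 config$species_a),
                  add_region_col(batch_date(region_b, config$K,
                                            config$include_indels,
                                            config$scoring),
                                 config$species_b))
    written <- c(written, write_tsv(ages,
                                    file.path(out_dir, "ltr_ages.tsv")))

    linkage <- NULL
    if (!is.null(config$genotypes)) {
      stage <- "linkage"
      seg <- read_genotypes(config$genotypes)
      anchor <- config$anchor %||% rownames(seg)[1]
      linkage <- cosegregation_report(seg, anchor)
      link_out <- linkage
      link_out$d_kosambi <- fmt_cm(link_out$d_kosambi)
      link_out$d_haldane <- fmt_cm(link_out$d_haldane)
      written <- c(written, write_tsv(link_out,
                                      file.path(out_dir, "linkage.tsv")))
    }

    stage <- "manifest"
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(package = "parcomp",
           version = as.character(utils::packageVersion("parcomp")),
           seed = config$seed,
           config = config[setdiff(names(config), "scoring")],
           scoring = unclass(config$scoring)),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)

    invisible(list(region_a = region_a, region_b = region_b, pairs = pairs,
                   collinearity = coll, composition = comp,
                   t_gc = t_gc, t_gc3 = t_gc3, gene_sizes = sizes,
                   size_tests = size_tests, expansion = expansion,
                   microsat = list(loci = loci, census_a = census_a,
                                   census_b = census_b,
                                   t_density = t_density),
                   ltr_ages = ages, linkage = linkage, files = written))
  }, error = on_fail)
}

#' Write a synthetic dataset to disk
#'
#' Generates a homologous region pair and a segregation matrix from a
#' [synthetic_region_spec()] and writes FASTA + GFF3 per species, a
#' genotype TSV and the generator ledger as JSON — a dataset
#' [run_compare()] can consume directly.
#'
#' @param spec a [synthetic_region_spec()].
#' @param dir output directory.
#' @param markers,r_to_anchor,n_individuals,missing_rate segregation
#'   parameters (see [generate_segregation()]); the first marker is the
#'   anchor.
#' @return invisibly, a list with the generated objects and a
#'   ready-to-use [run_config()].
#' @export
simulate_dataset <- function(spec, dir,
                             markers = c("ScOPA09", "ESP1", "PAR2",
                                         "ACBP1", "PAB"),
                             r_to_anchor = c(0, 0, 0, 0.11),
                             n_individuals = 76L, missing_rate = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair <- generate_homolog_pair(spec)
  seg <- generate_segregation(markers, r_to_anchor, n_individuals,
                              missing_rate)
  paths <- list(
    fasta_a = file.path(dir, paste0(spec$species[1], ".fasta")),
    gff_a = file.path(dir, paste0(spec$species[1], ".gff3")),
    fasta_b = file.path(dir, paste0(spec$species[2], ".fasta")),
    gff_b = file.path(dir, paste0(spec$species[2], ".gff3")),
    genotypes = file.path(dir, "genotypes.tsv"),
    ledger = file.path(dir, "ledger.json"))
  write_fasta(list(pair$region_a$record), paths$fasta_a)
  write_fasta(list(pair$region_b$record), paths$fasta_b)
  write_gff3(pair$region_a, paths$gff_a)
  write_gff3(pair$region_b, paths$gff_b)
  write_genotypes(seg$seg, paths$genotypes)
  jsonlite::write_json(list(region = pair$ledger,
                            segregation = seg$ledger),
                       paths$ledger, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # present the expanded, PAR-like region (generator species B) first,
  # the convention for a focal-region-versus-autosome comparison
  config <- run_config(fasta_a = paths$fasta_b, gff_a = paths$gff_b,
                       fasta_b = paths$fasta_a, gff_b = paths$gff_a,
                       species_a = spec$species[2],
                       species_b = spec$species[1],
                       genotypes = paths$genotypes, anchor = markers[1],
                       out_dir = file.path(dir, "report"),
                       K = spec$K, seed = spec$seed)
  invisible(list(pair = pair, seg = seg, paths = paths, config = config))
}
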