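#' Scenario configuration for the synthetic germinal-center generator
#'
#' Bundles everything the generator needs: template parameters, a gating tree
#' with pre-enrichment fractions, per-leaf true stop frequencies, sorting
#' enrichment factors, and the sequencing settings. Three presets mirror the
#' magnitudes measured in index-sorted germinal centers: `"wildtype"`
#' (DZ 4.6% / LZ 1.3% zone truths, BCR-low leaves enriched 10x),
#' `"wildtype-dz-split"` (a single DZ with BCR-high 2.2% / BCR-low 17.2%),
#' and `"bcl2"` (apoptosis-inhibited setting, DZ 11.6% / LZ 0.8%). Presets
#' are generator calibrations, not reproductions of any measured dataset.
#'
#' @param scenario Preset name.
#' @param total_cells Population size across all gates (default 20000).
#' @param seq_budget Cells sequenced per budget node (zone), default 500.
#' @param reads_per_cell_mean,reads_per_cell_size Negative-binomial
#'   reads-per-cell distribution for NGS emission (defaults 50, 5).
#' @param error_rate Per-base sequencing error rate for NGS reads
#'   (default 1e-3).
#' @param contaminants_per_sample Unique contaminant sequences injected per
#'   NGS sample (default 2).
#' @param contaminant_cells_worth Contaminant abundance in units of one
#'   cell's expected reads (default 0.3, below the strict (100/n)% filter).
#' @param divisions Maximum completed divisions for the snapshot division
#'   distribution assigned to cells (default 2).
#' @param template_codons,cdr_fraction Template parameters (defaults 131 codons,
#'   15% CDR).
#' @param generation One of `"prescribed"` (plant stops at the configured
#'   per-leaf truths) or `"mechanistic"` (run the SHM simulator per gate and
#'   let truth emerge).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("wildtype", "bcl2", "wildtype-dz-split"),
                            total_cells = 20000, seq_budget = 500,
                            reads_per_cell_mean = 50, reads_per_cell_size = 5,
                            error_rate = 1e-3, contaminants_per_sample = 2,
                            contaminant_cells_worth = 0.3, divisions = 2,
                            template_codons = 131, cdr_fraction = 0.15,
                            generation = c("prescribed", "mechanistic")) {
  scenario <- match.arg(scenario)
  generation <- match.arg(generation)
  preset <- switch(scenario,
    wildtype = list(
      tree = gating_tree(data.frame(
        name = c("GC", "DZ", "LZ", "BCRhigh_DZ", "BCRlow_DZ",
                 "BCRhigh_LZ", "BCRlow_LZ"),
        parent = c(NA, "GC", "GC", "DZ", "DZ", "LZ", "LZ"),
        fraction_of_parent = c(1, 0.5, 0.5, 0.84, 0.16, 0.84, 0.16))),
      leaf_truth = c(BCRhigh_DZ = 2.2, BCRlow_DZ = 17.2,
                     BCRhigh_LZ = 1.0, BCRlow_LZ = 2.875),
      enrichment = c(BCRhigh_DZ = 1, BCRlow_DZ = 10,
                     BCRhigh_LZ = 1, BCRlow_LZ = 10),
      budget_nodes = c("DZ", "LZ")),
    `wildtype-dz-split` = list(
      tree = gating_tree(data.frame(
        name = c("DZ", "BCRhigh_DZ", "BCRlow_DZ"),
        parent = c(NA, "DZ", "DZ"),
        fraction_of_parent = c(1, 0.84, 0.16))),
      leaf_truth = c(BCRhigh_DZ = 2.2, BCRlow_DZ = 17.2),
      enrichment = c(BCRhigh_DZ = 1, BCRlow_DZ = 10),
      budget_nodes = "DZ"),
    bcl2 = list(
      tree = gating_tree(data.frame(
        name = c("GC", "DZ", "LZ", "BCRhigh_DZ", "BCRlow_DZ"),
        parent = c(NA, "GC", "GC", "DZ", "DZ"),
        fraction_of_parent = c(1, 0.5, 0.5, 0.8, 0.2))),
      leaf_truth = c(BCRhigh_DZ = 8.25, BCRlow_DZ = 25.0, LZ = 0.8),
      enrichment = c(BCRhigh_DZ = 1, BCRlow_DZ = 10, LZ = 1),
      budget_nodes = c("DZ", "LZ")))
  structure(c(preset, list(
    scenario = scenario, total_cells = total_cells, seq_budget = seq_budget,
    reads_per_cell_mean = reads_per_cell_mean,
    reads_per_cell_size = reads_per_cell_size, error_rate = error_rate,
    contaminants_per_sample = contaminants_per_sample,
    contaminant_cells_worth = contaminant_cells_worth, divisions = divisions,
    template_codons = template_codons, cdr_fraction = cdr_fraction,
    generation = generation)), class = "scenario_config")
}

#' Generate a random in-frame V-gene template
#'
#' Draws codons uniformly from the 61 non-stop codons (so the frame-0
#' translation never contains a stop) and places CDR blocks covering about
#' `cdr_fraction` of codons at canonical relative positions. A synthetic
#' stand-in for an unpublished V-gene sequence.
#'
#' @param n_codons Number of codons (>= 10; default 131, i.e. 393 nt).
#' @param cdr_fraction Fraction of codons inside CDRs (default 0.15).
#' @param n_cdrs Number of CDR blocks (default 3).
#' @param id Template id.
#' @return A [v_gene_template()].
#' @export
generate_template <- function(n_codons = 131, cdr_fraction = 0.15, n_cdrs = 3,
                              id = "synthetic_vgene") {
  stopifnot(n_codons >= 10, cdr_fraction >= 0, cdr_fraction <= 0.5)
  seq <- paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
  cdrs <- empty_intervals()
  if (cdr_fraction > 0) {
    block <- max(1L, round(cdr_fraction * n_codons / n_cdrs))
    centers <- round(n_codons * seq(0.25, 0.8, length.out = n_cdrs))
    starts <- pmax(0L, pmin(n_codons - block, centers - block %/% 2L))
    cdrs <- data.frame(start = starts * 3L, end = (starts + block) * 3L)
    cdrs <- cdrs[!duplicated(cdrs$start), , drop = FALSE]
  }
  v_gene_template(seq, cdrs, id = id)
}

# all (pos0, alt) substitutions of `seq` that create an in-frame stop codon,
# excluding the final codon
stop_substitutions <- function(seq) {
  counts <- position_stop_counts(seq)
  n <- nchar(seq)
  out <- list()
  for (p in which(counts > 0)) {
    if (p > n - 3L) next  # final codon: stops there are not premature
    cstart <- ((p - 1L) %/% 3L) * 3L + 1L
    codon <- substr(seq, cstart, cstart + 2L)
    off <- p - cstart + 1L
    for (b in setdiff(DNA_BASES, substr(seq, p, p))) {
      v <- codon
      substr(v, off, off) <- b
      if (v %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- c(pos = p, alt = b)
      }
    }
  }
  data.frame(pos = as.integer(vapply(out, `[`, character(1), "pos")),
             alt = vapply(out, `[`, character(1), "alt"),
             stringsAsFactors = FALSE)
}

# apply `n_mut` random substitutions to a character-vector sequence; when
# avoid_stop, substitutions whose resulting codon would be a stop are
# rejected (retried); positions in `frozen` are never touched
background_mutations <- function(bases, n_mut, avoid_stop = TRUE,
                                 frozen = integer(0)) {
  len <- length(bases)
  for (m in seq_len(n_mut)) {
    for (try in 1:50) {
      p <- sample.int(len, 1L)
      if (p %in% frozen) next
      b <- sample(setdiff(DNA_BASES, bases[p]), 1L)
      if (avoid_stop) {
        cstart <- ((p - 1L) %/% 3L) * 3L + 1L
        if (cstart + 2L <= len) {
          codon <- bases[cstart:(cstart + 2L)]
          codon[p - cstart + 1L] <- b
          if (paste(codon, collapse = "") %in% STOP_CODONS) next
        }
      }
      bases[p] <- b
      break
    }
  }
  bases
}

#' Generate the per-gate cell population
#'
#' In `"prescribed"` mode each cell's stop status is Bernoulli(leaf truth);
#' stop-positive cells receive either one stop-creating substitution (80%)
#' or a 1-2 nt frameshifting deletion (20%), on top of stop-free background
#' mutations (per-division linear SHM), so every cell's sequence matches its
#' recorded truth exactly. In `"mechanistic"` mode sequences come from
#' [simulate_cohort()] and truth is whatever emerges.
#'
#' @param config A [scenario_config()].
#' @param template A [v_gene_template()].
#' @return List of class `gc_population`: `cells` data frame (`cell_id`,
#'   `gate`, `divisions`, `seq`, `premature_stop`, `frameshift`) and
#'   `gates` data frame (`gate`, `abs_fraction`, `truth_percent`,
#'   `n_cells`).
#' @export
generate_population <- function(config, template) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- config$tree
  root <- tree$name[is.na(tree$parent)]
  lw <- leaf_weights(tree, root)
  leaves <- lw$leaf
  if (!all(leaves %in% names(config$leaf_truth))) {
    stop("leaf truths missing for: ",
         paste(setdiff(leaves, names(config$leaf_truth)), collapse = ", "),
         call. = FALSE)
  }
  dist <- snapshot_division_distribution(config$divisions)
  p_m <- per_division_mutation_probability(template$length, 1e-3)
  subs <- stop_substitutions(template$seq)
  tpl_bases <- strsplit(template$seq, "")[[1]]
  all_cells <- vector("list", length(leaves))
  for (g in seq_along(leaves)) {
    gate <- leaves[g]
    n_g <- round(config$total_cells * lw$weight[g])
    truth <- config$leaf_truth[[gate]] / 100
    if (config$generation == "mechanistic") {
      cohort <- simulate_cohort(template, NULL, mutation_rates(),
                                divisions = dist, n_cells = n_g)
      cells <- cohort$cells
      all_cells[[g]] <- data.frame(
        cell_id = sprintf("%s_%s", gate, cells$cell_id), gate = gate,
        divisions = cells$divisions_completed, seq = cells$seq,
        premature_stop = cells$premature_stop,
        frameshift = cells$has_frameshift, stringsAsFactors = FALSE)
      next
    }
    divs <- sample(as.integer(names(dist)), n_g, replace = TRUE,
                   prob = as.numeric(dist))
    is_stop <- runif(n_g) < truth
    use_fs <- is_stop & runif(n_g) < 0.2
    seqs <- character(n_g)
    for (i in seq_len(n_g)) {
      bases <- tpl_bases
      frozen <- integer(0)
      if (is_stop[i] && !use_fs[i]) {
        row <- subs[sample.int(nrow(subs), 1L), ]
        bases[row$pos] <- row$alt
        cstart <- ((row$pos - 1L) %/% 3L) * 3L + 1L
        frozen <- cstart:(cstart + 2L)
      }
      n_bg <- rbinom(1L, divs[i], min(1, p_m))
      bases <- background_mutations(bases, n_bg, avoid_stop = TRUE,
                                    frozen = frozen)
      if (is_stop[i] && use_fs[i]) {
        dlen <- sample(1:2, 1L)
        start <- sample.int(length(bases) - dlen - 3L, 1L)
        bases <- bases[-(start:(start + dlen - 1L))]
      }
      seqs[i] <- paste(bases, collapse = "")
    }
    all_cells[[g]] <- data.frame(
      cell_id = sprintf("%s_c%05d", gate, seq_len(n_g)), gate = gate,
      divisions = divs, seq = seqs, premature_stop = is_stop,
      frameshift = use_fs, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, all_cells)
  gates <- data.frame(
    gate = leaves, abs_fraction = lw$weight,
    truth_percent = unname(config$leaf_truth[leaves]),
    n_cells = vapply(leaves, function(g) sum(cells$gate == g), integer(1)),
    row.names = NULL)
  structure(list(cells = cells, gates = gates, tree = tree),
            class = "gc_population")
}

#' Emit synthetic sequencing data for a population
#'
#' Draws cells for sequencing per budget node (zone) with the configured
#' enrichment factors (a 10x-enriched rare gate is oversampled tenfold
#' relative to its pre-enrichment fraction while the gating tree keeps the
#' true fraction), then emits per-gate Sanger samples, per-gate NGS samples
#' with negative-binomial reads per cell, per-base errors and sub-threshold
#' contaminant sequences, an index table with gate-conditional Gaussian
#' channels, and a sample manifest. When `out_dir` is given, everything is
#' also written to disk (FASTA/FASTQ/CSV/YAML/JSON).
#'
#' @param population A [generate_population()] result.
#' @param config The [scenario_config()].
#' @param out_dir Optional output directory.
#' @return List of class `gc_sequencing`: `sanger` and `ngs` (named lists of
#'   [sample_reads()]), `index` (data frame), `manifest`, `sampled`
#'   (per-gate sequencing counts incl. enrichment factors), `contaminants`.
#' @export
emit_sequencing <- function(population, config, out_dir = NULL) {
  tree <- population$tree
  gates <- population$gates
  cells <- population$cells
  enrich <- config$enrichment
  sampled_rows <- list(); sanger <- list(); ngs <- list()
  index <- list(); manifest <- list(); contam_rows <- list()
  for (node in config$budget_nodes) {
    lw <- leaf_weights(tree, node)
    # renormalize fractions within the budget node, apply enrichment
    w <- lw$weight / sum(lw$weight) * enrich[lw$leaf]
    n_seq <- round(config$seq_budget * w / sum(w))
    for (j in seq_along(lw$leaf)) {
      gate <- lw$leaf[j]
      pool <- cells[cells$gate == gate, , drop = FALSE]
      n_take <- min(n_seq[j], nrow(pool))
      take <- pool[sample.int(nrow(pool), n_take), , drop = FALSE]
      sampled_rows[[gate]] <- data.frame(
        gate = gate, zone = node, n_sequenced = n_take,
        enrichment = unname(enrich[gate]),
        pre_enrichment_fraction = lw$weight[j] / sum(lw$weight))
      sanger[[gate]] <- sample_reads(
        paste0("sanger_", gate),
        data.frame(read_id = take$cell_id, seq = take$seq,
                   stringsAsFactors = FALSE),
        n_cells_sorted = n_take, mode = "sanger")
      gi <- which(gates$gate == gate)
      index[[gate]] <- data.frame(
        cell_id = take$cell_id, gate = gate, zone = node,
        ch1 = rnorm(n_take, 1000 * gi, 100),
        ch2 = rnorm(n_take, 4000 - 700 * gi, 100), stringsAsFactors = FALSE)
      ng <- emit_ngs_sample(take, gate, config)
      ngs[[gate]] <- ng$sample
      contam_rows[[gate]] <- ng$contaminants
      manifest[[gate]] <- data.frame(
        sample_id = c(paste0("sanger_", gate), paste0("ngs_", gate)),
        file = c(file.path("sanger", paste0(gate, ".fasta")),
                 file.path("ngs", paste0(gate, ".fastq"))),
        n_cells_sorted = n_take, mode = c("sanger", "ngs"), gate = gate,
        stringsAsFactors = FALSE)
    }
  }
  out <- structure(list(
    sanger = sanger, ngs = ngs,
    index = do.call(rbind, c(index, list(make.row.names = FALSE))),
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    sampled = do.call(rbind, c(sampled_rows, list(make.row.names = FALSE))),
    contaminants = do.call(rbind, c(contam_rows, list(make.row.names = FALSE)))),
    class = "gc_sequencing")
  if (!is.null(out_dir)) write_scenario_files(population, config, out, out_dir)
  out
}

# one NGS sample for the sequenced cells of a gate: negative-binomial reads
# per cell, per-base substitution errors, contaminants below (100/n)%
emit_ngs_sample <- function(take, gate, config) {
  n_cells <- nrow(take)
  reads <- list()
  n_reads <- rnbinom(n_cells, mu = config$reads_per_cell_mean,
                     size = config$reads_per_cell_size)
  if (any(n_reads == 0L)) {
    warning("reads-per-cell draw of 0 for ", sum(n_reads == 0L), " cell(s) in ",
            gate, "; those cells drop out of the NGS sample")
  }
  for (i in seq_len(n_cells)) {
    if (n_reads[i] == 0L) next
    reads[[i]] <- rep(take$seq[i], n_reads[i])
  }
  reads <- unlist(reads)
  if (config$error_rate > 0 && length(reads)) {
    reads <- vapply(reads, add_read_errors, character(1),
                    error_rate = config$error_rate, USE.NAMES = FALSE)
  }
  mean_reads <- max(1, mean(n_reads))
  n_contam <- config$contaminants_per_sample
  contam <- character(0)
  contam_count <- integer(0)
  if (n_contam > 0) {
    contam_count <- rep(max(1L, round(config$contaminant_cells_worth * mean_reads)),
                        n_contam)
    contam <- vapply(seq_len(n_contam), function(k) {
      b <- strsplit(take$seq[sample.int(n_cells, 1L)], "")[[1]]
      paste(background_mutations(b, 5L, avoid_stop = FALSE), collapse = "")
    }, character(1))
    reads <- c(reads, rep(contam, contam_count))
  }
  reads <- reads[sample.int(length(reads))]  # shuffle read order
  sample <- sample_reads(
    paste0("ngs_", gate),
    data.frame(read_id = sprintf("%s_r%06d", gate, seq_along(reads)),
               seq = reads, stringsAsFactors = FALSE),
    n_cells_sorted = n_cells, mode = "ngs")
  contaminants <- if (n_contam > 0) {
    data.frame(gate = gate, seq = contam, read_count = contam_count,
               read_fraction = contam_count / length(reads),
               stringsAsFactors = FALSE)
  } else NULL
  list(sample = sample, contaminants = contaminants)
}

add_read_errors <- function(seq, error_rate) {
  n_err <- rbinom(1L, nchar(seq), error_rate)
  if (n_err == 0L) return(seq)
  bases <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(bases), n_err)
  for (p in pos) bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
  paste(bases, collapse = "")
}

write_scenario_files <- function(population, config, sequencing, out_dir,
                                 template = attr(population, "template")) {
  dir.create(file.path(out_dir, "sanger"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "ngs"), recursive = TRUE, showWarnings = FALSE)
  for (gate in names(sequencing$sanger)) {
    s <- sequencing$sanger[[gate]]
    writeLines(paste0(">", s$reads$read_id, "\n", s$reads$seq),
               file.path(out_dir, "sanger", paste0(gate, ".fasta")))
    n <- sequencing$ngs[[gate]]
    writeLines(paste0("@", n$reads$read_id, "\n", n$reads$seq, "\n+\n",
                      strrep("I", nchar(n$reads$seq))),
               file.path(out_dir, "ngs", paste0(gate, ".fastq")))
  }
  write.csv(sequencing$index, file.path(out_dir, "index.csv"), row.names = FALSE)
  write.csv(sequencing$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  write.table(population$cells, file.path(out_dir, "cells_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gating_tree(population$tree, file.path(out_dir, "tree.yaml"))
  truth <- list(scenario = config$scenario,
                gates = population$gates,
                sampled = sequencing$sampled,
                zone_truths = zone_truths(config))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' True stop frequencies of the budget nodes implied by the leaf truths
#'
#' @param config A [scenario_config()].
#' @return Named numeric vector of percentages, one per budget node.
#' @export
zone_truths <- function(config) {
  vapply(config$budget_nodes, function(node) {
    lw <- leaf_weights(config$tree, node)
    w <- lw$weight / sum(lw$weight)
    sum(w * config$leaf_truth[lw$leaf])
  }, numeric(1))
}

#' Generate a complete synthetic scenario
#'
#' One call that seeds the RNG, generates the template, the population and
#' the sequencing emission. Fully deterministic per seed.
#'
#' @param scenario Preset name or a ready-made [scenario_config()].
#' @param seed RNG seed.
#' @param out_dir Optional directory to write all files to.
#' @param ... Overrides passed to [scenario_config()] when `scenario` is a
#'   name.
#' @return List of class `gc_scenario`: `config`, `template`, `population`,
#'   `sequencing`, `seed`.
#' @export
generate_scenario <- function(scenario = "wildtype", seed = 1, out_dir = NULL,
                              ...) {
  config <- if (inherits(scenario, "scenario_config")) scenario
            else scenario_config(scenario, ...)
  set.seed(seed)
  template <- generate_template(config$template_codons, config$cdr_fraction)
  population <- generate_population(config, template)
  attr(population, "template") <- template
  sequencing <- emit_sequencing(population, config, out_dir = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(paste0(">", template$id, "\n", template$seq),
               file.path(out_dir, "template.fasta"))
    write_bed_intervals(template$cdr_intervals,
                        file.path(out_dir, "cdrs.bed"), chrom = template$id)
    write_scenario_files(population, config, sequencing, out_dir)
  }
  structure(list(config = config, template = template,
                 population = population, sequencing = sequencing,
                 seed = seed),
            class = "gc_scenario")
}
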