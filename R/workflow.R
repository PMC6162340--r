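#' Run the analytic expectation workflow
#'
#' Chains template annotation (when a template is supplied) and the analytic
#' risk model, reporting every intermediate in both rounding modes. Either
#' `q` or `template` must be provided.
#'
#' @param q Per-mutation stop probability; computed from `template` when
#'   `NULL`.
#' @param template Optional [v_gene_template()].
#' @param motif_patterns IUPAC hotspot patterns used when annotating.
#' @param weights Region weights, see [region_weights()].
#' @param L Gene length (defaults to the template's length when given).
#' @param mu Mutation rate per nt per division.
#' @param observations Deletion observations.
#' @param frameshift_fraction Fraction of indels causing frameshifts.
#' @param D Snapshot maximum divisions.
#' @return List of class `expectation_report`: `q`, `printed` and `full`
#'   chains (see [stop_expectation_chain()]).
#' @export
run_expectation_workflow <- function(q = NULL, template = NULL,
                                     motif_patterns = c("RGYW", "WRCY"),
                                     weights = region_weights(),
                                     L = NULL, mu = 1e-3,
                                     observations = deletion_observations(),
                                     frameshift_fraction = 2 / 3, D = 2) {
  if (is.null(q)) {
    if (is.null(template)) {
      stop("missing input: supply either q or a template to annotate",
           call. = FALSE)
    }
    part <- partition_regions(template,
                              find_hotspot_motifs(template, motif_patterns),
                              weights)
    q <- template_stop_probability(template, part)
  }
  if (is.null(L)) L <- if (!is.null(template)) template$length else 393
  args <- list(q = q, L = L, mu = mu, observations = observations,
               frameshift_fraction = frameshift_fraction, D = D)
  structure(list(
    q = q,
    printed = do.call(stop_expectation_chain, c(args, rounding = "printed")),
    full = do.call(stop_expectation_chain, c(args, rounding = "full"))),
    class = "expectation_report")
}

#' @export
print.expectation_report <- function(x, ...) {
  p <- x$printed
  cat(sprintf(
    "q = %.4f | p_m = %.3f -> p_point = %.3f | retain = %.3f -> p_del = %.3f -> p_fs = %.3f\n",
    x$q, p$p_m, p$p_point, p$retain_prob, p$p_del, p$p_fs))
  cat(sprintf("p_stop = %.3f -> expected DZ stop frequency = %.1f%% (printed mode; %.2f%% full precision)\n",
              p$p_stop, p$expected_percent, 100 * x$full$expected_frequency))
  invisible(x)
}

#' Run the sequencing analysis workflow on a synthetic scenario
#'
#' Full pipeline over an in-memory scenario or a scenario directory: Sanger
#' per-cell stop calling, join with the index table, per-gate tallies,
#' enrichment-corrected rollups at the budget nodes (plus the naive pooled
#' comparison), and NGS per-sample summaries. When `out_dir` is given,
#' summary tables and a reproducibility manifest (config hash, seed, stage
#' record counts) are written.
#'
#' @param scenario A `gc_scenario` from [generate_scenario()], or a path to
#'   a directory written by it.
#' @param out_dir Optional output directory.
#' @param ngs Also process the NGS samples (default TRUE; the Sanger branch
#'   is the one feeding the rollup).
#' @param params Alignment parameters.
#' @return List of class `analysis_result`: `per_cell`, `tallies`,
#'   `estimates` (per budget node: rollup + pooled), `ngs_summary`,
#'   `counts` (per-stage record accounting), `manifest`.
#' @export
run_analysis_workflow <- function(scenario, out_dir = NULL, ngs = TRUE,
                                  params = align_params()) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  template <- scenario$template
  seqg <- scenario$sequencing
  tree <- scenario$population$tree
  counts <- list()

  per_cell <- do.call(rbind, lapply(seqg$sanger, function(s) {
    sanger_call_cells(s, template, params)
  }))
  rownames(per_cell) <- NULL
  counts$sanger_cells_in <- nrow(per_cell)
  counts$sanger_cells_called <- sum(!is.na(per_cell$premature_stop))

  join <- join_index_data(seqg$index, per_cell)
  if (nrow(join$joined) == 0L) {
    stop("join stage produced no rows: index table and call table share no cell ids",
         call. = FALSE)
  }
  counts$joined_cells <- nrow(join$joined)
  tallies <- tally_gates(join$joined)
  counts$tallied_cells <- sum(tallies$n_sequenced)
  stopifnot(counts$joined_cells >= counts$tallied_cells)

  budget_nodes <- scenario$config$budget_nodes
  estimates <- do.call(rbind, lapply(budget_nodes, function(node) {
    est <- rollup_frequency(tree, node, tallies = tallies)
    data.frame(node = node,
               rollup_percent = est$frequency,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pooled_percent = pooled_frequency(tree, node, tallies = tallies),
               n_sequenced = est$n_effective,
               truth_percent = unname(zone_truths(scenario$config)[node]))
  }))

  ngs_summary <- NULL
  if (ngs && length(seqg$ngs)) {
    ngs_summary <- do.call(rbind, lapply(seqg$ngs, function(s) {
      res <- ngs_call_sample(s, template, params)
      data.frame(sample_id = res$sample_id,
                 n_cells_sorted = res$n_cells_sorted,
                 n_unique = nrow(res$sequences),
                 n_passing = sum(res$sequences$passes_threshold),
                 n_passing_reads = sum(res$sequences$read_count[
                   res$sequences$passes_threshold]),
                 stop_frequency_percent = res$stop_frequency_percent)
    }))
    rownames(ngs_summary) <- NULL
    counts$ngs_samples <- nrow(ngs_summary)
  }

  result <- structure(list(per_cell = per_cell, tallies = tallies,
                           estimates = estimates, ngs_summary = ngs_summary,
                           counts = counts),
                      class = "analysis_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(per_cell, file.path(out_dir, "per_cell_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(estimates, file.path(out_dir, "population_estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ngs_summary)) {
      write.table(ngs_summary, file.path(out_dir, "ngs_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cfg_path <- file.path(out_dir, "run_config.json")
    jsonlite::write_json(scenario$config, cfg_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE, dataframe = "rows")
    manifest <- list(
      package_version = as.character(utils::packageVersion("shmstop")),
      seed = scenario$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      counts = counts)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

# reload a scenario directory written by generate_scenario(out_dir=)
load_scenario <- function(dir) {
  needed <- c("template.fasta", "manifest.csv", "tree.yaml", "index.csv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing)) {
    stop("scenario directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  template <- read_template(file.path(dir, "template.fasta"),
                            cdr_bed = {
                              p <- file.path(dir, "cdrs.bed")
                              if (file.exists(p) && file.size(p) > 0) p else NULL
                            })
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  tree <- read_gating_tree(file.path(dir, "tree.yaml"))
  index <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  read_sample <- function(row) {
    sample_reads(row$sample_id, read_reads(file.path(dir, row$file)),
                 n_cells_sorted = row$n_cells_sorted, mode = row$mode)
  }
  sanger <- list(); ngs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (row$mode == "sanger") sanger[[row$gate]] <- read_sample(row)
    else ngs[[row$gate]] <- read_sample(row)
  }
  zones <- unique(truth$sampled$zone)
  config <- structure(list(tree = tree, budget_nodes = zones,
                           leaf_truth = setNames(truth$gates$truth_percent,
                                                 truth$gates$gate),
                           scenario = truth$scenario),
                      class = "scenario_config")
  structure(list(config = config, template = template,
                 population = list(tree = tree),
                 sequencing = list(sanger = sanger, ngs = ngs, index = index),
                 seed = NA_integer_),
            class = "gc_scenario")
}
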