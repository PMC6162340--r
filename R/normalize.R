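#' Gating tree with pre-enrichment fractions
#'
#' Represents the nested flow-cytometry gates used when sorting cells for
#' sequencing. Each non-root node carries its PRE-enrichment proportion of
#' its parent (from cytometry, never from sequenced-cell counts, so that
#' deliberate oversampling of rare gates can be corrected); leaves may carry
#' sequencing tallies (`n_sequenced`, `n_stop`).
#'
#' @param nodes Data frame with columns `name`, `parent` (`NA` for the
#'   root), `fraction_of_parent`, and optionally `n_sequenced`, `n_stop`
#'   for leaves.
#' @param covered_fraction Required sum of children fractions under each
#'   parent (default 1; set lower when the tree deliberately covers only
#'   part of a parent).
#' @return Object of class `gating_tree` (the validated data frame).
#' @export
gating_tree <- function(nodes, covered_fraction = 1) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("name", "parent", "fraction_of_parent") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1L) stop("tree must have exactly one root", call. = FALSE)
  non_root <- nodes$parent[!is.na(nodes$parent)]
  if (!all(non_root %in% nodes$name)) {
    stop("unknown parent(s): ",
         paste(setdiff(non_root, nodes$name), collapse = ", "), call. = FALSE)
  }
  for (p in unique(non_root)) {
    s <- sum(nodes$fraction_of_parent[!is.na(nodes$parent) & nodes$parent == p])
    if (abs(s - covered_fraction) > 1e-6) {
      stop("children of '", p, "' have fractions summing to ", s,
           " (expected ", covered_fraction, ")", call. = FALSE)
    }
  }
  if (!"n_sequenced" %in% names(nodes)) nodes$n_sequenced <- NA_integer_
  if (!"n_stop" %in% names(nodes)) nodes$n_stop <- NA_integer_
  bad <- !is.na(nodes$n_stop) & !is.na(nodes$n_sequenced) &
    nodes$n_stop > nodes$n_sequenced
  if (any(bad)) stop("n_stop exceeds n_sequenced at: ",
                     paste(nodes$name[bad], collapse = ", "), call. = FALSE)
  structure(nodes, class = c("gating_tree", "data.frame"))
}

tree_children <- function(tree, node) {
  tree$name[!is.na(tree$parent) & tree$parent == node]
}

tree_is_leaf <- function(tree, node) length(tree_children(tree, node)) == 0L

#' Stop-codon frequency of a leaf gate
#'
#' @param n_stop Number of sequenced cells carrying a premature stop.
#' @param n_sequenced Number of cells sequenced in the gate (> 0).
#' @return Percentage `100 * n_stop / n_sequenced`.
#' @export
leaf_frequency <- function(n_stop, n_sequenced) {
  stopifnot(n_stop >= 0)
  if (n_sequenced <= 0) stop("n_sequenced must be > 0", call. = FALSE)
  if (n_stop > n_sequenced) stop("n_stop exceeds n_sequenced", call. = FALSE)
  100 * n_stop / n_sequenced
}

#' Enrichment-corrected stop frequency of a population
#'
#' Rolls leaf frequencies up the gating tree by the PRE-enrichment gate
#' fractions: `frequency(node) = sum_children frequency(child) *
#' fraction_of_parent(child)`. This is the correction that undoes deliberate
#' oversampling of rare gates during sorting; it is associative, so rolling
#' up level by level equals a single flattened weighted sum over leaves.
#' Wilson 95% intervals are computed per leaf and propagated by the same
#' weights.
#'
#' @param tree A [gating_tree()] whose leaves carry tallies.
#' @param node Node name to estimate (default the root).
#' @param tallies Optional data frame (`gate`, `n_sequenced`, `n_stop`)
#'   overriding/supplying leaf tallies.
#' @param zero_policy What to do with leaves that have no sequenced cells:
#'   `"error"` (default) or `"renormalize"` (drop the leaf and rescale its
#'   siblings' fractions).
#' @return List of class `population_estimate`: `node`, `frequency`
#'   (percent), `ci_low`, `ci_high` (percent), `n_effective`, `leaves_used`.
#' @export
rollup_frequency <- function(tree, node = tree$name[is.na(tree$parent)],
                             tallies = NULL, zero_policy = c("error", "renormalize")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(tree, "gating_tree"))
  if (!node %in% tree$name) stop("unknown node: ", node, call. = FALSE)
  if (!is.null(tallies)) {
    m <- match(tree$name, tallies$gate)
    tree$n_sequenced <- ifelse(is.na(m), tree$n_sequenced, tallies$n_sequenced[m])
    tree$n_stop <- ifelse(is.na(m), tree$n_stop, tallies$n_stop[m])
  }
  lw <- leaf_weights(tree, node)
  miss <- lw$leaf[is.na(tree$n_sequenced[match(lw$leaf, tree$name)])]
  empty <- lw$leaf[!is.na(tree$n_sequenced[match(lw$leaf, tree$name)]) &
                     tree$n_sequenced[match(lw$leaf, tree$name)] == 0L]
  if (length(miss)) {
    stop("leaves below '", node, "' lack tallies: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(empty)) {
    if (zero_policy == "error") {
      stop("leaves with zero sequenced cells: ", paste(empty, collapse = ", "),
           "; use zero_policy = 'renormalize' to drop them", call. = FALSE)
    }
    lw <- lw[!lw$leaf %in% empty, , drop = FALSE]
    lw$weight <- lw$weight / sum(lw$weight)
  }
  idx <- match(lw$leaf, tree$name)
  n_seq <- tree$n_sequenced[idx]
  n_stop <- tree$n_stop[idx]
  freqs <- 100 * n_stop / n_seq
  cis <- t(vapply(seq_along(idx), function(i) wilson_ci(n_stop[i], n_seq[i]),
                  numeric(2)))
  structure(list(
    node = node,
    frequency = sum(lw$weight * freqs),
    ci_low = 100 * sum(lw$weight * cis[, 1]),
    ci_high = 100 * sum(lw$weight * cis[, 2]),
    n_effective = sum(n_seq),
    leaves_used = data.frame(leaf = lw$leaf, weight = lw$weight,
                             n_sequenced = n_seq, n_stop = n_stop,
                             frequency = freqs)
  ), class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f%% [%.2f, %.2f] from %d sequenced cells over %d leaves\n",
              x$node, x$frequency, x$ci_low, x$ci_high, x$n_effective,
              nrow(x$leaves_used)))
  invisible(x)
}

# flattened leaf weights below `node`: product of fraction_of_parent down
# each path (the node itself gets weight 1)
leaf_weights <- function(tree, node) {
  recurse <- function(n, w) {
    kids <- tree_children(tree, n)
    if (!length(kids)) {
      return(data.frame(leaf = n, weight = w, stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(kids, function(k) {
      recurse(k, w * tree$fraction_of_parent[tree$name == k])
    }))
  }
  recurse(node, 1)
}

# Wilson score interval (no continuity correction), via prop.test
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  as.numeric(suppressWarnings(
    prop.test(x, n, conf.level = conf, correct = FALSE)$conf.int))
}

#' Pooled (enrichment-naive) frequency over leaves
#'
#' The uncorrected estimate that simply pools sequenced cells across leaves;
#' biased whenever gates were differentially enriched during sorting.
#' Provided as the comparison baseline for [rollup_frequency()].
#'
#' @param tree A [gating_tree()] with leaf tallies.
#' @param node Node name.
#' @param tallies Optional tallies as in [rollup_frequency()].
#' @return Percentage.
#' @export
pooled_frequency <- function(tree, node = tree$name[is.na(tree$parent)],
                             tallies = NULL) {
  if (!is.null(tallies)) {
    m <- match(tree$name, tallies$gate)
    tree$n_sequenced <- ifelse(is.na(m), tree$n_sequenced, tallies$n_sequenced[m])
    tree$n_stop <- ifelse(is.na(m), tree$n_stop, tallies$n_stop[m])
  }
  lw <- leaf_weights(tree, node)
  idx <- match(lw$leaf, tree$name)
  leaf_frequency(sum(tree$n_stop[idx]), sum(tree$n_sequenced[idx]))
}

#' Join indexed FACS data with per-cell stop calls
#'
#' @param index_table Data frame with `cell_id`, gate label columns and any
#'   numeric channel columns.
#' @param call_table Per-cell call table (e.g. from [sanger_call_cells()])
#'   with `cell_id`.
#' @return List with `joined` (inner join) and `unmatched` (list of ids
#'   present in only one table).
#' @export
join_index_data <- function(index_table, call_table) {
  stopifnot("cell_id" %in% names(index_table), "cell_id" %in% names(call_table))
  if (anyDuplicated(index_table$cell_id)) {
    stop("duplicate cell_id in index table", call. = FALSE)
  }
  if (anyDuplicated(call_table$cell_id)) {
    stop("duplicate cell_id in call table", call. = FALSE)
  }
  joined <- merge(index_table, call_table, by = "cell_id", sort = TRUE)
  list(joined = joined,
       unmatched = list(
         index_only = setdiff(index_table$cell_id, call_table$cell_id),
         calls_only = setdiff(call_table$cell_id, index_table$cell_id)))
}

#' Per-gate tallies from a joined per-cell table
#'
#' @param joined Joined table from [join_index_data()] with a `gate` column
#'   and a logical `premature_stop` column.
#' @return Data frame `gate`, `n_sequenced`, `n_stop` (cells with `NA`
#'   calls, e.g. unalignable, are excluded from both counts).
#' @export
tally_gates <- function(joined) {
  ok <- joined[!is.na(joined$premature_stop), , drop = FALSE]
  agg <- aggregate(cbind(n_sequenced = rep(1L, nrow(ok)),
                         n_stop = as.integer(ok$premature_stop)),
                   by = list(gate = ok$gate), FUN = sum)
  agg
}

#' Read a gating tree from YAML or JSON
#'
#' The file holds a list of nodes with fields `name`, `parent` (omitted or
#' null for the root) and `fraction_of_parent`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [gating_tree()].
#' @export
read_gating_tree <- function(path) {
  nodes <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = FALSE)
  df <- do.call(rbind, lapply(nodes, function(n) {
    data.frame(name = n$name,
               parent = if (is.null(n$parent)) NA_character_ else n$parent,
               fraction_of_parent = if (is.null(n$fraction_of_parent)) 1
                                    else n$fraction_of_parent,
               stringsAsFactors = FALSE)
  }))
  gating_tree(df)
}

#' Write a gating tree to YAML
#' @param tree A [gating_tree()].
#' @param path Output path.
#' @export
write_gating_tree <- function(tree, path) {
  nodes <- lapply(seq_len(nrow(tree)), function(i) {
    n <- list(name = tree$name[i], fraction_of_parent = tree$fraction_of_parent[i])
    if (!is.na(tree$parent[i])) n$parent <- tree$parent[i]
    n
  })
  yaml::write_yaml(nodes, path)
  invisible(path)
}
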