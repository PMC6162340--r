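#' Mutation-rate bundle for the SHM simulator
#'
#' @param mu Point-mutation rate per nucleotide per division (default 1e-3).
#' @param p_del Per-division deletion probability (default 0.006, the value
#'   estimated from the published load/deletion correlation).
#' @param frameshift_fraction Fraction of deletion lengths that are not a
#'   multiple of 3 under the length distribution (informational; the
#'   simulator draws actual lengths).
#' @return List of class `mutation_rates`.
#' @export
mutation_rates <- function(mu = 1e-3, p_del = 0.006, frameshift_fraction = 2 / 3) {
  stopifnot(mu >= 0, p_del >= 0, p_del <= 1)
  structure(list(mu = mu, p_del = p_del,
                 frameshift_fraction = frameshift_fraction),
            class = "mutation_rates")
}

#' Deletion length distribution
#'
#' Default: uniform over 1, 2, 3 nt, so exactly 1/3 of deletions are
#' in-frame, matching the modelled 2/3 frameshift fraction.
#'
#' @param lengths Positive integer lengths.
#' @param probs Probabilities (normalized internally).
#' @return Data frame `length`, `prob`.
#' @export
deletion_length_dist <- function(lengths = 1:3, probs = rep(1 / 3, 3)) {
  stopifnot(length(lengths) == length(probs), all(lengths >= 1), all(probs >= 0))
  data.frame(length = as.integer(lengths), prob = probs / sum(probs))
}

# internal mutable cell state: bases (character vector) and 0-based template
# anchors tpos (deletions remove entries; substitutions keep anchors)
new_sim_state <- function(template) {
  list(bases = strsplit(template$seq, "")[[1]],
       tpos = 0:(template$length - 1L))
}

#' Apply one division of SHM to a sequence state
#'
#' Point mutations are drawn per division (`"bernoulli"`: at most one, with
#' probability `len * mu`, the linear treatment the analytic model uses;
#' `"poisson"`: count ~ Poisson(`len * mu`)), placed on positions with
#' probability proportional to the enrichment weight of their
#' template-projected location, substituting a uniform random alternative
#' base. Independently, with probability `p_del` one deletion occurs at a
#' uniform position with length drawn from `del_dist` (placed within the 3'
#' end). Substitutions are applied before the deletion within a division.
#'
#' @param state Internal state from a template (list with `bases`, `tpos`).
#' @param pos_weight Per-template-position weight vector (length L).
#' @param rates A [mutation_rates()].
#' @param mode `"bernoulli"` or `"poisson"`.
#' @param del_dist A [deletion_length_dist()].
#' @param division Division index recorded in the events.
#' @return List with updated `state` and an `events` data frame
#'   (`division`, `type`, `template_pos`, `cur_pos`, `detail`).
#' @export
mutate_one_division <- function(state, pos_weight, rates,
                                mode = c("bernoulli", "poisson"),
                                del_dist = deletion_length_dist(),
                                division = 1L) {
  mode <- match.arg(mode)
  step <- sim_step(state, pos_weight, rates, match.arg(mode), del_dist, division)
  events <- if (length(step$type)) {
    data.frame(division = step$division, type = step$type,
               template_pos = step$template_pos, cur_pos = step$cur_pos,
               detail = step$detail, stringsAsFactors = FALSE)
  } else NULL
  list(state = step$state, events = events)
}

# allocation-light division step shared by mutate_one_division and
# simulate_cohort; events returned as parallel vectors
sim_step <- function(state, pos_weight, rates, mode, del_dist, division) {
  len <- length(state$bases)
  if (len == 0L) stop("sequence fully deleted; cannot mutate", call. = FALSE)
  lambda <- len * rates$mu
  n_sub <- if (mode == "bernoulli") rbinom(1L, 1L, min(1, lambda)) else rpois(1L, lambda)
  type <- character(0); template_pos <- integer(0)
  cur_pos <- integer(0); detail <- character(0)
  for (s in seq_len(n_sub)) {
    w <- pos_weight[state$tpos + 1L]
    i <- sample.int(length(state$bases), 1L, prob = w)
    new <- sample(DNA_BASES[DNA_BASES != state$bases[i]], 1L)
    state$bases[i] <- new
    type <- c(type, "substitution"); template_pos <- c(template_pos, state$tpos[i])
    cur_pos <- c(cur_pos, i); detail <- c(detail, new)
  }
  if (runif(1L) < rates$p_del && length(state$bases) > 1L) {
    len_now <- length(state$bases)
    dlen <- sample(del_dist$length, 1L, prob = del_dist$prob)
    dlen <- min(dlen, len_now - 1L)
    # uniform start among placements that keep the deletion inside the gene,
    # so the drawn length (and its frame effect) is preserved at the 3' end
    start <- sample.int(len_now - dlen + 1L, 1L)
    type <- c(type, "deletion"); template_pos <- c(template_pos, state$tpos[start])
    cur_pos <- c(cur_pos, start); detail <- c(detail, as.character(dlen))
    keep <- -(start:(start + dlen - 1L))
    state$bases <- state$bases[keep]
    state$tpos <- state$tpos[keep]
  }
  list(state = state, division = rep(division, length(type)), type = type,
       template_pos = template_pos, cur_pos = cur_pos, detail = detail)
}

#' Simulate a cohort of dividing, hypermutating cells
#'
#' Each cell starts from the template, draws a number of completed divisions
#' (fixed integer or sampled from a `division_distribution`), and applies
#' [mutate_one_division()] that many times. Truth flags are derived from the
#' tracked state (template anchors and accumulated deletions), not from any
#' alignment, so they serve as an independent reference for the stop-calling
#' pipeline.
#'
#' @param template A [v_gene_template()].
#' @param partition Optional [partition_regions()]; `NULL` means uniform
#'   placement weights.
#' @param rates A [mutation_rates()].
#' @param divisions Integer (fixed divisions per cell) or a
#'   `division_distribution` to sample from.
#' @param n_cells Number of cells (> 0).
#' @param mode Per-division mutation-count mode, see [mutate_one_division()].
#' @param del_dist Deletion length distribution.
#' @return Object of class `sim_cohort`: list with `cells` (data frame:
#'   `cell_id`, `divisions_completed`, `seq`, `n_substitutions`,
#'   `n_deletions`, `has_stop_by_substitution`, `has_frameshift`,
#'   `premature_stop`) and `events` (replayable log).
#' @export
simulate_cohort <- function(template, partition = NULL, rates = mutation_rates(),
                            divisions = 2L, n_cells,
                            mode = c("bernoulli", "poisson"),
                            del_dist = deletion_length_dist()) {
  mode <- match.arg(mode)
  stopifnot(n_cells > 0)
  L <- template$length
  pos_weight <- if (is.null(partition)) rep(1, L) else attr(partition, "pos_weight")
  div_counts <- if (inherits(divisions, "division_distribution")) {
    sample(as.integer(names(divisions)), n_cells, replace = TRUE,
           prob = as.numeric(divisions))
  } else {
    rep(as.integer(divisions), n_cells)
  }
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  seqs <- character(n_cells)
  n_subs <- integer(n_cells); n_dels <- integer(n_cells)
  f_sub <- logical(n_cells); f_fs <- logical(n_cells); f_stop <- logical(n_cells)
  ev_cell <- list(); ev_div <- list(); ev_type <- list()
  ev_tpos <- list(); ev_cpos <- list(); ev_detail <- list()
  base_state <- new_sim_state(template)
  for (c_i in seq_len(n_cells)) {
    state <- base_state
    for (d in seq_len(div_counts[c_i])) {
      step <- sim_step(state, pos_weight, rates, mode, del_dist, division = d)
      state <- step$state
      if (length(step$type)) {
        k <- length(ev_cell) + 1L
        ev_cell[[k]] <- rep(cell_ids[c_i], length(step$type))
        ev_div[[k]] <- step$division; ev_type[[k]] <- step$type
        ev_tpos[[k]] <- step$template_pos; ev_cpos[[k]] <- step$cur_pos
        ev_detail[[k]] <- step$detail
        n_subs[c_i] <- n_subs[c_i] + sum(step$type == "substitution")
        n_dels[c_i] <- n_dels[c_i] + sum(step$type == "deletion")
      }
    }
    truth <- state_truth(state, L)
    seqs[c_i] <- paste(state$bases, collapse = "")
    f_sub[c_i] <- truth$has_stop_by_substitution
    f_fs[c_i] <- truth$has_frameshift
    f_stop[c_i] <- truth$premature_stop
  }
  cells <- data.frame(
    cell_id = cell_ids, divisions_completed = div_counts, seq = seqs,
    n_substitutions = n_subs, n_deletions = n_dels,
    has_stop_by_substitution = f_sub, has_frameshift = f_fs,
    premature_stop = f_stop, stringsAsFactors = FALSE)
  events <- data.frame(
    cell_id = unlist(ev_cell) %||% character(0),
    division = unlist(ev_div) %||% integer(0),
    type = unlist(ev_type) %||% character(0),
    template_pos = unlist(ev_tpos) %||% integer(0),
    cur_pos = unlist(ev_cpos) %||% integer(0),
    detail = unlist(ev_detail) %||% character(0), stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 events = events[, c("cell_id", "division", "type",
                                     "template_pos", "cur_pos", "detail")],
                 template_id = template$id, mode = mode),
            class = "sim_cohort")
}

# truth flags from tracked anchors: frameshift iff the net deleted length is
# not a multiple of 3; substitution stops counted only at codons fully
# upstream of the first frame break (when a net frameshift exists) and
# anchored strictly before the final template codon
state_truth <- function(state, L) {
  net <- L - length(state$bases)
  has_frameshift <- net %% 3L != 0L
  first_break <- Inf
  if (has_frameshift) {
    missing_before <- state$tpos - (seq_along(state$tpos) - 1L)
    frame_break_idx <- which(missing_before %% 3L != 0L)
    if (length(frame_break_idx)) first_break <- frame_break_idx[1]
  }
  has_sub_stop <- scan_stops(state$bases, state$tpos, first_break, L)
  list(has_stop_by_substitution = has_sub_stop,
       has_frameshift = has_frameshift,
       premature_stop = has_sub_stop || has_frameshift)
}

# shared stop rule: translate bases in frame 0; a stop codon counts iff its
# last base index is strictly below the first frame-break index and its
# first-base template anchor is strictly before the final template codon
scan_stops <- function(bases, tpos, first_break, L) {
  n_codon <- length(bases) %/% 3L
  if (n_codon == 0L) return(FALSE)
  i0 <- 3L * (seq_len(n_codon) - 1L) + 1L
  i0 <- i0[i0 + 2L < first_break]
  if (!length(i0)) return(FALSE)
  codons <- paste0(bases[i0], bases[i0 + 1L], bases[i0 + 2L])
  any(codons %in% STOP_CODONS & tpos[i0] < L - 3L)
}

#' Replay an event log on the template
#'
#' Applies a cell's recorded events in order to the template sequence;
#' the result must reproduce the simulated sequence exactly.
#'
#' @param template A [v_gene_template()].
#' @param events Event rows for one cell (from a `sim_cohort`).
#' @return The reconstructed nucleotide string.
#' @export
replay_events <- function(template, events) {
  bases <- strsplit(template$seq, "")[[1]]
  if (nrow(events)) {
    events <- events[order(events$division), , drop = FALSE]
    for (r in seq_len(nrow(events))) {
      if (events$type[r] == "substitution") {
        bases[events$cur_pos[r]] <- events$detail[r]
      } else {
        dlen <- as.integer(events$detail[r])
        start <- events$cur_pos[r]
        bases <- bases[-(start:(start + dlen - 1L))]
      }
    }
  }
  paste(bases, collapse = "")
}

#' Classify a mutated sequence against its template
#'
#' Alignment-based truth-independent classification: aligns the sequence
#' globally to the template and reports whether it carries a premature stop
#' (net frameshift, or an in-frame stop codon upstream of the final template
#' codon), plus substitution and deletion counts from the alignment.
#'
#' @param template A [v_gene_template()].
#' @param seq Nucleotide string.
#' @return List with `premature_stop`, `frameshift`, `n_substitutions`,
#'   `n_deletions`.
#' @export
classify_against_template <- function(template, seq) {
  if (!nzchar(seq)) stop("sequence is empty", call. = FALSE)
  if (seq == template$seq) {
    return(list(premature_stop = FALSE, frameshift = FALSE,
                n_substitutions = 0L, n_deletions = 0L))
  }
  aln <- align_to_template(seq, template)
  calls <- call_stops(aln, template)
  list(premature_stop = nrow(calls$calls) > 0L,
       frameshift = any(calls$calls$call_type == "frameshift"),
       n_substitutions = calls$n_substitutions,
       n_deletions = calls$n_deletion_runs)
}
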