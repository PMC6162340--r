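#' Alignment scoring parameters
#'
#' Defaults follow the classic EMBOSS-needle global alignment scheme:
#' match +5, mismatch -4, gap open 10, gap extend 0.5.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @param min_identity Identity floor below which a read is flagged
#'   unalignable (fraction, default 0.5).
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = 10,
                         gap_extend = 0.5, min_identity = 0.5) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_params")
}

# vectorized global alignment of many reads against one template; reads whose
# forward identity is below the floor are retried as reverse complements and
# the better orientation kept
align_reads <- function(seqs, template, params = align_params()) {
  stopifnot(all(nchar(seqs) > 0))
  mat <- Biostrings::nucleotideSubstitutionMatrix(params$match, params$mismatch,
                                                  baseOnly = TRUE)
  subject <- Biostrings::DNAString(template$seq)
  do_align <- function(x) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(x), subject,
                                  type = "global", substitutionMatrix = mat,
                                  gapOpening = params$gap_open,
                                  gapExtension = params$gap_extend)
  }
  fwd <- do_align(seqs)
  # as.character on pattern()/subject() equals alignedPattern()/-Subject()
  # for type = "global" and is orders of magnitude faster
  pattern <- as.character(Biostrings::pattern(fwd))
  subj <- as.character(Biostrings::subject(fwd))
  identity <- Biostrings::pid(fwd, type = "PID1") / 100
  score <- Biostrings::score(fwd)
  reoriented <- rep(FALSE, length(seqs))
  retry <- which(identity < params$min_identity)
  if (length(retry)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[retry])))
    rev <- do_align(rc)
    rid <- Biostrings::pid(rev, type = "PID1") / 100
    better <- rid > identity[retry]
    idx <- retry[better]
    if (length(idx)) {
      sel <- which(better)
      pattern[idx] <- as.character(Biostrings::pattern(rev))[sel]
      subj[idx] <- as.character(Biostrings::subject(rev))[sel]
      identity[idx] <- rid[sel]
      score[idx] <- Biostrings::score(rev)[sel]
      reoriented[idx] <- TRUE
    }
  }
  data.frame(pattern = pattern, subject = subj, score = score,
             identity = identity, reoriented = reoriented,
             aligned = identity >= params$min_identity,
             stringsAsFactors = FALSE)
}

#' Globally align a read to the template
#'
#' Needle-style global alignment with affine gaps. Reads that align better as
#' their reverse complement are auto-reoriented; reads whose identity stays
#' below the floor are flagged unalignable.
#'
#' @param read Nucleotide string.
#' @param template A [v_gene_template()].
#' @param params An [align_params()].
#' @return List with `pattern` (aligned read), `subject` (aligned template),
#'   `score`, `identity`, `reoriented` and `aligned`.
#' @export
align_to_template <- function(read, template, params = align_params()) {
  if (!nzchar(read)) stop("read is empty", call. = FALSE)
  row <- align_reads(read, template, params)
  as.list(row[1, ])
}

#' Call premature stop codons from an alignment
#'
#' The decision rule mirrors frame-aware translation of the read in the
#' template's forward frame:
#' * the net indel length is taken from the alignment's gap columns; if it is
#'   not a multiple of 3 a single `frameshift` call is made at the template
#'   codon of the first frame-breaking gap run;
#' * the read is translated codon-by-codon in the template-anchored frame
#'   (codon boundaries tracked through in-frame gaps); every stop codon that
#'   lies fully upstream of the first frame break and starts strictly before
#'   the template's final codon yields a `substitution_stop` call at its
#'   template codon index (1-based).
#'
#' @param alignment Result of [align_to_template()] (or one row of the
#'   internal vectorized aligner).
#' @param template A [v_gene_template()].
#' @return List with `calls` (data frame `codon_index`, `call_type`),
#'   `n_substitutions` (mismatch columns), `n_deletion_runs`, `net_indel`.
#' @export
call_stops <- function(alignment, template) {
  L <- template$length
  p <- strsplit(alignment$pattern, "")[[1]]
  s <- strsplit(alignment$subject, "")[[1]]
  stopifnot(length(p) == length(s))
  tpos_col <- cumsum(s != "-") - 1L          # template pos per column (-1 before start)
  status <- ifelse(p == "-", "del", ifelse(s == "-", "ins", "aln"))
  n_sub <- sum(status == "aln" & p != s)

  runs <- rle(status)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  gap_runs <- which(runs$values != "aln")
  n_del_runs <- sum(runs$values == "del")
  net_indel <- sum(s == "-") - sum(p == "-")
  first_break_patched <- Inf
  fs_codon <- NA_integer_
  # patched read index per column (read bases only)
  patched_idx <- cumsum(p != "-")
  if (net_indel %% 3L != 0L) {
    # a genuine net frameshift: locate the first gap run at which the
    # cumulative indel balance breaks frame (balanced gap pairs introduced
    # by the aligner across substitution clusters never reach this branch)
    net <- 0L
    for (g in gap_runs) {
      glen <- runs$lengths[g]
      net <- net + if (runs$values[g] == "ins") glen else -glen
      if (net %% 3L != 0L) {
        col0 <- run_start[g]
        if (runs$values[g] == "del") {
          # first read base after the deletion is the first out-of-frame base
          first_break_patched <- patched_idx[run_end[g]] + 1L
        } else {
          first_break_patched <- patched_idx[col0]
        }
        fs_codon <- max(tpos_col[col0], 0L) %/% 3L + 1L
        break
      }
    }
    if (is.na(fs_codon)) {  # fall back to the first gap run
      col0 <- run_start[gap_runs[1]]
      first_break_patched <- patched_idx[col0]
      fs_codon <- max(tpos_col[col0], 0L) %/% 3L + 1L
    }
  }

  # patched read with template anchors: read bases in order; matched columns
  # anchor at their template position, inserted bases at the preceding one
  keep <- p != "-"
  anchors <- pmax(tpos_col, 0L)[keep]
  bases <- p[keep]
  stops <- scan_stop_positions(bases, anchors, first_break_patched, L)

  calls <- data.frame(codon_index = integer(0), call_type = character(0),
                      stringsAsFactors = FALSE)
  if (!is.na(fs_codon)) {
    calls <- rbind(calls, data.frame(codon_index = fs_codon,
                                     call_type = "frameshift"))
  }
  if (length(stops)) {
    calls <- rbind(calls, data.frame(codon_index = stops,
                                     call_type = "substitution_stop"))
  }
  list(calls = calls, n_substitutions = n_sub,
       n_deletion_runs = n_del_runs, net_indel = net_indel)
}

# template codon indices (1-based) of stop codons in the frame-0 translation,
# restricted to codons fully upstream of the first frame break and starting
# strictly before the final template codon
scan_stop_positions <- function(bases, anchors, first_break, L) {
  n_codon <- length(bases) %/% 3L
  out <- integer(0)
  for (j in seq_len(n_codon)) {
    i0 <- 3L * (j - 1L) + 1L
    if (i0 + 2L >= first_break) break
    codon <- paste(bases[i0:(i0 + 2L)], collapse = "")
    if (codon %in% STOP_CODONS && anchors[i0] < L - 3L) {
      out <- c(out, anchors[i0] %/% 3L + 1L)
    }
  }
  out
}

#' Bundle reads for one sorted sample
#'
#' @param sample_id Sample name.
#' @param reads Data frame with columns `read_id`, `seq`.
#' @param n_cells_sorted Number of cells sorted into the sample (> 0).
#' @param mode `"sanger"` (one sequence per cell, no abundance filtering) or
#'   `"ngs"` (bulk amplicon reads, abundance-filtered).
#' @return List of class `sample_reads`.
#' @export
sample_reads <- function(sample_id, reads, n_cells_sorted,
                         mode = c("ngs", "sanger")) {
  mode <- match.arg(mode)
  stopifnot(n_cells_sorted > 0, nrow(reads) > 0,
            all(c("read_id", "seq") %in% names(reads)))
  if (mode == "sanger" && anyDuplicated(reads$read_id)) {
    stop("sanger mode requires exactly one sequence per cell id", call. = FALSE)
  }
  structure(list(sample_id = sample_id, reads = reads,
                 n_cells_sorted = as.integer(n_cells_sorted), mode = mode),
            class = "sample_reads")
}

#' Read FASTA/FASTQ into a reads data frame
#'
#' @param path File path; format inferred from extension (`.fastq`/`.fq` vs
#'   FASTA otherwise).
#' @return Data frame with `read_id`, `seq`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = as.character(set), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Collapse NGS reads to unique sequences
#'
#' @param sample A `sample_reads` in ngs mode.
#' @return Data frame with `seq_id`, `seq`, `read_count`, `read_fraction`
#'   (fractions sum to 1), ordered by decreasing count.
#' @export
collapse_reads <- function(sample) {
  stopifnot(inherits(sample, "sample_reads"))
  if (sample$mode != "ngs") stop("collapse_reads applies to ngs samples", call. = FALSE)
  if (nrow(sample$reads) == 0L) stop("sample has no reads", call. = FALSE)
  tab <- table(sample$reads$seq)
  tab <- sort(tab, decreasing = TRUE)
  data.frame(
    seq_id = sprintf("%s_u%04d", sample$sample_id, seq_along(tab)),
    seq = names(tab),
    read_count = as.integer(tab),
    read_fraction = as.integer(tab) / sum(tab),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the per-sample read-abundance threshold
#'
#' A sequence derived from one real cell among `n` sorted cells should make
#' up about (100/n)% of the sample's reads; sequences at or below that
#' fraction are treated as artifacts (PCR/sequencing errors, contaminants).
#' The comparison is strict: a sequence passes iff its read percentage is
#' strictly greater than `100 / n_cells_sorted`.
#'
#' @param collapsed Output of [collapse_reads()].
#' @param n_cells_sorted Number of cells sorted.
#' @return `collapsed` with a logical `passes_threshold` column.
#' @export
abundance_filter <- function(collapsed, n_cells_sorted) {
  stopifnot(n_cells_sorted > 0)
  collapsed$passes_threshold <-
    collapsed$read_fraction * 100 > 100 / n_cells_sorted
  collapsed
}

#' Per-sample stop-codon frequency from passing reads
#'
#' @param calls_table Per-sequence table with `read_count`,
#'   `passes_threshold` and `n_calls` columns.
#' @return Percentage: 100 x (reads of passing sequences with >= 1 call) /
#'   (all passing reads); `NA` with a warning when nothing passes.
#' @export
sample_stop_frequency <- function(calls_table) {
  pass <- calls_table[calls_table$passes_threshold &
                        !is.na(calls_table$n_calls), , drop = FALSE]
  total <- sum(pass$read_count)
  if (total == 0L) {
    warning("no reads pass the abundance threshold; frequency undefined")
    return(NA_real_)
  }
  100 * sum(pass$read_count[pass$n_calls > 0]) / total
}

#' Call stops across an NGS sample
#'
#' Collapses reads, applies the abundance threshold, aligns the passing
#' unique sequences to the template and calls stops. Sub-threshold sequences
#' are retained in the table (with `NA` calls) so filtering is auditable.
#'
#' @param sample A `sample_reads` in ngs mode.
#' @param template A [v_gene_template()].
#' @param params An [align_params()].
#' @return List with `sequences` (per-unique-sequence table: `seq_id`,
#'   `read_count`, `read_fraction`, `passes_threshold`, `aligned`,
#'   `n_calls`, `call_positions`, `call_types`, `premature_stop`,
#'   `frameshift`) and `stop_frequency_percent`.
#' @export
ngs_call_sample <- function(sample, template, params = align_params()) {
  collapsed <- abundance_filter(collapse_reads(sample), sample$n_cells_sorted)
  res <- call_seq_table(collapsed$seq, ifelse(collapsed$passes_threshold, TRUE, NA),
                        template, params)
  out <- cbind(collapsed, res)
  freq <- sample_stop_frequency(out)
  list(sequences = out, stop_frequency_percent = freq,
       sample_id = sample$sample_id, n_cells_sorted = sample$n_cells_sorted)
}

#' Call stops per cell in a Sanger sample
#'
#' One result row per sorted cell; no abundance filtering. Unalignable cells
#' are reported as missing (`NA` calls), never stop-positive.
#'
#' @param sample A `sample_reads` in sanger mode.
#' @param template A [v_gene_template()].
#' @param params An [align_params()].
#' @return Data frame with one row per cell: `cell_id`, `aligned`,
#'   `n_calls`, `call_positions`, `call_types`, `premature_stop`,
#'   `frameshift`.
#' @export
sanger_call_cells <- function(sample, template, params = align_params()) {
  stopifnot(inherits(sample, "sample_reads"))
  if (sample$mode != "sanger") stop("sanger_call_cells applies to sanger samples",
                                    call. = FALSE)
  res <- call_seq_table(sample$reads$seq, rep(TRUE, nrow(sample$reads)),
                        template, params)
  cbind(data.frame(cell_id = sample$reads$read_id, stringsAsFactors = FALSE), res)
}

# align + call a vector of sequences; `wanted` TRUE = call, NA = skip (kept as
# NA rows). Template-identical sequences short-circuit the aligner.
call_seq_table <- function(seqs, wanted, template, params) {
  n <- length(seqs)
  out <- data.frame(aligned = rep(NA, n), n_calls = rep(NA_integer_, n),
                    call_positions = rep(NA_character_, n),
                    call_types = rep(NA_character_, n),
                    premature_stop = rep(NA, n), frameshift = rep(NA, n))
  todo <- which(!is.na(wanted))
  if (!length(todo)) return(out)
  is_tpl <- seqs[todo] == template$seq
  out$aligned[todo[is_tpl]] <- TRUE
  out$n_calls[todo[is_tpl]] <- 0L
  out$premature_stop[todo[is_tpl]] <- FALSE
  out$frameshift[todo[is_tpl]] <- FALSE
  rest <- todo[!is_tpl]
  if (!length(rest)) return(out)
  alns <- align_reads(seqs[rest], template, params)
  for (i in seq_along(rest)) {
    r <- rest[i]
    out$aligned[r] <- alns$aligned[i]
    if (!alns$aligned[i]) {
      warning("sequence ", r, " unalignable (identity ",
              round(alns$identity[i], 2), "); excluded")
      next
    }
    cl <- call_stops(alns[i, ], template)
    out$n_calls[r] <- nrow(cl$calls)
    out$premature_stop[r] <- nrow(cl$calls) > 0L
    out$frameshift[r] <- any(cl$calls$call_type == "frameshift")
    if (nrow(cl$calls)) {
      out$call_positions[r] <- paste(cl$calls$codon_index, collapse = ";")
      out$call_types[r] <- paste(cl$calls$call_type, collapse = ";")
    }
  }
  out
}
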