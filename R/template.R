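#' @importFrom stats rbinom rpois runif rnorm rnbinom setNames aggregate prop.test
#' @importFrom utils read.table write.table head
NULL

#' Immunoglobulin V-gene template
#'
#' Construct the reference object used throughout the package: an in-frame
#' V-gene nucleotide sequence (reading frame fixed at offset 0) together with
#' its CDR annotations. The template anchors all frame and position logic:
#' codon indices, stop-risk enumeration, region weighting and alignment-based
#' stop calling are all expressed in its coordinates.
#'
#' @param seq Nucleotide string over A/C/G/T whose length is a multiple of 3
#'   and whose frame-0 translation contains no stop codon.
#' @param cdr_intervals Data frame with columns `start`, `end` giving CDR
#'   intervals in 0-based half-open nucleotide coordinates; must be within
#'   the sequence, sorted and non-overlapping. May be empty.
#' @param id Template identifier.
#' @return An object of class `v_gene_template` with elements `id`, `seq`,
#'   `length` and `cdr_intervals`.
#' @export
v_gene_template <- function(seq, cdr_intervals = empty_intervals(), id = "template") {
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGT]+$", seq)) {
    stop("template sequence must contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(seq)
  if (L %% 3L != 0L) {
    stop("template length must be a multiple of 3 (in-frame V gene), got ", L,
         call. = FALSE)
  }
  codons <- codon_split(seq)
  if (any(codons %in% STOP_CODONS)) {
    stop("template contains an internal stop codon at codon ",
         which(codons %in% STOP_CODONS)[1], call. = FALSE)
  }
  cdr_intervals <- validate_intervals(cdr_intervals, L, "cdr_intervals")
  structure(
    list(id = id, seq = seq, length = L, cdr_intervals = cdr_intervals),
    class = "v_gene_template"
  )
}

#' @export
print.v_gene_template <- function(x, ...) {
  cat("V-gene template '", x$id, "': ", x$length, " nt (", x$length / 3,
      " codons), ", nrow(x$cdr_intervals), " CDR interval(s)\n", sep = "")
  invisible(x)
}

#' Read a V-gene template from FASTA (+ optional BED CDRs)
#'
#' @param fasta Path to a single-record FASTA file.
#' @param cdr_bed Optional path to a BED-like file (>= 3 columns, 0-based
#'   half-open) with the CDR intervals.
#' @return A [v_gene_template()].
#' @export
read_template <- function(fasta, cdr_bed = NULL) {
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) != 1L) {
    stop("template FASTA must contain exactly one record, found ", length(set),
         call. = FALSE)
  }
  cdrs <- if (is.null(cdr_bed)) empty_intervals() else read_bed_intervals(cdr_bed)
  v_gene_template(as.character(set[[1]]), cdrs, id = names(set)[1])
}

#' Read intervals from a BED-like file
#'
#' Only the first three columns (chrom/name, start, end) are used; coordinates
#' are 0-based half-open as in BED.
#'
#' @param path File path.
#' @return Data frame with integer columns `start`, `end`.
#' @export
read_bed_intervals <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  iv <- data.frame(start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
  iv[order(iv$start), , drop = FALSE]
}

#' Write intervals as BED
#' @param intervals Data frame with `start`, `end` (0-based half-open).
#' @param path Output path.
#' @param chrom Value for the first BED column.
#' @export
write_bed_intervals <- function(intervals, path, chrom = "template") {
  df <- data.frame(chrom = chrom, start = intervals$start, end = intervals$end)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_intervals <- function() data.frame(start = integer(0), end = integer(0))

validate_intervals <- function(iv, L, what) {
  iv <- as.data.frame(iv)
  if (nrow(iv) == 0L) return(empty_intervals())
  iv <- data.frame(start = as.integer(iv$start), end = as.integer(iv$end))
  if (any(iv$start < 0L) || any(iv$end > L) || any(iv$start >= iv$end)) {
    stop(what, " must be non-empty intervals within [0, ", L, ")", call. = FALSE)
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
    stop(what, " must be non-overlapping", call. = FALSE)
  }
  rownames(iv) <- NULL
  iv
}

codon_split <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1L, L, by = 3L), seq(3L, L, by = 3L))
}

#' Locate AID hotspot motifs on a template
#'
#' Scans the forward strand for IUPAC degenerate patterns (classic AID
#' hotspots RGYW and WRCY by default) and returns the merged union of all
#' match footprints.
#'
#' @param template A [v_gene_template()].
#' @param motif_patterns Character vector of IUPAC patterns.
#' @return Data frame of merged, sorted intervals (`start`, `end`, 0-based
#'   half-open).
#' @export
find_hotspot_motifs <- function(template, motif_patterns = c("RGYW", "WRCY")) {
  ok <- grepl(sprintf("^[%s]+$", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")),
              toupper(motif_patterns))
  if (!all(ok)) {
    stop("invalid IUPAC symbol in pattern(s): ",
         paste(motif_patterns[!ok], collapse = ", "), call. = FALSE)
  }
  subject <- Biostrings::DNAString(template$seq)
  hits <- lapply(toupper(motif_patterns), function(p) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), subject, fixed = FALSE)
    IRanges::IRanges(start = Biostrings::start(m), end = Biostrings::end(m))
  })
  merged <- IRanges::reduce(do.call(c, hits))
  data.frame(start = IRanges::start(merged) - 1L, end = IRanges::end(merged))
}

REGION_CLASSES <- c("FR_plain", "FR_motif", "CDR_plain", "CDR_motif")

#' Default region enrichment weights
#'
#' Mutation-placement enrichment relative to plain framework sequence:
#' framework 1x, hotspot-motif framework 2x, CDR 5x, and a motif inside a
#' CDR composes multiplicatively to 10x by default.
#'
#' @param cdr CDR enrichment (default 5).
#' @param motif Motif enrichment (default 2).
#' @param cdr_motif Combined weight for motif-in-CDR (default `cdr * motif`).
#' @return Named numeric vector over the four region classes.
#' @export
region_weights <- function(cdr = 5, motif = 2, cdr_motif = cdr * motif) {
  w <- c(FR_plain = 1, FR_motif = motif, CDR_plain = cdr, CDR_motif = cdr_motif)
  if (any(w <= 0)) stop("region weights must be positive", call. = FALSE)
  w
}

#' Partition a template into enrichment regions
#'
#' Tiles `[0, L)` into maximal runs of constant class, where the class of a
#' position is decided by CDR and motif membership: CDR and motif ->
#' `CDR_motif`, CDR only -> `CDR_plain`, motif only -> `FR_motif`, neither ->
#' `FR_plain`.
#'
#' @param template A [v_gene_template()].
#' @param motif_intervals Data frame of motif intervals (`start`, `end`),
#'   e.g. from [find_hotspot_motifs()].
#' @param weights Named weights as from [region_weights()].
#' @return An object of class `region_partition`: data frame with columns
#'   `start`, `end`, `class`, `weight`, tiling `[0, L)` exactly, plus a
#'   per-position weight vector in attribute `pos_weight`.
#' @export
partition_regions <- function(template,
                              motif_intervals = find_hotspot_motifs(template),
                              weights = region_weights()) {
  stopifnot(all(REGION_CLASSES %in% names(weights)))
  L <- template$length
  motif_intervals <- validate_intervals(motif_intervals, L, "motif_intervals")
  in_cdr <- positions_in(template$cdr_intervals, L)
  in_motif <- positions_in(motif_intervals, L)
  cls <- ifelse(in_cdr & in_motif, "CDR_motif",
         ifelse(in_cdr, "CDR_plain",
         ifelse(in_motif, "FR_motif", "FR_plain")))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  part <- data.frame(
    start = c(0L, ends[-length(ends)]),
    end = ends,
    class = r$values,
    weight = unname(weights[r$values]),
    stringsAsFactors = FALSE
  )
  structure(part, class = c("region_partition", "data.frame"),
            pos_weight = unname(weights[cls]), L = L)
}

positions_in <- function(intervals, L) {
  x <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    x[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
  }
  x
}

#' Stop-codon risk of a single codon
#'
#' Enumerates all 9 single-nucleotide substitutions of a (non-stop) codon and
#' counts how many yield TAA, TAG or TGA. A codon with one such substitution
#' carries a 1-in-9 chance that a uniformly placed random point mutation in
#' it creates a stop; a doubly at-risk codon 2-in-9. The count is whatever
#' the enumeration yields; nothing is capped.
#'
#' @param codon A 3-letter string over A/C/G/T, not itself a stop codon.
#' @return List with `risk_count` (integer in 0..9) and `risk_probability`
#'   (`risk_count / 9`).
#' @export
codon_stop_risk <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be 3 nt over A/C/G/T", call. = FALSE)
  }
  if (codon %in% STOP_CODONS) {
    stop("codon ", codon, " is itself a stop codon; templates exclude internal stops",
         call. = FALSE)
  }
  k <- sum(vapply(1:3, function(pos) position_stop_count(codon, pos), integer(1)))
  list(risk_count = as.integer(k), risk_probability = k / 9)
}

# substitutions at one codon position (1..3) yielding a stop
position_stop_count <- function(codon, pos) {
  ref <- substr(codon, pos, pos)
  variants <- vapply(setdiff(DNA_BASES, ref), function(b) {
    v <- codon
    substr(v, pos, pos) <- b
    v
  }, character(1))
  sum(variants %in% STOP_CODONS)
}

#' Per-codon stop-risk profile of a template
#'
#' @param template A [v_gene_template()].
#' @param partition Optional [partition_regions()] result; if supplied, each
#'   codon is labelled with the region class of its first nucleotide.
#' @return Data frame with one row per codon: `codon_index` (1-based),
#'   `codon`, `risk_count`, `risk_probability`, and `region_class` when a
#'   partition is given.
#' @export
codon_risk_profile <- function(template, partition = NULL) {
  codons <- codon_split(template$seq)
  risk <- vapply(codons, function(cd) codon_stop_risk(cd)$risk_count, integer(1))
  out <- data.frame(
    codon_index = seq_along(codons),
    codon = unname(codons),
    risk_count = unname(risk),
    risk_probability = unname(risk) / 9
  )
  if (!is.null(partition)) {
    cls_by_pos <- rep(partition$class, partition$end - partition$start)
    out$region_class <- cls_by_pos[(out$codon_index - 1L) * 3L + 1L]
  }
  out
}

#' Probability that one point mutation creates a premature stop
#'
#' The template-level per-mutation stop probability q under region-weighted
#' mutation placement. A mutation lands on nucleotide position i with
#' probability proportional to the enrichment weight of i's region, and
#' substitutes one of the three alternative bases uniformly; q is the
#' probability the mutated codon is a stop. Computed position-wise:
#' q = sum_i w_i c_i / sum_i w_i with c_i the fraction of the 3 substitutions
#' at position i that create a stop. With all weights equal this reduces to
#' the unweighted mean codon risk (the no-enrichment case).
#'
#' @param template A [v_gene_template()].
#' @param partition A [partition_regions()] result (or `NULL` for uniform
#'   weights).
#' @return Probability in `[0, 1]`.
#' @export
template_stop_probability <- function(template, partition = NULL) {
  L <- template$length
  w <- if (is.null(partition)) rep(1, L) else attr(partition, "pos_weight")
  if (length(w) != L) stop("partition does not tile this template", call. = FALSE)
  counts <- position_stop_counts(template$seq)
  sum(w * counts / 3) / sum(w)
}

# per-nucleotide-position count (0..3) of stop-creating substitutions
position_stop_counts <- function(seq) {
  codons <- codon_split(seq)
  unlist(lapply(codons, function(cd) {
    vapply(1:3, function(pos) position_stop_count(cd, pos), integer(1))
  }), use.names = FALSE)
}
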