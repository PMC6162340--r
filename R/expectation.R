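#' Per-division probability of acquiring a point mutation
#'
#' SHM deposits point mutations at roughly `mu` per nucleotide per division,
#' so a gene of `L` nucleotides acquires a mutation in a division with
#' probability (in the model's linear treatment) `p_m = L * mu`. For the
#' canonical 393-nt V gene at mu = 1e-3 this is 0.393.
#'
#' @param L Gene length in nucleotides (> 0).
#' @param mu Point-mutation rate per nucleotide per division.
#' @return Probability `L * mu`.
#' @export
per_division_mutation_probability <- function(L, mu) {
  stopifnot(L > 0, mu >= 0)
  p_m <- L * mu
  if (p_m >= 1) {
    stop("L * mu = ", p_m, " >= 1: per-division probability interpretation breaks",
         call. = FALSE)
  }
  p_m
}

#' Per-division probability of a stop codon by point mutation
#'
#' @param q Per-mutation stop probability (from
#'   [template_stop_probability()]).
#' @param p_m Per-division mutation probability.
#' @return `q * p_m`.
#' @export
point_stop_probability <- function(q, p_m) {
  stopifnot(q >= 0, q <= 1, p_m >= 0, p_m <= 1)
  q * p_m
}

#' Estimate the per-division deletion probability
#'
#' Converts observed (mutation load, deletion fraction) pairs into a
#' per-division deletion probability: a cell with `load` point mutations is
#' assumed to have completed `load / p_m` divisions, so the per-division
#' retention (probability of NOT acquiring a deletion) solves
#' `retention^divisions = 1 - deletion_fraction`. The per-observation
#' retentions are averaged arithmetically.
#'
#' @param observations Data frame with columns `mutation_load` (> 0) and
#'   `deletion_fraction` (in `[0, 1)`). The default is the published
#'   correlation of point-mutation load and deletion frequency in vivo:
#'   high (20 mutations, 40% deleted), medium (15, 15%), low (5, 5%).
#' @param p_m Per-division mutation probability (> 0).
#' @param division_rounding Round division counts to the nearest integer
#'   (default TRUE; 20 / 0.393 = 50.9 is treated as 51 divisions).
#' @return List with `divisions`, `retention` (per observation),
#'   `retain_prob` (mean retention) and `p_del = 1 - retain_prob`.
#' @export
estimate_deletion_rate <- function(observations = deletion_observations(),
                                   p_m, division_rounding = TRUE) {
  stopifnot(nrow(observations) >= 1L, p_m > 0)
  load <- observations$mutation_load
  frac <- observations$deletion_fraction
  stopifnot(all(load > 0), all(frac >= 0))
  if (any(frac >= 1)) {
    stop("deletion_fraction must be < 1 (retention of 0 has no per-division root)",
         call. = FALSE)
  }
  n <- load / p_m
  if (division_rounding) n <- round(n)
  retention <- (1 - frac)^(1 / n)
  retain_prob <- mean(retention)
  list(divisions = n, retention = retention,
       retain_prob = retain_prob, p_del = 1 - retain_prob)
}

#' Published deletion-load observations
#'
#' The three (mutation load, deletion fraction) anchor points relating point
#' mutation counts to deletion frequency in germinal-center B cells.
#'
#' @return Data frame with columns `mutation_load`, `deletion_fraction`.
#' @export
deletion_observations <- function() {
  data.frame(mutation_load = c(20, 15, 5),
             deletion_fraction = c(0.40, 0.15, 0.05))
}

#' Per-division probability of a stop codon by frameshifting deletion
#'
#' Indels whose length is not a multiple of three shift the reading frame and
#' are treated as stop-causing; by default 2/3 of indels frameshift.
#'
#' @param p_del Per-division deletion probability.
#' @param frameshift_fraction Fraction of indels that are not a multiple of
#'   3 nt (default 2/3).
#' @return `p_del * frameshift_fraction`.
#' @export
frameshift_stop_probability <- function(p_del, frameshift_fraction = 2 / 3) {
  stopifnot(p_del >= 0, p_del <= 1,
            frameshift_fraction >= 0, frameshift_fraction <= 1)
  p_del * frameshift_fraction
}

#' Combined per-division stop probability
#'
#' @param p_point Point-mutation stop probability per division.
#' @param p_fs Frameshift stop probability per division.
#' @return `p_point + p_fs`.
#' @export
combined_stop_probability <- function(p_point, p_fs) {
  stopifnot(p_point >= 0, p_fs >= 0)
  p <- p_point + p_fs
  if (p > 1) stop("combined stop probability exceeds 1", call. = FALSE)
  p
}

#' Snapshot division distribution of a proliferating cohort
#'
#' In an exponentially doubling cohort observed at an instant, the proportion
#' of cells that have completed k of at most D divisions is weighted by
#' population doubling: `P(k) = 2^k / (2^(D+1) - 1)`. For D = 2 this is
#' 1/7, 2/7, 4/7 (14%/29%/57%).
#'
#' @param D Maximum number of completed divisions (integer >= 0).
#' @return Object of class `division_distribution`: named numeric vector of
#'   probabilities over k = 0..D summing to 1.
#' @export
snapshot_division_distribution <- function(D) {
  if (length(D) != 1L || is.na(D) || D < 0 || D != round(D)) {
    stop("D must be a single non-negative integer", call. = FALSE)
  }
  k <- 0:D
  p <- 2^k / (2^(D + 1) - 1)
  division_distribution(setNames(p, k))
}

#' Arbitrary division distribution
#'
#' @param probs Named numeric vector mapping completed divisions k to
#'   probability; must sum to 1 within 1e-12 after names are parsed as
#'   non-negative integers.
#' @return Object of class `division_distribution`.
#' @export
division_distribution <- function(probs) {
  k <- suppressWarnings(as.integer(names(probs)))
  if (anyNA(k) || any(k < 0)) {
    stop("probs must be named by non-negative integer division counts",
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("division probabilities must sum to 1 (got ", sum(probs), ")",
         call. = FALSE)
  }
  structure(as.numeric(probs), names = as.character(k),
            class = "division_distribution")
}

#' Expected stop-codon frequency in a snapshot cohort
#'
#' A cell that completes k divisions escapes a premature stop with
#' probability `(1 - p_stop)^k`; averaging the complement over the division
#' distribution gives the expected fraction of cells carrying a stop:
#' `E = sum_k P(k) (1 - (1 - p_stop)^k)`.
#'
#' @param dist A `division_distribution`.
#' @param p_stop Per-division combined stop probability.
#' @return Expected frequency in `[0, 1]`.
#' @export
expected_stop_frequency <- function(dist, p_stop) {
  stopifnot(inherits(dist, "division_distribution"), p_stop >= 0, p_stop <= 1)
  k <- as.integer(names(dist))
  sum(as.numeric(dist) * (1 - (1 - p_stop)^k))
}

#' The full analytic risk chain
#'
#' Chains the per-division model end to end: mutation probability ->
#' point-stop probability -> deletion rate -> frameshift-stop probability ->
#' combined risk -> expected dark-zone stop frequency under a 2^k snapshot
#' division distribution. Two rounding modes are provided because the
#' published headline numbers arise from rounding each intermediate to its
#' displayed precision (3 decimals on probabilities) before the next step:
#' `"printed"` reproduces that chain (0.393 -> 0.025 -> 0.994 -> 0.006 ->
#' 0.004 -> 0.029 -> 4.1%), `"full"` carries full precision throughout.
#'
#' @param q Per-mutation stop probability (default 0.064, the value computed
#'   for the original 393-nt template with enrichment weighting).
#' @param L Gene length in nt.
#' @param mu Mutation rate per nt per division.
#' @param observations Deletion observations (see
#'   [estimate_deletion_rate()]).
#' @param frameshift_fraction Fraction of indels causing frameshifts.
#' @param D Maximum completed divisions for the snapshot distribution.
#' @param rounding `"printed"` or `"full"`.
#' @return List of every intermediate: `p_m`, `p_point`, `retain_prob`,
#'   `p_del`, `p_fs`, `p_stop`, `distribution`, `expected_frequency` and
#'   `expected_percent`.
#' @export
stop_expectation_chain <- function(q = 0.064, L = 393, mu = 1e-3,
                                   observations = deletion_observations(),
                                   frameshift_fraction = 2 / 3, D = 2,
                                   rounding = c("printed", "full")) {
  rounding <- match.arg(rounding)
  rnd <- function(x) if (rounding == "printed") round(x, 3) else x
  p_m <- per_division_mutation_probability(L, mu)
  p_point <- rnd(point_stop_probability(q, p_m))
  del <- estimate_deletion_rate(observations, p_m)
  retain <- rnd(del$retain_prob)
  p_del <- 1 - retain
  p_fs <- rnd(frameshift_stop_probability(p_del, frameshift_fraction))
  p_stop <- rnd(combined_stop_probability(p_point, p_fs))
  dist <- snapshot_division_distribution(D)
  E <- expected_stop_frequency(dist, p_stop)
  list(q = q, p_m = p_m, p_point = p_point, retain_prob = retain,
       p_del = p_del, p_fs = p_fs, p_stop = p_stop, distribution = dist,
       expected_frequency = E, expected_percent = round(100 * E, 1),
       rounding = rounding)
}
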