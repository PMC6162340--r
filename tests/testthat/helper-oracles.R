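# independent brute-force oracles kept deliberately naive

ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# enumerate the 9 single-nucleotide variants of a codon, count stops
brute_codon_risk <- function(codon) {
  n <- 0L
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      v <- codon
      substr(v, pos, pos) <- b
      if (v %in% ORACLE_STOPS) n <- n + 1L
    }
  }
  n
}

# expected stop probability of one weighted random point mutation: enumerate
# every (position, alternative base) pair, weight by the position's region
# weight
brute_weighted_q <- function(seq, pos_weight) {
  num <- 0; den <- 0
  for (p in seq_len(nchar(seq))) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(seq, p, p)) next
      v <- seq
      substr(v, p, p) <- b
      cstart <- ((p - 1) %/% 3) * 3 + 1
      codon <- substr(v, cstart, cstart + 2)
      num <- num + pos_weight[p] * (codon %in% ORACLE_STOPS)
      den <- den + pos_weight[p]
    }
  }
  num / den
}

# naive sliding-window IUPAC match (forward strand), merged intervals
brute_motif_scan <- function(seq, patterns) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  L <- nchar(seq)
  hit <- logical(L)
  for (pat in patterns) {
    k <- nchar(pat)
    for (s in seq_len(L - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!substr(seq, s + j - 1, s + j - 1) %in% iupac[[substr(pat, j, j)]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) hit[s:(s + k - 1)] <- TRUE
    }
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts[r$values], end = ends[r$values])
}

# a small fixed template used across tests: 10 codons, no stops
toy_template <- function() {
  v_gene_template(paste0("ATGCAAGGCT", "ATTGGAGCTC", "ACGACGGGTT"),
                  id = "toy30")
}
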