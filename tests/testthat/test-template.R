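test_that("template constructor enforces frame, alphabet and stop-free translation", {
  expect_s3_class(toy_template(), "v_gene_template")
  expect_error(v_gene_template("ATGCA"), "multiple of 3")
  expect_error(v_gene_template("ATGNNN"), "A/C/G/T")
  expect_error(v_gene_template("ATGTAACCC"), "stop codon")
  expect_error(v_gene_template("ATGCCC", cdr_intervals = data.frame(start = 3, end = 9)),
               "within")
  expect_error(v_gene_template("ATGCCCGGG",
                               cdr_intervals = data.frame(start = c(0, 2), end = c(3, 5))),
               "non-overlapping")
})

test_that("codon stop risk matches brute-force enumeration for all 64 codons", {
  for (codon in ALL_CODONS) {
    if (codon %in% ORACLE_STOPS) {
      expect_error(codon_stop_risk(codon), "stop codon")
    } else {
      k <- brute_codon_risk(codon)
      r <- codon_stop_risk(codon)
      expect_identical(r$risk_count, k)
      expect_equal(r$risk_probability, k / 9)
    }
  }
  # the at-risk / doubly-at-risk classes named in the model
  expect_equal(codon_stop_risk("CAA")$risk_probability, 1 / 9)
  expect_equal(codon_stop_risk("TAT")$risk_probability, 2 / 9)
  expect_equal(codon_stop_risk("GGG")$risk_count, 0L)
})

test_that("hotspot motif search equals a naive window scan and merges overlaps", {
  expect_equal(nrow(find_hotspot_motifs(v_gene_template("AAAAAA"), "RGYW")), 0L)
  hit <- find_hotspot_motifs(v_gene_template("AGCTCAACA"), "AGCT")
  # literal match at offset 0
  expect_equal(hit$start[1], 0L)
  expect_equal(hit$end[1], 4L)
  set.seed(42)
  for (rep in 1:5) {
    tpl <- generate_template(n_codons = 40, cdr_fraction = 0)
    got <- find_hotspot_motifs(tpl, c("RGYW", "WRCY"))
    want <- brute_motif_scan(tpl$seq, c("RGYW", "WRCY"))
    expect_equal(got, want)
  }
  expect_error(find_hotspot_motifs(toy_template(), "RGYZ"), "IUPAC")
})

test_that("region partition classifies by CDR/motif membership and tiles exactly", {
  tpl <- v_gene_template(strrep("GCA", 5), cdr_intervals = data.frame(start = 3, end = 9))
  part <- partition_regions(tpl, motif_intervals = data.frame(start = 6, end = 12))
  expect_equal(part$start, c(0L, 3L, 6L, 9L, 12L))
  expect_equal(part$end, c(3L, 6L, 9L, 12L, 15L))
  expect_equal(part$class, c("FR_plain", "CDR_plain", "CDR_motif", "FR_motif", "FR_plain"))
  expect_equal(part$weight, c(1, 5, 10, 2, 1))
  # no CDRs, no motifs -> one FR_plain region covering [0, L)
  plain <- partition_regions(v_gene_template(strrep("GCA", 5)),
                             motif_intervals = data.frame(start = integer(0), end = integer(0)))
  expect_equal(nrow(plain), 1L)
  expect_equal(plain$class, "FR_plain")
  # tiling conservation on random fixtures
  set.seed(7)
  for (rep in 1:5) {
    tpl <- generate_template(n_codons = 50)
    part <- partition_regions(tpl)
    expect_equal(sum(part$end - part$start), tpl$length)
    expect_equal(part$start[-1], part$end[-nrow(part)])
  }
})

test_that("per-mutation stop probability q matches weighted enumeration", {
  # unweighted toy: (1 + 2 + 0) / 27
  tpl <- v_gene_template("CAATATGGG")
  expect_equal(template_stop_probability(tpl), 3 / 27)
  expect_equal(template_stop_probability(v_gene_template(strrep("GGG", 4))), 0)
  # middle codon as CDR weight 5 vs enumeration oracle
  tpl5 <- v_gene_template("CAATATGGG", cdr_intervals = data.frame(start = 3, end = 6))
  part5 <- partition_regions(tpl5, motif_intervals = empty <- data.frame(start = integer(0), end = integer(0)))
  q5 <- template_stop_probability(tpl5, part5)
  expect_equal(q5, brute_weighted_q(tpl5$seq, rep(c(1, 5, 1), each = 3)))
  # general random templates with motifs against the oracle
  set.seed(13)
  for (rep in 1:3) {
    tpl <- generate_template(n_codons = 30)
    part <- partition_regions(tpl)
    expect_equal(template_stop_probability(tpl, part),
                 brute_weighted_q(tpl$seq, attr(part, "pos_weight")))
  }
})

test_that("q is invariant to re-splitting regions and reduces to mean codon risk when unweighted", {
  set.seed(99)
  tpl <- generate_template(n_codons = 40)
  part <- partition_regions(tpl, weights = region_weights(cdr = 1, motif = 1, cdr_motif = 1))
  expect_equal(template_stop_probability(tpl, part),
               mean(codon_risk_profile(tpl)$risk_probability))
  # re-splitting: uniform weights via NULL partition equals explicit all-equal partition
  expect_equal(template_stop_probability(tpl, part), template_stop_probability(tpl))
})

test_that("q equals a Monte-Carlo estimate within 3 standard errors", {
  set.seed(4)
  tpl <- generate_template(n_codons = 50)
  part <- partition_regions(tpl)
  q <- template_stop_probability(tpl, part)
  w <- attr(part, "pos_weight")
  n <- 1e5
  pos <- sample.int(tpl$length, n, replace = TRUE, prob = w)
  bases <- strsplit(tpl$seq, "")[[1]]
  hits <- vapply(pos, function(p) {
    b <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
    cstart <- ((p - 1) %/% 3) * 3 + 1
    codon <- bases[cstart:(cstart + 2)]
    codon[p - cstart + 1] <- b
    paste(codon, collapse = "") %in% ORACLE_STOPS
  }, logical(1))
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(hits) - q), 3 * se)
})

test_that("risk profile reports region classes and FASTA/BED round-trip works", {
  dir <- withr::local_tempdir()
  set.seed(5)
  tpl <- generate_template(n_codons = 30)
  writeLines(paste0(">", tpl$id, "\n", tpl$seq), file.path(dir, "t.fasta"))
  write_bed_intervals(tpl$cdr_intervals, file.path(dir, "t.bed"))
  back <- read_template(file.path(dir, "t.fasta"), file.path(dir, "t.bed"))
  expect_equal(back$seq, tpl$seq)
  expect_equal(back$cdr_intervals, tpl$cdr_intervals)
  prof <- codon_risk_profile(tpl, partition_regions(tpl))
  expect_equal(nrow(prof), 30L)
  expect_true(all(prof$region_class %in%
                    c("FR_plain", "FR_motif", "CDR_plain", "CDR_motif")))
})
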