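test_that("global alignment handles identity, substitutions and contiguous gaps", {
  tpl <- toy_template()
  a <- align_to_template(tpl$seq, tpl)
  expect_equal(a$identity, 1)
  expect_false(grepl("-", a$pattern))
  s <- tpl$seq
  substr(s, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(s, 8, 8))[1]
  a1 <- align_to_template(s, tpl)
  expect_equal(sum(strsplit(a1$pattern, "")[[1]] != strsplit(a1$subject, "")[[1]]), 1L)
  # 2-nt deletion stays one contiguous gap under affine scoring
  s2 <- paste0(substr(tpl$seq, 1, 12), substr(tpl$seq, 15, tpl$length))
  a2 <- align_to_template(s2, tpl)
  expect_match(a2$pattern, "^[ACGT]+--[ACGT]+$")
  expect_error(align_to_template("", tpl), "empty")
})

test_that("reads aligning as reverse complement are auto-reoriented", {
  set.seed(31)
  tpl <- generate_template(n_codons = 50)
  s <- tpl$seq
  substr(s, 10, 10) <- "T"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- align_to_template(rc, tpl)
  expect_true(a$reoriented)
  expect_true(a$aligned)
  expect_gt(a$identity, 0.95)
})

test_that("stop calls localize substitutions and frameshifts to template codons", {
  set.seed(32)
  tpl <- generate_template(n_codons = 50)
  expect_equal(nrow(call_stops(align_to_template(tpl$seq, tpl), tpl)$calls), 0L)
  # plant a stop at a known codon
  subs <- shmstop:::stop_substitutions(tpl$seq)
  row <- subs[which.max(subs$pos), ]
  s <- tpl$seq
  substr(s, row$pos, row$pos) <- row$alt
  calls <- call_stops(align_to_template(s, tpl), tpl)
  expect_equal(calls$calls$call_type, "substitution_stop")
  expect_equal(calls$calls$codon_index, (row$pos - 1) %/% 3 + 1)
  # 1-nt deletion in codon 4 -> frameshift called at codon 4
  s1 <- paste0(substr(tpl$seq, 1, 9), substr(tpl$seq, 11, tpl$length))
  fs <- call_stops(align_to_template(s1, tpl), tpl)
  expect_equal(fs$calls$call_type, "frameshift")
  expect_equal(fs$calls$codon_index, 4)
  # a stop in the template's final codon is not premature
  last <- tpl$seq
  substr(last, tpl$length - 2, tpl$length) <- "TAA"
  expect_equal(nrow(call_stops(align_to_template(last, tpl), tpl)$calls), 0L)
})

test_that("read collapsing yields counts and fractions summing to one", {
  tpl <- toy_template()
  reads <- data.frame(read_id = sprintf("r%02d", 1:10),
                      seq = c(rep("AAATTTCCC", 6), rep("GGGCCCAAA", 4)))
  s <- sample_reads("s1", reads, n_cells_sorted = 5, mode = "ngs")
  col <- collapse_reads(s)
  expect_equal(nrow(col), 2L)
  expect_equal(col$read_fraction, c(0.6, 0.4))
  expect_equal(sum(col$read_fraction), 1)
  one <- collapse_reads(sample_reads("s2", data.frame(
    read_id = sprintf("r%d", 1:10), seq = rep("AAATTTCCC", 10)), 5, "ngs"))
  expect_equal(one$read_fraction, 1)
})

test_that("abundance threshold is strictly greater than (100/n) percent", {
  col <- data.frame(seq_id = c("a", "b", "c"), seq = c("A", "C", "G"),
                    read_count = c(50, 10, 940),
                    read_fraction = c(0.05, 0.01, 0.94))
  out <- abundance_filter(col, n_cells_sorted = 100)
  expect_equal(out$passes_threshold, c(TRUE, FALSE, TRUE))  # exactly 1% fails
  out2 <- abundance_filter(data.frame(read_fraction = 0.005, read_count = 5,
                                      seq_id = "x", seq = "A"), 100)
  expect_false(out2$passes_threshold)
})

test_that("sample stop frequency is computed over passing reads only", {
  tab <- data.frame(read_count = c(30, 70, 5),
                    passes_threshold = c(TRUE, TRUE, FALSE),
                    n_calls = c(1L, 0L, 3L))
  expect_equal(sample_stop_frequency(tab), 30)
  clean <- data.frame(read_count = c(10, 20), passes_threshold = TRUE,
                      n_calls = c(0L, 0L))
  expect_equal(sample_stop_frequency(clean), 0)
  none <- data.frame(read_count = 5, passes_threshold = FALSE, n_calls = 1L)
  expect_warning(f <- sample_stop_frequency(none), "undefined")
  expect_true(is.na(f))
})

test_that("an NGS sample with sub-threshold stop-bearing error reads filters them out", {
  set.seed(33)
  tpl <- generate_template(n_codons = 40)
  subs <- shmstop:::stop_substitutions(tpl$seq)
  stop_seq <- tpl$seq
  substr(stop_seq, subs$pos[1], subs$pos[1]) <- subs$alt[1]
  err_stop <- tpl$seq
  substr(err_stop, subs$pos[2], subs$pos[2]) <- subs$alt[2]
  # 100 cells sorted: 60 cells' worth of clean reads, 39 of a real stop clone,
  # 1 error read carrying a stop (1% == threshold -> excluded)
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    seq = c(rep(tpl$seq, 60), rep(stop_seq, 39), err_stop))
  s <- sample_reads("mix", reads, n_cells_sorted = 100, mode = "ngs")
  res <- ngs_call_sample(s, tpl)
  expect_equal(sum(res$sequences$passes_threshold), 2L)
  expect_equal(res$stop_frequency_percent, 100 * 39 / 99)
})

test_that("sanger calling reports per-cell results without abundance filtering", {
  set.seed(34)
  tpl <- generate_template(n_codons = 40)
  subs <- shmstop:::stop_substitutions(tpl$seq)
  stop_seq <- tpl$seq
  substr(stop_seq, subs$pos[1], subs$pos[1]) <- subs$alt[1]
  reads <- data.frame(read_id = sprintf("c%02d", 1:10),
                      seq = c(rep(tpl$seq, 9), stop_seq))
  s <- sample_reads("sg", reads, n_cells_sorted = 10, mode = "sanger")
  tab <- sanger_call_cells(s, tpl)
  expect_equal(nrow(tab), 10L)
  expect_equal(mean(tab$premature_stop), 0.1)
  # unalignable cell -> NA, warned, never stop-positive
  reads2 <- data.frame(read_id = c("c1", "c2"),
                       seq = c(tpl$seq, strrep("CGCGAT", 20)))
  s2 <- sample_reads("sg2", reads2, n_cells_sorted = 2, mode = "sanger")
  expect_warning(tab2 <- sanger_call_cells(s2, tpl), "unalignable")
  expect_true(is.na(tab2$premature_stop[2]))
  expect_error(sample_reads("dup", data.frame(read_id = c("a", "a"),
                                              seq = c("AAA", "CCC")), 2, "sanger"),
               "one sequence per cell")
})

test_that("alignment-based calls agree with simulator truth flags", {
  set.seed(35)
  tpl <- generate_template(n_codons = 80)
  co <- simulate_cohort(tpl, NULL, mutation_rates(mu = 5e-3, p_del = 0.05),
                        divisions = 2L, n_cells = 300, mode = "poisson")
  s <- sample_reads("sim", data.frame(read_id = co$cells$cell_id,
                                      seq = co$cells$seq),
                    n_cells_sorted = nrow(co$cells), mode = "sanger")
  tab <- sanger_call_cells(s, tpl)
  expect_identical(tab$premature_stop, co$cells$premature_stop)
  expect_identical(tab$frameshift, co$cells$has_frameshift)
})

test_that("stop frequency is invariant to read order and duplication", {
  set.seed(36)
  tpl <- generate_template(n_codons = 40)
  subs <- shmstop:::stop_substitutions(tpl$seq)
  stop_seq <- tpl$seq
  substr(stop_seq, subs$pos[1], subs$pos[1]) <- subs$alt[1]
  seqs <- c(rep(tpl$seq, 70), rep(stop_seq, 30))
  make <- function(x) sample_reads("s", data.frame(
    read_id = sprintf("r%04d", seq_along(x)), seq = x), 10, "ngs")
  f1 <- ngs_call_sample(make(seqs), tpl)$stop_frequency_percent
  f2 <- ngs_call_sample(make(sample(seqs)), tpl)$stop_frequency_percent
  f3 <- ngs_call_sample(make(rep(seqs, 2)), tpl)$stop_frequency_percent
  expect_equal(f1, 30)
  expect_equal(f2, f1)
  expect_equal(f3, f1)
})
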