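test_that("scan_motif agrees with exhaustive window checking", {
  r <- replicon("r", "GAATCGGACTC", circular = FALSE)
  m <- motif_spec("GANTC", 1, "m6A", partner_offset = 3)
  sites <- scan_motif(r, m)
  expect_equal(sites$start, c(1L, 7L))
  expect_equal(sites$strand, c("+", "+"))
  expect_equal(sites$meth_pos, c(2L, 8L))
  # oracle over all 7 pentamer positions, both strands
  orc <- oracle_scan(r$sequence, "GANTC")
  expect_equal(sites$start, orc$fwd)

  # random sequence, palindromic and non-palindromic motifs vs oracle
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  rr <- replicon("rr", seq, circular = FALSE)
  pal <- scan_motif(rr, motif_spec("GANTC", 1))
  expect_equal(pal$start, oracle_scan(seq, "GANTC")$fwd)
  np <- scan_motif(rr, motif_spec("RCGCCTC", 3, "m4C"))
  orc2 <- oracle_scan(seq, "RCGCCTC")
  expect_equal(sort(np$start[np$strand == "+"]), orc2$fwd)
  # minus-strand starts (5' base on the minus strand): an oracle match
  # starting at s on the reverse-complement string ends at plus coordinate
  # L - s + 1
  expect_equal(sort(np$start[np$strand == "-"]),
               sort(nchar(seq) - orc2$rev + 1))
})

test_that("palindromic motifs are scanned once per duplex position", {
  m <- motif_spec("GANTC", 1)
  expect_true(m$palindromic)
  expect_equal(iupac_revcomp("GANTC"), "GANTC")
  expect_true(is_iupac_palindrome("TCGANNNNNNNNTCGA"))
  expect_false(is_iupac_palindrome("CGCANNNNNGTG"))
  # scanning a sequence and its reverse complement finds equally many sites
  r <- test_small_genome()$replicons[[1]]
  rc <- replicon("rc", iupac_revcomp(r$sequence))
  expect_equal(nrow(scan_motif(rc, m)), nrow(scan_motif(r, m)))
  # no match in a motif-free sequence
  expect_equal(nrow(scan_motif(replicon("x", "AAAAAA", circular = FALSE), m)),
               0L)
})

test_that("circular scanning finds sites spanning the origin junction", {
  # GANTC split across the junction: ...GA | NTC...
  r <- replicon("r", paste0("TTCTTTTTTTTTTTTTTTGA"), circular = TRUE)
  sites <- scan_motif(r, motif_spec("GANTC", 1))
  expect_equal(sites$start, 19L)
  expect_equal(sites$meth_pos, 20L)
  linear <- replicon("r", r$sequence, circular = FALSE)
  expect_equal(nrow(scan_motif(linear, motif_spec("GANTC", 1))), 0L)
})

test_that("motif_strand_sites expands duplex occurrences per methylated strand", {
  r <- replicon("r", "GAATCGG", circular = FALSE)
  m <- motif_spec("GANTC", 1, partner_offset = 3)
  ss <- motif_strand_sites(scan_motif(r, m), m)
  expect_equal(ss$meth_pos, c(2L, 4L))
  expect_equal(ss$strand, c("+", "-"))
  # one-strand motifs yield one strand-site per occurrence
  m1 <- motif_spec("RCGCCTC", 3, "m4C")
  r2 <- replicon("r2", "ACGCCTCAAGAGGCGT", circular = FALSE)
  ss2 <- motif_strand_sites(scan_motif(r2, m1), m1)
  expect_equal(nrow(ss2), 2L)
  expect_setequal(ss2$strand, c("+", "-"))
})

test_that("expected_density matches exhaustive pentamer enumeration", {
  # oracle: enumerate all 4^5 pentamers and sum their probabilities
  enum_density <- function(iupac, gc) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    classes <- c(A = "A", C = "C", G = "G", T = "T", N = "ACGT")
    cols <- strsplit(iupac, "")[[1]]
    bases <- c("A", "C", "G", "T")
    grid <- expand.grid(rep(list(bases), length(cols)),
                        stringsAsFactors = FALSE)
    match_row <- function(row) {
      all(vapply(seq_along(cols), function(j) {
        grepl(row[[j]], classes[[cols[j]]], fixed = TRUE)
      }, logical(1)))
    }
    tot <- 0
    for (i in seq_len(nrow(grid))) {
      if (match_row(grid[i, ])) tot <- tot + prod(p[unlist(grid[i, ])])
    }
    tot * 1000
  }
  expect_equal(expected_density("GANTC", 0.5), 3.90625)       # 4/1024 * 1000
  expect_equal(expected_density("GANTC", 0.5), enum_density("GANTC", 0.5))
  expect_equal(expected_density("GANTC", 0.619),
               enum_density("GANTC", 0.619), tolerance = 1e-12)
  expect_equal(round(expected_density("GANTC", 0.619), 2), 3.48)
  # probability-1 columns: every position matches
  expect_equal(expected_density("NNNN", 0.3), 1000)
  # non-palindromic motifs are counted on both strands
  expect_equal(expected_density("RCGCCTC", 0.5),
               2 * 0.5 * (0.25)^6 * 1000)
  expect_error(expected_density("GANTC", 1.2), "gc")
})

test_that("region densities partition the genome and do the arithmetic", {
  # constructed fixture: 10 kb genome, 6 kb coding with 6 sites, 4 kb
  # intergenic with 8 sites -> densities 1.0 and 2.0 /kb
  base <- strrep("A", 10000)
  put <- function(s, pos, word) {
    substr(s, pos, pos + nchar(word) - 1L) <- word
    s
  }
  seq <- base
  coding_pos <- as.integer(seq(100, 5600, length.out = 6))
  inter_pos <- as.integer(seq(6100, 9900, length.out = 8))
  for (p in c(coding_pos, inter_pos)) seq <- put(seq, p, "GAATC")
  r <- replicon("chr", seq)
  ann <- data.frame(gene_id = "g1", transcript_id = "t1", replicon = "chr",
                    start = 1L, end = 6000L, strand = "+")
  gen <- genome("fix", list(r), annotation = ann)
  rd <- region_density(gen, motif_spec("GANTC", 1))
  expect_equal(rd$site_count[rd$region_class == "genome"], 14L)
  expect_equal(rd$density[rd$region_class == "coding"], 1.0)
  expect_equal(rd$density[rd$region_class == "intergenic"], 2.0)
  # partition conservation
  expect_equal(rd$site_count[rd$region_class == "genome"],
               sum(rd$site_count[rd$region_class != "genome"]))

  # degenerate partition: fully coding genome omits the intergenic report
  gen2 <- genome("fix2", list(r), annotation = transform(ann, end = 10000L))
  rd2 <- region_density(gen2, motif_spec("GANTC", 1))
  expect_false("intergenic" %in% rd2$region_class)
  # no annotation: genome-class only
  rd3 <- region_density(genome("fix3", list(r)), motif_spec("GANTC", 1))
  expect_equal(rd3$region_class, "genome")
})

test_that("partition conservation holds on a realistic annotated genome", {
  gen <- test_small_genome()
  rd <- region_density(gen, motif_spec("GANTC", 1))
  expect_equal(rd$site_count[rd$region_class == "genome"],
               sum(rd$site_count[rd$region_class != "genome"]))
  expect_equal(sum(rd$span_kb[rd$region_class != "genome"]),
               rd$span_kb[rd$region_class == "genome"])
})

test_that("cumulative GC skew sums windowed skews and flags extrema", {
  r <- replicon("r", "GGGGCCCC", circular = FALSE)
  sk <- cumulative_gc_skew(r, window = 4, step = 4)
  expect_equal(sk$skew, c(1, -1))
  expect_equal(sk$cumulative, c(1, 0))

  at <- replicon("at", strrep("AT", 50), circular = FALSE)
  sk2 <- cumulative_gc_skew(at, window = 10, step = 10)
  expect_true(all(sk2$skew == 0))
  expect_true(all(sk2$cumulative == 0))

  # G-rich half then C-rich half: cumulative maximum at the junction
  seq <- paste0(strrep("GGAT", 2500), strrep("CCAT", 2500))
  r3 <- replicon("r3", seq, circular = FALSE)
  sk3 <- cumulative_gc_skew(r3, window = 500, step = 500)
  expect_equal(which.max(sk3$cumulative), 20L)  # direct summation check
  expect_equal(attr(sk3, "max_pos"), sk3$center[20])
  expect_error(cumulative_gc_skew(replicon("s", "ACGT"), window = 10),
               "window")
})

test_that("group comparisons dispatch t test and ANOVA/Tukey correctly", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- compare_groups(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  shifted <- list(a = c(1, 2, 3), b = c(11, 12, 13))
  res2 <- compare_groups(shifted, var_equal = TRUE)
  # closed form pooled t: diff / (s_p sqrt(2/3)) with s_p = 1
  expect_equal(abs(res2$statistic), 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(res2$p.value, 0.001)
  # Welch reduces to the same value for equal variances
  res2w <- compare_groups(shifted)
  expect_equal(abs(res2w$statistic), abs(res2$statistic), tolerance = 1e-12)

  three <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res3 <- compare_groups(three)
  expect_equal(res3$statistic, 0)
  expect_equal(nrow(res3$tukey), 3L)
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "at least two")
})
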