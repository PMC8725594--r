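toy_annotated <- function(genes, len = 10000L, seed_seq = "ACGT") {
  r <- replicon("chr", strrep(seed_seq, len / 4L))
  genome("toy", list(r), annotation = genes)
}

gene_row <- function(id, start, end, strand, tx = id) {
  data.frame(gene_id = id, transcript_id = tx, replicon = "chr",
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

test_that("promoter extraction follows the upstream-window convention", {
  gen <- toy_annotated(rbind(gene_row("g1", 1000, 1500, "+"),
                             gene_row("g2", 1700, 2000, "-")))
  pr <- extract_promoters(gen, length = 125)
  p1 <- pr[pr$transcript_id == "g1", ]
  expect_equal(c(p1$start, p1$end), c(875L, 999L))
  p2 <- pr[pr$transcript_id == "g2", ]
  expect_equal(c(p2$start, p2$end), c(2001L, 2125L))
})

test_that("promoters wrap on circular replicons and are shared by transcripts", {
  gen <- toy_annotated(gene_row("g1", 50, 400, "+"))
  pr <- extract_promoters(gen, length = 125)
  expect_equal(nrow(pr), 2L)  # [L-75, L] and [1, 49]
  expect_equal(pr$start, c(10000L - 75L, 1L))
  expect_equal(pr$end, c(10000L, 49L))

  # two genes on one transcript share one promoter upstream of the span
  ann <- rbind(gene_row("gA", 3000, 3500, "+", tx = "op1"),
               gene_row("gB", 3600, 4200, "+", tx = "op1"))
  pr2 <- extract_promoters(toy_annotated(ann), length = 125)
  expect_equal(nrow(pr2), 1L)
  expect_equal(c(pr2$start, pr2$end), c(2875L, 2999L))
})

test_that("planted promoter motifs pick out exactly the seeded genes", {
  len <- 24000L
  seq <- strrep("A", len)
  genes <- do.call(rbind, lapply(1:12, function(i) {
    gene_row(sprintf("g%02d", i), i * 2000 - 500, i * 2000, "+")
  }))
  seeded <- c(2, 5, 7, 8, 11)
  for (i in seeded) {
    p <- i * 2000 - 560  # inside [start-125, start-1]
    substr(seq, p, p + 4) <- "GAATC"
  }
  gen <- genome("toy", list(replicon("chr", seq)), annotation = genes)
  hits <- genes_with_motif_in_promoter(gen, motif_spec("GANTC", 1))
  expect_equal(hits, sprintf("g%02d", seeded))
})

test_that("promoter gene sets are strand-consistent under reverse complement", {
  gen <- test_small_genome()
  hits_fwd <- genes_with_motif_in_promoter(gen, motif_spec("GANTC", 1))
  # mirror the genome: reverse-complement the sequence, flip the annotation
  r <- gen$replicons[[1]]
  len <- r$length
  ann <- gen$annotation
  ann_rc <- transform(ann,
                      start = len - end + 1L,
                      end = len - start + 1L,
                      strand = ifelse(strand == "+", "-", "+"))
  gen_rc <- genome("toy_rc", list(replicon(r$name, iupac_revcomp(r$sequence))),
                   annotation = ann_rc)
  hits_rc <- genes_with_motif_in_promoter(gen_rc, motif_spec("GANTC", 1))
  expect_equal(hits_fwd, hits_rc)
})

test_that("hypergeometric enrichment equals exact enumeration for N <= 12", {
  # oracle: enumerate all C(N, n) draws and count overlaps >= k
  enum_p <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    annotated <- seq_len(K)
    mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
  }
  res <- enrichment_test(N = 10, K = 4, n = 5, k = 4)
  expect_equal(res$p.value, 6 / 252, tolerance = 1e-12)  # C(4,4) C(6,1)/C(10,5)
  expect_equal(res$p.value, enum_p(10, 4, 5, 4), tolerance = 1e-12)
  for (case in list(c(12, 5, 6, 3), c(11, 3, 4, 1), c(9, 6, 3, 3),
                    c(12, 6, 6, 0))) {
    got <- enrichment_test(case[1], case[2], case[3], case[4])$p.value
    expect_equal(got, enum_p(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12,
                 label = paste(case, collapse = ","))
  }
})

test_that("enrichment edge cases: fold 1 at expectation, p = 1 at k = 0", {
  res <- enrichment_test(N = 100, K = 20, n = 10, k = 2)  # k = nK/N
  expect_equal(res$fold, 1)
  res0 <- enrichment_test(N = 50, K = 10, n = 5, k = 0)
  expect_equal(res0$p.value, 1)
  expect_error(enrichment_test(10, 4, 5, 5), "inconsistent")
})

test_that("group balance test flags skew and passes uniformity", {
  even <- group_balance_test(c(20, 18, 22, 19, 21, 20))
  expect_gt(even$p.value, 0.9)
  skewed <- group_balance_test(c(60, 5, 5, 10, 10, 10))
  expect_lt(skewed$p.value, 1e-6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_set(c("g1", "g2"), path)
  expect_equal(read_gene_set(path), c("g1", "g2"))
})
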