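# Promoter extraction and motif-in-promoter gene sets: the machinery behind
# candidate regulon construction (genes that are both co-regulated and carry
# a recognition site in their predicted promoter).

#' Extract predicted promoters
#'
#' The promoter of a transcript is the fixed-length window immediately
#' upstream of it: `[start - length, start - 1]` for plus-strand
#' transcripts, `[end + 1, end + length]` for minus-strand ones. On circular
#' replicons promoters wrap across the origin junction (represented as two
#' intervals); on linear replicons they are clipped. Promoters are not
#' clipped at upstream gene boundaries. One promoter per transcript, shared
#' by all its genes.
#'
#' @param gen A [genome()] with annotation.
#' @param length Promoter length in bp (default 125).
#' @return Data frame with one row per promoter interval: `transcript_id`,
#'   `replicon`, `start`, `end`, `strand` (wrapped promoters contribute two
#'   rows).
#' @export
extract_promoters <- function(gen, length = 125L) {
  stopifnot(inherits(gen, "genome"))
  ann <- gen$annotation
  if (nrow(ann) == 0L) stop("genome has no annotation")
  length <- as.integer(length)
  # transcript span: min start / max end over its genes
  key <- paste(ann$replicon, ann$transcript_id)
  tx <- data.frame(
    transcript_id = tapply(ann$transcript_id, key, `[`, 1),
    replicon = tapply(ann$replicon, key, `[`, 1),
    start = as.integer(tapply(ann$start, key, min)),
    end = as.integer(tapply(ann$end, key, max)),
    strand = tapply(ann$strand, key, `[`, 1),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    r <- gen$replicons[[tx$replicon[i]]]
    if (tx$strand[i] == "+") {
      lo <- tx$start[i] - length
      hi <- tx$start[i] - 1L
    } else {
      lo <- tx$end[i] + 1L
      hi <- tx$end[i] + length
    }
    rows[[i]] <- split_interval(lo, hi, r)
    rows[[i]]$transcript_id <- tx$transcript_id[i]
    rows[[i]]$replicon <- tx$replicon[i]
    rows[[i]]$strand <- tx$strand[i]
  }
  out <- do.call(rbind, rows)
  out <- out[c("transcript_id", "replicon", "start", "end", "strand")]
  rownames(out) <- NULL
  out
}

# Clip or wrap an interval [lo, hi] onto a replicon; returns a data frame of
# 1 or 2 rows with columns start, end.
split_interval <- function(lo, hi, rep) {
  len <- rep$length
  if (!rep$circular) {
    lo <- max(lo, 1L)
    hi <- min(hi, len)
    if (lo > hi) return(data.frame(start = integer(0), end = integer(0)))
    return(data.frame(start = lo, end = hi))
  }
  if (lo >= 1L && hi <= len) return(data.frame(start = lo, end = hi))
  if (lo < 1L) {
    return(data.frame(start = c(wrap_pos(lo, len), 1L),
                      end = c(len, hi)))
  }
  # hi > len
  data.frame(start = c(lo, 1L), end = c(len, wrap_pos(hi, len)))
}

#' Genes with a motif site in their promoter
#'
#' Genes whose transcript promoter overlaps the methylated-base position of
#' at least one motif site. Genes inherit their transcript's promoter;
#' a gene is counted once however many sites its promoter holds.
#'
#' @param gen A [genome()] with annotation.
#' @param motif A [motif_spec()] (scanned internally) or a precomputed site
#'   table from [scan_motif()].
#' @param promoters Output of [extract_promoters()]; computed at the default
#'   length when omitted.
#' @return Character vector of gene ids, sorted.
#' @export
genes_with_motif_in_promoter <- function(gen, motif, promoters = NULL) {
  stopifnot(inherits(gen, "genome"))
  if (is.null(promoters)) promoters <- extract_promoters(gen)
  sites <- if (inherits(motif, "motif_spec")) scan_motif(gen, motif) else motif
  hit_tx <- character(0)
  for (rn in unique(promoters$replicon)) {
    p <- promoters[promoters$replicon == rn, , drop = FALSE]
    s <- sites[sites$replicon == rn, , drop = FALSE]
    if (nrow(s) == 0L || nrow(p) == 0L) next
    ir_p <- IRanges::IRanges(p$start, p$end)
    ir_s <- IRanges::IRanges(s$meth_pos, width = 1L)
    hit <- IRanges::overlapsAny(ir_p, ir_s)
    hit_tx <- c(hit_tx, p$transcript_id[hit])
  }
  ann <- gen$annotation
  sort(unique(ann$gene_id[ann$transcript_id %in% hit_tx]))
}

#' Hypergeometric enrichment of a gene set
#'
#' Upper-tail hypergeometric test of the overlap between a gene set of size
#' `n` and the `K` genes annotated with a feature (e.g. a promoter motif) in
#' a universe of `N` genes: `p = P(X >= k)`. Fold enrichment is
#' `(k/n) / (K/N)`.
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n Size of the drawn gene set.
#' @param k Overlap between the set and the annotated genes.
#' @return List with `N`, `K`, `n`, `k`, `p.value`, `fold`.
#' @export
enrichment_test <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0L)) {
    stop("inconsistent contingency values")
  }
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0L && K > 0L) (k / n) / (K / N) else NA_real_
  list(N = N, K = K, n = n, k = k, p.value = p, fold = fold)
}

#' Goodness-of-fit of gene counts across expression groups
#'
#' Chi-square goodness-of-fit of observed gene counts across classes (e.g.
#' cell-cycle expression groups) against expected proportions, the check
#' behind calling a distribution across groups "unbiased". The test choice
#' is a pragmatic one; it is not uniquely implied by the analysis design.
#'
#' @param counts Integer vector of observed counts per group.
#' @param expected_prop Expected proportions (default uniform).
#' @return `htest` object from [stats::chisq.test()].
#' @export
group_balance_test <- function(counts, expected_prop = NULL) {
  if (is.null(expected_prop)) {
    expected_prop <- rep(1 / length(counts), length(counts))
  }
  stats::chisq.test(counts, p = expected_prop)
}

#' Write / read a gene set
#' @param genes Character vector of gene ids.
#' @param path File path (one id per line, TSV with header `gene_id`).
#' @return The gene ids (invisibly for the writer).
#' @export
write_gene_set <- function(genes, path) {
  utils::write.table(data.frame(gene_id = genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(genes)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)$gene_id
}
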