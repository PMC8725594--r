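# IUPAC motif scanning and density statistics.
#
# Motifs are stored 5'->3'; the printed convention of listing the opposite
# strand of a recognition pair as the base-wise complement (unreversed) is
# not used internally -- pairing always goes through the true reverse
# complement. Palindromic motifs (equal to their reverse complement under
# IUPAC semantics) are scanned on the plus strand only, yielding one site
# per duplex position.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)

TWOFOLD_CODES <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Specify a methylated motif
#'
#' A degenerate (IUPAC) recognition sequence together with the position of
#' the methylated base. For motifs whose opposite strand is also methylated
#' (the usual case for m6A recognition pairs), `partner_offset` gives the
#' 0-based position, on the motif strand, of the base that pairs with the
#' partner strand's methylated base; `NA` means the duplex is methylated on
#' the motif strand only.
#'
#' @param iupac Recognition sequence over IUPAC codes, 5'->3'.
#' @param meth_offset 0-based index of the methylated base within `iupac`.
#' @param mod_type `"m6A"` or `"m4C"`.
#' @param partner_offset 0-based index (on the motif strand) of the base
#'   paired with the partner-strand methylated base, or `NA`.
#' @return An object of class `motif_spec` with fields `iupac`,
#'   `meth_offset`, `mod_type`, `partner_offset` and `palindromic`.
#' @examples
#' motif_spec("GANTC", 1, "m6A", partner_offset = 3)
#' @export
motif_spec <- function(iupac, meth_offset, mod_type = c("m6A", "m4C"),
                       partner_offset = NA_integer_) {
  iupac <- toupper(iupac)
  mod_type <- match.arg(mod_type)
  k <- nchar(iupac)
  if (k < 4L || k > 20L) stop("motif length must be in [4, 20]")
  cols <- strsplit(iupac, "")[[1]]
  if (!all(cols %in% names(IUPAC_CLASSES))) stop("invalid IUPAC code in motif")
  meth_offset <- as.integer(meth_offset)
  if (meth_offset < 0L || meth_offset >= k) stop("meth_offset outside motif")
  meth_base <- cols[meth_offset + 1L]
  required <- if (mod_type == "m6A") "A" else "C"
  if (!grepl(required, IUPAC_CLASSES[[meth_base]], fixed = TRUE)) {
    stop("methylated base incompatible with ", mod_type)
  }
  if (!is.na(partner_offset)) {
    partner_offset <- as.integer(partner_offset)
    if (partner_offset < 0L || partner_offset >= k) {
      stop("partner_offset outside motif")
    }
  }
  structure(
    list(iupac = iupac, meth_offset = meth_offset, mod_type = mod_type,
         partner_offset = partner_offset,
         palindromic = is_iupac_palindrome(iupac)),
    class = "motif_spec"
  )
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s (%s), methylated base at offset %d%s%s\n",
              x$iupac, x$mod_type, x$meth_offset,
              if (x$palindromic) ", palindromic" else "",
              if (!is.na(x$partner_offset))
                sprintf(", partner at offset %d", x$partner_offset) else ""))
  invisible(x)
}

#' Is an IUPAC string its own reverse complement?
#' @param iupac IUPAC string.
#' @return Logical.
#' @export
is_iupac_palindrome <- function(iupac) {
  identical(iupac_revcomp(iupac), toupper(iupac))
}

#' Reverse complement of an IUPAC string
#' @param iupac IUPAC string.
#' @return Character string.
#' @export
iupac_revcomp <- function(iupac) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
}

# Sequence to scan for circular replicons: append the first k-1 bases so
# sites spanning the origin junction are found once.
scan_subject <- function(rep, k) {
  if (rep$circular && rep$length > k) {
    paste0(rep$sequence, substr(rep$sequence, 1L, k - 1L))
  } else {
    rep$sequence
  }
}

#' Locate all occurrences of a motif
#'
#' Finds every (possibly overlapping) match of a degenerate motif in a
#' genome. Palindromic motifs are matched on the plus strand only (one site
#' per duplex position); non-palindromic motifs are matched on both strands.
#' For minus-strand sites, `start` is the 1-based plus-strand coordinate of
#' the motif's first base read 5'->3' on the minus strand, and `meth_pos`
#' the plus-strand coordinate of the methylated base on that strand.
#' Circular replicons are scanned across the origin junction. Ambiguous (N)
#' bases in the genome are never matched.
#'
#' @param gen A [genome()] or [replicon()].
#' @param motif A [motif_spec()].
#' @return A data frame with columns `replicon`, `start`, `strand`,
#'   `meth_pos`, one row per site.
#' @examples
#' r <- replicon("r", "GAATCGGACTC", circular = FALSE)
#' scan_motif(r, motif_spec("GANTC", 1))
#' @export
scan_motif <- function(gen, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  reps <- if (inherits(gen, "genome")) gen$replicons else list(gen)
  out <- lapply(reps, scan_motif_replicon, motif = motif)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

scan_motif_replicon <- function(rep, motif) {
  stopifnot(inherits(rep, "replicon"))
  k <- nchar(motif$iupac)
  subject <- Biostrings::DNAString(scan_subject(rep, k))
  len <- rep$length

  fwd <- Biostrings::matchPattern(motif$iupac, subject, fixed = "subject")
  starts_f <- Biostrings::start(fwd)
  starts_f <- starts_f[starts_f <= len]
  res <- data.frame(
    replicon = rep(rep$name, length(starts_f)),
    start = wrap_pos(starts_f, len),
    strand = rep("+", length(starts_f)),
    meth_pos = wrap_pos(starts_f + motif$meth_offset, len),
    stringsAsFactors = FALSE
  )

  if (!motif$palindromic) {
    rcm <- iupac_revcomp(motif$iupac)
    rev <- Biostrings::matchPattern(rcm, subject, fixed = "subject")
    s <- Biostrings::start(rev)
    s <- s[s <= len]
    e <- s + k - 1L
    res_rev <- data.frame(
      replicon = rep(rep$name, length(s)),
      start = wrap_pos(e, len),
      strand = rep("-", length(s)),
      meth_pos = wrap_pos(e - motif$meth_offset, len),
      stringsAsFactors = FALSE
    )
    res <- rbind(res, res_rev)
  }
  res[order(res$start), , drop = FALSE]
}

#' Expand motif sites into per-strand methylated positions
#'
#' Each duplex occurrence of a motif contributes one strand-site per
#' methylated strand: always the motif strand's methylated base and, when
#' `partner_offset` is set, the opposite strand's methylated base. These
#' strand-sites are the units of all extent-of-methylation statistics.
#'
#' @param sites Output of [scan_motif()].
#' @param motif The corresponding [motif_spec()].
#' @param rep_lengths Named integer vector of replicon lengths (for circular
#'   wrapping of partner positions); optional when no wrapping can occur.
#' @return Data frame with columns `replicon`, `meth_pos`, `strand`.
#' @export
motif_strand_sites <- function(sites, motif, rep_lengths = NULL) {
  stopifnot(inherits(motif, "motif_spec"))
  own <- data.frame(replicon = sites$replicon, meth_pos = sites$meth_pos,
                    strand = sites$strand, stringsAsFactors = FALSE)
  if (is.na(motif$partner_offset)) return(own)
  # partner base plus-strand coordinate: start +/- partner_offset depending
  # on the orientation of the motif occurrence
  off <- motif$partner_offset
  pos <- ifelse(sites$strand == "+", sites$start + off, sites$start - off)
  if (!is.null(rep_lengths)) {
    pos <- wrap_pos(pos, rep_lengths[sites$replicon])
  }
  partner <- data.frame(
    replicon = sites$replicon,
    meth_pos = as.integer(pos),
    strand = ifelse(sites$strand == "+", "-", "+"),
    stringsAsFactors = FALSE
  )
  out <- rbind(own, partner)
  out[order(out$replicon, out$meth_pos, out$strand), , drop = FALSE]
}

#' Expected motif density in a random sequence
#'
#' Closed-form expectation of the number of motif sites per kb in an i.i.d.
#' random nucleotide sequence of given GC content, with base probabilities
#' p(G) = p(C) = gc/2 and p(A) = p(T) = (1 - gc)/2. Palindromic motifs are
#' counted on a single strand (one site per duplex position, matching
#' [scan_motif()]); non-palindromic motifs are counted on both strands.
#'
#' @param motif A [motif_spec()] or a plain IUPAC string.
#' @param gc GC fraction in (0, 1).
#' @return Expected sites per kb.
#' @examples
#' expected_density("GANTC", gc = 0.5)    # 4/1024 * 1000
#' expected_density("GANTC", gc = 0.619)  # ~3.48, the random expectation
#' @export
expected_density <- function(motif, gc) {
  if (inherits(motif, "motif_spec")) {
    iupac <- motif$iupac
    palin <- motif$palindromic
  } else {
    iupac <- toupper(motif)
    palin <- is_iupac_palindrome(iupac)
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cols <- strsplit(iupac, "")[[1]]
  if (!all(cols %in% names(IUPAC_CLASSES))) stop("invalid IUPAC code in motif")
  pr <- prod(vapply(cols, function(cc) {
    sum(p[strsplit(IUPAC_CLASSES[[cc]], "")[[1]]])
  }, numeric(1)))
  pr * 1000 * if (palin) 1 else 2
}

#' Motif density in genome, coding and intergenic partitions
#'
#' Classifies each motif site by the position of its methylated base: coding
#' if it lies within any annotated gene interval (either strand), intergenic
#' otherwise. Densities are site counts divided by the span of the class in
#' kb; the genome-class density uses the full sequence length. Without
#' annotation only the genome-class report is returned; a class with zero
#' span is omitted.
#'
#' @param gen A [genome()].
#' @param motif A [motif_spec()].
#' @return Data frame with columns `motif`, `region_class`, `site_count`,
#'   `span_kb`, `density`.
#' @export
region_density <- function(gen, motif) {
  stopifnot(inherits(gen, "genome"))
  sites <- scan_motif(gen, motif)
  total_bp <- sum(vapply(gen$replicons, `[[`, integer(1), "length"))
  res <- data.frame(
    motif = motif$iupac, region_class = "genome",
    site_count = nrow(sites), span_kb = total_bp / 1000,
    density = nrow(sites) / (total_bp / 1000),
    stringsAsFactors = FALSE
  )
  ann <- gen$annotation
  if (nrow(ann) == 0L) return(res)

  coding_bp <- 0L
  in_coding <- logical(nrow(sites))
  for (rn in names(gen$replicons)) {
    g <- ann[ann$replicon == rn, , drop = FALSE]
    if (nrow(g) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    coding_bp <- coding_bp + sum(IRanges::width(ir))
    idx <- sites$replicon == rn
    if (any(idx)) {
      q <- IRanges::IRanges(sites$meth_pos[idx], width = 1L)
      in_coding[idx] <- IRanges::overlapsAny(q, ir)
    }
  }
  inter_bp <- total_bp - coding_bp
  add <- data.frame(
    motif = motif$iupac,
    region_class = c("coding", "intergenic"),
    site_count = c(sum(in_coding), sum(!in_coding)),
    span_kb = c(coding_bp, inter_bp) / 1000,
    stringsAsFactors = FALSE
  )
  add <- add[add$span_kb > 0, , drop = FALSE]
  add$density <- add$site_count / add$span_kb
  rbind(res, add)
}

# Windowed and cumulative GC skew of a bare sequence; used both by the
# exported profile function and by skew-based origin inference.
cumulative_gc_skew_seq <- function(sequence, window, step = window) {
  len <- nchar(sequence)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window > len) stop("window larger than sequence")
  starts <- seq.int(1L, len - window + 1L, by = step)
  v <- Biostrings::Views(Biostrings::DNAString(sequence),
                         start = starts, width = window)
  f <- Biostrings::letterFrequency(v, letters = c("G", "C"))
  gc_tot <- f[, "G"] + f[, "C"]
  skew <- ifelse(gc_tot == 0, 0, (f[, "G"] - f[, "C"]) / gc_tot)
  cum <- cumsum(skew)
  centers <- as.integer(starts + window %/% 2L)
  out <- data.frame(center = centers, skew = skew, cumulative = cum)
  attr(out, "min_pos") <- centers[which.min(cum)]
  attr(out, "max_pos") <- centers[which.max(cum)]
  out
}

#' Cumulative GC skew along a replicon
#'
#' Per-window GC skew (G - C)/(G + C) (0 for windows without G or C) and its
#' running sum over consecutive windows. The positions of the global minimum
#' and maximum of the cumulative curve -- the classical origin and terminus
#' signatures of a circular bacterial chromosome -- are attached as
#' attributes `min_pos` and `max_pos`.
#'
#' @param rep A [replicon()].
#' @param window Window size in bp.
#' @param step Step between window starts in bp; defaults to `window`
#'   (non-overlapping). The shape of the cumulative curve is step-invariant.
#' @return Data frame with columns `center`, `skew`, `cumulative`, plus
#'   attributes `min_pos` and `max_pos`.
#' @export
cumulative_gc_skew <- function(rep, window = 10000L, step = window) {
  stopifnot(inherits(rep, "replicon"))
  cumulative_gc_skew_seq(rep$sequence, window = window, step = step)
}

#' Compare motif densities between groups
#'
#' Two groups are compared with a two-sample t test (Welch's unequal-variance
#' form by default); three or more with a one-way ANOVA followed by Tukey's
#' honestly significant difference post hoc test.
#'
#' @param densities_by_group Named list of numeric vectors (one per group,
#'   each of length >= 2).
#' @param var_equal For the two-group case, use the pooled-variance t test
#'   instead of Welch's.
#' @return For two groups, a list with `method`, `statistic`, `p.value` and
#'   the group means; for more, a list with `method`, `statistic` (F),
#'   `p.value` and a `tukey` data frame of pairwise comparisons.
#' @export
compare_groups <- function(densities_by_group, var_equal = FALSE) {
  if (!is.list(densities_by_group) || length(densities_by_group) < 2L) {
    stop("need at least two groups")
  }
  n <- vapply(densities_by_group, length, integer(1))
  if (any(n < 2L)) stop("each group needs at least two values")
  if (is.null(names(densities_by_group))) {
    names(densities_by_group) <- paste0("group", seq_along(densities_by_group))
  }
  if (length(densities_by_group) == 2L) {
    tt <- stats::t.test(densities_by_group[[1]], densities_by_group[[2]],
                        var.equal = var_equal)
    return(list(
      method = if (var_equal) "two-sample t (pooled)" else "two-sample t (Welch)",
      statistic = unname(tt$statistic), p.value = tt$p.value,
      means = vapply(densities_by_group, mean, numeric(1))
    ))
  }
  df <- data.frame(
    value = unlist(densities_by_group, use.names = FALSE),
    group = factor(rep(names(densities_by_group), times = n))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    method = "one-way ANOVA + Tukey HSD",
    statistic = an[["F value"]][1], p.value = an[["Pr(>F)"]][1],
    tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL)
  )
}

#' Write a motif density report
#'
#' @param reports Data frame as returned by [region_density()] (rows from
#'   several motifs/strains may be concatenated; a `strain` column is added
#'   when absent).
#' @param path Output TSV path.
#' @param strain Strain label used when `reports` has no `strain` column.
#' @return The written data frame, invisibly.
#' @export
write_density_report <- function(reports, path, strain = NA_character_) {
  if (is.null(reports$strain)) {
    reports <- cbind(strain = strain, reports)
  }
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(reports)
}

#' GANTC count and density of an assembly
#'
#' Convenience validation entry point: scans GANTC in a user-supplied FASTA
#' assembly and reports the total site count and density per kb, the numbers
#' used to compare methylome inventories across published genomes.
#'
#' @param fasta_path Path to an assembly FASTA.
#' @param circular Logical, recycled over records.
#' @return A list with `count`, `genome_kb` and `density_per_kb`.
#' @export
validate_assembly <- function(fasta_path, circular = TRUE) {
  gen <- parse_genome(fasta_path, ori_spec = list(), circular = circular)
  m <- motif_spec("GANTC", 1, "m6A", partner_offset = 3)
  sites <- scan_motif(gen, m)
  kb <- sum(vapply(gen$replicons, `[[`, integer(1), "length")) / 1000
  list(count = nrow(sites), genome_kb = kb, density_per_kb = nrow(sites) / kb)
}
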