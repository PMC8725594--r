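# Recovery of degenerate methylated motifs from catalogues of methylated
# genomic positions (strand-oriented marks), by iterative greedy column
# consensus over the sequence contexts of the marks.
#
# Each greedy round: (1) extract +/- flank windows centred on the methylated
# base, oriented 5'->3' on the methylated strand; (2) per column assign a
# base when its frequency reaches `col_major`, a 2-fold IUPAC code when the
# top two bases reach `col_pair`, else N; (3) trim flanking Ns; (4) accept
# the candidate when its detection rate over genome occurrences reaches
# `min_detect` and it explains at least `min_explained_frac` of the
# remaining marks; (5) remove explained marks and repeat.
#
# Non-palindromic motifs methylated on both strands split the marks into two
# reverse-complement context families, which keeps every discriminating
# column below the majority threshold. When the whole-set candidate fails
# validation, the round therefore refines: windows are filtered on the single
# most concentrated sub-threshold column and the consensus re-derived,
# repeatedly, until a family dominates. After acceptance, a consistent
# opposite-strand mark offset within the occurrence footprint is detected
# and recorded as the partner offset, so both strand families of a bipartite
# motif are explained by one discovered motif.

#' Discover methylated motifs from marked positions
#'
#' @param gen A [genome()] (or single [replicon()]) supplying sequence
#'   context and occurrence counts.
#' @param marks Data frame of methylated positions with columns `replicon`,
#'   `pos` (1-based, position of the methylated base on its strand, in
#'   plus-strand coordinates), `strand`, and optionally `mod_type`
#'   (`"m6A"`/`"m4C"`; marks are partitioned by modification type when
#'   present).
#' @param flank Half-width of the context window (bp); the default spans
#'   the longest bipartite recognition sequences seen in practice (16 bp
#'   with the methylated base at offset 3).
#' @param col_major Single-base column assignment threshold.
#' @param col_pair Two-base (2-fold IUPAC) column assignment threshold;
#'   3-fold-degenerate columns are collapsed to N.
#' @param min_detect Minimum fraction of genome occurrences of a candidate
#'   that must be marked.
#' @param min_explained_frac Minimum fraction of the remaining marks a
#'   candidate must explain.
#' @param max_motifs Safety cap on the number of motifs per modification
#'   type.
#' @return Data frame of class `discovered_motifs`, one row per motif:
#'   `iupac`, `meth_offset`, `mod_type`, `partner_offset`, `detection_rate`,
#'   `explained`, `n_occurrences`.
#' @export
discover_motifs <- function(gen, marks, flank = 12L, col_major = 0.9,
                            col_pair = 0.95, min_detect = 0.5,
                            min_explained_frac = 0.01, max_motifs = 10L) {
  if (inherits(gen, "replicon")) gen <- genome(gen$name, list(gen))
  stopifnot(inherits(gen, "genome"))
  empty <- data.frame(
    iupac = character(0), meth_offset = integer(0), mod_type = character(0),
    partner_offset = integer(0), detection_rate = numeric(0),
    explained = integer(0), n_occurrences = integer(0),
    stringsAsFactors = FALSE
  )
  if (is.null(marks) || nrow(marks) == 0L) {
    return(structure(empty, class = c("discovered_motifs", "data.frame")))
  }
  if (is.null(marks$mod_type)) marks$mod_type <- "m6A"
  marks <- marks[marks$replicon %in% names(gen$replicons), , drop = FALSE]

  seq_chars <- lapply(gen$replicons, function(r) strsplit(r$sequence, "")[[1]])

  out <- empty
  for (mt in unique(marks$mod_type)) {
    marks_mt <- marks[marks$mod_type == mt, , drop = FALSE]
    rem <- marks_mt
    n0 <- nrow(rem)
    found <- 0L
    while (nrow(rem) >= max(10L, ceiling(min_explained_frac * n0)) &&
           found < max_motifs) {
      cand <- next_motif_candidate(gen, seq_chars, rem, marks_mt, mt, flank,
                                   col_major, col_pair, min_detect,
                                   ceiling(min_explained_frac * nrow(rem)))
      if (is.null(cand)) break
      out <- rbind(out, cand$row)
      rem <- rem[!cand$explained_idx, , drop = FALSE]
      found <- found + 1L
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("discovered_motifs", "data.frame"))
}

# One greedy round: consensus (with refinement on failure), validation, and
# partner-offset detection. Refinement first drops windows that mismatch the
# current specified columns (evicting unrelated/spurious contexts), then, if
# the consensus is stuck, splits on the most concentrated sub-threshold
# column (separating reverse-complement context families). Returns NULL
# when no acceptable motif remains.
next_motif_candidate <- function(gen, seq_chars, rem, marks_all, mod_type,
                                 flank, col_major, col_pair, min_detect,
                                 min_explained) {
  W <- extract_windows(seq_chars, gen$replicons, rem, flank)
  sel <- rep(TRUE, nrow(W))
  floor_n <- max(20L, min_explained)
  tried <- 0L
  repeat {
    cons <- column_consensus(W[sel, , drop = FALSE], col_major, col_pair)
    cand <- trim_consensus(cons, flank)
    if (!is.null(cand)) {
      val <- validate_candidate(gen, rem, marks_all, cand, mod_type,
                                min_detect, min_explained)
      if (!is.null(val)) return(val)
    }
    tried <- tried + 1L
    if (tried > 2L * flank) return(NULL)
    # refinement 1: restrict to windows matching the specified columns
    if (any(cons != "N")) {
      keep <- sel & windows_match(W, cons)
      if (sum(keep) >= floor_n && sum(keep) < sum(sel)) {
        sel <- keep
        next
      }
    }
    # refinement 2: split on the best sub-threshold column
    filt <- best_subthreshold_column(W[sel, , drop = FALSE], cons, col_major)
    if (is.null(filt)) return(NULL)
    keep <- sel & (W[, filt$col] == filt$base)
    if (sum(keep) < floor_n || sum(keep) == sum(sel)) return(NULL)
    sel <- keep
  }
}

# Rows of W whose bases are compatible with every specified (non-N)
# consensus column.
windows_match <- function(W, cons) {
  ok <- rep(TRUE, nrow(W))
  for (j in which(cons != "N")) {
    allowed <- strsplit(IUPAC_CLASSES[[cons[j]]], "")[[1]]
    ok <- ok & (W[, j] %in% allowed)
  }
  ok
}

# Context windows, oriented 5'->3' on the methylated strand; one row per
# mark, 2*flank+1 columns, methylated base in the centre column.
extract_windows <- function(seq_chars, replicons, marks, flank) {
  offs <- -flank:flank
  n <- nrow(marks)
  W <- matrix(NA_character_, n, length(offs))
  for (rn in unique(marks$replicon)) {
    sc <- seq_chars[[rn]]
    len <- length(sc)
    idx_rows <- which(marks$replicon == rn)
    pos <- marks$pos[idx_rows]
    idx <- outer(pos, offs, `+`)
    idx <- ((idx - 1L) %% len) + 1L   # circular wrap
    W[idx_rows, ] <- sc[idx]
  }
  minus <- marks$strand == "-"
  if (any(minus)) {
    Wm <- W[minus, , drop = FALSE]
    Wm[] <- chartr("ACGT", "TGCA", Wm)
    W[minus, ] <- Wm[, rev(seq_along(offs)), drop = FALSE]
  }
  W
}

# Per-column IUPAC consensus: base, 2-fold code, or N.
column_consensus <- function(W, col_major, col_pair) {
  apply(W, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab) / max(sum(tab), 1L)
    names(f) <- names(tab)
    ord <- order(f, decreasing = TRUE)
    if (f[ord[1]] >= col_major) return(names(f)[ord[1]])
    if (f[ord[1]] + f[ord[2]] >= col_pair) {
      pair <- sort(names(f)[ord[1:2]])
      return(unname(TWOFOLD_CODES[paste(pair, collapse = "")]))
    }
    "N"
  })
}

# Trim flanking Ns; NULL when fewer than 4 specified columns or the
# methylated centre column got trimmed away.
trim_consensus <- function(cons, flank) {
  spec <- which(cons != "N")
  if (length(spec) < 4L) return(NULL)
  lo <- min(spec)
  hi <- max(spec)
  centre <- flank + 1L
  if (centre < lo || centre > hi) return(NULL)
  list(iupac = paste(cons[lo:hi], collapse = ""),
       meth_offset = centre - lo)
}

best_subthreshold_column <- function(W, cons, col_major) {
  ncols <- ncol(W)
  best <- NULL
  best_f <- 0
  for (j in seq_len(ncols)) {
    if (cons[j] != "N") next
    tab <- table(factor(W[, j], levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab) / max(sum(tab), 1L)
    i <- which.max(f)
    if (f[i] > best_f && f[i] < col_major) {
      best_f <- f[i]
      best <- list(col = j, base = c("A", "C", "G", "T")[i], freq = f[i])
    }
  }
  # only worth filtering when the column is informative at all
  if (!is.null(best) && best$freq < 0.45) return(NULL)
  best
}

# Validate a candidate: scan it, compute detection rate over occurrences and
# explained marks; detect a partner-strand offset among the unexplained
# opposite-strand marks. Returns NULL on rejection.
validate_candidate <- function(gen, rem, marks_all, cand, mod_type,
                               min_detect, min_explained) {
  mb <- substr(cand$iupac, cand$meth_offset + 1L, cand$meth_offset + 1L)
  required <- if (mod_type == "m6A") "A" else "C"
  if (!grepl(required, IUPAC_CLASSES[[mb]], fixed = TRUE)) return(NULL)
  spec <- motif_spec(cand$iupac, cand$meth_offset, mod_type)
  occ <- scan_motif(gen, spec)
  if (nrow(occ) == 0L) return(NULL)

  # detection against the full catalogue (sites explained by an earlier,
  # overlapping motif still count as methylated); explanation against the
  # remaining marks only, so accepted motifs stay disjoint
  all_key <- paste(marks_all$replicon, marks_all$pos, marks_all$strand)
  mark_key <- paste(rem$replicon, rem$pos, rem$strand)
  occ_key <- paste(occ$replicon, occ$meth_pos, occ$strand)
  detection_rate <- mean(occ_key %in% all_key)
  explained_idx <- mark_key %in% occ_key
  if (detection_rate < min_detect) return(NULL)
  if (sum(explained_idx) < min_explained) return(NULL)

  # partner-strand detection: opposite-strand marks at a consistent offset
  # within the occurrence footprint
  partner_offset <- NA_integer_
  k <- nchar(spec$iupac)
  rem2 <- rem[!explained_idx, , drop = FALSE]
  if (nrow(rem2) > 0L) {
    hits <- stats::setNames(integer(k), as.character(0:(k - 1L)))
    for (rn in unique(occ$replicon)) {
      o <- occ[occ$replicon == rn, , drop = FALSE]
      m2 <- rem2[rem2$replicon == rn, , drop = FALSE]
      if (nrow(m2) == 0L) next
      len <- gen$replicons[[rn]]$length
      opp <- ifelse(o$strand == "+", "-", "+")
      key_m <- paste(m2$pos, m2$strand)
      for (d in 0:(k - 1L)) {
        ppos <- ifelse(o$strand == "+", o$start + d, o$start - d)
        ppos <- wrap_pos(ppos, len)
        key_p <- paste(ppos, opp)
        hits[[as.character(d)]] <- hits[[as.character(d)]] +
          sum(key_p %in% key_m)
      }
    }
    if (max(hits) > 0L) {
      dbest <- names(hits)[which.max(hits)]
      if (hits[[dbest]] >= 0.5 * nrow(occ)) {
        partner_offset <- as.integer(dbest)
        spec_p <- motif_spec(cand$iupac, cand$meth_offset, mod_type,
                             partner_offset = partner_offset)
        ss <- motif_strand_sites(
          occ, spec_p,
          rep_lengths = vapply(gen$replicons, `[[`, integer(1), "length"))
        ss_key <- paste(ss$replicon, ss$meth_pos, ss$strand)
        explained_idx <- mark_key %in% ss_key
      }
    }
  }

  list(
    row = data.frame(
      iupac = cand$iupac, meth_offset = cand$meth_offset,
      mod_type = mod_type, partner_offset = partner_offset,
      detection_rate = detection_rate,
      explained = sum(explained_idx), n_occurrences = nrow(occ),
      stringsAsFactors = FALSE
    ),
    explained_idx = explained_idx
  )
}

#' Are two IUPAC motifs the same duplex motif?
#'
#' Two discovered motifs describe the same duplex recognition sequence when
#' they are equal or reverse complements of one another.
#'
#' @param a,b IUPAC strings.
#' @return Logical.
#' @export
motif_equivalent <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  identical(a, b) || identical(iupac_revcomp(a), b)
}

#' Canonical form of a duplex motif
#'
#' The lexicographically smaller of a motif and its reverse complement, so
#' the two orientations of a non-palindromic motif collapse to one name.
#'
#' @param iupac IUPAC string (vectorised).
#' @return Character vector.
#' @export
canonical_motif <- function(iupac) {
  vapply(toupper(iupac), function(m) {
    rc <- iupac_revcomp(m)
    if (rc < m) rc else m
  }, character(1), USE.NAMES = FALSE)
}

#' Write discovered motifs as TSV
#' @param motifs A `discovered_motifs` data frame.
#' @param path Output path.
#' @return `motifs`, invisibly.
#' @export
write_discovered_motifs <- function(motifs, path) {
  utils::write.table(as.data.frame(motifs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(motifs)
}
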