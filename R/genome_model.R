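# Genome containers and the ori-anchored circular coordinate frame.
#
# Coordinates are 1-based inclusive (GFF3 convention) throughout; circular
# arithmetic is modulo the replicon length. For replication-timing purposes
# ter is modelled as the antipode of ori (symmetric bidirectional forks); a
# GC-skew-derived terminus, when available, is stored separately as
# `skew_ter_pos` and never used by the timing model.

#' Construct a replicon
#'
#' A replicon is a (usually circular) DNA sequence with an origin of
#' replication and a terminus. The terminus used by all replication-timing
#' computations is the antipode of the origin, reflecting bidirectional forks
#' travelling at equal speed; a terminus estimated independently (e.g. from
#' cumulative GC skew) can be attached as `skew_ter_pos`.
#'
#' @param name Replicon identifier (e.g. `"chromosome"`, `"pSymA"`).
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (a single character
#'   string or a [Biostrings::DNAString]).
#' @param circular Logical; circular replicons wrap in all coordinate
#'   arithmetic.
#' @param ori_pos 1-based position of the origin of replication.
#' @param skew_ter_pos Optional 1-based terminus position estimated from data
#'   (reported, never used for timing).
#' @return An object of class `replicon`: a list with fields `name`,
#'   `sequence` (character), `length`, `circular`, `ori_pos`, `ter_pos`
#'   (antipode of `ori_pos`) and `skew_ter_pos`.
#' @examples
#' rep <- replicon("chr", "ACGTACGTAC", ori_pos = 1)
#' rep$ter_pos
#' @export
replicon <- function(name, sequence, circular = TRUE, ori_pos = 1L,
                     skew_ter_pos = NA_integer_) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("replicon sequence may only contain A, C, G, T, N")
  }
  len <- nchar(sequence)
  ori_pos <- as.integer(ori_pos)
  if (ori_pos < 1L || ori_pos > len) {
    stop("ori_pos out of range for replicon '", name, "'")
  }
  structure(
    list(
      name = as.character(name),
      sequence = sequence,
      length = len,
      circular = isTRUE(circular),
      ori_pos = ori_pos,
      ter_pos = antipode(ori_pos, len),
      skew_ter_pos = as.integer(skew_ter_pos)
    ),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf(
    "<replicon> %s: %s bp, %s, ori=%d, ter=%d (antipode)\n",
    x$name, format(x$length, big.mark = ","),
    if (x$circular) "circular" else "linear", x$ori_pos, x$ter_pos
  ))
  invisible(x)
}

# Antipode of a 1-based position on a circle of length len.
antipode <- function(pos, len) {
  as.integer(((pos - 1L + len %/% 2L) %% len) + 1L)
}

# Wrap a (possibly out-of-range) 1-based coordinate onto [1, len].
wrap_pos <- function(pos, len) {
  as.integer(((pos - 1L) %% len) + 1L)
}

#' Construct a genome
#'
#' A genome bundles one or more replicons with a gene annotation table. Gene
#' models carry a `transcript_id` so that promoters, which belong to
#' transcripts, can be shared by the genes of an operon.
#'
#' @param strain Strain identifier.
#' @param replicons A list of [replicon()] objects (names taken from the
#'   replicons themselves; must be unique).
#' @param annotation A data frame with columns `gene_id`, `transcript_id`,
#'   `replicon`, `start`, `end`, `strand` (1-based inclusive coordinates,
#'   strand `"+"` or `"-"`), or `NULL` for an unannotated genome.
#' @return An object of class `genome`.
#' @export
genome <- function(strain, replicons, annotation = NULL) {
  stopifnot(is.list(replicons), length(replicons) >= 1L)
  ok <- vapply(replicons, inherits, logical(1), what = "replicon")
  if (!all(ok)) stop("all elements of `replicons` must be replicon objects")
  nm <- vapply(replicons, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("replicon names must be unique")
  names(replicons) <- nm
  annotation <- validate_annotation(annotation, replicons)
  structure(
    list(strain = as.character(strain), replicons = replicons,
         annotation = annotation),
    class = "genome"
  )
}

validate_annotation <- function(annotation, replicons) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(empty_annotation())
  }
  need <- c("gene_id", "transcript_id", "replicon", "start", "end", "strand")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols)) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  annotation <- as.data.frame(annotation)[need]
  annotation$start <- as.integer(annotation$start)
  annotation$end <- as.integer(annotation$end)
  if (any(annotation$start > annotation$end)) {
    stop("gene models must satisfy start <= end")
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  unknown <- setdiff(unique(annotation$replicon), names(replicons))
  if (length(unknown)) {
    stop("gene models reference unknown replicon(s): ",
         paste(unknown, collapse = ", "))
  }
  lens <- vapply(replicons, `[[`, integer(1), "length")
  if (any(annotation$end > lens[annotation$replicon]) ||
      any(annotation$start < 1L)) {
    stop("gene model outside replicon sequence bounds")
  }
  rownames(annotation) <- NULL
  annotation
}

empty_annotation <- function() {
  data.frame(
    gene_id = character(0), transcript_id = character(0),
    replicon = character(0), start = integer(0), end = integer(0),
    strand = character(0), stringsAsFactors = FALSE
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> strain %s: %d replicon(s), %d gene model(s)\n",
              x$strain, length(x$replicons), nrow(x$annotation)))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Builds a [genome()] from a multi-record FASTA file and (optionally) a GFF3
#' annotation. Origins of replication are either given explicitly per
#' replicon or inferred from the extrema of the cumulative GC skew
#' (origin at the global minimum, data-derived terminus at the global
#' maximum). Skew inference assumes a chromosome-style leading-strand G
#' excess; for repABC replicons (rhizobial megaplasmids/chromids) the skew
#' signal can be weak, so inferred origins there should be treated as
#' provisional.
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param gff_path Optional path to a GFF3 file; features of type `gene` are
#'   used, with `ID` (or `locus_tag`) as the gene id and a `transcript_id`
#'   attribute (defaulting to the gene id) grouping genes into transcripts.
#' @param ori_spec Either the string `"infer"`, or a named vector/list of
#'   1-based origin positions keyed by replicon name (replicons without an
#'   entry default to position 1).
#' @param circular Logical, recycled over replicons.
#' @param skew_window Window size (bp) for skew-based origin inference.
#' @return A [genome()] object.
#' @export
parse_genome <- function(fasta_path, gff_path = NULL, ori_spec = "infer",
                         circular = TRUE, skew_window = 10000L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate FASTA record names")
  names(seqs) <- nm
  circular <- rep_len(circular, length(seqs))

  reps <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    seq_chr <- as.character(seqs[[i]])
    len <- nchar(seq_chr)
    skew_ter <- NA_integer_
    if (identical(ori_spec, "infer")) {
      win <- min(as.integer(skew_window), len)
      sk <- cumulative_gc_skew_seq(seq_chr, window = win)
      ori <- attr(sk, "min_pos")
      skew_ter <- attr(sk, "max_pos")
    } else {
      ori <- if (!is.null(ori_spec[[nm[i]]])) as.integer(ori_spec[[nm[i]]]) else 1L
      if (is.na(ori) || ori < 1L || ori > len) {
        stop("unresolvable ori_spec for replicon '", nm[i], "'")
      }
    }
    reps[[i]] <- replicon(nm[i], seq_chr, circular = circular[i],
                          ori_pos = ori, skew_ter_pos = skew_ter)
  }

  annotation <- if (!is.null(gff_path)) read_gene_models(gff_path) else NULL
  genome(strain = sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                      basename(fasta_path)),
         replicons = reps, annotation = annotation)
}

read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) return(empty_annotation())
  mc <- S4Vectors::mcols(gr)
  gene_id <- if (!is.null(mc$ID)) as.character(mc$ID) else
    if (!is.null(mc$locus_tag)) as.character(mc$locus_tag) else
      paste0("gene", seq_along(gr))
  transcript_id <- if (!is.null(mc$transcript_id))
    as.character(mc$transcript_id) else gene_id
  transcript_id[is.na(transcript_id)] <- gene_id[is.na(transcript_id)]
  data.frame(
    gene_id = gene_id,
    transcript_id = transcript_id,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Replication arm fraction of a position
#'
#' Fractional position of a locus along its replication arm: 0 at the origin,
#' 1 at the antipode of the origin, where the two bidirectional forks meet.
#' With forks of equal constant speed, a locus at arm fraction `f` is
#' replicated a fraction `f` of the way through the replication (C) period.
#'
#' @param rep A [replicon()].
#' @param pos Vector of 1-based positions.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' r <- replicon("chr", strrep("ACGT", 250), ori_pos = 1)
#' arm_fraction(r, c(1, 251, 501))
#' @export
arm_fraction <- function(rep, pos) {
  stopifnot(inherits(rep, "replicon"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > rep$length)) stop("position out of range")
  d <- abs(pos - rep$ori_pos)
  d <- pmin(d, rep$length - d)  # circular distance to ori
  d / (rep$length / 2)
}

#' GC fraction of a replicon
#' @param rep A [replicon()].
#' @return Fraction of G+C among non-N bases.
#' @export
gc_fraction <- function(rep) {
  stopifnot(inherits(rep, "replicon"))
  f <- Biostrings::letterFrequency(Biostrings::DNAString(rep$sequence),
                                   letters = c("G", "C", "A", "T"))
  unname((f[["G"]] + f[["C"]]) / sum(f))
}

#' Write a genome summary table
#'
#' One row per replicon: name, length, GC fraction, origin position, the
#' antipodal terminus used by the timing model, and the skew-derived terminus
#' when available.
#'
#' @param gen A [genome()].
#' @param path Output TSV path.
#' @return The summary data frame, invisibly.
#' @export
write_genome_summary <- function(gen, path) {
  stopifnot(inherits(gen, "genome"))
  df <- data.frame(
    replicon = vapply(gen$replicons, `[[`, character(1), "name"),
    length = vapply(gen$replicons, `[[`, integer(1), "length"),
    gc = vapply(gen$replicons, gc_fraction, numeric(1)),
    ori = vapply(gen$replicons, `[[`, integer(1), "ori_pos"),
    ter = vapply(gen$replicons, `[[`, integer(1), "ter_pos"),
    skew_ter = vapply(gen$replicons, `[[`, integer(1), "skew_ter_pos"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a genome to FASTA and GFF3
#'
#' Round-trip companion to [parse_genome()]: the FASTA holds one record per
#' replicon and the GFF3 one `gene` feature per gene model with `ID` and
#' `transcript_id` attributes.
#'
#' @param gen A [genome()].
#' @param fasta_path Output FASTA path.
#' @param gff_path Optional output GFF3 path.
#' @return `gen`, invisibly.
#' @export
write_genome <- function(gen, fasta_path, gff_path = NULL) {
  stopifnot(inherits(gen, "genome"))
  seqs <- Biostrings::DNAStringSet(
    vapply(gen$replicons, `[[`, character(1), "sequence"))
  names(seqs) <- names(gen$replicons)
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(gff_path)) {
    ann <- gen$annotation
    con <- file(gff_path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (r in gen$replicons) {
      writeLines(sprintf("##sequence-region %s 1 %d", r$name, r$length), con)
    }
    if (nrow(ann)) {
      writeLines(sprintf(
        "%s\tmethylcycle\tgene\t%d\t%d\t.\t%s\t.\tID=%s;transcript_id=%s",
        ann$replicon, ann$start, ann$end, ann$strand, ann$gene_id,
        ann$transcript_id), con)
    }
  }
  invisible(gen)
}
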