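# Relative replicon copy number from windowed sequencing depth.
#
# Mean depth per replicon is the unweighted mean of 10-kb window means;
# degenerate edge windows shorter than half a window are dropped for
# robustness to lengths that are not window multiples. Depth ratios relative
# to the chromosome are the observable that copy-number conclusions rest on.

#' Read / write windowed depth tables
#'
#' TSV with columns `replicon`, `center` (1-based window centre) and `depth`
#' (mean depth of the window) -- the reduction of a position-level coverage
#' track that standard alignment tooling produces upstream.
#'
#' @param path File path.
#' @param depths Data frame with the columns above.
#' @return The data frame (invisibly for the writer).
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicon", "center", "depth")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("depth table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$depth < 0)) stop("depths must be >= 0")
  df
}

#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(depths)
}

#' Relative sequencing depth of replicons
#'
#' Per-replicon mean depth (unweighted mean of window means) divided by the
#' mean depth of a reference replicon, conventionally the chromosome of the
#' same sample; the reference ratio is identically 1.
#'
#' @param depths Windowed depth table (`replicon`, `center`, `depth`).
#' @param reference Name of the reference replicon.
#' @return Data frame with columns `replicon`, `mean_depth`, `ratio`.
#' @export
relative_depth <- function(depths, reference) {
  if (!reference %in% depths$replicon) {
    stop("reference replicon '", reference, "' absent from depth table")
  }
  means <- tapply(depths$depth, depths$replicon, mean)
  ref <- means[[reference]]
  if (ref == 0) stop("reference replicon has zero mean depth")
  out <- data.frame(
    replicon = names(means),
    mean_depth = as.numeric(means),
    ratio = as.numeric(means) / ref,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$replicon != reference, out$replicon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent depth reduction implied by a ratio
#'
#' `100 * (1 - ratio)`: a secondary replicon at two copies per three
#' chromosome copies (ratio 2/3) is ~33% reduced.
#'
#' @param ratio Depth ratio(s) in (0, Inf).
#' @return Percent reduction (negative for ratios above 1).
#' @export
percent_reduction <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  100 * (1 - ratio)
}

#' Windowed mean depth from a position-level coverage vector
#'
#' Helper to reduce per-base depth to the windowed dialect; windows shorter
#' than half the window size at the replicon end are dropped.
#'
#' @param coverage Numeric vector of per-base depth.
#' @param replicon_name Replicon label for the output.
#' @param window Window size in bp.
#' @return Data frame `replicon`, `center`, `depth`.
#' @export
window_depth <- function(coverage, replicon_name, window = 10000L) {
  len <- length(coverage)
  window <- as.integer(window)
  starts <- seq.int(1L, len, by = window)
  ends <- pmin(starts + window - 1L, len)
  keep <- (ends - starts + 1L) >= window / 2
  starts <- starts[keep]
  ends <- ends[keep]
  depth <- vapply(seq_along(starts), function(i) {
    mean(coverage[starts[i]:ends[i]])
  }, numeric(1))
  data.frame(
    replicon = replicon_name,
    center = as.integer((starts + ends) %/% 2L),
    depth = depth,
    stringsAsFactors = FALSE
  )
}
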