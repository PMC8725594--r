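# Extent-of-methylation statistics from per-site call tables.
#
# The unit of every statistic is the strand-site: each strand of a duplex
# motif site is an independent observation, so a hemimethylated duplex
# contributes fractions {1, 0}. Window means are unweighted by coverage
# because the extent is already a per-site estimate.

METH_COLS <- c("replicon", "meth_pos", "strand", "motif", "fraction",
               "coverage", "replicate")

#' Read / write methylation-call tables
#'
#' The call-table dialect is a TSV with columns `replicon`, `meth_pos`
#' (1-based), `strand` (`+`/`-`), `motif`, `fraction` (estimated methylated
#' fraction in `[0, 1]`), `coverage` and `replicate` -- the minimal schema
#' that per-site base-modification output (e.g. SMRT-Link motif/modification
#' GFFs) reduces to.
#'
#' @param path File path.
#' @param records Data frame with the columns above.
#' @return `read_methylation_tsv()` returns the validated data frame;
#'   `write_methylation_tsv()` returns `records` invisibly.
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_methylation_records(df)
}

#' @rdname read_methylation_tsv
#' @export
write_methylation_tsv <- function(records, path) {
  records <- validate_methylation_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}

validate_methylation_records <- function(df) {
  missing_cols <- setdiff(METH_COLS, names(df))
  if (length(missing_cols)) {
    stop("methylation records lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[METH_COLS]
  df$meth_pos <- as.integer(df$meth_pos)
  df$fraction <- as.numeric(df$fraction)
  df$coverage <- as.integer(df$coverage)
  if (any(df$fraction < 0 | df$fraction > 1, na.rm = TRUE)) {
    stop("fraction must lie in [0, 1]")
  }
  if (any(df$coverage < 0, na.rm = TRUE)) stop("coverage must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

# Average replicates per strand-site (mean of fractions, coverage summed).
average_replicates <- function(records) {
  key <- interaction(records$replicon, records$meth_pos, records$strand,
                     records$motif, drop = TRUE)
  agg <- data.frame(
    replicon = tapply(records$replicon, key, `[`, 1),
    meth_pos = as.integer(tapply(records$meth_pos, key, `[`, 1)),
    strand = tapply(records$strand, key, `[`, 1),
    motif = tapply(records$motif, key, `[`, 1),
    fraction = as.numeric(tapply(records$fraction, key, mean)),
    coverage = as.integer(tapply(records$coverage, key, sum)),
    stringsAsFactors = FALSE
  )
  agg$replicate <- "averaged"
  rownames(agg) <- NULL
  agg
}

#' Sliding-window extent-of-methylation profile
#'
#' Computes, along one replicon, the mean extent of methylation of all
#' strand-sites falling in each sliding window. Records from several
#' replicates are first averaged per strand-site. Windows are centred on a
#' regular grid of `step` bp and wrap around the origin junction of circular
#' replicons; empty windows carry `n_sites = 0` and `NA` extent.
#'
#' @param records Methylation call records (one motif; several replicates
#'   allowed).
#' @param rep The [replicon()] profiled.
#' @param window Window size in bp (default 10 kb).
#' @param step Step between window centres in bp (default 1 kb).
#' @return An object of class `extent_profile`: list with `replicon`,
#'   `window`, `step`, `length`, `ori_pos`, `points` (data frame `center`,
#'   `mean_extent`, `n_sites`), `trend` (`NULL` until [fit_trend()]) and
#'   `pattern`.
#' @export
window_extent <- function(records, rep, window = 10000L, step = 1000L) {
  stopifnot(inherits(rep, "replicon"))
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < step) warning("window smaller than step: windows leave gaps")
  records <- records[records$replicon == rep$name, , drop = FALSE]
  if (nrow(records) && length(unique(records$replicate)) > 1L) {
    records <- average_replicates(records)
  }
  centers <- seq.int(1L, rep$length, by = step)
  half <- window / 2

  if (nrow(records) == 0L) {
    pts <- data.frame(center = centers, mean_extent = NA_real_, n_sites = 0L)
  } else {
    ord <- order(records$meth_pos)
    pos <- records$meth_pos[ord]
    frac <- records$fraction[ord]
    # unwrap the circle: replicate sites one period to the left and right so
    # any window [c - w/2, c + w/2) is a plain interval
    pos3 <- c(pos - rep$length, pos, pos + rep$length)
    frac3 <- c(frac, frac, frac)
    cs <- c(0, cumsum(frac3))
    lo <- centers - half
    hi <- centers + half
    i_lo <- findInterval(lo - 0.5, pos3)       # sites with pos >= lo
    i_hi <- findInterval(hi - 0.5, pos3)       # sites with pos < hi
    n <- i_hi - i_lo
    total <- cs[i_hi + 1L] - cs[i_lo + 1L]
    pts <- data.frame(
      center = centers,
      mean_extent = ifelse(n > 0, total / n, NA_real_),
      n_sites = as.integer(n)
    )
  }
  structure(
    list(replicon = rep$name, window = window, step = step,
         length = rep$length, ori_pos = rep$ori_pos, points = pts,
         trend = NULL, pattern = NULL),
    class = "extent_profile"
  )
}

#' @export
print.extent_profile <- function(x, ...) {
  filled <- x$points$n_sites > 0
  cat(sprintf(
    "<extent_profile> %s: %d windows (%d bp / step %d bp), mean extent %.3f%s\n",
    x$replicon, nrow(x$points), x$window, x$step,
    mean(x$points$mean_extent[filled]),
    if (is.null(x$pattern)) "" else paste0(", pattern=", x$pattern)))
  invisible(x)
}

#' Robust quadratic trend of an extent profile
#'
#' Fits a degree-2 polynomial to the windowed extents by iteratively
#' reweighted least squares with Huber weights (tuning constant 1.345 times
#' the robust scale) on an orthogonalised predictor, the `rlm(y ~ poly(x, 2))`
#' fit conventionally drawn over such profiles. The predictor is the genome
#' coordinate rotated so the origin maps to 0 (ter to `length/2`), which
#' linearises the replicon at ori.
#'
#' @param profile An [window_extent()] profile with at least 6 non-empty
#'   points.
#' @param maxit Maximum IRLS iterations.
#' @param acc Convergence tolerance on the coefficient updates.
#' @return The profile with a `trend` element: list with `coefficients`
#'   (length 3, orthogonal-polynomial basis), `model` (the `rlm` fit),
#'   `scale` (robust residual scale) and `iterations`.
#' @export
fit_trend <- function(profile, maxit = 50L, acc = 1e-8) {
  stopifnot(inherits(profile, "extent_profile"))
  pts <- profile$points[profile$points$n_sites > 0, , drop = FALSE]
  if (nrow(pts) < 6L) stop("need at least 6 non-empty windows to fit a trend")
  x <- rotate_coord(pts$center, profile$ori_pos, profile$length)
  y <- pts$mean_extent
  # degenerate case: (near-)exact polynomial data has zero robust scale, on
  # which IRLS cannot iterate -- the least-squares fit is then already the
  # robust fit
  ls_fit <- stats::lm(y ~ poly(x, 2))
  if (sqrt(mean(stats::residuals(ls_fit)^2)) < 1e-10) {
    fit <- ls_fit
    scale <- 0
    iters <- 0L
  } else {
    fit <- MASS::rlm(y ~ poly(x, 2), psi = MASS::psi.huber, k = 1.345,
                     maxit = maxit, acc = acc)
    scale <- fit$s
    iters <- length(fit$conv)
  }
  profile$trend <- list(
    coefficients = unname(stats::coef(fit)),
    model = fit,
    scale = scale,
    iterations = iters
  )
  profile
}

# Rotate a genome coordinate so ori -> 0 and the antipode -> length/2.
rotate_coord <- function(pos, ori, len) {
  (pos - ori) %% len
}

#' Classify an extent profile as frowning, smiling or flat
#'
#' Evaluates the fitted quadratic trend at the origin-proximal ends and at
#' the terminus (the midpoint of the replicon linearised at ori) and labels
#' the profile by the ter-minus-ori extent difference: greater than `theta`
#' is `ascending_to_ter` (the "frowning" profile of exponential growth),
#' less than `-theta` is `descending_to_ter` (the "smiling" bacteroid
#' profile), otherwise `flat`.
#'
#' @param profile An [window_extent()] profile; [fit_trend()] is applied if
#'   it has no trend yet.
#' @param theta Extent difference below which the profile counts as flat.
#' @return The profile with its `pattern` element set; the pattern string is
#'   also attached as attribute `"pattern"` of the return value for
#'   convenience via [profile_pattern()].
#' @export
classify_pattern <- function(profile, theta = 0.02) {
  stopifnot(inherits(profile, "extent_profile"))
  if (is.null(profile$trend)) profile <- fit_trend(profile)
  fit <- profile$trend$model
  ends <- data.frame(x = c(0, profile$length, profile$length / 2))
  pred <- stats::predict(fit, newdata = ends)
  e_ori <- mean(pred[1:2])
  e_ter <- pred[3]
  diff <- e_ter - e_ori
  profile$pattern <- if (diff > theta) "ascending_to_ter"
    else if (diff < -theta) "descending_to_ter" else "flat"
  profile$trend$ori_extent <- e_ori
  profile$trend$ter_extent <- e_ter
  profile
}

#' @rdname classify_pattern
#' @export
profile_pattern <- function(profile, theta = 0.02) {
  classify_pattern(profile, theta)$pattern
}

#' Persistently hypomethylated strand-sites
#'
#' Strand-sites whose estimated methylated fraction stays below `tau` (or
#' which are absent from the call table) in every replicate -- the signature
#' of sites the methyltransferase repeatedly fails to methylate, e.g.
#' because a bound protein occludes them.
#'
#' @param records Methylation call records across >= 2 replicates.
#' @param tau Fraction threshold below which a call counts as unmethylated.
#' @param sites Optional universe of strand-sites (data frame `replicon`,
#'   `meth_pos`, `strand`, e.g. from [motif_strand_sites()]); defaults to
#'   the union of strand-sites observed in any replicate. Sites in the
#'   universe never called in a replicate count as hypomethylated there.
#' @return Data frame of flagged strand-sites with the number of replicates,
#'   mean observed fraction and minimum coverage.
#' @export
persistent_hypomethylated <- function(records, tau = 0.2, sites = NULL) {
  reps <- unique(records$replicate)
  if (length(reps) < 2L) stop("need at least two replicates")
  if (is.null(sites)) {
    sites <- unique(records[c("replicon", "meth_pos", "strand")])
  }
  key_all <- paste(sites$replicon, sites$meth_pos, sites$strand)
  hypo <- rep(TRUE, nrow(sites))
  frac_sum <- numeric(nrow(sites))
  frac_n <- integer(nrow(sites))
  cov_min <- rep(NA_integer_, nrow(sites))
  for (r in reps) {
    rr <- records[records$replicate == r, , drop = FALSE]
    key_r <- paste(rr$replicon, rr$meth_pos, rr$strand)
    idx <- match(key_all, key_r)
    frac <- rr$fraction[idx]          # NA -> absent -> hypomethylated
    hypo <- hypo & (is.na(frac) | frac < tau)
    seen <- !is.na(frac)
    frac_sum[seen] <- frac_sum[seen] + frac[seen]
    frac_n[seen] <- frac_n[seen] + 1L
    cov_r <- rr$coverage[idx]
    cov_min <- pmin(cov_min, cov_r, na.rm = TRUE)
    cov_min[is.na(frac) & is.na(cov_min)] <- 0L
  }
  out <- sites[hypo, , drop = FALSE]
  out$n_replicates <- rep(length(reps), nrow(out))
  out$mean_fraction <- ifelse(frac_n[hypo] > 0,
                              frac_sum[hypo] / frac_n[hypo], NA_real_)
  out$min_coverage <- cov_min[hypo]
  rownames(out) <- NULL
  out
}

#' Mean extent of methylation of a replicon
#'
#' Unweighted mean of the per-strand-site fractions over a replicon, after
#' averaging replicates per site.
#'
#' @param records Methylation call records.
#' @param rep A [replicon()] or replicon name.
#' @return Mean extent in `[0, 1]`.
#' @export
replicon_mean_extent <- function(records, rep) {
  name <- if (inherits(rep, "replicon")) rep$name else as.character(rep)
  records <- records[records$replicon == name, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records for replicon '", name, "'")
  if (length(unique(records$replicate)) > 1L) {
    records <- average_replicates(records)
  }
  mean(records$fraction)
}

#' Write an extent profile as TSV
#' @param profile An [window_extent()] profile.
#' @param path Output path.
#' @return The points data frame, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "extent_profile"))
  utils::write.table(profile$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(profile$points)
}
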