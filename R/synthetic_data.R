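# Generators for every input the pipeline consumes: random genomes of
# controlled GC content, strain fixtures carrying defined motif inventories,
# methylation-call tables from cell-state mixtures with binomial sampling
# noise, and Poisson depth profiles with specified replicon copy ratios.
#
# Fixture genomes are ~1 Mb rather than full rhizobial size so complete
# analyses run in minutes; densities, not absolute counts, are the
# quantities compared at fixture scale. Every generator is deterministic
# under a fixed seed.

#' Random genome sequence of controlled GC content
#'
#' I.i.d. bases with p(G) = p(C) = gc/2 and p(A) = p(T) = (1 - gc)/2;
#' circular, origin at position 1 by default.
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction in (0, 1); the 0.619 default is the average GC
#'   content of the genus the fixtures emulate.
#' @param seed Optional integer seed.
#' @param name Replicon name.
#' @param ori_pos Origin position.
#' @return A [replicon()].
#' @export
random_genome <- function(length, gc = 0.619, seed = NULL,
                          name = "chromosome", ori_pos = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  run <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }
  seq <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  replicon(name, seq, circular = TRUE, ori_pos = ori_pos)
}

#' Random gene annotation for a replicon
#'
#' Tiles the replicon with gene models of geometric-ish lengths separated by
#' intergenic gaps, alternating strand, one transcript per gene. Intended
#' for coding/intergenic partitions and promoter analyses on synthetic
#' genomes; it makes no attempt at realistic gene structure beyond coding
#' density.
#'
#' @param rep A [replicon()].
#' @param mean_gene Mean gene length (bp).
#' @param mean_gap Mean intergenic gap (bp).
#' @param seed Optional integer seed.
#' @param prefix Gene id prefix.
#' @return Annotation data frame (see [genome()]).
#' @export
random_annotation <- function(rep, mean_gene = 900L, mean_gap = 150L,
                              seed = NULL, prefix = "g") {
  run <- function() {
    pos <- 1L
    rows <- list()
    i <- 0L
    while (pos < rep$length - mean_gene) {
      gap <- stats::rgeom(1, 1 / mean_gap) + 1L
      glen <- stats::rgeom(1, 1 / mean_gene) + 100L
      start <- pos + gap
      end <- min(start + glen - 1L, rep$length)
      if (start >= end) break
      i <- i + 1L
      rows[[i]] <- data.frame(
        gene_id = sprintf("%s%04d", prefix, i),
        transcript_id = sprintf("%s%04d", prefix, i),
        replicon = rep$name, start = start, end = end,
        strand = if (i %% 2L == 0L) "-" else "+",
        stringsAsFactors = FALSE
      )
      pos <- end
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Motif inventories of the four profiled strains
#'
#' The six methylated motifs and their methylated-base offsets: GANTC (the
#' CcrM target, shared by all strains) plus one or two strain-specific
#' motifs each. Non-palindromic m6A motifs carry the partner-strand
#' methylation offset; RCGCCTC (m4C) and WNCCGATG are methylated on the
#' motif strand only.
#'
#' @return Named list (by strain) of lists of [motif_spec()] objects.
#' @export
strain_inventories <- function() {
  gantc <- motif_spec("GANTC", 1, "m6A", partner_offset = 3)
  list(
    Rm2011 = list(
      GANTC = gantc,
      RCGCCTC = motif_spec("RCGCCTC", 3, "m4C"),
      `CGCANNNNNGTG` = motif_spec("CGCANNNNNGTG", 3, "m6A",
                                  partner_offset = 10)
    ),
    `FSM-MA` = list(
      GANTC = gantc,
      `TCGANNNNNNNNTCGA` = motif_spec("TCGANNNNNNNNTCGA", 3, "m6A",
                                      partner_offset = 12)
    ),
    NGR234 = list(
      GANTC = gantc,
      `CAGANNNNNNNGTTG` = motif_spec("CAGANNNNNNNGTTG", 3, "m6A",
                                     partner_offset = 12)
    ),
    OV14 = list(
      GANTC = gantc,
      WNCCGATG = motif_spec("WNCCGATG", 5, "m6A")
    )
  )
}

#' Build the four strain fixtures
#'
#' One ~1 Mb circular genome per strain at GC 0.619, annotated with random
#' gene models, carrying its motif inventory. Motifs whose natural
#' occurrence falls short of `min_sites` (the long bipartite ones) are
#' spiked: concrete instances are written at random non-overlapping
#' positions, recorded as ground truth in the `spiked` attribute.
#'
#' @param seed Integer seed (fixtures are byte-identical per seed).
#' @param length Genome length per strain.
#' @param min_sites Minimum occurrences per inventory motif.
#' @return Named list of fixtures; each is a list with `strain`, `genome`
#'   ([genome()]) and `inventory` (list of [motif_spec()]); spiked positions
#'   are attached as attribute `spiked` of the fixture.
#' @export
build_strain_fixtures <- function(seed = 1L, length = 1e6, min_sites = 200L) {
  inv <- strain_inventories()
  fixtures <- vector("list", length(inv))
  names(fixtures) <- names(inv)
  for (i in seq_along(inv)) {
    strain <- names(inv)[i]
    rep0 <- random_genome(length, gc = 0.619, seed = seed + i,
                          name = "chromosome")
    spiked <- list()
    for (m in inv[[i]]) {
      n_nat <- nrow(scan_motif(rep0, m))
      if (n_nat < min_sites) {
        sp <- spike_motif(rep0, m, n_spike = min_sites + 20L - n_nat,
                          seed = seed + 100L * i + nchar(m$iupac))
        rep0 <- sp$replicon
        spiked[[m$iupac]] <- sp$positions
      }
    }
    ann <- random_annotation(rep0, seed = seed + 10L * i,
                             prefix = paste0(substr(strain, 1, 2), "_"))
    fixtures[[i]] <- structure(
      list(strain = strain,
           genome = genome(strain, list(rep0), annotation = ann),
           inventory = inv[[i]]),
      spiked = spiked,
      class = "strain_fixture"
    )
  }
  fixtures
}

#' @export
print.strain_fixture <- function(x, ...) {
  cat(sprintf("<strain_fixture> %s: %d bp, motifs: %s\n", x$strain,
              x$genome$replicons[[1]]$length,
              paste(vapply(x$inventory, `[[`, character(1), "iupac"),
                    collapse = ", ")))
  invisible(x)
}

#' Spike concrete motif instances into a replicon
#'
#' Writes realised instances of a degenerate motif (degenerate columns drawn
#' from the genome's base composition restricted to the allowed bases) at
#' random, mutually non-overlapping positions.
#'
#' @param rep A [replicon()].
#' @param motif A [motif_spec()].
#' @param n_spike Number of instances.
#' @param seed Optional integer seed.
#' @return List with the modified `replicon` and the spike `positions`
#'   (plus-strand starts).
#' @export
spike_motif <- function(rep, motif, n_spike, seed = NULL) {
  run <- function() {
    k <- nchar(motif$iupac)
    cols <- strsplit(motif$iupac, "")[[1]]
    gc <- gc_fraction(rep)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chars <- strsplit(rep$sequence, "")[[1]]
    taken <- logical(rep$length)
    positions <- integer(0)
    guard <- 0L
    while (length(positions) < n_spike && guard < 50L * n_spike) {
      guard <- guard + 1L
      s <- sample.int(rep$length - k, 1L)
      if (any(taken[s:(s + k - 1L)])) next
      inst <- vapply(cols, function(cc) {
        allowed <- strsplit(IUPAC_CLASSES[[cc]], "")[[1]]
        if (length(allowed) == 1L) allowed else
          sample(allowed, 1L, prob = p[allowed] / sum(p[allowed]))
      }, character(1))
      chars[s:(s + k - 1L)] <- inst
      taken[s:(s + k - 1L)] <- TRUE
      positions <- c(positions, s)
    }
    list(
      replicon = replicon(rep$name, paste(chars, collapse = ""),
                          circular = rep$circular, ori_pos = rep$ori_pos),
      positions = sort(positions)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Cell-state mixture and detection-noise parameters
#'
#' Describes the population a methylation-call table is generated from: the
#' read proportions contributed by each differentiation stage (see
#' [differentiation_presets()]), the per-strand-call detection false
#' negative and false positive rates, and the mean sequencing coverage.
#'
#' @param proportions Named numeric vector over stage names, summing to 1.
#' @param fn False-negative rate per strand call (a truly methylated strand
#'   read as unmethylated).
#' @param fp False-positive rate per strand call.
#' @param mean_coverage Mean per-strand-site coverage (Poisson).
#' @return An object of class `state_mixture`.
#' @export
state_mixture <- function(proportions, fn = 0.05, fp = 0.01,
                          mean_coverage = 60) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (fn < 0 || fn > 1 || fp < 0 || fp > 1) stop("fn, fp must be in [0, 1]")
  structure(
    list(proportions = proportions, fn = fn, fp = fp,
         mean_coverage = mean_coverage),
    class = "state_mixture"
  )
}

#' Generate a methylation-call table from a strain fixture
#'
#' For every inventory motif, scans the fixture genome, expands duplex sites
#' to strand-sites, assigns each strand-site a true methylated fraction --
#' for GANTC, the mixture-weighted expected extent under the stage presets;
#' for all other motifs a constitutively high extent -- and then emulates
#' detection: coverage drawn Poisson, observed fraction Binomial(coverage,
#' f (1 - fn) + (1 - f) fp) / coverage. Strand-sites drawing zero coverage
#' are absent from the table, as in real call tables. A chosen number of
#' GANTC strand-sites can be planted as persistently unmethylated
#' (f = 0); their identities are attached as attribute `hypo_truth`.
#'
#' @param fixture A fixture from [build_strain_fixtures()] (or any list with
#'   `genome` and `inventory`).
#' @param mixture A [state_mixture()].
#' @param seed Optional integer seed.
#' @param replicate Replicate identifier stored in the records.
#' @param n_hypo Number of GANTC strand-sites planted unmethylated.
#' @param hypo_sites Explicit strand-sites to plant unmethylated (data frame
#'   `replicon`, `meth_pos`, `strand`), e.g. to keep the same planted sites
#'   across replicates; overrides `n_hypo`.
#' @param other_extent True extent of non-GANTC motifs (near-full,
#'   state-independent methylation).
#' @param presets Function mapping (stage, replicon_class) to
#'   [cell_cycle_params()]; defaults to [differentiation_presets()].
#' @return Methylation-record data frame (see [read_methylation_tsv()]) with
#'   attribute `hypo_truth`.
#' @export
generate_methylome <- function(fixture, mixture, seed = NULL,
                               replicate = "rep1", n_hypo = 0L,
                               hypo_sites = NULL, other_extent = 0.98,
                               presets = differentiation_presets) {
  stopifnot(inherits(mixture, "state_mixture"))
  run <- function() {
    gen <- fixture$genome
    lens <- vapply(gen$replicons, `[[`, integer(1), "length")
    out <- list()
    hypo_truth <- NULL
    for (m in fixture$inventory) {
      sites <- scan_motif(gen, m)
      ss <- motif_strand_sites(sites, m, rep_lengths = lens)
      ss <- unique(ss)
      if (m$iupac == "GANTC") {
        f <- numeric(nrow(ss))
        for (rn in names(gen$replicons)) {
          idx <- ss$replicon == rn
          af <- arm_fraction(gen$replicons[[rn]], ss$meth_pos[idx])
          rc <- if (rn == names(gen$replicons)[1]) "chromosome" else "secondary"
          fr <- rep(0, sum(idx))
          for (stage in names(mixture$proportions)) {
            w <- mixture$proportions[[stage]]
            if (w == 0) next
            fr <- fr + w * expected_extent(presets(stage, rc), af)
          }
          f[idx] <- fr
        }
        if (!is.null(hypo_sites)) {
          key_ss <- paste(ss$replicon, ss$meth_pos, ss$strand)
          key_h <- paste(hypo_sites$replicon, hypo_sites$meth_pos,
                         hypo_sites$strand)
          f[key_ss %in% key_h] <- 0
          hypo_truth <- hypo_sites
        } else if (n_hypo > 0L) {
          pick <- sample.int(nrow(ss), n_hypo)
          f[pick] <- 0
          hypo_truth <- ss[sort(pick), , drop = FALSE]
          rownames(hypo_truth) <- NULL
        }
      } else {
        f <- rep(other_extent, nrow(ss))
      }
      cov <- stats::rpois(nrow(ss), mixture$mean_coverage)
      p_obs <- f * (1 - mixture$fn) + (1 - f) * mixture$fp
      meth_reads <- stats::rbinom(nrow(ss), cov, p_obs)
      keep <- cov > 0L
      out[[m$iupac]] <- data.frame(
        replicon = ss$replicon[keep],
        meth_pos = ss$meth_pos[keep],
        strand = ss$strand[keep],
        motif = rep(m$iupac, sum(keep)),
        fraction = meth_reads[keep] / cov[keep],
        coverage = cov[keep],
        replicate = rep(replicate, sum(keep)),
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "hypo_truth") <- hypo_truth
    res
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Derive methylated-position marks from a call table
#'
#' Reduces a methylation-call table to the strand-oriented methylated
#' positions a motif-discovery step consumes: strand-sites whose observed
#' fraction reaches `threshold`. Modification types are carried over from
#' the motif labels when a `motif_mods` map is given.
#'
#' @param records Methylation-call records.
#' @param threshold Minimum observed fraction for a position to count as
#'   methylated.
#' @param motif_mods Optional named character vector mapping motif labels to
#'   `"m6A"`/`"m4C"`.
#' @return Data frame `replicon`, `pos`, `strand`, `mod_type`.
#' @export
marks_from_records <- function(records, threshold = 0.5, motif_mods = NULL) {
  keep <- records$fraction >= threshold
  out <- data.frame(
    replicon = records$replicon[keep],
    pos = records$meth_pos[keep],
    strand = records$strand[keep],
    mod_type = if (is.null(motif_mods)) "m6A"
      else unname(motif_mods[records$motif[keep]]),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Spurious methylated-position marks
#'
#' Uniformly random strand positions, emulating the scattered false calls of
#' kinetic modification detection; intended to stress motif discovery.
#'
#' @param gen A [genome()] or [replicon()].
#' @param n Number of spurious marks.
#' @param seed Optional integer seed.
#' @param mod_type Modification label.
#' @return Data frame `replicon`, `pos`, `strand`, `mod_type`.
#' @export
spurious_marks <- function(gen, n, seed = NULL, mod_type = "m6A") {
  reps <- if (inherits(gen, "genome")) gen$replicons else list(gen)
  run <- function() {
    lens <- vapply(reps, `[[`, integer(1), "length")
    if (is.null(names(lens))) {
      names(lens) <- vapply(reps, `[[`, character(1), "name")
    }
    rn <- names(lens)[sample.int(length(lens), n, replace = TRUE,
                                 prob = lens / sum(lens))]
    data.frame(
      replicon = rn,
      pos = vapply(rn, function(r) sample.int(lens[[r]], 1L), integer(1)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mod_type = mod_type,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Generate a windowed depth table with specified copy ratios
#'
#' Per 10-kb window, depth is drawn Poisson with mean
#' `mean_depth * ratio[replicon] * shape(center)`, where the shape is flat by
#' default or, when cell-cycle parameters are supplied, follows the
#' expected within-replicon copy-number gradient `2^(1 - t_r/T)` of an
#' asynchronous replicating population (normalised to mean 1 over windows).
#'
#' @param gen A [genome()].
#' @param copy_ratios Named numeric vector of per-replicon copy ratios
#'   (relative units; e.g. `c(chromosome = 3, pSymA = 2, pSymB = 2)`).
#' @param mean_depth Mean depth of a replicon at ratio 1.
#' @param window Window size in bp.
#' @param seed Optional integer seed.
#' @param params Optional [cell_cycle_params()] (or named list per replicon)
#'   enabling the ori-to-ter gradient.
#' @return Depth table (`replicon`, `center`, `depth`).
#' @export
generate_depth <- function(gen, copy_ratios, mean_depth = 30,
                           window = 10000L, seed = NULL, params = NULL) {
  stopifnot(inherits(gen, "genome"))
  if (any(copy_ratios <= 0)) stop("copy ratios must be positive")
  missing_reps <- setdiff(names(gen$replicons), names(copy_ratios))
  if (length(missing_reps)) {
    stop("no copy ratio for replicon(s): ",
         paste(missing_reps, collapse = ", "))
  }
  run <- function() {
    out <- list()
    for (rn in names(gen$replicons)) {
      r <- gen$replicons[[rn]]
      starts <- seq.int(1L, r$length, by = window)
      ends <- pmin(starts + as.integer(window) - 1L, r$length)
      keep <- (ends - starts + 1L) >= window / 2
      centers <- as.integer((starts[keep] + ends[keep]) %/% 2L)
      shape <- rep(1, length(centers))
      if (!is.null(params)) {
        pr <- if (inherits(params, "cell_cycle_params")) params else params[[rn]]
        cn <- copy_number_expectation(pr, r, centers)
        shape <- cn / mean(cn)
      }
      lambda <- mean_depth * copy_ratios[[rn]] * shape
      out[[rn]] <- data.frame(
        replicon = rn, center = centers,
        depth = stats::rpois(length(centers), lambda),
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
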