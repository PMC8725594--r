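# Population model of cell-cycle-gated CcrM methylation.
#
# An asynchronous exponential culture has steady-state age density
#   f(a) = (2 log 2 / T) * 2^(-a/T),  0 <= a < T,
# so young cells are twice as frequent as cells about to divide. A GANTC
# locus replicated at time t_r within the cycle is hemimethylated (half its
# strands unmethylated) until CcrM fires at t_ccrm; weighting every cell by
# its strand count, the population extent of methylation of that locus is
#   extent = 2^(-(t_ccrm - t_r)/T) = 2^(-Delta/T).
# The closed form is validated against the agent-based simulator rather than
# assumed; all bacteroid regimes (constitutive CcrM, endoreduplication,
# late shutoff) are simulated with the same machinery.

#' Cell-cycle and CcrM timing parameters
#'
#' Times are expressed in units of the doubling time `T` by default
#' (`T = 1`), but any time unit may be used consistently. The cell cycle of
#' a replicon starts at cell birth (time 0); bidirectional replication
#' initiates at `t_init` and completes at `t_init + C`; in the
#' `cycle_regulated` mode CcrM fires as a single pulse at `t_ccrm`
#' (constraint `t_init + C <= t_ccrm <= T`). In the `constitutive` mode CcrM
#' re-methylates each locus a fixed lag `delta` after its replication; in
#' the `off` mode new strands are never methylated. Endoreduplicating
#' populations perform `rounds` successive replication rounds (each of
#' duration `T`) without division; `t_off`, when finite, shuts CcrM down at
#' that time within the final round (late-bacteroid regime).
#'
#' @param T_ Doubling time / round duration (arbitrary units).
#' @param t_init Replication initiation time in `[0, T)`.
#' @param C Replication (C period) duration.
#' @param t_ccrm CcrM firing time for the `cycle_regulated` mode.
#' @param mode `"cycle_regulated"`, `"constitutive"` or `"off"`.
#' @param delta Lag between replication of a locus and its re-methylation in
#'   `constitutive` mode.
#' @param rounds Number of replication rounds (>= 1); values > 1 model
#'   endoreduplication without division.
#' @param t_off CcrM shutoff time within the final round, or `Inf` for no
#'   shutoff.
#' @param replicating Set `FALSE` for arrested populations that completed
#'   replication and methylation (e.g. stationary phase): every locus is
#'   fully methylated.
#' @return An object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(T_ = 1, t_init = 0.2, C = 0.5, t_ccrm = 0.7,
                              mode = c("cycle_regulated", "constitutive", "off"),
                              delta = 0, rounds = 1L, t_off = Inf,
                              replicating = TRUE) {
  mode <- match.arg(mode)
  stopifnot(T_ > 0, t_init >= 0, t_init < T_, C >= 0, delta >= 0,
            rounds >= 1L)
  if (t_init + C > T_ + 1e-9) stop("replication must finish within a round")
  if (mode == "cycle_regulated" && replicating) {
    if (t_ccrm < t_init + C - 1e-9 || t_ccrm > T_ + 1e-9) {
      stop("cycle_regulated mode requires t_init + C <= t_ccrm <= T")
    }
  }
  structure(
    list(T_ = T_, t_init = t_init, C = C, t_ccrm = t_ccrm, mode = mode,
         delta = delta, rounds = as.integer(rounds), t_off = t_off,
         replicating = isTRUE(replicating)),
    class = "cell_cycle_params"
  )
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat(sprintf(
    "<cell_cycle_params> mode=%s T=%g t_init=%g C=%g t_ccrm=%g delta=%g rounds=%d t_off=%g %s\n",
    x$mode, x$T_, x$t_init, x$C, x$t_ccrm, x$delta, x$rounds, x$t_off,
    if (x$replicating) "" else "(arrested)"))
  invisible(x)
}

#' Replication time of a locus
#'
#' With bidirectional forks of equal constant speed, a locus at arm fraction
#' `f` (see [arm_fraction()]) is replicated at `t_init + C * f` within the
#' round.
#'
#' @param params A [cell_cycle_params()].
#' @param rep A [replicon()] (ignored when `arm_frac` is given).
#' @param pos Positions on `rep`.
#' @param arm_frac Optionally, precomputed arm fractions instead of
#'   `rep`/`pos`.
#' @return Replication times in `[t_init, t_init + C]`.
#' @export
replication_time <- function(params, rep = NULL, pos = NULL, arm_frac = NULL) {
  stopifnot(inherits(params, "cell_cycle_params"))
  if (is.null(arm_frac)) arm_frac <- arm_fraction(rep, pos)
  params$t_init + params$C * arm_frac
}

#' Closed-form population extent of methylation
#'
#' Extent of methylation of a locus in an asynchronous exponential
#' population, as a function of the delay `Delta = t_ccrm - t_r` between the
#' locus's replication and CcrM firing: `2^(-Delta/T)`. `Delta = 0` (a locus
#' methylated immediately upon replication) gives 1; `Delta = T` gives 0.5,
#' the fully hemimethylated limit.
#'
#' @param delta_t Delay `Delta` (same units as `T_`); vectorised.
#' @param T_ Doubling time.
#' @return Extents in `(0, 1]`.
#' @examples
#' closed_form_extent(0.5)  # 2^-0.5 = 0.707..., an ori-proximal locus
#' @export
closed_form_extent <- function(delta_t, T_ = 1) {
  if (any(delta_t < -1e-9) || any(delta_t > T_ + 1e-9)) {
    stop("Delta must lie in [0, T]")
  }
  2^(-pmin(pmax(delta_t, 0), T_) / T_)
}

#' Expected copy number of a locus per cell
#'
#' Mean number of copies of a locus across an asynchronous exponential
#' population: `1 + P(age >= t_r)` under the steady-state age density, which
#' evaluates to `2^(1 - t_r/T)`. The origin-to-terminus depth ratio implied
#' by this is `2^(C/T)`.
#'
#' @param params A [cell_cycle_params()] in `cycle_regulated` mode with a
#'   single round.
#' @param rep,pos,arm_frac As in [replication_time()].
#' @return Mean copies per cell.
#' @export
copy_number_expectation <- function(params, rep = NULL, pos = NULL,
                                    arm_frac = NULL) {
  stopifnot(inherits(params, "cell_cycle_params"))
  t_r <- replication_time(params, rep, pos, arm_frac)
  2^(1 - t_r / params$T_)
}

#' Expected extent of methylation under any regime
#'
#' Deterministic (infinite-population) extent of methylation of a locus as a
#' function of its arm fraction, for every simulator mode. These expressions
#' integrate the per-cell strand counts over the population's age (or
#' elapsed-time) distribution: the exponential steady-state age density for
#' proliferating single-round populations, a uniform distribution over
#' `rounds * T` for endoreduplicating ones. They serve as fast generators
#' and as an analytic cross-check of [simulate_population()].
#'
#' @param params A [cell_cycle_params()].
#' @param arm_frac Vector of arm fractions in `[0, 1]`.
#' @return Extents in `(0, 1]`.
#' @export
expected_extent <- function(params, arm_frac) {
  stopifnot(inherits(params, "cell_cycle_params"))
  T_ <- params$T_
  t_r <- replication_time(params, arm_frac = arm_frac)
  if (!params$replicating) {
    return(rep(1, length(t_r)))
  }
  R <- params$rounds
  if (params$mode == "cycle_regulated") {
    if (R != 1L) stop("cycle_regulated mode is defined for a single round")
    return(closed_form_extent(params$t_ccrm - t_r, T_))
  }
  if (params$mode == "off") {
    # 2 methylated strands forever; per-round strand budget 2^r during
    # [0, t_r) and 2^(r+1) after replication, uniform time over R rounds
    meth <- 2 * R * T_
    tot <- sum(vapply(seq_len(R), function(r) 2^r, numeric(1)))
    total <- vapply(t_r, function(tr) {
      sum(vapply(seq_len(R), function(r) 2^r * tr + 2^(r + 1) * (T_ - tr),
                 numeric(1)))
    }, numeric(1))
    return(meth / total)
  }
  # constitutive, with optional shutoff at t_off in the final round
  d <- params$delta
  t_off <- params$t_off
  vapply(t_r, function(tr) {
    hemi_end <- min(tr + d, T_)
    meth_r <- numeric(R)
    tot_r <- numeric(R)
    for (r in seq_len(R)) {
      w <- 2^r  # strands entering round r
      remeth <- if (r < R) TRUE else (tr + d <= t_off)
      if (remeth) {
        meth_r[r] <- w * tr + w * (hemi_end - tr) + 2 * w * (T_ - hemi_end)
      } else {
        meth_r[r] <- w * tr + w * (T_ - tr)
      }
      tot_r[r] <- w * tr + 2 * w * (T_ - tr)
    }
    sum(meth_r) / sum(tot_r)
  }, numeric(1))
}

#' Agent-based population simulation of locus methylation
#'
#' Draws a population of cells (ages from the exponential steady-state
#' density for proliferating single-round populations; elapsed time uniform
#' over `rounds * T` for endoreduplicating ones) and tracks, for every locus,
#' the number of methylated and total DNA strands per cell under the chosen
#' CcrM mode. The per-locus extent of methylation is the population total of
#' methylated strands divided by the total strands (i.e. read-weighted, as a
#' sequencer samples strands, not cells).
#'
#' @param rep A [replicon()] (used for locus placement via arm fractions).
#' @param params A [cell_cycle_params()].
#' @param n_cells Number of cells (>= 100).
#' @param n_loci Number of loci on a regular grid (ignored when `positions`
#'   given).
#' @param positions Optional explicit locus positions (e.g. motif sites).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An object of class `population_sample`: a list with `loci` (data
#'   frame: `pos`, `arm_fraction`, `t_r`, `extent`), `ages`, `rounds_done`,
#'   `n_cells` and `params`.
#' @export
simulate_population <- function(rep, params, n_cells = 10000L, n_loci = 200L,
                                positions = NULL, seed = NULL) {
  stopifnot(inherits(rep, "replicon"), inherits(params, "cell_cycle_params"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 100L) stop("n_cells must be at least 100")
  if (is.null(positions)) {
    positions <- as.integer(round(seq(1, rep$length,
                                      length.out = n_loci + 1L)[-(n_loci + 1L)]))
  }
  run <- function() simulate_population_impl(rep, params, n_cells, positions)
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

simulate_population_impl <- function(rep, params, n_cells, positions) {
  T_ <- params$T_
  R <- params$rounds
  af <- arm_fraction(rep, positions)
  t_r <- replication_time(params, arm_frac = af)
  n_loci <- length(positions)

  if (!params$replicating) {
    ages <- rep(NA_real_, n_cells)
    extent <- rep(1, n_loci)
    meth <- matrix(2, n_loci, 1)
    rounds_done <- rep(R, n_cells)
  } else if (R == 1L) {
    # steady-state exponential age distribution: F(a) = 2 (1 - 2^(-a/T))
    u <- stats::runif(n_cells)
    ages <- -T_ * log2(1 - u / 2)
    rounds_done <- rep(1L, n_cells)
    counts <- strand_counts(ages, round_idx = rep(1L, n_cells),
                            t_r = t_r, params = params)
    extent <- rowSums(counts$meth) / rowSums(counts$total)
  } else {
    tau <- stats::runif(n_cells, 0, R * T_)
    round_idx <- pmin(floor(tau / T_) + 1L, R)
    ages <- tau - (round_idx - 1L) * T_
    rounds_done <- round_idx
    counts <- strand_counts(ages, round_idx = round_idx, t_r = t_r,
                            params = params)
    extent <- rowSums(counts$meth) / rowSums(counts$total)
  }

  structure(
    list(
      loci = data.frame(pos = positions, arm_fraction = af, t_r = t_r,
                        extent = extent),
      ages = ages, rounds_done = rounds_done, n_cells = n_cells,
      params = params
    ),
    class = "population_sample"
  )
}

# Methylated and total strand counts: loci x cells matrices. `round_idx` is
# the 1-based replication round each cell is currently in; `ages` the time
# within that round.
strand_counts <- function(ages, round_idx, t_r, params) {
  T_ <- params$T_
  n_loci <- length(t_r)
  n_cells <- length(ages)
  A <- matrix(ages, n_loci, n_cells, byrow = TRUE)
  Rd <- matrix(round_idx, n_loci, n_cells, byrow = TRUE)
  TR <- matrix(t_r, n_loci, n_cells)

  replicated <- A >= TR            # locus already replicated this round
  done_rounds <- (Rd - 1L) + replicated
  total <- 2^(done_rounds + 1)

  mode <- params$mode
  if (mode == "cycle_regulated") {
    meth <- ifelse(!replicated, 2,
                   ifelse(A >= params$t_ccrm, total, total / 2))
  } else if (mode == "off") {
    meth <- matrix(2, n_loci, n_cells)
  } else {
    # constitutive: new strands methylated `delta` after locus replication;
    # in the final round CcrM stops at t_off, so strands whose
    # re-methylation time exceeds t_off stay unmethylated
    remeth_time <- pmin(TR + params$delta, T_)
    allowed <- (Rd < params$rounds) | (remeth_time <= params$t_off)
    remethylated <- replicated & allowed & (A >= remeth_time)
    meth <- ifelse(!replicated, total,
                   ifelse(remethylated, total, total / 2))
  }
  list(meth = meth, total = total)
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf(
    "<population_sample> %d cells x %d loci, mode=%s; mean extent %.3f\n",
    x$n_cells, nrow(x$loci), x$params$mode, mean(x$loci$extent)))
  invisible(x)
}

#' Cell-cycle parameter presets for differentiation stages
#'
#' Canonical parameter sets whose simulated chromosome profiles reproduce
#' the qualitative regimes seen along free-living growth and terminal
#' bacteroid differentiation:
#'
#' * `exponential` -- dividing cells, cycle-regulated CcrM: extent ascends
#'   from ori to ter (the "frowning" profile of a replicon linearised at
#'   ori).
#' * `stationary` -- arrested cells that completed replication and
#'   methylation: flat at 1 before detection noise.
#' * `early_bacteroid` -- constitutive CcrM with a short lag, single round:
#'   flat near 1.
#' * `endoreduplicating` -- constitutive CcrM through several fast
#'   replication rounds without division: flat at an intermediate mean.
#' * `late_bacteroid` -- as `endoreduplicating` but CcrM shuts off partway
#'   through the final round: extent descends from ori to ter (the "smiling"
#'   profile).
#'
#' Secondary replicons (`replicon_class = "secondary"`) initiate replication
#' later in the cycle and replicate faster than the chromosome, reproducing
#' their higher ori-proximal extent in exponential cultures.
#'
#' @param stage One of the five stage names above.
#' @param replicon_class `"chromosome"` or `"secondary"`.
#' @return A [cell_cycle_params()].
#' @export
differentiation_presets <- function(stage = c("exponential", "stationary",
                                              "early_bacteroid",
                                              "endoreduplicating",
                                              "late_bacteroid"),
                                    replicon_class = c("chromosome",
                                                       "secondary")) {
  stage <- match.arg(stage)
  replicon_class <- match.arg(replicon_class)
  chrom <- replicon_class == "chromosome"
  switch(
    stage,
    exponential = if (chrom) {
      cell_cycle_params(t_init = 0.2, C = 0.5, t_ccrm = 0.7,
                        mode = "cycle_regulated")
    } else {
      cell_cycle_params(t_init = 0.4, C = 0.25, t_ccrm = 0.7,
                        mode = "cycle_regulated")
    },
    stationary = cell_cycle_params(mode = "cycle_regulated",
                                   replicating = FALSE),
    early_bacteroid = cell_cycle_params(t_init = 0.2, C = 0.1,
                                        mode = "constitutive", delta = 0.05),
    endoreduplicating = cell_cycle_params(t_init = 0.2, C = 0.1,
                                          mode = "constitutive",
                                          delta = 0.25, rounds = 4L),
    late_bacteroid = cell_cycle_params(t_init = 0.2, C = 0.1,
                                       mode = "constitutive", delta = 0.25,
                                       rounds = 4L, t_off = 0.5)
  )
}
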