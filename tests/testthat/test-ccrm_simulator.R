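test_that("replication time interpolates linearly along the arm", {
  p <- cell_cycle_params(t_init = 0.2, C = 0.6, t_ccrm = 0.9)
  r <- replicon("chr", strrep("ACGT", 250), ori_pos = 1)
  expect_equal(replication_time(p, r, 1), 0.2)          # ori
  expect_equal(replication_time(p, r, 501), 0.8)        # antipode
  expect_equal(replication_time(p, arm_frac = 0.5), 0.5)
  expect_error(cell_cycle_params(t_init = 0.5, C = 0.4, t_ccrm = 0.7),
               "t_init")
})

test_that("closed-form extent has the right endpoints and errors", {
  expect_equal(closed_form_extent(0), 1.0)
  expect_equal(closed_form_extent(1), 0.5)
  expect_equal(closed_form_extent(0.5), 2^-0.5)
  expect_equal(round(closed_form_extent(0.5), 2), 0.71)
  expect_error(closed_form_extent(-0.1), "Delta")
  expect_error(closed_form_extent(1.5), "Delta")
  # strict monotone decrease in the delay
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(closed_form_extent(d)) < 0))
})

test_that("agent-based populations converge to the closed form on a Delta grid", {
  r <- replicon("chr", strrep("ACGT", 25000), ori_pos = 1)  # 100 kb
  p <- cell_cycle_params(t_init = 0, C = 0.5, t_ccrm = 0.5)
  # loci across the arm span Delta = t_ccrm - t_r in [0, 0.5]
  ps <- simulate_population(r, p, n_cells = 1e4, n_loci = 40, seed = 101)
  expected <- closed_form_extent(p$t_ccrm - ps$loci$t_r)
  expect_lt(max(abs(ps$loci$extent - expected)), 0.01)

  # Delta up to a full period: t_init = 0, C = 0, t_ccrm sweeps the cycle
  for (tc in c(0.25, 0.75, 1)) {
    p2 <- cell_cycle_params(t_init = 0, C = 0, t_ccrm = tc)
    ps2 <- simulate_population(r, p2, n_cells = 1e4, n_loci = 5, seed = 7)
    expect_lt(max(abs(ps2$loci$extent - closed_form_extent(tc))), 0.01)
  }
})

test_that("population simulation reproduces the degenerate modes exactly", {
  r <- replicon("chr", strrep("ACGT", 2500), ori_pos = 1)
  # all loci replicated at birth, never re-methylated: every duplex
  # hemimethylated in every cell
  off <- cell_cycle_params(t_init = 0, C = 0, mode = "off")
  ps_off <- simulate_population(r, off, n_cells = 500, n_loci = 10, seed = 1)
  expect_true(all(ps_off$loci$extent == 0.5))
  # constitutive with zero lag: instantaneous re-methylation
  con <- cell_cycle_params(t_init = 0.2, C = 0.5, mode = "constitutive",
                           delta = 0)
  ps_con <- simulate_population(r, con, n_cells = 500, n_loci = 10, seed = 2)
  expect_true(all(ps_con$loci$extent == 1))
  # arrested: fully methylated
  ps_arr <- simulate_population(r, differentiation_presets("stationary"),
                                n_cells = 500, n_loci = 10, seed = 3)
  expect_true(all(ps_arr$loci$extent == 1))
  expect_error(simulate_population(r, con, n_cells = 10), "at least 100")
})

test_that("simulated endoreduplication regimes match their analytic extents", {
  r <- replicon("chr", strrep("ACGT", 25000), ori_pos = 1)
  for (stage in c("early_bacteroid", "endoreduplicating", "late_bacteroid")) {
    p <- differentiation_presets(stage)
    ps <- simulate_population(r, p, n_cells = 2e4, n_loci = 20, seed = 11)
    expect_lt(max(abs(ps$loci$extent -
                        expected_extent(p, ps$loci$arm_fraction))), 0.015,
              label = stage)
  }
})

test_that("copy number expectation matches the age-distribution integral", {
  p <- cell_cycle_params(t_init = 0, C = 1, t_ccrm = 1)
  expect_equal(copy_number_expectation(p, arm_frac = 0), 2.0)   # t_r = 0
  expect_equal(copy_number_expectation(p, arm_frac = 1), 1.0)   # t_r = T
  # ori:ter ratio equals 2^(C/T)
  p2 <- cell_cycle_params(t_init = 0.1, C = 0.6, t_ccrm = 0.8)
  ratio <- copy_number_expectation(p2, arm_frac = 0) /
    copy_number_expectation(p2, arm_frac = 1)
  expect_equal(ratio, 2^(p2$C / p2$T_))
  # numeric integral oracle: 1 + P(age >= t_r) under f(a)
  f <- function(a) (2 * log(2)) * 2^(-a)
  for (tr in c(0.2, 0.5, 0.9)) {
    p_repl <- stats::integrate(f, tr, 1)$value
    expect_equal(copy_number_expectation(p2, arm_frac = (tr - 0.1) / 0.6),
                 1 + p_repl, tolerance = 1e-6)
  }
  # strictly decreasing in replication time
  cn <- copy_number_expectation(p2, arm_frac = seq(0, 1, 0.1))
  expect_true(all(diff(cn) < 0))
})

test_that("differentiation regimes order mean extents as arrested > endoreduplicating > late shutoff", {
  r <- replicon("chr", strrep("ACGT", 25000), ori_pos = 1)
  for (s in c(5, 17, 23)) {
    m_arr <- mean(simulate_population(
      r, differentiation_presets("stationary"), 5000, 30, seed = s
    )$loci$extent)
    m_endo <- mean(simulate_population(
      r, differentiation_presets("endoreduplicating"), 5000, 30, seed = s
    )$loci$extent)
    m_late <- mean(simulate_population(
      r, differentiation_presets("late_bacteroid"), 5000, 30, seed = s
    )$loci$extent)
    m_off <- mean(simulate_population(
      r, cell_cycle_params(t_init = 0.2, C = 0.1, mode = "off", rounds = 4L),
      5000, 30, seed = s
    )$loci$extent)
    expect_gt(m_arr, m_endo)
    expect_gt(m_endo, m_late)
    expect_gt(m_late, m_off)  # late shutoff sits between constitutive and off
  }
})

test_that("secondary replicons initiated later show higher ori extent", {
  chrom <- differentiation_presets("exponential", "chromosome")
  sec <- differentiation_presets("exponential", "secondary")
  expect_gt(sec$t_init, chrom$t_init)
  expect_lt(sec$t_init + sec$C, chrom$t_init + chrom$C + 1e-9)
  r <- replicon("chr", strrep("ACGT", 25000), ori_pos = 1)
  e_chrom <- simulate_population(r, chrom, 5000, 10, seed = 31)$loci$extent[1]
  e_sec <- simulate_population(r, sec, 5000, 10, seed = 31)$loci$extent[1]
  expect_gt(e_sec, e_chrom)
  # analytic check of the same ordering
  expect_gt(expected_extent(sec, 0), expected_extent(chrom, 0))
})
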