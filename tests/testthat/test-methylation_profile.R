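make_records <- function(pos, frac, replicon = "chr", strand = "+",
                         motif = "GANTC", coverage = 60L,
                         replicate = "rep1") {
  data.frame(replicon = replicon, meth_pos = as.integer(pos),
             strand = strand, motif = motif, fraction = frac,
             coverage = coverage, replicate = replicate,
             stringsAsFactors = FALSE)
}

test_that("window means average strand-site fractions, unweighted", {
  r <- replicon("chr", strrep("ACGT", 5000))  # 20 kb
  rec <- make_records(c(3000, 3500), c(0.4, 0.8),
                      coverage = c(10L, 1000L))  # coverage must not weight
  prof <- window_extent(rec, r, window = 10000, step = 1000)
  w <- prof$points[prof$points$center == 3001, ]
  expect_equal(w$mean_extent, 0.6)
  expect_equal(w$n_sites, 2L)

  rec2 <- make_records(seq(500, 19500, by = 500), 1.0)
  prof2 <- window_extent(rec2, r, window = 10000, step = 1000)
  filled <- prof2$points$n_sites > 0
  expect_true(all(prof2$points$mean_extent[filled] == 1.0))

  # empty input: all-empty profile, no error
  prof3 <- window_extent(make_records(1, 1)[0, ], r)
  expect_true(all(prof3$points$n_sites == 0L))
})

test_that("window means are invariant to record order and replicate averaging", {
  r <- replicon("chr", strrep("ACGT", 5000))
  set.seed(3)
  pos <- sample(20000, 300)
  f1 <- runif(300)
  f2 <- runif(300)
  rec1 <- make_records(pos, f1, replicate = "a")
  rec2 <- make_records(pos, f2, replicate = "b")
  both <- rbind(rec1, rec2)
  shuffled <- both[sample(nrow(both)), ]
  p_ord <- window_extent(both, r)
  p_shuf <- window_extent(shuffled, r)
  expect_equal(p_ord$points, p_shuf$points)
  # concatenating replicates equals windowing the per-site means
  manual <- make_records(pos, (f1 + f2) / 2)
  p_manual <- window_extent(manual, r)
  expect_equal(p_ord$points$mean_extent, p_manual$points$mean_extent)
})

test_that("windows wrap across the origin junction", {
  r <- replicon("chr", strrep("ACGT", 5000))  # 20 kb, circular
  rec <- make_records(c(19900, 150), c(0.2, 0.8))
  prof <- window_extent(rec, r, window = 1000, step = 1000)
  w1 <- prof$points[1, ]  # window centred at 1 spans [19501, 500]
  expect_equal(w1$n_sites, 2L)
  expect_equal(w1$mean_extent, 0.5)
})

test_that("robust quadratic trend recovers exact and contaminated signals", {
  r <- replicon("chr", strrep("ACGT", 25000))  # 100 kb
  centers <- seq(1, r$length, by = 1000)
  x <- centers  # ori at 1: rotated coordinate equals the raw one
  truth <- function(x) 0.7 + 0.6 * (x / 1e5) - 0.5 * (x / 1e5)^2
  rec <- make_records(centers, truth(centers))
  prof <- window_extent(rec, r, window = 1000, step = 1000)
  prof <- fit_trend(prof)
  expect_length(prof$trend$coefficients, 3L)
  pred <- predict(prof$trend$model,
                  newdata = data.frame(x = rotate_coord(centers, 1, r$length)))
  expect_lt(max(abs(pred - truth(centers))), 1e-6)

  # flat data: curvature and slope vanish, intercept is the level
  rec_flat <- make_records(centers, 0.95)
  prof_flat <- fit_trend(window_extent(rec_flat, r, 1000, 1000))
  expect_equal(prof_flat$trend$coefficients[1], 0.95, tolerance = 1e-9)
  expect_lt(max(abs(prof_flat$trend$coefficients[2:3])), 1e-9)

  # 10% gross outliers: Huber IRLS beats ordinary least squares
  set.seed(9)
  y <- truth(centers) + rnorm(length(centers), 0, 0.01)
  out_idx <- sample(length(y), length(y) %/% 10)
  y[out_idx] <- y[out_idx] - 0.5
  rec_out <- make_records(centers, pmax(y, 0))
  prof_out <- fit_trend(window_extent(rec_out, r, 1000, 1000))
  xr <- rotate_coord(centers, 1, r$length)
  ols <- lm(pmax(y, 0) ~ poly(xr, 2))
  err_rlm <- mean((predict(prof_out$trend$model,
                           newdata = data.frame(x = xr)) - truth(centers))^2)
  err_ols <- mean((predict(ols) - truth(centers))^2)
  expect_lt(err_rlm, err_ols)

  expect_error(fit_trend(window_extent(make_records(1:3, rep(1, 3)), r,
                                       50000, 50000)),
               "at least 6")
})

test_that("profiles from the population model classify into the three regimes", {
  r <- random_genome(180000, seed = 77, name = "chr")
  fixture <- list(
    genome = genome("sim", list(r)),
    inventory = list(motif_spec("GANTC", 1, partner_offset = 3))
  )
  for (s in 1:3) {
    for (case in list(
      c(stage = "exponential", want = "ascending_to_ter"),
      c(stage = "stationary", want = "flat"),
      c(stage = "late_bacteroid", want = "descending_to_ter")
    )) {
      prop <- stats::setNames(1, case[["stage"]])
      rec <- generate_methylome(fixture, state_mixture(prop), seed = s)
      rec <- rec[rec$motif == "GANTC", ]
      prof <- window_extent(rec, r)
      expect_equal(profile_pattern(prof), case[["want"]],
                   label = paste(case[["stage"]], "seed", s))
    }
  }
})

test_that("persistently hypomethylated sites require failure in all replicates", {
  site <- function(frac, repl) make_records(100, frac, replicate = repl)
  all_low <- rbind(site(0, "a"), site(0.05, "b"), site(0.1, "c"))
  flagged <- persistent_hypomethylated(all_low, tau = 0.2)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$meth_pos, 100L)

  two_of_three <- rbind(site(0, "a"), site(0, "b"), site(0.9, "c"))
  expect_equal(nrow(persistent_hypomethylated(two_of_three, tau = 0.2)), 0L)
  expect_error(persistent_hypomethylated(site(0, "a")), "two replicates")
})

test_that("planted hypomethylated strand-sites are recovered exactly", {
  r <- random_genome(180000, seed = 78, name = "chr")
  fixture <- list(
    genome = genome("sim", list(r)),
    inventory = list(motif_spec("GANTC", 1, partner_offset = 3))
  )
  first <- generate_methylome(fixture, state_mixture(c(stationary = 1)),
                              seed = 21, replicate = "r1", n_hypo = 40)
  truth <- attr(first, "hypo_truth")
  expect_equal(nrow(truth), 40L)
  reps <- list(first)
  for (i in 2:3) {
    reps[[i]] <- generate_methylome(fixture, state_mixture(c(stationary = 1)),
                                    seed = 21 + i,
                                    replicate = paste0("r", i),
                                    hypo_sites = truth)
  }
  records <- do.call(rbind, lapply(reps, function(x) x[x$motif == "GANTC", ]))
  flagged <- persistent_hypomethylated(records, tau = 0.2)
  expect_equal(
    sort(paste(flagged$replicon, flagged$meth_pos, flagged$strand)),
    sort(paste(truth$replicon, truth$meth_pos, truth$strand))
  )
})

test_that("replicon mean extent averages strand-sites after replicates", {
  rec <- make_records(c(10, 20), c(1, 1))
  expect_equal(replicon_mean_extent(rec, "chr"), 1)
  rec2 <- make_records(c(10, 20), c(0.8, 1.0))
  expect_equal(replicon_mean_extent(rec2, "chr"), 0.9)
  # replicate averaging first: site means (0.5, 1.0) -> 0.75
  rec3 <- rbind(make_records(10, 0, replicate = "a"),
                make_records(10, 1, replicate = "b"),
                make_records(20, 1, replicate = "a"),
                make_records(20, 1, replicate = "b"))
  expect_equal(replicon_mean_extent(rec3, "chr"), 0.75)
  expect_error(replicon_mean_extent(rec2, "nope"), "no records")
})

test_that("stationary-phase generator yields ~95% mean extent at 5% miss rate", {
  fx <- test_strain_fixtures()
  rec <- generate_methylome(fx$Rm2011,
                            state_mixture(c(stationary = 1), fn = 0.05,
                                          fp = 0),
                            seed = 13)
  gantc <- rec[rec$motif == "GANTC", ]
  expect_equal(replicon_mean_extent(gantc, "chromosome"), 0.95,
               tolerance = 0.005)
})

test_that("methylation call tables round-trip through the TSV dialect", {
  rec <- make_records(c(5, 10), c(0.25, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_methylation_tsv(rec, path)
  back <- read_methylation_tsv(path)
  expect_equal(back, rec)
  expect_error(read_methylation_tsv({
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines("a\tb", p)
    p
  }), "lack column")
  bad <- rec
  bad$fraction[1] <- 1.5
  expect_error(write_methylation_tsv(bad, path), "fraction")
})
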