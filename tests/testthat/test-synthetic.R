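test_that("sequence generation is seed-deterministic", {
  cfg <- synthetic_config(length = 40, seed = 5)
  expect_identical(generate_sequence(cfg)$residues,
                   generate_sequence(cfg)$residues)
  cfg2 <- synthetic_config(length = 40, seed = 6)
  expect_false(identical(generate_sequence(cfg)$residues,
                         generate_sequence(cfg2)$residues))
})

test_that("targeted generation hits the requested mBf", {
  sc <- load_flex_scale()
  win <- window_spec()
  for (target in c(0.95, 1.0, 1.05)) {
    cfg <- synthetic_config(length = 100, target_mbf = target, seed = 31)
    rec <- generate_sequence(cfg, sc, win)
    # independent recomputation of the whole-sequence mBf
    m <- mean(brute_force_profile(rec, sc, win))
    expect_lt(abs(m - target), 0.05)
  }
  expect_error(generate_sequence(
    synthetic_config(length = 50, target_mbf = 2, seed = 1), sc, win),
    "outside the scale range")
  expect_error(generate_sequence(
    synthetic_config(length = 1, seed = 1), sc, win),
    ">= window width")
})

test_that("pool-restricted sequences use the scale quartiles", {
  sc <- load_flex_scale()
  stiff5 <- names(sort(sc$values))[1:5]
  rec <- generate_sequence(synthetic_config(length = 60, pool = "stiff",
                                            seed = 2), sc)
  expect_true(all(strsplit(rec$residues, "")[[1]] %in% stiff5))
})

test_that("synthetic disorder tracks are bounded, correlated and seeded", {
  for (s in 1:20) {
    cfg <- synthetic_config(length = 50, rho = 0.5, noise_sd = 0.4,
                            n_sites = 3, seed = s)
    prof <- flex_profile(generate_sequence(cfg))
    tr <- generate_disorder_track(prof, cfg)
    expect_true(all(tr$profile$pd >= 0 & tr$profile$pd <= 1))
    expect_equal(nrow(tr$truth), 3)
    expect_true(all(tr$truth$position %in% prof$positions))
  }

  # determinism
  cfg <- synthetic_config(length = 50, n_sites = 2, seed = 77)
  prof <- flex_profile(generate_sequence(cfg))
  t1 <- generate_disorder_track(prof, cfg)
  t2 <- generate_disorder_track(prof, cfg)
  expect_identical(t1$profile$pd, t2$profile$pd)
  expect_identical(t1$truth, t2$truth)

  # no injections -> empty truth set
  cfg0 <- synthetic_config(length = 50, n_sites = 0, seed = 3)
  expect_equal(nrow(generate_disorder_track(prof, cfg0)$truth), 0)

  # realized correlation approximates rho
  cors <- vapply(1:20, function(s) {
    cfg <- synthetic_config(length = 300, rho = 0.8, noise_sd = 0.1,
                            seed = 500 + s)
    prof <- flex_profile(generate_sequence(cfg))
    cor(prof$nbf, generate_disorder_track(prof, cfg)$profile$pd)
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.8), 0.1)
})

test_that("injected sites shift the log-quotient by the stated effect", {
  cfg <- synthetic_config(length = 200, rho = 0.8, noise_sd = 0.1,
                          n_sites = 4, effect = 3, seed = 11)
  prof <- flex_profile(generate_sequence(cfg))
  with_inj <- generate_disorder_track(prof, cfg)
  cfg0 <- cfg
  cfg0$n_sites <- 0L
  baseline <- generate_disorder_track(prof, cfg0)
  q1 <- log(prof$nbf / with_inj$profile$pd)
  q0 <- log(prof$nbf / baseline$profile$pd)
  sdq <- sd(q0)
  moved <- which(abs(q1 - q0) > 1e-9)
  expect_setequal(prof$positions[moved], with_inj$truth$position)
  expect_equal(abs(q1 - q0)[moved], rep(3 * sdq, 4), tolerance = 1e-6)
})

test_that("recovery degrades as link noise grows", {
  base <- synthetic_config(length = 300, rho = 0.8, n_sites = 5,
                           effect = 3, seed = 60)
  low <- base
  low$noise_sd <- 0.02
  high <- base
  high$noise_sd <- 0.5
  r_low <- recovery_experiment(low, 30)
  r_high <- recovery_experiment(high, 30)
  expect_gte(r_low$precision, r_high$precision)
})

test_that("the simulate bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(length = 80, rho = 0.7, noise_sd = 0.2,
                          n_sites = 3, seed = 9)
  paths <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  rec <- read_fasta(paths[["fasta"]])[[1]]
  prof <- flex_profile(rec)
  track <- read_disorder_profile(paths[["track"]], "generic",
                                 record_id = rec$id)
  paired <- pair_profiles(prof, track)
  expect_length(paired$nbf, 80)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), 3)
  # the written track equals the in-memory generator output
  regen <- generate_disorder_track(prof, cfg)
  expect_equal(track$pd, regen$profile$pd, tolerance = 1e-6)
})
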