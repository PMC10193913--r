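test_that("B-factor standardization centers and scales exactly", {
  expect_equal(normalize_bfactors(c(10, 20, 30)), c(-1, 0, 1))
  # any entry equal to the mean maps to zero
  x <- c(4, 7, 10, 7)
  expect_equal(normalize_bfactors(x)[c(2, 4)], c(0, 0))

  set.seed(11)
  for (i in 1:10) {
    v <- rnorm(50, mean = 30, sd = runif(1, 1, 20))
    out <- normalize_bfactors(v)
    expect_lt(abs(mean(out)), 1e-9)
    expect_lt(abs(sd(out) - 1), 1e-9)
  }

  expect_error(normalize_bfactors(rep(5, 4)), "degenerate B-factor series")
  expect_error(normalize_bfactors(3), "length >= 2")
})

test_that("window specifications are validated", {
  w <- window_spec()
  expect_equal(w$width, 3L)
  expect_equal(w$weights, c(0.25, 0.5, 0.25))
  expect_equal(window_spec(1)$weights, 1)
  expect_error(window_spec(4), "odd")
  expect_error(window_spec(3, c(0.2, 0.5, 0.3)), "symmetric")
  expect_error(window_spec(3, c(0.3, 0.5, 0.3)), "sum to 1")
  expect_error(window_spec(3, c(-0.25, 1.5, -0.25)), "positive")
})

test_that("profiles match hand-computed windowed averages", {
  sc <- toy_scale()  # G = 3, A = 1, V = 2
  p <- flex_profile(sequence_record("t", "GAV"), sc, window_spec())
  # middle: 0.25*3 + 0.5*1 + 0.25*2 = 1.75
  expect_equal(p$nbf[2], 1.75)
  # termini renormalize to (2/3, 1/3): (0.5*3 + 0.25*1)/0.75
  expect_equal(p$nbf[1], (0.5 * 3 + 0.25 * 1) / 0.75)
  expect_equal(p$nbf[3], (0.25 * 1 + 0.5 * 2) / 0.75)

  # homopolymer gives a constant profile at the residue's value
  for (w in list(window_spec(1), window_spec(3), window_spec(5))) {
    expect_equal(flex_profile(sequence_record("g", "GGGGG"), sc, w)$nbf,
                 rep(3, 5))
  }
})

test_that("profiles agree with a brute-force oracle and stay in scale bounds", {
  sc <- load_flex_scale()
  for (i in 1:100) {
    n <- 3 + (i %% 28)
    rec <- random_record(n, seed = 2000 + i)
    w <- window_spec(c(3, 5)[1 + (i %% 2)])
    p <- flex_profile(rec, sc, w)
    expect_equal(p$nbf, brute_force_profile(rec, sc, w), tolerance = 1e-12)
    expect_true(all(p$nbf >= min(sc$values) - 1e-12))
    expect_true(all(p$nbf <= max(sc$values) + 1e-12))
  }
})

test_that("symmetric windows commute with sequence reversal", {
  sc <- load_flex_scale()
  for (i in 1:10) {
    rec <- random_record(25, seed = 3000 + i)
    rev_rec <- sequence_record(rec$id, paste(rev(strsplit(
      rec$residues, "")[[1]]), collapse = ""))
    expect_equal(flex_profile(rev_rec, sc)$nbf,
                 rev(flex_profile(rec, sc)$nbf))
  }
})

test_that("substituting in a more flexible residue never lowers the profile", {
  sc <- load_flex_scale()
  rec <- random_record(30, seed = 99)
  p0 <- flex_profile(rec, sc)$nbf
  chars <- strsplit(rec$residues, "")[[1]]
  ord <- names(sort(sc$values))
  for (pos in c(1, 10, 30)) {
    higher <- ord[which(ord == chars[pos]) < seq_along(ord)]
    for (aa in higher) {
      mutated <- chars
      mutated[pos] <- aa
      p1 <- flex_profile(sequence_record("m", paste(mutated, collapse = "")),
                         sc)$nbf
      expect_true(all(p1 >= p0 - 1e-12))
      expect_gte(mean(p1), mean(p0))
    }
  }
})

test_that("unknown residue X contributes the scale mean", {
  sc <- toy_scale()
  p <- flex_profile(sequence_record("x", "XXX"), sc, window_spec(1))
  expect_equal(p$nbf, rep(mean(sc$values), 3))
})

test_that("segment mBf is the slice mean with reciprocal and literal forms", {
  sc <- load_flex_scale()
  rec <- random_record(40, seed = 5)
  p <- flex_profile(rec, sc)
  mf <- segment_mbf(p, 10, 25)
  expect_equal(mf$mbf, mean(p$nbf[10:25]))  # independent recomputation
  expect_equal(mf$n, 16L)
  expect_equal(mf$relative * mf$mbf, 1, tolerance = 1e-12)
  expect_equal(mf$literal_eq2, -mf$mbf)
  expect_error(segment_mbf(p, 30, 70), "outside profile")
  expect_error(segment_mbf(p, 20, 10), "inverted")

  # single residue, width-1 window: the residue's scale value
  p1 <- flex_profile(sequence_record("k", "K"), sc, window_spec(1))
  expect_equal(segment_mbf(p1, 1, 1)$mbf, unname(sc$values["K"]))
})

test_that("width-1 mBf is invariant under permutation of the segment", {
  sc <- load_flex_scale()
  rec <- random_record(20, seed = 17)
  p <- flex_profile(rec, sc, window_spec(1))
  m0 <- segment_mbf(p, 1, 20)$mbf
  set.seed(1)
  for (i in 1:5) {
    perm <- paste(sample(strsplit(rec$residues, "")[[1]]), collapse = "")
    pp <- flex_profile(sequence_record("perm", perm), sc, window_spec(1))
    expect_equal(segment_mbf(pp, 1, 20)$mbf, m0, tolerance = 1e-12)
  }
})

test_that("relative flexibility is the reciprocal", {
  expect_equal(relative_flexibility(1), 1)
  expect_equal(relative_flexibility(2), 0.5)
  mf <- segment_mbf(flex_profile(random_record(10, 3)), 2, 8)
  expect_equal(relative_flexibility(relative_flexibility(mf)), mf$mbf,
               tolerance = 1e-12)
  expect_error(relative_flexibility(0), "mbf > 0")
  expect_error(relative_flexibility(-2), "mbf > 0")
})

test_that("calibration with no anchors is a no-op", {
  sc <- load_flex_scale()
  expect_identical(calibrate_scale(sc, window_spec(), list()), sc)
})

test_that("calibration recovers a known affine transform of the scale", {
  sc <- load_flex_scale()
  win <- window_spec()
  g0 <- 2.5
  b0 <- -0.75
  anchors <- lapply(1:3, function(i) {
    rec <- random_record(30, seed = 4000 + i)
    m <- segment_mbf(flex_profile(rec, sc, win), 1, 30)$mbf
    list(record = rec, target = g0 * m + b0)
  })
  cal <- calibrate_scale(sc, win, anchors)
  expect_equal(unname(cal$values), unname(g0 * sc$values + b0),
               tolerance = 1e-6)
  # residue ordering is preserved by construction
  expect_equal(order(cal$values), order(sc$values))
})

test_that("degenerate calibration falls back to an offset-only fit", {
  sc <- load_flex_scale()
  win <- window_spec(1)
  rec <- sequence_record("g", "GGGGGGGG")
  anchors <- list(list(record = rec, target = 2),
                  list(record = rec, target = 2))
  expect_warning(cal <- calibrate_scale(sc, win, anchors),
                 "offset-only")
  m <- segment_mbf(flex_profile(rec, cal, win), 1, 8)$mbf
  expect_equal(m, 2)
})
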