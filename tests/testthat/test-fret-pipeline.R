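test_that("FRET efficiency follows E = IA / (IA + gamma * ID) frame by frame", {
  tr <- make_step_trace(n = 100, acc_levels = 50, don_levels = 50)
  ft <- compute_fret(tr, make_qc(step_frame = 51L, gamma = 1))
  expect_equal(ft$E, rep(0.5, 50))

  tr2 <- make_step_trace(n = 100, acc_levels = 80, don_levels = 40)
  ft2 <- compute_fret(tr2, make_qc(step_frame = 41L, gamma = 0.5))
  expect_equal(ft2$E, rep(0.8, 40))

  # background is removed before the ratio
  tr3 <- make_step_trace(n = 100, acc_levels = 60, don_levels = 60)
  ft3 <- compute_fret(tr3, make_qc(step_frame = 51L, gamma = 1,
                                   background = 10))
  expect_equal(ft3$E, rep(0.5, 50))
})

test_that("frames with non-positive denominator are dropped, many reject the trace", {
  don <- rep(50, 100); acc <- rep(50, 100)
  acc[5] <- -60  # one pathological frame
  tr <- structure(list(molecule_id = "x", donor = don, acceptor = acc,
                       frame_interval_s = 0.1, truth = NULL),
                  class = "intensity_trace")
  ft <- compute_fret(tr, make_qc(step_frame = 91L, gamma = 1))
  expect_equal(ft$n_dropped, 1L)
  expect_length(ft$E, 89)

  acc[1:30] <- -60  # a third of the pre-bleach region unusable
  tr$acceptor <- acc
  expect_error(compute_fret(tr, make_qc(step_frame = 91L, gamma = 1)),
               class = "smfretr_qc_error")
})

test_that("end-to-end efficiency recovery through qc on simulated traces", {
  p <- sim_params(n_molecules = 80, total_intensity = 100, noise_sd = 5,
                  background = 0, gamma_mean = 1.2, gamma_sd = 0,
                  states = list(c(0.65, 1)), seed = 909)
  traces <- simulate_ensemble(p)
  qc <- qc_ensemble(traces)
  Em <- unlist(lapply(seq_along(traces), function(i) {
    if (!qc$results[[i]]$accepted) return(NULL)
    mean(compute_fret(traces[[i]], qc$results[[i]])$E)
  }))
  expect_gt(length(Em), 20)
  expect_lt(abs(mean(Em) - 0.65), 0.02)
})

test_that("each retained trace contributes exactly unit histogram weight", {
  ft40 <- structure(list(molecule_id = 1, E = rep(0.5, 40), gamma = 1,
                         n_dropped = 0L), class = "fret_trace")
  h <- build_histogram(list(ft40))
  expect_equal(sum(h$weights), 1)
  k <- findInterval(0.5, h$bin_edges, rightmost.closed = TRUE)
  expect_equal(h$weights[k], 1)

  # short and long traces contribute equally
  ftA <- structure(list(molecule_id = 1, E = rep(0.3, 30), gamma = 1,
                        n_dropped = 0L), class = "fret_trace")
  ftB <- structure(list(molecule_id = 2, E = rep(0.9, 300), gamma = 1,
                        n_dropped = 0L), class = "fret_trace")
  h2 <- build_histogram(list(ftA, ftB))
  kA <- findInterval(0.3, h2$bin_edges, rightmost.closed = TRUE)
  kB <- findInterval(0.9, h2$bin_edges, rightmost.closed = TRUE)
  expect_equal(h2$weights[kA], 1)
  expect_equal(h2$weights[kB], 1)
  expect_equal(sum(h2$weights), 2)
})

test_that("traces at or below the minimum point count are excluded", {
  ft20 <- structure(list(molecule_id = 1, E = rep(0.5, 20), gamma = 1,
                         n_dropped = 0L), class = "fret_trace")
  ft21 <- structure(list(molecule_id = 2, E = rep(0.5, 21), gamma = 1,
                         n_dropped = 0L), class = "fret_trace")
  h <- build_histogram(list(ft20, ft21))
  expect_equal(h$n_molecules, 1L)
  expect_equal(h$n_excluded_short, 1L)
  expect_error(build_histogram(list(ft20)), "no traces")
})

test_that("histogram weight conservation is exact on random ensembles", {
  set.seed(42)
  fts <- lapply(1:37, function(i) {
    structure(list(molecule_id = i,
                   E = rnorm(sample(21:200, 1), runif(1, 0, 1), 0.3),
                   gamma = 1, n_dropped = 0L), class = "fret_trace")
  })
  h <- build_histogram(fts)
  expect_equal(sum(h$weights), as.numeric(h$n_molecules), tolerance = 1e-12)
})

test_that("histogram and fit are invariant to trace order", {
  set.seed(7)
  fts <- lapply(1:25, function(i) {
    structure(list(molecule_id = i,
                   E = rnorm(100, sample(c(0.3, 0.8), 1), 0.08),
                   gamma = 1, n_dropped = 0L), class = "fret_trace")
  })
  h1 <- build_histogram(fts)
  h2 <- build_histogram(fts[sample(25)])
  expect_equal(h1$weights, h2$weights)
  # bit-level identity is not required (weights are accumulated in trace
  # order), but the fit must agree to numerical precision
  expect_equal(fit_mixture(h1, 2, init = c(0.3, 0.8))$components,
               fit_mixture(h2, 2, init = c(0.3, 0.8))$components,
               tolerance = 1e-7)
})

test_that("mixture fit recovers a single sampled Gaussian", {
  s <- sample_mixture(5000, 0.65, 0.08, 1, seed = 3)
  f <- fit_mixture(build_histogram(s), 1)
  expect_lt(abs(f$components$mean - 0.65), 0.01)
  expect_equal(f$components$fractional_area, 1)
})

test_that("noiseless analytic histograms are refit to optimizer precision", {
  cases <- list(
    list(m = 0.65, s = 0.08, w = 1),
    list(m = c(0.3, 0.7), s = c(0.08, 0.1), w = c(0.4, 0.6)),
    list(m = c(0.29, 0.65, 0.88), s = rep(0.08, 3), w = c(0.25, 0.67, 0.08)))
  for (cs in cases) {
    h <- mixture_histogram(cs$m, cs$s, cs$w, total_weight = 100)
    f <- fit_mixture(h, length(cs$m), init = cs$m)
    expect_equal(f$components$mean, cs$m, tolerance = 1e-4)
    expect_equal(f$components$sd, cs$s, tolerance = 1e-4)
    expect_equal(f$components$fractional_area, cs$w, tolerance = 1e-4)
  }
})

test_that("shared-width fits constrain all components to one sd", {
  # exact self-fit when the generating widths really are equal
  h <- mixture_histogram(c(0.3, 0.67, 0.84), rep(0.08, 3),
                         c(0.58, 0.31, 0.12), total_weight = 50)
  f <- fit_mixture(h, 3, init = c(0.3, 0.67, 0.84), shared_sd = TRUE)
  expect_equal(f$components$mean, c(0.3, 0.67, 0.84), tolerance = 1e-4)
  expect_equal(f$components$sd, rep(0.08, 3), tolerance = 1e-4)
  # the generating areas follow the printed ~100% convention (they sum
  # to 1.01); the fit reports them renormalized to exactly 1
  expect_equal(f$components$fractional_area,
               c(0.58, 0.31, 0.12) / 1.01, tolerance = 1e-4)
  expect_length(unique(f$components$sd), 1)

  # on sampled data the constraint stabilizes the overlapping high pair
  s <- sample_mixture(5000, c(0.32, 0.67, 0.84), rep(0.08, 3),
                      c(0.58, 0.31, 0.12), seed = 5)
  fs <- fit_mixture(build_histogram(s), 3, init = c(0.32, 0.67, 0.84),
                    shared_sd = TRUE)
  expect_length(unique(fs$components$sd), 1)
  expect_lt(abs(fs$components$mean[3] - 0.84), 0.03)
})

test_that("residual SSE never increases with more components", {
  s <- sample_mixture(4000, c(0.3, 0.8), c(0.08, 0.08), c(0.5, 0.5), seed = 9)
  h <- build_histogram(s)
  sse <- vapply(1:4, function(k) fit_mixture(h, k)$residual_sse, 0)
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("fractional areas sum to one and components come sorted by mean", {
  s <- sample_mixture(3000, c(0.2, 0.6, 0.9), rep(0.07, 3),
                      c(0.3, 0.5, 0.2), seed = 4)
  f <- fit_mixture(build_histogram(s), 3)
  expect_equal(sum(f$components$fractional_area), 1, tolerance = 1e-6)
  expect_true(!is.unsorted(f$components$mean))
  expect_true(all(f$components$sd > 0))
  expect_true(all(f$components$mean >= -0.25 & f$components$mean <= 1.25))
})
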