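test_that("step detection finds ideal steps and ignores constant series", {
  # one clean step: new level starts at frame 4
  expect_equal(detect_steps(c(10, 10, 10, 0, 0, 0), min_segment = 2), 4L)
  expect_length(detect_steps(rep(5, 100)), 0)
  set.seed(1)
  expect_length(detect_steps(rnorm(400, 50, 3)), 0)
  # two steps up and down
  s <- c(rep(10, 50), rep(60, 50), rep(5, 50))
  expect_equal(detect_steps(s, min_segment = 5), c(51L, 101L))
  expect_error(detect_steps(c(1, 2), min_segment = 5), "too short")
})

test_that("noisy single steps are localized to within two frames", {
  set.seed(202)
  n_tr <- 300
  hits <- vapply(seq_len(n_tr), function(i) {
    true_step <- sample(50:350, 1)
    s <- c(rep(100, true_step - 1), rep(0, 400 - true_step + 1)) +
      rnorm(400, 0, 5)
    st <- detect_steps(s, max_steps = 2)
    length(st) >= 1 && min(abs(st - true_step)) <= 2
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("trace selection reproduces the accept/reject truth table", {
  # acceptor bleach before donor bleach: accepted
  good <- make_good_trace(a_bleach = 300, d_bleach = 600)
  r <- select_trace(good)
  expect_true(r$accepted)
  expect_equal(r$acceptor_bleach$step_frame, 300L)
  expect_equal(r$donor_bleach$step_frame, 600L)
  expect_equal(r$gamma, 1, tolerance = 1e-10)

  # donor bleaches first: order violation (acceptor drop at 600 comes later)
  swapped <- make_step_trace(
    acc_levels = c(80, 80, 0), acc_steps = c(300, 600),
    don_levels = c(20, 0, 0), don_steps = c(300, 600))
  expect_equal(select_trace(swapped)$reject_reason, "order_violation")

  # two downward acceptor steps: multi-step photobleaching
  multi <- make_step_trace(
    acc_levels = c(160, 80, 0, 0), acc_steps = c(200, 400, 600),
    don_levels = c(20, 20, 100, 0), don_steps = c(200, 400, 600))
  expect_equal(select_trace(multi)$reject_reason, "multi_step")

  # no acceptor bleach within the record
  no_acc <- make_step_trace(
    acc_levels = 80, don_levels = c(20, 0), don_steps = 600)
  expect_equal(select_trace(no_acc)$reject_reason, "no_acceptor_bleach")

  # acceptor bleaches but the donor survives the record
  no_don <- make_step_trace(
    acc_levels = c(80, 0), acc_steps = 300,
    don_levels = c(20, 100), don_steps = 300)
  expect_equal(select_trace(no_don)$reject_reason, "no_donor_bleach")

  short <- make_step_trace(n = 6)
  expect_equal(select_trace(short)$reject_reason, "too_short")
})

test_that("gamma is the ratio of the acceptor and donor jumps at acceptor bleach", {
  tr <- make_good_trace(a_bleach = 300, d_bleach = 600, E = 0.8)
  bc <- list(step_frame = 300L)
  expect_equal(estimate_gamma(tr, bc), 1, tolerance = 1e-12)

  tr2 <- make_step_trace(
    acc_levels = c(90, 0, 0), acc_steps = c(300, 600),
    don_levels = c(10, 55, 0), don_steps = c(300, 600))
  expect_equal(estimate_gamma(tr2, bc), 2, tolerance = 1e-12)

  # anticorrelation in the wrong direction is flagged, not returned
  tr3 <- make_step_trace(
    acc_levels = c(90, 0), acc_steps = 300,
    don_levels = c(55, 10), don_steps = 300)
  expect_error(estimate_gamma(tr3, bc), class = "smfretr_qc_error")
})

test_that("gamma estimation is invariant to a shared constant background", {
  tr <- make_good_trace(a_bleach = 300, d_bleach = 600, E = 0.7,
                        noise_sd = 3, seed = 11)
  shifted <- tr
  shifted$donor <- tr$donor + 37
  shifted$acceptor <- tr$acceptor + 37
  bc <- list(step_frame = 300L)
  expect_equal(estimate_gamma(shifted, bc), estimate_gamma(tr, bc),
               tolerance = 1e-12)
})

test_that("per-molecule gamma is recovered from simulated ensembles", {
  for (g in c(0.7, 1.0, 1.3)) {
    p <- sim_params(n_molecules = 120, total_intensity = 100, noise_sd = 5,
                    background = 0, gamma_mean = g, gamma_sd = 0,
                    seed = round(1000 * g))
    traces <- simulate_ensemble(p)
    qc <- qc_ensemble(traces)
    est <- vapply(Filter(function(r) r$accepted, qc$results),
                  function(r) r$gamma, 0)
    expect_gt(length(est), 20)
    expect_lt(abs(median(est) - g), 0.05)
  }
})

test_that("acceptance rises with acceptor/donor bleach-rate separation", {
  frac <- vapply(c(0.02, 0.05, 0.12), function(ra) {
    p <- sim_params(n_molecules = 250, acceptor_bleach_rate = ra,
                    donor_bleach_rate = 0.015, seed = 17)
    mean(vapply(qc_ensemble(simulate_ensemble(p))$results,
                function(r) r$accepted, TRUE))
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("qc summary counts partition the ensemble", {
  p <- sim_params(n_molecules = 60, seed = 23)
  qc <- qc_ensemble(simulate_ensemble(p))
  expect_identical(sum(qc$summary), 60L)
})
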