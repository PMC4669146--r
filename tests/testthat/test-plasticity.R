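pp20 <- plasticity_params(eta = 1, zeta = 1, tau_plus = 20, tau_minus = 20)

test_that("STDP pair sums match direct evaluation of the exponential kernel", {
  expect_equal(stdp_pair_sum(0, 10, pp20), exp(-0.5))
  expect_equal(stdp_pair_sum(10, 10, pp20), -1)  # tie counts as depression
  expect_equal(stdp_pair_sum(c(0, 5), 10, pp20), exp(-0.5) + exp(-0.25))
  expect_equal(stdp_pair_sum(numeric(0), 10, pp20), 0)
  expect_equal(stdp_pair_sum(10, 0, pp20), -exp(-0.5))
})

test_that("anti-Hebbian STDP is the temporally reversed rule", {
  expect_equal(astdp_pair_sum(0, 10, pp20), -exp(-0.5))
  expect_equal(astdp_pair_sum(10, 0, pp20), exp(-0.5))
  expect_equal(astdp_pair_sum(5, 5, pp20), 1)  # tie potentiates here
  # for any pair of trains, aSTDP(pre, post) equals STDP(post, pre)
  for (seed in 1:10) {
    tr <- withr::with_seed(seed, list(a = sort(runif(5, 0, 30)),
                                      b = sort(runif(7, 0, 30))))
    expect_equal(astdp_pair_sum(tr$a, tr$b, pp20),
                 stdp_pair_sum(tr$b, tr$a, pp20))
  }
})

test_that("trial update matches the brute-force double loop", {
  params <- plasticity_params(eta = 0.01, zeta = 0.004)
  for (seed in 1:8) {
    rec <- random_record(6, 4, 30, rate = 150, seed = seed)
    fast <- mstdp_trial_update(rec, params = params)
    slow <- brute_trial_update(rec, 6, 4, params)
    expect_equal(fast$dW, slow$dW, tolerance = 1e-13)
    expect_equal(fast$dQ, slow$dQ, tolerance = 1e-13)
  }
  # no hidden spikes: zero update
  rec0 <- random_record(6, 0, 30, rate = 150, seed = 1)
  attr(rec0, "n_hid") <- 4
  upd0 <- mstdp_trial_update(rec0, params = params)
  expect_equal(upd0$dW, matrix(0, 6, 4))
})

test_that("feedforward and feedback updates are exactly proportional", {
  params <- plasticity_params(eta = 0.01, zeta = 0.0025)
  for (seed in 1:10) {
    rec <- random_record(5, 5, 40, rate = 200, seed = 100 + seed)
    upd <- mstdp_trial_update(rec, params = params)
    expect_identical(max(abs(upd$dW / params$eta - t(upd$dQ) / params$zeta)), 0)
  }
})

test_that("plain STDP on feedback would give the opposite of the needed symmetry", {
  # for an isolated spike pair the feedback update under (non-mirrored) STDP
  # has the sign flipped relative to the feedforward update
  for (dt in c(-12, -3, 4, 15)) {
    ff <- stdp_pair_sum(0, dt, pp20)            # visible pre, hidden post
    fb_stdp <- stdp_pair_sum(dt, 0, pp20)       # hidden pre, visible post
    fb_astdp <- astdp_pair_sum(dt, 0, pp20)     # the mirrored choice
    expect_equal(sign(fb_stdp), -sign(ff))
    expect_equal(fb_astdp, ff)
  }
})

test_that("mirror symmetry Q = (zeta/eta) t(W) is preserved across updates", {
  params <- plasticity_params(eta = 0.01, zeta = 0.005,
                              w_min = -Inf, w_max = Inf)
  W <- withr::with_seed(1, matrix(runif(20, 0, 0.1), 5, 4))
  weights <- weight_state(W, (params$zeta / params$eta) * t(W), "signed")
  for (seed in 1:50) {
    rec <- random_record(5, 4, 30, rate = 150, seed = 200 + seed)
    weights <- apply_weight_update(weights,
                                   mstdp_trial_update(rec, params = params),
                                   params)
  }
  expect_lt(max(abs(weights$Q - (params$zeta / params$eta) * t(weights$W))),
            1e-12)
})

test_that("bout-count prediction reproduces the worked example and the delta limit", {
  counts <- structure(list(x = 2, y = 3, xhat = 1, dt1 = 10, dt2 = 15,
                           boundary = 10), class = "mstdp_counts")
  pred <- effective_rule_prediction(counts, pp20)
  expect_equal(pred[1, 1], exp(-0.5) * 6 - exp(-0.75) * 3, tolerance = 1e-12)

  # no late bout: pure potentiation
  counts$xhat <- 0; counts$dt2 <- NA_real_
  expect_equal(effective_rule_prediction(counts, pp20)[1, 1],
               exp(-0.5) * 2 * 3)

  # delta-bout identity: all spikes at exactly three instants
  x <- c(3, 0, 2); y <- c(1, 2); xh <- c(1, 1, 0)
  rec <- delta_record(x, y, xh, t1 = 0, t2 = 10, t3 = 25)
  cb <- count_bouts(rec, boundary = 5)
  expect_equal(cb$x, x); expect_equal(cb$y, y); expect_equal(cb$xhat, xh)
  upd <- mstdp_trial_update(rec, params = pp20)
  expect_equal(upd$dW, effective_rule_prediction(cb, pp20), tolerance = 1e-12)
})

test_that("scaled autoencoder rule has the perfect-reconstruction fixed point", {
  x <- c(2, 4, 0); y <- c(1, 3)
  expect_equal(scaled_autoencoder_rule(x, y, 0.5 * x, alpha = 0.5),
               matrix(0, 3, 2))
  expect_equal(scaled_autoencoder_rule(2, 1, 1, alpha = 0.5)[1, 1], 0)
  expect_equal(scaled_autoencoder_rule(x, c(0, 0), c(1, 1, 1), alpha = 1),
               matrix(0, 3, 2))
  expect_error(scaled_autoencoder_rule(x, y, x, alpha = 0), "alpha")
})

test_that("weight updates clip to the mode's bounds", {
  params <- plasticity_params(eta = 1, w_min = 0, w_max = 0.1)
  w <- weight_state(matrix(0.09, 2, 2), matrix(0.01, 2, 2), "nonneg")
  upd <- list(dW = matrix(0.05, 2, 2), dQ = matrix(-0.05, 2, 2))
  w2 <- apply_weight_update(w, upd, params)
  expect_true(all(w2$W == 0.1))
  expect_true(all(w2$Q == 0))
})
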