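test_that("local variation matches hand values and the Poisson expectation", {
  expect_equal(local_variation(c(2, 2, 2)), 0)
  expect_equal(local_variation(c(1, 3)), 3 * 2^2 / 4^2)  # = 0.75
  expect_true(is.na(local_variation(c(1))))
  set.seed(21)
  expect_lt(abs(local_variation(rexp(1e5)) - 1), 0.02)
  # pure ratio statistic: invariant to time rescaling
  set.seed(22); isis <- rgamma(500, 2, 2)
  expect_equal(local_variation(isis), local_variation(isis * 37.5))
})

test_that("firing rate is count over segment length", {
  seg <- list(t_start = 0, t_end = 50)
  expect_equal(firing_rate(seg, spike_train(seq(0.5, 49.5, 1), 50)), 1.0)
  expect_equal(firing_rate(seg, spike_train(numeric(0), 50)), 0)
  set.seed(9)
  est <- vapply(1:100, function(i)
    firing_rate(seg, poisson_train(2, 50)), numeric(1))
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("correlograms agree exactly with the brute-force pair oracle", {
  seg <- list(t_start = 0, t_end = 50)
  for (seed in 1:5) {
    tr1 <- poisson_train(2, 50, seed = seed, id = "a")       # <= ~200 spikes
    tr2 <- poisson_train(1.5, 50, seed = seed + 50, id = "b")
    expect_equal(autocorrelogram(tr1, seg, normalize = FALSE),
                 brute_correlogram(tr1$times, tr1$times,
                                   exclude_self = TRUE))
    expect_equal(crosscorrelogram(tr1, tr2, seg, normalize = FALSE),
                 brute_correlogram(tr1$times, tr2$times))
  }
  # single spike: no pairs
  expect_equal(autocorrelogram(spike_train(5, 50), seg), rep(0, 20))
  # empty comparison train
  expect_equal(crosscorrelogram(poisson_train(1, 50, seed = 1),
                                spike_train(numeric(0), 50), seg),
               rep(0, 20))
  # identical trains: CCG = ACG + zero-lag diagonal (1 after normalization)
  tr <- poisson_train(1, 50, seed = 3)
  acg <- autocorrelogram(tr, seg)
  ccg <- crosscorrelogram(tr, tr, seg)
  expect_equal(ccg, acg + c(1, rep(0, 19)))
})

test_that("periodic trains concentrate ACG mass at multiples of the period", {
  tr <- spike_train(seq(0.05, 49.95, by = 0.1), 50)  # 10 Hz
  acg <- autocorrelogram(tr, list(t_start = 0, t_end = 50))
  brute <- brute_correlogram(tr$times, tr$times, exclude_self = TRUE)
  expect_equal(acg * length(tr$times), brute)
  # all lags are multiples of 100 ms, which sit on 50-ms bin boundaries:
  # mass may only appear in a bin adjacent to such a boundary
  # 5 Hz periodic: lags are multiples of 200 ms -> only bins 4k / 4k+1
  tr5 <- spike_train(seq(0.05, 49.85, by = 0.2), 50)
  acg5 <- autocorrelogram(tr5, list(t_start = 0, t_end = 50))
  allowed <- sort(c(seq(4, 20, 4), seq(5, 20, 4)))
  expect_true(all(acg5[setdiff(1:20, allowed)] == 0))
  expect_gt(sum(acg5[allowed]), 0)
})

test_that("Poisson ACG is flat at rate x bin on average", {
  set.seed(33)
  acgs <- vapply(1:100, function(i)
    autocorrelogram(poisson_train(1, 50), list(t_start = 0, t_end = 50)),
    numeric(20))
  m <- rowMeans(acgs)
  expect_true(all(abs(m - 1 * 0.05) < 0.015))  # rate 1 Hz x 50 ms bins
})

test_that("minimal-distance statistics behave at the limits and are uniform for Poisson", {
  # identical trains: all s = 0, mass in bin 1
  tr <- poisson_train(2, 50, seed = 2)
  md <- minimal_distance_histogram(tr, tr)
  expect_equal(md[1], 1)
  expect_equal(sum(md), 1)
  # far-away two-spike reference: s -> 1, mass in last bin
  tr_far <- spike_train(c(400, 450), 500)
  tr_i <- spike_train(c(1, 2, 3), 500)
  md_far <- minimal_distance_histogram(tr_i, tr_far)
  expect_equal(md_far[25], 1)
  # sentinels for sparse references
  expect_true(all(is.na(minimal_distance_histogram(tr_i,
                                                   spike_train(5, 500)))))
  # uniformity for independent Poisson pairs (KS on the raw s values)
  set.seed(44)
  a <- poisson_train(2, 5000, id = "a")
  b <- poisson_train(2, 5000, id = "b")
  dbar <- mean(diff(b$times))
  pos <- findInterval(a$times, b$times)
  dmin <- pmin(ifelse(pos >= 1, a$times - b$times[pmax(pos, 1)], Inf),
               ifelse(pos < length(b$times),
                      b$times[pmin(pos + 1, length(b$times))] - a$times,
                      Inf))
  s <- 1 - exp(-2 * dmin / dbar)
  ks <- max(abs(seq_along(s) / length(s) - sort(s)))
  expect_lt(ks, 0.02)
})

test_that("SPIKE-distance satisfies the metric axioms on samples", {
  seg <- list(t_start = 0, t_end = 50)
  tr <- poisson_train(1.5, 50, seed = 8)
  expect_equal(spike_distance(tr, tr, seg), 0)
  set.seed(55)
  for (i in 1:20) {
    a <- poisson_train(runif(1, 0.5, 4), 50, id = "a")
    b <- poisson_train(runif(1, 0.5, 4), 50, id = "b")
    d1 <- spike_distance(a, b, seg); d2 <- spike_distance(b, a, seg)
    expect_equal(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
  # independent Poisson pairs average in (0.2, 0.5)
  set.seed(56)
  ds <- vapply(1:30, function(i)
    spike_distance(poisson_train(1, 100), poisson_train(1, 100),
                   list(t_start = 0, t_end = 100)), numeric(1))
  expect_gt(mean(ds), 0.2); expect_lt(mean(ds), 0.5)
  # sentinel when one train is silent in the segment
  expect_true(is.na(spike_distance(tr, spike_train(numeric(0), 50), seg)))
})

test_that("the assembled feature vector has the 68-block structure and symmetry", {
  set.seed(66)
  trains <- lapply(1:3, function(i) poisson_train(1.5, 50, id = paste0("n", i)))
  seg <- list(t_start = 0, t_end = 50)
  fv <- compute_feature_vector(trains, seg)
  expect_equal(length(fv), 68L)
  expect_identical(names(fv), feature_names())
  expect_equal(sum(fv[grep("^md", names(fv))]), 1)
  expect_false(attr(fv, "flagged"))
  # neuron-permutation invariance
  fv2 <- compute_feature_vector(trains[c(3, 1, 2)], seg)
  expect_equal(as.numeric(fv), as.numeric(fv2))
  # three identical trains: SD = 0, MD mass in bin 1
  fv3 <- compute_feature_vector(list(trains[[1]], trains[[1]], trains[[1]]),
                                seg)
  expect_equal(unname(fv3["sd"]), 0)
  expect_equal(unname(fv3["md01"]), 1)
  # sentinel propagation flags the row
  fv4 <- compute_feature_vector(list(trains[[1]], trains[[2]],
                                     spike_train(5, 50)), seg)
  expect_true(attr(fv4, "flagged"))
})

test_that("non-stationarity metrics match their closed forms", {
  set.seed(77)
  expect_lt(ks_distance_to_poisson(rexp(1e4)), 0.02)
  # perfectly regular ISIs: sup | 1{t >= T} - (1 - exp(-t/T)) | -> 1 - 1/e
  expect_lt(abs(ks_distance_to_poisson(rep(2, 1000)) - (1 - exp(-1))),
            0.01)
  expect_true(is.finite(ks_distance_to_poisson(c(1, 2))))  # n = 2, no crash

  # periodic train, window a multiple of the period -> zero SD
  tr <- spike_train(seq(0.25, 99.75, 0.5), 100)
  expect_equal(firing_rate_sd(tr, 5), 0)
  # Poisson: SD of windowed rate ~ sqrt(rate / window)
  set.seed(78)
  sds <- vapply(1:50, function(i) firing_rate_sd(poisson_train(4, 200), 2),
                numeric(1))
  expect_lt(abs(mean(sds) - sqrt(4 / 2)), 0.15)
  # rate-switching 1 <-> 3 Hz: SD ~ 1 Hz
  set.seed(79)
  half1 <- cumsum(rexp(400, 1)); half1 <- half1[half1 < 100]
  half2 <- 100 + cumsum(rexp(800, 3)); half2 <- half2[half2 < 200]
  tr_sw <- spike_train(unique(round(c(half1, half2), 4)), 200)
  sd_sw <- firing_rate_sd(tr_sw, 10)
  expect_lt(abs(sd_sw - 1), 0.35)
})
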