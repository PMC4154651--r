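test_that("burst segmentation follows the gap rule with inclusive boundary", {
  tr <- event_train(c("a", "b", "c", "a", "b"), c(0, 0.05, 0.10, 0.50, 0.55))
  bs <- segment_bursts(tr, 0.2)
  expect_length(bs, 2L)
  expect_equal(bs[[1]]$time, c(0, 0.05, 0.10))
  expect_equal(bs[[2]]$time, c(0.50, 0.55))

  # single event: one singleton burst
  expect_length(segment_bursts(event_train("a", 1), 0.2), 1L)

  # gaps exactly at the cut-off stay in one burst
  tr2 <- event_train(c("a", "b", "c"), c(0, 0.2, 0.4))
  expect_length(segment_bursts(tr2, 0.2), 1L)

  # empty train
  expect_length(segment_bursts(event_train(character(0), numeric(0)), 0.2), 0L)

  # conservation: burst sizes sum to train size
  sys <- fixture_small_system()
  expect_equal(sum(vapply(sys$bursts, nrow, integer(1))), nrow(sys$train))
})

test_that("lag model sigma matches the half-normal closed form and MC truth", {
  mk_bursts <- function(lags) {
    list(data.frame(node = as.character(seq_along(c(0, lags))),
                    time = cumsum(c(0, lags))))
  }
  # all lags equal delta -> sigma = delta
  b1 <- mk_bursts(rep(0.04, 12))
  expect_equal(fit_lag_model(b1)$sigma, 0.04, tolerance = 1e-12)

  # hand computation: lags {0.03, 0.04} (repeated to clear the minimum)
  b2 <- mk_bursts(rep(c(0.03, 0.04), 5))
  expect_equal(fit_lag_model(b2)$sigma, sqrt((0.0009 + 0.0016) / 2),
               tolerance = 1e-12)

  # Monte-Carlo consistency: half-normal with sigma = 0.02
  lags <- withr::with_seed(11, abs(rnorm(1e4, 0, 0.02)))
  expect_equal(fit_lag_model(mk_bursts(lags))$sigma, 0.02, tolerance = 0.025)

  # histogram fit agrees loosely with the MLE on half-normal data
  s_hist <- fit_lag_model(mk_bursts(lags), method = "hist")$sigma
  expect_equal(s_hist, 0.02, tolerance = 0.2)

  expect_error(fit_lag_model(mk_bursts(rep(0.03, 3))), "too few")
})

test_that("gaussian weight has the exact closed-form values", {
  s <- 0.035
  expect_equal(gaussian_weight(0, s), 1)
  expect_equal(gaussian_weight(s, s), exp(-1 / 2))
  expect_equal(gaussian_weight(2 * s, s), exp(-2))
  expect_true(all(diff(gaussian_weight(seq(0, 0.2, by = 0.01), s)) < 0))
  expect_error(gaussian_weight(-0.1, s), "nonnegative")
  expect_error(gaussian_weight(0.1, 0), "positive")
})

test_that("network construction matches the three-node worked example", {
  # burst: 1 at 0, 2 at dt12, 3 at dt13 -> links 1->2, 1->3, 2->3 only
  sigma <- 0.03
  dt12 <- 0.025; dt13 <- 0.060
  bursts <- list(data.frame(node = c("1", "2", "3"),
                            time = c(0, dt12, dt13)))
  net <- build_functional_network(bursts, list(sigma = sigma), 0.2)
  expect_equal(net$w["1", "2"], gaussian_weight(dt12, sigma))
  expect_equal(net$w["1", "3"], gaussian_weight(dt13, sigma))
  expect_equal(net$w["2", "3"], gaussian_weight(dt13 - dt12, sigma))
  expect_equal(net$w["2", "1"], 0)
  expect_equal(net$w["3", "1"], 0)
  expect_equal(net$w["3", "2"], 0)
})

test_that("reinforcement and simultaneity rules accumulate as specified", {
  # same 2-node sequence k times with identical lag
  k <- 7; delta <- 0.03; sigma <- 0.04
  bursts <- rep(list(data.frame(node = c("a", "b"), time = c(0, delta))), k)
  net <- build_functional_network(bursts, list(sigma = sigma), 0.2)
  expect_equal(net$w["a", "b"], k * gaussian_weight(delta, sigma))

  # simultaneous pair in k bursts: unit weight in both directions each time
  bs2 <- rep(list(data.frame(node = c("a", "b"), time = c(1, 1))), k)
  net2 <- build_functional_network(bs2, list(sigma = sigma), 0.2)
  expect_equal(net2$w["a", "b"], k)
  expect_equal(net2$w["b", "a"], k)

  # repeated firings of one node: first onset used
  bs3 <- list(data.frame(node = c("a", "a", "b"), time = c(0, 0.02, 0.03)))
  net3 <- build_functional_network(bs3, list(sigma = sigma), 0.2)
  expect_equal(net3$w["a", "b"], gaussian_weight(0.03, sigma))
})

test_that("construction equals brute-force enumeration on small trains", {
  for (s in 1:25) {
    tr <- withr::with_seed(s, {
      n_ev <- sample(2:5, 1)
      event_train(sample(letters[1:4], n_ev, replace = TRUE),
                  round(cumsum(runif(n_ev, 0, 0.12)), 4))
    })
    bursts <- segment_bursts(tr, 0.2)
    sigma <- 0.03
    net <- build_functional_network(bursts, list(sigma = sigma), 0.2)
    oracle <- oracle_build_network(bursts, sigma, 0.2)
    got <- net$w[rownames(oracle), colnames(oracle), drop = FALSE]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  }
})

test_that("total network weight respects the per-burst pair bound", {
  sys <- fixture_small_system()
  bound <- sum(vapply(sys$bursts, function(b) {
    nb <- length(unique(b$node)); nb * (nb - 1)
  }, numeric(1)))
  expect_lte(total_strength(sys$net), bound)
})

test_that("variation of information matches entropy arithmetic and igraph", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  # {1,2},{3,4} vs all singletons: H(A)=ln2, H(B)=ln4, I=ln2 -> VI=ln2
  expect_equal(variation_of_information(c(1, 1, 2, 2), 1:4), log(2),
               tolerance = 1e-12)
  # symmetry and igraph cross-check on random partitions
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    p <- withr::with_seed(s, list(a = sample(1:4, 30, TRUE),
                                  b = sample(1:5, 30, TRUE)))
    vi_ab <- variation_of_information(p$a, p$b)
    expect_equal(vi_ab, variation_of_information(p$b, p$a))
    expect_equal(vi_ab, igraph::compare(p$a, p$b, method = "vi"),
                 tolerance = 1e-10)
  }
  expect_error(variation_of_information(1:3, 1:4), "same items")
})

test_that("cut-off screening finds the plateau of a bimodal gap structure", {
  # lags ~30 ms inside bursts, ~30 s between bursts
  tr <- withr::with_seed(21, {
    nb <- 40
    starts <- cumsum(runif(nb, 25, 35))
    node <- character(0); tt <- numeric(0)
    for (b in seq_len(nb)) {
      sz <- sample(3:6, 1)
      node <- c(node, as.character(sample(1:12, sz)))
      tt <- c(tt, starts[b] + cumsum(c(0, runif(sz - 1, 0.01, 0.05))))
    }
    event_train(node, tt)
  })
  grid <- seq(0.02, 0.5, by = 0.02)
  cs <- cutoff_sensitivity(tr, grid)
  expect_equal(nrow(cs), length(grid) - 1L)
  plateau <- attr(cs, "plateau_start")
  expect_lte(plateau, 0.2)
  expect_true(all(cs$vi[cs$cutoff >= 0.2] == 0))

  # identical partitions everywhere -> all VI zero, 2-point grid -> 1 value
  cs2 <- cutoff_sensitivity(tr, c(0.2, 0.3))
  expect_equal(nrow(cs2), 1L)
  expect_equal(cs2$vi, 0)
})
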