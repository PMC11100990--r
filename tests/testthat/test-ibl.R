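test_that("activation matches hand-evaluated cases with noise off", {
  p <- noiseless_params()
  inst <- list(attributes = list(x = "a"), utility = 1, occurrences = 4)
  q <- list(x = "a")
  # single occurrence at lag 1, full match: ln(1^-0.5) = 0
  expect_equal(activation(inst, q, p, clock = 5), 0)
  # occurrences at lags 1 and 4
  inst2 <- list(attributes = list(x = "a"), utility = 1, occurrences = c(1, 4))
  expect_equal(activation(inst2, q, p, clock = 5), log(1 + 4^-0.5))
  # one mismatched attribute with S = 0, mu = omega = 1
  inst3 <- list(attributes = list(x = "b", y = "z"), utility = 1,
                occurrences = 4)
  expect_equal(activation(inst3, list(x = "a", y = "z"), p, clock = 5), -1)
})

test_that("activation rejects degenerate inputs", {
  p <- noiseless_params()
  inst <- list(attributes = list(x = "a"), utility = 1, occurrences = numeric(0))
  expect_error(activation(inst, list(x = "a"), p, clock = 5), "no occurrences")
  inst$occurrences <- 6
  expect_error(activation(inst, list(x = "a"), p, clock = 5),
               "future occurrence")
  inst$occurrences <- 4
  sims <- similarity_spec(default = NULL)
  expect_error(activation(inst, list(x = "a"), p, clock = 5, sims = sims),
               "missing similarity")
})

test_that("activation decays with lag and counts simultaneous-lag mass", {
  p <- noiseless_params()
  q <- list(x = "a")
  acts <- vapply(2:30, function(lag)
    activation(list(attributes = list(x = "a"), utility = 1,
                    occurrences = 1), q, p, clock = 1 + lag), numeric(1))
  expect_true(all(diff(acts) < 0))
  # m occurrences all at lag 1 -> ln(m)
  for (m in c(2, 5, 9)) {
    inst <- list(attributes = list(x = "a"), utility = 1,
                 occurrences = rep(7, m))
    expect_equal(activation(inst, q, p, clock = 8), log(m))
  }
})

test_that("retrieval probabilities are a stable, order-preserving soft-max", {
  expect_equal(retrieval_probabilities(c(5, 5, 5), 1), rep(1 / 3, 3))
  expect_equal(retrieval_probabilities(0.3, 2), 1)
  expect_equal(retrieval_probabilities(c(0, log(2)), 1), c(1 / 3, 2 / 3))
  expect_error(retrieval_probabilities(numeric(0), 1))
  expect_error(retrieval_probabilities(c(0, NaN), 1))
  # huge activations do not overflow thanks to the max shift
  expect_equal(sum(retrieval_probabilities(c(1e4, 1e4 + 1), 1)), 1)
  set.seed(7)
  for (rep in 1:50) {
    a <- rnorm(sample(2:8, 1), sd = 3)
    tau <- runif(1, 0.05, 2)
    pr <- retrieval_probabilities(a, tau)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_equal(pr, retrieval_probabilities(a + 17.3, tau),
                 tolerance = 1e-12) # shift invariance
    expect_equal(order(pr), order(a)) # order preserving
  }
})

test_that("blended values are convex combinations of stored utilities", {
  p <- noiseless_params(tau = 1)
  mem <- ibl_memory()
  mem <- record_outcome(mem, list(x = "a"), 0.7)
  mem <- record_outcome(mem, list(x = "b"), 0.7)
  expect_equal(blended_value(mem, list(x = "c"), p), 0.7)
  # equal activations, utilities 0 and 1 -> 0.5
  mem2 <- ibl_memory()
  mem2$instances <- list(
    list(attributes = list(x = "a"), utility = 0, occurrences = 1),
    list(attributes = list(x = "b"), utility = 1, occurrences = 1))
  mem2$clock <- 1L
  expect_equal(blended_value(mem2, list(x = "c"), p), 0.5)
  # P = [1/3, 2/3] from the soft-max example, u = [0, 1] -> 2/3
  mem3 <- ibl_memory()
  mem3$instances <- list(
    list(attributes = list(x = "q"), utility = 0, occurrences = 1),
    list(attributes = list(x = "q"), utility = 1, occurrences = rep(1, 2)))
  mem3$clock <- 1L
  # activations are 0 and ln 2 at lag 1 with tau = 1
  expect_equal(blended_value(mem3, list(x = "q"), p), 2 / 3)
  expect_error(blended_value(ibl_memory(), list(x = "a"), p), "cold option")
})

test_that("package equations match the brute-force oracle on small memories", {
  set.seed(101)
  for (rep in 1:40) {
    cs <- random_memory_case(sample(1:5, 1))
    p <- noiseless_params()
    acts <- vapply(cs$memory$instances, function(inst)
      activation(inst, cs$query, p, clock = cs$clock), numeric(1))
    oracle_acts <- vapply(cs$truth, function(tr)
      oracle_activation(tr$occ, cs$clock, d = 0.5, mu = 1,
                        sims_vec = as.numeric(tr$value == cs$query$x)),
      numeric(1))
    expect_equal(acts, oracle_acts, tolerance = 1e-10)
    expect_equal(retrieval_probabilities(acts, p$tau),
                 oracle_softmax(oracle_acts, p$tau), tolerance = 1e-10)
    u <- vapply(cs$memory$instances, function(i) i$utility, numeric(1))
    expect_equal(blended_value(cs$memory, cs$query, p),
                 oracle_blend(oracle_acts, u, p$tau), tolerance = 1e-10)
    expect_gte(blended_value(cs$memory, cs$query, p), min(u))
    expect_lte(blended_value(cs$memory, cs$query, p), max(u))
  }
})

test_that("retrieval mass concentrates on the max activation as tau -> 0", {
  pr <- retrieval_probabilities(c(0.1, 0.25, -0.4), tau = 1e-6)
  expect_gt(pr[2], 1 - 1e-6)
})

test_that("choose_option picks the argmax and breaks ties uniformly", {
  expect_equal(choose_option(c(A = 0.2, B = 0.9, C = 0.1)), "B")
  expect_equal(choose_option(c(A = 1.0)), "A")
  expect_error(choose_option(numeric(0)))
  expect_error(choose_option(c(A = Inf, B = 1)))
  set.seed(5)
  draws <- replicate(10000, choose_option(c(A = 0.5, B = 0.5)))
  expect_equal(mean(draws == "A"), 0.5, tolerance = 0.02)
})

test_that("record_outcome dedups by (attributes, utility) and advances the clock", {
  mem <- ibl_memory()
  mem <- record_outcome(mem, list(x = "a"), 1)
  expect_identical(mem$clock, 1L)
  expect_length(mem$instances, 1)
  mem <- record_outcome(mem, list(x = "a"), 1)
  expect_identical(mem$clock, 2L)
  expect_length(mem$instances, 1)
  expect_equal(mem$instances[[1]]$occurrences, c(1, 2))
  # utility is part of instance identity
  mem <- record_outcome(mem, list(x = "a"), 0)
  expect_length(mem$instances, 2)
  expect_error(record_outcome(mem, list(x = "a"), NA_real_))
})

test_that("prepopulation defines values before experience and is removable", {
  p <- noiseless_params(tau = 1)
  mem <- prepopulate(ibl_memory(), list(x = "a"), 1.0)
  expect_equal(blended_value(mem, list(x = "a"), p), 1.0)
  # one real observation of 0 pulls the value strictly inside (0, 1)
  mem <- record_outcome(mem, list(x = "a"), 0)
  v <- blended_value(mem, list(x = "a"), p)
  expect_gt(v, 0); expect_lt(v, 1)
  expect_error(blended_value(ibl_memory(), list(x = "a"), p), "cold option")
})

test_that("activation noise follows the configured distribution", {
  set.seed(9)
  inst <- list(attributes = list(x = "a"), utility = 1, occurrences = 4)
  p_log <- agent_params(noise = TRUE, sigma = 0.25)
  draws <- replicate(4000,
    activation(inst, list(x = "a"), p_log, clock = 5))
  # logistic xi: mean 0, sd sigma * pi / sqrt(3)
  expect_equal(mean(draws), 0, tolerance = 0.05)
  expect_equal(sd(draws), 0.25 * pi / sqrt(3), tolerance = 0.05)
  p_norm <- agent_params(noise = TRUE, sigma = 0.25, noise_dist = "normal")
  draws_n <- replicate(4000,
    activation(inst, list(x = "a"), p_norm, clock = 5))
  expect_equal(sd(draws_n), 0.25, tolerance = 0.03)
})

test_that("agent parameter defaults and invariants hold", {
  p <- agent_params()
  expect_equal(p$d, 0.5); expect_equal(p$mu, 1)
  expect_equal(p$sigma, 0.25); expect_equal(p$tau, 0.25 * sqrt(2))
  expect_error(agent_params(d = -1))
  expect_error(agent_params(sigma = -0.1))
  expect_error(agent_params(tau = 0))
  expect_error(agent_params(omega = c(x = -1)))
  # named per-attribute weights apply, unnamed attributes fall back to 1
  p2 <- noiseless_params(omega = c(x = 2))
  inst <- list(attributes = list(x = "b"), utility = 1, occurrences = 4)
  expect_equal(activation(inst, list(x = "a"), p2, clock = 5), -2)
})
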