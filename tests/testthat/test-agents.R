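toy_options <- function() list(task_option(list(x = "A")),
                               task_option(list(x = "B")))

test_that("fresh IBL values equal the optimistic prepopulation default", {
  ag <- make_agent("IBL", params = noiseless_params())
  v <- ibl_values(ag, toy_options())
  expect_equal(unname(v), c(1, 1))
  # identical options get identical values with noise off
  ag2 <- make_agent("IBL", params = noiseless_params())
  v2 <- ibl_values(ag2, list(task_option(list(x = "A")),
                             task_option(list(x = "A"))))
  expect_equal(v2[["opt1"]], v2[["opt2"]])
})

test_that("a rewarded option outranks one observed at zero", {
  ag <- make_agent("IBL", params = noiseless_params())
  opts <- toy_options()
  invisible(ibl_values(ag, opts)) # registers prepopulation
  ag$mem_ibl <- record_outcome(ag$mem_ibl, opts[[1]], 1)
  ag$mem_ibl <- record_outcome(ag$mem_ibl, opts[[2]], 0)
  v <- ibl_values(ag, opts)
  expect_gt(v[["opt1"]], v[["opt2"]])
})

degenerate_repr <- function() {
  r <- gaussian_representation(c(0, 0))
  function(option) r
}

test_that("GER with Sim_GM identically 1 reduces to the plain IBL model", {
  # every option maps to the same representation, so the representation
  # attribute contributes omega * (1 - 1) = 0 to every activation
  params <- noiseless_params()
  ag_ger <- make_agent("GER", params = params, repr_fun = degenerate_repr(),
                       sim_gm_fun = sim_gm("kl"))
  ag_ibl <- make_agent("IBL", params = params)
  opts <- toy_options()
  for (step in 1:6) {
    u <- (step %% 2)
    pick <- opts[[1 + step %% 2]]
    expect_equal(unname(ger_values(ag_ger, opts)),
                 unname(ibl_values(ag_ibl, opts)))
    ag_ger$mem_ger <- record_outcome(ag_ger$mem_ger,
                                     with_repr_test(ag_ger, pick), u)
    ag_ibl$mem_ibl <- record_outcome(ag_ibl$mem_ibl, pick, u)
  }
})

test_that("a mismatched representation lowers activation by mu * omega * (1 - Sim)", {
  params <- noiseless_params()
  r_mem <- gaussian_representation(0)
  r_query_half <- gaussian_representation(sqrt(2 * log(2))) # KL_sym = ln 2
  expect_equal(kl_similarity(r_mem, r_query_half), 0.5)
  inst <- list(attributes = list(x = "a", repr = r_mem), utility = 1,
               occurrences = 1)
  sims <- similarity_spec(repr = sim_gm("kl"))
  a_match <- activation(inst, list(x = "a", repr = r_mem), params,
                        clock = 2, sims = sims)
  a_half <- activation(inst, list(x = "a", repr = r_query_half), params,
                       clock = 2, sims = sims)
  expect_equal(a_match - a_half, 0.5)
})

test_that("options whose representation is nearer a rewarded instance score higher", {
  params <- noiseless_params()
  near <- gaussian_representation(0.2)
  far <- gaussian_representation(3)
  rewarded <- gaussian_representation(0)
  reprs <- list(A = near, B = far)
  ag <- make_agent("GER", params = params,
                   repr_fun = function(o) reprs[[o$attributes$x]],
                   sim_gm_fun = sim_gm("kl"), prepopulation = NULL)
  ag$mem_ger <- record_outcome(ag$mem_ger,
                               list(x = "A", repr = rewarded), 1)
  ag$mem_ger <- record_outcome(ag$mem_ger,
                               list(x = "B", repr = gaussian_representation(6)), 0)
  # two query options differing only in representation
  ag2 <- make_agent("GER", params = params,
                    repr_fun = function(o) reprs[[o$attributes$x]],
                    sim_gm_fun = sim_gm("kl"), prepopulation = NULL)
  ag2$mem_ger <- record_outcome(ag2$mem_ger, list(repr = rewarded), 1)
  ag2$mem_ger <- record_outcome(ag2$mem_ger, list(repr = gaussian_representation(10)), 0)
  v <- ger_values(ag2, list(task_option(list(x = "A")),
                            task_option(list(x = "B"))))
  expect_gt(v[["opt1"]], v[["opt2"]])
})

test_that("train_to_match converges on constant and realizable targets", {
  set.seed(21)
  net <- mlp_init(utility_net_spec(4, hidden = c(16, 16), seed = 21))
  X <- matrix(rnorm(40), 10, 4)
  # zero epochs: unchanged weights, initial MSE reported
  net0 <- train_to_match(net, X, rep(0.7, 10), epochs = 0)
  expect_identical(net0$W, net$W)
  expect_length(net0$loss, 1)
  netc <- train_to_match(net, X, rep(0.7, 10), epochs = 500, lr = 1e-2)
  expect_lt(netc$loss[length(netc$loss)], 1e-3)
  expect_true(all(abs(mlp_predict(netc, X) - 0.7) < 0.05))
  # linear teacher on 32-dim synthetic embeddings
  set.seed(22)
  X2 <- matrix(rnorm(200 * 32), 200, 32)
  w <- rnorm(32) / sqrt(32)
  y2 <- as.numeric(X2 %*% w)
  net2 <- mlp_init(utility_net_spec(32, hidden = c(64, 64), seed = 22))
  net2 <- train_to_match(net2, X2, y2, epochs = 1000, lr = 1e-2)
  expect_lt(mean((mlp_predict(net2, X2) - y2)^2), 0.01)
  expect_lte(net2$loss[length(net2$loss)], net2$loss[1])
})

test_that("network gradients agree with finite differences", {
  set.seed(31)
  spec <- utility_net_spec(3, hidden = 4, epochs = 1, lr = 0)
  net <- mlp_init(spec)
  net$W[[2]] <- matrix(rnorm(4), 4, 1) # move off the zero output layer
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  # analytic gradient of the first-layer weight (via one SGD step at tiny lr)
  loss_at <- function(w11) {
    n2 <- net; n2$W[[1]][1, 1] <- w11
    mean((mlp_predict(n2, X) - y)^2)
  }
  eps <- 1e-6
  num_grad <- (loss_at(net$W[[1]][1, 1] + eps) -
               loss_at(net$W[[1]][1, 1] - eps)) / (2 * eps)
  acts <- ginger:::mlp_forward(net, X)
  pred <- as.numeric(acts[[3]])
  delta <- matrix(2 * (pred - y) / 5, 5, 1)
  back <- delta %*% t(net$W[[2]]) * (acts[[2]] > 0)
  ana_grad <- crossprod(acts[[1]], back)[1, 1]
  expect_equal(ana_grad, num_grad, tolerance = 1e-6)
})

test_that("GIN values start at zero and track a frozen teacher after fitting", {
  reprs <- list(A = c(1, 0), B = c(0, 1))
  mk <- function() make_agent("GIN", params = noiseless_params(),
                              repr_fun = function(o) reprs[[o$attributes$x]],
                              net_spec = utility_net_spec(2, hidden = c(16, 16),
                                                          seed = 3))
  ag <- mk()
  opts <- toy_options()
  expect_equal(unname(gin_values(ag, opts)), c(0, 0))
  # build teacher experience, then converge the net on the frozen teacher
  for (i in 1:5) {
    ag$mem_ibl <- record_outcome(ag$mem_ibl, opts[[1]], 1)
    ag$mem_ibl <- record_outcome(ag$mem_ibl, opts[[2]], 0)
  }
  for (o in opts) {
    key <- ginger:::opt_key(o)
    ag$train_set[[key]] <- list(option = o, input = reprs[[o$attributes$x]])
  }
  ginger:::refit_net(ag, epochs = 2000)
  tp <- ginger:::teacher_params(ag$params)
  teach <- vapply(opts, function(o)
    blended_value(ag$mem_ibl, o, tp, ag$sims), numeric(1))
  v <- gin_values(ag, opts)
  expect_true(all(abs(unname(v) - teach) < 0.05))
})

test_that("GINGER values are the exact midpoint of GIN and GER values", {
  expect_equal(ginger_values(c(opt1 = 0.2), c(opt1 = 0.6)), c(opt1 = 0.4))
  expect_error(ginger_values(c(opt1 = 1), c(opt2 = 1)), "option set mismatch")
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    g1 <- setNames(rnorm(n), paste0("opt", 1:n))
    g2 <- setNames(rnorm(n), paste0("opt", 1:n))
    expect_identical(ginger_values(g1, g2), 0.5 * g1 + 0.5 * g2)
    expect_identical(ginger_values(g1, g1), g1)
  }
})

test_that("observe() requires a preceding step and agents are seed-deterministic", {
  ag <- make_agent("IBL", params = noiseless_params())
  expect_error(observe(ag, toy_options()[[1]], 1), "before agent_step")
  run_seq <- function(seed) {
    set.seed(seed)
    ag <- make_agent("IBL")
    picks <- character()
    for (t in 1:15) {
      ch <- agent_step(ag, toy_options())
      observe(ag, ch, as.numeric(ch$attributes$x == "A"))
      picks <- c(picks, ch$attributes$x)
    }
    picks
  }
  expect_identical(run_seq(99), run_seq(99))
})

test_that("tied values produce a uniform random choice", {
  ag <- make_agent("IBL", params = noiseless_params())
  set.seed(13)
  picks <- replicate(2000, {
    ch <- agent_step(ag, toy_options())
    ag$pending <- FALSE
    ch$attributes$x
  })
  expect_equal(mean(picks == "A"), 0.5, tolerance = 0.04)
})

test_that("all four agents master a deterministic toy bandit", {
  vae <- shared_vae()
  spec <- bandit_task_spec(n_episodes = 1, episode_min = 50, episode_max = 50,
                           p_target = 1, p_other = 0, seed = 5)
  for (kind in c("IBL", "GER", "GIN", "GINGER")) {
    set.seed(61)
    ag <- task_agent(kind, "bandit", params = noiseless_params(), vae = vae)
    rec <- run_bandit(ag, spec)
    acc <- mean(rec$correct[rec$trial >= 10 & rec$trial <= 50])
    expect_gte(acc, 0.95)
  }
})

test_that("pretraining samples reproducibly and seeds single-instance values", {
  spec <- phishing_task_spec(n = 239, embedding_dim = 8, seed = 2)
  st1 <- phishing_stream(spec)
  st2 <- phishing_stream(spec)
  expect_identical(st1, st2)
  expect_length(st1$pretrain_idx, 24)
  ag <- make_agent("IBL", params = noiseless_params(), prepopulation = NULL)
  i <- st1$pretrain_idx[1]
  opts <- email_options(st1$corpus, i)
  correct <- if (st1$corpus$label[i] == "phishing") opts[[2]] else opts[[1]]
  pretrain(ag, list(list(option = correct, reward = 1)))
  expect_equal(blended_value(ag$mem_ibl, correct, ag$params), 1)
})
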