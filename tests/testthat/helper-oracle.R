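# Independent brute-force transcription of the activation / retrieval /
# blending equations, written as plain loops over the algebra and kept
# deliberately separate from the package's code paths.

oracle_activation <- function(occurrences, clock, d, mu, sims_vec, omega = 1) {
  base <- 0
  for (tp in occurrences) base <- base + (clock - tp)^(-d)
  mism <- 0
  for (s in sims_vec) mism <- mism + omega * (s - 1)
  log(base) + mu * mism
}

oracle_softmax <- function(a, tau) {
  e <- numeric(length(a))
  for (i in seq_along(a)) e[i] <- exp(a[i] / tau)
  e / sum(e)
}

oracle_blend <- function(a, u, tau) {
  p <- oracle_softmax(a, tau)
  total <- 0
  for (i in seq_along(u)) total <- total + p[i] * u[i]
  total
}

# Random small memory over a single symbolic attribute, plus a query;
# returns everything needed to compare package vs oracle with noise off.
random_memory_case <- function(n_instances, clock = 10L) {
  vals <- c("a", "b", "c")
  mem <- ibl_memory()
  truth <- list()
  used <- character()
  for (i in seq_len(n_instances)) {
    repeat {
      v <- sample(vals, 1)
      u <- sample(c(0, 0.5, 1), 1)
      key <- paste(v, u)
      if (!key %in% used) break
    }
    used <- c(used, key)
    occ <- sort(sample.int(clock - 1L, sample(1:3, 1)))
    mem$instances[[i]] <- list(attributes = list(x = v), utility = u,
                               occurrences = as.numeric(occ))
    truth[[i]] <- list(value = v, utility = u, occ = occ)
  }
  mem$clock <- clock - 1L
  list(memory = mem, truth = truth,
       query = list(x = sample(vals, 1)), clock = clock)
}

# Shared small beta-VAE fixture, trained once per test session.
shared_vae <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- train_stimulus_bvae("bandit",
                                                      bvae_spec(seed = 11L),
                                                      size = 16L)
    cache
  }
})

noiseless_params <- function(...) agent_params(noise = FALSE, ...)

with_repr_test <- function(agent, option) ginger:::with_repr(agent, option)

email_feature_names_test <- function() ginger:::email_feature_names
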