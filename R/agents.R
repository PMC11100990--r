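# The four ablation agents share one interface. Agents are environments
# (reference semantics): stepping and observing mutate the agent in place,
# mirroring how an experiential learner accumulates memory across trials.
#
# IBL     — blended values over hand-crafted attributes only.
# GER     — adds a generative-model representation as an extra attribute whose
#           similarity is a Sim_GM metric (KL for Gaussian posteriors, cosine
#           for embeddings).
# GIN     — a utility network over representations, trained to match the
#           blended values of an internal teacher IBL model.
# GINGER  — evenly averages the GIN and GER per-option values.

agent_kinds <- c("IBL", "GER", "GIN", "GINGER")

opt_key <- function(option) {
  if (!is.null(option$id)) return(as.character(option$id))
  attrs <- option$attributes
  attrs <- attrs[setdiff(names(attrs), "repr")]
  paste(names(attrs), vapply(attrs, function(a) paste(format(a), collapse = ","),
                             character(1)),
        sep = "=", collapse = ";")
}

repr_to_vec <- function(repr) {
  if (inherits(repr, "gaussian_representation")) return(repr$mean)
  as.numeric(repr)
}

#' Create an ablation agent
#'
#' Constructs one of the four agents (IBL, GER, GIN, GINGER). All kinds use
#' identical default [agent_params()] (no fitting): the ablation varies only
#' which information channels are present, never the parameter values.
#'
#' @param kind `"IBL"`, `"GER"`, `"GIN"`, or `"GINGER"`.
#' @param params An [agent_params()].
#' @param sims [similarity_spec()] for the hand-crafted attributes.
#' @param repr_fun Function `task_option -> representation` (a
#'   [gaussian_representation()] or a numeric embedding). Required for GER,
#'   GIN and GINGER.
#' @param sim_gm_fun Representation similarity, e.g. [sim_gm()]. Required for
#'   GER and GINGER.
#' @param net_spec A [utility_net_spec()] for the utility network. Required
#'   for GIN and GINGER.
#' @param net_input_fun Function `(option, repr) -> numeric vector` mapping an
#'   option to the network input; defaults to the representation vector
#'   (posterior mean for Gaussians, the embedding itself otherwise).
#' @param prepopulation Default utility for optimistic prepopulation of
#'   unseen options, or `NULL` to disable (blending then errors on an empty
#'   memory).
#' @return A `ginger_agent` environment.
#' @export
make_agent <- function(kind, params = agent_params(),
                       sims = similarity_spec(),
                       repr_fun = NULL, sim_gm_fun = NULL,
                       net_spec = NULL, net_input_fun = NULL,
                       prepopulation = 1) {
  kind <- match.arg(kind, agent_kinds)
  needs_repr <- kind %in% c("GER", "GIN", "GINGER")
  needs_net <- kind %in% c("GIN", "GINGER")
  needs_sim <- kind %in% c("GER", "GINGER")
  if (needs_repr && is.null(repr_fun)) stop(kind, " requires repr_fun")
  if (needs_sim && is.null(sim_gm_fun)) stop(kind, " requires sim_gm_fun")
  if (needs_net && is.null(net_spec)) stop(kind, " requires net_spec")
  ag <- new.env(parent = emptyenv())
  ag$kind <- kind
  ag$params <- params
  ag$sims <- sims
  ag$sims_ger <- if (needs_sim)
    structure(list(fns = c(sims$fns, list(repr = sim_gm_fun)),
                   default = sims$default), class = "similarity_spec")
  ag$repr_fun <- repr_fun
  ag$repr_cache <- new.env(parent = emptyenv())
  ag$net <- if (needs_net) mlp_init(net_spec)
  ag$net_spec <- net_spec
  ag$net_input_fun <- if (is.null(net_input_fun))
    function(option, repr) repr_to_vec(repr) else net_input_fun
  ag$mem_ibl <- ibl_memory()     # IBL memory / GIN teacher memory
  ag$mem_ger <- ibl_memory()
  ag$train_set <- new.env(parent = emptyenv())  # key -> list(option, input)
  ag$prepop_done <- new.env(parent = emptyenv())
  ag$prepopulation <- prepopulation
  ag$pending <- FALSE
  ag$n_observed <- 0L
  ag$n_steps <- 0L
  class(ag) <- c("ginger_agent", "environment")
  ag
}

agent_repr <- function(agent, option) {
  key <- opt_key(option)
  if (!is.null(agent$repr_cache[[key]])) return(agent$repr_cache[[key]])
  r <- agent$repr_fun(option)
  if (is.null(r)) stop("missing representation for option '", key, "'")
  agent$repr_cache[[key]] <- r
  r
}

with_repr <- function(agent, option) {
  option$attributes$repr <- agent_repr(agent, option)
  option
}

ensure_prepopulated <- function(agent, mem_name, option) {
  if (is.null(agent$prepopulation)) return(invisible())
  key <- paste0(mem_name, "\r", opt_key(option))
  if (!is.null(agent$prepop_done[[key]])) return(invisible())
  agent$prepop_done[[key]] <- TRUE
  agent[[mem_name]] <- prepopulate(agent[[mem_name]], option,
                                   agent$prepopulation)
  invisible()
}

#' Blended values over hand-crafted attributes
#'
#' Per-option blended values of the plain IBL model (exact-match similarities
#' on symbolic features). Unseen options are optimistically prepopulated when
#' the agent enables prepopulation.
#'
#' @param agent A `ginger_agent`.
#' @param options List of `task_option`s.
#' @return Named numeric vector (names `opt1..optN` by position).
#' @export
ibl_values <- function(agent, options) {
  vapply(seq_along(options), function(i) {
    ensure_prepopulated(agent, "mem_ibl", options[[i]])
    blended_value(agent$mem_ibl, options[[i]], agent$params, agent$sims)
  }, numeric(1)) -> v
  names(v) <- paste0("opt", seq_along(options))
  v
}

#' Blended values with a generative representation attribute
#'
#' Like [ibl_values()] but each option additionally carries its
#' generative-model representation as the attribute `"repr"`, scored by the
#' agent's Sim_GM metric inside the activation's partial-matching sum. When
#' Sim_GM is identically 1 these values coincide with the plain IBL values.
#'
#' @inheritParams ibl_values
#' @return Named numeric vector.
#' @export
ger_values <- function(agent, options) {
  if (is.null(agent$sims_ger)) stop("agent has no Sim_GM configured")
  vapply(seq_along(options), function(i) {
    q <- with_repr(agent, options[[i]])
    ensure_prepopulated(agent, "mem_ger", q)
    blended_value(agent$mem_ger, q, agent$params, agent$sims_ger)
  }, numeric(1)) -> v
  names(v) <- paste0("opt", seq_along(options))
  v
}

#' Utility-network values over representations
#'
#' Per-option predictions of the agent's utility network applied to each
#' option's representation. The network is periodically refit to match the
#' blended values of the internal teacher IBL model (see [train_to_match()]).
#'
#' @inheritParams ibl_values
#' @return Named numeric vector.
#' @export
gin_values <- function(agent, options) {
  if (is.null(agent$net)) stop("agent has no utility network")
  vapply(seq_along(options), function(i) {
    x <- agent$net_input_fun(options[[i]], agent_repr(agent, options[[i]]))
    mlp_predict(agent$net, x)
  }, numeric(1)) -> v
  names(v) <- paste0("opt", seq_along(options))
  v
}

#' Evenly average GIN and GER values
#'
#' The full model's action values: the exact midpoint `0.5 * gin + 0.5 * ger`
#' per option.
#'
#' @param gin,ger Named numeric vectors over the same option set.
#' @return Named numeric vector.
#' @export
ginger_values <- function(gin, ger) {
  if (!identical(sort(names(gin)), sort(names(ger))))
    stop("option set mismatch")
  0.5 * gin + 0.5 * ger[names(gin)]
}

#' Train a utility network to match teacher values
#'
#' Fits the network by mean squared error against target utilities produced
#' by a teacher model (the IBL blended values), rather than against raw
#' environment rewards. Warm-starts from the current weights.
#'
#' @param net An `mlp` (see [mlp_init()]).
#' @param X Matrix of representation inputs (rows = samples).
#' @param targets Finite numeric teacher values.
#' @param epochs,lr Optional overrides of the spec's training settings.
#' @return The trained network with its MSE trace in `$loss`.
#' @export
train_to_match <- function(net, X, targets, epochs = net$spec$epochs,
                           lr = net$spec$lr) {
  mlp_train(net, X, targets, epochs = epochs, lr = lr)
}

teacher_params <- function(params) {
  params$noise <- FALSE
  params
}

refit_net <- function(agent, epochs = agent$net_spec$epochs) {
  keys <- ls(agent$train_set)
  if (length(keys) == 0L) return(invisible())
  X <- do.call(rbind, lapply(keys, function(k) agent$train_set[[k]]$input))
  # the teacher is the full IBL model, including optimistic prepopulation
  for (k in keys)
    ensure_prepopulated(agent, "mem_ibl", agent$train_set[[k]]$option)
  tp <- teacher_params(agent$params)
  y <- vapply(keys, function(k)
    blended_value(agent$mem_ibl, agent$train_set[[k]]$option, tp, agent$sims),
    numeric(1))
  agent$net <- train_to_match(agent$net, X, y, epochs = epochs)
  invisible()
}

agent_values <- function(agent, options) {
  switch(agent$kind,
         IBL = ibl_values(agent, options),
         GER = ger_values(agent, options),
         GIN = gin_values(agent, options),
         GINGER = ginger_values(gin_values(agent, options),
                                ger_values(agent, options)))
}

register_training_option <- function(agent, option) {
  key <- opt_key(option)
  if (is.null(agent$train_set[[key]]))
    agent$train_set[[key]] <- list(
      option = option,
      input = agent$net_input_fun(option, agent_repr(agent, option)))
  invisible()
}

#' Take one decision step
#'
#' Computes the kind-appropriate per-option values and chooses the
#' highest-valued option (exact ties broken uniformly at random). The chosen
#' option is returned with the value vector attached as the `"values"`
#' attribute; follow with [observe()] to record the outcome.
#'
#' @param agent A `ginger_agent`.
#' @param options List of `task_option`s presented this trial.
#' @return The chosen `task_option` (with `attr(, "values")`).
#' @export
agent_step <- function(agent, options) {
  # the teacher IBL can value every presented option, so all of them enter
  # the utility network's training set, not only the chosen one; refitting
  # just before prediction lets the network inherit the teacher's optimism
  # about options it has never tried
  if (agent$kind %in% c("GIN", "GINGER")) {
    for (o in options) register_training_option(agent, o)
    agent$n_steps <- agent$n_steps + 1L
    if ((agent$n_steps - 1L) %% agent$net_spec$refit_every == 0L)
      refit_net(agent)
  }
  v <- agent_values(agent, options)
  pick <- choose_option(v)
  idx <- match(pick, names(v))
  agent$pending <- TRUE
  chosen <- options[[idx]]
  attr(chosen, "values") <- v
  attr(chosen, "index") <- idx
  chosen
}

record_experience <- function(agent, option, reward) {
  agent$mem_ibl <- record_outcome(agent$mem_ibl, option, reward)
  if (agent$kind %in% c("GER", "GINGER"))
    agent$mem_ger <- record_outcome(agent$mem_ger, with_repr(agent, option),
                                    reward)
  if (agent$kind %in% c("GIN", "GINGER"))
    register_training_option(agent, option)
  invisible()
}

#' Record an observed outcome
#'
#' Stores the experienced (option, reward) pair into every memory the agent
#' kind maintains (IBL memory, GER memory with representation, GIN teacher
#' memory) and refits the utility network at the configured cadence.
#'
#' @param agent A `ginger_agent`.
#' @param option The `task_option` that was chosen.
#' @param reward Finite numeric reward.
#' @return The agent, invisibly.
#' @export
observe <- function(agent, option, reward) {
  if (!isTRUE(agent$pending))
    stop("observe() called before agent_step() on this trial")
  agent$pending <- FALSE
  record_experience(agent, option, reward)
  agent$n_observed <- agent$n_observed + 1L
  invisible(agent)
}

#' Pretrain an agent on labeled experience
#'
#' Records each (option, reward) pair as experience before trial 1 and, for
#' network-bearing agents, performs one initial fit to the teacher values.
#' Used by the phishing task, where a seeded 10% sample of the corpus
#' pretrains every model under comparison.
#'
#' @param agent A `ginger_agent`.
#' @param items List of `list(option =, reward =)` pairs.
#' @return The agent, invisibly.
#' @export
pretrain <- function(agent, items) {
  for (it in items) record_experience(agent, it$option, it$reward)
  if (agent$kind %in% c("GIN", "GINGER")) refit_net(agent)
  invisible(agent)
}
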