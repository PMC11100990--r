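# Seeded simulators for the three experimental paradigms: the nine-feature
# contextual bandit, the three-phase transfer-of-learning task, and the
# synthetic phishing identification task.

bandit_dims <- function() list(shape = stimulus_shapes,
                               color = stimulus_colors,
                               texture = stimulus_textures)

#' Contextual-bandit task specification
#'
#' Three options per trial, each a unique shape/color/texture combination;
#' across the three options every one of the 9 feature values appears exactly
#' once. One feature is the "feature of interest": choosing the option that
#' carries it pays reward 1 with probability `p_target` (default 75%), any
#' other option pays 1 with probability `p_other` (default 25%). Episodes
#' last 20-25 trials before the feature of interest changes.
#'
#' @param n_episodes Episodes per simulated run.
#' @param episode_min,episode_max Inclusive episode-length range in trials.
#' @param p_target,p_other Reward-1 probabilities for target / non-target
#'   choices.
#' @param seed Integer seed.
#' @return A `bandit_task_spec`.
#' @export
bandit_task_spec <- function(n_episodes = 20L, episode_min = 20L,
                             episode_max = 25L, p_target = 0.75,
                             p_other = 0.25, seed = 1L) {
  if (episode_min > episode_max) stop("episode length range must be ordered")
  if (any(c(p_target, p_other) < 0 | c(p_target, p_other) > 1))
    stop("reward probabilities must lie in [0, 1]")
  structure(list(n_episodes = as.integer(n_episodes),
                 episode_min = as.integer(episode_min),
                 episode_max = as.integer(episode_max),
                 p_target = p_target, p_other = p_other,
                 seed = as.integer(seed)), class = "bandit_task_spec")
}

#' Episode schedule for the contextual bandit
#'
#' Draws each episode's length uniformly from the configured range and a
#' fresh feature of interest per episode (never repeating the immediately
#' preceding one).
#'
#' @param spec A [bandit_task_spec()].
#' @return A data.frame with columns `episode`, `length`, `foi_dim`,
#'   `foi_value`.
#' @export
bandit_episodes <- function(spec) {
  set.seed(spec$seed)
  dims <- bandit_dims()
  feats <- do.call(rbind, lapply(names(dims), function(d)
    data.frame(dim = d, value = dims[[d]], stringsAsFactors = FALSE)))
  len_range <- spec$episode_min:spec$episode_max
  lens <- if (length(len_range) == 1L) rep(len_range, spec$n_episodes)
          else sample(len_range, spec$n_episodes, replace = TRUE)
  foi <- integer(spec$n_episodes)
  for (e in seq_len(spec$n_episodes)) {
    repeat {
      cand <- sample.int(nrow(feats), 1L)
      if (e == 1L || cand != foi[e - 1L]) break
    }
    foi[e] <- cand
  }
  data.frame(episode = seq_len(spec$n_episodes), length = lens,
             foi_dim = feats$dim[foi], foi_value = feats$value[foi],
             stringsAsFactors = FALSE)
}

#' Generate one bandit trial
#'
#' Builds the three options by independently permuting each dimension's three
#' values over the three screen positions, so each option has exactly one
#' shape, one color and one texture and the nine feature values each appear
#' exactly once across the options. Position assignment is randomized per
#' trial, so the target option's position is uniform.
#'
#' @param dims Named list of active dimensions and their values (defaults to
#'   all three stimulus dimensions).
#' @return List of three `task_option`s.
#' @export
bandit_trial <- function(dims = bandit_dims()) {
  perms <- lapply(dims, sample)
  lapply(1:3, function(pos) {
    attrs <- lapply(perms, `[[`, pos)
    task_option(attrs)
  })
}

#' Index of the option carrying the feature of interest
#'
#' @param options List of `task_option`s from one trial.
#' @param foi_dim,foi_value The feature of interest.
#' @return Integer position of the (unique) target option.
#' @export
target_index <- function(options, foi_dim, foi_value) {
  hits <- which(vapply(options, function(o)
    identical(o$attributes[[foi_dim]], foi_value), logical(1)))
  if (length(hits) != 1L) stop("feature of interest not unique in trial")
  hits
}

#' Probabilistic reward for a bandit choice
#'
#' Bernoulli(`p_target`) when the chosen option carries the feature of
#' interest, Bernoulli(`p_other`) otherwise.
#'
#' @param spec A [bandit_task_spec()].
#' @param option The chosen `task_option`.
#' @param foi_dim,foi_value The episode's feature of interest.
#' @return Reward in \{0, 1\}.
#' @export
bandit_feedback <- function(spec, option, foi_dim, foi_value) {
  if (!foi_dim %in% names(option$attributes))
    stop("option does not carry dimension '", foi_dim, "'")
  p <- if (identical(option$attributes[[foi_dim]], foi_value))
    spec$p_target else spec$p_other
  stats::rbinom(1L, 1L, p)
}

#' Run an agent through the contextual bandit
#'
#' Simulates the full episode schedule, one [agent_step()]/[observe()] pair
#' per trial, and logs one trial record per decision.
#'
#' @param agent A `ginger_agent` (or `NULL` for a uniform-random policy).
#' @param spec A [bandit_task_spec()].
#' @param run_id Identifier copied into the records.
#' @return A data.frame of trial records: `run`, `episode`, `trial` (within
#'   episode), `target_pos`, `chosen_pos`, `correct`, `reward`, and per-option
#'   values `v1..v3`.
#' @export
run_bandit <- function(agent, spec = bandit_task_spec(), run_id = 1L) {
  sched <- bandit_episodes(spec)
  rows <- vector("list", sum(sched$length))
  r <- 0L
  for (e in seq_len(nrow(sched))) {
    for (tr in seq_len(sched$length[e])) {
      options <- bandit_trial()
      tgt <- target_index(options, sched$foi_dim[e], sched$foi_value[e])
      if (is.null(agent)) {
        idx <- sample.int(3L, 1L)
        chosen <- options[[idx]]
        vals <- rep(NA_real_, 3L)
      } else {
        chosen <- agent_step(agent, options)
        idx <- attr(chosen, "index")
        vals <- as.numeric(attr(chosen, "values"))
      }
      reward <- bandit_feedback(spec, chosen, sched$foi_dim[e],
                                sched$foi_value[e])
      if (!is.null(agent)) observe(agent, chosen, reward)
      r <- r + 1L
      rows[[r]] <- data.frame(run = run_id, episode = e, trial = tr,
                              target_pos = tgt, chosen_pos = idx,
                              correct = as.integer(idx == tgt),
                              reward = reward,
                              v1 = vals[1], v2 = vals[2], v3 = vals[3])
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Transfer-of-learning task

#' Transfer-of-learning task specification
#'
#' Three phases of 15 trials (45 total): phase 1 presents shape-only options,
#' phase 2 adds color, phase 3 adds texture. Each phase's feature of interest
#' lives in the newest active dimension (shape, then color, then texture), so
#' previously learned dimensions become distractors and performance depends on
#' transferring knowledge across phases. Feedback follows the 75/25 scheme of
#' the contextual bandit.
#'
#' @param trials_per_phase Trials in each phase (default 15).
#' @param p_target,p_other Reward-1 probabilities.
#' @param seed Integer seed.
#' @return A `transfer_task_spec`.
#' @export
transfer_task_spec <- function(trials_per_phase = 15L, p_target = 0.75,
                               p_other = 0.25, seed = 1L) {
  structure(list(trials_per_phase = as.integer(trials_per_phase),
                 p_target = p_target, p_other = p_other,
                 seed = as.integer(seed),
                 phases = list(c("shape"), c("shape", "color"),
                               c("shape", "color", "texture"))),
            class = "transfer_task_spec")
}

#' Generate one transfer-task trial
#'
#' Options carry only the phase's active dimensions, with the same
#' feature-coverage construction as the bandit within each active dimension.
#'
#' @param spec A [transfer_task_spec()].
#' @param phase Phase number, 1-3.
#' @return List of three `task_option`s.
#' @export
transfer_trial <- function(spec, phase) {
  if (!phase %in% 1:3) stop("phase must be 1, 2 or 3")
  dims <- bandit_dims()[spec$phases[[phase]]]
  bandit_trial(dims)
}

#' Run an agent through the transfer task
#'
#' @param agent A `ginger_agent` (or `NULL` for a uniform-random policy).
#' @param spec A [transfer_task_spec()].
#' @param run_id Identifier copied into the records.
#' @return A data.frame of trial records with a `phase` column.
#' @export
run_transfer <- function(agent, spec = transfer_task_spec(), run_id = 1L) {
  set.seed(spec$seed)
  newest <- c("shape", "color", "texture")
  dims <- bandit_dims()
  foi_value <- unname(vapply(newest, function(d) sample(dims[[d]], 1L),
                             character(1)))
  rows <- list()
  for (phase in 1:3) {
    for (tr in seq_len(spec$trials_per_phase)) {
      options <- transfer_trial(spec, phase)
      tgt <- target_index(options, newest[phase], foi_value[phase])
      if (is.null(agent)) {
        idx <- sample.int(3L, 1L)
        chosen <- options[[idx]]
        vals <- rep(NA_real_, 3L)
      } else {
        chosen <- agent_step(agent, options)
        idx <- attr(chosen, "index")
        vals <- as.numeric(attr(chosen, "values"))
      }
      p <- if (idx == tgt) spec$p_target else spec$p_other
      reward <- stats::rbinom(1L, 1L, p)
      if (!is.null(agent)) observe(agent, chosen, reward)
      rows[[length(rows) + 1L]] <-
        data.frame(run = run_id, episode = phase, phase = phase, trial = tr,
                   target_pos = tgt, chosen_pos = idx,
                   correct = as.integer(idx == tgt), reward = reward,
                   v1 = vals[1], v2 = vals[2], v3 = vals[3])
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Phishing identification task

round_half_up <- function(x) floor(x + 0.5)

#' Phishing identification task specification
#'
#' A synthetic corpus of emails (six binary expert features, a ham/phishing
#' label, and an embedding) presented one at a time; the agent chooses
#' `"ham"` or `"phishing"` and earns 1 for a correct categorization, 0
#' otherwise. A seeded fraction of the corpus (default 10%) is held out to
#' pretrain every model before trial 1.
#'
#' @param n Corpus size (default 239, the scale of the reference corpus).
#' @param embedding_dim Embedding length (default 32 for tractable runs; set
#'   1536 to mirror language-model embeddings).
#' @param phishing_fraction Fraction of phishing emails.
#' @param effect_strength,noise_sd Passed to [generate_synthetic_emails()].
#' @param pretrain_fraction Fraction of the corpus used for pretraining.
#' @param seed Integer seed.
#' @return A `phishing_task_spec`.
#' @export
phishing_task_spec <- function(n = 239L, embedding_dim = 32L,
                               phishing_fraction = 0.5,
                               effect_strength = 0.4, noise_sd = 0.1,
                               pretrain_fraction = 0.10, seed = 1L) {
  if (pretrain_fraction <= 0 || pretrain_fraction >= 1)
    stop("pretrain_fraction must be in (0, 1)")
  structure(list(n = as.integer(n), embedding_dim = as.integer(embedding_dim),
                 phishing_fraction = phishing_fraction,
                 effect_strength = effect_strength, noise_sd = noise_sd,
                 pretrain_fraction = pretrain_fraction,
                 seed = as.integer(seed)), class = "phishing_task_spec")
}

#' Build the two decision options for an email
#'
#' Each option carries the email's six expert features plus an `action`
#' attribute (`"ham"` or `"phishing"`); the email's row index is kept in the
#' option's `meta` field for representation lookup.
#'
#' @param corpus A corpus from [generate_synthetic_emails()].
#' @param i Email row index.
#' @return List of two `task_option`s (ham first).
#' @export
email_options <- function(corpus, i) {
  feats <- as.list(corpus$features[i, ])
  lapply(c("ham", "phishing"), function(a) {
    o <- task_option(c(feats, list(action = a)),
                     id = sprintf("e%03d:%s", i, a))
    o$meta <- list(email = i)
    o
  })
}

#' Generate the phishing trial stream
#'
#' Generates the corpus, draws the seeded pretraining subset, and fixes the
#' presentation order of the remaining emails. Pretraining subset and stream
#' partition the corpus.
#'
#' @param spec A [phishing_task_spec()].
#' @return A list with `corpus`, integer vectors `pretrain_idx` and
#'   `stream_idx`.
#' @export
phishing_stream <- function(spec) {
  corpus <- generate_synthetic_emails(
    n = spec$n, embedding_dim = spec$embedding_dim,
    phishing_fraction = spec$phishing_fraction,
    effect_strength = spec$effect_strength, noise_sd = spec$noise_sd,
    seed = spec$seed)
  set.seed(spec$seed + 1L)
  n_pre <- round_half_up(spec$n * spec$pretrain_fraction)
  pretrain_idx <- sort(sample.int(spec$n, n_pre))
  stream_idx <- sample(setdiff(seq_len(spec$n), pretrain_idx))
  list(corpus = corpus, pretrain_idx = pretrain_idx, stream_idx = stream_idx)
}

#' Representation lookup for phishing options
#'
#' Returns a `repr_fun` for [make_agent()] that maps an email option to its
#' embedding row in the corpus.
#'
#' @param corpus A corpus from [generate_synthetic_emails()].
#' @return Function `task_option -> numeric embedding`.
#' @export
email_repr_fun <- function(corpus) {
  function(option) as.numeric(corpus$embeddings[option$meta$email, ])
}

#' Network input for phishing options
#'
#' Concatenates the email embedding with a 0/1 indicator of the `"phishing"`
#' action, so one utility network can value both options of a trial.
#'
#' @return Function `(option, repr) -> numeric vector` for [make_agent()].
#' @export
email_net_input_fun <- function() {
  function(option, repr)
    c(repr_to_vec(repr),
      as.numeric(identical(option$attributes$action, "phishing")))
}

#' Run an agent through the phishing task
#'
#' Pretrains the agent on the held-out subset (correct action, reward 1),
#' then streams the remaining emails in the seeded order.
#'
#' @param agent A `ginger_agent` (or `NULL` for a uniform-random policy).
#' @param spec A [phishing_task_spec()].
#' @param stream Optionally a precomputed [phishing_stream()] (so several
#'   agents can share one corpus and order).
#' @param run_id Identifier copied into the records.
#' @return A data.frame of trial records: `run`, `trial`, `email`, `label`,
#'   `chosen`, `correct`, `reward`, `v_ham`, `v_phishing`.
#' @export
run_phishing <- function(agent, spec = phishing_task_spec(),
                         stream = NULL, run_id = 1L) {
  if (is.null(stream)) stream <- phishing_stream(spec)
  corpus <- stream$corpus
  if (!is.null(agent)) {
    items <- lapply(stream$pretrain_idx, function(i) {
      opts <- email_options(corpus, i)
      correct <- if (corpus$label[i] == "phishing") opts[[2]] else opts[[1]]
      list(option = correct, reward = 1)
    })
    pretrain(agent, items)
  }
  rows <- vector("list", length(stream$stream_idx))
  for (t in seq_along(stream$stream_idx)) {
    i <- stream$stream_idx[t]
    options <- email_options(corpus, i)
    if (is.null(agent)) {
      idx <- sample.int(2L, 1L)
      chosen <- options[[idx]]
      vals <- rep(NA_real_, 2L)
    } else {
      chosen <- agent_step(agent, options)
      idx <- attr(chosen, "index")
      vals <- as.numeric(attr(chosen, "values"))
    }
    action <- c("ham", "phishing")[idx]
    correct <- as.integer(action == corpus$label[i])
    if (!is.null(agent)) observe(agent, chosen, correct)
    rows[[t]] <- data.frame(run = run_id, trial = t, email = i,
                            label = corpus$label[i], chosen = action,
                            correct = correct, reward = correct,
                            v_ham = vals[1], v_phishing = vals[2])
  }
  do.call(rbind, rows)
}
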