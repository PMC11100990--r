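#' Agent parameters for an Instance-Based Learning model
#'
#' Bundles the free parameters of the IBL activation, retrieval and blending
#' equations. Defaults follow the standard values used in dynamic
#' decision-making research: decay `d = 0.5`, mismatch penalty `mu = 1`,
#' attribute weights `omega = 1`, noise scale `sigma = 0.25`, and soft-max
#' temperature `tau = sigma * sqrt(2)` (the PyIBL convention).
#'
#' @param d Memory decay exponent, `d >= 0`.
#' @param mu Mismatch penalty applied to partial matches, dimensionless.
#' @param omega Attribute weights: a single nonnegative number applied to all
#'   attributes, or a named numeric vector of per-attribute weights (missing
#'   attributes default to 1).
#' @param sigma Activation noise scale, `sigma >= 0`.
#' @param tau Soft-max temperature, `tau > 0`. Defaults to `sigma * sqrt(2)`;
#'   if `sigma` is 0 a small positive floor (`1e-6`) keeps retrieval defined.
#' @param noise Logical; include the noise term `sigma * xi` in activations?
#' @param noise_dist Distribution of the noise variate `xi`: `"logistic"`
#'   (`log((1 - u) / u)`, `u ~ U(0,1)`) or `"normal"` (standard normal).
#'
#' @return An object of class `agent_params` (a named list).
#' @examples
#' p <- agent_params()
#' p$tau # 0.25 * sqrt(2)
#' @export
agent_params <- function(d = 0.5, mu = 1, omega = 1, sigma = 0.25,
                         tau = NULL, noise = TRUE,
                         noise_dist = c("logistic", "normal")) {
  noise_dist <- match.arg(noise_dist)
  if (d < 0) stop("d must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(unlist(omega) < 0)) stop("omega weights must be >= 0")
  if (is.null(tau)) tau <- if (sigma > 0) sigma * sqrt(2) else 1e-6
  if (tau <= 0) stop("tau must be > 0")
  structure(list(d = d, mu = mu, omega = omega, sigma = sigma, tau = tau,
                 noise = noise, noise_dist = noise_dist),
            class = "agent_params")
}

# Per-attribute weight lookup: scalar omega applies everywhere; named vector
# falls back to 1 for unnamed attributes.
omega_weight <- function(params, attr_name) {
  om <- params$omega
  if (length(om) == 1L && is.null(names(om))) return(as.numeric(om))
  if (!is.null(names(om)) && attr_name %in% names(om))
    return(as.numeric(om[[attr_name]]))
  1
}

# One draw of the activation noise variate xi.
noise_draw <- function(params) {
  if (identical(params$noise_dist, "normal")) return(stats::rnorm(1))
  u <- stats::runif(1)
  log((1 - u) / u)
}

#' Exact-match similarity
#'
#' The binary similarity used for hand-crafted task features: 1 for identical
#' values, 0 otherwise.
#'
#' @return A similarity function `(a, b) -> 0 or 1`.
#' @export
similarity_exact <- function() {
  f <- function(a, b) if (identical(a, b)) 1 else 0
  structure(f, exact = TRUE)
}

#' Similarity specification
#'
#' A named collection of per-attribute similarity functions. Attributes
#' without an entry use the `default` function (exact match unless overridden).
#' Every similarity function must attain its maximum (1) at self-comparison.
#'
#' @param ... Named similarity functions, one per attribute.
#' @param default Fallback similarity for attributes not named in `...`.
#' @return An object of class `similarity_spec`.
#' @examples
#' sims <- similarity_spec(shape = similarity_exact())
#' @export
similarity_spec <- function(..., default = similarity_exact()) {
  fns <- list(...)
  if (length(fns) && (is.null(names(fns)) || any(names(fns) == "")))
    stop("all similarity functions must be named by attribute")
  structure(list(fns = fns, default = default), class = "similarity_spec")
}

sim_for <- function(sims, attr_name) {
  if (!is.null(sims$fns[[attr_name]])) return(sims$fns[[attr_name]])
  if (is.null(sims$default)) stop("missing similarity for attribute '",
                                  attr_name, "'")
  sims$default
}

#' A choosable option
#'
#' An option is a named list of attribute values (hand-crafted symbolic
#' features and, optionally, a generative-model representation stored under
#' the reserved attribute name `"repr"`).
#'
#' @param attributes Named list of attribute values.
#' @param id Optional opaque identifier.
#' @return An object of class `task_option`.
#' @export
task_option <- function(attributes, id = NULL) {
  if (length(attributes) && (is.null(names(attributes)) ||
                             any(names(attributes) == "")))
    stop("option attributes must be named")
  structure(list(attributes = attributes, id = id), class = "task_option")
}

#' Create an empty instance memory
#'
#' Memory holds decision instances (attribute values, utility outcome, and the
#' time steps at which the instance occurred) plus a decision clock. The clock
#' starts at 0 and advances by exactly one per recorded decision; activation at
#' decision time uses `clock + 1` as the current time, so every stored
#' occurrence (including prepopulated ones at time 0) lies strictly in the
#' past.
#'
#' @return An object of class `ibl_memory`.
#' @export
ibl_memory <- function() {
  structure(list(instances = list(), clock = 0L), class = "ibl_memory")
}

new_instance <- function(attributes, utility, occurrences) {
  list(attributes = attributes, utility = utility,
       occurrences = as.numeric(occurrences))
}

# Index of a stored instance matching (attributes, utility), or 0.
match_instance <- function(memory, attributes, utility) {
  for (i in seq_along(memory$instances)) {
    inst <- memory$instances[[i]]
    if (isTRUE(all.equal(inst$utility, utility)) &&
        identical(inst$attributes, attributes)) return(i)
  }
  0L
}

#' Record a decision outcome into memory
#'
#' Advances the clock by one and stores the experienced (option, utility) pair.
#' A repeat observation of an identical (attributes, utility) instance appends
#' an occurrence time rather than duplicating the instance.
#'
#' @param memory An `ibl_memory`.
#' @param option The experienced `task_option` (or a named attribute list).
#' @param utility Finite numeric utility outcome.
#' @return The updated memory.
#' @export
record_outcome <- function(memory, option, utility) {
  if (!is.finite(utility)) stop("utility must be finite")
  attrs <- if (inherits(option, "task_option")) option$attributes else option
  memory$clock <- memory$clock + 1L
  idx <- match_instance(memory, attrs, utility)
  if (idx > 0L) {
    memory$instances[[idx]]$occurrences <-
      c(memory$instances[[idx]]$occurrences, memory$clock)
  } else {
    memory$instances[[length(memory$instances) + 1L]] <-
      new_instance(attrs, utility, memory$clock)
  }
  memory
}

#' Prepopulate memory with a default instance
#'
#' Inserts an instance at time 0 carrying the option's attributes and a default
#' utility, so that blended values are defined before any real experience.
#' Optimistic prepopulation (default utility at the task's maximum reward)
#' induces the exploration that learning in bandit-style tasks requires.
#'
#' @param memory An `ibl_memory`.
#' @param option A `task_option` (or named attribute list) to prepopulate.
#' @param utility Default utility, typically the task's maximum reward.
#' @return The updated memory.
#' @export
prepopulate <- function(memory, option, utility = 1) {
  attrs <- if (inherits(option, "task_option")) option$attributes else option
  idx <- match_instance(memory, attrs, utility)
  if (idx > 0L) return(memory)
  memory$instances[[length(memory$instances) + 1L]] <-
    new_instance(attrs, utility, 0)
  memory
}

#' Activation of a memory instance
#'
#' Computes the ACT-R style activation
#' \deqn{A_i(t) = \ln\!\Big(\sum_{t' \in T_i(t)} (t - t')^{-d}\Big) +
#'   \mu \sum_{j} \omega_j (S_{ij} - 1) + \sigma \xi}
#' combining power-law recency/frequency over the instance's occurrence times,
#' a partial-matching penalty over the query option's attributes, and optional
#' noise.
#'
#' An instance attribute absent for a query attribute scores similarity 0
#' (maximal mismatch); this arises in transfer tasks where old instances
#' predate newly introduced stimulus dimensions.
#'
#' @param instance A stored instance (attributes, utility, occurrences).
#' @param query The query `task_option`.
#' @param params An `agent_params`.
#' @param clock Current time step; all occurrences must be `< clock`.
#' @param sims A `similarity_spec`.
#' @return Scalar activation.
#' @export
activation <- function(instance, query, params, clock,
                       sims = similarity_spec()) {
  occ <- instance$occurrences
  if (length(occ) == 0L) stop("no occurrences")
  if (any(occ >= clock)) stop("future occurrence")
  qattrs <- if (inherits(query, "task_option")) query$attributes else query
  base <- log(sum((clock - occ)^(-params$d)))
  mismatch <- 0
  for (j in names(qattrs)) {
    sfun <- sim_for(sims, j)
    s <- if (j %in% names(instance$attributes))
      sfun(instance$attributes[[j]], qattrs[[j]]) else 0
    mismatch <- mismatch + omega_weight(params, j) * (s - 1)
  }
  a <- base + params$mu * mismatch
  if (isTRUE(params$noise) && params$sigma > 0)
    a <- a + params$sigma * noise_draw(params)
  a
}

#' Soft-max retrieval probabilities
#'
#' Maps instance activations to retrieval probabilities through a temperature-
#' controlled soft-max, computed with a max shift for numerical stability.
#'
#' @param activations Numeric vector of finite activations.
#' @param tau Temperature, `tau > 0`.
#' @return Probability vector summing to 1.
#' @export
retrieval_probabilities <- function(activations, tau) {
  if (length(activations) == 0L) stop("activations must be non-empty")
  if (any(!is.finite(activations))) stop("non-finite activation")
  if (tau <= 0) stop("tau must be > 0")
  z <- (activations - max(activations)) / tau
  e <- exp(z)
  e / sum(e)
}

# Activations of every stored instance against a query (internal).
memory_activations <- function(memory, query, params, sims,
                               clock = memory$clock + 1L) {
  vapply(memory$instances, activation, numeric(1),
         query = query, params = params, clock = clock, sims = sims)
}

#' Blended value of an option
#'
#' The retrieval-probability-weighted average of stored utilities: instances
#' are activated against the query option (partial matching doing the soft
#' grouping of memory by option), converted to retrieval probabilities, and
#' blended with their utilities. The result always lies within the range of
#' stored utilities.
#'
#' @param memory An `ibl_memory` with at least one instance.
#' @param query The query `task_option`.
#' @param params An `agent_params`.
#' @param sims A `similarity_spec`.
#' @param clock Current time step (defaults to the next decision time).
#' @return Scalar blended value.
#' @export
blended_value <- function(memory, query, params,
                          sims = similarity_spec(),
                          clock = memory$clock + 1L) {
  if (length(memory$instances) == 0L) stop("cold option")
  acts <- memory_activations(memory, query, params, sims, clock)
  p <- retrieval_probabilities(acts, params$tau)
  u <- vapply(memory$instances, function(i) i$utility, numeric(1))
  sum(p * u)
}

#' Choose the highest-valued option
#'
#' Returns the name of an argmax option; exact ties are broken uniformly at
#' random.
#'
#' @param values Named numeric vector or named list of finite option values.
#' @return The chosen option name.
#' @export
choose_option <- function(values) {
  v <- unlist(values)
  if (length(v) == 0L) stop("no options to choose from")
  if (any(!is.finite(v))) stop("non-finite option value")
  if (is.null(names(v)) || any(names(v) == ""))
    stop("option values must be named")
  top <- which(v == max(v))
  if (length(top) == 1L) return(names(v)[top])
  names(v)[top[sample.int(length(top), 1L)]]
}
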