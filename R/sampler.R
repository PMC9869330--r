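#' Dirichlet-multinomial posterior predictive of a mutation cluster
#'
#' Under the symmetric Dirichlet(1) base distribution over the C mutation
#' classes, a cluster ("dish") with class counts n gives class c the
#' posterior predictive probability (n_c + 1) / (sum(n) + C). An empty or
#' brand-new cluster gives 1/C for every class.
#'
#' @param counts Non-negative integer vector of per-class counts (length C).
#' @param class Optional class index (1-based). If `NULL`, the full
#'   probability vector over classes is returned.
#' @return Probability (or vector of probabilities summing to 1).
#' @examples
#' dish_predictive(c(3, 1, 0, 0), 1)   # (3+1)/(4+4) = 0.5
#' dish_predictive(numeric(96))[1]     # 1/96
#' @export
dish_predictive <- function(counts, class = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- (counts + 1) / (sum(counts) + length(counts))
  if (is.null(class)) p else p[class]
}

#' Conditional seating distribution at one restaurant
#'
#' Reference implementation of the Chinese-restaurant-franchise conditional
#' used when reseating a mutation of a given class: an existing table t is
#' chosen with probability proportional to its occupancy times the posterior
#' predictive of its dish for the class, and a new table with probability
#' proportional to the node's concentration parameter times the parent
#' predictive of the class. The parent predictive of a node is the mixture
#' `(sum_t n_t f_t(c) + alpha * parent) / (sum_t n_t + alpha)`, grounded at
#' 1/C for the base distribution; [layer_predictive()] computes one such
#' step.
#'
#' This mirrors the compiled sampler and exists for exposition and testing.
#'
#' @param table_sizes Integer vector of table occupancies at the node.
#' @param dish_counts List (one per table) of per-class count vectors of the
#'   table's dish.
#' @param class Class index (1-based) of the mutation being seated.
#' @param alpha Concentration parameter of the node.
#' @param parent_pred Predictive probability of `class` under the parent
#'   process (use `1/C` when the parent is the base distribution).
#' @return Numeric vector of length `length(table_sizes) + 1`; the last
#'   element is the new-table probability. Sums to 1.
#' @examples
#' # one table, occupancy 1, dish predictive 1/96, alpha 1, parent 1/96:
#' seating_probs(1, list(numeric(96)), 5, 1, 1 / 96)  # 0.5, 0.5
#' @export
seating_probs <- function(table_sizes, dish_counts, class, alpha, parent_pred) {
  stopifnot(length(table_sizes) == length(dish_counts), alpha > 0)
  if (any(table_sizes < 0)) stop("negative table occupancy", call. = FALSE)
  w <- vapply(seq_along(table_sizes), function(i)
    table_sizes[i] * dish_predictive(dish_counts[[i]], class),
    numeric(1))
  w <- c(w, alpha * parent_pred)
  w / sum(w)
}

#' @rdname seating_probs
#' @export
layer_predictive <- function(table_sizes, dish_counts, class, alpha,
                             parent_pred) {
  w <- vapply(seq_along(table_sizes), function(i)
    table_sizes[i] * dish_predictive(dish_counts[[i]], class),
    numeric(1))
  (sum(w) + alpha * parent_pred) / (sum(table_sizes) + alpha)
}

#' Resample a Dirichlet-process concentration parameter
#'
#' Auxiliary-variable Gibbs update for a concentration parameter shared by
#' one or more restaurants, under a Gamma(shape, beta) prior (beta is the
#' rate). For each restaurant j with `n[j] > 0` customers and `t[j]` tables,
#' draws `w_j ~ Beta(alpha + 1, n_j)` and `s_j ~ Bernoulli(n_j / (n_j +
#' alpha))`, then draws the new value from `Gamma(shape + sum(t) - sum(s),
#' rate = beta - sum(log w))`. With no customers anywhere the update is a
#' draw from the prior.
#'
#' Uses R's global RNG (the compiled sampler carries its own stream).
#'
#' @param alpha Current value (> 0).
#' @param n Integer vector of per-restaurant customer counts.
#' @param t Integer vector of per-restaurant table counts.
#' @param shape,beta Gamma prior shape and rate, both > 0.
#' @return New alpha value.
#' @export
sample_dp_concentration <- function(alpha, n, t, shape, beta) {
  stopifnot(length(n) == length(t), alpha > 0, shape > 0, beta > 0,
            all(n >= 0), all(t >= 0))
  keep <- n > 0
  if (!any(keep)) return(stats::rgamma(1, shape, rate = beta))
  n <- n[keep]; t <- t[keep]
  w <- stats::rbeta(length(n), alpha + 1, n)
  s <- stats::rbinom(length(n), 1, n / (n + alpha))
  rate <- beta - sum(log(w))
  if (rate <= 0) stop("non-positive rate in concentration update", call. = FALSE)
  stats::rgamma(1, shape + sum(t) - sum(s), rate = rate)
}

#' Sampler configuration
#'
#' Collects the Gibbs-sampling settings used by [run_chain()],
#' [run_multi_chain()] and [hdp_fit()]. Scheme-dependent defaults follow the
#' benchmarked settings: prior rate (beta) 20 for SBS-96 and 50 for ID-83.
#' The paper-scale sampling configuration is 20 chains of 200 samples spaced
#' 100 sweeps apart; the defaults here are the desk-scale profile (4 chains
#' x 20 samples, spacing 10, burn-in 500) suitable for moderate catalogs.
#'
#' @param scheme A [catalog_scheme()] or name, used for the beta default.
#' @param burnin Burn-in sweeps before the first recorded sample.
#' @param n_chains Number of independent chains.
#' @param n_samples Gibbs samples recorded per chain.
#' @param spacing Sweeps between recorded samples.
#' @param prior_shape,prior_beta Gamma prior (shape, rate) on concentration
#'   parameters.
#' @param init_dishes Number of clusters used by the dispersed round-robin
#'   initialization.
#' @param alpha_init Initial concentration value; defaults to the prior mean.
#' @param resample_alpha Resample concentration parameters each sweep?
#'   Setting `FALSE` fixes them at `alpha_init`.
#' @param seed Base seed; chain i uses `seed + i`.
#' @param checkpoint_path Optional path; the chain state is checkpointed
#'   there periodically (suffix `_chain<i>` is added per chain).
#' @param checkpoint_every Sweeps between checkpoints.
#' @param cores Chains run via `parallel::mclapply` when `cores > 1`;
#'   results are identical to serial execution because each chain owns its
#'   seed and RNG stream.
#' @return List of class `hdp_config`.
#' @export
hdp_config <- function(scheme = "SBS96", burnin = 500L, n_chains = 4L,
                       n_samples = 20L, spacing = 10L,
                       prior_shape = 1,
                       prior_beta = if (as_scheme(scheme)$name == "ID83") 50 else 20,
                       init_dishes = 8L,
                       alpha_init = prior_shape / prior_beta,
                       resample_alpha = TRUE, seed = 1L,
                       checkpoint_path = NULL, checkpoint_every = 1000L,
                       cores = 1L) {
  if (!is.numeric(prior_beta) || prior_beta <= 0)
    stop("prior_beta must be > 0", call. = FALSE)
  if (!is.numeric(prior_shape) || prior_shape <= 0)
    stop("prior_shape must be > 0", call. = FALSE)
  if (n_samples <= 0) stop("n_samples must be >= 1", call. = FALSE)
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  if (spacing < 1 || burnin < 0) stop("invalid burnin/spacing", call. = FALSE)
  structure(list(burnin = as.integer(burnin), n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 spacing = as.integer(spacing),
                 prior_shape = prior_shape, prior_beta = prior_beta,
                 init_dishes = as.integer(init_dishes),
                 alpha_init = alpha_init, resample_alpha = resample_alpha,
                 seed = as.integer(seed),
                 checkpoint_path = checkpoint_path,
                 checkpoint_every = as.integer(checkpoint_every),
                 cores = as.integer(cores)),
            class = "hdp_config")
}

# counts matrix from catalog or plain matrix
sampler_counts <- function(catalog) {
  if (inherits(catalog, "mutation_catalog")) catalog$counts
  else if (is.matrix(catalog)) catalog
  else stop("catalog must be a mutation_catalog or a count matrix",
            call. = FALSE)
}

# 0-based vectors for the compiled state
hierarchy_vectors <- function(hierarchy, sample_ids) {
  stopifnot(inherits(hierarchy, "hdp_hierarchy"))
  parent <- ifelse(is.na(hierarchy$parent), -1L,
                   as.integer(hierarchy$parent) - 1L)
  smp <- match(hierarchy$sample, sample_ids) - 1L
  smp[is.na(smp)] <- -1L
  leaves <- hierarchy$sample[hierarchy$kind == "leaf"]
  if (!setequal(leaves, sample_ids) || length(leaves) != length(sample_ids))
    stop("hierarchy leaves do not match catalog samples", call. = FALSE)
  list(parent = parent, node_sample = as.integer(smp),
       cp_group = as.integer(hierarchy$cp_group) - 1L)
}

new_crf_state <- function(counts, hv, config, seed) {
  crf_init(counts, hv$parent, hv$node_sample, hv$cp_group,
           config$prior_shape, config$prior_beta, config$init_dishes,
           config$alpha_init, isTRUE(config$resample_alpha),
           as.double(seed))
}

#' Run one Gibbs-sampling chain
#'
#' Initializes the Chinese-restaurant-franchise state by round-robin
#' assignment of mutations among `init_dishes` clusters, runs `burnin`
#' sweeps, then records one Gibbs sample (the per-cluster class counts and
#' per-sample counts) every `spacing` sweeps until `n_samples` are collected.
#' If `config$checkpoint_path` is set, the full serialized state is written
#' periodically; `resume = TRUE` restarts from such a file and reproduces
#' the uninterrupted run bit-for-bit.
#'
#' @param catalog A [mutation_catalog()] (or plain count matrix).
#' @param hierarchy An [hdp_hierarchy()] over the catalog's samples.
#' @param config An [hdp_config()].
#' @param chain_id Identifier stored in each sample; also offsets the seed:
#'   the chain runs with `config$seed + chain_id`.
#' @param resume If `TRUE` and the checkpoint file exists, continue from it.
#' @return List of `n_samples` Gibbs samples; each has `chain`, `index`,
#'   `class_counts` (classes x clusters) and `sample_counts` (samples x
#'   clusters).
#' @export
run_chain <- function(catalog, hierarchy, config, chain_id = 1L,
                      resume = FALSE) {
  counts <- sampler_counts(catalog)
  hv <- hierarchy_vectors(hierarchy, colnames(counts))
  ckpt <- if (!is.null(config$checkpoint_path))
    paste0(config$checkpoint_path, "_chain", chain_id) else NULL

  samples <- list()
  done <- 0L
  if (resume && !is.null(ckpt) && file.exists(ckpt)) {
    snap <- tryCatch(readRDS(ckpt), error = function(e)
      stop("corrupt checkpoint '", ckpt, "': ", conditionMessage(e),
           call. = FALSE))
    if (!identical(snap$format, "hdpsig-checkpoint-1"))
      stop("incompatible checkpoint version in '", ckpt, "'", call. = FALSE)
    state <- crf_restore(snap$state)
    samples <- snap$samples
    done <- as.integer(snap$sweeps_done)
  } else {
    state <- new_crf_state(counts, hv, config, config$seed + chain_id)
  }

  total <- config$burnin + config$spacing * config$n_samples
  record_at <- config$burnin + config$spacing * seq_len(config$n_samples)
  while (done < total) {
    nxt <- min(c(record_at[record_at > done], total,
                 if (!is.null(ckpt)) done + config$checkpoint_every))
    crf_run(state, nxt - done)
    done <- nxt
    if (done %in% record_at) {
      snap <- crf_snapshot(state)
      rownames(snap$class_counts) <- rownames(counts)
      rownames(snap$sample_counts) <- colnames(counts)
      samples[[length(samples) + 1L]] <-
        list(chain = chain_id, index = length(samples) + 1L,
             class_counts = snap$class_counts,
             sample_counts = snap$sample_counts,
             alpha = crf_alpha(state))
    }
    if (!is.null(ckpt))
      saveRDS(list(format = "hdpsig-checkpoint-1",
                   state = crf_serialize(state),
                   samples = samples, sweeps_done = done),
              ckpt)
  }
  samples
}

#' Run multiple independent chains
#'
#' Chain i runs with seed `config$seed + i`, so results are identical
#' whether chains execute serially or concurrently (`config$cores > 1`).
#'
#' @inheritParams run_chain
#' @return An object of class `posterior_archive`: list with `samples`
#'   (all Gibbs samples across chains), `n_chains`, `samples_per_chain`,
#'   `spacing`, `burnin`, `seeds` and `total` (catalog mutation total).
#' @export
run_multi_chain <- function(catalog, hierarchy, config, resume = FALSE) {
  counts <- sampler_counts(catalog)
  runner <- function(i) run_chain(catalog, hierarchy, config,
                                  chain_id = i, resume = resume)
  chains <- if (config$cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(config$n_chains), runner,
                       mc.cores = config$cores)
  } else {
    lapply(seq_len(config$n_chains), runner)
  }
  err <- vapply(chains, inherits, logical(1), "try-error")
  if (any(err)) stop("chain failure: ", chains[[which(err)[1]]], call. = FALSE)
  structure(list(samples = do.call(c, chains),
                 n_chains = config$n_chains,
                 samples_per_chain = config$n_samples,
                 spacing = config$spacing, burnin = config$burnin,
                 seeds = config$seed + seq_len(config$n_chains),
                 total = sum(counts)),
            class = "posterior_archive")
}

#' @export
print.posterior_archive <- function(x, ...) {
  cat("Posterior archive:", length(x$samples), "Gibbs samples (",
      x$n_chains, "chains x", x$samples_per_chain, ", spacing",
      x$spacing, ", burn-in", x$burnin, ")\n")
  invisible(x)
}
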