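# Independent oracles and fixture builders shared across tests.

# all set partitions of 1..n (list of lists of index vectors)
setparts <- function(n) {
  if (n == 1) return(list(list(1L)))
  prev <- setparts(n - 1L)
  out <- list()
  for (p in prev) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

canon_partition <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

# log CRP probability of a partition with the given block sizes
crp_lp <- function(alpha, sizes) {
  n <- sum(sizes)
  length(sizes) * log(alpha) + sum(lgamma(sizes)) -
    sum(log(alpha + 0:(n - 1)))
}

# log Dirichlet(1)-multinomial marginal of class counts over C classes
dm_lp <- function(counts, C) {
  lgamma(C) + sum(lgamma(counts + 1)) - lgamma(sum(counts) + C)
}

# Exact probabilities of the partition of items into dishes for a two-layer
# franchise (root + one leaf) with fixed concentrations, by exhaustive
# enumeration of (items -> leaf tables -> root tables).
partition_oracle <- function(classes, C, alpha_root, alpha_leaf) {
  n <- length(classes)
  acc <- list()
  for (tp in setparts(n)) {
    lp1 <- crp_lp(alpha_leaf, lengths(tp))
    for (rp in setparts(length(tp))) {
      lp0 <- crp_lp(alpha_root, lengths(rp))
      lpd <- 0
      dishes <- list()
      for (rb in rp) {
        items <- unlist(tp[rb])
        lpd <- lpd + dm_lp(tabulate(classes[items], nbins = C), C)
        dishes[[length(dishes) + 1L]] <- items
      }
      key <- canon_partition(dishes)
      acc[[key]] <- (acc[[key]] %||% 0) + exp(lp1 + lp0 + lpd)
    }
  }
  v <- unlist(acc)
  v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_catalog <- function(n_samples = 3, lambda = 4, scheme = "SBS96",
                           seed = 1) {
  sc <- catalog_scheme(scheme)
  set.seed(seed)
  m <- matrix(rpois(sc$n_classes * n_samples, lambda), sc$n_classes,
              dimnames = list(sc$class_labels,
                              paste0("smp", seq_len(n_samples))))
  mutation_catalog(m, sc)
}

# brute-force minimum assignment cost over all permutations (square matrix)
brute_min_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

tiny_config <- function(burnin = 40, n_chains = 2, n_samples = 5,
                        spacing = 4, seed = 1, ...) {
  hdp_config(burnin = burnin, n_chains = n_chains, n_samples = n_samples,
             spacing = spacing, seed = seed, ...)
}
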