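#' Pool mutation clusters across Gibbs samples
#'
#' Collects every non-empty mutation cluster from every Gibbs sample in the
#' archive into one pool, keeping provenance (chain, sample index) per
#' cluster.
#'
#' @param archive A `posterior_archive` from [run_multi_chain()].
#' @return Object of class `cluster_pool`: list with `class_counts`
#'   (classes x clusters), `sample_counts` (samples x clusters), `profiles`
#'   (column-normalized class counts), `chain` and `sample_index` per
#'   column, and `n_gibbs` (total Gibbs samples in the archive).
#' @export
pool_clusters <- function(archive) {
  stopifnot(inherits(archive, "posterior_archive"))
  if (length(archive$samples) == 0)
    stop("empty posterior archive", call. = FALSE)
  ccs <- list(); scs <- list(); chain <- integer(0); sidx <- integer(0)
  gid <- 0L
  for (g in archive$samples) {
    gid <- gid + 1L
    keep <- colSums(g$class_counts) > 0
    if (!any(keep)) next
    ccs[[length(ccs) + 1L]] <- g$class_counts[, keep, drop = FALSE]
    scs[[length(scs) + 1L]] <- g$sample_counts[, keep, drop = FALSE]
    chain <- c(chain, rep(g$chain, sum(keep)))
    sidx <- c(sidx, rep(gid, sum(keep)))
  }
  cc <- do.call(cbind, ccs)
  sc <- do.call(cbind, scs)
  structure(list(class_counts = cc, sample_counts = sc,
                 profiles = sweep_cols(cc),
                 chain = chain, sample_index = sidx,
                 n_gibbs = length(archive$samples)),
            class = "cluster_pool")
}

sweep_cols <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  m %*% diag(1 / cs, ncol(m))
}

cosine_matrix <- function(p) {
  nrm <- sqrt(colSums(p^2))
  nrm[nrm == 0] <- 1
  q <- p %*% diag(1 / nrm, ncol(p))
  s <- crossprod(q)
  s[s > 1] <- 1; s[s < 0] <- 0
  s
}

#' Group pooled clusters by divisive hierarchical clustering
#'
#' Groups mutation clusters with similar signature profiles by divisive
#' (DIANA-style) hierarchical clustering on cosine distance (1 - cosine
#' similarity): starting from a single cluster, the algorithm repeatedly
#' splits a branch by seeding a splinter with the member of maximal average
#' dissimilarity (ties broken by lowest column index) and moving members
#' whose average dissimilarity to the splinter is smaller than to the
#' remainder. Recursion on a branch stops when its members' mean cosine
#' similarity to the branch's summed-count profile reaches
#' `cohesion_threshold`; the leaves of the stopped recursion are the groups.
#'
#' @param pool A [pool_clusters()] result.
#' @param cohesion_threshold Stop threshold in (0, 1]; default 0.90.
#' @return List of groups, each of class `signature_group`: `members`
#'   (column indices), `class_counts` (summed), `sample_counts` (summed),
#'   `profile`, `support` (fraction of distinct Gibbs samples contributing),
#'   `single_class` flag.
#' @export
group_clusters <- function(pool, cohesion_threshold = 0.9) {
  stopifnot(inherits(pool, "cluster_pool"))
  if (!is.numeric(cohesion_threshold) || cohesion_threshold <= 0 ||
      cohesion_threshold > 1)
    stop("cohesion_threshold must be in (0, 1]", call. = FALSE)
  p <- pool$profiles
  m <- ncol(p)
  sim <- cosine_matrix(p)
  d <- 1 - sim

  cohesive <- function(idx) {
    q <- rowSums(pool$class_counts[, idx, drop = FALSE])
    qn <- sqrt(sum(q^2))
    if (qn == 0) return(TRUE)
    cs <- as.vector(crossprod(p[, idx, drop = FALSE], q / qn)) /
      sqrt(colSums(p[, idx, drop = FALSE]^2))
    mean(cs) >= cohesion_threshold
  }

  groups <- list()
  recurse <- function(idx) {
    if (length(idx) <= 1 || cohesive(idx)) {
      groups[[length(groups) + 1L]] <<- idx
      return(invisible(NULL))
    }
    halves <- diana_split(d, idx)
    recurse(halves$a)
    recurse(halves$b)
  }
  recurse(seq_len(m))

  lapply(groups, function(idx) make_group(pool, sort(idx)))
}

# One divisive step on the dissimilarity submatrix for `idx` (DIANA rule).
diana_split <- function(d, idx) {
  n <- length(idx)
  sub <- d[idx, idx, drop = FALSE]
  avg_all <- rowSums(sub) / (n - 1)
  seed <- which(avg_all == max(avg_all))[1] # ties: lowest index
  splinter <- seed
  rest <- setdiff(seq_len(n), seed)
  repeat {
    if (length(rest) <= 1) break
    gain <- vapply(rest, function(i) {
      a_rest <- sum(sub[i, setdiff(rest, i)]) / (length(rest) - 1)
      a_spl <- mean(sub[i, splinter])
      a_rest - a_spl
    }, numeric(1))
    if (max(gain) <= 0) break
    mv <- rest[which(gain == max(gain))[1]]
    splinter <- c(splinter, mv)
    rest <- setdiff(rest, mv)
  }
  list(a = idx[sort(splinter)], b = idx[sort(rest)])
}

make_group <- function(pool, idx) {
  cc <- rowSums(pool$class_counts[, idx, drop = FALSE])
  sc <- rowSums(pool$sample_counts[, idx, drop = FALSE])
  prof <- if (sum(cc) > 0) cc / sum(cc) else cc
  structure(list(
    members = idx,
    member_sample_index = pool$sample_index[idx],
    class_counts = cc, sample_counts = sc, profile = prof,
    support = group_support(idx, pool),
    single_class = max(prof) > 0.95),
    class = "signature_group")
}

#' Posterior support of a group of mutation clusters
#'
#' The fraction of distinct Gibbs samples (across all chains) contributing
#' at least one member cluster to the group. A Gibbs sample contributing
#' several member clusters counts once.
#'
#' @param members Column indices into the pool.
#' @param pool A [pool_clusters()] result.
#' @return Fraction in (0, 1].
#' @export
group_support <- function(members, pool) {
  length(unique(pool$sample_index[members])) / pool$n_gibbs
}

#' Extract signatures from the posterior archive
#'
#' Groups the pooled mutation clusters ([group_clusters()]), retains groups
#' whose posterior support reaches `support_cutoff` (default 0.9), and turns
#' each retained group into a signature: the class-wise sum of member
#' cluster counts divided by the group total. Exposures are posterior means:
#' the summed per-sample counts of the group divided by the total number of
#' Gibbs samples (a Gibbs sample without a member contributes zero);
#' their posterior spread is reported as a standard deviation across Gibbs
#' samples. Groups whose profile puts > 0.95 of mass on a single class are
#' flagged `single_class` (a known false-positive mode) but not removed.
#'
#' @param pool A [pool_clusters()] result.
#' @param archive The `posterior_archive` the pool came from.
#' @param support_cutoff Minimum support in (0, 1].
#' @param cohesion_threshold Passed to [group_clusters()].
#' @return Object of class `signature_extraction`: `signatures` (a
#'   [signature_set()] when a scheme is attached, else a profile matrix),
#'   `exposures` (signatures x samples posterior-mean counts),
#'   `exposure_sd`, `support` (per retained signature), `discarded`
#'   (data frame of discarded groups and supports), `groups` (all groups),
#'   `single_class` flags, `n_gibbs`, `status`.
#' @export
extract_signatures <- function(pool, archive, support_cutoff = 0.9,
                               cohesion_threshold = 0.9) {
  if (!is.numeric(support_cutoff) || support_cutoff <= 0 || support_cutoff > 1)
    stop("support_cutoff must be in (0, 1]", call. = FALSE)
  groups <- group_clusters(pool, cohesion_threshold)
  supports <- vapply(groups, `[[`, numeric(1), "support")
  keep <- supports >= support_cutoff
  ord <- order(vapply(groups, function(g) sum(g$class_counts), numeric(1)),
               decreasing = TRUE)
  kept <- ord[keep[ord]]

  status <- if (!any(keep)) "no group reached the support cutoff" else "ok"
  if (!any(keep))
    warning("no signature group reached support cutoff ", support_cutoff,
            call. = FALSE)

  K <- length(kept)
  C <- nrow(pool$class_counts)
  J <- nrow(pool$sample_counts)
  profs <- matrix(0, C, K,
                  dimnames = list(rownames(pool$class_counts),
                                  if (K) paste0("hdp.", seq_len(K))))
  expo <- matrix(0, K, J,
                 dimnames = list(colnames(profs),
                                 rownames(pool$sample_counts)))
  expo_sd <- expo
  for (k in seq_len(K)) {
    g <- groups[[kept[k]]]
    profs[, k] <- g$profile
    expo[k, ] <- g$sample_counts / pool$n_gibbs
    # per-Gibbs-sample totals per catalog sample (absent Gibbs samples = 0)
    per <- matrix(0, pool$n_gibbs, J)
    for (i in g$members) {
      gi <- pool$sample_index[i]
      per[gi, ] <- per[gi, ] + pool$sample_counts[, i]
    }
    expo_sd[k, ] <- apply(per, 2, stats::sd)
  }

  structure(list(
    signatures = profs,
    exposures = expo,
    exposure_sd = expo_sd,
    support = supports[kept],
    single_class = vapply(groups[kept], `[[`, logical(1), "single_class"),
    discarded = data.frame(
      group = which(!keep),
      support = supports[!keep],
      total = vapply(groups[!keep], function(g) sum(g$class_counts),
                     numeric(1))),
    groups = groups,
    n_gibbs = pool$n_gibbs,
    support_cutoff = support_cutoff,
    cohesion_threshold = cohesion_threshold,
    status = status),
    class = "signature_extraction")
}

#' @export
print.signature_extraction <- function(x, ...) {
  cat("Signature extraction:", ncol(x$signatures), "signatures retained at",
      "support >=", x$support_cutoff, "(", length(x$groups), "groups )\n")
  if (any(x$single_class))
    cat("Note:", sum(x$single_class), "retained signature(s) are essentially",
        "a single mutation class\n")
  invisible(x)
}

#' Per-signature diagnostics
#'
#' For each retained signature, tabulates the attributed mutation count and
#' proportion per sample (proportion 0 for zero-mutation samples), flags the
#' five samples with the highest attributed proportions, and counts the
#' member clusters contributed by every Gibbs sample (the support trace).
#'
#' @param result A [extract_signatures()] result.
#' @param catalog The catalog the archive was sampled from.
#' @return List with `attribution` (one data frame per signature:
#'   `sample`, `count`, `proportion`, `top5`) and `support_trace`
#'   (signatures x Gibbs-samples matrix of contributing-cluster counts).
#' @export
signature_diagnostics <- function(result, catalog) {
  stopifnot(inherits(result, "signature_extraction"),
            inherits(catalog, "mutation_catalog"))
  tot <- colSums(catalog$counts)
  if (!identical(sort(names(tot)), sort(colnames(result$exposures))))
    stop("catalog samples do not match extraction samples", call. = FALSE)
  tot <- tot[colnames(result$exposures)]
  K <- nrow(result$exposures)
  attribution <- lapply(seq_len(K), function(k) {
    cnt <- result$exposures[k, ]
    prop <- ifelse(tot > 0, cnt / tot, 0)
    ord <- order(prop, decreasing = TRUE)
    df <- data.frame(sample = names(cnt), count = as.numeric(cnt),
                     proportion = as.numeric(prop),
                     top5 = FALSE, stringsAsFactors = FALSE)
    df$top5[ord[seq_len(min(5, length(ord)))]] <- TRUE
    df
  })
  names(attribution) <- rownames(result$exposures)

  # which groups were retained, in signature order
  supports <- vapply(result$groups, `[[`, numeric(1), "support")
  ord <- order(vapply(result$groups, function(g) sum(g$class_counts),
                      numeric(1)), decreasing = TRUE)
  kept <- ord[supports[ord] >= result$support_cutoff]
  trace <- matrix(0L, K, result$n_gibbs,
                  dimnames = list(rownames(result$exposures), NULL))
  for (k in seq_len(K)) {
    g <- result$groups[[kept[k]]]
    tb <- table(g$member_sample_index)
    if (length(tb)) trace[k, as.integer(names(tb))] <- as.integer(tb)
  }
  list(attribution = attribution, support_trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
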