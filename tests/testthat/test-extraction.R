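# build a synthetic archive directly from cluster matrices
fake_archive <- function(samples_spec, n_classes = 6, n_cat_samples = 2) {
  samples <- lapply(seq_along(samples_spec), function(i) {
    cc <- samples_spec[[i]]
    sc <- matrix(0L, n_cat_samples, ncol(cc))
    # put all counts on catalog sample 1 for simplicity unless told otherwise
    sc[1, ] <- colSums(cc)
    list(chain = 1L, index = i, class_counts = cc, sample_counts = sc,
         alpha = c(1, 1))
  })
  structure(list(samples = samples, n_chains = 1L,
                 samples_per_chain = length(samples), spacing = 1L,
                 burnin = 0L, seeds = 1L,
                 total = sum(vapply(samples, function(s) sum(s$class_counts),
                                    numeric(1)))),
            class = "posterior_archive")
}

mat <- function(...) {
  cols <- list(...)
  do.call(cbind, lapply(cols, as.integer))
}

test_that("pooling keeps non-empty clusters with provenance and conserves counts", {
  arc <- fake_archive(list(
    mat(c(5, 0, 0, 0, 0, 0), c(0, 3, 0, 0, 0, 0), c(0, 0, 2, 0, 0, 0)),
    mat(c(4, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0), c(0, 0, 3, 0, 0, 0))))
  pool <- pool_clusters(arc)
  expect_equal(ncol(pool$class_counts), 5)  # the all-zero cluster is dropped
  expect_equal(sum(pool$class_counts), arc$total)
  expect_equal(pool$sample_index, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(colSums(pool$profiles), rep(1, 5))
  expect_error(pool_clusters(structure(list(samples = list()),
                                       class = "posterior_archive")),
               "empty")
})

test_that("identical profiles collapse to one group; distinct blocks separate", {
  same <- mat(c(3, 1, 0, 0, 0, 0), c(6, 2, 0, 0, 0, 0), c(9, 3, 0, 0, 0, 0))
  arc <- fake_archive(list(same))
  pool <- pool_clusters(arc)
  g <- group_clusters(pool, 0.9)
  expect_length(g, 1)
  expect_equal(g[[1]]$support, 1)

  # two well-separated blocks (between-block cosine < 0.3)
  b1 <- mat(c(10, 4, 0, 0, 0, 0), c(12, 5, 1, 0, 0, 0), c(11, 3, 0, 0, 0, 0))
  b2 <- mat(c(0, 0, 0, 8, 3, 1), c(0, 0, 0, 9, 4, 0), c(0, 0, 1, 10, 3, 0))
  arc2 <- fake_archive(list(cbind(b1, b2)))
  pool2 <- pool_clusters(arc2)
  g2 <- group_clusters(pool2, 0.9)
  expect_length(g2, 2)
  members <- lapply(g2, `[[`, "members")
  expect_true(setequal(members, list(1:3, 4:6)))
  expect_error(group_clusters(pool2, 1.5), "cohesion_threshold")
})

test_that("the divisive split reproduces a hand-executed splinter step", {
  # 4 points: {1,2} tight, {3,4} tight, far apart; 4 is the most isolated
  d <- matrix(c(0.00, 0.05, 0.80, 0.90,
                0.05, 0.00, 0.85, 0.95,
                0.80, 0.85, 0.00, 0.10,
                0.90, 0.95, 0.10, 0.00), 4, 4, byrow = TRUE)
  # hand trace: avg dissimilarities (0.583, 0.617, 0.583, 0.65) -> seed = 4;
  # then 3 moves to the splinter (closer to 4 than to {1,2}); 1,2 stay
  halves <- hdpsig:::diana_split(d, 1:4)
  expect_equal(sort(halves$a), 3:4)
  expect_equal(sort(halves$b), 1:2)
})

test_that("the divisive split agrees with an independent DIANA implementation", {
  skip_if_not_installed("cluster")
  set.seed(31)
  p <- cbind(matrix(rexp(6 * 4), 6), matrix(rexp(6 * 4) + 3, 6))
  d <- 1 - hdpsig:::cosine_matrix(hdpsig:::sweep_cols(p))
  halves <- hdpsig:::diana_split(d, seq_len(ncol(p)))
  di <- cluster::diana(stats::as.dist(d), diss = TRUE)
  top <- stats::cutree(stats::as.hclust(di), k = 2)
  expect_true(setequal(list(which(top == 1), which(top == 2)),
                       list(halves$a, halves$b)))
})

test_that("group support deduplicates multiple clusters per Gibbs sample", {
  cc <- mat(c(2, 0, 0, 0, 0, 0))
  arc <- fake_archive(list(cbind(cc, cc), cc, cc, cc))
  pool <- pool_clusters(arc)
  expect_equal(pool$n_gibbs, 4)
  # members from Gibbs samples {1, 1, 2}: counts once per distinct sample
  expect_equal(group_support(c(1, 2, 3), pool), 0.5)
  expect_equal(group_support(1:5, pool), 1)
  expect_equal(group_support(3, pool), 0.25)
})

test_that("extraction applies the support cutoff and normalizes profiles", {
  strong <- mat(c(8, 2, 0, 0, 0, 0))
  weak <- mat(c(0, 0, 0, 5, 5, 0))
  # strong appears in 20 of 20 samples, weak in 10 -> supports 1.0 and 0.5
  spec <- lapply(1:20, function(i) if (i <= 10) cbind(strong, weak) else strong)
  arc <- fake_archive(spec)
  pool <- pool_clusters(arc)
  res <- extract_signatures(pool, arc, support_cutoff = 0.9)
  expect_equal(ncol(res$signatures), 1)
  expect_equal(nrow(res$discarded), 1)
  expect_equal(res$discarded$support, 0.5)
  expect_equal(sum(res$signatures[, 1]), 1)
  # exposures are means over ALL Gibbs samples
  expect_equal(unname(res$exposures[1, 1]), 10)  # 8+2 mutations, every sample
  # profile of summed counts: clusters (2,0) and (0,2) -> (0.5, 0.5)
  arc2 <- fake_archive(list(mat(c(2, 0, 0, 0, 0, 0)),
                            mat(c(0, 2, 0, 0, 0, 0))))
  pool2 <- pool_clusters(arc2)
  res2 <- extract_signatures(pool2, arc2, support_cutoff = 0.1,
                             cohesion_threshold = 0.1)
  expect_equal(unname(res2$signatures[1:2, 1]), c(0.5, 0.5))
})

test_that("all groups together conserve the pooled counts", {
  arc <- fake_archive(lapply(1:6, function(i)
    mat(rpois(6, 3), rpois(6, 2))))
  pool <- pool_clusters(arc)
  groups <- group_clusters(pool, 0.9)
  tot <- Reduce(`+`, lapply(groups, `[[`, "class_counts"))
  expect_equal(unname(tot), unname(rowSums(pool$class_counts)))
})

test_that("raising the support cutoff never increases the signature count", {
  set.seed(12)
  arc <- fake_archive(lapply(1:10, function(i) {
    k <- sample(2:4, 1)
    do.call(cbind, lapply(seq_len(k), function(z) as.integer(rpois(6, 4))))
  }))
  pool <- pool_clusters(arc)
  cuts <- c(0.2, 0.5, 0.8, 1)
  ks <- vapply(cuts, function(ct)
    ncol(suppressWarnings(
      extract_signatures(pool, arc, support_cutoff = ct))$signatures),
    numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("grouping is invariant to column permutation of the pool", {
  set.seed(13)
  b1 <- mat(c(10, 4, 0, 0, 0, 0), c(12, 5, 1, 0, 0, 0))
  b2 <- mat(c(0, 0, 0, 8, 3, 1), c(0, 0, 1, 10, 3, 0))
  arc <- fake_archive(list(cbind(b1, b2)))
  pool <- pool_clusters(arc)
  perm <- c(3, 1, 4, 2)
  pool_p <- pool
  pool_p$class_counts <- pool$class_counts[, perm]
  pool_p$sample_counts <- pool$sample_counts[, perm]
  pool_p$profiles <- pool$profiles[, perm]
  pool_p$chain <- pool$chain[perm]
  pool_p$sample_index <- pool$sample_index[perm]
  g1 <- group_clusters(pool, 0.9)
  g2 <- group_clusters(pool_p, 0.9)
  prof1 <- lapply(g1, function(g) round(g$profile, 12))
  prof2 <- lapply(g2, function(g) round(g$profile, 12))
  expect_true(setequal(prof1, prof2))
})

test_that("diagnostics report proportions, top-5 flags and support traces", {
  sc <- catalog_scheme("SBS96")
  sigs <- example_signatures(2)
  pm <- example_prevalence_model(sigs, n_tumors = 8, mu = 200, size = 5)
  dat <- synthesize_dataset(pm, sigs, seed = 3)
  fit <- hdp_fit(dat$catalog, config = tiny_config(), seed = 3,
                 support_cutoff = 0.5, keep_archive = TRUE)
  dg <- signature_diagnostics(fit$extraction, dat$catalog)
  for (df in dg$attribution) {
    expect_true(all(df$proportion >= 0 & df$proportion <= 1))
    expect_equal(sum(df$top5), min(5, nrow(df)))
    ord <- order(df$proportion, decreasing = TRUE)
    expect_true(all(df$top5[ord[1:min(5, nrow(df))]]))
  }
  expect_equal(ncol(dg$support_trace), fit$n_gibbs)
  # zero-mutation sample gets proportion 0
  m <- dat$catalog$counts; m[, 1] <- 0L
  cat0 <- mutation_catalog(m, sc)
  dg0 <- signature_diagnostics(fit$extraction, cat0)
  expect_equal(dg0$attribution[[1]]$proportion[1], 0)
})
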