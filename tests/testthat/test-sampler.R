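test_that("hierarchy construction yields the right tree shapes", {
  h2 <- hdp_hierarchy(c("s1", "s2", "s3"))
  expect_equal(nrow(h2), 4)
  expect_equal(sum(h2$kind == "leaf"), 3)
  expect_equal(sum(h2$kind == "root"), 1)
  h3 <- hdp_hierarchy(c("a", "b", "c", "d"),
                      c(a = "g1", b = "g1", c = "g2", d = "g2"))
  expect_equal(nrow(h3), 7)
  expect_equal(sum(h3$kind == "group"), 2)
  expect_equal(max(h3$cp_group), 3)  # one alpha per level by default
  expect_error(hdp_hierarchy(c("a", "b"), c(a = "g1")), "does not cover")
  expect_error(hdp_hierarchy(character(0)), "non-empty")
})

test_that("dish predictive follows the Dirichlet-multinomial closed form", {
  expect_equal(dish_predictive(numeric(96))[1], 1 / 96)
  expect_equal(dish_predictive(c(3, 1, 0, 0), 1), 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    cnt <- rpois(96, 2)
    expect_equal(sum(dish_predictive(cnt)), 1)
  }
  expect_error(dish_predictive(c(-1, 2)), "non-negative")
})

test_that("seating distribution matches hand-evaluated masses", {
  # empty restaurant: all mass on the new table
  expect_equal(seating_probs(integer(0), list(), 1, alpha = 1,
                             parent_pred = 1 / 96), 1)
  # one table whose dish predictive equals 1/C, alpha 1, parent 1/C -> 50/50
  expect_equal(seating_probs(1, list(numeric(96)), 5, alpha = 1,
                             parent_pred = 1 / 96), c(0.5, 0.5))
  # always a distribution
  for (seed in 1:5) {
    set.seed(seed)
    nt <- sample(1:4, 1)
    dishes <- replicate(nt, rpois(96, 3), simplify = FALSE)
    p <- seating_probs(sample(1:5, nt, replace = TRUE), dishes,
                       sample(96, 1), alpha = runif(1, 0.1, 2),
                       parent_pred = 1 / 96)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("concentration update matches the grid-integrated posterior", {
  # one restaurant, n = 5 customers, t = 2 tables, Gamma(2, 4) prior
  shape <- 2; beta <- 4; n <- 5; t <- 2
  agrid <- seq(1e-4, 40, length.out = 1e5)
  lp <- dgamma(agrid, shape, rate = beta, log = TRUE) +
    t * log(agrid) + lgamma(agrid) - lgamma(agrid + n)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  exact_mean <- sum(w * agrid)
  exact_sd <- sqrt(sum(w * agrid^2) - exact_mean^2)

  set.seed(42)
  al <- 1; draws <- numeric(3e4)
  for (i in seq_along(draws)) {
    al <- sample_dp_concentration(al, n, t, shape, beta)
    draws[i] <- al
  }
  expect_lt(abs(mean(draws) - exact_mean), 4 * exact_sd / sqrt(3e4) * 5)
  expect_lt(abs(sd(draws) - exact_sd) / exact_sd, 0.05)
})

test_that("a single mutation occupies one dish and one table per level", {
  sc <- catalog_scheme("SBS96")
  m <- matrix(0L, 96, 1, dimnames = list(sc$class_labels, "s1"))
  m[17, 1] <- 1L
  h <- hdp_hierarchy("s1")
  smp <- run_chain(mutation_catalog(m, sc), h,
                   hdp_config(burnin = 10, n_chains = 1, n_samples = 3,
                              spacing = 2, seed = 1))
  for (g in smp) {
    expect_equal(ncol(g$class_counts), 1)
    expect_equal(sum(g$class_counts), 1)
    expect_equal(unname(g$class_counts[17, 1]), 1L)
  }
})

test_that("Gibbs samples conserve catalog totals and state stays consistent", {
  cat1 <- random_catalog(n_samples = 4, lambda = 4, seed = 7)
  h <- hdp_hierarchy(colnames(cat1$counts))
  smp <- run_chain(cat1, h, tiny_config())
  expect_length(smp, 5)
  for (g in smp) {
    expect_equal(sum(g$class_counts), sum(cat1$counts))
    expect_equal(unname(rowSums(g$sample_counts)),
                 unname(colSums(cat1$counts)))
    expect_identical(colSums(g$class_counts),
                     colSums(g$sample_counts))
  }
  # internal bookkeeping invariants, checked from a fresh state
  hv <- hdpsig:::hierarchy_vectors(h, colnames(cat1$counts))
  st <- hdpsig:::new_crf_state(cat1$counts, hv, tiny_config(), 123)
  hdpsig:::crf_run(st, 25)
  expect_true(hdpsig:::crf_check(st))
})

test_that("three-layer hierarchies sample and conserve like two-layer ones", {
  cat1 <- random_catalog(n_samples = 4, lambda = 4, seed = 8)
  groups <- setNames(c("t1", "t1", "t2", "t2"), colnames(cat1$counts))
  h <- hdp_hierarchy(colnames(cat1$counts), groups)
  smp <- run_chain(cat1, h, tiny_config())
  for (g in smp)
    expect_equal(sum(g$class_counts), sum(cat1$counts))
})

test_that("chains are reproducible, seed-sensitive and checkpoint-resumable", {
  cat1 <- random_catalog(n_samples = 3, lambda = 4, seed = 3)
  h <- hdp_hierarchy(colnames(cat1$counts))
  a <- run_chain(cat1, h, tiny_config())
  b <- run_chain(cat1, h, tiny_config())
  expect_identical(a, b)
  c2 <- run_chain(cat1, h, tiny_config(seed = 2))
  expect_false(identical(a, c2))

  td <- withr::local_tempdir()
  cfg <- tiny_config(checkpoint_path = file.path(td, "ck"),
                     checkpoint_every = 13)
  full <- run_chain(cat1, h, cfg)
  cfg_part <- cfg; cfg_part$n_samples <- 2L
  unlink(file.path(td, "ck_chain1"))
  run_chain(cat1, h, cfg_part)
  resumed <- run_chain(cat1, h, cfg, resume = TRUE)
  expect_identical(full, resumed)

  writeLines("garbage", file.path(td, "ck_chain1"))
  expect_error(run_chain(cat1, h, cfg, resume = TRUE), "corrupt checkpoint")
})

test_that("multi-chain archives aggregate and are execution-order invariant", {
  cat1 <- random_catalog(n_samples = 3, lambda = 3, seed = 4)
  h <- hdp_hierarchy(colnames(cat1$counts))
  cfg_serial <- tiny_config(n_chains = 3)
  cfg_par <- tiny_config(n_chains = 3, cores = 2)
  a <- run_multi_chain(cat1, h, cfg_serial)
  expect_length(a$samples, 15)
  b <- run_multi_chain(cat1, h, cfg_par)
  expect_identical(a$samples, b$samples)
  expect_error(hdp_config(n_chains = 0), "n_chains")
  expect_error(hdp_config(n_samples = 0), "n_samples")
})

test_that("sampling records are spaced after burn-in as configured", {
  cat1 <- random_catalog(n_samples = 2, lambda = 2, seed = 5)
  h <- hdp_hierarchy(colnames(cat1$counts))
  cfg <- hdp_config(burnin = 100, n_chains = 1, n_samples = 5, spacing = 10,
                    seed = 1)
  smp <- run_chain(cat1, h, cfg)
  expect_length(smp, 5)
  expect_equal(vapply(smp, `[[`, integer(1), "index"), 1:5)
})
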