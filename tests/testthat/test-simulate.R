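test_that("presence probability is the proportion of exposed tumors", {
  sigs <- example_signatures(1)
  expo <- matrix(c(0, 0, 5, 10), 1, dimnames = list("TruthSig1", NULL))
  m <- suppressWarnings(fit_prevalence_model(expo, rep("TypeA", 4)))
  expect_equal(m$params$p, 0.5)
  # all-zero signature: p = 0, no NB fit
  expo0 <- matrix(0, 1, 4, dimnames = list("S0", NULL))
  m0 <- suppressWarnings(fit_prevalence_model(expo0, rep("TypeA", 4)))
  expect_equal(m0$params$p, 0)
  expect_true(is.na(m0$params$mu))
})

test_that("NB maximum likelihood recovers known burden parameters", {
  set.seed(21)
  x <- matrix(rnbinom(500, mu = 100, size = 2), 1,
              dimnames = list("S1", NULL))
  x[x == 0] <- 1  # keep every tumor exposed so the fit sees all draws
  m <- fit_prevalence_model(x, rep("T", 500))
  expect_lt(abs(m$params$mu - 100) / 100, 0.10)
  expect_lt(abs(m$params$size - 2) / 2, 0.30)
  # fewer than 3 positive tumors: Poisson-like sentinel
  few <- matrix(c(40, 60, 0, 0, 0), 1, dimnames = list("S1", NULL))
  mf <- fit_prevalence_model(few, rep("T", 5))
  expect_equal(mf$params$mu, 50)
  expect_gte(mf$params$size, 1e6)
})

test_that("the burden sampler has negative-binomial mean and variance", {
  set.seed(22)
  mu <- 80; size <- 4
  x <- hdpsig:::rnb(1e5, mu, size)
  expect_lt(abs(mean(x) - mu) / mu, 0.05)
  expect_lt(abs(var(x) - (mu + mu^2 / size)) / (mu + mu^2 / size), 0.05)
  expect_identical(hdpsig:::rnb(5, 0, 10), rep(0, 5))
})

test_that("noise-free spectra are exact rounded mixtures of profiles", {
  sc <- catalog_scheme("SBS96")
  prof <- matrix(0, 96, 1, dimnames = list(sc$class_labels, "Flat4"))
  prof[1:4, 1] <- 0.25
  sigs <- signature_set(prof, sc)
  rows <- data.frame(type = "T", signature = "Flat4", p = 1,
                     mu = 1000, size = 1e9)  # burden tightly at 1000
  set.seed(23)
  sp <- synthesize_spectrum(rows, sigs, d = Inf)
  m_s <- sp$draw$m_s[["Flat4"]]
  expect_equal(unname(sp$spectrum[1:4]),
               as.integer(round(m_s * rep(0.25, 4))))
  # mixtures of several profiles, p = 1, d = Inf
  sigs3 <- example_signatures(3)
  rows3 <- data.frame(type = "T", signature = colnames(sigs3$profiles),
                      p = 1, mu = 500, size = 5)
  sp3 <- synthesize_spectrum(rows3, sigs3, d = Inf)
  manual <- round(rowSums(sigs3$profiles %*% diag(sp3$draw$m_s)))
  expect_equal(unname(sp3$spectrum), as.integer(manual))
})

test_that("spectrum totals match the prevalence-model expectation", {
  sigs <- example_signatures(2)
  rows <- data.frame(type = "T", signature = colnames(sigs$profiles),
                     p = c(0.7, 0.4), mu = c(300, 150), size = c(3, 5))
  expected_total <- sum(rows$p * rows$mu)
  set.seed(24)
  n <- 4000
  tots <- vapply(seq_len(n), function(i)
    sum(synthesize_spectrum(rows, sigs, d = 30)$spectrum), numeric(1))
  # MC standard error of the mean total
  se <- sd(tots) / sqrt(n)
  expect_lt(abs(mean(tots) - expected_total), 3 * se)
})

test_that("large single-signature spectra converge to the profile", {
  # resampling noise sets a cosine floor near 1 - 1/(2d) that does not
  # vanish with burden, so convergence to the profile is tested at reduced
  # noise; at the realistic d = 30 the spectrum stays above that floor
  sigs <- example_signatures(1)
  rows <- data.frame(type = "T", signature = "TruthSig1", p = 1,
                     mu = 2e5, size = 1e6)
  set.seed(25)
  sp_low_noise <- synthesize_spectrum(rows, sigs, d = 300)
  expect_gt(cosine_sim(sp_low_noise$spectrum, sigs$profiles[, 1]), 0.99)
  sp <- synthesize_spectrum(rows, sigs, d = 30)
  expect_gt(cosine_sim(sp$spectrum, sigs$profiles[, 1]), 0.96)
})

test_that("datasets are seed-reproducible with typed samples and ground truth", {
  sigs <- example_signatures(2)
  params <- data.frame(type = rep(c("Lung", "Skin"), each = 2),
                       signature = rep(colnames(sigs$profiles), 2),
                       p = c(1, 0.5, 0.8, 1),
                       mu = c(200, 100, 150, 300), size = 3)
  pm <- prevalence_model(params, c(Lung = 5L, Skin = 5L), d = 30)
  d1 <- synthesize_dataset(pm, sigs, seed = 11)
  d2 <- synthesize_dataset(pm, sigs, seed = 11)
  expect_identical(d1$catalog$counts, d2$catalog$counts)
  expect_identical(d1$truth$exposures, d2$truth$exposures)
  expect_equal(ncol(d1$catalog$counts), 10)
  expect_equal(unname(d1$catalog$sample_groups),
               rep(c("Lung", "Skin"), each = 5))
  expect_true(all(startsWith(colnames(d1$catalog$counts)[1:5], "Lung::")))
  expect_false(identical(d1$catalog$counts,
                         synthesize_dataset(pm, sigs, seed = 12)$catalog$counts))
  pm_bad <- pm; pm_bad$n_tumors["Lung"] <- 0L
  expect_error(synthesize_dataset(pm_bad, sigs, seed = 1), "positive")
})

test_that("fitting a synthesized cohort recovers the generator parameters", {
  sigs <- example_signatures(2)
  params <- data.frame(type = "T", signature = colnames(sigs$profiles),
                       p = c(0.8, 0.6), mu = c(400, 250), size = c(4, 4))
  pm <- prevalence_model(params, c(T = 800L), d = 30)
  dat <- synthesize_dataset(pm, sigs, seed = 31)
  fit <- fit_prevalence_model(dat$truth$exposures, dat$truth$tumor_type)
  for (i in 1:2) {
    row <- fit$params[fit$params$signature == params$signature[i], ]
    p_hat <- row$p
    se <- sqrt(params$p[i] * (1 - params$p[i]) / 800)
    expect_lt(abs(p_hat - params$p[i]), 4 * se)
    expect_lt(abs(row$mu - params$mu[i]) / params$mu[i], 0.10)
  }
})

test_that("prevalence models round trip through their file format", {
  sigs <- example_signatures(3)
  pm <- example_prevalence_model(sigs, n_tumors = 7, p = c(1, 0.5, 0.25),
                                 mu = c(100, 200, 300), size = c(2, 3, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_prevalence_model(pm, f)
  back <- read_prevalence_model(f)
  expect_equal(back$params$p, pm$params$p)
  expect_equal(back$params$mu, pm$params$mu)
  expect_equal(back$d, pm$d)
  expect_equal(unname(unlist(back$n_tumors)), unname(unlist(pm$n_tumors)))
  pm_inf <- example_prevalence_model(sigs, d = Inf)
  write_prevalence_model(pm_inf, f)
  expect_true(is.infinite(read_prevalence_model(f)$d))
})
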