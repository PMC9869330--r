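#' Discover mutational signatures by HDP mixture modelling
#'
#' Fits a hierarchical Dirichlet process mixture model to a mutation catalog
#' and extracts mutational signatures from the posterior. The pipeline is:
#' optional proportional downsampling of hypermutated spectra; construction
#' of the two- or three-layer Dirichlet-process hierarchy over samples
#' (three-layer when the catalog carries sample groups); Gibbs sampling of
#' the Chinese-restaurant-franchise representation over multiple independent
#' chains; pooling of the posterior mutation clusters; divisive hierarchical
#' grouping by cosine distance; and retention of groups supported by at
#' least `support_cutoff` of the Gibbs samples.
#'
#' Scheme-dependent defaults follow the benchmarked settings: for SBS-96,
#' concentration-prior rate (beta) 20 and downsampling threshold 3000; for
#' ID-83, beta 50 and no downsampling.
#'
#' @param catalog A [mutation_catalog()].
#' @param downsample_threshold Positive integer, `NULL` for the scheme
#'   default (3000 for SBS96, off for ID83), or `NA`/`Inf` to disable.
#' @param support_cutoff Minimum fraction of Gibbs samples that must contain
#'   a signature group for it to be retained (default 0.9).
#' @param cohesion_threshold Mean-cosine stop rule of the divisive grouping.
#' @param config An [hdp_config()]; defaults to the desk-scale profile with
#'   the scheme's prior.
#' @param seed Overrides `config$seed` when given.
#' @param keep_archive Keep the full posterior archive in the result?
#' @param resume Passed to [run_chain()] for checkpoint restart.
#' @return Object of class `hdp_fit`. Use `coef()` for the signature
#'   profile matrix, `$exposures` (via `summary()`) for posterior-mean
#'   attributed counts, `fitted()` for the reconstructed catalog,
#'   `residuals()` for observed minus reconstructed, `plot()` for profile
#'   bar plots, and `simulate()` for parametric replicates.
#' @examples
#' \donttest{
#' sigs <- example_signatures(2)
#' mod <- example_prevalence_model(sigs, n_tumors = 12, mu = 300)
#' dat <- synthesize_dataset(mod, sigs, seed = 7)
#' fit <- hdp_fit(dat$catalog, config = hdp_config(n_chains = 2,
#'   burnin = 100, n_samples = 10, spacing = 5), seed = 7)
#' coef(fit)[1:5, ]
#' }
#' @export
hdp_fit <- function(catalog,
                    downsample_threshold = NULL,
                    support_cutoff = 0.9,
                    cohesion_threshold = 0.9,
                    config = hdp_config(scheme = catalog$scheme),
                    seed = NULL,
                    keep_archive = FALSE,
                    resume = FALSE) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  cl <- match.call()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(downsample_threshold))
    downsample_threshold <-
      if (catalog$scheme$name == "SBS96") 3000L else NA_integer_

  input <- catalog
  if (!is.na(downsample_threshold) && is.finite(downsample_threshold))
    input <- downsample_spectra(catalog, downsample_threshold)

  hierarchy <- hdp_hierarchy(colnames(input$counts), input$sample_groups)
  archive <- run_multi_chain(input, hierarchy, config, resume = resume)
  pool <- pool_clusters(archive)
  extraction <- extract_signatures(pool, archive,
                                   support_cutoff = support_cutoff,
                                   cohesion_threshold = cohesion_threshold)

  structure(list(
    call = cl,
    catalog = catalog,
    downsampled = if (!identical(input, catalog)) input else NULL,
    downsample_threshold = downsample_threshold,
    hierarchy = hierarchy,
    config = config,
    archive = if (keep_archive) archive else NULL,
    n_gibbs = length(archive$samples),
    extraction = extraction,
    signatures = extraction$signatures,
    exposures = extraction$exposures,
    support = extraction$support),
    class = "hdp_fit")
}

#' @export
print.hdp_fit <- function(x, ...) {
  cat("HDP mutational-signature fit (", x$catalog$scheme$name, ")\n", sep = "")
  cat("  samples:", ncol(x$catalog$counts),
      " mutations:", sum(x$catalog$counts), "\n")
  if (!is.null(x$downsampled))
    cat("  downsampled to threshold", x$downsample_threshold, "->",
        sum(x$downsampled$counts), "mutations\n")
  cat("  Gibbs samples:", x$n_gibbs, "(", x$config$n_chains, "chains )\n")
  cat("  signatures retained:", ncol(x$signatures),
      "at support >=", x$extraction$support_cutoff, "\n")
  invisible(x)
}

#' @export
summary.hdp_fit <- function(object, ...) {
  sig <- colnames(object$signatures)
  df <- data.frame(
    signature = sig %||% character(0),
    support = as.numeric(object$support),
    total_exposure = rowSums(object$exposures),
    max_class_mass = if (length(sig)) apply(object$signatures, 2, max)
                     else numeric(0),
    single_class = object$extraction$single_class,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(fit = object, table = df,
              discarded = object$extraction$discarded)
  class(out) <- "summary.hdp_fit"
  out
}

#' @export
print.summary.hdp_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRetained signatures:\n")
  print(x$table, digits = 4)
  if (nrow(x$discarded)) {
    cat("\nDiscarded groups (support below cutoff):\n")
    print(x$discarded, digits = 3)
  }
  invisible(x)
}

#' @export
coef.hdp_fit <- function(object, ...) object$signatures

#' @export
fitted.hdp_fit <- function(object, ...) {
  # expected reconstructed catalog on the scale the sampler saw
  object$signatures %*% object$exposures
}

#' @export
residuals.hdp_fit <- function(object, ...) {
  obs <- if (!is.null(object$downsampled)) object$downsampled$counts
         else object$catalog$counts
  obs - fitted(object)
}

#' @export
plot.hdp_fit <- function(x, which = seq_len(ncol(x$signatures)), ...) {
  if (ncol(x$signatures) == 0) {
    warning("no signatures to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(1.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in which) {
    graphics::barplot(x$signatures[, k], border = NA, names.arg = NA,
                      ylab = "probability",
                      main = sprintf("%s (support %.2f)",
                                     colnames(x$signatures)[k],
                                     x$support[k]), ...)
  }
  invisible(x)
}

#' @export
simulate.hdp_fit <- function(object, nsim = 1, seed = NULL, d = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  if (is.null(d)) d <- if (object$catalog$scheme$name == "ID83") 10 else 30
  K <- ncol(object$signatures)
  if (K == 0) stop("cannot simulate from a fit with no signatures",
                   call. = FALSE)
  J <- ncol(object$exposures)
  lapply(seq_len(nsim), function(r) {
    counts <- matrix(0L, nrow(object$signatures), J,
                     dimnames = list(rownames(object$signatures),
                                     colnames(object$exposures)))
    for (j in seq_len(J)) {
      tot <- numeric(nrow(counts))
      for (k in seq_len(K)) {
        mst <- object$exposures[k, j] * object$signatures[, k]
        tot <- tot + if (is.infinite(d)) mst else rnb(length(mst), mst, d)
      }
      counts[, j] <- as.integer(round(tot))
    }
    mutation_catalog(counts, object$catalog$scheme,
                     object$catalog$sample_groups)
  })
}

#' Benchmark signature discovery on synthetic data
#'
#' For each seed: synthesize a dataset from the prevalence model, run
#' [hdp_fit()], match the discovered signatures to the ground truth and
#' compute PPV, TPR, mean cosine similarity and the composite measure. The
#' summary rows report mean and SD across seeds.
#'
#' @param model A [prevalence_model()].
#' @param signatures Ground-truth [signature_set()].
#' @param seeds Integer vector of seeds (one synthetic dataset + fit each).
#' @param max_distance Match cutoff, see [match_signatures()].
#' @param ... Passed to [hdp_fit()] (e.g. `config`, `downsample_threshold`).
#' @return List with `per_seed` (one metrics row per seed) and `summary`
#'   (mean and SD rows).
#' @export
run_benchmark <- function(model, signatures, seeds, max_distance = 0.1, ...) {
  if (length(seeds) == 0) stop("empty seed list", call. = FALSE)
  rows <- lapply(seeds, function(s) {
    dat <- synthesize_dataset(model, signatures, seed = s)
    fit <- hdp_fit(dat$catalog, seed = s, ...)
    truth_present <- dat$truth$exposures[rowSums(dat$truth$exposures) > 0, ,
                                         drop = FALSE]
    truth_profiles <- signatures$profiles[, rownames(truth_present),
                                          drop = FALSE]
    m <- match_signatures(coef(fit), truth_profiles,
                          max_distance = max_distance)
    met <- signature_metrics(m)
    data.frame(seed = s, K = ncol(coef(fit)), TP = met$TP, FP = met$FP,
               FN = met$FN, PPV = met$PPV, TPR = met$TPR,
               mean_cosine = met$mean_cosine, composite = met$composite)
  })
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, c("PPV", "TPR", "mean_cosine", "composite")]
  summary <- rbind(mean = colMeans(num), sd = apply(num, 2, stats::sd))
  list(per_seed = per_seed, summary = as.data.frame(summary))
}

#' Read a run configuration from YAML
#'
#' Reads sampler and extraction settings from a YAML file and applies the
#' scheme-dependent defaults for anything not given. Recognized keys are
#' the arguments of [hdp_config()] plus `scheme`, `downsample_threshold`,
#' `support_cutoff` and `cohesion_threshold`.
#'
#' @param path YAML file.
#' @return List with `config` (an [hdp_config()]), `scheme`, and the
#'   extraction settings.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- y$scheme %||% "SBS96"
  known <- names(formals(hdp_config))
  cfg <- do.call(hdp_config, c(list(scheme = scheme),
                               y[intersect(names(y), setdiff(known, "scheme"))]))
  list(config = cfg, scheme = scheme,
       downsample_threshold = y$downsample_threshold,
       support_cutoff = y$support_cutoff %||% 0.9,
       cohesion_threshold = y$cohesion_threshold %||% 0.9)
}

#' Bundled example signatures and prevalence model
#'
#' Deterministic, well-separated synthetic SBS-96 signature profiles and a
#' small prevalence model, used in examples and tests. Each signature
#' concentrates its mass on a distinct subset of classes with smooth decay,
#' so pairwise cosine similarities are below 0.25.
#'
#' @param k Number of signatures (2-5).
#' @return `example_signatures()`: a [signature_set()];
#'   `example_prevalence_model()`: a [prevalence_model()].
#' @export
example_signatures <- function(k = 3) {
  stopifnot(k >= 1, k <= 5)
  sc <- catalog_scheme("SBS96")
  C <- sc$n_classes
  profs <- vapply(seq_len(k), function(s) {
    # peaks spread over the catalog, distinct support per signature
    centers <- ((seq_len(8) - 1) * 12 + (s - 1) * 2 + 1) %% C + 1
    p <- rep(1e-4, C)
    for (ct in centers) {
      idx <- ((ct - 1 + -1:1) %% C) + 1
      p[idx] <- p[idx] + c(0.4, 1, 0.4) * (1 + 0.15 * s)
    }
    p / sum(p)
  }, numeric(C))
  dimnames(profs) <- list(sc$class_labels, paste0("TruthSig", seq_len(k)))
  signature_set(profs, sc)
}

#' @param signatures A [signature_set()] whose signatures the model covers.
#' @param n_tumors Tumors to synthesize for the single tumor type.
#' @param p Presence probability per signature.
#' @param mu,size Negative-binomial burden parameters.
#' @param d Per-class resampling noise dispersion.
#' @rdname example_signatures
#' @export
example_prevalence_model <- function(signatures, n_tumors = 30, p = 1,
                                     mu = 500, size = 3, d = 30) {
  ids <- colnames(signatures$profiles)
  params <- data.frame(type = "SynType", signature = ids,
                       p = rep(p, length.out = length(ids)),
                       mu = rep(mu, length.out = length(ids)),
                       size = rep(size, length.out = length(ids)),
                       stringsAsFactors = FALSE)
  prevalence_model(params, c(SynType = as.integer(n_tumors)), d = d)
}
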