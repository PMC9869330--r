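#' Prevalence model for synthetic catalogs
#'
#' A prevalence model holds, per (tumor type, signature): the presence
#' probability `p`, the mean burden `mu` among exposed tumors, and the
#' negative-binomial dispersion `size` (variance mu + mu^2/size), plus the
#' number of tumors to synthesize per type and the per-class resampling
#' noise dispersion `d` (30 for SBS-96, 10 for ID-83; `Inf` disables noise).
#'
#' @param params Data frame with columns `type`, `signature`, `p`, `mu`,
#'   `size`.
#' @param n_tumors Named integer vector: tumors to synthesize per type.
#' @param d Per-class resampling dispersion (or `Inf`).
#' @return Object of class `prevalence_model`.
#' @export
prevalence_model <- function(params, n_tumors, d = 30) {
  stopifnot(is.data.frame(params),
            all(c("type", "signature", "p", "mu", "size") %in% names(params)))
  if (any(params$p < 0 | params$p > 1))
    stop("presence probabilities must be in [0, 1]", call. = FALSE)
  pos <- params$p > 0
  if (any(pos & (is.na(params$mu) | params$mu <= 0 |
                 is.na(params$size) | params$size <= 0)))
    stop("mu and size must be positive where p > 0", call. = FALSE)
  if (!(is.numeric(d) && length(d) == 1 && d > 0))
    stop("d must be positive (Inf for no noise)", call. = FALSE)
  types <- unique(params$type)
  if (is.null(names(n_tumors)) || !all(types %in% names(n_tumors)))
    stop("n_tumors must be named by tumor type", call. = FALSE)
  structure(list(params = params, n_tumors = n_tumors[types], d = d),
            class = "prevalence_model")
}

#' @export
print.prevalence_model <- function(x, ...) {
  cat("Prevalence model:", length(unique(x$params$type)), "tumor types,",
      length(unique(x$params$signature)), "signatures, noise d =", x$d, "\n")
  invisible(x)
}

#' Fit a prevalence model from an exposure matrix
#'
#' Per tumor type and signature: `p` is the proportion of tumors of the type
#' with exposure > 0; `mu` and `size` are negative-binomial maximum-likelihood
#' estimates (via `fitdistrplus::fitdist`) on the positive exposures. With
#' fewer than 3 positive tumors no dispersion can be estimated; `size` is
#' then fixed at a large value (1e6, effectively Poisson) and `mu` at the
#' sample mean.
#'
#' @param exposures Non-negative matrix, signatures x tumors (attributed
#'   mutation counts).
#' @param tumor_types Character vector of length `ncol(exposures)`.
#' @param d Noise dispersion stored in the model.
#' @param n_tumors Tumors per type to synthesize; defaults to the observed
#'   counts.
#' @return A [prevalence_model()].
#' @export
fit_prevalence_model <- function(exposures, tumor_types, d = 30,
                                 n_tumors = NULL) {
  stopifnot(is.matrix(exposures), ncol(exposures) == length(tumor_types))
  if (any(exposures < 0)) stop("exposures must be non-negative", call. = FALSE)
  if (is.null(rownames(exposures)))
    rownames(exposures) <- paste0("S", seq_len(nrow(exposures)))
  tumor_types <- as.character(tumor_types)
  if (all(exposures == 0))
    warning("all exposures are zero; model has p = 0 everywhere",
            call. = FALSE)
  rows <- list()
  for (ty in unique(tumor_types)) {
    sub <- exposures[, tumor_types == ty, drop = FALSE]
    for (s in rownames(exposures)) {
      x <- sub[s, ]
      pos <- x[x > 0]
      p <- length(pos) / length(x)
      if (p == 0) {
        mu <- NA_real_; size <- NA_real_
      } else if (length(pos) < 3) {
        mu <- mean(pos); size <- 1e6
      } else {
        fit <- tryCatch(
          fitdistrplus::fitdist(as.integer(round(pos)), "nbinom"),
          error = function(e) NULL)
        if (is.null(fit) || any(is.na(fit$estimate))) {
          mu <- mean(pos); size <- 1e6
        } else {
          mu <- unname(fit$estimate["mu"])
          size <- unname(fit$estimate["size"])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, signature = s, p = p, mu = mu, size = size,
        stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, rows)
  if (is.null(n_tumors)) {
    n_tumors <- table(tumor_types)
    n_tumors <- stats::setNames(as.integer(n_tumors), names(n_tumors))
  }
  prevalence_model(params, n_tumors, d = d)
}

# NB(mean mu, size) with the degenerate mean-0 case returning 0
rnb <- function(n, mu, size) {
  out <- numeric(n)
  ok <- mu > 0
  if (length(mu) == 1) {
    if (mu > 0) out <- stats::rnbinom(n, mu = mu, size = size)
  } else {
    out[ok] <- stats::rnbinom(sum(ok), mu = mu[ok], size = size)
  }
  out
}

#' Synthesize one tumor spectrum
#'
#' For each signature of the model rows: presence is a Bernoulli(p) draw; if
#' present, the burden `m_s` is drawn from NB(mu, size); the expected
#' per-class counts are `m_s` times the signature profile; realistic
#' resampling noise then draws each class count from NB(mean, d)
#' independently (with `d = Inf` the expected counts are used unchanged).
#' The spectrum is the class-wise sum over signatures, rounded to integers.
#'
#' Uses R's global RNG; seed via [synthesize_dataset()] or `set.seed()`.
#'
#' @param model_rows Data frame rows of a [prevalence_model()] for one type.
#' @param signatures A [signature_set()] covering every signature with p > 0.
#' @param d Noise dispersion.
#' @return List with `spectrum` (integer vector over classes) and `draw`
#'   (record of presence, burdens `m_s`, expected and noisy class counts).
#' @export
synthesize_spectrum <- function(model_rows, signatures, d = 30) {
  stopifnot(inherits(signatures, "signature_set"))
  need <- model_rows$signature[model_rows$p > 0]
  have <- colnames(signatures$profiles)
  if (!all(need %in% have))
    stop("signature profiles missing for: ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  C <- nrow(signatures$profiles)
  S <- nrow(model_rows)
  present <- stats::runif(S) < model_rows$p
  m_s <- numeric(S)
  for (i in which(present))
    m_s[i] <- rnb(1, model_rows$mu[i], model_rows$size[i])
  expected <- matrix(0, C, S, dimnames = list(rownames(signatures$profiles),
                                              model_rows$signature))
  noisy <- expected
  for (i in which(m_s > 0)) {
    mst <- m_s[i] * signatures$profiles[, model_rows$signature[i]]
    expected[, i] <- mst
    noisy[, i] <- if (is.infinite(d)) mst else rnb(C, mu = mst, size = d)
  }
  spectrum <- as.integer(round(rowSums(noisy)))
  list(spectrum = stats::setNames(spectrum, rownames(signatures$profiles)),
       draw = list(present = present, m_s = stats::setNames(m_s, model_rows$signature),
                   expected = expected, noisy = noisy))
}

#' Synthesize a full catalog with known ground truth
#'
#' Draws `n_tumors[type]` independent tumors per type from the prevalence
#' model ([synthesize_spectrum()]). Sample ids encode the tumor type
#' (`Type::n`). The same seed always yields the identical dataset.
#'
#' @param model A [prevalence_model()].
#' @param signatures A [signature_set()].
#' @param seed Integer seed.
#' @return List with `catalog` (a [mutation_catalog()] with sample groups =
#'   tumor types) and `truth`: list of `signatures` (those with any true
#'   exposure), `exposures` (true burdens m_s, signatures x tumors),
#'   `tumor_type` and `seed`.
#' @export
synthesize_dataset <- function(model, signatures, seed = 1L) {
  stopifnot(inherits(model, "prevalence_model"),
            inherits(signatures, "signature_set"))
  if (any(model$n_tumors <= 0))
    stop("n_tumors must be positive for every type", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  C <- nrow(signatures$profiles)
  sig_ids <- colnames(signatures$profiles)
  cols <- list(); ids <- character(0); types <- character(0)
  expo <- list()
  for (ty in names(model$n_tumors)) {
    rows <- model$params[model$params$type == ty, , drop = FALSE]
    for (r in seq_len(model$n_tumors[[ty]])) {
      sp <- synthesize_spectrum(rows, signatures, d = model$d)
      cols[[length(cols) + 1L]] <- sp$spectrum
      id <- paste0(ty, "::", r)
      ids <- c(ids, id); types <- c(types, ty)
      e <- stats::setNames(numeric(length(sig_ids)), sig_ids)
      e[names(sp$draw$m_s)] <- sp$draw$m_s
      expo[[length(expo) + 1L]] <- e
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(rownames(signatures$profiles), ids)
  exposures <- do.call(cbind, expo)
  dimnames(exposures) <- list(sig_ids, ids)
  catalog <- mutation_catalog(counts, signatures$scheme,
                              stats::setNames(types, ids))
  list(catalog = catalog,
       truth = list(signatures = signatures, exposures = exposures,
                    tumor_type = stats::setNames(types, ids), seed = seed))
}

#' Read and write prevalence models
#'
#' Serialized as a YAML header (noise dispersion `d` and per-type tumor
#' counts) followed by a tab-separated table `type, signature, p, mu, size`,
#' separated by a line `---`.
#'
#' @param model A [prevalence_model()].
#' @param path File path.
#' @return `read_prevalence_model()` returns a [prevalence_model()].
#' @export
write_prevalence_model <- function(model, path) {
  hdr <- yaml::as.yaml(list(d = if (is.infinite(model$d)) "Inf" else model$d,
                            n_tumors = as.list(model$n_tumors)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, "---"), con)
  utils::write.table(model$params, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_prevalence_model
#' @export
read_prevalence_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sep <- which(lines == "---")[1]
  if (is.na(sep)) stop("missing '---' separator in model file", call. = FALSE)
  hdr <- yaml::yaml.load(paste(lines[seq_len(sep - 1)], collapse = "\n"))
  params <- utils::read.delim(text = paste(lines[-seq_len(sep)],
                                           collapse = "\n"),
                              stringsAsFactors = FALSE)
  d <- if (identical(hdr$d, "Inf")) Inf else as.numeric(hdr$d)
  prevalence_model(params, unlist(hdr$n_tumors), d = d)
}
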