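#' Mutation catalogs and signature sets
#'
#' A mutation catalog is an integer count matrix with one row per mutation
#' class of a [catalog_scheme()] and one column per sample. A signature set
#' has the same layout but holds multinomial probability vectors: each column
#' sums to 1.
#'
#' @param counts Numeric matrix, classes x samples. Row names must be the
#'   scheme's class labels (any order; rows are reordered canonically).
#'   Column names are sample ids.
#' @param scheme A [catalog_scheme()] or scheme name.
#' @param sample_groups Optional named character vector or factor mapping
#'   every sample id to a group label (e.g. cancer type).
#' @return An object of class `mutation_catalog`: list with `counts`
#'   (canonical order, integer), `scheme`, and `sample_groups` (or `NULL`).
#' @examples
#' sc <- catalog_scheme("SBS96")
#' m <- matrix(0L, sc$n_classes, 2,
#'             dimnames = list(sc$class_labels, c("s1", "s2")))
#' m[1, ] <- c(5L, 3L)
#' cat96 <- mutation_catalog(m, sc)
#' @export
mutation_catalog <- function(counts, scheme, sample_groups = NULL) {
  scheme <- as_scheme(scheme)
  counts <- check_class_matrix(counts, scheme, what = "catalog")
  if (any(counts != round(counts)))
    stop("catalog counts must be integers", call. = FALSE)
  if (any(counts < 0))
    stop("catalog counts must be non-negative", call. = FALSE)
  storage.mode(counts) <- "integer"
  ids <- colnames(counts)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(sample_groups)) {
    sample_groups <- as.character(sample_groups[ids])
    names(sample_groups) <- ids
    if (anyNA(sample_groups))
      stop("sample_groups must cover every sample; missing: ",
           paste(ids[is.na(sample_groups)], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, scheme = scheme,
                 sample_groups = sample_groups),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("Mutation catalog (", x$scheme$name, "): ", ncol(x$counts),
      " samples, ", sum(x$counts), " mutations\n", sep = "")
  if (!is.null(x$sample_groups))
    cat("Groups:", paste(unique(x$sample_groups), collapse = ", "), "\n")
  invisible(x)
}

#' @param profiles Numeric matrix of probabilities, classes x signatures;
#'   every column must sum to 1 within 1e-9.
#' @rdname mutation_catalog
#' @export
signature_set <- function(profiles, scheme) {
  scheme <- as_scheme(scheme)
  profiles <- check_class_matrix(profiles, scheme, what = "signature set")
  if (any(profiles < 0))
    stop("signature profiles must be non-negative", call. = FALSE)
  cs <- colSums(profiles)
  if (any(abs(cs - 1) > 1e-9))
    stop("signature columns must sum to 1 (off by up to ",
         format(max(abs(cs - 1))), ")", call. = FALSE)
  structure(list(profiles = profiles, scheme = scheme),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Signature set (", x$scheme$name, "): ", ncol(x$profiles),
      " signatures\n", sep = "")
  invisible(x)
}

# Validate row labels against the scheme and reorder rows canonically.
check_class_matrix <- function(m, scheme, what) {
  if (!is.matrix(m)) m <- as.matrix(m)
  lab <- rownames(m)
  if (is.null(lab))
    stop(what, " must have class labels as row names", call. = FALSE)
  want <- scheme$class_labels
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    stop(what, " has duplicate class labels: ",
         paste(dup, collapse = ", "), call. = FALSE)
  missing <- setdiff(want, lab)
  extra <- setdiff(lab, want)
  if (length(missing) || length(extra))
    stop(what, " class labels do not match scheme ", scheme$name,
         if (length(missing)) paste0("; missing: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ..."),
         if (length(extra)) paste0("; unexpected: ",
           paste(utils::head(extra, 5), collapse = ", "),
           if (length(extra) > 5) " ..."),
         call. = FALSE)
  m <- m[want, , drop = FALSE]
  if (is.null(colnames(m)) || ncol(m) == 0)
    stop(what, " must have at least one named column", call. = FALSE)
  m
}

#' Read and write catalog and signature files
#'
#' Files are tab-delimited with mutation-class labels in the first column and
#' sample (or signature) ids in the header. Rows may appear in any order in
#' the file; they are reordered to the scheme's canonical order on reading.
#' The header of the label column is ignored. Counts are written as integers,
#' probabilities with 10 significant digits, so write/read round trips are
#' exact for catalogs and within 1e-9 for signatures.
#'
#' @param path File path.
#' @param scheme A [catalog_scheme()] or scheme name.
#' @param sample_groups Optional group mapping, passed to [mutation_catalog()].
#' @return `read_catalog()` a `mutation_catalog`; `read_signatures()` a
#'   `signature_set`.
#' @export
read_catalog <- function(path, scheme, sample_groups = NULL) {
  m <- read_class_table(path)
  bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at row '%s', column '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  mutation_catalog(m, scheme, sample_groups)
}

#' @rdname read_catalog
#' @export
read_signatures <- function(path, scheme) {
  m <- read_class_table(path)
  signature_set(m, scheme)
}

read_class_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    stop("file must have a label column plus at least one sample column",
         call. = FALSE)
  lab <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                  function(x) as.numeric(as.character(x))))
    bad <- which(is.na(num) & !is.na(as.matrix(df[, -1, drop = FALSE])),
                 arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   lab[bad[1, 1]], colnames(df)[-1][bad[1, 2]]),
           call. = FALSE)
    m <- num
  }
  rownames(m) <- lab
  m
}

#' @param x A `mutation_catalog` or `signature_set`.
#' @rdname read_catalog
#' @export
write_catalog <- function(x, path) {
  if (inherits(x, "mutation_catalog")) {
    m <- x$counts
    vals <- format(m, scientific = FALSE, trim = TRUE)
  } else if (inherits(x, "signature_set")) {
    m <- x$profiles
    vals <- formatC(m, format = "g", digits = 10)
  } else stop("x must be a mutation_catalog or signature_set", call. = FALSE)
  if (ncol(m) == 0) stop("nothing to write: no columns", call. = FALSE)
  df <- data.frame(MutationType = rownames(m), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("MutationType", colnames(m))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write to '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname read_catalog
#' @export
write_signatures <- write_catalog

catalog_totals <- function(catalog) colSums(catalog$counts)
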