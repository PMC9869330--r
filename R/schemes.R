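#' Canonical mutation-class schemes
#'
#' A catalog scheme fixes the set and order of mutation classes over which
#' spectra and signatures are defined. Two schemes are supported:
#'
#' * `"SBS96"`: single-base substitutions in pyrimidine-centered trinucleotide
#'   context, labelled like `"A[C>A]A"`. Classes are ordered by substitution
#'   type (C>A, C>G, C>T, T>A, T>C, T>G) and, within each block, by the 5'
#'   then the 3' flanking base in A, C, G, T order (the COSMIC convention).
#' * `"ID83"`: the COSMIC v3 small insertion/deletion classification:
#'   1-bp deletions and insertions by base (C/T) and homopolymer length;
#'   longer deletions and insertions by length and repeat count; deletions
#'   flanked by microhomology by deletion and microhomology length. Labels
#'   use the text form `"DEL:C:1:0"`, `"INS:T:1:5"`, `"DEL:MH:5:2"`;
#'   deletions precede insertions.
#'
#' @param name Scheme name, `"SBS96"` or `"ID83"`.
#' @return An object of class `catalog_scheme`: a list with elements `name`,
#'   `class_labels` (ordered character vector) and `n_classes`.
#' @examples
#' sc <- catalog_scheme("SBS96")
#' sc$n_classes
#' head(sc$class_labels)
#' @export
catalog_scheme <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("scheme name must be a single string", call. = FALSE)
  labels <- switch(name,
    SBS96 = sbs96_labels(),
    ID83  = id83_labels(),
    stop(sprintf("unknown catalog scheme '%s' (supported: SBS96, ID83)", name),
         call. = FALSE)
  )
  structure(
    list(name = name, class_labels = labels, n_classes = length(labels)),
    class = "catalog_scheme"
  )
}

#' @export
print.catalog_scheme <- function(x, ...) {
  cat("Catalog scheme", x$name, "with", x$n_classes, "mutation classes\n")
  invisible(x)
}

sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (p5 in bases)
      for (p3 in bases)
        out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

id83_labels <- function() {
  hp <- 0:5   # homopolymer length beyond the indel itself (5 means 5+)
  rep_sizes <- 0:5
  mk1 <- function(type, base) paste(type, base, 1, hp, sep = ":")
  mkrep <- function(type, len) paste(type, "repeats", len, rep_sizes, sep = ":")
  mh <- c("DEL:MH:2:1",
          "DEL:MH:3:1", "DEL:MH:3:2",
          "DEL:MH:4:1", "DEL:MH:4:2", "DEL:MH:4:3",
          "DEL:MH:5:1", "DEL:MH:5:2", "DEL:MH:5:3", "DEL:MH:5:4", "DEL:MH:5:5")
  c(mk1("DEL", "C"), mk1("DEL", "T"),
    unlist(lapply(2:5, function(l) mkrep("DEL", l))),
    mh,
    mk1("INS", "C"), mk1("INS", "T"),
    unlist(lapply(2:5, function(l) mkrep("INS", l))))
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "catalog_scheme")) return(scheme)
  catalog_scheme(scheme)
}
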