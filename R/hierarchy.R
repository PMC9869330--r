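#' Build the Dirichlet-process hierarchy over samples
#'
#' Without groups the model is two-layer: a root Dirichlet process (whose base
#' distribution is the uniform Dirichlet over mutation classes) with one leaf
#' process per sample. With groups it is three-layer: root, one process per
#' group (e.g. cancer type), and one leaf per sample under its group's
#' process, so signatures are shared most readily among samples of the same
#' group.
#'
#' By default all processes at the same depth share one concentration
#' parameter (`cp_mode = "level"`); `cp_mode = "node"` gives every process
#' its own.
#'
#' @param sample_ids Character vector of sample ids.
#' @param sample_groups Optional named vector mapping every sample id to a
#'   group label.
#' @param cp_mode Concentration-parameter grouping: `"level"` or `"node"`.
#' @return An object of class `hdp_hierarchy`: data frame with one row per
#'   node (`node`, `parent`, `kind`, `sample`, `cp_group`), root first.
#' @examples
#' hdp_hierarchy(c("s1", "s2", "s3"))
#' hdp_hierarchy(c("s1", "s2"), c(s1 = "Lung", s2 = "Skin"))
#' @export
hdp_hierarchy <- function(sample_ids, sample_groups = NULL,
                          cp_mode = c("level", "node")) {
  cp_mode <- match.arg(cp_mode)
  if (length(sample_ids) == 0) stop("sample_ids must be non-empty", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  if (is.null(sample_groups)) {
    n <- length(sample_ids)
    df <- data.frame(
      node = seq_len(n + 1L),
      parent = c(NA_integer_, rep(1L, n)),
      kind = c("root", rep("leaf", n)),
      sample = c(NA_character_, sample_ids),
      level = c(0L, rep(1L, n)),
      stringsAsFactors = FALSE)
  } else {
    g <- as.character(sample_groups[sample_ids])
    if (anyNA(g))
      stop("sample_groups does not cover sample(s): ",
           paste(sample_ids[is.na(g)], collapse = ", "), call. = FALSE)
    groups <- unique(g)
    ng <- length(groups)
    n <- length(sample_ids)
    df <- data.frame(
      node = seq_len(1L + ng + n),
      parent = c(NA_integer_, rep(1L, ng), 1L + match(g, groups)),
      kind = c("root", rep("group", ng), rep("leaf", n)),
      sample = c(NA_character_, rep(NA_character_, ng), sample_ids),
      level = c(0L, rep(1L, ng), rep(2L, n)),
      stringsAsFactors = FALSE)
    attr(df, "groups") <- groups
  }
  df$cp_group <- if (cp_mode == "level") df$level + 1L else df$node
  df$cp_group <- as.integer(factor(df$cp_group))
  class(df) <- c("hdp_hierarchy", "data.frame")
  df
}

#' @export
print.hdp_hierarchy <- function(x, ...) {
  cat("HDP hierarchy:", nrow(x), "nodes (",
      sum(x$kind == "group"), "groups,", sum(x$kind == "leaf"), "leaves ),",
      max(x$cp_group), "concentration-parameter group(s)\n")
  invisible(x)
}
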