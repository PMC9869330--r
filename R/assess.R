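#' Cosine similarity of two non-negative vectors
#'
#' @param a,b Non-negative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return Cosine similarity in \[0, 1\].
#' @examples
#' cosine_sim(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("vectors must be non-negative", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector", call. = FALSE)
  min(1, max(0, sum(a * b) / (na * nb)))
}

# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials) on
# a square cost matrix; returns for each row the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_of_row <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign_of_row[p[j]] <- j - 1L
  assign_of_row
}

#' Match discovered signatures to ground truth
#'
#' Computes the cosine-distance matrix (1 - cosine similarity) between
#' discovered and ground-truth signatures, replaces distances greater than
#' `max_distance` (default 0.1) by a large value `L`, finds the assignment
#' minimizing total distance with the Hungarian algorithm (rectangular
#' matrices are padded with `L`-cost dummies), and discards assigned pairs
#' at cost `L`. Remaining pairs are true positives; unmatched discovered
#' signatures are false positives; unmatched truth signatures are false
#' negatives.
#'
#' @param discovered,truth [signature_set()]s on the same scheme (or plain
#'   profile matrices with identical row count). `discovered` may have zero
#'   columns (everything becomes a false negative).
#' @param max_distance Cosine-distance cutoff for an acceptable match.
#' @param L Large substitute distance; any value much larger than
#'   `ncol * max_distance` gives the same result.
#' @return Object of class `signature_match`: `tp` (data frame of matched
#'   pairs with cosine similarities), `fp`, `fn` (ids), and counts `TP`,
#'   `FP`, `FN`.
#' @export
match_signatures <- function(discovered, truth, max_distance = 0.1, L = 1000) {
  if (!(max_distance > 0 && max_distance < 1 && L > 1))
    stop("need 0 < max_distance < 1 < L", call. = FALSE)
  dd <- profile_matrix(discovered)
  tt <- profile_matrix(truth)
  if (inherits(discovered, "signature_set") && inherits(truth, "signature_set") &&
      !identical(discovered$scheme$name, truth$scheme$name))
    stop("signature sets are on different schemes", call. = FALSE)
  if (nrow(dd) != nrow(tt))
    stop("profile matrices have different numbers of classes", call. = FALSE)
  nd <- ncol(dd); nt <- ncol(tt)
  if (nt == 0) stop("truth set is empty", call. = FALSE)
  if (is.null(colnames(dd)) && nd) colnames(dd) <- paste0("D", seq_len(nd))
  if (is.null(colnames(tt))) colnames(tt) <- paste0("T", seq_len(nt))

  sim <- matrix(0, nd, nt)
  for (i in seq_len(nd)) for (j in seq_len(nt))
    sim[i, j] <- cosine_sim(dd[, i], tt[, j])
  dist <- 1 - sim
  dist[dist > max_distance] <- L

  n <- max(nd, nt)
  cost <- matrix(L, n, n)
  if (nd) cost[seq_len(nd), seq_len(nt)] <- dist
  tp <- data.frame(discovered = character(0), truth = character(0),
                   cosine = numeric(0), stringsAsFactors = FALSE)
  if (nd) {
    asg <- hungarian(cost)
    for (i in seq_len(nd)) {
      j <- asg[i]
      if (j <= nt && cost[i, j] < L)
        tp <- rbind(tp, data.frame(discovered = colnames(dd)[i],
                                   truth = colnames(tt)[j],
                                   cosine = sim[i, j],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(
    tp = tp,
    fp = setdiff(colnames(dd), tp$discovered),
    fn = setdiff(colnames(tt), tp$truth),
    TP = nrow(tp),
    FP = nd - nrow(tp),
    FN = nt - nrow(tp),
    max_distance = max_distance, L = L),
    class = "signature_match")
}

profile_matrix <- function(x) {
  if (inherits(x, "signature_set")) x$profiles
  else if (is.matrix(x)) x
  else stop("expected a signature_set or profile matrix", call. = FALSE)
}

#' @export
print.signature_match <- function(x, ...) {
  cat("Signature match: TP =", x$TP, ", FP =", x$FP, ", FN =", x$FN, "\n")
  invisible(x)
}

#' Discovery performance metrics
#'
#' PPV = TP/(TP+FP), TPR = TP/(TP+FN), the mean cosine similarity over
#' true-positive pairs, and their sum, the composite measure (0 when the
#' respective denominator is zero).
#'
#' @param match A [match_signatures()] result.
#' @return List of class `signature_metrics` with `PPV`, `TPR`,
#'   `mean_cosine`, `composite`, `TP`, `FP`, `FN`.
#' @export
signature_metrics <- function(match) {
  stopifnot(inherits(match, "signature_match"))
  ppv <- if (match$TP + match$FP > 0) match$TP / (match$TP + match$FP) else 0
  tpr <- if (match$TP + match$FN > 0) match$TP / (match$TP + match$FN) else 0
  mc <- if (match$TP > 0) mean(match$tp$cosine) else 0
  structure(list(PPV = ppv, TPR = tpr, mean_cosine = mc,
                 composite = composite_measure(ppv, tpr, mc),
                 TP = match$TP, FP = match$FP, FN = match$FN),
            class = "signature_metrics")
}

#' @param ppv,tpr,mean_cosine Component values.
#' @rdname signature_metrics
#' @export
composite_measure <- function(ppv, tpr, mean_cosine) ppv + tpr + mean_cosine

#' @export
print.signature_metrics <- function(x, ...) {
  cat(sprintf("PPV %.3f  TPR %.3f  mean cosine %.3f  composite %.3f\n",
              x$PPV, x$TPR, x$mean_cosine, x$composite))
  invisible(x)
}

#' Reconstruct a profile from a reference signature set
#'
#' Finds non-negative weights minimizing the Euclidean distance between the
#' target and a weighted sum of reference signatures (non-negative least
#' squares), e.g. to test whether a discovered signature is a merge of known
#' ones.
#'
#' @param target Non-negative vector (profile or spectrum).
#' @param reference A [signature_set()] or profile matrix.
#' @return List with `weights` (named), `reconstruction` and `cosine`
#'   (cosine similarity of reconstruction to target; 0 if the
#'   reconstruction is identically zero).
#' @export
reconstruct_signature <- function(target, reference) {
  A <- profile_matrix(reference)
  if (ncol(A) == 0) stop("empty reference set", call. = FALSE)
  if (length(target) != nrow(A))
    stop("target length does not match reference classes", call. = FALSE)
  fit <- pracma::lsqnonneg(A, as.numeric(target))
  w <- stats::setNames(fit$x, colnames(A))
  recon <- as.vector(A %*% w)
  cs <- if (sum(recon) == 0 || sum(target) == 0) 0
        else cosine_sim(target, recon)
  list(weights = w, reconstruction = recon, cosine = cs)
}
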