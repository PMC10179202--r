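# Matched classification accuracy: unsupervised cluster ids carry no class
# names, so clusters are assigned to ground-truth classes by maximising the
# total agreement over the contingency table (optimal bipartite matching).

# Hungarian algorithm (shortest augmenting path, O(n^3)) on a square cost
# matrix; returns for each row the assigned column (1-based). Minimises
# total cost.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
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
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  assign
}

#' Matched classification accuracy against ground truth
#'
#' Builds the cluster-by-class contingency table, finds the cluster-to-class
#' assignment that maximises the total number of agreeing images (optimal
#' bipartite matching via the Hungarian algorithm), and reports the overall
#' and per-class accuracy under that assignment: the ratio of correctly
#' classified projection images to the total.
#'
#' @param pred a `cryo_clusters` or an integer vector of predicted labels.
#' @param truth integer vector of ground-truth labels (same length).
#' @return An object of class `cryo_accuracy`: `overall` in `[0, 1]`,
#'   `per_class` (named by true class), `permutation` (predicted cluster ->
#'   true class), `table` (contingency), and `group_counts` (per matched
#'   class).
#' @export
match_labels_accuracy <- function(pred, truth) {
  if (inherits(pred, "cryo_clusters")) pred <- pred$labels
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  N <- length(truth)
  pl <- sort(unique(pred))
  tl <- sort(unique(truth))
  K <- max(length(pl), length(tl))
  tab <- matrix(0, K, K)
  rownames(tab) <- c(pl, rep(NA, K - length(pl)))[seq_len(K)]
  colnames(tab) <- c(tl, rep(NA, K - length(tl)))[seq_len(K)]
  for (a in seq_along(pl)) for (b in seq_along(tl))
    tab[a, b] <- sum(pred == pl[a] & truth == tl[b])
  assign <- hungarian_assign(max(tab) - tab)  # maximise agreement
  matched <- sum(tab[cbind(seq_len(K), assign)])
  per_class <- numeric(length(tl))
  names(per_class) <- tl
  counts <- integer(length(tl))
  names(counts) <- tl
  for (a in seq_len(K)) {
    b <- assign[a]
    if (b <= length(tl)) {
      cls <- as.character(tl[b])
      nb <- sum(truth == tl[b])
      per_class[cls] <- if (nb > 0) tab[a, b] / nb else NA_real_
      counts[cls] <- if (a <= length(pl)) sum(pred == pl[a]) else 0L
    }
  }
  perm <- assign[seq_along(pl)]
  names(perm) <- pl
  structure(list(overall = matched / N, per_class = per_class,
                 permutation = perm - 1L, table = tab,
                 group_counts = counts, n = N),
            class = "cryo_accuracy")
}

#' @export
print.cryo_accuracy <- function(x, ...) {
  cat(sprintf("Matched classification accuracy: %.2f%% (n = %d)\n",
              100 * x$overall, x$n))
  cat("Per-class accuracy:\n")
  for (cls in names(x$per_class))
    cat(sprintf("  class %s: %6.2f%%  (%d images in matched cluster)\n",
                cls, 100 * x$per_class[cls], x$group_counts[cls]))
  invisible(x)
}

#' Per-cluster group sizes
#'
#' Histogram of predicted cluster sizes; when a matching report is given the
#' clusters are relabelled to their matched ground-truth classes, which is
#' how group-count tables are usually presented.
#'
#' @param pred a `cryo_clusters` or integer label vector.
#' @param report optional `cryo_accuracy` used to map clusters to classes.
#' @param K optional number of clusters (so empty clusters report 0).
#' @return Named integer vector of sizes summing to N.
#' @export
group_counts <- function(pred, report = NULL, K = NULL) {
  if (inherits(pred, "cryo_clusters")) {
    if (is.null(K)) K <- pred$K
    pred <- pred$labels
  }
  if (!is.null(report)) return(report$group_counts)
  if (is.null(K)) K <- max(pred) + 1L
  counts <- tabulate(pred + 1L, nbins = K)
  names(counts) <- seq_len(K) - 1L
  counts
}

#' Write an accuracy report to JSON
#'
#' @param report a `cryo_accuracy`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "cryo_accuracy"))
  jsonlite::write_json(list(
    overall_accuracy = report$overall,
    per_class_accuracy = as.list(report$per_class),
    group_counts = as.list(report$group_counts),
    permutation = as.list(report$permutation),
    n = report$n), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
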