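#' Mean temporal profile matrix
#'
#' Mean over individuals of log2 abundance per day, one row per protein —
#' the feature x day matrix that profile clustering operates on. Additional
#' named rows (e.g. a mean total-IgM profile or an antibody-titre curve)
#' can be bound with [rbind()] before clustering.
#'
#' @param tensor complete log2-scale [abundance_tensor()].
#' @param proteins accessions to include (default all).
#' @return numeric matrix, rows = features, columns = days (sorted).
#' @export
profile_matrix <- function(tensor, proteins = tensor$proteins) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (!all(tensor$mask)) stop("tensor has missing values; impute first")
  days <- sort(unique(tensor$samples$day))
  rows <- match(proteins, tensor$proteins)
  if (anyNA(rows)) stop("unknown protein: ", proteins[is.na(rows)][1L])
  out <- vapply(days, function(d) {
    rowMeans(tensor$values[rows, tensor$samples$day == d, drop = FALSE])
  }, numeric(length(rows)))
  if (length(rows) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(proteins, days)
  out
}

#' Z-score profile rows
#'
#' Centres each row to mean 0 and scales to SD 1 (denominator `n - 1`).
#' Pearson correlations between rows are unchanged; the z-scoring exists
#' for display parity with heatmap software that standardizes rows.
#'
#' @param profile numeric matrix, features x days.
#' @return the standardized matrix.
#' @export
zscore_rows <- function(profile) {
  profile <- as.matrix(profile)
  sds <- apply(profile, 1L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("constant row: ",
         rownames(profile)[which(sds == 0 | !is.finite(sds))[1L]])
  }
  (profile - rowMeans(profile)) / sds
}

#' Pearson correlation dissimilarity between profile rows
#'
#' `d(i, j) = 1 - r(row_i, row_j)`, zero diagonal, range `[0, 2]`.
#'
#' @param profile numeric matrix with >= 2 rows of nonzero variance.
#' @return symmetric dissimilarity matrix.
#' @export
corr_dissimilarity <- function(profile) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2L) stop("need at least 2 rows")
  sds <- apply(profile, 1L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("constant row: ",
         rownames(profile)[which(sds == 0 | !is.finite(sds))[1L]])
  }
  d <- 1 - stats::cor(t(profile))
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with furthest-neighbour (complete) linkage,
#' whose merge heights are monotone non-decreasing by construction.
#'
#' @param dissimilarity symmetric non-negative matrix with zero diagonal.
#' @return an [stats::hclust] tree.
#' @export
hclust_complete <- function(dissimilarity) {
  dissimilarity <- as.matrix(dissimilarity)
  if (anyNA(dissimilarity)) stop("NaN/NA in dissimilarity")
  if (any(dissimilarity < 0)) stop("negative dissimilarity")
  if (max(abs(dissimilarity - t(dissimilarity))) > 1e-8) {
    stop("dissimilarity not symmetric")
  }
  stats::hclust(stats::as.dist(dissimilarity), method = "complete")
}

#' Unconstrained multiple-fragment seriation path
#'
#' The multiple-fragment (greedy edge insertion) heuristic: repeatedly add
#' the globally smallest dissimilarity edge that joins two endpoints of
#' different path fragments (never closing a cycle, never exceeding degree
#' two) until one Hamiltonian path remains.
#'
#' @param dissimilarity symmetric matrix.
#' @return integer permutation of `1:n` (leaf indices along the path).
#' @export
mf_path <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (n == 1L) return(1L)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  degree <- integer(n)
  adj <- vector("list", n)
  added <- 0L
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    if (degree[i] >= 2L || degree[j] >= 2L) next
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    parent[ri] <- rj
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    added <- added + 1L
    if (added == n - 1L) break
  }
  start <- which(degree == 1L)[1L]
  path <- integer(n)
  path[1L] <- start
  prev <- 0L
  for (s in 2L:n) {
    nxt <- setdiff(adj[[path[s - 1L]]], prev)
    prev <- path[s - 1L]
    path[s] <- nxt[1L]
  }
  path
}

#' Seriation of a dendrogram by optimal branch flipping
#'
#' Among the `2^(n-1)` leaf orders obtainable by flipping internal branches
#' of the tree, finds (by exact dynamic programming) one minimizing the sum
#' of dissimilarities between adjacent leaves, and orients it to agree with
#' the unconstrained multiple-fragment path (the greedy-edge-insertion
#' order of [mf_path()]). This reproduces the behaviour of heatmap
#' seriation tools that reorder a fixed complete-linkage tree.
#'
#' @param dissimilarity symmetric matrix the tree was built from.
#' @param tree an [stats::hclust] over the same leaves.
#' @return object of class `seriation_order`: list with `order` (integer
#'   permutation), `labels` (leaf labels in seriated order), `path_length`
#'   (adjacent-dissimilarity sum), `mf` (the unconstrained path).
#' @export
mf_seriation <- function(dissimilarity, tree) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (length(tree$order) != n) stop("tree/matrix leaf count mismatch")
  if (!is.null(rownames(d)) && !is.null(tree$labels) &&
      !identical(rownames(d), tree$labels)) {
    stop("tree/matrix leaf labels mismatch")
  }
  ord <- olo_order(tree, d)
  mf <- mf_path(d)
  # orient to agree with the MF path (undirected): prefer the orientation
  # whose leaf positions correlate positively with the MF positions
  pos_mf <- order(mf)
  if (stats::cor(order(ord), pos_mf) < stats::cor(order(rev(ord)), pos_mf)) {
    ord <- rev(ord)
  }
  structure(list(order = ord,
                 labels = if (!is.null(tree$labels)) tree$labels[ord] else ord,
                 path_length = path_length(d, ord),
                 mf = mf),
            class = "seriation_order")
}

#' @export
print.seriation_order <- function(x, ...) {
  cat(sprintf("seriation_order over %d leaves, path length %.4f\n",
              length(x$order), x$path_length))
  invisible(x)
}

#' Adjacent-dissimilarity sum of a leaf order
#'
#' @param dissimilarity symmetric matrix.
#' @param order integer permutation.
#' @return the sum of `d[order[i], order[i+1]]`.
#' @export
path_length <- function(dissimilarity, order) {
  d <- as.matrix(dissimilarity)
  if (length(order) < 2L) return(0)
  sum(d[cbind(order[-length(order)], order[-1L])])
}

# Exact optimal leaf ordering: for every node and ordered pair of boundary
# leaves (l leftmost, r rightmost) the minimal internal path cost; combine
# children over their junction leaves. O(n^3)-ish, fine at heatmap scale.
olo_order <- function(tree, d) {
  n <- nrow(d)
  if (n == 1L) return(1L)
  leaves <- vector("list", nrow(tree$merge))
  M <- vector("list", nrow(tree$merge))       # cost[l, r]
  node_leaves <- function(v) if (v < 0L) -v else leaves[[v]]
  get_cost <- function(v) {
    if (v < 0L) {
      m <- matrix(0, 1L, 1L, dimnames = list(-v, -v))
      return(m)
    }
    M[[v]]
  }
  for (v in seq_len(nrow(tree$merge))) {
    a <- tree$merge[v, 1L]; b <- tree$merge[v, 2L]
    la <- node_leaves(a); lb <- node_leaves(b)
    ca <- get_cost(a); cb <- get_cost(b)
    leaves[[v]] <- c(la, lb)
    all_lv <- leaves[[v]]
    m <- matrix(Inf, length(all_lv), length(all_lv),
                dimnames = list(all_lv, all_lv))
    # left end in A, right end in B
    for (l in seq_along(la)) for (r in seq_along(lb)) {
      # min over junction leaves h (right end of A), g (left end of B)
      best <- Inf
      for (h in seq_along(la)) for (g in seq_along(lb)) {
        val <- ca[l, h] + d[la[h], lb[g]] + cb[g, r]
        if (val < best) best <- val
      }
      i <- match(la[l], all_lv); j <- match(lb[r], all_lv)
      m[i, j] <- best
    }
    # left end in B, right end in A (mirror)
    for (l in seq_along(lb)) for (r in seq_along(la)) {
      best <- Inf
      for (h in seq_along(lb)) for (g in seq_along(la)) {
        val <- cb[l, h] + d[lb[h], la[g]] + ca[g, r]
        if (val < best) best <- val
      }
      i <- match(lb[l], all_lv); j <- match(la[r], all_lv)
      m[i, j] <- best
    }
    M[[v]] <- m
  }
  root <- nrow(tree$merge)
  mr <- M[[root]]
  idx <- which(mr == min(mr), arr.ind = TRUE)[1L, ]
  lvs <- leaves[[root]]
  reconstruct(tree, d, M, leaves, root, lvs[idx[1L]], lvs[idx[2L]])
}

reconstruct <- function(tree, d, M, leaves, v, l, r) {
  if (v < 0L) return(-v)
  a <- tree$merge[v, 1L]; b <- tree$merge[v, 2L]
  la <- if (a < 0L) -a else leaves[[a]]
  lb <- if (b < 0L) -b else leaves[[b]]
  ca <- if (a < 0L) matrix(0, 1L, 1L) else M[[a]]
  cb <- if (b < 0L) matrix(0, 1L, 1L) else M[[b]]
  if (l %in% la) {
    stopifnot(r %in% lb)
    best <- Inf; bh <- NA; bg <- NA
    for (h in seq_along(la)) for (g in seq_along(lb)) {
      val <- ca[match(l, la), h] + d[la[h], lb[g]] + cb[g, match(r, lb)]
      if (val < best) { best <- val; bh <- la[h]; bg <- lb[g] }
    }
    c(reconstruct(tree, d, M, leaves, a, l, bh),
      reconstruct(tree, d, M, leaves, b, bg, r))
  } else {
    stopifnot(l %in% lb, r %in% la)
    best <- Inf; bh <- NA; bg <- NA
    for (h in seq_along(lb)) for (g in seq_along(la)) {
      val <- cb[match(l, lb), h] + d[lb[h], la[g]] + ca[g, match(r, la)]
      if (val < best) { best <- val; bh <- lb[h]; bg <- la[g] }
    }
    c(reconstruct(tree, d, M, leaves, b, l, bh),
      reconstruct(tree, d, M, leaves, a, bg, r))
  }
}

#' Cut a dendrogram into clusters, labelled in seriation order
#'
#' Cuts at `k` groups (the `(n - k)`-th merge) or at a height; when a
#' seriation order is given, cluster ids are renumbered by first appearance
#' along that order, so cluster 1 is leftmost on a seriated heatmap.
#'
#' @param tree an [stats::hclust].
#' @param k number of clusters (or `NULL`).
#' @param height cut height (used when `k` is `NULL`).
#' @param order optional [mf_seriation()] result or integer permutation.
#' @return integer cluster labels named by leaf label.
#' @export
cut_clusters <- function(tree, k = NULL, height = NULL, order = NULL) {
  n <- length(tree$order)
  if (is.null(k) && is.null(height)) stop("give k or height")
  if (!is.null(k)) {
    if (k < 1L || k > n) stop("k out of range [1, ", n, "]")
    cl <- stats::cutree(tree, k = k)
  } else {
    if (height < 0) stop("height must be >= 0")
    cl <- stats::cutree(tree, h = height)
  }
  if (!is.null(order)) {
    ord <- if (inherits(order, "seriation_order")) order$order else order
    first_seen <- unique(cl[ord])
    cl <- match(cl, first_seen)
    names(cl) <- if (!is.null(tree$labels)) tree$labels else seq_len(n)
  }
  cl
}
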