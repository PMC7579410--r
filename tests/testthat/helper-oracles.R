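# Independent oracles used across the suite. Each is a deliberately plain
# re-derivation of the quantity it checks, sharing no code with the package
# implementation.

# --- global alignment: Gotoh affine-gap DP ---------------------------------
# match 1 / mismatch -1; a gap of length L costs open + L * extend
# (Biostrings convention). Returns the optimal score and one optimal
# alignment (deterministic traceback preferring diagonal, then gap-in-b,
# then gap-in-a).
oracle_align <- function(a, b, match = 1, mismatch = -1,
                         open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in B (A residue vs -)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in A
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -(open + (i - 1L) * extend)
  for (j in 2L:(m + 1L)) Y[1L, j] <- -(open + (j - 1L) * extend)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  ai <- character(); bi <- character()
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L]))
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(prev)
      ai <- c(A[i - 1L], ai); bi <- c(B[j - 1L], bi)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      from_m <- M[i - 1L, j] - open - extend
      from_x <- X[i - 1L, j] - extend
      ai <- c(A[i - 1L], ai); bi <- c("-", bi)
      state <- if (from_m >= from_x) 1L else 2L
      i <- i - 1L
      if (i == 1L && j > 1L) state <- 3L
    } else {
      from_m <- M[i, j - 1L] - open - extend
      from_y <- Y[i, j - 1L] - extend
      ai <- c("-", ai); bi <- c(B[j - 1L], bi)
      state <- if (from_m >= from_y) 1L else 3L
      j <- j - 1L
      if (j == 1L && i > 1L) state <- 2L
    }
  }
  list(score = score, a = paste(ai, collapse = ""), b = paste(bi, collapse = ""))
}

oracle_identity <- function(a, b) {
  al <- oracle_align(a, b)
  pa <- strsplit(al$a, "")[[1L]]; pb <- strsplit(al$b, "")[[1L]]
  shorter <- if (nchar(a) <= nchar(b)) pa else pb
  non_gap <- which(shorter != "-")
  span <- seq(min(non_gap), max(non_gap))
  100 * sum(pa[span] == pb[span]) / length(span)
}

# --- tryptic digestion: enumerate fragments over contiguous site spans -----
oracle_digest <- function(seq, mc, min_len, max_len) {
  aa <- strsplit(seq, "")[[1L]]; n <- length(aa)
  sites <- integer()
  for (i in seq_len(n - 1L)) {
    if (aa[i] %in% c("K", "R") && aa[i + 1L] != "P") sites <- c(sites, i)
  }
  bounds <- c(0L, sites, n)
  B <- length(bounds)
  out <- character()
  for (s in seq_len(B - 1L)) {
    for (e in (s + 1L):B) {
      if (e - s - 1L > mc) next   # internal cleavage sites spanned
      frag <- substr(seq, bounds[s] + 1L, bounds[e])
      if (nchar(frag) >= min_len && nchar(frag) <= max_len) out <- c(out, frag)
    }
  }
  unique(out)
}

# --- majority-group assembly: independent evaluation of the stated rule ----
oracle_groups <- function(sets, threshold = 0.5) {
  sets <- sets[vapply(sets, length, 1L) > 0L]
  remaining <- names(sets)[order(-vapply(sets, length, 1L), names(sets))]
  groups <- list()
  while (length(remaining)) {
    lead <- remaining[1L]
    join <- vapply(remaining, function(p) {
      length(intersect(sets[[p]], sets[[lead]])) / length(sets[[p]]) >=
        threshold
    }, TRUE)
    members <- remaining[join | remaining == lead]
    groups[[length(groups) + 1L]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  groups
}

# partition signature independent of group order
partition_sig <- function(member_lists) {
  unname(sort(vapply(member_lists,
                     function(m) paste(sort(m), collapse = ","), "")))
}

# --- BH step-up by hand ----------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# --- one-way ANOVA via lm --------------------------------------------------
oracle_anova <- function(groups) {
  y <- unlist(groups); g <- factor(rep(seq_along(groups),
                                       vapply(groups, length, 1L)))
  tab <- anova(lm(y ~ g))
  list(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
       r2 = tab$`Sum Sq`[1L] / sum(tab$`Sum Sq`))
}

# --- Anderson-Darling statistic, textbook case-3 formula -------------------
oracle_ad_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  u <- pnorm(z)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# --- Spearman: mid-rank Pearson + exact permutation p ----------------------
oracle_spearman_perm <- function(x, y) {
  rho_of <- function(yy) cor(rank(x), rank(yy))
  obs <- rho_of(y)
  perms <- permutations_all(length(y))
  rhos <- apply(perms, 1L, function(ix) rho_of(y[ix]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# --- complete-linkage agglomeration, plain re-derivation -------------------
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) dimnames(d) <- list(seq_len(n), seq_len(n))
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    heights <- c(heights, best)
    partitions[[length(partitions) + 1L]] <-
      partition_sig(lapply(clusters, as.character))
  }
  list(heights = heights, partitions = partitions)
}

# --- adjusted Rand index (mclust when present, else direct formula) --------
oracle_ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); sn <- comb2(sum(tab))
  (sij - si * sj / sn) / ((si + sj) / 2 - si * sj / sn)
}

# --- small helpers ---------------------------------------------------------
toy_tensor <- function(values, days, fish, scale = "log2") {
  samples <- data.frame(individual = rep(fish, each = length(days)),
                        day = rep(days, length(fish)))
  abundance_tensor(values, rownames(values), samples, scale = scale)
}

random_peptide_index <- function(n_prot, n_pep, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(n_prot), function(i) {
    sample(sprintf("pep%02d", seq_len(n_pep)), sample(1:n_pep, 1L))
  })
  names(sets) <- sprintf("PR%02d", seq_len(n_prot))
  sets
}

# build a peptide_index object directly from named peptide sets
index_from_sets <- function(sets) {
  pep2prot <- split(rep(names(sets), vapply(sets, length, 1L)),
                    unlist(sets, use.names = FALSE))
  structure(list(prot2pep = sets, pep2prot = pep2prot),
            class = "peptide_index", warnings = character())
}
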