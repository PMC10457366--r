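# Independent brute-force oracles used to validate the implementations.
# Each oracle evaluates the defining formula directly, sharing no code
# with the functions under test.

# maximum global alignment score by exhaustive enumeration of all
# alignments (three-way recursion, no memoisation, no DP table)
nw_enumerate <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# per-node k-nearest-neighbour edges by sorting every pairwise distance,
# ties to the smaller node index
knn_brute <- function(coords, k) {
  n <- nrow(coords)
  kk <- min(k, n - 1L)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    cand <- setdiff(seq_len(n), i)
    cand <- cand[order(d[cand], cand)]
    edges <- rbind(edges, cbind(i, cand[seq_len(kk)]))
  }
  edges
}

rball_brute <- function(coords, cutoff) {
  n <- nrow(coords)
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
      edges <- rbind(edges, c(i, j))
  }
  edges
}

edge_key <- function(e) sort(paste(e[, 1], e[, 2]))

# Kendall tau-b by explicit pair counting
kendall_brute <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Spearman as Pearson on average ranks, ranks assigned by definition
spearman_brute <- function(x, y) {
  avg_rank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# AUROC by exhaustive positive-negative pair counting, ties = 1/2
auroc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# first rank loss by direct evaluation of its definition
frl_brute <- function(t) {
  tot <- 0; tids <- unique(t$target_id)
  for (tid in tids) {
    d <- t[t$target_id == tid, ]
    best_pred <- d$model_id[d$pred_score == max(d$pred_score)]
    top <- d[d$model_id == min(best_pred), ]
    tot <- tot + max(d$true_score) - top$true_score
  }
  tot / length(tids)
}

# random proper or improper rigid transform of row-vector coordinates
rigid_transform <- function(coords, reflect = FALSE) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if ((det(R) < 0) != reflect) R[, 1] <- -R[, 1]
  t <- stats::rnorm(3, sd = 10)
  sweep(coords %*% R, 2, -t)
}

# interface membership by explicit double loop
interface_brute <- function(rec, lig, cutoff) {
  ri <- integer(0); li <- integer(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
    if (sqrt(sum((rec[i, ] - lig[j, ])^2)) < cutoff) {
      ri <- c(ri, i); li <- c(li, j)
    }
  }
  list(rec = sort(unique(ri)), lig = sort(unique(li)))
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}
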