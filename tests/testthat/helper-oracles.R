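# Independent brute-force oracles used to validate the package's
# implementations on small inputs. Deliberately naive code paths.

# AUC by explicit pair enumeration (ties count 1/2).
auc_pairs <- function(pos, neg) {
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Spearman rho as rank-then-Pearson, Pearson written out by hand.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Mann-Whitney U and two-sided p by full enumeration of group assignments.
mw_oracle <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  U_obs <- sum(outer(x, y, FUN = function(a, b) (a > b) + 0.5 * (a == b)))
  combos <- utils::combn(length(pool), n1)
  Us <- apply(combos, 2L, function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, FUN = function(p, q) (p > q) + 0.5 * (p == q)))
  })
  eps <- 1e-9
  p <- min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
  list(W = U_obs, p = p)
}

# Multi-source grid cost distance by edge-list Bellman-Ford relaxation.
bf_cost_distance <- function(cost, src_idx) {
  nr <- nrow(cost); nc <- ncol(cost)
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(cost[r, c])) next
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(cost[r2, c2])) next
      w <- (cost[r, c] + cost[r2, c2]) / 2 * if (all(d != 0)) sqrt(2) else 1
      edges[[length(edges) + 1L]] <- c(r + (c - 1) * nr, r2 + (c2 - 1) * nr, w)
    }
  }
  E <- do.call(rbind, edges)
  dist <- rep(Inf, nr * nc)
  dist[src_idx] <- 0
  repeat {
    changed <- FALSE
    if (!is.null(E)) for (i in seq_len(nrow(E))) {
      a <- E[i, 1]; b <- E[i, 2]; w <- E[i, 3]
      if (dist[a] + w < dist[b] - 1e-12) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a] - 1e-12) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- matrix(dist, nr, nc)
  out[is.na(cost)] <- NA
  out
}

# Minimum within-class SSD over all contiguous partitions, by enumeration.
jenks_oracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_ub <- NULL
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (m in seq_len(k)) tot <- tot + ssd(x[(cuts[m] + 1):cuts[m + 1]])
    if (tot < best - 1e-12) { best <- tot; best_ub <- x[cuts[-1]] }
  }
  list(ssd = best, breaks = best_ub)
}

# Size of the maximum independent set of a conflict graph (exhaustive).
max_indep_size <- function(conflict) {
  n <- nrow(conflict)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    if (length(members) < 2 || !any(conflict[members, members])) {
      best <- length(members)
    }
  }
  best
}
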