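# Independent reference implementations used as oracles. They deliberately
# avoid the package's code paths: ranks by counting (no sort), HRR by a
# double loop over pairs, hypergeometric tails by enumeration, MCL by dense
# matrix-power flow simulation with a hand-rolled component search.

make_expr <- function(n, m, seed = 1, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("%s%04d", prefix, seq_len(n)),
                         sprintf("a%03d", seq_len(m))))
}

# rank of gene j in gene i's list by counting strictly-larger correlations,
# ties broken by ascending identifier
oracle_rank_row <- function(v, ids, i) {
  n <- length(v)
  out <- integer(n)
  for (j in seq_len(n)) {
    if (j == i) next
    larger <- sum(v[-i] > v[j])
    tie_first <- sum(v == v[j] & seq_len(n) != i & ids < ids[j])
    out[j] <- 1L + larger + tie_first
  }
  out
}

oracle_hrr <- function(x) {
  r <- stats::cor(t(x))
  n <- nrow(r)
  ids <- rownames(x)
  rk <- matrix(0L, n, n)
  for (i in seq_len(n)) rk[i, ] <- oracle_rank_row(r[i, ], ids, i)
  h <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      h[i, j] <- h[j, i] <- max(rk[i, j], rk[j, i])
    }
  }
  h
}

# exhaustive hypergeometric upper tail: probability that a uniformly random
# size-`draws` subset of `universe_size` elements hits >= `x` of the `k`
# marked ones
oracle_hyper_tail <- function(x, k, universe_size, draws) {
  sets <- utils::combn(universe_size, draws)
  mean(colSums(sets <= k) >= x)
}

# dense MCL flow simulation (no pruning), components by BFS
oracle_mcl_flow <- function(adj, inflation, self_loop, iter = 200) {
  n <- nrow(adj)
  diag(adj) <- self_loop
  m <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(iter)) {
    prev <- m
    m <- m %*% m
    m <- m^inflation
    m <- sweep(m, 2, colSums(m), "/")
    if (max(abs(m - prev)) < 1e-12) break
  }
  reach <- (m > 1e-9) | t(m > 1e-9)
  diag(reach) <- TRUE
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- which(colSums(reach[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  split(rownames(adj), comp)
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# small clique edge list helper
clique_edges <- function(ids, weight = 1) {
  pr <- utils::combn(ids, 2L)
  data.frame(probeset_a = pr[1L, ], probeset_b = pr[2L, ], weight = weight,
             stringsAsFactors = FALSE)
}

module_recovery_ari <- function(clustering, truth) {
  pred <- stats::setNames(rep(0L, length(truth)), names(truth))
  for (nm in names(clustering$clusters))
    pred[clustering$clusters[[nm]]] <- as.integer(nm)
  mod <- truth > 0
  adjusted_rand_index(truth[mod], pred[mod])
}
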