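# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Naive Lance-Williams agglomeration: clusters kept in a plain list, merged
# pairwise with explicit loops; returns the sequence of merged leaf sets
# (sorted) and merge heights. On tie-free inputs the merge sequence is
# unique, so tie policies do not matter.
naive_lance_williams <- function(D, linkage) {
  n <- nrow(D)
  sq <- linkage == "ward_d2"
  cur <- if (sq) D^2 else D
  members <- as.list(seq_len(n))
  sets <- list()
  heights <- numeric(0)
  while (length(members) > 1L) {
    m <- length(members)
    bi <- bj <- 0L; bd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (cur[i, j] < bd) { bd <- cur[i, j]; bi <- i; bj <- j }
    }
    ni <- length(members[[bi]]); nj <- length(members[[bj]])
    new_row <- numeric(m)
    for (k in seq_len(m)) {
      if (k == bi || k == bj) next
      nk <- length(members[[k]])
      co <- switch(linkage,
        single   = c(0.5, 0.5, 0, -0.5),
        complete = c(0.5, 0.5, 0, 0.5),
        average  = c(ni, nj, 0, 0) / c(ni + nj, ni + nj, 1, 1),
        median   = c(0.5, 0.5, -0.25, 0),
        centroid = c(ni / (ni + nj), nj / (ni + nj), -ni * nj / (ni + nj)^2, 0),
        ward_d   = ,
        ward_d2  = c(ni + nk, nj + nk, -nk, 0) / (ni + nj + nk))
      new_row[k] <- co[1] * cur[bi, k] + co[2] * cur[bj, k] + co[3] * bd +
        co[4] * abs(cur[bi, k] - cur[bj, k])
    }
    merged <- sort(c(members[[bi]], members[[bj]]))
    sets[[length(sets) + 1L]] <- merged
    heights <- c(heights, if (sq) sqrt(bd) else bd)
    keep <- setdiff(seq_len(m), c(bi, bj))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    members <- c(members[keep], list(merged))
  }
  list(sets = sets, heights = heights)
}

# Merge trace of an hclust-style dendrogram in the same shape as the oracle.
merge_trace <- function(dend) {
  n <- length(dend$order)
  members <- vector("list", n - 1L)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) -x else members[[x]]
    members[[s]] <- c(pick(dend$merge[s, 1L]), pick(dend$merge[s, 2L]))
    sets[[s]] <- sort(members[[s]])
  }
  list(sets = sets, heights = dend$height)
}

# Exact hypergeometric tails by exhaustive enumeration: successes are items
# 1..H of a population 1..N; all n-subsets are equally likely.
brute_hyper <- function(N, H, n, h, tail) {
  if (n == 0L) {
    overlaps <- 0L
  } else {
    subs <- utils::combn(N, n)
    overlaps <- colSums(subs <= H)
  }
  switch(tail,
         upper = mean(overlaps >= h),
         lower = mean(overlaps <= h),
         point = mean(overlaps == h))
}

# Random matrix with (almost surely) tie-free pairwise distances.
random_tiefree_matrix <- function(n_items, n_dims) {
  m <- matrix(stats::runif(n_items * n_dims, 0, 1000), nrow = n_items)
  rownames(m) <- sprintf("item%02d", seq_len(n_items))
  m
}

linkage_names <- c("complete", "single", "average", "median", "ward_d",
                   "ward_d2", "centroid")
metric_names <- c("euclidean", "manhattan", "minkowski", "maximum")
hclust_equivalent <- c(complete = "complete", single = "single",
                       average = "average", median = "median",
                       ward_d = "ward.D", ward_d2 = "ward.D2",
                       centroid = "centroid")
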