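# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, flood fill, dense eigensolvers)
# through code paths disjoint from the package implementation.

# Benjamini-Hochberg step-up by the definition: adj p(i) = min over j >= i of
# p(j) * m / j (on the sorted scale), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# lexicographic next-permutation enumeration (independent of the package's
# recursive generator)
oracle_all_perms <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}

# exact two-sided Spearman p by full enumeration, rho via stats::cor on ranks
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- oracle_all_perms(n)
  rhos <- apply(perms, 1, function(pm) cor(rx[pm], ry))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# flood-fill connected-component labeling over a CSR adjacency (1-based API)
oracle_flood_fill <- function(active, ptr, idx) {
  V <- length(active)
  lab <- integer(V)
  cur <- 0L
  for (v in which(active)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[[1L]]
      queue <- queue[-1L]
      if (lab[x] > 0L || !active[x]) next
      lab[x] <- cur
      nbrs <- if (ptr[x + 1L] > ptr[x]) idx[(ptr[x] + 1L):ptr[x + 1L]] + 1L
              else integer(0)
      queue <- c(queue, nbrs[active[nbrs] & lab[nbrs] == 0L])
    }
  }
  lab
}

# sessions x V white-noise stack over a given geometry
noise_stack <- function(geometry, days, id = "x", sd = 1, seed = 1) {
  set.seed(seed)
  V <- if (geometry$type == "volume") length(geometry$mask_idx)
       else geometry$n_vertices
  structure(list(individual_id = id, days = as.integer(days),
                 X = matrix(rnorm(length(days) * V, 0, sd), length(days), V),
                 geometry = geometry),
            class = "session_stack")
}

# small deterministic stack from an explicit matrix
stack_from_matrix <- function(X, geometry, id = "x", days = seq_len(nrow(X))) {
  structure(list(individual_id = id, days = as.integer(days), X = X,
                 geometry = geometry), class = "session_stack")
}

tiny_geometry <- function(shape = c(8L, 8L, 8L)) make_phantom_mask(shape, 2)
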