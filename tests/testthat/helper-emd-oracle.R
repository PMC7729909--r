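# Independent earth-mover's-distance oracle: generic minimum-cost transport
# solved by successive shortest paths on the residual network. Shares no code
# with hierarchical_emd(), which uses the recursive tree formula.

min_cost_transport <- function(p, q, D) {
  stopifnot(length(p) == nrow(D), length(q) == ncol(D))
  m <- length(p); n <- length(q)
  N <- m + n + 2L; S <- 1L; T <- N
  cap <- matrix(0, N, N)
  cst <- matrix(0, N, N)
  cap[S, 1L + seq_len(m)] <- p
  cap[m + 1L + seq_len(n), T] <- q
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cap[1L + i, m + 1L + j] <- Inf
      cst[1L + i, m + 1L + j] <- D[i, j]
      cst[m + 1L + j, 1L + i] <- -D[i, j]
    }
  }
  total <- 0
  repeat {
    dist <- rep(Inf, N); dist[S] <- 0
    prev <- rep(NA_integer_, N)
    for (pass in seq_len(N)) {
      changed <- FALSE
      for (u in seq_len(N)) {
        if (!is.finite(dist[u])) next
        for (v in seq_len(N)) {
          if (cap[u, v] > 1e-12 && dist[u] + cst[u, v] < dist[v] - 1e-15) {
            dist[v] <- dist[u] + cst[u, v]
            prev[v] <- u
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[T])) break
    path <- integer(0L); v <- T
    while (v != S) { path <- c(v, path); v <- prev[v] }
    path <- c(S, path)
    bottleneck <- min(cap[cbind(path[-length(path)], path[-1L])])
    if (bottleneck < 1e-12) break
    for (e in seq_len(length(path) - 1L)) {
      u <- path[e]; v <- path[e + 1L]
      cap[u, v] <- cap[u, v] - bottleneck
      cap[v, u] <- cap[v, u] + bottleneck
      total <- total + bottleneck * cst[u, v]
    }
  }
  total
}

# Ground distance matrix over a hierarchy's leaves: height(LCA)/H.
hierarchy_ground_distance <- function(h) {
  leaves <- names(h$paths)
  H <- h$height
  full <- lapply(leaves, function(l) c(h$paths[[l]], l))
  D <- matrix(0, length(leaves), length(leaves), dimnames = list(leaves, leaves))
  for (i in seq_along(leaves)) {
    for (j in seq_along(leaves)) {
      if (i == j) next
      common <- 0L
      while (common < H && full[[i]][common + 1L] == full[[j]][common + 1L]) {
        common <- common + 1L
      }
      D[i, j] <- (H - common) / H
    }
  }
  D
}

emd_oracle <- function(p, q, h) {
  leaves <- names(h$paths)
  min_cost_transport(as.numeric(p[leaves]), as.numeric(q[leaves]),
                     hierarchy_ground_distance(h))
}

# Random balanced hierarchy with <= max_leaves leaves; labels chosen from a
# small alphabet so branches merge by shared path prefixes.
random_hierarchy <- function(max_leaves = 6L, max_height = 3L) {
  n_leaves <- sample(2:max_leaves, 1L)
  H <- sample(seq_len(max_height), 1L)
  leaves <- paste0("v", seq_len(n_leaves))
  paths <- lapply(leaves, function(l) {
    if (H == 1L) character(0L) else
      vapply(seq_len(H - 1L), function(d) sample(c("x", "y"), 1L), character(1L))
  })
  names(paths) <- leaves
  hierarchy("rand", paths)
}

random_distribution <- function(leaves, sparse = FALSE) {
  w <- stats::rexp(length(leaves))
  if (sparse && length(leaves) > 2L) {
    zero <- sample(seq_along(leaves), sample.int(length(leaves) - 2L, 1L))
    w[zero] <- 0
  }
  stats::setNames(w / sum(w), leaves)
}
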