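# Straight-line brute-force re-implementation of the seed/expand/merge
# mining procedure, written independently of the package code (explicit
# loops, no shared helpers). Used as the oracle for equivalence testing on
# small networks.

oracle_density <- function(w, set) {
  if (length(set) < 2) return(NA_real_)
  s <- 0
  for (x in 1:(length(set) - 1))
    for (y in (x + 1):length(set))
      s <- s + w[set[x], set[y]]
  s / (length(set) * (length(set) - 1) / 2)
}

oracle_lmqcm <- function(net, gamma, lambda = 1, tt = 1, beta = 0.4,
                         min_size = 3) {
  w <- net$weights
  ids <- rownames(w)
  n <- length(ids)

  # --- seeds: edges at least gamma with no strictly heavier incident edge
  seed_i <- character(0); seed_j <- character(0); seed_w <- numeric(0)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      wab <- w[a, b]
      if (wab < gamma) next
      ok <- TRUE
      for (k in 1:n) {
        if (w[a, k] > wab || w[b, k] > wab) { ok <- FALSE; break }
      }
      if (!ok) next
      pair <- sort(c(ids[a], ids[b]), method = "radix")
      seed_i <- c(seed_i, pair[1]); seed_j <- c(seed_j, pair[2])
      seed_w <- c(seed_w, wab)
    }
  }
  o <- order(-seed_w, seed_i, seed_j, method = "radix")
  seed_i <- seed_i[o]; seed_j <- seed_j[o]

  # --- expansion
  clusters <- list()
  for (s in seq_along(seed_i)) {
    C <- c(seed_i[s], seed_j[s])
    repeat {
      outside <- setdiff(ids, C)
      if (!length(outside)) break
      gains <- vapply(outside, function(v) sum(w[v, C]), numeric(1))
      cand <- outside[gains == max(gains)]
      v <- sort(cand, method = "radix")[1]
      alpha <- 1 - 1 / (2 * lambda * (length(C) + tt))
      if (oracle_density(w, c(C, v)) >= alpha * oracle_density(w, C)) {
        C <- c(C, v)
      } else break
    }
    clusters[[length(clusters) + 1]] <- sort(C, method = "radix")
  }

  # --- merge
  clusters <- clusters[vapply(clusters, length, 1L) >= 3]
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  clusters <- clusters[!duplicated(keys)]
  sort_clusters <- function(cl) {
    keys <- vapply(cl, paste, character(1), collapse = "\r")
    cl[order(-vapply(cl, length, 1L), keys, method = "radix")]
  }
  repeat {
    clusters <- sort_clusters(clusters)
    merged <- FALSE
    if (length(clusters) >= 2) {
      for (i in 1:(length(clusters) - 1)) {
        for (j in (i + 1):length(clusters)) {
          ov <- length(intersect(clusters[[i]], clusters[[j]]))
          if (ov / min(length(clusters[[i]]), length(clusters[[j]])) > beta) {
            clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]),
                                  method = "radix")
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  clusters <- clusters[vapply(clusters, length, 1L) >= min_size]
  sort_clusters(clusters)
}

# The package-side counterpart on a raw network (seed -> expand -> merge),
# returning the plain list of modules for comparison.
package_lmqcm <- function(net, gamma, lambda = 1, tt = 1, beta = 0.4,
                          min_size = 3) {
  params <- lmqcm_params(gamma = gamma, lambda = lambda, t = tt,
                         beta = beta, min_size = min_size)
  seeds <- find_local_max_edges(net, gamma)
  clusters <- lapply(seq_len(nrow(seeds)), function(k)
    as.character(expand_quasi_clique(net, c(seeds$gene_i[k],
                                            seeds$gene_j[k]), params)))
  ms <- merge_modules(clusters, beta = beta, min_size = min_size,
                      params = params)
  unname(ms$modules)
}

# Best Jaccard overlap of a reference gene set against mined modules.
best_jaccard <- function(reference, modules) {
  if (!length(modules$modules)) return(0)
  max(vapply(modules$modules, function(m)
    length(intersect(m, reference)) / length(union(m, reference)),
    numeric(1)))
}
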