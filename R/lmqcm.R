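#' lmQCM mining parameters
#'
#' Parameters of the local maximum Quasi-Clique Merger heuristic. `gamma`
#' is the minimum weight for a seed edge; during expansion a vertex is
#' admitted while the quasi-clique density stays above
#' `alpha_n = 1 - 1/(2 * lambda * (|C| + t))` times the current density;
#' clusters whose overlap ratio exceeds `beta` are merged; modules smaller
#' than `min_size` are not reported. The defaults (gamma 0.7, lambda 1,
#' t 1, beta 0.4, min_size 10, absolute Spearman weights, no degree
#' normalisation) are the reference lmQCM settings used for microarray
#' co-expression mining.
#'
#' @param gamma Seed-edge weight threshold in (0, 1].
#' @param lambda Expansion laxity, > 0.
#' @param t Expansion offset, >= 0.
#' @param beta Merge overlap ratio in (0, 1].
#' @param min_size Minimum reported module size (genes).
#' @param corr Correlation used for edge weights, `"spearman"` (default)
#'   or `"pearson"`.
#' @param absolute Use `|rho|` as the edge weight (default); otherwise
#'   negative correlations are clamped to zero.
#' @param normalize_weights Apply the degree normalisation
#'   `w_ij / sqrt(d_i d_j)` before mining (off by default).
#' @return A list of class `lmqcm_params`.
#' @export
lmqcm_params <- function(gamma = 0.7, lambda = 1, t = 1, beta = 0.4,
                         min_size = 10, corr = c("spearman", "pearson"),
                         absolute = TRUE, normalize_weights = FALSE) {
  corr <- match.arg(corr)
  stopifnot(gamma > 0, gamma <= 1, lambda > 0, t >= 0,
            beta > 0, beta <= 1, min_size >= 1)
  structure(list(gamma = gamma, lambda = lambda, t = t, beta = beta,
                 min_size = as.integer(min_size), corr = corr,
                 absolute = isTRUE(absolute),
                 normalize_weights = isTRUE(normalize_weights)),
            class = "lmqcm_params")
}

#' Build a weighted gene co-expression network
#'
#' Edge weights are correlation coefficients between gene expression
#' profiles: `|rho|` when `absolute = TRUE`, else `max(rho, 0)`. Genes with
#' constant expression get weight 0 to all partners (with a warning). The
#' diagonal is zero.
#'
#' @param expr A gene-level [expression_matrix()] with >= 3 samples.
#' @param method `"spearman"` (rank correlation, default) or `"pearson"`.
#' @param absolute Use absolute correlation as the weight.
#' @return An object of class `gene_network`: list with `weights` (dense
#'   symmetric matrix in `[0, 1]`, zero diagonal, gene ids as dimnames).
#' @export
build_weight_network <- function(expr, method = c("spearman", "pearson"),
                                 absolute = TRUE) {
  method <- match.arg(method)
  v <- expr$values
  if (ncol(v) < 3L) stop("need at least 3 samples for rank correlation")
  if (nrow(v) < 2L) stop("need at least 2 genes")
  rho <- suppressWarnings(cor(t(v), method = method))
  const <- apply(v, 1, function(r) all(r == r[1]))
  if (any(const)) {
    warning(sum(const), " constant gene(s) assigned zero weight")
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  w <- if (absolute) abs(rho) else pmax(rho, 0)
  diag(w) <- 0
  w[w > 1] <- 1  # guard against rounding just above 1
  structure(list(weights = w), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, mean off-diagonal weight %.3f\n",
              nrow(x$weights),
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

# Degree normalisation w_ij / sqrt(d_i d_j); isolated vertices keep 0.
normalize_network <- function(net) {
  w <- net$weights
  d <- rowSums(w)
  d[d == 0] <- 1
  w <- w / sqrt(outer(d, d))
  diag(w) <- 0
  structure(list(weights = w), class = "gene_network")
}

#' Find locally maximal seed edges
#'
#' An edge (i, j) seeds a quasi-clique iff no edge incident to i or j is
#' strictly heavier and its weight is at least `gamma`. Seeds are returned
#' sorted by weight descending, ties by the lexicographic endpoint pair.
#'
#' @param net A `gene_network`.
#' @param gamma Seed weight threshold.
#' @return data.frame with columns `gene_i`, `gene_j` (lexicographically
#'   ordered within each pair) and `weight`.
#' @export
find_local_max_edges <- function(net, gamma = 0.7) {
  w <- net$weights
  ids <- rownames(w)
  row_max <- apply(w, 1, max)
  cand <- which(upper.tri(w) & w >= gamma &
                  w >= row_max[row(w)] & w >= row_max[col(w)],
                arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(gene_i = character(), gene_j = character(),
                      weight = numeric()))
  a <- ids[cand[, 1]]; b <- ids[cand[, 2]]
  swap <- b < a
  gi <- ifelse(swap, b, a)
  gj <- ifelse(swap, a, b)
  wt <- w[cand]
  o <- lex_order(-wt, gi, gj)
  data.frame(gene_i = gi[o], gene_j = gj[o], weight = wt[o])
}

#' Grow a quasi-clique from a seed edge
#'
#' Starting from the seed pair, the candidate maximising the total weight
#' to the current set (ties: lexicographically smallest gene id) is tested;
#' it is admitted iff the density after addition is at least
#' `alpha_n * density(C)` with `alpha_n = 1 - 1/(2 lambda (|C| + t))`.
#' Expansion stops at the first rejection. Density of a set is the sum of
#' pairwise weights over the number of vertex pairs.
#'
#' @param net A `gene_network`.
#' @param seed_edge Character vector of the two seed gene ids.
#' @param params An [lmqcm_params()] object.
#' @return Character vector of member gene ids in accretion order, with an
#'   attribute `"trace"`: data.frame (gene, size, density, alpha, admitted)
#'   recording every admission decision.
#' @export
expand_quasi_clique <- function(net, seed_edge, params = lmqcm_params()) {
  w <- net$weights
  ids <- rownames(w)
  seed_edge <- as.character(seed_edge)
  if (!all(seed_edge %in% ids)) stop("seed genes not in network")
  members <- match(seed_edge, ids)
  in_set <- logical(length(ids))
  in_set[members] <- TRUE
  gain <- w[, members[1]] + w[, members[2]]
  sum_w <- w[members[1], members[2]]
  tr_gene <- ids[members]; tr_size <- c(1L, 2L)
  tr_density <- c(NA_real_, sum_w); tr_alpha <- c(NA_real_, NA_real_)
  tr_admitted <- c(TRUE, TRUE)
  repeat {
    k <- length(members)
    cand_gain <- gain
    cand_gain[in_set] <- -Inf
    best <- max(cand_gain)
    if (!is.finite(best)) break
    hits <- which(cand_gain == best)
    v <- if (length(hits) == 1L) hits else hits[lex_order(ids[hits])[1]]
    dens <- sum_w / (k * (k - 1) / 2)
    dens_new <- (sum_w + gain[v]) / ((k + 1) * k / 2)
    alpha <- 1 - 1 / (2 * params$lambda * (k + params$t))
    admitted <- dens_new >= alpha * dens
    tr_gene <- c(tr_gene, ids[v]); tr_size <- c(tr_size, k + 1L)
    tr_density <- c(tr_density, dens_new); tr_alpha <- c(tr_alpha, alpha)
    tr_admitted <- c(tr_admitted, admitted)
    if (!admitted) break
    in_set[v] <- TRUE
    sum_w <- sum_w + gain[v]
    gain <- gain + w[, v]
    members <- c(members, v)
  }
  structure(ids[members],
            trace = data.frame(gene = tr_gene, size = tr_size,
                               density = tr_density, alpha = tr_alpha,
                               admitted = tr_admitted))
}

# Deterministic cluster ordering: size descending, ties by the
# lexicographic sequence of (sorted) member ids.
order_clusters <- function(clusters) {
  key <- vapply(clusters, function(g) paste(lex_sort(g), collapse = "\r"),
                character(1))
  lex_order(-lengths(clusters), key)
}

#' Merge overlapping quasi-cliques into modules
#'
#' Clusters with fewer than 3 genes are discarded. Remaining clusters are
#' scanned largest-first and a pair is merged whenever
#' `|intersection| / min(sizes) > beta`; scanning restarts until no merge
#' fires. Modules smaller than `min_size` are then dropped and the result
#' sorted by size descending (ties by first gene id).
#'
#' @param clusters List of character vectors (gene sets).
#' @param beta Overlap ratio threshold.
#' @param min_size Minimum reported module size.
#' @param params Optional [lmqcm_params()] recorded in the result.
#' @return A `module_set`: list with `modules` (named list of
#'   lexicographically sorted gene vectors, names `M1`, `M2`, ...),
#'   `params`, and `provenance`.
#' @export
merge_modules <- function(clusters, beta = 0.4, min_size = 10,
                          params = NULL) {
  clusters <- lapply(clusters, function(g) lex_sort(unique(as.character(g))))
  clusters <- clusters[lengths(clusters) >= 3L]
  clusters <- clusters[!duplicated(vapply(clusters, paste, character(1),
                                          collapse = "\r"))]
  repeat {
    clusters <- clusters[order_clusters(clusters)]
    merged <- FALSE
    n <- length(clusters)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          ov <- length(intersect(clusters[[i]], clusters[[j]]))
          if (ov / min(length(clusters[[i]]), length(clusters[[j]])) > beta) {
            clusters[[i]] <- lex_sort(union(clusters[[i]], clusters[[j]]))
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
  clusters <- clusters[lengths(clusters) >= min_size]
  clusters <- clusters[order_clusters(clusters)]
  names(clusters) <- if (length(clusters)) paste0("M", seq_along(clusters)) else NULL
  structure(list(modules = clusters, params = params, provenance = NULL),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules", length(x$modules)))
  if (length(x$modules))
    cat(sprintf(" (sizes %s)", paste(lengths(x$modules), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Coerce a list of gene sets to a module_set
#'
#' Convenience constructor used to feed externally defined (for example
#' planted) modules into downstream analyses. Modules keep the given order
#' if named, otherwise they are sorted by size descending.
#'
#' @param x Named or unnamed list of character vectors.
#' @return A `module_set`.
#' @export
as_module_set <- function(x) {
  x <- lapply(x, function(g) lex_sort(unique(as.character(g))))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    x <- x[order_clusters(x)]
    names(x) <- paste0("M", seq_along(x))
  }
  structure(list(modules = x, params = NULL, provenance = NULL),
            class = "module_set")
}

#' Mine co-expression modules with lmQCM
#'
#' Composition of [build_weight_network()], [find_local_max_edges()],
#' [expand_quasi_clique()] for every seed, and [merge_modules()]. Fully
#' deterministic given the input matrix and parameters.
#'
#' @param expr A preprocessed gene-level [expression_matrix()].
#' @param params An [lmqcm_params()] object.
#' @return A `module_set` whose `provenance` records the input shape and
#'   seed edges, and with attribute `"traces"`: one accretion trace per
#'   expanded seed (see [expand_quasi_clique()]).
#' @export
mine_modules <- function(expr, params = lmqcm_params()) {
  net <- build_weight_network(expr, method = params$corr,
                              absolute = params$absolute)
  if (params$normalize_weights) net <- normalize_network(net)
  seeds <- find_local_max_edges(net, params$gamma)
  clusters <- vector("list", nrow(seeds))
  traces <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    cl <- expand_quasi_clique(net, c(seeds$gene_i[k], seeds$gene_j[k]), params)
    traces[[k]] <- attr(cl, "trace")
    clusters[[k]] <- as.character(cl)
  }
  ms <- merge_modules(clusters, beta = params$beta,
                      min_size = params$min_size, params = params)
  ms$provenance <- list(n_genes = nrow(expr$values),
                        n_samples = ncol(expr$values),
                        feature_kind = expr$feature_kind,
                        seeds = seeds)
  attr(ms, "traces") <- traces
  ms
}

#' Write modules as TSV (module_id, size, comma-separated genes)
#'
#' @param modules A `module_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  lines <- c("module_id\tsize\tgenes",
             vapply(seq_along(modules$modules), function(i) {
               g <- modules$modules[[i]]
               paste(names(modules$modules)[i], length(g),
                     paste(g, collapse = ","), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export the network edge list (gene_i, gene_j, weight)
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @param min_weight Only edges at or above this weight are written.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, min_weight = 0) {
  w <- net$weights
  ids <- rownames(w)
  keep <- which(upper.tri(w) & w >= min_weight, arr.ind = TRUE)
  df <- data.frame(gene_i = ids[keep[, 1]], gene_j = ids[keep[, 2]],
                   weight = w[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
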