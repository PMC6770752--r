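# Small builders shared across test files.

# Expression matrix from a plain matrix, adding default dimnames.
make_expr <- function(values, feature_kind = "gene",
                      features = NULL, samples = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- features %||% sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, feature_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric weighted network from an edge list given as a named vector
# like c("a|b" = 0.9, "b|c" = 0.8); absent edges weigh 0.
make_network <- function(edges, ids = NULL) {
  pairs <- strsplit(names(edges), "|", fixed = TRUE)
  if (is.null(ids))
    ids <- sort(unique(unlist(pairs)), method = "radix")
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_along(edges)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    w[i, j] <- w[j, i] <- edges[[k]]
  }
  structure(list(weights = w), class = "gene_network")
}

# Random symmetric weight matrix in [0,1] with zero diagonal.
random_network <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  structure(list(weights = w), class = "gene_network")
}

# A quick two-group annotation for a set of samples.
make_annotation <- function(samples, groups) {
  data.frame(sample_id = samples, fusion_group = groups)
}

# A small synthetic spec used where the full default would be overkill.
small_spec <- function(...) {
  args <- list(n_genes = 120,
               n_samples = c(negative = 10, PAX3 = 8, PAX7 = 4),
               module_sizes = c(20, 15), delta = c(2, 0),
               probe_counts = 1:2, probe_probs = c(0.6, 0.4),
               cnv_module = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}
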