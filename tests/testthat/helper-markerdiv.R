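# Shared fixture builders and independent oracles.

make_bands <- function(n, system = "RAPD") {
  data.frame(system = system,
             primer = sprintf("%s-T%03d", system, seq_len(n)),
             size = 100L + 10L * seq_len(n))
}

make_matrix <- function(values, system = "RAPD", ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(values)))
  rownames(values) <- ids
  marker_matrix(values, make_bands(ncol(values), system))
}

make_table <- function(ids, populations, types = "invasive") {
  data.frame(sample_id = ids, population = populations,
             population_type = rep_len(types, length(ids)))
}

random_matrix <- function(n_samples, n_bands, p = 0.5, system = "RAPD") {
  make_matrix(matrix(rbinom(n_samples * n_bands, 1, p), n_samples), system)
}

# independent Nei-Li oracle: literal count of the three band classes
nei_li_oracle <- function(x, y) {
  nx <- sum(x == 1)
  ny <- sum(y == 1)
  nxy <- sum(x == 1 & y == 1)
  if (nx + ny == 0) return(0)
  1 - 2 * nxy / (nx + ny)
}

# independent pairwise oracle: explicit double loop
pairwise_oracle <- function(v) {
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- nei_li_oracle(v[i, ], v[j, ])
    }
  }
  d
}

# random strictly-positive distance matrix with continuous entries
# (ties have probability zero)
random_dist <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}

leaf_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}
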