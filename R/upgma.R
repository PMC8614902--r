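#' UPGMA dendrogram from a Gd matrix
#'
#' Agglomerative average-linkage clustering: at every step the pair of
#' clusters with the smallest mean cross-pair distance merges at a node of
#' height d/2, so branch lengths are in Gd units and every leaf is
#' equidistant from the root (an ultrametric tree). The cluster-update is
#' the size-weighted (arithmetic-mean-over-all-pairs) rule. When two pairs
#' tie exactly at the minimal distance, the pair whose sorted pair of
#' smallest member labels is lexicographically first merges, so the result
#' is deterministic.
#'
#' @param dm labelled symmetric dissimilarity matrix (zero diagonal,
#'   non-negative entries), at least 2 labels.
#' @return a rooted, ultrametric `phylo` tree (package \pkg{ape}) with
#'   branch lengths.
#' @examples
#' dm <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(dm))
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || is.null(rownames(dm))) {
    stop("need a labelled square matrix")
  }
  if (any(abs(dm - t(dm)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(dm < 0)) stop("negative distances are not allowed")
  if (any(grepl("[][();,:' ]", rownames(dm)))) {
    stop("labels contain characters reserved by the Newick format")
  }
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 labels")
  labs <- rownames(dm)
  D <- dm
  dimnames(D) <- NULL
  frag <- labs                    # Newick fragment per active cluster
  height <- numeric(n)            # current node height per cluster
  size <- rep(1L, n)
  minlab <- labs                  # smallest member label, for tie-breaks
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[b]; j <- idx[a]
        d <- D[i, j]
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        } else if (d == best_d) {
          k1 <- sort(c(minlab[i], minlab[j]))
          k2 <- sort(c(minlab[best[1]], minlab[best[2]]))
          if (k1[1] < k2[1] || (k1[1] == k2[1] && k1[2] < k2[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    # children ordered by smallest member label, for a canonical layout
    first <- if (minlab[i] <= minlab[j]) c(i, j) else c(j, i)
    frag[i] <- sprintf("(%s:%s,%s:%s)",
                       frag[first[1]], format(h - height[first[1]], digits = 15),
                       frag[first[2]], format(h - height[first[2]], digits = 15))
    height[i] <- h
    # size-weighted average linkage update
    others <- setdiff(idx, c(i, j))
    D[i, others] <- (size[i] * D[i, others] + size[j] * D[j, others]) /
      (size[i] + size[j])
    D[others, i] <- D[i, others]
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    active[j] <- FALSE
  }
  ape::read.tree(text = paste0(frag[which(active)], ";"))
}

#' Serialize a tree to Newick
#'
#' Branch lengths are kept; internal node labels (bootstrap supports, when
#' present) are written as standard internal Newick labels. Reading the
#' string back with [ape::read.tree()] reproduces the tree.
#'
#' @param tree a `phylo` object.
#' @param path optional file to write to; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly, when writing to a file).
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Canonical key of one rooted clade, as the side of the induced leaf
# bipartition NOT containing the reference leaf (the alphabetically first
# label). Returns NA for trivial sides (empty or single-leaf complement of
# the full set is kept: a clade of n-1 leaves maps to a 1-leaf side, which
# is still an internal edge of the rooted tree).
canonical_bipartition <- function(clade_labels, all_labels) {
  ref <- sort(all_labels)[1]
  side <- if (ref %in% clade_labels) setdiff(all_labels, clade_labels) else
    clade_labels
  if (length(side) == 0L || length(side) == length(all_labels)) {
    return(NA_character_)
  }
  paste(sort(side), collapse = "|")
}

# clade keys for every internal node, in node-number order
node_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  vapply(parts, function(idx) canonical_bipartition(labs[idx], labs),
         character(1))
}

#' Leaf bipartitions induced by a tree's internal edges
#'
#' Each internal node of the rooted tree defines a split of the leaf set;
#' splits are canonicalized as the side not containing the alphabetically
#' first leaf and returned as a set (duplicates and the trivial root split
#' removed). A two-leaf tree has no informative internal edge and yields
#' an empty set.
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical bipartition keys, each the sorted
#'   labels of one side joined with `|`.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  keys <- node_bipartitions(tree)
  sort(unique(keys[!is.na(keys)]))
}

#' UPGMA tree with character-resampling bootstrap support
#'
#' Builds the observed tree from the full matrix (per-unit consensus
#' profiles -> Nei-Li Gd -> UPGMA when `table` is given; individual
#' profiles -> Gd -> UPGMA when it is `NULL`), then resamples band
#' columns with replacement — the same number of columns, stratified by
#' marker system so a combined RAPD+ISSR+REMAP matrix keeps its
#' composition — rebuilds the whole chain `replicates` times, and
#' annotates each internal node of the observed tree with the percentage
#' of replicate trees containing the same leaf bipartition. The root node,
#' whose bipartition is trivial, is left unannotated.
#'
#' @inheritParams between_population_gd
#' @param table a sample table, or `NULL` to build an individual-level
#'   tree whose leaves are the samples themselves.
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling; the same seed always
#'   yields the same annotated tree.
#' @return a `phylo` tree whose `node.label` holds integer support
#'   percentages (`""` on the root).
#' @export
bootstrap_support <- function(x, table = NULL, units = NULL,
                              replicates = 100, seed = 20211025,
                              tie = c("absent", "present")) {
  tie <- match.arg(tie)
  validate_marker_matrix(x)
  if (replicates < 1) stop("replicates must be >= 1")
  V <- x$values
  if (is.null(table)) {
    rows_of <- as.list(seq_len(nrow(V)))
    names(rows_of) <- rownames(V)
  } else {
    validate_sample_table(table, x)
    units <- resolve_units(table, units)
    pop_of <- table$population[match(rownames(V), table$sample_id)]
    rows_of <- lapply(units, function(pops) which(pop_of %in% pops))
    empty <- names(units)[lengths(rows_of) == 0L]
    if (length(empty)) stop("unit with no samples: ", paste(empty, collapse = ", "))
  }
  # the whole chain, on a plain values matrix so bootstrap replicates
  # (which duplicate band columns by construction) need no re-validation
  build <- function(v) {
    prof <- do.call(rbind, lapply(rows_of, function(r) {
      consensus_profile(v[r, , drop = FALSE], tie = tie)
    }))
    upgma(suppressWarnings(pairwise_gd(prof)))
  }
  observed <- build(V)
  obs_keys <- node_bipartitions(observed)
  counts <- integer(length(obs_keys))
  groups <- split(seq_len(ncol(V)), x$bands$system)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- unlist(lapply(groups, function(g) {
      g[sample.int(length(g), length(g), replace = TRUE)]
    }), use.names = FALSE)
    keys <- tree_bipartitions(build(V[, cols, drop = FALSE]))
    counts <- counts + (obs_keys %in% keys)
  }
  support <- round(100 * counts / replicates)
  support[is.na(obs_keys)] <- NA_integer_
  observed$node.label <- ifelse(is.na(support), "", as.character(support))
  observed
}
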