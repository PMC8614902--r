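#' Nei-Li genetic diversity between two binary band profiles
#'
#' The band-sharing dissimilarity
#' \deqn{Gd = 1 - \frac{2 N_{xy}}{N_x + N_y}}
#' where \eqn{N_x} and \eqn{N_y} are the numbers of bands present in each
#' profile and \eqn{N_{xy}} the number present in both. `Gd` lies in
#' \eqn{[0, 1]}: 0 exactly when the two presence sets coincide, 1 when
#' they are disjoint. The degenerate pair of two all-absent profiles has
#' identical (empty) presence sets and is scored 0, with a warning.
#'
#' @param x,y binary vectors (0/1 or logical) of equal length, one element
#'   per scored band.
#' @return a single number in `[0, 1]`.
#' @examples
#' nei_li(c(1, 1, 0, 1), c(1, 0, 1, 1)) # 1 - 4/6
#' @export
nei_li <- function(x, y) {
  if (length(x) != length(y)) {
    stop("profiles differ in length: ", length(x), " vs ", length(y))
  }
  x <- as.integer(x)
  y <- as.integer(y)
  if (any(!(c(x, y) %in% c(0L, 1L)))) stop("profiles must be binary (0/1)")
  nx <- sum(x)
  ny <- sum(y)
  if (nx + ny == 0L) {
    warning("both profiles are all-zero; Gd defined as 0")
    return(0)
  }
  1 - 2 * sum(x & y) / (nx + ny)
}

#' All pairwise Nei-Li diversities between samples
#'
#' @param x a `marker_matrix` (or a plain binary matrix with row names).
#' @return a symmetric numeric matrix with zero diagonal, labelled by
#'   sample id; entry (i, j) is [nei_li()] of rows i and j.
#' @export
pairwise_gd <- function(x) {
  v <- if (inherits(x, "marker_matrix")) x$values else as.matrix(x)
  if (nrow(v) < 2L) stop("need at least 2 samples for a distance matrix")
  storage.mode(v) <- "double"
  shared <- v %*% t(v)                 # Nxy for every pair
  n <- rowSums(v)                      # Nx per sample
  tot <- outer(n, n, `+`)
  d <- 1 - 2 * shared / tot
  if (any(tot == 0)) {
    warning("all-zero profile pair(s); Gd defined as 0")
    d[tot == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

#' Validate a labelled Gd distance matrix
#'
#' @param dm square numeric matrix.
#' @param tol numeric tolerance for the symmetry and diagonal checks.
#' @return `dm` with symmetrized rounding noise removed, or an error.
#' @export
validate_gd_matrix <- function(dm, tol = 1e-8) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must be labelled")
  if (any(abs(dm - t(dm)) > tol)) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > tol)) stop("distance matrix diagonal is not zero")
  if (any(dm < -tol) || any(dm > 1 + tol)) {
    stop("Gd entries must lie in [0, 1]")
  }
  colnames(dm) <- rownames(dm)
  (dm + t(dm)) / 2
}

#' Majority-rule consensus profile of a set of samples
#'
#' The population-level binary profile used to compare whole populations:
#' band j is scored present when more than half of the samples carry it.
#' A band carried by exactly half of an even-sized sample set is a tie;
#' by default it is scored absent (the conservative choice), but
#' `tie = "present"` scores it present instead.
#'
#' @param x a `marker_matrix` (or plain binary matrix) whose rows are the
#'   samples to summarize.
#' @param tie `"absent"` (default) or `"present"`: the state assigned to
#'   a band present in exactly half of the samples.
#' @return integer 0/1 vector, one element per band, named by band id.
#' @export
consensus_profile <- function(x, tie = c("absent", "present")) {
  tie <- match.arg(tie)
  v <- if (inherits(x, "marker_matrix")) x$values else as.matrix(x)
  counts <- colSums(v)
  half <- nrow(v) / 2
  out <- if (tie == "absent") as.integer(counts > half) else
    as.integer(counts >= half)
  names(out) <- colnames(v)
  out
}

# Resolve a units spec into a named list of population-name vectors.
# `units` may be NULL (one unit per population), a character vector of
# population names, or a named list whose elements are vectors of
# populations to pool (e.g. list(invasive = c("Moscow", "Kaluga"))).
resolve_units <- function(table, units = NULL) {
  pops <- unique(table$population)
  if (is.null(units)) {
    units <- as.list(pops)
    names(units) <- pops
  } else if (is.character(units)) {
    nm <- units
    units <- as.list(units)
    names(units) <- nm
  }
  if (is.null(names(units)) || any(names(units) == "")) {
    stop("pooled units must be named")
  }
  unknown <- setdiff(unlist(units), pops)
  if (length(unknown)) {
    stop("unknown population: ", paste(unknown, collapse = ", "))
  }
  units
}

#' Nei-Li diversity between population consensus profiles
#'
#' For each analysis unit (a population, or a named pool of populations)
#' the samples are reduced to a majority-rule consensus profile, and
#' [nei_li()] is computed between every pair of consensus profiles. This
#' is the between-population diversity matrix from which population-level
#' dendrograms are built.
#'
#' @param x a `marker_matrix`.
#' @param table a sample table covering the matrix samples.
#' @param units `NULL` (each population is a unit), a character vector of
#'   population names, or a named list of population vectors defining
#'   pooled units.
#' @inheritParams consensus_profile
#' @return symmetric Gd matrix labelled by unit name.
#' @export
between_population_gd <- function(x, table, units = NULL,
                                  tie = c("absent", "present")) {
  tie <- match.arg(tie)
  validate_marker_matrix(x)
  units <- resolve_units(table, units)
  if (length(units) < 2L) stop("need at least 2 units")
  profiles <- vapply(units, function(pops) {
    consensus_profile(subset_populations(x, table, pops), tie = tie)
  }, integer(ncol(x$values)))
  pairwise_gd(t(profiles))
}

#' Within-unit diversity summary
#'
#' Minimum, mean and maximum Nei-Li diversity over all k(k-1)/2 sample
#' pairs within one analysis unit (a population or a pool of
#' populations).
#'
#' @inheritParams between_population_gd
#' @param unit character vector of population names forming the unit.
#' @param name label for the unit in the output; defaults to the
#'   populations pasted with `+`.
#' @return one-row data frame with columns `unit`, `n_samples`, `n_pairs`,
#'   `min_gd`, `mean_gd`, `max_gd`.
#' @export
within_population_gd <- function(x, table, unit, name = NULL) {
  if (is.null(name)) name <- paste(unit, collapse = "+")
  sub <- subset_populations(x, table, unit)
  k <- nrow(sub$values)
  if (k < 2L) {
    stop("unit '", name, "' has ", k, " sample; within-population ",
         "diversity needs at least 2")
  }
  d <- pairwise_gd(sub)
  v <- d[upper.tri(d)]
  data.frame(unit = name, n_samples = k, n_pairs = length(v),
             min_gd = min(v), mean_gd = mean(v), max_gd = max(v))
}

#' Off-diagonal summary of a distance matrix
#'
#' @param dm a labelled symmetric Gd matrix.
#' @return named list with `min`, `mean`, `max` over the strict upper
#'   triangle and `n_pairs`, the number of entries summarized.
#' @export
gd_range <- function(dm) {
  dm <- validate_gd_matrix(dm)
  if (nrow(dm) < 2L) stop("need at least 2 labels")
  v <- dm[upper.tri(dm)]
  list(min = min(v), mean = mean(v), max = max(v), n_pairs = length(v))
}

#' Round half away from zero
#'
#' Decimal rounding in which a 5 in the first dropped place rounds up
#' (1.25 -> 1.3 at one decimal), the convention used in the reported
#' diversity tables, rather than R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ratio of two diversity values
#'
#' The conventional "times lower" comparison: the reference diversity
#' (typically the invasive population's) divided by another unit's,
#' rounded half-up to one decimal.
#'
#' @param reference numeric Gd of the reference unit.
#' @param other numeric Gd of the compared unit; must be positive.
#' @return the ratio, one decimal.
#' @export
diversity_ratio <- function(reference, other) {
  if (any(other <= 0)) stop("cannot form a ratio over a zero diversity")
  round_half_up(reference / other, 1)
}

#' Aggregate within-unit summaries against a reference unit
#'
#' Stacks per-unit diversity summaries, appends their unweighted column
#' means as an `"average"` row, and, when a reference summary is given
#' (e.g. a native population), adds a `gd_difference` column holding the
#' reference mean minus each unit's mean (and minus the average).
#'
#' @param summaries data frame of rows from [within_population_gd()].
#' @param reference optional single summary row to difference against;
#'   it is appended last, with no difference of its own.
#' @return data frame mirroring the input with the average row (and the
#'   reference row plus `gd_difference` column, when supplied).
#' @export
aggregate_gd_summaries <- function(summaries, reference = NULL) {
  stopifnot(nrow(summaries) >= 1L)
  avg <- data.frame(unit = "average",
                    n_samples = NA_integer_,
                    n_pairs = NA_integer_,
                    min_gd = mean(summaries$min_gd),
                    mean_gd = mean(summaries$mean_gd),
                    max_gd = mean(summaries$max_gd))
  out <- rbind(summaries, avg)
  if (!is.null(reference)) {
    stopifnot(nrow(reference) == 1L)
    out$gd_difference <- reference$mean_gd - out$mean_gd
    ref <- reference
    ref$gd_difference <- NA_real_
    out <- rbind(out, ref)
  }
  rownames(out) <- NULL
  out
}

#' Read / write a labelled Gd matrix as CSV
#'
#' Square CSV with unit labels in the first column and as header.
#'
#' @param path file path.
#' @return `read_gd_matrix`: a validated symmetric matrix.
#' @export
read_gd_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_gd_matrix(m)
}

#' @rdname read_gd_matrix
#' @param dm a labelled symmetric Gd matrix.
#' @export
write_gd_matrix <- function(dm, path) {
  dm <- validate_gd_matrix(dm)
  df <- data.frame(unit = rownames(dm), dm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Gd matrix in square PHYLIP format
#'
#' For interoperability with classical phylogeny tools: first line the
#' number of units, then one row per unit with the label padded to 10
#' characters followed by the full row of distances.
#'
#' @inheritParams write_gd_matrix
#' @export
write_gd_phylip <- function(dm, path) {
  dm <- validate_gd_matrix(dm)
  lines <- c(format(nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(formatC(dm[i, ], format = "f", digits = 6),
                            collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
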