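#' @keywords internal
"_PACKAGE"

MARKER_SYSTEMS <- c("RAPD", "ISSR", "REMAP")
POPULATION_TYPES <- c("invasive", "feral", "native", "variety")

band_ids <- function(bands) {
  paste(bands$system, bands$primer, bands$size, sep = ":")
}

#' Construct a dominant-marker matrix
#'
#' A `marker_matrix` holds a binary samples-by-bands table from dominant
#' marker fingerprinting (RAPD, ISSR, REMAP), where 1 records the presence
#' of a scored PCR band of a given size for a given primer and 0 its
#' absence. A band is identified by the triple (marker system, primer
#' label, fragment size in bp); two bands with the same triple are the same
#' character, so the triple must be unique within a matrix.
#'
#' @param values numeric or integer matrix of 0/1 values, rows = samples,
#'   columns = bands. Row names, if present, are used as sample ids.
#' @param bands data frame with columns `system` (one of `"RAPD"`,
#'   `"ISSR"`, `"REMAP"`), `primer` (character, e.g. `"OPA-2"` or
#'   `"MS6+Thv19"`) and `size` (positive integer, base pairs), one row per
#'   column of `values`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `rownames(values)`.
#' @return An object of class `marker_matrix`: a list with elements
#'   `values` (integer matrix with sample ids as row names and
#'   `SYSTEM:PRIMER:SIZE` column names) and `bands` (the band metadata).
#' @examples
#' m <- marker_matrix(
#'   rbind(s1 = c(1, 0, 1), s2 = c(1, 1, 0)),
#'   data.frame(system = "RAPD", primer = "OPA-2", size = c(500, 700, 1300))
#' )
#' m
#' @export
marker_matrix <- function(values, bands, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    stop("sample ids are required (row names of `values` or `sample_ids`)")
  }
  bands <- as.data.frame(bands)
  bands$system <- as.character(bands$system)
  bands$primer <- as.character(bands$primer)
  bands$size <- as.integer(bands$size)
  storage.mode(values) <- "integer"
  rownames(values) <- as.character(sample_ids)
  colnames(values) <- band_ids(bands)
  x <- structure(list(values = values, bands = bands), class = "marker_matrix")
  validate_marker_matrix(x)
}

#' Validate a marker matrix
#'
#' Checks the structural invariants: strictly binary values, unique sample
#' ids, positive fragment sizes, known marker systems, and uniqueness of
#' the (system, primer, size) band identity.
#'
#' @param x a `marker_matrix`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_marker_matrix <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  v <- x$values
  b <- x$bands
  if (nrow(v) < 1L) stop("marker matrix must contain at least one sample")
  if (ncol(v) != nrow(b)) {
    stop("band metadata has ", nrow(b), " rows but the matrix has ",
         ncol(v), " columns")
  }
  bad <- which(!(v %in% c(0L, 1L)) | is.na(v))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(v)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(v)) + 1L
    stop("non-binary cell value '", v[i, j], "' at (row ", i, ", col ", j, ")")
  }
  dup <- duplicated(rownames(v))
  if (any(dup)) {
    stop("duplicate sample id: ", paste(unique(rownames(v)[dup]), collapse = ", "))
  }
  if (any(is.na(b$size)) || any(b$size <= 0L)) {
    stop("fragment sizes must be positive integers (bp)")
  }
  unknown <- setdiff(unique(b$system), MARKER_SYSTEMS)
  if (length(unknown)) {
    stop("unknown marker system: ", paste(unknown, collapse = ", "))
  }
  dupb <- duplicated(band_ids(b))
  if (any(dupb)) {
    stop("duplicate band identity: ",
         paste(unique(band_ids(b)[dupb]), collapse = ", "))
  }
  x
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$values), "samples x", ncol(x$values), "bands\n")
  tab <- table(x$bands$system)
  cat("  systems:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Sample identifiers of a marker matrix
#' @param x a `marker_matrix`.
#' @return character vector of sample ids, in matrix row order.
#' @export
sample_ids <- function(x) rownames(x$values)

parse_band_header <- function(header) {
  parts <- strsplit(header, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed band header '", header[bad[1]], "' (column ", bad[1] + 1L,
         "): expected SYSTEM:PRIMER:SIZE")
  }
  m <- do.call(rbind, parts)
  size <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(size))
  if (length(bad)) {
    stop("malformed band header '", header[bad[1]], "' (column ", bad[1] + 1L,
         "): size is not an integer")
  }
  data.frame(system = m[, 1], primer = m[, 2], size = size)
}

#' Read a marker matrix from CSV
#'
#' The file dialect is UTF-8 CSV with the first column `sample_id` and one
#' column per band, headed `SYSTEM:PRIMER:SIZE` (e.g. `RAPD:OPA-2:1300`).
#' Cell values must be exactly 0 or 1; anything else is rejected with the
#' offending coordinates.
#'
#' @param path path to a CSV file.
#' @return a validated [marker_matrix()].
#' @seealso [write_marker_matrix()]
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file must have a sample_id column and at least one band")
  if (names(df)[1] != "sample_id") {
    stop("first column must be 'sample_id', got '", names(df)[1], "'")
  }
  bands <- parse_band_header(names(df)[-1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(raw %in% c("0", "1")))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(raw)) + 1L
    # col is reported in file coordinates (sample_id column is column 1)
    stop("non-binary cell value '", raw[i, j], "' at (row ", i,
         ", col ", j + 1L, ")")
  }
  values <- matrix(as.integer(raw), nrow = nrow(raw))
  rownames(values) <- df$sample_id
  marker_matrix(values, bands)
}

#' Write a marker matrix to CSV
#'
#' Writes the dialect read by [read_marker_matrix()]; `read` after `write`
#' reproduces the matrix exactly. Matrices without bands are refused.
#'
#' @param x a `marker_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(x, path) {
  validate_marker_matrix(x)
  if (ncol(x$values) == 0L) stop("refusing to write a matrix with no bands")
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' Tab-separated file with columns `sample_id`, `population`,
#' `population_type` (`invasive`, `feral`, `native` or `variety`) and
#' optional `latitude`, `longitude` in decimal degrees.
#'
#' @param path path to a TSV file.
#' @return a validated data frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate a sample table
#'
#' @param table data frame with at least `sample_id`, `population` and
#'   `population_type` columns.
#' @param matrix optionally, a `marker_matrix` the table must describe:
#'   every sample id in the matrix must appear exactly once.
#' @return the table, or an error.
#' @export
validate_sample_table <- function(table, matrix = NULL) {
  need <- c("sample_id", "population", "population_type")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(table$sample_id)
  if (any(dup)) {
    stop("duplicate sample id in table: ",
         paste(unique(table$sample_id[dup]), collapse = ", "))
  }
  bad <- setdiff(unique(table$population_type), POPULATION_TYPES)
  if (length(bad)) {
    stop("unknown population type: ", paste(bad, collapse = ", "))
  }
  if (!is.null(matrix)) {
    miss <- setdiff(sample_ids(matrix), table$sample_id)
    if (length(miss)) {
      stop("samples missing from table: ", paste(miss, collapse = ", "))
    }
  }
  table
}

#' Subset a marker matrix to named populations
#'
#' Keeps the rows belonging to the given populations (a pool), in their
#' original row order, with band columns unchanged. Pooling several
#' populations into one analysis unit (for instance merging regional
#' collections into a single invasive population) is done by naming them
#' all.
#'
#' @param x a `marker_matrix`.
#' @param table a sample table (see [read_sample_table()]).
#' @param populations character vector of population names to keep.
#' @return a `marker_matrix` restricted to those samples.
#' @export
subset_populations <- function(x, table, populations) {
  validate_sample_table(table, x)
  unknown <- setdiff(populations, unique(table$population))
  if (length(unknown)) {
    stop("unknown population: ", paste(unknown, collapse = ", "))
  }
  keep_ids <- table$sample_id[table$population %in% populations]
  keep <- sample_ids(x) %in% keep_ids
  if (!any(keep)) stop("no samples of the named populations are in the matrix")
  marker_matrix(x$values[keep, , drop = FALSE], x$bands)
}

#' Combine per-system marker matrices by column concatenation
#'
#' Joins matrices scored with different marker systems (or primer sets) on
#' the same samples into one matrix whose bands are the concatenation of
#' all inputs' bands. Rows are aligned by sample id; inputs may list
#' samples in different orders, but must contain exactly the same sample
#' set.
#'
#' @param matrices list of `marker_matrix` objects.
#' @return a `marker_matrix` with `sum(bands)` columns, sample order taken
#'   from the first input.
#' @export
concat_systems <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  lapply(matrices, validate_marker_matrix)
  ids <- sample_ids(matrices[[1]])
  for (m in matrices[-1]) {
    extra <- setdiff(sample_ids(m), ids)
    missing <- setdiff(ids, sample_ids(m))
    if (length(extra) || length(missing)) {
      stop("sample sets differ between matrices; only in one: ",
           paste(c(extra, missing), collapse = ", "))
    }
  }
  values <- do.call(cbind, lapply(matrices, function(m) {
    m$values[ids, , drop = FALSE]
  }))
  bands <- do.call(rbind, lapply(matrices, `[[`, "bands"))
  marker_matrix(values, bands, sample_ids = ids)
}

#' Identify monomorphic and population-diagnostic bands
#'
#' Classifies bands by their distribution across populations:
#' \describe{
#'   \item{`species_monomorphic`}{present in (at least a fraction
#'     `threshold` of) every population's samples — candidate
#'     species-specific fragments.}
#'   \item{`population_diagnostic`}{present in every sample (fraction
#'     `>= threshold`) of exactly one population and absent elsewhere —
#'     candidate markers for that population.}
#'   \item{`population_absent`}{absent from one population but present in
#'     at least one sample of every other population — the complementary
#'     kind of diagnostic fragment.}
#' }
#' With the default `threshold = 1` the classification is strictly
#' categorical (all/none), which is how diagnostic fragments are usually
#' read off gels.
#'
#' @param x a `marker_matrix`.
#' @param table a sample table covering the matrix samples.
#' @param threshold presence frequency required within a population for
#'   the band to count as "fixed present" there (and `1 - threshold` as
#'   "fixed absent"); default 1.
#' @return data frame with columns `band`, `system`, `primer`, `size`,
#'   `scope` and `population` (`NA` for species-wide bands). Zero rows if
#'   nothing qualifies.
#' @export
find_diagnostic_bands <- function(x, table, threshold = 1) {
  validate_marker_matrix(x)
  validate_sample_table(table, x)
  stopifnot(threshold > 0.5, threshold <= 1)
  pop_of <- table$population[match(sample_ids(x), table$sample_id)]
  pops <- unique(pop_of)
  # per-population presence frequency of each band
  freq <- matrix(0, nrow = length(pops), ncol = ncol(x$values),
                 dimnames = list(pops, colnames(x$values)))
  for (p in seq_along(pops)) {
    freq[p, ] <- colMeans(x$values[pop_of == pops[p], , drop = FALSE])
  }
  fixed_present <- freq >= threshold
  fixed_absent <- freq <= (1 - threshold)
  any_present <- freq > 0

  rows <- list()
  mono <- which(apply(fixed_present, 2, all))
  for (j in mono) {
    rows[[length(rows) + 1L]] <- data.frame(
      band = band_ids(x$bands)[j], x$bands[j, ],
      scope = "species_monomorphic", population = NA_character_)
  }
  if (length(pops) >= 2L) {
    for (j in seq_len(ncol(x$values))) {
      if (j %in% mono) next
      pres <- which(fixed_present[, j])
      if (length(pres) == 1L && all(fixed_absent[-pres, j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          band = band_ids(x$bands)[j], x$bands[j, ],
          scope = "population_diagnostic", population = pops[pres])
      }
      abs_p <- which(fixed_absent[, j])
      if (length(abs_p) == 1L && all(any_present[-abs_p, j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          band = band_ids(x$bands)[j], x$bands[j, ],
          scope = "population_absent", population = pops[abs_p])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(band = character(), system = character(), primer = character(),
               size = integer(), scope = character(), population = character())
  rownames(out) <- NULL
  out
}
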