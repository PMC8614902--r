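#' Bundled example datasets
#'
#' Small labelled tables from a comparative study of invasive lupin
#' (*Lupinus polyphyllus*) and hogweed (*Heracleum sosnowskyi*)
#' populations, shipped as plain-text fixtures:
#' \describe{
#'   \item{`lupin_between_gd`}{6x6 Nei-Li Gd matrix between four invasive
#'     regional lupin populations, a feral botanical-garden population
#'     (MBG) and the 'Minaret' variety (combined RAPD+ISSR+REMAP data).}
#'   \item{`hogweed_between_gd`}{5x5 Gd matrix between the native
#'     Caucasus hogweed population and four invasive populations.}
#'   \item{`hogweed_within_gd`}{per-population within-population Gd
#'     min/mean/max for hogweed, native population last.}
#'   \item{`lupin_method_gd`}{mean within-unit Gd of the pooled invasive,
#'     feral and variety lupin units, per marker system and combined.}
#' }
#'
#' @param name one of the dataset names above.
#' @return a validated Gd matrix for the `*_between_gd` names, otherwise
#'   a data frame.
#' @examples
#' gd_range(markerdiv_example("lupin_between_gd"))
#' @export
markerdiv_example <- function(name = c("lupin_between_gd",
                                       "hogweed_between_gd",
                                       "hogweed_within_gd",
                                       "lupin_method_gd")) {
  name <- match.arg(name)
  ext <- if (grepl("between", name)) ".csv" else ".tsv"
  path <- system.file("extdata", paste0(name, ext), package = "markerdiv",
                      mustWork = TRUE)
  if (ext == ".csv") read_gd_matrix(path) else
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Copy the bundled fixtures into a directory
#'
#' @param dir target directory (created if needed).
#' @return invisibly, the copied file paths.
#' @export
copy_fixtures <- function(dir) {
  src <- list.files(system.file("extdata", package = "markerdiv"),
                    full.names = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.copy(src, dir, overwrite = TRUE)
  if (!all(ok)) stop("could not copy fixtures to ", dir)
  invisible(file.path(dir, basename(src)))
}

#' Run the full diversity analysis
#'
#' End-to-end orchestration of the package: per-system matrices are
#' combined, between-unit and within-unit Nei-Li diversities computed,
#' and UPGMA dendrograms with bootstrap support built, with every table
#' and tree written to `out_dir`.
#'
#' Outputs written (all plain text):
#' \itemize{
#'   \item `between_gd_<system>.csv`, `between_gd_combined.csv` —
#'     between-unit Gd matrices, plus `between_gd_summary.tsv` with the
#'     off-diagonal min/mean/max of each;
#'   \item `within_gd.tsv` — per-unit within-unit summaries with the
#'     average row and, when `reference_unit` is given, the
#'     reference-minus-unit difference column;
#'   \item `tree_<system>.nwk`, `tree_combined.nwk` — unit-level UPGMA
#'     trees with bootstrap supports;
#'   \item `tree_individuals_<unit>.nwk` — individual-level tree of one
#'     unit, when `individual_unit` is given;
#'   \item `diagnostic_bands.tsv` — monomorphic/diagnostic band report on
#'     the combined matrix;
#'   \item `run_log.txt` — seed, package version and every analysis
#'     toggle in force.
#' }
#'
#' @param matrices named list (names = marker systems) of
#'   `marker_matrix` objects or paths readable by [read_marker_matrix()].
#' @param table sample table data frame or path readable by
#'   [read_sample_table()].
#' @param units unit spec as in [between_population_gd()]; `NULL` treats
#'   every population as a unit.
#' @param reference_unit optional name of one unit (after pooling) whose
#'   within-unit mean anchors the difference column, typically a native
#'   population.
#' @param individual_unit optional character vector of populations whose
#'   individual samples get their own bootstrap tree.
#' @param combination `"concatenate"` (default: band columns of all
#'   systems joined before any distance computation) or `"average"`
#'   (per-system Gd matrices averaged; the combined tree then carries no
#'   bootstrap supports, since averaged distances have no columns to
#'   resample).
#' @param replicates bootstrap replicates per tree (default 100).
#' @param seed integer seed; re-running with the same inputs and seed
#'   reproduces every output byte for byte.
#' @param tie consensus tie rule, see [consensus_profile()].
#' @param out_dir output directory, created if needed; `NULL` computes
#'   everything without writing files.
#' @return invisibly, a list with the per-system and combined matrices,
#'   ranges, trees, the within-unit report and the diagnostic-band
#'   report.
#' @export
run_pipeline <- function(matrices, table, units = NULL,
                         reference_unit = NULL, individual_unit = NULL,
                         combination = c("concatenate", "average"),
                         replicates = 100, seed = 20211025,
                         tie = c("absent", "present"), out_dir = NULL) {
  combination <- match.arg(combination)
  tie <- match.arg(tie)
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    stop("`matrices` must be a named list (names = marker systems)")
  }
  matrices <- lapply(matrices, function(m) {
    if (is.character(m)) read_marker_matrix(m) else validate_marker_matrix(m)
  })
  if (is.character(table)) table <- read_sample_table(table)
  validate_sample_table(table)
  units_res <- resolve_units(table, units)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # process systems in sorted-name order so every output (including
  # derived bootstrap seeds) is invariant to the listing order
  systems <- sort(names(matrices))
  matrices <- matrices[systems]
  combined <- concat_systems(matrices)

  # between-unit matrices and trees, per system and combined
  between <- lapply(matrices, between_population_gd, table = table,
                    units = units_res, tie = tie)
  between$combined <- if (combination == "concatenate") {
    between_population_gd(combined, table, units = units_res, tie = tie)
  } else {
    validate_gd_matrix(Reduce(`+`, between[systems]) / length(systems))
  }
  trees <- list()
  for (i in seq_along(systems)) {
    trees[[systems[i]]] <- bootstrap_support(
      matrices[[systems[i]]], table, units = units_res,
      replicates = replicates, seed = seed + i, tie = tie)
  }
  trees$combined <- if (combination == "concatenate") {
    bootstrap_support(combined, table, units = units_res,
                      replicates = replicates, seed = seed, tie = tie)
  } else {
    upgma(between$combined)
  }
  ranges <- lapply(between, gd_range)

  # within-unit diversity (units with >= 2 samples only)
  pop_of <- table$population[match(sample_ids(combined), table$sample_id)]
  sizes <- vapply(units_res, function(p) sum(pop_of %in% p), integer(1))
  ok_units <- names(units_res)[sizes >= 2L]
  within <- do.call(rbind, lapply(ok_units, function(u) {
    within_population_gd(combined, table, units_res[[u]], name = u)
  }))
  report <- if (!is.null(reference_unit)) {
    stopifnot(reference_unit %in% within$unit)
    ref <- within[within$unit == reference_unit, ]
    aggregate_gd_summaries(within[within$unit != reference_unit, ], ref)
  } else {
    aggregate_gd_summaries(within)
  }

  indiv_tree <- NULL
  if (!is.null(individual_unit)) {
    sub <- subset_populations(combined, table, individual_unit)
    indiv_tree <- bootstrap_support(sub, table = NULL,
                                    replicates = replicates, seed = seed)
  }
  diag_bands <- find_diagnostic_bands(combined, table)

  if (!is.null(out_dir)) {
    for (nm in names(between)) {
      write_gd_matrix(between[[nm]], file.path(out_dir,
                                               paste0("between_gd_", nm, ".csv")))
      to_newick(trees[[nm]], file.path(out_dir, paste0("tree_", nm, ".nwk")))
    }
    rng <- data.frame(matrix = names(ranges),
                      min_gd = vapply(ranges, `[[`, 0, "min"),
                      mean_gd = vapply(ranges, `[[`, 0, "mean"),
                      max_gd = vapply(ranges, `[[`, 0, "max"))
    utils::write.table(rng, file.path(out_dir, "between_gd_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report, file.path(out_dir, "within_gd.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(diag_bands, file.path(out_dir, "diagnostic_bands.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(indiv_tree)) {
      to_newick(indiv_tree,
                file.path(out_dir,
                          paste0("tree_individuals_",
                                 paste(individual_unit, collapse = "+"), ".nwk")))
    }
    log_lines <- c(
      paste0("markerdiv ", as.character(utils::packageVersion("markerdiv"))),
      paste0("seed: ", seed),
      paste0("systems: ", paste(systems, collapse = ", ")),
      paste0("combination mode: ", combination),
      paste0("distance: Nei-Li Gd = 1 - 2*Nxy/(Nx+Ny), Nx/Ny = total bands per profile"),
      paste0("consensus tie rule: exactly half present -> ", tie),
      paste0("bootstrap replicates: ", replicates,
             " (band columns, stratified by marker system)"),
      paste0("UPGMA tie-break: lexicographically smallest label pair"),
      paste0("units: ", paste(vapply(names(units_res), function(u)
        paste0(u, "=", paste(units_res[[u]], collapse = "+")), character(1)),
        collapse = "; ")),
      paste0("reference unit: ", if (is.null(reference_unit)) "none" else reference_unit)
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  invisible(list(between = between, ranges = ranges, trees = trees,
                 within = report, individual_tree = indiv_tree,
                 diagnostic_bands = diag_bands, combined_matrix = combined))
}
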