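#' Configuration for the dominant-marker simulator
#'
#' Describes a multi-population dominant-marker study. Three kinds of
#' bands are generated, mirroring what marker fingerprinting of structured
#' plant populations typically shows:
#' \itemize{
#'   \item species-wide monomorphic bands, fixed present in every sample
#'     (fraction `monomorphic_fraction`);
#'   \item population-diagnostic bands, fixed present in one designated
#'     population and absent everywhere else (fraction
#'     `diagnostic_fraction`, assigned round-robin across populations);
#'   \item ordinary polymorphic bands: an ancestral presence frequency
#'     \eqn{\pi_j \sim Beta(a, b)} per band, a population frequency drawn
#'     from the Balding-Nichols distribution
#'     \eqn{f_{pj} \sim Beta(\pi_j (1-\theta)/\theta,
#'     (1-\pi_j)(1-\theta)/\theta)} (with \eqn{f_{pj} = \pi_j} when
#'     \eqn{\theta = 0}), and independent Bernoulli(\eqn{f_{pj}}) presence
#'     per sample.
#' }
#' `differentiation` (\eqn{\theta}) is the single knob controlling how far
#' population band frequencies drift apart: 0 gives panmixia, values near
#' 1 give strong among-population differentiation.
#'
#' @param n_populations number of populations.
#' @param samples_per_population samples per population (scalar or vector
#'   of length `n_populations`); each at least 2.
#' @param bands_per_system named counts of bands for the `RAPD`, `ISSR`
#'   and `REMAP` systems.
#' @param differentiation theta in `[0, 1)`.
#' @param ancestral_band_freq Beta shape pair `(a, b)` for ancestral band
#'   frequencies.
#' @param monomorphic_fraction fraction of bands fixed present everywhere.
#' @param diagnostic_fraction fraction of bands private-fixed in a single
#'   population.
#' @param population_types character vector of population types recycled
#'   over populations (default all `"invasive"`).
#' @param seed integer seed making the draw reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 4,
                       samples_per_population = 10,
                       bands_per_system = c(RAPD = 60, ISSR = 40, REMAP = 25),
                       differentiation = 0.15,
                       ancestral_band_freq = c(1, 1),
                       monomorphic_fraction = 0.10,
                       diagnostic_fraction = 0.05,
                       population_types = "invasive",
                       seed = 20211025) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    samples_per_population = rep_len(as.integer(samples_per_population),
                                     n_populations),
    bands_per_system = bands_per_system,
    differentiation = differentiation,
    ancestral_band_freq = ancestral_band_freq,
    monomorphic_fraction = monomorphic_fraction,
    diagnostic_fraction = diagnostic_fraction,
    population_types = rep_len(population_types, n_populations),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_populations < 1L) stop("need at least one population")
  if (any(cfg$samples_per_population < 2L)) {
    stop("each population needs at least 2 samples")
  }
  if (is.null(names(cfg$bands_per_system)) ||
      !all(names(cfg$bands_per_system) %in% MARKER_SYSTEMS)) {
    stop("bands_per_system must be named with RAPD/ISSR/REMAP")
  }
  if (any(cfg$bands_per_system < 1)) stop("band counts must be positive")
  th <- cfg$differentiation
  if (th < 0 || th >= 1) stop("differentiation must lie in [0, 1)")
  if (any(cfg$ancestral_band_freq <= 0)) stop("Beta shapes must be positive")
  fr <- cfg$monomorphic_fraction + cfg$diagnostic_fraction
  if (cfg$monomorphic_fraction < 0 || cfg$diagnostic_fraction < 0 || fr > 1) {
    stop("band-class fractions must be non-negative and sum to at most 1")
  }
  if (!all(cfg$population_types %in% POPULATION_TYPES)) {
    stop("unknown population type")
  }
  cfg
}

#' Simulate a multi-population dominant-marker dataset
#'
#' Draws a binary marker matrix, a matching sample table and the full
#' generating truth under a [sim_config()]. Bands are independent given
#' their population frequencies (anonymous dominant characters carry no
#' linkage information), and dominance is modelled directly at the band
#' level: the presence probability is the band frequency itself.
#'
#' @param config a `sim_config`.
#' @return list with elements `matrix` (a `marker_matrix`), `table` (a
#'   sample table data frame) and `truth` (per-band ancestral frequencies
#'   `pi`, the populations-by-bands frequency matrix `f`, per-band `role`,
#'   the per-population `expected_within_gd`, and the `config`).
#' @export
simulate_markers <- function(config) {
  cfg <- validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n_pop <- cfg$n_populations
  pops <- sprintf("Pop%02d", seq_len(n_pop))
  n_per <- cfg$samples_per_population
  total_bands <- sum(cfg$bands_per_system)

  bands <- do.call(rbind, lapply(names(cfg$bands_per_system), function(sys) {
    k <- cfg$bands_per_system[[sys]]
    data.frame(system = sys,
               primer = sprintf("%s-P%03d", sys, seq_len(k)),
               size = sample(seq(200L, 2000L, by = 10L), k, replace = TRUE))
  }))

  n_mono <- round(cfg$monomorphic_fraction * total_bands)
  n_diag <- round(cfg$diagnostic_fraction * total_bands)
  role <- rep("ordinary", total_bands)
  slots <- sample.int(total_bands)        # spread roles over systems
  if (n_mono > 0) role[slots[seq_len(n_mono)]] <- "monomorphic"
  diag_idx <- if (n_diag > 0) slots[n_mono + seq_len(n_diag)] else integer()
  role[diag_idx] <- "diagnostic"
  diag_pop <- rep(NA_character_, total_bands)
  if (length(diag_idx)) {
    diag_pop[diag_idx] <- pops[((seq_along(diag_idx) - 1L) %% n_pop) + 1L]
  }

  a <- cfg$ancestral_band_freq[1]
  b <- cfg$ancestral_band_freq[2]
  th <- cfg$differentiation
  pi_j <- stats::rbeta(total_bands, a, b)
  f <- matrix(0, n_pop, total_bands, dimnames = list(pops, band_ids(bands)))
  ord <- which(role == "ordinary")
  for (p in seq_len(n_pop)) {
    if (th == 0) {
      f[p, ord] <- pi_j[ord]
    } else {
      f[p, ord] <- stats::rbeta(length(ord),
                                pi_j[ord] * (1 - th) / th,
                                (1 - pi_j[ord]) * (1 - th) / th)
    }
  }
  f[, role == "monomorphic"] <- 1
  for (j in diag_idx) f[, j] <- as.numeric(pops == diag_pop[j])
  pi_j[role == "monomorphic"] <- 1
  pi_j[diag_idx] <- 1 / n_pop

  values <- matrix(0L, sum(n_per), total_bands)
  ids <- character(sum(n_per))
  pop_col <- character(sum(n_per))
  r <- 0L
  for (p in seq_len(n_pop)) {
    for (s in seq_len(n_per[p])) {
      r <- r + 1L
      values[r, ] <- stats::rbinom(total_bands, 1L, f[p, ])
      ids[r] <- sprintf("%s_s%02d", pops[p], s)
      pop_col[r] <- pops[p]
    }
  }
  rownames(values) <- ids
  table <- data.frame(sample_id = ids, population = pop_col,
                      population_type = rep(cfg$population_types, n_per),
                      latitude = NA_real_, longitude = NA_real_)
  exp_within <- vapply(seq_len(n_pop),
                       function(p) expected_within_gd(f[p, ]), numeric(1))
  names(exp_within) <- pops
  list(matrix = marker_matrix(values, bands),
       table = table,
       truth = list(pi = pi_j, f = f, role = role, diagnostic_population = diag_pop,
                    expected_within_gd = exp_within, config = cfg))
}

#' Expected within-population diversity from band frequencies
#'
#' Ratio-of-expectations approximation to the mean Nei-Li Gd between two
#' random members of a population with independent bands of presence
#' frequency \eqn{f_j}: since \eqn{E[N_{xy}] = \sum_j f_j^2} and
#' \eqn{E[(N_x + N_y)/2] = \sum_j f_j},
#' \deqn{E[Gd] \approx 1 - \frac{\sum_j f_j^2}{\sum_j f_j}.}
#' The approximation (expectation of a ratio replaced by the ratio of
#' expectations) is accurate when many bands contribute, which is the
#' regime of marker fingerprinting panels.
#'
#' @param frequencies vector of band presence frequencies in `[0, 1]`,
#'   not all zero.
#' @return expected Gd, a number in `[0, 1]`.
#' @examples
#' expected_within_gd(rep(0.5, 100)) # 0.5
#' expected_within_gd(c(1, 1, 0.5))  # 0.1
#' @export
expected_within_gd <- function(frequencies) {
  stopifnot(all(frequencies >= 0), all(frequencies <= 1))
  s <- sum(frequencies)
  if (s == 0) stop("expected Gd is undefined when every band frequency is 0")
  1 - sum(frequencies^2) / s
}

#' Parameter-recovery experiment for the simulator
#'
#' Simulates a dataset, runs it through the diversity pipeline, and
#' compares the observed mean within-population Gd of every population
#' with the closed-form expectation from the population's true band
#' frequencies.
#'
#' @param config a `sim_config`.
#' @return list with `per_population` (data frame of observed and expected
#'   within-population mean Gd and their absolute error),
#'   `max_abs_error`, and `between` (the between-population consensus Gd
#'   matrix with its off-diagonal mean).
#' @export
recovery_experiment <- function(config) {
  sim <- simulate_markers(config)
  pops <- rownames(sim$truth$f)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    obs <- within_population_gd(sim$matrix, sim$table, p)
    data.frame(population = p,
               observed_mean_gd = obs$mean_gd,
               expected_mean_gd = unname(sim$truth$expected_within_gd[p]))
  }))
  per_pop$abs_error <- abs(per_pop$observed_mean_gd - per_pop$expected_mean_gd)
  between <- if (length(pops) >= 2L) {
    between_population_gd(sim$matrix, sim$table)
  } else NULL
  list(per_population = per_pop,
       max_abs_error = max(per_pop$abs_error),
       between = between,
       between_mean = if (is.null(between)) NA_real_ else gd_range(between)$mean)
}
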