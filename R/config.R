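#' Default experiment configuration
#'
#' The configuration tree used by the experiment runners, with the study
#' conditions as defaults: Balding-Nichols founders at F_ST 0.1 over 10,000
#' loci on a 102-Mb region, a 50-50 single-generation admixture followed by
#' six generations of random mating producing 800 diploids, unmixed proxy
#' groups of 100 individuals expanded from 38 and 50 founders, and the
#' sampling-design grid with 5 replicates per cell.
#'
#' @return A nested list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    population = list(
      n_loci = 10000L,
      fst = 0.1,
      region_length_bp = 1.02e8,
      recomb_rate = 1e-8,
      mutation_rate = 0,
      n_admix_founders = 50L,     # per ancestral population
      n_unmixed_founders = c(38L, 50L),
      n_unmixed = c(100L, 100L),
      n_admixed = 800L,
      n_generations = 6L
    ),
    grid = list(
      x = c(10L, 30L, 100L),
      y = c(10L, 100L, 400L, 700L),
      z = NULL,                   # NULL = symmetric (z = x per cell)
      replicates = 5L
    ),
    inference = list(
      engine = "em",
      K = 2L,
      tol = 1e-2,
      max_iter = 600L,
      accelerate = TRUE
    ),
    correction = list(
      mode = "none",              # none | resample | weights
      prior = "uniform"           # uniform | numeric triple
    ),
    demography = list(
      alpha = c(0.99, 0.5, 0.1),
      n0 = 10000,
      split_generations = 1000,
      x_sweep = c(5L, 10L, 20L, 30L, 40L, 50L),
      n_sampled = 50L,
      n_admixed = 50L,
      n_generations = 5L
    ),
    seed = 1L
  ), class = "experiment_config")
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML key-value file, overlays it on [default_config()], rejects
#' unknown keys, and validates ranges (counts positive, F_ST in (0, 0.5),
#' engine/correction from their allowed sets).
#'
#' @param path Path to a YAML config file; `NULL` returns the defaults.
#' @return A validated `experiment_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "full_grid.yaml",
#'                                package = "admixbias"))
#' length(grid_cells(cfg))  # 96 cells
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing config file: ", path)
    user <- fix_yaml_keys(yaml::read_yaml(path))
    cfg <- merge_config(cfg, user, "")
  }
  validate_config(structure(cfg, class = "experiment_config"))
}

# YAML 1.1 parses bare y/n keys as booleans; map them back to the grid
# field names they can only have meant.
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "TRUE"] <- "y"
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, fix_yaml_keys)
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  if (!is.list(user)) stop("config section '", prefix, "' must be a mapping")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  p <- cfg$population
  check_count <- function(v, nm, min = 1) {
    if (any(!is.finite(v)) || any(v < min) || any(v != floor(v))) {
      stop("config value out of range: ", nm, " (must be integer >= ", min, ")")
    }
  }
  check_count(p$n_loci, "population.n_loci")
  check_count(p$n_admix_founders, "population.n_admix_founders")
  check_count(p$n_unmixed_founders, "population.n_unmixed_founders")
  check_count(p$n_unmixed, "population.n_unmixed")
  check_count(p$n_admixed, "population.n_admixed", min = 0)
  check_count(p$n_generations, "population.n_generations")
  if (p$fst <= 0 || p$fst >= 0.5) stop("population.fst must be in (0, 0.5)")
  if (p$region_length_bp <= 0) stop("population.region_length_bp must be > 0")
  g <- cfg$grid
  check_count(g$x, "grid.x")
  check_count(g$y, "grid.y")
  if (!is.null(g$z)) check_count(g$z, "grid.z")
  check_count(g$replicates, "grid.replicates")
  inf <- cfg$inference
  if (!inf$engine %in% c("em", "eigen")) {
    stop("inference.engine must be 'em' or 'eigen'")
  }
  check_count(inf$K, "inference.K")
  check_count(inf$max_iter, "inference.max_iter")
  if (inf$tol <= 0) stop("inference.tol must be > 0")
  corr <- cfg$correction
  if (!corr$mode %in% c("none", "resample", "weights")) {
    stop("correction.mode must be none, resample or weights")
  }
  if (!(identical(corr$prior, "uniform") ||
        (is.numeric(corr$prior) && length(corr$prior) == 3))) {
    stop("correction.prior must be 'uniform' or a numeric triple")
  }
  d <- cfg$demography
  if (any(d$alpha <= 0) || any(d$alpha > 1)) {
    stop("demography.alpha must lie in (0, 1]")
  }
  if (d$n0 <= 0) stop("demography.n0 must be > 0")
  cfg
}

#' Enumerate the sampling-design cells of a configuration
#'
#' Expands the grid section into one [sample_spec()] per `(x, y, z)`
#' combination. With `grid.z = NULL` the grid is symmetric (`z = x`), giving
#' `|x| * |y|` cells; with an explicit `z` list the full `|x| * |y| * |z|`
#' product is enumerated.
#'
#' @param cfg An `experiment_config`.
#' @return A list of [sample_spec()] objects.
#' @export
grid_cells <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  g <- cfg$grid
  if (is.null(g$z)) {
    cells <- expand.grid(x = g$x, y = g$y)
    cells$z <- cells$x
  } else {
    cells <- expand.grid(x = g$x, y = g$y, z = g$z)
  }
  lapply(seq_len(nrow(cells)), function(i) {
    sample_spec(cells$x[i], cells$y[i], cells$z[i])
  })
}
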