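#' Genotype table
#'
#' The basic genotype container: an individuals-by-loci matrix of
#' alternate-allele counts for biallelic loci, with entries in `{0, 1, 2}`
#' and `9` as the missing code.
#'
#' @param matrix Integer matrix, individuals in rows, loci in columns.
#' @param individual_ids Character vector of row names (defaults to
#'   `ind1..indN`).
#' @param locus_ids Character vector of column names (defaults to
#'   `rs1..rsM`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(matrix, individual_ids = NULL, locus_ids = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(m)))
  if (is.null(locus_ids)) locus_ids <- paste0("rs", seq_len(ncol(m)))
  if (length(individual_ids) != nrow(m)) stop("individual_ids must match rows")
  if (length(locus_ids) != ncol(m)) stop("locus_ids must match columns")
  bad <- !(m %in% c(0L, 1L, 2L, 9L))
  if (any(bad)) {
    stop("genotypes must be 0/1/2 with 9 as the missing code")
  }
  dimnames(m) <- list(as.character(individual_ids), as.character(locus_ids))
  structure(list(matrix = m), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d loci (%.2f%% missing)\n",
    nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix == 9L)
  ))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$matrix)

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_table")) return(x$matrix)
  if (inherits(x, "cohort")) return(x$genotypes$matrix)
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Group-label table
#'
#' Per-individual auxiliary labels: the group `u` (1 = unmixed population 1,
#' 2 = unmixed population 2, 3 = admixed) and, when known, the true ancestry
#' proportion `theta` (fraction of the genome from population 2).
#'
#' @param individual_ids Character vector.
#' @param group Integer vector in `{1, 2, 3}`, one per individual.
#' @param true_theta Optional numeric vector in `[0, 1]` (NA allowed).
#' @return A `label_table`: a data frame with columns `individual_id`,
#'   `group`, `true_theta`.
#' @export
label_table <- function(individual_ids, group, true_theta = NULL) {
  n <- length(individual_ids)
  group <- as.integer(group)
  if (length(group) != n) stop("one group label per individual required")
  if (!all(group %in% 1:3)) stop("group labels must be in {1, 2, 3}")
  if (is.null(true_theta)) true_theta <- rep(NA_real_, n)
  if (length(true_theta) != n) stop("true_theta must match individuals")
  ok <- is.na(true_theta) | (true_theta >= 0 & true_theta <= 1)
  if (!all(ok)) stop("true_theta must lie in [0, 1]")
  structure(
    data.frame(
      individual_id = as.character(individual_ids),
      group = group,
      true_theta = as.numeric(true_theta),
      stringsAsFactors = FALSE
    ),
    class = c("label_table", "data.frame")
  )
}

#' Cohort: genotypes + labels (+ ancestry segments)
#'
#' Binds a [genotype_table()] to its [label_table()] and, for simulated
#' individuals, the per-haplotype local-ancestry segments from which the
#' true ancestry proportion is computed. Unmixed individuals must carry
#' theta 0 (group 1) or 1 (group 2); admixed individuals theta in (0, 1).
#'
#' @param genotypes A [genotype_table()].
#' @param labels A [label_table()] over the same individuals, same order.
#' @param segments Optional list (one element per individual) of two-element
#'   lists of segment data frames with columns `start`, `end`, `pop`
#'   (0-based, half-open intervals; pop in {1, 2}).
#' @param provenance Optional character vector of source-individual ids,
#'   used to track duplication through expansion and resampling. Defaults
#'   to the individual ids.
#' @return An object of class `cohort`.
#' @export
cohort <- function(genotypes, labels, segments = NULL, provenance = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (!inherits(labels, "label_table")) stop("labels must be a label_table")
  n <- nrow(genotypes$matrix)
  if (nrow(labels) != n) stop("labels must cover every individual")
  if (!identical(labels$individual_id, rownames(genotypes$matrix))) {
    stop("label order must match genotype rows")
  }
  th <- labels$true_theta
  if (any(labels$group == 1L & !is.na(th) & th != 0)) {
    stop("group-1 individuals must have theta = 0")
  }
  if (any(labels$group == 2L & !is.na(th) & th != 1)) {
    stop("group-2 individuals must have theta = 1")
  }
  if (!is.null(segments) && length(segments) != n) {
    stop("segments must have one entry per individual")
  }
  if (is.null(provenance)) provenance <- labels$individual_id
  if (length(provenance) != n) stop("provenance must match individuals")
  structure(
    list(
      genotypes = genotypes, labels = labels,
      segments = segments, provenance = as.character(provenance)
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$labels$group, levels = 1:3))
  cat(sprintf(
    "cohort: %d individuals x %d loci | groups u=1:%d u=2:%d u=3:%d%s\n",
    nrow(x$genotypes$matrix), ncol(x$genotypes$matrix),
    tab[1], tab[2], tab[3],
    if (!is.null(x$segments)) " | ancestry segments tracked" else ""
  ))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param x A `cohort`.
#' @return Integer count.
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$genotypes$matrix)
}

#' Subset a cohort by individual index
#'
#' Rows may repeat (sampling with replacement); repeated rows get fresh
#' unique individual ids while `provenance` keeps the source id.
#'
#' @param x A `cohort`.
#' @param idx Integer indices into the cohort's individuals.
#' @return A `cohort` with `length(idx)` individuals.
#' @export
subset_cohort <- function(x, idx) {
  stopifnot(inherits(x, "cohort"))
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > n_individuals(x))) stop("index out of range")
  m <- x$genotypes$matrix[idx, , drop = FALSE]
  ids <- make.unique(rownames(m), sep = "_dup")
  gt <- genotype_table(m, ids, colnames(m))
  lb <- label_table(ids, x$labels$group[idx], x$labels$true_theta[idx])
  segs <- if (!is.null(x$segments)) x$segments[idx] else NULL
  cohort(gt, lb, segs, provenance = x$provenance[idx])
}

#' Concatenate cohorts over the same loci
#' @param ... `cohort` objects sharing identical locus ids.
#' @return A single combined `cohort`.
#' @export
bind_cohorts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, logical(1), "cohort")))
  loci <- colnames(xs[[1]]$genotypes$matrix)
  for (x in xs) {
    if (!identical(colnames(x$genotypes$matrix), loci)) {
      stop("cohorts must share identical loci")
    }
  }
  m <- do.call(rbind, lapply(xs, function(x) x$genotypes$matrix))
  ids <- make.unique(rownames(m), sep = "_x")
  rownames(m) <- ids
  gt <- genotype_table(m, ids, loci)
  lb <- label_table(
    ids,
    unlist(lapply(xs, function(x) x$labels$group)),
    unlist(lapply(xs, function(x) x$labels$true_theta))
  )
  any_seg <- any(vapply(xs, function(x) !is.null(x$segments), logical(1)))
  segs <- if (any_seg) {
    do.call(c, lapply(xs, function(x) {
      if (is.null(x$segments)) vector("list", n_individuals(x)) else x$segments
    }))
  } else NULL
  cohort(gt, lb, segs,
         provenance = unlist(lapply(xs, function(x) x$provenance)))
}
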