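#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `eigenstrat` reads the `.geno`/`.ind`/`.snp`
#' triplet used throughout the structure-analysis ecosystem: `.geno` has one
#' row per locus and one digit per individual (0/1/2, 9 = missing), `.ind`
#' one individual per row (id, sex, label), `.snp` one locus per row.
#' `tsv` reads a tab-separated individuals-by-loci matrix with a header row
#' of locus ids and individual ids in the first column.
#'
#' @param path For `eigenstrat`, the file prefix (so `prefix.geno` etc.);
#'   for `tsv`, the file path.
#' @param format `"eigenstrat"` or `"tsv"`.
#' @return A [genotype_table()] (individuals in rows).
#' @export
read_genotypes <- function(path, format = c("eigenstrat", "tsv")) {
  format <- match.arg(format)
  if (format == "eigenstrat") {
    geno_file <- paste0(path, ".geno")
    ind_file <- paste0(path, ".ind")
    snp_file <- paste0(path, ".snp")
    for (f in c(geno_file, ind_file, snp_file)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    lines <- readLines(geno_file)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("no loci in ", geno_file)
    ind <- read.table(ind_file, header = FALSE, stringsAsFactors = FALSE)
    snp <- read.table(snp_file, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(snp) != length(lines)) {
      stop(sprintf(".geno has %d loci but .snp lists %d",
                   length(lines), nrow(snp)))
    }
    if (any(nchar(lines) != nrow(ind))) {
      stop(".geno row lengths do not match the .ind individual count")
    }
    digits <- strsplit(lines, "")
    allowed <- c("0", "1", "2", "9")
    if (!all(unlist(digits) %in% allowed)) {
      stop("invalid genotype character in .geno (must be 0/1/2/9)")
    }
    # loci on disk rows -> columns of the vapply result = individuals x loci
    m <- vapply(digits, function(d) as.integer(d), integer(nrow(ind)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    genotype_table(m, individual_ids = ind[[1]], locus_ids = snp[[1]])
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0 || ncol(df) < 2) stop("no loci in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric genotype entries in ", path)
    genotype_table(m, individual_ids = df[[1]],
                   locus_ids = colnames(df)[-1])
  }
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]: writes the `.geno`/`.ind`/`.snp` triplet
#' (loci as rows, one digit per individual) or a tab-separated
#' individuals-by-loci table. Round-trips are exact, including the missing
#' code 9.
#'
#' @param table A [genotype_table()].
#' @param path File prefix (`eigenstrat`) or file path (`tsv`).
#' @param format `"eigenstrat"` or `"tsv"`.
#' @param groups Optional per-individual labels for the `.ind` third column.
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(table, path, format = c("eigenstrat", "tsv"),
                            groups = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(table, "genotype_table"))
  m <- table$matrix
  if (format == "eigenstrat") {
    # one row per locus
    rows <- apply(t(m), 1, paste, collapse = "")
    writeLines(rows, paste0(path, ".geno"))
    if (is.null(groups)) groups <- rep("Pop", nrow(m))
    writeLines(paste(rownames(m), "U", groups), paste0(path, ".ind"))
    writeLines(
      paste(colnames(m), 1, format(seq_len(ncol(m)) * 1e-6), seq_len(ncol(m))),
      paste0(path, ".snp")
    )
    invisible(paste0(path, c(".geno", ".ind", ".snp")))
  } else {
    df <- data.frame(individual_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  }
}

#' Write an ancestry (Q) matrix
#'
#' One row per individual, `K` space-separated proportions printed with six
#' decimals, matching the `.Q` convention of admixture software.
#'
#' @param fit An `admixture_fit` or a plain numeric matrix with rows on the
#'   probability simplex.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_qmatrix <- function(fit, path) {
  q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  if (any(!is.finite(q))) stop("Q contains non-finite entries")
  if (any(abs(rowSums(q) - 1) > 1e-5)) stop("Q rows must sum to 1")
  writeLines(apply(q, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             path)
  invisible(path)
}

#' Read an ancestry (Q) matrix
#' @param path File written by [write_qmatrix()].
#' @return Numeric matrix, rows on the simplex.
#' @export
read_qmatrix <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write / read a label table
#'
#' Tab-separated with header `individual_id  group  true_theta`.
#'
#' @param labels A [label_table()].
#' @param path File path.
#' @return `write_labels` invisibly returns `path`; `read_labels` returns a
#'   [label_table()].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_table"))
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  label_table(df$individual_id, df$group, df$true_theta)
}
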