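#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix together with its identifiers,
#' species tag and normalization state. All downstream operations in the
#' package consume and produce this container.
#'
#' @param values Numeric matrix, genes in rows, samples (or cells) in
#'   columns. Dimnames, when present, must agree with `gene_ids` /
#'   `sample_ids`.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: rownames of `values`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: colnames of `values`).
#' @param species Either `"mouse"` or `"human"`.
#' @param state Either `"raw"` or `"zscored"`.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `species`, `state`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              species = c("human", "mouse"),
                              state = c("raw", "zscored")) {
  species <- match.arg(species)
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(gene_ids) || length(gene_ids) != nrow(values))
    stop("gene_ids must match the number of rows")
  if (is.null(sample_ids) || length(sample_ids) != ncol(values))
    stop("sample_ids must match the number of columns")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, species = species, state = state),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$species, x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample-wise z-score normalization
#'
#' Standardizes every sample (column) by its own mean and standard
#' deviation, so that each sample's expression values are on a common
#' scale regardless of platform or sequencing depth. Constant columns
#' cannot be standardized; they are set to all-zero and reported via a
#' warning (degenerate control samples occur on real arrays and should
#' not abort a run).
#'
#' @param m An [expression_matrix()] with `state = "raw"`.
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1).
#' @return An `expr_matrix` with `state = "zscored"`. Columns that were
#'   constant are listed in attribute `"constant_samples"`.
#' @export
zscore_samples <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(m, "expr_matrix"))
  if (m$state != "raw")
    stop("state mismatch: input is already z-scored")
  v <- m$values
  n <- nrow(v)
  mu <- colMeans(v)
  ctr <- sweep(v, 2L, mu, "-")
  ss <- colSums(ctr^2)
  denom <- if (sd_type == "population") n else n - 1L
  sdv <- sqrt(ss / denom)
  const <- sdv <= .Machine$double.eps * max(1, abs(mu)) * n
  sdv[const] <- 1
  z <- sweep(ctr, 2L, sdv, "/")
  if (any(const)) {
    z[, const] <- 0
    warning("constant sample(s) set to zero: ",
            paste(m$sample_ids[const], collapse = ", "))
  }
  out <- expression_matrix(z, m$gene_ids, m$sample_ids,
                           species = m$species, state = "zscored")
  attr(out, "constant_samples") <- m$sample_ids[const]
  out
}

#' Read an expression matrix from disk
#'
#' @param path File path. For `format = "mtx"` this is the MatrixMarket
#'   file; `genes.txt` and `samples.txt` sidecars are expected alongside
#'   it (one identifier per line).
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param species,state Passed to [expression_matrix()].
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, format = c("tsv", "csv", "mtx"),
                        species = "human", state = "raw") {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    side <- function(f) {
      p <- file.path(dirname(path), f)
      if (!file.exists(p)) stop("missing sidecar file: ", p)
      readLines(p)
    }
    return(expression_matrix(m, side("genes.txt"), side("samples.txt"),
                             species = species, state = state))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs a gene column and >= 1 sample")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- df[-1L]
  num <- suppressWarnings(lapply(vals, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(vals[[j]]) &
                   trimws(vals[[j]]) != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   vals[[j]][bad[1L]], genes[bad[1L]], names(vals)[j]))
  }
  m <- do.call(cbind, num)
  rownames(m) <- genes
  colnames(m) <- names(vals)
  expression_matrix(m, species = species, state = state)
}

#' Write an expression matrix to disk
#'
#' Round-trips with [read_matrix()]: identifiers exactly, values to
#' better than 1e-12 relative precision.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"` (MatrixMarket with
#'   `genes.txt`/`samples.txt` sidecars).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "expr_matrix"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(m$sample_ids, file.path(dirname(path), "samples.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene = m$gene_ids,
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", m$sample_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
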