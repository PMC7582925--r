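#' Construct a signature matrix
#'
#' Genes x cell-types matrix of mean expression profiles, the design
#' matrix E of the deconvolution model, with per-column provenance
#' (which dataset/species each column came from).
#'
#' @param values Numeric matrix, genes in rows, one column per cell
#'   type (dimnames required).
#' @param provenance Named character vector, one entry per column
#'   (default `"unknown"`).
#' @return A list of class `"signature_matrix"`.
#' @export
signature_matrix <- function(values, provenance = NULL) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-type columns")
  if (is.null(provenance))
    provenance <- stats::setNames(rep("unknown", ncol(values)),
                                  colnames(values))
  stopifnot(length(provenance) == ncol(values))
  names(provenance) <- colnames(values)
  structure(list(values = values, cell_types = colnames(values),
                 gene_ids = rownames(values), provenance = provenance),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  src <- split(names(x$provenance), x$provenance)
  for (s in names(src))
    cat(sprintf("  %s: %s\n", s, paste(src[[s]], collapse = ", ")))
  invisible(x)
}

#' Build cell-type signatures from an annotated reference
#'
#' The signature of cell type t is the per-gene mean over all cells
#' annotated t, restricted to the supplied gene set.
#'
#' @param ref An `expr_matrix` (cells in columns).
#' @param annot data.frame with columns `cell_id`, `cell_type`.
#' @param genes Gene ids to keep (default: all genes of `ref`).
#' @param provenance Label recorded for every column (default: the
#'   species of `ref`).
#' @return A [signature_matrix()].
#' @export
build_signatures <- function(ref, annot, genes = ref$gene_ids,
                             provenance = ref$species) {
  stopifnot(inherits(ref, "expr_matrix"))
  if (!all(annot$cell_id %in% ref$sample_ids))
    stop("annotated cell id missing from matrix: ",
         paste(utils::head(setdiff(annot$cell_id, ref$sample_ids), 3),
               collapse = ", "))
  if (!all(genes %in% ref$gene_ids))
    stop("unknown gene id(s) requested")
  types <- unique(annot$cell_type)
  v <- ref$values[genes, , drop = FALSE]
  sig <- vapply(types, function(t) {
    cells <- annot$cell_id[annot$cell_type == t]
    rowMeans(v[, cells, drop = FALSE])
  }, numeric(length(genes)))
  sig <- matrix(sig, nrow = length(genes),
                dimnames = list(genes, types))
  signature_matrix(sig, stats::setNames(rep(provenance, length(types)),
                                        types))
}

#' Complete a human signature matrix with mouse cell types
#'
#' Human cell-type columns are kept untouched; cell types absent from
#' the human reference are filled in with the corresponding mouse
#' signature column, translated to human gene identifiers through the
#' homolog map. Gene rows are restricted to the homolog-shared set and
#' column order follows `full_types` exactly.
#'
#' @param human_sig,mouse_sig [signature_matrix()] objects (human gene
#'   ids and mouse gene ids respectively).
#' @param map A [homolog_map()].
#' @param full_types The complete ordered cell-type list the output
#'   must contain (default [brain_cell_types()]).
#' @return A `signature_matrix` over the shared genes with provenance
#'   `"human"` / `"mouse"` per column.
#' @export
complete_with_mouse <- function(human_sig, mouse_sig, map,
                                full_types = brain_cell_types()) {
  stopifnot(inherits(human_sig, "signature_matrix"),
            inherits(mouse_sig, "signature_matrix"),
            inherits(map, "homolog_map"))
  missing_both <- setdiff(full_types,
                          union(human_sig$cell_types,
                                mouse_sig$cell_types))
  if (length(missing_both))
    stop("cell type(s) absent from both references: ",
         paste(missing_both, collapse = ", "))
  pairs <- map$pairs[map$pairs$mouse_gene %in% mouse_sig$gene_ids &
                       map$pairs$human_gene %in% human_sig$gene_ids, ]
  if (nrow(pairs) == 0L) stop("no joinable genes")
  out <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(full_types),
                dimnames = list(pairs$human_gene, full_types))
  prov <- stats::setNames(character(length(full_types)), full_types)
  for (t in full_types) {
    if (t %in% human_sig$cell_types) {
      out[, t] <- human_sig$values[pairs$human_gene, t]
      prov[t] <- unname(human_sig$provenance[t])
    } else {
      out[, t] <- mouse_sig$values[pairs$mouse_gene, t]
      prov[t] <- unname(mouse_sig$provenance[t])
    }
  }
  signature_matrix(out, prov)
}

#' Translate a signature matrix across species
#'
#' Renames the gene rows of a mouse signature to their human homolog
#' symbols (or vice versa), dropping genes without a mapping.
#'
#' @param sig A [signature_matrix()].
#' @param map A [homolog_map()].
#' @param to Target gene namespace, `"human"` or `"mouse"`.
#' @return A `signature_matrix` on the mapped genes.
#' @export
translate_signature <- function(sig, map, to = c("human", "mouse")) {
  to <- match.arg(to)
  stopifnot(inherits(sig, "signature_matrix"),
            inherits(map, "homolog_map"))
  from_col <- if (to == "human") "mouse_gene" else "human_gene"
  to_col <- if (to == "human") "human_gene" else "mouse_gene"
  pairs <- map$pairs[map$pairs[[from_col]] %in% sig$gene_ids, ]
  if (nrow(pairs) == 0L) stop("no joinable genes")
  v <- sig$values[pairs[[from_col]], , drop = FALSE]
  rownames(v) <- pairs[[to_col]]
  signature_matrix(v, sig$provenance)
}

#' Write / read a signature matrix as TSV
#'
#' The TSV carries one `#provenance:` comment line per column before
#' the header.
#' @param sig A `signature_matrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_signatures <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in sig$cell_types)
    writeLines(sprintf("#provenance: %s\t%s", t, sig$provenance[t]), con)
  df <- data.frame(gene = sig$gene_ids, sig$values, check.names = FALSE)
  colnames(df) <- c("gene", sig$cell_types)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  prov_lines <- grep("^#provenance:", lines, value = TRUE)
  prov <- NULL
  if (length(prov_lines)) {
    parts <- strsplit(sub("^#provenance: ", "", prov_lines), "\t")
    prov <- stats::setNames(vapply(parts, `[`, "", 2L),
                            vapply(parts, `[`, "", 1L))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  signature_matrix(m, provenance = prov[colnames(m)])
}
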