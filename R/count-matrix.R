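#' Sparse UMI count matrix with modality tag
#'
#' The pipeline's central container: a sparse non-negative integer matrix of
#' UMI counts with barcodes as rows and genes as columns, tagged with the
#' assay modality (`"cell"` for whole protoplasts/cells, `"nucleus"` for
#' isolated nuclei) and a library identifier.
#'
#' @param counts a matrix or [Matrix::sparseMatrix()] of non-negative
#'   integer counts, barcodes x genes. Dimnames supply barcode and gene ids
#'   unless given explicitly.
#' @param barcodes character vector of unique barcode ids (rows)
#' @param genes character vector of unique gene ids (columns)
#' @param modality `"cell"` or `"nucleus"`
#' @param library_id free-text library label
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `modality` and `library_id`.
#' @examples
#' m <- count_matrix(matrix(0:5, 2, 3,
#'                          dimnames = list(c("b1", "b2"), c("g1", "g2", "g3"))),
#'                   modality = "cell")
#' dim(m)
#' @export
count_matrix <- function(counts, barcodes = rownames(counts),
                         genes = colnames(counts),
                         modality = c("cell", "nucleus"),
                         library_id = "lib1") {
  modality <- match.arg(modality)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) || is.null(genes))
    stop_format("count_matrix: barcodes and genes must be provided ",
                "(as dimnames or arguments)")
  barcodes <- as.character(barcodes)
  genes <- as.character(genes)
  if (length(barcodes) != nrow(counts) || length(genes) != ncol(counts))
    stop_format("count_matrix: label lengths (", length(barcodes), " x ",
                length(genes), ") do not match matrix dimensions (",
                nrow(counts), " x ", ncol(counts), ")")
  if (anyDuplicated(barcodes))
    stop_format("count_matrix: duplicate barcodes, e.g. '",
                barcodes[duplicated(barcodes)][1], "'")
  if (anyDuplicated(genes))
    stop_format("count_matrix: duplicate gene ids, e.g. '",
                genes[duplicated(genes)][1], "'")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop_format("count_matrix: entries must be non-negative integers")
  dimnames(counts) <- list(barcodes, genes)
  structure(list(counts = counts, modality = modality,
                 library_id = library_id),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Barcode and gene ids of a count matrix
#' @param x a `count_matrix`
#' @return character vector of ids
#' @export
barcodes <- function(x) rownames(x$counts)

#' @rdname barcodes
#' @export
genes <- function(x) colnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d barcodes x %d genes, modality=%s, library=%s\n",
              nrow(x$counts), ncol(x$counts), x$modality, x$library_id))
  cat(sprintf("  total UMIs: %s; nonzero entries: %s\n",
              format(sum(x$counts), big.mark = ","),
              format(length(x$counts@x), big.mark = ",")))
  invisible(x)
}

#' Subset a count matrix by barcodes and/or genes
#' @param x a `count_matrix`
#' @param i barcode index/names (rows); missing keeps all
#' @param j gene index/names (columns); missing keeps all
#' @param ... ignored
#' @return a `count_matrix`
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  cts <- x$counts
  if (!missing(i)) cts <- cts[i, , drop = FALSE]
  if (!missing(j)) cts <- cts[, j, drop = FALSE]
  count_matrix(cts, modality = x$modality, library_id = x$library_id)
}
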