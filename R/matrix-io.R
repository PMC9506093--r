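#' Read a 10x-style MTX bundle
#'
#' Reads `matrix.mtx(.gz)`, `barcodes.tsv(.gz)` and `features.tsv(.gz)` from
#' a directory. The on-disk matrix may store genes as rows (the Cell Ranger
#' convention) or barcodes as rows; either way the returned object is
#' normalized to barcodes x genes. MatrixMarket indices are 1-based on disk;
#' all internal indexing is ordinary R indexing — the conversion never
#' leaves this module.
#'
#' @param dir directory containing the three files
#' @param dialect `"genes_as_rows"` (10x convention, default) or
#'   `"barcodes_as_rows"` for the orientation of the on-disk matrix
#' @param modality `"cell"` or `"nucleus"`
#' @param library_id library label attached to the result
#' @return a [count_matrix()]
#' @export
read_10x <- function(dir, dialect = c("genes_as_rows", "barcodes_as_rows"),
                     modality = c("cell", "nucleus"),
                     library_id = basename(dir)) {
  dialect <- match.arg(dialect)
  modality <- match.arg(modality)
  mtx <- find_bundle_file(dir, "matrix.mtx")
  bcf <- find_bundle_file(dir, "barcodes.tsv")
  ftf <- find_bundle_file(dir, "features.tsv")
  m <- tryCatch(Matrix::readMM(open_maybe_gz(mtx)),
                error = function(e) stop_format("read_10x: cannot parse '",
                                                mtx, "': ", conditionMessage(e)))
  bc <- read_tsv_col(bcf, 1L)
  ft <- utils::read.table(open_maybe_gz(ftf), sep = "\t",
                          colClasses = "character", quote = "",
                          col.names = paste0("V", 1:3), fill = TRUE,
                          header = FALSE)
  if (dialect == "genes_as_rows") m <- Matrix::t(m)
  if (nrow(m) != length(bc))
    stop_format("read_10x: ", mtx, " has ", nrow(m),
                " barcode entries but ", bcf, " lists ", length(bc))
  if (ncol(m) != nrow(ft))
    stop_format("read_10x: ", mtx, " has ", ncol(m),
                " gene entries but ", ftf, " lists ", nrow(ft))
  count_matrix(m, barcodes = bc, genes = ft[[1L]],
               modality = modality, library_id = library_id)
}

#' Write a count matrix as a 10x-style MTX bundle
#'
#' @param matrix a [count_matrix()]
#' @param dir output directory, created if absent
#' @param dialect orientation of the on-disk matrix (see [read_10x()])
#' @return invisibly, the paths written
#' @export
write_10x <- function(matrix, dir,
                      dialect = c("genes_as_rows", "barcodes_as_rows")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(matrix, "count_matrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("write_10x: cannot create directory '", dir, "'")
  m <- matrix$counts
  if (dialect == "genes_as_rows") m <- Matrix::t(m)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(m, paths[1])
  writeLines(barcodes(matrix), paths[2])
  utils::write.table(
    data.frame(id = genes(matrix), name = genes(matrix),
               type = "Gene Expression"),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read an interaction gene-pair table
#'
#' Reads a two-column TSV of (geneA, geneB) interaction pairs and restricts
#' it to a known gene universe. Pairs are kept in file order and within-pair
#' order is preserved exactly: downstream the two members define the x and y
#' axes of the per-cluster correlation, so order is meaningful. Dropped rows
#' (unknown gene, self-pair, exact duplicate — first occurrence kept) are
#' itemized in the attached report.
#'
#' @param file path to a TSV with at least two columns (no header expected;
#'   a `geneA`/`geneB` header line is tolerated and skipped)
#' @param genes character vector: the gene-id universe (e.g. `genes(mat)`)
#' @param source free-text provenance label stored on the table
#' @return a `pair_table`: data.frame with columns `geneA`, `geneB`, plus
#'   attributes `source` and `report` (data.frame of dropped pairs + reason)
#' @export
read_pairs <- function(file, genes, source = file) {
  raw <- tryCatch(
    utils::read.table(open_maybe_gz(file), sep = "\t", quote = "",
                      colClasses = "character", header = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop_format("read_pairs: '", file, "' is empty or ",
                                    "unreadable: ", conditionMessage(e)))
  if (nrow(raw) == 0) stop_format("read_pairs: '", file, "' is empty")
  if (ncol(raw) < 2)
    stop_format("read_pairs: '", file, "' has fewer than 2 columns")
  if (identical(tolower(raw[1, 1]), "genea")) raw <- raw[-1, , drop = FALSE]
  pair_table(raw[[1]], raw[[2]], genes = genes, source = source)
}

#' Construct and validate a gene-pair table
#'
#' @param geneA,geneB character vectors of equal length
#' @param genes optional gene universe; pairs with members outside it are
#'   dropped and reported
#' @param source provenance label
#' @return a `pair_table` (see [read_pairs()])
#' @export
pair_table <- function(geneA, geneB, genes = NULL, source = "constructed") {
  df <- data.frame(geneA = as.character(geneA), geneB = as.character(geneB),
                   stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(df))
  if (!is.null(genes)) {
    bad <- !(df$geneA %in% genes) | !(df$geneB %in% genes)
    reason[bad] <- "unknown_gene"
  }
  self <- is.na(reason) & df$geneA == df$geneB
  reason[self] <- "self_pair"
  key <- paste(df$geneA, df$geneB, sep = "\r")
  dup <- is.na(reason) & duplicated(key)
  reason[dup] <- "duplicate"
  report <- cbind(df[!is.na(reason), , drop = FALSE],
                  reason = reason[!is.na(reason)])
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  rownames(report) <- NULL
  structure(out, source = source, report = report,
            class = c("pair_table", "data.frame"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d pairs over %d genes (source: %s; %d dropped)\n",
              nrow(x), length(unique(c(x$geneA, x$geneB))),
              attr(x, "source"), nrow(attr(x, "report"))))
  invisible(x)
}

#' Read a barcode-to-cluster assignment table
#'
#' Two-column TSV: barcode, cluster id. Cluster ids are opaque strings
#' (numeric and letter schemes both occur in practice). Whether each barcode
#' exists in a companion count matrix is checked when the two are joined,
#' not here.
#'
#' @param file TSV path
#' @return a `cluster_assignment`: list with `labels` (named character
#'   vector, names = barcodes) and `cluster_ids` (ordered unique ids)
#' @export
read_clusters <- function(file) {
  raw <- utils::read.table(open_maybe_gz(file), sep = "\t", quote = "",
                           colClasses = "character", header = FALSE)
  if (ncol(raw) < 2) stop_format("read_clusters: '", file, "' needs 2 columns")
  cluster_assignment(stats::setNames(raw[[2]], raw[[1]]))
}

#' Construct a cluster assignment
#' @param labels named character vector: names are barcodes, values cluster ids
#' @return a `cluster_assignment`
#' @export
cluster_assignment <- function(labels) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop_format("cluster_assignment: every entry needs a barcode name")
  if (anyDuplicated(names(labels)))
    stop_format("cluster_assignment: duplicate barcode '",
                names(labels)[duplicated(names(labels))][1], "'")
  if (any(is.na(labels) | !nzchar(labels)))
    stop_format("cluster_assignment: empty cluster id for barcode '",
                names(labels)[is.na(labels) | !nzchar(labels)][1], "'")
  structure(list(labels = labels, cluster_ids = unique(unname(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d barcodes in %d clusters\n",
              length(x$labels), length(x$cluster_ids)))
  invisible(x)
}

#' Read a marker table
#'
#' Two-column TSV: gene id, cell-type label. A gene may mark several cell
#' types, but must be unique within a cell type.
#'
#' @param file TSV path
#' @return a `marker_table`: data.frame with columns `gene`, `cell_type`
#' @export
read_markers <- function(file) {
  raw <- utils::read.table(open_maybe_gz(file), sep = "\t", quote = "",
                           colClasses = "character", header = FALSE)
  if (ncol(raw) < 2) stop_format("read_markers: '", file, "' needs 2 columns")
  marker_table(raw[[1]], raw[[2]])
}

#' Construct a marker table
#' @param gene,cell_type character vectors of equal length
#' @return a `marker_table`
#' @export
marker_table <- function(gene, cell_type) {
  df <- data.frame(gene = as.character(gene),
                   cell_type = as.character(cell_type))
  key <- paste(df$gene, df$cell_type, sep = "\r")
  if (anyDuplicated(key))
    stop_format("marker_table: duplicate marker '",
                df$gene[duplicated(key)][1], "' within a cell type")
  structure(df, class = c("marker_table", "data.frame"))
}

# -- small file helpers -------------------------------------------------------

find_bundle_file <- function(dir, base) {
  for (cand in file.path(dir, c(base, paste0(base, ".gz"))))
    if (file.exists(cand)) return(cand)
  stop_format("missing '", base, "(.gz)' in '", dir, "'")
}

open_maybe_gz <- function(path) {
  if (!file.exists(path)) stop_format("file not found: '", path, "'")
  if (endsWith(path, ".gz")) gzfile(path) else path
}

read_tsv_col <- function(path, col) {
  x <- readLines(open_maybe_gz(path))
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), col)
}
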