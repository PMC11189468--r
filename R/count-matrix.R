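#' Count matrix container
#'
#' Bundles a genes-by-patients matrix of non-negative integer read counts with
#' its per-gene annotation. Rows are genes, columns are patients; the
#' annotation carries the chromosome label used by [filter_genes()] to drop
#' sex-linked (`"X"`/`"Y"`) and unannotated (`NA`) features.
#'
#' @param counts numeric matrix, genes x patients, non-negative integers with
#'   unique row and column names.
#' @param genes data frame with columns `gene_id` and `chromosome`
#'   (`"1"`..`"22"`, `"X"`, `"Y"`, or `NA` for unannotated). Defaults to an
#'   all-unknown annotation built from the row names.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `genes` (a tibble, one row per matrix row, same order).
#' @examples
#' m <- matrix(rpois(6, 10), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("p1", "p2", "p3")))
#' cm <- count_matrix(m, data.frame(gene_id = c("g1", "g2"),
#'                                  chromosome = c("1", "X")))
#' dim(cm)
#' @export
count_matrix <- function(counts, genes = NULL) {
  abort_if(!is.matrix(counts) || !is.numeric(counts),
           "`counts` must be a numeric matrix (genes x patients).")
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "`counts` must have gene row names and patient column names.")
  abort_if(anyDuplicated(rownames(counts)) > 0, "duplicate gene ids in `counts`.")
  abort_if(anyDuplicated(colnames(counts)) > 0, "duplicate patient ids in `counts`.")
  abort_if(any(!is.finite(counts)) || any(counts < 0),
           "`counts` must be finite and non-negative.")
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = rownames(counts),
                            chromosome = NA_character_)
  }
  genes <- tibble::as_tibble(genes)
  abort_if(!all(c("gene_id", "chromosome") %in% names(genes)),
           "`genes` needs columns `gene_id` and `chromosome`.")
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  abort_if(anyNA(genes$gene_id), "`genes` must annotate every row of `counts`.")
  genes$chromosome <- as.character(genes$chromosome)
  structure(list(counts = counts, genes = genes), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d patients\n", nrow(x$counts), ncol(x$counts)))
  chr <- x$genes$chromosome
  cat(sprintf("  sex-linked: %d, unannotated: %d\n",
              sum(chr %in% c("X", "Y")), sum(is.na(chr))))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x)
}

#' Read and write cohort data in plain-text formats
#'
#' `write_cohort_data()` writes a simulated (or assembled) cohort to disk:
#' counts as TSV (gene_id column + one column per patient) and MatrixMarket,
#' gene annotation TSV, cohort table CSV, and — for simulated cohorts — the
#' ground truth as JSON. `read_count_matrix()` and `read_cohort_table()`
#' load the same formats back.
#'
#' @param x a list with elements `counts` (a [count_matrix()]), `cohort`
#'   (data frame), and optionally `truth`, as returned by [simulate_cohort()].
#' @param dir output directory, created if missing.
#' @return `write_cohort_data()` returns the directory path invisibly.
#' @export
write_cohort_data <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- as_count_matrix(x$counts)
  tsv <- data.frame(gene_id = rownames(cm$counts), cm$counts, check.names = FALSE)
  utils::write.table(tsv, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.table(as.data.frame(cm$genes), file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(x$cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(x$truth)) {
    jsonlite::write_json(unclass(x$truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort_data
#' @param counts_tsv,genes_tsv,path file paths.
#' @export
read_count_matrix <- function(counts_tsv, genes_tsv = NULL) {
  tab <- utils::read.delim(counts_tsv, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  genes <- if (!is.null(genes_tsv)) {
    utils::read.delim(genes_tsv, colClasses = "character")
  }
  count_matrix(m, genes)
}

#' @rdname write_cohort_data
#' @export
read_cohort_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
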