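## Readers and writers for the plain-text interchange formats: headered
## TSV for library / sample sheet / counts / metadata / survival tables,
## MatrixMarket triplets for cell matrices, GMT for gene sets.

read_tsv_df <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a guide library TSV
#'
#' Columns: guide_id, gene, protospacer, is_ntc.
#' @param path File path.
#' @return The validated library data frame.
#' @export
read_guide_library <- function(path) {
  validate_guide_library(read_tsv_df(path))
}

#' @rdname read_guide_library
#' @param lib Guide library data frame.
#' @export
write_guide_library <- function(lib, path) {
  write_tsv_df(validate_guide_library(lib), path)
}

#' Read / write a sample sheet TSV
#'
#' Columns: sample_id, genotype, stage, mouse_id, barcode.
#' @param path File path.
#' @return The validated sample sheet.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read_tsv_df(path))
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_df(validate_sample_sheet(sheet), path)
}

#' Read / write a guide x sample count matrix TSV
#'
#' First column \code{guide_id}, remaining columns one per sample.
#' @param path File path.
#' @return Integer matrix with guide rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_df(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_count_matrix
#' @param counts Count matrix.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_df(df, path)
}

#' Read / write a survival table TSV
#'
#' Columns: subject_id, time, event, group.
#' @param path File path.
#' @return Validated survival table data frame.
#' @export
read_survival_table <- function(path) {
  validate_survival_table(read_tsv_df(path))
}

#' @rdname read_survival_table
#' @param tab Survival table.
#' @export
write_survival_table <- function(tab, path) {
  write_tsv_df(validate_survival_table(tab), path)
}

#' Write a cell matrix as MatrixMarket triplet plus metadata TSV
#'
#' Emits \code{<prefix>.mtx} (genes x cells, MatrixMarket coordinate
#' format), \code{<prefix>.genes.tsv}, \code{<prefix>.cells.tsv} and
#' \code{<prefix>.meta.tsv}.
#'
#' @param m Gene x cell matrix.
#' @param meta Per-cell metadata data frame (first column cell ids).
#' @param prefix Output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_cell_matrix <- function(m, meta, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".genes.tsv"))
  writeLines(colnames(m), paste0(prefix, ".cells.tsv"))
  write_tsv_df(meta, paste0(prefix, ".meta.tsv"))
  invisible(prefix)
}

#' Read a cell matrix written by \code{\link{write_cell_matrix}}
#'
#' @param prefix Path prefix.
#' @return List: \code{m} (dense gene x cell matrix), \code{meta}.
#' @export
read_cell_matrix <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".genes.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".cells.tsv"))
  list(m = m, meta = read_tsv_df(paste0(prefix, ".meta.tsv")))
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated name,
#' description, then member symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
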