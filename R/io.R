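# Tabular readers/writers for the pipeline's plain-text dialects.

#' Read an expression matrix from tab-separated text
#'
#' First column = gene symbol, header row = sample ids, values = linear
#' intensities.
#'
#' @param path TSV file.
#' @return numeric matrix genes x samples.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  .check_expression_matrix(m)
}

#' Write an expression matrix as tab-separated text
#' @param x matrix genes x samples.
#' @param path output TSV.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample labels (two-column TSV: sample_id, class)
#' @param path TSV file with classes `cancer`/`control`.
#' @return named character vector.
#' @export
read_sample_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_sample_labels
#' @param labels named character vector.
#' @export
write_sample_labels <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels), class = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an SL gene-pair list (two-column TSV, optional provenance column)
#' @param path TSV file.
#' @return data frame `gene_a`, `gene_b` (+ `provenance`), canonicalized
#'   via [sl_pair_table()].
#' @export
read_sl_pairs <- function(path) {
  if (!file.exists(path)) stop("SL pair file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  if (ncol(df) >= 3) names(df)[3] <- "provenance"
  sl_pair_table(df)
}

#' @rdname read_sl_pairs
#' @param pairs data frame.
#' @export
write_sl_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a core-level IHC score table (CSV)
#' @param path CSV with columns patient_id, stain_id, core_id, intensity,
#'   percent.
#' @return data frame.
#' @export
read_ihc_scores <- function(path) {
  if (!file.exists(path)) stop("IHC score file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a clinical table (CSV)
#' @param path CSV with at least patient_id, time, event, stage.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a screening stage table as TSV
#' @param x data frame (or `sl_screen` / `marker_screen` results).
#' @param path output TSV.
#' @export
write_stage_table <- function(x, path) {
  if (inherits(x, "marker_screen")) x <- x$results
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
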