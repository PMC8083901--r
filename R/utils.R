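# internal helpers shared across modules

# run `expr` under a given RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream of per-task seeds from one master seed, kept inside 32-bit range
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.check_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  x
}

# normalize sample labels to a named character vector with levels cancer/control
.check_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      stop("label table needs columns sample_id and class", call. = FALSE)
    labels <- setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
  }
  if (is.null(names(labels)))
    stop("labels must be named by sample id", call. = FALSE)
  labels <- labels[sample_ids]
  if (anyNA(labels) || !all(sample_ids %in% names(labels)))
    stop("every sample in the matrix must be labeled", call. = FALSE)
  if (!all(labels %in% c("cancer", "control")))
    stop("labels must be 'cancer' or 'control'", call. = FALSE)
  if (sum(labels == "cancer") < 2L || sum(labels == "control") < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
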