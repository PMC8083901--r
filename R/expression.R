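#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common empirical distribution: the
#' reference is the row-wise mean of the per-column sorted values, and each
#' value is replaced by the reference value at its within-column rank. Tied
#' values receive the average of the reference values spanned by their tied
#' ranks, so the operation is idempotent.
#'
#' @param x numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames); all values finite.
#' @return a matrix of the same shape; every column shares one sorted value
#'   multiset and within-column ranks are preserved.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(x) {
  x <- .check_expression_matrix(x)
  if (ncol(x) == 1L) {
    warning("single sample: quantile normalization is a no-op")
    return(x)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    approx(seq_along(ref), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Log2 ratios of cancer samples versus averaged controls
#'
#' For each gene, the control samples are averaged on the linear intensity
#' scale and each cancer sample's intensity is expressed as
#' log2(intensity / control mean). Only cancer columns are returned.
#'
#' @param x positive numeric matrix, genes x samples.
#' @param labels sample class labels: either a named character vector
#'   (names = sample ids, values `"cancer"`/`"control"`) or a two-column
#'   data frame `(sample_id, class)`.
#' @return numeric matrix genes x cancer samples of log2 ratios, with
#'   attribute `"control_mean"` (per-gene control means).
#' @export
log_ratio_vs_controls <- function(x, labels) {
  x <- .check_expression_matrix(x)
  labels <- .check_labels(labels, colnames(x))
  if (any(x <= 0))
    stop("intensities must be positive to take log ratios", call. = FALSE)
  ctrl <- names(labels)[labels == "control"]
  canc <- names(labels)[labels == "cancer"]
  ctrl_mean <- rowMeans(x[, ctrl, drop = FALSE])
  bad <- ctrl_mean <= 0
  if (any(bad))
    stop("non-positive control mean for gene(s): ",
         paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  ratios <- log2(sweep(x[, canc, drop = FALSE], 1L, ctrl_mean, "/"))
  attr(ratios, "control_mean") <- ctrl_mean
  ratios
}

#' Three-level regulation calls at a fold-change cutoff
#'
#' A gene is called `up` in a cancer sample when its log2 ratio is at least
#' `log2(fold_cutoff)`, `down` when at most `-log2(fold_cutoff)`, and
#' `neutral` otherwise. Boundaries are inclusive.
#'
#' @param ratios log2-ratio matrix from [log_ratio_vs_controls()].
#' @param fold_cutoff fold-change cutoff on the linear scale, > 1
#'   (default 1.5; a relaxed 1.4 is conventional for validation cohorts).
#' @return character matrix of `"up"`/`"down"`/`"neutral"` with attribute
#'   `"fold_cutoff"`.
#' @export
call_regulation <- function(ratios, fold_cutoff = 1.5) {
  if (!is.numeric(fold_cutoff) || length(fold_cutoff) != 1L || fold_cutoff <= 1)
    stop("`fold_cutoff` must be a single number > 1", call. = FALSE)
  thr <- log2(fold_cutoff)
  calls <- matrix("neutral", nrow(ratios), ncol(ratios), dimnames = dimnames(ratios))
  calls[ratios >= thr] <- "up"
  calls[ratios <= -thr] <- "down"
  attr(calls, "fold_cutoff") <- fold_cutoff
  calls
}

#' Joint co-expression pattern fractions for one gene pair
#'
#' Over the cancer samples, counts the ordered joint regulation patterns
#' (up,up), (up,down), (down,up), (down,down) for genes `gene_a`, `gene_b`
#' and divides by the total number of cancer samples; samples where either
#' gene is neutral count only in the denominator.
#'
#' @param calls regulation-call matrix from [call_regulation()].
#' @param gene_a,gene_b gene ids (rownames of `calls`).
#' @return one-row data frame with `gene_a`, `gene_b`, `f_uu`, `f_ud`,
#'   `f_du`, `f_dd`, `n_samples`.
#' @export
pattern_fractions <- function(calls, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(calls))
      stop("gene not present in calls: ", g, call. = FALSE)
  a <- calls[gene_a, ]
  b <- calls[gene_b, ]
  n <- length(a)
  data.frame(
    gene_a = gene_a, gene_b = gene_b,
    f_uu = sum(a == "up" & b == "up") / n,
    f_ud = sum(a == "up" & b == "down") / n,
    f_du = sum(a == "down" & b == "up") / n,
    f_dd = sum(a == "down" & b == "down") / n,
    n_samples = n,
    stringsAsFactors = FALSE
  )
}

#' Pattern fractions for a table of gene pairs
#'
#' @param calls regulation-call matrix.
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @return data frame, one row per pair, as in [pattern_fractions()].
#' @export
pattern_fraction_table <- function(calls, pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  out <- lapply(seq_len(nrow(pairs)), function(i)
    pattern_fractions(calls, pairs$gene_a[i], pairs$gene_b[i]))
  do.call(rbind, out)
}

# pattern fraction of one pair given raw intensities and a control index set;
# shared by the observed statistic and the permutation null
.pair_fraction <- function(va, vb, ctrl_idx, pattern, thr) {
  ma <- mean(va[ctrl_idx])
  mb <- mean(vb[ctrl_idx])
  ra <- log2(va[-ctrl_idx] / ma)
  rb <- log2(vb[-ctrl_idx] / mb)
  a_up <- ra >= thr; a_dn <- ra <= -thr
  b_up <- rb >= thr; b_dn <- rb <= -thr
  hits <- switch(pattern,
    uu = a_up & b_up, ud = a_up & b_dn,
    du = a_dn & b_up, dd = a_dn & b_dn,
    stop("pattern must be one of uu/ud/du/dd", call. = FALSE))
  sum(hits) / length(ra)
}

#' Permutation p-value for a co-expression pattern fraction
#'
#' Generates the null distribution of a pattern fraction by repeatedly
#' relabelling which samples form the control set (keeping the class sizes
#' fixed), recomputing the log ratios, regulation calls, and the pattern
#' fraction over the relabelled cancer set. The upper-tail p-value uses the
#' add-one estimator `(1 + #{permuted >= observed}) / (n_perm + 1)`, so p is
#' never exactly zero.
#'
#' @param x positive expression matrix (genes x samples), typically already
#'   quantile-normalized (normalization is label-free, so it is not redone
#'   per rearrangement).
#' @param labels sample labels as in [log_ratio_vs_controls()].
#' @param gene_a,gene_b the gene pair.
#' @param pattern one of `"uu"`, `"ud"`, `"du"`, `"dd"`.
#' @param n_perm number of random rearrangements (default 10000).
#' @param seed RNG seed; identical inputs and seed give an identical p.
#' @param fold_cutoff fold-change cutoff for the regulation calls.
#' @param exact enumerate *all* control-set choices instead of sampling
#'   (only sensible for small cohorts; refuses more than 50000 sets). The
#'   exact p is `#\{fraction >= observed\} / #sets` — no add-one correction,
#'   since the full null distribution is available.
#' @return the permutation p-value, with attributes `"observed"` (observed
#'   fraction) and `"n_perm"`.
#' @export
permutation_pvalue <- function(x, labels, gene_a, gene_b,
                               pattern = c("uu", "ud", "du", "dd"),
                               n_perm = 10000, seed = 20210415,
                               fold_cutoff = 1.5, exact = FALSE) {
  pattern <- match.arg(pattern)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  x <- .check_expression_matrix(x)
  labels <- .check_labels(labels, colnames(x))
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(x)) stop("gene not present in matrix: ", g, call. = FALSE)
  thr <- log2(fold_cutoff)
  n <- ncol(x)
  n_ctrl <- sum(labels == "control")
  if (n_ctrl >= n) stop("control class size incompatible with matrix", call. = FALSE)
  va <- x[gene_a, ]
  vb <- x[gene_b, ]
  obs <- .pair_fraction(va, vb, which(labels == "control"), pattern, thr)
  if (exact) {
    if (choose(n, n_ctrl) > 50000)
      stop("too many control-set choices for exact enumeration", call. = FALSE)
    sets <- combn(n, n_ctrl)
    f <- apply(sets, 2L, function(idx) .pair_fraction(va, vb, idx, pattern, thr))
    p <- mean(f >= obs)
    attr(p, "observed") <- obs
    attr(p, "n_perm") <- ncol(sets)
    return(p)
  }
  hits <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n_ctrl)
      if (.pair_fraction(va, vb, idx, pattern, thr) >= obs) count <- count + 1L
    }
    count
  })
  p <- (1 + hits) / (n_perm + 1)
  attr(p, "observed") <- obs
  attr(p, "n_perm") <- n_perm
  p
}

#' Screen a table of SL gene pairs against an expression cohort
#'
#' End-to-end screening stage: quantile normalization (optional), log ratios
#' versus averaged controls, regulation calls at `fold_cutoff`, the four
#' pattern fractions per pair, permutation p-values for the requested
#' patterns, and Storey q-values per pattern across pairs.
#'
#' @param x positive expression matrix, genes x samples.
#' @param labels sample labels (`"cancer"`/`"control"`).
#' @param pairs data frame of candidate pairs (`gene_a`, `gene_b`); pairs
#'   with genes absent from the matrix are dropped with a warning; self-pairs
#'   are rejected; duplicated unordered pairs are collapsed keeping the first
#'   orientation seen.
#' @param fold_cutoff linear fold-change cutoff (default 1.5).
#' @param patterns patterns to test by permutation (default `c("uu","du")`,
#'   the patterns used for panel selection; any subset of the four).
#' @param n_perm permutations per test.
#' @param seed master seed; per-pair seeds are derived from it.
#' @param normalize quantile-normalize first (default TRUE).
#' @return an object of class `sl_screen`: a data frame with the pair, the
#'   four fractions, `p_<pattern>` and `q_<pattern>` columns, and
#'   `n_samples`.
#' @export
screen_sl_pairs <- function(x, labels, pairs, fold_cutoff = 1.5,
                            patterns = c("uu", "du"), n_perm = 10000,
                            seed = 20210415, normalize = TRUE) {
  x <- .check_expression_matrix(x)
  patterns <- match.arg(patterns, c("uu", "ud", "du", "dd"), several.ok = TRUE)
  pairs <- sl_pair_table(pairs)
  keep <- pairs$gene_a %in% rownames(x) & pairs$gene_b %in% rownames(x)
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) dropped: gene(s) absent from the matrix")
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no screenable pairs", call. = FALSE)
  if (normalize) x <- quantile_normalize(x)
  ratios <- log_ratio_vs_controls(x, labels)
  calls <- call_regulation(ratios, fold_cutoff)
  res <- pattern_fraction_table(calls, pairs)
  seeds <- derive_seeds(seed, nrow(pairs) * length(patterns))
  k <- 0L
  for (pat in patterns) {
    pv <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      k <- k + 1L
      pv[i] <- permutation_pvalue(x, labels, pairs$gene_a[i], pairs$gene_b[i],
                                  pattern = pat, n_perm = n_perm,
                                  seed = seeds[k], fold_cutoff = fold_cutoff)
    }
    res[[paste0("p_", pat)]] <- pv
    res[[paste0("q_", pat)]] <- storey_qvalues(pv)
  }
  attr(res, "fold_cutoff") <- fold_cutoff
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("sl_screen", "data.frame")
  res
}

#' @export
print.sl_screen <- function(x, ...) {
  cat("SL pair expression screen: ", nrow(x), " pairs over ",
      x$n_samples[1], " cancer samples (fold cutoff ",
      attr(x, "fold_cutoff"), ", ", attr(x, "n_perm"), " permutations)\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3, row.names = FALSE)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more pairs\n", sep = "")
  invisible(x)
}

#' Validate and canonicalize an SL pair table
#'
#' Drops self-pairs (with a warning) and collapses duplicated unordered
#' pairs, keeping the orientation of the first occurrence.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b` (an optional
#'   `provenance` column is preserved).
#' @return the cleaned data frame.
#' @export
sl_pair_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  self <- pairs$gene_a == pairs$gene_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    pairs <- pairs[!self, , drop = FALSE]
  }
  key <- ifelse(pairs$gene_a < pairs$gene_b,
                paste(pairs$gene_a, pairs$gene_b),
                paste(pairs$gene_b, pairs$gene_a))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Select the initial panel of pairs from screened fractions
#'
#' A pair qualifies when its (up,up) fraction reaches `threshold`, or its
#' (down,up) fraction reaches `threshold` — except that pairs containing the
#' gene `kras_gene`, for which the more stringent `kras_threshold` applies to
#' qualification via the (down,up) fraction. Pairs on `include_list` are
#' always included and flagged `"prior-knowledge"`.
#'
#' @param records data frame with `gene_a`, `gene_b`, `f_uu`, `f_du`
#'   (e.g. an `sl_screen`).
#' @param threshold ordinary fraction threshold (default 0.15).
#' @param kras_threshold stricter threshold for the (down,up) fraction of
#'   pairs containing `kras_gene` (default 0.25).
#' @param include_list optional data frame (`gene_a`, `gene_b`) of pairs to
#'   force into the panel.
#' @param kras_gene gene symbol the stricter rule applies to (default
#'   `"KRAS"`).
#' @return data frame of selected pairs with a `reason` column
#'   (`"f_uu"`, `"f_du"`, `"f_uu+f_du"` or `"prior-knowledge"`).
#' @export
select_initial_panel <- function(records, threshold = 0.15,
                                 kras_threshold = 0.25, include_list = NULL,
                                 kras_gene = "KRAS") {
  stopifnot(threshold > 0, threshold <= 1, kras_threshold > 0, kras_threshold <= 1)
  records <- as.data.frame(records)
  has_kras <- records$gene_a == kras_gene | records$gene_b == kras_gene
  qual_uu <- records$f_uu >= threshold
  qual_du <- ifelse(has_kras, records$f_du >= kras_threshold,
                    records$f_du >= threshold)
  reason <- character(nrow(records))
  reason[qual_uu & !qual_du] <- "f_uu"
  reason[!qual_uu & qual_du] <- "f_du"
  reason[qual_uu & qual_du] <- "f_uu+f_du"
  sel <- records[qual_uu | qual_du, , drop = FALSE]
  sel$reason <- reason[qual_uu | qual_du]
  if (!is.null(include_list) && nrow(include_list) > 0) {
    key <- function(d) ifelse(d$gene_a < d$gene_b,
                              paste(d$gene_a, d$gene_b),
                              paste(d$gene_b, d$gene_a))
    extra_keys <- setdiff(key(include_list), if (nrow(sel)) key(sel) else character())
    for (k in extra_keys) {
      i <- match(k, key(include_list))
      j <- match(k, key(records))
      if (!is.na(j)) {
        row <- records[j, , drop = FALSE]
      } else {
        row <- records[0, , drop = FALSE][NA_integer_, , drop = FALSE]
        row$gene_a <- include_list$gene_a[i]
        row$gene_b <- include_list$gene_b[i]
      }
      row$reason <- "prior-knowledge"
      sel <- rbind(sel, row)
    }
  }
  rownames(sel) <- NULL
  sel
}
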