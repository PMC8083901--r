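#' Storey q-values
#'
#' Converts p-values to q-values (FDR analogues). The proportion of true
#' nulls pi0 is estimated with the Storey–Tibshirani smoother: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over a lambda grid, a natural cubic
#' smoothing spline (3 df) through those points, evaluated at the largest
#' grid value. With fewer than 20 p-values the smoother is unreliable and a
#' fixed lambda = 0.5 estimate is used instead. pi0 is clipped to (0, 1].
#' Given pi0, q(i) = min over j with p(j) >= p(i) of pi0 * m * p(j) / rank(j).
#'
#' With `pi0 = 1` the result equals Benjamini–Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda grid for the pi0 smoother (default 0.05, 0.10, ..., 0.95).
#' @param pi0 optional: force the null proportion instead of estimating it.
#' @return numeric vector of q-values in \[0, 1\], same order as `p`;
#'   attribute `"pi0"` carries the null-proportion estimate.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (is.null(pi0)) {
    if (m < 20L) {
      pi0 <- mean(p > 0.5) / 0.5
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
    }
  }
  pi0 <- min(pi0, 1)
  pi0 <- max(pi0, .Machine$double.eps)  # keep q well-defined when all p tiny
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}
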