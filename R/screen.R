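#' Constrained survival screen over single and paired markers
#'
#' For each marker: patients with complete calls are stratified into the
#' marker's subset vs "otherwise", follow-up is administratively censored at
#' `horizon_months`, and — provided both the subset and its complement hold
#' at least `min_subset` patients — a log-rank test, a univariate Cox model,
#' and a stage-adjusted Cox model (stage III-IV vs I-II) are fitted.
#' Markers failing the size guard are reported with status
#' `"skipped_small_subset"`; fitting problems surface as status `"error"`.
#' No multiplicity correction is applied to the headline p-values; a
#' Benjamini-Hochberg column `p_bh` over the tested markers is provided for
#' reference.
#'
#' @param markers list of `marker_definition`s (see [enumerate_markers()]).
#' @param calls IHC call table (long format or matrix, see
#'   [marker_membership()]).
#' @param clinical data frame with `patient_id`, `time` (months), `event`
#'   (1 = death), and `stage` (I-IV); other columns are ignored here.
#' @param min_subset minimum patients required in the marker subset and in
#'   its complement (default 5).
#' @param horizon_months administrative censoring horizon (default 120).
#' @param adjust_stage fit the stage-adjusted model (default TRUE).
#' @param keep_fits keep the full `cox_fit` objects (default FALSE; the
#'   result table always carries the estimates).
#' @return a `marker_screen`: list with `results` (data frame sorted by
#'   univariate p), `markers`, and optionally `fits`.
#' @export
screen_markers <- function(markers, calls, clinical, min_subset = 5,
                           horizon_months = 120, adjust_stage = TRUE,
                           keep_fits = FALSE) {
  stopifnot(is.list(markers), length(markers) > 0)
  if (inherits(markers, "marker_definition")) markers <- list(markers)
  wide <- if (is.matrix(calls)) calls else call_matrix(calls)
  clinical <- as.data.frame(clinical)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(clinical)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  stage_bin <- if ("stage" %in% names(clinical))
    .stage_binary(clinical$stage) else rep(NA_integer_, nrow(clinical))
  rows <- vector("list", length(markers))
  fits <- if (keep_fits) vector("list", length(markers)) else NULL
  for (i in seq_along(markers)) {
    mk <- markers[[i]]
    row <- data.frame(marker = format(mk), arity = length(mk$stains),
                      pattern = paste(mk$pattern, collapse = ","),
                      n = NA_integer_, n_risk = NA_integer_,
                      n_events = NA_integer_,
                      logrank_chisq = NA_real_, logrank_p = NA_real_,
                      hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, lr_chisq = NA_real_,
                      adj_hr = NA_real_, adj_ci_lo = NA_real_,
                      adj_ci_hi = NA_real_, adj_p = NA_real_,
                      adj_lr_chisq = NA_real_,
                      status = "tested", stringsAsFactors = FALSE)
    res <- tryCatch({
      ind <- marker_membership(wide, mk)
      j <- match(names(ind), clinical$patient_id)
      ok <- !is.na(j) & !is.na(clinical$time[j]) & !is.na(clinical$event[j])
      ind <- ind[ok]; j <- j[ok]
      cen <- censor_at_horizon(clinical$time[j], clinical$event[j],
                               horizon_months)
      row$n <- length(ind)
      row$n_risk <- sum(ind)
      row$n_events <- sum(cen$event)
      if (sum(ind) < min_subset || sum(1 - ind) < min_subset) {
        row$status <- "skipped_small_subset"
      } else {
        lr <- logrank_test(cen$time, cen$event, ind)
        row$logrank_chisq <- lr$chi_square
        row$logrank_p <- lr$p_value
        uni <- cox_fit(cen$time, cen$event, data.frame(marker = ind))
        row$hr <- uni$coefficients$hr[1]
        row$ci_lo <- uni$coefficients$ci_lo[1]
        row$ci_hi <- uni$coefficients$ci_hi[1]
        row$p <- uni$coefficients$p[1]
        row$lr_chisq <- uni$lr_chisq
        if (!uni$converged) row$status <- "not_converged"
        if (adjust_stage) {
          sb <- stage_bin[j]
          keep <- !is.na(sb)
          if (sum(keep) >= 2 * min_subset && length(unique(sb[keep])) == 2L &&
              length(unique(ind[keep])) == 2L) {
            adj <- cox_fit(cen$time[keep], cen$event[keep],
                           data.frame(marker = ind[keep], stage = sb[keep]))
            row$adj_hr <- adj$coefficients$hr[1]
            row$adj_ci_lo <- adj$coefficients$ci_lo[1]
            row$adj_ci_hi <- adj$coefficients$ci_hi[1]
            row$adj_p <- adj$coefficients$p[1]
            row$adj_lr_chisq <- adj$lr_chisq
            if (!adj$converged) row$status <- "not_converged"
          }
        }
        if (keep_fits) fits[[i]] <- uni
      }
      row
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  results <- do.call(rbind, rows)
  tested <- results$status == "tested"
  results$p_bh <- NA_real_
  results$p_bh[tested] <- p.adjust(results$p[tested], method = "BH")
  ord <- order(results$p, na.last = TRUE)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, markers = markers[ord],
                 fits = if (keep_fits) fits[ord] else NULL,
                 min_subset = min_subset, horizon_months = horizon_months),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, n = 10, ...) {
  r <- x$results
  cat("Marker survival screen: ", nrow(r), " markers (",
      sum(r$status == "tested"), " tested, ",
      sum(r$status == "skipped_small_subset"), " skipped: subset < ",
      x$min_subset, "); horizon ", x$horizon_months, " months\n", sep = "")
  show <- utils::head(r[, c("marker", "n_risk", "hr", "ci_lo", "ci_hi", "p",
                            "adj_hr", "adj_p", "status")], n)
  print.data.frame(show, digits = 3, row.names = FALSE)
  if (nrow(r) > n) cat("... ", nrow(r) - n, " more markers\n", sep = "")
  invisible(x)
}

#' @export
summary.marker_screen <- function(object, alpha = 0.05, ...) {
  r <- object$results
  sig <- r[!is.na(r$p) & r$p < alpha & r$status == "tested", , drop = FALSE]
  cat(nrow(sig), "markers with univariate Cox p <", alpha, "\n")
  invisible(sig)
}

#' Kaplan-Meier plot for one screened marker
#'
#' @param x a `marker_screen`.
#' @param marker_index row of the results table to plot (default 1, the
#'   most significant marker).
#' @param calls,clinical the inputs used for the screen.
#' @param ... passed to [graphics::plot()].
#' @export
plot.marker_screen <- function(x, marker_index = 1, calls, clinical, ...) {
  mk <- x$markers[[marker_index]]
  wide <- if (is.matrix(calls)) calls else call_matrix(calls)
  ind <- marker_membership(wide, mk)
  j <- match(names(ind), clinical$patient_id)
  cen <- censor_at_horizon(clinical$time[j], clinical$event[j],
                           x$horizon_months)
  fit <- survfit(Surv(cen$time, cen$event) ~ ind)
  plot(fit, lty = c(1, 2), xlab = "Months", ylab = "Overall survival",
       main = format(mk), ...)
  legend("bottomleft", lty = c(1, 2), bty = "n",
         legend = c("otherwise", format(mk)))
  invisible(x)
}

#' Combine two markers into a joint risk subset
#'
#' The joint subset is the intersection of the two markers' risk subsets; a
#' marker declared `protective` contributes the *complement* of its subset
#' (its poor-survival side) when `combine_protective = "complement"`
#' (default), or its subset as-is otherwise. The combined indicator is then
#' put through the same subset-size guard and a stage-adjusted Cox model.
#'
#' @param marker_a,marker_b `marker_definition`s.
#' @param calls,clinical as in [screen_markers()].
#' @param min_subset minimum size for the joint subset and its complement.
#' @param horizon_months administrative censoring horizon.
#' @param combine_protective `"complement"` (default) or `"as-is"`.
#' @return a `combined_marker`: list with `fit` (stage-adjusted `cox_fit`
#'   or NULL), `indicator`, `n_joint`, `status`, `label`.
#' @export
combine_markers <- function(marker_a, marker_b, calls, clinical,
                            min_subset = 5, horizon_months = 120,
                            combine_protective = c("complement", "as-is")) {
  combine_protective <- match.arg(combine_protective)
  wide <- if (is.matrix(calls)) calls else call_matrix(calls)
  risk_side <- function(mk) {
    ind <- marker_membership(wide, mk)
    if (mk$orientation == "protective" && combine_protective == "complement")
      ind <- setNames(1L - ind, names(ind))
    ind
  }
  ia <- risk_side(marker_a)
  ib <- risk_side(marker_b)
  common <- intersect(names(ia), names(ib))
  joint <- setNames(ia[common] * ib[common], common)
  label <- paste0("[", format(marker_a), "] & [", format(marker_b), "]")
  j <- match(names(joint), clinical$patient_id)
  ok <- !is.na(j) & !is.na(clinical$time[j]) & !is.na(clinical$event[j])
  joint <- joint[ok]; j <- j[ok]
  cen <- censor_at_horizon(clinical$time[j], clinical$event[j], horizon_months)
  out <- list(label = label, indicator = joint, n_joint = sum(joint),
              n = length(joint), fit = NULL, status = "tested")
  if (sum(joint) < min_subset || sum(1 - joint) < min_subset) {
    out$status <- "skipped_small_subset"
  } else {
    sb <- .stage_binary(clinical$stage[j])
    keep <- !is.na(sb)
    covs <- if (sum(keep) && length(unique(sb[keep])) == 2L)
      data.frame(marker = joint[keep], stage = sb[keep])
    else data.frame(marker = joint)
    tt <- if (identical(names(covs), c("marker", "stage"))) cen[keep, ] else cen
    out$fit <- tryCatch(cox_fit(tt$time, tt$event, covs),
                        error = function(e) {
                          out$status <<- paste0("error: ", conditionMessage(e))
                          NULL
                        })
  }
  class(out) <- "combined_marker"
  out
}

#' @export
print.combined_marker <- function(x, ...) {
  cat("Combined marker ", x$label, ": joint subset n = ", x$n_joint,
      " of ", x$n, " (", x$status, ")\n", sep = "")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
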