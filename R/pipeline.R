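#' Pipeline configuration
#'
#' Collects the tunable constants of the end-to-end screen with their
#' conventional defaults: 1.5-fold call cutoff (1.4 for validation
#' cohorts), 10,000 permutations, panel thresholds 15% / 25% (the stricter
#' one for KRAS-pair qualification via the down/up fraction), a 5-patient
#' minimum subset, a 120-month (10-year) follow-up horizon, and alpha =
#' 0.05.
#'
#' @param expression,labels,sl_pairs,ihc_scores,stain_panel,clinical input
#'   file paths (NULL skips the stage needing them).
#' @param fold_cutoff,validation_fold_cutoff,n_perm,panel_threshold,kras_threshold,min_subset,horizon_months,alpha,seed
#'   numeric parameters; see Details.
#' @param combine_protective how protective markers enter combinations
#'   (`"complement"` or `"as-is"`).
#' @return a `pipeline_config` (validated named list).
#' @export
pipeline_config <- function(expression = NULL, labels = NULL, sl_pairs = NULL,
                            ihc_scores = NULL, stain_panel = NULL,
                            clinical = NULL,
                            fold_cutoff = 1.5, validation_fold_cutoff = 1.4,
                            n_perm = 10000, panel_threshold = 0.15,
                            kras_threshold = 0.25, min_subset = 5,
                            horizon_months = 120, alpha = 0.05,
                            seed = 20210415,
                            combine_protective = "complement") {
  cfg <- list(expression = expression, labels = labels, sl_pairs = sl_pairs,
              ihc_scores = ihc_scores, stain_panel = stain_panel,
              clinical = clinical,
              fold_cutoff = fold_cutoff,
              validation_fold_cutoff = validation_fold_cutoff,
              n_perm = n_perm, panel_threshold = panel_threshold,
              kras_threshold = kras_threshold, min_subset = min_subset,
              horizon_months = horizon_months, alpha = alpha, seed = seed,
              combine_protective = combine_protective)
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(cfg$fold_cutoff > 1, cfg$validation_fold_cutoff > 1,
            cfg$n_perm >= 1,
            cfg$panel_threshold > 0, cfg$panel_threshold <= 1,
            cfg$kras_threshold > 0, cfg$kras_threshold <= 1,
            cfg$min_subset >= 1, cfg$horizon_months > 0,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$combine_protective %in% c("complement", "as-is"))
  invisible(cfg)
}

.config_numeric_keys <- c("fold_cutoff", "validation_fold_cutoff", "n_perm",
                          "panel_threshold", "kras_threshold", "min_subset",
                          "horizon_months", "alpha", "seed")

#' Read / write a pipeline configuration file
#'
#' Plain `key = value` text, one entry per line; `#` starts a comment.
#' Round-trips losslessly through [write_pipeline_config()].
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  args <- as.list(vals)
  names(args) <- keys
  for (k in intersect(keys, .config_numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  args <- args[!vapply(args, function(v) identical(v, ""), logical(1))]
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  keep <- !vapply(cfg, is.null, logical(1))
  vals <- vapply(cfg[keep], function(v) format(v, scientific = FALSE),
                 character(1))
  writeLines(paste(names(cfg)[keep], "=", vals), path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) if (!is.null(x[[k]])) cat("  ", k, " = ", x[[k]], "\n", sep = "")
  invisible(x)
}

#' Run the end-to-end marker-discovery pipeline
#'
#' Executes, in order and as inputs allow: the SL-pair expression screen
#' with permutation p-values and q-values; initial-panel selection; IHC
#' core aggregation and over/under calls; stain-pair enumeration; the
#' survival screen over single and paired markers; and combinations of any
#' two significant markers (protective markers contributing their
#' complement). Each stage writes a TSV/CSV into `out_dir`; a run log
#' records parameters, seed and package version. Any stage failure aborts
#' with the stage name.
#'
#' Outputs are pure functions of (inputs, config, seed): rerunning with the
#' same config gives byte-identical stage tables (the run log carries a
#' timestamp and is excluded from that guarantee).
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list of per-stage results and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("slmarker ", as.character(packageVersion("slmarker")),
       " | started ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("seed = ", config$seed)
  results <- list(out_dir = out_dir)
  stage <- function(name, expr) {
    logf("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  screen <- NULL
  if (!is.null(config$expression)) {
    screen <- stage("screen-expression", {
      x <- read_expression_matrix(config$expression)
      labels <- read_sample_labels(config$labels)
      pairs <- read_sl_pairs(config$sl_pairs)
      sc <- screen_sl_pairs(x, labels, pairs,
                            fold_cutoff = config$fold_cutoff,
                            n_perm = config$n_perm, seed = config$seed)
      write_stage_table(sc, file.path(out_dir, "expression_screen.tsv"))
      sc
    })
    results$expression_screen <- screen
    results$initial_panel <- stage("select-panel", {
      panel <- select_initial_panel(screen,
                                    threshold = config$panel_threshold,
                                    kras_threshold = config$kras_threshold)
      write_stage_table(panel, file.path(out_dir, "initial_panel.tsv"))
      panel
    })
  }

  calls <- NULL
  spanel <- NULL
  if (!is.null(config$ihc_scores)) {
    calls <- stage("call-ihc", {
      spanel <- if (is.null(config$stain_panel)) default_stain_panel()
                else read_stain_panel(config$stain_panel)
      scores <- read_ihc_scores(config$ihc_scores)
      cl <- call_ihc(scores, spanel)
      write.csv(cl, file.path(out_dir, "ihc_calls.csv"), row.names = FALSE)
      cl
    })
    results$ihc_calls <- calls
    results$stain_pairs <- stage("enumerate-pairs", {
      sp <- enumerate_stain_pairs(spanel)
      write_stage_table(sp, file.path(out_dir, "stain_pairs.tsv"))
      sp
    })
  }

  if (!is.null(calls) && !is.null(config$clinical)) {
    clinical <- stage("read-clinical", read_clinical(config$clinical))
    mscreen <- stage("survival-screen", {
      markers <- enumerate_markers(spanel)
      ms <- screen_markers(markers, calls, clinical,
                           min_subset = config$min_subset,
                           horizon_months = config$horizon_months)
      write_stage_table(ms, file.path(out_dir, "survival_screen.tsv"))
      ms
    })
    results$survival_screen <- mscreen
    results$combinations <- stage("combine", {
      r <- mscreen$results
      sig <- which(r$status == "tested" & !is.na(r$p) & r$p < config$alpha)
      combos <- list()
      if (length(sig) >= 2) {
        idx <- combn(sig, 2)
        for (c_i in seq_len(ncol(idx))) {
          i <- idx[1, c_i]; j <- idx[2, c_i]
          ma <- mscreen$markers[[i]]; mb <- mscreen$markers[[j]]
          # markers whose subset carries HR < 1 are protective
          if (!is.na(r$hr[i]) && r$hr[i] < 1) ma$orientation <- "protective"
          if (!is.na(r$hr[j]) && r$hr[j] < 1) mb$orientation <- "protective"
          combos[[length(combos) + 1L]] <-
            combine_markers(ma, mb, calls, clinical,
                            min_subset = config$min_subset,
                            horizon_months = config$horizon_months,
                            combine_protective = config$combine_protective)
        }
      }
      tab <- do.call(rbind, lapply(combos, function(cm) {
        hr <- ci_lo <- ci_hi <- p <- lr <- NA_real_
        if (!is.null(cm$fit)) {
          co <- cm$fit$coefficients
          hr <- co$hr[1]; ci_lo <- co$ci_lo[1]; ci_hi <- co$ci_hi[1]
          p <- co$p[1]; lr <- cm$fit$lr_chisq
        }
        data.frame(combination = cm$label, n_joint = cm$n_joint, hr = hr,
                   ci_lo = ci_lo, ci_hi = ci_hi, p = p, lr_chisq = lr,
                   status = cm$status, stringsAsFactors = FALSE)
      }))
      if (is.null(tab))
        tab <- data.frame(combination = character(), n_joint = integer(),
                          hr = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), p = numeric(),
                          lr_chisq = numeric(), status = character())
      write_stage_table(tab, file.path(out_dir, "combinations.tsv"))
      tab
    })
  }
  logf("finished ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  invisible(results)
}
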