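#' @name ihc
#' @title Immunohistochemistry panel: scores, cutoff rules, calls, markers
#'
#' @description
#' Stains are protein + cellular-compartment assays scored on tissue cores
#' with ordinal intensity grades 0, +/-, 1+, 2+, 3+ (numerically coded 0,
#' 0.5, 1, 2, 3) and, for some stains, a percent-positive value. Per-patient
#' scores are the mean over available cancerous cores; a rule attached to
#' each stain then dichotomizes patients into over- vs under-expression.
NULL

# ---- cutoff rule grammar -------------------------------------------------
# A rule is one or two atoms joined by "and"/"or". An atom is a comparator
# (<, <=, >, >=) plus a value; suffix "+" refers to the aggregated intensity
# grade, "%" to the aggregated percent-positive. Unicode comparators from
# published tables are accepted.

.normalize_rule_text <- function(text) {
  text <- gsub("\u2266|\u2264", "<=", text)
  text <- gsub("\u2267|\u2265", ">=", text)
  text <- gsub("\\s+", " ", trimws(text))
  text
}

.parse_rule_atom <- function(atom) {
  m <- regmatches(atom, regexec("^(<=|>=|<|>) ?([0-9.]+) ?(\\+|%)?$", atom))[[1]]
  if (length(m) == 0L) stop("unparseable cutoff atom: '", atom, "'", call. = FALSE)
  list(op = m[2], value = as.numeric(m[3]),
       var = if (identical(m[4], "%")) "percent" else "intensity")
}

#' Parse a stain cutoff rule into a predicate
#'
#' @param text rule text, e.g. `"<1+"`, `"<=1+"`, `">=1+ and >=10%"`,
#'   `">0%"`.
#' @return a function `f(intensity, percent)` returning TRUE/FALSE, with
#'   attributes `"text"` and `"uses_percent"`.
#' @export
parse_cutoff_rule <- function(text) {
  norm <- .normalize_rule_text(text)
  conj <- grepl(" and ", norm, fixed = TRUE)
  disj <- grepl(" or ", norm, fixed = TRUE)
  if (conj && disj) stop("mixed and/or rules not supported: '", text, "'", call. = FALSE)
  parts <- strsplit(norm, if (disj) " or " else " and ", fixed = TRUE)[[1]]
  atoms <- lapply(parts, .parse_rule_atom)
  combine <- if (disj) any else all
  f <- function(intensity, percent = NA_real_) {
    vals <- vapply(atoms, function(a) {
      x <- if (a$var == "percent") percent else intensity
      if (is.na(x)) stop("rule references ", a$var, " but it is missing", call. = FALSE)
      switch(a$op, "<" = x < a$value, "<=" = x <= a$value,
             ">" = x > a$value, ">=" = x >= a$value)
    }, logical(1))
    combine(vals)
  }
  attr(f, "text") <- text
  attr(f, "uses_percent") <- any(vapply(atoms, function(a) a$var == "percent", logical(1)))
  f
}

#' Load a stain panel definition
#'
#' Reads a CSV with columns `stain_id`, `protein`, `compartment` (N =
#' nucleus, C = cytoplasm, M = membrane), `under_rule`, `over_rule`, parses
#' all cutoff rules at load time, and returns a `stain_panel`. A patient's
#' call is *over* iff the over-rule holds and *under* otherwise, so the two
#' rules partition the score space by construction; the under-rule text is
#' kept for display and consistency checks.
#'
#' @param path CSV file path.
#' @return a `stain_panel` (data frame with parsed rules in attributes).
#' @export
read_stain_panel <- function(path) {
  if (!file.exists(path)) stop("stain panel file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("stain_id", "protein", "compartment", "under_rule", "over_rule")
  if (!all(need %in% names(df)))
    stop("stain panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$stain_id)) stop("duplicate stain_id in panel", call. = FALSE)
  if (!all(df$compartment %in% c("N", "C", "M")))
    stop("compartment must be N, C or M", call. = FALSE)
  over <- lapply(df$over_rule, parse_cutoff_rule)
  under <- lapply(df$under_rule, parse_cutoff_rule)
  names(over) <- names(under) <- df$stain_id
  attr(df, "over_rules") <- over
  attr(df, "under_rules") <- under
  class(df) <- c("stain_panel", "data.frame")
  df
}

#' The default 29-stain oral-cancer panel
#'
#' The packaged panel of 29 IHC stains over 21 proteins (8 stained in two
#' cellular compartments) with their over/under-expression cutoff rules.
#'
#' @return a `stain_panel`.
#' @export
default_stain_panel <- function() {
  read_stain_panel(system.file("extdata", "stain_panel_oscc.csv",
                               package = "slmarker", mustWork = TRUE))
}

#' @export
print.stain_panel <- function(x, ...) {
  cat("IHC stain panel: ", nrow(x), " stains, ",
      length(unique(x$protein)), " proteins\n", sep = "")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# ---- scores --------------------------------------------------------------

#' Convert symbolic intensity grades to their numeric coding
#'
#' Grades 0, +/-, 1+, 2+, 3+ code to 0, 0.5, 1, 2, 3. Numeric input already
#' on that grid passes through.
#'
#' @param grade character or numeric vector.
#' @return numeric vector on the five-level grid.
#' @export
code_intensity_grade <- function(grade) {
  if (is.numeric(grade)) {
    bad <- !grade %in% c(0, 0.5, 1, 2, 3)
    if (any(bad)) stop("intensity grade outside {0, 0.5, 1, 2, 3}", call. = FALSE)
    return(grade)
  }
  map <- c("0" = 0, "\u00b1" = 0.5, "+-" = 0.5, "+/-" = 0.5,
           "1+" = 1, "2+" = 2, "3+" = 3)
  out <- map[as.character(grade)]
  if (anyNA(out)) stop("unknown intensity grade: ",
                       paste(unique(grade[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}

#' Aggregate per-core IHC scores to patient level
#'
#' Takes the arithmetic mean of the numerically coded intensity grades over
#' the available cancerous cores of each patient x stain (typically three
#' cores; core loss is tolerated); percent-positive is averaged the same
#' way. Patients with no scored core for a stain simply have no row.
#'
#' @param scores data frame with columns `patient_id`, `stain_id`,
#'   `core_id`, `intensity` (numeric coding or symbolic grades) and
#'   optionally `percent`.
#' @return data frame `patient_id`, `stain_id`, `intensity` (mean grade),
#'   `percent` (mean, NA when absent), `n_cores`.
#' @export
aggregate_cores <- function(scores) {
  need <- c("patient_id", "stain_id", "core_id", "intensity")
  if (!all(need %in% names(scores)))
    stop("scores need columns: ", paste(need, collapse = ", "), call. = FALSE)
  scores$intensity <- code_intensity_grade(scores$intensity)
  if (is.null(scores$percent)) scores$percent <- NA_real_
  key <- interaction(scores$patient_id, scores$stain_id, drop = TRUE)
  agg <- function(v) tapply(v, key, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  first <- !duplicated(key)
  out <- data.frame(
    patient_id = as.character(scores$patient_id[first]),
    stain_id = as.character(scores$stain_id[first]),
    stringsAsFactors = FALSE
  )
  k <- as.character(key[first])
  out$intensity <- as.numeric(agg(scores$intensity)[k])
  out$percent <- as.numeric(agg(scores$percent)[k])
  out$n_cores <- as.integer(tapply(scores$intensity, key, length)[k])
  out[order(out$patient_id, out$stain_id), , drop = FALSE]
}

#' Apply stain cutoff rules to aggregated scores
#'
#' A patient is called `over` for a stain iff the stain's over-rule holds on
#' the aggregated intensity (and aggregated percent, where the rule uses
#' it); otherwise `under`.
#'
#' @param aggregated output of [aggregate_cores()].
#' @param panel a `stain_panel`.
#' @return data frame `patient_id`, `stain_id`, `call`, `intensity`,
#'   `percent`.
#' @export
apply_cutoffs <- function(aggregated, panel) {
  stopifnot(inherits(panel, "stain_panel"))
  rules <- attr(panel, "over_rules")
  unknown <- setdiff(unique(aggregated$stain_id), names(rules))
  if (length(unknown))
    stop("stain(s) not in panel: ", paste(unknown, collapse = ", "), call. = FALSE)
  call <- character(nrow(aggregated))
  for (i in seq_len(nrow(aggregated))) {
    f <- rules[[aggregated$stain_id[i]]]
    call[i] <- if (f(aggregated$intensity[i], aggregated$percent[i])) "over" else "under"
  }
  data.frame(patient_id = aggregated$patient_id,
             stain_id = aggregated$stain_id,
             call = call,
             intensity = aggregated$intensity,
             percent = aggregated$percent,
             stringsAsFactors = FALSE)
}

#' Score a raw IHC table into patient-level calls
#'
#' Convenience wrapper: [aggregate_cores()] then [apply_cutoffs()].
#'
#' @inheritParams aggregate_cores
#' @inheritParams apply_cutoffs
#' @return call table as in [apply_cutoffs()].
#' @export
call_ihc <- function(scores, panel) apply_cutoffs(aggregate_cores(scores), panel)

# ---- pair enumeration and markers ---------------------------------------

#' Enumerate all distinct stain pairs
#'
#' All unordered pairs of stains, excluding pairs whose two stains assay the
#' same protein in different compartments. The count is
#' C(n, 2) - sum over proteins of C(k_protein, 2).
#'
#' @param panel a `stain_panel` (or data frame with `stain_id`, `protein`).
#' @return data frame `stain_a`, `stain_b`, `protein_a`, `protein_b`.
#' @export
enumerate_stain_pairs <- function(panel) {
  stopifnot(all(c("stain_id", "protein") %in% names(panel)))
  if (anyDuplicated(panel$stain_id)) stop("stain ids must be unique", call. = FALSE)
  n <- nrow(panel)
  if (n < 2L)
    return(data.frame(stain_a = character(), stain_b = character(),
                      protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  idx <- combn(n, 2L)
  keep <- panel$protein[idx[1, ]] != panel$protein[idx[2, ]]
  data.frame(stain_a = panel$stain_id[idx[1, keep]],
             stain_b = panel$stain_id[idx[2, keep]],
             protein_a = panel$protein[idx[1, keep]],
             protein_b = panel$protein[idx[2, keep]],
             stringsAsFactors = FALSE)
}

#' Define a single or paired marker
#'
#' A marker is an ordered set of one or two stains plus a direction pattern
#' (`"up"` = over-expressed, `"down"` = under-expressed) defining the risk
#' subset: a patient is in the subset iff every component stain matches its
#' arrow; everyone else is "otherwise". `orientation = "protective"` records
#' that the subset carries *better* survival, which matters when combining
#' markers (see [combine_markers()]).
#'
#' @param stains character vector of 1 or 2 stain ids.
#' @param pattern same-length vector over `"up"`/`"down"` (unicode arrows
#'   accepted).
#' @param orientation `"risk"` (default) or `"protective"`.
#' @return a `marker_definition`.
#' @export
marker <- function(stains, pattern, orientation = c("risk", "protective")) {
  orientation <- match.arg(orientation)
  stains <- as.character(stains)
  if (!length(stains) %in% 1:2) stop("markers have 1 or 2 stains", call. = FALSE)
  if (length(stains) == 2L && stains[1] == stains[2])
    stop("paired marker cannot repeat a stain", call. = FALSE)
  pattern <- as.character(pattern)
  pattern[pattern %in% c("\u2191", "over")] <- "up"
  pattern[pattern %in% c("\u2193", "under")] <- "down"
  if (length(pattern) != length(stains) || !all(pattern %in% c("up", "down")))
    stop("pattern must match arity and use up/down", call. = FALSE)
  structure(list(stains = stains, pattern = pattern, orientation = orientation),
            class = "marker_definition")
}

#' @export
format.marker_definition <- function(x, ...) {
  arrows <- c(up = "\u2191", down = "\u2193")
  paste(paste0(x$stains, arrows[x$pattern]), collapse = "-")
}

#' @export
print.marker_definition <- function(x, ...) {
  cat(format(x), " (", x$orientation, " marker) vs otherwise\n", sep = "")
  invisible(x)
}

#' Patient membership in a marker's risk subset
#'
#' @param calls call table from [apply_cutoffs()] / [call_ihc()] (long
#'   format) or a patients x stains matrix of `"over"`/`"under"`.
#' @param marker a `marker_definition`.
#' @return named integer vector (1 = in the marker's subset, 0 =
#'   otherwise) over patients with complete calls for every component
#'   stain; patients with missing calls are dropped.
#' @export
marker_membership <- function(calls, marker) {
  stopifnot(inherits(marker, "marker_definition"))
  wide <- if (is.matrix(calls)) calls else call_matrix(calls)
  missing_stains <- setdiff(marker$stains, colnames(wide))
  if (length(missing_stains))
    stop("no calls for stain(s): ", paste(missing_stains, collapse = ", "),
         call. = FALSE)
  sub <- wide[, marker$stains, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  sub <- sub[complete, , drop = FALSE]
  want <- ifelse(marker$pattern == "up", "over", "under")
  ind <- rep(1L, nrow(sub))
  for (j in seq_along(want)) ind <- ind * as.integer(sub[, j] == want[j])
  setNames(ind, rownames(sub))
}

#' Pivot a long call table to a patients x stains matrix
#'
#' @param calls long call table (`patient_id`, `stain_id`, `call`).
#' @return character matrix patients x stains of `"over"`/`"under"`/NA.
#' @export
call_matrix <- function(calls) {
  patients <- sort(unique(calls$patient_id))
  stains <- sort(unique(calls$stain_id))
  m <- matrix(NA_character_, length(patients), length(stains),
              dimnames = list(patients, stains))
  m[cbind(match(calls$patient_id, patients), match(calls$stain_id, stains))] <-
    calls$call
  m
}

#' Build the standard marker set from a panel
#'
#' One single-stain marker per stain (risk arrow `"up"`, i.e. over vs
#' under; direction is a labelling convention — the survival tests are
#' symmetric) and, for every distinct stain pair, one paired marker per
#' requested direction pattern.
#'
#' @param panel a `stain_panel`.
#' @param pair_patterns character vector of two-letter patterns over
#'   `u`/`d` (default all four: `"uu"`, `"ud"`, `"du"`, `"dd"`).
#' @param singles include single-stain markers (default TRUE).
#' @return list of `marker_definition`s.
#' @export
enumerate_markers <- function(panel, pair_patterns = c("uu", "ud", "du", "dd"),
                              singles = TRUE) {
  out <- list()
  if (singles)
    out <- lapply(panel$stain_id, function(s) marker(s, "up"))
  pairs <- enumerate_stain_pairs(panel)
  dir <- c(u = "up", d = "down")
  for (i in seq_len(nrow(pairs))) {
    for (pat in pair_patterns) {
      letters2 <- strsplit(pat, "")[[1]]
      out[[length(out) + 1L]] <- marker(c(pairs$stain_a[i], pairs$stain_b[i]),
                                        dir[letters2])
    }
  }
  out
}
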