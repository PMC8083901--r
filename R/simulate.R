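#' Simulate a tumor/control expression cohort with planted SL-pair signal
#'
#' Background intensities are log-normal: per-gene log2 means ~ N(8, 1.5^2)
#' plus i.i.d. sample noise whose standard deviation is chosen so that a
#' spurious fold-change call (either direction, at `fold_cutoff`) occurs at
#' `background_call_rate` in a background gene. For every planted pair, a
#' `fraction` share of the cancer samples (rounded) receives a coordinated
#' log2 shift of `log2(planted_fold)` in the planted pattern's directions
#' for both genes, so those samples are called in the pattern with high
#' probability while the control mean is untouched.
#'
#' @param n_cancer,n_control sample sizes (defaults 57 / 22, mirroring a
#'   typical microarray screening cohort).
#' @param n_genes genes in the matrix (default 200).
#' @param planted data frame with columns `gene_a`, `gene_b`, `pattern`
#'   (`"uu"`/`"ud"`/`"du"`/`"dd"`), `fraction`; gene names must be among the
#'   generated `GENE###` ids. NULL plants nothing.
#' @param n_background_pairs extra null pairs appended to the SL pair table
#'   (default 20), drawn from genes not used by planted pairs.
#' @param background_call_rate target spurious call rate per background
#'   gene (default 0.10).
#' @param fold_cutoff call cutoff the rate is calibrated against (1.5).
#' @param planted_fold fold shift given to planted samples (default 3).
#' @param seed RNG seed; the generator is fully reproducible given
#'   (arguments, seed).
#' @return list: `values` (positive matrix genes x samples), `labels`
#'   (named vector), `pairs` (SL pair table: planted then background, with
#'   `provenance`), `truth` (the arguments, including the realized planted
#'   sample sets).
#' @export
simulate_expression <- function(n_cancer = 57, n_control = 22, n_genes = 200,
                                planted = NULL, n_background_pairs = 20,
                                background_call_rate = 0.10,
                                fold_cutoff = 1.5, planted_fold = 3,
                                seed = 1) {
  stopifnot(n_cancer >= 2, n_control >= 2, n_genes >= 2)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  samples <- c(sprintf("T%02d", seq_len(n_cancer)),
               sprintf("N%02d", seq_len(n_control)))
  labels <- setNames(rep(c("cancer", "control"), c(n_cancer, n_control)),
                     samples)
  # noise sd such that P(|log2 ratio| >= log2(cutoff)) ~= rate; the log2
  # ratio of a background gene is approximately N(0, sigma^2 (1 + 1/n_control))
  sigma <- log2(fold_cutoff) / qnorm(1 - background_call_rate / 2) /
    sqrt(1 + 1 / n_control)
  truth_sets <- list()
  values <- with_seed(seed, {
    mu <- rnorm(n_genes, mean = 8, sd = 1.5)
    log2x <- matrix(rnorm(n_genes * length(samples), sd = sigma),
                    n_genes, dimnames = list(genes, samples)) + mu
    if (!is.null(planted)) {
      stopifnot(all(c("gene_a", "gene_b", "pattern", "fraction") %in% names(planted)))
      delta <- log2(planted_fold)
      for (i in seq_len(nrow(planted))) {
        ga <- planted$gene_a[i]; gb <- planted$gene_b[i]
        if (!all(c(ga, gb) %in% genes))
          stop("planted pair references unknown gene(s)", call. = FALSE)
        k <- round(planted$fraction[i] * n_cancer)
        if (k < 1) warning("planted fraction yields < 1 cancer sample")
        pick <- sample(seq_len(n_cancer), k)
        signs <- switch(planted$pattern[i],
                        uu = c(1, 1), ud = c(1, -1), du = c(-1, 1),
                        dd = c(-1, -1),
                        stop("pattern must be uu/ud/du/dd", call. = FALSE))
        log2x[ga, pick] <- log2x[ga, pick] + signs[1] * delta
        log2x[gb, pick] <- log2x[gb, pick] + signs[2] * delta
        truth_sets[[i]] <- samples[pick]
      }
    }
    2^log2x
  })
  used <- if (is.null(planted)) character() else
    unique(c(planted$gene_a, planted$gene_b))
  pool <- setdiff(genes, used)
  bg <- NULL
  if (n_background_pairs > 0) {
    if (length(pool) < 2 * n_background_pairs)
      stop("not enough free genes for background pairs", call. = FALSE)
    pick <- with_seed(seed + 1, sample(pool, 2 * n_background_pairs))
    bg <- data.frame(gene_a = pick[seq_len(n_background_pairs)],
                     gene_b = pick[n_background_pairs + seq_len(n_background_pairs)],
                     provenance = "background", stringsAsFactors = FALSE)
  }
  pl <- if (is.null(planted)) NULL else
    data.frame(gene_a = planted$gene_a, gene_b = planted$gene_b,
               provenance = "planted", stringsAsFactors = FALSE)
  pairs <- rbind(pl, bg)
  list(values = values, labels = labels, pairs = pairs,
       truth = list(planted = planted, planted_samples = truth_sets,
                    background_call_rate = background_call_rate,
                    sigma = sigma, fold_cutoff = fold_cutoff,
                    planted_fold = planted_fold, n_cancer = n_cancer,
                    n_control = n_control, n_genes = n_genes, seed = seed))
}

# draw three core grades + a percent consistent with a target call;
# rejection sampling against the stain's over-rule, deterministic fallback
.scores_for_call <- function(over_rule, call) {
  grades <- c(0, 0.5, 1, 2, 3)
  w_over <- c(0.03, 0.05, 0.17, 0.35, 0.40)
  w_under <- rev(w_over)
  for (try in 1:50) {
    g <- sample(grades, 3, replace = TRUE,
                prob = if (call == "over") w_over else w_under)
    pct <- if (call == "over") round(runif(1, 10, 95)) else
      sample(c(0, round(runif(1, 0, 9))), 1)
    hit <- over_rule(mean(g), pct)
    if ((call == "over") == hit) return(list(grades = g, percent = pct))
  }
  if (call == "over") list(grades = c(3, 3, 3), percent = 50)
  else list(grades = c(0, 0, 0), percent = 0)
}

#' Simulate an IHC + survival cohort with planted marker effects
#'
#' Generates per-patient stain calls, three noisy cores per call, clinical
#' covariates, and survival times from a proportional-hazards model with
#' exponential baseline, planted marker log-hazards, a stage effect, and
#' independent exponential censoring.
#'
#' Call generation: stains not involved in a planted marker match their
#' "over" side with probability `stain_prevalence` (optionally with
#' exchangeable latent-Gaussian dependence `dependence`). For each planted
#' marker, joint membership is drawn at its `prevalence`; member patients
#' receive exactly the marker's call pattern on its stains, non-members draw
#' each component call at a marginal rate excluding the joint event, so the
#' realized risk prevalence matches the target in expectation.
#'
#' Survival: hazard_i = `baseline_rate` * exp(stage_lhr * stage_bin_i +
#' sum_k log_hr_k * member_ik); censoring times are Exp(`censor_rate`)
#' (`censor_rate = 0` means no censoring). Times are in months; no
#' administrative horizon is applied here (the screen applies it).
#'
#' @param panel a `stain_panel` (default [default_stain_panel()]).
#' @param n_patients cohort size (default 160).
#' @param planted list of `list(marker = marker_definition, log_hr =,
#'   prevalence =)` entries; NULL plants nothing.
#' @param stain_prevalence scalar or named-by-stain vector of P(call =
#'   over) for stains outside planted markers (default 0.5).
#' @param component_prevalence marginal probability that a single component
#'   stain of a planted marker matches its arrow (default 0.3; must be >=
#'   the marker prevalence).
#' @param dependence exchangeable latent correlation among non-planted
#'   stains (default 0).
#' @param baseline_rate exponential baseline hazard per month (default
#'   0.01, i.e. ~69-month median at reference covariates).
#' @param censor_rate exponential censoring rate per month (default 0.005).
#' @param stage_lhr log hazard ratio of stage III-IV vs I-II (default
#'   log(3.15)).
#' @param stage_probs probabilities of stages I-IV (default c(0.43, 0.17,
#'   0.13, 0.27)).
#' @param seed RNG seed.
#' @return list: `scores` (long core-level IHC table), `clinical`
#'   (patient_id, time, event, stage, grade, ln_metastasis, age, sex,
#'   alcohol, betel, smoking), `truth` (planted memberships and all rates).
#' @export
simulate_cohort <- function(panel = default_stain_panel(), n_patients = 160,
                            planted = NULL, stain_prevalence = 0.5,
                            component_prevalence = 0.3, dependence = 0,
                            baseline_rate = 0.01, censor_rate = 0.005,
                            stage_lhr = log(3.15),
                            stage_probs = c(0.43, 0.17, 0.13, 0.27),
                            seed = 1) {
  stopifnot(inherits(panel, "stain_panel"), n_patients >= 1,
            baseline_rate > 0, censor_rate >= 0,
            dependence >= 0, dependence < 1)
  stains <- panel$stain_id
  prev <- if (length(stain_prevalence) == 1L)
    setNames(rep(stain_prevalence, length(stains)), stains)
  else stain_prevalence[stains]
  stopifnot(all(prev > 0 & prev < 1))
  patients <- sprintf("P%03d", seq_len(n_patients))
  over_rules <- attr(panel, "over_rules")
  with_seed(seed, {
    call_mat <- matrix(NA_character_, n_patients, length(stains),
                       dimnames = list(patients, stains))
    # stains outside planted markers: exchangeable latent-Gaussian threshold
    planted_stains <- unique(unlist(lapply(planted, function(p) p$marker$stains)))
    free <- setdiff(stains, planted_stains)
    if (length(free)) {
      w <- rnorm(n_patients)
      for (s in free) {
        z <- sqrt(dependence) * w + sqrt(1 - dependence) * rnorm(n_patients)
        call_mat[, s] <- ifelse(z <= qnorm(prev[s]), "over", "under")
      }
    }
    membership <- matrix(0L, n_patients, length(planted),
                         dimnames = list(patients, NULL))
    for (k in seq_along(planted)) {
      pk <- planted[[k]]
      stopifnot(inherits(pk$marker, "marker_definition"),
                pk$prevalence > 0, pk$prevalence < 1)
      want <- ifelse(pk$marker$pattern == "up", "over", "under")
      other <- ifelse(want == "over", "under", "over")
      m <- rbinom(n_patients, 1, pk$prevalence)
      membership[, k] <- m
      arity <- length(pk$marker$stains)
      q <- max(0, (component_prevalence - pk$prevalence) / (1 - pk$prevalence))
      for (i in seq_len(n_patients)) {
        if (m[i] == 1L) {
          call_mat[i, pk$marker$stains] <- want
        } else if (arity == 1L) {
          call_mat[i, pk$marker$stains] <- other
        } else {
          repeat {
            hit <- runif(arity) < q
            if (!all(hit)) break
          }
          call_mat[i, pk$marker$stains] <- ifelse(hit, want, other)
        }
      }
    }
    # survival
    stage <- sample(c("I", "II", "III", "IV"), n_patients, replace = TRUE,
                    prob = stage_probs)
    stage_bin <- as.integer(stage %in% c("III", "IV"))
    lp <- stage_lhr * stage_bin
    for (k in seq_along(planted)) lp <- lp + planted[[k]]$log_hr * membership[, k]
    t_event <- rexp(n_patients, rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n_patients, rate = censor_rate)
              else rep(Inf, n_patients)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(
      patient_id = patients, time = time, event = event, stage = stage,
      grade = sample(c("low", "intermediate", "high"), n_patients, TRUE,
                     prob = c(0.43, 0.55, 0.02)),
      ln_metastasis = sample(c("yes", "no"), n_patients, TRUE,
                             prob = c(0.26, 0.74)),
      age = round(runif(n_patients, 30, 80)),
      sex = sample(c("male", "female"), n_patients, TRUE, prob = c(0.9, 0.1)),
      alcohol = sample(c("yes", "no"), n_patients, TRUE, prob = c(0.5, 0.5)),
      betel = sample(c("yes", "no"), n_patients, TRUE, prob = c(0.6, 0.4)),
      smoking = sample(c("yes", "no"), n_patients, TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    # core-level scores consistent with the calls
    rows <- vector("list", n_patients * length(stains))
    r <- 0L
    for (i in seq_len(n_patients)) {
      for (s in stains) {
        sc <- .scores_for_call(over_rules[[s]], call_mat[i, s])
        r <- r + 1L
        rows[[r]] <- data.frame(patient_id = patients[i], stain_id = s,
                                core_id = 1:3, intensity = sc$grades,
                                percent = sc$percent, stringsAsFactors = FALSE)
      }
    }
    scores <- do.call(rbind, rows)
    list(scores = scores, clinical = clinical,
         truth = list(calls = call_mat, membership = membership,
                      planted = planted, stain_prevalence = prev,
                      component_prevalence = component_prevalence,
                      dependence = dependence, baseline_rate = baseline_rate,
                      censor_rate = censor_rate, stage_lhr = stage_lhr,
                      stage_probs = stage_probs, seed = seed))
  })
}
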