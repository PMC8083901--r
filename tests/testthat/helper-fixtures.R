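# in-code fixture builders and independent oracles shared across tests

# a small expression matrix with named genes/samples
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# write a stain-panel data frame to a temp CSV and load it
make_panel <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_stain_panel(path)
}

# a 3-stain toy panel over distinct proteins
tiny_panel <- function() {
  make_panel(data.frame(
    stain_id = c("A(N)", "B(C)", "C(M)"),
    protein = c("A", "B", "C"),
    compartment = c("N", "C", "M"),
    under_rule = c("<1+", "<=1+", "<1+"),
    over_rule = c(">=1+", ">1+", ">=1+"),
    stringsAsFactors = FALSE))
}

# brute-force permutation null: enumerate every control-set choice and
# recompute the pattern fraction from scratch (independent of the package's
# internal .pair_fraction)
oracle_exact_permutation <- function(x, gene_a, gene_b, n_ctrl, pattern,
                                     fold_cutoff = 1.5) {
  thr <- log2(fold_cutoff)
  n <- ncol(x)
  sets <- combn(n, n_ctrl)
  apply(sets, 2, function(ctrl) {
    canc <- setdiff(seq_len(n), ctrl)
    ra <- log2(x[gene_a, canc] / mean(x[gene_a, ctrl]))
    rb <- log2(x[gene_b, canc] / mean(x[gene_b, ctrl]))
    call1 <- ifelse(ra >= thr, "u", ifelse(ra <= -thr, "d", "n"))
    call2 <- ifelse(rb >= thr, "u", ifelse(rb <= -thr, "d", "n"))
    mean(paste0(call1, call2) == pattern)
  })
}

# direct q-value formula with a fixed pi0 (independent implementation)
oracle_qvalues <- function(p, pi0) {
  m <- length(p)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# hand-computed two-group log-rank chi-square from 2x2 risk tables
oracle_logrank_chisq <- function(time, event, group) {
  dt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n0 <- sum(at_risk & group == 0)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    n <- n1 + n0
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# labels vector for a cancer/control split
split_labels <- function(samples, n_cancer) {
  setNames(rep(c("cancer", "control"),
               c(n_cancer, length(samples) - n_cancer)), samples)
}

# simulated pipeline inputs on disk + a matching config (shared by the
# pipeline and acceptance suites)
write_sim_inputs <- function(dir, seed = 21) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- data.frame(gene_a = "GENE001", gene_b = "GENE002",
                        pattern = "uu", fraction = 0.4)
  sim <- simulate_expression(n_cancer = 20, n_control = 10, n_genes = 30,
                             planted = planted, n_background_pairs = 6,
                             seed = seed)
  write_expression_matrix(sim$values, file.path(dir, "expression.tsv"))
  write_sample_labels(sim$labels, file.path(dir, "labels.tsv"))
  write_sl_pairs(sim$pairs, file.path(dir, "sl_pairs.tsv"))
  mk <- marker(c("A(N)", "B(C)"), c("down", "down"))
  coh <- simulate_cohort(panel = tiny_panel(), n_patients = 80,
                         planted = list(list(marker = mk, log_hr = log(3),
                                             prevalence = 0.2)),
                         seed = seed + 1)
  write.csv(coh$scores, file.path(dir, "ihc_scores.csv"), row.names = FALSE)
  write.csv(coh$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  panel_path <- file.path(dir, "panel.csv")
  write.csv(data.frame(stain_id = c("A(N)", "B(C)", "C(M)"),
                       protein = c("A", "B", "C"),
                       compartment = c("N", "C", "M"),
                       under_rule = c("<1+", "<=1+", "<1+"),
                       over_rule = c(">=1+", ">1+", ">=1+")),
            panel_path, row.names = FALSE)
  dir
}

sim_config <- function(dir, ...) {
  pipeline_config(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    sl_pairs = file.path(dir, "sl_pairs.tsv"),
    ihc_scores = file.path(dir, "ihc_scores.csv"),
    stain_panel = file.path(dir, "panel.csv"),
    clinical = file.path(dir, "clinical.csv"),
    n_perm = 100, seed = 7, ...)
}

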