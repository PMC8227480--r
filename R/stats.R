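# The study's statistical battery: normality-gated two-sample comparisons,
# summary-statistic t-tests, split-plot (mixed) group-by-time ANOVA,
# Spearman correlations, 2x2 chi-square, and the cohort-level analysis plan.

nirs_test <- function(test, statistic, df = NA_real_, p, direction = NA_real_,
                      n = NA_integer_, branch = NA_character_) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(min(max(p, 0), 1)),
                 direction = unname(direction), n = n, branch = branch),
            class = "nirs_test")
}

#' @export
print.nirs_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (!is.na(x$df[1])) paste0(", df = ",
                                          paste(signif(x$df, 4),
                                                collapse = ",")) else "",
              x$p))
  invisible(x)
}

# Shapiro-Wilk normality check; constant samples are treated as non-normal
# (the rank branch handles ties explicitly).
is_normalish <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Normality-gated two-sample comparison
#'
#' Mirrors the analysis policy: each sample (paired: the differences) is
#' checked with the Shapiro-Wilk test; when normality is not rejected
#' (p > 0.05) for both, the parametric branch fires (pooled-variance
#' Student t, or paired t), otherwise the rank branch (Mann-Whitney U with
#' normal approximation and tie correction, or Wilcoxon signed-rank). The
#' result records which branch fired.
#'
#' @param a,b Numeric samples (n >= 3 each; equal length when paired).
#' @param paired Paired comparison.
#' @return A `nirs_test` (fields: test, statistic, df, p, direction, n,
#'   branch).
#' @export
shapiro_gate_compare <- function(a, b, paired = FALSE) {
  if (length(a) < 3 || length(b) < 3) {
    nw_stop("need n >= 3 per sample", "invalid_input")
  }
  if (paired && length(a) != length(b)) {
    nw_stop("paired samples must have equal length", "invalid_input")
  }
  normal <- if (paired) is_normalish(a - b) else
    is_normalish(a) && is_normalish(b)
  dir <- sign(mean(a) - mean(b))
  if (normal) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
    nirs_test(if (paired) "paired t" else "Student t (pooled)",
              tt$statistic, tt$parameter, tt$p.value, dir,
              c(length(a), length(b)), "parametric")
  } else if (paired) {
    d <- a - b
    if (all(d == 0)) {
      return(nirs_test("Wilcoxon signed-rank", 0, NA, 1, 0,
                       c(length(a), length(b)), "rank"))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE,
                                              correct = FALSE))
    nirs_test("Wilcoxon signed-rank", wt$statistic, NA, wt$p.value, dir,
              c(length(a), length(b)), "rank")
  } else {
    if (length(unique(c(a, b))) == 1) {
      return(nirs_test("Mann-Whitney U", length(a) * length(b) / 2, NA, 1,
                       0, c(length(a), length(b)), "rank"))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    nirs_test("Mann-Whitney U", wt$statistic, NA, wt$p.value, dir,
              c(length(a), length(b)), "rank")
  }
}

#' Two-sample t-test from summary statistics
#'
#' Student t-test computed from printed means, SDs and group sizes, as used
#' for worked examples from summary tables. The pooled-variance variant
#' uses s2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2) with df n1+n2-2; the
#' Welch variant uses the Satterthwaite df.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant "pooled" (default) or "welch".
#' @return A `nirs_test`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) nw_stop("need n >= 2 per group", "invalid_input")
  if (sd1 < 0 || sd2 < 0) nw_stop("SDs must be >= 0", "invalid_input")
  delta <- mean1 - mean2
  if (variant == "pooled") {
    s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (delta == 0) {
      return(nirs_test(paste0("t from summary (", variant, ")"), 0, df, 1,
                       0, c(n1, n2)))
    }
    warning("zero variance with unequal means; p = 0")
    return(nirs_test(paste0("t from summary (", variant, ")"),
                     sign(delta) * Inf, df, 0, sign(delta), c(n1, n2)))
  }
  t <- delta / se
  nirs_test(paste0("t from summary (", variant, ")"), t, df,
            2 * stats::pt(-abs(t), df), sign(delta), c(n1, n2))
}

#' Mixed (split-plot) group-by-time ANOVA interaction
#'
#' Two-way mixed-design ANOVA with a between-subject treatment factor and a
#' within-subject time factor (subject as the blocking factor), no
#' sphericity correction. Returns the interaction F with df
#' ((t-1), (t-1)(N-g)) — (2, 44) for 12+12 subjects at 3 timepoints.
#' Subjects with incomplete timepoint series are dropped (listwise) with a
#' message.
#'
#' @param table Cohort table with columns `subject`, `treatment`,
#'   `timepoint` and the outcome.
#' @param outcome Name of the outcome column (default "tot_auc").
#' @return A `nirs_test`; `statistic` is the interaction F.
#' @export
mixed_anova_interaction <- function(table, outcome = "tot_auc") {
  need <- c("subject", "treatment", "timepoint", outcome)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    nw_stop(paste("missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  }
  tps <- sort(unique(table$timepoint))
  cnt <- table(table$subject)
  complete <- names(cnt)[cnt == length(tps)]
  dropped <- setdiff(unique(table$subject), complete)
  if (length(dropped)) {
    message(sprintf("mixed ANOVA: dropping %d incomplete subject(s)",
                    length(dropped)))
  }
  d <- table[table$subject %in% complete, c(need)]
  d <- d[order(d$subject, d$timepoint), ]
  y <- d[[outcome]]
  subj <- factor(d$subject)
  grp <- factor(d$treatment)
  tim <- factor(d$timepoint)
  N <- nlevels(subj)
  g <- nlevels(grp)
  t_ <- nlevels(tim)
  if (t_ < 2 || g < 2 || N <= g) {
    nw_stop("need >= 2 groups, >= 2 timepoints, and N > g", "invalid_input")
  }
  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_tim <- tapply(y, tim, mean)
  m_cell <- tapply(y, list(grp, tim), mean)
  n_g <- tapply(y, grp, length) / t_
  subj_grp <- tapply(as.character(d$treatment), subj, `[`, 1)

  ss_between <- t_ * sum((m_subj - grand)^2)
  ss_group <- t_ * sum(n_g * (m_grp - grand)^2)
  ss_time <- N * sum((m_tim - grand)^2)
  ss_gt <- sum(rep(n_g, times = t_) *
                 (m_cell - outer(m_grp, rep(1, t_)) -
                    outer(rep(1, g), m_tim) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_werr <- ss_total - ss_between - ss_time - ss_gt
  df_gt <- (g - 1) * (t_ - 1)
  df_err <- (t_ - 1) * (N - g)
  f <- (ss_gt / df_gt) / (ss_werr / df_err)
  if (!is.finite(f)) f <- 0
  nirs_test("mixed ANOVA interaction (group x time)", f, c(df_gt, df_err),
            stats::pf(f, df_gt, df_err, lower.tail = FALSE),
            n = N)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses the t approximation with df = n - 2.
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @return A `nirs_test`; `statistic` is rho.
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) nw_stop("need n >= 4 complete pairs", "invalid_input")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    nw_stop("correlation undefined for constant input",
            "undefined_correlation")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  nirs_test("Spearman rho", rho, n - 2, p, sign(rho), n)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction: X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)),
#' df = 1.
#'
#' @param a,b First row counts; @param c,d second row counts.
#' @return A `nirs_test`.
#' @export
chi_square_proportions <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    nw_stop("counts must be non-negative integers", "invalid_table")
  }
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    nw_stop("zero margin in 2x2 table", "invalid_table")
  }
  n <- sum(cnt)
  x2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  nirs_test("chi-square (2x2, uncorrected)", x2, 1,
            stats::pchisq(x2, 1, lower.tail = FALSE),
            sign(a / (a + b) - c / (c + d)), n)
}

#' Within-subject linear-trend t-test
#'
#' Per-subject slope over the scheduled timepoints (linear contrast),
#' tested against zero with a one-sample t-test. Used for the "declining
#' trend" analyses over T0/T1/T2.
#'
#' @param mat Subjects x timepoints matrix of outcome values (timepoints in
#'   chronological order).
#' @return A `nirs_test`.
#' @export
trend_t_test <- function(mat) {
  t_ <- ncol(mat)
  if (t_ < 2 || nrow(mat) < 3) {
    nw_stop("need >= 3 subjects and >= 2 timepoints", "invalid_input")
  }
  ctr <- seq_len(t_) - mean(seq_len(t_))
  slopes <- as.numeric(mat %*% ctr) / sum(ctr^2)
  tt <- stats::t.test(slopes)
  nirs_test("within-subject linear trend t", tt$statistic, tt$parameter,
            tt$p.value, sign(mean(slopes)), nrow(mat))
}

# ---- cohort-level analysis plan -------------------------------------------

cohort_required_cols <- c(
  "subject", "cohort", "treatment", "timepoint", "tot_auc", "maff_auc",
  "laff_auc", "edss", "age", "sex", "phenotype", "t25fw_speed", "mwd6",
  "bbs", "rti", "rti_category")

test_row <- function(id, res) {
  data.frame(id = id, test = res$test, statistic = res$statistic,
             df = if (length(res$df) > 1) paste(signif(res$df, 6),
                                                collapse = ",") else
               as.character(res$df),
             p = res$p, direction = res$direction,
             n = paste(res$n, collapse = ","),
             branch = res$branch %||% NA_character_,
             stringsAsFactors = FALSE)
}

safe_test <- function(id, expr) {
  res <- tryCatch(expr, nirswalk_error = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(res)) NULL else test_row(id, res)
}

#' Run the cohort analysis plan
#'
#' Executes the study's analysis battery over a cohort table (one row per
#' subject x timepoint): baseline patient-vs-healthy comparisons of the
#' three biomarkers; baseline subgroup contrasts (age median split, sex,
#' phenotype, EDSS 6.0 vs 6.5); baseline Spearman correlations of the
#' biomarkers with EDSS, gait speed, 6-minute distance and balance;
#' within-arm T0->T2 change tests (linear trend and paired) and the
#' between-arm change comparison; mixed group-by-time ANOVAs; correlations
#' of biomarker changes with relative training intensity (overall and per
#' arm) plus high/low intensity contrasts; correlations of changes in the
#' more affected hemisphere with functional changes; and the baseline
#' total-activation vs gait-speed-change correlation. No multiple-testing
#' correction is applied (the number of tests run is annotated). Contrasts
#' whose subgroups are too small are skipped. The report is deterministic
#' and invariant to row order.
#'
#' @param table Cohort table with the columns listed in the error message
#'   on failure (see package vignette).
#' @param alpha Significance level for the `significant` flag.
#' @return A data.frame report (one row per test: id, test, statistic, df,
#'   p, direction, n, branch, significant) with attribute `n_tests`.
#' @export
analyze_cohort <- function(table, alpha = 0.05) {
  miss <- setdiff(cohort_required_cols, names(table))
  if (length(miss)) {
    nw_stop(paste("cohort table missing columns:",
                  paste(miss, collapse = ", ")), "schema_error")
  }
  if (nrow(table) == 0) nw_stop("empty cohort table", "schema_error")
  if (anyDuplicated(table[c("subject", "timepoint")])) {
    nw_stop("(subject, timepoint) rows must be unique", "schema_error")
  }
  table <- table[order(table$subject, table$timepoint), ]
  base <- table[table$timepoint == "T0", ]
  pw <- base[base$cohort == "PwMS", ]
  he <- base[base$cohort == "healthy", ]
  rows <- list()
  add <- function(r) if (!is.null(r)) rows[[length(rows) + 1]] <<- r

  # (1) baseline PwMS vs healthy
  for (v in c("tot_auc", "maff_auc", "laff_auc")) {
    add(safe_test(paste0("baseline_pwms_vs_healthy_", v),
                  shapiro_gate_compare(pw[[v]], he[[v]])))
  }

  # (2) baseline subgroup contrasts within patients (on total activation)
  if (nrow(pw) >= 6) {
    split2 <- function(id, sel_a, sel_b) {
      if (sum(sel_a) >= 3 && sum(sel_b) >= 3) {
        add(safe_test(id, shapiro_gate_compare(pw$tot_auc[sel_a],
                                               pw$tot_auc[sel_b])))
      }
    }
    med_age <- stats::median(pw$age)
    split2("baseline_age_split", pw$age >= med_age, pw$age < med_age)
    split2("baseline_sex", pw$sex == "M", pw$sex == "F")
    split2("baseline_phenotype", pw$phenotype == "primary progressive",
           pw$phenotype == "secondary progressive")
    split2("baseline_edss", pw$edss >= 6.5, pw$edss <= 6.0)
  }

  # (3) baseline correlations with clinical/performance parameters
  for (v in c("tot_auc", "maff_auc", "laff_auc")) {
    for (cv in c("edss", "t25fw_speed", "mwd6", "bbs")) {
      add(safe_test(paste0("baseline_corr_", v, "_", cv),
                    spearman_correlation(pw[[v]], pw[[cv]])))
    }
  }

  # change scores T2 - T0 per patient (complete pairs only)
  wide <- function(v) {
    t0 <- table[table$cohort == "PwMS" & table$timepoint == "T0",
                c("subject", "treatment", v)]
    t1 <- table[table$cohort == "PwMS" & table$timepoint == "T1",
                c("subject", v)]
    t2 <- table[table$cohort == "PwMS" & table$timepoint == "T2",
                c("subject", v)]
    m <- merge(merge(t0, t1, by = "subject", suffixes = c("_T0", "_T1")),
               t2, by = "subject")
    names(m)[3:5] <- c("T0", "T1", "T2")
    m
  }
  wtot <- wide("tot_auc")
  wmaff <- wide("maff_auc")
  wlaff <- wide("laff_auc")
  wspeed <- wide("t25fw_speed")
  wmwd <- wide("mwd6")
  delta <- data.frame(
    subject = wtot$subject, treatment = wtot$treatment,
    d_tot = wtot$T2 - wtot$T0, d_maff = wmaff$T2 - wmaff$T0,
    d_laff = wlaff$T2 - wlaff$T0, d_speed = wspeed$T2 - wspeed$T0,
    d_mwd = wmwd$T2 - wmwd$T0, stringsAsFactors = FALSE)
  rti_by_subj <- unique(table[table$cohort == "PwMS",
                              c("subject", "rti", "rti_category")])
  delta <- merge(delta, rti_by_subj, by = "subject")

  # (4) within-arm trends and between-arm change comparison
  for (arm in c("RAGT", "OW")) {
    for (v in list(c("tot", "wtot"), c("maff", "wmaff"),
                   c("laff", "wlaff"))) {
      w <- get(v[2])
      m <- as.matrix(w[w$treatment == arm, c("T0", "T1", "T2")])
      if (nrow(m) >= 3) {
        add(safe_test(paste0("trend_", arm, "_", v[1]), trend_t_test(m)))
        add(safe_test(paste0("paired_T0T2_", arm, "_", v[1]),
                      shapiro_gate_compare(m[, "T2"], m[, "T0"],
                                           paired = TRUE)))
      }
    }
  }
  add(safe_test("change_between_arms_tot",
                shapiro_gate_compare(delta$d_tot[delta$treatment == "RAGT"],
                                     delta$d_tot[delta$treatment == "OW"])))

  # (5) mixed group-by-time ANOVA
  pwl <- table[table$cohort == "PwMS", ]
  for (v in c("tot_auc", "maff_auc")) {
    add(safe_test(paste0("anova_interaction_", v),
                  mixed_anova_interaction(pwl, v)))
  }

  # (6) training-intensity relationships
  for (v in c("d_tot", "d_maff", "d_laff")) {
    add(safe_test(paste0("corr_rti_", v, "_all"),
                  spearman_correlation(delta$rti, delta[[v]])))
    for (arm in c("RAGT", "OW")) {
      sel <- delta$treatment == arm
      add(safe_test(paste0("corr_rti_", v, "_", arm),
                    spearman_correlation(delta$rti[sel], delta[[v]][sel])))
    }
  }
  for (arm in c("RAGT", "OW")) {
    sel <- delta$treatment == arm
    hi <- sel & delta$rti_category == "high"
    lo <- sel & delta$rti_category == "low"
    if (sum(hi) >= 3 && sum(lo) >= 3) {
      for (v in c("d_tot", "d_maff")) {
        add(safe_test(paste0("rti_category_", arm, "_", v),
                      shapiro_gate_compare(delta[[v]][hi], delta[[v]][lo])))
      }
    }
  }

  # (7) biomarker change vs functional change
  add(safe_test("corr_dmaff_dspeed",
                spearman_correlation(delta$d_maff, delta$d_speed)))
  add(safe_test("corr_dmaff_dmwd",
                spearman_correlation(delta$d_maff, delta$d_mwd)))

  # (8) baseline activation vs subsequent gait-speed change
  bt <- merge(pw[, c("subject", "tot_auc")],
              delta[, c("subject", "d_speed")], by = "subject")
  add(safe_test("corr_baseline_tot_dspeed",
                spearman_correlation(bt$tot_auc, bt$d_speed)))

  rep <- do.call(rbind, rows)
  rep$significant <- rep$p < alpha
  attr(rep, "n_tests") <- nrow(rep)
  attr(rep, "alpha") <- alpha
  rep
}
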