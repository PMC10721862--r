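#' Post-minus-pre delta responses
#'
#' The per-subject, per-session outcome fed into the mixed ANOVA: metric
#' value in the post-injection epoch minus the pre-injection baseline.
#'
#' @param tp2,tp1 Numeric vectors (same length, paired by position).
#'
#' @return `tp2 - tp1`.
#' @export
delta_response <- function(tp2, tp1) {
  if (length(tp2) != length(tp1)) stopf("paired values required")
  if (anyNA(tp2) || anyNA(tp1)) stopf("missing session value")
  tp2 - tp1
}

# Core mixed between(group) x within(treatment) ANOVA on the per-subject
# psilocybin-minus-saline contrast d. With two within levels the design
# collapses exactly: the interaction F is the one-way F of d between
# groups, and the treatment F tests the unweighted mean of the group means
# of d (Type III), both with df (1, n - 2).
mixed_anova_f <- function(d, group) {
  g <- factor(group)
  n <- length(d)
  if (nlevels(g) != 2) stopf("exactly two groups required")
  n1 <- sum(g == levels(g)[1]); n2 <- n - n1
  if (min(n1, n2) < 2) stopf("need >= 2 subjects per group")
  m1 <- mean(d[g == levels(g)[1]]); m2 <- mean(d[g == levels(g)[2]])
  ssw <- sum((d - ifelse(g == levels(g)[1], m1, m2))^2)
  mse <- ssw / (n - 2)
  # treatment: unweighted grand mean of d (divide by 2 for the y scale is
  # irrelevant to F)
  b0 <- (m1 + m2) / 2
  f_t <- if (mse > 0) b0^2 / (mse * (1 / n1 + 1 / n2) / 4) else Inf
  # interaction: between-group difference of d
  f_i <- if (mse > 0) (n1 * n2 / n) * (m1 - m2)^2 / mse else Inf
  list(f_treatment = f_t, f_interaction = f_i, df = c(1, n - 2))
}

#' Repeated-measures (mixed between-within) ANOVA on delta responses
#'
#' Within-subject treatment effect (psilocybin vs saline) and
#' subgroup-by-treatment interaction for a two-session crossover with a
#' two-level between factor. Outcomes are the per-session delta responses;
#' the model reduces to tests on the per-subject treatment contrast, with
#' df `(1, n_subjects - 2)` for both effects (Type III, robust to the
#' unbalanced 15:6 allocation).
#'
#' @param delta Numeric vector of delta responses, one per subject x
#'   session.
#' @param treatment `"psilocybin"`/`"saline"` per entry.
#' @param subject Subject id per entry (each id once per treatment).
#' @param group Group label per subject entry.
#'
#' @return List of class `rm_anova`: `f_treatment`, `f_interaction`,
#'   `df`, `p_treatment`, `p_interaction`, `n_subjects`, `contrast` (the
#'   per-subject psilocybin-minus-saline values), `group_by_subject`.
#' @export
rm_anova <- function(delta, treatment, subject, group) {
  tab <- table(subject, treatment)
  if (!all(dim(tab) == c(length(unique(subject)), 2)) || any(tab != 1)) {
    stopf("every subject needs exactly one delta per treatment")
  }
  subj <- unique(subject)
  d <- vapply(subj, function(s) {
    delta[subject == s & treatment == "psilocybin"] -
      delta[subject == s & treatment == "saline"]
  }, 0)
  sg <- vapply(subj, function(s) group[match(s, subject)], "")
  res <- mixed_anova_f(d, sg)
  structure(list(
    f_treatment = res$f_treatment, f_interaction = res$f_interaction,
    df = res$df,
    p_treatment = pf(res$f_treatment, res$df[1], res$df[2], lower.tail = FALSE),
    p_interaction = pf(res$f_interaction, res$df[1], res$df[2],
                       lower.tail = FALSE),
    n_subjects = length(subj), contrast = stats::setNames(d, subj),
    group_by_subject = stats::setNames(sg, subj)
  ), class = "rm_anova")
}

#' Permutation p-values for the mixed between-within ANOVA
#'
#' Non-parametric counterpart of [rm_anova()] for unbalanced
#' between-within designs. The treatment effect is tested by randomly
#' swapping the two sessions within each subject (sign flips of the
#' subject contrast); the interaction by permuting group labels between
#' subjects while keeping within-subject pairs intact. P-values carry the
#' add-one correction and are never zero.
#'
#' @inheritParams rm_anova
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#'
#' @return List: `p_treatment`, `p_interaction`, `n_perm`, plus the
#'   observed `f_treatment`/`f_interaction`.
#' @export
permutation_anova <- function(delta, treatment, subject, group,
                              n_perm = 10000, seed = 1) {
  if (n_perm < 100) warnf("n_perm < 100 gives very coarse p-values")
  obs <- rm_anova(delta, treatment, subject, group)
  d <- obs$contrast
  sg <- obs$group_by_subject
  n <- length(d)
  with_seed(seed, {
    ft <- vapply(seq_len(n_perm), function(k) {
      mixed_anova_f(d * sample(c(-1, 1), n, replace = TRUE), sg)$f_treatment
    }, 0)
    fi <- vapply(seq_len(n_perm), function(k) {
      mixed_anova_f(d, sample(sg))$f_interaction
    }, 0)
    list(p_treatment = (1 + sum(ft >= obs$f_treatment)) / (n_perm + 1),
         p_interaction = (1 + sum(fi >= obs$f_interaction)) / (n_perm + 1),
         n_perm = n_perm,
         f_treatment = obs$f_treatment, f_interaction = obs$f_interaction)
  })
}

#' Normality and variance-homogeneity checks per design cell
#'
#' Shapiro-Wilk p-value per cell and a Bartlett p-value for equality of
#' variances across cells, the standard screens run before trusting
#' parametric ANOVA p-values.
#'
#' @param values Numeric vector.
#' @param cell Cell label per value (>= 3 values per cell).
#'
#' @return List: `shapiro` (named vector of per-cell p), `bartlett`
#'   (scalar p).
#' @export
assumption_checks <- function(values, cell) {
  cells <- split(values, cell)
  if (any(vapply(cells, length, 0L) < 3)) stopf("need >= 3 values per cell")
  if (any(vapply(cells, function(x) sd(x) == 0, TRUE))) {
    stopf("constant cell: checks undefined")
  }
  sw <- vapply(cells, function(x) shapiro.test(x)$p.value, 0)
  bt <- bartlett.test(cells)$p.value
  list(shapiro = sw, bartlett = bt)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for `m` tests (`m` may exceed the number of
#' p-values supplied, e.g. when only a subset is reported).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Total number of tests (default `length(p)`).
#'
#' @return Adjusted p-values, monotone in the input order, capped at 1.
#' @export
fdr_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  if (m < length(p)) stopf("m must be >= length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Spearman rank correlation with t-transform
#'
#' Rank correlation with average ranks for ties, a two-sided p-value
#' (exact for small samples without ties, t approximation otherwise, via
#' `stats::cor.test`), and the absolute-value t-transform
#' `t = |rho| / sqrt((1 - rho^2) / (N - 2))` used for cluster-defining
#' thresholds on correlation maps.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#'
#' @return List of class `spearman_result`: `rho`, `n`, `p`, `t`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 4) stopf("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  structure(list(rho = rho, n = length(x), p = ct$p.value,
                 t = rho_to_t(rho, length(x))),
            class = "spearman_result")
}

#' Transform a correlation coefficient to a t value
#'
#' `t = |rho| / sqrt((1 - rho^2) / (N - 2))`; by construction t >= 0
#' (the sign of the association is carried by rho). `|rho| = 1` yields
#' `Inf`.
#'
#' @param rho Correlation in `[-1, 1]`.
#' @param n Sample size, >= 3.
#'
#' @return t value.
#' @export
#' @examples
#' rho_to_t(0.57, 15)  # ~2.50
rho_to_t <- function(rho, n) {
  if (n < 3) stopf("n must be >= 3")
  if (abs(rho) > 1) stopf("|rho| must be <= 1")
  if (abs(rho) == 1) return(Inf)
  abs(rho) / sqrt((1 - rho^2) / (n - 2))
}

#' Upper-tail critical value of the t or F distribution
#'
#' Cluster-defining and edge-primary thresholds reported to two decimals,
#' e.g. `critical_threshold(0.01, 20)` = 2.53 and
#' `critical_threshold(0.01, 1, df2 = 40, dist = "f")` = 7.31.
#'
#' @param alpha Upper-tail probability, in (0, 1).
#' @param df Degrees of freedom (numerator df for `"f"`).
#' @param df2 Denominator df (required for `"f"`).
#' @param dist `"t"` (default) or `"f"`.
#'
#' @return Critical value rounded to two decimals.
#' @export
critical_threshold <- function(alpha, df, df2 = NULL, dist = c("t", "f")) {
  dist <- match.arg(dist)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (df < 1) stopf("df must be >= 1")
  val <- if (dist == "t") {
    qt(1 - alpha, df)
  } else {
    if (is.null(df2)) stopf("df2 required for the F distribution")
    qf(1 - alpha, df, df2)
  }
  round(val, 2)
}

#' Normalized relapse rate
#'
#' Relapse-phase alcohol intake as a percentage of baseline intake; the
#' dimensional measure of the ADE phenotype (100% = no relapse increase).
#'
#' @param baseline Baseline intake in g/kg (> 0).
#' @param relapse Relapse intake in g/kg (>= 0).
#'
#' @return `100 * relapse / baseline`.
#' @export
normalized_relapse <- function(baseline, relapse) {
  if (any(baseline <= 0)) stopf("baseline must be positive")
  if (any(relapse < 0)) stopf("relapse must be non-negative")
  100 * relapse / baseline
}
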