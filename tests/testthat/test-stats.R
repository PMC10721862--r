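test_that("delta responses subtract pairwise", {
  expect_equal(delta_response(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(delta_response(c(3, 1), c(1, 2)), -delta_response(c(1, 2), c(3, 1)))
  expect_equal(delta_response(c(5, 7, 9), c(1, 2, 3)), c(4, 5, 6))
  expect_error(delta_response(c(1, NA), c(1, 2)), "missing")
})

test_that("mixed ANOVA agrees with the aov Error-stratum oracle", {
  # balanced case, where Type I and Type III coincide
  set.seed(31)
  n_per <- 8
  subj <- paste0("S", 1:(2 * n_per))
  grp <- rep(c("A", "B"), each = n_per)
  long <- expand.grid(subject = subj, treatment = c("psilocybin", "saline"),
                      stringsAsFactors = FALSE)
  long$group <- grp[match(long$subject, subj)]
  long$y <- rnorm(nrow(long)) +
    ifelse(long$treatment == "psilocybin", 0.8, 0) +
    ifelse(long$treatment == "psilocybin" & long$group == "B", 0.5, 0)
  fit <- rm_anova(long$y, long$treatment, long$subject, long$group)
  expect_equal(fit$df, c(1, 2 * n_per - 2))

  oracle <- summary(stats::aov(
    y ~ group * treatment + Error(factor(subject) / treatment), data = long))
  # find the within-subject stratum (the one containing the treatment term)
  within <- NULL
  for (st in oracle) {
    tab <- st[[1]]
    if ("treatment" %in% trimws(rownames(tab))) within <- tab
  }
  rownames(within) <- trimws(rownames(within))
  expect_equal(fit$f_treatment, within["treatment", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$f_interaction, within["group:treatment", "F value"],
               tolerance = 1e-10)
})

test_that("design df matches the 21-subject two-group crossover", {
  set.seed(32)
  coh <- generate_cohort(15, 6, seed = 1)
  long <- expand.grid(subject = coh$subject_id,
                      treatment = c("psilocybin", "saline"),
                      stringsAsFactors = FALSE)
  long$group <- coh$group[match(long$subject, coh$subject_id)]
  long$y <- rnorm(42)
  fit <- rm_anova(long$y, long$treatment, long$subject, long$group)
  expect_equal(fit$df, c(1, 19))
  expect_error(rm_anova(long$y[-1], long$treatment[-1], long$subject[-1],
                        long$group[-1]), "exactly one")
})

test_that("parametric mixed ANOVA is calibrated and powered", {
  set.seed(33)
  n_reps <- 500
  rej <- 0
  for (k in seq_len(n_reps)) {
    d <- rnorm(21)  # null: no treatment effect
    g <- rep(c("A", "B"), c(15, 6))
    f <- psiloconn:::mixed_anova_f(d, g)
    if (pf(f$f_treatment, 1, 19, lower.tail = FALSE) < 0.05) rej <- rej + 1
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_reps)
  expect_gte(rej / n_reps, ci[1])
  expect_lte(rej / n_reps, ci[2])

  # 2-SD shift: high power
  hits <- 0
  for (k in 1:100) {
    d <- rnorm(21) + 2
    g <- rep(c("A", "B"), c(15, 6))
    f <- psiloconn:::mixed_anova_f(d, g)
    if (pf(f$f_treatment, 1, 19, lower.tail = FALSE) < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("permutation ANOVA is deterministic and tracks the parametric p", {
  set.seed(34)
  long <- expand.grid(subject = paste0("S", 1:12),
                      treatment = c("psilocybin", "saline"),
                      stringsAsFactors = FALSE)
  long$group <- rep(c("A", "B"), 6)[match(long$subject, paste0("S", 1:12))]
  long$y <- rnorm(24) + ifelse(long$treatment == "psilocybin", 0.9, 0)
  p1 <- permutation_anova(long$y, long$treatment, long$subject, long$group,
                          n_perm = 500, seed = 7)
  p2 <- permutation_anova(long$y, long$treatment, long$subject, long$group,
                          n_perm = 500, seed = 7)
  expect_identical(p1$p_treatment, p2$p_treatment)
  expect_gte(p1$p_treatment, 1 / 501)

  # Gaussian data: permutation and parametric p agree closely
  gaps <- replicate(20, {
    long$y <- rnorm(24) + ifelse(long$treatment == "psilocybin", 0.5, 0)
    fit <- rm_anova(long$y, long$treatment, long$subject, long$group)
    pp <- permutation_anova(long$y, long$treatment, long$subject,
                            long$group, n_perm = 2000,
                            seed = sample.int(1e6, 1))
    abs(pp$p_treatment - fit$p_treatment)
  })
  expect_lt(median(gaps), 0.02)
})

test_that("assumption checks detect what they should", {
  set.seed(35)
  vals <- c(rnorm(20), rnorm(20, sd = 3))
  cell <- rep(c("a", "b"), each = 20)
  ck <- assumption_checks(vals, cell)
  expect_length(ck$shapiro, 2)
  expect_lt(ck$bartlett, 0.05)  # variance ratio 9
  expect_error(assumption_checks(rep(1, 10), rep(c("a", "b"), 5)),
               "constant")
  expect_error(assumption_checks(rnorm(4), rep(c("a", "b"), 2)), ">= 3")
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- fdr_adjust(p)
  expect_equal(order(adj), order(p))
  expect_true(all(adj <= 1) && all(adj >= p))
  # m larger than the supplied set scales up
  expect_equal(fdr_adjust(0.01, m = 44), 0.44)
  expect_error(fdr_adjust(c(0.1, 0.2), m = 1), "m must be")
  expect_error(fdr_adjust(1.2), "\\[0, 1\\]")
})

test_that("Spearman correlation handles monotone maps and ties", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)

  # tied data against an average-rank oracle
  set.seed(36)
  a <- sample(1:4, 20, replace = TRUE)
  b <- sample(1:4, 20, replace = TRUE)
  sp <- spearman_rho(a, b)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(sp$rho, oracle, tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 10), 1:10), "constant")
})

test_that("rho-to-t transform matches the printed formula", {
  expect_equal(rho_to_t(0, 10), 0)
  expect_equal(rho_to_t(0.57, 15), 2.50, tolerance = 0.005)
  expect_equal(rho_to_t(-0.57, 15), rho_to_t(0.57, 15))
  expect_true(is.infinite(rho_to_t(1, 10)))
  expect_error(rho_to_t(0.5, 2), ">= 3")
  # monotone in |rho| and in N
  expect_gt(rho_to_t(0.6, 10), rho_to_t(0.5, 10))
  expect_gt(rho_to_t(0.5, 20), rho_to_t(0.5, 10))
})

test_that("critical thresholds reproduce the standard table", {
  expect_equal(critical_threshold(0.01, 20), 2.53)
  expect_equal(critical_threshold(0.001, 13), 3.85)
  expect_equal(critical_threshold(0.5, 20), 0.00)
  expect_equal(critical_threshold(0.01, 1, df2 = 40, dist = "f"), 7.31)
  expect_error(critical_threshold(1.5, 10), "alpha")
  expect_error(critical_threshold(0.01, 1, dist = "f"), "df2")
})

test_that("normalized relapse rate is the baseline percentage", {
  expect_equal(normalized_relapse(6, 6), 100)
  expect_equal(normalized_relapse(6.35, 8.10), 127.6, tolerance = 0.05)
  expect_error(normalized_relapse(0, 5), "positive")
})

test_that("cluster labeling respects the chosen connectivity", {
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE  # diagonal neighbour: separate under 6-connectivity
  lab6 <- psiloconn:::label_clusters(m, 6)
  expect_equal(max(lab6), 2)
  lab18 <- psiloconn:::label_clusters(m, 18)
  expect_equal(max(lab18), 1)
})

test_that("cluster correction finds planted blocks and respects the floor", {
  set.seed(37)
  d <- c(8, 8, 4)
  n <- 12
  # planted activation block with a strong effect
  maps <- lapply(1:n, function(i) {
    m <- array(rnorm(prod(d)), d)
    m[2:4, 2:4, 1:2] <- m[2:4, 2:4, 1:2] + 2
    m
  })
  res <- cluster_correct(maps, cdt = 2.53, n_perm = 200, seed = 38)
  expect_gt(nrow(res$clusters), 0)
  expect_lte(res$clusters$p_fwe[1], 0.05)
  expect_gte(res$clusters$extent[1], 18)
  expect_true(all(res$clusters$p_fwe >= 1 / 201))

  # map everywhere below the threshold: no clusters
  flat <- lapply(1:n, function(i) array(rnorm(prod(d), 0, 0.01), d))
  res2 <- cluster_correct(flat, cdt = 10, n_perm = 50, seed = 39)
  expect_equal(nrow(res2$clusters), 0)
})

test_that("correlation-mode cluster correction recovers a covariate effect", {
  set.seed(40)
  d <- c(6, 6, 3)
  n <- 15
  cov <- rnorm(n)
  maps <- lapply(1:n, function(i) {
    m <- array(rnorm(prod(d)), d)
    m[1:3, 1:3, 1] <- m[1:3, 1:3, 1] + 2.5 * cov[i]
    m
  })
  res <- cluster_correct(maps, cdt = 2.65, type = "correlation",
                         covariate = cov, n_perm = 200, seed = 41)
  expect_gt(nrow(res$clusters), 0)
  expect_lte(res$clusters$p_fwe[1], 0.05)
})
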