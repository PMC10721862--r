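#' Run the full crossover connectivity analysis on a synthetic cohort
#'
#' Drives every stage of the pipeline end to end: simulate both sessions
#' per subject, preprocess (framewise displacement, scrubbing, motion
#' regression, band-pass), split TP1/TP2 epochs, compute Fisher-z
#' connectivity and post-minus-pre difference matrices, then run the
#' inference layer: mixed-ANOVA (parametric and permutation) on the mean
#' DMN connectivity delta responses, the network-based statistic on the
#' difference matrices, and the Spearman correlation between normalized
#' relapse rate and the psilocybin-induced DMN connectivity decrease
#' (Delta-sal minus Delta-psi) in the ADE subgroup.
#'
#' @param cohort A [generate_cohort()] table.
#' @param spec An [effect_spec()].
#' @param seed RNG seed governing all simulation and permutation draws.
#' @param n_frames Frames per session (default 1450).
#' @param n_perm_anova Permutations for the ANOVA (default 2000).
#' @param n_perm_nbs Permutations for the NBS (default 2000).
#' @param f_pt NBS primary threshold (default 7.31).
#' @param run_nbs Set `FALSE` to skip the NBS stage.
#'
#' @return List of class `cohort_analysis`: `dmn` (per subject x session
#'   delta responses), `anova`, `perm_anova`, `nbs`, `spearman`
#'   (relapse vs DMN decrease, ADE only), `diffs`, `cohort`.
#' @export
analyze_cohort <- function(cohort, spec = effect_spec(), seed = 1,
                           n_frames = 1450, n_perm_anova = 2000,
                           n_perm_nbs = 2000, f_pt = 7.31, run_nbs = TRUE) {
  sessions <- expand.grid(subject = cohort$subject_id,
                          treatment = c("psilocybin", "saline"),
                          stringsAsFactors = FALSE)
  diffs <- vector("list", nrow(sessions))
  dmn_delta <- numeric(nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    subj <- cohort[cohort$subject_id == sessions$subject[i], ]
    ses <- simulate_session(subj, sessions$treatment[i], spec,
                            seed = sub_seed(seed, i), n_frames = n_frames)
    pre <- preprocess_session(ses)
    z1 <- fc_matrix(pre$tp1, epoch = "TP1")
    z2 <- fc_matrix(pre$tp2, epoch = "TP2")
    diffs[[i]] <- diff_matrix(z2, z1, session = sessions$treatment[i])
    dmn_delta[i] <- delta_response(dmn_connectivity(z2)$mean,
                                   dmn_connectivity(z1)$mean)
  }
  grp <- cohort$group[match(sessions$subject, cohort$subject_id)]
  aov_res <- rm_anova(dmn_delta, sessions$treatment, sessions$subject, grp)
  perm_res <- permutation_anova(dmn_delta, sessions$treatment,
                                sessions$subject, grp,
                                n_perm = n_perm_anova,
                                seed = sub_seed(seed, 9001))
  nbs_res <- NULL
  if (run_nbs) {
    nbs_res <- nbs_permutation_test(diffs, sessions$treatment,
                                    sessions$subject, group = grp,
                                    contrast = "treatment", f_pt = f_pt,
                                    n_perm = n_perm_nbs,
                                    seed = sub_seed(seed, 9002))
  }
  # psilocybin-induced DMN decrease vs relapse intensity (ADE only)
  sp <- NULL
  ade <- cohort$subject_id[cohort$group == "ADE"]
  if (length(ade) >= 4) {
    dec <- vapply(ade, function(s) {
      dmn_delta[sessions$subject == s & sessions$treatment == "saline"] -
        dmn_delta[sessions$subject == s & sessions$treatment == "psilocybin"]
    }, 0)
    rn <- cohort$relapse_norm[match(ade, cohort$subject_id)]
    sp <- spearman_rho(rn, dec)
  }
  structure(list(
    dmn = data.frame(subject = sessions$subject,
                     treatment = sessions$treatment, group = grp,
                     dmn_delta = dmn_delta, stringsAsFactors = FALSE),
    anova = aov_res, perm_anova = perm_res, nbs = nbs_res, spearman = sp,
    diffs = diffs, cohort = cohort
  ), class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Crossover cohort analysis: %d subjects (%d ADE, %d control)\n",
              nrow(x$cohort), sum(x$cohort$group == "ADE"),
              sum(x$cohort$group == "control")))
  cat(sprintf("Mean DMN connectivity, treatment effect: F(%d,%d) = %.3f, p = %.4g, p_perm = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$f_treatment,
              x$anova$p_treatment, x$perm_anova$p_treatment))
  cat(sprintf("Group-by-treatment interaction: F = %.3f, p = %.4g\n",
              x$anova$f_interaction, x$anova$p_interaction))
  if (!is.null(x$nbs) && length(x$nbs$components)) {
    cmp <- x$nbs$components[[1]]
    cat(sprintf("NBS: largest component extent %d edges, p_FWE = %.4g\n",
                cmp$extent, cmp$p_fwe))
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("Relapse vs DMN decrease (ADE): rho = %.3f, p = %.4g\n",
                x$spearman$rho, x$spearman$p))
  }
  invisible(x)
}
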