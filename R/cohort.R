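#' Generate a synthetic crossover cohort
#'
#' Builds the subject table for a two-group, two-session crossover design:
#' alcohol-experienced (ADE) animals with baseline and relapse drinking
#' intakes, plus water-drinking controls. Each subject is assigned a
#' randomized session order (psilocybin first or saline first). ADE relapse
#' intake is drawn strictly above the animal's baseline intake, matching the
#' relapse-like increase in voluntary consumption that defines the ADE
#' phenotype; intake parameters default to the group means/SDs of the
#' emulated study (baseline 6.35 +/- 1.75 g/kg, relapse 8.10 +/- 1.74 g/kg).
#'
#' @param n_ade Number of ADE subjects (default 15).
#' @param n_con Number of control subjects (default 6).
#' @param seed Integer RNG seed; identical inputs and seed give a
#'   byte-identical table.
#' @param baseline_mean,baseline_sd Mean and SD (g/kg) of ADE baseline
#'   alcohol intake.
#' @param increment_mean,increment_sd Mean and SD (g/kg) of the relapse
#'   increment added to baseline; the increment is floored at 0.1 g/kg so
#'   relapse always exceeds baseline.
#'
#' @return A `data.frame` of class `cohort` with one row per subject:
#'   `subject_id`, `group` (`"ADE"`/`"control"`), `session_order`
#'   (`"psi-first"`/`"sal-first"`), `baseline_intake`, `relapse_intake`
#'   (g/kg; `NA` for controls), and `relapse_norm` (relapse as percent of
#'   baseline, see [normalized_relapse()]).
#' @export
#' @examples
#' coh <- generate_cohort(15, 6, seed = 1)
#' table(coh$group)
generate_cohort <- function(n_ade = 15, n_con = 6, seed = 1,
                            baseline_mean = 6.35, baseline_sd = 1.75,
                            increment_mean = 1.75, increment_sd = 1.0) {
  if (!is_count(n_ade) || !is_count(n_con)) {
    stopf("n_ade and n_con must be non-negative integers")
  }
  if (n_ade + n_con < 1) {
    stopf("invalid cohort: n_ade + n_con must be at least 1")
  }
  n <- n_ade + n_con
  with_seed(seed, {
    baseline <- rep(NA_real_, n)
    relapse <- rep(NA_real_, n)
    if (n_ade > 0) {
      # truncated draws: baseline positive, relapse strictly above baseline
      b <- rnorm(n_ade, baseline_mean, baseline_sd)
      while (any(b <= 0.5)) {
        b[b <= 0.5] <- rnorm(sum(b <= 0.5), baseline_mean, baseline_sd)
      }
      inc <- pmax(rnorm(n_ade, increment_mean, increment_sd), 0.1)
      baseline[seq_len(n_ade)] <- b
      relapse[seq_len(n_ade)] <- b + inc
    }
    order <- sample(c("psi-first", "sal-first"), n, replace = TRUE)
    out <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = rep(c("ADE", "control"), c(n_ade, n_con)),
      session_order = order,
      baseline_intake = baseline,
      relapse_intake = relapse,
      stringsAsFactors = FALSE
    )
    out$relapse_norm <- ifelse(
      is.na(out$baseline_intake), NA_real_,
      100 * out$relapse_intake / out$baseline_intake
    )
    attr(out, "seed") <- seed
    class(out) <- c("cohort", "data.frame")
    out
  })
}
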