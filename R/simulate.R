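#' Specify the injected treatment effect for synthetic sessions
#'
#' Parameters of the ground-truth drug effect realized by
#' [simulate_session()]. Under psilocybin the post-injection generating
#' model (i) scales the cortical/DMN factor loadings down by a per-subject
#' coupling decrement and (ii) adds shared coupling from the dorsal raphe
#' (DRN) and hypothalamus (HypR) to the cortical factor. The decrement is
#' attenuated linearly in the subject's normalized relapse rate above 100%
#' (`blunting_beta`), emulating relapse-dependent blunting of the drug
#' response; the realized decrement is floored at zero.
#'
#' @param dmn_drop Coupling decrement (fraction of the cortical/DMN factor
#'   loading removed post-injection), dimensionless, >= 0.
#' @param hub_gain Loading of DRN and HypR onto the cortical factor added
#'   post-injection, >= 0.
#' @param blunting_beta Attenuation of `dmn_drop` per unit of
#'   (relapse_norm - 100)/100; 0 disables blunting.
#' @param noise_sd SD of idiosyncratic white noise added per region.
#' @param motion_spike_prob Per-frame probability of a motion step.
#' @param motion_spike_amp Amplitude of motion steps in mm.
#'
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(dmn_drop = 0.35, hub_gain = 0.4, blunting_beta = 2,
                        noise_sd = 1, motion_spike_prob = 0.02,
                        motion_spike_amp = 0.1) {
  if (dmn_drop < 0 || hub_gain < 0) stopf("dmn_drop and hub_gain must be >= 0")
  if (blunting_beta < 0) stopf("blunting_beta must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (motion_spike_prob < 0 || motion_spike_prob > 1) {
    stopf("motion_spike_prob must be a probability")
  }
  if (motion_spike_amp < 0) stopf("motion_spike_amp must be >= 0")
  structure(list(
    dmn_drop = dmn_drop, hub_gain = hub_gain, blunting_beta = blunting_beta,
    noise_sd = noise_sd, motion_spike_prob = motion_spike_prob,
    motion_spike_amp = motion_spike_amp
  ), class = "effect_spec")
}

# Per-subject realized coupling decrement. Controls (or subjects without a
# relapse measurement) receive the full decrement.
blunted_drop <- function(spec, relapse_norm) {
  if (is.na(relapse_norm)) return(spec$dmn_drop)
  spec$dmn_drop * max(0, 1 - spec$blunting_beta * (relapse_norm - 100) / 100)
}

#' Simulate a six-parameter rigid-motion trace
#'
#' Low-amplitude smooth drift (well below typical scrubbing thresholds)
#' with occasional step displacements ("spikes") on a random translation
#' axis. Because framewise displacement differentiates the trace, a step
#' produces a single suprathreshold frame.
#'
#' @param n_frames Number of frames.
#' @param spike_prob Per-frame probability of inserting a step.
#' @param spike_amp Step amplitude in mm (must be >= 0).
#' @param seed RNG seed.
#' @param drift_sd SD of per-frame translation drift increments (mm);
#'   rotation increments use `drift_sd / 10` (radians).
#'
#' @return `n_frames x 6` matrix, columns `tx, ty, tz` (mm) and
#'   `rx, ry, rz` (radians).
#' @export
make_motion <- function(n_frames, spike_prob = 0.02, spike_amp = 0.1,
                        seed = 1, drift_sd = 0.002) {
  if (!is_count(n_frames) || n_frames < 2) stopf("n_frames must be >= 2")
  if (spike_prob < 0 || spike_prob > 1) stopf("spike_prob must be in [0, 1]")
  if (spike_amp < 0) stopf("spike_amp must be >= 0 (negative amplitude)")
  with_seed(seed, {
    m <- cbind(
      matrix(rnorm(3 * n_frames, 0, drift_sd), n_frames, 3),
      matrix(rnorm(3 * n_frames, 0, drift_sd / 10), n_frames, 3)
    )
    m <- apply(m, 2, cumsum)
    if (spike_prob > 0 && spike_amp > 0) {
      at <- which(runif(n_frames) < spike_prob)
      at <- at[at > 1]
      for (k in at) {
        ax <- sample.int(3, 1)
        m[k:n_frames, ax] <- m[k:n_frames, ax] + sample(c(-1, 1), 1) * spike_amp
      }
    }
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    m
  })
}

#' Simulate one resting-state session for a subject
#'
#' Generates region time courses from a linear latent-factor model with
#' three band-limited (0.01-0.1 Hz) community factors (cortical/DMN,
#' sensory-motor, subcortical) plus idiosyncratic white noise. Each region
#' loads on its community factor; DMN members drawn from the sensory system
#' (Aud1, Aud2, V1) carry a cross-loading onto the cortical factor so the
#' 12-region DMN is coherent. Under psilocybin, the generating model
#' switches at the injection frame: cortical/DMN factor loadings are scaled
#' by `1 - drop` (the subject's relapse-blunted decrement, see
#' [effect_spec()]) and DRN/HypR gain a `hub_gain` loading on the cortical
#' factor. Under saline one model generates the whole session.
#'
#' @param subject One row of a [generate_cohort()] table (or a list with
#'   `subject_id`, `group`, `relapse_norm`).
#' @param treatment `"psilocybin"` or `"saline"`.
#' @param spec An [effect_spec()].
#' @param seed RNG seed.
#' @param n_frames Frames per session (default 1450 at `tr` 1.5 s).
#' @param tr Repetition time in seconds.
#' @param injection_frame Frame after which the post-injection model
#'   applies; default frame 400 (minute 10) for full-length sessions and
#'   `floor(n_frames / 2)` for shorter ones.
#'
#' @return List of class `synthetic_session`: `roi_ts` (44 x n_frames
#'   matrix, labeled rows), `motion` (n_frames x 6), `tr`, `treatment`,
#'   `subject_id`, and `ground_truth` (the realized decrement and gain).
#' @export
simulate_session <- function(subject, treatment = c("psilocybin", "saline"),
                             spec = effect_spec(), seed = 1,
                             n_frames = 1450, tr = 1.5,
                             injection_frame = NULL) {
  treatment <- match.arg(treatment)
  if (!inherits(spec, "effect_spec")) stopf("spec must be an effect_spec()")
  if (!is_count(n_frames) || n_frames < 8) stopf("n_frames too small")
  if (is.null(injection_frame)) {
    injection_frame <- if (n_frames >= 800) 400L else floor(n_frames / 2)
  }
  labs <- region_labels()
  comm <- region_communities()
  r <- length(labs)

  rn <- if (!is.null(subject$relapse_norm)) subject$relapse_norm else NA_real_
  drop <- if (identical(subject$group, "ADE")) {
    blunted_drop(spec, rn)
  } else {
    spec$dmn_drop
  }

  # base loadings: community factor 0.8; sensory DMN members split between
  # the sensory and cortical factors
  load_pre <- matrix(0, r, 3, dimnames = list(labs, NULL))
  load_pre[cbind(seq_len(r), comm)] <- 0.8
  dmn_sensory <- c("Aud1", "Aud2", "V1")
  load_pre[dmn_sensory, 2] <- 0.55
  load_pre[dmn_sensory, 1] <- 0.55

  load_post <- load_pre
  if (treatment == "psilocybin") {
    affected <- comm == 1L | labs %in% dmn_sensory
    load_post[affected, 1] <- load_post[affected, 1] * (1 - drop)
    load_post[c("DRN", "HypR"), 1] <- load_post[c("DRN", "HypR"), 1] +
      spec$hub_gain
  }

  with_seed(seed, {
    fac <- matrix(rnorm(3 * n_frames), 3, n_frames)
    fac <- bandpass(fac, band = c(0.01, 0.1), tr = tr)
    fac <- fac / apply(fac, 1, sd)
    noise <- matrix(rnorm(r * n_frames, 0, spec$noise_sd), r, n_frames)
    pre_idx <- seq_len(injection_frame)
    post_idx <- setdiff(seq_len(n_frames), pre_idx)
    ts <- matrix(0, r, n_frames, dimnames = list(labs, NULL))
    ts[, pre_idx] <- load_pre %*% fac[, pre_idx, drop = FALSE]
    if (length(post_idx)) {
      ts[, post_idx] <- load_post %*% fac[, post_idx, drop = FALSE]
    }
    ts <- ts + noise
    motion <- make_motion(n_frames, spec$motion_spike_prob,
                          spec$motion_spike_amp, seed = sub_seed(seed, 17))
    structure(list(
      roi_ts = ts, motion = motion, tr = tr, treatment = treatment,
      subject_id = subject$subject_id,
      injection_frame = injection_frame,
      ground_truth = list(drop = if (treatment == "psilocybin") drop else 0,
                          hub_gain = if (treatment == "psilocybin")
                            spec$hub_gain else 0,
                          spec = spec)
    ), class = "synthetic_session")
  })
}

#' Expand a session to a small voxel volume
#'
#' Builds a synthetic 4D grid whose voxels inherit their region's time
#' course plus voxel-level white noise, together with the region-label
#' volume and gray-matter mask. Voxels are allocated to the 44 regions as
#' contiguous runs of the linearized grid, which is sufficient for
#' voxel-wise connectivity and cluster-inference testing at desk scale.
#'
#' @param session A [simulate_session()] result.
#' @param dims 3D grid dimensions (default `c(16, 16, 8)`).
#' @param voxel_size Isotropic voxel size in mm (default 0.3).
#' @param voxel_noise_sd SD of voxel-level noise.
#' @param frames Optional frame indices to realize (default all).
#' @param seed RNG seed.
#'
#' @return List: `vol` (4D array), `labels` (3D integer array indexing
#'   [region_labels()]), `mask` (3D logical), `voxel_size`.
#' @export
simulate_volume <- function(session, dims = c(16, 16, 8), voxel_size = 0.3,
                            voxel_noise_sd = 0.5, frames = NULL, seed = 1) {
  stopifnot(inherits(session, "synthetic_session"), length(dims) == 3)
  nv <- prod(dims)
  r <- nrow(session$roi_ts)
  if (nv < r) stopf("grid too small for %d regions", r)
  if (is.null(frames)) frames <- seq_len(ncol(session$roi_ts))
  lab_lin <- as.integer(cut(seq_len(nv), breaks = r, labels = FALSE))
  labels <- array(lab_lin, dim = dims)
  ts <- session$roi_ts[, frames, drop = FALSE]
  with_seed(seed, {
    vol <- ts[lab_lin, , drop = FALSE] +
      matrix(rnorm(nv * length(frames), 0, voxel_noise_sd), nv)
    dim(vol) <- c(dims, length(frames))
    list(vol = vol, labels = labels, mask = array(TRUE, dims),
         voxel_size = voxel_size)
  })
}
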