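#' Sample a synthetic walking population
#'
#' Draws per-subject kinematic profiles for the parametric walker used
#' throughout the package's experiments. Each profile is a population base
#' value plus `separation` times a subject-specific deviation drawn from a
#' fixed prior, so `separation` directly scales how distinguishable subjects
#' are: at `separation = 0` every profile is identical (identification can
#' only reach chance), at the default `1` subjects differ in stride
#' frequency (s.d. 0.08 Hz around 1 Hz), step amplitude, limb segment
#' lengths, posture, and a per-joint oscillation signature — the kinds of
#' inter-subject differences a skeleton tracker records from real walkers.
#' Sensor noise (`noise_sd`, default 5 mm) is a property of the recording,
#' not of the subject, and is not scaled by `separation`.
#'
#' @param n_subjects Number of subjects `P` (`>= 2`).
#' @param separation Non-negative scale of inter-subject dispersion.
#' @param noise_sd Additive Gaussian sensor noise, meters, per coordinate.
#' @param seed Optional integer seed; the same seed reproduces the
#'   population exactly.
#' @return A tibble with one row per subject: identifier, scalar kinematic
#'   parameters, and list columns `joint_amp`, `joint_phase` (20 each) and
#'   `posture` (20 x 3 offsets).
#' @export
sample_population <- function(n_subjects, separation = 1, noise_sd = 0.005,
                              seed = NULL) {
  if (n_subjects < 2L) abort("A population needs at least 2 subjects.")
  if (!is.null(seed)) set.seed(seed)
  s <- separation
  nb <- 20L
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  prof <- tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    stride_freq = clamp(1.0 + s * rnorm(n_subjects, 0, 0.08), 0.55, 1.45),
    step_amp = clamp(0.35 + s * rnorm(n_subjects, 0, 0.04), 0.15, 0.6),
    thigh = clamp(0.45 + s * rnorm(n_subjects, 0, 0.025), 0.3, 0.6),
    shank = clamp(0.42 + s * rnorm(n_subjects, 0, 0.025), 0.3, 0.6),
    upper_arm = clamp(0.30 + s * rnorm(n_subjects, 0, 0.02), 0.2, 0.4),
    forearm = clamp(0.27 + s * rnorm(n_subjects, 0, 0.02), 0.18, 0.36),
    hip_width = clamp(0.18 + s * rnorm(n_subjects, 0, 0.015), 0.12, 0.26),
    shoulder_width = clamp(0.34 + s * rnorm(n_subjects, 0, 0.02), 0.26, 0.44),
    torso = clamp(0.55 + s * rnorm(n_subjects, 0, 0.03), 0.45, 0.68),
    neck_head = clamp(0.25 + s * rnorm(n_subjects, 0, 0.015), 0.18, 0.32),
    arm_swing = clamp(0.25 + s * rnorm(n_subjects, 0, 0.05), 0.05, 0.5),
    noise_sd = noise_sd
  )
  prof$joint_amp <- lapply(seq_len(n_subjects),
                           function(i) s * abs(rnorm(nb, 0, 0.015)))
  prof$joint_phase <- lapply(seq_len(n_subjects),
                             function(i) s * runif(nb, -pi, pi))
  prof$posture <- lapply(seq_len(n_subjects),
                         function(i) s * matrix(rnorm(nb * 3L, 0, 0.01), nb, 3L))
  prof
}

#' Synthesize one walking sequence
#'
#' Generates a Kinect-like 20-joint skeleton recording from a subject
#' profile: the hip center advances at constant forward speed along z while
#' bobbing vertically at twice the stride frequency; the legs swing
#' anti-phase as rigid thigh+shank pendulums at the stride frequency (so the
#' forward ankle positions oscillate as `+/- sin(2*pi*f*t + phi)` about the
#' hip); the arms counter-swing against the ipsilateral leg; per-joint
#' signature oscillations and constant posture offsets individualize the
#' subject; and i.i.d. Gaussian noise of `noise_sd` meters is added to every
#' coordinate. The resulting inter-ankle distance is periodic with exactly
#' two maxima per gait cycle (one per step), the structure the segmentation
#' stage relies on. Coordinates: x lateral, y vertical, z forward, meters.
#'
#' The walker stays inside a depth sensor's capture volume: the hip advances
#' along a corridor of length `corridor` meters and turns around at each end
#' (real recordings are walks across a room, repeated or returned), so all
#' coordinates remain bounded the way tracked skeletons are. The walking
#' direction only flips the sign of the forward body-frame offsets; the
#' inter-ankle distance is unaffected by it.
#'
#' @param profile One row of [sample_population()] (or an equivalent list).
#' @param duration Recording length in seconds.
#' @param fps Frames per second (default 30).
#' @param seed Optional seed for the starting gait phase, starting position
#'   and the noise.
#' @param phase0 Starting gait phase in radians; by default drawn uniformly.
#' @param noise_sd Override the profile's sensor noise (e.g. 0 for a
#'   noiseless reference signal).
#' @param corridor Length of the walkable span in meters (default 3.5,
#'   roughly a Kinect's usable depth range).
#' @param sequence_id Identifier for the generated recording.
#' @return A [skeleton_sequence] of `duration * fps` frames.
#' @export
synthesize_sequence <- function(profile, duration = 10, fps = 30, seed = NULL,
                                phase0 = NULL, noise_sd = NULL,
                                corridor = 3.5, sequence_id = "walk1") {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- as.list(profile)
    for (nm in c("joint_amp", "joint_phase", "posture")) {
      profile[[nm]] <- profile[[nm]][[1L]]
    }
  }
  if (!is.null(seed)) set.seed(seed)
  phase0 <- phase0 %||% runif(1, 0, 2 * pi)
  noise_sd <- noise_sd %||% profile$noise_sd
  nfr <- as.integer(round(duration * fps))
  t <- (seq_len(nfr) - 1L) / fps
  th <- 2 * pi * profile$stride_freq * t + phase0
  nb <- 20L
  pos <- array(0, c(nfr, nb, 3L))

  leg <- profile$thigh + profile$shank
  swing <- asin(clamp01(profile$step_amp / leg, 0.05, 0.9))
  hipy <- leg + 0.08 + 0.02 * cos(2 * th)
  hipx <- 0.01 * sin(th)
  # distance walked, folded into the corridor as a triangle wave; heading is
  # +1 on the outbound leg and -1 on the return leg
  dist <- 2 * profile$step_amp * profile$stride_freq * t +
    runif(1, 0, 2 * corridor)
  ph <- dist %% (2 * corridor)
  hipz <- ifelse(ph <= corridor, ph, 2 * corridor - ph)
  heading <- ifelse(ph <= corridor, 1, -1)

  # joints are laid out in the body frame (z forward relative to the hip),
  # then mapped to world coordinates as world_z = hipz + heading * body_z
  set_joint <- function(j, x, y, z) {
    pos[, j, 1L] <<- x; pos[, j, 2L] <<- y; pos[, j, 3L] <<- z
  }
  # torso column
  set_joint(1L, hipx, hipy, 0)                                      # HipCenter
  set_joint(2L, hipx, hipy + 0.45 * profile$torso, 0)               # Spine
  set_joint(3L, hipx, hipy + profile$torso, 0)                      # ShoulderCenter
  set_joint(4L, hipx, hipy + profile$torso + profile$neck_head,
            0.005 * sin(th + 1))                                    # Head
  # legs: left swings with +sin, right anti-phase
  leg_side <- function(sgn, alpha, hip_j, knee_j, ankle_j, foot_j) {
    hx <- hipx + sgn * profile$hip_width / 2
    hy <- hipy - 0.05
    set_joint(hip_j, hx, hy, 0)
    kx <- hx
    ky <- hy - profile$thigh * cos(alpha)
    kz <- profile$thigh * sin(alpha)
    set_joint(knee_j, kx, ky, kz)
    ay <- ky - profile$shank * cos(alpha)
    az <- kz + profile$shank * sin(alpha)
    set_joint(ankle_j, kx, ay, az)
    set_joint(foot_j, kx, ay - 0.04, az + 0.12)
  }
  aL <- swing * sin(th)
  aR <- swing * sin(th + pi)
  leg_side(-1, aL, 13L, 14L, 15L, 16L)   # HipLeft..FootLeft
  leg_side(+1, aR, 17L, 18L, 19L, 20L)   # HipRight..FootRight
  # arms: counter-phase to the same-side leg
  arm_side <- function(sgn, gamma, sh_j, el_j, wr_j, ha_j) {
    sx <- hipx + sgn * profile$shoulder_width / 2
    sy <- hipy + profile$torso - 0.03
    set_joint(sh_j, sx, sy, 0)
    ex <- sx
    ey <- sy - profile$upper_arm * cos(gamma)
    ez <- profile$upper_arm * sin(gamma)
    set_joint(el_j, ex, ey, ez)
    wy <- ey - profile$forearm * cos(1.1 * gamma)
    wz <- ez + profile$forearm * sin(1.1 * gamma)
    set_joint(wr_j, ex, wy, wz)
    set_joint(ha_j, ex, wy - 0.08 * cos(gamma), wz + 0.08 * sin(gamma))
  }
  arm_side(-1, profile$arm_swing * sin(th + pi), 5L, 6L, 7L, 8L)
  arm_side(+1, profile$arm_swing * sin(th), 9L, 10L, 11L, 12L)
  # per-joint signature oscillation (forward axis) and posture offsets,
  # both in the body frame; then map body-frame z to world coordinates
  for (j in seq_len(nb)) {
    pos[, j, 3L] <- pos[, j, 3L] +
      profile$joint_amp[j] * sin(th + profile$joint_phase[j])
    pos[, j, ] <- pos[, j, ] +
      matrix(profile$posture[j, ], nfr, 3L, byrow = TRUE)
  }
  pos[, , 3L] <- hipz + heading * pos[, , 3L]
  if (noise_sd > 0) {
    pos <- pos + array(rnorm(length(pos), 0, noise_sd), dim(pos))
  }
  dat <- tibble(
    frame = rep(seq_len(nfr) - 1L, each = nb),
    joint = rep(seq_len(nb), times = nfr),
    x = as.vector(t(pos[, , 1L])),
    y = as.vector(t(pos[, , 2L])),
    z = as.vector(t(pos[, , 3L]))
  )
  skeleton_sequence(dat, subject_id = profile$subject_id,
                    sequence_id = sequence_id, fps = fps)
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full population of walking recordings
#'
#' Samples `n_subjects` profiles and synthesizes `sequences_per_subject`
#' recordings for each, with a fresh random starting phase and noise
#' realization per recording. Deterministic under `seed`.
#'
#' @inheritParams sample_population
#' @param sequences_per_subject Recordings per subject (default 5, matching
#'   the usual per-subject session count in public Kinect gait collections).
#' @param duration,fps Passed to [synthesize_sequence()].
#' @return A list of [skeleton_sequence] objects, named
#'   `"<subject>/<sequence>"`.
#' @examples
#' walks <- simulate_population(3, duration = 5, seed = 1)
#' length(walks)  # 15
#' @export
simulate_population <- function(n_subjects = 10L, sequences_per_subject = 5L,
                                duration = 10, fps = 30, separation = 1,
                                noise_sd = 0.005, seed = NULL) {
  if (duration < 4) abort("`duration` must be at least 4 seconds.")
  if (!is.null(seed)) set.seed(seed)
  prof <- sample_population(n_subjects, separation = separation,
                            noise_sd = noise_sd)
  out <- list()
  for (i in seq_len(n_subjects)) {
    for (q in seq_len(sequences_per_subject)) {
      sid <- sprintf("walk%d", q)
      seqn <- synthesize_sequence(prof[i, ], duration = duration, fps = fps,
                                  sequence_id = sid)
      out[[paste0(prof$subject_id[i], "/", sid)]] <- seqn
    }
  }
  out
}
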