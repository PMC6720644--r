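# Seeded synthetic flight-campaign generator.
#
# Emulates a 14-subject x 3-difficulty x 4-phase simulator campaign: a latent
# workload level per run-phase drives sign-structured features and quantized
# NASA-TLX answers.  Distributional choices (Gaussian latent + noise,
# truncation of dispersions, renormalization of eye-time proportions) are
# artifact constants; only the design (sample sizes, phase/difficulty
# ordering, feature signs, TLX grid) is dictated by the experimental setup
# being emulated.

#' Campaign generator configuration
#'
#' Defaults state the emulated world: 14 subjects, three difficulty levels
#' (LL: display failure only; ML: + aileron jam; HL: + engine shutdown),
#' four ordered phases. Latent workload (NASA-TLX units, 0-100) is
#' `phase base + post-fault difficulty effect + subject effect + noise`,
#' clipped to `[0, 100]`. Phase bases put the fault phase highest, taxiing
#' above normal climbing, and flaring-out in between; difficulty separates
#' runs only from the fault phase onward, so pre-fault phases are
#' statistically indistinguishable across difficulties.
#'
#' @param seed Integer seed; the whole campaign is reproducible from it.
#' @param n_subjects Number of subjects (default 14).
#' @param phase_base Named latent workload base per phase.
#' @param difficulty_effect Named shift added in the fault and flaring-out
#'   phases.
#' @param subject_sd SD of the per-subject random effect.
#' @param noise_sd SD of the per-record latent observation noise.
#' @param tlx_offsets Named per-dimension offsets applied to the latent
#'   workload before quantization (roughly: high MD/PD/EF, low OP/FR).
#' @param tlx_noise_sd SD of per-dimension TLX answer noise.
#' @param feature_noise Multiplier on the per-feature observation noise.
#' @return A `wl_campaign_config` list.
#' @export
campaign_config <- function(seed = 1L,
                            n_subjects = 14L,
                            phase_base = c(taxiing = 40, normal_climbing = 25,
                                           fault = 70, flaring_out = 32),
                            difficulty_effect = c(LL = -12, ML = 0, HL = 12),
                            subject_sd = 5,
                            noise_sd = 3,
                            tlx_offsets = c(MD = 10, PD = 8, TD = 0,
                                            OP = -18, EF = 6, FR = -15),
                            tlx_noise_sd = 5,
                            feature_noise = 1) {
  stopifnot(n_subjects >= 1,
            all(names(phase_base) == phase_levels()),
            all(names(difficulty_effect) == difficulty_levels()),
            all(phase_base >= 0 & phase_base <= 100),
            subject_sd >= 0, noise_sd >= 0, tlx_noise_sd >= 0,
            feature_noise >= 0)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 phase_base = phase_base,
                 difficulty_effect = difficulty_effect,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 tlx_offsets = tlx_offsets, tlx_noise_sd = tlx_noise_sd,
                 feature_noise = feature_noise),
            class = "wl_campaign_config")
}

# Per-feature linear response to latent workload: value = base + slope * w01
# + N(0, sd), with w01 the latent workload rescaled to [-1, 1] around 50.
# Signs follow the documented physiology: x4,x5,x6,x8,x9 rise with workload;
# x7,x10,x11 fall.  Flight dispersions x1..x3 rise (less stable maneuvering
# under load) — an artifact choice, not part of the sign contract.
feature_response <- function() {
  data.frame(
    feature = feature_cols(),
    base  = c(2.5, 30, 15, 85, 0.9, 38, 0.06, 4.5, 65, 18, 10),
    slope = c(1.5, 25, 10, 20, 0.4, 14, -0.035, 0.8, 18, -8, -6),
    sd    = c(0.4, 6, 3, 5, 0.08, 5, 0.008, 0.25, 4, 2.5, 1.5)
  )
}

#' Generate a synthetic flight campaign
#'
#' Produces one run per subject x difficulty (42 runs by default) with four
#' phase records each, plus per-run NASA-TLX answers tied to the fault-phase
#' latent workload (questionnaires are filled in after the flight, when the
#' failure dominates the impression). Fully reproducible per seed.
#'
#' @param config A [campaign_config()].
#' @return List with `features` (feature table, one row per run-phase),
#'   `tlx` (TLX table, one row per run), and `latent` (run_id, phase, latent
#'   workload — for test assertions only).
#' @export
generate_campaign <- function(config = campaign_config()) {
  stopifnot(inherits(config, "wl_campaign_config"))
  set.seed(config$seed)
  phases <- phase_levels()
  diffs <- difficulty_levels()
  resp <- feature_response()

  subj_eff <- stats::rnorm(config$n_subjects, 0, config$subject_sd)

  rows <- list(); tlx_rows <- list(); lat_rows <- list()
  run <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (d in diffs) {
      run <- run + 1L
      run_id <- sprintf("run%02d", run)
      for (ph in phases) {
        post_fault <- ph %in% c("fault", "flaring_out")
        w <- config$phase_base[[ph]] +
          (if (post_fault) config$difficulty_effect[[d]] else 0) +
          subj_eff[s] + stats::rnorm(1, 0, config$noise_sd)
        w <- min(max(w, 0), 100)
        w01 <- (w - 50) / 50
        vals <- resp$base + resp$slope * w01 +
          stats::rnorm(11, 0, resp$sd * config$feature_noise)
        names(vals) <- feature_cols()
        # physical plausibility: truncate dispersions/magnitudes, keep
        # proportions in [0, 100] with total <= 100
        vals[c("x1", "x2", "x3")] <- pmax(vals[c("x1", "x2", "x3")], 0)
        vals[c("x4", "x5", "x6", "x7", "x8")] <-
          pmax(vals[c("x4", "x5", "x6", "x7", "x8")], 1e-3)
        pr <- pmin(pmax(vals[c("x9", "x10", "x11")], 0), 100)
        if (sum(pr) > 100) pr <- 100 * pr / sum(pr)
        vals[c("x9", "x10", "x11")] <- pr
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = run_id, subject_id = sprintf("subj%02d", s),
          difficulty = d, phase = ph, t(vals))
        lat_rows[[length(lat_rows) + 1L]] <- data.frame(
          run_id = run_id, subject_id = sprintf("subj%02d", s),
          difficulty = d, phase = ph, workload = w)
      }
      w_fault <- lat_rows[[length(lat_rows) - 1L]]$workload  # fault phase
      scores <- w_fault + config$tlx_offsets +
        stats::rnorm(6, 0, config$tlx_noise_sd)
      scores <- pmin(pmax(unify_to_scale(scores), 0), 100)
      tlx_rows[[length(tlx_rows) + 1L]] <-
        data.frame(run_id = run_id, t(stats::setNames(scores, tlx_cols())))
    }
  }
  features <- do.call(rbind, rows)
  features$difficulty <- factor(features$difficulty, levels = diffs)
  features$phase <- factor(features$phase, levels = phases)
  list(features = features,
       tlx = do.call(rbind, tlx_rows),
       latent = do.call(rbind, lat_rows))
}

#' Generate labeled data from a fusion model
#'
#' Oracle data for parameter-recovery tests: raw feature rows are drawn so
#' their z-scores are uniform over the standardized range `[-2, 2]`, and the
#' targets are the model's own forward pass (optionally plus noise). Training
#' a fresh weight matrix on a noise-free draw must therefore recover the
#' generator's outputs.
#'
#' @param model A `wl_fusion_model`.
#' @param n Number of samples (0 gives an empty dataset).
#' @param seed Integer seed.
#' @param noise_sd SD of additive target noise (default 0).
#' @return List with `x` (n x k raw feature matrix) and `y` (n x r target
#'   matrix).
#' @export
generate_from_model <- function(model, n, seed = 1L, noise_sd = 0) {
  set.seed(seed)
  k <- length(model$standardizer$center)
  z <- matrix(stats::runif(n * k, -2, 2), nrow = n, ncol = k)
  x <- sweep(sweep(z, 2, model$standardizer$scale, "*"),
             2, model$standardizer$center, "+")
  colnames(x) <- model$standardizer$columns
  if (n == 0) return(list(x = x, y = matrix(numeric(0), 0, model$r)))
  scores <- project_features(model, x)
  Rbar <- applicability_matrix(scores, model$partitions)
  y <- t(model$weights %*% Rbar)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  list(x = x, y = y)
}
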