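# Synthetic stimulus-level data under two competing generative regimes.
#
# The "discrete" regime draws classifier probability vectors from five
# category-specific Dirichlet distributions whose centroids span four
# simplex dimensions, so category structure is genuinely five-way. The
# "core_affect" regime makes the probability vector a noisy function of
# exactly two latent dimensions (valence, arousal): noise-free vectors are
# an affine map of (v, a) onto the simplex (centered rank <= 2 by
# construction), and noise enters as a Gaussian perturbation on the log
# scale re-normalized through softmax.

#' Default category affect means
#'
#' Stimulus-level mean valence per category follows reported norms for this
#' stimulus set (neutral 5.21, amusement 6.57, fear 3.73, disgust 2.82,
#' sexual desire 5.51). No arousal norms are available, so arousal defaults
#' are free parameters chosen to put neutral low and the four emotional
#' categories high.
#'
#' @return Tibble with `category`, `valence`, `arousal`.
#' @export
default_affect_means <- function() {
  tibble(
    category = emotion_categories(),
    valence  = c(6.57, 2.82, 3.73, 5.21, 5.51),
    arousal  = c(5.80, 6.40, 7.20, 2.80, 6.60)
  )
}

#' Synthetic-data configuration
#'
#' Bundles the generative parameters shared by [simulate_stimuli()] and
#' [simulate_subject_ratings()].
#'
#' @param regime `"discrete"` or `"core_affect"`.
#' @param n_per_category Stimuli per category (default 26, i.e. 130 videos
#'   over 5 balanced categories).
#' @param n_subjects Raters for subject-level simulation (default 110).
#' @param affect_means Tibble of per-category mean valence/arousal; defaults
#'   to [default_affect_means()].
#' @param sigma_e Gaussian rating noise sd on the 1-9 scale, used both for
#'   stimulus-level affect jitter and rater-level noise (default 0.8).
#' @param kappa Dirichlet concentration for the discrete regime (default 30;
#'   larger = tighter clusters around the centroids).
#' @param own_mass,other_mass Discrete-regime centroid masses: the video's
#'   own class receives `own_mass` (default 0.6) and each other class
#'   `other_mass` (default 0.1); must sum to 1 over the five classes.
#' @param logit_noise_sd Core-affect-regime Gaussian noise sd on the log
#'   scale (default 0.5).
#' @param endorsement_fidelity Scales how strongly endorsements track the
#'   generating structure, in (0, 1] (default 0.9).
#' @param endorsement_noise_sd Gaussian noise sd on endorsement fractions
#'   before clipping to `[0, 1]` (default 0.05).
#' @param noise_free If `TRUE`, all stochastic components are switched off
#'   (the Dirichlet-concentration-to-infinity / zero-logit-noise limit).
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   bit-identical datasets.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(regime = c("discrete", "core_affect"),
                             n_per_category = 26,
                             n_subjects = 110,
                             affect_means = default_affect_means(),
                             sigma_e = 0.8,
                             kappa = 30,
                             own_mass = 0.6,
                             other_mass = 0.1,
                             logit_noise_sd = 0.5,
                             endorsement_fidelity = 0.9,
                             endorsement_noise_sd = 0.05,
                             noise_free = FALSE,
                             seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(
    n_per_category >= 1, n_subjects >= 1,
    sigma_e >= 0, kappa > 0, logit_noise_sd >= 0,
    endorsement_fidelity > 0, endorsement_fidelity <= 1,
    endorsement_noise_sd >= 0
  )
  if (abs(own_mass + 4 * other_mass - 1) > 1e-8) {
    abort("own_mass + 4 * other_mass must equal 1",
          class = "affectdim_validation_error")
  }
  affect_means <- as_tibble(affect_means)
  stopifnot(setequal(affect_means$category, emotion_categories()),
            all(affect_means$valence >= 1 & affect_means$valence <= 9),
            all(affect_means$arousal >= 1 & affect_means$arousal <= 9))
  affect_means <- affect_means[match(emotion_categories(), affect_means$category), ]
  structure(
    list(regime = regime, n_per_category = n_per_category,
         n_subjects = n_subjects, affect_means = affect_means,
         sigma_e = sigma_e, kappa = kappa, own_mass = own_mass,
         other_mass = other_mass, logit_noise_sd = logit_noise_sd,
         endorsement_fidelity = endorsement_fidelity,
         endorsement_noise_sd = endorsement_noise_sd,
         noise_free = noise_free, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Affine map from centered (v, a) onto the simplex. Row c of the returned
# weight matrix points towards category c's affect mean; the scale alpha is
# the largest keeping every probability >= floor over the whole [1,9]^2
# square, so the map is exactly affine (never clipped) on valid inputs.
core_affect_map <- function(affect_means, floor = 0.02) {
  M <- as.matrix(affect_means[, c("valence", "arousal")])
  m0 <- colMeans(M)
  W <- sweep(M, 2, m0)           # rows sum to zero columnwise
  zmax <- pmax(abs(9 - m0), abs(1 - m0))
  bound <- abs(W) %*% zmax       # max |W_c . z| over the square, per class
  alpha <- (0.2 - floor) / max(bound)
  list(W = W, m0 = m0, alpha = alpha, floor = floor)
}

core_affect_probs <- function(v, a, map) {
  Z <- cbind(v - map$m0[1], a - map$m0[2])
  P <- 0.2 + map$alpha * (Z %*% t(map$W))
  colnames(P) <- prob_cols()
  P
}

rdirichlet_rows <- function(alpha_matrix) {
  G <- matrix(rgamma(length(alpha_matrix), shape = alpha_matrix, rate = 1),
              nrow = nrow(alpha_matrix))
  sweep(G, 1, rowSums(G), "/")
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  sweep(E, 1, rowSums(E), "/")
}

#' Simulate a stimulus table under a generative regime
#'
#' Generates a full stimulus table (affect ratings, label endorsements,
#' classifier probability vectors) under either competing hypothesis about
#' where classifier structure comes from. The realized generating
#' parameters are attached as the `"ground_truth"` attribute for recovery
#' tests.
#'
#' In the `"discrete"` regime each category has its own simplex centroid
#' (own-class mass `own_mass`, others `other_mass`); probability vectors are
#' Dirichlet draws with concentration `kappa` around the centroid. The five
#' centroids span four simplex dimensions, so no two-dimensional projection
#' can represent them exactly.
#'
#' In the `"core_affect"` regime the probability vector is a function of the
#' stimulus's latent (valence, arousal) alone: an affine map onto the
#' simplex, perturbed (unless noise-free) by Gaussian noise on the log scale
#' and re-normalized. Noise-free, the centered probability matrix has rank
#' at most 2 — the regime's dimensionality claim holds by construction.
#'
#' @param regime `"discrete"` or `"core_affect"`; ignored when `config` is
#'   supplied.
#' @param config Optionally a full [synthetic_config()]; otherwise one is
#'   built from `regime`, `seed` and `...`.
#' @param seed Integer seed (overrides the config seed when given).
#' @param ... Passed to [synthetic_config()].
#' @return A validated stimulus tibble with a `"ground_truth"` attribute.
#' @export
#' @examples
#' x <- simulate_stimuli("discrete", seed = 7, n_per_category = 6)
#' dplyr::count(x, category)
simulate_stimuli <- function(regime = c("discrete", "core_affect"),
                             config = NULL, seed = NULL, ...) {
  if (is.null(config)) {
    regime <- match.arg(regime)
    config <- synthetic_config(regime = regime, seed = seed %||% 1L, ...)
  }
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)

  cats <- emotion_categories()
  n <- config$n_per_category * length(cats)
  category <- rep(cats, each = config$n_per_category)
  mu <- config$affect_means[match(category, config$affect_means$category), ]

  out <- run_seeded(derive_seed(config$seed, "simulate"), {
    aff_sd <- if (config$noise_free) 0 else config$sigma_e
    valence <- clip(mu$valence + rnorm(n, 0, aff_sd), 1, 9)
    arousal <- clip(mu$arousal + rnorm(n, 0, aff_sd), 1, 9)

    if (config$regime == "discrete") {
      centroids <- matrix(config$other_mass, 5, 5,
                          dimnames = list(cats, prob_cols()))
      diag(centroids) <- config$own_mass
      C <- centroids[category, , drop = FALSE]
      P <- if (config$noise_free) C else rdirichlet_rows(config$kappa * C)
      colnames(P) <- prob_cols()
      # endorsement profile mirrors the centroid shape, scaled by fidelity
      prof <- config$endorsement_fidelity *
        (centroids[category, , drop = FALSE] + 0.15)
      truth <- list(regime = "discrete", centroids = centroids,
                    config = config)
    } else {
      map <- core_affect_map(config$affect_means)
      P0 <- core_affect_probs(valence, arousal, map)
      P <- if (config$noise_free || config$logit_noise_sd == 0) {
        P0
      } else {
        softmax_rows(log(P0) +
                       matrix(rnorm(n * 5, 0, config$logit_noise_sd), n, 5))
      }
      colnames(P) <- prob_cols()
      # monotone link: endorsement of label c rises with the projection of
      # centered (v, a) onto category c's direction
      U <- map$W / sqrt(rowSums(map$W^2))
      Z <- cbind(valence - map$m0[1], arousal - map$m0[2])
      prof <- config$endorsement_fidelity *
        stats::plogis(Z %*% t(U) - 0.5)
      truth <- list(regime = "core_affect", map = map, config = config)
    }
    e_sd <- if (config$noise_free) 0 else config$endorsement_noise_sd
    E <- clip(prof + matrix(rnorm(n * 5, 0, e_sd), n, 5), 0, 1)
    colnames(E) <- endorse_cols()
    list(valence = valence, arousal = arousal, P = P, E = E, truth = truth)
  })

  stimuli <- bind_cols(
    tibble(video_id = sprintf("vid_%03d", seq_len(n)),
           category = category,
           valence = out$valence, arousal = out$arousal),
    as_tibble(out$E), as_tibble(out$P)
  )
  stimuli <- validate_stimulus_table(stimuli)
  attr(stimuli, "ground_truth") <- out$truth
  stimuli
}

#' Simulate subject-level affect ratings around a stimulus table
#'
#' Each subject's rating of a stimulus is the stimulus's mean valence (or
#' arousal) plus independent Gaussian noise with sd `sigma_e`, clipped to
#' the `[1, 9]` scale. Feeding the result to [aggregate_ratings()] recovers
#' the stimulus means up to sampling noise; feeding it to
#' [split_half_reliability()] measures how reliable that aggregation is.
#'
#' @param stimuli A valid stimulus table.
#' @param n_subjects Number of raters (default 110).
#' @param sigma_e Rater noise sd (default 0.8).
#' @param seed Integer seed.
#' @return Long tibble with `subject_id`, `video_id`, `valence`, `arousal`.
#' @export
simulate_subject_ratings <- function(stimuli, n_subjects = 110,
                                     sigma_e = 0.8, seed = 1L) {
  stimuli <- validate_stimulus_table(stimuli)
  stopifnot(n_subjects >= 1, sigma_e >= 0)
  n <- nrow(stimuli)
  run_seeded(derive_seed(seed, "subject_ratings"), {
    tibble(
      subject_id = rep(sprintf("sub_%03d", seq_len(n_subjects)), each = n),
      video_id = rep(stimuli$video_id, times = n_subjects),
      valence = clip(rep(stimuli$valence, times = n_subjects) +
                       rnorm(n * n_subjects, 0, sigma_e), 1, 9),
      arousal = clip(rep(stimuli$arousal, times = n_subjects) +
                       rnorm(n * n_subjects, 0, sigma_e), 1, 9)
    )
  })
}
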