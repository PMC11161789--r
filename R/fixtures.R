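# Synthetic fixtures: parcellations, connectomes, annotation maps,
# ground-truth studies and cohorts with known injected structure, so the
# full pipeline is testable without any external data. Every generator is
# deterministic under its seed.

#' Synthetic fixture specification
#'
#' Collects the knobs of the synthetic-data generators: parcellation size,
#' SC distance-decay rate and noise, map smoothness, the ground-truth
#' parameter vector, observable dimensions, and cohort design (size, age
#' range, injected age slope and group-effect profile).
#'
#' @param n_regions Even number of regions (two hemispheres), default 68.
#' @param lambda Exponential distance-decay rate of SC (1/radian).
#' @param sc_noise_sd Relative SC noise standard deviation.
#' @param smoothness Spatial correlation length of map noise (radian).
#' @param true_vector Ground-truth coefficient vector (two-map scheme);
#'   `NULL` for the package default.
#' @param n_frames,tr_seconds,window_frames BOLD dimensions of generated
#'   fit targets.
#' @param target_runs Independent runs pooled into each phase target
#'   (FCD entries pooled, FCs averaged in Fisher z). The default 3 mirrors
#'   group-level targets; parameter-recovery harnesses use 1 so that,
#'   under matched evaluation seeds, the true vector reproduces the
#'   target exactly and is the exact optimum of the training cost.
#' @param dt_s,burn_in_s Integration step and burn-in of generated studies.
#' @param cohort_size,age_range Number of subjects and age span (years).
#' @param age_slope Injected cortical E/I change per year of age.
#' @param group_effect_sd Scale of the injected performance-group effect.
#' @param subject_noise_sd Per-subject E/I map noise.
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_regions = 68L, lambda = 5, sc_noise_sd = 0.1,
                         smoothness = 0.5, true_vector = NULL,
                         n_frames = 330L, tr_seconds = 0.72,
                         window_frames = 83L, target_runs = 3L,
                         dt_s = 0.002, burn_in_s = 10,
                         cohort_size = 885L, age_range = c(8, 23),
                         age_slope = -0.01, group_effect_sd = 0.02,
                         subject_noise_sd = 0.05, seed = 1L) {
  if (n_regions %% 2 != 0 || n_regions < 4)
    pfic_error("pfic_invalid_config", "n_regions must be even and >= 4")
  if (sc_noise_sd < 0 || subject_noise_sd < 0)
    pfic_error("pfic_invalid_config", "noise sds must be nonnegative")
  structure(list(n_regions = as.integer(n_regions), lambda = lambda,
                 sc_noise_sd = sc_noise_sd, smoothness = smoothness,
                 true_vector = true_vector, n_frames = as.integer(n_frames),
                 tr_seconds = tr_seconds,
                 window_frames = as.integer(window_frames),
                 target_runs = as.integer(target_runs), dt_s = dt_s,
                 burn_in_s = burn_in_s, cohort_size = as.integer(cohort_size),
                 age_range = age_range, age_slope = age_slope,
                 group_effect_sd = group_effect_sd,
                 subject_noise_sd = subject_noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Synthetic two-hemisphere parcellation
#'
#' Places `n_regions/2` quasi-uniform parcel centroids per hemisphere
#' (Fibonacci lattice on each half of the unit sphere, randomly rotated
#' about the left-right axis by the seed), mirror-symmetric across
#' hemispheres. Also derives a synthetic sensorimotor-association rank
#' (monotone along an inferior-posterior to superior-anterior axis) and
#' seven mirror-symmetric network labels (k-means on centroid coordinates).
#'
#' @param n_regions Even region count.
#' @param seed Integer seed.
#' @return List with `centroids` (n x 3, unit norm), `hemisphere`,
#'   `distances` (great-circle, radians), `sa_rank`, `network_label`.
#' @export
make_parcellation <- function(n_regions = 68L, seed = 1L) {
  if (n_regions < 4 || n_regions %% 2 != 0)
    pfic_error("pfic_invalid_config", "n_regions must be even and >= 4")
  m <- n_regions / 2
  set.seed(seed)
  phi0 <- runif(1, 0, 2 * pi)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(m)
  u <- (k - 0.5) / m            # distance from the midline plane
  phi <- phi0 + k * golden
  r <- sqrt(1 - u^2)
  left <- cbind(x = -u, y = r * cos(phi), z = r * sin(phi))
  right <- left; right[, 1] <- -right[, 1]
  centroids <- rbind(left, right)
  hemisphere <- rep(c("L", "R"), each = m)
  dots <- pmin(pmax(tcrossprod(centroids), -1), 1)
  distances <- acos(dots)
  diag(distances) <- 0
  # S-A rank: sensorimotor pole posterior-inferior, association pole
  # anterior-superior; mirror-symmetric by construction
  sa_axis <- centroids[, 2] + centroids[, 3]
  sa_rank <- rank(sa_axis, ties.method = "first")
  km <- kmeans(left[, 2:3], centers = min(7L, m - 1L), nstart = 5)
  network_label <- rep(km$cluster, 2)
  list(centroids = centroids, hemisphere = hemisphere,
       distances = distances, sa_rank = as.integer(sa_rank),
       network_label = as.integer(network_label))
}

#' Synthetic structural connectome (exponential distance rule)
#'
#' `SC_ij = exp(-lambda * d_ij) * (1 + eps_ij)` with symmetric truncated
#' Gaussian noise, zero diagonal, and the matrix scaled so its maximum
#' entry is 1.
#'
#' @param parcellation Output of [make_parcellation()].
#' @param lambda Distance-decay rate (1/radian), `> 0`.
#' @param noise_sd Relative noise sd; truncated at 3 sd and at -0.95.
#' @param seed Integer seed.
#' @return A [connectome()] carrying the parcellation metadata.
#' @export
make_synthetic_sc <- function(parcellation, lambda = 5, noise_sd = 0.1,
                              seed = 1L) {
  if (lambda <= 0)
    pfic_error("pfic_invalid_config", "lambda must be positive")
  d <- parcellation$distances
  n <- nrow(d)
  set.seed(seed + 1L)
  eps <- matrix(rnorm(n * n, sd = noise_sd), n, n)
  eps <- (eps + t(eps)) / sqrt(2)
  eps <- pmin(pmax(eps, max(-3 * noise_sd, -0.95)), 3 * noise_sd)
  sc <- exp(-lambda * d) * (1 + eps)
  diag(sc) <- 0
  sc <- sc / max(sc)
  connectome(sc, hemisphere = parcellation$hemisphere,
             centroids = parcellation$centroids,
             network_label = parcellation$network_label,
             sa_rank = parcellation$sa_rank)
}

# smooth spatial noise: distance-kernel-weighted average of white noise
smooth_field <- function(distances, h, n_draws) {
  K <- exp(-distances^2 / (2 * h^2))
  K <- K / rowSums(K)
  drop(K %*% rnorm(n_draws))
}

#' Synthetic regional annotation maps
#'
#' Emulates the two anchor maps of the pFIC parameterization: the myelin
#' proxy follows the anterior-posterior axis and the functional gradient
#' the inferior-superior axis, each plus smooth spatial noise; both are
#' z-scored. The axes are orthogonal, so the maps are near-orthogonal by
#' construction.
#'
#' @param parcellation Output of [make_parcellation()].
#' @param smoothness Spatial correlation length (radian) of the noise.
#' @param seed Integer seed.
#' @return A [regional_maps()]; attribute `"map_correlation"` reports the
#'   realized myelin-gradient correlation.
#' @export
make_synthetic_maps <- function(parcellation, smoothness = 0.5, seed = 1L) {
  set.seed(seed + 2L)
  n <- nrow(parcellation$centroids)
  noise_scale <- 0.3
  my <- parcellation$centroids[, 2] +
    noise_scale * smooth_field(parcellation$distances, smoothness, n)
  gr <- parcellation$centroids[, 3] +
    noise_scale * smooth_field(parcellation$distances, smoothness, n)
  zs <- function(v) (v - mean(v)) / sd(v)
  maps <- regional_maps(myelin = zs(my), gradient = zs(gr))
  attr(maps, "map_correlation") <- cor(zs(my), zs(gr))
  maps
}

#' Default ground-truth coefficient vector for synthetic studies
#'
#' A two-map scheme vector inside the default search bounds, with graded
#' regional structure on all three synaptic quantities.
#'
#' @return Named numeric vector of length 10.
#' @export
default_true_vector <- function() {
  c(w_ee_b0 = 2.8, w_ee_b_myelin = -0.4, w_ee_b_gradient = 0.5,
    w_ei_b0 = 3.0, w_ei_b_myelin = -0.5, w_ei_b_gradient = 0.6,
    sigma_b0 = 0.008, sigma_b_myelin = 5e-4, sigma_b_gradient = -5e-4,
    g = 2.4)
}

#' Generate a ground-truth study for parameter recovery
#'
#' Expands the true coefficient vector on a synthetic connectome and maps,
#' calibrates feedback inhibition, runs three independent-seed stochastic
#' simulations, converts them to BOLD, and packages FC/FCD targets for
#' train/validation/test along with the true regional E/I map.
#'
#' @param fs A [fixture_spec()].
#' @param scheme A [parameterization_scheme()]; default two-map.
#' @param constants A [neural_constants()].
#' @return List with `connectome`, `maps`, `scheme`, `targets` (named list
#'   `train`/`validation`/`test` of [fit_target()]), `true_params`,
#'   `true_vector`, `true_ei` (an `ei_map`), and the per-phase seeds.
#' @export
make_ground_truth_study <- function(fs = fixture_spec(),
                                    scheme = parameterization_scheme(),
                                    constants = neural_constants()) {
  parc <- make_parcellation(fs$n_regions, fs$seed)
  conn <- make_synthetic_sc(parc, fs$lambda, fs$sc_noise_sd, fs$seed)
  maps <- make_synthetic_maps(parc, fs$smoothness, fs$seed)
  vec <- fs$true_vector %||% default_true_vector()
  pars <- expand_parameters(vec, maps, scheme)
  cal <- calibrate_fic(pars, conn, constants, dt_s = fs$dt_s)
  seeds <- fs$seed * 1000L + c(train = 1L, validation = 2L, test = 3L)
  # ~30 s of BOLD discarded as hemodynamic transient: the shared drift of
  # the Balloon-Windkessel states toward steady state otherwise inflates
  # FC toward 1
  drop <- as.integer(ceiling(30 / fs$tr_seconds))
  duration <- fs$burn_in_s + (fs$n_frames + drop) * fs$tr_seconds
  runs_per_phase <- fs$target_runs %||% 3L
  first_sim <- NULL
  targets <- lapply(seeds, function(s) {
    # group-style targets: several independent runs per phase; FCD entries
    # pooled into one distribution, FCs averaged in Fisher z space
    bolds <- lapply(seq_len(runs_per_phase) - 1L, function(k) {
      sim <- simulate_fic(cal, conn, constants, duration_s = duration,
                          dt_s = fs$dt_s, burn_in_s = fs$burn_in_s,
                          seed = s + 100L * k, tr_s = fs$tr_seconds)
      if (is.null(first_sim)) first_sim <<- sim
      bold_timeseries(
        sim$bold$data[-seq_len(drop), , drop = FALSE][
          seq_len(fs$n_frames), , drop = FALSE], fs$tr_seconds)
    })
    zfc <- lapply(bolds, function(b) atanh(pmin(pmax(static_fc(b),
                                                     -(1 - 1e-7)),
                                                1 - 1e-7)))
    fc <- tanh(Reduce(`+`, zfc) / length(zfc))
    diag(fc) <- 1
    entries <- unlist(lapply(bolds, function(b)
      fcd_entries(fcd_matrix(b, fs$window_frames))))
    fit_target(fc = fc, fcd_entries = entries,
               window_frames = fs$window_frames, n_frames = fs$n_frames,
               tr_seconds = fs$tr_seconds)
  })
  list(connectome = conn, maps = maps, scheme = scheme,
       targets = targets, true_params = cal, true_vector = vec,
       true_ei = ei_ratio(first_sim), seeds = seeds,
       parcellation = parc)
}

#' Generate a synthetic subject cohort with injected structure
#'
#' Emulates a developmental cohort: ages uniform over the range,
#' performance driven by a latent trait independent of age, and a latent
#' per-subject regional E/I map
#' `baseline + age_slope * age + effect_profile * perf_label + noise`,
#' where the effect profile is graded along the synthetic
#' sensorimotor-association rank. Group-level E/I estimates are means of
#' member maps.
#'
#' @param fs A [fixture_spec()].
#' @return List with `subjects` (data.frame: `subject_id`, `age`, `motion`,
#'   `performance`, `perf_label`), `subject_ei` (subjects x regions),
#'   `baseline_ei`, `effect_profile`, `sa_rank`, `parcellation`.
#' @export
make_synthetic_cohort <- function(fs = fixture_spec()) {
  parc <- make_parcellation(fs$n_regions, fs$seed)
  n <- fs$cohort_size
  set.seed(fs$seed + 3L)
  age <- sort(runif(n, fs$age_range[1], fs$age_range[2]))
  latent <- rnorm(n)
  performance <- latent + rnorm(n, sd = 0.5)
  motion <- pmax(0.02, 0.25 - 0.008 * age + rnorm(n, sd = 0.03))
  perf_label <- as.integer(performance > median(performance))
  sa01 <- (parc$sa_rank - 1) / (fs$n_regions - 1)
  baseline <- 3 + 0.3 * smooth_field(parc$distances, fs$smoothness,
                                     fs$n_regions)
  effect <- -fs$group_effect_sd *
    (sa01 + 0.05 * rnorm(fs$n_regions))
  ei <- matrix(baseline, n, fs$n_regions, byrow = TRUE) +
    fs$age_slope * age +
    outer(perf_label, effect) +
    matrix(rnorm(n * fs$n_regions, sd = fs$subject_noise_sd),
           n, fs$n_regions)
  subjects <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)), age = age,
    motion = motion, performance = performance, perf_label = perf_label,
    stringsAsFactors = FALSE)
  list(subjects = subjects, subject_ei = ei, baseline_ei = baseline,
       effect_profile = effect, sa_rank = parc$sa_rank,
       parcellation = parc)
}
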