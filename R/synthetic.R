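#' Scenario configuration for the synthetic study design
#'
#' Describes the simulated study: a batch of fingerprints with a fixed
#' common-peak profile and lognormal batch-to-batch variation, two planted
#' hepatotoxic peaks whose areas drive the serum enzyme endpoints, and
#' per-animal lognormal noise around each group mean. The defaults emulate
#' the reference regime: 21 batches x 10 common peaks with all pairwise
#' cosine similarities above 0.9, toxic peaks 9 and 10 (the two diterpenoid
#' lactones), control baselines 32 U/L (ALT) and 83 U/L (AST), 10 animals
#' per group, and effect sizes calibrated so group-mean ALT spans roughly
#' 3775-17308 U/L and AST 1434-11938 U/L.
#'
#' @param n_samples Number of fingerprint batches (21).
#' @param n_peaks Number of common peaks (10).
#' @param toxic_peaks Indices of the planted toxic peaks (`c(9, 10)`).
#' @param effect_alt,effect_ast Toxic-peak effect sizes in U/L per unit
#'   peak area (named by toxic peak index); non-toxic peaks contribute 0.
#' @param baseline_alt,baseline_ast Vehicle-control enzyme levels (U/L).
#' @param noise_cv Coefficient of variation of per-animal lognormal noise
#'   around the group mean (0.3).
#' @param animals_per_group Animals per treatment group (10).
#' @param base_areas Common-peak base profile (arbitrary detector units,
#'   decreasing; the two toxic peaks are minor constituents).
#' @param scale_sigma Log-sd of the shared per-sample scale factor (0.15):
#'   batch concentration and injection variability move every peak of a
#'   sample together, so the bulk constituents covary across batches while
#'   cosine similarity is untouched (it is scale-invariant).
#' @param area_lognormal_sigma Log-sd of the idiosyncratic batch-to-batch
#'   variation of non-toxic peaks on top of the shared factor (0.10; keeps
#'   all pairwise similarities > 0.9).
#' @param toxic_factor_sigma Log-sd of the lognormal factor shared by the
#'   toxic peaks (0.55): the two diterpenoid lactones co-vary across
#'   batches, so their joint content fluctuates several-fold while the
#'   bulk composition stays stable — the feature that makes the toxicity
#'   signal recoverable against near-identical fingerprints.
#' @param toxic_area_sigma Additional idiosyncratic log-sd of each toxic
#'   peak on top of the shared factor (0.25).
#' @param rts Consensus retention times (minutes) of the common peaks.
#' @param seed Integer seed; a fixed seed makes every generator
#'   bit-reproducible.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 21L, n_peaks = 10L,
                            toxic_peaks = c(9L, 10L),
                            effect_alt = c(`9` = 34, `10` = 40),
                            effect_ast = c(`9` = 20, `10` = 23),
                            baseline_alt = 32, baseline_ast = 83,
                            noise_cv = 0.3, animals_per_group = 10L,
                            base_areas = c(1250, 1000, 860, 740, 620, 510,
                                           420, 340, 120, 95)[seq_len(n_peaks)],
                            scale_sigma = 0.15,
                            area_lognormal_sigma = 0.10,
                            toxic_factor_sigma = 0.55,
                            toxic_area_sigma = 0.25,
                            rts = seq(4, 44, length.out = n_peaks),
                            seed = 1L) {
  stopifnot(n_samples >= 2, n_peaks >= 1,
            all(toxic_peaks >= 1), all(toxic_peaks <= n_peaks),
            noise_cv > 0, animals_per_group >= 2,
            length(base_areas) == n_peaks, all(base_areas > 0),
            scale_sigma >= 0, area_lognormal_sigma >= 0,
            toxic_factor_sigma >= 0, toxic_area_sigma >= 0,
            length(effect_alt) == length(toxic_peaks),
            length(effect_ast) == length(toxic_peaks))
  structure(list(n_samples = as.integer(n_samples),
                 n_peaks = as.integer(n_peaks),
                 toxic_peaks = as.integer(toxic_peaks),
                 effect_alt = effect_alt, effect_ast = effect_ast,
                 baseline_alt = baseline_alt, baseline_ast = baseline_ast,
                 noise_cv = noise_cv,
                 animals_per_group = as.integer(animals_per_group),
                 base_areas = base_areas, scale_sigma = scale_sigma,
                 area_lognormal_sigma = area_lognormal_sigma,
                 toxic_factor_sigma = toxic_factor_sigma,
                 toxic_area_sigma = toxic_area_sigma,
                 rts = rts, seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario:", x$n_samples, "samples x", x$n_peaks,
      "common peaks; toxic peaks:",
      paste(x$toxic_peaks, collapse = ", "), "\n")
  cat("  area log-sd", x$area_lognormal_sigma, "(toxic",
      x$toxic_area_sigma, "), animal noise CV", x$noise_cv,
      ", n/group", x$animals_per_group, ", seed", x$seed, "\n")
  invisible(x)
}

#' Generate a batch of synthetic fingerprints
#'
#' Peak area of sample i, peak j is
#' `base_areas[j] * s_i * d_i^(j is toxic) * exp(sigma_j * z_ij)`, where
#' `s_i` is a shared lognormal per-sample scale factor (log-sd
#' `scale_sigma`; batch concentration/injection variability that moves all
#' peaks of a sample together), `d_i` is a lognormal factor shared by the
#' toxic peaks only (log-sd `toxic_factor_sigma`; co-variation of the
#' diterpenoid contents across batches), and `z_ij` are independent
#' standard normals with `sigma_j = area_lognormal_sigma` for bulk peaks
#' and `toxic_area_sigma` for the planted toxic peaks. The default sigmas
#' keep all pairwise cosine similarities above 0.9 while the toxic-peak
#' contents vary several-fold.
#'
#' @param config A [scenario_config()].
#' @return A [common_peak_table()] with samples `S01...` and peaks
#'   `1..n_peaks`.
#' @export
generate_fingerprints <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  rs <- .preserve_rng(config$seed)
  on.exit(.restore_rng(rs), add = TRUE)
  n <- config$n_samples; p <- config$n_peaks
  sig <- rep(config$area_lognormal_sigma, p)
  sig[config$toxic_peaks] <- config$toxic_area_sigma
  s <- exp(stats::rnorm(n, 0, config$scale_sigma))
  d <- exp(stats::rnorm(n, 0, config$toxic_factor_sigma))
  Z <- matrix(stats::rnorm(n * p), n, p)
  areas <- s * sweep(exp(sweep(Z, 2L, sig, "*")), 2L, config$base_areas, "*")
  areas[, config$toxic_peaks] <- areas[, config$toxic_peaks, drop = FALSE] * d
  rownames(areas) <- sprintf("S%02d", seq_len(n))
  colnames(areas) <- as.character(seq_len(p))
  common_peak_table(areas, rts = config$rts)
}

#' Generate raw per-sample peak lists
#'
#' Like [generate_fingerprints()] but emitted as chromatogram peak lists:
#' each common peak gets a small retention-time jitter per sample, and each
#' sample additionally carries a few minor sample-specific peaks (at random
#' retention times, absent from other samples) so that common-peak matching
#' is non-trivial. The minor peaks total well under 20% of the area, so the
#' common peaks account for more than 80% of the overall peak area.
#'
#' @param config A [scenario_config()].
#' @param rt_jitter_sd SD of the per-sample retention-time jitter (min).
#' @param n_minor Minor (non-common) peaks per sample.
#' @return Long data frame with columns `sample_id`, `rt`, `area`, plus a
#'   `truth` attribute holding the underlying `common_peak_table`.
#' @export
generate_chromatograms <- function(config = scenario_config(),
                                   rt_jitter_sd = 0.05, n_minor = 3L) {
  t <- generate_fingerprints(config)
  rs <- .preserve_rng(config$seed + 1000L)
  on.exit(.restore_rng(rs), add = TRUE)
  n <- config$n_samples; p <- config$n_peaks
  rows <- lapply(seq_len(n), function(i) {
    rt <- config$rts + stats::rnorm(p, 0, rt_jitter_sd)
    minor_rt <- stats::runif(n_minor, min(config$rts) + 2, max(config$rts) - 2)
    # keep minor peaks away from common-peak windows
    for (k in seq_along(minor_rt)) {
      while (min(abs(minor_rt[k] - config$rts)) < 1.5) {
        minor_rt[k] <- stats::runif(1, min(config$rts) + 2, max(config$rts) - 2)
      }
    }
    minor_area <- stats::runif(n_minor, 0.005, 0.03) * sum(t$areas[i, ])
    d <- data.frame(sample_id = rownames(t$areas)[i],
                    rt = c(rt, minor_rt),
                    area = c(t$areas[i, ], minor_area))
    d[order(d$rt), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- t
  out
}

#' Generate per-animal toxicity endpoints from a fingerprint table
#'
#' The group-mean response of sample i is
#' `baseline + sum_j effect_j * area_ij` over the toxic peaks (non-toxic
#' peaks contribute nothing); each of the `animals_per_group` animals draws
#' a lognormal value around that mean with coefficient of variation
#' `noise_cv`. ALT and AST get independent animal noise.
#'
#' @param t A [common_peak_table()] whose peaks include the configured
#'   toxic peaks.
#' @param config A [scenario_config()].
#' @return Object of class `toxicity_table`: `animals` (long data frame
#'   `sample_id`, `animal`, `ALT`, `AST`), `group_means` (observed
#'   per-sample means), `true_means` (noise-free means).
#' @export
generate_toxicity <- function(t, config = scenario_config()) {
  stopifnot(inherits(t, "common_peak_table"),
            inherits(config, "scenario_config"),
            max(config$toxic_peaks) <= ncol(t$areas))
  rs <- .preserve_rng(config$seed + 2000L)
  on.exit(.restore_rng(rs), add = TRUE)
  A <- t$areas[, config$toxic_peaks, drop = FALSE]
  mu_alt <- config$baseline_alt + as.vector(A %*% config$effect_alt)
  mu_ast <- config$baseline_ast + as.vector(A %*% config$effect_ast)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  k <- config$animals_per_group
  draw <- function(mu) {
    # meanlog chosen so the arithmetic mean equals mu
    stats::rlnorm(k, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- lapply(seq_len(nrow(A)), function(i) {
    data.frame(sample_id = rownames(A)[i], animal = seq_len(k),
               ALT = draw(mu_alt[i]), AST = draw(mu_ast[i]))
  })
  animals <- do.call(rbind, rows)
  gm <- cbind(ALT = tapply(animals$ALT, animals$sample_id, mean),
              AST = tapply(animals$AST, animals$sample_id, mean))
  gm <- gm[rownames(A), , drop = FALSE]
  structure(list(animals = animals, group_means = gm,
                 true_means = cbind(ALT = mu_alt, AST = mu_ast)),
            class = "toxicity_table")
}

#' @export
print.toxicity_table <- function(x, ...) {
  rng_alt <- range(x$group_means[, "ALT"])
  rng_ast <- range(x$group_means[, "AST"])
  cat("Per-animal toxicity:", nrow(x$group_means), "groups x",
      nrow(x$animals) / nrow(x$group_means), "animals\n")
  cat("  group-mean ALT ", round(rng_alt[1]), "-", round(rng_alt[2]),
      " U/L, AST ", round(rng_ast[1]), "-", round(rng_ast[2]), " U/L\n",
      sep = "")
  invisible(x)
}

#' Generate two lognormal toxicity groups with a known ratio
#'
#' Fixture generator for equivalence testing: two per-animal groups whose
#' population geometric-mean ratio (candidate/original) is exactly
#' `geo_mean_ratio`.
#'
#' @param geo_mean_ratio Target population geometric-mean ratio (> 0).
#' @param cv Lognormal coefficient of variation (> 0).
#' @param n Animals per group (>= 2).
#' @param seed Integer seed.
#' @param original_mean Geometric mean of the original group (U/L).
#' @return List with numeric vectors `candidate` and `original`.
#' @export
generate_equivalence_groups <- function(geo_mean_ratio, cv, n, seed = 1L,
                                        original_mean = 8000) {
  stopifnot(geo_mean_ratio > 0, cv > 0, n >= 2)
  rs <- .preserve_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  sdlog <- sqrt(log(1 + cv^2))
  list(candidate = stats::rlnorm(n, log(original_mean) + log(geo_mean_ratio),
                                 sdlog),
       original = stats::rlnorm(n, log(original_mean), sdlog))
}
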