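#' Simulation configuration
#'
#' Shared settings for the synthetic-data generators. Every generator is
#' deterministic under a fixed seed. Replicate noise for expression-style
#' quantities is multiplicative (`value * (1 + eps)`, `eps` Gaussian with
#' s.d. `noise_sd`), so the replicate s.d. scales with the level as qPCR
#' error approximately does; decay courses use additive Gaussian noise
#' scaled to the starting level.
#'
#' @param seed Integer seed.
#' @param n_replicates Biological replicates per condition (>= 2;
#'   default 3).
#' @param noise_sd Relative s.d. of replicate noise (>= 0; 0 gives exact
#'   model means).
#' @param timepoints Hours after transcriptional inhibition for decay
#'   courses (non-negative).
#' @param tiling_positions Nucleotide offsets of tiling primers within
#'   the intron, or `NULL` to place 12 positions evenly across it.
#' @param depth Expected reads per base per expressed gene copy in the
#'   coverage simulator.
#' @param n_cells Cells per sample in the smFISH simulator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_replicates = 3L, noise_sd = 0.1,
                       timepoints = c(0, 2, 4, 6), tiling_positions = NULL,
                       depth = 1, n_cells = 100L) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (any(timepoints < 0)) {
    stop("negative timepoints are not allowed", call. = FALSE)
  }
  stopifnot(depth >= 0, n_cells >= 1L)
  structure(
    list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         noise_sd = noise_sd, timepoints = timepoints,
         tiling_positions = tiling_positions, depth = depth,
         n_cells = as.integer(n_cells)),
    class = "sim_config"
  )
}

mult_noise <- function(mean_val, n_rep, noise_sd) {
  matrix(mean_val, length(mean_val), n_rep) *
    (1 + matrix(stats::rnorm(length(mean_val) * n_rep, sd = noise_sd),
                length(mean_val), n_rep))
}

new_tiling_profile <- function(position, reps, fraction, truth) {
  structure(
    data.frame(position = position,
               mean = rowMeans(reps),
               sd = apply(reps, 1L, stats::sd)),
    replicates = reps, fraction = fraction, truth = truth,
    class = c("tiling_profile", "data.frame")
  )
}

#' Simulate paired total and chromatin-bound tiling fold-change profiles
#'
#' Generates per-primer fold-change replicates across the intron from the
#' steady-state intron model: the mean at each position is
#' [fold_change_profile()] under the supplied fold changes, and each
#' replicate multiplies it by `1 + eps` with Gaussian `eps`. The
#' ground-truth parameters are attached to each profile (attribute
#' `truth`) so recovery tests can compare against them.
#'
#' @param base Baseline [intron_params()]; `base$f_lariat` is the lariat
#'   retention used for the chromatin-bound profile.
#' @param fc [fold_change_params()] defining the condition (the
#'   elongation factor `beta` is fixed by the caller, not simulated).
#' @param cfg A [sim_config()].
#' @return Named list with `total` and `chromatin` tiling profiles
#'   (class `tiling_profile`: data frame `position`, `mean`, `sd` with a
#'   replicate matrix attribute).
#' @export
sim_tiling_profiles <- function(base, fc, cfg = sim_config()) {
  stopifnot(inherits(base, "intron_params"), inherits(fc, "fc_params"),
            inherits(cfg, "sim_config"))
  pos <- cfg$tiling_positions
  if (is.null(pos)) pos <- round(seq(0.04, 0.96, length.out = 12) * base$L)
  check_intron_pos(base, pos)
  set.seed(cfg$seed)
  truth <- list(base = unclass(base), fc = unclass(fc),
                noise_sd = cfg$noise_sd, seed = cfg$seed)
  out <- lapply(c(total = "total", chromatin = "chromatin"), function(fr) {
    mu <- fold_change_profile(base, fc, pos, fr)
    new_tiling_profile(pos, mult_noise(mu, cfg$n_replicates, cfg$noise_sd),
                       fr, truth)
  })
  out
}

#' Summarized decay course
#'
#' Container for transcript abundance after transcriptional inhibition,
#' collapsed to per-timepoint mean, s.d. of the mean, and the number of
#' underlying observations.
#'
#' @param time Hours after inhibition.
#' @param mean Mean abundance per timepoint.
#' @param sd Standard error of each mean (> 0 required for fitting).
#' @param n Observations behind each mean.
#' @return Data frame of class `decay_course`.
#' @export
decay_course <- function(time, mean, sd, n = NA_integer_) {
  stopifnot(length(time) == length(mean), length(sd) == length(mean))
  if (any(time < 0)) stop("negative timepoints are not allowed", call. = FALSE)
  structure(data.frame(time = time, mean = mean, sd = sd, n = n),
            class = c("decay_course", "data.frame"))
}

#' Simulate a qPCR-style transcription-inhibition decay course
#'
#' Mean abundance follows `(m0 - a) 2^(-t / halflife) + a`; replicates
#' add Gaussian noise with s.d. `noise_sd * m0` (additive, matching
#' abundance-scale measurement error). Ground truth is attached as the
#' `truth` attribute.
#'
#' @param m0 Abundance at `t = 0`.
#' @param halflife Half-life in hours (> 0; `Inf` gives a flat profile).
#' @param cfg A [sim_config()] (supplies timepoints, replicates, noise,
#'   seed).
#' @param asymptote Residual level in `[0, m0)`.
#' @return A [decay_course()] whose `sd` column is the standard error of
#'   the replicate mean, with attributes `replicates` and `truth`.
#' @export
sim_decay_course <- function(m0, halflife, cfg = sim_config(),
                             asymptote = 0) {
  stopifnot(inherits(cfg, "sim_config"), m0 > 0)
  if (halflife <= 0) stop("halflife must be > 0", call. = FALSE)
  if (asymptote < 0 || asymptote >= m0) {
    stop("asymptote must lie in [0, m0)", call. = FALSE)
  }
  t <- cfg$timepoints
  set.seed(cfg$seed)
  mu <- (m0 - asymptote) * 2^(-t / halflife) + asymptote
  reps <- matrix(mu, length(t), cfg$n_replicates) +
    matrix(stats::rnorm(length(t) * cfg$n_replicates,
                        sd = cfg$noise_sd * m0),
           length(t), cfg$n_replicates)
  out <- decay_course(t, rowMeans(reps),
                      apply(reps, 1L, stats::sd) / sqrt(cfg$n_replicates),
                      n = cfg$n_replicates)
  attr(out, "replicates") <- reps
  attr(out, "truth") <- list(m0 = m0, halflife = halflife,
                             asymptote = asymptote, noise_sd = cfg$noise_sd,
                             seed = cfg$seed)
  out
}

#' Simulate an smFISH cell table
#'
#' Cell areas are log-normal (configurable median and log-scale spread);
#' mRNA foci counts are Poisson with mean `density * area`, so the mean
#' foci-per-area converges to `density` as the number of cells grows.
#'
#' @param density Expected mRNA foci per square micron (>= 0).
#' @param cfg A [sim_config()] (supplies `n_cells` and `seed`).
#' @param area_median Median cell area in square microns.
#' @param area_log_sd Log-scale s.d. of the area distribution.
#' @return Data frame `cell_id`, `area`, `foci` with a `truth` attribute.
#' @export
sim_smfish_cells <- function(density, cfg = sim_config(),
                             area_median = 10, area_log_sd = 0.4) {
  stopifnot(inherits(cfg, "sim_config"), density >= 0,
            area_median > 0, area_log_sd >= 0)
  set.seed(cfg$seed)
  area <- stats::rlnorm(cfg$n_cells, log(area_median), area_log_sd)
  foci <- stats::rpois(cfg$n_cells, density * area)
  structure(
    data.frame(cell_id = seq_len(cfg$n_cells), area = area, foci = foci),
    truth = list(density = density, seed = cfg$seed)
  )
}

#' Simulate an smFISH decay experiment and collapse it to a course
#'
#' One cell table per timepoint with the density following the decay
#' curve; each timepoint is collapsed to the mean foci-per-area with its
#' standard error across cells, the summarized form the decay fits
#' consume.
#'
#' @param density0 Starting density (foci per square micron) at `t = 0`.
#' @inheritParams sim_decay_course
#' @return List with `course` (a [decay_course()]) and `cells` (list of
#'   per-timepoint cell tables).
#' @export
sim_smfish_decay <- function(density0, halflife, cfg = sim_config(),
                             asymptote = 0) {
  stopifnot(inherits(cfg, "sim_config"), density0 > 0, halflife > 0,
            asymptote >= 0, asymptote < density0)
  t <- cfg$timepoints
  dens <- (density0 - asymptote) * 2^(-t / halflife) + asymptote
  cells <- lapply(seq_along(t), function(k) {
    sim_smfish_cells(dens[k], sim_config(
      seed = cfg$seed + k, n_cells = cfg$n_cells,
      n_replicates = cfg$n_replicates, noise_sd = cfg$noise_sd))
  })
  per_cell <- lapply(cells, function(tb) tb$foci / tb$area)
  course <- decay_course(
    t,
    vapply(per_cell, mean, numeric(1)),
    vapply(per_cell, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    n = cfg$n_cells
  )
  attr(course, "truth") <- list(m0 = density0, halflife = halflife,
                                asymptote = asymptote, seed = cfg$seed)
  list(course = course, cells = cells)
}

#' Simulate strand-specific nascent-transcript 3'-end coverage
#'
#' Per-base expected counts are proportional to the local PolII density
#' `F / v` under a piecewise-constant speed: over the termination window
#' the speed is fixed at the reference value, over the remaining gene
#' body it is `body_speed_fc` times the reference. A two-state copy
#' mixture is supported: a fraction `spread_frac` of gene copies are in a
#' Polycomb state whose body speed is `silenced_speed_ratio` times the
#' active-state speed; the expected density is the copy-weighted sum.
#' Counts are Poisson-sampled per base.
#'
#' @param gene A [gene_windows()] annotation.
#' @param body_speed_fc Gene-body speed fold change of the active state
#'   relative to the reference condition (> 0).
#' @param spread_frac Fraction of copies in the slow Polycomb state, in
#'   `[0, 1]`.
#' @param cfg A [sim_config()] (supplies `depth` and `seed`); `depth = 0`
#'   gives an empty (all-zero) track.
#' @param silenced_speed_ratio Relative speed of the Polycomb state
#'   (default 0.1).
#' @return A [coverage_track()] spanning the gene with a `truth`
#'   attribute.
#' @export
sim_coverage <- function(gene, body_speed_fc = 1, spread_frac = 0,
                         cfg = sim_config(), silenced_speed_ratio = 0.1) {
  stopifnot(inherits(gene, "gene_windows"), inherits(cfg, "sim_config"))
  if (body_speed_fc <= 0) stop("body_speed_fc must be > 0", call. = FALSE)
  if (spread_frac < 0 || spread_frac > 1) {
    stop("spread_frac must lie in [0, 1]", call. = FALSE)
  }
  set.seed(cfg$seed)
  pos <- seq.int(gene$start, gene$end - 1L)
  in_term <- pos >= gene$term_start & pos < gene$term_end
  # density ~ 1/v per copy state; termination-window speed fixed at 1
  body_density <- (1 - spread_frac) / body_speed_fc +
    spread_frac / (body_speed_fc * silenced_speed_ratio)
  lambda <- ifelse(in_term, cfg$depth, cfg$depth * body_density)
  counts <- stats::rpois(length(pos), lambda)
  tr <- coverage_track(start = gene$start, counts = counts,
                       seqname = gene$seqname, strand = gene$strand)
  attr(tr, "truth") <- list(body_speed_fc = body_speed_fc,
                            spread_frac = spread_frac,
                            silenced_speed_ratio = silenced_speed_ratio,
                            depth = cfg$depth, seed = cfg$seed)
  tr
}

#' Simulate a spliced/unspliced expression time course
#'
#' For each timepoint the splicing rate is `k_s` scaled by the schedule
#' entry; spliced and unspliced levels are the steady states of the
#' two-species system and replicates carry multiplicative Gaussian noise.
#' With an all-ones schedule the spliced:unspliced ratio is constant
#' across timepoints; varying the unspliced degradation rate leaves the
#' ratio unchanged.
#'
#' @param schedule Named, strictly positive vector of splicing-rate fold
#'   changes per condition (first entry is typically the reference, e.g.
#'   `c(NV = 1, `2W` = 2)`).
#' @param base A [two_species_params()] baseline.
#' @param cfg A [sim_config()].
#' @return Long data frame `condition`, `target` ("spliced"/"unspliced"),
#'   `replicate`, `value`, with a `truth` attribute.
#' @export
sim_ratio_timecourse <- function(schedule, base, cfg = sim_config()) {
  stopifnot(inherits(base, "two_species_params"), inherits(cfg, "sim_config"))
  if (any(schedule <= 0)) {
    stop("splicing-rate schedule must be strictly positive", call. = FALSE)
  }
  if (is.null(names(schedule))) {
    names(schedule) <- paste0("T", seq_along(schedule))
  }
  set.seed(cfg$seed)
  rows <- lapply(names(schedule), function(cond) {
    p <- two_species_params(base$F, base$k_s * schedule[[cond]], base$d_S,
                            base$d_U)
    ss <- steady_state(p)
    mu <- c(spliced = ss$S, unspliced = ss$U)
    reps <- mult_noise(mu, cfg$n_replicates, cfg$noise_sd)
    data.frame(
      condition = cond,
      target = rep(c("spliced", "unspliced"), cfg$n_replicates),
      replicate = rep(seq_len(cfg$n_replicates), each = 2L),
      value = as.vector(reps)
    )
  })
  structure(do.call(rbind, rows),
            truth = list(schedule = schedule, base = unclass(base),
                         noise_sd = cfg$noise_sd, seed = cfg$seed))
}

#' Write the ground-truth sidecar of a synthetic dataset
#'
#' Serializes the `truth` attribute attached by the generators to a JSON
#' file next to the dataset, enabling parameter-recovery tests on
#' archived simulations.
#'
#' @param x A simulated object carrying a `truth` attribute.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no `truth` attribute", call. = FALSE)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
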