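#' Gaussian log-likelihood from replicate-derived uncertainties
#'
#' Builds the additive-Gaussian likelihood used throughout the fits: each
#' datum has zero-mean Gaussian error with a standard deviation estimated
#' from replicates, so
#' `log L(theta) = -0.5 * sum(((y - mu(theta)) / sd)^2) - sum(log sd) -
#' 0.5 n log(2 pi)`. Non-finite predictions yield `-Inf` (a hard
#' constraint the sampler handles).
#'
#' @param observed Observed means per datum.
#' @param sd Per-datum standard deviations (> 0).
#' @param predict Function mapping a named parameter vector to predicted
#'   means.
#' @return A log-likelihood function of the parameter vector.
#' @export
gaussian_loglik <- function(observed, sd, predict) {
  stopifnot(length(observed) == length(sd))
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("every datum needs a finite positive s.d.", call. = FALSE)
  }
  const <- -sum(log(sd)) - 0.5 * length(observed) * log(2 * pi)
  function(theta) {
    mu <- predict(theta)
    if (any(!is.finite(mu))) return(-Inf)
    -0.5 * sum(((observed - mu) / sd)^2) + const
  }
}

# replicate s.d. with an n-1 denominator and a 5% relative floor, so a
# run of near-identical replicates cannot collapse the likelihood
floor_sd <- function(sd, mean, rel_floor = 0.05) {
  pmax(sd, rel_floor * abs(mean))
}

#' Drop the untreated timepoint from a decay course
#'
#' Decay fits use only the post-uptake timepoints: inhibitor uptake and
#' transcriptional shutdown are not instantaneous, so the untreated
#' (t = 0) sample is excluded before fitting.
#'
#' @param course A [decay_course()].
#' @return The course without its `time == 0` rows.
#' @export
exclude_untreated <- function(course) {
  stopifnot(inherits(course, "decay_course"))
  out <- course[course$time > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an exponential decay model to a transcript decay course
#'
#' Nested-sampling posterior over `(m0, delta)` — or `(m0, delta, a)` for
#' the asymptote variant, where the residual level `a` captures
#' incomplete transcriptional shutdown. The caller is expected to have
#' excluded the untreated T0 timepoint (inhibitor uptake is not
#' instantaneous). The returned result carries a `halflife` element with
#' the posterior mean and s.d. of `ln(2)/delta`.
#'
#' @param course A [decay_course()] with at least 3 timepoints and
#'   strictly positive `sd`.
#' @param prior Optional [prior_box()]; the default uses
#'   `m0` in `[0, 3 max(mean)]`, `delta` in `[0.01, 2]` per hour and (for
#'   the asymptote variant) `a` in `[0, max(mean)]`.
#' @param cfg An [ns_config()].
#' @param variant `"single"` (decay to zero) or `"asymptote"`.
#' @return An `ns_result` with extra elements `halflife` (list `mean`,
#'   `sd`) and `variant`.
#' @export
fit_decay <- function(course, prior = NULL, cfg = ns_config(),
                      variant = c("single", "asymptote")) {
  variant <- match.arg(variant)
  stopifnot(inherits(course, "decay_course"))
  if (nrow(course) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (all(course$mean == 0)) stop("all-zero course rejected", call. = FALSE)
  if (any(!is.finite(course$sd)) || any(course$sd <= 0)) {
    stop("every timepoint needs a positive s.d.", call. = FALSE)
  }
  top <- max(course$mean)
  if (is.null(prior)) {
    prior <- if (variant == "single") {
      prior_box(m0 = c(0, 3 * top), delta = c(0.01, 2))
    } else {
      prior_box(m0 = c(0, 3 * top), delta = c(0.01, 2), a = c(0, top))
    }
  }
  predict <- if (variant == "single") {
    function(th) decay_curve(course$time, th[["m0"]], th[["delta"]])
  } else {
    function(th) {
      if (th[["a"]] >= th[["m0"]]) return(NaN)
      decay_curve(course$time, th[["m0"]], th[["delta"]], th[["a"]])
    }
  }
  ll <- gaussian_loglik(course$mean, course$sd, predict)
  res <- nested_sampling(ll, prior, cfg)
  hl <- log(2) / res$samples[, "delta"]
  hmean <- sum(hl * res$weights)
  res$halflife <- list(mean = hmean,
                       sd = sqrt(sum((hl - hmean)^2 * res$weights)))
  res$variant <- variant
  res
}

#' Compare shared-rate and different-rate decay models across conditions
#'
#' Runs nested sampling for two models of a pair of decay courses: one
#' with a common decay rate (`m0A`, `m0B`, `delta`) and one allowing the
#' rates to differ (`m0A`, `m0B`, `deltaA`, `deltaB`), and returns the
#' Bayes factor `Z_different / Z_shared`. Values near 1 are weak evidence
#' either way on the Jeffreys scale; values well below 1 favour a shared
#' rate, values well above 1 a genuine rate difference.
#'
#' @param course_a,course_b [decay_course()] objects (T0 already
#'   excluded by the caller).
#' @param priors Optional list with elements `m0_a`, `m0_b`, `delta`,
#'   each `c(lower, upper)`; defaults mirror [fit_decay()].
#' @param cfg An [ns_config()]; the two runs use `seed` and `seed + 1`.
#' @return A [bayes_factor()] (different / shared) with the two fits
#'   attached as `fit_different` and `fit_shared`.
#' @export
compare_decay <- function(course_a, course_b, priors = NULL,
                          cfg = ns_config()) {
  stopifnot(inherits(course_a, "decay_course"),
            inherits(course_b, "decay_course"))
  for (co in list(course_a, course_b)) {
    if (any(!is.finite(co$sd)) || any(co$sd <= 0)) {
      stop("every timepoint needs a positive s.d.", call. = FALSE)
    }
  }
  if (is.null(priors)) {
    priors <- list(m0_a = c(0, 3 * max(course_a$mean)),
                   m0_b = c(0, 3 * max(course_b$mean)),
                   delta = c(0.01, 2))
  }
  y <- c(course_a$mean, course_b$mean)
  s <- c(course_a$sd, course_b$sd)
  na <- nrow(course_a)
  pred_diff <- function(th) {
    c(decay_curve(course_a$time, th[["m0_a"]], th[["delta_a"]]),
      decay_curve(course_b$time, th[["m0_b"]], th[["delta_b"]]))
  }
  pred_same <- function(th) {
    c(decay_curve(course_a$time, th[["m0_a"]], th[["delta"]]),
      decay_curve(course_b$time, th[["m0_b"]], th[["delta"]]))
  }
  box_diff <- prior_box(m0_a = priors$m0_a, m0_b = priors$m0_b,
                        delta_a = priors$delta, delta_b = priors$delta)
  box_same <- prior_box(m0_a = priors$m0_a, m0_b = priors$m0_b,
                        delta = priors$delta)
  fit_diff <- nested_sampling(gaussian_loglik(y, s, pred_diff), box_diff,
                              cfg)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  fit_same <- nested_sampling(gaussian_loglik(y, s, pred_same), box_same,
                              cfg2)
  bf <- bayes_factor(fit_diff, fit_same)
  bf$fit_different <- fit_diff
  bf$fit_shared <- fit_same
  bf
}

#' Correct transcription-inhibition qPCR courses for equal-loading bias
#'
#' qPCR requires equal total RNA per sample, but global RNA levels fall
#' after transcription inhibition, biasing apparent decay profiles. Using
#' a slow-decaying reference transcript of known half-life (AT5G40370,
#' about 24 h), the correction factor at each timepoint is
#' `c(t) = 2^(-t / ref_halflife) / ref_measured(t)`; multiplying every
#' profile by `c(t)` removes the bias, and the corrected reference equals
#' its assumed true decay exactly. Applying the correction to
#' already-corrected profiles (with the corrected reference) is the
#' identity.
#'
#' @param profiles Named list of [decay_course()] objects measured at the
#'   same timepoints as the reference.
#' @param ref_profile The reference transcript's measured
#'   [decay_course()], normalized to its T0 value; all means must be
#'   non-zero.
#' @param ref_halflife Assumed true reference half-life in hours
#'   (default 24).
#' @return List with `profiles` (corrected, same names), `reference`
#'   (corrected reference) and `factors` (the per-timepoint `c(t)`).
#' @export
correct_decay_bias <- function(profiles, ref_profile, ref_halflife = 24) {
  stopifnot(inherits(ref_profile, "decay_course"), ref_halflife > 0)
  if (inherits(profiles, "decay_course")) profiles <- list(profiles)
  if (any(ref_profile$mean == 0)) {
    stop("reference profile contains zero values", call. = FALSE)
  }
  cf <- 2^(-ref_profile$time / ref_halflife) / ref_profile$mean
  apply_cf <- function(co) {
    if (!isTRUE(all.equal(co$time, ref_profile$time))) {
      stop("profile timepoints must match the reference", call. = FALSE)
    }
    co$mean <- co$mean * cf
    co$sd <- co$sd * cf
    co
  }
  list(profiles = lapply(profiles, apply_cf),
       reference = apply_cf(ref_profile),
       factors = cf)
}

#' Fit the intron fold-change model to tiling profiles
#'
#' Joint nested-sampling fit of the steady-state intron model to
#' fold-change tiling profiles. The elongation fold change `beta` is
#' fixed externally (it is constrained by the NET-seq termination index,
#' not by the tiling data); the inferred parameters are the initiation
#' fold change(s) (`alpha_total`, plus `alpha_cb` when a chromatin-bound
#' profile is supplied — the two experiments may shut down differently),
#' the intron processing fold change `gamma`, and optionally the lariat
#' retention `f_lariat` of the chromatin-bound fraction. The likelihood
#' is Gaussian with per-primer s.d. from the replicates (5% relative
#' floor).
#'
#' @param total Total-RNA `tiling_profile` (from [sim_tiling_profiles()]
#'   or constructed from data).
#' @param cb Optional chromatin-bound `tiling_profile`; when absent the
#'   fit is total-only and `f_lariat` is irrelevant.
#' @param base Baseline [intron_params()].
#' @param beta Fixed elongation fold change (e.g. 0.8 at 2 weeks of cold,
#'   0.65 at 4 weeks).
#' @param priors Optional list with `alpha`, `gamma` (and `f_lariat`)
#'   bounds; defaults are fold changes in `[0.01, 20]` and `f_lariat` in
#'   `[0, 1]`.
#' @param cfg An [ns_config()].
#' @param f_lariat_mode `"infer"` (default, requires `cb`) or `"fixed"`.
#' @param f_lariat_fixed Value used when `f_lariat_mode = "fixed"`.
#' @return An `ns_result` over the inferred parameters.
#' @export
fit_intron <- function(total, cb = NULL, base, beta, priors = NULL,
                       cfg = ns_config(),
                       f_lariat_mode = c("infer", "fixed"),
                       f_lariat_fixed = 0.17) {
  f_lariat_mode <- match.arg(f_lariat_mode)
  stopifnot(inherits(total, "tiling_profile"), inherits(base, "intron_params"),
            is.numeric(beta), beta > 0)
  if (nrow(total) < 2L || (!is.null(cb) && nrow(cb) < 2L)) {
    stop("a single tiling position cannot constrain the model", call. = FALSE)
  }
  if (is.null(priors)) priors <- list(alpha = c(0.01, 20),
                                      gamma = c(0.01, 20),
                                      f_lariat = c(0, 1))
  with_cb <- !is.null(cb)
  infer_f <- with_cb && f_lariat_mode == "infer"

  spec <- list(alpha_total = priors$alpha)
  if (with_cb) spec$alpha_cb <- priors$alpha
  spec$gamma <- priors$gamma
  if (infer_f) spec$f_lariat <- priors$f_lariat
  box <- prior_box(spec)

  y <- total$mean
  s <- floor_sd(total$sd, total$mean)
  if (with_cb) {
    y <- c(y, cb$mean)
    s <- c(s, floor_sd(cb$sd, cb$mean))
  }
  # closed-form fold-change predictor on precomputed transit times:
  # FC(l) = alpha * (a/beta + 1/(gamma k_s) + w c) / (a + 1/k_s + w c)
  # with a = (L - l)/v, c = l/k_d, and lariat weight w (1 for total,
  # f_lariat for chromatin-bound, present in numerator and denominator
  # because lariat retention is assumed unchanged in the cold)
  inv_ks <- 1 / base$k_s
  a_tot <- (base$L - total$position) / base$v
  c_tot <- total$position / base$k_d
  den_tot <- a_tot + inv_ks + c_tot
  if (with_cb) {
    a_cb <- (base$L - cb$position) / base$v
    c_cb <- cb$position / base$k_d
  }
  predict <- function(th) {
    g <- inv_ks / th[["gamma"]]
    mu <- th[["alpha_total"]] * (a_tot / beta + g + c_tot) / den_tot
    if (with_cb) {
      f <- if (infer_f) th[["f_lariat"]] else f_lariat_fixed
      mu <- c(mu, th[["alpha_cb"]] * (a_cb / beta + g + f * c_cb) /
                (a_cb + inv_ks + f * c_cb))
    }
    mu
  }
  res <- nested_sampling(gaussian_loglik(y, s, predict), box, cfg)
  res$beta <- beta
  res
}

#' Splicing-rate fold change from spliced/unspliced expression
#'
#' Computes, per condition, the fold change of the spliced:unspliced
#' ratio relative to a reference condition:
#' `FC = (S_c / U_c) / (S_ref / U_ref)`. At steady state the ratio equals
#' `k_s / d_S`, so — provided the spliced-transcript decay rate is
#' unchanged between conditions — the fold change in the ratio equals
#' the fold change in the splicing rate (this caveat is recorded in the
#' output's `assumes` attribute). Standard errors are propagated to
#' first order (delta method): the relative variance of the fold change
#' is the sum of the four relative variances. The result is invariant to
#' rescaling all expression values by a common factor.
#'
#' @param tab Long data frame with columns `condition`, `target`
#'   (`"spliced"` / `"unspliced"`), `replicate`, `value`.
#' @param reference Reference condition label (e.g. `"NV"`).
#' @return Data frame `condition`, `fold_change`, `se` (reference row
#'   included with fold change 1), with attribute
#'   `assumes = "unchanged spliced-transcript decay rate"`.
#' @export
splicing_fc <- function(tab, reference) {
  need <- c("condition", "target", "replicate", "value")
  if (!all(need %in% names(tab))) {
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!reference %in% tab$condition) {
    stop("reference condition not present", call. = FALSE)
  }
  agg <- stats::aggregate(value ~ condition + target, tab, function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  agg <- cbind(agg[c("condition", "target")], as.data.frame(agg$value))
  if (any(agg$mean <= 0)) {
    stop("nonpositive expression means rejected", call. = FALSE)
  }
  get <- function(cond, targ) agg[agg$condition == cond & agg$target == targ, ]
  conds <- unique(tab$condition)
  s_ref <- get(reference, "spliced")
  u_ref <- get(reference, "unspliced")
  out <- do.call(rbind, lapply(conds, function(cond) {
    s <- get(cond, "spliced")
    u <- get(cond, "unspliced")
    fc <- (s$mean / u$mean) / (s_ref$mean / u_ref$mean)
    rel <- sqrt((s$se / s$mean)^2 + (u$se / u$mean)^2 +
                  (s_ref$se / s_ref$mean)^2 + (u_ref$se / u_ref$mean)^2)
    data.frame(condition = cond, fold_change = fc, se = fc * rel)
  }))
  attr(out, "assumes") <- "unchanged spliced-transcript decay rate"
  out
}

#' One-tailed replicate comparison of ratio fold changes
#'
#' Compares per-replicate ratio fold changes between a mutant and the
#' wild type with a one-tailed two-sample t-test, using a
#' Bonferroni-adjusted significance level (0.05 / `n_comparisons`;
#' three comparisons give alpha = 0.0167).
#'
#' @param fc_wt,fc_mut Numeric vectors of per-replicate fold changes.
#' @param alternative Direction of the alternative for the mutant mean
#'   relative to wild type (`"less"` or `"greater"`).
#' @param n_comparisons Number of comparisons sharing the 0.05 budget.
#' @return List with `p_value`, `alpha` and `significant`.
#' @export
ratio_fc_ttest <- function(fc_wt, fc_mut,
                           alternative = c("less", "greater"),
                           n_comparisons = 3L) {
  alternative <- match.arg(alternative)
  tt <- stats::t.test(fc_mut, fc_wt, alternative = alternative)
  alpha <- 0.05 / n_comparisons
  list(p_value = unname(tt$p.value), alpha = alpha,
       significant = unname(tt$p.value) < alpha)
}
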