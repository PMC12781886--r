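#' Kinetic parameters for steady-state RNA profiles across an intron
#'
#' Bundles the rates that determine the steady-state abundance of intronic
#' RNA along a long intron. Two species contribute signal at an intronic
#' position: the nascent transcript (PolII has passed the position but the
#' intron is not yet processed) and the excised intron lariat, which is
#' degraded 5'->3' so that positions further from the intron donor survive
#' longer and accumulate more signal.
#'
#' @param init_rate Productive transcription initiation rate `F`
#'   (transcripts per unit time). Only initiation events that produce an
#'   elongating PolII traversing the gene body count.
#' @param pol_speed PolII elongation speed `v` (nt per unit time).
#' @param proc_rate Intron processing rate `k_s` (1 per unit time): the
#'   composite rate at which intronic nascent RNA is converted into a
#'   released lariat.
#' @param lariat_speed Lariat 5'->3' degradation speed `k_d` (nt per unit
#'   time).
#' @param intron_length Intron length `L` (nt).
#' @param f_lariat Fraction of the lariat component retained in the
#'   chromatin-bound RNA fraction, in `[0, 1]`. The total RNA fraction
#'   always contains the full lariat component.
#'
#' @return An object of class `intron_params`.
#' @seealso [nascent_profile()], [lariat_profile()], [fraction_profile()],
#'   [fold_change_profile()]
#' @export
intron_params <- function(init_rate, pol_speed, proc_rate, lariat_speed,
                          intron_length, f_lariat = 0) {
  stopifnot(
    is.numeric(init_rate), length(init_rate) == 1L, init_rate >= 0,
    is.numeric(pol_speed), pol_speed > 0,
    is.numeric(proc_rate), proc_rate > 0,
    is.numeric(lariat_speed), lariat_speed > 0,
    is.numeric(intron_length), intron_length > 0
  )
  if (!is.numeric(f_lariat) || f_lariat < 0 || f_lariat > 1) {
    stop("`f_lariat` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(F = init_rate, v = pol_speed, k_s = proc_rate, k_d = lariat_speed,
         L = intron_length, f_lariat = f_lariat),
    class = "intron_params"
  )
}

#' Condition fold changes applied to the intron model
#'
#' Fold changes (cold relative to non-vernalized) applied to the baseline
#' intron kinetics when predicting cold tiling profiles. Initiation fold
#' changes are allowed to differ between the total-RNA and chromatin-bound
#' experiments (they are separate experiments with variable shutdown at a
#' given timepoint); the elongation fold change `beta` is fixed externally
#' (e.g. from the NET-seq termination index) and never inferred from the
#' tiling data; lariat degradation is assumed unchanged.
#'
#' @param alpha_total Fold change in productive initiation for the
#'   total-RNA experiment.
#' @param alpha_cb Fold change in productive initiation for the
#'   chromatin-bound experiment (defaults to `alpha_total`).
#' @param beta Fold change in PolII elongation speed (externally fixed).
#' @param gamma Fold change in the intron processing rate.
#' @return An object of class `fc_params`.
#' @export
fold_change_params <- function(alpha_total, alpha_cb = alpha_total,
                               beta = 1, gamma = 1) {
  vals <- c(alpha_total = alpha_total, alpha_cb = alpha_cb,
            beta = beta, gamma = gamma)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fold changes must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "fc_params")
}

check_intron_pos <- function(p, pos) {
  bad <- which(!is.finite(pos) | pos < 0 | pos > p$L)
  if (length(bad)) {
    stop(sprintf(
      "intron offset(s) %s outside [0, %g]",
      paste(signif(pos[bad[seq_len(min(3L, length(bad)))]], 6), collapse = ", "),
      p$L), call. = FALSE)
  }
  invisible(pos)
}

#' Nascent-transcript contribution to intronic signal
#'
#' At steady state a position `ell` nt downstream of the intron donor
#' carries nascent signal from every PolII that has passed it but whose
#' intron is not yet processed: transit of the remaining `L - ell` nt takes
#' `(L - ell)/v`, and processing adds a further mean dwell of `1/k_s`, so
#' the signal is `F * ((L - ell)/v + 1/k_s)`. The slope along the intron is
#' `-F/v` (the PolII density) and the level at the intron acceptor is
#' `F/k_s`.
#'
#' @param p An [intron_params()] object.
#' @param ell Numeric vector of nt offsets from the intron donor (5'
#'   splice site), in `[0, L]`.
#' @return Steady-state signal in transcript-equivalents.
#' @export
nascent_profile <- function(p, ell) {
  stopifnot(inherits(p, "intron_params"))
  check_intron_pos(p, ell)
  p$F * ((p$L - ell) / p$v + 1 / p$k_s)
}

#' Lariat contribution to intronic signal
#'
#' The excised lariat is degraded 5'->3' at speed `k_d`, so the RNA at
#' offset `ell` survives for a time `ell/k_d` after excision and the
#' steady-state lariat signal is `F * ell / k_d`: zero at the donor and
#' rising with slope `F/k_d` towards the acceptor.
#'
#' @inheritParams nascent_profile
#' @return Steady-state lariat signal in transcript-equivalents.
#' @export
lariat_profile <- function(p, ell) {
  stopifnot(inherits(p, "intron_params"))
  check_intron_pos(p, ell)
  p$F * ell / p$k_d
}

#' Intronic signal for a measured RNA fraction
#'
#' Total RNA contains the full nascent and lariat components; the
#' chromatin-bound fraction contains the nascent component plus the
#' fraction `f_lariat` of the lariat component that remains chromatin
#' retained while being degraded.
#'
#' @inheritParams nascent_profile
#' @param fraction `"total"` or `"chromatin"`.
#' @return Steady-state signal in transcript-equivalents.
#' @export
fraction_profile <- function(p, ell, fraction = c("total", "chromatin")) {
  fraction <- match.arg(fraction)
  w <- if (fraction == "total") 1 else p$f_lariat
  nascent_profile(p, ell) + w * lariat_profile(p, ell)
}

#' Fold-change profile across the intron between two conditions
#'
#' Ratio of the steady-state fraction profile under condition kinetics
#' (`alpha * F`, `beta * v`, `gamma * k_s`, `k_d` and `f_lariat`
#' unchanged) to the profile under the baseline kinetics, evaluated at
#' offsets `ell`. The initiation fold change used is `alpha_total` for the
#' total fraction and `alpha_cb` for the chromatin-bound fraction.
#'
#' @param base Baseline [intron_params()].
#' @param fc [fold_change_params()].
#' @inheritParams fraction_profile
#' @return Dimensionless fold change (condition / baseline), vectorized
#'   over `ell`.
#' @export
fold_change_profile <- function(base, fc, ell,
                                fraction = c("total", "chromatin")) {
  stopifnot(inherits(base, "intron_params"), inherits(fc, "fc_params"))
  fraction <- match.arg(fraction)
  alpha <- if (fraction == "total") fc$alpha_total else fc$alpha_cb
  cond <- intron_params(
    init_rate = alpha * base$F,
    pol_speed = fc$beta * base$v,
    proc_rate = fc$gamma * base$k_s,
    lariat_speed = base$k_d,
    intron_length = base$L,
    f_lariat = base$f_lariat
  )
  fraction_profile(cond, ell, fraction) / fraction_profile(base, ell, fraction)
}

#' Two-species spliced/unspliced transcript model
#'
#' Parameters of the linear system `dU/dt = F - (k_s + d_U) U`,
#' `dS/dt = k_s U - d_S S`: unspliced transcripts are produced at rate
#' `F`, converted to spliced at rate `k_s` and (optionally) degraded at
#' rate `d_U`; spliced transcripts decay at rate `d_S`.
#'
#' @param init_rate Production rate of unspliced transcripts `F`.
#' @param splice_rate Splicing rate `k_s` (1/time).
#' @param spliced_decay Spliced-transcript decay rate `d_S` (1/time).
#' @param unspliced_decay Unspliced-transcript degradation rate `d_U`
#'   (1/time, default 0; the variant with `d_U > 0` models degradation of
#'   the unspliced form, e.g. by NMD).
#' @return An object of class `two_species_params`.
#' @export
two_species_params <- function(init_rate, splice_rate, spliced_decay,
                               unspliced_decay = 0) {
  stopifnot(init_rate > 0, splice_rate > 0, spliced_decay > 0,
            unspliced_decay >= 0)
  structure(
    list(F = init_rate, k_s = splice_rate, d_S = spliced_decay,
         d_U = unspliced_decay),
    class = "two_species_params"
  )
}

#' Steady state of the two-species spliced/unspliced system
#'
#' Returns `U = F / (k_s + d_U)`, `S = F k_s / ((k_s + d_U) d_S)` and the
#' spliced-to-unspliced ratio `R = S/U = k_s / d_S`. The ratio is exactly
#' independent of the unspliced degradation rate, which is why a changed
#' spliced:unspliced ratio cannot be explained by changed degradation of
#' the unspliced form and instead reflects the splicing rate (given an
#' unchanged spliced-transcript decay rate).
#'
#' @param p A [two_species_params()] object.
#' @return List with elements `U`, `S` and `ratio`.
#' @export
steady_state <- function(p) {
  stopifnot(inherits(p, "two_species_params"))
  U <- p$F / (p$k_s + p$d_U)
  S <- p$F * p$k_s / ((p$k_s + p$d_U) * p$d_S)
  list(U = U, S = S, ratio = p$k_s / p$d_S)
}

#' Convert between decay rate and half-life
#'
#' `t_half = ln(2) / delta` and conversely; the two functions are exact
#' inverses of one another.
#'
#' @param delta Decay rate in 1/h (strictly positive).
#' @param halflife Half-life in hours (strictly positive).
#' @return Half-life in hours (`rate_to_halflife`) or decay rate in 1/h
#'   (`halflife_to_rate`).
#' @export
rate_to_halflife <- function(delta) {
  if (any(!is.numeric(delta)) || any(delta <= 0)) {
    stop("decay rate must be strictly positive", call. = FALSE)
  }
  log(2) / delta
}

#' @rdname rate_to_halflife
#' @export
halflife_to_rate <- function(halflife) {
  if (any(!is.numeric(halflife)) || any(halflife <= 0)) {
    stop("half-life must be strictly positive", call. = FALSE)
  }
  log(2) / halflife
}

#' Exponential decay curve with optional asymptote
#'
#' Mean transcript abundance at time `t` after transcriptional
#' inhibition: `(m0 - a) * exp(-delta * t) + a`. The non-zero asymptote
#' `a` captures residual transcription if shutdown is incomplete.
#'
#' @param time Hours after inhibition (non-negative).
#' @param m0 Abundance at `t = 0`.
#' @param delta Decay rate (1/h).
#' @param asymptote Residual level `a`, `0 <= a < m0`.
#' @return Mean abundance, vectorized over `time`.
#' @export
decay_curve <- function(time, m0, delta, asymptote = 0) {
  if (any(time < 0)) stop("negative timepoints are not allowed", call. = FALSE)
  (m0 - asymptote) * exp(-delta * time) + asymptote
}

#' Fraction of gene copies in the slow (Polycomb) state from a speed
#' fold change
#'
#' If each gene copy is either in a transcriptionally active state
#' (relative speed 1) or in an H3K27me3-spread Polycomb state with
#' relative speed `r` (about 10-fold lower), the copy-averaged speed fold
#' change observed across the population is the arithmetic mixture
#' `(1 - p) * 1 + p * r`. Solving for the Polycomb fraction gives
#' `p = (1 - speed_fc) / (1 - r)`.
#'
#' @param speed_fc Observed overall PolII speed fold change relative to
#'   the fully active state, in `(r, 1]`.
#' @param silenced_speed_ratio Relative speed `r` of the silenced state
#'   (default 0.1).
#' @return Fraction `p` in `[0, 1)`, vectorized over `speed_fc`.
#' @export
spread_fraction <- function(speed_fc, silenced_speed_ratio = 0.1) {
  r <- silenced_speed_ratio
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0, r < 1)
  if (any(speed_fc <= r) || any(speed_fc > 1)) {
    stop(sprintf(
      "speed fold change must lie in (%g, 1] for a two-state mixture", r),
      call. = FALSE)
  }
  (1 - speed_fc) / (1 - r)
}
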