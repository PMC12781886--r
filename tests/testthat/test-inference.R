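test_that("noise-free decay data identify the decay rate to high precision", {
  truth <- halflife_to_rate(4.1)
  co <- decay_course(c(2, 4, 6), decay_curve(c(2, 4, 6), 1.4, truth),
                     sd = rep(1e-6, 3))
  f <- fit_decay(co, cfg = ns_config(n_live = 100, seed = 2))
  delta_hat <- f$summary$mean[f$summary$parameter == "delta"]
  expect_lt(abs(delta_hat - truth) / truth, 5e-6)
  expect_equal(f$halflife$mean, 4.1, tolerance = 1e-4)
})

test_that("half-life recovery on smFISH-like noise stays within 3 posterior s.d.", {
  co <- smfish_course(seed = 7, m0 = 1.4, halflife = 4.1)
  f <- fit_decay(co, cfg = ns_config(n_live = 150, seed = 1))
  expect_lt(abs(f$halflife$mean - 4.1), 3 * f$halflife$sd)
  expect_lt(f$halflife$sd, 1.5)
})

test_that("the asymptote posterior concentrates near zero when decay is complete", {
  co <- smfish_course(seed = 1, m0 = 1.4, halflife = 4.1)
  f <- fit_decay(co, cfg = ns_config(n_live = 150, seed = 1),
                 variant = "asymptote")
  ps <- posterior_summary(f)
  a_row <- ps[ps$parameter == "a", ]
  prior_upper <- max(co$mean)
  expect_lt(a_row$median, 0.35 * prior_upper)
  expect_lt(a_row$q025, 0.05 * prior_upper)
})

test_that("degenerate decay inputs are rejected", {
  expect_error(fit_decay(decay_course(c(2, 4), c(1, 0.5), c(0.1, 0.1))),
               "3 timepoints")
  expect_error(fit_decay(decay_course(c(2, 4, 6), c(0, 0, 0), rep(0.1, 3))),
               "all-zero")
  expect_error(fit_decay(decay_course(c(2, 4, 6), c(1, 0.5, 0.2), rep(0, 3))),
               "positive s.d.")
})

test_that("model comparison favours shared rates on identical courses and separates 5-fold rates", {
  co <- smfish_course(seed = 3)
  bf_same <- compare_decay(co, co, cfg = ns_config(n_live = 100, seed = 1))
  expect_lt(bf_same$value, sqrt(10))
  a <- exclude_untreated(sim_decay_course(1.4, 2, sim_config(seed = 4, noise_sd = 0.02)))
  b <- exclude_untreated(sim_decay_course(1.4, 10, sim_config(seed = 5, noise_sd = 0.02)))
  bf_diff <- compare_decay(a, b, cfg = ns_config(n_live = 100, seed = 2))
  expect_gt(bf_diff$value, 100)
})

test_that("loading-bias correction matches the closed form and is idempotent", {
  ref <- decay_course(c(0, 6), c(1, 0.5), c(0.02, 0.02))
  target <- decay_course(c(0, 6), c(1, 0.25), c(0.02, 0.02))
  out <- correct_decay_bias(list(flc = target), ref, ref_halflife = 24)
  expect_equal(out$factors[2], 2^(-0.25) / 0.5, tolerance = 1e-12)
  expect_equal(round(out$factors[2], 3), 1.682)
  expect_equal(out$profiles$flc$mean[2], 0.25 * 2^(-0.25) / 0.5,
               tolerance = 1e-12)
  expect_equal(round(out$profiles$flc$mean[2], 3), 0.42)
  # corrected reference equals its assumed true decay exactly
  expect_equal(out$reference$mean, 2^(-c(0, 6) / 24), tolerance = 1e-12)
  # re-applying with the corrected reference changes nothing
  again <- correct_decay_bias(out$profiles, out$reference, ref_halflife = 24)
  expect_equal(again$factors, c(1, 1), tolerance = 1e-12)
  expect_equal(again$profiles$flc$mean, out$profiles$flc$mean,
               tolerance = 1e-12)
  # a reference measured exactly on its true decay gives unit factors
  exact <- decay_course(c(0, 6), 2^(-c(0, 6) / 24), c(0.02, 0.02))
  expect_equal(correct_decay_bias(list(x = target), exact)$factors, c(1, 1),
               tolerance = 1e-12)
  expect_error(correct_decay_bias(list(target), decay_course(c(0, 6), c(1, 0), c(1, 1))),
               "zero")
  off_grid <- decay_course(c(0, 4), c(1, 0.5), c(0.02, 0.02))
  expect_error(correct_decay_bias(list(off_grid), ref), "match")
})

test_that("intron fit on identity data concentrates gamma at 1", {
  cfg0 <- sim_config(seed = 1, noise_sd = 0)
  prof <- sim_tiling_profiles(base_intron(), fold_change_params(1), cfg0)
  fit <- fit_intron(prof$total, prof$chromatin, base = base_intron(),
                    beta = 1, cfg = ns_config(n_live = 100, seed = 3))
  ps <- posterior_summary(fit)
  g <- ps[ps$parameter == "gamma", ]
  expect_lt(abs(g$median - 1), 3 * g$sd)
  a <- ps[ps$parameter == "alpha_total", ]
  expect_equal(a$mean, 1, tolerance = 0.1)
})

test_that("the intron likelihood peaks at the generating parameters on noise-free data", {
  cfg0 <- sim_config(seed = 2, noise_sd = 0)
  prof <- sim_tiling_profiles(base_intron(), fc_2w(), cfg0)
  base <- base_intron()
  ll_at <- function(alpha_t, alpha_c, gamma, f) {
    fc <- fold_change_params(alpha_t, alpha_c, 0.8, gamma)
    b <- intron_params(base$F, base$v, base$k_s, base$k_d, base$L, f)
    mu_t <- fold_change_profile(b, fc, prof$total$position, "total")
    mu_c <- fold_change_profile(b, fc, prof$chromatin$position, "chromatin")
    -sum((prof$total$mean - mu_t)^2) - sum((prof$chromatin$mean - mu_c)^2)
  }
  truth_ll <- ll_at(0.67, 1.3, 6.8, 0.17)
  expect_gt(truth_ll, ll_at(0.8, 1.3, 6.8, 0.17))
  expect_gt(truth_ll, ll_at(0.67, 1.0, 6.8, 0.17))
  expect_gt(truth_ll, ll_at(0.67, 1.3, 2.0, 0.17))
  expect_gt(truth_ll, ll_at(0.67, 1.3, 6.8, 0.6))
})

test_that("single-position profiles cannot be fitted", {
  cfg1 <- sim_config(seed = 1, tiling_positions = 1500)
  prof <- sim_tiling_profiles(base_intron(), fc_2w(), cfg1)
  expect_error(fit_intron(prof$total, prof$chromatin, base = base_intron(),
                          beta = 0.8), "single")
})

test_that("splicing fold change follows the ratio arithmetic with delta-method errors", {
  mk <- function(s_nv, u_nv, s_c, u_c) {
    data.frame(condition = rep(c("NV", "2W"), each = 6),
               target = rep(rep(c("spliced", "unspliced"), each = 3), 2),
               replicate = rep(1:3, 4),
               value = c(s_nv, u_nv, s_c, u_c))
  }
  # equal means: FC 1
  tab <- mk(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(splicing_fc(tab, "NV")$fold_change, c(1, 1))
  # spliced halves while unspliced quarters: FC 2
  tab2 <- mk(c(4, 4, 4), c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
  fc2 <- splicing_fc(tab2, "NV")
  expect_equal(fc2$fold_change[fc2$condition == "2W"], 2)
  # invariant to a common rescaling
  tab3 <- tab2
  tab3$value <- tab3$value * 37.5
  expect_equal(splicing_fc(tab3, "NV")$fold_change, fc2$fold_change)
  # delta-method propagation against a hand computation
  tab4 <- mk(c(4.2, 3.8, 4.0), c(4.1, 3.9, 4.0), c(2.2, 1.9, 1.9),
             c(1.1, 0.9, 1.0))
  fc4 <- splicing_fc(tab4, "NV")
  m <- function(v) mean(v)
  se <- function(v) sd(v) / sqrt(3)
  fc_hand <- (m(c(2.2, 1.9, 1.9)) / m(c(1.1, 0.9, 1.0))) /
    (m(c(4.2, 3.8, 4.0)) / m(c(4.1, 3.9, 4.0)))
  rel <- sqrt((se(c(2.2, 1.9, 1.9)) / m(c(2.2, 1.9, 1.9)))^2 +
                (se(c(1.1, 0.9, 1.0)) / m(c(1.1, 0.9, 1.0)))^2 +
                (se(c(4.2, 3.8, 4.0)) / m(c(4.2, 3.8, 4.0)))^2 +
                (se(c(4.1, 3.9, 4.0)) / m(c(4.1, 3.9, 4.0)))^2)
  row <- fc4[fc4$condition == "2W", ]
  expect_equal(row$fold_change, fc_hand, tolerance = 1e-12)
  expect_equal(row$se, fc_hand * rel, tolerance = 1e-12)
  expect_match(attr(fc4, "assumes"), "decay")
  bad <- mk(c(1, 1, 1), c(1, 1, 1), c(-1, -1, -1), c(1, 1, 1))
  expect_error(splicing_fc(bad, "NV"), "onpositive")
})

test_that("splicing-rate fold change is recovered from a simulated course", {
  tsp <- two_species_params(1, 2, 0.2)
  tab <- sim_ratio_timecourse(c(NV = 1, W2 = 2), tsp,
                              sim_config(seed = 13, noise_sd = 0.1))
  fc <- splicing_fc(tab, "NV")
  row <- fc[fc$condition == "W2", ]
  expect_lt(abs(row$fold_change - 2), 3 * row$se)
})

test_that("one-tailed mutant comparison uses the Bonferroni-adjusted level", {
  set.seed(21)
  wt <- rnorm(3, 2.0, 0.1)
  mut <- rnorm(3, 1.0, 0.1)
  res <- ratio_fc_ttest(wt, mut, alternative = "less")
  expect_equal(res$alpha, 0.05 / 3)
  expect_true(res$significant)
  same <- ratio_fc_ttest(wt, wt + rnorm(3, 0, 0.01), alternative = "less")
  expect_false(same$significant)
})
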