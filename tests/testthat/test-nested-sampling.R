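test_that("bounding ellipsoid contains every point across random clouds", {
  set.seed(11)
  for (k in 1:100) {
    d <- sample(1:4, 1)
    n <- sample((d + 2):40, 1)
    pts <- matrix(rnorm(n * d, sd = runif(1, 0.1, 3)), n, d)
    e <- bounding_ellipsoid(pts, enlarge = sample(c(1, 1.25, 2), 1))
    centered <- sweep(pts, 2L, e$center)
    maha <- rowSums((centered %*% e$prec) * centered)
    expect_true(all(maha <= 1 + 1e-8))
  }
})

test_that("ellipsoid of points on the unit circle is the scaled unit disc", {
  theta <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- cbind(cos(theta), sin(theta))
  enlarge <- 1.44
  e <- bounding_ellipsoid(pts, enlarge = enlarge)
  expect_equal(unname(e$center), c(0, 0), tolerance = 1e-10)
  # cov scaled so the circle is the boundary, then volume-enlarged:
  # both axes^2 equal enlarge^(2/d) = enlarge
  ev <- eigen(e$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, rep(enlarge, 2), tolerance = 1e-8)
})

test_that("a degenerate point cloud is regularized with a warning", {
  pts <- matrix(rep(c(0.3, 0.7), each = 5), 5, 2)
  expect_warning(e <- bounding_ellipsoid(pts), "regularized")
  centered <- sweep(pts, 2L, e$center)
  expect_true(all(rowSums((centered %*% e$prec) * centered) <= 1 + 1e-8))
  expect_lt(max(abs(e$cov)), 1e-4)
})

test_that("evidence is exact for a constant likelihood (prior integrates to 1)", {
  r <- nested_sampling(function(th) 0, prior_box(x = c(0, 1)),
                       ns_config(n_live = 400, seed = 1))
  expect_equal(r$logZ, 0, tolerance = 1e-9)
})

test_that("evidence matches the step-integral and quadrature oracles", {
  pb <- prior_box(x = c(0, 1))
  # top-hat: Z = 0.5
  r_step <- nested_sampling(function(th) if (th[["x"]] < 0.5) 0 else -Inf,
                            pb, ns_config(n_live = 400, seed = 2))
  expect_lt(abs(r_step$logZ - log(0.5)), 3 * r_step$logZ_err)
  # Gaussian in 1-D: oracle = adaptive quadrature of the integrand
  or1 <- log(stats::integrate(function(x) dnorm(x, 0.5, 0.05), 0, 1)$value)
  r_g <- nested_sampling(function(th) dnorm(th[["x"]], 0.5, 0.05, log = TRUE),
                         pb, ns_config(n_live = 400, seed = 3))
  expect_lt(abs(r_g$logZ - or1), 3 * r_g$logZ_err)
  # separable 2-D Gaussian: oracle = product of 1-D quadratures
  pb2 <- prior_box(x = c(0, 1), y = c(0, 2))
  or2 <- log(stats::integrate(function(x) dnorm(x, 0.3, 0.1), 0, 1)$value) +
    log(stats::integrate(function(y) dnorm(y, 1.2, 0.2), 0, 2)$value / 2)
  ll2 <- function(th) dnorm(th[["x"]], 0.3, 0.1, log = TRUE) +
    dnorm(th[["y"]], 1.2, 0.2, log = TRUE)
  r2 <- nested_sampling(ll2, pb2, ns_config(n_live = 400, seed = 4))
  expect_lt(abs(r2$logZ - or2), 3 * r2$logZ_err)
})

test_that("posterior summaries match the conjugate closed form", {
  # uniform prior on [0,1] with a narrow Gaussian likelihood: posterior is
  # (effectively untruncated) N(0.5, 0.05)
  r <- nested_sampling(function(th) dnorm(th[["x"]], 0.5, 0.05, log = TRUE),
                       prior_box(x = c(0, 1)),
                       ns_config(n_live = 400, seed = 5))
  se <- 0.05 / sqrt(effective_sample_size(r))
  expect_lt(abs(r$summary$mean - 0.5), 3 * se)
  expect_equal(r$summary$sd, 0.05, tolerance = 0.15)
  ps <- posterior_summary(r)
  expect_equal(ps$median, 0.5, tolerance = 3 * se + 1e-3)
  expect_equal(ps$q975 - ps$q025, 2 * 1.96 * 0.05, tolerance = 0.25)
})

test_that("a symmetric bimodal likelihood has its posterior mean at the midpoint", {
  ll <- function(th) log(dnorm(th[["x"]], 0.3, 0.03) +
                           dnorm(th[["x"]], 0.7, 0.03))
  r <- nested_sampling(ll, prior_box(x = c(0, 1)),
                       ns_config(n_live = 500, seed = 6))
  se <- r$summary$sd / sqrt(effective_sample_size(r))
  expect_lt(abs(r$summary$mean - 0.5), 5 * se)
})

test_that("retired likelihoods are non-decreasing and weights normalize", {
  r <- nested_sampling(function(th) dnorm(th[["x"]], 0.4, 0.1, log = TRUE),
                       prior_box(x = c(0, 1)),
                       ns_config(n_live = 100, seed = 7))
  dead <- r$loglike[seq_len(r$n_iter)]
  expect_true(all(diff(dead) >= 0))
  expect_equal(sum(r$weights), 1, tolerance = 1e-9)
  expect_true(r$logZ_err > 0)
})

test_that("a fixed seed reproduces the run bit for bit", {
  ll <- function(th) dnorm(th[["x"]], 0.5, 0.1, log = TRUE)
  cfg <- ns_config(n_live = 100, seed = 42)
  r1 <- nested_sampling(ll, prior_box(x = c(0, 1)), cfg)
  r2 <- nested_sampling(ll, prior_box(x = c(0, 1)), cfg)
  expect_identical(r1$logZ, r2$logZ)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$weights, r2$weights)
})

test_that("evidence error shrinks like n_live^(-1/2)", {
  ll <- function(th) dnorm(th[["x"]], 0.5, 0.05, log = TRUE)
  errs <- vapply(c(100, 400, 1600), function(nl) {
    nested_sampling(ll, prior_box(x = c(0, 1)),
                    ns_config(n_live = nl, seed = 8))$logZ_err
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.35)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.35)
})

test_that("exceeding max_iter flags the result and blocks Bayes factors", {
  ll <- function(th) dnorm(th[["x"]], 0.5, 0.05, log = TRUE)
  expect_warning(
    r <- nested_sampling(ll, prior_box(x = c(0, 1)),
                         ns_config(n_live = 100, seed = 9, max_iter = 20L)),
    "non-converged")
  expect_false(r$converged)
  ok <- nested_sampling(ll, prior_box(x = c(0, 1)),
                        ns_config(n_live = 100, seed = 9))
  expect_error(bayes_factor(r, ok), "converged")
  expect_error(posterior_summary(r), "non-converged")
})

test_that("Bayes factors follow the evidence ratio and Jeffreys labels", {
  ll <- function(th) dnorm(th[["x"]], 0.5, 0.05, log = TRUE)
  r <- nested_sampling(ll, prior_box(x = c(0, 1)),
                       ns_config(n_live = 100, seed = 10))
  expect_equal(bayes_factor(r, r)$value, 1)
  # a log-evidence offset of ln(0.86) gives BF 0.86: weak evidence band
  shifted <- r
  shifted$logZ <- r$logZ + log(0.86)
  bf <- bayes_factor(shifted, r)
  expect_equal(bf$value, 0.86, tolerance = 1e-12)
  expect_match(bf$label, "weak")
  # swapping arguments gives the reciprocal
  expect_equal(bayes_factor(r, shifted)$value, 1 / 0.86, tolerance = 1e-12)
  expect_match(jeffreys_label(50), "strong")
  expect_match(jeffreys_label(1 / 200), "decisive")
})

test_that("prior and configuration invariants are enforced", {
  expect_error(prior_box(a = c(2, 1)), "lower < upper")
  expect_error(prior_box(c(0, 1)), "named")
  expect_error(ns_config(dlogz = 0), "dlogz")
  pb3 <- prior_box(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  expect_error(
    nested_sampling(function(th) 0, pb3, ns_config(n_live = 5, seed = 1)),
    "below 2 x dimension")
})

test_that("weighted quantiles invert the weighted CDF", {
  x <- c(1, 2, 3, 4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(weighted_quantile(x, w, 0.05), 1)
  expect_equal(weighted_quantile(x, w, 0.3), 2)
  expect_equal(weighted_quantile(x, w, 0.9), 4)
  expect_equal(weighted_quantile(x, w, 1), 4)
})
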