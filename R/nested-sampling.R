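#' Uniform box prior over named parameters
#'
#' Independent uniform priors, one per parameter, specified as named
#' `c(lower, upper)` pairs. The box supports the unit-cube
#' parameterisation used internally by the sampler.
#'
#' @param ... Named numeric vectors of length 2, e.g.
#'   `prior_box(alpha = c(0.01, 20), gamma = c(0.01, 20))`.
#' @return An object of class `prior_box` with fields `names`, `lower`,
#'   `upper` and a `transform(u)` mapping unit-cube coordinates to
#'   parameter values.
#' @export
prior_box <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && is.null(names(specs))) {
    specs <- specs[[1]]
  }
  if (length(specs) == 0L || is.null(names(specs)) || any(names(specs) == "")) {
    stop("prior_box() needs named c(lower, upper) arguments", call. = FALSE)
  }
  lower <- vapply(specs, `[`, numeric(1), 1L)
  upper <- vapply(specs, `[`, numeric(1), 2L)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("each prior bound must satisfy lower < upper (finite)", call. = FALSE)
  }
  nm <- names(specs)
  names(lower) <- names(upper) <- nm
  box <- list(names = nm, lower = lower, upper = upper)
  box$transform <- function(u) {
    if (is.matrix(u)) {
      th <- sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
      colnames(th) <- nm
      th
    } else {
      stats::setNames(lower + u * (upper - lower), nm)
    }
  }
  structure(box, class = "prior_box")
}

#' Nested-sampling configuration
#'
#' @param n_live Number of live points (must be at least twice the
#'   dimension of the problem).
#' @param dlogz Termination threshold on the estimated log of the
#'   remaining evidence contribution (default 0.5).
#' @param enlarge Volume enlargement factor applied to the bounding
#'   ellipsoid (>= 1).
#' @param max_iter Safety cap on iterations; exceeding it yields a result
#'   flagged as non-converged.
#' @param seed Integer seed; every run is reproducible under a fixed
#'   seed.
#' @return An object of class `ns_config`.
#' @export
ns_config <- function(n_live = 400L, dlogz = 0.5, enlarge = 1.25,
                      max_iter = 100000L, seed = 1L) {
  stopifnot(n_live >= 2L, dlogz > 0, enlarge >= 1, max_iter >= 1L,
            is.numeric(seed), length(seed) == 1L)
  structure(
    list(n_live = as.integer(n_live), dlogz = dlogz, enlarge = enlarge,
         max_iter = as.integer(max_iter), seed = as.integer(seed)),
    class = "ns_config"
  )
}

#' Minimum-covariance bounding ellipsoid of a point cloud
#'
#' Fits an ellipsoid of the form
#' `(x - c)^T A (x - c) <= 1` around the points, using the sample
#' covariance as the shape and scaling it so the farthest point lies on
#' the boundary, then enlarging the volume by `enlarge`. A degenerate
#' cloud (fewer points than `d + 1`, or a singular covariance) is
#' regularized by adding a small jitter to the covariance diagonal, with
#' a warning.
#'
#' @param points Numeric matrix, one row per point.
#' @param enlarge Volume enlargement factor (>= 1).
#' @return List of class `ns_ellipsoid` with `center`, `cov` (the scaled
#'   covariance `A^{-1}`), `prec` (`A`), and the upper-triangular Cholesky
#'   factor `chol_cov` used for sampling.
#' @export
bounding_ellipsoid <- function(points, enlarge = 1) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), nrow(points) >= 1L, enlarge >= 1)
  d <- ncol(points)
  center <- colMeans(points)
  C <- if (nrow(points) > 1L) stats::cov(points) else matrix(0, d, d)
  scale0 <- mean(diag(C))
  jitter <- 1e-10 * max(1, sum(center^2))
  ok <- FALSE
  if (nrow(points) >= d + 1L && all(is.finite(C))) {
    ev <- tryCatch(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    ok <- all(ev > max(ev) * 1e-10) && min(ev) > 0
  }
  if (!ok) {
    warning("degenerate point cloud; ellipsoid shape matrix regularized",
            call. = FALSE)
    C <- C + diag(max(jitter, 1e-6 * scale0), d)
  }
  Cinv <- solve(C)
  centered <- sweep(points, 2L, center)
  f <- max(rowSums((centered %*% Cinv) * centered))   # max Mahalanobis^2
  f <- max(f, jitter)
  scale <- f * enlarge^(2 / d)
  cov_s <- C * scale
  structure(
    list(center = center, cov = cov_s, prec = Cinv / scale,
         chol_cov = chol(cov_s), dim = d),
    class = "ns_ellipsoid"
  )
}

#' @keywords internal
ellipsoid_contains <- function(e, x, tol = 1e-8) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  centered <- sweep(x, 2L, e$center)
  rowSums((centered %*% e$prec) * centered) <= 1 + tol
}

#' @keywords internal
ellipsoid_sample <- function(e, n) {
  d <- e$dim
  z <- matrix(stats::rnorm(n * d), n, d)
  z <- z / sqrt(rowSums(z^2))
  r <- stats::runif(n)^(1 / d)
  sweep((z * r) %*% e$chol_cov, 2L, e$center, "+")
}

logaddexp <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

#' Single-ellipsoid nested sampling
#'
#' Computes the Bayesian evidence `Z = integral of L over the prior` and
#' weighted posterior samples for a log-likelihood over a uniform box
#' prior. Live points are initialised from the prior; at each iteration
#' the lowest-likelihood point is retired under the deterministic
#' prior-volume shrinkage `X -> X exp(-1 / n_live)` with trapezoidal
#' quadrature weight `w_i = (X_{i-1} - X_{i+1}) / 2`, and replaced by a
#' point drawn uniformly inside the enlarged bounding ellipsoid of the
#' live set (rejection sampling, accepting only a strictly higher
#' likelihood than the retired point). Iteration stops when the
#' estimated remaining contribution `log(1 + L_max X / Z)` drops below
#' `dlogz`, after which the live points are absorbed with weight
#' `X / n_live` each.
#'
#' Exact likelihood ties among live points (plateaus, including the
#' `-Inf` region of a hard constraint) break the uniform
#' order-statistics argument behind exponential shrinkage, so tied
#' points are retired together as a block: `m` tied points among `n`
#' shrink the volume linearly, `X -> X (n - m) / n`, and share the
#' retired interval equally. This keeps evidence estimates unbiased for
#' step and top-hat likelihoods. `-Inf` log-likelihoods contribute zero
#' weight. If more than `1e4` consecutive ellipsoid draws are rejected,
#' the ellipsoid is re-fitted with a progressively larger enlargement.
#'
#' The statistical uncertainty is `logZ_err = sqrt(H / n_live)` with `H`
#' the information (nats).
#'
#' @param loglike Function of a named parameter vector returning a finite
#'   value or `-Inf`.
#' @param prior A [prior_box()].
#' @param config An [ns_config()]; `n_live` must be at least twice the
#'   number of parameters.
#' @return An object of class `ns_result`: `logZ`, `logZ_err`, `H`,
#'   `samples` (matrix of parameter vectors), `logwt` (unnormalized log
#'   weights `log(w_i L_i)`), `weights` (normalized, summing to 1),
#'   `summary` (per-parameter posterior mean and s.d.), `n_iter`,
#'   `n_call`, `converged`, `seed`, `config`.
#' @export
nested_sampling <- function(loglike, prior, config = ns_config()) {
  stopifnot(inherits(prior, "prior_box"), inherits(config, "ns_config"))
  d <- length(prior$names)
  n <- config$n_live
  if (n < 2L * d) {
    stop(sprintf("n_live = %d is below 2 x dimension (%d)", n, 2L * d),
         call. = FALSE)
  }
  set.seed(config$seed)

  eval_u <- function(u) loglike(prior$transform(u))

  u_live <- matrix(stats::runif(n * d), n, d)
  logl_live <- apply(u_live, 1L, eval_u)
  if (any(is.na(logl_live)) || any(logl_live == Inf)) {
    stop("log-likelihood must be finite or -Inf over the prior box",
         call. = FALSE)
  }
  n_call <- n

  cap <- 1024L
  dead_u <- matrix(NA_real_, cap, d)
  dead_logl <- numeric(cap)
  dead_logwt <- numeric(cap)

  logZ <- -Inf
  H <- 0
  logX <- 0
  i <- 0L
  converged <- TRUE
  ell <- NULL
  ell_age <- Inf
  refit_every <- max(5L, n %/% 10L)

  acc_point <- function(logwt, logl) {
    # incremental evidence/information update (closure over logZ, H)
    if (logwt == -Inf) return(invisible())
    logZ_new <- logaddexp(logZ, logwt)
    H <<- exp(logwt - logZ_new) * logl +
      (if (logZ > -Inf) exp(logZ - logZ_new) * (H + logZ) else 0) -
      logZ_new
    logZ <<- logZ_new
    invisible()
  }
  record_dead <- function(idx, logwt_each) {
    for (w in idx) {
      i <<- i + 1L
      if (i > cap) {
        cap <<- cap * 2L
        dead_u <<- rbind(dead_u, matrix(NA_real_, cap - nrow(dead_u), d))
        length(dead_logl) <<- cap
        length(dead_logwt) <<- cap
      }
      dead_u[i, ] <<- u_live[w, ]
      dead_logl[i] <<- logl_live[w]
      dead_logwt[i] <<- logwt_each
      acc_point(logwt_each, logl_live[w])
    }
  }

  repeat {
    logl_w <- min(logl_live)
    tied <- which(logl_live == logl_w)
    m <- length(tied)

    if (m == 1L) {
      # trapezoidal weight (X_prev - X_next-but-one) / 2 under the
      # deterministic exp(-1/n) schedule
      logX_new <- logX - 1 / n
      width <- 0.5 * (exp(logX) - exp(logX_new - 1 / n))
      logwt <- if (logl_w == -Inf) -Inf else log(width) + logl_w
      record_dead(tied, logwt)
      logX <- logX_new
    } else {
      # likelihood plateau: retire the block with linear shrinkage
      frac <- (n - m) / n
      width_each <- exp(logX) * (1 - frac) / m
      logwt <- if (logl_w == -Inf) -Inf else log(width_each) + logl_w
      record_dead(tied, logwt)
      logX <- if (frac > 0) logX + log(frac) else -Inf
    }

    pending <- tied   # retired but not yet replaced
    alive <- setdiff(seq_len(n), tied)
    logl_max <- if (length(alive)) max(logl_live[alive]) else -Inf
    if (logl_max == -Inf && logZ == -Inf) {
      stop("all live points have -Inf log-likelihood; prior box excludes ",
           "the support", call. = FALSE)
    }
    remain <- if (logX == -Inf || logl_max == -Inf) -Inf else logl_max + logX
    if (remain == -Inf) break
    done <- (logZ > -Inf) && (logaddexp(logZ, remain) - logZ < config$dlogz)
    if (done) break
    if (i >= config$max_iter) {
      converged <- FALSE
      warning("max_iter reached before dlogz termination; ",
              "result flagged non-converged", call. = FALSE)
      break
    }

    # replace the retired point(s); a stale ellipsoid is conservative
    # (live points only move inward), so refit only at intervals
    enlarge <- config$enlarge
    for (worst in tied) {
      if (ell_age >= refit_every) {
        ell <- bounding_ellipsoid(u_live, enlarge)
        ell_age <- 0L
      }
      rejected <- 0L
      found <- FALSE
      while (!found) {
        cand <- ellipsoid_sample(ell, 64L)
        in_cube <- rowSums(cand < 0 | cand > 1) == 0L
        for (j in which(in_cube)) {
          ll <- eval_u(cand[j, ])
          n_call <- n_call + 1L
          if (ll > logl_w) {
            u_live[worst, ] <- cand[j, ]
            logl_live[worst] <- ll
            found <- TRUE
            break
          }
          rejected <- rejected + 1L
        }
        rejected <- rejected + sum(!in_cube)
        if (!found && rejected > 10000L) {
          enlarge <- enlarge * 1.5
          ell <- bounding_ellipsoid(u_live, enlarge)
          ell_age <- 0L
          rejected <- 0L
        }
      }
      ell_age <- ell_age + 1L
      pending <- setdiff(pending, worst)
    }
  }

  # absorb the remaining live points (excluding any slot retired but not
  # replaced before termination) at the final prior volume
  live_idx <- setdiff(seq_len(n), pending)
  n_final <- length(live_idx)
  ord <- live_idx[order(logl_live[live_idx])]
  logwidth_live <- if (logX == -Inf || n_final == 0L) -Inf else
    logX - log(n_final)
  live_logwt <- ifelse(logl_live[ord] == -Inf | logwidth_live == -Inf, -Inf,
                       logwidth_live + logl_live[ord])
  for (k in seq_along(ord)) acc_point(live_logwt[k], logl_live[ord][k])

  u_all <- rbind(dead_u[seq_len(i), , drop = FALSE],
                 u_live[ord, , drop = FALSE])
  logl_all <- c(dead_logl[seq_len(i)], logl_live[ord])
  logwt_all <- c(dead_logwt[seq_len(i)], live_logwt)
  keep <- logwt_all > -Inf
  samples <- prior$transform(u_all)
  w <- exp(logwt_all - logZ)
  w[!keep] <- 0
  w <- w / sum(w)

  post_mean <- colSums(samples * w)
  post_var <- colSums(sweep(samples, 2L, post_mean)^2 * w)
  summary <- data.frame(
    parameter = prior$names,
    mean = unname(post_mean),
    sd = unname(sqrt(pmax(post_var, 0))),
    row.names = NULL
  )

  structure(
    list(logZ = logZ, logZ_err = sqrt(max(H, 0) / n), H = H,
         samples = samples, loglike = logl_all, logwt = logwt_all,
         weights = w, summary = summary, n_iter = i, n_call = n_call,
         converged = converged, seed = config$seed, config = config),
    class = "ns_result"
  )
}

#' @export
print.ns_result <- function(x, ...) {
  cat(sprintf("Nested sampling result (%s)\n",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  logZ = %.4f +/- %.4f   H = %.3f nats   iterations = %d\n",
              x$logZ, x$logZ_err, x$H, x$n_iter))
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4g +/- %.3g\n", s$parameter[k], s$mean[k], s$sd[k]))
  }
  invisible(x)
}

#' Importance-weighted posterior summary
#'
#' Per-parameter posterior mean, standard deviation, median and central
#' 95% credible interval computed from the weighted nested-sampling
#' samples.
#'
#' @param r A converged [nested_sampling()] result.
#' @return A data frame with columns `parameter`, `mean`, `sd`, `median`,
#'   `q025`, `q975`.
#' @export
posterior_summary <- function(r) {
  stopifnot(inherits(r, "ns_result"))
  if (!r$converged) stop("result is flagged non-converged", call. = FALSE)
  qs <- t(vapply(seq_along(r$summary$parameter), function(k) {
    weighted_quantile(r$samples[, k], r$weights, c(0.025, 0.5, 0.975))
  }, numeric(3)))
  out <- r$summary
  out$median <- qs[, 2]
  out$q025 <- qs[, 1]
  out$q975 <- qs[, 3]
  out
}

#' Weighted quantiles of a sample
#'
#' Quantiles of `x` under normalized weights `w`, by inversion of the
#' weighted empirical CDF (no interpolation beyond adjacent order
#' statistics).
#'
#' @param x Numeric vector.
#' @param w Non-negative weights (normalized internally).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Effective sample size of a weighted posterior
#'
#' Kish effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param r An `ns_result`.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(r) {
  stopifnot(inherits(r, "ns_result"))
  sum(r$weights)^2 / sum(r$weights^2)
}

#' Bayes factor from two nested-sampling runs
#'
#' `exp(logZ_a - logZ_b)`, with the uncertainty of the log Bayes factor
#' propagated as the root sum of squares of the two `logZ_err` values,
#' and a qualitative label on the Jeffreys scale.
#'
#' @param a,b Converged [nested_sampling()] results (numerator and
#'   denominator models).
#' @return Object of class `bayes_factor` with fields `value`,
#'   `log_value`, `se_log`, `label`.
#' @export
bayes_factor <- function(a, b) {
  stopifnot(inherits(a, "ns_result"), inherits(b, "ns_result"))
  if (!a$converged || !b$converged) {
    stop("Bayes factors require converged runs", call. = FALSE)
  }
  lv <- a$logZ - b$logZ
  structure(
    list(value = exp(lv), log_value = lv,
         se_log = sqrt(a$logZ_err^2 + b$logZ_err^2),
         label = jeffreys_label(exp(lv))),
    class = "bayes_factor"
  )
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Bayes factor = %.3g (log = %.3f +/- %.3f): %s\n",
              x$value, x$log_value, x$se_log, x$label))
  invisible(x)
}

#' Jeffreys-scale label for a Bayes factor
#'
#' Categorises the strength of evidence for the numerator model:
#' `|log10 BF| < 0.5` is "weak" (barely worth mentioning) either way,
#' then "substantial", "strong", "very strong" and "decisive" at
#' half-decade steps, suffixed with the favoured side.
#'
#' @param bf Positive Bayes factor (numerator / denominator).
#' @return Character label.
#' @export
jeffreys_label <- function(bf) {
  stopifnot(bf > 0)
  l <- abs(log10(bf))
  grade <- if (l < 0.5) "weak" else if (l < 1) "substantial" else
    if (l < 1.5) "strong" else if (l < 2) "very strong" else "decisive"
  side <- if (l < 0.5) "either way" else
    if (bf > 1) "for numerator model" else "for denominator model"
  paste0(grade, " evidence (", side, ")")
}
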