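#' Extract clade-informative counts from a sample
#'
#' For every barcode position of the clade: `x` = reads carrying the
#' clade-specific allele (both strands summed), `y` = reads carrying any
#' allele at the position.  Barcode positions absent from the sample matrix
#' contribute `x = y = 0`.
#'
#' @param sample an [allele_counts] object for one metagenomic sample
#'   (single sample row), aligned to the same reference assembly as `db`.
#' @param db a `reference_db`.
#' @param clade_id one of `db$clades$clade_id`.
#' @return list with `clade_id`, `positions`, `x`, `y`, and `n_missing`
#'   (barcode positions not present in the sample matrix).
#' @export
extract_informative_counts <- function(sample, db, clade_id) {
  if (length(sample$sample_ids) != 1L) {
    stop("expected a single-sample allele_counts object")
  }
  bc <- db$barcodes[[clade_id]]
  if (is.null(bc)) stop("unknown clade: ", clade_id)
  pi <- match(bc$position, sample$positions)
  present <- !is.na(pi)
  x <- numeric(nrow(bc))
  y <- numeric(nrow(bc))
  if (any(present)) {
    cnt <- sample$counts[1L, pi[present], , , drop = FALSE]
    tot <- matrix(cnt, nrow = sum(present))  # positions x 8
    y[present] <- rowSums(tot)
    ai <- match(bc$allele[present], NUCLEOTIDES)
    n_present <- sum(present)
    x[present] <- tot[cbind(seq_len(n_present), ai)] +
      tot[cbind(seq_len(n_present), ai + 4L)]
  }
  list(clade_id = clade_id, positions = bc$position, x = x, y = y,
       n_missing = sum(!present))
}

#' Fit the all-allele depth model and derive the dispersion prior
#'
#' Step one of the two-step model: read depth across all alleles at the
#' clade's informative positions is fit as an ordinary negative binomial
#' (mean `lambda_all`, dispersion shape `alpha_all`, variance
#' `lambda + lambda^2 / alpha`).  The prior over the clade-specific
#' dispersion is `Gamma(a, b = 1)` (shape-rate) with
#' `a = mean(y) / (var(y) - mean(y))`; when the depths are not overdispersed
#' (`var <= mean`) a weakly-informative wide prior is substituted and
#' flagged.
#'
#' @param y depth vector (length >= 2).
#' @param classical_shape use the classical method-of-moments shape
#'   `mean^2 / (var - mean)` instead of the default `mean / (var - mean)`
#'   (default `FALSE`).
#' @return list with `lambda_all`, `alpha_all`, and `prior` (list: `a`, `b`,
#'   `fallback` flag).
#' @export
fit_all_alleles <- function(y, classical_shape = FALSE) {
  if (length(y) < 2L) stop("need at least 2 positions to fit depths")
  if (all(y == 0)) {
    stop("no coverage: all-allele depths are uniformly zero")
  }
  ybar <- mean(y)
  s2 <- stats::var(y)
  if (s2 > ybar) {
    a <- if (classical_shape) ybar^2 / (s2 - ybar) else ybar / (s2 - ybar)
    prior <- list(a = a, b = 1, fallback = FALSE)
  } else {
    # near-Poisson depths: wide prior permitting large dispersion shapes
    prior <- list(a = 2, b = 0.02, fallback = TRUE)
  }
  fit <- nb_mle(y)
  list(lambda_all = fit$mu, alpha_all = fit$size, prior = prior)
}

# Negative-binomial MLE (mean/shape parameterization) with moment start.
nb_mle <- function(y) {
  ybar <- mean(y)
  s2 <- stats::var(y)
  if (s2 <= ybar || ybar == 0) {
    # effectively Poisson (or degenerate): return a large finite shape
    return(list(mu = ybar, size = 1e6))
  }
  start <- c(log(ybar), log(max(ybar^2 / (s2 - ybar), 1e-3)))
  nll <- function(p) {
    -sum(stats::dnbinom(y, mu = exp(p[1]), size = exp(p[2]), log = TRUE))
  }
  opt <- tryCatch(stats::optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(opt)) return(list(mu = ybar, size = ybar^2 / (s2 - ybar)))
  list(mu = exp(opt$par[1]), size = min(exp(opt$par[2]), 1e6))
}

# Collapse a count vector to unique values with multiplicities; informative
# positions share few distinct depths, which makes likelihood evaluations
# O(unique) instead of O(n).
weighted_counts <- function(x) {
  tab <- table(x)
  list(v = as.numeric(names(tab)), w = as.numeric(tab))
}

# Zero-inflated NB log-likelihood.  x: counts; pi in [0,1]; NB has mean
# lambda and shape alpha.
zinb_loglik <- function(x, pi, lambda, alpha) {
  wc <- weighted_counts(x)
  zinb_loglik_w(wc$v, wc$w, pi, lambda, alpha)
}

zinb_loglik_w <- function(v, w, pi, lambda, alpha) {
  p0 <- stats::dnbinom(0, size = alpha, mu = lambda)
  zero <- v == 0
  sum(w[zero]) * log(pi + (1 - pi) * p0) +
    sum(w[!zero] * (log1p(-pi) +
                      stats::dnbinom(v[!zero], size = alpha, mu = lambda,
                                     log = TRUE)))
}

# Univariate stepping-out + shrinkage slice sampler (Neal 2003).  The
# domain is hard-bounded to |x| <= bound (log-scale parameters: e^20 spans
# any realistic depth or dispersion) so that flat conditionals cannot drift
# into numerically undefined territory.
slice_sample_1d <- function(x0, log_target_raw, w = 1, max_steps = 30,
                            bound = 20) {
  log_target <- function(t) {
    if (abs(t) > bound) return(-Inf)
    v <- log_target_raw(t)
    if (is.finite(v)) v else -Inf
  }
  f0 <- log_target(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  logy <- f0 + log(stats::runif(1))
  u <- stats::runif(1)
  L <- x0 - u * w
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && log_target(L) > logy) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && log_target(R) > logy) {
    R <- R + w
    k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (log_target(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

#' Fit the zero-inflated model by Slice-within-Gibbs sampling
#'
#' The generative model per informative position i:
#' `x_i ~ Poisson(lambda_i * z_i)`, `z_i ~ Bernoulli(1 - pi)`,
#' `lambda_i ~ Gamma(alpha, beta)` with `beta = alpha / lambda`, so that
#' marginally `x_i | z_i = 1` is negative binomial with mean `lambda` and
#' variance `lambda + lambda^2 / alpha`.  The latent `z_i` are updated from
#' their exact Bernoulli full conditionals with `lambda_i` marginalized;
#' `pi` from its conjugate Beta full conditional under a `Beta(1, 1)` prior;
#' `lambda` and `alpha` by stepping-out slice sampling on the log scale,
#' with the step-one dispersion prior `Gamma(a, b)` applied to `alpha` and a
#' scale-invariant (flat on log) prior on `lambda`.
#'
#' @param ic informative counts from [extract_informative_counts()], or any
#'   list with elements `x` and `y`.
#' @param prior dispersion prior (list `a`, `b`) from [fit_all_alleles()].
#' @param steps chain length (default 10000).
#' @param burnin_frac fraction of the chain discarded (default 0.10).
#' @param seed integer seed; identical seeds and inputs give bit-identical
#'   draws.
#' @param min_supporting inference proceeds only when strictly more than
#'   this many positions have at least one clade-allele read (default 10);
#'   otherwise the fit is returned with status `"no_call"`.
#' @param lambda_all,alpha_all step-one estimates carried into the fit
#'   record (optional; filled by [classify_sample()]).
#' @param lambda_sdlog standard deviation (log scale) of the diffuse
#'   lognormal prior over `lambda`, centred on `lambda_all` (default 2).
#'   When no positive `lambda_all` is available the prior on `log(lambda)`
#'   is flat.  The prior is negligible against any informative data but
#'   keeps the posterior proper when every clade-allele count is zero,
#'   where depth-zero and clade-absence are otherwise confounded.
#' @return An object of class `clade_fit` with posterior draws (matrix with
#'   columns `pi`, `lambda`, `alpha`), MAP values, the 95% HPD interval over
#'   `pi`, convergence diagnostics, and metadata.
#' @export
fit_zinb_gibbs <- function(ic, prior, steps = 10000, burnin_frac = 0.10,
                           seed = NULL, min_supporting = 10,
                           lambda_all = NA_real_, alpha_all = NA_real_,
                           lambda_sdlog = 2) {
  x <- ic$x
  n <- length(x)
  n_supporting <- sum(x >= 1)
  base <- clade_fit_skeleton(ic, "gibbs", lambda_all, alpha_all, prior, seed)
  if (n_supporting <= min_supporting) {
    base$status <- "no_call"
    return(base)
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- steps - floor(steps * burnin_frac)
  draws <- matrix(NA_real_, keep, 3,
                  dimnames = list(NULL, c("pi", "lambda", "alpha")))
  pi_cur <- 0.5
  xs <- x[x >= 1]
  lambda <- if (length(xs) > 0L) max(mean(xs), 0.1) else 0.5
  alpha <- min(max(prior$a / prior$b, 0.1), 100)
  zero <- x == 0
  xpos <- x[!zero]
  n_nonzero <- length(xpos)
  z_zero <- rep(TRUE, sum(zero))  # z for the zero-count positions
  x_zero_n <- sum(zero)
  wc <- weighted_counts(xpos)  # fixed across iterations
  lam_prior <- if (is.finite(lambda_all) && lambda_all > 0) {
    function(lt) stats::dnorm(lt, log(lambda_all), lambda_sdlog, log = TRUE)
  } else {
    function(lt) 0
  }
  ll_lambda <- function(lt, alpha, nz0) {
    # nz0 zero-count positions currently assigned z = 1
    l <- exp(lt)
    sum(wc$w * stats::dnbinom(wc$v, size = alpha, mu = l, log = TRUE)) +
      nz0 * stats::dnbinom(0, size = alpha, mu = l, log = TRUE) +
      lam_prior(lt)
  }
  ll_alpha <- function(at, lambda, nz0) {
    a <- exp(at)
    sum(wc$w * stats::dnbinom(wc$v, size = a, mu = lambda, log = TRUE)) +
      nz0 * stats::dnbinom(0, size = a, mu = lambda, log = TRUE) +
      stats::dgamma(a, shape = prior$a, rate = prior$b, log = TRUE) + at
  }
  for (s in seq_len(steps)) {
    # z | rest (zero-count positions only; x > 0 forces z = 1)
    p_nb0 <- stats::dnbinom(0, size = alpha, mu = lambda)
    p1 <- (1 - pi_cur) * p_nb0
    prob_z1 <- p1 / (pi_cur + p1)
    z_zero <- stats::runif(x_zero_n) < prob_z1
    nz0 <- sum(z_zero)           # zero-count positions with z = 1
    n0 <- x_zero_n - nz0         # systematically-absent positions
    # pi | z  (Beta(1,1) prior)
    pi_cur <- stats::rbeta(1, 1 + n0, 1 + n_nonzero + nz0)
    # lambda | z, alpha (slice on log scale)
    lt <- slice_sample_1d(log(lambda),
                          function(t) ll_lambda(t, alpha, nz0), w = 1)
    lambda <- exp(lt)
    # alpha | z, lambda (slice on log scale, Gamma prior)
    at <- slice_sample_1d(log(alpha),
                          function(t) ll_alpha(t, lambda, nz0), w = 1)
    alpha <- exp(at)
    k <- s - (steps - keep)
    if (k >= 1L) draws[k, ] <- c(pi_cur, lambda, alpha)
  }
  base$status <- "ok"
  base$draws <- draws
  base$map <- c(pi = density_mode(draws[, "pi"], 0, 1),
                lambda = density_mode(draws[, "lambda"]),
                alpha = density_mode(draws[, "alpha"]))
  base$hpd_pi <- hpd_interval(draws[, "pi"])
  rhat <- split_rhat(draws[, "pi"])
  base$rhat_pi <- rhat
  if (is.finite(rhat) && rhat > 1.1) {
    base$warnings <- c(base$warnings,
                       sprintf("non-convergent chain: split-Rhat(pi) = %.3f",
                               rhat))
  }
  base
}

clade_fit_skeleton <- function(ic, method, lambda_all, alpha_all, prior,
                               seed) {
  structure(list(
    clade_id = ic$clade_id %||% NA_character_,
    method = method, status = "ok",
    n_positions = length(ic$x), n_supporting = sum(ic$x >= 1),
    draws = NULL, pi_grid = NULL, pi_weight = NULL,
    map = c(pi = NA_real_, lambda = NA_real_, alpha = NA_real_),
    hpd_pi = c(lower = NA_real_, upper = NA_real_),
    lambda_all = lambda_all, alpha_all = alpha_all,
    prior = prior, seed = seed, rhat_pi = NA_real_,
    warnings = character(0)), class = "clade_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.clade_fit <- function(x, ...) {
  cat("clade_fit [", x$method, "] ", x$clade_id, ": status = ", x$status,
      sep = "")
  if (x$status == "ok") {
    cat(sprintf("; pi MAP = %.3f [%.3f, %.3f], lambda = %.2f",
                x$map["pi"], x$hpd_pi[1], x$hpd_pi[2], x$map["lambda"]))
  }
  cat("\n")
  invisible(x)
}

# Mode of a posterior sample via kernel density (bounded support optional).
density_mode <- function(draws, from = NULL, to = NULL) {
  if (length(unique(draws)) == 1L) return(draws[1])
  d <- if (is.null(from)) {
    stats::density(draws)
  } else {
    stats::density(draws, from = from, to = to)
  }
  d$x[which.max(d$y)]
}

# Split-chain potential scale reduction on a single chain.
split_rhat <- function(v) {
  n <- floor(length(v) / 2)
  if (n < 2) return(NA_real_)
  halves <- list(v[1:n], v[(n + 1):(2 * n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the zero-inflated model by penalized maximum likelihood
#'
#' Maximizes the ZINB likelihood with the step-one dispersion prior applied
#' as a penalty on `alpha` (preserving the two-step information flow;
#' `prior = NULL` gives the unconstrained fit used as a baseline in the
#' recovery experiments).  The
#' detection quantities normally read off the posterior are derived from the
#' normalized profile likelihood over a grid of `pi` values, which stands in
#' for the posterior density (profile-likelihood interval in place of HPD).
#'
#' @inheritParams fit_zinb_gibbs
#' @param grid_points number of `pi` grid points for the profile (default
#'   51).
#' @return a `clade_fit` with `pi_grid` / `pi_weight` in place of draws.
#' @export
fit_zinb_mle <- function(ic, prior, min_supporting = 10, grid_points = 51,
                         lambda_all = NA_real_, alpha_all = NA_real_,
                         lambda_sdlog = 2) {
  x <- ic$x
  base <- clade_fit_skeleton(ic, "mle", lambda_all, alpha_all, prior, NULL)
  if (base$n_supporting <= min_supporting) {
    base$status <- "no_call"
    return(base)
  }
  xs <- x[x >= 1]
  lam0 <- if (length(xs) > 0L) max(mean(xs), 0.1) else 0.5
  alpha0 <- if (is.null(prior)) 5 else
    min(max(prior$a / prior$b, 0.1), 100)
  penalty <- if (is.null(prior)) {
    function(alpha) 0  # unconstrained fit: no dispersion prior
  } else {
    # log-scale prior density (Jacobian included), matching the sampler's
    # parameterization; keeps the penalty bounded when the prior shape < 1
    function(alpha) {
      stats::dgamma(alpha, shape = prior$a, rate = prior$b, log = TRUE) +
        log(alpha)
    }
  }
  lam_prior <- if (is.finite(lambda_all) && lambda_all > 0) {
    function(lt) stats::dnorm(lt, log(lambda_all), lambda_sdlog, log = TRUE)
  } else {
    function(lt) 0
  }
  wc <- weighted_counts(x)
  nll <- function(p) {
    pi <- stats::plogis(p[1])
    -(zinb_loglik_w(wc$v, wc$w, pi, exp(p[2]), exp(p[3])) +
        penalty(exp(p[3])) + lam_prior(p[2]))
  }
  best <- NULL
  for (pi_start in c(0.05, 0.5, 0.95)) {
    opt <- tryCatch(
      stats::optim(c(stats::qlogis(pi_start), log(lam0), log(alpha0)), nll,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    # coarse grid fallback
    grid <- expand.grid(pi = seq(0.01, 0.99, length.out = 15),
                        lambda = lam0 * c(0.25, 0.5, 1, 2, 4),
                        alpha = alpha0 * c(0.2, 1, 5))
    vals <- mapply(function(p, l, a) {
      zinb_loglik_w(wc$v, wc$w, p, l, a) + penalty(a) + lam_prior(log(l))
    }, grid$pi, grid$lambda, grid$alpha)
    i <- which.max(vals)
    est <- c(pi = grid$pi[i], lambda = grid$lambda[i], alpha = grid$alpha[i])
    base$warnings <- c(base$warnings, "optimizer failure: coarse-grid fit")
  } else {
    est <- c(pi = stats::plogis(best$par[1]), lambda = exp(best$par[2]),
             alpha = exp(best$par[3]))
  }
  # profile likelihood over pi
  grid <- seq(0, 1, length.out = grid_points)
  pl <- numeric(grid_points)
  p_prev <- c(log(est["lambda"]), log(est["alpha"]))
  nll2 <- function(p, pi) {
    -(zinb_loglik_w(wc$v, wc$w, pi, exp(p[1]), exp(p[2])) +
        penalty(exp(p[2])) + lam_prior(p[1]))
  }
  for (i in seq_len(grid_points)) {
    pi_i <- min(max(grid[i], 0), 1 - 1e-12)
    o <- tryCatch(stats::optim(p_prev, nll2, pi = pi_i,
                               method = "Nelder-Mead",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o)) {
      pl[i] <- -Inf
    } else {
      pl[i] <- -o$value
      p_prev <- o$par
    }
  }
  w <- exp(pl - max(pl))
  w <- w / sum(w)
  base$status <- "ok"
  base$pi_grid <- grid
  base$pi_weight <- w
  base$map <- est
  base$hpd_pi <- grid_hpd(grid, w, 0.95)
  base
}

# Shortest contiguous grid window holding at least `mass` of the weight.
grid_hpd <- function(grid, w, mass = 0.95) {
  n <- length(grid)
  cs <- c(0, cumsum(w))
  best <- c(grid[1], grid[n])
  best_len <- Inf
  for (i in seq_len(n)) {
    j <- i
    while (j <= n && cs[j + 1] - cs[i] < mass) j <- j + 1
    if (j > n) break
    len <- grid[j] - grid[i]
    if (len < best_len) {
      best_len <- len
      best <- c(grid[i], grid[j])
    }
  }
  c(lower = best[1], upper = best[2])
}

#' Highest posterior density interval from draws
#'
#' Empirical sorted-window method: the shortest interval between order
#' statistics containing the stated mass.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval mass (default 0.95).
#' @return named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HPD interval")
  s <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k - 1])
}

#' Posterior mass of pi below a threshold
#'
#' @param fit a `clade_fit`.
#' @param thresh threshold on pi.
#' @return fraction of posterior (or normalized profile-likelihood) mass
#'   strictly below `thresh`.
#' @export
pi_mass_below <- function(fit, thresh) {
  if (!is.null(fit$draws)) {
    mean(fit$draws[, "pi"] < thresh)
  } else if (!is.null(fit$pi_weight)) {
    sum(fit$pi_weight[fit$pi_grid < thresh])
  } else {
    NA_real_
  }
}

#' Relative abundance of a clade
#'
#' The ratio of the MAP clade-specific depth to the MAP all-allele depth.
#' May exceed 1 through sampling noise; capping happens at the profile
#' level, not here.
#'
#' @param fit a `clade_fit` with `lambda_all` available.
#' @return fraction, or `NA` (no-call) when `lambda_all` is zero or missing.
#' @export
relative_abundance <- function(fit) {
  lam_cs <- unname(fit$map["lambda"])
  lam_all <- fit$lambda_all
  if (is.na(lam_all) || lam_all == 0) return(NA_real_)
  if (is.na(lam_cs)) return(NA_real_)
  lam_cs / lam_all
}

#' Detection decision for one clade
#'
#' A clade is detected when the fraction of the pi posterior below
#' `d_thresh` is at least `p_frac`, the lower bound of the 95% HPD interval
#' over pi is below `hpd_low_max`, and the relative abundance is at least
#' `min_abundance`.
#'
#' @param fit a `clade_fit`.
#' @param d_thresh divergence threshold on pi (default 0.35).
#' @param p_frac required posterior mass below `d_thresh` (default 0.50).
#' @param hpd_low_max ceiling on the HPD lower bound (default 0.10,
#'   strict `<`).
#' @param min_abundance abundance floor (default 0.01, `>=` passes).
#' @param abundance relative abundance (default computed from `fit`).
#' @return logical detection flag (`FALSE` for non-`"ok"` fits).
#' @export
decide_detection <- function(fit, d_thresh = 0.35, p_frac = 0.50,
                             hpd_low_max = 0.10, min_abundance = 0.01,
                             abundance = relative_abundance(fit)) {
  if (fit$status != "ok") return(FALSE)
  mass <- pi_mass_below(fit, d_thresh)
  isTRUE(mass >= p_frac) &&
    isTRUE(unname(fit$hpd_pi["lower"]) < hpd_low_max) &&
    isTRUE(abundance >= min_abundance)
}

#' Classify one metagenomic sample against a reference database
#'
#' Runs the two-step model for every clade: the all-allele negative-binomial
#' fit, then the zero-inflated clade-specific fit (Gibbs or penalized MLE),
#' detection, and relative abundance; finally normalizes each hierarchical
#' level (see [normalize_profile()]).
#'
#' @param sample a single-sample [allele_counts] object.
#' @param db a `reference_db`.
#' @param method `"mle"` (fast, default) or `"gibbs"`.
#' @param steps,burnin_frac Gibbs chain parameters (defaults 10000 / 0.10).
#' @param seed integer seed; each clade uses a sub-seed derived from it.
#' @param d_thresh,p_frac,hpd_low_max,min_abundance detection thresholds,
#'   see [decide_detection()].
#' @param min_supporting see [fit_zinb_gibbs()].
#' @param keep_fits attach the list of `clade_fit` objects as an attribute
#'   (default `FALSE`).
#' @return a `sample_profile`: data.frame with one row per clade (columns
#'   `clade`, `level`, `detected`, `relative_abundance`, `pi_map`,
#'   `pi_hpd_low`, `pi_hpd_high`, `n_informative_positions`,
#'   `n_supporting`, `status`, `flags`), with a `levels` attribute holding
#'   per-level classified/unclassified fractions.
#' @export
classify_sample <- function(sample, db, method = c("mle", "gibbs"),
                            steps = 10000, burnin_frac = 0.10, seed = NULL,
                            d_thresh = 0.35, p_frac = 0.50,
                            hpd_low_max = 0.10, min_abundance = 0.01,
                            min_supporting = 10, keep_fits = FALSE) {
  method <- match.arg(method)
  clade_ids <- db$clades$clade_id
  fits <- vector("list", length(clade_ids))
  names(fits) <- clade_ids
  rows <- vector("list", length(clade_ids))
  for (i in seq_along(clade_ids)) {
    id <- clade_ids[i]
    ic <- extract_informative_counts(sample, db, id)
    fit <- if (all(ic$y == 0)) {
      f <- clade_fit_skeleton(ic, method, NA_real_, NA_real_, NULL, seed)
      f$status <- "no_coverage"
      f
    } else {
      step1 <- fit_all_alleles(ic$y)
      sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
      if (method == "gibbs") {
        fit_zinb_gibbs(ic, step1$prior, steps = steps,
                       burnin_frac = burnin_frac, seed = sub_seed,
                       min_supporting = min_supporting,
                       lambda_all = step1$lambda_all,
                       alpha_all = step1$alpha_all)
      } else {
        fit_zinb_mle(ic, step1$prior, min_supporting = min_supporting,
                     lambda_all = step1$lambda_all,
                     alpha_all = step1$alpha_all)
      }
    }
    fits[[i]] <- fit
    ra <- relative_abundance(fit)
    det <- decide_detection(fit, d_thresh = d_thresh, p_frac = p_frac,
                            hpd_low_max = hpd_low_max,
                            min_abundance = min_abundance, abundance = ra)
    flags <- character(0)
    if (!is.null(fit$prior) && isTRUE(fit$prior$fallback)) {
      flags <- c(flags, "wide_prior")
    }
    if (ic$n_missing > 0L) flags <- c(flags, "missing_positions")
    flags <- c(flags, fit$warnings)
    rows[[i]] <- data.frame(
      clade = id, level = db$clades$level[i], detected = det,
      relative_abundance = if (is.na(ra)) 0 else ra,
      pi_map = unname(fit$map["pi"]),
      pi_hpd_low = unname(fit$hpd_pi["lower"]),
      pi_hpd_high = unname(fit$hpd_pi["upper"]),
      n_informative_positions = fit$n_positions,
      n_supporting = fit$n_supporting,
      status = fit$status,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, rows)
  class(profile) <- c("sample_profile", "data.frame")
  attr(profile, "params") <- list(
    method = method, steps = steps, burnin_frac = burnin_frac, seed = seed,
    d_thresh = d_thresh, p_frac = p_frac, hpd_low_max = hpd_low_max,
    min_abundance = min_abundance, min_supporting = min_supporting)
  if (keep_fits) attr(profile, "fits") <- fits
  normalize_profile(profile)
}

#' Normalize a sample profile per hierarchical level
#'
#' Clade abundances are estimated independently and may sum above 1 at a
#' level through sampling noise; such levels are scaled down so detected
#' abundances sum to exactly 1.  Levels summing to at most 1 are untouched:
#' the shortfall is the unclassified (novel) fraction.
#'
#' @param profile a `sample_profile`.
#' @return the profile with abundances normalized and a refreshed `levels`
#'   attribute (data.frame: `level`, `classified`, `unclassified`).
#' @export
normalize_profile <- function(profile) {
  if (nrow(profile) == 0L) {
    attr(profile, "levels") <-
      data.frame(level = integer(0), classified = numeric(0),
                 unclassified = numeric(0))
    return(profile)
  }
  for (lv in unique(profile$level)) {
    sel <- profile$level == lv & profile$detected
    s <- sum(profile$relative_abundance[sel])
    if (s > 1) {
      scale_sel <- profile$level == lv
      profile$relative_abundance[scale_sel] <-
        profile$relative_abundance[scale_sel] / s
    }
  }
  lv_tab <- do.call(rbind, lapply(sort(unique(profile$level)), function(lv) {
    cl <- sum(profile$relative_abundance[profile$level == lv &
                                           profile$detected])
    data.frame(level = lv, classified = cl,
               unclassified = max(0, 1 - cl))
  }))
  attr(profile, "levels") <- lv_tab
  profile
}

#' Write a sample profile as TSV
#'
#' Metadata (tool version, resolved parameters, seed) is embedded as
#' `#`-prefixed header lines.
#'
#' @param profile a `sample_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  par <- attr(profile, "params")
  writeLines(paste0("# cladecall ",
                    as.character(utils::packageVersion("cladecall"))), con)
  if (!is.null(par)) {
    writeLines(paste0("# ", names(par), "=",
                      vapply(par, function(v) {
                        if (is.null(v)) "NA" else as.character(v)
                      }, "")), con)
  }
  utils::write.table(profile, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
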