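# Bayesian estimation of the exclusion-energy observation model by adaptive
# Metropolis-within-Gibbs: global parameters are updated one at a time by
# random-walk Metropolis, per-pixel SQREs by a vectorised simultaneous
# Metropolis sweep (each pixel's likelihood factorises given the globals).
# Adaptation targets standard acceptance rates and is frozen after burn-in
# to preserve detailed balance.

#' Uniform prior specification
#'
#' All parameters carry independent uniform priors. The SQRE interval
#' `[0, e_max]` with `e_max = 5` (energies to 25 kT) is wide enough to be
#' uninformative relative to the few-kT energies seen in synapses.
#'
#' @param e_max Upper bound of the per-pixel SQRE priors, kT^1/2.
#' @param mu_max,A_max Upper bounds for the free-surface means and the
#'   complex amplitude, counts; `NULL` defers to 10x the data maximum.
#' @param alpha_bounds,beta_bounds Bounds for the constrained-fit regression
#'   intercept and slope magnitude.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(e_max = 5, mu_max = NULL, A_max = NULL,
                       alpha_bounds = c(0.01, 5), beta_bounds = c(0.02, 3)) {
  stopifnot(e_max > 0, alpha_bounds[1] < alpha_bounds[2],
            beta_bounds[1] < beta_bounds[2])
  structure(list(e_max = e_max, mu_max = mu_max, A_max = A_max,
                 alpha_bounds = alpha_bounds, beta_bounds = beta_bounds),
            class = "prior_spec")
}

# Family log-likelihood kernels with count-only constants dropped (valid in
# Metropolis ratios; full likelihood lives in pixel_loglik()).
ll_kernel <- function(family, dispersion) {
  switch(family,
    poisson = function(x, m) x * log(m) - m,
    gaussian = function(x, m) -0.5 * log(m) - (x - m)^2 / (2 * dispersion * m),
    gamma = function(x, m) -dispersion * log(m) - dispersion * pmax(x, 0.5) / m)
}

reflect <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + pmin(y, 2 * r - y)
}

#' Fit the exclusion-energy model to a two-colour image by MCMC
#'
#' The core fitting function. In `"unconstrained"` mode every
#' contact-interface pixel carries an independent pair of SQREs
#' `(e_C, e_I)`; the fitted object includes a precision-weighted total
#' least-squares line through the posterior-mean SQREs, which is the test of
#' the predicted linear relation. In `"constrained"` mode the linear
#' relation is imposed: the regression parameters `(alpha, beta)` are
#' estimated along with one latent `e_C` per pixel and
#' `e_I = max(0, alpha - beta e_C)` (energies clamped non-negative past the
#' line's zero crossing).
#'
#' Global parameters estimated: `mu_fs_small`, `mu_fs_long`, `A_B`,
#' `Gamma_barrier` (plus `alpha`, `beta` when constrained). Backgrounds and
#' the noise dispersion are taken as known from `spec` (measured off-cell /
#' fixed by the family).
#'
#' @param image A [two_channel_image()].
#' @param masks A [region_masks()]; at least 50 pixels per region.
#' @param spec A [fluor_spec()] template: supplies the noise family,
#'   dispersion and backgrounds, and initial values for the estimated
#'   globals.
#' @param mode `"unconstrained"` or `"constrained"`.
#' @param priors A [prior_spec()].
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Sweeps per chain.
#' @param burn Burn-in sweeps discarded (default half).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `"sqre_fit"`.
#' @export
sqre_fit <- function(image, masks, spec = fluor_spec(),
                     mode = c("unconstrained", "constrained"),
                     priors = prior_spec(), n_chains = 2,
                     n_iter = 3000, burn = floor(n_iter / 2), seed = 1,
                     estimate_barrier = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "two_channel_image"),
            inherits(masks, "region_masks"),
            inherits(spec, "fluor_spec"), inherits(priors, "prior_spec"),
            n_chains >= 1, n_iter > burn)
  ci <- masks$contact_interface; fs <- masks$free_surface
  n_ci <- sum(ci); n_fs <- sum(fs)
  if (n_ci < 50 || n_fs < 50)
    stop(sprintf("under-identified input: %d contact-interface and %d ",
                 n_ci, n_fs),
         "free-surface pixels (need >= 50 of each)")
  dat <- list(Fs_ci = as.numeric(image$small[ci]),
              Fl_ci = as.numeric(image$long[ci]),
              Fs_fs = as.numeric(image$small[fs]),
              Fl_fs = as.numeric(image$long[fs]))
  cmax <- max(unlist(dat))
  mu_max <- if (is.null(priors$mu_max)) 10 * cmax else priors$mu_max
  A_max <- if (is.null(priors$A_max)) 10 * cmax else priors$A_max

  if (estimate_barrier) {
    g_names <- c("mu_fs_small", "mu_fs_long", "A_B", "Gamma_barrier")
    lo <- c(1e-3, 1e-3, 0, 1e-3)
    hi <- c(mu_max, mu_max, A_max, 1)
  } else {
    g_names <- c("mu_fs_small", "mu_fs_long", "A_B")
    lo <- c(1e-3, 1e-3, 0)
    hi <- c(mu_max, mu_max, A_max)
  }
  if (mode == "constrained") {
    g_names <- c(g_names, "alpha", "beta")
    lo <- c(lo, priors$alpha_bounds[1], priors$beta_bounds[1])
    hi <- c(hi, priors$alpha_bounds[2], priors$beta_bounds[2])
  }
  names(lo) <- names(hi) <- g_names

  chains <- vector("list", n_chains)
  pix_acc <- vector("list", n_chains)
  acc_rates <- vector("list", n_chains)
  for (cn in seq_len(n_chains)) {
    res <- run_image_chain(dat, spec, mode, priors, lo, hi,
                           n_iter = n_iter, burn = burn,
                           seed = seed + cn - 1, jitter = (cn - 1) / n_chains)
    chains[[cn]] <- res$globals
    pix_acc[[cn]] <- res$pixels
    acc_rates[[cn]] <- res$acc
  }
  cs <- chain_set(lapply(chains, function(m) m[(burn + 1):n_iter, , drop = FALSE]),
                  seeds = seed + seq_len(n_chains) - 1)
  rhat <- gelman_rubin(cs)
  draws <- do.call(rbind, cs$chains)
  gsum <- data.frame(
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q025 = apply(draws, 2, stats::quantile, 0.025),
    q975 = apply(draws, 2, stats::quantile, 0.975),
    rhat = rhat)

  # pool per-pixel posterior moments across chains
  n_eff <- (n_iter - burn) * n_chains
  sum1 <- Reduce(`+`, lapply(pix_acc, `[[`, "s1"))
  sum2 <- Reduce(`+`, lapply(pix_acc, `[[`, "s2"))
  pm <- sum1 / n_eff
  pv <- pmax(sum2 / n_eff - pm^2, 0)
  pixel <- data.frame(e_C_mean = pm[, 1], e_C_sd = sqrt(pv[, 1]),
                      e_I_mean = pm[, 2], e_I_sd = sqrt(pv[, 2]))
  if (mode == "constrained") {
    pixel$z_hat_mean <- pm[, 3]
    pixel$z_hat_sd <- sqrt(pv[, 3])
  }

  line <- if (mode == "unconstrained") {
    tls_line(pixel$e_C_mean, pixel$e_I_mean,
             pixel$e_C_sd^2, pixel$e_I_sd^2)
  } else {
    list(alpha = gsum["alpha", "mean"], beta = gsum["beta", "mean"],
         slope = -gsum["beta", "mean"], method = "constrained posterior mean")
  }

  structure(list(mode = mode, globals = gsum, chain_set = cs,
                 pixel = pixel, line = line,
                 acceptance = acc_rates, priors = priors, spec = spec,
                 n_ci = n_ci, n_fs = n_fs, n_iter = n_iter, burn = burn,
                 n_chains = n_chains, seed = seed,
                 converged = max(rhat) < 1.1,
                 masks = masks, data = dat),
            class = "sqre_fit")
}

# One adaptive Metropolis-within-Gibbs chain over the image model.
#
# Unconstrained mode: each ci pixel carries (e_C, e_I), uniform on
# [0, e_max]^2. Constrained mode: each pixel carries the normalised
# separation z_hat, uniform on [zh_lo, zh_hi] (a bounded interval
# containing [0, 1]); the quadratic spring model then gives
# e_C = (alpha/beta) |z_hat| and e_I = alpha |1 - z_hat|, so both energies
# rise away from their natural lengths and the per-pixel prior volume does
# not scale with the regression parameters.
run_image_chain <- function(dat, spec, mode, priors, lo, hi,
                            n_iter, burn, seed, jitter = 0) {
  set.seed(seed)
  ll <- ll_kernel(spec$noise_family, spec$dispersion)
  bgs <- spec$bg_small; bgl <- spec$bg_long
  est_bar <- "Gamma_barrier" %in% names(lo)
  Gam <- function(g) if (est_bar) g[["Gamma_barrier"]] else spec$Gamma_barrier
  n <- length(dat$Fs_ci)
  e_max <- priors$e_max
  zh_lo <- -0.1; zh_hi <- 1.1
  g_names <- names(lo)
  np <- length(g_names)
  constrained <- mode == "constrained"

  pix_energies <- function(g, zh) {
    eC <- (g["alpha"] / g["beta"]) * abs(zh)
    list(eC = eC, eI = g["alpha"] * abs(1 - zh))
  }

  # moment-based initialisation, jittered per chain; fall back to prior
  # draws if the likelihood is not finite
  init_globals <- function(random = FALSE) {
    if (random) {
      g <- stats::runif(np, lo, hi)
    } else {
      mu_s <- max(mean(dat$Fs_fs) - bgs, 1e-2)
      mu_l <- max(mean(dat$Fl_fs) - bgl, 1e-2)
      # the dim tail of the ci small channel estimates the barrier floor
      floor_s <- stats::quantile(dat$Fs_ci, 0.02, names = FALSE)
      G0 <- if (est_bar) min(max((floor_s - bgs) / mu_s, 0.05), 1)
            else spec$Gamma_barrier
      A <- max(stats::quantile(dat$Fs_ci, 0.98, names = FALSE) - bgs -
               G0 * mu_s, 1e-2)
      g <- c(mu_s, mu_l, A)
      if (est_bar) g <- c(g, G0)
      if (constrained) g <- c(g, 1.5, 0.8)
      g <- g * exp(stats::rnorm(np, 0, 0.05 + 0.1 * jitter))
    }
    pmin(pmax(g, lo + 1e-9), hi - 1e-9)
  }
  for (attempt in 1:20) {
    g <- init_globals(random = attempt > 3)
    names(g) <- g_names
    eC0 <- pmin(sqrt(pmax(-log(pmax(
      (dat$Fs_ci - bgs - Gam(g) * g[["mu_fs_small"]]) / g[["A_B"]],
      1e-4)), 0)), e_max)
    if (constrained) {
      zh <- pmin(pmax(eC0 * g["beta"] / g["alpha"], zh_lo + 1e-6), zh_hi - 1e-6)
      en <- pix_energies(g, zh)
      eC <- en$eC; eI <- en$eI
    } else {
      zh <- NULL
      eC <- eC0
      eI <- pmin(sqrt(pmax(-log(pmax(
        (dat$Fl_ci - bgl) / g["mu_fs_long"], 1e-4)), 0)), e_max)
    }
    m_ci_s <- Gam(g) * g[["mu_fs_small"]] + g[["A_B"]] * exp(-eC^2) + bgs
    m_ci_l <- g["mu_fs_long"] * exp(-eI^2) + bgl
    ll_tot <- sum(ll(dat$Fs_ci, m_ci_s)) + sum(ll(dat$Fl_ci, m_ci_l)) +
      sum(ll(dat$Fs_fs, g["mu_fs_small"] + bgs)) +
      sum(ll(dat$Fl_fs, g["mu_fs_long"] + bgl))
    if (is.finite(ll_tot)) break
    if (attempt == 20) stop("could not find a finite-likelihood start")
  }

  scales <- pmax(0.05 * (g - lo), 0.01)
  s_pix <- rep(if (constrained) 0.08 else 0.3, n)
  ridge_scale <- 0.05; ridge_acc <- 0L; ridge_try <- 0L
  acc_g <- integer(np); try_g <- integer(np)
  acc_p <- numeric(n); try_p <- 0L

  globals <- matrix(NA_real_, n_iter, np, dimnames = list(NULL, g_names))
  s1 <- matrix(0, n, 3); s2 <- matrix(0, n, 3)

  ll_ci_small <- function(g, eC) ll(dat$Fs_ci,
    Gam(g) * g[["mu_fs_small"]] + g[["A_B"]] * exp(-eC^2) + bgs)
  ll_ci_long <- function(g, eI) ll(dat$Fl_ci,
    g["mu_fs_long"] * exp(-eI^2) + bgl)

  cur_s <- ll_ci_small(g, eC)   # per-pixel vectors, cached
  cur_l <- ll_ci_long(g, eI)
  cur_fs_s <- sum(ll(dat$Fs_fs, g["mu_fs_small"] + bgs))
  cur_fs_l <- sum(ll(dat$Fl_fs, g["mu_fs_long"] + bgl))

  for (it in seq_len(n_iter)) {
    # -- globals, one-at-a-time random walk Metropolis
    for (j in seq_len(np)) {
      gp <- g
      gp[j] <- reflect(g[j] + stats::rnorm(1, 0, scales[j]), lo[j], hi[j])
      nm <- g_names[j]
      new_s <- cur_s; new_l <- cur_l
      new_fs_s <- cur_fs_s; new_fs_l <- cur_fs_l
      eC_p <- eC; eI_p <- eI
      if (nm %in% c("alpha", "beta")) {
        en <- pix_energies(gp, zh)
        eC_p <- en$eC; eI_p <- en$eI
        new_s <- ll_ci_small(gp, eC_p)
        new_l <- ll_ci_long(gp, eI_p)
      } else if (nm == "mu_fs_long") {
        new_l <- ll_ci_long(gp, eI)
        new_fs_l <- sum(ll(dat$Fl_fs, gp["mu_fs_long"] + bgl))
      } else {
        new_s <- ll_ci_small(gp, eC)
        if (nm == "mu_fs_small")
          new_fs_s <- sum(ll(dat$Fs_fs, gp["mu_fs_small"] + bgs))
      }
      d <- (sum(new_s) - sum(cur_s)) + (sum(new_l) - sum(cur_l)) +
        (new_fs_s - cur_fs_s) + (new_fs_l - cur_fs_l)
      try_g[j] <- try_g[j] + 1L
      if (is.finite(d) && log(stats::runif(1)) < d) {
        g <- gp; cur_s <- new_s; cur_l <- new_l
        cur_fs_s <- new_fs_s; cur_fs_l <- new_fs_l
        eC <- eC_p; eI <- eI_p
        acc_g[j] <- acc_g[j] + 1L
      }
    }
    # -- joint ridge move: shift Gamma_barrier with A_B compensating so the
    # optimal-binding mean Gamma*mu_s + A_B stays fixed (the two are nearly
    # degenerate when few pixels sit on the exclusion floor)
    if (est_bar) {
      dG <- stats::rnorm(1, 0, ridge_scale)
      gp <- g
      gp["Gamma_barrier"] <- g["Gamma_barrier"] + dG
      gp["A_B"] <- g["A_B"] + dG * g["mu_fs_small"]
      ridge_try <- ridge_try + 1L
      if (gp["Gamma_barrier"] > lo["Gamma_barrier"] &&
          gp["Gamma_barrier"] < hi["Gamma_barrier"] &&
          gp["A_B"] > lo["A_B"] && gp["A_B"] < hi["A_B"]) {
        new_s <- ll_ci_small(gp, eC)
        d <- sum(new_s) - sum(cur_s)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          g <- gp; cur_s <- new_s; ridge_acc <- ridge_acc + 1L
        }
      }
    }
    # -- per-pixel latents, simultaneous vectorised Metropolis
    if (constrained) {
      prop <- reflect(zh + stats::rnorm(n, 0, s_pix), zh_lo, zh_hi)
      eC_p <- (g["alpha"] / g["beta"]) * abs(prop)
      eI_p <- g["alpha"] * abs(1 - prop)
      new_s <- ll_ci_small(g, eC_p)
      new_l <- ll_ci_long(g, eI_p)
      d <- (new_s - cur_s) + (new_l - cur_l)
      acc <- log(stats::runif(n)) < d
      zh[acc] <- prop[acc]
      eC[acc] <- eC_p[acc]; eI[acc] <- eI_p[acc]
      cur_s[acc] <- new_s[acc]; cur_l[acc] <- new_l[acc]
    } else {
      prop <- reflect(eC + stats::rnorm(n, 0, s_pix), 0, e_max)
      new_s <- ll_ci_small(g, prop)
      d <- new_s - cur_s
      acc <- log(stats::runif(n)) < d
      eC[acc] <- prop[acc]; cur_s[acc] <- new_s[acc]
      propI <- reflect(eI + stats::rnorm(n, 0, s_pix), 0, e_max)
      new_l <- ll_ci_long(g, propI)
      dI <- new_l - cur_l
      accI <- log(stats::runif(n)) < dI
      eI[accI] <- propI[accI]; cur_l[accI] <- new_l[accI]
      acc <- acc | accI   # pooled for adaptation
    }
    acc_p <- acc_p + acc; try_p <- try_p + 1L

    # -- adaptation (frozen after burn-in)
    if (it <= burn && it %% 50 == 0) {
      rate_g <- acc_g / pmax(try_g, 1)
      scales <- scales * exp((rate_g - 0.44) * 0.5)
      scales <- pmin(scales, (hi - lo) / 2)
      rate_p <- acc_p / try_p
      s_max <- if (constrained) (zh_hi - zh_lo) / 2 else e_max / 2
      s_pix <- pmin(pmax(s_pix * exp((rate_p - 0.35) * 0.5), 0.005), s_max)
      ridge_scale <- min(max(ridge_scale *
        exp((ridge_acc / max(ridge_try, 1) - 0.44) * 0.5), 1e-4), 0.5)
      ridge_acc <- 0L; ridge_try <- 0L
      acc_g[] <- 0L; try_g[] <- 0L; acc_p[] <- 0; try_p <- 0L
    }
    globals[it, ] <- g
    if (it > burn) {
      zcol <- if (constrained) zh else separation_guess(eC, g, priors)
      s1 <- s1 + cbind(eC, eI, zcol)
      s2 <- s2 + cbind(eC^2, eI^2, zcol^2)
    }
  }
  list(globals = globals, pixels = list(s1 = s1, s2 = s2),
       acc = c(globals = mean(acc_g / pmax(try_g, 1)),
               pixels = mean(acc_p / max(try_p, 1))))
}

# crude normalised-separation proxy for unconstrained chains (scaled by the
# running line is not available per sweep; the fit-level reconstruction in
# reconstruct_separation() is the supported route)
separation_guess <- function(eC, g, priors) eC / priors$e_max

# Precision-weighted total least squares through (x, y) with known,
# heteroscedastic error variances in both coordinates (York's iterative
# errors-in-variables solution); consistent under unequal per-point
# uncertainty, unlike the plain principal axis.
tls_line <- function(x, y, vx, vy) {
  # principal-axis start
  cx <- stats::cov(cbind(x, y))
  v <- eigen(cx, symmetric = TRUE)$vectors[, 1]
  b <- v[2] / v[1]
  xb <- yb <- NA_real_
  for (it in 1:100) {
    w <- 1 / (vy + b^2 * vx + 1e-9)
    xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
    U <- x - xb; V <- y - yb
    bv <- w * (U * vy + b * V * vx)
    bnew <- sum(w * bv * V) / sum(w * bv * U)
    if (!is.finite(bnew)) break
    done <- abs(bnew - b) < 1e-12
    b <- bnew
    if (done) break
  }
  list(alpha = yb - b * xb, beta = abs(b), slope = b,
       method = "precision-weighted total least squares (errors-in-variables)")
}

#' General adaptive random-walk Metropolis sampler over a bounded box
#'
#' Componentwise random-walk Metropolis with reflection at the uniform prior
#' bounds and Robbins-Monro scale adaptation during burn-in. Used for small
#' (global-parameter scale) problems and sampler validation; image fits use
#' the dedicated vectorised sweep inside [sqre_fit()].
#'
#' @param loglik Function of the parameter vector returning a log-likelihood
#'   (use `function(th) 0` for prior-only sampling).
#' @param lower,upper Named numeric vectors of uniform prior bounds.
#' @param n_chains Number of chains (>= 2 recommended).
#' @param n_iter Iterations per chain.
#' @param burn Burn-in iterations (kept in the returned chains' attribute,
#'   removed from [gelman_rubin()] input by the caller if desired; default
#'   discarded here).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param init Optional start; defaults to prior draws (re-drawn up to 20
#'   times if the likelihood is not finite).
#' @return A `"chain_set"` (post-burn-in draws).
#' @export
run_mcmc <- function(loglik, lower, upper, n_chains = 2, n_iter = 2000,
                     burn = floor(n_iter / 2), seed = 1, init = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            n_chains >= 1, n_iter > burn)
  np <- length(lower)
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("par", seq_len(np))
  out <- vector("list", n_chains)
  for (cn in seq_len(n_chains)) {
    set.seed(seed + cn - 1)
    th <- NULL
    for (attempt in 1:20) {
      cand <- if (!is.null(init) && attempt == 1)
        pmin(pmax(init, lower + 1e-12), upper - 1e-12)
      else stats::runif(np, lower, upper)
      if (is.finite(loglik(cand))) { th <- cand; break }
    }
    if (is.null(th)) stop("could not find a finite-likelihood start")
    cur <- loglik(th)
    sc <- (upper - lower) / 10
    accept <- integer(np); tries <- integer(np)
    draws <- matrix(NA_real_, n_iter, np, dimnames = list(NULL, nm))
    for (it in seq_len(n_iter)) {
      for (j in seq_len(np)) {
        thp <- th
        thp[j] <- reflect(th[j] + stats::rnorm(1, 0, sc[j]), lower[j], upper[j])
        llp <- loglik(thp)
        tries[j] <- tries[j] + 1L
        if (is.finite(llp) && log(stats::runif(1)) < llp - cur) {
          th <- thp; cur <- llp; accept[j] <- accept[j] + 1L
        }
      }
      if (it <= burn && it %% 50 == 0) {
        sc <- pmin(sc * exp((accept / pmax(tries, 1) - 0.44) * 0.5),
                   (upper - lower) / 2)
        accept[] <- 0L; tries[] <- 0L
      }
      draws[it, ] <- th
    }
    out[[cn]] <- draws[(burn + 1):n_iter, , drop = FALSE]
  }
  chain_set(out, seeds = seed + seq_len(n_chains) - 1)
}

#' Construct a chain set
#'
#' @param chains List of equal-size draw matrices (iterations x parameters).
#' @param seeds Integer seed per chain (must be distinct).
#' @return An object of class `"chain_set"`.
#' @export
chain_set <- function(chains, seeds = seq_along(chains)) {
  stopifnot(is.list(chains), length(chains) >= 1)
  d <- dim(chains[[1]])
  for (ch in chains) stopifnot(identical(dim(ch), d))
  if (anyDuplicated(seeds)) stop("chain seeds must be distinct")
  structure(list(chains = chains, seeds = seeds,
                 param_names = colnames(chains[[1]])),
            class = "chain_set")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The standard multiple-chain convergence statistic per parameter:
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain variance and
#' `B` the between-chain variance of the chain means. Degenerate chains with
#' zero within- and between-chain variance (e.g. duplicated identical
#' chains) return exactly 1. A run is flagged converged when
#' `max(rhat) < 1.1`.
#'
#' @param chains A `"chain_set"` with at least 2 chains of equal length.
#' @return Named vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  m <- length(chains$chains)
  if (m < 2) stop("at least 2 chains are required")
  n <- nrow(chains$chains[[1]])
  np <- ncol(chains$chains[[1]])
  rhat <- numeric(np)
  for (j in seq_len(np)) {
    xs <- vapply(chains$chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(xs, 2, stats::var))
    B <- n * stats::var(colMeans(xs))
    # degenerate-variance guard: no within-chain variance, or no
    # between-chain spread at all (duplicated chains), reads as converged
    if (W < 1e-300 || B < 1e-10 * W) { rhat[j] <- 1; next }
    rhat[j] <- sqrt(((n - 1) / n * W + B / n) / W)
  }
  names(rhat) <- chains$param_names
  rhat
}

#' Fit with independent per-pixel energies (linearity test)
#'
#' Convenience wrapper for [sqre_fit()] with `mode = "unconstrained"`.
#' @inheritParams sqre_fit
#' @param ... Passed to [sqre_fit()].
#' @return An `"sqre_fit"` object.
#' @export
fit_unconstrained <- function(image, masks, spec = fluor_spec(), ...) {
  sqre_fit(image, masks, spec, mode = "unconstrained", ...)
}

#' Fit with the SQRE linear relation imposed
#'
#' Convenience wrapper for [sqre_fit()] with `mode = "constrained"`: the
#' regression parameters `(alpha, beta)` are estimated and each pixel
#' carries a single latent coordinate.
#' @inheritParams sqre_fit
#' @param ... Passed to [sqre_fit()].
#' @return An `"sqre_fit"` object.
#' @export
fit_constrained <- function(image, masks, spec = fluor_spec(), ...) {
  sqre_fit(image, masks, spec, mode = "constrained", ...)
}

#' Is the regression slope equal to one?
#'
#' Equal spring constants for the complex and the long ligand would give a
#' slope magnitude of exactly 1; this reports the posterior evidence.
#'
#' @param fit A constrained `"sqre_fit"`.
#' @param level Credible level (default 0.95).
#' @return A list with `p_gt_1` = P(beta > 1), `ci`, and `covers_one`.
#' @export
slope_unity_test <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sqre_fit"))
  if (fit$mode != "constrained" ||
      !"beta" %in% fit$chain_set$param_names)
    stop("slope_unity_test requires a constrained fit with beta draws")
  b <- unlist(lapply(fit$chain_set$chains, function(ch) ch[, "beta"]))
  a2 <- (1 - level) / 2
  ci <- stats::quantile(b, c(a2, 1 - a2), names = FALSE)
  list(p_gt_1 = mean(b > 1), ci = ci,
       covers_one = ci[1] <= 1 && 1 <= ci[2],
       posterior_mean = mean(b))
}

#' Posterior probability that patternation is predicted
#'
#' Fraction of posterior `(alpha, beta)` draws whose regression line
#' intersects the unstable region of the `k = 0` stability margin (see
#' [patternation_test()]).
#'
#' @param fit A constrained `"sqre_fit"`.
#' @param p A [dynamics_params()] object.
#' @param n_draws Number of posterior draws evaluated (subsampled evenly).
#' @param n_line Sampling points per line.
#' @return A list with `probability`, and `per_draw` (data.frame of alpha,
#'   beta, intersects).
#' @export
patternation_posterior <- function(fit, p, n_draws = 100, n_line = 101) {
  stopifnot(inherits(fit, "sqre_fit"), inherits(p, "dynamics_params"))
  if (fit$mode != "constrained")
    stop("patternation_posterior requires a constrained fit")
  draws <- do.call(rbind, fit$chain_set$chains)[, c("alpha", "beta")]
  idx <- unique(round(seq(1, nrow(draws), length.out = min(n_draws, nrow(draws)))))
  res <- vapply(idx, function(i) {
    ln <- sqre_line(max(draws[i, "alpha"], 1e-3), max(draws[i, "beta"], 1e-3))
    patternation_test(ln, p, n = n_line)$intersects
  }, logical(1))
  list(probability = mean(res),
       per_draw = data.frame(alpha = draws[idx, "alpha"],
                             beta = draws[idx, "beta"], intersects = res))
}

#' Reconstruct the hidden membrane-separation distribution
#'
#' Maps posterior-mean complex SQREs through the spring model to the
#' normalised separation `z_hat` (0 at the bond length, 1 at the long-ligand
#' length) and reports the histogram with its density modes.
#'
#' @param fit An `"sqre_fit"`.
#' @param springs A [spring_params()] object.
#' @param bw Kernel bandwidth for mode counting.
#' @return A list with `z_hat` (per pixel), `hist` (histogram object), and
#'   `modes` (locations of density maxima).
#' @export
reconstruct_separation <- function(fit, springs = spring_params(), bw = 0.06) {
  stopifnot(inherits(fit, "sqre_fit"))
  z_hat <- if (!is.null(fit$pixel$z_hat_mean)) fit$pixel$z_hat_mean
           else separation_from_sqre(fit$pixel$e_C_mean, springs)
  h <- graphics::hist(z_hat, breaks = 30, plot = FALSE)
  d <- stats::density(z_hat, bw = bw)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  pk <- pk[d$y[pk] > 0.1 * max(d$y)]
  list(z_hat = z_hat, hist = h, modes = d$x[pk], density = d)
}

#' Per-pixel energy posteriors under known global parameters
#'
#' Fast deterministic alternative to the full MCMC when the global
#' parameters are known (or taken from a previous fit): each
#' contact-interface pixel's SQRE posterior is integrated on a grid under
#' the uniform prior, independently per channel. Used by the PSF-bias
#' study, where the same globals generate both the blurred and deconvolved
#' images.
#'
#' @param image A [two_channel_image()].
#' @param mask Logical array selecting the contact-interface pixels.
#' @param spec A [fluor_spec()] with the (known) global parameters.
#' @param e_max Upper bound of the uniform SQRE prior.
#' @param n_grid Grid resolution.
#' @return A data.frame with per-pixel `e_C_mean`, `e_C_sd`, `e_I_mean`,
#'   `e_I_sd`.
#' @export
fit_pixel_energies <- function(image, mask, spec, e_max = 5, n_grid = 400) {
  stopifnot(inherits(image, "two_channel_image"), inherits(spec, "fluor_spec"))
  eg <- seq(e_max / (2 * n_grid), e_max * (1 - 1 / (2 * n_grid)),
            length.out = n_grid)
  post <- function(counts, means) {
    ll <- outer(counts, log(means)) - rep(means, each = length(counts))
    if (spec$noise_family != "poisson")
      ll <- t(vapply(counts, function(x) pixel_loglik(rep(x, n_grid), means, spec),
                     numeric(n_grid)))
    ll <- ll - apply(ll, 1, max)
    w <- exp(ll); w <- w / rowSums(w)
    m <- as.numeric(w %*% eg)
    v <- pmax(as.numeric(w %*% eg^2) - m^2, 0)
    list(mean = m, sd = sqrt(v))
  }
  pc <- post(as.numeric(image$small[mask]), ci_mean_small(spec, eg))
  pi_ <- post(as.numeric(image$long[mask]), ci_mean_long(spec, eg))
  data.frame(e_C_mean = pc$mean, e_C_sd = pc$sd,
             e_I_mean = pi_$mean, e_I_sd = pi_$sd)
}

#' Fit a line in SQRE coordinates with uncertainties in both axes
#'
#' @param e_C,e_I Per-pixel SQRE estimates.
#' @param var_C,var_I Their variances.
#' @return A list with `alpha`, `beta` (slope magnitude), `slope`, `method`.
#' @export
sqre_line_fit <- function(e_C, e_I, var_C, var_I) {
  tls_line(e_C, e_I, var_C, var_I)
}
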