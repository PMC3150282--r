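# Methods for the fitted model object.

#' @export
print.sqre_fit <- function(x, ...) {
  cat(sprintf("Exclusion-energy model fit (%s), %d ci / %d fs pixels\n",
              x$mode, x$n_ci, x$n_fs))
  cat(sprintf("  %d chains x %d sweeps (burn-in %d), noise family %s\n",
              x$n_chains, x$n_iter, x$burn, x$spec$noise_family))
  cat(sprintf("  SQRE line: e_I = %.3f %+.3f * e_C  [%s]\n",
              x$line$alpha, x$line$slope, x$line$method))
  cat(sprintf("  max R-hat %.3f (%s)\n", max(x$globals$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.sqre_fit <- function(object, ...) {
  out <- list(mode = object$mode, globals = object$globals,
              line = object$line,
              pixel_summary = data.frame(
                mean_e_C = mean(object$pixel$e_C_mean),
                mean_e_I = mean(object$pixel$e_I_mean),
                max_E_C = max(object$pixel$e_C_mean)^2,
                max_E_I = max(object$pixel$e_I_mean)^2),
              acceptance = object$acceptance,
              converged = object$converged)
  class(out) <- "summary.sqre_fit"
  out
}

#' @export
print.summary.sqre_fit <- function(x, ...) {
  cat(sprintf("Exclusion-energy model fit (%s)\n\nGlobal parameters:\n", x$mode))
  print(round(x$globals, 4))
  cat(sprintf("\nSQRE line: e_I = %.3f %+.3f * e_C\n", x$line$alpha, x$line$slope))
  cat(sprintf("Mean SQREs over the interface: e_C %.3f, e_I %.3f kT^1/2\n",
              x$pixel_summary$mean_e_C, x$pixel_summary$mean_e_I))
  cat(sprintf("Converged (max R-hat < 1.1): %s\n", x$converged))
  invisible(x)
}

#' @export
coef.sqre_fit <- function(object, ...) {
  g <- stats::setNames(object$globals$mean, rownames(object$globals))
  if (object$mode == "unconstrained")
    g <- c(g, alpha = object$line$alpha, beta = object$line$beta)
  g
}

# Posterior-mean model means for every analysed pixel (list of per-region
# vectors, in mask order).
#' @export
fitted.sqre_fit <- function(object, ...) {
  g <- stats::setNames(object$globals$mean, rownames(object$globals))
  sp <- object$spec
  sp$mu_fs_small <- g[["mu_fs_small"]]; sp$mu_fs_long <- g[["mu_fs_long"]]
  sp$A_B <- g[["A_B"]]
  if ("Gamma_barrier" %in% names(g)) sp$Gamma_barrier <- g[["Gamma_barrier"]]
  list(ci_small = ci_mean_small(sp, object$pixel$e_C_mean),
       ci_long = ci_mean_long(sp, object$pixel$e_I_mean),
       fs_small = sp$mu_fs_small + sp$bg_small,
       fs_long = sp$mu_fs_long + sp$bg_long)
}

#' @export
residuals.sqre_fit <- function(object, ...) {
  f <- fitted(object)
  v <- function(m) switch(object$spec$noise_family,
    poisson = m, gaussian = object$spec$dispersion * m,
    gamma = m^2 / object$spec$dispersion)
  list(ci_small = (object$data$Fs_ci - f$ci_small) / sqrt(v(f$ci_small)),
       ci_long = (object$data$Fl_ci - f$ci_long) / sqrt(v(f$ci_long)),
       fs_small = (object$data$Fs_fs - f$fs_small) / sqrt(v(f$fs_small)),
       fs_long = (object$data$Fl_fs - f$fs_long) / sqrt(v(f$fs_long)))
}

#' Posterior-predictive count simulation from a fitted model
#'
#' Draws new pixel counts around the posterior-mean model means under the
#' fitted noise family (a posterior-predictive check against the observed
#' histograms).
#'
#' @param object An `"sqre_fit"`.
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element has `ci_small`, `ci_long`,
#'   `fs_small`, `fs_long` count vectors.
#' @export
simulate.sqre_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  sp <- object$spec
  draw <- function(m, n = length(m)) {
    if (length(m) == 1) m <- rep(m, n)
    as.numeric(draw_counts(matrix(m), sp))
  }
  lapply(seq_len(nsim), function(i)
    list(ci_small = draw(f$ci_small), ci_long = draw(f$ci_long),
         fs_small = draw(f$fs_small, object$n_fs),
         fs_long = draw(f$fs_long, object$n_fs)))
}

#' Plot a fitted exclusion-energy model
#'
#' `which = "sqre"` draws the joint distribution of posterior-mean SQREs
#' with the fitted line (the linearity diagnostic); `which = "zhat"` the
#' reconstructed separation histogram; `which = "stability"` the stability
#' plot (requires `dynamics`).
#'
#' @param x An `"sqre_fit"`.
#' @param which `"sqre"`, `"zhat"` or `"stability"`.
#' @param dynamics A [dynamics_params()] (stability plot only).
#' @param ... Passed to the underlying plot.
#' @export
plot.sqre_fit <- function(x, which = c("sqre", "zhat", "stability"),
                          dynamics = NULL, ...) {
  which <- match.arg(which)
  if (which == "sqre") {
    graphics::plot(x$pixel$e_C_mean, x$pixel$e_I_mean,
                   pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("steelblue", 0.5),
                   xlab = expression(e[C] ~ (kT^{1/2})),
                   ylab = expression(e[I] ~ (kT^{1/2})),
                   main = "Posterior-mean SQREs", ...)
    graphics::abline(a = x$line$alpha, b = x$line$slope, col = "grey30", lwd = 2)
  } else if (which == "zhat") {
    rec <- reconstruct_separation(x)
    graphics::hist(rec$z_hat, breaks = 30, col = "grey80",
                   xlab = expression(hat(z)), main = "Reconstructed separation", ...)
  } else {
    if (is.null(dynamics)) stop("stability plot needs dynamics_params")
    ln <- sqre_line(max(x$line$alpha, 1e-3), max(x$line$beta, 1e-3))
    sc <- stability_curve(ln, dynamics, e_max = max(2.5, x$line$alpha * 1.5))
    plot(sc, ...)
    graphics::abline(a = ln$alpha, b = -ln$beta, col = "grey30", lwd = 2)
  }
  invisible(x)
}

#' @export
plot.stability_curve <- function(x, ...) {
  graphics::image(x$e_C, x$e_I, x$margin > 0,
                  col = c("#c6dbef", "white"),
                  xlab = expression(e[C] ~ (kT^{1/2})),
                  ylab = expression(e[I] ~ (kT^{1/2})),
                  main = "Stability plot (shaded = stable)", ...)
  if (nrow(x$curve))
    graphics::points(x$curve$e_C, x$curve$e_I, pch = 16, cex = 0.3)
  invisible(x)
}
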