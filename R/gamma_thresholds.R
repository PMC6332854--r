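# Gamma-distribution significance machinery: the genome-wide set of per-locus
# additive variances is modelled as gamma-distributed; loci exceeding the
# Bonferroni-corrected gamma quantile are called significant. For haplotype
# loci the gamma parameters depend on the allele count k, so they are fitted
# per k class and smoothed over k (cubic polynomial for the shape, Brody
# asymptotic curve for the rate).

#' Method-of-moments gamma fit
#'
#' Newton-Raphson-derived moment approximation: with
#' `s = ln(mean(x)) - mean(ln(x))`, the shape is
#' `alpha = (3 - s + sqrt((3 - s)^2 + 24 s)) / (12 s)` and the rate is
#' `beta = alpha / mean(x)`.
#'
#' @param x Positive, non-constant variances (n >= 2).
#' @return A `gamma_fit`: list with `n`, `s`, `alpha`, `beta`, `mean`.
#' @export
fit_gamma_mom <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 variances")
  if (any(x <= 0)) stop("variances must be strictly positive (log undefined)")
  s <- log(mean(x)) - mean(log(x))
  if (s <= .Machine$double.eps * 100) {
    stop("variances are (nearly) constant: s = ", s,
         "; gamma shape diverges")
  }
  alpha <- (3 - s + sqrt((3 - s)^2 + 24 * s)) / (12 * s)
  structure(list(n = length(x), s = s, alpha = alpha,
                 beta = alpha / mean(x), mean = mean(x)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("gamma_fit: n =", x$n, "shape =", signif(x$alpha, 4),
      "rate =", signif(x$beta, 4), "\n")
  invisible(x)
}

#' Per-allele-count gamma class fits
#'
#' Splits the per-locus variances by allele count `k` and fits the moment
#' approximation in each class. Zero variances are excluded (with their
#' count reported); classes with fewer than `min_n` usable loci, or with
#' constant variances, are dropped.
#'
#' @param loci Data frame from [locus_variances()] with columns `k`, `sigma2`.
#' @param min_n Minimum usable loci per class (default 10).
#' @return Data frame with `k`, `n`, `s`, `alpha`, `beta`, `mu`; dropped
#'   zero-variance count in attribute `"n_zero"`.
#' @export
fit_gamma_classes <- function(loci, min_n = 10L) {
  ok <- !is.na(loci$sigma2)
  n_zero <- sum(loci$sigma2[ok] <= 0)
  use <- ok & loci$sigma2 > 0
  if (n_zero > 0) message(n_zero, " zero variance(s) excluded from gamma fitting")
  sp <- split(loci$sigma2[use], loci$k[use])
  rows <- lapply(names(sp), function(kk) {
    x <- sp[[kk]]
    if (length(x) < min_n || diff(range(x)) == 0) return(NULL)
    f <- fit_gamma_mom(x)
    data.frame(k = as.integer(kk), n = f$n, s = f$s, alpha = f$alpha,
               beta = f$beta, mu = f$mean)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no allele-count class had enough positive variances")
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_zero") <- n_zero
  out
}

#' Smooth gamma parameters over allele counts
#'
#' Cubic ordinary-least-squares regression of the class shapes `alpha(k)` on
#' `k`, and a Brody asymptotic curve `beta(k) = A (1 - B exp(-kappa k))` for
#' the class rates, fitted by nonlinear least squares (starting values:
#' `A = max(beta)`, `B = 1 - beta(k_min)/A`, `kappa = 0.1`, with perturbed
#' restarts on non-convergence).
#'
#' @param classes Data frame from [fit_gamma_classes()].
#' @return A `smoothed_params`: cubic coefficients, Brody parameters,
#'   residuals, and predictor functions `alpha_fun(k)`, `beta_fun(k)`.
#' @export
smooth_params <- function(classes) {
  if (nrow(classes) < 5L) {
    stop("need >= 5 distinct allele-count classes for the cubic fit (got ",
         nrow(classes), ")")
  }
  # classes are weighted by their locus counts so sparsely populated edge
  # allele counts do not drag the curves
  cub <- stats::lm(alpha ~ poly(k, 3, raw = TRUE), data = classes,
                   weights = classes$n)
  co <- unname(stats::coef(cub))
  alpha_fun <- function(k) co[1] + co[2] * k + co[3] * k^2 + co[4] * k^3

  A0 <- max(classes$beta)
  B0 <- 1 - classes$beta[which.min(classes$k)] / A0
  starts <- list(
    c(A = A0, B = B0, kappa = 0.1),
    c(A = A0, B = ifelse(B0 == 0, 0.5, 2 * B0), kappa = 0.05),
    c(A = A0 * 1.5, B = -0.5, kappa = 0.2),
    c(A = mean(classes$beta), B = -1, kappa = 0.3),
    c(A = min(classes$beta), B = -2, kappa = 0.5)
  )
  brody <- NULL
  for (st in starts) {
    brody <- tryCatch(
      minpack.lm::nlsLM(beta ~ A * (1 - B * exp(-kappa * k)),
                        data = classes, start = as.list(st),
                        weights = classes$n,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(brody)) break
  }
  if (is.null(brody)) {
    stop("Brody fit for beta(k) did not converge after ", length(starts),
         " restarts; class rates: ",
         paste(signif(classes$beta, 3), collapse = ", "))
  }
  bp <- stats::coef(brody)
  beta_fun <- function(k) bp[["A"]] * (1 - bp[["B"]] * exp(-bp[["kappa"]] * k))

  kr <- range(classes$k)
  kk <- seq(kr[1], kr[2])
  if (any(alpha_fun(kk) <= 0) || any(beta_fun(kk) <= 0)) {
    stop("smoothed gamma parameters are not positive over the observed ",
         "allele-count range; refusing to threshold with them")
  }
  structure(list(
    cubic_coef = co,
    brody = as.list(bp),
    alpha_resid = stats::resid(cub),
    beta_resid = stats::resid(brody),
    alpha_fun = alpha_fun, beta_fun = beta_fun,
    k_range = kr
  ), class = "smoothed_params")
}

#' @export
print.smoothed_params <- function(x, ...) {
  cat("smoothed_params: alpha(k) cubic coef =",
      paste(signif(x$cubic_coef, 4), collapse = ", "), "\n")
  cat("  beta(k) Brody: A =", signif(x$brody$A, 4),
      "B =", signif(x$brody$B, 4), "kappa =", signif(x$brody$kappa, 4), "\n")
  invisible(x)
}

#' Bonferroni-corrected gamma variance thresholds
#'
#' The cutoff for allele count `k` is the inverse gamma CDF at probability
#' `1 - level/n_tests` with parameters `(alpha(k), beta(k))` — smoothed
#' curves when a `smoothed_params` is supplied, class fits otherwise. For a
#' single `gamma_fit` (the SNP analysis) one cutoff is returned (`k = 2`).
#'
#' @param fits A `gamma_fit`, a class-fit data frame, or a `smoothed_params`.
#' @param n_tests Number of tests in the analysis (>= 1).
#' @param level Family-wise error level (default 0.05).
#' @param k Allele counts to tabulate (required for `smoothed_params`;
#'   defaults to the observed class ks otherwise).
#' @return Data frame with `k`, `alpha`, `beta`, `cutoff`.
#' @export
gamma_thresholds <- function(fits, n_tests, level = 0.05, k = NULL) {
  stopifnot(n_tests >= 1, level > 0, level < 1)
  pp <- 1 - level / n_tests
  if (pp >= 1) stop("probability underflow at n_tests = ", n_tests)
  if (inherits(fits, "gamma_fit")) {
    tab <- data.frame(k = 2L, alpha = fits$alpha, beta = fits$beta)
  } else if (inherits(fits, "smoothed_params")) {
    if (is.null(k)) k <- seq(fits$k_range[1], fits$k_range[2])
    # outside the fitted class range the cubic is an untrustworthy
    # extrapolation, so boundary-class parameters are reused there
    kq <- pmin(pmax(k, fits$k_range[1]), fits$k_range[2])
    tab <- data.frame(k = k, alpha = fits$alpha_fun(kq),
                      beta = fits$beta_fun(kq))
  } else {
    tab <- fits[, c("k", "alpha", "beta")]
    if (!is.null(k)) tab <- tab[tab$k %in% k, , drop = FALSE]
  }
  if (any(tab$alpha <= 0) || any(tab$beta <= 0)) {
    stop("gamma parameters must be positive")
  }
  tab$cutoff <- stats::qgamma(pp, shape = tab$alpha, rate = tab$beta)
  rownames(tab) <- NULL
  tab
}

#' Flag loci exceeding their variance threshold
#'
#' A locus is significant iff its additive variance is at or above the
#' cutoff for its allele count.
#'
#' @param loci Data frame from [locus_variances()].
#' @param thresholds Data frame from [gamma_thresholds()].
#' @return `loci` with columns `cutoff` and `flagged` added.
#' @export
call_significant <- function(loci, thresholds) {
  m <- match(loci$k, thresholds$k)
  if (anyNA(m)) {
    stop("no threshold for allele count(s): ",
         paste(sort(unique(loci$k[is.na(m)])), collapse = ", "))
  }
  loci$cutoff <- thresholds$cutoff[m]
  loci$flagged <- !is.na(loci$sigma2) & loci$sigma2 >= loci$cutoff
  loci
}
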