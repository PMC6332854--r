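# Linear mixed model machinery: the animal model y = Xb + u + e with
# u ~ MVN(0, G Vg) and e ~ MVN(0, I Ve) is fitted by REML after a single
# eigendecomposition of the GRM rotates the covariance to diagonal form
# (the EMMA device). Per-predictor tests reuse the null-model variance ratio
# (EMMAX/P3D) unless an exact per-predictor fit is requested.

.eigen_grm <- function(grm) {
  if (inherits(grm, "grm")) grm <- grm$mat
  e <- eigen(grm, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop("relationship matrix is not positive semi-definite")
  }
  e$values <- pmax(e$values, 0)
  e
}

# Profile REML log-likelihood at variance ratio lambda = Vg/Ve for rotated
# data (yt = U'y, Xt = U'X, d = eigenvalues of G).
.reml_ll <- function(lambda, yt, Xt, d) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- lambda * d + 1
  XtW <- Xt / v
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / v)
  -0.5 * ((n - p) * (log(2 * pi) + 1 + log(rss / (n - p))) +
            sum(log(v)) + determinant(XtWX, logarithm = TRUE)$modulus)
}

# Core REML fit over log10(lambda) in [-6, 6]; returns variance components,
# GLS fixed effects, and the rotated pieces for reuse.
.reml_fit <- function(y, X, eig) {
  n <- length(y)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  d <- eig$values
  identifiable <- diff(range(d)) > 1e-8
  if (!identifiable) {
    warning("relationship matrix has (near-)constant eigenvalues: ",
            "Vg and Ve are not separately identifiable; returning a ",
            "boundary fit with Vg = 0")
    opt_l <- 1e-6
  } else {
    opt <- stats::optimize(function(ll) .reml_ll(10^ll, yt, Xt, d),
                           interval = c(-6, 6), maximum = TRUE, tol = 1e-8)
    opt_l <- 10^opt$maximum
    if (opt$maximum <= -6 + 1e-6) opt_l <- 0
  }
  v <- opt_l * d + 1
  XtW <- Xt / v
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / v)
  ve <- rss / (n - ncol(Xt))
  vg <- opt_l * ve
  list(Vg = vg, Ve = ve, lambda = opt_l,
       loglik = as.numeric(.reml_ll(max(opt_l, 1e-12), yt, Xt, d)),
       beta = as.numeric(beta),
       beta_se = sqrt(diag(solve(XtWX)) * ve),
       yt = as.numeric(yt), Xt = Xt, eig = eig)
}

#' Pre-adjust the phenotype for fixed effects
#'
#' Estimates contemporary-group class effects and a linear age covariate
#' under the animal model (REML with the GRM as relationship structure) and
#' returns `y - X beta_hat`, centred around zero.
#'
#' @param y Numeric trait vector (kg).
#' @param cg Contemporary-group labels (factor or character); every group
#'   must have at least 3 records.
#' @param age Numeric age covariate (days).
#' @param grm A `grm` from [compute_grm()] (or its eigendecomposition).
#' @return Numeric vector of adjusted phenotypes, with the fitted model in
#'   attribute `"fit"`.
#' @export
preadjust_phenotype <- function(y, cg, age, grm) {
  stopifnot(is.numeric(y), is.numeric(age),
            length(y) == length(cg), length(y) == length(age))
  cg <- factor(cg)
  tab <- table(cg)
  if (any(tab < 3L)) {
    stop("contemporary group(s) with fewer than 3 records: ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  }
  # degenerate designs (one group, constant age) reduce to mean adjustment
  dat <- data.frame(cg = cg, age = age)
  rhs <- c(if (nlevels(cg) > 1L) "cg",
           if (stats::var(age) > 0) "age")
  form <- if (length(rhs)) stats::reformulate(rhs) else ~ 1
  X <- stats::model.matrix(form, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("confounded fixed-effect design: rank ", qrX$rank, " < ", ncol(X),
         " columns (contemporary groups collinear with age?)")
  }
  eig <- if (is.list(grm) && !is.null(grm$vectors)) grm else .eigen_grm(grm)
  fit <- .reml_fit(y, X, eig)
  adj <- as.numeric(y - X %*% fit$beta)
  names(fit$beta) <- colnames(X)
  names(fit$beta_se) <- colnames(X)
  attr(adj, "fit") <- fit[c("Vg", "Ve", "lambda", "beta", "beta_se",
                            "loglik")]
  adj
}

#' Fit the null mixed model
#'
#' REML fit of `y = 1 mu + u + e` with `u ~ MVN(0, G Vg)`, by 1-D
#' optimization of the profile REML likelihood over the variance ratio
#' `lambda = Vg/Ve` on eigen-rotated data.
#'
#' @param y_adj Pre-adjusted phenotype vector.
#' @param grm A `grm`, its matrix, or a precomputed eigendecomposition.
#' @return A `null_fit`: `Vg`, `Ve`, `lambda`, `loglik`, plus the rotated
#'   data and eigendecomposition reused by [test_predictors()].
#' @export
fit_null <- function(y_adj, grm) {
  stopifnot(all(is.finite(y_adj)))
  eig <- if (is.list(grm) && !is.null(grm$vectors)) grm else .eigen_grm(grm)
  X <- matrix(1, length(y_adj), 1)
  fit <- .reml_fit(y_adj, X, eig)
  structure(fit, class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("null_fit: Vg =", signif(x$Vg, 4), "Ve =", signif(x$Ve, 4),
      "lambda =", signif(x$lambda, 4),
      "h2 =", signif(x$Vg / (x$Vg + x$Ve), 3), "\n")
  invisible(x)
}

#' Test predictors in the mixed model
#'
#' Generalized-least-squares estimate of the allele substitution effect of
#' each dosage column under covariance `Vg G + Ve I`, with the variance
#' ratio fixed at the null-model estimate (EMMAX-style) or re-estimated per
#' predictor (`exact = TRUE`). The Wald p-value is `P(chisq_1 >=
#' (effect/SE)^2)`. Constant columns are skipped (NA row).
#'
#' @param dosage Numeric matrix (samples x predictors) of 0/1/2 dosages, or
#'   a single vector.
#' @param null A `null_fit` from [fit_null()].
#' @param exact Re-optimize lambda for each predictor (slower; default
#'   `FALSE` reuses the null-model lambda).
#' @return Data frame with `effect`, `se`, `p` per predictor.
#' @export
test_predictors <- function(dosage, null, exact = FALSE) {
  stopifnot(inherits(null, "null_fit"))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1)
  n <- nrow(dosage)
  stopifnot(n == length(null$yt))
  keep <- apply(dosage, 2, function(x) stats::var(x) > 0)
  if (any(!keep)) {
    message(sum(!keep), " constant predictor(s) skipped")
  }
  out <- data.frame(effect = rep(NA_real_, ncol(dosage)),
                    se = NA_real_, p = NA_real_)
  if (!any(keep)) return(out)
  Xt <- crossprod(null$eig$vectors, dosage[, keep, drop = FALSE])
  yt <- null$yt
  ones_t <- null$Xt[, 1]
  d <- null$eig$values
  if (exact) {
    res <- t(vapply(seq_len(ncol(Xt)), function(j) {
      fit <- .reml_fit_rotated(yt, cbind(ones_t, Xt[, j]), d)
      fit
    }, numeric(3)))
  } else {
    v <- null$lambda * d + 1
    iv <- 1 / v
    s11 <- sum(ones_t^2 * iv)
    s1y <- sum(ones_t * yt * iv)
    Xiv <- Xt * iv
    s12 <- colSums(Xiv * ones_t)
    s22 <- colSums(Xiv * Xt)
    sxy <- colSums(Xiv * yt)
    det2 <- s11 * s22 - s12^2
    b2 <- (s11 * sxy - s12 * s1y) / det2
    b1 <- (s1y - s12 * b2) / s11
    # residual sum of squares in the whitened metric, column-wise
    yy <- sum(yt^2 * iv)
    rss <- yy - 2 * (b1 * s1y + b2 * sxy) +
      b1^2 * s11 + 2 * b1 * b2 * s12 + b2^2 * s22
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 * s11 / det2)
    res <- cbind(b2, se, stats::pchisq((b2 / se)^2, 1, lower.tail = FALSE))
  }
  out$effect[keep] <- res[, 1]
  out$se[keep] <- res[, 2]
  out$p[keep] <- res[, 3]
  out
}

# Exact per-predictor REML on already-rotated data; returns c(effect, se, p).
.reml_fit_rotated <- function(yt, Xt, d) {
  n <- length(yt)
  opt <- stats::optimize(function(ll) .reml_ll(10^ll, yt, Xt, d),
                         interval = c(-6, 6), maximum = TRUE, tol = 1e-8)
  lambda <- 10^opt$maximum
  v <- lambda * d + 1
  XtW <- Xt / v
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  sigma2 <- sum(r^2 / v) / (n - ncol(Xt))
  cov <- solve(XtWX) * sigma2
  eff <- beta[2]
  se <- sqrt(cov[2, 2])
  c(eff, se, stats::pchisq((eff / se)^2, 1, lower.tail = FALSE))
}

#' Association scan over a window set
#'
#' Enumerates every haplotype locus of the window set and tests each allele
#' as its own one-vs-rest dosage predictor, yielding the per-allele effects
#' and frequencies consumed by the additive-variance formulas. With
#' `w = 1` this is exactly the single-SNP analysis (the two alleles of each
#' SNP give the usual paired +/- effects).
#'
#' @param geno Post-QC [phased_genotypes()] panel.
#' @param y_adj Pre-adjusted phenotype vector (same sample order).
#' @param null A `null_fit` from [fit_null()].
#' @param w Window size in SNPs.
#' @param exact,pool_rare Passed through to [test_predictors()] /
#'   [enumerate_locus()].
#' @return Data frame with one row per (locus, allele): window coordinates,
#'   `k`, `allele`, `freq`, `effect`, `se`, `p`.
#' @export
assoc_scan <- function(geno, y_adj, null, w, exact = FALSE,
                       pool_rare = FALSE) {
  ws <- build_windows(geno, w)
  nw <- nrow(ws$windows)
  if (nw == 0L) stop("no windows to test")
  chunks <- split(seq_len(nw), ceiling(seq_len(nw) / 250))
  parts <- lapply(chunks, function(ch) {
    loci <- lapply(ch, function(i) {
      enumerate_locus(geno, i, ws, pool_rare = pool_rare)
    })
    ks <- vapply(loci, function(l) l$k, integer(1))
    dos <- do.call(cbind, lapply(loci, function(l) l$dosage))
    res <- suppressMessages(test_predictors(dos, null, exact = exact))
    idx <- rep(ch, ks)
    wdf <- ws$windows[idx, , drop = FALSE]
    data.frame(
      chrom = wdf$chrom, window = idx,
      first_id = wdf$first_id, last_id = wdf$last_id,
      start_bp = wdf$start_bp, end_bp = wdf$end_bp,
      k = rep(ks, ks),
      allele = unlist(lapply(loci, function(l) l$alleles)),
      freq = unlist(lapply(loci, function(l) l$freq)),
      effect = res$effect, se = res$se, p = res$p,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
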