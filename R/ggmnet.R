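#' Residualize traits on covariates
#'
#' Replaces each trait by its least-squares residual on
#' `[intercept | covariates]`. With no covariates this is mean-centering.
#' Missing trait values are mean-imputed per trait before the regression
#' (the imputation count is attached as an attribute) so the downstream
#' correlation matrix is computed on a complete matrix.
#'
#' @param traits numeric samples x traits matrix, or a [trait_matrix()]
#'   (raw scale is used as-is).
#' @param covariates optional covariate matrix.
#' @return Residual matrix (samples x traits), attribute `n_imputed`.
#' @export
residualize <- function(traits, covariates = NULL) {
  Y <- if (inherits(traits, "trait_matrix")) traits$values else
    as.matrix(traits)
  n_imp <- sum(is.na(Y))
  if (n_imp > 0) {
    for (j in seq_len(ncol(Y))) {
      nas <- is.na(Y[, j])
      if (any(nas)) Y[nas, j] <- mean(Y[, j], na.rm = TRUE)
    }
  }
  X <- cbind(rep(1, nrow(Y)),
             if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  R <- qr.resid(qx, Y)
  dimnames(R) <- dimnames(Y)
  attr(R, "n_imputed") <- n_imp
  R
}

#' Shrinkage estimate of the correlation matrix
#'
#' Linear shrinkage of the sample correlation matrix toward the identity
#' (the correlation-scale target): `R* = (1 - lambda) R + lambda I`, with
#' the analytic optimal intensity of Schafer & Strimmer,
#' `lambda = sum Var(r_ij) / sum r_ij^2` over off-diagonal entries,
#' clamped to `[0, 1]`. For any `lambda > 0` the shrunken matrix is
#' positive definite, so its inverse (and hence partial correlations)
#' exists even when traits outnumber samples.
#'
#' @param x samples x traits matrix (e.g. output of [residualize()]).
#' @param lambda optional fixed intensity overriding the analytic
#'   estimate.
#' @return List: `R_star` (shrunken correlation matrix), `lambda`,
#'   `lambda_estimated` (the analytic value before any override), `n`.
#' @export
shrinkage_correlation <- function(x, lambda = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)                       # centered, unit variance
  R <- crossprod(z) / (n - 1)
  # Var(r_ij) from the empirical variance of the per-sample products
  # w_kij = z_ki z_kj:  Var(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar)^2
  sum_var <- 0; sum_r2 <- 0
  w_mean <- R * (n - 1) / n
  for (j in seq_len(p - 1)) {
    wj <- z[, j] * z[, (j + 1):p, drop = FALSE]
    vw <- colSums(sweep(wj, 2, w_mean[j, (j + 1):p], `-`)^2)
    sum_var <- sum_var + n / (n - 1)^3 * sum(vw)
    sum_r2 <- sum_r2 + sum(R[j, (j + 1):p]^2)
  }
  lam_est <- if (sum_r2 > 0) min(1, max(0, sum_var / sum_r2)) else 1
  lam <- if (is.null(lambda)) lam_est else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
    lambda
  }
  R_star <- (1 - lam) * R
  diag(R_star) <- 1
  list(R_star = R_star, lambda = lam, lambda_estimated = lam_est, n = n)
}

#' Partial correlations from a (shrunken) correlation matrix
#'
#' Inverts the correlation matrix and scales the negated off-diagonal
#' precision entries: `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`,
#' unit diagonal.
#'
#' @param R_star positive-definite correlation matrix.
#' @return Symmetric partial-correlation matrix.
#' @export
partial_correlations <- function(R_star) {
  ch <- tryCatch(chol(R_star), error = function(e) NULL)
  if (is.null(ch)) stop("correlation matrix is not positive definite")
  omega <- chol2inv(ch)
  pc <- -omega / sqrt(diag(omega) %o% diag(omega))
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2              # exact symmetry
  dimnames(pc) <- dimnames(R_star)
  pc
}

#' Call significant partial-correlation edges
#'
#' P values per trait pair come either from the normal approximation to
#' the Fisher z-transform of the partial correlation, with effective
#' degrees of freedom `n - (T - 2) - 3` (the `T - 2` other traits are
#' conditioned on), or from an empirical permutation null (independent
#' column permutations; the null pools |pcor| over all pairs and
#' permutations). Edges are the pairs with
#' `p < alpha / (T (T - 1) / 2)` — the Bonferroni bound over all pairs.
#'
#' @param pcor symmetric partial-correlation matrix.
#' @param n number of samples behind `pcor`.
#' @param method `"fisher"` (default) or `"permutation"`.
#' @param alpha nominal level (default 0.05).
#' @param residuals residual matrix (required for `"permutation"`).
#' @param n_perm number of column permutations (default 200).
#' @param lambda shrinkage intensity to reuse in permutation refits
#'   (`NULL`: re-estimated per permutation).
#' @param seed seed for the permutation null.
#' @return List: `edge_p` (symmetric matrix), `edges` (data.frame
#'   `trait_i`, `trait_j`, `pcor`, `p`), `threshold`, `method`.
#' @export
call_edges <- function(pcor, n, method = c("fisher", "permutation"),
                       alpha = 0.05, residuals = NULL, n_perm = 200L,
                       lambda = NULL, seed = 1L) {
  method <- match.arg(method)
  T_ <- ncol(pcor)
  threshold <- bonferroni_threshold(alpha, T_ * (T_ - 1) / 2)
  if (method == "fisher") {
    kappa <- n - (T_ - 2) - 3
    if (kappa < 3)
      stop("effective degrees of freedom n - (T - 2) - 3 = ", kappa,
           " < 3; use method = \"permutation\"")
    z <- atanh(pmin(pmax(pcor, -1 + 1e-15), 1 - 1e-15))
    edge_p <- 2 * stats::pnorm(-abs(z) * sqrt(kappa))
  } else {
    if (is.null(residuals))
      stop("permutation method needs the residual matrix")
    obs <- abs(pcor[upper.tri(pcor)])
    null_vals <- numeric(0)
    for (b in seq_len(n_perm)) {
      set.seed(sub_seed(seed, paste0("ggm-perm-", b)))
      perm <- apply(residuals, 2, sample)
      sc <- shrinkage_correlation(perm, lambda = lambda)
      pcp <- partial_correlations(sc$R_star)
      null_vals <- c(null_vals, abs(pcp[upper.tri(pcp)]))
    }
    null_sorted <- sort(null_vals)
    exceed <- length(null_vals) -
      findInterval(obs - 1e-15, null_sorted)
    pv <- (1 + exceed) / (1 + length(null_vals))
    edge_p <- matrix(1, T_, T_, dimnames = dimnames(pcor))
    edge_p[upper.tri(edge_p)] <- pv
    edge_p <- pmin(edge_p, t(edge_p))
  }
  diag(edge_p) <- 1
  edge_p <- (edge_p + t(edge_p)) / 2
  dimnames(edge_p) <- dimnames(pcor)
  ids <- colnames(pcor)
  if (is.null(ids)) ids <- paste0("T", seq_len(T_))
  ut <- which(upper.tri(pcor) & edge_p < threshold, arr.ind = TRUE)
  edges <- data.frame(trait_i = ids[ut[, 1]], trait_j = ids[ut[, 2]],
                      pcor = pcor[ut], p = edge_p[ut],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p, edges$trait_i, edges$trait_j), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(edge_p = edge_p, edges = edges, threshold = threshold,
       method = method)
}

#' Fit a shrinkage Gaussian graphical model of the trait panel
#'
#' End-to-end GGM construction: residualize raw traits on covariates,
#' shrink the sample correlation matrix toward the identity with the
#' analytic optimal intensity, invert to partial correlations, and call
#' Bonferroni-significant edges.
#'
#' @param traits a [trait_matrix()] (raw scale) or numeric matrix.
#' @param covariates optional covariate matrix regressed out first.
#' @param method edge P value mode, see [call_edges()].
#' @param alpha nominal level.
#' @param lambda optional fixed shrinkage intensity.
#' @param n_perm,seed permutation-mode settings.
#' @return Object of class `ggm_fit`: `lambda`, `pcor`, `edge_p`,
#'   `edges`, `threshold`, `n`, `n_traits`, `method`, `n_imputed`.
#' @export
ggm_fit <- function(traits, covariates = NULL,
                    method = c("fisher", "permutation"), alpha = 0.05,
                    lambda = NULL, n_perm = 200L, seed = 1L) {
  method <- match.arg(method)
  res <- residualize(traits, covariates)
  sc <- shrinkage_correlation(res, lambda = lambda)
  pc <- partial_correlations(sc$R_star)
  ce <- call_edges(pc, n = sc$n, method = method, alpha = alpha,
                   residuals = res, n_perm = n_perm, lambda = lambda,
                   seed = seed)
  structure(list(lambda = sc$lambda,
                 lambda_estimated = sc$lambda_estimated,
                 pcor = pc, edge_p = ce$edge_p, edges = ce$edges,
                 threshold = ce$threshold, n = sc$n, n_traits = ncol(pc),
                 method = method,
                 n_imputed = attr(res, "n_imputed")),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("ggm_fit:", x$n_traits, "traits, n =", x$n, "\n")
  cat("  shrinkage lambda:", signif(x$lambda, 3),
      "(analytic estimate", paste0(signif(x$lambda_estimated, 3), ")\n"))
  cat("  edges:", nrow(x$edges), "at p <",
      format(x$threshold, digits = 3), "(", x$method, ")\n")
  invisible(x)
}
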