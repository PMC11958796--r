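#' Optimal rigid-body superposition of paired abundance matrices
#'
#' Finds the translation and proper rotation of the starting compositions `x`
#' that minimise the root-mean-square deviation (RMSD) from the paired final
#' compositions `y` (row i of `x` is the parent of row i of `y`). Both
#' matrices are centred on their column means; the rotation is obtained from
#' the singular value decomposition of the cross-covariance `Xc' Yc = U S V'`
#' as `Q = U C V'` with `C = diag(1, ..., 1, det(U V'))`, which forbids
#' reflections (the standard Kabsch determinant correction). The fitted
#' points are `Xc Q + centroid(y)`.
#'
#' @param x,y [rel_abund()] matrices (or plain numeric matrices) with
#'   identical dimensions, identical ASV columns, and row-paired samples;
#'   at least 3 rows.
#' @return object of class `"superposition"`: list with `rotation` (p x p
#'   proper orthogonal), `translation` (the y centroid minus the rotated x
#'   centroid), `x_center`, `y_center`, `rmsd`, and the dimnames needed to
#'   apply the transform to new tables.
#' @export
kabsch_fit <- function(x, y) {
  x <- unclass(x); y <- unclass(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  if (!is.null(colnames(x)) && !is.null(colnames(y)) &&
      !identical(colnames(x), colnames(y)))
    stop("x and y must share the same ASV columns in the same order")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    stop("x and y rows must be paired (same sample order)")
  if (nrow(x) < 3) stop("at least 3 paired samples required")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  dsign <- sign(det(s$u %*% t(s$v)))
  if (dsign == 0) dsign <- 1
  corr <- c(rep(1, ncol(x) - 1), dsign)
  rot <- s$u %*% (corr * t(s$v))
  fitted <- xc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  structure(list(rotation = rot,
                 translation = cy - as.vector(cx %*% rot),
                 x_center = cx, y_center = cy,
                 rmsd = rmsd,
                 asv_ids = colnames(x)),
            class = "superposition")
}

#' Apply a fitted superposition to a table of compositions
#'
#' @param fit a `"superposition"` from [kabsch_fit()].
#' @param x matrix with the same ASV columns as the fit.
#' @return the transformed matrix (rows move rigidly; entries are no longer
#'   guaranteed to be proportions).
#' @export
apply_superposition <- function(fit, x) {
  x <- unclass(x)
  if (!is.null(colnames(x)) && !is.null(fit$asv_ids) &&
      !identical(colnames(x), fit$asv_ids))
    stop("ASV columns do not match the fitted transform")
  out <- sweep(x, 2, fit$x_center) %*% fit$rotation
  out <- sweep(out, 2, fit$y_center, `+`)
  dimnames(out) <- dimnames(x)
  out
}

#' Null RMSD confidence interval from cell-shuffled starting matrices
#'
#' Repeats the superposition after flattening `x` and randomly permuting all
#' of its cells (destroying both the sample and the ASV structure while
#' keeping the value distribution), refitting against the unmodified `y`
#' each time. The 2.5th and 97.5th percentiles of the null RMSDs form a 95%
#' confidence interval against which the observed RMSD is judged.
#'
#' @param x,y as in [kabsch_fit()].
#' @param n_rand number of shuffles (default 50).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `null_rmsd` (all n_rand values),
#'   `n_randomisations`.
#' @export
randomised_rmsd_ci <- function(x, y, n_rand = 50, seed = 1) {
  if (n_rand < 2) warning("n_rand < 2 gives a degenerate confidence interval")
  x <- unclass(x)
  null_rmsd <- with_seed(seed, vapply(seq_len(n_rand), function(i) {
    xs <- matrix(sample(as.vector(x)), nrow(x), ncol(x),
                 dimnames = dimnames(x))
    kabsch_fit(xs, y)$rmsd
  }, numeric(1)))
  q <- unname(stats::quantile(null_rmsd, c(0.025, 0.975)))
  list(lower = q[1], upper = q[2], null_rmsd = null_rmsd,
       n_randomisations = n_rand)
}

#' Compare SVD components of transformed starts against held-out replicates
#'
#' Applies a fitted superposition to the starting compositions and contrasts
#' the first and second singular-value-decomposition component scores (left
#' singular vectors scaled by their singular values, after centring each
#' matrix on its own column means by default) of the prediction against each
#' held-out final replicate. Component signs are aligned so the paired
#' Pearson correlation is non-negative; the reported R-squared is unaffected
#' by that choice.
#'
#' @param x starting compositions (rows paired with every holdout).
#' @param fit `"superposition"` from [kabsch_fit()].
#' @param holdouts named list of final-replicate matrices, row-paired with `x`.
#' @param n_components number of leading components to compare (default 2).
#' @param center centre matrices on column means before the SVD (default TRUE).
#' @return data.frame with columns `replicate_id`, `component`, `r_squared`,
#'   `p_value`, `slope`, `intercept`.
#' @export
predict_and_compare <- function(x, fit, holdouts, n_components = 2, center = TRUE) {
  if (nrow(unclass(x)) < 3) stop("at least 3 paired samples required")
  pred <- apply_superposition(fit, x)
  scores <- function(m) {
    m <- unclass(m)
    if (center) m <- sweep(m, 2, colMeans(m))
    s <- svd(m, nu = n_components, nv = 0)
    s$u %*% diag(s$d[seq_len(n_components)], n_components)
  }
  sp <- scores(pred)
  out <- lapply(names(holdouts), function(id) {
    sh <- scores(holdouts[[id]])
    do.call(rbind, lapply(seq_len(n_components), function(cc) {
      a <- sp[, cc]; b <- sh[, cc]
      if (stats::cor(a, b) < 0) b <- -b
      ct <- stats::cor.test(a, b, alternative = "two.sided")
      lmfit <- stats::lm(b ~ a)
      data.frame(replicate_id = id, component = cc,
                 r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 slope = unname(stats::coef(lmfit)[2]),
                 intercept = unname(stats::coef(lmfit)[1]))
    }))
  })
  do.call(rbind, out)
}
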