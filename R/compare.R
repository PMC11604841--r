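#' Eight-region lung partition about the carina
#'
#' Splits the lung mask into {left, right} x {superior, inferior} x
#' {anterior, posterior} by the three planes through the carina voxel:
#' sagittal (x) for left/right, transverse (z) for superior/inferior, and
#' coronal (y) for anterior/posterior.  Under the package axis convention
#' (x: right to left), voxels with `x < carina_x` belong to the right
#' lung.  Labels 1-8; every masked voxel gets exactly one label.
#'
#' @param mask logical 3D lung mask.
#' @param carina_voxel numeric(3), 1-based (x, y, z) of the carina.
#' @return a `region_partition`: `labels` (integer array, 0 outside),
#'   `names` (label -> region name), `carina_voxel`.  Empty regions
#'   trigger a warning.
#' @export
split_regions <- function(mask, carina_voxel) {
  dm <- dim(mask)
  stopifnot(length(carina_voxel) == 3,
            all(carina_voxel >= 1), all(carina_voxel <= dm))
  g <- coord_grids(dm)
  left <- g$x >= carina_voxel[1]           # x: right -> left
  sup <- g$z >= carina_voxel[3]            # z: inferior -> superior
  post <- g$y >= carina_voxel[2]           # y: anterior -> posterior
  lab <- 1L + left + 2L * sup + 4L * post
  lab[!mask] <- 0L
  nm <- as.vector(outer(outer(c("right", "left"), c("inferior", "superior"),
                              paste, sep = "-"),
                        c("anterior", "posterior"), paste, sep = "-"))
  counts <- tabulate(lab[mask], nbins = 8)
  if (any(counts == 0))
    warning("empty regions: ", paste(nm[counts == 0], collapse = ", "))
  structure(list(labels = lab, names = nm,
                 carina_voxel = carina_voxel),
            class = "region_partition")
}

#' Regional VDP from a defect mask and a partition
#'
#' @param defect logical defect mask.
#' @param mask logical lung mask.
#' @param partition a `region_partition` from [split_regions()].
#' @return data.frame: region, n_voxels, vdp_percent (plus a `global` row).
#' @export
regional_vdp <- function(defect, mask, partition) {
  lab <- partition$labels
  rows <- lapply(1:8, function(l) {
    sel <- lab == l & mask
    data.frame(region = partition$names[l], n_voxels = sum(sel),
               vdp_percent = if (sum(sel) > 0)
                 100 * sum(defect & sel) / sum(sel) else NA_real_)
  })
  rbind(data.frame(region = "global", n_voxels = sum(mask),
                   vdp_percent = 100 * sum(defect & mask) / sum(mask)),
        do.call(rbind, rows))
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A and B| / (|A| + |B|)`; if both masks are empty the DSC is
#' defined as 1 with attribute `both_empty = TRUE`.
#'
#' @param a,b logical arrays of identical shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Slab-average a 3D map along one axis
#'
#' Non-overlapping mean pooling (to match a thick-slice comparator's
#' out-of-plane resolution); boolean inputs are pooled as 0/1 and
#' re-binarized with the tie rule `>= 0.5 -> defect`.  A trailing
#' incomplete slab is pooled over its actual extent with a warning.
#'
#' @param map3d 3D array (numeric or logical).
#' @param slab_vox slab thickness in voxels.
#' @param axis axis to pool along (default 2, anterior-posterior).
#' @return pooled map, same shape (each voxel carries its slab value).
#' @export
slab_match <- function(map3d, slab_vox, axis = 2) {
  stopifnot(slab_vox >= 1)
  was_logical <- is.logical(map3d)
  if (dim(map3d)[axis] %% slab_vox != 0)
    warning("axis extent not divisible by slab; last slab truncated")
  out <- slab_average(map3d + 0, slab_vox, axis)
  if (was_logical) out <- out >= 0.5
  out
}

#' Bland-Altman agreement
#'
#' Differences `d = x - y`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 sd(d)` (sample SD, n-1 denominator).
#'
#' @param x,y paired numeric vectors (length >= 2).
#' @return list: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s, n = length(d))
}

#' Mixed-effects correlation with marginal R-squared and Satterthwaite p
#'
#' Fits `y = b0 + b1 x + u_subject + e` by restricted maximum likelihood
#' (random subject intercept), computed directly on the dense
#' generalized-least-squares form.  The marginal coefficient of
#' determination is the Nakagawa-Schielzeth form
#' `var(b1 x) / (var(b1 x) + s2_u + s2_e)`, and the p-value for `b1` uses
#' a t-test with Satterthwaite degrees of freedom (delta method on the
#' REML variance-parameter covariance).  A boundary fit (`s2_u = 0`)
#' reduces to ordinary least squares with `n - 2` df and is reported as
#' such.
#'
#' @param x,y numeric vectors.
#' @param subject_ids grouping factor (>= 3 subjects).
#' @return list: `beta` (intercept, slope), `r2_marginal`, `p_value`,
#'   `df_satterthwaite`, `sigma2_u`, `sigma2_e`, `singular`.
#' @export
lmm_correlation <- function(x, y, subject_ids) {
  subject_ids <- as.factor(subject_ids)
  stopifnot(length(x) == length(y), length(x) == length(subject_ids))
  if (nlevels(subject_ids) < 3) stop("need at least 3 subjects")
  n <- length(y)
  X <- cbind(1, x)
  Z <- stats::model.matrix(~ subject_ids - 1)
  ZZt <- Z %*% t(Z)
  In <- diag(n)
  # profiled REML in gamma = s2_u / s2_e
  reml <- function(log_gamma) {
    V0 <- In + exp(log_gamma) * ZZt
    ch <- chol(V0)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    beta <- solve(XtViX, XtVi %*% y)
    r <- y - X %*% beta
    q <- as.numeric(crossprod(r, Vi %*% r))
    s2 <- q / (n - ncol(X))
    ll <- -0.5 * ((n - ncol(X)) * log(s2) + 2 * sum(log(diag(ch))) +
                    log(det(XtViX)) + (n - ncol(X)))
    list(ll = ll, beta = beta, s2e = s2, s2u = exp(log_gamma) * s2, Vi = Vi,
         XtViX = XtViX)
  }
  opt <- stats::optimize(function(lg) -reml(lg)$ll, c(-12, 8))
  # flat profile (e.g. one observation per subject): the variance split is
  # unidentifiable; take the boundary s2_u -> 0 (ordinary regression)
  if (reml(-12)$ll >= reml(opt$minimum)$ll - 1e-8) opt$minimum <- -12
  fit <- reml(opt$minimum)
  singular <- fit$s2u < 1e-4 * (fit$s2u + fit$s2e)
  # covariance of beta at (s2u, s2e)
  vc_beta <- function(th) {
    V <- th[2] * In + th[1] * ZZt
    Vi <- solve(V)
    solve(crossprod(X, Vi %*% X))
  }
  th <- c(fit$s2u, fit$s2e)
  f_slope <- function(th) vc_beta(th)[2, 2]
  var_b1 <- f_slope(th)
  se_b1 <- sqrt(var_b1)
  tstat <- fit$beta[2] / se_b1
  if (singular) {
    df <- n - 2
  } else {
    # Satterthwaite: df = 2 f^2 / (g' A g), A = cov(th_hat) from the
    # observed REML information, g = grad f (central differences)
    ll_th <- function(th) {
      V <- th[2] * In + th[1] * ZZt
      ch <- chol(V)
      Vi <- chol2inv(ch)
      XtViX <- crossprod(X, Vi %*% X)
      beta <- solve(XtViX, crossprod(X, Vi %*% y))
      r <- y - X %*% beta
      -0.5 * (2 * sum(log(diag(ch))) + log(det(XtViX)) +
                as.numeric(crossprod(r, Vi %*% r)))
    }
    hstep <- pmin(pmax(1e-4 * th, 1e-8), th / 4)
    ll_safe <- function(t2) tryCatch(ll_th(pmax(t2, 1e-300)),
                                     error = function(e) NA_real_)
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
      H[i, j] <- (ll_safe(th + ei + ej) - ll_safe(th + ei - ej) -
                    ll_safe(th - ei + ej) + ll_safe(th - ei - ej)) /
        (4 * hstep[i] * hstep[j])
    }
    A <- if (anyNA(H)) NULL else tryCatch(solve(-H), error = function(e) NULL)
    g <- numeric(2)
    for (i in 1:2) {
      ei <- c(0, 0); ei[i] <- hstep[i]
      g[i] <- (f_slope(th + ei) - f_slope(pmax(th - ei, 1e-12))) /
        (th[i] + ei[i] - pmax(th[i] - ei[i], 1e-12))
    }
    df <- if (is.null(A)) n - 2 else {
      den <- as.numeric(t(g) %*% A %*% g)
      if (den <= 0) n - 2 else min(2 * var_b1^2 / den, 1e6)
    }
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  fix_var <- stats::var(as.numeric(fit$beta[2] * x))
  r2 <- fix_var / (fix_var + fit$s2u + fit$s2e)
  list(beta = as.numeric(fit$beta), r2_marginal = r2, p_value = p,
       df_satterthwaite = df, sigma2_u = if (singular) 0 else fit$s2u,
       sigma2_e = fit$s2e, singular = singular, t = as.numeric(tstat))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise t-tests
#'
#' Standard one-way F-test across the named groups, then all pairwise
#' two-sample t-tests (pooled variance) with p-values multiplied by the
#' number of comparisons (clipped at 1).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list: `anova_p`, `F`, `pairwise_p` (named vector,
#'   Bonferroni-adjusted), `pairwise_p_raw`.
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  v <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, 1L)),
              labels = names(groups))
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))))
    stop("zero within-group variance in all groups")
  k <- nlevels(f); n <- length(v)
  ssb <- sum(tapply(v, f, function(g) length(g) * (mean(g) - mean(v))^2))
  ssw <- sum(tapply(v, f, function(g) sum((g - mean(g))^2)))
  Fst <- (ssb / (k - 1)) / (ssw / (n - k))
  anova_p <- stats::pf(Fst, k - 1, n - k, lower.tail = FALSE)
  prs <- utils::combn(names(groups), 2)
  m <- ncol(prs)
  raw <- vapply(seq_len(m), function(j) {
    a <- groups[[prs[1, j]]]; b <- groups[[prs[2, j]]]
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  names(raw) <- paste(prs[1, ], prs[2, ], sep = " vs ")
  list(anova_p = anova_p, F = Fst, pairwise_p = pmin(raw * m, 1),
       pairwise_p_raw = raw)
}
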