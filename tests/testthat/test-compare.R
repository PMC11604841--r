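test_that("region partition: counting, exact partition, boundary warning", {
  mask <- array(FALSE, c(20, 20, 20))
  mask[3:18, 3:18, 3:18] <- TRUE           # cuboid, centroid (10.5, ...)
  p <- split_regions(mask, c(11, 11, 11))
  counts <- tabulate(p$labels[mask], nbins = 8)
  expect_equal(sum(counts), sum(mask))
  expect_true(all(abs(counts - sum(mask) / 8) / (sum(mask) / 8) < 0.1))
  # every masked voxel gets exactly one label; outside 0
  expect_true(all(p$labels[mask] %in% 1:8))
  expect_true(all(p$labels[!mask] == 0))
  # carina on the mask's face -> empty regions + warning
  expect_warning(split_regions(mask, c(3, 11, 11)), "empty")
})

test_that("volume-weighted regional VDPs recombine to the global VDP", {
  set.seed(13)
  for (rep in 1:20) {
    dm <- c(12, 12, 12)
    mask <- array(runif(prod(dm)) < 0.4, dm)
    if (!any(mask)) next
    defect <- mask & array(runif(prod(dm)) < 0.25, dm)
    car <- c(sample(3:10, 1), sample(3:10, 1), sample(3:10, 1))
    p <- suppressWarnings(split_regions(mask, car))
    tab <- regional_vdp(defect, mask, p)
    reg <- tab[tab$region != "global" & tab$n_voxels > 0, ]
    recomb <- sum(reg$vdp_percent * reg$n_voxels) / sum(reg$n_voxels)
    expect_equal(recomb, tab$vdp_percent[tab$region == "global"],
                 tolerance = 1e-12)
  }
})

test_that("dice: exact toys, symmetry, padding invariance", {
  a <- array(FALSE, c(4, 4, 1)); a[1:4] <- TRUE
  expect_equal(dice(a, a), 1.0, ignore_attr = TRUE)
  b <- array(FALSE, c(4, 4, 1)); b[13:16] <- TRUE
  expect_equal(dice(a, b), 0.0)
  cc <- array(FALSE, c(4, 4, 1)); cc[3:6] <- TRUE
  expect_equal(dice(a, cc), 0.5)       # |a|=4, |b|=4, overlap 2
  expect_error(dice(a, array(FALSE, c(4, 5, 1))), "mismatch")
  d0 <- dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2)))
  expect_equal(as.numeric(d0), 1)
  expect_true(attr(d0, "both_empty"))
  set.seed(14)
  for (rep in 1:100) {
    x <- array(runif(64) < 0.3, c(4, 4, 4))
    y <- array(runif(64) < 0.3, c(4, 4, 4))
    d <- dice(x, y)
    expect_identical(d, dice(y, x))
    xp <- array(FALSE, c(6, 6, 6)); xp[2:5, 2:5, 2:5] <- x
    yp <- array(FALSE, c(6, 6, 6)); yp[2:5, 2:5, 2:5] <- y
    expect_identical(as.numeric(d), as.numeric(dice(xp, yp)))
  }
})

test_that("slab matching: identity, tie rule, mean conservation", {
  m <- array(runif(48), c(4, 6, 2))
  expect_identical(slab_match(m, 1), m + 0)
  expect_equal(mean(slab_match(m, 3)), mean(m), tolerance = 1e-12)
  # alternating 0/1 column, slab 2 -> pooled 0.5 -> binarized to 1 (>= .5)
  b <- array(FALSE, c(1, 6, 1)); b[1, c(1, 3, 5), 1] <- TRUE
  pooled <- slab_match(b, 2)
  expect_true(all(pooled))
  expect_warning(slab_match(m, 4), "truncated")
})

test_that("Bland-Altman arithmetic and properties", {
  # d = (1, -1, 0): bias 0, sd 1, LoA +/- 1.96
  ba <- bland_altman(c(2, 0, 1), c(1, 1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  # self-comparison: zero bias, zero-width LoA
  x <- runif(10)
  ba2 <- bland_altman(x, x)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)
  # translation shifts bias only
  ba3 <- bland_altman(c(2, 0, 1) + 5, c(1, 1, 1))
  expect_equal(ba3$bias, 5)
  expect_equal(ba3$loa_high - ba3$loa_low, ba$loa_high - ba$loa_low)
  expect_error(bland_altman(1, 1), "2")
})

test_that("mixed model matches lme4 and the OLS limit", {
  set.seed(15)
  n_subj <- 12
  id <- rep(seq_len(n_subj), each = 2)
  x <- rnorm(2 * n_subj, 10, 3)
  y <- 2 + 0.5 * x + rep(rnorm(n_subj, 0, 1.5), each = 2) +
    rnorm(2 * n_subj, 0, 1)
  fit <- lmm_correlation(x, y, id)
  m <- lme4::lmer(y ~ x + (1 | id), REML = TRUE)
  expect_equal(fit$beta, unname(lme4::fixef(m)), tolerance = 1e-4)
  expect_equal(fit$sigma2_u,
               unname(as.numeric(lme4::VarCorr(m)$id)), tolerance = 1e-3)
  expect_equal(fit$sigma2_e, unname(stats::sigma(m)^2), tolerance = 1e-3)
  # Satterthwaite df sits between the subject- and observation-level df
  expect_gt(fit$df_satterthwaite, n_subj - 2)
  expect_lt(fit$df_satterthwaite, 2 * n_subj - 2)

  # one observation per subject: OLS equivalence
  x1 <- rnorm(400); y1 <- 1 + 0.3 * x1 + rnorm(400)
  f1 <- lmm_correlation(x1, y1, seq_len(400))
  s1 <- summary(lm(y1 ~ x1))
  expect_true(f1$singular)
  expect_lt(abs(f1$r2_marginal - s1$r.squared), 1e-3)
  expect_equal(f1$p_value, unname(coef(s1)[2, 4]), tolerance = 1e-9)
  expect_equal(f1$df_satterthwaite, 398)

  # perfect fit: r2 -> 1, p -> 0
  yp <- 2 * x[1:24] + 1e-8 * rnorm(24)
  fp <- lmm_correlation(x[1:24], yp, id)
  expect_gt(fp$r2_marginal, 0.999)
  expect_lt(fp$p_value, 1e-12)
  expect_error(lmm_correlation(1:4, 1:4, c(1, 1, 2, 2)), "3 subjects")
})

test_that("simulated mixed model: slope unbiased, CI-level sane", {
  set.seed(16)
  nrep <- 120
  b1 <- numeric(nrep)
  for (r in seq_len(nrep)) {
    id <- rep(1:12, each = 2)
    x <- rnorm(24, 5, 2)
    y <- 1 + 0.8 * x + rep(rnorm(12, 0, 1), each = 2) + rnorm(24, 0, 0.7)
    b1[r] <- lmm_correlation(x, y, id)$beta[2]
  }
  expect_lt(abs(mean(b1) - 0.8), 3 * sd(b1) / sqrt(nrep))
})

test_that("ANOVA + Bonferroni matches hand computation", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(7, 8, 9))
  res <- anova_bonferroni(g)
  # ssb = 72, ssw = 6, F = (72/2)/(6/6) = 36
  expect_equal(res$F, 36)
  expect_equal(res$anova_p, stats::pf(36, 2, 6, lower.tail = FALSE))
  expect_equal(length(res$pairwise_p), 3)
  expect_equal(res$pairwise_p,
               pmin(res$pairwise_p_raw * 3, 1), tolerance = 1e-12)
  # identical groups: F ~ 0, all adjusted p = 1
  res0 <- anova_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res0$F, 0)
  expect_equal(unname(res0$pairwise_p), 1)
  expect_error(anova_bonferroni(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group")
})
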