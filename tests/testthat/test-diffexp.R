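test_that("two-group fit matches per-gene closed-form recomputation", {
  study <- fixture_6x6()
  fit <- fit_two_group(study, c("CASE", "CONTROL"))
  expect_equal(fit$df, 4)
  expect_equal(fit$u, sqrt(2 / 3))
  for (g in seq_len(6)) {
    a <- study$matrix[g, 1:3]; b <- study$matrix[g, 4:6]
    expect_equal(fit$log2fc[g], mean(a) - mean(b))
    expect_equal(fit$s2[g],
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4)
  }
  # constant gene has zero variance, kept for moderation rescue
  expect_equal(fit$s2[2], 0)
  expect_error(fit_two_group(study, c("CASE", "NOPE")), "NOPE")
})

test_that("fold change is the difference of group means", {
  m <- matrix(rep(c(5, 3), each = 2), nrow = 1)
  m <- rbind(m, m + 1)
  dimnames(m) <- list(c("G1", "G2"), paste0("S", 1:4))
  st <- expression_study(m + matrix(c(0, .1, 0, .1, 0, .1, 0, .1), 2),
                        setNames(rep(c("A", "B"), each = 2), colnames(m)))
  fit <- fit_two_group(st, c("A", "B"))
  expect_equal(fit$log2fc, c(2, 2))
})

test_that("prior estimation recovers planted hyperparameters", {
  set.seed(3)
  G <- 5000; d0 <- 4; s0 <- 1; d <- 4
  sigma2 <- s0 * d0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  pr <- estimate_prior(s2, d)
  expect_gt(pr$d0, 3); expect_lt(pr$d0, 5)
  expect_gt(pr$s0_sq, 0.9); expect_lt(pr$s0_sq, 1.1)
})

test_that("prior estimation degenerates safely", {
  # identical variances: dispersion below sampling floor -> d0 = Inf
  pr <- estimate_prior(rep(0.5, 100), 4)
  expect_identical(pr$d0, Inf)
  # too few genes -> fallback with warning
  expect_warning(pr2 <- estimate_prior(c(0.4, 0.5, 0.6, 0.5, 0.4), 4),
                 "fewer than 10")
  expect_identical(pr2$d0, Inf)
  expect_error(estimate_prior(rep(0, 50), 4), "degenerate")
})

test_that("trigamma inversion solves trigamma(x) = y across scales", {
  for (x in c(0.01, 0.5, 2, 10, 1e4))
    expect_equal(proteosig:::trigamma_inverse(trigamma(x)), x,
                 tolerance = 1e-6)
})

test_that("moderated t reduces to the pooled t at d0 = 0", {
  study <- fixture_6x6()
  fit <- fit_two_group(study, c("CASE", "CONTROL"))
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "moderation_prior")
  tab <- moderated_t(fit, prior0)
  keep <- fit$s2 > 0
  ordinary <- fit$log2fc[keep] / (fit$u * sqrt(fit$s2[keep]))
  expect_equal(tab$t[match(fit$gene[keep], tab$gene)], ordinary,
               tolerance = 1e-10)
})

test_that("moderated t at d0 = Inf uses one shared variance and normal tails", {
  study <- fixture_6x6()
  fit <- fit_two_group(study, c("CASE", "CONTROL"))
  prior <- structure(list(d0 = Inf, s0_sq = 0.04),
                     class = "moderation_prior")
  tab <- moderated_t(fit, prior)
  expect_equal(tab$t, fit$log2fc / (fit$u * 0.2), tolerance = 1e-12)
  expect_equal(tab$p, pmin(2 * pnorm(-abs(tab$t)), 1), tolerance = 1e-12)
})

test_that("zero effect gives t = 0 and p = 1", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
              dimnames = list("G1", paste0("S", 1:6)))
  m <- rbind(G1 = m[1, ], G2 = c(2, 3, 4, 2, 3, 4))
  colnames(m) <- paste0("S", 1:6)
  st <- expression_study(m, setNames(rep(c("A", "B"), 3)[c(1, 3, 5, 2, 4, 6)],
                                     colnames(m)))
  st <- expression_study(m, setNames(c("A", "A", "A", "B", "B", "B"),
                                     colnames(m)))
  tab <- moderated_t(fit_two_group(st, c("A", "B")),
                     structure(list(d0 = 4, s0_sq = 1),
                               class = "moderation_prior"))
  expect_equal(tab$t, c(0, 0))
  expect_equal(tab$p, c(1, 1))
})

test_that("posterior variance shrinks monotonically toward the prior", {
  spec <- small_spec(seed = 21, n_per_group = 3, n_stages = 1)
  u <- make_universe(spec)
  st <- make_staged_expression(spec, u$universe$genes[1:50], u$universe,
                               "early")
  fit <- fit_two_group(st, c("STAGE_1", "CONTROL"))
  pr <- estimate_prior(fit$s2, fit$df)
  tab <- moderated_t(fit, pr)
  lo <- pmin(tab$s2, pr$s0_sq) - 1e-12
  hi <- pmax(tab$s2, pr$s0_sq) + 1e-12
  expect_true(all(tab$s2_post >= lo & tab$s2_post <= hi))
})

test_that("moderated t agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(99)
  G <- 300
  sigma2 <- 0.5 * 8 / rchisq(G, 8)
  m <- matrix(rnorm(G * 8, sd = sqrt(sigma2)), nrow = G)
  m[1:30, 1:4] <- m[1:30, 1:4] + 1.5
  dimnames(m) <- list(paste0("G", 1:G), paste0("S", 1:8))
  st <- expression_study(m, setNames(rep(c("CASE", "CONTROL"), each = 4),
                                     colnames(m)))
  fit <- fit_two_group(st, c("CASE", "CONTROL"))
  pr <- estimate_prior(fit$s2, fit$df)
  tab <- moderated_t(fit, pr)

  design <- cbind(Intercept = 1, case = rep(c(1, 0), each = 4))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(pr$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, unname(lf$t[, "case"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(lf$p.value[, "case"]), tolerance = 1e-8)
})

test_that("direction calls follow the sign of the fold change at the cutoff", {
  spec <- small_spec(seed = 5, n_per_group = 10, n_stages = 1)
  u <- make_universe(spec)
  aff <- u$universe$genes[1:100]
  st <- make_staged_expression(spec, aff, u$universe, "early")
  tab <- run_de(st, c("STAGE_1", "CONTROL"))
  sig <- tab[tab$adj_p < 0.05, ]
  expect_true(all(sig$direction == sign(sig$log2fc)))
  expect_true(all(tab$direction[tab$adj_p >= 0.05] == 0))
  truth <- attr(st, "affected")
  called <- de_signs(tab)
  agree <- intersect(names(called), names(truth))
  expect_gt(length(agree) / length(truth), 0.75)
  expect_true(all(called[agree] == truth[agree]))
})
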