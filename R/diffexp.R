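#' Ordinary two-group fit per gene
#'
#' For each gene, the log2 fold change between two conditions, the pooled
#' residual variance with its degrees of freedom, and the unscaled standard
#' deviation of the contrast.
#'
#' @param study An [expression_study()] on log2 scale.
#' @param contrast Character vector `c(condition_a, condition_b)`; the fold
#'   change is mean(a) - mean(b), so `b` is typically the control.
#' @return An object of class `two_group_fit`: a list with per-gene vectors
#'   `log2fc` and `s2`, and scalars `df` (residual degrees of freedom
#'   `n_a + n_b - 2`), `u` (`sqrt(1/n_a + 1/n_b)`), `n_a`, `n_b`.
#' @export
fit_two_group <- function(study, contrast) {
  stopifnot(length(contrast) == 2)
  for (cond in contrast)
    if (!cond %in% study$condition)
      stop("condition '", cond, "' not present in sample metadata")
  a <- study$matrix[, study$condition == contrast[1], drop = FALSE]
  b <- study$matrix[, study$condition == contrast[2], drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2 || n_b < 2)
    stop("need at least 2 samples per contrasted condition")
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  rss <- rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)
  df <- n_a + n_b - 2
  structure(list(gene = rownames(study$matrix),
                 log2fc = unname(mean_a - mean_b),
                 s2 = unname(rss / df),
                 df = df,
                 u = sqrt(1 / n_a + 1 / n_b),
                 n_a = n_a, n_b = n_b,
                 contrast = contrast),
            class = "two_group_fit")
}

# solve trigamma(x) = y by Newton iteration (monotone decreasing, convex)
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))       # trigamma(x) ~ 1/x^2 for small x
  if (y < 1e-6) return(1 / y)            # trigamma(x) ~ 1/x for large x
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    delta <- (trigamma(x) - y) / psigamma(x, 2)
    x_new <- x - delta
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < 1e-10 * x) { x <- x_new; break }
    x <- x_new
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching of log residual variances to a scaled F distribution
#' (the hierarchical model behind variance moderation): with
#' `e_g = log(s2_g) - digamma(d/2) + log(d/2)`, the between-gene excess of
#' `var(e_g)` over `trigamma(d/2)` determines the prior degrees of freedom
#' `d0` via trigamma inversion, and the prior variance `s0_sq` follows from
#' the mean of `e_g`. When the observed dispersion does not exceed the
#' sampling floor, `d0` is infinite and `s0_sq` reduces to the pooled value.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom shared by all genes.
#' @return An object of class `moderation_prior`: list with `d0` (possibly
#'   `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  stopifnot(df >= 1)
  if (all(s2 <= 0)) stop("all residual variances are zero; degenerate data")
  pos <- s2[s2 > 0]
  if (length(pos) < length(s2))
    warning(length(s2) - length(pos),
            " zero-variance gene(s) excluded from prior estimation")
  if (length(pos) < 10) {
    warning("fewer than 10 positive variances; using d0 = Inf fallback")
    return(structure(list(d0 = Inf, s0_sq = mean(pos)),
                     class = "moderation_prior"))
  }
  e <- log(pos) - digamma(df / 2) + log(df / 2)
  G <- length(e)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * G / (G - 1) - trigamma(df / 2)
  if (excess <= 0) {
    # no between-gene dispersion beyond the sampling floor: one shared
    # variance; E[e_g] = log(sigma^2), so exp(ebar) is its unbiased-log
    # estimate (the finite-d0 correction term vanishes as d0 -> Inf)
    d0 <- Inf
    s0_sq <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat("Moderation prior: d0 =", format(x$d0), " s0^2 =", format(x$s0_sq), "\n")
  invisible(x)
}

#' Moderated t-statistics and direction calls
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, and tests
#' `t = log2fc / (u * sqrt(s2_post))` on `d0 + df` degrees of freedom
#' (standard normal when `d0` is infinite). P-values are two-sided and
#' BH-adjusted across genes; a gene's direction is `sign(log2fc)` when its
#' adjusted p is below `direction_alpha` and 0 otherwise.
#'
#' @param fit A `two_group_fit` from [fit_two_group()].
#' @param prior A `moderation_prior` from [estimate_prior()]; estimated from
#'   the fit when omitted.
#' @param direction_alpha Adjusted-p cutoff for direction calls (default
#'   0.05).
#' @return A `de_table` data frame: `gene`, `log2fc`, `s2`, `s2_post`,
#'   `t`, `df_total`, `p`, `adj_p`, `direction`; the prior is attached as
#'   attribute `prior`.
#' @export
moderated_t <- function(fit, prior = NULL, direction_alpha = 0.05) {
  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df)
  stopifnot(inherits(prior, "moderation_prior"),
            direction_alpha > 0, direction_alpha < 1)
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(fit$s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
    df_total <- d0 + fit$df
  }
  keep <- s2_post > 0
  if (any(!keep))
    warning(sum(!keep), " gene(s) with zero posterior variance dropped")
  tstat <- fit$log2fc[keep] / (fit$u * sqrt(s2_post[keep]))
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  p <- pmin(p, 1)
  adj_p <- bh_adjust(pmax(p, .Machine$double.xmin))
  direction <- ifelse(adj_p < direction_alpha, sign(fit$log2fc[keep]), 0)
  out <- data.frame(gene = fit$gene[keep],
                    log2fc = fit$log2fc[keep],
                    s2 = fit$s2[keep],
                    s2_post = s2_post[keep],
                    t = tstat,
                    df_total = df_total,
                    p = p,
                    adj_p = adj_p,
                    direction = as.integer(direction),
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "contrast") <- fit$contrast
  class(out) <- c("de_table", "data.frame")
  out
}

#' Two-group differential expression in one call
#'
#' Convenience wrapper: [fit_two_group()], [estimate_prior()],
#' [moderated_t()].
#'
#' @inheritParams fit_two_group
#' @inheritParams moderated_t
#' @return A `de_table` (see [moderated_t()]).
#' @export
run_de <- function(study, contrast, direction_alpha = 0.05) {
  fit <- fit_two_group(study, contrast)
  moderated_t(fit, estimate_prior(fit$s2, fit$df),
              direction_alpha = direction_alpha)
}

#' Extract the signed significant gene set from a DE table
#'
#' @param de A `de_table`.
#' @return Named -1/+1 vector over genes with non-zero direction.
#' @export
de_signs <- function(de) {
  sig <- de[de$direction != 0, , drop = FALSE]
  stats::setNames(as.numeric(sig$direction), sig$gene)
}
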