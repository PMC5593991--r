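# ---------------------------------------------------------------------------
# Empirical-Bayes variance moderation and B-statistic (log posterior odds of
# differential expression) for per-probe linear model fits.
#
# Model: residual variances s^2_g | sigma^2_g ~ sigma^2_g * chisq(d_g)/d_g,
# with a scaled inverse chi-square prior sigma^2_g ~ s0^2 * d0 / chisq(d0).
# (d0, s0^2) are estimated by matching the first two moments of log s^2 to
# the implied log-F distribution (digamma/trigamma inversion); the posterior
# variance s~^2 = (d0 s0^2 + d s^2)/(d0 + d) yields a moderated t on d0 + d
# degrees of freedom. The B-statistic adds a two-component prior on the
# coefficient (differentially expressed with probability p_de, with prior
# variance v0 estimated from the top tail of the moderated t).
# ---------------------------------------------------------------------------

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for x > 0, used when matching
#' the variance of log residual variances to the prior degrees of freedom.
#'
#' @param y positive value.
#' @return x with trigamma(x) = y.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(y >= 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate the variance prior (d0, s0^2) from residual variances
#'
#' Moment matching on the log scale: with z = log s^2,
#' e = z - digamma(d/2) + log(d/2) has mean log s0^2 + digamma(d0/2) -
#' log(d0/2) and variance trigamma(d/2) + trigamma(d0/2). If the empirical
#' variance of e does not exceed the sampling contribution trigamma(d/2), the
#' variances are consistent with a point prior and d0 = Inf is reported.
#'
#' @param s2 per-probe residual variances (zeros are handled by offsetting,
#'   mirroring standard practice).
#' @param df residual degrees of freedom (scalar or per-probe).
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(length(s2) >= 2, all(df >= 1))
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  stopifnot(sum(ok) >= 2)
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Posterior (moderated) variances
#'
#' @param s2 residual variances; `df` their degrees of freedom.
#' @param d0,s0_sq prior degrees of freedom and variance.
#' @return vector of posterior variances `(d0*s0_sq + df*s2)/(d0 + df)`;
#'   `s0_sq` everywhere when `d0` is infinite.
#' @export
squeeze_variances <- function(s2, df, d0, s0_sq) {
  if (!is.finite(d0)) return(rep(s0_sq, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0_sq + df * s2) / (d0 + df)
}

# Prior coefficient variance (in units of the unscaled variance) estimated
# from the top tail of the moderated t, assuming a proportion p_de of probes
# are differentially expressed. Mirrors the standard mixture-quantile method.
estimate_v0 <- function(tstat, v_unscaled, df, p_de) {
  n <- length(tstat)
  ntarget <- ceiling(p_de / 2 * n)
  if (ntarget < 1) return(NA_real_)
  p <- max(ntarget / n, p_de)
  at <- abs(tstat)
  max_df <- 800
  big <- df > max_df
  if (any(big)) {
    at[big] <- stats::qt(stats::pt(at[big], df = df[big], lower.tail = FALSE),
                         df = max_df, lower.tail = FALSE)
    df[big] <- max_df
  }
  o <- order(at, decreasing = TRUE)[seq_len(ntarget)]
  at <- at[o]; v1 <- v_unscaled[o]; dfo <- df[o]
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(at, df = dfo, lower.tail = FALSE)
  ptarget <- ((r - 0.5) / n - (1 - p) * p0) / p
  v0 <- rep(0, ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = dfo[pos], lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((at[pos] / qtarget)^2 - 1)
  }
  mean(v0)
}

#' Log posterior odds of differential expression (B-statistic)
#'
#' @param tstat moderated t-statistics.
#' @param v_unscaled unscaled coefficient variances (diagonal of
#'   `(X'X)^-1` for the tested coefficient).
#' @param df total degrees of freedom of the moderated t (d0 + d).
#' @param p_de prior proportion of differentially expressed probes.
#' @param v0 prior coefficient variance (unscaled units); estimated from the
#'   top tail when `NULL`.
#' @return vector of B-statistics (natural-log odds).
#' @export
b_statistic <- function(tstat, v_unscaled, df, p_de = 0.01, v0 = NULL) {
  stopifnot(p_de > 0, p_de < 1)
  if (is.null(v0)) v0 <- estimate_v0(tstat, v_unscaled, df, p_de)
  df <- rep_len(df, length(tstat))
  r <- rep_len((v_unscaled + v0) / v_unscaled, length(tstat))
  t2 <- tstat^2
  fin <- is.finite(df)
  kernel <- numeric(length(tstat))
  kernel[fin] <- (1 + df[fin]) / 2 *
    log((t2[fin] + df[fin]) / (t2[fin] / r[fin] + df[fin]))
  kernel[!fin] <- t2[!fin] * (1 - 1 / r[!fin]) / 2
  log(p_de / (1 - p_de)) - log(r) / 2 + kernel
}

#' Empirical-Bayes moderation of a per-probe fit table
#'
#' Takes ordinary per-probe least-squares results (from [fit_models()] /
#' [probe_lm()]) and adds the variance-prior estimate, posterior variances,
#' moderated t, p-values on d0 + d degrees of freedom, and the B-statistic
#' for each coefficient.
#'
#' @param fit a `probe_fit` object.
#' @param p_de prior proportion of differentially expressed probes.
#' @return the fit with components `d0`, `s0_sq`, `s2_post`, and matrices
#'   `t`, `p`, `B` (probe x coefficient), plus `v0` per coefficient.
#' @export
ebayes_moderate <- function(fit, p_de = 0.01) {
  stopifnot(inherits(fit, "probe_fit"))
  if (sum(fit$df > 0) < 30) {
    warning("fewer than 30 probes with positive residual df; prior estimate unstable")
  }
  pr <- fit_variance_prior(fit$s2, fit$df)
  s2_post <- squeeze_variances(fit$s2, fit$df, pr$d0, pr$s0_sq)
  df_total <- pr$d0 + fit$df
  tmat <- fit$coefficients / (sqrt(s2_post) *
            matrix(sqrt(fit$v_unscaled), nrow(fit$coefficients),
                   ncol(fit$coefficients), byrow = TRUE))
  pmat <- 2 * stats::pt(abs(tmat), df = df_total, lower.tail = FALSE)
  v0 <- numeric(ncol(tmat))
  Bmat <- tmat
  for (j in seq_len(ncol(tmat))) {
    v0[j] <- estimate_v0(tmat[, j], rep(fit$v_unscaled[j], nrow(tmat)),
                         rep_len(df_total, nrow(tmat)), p_de)
    Bmat[, j] <- b_statistic(tmat[, j], rep(fit$v_unscaled[j], nrow(tmat)),
                             df_total, p_de, v0 = v0[j])
  }
  fit$d0 <- pr$d0
  fit$s0_sq <- pr$s0_sq
  fit$s2_post <- s2_post
  fit$df_total <- rep_len(df_total, length(fit$s2))
  fit$t <- tmat
  fit$p <- pmat
  fit$B <- Bmat
  fit$p_de <- p_de
  fit$v0 <- v0
  fit$moderated <- TRUE
  fit
}
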