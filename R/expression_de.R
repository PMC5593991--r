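# ---------------------------------------------------------------------------
# Dual-model microarray differential expression screen:
# quantile normalization -> low-signal filter -> PC1 technical covariate ->
# per-probe least squares under two models (with and without PC1) ->
# empirical-Bayes moderation and B-statistic ranking -> top-K intersection ->
# replication direction-consistency validation.
# ---------------------------------------------------------------------------

#' Quantile-normalize a log-intensity matrix
#'
#' Every column is mapped onto the row-wise mean of the sorted columns, so all
#' arrays share one intensity distribution while within-array ranks are
#' preserved (average-tie rule). Delegates to `limma::normalizeQuantiles`.
#'
#' @param matrix probe x sample numeric matrix (>= 2 columns, finite).
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, all(is.finite(matrix)))
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Low-signal probe filter
#'
#' Keeps probes whose intensity exceeds the per-array background quantile in
#' at least `min_fraction` of the arrays; the rest are treated as unexpressed.
#'
#' @param matrix probe x sample matrix.
#' @param background_quantile per-array background quantile in (0, 1).
#' @param min_fraction minimum fraction of arrays above background.
#' @return list with `keep` (logical per probe), `retained` ids, and a
#'   `log` entry of counts in/out.
#' @export
low_signal_filter <- function(matrix, background_quantile = 0.1,
                              min_fraction = 0.5) {
  stopifnot(background_quantile > 0, background_quantile < 1,
            min_fraction >= 0, min_fraction <= 1)
  bg <- apply(matrix, 2, stats::quantile, probs = background_quantile)
  above <- sweep(matrix, 2, bg, ">")
  keep <- rowMeans(above) >= min_fraction
  list(keep = keep,
       retained = rownames(matrix)[keep],
       log = data.frame(probes_in = nrow(matrix), probes_kept = sum(keep),
                        probes_removed = sum(!keep),
                        background_quantile = background_quantile,
                        min_fraction = min_fraction))
}

#' First-principal-component scores of an expression matrix
#'
#' Probe-wise centers the matrix and projects the samples on the first right
#' singular vector; used as the technical (batch) nuisance covariate. The
#' sign is fixed so the first sample's score is non-negative.
#'
#' @param matrix probe x sample matrix (>= 2 samples).
#' @return list with `scores` (per sample) and `var_explained` in [0, 1].
#' @export
pc1_scores <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2)
  xc <- matrix - rowMeans(matrix)
  # eigen of the small sample x sample cross-product; PC1 only
  cp <- crossprod(xc)
  ev <- eigen(cp, symmetric = TRUE)
  scores <- ev$vectors[, 1] * sqrt(ev$values[1])
  if (scores[1] < 0) scores <- -scores
  names(scores) <- colnames(matrix)
  list(scores = scores,
       var_explained = ev$values[1] / sum(pmax(ev$values, 0)))
}

#' Per-probe ordinary least squares
#'
#' Fits the same linear model to every probe of a log2 matrix by direct
#' normal-equations algebra, returning coefficients, residual variances and
#' the unscaled coefficient variances needed for moderation.
#'
#' @param matrix probe x sample matrix.
#' @param design sample x coefficient design matrix (full rank).
#' @return a `probe_fit` object.
#' @export
probe_lm <- function(matrix, design) {
  stopifnot(is.matrix(matrix), nrow(design) == ncol(matrix))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  xtx_inv <- chol2inv(chol(crossprod(design)))
  coefs <- matrix %*% design %*% xtx_inv        # probe x coef
  fitted <- tcrossprod(coefs, design)
  res <- matrix - fitted
  df <- nrow(design) - ncol(design)
  s2 <- if (df > 0) rowSums(res^2) / df else rep(NA_real_, nrow(matrix))
  colnames(coefs) <- colnames(design)
  structure(list(coefficients = coefs,
                 s2 = s2,
                 df = rep(df, nrow(matrix)),
                 v_unscaled = stats::setNames(diag(xtx_inv), colnames(design)),
                 design = design,
                 probes = rownames(matrix)),
            class = "probe_fit")
}

#' @export
print.probe_fit <- function(x, ...) {
  cat(sprintf("probe_fit: %d probes, %d coefficients (%s), residual df %d%s\n",
              length(x$s2), ncol(x$coefficients),
              paste(colnames(x$coefficients), collapse = ", "), x$df[1],
              if (isTRUE(x$moderated))
                sprintf("; moderated (d0 = %.3g, s0^2 = %.3g)", x$d0, x$s0_sq)
              else ""))
  invisible(x)
}

factor_design <- function(samples, with_pc1 = FALSE, pc1 = NULL) {
  # treatment coding with reference levels F / CTRL / none, so coefficients
  # read M vs F, LPD vs CTRL, swim vs none
  X <- cbind(`(Intercept)` = 1,
             sexM = as.numeric(samples$sex == "M"),
             dietLPD = as.numeric(samples$diet == "LPD"),
             stressswim = as.numeric(samples$stress == "swim"))
  drop <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
  X <- X[, c(TRUE, !drop), drop = FALSE]
  if (with_pc1) X <- cbind(X, PC1 = pc1)
  X
}

#' Fit the two screening models to an expression experiment
#'
#' Model A: Sex + Diet + Stress. Model B: PC1 + Sex + Diet + Stress, where
#' PC1 is computed on the probe-centered main-batch matrix only. Both models
#' are fitted to the main batch; a separate model (Diet + Stress, no PC1) is
#' fitted to the male-only replication batch.
#'
#' @param exp an `expression_experiment` (or list with `matrix`, `samples`).
#' @return list with `probe_fit` objects `A`, `B`, `replication`, plus the
#'   `pc1` result.
#' @export
fit_models <- function(exp) {
  samples <- exp$samples
  stopifnot(!anyNA(samples$sex), !anyNA(samples$diet), !anyNA(samples$stress),
            all(is.finite(exp$matrix)),
            !anyDuplicated(samples$sample_id))
  main <- samples$batch == "main"
  m_main <- exp$matrix[, main, drop = FALSE]
  pc1 <- pc1_scores(m_main)
  fitA <- probe_lm(m_main, factor_design(samples[main, ]))
  fitB <- probe_lm(m_main, factor_design(samples[main, ], with_pc1 = TRUE,
                                         pc1 = pc1$scores))
  rep_fit <- NULL
  if (any(!main)) {
    rep_fit <- probe_lm(exp$matrix[, !main, drop = FALSE],
                        factor_design(samples[!main, ]))
  }
  list(A = fitA, B = fitB, replication = rep_fit, pc1 = pc1)
}

#' Intersect the top-K probes of two moderated fits
#'
#' Probes are ranked within each model by descending B-statistic for the
#' named coefficient (ties broken by ascending p-value, then probe id); the
#' candidate set is the intersection of the two top-K lists.
#'
#' @param fitA,fitB moderated `probe_fit` objects over the same probes.
#' @param coef coefficient name to rank on (default `"stressswim"`).
#' @param K rank cutoff.
#' @return character vector of candidate probe ids (sorted).
#' @export
consensus_top_k <- function(fitA, fitB, coef = "stressswim", K = 1000L) {
  stopifnot(identical(fitA$probes, fitB$probes),
            coef %in% colnames(fitA$B), coef %in% colnames(fitB$B))
  sort(intersect(top_k_probes(fitA, coef, K), top_k_probes(fitB, coef, K)))
}

#' Top-K probes of one moderated fit by B-statistic
#'
#' @param fit a moderated `probe_fit`.
#' @param coef ranked coefficient.
#' @param K list length.
#' @return probe ids in rank order (B desc, p asc, probe id).
#' @export
top_k_probes <- function(fit, coef = "stressswim", K = 1000L) {
  o <- order(-fit$B[, coef], fit$p[, coef], fit$probes)
  fit$probes[o][seq_len(min(K, length(o)))]
}

#' Replication direction-consistency filter
#'
#' Keeps candidates that at least tend to be differentially expressed in the
#' independent replication batch (p < `alpha_rep`) with the same log2
#' fold-change sign as the main experiment. A zero fold change matches no
#' sign and is never kept.
#'
#' @param candidates candidate probe ids.
#' @param main_fit moderated fit supplying the main-experiment log2FC sign
#'   (model A by convention).
#' @param replication_fit moderated fit on the replication batch.
#' @param coef tested coefficient.
#' @param alpha_rep lenient replication threshold (default 0.1).
#' @param moderated use the replication fit's moderated p-values instead of
#'   the exact per-probe t (default FALSE; see [ordinary_t()] for why).
#' @return character vector of validated probe ids.
#' @export
replication_validate <- function(candidates, main_fit, replication_fit,
                                 coef = "stressswim", alpha_rep = 0.1,
                                 moderated = FALSE) {
  i_m <- match(candidates, main_fit$probes)
  i_r <- match(candidates, replication_fit$probes)
  stopifnot(!anyNA(i_m), !anyNA(i_r))
  p_rep <- if (moderated) replication_fit$p[, coef]
           else ordinary_t(replication_fit, coef)$p
  s_main <- sign(main_fit$coefficients[i_m, coef])
  s_rep <- sign(replication_fit$coefficients[i_r, coef])
  keep <- p_rep[i_r] < alpha_rep & s_main == s_rep & s_main != 0
  candidates[keep]
}

#' Ordinary (unmoderated) per-probe t statistics for one coefficient
#'
#' The classical t statistic is pivotal -- exactly t-distributed on the
#' residual df whatever the probe's true variance -- which keeps the lenient
#' replication filter's null pass rate exactly at alpha/2 regardless of how
#' probe variances are distributed. Used for the replication batch, where
#' only 5 residual df are available and calibration matters more than power.
#'
#' @param fit a `probe_fit`.
#' @param coef coefficient name.
#' @return list with `t` and two-sided `p` per probe.
#' @export
ordinary_t <- function(fit, coef) {
  stopifnot(inherits(fit, "probe_fit"), coef %in% colnames(fit$coefficients))
  tt <- fit$coefficients[, coef] / sqrt(fit$s2 * fit$v_unscaled[coef])
  list(t = tt, p = 2 * stats::pt(abs(tt), fit$df, lower.tail = FALSE))
}

#' Scale transcript values relative to their per-transcript maximum
#'
#' Divides each row by its maximum so every transcript's largest tissue value
#' is exactly 1 (the "Relative" heatmap convention).
#'
#' @param x matrix or data.frame of per-transcript tissue values.
#' @return matrix of values in [0, 1].
#' @export
relative_scale <- function(x) {
  x <- as.matrix(x)
  mx <- apply(x, 1, max)
  stopifnot(all(mx > 0))
  x / mx
}

#' Run the full dual-model differential expression screen
#'
#' Quantile normalization, low-signal filtering, PC1 extraction on the main
#' batch, dual-model per-probe fits with empirical-Bayes moderation,
#' top-K B-statistic intersection, and replication direction-consistency
#' validation. Deterministic given the input matrix.
#'
#' @param exp an `expression_experiment`.
#' @param K top-rank cutoff per model.
#' @param alpha_rep replication threshold.
#' @param p_de prior proportion of differentially expressed probes.
#' @param coef tested coefficient (default the acute-stress term).
#' @param filter_quantile,filter_min_fraction low-signal filter settings;
#'   set `filter_quantile = NULL` to skip filtering.
#' @param normalize quantile-normalize the matrix first (default TRUE).
#' @return a `de_screen` object: fits, pc1, candidate and validated probe
#'   sets, the per-probe results table, and a filter/stage log.
#' @export
de_screen <- function(exp, K = 1000L, alpha_rep = 0.1, p_de = 0.01,
                      coef = "stressswim", filter_quantile = 0.1,
                      filter_min_fraction = 0.5, normalize = TRUE) {
  mat <- exp$matrix
  if (normalize) mat <- quantile_normalize(mat)
  flt <- NULL
  if (!is.null(filter_quantile)) {
    flt <- low_signal_filter(mat, filter_quantile, filter_min_fraction)
    mat <- mat[flt$keep, , drop = FALSE]
  }
  fits <- fit_models(list(matrix = mat, samples = exp$samples))
  fits$A <- ebayes_moderate(fits$A, p_de = p_de)
  fits$B <- ebayes_moderate(fits$B, p_de = p_de)
  if (is.null(fits$replication)) {
    stop("no replication-batch arrays present; the screen requires them")
  }
  rep_p <- ordinary_t(fits$replication, coef)$p
  candidates <- consensus_top_k(fits$A, fits$B, coef = coef, K = K)
  validated <- replication_validate(candidates, fits$A, fits$replication,
                                    coef = coef, alpha_rep = alpha_rep)
  ix <- fits$A$probes
  res <- data.frame(probe = ix,
                    logFC_A = fits$A$coefficients[, coef],
                    B_A = fits$A$B[, coef],
                    p_A = fits$A$p[, coef],
                    logFC_B = fits$B$coefficients[, coef],
                    B_B = fits$B$B[, coef],
                    p_B = fits$B$p[, coef],
                    logFC_rep = fits$replication$coefficients[, coef],
                    p_rep = rep_p,
                    candidate = ix %in% candidates,
                    validated = ix %in% validated,
                    row.names = NULL)
  structure(list(fits = fits, pc1 = fits$pc1, candidates = candidates,
                 validated = validated, table = res, K = K,
                 alpha_rep = alpha_rep, coef = coef,
                 filter_log = if (!is.null(flt)) flt$log),
            class = "de_screen")
}

#' @export
print.de_screen <- function(x, ...) {
  cat("Dual-model differential expression screen\n")
  if (!is.null(x$filter_log)) {
    cat(sprintf("  low-signal filter: %d -> %d probes\n",
                x$filter_log$probes_in, x$filter_log$probes_kept))
  }
  cat(sprintf("  PC1 variance explained (main batch): %.1f%%\n",
              100 * x$pc1$var_explained))
  cat(sprintf("  coefficient %s: top-%d intersection -> %d candidates, %d validated (p < %g, same direction)\n",
              x$coef, x$K, length(x$candidates), length(x$validated),
              x$alpha_rep))
  invisible(x)
}
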