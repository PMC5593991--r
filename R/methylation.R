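# ---------------------------------------------------------------------------
# Repeated-measures analysis of bisulfite pyrosequencing % methylation:
# per-assay linear mixed model with a random intercept per animal (compound
# symmetry across the CpGs of an assay), Type-III Wald F tests with
# containment denominator df, and within-sex diet contrasts on the model
# marginal means.
# ---------------------------------------------------------------------------

#' Fit the per-assay repeated-measures CpG mixed model
#'
#' pct ~ Sex + Diet + Sex:Diet + CpG (fixed) + (1 | animal), fitted by REML
#' (`lme4`). All CpGs of one assay are tested jointly: neighbouring CpGs in
#' one animal are never independent, which the animal random intercept
#' absorbs. Fixed effects are tested with Type-III Wald F statistics;
#' denominator df follow the containment rule (animals - cells for
#' between-animal terms; the within-animal stratum's residual df for the CpG
#' term). Percent methylation is analyzed on the raw percent scale.
#'
#' @param table a `methylation_table` (long format: `animal_id`, `sex`,
#'   `diet`, `assay`, `cpg`, `pct`).
#' @param assay assay name to analyze.
#' @param cpg_fixed include CpG position as a fixed effect (default TRUE).
#' @return a `cpg_mixed_model`: fixed-effect test table, variance components,
#'   Sex x Diet cell means with SE, singularity flag, and the `lmer` fit.
#' @export
fit_cpg_mixed_model <- function(table, assay, cpg_fixed = TRUE) {
  d <- data.frame(table)
  d <- d[d$assay == assay, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for assay ", assay)
  d$sex <- factor(d$sex); d$diet <- factor(d$diet)
  d$cpg <- factor(d$cpg); d$animal_id <- factor(d$animal_id)
  stopifnot(nlevels(d$cpg) >= 2 || !cpg_fixed,
            all(table(d$sex, d$diet) > 0))
  n_animals <- nlevels(d$animal_id)
  n_cells <- nlevels(d$sex) * nlevels(d$diet)
  if (stats::var(d$pct) < 1e-12) {
    warning("response is constant for assay ", assay,
            "; exact-fit branch (all F = 0)")
    terms <- c("sex", "diet", if (cpg_fixed) "cpg", "sex:diet")
    cells <- unique(d[c("sex", "diet")])
    cells$emmean <- d$pct[1]; cells$se <- 0
    return(structure(list(
      assay = assay,
      fixed = data.frame(term = terms, df = NA_integer_,
                         df_error = NA_integer_, F = 0, p = 1),
      varcomp = c(animal = 0, residual = 0),
      cell_means = cells[order(cells$sex, cells$diet), ],
      singular = TRUE, exact_fit = TRUE, fit = NULL,
      df_between = n_animals - n_cells),
      class = "cpg_mixed_model"))
  }
  fml <- if (cpg_fixed) pct ~ sex * diet + cpg + (1 | animal_id)
         else pct ~ sex * diet + (1 | animal_id)
  ctr <- list(sex = "contr.sum", diet = "contr.sum")
  if (cpg_fixed) ctr$cpg <- "contr.sum"
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = TRUE, contrasts = ctr,
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore"))))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  vc <- lme4::VarCorr(fit)
  var_animal <- as.numeric(vc$animal_id[1])
  var_resid <- attr(vc, "sc")^2
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  X <- lme4::getME(fit, "X")
  asgn <- attr(X, "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  p_fixed <- length(beta)
  N <- nrow(d)
  df_between <- n_animals - n_cells
  df_within <- N - n_animals - (p_fixed - n_cells)
  fixed <- do.call(rbind, lapply(seq_along(terms_lab), function(k) {
    idx <- which(asgn == k)
    b <- beta[idx]
    Vk <- V[idx, idx, drop = FALSE]
    Fv <- drop(crossprod(b, solve(Vk, b))) / length(idx)
    ddf <- if (terms_lab[k] == "cpg") df_within else df_between
    data.frame(term = terms_lab[k], df = length(idx), df_error = ddf,
               F = Fv, p = stats::pf(Fv, length(idx), ddf, lower.tail = FALSE))
  }))
  rownames(fixed) <- NULL
  # Sex x Diet marginal means: predictions averaged over CpG levels
  grid <- expand.grid(sex = levels(d$sex), diet = levels(d$diet),
                      cpg = levels(d$cpg), KEEP.OUT.ATTRS = FALSE)
  if (!cpg_fixed) grid <- unique(grid[c("sex", "diet")])
  Xg <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid,
                            contrasts.arg = ctr)
  key <- interaction(grid$sex, grid$diet, sep = ".", lex.order = TRUE)
  cvecs <- t(vapply(levels(key), function(lv) {
    colMeans(Xg[key == lv, , drop = FALSE])
  }, numeric(ncol(Xg))))
  cells <- data.frame(do.call(rbind, strsplit(levels(key), ".", fixed = TRUE)))
  names(cells) <- c("sex", "diet")
  cells$emmean <- drop(cvecs %*% beta)
  cells$se <- sqrt(rowSums((cvecs %*% V) * cvecs))
  structure(list(assay = assay, fixed = fixed,
                 varcomp = c(animal = var_animal, residual = var_resid),
                 cell_means = cells, cell_cvecs = cvecs, vcov = V, beta = beta,
                 singular = singular, exact_fit = FALSE, fit = fit,
                 df_between = df_between),
            class = "cpg_mixed_model")
}

#' @export
print.cpg_mixed_model <- function(x, ...) {
  cat(sprintf("Repeated-measures CpG mixed model, assay %s\n", x$assay))
  fx <- x$fixed
  fx$F <- signif(fx$F, 4); fx$p <- signif(fx$p, 3)
  print(fx, row.names = FALSE)
  cat(sprintf("Variance components: animal %.4g, residual %.4g%s\n",
              x$varcomp["animal"], x$varcomp["residual"],
              if (x$singular) " (singular: random intercept at boundary, reduces to OLS)" else ""))
  invisible(x)
}

#' Within-sex diet contrasts on mixed-model marginal means
#'
#' Tests LPD vs CTRL separately within females and males on the Sex x Diet
#' marginal means of a fitted CpG mixed model, Bonferroni-corrected over the
#' declared contrasts; denominator df from the between-animal stratum.
#'
#' @param result a `cpg_mixed_model`.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param alpha decision level.
#' @return data.frame with one row per contrast.
#' @export
pairwise_cells <- function(result, correction = c("bonferroni", "none"),
                           alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(inherits(result, "cpg_mixed_model"), !result$exact_fit)
  cm <- result$cell_means
  out <- do.call(rbind, lapply(unique(cm$sex), function(sx) {
    i <- which(cm$sex == sx & cm$diet == "LPD")
    j <- which(cm$sex == sx & cm$diet == "CTRL")
    d <- result$cell_cvecs[i, ] - result$cell_cvecs[j, ]
    est <- drop(d %*% result$beta)
    se <- sqrt(drop(t(d) %*% result$vcov %*% d))
    tt <- est / se
    p <- 2 * stats::pt(abs(tt), result$df_between, lower.tail = FALSE)
    data.frame(sex = sx, contrast = "LPD - CTRL", estimate = est, se = se,
               t = tt, df = result$df_between, p = p)
  }))
  m <- if (correction == "bonferroni") nrow(out) else 1L
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Global (retrotransposon) methylation check
#'
#' Applies the factorial GLM machinery to repeat-element assays (B1, IAP) on
#' animal-level mean methylation, to verify the absence of global shifts.
#'
#' @param table a `methylation_table`.
#' @param assays assays to test.
#' @return named list of `factorial_glm` fits (response: per-animal mean
#'   percent methylation, factors Sex x Diet).
#' @export
global_methylation_check <- function(table, assays = c("B1", "IAP")) {
  d <- data.frame(table)
  out <- lapply(assays, function(a) {
    da <- d[d$assay == a, , drop = FALSE]
    if (nrow(da) == 0) stop("no rows for assay ", a)
    agg <- stats::aggregate(pct ~ animal_id + sex + diet, data = da, FUN = mean)
    factorial_glm(agg, "pct", c("sex", "diet"), interactions = "full")
  })
  stats::setNames(out, assays)
}
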