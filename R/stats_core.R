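# ---------------------------------------------------------------------------
# Shared statistical engine: full-factorial "generalized linear models
# (normal, identity)" = ordinary least squares with Type-III-style F tests,
# estimated marginal means with pooled SE, Newman-Keuls and Bonferroni
# post-hoc procedures, and repeated-measures ANOVA.
# ---------------------------------------------------------------------------

#' Fit a factorial GLM (normal, identity) with Type-III tests and EMMs
#'
#' Ordinary least squares with sum-to-zero factor coding, so dropping a
#' term's columns yields Type-III-style F tests and estimated marginal means
#' carry their usual averaged-over-the-other-factors meaning with a pooled
#' residual SE ("assuming equal variance").
#'
#' @param data data.frame of observations.
#' @param response response column name.
#' @param factors character vector of factor column names (e.g. Sex, Diet,
#'   with Stress as a co-factor simply listed third).
#' @param interactions `"two-way"` (all pairwise, the study's convention),
#'   `"full"`, or `"none"`.
#' @return a `factorial_glm` object with the `lm` fit, an ANOVA table
#'   (term, df, F, p), residual df and variance.
#' @export
factorial_glm <- function(data, response, factors,
                          interactions = c("two-way", "full", "none")) {
  interactions <- match.arg(interactions)
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  data <- data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  cells <- interaction(data[factors], drop = FALSE)
  if (interactions == "full" && any(table(droplevels(cells)) == 0)) {
    empties <- names(which(table(cells) == 0))
    stop("empty design cell(s) with full interactions requested: ",
         paste(empties, collapse = ", "))
  }
  rhs <- switch(interactions,
                "none" = paste(factors, collapse = " + "),
                "two-way" = if (length(factors) > 1)
                  sprintf("(%s)^2", paste(factors, collapse = " + "))
                  else factors,
                "full" = paste(factors, collapse = " * "))
  fml <- stats::as.formula(paste(response, "~", rhs))
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = ctr)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) stop("design matrix not of full rank")
  asgn <- attr(X, "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  n <- nrow(X)
  rdf <- fit$df.residual
  sigma2 <- sum(stats::residuals(fit)^2) / rdf
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- stats::coef(fit)
  exact_fit <- sigma2 < 1e-12 * max(mean(X %*% beta)^2, 1)
  if (exact_fit) warning("zero residual variance: exact-fit branch")
  an <- do.call(rbind, lapply(seq_along(terms_lab), function(k) {
    idx <- which(asgn == k)
    b <- beta[idx]
    if (exact_fit) {
      Fv <- if (sum(b^2) < 1e-20) 0 else Inf
      return(data.frame(term = terms_lab[k], df = length(idx), F = Fv,
                        p = if (Fv == 0) 1 else 0))
    }
    V <- xtx_inv[idx, idx, drop = FALSE] * sigma2
    Fv <- drop(crossprod(b, solve(V, b))) / length(idx)
    data.frame(term = terms_lab[k], df = length(idx),
               F = Fv, p = stats::pf(Fv, length(idx), rdf, lower.tail = FALSE))
  }))
  rownames(an) <- NULL
  structure(list(fit = fit, anova = an, data = data, response = response,
                 factors = factors, sigma2 = sigma2, df_residual = rdf,
                 xtx_inv = xtx_inv, interactions = interactions),
            class = "factorial_glm")
}

#' @export
print.factorial_glm <- function(x, ...) {
  cat(sprintf("Factorial GLM (normal, identity): %s ~ %s [%s interactions]\n",
              x$response, paste(x$factors, collapse = " x "), x$interactions))
  an <- x$anova
  an$F <- signif(an$F, 4); an$p <- signif(an$p, 3)
  print(an, row.names = FALSE)
  cat(sprintf("Residual df %d, residual variance %.4g\n",
              x$df_residual, x$sigma2))
  invisible(x)
}

#' Estimated marginal means
#'
#' Model predictions on the full factorial reference grid, averaged over the
#' factors not named in `specs`, with pooled-variance standard errors.
#'
#' @param object a `factorial_glm`.
#' @param specs factor name(s); one name gives level EMMs, several give cell
#'   EMMs over their combinations.
#' @return data.frame with the spec levels, `emmean`, `se`, `df`, and `n`
#'   (observations contributing to each margin).
#' @export
emm <- function(object, specs = object$factors) {
  stopifnot(inherits(object, "factorial_glm"), all(specs %in% object$factors))
  grid <- expand.grid(lapply(object$data[object$factors], levels),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- object$factors
  Xg <- stats::model.matrix(stats::delete.response(stats::terms(object$fit)),
                            grid, contrasts.arg = object$fit$contrasts)
  key <- interaction(grid[specs], drop = FALSE, sep = ".", lex.order = TRUE)
  data_key <- interaction(object$data[specs], drop = FALSE, sep = ".",
                          lex.order = TRUE)
  beta <- stats::coef(object$fit)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    rows <- which(key == lv)
    cvec <- colMeans(Xg[rows, , drop = FALSE])
    est <- drop(cvec %*% beta)
    se <- sqrt(drop(t(cvec) %*% object$xtx_inv %*% cvec) * object$sigma2)
    lv_vals <- grid[rows[1], specs, drop = FALSE]
    cbind(lv_vals, data.frame(emmean = est, se = se, df = object$df_residual,
                              n = sum(data_key == lv)))
  }))
  rownames(out) <- NULL
  out
}

#' Newman-Keuls (SNK) stepwise post-hoc comparisons
#'
#' Orders the cell means and tests each span of r ordered means with the
#' studentized range statistic q = (max - min)/SE against
#' `qtukey(1 - alpha, r, df)`; a non-significant span blocks every pair it
#' contains (standard SNK step-down logic). Unequal cell sizes are handled
#' through the harmonic-mean n; SE = sqrt(MSE / n_h) with the model's pooled
#' residual variance.
#'
#' @param object a `factorial_glm`.
#' @param specs factors whose cells are compared (default: all factors).
#' @param alpha familywise level.
#' @return an `snk_result` data.frame of all pairs: means, span `r`, `q`,
#'   critical value, and `significant`.
#' @export
newman_keuls <- function(object, specs = object$factors, alpha = 0.05) {
  cells <- emm(object, specs)
  stopifnot(nrow(cells) >= 2, all(cells$n > 0))
  k <- nrow(cells)
  n_h <- k / sum(1 / cells$n)
  se <- sqrt(object$sigma2 / n_h)
  df <- object$df_residual
  o <- order(cells$emmean)
  mu <- cells$emmean[o]
  lab <- apply(cells[o, seq_along(specs), drop = FALSE], 1, paste, collapse = ".")
  sig <- blocked <- matrix(FALSE, k, k)
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      if (blocked[i, j]) next
      q <- (mu[j] - mu[i]) / se
      crit <- stats::qtukey(1 - alpha, nmeans = r, df = df)
      if (q >= crit) sig[i, j] <- TRUE
      else {
        # block all pairs inside a non-significant span
        for (a in i:j) for (b in a:j) if (b > a) blocked[a, b] <- TRUE
      }
    }
  }
  pairs <- which(upper.tri(sig), arr.ind = TRUE)
  out <- data.frame(group1 = lab[pairs[, 1]], group2 = lab[pairs[, 2]],
                    mean1 = mu[pairs[, 1]], mean2 = mu[pairs[, 2]],
                    r = pairs[, 2] - pairs[, 1] + 1)
  out$q <- (out$mean2 - out$mean1) / se
  out$q_crit <- stats::qtukey(1 - alpha, nmeans = out$r, df = df)
  out$significant <- sig[pairs] & !blocked[pairs]
  attr(out, "se") <- se
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  class(out) <- c("snk_result", "data.frame")
  out
}

#' Bonferroni-adjusted pairwise cell comparisons
#'
#' Pooled-variance t tests between declared cell pairs with the Bonferroni
#' multiplier equal to the number of declared pairs.
#'
#' @param object a `factorial_glm`.
#' @param specs factors whose cells are compared.
#' @param pairs list of length-2 character vectors naming cell pairs (levels
#'   joined by "."); default: all pairs.
#' @param alpha familywise level.
#' @return data.frame with estimate, t, raw and adjusted p, decision.
#' @export
bonferroni_pairs <- function(object, specs = object$factors, pairs = NULL,
                             alpha = 0.05) {
  cells <- emm(object, specs)
  lab <- apply(cells[, seq_along(specs), drop = FALSE], 1, paste, collapse = ".")
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(nrow(cells))), arr.ind = TRUE)
    pairs <- lapply(seq_len(nrow(idx)), function(i) lab[idx[i, ]])
  }
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- match(pr[1], lab); j <- match(pr[2], lab)
    stopifnot(!is.na(i), !is.na(j))
    est <- cells$emmean[i] - cells$emmean[j]
    se <- sqrt(object$sigma2 * (1 / cells$n[i] + 1 / cells$n[j]))
    tt <- est / se
    p <- 2 * stats::pt(abs(tt), object$df_residual, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], estimate = est, t = tt,
               p = p, p_adj = min(1, p * m))
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA with subject blocking
#'
#' Univariate split-plot ANOVA: between-subject grouping factors tested
#' against the subject stratum, the within factor and its group interaction
#' against the within-subject stratum (no sphericity correction). Delegates
#' to `aov` with an `Error(subject)` term. With a single within level the
#' design collapses to [factorial_glm()].
#'
#' @param data data.frame in long format.
#' @param response,subject,within column names; `between` a character vector
#'   of grouping factor names.
#' @return data.frame with term, df, df_error, F, p per tested effect.
#' @export
repeated_measures_glm <- function(data, response, subject, within, between) {
  data <- data.frame(data)
  for (f in c(subject, within, between)) data[[f]] <- factor(data[[f]])
  if (nlevels(data[[within]]) == 1) {
    fg <- factorial_glm(data, response, between, interactions = "full")
    an <- fg$anova
    an$df_error <- fg$df_residual
    return(an[, c("term", "df", "df_error", "F", "p")])
  }
  grp <- if (length(between) > 1)
    paste0("(", paste(between, collapse = " * "), ")") else between
  fml <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s)",
                                   response, grp, within, subject))
  av <- summary(stats::aov(fml, data = data))
  out <- do.call(rbind, lapply(av, function(stratum) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_row <- terms == "Residuals"
    df_err <- tab$Df[resid_row]
    keep <- !resid_row
    if (!any(keep)) return(NULL)
    data.frame(term = terms[keep], df = tab$Df[keep], df_error = df_err,
               F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep])
  }))
  rownames(out) <- NULL
  out
}
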