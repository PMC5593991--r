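# ---------------------------------------------------------------------------
# Delta-Ct qPCR analysis: normalization against two housekeeping genes,
# fold-change computation relative to a declared reference group, and the
# Sex x Diet factorial analysis of fold changes.
# ---------------------------------------------------------------------------

#' Delta-Ct normalization against two housekeeping genes
#'
#' For each animal x region, the target Ct is reduced by the arithmetic mean
#' of the two housekeeping Cts (the geometric mean on the linear expression
#' scale). Animals missing a housekeeping value are excluded with a message.
#'
#' @param table a `ct_table` (long format: `animal_id`, `sex`, `diet`,
#'   `region`, `gene`, `ct`) with attribute `hk_genes`, or pass `hk`.
#' @param hk the two housekeeping gene names.
#' @return data.frame of targets with `delta_ct` added (housekeeping rows
#'   dropped).
#' @export
delta_ct <- function(table, hk = attr(table, "hk_genes")) {
  d <- data.frame(table)
  stopifnot(length(hk) == 2, all(d$ct > 0))
  key <- paste(d$animal_id, d$region, sep = "\r")
  hk_rows <- d$gene %in% hk
  hk_n <- tapply(d$gene[hk_rows], key[hk_rows], function(g) length(unique(g)))
  complete <- names(hk_n)[hk_n == 2]
  bad <- setdiff(unique(key), complete)
  if (length(bad)) {
    message(length(bad), " animal x region unit(s) excluded: missing housekeeping Ct")
  }
  hk_mean <- tapply(d$ct[hk_rows], key[hk_rows], mean)
  out <- d[!hk_rows & key %in% complete, , drop = FALSE]
  out$delta_ct <- out$ct -
    as.numeric(hk_mean[paste(out$animal_id, out$region, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Fold changes relative to a reference group
#'
#' FC = 2^-(delta_ct - reference mean delta_ct), with the reference mean
#' taken per gene x region over the rows matching `reference` (default:
#' control-diet animals), so the reference group's geometric-mean fold change
#' is 1 by construction.
#'
#' @param delta data.frame from [delta_ct()].
#' @param reference named list of column = value filters defining the
#'   reference group (default `list(diet = "CTRL")`).
#' @return the input with a `fold_change` column.
#' @export
fold_change <- function(delta, reference = list(diet = "CTRL")) {
  d <- data.frame(delta)
  ref <- rep(TRUE, nrow(d))
  for (col in names(reference)) ref <- ref & d[[col]] %in% reference[[col]]
  stopifnot(any(ref))
  grp <- paste(d$gene, d$region, sep = "\r")
  ref_mean <- tapply(d$delta_ct[ref], grp[ref], mean)
  stopifnot(all(grp %in% names(ref_mean)))
  d$fold_change <- 2^-(d$delta_ct - as.numeric(ref_mean[grp]))
  d
}

#' Factorial analysis of qPCR fold changes for one gene and region
#'
#' Two-way Sex x Diet GLM (normal, identity) on fold changes (or log2 fold
#' changes), with estimated marginal means per factor and per cell, direction
#' calls in the males-vs-females / LPD-vs-control convention, and
#' Bonferroni-adjusted within-diet sex contrasts.
#'
#' @param fc data.frame from [fold_change()].
#' @param gene,region gene and brain region to analyze.
#' @param log2_scale analyze log2(FC) instead of FC (default FALSE: marginal
#'   means are reported on the fold-change scale).
#' @return a `qpcr_result`: the `factorial_glm`, EMM tables, direction calls,
#'   and the post-hoc table.
#' @export
analyze_gene <- function(fc, gene, region, log2_scale = FALSE) {
  d <- fc[fc$gene == gene & fc$region == region, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for ", gene, " / ", region)
  d$response <- if (log2_scale) log2(d$fold_change) else d$fold_change
  g <- factorial_glm(d, "response", c("sex", "diet"), interactions = "full")
  emm_sex <- emm(g, "sex")
  emm_diet <- emm(g, "diet")
  emm_cells <- emm(g, c("sex", "diet"))
  dir_sex <- if (emm_sex$emmean[emm_sex$sex == "M"] >
                 emm_sex$emmean[emm_sex$sex == "F"]) "Up" else "Down"
  dir_diet <- if (emm_diet$emmean[emm_diet$diet == "LPD"] >
                  emm_diet$emmean[emm_diet$diet == "CTRL"]) "Up" else "Down"
  posthoc <- bonferroni_pairs(g, c("sex", "diet"),
                              pairs = list(c("F.CTRL", "M.CTRL"),
                                           c("F.LPD", "M.LPD")))
  structure(list(gene = gene, region = region, glm = g,
                 emm_sex = emm_sex, emm_diet = emm_diet, emm_cells = emm_cells,
                 direction = c(sex_males_vs_females = dir_sex,
                               diet_lpd_vs_control = dir_diet),
                 posthoc = posthoc, log2_scale = log2_scale),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qPCR factorial analysis: %s (%s), %s scale\n", x$gene, x$region,
              if (x$log2_scale) "log2 fold-change" else "fold-change"))
  print(x$glm)
  cat(sprintf("Direction: Sex (M vs F) %s, Diet (LPD vs CTRL) %s\n",
              x$direction[1], x$direction[2]))
  cat("Within-diet sex contrasts (Bonferroni):\n")
  ph <- x$posthoc
  ph$p_adj <- signif(ph$p_adj, 3)
  print(ph[c("group1", "group2", "estimate", "p_adj", "significant")],
        row.names = FALSE)
  invisible(x)
}
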