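make_cells <- function(means, n = 6, dev = NULL) {
  # balanced 2x2 data with exact cell means; dev sums to zero within cells
  if (is.null(dev)) dev <- scale(rnorm(n), scale = FALSE)[, 1]
  cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(1:4, function(i) {
    data.frame(sex = cells$sex[i], diet = cells$diet[i],
               value = means[i] + dev)
  }))
}

test_that("additive cell means give a zero interaction and EMMs equal to marginal means", {
  set.seed(20)
  d <- make_cells(c(10, 12, 14, 16))
  g <- factorial_glm(d, "value", c("sex", "diet"), interactions = "full")
  an <- g$anova
  expect_lt(an$F[an$term == "sex:diet"], 1e-20)
  es <- emm(g, "sex")
  expect_equal(es$emmean, tapply(d$value, d$sex, mean)[es$sex],
               ignore_attr = TRUE)
  ec <- emm(g, c("sex", "diet"))
  expect_equal(ec$emmean,
               c(tapply(d$value, paste(d$sex, d$diet), mean)[paste(ec$sex, ec$diet)]),
               ignore_attr = TRUE)
})

test_that("a pure crossover puts all between-cell variance in the interaction", {
  set.seed(21)
  d <- make_cells(c(10, 12, 12, 10))
  g <- factorial_glm(d, "value", c("sex", "diet"), interactions = "full")
  an <- g$anova
  expect_lt(an$F[an$term == "sex"], 1e-20)
  expect_lt(an$F[an$term == "diet"], 1e-20)
  expect_gt(an$F[an$term == "sex:diet"], 1)
})

test_that("unbalanced Type-III F and EMMs match the car/emmeans oracle", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(3:7, 4, replace = TRUE)
    d <- do.call(rbind, lapply(1:4, function(i) {
      cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                           stringsAsFactors = FALSE)
      data.frame(sex = cells$sex[i], diet = cells$diet[i], value = rnorm(n[i]))
    }))
    g <- factorial_glm(d, "value", c("sex", "diet"), interactions = "full")
    lm_fit <- lm(value ~ sex * diet, data = d,
                 contrasts = list(sex = "contr.sum", diet = "contr.sum"))
    ca <- car::Anova(lm_fit, type = 3)
    for (tm in c("sex", "diet", "sex:diet")) {
      expect_equal(g$anova$F[g$anova$term == tm], ca[tm, "F value"],
                   tolerance = 1e-10)
    }
    em <- as.data.frame(suppressMessages(emmeans::emmeans(lm_fit, "sex")))
    mine <- emm(g, "sex")
    expect_equal(mine$emmean, em$emmean, tolerance = 1e-10)
    expect_equal(mine$se, em$SE, tolerance = 1e-10)
  }
})

test_that("results are invariant to factor level order", {
  set.seed(23)
  d <- make_cells(c(1, 3, 2, 5))
  g1 <- factorial_glm(d, "value", c("sex", "diet"), interactions = "full")
  d2 <- d
  d2$sex <- factor(d2$sex, levels = c("M", "F"))
  d2$diet <- factor(d2$diet, levels = c("LPD", "CTRL"))
  g2 <- factorial_glm(d2, "value", c("sex", "diet"), interactions = "full")
  expect_equal(g1$anova$F, g2$anova$F)
  e1 <- emm(g1, "sex"); e2 <- emm(g2, "sex")
  expect_equal(e1$emmean[order(as.character(e1$sex))],
               e2$emmean[order(as.character(e2$sex))], ignore_attr = TRUE)
})

test_that("SNK reproduces a hand-stepped studentized-range oracle", {
  # 4 groups, n = 6 each, exact means {0, 1.2, 1.4, 3.0}, MSE exactly 1
  a <- sqrt(5) / 2
  dev <- c(-a, -a, 0, 0, a, a)
  d <- data.frame(grp = rep(c("A", "B", "C", "D"), each = 6),
                  value = c(0 + dev, 1.2 + dev, 1.4 + dev, 3.0 + dev))
  g <- factorial_glm(d, "value", "grp", interactions = "none")
  expect_equal(g$sigma2, 1, tolerance = 1e-12)
  # published 5% studentized-range points for df = 20
  expect_equal(qtukey(0.95, 2, 20), 2.950, tolerance = 1e-3)
  expect_equal(qtukey(0.95, 3, 20), 3.578, tolerance = 1e-3)
  expect_equal(qtukey(0.95, 4, 20), 3.958, tolerance = 1e-3)
  # hand stepping with SE = sqrt(1/6) = 0.4082:
  #   span ABCD: q = 3.0/0.4082 = 7.35 > 3.958   -> significant
  #   span ABC : q = 1.4/0.4082 = 3.43 < 3.578   -> ns, blocks AB, AC, BC
  #   span BCD : q = 1.8/0.4082 = 4.41 > 3.578   -> significant
  #   span CD  : q = 1.6/0.4082 = 3.92 > 2.950   -> significant
  snk <- newman_keuls(g, "grp")
  sig <- snk$significant
  names(sig) <- paste(snk$group1, snk$group2)
  expect_true(sig[["A D"]]); expect_true(sig[["B D"]]); expect_true(sig[["C D"]])
  expect_false(sig[["A B"]]); expect_false(sig[["A C"]]); expect_false(sig[["B C"]])
})

test_that("SNK with equal means declares nothing; two groups reduce to the pooled t", {
  set.seed(24)
  d <- data.frame(grp = rep(c("A", "B", "C"), each = 8), value = rnorm(24))
  d$value <- d$value - ave(d$value, d$grp)  # all means exactly 0
  d$value <- d$value + rnorm(24, sd = 1e-8) # avoid exact ties in means
  g <- factorial_glm(d, "value", "grp", interactions = "none")
  expect_false(any(newman_keuls(g, "grp")$significant))
  for (i in 1:5) {
    d2 <- data.frame(grp = rep(c("A", "B"), each = 7),
                     value = rnorm(14, mean = rep(c(0, i / 3), each = 7)))
    g2 <- factorial_glm(d2, "value", "grp", interactions = "none")
    snk <- newman_keuls(g2, "grp")
    tt <- t.test(value ~ grp, data = d2, var.equal = TRUE)
    expect_equal(snk$significant, tt$p.value < 0.05)
  }
})

test_that("Bonferroni adjustment multiplies by the number of declared pairs", {
  set.seed(25)
  d <- make_cells(c(0, 2, 0, 2))
  g <- factorial_glm(d, "value", c("sex", "diet"), interactions = "full")
  one <- bonferroni_pairs(g, c("sex", "diet"), pairs = list(c("F.CTRL", "M.CTRL")))
  expect_equal(one$p_adj, one$p)  # single contrast: factor 1
  all4 <- bonferroni_pairs(g, c("sex", "diet"),
                           pairs = list(c("F.CTRL", "M.CTRL"), c("F.LPD", "M.LPD"),
                                        c("F.CTRL", "F.LPD"), c("M.CTRL", "M.LPD")))
  expect_equal(all4$p_adj, pmin(1, all4$p * 4))
  expect_true(all(all4$p_adj >= all4$p))
})

test_that("SNK blocking is internally consistent on random instances", {
  set.seed(26)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    d <- data.frame(grp = rep(LETTERS[1:k], each = 5),
                    value = rnorm(5 * k, mean = rep(runif(k, 0, 2), each = 5)))
    g <- factorial_glm(d, "value", "grp", interactions = "none")
    snk <- newman_keuls(g, "grp")
    # reconstruct ordered positions from the means
    mu <- sort(tapply(d$value, d$grp, mean))
    pos <- setNames(seq_along(mu), names(mu))
    i1 <- pmin(pos[snk$group1], pos[snk$group2])
    i2 <- pmax(pos[snk$group1], pos[snk$group2])
    sig <- matrix(NA, k, k)
    sig[cbind(i1, i2)] <- snk$significant
    for (r in seq_len(nrow(snk))) {
      if (sig[i1[r], i2[r]]) {
        # every significant pair exceeds its critical value ...
        expect_gte(snk$q[r], snk$q_crit[r])
        # ... and every enclosing span is significant too (no blocked parent)
        for (a in 1:i1[r]) for (b in i2[r]:k) {
          if (!(a == i1[r] && b == i2[r])) expect_true(sig[a, b])
        }
      }
    }
  }
})

test_that("repeated-measures ANOVA reproduces the split-plot df bookkeeping", {
  set.seed(27)
  d <- expand.grid(subject = factor(1:58), time = factor(1:7))
  d$group <- factor(rep(rep(1:4, c(15, 15, 14, 14)), 7))
  d$y <- rnorm(nrow(d)) + as.numeric(d$time) * 0.1
  rm <- repeated_measures_glm(d, "y", "subject", "time", "group")
  expect_equal(rm$df[rm$term == "group"], 3)
  expect_equal(rm$df_error[rm$term == "group"], 54)
  expect_equal(rm$df[rm$term == "time"], 6)
  expect_equal(rm$df_error[rm$term == "time"], 324)
  expect_equal(rm$df[rm$term == "group:time"], 18)
  expect_equal(rm$df_error[rm$term == "group:time"], 324)
})

test_that("a single time point collapses the repeated-measures model to the factorial GLM", {
  set.seed(28)
  d <- data.frame(subject = factor(1:40), time = factor(1),
                  sex = rep(c("F", "M"), 20), diet = rep(c("CTRL", "LPD"), each = 20))
  d$y <- rnorm(40)
  rm <- repeated_measures_glm(d, "y", "subject", "time", c("sex", "diet"))
  g <- factorial_glm(d, "y", c("sex", "diet"), interactions = "full")
  expect_equal(rm$F, g$anova$F)
  expect_equal(rm$p, g$anova$p)
})

test_that("a constant response triggers the exact-fit branch with all F zero", {
  d <- make_cells(c(3, 3, 3, 3), dev = rep(0, 5))
  expect_warning(g <- factorial_glm(d, "value", c("sex", "diet"),
                                    interactions = "full"), "exact-fit")
  expect_true(all(g$anova$F == 0))
  expect_true(all(g$anova$p == 1))
})
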