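test_that("quantile normalization equalizes column distributions and preserves ranks", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)
  set.seed(1)
  x <- matrix(rnorm(300), 50, 6)
  q <- quantile_normalize(x)
  sorted <- apply(q, 2, sort)
  for (j in 2:6) {
    expect_equal(sorted[, j], sorted[, 1])
    expect_equal(cor(q[, j], x[, j], method = "spearman"), 1)
  }
})

test_that("low-signal filter keeps everything at min_fraction 0 and removes dead probes", {
  set.seed(2)
  m <- matrix(rnorm(200, mean = 8), 20, 10)
  expect_true(all(low_signal_filter(m, 0.1, 0)$keep))
  m[1, ] <- -100  # below background everywhere
  expect_false(low_signal_filter(m, 0.1, 0.5)$keep[1])
  exp <- simulate_expression(sim_design(n_probes = 4000), seed = 5,
                             dead_fraction = 0.05)
  flt <- low_signal_filter(quantile_normalize(exp$matrix))
  removed <- rownames(exp$matrix)[!flt$keep]
  expect_true(all(exp$truth$dead_probes %in% removed))
})

test_that("PC1 scores match an SVD oracle and recover the simulated batch axis", {
  set.seed(3)
  u <- rnorm(40); v <- rnorm(6)
  rank1 <- outer(u, v)
  p <- pc1_scores(rank1 - rowMeans(rank1) + 5)
  expect_equal(p$var_explained, 1)
  x <- matrix(rnorm(240), 40, 6)
  got <- pc1_scores(x)
  sv <- svd(x - rowMeans(x))
  oracle <- sv$v[, 1] * sv$d[1]
  if (sign(oracle[1]) != sign(got$scores[1])) oracle <- -oracle
  expect_equal(unname(got$scores), oracle, tolerance = 1e-8)
  exp <- simulate_expression(sim_design(n_probes = 3000),
                             noise = noise_model(batch_frac = 0.5), seed = 6)
  main <- exp$samples$batch == "main"
  sc <- pc1_scores(exp$matrix[, main])$scores
  expect_gt(abs(cor(sc, exp$truth$batch_scores[main])), 0.95)
})

test_that("per-probe least squares agrees with lm to near machine precision", {
  # two-group toy probe: logFC 1, zero residual variance
  X <- cbind(1, c(0, 0, 1, 1))
  colnames(X) <- c("(Intercept)", "grp")
  f <- probe_lm(matrix(c(5, 5, 6, 6), 1, 4), X)
  expect_equal(unname(f$coefficients[1, ]), c(5, 1))
  expect_equal(f$s2, 0)
  # intercept-only model recovers the sample mean
  y <- rnorm(10)
  f0 <- probe_lm(matrix(y, 1, 10), matrix(1, 10, 1,
                 dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(f0$coefficients[1, 1]), mean(y))
  set.seed(4)
  Y <- matrix(rnorm(20 * 12), 20, 12)
  X <- cbind(`(Intercept)` = 1, a = rnorm(12), b = rep(0:1, 6))
  f <- probe_lm(Y, X)
  for (g in 1:20) {
    o <- lm(Y[g, ] ~ 0 + X)
    expect_equal(unname(f$coefficients[g, ]), unname(coef(o)), tolerance = 1e-10)
    expect_equal(f$s2[g], sum(resid(o)^2) / o$df.residual, tolerance = 1e-10)
  }
  Xbad <- cbind(X, a2 = X[, "a"])
  expect_error(probe_lm(Y, Xbad), "a2")
})

test_that("top-K intersection matches a brute-force sort oracle", {
  set.seed(5)
  mk_fit <- function(B, p) {
    structure(list(B = cbind(stressswim = B), p = cbind(stressswim = p),
                   probes = sprintf("P%03d", seq_along(B))),
              class = "probe_fit")
  }
  B <- rnorm(200); p <- runif(200)
  same <- mk_fit(B, p)
  expect_length(consensus_top_k(same, same, K = 50), 50)
  rev_fit <- mk_fit(-B, p)
  expect_length(consensus_top_k(mk_fit(B, p), rev_fit, K = 100), 0)
  fA <- mk_fit(rnorm(200), runif(200))
  fB <- mk_fit(rnorm(200), runif(200))
  brute <- function(f, K) {
    d <- data.frame(B = f$B[, 1], p = f$p[, 1], id = f$probes)
    d <- d[order(-d$B, d$p, d$id), ]
    d$id[1:K]
  }
  expect_identical(consensus_top_k(fA, fB, K = 60),
                   sort(intersect(brute(fA, 60), brute(fB, 60))))
})

test_that("replication filter applies the p < 0.1 same-direction rule", {
  mk <- function(lfc, s2 = NULL, probes = sprintf("P%d", seq_along(lfc))) {
    structure(list(coefficients = cbind(stressswim = lfc),
                   s2 = s2 %||% rep(1, length(lfc)),
                   df = rep(5, length(lfc)),
                   v_unscaled = c(stressswim = 1),
                   probes = probes), class = "probe_fit")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  main <- mk(c(1, 1, 1))
  # choose replication effects whose ordinary t gives p ~ {0.05, 0.05, 0.2}
  t_for_p <- function(p) qt(1 - p / 2, df = 5)
  repl <- mk(c(t_for_p(0.05), -t_for_p(0.05), t_for_p(0.2)))
  got <- replication_validate(c("P1", "P2", "P3"), main, repl, alpha_rep = 0.1)
  expect_identical(got, "P1")   # same sign, p = 0.05 kept; opposite sign dropped;
                                # p = 0.2 dropped
  main0 <- mk(c(0))
  repl0 <- mk(c(10), probes = "P1")
  main0$probes <- "P1"
  expect_length(replication_validate("P1", main0, repl0), 0)  # sign 0 never matches
})

test_that("relative scaling divides by the per-transcript maximum", {
  expect_equal(unname(relative_scale(rbind(c(2, 4, 8)))), rbind(c(0.25, 0.5, 1)))
  expect_equal(unname(relative_scale(rbind(c(3, 3, 3)))), rbind(c(1, 1, 1)))
  set.seed(6)
  x <- matrix(runif(30, 1, 5), 5, 6)
  expect_equal(relative_scale(relative_scale(x)), relative_scale(x))
})

test_that("the whole screen is deterministic given its input", {
  exp <- simulate_expression(sim_design(n_probes = 2000),
                             effects = list(effect_spec(1:20, "stress", 1)),
                             seed = 8)
  s1 <- de_screen(exp, K = 200)
  s2 <- de_screen(exp, K = 200)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$validated, s2$validated)
})

test_that("an alpha_rep of zero empties the validated set", {
  exp <- simulate_expression(sim_design(n_probes = 1500),
                             effects = list(effect_spec(1:20, "stress", 1)),
                             seed = 9)
  scr <- de_screen(exp, K = 200, alpha_rep = 0)
  expect_length(scr$validated, 0)
})
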