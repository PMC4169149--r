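test_that("balanced one-way designs reproduce closed-form ANOVA REML", {
  set.seed(11)
  interior <- 0
  for (case in 1:6) {
    g <- sample(8:15, 1)
    m <- sample(2:4, 1)
    sb <- runif(1, 0.2, 1.5)
    y <- rep(rnorm(g, sd = sqrt(sb)), each = m) + rnorm(g * m)
    group <- rep(seq_len(g), each = m)
    cf <- oneway_reml(y, group)
    Y <- matrix(tapply(y, group, mean), ncol = 1)
    SSW <- matrix(sum((y - ave(y, group))^2), 1, 1)
    fit <- fit_mvlmm(Y, m = m, SSW = SSW,
                     random = list(rt_ident("diag", "group")),
                     residual = "diag")
    if (cf$sigma2_b > 0) {
      ## interior optimum: the ANOVA identities are the REML estimates
      interior <- interior + 1
      expect_equal(drop(fit$components$group), cf$sigma2_b,
                   tolerance = 1e-8 * max(1, cf$sigma2_b))
      expect_equal(fit$components$residual[1, 1], cf$sigma2_w,
                   tolerance = 1e-7)
    } else {
      ## boundary: group variance pinned at 0, residual is the pooled
      ## variance about the grand mean
      expect_lt(drop(fit$components$group), 1e-8)
      expect_equal(fit$components$residual[1, 1],
                   sum((y - mean(y))^2) / (g * m - 1), tolerance = 1e-7)
    }
  }
  expect_gte(interior, 3)   # most cases must exercise the identity
})

test_that("a model with no random terms equals the dense OLS residual likelihood", {
  set.seed(3)
  n <- 25; t <- 2; m <- 2
  gv <- matrix(0, n, t)
  ph <- make_pheno(gv, mu = c(1, 5), m = m, resid_sd = 1.3, seed = 3)
  st <- magicqtl:::pheno_line_stats(ph)
  fit <- fit_mvlmm(st$Y, m = m, SSW = st$SSW, random = list(),
                   residual = "diag")
  dl <- long_design(n, t, m)
  covfun <- function(par) diag(exp(par)[dl$trait])
  oracle <- dense_reml_fit(ph$value, dl$X, covfun, npar = t, seed = 5)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
})

test_that("small multitrait fits match the dense brute-force REML maximiser", {
  set.seed(21)
  n <- 20; t <- 2; m <- 2; K <- 3
  P <- random_prob_matrix(n, K)
  a <- rnorm(K * 4, sd = 0.5)
  gv <- cbind(P %*% a, P %*% a * 0.5) + matrix(rnorm(n * t, sd = 0.4), n, t)
  ph <- make_pheno(gv, mu = c(9, 10), m = m, seed = 22)
  st <- magicqtl:::pheno_line_stats(ph)
  red <- reduce_dimension(P)
  fit <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                   random = list(rt_genome(red$eig, "diag"),
                                 rt_ident("diag")),
                   residual = "diag")
  dl <- long_design(n, t, m)
  PPt <- tcrossprod(P)
  covfun <- function(par) {
    Ga <- diag(exp(par[1:2]), 2)
    Gp <- diag(exp(par[3:4]), 2)
    R <- diag(exp(par[5:6]), 2)
    Vg <- kronecker(Ga, PPt) + kronecker(Gp, diag(n))
    dl$Zg %*% Vg %*% t(dl$Zg) + diag(diag(R)[dl$trait])
  }
  oracle <- dense_reml_fit(ph$value, dl$X, covfun, npar = 6, seed = 7,
                           n_starts = 5)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
})

test_that("likelihoods are deterministic across initial values", {
  set.seed(5)
  n <- 15; t <- 3; m <- 2
  gv <- matrix(rnorm(n * t, sd = 0.6), n, t)
  ph <- make_pheno(gv, mu = c(1, 2, 3), m = m, seed = 6)
  st <- magicqtl:::pheno_line_stats(ph)
  terms <- list(rt_ident("us"))
  f1 <- fit_mvlmm(st$Y, m = m, SSW = st$SSW, random = terms,
                  residual = "diag")
  f2 <- fit_mvlmm(st$Y, m = m, SSW = st$SSW, random = terms,
                  residual = "diag", init = f1$theta + 0.8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("nested models keep likelihood monotone and boundary fits collapse", {
  set.seed(9)
  n <- 18; t <- 2; m <- 2
  ## no genome signal at all: genome variance should pin near zero
  gv <- matrix(rnorm(n * t, sd = 0.5), n, t)
  ph <- make_pheno(gv, mu = c(0, 1), m = m, seed = 10)
  st <- magicqtl:::pheno_line_stats(ph)
  P <- random_prob_matrix(n, 2)
  red <- reduce_dimension(P)
  f_null <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                      random = list(rt_ident("diag")), residual = "diag")
  f_full <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                      random = list(rt_genome(red$eig, "diag"),
                                    rt_ident("diag")),
                      residual = "diag")
  expect_gte(f_full$loglik, f_null$loglik - 1e-6)
  ## adding a true-zero variance term changes the likelihood only at the
  ## boundary-resolution level
  expect_lt(f_full$loglik - f_null$loglik, 2)
  if (all(f_full$boundary$genome))
    expect_equal(f_full$loglik, f_null$loglik, tolerance = 1e-6)
})

test_that("REML is invariant to reordering lines", {
  set.seed(31)
  n <- 16; t <- 2; m <- 2
  P <- random_prob_matrix(n, 2)
  gv <- matrix(rnorm(n * t), n, t)
  ph <- make_pheno(gv, mu = c(0, 0), m = m, seed = 32)
  st <- magicqtl:::pheno_line_stats(ph)
  perm <- sample(n)
  f1 <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                  random = list(rt_genome(reduce_dimension(P)$eig, "diag"),
                                rt_ident("diag")),
                  residual = "diag")
  f2 <- fit_mvlmm(st$Y[perm, ], m = m, SSW = st$SSW,
                  random = list(rt_genome(reduce_dimension(P[perm, ])$eig,
                                          "diag"),
                                rt_ident("diag")),
                  residual = "diag")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
})

test_that("block-term BLUPs match the dense generalized-least-squares oracle", {
  set.seed(41)
  n <- 10; t <- 2; m <- 2
  W <- random_prob_matrix(n, 1)           # one founder block
  a_true <- c(1, -1, -0.5, 0.5)
  gv <- cbind(W %*% a_true, W %*% a_true) +
    matrix(rnorm(n * t, sd = 0.3), n, t)
  ph <- make_pheno(gv, mu = c(0, 2), m = m, seed = 42)
  st <- magicqtl:::pheno_line_stats(ph)
  fit <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                   random = list(rt_ident("diag"),
                                 rt_block(W, "diag", "qtl1")),
                   residual = "diag")
  bp <- blups_with_pev(fit, "qtl1")
  ## dense route at the fitted components
  Gp <- fit$components$polygenic
  R <- fit$components$residual
  s2q <- fit$components$qtl1
  dl <- long_design(n, t, m)
  Zq <- dl$Zg %*% kronecker(diag(t), W)
  Gq <- diag(rep(s2q, each = 4))
  V <- dl$Zg %*% kronecker(Gp, diag(n)) %*% t(dl$Zg) +
    Zq %*% Gq %*% t(Zq) + diag(diag(R)[dl$trait])
  dres <- dense_blup(ph$value, dl$X, V, Zq, Gq)
  expect_equal(bp$blup, dres$blup, tolerance = 1e-6)
  expect_equal(bp$pev, Gq - dres$var, tolerance = 1e-6)
  ## shrinkage: PEV diagonal below the prior variance
  expect_true(all(diag(bp$pev) <= rep(s2q, each = 4) + 1e-10))
})

test_that("zero-variance terms have zero BLUPs and PEV", {
  set.seed(51)
  n <- 14; t <- 2; m <- 2
  gv <- matrix(rnorm(n * t), n, t)
  ph <- make_pheno(gv, mu = c(0, 0), m = m, seed = 52)
  st <- magicqtl:::pheno_line_stats(ph)
  W <- random_prob_matrix(n, 1)
  ## response unrelated to W: variance should hit the boundary
  fit <- fit_mvlmm(st$Y, m = m, SSW = st$SSW,
                   random = list(rt_ident("diag"),
                                 rt_block(W, "ident", "qtl1")),
                   residual = "diag")
  expect_s3_class(fit, "mvlmm_fit")
  bp <- blups_with_pev(fit, "qtl1")
  expect_length(bp$blup, 8)
  if (all(fit$boundary$qtl1)) {
    expect_lt(max(abs(bp$blup)), 1e-6)
    expect_lt(max(abs(bp$pev)), 1e-6)
  }
})
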