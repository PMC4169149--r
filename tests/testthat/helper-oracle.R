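# Independent oracles used across the suite.  These deliberately avoid
# the package's internals: likelihoods are evaluated densely on the
# whole observation vector and maximised by generic numerical
# optimisation.

# Dense REML log-likelihood for a fixed covariance V (N x N):
# l = -1/2 [ (N - p) log 2pi + log|V| + log|X'V^-1 X| + y' Py ]
dense_reml_loglik <- function(y, X, V) {
  N <- length(y)
  p <- ncol(X)
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  b <- crossprod(X, Vi_y)
  beta <- solve(XtViX, b)
  quad <- sum(y * Vi_y) - sum(b * beta)
  -0.5 * ((N - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
            determinant(XtViX, logarithm = TRUE)$modulus[1] + quad)
}

# Maximise dense REML over a parameter vector; covfun(par) returns V.
dense_reml_fit <- function(y, X, covfun, npar, lower = rep(-25, npar),
                           upper = rep(25, npar), n_starts = 4,
                           start_sd = 1.5, seed = 1) {
  obj <- function(par) {
    V <- covfun(par)
    ll <- tryCatch(dense_reml_loglik(y, X, V), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e9)
    -ll
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) rep(0, npar) else rnorm(npar, sd = start_sd)
    start <- pmin(pmax(start, lower + 0.01), upper - 0.01)
    opt <- tryCatch(nlminb(start, obj, lower = lower, upper = upper,
                           control = list(iter.max = 800, eval.max = 2000)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  list(loglik = -best$objective, par = best$par)
}

# BLUP and variance of random effects u ~ N(0, G) with obs design Z:
# u_hat = G Z' P y, var(u_hat) = G Z' P Z G, with P the REML projector.
dense_blup <- function(y, X, V, Z, G) {
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  Pmat <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  u <- G %*% crossprod(Z, Pmat %*% y)
  Vu <- G %*% crossprod(Z, Pmat %*% Z) %*% G
  list(blup = as.vector(u), var = Vu)
}

# Long-format design pieces for a balanced line x trait x rep layout
# matching sim_phenotypes() ordering (line fastest, then trait, then rep).
long_design <- function(n, t, m) {
  line <- rep(rep(seq_len(n), t), m)
  trait <- rep(rep(seq_len(t), each = n), m)
  X <- matrix(0, n * t * m, t)
  X[cbind(seq_along(trait), trait)] <- 1
  ## indicator of (trait, line) cell, trait-major to match G_t (x) B_n
  Zg <- matrix(0, n * t * m, n * t)
  Zg[cbind(seq_along(line), (trait - 1L) * n + line)] <- 1
  list(line = line, trait = trait, X = X, Zg = Zg)
}

# Brute-force forward-backward oracle for a <= 3-marker chromosome:
# enumerate all founder-state paths with the same transition/emission
# model as the HMM.
enumerate_posteriors <- function(score_row, founder_geno, pos,
                                 error_rate = 1e-4, n_f = 4) {
  rk <- length(pos)
  emis <- function(j, s) {
    if (is.na(score_row[j])) return(1)
    if (founder_geno[s, j] == score_row[j]) 1 - error_rate else error_rate
  }
  trans <- function(d, s1, s2) {
    r <- 0.5 * (1 - exp(-2 * d / 100))
    off <- r / (1 + 2 * r)
    if (s1 == s2) 1 - 3 * off else off
  }
  states <- as.matrix(expand.grid(rep(list(seq_len(n_f)), rk)))
  wts <- apply(states, 1, function(ss) {
    w <- (1 / n_f) * emis(1, ss[1])
    for (j in seq_len(rk - 1))
      w <- w * trans(pos[j + 1] - pos[j], ss[j], ss[j + 1]) *
        emis(j + 1, ss[j + 1])
    w
  })
  post <- matrix(0, rk, n_f)
  for (j in seq_len(rk)) for (s in seq_len(n_f))
    post[j, s] <- sum(wts[states[, j] == s])
  post / rowSums(post)
}

# Closed-form REML for the balanced one-way random-effects model.
oneway_reml <- function(y, group) {
  g <- length(unique(group))
  m <- length(y) / g
  means <- tapply(y, group, mean)
  msb <- m * var(as.vector(means))
  msw <- sum((y - means[group])^2) / (g * (m - 1))
  list(sigma2_b = max(0, (msb - msw) / m), sigma2_w = msw)
}

# Small random founder-probability matrix: n lines, K intervals, rows of
# each founder block on the simplex.
random_prob_matrix <- function(n, K, n_f = 4) {
  P <- matrix(0, n, K * n_f)
  for (j in seq_len(K)) {
    raw <- matrix(rexp(n * n_f), n, n_f)^2
    P[, (j - 1) * n_f + seq_len(n_f)] <- raw / rowSums(raw)
  }
  P
}

# founder_probs wrapper around an arbitrary interval-mode matrix
as_founder_probs <- function(P, n_f = 4, chrom = "C1") {
  K <- ncol(P) / n_f
  index <- data.frame(chrom = chrom, item = rep(seq_len(K), each = n_f),
                      founder = rep(seq_len(n_f), K),
                      left_cM = rep(seq_len(K) - 1, each = n_f) * 10,
                      right_cM = rep(seq_len(K), each = n_f) * 10,
                      pos_cM = (rep(seq_len(K), each = n_f) - 0.5) * 10,
                      stringsAsFactors = FALSE)
  rownames(P) <- paste0("L", seq_len(nrow(P)))
  magicqtl:::new_founder_probs(P, index, NULL, "interval", n_f)
}

# long phenotype frame from a line x trait matrix of genetic values
make_pheno <- function(gvals, mu, m = 2, resid_sd = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(gvals); t <- ncol(gvals)
  lines <- paste0("L", seq_len(n))
  traits <- paste0("T", seq_len(t))
  data.frame(
    line = rep(rep(lines, t), m),
    trait = rep(rep(traits, each = n), m),
    rep = rep(seq_len(m), each = n * t),
    value = rep(rep(mu, each = n), m) + rep(as.vector(gvals), m) +
      rnorm(n * t * m, sd = resid_sd),
    stringsAsFactors = FALSE)
}
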