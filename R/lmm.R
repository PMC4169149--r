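## REML engine for the multitrait / multienvironment mixed models used
## by the whole-genome scan.
##
## Model (n lines, t traits/environments, m replicates, balanced):
##   y_isk = mu_s + u_gis + e_isk,   e ~ N(0, R) across traits within a
## (line, replicate) unit, independent across units.  The genetic
## covariance of vec(U_g) (traits stacked, trait-major) is a sum of
## Kronecker terms T(theta) (x) B, where B is either the identity
## (polygenic), the eigendecomposed whole-genome kernel PP' (the
## dimension-reduced marker term), or a low-rank founder-probability
## block WW' for a selected QTL.
##
## REML factorises exactly (orthonormal transform over replicates) into
## a line-means model plus within-line replicate contrasts.  The means
## covariance is diagonalised by the genome kernel's eigenbasis; selected
## QTL blocks are handled with Woodbury/determinant-lemma identities, so
## every likelihood and gradient evaluation costs O(n t^3 + n q^2) with
## q = total founder columns of selected QTL.  Likelihoods carry their
## full constants and match a dense whole-data REML evaluation exactly.

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- variance structure parameterisations -------------------------------

struct_npar <- function(structure, t) {
  switch(structure,
         diag = t,
         us = t * (t + 1L) / 2L,
         ident = 1L,
         common = 1L,
         stop("unknown structure: ", structure))
}

## lower-triangle index order for "us": column-wise (1,1),(2,1),..,(t,t)
us_index <- function(t) {
  ij <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
}

struct_build <- function(structure, theta, t) {
  switch(structure,
         diag = diag(exp(theta), t, t),
         us = {
           L <- matrix(0, t, t)
           ij <- us_index(t)
           v <- theta
           v[ij[, 1] == ij[, 2]] <- exp(theta[ij[, 1] == ij[, 2]])
           L[ij] <- v
           L %*% t(L)
         },
         ident = diag(exp(theta), t, t),
         common = matrix(exp(theta), t, t))
}

## derivative of T wrt parameter k (on the internal scale)
struct_deriv <- function(structure, theta, t, k) {
  switch(structure,
         diag = {
           D <- matrix(0, t, t); D[k, k] <- exp(theta[k]); D
         },
         us = {
           ij <- us_index(t)
           L <- matrix(0, t, t)
           v <- theta
           diag_sel <- ij[, 1] == ij[, 2]
           v[diag_sel] <- exp(theta[diag_sel])
           L[ij] <- v
           dL <- matrix(0, t, t)
           dL[ij[k, 1], ij[k, 2]] <- if (diag_sel[k]) L[ij[k, 1], ij[k, 2]] else 1
           dL %*% t(L) + L %*% t(dL)
         },
         ident = diag(exp(theta), t, t),
         common = matrix(exp(theta), t, t))
}

struct_init <- function(structure, t, v) {
  switch(structure,
         diag = rep(log(v), t),
         us = {
           ij <- us_index(t)
           ifelse(ij[, 1] == ij[, 2], 0.5 * log(v), 0)
         },
         ident = log(v),
         common = log(v))
}

## ---- batched symmetric t x t inverse / logdet ---------------------------

## M: n x t^2 matrix (column-major t x t blocks per row).  Returns
## list(inv = n x t^2, logdet = n vector).  Supports t <= 3.
batch_inv_sym <- function(M, t) {
  if (t == 1L) {
    return(list(inv = 1 / M, logdet = log(M[, 1])))
  }
  if (t == 2L) {
    a <- M[, 1]; b <- M[, 2]; d <- M[, 4]
    det <- a * d - b * b
    inv <- cbind(d, -b, -b, a) / det
    return(list(inv = inv, logdet = log(det)))
  }
  if (t == 3L) {
    a <- M[, 1]; b <- M[, 2]; c <- M[, 3]
    d <- M[, 5]; e <- M[, 6]; f <- M[, 9]
    A11 <- d * f - e * e
    A12 <- c * e - b * f
    A13 <- b * e - c * d
    det <- a * A11 + b * A12 + c * A13
    i11 <- A11 / det
    i12 <- A12 / det
    i13 <- A13 / det
    i22 <- (a * f - c * c) / det
    i23 <- (b * c - a * e) / det
    i33 <- (a * d - b * b) / det
    inv <- cbind(i11, i12, i13, i12, i22, i23, i13, i23, i33)
    return(list(inv = inv, logdet = log(det)))
  }
  stop("only t <= 3 traits/environments are supported")
}

## apply block-diagonal inverse (n x t^2) to V (nt x k, trait-major rows)
batch_block_mult <- function(Minv, V, n, t) {
  k <- ncol(V)
  out <- matrix(0, n * t, k)
  for (s in seq_len(t)) {
    rs <- (s - 1L) * n + seq_len(n)
    acc <- matrix(0, n, k)
    for (sp in seq_len(t)) {
      rsp <- (sp - 1L) * n + seq_len(n)
      acc <- acc + Minv[, (sp - 1L) * t + s] * V[rsp, , drop = FALSE]
    }
    out[rs, ] <- acc
  }
  out
}

## ---- random term constructors -------------------------------------------

#' Random-term constructors for [fit_mvlmm()]
#'
#' `rt_genome()` declares the dimension-reduced whole-genome marker term
#' with kernel `PP'` supplied as its eigendecomposition (see
#' [reduce_dimension()]); `rt_ident()` declares an identity-kernel term
#' (the polygenic effect); `rt_block()` declares a low-rank
#' founder-probability block term (a selected QTL), with `structure`
#' `"diag"` (separate variance per trait), `"ident"` (one variance,
#' trait-specific effects) or `"common"` (one founder-effect vector
#' shared by all traits/environments).
#'
#' @param eig eigendecomposition `list(values, vectors)` of the genome
#'   kernel.
#' @param W `n x k` matrix of founder probabilities for the block term.
#' @param structure trait covariance structure: `"diag"`, `"us"`
#'   (unstructured, genome/identity terms only), `"ident"` or `"common"`
#'   (block terms only).
#' @param name term label (unique within a fit).
#' @return term specification list.
#' @name random_terms
NULL

#' @rdname random_terms
#' @export
rt_genome <- function(eig, structure = c("diag", "us"), name = "genome") {
  structure <- match.arg(structure)
  list(kind = "dense", B = "eig", eig = eig, structure = structure, name = name)
}

#' @rdname random_terms
#' @export
rt_ident <- function(structure = c("diag", "us"), name = "polygenic") {
  structure <- match.arg(structure)
  list(kind = "dense", B = "ident", eig = NULL, structure = structure, name = name)
}

#' @rdname random_terms
#' @export
rt_block <- function(W, structure = c("diag", "ident", "common"), name) {
  structure <- match.arg(structure)
  list(kind = "lowrank", W = as.matrix(W), structure = structure, name = name)
}

## ---- model assembly ------------------------------------------------------

build_mvlmm <- function(Y, m, SSW, random, residual, control) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  if (t > 3L) stop("only t <= 3 traits/environments are supported")
  m <- as.integer(m)
  if (m > 1L && is.null(SSW))
    stop("SSW (within-line cross-products) required when m > 1")
  nm <- vapply(random, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate random term names")
  dense <- random[vapply(random, function(x) x$kind == "dense", TRUE)]
  lowrank <- random[vapply(random, function(x) x$kind == "lowrank", TRUE)]
  genome <- Filter(function(x) x$B == "eig", dense)
  if (length(genome) > 1L)
    stop("at most one genome (eigendecomposed kernel) term is supported")
  if (length(genome) == 1L) {
    U <- genome[[1]]$eig$vectors
    lam_raw <- pmax(genome[[1]]$eig$values, 0)
  } else {
    U <- NULL
    lam_raw <- NULL
  }
  vscale <- mean(apply(Y, 2, stats::var))
  if (!is.finite(vscale) || vscale <= 0) vscale <- 1
  ## rotated, sqrt(m)-scaled means and fixed design
  Z <- if (is.null(U)) Y else crossprod(U, Y)
  ystar <- sqrt(m) * as.vector(Z)
  u1 <- if (is.null(U)) rep(1, n) else as.vector(crossprod(U, rep(1, n)))
  Xstar <- matrix(0, n * t, t)
  for (s in seq_len(t)) Xstar[(s - 1L) * n + seq_len(n), s] <- sqrt(m) * u1
  ## dense term eigenvalue columns (scaled to mean 1)
  dense_meta <- lapply(dense, function(tm) {
    if (tm$B == "eig") {
      sc <- mean(lam_raw)
      list(name = tm$name, structure = tm$structure,
           lam = lam_raw / sc, scale = sc)
    } else {
      list(name = tm$name, structure = tm$structure, lam = rep(1, n), scale = 1)
    }
  })
  ## low-rank terms: rotate and scale
  lowrank_meta <- lapply(lowrank, function(tm) {
    W <- tm$W
    stopifnot(nrow(W) == n)
    Wr <- if (is.null(U)) W else crossprod(U, W)
    sc <- mean(colSums(Wr^2))
    if (sc <= 0) sc <- 1
    list(name = tm$name, structure = tm$structure,
         W = Wr / sqrt(sc), scale = sc, k = ncol(W))
  })
  ## parameter table
  blocks <- list()
  off <- 0L
  add_block <- function(blocks, type, id, structure, npar) {
    blocks[[length(blocks) + 1L]] <- list(type = type, id = id,
                                          structure = structure,
                                          npar = npar, offset = off)
    blocks
  }
  for (i in seq_along(dense_meta)) {
    np <- struct_npar(dense_meta[[i]]$structure, t)
    blocks <- add_block(blocks, "dense", i, dense_meta[[i]]$structure, np)
    off <- off + np
  }
  for (i in seq_along(lowrank_meta)) {
    st <- lowrank_meta[[i]]$structure
    np <- if (st == "diag") t else 1L
    blocks <- add_block(blocks, "lowrank", i, st, np)
    off <- off + np
  }
  np <- struct_npar(residual, t)
  blocks <- add_block(blocks, "resid", 0L, residual, np)
  off <- off + np
  lb <- log(control$lb_factor * vscale)
  lower <- rep(lb, off)
  upper <- rep(log(1e8 * vscale), off)
  for (b in blocks) {           # off-diagonal us parameters unbounded
    if (b$structure == "us") {
      ij <- us_index(t)
      offd <- which(ij[, 1] != ij[, 2])
      lower[b$offset + offd] <- -30
      upper[b$offset + offd] <- 30
    }
  }
  list(n = n, t = t, m = m, npar = off, blocks = blocks,
       dense = dense_meta, lowrank = lowrank_meta, residual = residual,
       U = U, lam_raw = lam_raw, ystar = ystar, Xstar = Xstar,
       SSW = SSW, vscale = vscale, lower = lower, upper = upper,
       lines = rownames(Y), traits = colnames(Y))
}

block_theta <- function(model, theta, b) theta[b$offset + seq_len(b$npar)]

## expand theta into component matrices (internal scale)
theta_components <- function(model, theta) {
  t <- model$t
  Ts <- list(); Gs <- list(); R <- NULL
  for (b in model$blocks) {
    th <- block_theta(model, theta, b)
    if (b$type == "dense") {
      Ts[[b$id]] <- struct_build(b$structure, th, t)
    } else if (b$type == "lowrank") {
      k <- ncol(model$lowrank[[b$id]]$W)
      g <- switch(b$structure,
                  diag = rep(exp(th), each = k),
                  ident = rep(exp(th), t * k),
                  common = rep(exp(th), k))
      Gs[[b$id]] <- g
    } else {
      R <- struct_build(b$structure, th, t)
    }
  }
  list(T = Ts, g = Gs, R = R)
}

## assemble F (nt x q) from low-rank terms; returns F and column map
build_F <- function(model) {
  n <- model$n; t <- model$t; m <- model$m
  cols <- list(); mapc <- list()
  for (i in seq_along(model$lowrank)) {
    lm <- model$lowrank[[i]]
    k <- ncol(lm$W)
    if (lm$structure %in% c("diag", "ident")) {
      ## columns (s, f): e_s (x) W[, f]
      Fi <- matrix(0, n * t, t * k)
      for (s in seq_len(t))
        Fi[(s - 1L) * n + seq_len(n), (s - 1L) * k + seq_len(k)] <-
          sqrt(m) * lm$W
      mapc[[i]] <- data.frame(term = i, trait = rep(seq_len(t), each = k),
                              col = rep(seq_len(k), t))
    } else {                    # common: 1_t (x) W[, f]
      Fi <- matrix(0, n * t, k)
      for (s in seq_len(t))
        Fi[(s - 1L) * n + seq_len(n), ] <- sqrt(m) * lm$W
      mapc[[i]] <- data.frame(term = i, trait = NA_integer_,
                              col = seq_len(k))
    }
    cols[[i]] <- Fi
  }
  if (!length(cols)) return(list(F = matrix(0, n * t, 0),
                                 map = data.frame(term = integer(0),
                                                  trait = integer(0),
                                                  col = integer(0))))
  list(F = do.call(cbind, cols), map = do.call(rbind, mapc))
}

## ---- core evaluation -----------------------------------------------------

## Evaluates REML loglik, gradient and the solve cache at theta.
mv_eval <- function(model, theta, Fmat) {
  n <- model$n; t <- model$t; m <- model$m
  cmp <- theta_components(model, theta)
  ## Sigma0 blocks: M_i = sum_d m lam_d[i] T_d + R
  M <- matrix(0, n, t * t)
  Rv <- as.vector(cmp$R)
  for (d in seq_along(model$dense)) {
    Tv <- as.vector(cmp$T[[d]])
    M <- M + (m * model$dense[[d]]$lam) %*% t(Tv)
  }
  M <- M + rep(1, n) %*% t(Rv)
  bi <- batch_inv_sym(M, t)
  Minv <- bi$inv
  q <- ncol(Fmat$F)
  g <- if (q) unlist(cmp$g) else numeric(0)
  if (q) {
    Fs <- batch_block_mult(Minv, Fmat$F, n, t)   # Sigma0^{-1} F
    Fhat <- sweep(Fs, 2L, sqrt(g), `*`)
    Cq <- crossprod(Fmat$F, Fhat)                # F' S0^{-1} F g^{1/2}
    H <- diag(q) + sweep(Cq, 1L, sqrt(g), `*`)   # I + g2 F'S0F g2
    H <- (H + t(H)) / 2
    cH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cH)) return(list(ok = FALSE))
    ldH <- 2 * sum(log(diag(cH)))
    Hinv <- chol2inv(cH)
  } else {
    Fhat <- matrix(0, n * t, 0); Hinv <- matrix(0, 0, 0); ldH <- 0
  }
  solveSigma <- function(V) {
    V0 <- batch_block_mult(Minv, V, n, t)
    if (q) V0 - Fhat %*% (Hinv %*% crossprod(Fhat, V)) else V0
  }
  X <- model$Xstar
  y <- model$ystar
  Xs <- solveSigma(X)
  XtVX <- crossprod(X, Xs)
  cX <- tryCatch(chol((XtVX + t(XtVX)) / 2), error = function(e) NULL)
  if (is.null(cX)) return(list(ok = FALSE))
  XtVXinv <- chol2inv(cX)
  vy <- solveSigma(cbind(y))
  bvec <- crossprod(X, vy)
  beta <- XtVXinv %*% bvec
  quad <- sum(y * vy) - sum(bvec * beta)
  w <- as.vector(vy) - as.vector(Xs %*% beta)
  ldS <- sum(bi$logdet) + ldH
  ldX <- 2 * sum(log(diag(cX)))
  ll <- -0.5 * ((n * t - t) * log(2 * pi) + ldS + ldX + quad)
  ## within-replicate contrast part
  Rinv <- solve(cmp$R)
  if (m > 1L) {
    ldR <- determinant(cmp$R, logarithm = TRUE)$modulus[1]
    ll <- ll - 0.5 * (n * (m - 1) * (t * log(2 * pi) + ldR) +
                        sum(Rinv * model$SSW))
  }
  list(ok = TRUE, ll = ll, Minv = Minv, Fhat = Fhat, Hinv = Hinv,
       Xs = Xs, XtVXinv = XtVXinv, w = w, beta = beta, g = g,
       cmp = cmp, solveSigma = solveSigma, Fmat = Fmat, Rinv = Rinv,
       quad = quad)
}

## analytic gradient of the REML loglik at a cached evaluation
mv_grad <- function(model, theta, ev) {
  n <- model$n; t <- model$t; m <- model$m
  w <- ev$w
  ws <- matrix(w, n, t)
  q <- length(ev$g)
  rows <- function(s) (s - 1L) * n + seq_len(n)
  ## trace families: D in {lam_d} per dense term and 1 for residual
  fam_D <- c(lapply(model$dense, function(d) m * d$lam), list(rep(1, n)))
  Fs_by_trait <- if (q) lapply(seq_len(t), function(s)
    ev$Fhat[rows(s), , drop = FALSE]) else NULL
  Xs_by_trait <- lapply(seq_len(t), function(s)
    ev$Xs[rows(s), , drop = FALSE])
  traceP <- vector("list", length(fam_D))
  Qw <- vector("list", length(fam_D))
  for (fi in seq_along(fam_D)) {
    D <- fam_D[[fi]]
    Tr <- matrix(0, t, t); Qm <- matrix(0, t, t)
    for (s in seq_len(t)) for (sp in s:t) {
      v <- sum(D * ev$Minv[, (sp - 1L) * t + s])
      Qm[s, sp] <- Qm[sp, s] <- sum(D * ws[, s] * ws[, sp])
      if (q) {
        K <- crossprod(Fs_by_trait[[sp]] * D, Fs_by_trait[[s]])
        v <- v - sum(ev$Hinv * t(K))
      }
      XK <- crossprod(Xs_by_trait[[sp]] * D, Xs_by_trait[[s]])
      v <- v - sum(ev$XtVXinv * t(XK))
      Tr[s, sp] <- Tr[sp, s] <- v
    }
    traceP[[fi]] <- Tr
    Qw[[fi]] <- Qm
  }
  ## F' P F and F' w for low-rank parameters
  if (q) {
    Fm <- ev$Fmat$F
    FtSF0 <- crossprod(Fm, batch_block_mult(ev$Minv, Fm, n, t))
    CqT <- crossprod(Fm, ev$Fhat)               # F'S0F g1/2
    FtSiF <- FtSF0 - CqT %*% ev$Hinv %*% t(CqT)
    FtX <- crossprod(Fm, ev$Xs)                 # F' Sigma^{-1} X
    FtPF <- FtSiF - FtX %*% ev$XtVXinv %*% t(FtX)
    dFtPF <- diag(FtPF)
    Ftw <- as.vector(crossprod(Fm, w))
  }
  gr <- numeric(model$npar)
  for (b in model$blocks) {
    th <- block_theta(model, theta, b)
    if (b$type == "dense") {
      fi <- b$id
      for (k in seq_len(b$npar)) {
        dT <- struct_deriv(b$structure, th, t, k)
        gr[b$offset + k] <- -0.5 * (sum(dT * traceP[[fi]]) -
                                      sum(dT * Qw[[fi]]))
      }
    } else if (b$type == "lowrank") {
      mapc <- ev$Fmat$map
      sel_term <- mapc$term == b$id
      for (k in seq_len(b$npar)) {
        sel <- if (b$structure == "diag") sel_term & mapc$trait == k else sel_term
        gc <- ev$g[sel]
        gr[b$offset + k] <- -0.5 * (sum(gc * dFtPF[sel]) -
                                      sum(gc * Ftw[sel]^2))
      }
    } else {                    # residual
      fi <- length(fam_D)
      Rinv <- ev$Rinv
      for (k in seq_len(b$npar)) {
        dR <- struct_deriv(b$structure, th, t, k)
        gk <- -0.5 * (sum(dR * traceP[[fi]]) - sum(dR * Qw[[fi]]))
        if (m > 1L) {
          RdR <- Rinv %*% dR
          gk <- gk - 0.5 * (n * (m - 1) * sum(diag(RdR)) -
                              sum((Rinv %*% model$SSW %*% Rinv) * dR))
        }
        gr[b$offset + k] <- gk
      }
    }
  }
  gr
}

## default equal-split initial values
default_init <- function(model) {
  nterms <- length(model$dense) + length(model$lowrank) + 1L
  v0 <- model$vscale / nterms
  init <- numeric(model$npar)
  for (b in model$blocks) {
    v <- if (b$type == "resid" && model$m > 1L)
      max(mean(diag(model$SSW)) / (model$n * (model$m - 1)),
          1e-8 * model$vscale)
    else v0
    init[b$offset + seq_len(b$npar)] <- struct_init(b$structure, model$t, v)
  }
  init
}

## map actual-scale component estimates (a previous fit's `components`)
## onto the internal parameter vector; missing components keep defaults
components_to_theta <- function(model, comps) {
  theta <- default_init(model)
  lbv <- exp(model$lower[1])
  for (b in model$blocks) {
    nm <- if (b$type == "dense") model$dense[[b$id]]$name
    else if (b$type == "lowrank") model$lowrank[[b$id]]$name
    else "residual"
    val <- comps[[nm]]
    if (is.null(val)) next
    if (b$type == "lowrank") {
      sc <- model$lowrank[[b$id]]$scale
      theta[b$offset + seq_len(b$npar)] <-
        log(pmax(as.numeric(val) * sc, lbv))
      next
    }
    sc <- if (b$type == "dense") model$dense[[b$id]]$scale else 1
    Tm <- as.matrix(val) * sc
    if (b$structure %in% c("diag", "ident", "common")) {
      v <- if (b$npar == 1L) mean(diag(Tm)) else diag(Tm)
      theta[b$offset + seq_len(b$npar)] <- log(pmax(v, lbv))
    } else {                    # us: log-Cholesky
      d <- mean(diag(Tm))
      L <- t(chol(Tm + diag(max(d, lbv) * 1e-8 + lbv, model$t)))
      ij <- us_index(model$t)
      pars <- L[ij]
      dsel <- ij[, 1] == ij[, 2]
      pars[dsel] <- log(pmax(pars[dsel], sqrt(lbv)))
      theta[b$offset + seq_len(b$npar)] <- pars
    }
  }
  theta
}

## ---- public fitting interface -------------------------------------------

#' Fit a multitrait / multienvironment linear mixed model by REML
#'
#' Fits trait-specific intercepts plus the declared random terms to
#' balanced line-by-trait data, maximising the residual log-likelihood
#' with a bounded quasi-Newton optimizer and analytic gradients.
#' Variances are parameterised on the log scale and unstructured
#' matrices through their log-Cholesky factors, so iterates stay inside
#' the parameter space; a variance whose optimum lies on the zero
#' boundary is driven to the lower bound and flagged.
#'
#' @param Y `n x t` matrix of line-by-trait replicate means.
#' @param m number of replicates per line and trait.
#' @param SSW `t x t` matrix of within-line replicate cross-products
#'   (deviations from line means, summed over lines and replicates);
#'   required when `m > 1`.
#' @param random list of terms from [rt_genome()], [rt_ident()],
#'   [rt_block()].
#' @param residual residual covariance across traits within a
#'   replicate unit: `"diag"` or `"us"`.
#' @param init optional initial parameter vector (internal scale).
#' @param init_components optional list of component estimates (as in a
#'   fit's `components`) used as starting values; entries are matched
#'   by term name and missing ones fall back to defaults.
#' @param control list: `iter_max` (400), `restarts` (3),
#'   `lb_factor` (1e-12, lower variance bound relative to the
#'   phenotypic variance), `rel_tol` (1e-12), `newton` (TRUE, final
#'   Newton polish).
#' @return `mvlmm_fit` object: REML log-likelihood (`loglik`),
#'   variance-component estimates per term (`components`, actual
#'   scale), boundary flags, convergence information, and a solve
#'   cache used by [blups_with_pev()] and the scan.
#' @export
fit_mvlmm <- function(Y, m = 1, SSW = NULL, random = list(),
                      residual = c("diag", "us"), init = NULL,
                      init_components = NULL, control = list()) {
  residual <- match.arg(residual)
  ctl <- utils::modifyList(list(iter_max = 400L, restarts = 3L,
                                lb_factor = 1e-12, rel_tol = 1e-12), control)
  model <- build_mvlmm(Y, m, SSW, random, residual, ctl)
  Fmat <- build_F(model)
  if (is.null(init)) {
    init <- if (!is.null(init_components))
      tryCatch(components_to_theta(model, init_components),
               error = function(e) default_init(model))
    else default_init(model)
  }
  init <- pmin(pmax(init, model$lower + 1e-9), model$upper - 1e-9)
  last <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta)) return(last$ev)
    ev <- mv_eval(model, theta, Fmat)
    last$theta <- theta; last$ev <- ev
    ev
  }
  obj <- function(theta) {
    ev <- eval_at(theta)
    if (!ev$ok || !is.finite(ev$ll)) return(1e10)
    -ev$ll
  }
  grad <- function(theta) {
    ev <- eval_at(theta)
    if (!ev$ok || !is.finite(ev$ll)) return(rep(0, length(theta)))
    -mv_grad(model, theta, ev)
  }
  best <- NULL
  set_try <- function(start) {
    opt <- tryCatch(
      stats::nlminb(start, obj, grad, lower = model$lower,
                    upper = model$upper,
                    control = list(iter.max = ctl$iter_max,
                                   eval.max = 4L * ctl$iter_max,
                                   rel.tol = ctl$rel_tol,
                                   x.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) return(NULL)
    opt
  }
  opt <- set_try(init)
  tries <- 0L
  while ((is.null(opt) || opt$convergence > 1) && tries < ctl$restarts) {
    tries <- tries + 1L
    jit <- init + stats::rnorm(length(init), sd = 0.5)
    cand <- set_try(pmin(pmax(jit, model$lower + 1e-9), model$upper - 1e-9))
    if (!is.null(cand) &&
        (is.null(opt) || cand$objective < opt$objective)) opt <- cand
  }
  if (is.null(opt)) stop("REML fit failed: optimizer did not return a value")
  theta <- opt$par
  ## Newton polish on the free coordinates (numerical Hessian of the
  ## analytic gradient) so the maximiser is resolved well beyond the
  ## line-search stopping tolerance
  if (isTRUE(ctl$newton %||% TRUE)) {
    free <- which(theta > model$lower + 1e-7 & theta < model$upper - 1e-7)
    if (length(free)) {
      f0 <- obj(theta)
      g <- grad(theta)[free]
      for (outer in 1:3) {
        if (max(abs(g)) < 1e-9) break
        ## numerical Hessian of the analytic gradient, computed once
        ## per cycle and reused over several Newton steps
        H <- matrix(0, length(free), length(free))
        h <- 1e-5
        for (k in seq_along(free)) {
          tp <- theta; tp[free[k]] <- tp[free[k]] + h
          H[, k] <- (grad(tp)[free] - g) / h
        }
        H <- (H + t(H)) / 2
        stalled <- FALSE
        for (inner in 1:5) {
          step <- tryCatch(solve(H, g), error = function(e) NULL)
          if (is.null(step) || !all(is.finite(step))) { stalled <- TRUE; break }
          cand <- theta
          ok <- FALSE
          for (half in 0:4) {
            cand[free] <- theta[free] - step / 2^half
            cand <- pmin(pmax(cand, model$lower), model$upper)
            fc <- obj(cand)
            if (is.finite(fc) && fc <= f0 + 1e-10) { ok <- TRUE; f0 <- fc; break }
          }
          if (!ok) { stalled <- TRUE; break }
          theta <- cand
          g <- grad(theta)[free]
          if (max(abs(g)) < 1e-9) break
        }
        if (stalled || max(abs(g)) < 1e-9) break
      }
    }
  }
  ev <- eval_at(theta)
  ## actual-scale components
  cmp <- theta_components(model, theta)
  components <- list()
  boundary <- list()
  for (b in model$blocks) {
    if (b$type == "dense") {
      dm <- model$dense[[b$id]]
      components[[dm$name]] <- cmp$T[[b$id]] / dm$scale
      boundary[[dm$name]] <-
        theta[b$offset + seq_len(b$npar)] <= model$lower[b$offset + 1] + 1e-6
    } else if (b$type == "lowrank") {
      lm <- model$lowrank[[b$id]]
      components[[lm$name]] <- exp(theta[b$offset + seq_len(b$npar)]) / lm$scale
      boundary[[lm$name]] <-
        theta[b$offset + seq_len(b$npar)] <= model$lower[b$offset + 1] + 1e-6
    } else {
      components[["residual"]] <- cmp$R
      boundary[["residual"]] <- rep(FALSE, b$npar)
    }
  }
  structure(list(loglik = ev$ll, theta = theta, components = components,
                 boundary = boundary, convergence = opt$convergence,
                 iterations = opt$iterations,
                 grad_norm = max(abs(grad(theta))),
                 model = model, ev = ev, residual = residual),
            class = "mvlmm_fit")
}

#' @export
print.mvlmm_fit <- function(x, ...) {
  cat("REML fit:", x$model$n, "lines x", x$model$t, "traits,",
      x$model$m, "rep(s); logLik =", format(x$loglik, digits = 10), "\n")
  for (nm in names(x$components)) {
    v <- x$components[[nm]]
    if (is.matrix(v)) {
      cat("  ", nm, " (", if (nm == "residual") x$residual else "matrix",
          "): diag = ", paste(signif(diag(v), 4), collapse = ", "), "\n",
          sep = "")
    } else {
      cat("  ", nm, ": ", paste(signif(v, 4), collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Residual (REML) log-likelihood of a fit
#'
#' Reported with its full constants, so differences between nested fits
#' are likelihood-ratio statistics.
#'
#' @param fit an `mvlmm_fit`.
#' @return scalar log-likelihood.
#' @export
residual_loglik <- function(fit) {
  stopifnot(inherits(fit, "mvlmm_fit"))
  fit$loglik
}

#' @export
logLik.mvlmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$model$npar, class = "logLik")
}

#' BLUPs and prediction-error variance for a block term
#'
#' Returns the best linear unbiased predictions of the founder effects
#' of a low-rank (selected QTL) term together with their joint
#' prediction-error variance matrix, both on the actual effect scale.
#'
#' @param fit an `mvlmm_fit`.
#' @param term term name as given to [rt_block()].
#' @return list with `blup` (named vector), `pev` (matrix), and the
#'   column `map` (term/trait/founder-column indices).
#' @export
blups_with_pev <- function(fit, term) {
  model <- fit$model; ev <- fit$ev
  idx <- which(vapply(model$lowrank, `[[`, "", "name") == term)
  if (!length(idx)) stop("no such block term: ", term)
  mapc <- ev$Fmat$map
  sel <- mapc$term == idx
  Fm <- ev$Fmat$F
  w <- ev$w
  g <- ev$g
  sc <- model$lowrank[[idx]]$scale
  ## BLUP (actual scale): (1/sqrt(sc)) Gamma_sc F_sc' P y
  Ftw <- as.vector(crossprod(Fm[, sel, drop = FALSE], w))
  blup <- (g[sel] * Ftw) / sqrt(sc)
  ## F' P F restricted to the term's columns
  FtS0F <- crossprod(Fm[, sel, drop = FALSE],
                     batch_block_mult(ev$Minv, Fm[, sel, drop = FALSE],
                                      model$n, model$t))
  CqT <- crossprod(Fm[, sel, drop = FALSE], ev$Fhat)
  FtSiF <- FtS0F - CqT %*% ev$Hinv %*% t(CqT)
  FtX <- crossprod(Fm[, sel, drop = FALSE], ev$Xs)
  FtPF <- FtSiF - FtX %*% ev$XtVXinv %*% t(FtX)
  G <- diag(g[sel], sum(sel))
  pev <- (G - G %*% FtPF %*% G) / sc
  pev <- (pev + t(pev)) / 2
  list(blup = blup, pev = pev, map = mapc[sel, , drop = FALSE])
}

## BLUPs of the whole-genome interval x founder effects and the diagonal
## (and cross-trait) entries of their variance, via the back-transform
## a = P'(PP')^{-1/2} a*.  `Wfull` must be U' P over the remaining
## probability columns; `Ga` is the genome term's actual T matrix.
## Returns list(blup = ncol x t matrix, var = list over trait pairs).
genome_effects <- function(fit, Wfull, want_var = TRUE) {
  model <- fit$model; ev <- fit$ev
  n <- model$n; t <- model$t; m <- model$m
  gname <- vapply(model$dense, `[[`, "", "name")
  if (!any(gname == "genome")) stop("fit has no genome term")
  Ga <- fit$components[["genome"]]
  ws <- matrix(ev$w, n, t)
  ## blup(a)_s = sqrt(m) W' (sum_s' Ga[s, s'] w_s')
  blup <- sqrt(m) * crossprod(Wfull, ws %*% Ga)
  if (!want_var) return(list(blup = blup))
  rows <- function(s) (s - 1L) * n + seq_len(n)
  q <- length(ev$g)
  ## V[s3, s4](col) = W_col' Pgrid_{s3 s4} W_col
  Vq <- array(0, c(ncol(Wfull), t, t))
  HinvT <- ev$Hinv
  for (s3 in seq_len(t)) for (s4 in seq_len(t)) {
    if (s4 < s3) { Vq[, s3, s4] <- Vq[, s4, s3]; next }
    v <- colSums(Wfull * Wfull * ev$Minv[, (s4 - 1L) * t + s3])
    if (q) {
      T3 <- crossprod(ev$Fhat[rows(s3), , drop = FALSE], Wfull)
      T4 <- if (s4 == s3) T3 else
        crossprod(ev$Fhat[rows(s4), , drop = FALSE], Wfull)
      v <- v - colSums(T3 * (HinvT %*% T4))
    }
    X3 <- crossprod(ev$Xs[rows(s3), , drop = FALSE], Wfull)
    X4 <- if (s4 == s3) X3 else
      crossprod(ev$Xs[rows(s4), , drop = FALSE], Wfull)
    v <- v - colSums(X3 * (ev$XtVXinv %*% X4))
    Vq[, s3, s4] <- v
  }
  ## var(a)_{s1 s2}(col) = m sum_{s3 s4} Ga[s1,s3] Ga[s2,s4] V[s3,s4](col)
  var_a <- array(0, c(ncol(Wfull), t, t))
  for (s1 in seq_len(t)) for (s2 in seq_len(t)) {
    acc <- 0
    for (s3 in seq_len(t)) for (s4 in seq_len(t))
      acc <- acc + Ga[s1, s3] * Ga[s2, s4] * Vq[, s3, s4]
    var_a[, s1, s2] <- m * acc
  }
  list(blup = blup, var = var_a)
}
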