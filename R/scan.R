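## Forward-selection whole-genome scan.
##
## All intervals enter the model simultaneously as random
## founder-indexed effects a ~ N(0, G_a (x) I), fitted in the
## dimension-reduced equivalent form with kernel (PP')^{1/2}.  Each
## round tests H0: G_a = 0 with a residual likelihood-ratio statistic
## whose null is a binomial mixture of chi-squares; on rejection a
## correlated-effects model is fitted and the interval with the largest
## multivariate outlier statistic becomes the next putative QTL.

#' Dimension reduction of the founder-probability design
#'
#' Computes the symmetric square root kernel of `PP'` via
#' eigendecomposition.  Fitting the genome term with this kernel is
#' exactly equivalent to fitting all interval-by-founder effects, with
#' model dimension equal to the number of lines; interval-level effects
#' and their variances are recovered by the back-transform
#' `a = P'(PP')^{-1/2} a*`.
#'
#' @param P founder-probability matrix (`n` lines x columns), or a
#'   `founder_probs` object.
#' @param PPt optional precomputed `PP'`.
#' @return object of class `reduced_design`: list with `eig`
#'   (`values` clamped at 0, `vectors`) and `K` (the symmetric PSD
#'   square root).
#' @export
reduce_dimension <- function(P, PPt = NULL) {
  if (inherits(P, "founder_probs")) P <- P$prob
  if (is.null(PPt)) {
    if (!all(is.finite(P))) stop("non-finite entries in probability matrix")
    PPt <- tcrossprod(P)
  }
  e <- eigen((PPt + t(PPt)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8 * max(vals)))
    warning("PP' has a markedly negative eigenvalue; clamping")
  vals <- pmax(vals, 0)
  K <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  structure(list(eig = list(values = vals, vectors = e$vectors), K = K),
            class = "reduced_design")
}

#' Chi-square mixture p-value for variance-component tests
#'
#' Tail probability of the boundary null distribution
#' \deqn{(1/2)^t \sum_{k=0}^t \binom{t}{k} \chi^2_k,}
#' the null of the likelihood-ratio statistic for testing that a
#' diagonal t x t variance matrix is zero.
#'
#' @param x statistic value(s); small negative values (numerical noise)
#'   are clamped to 0 with a warning.
#' @param t number of traits or environments (mixture order, >= 1).
#' @return p-value(s); at `x = 0` the value is `1 - (1/2)^t`, the total
#'   mass above the point mass at zero.
#' @export
mixture_chisq_pvalue <- function(x, t) {
  stopifnot(t >= 1, t == round(t))
  if (any(x < 0)) {
    if (any(x < -1e-6)) warning("negative statistic clamped to 0")
    x <- pmax(x, 0)
  }
  p <- numeric(length(x))
  for (k in seq_len(t))
    p <- p + choose(t, k) * stats::pchisq(x, df = k, lower.tail = FALSE)
  p * 0.5^t
}

## symmetric Moore-Penrose generalized inverse
pinv_sym <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

## ---- scan state ----------------------------------------------------------

#' Initialise a whole-genome scan
#'
#' Aligns phenotypes with the probability matrix, computes line means
#' and within-line replicate cross-products, and sets up the selection
#' bookkeeping.
#'
#' @param pheno long phenotype data frame (`line`, `trait`, `rep`,
#'   `value`), balanced.
#' @param probs `founder_probs` (interval or marker mode).
#' @param mode `"multitrait"` (trait-specific QTL effects with separate
#'   variances) or `"multienv"` (a common founder effect across
#'   environments plus environment-specific deviations).
#' @param alpha forward-selection significance level (default 0.05).
#' @param PPt optional precomputed `PP'` of the full probability matrix
#'   (reused across phenotype replicates in simulation studies).
#' @return A `scan_state` object.
#' @export
scan_init <- function(pheno, probs, mode = c("multitrait", "multienv"),
                      alpha = 0.05, PPt = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(probs, "founder_probs"))
  st <- pheno_line_stats(pheno)
  plines <- rownames(probs$prob)
  common <- intersect(plines, st$lines)
  if (!length(common)) stop("no lines shared between phenotypes and probabilities")
  dropped <- length(st$lines) - length(common)
  if (dropped > 0)
    message(dropped, " phenotyped line(s) absent from probability matrix: dropped")
  P <- probs$prob[common, , drop = FALSE]
  Y <- st$Y[common, , drop = FALSE]
  if (is.null(PPt)) PPt <- tcrossprod(P)
  index <- probs$index
  key <- paste(index$chrom, index$item)
  ufirst <- !duplicated(key)
  items <- data.frame(chrom = index$chrom[ufirst], item = index$item[ufirst],
                      pos_cM = index$pos_cM[ufirst],
                      stringsAsFactors = FALSE)
  if (!is.null(index$left_cM)) {
    items$left_cM <- index$left_cM[ufirst]
    items$right_cM <- index$right_cM[ufirst]
  }
  nf <- probs$n_founders
  items$col_start <- (seq_len(nrow(items)) - 1L) * nf + 1L
  structure(list(Y = Y, m = st$m, SSW = st$SSW, P = P, PPt = PPt,
                 items = items, n_founders = nf, mode = mode, alpha = alpha,
                 selected = integer(0), traits = st$traits,
                 warm = new.env(parent = emptyenv()),
                 log = list()),
            class = "scan_state")
}

state_remaining_cols <- function(state) {
  nf <- state$n_founders
  if (!length(state$selected)) return(seq_len(ncol(state$P)))
  sel_cols <- as.vector(outer(0:(nf - 1L),
                              state$items$col_start[state$selected], `+`))
  setdiff(seq_len(ncol(state$P)), sort(sel_cols))
}

item_cols <- function(state, i) {
  state$items$col_start[i] + 0:(state$n_founders - 1L)
}

## eigendecomposition of PP' for the remaining columns (rank-4 downdates
## of the full kernel per selected interval)
state_reduced <- function(state) {
  PPt <- state$PPt
  for (i in state$selected) {
    Pj <- state$P[, item_cols(state, i), drop = FALSE]
    PPt <- PPt - tcrossprod(Pj)
  }
  reduce_dimension(NULL, PPt = PPt)
}

## random terms for the currently selected QTL
state_qtl_terms <- function(state) {
  out <- list()
  for (i in seq_along(state$selected)) {
    Pj <- state$P[, item_cols(state, state$selected[i]), drop = FALSE]
    nm <- paste0("qtl", i)
    if (state$mode == "multitrait") {
      out <- c(out, list(rt_block(Pj, "diag", nm)))
    } else {
      keep_int <- if (is.null(state$qtle_drop)) TRUE else
        !(i %in% state$qtle_drop)
      out <- c(out, list(rt_block(Pj, "common", paste0(nm, "_main"))))
      if (keep_int)
        out <- c(out, list(rt_block(Pj, "ident", paste0(nm, "_int"))))
    }
  }
  out
}

state_fit <- function(state, genome = TRUE, correlated = FALSE,
                      red = NULL, drop_term = NULL, init = NULL) {
  terms <- list()
  if (genome) {
    if (is.null(red)) red <- state_reduced(state)
    terms <- c(terms, list(rt_genome(red$eig, if (correlated) "us" else "diag")))
  }
  terms <- c(terms, list(rt_ident(if (correlated) "us" else "diag",
                                  "polygenic")))
  qterms <- state_qtl_terms(state)
  if (!is.null(drop_term))
    qterms <- Filter(function(tm) tm$name != drop_term, qterms)
  terms <- c(terms, qterms)
  ## warm-start from the previous fit of the same model family.  When
  ## the term set changed (a QTL entered or left the model) the genome
  ## variance is re-initialised from defaults: carrying over a large
  ## G_a start lets the genome term absorb the new QTL's signal on the
  ## near-flat ridge between the two terms.
  key <- paste(genome, correlated, drop_term %||% "", sep = "|")
  cur_names <- c(vapply(terms, `[[`, "", "name"), "residual")
  warm <- if (!is.null(state$warm)) get0(key, envir = state$warm) else NULL
  if (!is.null(warm)) {
    if (!setequal(names(warm), cur_names)) warm$genome <- NULL
    warm <- warm[intersect(names(warm), cur_names)]
  }
  fit <- fit_mvlmm(state$Y, m = state$m, SSW = state$SSW, random = terms,
                   residual = "diag", init = init, init_components = warm)
  if (!is.null(state$warm)) assign(key, fit$components, envir = state$warm)
  fit
}

#' Likelihood-ratio presence test for remaining QTL variation
#'
#' Fits the working model with a diagonal trait-variance matrix for the
#' (dimension-reduced) whole-genome term, diagonal polygenic effects
#' and all previously selected QTL, and the null model omitting the
#' genome term; the statistic `2(l1 - l0)` is referred to the
#' chi-square mixture of order t.
#'
#' @param state a `scan_state`.
#' @param red optional precomputed [reduce_dimension()] design for the
#'   remaining columns.
#' @return list: `statistic`, `df`, `p_value`, `loglik1`, `loglik0`,
#'   `reject`.
#' @export
qtl_presence_test <- function(state, red = NULL) {
  t <- ncol(state$Y)
  if (is.null(red)) red <- state_reduced(state)
  fit0 <- state_fit(state, genome = FALSE)
  fit1 <- state_fit(state, genome = TRUE, red = red)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (stat < 0) {
    if (stat < -1e-6) warning("negative LR statistic (", signif(stat, 3),
                              ") clamped to 0")
    stat <- 0
  }
  p <- mixture_chisq_pvalue(stat, t)
  list(statistic = stat, df = t, p_value = p,
       loglik1 = fit1$loglik, loglik0 = fit0$loglik,
       reject = p <= state$alpha)
}

#' Multivariate outlier statistics for the remaining intervals
#'
#' Fits the correlated-effects model (unstructured trait covariance for
#' both the genome term and the polygenic term) and computes, for every
#' remaining interval, the outlier statistic
#' \deqn{t^2_{kj} = \sum_f \tilde a_{kjf}' G_a^- \tilde a_{kjf} /
#'       \sum_f tr(G_a^- var(\tilde a_{kjf}))}
#' from the back-transformed interval-level BLUPs.  If the correlated
#' fit fails to converge the diagonal fit is used instead (logged).
#'
#' @param state a `scan_state`.
#' @param red optional precomputed [reduce_dimension()] design.
#' @return list: `table` (data frame chrom/item/pos/t2), `fit`, `Ga`,
#'   `correlated` flag.
#' @export
outlier_statistics <- function(state, red = NULL) {
  if (is.null(red)) red <- state_reduced(state)
  fit <- tryCatch(state_fit(state, correlated = TRUE, red = red),
                  error = function(e) NULL)
  correlated <- !is.null(fit) && fit$convergence <= 1
  if (!correlated) {
    message("correlated fit failed; falling back to diagonal variance model")
    fit <- state_fit(state, correlated = FALSE, red = red)
  }
  rem <- state_remaining_cols(state)
  Wfull <- crossprod(red$eig$vectors, state$P[, rem, drop = FALSE])
  ge <- genome_effects(fit, Wfull)
  Ga <- fit$components[["genome"]]
  Gai <- pinv_sym(Ga)
  nf <- state$n_founders
  t <- ncol(state$Y)
  ncols <- length(rem)
  num_c <- rowSums((ge$blup %*% Gai) * ge$blup)        # a' Ga^- a per column
  den_c <- numeric(ncols)
  for (s1 in seq_len(t)) for (s2 in seq_len(t))
    den_c <- den_c + Gai[s1, s2] * ge$var[, s2, s1]     # tr(Ga^- V) per column
  grp <- rep(seq_len(ncols / nf), each = nf)
  num <- tapply(num_c, grp, sum)
  den <- tapply(den_c, grp, sum)
  rem_items <- which(!(seq_len(nrow(state$items)) %in% state$selected))
  tab <- state$items[rem_items, c("chrom", "item", "pos_cM")]
  tab$t2 <- as.vector(num / pmax(den, .Machine$double.eps))
  rownames(tab) <- NULL
  list(table = tab, fit = fit, Ga = Ga, correlated = correlated)
}

#' Select the outlying interval and update the scan state
#'
#' Moves the interval with the largest outlier statistic out of the
#' remaining probability matrix and registers its QTL random effect(s):
#' in multitrait mode one term with a separate variance per trait; in
#' multienvironment mode both a common founder-effect term and an
#' environment-interaction term.  Ties break to the first interval in
#' map order.
#'
#' @param state a `scan_state`.
#' @param t2_table table from [outlier_statistics()].
#' @return updated `scan_state`.
#' @export
select_and_update <- function(state, t2_table) {
  best <- which.max(t2_table$t2)   # ties break to map order
  pick <- which(state$items$chrom == t2_table$chrom[best] &
                  state$items$item == t2_table$item[best])
  stopifnot(length(pick) == 1L, !(pick %in% state$selected))
  state$selected <- c(state$selected, pick)
  state
}

#' Run the forward-selection whole-genome scan
#'
#' Alternates the presence test and outlier selection until the test is
#' retained (or `max_qtl` reached).  In multienvironment mode the
#' selected QTL are then subjected to backward QTL-by-environment
#' reduction ([qtl_by_env_test()]): the least significant
#' non-significant interaction term is removed and the model refitted,
#' repeatedly.  The final correlated model (selected QTL, remaining
#' genome term, unstructured polygenic covariance) is refitted for
#' reporting.
#'
#' @inheritParams scan_init
#' @param max_qtl selection cap (default 40).
#' @param verbose print per-round progress.
#' @return A `magic_scan` object: `qtl` (data frame of selected
#'   intervals in selection order), `final_fit`, `state`, `rounds`
#'   (per-round statistics), `mode`, `alpha`.
#' @export
run_scan <- function(pheno, probs, mode = c("multitrait", "multienv"),
                     alpha = 0.05, max_qtl = 40L, PPt = NULL,
                     verbose = FALSE) {
  mode <- match.arg(mode)
  state <- scan_init(pheno, probs, mode = mode, alpha = alpha, PPt = PPt)
  rounds <- list()
  repeat {
    red <- state_reduced(state)
    pt <- qtl_presence_test(state, red = red)
    round_log <- list(n_selected = length(state$selected),
                      statistic = pt$statistic, p_value = pt$p_value,
                      reject = pt$reject)
    if (verbose)
      message(sprintf("round %d: X2 = %.3f, p = %.4g (%s)",
                      length(rounds) + 1L, pt$statistic, pt$p_value,
                      if (pt$reject) "reject" else "retain"))
    if (!pt$reject || length(state$selected) >= max_qtl) {
      rounds[[length(rounds) + 1L]] <- round_log
      if (length(state$selected) >= max_qtl && pt$reject)
        warning("selection cap of ", max_qtl, " QTL reached")
      break
    }
    os <- outlier_statistics(state, red = red)
    state <- select_and_update(state, os$table)
    sel <- state$selected[length(state$selected)]
    round_log$selected_chrom <- state$items$chrom[sel]
    round_log$selected_item <- state$items$item[sel]
    round_log$selected_pos <- state$items$pos_cM[sel]
    round_log$t2 <- max(os$table$t2)
    rounds[[length(rounds) + 1L]] <- round_log
    if (verbose)
      message(sprintf("  selected %s interval %d (%.1f cM), t2 = %.2f",
                      round_log$selected_chrom, round_log$selected_item,
                      round_log$selected_pos, round_log$t2))
  }
  qtle <- NULL
  if (mode == "multienv" && length(state$selected)) {
    red <- qtl_by_env_reduce(state, alpha = alpha)
    state <- red$state
    qtle <- red$tests
  }
  final_fit <- if (length(state$selected))
    tryCatch(state_fit(state, correlated = TRUE),
             error = function(e) state_fit(state, correlated = FALSE))
  else NULL
  qtl <- if (length(state$selected))
    cbind(state$items[state$selected,
                      intersect(c("chrom", "item", "pos_cM", "left_cM",
                                  "right_cM"), names(state$items))],
          order = seq_along(state$selected))
  else state$items[0, ]
  rownames(qtl) <- NULL
  structure(list(qtl = qtl, final_fit = final_fit, state = state,
                 rounds = rounds, qtle = qtle, mode = mode, alpha = alpha),
            class = "magic_scan")
}

#' @export
print.magic_scan <- function(x, ...) {
  cat("Whole-genome", x$mode, "scan: ", nrow(x$qtl), "QTL selected in",
      length(x$rounds), "round(s)\n")
  if (nrow(x$qtl)) print(x$qtl)
  invisible(x)
}

#' QTL-by-environment interaction test
#'
#' Residual likelihood-ratio test of a zero environment-interaction
#' variance for one selected QTL, allowing for all other model terms.
#' The null distribution is a point mass of 0.5 at zero mixed with half
#' a chi-square on 1 df.
#'
#' @param state a multienvironment `scan_state` with selected QTL.
#' @param qtl index of the QTL in selection order.
#' @return list: `statistic`, `p_value`.
#' @export
qtl_by_env_test <- function(state, qtl) {
  stopifnot(state$mode == "multienv", qtl %in% seq_along(state$selected))
  if (!is.null(state$qtle_drop) && qtl %in% state$qtle_drop)
    stop("interaction term for QTL ", qtl, " already removed")
  fit_full <- state_fit(state, correlated = TRUE)
  fit_red <- state_fit(state, correlated = TRUE,
                       drop_term = paste0("qtl", qtl, "_int"))
  stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  p <- if (stat <= 1e-8) 0.5 else
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

## backward elimination of non-significant QTL-by-environment terms
qtl_by_env_reduce <- function(state, alpha = 0.05) {
  tests <- list()
  repeat {
    active <- setdiff(seq_along(state$selected), state$qtle_drop)
    if (!length(active)) break
    ps <- vapply(active, function(j) qtl_by_env_test(state, j)$p_value, 0)
    tests[[length(tests) + 1L]] <- data.frame(qtl = active, p_value = ps)
    worst <- which.max(ps)
    if (ps[worst] <= alpha) break
    state$qtle_drop <- c(state$qtle_drop, active[worst])
  }
  list(state = state, tests = tests)
}

## ---- phenotype preparation ----------------------------------------------

## line-by-trait means, replicate count and within-line cross-products
pheno_line_stats <- function(pheno) {
  stopifnot(all(c("line", "trait", "value") %in% names(pheno)))
  if (anyNA(pheno$value)) stop("missing phenotype values are not supported")
  lines <- unique(as.character(pheno$line))
  traits <- unique(as.character(pheno$trait))
  li <- match(as.character(pheno$line), lines)
  ti <- match(as.character(pheno$trait), traits)
  cnt <- table(li, ti)
  m <- cnt[1]
  if (any(cnt != m))
    stop("unbalanced phenotypes: every line x trait needs the same replicate count")
  n <- length(lines); t <- length(traits)
  Y <- matrix(0, n, t, dimnames = list(lines, traits))
  agg <- rowsum(pheno$value, group = (ti - 1L) * n + li)
  Y[as.integer(rownames(agg))] <- agg / m
  SSW <- NULL
  if (m > 1L) {
    if (!"rep" %in% names(pheno)) stop("replicated phenotypes need a rep column")
    dev <- pheno$value - Y[cbind(li, ti)]
    ri <- match(pheno$rep, unique(pheno$rep))
    D <- matrix(0, n * m, t)
    D[cbind((ri - 1L) * n + li, ti)] <- dev
    SSW <- crossprod(D)
  }
  list(Y = Y, m = as.integer(m), SSW = SSW, lines = lines, traits = traits)
}
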