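## Per-QTL summaries: founder effect sizes, significance probabilities,
## LOGP scores and percentage of genetic variance explained.

#' Significance probability of a QTL from its BLUPs and PEV
#'
#' Computes the quadratic distance `c2 = a' V^- a` of the predicted
#' founder effects from zero, referred to a chi-square on
#' `n_f - 1` degrees of freedom (the founder effects carry one linear
#' constraint through the probabilities), and the analogous per-founder
#' probabilities on 1 df using each founder's own effect and PEV entry.
#'
#' @param effects length-`n_f` vector of predicted founder effects.
#' @param pev `n_f x n_f` prediction-error variance matrix (PSD).
#' @param df degrees of freedom for the overall test (default
#'   `n_f - 1`).
#' @return list: `c2`, `p` (overall), `founder_c2`, `founder_p`,
#'   `degenerate` (zero PEV with nonzero effect).
#' @export
qtl_probability <- function(effects, pev, df = length(effects) - 1L) {
  effects <- as.numeric(effects)
  pev <- as.matrix(pev)
  stopifnot(nrow(pev) == length(effects), ncol(pev) == length(effects))
  degenerate <- FALSE
  if (max(abs(pev)) < .Machine$double.eps * 100) {
    if (max(abs(effects)) > 0) degenerate <- TRUE
    c2 <- if (degenerate) Inf else 0
  } else {
    c2 <- as.numeric(effects %*% pinv_sym(pev) %*% effects)
  }
  p <- stats::pchisq(c2, df = df, lower.tail = FALSE)
  d <- diag(pev)
  fc2 <- ifelse(d > .Machine$double.eps * 100, effects^2 / d,
                ifelse(abs(effects) > 0, Inf, 0))
  fp <- stats::pchisq(fc2, df = 1, lower.tail = FALSE)
  list(c2 = c2, p = p, founder_c2 = fc2, founder_p = fp,
       degenerate = degenerate)
}

#' LOGP score
#'
#' `-log10(p)`, the strength measure reported for each QTL (similar in
#' spirit to a LOD score).  `p = 0` maps to the cap (default 16).
#'
#' @param p probability in `[0, 1]`.
#' @param cap value returned for `p = 0`.
#' @return LOGP score(s).
#' @export
logp <- function(p, cap = 16) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  ifelse(p <= 10^(-cap), cap, -log10(p))
}

#' Percentage of genetic variance explained by each QTL
#'
#' For an average line, the QTL indicator has multinomial covariance
#' `var(q_bar_j) = diag(p_bar_j) - p_bar_j p_bar_j'`, so QTL j
#' contributes `a_js' var(q_bar_j) a_js` to the genetic variance of
#' trait s.  The total per-trait genetic variance adds the non-selected
#' genome contribution `sigma2_a[s] * sum(p_bar_rem^2)` and the
#' polygenic variance, and the percentage is the ratio times 100.
#'
#' @param effects list over QTL of `n_f x t` matrices of founder sizes
#'   (columns = traits/environments).
#' @param pbar list over QTL of length-`n_f` average founder
#'   probabilities.
#' @param sigma2_p length-`t` polygenic variances.
#' @param sigma2_a length-`t` variances of the non-selected genome term
#'   (default 0).
#' @param pbar_rem average founder probabilities over all non-selected
#'   columns (default none).
#' @return `n_qtl x t` matrix of percentages.
#' @export
percent_variance <- function(effects, pbar, sigma2_p, sigma2_a = 0,
                             pbar_rem = NULL) {
  stopifnot(length(effects) == length(pbar))
  t <- if (length(effects)) ncol(effects[[1]]) else length(sigma2_p)
  sigma2_a <- rep_len(sigma2_a, t)
  sigma2_p <- rep_len(sigma2_p, t)
  contrib <- matrix(0, length(effects), t)
  for (j in seq_along(effects)) {
    p <- as.numeric(pbar[[j]])
    Vq <- diag(p) - tcrossprod(p)
    A <- as.matrix(effects[[j]])
    contrib[j, ] <- colSums((Vq %*% A) * A)
  }
  rem <- if (is.null(pbar_rem)) 0 else sum(pbar_rem^2)
  total <- colSums(contrib) + sigma2_a * rem + sigma2_p
  if (any(total <= 0)) stop("total genetic variance is zero; PV undefined")
  pv <- 100 * sweep(contrib, 2L, total, `/`)
  dimnames(pv) <- list(names(effects), names(sigma2_p))
  pv
}

## joint BLUPs + PEV over several block terms (needed for common +
## interaction effects of a multienvironment QTL)
blups_with_pev_multi <- function(fit, terms) {
  model <- fit$model; ev <- fit$ev
  names_lr <- vapply(model$lowrank, `[[`, "", "name")
  idx <- match(terms, names_lr)
  if (anyNA(idx)) stop("no such block term(s): ",
                       paste(terms[is.na(idx)], collapse = ", "))
  mapc <- ev$Fmat$map
  sel <- mapc$term %in% idx
  Fm <- ev$Fmat$F[, sel, drop = FALSE]
  g <- ev$g[sel]
  scl <- vapply(mapc$term[sel], function(i) model$lowrank[[i]]$scale, 0)
  Ftw <- as.vector(crossprod(Fm, ev$w))
  blup <- g * Ftw / sqrt(scl)
  FtS0F <- crossprod(Fm, batch_block_mult(ev$Minv, Fm, model$n, model$t))
  CqT <- crossprod(Fm, ev$Fhat)
  FtSiF <- FtS0F - CqT %*% ev$Hinv %*% t(CqT)
  FtX <- crossprod(Fm, ev$Xs)
  FtPF <- FtSiF - FtX %*% ev$XtVXinv %*% t(FtX)
  G <- diag(g, length(g))
  pev <- G - G %*% FtPF %*% G
  pev <- sweep(sweep(pev, 1L, sqrt(scl), `/`), 2L, sqrt(scl), `/`)
  list(blup = blup, pev = (pev + t(pev)) / 2,
       map = cbind(mapc[sel, , drop = FALSE], name = names_lr[mapc$term[sel]]))
}

#' Summarise a whole-genome scan
#'
#' Builds the per-QTL report: founder effect sizes per trait or
#' environment (BLUPs of `a*_js`; in multienvironment mode the common
#' effect plus the environment deviation when the interaction was
#' retained), per-founder and overall significance probabilities and
#' LOGP scores, and the percentage of genetic variance explained.
#'
#' @param object a `magic_scan`.
#' @param logp_cap cap for LOGP at `p = 0`.
#' @param ... unused.
#' @return A `magic_scan_summary`: data frame `table` with one row per
#'   QTL x trait x founder (columns `chrom`, `left_cM`, `right_cM`,
#'   `trait`, `founder`, `size`, `founder_prob`, `founder_logp`,
#'   `prob`, `pv`, `logp`), plus `totals` (per-trait total PV).
#' @export
summary.magic_scan <- function(object, logp_cap = 16, ...) {
  scan <- object
  state <- scan$state
  nf <- state$n_founders
  t <- ncol(state$Y)
  traits <- state$traits
  empty <- data.frame(chrom = character(0), left_cM = numeric(0),
                      right_cM = numeric(0), trait = character(0),
                      founder = character(0), size = numeric(0),
                      founder_prob = numeric(0), founder_logp = numeric(0),
                      prob = numeric(0), pv = numeric(0), logp = numeric(0))
  if (!nrow(scan$qtl))
    return(structure(list(table = empty, totals = setNames(numeric(t), traits),
                          mode = scan$mode), class = "magic_scan_summary"))
  fit <- scan$final_fit
  nq <- length(state$selected)
  eff <- vector("list", nq)          # n_f x t per QTL
  pevs <- vector("list", nq)         # list over traits of n_f x n_f
  pbar <- vector("list", nq)
  for (j in seq_len(nq)) {
    cols <- item_cols(state, state$selected[j])
    pbar[[j]] <- colMeans(state$P[, cols, drop = FALSE])
    if (scan$mode == "multitrait") {
      bp <- blups_with_pev(fit, paste0("qtl", j))
      A <- matrix(0, nf, t); Vs <- vector("list", t)
      for (s in seq_len(t)) {
        rows <- which(bp$map$trait == s)
        A[, s] <- bp$blup[rows]
        Vs[[s]] <- bp$pev[rows, rows, drop = FALSE]
      }
      eff[[j]] <- A; pevs[[j]] <- Vs
    } else {
      has_int <- is.null(state$qtle_drop) || !(j %in% state$qtle_drop)
      terms <- paste0("qtl", j, if (has_int) c("_main", "_int") else "_main")
      bp <- blups_with_pev_multi(fit, terms)
      A <- matrix(0, nf, t); Vs <- vector("list", t)
      main_rows <- which(bp$map$name == paste0("qtl", j, "_main"))
      for (s in seq_len(t)) {
        if (has_int) {
          int_rows <- which(bp$map$name == paste0("qtl", j, "_int") &
                              bp$map$trait == s)
          L <- matrix(0, nf, length(bp$blup))
          L[cbind(seq_len(nf), main_rows)] <- 1
          L[cbind(seq_len(nf), int_rows)] <- 1
        } else {
          L <- matrix(0, nf, length(bp$blup))
          L[cbind(seq_len(nf), main_rows)] <- 1
        }
        A[, s] <- as.vector(L %*% bp$blup)
        Vs[[s]] <- L %*% bp$pev %*% t(L)
      }
      eff[[j]] <- A; pevs[[j]] <- Vs
    }
  }
  ## percent variance from the final fit's variance components
  Ga <- fit$components[["genome"]]
  Gp <- fit$components[["polygenic"]]
  sigma2_a <- if (is.null(Ga)) rep(0, t) else diag(as.matrix(Ga))
  sigma2_p <- diag(as.matrix(Gp))
  rem <- state_remaining_cols(state)
  pbar_rem <- colMeans(state$P[, rem, drop = FALSE])
  pv <- percent_variance(eff, pbar, sigma2_p = sigma2_p,
                         sigma2_a = sigma2_a, pbar_rem = pbar_rem)
  rows <- list()
  for (j in seq_len(nq)) {
    it <- state$items[state$selected[j], ]
    left <- if (!is.null(it$left_cM)) it$left_cM else it$pos_cM
    right <- if (!is.null(it$right_cM)) it$right_cM else it$pos_cM
    for (s in seq_len(t)) {
      qp <- qtl_probability(eff[[j]][, s], pevs[[j]][[s]])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = it$chrom, left_cM = left, right_cM = right,
        trait = traits[s], founder = paste0("F", seq_len(nf)),
        size = eff[[j]][, s],
        founder_prob = qp$founder_p,
        founder_logp = logp(qp$founder_p, cap = logp_cap),
        prob = qp$p, pv = pv[j, s], logp = logp(qp$p, cap = logp_cap),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, totals = setNames(colSums(pv), traits),
                 mode = scan$mode), class = "magic_scan_summary")
}

#' @export
print.magic_scan_summary <- function(x, ...) {
  if (!nrow(x$table)) {
    cat("No QTL selected.\n")
    return(invisible(x))
  }
  tab <- x$table
  tab$size <- round(tab$size, 3)
  tab$founder_prob <- round(tab$founder_prob, 4)
  tab$founder_logp <- round(tab$founder_logp, 1)
  tab$prob <- round(tab$prob, 4)
  tab$pv <- round(tab$pv, 1)
  tab$logp <- round(tab$logp, 1)
  print(tab, row.names = FALSE)
  cat("\nTotal % genetic variance by trait:",
      paste(sprintf("%s = %.1f", names(x$totals), x$totals), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a QTL summary table to CSV
#'
#' @param summary a `magic_scan_summary`.
#' @param file output path.
#' @export
write_qtl_summary <- function(summary, file) {
  utils::write.csv(summary$table, file, row.names = FALSE)
  invisible(file)
}
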