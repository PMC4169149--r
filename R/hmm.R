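## Founder-origin probabilities via a hidden Markov model.
##
## States are the n_f founder origins of an inbred line's single
## haplotype.  The transition over an interval of d cM uses the
## two-point origin-switch probability for a four-way funnel RIL selfed
## to near-fixation: with Haldane recombination fraction
## r = (1 - exp(-2d/100))/2, every off-diagonal transition probability
## is r/(1+2r) (total switch probability 3r/(1+2r)); this combines
## Haldane-Waddington selfing with the single-meiosis mosaic of each
## two-way F1 gamete and is verified against the simulator in the test
## suite.  Emissions score observed marker alleles against known founder
## alleles with error rate `error_rate`; missing scores are
## uninformative.

haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

## n_f x n_f transition matrix over genetic distance d (cM)
ril4_transition <- function(d_cM, n_f = 4L) {
  r <- haldane_r(d_cM)
  off <- r / (1 + 2 * r)
  T <- matrix(off, n_f, n_f)
  diag(T) <- 1 - (n_f - 1) * off
  T
}

prob_colnames <- function(index) {
  paste0(index$chrom, ".", index$item, ".F", index$founder)
}

new_founder_probs <- function(prob, index, map, mode, n_founders) {
  colnames(prob) <- prob_colnames(index)
  structure(list(prob = prob, index = index, map = map, mode = mode,
                 n_founders = as.integer(n_founders)),
            class = "founder_probs")
}

#' @export
print.founder_probs <- function(x, ...) {
  cat(sprintf("Founder probabilities (%s mode): %d lines x %d %ss x %d founders\n",
              x$mode, nrow(x$prob), nrow(x$index) / x$n_founders,
              x$mode, x$n_founders))
  invisible(x)
}

#' Founder-origin posterior probabilities at markers
#'
#' Runs the forward-backward algorithm per chromosome and line over the
#' founder-origin state space, with per-marker rescaling for numerical
#' stability.
#'
#' @param scores `n_lines` x `n_markers` matrix of marker scores
#'   (allele codes; `NA` = missing).  Columns must be named by marker
#'   and match the map.
#' @param founder_geno `n_founders` x `n_markers` matrix of founder
#'   alleles (no missing values).
#' @param map a [magic_map()].
#' @param error_rate emission error probability (default 1e-4).
#' @return A `founder_probs` object in marker mode: matrix `prob`
#'   (`n_lines` rows, one column per marker x founder, block-structured
#'   chromosome/marker/founder) plus an `index` data frame with columns
#'   `chrom`, `item` (marker index within chromosome), `founder`,
#'   `marker`, `pos_cM`.
#' @export
founder_posteriors <- function(scores, founder_geno, map, error_rate = 1e-4) {
  map <- validate_magic_map(map)
  if (is.null(colnames(scores)))
    stop("scores must have marker column names")
  missing_in_map <- setdiff(colnames(scores), map$marker)
  if (length(missing_in_map))
    stop("markers in scores but not on map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "))
  if (!all(map$marker %in% colnames(scores)))
    stop("map markers missing from scores: ",
         paste(utils::head(setdiff(map$marker, colnames(scores)), 5),
               collapse = ", "))
  scores <- scores[, map$marker, drop = FALSE]
  founder_geno <- founder_geno[, map$marker, drop = FALSE]
  n <- nrow(scores)
  n_f <- nrow(founder_geno)
  if (all(is.na(scores)) || any(rowSums(!is.na(scores)) == 0L))
    warning("line(s) with all-missing marker scores: posteriors are uniform")
  idx <- map_split(map)
  blocks <- vector("list", length(idx))
  index <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    jj <- idx[[k]]
    rk <- length(jj)
    pos <- map$pos_cM[jj]
    ## emissions: list of n x n_f matrices
    E <- vector("list", rk)
    for (j in seq_len(rk)) {
      s <- scores[, jj[j]]
      fa <- founder_geno[, jj[j]]
      Ej <- matrix(1, n, n_f)
      obs <- !is.na(s)
      if (any(obs)) {
        match_mat <- outer(s[obs], fa, "==")
        Ej[obs, ] <- ifelse(match_mat, 1 - error_rate, error_rate)
      }
      E[[j]] <- Ej
    }
    Tm <- lapply(diff(pos), ril4_transition, n_f = n_f)
    ## forward
    alpha <- vector("list", rk)
    a <- E[[1]] / n_f
    alpha[[1]] <- a / rowSums(a)
    for (j in seq_len(rk - 1L)) {
      a <- (alpha[[j]] %*% Tm[[j]]) * E[[j + 1L]]
      alpha[[j + 1L]] <- a / rowSums(a)
    }
    ## backward
    beta <- vector("list", rk)
    beta[[rk]] <- matrix(1 / n_f, n, n_f)
    for (j in rev(seq_len(rk - 1L))) {
      b <- (beta[[j + 1L]] * E[[j + 1L]]) %*% t(Tm[[j]])
      beta[[j]] <- b / rowSums(b)
    }
    post <- matrix(0, n, rk * n_f)
    for (j in seq_len(rk)) {
      p <- alpha[[j]] * beta[[j]]
      post[, (j - 1L) * n_f + seq_len(n_f)] <- p / rowSums(p)
    }
    blocks[[k]] <- post
    index[[k]] <- data.frame(
      chrom = map$chrom[jj][rep(seq_len(rk), each = n_f)],
      item = rep(seq_len(rk), each = n_f),
      founder = rep(seq_len(n_f), rk),
      marker = rep(map$marker[jj], each = n_f),
      pos_cM = rep(pos, each = n_f),
      stringsAsFactors = FALSE)
  }
  prob <- do.call(cbind, blocks)
  rownames(prob) <- rownames(scores)
  new_founder_probs(prob, do.call(rbind, index), map, "marker", n_f)
}

#' Interval-averaged founder probabilities
#'
#' Converts marker-mode probabilities to interval mode: the probability
#' block for interval j on a chromosome is the arithmetic mean of the
#' posterior blocks at its two flanking markers, renormalised per line.
#' A chromosome with a single marker contributes no intervals.
#'
#' @param fp a marker-mode `founder_probs` object.
#' @return A `founder_probs` object in interval mode; `index` gains
#'   `left_cM`, `right_cM` and `pos_cM` (interval midpoint).
#' @export
interval_average <- function(fp) {
  stopifnot(inherits(fp, "founder_probs"), fp$mode == "marker")
  n_f <- fp$n_founders
  out_blocks <- list()
  out_index <- list()
  for (cc in unique(fp$index$chrom)) {
    sel <- fp$index$chrom == cc
    items <- unique(fp$index$item[sel])
    rk <- length(items)
    if (rk < 2L) {
      message("chromosome ", cc, " has a single marker: no intervals")
      next
    }
    cols <- which(sel)
    P <- fp$prob[, cols, drop = FALSE]
    pos <- fp$index$pos_cM[sel][seq(1, by = n_f, length.out = rk)]
    iv <- matrix(0, nrow(P), (rk - 1L) * n_f)
    for (j in seq_len(rk - 1L)) {
      a <- P[, (j - 1L) * n_f + seq_len(n_f), drop = FALSE]
      b <- P[, j * n_f + seq_len(n_f), drop = FALSE]
      m <- (a + b) / 2
      iv[, (j - 1L) * n_f + seq_len(n_f)] <- m / rowSums(m)
    }
    out_blocks[[cc]] <- iv
    out_index[[cc]] <- data.frame(
      chrom = cc,
      item = rep(seq_len(rk - 1L), each = n_f),
      founder = rep(seq_len(n_f), rk - 1L),
      left_cM = rep(pos[-rk], each = n_f),
      right_cM = rep(pos[-1L], each = n_f),
      pos_cM = rep((pos[-rk] + pos[-1L]) / 2, each = n_f),
      stringsAsFactors = FALSE)
  }
  prob <- do.call(cbind, out_blocks)
  rownames(prob) <- rownames(fp$prob)
  new_founder_probs(prob, do.call(rbind, out_index), fp$map, "interval", n_f)
}

#' Indicator founder probabilities from true simulated origins
#'
#' Builds the probability matrix directly from the (known) simulated
#' founder origins: at each marker the block row is the indicator of
#' the true founder.  Mainly used to validate the HMM and for idealised
#' analyses.
#'
#' @param pop a `magic_pop`.
#' @return A marker-mode `founder_probs`.
#' @export
origin_probs <- function(pop) {
  map <- pop$map
  n <- nrow(pop$origins)
  n_f <- pop$n_founders
  prob <- matrix(0, n, nrow(map) * n_f)
  for (j in seq_len(nrow(map))) {
    prob[cbind(seq_len(n), (j - 1L) * n_f + pop$origins[, j])] <- 1
  }
  rownames(prob) <- rownames(pop$origins)
  idx <- map_split(map)
  index <- do.call(rbind, lapply(seq_along(idx), function(k) {
    jj <- idx[[k]]
    data.frame(chrom = map$chrom[jj][rep(seq_along(jj), each = n_f)],
               item = rep(seq_along(jj), each = n_f),
               founder = rep(seq_len(n_f), length(jj)),
               marker = rep(map$marker[jj], each = n_f),
               pos_cM = rep(map$pos_cM[jj], each = n_f),
               stringsAsFactors = FALSE)
  }))
  new_founder_probs(prob, index, map, "marker", n_f)
}
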