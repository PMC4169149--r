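## Phenotype simulation for MAGIC studies.
##
## Generating model per line i, trait/environment j, replicate k:
##   y_ijk = mu_j + sum_l q_il' a_jl + u_pij + e_ijk
## with founder indicator q_il at QTL l, founder-by-trait sizes a_jl,
## polygenic effects u_pi ~ N(0, G_p) across traits and iid N(0, sd^2)
## residuals.

#' Specify a simulated QTL
#'
#' @param chrom chromosome name (must match the map).
#' @param pos_cM position in centimorgans.
#' @param sizes `n_founders` x `n_traits` matrix of founder effect sizes.
#' @return list of class `qtl_effect`.
#' @export
qtl_effect <- function(chrom, pos_cM, sizes) {
  sizes <- as.matrix(sizes)
  structure(list(chrom = as.character(chrom), pos_cM = as.numeric(pos_cM),
                 sizes = sizes), class = "qtl_effect")
}

## symmetric PSD square root (used for drawing correlated effects)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate phenotypes for a MAGIC population
#'
#' @param pop a `magic_pop` from [sim_magic()].
#' @param mu numeric vector of trait (or environment) means; its length
#'   sets the number of traits.
#' @param Gp `t` x `t` polygenic variance-covariance matrix across
#'   traits/environments (symmetric PSD).
#' @param resid_sd residual standard deviation (iid across observations).
#' @param n_reps replicates per line and trait.
#' @param qtl_effects list of [qtl_effect()]s (possibly empty).
#' @param seed integer seed.
#' @param traits optional trait labels (default `T1..Tt`).
#' @return Long-format data frame (class `magic_pheno`) with columns
#'   `line`, `trait`, `rep`, `value`.
#' @export
sim_phenotypes <- function(pop, mu, Gp, resid_sd = 1, n_reps = 2,
                           qtl_effects = list(), seed = 1, traits = NULL) {
  t <- length(mu)
  Gp <- as.matrix(Gp)
  if (!all(dim(Gp) == c(t, t))) stop("Gp dimension must match length(mu)")
  if (max(abs(Gp - t(Gp))) > 1e-10) stop("Gp must be symmetric")
  n <- nrow(pop$origins)
  lines <- rownames(pop$origins)
  if (is.null(traits)) traits <- paste0("T", seq_len(t))
  map <- pop$map
  ## genetic value per line x trait
  gval <- matrix(0, n, t)
  for (q in qtl_effects) {
    if (!q$chrom %in% map_chroms(map))
      stop("QTL chromosome ", q$chrom, " not on map")
    maxpos <- max(map$pos_cM[map$chrom == q$chrom])
    if (q$pos_cM < 0 || q$pos_cM > maxpos)
      stop("QTL position ", q$pos_cM, " off map for chromosome ", q$chrom)
    if (!all(dim(q$sizes) == c(pop$n_founders, t)))
      stop("QTL sizes matrix must be n_founders x n_traits")
    org <- vapply(pop$genomes, function(g) org_at(g[[q$chrom]], q$pos_cM), 0L)
    gval <- gval + q$sizes[org, , drop = FALSE]
  }
  set.seed(derive_seed(seed, 211L))
  up <- matrix(stats::rnorm(n * t), n, t) %*% psd_sqrt(Gp)
  gval <- gval + up
  e <- array(stats::rnorm(n * t * n_reps, sd = resid_sd), c(n, t, n_reps))
  out <- data.frame(
    line = rep(lines, times = t * n_reps),
    trait = rep(rep(traits, each = n), times = n_reps),
    rep = rep(seq_len(n_reps), each = n * t),
    value = as.vector(outer(gval, rep(1, n_reps)) + e) +
      rep(rep(mu, each = n), times = n_reps),
    stringsAsFactors = FALSE)
  structure(out, class = c("magic_pheno", "data.frame"),
            mu = mu, Gp = Gp, resid_sd = resid_sd, n_reps = n_reps,
            seed = seed)
}

#' Polygenic covariance of the bundled simulation designs
#'
#' The three-trait polygenic covariance used by the packaged null and
#' power study designs: variances 0.5 with correlations 0.7 (traits 1-2)
#' and 0.5 (with trait 3).
#'
#' @return 3 x 3 covariance matrix.
#' @export
study_polygenic_cov <- function() {
  0.5 * matrix(c(1, 0.7, 0.5,
                 0.7, 1, 0.5,
                 0.5, 0.5, 1), 3, 3)
}

#' Trait means of the bundled simulation designs
#' @return numeric vector (9, 10, 12).
#' @export
study_trait_means <- function() c(9, 10, 12)

#' QTL specification of the bundled power study design
#'
#' Four QTL on chromosomes 1-4 for three traits, founder sizes of
#' magnitude 0.3 with pattern (+,-,-,+): a fully pleiotropic QTL on
#' chromosome 1; a QTL on chromosome 2 with the sign pattern flipped for
#' trait 3; a QTL on chromosome 3 expressed only in trait 3; and a QTL
#' on chromosome 4 absent in trait 3.  With uniform founder
#' probabilities each active QTL contributes 0.09 to the genetic
#' variance of its trait (11.7% of the per-trait total of 0.77).
#'
#' @return list of [qtl_effect()]s.
#' @export
power_qtl_effects <- function() {
  a <- c(0.3, -0.3, -0.3, 0.3)
  z <- rep(0, 4)
  list(
    qtl_effect("C1", 141, cbind(a, a, a)),
    qtl_effect("C2", 160, cbind(a, a, -a)),
    qtl_effect("C3", 174, cbind(z, z, a)),
    qtl_effect("C4", 207, cbind(a, a, z)))
}
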