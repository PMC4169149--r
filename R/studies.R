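## Null and power simulation studies: the end-to-end pipeline
## (population -> marker scores -> HMM probabilities -> scan) run over
## phenotype replicates on a fixed simulated genome.

#' Simulate a genome set and its founder probabilities
#'
#' Simulates a four-way MAGIC population on the given map, founder
#' marker genotypes, line marker scores, HMM founder posteriors and
#' interval-averaged probabilities, plus the precomputed `PP'` kernel
#' shared by all scans on this genome set.
#'
#' @param map a [magic_map()] (default: seven 300-cM chromosomes with
#'   201 equally spaced markers, 1.5-cM spacing).
#' @param n_lines number of RILs (default 500).
#' @param seed integer seed.
#' @param informative fully informative founder alleles instead of
#'   biallelic 0.5-frequency markers.
#' @param error_rate HMM emission error rate.
#' @param use_hmm if `FALSE`, use indicator probabilities from the true
#'   simulated origins instead of HMM posteriors.
#' @return list: `pop`, `probs` (interval mode), `PPt`, `map`, `seed`.
#' @export
prepare_genome <- function(map = sim_linkage_map(7, 300, 201),
                           n_lines = 500, seed = 1, informative = FALSE,
                           error_rate = 1e-4, use_hmm = TRUE) {
  pop <- sim_magic(map, n_lines = n_lines, seed = seed)
  if (use_hmm) {
    fg <- sim_founder_genotypes(map, informative = informative, seed = seed)
    scores <- sim_marker_scores(pop, fg)
    mp <- founder_posteriors(scores, fg, map, error_rate = error_rate)
  } else {
    mp <- origin_probs(pop)
  }
  probs <- interval_average(mp)
  list(pop = pop, probs = probs, PPt = tcrossprod(probs$prob),
       map = map, seed = seed)
}

study_se_prop <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

#' Null simulation study
#'
#' Repeatedly simulates phenotypes with no QTL (trait means 9/10/12,
#' polygenic covariance [study_polygenic_cov()], unit residual error,
#' two replicates) on a fixed genome set and runs the multitrait scan,
#' reporting the type-I error rate (proportion of replicates selecting
#' at least one QTL) and the mean number of false-positive QTL per
#' replicate, with Monte-Carlo standard errors.
#'
#' @param reps number of phenotype replicates.
#' @param genome output of [prepare_genome()]; simulated with
#'   `seed` if `NULL`.
#' @param n_lines,map passed to [prepare_genome()] when simulating.
#' @param alpha selection level.
#' @param seed integer master seed.
#' @param max_qtl per-scan selection cap.
#' @param verbose print per-replicate progress.
#' @return `magic_study` list: `type1`, `type1_se`, `mean_fp`,
#'   `mean_fp_se`, `n_selected` (per replicate), `reps`, `failures`,
#'   `alpha`, `seed`.
#' @export
run_null_study <- function(reps = 200, genome = NULL, n_lines = 500,
                           map = sim_linkage_map(7, 300, 201),
                           alpha = 0.05, seed = 1, max_qtl = 40L,
                           verbose = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (is.null(genome))
    genome <- prepare_genome(map, n_lines = n_lines, seed = seed)
  n_sel <- rep(NA_integer_, reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    pheno <- sim_phenotypes(genome$pop, mu = study_trait_means(),
                            Gp = study_polygenic_cov(), resid_sd = 1,
                            n_reps = 2, qtl_effects = list(),
                            seed = derive_seed(seed, 100000L + r))
    scan <- tryCatch(
      run_scan(pheno, genome$probs, mode = "multitrait", alpha = alpha,
               PPt = genome$PPt, max_qtl = max_qtl),
      error = function(e) NULL)
    if (is.null(scan)) {
      failures <- failures + 1L
      next
    }
    n_sel[r] <- nrow(scan$qtl)
    if (verbose) message("replicate ", r, ": ", n_sel[r], " QTL")
  }
  ok <- !is.na(n_sel)
  nr <- sum(ok)
  type1 <- mean(n_sel[ok] >= 1L)
  structure(list(type1 = type1, type1_se = study_se_prop(type1, nr),
                 mean_fp = mean(n_sel[ok]),
                 mean_fp_se = stats::sd(n_sel[ok]) / sqrt(nr),
                 n_selected = n_sel, reps = reps, failures = failures,
                 alpha = alpha, seed = seed, design = "null"),
            class = "magic_study")
}

## match selected intervals against true QTL positions
match_detections <- function(qtl_tab, truth, window) {
  det <- logical(length(truth))
  det_row <- rep(NA_integer_, length(truth))
  fp <- rep(TRUE, nrow(qtl_tab))
  for (i in seq_along(truth)) {
    q <- truth[[i]]
    on_chrom <- which(qtl_tab$chrom == q$chrom)
    if (!length(on_chrom)) next
    d <- abs(qtl_tab$pos_cM[on_chrom] - q$pos_cM)
    hit <- on_chrom[d <= window]
    if (length(hit)) {
      det[i] <- TRUE
      det_row[i] <- hit[which.min(d[match(hit, on_chrom)])]
      fp[hit] <- FALSE
    }
  }
  list(detected = det, det_row = det_row, fp = fp)
}

#' Power simulation study
#'
#' Repeatedly simulates phenotypes under the bundled four-QTL power
#' design ([power_qtl_effects()]) on a fixed genome set, runs the
#' multitrait scan and scores, per replicate: detection of each true
#' QTL (a selected interval with midpoint within `window` cM of the
#' true position), false-positive selections per chromosome, and the
#' reported founder effect sizes at each detected QTL.
#'
#' @inheritParams run_null_study
#' @param window detection window in cM (default 5).
#' @return `magic_study` list: `detection` (per-QTL proportions),
#'   `total_detected` (mean over replicates), `fp_by_chrom`,
#'   `fp_total`, `sizes` (mean estimated founder x trait sizes per QTL
#'   over detecting replicates, with counts), `reps`, `failures`.
#' @export
run_power_study <- function(reps = 200, genome = NULL, n_lines = 500,
                            map = sim_linkage_map(7, 300, 201),
                            alpha = 0.05, seed = 1, window = 5,
                            max_qtl = 40L, verbose = FALSE) {
  if (is.null(genome))
    genome <- prepare_genome(map, n_lines = n_lines, seed = seed)
  qtl_true <- power_qtl_effects()
  nq <- length(qtl_true)
  nf <- 4L
  t <- 3L
  chroms <- map_chroms(genome$map)
  det_mat <- matrix(NA, reps, nq)
  fp_mat <- matrix(NA_integer_, reps, length(chroms),
                   dimnames = list(NULL, chroms))
  size_sum <- array(0, c(nq, nf, t))
  size_n <- integer(nq)
  failures <- 0L
  for (r in seq_len(reps)) {
    pheno <- sim_phenotypes(genome$pop, mu = study_trait_means(),
                            Gp = study_polygenic_cov(), resid_sd = 1,
                            n_reps = 2, qtl_effects = qtl_true,
                            seed = derive_seed(seed, 200000L + r))
    scan <- tryCatch(
      run_scan(pheno, genome$probs, mode = "multitrait", alpha = alpha,
               PPt = genome$PPt, max_qtl = max_qtl),
      error = function(e) NULL)
    if (is.null(scan)) {
      failures <- failures + 1L
      next
    }
    mm <- match_detections(scan$qtl, qtl_true, window)
    det_mat[r, ] <- mm$detected
    fp_mat[r, ] <- 0L
    if (any(mm$fp)) {
      tt <- table(factor(scan$qtl$chrom[mm$fp], levels = chroms))
      fp_mat[r, ] <- as.integer(tt)
    }
    if (any(mm$detected)) {
      sm <- summary(scan)
      for (i in which(mm$detected)) {
        row <- scan$qtl[mm$det_row[i], ]
        sel <- sm$table$chrom == row$chrom &
          abs((sm$table$left_cM + sm$table$right_cM) / 2 - row$pos_cM) < 1e-9
        sub <- sm$table[sel, ]
        tr_levels <- unique(sub$trait)
        A <- matrix(0, nf, t)
        for (s in seq_len(t))
          A[, s] <- sub$size[sub$trait == tr_levels[s]]
        size_sum[i, , ] <- size_sum[i, , ] + A
        size_n[i] <- size_n[i] + 1L
      }
    }
    if (verbose)
      message("replicate ", r, ": detected ",
              paste(as.integer(mm$detected), collapse = ""),
              ", FP = ", sum(mm$fp))
  }
  ok <- !is.na(det_mat[, 1])
  nr <- sum(ok)
  detection <- colMeans(det_mat[ok, , drop = FALSE])
  sizes <- lapply(seq_len(nq), function(i)
    if (size_n[i]) size_sum[i, , ] / size_n[i] else matrix(NA_real_, nf, t))
  structure(list(detection = detection,
                 detection_se = study_se_prop(detection, nr),
                 total_detected = mean(rowSums(det_mat[ok, , drop = FALSE])),
                 fp_by_chrom = colSums(fp_mat[ok, , drop = FALSE]) / nr,
                 fp_total = sum(fp_mat[ok, ]) / nr,
                 sizes = sizes, sizes_n = size_n,
                 true_sizes = lapply(qtl_true, `[[`, "sizes"),
                 reps = reps, failures = failures, window = window,
                 alpha = alpha, seed = seed, design = "power"),
            class = "magic_study")
}

#' @export
print.magic_study <- function(x, ...) {
  if (x$design == "null") {
    cat(sprintf("Null study (%d replicates, alpha = %.2f):\n", x$reps, x$alpha))
    cat(sprintf("  type-I error rate: %.3f (SE %.3f)\n", x$type1, x$type1_se))
    cat(sprintf("  mean false-positive QTL per replicate: %.3f (SE %.3f)\n",
                x$mean_fp, x$mean_fp_se))
  } else {
    cat(sprintf("Power study (%d replicates, alpha = %.2f, window %.0f cM):\n",
                x$reps, x$alpha, x$window))
    cat("  detection proportions:",
        paste(sprintf("%.3f", x$detection), collapse = ", "), "\n")
    cat(sprintf("  mean true QTL detected: %.3f of %d\n",
                x$total_detected, length(x$detection)))
    cat(sprintf("  false-positive proportion per replicate: %.3f\n",
                x$fp_total))
  }
  if (x$failures) cat("  failed replicates excluded:", x$failures, "\n")
  invisible(x)
}
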