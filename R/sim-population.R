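## Four-way MAGIC population simulator.
##
## A chromosome homolog is a piecewise-constant founder-origin function,
## stored as list(ends, org): `ends` are the right endpoints (cM) of the
## segments tiling [0, L], `org` the founder label (1..4) of each segment.

make_homolog <- function(founder, L) list(ends = L, org = as.integer(founder))

## founder origin of homolog `h` at positions `x` (vectorised)
org_at <- function(h, x) {
  idx <- pmin(findInterval(x, h$ends) + 1L, length(h$org))
  h$org[idx]
}

## One meiosis under the Haldane model (no interference): crossovers are a
## Poisson process at rate 1/100 per cM along the bivalent; the gamete
## copies from one homolog and switches at every crossover.
meiosis_gamete <- function(h1, h2, L) {
  cur <- sample.int(2L, 1L)
  nxo <- if (L > 0) stats::rpois(1L, L / 100) else 0L
  if (nxo == 0L) return(if (cur == 1L) h1 else h2)
  xo <- sort(stats::runif(nxo, 0, L))
  starts <- c(0, xo)
  stops <- c(xo, L)
  hs <- list(h1, h2)
  ends <- vector("list", length(starts))
  org <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    h <- hs[[cur]]
    i1 <- min(findInterval(starts[b], h$ends) + 1L, length(h$org))
    i2 <- min(findInterval(stops[b], h$ends, left.open = TRUE) + 1L,
              length(h$org))
    i2 <- max(i1, i2)
    ends[[b]] <- pmin(h$ends[i1:i2], stops[b])
    org[[b]] <- h$org[i1:i2]
    cur <- 3L - cur
  }
  ends <- unlist(ends)
  org <- unlist(org)
  ## drop zero-length segments, then merge adjacent equal founders
  pos <- c(ends[1] > 0, diff(ends) > 0)
  ends <- ends[pos]
  org <- org[pos]
  keep <- c(org[-length(org)] != org[-1L], TRUE)
  list(ends = ends[keep], org = org[keep])
}

## Simulate one RIL chromosome through the classic funnel
## (F1 x F2) x (F3 x F4) followed by selfing with single-seed descent.
## Returns list(genome = resolved homolog, het = pre-resolution
## heterozygosity indicator function evaluated later at markers).
sim_ril_chromosome <- function(L, selfing) {
  g1 <- meiosis_gamete(make_homolog(1L, L), make_homolog(2L, L), L)
  g2 <- meiosis_gamete(make_homolog(3L, L), make_homolog(4L, L), L)
  plant <- list(g1, g2)
  for (gen in seq_len(selfing)) {
    plant <- list(meiosis_gamete(plant[[1]], plant[[2]], L),
                  meiosis_gamete(plant[[1]], plant[[2]], L))
  }
  ## residual heterozygosity is resolved by taking one homolog at random
  list(final = plant, genome = plant[[sample.int(2L, 1L)]])
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(k)) %% 2147483647)
}

#' Simulate a four-way MAGIC population
#'
#' Simulates recombinant inbred lines from the classic four-way funnel
#' cross (F1 x F2) x (F3 x F4): each line receives one recombined gamete
#' from each two-way F1, then is selfed by single-seed descent.  Meiosis
#' follows the Haldane model (crossovers a Poisson process, no
#' interference).  After the selfing generations, residual heterozygosity
#' (about \eqn{(1/2)^g} of loci after \eqn{g} selfings) is resolved by
#' sampling one of the two homologs per chromosome, so every line carries
#' a single founder origin at each locus.
#'
#' @param map a [magic_map()].
#' @param n_lines number of RILs to simulate.
#' @param n_founders number of founders; only the classic four-way funnel
#'   (4) is supported.
#' @param selfing number of selfing generations (>= 1; default 6).
#' @param seed integer master seed; per-line substreams are derived
#'   deterministically from it.
#' @param keep_het if `TRUE`, record the proportion of marker loci still
#'   heterozygous before resolution (component `het_rate`).
#' @return A `magic_pop` object: list with `map`, `origins` (an
#'   `n_lines` x `n_markers` integer matrix of founder origins, lines in
#'   rows), `genomes` (per line, per chromosome segment lists), `seed`,
#'   `selfing` and `het_rate`.
#' @export
sim_magic <- function(map, n_lines, n_founders = 4, selfing = 6, seed = 1,
                      keep_het = FALSE) {
  if (n_founders != 4)
    stop("unsupported design: only the classic four-way funnel (n_founders = 4) is implemented")
  if (selfing < 1) stop("selfing generations must be >= 1")
  map <- validate_magic_map(map)
  chroms <- map_chroms(map)
  idx <- map_split(map)
  lens <- vapply(chroms, function(cc) max(map$pos_cM[map$chrom == cc]), 0)
  origins <- matrix(NA_integer_, n_lines, nrow(map),
                    dimnames = list(paste0("L", seq_len(n_lines)), map$marker))
  genomes <- vector("list", n_lines)
  het_n <- 0L
  for (i in seq_len(n_lines)) {
    set.seed(derive_seed(seed, i))
    gi <- vector("list", length(chroms))
    names(gi) <- chroms
    for (k in seq_along(chroms)) {
      sim <- sim_ril_chromosome(lens[k], selfing)
      gi[[k]] <- sim$genome
      pos <- map$pos_cM[idx[[k]]]
      origins[i, idx[[k]]] <- org_at(sim$genome, pos)
      if (keep_het) {
        o1 <- org_at(sim$final[[1]], pos)
        o2 <- org_at(sim$final[[2]], pos)
        het_n <- het_n + sum(o1 != o2)
      }
    }
    genomes[[i]] <- gi
  }
  structure(list(map = map, origins = origins, genomes = genomes,
                 n_founders = 4L, selfing = selfing, seed = seed,
                 het_rate = if (keep_het) het_n / (n_lines * nrow(map)) else NA_real_),
            class = "magic_pop")
}

#' @export
print.magic_pop <- function(x, ...) {
  cat("Four-way MAGIC population:", nrow(x$origins), "lines,",
      ncol(x$origins), "markers,", x$selfing, "selfing generations\n")
  invisible(x)
}

#' Simulate founder marker genotypes
#'
#' By default founders carry biallelic scores drawn independently with
#' allele frequency 0.5 at every marker (SNP-like map).  With
#' `informative = TRUE` each founder carries a private allele at every
#' marker (fully informative, e.g. microsatellite-like), useful for
#' checking founder-origin recovery.
#'
#' @param map a [magic_map()].
#' @param n_founders number of founders (default 4).
#' @param informative give each founder a unique allele at every marker.
#' @param seed integer seed.
#' @return integer matrix `n_founders` x `n_markers` of allele codes.
#' @export
sim_founder_genotypes <- function(map, n_founders = 4, informative = FALSE,
                                  seed = 1) {
  r <- nrow(map)
  if (informative) {
    g <- matrix(rep(seq_len(n_founders), r), n_founders, r)
  } else {
    set.seed(derive_seed(seed, 97L))
    g <- matrix(sample(c(1L, 2L), n_founders * r, replace = TRUE),
                n_founders, r)
  }
  dimnames(g) <- list(paste0("F", seq_len(n_founders)), map$marker)
  g
}

#' Derive line marker scores from founder origins
#'
#' Each (inbred) line's score at a marker is the allele of the founder
#' whose segment the line carries there.
#'
#' @param pop a `magic_pop`.
#' @param founder_geno matrix from [sim_founder_genotypes()].
#' @return integer matrix `n_lines` x `n_markers`.
#' @export
sim_marker_scores <- function(pop, founder_geno) {
  stopifnot(ncol(founder_geno) == ncol(pop$origins))
  r <- ncol(pop$origins)
  scores <- matrix(NA_integer_, nrow(pop$origins), r,
                   dimnames = dimnames(pop$origins))
  for (j in seq_len(r)) scores[, j] <- founder_geno[pop$origins[, j], j]
  scores
}
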