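test_that("fully informative markers pin the posterior on the true founder", {
  map <- magic_map(rep("C1", 3), c("M1", "M2", "M3"), c(0, 10, 20))
  fg <- sim_founder_genotypes(map, informative = TRUE)
  scores <- matrix(c(2, 2, 2), 1, 3, dimnames = list("L1", map$marker))
  fp <- founder_posteriors(scores, fg, map, error_rate = 1e-4)
  expect_equal(as.vector(fp$prob[1, 5:8]), c(0, 1, 0, 0), tolerance = 1e-3)
  ## invariant to shrinking the error rate
  fp2 <- founder_posteriors(scores, fg, map, error_rate = 1e-8)
  expect_equal(fp$prob, fp2$prob, tolerance = 1e-3)
})

test_that("uninformative data preserve the uniform prior", {
  map <- magic_map(rep("C1", 2), c("M1", "M2"), c(0, 50))
  fg <- matrix(1L, 4, 2, dimnames = list(NULL, map$marker))  # all same allele
  scores <- matrix(1L, 1, 2, dimnames = list("L1", map$marker))
  fp <- founder_posteriors(scores, fg, map)
  expect_equal(as.vector(fp$prob[1, ]), rep(0.25, 8), tolerance = 1e-10)
  ## all-missing line warns and is uniform
  scores_na <- matrix(NA_integer_, 1, 2, dimnames = list("L1", map$marker))
  expect_warning(fpn <- founder_posteriors(scores_na, fg, map), "all-missing")
  expect_equal(as.vector(fpn$prob[1, ]), rep(0.25, 8))
})

test_that("posteriors match exhaustive path enumeration on small chromosomes", {
  set.seed(42)
  for (rk in 2:3) {
    pos <- sort(c(0, runif(rk - 1, 5, 60)))
    map <- magic_map(rep("C1", rk), paste0("M", seq_len(rk)), pos)
    for (case in 1:8) {
      fg <- matrix(sample(1:2, 4 * rk, replace = TRUE), 4, rk,
                   dimnames = list(NULL, map$marker))
      sc <- matrix(sample(c(1:2, NA), rk, replace = TRUE), 1, rk,
                   dimnames = list("L1", map$marker))
      fp <- suppressWarnings(founder_posteriors(sc, fg, map,
                                                error_rate = 1e-3))
      oracle <- enumerate_posteriors(sc[1, ], fg, pos, error_rate = 1e-3)
      got <- matrix(fp$prob[1, ], rk, 4, byrow = TRUE)
      expect_lt(max(abs(got - oracle)), 1e-10)
    }
  }
})

test_that("unknown markers and missing map markers raise keyed errors", {
  map <- magic_map(rep("C1", 2), c("M1", "M2"), c(0, 10))
  fg <- sim_founder_genotypes(map, informative = TRUE)
  sc <- matrix(1L, 1, 2, dimnames = list("L1", c("M1", "MX")))
  expect_error(founder_posteriors(sc, fg, map), "MX")
  sc2 <- matrix(1L, 1, 1, dimnames = list("L1", "M1"))
  expect_error(founder_posteriors(sc2, fg[, 1, drop = FALSE], map), "M2")
})

test_that("transition rows approach the stationary distribution with distance", {
  Tm <- magicqtl:::ril4_transition(1e6)
  expect_equal(as.vector(Tm), rep(0.25, 16), tolerance = 1e-6)
  ## two-point switch probability matches brute-force simulation
  for (d in c(10, 40)) {
    map <- magic_map(c("C1", "C1"), c("M1", "M2"), c(0, d))
    pop <- sim_magic(map, n_lines = 3000, seed = 100 + d)
    sw <- mean(pop$origins[, 1] != pop$origins[, 2])
    r <- 0.5 * (1 - exp(-2 * d / 100))
    pred <- 3 * r / (1 + 2 * r)
    expect_lt(abs(sw - pred), 3 * sqrt(pred * (1 - pred) / 3000) + 0.005)
  }
})

test_that("argmax founder recovers the simulated origin on informative maps", {
  map <- sim_linkage_map(1, 150, 76)   # 2 cM spacing
  pop <- sim_magic(map, n_lines = 120, seed = 8)
  fg <- sim_founder_genotypes(map, informative = TRUE)
  sc <- sim_marker_scores(pop, fg)
  fp <- founder_posteriors(sc, fg, map)
  call <- matrix(max.col(matrix(t(fp$prob), ncol = 4, byrow = TRUE)),
                 nrow(fp$prob), nrow(map), byrow = TRUE)
  expect_gt(mean(call == pop$origins), 0.99)
})

test_that("interval averaging is the renormalised mean of flanking blocks", {
  map <- magic_map(rep("C1", 3), c("M1", "M2", "M3"), c(0, 10, 20))
  fg <- sim_founder_genotypes(map, informative = TRUE)
  sc <- matrix(c(1, 2, 2), 1, 3, dimnames = list("L1", map$marker))
  fp <- founder_posteriors(sc, fg, map, error_rate = 1e-6)
  iv <- interval_average(fp)
  expect_equal(nrow(iv$index) / 4, 2)
  ## flanking posteriors ~(1,0,0,0) and ~(0,1,0,0) -> midpoint
  expect_equal(as.vector(iv$prob[1, 1:4]), c(0.5, 0.5, 0, 0),
               tolerance = 1e-3)
  ## identical flanking posteriors are preserved
  expect_equal(as.vector(iv$prob[1, 5:8]), c(0, 1, 0, 0), tolerance = 1e-3)
  ## rows always renormalised
  expect_equal(rowSums(matrix(iv$prob[1, ], 2, 4, byrow = TRUE)), c(1, 1))
  ## interval index carries midpoints
  expect_equal(unique(iv$index$pos_cM), c(5, 15))
})

test_that("probability matrices satisfy the block-row-sum invariant", {
  map <- sim_linkage_map(2, 60, 7)
  pop <- sim_magic(map, n_lines = 30, seed = 4)
  fg <- sim_founder_genotypes(map, seed = 4)
  sc <- sim_marker_scores(pop, fg)
  fp <- founder_posteriors(sc, fg, map)
  iv <- interval_average(fp)
  for (obj in list(fp, iv)) {
    nb <- ncol(obj$prob) / 4
    for (b in seq_len(nb)) {
      rs <- rowSums(obj$prob[, (b - 1) * 4 + 1:4])
      expect_lt(max(abs(rs - 1)), 1e-8)
    }
    expect_true(all(obj$prob >= 0 & obj$prob <= 1))
  }
})
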