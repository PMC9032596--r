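# independent oracle: P(genotype at an inner position | flanking genotypes)
# by enumerating gamete allele paths under Haldane's map function
enumerate_prob <- function(gL, gR, dL, dR) {
  r <- function(d) 0.5 * (1 - exp(-2 * d / 100))
  t1 <- function(a, b, d) ifelse(a == b, 1 - r(d), r(d))
  w <- rep(0, 3)
  for (a1L in 0:1) for (a1m in 0:1) for (a1R in 0:1)
    for (a2L in 0:1) for (a2m in 0:1) for (a2R in 0:1) {
      if (a1L + a2L + 1 != gL || a1R + a2R + 1 != gR) next
      w[a1m + a2m + 1] <- w[a1m + a2m + 1] +
        0.5 * t1(a1L, a1m, dL) * t1(a1m, a1R, dR) *
        0.5 * t1(a2L, a2m, dL) * t1(a2m, a2R, dR)
    }
  w / sum(w)
}

scan_fixture <- function(seed = 99, n = 150, beta = 0.9) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_f2 = n, n_chromosomes = 2,
                    markers_per_chromosome = 8,
                    chromosome_lengths = c(90, 70),
                    qtl_architecture = NULL)
  map <- make_map(cfg)
  g <- simulate_f2_genotypes(map, cfg)
  y <- rnorm(n) + beta * (unclass(g)[, 5] - 2)
  list(map = map, g = g, y = y,
       gp = genotype_probabilities(map, g, step_cM = 1))
}

test_that("genotype probabilities are degenerate at typed markers and sum to 1", {
  fx <- scan_fixture()
  gp <- fx$gp
  for (ch in gp) {
    expect_equal(ch$pAA + ch$pAB + ch$pBB,
                 matrix(1, nrow(ch$pAA), ncol(ch$pAA)))
    typed <- which(!is.na(ch$marker))
    for (j in typed) {
      gobs <- unclass(fx$g)[, ch$marker[j]]
      expect_equal(ch$pAA[, j], as.numeric(gobs == 1))
      expect_equal(ch$pBB[, j], as.numeric(gobs == 3))
    }
  }
  expect_error(genotype_probabilities(fx$map, fx$g, step_cM = 0), "positive")
})

test_that("interior probabilities match brute-force gamete enumeration", {
  # two markers 12 cM apart, query at 5 cM from the left
  map <- data.frame(marker = c("mL", "mR"), chromosome = 1,
                    pos_cM = c(0, 12), pos_bp = c(1, 12e6 + 1))
  class(map) <- c("genetic_map", "data.frame")
  g <- matrix(rep(1:3, times = 3)[order(rep(1:3, times = 3))], 9, 1)
  g <- cbind(rep(1:3, each = 3), rep(1:3, times = 3))
  colnames(g) <- map$marker
  rownames(g) <- sprintf("I%d", 1:9)
  class(g) <- "f2_geno"; attr(g, "map") <- map
  gp <- genotype_probabilities(map, g, step_cM = 5)
  ch <- gp[[1]]
  j <- which(ch$pos == 5)
  for (i in 1:9) {
    expected <- enumerate_prob(unclass(g)[i, 1], unclass(g)[i, 2], 5, 7)
    expect_equal(c(ch$pAA[i, j], ch$pAB[i, j], ch$pBB[i, j]), expected,
                 tolerance = 1e-12)
  }
  # midpoint between two AA markers 10 cM apart is almost surely AA
  mid <- enumerate_prob(1, 1, 5, 5)
  expect_gt(mid[1], 0.9)
})

test_that("missing genotypes fall back to the nearest typed flanks", {
  fx <- scan_fixture(seed = 5)
  g2 <- unclass(fx$g)
  g2[3, 2] <- NA            # interior missing
  g2[4, 1] <- NA            # missing at the chromosome start
  attr(g2, "map") <- fx$map; class(g2) <- "f2_geno"
  gp <- genotype_probabilities(fx$map, g2)
  ch <- gp[[1]]
  expect_equal(ch$pAA + ch$pAB + ch$pBB,
               matrix(1, nrow(ch$pAA), ncol(ch$pAA)))
  # the individual missing at marker 2 gets the flanking-conditional there
  j2 <- which(ch$marker == fx$map$marker[2])
  d12 <- fx$map$pos_cM[2] - fx$map$pos_cM[1]
  d23 <- fx$map$pos_cM[3] - fx$map$pos_cM[2]
  expected <- enumerate_prob(g2[3, 1], g2[3, 3], d12, d23)
  expect_equal(c(ch$pAA[3, j2], ch$pAB[3, j2], ch$pBB[3, j2]), expected,
               tolerance = 1e-12)
  # before the first typed marker the 1:2:1 prior enters; still a
  # distribution and degenerate nowhere
  j1 <- which(ch$marker == fx$map$marker[1])
  expect_lt(max(ch$pAA[4, j1], ch$pAB[4, j1], ch$pBB[4, j1]), 1)
})

test_that("LOD at typed markers equals the two-degree regression oracle", {
  fx <- scan_fixture()
  sc <- cim_scan(fx$gp, fx$y, NULL)
  for (m in fx$map$marker) {
    gm <- unclass(fx$g)[, m]
    x <- (gm == 3) - (gm == 1)
    z <- as.numeric(gm == 2)
    rss1 <- sum(resid(lm(fx$y ~ x + z))^2)
    rss0 <- sum((fx$y - mean(fx$y))^2)
    lod <- length(fx$y) / 2 * log10(rss0 / rss1)
    expect_equal(sc$lod[!is.na(sc$marker) & sc$marker == m], lod,
                 tolerance = 1e-8)
  }
})

test_that("CIM with an empty cofactor set is exactly interval mapping", {
  fx <- scan_fixture()
  # force an empty stepwise selection via an unattainable entry threshold
  empty <- select_cofactors(fx$gp, fx$y, alpha_in = 0)
  expect_equal(nrow(empty), 0)
  im <- cim_scan(fx$gp, fx$y, NULL)
  cim <- cim_scan(fx$gp, fx$y, empty)
  expect_identical(im$lod, cim$lod)
  expect_identical(im$a, cim$a)
  expect_identical(im$d, cim$d)
})

test_that("stepwise cofactor selection finds a strong QTL and respects ties", {
  fx <- scan_fixture(seed = 13, beta = 1.2)
  cof <- select_cofactors(fx$gp, fx$y)
  # marker 5 (or an immediate neighbour on chromosome 1) must be selected
  sel_idx <- match(cof$marker, fx$map$marker)
  expect_true(any(abs(sel_idx - 5) <= 1))
  # no phenotypic variance -> nothing selected
  expect_equal(nrow(select_cofactors(fx$gp, rep(1, length(fx$y)))), 0)
})

test_that("cim_scan absorbs background QTLs through cofactors", {
  set.seed(301)
  cfg <- sim_config(seed = 301, n_f2 = 346, n_chromosomes = 2,
                    markers_per_chromosome = 12,
                    chromosome_lengths = c(110, 110),
                    qtl_architecture = NULL)
  map <- make_map(cfg)
  g <- simulate_f2_genotypes(map, cfg)
  G <- unclass(g)
  # two additive QTLs at markers 3 (chr 1) and 18 (chr 2)
  y <- 1.0 * (G[, 3] - 2) + 1.0 * (G[, 18] - 2) + rnorm(346, 0, 2)
  gp <- genotype_probabilities(map, g)
  cof <- select_cofactors(gp, y)
  sc_cim <- cim_scan(gp, y, cof)
  sc_im <- cim_scan(gp, y, NULL)
  # the scan on chr 1 conditions on chr 2 markers, so the chr 1 peak LOD
  # cannot systematically fall below interval mapping's
  pk_cim <- max(sc_cim$lod[sc_cim$chromosome == 1])
  pk_im <- max(sc_im$lod[sc_im$chromosome == 1])
  expect_gt(pk_cim, 0.8 * pk_im)
})

test_that("permutation thresholds behave like empirical quantiles", {
  fx <- scan_fixture(seed = 23)
  thr <- permutation_threshold(fx$gp, fx$y, NULL, n_perm = 100,
                               alpha = c(1, 0.2, 0.05), seed = 9)
  mx <- attr(thr, "max_lods")
  expect_length(mx, 100)
  expect_equal(unname(thr[["1"]]), min(mx))
  expect_lte(thr[["0.2"]], thr[["0.05"]])       # monotone in alpha
  expect_error(permutation_threshold(fx$gp, fx$y, NULL, n_perm = 50),
               "at least 100")
})

test_that("peak calling splits segments, reports flanks and classifies", {
  fx <- scan_fixture()
  sc <- cim_scan(fx$gp, fx$y, NULL)
  expect_equal(nrow(call_qtl_peaks(sc, threshold = 1e6)), 0)
  pk <- call_qtl_peaks(sc, threshold = 3, prefix = "qT")
  expect_gte(nrow(pk), 1)
  expect_true(all(pk$lod >= 3))
  top <- pk[which.max(pk$lod), ]
  expect_equal(top$chromosome, 1)
  # truth sits at marker 5 (51.43 cM); flanks must bracket the peak
  mk <- fx$map[fx$map$chromosome == 1, ]
  expect_lte(mk$pos_cM[match(top$marker_left, mk$marker)], top$pos_cM)
  expect_gte(mk$pos_cM[match(top$marker_right, mk$marker)], top$pos_cM)
  expect_true(top$gene_action %in% c("A", "PD", "D", "OD"))
  expect_true(top$pve > 0 && top$pve < 100)
  # two supra-threshold segments on one chromosome give two peaks
  curve <- data.frame(chromosome = 1, pos_cM = 0:100, marker = NA,
                      lod = c(rep(5, 20), rep(0, 30), rep(6, 20),
                              rep(0, 31)),
                      a = 1, d = 0, pve = 5)
  attr(curve, "map") <- fx$map
  class(curve) <- c("lod_curve", "data.frame")
  pk2 <- call_qtl_peaks(curve, 3)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$pos_cM, c(0, 50))    # leftmost position on ties
})

test_that("gene-action classes partition every finite effect pair", {
  ga <- classify_gene_action(c(-1.03, -0.61, 0.17, 1, 0, 0, -0.75),
                             c(-1.20, 0.97, 0.10, 0, 1.5, 0, -0.11))
  expect_equal(ga$ratio[1:4], c(1.17, 1.59, 0.59, 0))
  expect_equal(as.character(ga$class),
               c("D", "OD", "PD", "A", "OD", "A", "A"))
  # boundaries are right-closed
  expect_equal(as.character(classify_gene_action(1, 0.2)$class), "A")
  expect_equal(as.character(classify_gene_action(1, 0.8)$class), "PD")
  expect_equal(as.character(classify_gene_action(1, 1.2)$class), "D")
  expect_equal(as.character(classify_gene_action(1, 1.2000001)$class), "OD")
  set.seed(2)
  ga2 <- classify_gene_action(rnorm(200), rnorm(200))
  expect_false(anyNA(ga2$class))
  expect_error(classify_gene_action(Inf, 1), "finite")
})

test_that("a 14%-PVE locus in the full study design is localised", {
  cfg <- one_qtl_config(seed = 77)
  st <- simulate_one_qtl_study(cfg)
  fm <- family_means(st$phenotypes, "20cm")
  gp <- genotype_probabilities(st$map, st$genotypes)
  cof <- select_cofactors(gp, fm)
  thr <- permutation_threshold(gp, fm, cof, n_perm = 200, seed = 7)
  pk <- call_qtl_peaks(cim_scan(gp, fm, cof), thr)
  pk4 <- pk[pk$chromosome == 4, ]
  expect_equal(nrow(pk4), 1)
  expect_lt(abs(pk4$pos_cM - st$truth_pos), 5)
  expect_lt(pk4$a, 0)      # tolerant-parent allele increases the trait
})
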