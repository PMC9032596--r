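test_that("default map has the study dimensions and spacing", {
  map <- make_map(sim_config())
  expect_equal(nrow(map), 260)
  expect_equal(length(unique(map$chromosome)), 10)
  spac <- unlist(lapply(split(map$pos_cM, map$chromosome), diff))
  expect_equal(length(spac), 250)
  expect_equal(mean(spac), 1410.6 / 250)          # 5.6424 cM
  expect_true(all(spac > 0))
  # deterministic physical positions from the linear cM -> bp scaling
  expect_equal(map$pos_bp, mesoqtl:::cM_to_bp(map$pos_cM))
})

test_that("degenerate maps and invalid configs are handled", {
  cfg1 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 2,
                     chromosome_lengths = 37.5, qtl_architecture = NULL)
  map1 <- make_map(cfg1)
  expect_equal(diff(map1$pos_cM), 37.5)
  expect_error(sim_config(chromosome_lengths = c(0, rep(100, 9)),
                          qtl_architecture = NULL),
               "chromosome length")
  expect_error(sim_config(n_f2 = 0, qtl_architecture = NULL), ">= 1")
  qtl_off <- data.frame(qtl = "q", chromosome = 1, pos_cM = 500,
                        environment = "3cm", a = 1, d = 0)
  expect_error(sim_config(qtl_architecture = qtl_off), "outside")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  m1 <- make_map(cfg); m2 <- make_map(cfg)
  expect_identical(m1, m2)
  g1 <- simulate_f2_genotypes(m1, cfg)
  g2 <- simulate_f2_genotypes(m1, cfg)
  expect_identical(g1, g2)
  p1 <- simulate_f23_phenotypes(g1, NULL, cfg, seed = 5)
  p2 <- simulate_f23_phenotypes(g1, NULL, cfg, seed = 5)
  expect_identical(p1, p2)
})

test_that("co-located loci never recombine", {
  loci <- data.frame(marker = c("a", "b"), chromosome = 1,
                     pos_cM = c(10, 10), pos_bp = c(1, 2))
  class(loci) <- c("genetic_map", "data.frame")
  g <- simulate_f2_genotypes(loci, tiny_config(seed = 2))
  expect_identical(unname(unclass(g)[, 1]), unname(unclass(g)[, 2]))
})

test_that("segregation is Mendelian 1:2:1 and unlinked loci independent", {
  cfg <- sim_config(seed = 31, n_f2 = 10000, n_chromosomes = 2,
                    markers_per_chromosome = 3,
                    chromosome_lengths = c(50, 50),
                    qtl_architecture = NULL)
  g <- unclass(simulate_f2_genotypes(make_map(cfg), cfg))
  for (j in seq_len(ncol(g))) {
    cnt <- tabulate(g[, j], 3)
    expect_gt(stats::chisq.test(cnt, p = c(.25, .5, .25))$p.value, 0.001)
  }
  # across chromosomes: no association
  expect_gt(stats::chisq.test(table(g[, 1], g[, 4]))$p.value, 0.001)
})

test_that("observed recombinant fractions follow the map function", {
  d <- 20
  cfg <- sim_config(seed = 17, n_f2 = 10000, n_chromosomes = 1,
                    markers_per_chromosome = 2, chromosome_lengths = d,
                    qtl_architecture = NULL)
  g <- unclass(simulate_f2_genotypes(make_map(cfg), cfg))
  # count recombinant gametes via homozygote transitions: each individual
  # carries 2 gametes; P(genotype pair) follows the F2 transition matrix
  r_true <- recombination_fraction(d)
  T2 <- mesoqtl:::f2_transition(r_true)
  tab <- table(factor(g[, 1], 1:3), factor(g[, 2], 1:3))
  p_exp <- T2 * c(.25, .5, .25)
  expect_gt(stats::chisq.test(as.vector(tab),
                              p = as.vector(p_exp))$p.value, 0.001)
})

test_that("noise-free family means take the three F2:3 genetic values", {
  qtl <- data.frame(qtl = "q1", chromosome = 1, pos_cM = 45,
                    environment = "E1", a = 1.4, d = 0.6)
  cfg <- sim_config(seed = 4, n_f2 = 200, n_chromosomes = 1,
                    markers_per_chromosome = 10, chromosome_lengths = 90,
                    environments = "E1", env_means = NULL,
                    residual_sd = 0, gxe_sd = 0, qtl_architecture = qtl)
  loci <- make_map(cfg)
  loci <- rbind(loci, data.frame(marker = "q1", chromosome = 1,
                                 pos_cM = 45, pos_bp = 45000001))
  loci <- loci[order(loci$pos_cM), ]
  class(loci) <- c("genetic_map", "data.frame")
  g <- simulate_f2_genotypes(loci, cfg)
  ph <- simulate_f23_phenotypes(g, qtl, cfg)
  fm <- family_means(ph, "E1")
  expect_setequal(round(unique(fm), 10), c(1.4, -1.4, 0.3))
  gq <- unclass(g)[, "q1"]
  expect_equal(unname(fm[gq == 3]), rep(1.4, sum(gq == 3)))
  expect_equal(unname(fm[gq == 2]), rep(0.3, sum(gq == 2)))
  # all-zero architecture: phenotype variance is residual-only
  cfg0 <- sim_config(seed = 5, n_f2 = 300, n_chromosomes = 1,
                     markers_per_chromosome = 5, chromosome_lengths = 50,
                     environments = "E1", env_means = NULL,
                     residual_sd = 1, gxe_sd = 0, qtl_architecture = NULL)
  g0 <- simulate_f2_genotypes(make_map(cfg0), cfg0)
  ph0 <- simulate_f23_phenotypes(g0, NULL, cfg0)
  expect_lt(abs(stats::var(ph0$value) - 1), 0.15)
})

test_that("phenotype simulation rejects off-map QTLs", {
  cfg <- tiny_config(seed = 6)
  g <- simulate_f2_genotypes(make_map(cfg), cfg)
  bad <- data.frame(qtl = "qX", chromosome = 1, pos_cM = 33.33,
                    environment = "3cm", a = 1, d = 0)
  expect_error(simulate_f23_phenotypes(g, bad, cfg), "not on the genotyped")
})

test_that("pool read simulation matches its sampling model", {
  cfg <- sim_config(seed = 8, n_f2 = 60, n_chromosomes = 1,
                    markers_per_chromosome = 2, chromosome_lengths = 10,
                    sequencing_error = 0, qtl_architecture = NULL)
  # 1000 unlinked sites: huge inter-site distances
  loci <- data.frame(marker = sprintf("s%04d", 1:1000), chromosome = 1,
                     pos_cM = seq(0, by = 1e4, length.out = 1000),
                     pos_bp = seq_len(1000) * 1000,
                     ref = "A", alt = "T", vclass = "SNP")
  class(loci) <- c("genetic_map", "data.frame")
  g <- simulate_f2_genotypes(loci, cfg)
  pools <- simulate_pool_reads(g, 1:30, 31:60, loci, cfg)
  # parents are error-free homozygotes
  expect_true(all(pools$p1_alt == 0))
  expect_true(all(pools$p2_ref == 0))
  idx <- index_track(pools, index_parent = "parent2")
  expect_true(all(idx$index_lm >= 0 & idx$index_lm <= 1, na.rm = TRUE))
  # unlinked, unselected sites: mean index near 1/2 in both pools
  expect_lt(abs(mean(idx$index_lm, na.rm = TRUE) - 0.5), 0.02)
  expect_lt(abs(mean(idx$index_sm, na.rm = TRUE) - 0.5), 0.02)
  # monomorphic site: force all members AA -> zero alternate reads
  g2 <- unclass(g)
  g2[, 1] <- 1L
  attr(g2, "map") <- loci; class(g2) <- "f2_geno"
  pools2 <- simulate_pool_reads(g2, 1:30, 31:60, loci[1, ], cfg)
  expect_equal(pools2$lm_alt, 0)
  expect_equal(pools2$sm_alt, 0)
  expect_error(simulate_pool_reads(g, integer(0), 31:60, loci, cfg),
               "non-empty")
  expect_error(simulate_pool_reads(g, 1:30, 30:60, loci, cfg), "disjoint")
})

test_that("scenario_study writes a complete, reproducible bundle", {
  cfg <- sim_config(seed = 21, n_f2 = 80, n_chromosomes = 2,
                    markers_per_chromosome = 6,
                    chromosome_lengths = c(60, 50), replicates = 4,
                    bulk_size = 10, site_spacing_cM = 2,
                    qtl_architecture = NULL)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- scenario_study(cfg, d1)
  r2 <- scenario_study(cfg, d2)
  expect_true(all(file.exists(unlist(r1$paths))))
  expect_equal(nrow(r1$phenotypes), 80 * 3 * 4)
  expect_length(intersect(r1$truth$bulk_high, r1$truth$bulk_low), 0)
  expect_length(r1$truth$bulk_high, 10)
  for (f in c("map", "genotypes", "phenotypes", "truth"))
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
  expect_identical(read_vcf_pools(r1$paths$vcf), read_vcf_pools(r2$paths$vcf))
})
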