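test_that("extreme-bulk selection is deterministic and disjoint", {
  means <- stats::setNames(c(5, 1, 9, 3, 7, 2), sprintf("F%d", 1:6))
  b <- select_extreme_bulks(means, k = 2)
  expect_equal(b$high, c("F3", "F5"))
  expect_equal(b$low, c("F2", "F6"))
  b1 <- select_extreme_bulks(means, k = 1)
  expect_equal(b1$high, "F3"); expect_equal(b1$low, "F2")
  expect_error(select_extreme_bulks(means, k = 4), "exceeds")
  # ties break by family id, with a warning when everything ties
  expect_warning(bt <- select_extreme_bulks(
    stats::setNames(rep(1, 6), sprintf("F%d", 1:6)), k = 2), "id order")
  expect_equal(bt$low, c("F1", "F2"))
  expect_length(intersect(bt$high, bt$low), 0)
})

test_that("informative-site filtering keeps exact bookkeeping", {
  good <- make_sites(800)
  het_parent <- make_sites(100, p1_gt = "0/1")
  low_depth <- make_sites(100, lm_ref = 4, lm_alt = 5)   # depth 9 < 10
  panel <- rbind(good, het_parent, low_depth)
  kept <- filter_informative_sites(panel, min_depth = 10)
  expect_equal(nrow(kept), 800)
  expect_equal(unname(attr(kept, "removed")["parent"]), 100)
  expect_equal(unname(attr(kept, "removed")["depth"]), 100)
  # same-allele homozygous parents are uninformative too
  same <- make_sites(5, p1_gt = "1/1", p2_gt = "1/1")
  expect_equal(nrow(filter_informative_sites(same)), 0)
})

test_that("pool indices are depth ratios with masking, delta their difference", {
  s <- make_sites(3, lm_ref = c(21, 0, 40), lm_alt = c(21, 30, 0),
                  sm_ref = c(10, 0, 0), sm_alt = c(30, 0, 25))
  idx1 <- compute_index(s, "LM", "parent1")     # parent1 carries ref
  expect_equal(idx1, c(0.5, 0, 1))
  idx2 <- compute_index(s, "SM", "parent1")
  expect_equal(idx2, c(0.25, NA, 0))            # zero depth masked
  tr <- index_track(s)
  expect_equal(tr$delta, c(0.25, NA, 1))
  expect_true(all(abs(tr$delta) <= 1, na.rm = TRUE))
  # orientation flip mirrors the index
  expect_equal(compute_index(s, "LM", "parent2"), 1 - idx1)
  # parent pools at error-free informative sites are exactly 0/1
  expect_equal(compute_index(s, "P1", "parent1"), rep(1, 3))
  expect_equal(compute_index(s, "P2", "parent1"), rep(0, 3))
})

test_that("sliding windows equal a site-by-site brute force", {
  set.seed(14)
  n <- 400
  s <- make_sites(n, pos_bp = sort(sample(1:5e6, n)),
                  lm_ref = rbinom(n, 40, 0.5), lm_alt = rbinom(n, 40, 0.5),
                  sm_ref = rbinom(n, 40, 0.5), sm_alt = rbinom(n, 40, 0.5))
  tr <- index_track(s)
  win <- sliding_window(tr, window_bp = 1e6, step_bp = 25e4, min_sites = 5)
  for (w in seq_len(nrow(win))) {
    inw <- tr$pos_bp >= win$start_bp[w] &
      tr$pos_bp < win$start_bp[w] + 1e6 & !is.na(tr$delta)
    if (sum(inw) >= 5) {
      expect_equal(win$delta[w], mean(tr$delta[inw]))
      expect_equal(win$index_lm[w], mean(tr$index_lm[inw]))
    } else {
      expect_true(is.na(win$delta[w]))
    }
  }
  # constant track: every unmasked window mean equals the constant
  s2 <- make_sites(50, pos_bp = (1:50) * 1e4,
                   lm_ref = 30, lm_alt = 10, sm_ref = 10, sm_alt = 30)
  w2 <- sliding_window(index_track(s2), 1e5, 5e4, min_sites = 1)
  expect_true(all(abs(w2$delta[!is.na(w2$delta)] - 0.5) < 1e-12))
  expect_error(sliding_window(tr, 1e5, 2e5), "window_bp >= step_bp")
})

test_that("the simulated null band is symmetric and narrows with depth", {
  ci <- simulate_null_ci(bulk_size = 30, depths = c(10, 45, 100, 200),
                         n_sim = 5000, seed = 3)
  expect_equal(nrow(ci), 4)
  # symmetry of the two tails
  expect_lt(max(abs(ci$ci_low + ci$ci_high)), 0.03)
  width <- ci$ci_high - ci$ci_low
  expect_true(all(diff(width) < 0))     # monotone narrowing
  # interpolation is exact at grid points and monotone between
  ib <- interpolate_ci(ci, c(10, 27.5, 45))
  expect_equal(ib$ci_high[1], ci$ci_high[1])
  expect_true(ib$ci_high[2] <= ci$ci_high[1] &&
                ib$ci_high[2] >= ci$ci_high[2])
  expect_error(simulate_null_ci(level = 1.5), "level")
  expect_error(simulate_null_ci(n_sim = 10), "at least 1000")
  expect_error(simulate_null_ci(population = "RIL"), "F2")
})

test_that("region calling merges by gap and clips to supporting sites", {
  win <- data.frame(chromosome = 1,
                    start_bp = seq(1, by = 2e5, length.out = 10),
                    end_bp = seq(1, by = 2e5, length.out = 10) + 2e5 - 1,
                    n_sites = 20, index_lm = 0.5, index_sm = 0.5,
                    delta = c(0.5, 0.5, 0.05, 0.5, rep(0.02, 6)),
                    ci_low = -0.3, ci_high = 0.3)
  class(win) <- c("window_track", "data.frame")
  r0 <- call_linked_regions(win, merge_gap_bp = 0)
  expect_equal(nrow(r0), 2)
  r1 <- call_linked_regions(win, merge_gap_bp = 2e5)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start_bp, 1)
  expect_equal(r1$end_bp, 4 * 2e5)
  # no significant window -> empty result
  win$delta <- 0
  expect_equal(nrow(call_linked_regions(win)), 0)
  # negative delta is significant two-sided but not one-sided
  win$delta <- c(-0.5, rep(0, 9))
  expect_equal(nrow(call_linked_regions(win, sides = "two")), 1)
  expect_equal(nrow(call_linked_regions(win, sides = "one")), 0)
})

test_that("a selected locus produces a called region over the truth", {
  # one chromosome; bulks truly divergent at 50 cM (= 50 Mb hereabouts)
  qtl <- data.frame(qtl = "qB", chromosome = 1, pos_cM = 50,
                    environment = "20cm", a = -2, d = 0)
  cfg <- sim_config(seed = 41, n_f2 = 200, n_chromosomes = 1,
                    markers_per_chromosome = 11, chromosome_lengths = 100,
                    environments = "20cm", env_means = c("20cm" = 13),
                    residual_sd = 2, gxe_sd = 0, bulk_size = 30,
                    site_spacing_cM = 0.1, qtl_architecture = qtl)
  st <- scenario_study(cfg)
  tr <- site_ci(index_track(filter_informative_sites(st$pools)),
                simulate_null_ci(bulk_size = 30, n_sim = 5000, seed = 2))
  win <- sliding_window(tr)
  regs <- call_linked_regions(win, tr)
  expect_gt(nrow(regs), 0)
  hit <- regs$start_bp <= 50e6 & regs$end_bp >= 50e6
  expect_true(any(hit))
  # the peak window sits near the selected locus and is positive (LM bulk
  # enriched for the tolerant allele)
  expect_gt(max(win$delta, na.rm = TRUE), 0.3)
})
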