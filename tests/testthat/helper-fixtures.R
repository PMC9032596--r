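# small study configurations shared across test files

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_f2 = 100, n_chromosomes = 2,
             markers_per_chromosome = 8, chromosome_lengths = c(90, 70),
             qtl_architecture = NULL, site_spacing_cM = 2, ...)
}

# one-QTL single-environment design used for scan tests; residual sd set so
# the locus explains about 14% of family-mean variance (a^2/2 against
# sigma^2 / r)
one_qtl_config <- function(seed, a = -1.25, d = -0.18, pos = 88.2,
                           chromosome = 4, n_f2 = 346,
                           residual_sd = 6.94) {
  qtl <- data.frame(qtl = "qTrue", chromosome = chromosome, pos_cM = pos,
                    environment = "20cm", a = a, d = d,
                    stringsAsFactors = FALSE)
  sim_config(seed = seed, n_f2 = n_f2, environments = "20cm",
             env_means = c("20cm" = 13.09), residual_sd = residual_sd,
             gxe_sd = 0, qtl_architecture = qtl)
}

# genotypes over the marker map plus the true QTL locus, simulated jointly
simulate_one_qtl_study <- function(cfg) {
  map <- make_map(cfg)
  qtl <- cfg$qtl_architecture
  loci <- rbind(map, data.frame(marker = qtl$qtl[1],
                                chromosome = qtl$chromosome[1],
                                pos_cM = qtl$pos_cM[1],
                                pos_bp = mesoqtl:::cM_to_bp(qtl$pos_cM[1])))
  loci <- loci[order(loci$chromosome, loci$pos_cM), ]
  class(loci) <- c("genetic_map", "data.frame")
  g_all <- simulate_f2_genotypes(loci, cfg)
  ph <- simulate_f23_phenotypes(g_all, qtl, cfg, seed = NULL)
  g <- g_all[, map$marker, drop = FALSE]
  attr(g, "map") <- map
  class(g) <- "f2_geno"
  list(map = map, genotypes = g, phenotypes = ph,
       truth_pos = qtl$pos_cM[1], truth_chr = qtl$chromosome[1])
}

# balanced family x environment x replicate table from given variance
# components (family, GxE and residual effects all normal)
simulate_vc_table <- function(n_fam = 200, n_env = 3, n_rep = 10,
                              sigma_g2 = 4, sigma_ge2 = 3, sigma_eps2 = 2) {
  fam <- sprintf("F%03d", seq_len(n_fam))
  env <- paste0("E", seq_len(n_env))
  gf <- stats::rnorm(n_fam, 0, sqrt(sigma_g2))
  ge <- matrix(stats::rnorm(n_fam * n_env, 0, sqrt(sigma_ge2)),
               n_fam, n_env)
  out <- expand.grid(replicate = seq_len(n_rep), family = fam,
                     environment = env, stringsAsFactors = FALSE)
  fi <- match(out$family, fam)
  ei <- match(out$environment, env)
  out$value <- gf[fi] + ge[cbind(fi, ei)] +
    stats::rnorm(nrow(out), 0, sqrt(sigma_eps2))
  out[, c("family", "environment", "replicate", "value")]
}

# minimal pool_sites row constructor for hand-built fixtures
make_sites <- function(n, chromosome = 1, pos_bp = NULL,
                       p1_gt = "0/0", p2_gt = "1/1",
                       lm_ref = 20, lm_alt = 20, sm_ref = 20, sm_alt = 20,
                       vclass = "SNP") {
  out <- data.frame(
    site = sprintf("s%04d", seq_len(n)),
    chromosome = rep_len(chromosome, n),
    pos_bp = if (is.null(pos_bp)) seq_len(n) * 1000 else pos_bp,
    ref = "A", alt = "T", vclass = rep_len(vclass, n),
    p1_gt = rep_len(p1_gt, n), p2_gt = rep_len(p2_gt, n),
    p1_ref = 30, p1_alt = 0, p2_ref = 0, p2_alt = 30,
    lm_ref = rep_len(lm_ref, n), lm_alt = rep_len(lm_alt, n),
    sm_ref = rep_len(sm_ref, n), sm_alt = rep_len(sm_alt, n),
    stringsAsFactors = FALSE)
  class(out) <- c("pool_sites", "data.frame")
  out
}
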