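#' Simulation configuration for a deep-sowing mapping study
#'
#' Bundles every parameter of the synthetic study generator: the biparental
#' cross (two inbred parents, an F2 of `n_f2` plants, selfed once to F2:3
#' families), the genetic map scaffold, the multi-environment phenotype
#' model, and the pooled-sequencing layer used for bulked-segregant analysis.
#'
#' Defaults reproduce the dimensions of a typical maize deep-sowing trial:
#' 346 F2 plants genotyped at 260 markers on 10 chromosomes spanning
#' 1410.6 cM (mean marker interval 5.64 cM within chromosomes), F2:3
#' phenotypes scored in three sowing-depth environments with 10 replicates,
#' extreme bulks of 30 + 30 plants, and pool coverage of about 45 reads per
#' site.
#'
#' @param seed Integer seed; fixing it makes every generator output
#'   reproducible.
#' @param n_f2 Number of F2 individuals.
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Integer vector (recycled) of marker counts
#'   per chromosome.
#' @param chromosome_lengths Numeric vector of chromosome lengths in cM.
#' @param environments Character vector of environment labels.
#' @param env_means Named numeric vector of environment mean trait values
#'   (cm). Unnamed environments default to 0.
#' @param replicates Replicates per family and environment.
#' @param qtl_architecture Data frame of true QTL effects with columns
#'   `qtl`, `chromosome`, `pos_cM`, `environment`, `a`, `d`. Positive `a`
#'   means the second parent's allele increases the trait (the convention of
#'   maize QTL tables where the tolerant first parent has negative `a`).
#'   Defaults to [mes_qtl_architecture()].
#' @param residual_sd Within-family residual standard deviation (trait
#'   units), recycled across environments.
#' @param gxe_sd Standard deviation of family-by-environment interaction
#'   deviations.
#' @param bulk_size Number of F2 plants per extreme bulk.
#' @param coverage_mean Mean sequencing depth per pool and site (Poisson).
#' @param sequencing_error Probability that a read reports the wrong allele
#'   (symmetric flip).
#' @param map_function `"haldane"` (default) or `"kosambi"`, used both to
#'   simulate recombination and downstream for genotype probabilities.
#' @param mb_per_cM Linear cM-to-bp scaling used to assign physical
#'   positions (default 1 cM = 1 Mb).
#' @param site_spacing_cM Spacing of simulated variant sites along the map.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [make_map()], [simulate_f2_genotypes()], [scenario_study()]
#' @export
sim_config <- function(seed = 1L,
                       n_f2 = 346L,
                       n_chromosomes = 10L,
                       markers_per_chromosome = 26L,
                       chromosome_lengths = c(200, 170, 160, 150, 140,
                                              130, 130, 120, 110, 100.6),
                       environments = c("3cm", "15cm", "20cm"),
                       env_means = c("3cm" = 3.74, "15cm" = 10.95,
                                     "20cm" = 13.09),
                       replicates = 10L,
                       qtl_architecture = mes_qtl_architecture(),
                       residual_sd = c(0.6, 2.0, 3.0),
                       gxe_sd = 0.8,
                       bulk_size = 30L,
                       coverage_mean = 45,
                       sequencing_error = 0.001,
                       map_function = c("haldane", "kosambi"),
                       mb_per_cM = 1,
                       site_spacing_cM = 0.1) {
  map_function <- match.arg(map_function)
  markers_per_chromosome <- rep_len(as.integer(markers_per_chromosome),
                                    n_chromosomes)
  chromosome_lengths <- rep_len(as.numeric(chromosome_lengths),
                                n_chromosomes)
  residual_sd <- rep_len(as.numeric(residual_sd), length(environments))
  names(residual_sd) <- environments
  em <- rep(0, length(environments))
  names(em) <- environments
  if (!is.null(env_means)) {
    known <- intersect(names(env_means), environments)
    em[known] <- env_means[known]
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_f2 = as.integer(n_f2),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = markers_per_chromosome,
    chromosome_lengths = chromosome_lengths,
    environments = environments, env_means = em,
    replicates = as.integer(replicates),
    qtl_architecture = qtl_architecture,
    residual_sd = residual_sd, gxe_sd = as.numeric(gxe_sd),
    bulk_size = as.integer(bulk_size),
    coverage_mean = as.numeric(coverage_mean),
    sequencing_error = as.numeric(sequencing_error),
    map_function = map_function, mb_per_cM = as.numeric(mb_per_cM),
    site_spacing_cM = as.numeric(site_spacing_cM)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_f2 < 1L || cfg$n_chromosomes < 1L || cfg$replicates < 1L ||
      cfg$bulk_size < 1L)
    stop("all counts in a sim_config must be >= 1", call. = FALSE)
  if (any(cfg$markers_per_chromosome < 2L))
    stop("each chromosome needs at least 2 markers", call. = FALSE)
  if (any(!is.finite(cfg$chromosome_lengths)) ||
      any(cfg$chromosome_lengths <= 0))
    stop("invalid config: zero or negative chromosome length", call. = FALSE)
  if (cfg$sequencing_error < 0 || cfg$sequencing_error > 1)
    stop("sequencing_error must lie in [0, 1]", call. = FALSE)
  if (any(cfg$residual_sd < 0) || cfg$gxe_sd < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  if (cfg$coverage_mean <= 0)
    stop("coverage_mean must be positive", call. = FALSE)
  qa <- cfg$qtl_architecture
  if (!is.null(qa) && nrow(qa) > 0) {
    need <- c("qtl", "chromosome", "pos_cM", "environment", "a", "d")
    if (!all(need %in% names(qa)))
      stop("qtl_architecture needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    if (any(qa$chromosome < 1 | qa$chromosome > cfg$n_chromosomes))
      stop("QTL chromosome outside the configured genome", call. = FALSE)
    off <- qa$pos_cM > cfg$chromosome_lengths[qa$chromosome] | qa$pos_cM < 0
    if (any(off))
      stop("QTL position outside its chromosome: ",
           paste(unique(qa$qtl[off]), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Map-function recombination fraction
#'
#' Converts a map distance in cM to a recombination fraction under the
#' Haldane (no interference) or Kosambi map function.
#'
#' @param d_cM Numeric vector of distances in cM.
#' @param method `"haldane"` or `"kosambi"`.
#' @return Recombination fractions in \[0, 0.5\].
#' @export
recombination_fraction <- function(d_cM, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  d <- d_cM / 100
  switch(method,
         haldane = 0.5 * (1 - exp(-2 * d)),
         kosambi = 0.5 * tanh(2 * d))
}

#' Build the genetic map scaffold
#'
#' Places markers evenly along each chromosome and assigns deterministic
#' physical positions by a fixed linear cM-to-bp scaling.
#'
#' @param config A [sim_config()].
#' @return A `genetic_map`: data frame with columns `marker`, `chromosome`,
#'   `pos_cM`, `pos_bp`, cM strictly increasing within chromosomes.
#' @examples
#' map <- make_map(sim_config())
#' nrow(map)           # 260 markers
#' @export
make_map <- function(config) {
  validate_sim_config(config)
  rows <- lapply(seq_len(config$n_chromosomes), function(chr) {
    m <- config$markers_per_chromosome[chr]
    L <- config$chromosome_lengths[chr]
    pos <- seq(0, L, length.out = m)
    data.frame(
      marker = sprintf("c%d_m%02d", chr, seq_len(m)),
      chromosome = chr,
      pos_cM = pos,
      pos_bp = cM_to_bp(pos, config$mb_per_cM),
      stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

cM_to_bp <- function(pos_cM, mb_per_cM = 1) {
  as.integer(round(pos_cM * mb_per_cM * 1e6)) + 1L
}

#' Simulate variant-site positions along the genome
#'
#' Generates a dense panel of biallelic variant sites (SNPs and small
#' InDels) evenly spaced along each chromosome, with physical positions from
#' the same cM-to-bp scaling as the marker map. Parents are fixed for
#' opposite alleles at every site (only such sites are informative for
#' bulked-segregant mapping).
#'
#' @param config A [sim_config()].
#' @param snp_fraction Fraction of sites that are SNPs (the rest are
#'   InDels).
#' @return A `genetic_map`-like data frame with additional columns `ref`,
#'   `alt`, `vclass`.
#' @export
make_variant_sites <- function(config, snp_fraction = 0.85) {
  validate_sim_config(config)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(config$n_chromosomes), function(chr) {
    L <- config$chromosome_lengths[chr]
    pos <- seq(config$site_spacing_cM / 2, L, by = config$site_spacing_cM)
    n <- length(pos)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    is_snp <- stats::runif(n) < snp_fraction
    ins <- vapply(seq_len(n), function(i)
      paste0(ref[i], paste(sample(bases, 1 + sample(3, 1), TRUE),
                           collapse = "")), "")
    data.frame(
      marker = sprintf("s%d_%05d", chr, seq_len(n)),
      chromosome = chr,
      pos_cM = pos,
      pos_bp = cM_to_bp(pos, config$mb_per_cM),
      ref = ref,
      alt = ifelse(is_snp, alt, ins),
      vclass = ifelse(is_snp, "SNP", "InDel"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate F2 genotypes along a map
#'
#' Each F2 individual is formed from two independent gametes. A gamete is a
#' Markov walk along each chromosome: the allele at the first locus is drawn
#' at random and crossovers occur between adjacent loci with the
#' recombination fraction implied by the configured map function (Haldane by
#' default, so no crossover interference).
#'
#' @param map A `genetic_map` (any locus density; columns `marker`,
#'   `chromosome`, `pos_cM`).
#' @param config A [sim_config()] supplying `n_f2` and `map_function`.
#' @param seed Optional seed (defaults to the config seed; pass `NULL` to
#'   use the current RNG state).
#' @return An `f2_geno` integer matrix (individuals x loci) with codes
#'   1 = AA (first-parent homozygote), 2 = AB, 3 = BB, and the map stored in
#'   `attr(, "map")`.
#' @export
simulate_f2_genotypes <- function(map, config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_f2
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(sprintf("F%03d", seq_len(n)), map$marker))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$pos_cM[idx]
    if (is.unsorted(pos)) stop("map positions must be ordered within ",
                               "chromosomes", call. = FALSE)
    r <- recombination_fraction(diff(pos), config$map_function)
    g1 <- simulate_gamete(n, r)
    g2 <- simulate_gamete(n, r)
    geno[, idx] <- g1 + g2 + 1L
  }
  structure(geno, map = map, class = "f2_geno")
}

# one gamete per row; alleles 0 (parent 1) / 1 (parent 2)
simulate_gamete <- function(n, r) {
  m <- length(r) + 1L
  a <- matrix(0L, n, m)
  a[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (j in seq_along(r)) {
    flip <- stats::rbinom(n, 1L, r[j])
    a[, j + 1L] <- ifelse(flip == 1L, 1L - a[, j], a[, j])
  }
  a
}

#' Simulate F2:3 family phenotypes in multiple environments
#'
#' The genetic value of an F2:3 family is the expectation over one selfing
#' generation of its F2 parent's genotype at each true QTL: `BB` (second
#' parent homozygote) contributes `+a`, `AA` contributes `-a`, and a
#' heterozygous parent contributes `d/2` because selfing halves the
#' heterozygote dominance deviation. Observed values add an environment main
#' effect, an independent normal family-by-environment deviation, and
#' replicate-level residual noise.
#'
#' @param genos An `f2_geno` matrix containing a column for every QTL locus.
#' @param qtl QTL architecture data frame (`qtl`, `chromosome`, `pos_cM`,
#'   `environment`, `a`, `d`); defaults to the architecture in `config`.
#' @param config A [sim_config()].
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A `phenotype_table` data frame (`family`, `environment`,
#'   `replicate`, `value`) with the per-family genetic values per
#'   environment stored in `attr(, "genetic_values")`.
#' @export
simulate_f23_phenotypes <- function(genos, qtl = config$qtl_architecture,
                                    config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- attr(genos, "map")
  n <- nrow(genos)
  envs <- config$environments
  gv <- matrix(0, n, length(envs), dimnames = list(rownames(genos), envs))
  if (!is.null(qtl) && nrow(qtl) > 0) {
    for (q in unique(qtl$qtl)) {
      qrows <- qtl[qtl$qtl == q, ]
      hit <- which(map$chromosome == qrows$chromosome[1] &
                     abs(map$pos_cM - qrows$pos_cM[1]) < 1e-6)
      if (length(hit) == 0)
        stop("QTL ", q, " is not on the genotyped map", call. = FALSE)
      g <- genos[, hit[1]]
      for (k in seq_len(nrow(qrows))) {
        e <- qrows$environment[k]
        if (!e %in% envs) next
        gv[, e] <- gv[, e] +
          ifelse(g == 3L, qrows$a[k],
                 ifelse(g == 1L, -qrows$a[k], qrows$d[k] / 2))
      }
    }
  }
  r <- config$replicates
  ge <- matrix(stats::rnorm(n * length(envs), 0, config$gxe_sd),
               n, length(envs))
  out <- vector("list", length(envs))
  for (j in seq_along(envs)) {
    e <- envs[j]
    mu <- config$env_means[[e]] + gv[, j] + ge[, j]
    vals <- rep(mu, each = r) +
      stats::rnorm(n * r, 0, config$residual_sd[[e]])
    out[[j]] <- data.frame(
      family = rep(rownames(genos), each = r),
      environment = e,
      replicate = rep(seq_len(r), times = n),
      value = vals,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "genetic_values") <- gv
  class(res) <- c("phenotype_table", "data.frame")
  res
}

#' Simulate pooled sequencing reads over two bulks and the parents
#'
#' For every variant site the alternate (second-parent) allele frequency of
#' a bulk is `(2 n_BB + n_AB) / (2 k)` over its `k` member F2 plants. Total
#' depth per pool and site is Poisson with the configured mean coverage;
#' alternate read counts are binomial at the bulk allele frequency after a
#' symmetric sequencing-error flip. Parent pools are homozygous (allele
#' frequency 0 or 1 before error).
#'
#' @param genos `f2_geno` matrix containing a column for every site.
#' @param lm_members,sm_members Character or integer indices of the bulk
#'   members (rows of `genos`); must be non-empty and disjoint.
#' @param sites Variant site table from [make_variant_sites()] (or any data
#'   frame with `marker`, `chromosome`, `pos_bp`, `ref`, `alt`, `vclass`).
#' @param config A [sim_config()].
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return A `pool_sites` data frame with ref/alt depths for the four
#'   samples (`p1`, `p2`, `lm`, `sm`) and parent genotypes `0/0` / `1/1`.
#' @export
simulate_pool_reads <- function(genos, lm_members, sm_members, sites,
                                config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(lm_members) == 0 || length(sm_members) == 0)
    stop("bulk member sets must be non-empty", call. = FALSE)
  G <- unclass(genos)
  if (is.numeric(lm_members)) lm_members <- rownames(G)[lm_members]
  if (is.numeric(sm_members)) sm_members <- rownames(G)[sm_members]
  if (length(intersect(lm_members, sm_members)) > 0)
    stop("bulk member sets must be disjoint", call. = FALSE)
  miss <- setdiff(sites$marker, colnames(G))
  if (length(miss) > 0)
    stop("sites absent from the genotype matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  Glm <- G[lm_members, sites$marker, drop = FALSE]
  Gsm <- G[sm_members, sites$marker, drop = FALSE]
  p_lm <- colSums(Glm - 1L) / (2 * nrow(Glm))
  p_sm <- colSums(Gsm - 1L) / (2 * nrow(Gsm))
  e <- config$sequencing_error
  flip <- function(p) p * (1 - e) + (1 - p) * e
  ns <- nrow(sites)
  draw <- function(p) {
    depth <- stats::rpois(ns, config$coverage_mean)
    alt <- stats::rbinom(ns, depth, flip(p))
    list(ref = depth - alt, alt = alt)
  }
  lm <- draw(p_lm); sm <- draw(p_sm)
  p1 <- draw(rep(0, ns)); p2 <- draw(rep(1, ns))
  out <- data.frame(
    site = sites$marker, chromosome = sites$chromosome,
    pos_bp = sites$pos_bp, ref = sites$ref, alt = sites$alt,
    vclass = sites$vclass, p1_gt = "0/0", p2_gt = "1/1",
    p1_ref = p1$ref, p1_alt = p1$alt, p2_ref = p2$ref, p2_alt = p2$alt,
    lm_ref = lm$ref, lm_alt = lm$alt, sm_ref = sm$ref, sm_alt = sm$alt,
    stringsAsFactors = FALSE)
  class(out) <- c("pool_sites", "data.frame")
  out
}

#' Simulate a complete deep-sowing mapping study
#'
#' Runs the whole generator end to end under one seed: marker map, dense
#' variant sites, F2 genotypes (markers, sites, and true QTL simulated as
#' one linked process), F2:3 phenotypes in every environment, extreme-bulk
#' selection on family means in the bulking environment, and pooled reads
#' for the two bulks and parents. All stage inputs are written to `dir` in
#' their interchange formats (TSV, VCF, JSON).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param bulk_environment Environment whose family means rank the bulks
#'   (default: last configured environment, the deepest sowing).
#' @return Invisibly, a list with `config`, `map`, `genotypes` (markers
#'   only), `phenotypes`, `pools`, `truth` (true QTL genotypes, genetic
#'   values, bulk members), and `paths`.
#' @export
scenario_study <- function(config = sim_config(), dir = NULL,
                           bulk_environment = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  if (is.null(bulk_environment))
    bulk_environment <- config$environments[length(config$environments)]
  map <- make_map(config)
  sites <- make_variant_sites(config)
  qa <- config$qtl_architecture
  loci <- rbind(map[, c("marker", "chromosome", "pos_cM", "pos_bp")],
                sites[, c("marker", "chromosome", "pos_cM", "pos_bp")])
  if (!is.null(qa) && nrow(qa) > 0) {
    qp <- unique(qa[, c("qtl", "chromosome", "pos_cM")])
    loci <- rbind(loci, data.frame(
      marker = qp$qtl, chromosome = qp$chromosome, pos_cM = qp$pos_cM,
      pos_bp = cM_to_bp(qp$pos_cM, config$mb_per_cM)))
  }
  # ties in position are fine: r = 0 between co-located loci keeps the
  # gamete walk consistent
  loci <- loci[order(loci$chromosome, loci$pos_cM, loci$marker), ]
  rownames(loci) <- NULL
  class(loci) <- c("genetic_map", "data.frame")
  genos_all <- simulate_f2_genotypes(loci, config, seed = NULL)
  phenos <- simulate_f23_phenotypes(genos_all, qa, config, seed = NULL)
  fam_means <- family_means(phenos, bulk_environment)
  bulks <- select_extreme_bulks(fam_means, k = config$bulk_size)
  pools <- simulate_pool_reads(genos_all, bulks$high, bulks$low, sites,
                               config, seed = NULL)
  genos <- genos_all[, map$marker, drop = FALSE]
  attr(genos, "map") <- map
  class(genos) <- "f2_geno"
  qtl_geno <- NULL
  if (!is.null(qa) && nrow(qa) > 0) {
    qn <- intersect(unique(qa$qtl), colnames(genos_all))
    qtl_geno <- unclass(genos_all)[, qn, drop = FALSE]
  }
  truth <- list(config = config[setdiff(names(config), "qtl_architecture")],
                qtl_architecture = qa,
                qtl_genotypes = qtl_geno,
                genetic_values = attr(phenos, "genetic_values"),
                bulk_high = bulks$high, bulk_low = bulks$low,
                bulk_environment = bulk_environment)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory ", dir, call. = FALSE)
    paths <- list(map = file.path(dir, "map.tsv"),
                  genotypes = file.path(dir, "genotypes.tsv"),
                  phenotypes = file.path(dir, "phenotypes.tsv"),
                  vcf = file.path(dir, "pools.vcf.gz"),
                  truth = file.path(dir, "truth.json"))
    write_genetic_map(map, paths$map)
    write_genotypes(genos, paths$genotypes)
    write_phenotypes(phenos, paths$phenotypes)
    write_pool_vcf(pools, paths$vcf)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(list(config = config, map = map, genotypes = genos,
                 phenotypes = phenos, sites = sites, pools = pools,
                 truth = truth, paths = paths))
}

#' Per-family trait means in one environment
#'
#' @param phenos A `phenotype_table`.
#' @param environment Environment label to average within (default: all
#'   pooled).
#' @return Named numeric vector of family means, in family order of first
#'   appearance.
#' @export
family_means <- function(phenos, environment = NULL) {
  if (!is.null(environment)) {
    if (!all(environment %in% phenos$environment))
      stop("unknown environment: ",
           paste(setdiff(environment, phenos$environment), collapse = ", "),
           call. = FALSE)
    phenos <- phenos[phenos$environment %in% environment, ]
  }
  fams <- unique(phenos$family)
  out <- vapply(split(phenos$value, factor(phenos$family, levels = fams)),
                mean, 0)
  out
}
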