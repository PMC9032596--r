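#' Select extreme-phenotype bulks
#'
#' Picks the `k` families with the largest and the `k` with the smallest
#' trait means. Ties are broken by family id so the selection is
#' deterministic; an all-equal input still yields a valid (id-ordered)
#' selection, with a warning.
#'
#' @param x Either a named numeric vector of family means or a
#'   `phenotype_table` (then `environment` selects the ranking
#'   environment).
#' @param k Bulk size (>= 1).
#' @param environment Environment label used when `x` is a phenotype table.
#' @return A list with `high` and `low`: disjoint character vectors of `k`
#'   family ids each.
#' @export
select_extreme_bulks <- function(x, k = 30, environment = NULL) {
  if (is.data.frame(x)) x <- family_means(x, environment)
  if (is.null(names(x))) stop("family means must be named", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (2 * k > length(x))
    stop("2k exceeds the number of families", call. = FALSE)
  if (length(unique(x)) == 1)
    warning("all family means equal; selection falls back to id order")
  ids <- names(x)
  # one shared ranking keeps the tails disjoint even under heavy ties
  ord <- order(x, ids)
  list(high = ids[rev(ord)[seq_len(k)]], low = ids[ord[seq_len(k)]])
}

#' Keep sites informative for bulked-segregant mapping
#'
#' Retains sites where the two parents are homozygous for different alleles
#' and both offspring pools reach a minimum total depth.
#'
#' @param sites A `pool_sites` data frame (see [simulate_pool_reads()] /
#'   [read_vcf_pools()]).
#' @param min_depth Minimum total depth per offspring pool (default 10).
#' @return The filtered `pool_sites`, with counts of removals by reason in
#'   `attr(, "removed")`.
#' @export
filter_informative_sites <- function(sites, min_depth = 10) {
  hom <- c("0/0", "1/1", "0|0", "1|1")
  ok_parent <- sites$p1_gt %in% hom & sites$p2_gt %in% hom &
    substr(sites$p1_gt, 1, 1) != substr(sites$p2_gt, 1, 1)
  ok_depth <- (sites$lm_ref + sites$lm_alt) >= min_depth &
    (sites$sm_ref + sites$sm_alt) >= min_depth
  out <- sites[ok_parent & ok_depth, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(parent = sum(!ok_parent),
                            depth = sum(ok_parent & !ok_depth))
  out
}

#' Per-site SNP/InDel index of one pool
#'
#' Fraction of a pool's reads carrying the index parent's allele. Sites with
#' zero depth in the pool are masked (`NA`), never reported as 0.
#'
#' @param sites A `pool_sites` data frame.
#' @param pool `"LM"` or `"SM"` (or `"P1"` / `"P2"` for the parent pools).
#' @param index_parent Which parent's allele defines the index (default the
#'   first, deep-sowing tolerant, parent).
#' @return Numeric vector of indices in \[0, 1\] (`NA` where masked).
#' @export
compute_index <- function(sites, pool = c("LM", "SM", "P1", "P2"),
                          index_parent = c("parent1", "parent2")) {
  pool <- match.arg(pool)
  index_parent <- match.arg(index_parent)
  pre <- c(LM = "lm", SM = "sm", P1 = "p1", P2 = "p2")[[pool]]
  ref <- sites[[paste0(pre, "_ref")]]
  alt <- sites[[paste0(pre, "_alt")]]
  tot <- ref + alt
  # which physical allele belongs to the index parent at each site
  p1_ref <- substr(sites$p1_gt, 1, 1) == "0"
  want_ref <- if (index_parent == "parent1") p1_ref else !p1_ref
  idx <- ifelse(want_ref, ref, alt) / tot
  idx[tot == 0] <- NA_real_
  idx
}

#' Per-site index track of both pools and their difference
#'
#' Builds the SNP-index of the LM (high) and SM (low) pools and the
#' delta index `delta = index_LM - index_SM`. Masking (zero depth)
#' propagates to delta.
#'
#' @inheritParams compute_index
#' @return An `index_track` data frame: site coordinates, `vclass`,
#'   per-pool depths, `index_lm`, `index_sm`, `delta`.
#' @export
index_track <- function(sites, index_parent = c("parent1", "parent2")) {
  index_parent <- match.arg(index_parent)
  ilm <- compute_index(sites, "LM", index_parent)
  ism <- compute_index(sites, "SM", index_parent)
  out <- data.frame(
    site = sites$site, chromosome = sites$chromosome,
    pos_bp = sites$pos_bp, vclass = sites$vclass,
    depth_lm = sites$lm_ref + sites$lm_alt,
    depth_sm = sites$sm_ref + sites$sm_alt,
    index_lm = ilm, index_sm = ism,
    delta = delta_index(ilm, ism),
    stringsAsFactors = FALSE)
  class(out) <- c("index_track", "data.frame")
  out
}

#' Delta index of two pools
#'
#' @param index_lm,index_sm Per-site indices (`NA` = masked).
#' @return `index_lm - index_sm`; `NA` where either side is masked.
#' @export
delta_index <- function(index_lm, index_sm) index_lm - index_sm

#' Simulated null confidence band for the delta index
#'
#' Monte-Carlo distribution of the delta index at an unlinked site: each
#' replicate draws two independent bulks of `bulk_size` F2 plants (genotypes
#' 1:2:1, equivalently 2 x `bulk_size` alleles at frequency 1/2), then
#' binomial read counts at the given depth for each bulk, and forms the
#' difference of the two pool indices. The central `level` interval is
#' tabulated on a depth grid; [interpolate_ci()] linearises between grid
#' depths.
#'
#' @param bulk_size Plants per bulk (default 30).
#' @param depths Depth grid (reads per site).
#' @param n_sim Replicates per depth (>= 1000; default 10000).
#' @param level Confidence level in (0.5, 1), default 0.99.
#' @param population Population type of the bulked individuals; only `"F2"`
#'   is implemented.
#' @param seed Optional seed.
#' @return A `delta_ci` data frame: `depth`, `ci_low`, `ci_high`.
#' @export
simulate_null_ci <- function(bulk_size = 30, depths = seq(5, 200, by = 5),
                             n_sim = 10000, level = 0.99,
                             population = "F2", seed = NULL) {
  if (!identical(population, "F2"))
    stop("only the F2 population type is implemented", call. = FALSE)
  if (n_sim < 1000) stop("n_sim must be at least 1000", call. = FALSE)
  if (level <= 0.5 || level >= 1)
    stop("level must lie in (0.5, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(depths, function(dp) {
    p1 <- stats::rbinom(n_sim, 2 * bulk_size, 0.5) / (2 * bulk_size)
    p2 <- stats::rbinom(n_sim, 2 * bulk_size, 0.5) / (2 * bulk_size)
    d <- stats::rbinom(n_sim, dp, p1) / dp -
      stats::rbinom(n_sim, dp, p2) / dp
    q <- stats::quantile(d, probs, type = 7, names = FALSE)
    data.frame(depth = dp, ci_low = q[1], ci_high = q[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "bulk_size") <- bulk_size
  class(out) <- c("delta_ci", "data.frame")
  out
}

#' Interpolate a simulated confidence band at arbitrary depths
#'
#' @param ci A [simulate_null_ci()] table.
#' @param depth Numeric vector of depths (values outside the grid are
#'   clamped to its ends).
#' @return Data frame with `ci_low` and `ci_high` per input depth.
#' @export
interpolate_ci <- function(ci, depth) {
  data.frame(
    ci_low = stats::approx(ci$depth, ci$ci_low, xout = depth,
                           rule = 2)$y,
    ci_high = stats::approx(ci$depth, ci$ci_high, xout = depth,
                            rule = 2)$y)
}

#' Attach the per-site confidence band to an index track
#'
#' Each site's band is the simulated null interval interpolated at the mean
#' of its two pool depths.
#'
#' @param track An [index_track()].
#' @param ci A [simulate_null_ci()] table.
#' @return The track with `ci_low` / `ci_high` columns added.
#' @export
site_ci <- function(track, ci) {
  b <- interpolate_ci(ci, (track$depth_lm + track$depth_sm) / 2)
  track$ci_low <- b$ci_low
  track$ci_high <- b$ci_high
  track
}

#' Sliding-window averages of an index track
#'
#' Tiles each chromosome with windows of `window_bp` starting every
#' `step_bp` from position 1 and averages (unweighted) the per-site indices,
#' delta values, and, if present, confidence bounds of the sites falling in
#' `[start, start + window_bp)`. Windows with fewer than `min_sites`
#' unmasked sites are masked.
#'
#' @param track An [index_track()] (optionally with a band from
#'   [site_ci()]).
#' @param window_bp Window size in bp (default 1 Mb).
#' @param step_bp Step between window starts (default 200 kb); must satisfy
#'   `window_bp >= step_bp > 0`.
#' @param min_sites Minimum unmasked sites per window (default 10).
#' @return A `window_track` data frame: `chromosome`, `start_bp`, `end_bp`
#'   (inclusive), `n_sites`, `index_lm`, `index_sm`, `delta`, and band
#'   columns when available; masked windows carry `NA` means.
#' @export
sliding_window <- function(track, window_bp = 1e6, step_bp = 2e5,
                           min_sites = 10) {
  if (step_bp <= 0 || window_bp < step_bp)
    stop("need window_bp >= step_bp > 0", call. = FALSE)
  has_ci <- all(c("ci_low", "ci_high") %in% names(track))
  rows <- lapply(unique(track$chromosome), function(chr) {
    tc <- track[track$chromosome == chr & !is.na(track$delta), ]
    tc <- tc[order(tc$pos_bp), ]
    maxp <- max(track$pos_bp[track$chromosome == chr])
    starts <- seq(1, maxp, by = step_bp)
    res <- data.frame(chromosome = chr, start_bp = starts,
                      end_bp = pmin(starts + window_bp - 1, maxp))
    # member sites per window as contiguous ranges over the
    # position-sorted track, so each mean is an exact plain mean
    lo <- findInterval(starts - 0.5, tc$pos_bp) + 1L
    hi <- findInterval(starts + window_bp - 0.5, tc$pos_bp)
    cnt <- pmax(hi - lo + 1L, 0L)
    res$n_sites <- cnt
    stat <- function(v) {
      out <- rep(NA_real_, length(starts))
      for (w in which(cnt >= min_sites))
        out[w] <- mean(v[lo[w]:hi[w]])
      out
    }
    res$index_lm <- stat(tc$index_lm)
    res$index_sm <- stat(tc$index_sm)
    res$delta <- stat(tc$delta)
    if (has_ci) {
      res$ci_low <- stat(tc$ci_low)
      res$ci_high <- stat(tc$ci_high)
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  attr(out, "min_sites") <- min_sites
  class(out) <- c("window_track", "data.frame")
  out
}

#' Call linked regions from windowed delta indices
#'
#' Windows whose mean delta index falls outside the confidence band are
#' significant; overlapping or near-adjacent significant windows (gap at
#' most `merge_gap_bp`) merge into one region. Region endpoints are the
#' extremes of the member windows, clipped to the outermost supporting
#' sites when the site track is supplied.
#'
#' @param windows A [sliding_window()] track carrying `ci_low` / `ci_high`
#'   (from [site_ci()] applied before windowing).
#' @param track Optional site-level [index_track()] used to clip region ends
#'   to observed sites.
#' @param merge_gap_bp Maximum gap between significant windows that still
#'   merges (default 0 = overlap/adjacency only).
#' @param sides `"two"` (default): either tail of the band is significant;
#'   `"one"`: only `delta > ci_high`.
#' @param label_prefix Prefix for region labels.
#' @return A `genomic_regions` data frame: `region`, `chromosome`,
#'   `start_bp`, `end_bp` (1-based inclusive), `length_mb`, `n_windows`,
#'   `peak_delta`.
#' @export
call_linked_regions <- function(windows, track = NULL, merge_gap_bp = 0,
                                sides = c("two", "one"),
                                label_prefix = "region") {
  sides <- match.arg(sides)
  if (!all(c("ci_low", "ci_high") %in% names(windows)))
    stop("windows lack a confidence band; apply site_ci() before windowing",
         call. = FALSE)
  sig <- !is.na(windows$delta) &
    (windows$delta > windows$ci_high |
       (sides == "two" & windows$delta < windows$ci_low))
  sw <- windows[sig, , drop = FALSE]
  if (nrow(sw) == 0) {
    out <- data.frame(region = character(0), chromosome = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      length_mb = numeric(0), n_windows = integer(0),
                      peak_delta = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("genomic_regions", "data.frame")
    return(out)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(sw$chromosome),
    ranges = IRanges::IRanges(start = sw$start_bp, end = sw$end_bp))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap_bp + 1)
  ov <- GenomicRanges::findOverlaps(gr, red)
  memb <- S4Vectors::subjectHits(ov)
  rows <- lapply(seq_along(red), function(i) {
    wi <- which(memb == i)
    chr <- sw$chromosome[wi[1]]
    s <- GenomicRanges::start(red)[i]
    e <- GenomicRanges::end(red)[i]
    if (!is.null(track)) {
      ts <- track[track$chromosome == chr & !is.na(track$delta) &
                    track$pos_bp >= s & track$pos_bp <= e, ]
      if (nrow(ts) > 0) {
        s <- min(ts$pos_bp); e <- max(ts$pos_bp)
      }
    }
    data.frame(chromosome = chr, start_bp = s, end_bp = e,
               n_windows = length(wi),
               peak_delta = sw$delta[wi[which.max(abs(sw$delta[wi]))]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$start_bp), ]
  idx <- stats::ave(seq_len(nrow(out)), out$chromosome, FUN = seq_along)
  out <- data.frame(region = sprintf("%s%s-%d", label_prefix,
                                     out$chromosome, idx),
                    out, stringsAsFactors = FALSE)
  out$length_mb <- region_length_mb(out$start_bp, out$end_bp)
  out <- out[, c("region", "chromosome", "start_bp", "end_bp",
                 "length_mb", "n_windows", "peak_delta")]
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}
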