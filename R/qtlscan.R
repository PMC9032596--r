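#' Conditional genotype probabilities on a scan grid
#'
#' Computes, for every individual and every grid position (pseudomarkers at
#' `step_cM` spacing plus the typed markers themselves), the probability of
#' each F2 genotype given the nearest flanking typed markers, under the
#' chosen map function. At a typed, observed marker the distribution is
#' degenerate on the observed code; missing genotypes are bridged by
#' conditioning on the nearest non-missing markers on each side (or the
#' 1:2:1 prior beyond the terminal typed marker).
#'
#' @param map A `genetic_map` restricted to the typed markers.
#' @param genos An `f2_geno` matrix (codes 1/2/3, `NA` = missing) whose
#'   columns match `map$marker`.
#' @param step_cM Grid spacing in cM (> 0).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return A `geno_prob` object: per chromosome a list with `pos` (grid
#'   positions), `marker` (marker name or `NA` per position), and `pAA`,
#'   `pAB`, `pBB` (individuals x positions).
#' @export
genotype_probabilities <- function(map, genos, step_cM = 1,
                                   map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (step_cM <= 0) stop("step_cM must be positive", call. = FALSE)
  if (!all(map$marker %in% colnames(genos)))
    stop("genotype matrix lacks mapped markers", call. = FALSE)
  G_all <- unclass(genos)
  n <- nrow(G_all)
  chrs <- unique(map$chromosome)
  out <- vector("list", length(chrs))
  names(out) <- as.character(chrs)
  for (ci in seq_along(chrs)) {
    mk <- map[map$chromosome == chrs[ci], ]
    mpos <- mk$pos_cM
    m <- length(mpos)
    G <- G_all[, mk$marker, drop = FALSE]
    grid <- sort(unique(round(c(mpos, seq(min(mpos), max(mpos),
                                          by = step_cM)), 8)))
    P <- length(grid)
    pAA <- matrix(0, n, P); pAB <- matrix(0, n, P); pBB <- matrix(0, n, P)
    complete <- !anyNA(G)
    if (!complete) {
      # per individual: nearest non-missing marker at/left and at/right
      lastNM <- matrix(0L, n, m); nextNM <- matrix(m + 1L, n, m)
      cur <- rep(0L, n)
      for (j in seq_len(m)) {
        cur <- ifelse(!is.na(G[, j]), j, cur); lastNM[, j] <- cur
      }
      cur <- rep(m + 1L, n)
      for (j in rev(seq_len(m))) {
        cur <- ifelse(!is.na(G[, j]), j, cur); nextNM[, j] <- cur
      }
    }
    mgrid <- round(mpos, 8)
    for (p in seq_len(P)) {
      pos <- grid[p]
      jL <- findInterval(pos, mgrid)           # last marker at/left
      jR <- if (jL >= 1 && mgrid[jL] == pos) jL else jL + 1L
      if (complete) {
        if (jR == jL) {                         # typed position
          g <- G[, jL]
          pAA[, p] <- g == 1L; pAB[, p] <- g == 2L; pBB[, p] <- g == 3L
        } else {
          rL <- recombination_fraction(pos - mpos[jL], map_function)
          rR <- recombination_fraction(mpos[jR] - pos, map_function)
          TL <- f2_transition(rL); TR <- f2_transition(rR)
          # 9 flanking combinations x 3 genotypes, normalised
          W <- matrix(0, 9, 3)
          for (gl in 1:3) for (gr in 1:3) {
            w <- TL[gl, ] * TR[, gr]
            W[gl + 3L * (gr - 1L), ] <- w / sum(w)
          }
          combo <- G[, jL] + 3L * (G[, jR] - 1L)
          pAA[, p] <- W[combo, 1L]
          pAB[, p] <- W[combo, 2L]
          pBB[, p] <- W[combo, 3L]
        }
      } else {
        jl <- if (jL >= 1L) lastNM[, jL] else rep(0L, n)
        jr <- if (jR <= m) nextNM[, jR] else rep(m + 1L, n)
        # typed & observed at pos: jl == jr handled by r = 0 transitions
        L <- matrix(rep(c(0.25, 0.5, 0.25), each = n), n, 3)
        hasL <- jl >= 1L
        if (any(hasL)) {
          rL <- recombination_fraction(pos - mpos[pmax(jl, 1L)],
                                       map_function)
          gl <- G[cbind(seq_len(n), pmax(jl, 1L))]
          for (g in 1:3)
            L[hasL, g] <- f2_trans_el(rL[hasL], gl[hasL], rep(g, sum(hasL)))
        }
        R <- matrix(1, n, 3)
        hasR <- jr <= m
        if (any(hasR)) {
          rR <- recombination_fraction(mpos[pmin(jr, m)] - pos,
                                       map_function)
          gr <- G[cbind(seq_len(n), pmin(jr, m))]
          for (g in 1:3)
            R[hasR, g] <- f2_trans_el(rR[hasR], rep(g, sum(hasR)), gr[hasR])
        }
        W <- L * R
        W <- W / rowSums(W)
        pAA[, p] <- W[, 1L]; pAB[, p] <- W[, 2L]; pBB[, p] <- W[, 3L]
      }
    }
    mk_at <- match(grid, mgrid)
    out[[ci]] <- list(chromosome = chrs[ci], pos = grid,
                      marker = ifelse(is.na(mk_at), NA_character_,
                                      mk$marker[mk_at]),
                      pAA = pAA, pAB = pAB, pBB = pBB)
  }
  structure(out, map = map, step_cM = step_cM, n = n,
            map_function = map_function, class = "geno_prob")
}

# F2 genotype transition matrix over recombination fraction r
# rows = genotype at the left locus (1 = AA, 2 = AB, 3 = BB)
f2_transition <- function(r) {
  matrix(c((1 - r)^2,     2 * r * (1 - r), r^2,
           r * (1 - r),   (1 - r)^2 + r^2, r * (1 - r),
           r^2,           2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

# vectorised element T[i, j](r) of the F2 transition matrix
f2_trans_el <- function(r, i, j) {
  a1 <- (1 - r)^2; a2 <- 2 * r * (1 - r); a3 <- r^2
  a4 <- r * (1 - r); a5 <- a1 + a3
  vals <- cbind(a1, a2, a3, a4, a5, a4, a3, a2, a1)
  vals[cbind(seq_along(r), (i - 1L) * 3L + j)]
}

# expected additive dosage (second-parent allele count - 1) and
# heterozygote probability at every grid position, plus position bookkeeping
grid_dosages <- function(gp) {
  xs <- lapply(gp, function(ch) ch$pBB - ch$pAA)
  zs <- lapply(gp, function(ch) ch$pAB)
  pos <- do.call(rbind, lapply(gp, function(ch)
    data.frame(chromosome = ch$chromosome, pos_cM = ch$pos,
               marker = ch$marker, stringsAsFactors = FALSE)))
  list(x = do.call(cbind, xs), z = do.call(cbind, zs), pos = pos)
}

# marker-only dosage matrices (for cofactor selection/fitting)
marker_dosages <- function(gp) {
  d <- grid_dosages(gp)
  keep <- !is.na(d$pos$marker)
  list(x = d$x[, keep, drop = FALSE], z = d$z[, keep, drop = FALSE],
       pos = d$pos[keep, , drop = FALSE])
}

#' Select background cofactor markers by stepwise regression
#'
#' Forward-backward stepwise selection of markers on the phenotype, each
#' marker entering with both an additive and a dominance column (a 2-df
#' F test). Markers enter while the smallest entry p-value is below
#' `alpha_in` and leave while the largest exit p-value is above
#' `alpha_out`. Ties break on the smaller p-value, then the lower marker
#' index, so the procedure is deterministic. After convergence only the
#' `max_cofactors` strongest selections (by marginal 2-df F statistic
#' against the trait) are kept as background markers, mirroring the
#' composite-interval-mapping convention of a small fixed number of
#' background parameters.
#'
#' @param gp A [genotype_probabilities()] grid (markers are taken from it so
#'   missing genotypes are handled by their conditional expectations).
#' @param y Phenotype vector (typically F2:3 family means), one value per
#'   individual, no `NA`.
#' @param alpha_in,alpha_out Entry and exit thresholds (default 0.05).
#' @param max_cofactors Maximum number of background markers retained
#'   (default 5); `Inf` keeps the full stepwise selection.
#' @param max_steps Safety cap on selection sweeps.
#' @return A `cim_cofactors` object: data frame of selected markers
#'   (`marker`, `chromosome`, `pos_cM`) with the dosage matrices in
#'   attributes `x` and `z`.
#' @export
select_cofactors <- function(gp, y, alpha_in = 0.05, alpha_out = 0.05,
                             max_cofactors = 5L, max_steps = 50L) {
  md <- marker_dosages(gp)
  M <- ncol(md$x)
  n <- length(y)
  empty <- function() {
    res <- md$pos[integer(0), , drop = FALSE]
    attr(res, "x") <- md$x[, integer(0), drop = FALSE]
    attr(res, "z") <- md$z[, integer(0), drop = FALSE]
    class(res) <- c("cim_cofactors", "data.frame")
    res
  }
  if (M == 0 || stats::var(y) == 0) return(empty())
  sel <- integer(0)
  design <- function(idx) {
    cbind(`(Intercept)` = rep(1, n),
          md$x[, idx, drop = FALSE], md$z[, idx, drop = FALSE])
  }
  rss_of <- function(idx) {
    f <- stats::lm.fit(design(idx), y)
    sum(f$residuals^2)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    cand <- setdiff(seq_len(M), sel)
    if (length(cand) > 0) {
      qrc <- qr(design(sel))
      rk <- qrc$rank
      yr <- qr.resid(qrc, y)
      rss0 <- sum(yr^2)
      xr <- qr.resid(qrc, md$x[, cand, drop = FALSE])
      zr <- qr.resid(qrc, md$z[, cand, drop = FALSE])
      gxx <- colSums(xr^2); gzz <- colSums(zr^2); gxz <- colSums(xr * zr)
      ax <- as.vector(crossprod(xr, yr)); az <- as.vector(crossprod(zr, yr))
      det <- gxx * gzz - gxz^2
      quad <- ifelse(det > 1e-10 * pmax(gxx * gzz, 1e-300),
                     (gzz * ax^2 - 2 * gxz * ax * az + gxx * az^2) / det,
                     ifelse(gxx > 1e-12, ax^2 / gxx, 0))
      quad <- pmin(pmax(quad, 0), rss0)
      df2 <- n - rk - 2L
      if (df2 > 0) {
        Fv <- (quad / 2) / pmax((rss0 - quad) / df2, 1e-300)
        pv <- stats::pf(Fv, 2, df2, lower.tail = FALSE)
        best <- which.min(pv)          # ties -> lowest index
        if (is.finite(pv[best]) && pv[best] < alpha_in) {
          sel <- sort(c(sel, cand[best]))
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(sel) > 0) {
      rss_full <- rss_of(sel)
      df_full <- n - (1L + 2L * length(sel))
      if (df_full > 0) {
        pv <- vapply(sel, function(mi) {
          rss_red <- rss_of(setdiff(sel, mi))
          Fv <- ((rss_red - rss_full) / 2) / pmax(rss_full / df_full, 1e-300)
          stats::pf(Fv, 2, df_full, lower.tail = FALSE)
        }, 0)
        worst <- which.max(pv)
        if (pv[worst] > alpha_out) {
          sel <- setdiff(sel, sel[worst])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (length(sel) > max_cofactors) {
    # rank by marginal 2-df F against the trait; ties keep lower index
    fstat <- vapply(sel, function(mi) {
      f <- stats::lm.fit(cbind(1, md$x[, mi], md$z[, mi]), y)
      rss1 <- sum(f$residuals^2)
      rss0 <- sum((y - mean(y))^2)
      ((rss0 - rss1) / 2) / (rss1 / (n - 3))
    }, 0)
    sel <- sort(sel[order(-fstat, sel)[seq_len(max_cofactors)]])
  }
  res <- md$pos[sel, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "x") <- md$x[, sel, drop = FALSE]
  attr(res, "z") <- md$z[, sel, drop = FALSE]
  class(res) <- c("cim_cofactors", "data.frame")
  res
}

# Precomputes everything about a scan that does not depend on the phenotype:
# grid dosages residualised against each position's active cofactor block
# (cofactors within window_cM of the position are excluded), Gram terms, and
# per-block QR decompositions. Scanning a phenotype (or a matrix of permuted
# phenotypes) then costs two matrix products.
scan_engine <- function(gp, cofactors = NULL, window_cM = 10) {
  d <- grid_dosages(gp)
  n <- nrow(d$x)
  P <- ncol(d$x)
  k <- if (is.null(cofactors)) 0L else nrow(cofactors)
  if (k > 0) {
    cx <- attr(cofactors, "x"); cz <- attr(cofactors, "z")
    active <- matrix(TRUE, P, k)
    for (j in seq_len(k)) {
      same <- d$pos$chromosome == cofactors$chromosome[j] &
        abs(d$pos$pos_cM - cofactors$pos_cM[j]) <= window_cM
      active[same, j] <- FALSE
    }
    key <- apply(active, 1, function(a) paste(which(a), collapse = ","))
  } else {
    key <- rep("", P)
  }
  groups <- split(seq_len(P), key)
  Xr <- d$x; Zr <- d$z
  qrs <- vector("list", length(groups))
  grp_of <- integer(P)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    grp_of[idx] <- gi
    act <- if (k > 0) which(active[idx[1], ]) else integer(0)
    C <- cbind(rep(1, n),
               if (length(act)) cx[, act, drop = FALSE],
               if (length(act)) cz[, act, drop = FALSE])
    qrc <- qr(C)
    # drop collinear cofactor columns silently via the QR rank
    qrs[[gi]] <- qrc
    Xr[, idx] <- qr.resid(qrc, d$x[, idx, drop = FALSE])
    Zr[, idx] <- qr.resid(qrc, d$z[, idx, drop = FALSE])
  }
  gxx <- colSums(Xr^2); gzz <- colSums(Zr^2); gxz <- colSums(Xr * Zr)
  det <- gxx * gzz - gxz^2
  ok2 <- det > 1e-9 * pmax(gxx * gzz, 1e-300) & gxx > 1e-12 & gzz > 1e-12
  ok1 <- !ok2 & gxx > 1e-12

  rss0_fun <- function(Y) {     # blocks x columns null RSS
    vapply(seq_along(groups), function(gi) {
      Yr <- qr.resid(qrs[[gi]], Y)
      colSums(Yr^2)
    }, numeric(ncol(Y)))
  }
  quad_fun <- function(A, B) {  # P x K explained sums of squares
    Q <- matrix(0, nrow(A), ncol(A))
    if (any(ok2))
      Q[ok2, ] <- (gzz[ok2] * A[ok2, , drop = FALSE]^2 -
                     2 * gxz[ok2] * A[ok2, , drop = FALSE] *
                     B[ok2, , drop = FALSE] +
                     gxx[ok2] * B[ok2, , drop = FALSE]^2) / det[ok2]
    if (any(ok1))
      Q[ok1, ] <- A[ok1, , drop = FALSE]^2 / gxx[ok1]
    Q
  }
  scan_y <- function(y) {
    Y <- matrix(y, ncol = 1)
    A <- crossprod(Xr, Y); B <- crossprod(Zr, Y)
    R0g <- rss0_fun(Y)                       # 1 x n_groups
    R0 <- matrix(R0g, ncol = 1)[grp_of, , drop = FALSE]
    quad <- pmin(quad_fun(A, B), R0 * (1 - 1e-12))
    rss1 <- R0 - quad
    lod <- (n / 2) * log10(R0 / rss1)
    alpha <- beta <- numeric(P)
    alpha[ok2] <- (gzz[ok2] * A[ok2, 1] - gxz[ok2] * B[ok2, 1]) / det[ok2]
    beta[ok2] <- (gxx[ok2] * B[ok2, 1] - gxz[ok2] * A[ok2, 1]) / det[ok2]
    alpha[ok1] <- A[ok1, 1] / gxx[ok1]
    tss <- sum((y - mean(y))^2)
    data.frame(chromosome = d$pos$chromosome, pos_cM = d$pos$pos_cM,
               marker = d$pos$marker, lod = lod[, 1],
               a = alpha, d_coef = beta,
               rss0 = R0[, 1], rss1 = rss1[, 1], tss = tss,
               stringsAsFactors = FALSE)
  }
  max_lod <- function(Y) {
    A <- crossprod(Xr, Y); B <- crossprod(Zr, Y)
    R0g <- rss0_fun(Y)                       # K x n_groups
    if (is.null(dim(R0g))) R0g <- matrix(R0g, nrow = ncol(Y))
    R0 <- t(R0g)[grp_of, , drop = FALSE]     # P x K
    quad <- pmin(quad_fun(A, B), R0 * (1 - 1e-12))
    lod <- (n / 2) * log10(R0 / (R0 - quad))
    apply(lod, 2, max)
  }
  list(scan_y = scan_y, max_lod = max_lod, n = n, pos = d$pos)
}

#' Composite interval mapping scan
#'
#' Haley-Knott regression of the phenotype on expected additive dosage and
#' heterozygote probability at every grid position, with the selected
#' background cofactors in the model; cofactors within `window_cM` of the
#' test position (same chromosome) are excluded from its fit. The score is
#' \deqn{LOD = (n/2)\,\log_{10}(RSS_{null}/RSS_{full})}
#' where the null model carries the same cofactors but no QTL terms. With an
#' empty cofactor set the scan reduces exactly to plain interval mapping.
#'
#' @param gp A [genotype_probabilities()] grid.
#' @param y Phenotype vector (F2:3 family means by default), one value per
#'   individual, no `NA`.
#' @param cofactors A [select_cofactors()] result, or `NULL` for plain
#'   interval mapping.
#' @param window_cM Cofactor exclusion window around the test position
#'   (default 10 cM).
#' @param d_scale Multiplier taking the fitted heterozygote coefficient to
#'   the reported dominance effect: 2 (default) when `y` are F2:3 family
#'   means, since selfing halves the heterozygote dominance deviation; use 1
#'   for per-F2 phenotypes.
#' @return A `lod_curve` data frame: `chromosome`, `pos_cM`, `marker`,
#'   `lod`, `a` (additive effect, positive = second parent increases the
#'   trait), `d` (dominance effect on the F2 scale), `pve` (percent variance
#'   explained by the position terms).
#' @export
cim_scan <- function(gp, y, cofactors = NULL, window_cM = 10, d_scale = 2) {
  if (anyNA(y)) stop("phenotype vector must not contain NA", call. = FALSE)
  if (length(y) != attr(gp, "n"))
    stop("phenotype length does not match the genotyped individuals",
         call. = FALSE)
  eng <- scan_engine(gp, cofactors, window_cM)
  sc <- eng$scan_y(y)
  out <- data.frame(chromosome = sc$chromosome, pos_cM = sc$pos_cM,
                    marker = sc$marker, lod = sc$lod, a = sc$a,
                    d = d_scale * sc$d_coef,
                    pve = 100 * (sc$rss0 - sc$rss1) / sc$tss,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- eng$n
  attr(out, "map") <- attr(gp, "map")
  attr(out, "cofactors") <- cofactors
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype vector, rescans the genome (same grid, cofactors
#' and window), records the genome-wide maximum LOD of each permutation, and
#' returns the `1 - alpha` empirical quantile (type-7 interpolation).
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error rate(s).
#' @param seed Optional seed for the permutations.
#' @return Threshold(s) with the permutation maxima in
#'   `attr(, "max_lods")`.
#' @export
permutation_threshold <- function(gp, y, cofactors = NULL, n_perm = 1000,
                                  alpha = 0.05, window_cM = 10,
                                  seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eng <- scan_engine(gp, cofactors, window_cM)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  mx <- eng$max_lod(Y)
  thr <- stats::quantile(mx, probs = 1 - alpha, type = 7, names = FALSE)
  names(thr) <- as.character(alpha)
  attr(thr, "max_lods") <- mx
  thr
}

#' Call QTL peaks from a LOD curve
#'
#' One peak per contiguous supra-threshold segment per chromosome: the
#' highest-LOD position wins (ties go to the leftmost). Flanking markers are
#' the nearest typed markers bracketing the peak; additive and dominance
#' effects, their Stuber |d/a| gene-action class, and the percent variance
#' explained are taken from the peak fit.
#'
#' @param curve A [cim_scan()] result.
#' @param threshold Genome-wide LOD threshold.
#' @param prefix Name prefix for called QTLs (default `"qtl"`).
#' @return A `qtl_peaks` data frame: `qtl`, `chromosome`, `pos_cM`, `lod`,
#'   `marker_left`, `marker_right`, `a`, `d`, `da_ratio`, `gene_action`,
#'   `pve`. Zero rows when nothing exceeds the threshold.
#' @export
call_qtl_peaks <- function(curve, threshold, prefix = "qtl") {
  map <- attr(curve, "map")
  res <- list()
  for (chr in unique(curve$chromosome)) {
    cc <- curve[curve$chromosome == chr, ]
    above <- cc$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    segs <- which(runs$values)
    for (s in segs) {
      seg <- cc[starts[s]:ends[s], ]
      pk <- seg[which.max(seg$lod), ]          # leftmost on ties
      mk <- map[map$chromosome == chr, ]
      left <- mk$marker[max(c(1L, which(mk$pos_cM <= pk$pos_cM)))]
      rcand <- which(mk$pos_cM >= pk$pos_cM)
      right <- mk$marker[if (length(rcand)) min(rcand) else nrow(mk)]
      cls <- classify_gene_action(pk$a, pk$d)
      res[[length(res) + 1L]] <- data.frame(
        chromosome = chr, pos_cM = pk$pos_cM, lod = pk$lod,
        marker_left = left, marker_right = right,
        a = pk$a, d = pk$d, da_ratio = cls$ratio,
        gene_action = cls$class, pve = pk$pve,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    out <- data.frame(qtl = character(0), chromosome = integer(0),
                      pos_cM = numeric(0), lod = numeric(0),
                      marker_left = character(0), marker_right = character(0),
                      a = numeric(0), d = numeric(0), da_ratio = numeric(0),
                      gene_action = character(0), pve = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
    idx <- stats::ave(seq_len(nrow(out)), out$chromosome, FUN = seq_along)
    out <- cbind(qtl = sprintf("%s%s-%d", prefix, out$chromosome, idx), out)
  }
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' Stuber gene-action classification
#'
#' Classifies a QTL by the ratio of its dominance to additive effect:
#' additive (A) for |d/a| in \[0, 0.20\], partial dominance (PD) in
#' (0.20, 0.80\], dominance (D) in (0.80, 1.20\], over-dominance (OD) above
#' 1.20. The right-closed intervals resolve the gap left by the
#' conventional "0.00-0.20 / 0.21-0.80 / ..." notation. `a = 0` with
#' `d != 0` is classed OD by convention; `a = d = 0` is A.
#'
#' @param a,d Additive and dominance effects (vectorised, finite).
#' @return A data frame with `ratio` (|d/a| rounded to 2 decimals for
#'   reporting; classification uses the unrounded value) and `class`
#'   (factor with levels A, PD, D, OD).
#' @examples
#' classify_gene_action(-1.03, -1.20)  # ratio 1.17, class D
#' @export
classify_gene_action <- function(a, d) {
  if (any(!is.finite(a)) || any(!is.finite(d)))
    stop("effects must be finite", call. = FALSE)
  ratio <- ifelse(a == 0, ifelse(d == 0, 0, Inf), abs(d / a))
  cls <- cut(ratio, breaks = c(-Inf, 0.20, 0.80, 1.20, Inf),
             labels = c("A", "PD", "D", "OD"), right = TRUE)
  cls[a == 0 & d != 0] <- "OD"
  data.frame(ratio = round(ratio, 2), class = cls)
}
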