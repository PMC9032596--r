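#' Variance components of a balanced family-by-environment trial
#'
#' Decomposes a balanced F2:3 trial (g families x n environments x r
#' replicates) by the expected-mean-squares method of the two-way ANOVA:
#' \deqn{\hat\sigma^2_\epsilon = MS_{error},\quad
#'       \hat\sigma^2_{ge} = (MS_{GE} - MS_{error})/r,\quad
#'       \hat\sigma^2_g  = (MS_{G} - MS_{GE})/(nr).}
#' Negative component estimates are truncated to zero (the raw values are
#' kept in the result).
#'
#' @param phenos A `phenotype_table` data frame with columns `family`,
#'   `environment`, `replicate`, `value`; the design must be balanced.
#' @return A `variance_components` list: `sigma_g2`, `sigma_ge2`,
#'   `sigma_eps2`, `n_env`, `n_rep`, `n_fam`, plus the mean squares (`ms`)
#'   and untruncated estimates (`raw`).
#' @examples
#' ph <- expand.grid(family = paste0("F", 1:4), environment = c("a", "b"),
#'                   replicate = 1:3)
#' ph$value <- rnorm(nrow(ph))
#' estimate_variance_components(ph)
#' @export
estimate_variance_components <- function(phenos) {
  need <- c("family", "environment", "value")
  if (!all(need %in% names(phenos)))
    stop("phenotype table needs columns family, environment, value",
         call. = FALSE)
  if (any(!is.finite(phenos$value)))
    stop("trait values must be finite", call. = FALSE)
  fam <- factor(phenos$family)
  env <- factor(phenos$environment)
  g <- nlevels(fam); n <- nlevels(env)
  if (g < 2 || n < 2)
    stop("need at least 2 families and 2 environments", call. = FALSE)
  counts <- table(fam, env)
  r <- counts[1, 1]
  if (any(counts != r))
    stop("unbalanced design: replicate counts differ across cells",
         call. = FALSE)
  if (r < 2)
    stop("need at least 2 replicates per cell", call. = FALSE)
  y <- phenos$value
  grand <- mean(y)
  fm <- tapply(y, fam, mean)
  em <- tapply(y, env, mean)
  cm <- tapply(y, list(fam, env), mean)
  ss_g <- n * r * sum((fm - grand)^2)
  ss_e <- g * r * sum((em - grand)^2)
  ss_ge <- r * sum((cm - outer(fm, rep(1, n)) -
                      outer(rep(1, g), em) + grand)^2)
  ss_err <- sum((y - cm[cbind(fam, env)])^2)
  ms <- c(G = ss_g / (g - 1), E = ss_e / (n - 1),
          GE = ss_ge / ((g - 1) * (n - 1)),
          error = ss_err / (g * n * (r - 1)))
  raw <- c(sigma_g2 = (ms[["G"]] - ms[["GE"]]) / (n * r),
           sigma_ge2 = (ms[["GE"]] - ms[["error"]]) / r,
           sigma_eps2 = ms[["error"]])
  structure(list(sigma_g2 = max(0, raw[["sigma_g2"]]),
                 sigma_ge2 = max(0, raw[["sigma_ge2"]]),
                 sigma_eps2 = max(0, raw[["sigma_eps2"]]),
                 n_env = n, n_rep = as.integer(r), n_fam = g,
                 ms = ms, raw = raw),
            class = "variance_components")
}

vc_denominator <- function(vc) {
  vc$sigma_g2 + vc$sigma_ge2 / vc$n_env +
    vc$sigma_eps2 / (vc$n_env * vc$n_rep)
}

#' Broad-sense heritability across environments
#'
#' \deqn{H_B^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/n +
#'   \sigma_\epsilon^2/(nr))}
#' i.e. the genotypic share of the variance of a family mean over `n`
#' environments and `r` replicates.
#'
#' @param vc A [estimate_variance_components()] result (or a compatible
#'   list).
#' @return Proportion in \[0, 1\].
#' @export
broad_sense_heritability <- function(vc) {
  den <- vc_denominator(vc)
  if (den <= 0) stop("heritability undefined: zero phenotypic variance",
                     call. = FALSE)
  vc$sigma_g2 / den
}

#' Genotype-by-environment interaction heritability
#'
#' Share of family-mean variance attributable to the genotype-by-environment
#' interaction, \eqn{(\sigma_{ge}^2/n)} over the same denominator as
#' [broad_sense_heritability()]. Reports of this statistic sometimes print
#' \eqn{\sigma_g^2/n} in the numerator; that form equals \eqn{H_B^2/n} and
#' is available via `as_printed = TRUE` for auditing, but the interaction
#' component is the default.
#'
#' @inheritParams broad_sense_heritability
#' @param as_printed Use \eqn{\sigma_g^2/n} in the numerator.
#' @return Proportion in \[0, 1\].
#' @export
ge_heritability <- function(vc, as_printed = FALSE) {
  den <- vc_denominator(vc)
  if (den <= 0) stop("heritability undefined: zero phenotypic variance",
                     call. = FALSE)
  num <- if (as_printed) vc$sigma_g2 / vc$n_env else vc$sigma_ge2 / vc$n_env
  num / den
}

#' Heterosis indices from generation means
#'
#' Given the two parental means, the F1 mean, and the F2:3 mean of a trait,
#' computes the mid-parent value `MP`, the better-parent value `P_H`, and
#' the classical indices: heterosis index `HI = F1/MP x 100`, relative
#' heterosis `RH = (F1 - MP)/F1 x 100`, mid-parent heterosis
#' `MH = (F1 - MP)/MP x 100`, over-parent heterosis
#' `OH = (F1 - P_H)/P_H x 100`, and the F2:3 advantage reduction rate
#' `ARR = (F23 - F1)/F1 x 100`. `HI = MH + 100` holds identically.
#'
#' @param p1_mean,p2_mean,f1_mean Parental and F1 trait means (> 0).
#' @param f23_mean F2:3 population mean (`NA` allowed; ARR is then `NA`).
#' @return A `heterosis_result` list with `MP`, `P_H`, `HI`, `RH`, `MH`,
#'   `OH`, `ARR` (percentages).
#' @examples
#' heterosis(3.82, 2.32, 4.956, 3.74)
#' @export
heterosis <- function(p1_mean, p2_mean, f1_mean, f23_mean = NA_real_) {
  if (any(c(p1_mean, p2_mean, f1_mean) <= 0, na.rm = FALSE))
    stop("generation means must be positive", call. = FALSE)
  mp <- (p1_mean + p2_mean) / 2
  ph <- max(p1_mean, p2_mean)
  structure(list(
    MP = mp, P_H = ph,
    HI = f1_mean / mp * 100,
    RH = (f1_mean - mp) / f1_mean * 100,
    MH = (f1_mean - mp) / mp * 100,
    OH = (f1_mean - ph) / ph * 100,
    ARR = (f23_mean - f1_mean) / f1_mean * 100),
    class = "heterosis_result")
}

#' Rate of change of a trait between sowing depths
#'
#' Percentage change of the deep-sowing mean relative to the normal-depth
#' mean, `RC = (mean_deep/mean_normal - 1) x 100`, so a mesocotyl that
#' lengthens from 3.82 to 12.70 cm has RC = 232.46%. The alternative
#' orientation `(1 - mean_normal/mean_deep) x 100` sometimes seen in print
#' is available via `as_printed = TRUE` for auditing.
#'
#' @param mean_normal Trait mean at the normal sowing depth (> 0).
#' @param mean_deep Trait mean at the deep sowing depth.
#' @param as_printed Use the `(1 - mean_normal/mean_deep)` form.
#' @return Percentage (vectorised).
#' @examples
#' rate_of_change(3.82, 12.70)  # 232.46
#' @export
rate_of_change <- function(mean_normal, mean_deep, as_printed = FALSE) {
  if (any(mean_normal <= 0))
    stop("normal-depth mean must be positive", call. = FALSE)
  if (as_printed) (1 - mean_normal / mean_deep) * 100
  else (mean_deep / mean_normal - 1) * 100
}

#' Distribution descriptors of a trait
#'
#' Mean, standard deviation, coefficient of variation, moment skewness,
#' excess kurtosis, and range, plus the segregation-analysis normality rule
#' of thumb: a trait is flagged approximately normal when both |skewness|
#' and |excess kurtosis| are below 1.
#'
#' @param values Numeric vector of at least 3 finite trait values.
#' @return A `distribution_summary` list: `n`, `mean`, `sd`, `cv_pct`,
#'   `skewness`, `kurtosis` (excess, normal = 0), `min`, `max`,
#'   `normal_flag`.
#' @export
describe_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop("need at least 3 finite values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  cm <- values - m
  m2 <- mean(cm^2)
  # constant data: sd = 0, moments defined as 0 (flagged normal)
  skew <- if (m2 > 0) mean(cm^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cm^4) / m2^2 - 3 else 0
  structure(list(n = n, mean = m, sd = s,
                 cv_pct = if (m != 0) 100 * s / m else NA_real_,
                 skewness = skew, kurtosis = kurt,
                 min = min(values), max = max(values),
                 normal_flag = abs(skew) < 1 && abs(kurt) < 1),
            class = "distribution_summary")
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a test sample relative to a calibrator
#' sample, each normalised to a reference gene:
#' \deqn{2^{-[(Ct_{target,test} - Ct_{ref,test}) -
#'           (Ct_{target,cal} - Ct_{ref,cal})]}.}
#'
#' @param ct_target_test,ct_ref_test Cycle thresholds in the test sample.
#' @param ct_target_cal,ct_ref_cal Cycle thresholds in the calibrator.
#' @return Fold change (vectorised).
#' @examples
#' relative_expression_ddct(24, 20, 26, 20)  # 4
#' @export
relative_expression_ddct <- function(ct_target_test, ct_ref_test,
                                     ct_target_cal, ct_ref_cal) {
  stopifnot(all(is.finite(c(ct_target_test, ct_ref_test,
                            ct_target_cal, ct_ref_cal))))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}
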