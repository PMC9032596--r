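#' Published mesocotyl-length QTL effects
#'
#' The 16 QTL-by-environment entries reported for mesocotyl length (MES) in
#' a W64A x K12 F2:3 maize population scored at 3, 15 and 20 cm sowing
#' depth: peak position, flanking-marker interval, LOD, additive (`a`) and
#' dominance (`d`) effects, and percent variance explained. The sign
#' convention is that positive `a` means the K12 (intolerant) allele
#' increases the trait, so negative values mark W64A alleles that lengthen
#' the mesocotyl.
#'
#' @return Data frame with columns `qtl`, `bin`, `chromosome`,
#'   `environment`, `pos_cM`, `marker_interval`, `lod`, `a`, `d`, `pve`.
#' @export
mes_qtl_table <- function() {
  utils::read.delim(system.file("extdata", "mes_qtl_effects.tsv",
                                package = "mesoqtl"),
                    stringsAsFactors = FALSE)
}

#' Published linked BSA regions for mesocotyl length
#'
#' The seven SNP-/InDel-index regions linked to mesocotyl length at 20 cm
#' sowing depth (physical endpoints, 1-based inclusive, B73 v4
#' coordinates).
#'
#' @return Data frame with columns `region`, `chromosome`, `start_bp`,
#'   `end_bp`, `vclass`.
#' @export
mes_bsa_regions <- function() {
  utils::read.delim(system.file("extdata", "mes_bsa_regions.tsv",
                                package = "mesoqtl"),
                    stringsAsFactors = FALSE)
}

#' Published generation means of mesocotyl length
#'
#' Mean mesocotyl length (cm) of the tolerant parent W64A, the intolerant
#' parent K12, and the F2:3 population at 3, 15 and 20 cm sowing depth.
#'
#' @return Data frame with columns `material`, `depth_cm`, `mes_cm`.
#' @export
mes_generation_means <- function() {
  utils::read.delim(system.file("extdata", "mes_generation_means.tsv",
                                package = "mesoqtl"),
                    stringsAsFactors = FALSE)
}

#' Default true-QTL architecture for the study simulator
#'
#' Turns the published QTL effect table ([mes_qtl_table()]) into the
#' simulator's truth format: one row per QTL and environment with the
#' published `a` and `d` (zero in environments where a QTL was not
#' detected) and one consensus position per QTL (the rounded mean of its
#' per-environment peak positions).
#'
#' @param environments Environment labels to cover.
#' @return Data frame with columns `qtl`, `chromosome`, `pos_cM`,
#'   `environment`, `a`, `d`.
#' @export
mes_qtl_architecture <- function(environments = c("3cm", "15cm", "20cm")) {
  tab <- mes_qtl_table()
  qtls <- unique(tab$qtl)
  rows <- lapply(qtls, function(q) {
    tq <- tab[tab$qtl == q, ]
    pos <- round(mean(tq$pos_cM), 1)
    hit <- match(environments, tq$environment)
    data.frame(qtl = q, chromosome = tq$chromosome[1], pos_cM = pos,
               environment = environments,
               a = ifelse(is.na(hit), 0, tq$a[hit]),
               d = ifelse(is.na(hit), 0, tq$d[hit]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
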