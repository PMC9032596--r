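#' Read and write the genetic map table
#'
#' TSV with columns `marker`, `chromosome`, `pos_cM`, `pos_bp`. Loading
#' checks the map invariants: unique marker names and strictly increasing
#' cM (and non-decreasing bp) within each chromosome.
#'
#' @param path File path.
#' @return A `genetic_map` data frame.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "pos_cM", "pos_bp")
  if (!all(need %in% names(map)))
    stop("map file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$marker))
    stop("duplicated marker names: ",
         paste(utils::head(map$marker[duplicated(map$marker)], 3),
               collapse = ", "), call. = FALSE)
  for (chr in unique(map$chromosome)) {
    p <- map$pos_cM[map$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("map positions not strictly increasing on chromosome ", chr,
           call. = FALSE)
    b <- map$pos_bp[map$chromosome == chr]
    if (any(diff(b) < 0))
      stop("physical positions decrease on chromosome ", chr, call. = FALSE)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname read_genetic_map
#' @param map A `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write the F2 genotype matrix
#'
#' TSV with individuals in rows (first column `individual`) and one column
#' per marker holding the codes `AA`, `AB`, `BB`, or `NA`/empty for
#' missing. Codes are whitespace-trimmed on input. Every genotyped marker
#' must be present on the map.
#'
#' @param path File path.
#' @param map The corresponding `genetic_map`.
#' @return An `f2_geno` integer matrix (1/2/3, `NA` missing) with the map
#'   attached.
#' @export
read_genotypes <- function(path, map) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           na.strings = c("NA", ""))
  if (names(tab)[1] != "individual")
    stop("genotype file must start with an 'individual' column",
         call. = FALSE)
  markers <- names(tab)[-1]
  unknown <- setdiff(markers, map$marker)
  if (length(unknown) > 0)
    stop("marker(s) absent from the map: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  codes <- c(AA = 1L, AB = 2L, BB = 3L)
  g <- vapply(tab[-1], function(col) {
    col <- trimws(col)
    bad <- !is.na(col) & !col %in% names(codes)
    if (any(bad))
      stop("unknown genotype code: ",
           paste(utils::head(unique(col[bad]), 3), collapse = ", "),
           call. = FALSE)
    codes[col]
  }, integer(nrow(tab)))
  rownames(g) <- tab$individual
  # order columns along the map
  keep <- map[map$marker %in% markers, ]
  g <- g[, keep$marker, drop = FALSE]
  structure(g, map = keep, class = "f2_geno")
}

#' @rdname read_genotypes
#' @param genos An `f2_geno` matrix.
#' @export
write_genotypes <- function(genos, path) {
  g <- unclass(genos)
  chr <- matrix(c("AA", "AB", "BB")[g], nrow(g), ncol(g),
                dimnames = dimnames(g))
  out <- data.frame(individual = rownames(g), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write the phenotype table
#'
#' TSV with columns `family`, `environment`, `replicate`, `value`.
#'
#' @param path File path.
#' @return A `phenotype_table` data frame.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "environment", "replicate", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$value)))
    stop("non-finite trait values in ", path, call. = FALSE)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' @rdname read_phenotypes
#' @param phenos A `phenotype_table`.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.table(as.data.frame(phenos), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled variant sites from a VCF
#'
#' Parses a VCF v4.2 with an `AD` (allelic depths) FORMAT field for four
#' samples: the two parents and the two offspring bulks. Only biallelic
#' records are kept; multiallelic records are skipped with a logged count.
#' The variant class is `SNP` when both alleles are single bases, `InDel`
#' otherwise.
#'
#' @param path VCF path (plain or gzipped).
#' @param sample_roles Named character vector mapping roles `parent1`,
#'   `parent2`, `LM`, `SM` to sample names in the VCF.
#' @return A `pool_sites` data frame (see [simulate_pool_reads()]), with
#'   the number of skipped multiallelic records in
#'   `attr(, "n_multiallelic")`.
#' @export
read_vcf_pools <- function(path,
                           sample_roles = c(parent1 = "P1", parent2 = "P2",
                                            LM = "LM", SM = "SM")) {
  roles <- c("parent1", "parent2", "LM", "SM")
  if (!all(roles %in% names(sample_roles)))
    stop("sample_roles must name: ", paste(roles, collapse = ", "),
         call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_roles <- sample_roles[!sample_roles %in% samples]
  if (length(missing_roles) > 0)
    stop("sample(s) absent from the VCF: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    alt <- alt[!multi]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  gt <- vcfR::extract.gt(v, element = "GT")
  for (role in roles) {
    s <- sample_roles[[role]]
    if (all(is.na(ad[, s])))
      stop("sample ", s, " (", role, ") carries no AD field", call. = FALSE)
  }
  split_ad <- function(s) {
    parts <- strsplit(ifelse(is.na(s), "0,0", s), ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1L)),
         alt = as.integer(vapply(parts, function(p)
           if (length(p) > 1) p[2] else "0", "")))
  }
  p1 <- split_ad(ad[, sample_roles[["parent1"]]])
  p2 <- split_ad(ad[, sample_roles[["parent2"]]])
  lm <- split_ad(ad[, sample_roles[["LM"]]])
  sm <- split_ad(ad[, sample_roles[["SM"]]])
  ref <- vcfR::getREF(v)
  ids <- vcfR::getID(v)
  out <- data.frame(
    site = ifelse(is.na(ids) | ids == ".",
                  paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v)), ids),
    chromosome = type.convert(vcfR::getCHROM(v), as.is = TRUE),
    pos_bp = vcfR::getPOS(v),
    ref = ref, alt = alt,
    vclass = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "InDel"),
    p1_gt = unname(gt[, sample_roles[["parent1"]]]),
    p2_gt = unname(gt[, sample_roles[["parent2"]]]),
    p1_ref = p1$ref, p1_alt = p1$alt, p2_ref = p2$ref, p2_alt = p2$alt,
    lm_ref = lm$ref, lm_alt = lm$alt, sm_ref = sm$ref, sm_alt = sm$alt,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- sum(multi)
  class(out) <- c("pool_sites", "data.frame")
  out
}

#' Write pooled variant sites as a VCF
#'
#' Emits a VCF v4.2 with `GT:AD` for the four samples (P1, P2, LM, SM).
#' The output is gzip-compressed (use a `.vcf.gz` path).
#'
#' @param sites A `pool_sites` data frame.
#' @param path Output path.
#' @export
write_pool_vcf <- function(sites, path) {
  fix <- cbind(CHROM = as.character(sites$chromosome),
               POS = as.character(sites$pos_bp),
               ID = sites$site, REF = sites$ref, ALT = sites$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  fmt <- function(gt, ref, alt) paste0(gt, ":", ref, ",", alt)
  lm_gt <- "0/1"; sm_gt <- "0/1"
  gt <- cbind(FORMAT = "GT:AD",
              P1 = fmt(sites$p1_gt, sites$p1_ref, sites$p1_alt),
              P2 = fmt(sites$p2_gt, sites$p2_ref, sites$p2_alt),
              LM = fmt(lm_gt, sites$lm_ref, sites$lm_alt),
              SM = fmt(sm_gt, sites$sm_ref, sites$sm_alt))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                   "Description=\"Allelic depths (ref,alt)\">"))
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `comparison`, `log2fc`, `fdr`.
#'
#' @param path File path.
#' @return Data frame ready for [deg_filter()].
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(tab)))
    stop("DEG file needs columns: gene_id, log2fc, fdr", call. = FALSE)
  if (any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE))
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  tab
}

#' Read a gene-annotation interval table
#'
#' TSV with columns `gene_id`, `chromosome`, `start_bp`, `end_bp`
#' (1-based inclusive).
#'
#' @param path File path.
#' @return Data frame for [candidate_genes()].
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% names(tab)))
    stop("annotation file needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tab
}
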