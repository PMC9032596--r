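#' Physical interval of a QTL peak
#'
#' The physical support of a called QTL is the interval spanned by its
#' flanking markers on the genetic map.
#'
#' @param peak One row of a [call_qtl_peaks()] result (or any list with
#'   `marker_left`, `marker_right`, `chromosome`).
#' @param map A `genetic_map` with physical positions (`pos_bp`).
#' @return A one-row `genomic_regions` data frame (`chromosome`,
#'   `start_bp`, `end_bp`, `length_mb`, 1-based inclusive).
#' @export
qtl_physical_interval <- function(peak, map) {
  lk <- map[map$marker == peak$marker_left, ]
  rk <- map[map$marker == peak$marker_right, ]
  if (nrow(lk) != 1 || nrow(rk) != 1 ||
      is.na(lk$pos_bp) || is.na(rk$pos_bp))
    stop("flanking markers lack physical positions", call. = FALSE)
  s <- min(lk$pos_bp, rk$pos_bp)
  e <- max(lk$pos_bp, rk$pos_bp)
  if (s >= e)
    stop("zero-length physical interval for the flanking markers",
         call. = FALSE)
  out <- data.frame(chromosome = peak$chromosome, start_bp = s, end_bp = e,
                    length_mb = region_length_mb(s, e))
  class(out) <- c("genomic_regions", "data.frame")
  out
}

#' Length of a genomic region in Mb
#'
#' `(end - start)/1e6`, rounded half-up to two decimals, the convention of
#' printed QTL-region tables.
#'
#' @param start_bp,end_bp 1-based inclusive endpoints (`start < end`);
#'   vectorised.
#' @return Lengths in Mb, two decimals.
#' @examples
#' region_length_mb(243149664, 251888006)  # 8.74
#' @export
region_length_mb <- function(start_bp, end_bp) {
  if (any(start_bp >= end_bp))
    stop("region start must lie before its end", call. = FALSE)
  floor((end_bp - start_bp) / 1e6 * 100 + 0.5) / 100
}

#' Assemble evidence intervals from QTL and BSA results
#'
#' Normalises heterogeneous interval evidence (QTL physical intervals,
#' linked BSA regions, externally curated QTLs) into one table for
#' clustering.
#'
#' @param regions Data frame with `chromosome`, `start_bp`, `end_bp` and
#'   optionally `source`, `type`, `pve`, `score`.
#' @param source Character scalar or vector naming the evidence (used when
#'   `regions` lacks a `source` column).
#' @param type Evidence class, `"QTL"` or `"BSA"`.
#' @return An `evidence_intervals` data frame.
#' @export
evidence_intervals <- function(regions, source = NULL,
                               type = c("QTL", "BSA")) {
  type <- match.arg(type)
  out <- data.frame(
    chromosome = regions$chromosome,
    start_bp = regions$start_bp, end_bp = regions$end_bp,
    source = if (!is.null(regions$source)) regions$source
             else if (!is.null(source)) source
             else if (!is.null(regions$region)) regions$region
             else if (!is.null(regions$qtl)) regions$qtl
             else sprintf("interval%d", seq_len(nrow(regions))),
    type = if (!is.null(regions$type)) regions$type else type,
    pve = if (!is.null(regions$pve)) regions$pve else NA_real_,
    stringsAsFactors = FALSE)
  if (any(out$start_bp >= out$end_bp))
    stop("evidence intervals must have start < end", call. = FALSE)
  class(out) <- c("evidence_intervals", "data.frame")
  out
}

#' Cluster overlapping evidence intervals
#'
#' Single-linkage clustering on the physical axis: intervals on the same
#' chromosome whose gap is at most `max_gap_bp` fall in one cluster. The
#' result is independent of input order.
#'
#' @param intervals An [evidence_intervals()] table (or several rbind-ed).
#' @param max_gap_bp Maximum tolerated gap (default 2 Mb, chosen so that
#'   BSA regions separated by short uninformative stretches still join one
#'   constitutive locus).
#' @return The input with a `cluster` id column, ordered by chromosome and
#'   start.
#' @export
merge_evidence <- function(intervals, max_gap_bp = 2e6) {
  iv <- intervals[order(intervals$chromosome, intervals$start_bp,
                        intervals$end_bp, intervals$source), ]
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(iv$chromosome),
    ranges = IRanges::IRanges(start = iv$start_bp, end = iv$end_bp))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap_bp + 1)
  # every interval is contained in exactly one reduced range
  ov <- GenomicRanges::findOverlaps(gr, red)
  iv$cluster <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  rownames(iv) <- NULL
  class(iv) <- c("evidence_intervals", "data.frame")
  iv
}

#' Define a constitutive QTL (cQTL) from one evidence cluster
#'
#' A cluster qualifies as a cQTL when it carries evidence of the required
#' types (by default at least one QTL-derived and one BSA-derived
#' interval). The cQTL envelope is the span from the smallest member start
#' to the largest member end; the summed PVE of the member QTLs is
#' reported.
#'
#' @param members An [evidence_intervals()] subset forming one cluster (one
#'   chromosome).
#' @param require_types Evidence types that must all be present
#'   (default `c("QTL", "BSA")`); use `NULL` to accept any cluster.
#' @param name cQTL label.
#' @return A `cqtl_report` list: `name`, `chromosome`, `start_bp`,
#'   `end_bp`, `length_mb`, `members`, `pve_total`; or `NULL` (with a
#'   message) when the membership rule fails.
#' @export
define_cqtl <- function(members, require_types = c("QTL", "BSA"),
                        name = "cQTL") {
  if (length(unique(members$chromosome)) != 1)
    stop("a cQTL cluster must lie on one chromosome", call. = FALSE)
  if (!is.null(require_types) &&
      !all(require_types %in% members$type)) {
    message("cluster on chromosome ", members$chromosome[1],
            " lacks evidence types ",
            paste(setdiff(require_types, members$type), collapse = ", "),
            "; not a cQTL")
    return(NULL)
  }
  s <- min(members$start_bp); e <- max(members$end_bp)
  structure(list(
    name = name,
    chromosome = members$chromosome[1],
    start_bp = s, end_bp = e,
    length_mb = region_length_mb(s, e),
    members = members,
    pve_total = sum(members$pve[members$type == "QTL"], na.rm = TRUE)),
    class = "cqtl_report")
}

#' Filter a differential-expression table
#'
#' Keeps genes significant at `FDR < fdr_max` with `|log2FC| > lfc_min`
#' (both inequalities strict).
#'
#' @param degs Data frame with columns `gene_id`, `log2fc`, `fdr` and
#'   optionally `comparison`.
#' @param fdr_max FDR threshold (default 0.001).
#' @param lfc_min Minimum |log2 fold-change| (default 1).
#' @return The filtered rows.
#' @export
deg_filter <- function(degs, fdr_max = 0.001, lfc_min = 1) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(degs)))
    stop("DEG table needs columns gene_id, log2fc, fdr", call. = FALSE)
  out <- degs[degs$fdr < fdr_max & abs(degs$log2fc) > lfc_min, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate candidate genes inside a cQTL
#'
#' Genes whose annotated interval overlaps the cQTL envelope and that are
#' differentially expressed (after [deg_filter()]) in at least one
#' comparison are the candidates, each annotated with its comparisons and
#' fold-changes.
#'
#' @param report A [define_cqtl()] result.
#' @param annotation Gene intervals: data frame with `gene_id`,
#'   `chromosome`, `start_bp`, `end_bp` (1-based inclusive, same assembly
#'   convention as the regions).
#' @param degs DEG table (see [deg_filter()]); filtering is applied here.
#' @param fdr_max,lfc_min Passed to [deg_filter()].
#' @return A data frame of candidates: `gene_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `comparison`, `log2fc`, `direction`, with the full envelope
#'   gene list in `attr(, "genes_in_region")`.
#' @export
candidate_genes <- function(report, annotation, degs, fdr_max = 0.001,
                            lfc_min = 1) {
  if (!report$chromosome %in% unique(annotation$chromosome))
    stop("annotation lacks chromosome ", report$chromosome,
         "; unmatched names: ",
         paste(utils::head(setdiff(unique(annotation$chromosome),
                                   report$chromosome), 5), collapse = ", "),
         call. = FALSE)
  inreg <- annotation[annotation$chromosome == report$chromosome &
                        annotation$start_bp <= report$end_bp &
                        annotation$end_bp >= report$start_bp, ,
                      drop = FALSE]
  de <- deg_filter(degs, fdr_max, lfc_min)
  hits <- merge(inreg, de, by = "gene_id")
  if (nrow(hits) > 0) {
    hits$direction <- ifelse(hits$log2fc > 0, "up", "down")
    if (!"comparison" %in% names(hits)) hits$comparison <- NA_character_
    hits <- hits[order(hits$start_bp, hits$gene_id, hits$comparison),
                 c("gene_id", "chromosome", "start_bp", "end_bp",
                   "comparison", "log2fc", "direction")]
  } else {
    hits <- data.frame(gene_id = character(0), chromosome = integer(0),
                       start_bp = numeric(0), end_bp = numeric(0),
                       comparison = character(0), log2fc = numeric(0),
                       direction = character(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  attr(hits, "genes_in_region") <- inreg$gene_id
  hits
}
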