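# Methylation-expression integration: quadrant ("starburst")
# classification, exclusive genomic-region attribution, Table-style count
# matrices, and cross-platform concordance.

REGION_GROUPS <- c("PromoterAssociated", "Enhancer", "TSS_only",
                   "Upstream5pFirstExon", "GeneBodyOnly", "Intergenic")
QUADRANTS <- c("Q1", "Q2", "Q3", "Q4", "none")

#' Exclusive genomic-region assignment of a probe
#'
#' Each probe maps to exactly one group by precedence: the
#' promoter-associated flag, then the enhancer flag, then any
#' TSS200/TSS1500 tag (`TSS_only`), then any 5'UTR/first-exon tag
#' (`Upstream5pFirstExon`), then any gene-body/3'UTR tag
#' (`GeneBodyOnly`), else `Intergenic`. The precedence order is a
#' documented tie-break (the group vocabulary does not define one) and
#' can be overridden.
#'
#' @param annotation `ProbeAnnotation` (any number of rows).
#' @param precedence order in which the first four groups are checked.
#' @return character vector of region groups, one per probe.
#' @export
assign_region <- function(annotation,
                          precedence = c("PromoterAssociated", "Enhancer",
                                         "TSS_only",
                                         "Upstream5pFirstExon",
                                         "GeneBodyOnly")) {
  tags <- split_multi(annotation$gene_region_tags)
  has <- function(t) vapply(tags, function(x) any(x %in% t), logical(1))
  crit <- list(
    PromoterAssociated = annotation$promoter_associated,
    Enhancer = annotation$enhancer,
    TSS_only = has(c("TSS200", "TSS1500")),
    Upstream5pFirstExon = has(c("UTR5", "FirstExon")),
    GeneBodyOnly = has(c("Body", "UTR3"))
  )
  out <- rep("Intergenic", nrow(annotation))
  for (g in rev(precedence)) out[crit[[g]]] <- g
  out
}

#' Quadrant classification of a (delta-beta, logFC) pair
#'
#' Gates are strict (`>`): the thresholds are drawn at the limits of
#' technical noise and points on them stay unclassified. With
#' delta-beta = arterial - venous and logFC = arterial - venous:
#' Q1 = hypomethylated and up-regulated in arterial (delta < -t_m,
#' logFC > +t_e); Q2 = hypermethylated and up (concordant);
#' Q3 = hypermethylated and down, i.e. hypomethylated and up in venous
#' (the reciprocal partner of Q1); Q4 = hypomethylated and down.
#'
#' @param delta_beta,logfc numeric vectors (recycled to common length).
#' @param config `AnalysisConfig` supplying `delta_beta_cutoff` (t_m) and
#'   `logfc_cutoff` (t_e).
#' @return character vector of labels Q1/Q2/Q3/Q4/none.
#' @export
classify_quadrant <- function(delta_beta, logfc,
                              config = analysis_config()) {
  tm <- config$delta_beta_cutoff
  te <- config$logfc_cutoff
  n <- max(length(delta_beta), length(logfc))
  delta_beta <- rep_len(delta_beta, n)
  logfc <- rep_len(logfc, n)
  out <- rep("none", n)
  out[delta_beta < -tm & logfc > te] <- "Q1"
  out[delta_beta > tm & logfc > te] <- "Q2"
  out[delta_beta > tm & logfc < -te] <- "Q3"
  out[delta_beta < -tm & logfc < -te] <- "Q4"
  out
}

#' Integrate methylation and expression per gene
#'
#' Joins the per-probe methylation results to the gene-level expression
#' logFC by gene symbol: every analysable probe of a gene receives the
#' gene's single logFC, a per-probe quadrant label, and its exclusive
#' region group. Probes annotated to several genes contribute one row per
#' gene. The promoter-probe fraction counts the gene's probes whose
#' region tags include TSS200/TSS1500 among all its analysable probes.
#' Genes with no expression record (or no surviving probe) are skipped
#' and counted in the attached log.
#'
#' @param dmps `DmpRecords` for all analysable probes.
#' @param de `DeRecords` (gene symbols must be unique).
#' @param annotation `ProbeAnnotation`.
#' @param config `AnalysisConfig`.
#' @return data.frame of class `IntegrationRecords`, one row per
#'   (gene, probe): gene, logfc, probe_id, delta_beta, quadrant,
#'   region_group, is_promoter_probe; per-gene summary in attribute
#'   `gene_summary` (gene, logfc, n_promoter_probes, n_probes,
#'   promoter_probe_fraction); skip counts in attribute `log`.
#' @export
integrate_gene <- function(dmps, de, annotation,
                           config = analysis_config()) {
  if (anyDuplicated(de$gene))
    stop("duplicate gene symbols in expression results", call. = FALSE)
  idx <- match(dmps$probe_id, annotation$probe_id)
  gsyms <- split_multi(annotation$gene_symbols[idx])
  tags <- split_multi(annotation$gene_region_tags[idx])
  region <- assign_region(annotation[idx, , drop = FALSE])

  nper <- lengths(gsyms)
  rows <- rep(seq_len(nrow(dmps)), nper)
  long <- data.frame(
    gene = unlist(gsyms),
    probe_id = dmps$probe_id[rows],
    delta_beta = dmps$delta_beta[rows],
    region_group = region[rows],
    tag = unlist(lapply(tags, function(x) x)),  # parallel to gene list
    stringsAsFactors = FALSE
  )
  long$is_promoter_probe <- long$tag %in% c("TSS200", "TSS1500")

  de_idx <- match(long$gene, de$gene)
  skipped_genes <- setdiff(long$gene, de$gene)
  long <- long[!is.na(de_idx), , drop = FALSE]
  long$logfc <- de$logfc[de_idx[!is.na(de_idx)]]
  long$quadrant <- classify_quadrant(long$delta_beta, long$logfc, config)
  long <- long[order(long$gene, long$probe_id),
               c("gene", "logfc", "probe_id", "delta_beta", "quadrant",
                 "region_group", "is_promoter_probe")]
  rownames(long) <- NULL

  n_probes <- tapply(long$probe_id, long$gene, length)
  n_prom <- tapply(long$is_promoter_probe, long$gene, sum)
  genes <- sort(unique(long$gene))
  summary <- data.frame(
    gene = genes,
    logfc = de$logfc[match(genes, de$gene)],
    n_promoter_probes = as.integer(n_prom[genes]),
    n_probes = as.integer(n_probes[genes]),
    promoter_probe_fraction = as.integer(n_prom[genes]) /
      as.integer(n_probes[genes]),
    stringsAsFactors = FALSE
  )
  attr(long, "gene_summary") <- summary
  attr(long, "log") <- list(genes_without_expression =
                              length(skipped_genes))
  class(long) <- c("IntegrationRecords", "data.frame")
  long
}

#' Quadrant-by-region count table
#'
#' For each (overlapping) region family -- all probes; probes within 1500
#' bp upstream, 5'UTR or first exon; TSS probes excluding 5'UTR/first
#' exon; enhancer-flagged; promoter-flagged; gene-body-only -- counts the
#' probes falling in each quadrant, plus the family totals and the
#' proportions of each count to its family total. Families are computed
#' from tags/flags directly and overlap by design (they are not the
#' exclusive [assign_region()] map). Probes appearing under several genes
#' are counted once, with a single quadrant label (the first non-`none`
#' label across its genes, by gene order).
#'
#' @param records `IntegrationRecords`.
#' @param annotation `ProbeAnnotation`.
#' @return list of class `QuadrantRegionTable` with matrices `counts` and
#'   `proportions` (families x \{all, Q1..Q4\}).
#' @export
quadrant_region_table <- function(records, annotation) {
  # one quadrant per probe: first non-none across its gene rows
  recs <- records[order(records$probe_id, records$gene), ]
  nz <- recs[recs$quadrant != "none", ]
  qual <- nz$quadrant[!duplicated(nz$probe_id)]
  names(qual) <- nz$probe_id[!duplicated(nz$probe_id)]
  probes <- unique(recs$probe_id)
  quad <- ifelse(probes %in% names(qual), qual[probes], "none")

  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  tags <- split_multi(ann$gene_region_tags)
  has <- function(t) vapply(tags, function(x) any(x %in% t), logical(1))
  upstream <- has(c("TSS1500", "TSS200", "UTR5", "FirstExon"))
  tss_excl <- has(c("TSS1500", "TSS200")) & !has(c("UTR5", "FirstExon"))
  body_only <- has(c("Body", "UTR3")) &
    !has(c("TSS1500", "TSS200", "UTR5", "FirstExon"))
  fams <- list(
    All = rep(TRUE, length(probes)),
    Upstream1500_5pUTR_1stExon = upstream,
    TSS_excluding_5pUTR_1stExon = tss_excl,
    Enhancer = ann$enhancer,
    PromoterAssociated = ann$promoter_associated,
    GeneBodyOnly = body_only
  )
  counts <- t(vapply(fams, function(f) {
    c(all = sum(f),
      vapply(c("Q1", "Q2", "Q3", "Q4"),
             function(q) sum(f & quad == q), numeric(1)))
  }, numeric(5)))
  props <- counts / counts[, "all"]
  props[counts[, "all"] == 0, ] <- NA_real_
  out <- list(counts = counts, proportions = props)
  class(out) <- "QuadrantRegionTable"
  out
}

#' Cross-platform concordance
#'
#' Pearson correlation and mean absolute difference between matched
#' methylation measurements from the array and a second (locus-specific)
#' platform.
#'
#' @param array_beta,second_platform_beta numeric vectors of matched
#'   values (>= 3).
#' @return list: `pearson_r`, `mean_abs_diff`, `n`.
#' @export
platform_concordance <- function(array_beta, second_platform_beta) {
  array_beta <- as.numeric(array_beta)
  second_platform_beta <- as.numeric(second_platform_beta)
  if (length(array_beta) != length(second_platform_beta))
    stop("vectors differ in length", call. = FALSE)
  if (length(array_beta) < 3)
    stop("need >= 3 matched measurements", call. = FALSE)
  if (stats::sd(array_beta) == 0 || stats::sd(second_platform_beta) == 0)
    stop("degenerate input: constant vector has undefined correlation",
         call. = FALSE)
  list(pearson_r = stats::cor(array_beta, second_platform_beta),
       mean_abs_diff = mean(abs(array_beta - second_platform_beta)),
       n = length(array_beta))
}
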