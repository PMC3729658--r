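#' avmeth: arterial-versus-venous endothelial methylome analysis
#'
#' Differential DNA methylation analysis for two-channel, Infinium-style
#' methylation arrays in a paired two-group (arterial vs venous endothelial
#' cell) design, with integration against gene-expression log fold changes
#' and a synthetic-data generator carrying a planted-truth ledger.
#'
#' The main entry point is [run_pipeline()]; the stage functions
#' ([qc_filter()], [compute_beta_m()], [normalize_type2()], [call_dmps()],
#' [integrate_gene()], ...) are all exported for programmatic use.
#'
#' @name avmeth-package
#' @keywords internal
"_PACKAGE"

GENE_REGION_TAGS <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body", "UTR3")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
GROUPS <- c("arterial", "venous")

# -------------------------------------------------------------------------
# Probe annotation

#' Construct a probe annotation table
#'
#' The annotation mirrors the columns of an Infinium HM450-style manifest:
#' genomic position (1-based), probe design type (the two Infinium
#' chemistries "I"/"II"), semicolon-separated gene symbols with a parallel
#' list of gene-region tags (TSS200, TSS1500, UTR5, FirstExon, Body, UTR3),
#' and promoter/enhancer flags.
#'
#' @param probe_id character vector, unique probe identifiers.
#' @param chromosome character vector ("1".."22", "X", "Y").
#' @param position integer vector, 1-based base-pair position.
#' @param design_type "I" or "II".
#' @param gene_symbols semicolon-separated gene symbols ("" if intergenic).
#' @param gene_region_tags semicolon-separated region tags, parallel to
#'   `gene_symbols`.
#' @param enhancer,promoter_associated logical flags.
#' @param island_relation CpG-island relation
#'   (Island/Shore/Shelf/OpenSea).
#' @return A `data.frame` of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(probe_id, chromosome, position, design_type,
                             gene_symbols = "", gene_region_tags = "",
                             enhancer = FALSE, promoter_associated = FALSE,
                             island_relation = "OpenSea") {
  n <- length(probe_id)
  ann <- data.frame(
    probe_id = as.character(probe_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    design_type = as.character(design_type),
    gene_symbols = rep_len(as.character(gene_symbols), n),
    gene_region_tags = rep_len(as.character(gene_region_tags), n),
    enhancer = rep_len(as.logical(enhancer), n),
    promoter_associated = rep_len(as.logical(promoter_associated), n),
    island_relation = rep_len(as.character(island_relation), n),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  class(ann) <- c("ProbeAnnotation", "data.frame")
  ann
}

validate_annotation <- function(ann) {
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup) > 0)
    stop("duplicate probe_id in manifest: ", dup[1], call. = FALSE)
  if (anyNA(ann$position))
    stop("unparseable probe position in manifest", call. = FALSE)
  if (any(ann$position < 1))
    stop("manifest positions must be >= 1 (1-based)", call. = FALSE)
  bad <- !ann$design_type %in% c("I", "II")
  if (any(bad))
    stop("design_type must be 'I' or 'II' (probe ",
         ann$probe_id[which(bad)[1]], ")", call. = FALSE)
  ng <- lengths(split_multi(ann$gene_symbols))
  nt <- lengths(split_multi(ann$gene_region_tags))
  if (any(ng != nt))
    stop("gene_symbols and gene_region_tags are not parallel (probe ",
         ann$probe_id[which(ng != nt)[1]], ")", call. = FALSE)
  invisible(ann)
}

# split ";"-packed fields; "" -> character(0)
split_multi <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Read a probe annotation manifest (CSV)
#'
#' The CSV must name at least `probe_id`, `chromosome`, `position` and
#' `design_type`; `gene_symbols`, `gene_region_tags`, `enhancer`,
#' `promoter_associated` and `island_relation` are optional and default to
#' empty / `FALSE` / `"OpenSea"`. Multi-gene probes pack parallel entries
#' with ";" (e.g. gene `"NOS3;NOS3"`, tags `"TSS1500;Body"`).
#'
#' @param path CSV file path.
#' @return A `ProbeAnnotation` data.frame; the number of rows parsed is
#'   attached as attribute `n_parsed`.
#' @export
read_manifest <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("probe_id", "chromosome", "position", "design_type")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.integer(raw$position))
  if (anyNA(pos)) {
    line <- which(is.na(pos))[1]
    stop("unparseable position at manifest data line ", line,
         " (probe ", raw$probe_id[line], ")", call. = FALSE)
  }
  opt_chr <- function(col, default) {
    if (col %in% names(raw)) ifelse(is.na(raw[[col]]), default, raw[[col]])
    else rep(default, nrow(raw))
  }
  opt_lgl <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    v <- toupper(trimws(raw[[col]]))
    v %in% c("TRUE", "T", "1", "YES")
  }
  ann <- probe_annotation(
    probe_id = raw$probe_id,
    chromosome = raw$chromosome,
    position = pos,
    design_type = raw$design_type,
    gene_symbols = opt_chr("gene_symbols", ""),
    gene_region_tags = opt_chr("gene_region_tags", ""),
    enhancer = opt_lgl("enhancer"),
    promoter_associated = opt_lgl("promoter_associated"),
    island_relation = opt_chr("island_relation", "OpenSea")
  )
  attr(ann, "n_parsed") <- nrow(ann)
  ann
}

#' Write a probe annotation manifest (CSV)
#' @param annotation `ProbeAnnotation`.
#' @param path output CSV path.
#' @export
write_manifest <- function(annotation, path) {
  utils::write.csv(as.data.frame(annotation), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# -------------------------------------------------------------------------
# Sample sheet

#' Construct / read / write a sample sheet
#'
#' A sample sheet has columns `sample_id`, `group` (arterial/venous) and
#' `pair_id` (placenta of origin for the paired design). Sample ids must be
#' unique and each pair id may appear at most once per group.
#'
#' @param sample_id,group,pair_id character vectors.
#' @return data.frame of class `SampleSheet`.
#' @export
sample_sheet <- function(sample_id, group, pair_id) {
  sheet <- data.frame(sample_id = as.character(sample_id),
                      group = as.character(group),
                      pair_id = as.character(pair_id),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (!all(sheet$group %in% GROUPS))
    stop("group must be one of: ", paste(GROUPS, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet[, c("group", "pair_id")]))
    stop("a pair_id appears more than once within a group", call. = FALSE)
  class(sheet) <- c("SampleSheet", "data.frame")
  sheet
}

#' @rdname sample_sheet
#' @param path CSV path.
#' @export
read_sample_sheet <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  sample_sheet(raw$sample_id, raw$group, raw$pair_id)
}

#' @rdname sample_sheet
#' @param sheet a `SampleSheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# -------------------------------------------------------------------------
# Matrix TSV IO (row label column "probe_id"; 6 significant digits default)

#' Read / write a labelled numeric matrix as TSV
#'
#' The text matrix format used throughout: tab-separated, first column
#' holds row labels under a header name (default `"probe_id"`), remaining
#' columns are samples. Values use a decimal point, no thousands
#' separators; writing rounds to `digits` significant digits (default 6),
#' so write-then-read round-trips are bit-identical at that precision.
#'
#' @param path TSV path.
#' @param label_col name of the row-label column.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, label_col = "probe_id") {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!label_col %in% names(raw))
    stop("matrix file ", path, " lacks label column '", label_col, "'",
         call. = FALSE)
  labs <- as.character(raw[[label_col]])
  m <- as.matrix(raw[, setdiff(names(raw), label_col), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with dimnames.
#' @param digits significant digits written (default 6).
#' @export
write_matrix_tsv <- function(m, path, label_col = "probe_id", digits = 6) {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label_col
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# -------------------------------------------------------------------------
# ArrayDataset

#' Assemble an array dataset
#'
#' Bundles the two-channel intensities (methylated `meth`, unmethylated
#' `unmeth`), detection p-values, optional negative-control intensities,
#' the probe annotation and the sample sheet, with all matrices aligned on
#' shared probe and sample labels.
#'
#' @param annotation `ProbeAnnotation`.
#' @param meth,unmeth non-negative intensity matrices (probes x samples).
#' @param detection_p matrix in \[0,1\] or `NULL` (compute later from
#'   negative controls via [compute_detection_p()]).
#' @param samples `SampleSheet`.
#' @param negctrl optional negative-control intensity matrix
#'   (controls x samples).
#' @param qc_log list carried along (alignment drops recorded here).
#' @return list of class `ArrayDataset`.
#' @export
array_dataset <- function(annotation, meth, unmeth, detection_p, samples,
                          negctrl = NULL, qc_log = list()) {
  stopifnot(inherits(annotation, "ProbeAnnotation"),
            inherits(samples, "SampleSheet"))
  if (min(meth, na.rm = TRUE) < 0 || min(unmeth, na.rm = TRUE) < 0)
    stop("negative intensity in meth/unmeth matrix", call. = FALSE)

  mats <- list(meth = meth, unmeth = unmeth)
  if (!is.null(detection_p)) mats$detection_p <- detection_p

  probes <- Reduce(intersect,
                   c(list(annotation$probe_id), lapply(mats, rownames)))
  samps <- Reduce(intersect,
                  c(list(samples$sample_id), lapply(mats, colnames)))
  if (length(samps) == 0)
    stop("zero overlapping samples between matrices and sample sheet",
         call. = FALSE)
  miss_sheet <- setdiff(samples$sample_id, samps)
  if (length(miss_sheet) > 0)
    stop("sample sheet lists sample(s) absent from matrices: ",
         paste(miss_sheet, collapse = ", "), call. = FALSE)
  # preserve annotation probe order and sheet sample order
  probes <- annotation$probe_id[annotation$probe_id %in% probes]
  samps <- samples$sample_id[samples$sample_id %in% samps]

  dropped <- lapply(mats, function(m) setdiff(rownames(m), probes))
  n_dropped <- sum(lengths(dropped) > 0)
  if (n_dropped > 0 || length(probes) < nrow(annotation)) {
    qc_log$alignment <- list(
      probes_kept = length(probes),
      probes_dropped_per_file = lengths(dropped),
      annotation_only = sum(!annotation$probe_id %in% probes)
    )
  }
  mats <- lapply(mats, function(m) m[probes, samps, drop = FALSE])
  if (!is.null(negctrl)) negctrl <- negctrl[, samps, drop = FALSE]

  ds <- list(annotation = annotation[match(probes, annotation$probe_id), ],
             meth = mats$meth, unmeth = mats$unmeth,
             detection_p = mats$detection_p,
             negctrl = negctrl,
             samples = samples[match(samps, samples$sample_id), ],
             qc_log = qc_log)
  class(ds$annotation) <- c("ProbeAnnotation", "data.frame")
  class(ds$samples) <- c("SampleSheet", "data.frame")
  class(ds) <- "ArrayDataset"
  ds
}

#' Read an array dataset from TSV/CSV files
#'
#' Matrices are aligned by label intersection (never positionally); any
#' probes missing from one of the files are dropped and recorded in the
#' dataset's `qc_log`. A sample listed in the sheet but absent from the
#' matrices is a hard error.
#'
#' @param meth_path,unmeth_path,detp_path TSV matrix paths (`detp_path`
#'   may be `NULL`).
#' @param sheet_path sample sheet CSV.
#' @param manifest_path probe annotation CSV.
#' @return `ArrayDataset`.
#' @export
read_array_dataset <- function(meth_path, unmeth_path, detp_path,
                               sheet_path, manifest_path) {
  array_dataset(
    annotation = read_manifest(manifest_path),
    meth = read_matrix_tsv(meth_path),
    unmeth = read_matrix_tsv(unmeth_path),
    detection_p = if (!is.null(detp_path)) read_matrix_tsv(detp_path),
    samples = read_sample_sheet(sheet_path)
  )
}

#' Read a gene-level log2 expression matrix
#'
#' @param path TSV with label column `gene`.
#' @param sheet `SampleSheet` to align samples against.
#' @return list of class `ExpressionMatrix` with elements `values`
#'   (genes x samples, log2 units) and `samples`.
#' @export
read_expression <- function(path, sheet) {
  values <- read_matrix_tsv(path, label_col = "gene")
  expression_matrix(values, sheet)
}

#' @rdname read_expression
#' @param values genes x samples numeric matrix, log2 expression units,
#'   rownames = gene symbols (must be unique).
#' @export
expression_matrix <- function(values, sheet) {
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  keep <- intersect(sheet$sample_id, colnames(values))
  miss <- setdiff(sheet$sample_id, keep)
  if (length(miss) > 0)
    stop("expression matrix lacks sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  em <- list(values = values[, sheet$sample_id, drop = FALSE],
             samples = sheet)
  class(em) <- "ExpressionMatrix"
  em
}

# -------------------------------------------------------------------------
# DMP result writers

#' Write the DMP result table (TSV) and a BED track
#'
#' The TSV has one row per probe with group means, delta-beta, moderated t,
#' p, BH-adjusted p, and the DMP call. The BED is 0-based half-open
#' (UCSC dialect), single-bp intervals: `chrom start end name score` with
#' `score = round(1000 * |delta_beta|)` and `name = probe_id`. Probes
#' without coordinates in the annotation are skipped in the BED and
#' counted in the returned log.
#'
#' @param records DMP record data.frame from [call_dmps()].
#' @param path output TSV path.
#' @export
write_dmp_table <- function(records, path) {
  cols <- c("probe_id", "mean_beta_arterial", "mean_beta_venous",
            "delta_beta", "t_stat", "df", "p_value", "adj_p", "is_dmp",
            "direction")
  df <- as.data.frame(records)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dmp_table
#' @param annotation `ProbeAnnotation` supplying coordinates.
#' @return for `write_dmp_bed`, invisibly a list with `n_written` and
#'   `n_skipped` (probes lacking coordinates).
#' @export
write_dmp_bed <- function(records, annotation, path) {
  idx <- match(records$probe_id, annotation$probe_id)
  ok <- !is.na(idx)
  ann <- annotation[idx[ok], , drop = FALSE]
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0) {                # paste0() pads zero-length args
    writeLines(character(0), path)
    return(invisible(list(n_written = 0L, n_skipped = sum(!ok))))
  }
  bed <- data.frame(
    chrom = paste0("chr", ann$chromosome),
    start = ann$position - 1L,          # 0-based half-open
    end = ann$position,
    name = rec$probe_id,
    score = round(1000 * abs(rec$delta_beta)),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(list(n_written = sum(ok), n_skipped = sum(!ok)))
}
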