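# QC filtering, beta/M computation, simplified type-II -> type-I quantile
# normalization, global-methylation summary, variability selection and
# hierarchical clustering.

#' Analysis configuration
#'
#' Holds the thresholds used throughout the pipeline: the detection
#' p-value QC cutoff (probes failing in *any* sample are removed), the
#' BH-adjusted p cutoff and the inclusive delta-beta effect-size cutoff
#' for DMP calling, the (strict) delta-beta and logFC gates of the
#' quadrant classification, the coefficient-of-variation cutoff and
#' top-N for variable-probe selection, and the inference options.
#'
#' The DMP delta-beta rule (>= 0.10, inclusive) and the quadrant gate
#' (> 0.10, strict, "limits of technical noise") are deliberately separate
#' entries.
#'
#' @param detection_p_cutoff detection p QC threshold (default 0.05).
#' @param fdr_cutoff BH-adjusted p threshold, inclusive (default 0.05).
#' @param delta_beta_cutoff DMP |delta-beta| threshold, inclusive
#'   (default 0.10).
#' @param logfc_cutoff expression gate for quadrants, strict (default 0.5).
#' @param cv_cutoff SD/mean threshold for variable probes (default 0.4).
#' @param top_n_variable probes kept for the heatmap clustering
#'   (default 1000).
#' @param use_moderated_t use empirical-Bayes moderated t (default TRUE).
#' @param paired_design test on per-pair differences (default FALSE; the
#'   published analysis did not mention a pairing term, but pairs exist
#'   and paired mode is recommended when they do).
#' @param min_dmr_probes,max_dmr_gap DMR chaining parameters.
#' @param seed integer seed recorded with the run.
#' @return list of class `AnalysisConfig`.
#' @export
analysis_config <- function(detection_p_cutoff = 0.05, fdr_cutoff = 0.05,
                            delta_beta_cutoff = 0.10, logfc_cutoff = 0.5,
                            cv_cutoff = 0.4, top_n_variable = 1000L,
                            use_moderated_t = TRUE, paired_design = FALSE,
                            min_dmr_probes = 3L, max_dmr_gap = 1000L,
                            seed = 1L) {
  cfg <- list(detection_p_cutoff = detection_p_cutoff,
              fdr_cutoff = fdr_cutoff,
              delta_beta_cutoff = delta_beta_cutoff,
              logfc_cutoff = logfc_cutoff, cv_cutoff = cv_cutoff,
              top_n_variable = as.integer(top_n_variable),
              use_moderated_t = isTRUE(use_moderated_t),
              paired_design = isTRUE(paired_design),
              min_dmr_probes = as.integer(min_dmr_probes),
              max_dmr_gap = as.integer(max_dmr_gap),
              seed = as.integer(seed))
  cuts <- c(cfg$detection_p_cutoff, cfg$fdr_cutoff, cfg$delta_beta_cutoff,
            cfg$logfc_cutoff, cfg$cv_cutoff)
  if (any(cuts <= 0)) stop("all cutoffs must be strictly positive",
                           call. = FALSE)
  if (cfg$top_n_variable < 2) stop("top_n_variable must be >= 2",
                                   call. = FALSE)
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}

#' Detection p-values from negative-control probes
#'
#' Per sample, a Normal(mu, sigma) is fitted to the negative-control total
#' intensities; each probe's detection p is the upper-tail probability of
#' its total intensity (meth + unmeth) under that background model. If the
#' dataset already carries a detection-p matrix it is returned unchanged.
#'
#' @param dataset `ArrayDataset` with `negctrl` of >= 10 control probes.
#' @return the dataset with `detection_p` filled in.
#' @export
compute_detection_p <- function(dataset) {
  if (!is.null(dataset$detection_p)) return(dataset)
  if (is.null(dataset$negctrl) || nrow(dataset$negctrl) < 10)
    stop("need >= 10 negative-control probes to estimate detection p; ",
         "supply a detection_p matrix instead", call. = FALSE)
  total <- dataset$meth + dataset$unmeth
  mu <- colMeans(dataset$negctrl)
  sd <- apply(dataset$negctrl, 2, stats::sd)
  p <- stats::pnorm(sweep(sweep(total, 2, mu), 2, sd, "/"),
                    lower.tail = FALSE)
  dimnames(p) <- dimnames(total)
  dataset$detection_p <- p
  dataset
}

#' Quality-filter an array dataset
#'
#' Removes (a) any probe with detection p above the cutoff in *any*
#' sample and (b) all probes on chromosomes X and Y (to eliminate sex
#' bias). Both counts are recorded separately in the dataset's `qc_log`;
#' surviving probe order is preserved.
#'
#' @param dataset `ArrayDataset` with detection p available.
#' @param config `AnalysisConfig`.
#' @return filtered `ArrayDataset`.
#' @export
qc_filter <- function(dataset, config = analysis_config()) {
  if (is.null(dataset$detection_p))
    stop("detection_p missing; run compute_detection_p() first",
         call. = FALSE)
  fail_det <- apply(dataset$detection_p > config$detection_p_cutoff, 1, any)
  sexchr <- dataset$annotation$chromosome %in% c("X", "Y")
  keep <- !fail_det & !sexchr
  if (!any(keep))
    stop("QC removed all probes", call. = FALSE)
  qc <- dataset$qc_log
  qc$detection_failed <- sum(fail_det)
  qc$sex_chromosome <- sum(sexchr)
  qc$failed_both <- sum(fail_det & sexchr)
  qc$probes_in <- length(keep)
  qc$probes_kept <- sum(keep)
  out <- dataset
  out$annotation <- dataset$annotation[keep, , drop = FALSE]
  class(out$annotation) <- c("ProbeAnnotation", "data.frame")
  for (f in c("meth", "unmeth", "detection_p"))
    out[[f]] <- dataset[[f]][keep, , drop = FALSE]
  out$qc_log <- qc
  out
}

#' Compute beta- and M-value matrices
#'
#' beta = (meth + a_b) / (meth + unmeth + 2 a_b), the methylated-signal
#' fraction; M = log2((meth + a_m) / (unmeth + a_m)). Defaults keep the
#' unoffset beta formula (a_b = 0) while protecting M from zero
#' intensities (a_m = 1, negligible at array intensity scale). With both
#' offsets zero, M = log2(beta/(1-beta)) exactly.
#'
#' @param dataset QC-filtered `ArrayDataset`.
#' @param alpha_beta,alpha_m additive intensity offsets.
#' @return list of class `MethylationMatrices`: `beta`, `mvalue`,
#'   `kept_probe_ids`, `annotation`, `samples`, `qc_log`, `normalized`.
#' @export
compute_beta_m <- function(dataset, alpha_beta = 0, alpha_m = 1) {
  tot <- dataset$meth + dataset$unmeth + 2 * alpha_beta
  beta <- (dataset$meth + alpha_beta) / tot
  zero <- tot == 0
  qc <- dataset$qc_log
  if (any(zero)) {
    beta[zero] <- NA_real_
    qc$zero_intensity_cells <- sum(zero)
  }
  mval <- log2((dataset$meth + alpha_m) / (dataset$unmeth + alpha_m))
  mm <- list(beta = beta, mvalue = mval,
             kept_probe_ids = rownames(beta),
             annotation = dataset$annotation,
             samples = dataset$samples,
             qc_log = qc,
             normalized = FALSE)
  class(mm) <- "MethylationMatrices"
  mm
}

#' Simplified type-II -> type-I quantile normalization
#'
#' A documented substitute for within-array probe-type normalization: per
#' sample, type-II beta values are monotonically mapped onto the empirical
#' type-I beta distribution by linear interpolation between order
#' statistics (plotting positions (i - 0.5)/n). Type-I values are left
#' unchanged; M-values are recomputed from the normalized beta via
#' M = log2(beta/(1-beta)) (beta clamped to \[1e-6, 1-1e-6\]). Rank order
#' within type-II probes is preserved per sample. With fewer than 100
#' probes of either type, normalization is skipped with a warning.
#'
#' @param matrices `MethylationMatrices` (carries the annotation).
#' @return normalized `MethylationMatrices` with `normalized = TRUE` and
#'   `normalization_method = "type2_quantile_substitute"`.
#' @export
normalize_type2 <- function(matrices) {
  ann <- matrices$annotation
  is2 <- ann$design_type[match(rownames(matrices$beta),
                               ann$probe_id)] == "II"
  if (sum(is2) < 100 || sum(!is2) < 100) {
    warning("fewer than 100 probes of one design type; ",
            "normalization skipped")
    matrices$qc_log$normalization <- "skipped_too_few_probes"
    return(matrices)
  }
  beta <- matrices$beta
  for (j in seq_len(ncol(beta))) {
    b1 <- sort(beta[!is2, j])
    b2 <- beta[is2, j]
    p2 <- (rank(b2, ties.method = "average") - 0.5) / length(b2)
    grid1 <- (seq_along(b1) - 0.5) / length(b1)
    beta[is2, j] <- stats::approx(grid1, b1, xout = p2, rule = 2)$y
  }
  bc <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  matrices$beta <- beta
  matrices$mvalue <- log2(bc / (1 - bc))
  matrices$normalized <- TRUE
  matrices$normalization_method <- "type2_quantile_substitute"
  matrices
}

#' Global methylation proxy
#'
#' The mean beta over all analysable probes per sample (missing cells
#' excluded), plus per-group arithmetic means of the member samples'
#' values -- the standard proxy for global methylation on these arrays.
#'
#' @param matrices `MethylationMatrices`.
#' @param sheet `SampleSheet` (defaults to the one carried in `matrices`).
#' @return list of class `GlobalMethylationSummary` with
#'   `per_sample_mean_beta` and `per_group_mean_beta`.
#' @export
global_methylation <- function(matrices, sheet = matrices$samples) {
  if (nrow(matrices$beta) == 0) stop("empty beta matrix", call. = FALSE)
  per_sample <- colMeans(matrices$beta, na.rm = TRUE)
  grp <- sheet$group[match(names(per_sample), sheet$sample_id)]
  per_group <- vapply(split(per_sample, grp), mean, numeric(1))
  out <- list(per_sample_mean_beta = per_sample,
              per_group_mean_beta = per_group)
  class(out) <- "GlobalMethylationSummary"
  out
}

probe_cv <- function(beta) {
  mu <- rowMeans(beta, na.rm = TRUE)
  sd <- apply(beta, 1, stats::sd, na.rm = TRUE)
  cv <- sd / mu
  cv[mu == 0] <- NA_real_   # undefined, excluded downstream
  cv
}

#' Variable-probe selection
#'
#' The coefficient of variation is SD/mean of *beta* per probe (M-values
#' can be negative, making SD/mean meaningless). `select_variable_probes`
#' returns probes with CV above `config$cv_cutoff`;
#' `top_variable` returns the `n` probes of largest CV, ties broken by
#' probe id (lexicographic). Probes with mean beta 0 have undefined CV and
#' are excluded.
#'
#' @param matrices `MethylationMatrices`.
#' @param config `AnalysisConfig`.
#' @return character vector of probe ids.
#' @export
select_variable_probes <- function(matrices, config = analysis_config()) {
  cv <- probe_cv(matrices$beta)
  rownames(matrices$beta)[!is.na(cv) & cv > config$cv_cutoff]
}

#' @rdname select_variable_probes
#' @param n number of probes to return.
#' @export
top_variable <- function(matrices, n) {
  cv <- probe_cv(matrices$beta)
  ids <- rownames(matrices$beta)[!is.na(cv)]
  cv <- cv[!is.na(cv)]
  if (n >= length(ids)) {
    if (n > length(ids))
      warning("n (", n, ") exceeds available probes (", length(ids),
              "); returning all")
    n <- length(ids)
  }
  ids[order(-cv, ids)][seq_len(n)]
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on M-values of the selected
#' probes: Euclidean distance, average linkage (both configurable).
#' Deterministic given input; sample order does not affect tree topology
#' or heights.
#'
#' @param matrices `MethylationMatrices`.
#' @param probe_ids probes to cluster on (default: all).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage passed to [stats::hclust()] (default `"average"`).
#' @param values `"mvalue"` (default) or `"beta"`.
#' @return list of class `ClusteringResult`: `selected_probe_ids`,
#'   `merge`, `height`, `sample_order`, `labels`, `k2_labels`, `hclust`.
#' @export
hierarchical_cluster <- function(matrices, probe_ids = NULL,
                                 distance = "euclidean",
                                 linkage = "average",
                                 values = "mvalue") {
  x <- matrices[[values]]
  if (!is.null(probe_ids)) x <- x[probe_ids, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 probes and >= 2 samples to cluster", call. = FALSE)
  d <- switch(distance,
              euclidean = stats::dist(t(x)),
              correlation = stats::as.dist(1 - stats::cor(x)),
              stop("unknown distance: ", distance, call. = FALSE))
  hc <- stats::hclust(d, method = linkage)
  k2 <- stats::cutree(hc, k = 2)
  out <- list(selected_probe_ids = rownames(x),
              merge = hc$merge, height = hc$height,
              sample_order = hc$labels[hc$order],
              labels = hc$labels,
              k2_labels = k2,
              hclust = hc)
  class(out) <- "ClusteringResult"
  out
}
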