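# Per-probe two-group inference: pooled / paired group statistics,
# empirical-Bayes variance moderation (moment estimator on log variances),
# moderated t, Benjamini-Hochberg FDR, DMP calling (test on M-values,
# effect size on beta), DMR block chaining, and expression logFC.

#' Per-feature two-group statistics
#'
#' Unpaired: group means, pooled within-group variance s2 and residual
#' df = n_A + n_V - 2. Paired: the same group means, but s2 is the
#' variance of the per-pair (arterial - venous) differences with
#' df = n_pairs - 1.
#'
#' @param x values matrix (features x samples).
#' @param sheet `SampleSheet` matching the columns of `x`.
#' @param paired use the per-pair differences.
#' @return data.frame: `mean_arterial`, `mean_venous`, `s2`, `df`,
#'   with attributes `n_arterial`, `n_venous`, `n_pairs`, `paired`.
#' @export
group_stats <- function(x, sheet, paired = FALSE) {
  grp <- sheet$group[match(colnames(x), sheet$sample_id)]
  a <- grp == "arterial"; v <- grp == "venous"
  if (sum(a) < 2 || sum(v) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  mean_a <- rowMeans(x[, a, drop = FALSE])
  mean_v <- rowMeans(x[, v, drop = FALSE])
  if (paired) {
    pid <- sheet$pair_id[match(colnames(x), sheet$sample_id)]
    common <- intersect(pid[a], pid[v])
    if (length(common) < 2)
      stop("paired design needs >= 2 complete pairs", call. = FALSE)
    ai <- which(a)[match(common, pid[a])]
    vi <- which(v)[match(common, pid[v])]
    diffs <- x[, ai, drop = FALSE] - x[, vi, drop = FALSE]
    s2 <- apply(diffs, 1, stats::var)
    df <- length(common) - 1
    n_pairs <- length(common)
  } else {
    va <- apply(x[, a, drop = FALSE], 1, stats::var)
    vv <- apply(x[, v, drop = FALSE], 1, stats::var)
    s2 <- ((sum(a) - 1) * va + (sum(v) - 1) * vv) / (sum(a) + sum(v) - 2)
    df <- sum(a) + sum(v) - 2
    n_pairs <- NA_integer_
  }
  out <- data.frame(mean_arterial = mean_a, mean_venous = mean_v,
                    s2 = s2, df = df, row.names = rownames(x))
  attr(out, "n_arterial") <- sum(a)
  attr(out, "n_venous") <- sum(v)
  attr(out, "n_pairs") <- n_pairs
  attr(out, "paired") <- paired
  out
}

# invert trigamma by Newton iteration (monotone decreasing target)
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes variance prior (moment estimator)
#'
#' Estimates the scaled inverse-chi-square prior (d0, s0^2) for the
#' per-feature variances by matching moments of e = log(s2) -
#' digamma(df/2) + log(df/2): solve trigamma(d0/2) = var(e) -
#' trigamma(df/2) for d0 and set s0^2 = exp(mean(e) + digamma(d0/2) -
#' log(d0/2)). When the observed spread of log variances does not exceed
#' what sampling alone implies (var(e) <= trigamma(df/2)), d0 is infinite
#' (fully pooled variance) and s0^2 = exp(mean(e)).
#'
#' Features with zero variance are excluded from estimation; at least 50
#' positive variances are required.
#'
#' @param s_sq numeric vector of per-feature variances.
#' @param d_g residual degrees of freedom (scalar).
#' @return list of class `EbayesHyperparams`: `d0`, `s0_sq`, `n_used`.
#' @export
eb_fit <- function(s_sq, d_g) {
  pos <- s_sq > 0 & is.finite(s_sq)
  if (!any(pos)) stop("all variances are zero", call. = FALSE)
  if (sum(pos) < 50)
    stop("need >= 50 features with positive variance (got ", sum(pos),
         ")", call. = FALSE)
  e <- log(s_sq[pos]) - digamma(d_g / 2) + log(d_g / 2)
  ve <- stats::var(e)
  excess <- ve - trigamma(d_g / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = sum(pos)),
            class = "EbayesHyperparams")
}

#' Moderated t-statistics
#'
#' Shrinks each feature's variance toward the prior,
#' s~2 = (d0 s0^2 + df s2)/(d0 + df), and tests the group-mean difference
#' with t = (mean_A - mean_V) / (s~ * se_scale), df = d0 + df_g, two-sided
#' Student p. Unpaired se_scale = sqrt(1/n_A + 1/n_V); paired
#' se_scale = 1/sqrt(n_pairs). d0 = 0 reduces exactly to the classical
#' t; d0 = Inf uses s~2 = s0^2 with a Normal reference.
#'
#' @param stats_df output of [group_stats()].
#' @param hyper `EbayesHyperparams` (or `list(d0 = 0)` for the plain t).
#' @return data.frame `t_stat`, `df`, `p_value`, `s2_post`.
#' @export
moderated_t <- function(stats_df, hyper) {
  d0 <- hyper$d0
  dg <- stats_df$df
  if (is.infinite(d0)) {
    s2_post <- rep(hyper$s0_sq, nrow(stats_df))
  } else if (d0 == 0) {
    s2_post <- stats_df$s2
  } else {
    s2_post <- (d0 * hyper$s0_sq + dg * stats_df$s2) / (d0 + dg)
  }
  if (isTRUE(attr(stats_df, "paired"))) {
    se_scale <- 1 / sqrt(attr(stats_df, "n_pairs"))
  } else {
    se_scale <- sqrt(1 / attr(stats_df, "n_arterial") +
                     1 / attr(stats_df, "n_venous"))
  }
  diff <- stats_df$mean_arterial - stats_df$mean_venous
  tt <- diff / (sqrt(s2_post) * se_scale)
  df_tot <- d0 + dg
  p <- 2 * stats::pt(abs(tt), df = df_tot, lower.tail = FALSE)
  p[diff == 0] <- 1  # exact zeros (incl. 0/0) test nothing
  tt[is.nan(tt)] <- 0
  data.frame(t_stat = tt, df = df_tot, p_value = p, s2_post = s2_post,
             row.names = rownames(stats_df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_(i) = min over j >= i of m * p_(j) / j on the ascending sort,
#' capped at 1, returned in input order; tied p-values receive identical
#' adjusted values.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m * p[o] / (m:1)))
  adj[order(o)]
}

#' Call differentially methylated probes
#'
#' Group means and the delta-beta effect size come from the beta matrix;
#' the (moderated) t-test runs on the M-value matrix -- the standard
#' dual-scale convention. A probe is a DMP iff BH-adjusted p <=
#' `fdr_cutoff` (inclusive) and |delta_beta| >= `delta_beta_cutoff`
#' (inclusive); direction follows the sign of delta_beta
#' (arterial - venous).
#'
#' @param matrices `MethylationMatrices`.
#' @param sheet `SampleSheet` (defaults to the one in `matrices`).
#' @param config `AnalysisConfig`.
#' @return data.frame of class `DmpRecords` with one row per probe:
#'   probe_id, mean_beta_arterial, mean_beta_venous, delta_beta, t_stat,
#'   df, p_value, adj_p, is_dmp, direction; hyperparameters in attribute
#'   `ebayes`.
#' @export
call_dmps <- function(matrices, sheet = matrices$samples,
                      config = analysis_config()) {
  bstats <- group_stats(matrices$beta, sheet,
                        paired = config$paired_design)
  mstats <- group_stats(matrices$mvalue, sheet,
                        paired = config$paired_design)
  if (config$use_moderated_t) {
    hyper <- eb_fit(mstats$s2, mstats$df[1])
  } else {
    hyper <- list(d0 = 0, s0_sq = NA_real_)
  }
  test <- moderated_t(mstats, hyper)
  adj <- bh_adjust(test$p_value)
  delta <- bstats$mean_arterial - bstats$mean_venous
  is_dmp <- adj <= config$fdr_cutoff &
    abs(delta) >= config$delta_beta_cutoff
  rec <- data.frame(
    probe_id = rownames(matrices$beta),
    mean_beta_arterial = bstats$mean_arterial,
    mean_beta_venous = bstats$mean_venous,
    delta_beta = delta,
    t_stat = test$t_stat, df = test$df, p_value = test$p_value,
    adj_p = adj,
    is_dmp = is_dmp,
    direction = ifelse(!is_dmp, "none",
                       ifelse(delta > 0, "hyper_in_arterial",
                              "hyper_in_venous")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(rec, "ebayes") <- hyper
  class(rec) <- c("DmpRecords", "data.frame")
  rec
}

#' Chain DMPs into differentially methylated regions
#'
#' Within each chromosome, DMPs are sorted by position and consecutive
#' same-direction DMPs are greedily chained while the inter-probe gap is
#' at most `max_gap` and the running set of shared gene symbols stays
#' non-empty; chains of at least `min_probes` members are emitted. The
#' region spans the member probe positions (1-based inclusive), its gene
#' is the first shared symbol, and `mean_delta_beta` averages the member
#' delta-betas.
#'
#' @param dmps `DmpRecords` (only rows with `is_dmp` are used).
#' @param annotation `ProbeAnnotation` supplying coordinates and genes.
#' @param min_probes minimum chain length (default 3).
#' @param max_gap maximum inter-probe gap in bp (default 1000).
#' @return data.frame of class `DmRegions`: gene, chromosome, start, end,
#'   probe_ids (";"-packed), n_probes, direction, mean_delta_beta.
#' @export
aggregate_dmrs <- function(dmps, annotation, min_probes = 3L,
                           max_gap = 1000L) {
  d <- dmps[dmps$is_dmp, , drop = FALSE]
  empty <- data.frame(gene = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      probe_ids = character(0), n_probes = integer(0),
                      direction = character(0),
                      mean_delta_beta = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("DmRegions", "data.frame")
  if (nrow(d) == 0) return(empty)
  idx <- match(d$probe_id, annotation$probe_id)
  d$chromosome <- annotation$chromosome[idx]
  d$position <- annotation$position[idx]
  gsyms <- split_multi(annotation$gene_symbols[idx])
  d <- d[order(d$chromosome, d$position), , drop = FALSE]
  gsyms <- gsyms[order(annotation$chromosome[idx],
                       annotation$position[idx])]

  regions <- list()
  chain <- integer(0); shared <- character(0)
  flush <- function(chain, shared) {
    if (length(chain) < min_probes) return(NULL)
    rows <- d[chain, ]
    data.frame(gene = shared[1],
               chromosome = rows$chromosome[1],
               start = min(rows$position), end = max(rows$position),
               probe_ids = paste(rows$probe_id, collapse = ";"),
               n_probes = length(chain),
               direction = rows$direction[1],
               mean_delta_beta = mean(rows$delta_beta),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(d))) {
    extend <- length(chain) > 0 &&
      d$chromosome[i] == d$chromosome[chain[length(chain)]] &&
      d$direction[i] == d$direction[chain[length(chain)]] &&
      (d$position[i] - d$position[chain[length(chain)]]) <= max_gap &&
      length(intersect(shared, gsyms[[i]])) > 0
    if (extend) {
      chain <- c(chain, i)
      shared <- intersect(shared, gsyms[[i]])
    } else {
      regions[[length(regions) + 1]] <- flush(chain, shared)
      chain <- i
      shared <- gsyms[[i]]
      if (length(shared) == 0) chain <- integer(0)  # intergenic DMP
    }
  }
  regions[[length(regions) + 1]] <- flush(chain, shared)
  regions <- Filter(Negate(is.null), regions)
  if (length(regions) == 0) return(empty)
  out <- do.call(rbind, regions)
  class(out) <- c("DmRegions", "data.frame")
  out
}

#' Gene-expression log fold changes
#'
#' logFC = mean(arterial) - mean(venous) on the log2 expression values;
#' t, p and BH-adjusted p come from the same (moderated) machinery used
#' for methylation.
#'
#' @param expr `ExpressionMatrix`.
#' @param sheet `SampleSheet` (defaults to the one in `expr`).
#' @param config `AnalysisConfig`.
#' @return data.frame of class `DeRecords`: gene, logfc, t_stat,
#'   p_value, adj_p.
#' @export
expression_logfc <- function(expr, sheet = expr$samples,
                             config = analysis_config()) {
  st <- group_stats(expr$values, sheet, paired = config$paired_design)
  hyper <- if (config$use_moderated_t) eb_fit(st$s2, st$df[1])
           else list(d0 = 0, s0_sq = NA_real_)
  test <- moderated_t(st, hyper)
  out <- data.frame(gene = rownames(expr$values),
                    logfc = st$mean_arterial - st$mean_venous,
                    t_stat = test$t_stat, p_value = test$p_value,
                    adj_p = bh_adjust(test$p_value),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "ebayes") <- hyper
  class(out) <- c("DeRecords", "data.frame")
  out
}
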