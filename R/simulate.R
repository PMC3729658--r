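# Synthetic two-channel methylation-array + expression generator with a
# planted-truth ledger. The stated world: 9 placenta-matched pairs per
# group, block-structured DMRs (all probes of a gene share the planted
# shift), a global mean-beta offset applied to the venous group, and a
# subset of DMR genes with reciprocal expression effects.

#' Simulate a probe annotation manifest
#'
#' Lays probes out gene by gene along chromosomes: each gene gets a probe
#' count drawn from `probes_per_gene_range`, probes spaced 50-400 bp apart
#' (so same-gene probes chain within a 1 kb gap), genes separated by >=10
#' kb. Region tags are drawn to cover all six classes; promoter and
#' enhancer flags are Bernoulli with rates 0.25 and 0.17 (the HM450-wide
#' proportions of promoter-associated and enhancer probes). A fraction of
#' intergenic probes (no gene) and sex-chromosome probes are included.
#'
#' @param n_genes number of genes (>= 1).
#' @param probes_per_gene_range length-2 integer vector (min, max).
#' @param sex_chrom_fraction fraction of genes placed on X/Y.
#' @param seed integer seed; identical seed + params give identical output.
#' @param intergenic_fraction fraction of extra probes with no gene.
#' @param type2_fraction fraction of probes with Infinium design type II.
#' @return `ProbeAnnotation`.
#' @export
simulate_manifest <- function(n_genes, probes_per_gene_range = c(3L, 12L),
                              sex_chrom_fraction = 0.03, seed = 1L,
                              intergenic_fraction = 0.05,
                              type2_fraction = 0.72) {
  stopifnot(n_genes >= 1, sex_chrom_fraction >= 0, sex_chrom_fraction <= 1)
  r <- probes_per_gene_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
    stop("probes_per_gene_range must be (min, max) with min <= max",
         call. = FALSE)
  withr::with_seed(seed, {
    rng <- seq.int(r[1], r[2])   # sample() first-arg scalar trap
    n_probes_gene <- rng[sample.int(length(rng), n_genes, replace = TRUE)]
    sexy <- stats::runif(n_genes) < sex_chrom_fraction
    chrom <- ifelse(sexy,
                    sample(c("X", "Y"), n_genes, replace = TRUE,
                           prob = c(0.9, 0.1)),
                    as.character(sample.int(22L, n_genes, replace = TRUE)))
    genes <- sprintf("GENE%05d", seq_len(n_genes))

    n_total <- sum(n_probes_gene)
    gene_of <- rep(genes, n_probes_gene)
    chrom_of <- rep(chrom, n_probes_gene)
    # probe spacing 50-400 bp within a gene; fresh gene start per chromosome
    # cursor advanced by >= 10 kb between genes
    gaps <- sample(50:400, n_total, replace = TRUE)
    gap_sum <- vapply(split(gaps, factor(gene_of, levels = genes)),
                      sum, numeric(1))
    gene_jumps <- sample(10000:50000, n_genes, replace = TRUE)
    gene_starts <- numeric(n_genes)
    cursor <- stats::setNames(rep(1, 24), c(as.character(1:22), "X", "Y"))
    for (g in seq_len(n_genes)) {
      cursor[chrom[g]] <- cursor[chrom[g]] + gene_jumps[g]
      gene_starts[g] <- cursor[chrom[g]]
      cursor[chrom[g]] <- cursor[chrom[g]] + gap_sum[g] + 1
    }
    offs <- stats::ave(gaps, gene_of, FUN = cumsum)
    position <- rep(gene_starts, n_probes_gene) + offs
    # region tag by probe index within gene: upstream block first, then
    # gene-body order, covering all six classes
    within_idx <- stats::ave(seq_len(n_total), gene_of,
                             FUN = seq_along)
    within_n <- rep(n_probes_gene, n_probes_gene)
    frac <- (within_idx - 0.5) / within_n
    tag <- cut(frac, breaks = c(0, 0.15, 0.30, 0.42, 0.54, 0.85, 1),
               labels = c("TSS1500", "TSS200", "UTR5", "FirstExon",
                          "Body", "UTR3"))
    tag <- as.character(tag)

    # a second annotated gene for some probes (bidirectional promoters etc)
    multi <- stats::runif(n_total) < 0.02 & within_idx > 1
    gene_sym <- ifelse(multi, paste(gene_of, gene_of, sep = ";"), gene_of)
    tags2 <- sample(GENE_REGION_TAGS, n_total, replace = TRUE)
    tag_sym <- ifelse(multi, paste(tag, tags2, sep = ";"), tag)

    n_inter <- round(intergenic_fraction * n_total)
    if (n_inter > 0) {
      ichrom <- as.character(sample.int(22L, n_inter, replace = TRUE))
      ipos <- sample.int(2e8L, n_inter)
      chrom_of <- c(chrom_of, ichrom)
      position <- c(position, ipos)
      gene_sym <- c(gene_sym, rep("", n_inter))
      tag_sym <- c(tag_sym, rep("", n_inter))
    }
    n <- n_total + n_inter
    ann <- probe_annotation(
      probe_id = sprintf("cg%08d", seq_len(n)),
      chromosome = chrom_of,
      position = position,
      design_type = ifelse(stats::runif(n) < type2_fraction, "II", "I"),
      gene_symbols = gene_sym,
      gene_region_tags = tag_sym,
      enhancer = stats::runif(n) < 0.17,
      promoter_associated = stats::runif(n) < 0.25,
      island_relation = sample(ISLAND_RELATIONS, n, replace = TRUE,
                               prob = c(0.31, 0.23, 0.10, 0.36))
    )
    ann
  })
}

#' Default noise model for the generator
#'
#' `beta_concentration` controls the Beta noise around each latent
#' methylation fraction (variance mu(1-mu)/(k+1)); 50 makes a planted
#' delta-beta of 0.10 detectable at ~80% power with 9 samples per group.
#' `intensity_scale` is the log-normal location of total probe intensity;
#' background means differ by design type (type II higher) so the
#' normalization stage has a visible artifact to remove.
#'
#' @param intensity_scale median total intensity per probe.
#' @param beta_concentration Beta noise concentration.
#' @param background_mean named means for type I / II additive background.
#' @param pair_sd sd of the per-pair random effect on latent beta.
#' @param expr_sd residual sd of log2 expression.
#' @param expr_pair_sd sd of the per-pair random effect on expression.
#' @param failed_probe_fraction fraction of probes given detection p >
#'   0.05 in at least one sample.
#' @export
noise_defaults <- function(intensity_scale = 10000,
                           beta_concentration = 50,
                           background_mean = c(I = 100, II = 300),
                           pair_sd = 0.01,
                           expr_sd = 0.25,
                           expr_pair_sd = 0.10,
                           failed_probe_fraction = 0.005) {
  list(intensity_scale = intensity_scale,
       beta_concentration = beta_concentration,
       background_mean = background_mean,
       pair_sd = pair_sd, expr_sd = expr_sd, expr_pair_sd = expr_pair_sd,
       failed_probe_fraction = failed_probe_fraction)
}

#' Simulate a paired two-group methylation + expression dataset
#'
#' Per probe a baseline methylation fraction is drawn from a trimodal
#' mixture (modes near 0.05 / 0.5 / 0.9, the shape of real array beta
#' distributions). DMR genes are planted as blocks: every probe of the
#' gene gets the same delta-beta shift, added to the arterial group for
#' direction `hyper_in_arterial`, to the venous group otherwise; planted
#' probes draw their baseline from Uniform(0.1, 0.9 - |delta|) so the
#' shift never clips. The global offset is added to the venous group's
#' latent methylation of every probe. Observed fractions are Beta draws
#' around the latent mean; intensities are `meth = T*m`, `unmeth =
#' T*(1-m)` with log-normal totals `T`, plus additive log-normal
#' background (type II > type I). A subset of DMR genes is reciprocal:
#' their expression gets a planted log2 fold change in the arterial group
#' with sign opposite to the methylation direction. A per-pair random
#' effect is shared by both members of each placenta pair on both
#' platforms. Fully deterministic under `seed`.
#'
#' @param manifest `ProbeAnnotation` (e.g. from [simulate_manifest()]).
#' @param n_pairs number of arterial/venous pairs (>= 2; the study used 9).
#' @param truth list: `n_dmr_genes`, `delta_beta`, `n_reciprocal`,
#'   `logfc`, `global_offset` (venous-group latent shift).
#' @param noise list from [noise_defaults()].
#' @param seed integer seed.
#' @return list with elements `dataset` (`ArrayDataset`), `expression`
#'   (`ExpressionMatrix`) and `truth` (`SimulationTruth`: dmr_ledger,
#'   reciprocal_genes, global_offset, seed, params, plus the latent
#'   matrices `latent_mu` / `latent_beta` for truth-recovery checks).
#' @export
simulate_dataset <- function(manifest, n_pairs = 9L,
                             truth = list(n_dmr_genes = 50L,
                                          delta_beta = 0.3,
                                          n_reciprocal = 20L,
                                          logfc = 1.0,
                                          global_offset = -0.045),
                             noise = noise_defaults(), seed = 1L) {
  stopifnot(n_pairs >= 2, abs(truth$delta_beta) <= 1)
  genes_df <- split_multi(manifest$gene_symbols)
  all_genes <- sort(unique(unlist(genes_df)))
  autosomal <- manifest$chromosome %in% as.character(1:22)
  auto_genes <- sort(unique(unlist(genes_df[autosomal])))
  if (truth$n_dmr_genes > length(auto_genes))
    stop("requested more DMR genes (", truth$n_dmr_genes,
         ") than autosomal genes in manifest (", length(auto_genes), ")",
         call. = FALSE)

  withr::with_seed(seed, {
    sheet <- sample_sheet(
      sample_id = c(sprintf("A%02d", seq_len(n_pairs)),
                    sprintf("V%02d", seq_len(n_pairs))),
      group = rep(GROUPS, each = n_pairs),
      pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2)
    )
    n_probe <- nrow(manifest)
    n_samp <- 2L * n_pairs
    arterial <- sheet$group == "arterial"

    dmr_genes <- sample(auto_genes, truth$n_dmr_genes)
    direction <- sample(c("hyper_in_arterial", "hyper_in_venous"),
                        truth$n_dmr_genes, replace = TRUE)
    primary_gene <- vapply(genes_df, function(g)
      if (length(g)) g[1] else "", character(1))
    probe_sets <- lapply(dmr_genes, function(g)
      manifest$probe_id[primary_gene == g])

    # baselines: trimodal mixture; planted probes get clipping headroom
    comp <- sample(1:3, n_probe, replace = TRUE, prob = c(0.45, 0.15, 0.40))
    mode <- c(0.05, 0.5, 0.9)[comp]
    cb <- 30
    baseline <- stats::rbeta(n_probe, mode * cb, (1 - mode) * cb)
    planted <- manifest$probe_id %in% unlist(probe_sets)
    d <- abs(truth$delta_beta)
    baseline[planted] <- stats::runif(sum(planted), 0.10, 0.90 - d)

    mu <- matrix(baseline, n_probe, n_samp,
                 dimnames = list(manifest$probe_id, sheet$sample_id))
    for (i in seq_along(dmr_genes)) {
      rows <- match(probe_sets[[i]], manifest$probe_id)
      cols <- if (direction[i] == "hyper_in_arterial") arterial else !arterial
      mu[rows, cols] <- mu[rows, cols] + d
    }
    mu[, !arterial] <- mu[, !arterial] + truth$global_offset
    pair_eff <- stats::rnorm(n_pairs, 0, noise$pair_sd)
    mu <- sweep(mu, 2, pair_eff[match(sheet$pair_id,
                                      sprintf("P%02d", seq_len(n_pairs)))],
                "+")
    mu <- pmin(pmax(mu, 0.001), 0.999)

    kappa <- noise$beta_concentration
    m <- matrix(stats::rbeta(n_probe * n_samp, mu * kappa,
                             (1 - mu) * kappa),
                n_probe, n_samp, dimnames = dimnames(mu))

    total <- matrix(stats::rlnorm(n_probe * n_samp,
                                  log(noise$intensity_scale), 0.3),
                    n_probe, n_samp, dimnames = dimnames(mu))
    bg_mean <- noise$background_mean[manifest$design_type]
    bg <- function() matrix(
      stats::rlnorm(n_probe * n_samp, log(rep(bg_mean, n_samp)), 0.3),
      n_probe, n_samp, dimnames = dimnames(mu))
    meth <- total * m + bg()
    unmeth <- total * (1 - m) + bg()

    # detection p: near zero for signal probes; a configurable fraction
    # "fail" (p > 0.05) in 1-3 random samples
    detp <- matrix(stats::rbeta(n_probe * n_samp, 1, 400),
                   n_probe, n_samp, dimnames = dimnames(mu))
    n_fail <- round(noise$failed_probe_fraction * n_probe)
    if (n_fail > 0) {
      fail_rows <- sample.int(n_probe, n_fail)
      for (r in fail_rows) {
        cols <- sample.int(n_samp, sample(1:3, 1))
        detp[r, cols] <- stats::runif(length(cols), 0.051, 1)
      }
    }
    negctrl <- matrix(stats::rlnorm(600L * n_samp, log(150), 0.4),
                      600L, n_samp,
                      dimnames = list(sprintf("neg%04d", 1:600),
                                      sheet$sample_id))

    # expression: baseline + pair effect + planted logFC on arterial for
    # reciprocal genes (sign opposite the methylation direction)
    recip_idx <- seq_len(min(truth$n_reciprocal, truth$n_dmr_genes))
    recip_genes <- dmr_genes[recip_idx]
    recip_lfc <- ifelse(direction[recip_idx] == "hyper_in_arterial",
                        -abs(truth$logfc), abs(truth$logfc))
    n_gene <- length(all_genes)
    expr_base <- stats::rnorm(n_gene, 7, 1.5)
    expr <- matrix(expr_base, n_gene, n_samp,
                   dimnames = list(all_genes, sheet$sample_id))
    epair <- stats::rnorm(n_pairs, 0, noise$expr_pair_sd)
    expr <- sweep(expr, 2,
                  epair[match(sheet$pair_id,
                              sprintf("P%02d", seq_len(n_pairs)))], "+")
    gi <- match(recip_genes, all_genes)
    expr[gi, arterial] <- expr[gi, arterial] + recip_lfc
    expr <- expr + matrix(stats::rnorm(n_gene * n_samp, 0, noise$expr_sd),
                          n_gene, n_samp)

    dataset <- array_dataset(manifest, meth, unmeth, detp, sheet,
                             negctrl = negctrl)
    em <- expression_matrix(expr, sheet)
    truth_out <- structure(list(
      dmr_ledger = data.frame(
        gene = dmr_genes,
        probe_ids = vapply(probe_sets, paste, character(1),
                           collapse = ";"),
        direction = direction,
        planted_delta_beta = ifelse(direction == "hyper_in_arterial",
                                    d, -d),
        stringsAsFactors = FALSE),
      reciprocal_genes = data.frame(
        gene = recip_genes,
        planted_logfc = recip_lfc,
        direction = direction[recip_idx],
        stringsAsFactors = FALSE),
      global_offset = truth$global_offset,
      seed = seed,
      params = list(n_pairs = n_pairs, truth = truth, noise = noise),
      latent_mu = mu,
      latent_beta = m
    ), class = "SimulationTruth")
    list(dataset = dataset, expression = em, truth = truth_out)
  })
}

#' Simulate a second, locus-specific methylation platform
#'
#' Emulates a mass-spectrometry style bisulphite platform measuring CpG
#' *units*: consecutive CpGs are averaged in groups of
#' `cpg_unit_grouping`, truncated Gaussian noise of sd `noise_sd` is
#' added, and values are clipped to \[0,1\].
#'
#' @param beta_truth numeric matrix (CpGs x samples) or vector of true
#'   methylation fractions restricted to the target regions.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param cpg_unit_grouping CpGs averaged per unit.
#' @param seed integer seed.
#' @return matrix (units x samples) of unit-level beta measurements.
#' @export
simulate_second_platform <- function(beta_truth, noise_sd = 0.05,
                                     cpg_unit_grouping = 1L, seed = 1L) {
  stopifnot(noise_sd >= 0, cpg_unit_grouping >= 1)
  if (is.null(dim(beta_truth)))
    beta_truth <- matrix(beta_truth, ncol = 1,
                         dimnames = list(names(beta_truth), "value"))
  if (nrow(beta_truth) == 0)
    stop("empty region set: no CpGs to measure", call. = FALSE)
  unit <- ceiling(seq_len(nrow(beta_truth)) / cpg_unit_grouping)
  avg <- rowsum(beta_truth, unit) / as.vector(table(unit))
  rownames(avg) <- sprintf("unit%04d", seq_len(nrow(avg)))
  withr::with_seed(seed, {
    noisy <- avg + matrix(stats::rnorm(length(avg), 0, noise_sd),
                          nrow(avg), ncol(avg))
  })
  pmin(pmax(noisy, 0), 1)
}
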