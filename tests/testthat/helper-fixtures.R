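# Shared fixtures and independent mini-oracles, all built in code.

# a small hand-written annotation covering every region class
tiny_manifest <- function() {
  probe_annotation(
    probe_id = sprintf("cg%03d", 1:8),
    chromosome = c("1", "1", "1", "1", "7", "X", "2", "2"),
    position = c(100L, 300L, 800L, 1500L, 150690000L, 500L, 900L, 1200L),
    design_type = c("I", "II", "II", "I", "II", "II", "I", "II"),
    gene_symbols = c("GA", "GA", "GA", "GA;GB", "NOS3", "GX", "", "GB"),
    gene_region_tags = c("TSS1500", "TSS200", "UTR5", "Body;FirstExon",
                         "TSS200", "Body", "", "UTR3"),
    enhancer = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    promoter_associated = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                            FALSE, FALSE)
  )
}

tiny_sheet <- function(n_pairs = 2) {
  sample_sheet(
    sample_id = c(sprintf("A%02d", seq_len(n_pairs)),
                  sprintf("V%02d", seq_len(n_pairs))),
    group = rep(c("arterial", "venous"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2)
  )
}

# MethylationMatrices built directly from a beta matrix
mm_from_beta <- function(beta, sheet, annotation = NULL) {
  bc <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  structure(list(beta = beta, mvalue = log2(bc / (1 - bc)),
                 kept_probe_ids = rownames(beta),
                 annotation = annotation, samples = sheet,
                 qc_log = list(), normalized = FALSE),
            class = "MethylationMatrices")
}

# independent brute-force BH step-up: adj_(i) = min_{j>=i} m p_(j)/j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# default small simulation for downstream tests
small_sim <- function(seed = 1, n_genes = 200, n_pairs = 9,
                      truth = list(n_dmr_genes = 20, delta_beta = 0.3,
                                   n_reciprocal = 10, logfc = 1,
                                   global_offset = 0),
                      noise = noise_defaults()) {
  man <- simulate_manifest(n_genes, c(4, 8), sex_chrom_fraction = 0.02,
                           seed = seed)
  simulate_dataset(man, n_pairs, truth, noise, seed = seed + 1000)
}
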