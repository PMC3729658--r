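# fixture dataset built directly from matrices
fixture_dataset <- function(meth, unmeth, detp = NULL, negctrl = NULL,
                            ann = NULL, sheet = NULL) {
  if (is.null(sheet)) sheet <- tiny_sheet(ncol(meth) / 2)
  if (is.null(ann))
    ann <- probe_annotation(rownames(meth),
                            chromosome = "1",
                            position = seq_len(nrow(meth)) * 1000L,
                            design_type = "II")
  array_dataset(ann, meth, unmeth, detp, sheet, negctrl = negctrl)
}

test_that("detection p matches the closed-form Normal tail", {
  set.seed(1)
  sheet <- tiny_sheet(2)
  ids <- c("p1", "p2", "p3")
  negctrl <- matrix(stats::rnorm(20 * 4, 200, 30), 20, 4,
                    dimnames = list(NULL, sheet$sample_id))
  mu <- colMeans(negctrl); sd <- apply(negctrl, 2, stats::sd)
  # probe totals: at the background mean, 10 sd above, and in between
  tot <- rbind(mu, mu + 10 * sd, mu + 2 * sd)
  meth <- tot * 0.6; unmeth <- tot * 0.4
  dimnames(meth) <- dimnames(unmeth) <- list(ids, sheet$sample_id)
  ds <- compute_detection_p(fixture_dataset(meth, unmeth,
                                            negctrl = negctrl))
  expect_equal(unname(ds$detection_p[1, ]), rep(0.5, 4), tolerance = 1e-12)
  expect_true(all(ds$detection_p[2, ] < 1e-15))
  expected <- stats::pnorm(tot[3, ], mu, sd, lower.tail = FALSE)
  expect_equal(unname(ds$detection_p[3, ]), unname(expected),
               tolerance = 1e-12)
  # supplied detection_p short-circuits; too few controls errors
  ds2 <- compute_detection_p(ds)
  expect_identical(ds2$detection_p, ds$detection_p)
  expect_error(compute_detection_p(
    fixture_dataset(meth, unmeth, negctrl = negctrl[1:5, ])),
    "negative-control")
})

test_that("qc_filter applies the any-sample rule and sex removal", {
  set.seed(2)
  n <- 100
  sheet <- tiny_sheet(9)
  ids <- sprintf("cg%03d", 1:n)
  chrom <- rep("3", n)
  chrom[96:100] <- c("X", "X", "Y", "X", "X")   # 5 sex probes
  ann <- probe_annotation(ids, chrom, seq_len(n) * 500L, "II")
  meth <- matrix(500, n, 18, dimnames = list(ids, sheet$sample_id))
  detp <- matrix(0.0001, n, 18, dimnames = list(ids, sheet$sample_id))
  detp[1:6, 3] <- 0.2          # 6 autosomal fail in exactly one sample
  detp[96, 10] <- 0.9          # 1 sex probe also fails detection
  ds <- fixture_dataset(meth, meth, detp, ann = ann, sheet = sheet)
  out <- qc_filter(ds)
  expect_equal(nrow(out$meth), 100 - 7 - 5 + 1)   # 89 remain
  expect_equal(out$qc_log$detection_failed, 7)
  expect_equal(out$qc_log$sex_chromosome, 5)
  expect_equal(out$qc_log$failed_both, 1)
  # a probe failing in exactly 1 of 18 samples is removed
  expect_false("cg001" %in% rownames(out$meth))
  # a perfect-detection X probe is removed
  expect_false("cg099" %in% rownames(out$meth))
  # order of survivors preserved
  expect_identical(rownames(out$meth), ids[ids %in% rownames(out$meth)])
  # clean fixture: nothing removed
  clean <- qc_filter(fixture_dataset(meth[1:10, ], meth[1:10, ],
                                     detp[1:10, ] * 0 + 1e-4,
                                     sheet = sheet))
  expect_equal(nrow(clean$meth), 10)
  # all removed -> hard error
  expect_error(qc_filter(fixture_dataset(meth[1:2, ], meth[1:2, ],
                                         detp[1:2, ] * 0 + 0.5,
                                         sheet = sheet)),
               "all probes")
})

test_that("beta and M formulas and their identity", {
  sheet <- tiny_sheet(1)
  mk <- function(v) matrix(v, 2, 2,
                           dimnames = list(c("a", "b"), sheet$sample_id))
  ds <- fixture_dataset(mk(c(500, 900)), mk(c(500, 100)), sheet = sheet)
  mm <- compute_beta_m(ds)                       # defaults: a_b=0, a_m=1
  expect_equal(unname(mm$beta[1, 1]), 0.5)
  expect_equal(unname(mm$mvalue[1, 1]), 0)       # 501/501 symmetric
  expect_equal(unname(mm$beta[2, 1]), 0.9)
  expect_equal(unname(mm$mvalue[2, 1]), log2(901 / 101))
  mm0 <- compute_beta_m(ds, alpha_beta = 0, alpha_m = 0)
  expect_equal(unname(mm0$mvalue[2, 1]), log2(900 / 100))
  # algebraic identity at zero offsets
  expect_equal(mm0$mvalue, log2(mm0$beta / (1 - mm0$beta)),
               tolerance = 1e-12)
  # zero total intensity -> missing, logged
  dz <- fixture_dataset(mk(c(0, 1)), mk(c(0, 1)), sheet = sheet)
  mmz <- compute_beta_m(dz)
  expect_true(is.na(mmz$beta[1, 1]))
  expect_equal(mmz$qc_log$zero_intensity_cells, 2)
})

test_that("type-II normalization: identity, planted offset, independence", {
  set.seed(3)
  sheet <- tiny_sheet(2)
  n1 <- 150
  b1 <- stats::runif(n1)
  ann <- probe_annotation(sprintf("cg%04d", 1:(2 * n1)), "1",
                          seq_len(2 * n1) * 100L,
                          rep(c("I", "II"), each = n1))
  # type II carries the same values as type I: map must be the identity
  beta <- matrix(rep(c(b1, b1), 4), 2 * n1, 4,
                 dimnames = list(ann$probe_id, sheet$sample_id))
  mm <- mm_from_beta(beta, sheet, ann)
  out <- normalize_type2(mm)
  expect_equal(out$beta, beta, tolerance = 1e-9)
  expect_true(out$normalized)

  # uniform +0.1 shift on type II is removed to < 0.01
  b2 <- pmin(b1 + 0.1, 0.999)
  beta2 <- matrix(rep(c(b1, b2), 4), 2 * n1, 4,
                  dimnames = list(ann$probe_id, sheet$sample_id))
  out2 <- normalize_type2(mm_from_beta(beta2, sheet, ann))
  gap <- abs(mean(out2$beta[1:n1, 1]) - mean(out2$beta[(n1 + 1):(2 * n1), 1]))
  expect_lt(gap, 0.01)
  # rank order within type II preserved per sample
  expect_identical(order(out2$beta[(n1 + 1):(2 * n1), 2]),
                   order(beta2[(n1 + 1):(2 * n1), 2]))
  # M recomputed via logit2
  bc <- pmin(pmax(out2$beta, 1e-6), 1 - 1e-6)
  expect_equal(out2$mvalue, log2(bc / (1 - bc)), tolerance = 1e-12)

  # samples processed independently: permuting columns permutes outputs
  perm <- c(3, 1, 4, 2)
  outp <- normalize_type2(mm_from_beta(beta2[, perm], sheet, ann))
  expect_equal(outp$beta, out2$beta[, perm])

  # too few probes of one type: warn and skip
  expect_warning(sk <- normalize_type2(mm_from_beta(beta2[c(1:30, 151:250), ],
                                                    sheet, ann)),
                 "skipped")
  expect_false(sk$normalized)
})

test_that("global methylation proxy", {
  sheet <- tiny_sheet(2)
  beta <- matrix(0.4, 5, 4, dimnames = list(paste0("p", 1:5),
                                            sheet$sample_id))
  g <- global_methylation(mm_from_beta(beta, sheet))
  expect_equal(unname(g$per_sample_mean_beta), rep(0.4, 4))
  expect_equal(unname(g$per_group_mean_beta), c(0.4, 0.4))
  # group mean is the arithmetic mean of member samples
  beta[, 1] <- 0.8
  g2 <- global_methylation(mm_from_beta(beta, sheet))
  expect_equal(unname(g2$per_group_mean_beta["arterial"]),
               mean(g2$per_sample_mean_beta[1:2]))
  # single-sample group equals that sample's mean
  s1 <- sample_sheet(c("A01", "V01", "V02"),
                     c("arterial", "venous", "venous"),
                     c("P1", "P1", "P2"))
  b1 <- matrix(c(0.2, 0.6, 0.3, 0.5, 0.1, 0.9), 2, 3,
               dimnames = list(c("x", "y"), s1$sample_id))
  g3 <- global_methylation(mm_from_beta(b1, s1), s1)
  expect_equal(unname(g3$per_group_mean_beta["arterial"]),
               mean(b1[, "A01"]))
})

test_that("variability selection: CV on beta, cutoffs and ties", {
  sheet <- tiny_sheet(1)
  beta <- rbind(varp = c(0.2, 0.6), flat = c(0.5, 0.5),
                zero = c(0, 0), tie_b = c(0.2, 0.4), tie_a = c(0.3, 0.6))
  colnames(beta) <- sheet$sample_id
  mm <- mm_from_beta(beta, sheet)
  # hand formula: sd(0.2,0.6)/mean = 0.2828/0.4
  expect_equal(sd(c(0.2, 0.6)) / 0.4, 0.7071, tolerance = 1e-4)
  sel <- select_variable_probes(mm, analysis_config(cv_cutoff = 0.4))
  expect_true("varp" %in% sel)
  expect_false("flat" %in% sel)        # CV 0
  expect_false("zero" %in% sel)        # undefined CV excluded
  # tie_a and tie_b have identical CV; lexicographic tie-break
  expect_equal(top_variable(mm, 3), c("varp", "tie_a", "tie_b"))
  expect_warning(allp <- top_variable(mm, 99), "exceeds")
  expect_equal(length(allp), 4)        # zero-mean probe excluded
})

test_that("hierarchical clustering: structure, duplicates, invariance", {
  set.seed(6)
  s <- small_sim(seed = 41, n_genes = 120,
                 truth = list(n_dmr_genes = 36, delta_beta = 0.4,
                              n_reciprocal = 0, logfc = 0,
                              global_offset = 0))
  mm <- compute_beta_m(qc_filter(s$dataset))
  sel <- select_variable_probes(mm)
  cl <- hierarchical_cluster(mm, sel)
  expect_equal(nrow(cl$merge), ncol(mm$beta) - 1)
  expect_true(all(diff(cl$height) >= -1e-12))
  expect_equal(adjusted_rand(cl$k2_labels, mm$samples$group), 1)

  # duplicated sample merges first at height 0
  beta <- mm$beta[sel[1:50], ]
  beta[, 2] <- beta[, 1]
  cld <- hierarchical_cluster(mm_from_beta(beta, mm$samples))
  expect_equal(cld$height[1], 0)
  expect_setequal(abs(cld$merge[1, ]), c(1, 2))

  # permuting sample order leaves heights and the k2 partition alone
  # (compare on the same logit-recomputed M-values)
  cl <- hierarchical_cluster(mm_from_beta(mm$beta[sel, ], mm$samples))
  perm <- sample(ncol(mm$beta))
  clp <- hierarchical_cluster(mm_from_beta(mm$beta[sel, perm],
                                           mm$samples))
  expect_equal(sort(clp$height), sort(cl$height))
  expect_equal(adjusted_rand(clp$k2_labels[cl$labels], cl$k2_labels), 1)
  expect_error(hierarchical_cluster(mm, sel[1]), ">= 2 probes")
})
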