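mk_mat <- function(rows, sheet) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), sheet$sample_id)
  m
}

test_that("group_stats: pooled and paired formulas", {
  sheet <- tiny_sheet(2)
  st <- group_stats(mk_mat(list(p = c(0.2, 0.2, 0.8, 0.8)), sheet), sheet)
  expect_equal(st$mean_arterial, 0.2)
  expect_equal(st$mean_venous, 0.8)
  expect_equal(st$s2, 0)
  expect_equal(st$df, 2)

  # textbook pooled variance on a 3+3 hand dataset
  sh3 <- tiny_sheet(3)
  a <- c(1.1, 2.3, 0.7); v <- c(3.0, 2.2, 2.6)
  st3 <- group_stats(mk_mat(list(p = c(a, v)), sh3), sh3)
  pooled <- (2 * var(a) + 2 * var(v)) / 4
  expect_equal(st3$s2, pooled, tolerance = 1e-12)
  expect_equal(st3$mean_arterial - st3$mean_venous, mean(a) - mean(v),
               tolerance = 1e-12)

  # identical per-pair offsets: paired variance collapses to zero
  x <- c(1, 5, 9, 2, 6, 10)   # each pair differs by exactly -1
  stp <- group_stats(mk_mat(list(p = x), sh3), sh3, paired = TRUE)
  stu <- group_stats(mk_mat(list(p = x), sh3), sh3)
  expect_equal(stp$s2, 0)
  expect_equal(stp$df, 2)
  expect_gt(stu$s2, 0)
  expect_error(group_stats(mk_mat(list(p = c(1, 2)), tiny_sheet(1)),
                           tiny_sheet(1)), ">= 2 samples")
})

test_that("trigamma inversion matches brute-force bisection", {
  bisect <- function(x) {
    lo <- 1e-3; hi <- 1e3
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > x) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (x in c(0.01, 0.1, 0.5, 1, 2, 10, 100)) {
    expect_equal(avmeth:::trigamma_inverse(x), bisect(x),
                 tolerance = 1e-6)
  }
})

test_that("eb_fit: degenerate limit and moment recovery", {
  # equal variances: no excess spread -> d0 infinite, s0 = the common
  # value up to the digamma bias factor exp(log(dg/2) - digamma(dg/2))
  # (which tends to 1 as dg grows)
  h <- eb_fit(rep(0.02, 100), 16)
  expect_true(is.infinite(h$d0))
  expect_equal(h$s0_sq, 0.02 * exp(log(8) - digamma(8)),
               tolerance = 1e-12)
  expect_equal(h$s0_sq, 0.02, tolerance = 0.1)
  h2b <- eb_fit(rep(0.02, 100), 400)    # bias factor ~1 at large df
  expect_equal(h2b$s0_sq, 0.02, tolerance = 5e-3)

  # scaled-F draws with known hyperparameters (small-n version; the
  # 20,000-probe recovery runs in the acceptance suite)
  withr::with_seed(7, {
    s2 <- 0.02 * stats::rf(5000, df1 = 16, df2 = 4)
    h2 <- eb_fit(s2, 16)
  })
  expect_lt(abs(h2$d0 - 4), 1)
  expect_lt(abs(h2$s0_sq / 0.02 - 1), 0.15)
  expect_error(eb_fit(rep(0, 100), 16), "zero")
  expect_error(eb_fit(rep(0.1, 10), 16), ">= 50")
})

test_that("moderated t: limits, hand value, monotonicity in d0", {
  sheet <- tiny_sheet(3)
  withr::with_seed(8, x <- matrix(stats::rnorm(60 * 6), 60, 6,
                                  dimnames = list(sprintf("f%02d", 1:60),
                                                  sheet$sample_id)))
  st <- group_stats(x, sheet)
  # d0 = 0 equals the classical equal-variance two-sample t
  plain <- moderated_t(st, list(d0 = 0, s0_sq = NA))
  for (i in c(1, 17, 42)) {
    tt <- stats::t.test(x[i, 1:3], x[i, 4:6], var.equal = TRUE)
    expect_equal(plain$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(plain$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # equal means -> t = 0, p = 1
  st0 <- group_stats(mk_mat(list(p = rep(c(1, 2, 3), 2)), sheet), sheet)
  m0 <- moderated_t(st0, list(d0 = 4, s0_sq = 0.5))
  expect_equal(m0$t_stat, 0)
  expect_equal(m0$p_value, 1)
  # fixed toy numbers: diff 0.3, posterior s2 0.01, n = 3+3
  sttoy <- data.frame(mean_arterial = 0.3, mean_venous = 0, s2 = 0.01,
                      df = 4)
  attr(sttoy, "n_arterial") <- 3; attr(sttoy, "n_venous") <- 3
  attr(sttoy, "paired") <- FALSE
  toy <- moderated_t(sttoy, list(d0 = 0, s0_sq = NA))
  expect_equal(toy$t_stat, 0.3 / (0.1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(toy$t_stat, 3.674, tolerance = 1e-3)

  # |t| moves monotonically from the plain t toward the fully pooled t
  # as d0 grows
  hyperseq <- c(0, 0.5, 2, 8, 32, 1e6)
  i <- 5
  ts <- vapply(hyperseq, function(d0)
    moderated_t(st, list(d0 = d0, s0_sq = 1))$t_stat[i], numeric(1))
  pooled_t <- moderated_t(st, list(d0 = Inf, s0_sq = 1))$t_stat[i]
  gaps <- abs(pooled_t - ts)
  expect_true(all(diff(gaps) <= 1e-12))   # each step closes on the limit
  expect_equal(ts[length(ts)], pooled_t, tolerance = 1e-3)
})

test_that("eb shrinkage and moderated t agree with the limma oracle", {
  skip_if_not_installed("limma")
  sheet <- tiny_sheet(9)
  withr::with_seed(23, {
    # heterogeneous true variances (scaled inverse-chi-square, d0 = 6)
    # so the prior df is finite and both estimators take the same branch
    sds <- sqrt(0.15 * 6 / stats::rchisq(500, df = 6))
    x <- matrix(stats::rnorm(500 * 18, 0, rep(sds, 18)), 500, 18,
                dimnames = list(sprintf("f%03d", 1:500),
                                sheet$sample_id))
  })
  x[1:40, 1:9] <- x[1:40, 1:9] + 0.5
  st <- group_stats(x, sheet)
  h <- eb_fit(st$s2, st$df[1])
  sq <- limma::squeezeVar(st$s2, df = st$df[1])
  expect_equal(h$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(h$s0_sq, sq$var.prior, tolerance = 1e-6)
  design <- cbind(1, sheet$group == "arterial")
  fit <- limma::eBayes(limma::lmFit(x, design))
  mt <- moderated_t(st, h)
  expect_equal(mt$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("bh_adjust: examples and brute-force oracle equivalence", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(1:300, 1)
      p <- switch(sample(3, 1),
                  stats::runif(n),
                  round(stats::runif(n), 2),          # many ties
                  stats::rbeta(n, 0.3, 1))            # skewed small ps
      expect_identical(bh_adjust(p), bh_brute(p))
    }
  })
})

test_that("call_dmps applies both gates, each inclusive", {
  s <- small_sim(seed = 55)
  mm <- compute_beta_m(qc_filter(s$dataset))
  d <- call_dmps(mm)
  expect_equal(d$delta_beta, d$mean_beta_arterial - d$mean_beta_venous,
               tolerance = 1e-12)
  expect_identical(d$is_dmp,
                   d$adj_p <= 0.05 & abs(d$delta_beta) >= 0.10)
  expect_true(all(d$direction[d$is_dmp & d$delta_beta > 0] ==
                    "hyper_in_arterial"))
  expect_true(all(d$direction[!d$is_dmp] == "none"))
  # significant but small effect is not a DMP; big effect with weak
  # evidence is not a DMP
  expect_false(any(d$is_dmp & abs(d$delta_beta) < 0.10))
  expect_false(any(d$is_dmp & d$adj_p > 0.05))
  # planted blocks dominate the calls
  planted <- unlist(strsplit(s$truth$dmr_ledger$probe_ids, ";"))
  expect_gt(mean(d$probe_id[d$is_dmp] %in% planted), 0.9)
})

test_that("aggregate_dmrs chains by direction, gap and shared gene", {
  ann <- probe_annotation(
    probe_id = sprintf("p%d", 1:7),
    chromosome = c(rep("5", 5), "5", "9"),
    position = c(100L, 400L, 900L, 1900L, 3900L, 10000L, 100L),
    design_type = "II",
    gene_symbols = c(rep("GG", 5), "GG", "GH"),
    gene_region_tags = c(rep("Body", 5), "Body", "Body")
  )
  rec <- function(ids, delta) data.frame(
    probe_id = ids, delta_beta = delta, is_dmp = TRUE,
    direction = ifelse(delta > 0, "hyper_in_arterial", "hyper_in_venous"),
    stringsAsFactors = FALSE)
  # gaps 300/500/1000 chain; the 2000 gap breaks the chain
  r <- aggregate_dmrs(rec(sprintf("p%d", 1:5), rep(0.3, 5)), ann)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_probes, 4)
  expect_equal(r$start, 100); expect_equal(r$end, 1900)
  expect_equal(r$gene, "GG")
  expect_equal(r$mean_delta_beta, 0.3)
  # two DMPs only: below min_probes
  expect_equal(nrow(aggregate_dmrs(rec(c("p1", "p2"), c(0.3, 0.3)), ann)),
               0)
  # alternating directions never chain
  expect_equal(nrow(aggregate_dmrs(
    rec(sprintf("p%d", 1:4), c(0.3, -0.3, 0.3, -0.3)), ann)), 0)
  # min_probes is honored
  r2 <- aggregate_dmrs(rec(sprintf("p%d", 1:5), rep(0.3, 5)), ann,
                       min_probes = 5)
  expect_equal(nrow(r2), 0)
})

test_that("expression_logfc: sign convention and trivial cases", {
  sh <- tiny_sheet(3)
  vals <- rbind(flat = rep(5, 6),
                dn = c(5, 5, 5, 6.233, 6.233, 6.233))
  # pad with null genes so eb_fit has material
  withr::with_seed(9, pad <- matrix(stats::rnorm(60 * 6, 7, 0.3), 60, 6))
  rownames(pad) <- sprintf("null%02d", 1:60)
  vals <- rbind(vals, pad)
  colnames(vals) <- sh$sample_id
  em <- expression_matrix(vals, sh)
  de <- expression_logfc(em)
  expect_equal(de$logfc[de$gene == "flat"], 0)
  expect_equal(de$logfc[de$gene == "dn"], -1.233, tolerance = 1e-12)
  expect_equal(de$adj_p, bh_adjust(de$p_value))
})
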