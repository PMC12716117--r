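test_that("median polish decomposes an exactly additive matrix", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2),(3,4)
  mp <- median_polish(x)
  expect_equal(mp$overall, 2.5)
  expect_equal(unname(mp$row), c(-1, 1))
  expect_equal(unname(mp$col), c(-0.5, 0.5))
  expect_true(all(abs(mp$residuals) < 1e-12))
  # normalization removes only the column effect
  expect_equal(mp$normalized, sweep(x, 2, c(-0.5, 0.5), "-"))
})

test_that("a doubly median-centered matrix is a median-polish fixed point", {
  x <- matrix(c(-1, 1, 0, 0, 0, 0, 1, -1, 0), 3, 3)
  mp <- median_polish(x)
  expect_equal(mp$residuals, x, ignore_attr = TRUE)
  expect_equal(unname(mp$row), rep(0, 3))
  expect_equal(unname(mp$col), rep(0, 3))
})

test_that("median polish satisfies the reconstruction identity", {
  set.seed(61)
  x <- matrix(rnorm(60, 20, 2), 10, 6)
  mp <- median_polish(x)
  recon <- mp$overall + outer(mp$row, mp$col, "+") + mp$residuals
  expect_lt(max(abs(x - recon)), 1e-9)
  # column medians vanish after the final column sweep
  expect_lt(max(abs(apply(mp$residuals, 2, median))), 1e-6)
  # with an odd sample count both residual medians vanish at convergence
  # (even counts use midpoint medians, which can stall short of zero)
  x7 <- matrix(rnorm(70, 20, 2), 10, 7)
  mp7 <- median_polish(x7)
  expect_lt(max(abs(apply(mp7$residuals, 1, median))), 1e-4)
  expect_lt(max(abs(apply(mp7$residuals, 2, median))), 1e-6)
  # all-missing rows are dropped with a warning
  x_na <- x; x_na[3, ] <- NA
  expect_warning(mp2 <- median_polish(x_na), "all-missing")
  expect_equal(nrow(mp2$normalized), 9)
})

test_that("paired differences honor the quantifiability filter", {
  design <- make_design(3)
  ab <- matrix(NA_real_, 3, 6)
  # P1: all pairs complete, treated - control = +2
  ab[1, ] <- c(10, 10, 10, 12, 12, 12)
  # P2: only donor 1 complete
  ab[2, ] <- c(9, NA, NA, 11, NA, NA)
  # P3: two complete pairs with differences +1 and +3
  ab[3, ] <- c(8, 8, NA, 9, 11, NA)
  q <- make_quant(ab, design)
  pairs <- paired_log2fc(q, min_pairs = 2)
  expect_equal(rownames(pairs$diffs), c("P1", "P3"))
  expect_equal(pairs$n_excluded, 1)
  expect_equal(pairs$lfc$log2fc[pairs$lfc$label == "P1"], 2)
  expect_equal(pairs$lfc$log2fc[pairs$lfc$label == "P3"], 2)
  expect_equal(pairs$lfc$n_pairs, c(3L, 2L))
})

test_that("an injected fold change is recovered by the paired estimate", {
  set.seed(62)
  design <- make_design(6)
  base <- rnorm(6, 20, 2)
  ab <- cbind(
    matrix(rnorm(36, rep(base, 6), 0.3), 6, 6),          # control
    matrix(rnorm(36, rep(base + 1.5, 6), 0.3), 6, 6)     # treated
  )
  q <- make_quant(ab, design)
  lfc <- paired_log2fc(q)$lfc
  expect_true(all(abs(lfc$log2fc - 1.5) < 0.4))
})

test_that("the unmoderated test equals the classical one-sample t everywhere", {
  # hand-computed case: mean 1, s^2 = 0.02667, t = 12.25
  d <- matrix(c(1.0, 1.2, 0.8, 1.0), 1, 4, dimnames = list("P1", NULL))
  fit <- moderated_t(d, d0 = 0)
  expect_equal(round(fit$results$t, 2), 12.25)
  expect_equal(fit$results$p, t.test(d[1, ])$p.value, tolerance = 1e-12)

  set.seed(63)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    x <- rnorm(n, sample(c(0, 0.5), 1), runif(1, 0.1, 2))
    fit <- moderated_t(matrix(x, 1), d0 = 0)
    ref <- t.test(x)
    expect_equal(fit$results$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fit$results$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large prior df shrinks every posterior variance to the prior", {
  set.seed(64)
  d <- matrix(rnorm(50 * 6), 50, 6)
  fit <- moderated_t(d, d0 = 1e9, s0_sq = 0.05)
  expect_true(all(abs(fit$results$s2_post - 0.05) < 1e-4))
})

test_that("posterior variance lies between the prior and sample variance", {
  set.seed(65)
  d <- matrix(rnorm(100 * 6, 0, 0.3), 100, 6)
  fit <- moderated_t(d)
  lo <- pmin(fit$eb$s0_sq, fit$results$s2)
  hi <- pmax(fit$eb$s0_sq, fit$results$s2)
  expect_true(all(fit$results$s2_post >= lo - 1e-12 &
                    fit$results$s2_post <= hi + 1e-12))
})

test_that("EB hyperparameters are recovered on a null panel with known prior", {
  set.seed(66)
  G <- 2000; d0_true <- 4; s0_true <- 0.05; n <- 6
  sigma2 <- d0_true * s0_true / rchisq(G, d0_true)
  d <- matrix(rnorm(G * n, 0, sqrt(rep(sigma2, n))), G, n,
              dimnames = list(paste0("P", 1:G), NULL))
  fit <- moderated_t(d)
  expect_gte(fit$eb$d0, 2)
  expect_lte(fit$eb$d0, 8)
  expect_lt(abs(fit$eb$s0_sq - s0_true) / s0_true, 0.3)
  # type-I error at the nominal 5% level
  typeI <- mean(fit$results$p < 0.05)
  expect_gte(typeI, 0.04)
  expect_lte(typeI, 0.06)
})

test_that("the EB estimator matches limma's variance squeezing", {
  skip_if_not_installed("limma")
  set.seed(67)
  G <- 500; n <- 6
  sigma2 <- 4 * 0.05 / rchisq(G, 4)
  d <- matrix(rnorm(G * n, 0.2, sqrt(rep(sigma2, n))), G, n,
              dimnames = list(paste0("P", 1:G), NULL))
  fit <- moderated_t(d)
  sv <- limma::squeezeVar(apply(d, 1, var), df = n - 1)
  expect_equal(fit$eb$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(fit$eb$s0_sq, sv$var.prior, tolerance = 1e-6)
  expect_equal(fit$results$s2_post, unname(sv$var.post), tolerance = 1e-6)
  # full moderated t cross-check through limma's one-sample fit
  lf <- limma::eBayes(limma::lmFit(d, matrix(1, n, 1)))
  expect_equal(fit$results$t, unname(lf$t[, 1]), tolerance = 1e-6)
  expect_equal(fit$results$p, unname(lf$p.value[, 1]), tolerance = 1e-6)
})

test_that("zero-variance proteoforms are flagged when unmoderated", {
  d <- rbind(P1 = c(1, 1, 1, 1), P2 = c(0.9, 1.1, 1.0, 1.2))
  expect_warning(fit <- moderated_t(d, d0 = 0), "zero-variance")
  expect_true(fit$results$zero_var_flag[1])
  expect_true(is.na(fit$results$p[1]))
  # with a positive prior the same input is handled by moderation
  fit2 <- moderated_t(d, d0 = 4, s0_sq = 0.05)
  expect_false(any(fit2$results$zero_var_flag))
  expect_true(all(is.finite(fit2$results$p)))
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  step_up <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[ord[i]] <- min(vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
    }
    q
  }
  set.seed(68)
  d <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(paste0("P", 1:200), NULL))
  fit <- moderated_t(d)
  expect_equal(fit$results$p_adj, step_up(fit$results$p), tolerance = 1e-12)
  expect_true(all(fit$results$p_adj >= fit$results$p))
  # adjusted values preserve the raw ordering
  ord <- order(fit$results$p)
  expect_true(all(diff(fit$results$p_adj[ord]) >= -1e-12))
})

test_that("volcano classification uses strict cutoffs on p and log2FC", {
  res <- tibble::tibble(
    p = c(0.01, 0.01, 0.06, 0.01, 0.05),
    p_adj = p.adjust(p, "BH"),
    log2fc = c(1.5, 0.5, -2, -1.2, 3)
  )
  out <- volcano_classify(res)
  expect_equal(out$class, c("increased", "null", "null", "decreased", "null"))
})

test_that("the presence test equals exhaustive subset enumeration", {
  design <- make_design(6)  # 12 samples, 6 per condition
  enum_prob <- function(N, n_g, k) {
    subsets <- utils::combn(N, k)
    mean(apply(subsets, 2, function(s) all(s <= n_g)))
  }
  # treated-unique in all 6 treated samples: C(6,6)/C(12,6) = 1/924
  ab <- matrix(NA_real_, 3, 12)
  ab[1, design$condition == "treated"] <- 20
  ab[2, which(design$condition == "treated")[1:2]] <- 20
  ab[3, c(1, 7)] <- 20  # one control + one treated: not applicable
  q <- make_quant(ab, design)
  pr <- presence_test(q)
  expect_equal(pr$probability[1], 1 / 924, tolerance = 1e-12)
  expect_true(pr$significant[1])
  expect_equal(pr$probability[2], 15 / 66, tolerance = 1e-12)
  expect_false(pr$significant[2])
  expect_true(is.na(pr$probability[3]))
  expect_equal(pr$probability[1], enum_prob(12, 6, 6), tolerance = 1e-12)
  expect_equal(pr$probability[2], enum_prob(12, 6, 2), tolerance = 1e-12)
  # k = 1 gives n_g / N and can never reach 0.01 in this design
  ab1 <- matrix(NA_real_, 1, 12); ab1[1, 1] <- 20
  pr1 <- presence_test(make_quant(ab1, design))
  expect_equal(pr1$probability, 6 / 12)
  # full enumeration sweep for every k in one group
  for (k in 1:6) {
    abk <- matrix(NA_real_, 1, 12)
    abk[1, which(design$condition == "control")[1:k]] <- 20
    prk <- presence_test(make_quant(abk, design))
    expect_equal(prk$probability, enum_prob(12, 6, k), tolerance = 1e-12)
  }
})

test_that("regional trends count contained proteoforms by fold-change sign", {
  map <- default_region_map()
  res <- tibble::tibble(
    gene = c("GCG", "GCG", "GCG", "GCG"),
    first_aa = c(95L, 100L, 120L, 60L),
    last_aa = c(170L, 160L, 178L, 200L),  # last spans beyond the region
    log2fc = c(0.2, 1.1, -0.3, 2)
  )
  tr <- regional_trend(res, map, "GCG", "major proglucagon fragment")
  expect_equal(tr$n_up, 2)
  expect_equal(tr$n_down, 1)
  expect_equal(tr$n_total, 3)  # the spanning proteoform is excluded
  expect_error(regional_trend(res, map, "GCG", "nonexistent"), "unknown region")
  # zero fold change counts as neither direction
  res0 <- tibble::tibble(gene = "GCG", first_aa = 95L, last_aa = 170L,
                         log2fc = 0)
  tr0 <- regional_trend(res0, map, "GCG", "major proglucagon fragment")
  expect_equal(c(tr0$n_up, tr0$n_down, tr0$n_total), c(0, 0, 1))
})

test_that("the pipeline-level type-I error is near nominal on null data", {
  set.seed(69)
  design <- make_design(6)
  G <- 2000
  base <- rnorm(G, 20, 2)
  sample_eff <- rnorm(12, 0, 0.5)  # sample effects for normalization to remove
  ab <- outer(base, sample_eff, "+") + matrix(rnorm(G * 12, 0, 0.3), G, 12)
  q <- make_quant(ab, design)
  fit <- differential_abundance(q)
  typeI <- mean(fit$results$p < 0.05)
  expect_gte(typeI, 0.04)
  expect_lte(typeI, 0.06)
})

test_that("reproduce_reported_counts recomputes headline numbers from a table", {
  set.seed(70)
  n <- 120
  res <- tibble::tibble(
    gene = sample(c("GCG", "CHGA", "INS"), n, replace = TRUE),
    first_aa = sample(1:400, n, replace = TRUE),
    last_aa = NA_integer_,
    p = runif(n),
    log2fc = rnorm(n, 0, 1.2)
  )
  res$last_aa <- res$first_aa + sample(10:80, n, replace = TRUE)
  counts <- reproduce_reported_counts(res)
  expect_equal(counts$n_quantifiable, n)
  expect_equal(counts$n_increased, sum(res$p < 0.05 & res$log2fc > 1))
  expect_equal(counts$n_decreased, sum(res$p < 0.05 & res$log2fc < -1))
  grpp <- res$gene == "GCG" & res$first_aa >= 18 & res$last_aa <= 52
  expect_equal(counts$grpp_total, sum(grpp))
  expect_equal(counts$grpp_down, sum(grpp & res$log2fc < 0))
  pres <- matrix(runif(40 * 12) < 0.5, 40, 12)
  counts2 <- reproduce_reported_counts(res, presence = pres)
  expect_equal(counts2$n_half_complete, sum(rowMeans(pres) >= 0.5))
})
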