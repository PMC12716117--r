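test_that("observations merge within tolerance and split beyond it", {
  near <- make_psm(n = 2, scan = 1:2,
                   mass_da = c(5000, 5000 * (1 + 5e-6)),  # 5 ppm apart
                   rt_min = c(30, 30.1))
  expect_equal(dplyr::n_distinct(cluster_observations(near)$cluster_id), 1)

  far <- make_psm(n = 2, scan = 1:2,
                  mass_da = c(5000, 5000 * (1 + 50e-6)),  # 50 ppm apart
                  rt_min = c(30, 30.1))
  expect_equal(dplyr::n_distinct(cluster_observations(far)$cluster_id), 2)

  rt_far <- make_psm(n = 2, scan = 1:2, mass_da = 5000, rt_min = c(30, 35))
  expect_equal(dplyr::n_distinct(cluster_observations(rt_far)$cluster_id), 2)
})

test_that("clustering recovers known membership on simulated observations", {
  skip_if_not_installed("mclust")
  set.seed(51)
  true_mass <- runif(20, 2000, 20000)
  true_rt <- runif(20, 10, 90)
  truth <- sample(rep(1:20, each = 10))
  # instrument-bounded mass error (within +/- 3 ppm of truth); complete
  # linkage bounds the cluster diameter, so the error model must too
  obs <- make_psm(
    n = 200, scan = 1:200,
    mass_da = true_mass[truth] * (1 + runif(200, -3, 3) * 1e-6),
    rt_min = pmax(0, true_rt[truth] + rnorm(200, 0, 0.3))
  )
  cl <- cluster_observations(obs)$cluster_id
  expect_gt(mclust::adjustedRandIndex(cl, truth), 0.95)
  # partition property: memberships cover every observation once
  expect_equal(length(cl), 200)
  expect_false(anyNA(cl))
})

test_that("clustering is invariant to input row order", {
  set.seed(52)
  obs <- make_psm(n = 60, scan = 1:60,
                  mass_da = runif(60, 4000, 4002),
                  rt_min = runif(60, 20, 40))
  a <- cluster_observations(obs)
  perm <- sample.int(60)
  b <- cluster_observations(obs[perm, ])
  # compare partitions via co-membership of scan pairs
  part_a <- split(a$scan, a$cluster_id)
  part_b <- split(b$scan, b$cluster_id)
  canon <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","),
                                   character(1)))
  expect_equal(canon(part_a), canon(part_b))
})

test_that("consensus assignment transfers identifications across runs", {
  # identified as INS_25-54 in 5 runs, unidentified in 7 more
  rec <- dplyr::bind_rows(
    make_psm(n = 5, dataset_id = paste0("d", 1:5), scan = 1:5),
    make_psm(n = 7, dataset_id = paste0("d", 6:12), scan = 6:12,
             gene = NA, accession = NA, first_aa = NA, last_aa = NA,
             evalue = NA)
  )
  rec <- cluster_observations(rec)
  expect_equal(dplyr::n_distinct(rec$cluster_id), 1)
  cons <- assign_consensus(rec)
  expect_equal(cons$label, "INS_25-54")
  expect_equal(cons$n_members, 12)
  expect_equal(cons$n_identified, 5)

  # no identified members -> unidentified cluster
  feat <- cluster_observations(
    make_psm(n = 3, scan = 1:3, gene = NA, accession = NA,
             first_aa = NA, last_aa = NA, evalue = NA))
  expect_true(is.na(assign_consensus(feat)$label))

  # equal vote counts: best E-value wins
  tie <- dplyr::bind_rows(
    make_psm(n = 3, dataset_id = paste0("x", 1:3), scan = 1:3,
             first_aa = 25, last_aa = 54, evalue = c(1e-8, 1e-5, 1e-4)),
    make_psm(n = 3, dataset_id = paste0("y", 1:3), scan = 4:6,
             first_aa = 25, last_aa = 55, evalue = c(1e-4, 1e-4, 1e-4))
  )
  tie <- cluster_observations(tie, ppm_tol = 1e5)  # force one cluster
  expect_equal(dplyr::n_distinct(tie$cluster_id), 1)
  expect_equal(assign_consensus(tie)$label, "INS_25-54")
})

test_that("CV roll-up sums channel maxima and counts member PSMs", {
  rec <- make_psm(n = 3, scan = 1:3, cv_volts = c("-55", "-45", "-35"),
                  intensity = c(1e6, 2e6, 1e6))
  rec$cluster_id <- 1L
  out <- rollup_cv(rec)
  expect_equal(out$abundance, 4e6)
  expect_equal(out$spectral_count, 3L)

  single <- make_psm(cv_volts = "-45", intensity = 7.7e5)
  single$cluster_id <- 1L
  expect_equal(rollup_cv(single)$abundance, 7.7e5)

  # two features in the same CV channel: max by default, sum on request
  dupcv <- make_psm(n = 2, scan = 1:2, cv_volts = "-45",
                    intensity = c(3e5, 5e5))
  dupcv$cluster_id <- 1L
  expect_equal(rollup_cv(dupcv)$abundance, 5e5)
  expect_equal(rollup_cv(dupcv, within_cv = "sum")$abundance, 8e5)

  # generator bookkeeping: random split across channels re-sums to the total
  set.seed(53)
  total <- 3.2e7
  w <- rgamma(3, 2); w <- w / sum(w)
  split_rec <- make_psm(n = 3, scan = 1:3, cv_volts = c("-55", "-45", "-35"),
                        intensity = total * w)
  split_rec$cluster_id <- 1L
  expect_equal(rollup_cv(split_rec)$abundance, total,
               tolerance = 1e-6)
})

test_that("roll-up abundance never decreases when a member is added", {
  set.seed(54)
  rec <- make_psm(n = 4, scan = 1:4, cv_volts = c("-55", "-45", "-35", "-45"),
                  intensity = runif(4, 1e5, 1e6))
  rec$cluster_id <- 1L
  base <- rollup_cv(rec)$abundance
  extra <- make_psm(scan = 5, cv_volts = "-35", intensity = 2e6)
  extra$cluster_id <- 1L
  expect_gte(rollup_cv(dplyr::bind_rows(rec, extra))$abundance, base)
})

test_that("build_quant_matrix produces a log2 matrix with the design's shape", {
  design <- make_design(2)  # 4 samples
  rec <- dplyr::bind_rows(
    make_psm(n = 3, dataset_id = design$sample_id[c(1, 2, 3)], scan = 1:3,
             intensity = 8),
    make_psm(n = 2, dataset_id = design$sample_id[c(1, 4)], scan = 4:5,
             gene = "GCG", accession = "SYN_GCG", first_aa = 21, last_aa = 50,
             mass_da = 3000, rt_min = 60, intensity = c(16, 32))
  )
  rec <- cluster_observations(rec)
  q <- build_quant_matrix(rec, design)
  expect_equal(dim(q$abundance), c(2, 4))
  expect_equal(sort(rownames(q$abundance)), c("GCG_21-50", "INS_25-54"))
  # log2 of intensity 8 is exactly 3
  expect_equal(unname(q$abundance["INS_25-54", design$sample_id[1]]), 3)
  # missing pattern follows the observations
  expect_equal(unname(is.na(q$abundance["INS_25-54", ])),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(is.na(q$abundance["GCG_21-50", ])),
               c(FALSE, TRUE, TRUE, FALSE))
  # tidy view is long with design attached
  td <- tidy(q)
  expect_equal(nrow(td), 8)
  expect_true(all(c("donor_id", "condition", "spectral_count") %in% names(td)))
})

test_that("quant matrix dimensions match the generator manifest", {
  sim <- simulate_islet_study(small_sim_config(), seed = 55)
  rec <- cluster_observations(sim$psm)
  q <- build_quant_matrix(rec, sim$design)
  expect_equal(ncol(q$abundance), nrow(sim$design))
  # identified rows cannot exceed the number of true proteoforms (clusters
  # may split but merged rows are keyed by consensus proteoform)
  expect_lte(nrow(q$abundance), nrow(sim$manifest$catalog) +
               sum(grepl("\\.", rownames(q$abundance))))
})

test_that("top proteoforms rank by median spectral count with a sort oracle", {
  design <- make_design(2)
  set.seed(56)
  n_pf <- 30
  counts <- matrix(rpois(n_pf * 4, 5), n_pf, 4)
  labels <- sprintf("SST_%d-%d", 1:n_pf, 1:n_pf + 40)
  dimnames(counts) <- list(labels, design$sample_id)
  q <- make_quant(matrix(20, n_pf, 4, dimnames = dimnames(counts)),
                  design, counts = counts, genes = rep("SST", n_pf))
  top <- top_n_by_spectral_count(q, "SST", n = 10)
  med <- apply(counts, 1, median)
  oracle <- labels[order(-med, labels)][1:10]
  expect_equal(top$label, oracle)
  expect_equal(nrow(top_n_by_spectral_count(q, "SST", n = 100)), n_pf)
  expect_equal(nrow(top_n_by_spectral_count(q, "INS", n = 5)), 0)
})
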