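two_group_A <- function(n_per = 4, p = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(abs(rnorm(2 * n_per * p, 0.3, 0.1)), 2 * n_per, p)
  v <- v / sqrt(rowSums(v^2))
  dimnames(v) <- list(paste0("s", seq_len(2 * n_per)), paste0("o", seq_len(p)))
  list(A = make_A(v),
       meta = make_meta(rownames(v), group = rep(c("g1", "g2"), each = n_per)))
}

test_that("per-OTU variance explained equals univariate regression R^2", {
  fx <- two_group_A(n_per = 4, p = 8, seed = 5)
  fit <- rda_two_group(fx$A, fx$meta, c("g1", "g2"))
  g <- factor(fx$meta$group)
  oracle <- apply(fx$A$values, 2, function(col)
    summary(lm(col ~ g))$r.squared)
  expect_equal(unname(fit$variance_explained), unname(oracle),
               tolerance = 1e-10)
  # overall constrained proportion agrees with vegan's RDA
  vfit <- vegan::rda(fx$A$values ~ g)
  expect_equal(fit$constrained_proportion,
               vfit$CCA$tot.chi / vfit$tot.chi, tolerance = 1e-8)
})

test_that("variance explained hits its boundary cases", {
  v <- matrix(c(0.5, 0.5, 0.1,
                0.5, 0.7, 0.1,
                0.5, 0.5, 0.3,
                0.5, 0.7, 0.3), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("equal", "noisy", "clean")))
  # 'equal': same group means -> 0; 'clean': constant within group -> 1
  A <- make_A(v)
  meta <- make_meta(rownames(v), group = c("g1", "g1", "g2", "g2"))
  fit <- rda_two_group(A, meta, c("g1", "g2"))
  expect_equal(unname(fit$variance_explained["equal"]), 0)
  expect_equal(unname(fit$variance_explained["clean"]), 1)
  # constant column (zero variance) is defined as 0, not NaN
  v2 <- cbind(v, const = 0.2)
  fit2 <- rda_two_group(make_A(v2), meta, c("g1", "g2"))
  expect_equal(unname(fit2$variance_explained["const"]), 0)
  expect_error(rda_two_group(A, make_meta(rownames(v),
                                          group = c("g1", "g2", "g2", "g2")),
                             c("g1", "g2")), ">= 2 samples")
})

test_that("key-OTU selection thresholds and directs membership", {
  v <- matrix(c(0.9, 0.10, 0.30,
                0.8, 0.12, 0.31,
                0.3, 0.60, 0.30,
                0.4, 0.62, 0.32), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("o1", "o2", "o3")))
  A <- make_A(v)
  meta <- make_meta(rownames(v), group = c("ref", "ref", "con", "con"))
  fit <- rda_two_group(A, meta, c("ref", "con"))
  keys <- select_key_otus(fit, threshold = 0.10)
  expect_identical(keys$N, "o1")
  expect_identical(keys$M, "o2")
  expect_true(all(keys$variance_explained > 0.10))
  # all below threshold -> empty sets -> flagged error
  expect_error(select_key_otus(fit, threshold = 0.999), "empty")
})

test_that("WT-index follows I_j = I_jwt/|N| - I_jki/|M| exactly", {
  v <- matrix(c(0.6, 0.2, 0.8,
                0.0, 0.0, 0.0,
                0.3, 0.5, 0.1), 3, 3, byrow = TRUE,
              dimnames = list(c("j1", "j2", "j3"), c("o1", "o2", "o3")))
  A <- make_A(v)
  k1 <- structure(list(N = "o1", M = "o2",
                       variance_explained = c(o1 = 0.5, o2 = 0.3),
                       threshold = 0.1), class = "key_otu_set")
  wi <- wt_index(A, k1)
  expect_equal(wi$index[wi$sample_id == "j1"], 0.4)
  expect_equal(wi$index[wi$sample_id == "j2"], 0)   # all key OTUs absent
  k2 <- structure(list(N = c("o1", "o3"), M = "o2",
                       variance_explained = c(o1 = .5, o3 = .4, o2 = .3),
                       threshold = 0.1), class = "key_otu_set")
  wi2 <- wt_index(A, k2)
  expect_equal(wi2$index[wi2$sample_id == "j1"], (0.6 + 0.8) / 2 - 0.2)
  expect_error(wt_index(A, structure(list(N = "o9", M = "o2"),
                                     class = "key_otu_set")), "o9")
})

test_that("WT-index is linear in N-abundances and bounded in [-1, 1]", {
  fx <- two_group_A(n_per = 5, p = 10, seed = 9)
  keys <- structure(list(N = paste0("o", 1:3), M = paste0("o", 4:5),
                         variance_explained = NULL, threshold = 0.1),
                    class = "key_otu_set")
  wi <- wt_index(fx$A, keys)
  expect_true(all(wi$index >= -1 & wi$index <= 1))
  c_scale <- 0.5
  v2 <- fx$A$values
  v2[, keys$N] <- v2[, keys$N] * c_scale
  wi2 <- wt_index(make_A(v2), keys)
  expect_equal(wi2$i_wt, wi$i_wt * c_scale, tolerance = 1e-12)
  expect_equal(wi2$i_ki, wi$i_ki)
})

test_that("midrank AUC matches the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("p", "p", "n", "n"), positive = "p")$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("p", "n"), 3), "p")$auc, 0.5)
  expect_error(roc_auc(1:3, rep("p", 3), "p"), "both classes")

  set.seed(11)
  for (rep in 1:5) {
    scores <- round(rnorm(20), 1)       # rounding forces some ties
    labels <- sample(rep(c("p", "n"), 10))
    expect_equal(roc_auc(scores, labels, "p")$auc,
                 auc_oracle(scores[labels == "p"], scores[labels == "n"]))
  }
  # complement property in the tie-free case
  set.seed(12)
  s <- rnorm(20); l <- rep(c("p", "n"), 10)
  expect_equal(roc_auc(s, l, "p")$auc + roc_auc(-s, l, "p")$auc, 1)
  # agreement with the reference ROC implementation
  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::auc(pROC::roc(l, s, levels = c("n", "p"),
                                             direction = "<")))
  expect_equal(roc_auc(s, l, "p")$auc, as.numeric(pr))
})

test_that("stratified percentile bootstrap CI behaves at the edges", {
  ci <- bootstrap_auc_ci(c(0.9, 0.8, 0.1, 0.2), c("p", "p", "n", "n"),
                         positive = "p", n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))
  ci2 <- bootstrap_auc_ci(c(0.9, 0.1), c("p", "n"), positive = "p",
                          n_boot = 100, seed = 1)
  expect_equal(unname(ci2), c(1, 1))
})

test_that("bootstrap interval brackets the point AUC in most replications", {
  set.seed(21)
  hits <- vapply(1:100, function(i) {
    scores <- c(rnorm(15, 0.8), rnorm(15, 0))
    labels <- rep(c("p", "n"), each = 15)
    auc <- roc_auc(scores, labels, "p")$auc
    ci <- bootstrap_auc_ci(scores, labels, "p", n_boot = 200, seed = i)
    ci[1] <= auc && auc <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("LOOCV refits selection per fold and separates planted groups", {
  spec <- synth_spec(p_otus = 100, n_per_group = c(15, 15),
                     n_ref_enriched = 20, n_contrast_enriched = 20,
                     log2_fc = 2, depth = list(type = "fixed", mean = 9000),
                     seed = 31)
  sim <- synth_community(spec)
  roc <- loocv_auc(sim$table, sim$metadata, spec$groups, n_boot = 100,
                   seed = 2)
  expect_gte(roc$auc, 0.95)
  expect_identical(roc$cv_mode, "loocv")
  expect_true(roc$ci_low <= roc$ci_high)
  expect_true(roc$ci_low >= 0 && roc$ci_high <= 1)

  tiny <- subset_otu_table(sim$table, samples = 1:2)
  expect_error(loocv_auc(tiny, sim$metadata, spec$groups), ">= 2 samples")
})

test_that("under the null, high LOOCV AUC is rare and the mean is central", {
  aucs <- vapply(1:20, function(s) {
    spec <- synth_spec(p_otus = 20, n_per_group = c(15, 15), log2_fc = 0,
                       n_ref_enriched = 0, n_contrast_enriched = 0,
                       seed = 700 + s)
    sim <- synth_community(spec)
    loocv_auc(sim$table, sim$metadata, spec$groups, n_boot = 2,
              seed = s)$auc
  }, 0)
  expect_lte(mean(aucs > 0.9), 0.05)
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("planted reference group scores higher in every seeded run", {
  wins <- vapply(1:20, function(s) {
    spec <- synth_spec(p_otus = 60, n_per_group = c(8, 8),
                       n_ref_enriched = 10, n_contrast_enriched = 10,
                       log2_fc = 3, seed = 900 + s)
    sim <- synth_community(spec)
    A <- hellinger(sim$table)
    keys <- select_key_otus(rda_two_group(A, sim$metadata, spec$groups))
    wi <- wt_index(A, keys)
    ref <- sim$metadata$group == spec$groups[1]
    mean(wi$index[ref]) > mean(wi$index[!ref])
  }, TRUE)
  expect_identical(sum(wins), 20L)
})
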