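test_that("prevalence filter keeps strictly > min_fraction", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10),
                                        c("in5", "in4", "never")))
  m[1:5, 1] <- 3
  m[1:4, 2] <- 3
  m[1, 3] <- 0
  m[, 3][1] <- 0; m[1, 1] <- 3   # ensure non-empty rows are irrelevant here
  tab <- otu_table(m)
  out <- prevalence_filter(tab, 0.40)
  expect_identical(out$otu_ids, "in5")
})

test_that("sparcc output is symmetric with unit diagonal and honours structure", {
  spec <- synth_spec(p_otus = 30, n_per_group = c(100, 100), log2_fc = 0,
                     n_ref_enriched = 0, n_contrast_enriched = 0,
                     corr_blocks = list(list(size = 4, rho = 0.9)),
                     seed = 41)
  sim <- synth_community(spec)
  r <- sparcc(sim$table, seed = 1)
  expect_equal(unname(diag(r)), rep(1, 30))
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  block <- sim$truth$block_members[[1]]
  inb <- matrix(FALSE, 30, 30, dimnames = dimnames(r))
  inb[block, block] <- TRUE
  expect_gt(min(r[upper.tri(r) & inb]), max(r[upper.tri(r) & !inb]))

  expect_error(sparcc(subset_otu_table(sim$table, otus = 1:3)), "4 OTUs")
  expect_error(sparcc(subset_otu_table(sim$table, samples = 1:3)),
               "4 samples")
})

test_that("a perfectly co-varying abundant pair reaches r >= 0.9", {
  set.seed(42)
  n <- 100; p <- 30
  mu <- rnorm(p, 0, 1)
  mu[1:2] <- 2.5                       # abundant, so count noise is small
  logs <- matrix(rnorm(n * p, 0, 0.8), n, p, byrow = FALSE)
  logs <- sweep(logs, 2, mu, "+")
  logs[, 2] <- logs[, 1] + rnorm(n, 0, 0.01)   # co-varying, eps -> 0
  pr <- exp(logs); pr <- pr / rowSums(pr)
  counts <- t(vapply(seq_len(n), function(i)
    rmultinom(1, 50000, pr[i, ])[, 1], integer(p)))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("o", 1:p))
  r <- sparcc(otu_table(counts), seed = 3)
  expect_gte(r["o1", "o2"], 0.9)
})

test_that("sparcc on independent components stays near zero", {
  spec <- synth_spec(p_otus = 30, n_per_group = c(100, 100), log2_fc = 0,
                     n_ref_enriched = 0, n_contrast_enriched = 0,
                     basis_logsd = 0,   # equal basis variances
                     seed = 43)
  sim <- synth_community(spec)
  r <- sparcc(sim$table, seed = 2)
  off <- abs(r[upper.tri(r)])
  expect_lte(median(off), 0.15)
})

test_that("the deterministic basis solve is permutation-equivariant", {
  set.seed(44)
  frac <- matrix(rgamma(50 * 10, 2), 50, 10)
  frac <- frac / rowSums(frac)
  Tm <- wtnet:::variation_matrix(frac)
  r <- wtnet:::sparcc_from_T(Tm, 10, 0.1)
  perm <- sample(10)
  r2 <- wtnet:::sparcc_from_T(Tm[perm, perm], 10, 0.1)
  expect_equal(r2, r[perm, perm], tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one convention", {
  spec <- synth_spec(p_otus = 8, n_per_group = c(10, 10), log2_fc = 0,
                     n_ref_enriched = 0, n_contrast_enriched = 0, seed = 45)
  sim <- synth_community(spec)
  r_obs <- sparcc(sim$table, seed = 1)
  # an observed |R| above anything attainable -> p = 1/(n_perm + 1)
  fake <- r_obs; fake[] <- 2; diag(fake) <- 1
  pv <- permutation_pvalues(sim$table, fake, n_perm = 19, seed = 3,
                            perm_estimation_iter = 2)
  expect_equal(unname(pv[upper.tri(pv)]), rep(1 / 20, choose(8, 2)))
  # an observed R of 0 is never more extreme than a permutation -> p = 1
  zero <- r_obs; zero[] <- 0; diag(zero) <- 1
  pv0 <- permutation_pvalues(sim$table, zero, n_perm = 19, seed = 3,
                             perm_estimation_iter = 2)
  expect_true(all(pv0[upper.tri(pv0)] == 1))
})

test_that("null permutation p-values are approximately uniform", {
  spec <- synth_spec(p_otus = 20, n_per_group = c(15, 15), log2_fc = 0,
                     n_ref_enriched = 0, n_contrast_enriched = 0, seed = 46)
  sim <- synth_community(spec)
  r_obs <- sparcc(sim$table, seed = 5)
  pv <- permutation_pvalues(sim$table, r_obs, n_perm = 200, seed = 6,
                            perm_estimation_iter = 3)
  p <- pv[upper.tri(pv)]
  ks <- ks_oracle_uniform(p)
  expect_lt(ks, 0.1)
  # null calibration of the nominal 0.05 level
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03 + 1e-9)
})

test_that("edge thresholds are strict and filtering is monotone", {
  ids <- c("a", "b", "c")
  r <- matrix(c(1, 0.8, 0.7,
                0.8, 1, 0.9,
                0.7, 0.9, 1), 3, 3, dimnames = list(ids, ids))
  p <- matrix(c(NA, 0.01, 0.01,
                0.01, NA, 0.05,
                0.01, 0.05, NA), 3, 3, dimnames = list(ids, ids))
  net <- build_network(r, p, p_max = 0.05, r_min_abs = 0.7)
  # (a,b): R=0.8, p=0.01 -> edge; (a,c): R=0.7 not > 0.7 -> no edge;
  # (b,c): p=0.05 not < 0.05 -> no edge
  expect_identical(nrow(net$edges), 1L)
  expect_identical(sort(c(net$edges$source, net$edges$target)), c("a", "b"))
  expect_identical(net$nodes, ids)   # isolated nodes retained

  set.seed(47)
  rr <- matrix(runif(100, -1, 1), 10, 10); rr <- (rr + t(rr)) / 2; diag(rr) <- 1
  pp <- matrix(runif(100), 10, 10); pp <- (pp + t(pp)) / 2; diag(pp) <- NA
  loose <- build_network(rr, pp, p_max = 0.2, r_min_abs = 0.3)
  tight <- build_network(rr, pp, p_max = 0.05, r_min_abs = 0.7)
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("topology metrics match closed forms on canonical graphs", {
  tri <- make_net(list(list("a", "b"), list("b", "c"), list("a", "c")))
  tt <- topology(tri)
  expect_equal(tt$network_density, 1)
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$characteristic_path_length, 1)
  expect_equal(tt$network_centralization, 0)
  expect_equal(tt$avg_num_neighbors, 2)
  expect_equal(tt$n_isolated, 0)

  star <- make_net(list(list("hub", "l1"), list("hub", "l2"),
                        list("hub", "l3")))
  ts <- topology(star)
  expect_equal(ts$network_centralization, 1)
  expect_equal(unname(ts$eigenvector_centrality["hub"]), 1)
  expect_equal(unname(ts$eigenvector_centrality["l1"]), 1 / sqrt(3),
               tolerance = 1e-10)

  path <- make_net(list(list("A", "B"), list("B", "C")))
  tp <- topology(path)
  expect_equal(tp$characteristic_path_length, 4 / 3)
  # eigenvector centrality vs power iteration
  adj <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pi_ev <- power_iteration(adj)
  expect_equal(unname(tp$eigenvector_centrality[c("A", "B", "C")]),
               pi_ev / max(pi_ev), tolerance = 1e-8)
})

test_that("topology scalars are invariant under node relabeling", {
  set.seed(48)
  edges <- list()
  nodes <- paste0("n", 1:12)
  pairs <- combn(nodes, 2)
  sel <- sample(ncol(pairs), 14)
  edges <- lapply(sel, function(i) list(pairs[1, i], pairs[2, i]))
  net <- make_net(edges, nodes = nodes)
  relabel <- setNames(paste0("x", sample(12)), nodes)
  net2 <- co_network(unname(relabel[net$nodes]),
                     data.frame(source = unname(relabel[net$edges$source]),
                                target = unname(relabel[net$edges$target]),
                                r = net$edges$r, p = net$edges$p))
  s1 <- wtnet:::topology_scalars(topology(net))
  s2 <- wtnet:::topology_scalars(topology(net2))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("KS comparison matches the brute-force ECDF oracle and is symmetric", {
  mk <- function(deg) {
    t <- topology(make_net(list(list("a", "b"))))
    t$degree <- deg
    t$eigenvector_centrality <- deg / max(deg)
    t
  }
  a <- mk(c(1, 1, 2)); b <- mk(c(3, 3, 4))
  cmp <- compare_topologies(a, b)
  expect_equal(cmp$ks_degree$statistic, ks_oracle(c(1, 1, 2), c(3, 3, 4)))
  expect_equal(cmp$ks_degree$statistic, 1)   # disjoint support
  self <- compare_topologies(a, a)
  expect_equal(self$ks_degree$statistic, 0)
  expect_equal(self$ks_degree$p_value, 1)
  rev <- compare_topologies(b, a)
  expect_equal(rev$ks_degree$statistic, cmp$ks_degree$statistic)
  expect_equal(rev$ks_degree$p_value, cmp$ks_degree$p_value)

  set.seed(49)
  x <- rpois(15, 3); y <- rpois(12, 5)
  a2 <- mk(x + 1); b2 <- mk(y + 1)
  expect_equal(compare_topologies(a2, b2)$ks_degree$statistic,
               ks_oracle(x + 1, y + 1), tolerance = 1e-12)
})
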