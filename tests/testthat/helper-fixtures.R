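# small fixtures built in code, shared across test files

tiny_table <- function() {
  otu_table(matrix(1:6, 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))))
}

# build a transformed_table directly from a samples x OTUs value matrix
make_A <- function(values) {
  structure(list(sample_ids = rownames(values), otu_ids = colnames(values),
                 values = values),
            class = "transformed_table")
}

make_meta <- function(sample_ids, group, ...) {
  sample_metadata(data.frame(sample_id = sample_ids, group = group, ...,
                             stringsAsFactors = FALSE))
}

# co_network from a terse edge spec; nodes default to edge endpoints
make_net <- function(edges, nodes = NULL) {
  df <- data.frame(source = vapply(edges, `[[`, "", 1),
                   target = vapply(edges, `[[`, "", 2),
                   r = vapply(edges, function(e)
                     if (length(e) > 2) as.numeric(e[[3]]) else 0.8, 0),
                   p = 0.01, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(df$source, df$target))
  co_network(nodes, df)
}

# distances between rows, as a distance_matrix (Euclidean)
euclid_dm <- function(x) {
  d <- as.matrix(dist(x))
  distance_matrix(d)
}

bc_oracle <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# one-sample KS distance of values in (0,1] from the uniform distribution
ks_oracle_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p))
}

# exhaustive two-sample KS statistic: max ECDF gap scanned over all values
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# AUC by exhaustive pairwise comparison: wins + half ties
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_enum_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  centre <- n1 * (n - n1) / 2
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# principal eigenvector of an adjacency matrix by power iteration;
# the +I shift keeps bipartite graphs (eigenvalues +/- lambda) convergent
power_iteration <- function(adj, iters = 100000, tol = 1e-14) {
  shifted <- adj + diag(nrow(adj))
  v <- rep(1 / sqrt(nrow(adj)), nrow(adj))
  for (i in seq_len(iters)) {
    w <- shifted %*% v
    w <- as.vector(w) / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  abs(v)
}
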