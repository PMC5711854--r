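#' The wild-type index
#'
#' For sample \eqn{j} with Hellinger abundances \eqn{A_{ij}}:
#' \deqn{I_{j\mathrm{wt}} = \sum_{i \in N} A_{ij}, \quad
#'       I_{j\mathrm{ki}} = \sum_{i \in M} A_{ij}, \quad
#'       I_j = I_{j\mathrm{wt}}/|N| - I_{j\mathrm{ki}}/|M|}
#' where \eqn{N} are the reference-group-enriched key OTUs and \eqn{M} the
#' contrast-group-enriched ones. Since each \eqn{A_{ij} \in [0,1]},
#' \eqn{I_j \in [-1, 1]}; positive values indicate a community more similar
#' to the reference group.
#'
#' @param A a \code{transformed_table}.
#' @param keys a \code{key_otu_set}.
#' @return object of class \code{wt_index}: data.frame with columns
#'   \code{sample_id}, \code{i_wt}, \code{i_ki}, \code{index}; the key set is
#'   attached as attribute \code{keys}.
#' @export
wt_index <- function(A, keys) {
  stopifnot(inherits(A, "transformed_table"), inherits(keys, "key_otu_set"))
  missing <- setdiff(c(keys$N, keys$M), A$otu_ids)
  if (length(missing))
    stop("key OTUs missing from the table: ", paste(missing, collapse = ", "))
  i_wt <- rowSums(A$values[, keys$N, drop = FALSE])
  i_ki <- rowSums(A$values[, keys$M, drop = FALSE])
  out <- data.frame(sample_id = A$sample_ids,
                    i_wt = unname(i_wt), i_ki = unname(i_ki),
                    index = unname(i_wt / length(keys$N) -
                                   i_ki / length(keys$M)),
                    stringsAsFactors = FALSE)
  attr(out, "keys") <- keys
  class(out) <- c("wt_index", "data.frame")
  out
}

#' ROC area under the curve by the midrank Mann-Whitney statistic
#'
#' \eqn{AUC = U / (n_1 n_2)} with midranks, i.e. the probability that a
#' random positive scores above a random negative, ties counting one half.
#'
#' @param scores numeric per-sample scores.
#' @param labels per-sample class labels.
#' @param positive the label treated as positive (scores expected high).
#' @return object of class \code{roc_result}: list with \code{auc},
#'   \code{pairs} (score/label data.frame sorted by decreasing score),
#'   \code{ci_low}, \code{ci_high}, \code{n_bootstrap}, \code{cv_mode}.
#' @export
roc_auc <- function(scores, labels, positive) {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0 || n2 == 0)
    stop("both classes must be present (positives: ", n1,
         ", negatives: ", n2, ")")
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  ord <- order(scores, decreasing = TRUE)
  structure(list(auc = auc,
                 pairs = data.frame(score = scores[ord],
                                    label = labels[ord],
                                    stringsAsFactors = FALSE),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_bootstrap = 0L, cv_mode = "none",
                 n_positive = n1, n_negative = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("AUC =", round(x$auc, 4))
  if (!is.na(x$ci_low))
    cat(", 95% CI (", round(x$ci_low, 4), ", ", round(x$ci_high, 4),
        "), ", x$n_bootstrap, " bootstrap replicates", sep = "")
  cat(" [cv:", x$cv_mode, "]\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement within each class
#' (stratified, so no resample loses a class) and takes the percentile
#' interval of the replicate AUCs.
#'
#' @param scores,labels,positive as in \code{\link{roc_auc}}.
#' @param n_boot number of bootstrap replicates (study setting: 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric \code{c(ci_low, ci_high)}.
#' @export
bootstrap_auc_ci <- function(scores, labels, positive, n_boot = 1000,
                             level = 0.95, seed = 1) {
  is_pos <- labels == positive
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  reps <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    ps <- sample(pos, replace = TRUE)
    ns <- sample(neg, replace = TRUE)
    r <- rank(c(ps, ns))
    (sum(r[seq_along(ps)]) - length(ps) * (length(ps) + 1) / 2) /
      (length(ps) * length(ns))
  }, 0))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Leave-one-out cross-validated WT-index ROC
#'
#' For each sample the whole discriminant pipeline is refit without it:
#' Hellinger transform, two-group RDA, key-OTU selection at
#' \code{threshold}; the held-out sample is then scored with the
#' training-fold key set. All held-out (index, label) pairs are pooled into
#' one ROC with the reference group as positive class, and a stratified
#' percentile bootstrap CI is attached. Folds where selection fails (an
#' empty N or M) contribute score 0 and are recorded in attribute
#' \code{failed_folds}.
#'
#' @param table an \code{otu_table} (raw counts; the Hellinger transform
#'   normalizes depth).
#' @param meta \code{sample_metadata}.
#' @param group_pair (reference, contrast) group labels.
#' @param threshold key-OTU variance-explained cutoff.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed integer seed (used only by the bootstrap; LOOCV itself is
#'   deterministic).
#' @return a \code{roc_result} with \code{cv_mode = "loocv"} and a
#'   \code{scores} data.frame (sample_id, index, group) attached.
#' @export
loocv_auc <- function(table, meta, group_pair, threshold = 0.10,
                      n_boot = 1000, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  meta <- match_meta(table, meta)
  keep <- meta$group %in% group_pair
  table <- subset_otu_table(table, samples = keep)
  meta <- meta[keep, , drop = FALSE]
  n_by <- base::table(factor(meta$group, levels = group_pair))
  if (any(n_by < 2)) stop("each group needs >= 2 samples for LOOCV")
  n <- length(table$sample_ids)
  if (n < 3) stop("LOOCV needs at least 3 samples")

  A_all <- hellinger(table)   # per-sample transform: no leakage across folds
  idx <- numeric(n)
  failed <- character()
  for (j in seq_len(n)) {
    A_train <- structure(list(sample_ids = A_all$sample_ids[-j],
                              otu_ids = A_all$otu_ids,
                              values = A_all$values[-j, , drop = FALSE]),
                         class = "transformed_table")
    keys <- tryCatch(
      select_key_otus(rda_two_group(A_train, meta[-j, , drop = FALSE],
                                    group_pair, n_axes = 1),
                      threshold = threshold),
      error = function(e) NULL)
    if (is.null(keys)) {
      idx[j] <- 0
      failed <- c(failed, table$sample_ids[j])
    } else {
      A_test <- structure(list(sample_ids = A_all$sample_ids[j],
                               otu_ids = A_all$otu_ids,
                               values = A_all$values[j, , drop = FALSE]),
                          class = "transformed_table")
      idx[j] <- wt_index(A_test, keys)$index
    }
  }
  res <- roc_auc(idx, meta$group, positive = group_pair[1])
  ci <- bootstrap_auc_ci(idx, meta$group, positive = group_pair[1],
                         n_boot = n_boot, seed = seed)
  res$ci_low <- ci[["ci_low"]]
  res$ci_high <- ci[["ci_high"]]
  res$n_bootstrap <- n_boot
  res$cv_mode <- "loocv"
  res$scores <- data.frame(sample_id = table$sample_ids, index = idx,
                           group = meta$group, stringsAsFactors = FALSE)
  attr(res, "failed_folds") <- failed
  res
}
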