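#' Rarefy an OTU table by repeated subsampling without replacement
#'
#' Each permutation subsamples every retained sample down to exactly
#' \code{depth} reads without replacement (multivariate hypergeometric, the
#' QIIME convention). The returned table holds the mean count over
#' permutations, so entries need not be integral; per-permutation tables have
#' row sums exactly equal to \code{depth}.
#'
#' Permutation \code{k} uses seed \code{seed + k}, so results are fully
#' reproducible and individual permutations can be regenerated in isolation.
#'
#' @param table an \code{otu_table}.
#' @param depth target reads per sample (positive integer).
#' @param n_perm number of subsampling permutations.
#' @param seed integer seed.
#' @param on_shallow what to do with samples whose total is below
#'   \code{depth}: \code{"drop"} them or raise an \code{"error"}.
#' @param return_permutations also return the list of per-permutation tables.
#' @return the averaged \code{otu_table} (attribute \code{rarefaction} records
#'   depth, n_perm, seed and dropped samples); if
#'   \code{return_permutations}, a list with elements \code{averaged} and
#'   \code{permutations}.
#' @export
rarefy <- function(table, depth, n_perm = 1000, seed = 1,
                   on_shallow = c("drop", "error"),
                   return_permutations = FALSE) {
  stopifnot(inherits(table, "otu_table"), depth > 0, n_perm >= 1)
  on_shallow <- match.arg(on_shallow)
  totals <- rowSums(table$counts)
  shallow <- table$sample_ids[totals < depth]
  if (length(shallow) && on_shallow == "error")
    stop("samples below rarefaction depth ", depth, ": ",
         paste(shallow, collapse = ", "))
  keep <- totals >= depth
  if (!any(keep)) stop("no samples reach depth ", depth)
  m <- table$counts[keep, , drop = FALSE]
  p <- ncol(m)

  subsample_row <- function(counts, depth) {
    if (sum(counts) == depth) return(counts)
    reads <- rep.int(seq_len(p), counts)
    tabulate(sample(reads, depth), nbins = p)
  }

  acc <- matrix(0, nrow(m), p, dimnames = dimnames(m))
  perms <- if (return_permutations) vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    mk <- withr::with_seed(seed + k, {
      t(apply(m, 1L, subsample_row, depth = depth))
    })
    dimnames(mk) <- dimnames(m)
    acc <- acc + mk
    if (return_permutations)
      perms[[k]] <- otu_table(mk, taxonomy = table$taxonomy)
  }
  avg <- otu_table(acc / n_perm, taxonomy = table$taxonomy,
                   check_integer = FALSE)
  attr(avg, "rarefaction") <- list(depth = depth, n_perm = n_perm,
                                   seed = seed, dropped = shallow)
  if (return_permutations) list(averaged = avg, permutations = perms) else avg
}
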