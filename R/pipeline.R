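#' Pipeline configuration
#'
#' A flat, validated configuration for \code{\link{run_full}}. All study
#' thresholds appear with their published defaults: key-OTU variance
#' explained 0.10, network prevalence 0.40, edge p < 0.05 and |R| > 0.7,
#' rarefaction depth 9000, and 1000-replicate resampling counts.
#'
#' @param table path to the OTU table.
#' @param metadata path to the sample metadata TSV.
#' @param out_dir output directory (created if missing).
#' @param group_a,group_b the two group labels (reference first).
#' @param dialect OTU-table dialect, see \code{\link{read_otu_table}}.
#' @param rarefy_depth rarefaction depth (reads); \code{0} disables
#'   rarefaction.
#' @param rarefy_perms rarefaction permutations.
#' @param key_threshold key-OTU variance-explained cutoff.
#' @param prevalence network prevalence filter fraction.
#' @param p_max,r_min edge thresholds.
#' @param network_perms SparCC permutation count.
#' @param sparcc_iter SparCC estimation iterations.
#' @param perm_sparcc_iter estimation iterations inside the permutation test.
#' @param n_boot bootstrap replicates for the AUC CI.
#' @param cv \code{"loocv"} or \code{"none"}.
#' @param variance_target cumulative PCoA variance for the MANOVA.
#' @param seed master integer seed; stage seeds are derived from it
#'   (documented in the run manifest).
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(table, metadata, out_dir,
                            group_a, group_b,
                            dialect = "plain_tsv",
                            rarefy_depth = 9000, rarefy_perms = 1000,
                            key_threshold = 0.10, prevalence = 0.40,
                            p_max = 0.05, r_min = 0.7,
                            network_perms = 1000, sparcc_iter = 20,
                            perm_sparcc_iter = 5,
                            n_boot = 1000, cv = "loocv",
                            variance_target = 0.80, seed = 1) {
  cfg <- list(table = table, metadata = metadata, out_dir = out_dir,
              group_a = group_a, group_b = group_b, dialect = dialect,
              rarefy_depth = rarefy_depth, rarefy_perms = rarefy_perms,
              key_threshold = key_threshold, prevalence = prevalence,
              p_max = p_max, r_min = r_min,
              network_perms = network_perms, sparcc_iter = sparcc_iter,
              perm_sparcc_iter = perm_sparcc_iter,
              n_boot = n_boot, cv = cv,
              variance_target = variance_target, seed = as.integer(seed))
  stopifnot(is.character(cfg$table), is.character(cfg$metadata))
  if (!cfg$key_threshold > 0 || cfg$key_threshold >= 1)
    stop("key_threshold must be in (0, 1)")
  if (cfg$prevalence < 0 || cfg$prevalence >= 1)
    stop("prevalence must be in [0, 1)")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must be in (0, 1]")
  if (cfg$r_min < 0 || cfg$r_min >= 1) stop("r_min must be in [0, 1)")
  if (cfg$variance_target <= 0 || cfg$variance_target > 1)
    stop("variance_target must be in (0, 1]")
  for (f in c("rarefy_perms", "network_perms", "sparcc_iter",
              "perm_sparcc_iter", "n_boot"))
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$rarefy_depth < 0) stop("rarefy_depth must be >= 0")
  if (!cfg$cv %in% c("loocv", "none")) stop("cv must be 'loocv' or 'none'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat YAML key/value file
#' @param path config file; keys are \code{\link{pipeline_config}} arguments.
#' @param ... overrides taking precedence over the file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_msg <- function(...) message("[wtnet] ", ...)

#' Run the full analysis pipeline
#'
#' Executes, on one OTU table and metadata file: rarefaction; alpha
#' diversity (observed OTUs, Shannon); Bray-Curtis beta diversity with PCoA;
#' Hellinger transform, two-group RDA, key-OTU selection and the WT-index
#' with (optionally leave-one-out cross-validated) ROC/AUC and a stratified
#' bootstrap CI; per-group prevalence-filtered SparCC networks with
#' permutation edge p-values; topology metrics and their KS comparison;
#' per-phylum Mann-Whitney tests with BH-FDR (when taxonomy is present); and
#' a MANOVA on the principal coordinates reaching the variance target.
#'
#' Every output is written under \code{out_dir} without timestamps, so a
#' rerun with an identical configuration reproduces every file byte for
#' byte. \code{manifest.json} records all parameters, derived stage seeds
#' and the package version.
#'
#' @param config a \code{pipeline_config}.
#' @return (invisibly) the summary list written to \code{summary.json}.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(rarefy = config$seed + 1000L,
                boot = config$seed + 2000L,
                sparcc_a = config$seed + 3000L,
                sparcc_b = config$seed + 4000L,
                perm_a = config$seed + 5000L,
                perm_b = config$seed + 6000L)
  gp <- c(config$group_a, config$group_b)

  stage_msg("reading inputs")
  tab <- read_otu_table(config$table, dialect = config$dialect)
  meta <- read_sample_metadata(config$metadata)
  meta <- match_meta(tab, meta)

  if (config$rarefy_depth > 0) {
    stage_msg("rarefying to ", config$rarefy_depth, " reads, ",
              config$rarefy_perms, " permutations")
    rar <- rarefy(tab, config$rarefy_depth, n_perm = config$rarefy_perms,
                  seed = seeds$rarefy, on_shallow = "drop")
  } else rar <- tab
  keep <- match(rar$sample_ids, meta$sample_id)
  meta_r <- meta[keep, , drop = FALSE]

  stage_msg("alpha and beta diversity")
  alpha <- data.frame(sample_id = rar$sample_ids,
                      group = meta_r$group,
                      observed_otus = alpha_diversity(rar, "observed_otus"),
                      shannon = alpha_diversity(rar, "shannon"),
                      stringsAsFactors = FALSE)
  write_tsv(alpha, file.path(config$out_dir, "alpha_diversity.tsv"))
  dm <- bray_curtis(rar)
  write_distance_matrix(dm, file.path(config$out_dir, "bray_curtis.tsv"))
  ord <- pcoa(dm, n_axes = min(4, nrow(dm) - 1))
  write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates,
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "pcoa.tsv"))

  stage_msg("RDA, key OTUs and WT-index")
  A <- hellinger(tab)   # raw counts: Hellinger already normalizes depth
  fit <- rda_two_group(A, meta, gp)
  keys <- select_key_otus(fit, threshold = config$key_threshold)
  write_tsv(data.frame(
    otu_id = c(keys$N, keys$M),
    set = c(rep("N", length(keys$N)), rep("M", length(keys$M))),
    variance_explained = keys$variance_explained[c(keys$N, keys$M)],
    stringsAsFactors = FALSE),
    file.path(config$out_dir, "key_otus.tsv"))
  wi <- wt_index(A, keys)
  wi$group <- meta$group
  write_tsv(wi, file.path(config$out_dir, "wt_index.tsv"))

  if (config$cv == "loocv") {
    stage_msg("LOOCV ROC with ", config$n_boot, " bootstrap replicates")
    roc <- loocv_auc(tab, meta, gp, threshold = config$key_threshold,
                     n_boot = config$n_boot, seed = seeds$boot)
  } else {
    sub <- meta$group %in% gp
    roc <- roc_auc(wi$index[sub], meta$group[sub], positive = gp[1])
    ci <- bootstrap_auc_ci(wi$index[sub], meta$group[sub], positive = gp[1],
                           n_boot = config$n_boot, seed = seeds$boot)
    roc$ci_low <- ci[["ci_low"]]; roc$ci_high <- ci[["ci_high"]]
    roc$n_bootstrap <- config$n_boot
  }
  write_tsv(roc$pairs, file.path(config$out_dir, "roc_points.tsv"))

  stage_msg("per-group SparCC networks (", config$network_perms,
            " permutations)")
  nets <- list(); tops <- list()
  for (gi in 1:2) {
    g <- gp[gi]
    gt <- subset_otu_table(tab, samples = meta$group == g)
    gt <- prevalence_filter(gt, config$prevalence)
    r <- sparcc(gt, n_estimation_iter = config$sparcc_iter,
                seed = seeds[[paste0("sparcc_", letters[gi])]])
    pv <- permutation_pvalues(gt, r, n_perm = config$network_perms,
                              seed = seeds[[paste0("perm_", letters[gi])]],
                              perm_estimation_iter = config$perm_sparcc_iter)
    net <- build_network(r, pv, p_max = config$p_max,
                         r_min_abs = config$r_min)
    slug <- gsub("[^A-Za-z0-9]+", "_", g)
    write_network(net, file.path(config$out_dir,
                                 paste0("network_", slug, ".tsv")))
    write_network(net, file.path(config$out_dir,
                                 paste0("network_", slug, ".graphml")),
                  format = "graphml")
    nets[[g]] <- net
    tops[[g]] <- topology(net)
    jsonlite::write_json(
      c(as.list(topology_scalars(tops[[g]])),
        list(degree = unname(tops[[g]]$degree),
             eigenvector_centrality =
               unname(tops[[g]]$eigenvector_centrality))),
      file.path(config$out_dir, paste0("topology_", slug, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  cmp <- compare_topologies(tops[[gp[1]]], tops[[gp[2]]])
  write_tsv(cmp$metrics, file.path(config$out_dir, "topology_compare.tsv"))

  phylum <- NULL
  if (!is.null(tab$taxonomy)) {
    stage_msg("per-phylum tests")
    phylum <- phylum_abundance_test(tab, meta, gp)
    write_tsv(phylum, file.path(config$out_dir, "phylum_tests.tsv"))
  }

  man <- tryCatch(manova_on_pcs(dm, meta_r,
                                variance_target = config$variance_target),
                  error = function(e) list(statistic = NA_real_,
                                           p_value = NA_real_,
                                           n_axes = NA_integer_,
                                           method = conditionMessage(e)))

  summary <- list(
    n_samples = length(tab$sample_ids),
    n_otus = length(tab$otu_ids),
    groups = gp,
    n_per_group = as.list(stats::setNames(
      as.integer(base::table(factor(meta$group, levels = gp))), gp)),
    auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
    cv = roc$cv_mode, n_bootstrap = roc$n_bootstrap,
    n_key_otus = length(keys$N) + length(keys$M),
    n_ref_enriched = length(keys$N), n_contrast_enriched = length(keys$M),
    manova = list(statistic = man$statistic, p_value = man$p_value,
                  n_axes = man$n_axes, method = man$method),
    topology = lapply(tops, function(t) as.list(topology_scalars(t))),
    ks_degree_p = cmp$ks_degree$p_value,
    ks_centrality_p = cmp$ks_centrality$p_value,
    n_phyla_tested = if (!is.null(phylum)) nrow(phylum) else 0L,
    n_phyla_fdr05 = if (!is.null(phylum))
      sum(phylum$adjusted_p < 0.05) else 0L)
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(parameters = unclass(config), stage_seeds = seeds,
                   package_version = as.character(
                     utils::packageVersion("wtnet")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
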