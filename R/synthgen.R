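#' Specification of a synthetic two-group OTU study
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: per-sample basis log-abundances drawn from a multivariate normal
#' with optional within-block correlation, a group effect of
#' \code{log2_fc * log(2)} added to the planted OTUs' means (reference-group
#' samples get it on the reference-enriched set, contrast-group samples on
#' the contrast-enriched set), closure to proportions, and multinomial count
#' draws at each sample's depth.
#'
#' Defaults mirror the study scale: 300 OTUs, 15 samples per group, 30
#' reference-enriched and 20 contrast-enriched OTUs, fixed depth 9000.
#' Planted OTUs are drawn from the upper-median abundance half of the
#' community (the study's key OTUs include dominant genera); correlation
#' blocks are assigned to randomly chosen disjoint OTU sets.
#'
#' @param p_otus number of OTUs.
#' @param n_per_group length-2 integer, samples per group.
#' @param groups the two group labels (reference first).
#' @param depth list: \code{type} \code{"fixed"} or \code{"lognormal"},
#'   \code{mean} reads per sample, \code{sdlog} (lognormal only).
#' @param n_ref_enriched,n_contrast_enriched planted set sizes.
#' @param log2_fc planted log2 fold change (0 = null data).
#' @param basis_logmean,basis_logsd mean/sd of the between-OTU log-abundance
#'   distribution.
#' @param sample_logsd within-group per-sample log-scale noise sd.
#' @param corr_blocks list of \code{list(size =, rho =)} correlation blocks
#'   on the basis logs.
#' @param n_phyla number of phyla for the simple taxonomy assignment.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return validated list of class \code{synth_spec}.
#' @export
synth_spec <- function(p_otus = 300, n_per_group = c(15, 15),
                       groups = c("+/+", "+/R258W"),
                       depth = list(type = "fixed", mean = 9000,
                                    sdlog = 0.25),
                       n_ref_enriched = 30, n_contrast_enriched = 20,
                       log2_fc = 2, basis_logmean = 0, basis_logsd = 2,
                       sample_logsd = 1, corr_blocks = list(),
                       n_phyla = 6, seed = 1) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  stopifnot(p_otus >= 4, length(n_per_group) == 2, all(n_per_group >= 1),
            length(groups) == 2, log2_fc >= 0, sample_logsd > 0,
            depth$mean > 0)
  if (n_ref_enriched + n_contrast_enriched > p_otus)
    stop("planted sets exceed the number of OTUs")
  for (b in corr_blocks)
    stopifnot(b$size >= 2, b$rho > -1, b$rho < 1)
  if (sum(vapply(corr_blocks, `[[`, 0, "size")) > p_otus)
    stop("correlation blocks exceed the number of OTUs")
  structure(list(p_otus = p_otus, n_per_group = n_per_group, groups = groups,
                 depth = depth, n_ref_enriched = n_ref_enriched,
                 n_contrast_enriched = n_contrast_enriched,
                 log2_fc = log2_fc, basis_logmean = basis_logmean,
                 basis_logsd = basis_logsd, sample_logsd = sample_logsd,
                 corr_blocks = corr_blocks, n_phyla = n_phyla, seed = seed),
            class = "synth_spec")
}

phylum_pool <- c("Bacteroidetes", "Firmicutes", "Actinobacteria",
                 "Verrucomicrobia", "Proteobacteria", "Tenericutes",
                 "Deferribacteres", "Cyanobacteria")

# block-structured noise: per-block Cholesky, independent remainder
draw_block_noise <- function(n, p, sd, blocks, block_members) {
  z <- matrix(stats::rnorm(n * p, sd = sd), n, p)
  for (bi in seq_along(blocks)) {
    rho <- blocks[[bi]]$rho
    idx <- block_members[[bi]]
    S <- matrix(rho, length(idx), length(idx))
    diag(S) <- 1
    L <- chol(S)
    z[, idx] <- (matrix(stats::rnorm(n * length(idx)), n) %*% L) * sd
  }
  z
}

#' Generate a synthetic two-group OTU table with ground truth
#'
#' @param spec a \code{synth_spec}.
#' @param expected_props also estimate per-group expected proportions by
#'   Monte Carlo (\code{expected_props_m} draws per group); off by default
#'   because it dominates runtime in seed sweeps.
#' @param expected_props_m Monte Carlo draws for the expected proportions.
#' @return list with \code{table} (an \code{otu_table} with taxonomy),
#'   \code{metadata} (\code{sample_metadata}) and \code{truth}: list with
#'   planted sets \code{N} (reference-enriched ids) and \code{M}, the basis
#'   correlation matrix, block membership, per-OTU phylum, depths, and (if
#'   requested) \code{expected_props} (2 x p matrix).
#' @export
synth_community <- function(spec, expected_props = FALSE,
                            expected_props_m = 5000) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- spec$p_otus
  n <- sum(spec$n_per_group)
  withr::with_seed(spec$seed, {
    otu_ids <- sprintf("otu%03d", seq_len(p))
    mu <- stats::rnorm(p, spec$basis_logmean, spec$basis_logsd)

    eligible <- which(mu >= stats::median(mu))
    n_plant <- spec$n_ref_enriched + spec$n_contrast_enriched
    if (n_plant > length(eligible))
      stop("not enough abundant OTUs to plant the differential sets")
    planted <- sample(eligible, n_plant)
    idx_N <- planted[seq_len(spec$n_ref_enriched)]
    idx_M <- setdiff(planted, idx_N)

    free <- seq_len(p)
    block_members <- lapply(spec$corr_blocks, function(b) {
      m <- sample(free, b$size)
      free <<- setdiff(free, m)
      m
    })

    effect <- spec$log2_fc * log(2)
    shift <- matrix(0, n, p)
    grp <- rep(spec$groups, spec$n_per_group)
    shift[grp == spec$groups[1], idx_N] <- effect
    shift[grp == spec$groups[2], idx_M] <- effect

    noise <- draw_block_noise(n, p, spec$sample_logsd, spec$corr_blocks,
                              block_members)
    z <- matrix(mu, n, p, byrow = TRUE) + shift + noise
    props <- exp(z)
    props <- props / rowSums(props)

    depths <- switch(spec$depth$type,
      fixed = rep(round(spec$depth$mean), n),
      lognormal = pmax(100L, round(stats::rlnorm(
        n, log(spec$depth$mean), spec$depth$sdlog))),
      stop("unknown depth model: ", spec$depth$type))
    counts <- t(vapply(seq_len(n), function(i)
      stats::rmultinom(1, depths[i], props[i, ])[, 1], integer(p)))

    phyla <- sample(phylum_pool[seq_len(spec$n_phyla)], p, replace = TRUE)
    taxonomy <- stats::setNames(paste0("k__Bacteria; p__", phyla), otu_ids)

    sample_ids <- sprintf("s%03d", seq_len(n))
    rownames(counts) <- sample_ids
    colnames(counts) <- otu_ids
    meta <- sample_metadata(data.frame(
      sample_id = sample_ids, group = grp, subject = sample_ids,
      timepoint = 0, housing = "sh", stringsAsFactors = FALSE))

    corr <- diag(p)
    for (bi in seq_along(block_members)) {
      idx <- block_members[[bi]]
      corr[idx, idx] <- spec$corr_blocks[[bi]]$rho
      diag(corr)[idx] <- 1
    }

    ep <- NULL
    if (expected_props) {
      ep <- t(vapply(1:2, function(gi) {
        sh <- numeric(p)
        if (gi == 1) sh[idx_N] <- effect else sh[idx_M] <- effect
        zz <- matrix(mu + sh, expected_props_m, p, byrow = TRUE) +
          draw_block_noise(expected_props_m, p, spec$sample_logsd,
                           spec$corr_blocks, block_members)
        pr <- exp(zz)
        colMeans(pr / rowSums(pr))
      }, numeric(p)))
      dimnames(ep) <- list(spec$groups, otu_ids)
    }

    list(table = otu_table(counts, taxonomy = taxonomy),
         metadata = meta,
         truth = list(N = otu_ids[idx_N], M = otu_ids[idx_M],
                      basis_corr = corr,
                      block_members = lapply(block_members, function(i)
                        otu_ids[i]),
                      phylum = stats::setNames(phyla, otu_ids),
                      basis_logmean = stats::setNames(mu, otu_ids),
                      depths = depths,
                      expected_props = ep))
  })
}

#' Generate a longitudinal (random-walk) synthetic study
#'
#' Each subject starts from its own baseline basis log-abundance draw (as in
#' \code{\link{synth_community}}, planted effects included) and then follows
#' a per-OTU Gaussian random walk across timepoints with a group-specific
#' per-day drift sd; the group with larger drift shows larger expected
#' Bray-Curtis deviation from baseline.
#'
#' @param spec a \code{synth_spec}; \code{n_per_group} is read as subjects
#'   per group.
#' @param drift_sd length-2 numeric, per-day random-walk sd per group
#'   (non-negative; scaled by the square root of elapsed days).
#' @param timepoints integer days (treatment starts at day 0); baselines are
#'   the timepoints < 0.
#' @return list with \code{table}, \code{metadata} (sample per subject x
#'   timepoint) and \code{truth}.
#' @export
synth_longitudinal <- function(spec, drift_sd = c(0.1, 0.3),
                               timepoints = c(-20, -10, -3, 0, 1, 2, 3, 8)) {
  stopifnot(inherits(spec, "synth_spec"), length(drift_sd) == 2,
            all(drift_sd >= 0), length(timepoints) >= 2)
  timepoints <- sort(timepoints)
  p <- spec$p_otus
  n_subj <- sum(spec$n_per_group)
  nt <- length(timepoints)
  withr::with_seed(spec$seed, {
    otu_ids <- sprintf("otu%03d", seq_len(p))
    mu <- stats::rnorm(p, spec$basis_logmean, spec$basis_logsd)
    eligible <- which(mu >= stats::median(mu))
    planted <- sample(eligible,
                      spec$n_ref_enriched + spec$n_contrast_enriched)
    idx_N <- planted[seq_len(spec$n_ref_enriched)]
    idx_M <- setdiff(planted, idx_N)
    free <- seq_len(p)
    block_members <- lapply(spec$corr_blocks, function(b) {
      m <- sample(free, b$size); free <<- setdiff(free, m); m
    })
    effect <- spec$log2_fc * log(2)
    grp_subj <- rep(spec$groups, spec$n_per_group)

    z0 <- matrix(mu, n_subj, p, byrow = TRUE) +
      draw_block_noise(n_subj, p, spec$sample_logsd, spec$corr_blocks,
                       block_members)
    z0[grp_subj == spec$groups[1], idx_N] <-
      z0[grp_subj == spec$groups[1], idx_N] + effect
    z0[grp_subj == spec$groups[2], idx_M] <-
      z0[grp_subj == spec$groups[2], idx_M] + effect

    rows <- list(); meta_rows <- list(); k <- 0L
    for (s in seq_len(n_subj)) {
      sd_g <- drift_sd[match(grp_subj[s], spec$groups)]
      z <- z0[s, ]
      for (ti in seq_len(nt)) {
        if (ti > 1) {
          dt <- timepoints[ti] - timepoints[ti - 1]
          z <- z + stats::rnorm(p, 0, sd_g * sqrt(dt))
        }
        pr <- exp(z); pr <- pr / sum(pr)
        depth <- switch(spec$depth$type,
          fixed = round(spec$depth$mean),
          lognormal = max(100L, round(stats::rlnorm(
            1, log(spec$depth$mean), spec$depth$sdlog))))
        k <- k + 1L
        rows[[k]] <- stats::rmultinom(1, depth, pr)[, 1]
        meta_rows[[k]] <- data.frame(
          sample_id = sprintf("sub%02d_t%+03d", s, timepoints[ti]),
          group = grp_subj[s], subject = sprintf("sub%02d", s),
          timepoint = timepoints[ti],
          housing = if (grp_subj[s] == spec$groups[1]) "sh" else "ch",
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
    meta <- do.call(rbind, meta_rows)
    rownames(counts) <- meta$sample_id
    colnames(counts) <- otu_ids
    list(table = otu_table(counts),
         metadata = sample_metadata(meta),
         truth = list(N = otu_ids[idx_N], M = otu_ids[idx_M],
                      drift_sd = drift_sd, timepoints = timepoints))
  })
}
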