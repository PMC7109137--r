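#' Per-site allele statistics
#'
#' @param g a [genotype_matrix()].
#' @return Data frame with per-site alternate-allele frequency `p`, minor
#'   allele frequency `maf` (both from non-missing dosages) and missing
#'   fraction `missing`.
#' @export
site_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  data.frame(
    chrom = g$sites$chrom, pos = g$sites$pos,
    p = p, maf = pmin(p, 1 - p),
    missing = colMeans(is.na(g$dosage))
  )
}

subset_sites <- function(g, keep) {
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$sites[keep, , drop = FALSE], imputed = g$imputed)
}

new_filter_report <- function(kind, n_sites_in, stages, n_sites_out,
                              n_ind_in = NULL, n_ind_out = NULL, thresholds) {
  structure(list(kind = kind, n_sites_in = n_sites_in, stages = stages,
                 n_sites_out = n_sites_out, n_ind_in = n_ind_in,
                 n_ind_out = n_ind_out, thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report (", x$kind, ")\n", sep = "")
  cat("  sites in:  ", x$n_sites_in, "\n", sep = "")
  for (s in names(x$stages)) {
    cat(sprintf("  removed by %-12s %d\n", paste0(s, ":"), x$stages[[s]]))
  }
  cat("  sites out: ", x$n_sites_out, "\n", sep = "")
  if (!is.null(x$n_ind_in) && x$n_ind_in != x$n_ind_out) {
    cat("  individuals: ", x$n_ind_in, " -> ", x$n_ind_out, "\n", sep = "")
  }
  invisible(x)
}

#' Write a filter report as plain text and JSON
#'
#' @param report a `filter_report` from [filter_sites()] or [filter_coverage()].
#' @param path_txt,path_json output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_filter_report <- function(report, path_txt = NULL, path_json = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (!is.null(path_txt)) {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path_txt)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(report)
}

#' Marker quality filters: missingness, MAF, adjacency
#'
#' Applies, in order: (1) remove sites whose missing fraction exceeds
#' `max_missing_frac`; (2) remove sites with minor allele frequency below
#' `min_maf` (computed on non-missing dosages; a site at exactly `min_maf`
#' is retained); (3) when `remove_adjacent`, remove any site whose
#' same-chromosome predecessor lies within 1 bp — i.e. of each pair
#' separated by at most one base, the higher-position member is dropped.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated per-site missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @param remove_adjacent drop near-adjacent (<= 1 bp) sites?
#' @return List with the filtered `genotypes` and a `report`
#'   (`filter_report`) counting removals per rule.
#' @export
filter_sites <- function(g, max_missing_frac = 0.10, min_maf = 0.05,
                         remove_adjacent = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_in <- ncol(g$dosage)
  if (n_in == 0L) stop("empty genotype matrix")

  miss <- colMeans(is.na(g$dosage))
  keep1 <- miss <= max_missing_frac
  g1 <- subset_sites(g, keep1)

  if (ncol(g1$dosage) > 0L) {
    p <- colMeans(g1$dosage, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep2 <- !is.na(maf) & maf >= min_maf
  } else keep2 <- logical(0)
  g2 <- subset_sites(g1, keep2)

  if (remove_adjacent && ncol(g2$dosage) > 0L) {
    keep3 <- rep(TRUE, ncol(g2$dosage))
    for (ch in unique(g2$sites$chrom)) {
      idx <- which(g2$sites$chrom == ch)
      if (length(idx) > 1L) {
        close_pair <- diff(g2$sites$pos[idx]) <= 1L
        keep3[idx[-1L][close_pair]] <- FALSE
      }
    }
  } else keep3 <- rep(TRUE, ncol(g2$dosage))
  g3 <- subset_sites(g2, keep3)

  stages <- list(missingness = sum(!keep1), maf = sum(!keep2),
                 adjacency = sum(!keep3))
  if (ncol(g3$dosage) == 0L) {
    stop("all sites removed by filters; relax max_missing_frac (",
         max_missing_frac, ") or min_maf (", min_maf, ")")
  }
  report <- new_filter_report(
    "sites", n_in, stages, ncol(g3$dosage),
    n_ind_in = nrow(g$dosage), n_ind_out = nrow(g3$dosage),
    thresholds = list(max_missing_frac = max_missing_frac, min_maf = min_maf,
                      remove_adjacent = remove_adjacent)
  )
  list(genotypes = g3, report = report)
}

#' Coverage-style filters (site coverage, taxa coverage, MAF)
#'
#' GBS-pipeline style filtering: drops sites with non-missing fraction
#' below `min_site_cov`, then individuals with non-missing fraction (over
#' the retained sites) below `min_taxa_cov`, then sites with minor allele
#' frequency below `min_maf`.
#'
#' @param g a [genotype_matrix()].
#' @param min_site_cov minimum per-site non-missing fraction.
#' @param min_taxa_cov minimum per-individual non-missing fraction.
#' @param min_maf minimum minor allele frequency.
#' @return List with filtered `genotypes` and a `report`.
#' @export
filter_coverage <- function(g, min_site_cov = 0.9, min_taxa_cov = 0.8,
                            min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_in <- ncol(g$dosage)
  if (n_in == 0L) stop("empty genotype matrix")

  scov <- colMeans(!is.na(g$dosage))
  keep_s <- scov >= min_site_cov
  g1 <- subset_sites(g, keep_s)
  if (ncol(g1$dosage) == 0L) stop("all sites removed by site-coverage filter")

  tcov <- rowMeans(!is.na(g1$dosage))
  keep_t <- tcov >= min_taxa_cov
  if (!any(keep_t)) stop("all individuals removed by taxa-coverage filter")
  g2 <- genotype_matrix(g1$dosage[keep_t, , drop = FALSE], g1$sites,
                        imputed = g1$imputed)

  p <- colMeans(g2$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf >= min_maf
  g3 <- subset_sites(g2, keep_m)
  if (ncol(g3$dosage) == 0L) stop("all sites removed by MAF filter")

  report <- new_filter_report(
    "coverage", n_in,
    list(site_coverage = sum(!keep_s), taxa_coverage = sum(!keep_t),
         maf = sum(!keep_m)),
    ncol(g3$dosage), n_ind_in = nrow(g$dosage), n_ind_out = nrow(g3$dosage),
    thresholds = list(min_site_cov = min_site_cov, min_taxa_cov = min_taxa_cov,
                      min_maf = min_maf)
  )
  list(genotypes = g3, report = report)
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing entry by its site's mean non-missing dosage
#' (real-valued). A deterministic stand-in for haplotype-based imputation;
#' the `seed` argument is accepted for interface stability with stochastic
#' imputers and only logged.
#'
#' @param g a [genotype_matrix()].
#' @param seed integer; reserved, logged only.
#' @return An imputed [genotype_matrix()] (no missing entries).
#' @export
impute_mean <- function(g, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss_per_site <- colSums(is.na(g$dosage))
  if (any(miss_per_site == nrow(g$dosage))) {
    j <- which(miss_per_site == nrow(g$dosage))[1L]
    stop("site ", colnames(g$dosage)[j],
         " is fully missing; filter sites before imputation")
  }
  if (!anyNA(g$dosage)) {
    g$imputed <- TRUE
    return(g)
  }
  message("impute_mean: deterministic mean imputation (seed ", seed, " logged, unused)")
  d <- g$dosage
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  genotype_matrix(d, g$sites, imputed = TRUE)
}

#' Per-individual heterozygosity
#'
#' Proportion of non-missing SNP loci at which the individual is
#' heterozygous (dosage exactly 1). Intended for raw integer dosages.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector in \[0, 1\], one entry per individual.
#' @export
heterozygosity <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nonmiss <- rowSums(!is.na(g$dosage))
  if (any(nonmiss == 0L)) {
    stop("individual ", rownames(g$dosage)[which(nonmiss == 0L)[1L]],
         " has no non-missing sites")
  }
  het <- rowSums(g$dosage == 1, na.rm = TRUE)
  setNames(het / nonmiss, rownames(g$dosage))
}
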