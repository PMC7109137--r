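#' Default trait panel for the breeding-population simulator
#'
#' Eight fruit-quality traits with narrow-sense heritabilities spanning
#' 0.15-0.50, means and phenotypic SDs typical of a diverse apple
#' accession panel (fruit weight in g, russet/crispness/juiciness/
#' astringency on 0-9 scores, firmness kg/cm3, soluble solids %, acidity
#' % malic acid). Permanent-environment fraction defaults to 0.15 of the
#' phenotypic variance for every trait.
#'
#' @param pe_fraction permanent-environment variance fraction.
#' @param n_qtl number of QTL per trait.
#' @return Data frame with columns `name`, `h2`, `pe_fraction`, `mean`,
#'   `sd`, `n_qtl`.
#' @export
default_traits <- function(pe_fraction = 0.15, n_qtl = 200L) {
  data.frame(
    name = c("AVFW", "FIRM", "ASTR", "RUSS", "SSC", "TA", "CRISP", "JUIC"),
    h2 = c(0.50, 0.41, 0.26, 0.21, 0.18, 0.17, 0.15, 0.15),
    pe_fraction = pe_fraction,
    mean = c(136, 7.8, 0.9, 2.5, 15.4, 0.83, 3.5, 2.6),
    sd = c(90, 2.5, 1.1, 0.99, 1.8, 0.37, 1.0, 1.2),
    n_qtl = as.integer(n_qtl),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes a two-generation cross-pollinated breeding population:
#' founder accessions genotyped at biallelic SNPs spread over several
#' chromosomes, a crossing design with a target mean number of crosses
#' per parent, gene-dropped progeny, and repeated multi-trait phenotypes
#' with additive, permanent-environment, year and residual components.
#'
#' @param n_founders number of parental accessions.
#' @param n_chromosomes number of chromosomes.
#' @param n_snps total SNPs (distributed near-evenly over chromosomes).
#' @param maf_range founder allele frequencies drawn uniformly here.
#' @param chr_length_morgans genetic length per chromosome (M).
#' @param chr_length_bp physical length per chromosome (bp).
#' @param mean_crosses_per_parent expected crosses each parent enters.
#' @param progeny_per_cross offspring per cross.
#' @param traits data.frame as [default_traits()].
#' @param n_years repeated-record years for parents.
#' @param progeny_records records per progeny (default one).
#' @param year_effect_sd year effects are `(0, 0.2 sd, ...)` per trait;
#'   scaling factor of the non-reference year offsets.
#' @param missing_rate missing-genotype rate applied when a study is
#'   written to disk (exercises the filters/imputation).
#' @param seed master seed; every random draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 274L, n_chromosomes = 17L, n_snps = 6400L,
                       maf_range = c(0.05, 0.5), chr_length_morgans = 1.0,
                       chr_length_bp = 3e7, mean_crosses_per_parent = 2,
                       progeny_per_cross = 18L, traits = default_traits(),
                       n_years = 2L, progeny_records = 1L,
                       year_effect_sd = 0.2, missing_rate = 0.04, seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders), n_chromosomes = as.integer(n_chromosomes),
    n_snps = as.integer(n_snps), maf_range = maf_range,
    chr_length_morgans = chr_length_morgans, chr_length_bp = chr_length_bp,
    mean_crosses_per_parent = mean_crosses_per_parent,
    progeny_per_cross = as.integer(progeny_per_cross), traits = traits,
    n_years = as.integer(n_years), progeny_records = as.integer(progeny_records),
    year_effect_sd = year_effect_sd, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_snps <= 0L) stop("n_snps must be positive")
  stopifnot(is.data.frame(traits),
            all(c("name", "h2", "pe_fraction", "mean", "sd", "n_qtl") %in% names(traits)))
  if (any(traits$h2 + traits$pe_fraction > 1)) {
    stop("h2 + pe_fraction must not exceed 1 for any trait")
  }
  if (any(traits$n_qtl > cfg$n_snps)) stop("n_qtl exceeds n_snps")
  class(cfg) <- "sim_config"
  cfg
}

# Small deterministic sub-seed scheme; keeps derived seeds < 2^31.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

#' Simulate founder genotypes
#'
#' Founder haplotypes are drawn site-wise independently (linkage
#' equilibrium, Hardy-Weinberg) with allele frequencies uniform on
#' `maf_range`; positions are distinct with at least 2 bp spacing so the
#' adjacency filter is exercised only by constructed inputs.
#'
#' @param cfg a [sim_config()].
#' @return List of class `founder_sim`: `genotypes` (a
#'   [genotype_matrix()]), `haplotypes` (list `H1`, `H2` of 0/1 matrices),
#'   `freq` (per-site allele frequencies).
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps <= 0L) stop("n_snps must be positive")
  per_chr <- rep(cfg$n_snps %/% cfg$n_chromosomes, cfg$n_chromosomes)
  rem <- cfg$n_snps %% cfg$n_chromosomes
  if (rem > 0L) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1L
  max_sites <- floor(cfg$chr_length_bp / 2)
  if (any(per_chr > max_sites)) {
    stop("too many SNPs for chromosome length: cannot keep >= 2 bp spacing")
  }
  ids <- sprintf("P%04d", seq_len(cfg$n_founders))
  withr::with_seed(sub_seed(cfg$seed, 1L), {
    sites <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(c_) {
      pos <- sort(sample.int(max_sites, per_chr[c_])) * 2L
      data.frame(chrom = sprintf("chr%02d", c_), pos = pos,
                 stringsAsFactors = FALSE)
    }))
    m <- nrow(sites)
    freq <- runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
    alleles <- c("A", "C", "G", "T")
    ra <- t(vapply(seq_len(m), function(j) sample(alleles, 2L), character(2L)))
    sites$ref <- ra[, 1L]; sites$alt <- ra[, 2L]
    n <- cfg$n_founders
    H1 <- matrix(rbinom(n * m, 1L, rep(freq, each = n)), n, m)
    H2 <- matrix(rbinom(n * m, 1L, rep(freq, each = n)), n, m)
    rownames(H1) <- rownames(H2) <- ids
    g <- genotype_matrix(H1 + H2, sites)
    structure(list(genotypes = g, haplotypes = list(H1 = H1, H2 = H2),
                   freq = freq, cfg = cfg),
              class = "founder_sim")
  })
}

#' Simulate a two-generation crossing design
#'
#' Draws random parent pairs (no selfing) so that the expected number of
#' crosses each founder enters equals `mean_crosses_per_parent`; every
#' cross contributes `progeny_per_cross` offspring.
#'
#' @param cfg a [sim_config()].
#' @param founder_ids ids of the parental generation.
#' @return A [pedigree_table()] with founders first, then progeny.
#' @export
simulate_pedigree <- function(cfg, founder_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mean_crosses_per_parent <= 0) stop("mean_crosses_per_parent must be > 0")
  nf <- length(founder_ids)
  if (nf < 2L) stop("need at least 2 founders")
  n_crosses <- max(1L, round(nf * cfg$mean_crosses_per_parent / 2))
  withr::with_seed(sub_seed(cfg$seed, 2L), {
    pairs <- t(vapply(seq_len(n_crosses),
                      function(i) sample.int(nf, 2L), integer(2L)))
    n_prog <- n_crosses * cfg$progeny_per_cross
    prog_ids <- sprintf("F2_%05d", seq_len(n_prog))
    sire <- rep(founder_ids[pairs[, 1L]], each = cfg$progeny_per_cross)
    dam <- rep(founder_ids[pairs[, 2L]], each = cfg$progeny_per_cross)
    pedigree_table(
      c(founder_ids, prog_ids),
      c(rep(NA_character_, nf), sire),
      c(rep(NA_character_, nf), dam),
      generation = c(rep(1L, nf), rep(2L, n_prog))
    )
  })
}

#' Drop genes through a pedigree
#'
#' Transmits founder haplotypes to descendants: each gamete is formed per
#' chromosome with a Poisson(`chr_length_morgans`) number of crossovers at
#' uniform positions (Haldane model, no interference) between the two
#' parental haplotypes. Returns dosages for every pedigree individual.
#'
#' @param founders a `founder_sim` (from [simulate_founders()]).
#' @param ped a [pedigree_table()] whose founders all appear in `founders`.
#' @param cfg a [sim_config()].
#' @return List: `genotypes` ([genotype_matrix()] over all individuals),
#'   `haplotypes` (`H1`, `H2` over all individuals).
#' @export
gene_drop <- function(founders, ped, cfg) {
  stopifnot(inherits(founders, "founder_sim"), inherits(ped, "pedigree_table"))
  sites <- founders$genotypes$sites
  m <- nrow(sites)
  ids <- ped$individual
  n <- length(ids)
  chr_idx <- split(seq_len(m), sites$chrom)
  chr_pos <- lapply(chr_idx, function(ix) sites$pos[ix])
  H1 <- matrix(NA_integer_, n, m, dimnames = list(ids, NULL))
  H2 <- matrix(NA_integer_, n, m, dimnames = list(ids, NULL))
  f_ids <- rownames(founders$haplotypes$H1)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  fm <- match(ids[is_founder], f_ids)
  if (anyNA(fm)) {
    stop("pedigree founder(s) lack simulated haplotypes: ",
         paste(utils::head(ids[is_founder][is.na(fm)], 5L), collapse = ", "))
  }
  H1[is_founder, ] <- founders$haplotypes$H1[fm, , drop = FALSE]
  H2[is_founder, ] <- founders$haplotypes$H2[fm, , drop = FALSE]

  gamete <- function(p) {
    out <- integer(m)
    for (ci in seq_along(chr_idx)) {
      ix <- chr_idx[[ci]]
      pos <- chr_pos[[ci]]
      k <- rpois(1L, cfg$chr_length_morgans)
      start <- sample.int(2L, 1L)
      if (k == 0L) {
        out[ix] <- if (start == 1L) H1[p, ix] else H2[p, ix]
      } else {
        xo <- sort(runif(k, 0, cfg$chr_length_bp))
        seg <- findInterval(pos, xo)
        pick <- (start + seg) %% 2L  # 1 -> H1, 0 -> H2
        out[ix] <- ifelse(pick == 1L, H1[p, ix], H2[p, ix])
      }
    }
    out
  }

  withr::with_seed(sub_seed(cfg$seed, 3L), {
    for (i in which(!is_founder)) {
      if (is.na(si[i]) || is.na(di[i])) {
        stop("individual '", ids[i], "' has an unknown parent; cannot gene-drop")
      }
      H1[i, ] <- gamete(si[i])
      H2[i, ] <- gamete(di[i])
    }
  })
  dos <- H1 + H2
  rownames(dos) <- ids
  list(genotypes = genotype_matrix(dos, sites),
       haplotypes = list(H1 = H1, H2 = H2))
}

#' Simulate repeated multi-trait phenotypes with known truth
#'
#' Per trait: additive effects at `n_qtl` randomly chosen sites are drawn
#' standard normal and rescaled so the realized variance of the true
#' breeding values equals `h2 * sd^2`; permanent-environment deviations
#' are normal with variance `pe_fraction * sd^2`; the record of individual
#' i in year t is `mean + year_effect_t + bv_i + pe_i + e_it` with
#' residual variance `(1 - h2 - pe_fraction) * sd^2` (exactly zero allowed
#' as the noise-free limit). Parents (pedigree founders) receive
#' `n_years` records, progeny `progeny_records` record(s).
#'
#' @param g [genotype_matrix()] covering every phenotyped individual.
#' @param ped a [pedigree_table()].
#' @param cfg a [sim_config()].
#' @return List: `phenotypes` (`phenotype_records`) and `truth`
#'   (`simulation_truth`: per-trait QTL indices/effects, `true_bv`,
#'   `true_pe`, `year_effects`, realized variance components).
#' @export
simulate_phenotypes <- function(g, ped, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(ped, "pedigree_table"),
            inherits(cfg, "sim_config"))
  ids <- ped$individual
  if (!all(ids %in% rownames(g$dosage))) {
    stop("genotype matrix does not cover all pedigree individuals")
  }
  dos <- g$dosage[ids, , drop = FALSE]
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  n <- length(ids)
  m <- ncol(dos)
  rec_years <- ifelse(is_founder, cfg$n_years, cfg$progeny_records)

  all_rows <- list()
  truth <- list()
  for (ti in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[ti, ]
    vp <- tr$sd^2
    resid_var <- (1 - tr$h2 - tr$pe_fraction) * vp
    if (resid_var < -1e-12) stop("negative residual variance for trait ", tr$name)
    resid_var <- max(resid_var, 0)
    withr::with_seed(sub_seed(cfg$seed, 100L + ti), {
      qtl <- sort(sample.int(m, tr$n_qtl))
      alpha <- rnorm(tr$n_qtl)
      bv <- drop(dos[, qtl, drop = FALSE] %*% alpha)
      bv <- bv - mean(bv)
      v_bv <- stats::var(bv)
      if (v_bv <= 0) stop("degenerate true breeding values for trait ", tr$name)
      sc <- sqrt(tr$h2 * vp / v_bv)
      alpha <- alpha * sc
      bv <- bv * sc
      pe <- rnorm(n, 0, sqrt(tr$pe_fraction * vp))
      year_effects <- c(0, rep(cfg$year_effect_sd * tr$sd,
                               max(cfg$n_years - 1L, 0)) *
                            seq_len(max(cfg$n_years - 1L, 0)))
      e_list <- lapply(seq_len(cfg$n_years), function(t_) {
        rnorm(n, 0, sqrt(resid_var))
      })
      rows <- list()
      for (t_ in seq_len(cfg$n_years)) {
        take <- rec_years >= t_
        if (!any(take)) next
        rows[[t_]] <- data.frame(
          individual = ids[take], year = t_, trait = tr$name,
          value = tr$mean + year_effects[t_] + bv[take] + pe[take] +
            e_list[[t_]][take],
          stringsAsFactors = FALSE
        )
      }
      rec <- do.call(rbind, rows)
      all_rows[[ti]] <- rec
      truth[[tr$name]] <- list(
        qtl = qtl, effects = alpha,
        true_bv = setNames(bv, ids), true_pe = setNames(pe, ids),
        year_effects = year_effects,
        realized = list(
          var_bv = stats::var(bv), var_pe = stats::var(pe),
          resid_var = resid_var,
          h2 = stats::var(bv) / (stats::var(bv) + stats::var(pe) + resid_var)
        )
      )
    })
  }
  rec <- do.call(rbind, all_rows)
  phen <- phenotype_records(rec$individual, rec$year, rec$trait, rec$value)
  structure(list(phenotypes = phen,
                 truth = structure(truth, class = "simulation_truth")),
            class = "phenotype_sim")
}

#' Build a complete synthetic study
#'
#' Runs the whole generator at its default scale — 274 founder accessions,
#' ~274 crosses of ~18 offspring (about 5000 progeny), 6400 SNPs on 17
#' chromosomes, 8 traits with heritabilities 0.15-0.50 and two harvest
#' years of parental records — and (optionally) writes every standard
#' input file: pedigree and phenotype CSVs, parental genotypes as VCF and
#' dosage TSV (with `missing_rate` of entries masked), and the truth
#' tables as CSV + JSON.
#'
#' @param seed master seed.
#' @param out_dir directory to write files into; `NULL` to skip writing.
#' @param cfg optionally a custom [sim_config()] (its seed wins over
#'   `seed` when supplied).
#' @return List of class `study_data`: `cfg`, `pedigree`, `genotypes`
#'   (all individuals, complete), `genotypes_observed` (parents only,
#'   with missingness), `phenotypes`, `truth`, `paths`.
#' @export
default_study <- function(seed = 1L, out_dir = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  fs <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
  gd <- gene_drop(fs, ped, cfg)
  ph <- simulate_phenotypes(gd$genotypes, ped, cfg)

  par_ids <- founders(ped)
  gpar <- gd$genotypes
  gpar <- genotype_matrix(gpar$dosage[par_ids, , drop = FALSE], gpar$sites)
  if (cfg$missing_rate > 0) {
    d <- gpar$dosage
    mask <- withr::with_seed(sub_seed(cfg$seed, 4L), {
      matrix(runif(length(d)) < cfg$missing_rate, nrow(d), ncol(d))
    })
    d[mask] <- NA_real_
    gpar <- genotype_matrix(d, gpar$sites)
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      pedigree = file.path(out_dir, "pedigree.csv"),
      phenotypes = file.path(out_dir, "phenotypes.csv"),
      genotypes_vcf = file.path(out_dir, "genotypes.vcf"),
      genotypes_tsv = file.path(out_dir, "genotypes.tsv"),
      truth_csv = file.path(out_dir, "truth_bv.csv"),
      truth_json = file.path(out_dir, "truth_meta.json")
    )
    write_pedigree(ped, paths$pedigree)
    write_phenotypes(ph$phenotypes, paths$phenotypes)
    write_vcf(gpar, paths$genotypes_vcf)
    write_dosage_tsv(gpar, paths$genotypes_tsv)
    tb <- do.call(cbind, lapply(ph$truth, function(t_) t_$true_bv))
    data.table::fwrite(
      cbind(data.table::data.table(individual = rownames(tb)),
            data.table::as.data.table(tb)),
      paths$truth_csv
    )
    jsonlite::write_json(
      lapply(ph$truth, function(t_) list(
        qtl = t_$qtl, effects = t_$effects, year_effects = t_$year_effects,
        realized = t_$realized
      )),
      paths$truth_json, auto_unbox = TRUE, digits = NA
    )
  }
  structure(list(cfg = cfg, pedigree = ped, genotypes = gd$genotypes,
                 genotypes_observed = gpar, phenotypes = ph$phenotypes,
                 truth = ph$truth, paths = paths),
            class = "study_data")
}
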