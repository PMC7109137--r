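# Shared simulated studies for the heavier tests. Each is computed once
# per test run on first use and cached; scales and seeds are fixed up
# front as the stated world of the acceptance criteria.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# Heritability-recovery world: >= 1500 phenotyped progeny, three traits
# at true h2 0.15 / 0.30 / 0.50.
recovery_study <- function() {
  cached("recovery", {
    traits <- data.frame(
      name = c("low", "mid", "high"), h2 = c(0.15, 0.30, 0.50),
      pe_fraction = 0.15, mean = c(10, 20, 30), sd = c(1, 2, 3),
      n_qtl = 200L, stringsAsFactors = FALSE
    )
    cfg <- sim_config(n_founders = 160L, n_snps = 800L,
                      progeny_per_cross = 10L, traits = traits, seed = 501L)
    fs <- simulate_founders(cfg)
    ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
    gd <- gene_drop(fs, ped, cfg)
    ph <- simulate_phenotypes(gd$genotypes, ped, cfg)
    list(cfg = cfg, ped = ped, geno = gd$genotypes, phen = ph$phenotypes,
         truth = ph$truth)
  })
}

# Eight-trait world scaled to 200 parents / 2000 progeny (the default
# trait panel, h2 0.15-0.50) with per-trait own-phenotype BLUP-BVs and
# progeny-based GCA fits.
eight_trait_study <- function() {
  cached("eight", {
    cfg <- sim_config(n_founders = 200L, n_snps = 2000L,
                      progeny_per_cross = 10L, seed = 601L)
    fs <- simulate_founders(cfg)
    ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
    gd <- gene_drop(fs, ped, cfg)
    ph <- simulate_phenotypes(gd$genotypes, ped, cfg)
    par_ids <- founders(ped)
    own_phen <- ph$phenotypes[ph$phenotypes$individual %in% par_ids, ]
    prog_phen <- ph$phenotypes[!(ph$phenotypes$individual %in% par_ids), ]
    ped_par <- pedigree_table(par_ids, NA, NA)
    traits <- cfg$traits$name
    own <- gca <- list()
    for (tr in traits) {
      own[[tr]] <- own_phenotype_blup(own_phen, ped_par, tr)
      gca[[tr]] <- suppressMessages(progeny_gca(prog_phen, ped, tr, par_ids))
    }
    list(cfg = cfg, ped = ped, geno = gd$genotypes, phen = ph$phenotypes,
         truth = ph$truth, par_ids = par_ids, own = own, gca = gca)
  })
}

# Cross-validation world: 274 accessions, 2000 SNPs, eight traits; own
# BLUP-BVs, GCA, and the genomic relationship matrix of the accessions.
# Accession and SNP counts are the criterion's reduced scale; the progeny
# scale stays at the generator default (~18 per cross, ~5000 offspring).
cv_study <- function() {
  cached("cv", {
    cfg <- sim_config(n_founders = 274L, n_snps = 2000L, seed = 701L)
    fs <- simulate_founders(cfg)
    ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
    gd <- gene_drop(fs, ped, cfg)
    ph <- simulate_phenotypes(gd$genotypes, ped, cfg)
    par_ids <- founders(ped)
    own_phen <- ph$phenotypes[ph$phenotypes$individual %in% par_ids, ]
    prog_phen <- ph$phenotypes[!(ph$phenotypes$individual %in% par_ids), ]
    ped_par <- pedigree_table(par_ids, NA, NA)
    gpar <- genotype_matrix(gd$genotypes$dosage[par_ids, , drop = FALSE],
                            gd$genotypes$sites)
    G <- make_invertible(gmat_vanraden(gpar))
    traits <- cfg$traits$name
    own <- gca <- list()
    for (tr in traits) {
      own[[tr]] <- own_phenotype_blup(own_phen, ped_par, tr)
      gca[[tr]] <- suppressMessages(progeny_gca(prog_phen, ped, tr, par_ids))
    }
    list(cfg = cfg, ped = ped, par_ids = par_ids, G = G,
         truth = ph$truth, own = own, gca = gca)
  })
}
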