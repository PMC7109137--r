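test_that("sim_config validates trait settings", {
  tr <- default_traits()
  expect_s3_class(sim_config(), "sim_config")
  tr_bad <- tr; tr_bad$h2[1] <- 0.95  # + pe 0.15 > 1
  expect_error(sim_config(traits = tr_bad), "exceed 1")
  tr_q <- tr; tr_q$n_qtl <- 10000L
  expect_error(sim_config(traits = tr_q, n_snps = 500L), "n_qtl")
})

test_that("founder simulation respects HWE expectations and determinism", {
  cfg <- sim_config(n_founders = 400L, n_snps = 300L, maf_range = c(0.5, 0.5),
                    seed = 5L)
  fs <- simulate_founders(cfg)
  # mean dosage per site ~ Binomial(2n, 0.5)/n: 1 +- 3 SE
  se <- sqrt(2 * 0.5 * 0.5 / 400)
  mu <- colMeans(fs$genotypes$dosage)
  expect_gt(min(mu), 1 - 4 * se)
  expect_lt(max(mu), 1 + 4 * se)
  expect_gt(mean(abs(mu - 1) < 3 * se), 0.95)

  fs2 <- simulate_founders(cfg)
  expect_identical(fs$genotypes$dosage, fs2$genotypes$dosage)

  expect_error(sim_config(n_snps = 0L), "positive")
  expect_error(simulate_founders(
    sim_config(n_snps = 1000L, n_chromosomes = 1L, chr_length_bp = 500)),
    "spacing")
  # positions at least 2 bp apart
  pos <- fs$genotypes$sites$pos
  ch <- fs$genotypes$sites$chrom
  expect_true(all(unlist(tapply(pos, ch, diff)) >= 2))
})

test_that("crossing design hits the expected scale and avoids selfing", {
  cfg <- sim_config(n_founders = 274L, progeny_per_cross = 18L, seed = 2L)
  ids <- sprintf("P%04d", 1:274)
  ped <- simulate_pedigree(cfg, ids)
  prog <- ped[!(ped$individual %in% ids), ]
  expect_equal(nrow(prog) / 18L, 274L)  # ~274 crosses of 18 offspring
  expect_gte(nrow(prog), 4900L)
  expect_lte(nrow(prog), 5000L)
  expect_true(all(prog$sire != prog$dam))
  ped2 <- simulate_pedigree(cfg, ids)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))
  expect_error(simulate_pedigree(sim_config(mean_crosses_per_parent = 0), ids),
               "mean_crosses_per_parent")
})

test_that("gene drop transmits whole haplotypes when map length is zero", {
  cfg <- sim_config(n_founders = 10L, n_snps = 60L, n_chromosomes = 2L,
                    chr_length_morgans = 0, progeny_per_cross = 3L, seed = 9L,
                    traits = default_traits(n_qtl = 30L)[1, ])
  fs <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
  gd <- gene_drop(fs, ped, cfg)
  ids <- ped$individual
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)
  ch <- fs$genotypes$sites$chrom
  for (i in which(!is.na(si))) {
    for (cc in unique(ch)) {
      ix <- which(ch == cc)
      h <- gd$haplotypes$H1[i, ix]
      p1 <- gd$haplotypes$H1[si[i], ix]; p2 <- gd$haplotypes$H2[si[i], ix]
      expect_true(identical(h, p1) || identical(h, p2))
    }
  }
})

test_that("gene drop reproduces pedigree-expected genomic relationships", {
  cfg <- sim_config(n_founders = 60L, n_snps = 2000L, progeny_per_cross = 6L,
                    seed = 33L, traits = default_traits()[1, ])
  fs <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
  gd <- gene_drop(fs, ped, cfg)
  poly <- filter_sites(gd$genotypes, max_missing_frac = 1, min_maf = 1e-9,
                       remove_adjacent = FALSE)$genotypes
  G <- gmat_vanraden(poly)
  ids <- ped$individual
  prog <- ped[!is.na(ped$sire), ]
  # parent-offspring pairs
  po <- mean(G[cbind(match(prog$individual, ids), match(prog$sire, ids))])
  expect_lt(abs(po - 0.5), 0.1)
  # full sibs share both parents; half sibs share exactly one
  key <- paste(prog$sire, prog$dam)
  fs_pairs <- hs_pairs <- numeric(0)
  fam <- split(match(prog$individual, ids), key)
  for (f in fam) {
    if (length(f) >= 2) fs_pairs <- c(fs_pairs, G[t(utils::combn(f, 2))])
  }
  sires <- split(match(prog$individual, ids), prog$sire)
  for (s in names(sires)) {
    idx <- sires[[s]]
    if (length(idx) >= 2) {
      prs <- t(utils::combn(idx, 2))
      same_fam <- key[match(prs[, 1], match(prog$individual, ids))] ==
        key[match(prs[, 2], match(prog$individual, ids))]
      hs_pairs <- c(hs_pairs, G[prs[!same_fam, , drop = FALSE]])
    }
  }
  expect_lt(abs(mean(fs_pairs) - 0.5), 0.1)
  if (length(hs_pairs) > 5) expect_lt(abs(mean(hs_pairs) - 0.25), 0.1)
})

test_that("phenotype generation matches its stated generative model", {
  st <- recovery_study()
  truth <- st$truth
  phen <- st$phen
  for (tr in names(truth)) {
    t_ <- truth[[tr]]
    cfg_tr <- st$cfg$traits[st$cfg$traits$name == tr, ]
    # regression of record on true BV has slope ~ 1
    sub <- phen[phen$trait == tr & phen$year == 1, ]
    bv <- t_$true_bv[sub$individual]
    expect_lt(abs(unname(coef(lm(sub$value ~ bv))[2]) - 1), 0.05)
    # realized h2 within year close to target
    expect_lt(abs(var(bv) / var(sub$value) - cfg_tr$h2), 0.05)
    # recorded realized components are consistent
    expect_equal(t_$realized$var_bv, var(t_$true_bv), tolerance = 1e-12)
  }
})

test_that("noise-free limit returns records equal to mean + year + BV", {
  tr <- data.frame(name = "pure", h2 = 1, pe_fraction = 0, mean = 50, sd = 4,
                   n_qtl = 50L)
  cfg <- sim_config(n_founders = 20L, n_snps = 200L, progeny_per_cross = 2L,
                    traits = tr, seed = 8L)
  fs <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, genotype_ids(fs$genotypes))
  gd <- gene_drop(fs, ped, cfg)
  ph <- simulate_phenotypes(gd$genotypes, ped, cfg)
  t_ <- ph$truth$pure
  y1 <- ph$phenotypes[ph$phenotypes$year == 1, ]
  expect_equal(y1$value, unname(50 + t_$true_bv[y1$individual]),
               tolerance = 1e-12)
  y2 <- ph$phenotypes[ph$phenotypes$year == 2, ]
  expect_equal(y2$value,
               unname(50 + t_$year_effects[2] + t_$true_bv[y2$individual]),
               tolerance = 1e-12)
})

test_that("default_study writes a complete, re-readable, reproducible bundle", {
  # scaled-down configuration; full scale is exercised by the same code path
  cfg <- sim_config(n_founders = 30L, n_snps = 120L, n_chromosomes = 4L,
                    progeny_per_cross = 3L, seed = 12L,
                    traits = default_traits(n_qtl = 40L)[c(1, 5, 7), ])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- suppressMessages(default_study(out_dir = d1, cfg = cfg))
  s2 <- suppressMessages(default_study(out_dir = d2, cfg = cfg))
  # readers accept every artifact
  ped <- read_pedigree(s1$paths$pedigree)
  expect_equal(as.data.frame(ped),
               as.data.frame(s1$pedigree)[c("individual", "sire", "dam")])
  ph <- suppressMessages(read_phenotypes(s1$paths$phenotypes))
  expect_equal(sort(unique(ph$trait)), sort(cfg$traits$name))
  gv <- suppressMessages(suppressWarnings(
    read_genotypes(s1$paths$genotypes_vcf, "vcf")))
  gt <- read_genotypes(s1$paths$genotypes_tsv, "dosage_tsv")
  expect_equal(unname(gv$dosage), unname(gt$dosage))
  expect_equal(dim(gv)[1], 30L)
  # fixed seed -> byte-identical files
  for (p in c("pedigree", "phenotypes", "genotypes_vcf", "genotypes_tsv",
              "truth_csv", "truth_json")) {
    expect_identical(readLines(s1$paths[[p]]), readLines(s2$paths[[p]]),
                     label = p)
  }
})
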