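#' Run the full genome-assisted parental-selection study
#'
#' Orchestrates the complete analysis for every requested trait:
#' own-phenotype BLUP-BVs of the parental accessions, progeny-based GCA
#' and heritability, the BLUP-BV/GCA correlation, SNP filtering +
#' imputation + genomic relationship matrix, and replicated k-fold
#' genomic-prediction cross-validation. Emits a per-trait summary table
#' (CSV), per-trait CV archives (CSV), a plain-text report, and a JSON
#' settings/versions log. Any stage failure aborts with a stage-labeled
#' message.
#'
#' The JSON config has the shape:
#' \preformatted{
#' {
#'   "seed": 1,
#'   "out_dir": "study_out",
#'   "simulate": { "n_founders": 120, "progeny_per_cross": 10, ... }
#'     // or "inputs": {"pedigree": ..., "phenotypes": ...,
#'     //               "genotypes": ..., "genotype_format": "vcf"}
#'   "traits": ["AVFW", ...],            // optional, default: all observed
#'   "cv": { "k": 11, "repeats": 20 },   // optional
#'   "filters": { "max_missing_frac": 0.10, "min_maf": 0.05 }  // optional
#' }
#' }
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @return Invisibly, a list with the `trait_summary` data.frame, per-trait
#'   details, and output paths.
#' @export
run_study <- function(config) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir %||% "gapsel_study"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dat <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      scfg <- do.call(sim_config, c(sim_args, list(seed = seed)))
      default_study(seed = seed, out_dir = NULL, cfg = scfg)
    } else if (!is.null(cfg$inputs)) {
      ped <- read_pedigree(cfg$inputs$pedigree)
      phen <- read_phenotypes(cfg$inputs$phenotypes)
      fmt <- cfg$inputs$genotype_format %||% "vcf"
      gobs <- read_genotypes(cfg$inputs$genotypes, format = fmt)
      list(pedigree = ped, phenotypes = phen, genotypes_observed = gobs,
           truth = NULL)
    } else stop("config must contain either 'simulate' or 'inputs'")
  })
  ped <- dat$pedigree
  phen <- dat$phenotypes
  par_ids <- intersect(parents_of(ped), founders(ped))
  if (length(par_ids) == 0L) par_ids <- founders(ped)
  own_phen <- phen[phen$individual %in% par_ids, , drop = FALSE]
  prog_phen <- phen[!(phen$individual %in% par_ids), , drop = FALSE]
  traits <- cfg$traits %||% unique(phen$trait)
  unknown <- setdiff(traits, unique(phen$trait))
  if (length(unknown) > 0L) {
    stop("stage 'inputs': unknown trait(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  filt <- stage("filters", {
    f <- cfg$filters %||% list()
    filter_sites(dat$genotypes_observed,
                 max_missing_frac = f$max_missing_frac %||% 0.10,
                 min_maf = f$min_maf %||% 0.05)
  })
  write_filter_report(filt$report,
                      file.path(out_dir, "filter_report.txt"),
                      file.path(out_dir, "filter_report.json"))
  Gmat <- stage("relmat", {
    gi <- impute_mean(filt$genotypes, seed = seed)
    make_invertible(gmat_vanraden(gi))
  })
  # Pedigree restricted to the parental accessions, keeping any links
  # among them (links to individuals outside the subset become unknown).
  ped_parents <- stage("relmat", {
    keep <- ped$individual %in% par_ids
    s <- ped$sire[keep]; d <- ped$dam[keep]
    s[!(s %in% par_ids)] <- NA_character_
    d[!(d %in% par_ids)] <- NA_character_
    pedigree_table(ped$individual[keep], s, d)
  })

  cvk <- as.integer(cfg$cv$k %||% 11L)
  cvr <- as.integer(cfg$cv$repeats %||% 20L)

  per_trait <- list()
  summary_rows <- list()
  for (tr in traits) {
    own <- stage(paste0("own_phenotype_blup[", tr, "]"),
                 own_phenotype_blup(own_phen, ped_parents, tr))
    gca <- stage(paste0("progeny_gca[", tr, "]"),
                 progeny_gca(prog_phen, ped, tr, parent_ids = par_ids))
    r_og <- stage(paste0("corr_own_vs_gca[", tr, "]"),
                  corr_own_vs_gca(own$blupbv, gca$gca))
    cv <- stage(paste0("cv[", tr, "]"), {
      bb <- own$blupbv[intersect(names(own$blupbv), rownames(Gmat))]
      cv_genomic_prediction(bb, Gmat, k = cvk, repeats = cvr,
                            seed = seed, gca = gca$gca, trait = tr)
    })
    s <- summary(cv)
    data.table::fwrite(cv$accuracy, file.path(out_dir, paste0("cv_", tr, ".csv")))
    per_trait[[tr]] <- list(own = own, gca = gca, corr_own_gca = r_og, cv = cv)
    summary_rows[[tr]] <- data.frame(
      trait = tr, h2_progeny = gca$h2, corr_blupbv_gca = r_og,
      mean_cv_accuracy = s$mean_accuracy, corr_gebv_gca_mean = s$mean_corr_gca
    )
  }
  trait_summary <- do.call(rbind, summary_rows)
  rownames(trait_summary) <- NULL
  data.table::fwrite(trait_summary, file.path(out_dir, "trait_summary.csv"))

  report <- c(
    "Genome-assisted parental selection: study report",
    sprintf("seed %d; %d traits; CV %d folds x %d repeats", seed,
            nrow(trait_summary), cvk, cvr),
    sprintf("markers: %d sites retained of %d", filt$report$n_sites_out,
            filt$report$n_sites_in),
    "",
    "trait    h2_progeny  corr(BLUP-BV,GCA)  mean CV accuracy  corr(GEBV,GCA)",
    sprintf("%-8s %10.3f %18.3f %17.3f %15.3f", trait_summary$trait,
            trait_summary$h2_progeny, trait_summary$corr_blupbv_gca,
            trait_summary$mean_cv_accuracy, trait_summary$corr_gebv_gca_mean)
  )
  if (nrow(trait_summary) >= 3L) {
    report <- c(report, "", sprintf(
      "across traits: corr[corr(BLUP-BV,GCA), sqrt(h2)] = %.3f",
      stats::cor(trait_summary$corr_blupbv_gca, sqrt(trait_summary$h2_progeny))
    ))
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  jsonlite::write_json(list(
    package = "gapsel",
    version = as.character(utils::packageVersion("gapsel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, cv = list(k = cvk, repeats = cvr),
    traits = traits
  ), file.path(out_dir, "settings.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(trait_summary = trait_summary, per_trait = per_trait,
                 filter_report = filt$report, out_dir = out_dir))
}
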