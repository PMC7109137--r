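#' Own-phenotype BLUP breeding values
#'
#' Fits the repeatability animal model (harvest year fixed, additive and
#' permanent-environment random effects, pedigree relationship matrix) to
#' an accession's own repeated records and returns the additive BLUPs
#' (BLUP-BV) of the accessions with records.
#'
#' @param phen `phenotype_records` holding the accessions' repeated records.
#' @param ped a [pedigree_table()] covering those accessions.
#' @param trait trait name.
#' @param ... passed to [reml_fit()] (e.g. `method`).
#' @return List of class `own_blup`: `trait`, `blupbv` (named vector,
#'   accessions with records only), `fit` (the full `mixed_model_fit`).
#' @export
own_phenotype_blup <- function(phen, ped, trait, ...) {
  stopifnot(inherits(ped, "pedigree_table"))
  A <- amat(ped)
  d <- build_design(phen, trait, ids = ped$individual, fixed_year = TRUE)
  fit <- reml_fit(d, A, include_pe = TRUE, ...)
  with_rec <- unique(d$record_individual)
  structure(list(trait = trait, blupbv = fit$ebv[with_rec], fit = fit),
            class = "own_blup")
}

#' @export
print.own_blup <- function(x, ...) {
  cat(sprintf("own_blup '%s': %d accessions, sigma2_a = %.4g\n",
              x$trait, length(x$blupbv), x$fit$varcomp$sigma2_a))
  invisible(x)
}

#' General combining ability from progeny test data
#'
#' Fits the individual-tree model to progeny records, with the pedigree
#' relationship matrix over parents and progeny jointly, and reads each
#' parent's GCA as its additive BLUP from this fit (parents carry no
#' records; their values are relationship-weighted projections of progeny
#' information). Also returns the progeny-data variance components, from
#' which narrow-sense heritability is estimated.
#'
#' The permanent-environment term is included only when at least one
#' progeny has repeated records; with single records it is not separable
#' from the residual (heritability is unaffected either way).
#'
#' @param phen_progeny `phenotype_records` of the progeny (parents must
#'   not carry records here).
#' @param ped a [pedigree_table()] linking progeny to parents.
#' @param trait trait name.
#' @param parent_ids parents whose GCA is wanted.
#' @param include_pe `NULL` (auto) or logical.
#' @param ... passed to [reml_fit()].
#' @return List of class `progeny_gca`: `trait`, `gca` (named vector over
#'   `parent_ids`), `variances`, `h2`, `low_information` (parents with no
#'   phenotyped progeny), `fit`.
#' @export
progeny_gca <- function(phen_progeny, ped, trait, parent_ids,
                        include_pe = NULL, ...) {
  stopifnot(inherits(ped, "pedigree_table"))
  parent_ids <- as.character(parent_ids)
  if (!all(parent_ids %in% ped$individual)) {
    stop("parent id(s) missing from pedigree: ",
         paste(utils::head(setdiff(parent_ids, ped$individual), 5L), collapse = ", "))
  }
  sub <- phen_progeny[phen_progeny$trait == trait, , drop = FALSE]
  if (any(sub$individual %in% parent_ids)) {
    stop("progeny phenotype table contains records for parent accessions")
  }
  if (is.null(include_pe)) {
    include_pe <- anyDuplicated(sub$individual) > 0L
  }
  A <- amat(ped)
  d <- build_design(phen_progeny, trait, ids = ped$individual,
                    fixed_year = TRUE)
  fit <- reml_fit(d, A, include_pe = include_pe, ...)
  gca <- fit$ebv[parent_ids]
  kids_phenotyped <- unique(sub$individual)
  has_kid <- vapply(parent_ids, function(p) {
    any((ped$sire %in% p | ped$dam %in% p) & ped$individual %in% kids_phenotyped)
  }, logical(1))
  low_info <- parent_ids[!has_kid]
  if (length(low_info) > 0L) {
    message(length(low_info), " parent(s) without phenotyped progeny; ",
            "GCA flagged low-information")
  }
  h2 <- tryCatch(heritability(fit$varcomp), error = function(e) NA_real_)
  structure(list(trait = trait, gca = gca, variances = fit$varcomp,
                 h2 = h2, low_information = low_info, fit = fit),
            class = "progeny_gca")
}

#' @export
print.progeny_gca <- function(x, ...) {
  cat(sprintf("progeny_gca '%s': %d parents, h2 = %.3f\n",
              x$trait, length(x$gca), x$h2))
  invisible(x)
}

#' Correlation between own-phenotype BLUP-BV and progeny-based GCA
#'
#' Product-moment (Pearson) correlation over the accessions present in
#' both named vectors.
#'
#' @param blupbv named numeric vector (e.g. `own_blup$blupbv`).
#' @param gca named numeric vector (e.g. `progeny_gca$gca`).
#' @return Pearson correlation.
#' @export
corr_own_vs_gca <- function(blupbv, gca) {
  shared <- intersect(names(blupbv), names(gca))
  if (length(shared) < 3L) stop("fewer than 3 shared accessions")
  x <- blupbv[shared]; y <- gca[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in BLUP-BV or GCA over shared accessions")
  }
  stats::cor(x, y)
}

#' Random near-equal k-fold partition
#'
#' Splits `n` records into `k` disjoint folds whose sizes differ by at
#' most one, larger folds first (274 records and 11 folds give ten folds
#' of 25 and one of 24). Seeded and reproducible.
#'
#' @param n number of records.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return Integer vector of length `n` with fold labels in `1:k`.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n (got k=", k, ", n=", n, ")")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(k), sizes)
  fold
}

#' Replicated k-fold cross-validation of genomic prediction
#'
#' For each repeat, accessions are partitioned into `k` folds; each fold
#' in turn is withheld, the GBLUP model (intercept plus additive effect
#' with genomic covariance) is refitted by REML to the training
#' accessions' BLUP-BVs, and the withheld accessions' GEBVs are read off
#' through the genomic relationship matrix. Prediction accuracy per fold
#' is the correlation between GEBV and BLUP-BV in the validation set;
#' when `gca` is supplied, the correlation between GEBV and GCA is
#' recorded as well.
#'
#' @param blupbv named numeric vector of own-phenotype BLUP-BVs.
#' @param g genomic relationship matrix covering all names of `blupbv`.
#' @param k folds per repeat.
#' @param repeats number of repeats; repeat r uses seed `seed + r`.
#' @param seed master seed.
#' @param gca optional named GCA vector.
#' @param trait optional trait label carried into the result.
#' @return A `cv_result`: per-fold table (`accuracy`), fold assignments,
#'   seeds and settings. See [summary.cv_result()].
#' @export
cv_genomic_prediction <- function(blupbv, g, k = 11L, repeats = 20L, seed = 1L,
                                  gca = NULL, trait = NULL) {
  ids <- names(blupbv)
  if (is.null(ids)) stop("blupbv must be a named vector")
  if (!all(ids %in% rownames(g))) {
    stop("genomic relationship matrix does not cover all accessions")
  }
  n <- length(blupbv)
  if (n %/% k < 3L) {
    stop("validation folds would have fewer than 3 accessions (n=", n,
         ", k=", k, ")")
  }
  G <- g[ids, ids, drop = FALSE]
  if (is.null(attr(G, "kind"))) attr(G, "kind") <- attr(g, "kind")
  phen <- phenotype_records(ids, 1L, "blupbv", unname(blupbv))
  # folds are assigned in canonical (sorted) id order so that summaries are
  # invariant to the ordering of the input vectors
  ids_sorted <- sort(ids)
  rows <- list()
  fold_assignments <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- seed + r
    fold_sorted <- make_folds(n, k, rep_seed)
    fold <- fold_sorted[match(ids, ids_sorted)]
    fold_assignments[[r]] <- fold
    for (f in seq_len(k)) {
      val <- ids[fold == f]
      train <- ids[fold != f]
      d <- build_design(phen[phen$individual %in% train, , drop = FALSE],
                        "blupbv", ids = ids, fixed_year = FALSE)
      fit <- reml_fit(d, G, include_pe = FALSE)
      gebv <- fit$ebv[val]
      acc <- stats::cor(gebv, blupbv[val])
      acc_gca <- if (!is.null(gca)) stats::cor(gebv, gca[val]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, n_val = length(val),
        acc_blupbv = acc, acc_gca = acc_gca
      )
    }
  }
  structure(list(
    trait = trait, n_folds = as.integer(k), n_repeats = as.integer(repeats),
    seed = as.integer(seed), fold_assignments = fold_assignments,
    accuracy = do.call(rbind, rows)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("cv_result%s: %d folds x %d repeats (seed %d)\n",
              if (!is.null(x$trait)) paste0(" '", x$trait, "'") else "",
              x$n_folds, x$n_repeats, x$seed))
  cat(sprintf("  accuracy corr(GEBV, BLUP-BV): mean %.3f [Q1 %.3f, median %.3f, Q3 %.3f]\n",
              s$mean_accuracy, s$q1, s$median, s$q3))
  if (!all(is.na(x$accuracy$acc_gca))) {
    cat(sprintf("  corr(GEBV, GCA): mean %.3f\n", s$mean_corr_gca))
  }
  invisible(x)
}

#' Summarize a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return List with mean and quartiles of per-fold accuracies, per-repeat
#'   means, and the mean GEBV-GCA correlation when recorded.
#' @export
summary.cv_result <- function(object, ...) {
  a <- object$accuracy$acc_blupbv
  per_rep <- tapply(a, object$accuracy$rep, mean)
  list(
    mean_accuracy = mean(a),
    q1 = unname(stats::quantile(a, 0.25)),
    median = stats::median(a),
    q3 = unname(stats::quantile(a, 0.75)),
    per_repeat_mean = as.numeric(per_rep),
    mean_corr_gca = if (all(is.na(object$accuracy$acc_gca))) NA_real_
                    else mean(object$accuracy$acc_gca, na.rm = TRUE)
  )
}

#' @importFrom stats median
NULL
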