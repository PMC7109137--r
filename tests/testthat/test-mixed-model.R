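test_that("build_design shapes X, y and the incidence mapping", {
  phen <- phenotype_records(rep(c("a", "b"), each = 2), rep(1:2, 2), "tr",
                            c(1, 2, 3, 4))
  ids <- c("a", "b", "c")
  d <- build_design(phen, "tr", ids, fixed_year = TRUE)
  expect_length(d$y, 4L)
  expect_equal(colnames(d$X), c("(Intercept)", "year2"))
  expect_equal(d$individual_ids, ids)
  Z <- design_incidence(d)
  expect_true(all(rowSums(Z) == 1))
  expect_equal(colSums(Z), c(a = 2, b = 2, c = 0))

  d0 <- build_design(phen, "tr", ids, fixed_year = FALSE)
  expect_equal(ncol(d0$X), 1L)

  # single-record individual still contributes one incidence row
  phen1 <- phenotype_records(c("a", "a", "b"), c(1, 2, 1), "tr", c(1, 2, 3))
  d1 <- build_design(phen1, "tr", c("a", "b"))
  expect_equal(nrow(d1$X), 3L)
  expect_true(all(rowSums(design_incidence(d1)) == 1))

  expect_error(build_design(phen, "nope", ids), "no records")
  expect_error(build_design(phenotype_records("a", 1, "tr", 1), "tr", "a"),
               "fewer than 2")
})

test_that("REML matches balanced one-way ANOVA estimators (both algorithms)", {
  set.seed(42)
  n_ind <- 80L; m <- 2L
  ids <- sprintf("I%03d", seq_len(n_ind))
  a <- rnorm(n_ind, 0, sqrt(2))
  grp <- rep(ids, each = m)
  y <- a[rep(seq_len(n_ind), each = m)] + rnorm(n_ind * m)
  phen <- phenotype_records(grp, rep(seq_len(m), n_ind), "tr", y)
  K <- amat(pedigree_table(ids, NA, NA))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)
  truth <- anova_oracle(y, grp, m)
  for (meth in c("ai", "auto")) {
    fit <- reml_fit(d, K, include_pe = FALSE, method = meth)
    expect_true(fit$varcomp$converged)
    expect_equal(fit$varcomp$sigma2_a, truth[["s2a"]], tolerance = 1e-4)
    expect_equal(fit$varcomp$sigma2_e, truth[["s2e"]], tolerance = 1e-4)
  }
})

test_that("converged fixed effects equal the dense GLS oracle", {
  set.seed(7)
  ids <- sprintf("I%02d", 1:20)
  ped <- random_pedigree(20)
  ids <- ped$individual
  K <- make_invertible(amat(ped))
  phen <- phenotype_records(rep(ids, 2), rep(1:2, each = 20), "tr",
                            rnorm(40, 10))
  d <- build_design(phen, "tr", ids, fixed_year = TRUE)
  fit <- suppressWarnings(reml_fit(d, K, include_pe = TRUE))
  v <- fit$varcomp
  Z <- design_incidence(d)
  beta_gls <- gls_oracle(d$y, d$X, Z, unclass(K), v$sigma2_a, v$sigma2_e,
                         Zp = Z, s2p = v$sigma2_p)
  expect_equal(unname(fit$beta), unname(beta_gls), tolerance = 1e-8)
})

test_that("BLUPs solve Henderson's MME, including individuals without records", {
  set.seed(19)
  ped <- random_pedigree(24)
  ids <- ped$individual
  K <- make_invertible(amat(ped))
  rec_ids <- sample(ids, 16)  # 8 individuals have no records
  phen <- phenotype_records(rep(rec_ids, 2), rep(1:2, each = 16), "tr",
                            rnorm(32, 5, 2))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)

  for (pe in c(FALSE, TRUE)) {
    fit <- suppressWarnings(reml_fit(d, K, include_pe = pe))
    v <- fit$varcomp
    Z <- design_incidence(d)
    ora <- if (pe) {
      mme_oracle(d$y, d$X, Z, unclass(K), v$sigma2_a, v$sigma2_e, Zp = Z,
                 s2p = v$sigma2_p)
    } else {
      mme_oracle(d$y, d$X, Z, unclass(K), v$sigma2_a, v$sigma2_e)
    }
    expect_equal(unname(fit$beta), unname(ora$beta), tolerance = 1e-8)
    expect_equal(unname(fit$ebv), unname(ora$a), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # recordless individuals carry nonzero relationship-projected values
    norec <- setdiff(ids, rec_ids)
    expect_true(any(abs(fit$ebv[norec]) > 1e-8))
  }
})

test_that("shrinkage identity holds for K = I with single records", {
  set.seed(3)
  ids <- sprintf("I%02d", 1:50)
  y <- rnorm(50, 20, 3)
  phen <- phenotype_records(ids, 1, "tr", y)
  K <- amat(pedigree_table(ids, NA, NA))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)
  fit <- reml_fit(d, K, include_pe = FALSE)
  v <- fit$varcomp
  lam <- v$sigma2_a / (v$sigma2_a + v$sigma2_e)
  expect_equal(unname(fit$ebv), lam * (y - mean(y)), tolerance = 1e-8)
  expect_lt(abs(mean(fit$ebv)), 1e-8)
})

test_that("EM iterations never decrease the restricted likelihood", {
  set.seed(13)
  ped <- random_pedigree(30)
  ids <- ped$individual
  K <- amat(ped)
  phen <- phenotype_records(rep(ids, 2), rep(1:2, each = 30), "tr",
                            rnorm(60, 0, 2))
  d <- build_design(phen, "tr", ids)
  fit <- suppressWarnings(reml_fit(d, K, include_pe = TRUE, method = "em",
                                   max_iter = 60))
  h <- fit$varcomp$history
  expect_true(all(h$step[-1] == "em"))
  expect_true(all(diff(h$logL) > -1e-9))
})

test_that("profile and AI solvers agree on the two-component model", {
  set.seed(23)
  ped <- random_pedigree(35)
  K <- make_invertible(amat(ped))
  ids <- ped$individual
  u <- drop(t(chol(unclass(K))) %*% rnorm(35, 0, 1.2))
  phen <- phenotype_records(ids, 1, "tr", 4 + u + rnorm(35))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)
  f_ai <- reml_fit(d, K, include_pe = FALSE, method = "ai")
  f_pr <- reml_fit(d, K, include_pe = FALSE, method = "auto")
  expect_equal(f_pr$varcomp$sigma2_a, f_ai$varcomp$sigma2_a, tolerance = 1e-3)
  expect_equal(f_pr$varcomp$sigma2_e, f_ai$varcomp$sigma2_e, tolerance = 1e-3)
  expect_equal(f_pr$varcomp$log_likelihood, f_ai$varcomp$log_likelihood,
               tolerance = 1e-6)
  expect_equal(f_pr$ebv, f_ai$ebv, tolerance = 1e-4)
})

test_that("pure-noise data leave (almost) no variance to the additive term", {
  # sigma2_a = 0 truth; with 2 records per individual the between-individual
  # variance is identified and its REML estimate must sit within null
  # sampling error of zero (bounded below, so never negative).
  set.seed(77)
  n <- 500L
  ids <- sprintf("I%03d", seq_len(n))
  y <- rnorm(2L * n)
  phen <- phenotype_records(rep(ids, each = 2L), rep(1:2, n), "tr", y)
  K <- amat(pedigree_table(ids, NA, NA))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)
  fit <- reml_fit(d, K, include_pe = FALSE)
  expect_gte(fit$varcomp$sigma2_a, fit$varcomp$lower_bound * 0.99)
  expect_lt(heritability(fit$varcomp), 0.05)  # ~3 SE of the null ANOVA estimator
  expect_lt(max(abs(fit$ebv)) / sd(y), 0.25)  # strong shrinkage toward 0
})

test_that("heritability and repeatability follow their definitions", {
  v <- list(sigma2_a = 0.5, sigma2_p = 0.2, sigma2_e = 0.3)
  expect_equal(heritability(v), 0.5)
  expect_equal(repeatability(v), 0.7)
  expect_equal(heritability(list(sigma2_a = 0, sigma2_p = 0.2, sigma2_e = 0.8)), 0)
  expect_equal(heritability(list(sigma2_a = 1, sigma2_p = 0, sigma2_e = 0)), 1)
  expect_equal(repeatability(list(sigma2_a = 0, sigma2_p = 0, sigma2_e = 1)), 0)
  # sigma2_p absent counts as zero
  expect_equal(heritability(list(sigma2_a = 0.4, sigma2_e = 0.6)), 0.4)
  expect_equal(repeatability(list(sigma2_a = 0.4, sigma2_e = 0.6)), 0.4)
  expect_error(heritability(list(sigma2_a = 0, sigma2_p = 0, sigma2_e = 0)),
               "zero")
})

test_that("degenerate constant response yields zero BLUPs and the mean", {
  ids <- sprintf("I%02d", 1:10)
  phen <- phenotype_records(ids, 1, "tr", rep(5, 10))
  K <- amat(pedigree_table(ids, NA, NA))
  d <- build_design(phen, "tr", ids, fixed_year = FALSE)
  fit <- reml_fit(d, K, include_pe = FALSE)
  expect_equal(unname(fit$beta[1]), 5)
  expect_true(all(fit$ebv == 0))
})

test_that("mixed-model fits serialize to CSV + JSON", {
  set.seed(5)
  ids <- sprintf("I%02d", 1:12)
  phen <- phenotype_records(rep(ids, 2), rep(1:2, each = 12), "tr", rnorm(24))
  K <- amat(pedigree_table(ids, NA, NA))
  d <- build_design(phen, "tr", ids)
  fit <- suppressWarnings(reml_fit(d, K, include_pe = TRUE))
  csvf <- withr::local_tempfile(fileext = ".csv")
  jsf <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, csvf, jsf)
  df <- utils::read.csv(csvf)
  expect_equal(df$individual, ids)
  expect_equal(df$ebv, unname(fit$ebv))
  meta <- jsonlite::read_json(jsf, simplifyVector = TRUE)
  expect_equal(meta$sigma2_e, fit$varcomp$sigma2_e)
  expect_true(isTRUE(meta$converged))
})
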