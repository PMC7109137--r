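#' Build the design bundle for an individual-tree mixed model
#'
#' Assembles, for one trait, the response vector and incidence structure of
#' the repeatability animal model y = Xb + Za + Zp + e: X holds the overall
#' mean and (optionally) harvest-year effects with the earliest year as
#' reference; Z relates each record to its individual. Individuals listed
#' in `ids` but without records take part only through the relationship
#' matrix (they still receive breeding values from [reml_fit()]).
#'
#' @param phen a `phenotype_records` data.frame.
#' @param trait trait name to model.
#' @param ids character vector of individual ids; must cover every
#'   individual with records of the trait.
#' @param fixed_year include harvest year as a fixed factor? With a single
#'   observed year the model silently reduces to intercept-only.
#' @return A `design_bundle`: list with `y`, `X`, `map` (record ->
#'   position in `ids`), `individual_ids`, `trait`, `years`.
#' @export
build_design <- function(phen, trait, ids, fixed_year = TRUE) {
  stopifnot(inherits(phen, "data.frame"))
  sub <- phen[phen$trait == trait & !is.na(phen$value), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for trait '", trait, "'")
  if (length(unique(sub$individual)) < 2L) {
    stop("fewer than 2 distinct individuals with records for trait '", trait, "'")
  }
  ids <- as.character(ids)
  missing_ids <- setdiff(unique(sub$individual), ids)
  if (length(missing_ids) > 0L) {
    stop("individual(s) with records absent from ids: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  years <- sort(unique(sub$year))
  if (fixed_year && length(years) > 1L) {
    yf <- factor(sub$year, levels = years)  # reference = earliest year
    X <- stats::model.matrix(~yf)
    colnames(X) <- c("(Intercept)", paste0("year", years[-1L]))
  } else {
    X <- matrix(1, nrow(sub), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  structure(list(
    y = sub$value, X = X, map = match(sub$individual, ids),
    individual_ids = ids, record_individual = sub$individual,
    record_year = sub$year, trait = trait, years = years
  ), class = "design_bundle")
}

#' Incidence matrix of a design bundle
#'
#' Dense 0/1 matrix relating records to individuals; identical for the
#' additive and permanent-environment terms. Mostly for oracle checks —
#' [reml_fit()] works with the index representation directly.
#'
#' @param d a `design_bundle`.
#' @return Numeric matrix, records x individuals.
#' @export
design_incidence <- function(d) {
  Z <- matrix(0, length(d$y), length(d$individual_ids),
              dimnames = list(NULL, d$individual_ids))
  Z[cbind(seq_along(d$y), d$map)] <- 1
  Z
}

#' REML fit of the individual-tree mixed model
#'
#' Estimates variance components by restricted maximum likelihood and
#' returns BLUEs of fixed effects and BLUPs of additive (and optionally
#' permanent-environment) effects. The additive covariance is
#' `sigma2_a * K` for the supplied relationship matrix K (pedigree A or
#' genomic G); breeding values are returned for every individual in K,
#' including those without records, via the relationship-weighted
#' projection `sigma2_a K Z' P y`.
#'
#' Algorithms: `"ai"` is average-information REML with EM fallback when an
#' AI step leaves the parameter space or decreases the restricted
#' likelihood; `"em"` is pure EM (slow, monotone); `"auto"` uses a profiled
#' eigendecomposition solver for the two-component model (no permanent
#' environment) and AI otherwise. Variances are bounded below at
#' `1e-6 * var(y)`. Convergence: relative change in restricted log
#' likelihood below `tol`.
#'
#' @param d a `design_bundle` from [build_design()].
#' @param k relationship matrix covering (at least) all individuals in `d`;
#'   ids are matched by dimnames.
#' @param include_pe include a permanent-environment random effect
#'   (identity covariance, same incidence as the additive term)?
#' @param method `"auto"`, `"ai"` or `"em"`.
#' @param max_iter,tol iteration control.
#' @param verbose print per-iteration progress?
#' @return A `mixed_model_fit`: list with `beta` (fixed effects), `ebv`
#'   (named, all individuals in K), `pe` (named or `NULL`), `varcomp`
#'   (sigma2_a, sigma2_p, sigma2_e, logL, converged, n_iter, history),
#'   `relationship_kind`, `method`.
#' @export
reml_fit <- function(d, k, include_pe = TRUE,
                     method = c("auto", "ai", "em"),
                     max_iter = 200L, tol = 1e-8, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(d, "design_bundle"))
  k_ids <- rownames(k)
  if (is.null(k_ids)) stop("relationship matrix must carry individual ids as dimnames")
  if (!all(d$individual_ids %in% k_ids)) {
    stop("relationship matrix does not cover all individuals in the design")
  }
  y <- d$y
  n <- length(y)
  X <- d$X
  map_k <- match(d$record_individual, k_ids)
  K <- as.matrix(unclass(k))

  M_a <- K[map_k, map_k, drop = FALSE]
  comps <- list(a = M_a)
  qdims <- c(a = nrow(K))
  if (include_pe) {
    comps$pe <- 1 * outer(map_k, map_k, `==`)
    qdims <- c(qdims, pe = length(unique(map_k)))
  }
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    # Degenerate constant response: no variance to partition; all random
    # effects are zero and the mean is the only estimable quantity.
    beta0 <- setNames(c(mean(y), rep(0, ncol(X) - 1L)), colnames(X))
    varcomp <- structure(list(
      sigma2_a = 0, sigma2_p = if (include_pe) 0 else NULL, sigma2_e = 0,
      log_likelihood = NA_real_, converged = TRUE, n_iterations = 0L,
      history = NULL, lower_bound = 0
    ), class = "variance_estimates")
    return(structure(list(
      beta = beta0, ebv = setNames(rep(0, nrow(K)), k_ids),
      pe = if (include_pe) setNames(rep(0, nrow(K)), k_ids) else NULL,
      varcomp = varcomp, relationship_kind = attr(k, "kind") %||% "unknown",
      method = "degenerate", trait = d$trait, individual_ids = k_ids,
      n_records = n
    ), class = "mixed_model_fit"))
  }
  lb <- 1e-6 * stats::var(y)

  if (method == "auto" && !include_pe) {
    est <- reml_profile_2comp(y, X, M_a, lb)
  } else {
    if (method == "auto") method <- "ai"
    est <- reml_iterate(y, X, comps, qdims, method, max_iter, tol, lb, verbose)
  }

  # Final quantities at the converged variances (shared code path).
  s2 <- est$s2  # named: a, (pe), e
  V <- s2[["a"]] * M_a + s2[["e"]] * diag(n)
  if (include_pe) V <- V + s2[["pe"]] * comps$pe
  cholV <- chol(V)
  Vinv <- chol2inv(cholV)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  beta <- drop(solve(XtVinvX, crossprod(VinvX, y)))
  names(beta) <- colnames(X)
  Py <- Vinv %*% (y - X %*% beta)  # equals P y since X' P y = 0
  zz <- numeric(nrow(K))
  agg <- rowsum(as.numeric(Py), group = map_k)
  zz[as.integer(rownames(agg))] <- agg[, 1L]
  ebv <- drop(s2[["a"]] * (K %*% zz))
  names(ebv) <- k_ids
  pe <- NULL
  if (include_pe) pe <- setNames(s2[["pe"]] * zz, k_ids)

  varcomp <- structure(list(
    sigma2_a = unname(s2[["a"]]),
    sigma2_p = if (include_pe) unname(s2[["pe"]]) else NULL,
    sigma2_e = unname(s2[["e"]]),
    log_likelihood = est$logL, converged = est$converged,
    n_iterations = est$n_iter, history = est$history,
    lower_bound = lb
  ), class = "variance_estimates")

  structure(list(
    beta = beta, ebv = ebv, pe = pe, varcomp = varcomp,
    relationship_kind = attr(k, "kind") %||% "unknown",
    method = est$method, trait = d$trait,
    individual_ids = k_ids, n_records = n
  ), class = "mixed_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restricted log likelihood and derivative ingredients at variances s2.
reml_eval <- function(y, X, comps, s2) {
  n <- length(y); p <- ncol(X)
  V <- s2[["e"]] * diag(n)
  for (nm in names(comps)) V <- V + s2[[nm]] * comps[[nm]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  Vinv <- chol2inv(cholV)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  cholXVX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(cholXVX)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(cholXVX) %*% t(VinvX)
  Py <- P %*% y
  logL <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholXVX))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
  list(P = P, Py = Py, logL = logL)
}

reml_iterate <- function(y, X, comps, qdims, method, max_iter, tol, lb, verbose) {
  n <- length(y)
  all_comps <- c(comps, list(e = NULL))  # NULL marks the identity residual
  cn <- names(all_comps)
  qdims <- c(qdims, e = n)
  s2 <- setNames(rep(stats::var(y) / length(cn), length(cn)), cn)
  ev <- reml_eval(y, X, comps, s2)
  if (is.null(ev)) stop("REML: initial variance matrix not positive definite")
  history <- data.frame(iter = 0L, logL = ev$logL, step = "init")
  converged <- FALSE
  iter <- 0L

  derivs <- function(ev) {
    trPV <- yPVPy <- numeric(length(cn))
    tvecs <- matrix(0, n, length(cn))
    for (i in seq_along(cn)) {
      Vi_Py <- if (cn[i] == "e") ev$Py else all_comps[[i]] %*% ev$Py
      trPV[i] <- if (cn[i] == "e") sum(diag(ev$P)) else sum(ev$P * all_comps[[i]])
      yPVPy[i] <- sum(ev$Py * Vi_Py)
      tvecs[, i] <- Vi_Py
    }
    list(score = -0.5 * (trPV - yPVPy), trPV = trPV, yPVPy = yPVPy, tvecs = tvecs)
  }
  em_step <- function(s2, dv) {
    new <- s2 + (s2^2 / qdims) * (dv$yPVPy - dv$trPV)
    pmax(new, lb)
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    dv <- derivs(ev)
    proposal <- NULL
    step_type <- method
    if (method == "ai") {
      AI <- 0.5 * crossprod(dv$tvecs, ev$P %*% dv$tvecs)
      ai_ok <- rcond(AI) > 1e-12
      if (ai_ok) {
        delta <- drop(solve(AI, dv$score))
        cand <- s2 + delta
        if (all(cand >= lb)) proposal <- cand else step_type <- "em"
      } else step_type <- "em"
    }
    if (is.null(proposal)) {
      step_type <- "em"
      proposal <- em_step(s2, dv)
    }
    ev_new <- reml_eval(y, X, comps, setNames(proposal, cn))
    if (method == "ai" && step_type == "ai" &&
        (is.null(ev_new) || ev_new$logL < ev$logL - 1e-10)) {
      step_type <- "em"
      proposal <- em_step(s2, dv)
      ev_new <- reml_eval(y, X, comps, setNames(proposal, cn))
    }
    if (is.null(ev_new)) {
      warning("REML: likelihood evaluation failed; stopping early")
      break
    }
    rel <- abs(ev_new$logL - ev$logL) / (abs(ev$logL) + 1e-10)
    s2 <- setNames(proposal, cn)
    ev <- ev_new
    history <- rbind(history,
                     data.frame(iter = iter, logL = ev$logL, step = step_type))
    if (verbose) {
      message(sprintf("iter %3d [%s] logL = %.8f  %s", iter, step_type, ev$logL,
                      paste(sprintf("%s=%.5g", cn, s2), collapse = " ")))
    }
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("REML did not converge in ", max_iter, " iterations")
  }
  list(s2 = s2, logL = ev$logL, converged = converged, n_iter = iter,
       history = history, method = method)
}

# Profiled REML for y = Xb + u + e with var(u) = s2_a * M, var(e) = s2_e I.
# Eigendecompose M once; maximize the restricted likelihood over
# lambda = s2_a / s2_e by golden-section search on log(lambda).
reml_profile_2comp <- function(y, X, M, lb) {
  n <- length(y); p <- ncol(X)
  eg <- eigen(M, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  n_eval <- 0L
  obj <- function(loglam) {
    n_eval <<- n_eval + 1L
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, w * Xt)
    cholXWX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cholXWX)) return(1e10)
    beta <- backsolve(cholXWX, forwardsolve(t(cholXWX), crossprod(Xt, w * yt)))
    r <- yt - Xt %*% beta
    q <- sum(w * r^2)
    s2e <- q / (n - p)
    0.5 * (sum(log(lam * d + 1)) + (n - p) * log(s2e) +
             2 * sum(log(diag(cholXWX))) + (n - p) * (1 + log(2 * pi)))
  }
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-9)
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xt, w * Xt)
  beta <- solve(XtWX, crossprod(Xt, w * yt))
  s2e <- sum(w * (yt - Xt %*% beta)^2) / (n - p)
  s2 <- c(a = max(lam * s2e, lb), e = max(s2e, lb))
  list(s2 = s2, logL = -opt$objective, converged = TRUE, n_iter = n_eval,
       history = data.frame(iter = n_eval, logL = -opt$objective,
                            step = "profile"),
       method = "profile")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  v <- x$varcomp
  cat(sprintf("mixed_model_fit (%s K, method %s): %d records, %d individuals\n",
              x$relationship_kind, x$method, x$n_records, length(x$ebv)))
  cat(sprintf("  sigma2_a = %.5g%s, sigma2_e = %.5g, logL = %.4f, %s\n",
              v$sigma2_a,
              if (!is.null(v$sigma2_p)) sprintf(", sigma2_p = %.5g", v$sigma2_p) else "",
              v$sigma2_e, v$log_likelihood,
              if (v$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Narrow-sense heritability from variance estimates
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_p + sigma2_e); a missing
#' permanent-environment component counts as zero.
#'
#' @param v a `variance_estimates` object (from a [reml_fit()]), or a list
#'   with elements `sigma2_a`, `sigma2_e` and optionally `sigma2_p`.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(v) {
  s2p <- v$sigma2_p %||% 0
  tot <- v$sigma2_a + s2p + v$sigma2_e
  if (tot <= 0) stop("all variance components are zero")
  v$sigma2_a / tot
}

#' Repeatability from variance estimates
#'
#' t = (sigma2_a + sigma2_p) / (sigma2_a + sigma2_p + sigma2_e): the upper
#' bound on heritability with repeated records.
#'
#' @inheritParams heritability
#' @return Repeatability in \[0, 1\].
#' @export
repeatability <- function(v) {
  s2p <- v$sigma2_p %||% 0
  tot <- v$sigma2_a + s2p + v$sigma2_e
  if (tot <= 0) stop("all variance components are zero")
  (v$sigma2_a + s2p) / tot
}

#' Serialize a mixed-model fit
#'
#' Writes per-individual predictions as CSV and the variance components,
#' likelihood and settings as a JSON sidecar.
#'
#' @param fit a `mixed_model_fit`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (!is.null(csv_path)) {
    df <- data.frame(individual = names(fit$ebv), ebv = unname(fit$ebv))
    if (!is.null(fit$pe)) df$pe <- unname(fit$pe)
    data.table::fwrite(df, csv_path)
  }
  if (!is.null(json_path)) {
    v <- fit$varcomp
    jsonlite::write_json(list(
      trait = fit$trait, relationship_kind = fit$relationship_kind,
      method = fit$method, n_records = fit$n_records,
      sigma2_a = v$sigma2_a, sigma2_p = v$sigma2_p, sigma2_e = v$sigma2_e,
      log_likelihood = v$log_likelihood, converged = v$converged,
      n_iterations = v$n_iterations,
      beta = as.list(fit$beta)
    ), json_path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(fit)
}
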