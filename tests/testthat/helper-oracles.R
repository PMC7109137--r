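# Independent oracles used across tests. These deliberately avoid the code
# paths they validate (amat's tabular loop, reml_fit's factorizations).

# Recursive coefficient-of-coancestry kinship oracle: a(i,j) = 2 f(i,j),
# f(i,i) = 0.5 (1 + f(s_i, d_i)), f(i,j) = 0.5 (f(s_i, j) + f(d_i, j))
# for j preceding i; unknown parents contribute 0.
kinship_oracle <- function(ped) {
  ids <- ped$individual
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fs <- if (is.na(si[i]) || is.na(di[i])) 0 else f[si[i], di[i]]
    f[i, i] <- 0.5 * (1 + fs)
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        fsj <- if (is.na(si[i])) 0 else f[si[i], j]
        fdj <- if (is.na(di[i])) 0 else f[di[i], j]
        f[i, j] <- f[j, i] <- 0.5 * (fsj + fdj)
      }
    }
  }
  2 * f
}

# Random acyclic pedigree, founders first with some later individuals
# having one or two known (earlier) parents; optionally shuffled to check
# topological re-sorting.
random_pedigree <- function(n, p_founder = 0.35, shuffle = FALSE) {
  ids <- sprintf("id%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3L && stats::runif(1) > p_founder) {
      pars <- sample(seq_len(i - 1L), 2L)
      sire[i] <- ids[pars[1L]]
      if (stats::runif(1) > 0.2) dam[i] <- ids[pars[2L]]
    }
  }
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  pedigree_table(ids[ord], sire[ord], dam[ord])
}

# Dense GLS oracle for the fixed effects at known variance components.
gls_oracle <- function(y, X, Za, K, s2a, s2e, Zp = NULL, s2p = 0) {
  V <- s2a * Za %*% K %*% t(Za) + s2e * diag(length(y))
  if (!is.null(Zp)) V <- V + s2p * Zp %*% t(Zp)
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Henderson mixed-model-equation oracle at known variance components;
# includes individuals without records (columns of Za/Zp may be all-zero).
mme_oracle <- function(y, X, Za, K, s2a, s2e, Zp = NULL, s2p = 0) {
  Kinv <- solve(K)
  la <- s2e / s2a
  if (is.null(Zp)) {
    C <- rbind(
      cbind(crossprod(X), crossprod(X, Za)),
      cbind(crossprod(Za, X), crossprod(Za) + Kinv * la)
    )
    rhs <- c(crossprod(X, y), crossprod(Za, y))
    sol <- solve(C, rhs)
    p_ <- ncol(X)
    list(beta = sol[seq_len(p_)], a = sol[-seq_len(p_)], pe = NULL)
  } else {
    lp <- s2e / s2p
    C <- rbind(
      cbind(crossprod(X), crossprod(X, Za), crossprod(X, Zp)),
      cbind(crossprod(Za, X), crossprod(Za) + Kinv * la, crossprod(Za, Zp)),
      cbind(crossprod(Zp, X), crossprod(Zp, Za), crossprod(Zp) + diag(ncol(Zp)) * lp)
    )
    rhs <- c(crossprod(X, y), crossprod(Za, y), crossprod(Zp, y))
    sol <- solve(C, rhs)
    p_ <- ncol(X); q <- ncol(Za)
    list(beta = sol[seq_len(p_)], a = sol[p_ + seq_len(q)],
         pe = sol[p_ + q + seq_len(ncol(Zp))])
  }
}

# Balanced one-way ANOVA estimators (m records per individual).
anova_oracle <- function(y, group, m) {
  ybar_i <- tapply(y, group, mean)
  ybar <- mean(y)
  n_ind <- length(ybar_i)
  MSB <- m * sum((ybar_i - ybar)^2) / (n_ind - 1)
  MSW <- sum((y - ybar_i[group])^2) / (n_ind * (m - 1))
  c(s2a = (MSB - MSW) / m, s2e = MSW)
}

# Small toy genotype matrix builder.
toy_genotypes <- function(dosage, chrom, pos, ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(dosage)))
  rownames(dosage) <- ids
  genotype_matrix(dosage, data.frame(chrom = chrom, pos = pos))
}
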