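#' Construct a genotype (dosage) matrix
#'
#' Individuals x SNP-site matrix of alternate-allele counts with
#' chromosome/position metadata. Raw matrices hold dosages in
#' \{0, 1, 2, NA\}; after [impute_mean()] entries may be real-valued
#' (the `imputed` attribute is then set).
#'
#' @param dosage numeric matrix, individuals in rows, sites in columns,
#'   entries 0/1/2 or `NA`; rownames are individual ids.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per dosage column. Positions must be strictly
#'   increasing within each chromosome.
#' @param imputed logical; `TRUE` when entries are real-valued imputations.
#' @return A `genotype_matrix` object (list with `dosage` and `sites`).
#' @export
genotype_matrix <- function(dosage, sites, imputed = FALSE) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage matrix must have individual ids as rownames")
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if (ncol(dosage) != nrow(sites)) {
    stop("site metadata rows (", nrow(sites), ") do not match dosage columns (",
         ncol(dosage), ")")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate individual ids in genotype matrix")
  if (!imputed) {
    vals <- dosage[!is.na(dosage)]
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      stop("raw dosages must be 0, 1, 2 or missing")
    }
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$ref)) sites$ref <- NA_character_
  if (is.null(sites$alt)) sites$alt <- NA_character_
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  rownames(sites) <- NULL
  if (ncol(dosage) > 0L) {
    colnames(dosage) <- paste0(sites$chrom, ":", sites$pos)
  }
  structure(list(dosage = dosage, sites = sites, imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites on %d chromosome(s)%s\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$sites$chrom)),
              if (isTRUE(x$imputed)) " (imputed)" else ""))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Individual ids of a genotype matrix
#' @param g a [genotype_matrix()].
#' @return Character vector of individual ids (row order).
#' @export
genotype_ids <- function(g) rownames(g$dosage)

#' Read genotypes from VCF or a dosage TSV
#'
#' The VCF route (via \pkg{VariantAnnotation}) uses the GT field of
#' biallelic SNV records; multiallelic records are skipped with a message,
#' `./.` becomes missing. The dosage TSV dialect has individuals in rows,
#' an `id` first column, and one column per site named `chrom:pos` holding
#' 0/1/2 or `NA`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  g <- switch(format, vcf = read_genotypes_vcf(path), dosage_tsv = read_genotypes_tsv(path))
  if (ncol(g$dosage) == 0L) stop("no usable sites parsed from ", path)
  g
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF: no GT field in ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  if (any(multi)) {
    message(sum(multi), " multiallelic VCF record(s) skipped")
  }
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = as.character(rr$REF)[keep],
    alt = vapply(as(alt[keep], "CharacterList"), function(a) a[[1L]], ""),
    stringsAsFactors = FALSE
  )
  dos <- gt_to_dosage(gt)  # sites x samples
  dosage <- t(dos)
  rownames(dosage) <- colnames(gt)
  genotype_matrix(dosage, sites)
}

gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA, "." = NA)
  vals <- map[gt]
  unknown <- is.na(vals) & !(gt %in% names(map))
  if (any(unknown)) {
    stop("unrecognised GT value '", gt[which(unknown)[1L]], "' in VCF")
  }
  matrix(vals, nrow = nrow(gt), dimnames = dimnames(gt))
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (names(dt)[1L] != "id") {
    stop("malformed dosage TSV header: first column must be 'id'")
  }
  ids <- as.character(dt[[1L]])
  cols <- names(dt)[-1L]
  parts <- strsplit(cols, ":", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed dosage TSV header: site columns must be named chrom:pos")
  }
  sites <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(sites$pos)) stop("malformed dosage TSV header: non-integer position")
  dosage <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(dosage) <- "numeric"
  rownames(dosage) <- ids
  genotype_matrix(dosage, sites)
}

#' Write genotypes as a dosage TSV
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  dt <- data.table::as.data.table(g$dosage)
  names(dt) <- paste0(g$sites$chrom, ":", g$sites$pos)
  dt <- cbind(data.table::data.table(id = rownames(g$dosage)), dt)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotypes. Requires integer dosages
#' (not an imputed matrix); heterozygotes are written `0/1`, missing `./.`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (isTRUE(g$imputed)) stop("cannot write an imputed (real-valued) matrix as VCF")
  ref <- ifelse(is.na(g$sites$ref), "A", g$sites$ref)
  alt <- ifelse(is.na(g$sites$alt), "C", g$sites$alt)
  gt_codes <- c("0/0", "0/1", "1/1")
  ids <- rownames(g$dosage)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gapsel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  m <- ncol(g$dosage)
  for (j in seq_len(m)) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(g$sites$chrom[j], g$sites$pos[j],
                       paste0(g$sites$chrom[j], "_", g$sites$pos[j]),
                       ref[j], alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
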