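#' Construct a pedigree table
#'
#' A pedigree table holds trio records (individual, sire, dam) in
#' parent-before-offspring (topological) order. Unknown parents are `NA`.
#' The constructor validates uniqueness, resolvability of parents and
#' acyclicity, and sorts topologically if needed.
#'
#' @param individual character vector of unique individual ids.
#' @param sire,dam character vectors of parent ids; `NA`, `""` or `"0"`
#'   denote an unknown parent.
#' @param generation optional integer generation label per individual.
#' @return A `pedigree_table`: a `data.frame` with columns `individual`,
#'   `sire`, `dam` (and `generation` when supplied), topologically ordered.
#' @examples
#' ped <- pedigree_table(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' founders(ped)
#' @export
pedigree_table <- function(individual, sire, dam, generation = NULL) {
  individual <- as.character(individual)
  sire <- normalize_parent(rep_len(sire, length(individual)))
  dam <- normalize_parent(rep_len(dam, length(individual)))
  dup <- individual[duplicated(individual)]
  if (length(dup) > 0L) {
    stop("duplicate individual id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  }
  for (p in c(sire, dam)) {
    if (!is.na(p) && !(p %in% individual)) {
      stop("parent '", p, "' is not listed as an individual")
    }
  }
  ord <- topo_order(individual, sire, dam)
  out <- data.frame(
    individual = individual[ord], sire = sire[ord], dam = dam[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(generation)) out$generation <- as.integer(generation)[ord]
  class(out) <- c("pedigree_table", "data.frame")
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Kahn's algorithm; errors with the id of one individual on a cycle.
topo_order <- function(individual, sire, dam) {
  n <- length(individual)
  si <- match(sire, individual)
  di <- match(dam, individual)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("pedigree cycle detected involving '", individual[i], "'")
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected involving '", individual[left[1L]], "'")
  }
  ord
}

#' @export
print.pedigree_table <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf(
    "pedigree_table: %d individuals (%d founders, %d with >=1 known parent)\n",
    nrow(x), nf, nrow(x) - nf
  ))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Founder ids of a pedigree
#'
#' @param ped a [pedigree_table()].
#' @return Character vector of individuals with both parents unknown.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  ped$individual[is.na(ped$sire) & is.na(ped$dam)]
}

#' Parent ids of a pedigree
#'
#' @param ped a [pedigree_table()].
#' @return Character vector of individuals appearing as sire or dam.
#' @export
parents_of <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  unique(stats::na.omit(c(ped$sire, ped$dam)))
}

#' Read a pedigree CSV
#'
#' Expects a header `individual,sire,dam`; unknown parents may be encoded
#' as an empty string or `"0"`. Rows need not be in parent-first order;
#' the result is sorted topologically.
#'
#' @param path path to a CSV file.
#' @return A [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          na.strings = NULL)
  need <- c("individual", "sire", "dam")
  if (!all(need %in% names(dt))) {
    stop("pedigree file must have header 'individual,sire,dam'; got: ",
         paste(names(dt), collapse = ","))
  }
  pedigree_table(dt$individual, dt$sire, dt$dam)
}

#' Write a pedigree CSV
#'
#' @param ped a [pedigree_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree_table"))
  out <- data.frame(
    individual = ped$individual,
    sire = ifelse(is.na(ped$sire), "", ped$sire),
    dam = ifelse(is.na(ped$dam), "", ped$dam)
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read long-format phenotype records
#'
#' Expects a header `individual,year,trait,value`. Rows whose value is
#' `NA` or empty are skipped with a message; other non-numeric values are
#' an error naming the offending row. Duplicate (individual, year, trait)
#' combinations are an error.
#'
#' @param path path to a CSV file.
#' @return A `phenotype_records` data.frame with typed columns.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          na.strings = NULL)
  need <- c("individual", "year", "trait", "value")
  if (!all(need %in% names(dt))) {
    stop("phenotype file must have header 'individual,year,trait,value'; got: ",
         paste(names(dt), collapse = ","))
  }
  val_chr <- dt$value
  missing_mask <- is.na(val_chr) | val_chr == "" | toupper(val_chr) == "NA"
  val <- suppressWarnings(as.numeric(val_chr))
  bad <- which(is.na(val) & !missing_mask)
  if (length(bad) > 0L) {
    stop("non-numeric phenotype value '", val_chr[bad[1L]], "' at data row ", bad[1L])
  }
  if (any(missing_mask)) {
    message(sum(missing_mask), " phenotype row(s) with missing value skipped")
  }
  keep <- !missing_mask
  phenotype_records(dt$individual[keep], as.integer(dt$year[keep]),
                    dt$trait[keep], val[keep])
}

#' Construct phenotype records
#'
#' @param individual,year,trait,value parallel vectors; one measurement per
#'   (individual, year, trait).
#' @return A `phenotype_records` data.frame.
#' @export
phenotype_records <- function(individual, year, trait, value) {
  year <- as.integer(year)
  if (anyNA(year)) stop("non-integer year in phenotype records")
  df <- data.frame(
    individual = as.character(individual), year = year,
    trait = as.character(trait), value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  key <- paste(df$individual, df$year, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    stop("duplicate phenotype record for (", d$individual, ", ", d$year,
         ", ", d$trait, ")")
  }
  class(df) <- c("phenotype_records", "data.frame")
  df
}

#' Write phenotype records to CSV
#'
#' @param phen a `phenotype_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  data.table::fwrite(as.data.frame(phen)[, c("individual", "year", "trait", "value")],
                     path)
  invisible(path)
}

#' @export
print.phenotype_records <- function(x, ...) {
  cat(sprintf("phenotype_records: %d records, %d individuals, traits: %s\n",
              nrow(x), length(unique(x$individual)),
              paste(unique(x$trait), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
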