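#' Genotype dataset container
#'
#' Bundles an animals-by-SNP allele-count matrix with its SNP map and the
#' animals' birth dates. Calls count copies of the declared counted allele,
#' coded 0/1/2 with `NA` for missing; after mean-dosage imputation fractional
#' dosages are permitted. Birth dates are decimal years (month and day folded
#' into a fraction of a year).
#'
#' @param calls numeric matrix, animals x SNPs, values in \{0, 1, 2, NA\}
#'   (fractional dosages allowed). Row names are animal ids, column names SNP
#'   ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos`, and optionally
#'   `allele_counted`, `allele_other`. Positions are 1-based base pairs.
#' @param birth_date numeric vector of decimal-year birth dates, one per
#'   animal (recycled names from `calls` row names if unnamed).
#' @param karyotype character vector of admissible chromosome labels.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, map, birth_date,
                             karyotype = c(as.character(1:29), "X")) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- map$snp
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)))
  if (is.null(map$allele_counted)) map$allele_counted <- "A"
  if (is.null(map$allele_other)) map$allele_other <- "B"
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(calls)) {
    stop("map has ", nrow(map), " loci but calls has ", ncol(calls), " columns")
  }
  if (!all(map$snp == colnames(calls))) {
    stop("map SNP ids do not match calls column names")
  }
  bad_chrom <- setdiff(unique(map$chrom), karyotype)
  if (length(bad_chrom)) {
    stop("chromosome labels outside declared karyotype: ",
         paste(bad_chrom, collapse = ", "))
  }
  if (any(map$pos < 0L, na.rm = TRUE)) stop("negative map positions")
  if (length(birth_date) != nrow(calls)) {
    stop("birth_date length ", length(birth_date), " != ", nrow(calls), " animals")
  }
  if (!all(is.finite(birth_date))) stop("birth_date must be finite")
  birth_date <- setNames(as.numeric(birth_date), rownames(calls))
  ok <- is.na(calls) | (calls >= 0 & calls <= 2)
  if (!all(ok)) stop("calls outside [0, 2]")
  structure(
    list(calls = calls, map = map, birth_date = birth_date,
         karyotype = karyotype),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat("genotype_dataset:", nrow(x$calls), "animals x", ncol(x$calls), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = " "), "\n")
  cat(sprintf("  birth dates: %.2f - %.2f\n",
              min(x$birth_date), max(x$birth_date)))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$calls)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Number of animals / loci in a genotype dataset
#' @param g a `genotype_dataset`
#' @return integer count.
#' @export
n_animals <- function(g) nrow(g$calls)

#' @rdname n_animals
#' @export
n_loci <- function(g) ncol(g$calls)

#' Subset a genotype dataset
#'
#' @param g a `genotype_dataset`
#' @param animals animal ids, indices, or logical mask (default: keep all)
#' @param loci SNP ids, indices, or logical mask (default: keep all)
#' @return the subsetted `genotype_dataset`.
#' @export
subset_genotypes <- function(g, animals = NULL, loci = NULL) {
  ai <- if (is.null(animals)) seq_len(nrow(g$calls)) else animals
  if (is.character(ai)) {
    ai <- match(ai, rownames(g$calls))
    if (anyNA(ai)) stop("unknown animal ids in subset")
  }
  li <- if (is.null(loci)) seq_len(ncol(g$calls)) else loci
  if (is.character(li)) {
    li <- match(li, g$map$snp)
    if (anyNA(li)) stop("unknown SNP ids in subset")
  }
  genotype_dataset(g$calls[ai, li, drop = FALSE], g$map[li, , drop = FALSE],
                   g$birth_date[ai], karyotype = g$karyotype)
}

# ---- PLINK PED/MAP ----------------------------------------------------------

strip_ped_ext <- function(path) sub("\\.(ped|map)$", "", path)

#' Read genotypes from disk
#'
#' Two formats are supported. `ped_map` is the PLINK text pair
#' `<prefix>.ped` / `<prefix>.map`; the PED phenotype column carries the
#' decimal-year birth date and missing genotypes are coded `0 0`. The counted
#' allele at each locus is the lexicographically smaller of the two alleles
#' observed there, a deterministic rule that makes write/read round trips the
#' identity. `counts_csv` is a plain CSV with columns `animal`, `birth_date`,
#' then one 0/1/2 column per SNP; an optional companion map CSV
#' (`snp,chrom,pos[,allele_counted,allele_other]`) supplies positions,
#' otherwise loci are placed on chromosome 1 at 1 kb spacing.
#'
#' @param path file path (for `ped_map`, the prefix or either member of the
#'   pair).
#' @param format `"ped_map"` or `"counts_csv"`.
#' @param map_path optional map CSV for `counts_csv` input.
#' @param karyotype admissible chromosome labels.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "counts_csv"),
                           map_path = NULL,
                           karyotype = c(as.character(1:29), "X")) {
  format <- match.arg(format)
  if (format == "ped_map") {
    read_ped_map(strip_ped_ext(path), karyotype)
  } else {
    read_counts_csv(path, map_path, karyotype)
  }
}

read_ped_map <- function(prefix, karyotype) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  map_lines <- readLines(map_path)
  if (!length(map_lines)) stop("parse error: ", map_path, " is empty")
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L)) {
    stop("parse error in ", map_path, " line ", which(nf != 4L)[1],
         ": expected 4 fields (chrom, snp, cM, bp)")
  }
  mm <- do.call(rbind, map_fields)
  map <- data.frame(snp = mm[, 2], chrom = mm[, 1],
                    pos = as.integer(mm[, 4]), stringsAsFactors = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) stop("parse error: ", ped_path, " is empty")
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(fields)
  expect <- 6L + 2L * m
  if (any(nf != expect)) {
    stop("parse error in ", ped_path, " line ", which(nf != expect)[1],
         ": expected ", expect, " fields, found ", nf[nf != expect][1])
  }
  n <- length(fields)
  ids <- vapply(fields, `[[`, "", 2L)
  birth_date <- as.numeric(vapply(fields, `[[`, "", 6L))
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    gcol <- fields[[i]][-(1:6)]
    a1[i, ] <- gcol[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- gcol[seq(2L, 2L * m, by = 2L)]
  }
  calls <- matrix(NA_real_, n, m, dimnames = list(ids, map$snp))
  allele_counted <- character(m)
  allele_other <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2L) {
      stop("data error at locus ", map$snp[j], ": more than two alleles (",
           paste(alleles, collapse = ", "), ")")
    }
    if (length(alleles) == 0L) alleles <- c("A", "B")
    if (length(alleles) == 1L) alleles <- c(alleles, ".")
    allele_counted[j] <- alleles[1]
    allele_other[j] <- alleles[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] == alleles[1]) + (a2[, j] == alleles[1])
    calls[miss, j] <- NA_real_
  }
  map$allele_counted <- allele_counted
  map$allele_other <- allele_other
  genotype_dataset(calls, map, birth_date, karyotype)
}

read_counts_csv <- function(path, map_path, karyotype) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.table(path, sep = ",", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("parse error: ", path, " has no data rows")
  if (!all(c("animal", "birth_date") %in% names(df))) {
    stop("counts CSV must have 'animal' and 'birth_date' columns")
  }
  snp_cols <- setdiff(names(df), c("animal", "birth_date"))
  if (!length(snp_cols)) stop("counts CSV has no SNP columns")
  calls <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(calls) <- "double"
  rownames(calls) <- as.character(df$animal)
  if (!is.null(map_path)) {
    mp <- read.table(map_path, sep = ",", header = TRUE,
                     stringsAsFactors = FALSE)
    mp <- mp[match(snp_cols, mp$snp), , drop = FALSE]
    if (anyNA(mp$snp)) stop("map CSV is missing loci present in ", path)
    map <- mp
  } else {
    map <- data.frame(snp = snp_cols, chrom = "1",
                      pos = seq_along(snp_cols) * 1000L,
                      stringsAsFactors = FALSE)
  }
  genotype_dataset(calls, map, df$birth_date, karyotype)
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()]. For `ped_map` the counted/other allele
#' letters from the map are written (missing as `0 0`), so reading the pair
#' back reproduces the calls exactly provided the counted allele sorts before
#' the other allele (the constructor default `A`/`B` does). Fractional
#' dosages cannot be represented in PED and raise an error.
#'
#' @param g a [genotype_dataset()]
#' @param path output prefix (`ped_map`) or CSV path (`counts_csv`)
#' @param format `"ped_map"` or `"counts_csv"`
#' @param map_path optional companion map CSV path for `counts_csv`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("ped_map", "counts_csv"),
                            map_path = NULL) {
  format <- match.arg(format)
  if (format == "ped_map") {
    frac <- !is.na(g$calls) & g$calls != round(g$calls)
    if (any(frac)) stop("fractional dosages cannot be written as PED")
    prefix <- strip_ped_ext(path)
    map <- g$map
    write.table(data.frame(map$chrom, map$snp, 0, map$pos),
                paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    n <- nrow(g$calls); m <- ncol(g$calls)
    geno <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      cj <- g$calls[, j]
      a <- map$allele_counted[j]; b <- map$allele_other[j]
      first <- ifelse(is.na(cj), "0", ifelse(cj >= 1, a, b))
      second <- ifelse(is.na(cj), "0", ifelse(cj == 2, a, b))
      geno[, 2L * j - 1L] <- first
      geno[, 2L * j] <- second
    }
    out <- cbind("FAM1", rownames(g$calls), "0", "0", "0",
                 format(g$birth_date, digits = 10, trim = TRUE), geno)
    write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(animal = rownames(g$calls),
                     birth_date = g$birth_date,
                     g$calls, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    if (!is.null(map_path)) {
      write.table(g$map, map_path, sep = ",", quote = FALSE,
                  row.names = FALSE)
    }
  }
  invisible(path)
}

# ---- pedigree ---------------------------------------------------------------

#' Pedigree container
#'
#' @param animal,sire,dam character/integer ids; `0`, `""` or `NA` denote an
#'   unknown parent.
#' @param birth_date numeric decimal years (NA allowed).
#' @return data.frame of class `pedigree` with character ids and `"0"` as the
#'   unknown-parent sentinel.
#' @export
pedigree <- function(animal, sire, dam, birth_date = NA_real_) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- "0"
    x
  }
  ped <- data.frame(animal = as.character(animal), sire = norm(sire),
                    dam = norm(dam),
                    birth_date = as.numeric(rep_len(birth_date, length(animal))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  if (any(ped$animal == "0")) stop("'0' is reserved for unknown parents")
  known <- c(ped$sire, ped$dam)
  known <- setdiff(known, c("0", ped$animal))
  if (length(known)) {
    stop("parents absent from the animal column: ",
         paste(head(known, 5), collapse = ", "))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read / write a pedigree CSV (animal,sire,dam,birth_date; 0 = unknown)
#' @param path CSV file path.
#' @return [pedigree()] for the reader; `path` invisibly for the writer.
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character", "numeric"))
  pedigree(df$animal, df$sire, df$dam, df$birth_date)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()]
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Topological order of a pedigree (parents before offspring); errors on a
# cycle, naming an animal inside it.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]   # NA for unknown
  depth <- rep(NA_integer_, n)
  compute <- function(i) {
    stack <- i; onpath <- integer(0)
    while (length(stack)) {
      j <- stack[length(stack)]
      if (!is.na(depth[j])) { stack <- stack[-length(stack)]; next }
      parents <- c(si[j], di[j]); parents <- parents[!is.na(parents)]
      pending <- parents[is.na(depth[parents])]
      if (length(pending)) {
        if (any(pending %in% stack)) {
          stop("pedigree cycle detected involving animal ",
               ped$animal[pending[pending %in% stack][1]])
        }
        stack <- c(stack, pending)
      } else {
        depth[j] <<- if (length(parents)) max(depth[parents]) + 1L else 0L
        stack <- stack[-length(stack)]
      }
    }
  }
  for (i in seq_len(n)) if (is.na(depth[i])) compute(i)
  order(depth, seq_len(n))
}

# ---- trait tables -----------------------------------------------------------

#' Trait table of EBVs with accuracies and per-trait constants
#'
#' @param records data.frame with columns `animal`, `trait`, `ebv`,
#'   `accuracy_r2` (reliability, in \[0, 1\]).
#' @param traits data.frame with columns `trait`, `h2` (heritability, in
#'   (0, 1\]) and `c` (fraction of genetic variance not captured by markers,
#'   in \[0, 1\]).
#' @return list of class `trait_table`.
#' @export
trait_table <- function(records, traits) {
  stopifnot(all(c("animal", "trait", "ebv", "accuracy_r2") %in% names(records)),
            all(c("trait", "h2", "c") %in% names(traits)))
  if (any(records$accuracy_r2 < 0 | records$accuracy_r2 > 1, na.rm = TRUE)) {
    stop("accuracy_r2 outside [0, 1]")
  }
  if (any(traits$h2 <= 0 | traits$h2 > 1)) stop("h2 outside (0, 1]")
  if (any(traits$c < 0 | traits$c > 1)) stop("c outside [0, 1]")
  missing_tr <- setdiff(unique(records$trait), traits$trait)
  if (length(missing_tr)) {
    stop("traits without h2/c rows: ", paste(missing_tr, collapse = ", "))
  }
  structure(list(records = records, traits = traits), class = "trait_table")
}

#' Read a trait table from two CSVs
#' @param records_path CSV `animal,trait,ebv,accuracy_r2`
#' @param traits_path CSV `trait,h2,c`
#' @return a [trait_table()].
#' @export
read_trait_table <- function(records_path, traits_path) {
  trait_table(read.table(records_path, sep = ",", header = TRUE,
                         stringsAsFactors = FALSE),
              read.table(traits_path, sep = ",", header = TRUE,
                         stringsAsFactors = FALSE))
}
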