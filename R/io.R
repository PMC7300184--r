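## All writers are deterministic: fixed column order, fixed decimal
## formatting, "\n" line endings.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

fmt6 <- function(x) {
  out <- sprintf("%.6f", x)
  out[x == 0] <- "0"
  out[x == 1] <- "1"
  out
}

#' Write and read breed allele-frequency tables
#'
#' The frequency TSV is the package's exchange format for reference
#' panels: columns `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`, then
#' one `freq_<breed>` column per breed (allele-A frequency, 6 decimal
#' places). Breed order in the header is authoritative and is preserved
#' in every downstream vector and table. The `allele_a` column fixes the
#' orientation of genotype coding (codes count copies of allele A).
#'
#' @param panel a [reference_panel()].
#' @param path output file.
#' @return `write_freq_table()` returns the path invisibly;
#'   `read_freq_table()` returns a `"reference_panel"`.
#' @export
write_freq_table <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  al <- panel$alleles
  if (is.null(al)) {
    al <- data.frame(snp_id = panel$snp_ids, chrom = 0L,
                     pos = seq_along(panel$snp_ids),
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  } else {
    al <- al[match(panel$snp_ids, al$snp_id), ]
  }
  df <- data.frame(al[c("snp_id", "chrom", "pos", "allele_a", "allele_b")],
                   stringsAsFactors = FALSE)
  for (b in panel$breeds) df[[paste0("freq_", b)]] <- fmt6(panel$freq[, b])
  write_tsv(df, path)
}

#' @rdname write_freq_table
#' @param clamp frequency clamp applied on load (default 1e-6).
#' @export
read_freq_table <- function(path, clamp = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("frequency table ", path, " lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  fcols <- grep("^freq_", names(df), value = TRUE)
  if (!length(fcols))
    stop("frequency table ", path, " has no freq_<breed> columns",
         call. = FALSE)
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id in ", path, ": ",
         df$snp_id[anyDuplicated(df$snp_id)], call. = FALSE)
  for (cc in fcols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("frequency outside [0, 1] in %s: row %d, column %s",
                   path, bad[1L], cc), call. = FALSE)
    df[[cc]] <- v
  }
  freq <- as.matrix(df[fcols])
  colnames(freq) <- sub("^freq_", "", fcols)
  rownames(freq) <- df$snp_id
  reference_panel(freq,
                  alleles = df[c("snp_id", "chrom", "pos", "allele_a",
                                 "allele_b")],
                  clamp = clamp)
}

#' Write and read PLINK text PED/MAP genotypes
#'
#' Standard PLINK text format: the MAP file has one row per SNP
#' (chromosome, SNP id, genetic distance, base-pair position); the PED
#' file has six leading columns (family, individual, father, mother, sex,
#' phenotype) followed by two allele calls per SNP. Missing calls are
#' written and read as `0 0`.
#'
#' On reading, each SNP's calls are mapped to the A/B coding (code =
#' number of copies of allele A) using the supplied allele table; without
#' one, the lexicographically smaller observed allele is taken as allele
#' A and a warning is issued, since the orientation is then a convention
#' rather than a recorded fact.
#'
#' @param geno a [snp_genotypes()] matrix.
#' @param ped,map file paths.
#' @param alleles data frame with columns `snp_id`, `allele_a`,
#'   `allele_b` (and optionally `chrom`, `pos`) fixing the letter coding;
#'   for writing, defaults to alleles `A`/`C` on chromosome 0.
#' @return `write_ped_map()` returns the paths invisibly;
#'   `read_ped_map()` returns a [snp_genotypes()] matrix in MAP order.
#' @export
write_ped_map <- function(geno, ped, map, alleles = NULL) {
  snps <- colnames(geno)
  if (is.null(alleles)) {
    alleles <- data.frame(snp_id = snps, chrom = 0L,
                          pos = seq_along(snps),
                          allele_a = "A", allele_b = "C",
                          stringsAsFactors = FALSE)
  } else {
    alleles <- alleles[match(snps, alleles$snp_id), ]
    if (anyNA(alleles$snp_id))
      stop("allele table lacks SNP(s) present in the genotypes",
           call. = FALSE)
    if (is.null(alleles$chrom)) alleles$chrom <- 0L
    if (is.null(alleles$pos)) alleles$pos <- seq_along(snps)
  }
  map_lines <- paste(alleles$chrom, snps, 0, alleles$pos, sep = "\t")
  con <- file(map, open = "wb"); writeLines(map_lines, con, sep = "\n")
  close(con)

  g <- unclass(geno)
  n <- nrow(g)
  a <- alleles$allele_a
  b <- alleles$allele_b
  lines <- character(n)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    call1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, a, b))
    call2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, a, b))
    lines[i] <- paste(c(rownames(g)[i], rownames(g)[i], "0", "0", "0", "-9",
                        rbind(call1, call2)), collapse = " ")
  }
  con <- file(ped, open = "wb"); writeLines(lines, con, sep = "\n")
  close(con)
  invisible(list(ped = ped, map = map))
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(ped, map, alleles = NULL) {
  for (f in c(ped, map))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  mp <- utils::read.table(map, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp_id", "cm", "pos"))
  M <- nrow(mp)
  if (anyDuplicated(mp$snp_id))
    stop("duplicate snp_id in ", map, call. = FALSE)
  lines <- readLines(ped)
  n <- length(lines)
  codes <- matrix(NA_integer_, n, M)
  ids <- character(n)
  valid <- c("A", "C", "G", "T", "0")
  allele_mat <- matrix(NA_character_, n, 2L * M)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(fields) != 6L + 2L * M)
      stop(sprintf(
        "ragged PED row at line %d of %s: %d fields, expected %d",
        i, ped, length(fields), 6L + 2L * M), call. = FALSE)
    ids[i] <- fields[2L]
    al <- fields[-(1:6)]
    bad <- setdiff(unique(al), valid)
    if (length(bad))
      stop(sprintf("invalid allele symbol '%s' at line %d of %s",
                   bad[1L], i, ped), call. = FALSE)
    allele_mat[i, ] <- al
  }
  a1 <- allele_mat[, 2L * seq_len(M) - 1L, drop = FALSE]
  a2 <- allele_mat[, 2L * seq_len(M), drop = FALSE]
  if (is.null(alleles)) {
    warned <- FALSE
    allele_a <- character(M)
    for (k in seq_len(M)) {
      obs <- sort(setdiff(unique(c(a1[, k], a2[, k])), "0"))
      allele_a[k] <- if (length(obs)) obs[1L] else "A"
      if (length(obs) > 1L) warned <- TRUE
    }
    if (warned)
      warning("no allele table supplied; taking the lexicographically ",
              "smaller observed allele as allele A", call. = FALSE)
  } else {
    idx <- match(mp$snp_id, alleles$snp_id)
    if (anyNA(idx))
      stop("allele table lacks SNP(s) present in ", map, call. = FALSE)
    allele_a <- alleles$allele_a[idx]
    allele_b <- alleles$allele_b[idx]
    for (k in seq_len(M)) {
      obs <- setdiff(unique(c(a1[, k], a2[, k])), "0")
      unknown <- setdiff(obs, c(allele_a[k], allele_b[k]))
      if (length(unknown))
        stop(sprintf(
          "allele '%s' at SNP %s is neither allele_a nor allele_b; check strand/allele coding",
          unknown[1L], mp$snp_id[k]), call. = FALSE)
    }
  }
  for (k in seq_len(M)) {
    miss <- a1[, k] == "0" | a2[, k] == "0"
    codes[, k] <- (a1[, k] == allele_a[k]) + (a2[, k] == allele_a[k])
    codes[miss, k] <- NA_integer_
  }
  snp_genotypes(codes, animal_ids = ids, snp_ids = mp$snp_id)
}

#' Read a breed-assignment table
#'
#' Two-column TSV (`animal_id`, `breed`) linking genotyped animals to
#' their labeled breed.
#'
#' @param path file path.
#' @return data frame with columns `animal_id` and `breed`.
#' @export
read_breed_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("animal_id", "breed") %in% names(df)))
    stop("breed table ", path,
         " must have columns 'animal_id' and 'breed'", call. = FALSE)
  df
}

#' Write a GBC results table
#'
#' One row per animal: `animal_id`, one column per panel breed (GBC to 6
#' decimal places, exact zeros and ones written as `0` and `1`), the row
#' `sum`, the solution log-likelihood, the number of non-missing SNPs
#' used, and the convergence flag.
#'
#' @param fit an `"admix_fit"`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gbc_table <- function(fit, path) {
  stopifnot(inherits(fit, "admix_fit"))
  df <- data.frame(animal_id = fit$animal_ids, stringsAsFactors = FALSE)
  for (b in fit$breeds) df[[b]] <- fmt6(fit$gbc[, b])
  df$sum <- fmt6(rowSums(fit$gbc))
  df$loglik <- sprintf("%.6f", fit$loglik)
  df$n_snps_used <- fit$n_snps_used
  df$converged <- fit$converged
  write_tsv(df, path)
}

#' Write a curation report
#'
#' @param report the `report` data frame from [curate_reference()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_curation_report <- function(report, path) {
  report$score <- sprintf("%.6f", report$score)
  write_tsv(report[c("animal_id", "breed", "score", "excluded")], path)
}

#' Read a run-configuration file
#'
#' YAML configuration supplying defaults for the command-line interface.
#' Recognized keys: `penalty`, `lambda`, `gamma`, `max_iter`, `tol_kkt`,
#' `tol_obj`, `cutoff`, `curation_mode`, `normalization`, `pseudocount`,
#' `clamp`, `seed`. Unknown keys are rejected by name, so typos fail
#' loudly rather than being ignored.
#'
#' @param path YAML file.
#' @return A named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config ", path, " is not a key-value mapping",
                          call. = FALSE)
  known <- c("penalty", "lambda", "gamma", "max_iter", "tol_kkt", "tol_obj",
             "cutoff", "curation_mode", "normalization", "pseudocount",
             "clamp", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}
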