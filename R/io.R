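#' Pedigree CSV round-trip
#'
#' Plain CSV with columns id, sire, dam, sex, generation, tbv, phenotype;
#' 0 marks an unknown parent and males have empty phenotypes.
#'
#' @param ped pedigree data.frame (as produced by [run_program()]).
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_pedigree <- function(ped, path) {
  cols <- c("id", "sire", "dam", "sex", "generation", "tbv", "phenotype")
  stopifnot(all(cols %in% names(ped)))
  utils::write.csv(ped[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  ped$id <- as.integer(ped$id)
  ped$sire <- as.integer(ped$sire)
  ped$dam <- as.integer(ped$dam)
  ped$generation <- as.integer(ped$generation)
  ped
}

#' Export a (masked or imputed) dosage matrix as plain text
#'
#' Whitespace-separated matrix with animal ids in the first column; missing
#' dosages are written as the sentinel -1.
#'
#' @param geno numeric/integer matrix (animals x markers, rownames = ids),
#'   NA for missing.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_dosage_matrix <- function(geno, path) {
  out <- geno
  out[is.na(out)] <- -1
  df <- data.frame(id = rownames(geno), out, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export genotypes as VCF
#'
#' Unphased VCFv4.2 with `GT` (missing = `./.`) and a `DS` dosage field;
#' fractional imputed dosages are carried in `DS` while `GT` holds the hard
#' call where one exists.
#'
#' @param geno dosage matrix (animals x markers, rownames = ids); fractional
#'   values allowed, NA = missing.
#' @param site_chr chromosome index per marker column.
#' @param site_bp 0-based physical position per marker column.
#' @param path file path.
#' @param hard optional matrix of hard calls (NA = no call); computed with
#'   [hard_calls()] when NULL.
#' @return invisibly, the path.
#' @export
write_genotypes_vcf <- function(geno, site_chr, site_bp, path, hard = NULL) {
  stopifnot(ncol(geno) == length(site_chr), ncol(geno) == length(site_bp))
  if (is.null(hard)) hard <- hard_calls(geno)
  gt_of <- function(h) {
    ifelse(is.na(h), "./.", c("0/0", "0/1", "1/1")[h + 1L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr%d>", sort(unique(site_chr))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")), con)
  for (j in seq_len(ncol(geno))) {
    ds <- ifelse(is.na(geno[, j]), ".", format(geno[, j], digits = 4,
                                               trim = TRUE))
    fields <- paste(gt_of(hard[, j]), ds, sep = ":")
    writeLines(paste(c(sprintf("chr%d", site_chr[j]), site_bp[j] + 1L,
                       sprintf("m%d", j), "A", "B", ".", "PASS", ".",
                       "GT:DS", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Export EBVs as CSV
#'
#' Columns id, method, scenario, ebv.
#'
#' @param ebv named numeric vector (names = animal ids).
#' @param method method tag ("BLUP" or "ssGBLUP").
#' @param scenario scenario id.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_ebv <- function(ebv, method, scenario, path) {
  utils::write.csv(data.frame(id = names(ebv), method = method,
                              scenario = scenario, ebv = unname(ebv)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dump a matrix in coordinate (i, j, value) text format
#'
#' Sparse matrices write their nonzeros; dense matrices every entry.
#'
#' @param m matrix or Matrix.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_matrix_coo <- function(m, path) {
  if (inherits(m, "sparseMatrix")) {
    tm <- methods::as(m, "TsparseMatrix")
    df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, value = tm@x)
  } else {
    df <- data.frame(i = rep(seq_len(nrow(m)), ncol(m)),
                     j = rep(seq_len(ncol(m)), each = nrow(m)),
                     value = as.vector(m))
    df <- df[df$value != 0, ]
  }
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
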