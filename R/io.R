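#' Write genotypes to PLINK bed/bim/fam
#'
#' SNP-major .bed with the standard magic bytes; dosages of allele1 map to the
#' PLINK two-bit codes with allele1 as the A1 (first) allele.
#'
#' @param G a [geno_matrix()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @param sex optional character vector (`"male"`/`"female"`) for the fam
#'   file.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix, sex = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  n <- nrow(D); m <- ncol(D)
  v <- G$variants
  utils::write.table(
    data.frame(v$chr, v$id, 0, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  sexcode <- if (is.null(sex)) rep(0L, n) else
    ifelse(sex == "male", 1L, ifelse(sex == "female", 2L, 0L))
  utils::write.table(
    data.frame(G$subject_ids, G$subject_ids, 0, 0, sexcode, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  # two-bit codes per genotype: hom A1 = 00, missing = 01, het = 10,
  # hom A2 = 11; samples packed 4 per byte, LSB first, SNP-major
  code <- matrix(3L, n, m)              # dosage 0 (hom allele2) -> 11
  code[D == 2L] <- 0L
  code[D == 1L] <- 2L
  code[is.na(D)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4L
  codes_padded <- rbind(code, matrix(0L, pad - n, m))
  i4 <- matrix(seq_len(pad), nrow = 4)
  bytes <- codes_padded[i4[1, ], , drop = FALSE] +
    4L * codes_padded[i4[2, ], , drop = FALSE] +
    16L * codes_padded[i4[3, ], , drop = FALSE] +
    64L * codes_padded[i4[4, ], , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read genotypes from PLINK bed/bim/fam
#'
#' Inverse of [write_plink()]: expects a SNP-major .bed and returns dosages of
#' the bim A1 allele.
#'
#' @param prefix path prefix of the fileset.
#' @return a [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character",
                                          "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpv * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  D <- matrix(NA_integer_, n, m)
  D[codes == 0L] <- 2L
  D[codes == 2L] <- 1L
  D[codes == 3L] <- 0L
  geno_matrix(D, bim[c("id", "chr", "pos", "allele1", "allele2")],
              as.character(fam[[2]]))
}

#' Write genotypes to VCF
#'
#' Minimal VCFv4.2 with GT fields; allele2 is written as REF and allele1 as
#' ALT, so the ALT count equals the allele1 dosage.
#'
#' @param G a [geno_matrix()].
#' @param path output `.vcf` path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- t(G$dosages)  # variants x subjects
  gt <- matrix("./.", nrow(D), ncol(D))
  gt[!is.na(D) & D == 0L] <- "0/0"
  gt[!is.na(D) & D == 1L] <- "0/1"
  gt[!is.na(D) & D == 2L] <- "1/1"
  v <- G$variants
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$subject_ids), collapse = "\t"),
    paste(v$chr, v$pos, v$id, v$allele2, v$allele1, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses GT fields via the vcfR package; dosages count the ALT allele
#' (stored as allele1).
#'
#' @param path a `.vcf` / `.vcf.gz` file.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  D <- t(apply(gt, 1, alt_count))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  geno_matrix(t(D), data.frame(id = fix$ID, chr = fix$CHROM,
                               pos = as.integer(fix$POS),
                               allele1 = fix$ALT, allele2 = fix$REF),
              colnames(gt))
}

#' Write a weight table as tab-delimited text
#'
#' Standard summary-statistic layout with header
#' `SNP CHR BP A1 A2 FREQ BETA INFO P`.
#'
#' @param weights a [weight_table()].
#' @param path output path.
#' @param p optional per-variant p-values (written as NA when absent).
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path, p = NULL) {
  stopifnot(inherits(weights, "weight_table"))
  out <- data.frame(SNP = weights$id, CHR = weights$chr, BP = weights$pos,
                    A1 = weights$effect_allele, A2 = weights$other_allele,
                    FREQ = weights$freq, BETA = weights$weight,
                    INFO = weights$info,
                    P = if (is.null(p)) NA else p)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a weight table from delimited text
#'
#' Whitespace- or tab-delimited with a header; column names are matched
#' case-insensitively against common aliases (SNP/ID/RSID; CHR/CHROM;
#' BP/POS; A1/EA/EFFECT_ALLELE; A2/OA/OTHER_ALLELE; FREQ/EAF/FRQ;
#' BETA/B/EFFECT/WEIGHT; INFO).
#'
#' @param path input file.
#' @return a [weight_table()].
#' @export
read_weight_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- toupper(names(d))
  pick <- function(aliases, required = TRUE) {
    i <- which(nm %in% aliases)[1]
    if (is.na(i)) {
      if (required) stop("weight table lacks a column among: ",
                         paste(aliases, collapse = "/"))
      return(NULL)
    }
    d[[i]]
  }
  info <- pick(c("INFO"), required = FALSE)
  id <- pick(c("SNP", "ID", "RSID"))
  weight_table(
    id = id, chr = pick(c("CHR", "CHROM")), pos = pick(c("BP", "POS")),
    effect_allele = pick(c("A1", "EA", "EFFECT_ALLELE")),
    other_allele = pick(c("A2", "OA", "OTHER_ALLELE")),
    freq = pick(c("FREQ", "EAF", "FRQ")),
    weight = pick(c("BETA", "B", "EFFECT", "WEIGHT")),
    info = if (is.null(info)) rep(1, length(id)) else info)
}

#' Write the register tables of a synthetic study to CSV
#'
#' Emits `subjects.csv`, `prescriptions.csv`, `ect_events.csv`, `truth.csv`,
#' one weight table per trait (`weights_<trait>.tsv`), and the genotypes as
#' PLINK bed/bim/fam plus VCF.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(dir, f), row.names = FALSE)
  wcsv(study$subjects, "subjects.csv")
  wcsv(study$prescriptions, "prescriptions.csv")
  wcsv(study$ect_events, "ect_events.csv")
  wcsv(study$truth, "truth.csv")
  for (tr in names(study$weights))
    write_weight_table(study$weights[[tr]],
                       file.path(dir, sprintf("weights_%s.tsv", tr)))
  write_plink(study$genotypes, file.path(dir, "genotypes"),
              sex = study$subjects$reported_sex)
  write_vcf(study$genotypes, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}
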