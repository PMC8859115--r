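#' Write a cohort to VCF + phenotype TSV
#'
#' Genotypes are written as a VCF 4.2 body with `GT` (rounded dosage) and
#' `DS` (dosage, 6 decimal places) FORMAT fields; missing genotypes as `./.`.
#' Per-SNP drawn minor allele frequencies (when present) go into the INFO
#' column, and causal-truth indices are preserved in `##causal_<trait>`
#' header lines so that `read_cohort(write_cohort(x))` reproduces `x` up to
#' the declared 1e-6 dosage precision. The phenotype TSV is tab-delimited
#' with header `subject_id sex age synthetic <trait1> <trait2> ...`.
#'
#' @param cohort A `cohort`.
#' @param vcf_path,pheno_path Output paths (`.gz` suffix enables gzip).
#' @return Invisibly, the two paths.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, vcf_path, pheno_path) {
  stopifnot(inherits(cohort, "cohort"))
  dos <- cohort$dosages
  n <- nrow(dos); m <- ncol(dos)
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path, "w") else file(vcf_path, "w")
  on.exit(close(con), add = TRUE)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=smotescan",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Simulated minor allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">")
  for (tn in names(cohort$causal_truth))
    hdr <- c(hdr, sprintf("##causal_%s=%s", tn,
                          paste(cohort$causal_truth[[tn]], collapse = ",")))
  writeLines(hdr, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$subjects$subject_id),
                   collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  info <- if (is.null(cohort$maf)) rep(".", m) else sprintf("MAF=%.6f", cohort$maf)
  for (j in seq_len(m)) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[pmin(pmax(round(d), 0), 2) + 1L])
    ds <- ifelse(is.na(d), ".", sprintf("%.6f", d))
    row <- c(cohort$snp_meta$chrom[j], cohort$snp_meta$pos[j],
             cohort$snp_meta$id[j], cohort$snp_meta$ref[j],
             cohort$snp_meta$alt[j], ".", ".", info[j], "GT:DS",
             paste(gt, ds, sep = ":"))
    writeLines(paste(row, collapse = "\t"), con)
  }
  ph <- data.frame(subject_id = cohort$subjects$subject_id,
                   sex = cohort$subjects$sex,
                   age = cohort$subjects$age,
                   synthetic = as.integer(cohort$synthetic),
                   stringsAsFactors = FALSE)
  ph <- cbind(ph, as.data.frame(cohort$traits))
  write.table(ph, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, pheno = pheno_path))
}

#' Read a cohort from VCF + phenotype TSV
#'
#' Strict parser for the dialect written by [write_cohort()]: dosages are
#' taken from the `DS` FORMAT field when present, otherwise from `GT`.
#' Malformed rows, unsorted positions within a chromosome, and missing
#' phenotype columns raise errors naming the offending line or column.
#'
#' @param vcf_path,pheno_path Input paths.
#' @return A `cohort`.
#' @export
read_cohort <- function(vcf_path, pheno_path) {
  lines <- readLines(vcf_path)
  meta <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM"))
    stop("VCF parse error at line ", length(meta) + 1L,
         ": missing #CHROM header line")
  header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  if (length(header) < 10) stop("VCF parse error: no sample columns")
  samples <- header[-(1:9)]
  n <- length(samples); m <- length(body) - 1L
  dos <- matrix(NA_real_, n, m)
  chrom <- integer(m); pos <- integer(m)
  id <- ref <- alt <- character(m); maf <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    lineno <- length(meta) + 1L + j
    f <- strsplit(body[j + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + n)
      stop("VCF parse error at line ", lineno, ": expected ", 9 + n,
           " fields, found ", length(f))
    chrom[j] <- as.integer(f[1]); pos[j] <- as.integer(f[2])
    id[j] <- f[3]; ref[j] <- f[4]; alt[j] <- f[5]
    if (grepl("MAF=", f[8], fixed = TRUE))
      maf[j] <- as.numeric(sub(".*MAF=([0-9.eE+-]+).*", "\\1", f[8]))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_i <- match("DS", fmt); gt_i <- match("GT", fmt)
    if (is.na(ds_i) && is.na(gt_i))
      stop("VCF parse error at line ", lineno, ": FORMAT has neither GT nor DS")
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    if (!is.na(ds_i)) {
      v <- vapply(cells, `[`, "", ds_i)
      dos[, j] <- suppressWarnings(as.numeric(v))  # "." -> NA
    } else {
      g <- vapply(cells, `[`, "", gt_i)
      v <- rep(NA_real_, n)
      v[g %in% c("0/0", "0|0")] <- 0
      v[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
      v[g %in% c("1/1", "1|1")] <- 2
      dos[, j] <- v
    }
    if (j > 1) {
      if (chrom[j] < chrom[j - 1L])
        stop("VCF parse error at line ", lineno,
             ": chromosomes out of order")
      if (chrom[j] == chrom[j - 1L] && pos[j] <= pos[j - 1L])
        stop("VCF parse error at line ", lineno,
             ": positions not strictly increasing within chromosome ", chrom[j])
    }
  }
  if (all(is.na(maf))) maf <- NULL

  ph <- read.delim(pheno_path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("subject_id", "sex", "age"))
    if (!col %in% names(ph)) stop("phenotype TSV is missing column '", col, "'")
  if (!identical(ph$subject_id, samples))
    stop("phenotype subject_id column does not match VCF sample order")
  synthetic <- if ("synthetic" %in% names(ph)) as.logical(ph$synthetic)
               else rep(FALSE, n)
  trait_cols <- setdiff(names(ph), c("subject_id", "sex", "age", "synthetic"))
  traits <- as.matrix(ph[trait_cols])
  storage.mode(traits) <- "integer"
  dimnames(traits) <- list(NULL, trait_cols)

  causal <- list()
  for (ln in meta[grepl("^##causal_", meta)]) {
    kv <- sub("^##causal_", "", ln)
    nm <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    causal[[nm]] <- if (nzchar(val)) as.integer(strsplit(val, ",")[[1]]) else integer(0)
  }
  if (!length(causal)) causal <- setNames(rep(list(integer(0)),
                                              length(trait_cols)), trait_cols)

  new_cohort(dos,
             data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                        alt = alt, stringsAsFactors = FALSE),
             data.frame(subject_id = ph$subject_id, sex = ph$sex,
                        age = ph$age, stringsAsFactors = FALSE),
             traits, causal, maf = maf, synthetic = synthetic)
}

#' Write / read an association table as PLINK-like TSV
#'
#' Columns `CHR POS ID P` (plus `STAT` and `FLAG` when available).
#'
#' @param assoc An `assoc_table` (see [assoc_scan()]).
#' @param path Output path.
#' @return `write_assoc` the path, invisibly; `read_assoc` an `assoc_table`.
#' @export
write_assoc <- function(assoc, path) {
  df <- data.frame(CHR = assoc$chrom, POS = assoc$pos, ID = assoc$id,
                   P = assoc$p, STAT = assoc$stat, FLAG = assoc$flag)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("CHR", "POS", "ID", "P"))
    if (!col %in% names(df)) stop("association TSV is missing column '", col, "'")
  new_assoc_table(df$CHR, df$POS, df$ID,
                  stat = if ("STAT" %in% names(df)) df$STAT else rep(NA_real_, nrow(df)),
                  p = df$P,
                  flag = if ("FLAG" %in% names(df)) df$FLAG else rep("", nrow(df)))
}
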