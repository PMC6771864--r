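# Readers and writers for every on-disk format the pipeline touches:
# summary-statistics TSV, VCF (GT hard calls), BED gene intervals, GMT gene
# sets and the cohort visit TSV. Internal coordinates are 1-based closed
# everywhere; BED's 0-based half-open convention is converted exactly once,
# at ingestion/serialisation.

#' Write / read GWAS summary statistics (TSV)
#'
#' Columns: SNP, CHR, BP, A1 (effect/counted allele), A2, BETA, SE, P, FRQ.
#' On read, rows with non-finite BETA/SE, SE <= 0, or P outside (0, 1] are
#' dropped and counted (attribute `n_dropped`, also reported via
#' `message()`); duplicate variant keys (CHR:BP:A1:A2) are an error.
#'
#' @param x a `sumstat_table` data.frame.
#' @param path file path.
#' @return `read_sumstats()` returns a `sumstat_table`.
#' @export
write_sumstats <- function(x, path) {
  need_cols(x, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "FRQ"),
            "sumstat table")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  req <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("summary statistics file is missing required column(s): ",
         paste(miss, collapse = ", "))
  suppressWarnings({
    x$BETA <- as.numeric(x$BETA); x$SE <- as.numeric(x$SE)
    x$P <- as.numeric(x$P)
  })
  ok <- is.finite(x$BETA) & is.finite(x$SE) & x$SE > 0 &
    is.finite(x$P) & x$P > 0 & x$P <= 1
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " summary-statistic row(s) failed validation and were dropped")
  x <- x[ok, , drop = FALSE]
  if (!nrow(x)) stop("no usable summary-statistic rows in ", path)
  key <- paste(x$CHR, x$BP, x$A1, x$A2, sep = ":")
  if (anyDuplicated(key)) stop("duplicate variant keys in ", path)
  rownames(x) <- NULL
  attr(x, "n_dropped") <- n_dropped
  class(x) <- c("sumstat_table", "data.frame")
  x
}

#' Write genotype dosages as a minimal VCF 4.2 (GT hard calls)
#'
#' One biallelic record per variant; dosage 0/1/2 becomes GT `0/0`, `0/1`,
#' `1/1` with ALT = the counted (a1) allele; missing dosage becomes `./.`.
#'
#' @param dm a `dosage_matrix`.
#' @param path output `.vcf` path (uncompressed text).
#' @export
write_vcf <- function(dm, path) {
  stopifnot(inherits(dm, "dosage_matrix"))
  v <- dm$variants
  G <- dm$dosages
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  # ALT is the counted allele so alt-allele count == dosage
  body <- vapply(seq_len(nrow(v)), function(j) {
    calls <- ifelse(is.na(G[, j]), "./.", gt[G[, j] + 1L])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS",
            ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Additive dosage = count of ALT alleles from the GT field; `./.` is
#' missing (never silently 0). Multi-allelic records are rejected unless
#' `skip_multiallelic = TRUE`, in which case they are dropped and counted.
#'
#' @param path VCF path (plain text or gzipped).
#' @param skip_multiallelic drop multi-allelic records instead of erroring.
#' @return a `dosage_matrix` (maf column = observed ALT frequency among
#'   non-missing calls, capped at its folded value where relevant).
#' @export
read_vcf <- function(path, skip_multiallelic = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!skip_multiallelic)
      stop(sum(multi), " multi-allelic record(s); set skip_multiallelic = TRUE to drop them")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    known <- !is.na(g) & !g %in% c("./.", ".|.", ".")
    parts <- strsplit(g[known], "[/|]")
    bad <- vapply(parts, function(p) any(!p %in% c("0", "1", ".")), logical(1))
    if (any(bad))
      stop("malformed GT at record line(s): ",
           paste(which(known)[bad], collapse = ", "))
    out[known] <- vapply(parts, function(p) sum(p == "1"), integer(1))
    out
  }
  dos <- t(apply(gt, 1L, count_alt))
  if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L)
  dos <- t(dos)  # samples x variants
  colnames(dos) <- fix$ID
  rownames(dos) <- colnames(gt)
  frq <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), a1 = fix$ALT,
                         a2 = fix$REF, maf = pmin(frq, 1 - frq),
                         block = NA_integer_, apoe_slot = NA_character_,
                         stringsAsFactors = FALSE)
  samples <- data.frame(iid = colnames(gt), role = NA_character_, pop = NA,
                        stringsAsFactors = FALSE)
  storage.mode(dos) <- "integer"
  structure(list(dosages = dos, variants = variants, samples = samples),
            class = "dosage_matrix")
}

#' Write / read gene intervals (BED)
#'
#' On disk BED is 0-based half-open; in memory intervals are 1-based closed,
#' so `chr19 44400000 46500000` loads as `[44400001, 46500000]`.
#'
#' @param genes data.frame chrom/start/end/gene (1-based closed).
#' @param path file path.
#' @export
write_bed <- function(genes, path) {
  need_cols(genes, c("chrom", "start", "end", "gene"), "gene table")
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(V1 = "character"))
  if (ncol(x) < 4L) stop("BED file needs chrom, start, end, name columns")
  names(x)[1:4] <- c("chrom", "start", "end", "gene")
  if (any(x$start > x$end)) stop("BED interval with start > end")
  x$start <- as.integer(x$start) + 1L  # to 1-based closed
  x$end <- as.integer(x$end)
  x[, c("chrom", "start", "end", "gene")]
}

#' Write / read gene sets (GMT)
#'
#' GMT: one set per line, `name <TAB> description <TAB> member...`.
#' Duplicate set names are an error on read.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nms)) stop("duplicate gene-set name in ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  sets
}

#' Write / read the longitudinal cohort table (TSV)
#'
#' Columns IID, SEX, AGE, VISIT, DX (one of CN/MCI/AD), SUVR (optional, NA
#' allowed). On read, visits are sorted within subject; unknown DX codes and
#' duplicate (IID, VISIT) pairs are errors.
#'
#' @param visits visit-level data.frame.
#' @param path file path.
#' @export
write_cohort <- function(visits, path) {
  need_cols(visits, c("IID", "SEX", "AGE", "VISIT", "DX"), "cohort table")
  utils::write.table(visits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need_cols(x, c("IID", "SEX", "AGE", "VISIT", "DX"), "cohort file")
  bad <- setdiff(unique(x$DX), c("CN", "MCI", "AD"))
  if (length(bad))
    stop("unknown DX code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(x[, c("IID", "VISIT")]))
    stop("duplicate (IID, VISIT) records")
  x <- x[order(x$IID, x$VISIT), , drop = FALSE]
  rownames(x) <- NULL
  if (!"SUVR" %in% names(x)) x$SUVR <- NA_real_
  x
}
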