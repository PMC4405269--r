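# Genotype container and readers/writers for the plain formats used by the
# pipeline: VCF (DS or GT), dosage TSV, phenotype TSV, scan-result TSV.

#' Genotype data container
#'
#' A light container for a panel of biallelic SNPs: an annotation data frame
#' (`rsid`, `chrom`, `pos`, `ref`, `alt`, `maf`, `quality`, `flipped`) and a
#' SNP x individual dosage matrix with values in `[0, 2]` counting the minor
#' allele.
#'
#' @param dosage Numeric matrix, SNPs in rows, individuals in columns.
#' @param info Data frame with one row per SNP; missing annotation columns
#'   are filled with defaults.
#' @param samples Optional individual identifiers (default column names of
#'   `dosage`, else `ind1..indn`).
#' @return An object of class `"genotype_data"`.
#' @export
genotype_data <- function(dosage, info = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (any(dosage < -1e-8 | dosage > 2 + 1e-8, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  m <- nrow(dosage)
  if (is.null(samples)) samples <- colnames(dosage)
  if (is.null(samples)) samples <- paste0("ind", seq_len(ncol(dosage)))
  if (length(samples) != ncol(dosage)) {
    stop("`samples` must name every dosage column", call. = FALSE)
  }
  if (is.null(info)) info <- data.frame(rsid = paste0("snp", seq_len(m)))
  info <- as.data.frame(info)
  if (nrow(info) != m) stop("`info` must have one row per SNP", call. = FALSE)
  defaults <- list(rsid = paste0("snp", seq_len(m)), chrom = "1",
                   pos = seq_len(m), ref = "A", alt = "B",
                   maf = pmin(rowMeans(dosage) / 2, 1 - rowMeans(dosage) / 2),
                   quality = NA_real_, flipped = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(info)) info[[nm]] <- defaults[[nm]]
  }
  if (any(info$pos < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  colnames(dosage) <- samples
  rownames(dosage) <- info$rsid
  structure(list(info = info[c("rsid", "chrom", "pos", "ref", "alt", "maf",
                               "quality", "flipped")],
                 dosage = dosage, samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("Genotype panel: %d SNP(s) x %d individuals\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(utils::head(x$info, 5), row.names = FALSE)
  invisible(x)
}

as_genotype_data <- function(x) {
  if (inherits(x, "genotype_data")) return(x)
  if (is.matrix(x)) return(genotype_data(x))
  stop("expected a genotype_data object or a SNP x individual dosage matrix",
       call. = FALSE)
}

#' Subset a genotype panel by SNP index
#' @param gd A [genotype_data] object.
#' @param idx SNP row indices (or logical vector).
#' @return A [genotype_data] with the selected SNPs.
#' @export
subset_genotypes <- function(gd, idx) {
  gd <- as_genotype_data(gd)
  genotype_data(gd$dosage[idx, , drop = FALSE],
                gd$info[idx, , drop = FALSE], gd$samples)
}

# orient a dosage matrix to count the minor allele; returns flip flags
orient_minor <- function(dosage) {
  af <- rowMeans(dosage) / 2
  flip <- af > 0.5
  if (any(flip)) {
    dosage[flip, ] <- 2 - dosage[flip, , drop = FALSE]
    message(sum(flip), " SNP(s) flipped to minor-allele dosage")
  }
  list(dosage = dosage, maf = ifelse(flip, 1 - af, af), flipped = flip)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF records are converted to per-individual dosages using the `DS` format
#' field when present, otherwise by counting alternate alleles in `GT`.
#' Multiallelic records are skipped with a message. Dosages are oriented to
#' count the minor allele (flips are recorded in the `flipped` column). The
#' dosage-TSV layout is the one written by [write_genotypes()]: columns
#' `rsid`, `chrom`, `pos`, `ref`, `alt`, `quality`, then one column per
#' individual.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param samples Optional sample ids to select and order by; unknown ids
#'   are an error listing the offenders.
#' @return A [genotype_data] object.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           samples = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- t(fx)  # single-record VCFs drop dimensions
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      message(sum(multi), " multiallelic record(s) skipped")
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    if (nrow(fix) == 0) stop("no biallelic records in VCF", call. = FALSE)
    fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(dim(fmt))) fmt <- t(fmt)
    if (all(is.na(fmt))) {
      gt <- vcfR::extract.gt(v, element = "GT")
      if (is.null(dim(gt))) gt <- t(gt)
      fmt <- apply(gt, c(1, 2), function(x) {
        if (is.na(x)) return(NA_real_)
        sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
      })
    }
    dosage <- matrix(as.numeric(fmt), nrow = nrow(fix),
                     dimnames = dimnames(fmt))
    ids <- colnames(dosage)
    quality <- rep(NA_real_, nrow(fix))
    info0 <- data.frame(rsid = fix$ID, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, quality = quality)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    meta <- c("rsid", "chrom", "pos", "ref", "alt", "quality")
    have <- intersect(meta, names(tab))
    if (!"rsid" %in% have) stop("dosage TSV must have an 'rsid' column",
                                call. = FALSE)
    ids <- setdiff(names(tab), meta)
    dosage <- as.matrix(tab[ids])
    colnames(dosage) <- ids
    info0 <- tab[have]
  }
  if (anyNA(dosage)) {
    mu <- rowMeans(dosage, na.rm = TRUE)
    na_idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[na_idx] <- mu[na_idx[, 1]]
    message(nrow(na_idx), " missing dosage(s) mean-imputed")
  }
  if (!is.null(samples)) {
    unknown <- setdiff(samples, ids)
    if (length(unknown)) {
      stop("sample id(s) not present in genotype file: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    dosage <- dosage[, samples, drop = FALSE]
    ids <- samples
  }
  om <- orient_minor(dosage)
  info0$maf <- om$maf
  info0$flipped <- om$flipped
  genotype_data(om$dosage, info0, ids)
}

#' Write genotypes as a dosage TSV
#'
#' Rows are SNPs, columns are `rsid`, `chrom`, `pos`, `ref`, `alt`,
#' `quality`, then one dosage column per individual.
#'
#' @param gd A [genotype_data] object.
#' @param path Output path.
#' @export
write_genotypes <- function(gd, path) {
  gd <- as_genotype_data(gd)
  tab <- cbind(gd$info[c("rsid", "chrom", "pos", "ref", "alt", "quality")],
               as.data.frame(gd$dosage, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a phenotype table
#'
#' Tab-separated with columns `id`, `stratum`, covariates, then
#' `<pheno>_pre` / `<pheno>_post` per phenotype — the layout produced by
#' [simulate_trial()] and consumed by [prepare_phenotypes()].
#'
#' @param pheno Data frame (e.g. `simulate_trial(...)$pheno`).
#' @param path File path.
#' @return `write_phenotypes` returns the path invisibly; `read_phenotypes`
#'   the data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a scan result table
#'
#' Fixed, documented column order: `rsid`, `chrom`, `pos`, `ref`, `alt`,
#' `maf`, `quality`, `log10_bf_av`, `log10_bf_all`, `log10_bf_uni`, the
#' per-phenotype univariate `log10` BFs, then the per-phenotype posterior
#' triplets. Floats are written with 6 significant digits; a write-then-read
#' round trip reproduces the table at that precision.
#'
#' @param scan A `"scan_result"` data frame from [full_scan()].
#' @param path File path.
#' @return `write_scan_results` returns the path invisibly;
#'   `read_scan_results` the table (class `"scan_result"`).
#' @export
write_scan_results <- function(scan, path) {
  out <- as.data.frame(scan)
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("pos", "n")
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Serialize a truth specification to JSON
#'
#' Stores all generating parameters of a [truth_spec()] (matrices as nested
#' arrays) so a synthetic dataset can be regenerated exactly.
#'
#' @param truth A `"truth_spec"`.
#' @param path File path.
#' @export
write_truth_spec <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to serialize truth specs",
         call. = FALSE)
  }
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
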