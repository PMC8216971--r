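#' Missing-genotype sentinel
#'
#' Dosage matrices code missing genotypes as `NA_integer_`; this constant is
#' exported so calling code never hard-codes the sentinel.
#' @export
MISSING <- NA_integer_

#' Construct a genotype dataset
#'
#' The central container of the package: a sample x locus matrix of
#' alternative-allele dosages (0, 1, 2 or `NA` for missing) together with
#' locus metadata and a provenance label per sample. Invariants (matching
#' dimensions, complete provenance labels, dosage range) are checked on
#' construction and re-checked after every filtering step.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of sample ids (rownames of `dosage`).
#' @param loci data.frame with columns `id`, `scaffold`, `position`, `ref`,
#'   `alt` describing each locus (one row per column of `dosage`).
#' @param provenance_of named character vector mapping sample id to
#'   provenance id.
#' @return An object of class `GenotypeDataset`.
#' @export
genotype_dataset <- function(dosage, samples, loci, provenance_of) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples))
    stop("dosage rows (", nrow(dosage), ") != number of samples (",
         length(samples), ")")
  if (ncol(dosage) != nrow(loci))
    stop("dosage columns (", ncol(dosage), ") != number of loci (",
         nrow(loci), ")")
  req <- c("id", "scaffold", "position", "ref", "alt")
  if (!all(req %in% names(loci)))
    stop("loci table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(loci$id))
    stop("duplicate locus ids")
  if (anyDuplicated(paste(loci$scaffold, loci$position)))
    stop("duplicate (scaffold, position) pairs")
  if (any(loci$ref == loci$alt))
    stop("ref and alt alleles must differ")
  if (!all(samples %in% names(provenance_of)))
    stop("samples without a provenance label: ",
         paste(setdiff(samples, names(provenance_of)), collapse = ", "))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- samples
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage,
                 samples = as.character(samples),
                 loci = as.data.frame(loci, stringsAsFactors = FALSE),
                 provenance_of = provenance_of[samples]),
            class = "GenotypeDataset")
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat("GenotypeDataset:", length(x$samples), "samples x", nrow(x$loci),
      "loci;", length(unique(x$provenance_of)), "provenances;",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "missing\n")
  invisible(x)
}

#' @export
dim.GenotypeDataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset by samples and/or loci
#'
#' @param ds a `GenotypeDataset`.
#' @param samples sample ids or logical/integer index to keep (default all).
#' @param loci locus ids or logical/integer index to keep (default all).
#' @return the subsetted `GenotypeDataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(ds$samples) else
    if (is.character(samples)) match(samples, ds$samples) else samples
  li <- if (is.null(loci)) seq_len(nrow(ds$loci)) else
    if (is.character(loci)) match(loci, ds$loci$id) else loci
  if (anyNA(si)) stop("unknown sample id in subset")
  if (is.numeric(li) && anyNA(li)) stop("unknown locus id in subset")
  genotype_dataset(ds$dosage[si, li, drop = FALSE],
                   ds$samples[si],
                   ds$loci[li, , drop = FALSE],
                   ds$provenance_of)
}

#' Per-locus alternative-allele frequency
#'
#' Computed on non-missing calls only.
#' @param ds a `GenotypeDataset`.
#' @return numeric vector, one frequency per locus (NaN if fully missing).
#' @export
alt_freq <- function(ds) {
  colMeans(ds$dosage, na.rm = TRUE) / 2
}

#' Per-locus minor allele frequency
#'
#' The minor allele is recomputed per dataset (not assumed to be ALT).
#' @param ds a `GenotypeDataset`.
#' @return numeric vector of MAFs.
#' @export
minor_allele_freq <- function(ds) {
  p <- alt_freq(ds)
  pmin(p, 1 - p)
}

# Parse one GT string vector into dosages. "/" and "|" are equivalent;
# half-calls count as missing.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  a <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1,\\2", gt)
  ok <- grepl(",", a, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  if (any(ok)) {
    parts <- strsplit(a[ok], ",", fixed = TRUE)
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, `[`, "", 2L)
    full <- a1 != "." & a2 != "."
    d <- rep(NA_integer_, sum(ok))
    d[full] <- as.integer(a1[full]) + as.integer(a2[full])
    out[ok] <- d
  }
  out
}

#' Read a VCF file into a genotype dataset
#'
#' Reads a VCF v4.x file (GT field required), keeping biallelic SNP records
#' only. Dosage is the count of alternative alleles; `./.` and half-calls
#' become missing. Multi-allelic and non-SNP records are dropped and the
#' count is reported via `message()`.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param provenance_of optional named character vector mapping sample id to
#'   provenance; by default the provenance is the sample-id prefix before the
#'   last underscore (the convention used by [write_vcf()] fixtures), or the
#'   sample id itself when there is no underscore.
#' @return a `GenotypeDataset`.
#' @export
read_vcf <- function(path, provenance_of = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_vcf_lines(path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gt <- gt[keep, , drop = FALSE]
  loci <- data.frame(
    id = names(rr),
    scaffold = as.character(GenomeInfoDb::seqnames(rr)),
    position = BiocGenerics::start(rr),
    ref = ref[keep],
    alt = alt1[keep],
    stringsAsFactors = FALSE)
  samples <- colnames(gt)
  dosage <- matrix(.gt_to_dosage(as.vector(gt)), nrow = nrow(gt))
  dosage <- t(dosage)  # samples x loci
  if (is.null(provenance_of)) {
    prov <- ifelse(grepl("_", samples),
                   sub("_[^_]*$", "", samples), samples)
    provenance_of <- stats::setNames(prov, samples)
  }
  genotype_dataset(dosage, samples, loci, provenance_of)
}

# Cheap structural validation so malformed files fail with a line number.
.validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF (line 1): missing ##fileformat header in ", path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr))
    stop("malformed VCF: no #CHROM header line in ", path)
  ncol_hdr <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#"))
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields != ncol_hdr]
  if (length(bad))
    stop("malformed VCF (line ", bad[1], "): expected ", ncol_hdr,
         " tab-separated fields")
  invisible(TRUE)
}

#' Write a genotype dataset as a minimal GT-only VCF
#'
#' Inverse of [read_vcf()] on the supported subset (diploid biallelic SNPs,
#' unphased GT). Missing dosages are written as `./.`.
#'
#' @param ds a nonempty `GenotypeDataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  if (!length(ds$samples) || !nrow(ds$loci)) stop("empty dataset")
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=provscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t"))
  gt <- matrix("./.", nrow = nrow(ds$dosage), ncol = ncol(ds$dosage))
  ok <- !is.na(ds$dosage)
  gt[ok] <- gt_codes[ds$dosage[ok] + 1L]
  body <- paste(ds$loci$scaffold, ds$loci$position, ds$loci$id,
                ds$loci$ref, ds$loci$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read provenance, climate, ring-width and site-climate tables
#'
#' CSV schemas: `provenances.csv` (id, lat, lon, elev, n_samples optional);
#' `climate.csv` (provenance, then one column per climate variable);
#' `rings.csv` (tree, provenance, year, earlywood, latewood, total);
#' `site_climate.csv` (year, month, variable, value). Any path may be `NULL`
#' to skip that table.
#'
#' @param provenances_csv,climate_csv,rings_csv,site_climate_csv file paths.
#' @return a list with elements `provenances`, `climate`, `rings`,
#'   `site_climate` (those requested; others `NULL`).
#' @export
read_tables <- function(provenances_csv = NULL, climate_csv = NULL,
                        rings_csv = NULL, site_climate_csv = NULL) {
  out <- list(provenances = NULL, climate = NULL, rings = NULL,
              site_climate = NULL)
  if (!is.null(provenances_csv)) {
    pv <- utils::read.csv(provenances_csv, stringsAsFactors = FALSE)
    need <- c("id", "lat", "lon", "elev")
    if (!all(need %in% names(pv)))
      stop("provenances.csv missing column(s): ",
           paste(setdiff(need, names(pv)), collapse = ", "))
    if (any(pv$lat < -90 | pv$lat > 90))
      stop("latitude outside [-90, 90]")
    if (anyDuplicated(pv$id)) stop("duplicate provenance id")
    out$provenances <- pv
  }
  if (!is.null(climate_csv)) {
    cl <- utils::read.csv(climate_csv, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (!"provenance" %in% names(cl))
      stop("climate.csv missing column: provenance")
    m <- as.matrix(cl[, setdiff(names(cl), "provenance"), drop = FALSE])
    if (ncol(m) < 2) stop("climate table needs >= 2 variables")
    if (anyNA(m)) stop("climate table has missing cells")
    if (anyDuplicated(cl$provenance)) stop("duplicate provenance row")
    rownames(m) <- cl$provenance
    out$climate <- m
    if (!is.null(out$provenances) &&
        !setequal(rownames(m), out$provenances$id))
      stop("provenance mismatch between provenances.csv and climate.csv")
  }
  if (!is.null(rings_csv)) {
    rg <- utils::read.csv(rings_csv, stringsAsFactors = FALSE)
    need <- c("tree", "provenance", "year", "earlywood", "latewood", "total")
    if (!all(need %in% names(rg)))
      stop("rings.csv missing column(s): ",
           paste(setdiff(need, names(rg)), collapse = ", "))
    if (any(rg$earlywood < 0 | rg$latewood < 0 | rg$total < 0, na.rm = TRUE))
      stop("negative ring width")
    sp <- split(rg$year, rg$tree)
    noncon <- names(sp)[vapply(sp, function(y)
      any(diff(sort(y)) != 1L), logical(1))]
    if (length(noncon))
      stop("non-consecutive years for tree(s): ",
           paste(utils::head(noncon, 5), collapse = ", "))
    out$rings <- rg
  }
  if (!is.null(site_climate_csv)) {
    sc <- utils::read.csv(site_climate_csv, stringsAsFactors = FALSE)
    need <- c("year", "month", "variable", "value")
    if (!all(need %in% names(sc)))
      stop("site_climate.csv missing column(s): ",
           paste(setdiff(need, names(sc)), collapse = ", "))
    out$site_climate <- sc
  }
  out
}
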