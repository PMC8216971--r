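test_that("GT fields are coded as alt-allele dosage with missing sentinels", {
  f <- tempfile(fileext = ".vcf")
  write_text_vcf(f, c(
    "chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "chr1\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0/.\t0/0"))
  ds <- read_vcf(f)
  expect_equal(unname(ds$dosage[, "s1"]), c(0L, 1L, 2L, NA))
  # phased and unphased are equivalent; half-calls are missing
  expect_equal(unname(ds$dosage[, "s2"]), c(1L, 2L, NA, 0L))
  expect_equal(ds$loci$position, c(100L, 200L))
  expect_equal(ds$loci$ref, c("A", "C"))
})

test_that("multi-allelic and non-SNP records are dropped with a message", {
  f <- tempfile(fileext = ".vcf")
  write_text_vcf(f, c(
    "chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t200\ts2\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t1/2\t0/0\t0/0",
    "chr1\t300\ts3\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/0",
    "chr1\t400\ts4\tCA\tC\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/0",
    "chr1\t500\ts5\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/0"))
  expect_message(ds <- read_vcf(f), "dropped 2")
  expect_equal(ds$loci$id, c("s1", "s3", "s5"))
})

test_that("write_vcf emits GT-only records and round trips exactly", {
  ds <- fixture_dataset()
  expect_equal(dim(ds), c(6L, 12L))
  f <- tempfile(fileext = ".vcf")
  write_vcf(ds, f)
  lines <- readLines(f)
  expect_true(any(grepl("\t0/0", lines)))
  # missing dosage -> ./.
  expect_equal(sum(grepl("\\./\\.", lines)), sum(apply(
    is.na(ds$dosage), 2, any)))
  ds2 <- read_vcf(f)
  expect_identical(unname(ds2$dosage), unname(ds$dosage))
  expect_equal(ds2$loci$position, ds$loci$position)
  expect_equal(unname(ds2$provenance_of), unname(ds$provenance_of))

  # explicit 2 samples x 1 locus example
  one <- genotype_dataset(matrix(c(0L, 2L), 2, 1), c("a_1", "b_1"),
                          data.frame(id = "x", scaffold = "s", position = 1L,
                                     ref = "A", alt = "T"),
                          c(a_1 = "a", b_1 = "b"))
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(one, f2)
  body <- readLines(f2)
  body <- body[!startsWith(body, "#")]
  expect_match(body, "0/0\t1/1")
})

test_that("malformed VCF fails with the offending line number", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t100\tx\tA\tG\t.\tPASS\t.\tGT\t0/0",
    "chr1\t200\tbroken line without tabs"), f)
  expect_error(read_vcf(f), "line 4")
  expect_error(read_vcf(tempfile()), "no such file")
  f2 <- tempfile(fileext = ".vcf")
  writeLines("not a vcf", f2)
  expect_error(read_vcf(f2), "fileformat")
})

test_that("dataset invariants are enforced on construction", {
  loci <- data.frame(id = c("a", "b"), scaffold = "s", position = 1:2,
                     ref = "A", alt = "T")
  d <- matrix(0L, 2, 2)
  prov <- c(s1 = "p", s2 = "p")
  expect_silent(genotype_dataset(d, c("s1", "s2"), loci, prov))
  expect_error(genotype_dataset(d[1, , drop = FALSE], c("s1", "s2"), loci,
                                prov), "rows")
  expect_error(genotype_dataset(d, c("s1", "s3"), loci, prov), "provenance")
  bad <- loci; bad$alt <- c("A", "T")
  expect_error(genotype_dataset(d, c("s1", "s2"), bad, prov), "differ")
  dup <- loci; dup$position <- c(1L, 1L)
  expect_error(genotype_dataset(d, c("s1", "s2"), dup, prov), "duplicate")
  d3 <- d; d3[1, 1] <- 3L
  expect_error(genotype_dataset(d3, c("s1", "s2"), loci, prov), "dosages")
})

test_that("read_tables enforces schemas and totals add up", {
  # a 16-provenance table whose sample sizes sum to 178
  n <- c(10, 13, 10, 9, 11, 13, 10, 11, 10, 11, 9, 13, 15, 12, 11, 10)
  expect_equal(sum(n), 178)
  pv <- data.frame(id = sprintf("P%02d", 1:16),
                   lat = seq(44.4, 54.5, length.out = 16),
                   lon = seq(-124.9, -117.0, length.out = 16),
                   elev = rep(c(150, 600, 900, 750), 4),
                   n_samples = n)
  fp <- tempfile(fileext = ".csv"); write.csv(pv, fp, row.names = FALSE)
  cl <- matrix(rnorm(16 * 247), 16,
               dimnames = list(NULL, paste0("v", 1:247)))
  fc <- tempfile(fileext = ".csv")
  write.csv(data.frame(provenance = pv$id, cl, check.names = FALSE), fc,
            row.names = FALSE)
  tabs <- read_tables(provenances_csv = fp, climate_csv = fc)
  expect_equal(sum(tabs$provenances$n_samples), 178)
  expect_equal(dim(tabs$climate), c(16L, 247L))

  # negative ring width is rejected
  rg <- data.frame(tree = "t1", provenance = "P01", year = 2000:2002,
                   earlywood = c(1, -0.2, 1), latewood = 0.5, total = 1.5)
  fr <- tempfile(fileext = ".csv"); write.csv(rg, fr, row.names = FALSE)
  expect_error(read_tables(rings_csv = fr), "negative")
  rg2 <- data.frame(tree = "t1", provenance = "P01",
                    year = c(2000, 2001, 2003), earlywood = 1,
                    latewood = 0.5, total = 1.5)
  fr2 <- tempfile(fileext = ".csv"); write.csv(rg2, fr2, row.names = FALSE)
  expect_error(read_tables(rings_csv = fr2), "non-consecutive")

  # latitude range and provenance mismatch
  pv_bad <- pv; pv_bad$lat[1] <- 95
  fb <- tempfile(fileext = ".csv"); write.csv(pv_bad, fb, row.names = FALSE)
  expect_error(read_tables(provenances_csv = fb), "latitude")
  pv2 <- pv; pv2$id[1] <- "XX"
  f2 <- tempfile(fileext = ".csv"); write.csv(pv2, f2, row.names = FALSE)
  expect_error(read_tables(provenances_csv = f2, climate_csv = fc),
               "mismatch")
})

test_that("subsetting preserves invariants and labels", {
  ds <- fixture_dataset()
  sub <- subset_dataset(ds, samples = ds$samples[1:3],
                        loci = ds$loci$id[c(2, 5)])
  expect_equal(dim(sub), c(3L, 2L))
  expect_equal(sub$loci$id, ds$loci$id[c(2, 5)])
  expect_error(subset_dataset(ds, samples = "nope"), "unknown sample")
  p <- alt_freq(ds)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  expect_true(all(minor_allele_freq(ds) <= 0.5, na.rm = TRUE))
})
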