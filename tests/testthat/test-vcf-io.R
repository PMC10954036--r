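vcf_text <- function(records, samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("phased GT fields transcribe directly into haplotypes and dosages", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text("s1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
                      c("a", "b")), f)
  d <- read_vcf(f)
  expect_equal(as.vector(d$haplotypes$alleles), c(0L, 1L, 1L, 1L))
  expect_equal(unname(d$genotypes[1, ]), c(1L, 2L))
  expect_equal(d$variants$pos, 100L)
  expect_equal(d$variants$site_index, 0L)
})

test_that("multi-allelic and indel records are skipped with a count", {
  recs <- sprintf("s1\t%d\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1", (1:10) * 10)
  recs[4] <- "s1\t40\t.\tA\tT,G\t.\tPASS\t.\tGT\t0|1\t1|2"
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(recs, c("a", "b")), f)
  expect_message(d <- read_vcf(f), "skipped 1")
  expect_equal(nrow(d$variants), 9L)
  expect_equal(d$n_skipped, 1L)
  expect_false(40L %in% d$variants$pos)
})

test_that("unphased or missing genotypes are an error naming the offender", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(c("s1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
                        "s1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0|1\t1/1"),
                      c("a", "b")), f)
  expect_error(read_vcf(f), "b.*s1:20|s1:20.*b")
  expect_silent(suppressMessages(d <- read_vcf(f, haplotypes = FALSE)))
  expect_equal(unname(d$genotypes[, "b"]), c(2L, 2L))
})

test_that("an empty VCF is an error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(character(0), c("a", "b")), f)
  expect_error(suppressWarnings(read_vcf(f)))
})

test_that("write/read round-trip reproduces a simulated 500-site matrix, and
           an independent text re-parse agrees", {
  sim <- simulate_dataset(sim_config(seed = 5, n_diploids = 2,
                                     scaffolds = c(sA = 5e5),
                                     snp_per_mb = 1000, sweep = NULL))
  expect_equal(nrow(sim$variants), 500L)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(f, sim$variants, sim$haplotypes, sim$scaffolds)
  back <- read_vcf(f)
  expect_identical(unname(back$haplotypes$alleles),
                   unname(sim$haplotypes$alleles))
  expect_identical(back$variants$pos, sim$variants$pos)
  expect_equal(back$scaffolds, sim$scaffolds)
  # independent re-parse: raw text, no vcfR
  ln <- readLines(f)
  body <- ln[!startsWith(ln, "#")]
  gt <- do.call(rbind, lapply(strsplit(body, "\t"), function(x) x[10:13]))
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt))
  redone <- matrix(0L, 8, nrow(gt))
  redone[seq(1, 8, 2), ] <- t(a1)
  redone[seq(2, 8, 2), ] <- t(a2)
  expect_identical(redone, unname(sim$haplotypes$alleles))
})

test_that("popmap contracts: ordering, coverage, extra labels, conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tPAG", "s2\tPAG", "s3\tGO", "s4\tGO"), f)
  pm <- read_popmap(f)
  expect_equal(attr(pm, "populations"), c("PAG", "GO"))
  expect_error(read_popmap(f, vcf_samples = c("s1", "s2", "s3", "s4", "s9")),
               "s9")
  writeLines(c("s1\tPAG", "s2\tPAG", "s3\tGO", "s4\tGO", "s5\tIO", "s6\tIO"),
             f)
  expect_message(pm2 <- read_popmap(f, pops = c("PAG", "GO")), "dropping 2")
  expect_equal(nrow(pm2), 4L)
  writeLines(c("s1\tPAG", "s1\tGO", "s2\tPAG", "s3\tGO"), f)
  expect_error(read_popmap(f), "conflicting")
})

test_that("region files honor their coordinate dialect and invert exactly", {
  reg <- data.frame(scaffold = "scaffold_27", start = 1481656L,
                    end = 1621714L, stringsAsFactors = FALSE)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fbed <- withr::local_tempfile(fileext = ".bed")
  write_regions(reg, ftsv, dialect = "tsv")
  write_regions(reg, fbed, dialect = "bed")
  tsv <- read.table(ftsv, header = TRUE, skip = 1, sep = "\t")
  bed <- read.table(fbed, header = TRUE, skip = 1, sep = "\t")
  expect_equal(c(tsv$start, tsv$end), c(1481656L, 1621714L))
  expect_equal(c(bed$start, bed$end), c(1481655L, 1621714L))
  # mutual inversion through the reader
  expect_equal(read_regions(fbed)$start, reg$start)
  expect_equal(read_regions(ftsv)$start, reg$start)
  # empty list -> header-only file
  f0 <- withr::local_tempfile(fileext = ".tsv")
  write_regions(reg[0, ], f0)
  expect_length(readLines(f0), 2L)
  expect_error(write_regions(data.frame(scaffold = "x", start = 5, end = 2),
                             ftsv), "start > end")
})

test_that("scaffold length table validates against the variant table", {
  v <- toy_variants(c(100L, 5000L))
  expect_error(check_scaffolds <- sweepscanr:::check_scaffolds(c(other = 1e4), v),
               "without a length")
  expect_error(sweepscanr:::check_scaffolds(c(s1 = 2000), v), "smaller than")
  expect_true(sweepscanr:::check_scaffolds(c(s1 = 1e4), v))
})
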