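test_that("mutation table reader builds tumors with correct burdens", {
  maf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "tumor_id\tgene\thgvs_c\thgvs_p\tvariant_class",
    "T1\tTP53\tc.524G>A\tp.R175H\tsubstitution",
    "T1\tKRAS\tc.35G>T\tp.G12V\tsubstitution",
    "T2\tPTEN\tc.800delA\tp.K267Rfs*9\tdeletion"
  ), maf)
  coh <- read_mutation_table(maf)
  expect_s3_class(coh, "msi_cohort")
  expect_equal(nrow(coh$samples), 2)
  b <- tumor_burden(coh)
  expect_equal(b$burden[b$tumor_id == "T1"], 2L)
  expect_equal(b$burden[b$tumor_id == "T2"], 1L)
})

test_that("a deletion row yields a deletion-class mutation and class clashes are caught", {
  muts <- tibble::tibble(tumor_id = "218", gene = "PTEN",
                         hgvs_c = "c.800delA", hgvs_p = "p.K267Rfs*9")
  coh <- cohort(muts)
  expect_equal(coh$mutations$variant_class, "deletion")

  muts$variant_class <- "substitution"
  expect_error(cohort(muts), "inconsistent")
})

test_that("zero-mutation tumors ride in via the samples side-table", {
  maf <- tempfile(fileext = ".tsv")
  smp <- tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene\thgvs_c\tvariant_class",
               "T1\tTP53\tc.524G>A\tsubstitution"), maf)
  writeLines(c("tumor_id\tmsi_status", "T1\tMSS", "T2\tMSI-H"), smp)
  coh <- read_mutation_table(maf, samples_path = smp)
  expect_equal(nrow(coh$samples), 2)
  b <- tumor_burden(coh)
  expect_equal(b$burden[b$tumor_id == "T2"], 0L)
  expect_equal(unname(group_sizes(coh)["MSI_H"]), 1L)
})

test_that("unparseable rows are rejected and reported, not silently dropped", {
  maf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "tumor_id\tgene\thgvs_c\tvariant_class",
    "T1\tTP53\tc.524G>A\tsubstitution",
    "T1\tKRAS\t\tsubstitution",                 # no HGVS at all
    "T2\tPTEN\tc.800delA\tnot_a_class"
  ), maf)
  expect_message(coh <- read_mutation_table(maf), "rejected 2")
  expect_equal(nrow(attr(coh, "rejected")), 2)
  expect_equal(nrow(coh$mutations), 1)
})

test_that("missing required columns and duplicate rows are format/validation errors", {
  maf <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tgene", "T1\tTP53"), maf)
  expect_error(read_mutation_table(maf), "format error")

  dup <- tibble::tibble(tumor_id = c("T1", "T1"), gene = c("PTEN", "PTEN"),
                        hgvs_c = c("c.800delA", "c.800delA"),
                        variant_class = "deletion")
  expect_error(cohort(dup), "duplicate")
})

test_that("MSI-Low collapses into MSS", {
  coh <- cohort(tibble::tibble(tumor_id = "T1", gene = "APC",
                               hgvs_c = "c.100C>T"),
                samples = tibble::tibble(tumor_id = "T1",
                                         msi_status = "MSI-L"))
  expect_equal(coh$samples$msi_status, "MSS")
})

test_that("write/read round trip preserves every mutation tuple and burden sums", {
  sim <- generate_cohort(simulation_params(n_mss = 15, n_msih = 8, seed = 42))
  coh <- sim$cohort
  maf <- tempfile(fileext = ".tsv")
  smp <- tempfile(fileext = ".tsv")
  write_mutation_table(coh, maf, samples_path = smp)
  back <- read_mutation_table(maf, samples_path = smp)

  key <- function(x) {
    sort(paste(x$mutations$tumor_id, x$mutations$gene,
               x$mutations$hgvs_c, x$mutations$variant_class))
  }
  expect_identical(key(back), key(coh))
  expect_identical(sort(back$samples$tumor_id), sort(coh$samples$tumor_id))
  # mutation counts over tumors account for every parsed row
  expect_equal(sum(tumor_burden(back)$burden), nrow(back$mutations))
})

test_that("minimal VCF reader assigns records to carrier samples", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T1", "T2", sep = "\t"),
    paste("10", "100", ".", "A", "C", ".", "PASS",
          "GENE=PTEN;HGVSC=c.974T>G;HGVSP=p.L325R", "GT", "0/1", "0/0",
          sep = "\t"),
    paste("10", "200", ".", "CA", "C", ".", "PASS",
          "GENE=PTEN;HGVSC=c.800delA;HGVSP=p.K267Rfs*9", "GT", "0/0", "1/1",
          sep = "\t")
  ), vcf)
  coh <- read_minimal_vcf(vcf)
  expect_equal(nrow(coh$mutations), 2)
  expect_equal(coh$mutations$tumor_id, c("T1", "T2"))
  expect_equal(coh$mutations$variant_class, c("substitution", "deletion"))
})

test_that("VCF without samples gives an empty cohort; symbolic ALTs are skipped with a warning", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"c\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("10", "100", ".", "A", "C", ".", "PASS",
          "GENE=PTEN;HGVSC=c.974T>G", sep = "\t")
  ), vcf)
  coh <- read_minimal_vcf(vcf)
  expect_equal(nrow(coh$mutations), 0)
  expect_equal(nrow(coh$samples), 0)

  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T1", sep = "\t"),
    paste("10", "100", ".", "A", "<DEL>", ".", "PASS", "GENE=PTEN", "GT",
          "0/1", sep = "\t"),
    paste("10", "200", ".", "A", "C", ".", "PASS",
          "GENE=PTEN;HGVSC=c.974T>G", "GT", "0/1", sep = "\t")
  ), vcf2)
  expect_warning(coh2 <- read_minimal_vcf(vcf2), "symbolic")
  expect_equal(nrow(coh2$mutations), 1)
})

test_that("cohort summary reports group sizes, separates unknowns, and flags non-evaluable sections", {
  sim <- generate_cohort(simulation_params(seed = 3))
  smry <- write_cohort_summary(sim$cohort)
  n_row <- smry[smry$section == "n", ]
  expect_equal(n_row$mss, 113)
  expect_equal(n_row$msih, 29)
  # unknown site tumors excluded from the site denominators
  site <- smry[smry$section == "site" & smry$level != "unknown", ]
  unk <- smry[smry$section == "site" & smry$level == "unknown", ]
  expect_equal(sum(site$mss) + sum(unk$mss), 113)

  one <- cohort(tibble::tibble(tumor_id = "T1", gene = "APC",
                               hgvs_c = "c.100C>T"),
                samples = tibble::tibble(tumor_id = "T1", msi_status = "MSS"))
  smry1 <- write_cohort_summary(one)
  expect_true(all(is.na(smry1$p_value)))

  all_unk <- cohort(
    tibble::tibble(tumor_id = c("T1", "T2"), gene = "APC",
                   hgvs_c = c("c.100C>T", "c.200C>T")),
    samples = tibble::tibble(tumor_id = c("T1", "T2"),
                             msi_status = c("MSS", "MSI_H"))
  )
  s2 <- write_cohort_summary(all_unk)
  expect_equal(s2$note[s2$section == "site"], "not evaluable")
})
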