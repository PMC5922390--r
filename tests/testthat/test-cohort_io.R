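test_that("variant table round-trips with validation against the panel", {
  panel <- gene_panel()
  df <- dplyr::bind_rows(
    make_variant(patient_id = "P1"),
    make_variant(patient_id = "P2", pos = 55249080L, normal_alt = 15L),
    make_variant(patient_id = "P3", gene = "KRAS", contig = "12", pos = 25358200L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(df, -origin), path)
  back <- read_variant_table(path, panel)
  expect_equal(nrow(back), 3)
  expect_true(all(back$origin == "unassigned"))
  expect_equal(back$tumor_alt, df$tumor_alt)

  bad_gene <- dplyr::mutate(df, gene = c("EGFR", "TP53", "KRAS"))
  readr::write_tsv(bad_gene, path)
  expect_error(read_variant_table(path, panel), "TP53")

  bad_counts <- dplyr::mutate(df, tumor_alt = c(99L, 24L, 24L))
  readr::write_tsv(bad_counts, path)
  expect_error(read_variant_table(path, panel), "depth")

  non_int <- dplyr::mutate(df, tumor_depth = c(60.5, 60, 60))
  readr::write_tsv(non_int, path)
  expect_error(read_variant_table(path, panel), "integer")
})

test_that("paired VCF input splits multi-allelics, restricts to the panel, and joins normal evidence", {
  td <- withr::local_tempdir()
  tumor <- write_mini_vcf(file.path(td, "t.vcf"), data.frame(
    chrom = c("7", "7", "12", "1"),
    pos = c(55249071, 55249100, 25358200, 5),
    ref = c("C", "G", "A", "T"), alt = c("T", "T,A", "G", "A"),
    ad = c("40,20", "30,10,6", "35,12", "50,10"),
    conseq = c("missense", "missense", "nonsense", "missense")
  ), sample = "TUM")
  normal <- write_mini_vcf(file.path(td, "n.vcf"), data.frame(
    chrom = "7", pos = 55249071, ref = "C", alt = "T",
    ad = "15,15", conseq = "missense"
  ), sample = "NOR")
  v <- read_paired_vcf(tumor, normal)
  # chr1:5 is outside every panel interval
  expect_equal(nrow(v), 4)
  expect_false(any(v$pos == 5))
  # multi-allelic record became two rows sharing contig/pos/ref
  multi <- dplyr::filter(v, pos == 55249100)
  expect_equal(sort(multi$alt), c("A", "T"))
  expect_equal(unique(multi$ref), "G")
  # site present in normal carries its evidence; absent sites default to 0/0
  hit <- dplyr::filter(v, pos == 55249071)
  expect_equal(hit$normal_alt, 15L)
  expect_equal(hit$normal_depth, 30L)
  expect_true(all(dplyr::filter(v, pos != 55249071)$normal_depth == 0L))
  expect_true(all(v$origin == "unassigned"))
  expect_equal(dplyr::filter(v, contig == "12")$gene, "KRAS")
})

test_that("contig naming mismatch between tumor and normal is an explicit error", {
  td <- withr::local_tempdir()
  tumor <- write_mini_vcf(file.path(td, "t.vcf"), data.frame(
    chrom = "chr7", pos = 55249071, ref = "C", alt = "T",
    ad = "40,20", conseq = "missense"
  ))
  normal <- write_mini_vcf(file.path(td, "n.vcf"), data.frame(
    chrom = "7", pos = 55249071, ref = "C", alt = "T",
    ad = "15,15", conseq = "missense"
  ))
  expect_error(read_paired_vcf(tumor, normal), "chr")
  v <- read_paired_vcf(tumor, normal, chr_normalize = TRUE)
  expect_equal(v$normal_alt, 15L)
})

test_that("VCF and flat-table input produce identical variant lists for equivalent content", {
  td <- withr::local_tempdir()
  tumor <- write_mini_vcf(file.path(td, "t.vcf"), data.frame(
    chrom = "7", pos = 55249071, ref = "C", alt = "T",
    ad = "40,20", conseq = "missense"
  ), sample = "P1")
  normal <- write_mini_vcf(file.path(td, "n.vcf"), data.frame(
    chrom = "7", pos = 55249071, ref = "C", alt = "T",
    ad = "15,15", conseq = "missense"
  ), sample = "P1")
  from_vcf <- read_paired_vcf(tumor, normal)
  flat <- make_variant(
    patient_id = "P1", tumor_depth = 60L, tumor_alt = 20L,
    normal_depth = 30L, normal_alt = 15L
  )
  tsv <- file.path(td, "v.tsv")
  readr::write_tsv(dplyr::select(flat, -origin), tsv)
  from_table <- read_variant_table(tsv)
  expect_equal(as.data.frame(from_vcf), as.data.frame(from_table))
})

test_that("annotation table enforces key uniqueness and the AF/database invariant", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ok <- dplyr::bind_rows(
    make_annotation(pos = 1L, population_af = 0.25),
    make_annotation(pos = 2L, population_af = NA_real_),
    make_annotation(pos = 3L, in_database = FALSE)
  )
  readr::write_tsv(dplyr::mutate(ok, in_database = as.integer(in_database)), path, na = "")
  ann <- read_annotation_table(path)
  expect_equal(ann$population_af, c(0.25, NA, NA))
  expect_equal(ann$in_database, c(TRUE, TRUE, FALSE))

  dup <- dplyr::bind_rows(make_annotation(pos = 1L), make_annotation(pos = 1L))
  readr::write_tsv(dplyr::mutate(dup, in_database = as.integer(in_database)), path, na = "")
  expect_error(read_annotation_table(path), "duplicate")

  bad_af <- make_annotation(pos = 1L, population_af = 1.5)
  readr::write_tsv(dplyr::mutate(bad_af, in_database = as.integer(in_database)), path, na = "")
  expect_error(read_annotation_table(path), "\\[0, 1\\]")

  orphan <- make_annotation(pos = 1L, in_database = FALSE, population_af = 0.1)
  readr::write_tsv(dplyr::mutate(orphan, in_database = as.integer(in_database)), path, na = "")
  expect_error(read_annotation_table(path), "in_database")
})

test_that("a site missing from the annotation table means not-in-database, AF absent", {
  variants <- make_variant(origin = "germline")
  ann <- make_annotation(pos = 999L) # different site
  f <- apply_filter(variants, ann, filter_regime("database_membership"))
  expect_true(f$retained)
  f2 <- apply_filter(variants, ann, filter_regime("af_threshold", af_cutoff = 0.001))
  expect_true(f2$retained)
})

test_that("report tables are byte-stable and an empty cohort writes headers only", {
  co <- generate_cohort(cohort_config(n_patients = 12, seed = 3))
  aud <- run_audit(co$variants, co$annotations, co$rna_counts)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report_tables(aud, d1)
  p2 <- write_report_tables(aud, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }
  # per-gene origin table round-trips to identical counts
  back <- readr::read_tsv(p1[["origin_table"]], show_col_types = FALSE)
  per_gene <- dplyr::filter(back, !startsWith(gene, "TOTAL"))
  expect_equal(per_gene$n_germline, aud$gene_counts$n_germline)
  expect_equal(per_gene$n_somatic, aud$gene_counts$n_somatic)
  expect_equal(per_gene$unique_sites, aud$gene_counts$unique_sites)

  # empty cohort: header rows only in the per-regime confusion table
  empty <- make_variant()[0, ]
  aud0 <- run_audit(empty, make_annotation()[0, ], patients = character(0))
  d0 <- withr::local_tempdir()
  p0 <- write_report_tables(aud0, d0)
  expect_equal(length(readLines(p0[["confusion"]])), 1L)
  expect_equal(length(readLines(p0[["burden"]])), 1L)
})
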