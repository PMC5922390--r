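#' Read a per-patient variant table
#'
#' Flat tab-separated alternative to paired VCF input: one row per observed
#' variant per patient with matched tumor/normal read evidence. An optional
#' `origin` column ("germline"/"somatic") is honoured for fixture mode
#' (trusted labels, e.g. synthetic truth); otherwise origin starts
#' `"unassigned"` until [classify_cohort()] runs.
#'
#' @param path Tab-separated UTF-8 file with header columns `patient_id`,
#'   `contig`, `pos`, `ref`, `alt`, `gene`, `consequence`, `tumor_depth`,
#'   `tumor_alt`, `normal_depth`, `normal_alt` (and optionally `origin`).
#' @param panel A [gene_panel()]; gene symbols are validated against it.
#' @return A tibble of observed variants (one row per patient-variant).
#' @export
read_variant_table <- function(path, panel = gene_panel()) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = "c", contig = "c", pos = "d", ref = "c", alt = "c",
      gene = "c", consequence = "c",
      tumor_depth = "d", tumor_alt = "d", normal_depth = "d", normal_alt = "d",
      .default = "c"
    ),
    progress = FALSE
  )
  count_cols <- c("pos", "tumor_depth", "tumor_alt", "normal_depth", "normal_alt")
  stop_cols(df, setdiff(variant_cols, "origin"), "variant table")
  for (cc in count_cols) {
    v <- df[[cc]]
    if (any(is.na(v)) || any(v != floor(v))) {
      abort(sprintf("column '%s' must be integer-valued with no missing entries", cc))
    }
    df[[cc]] <- as.integer(v)
  }
  if (!"origin" %in% names(df)) df$origin <- "unassigned"
  df <- select(df, dplyr::all_of(variant_cols))
  validate_variants(df, panel)
  as_tibble(df)
}

#' Read paired tumor/normal VCFs restricted to the panel footprint
#'
#' Reads two single-sample VCF v4.x files, keeps single-nucleotide variants
#' inside the panel intervals, splits multi-allelic records into one row per
#' alternate allele, and joins normal-sample evidence onto the tumor records
#' by exact site identity (contig, position, ref, alt). A tumor variant absent
#' from the normal file gets `normal_alt = 0` and `normal_depth = 0` (no
#' normal record means no measured normal coverage is carried). Indels are
#' dropped with a message giving the count.
#'
#' Depth and alt support are taken from the per-sample `AD` field when
#' present (depth = sum of allele depths), else from `DP` with alt support 0.
#' Consequence is consumed, not computed: supply the INFO tag naming it via
#' `consequence_field`; records without it get `"other"` (and are then
#' excluded from downstream tallies, which use missense/nonsense only).
#'
#' @param tumor_path,normal_path Paths to the tumor and normal VCF files.
#' @param panel A [gene_panel()].
#' @param consequence_field INFO tag holding the coding consequence
#'   (values among "missense", "nonsense", anything else -> "other").
#' @param chr_normalize If `TRUE`, a bare/"chr"-prefixed contig naming
#'   difference between the two files is reconciled by stripping the prefix.
#'   Default `FALSE`: a naming mismatch is an error, never silently coerced.
#' @return A tibble of observed variants with `origin = "unassigned"`.
#' @export
read_paired_vcf <- function(tumor_path, normal_path, panel = gene_panel(),
                            consequence_field = "CONSEQ",
                            chr_normalize = FALSE) {
  tumor <- read_one_vcf(tumor_path, consequence_field)
  normal <- read_one_vcf(normal_path, consequence_field)
  t_chr <- any(grepl("^chr", tumor$contig))
  n_chr <- any(grepl("^chr", normal$contig))
  if (nrow(tumor) > 0 && nrow(normal) > 0 && t_chr != n_chr) {
    if (!chr_normalize) {
      abort(paste(
        "contig naming mismatch between tumor and normal VCFs",
        "(one uses a 'chr' prefix, the other does not);",
        "set chr_normalize = TRUE to strip the prefix explicitly"
      ))
    }
    tumor$contig <- sub("^chr", "", tumor$contig)
    normal$contig <- sub("^chr", "", normal$contig)
  }
  # Restrict to the panel footprint and attach the gene symbol by overlap.
  gr <- panel_granges(panel)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(tumor$contig, IRanges::IRanges(tumor$pos, tumor$pos)),
    gr
  )
  tumor <- tumor[S4Vectors::queryHits(hits), , drop = FALSE]
  tumor$gene <- gr$gene[S4Vectors::subjectHits(hits)]
  normal <- rename(normal,
    normal_depth = "depth", normal_alt = "alt_reads"
  )
  out <- tumor |>
    rename(tumor_depth = "depth", tumor_alt = "alt_reads") |>
    left_join(
      select(normal, "contig", "pos", "ref", "alt", "normal_depth", "normal_alt"),
      by = c("contig", "pos", "ref", "alt")
    ) |>
    mutate(
      normal_depth = if_else(is.na(.data$normal_depth), 0L, .data$normal_depth),
      normal_alt = if_else(is.na(.data$normal_alt), 0L, .data$normal_alt),
      origin = "unassigned"
    ) |>
    select(dplyr::all_of(variant_cols))
  validate_variants(out, panel)
  out
}

# Parse one single-sample VCF into a flat SNV tibble. Multi-allelic records
# are split by VariantAnnotation::expand(); indels are counted and dropped.
read_one_vcf <- function(path, consequence_field) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) {
      abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
    }
  )
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L & alt %in% c("A", "C", "G", "T")
  n_indel <- sum(!is_snv)
  if (n_indel > 0) {
    inform(sprintf("%s: dropped %d non-SNV record(s) (SNV-only analysis)", basename(path), n_indel))
  }
  geno <- VariantAnnotation::geno(vcf)
  n <- length(rr)
  sample_idx <- 1L
  depth <- rep(0L, n)
  alt_reads <- rep(0L, n)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    # after expand(), AD collapses to (ref, this alt) per record: either a
    # 3-d array [record, sample, 2] or a list matrix for ragged input
    if (is.array(ad) && length(dim(ad)) == 3) {
      ref_d <- ad[, sample_idx, 1]
      alt_d <- ad[, sample_idx, 2]
      depth <- as.integer(if_else(is.na(ref_d), 0L, ref_d) +
        if_else(is.na(alt_d), 0L, alt_d))
      alt_reads <- as.integer(if_else(is.na(alt_d), 0L, alt_d))
    } else {
      for (i in seq_len(n)) {
        adi <- ad[i, sample_idx][[1]]
        if (!all(is.na(adi))) {
          depth[i] <- sum(adi, na.rm = TRUE)
          alt_reads[i] <- adi[length(adi)]
        }
      }
    }
  } else if ("DP" %in% names(geno)) {
    dp <- geno$DP[, sample_idx]
    depth <- if_else(is.na(dp), 0L, as.integer(dp))
  }
  info <- VariantAnnotation::info(vcf)
  consequence <- rep("other", n)
  if (consequence_field %in% names(info)) {
    val <- as.character(info[[consequence_field]])
    consequence <- if_else(val %in% c("missense", "nonsense"), val, "other")
  }
  tibble(
    patient_id = colnames(vcf)[sample_idx] %||% "sample",
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    consequence = consequence,
    depth = as.integer(depth), alt_reads = as.integer(alt_reads)
  )[is_snv, , drop = FALSE]
}

#' Read a population annotation table
#'
#' Loads per-site database membership (dbSNP-style) and optional population
#' allele frequency. An absent frequency is not a frequency of zero: the
#' rescue filter rule hinges on sites that are catalogued but carry no
#' reported frequency, so the distinction is preserved (`NA` = absent).
#'
#' @param path Tab-separated file with columns `contig`, `pos`, `ref`, `alt`,
#'   `in_database` (0/1 or TRUE/FALSE), `population_af` (empty = absent).
#' @return A tibble keyed by site with columns `contig`, `pos`, `ref`, `alt`,
#'   `in_database` (logical), `population_af` (double, `NA` = absent). Sites
#'   missing from the table mean "not in database, frequency absent".
#' @export
read_annotation_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      contig = "c", pos = "i", ref = "c", alt = "c",
      in_database = "l", population_af = "d"
    ),
    progress = FALSE
  )
  stop_cols(df, c("contig", "pos", "ref", "alt", "in_database", "population_af"),
    "annotation table")
  k <- key_str(df$contig, df$pos, df$ref, df$alt)
  if (anyDuplicated(k)) {
    abort(sprintf(
      "duplicate annotation key(s): %s",
      paste(unique(k[duplicated(k)]), collapse = ", ")
    ))
  }
  af <- df$population_af
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    abort("population_af must lie in [0, 1]")
  }
  if (any(!is.na(af) & !df$in_database)) {
    abort("a reported population_af implies a database record (in_database must be true)")
  }
  as_tibble(df)
}

#' Read RNA allele counts at variant loci
#'
#' @param path Tab-separated file with columns `patient_id`, `contig`, `pos`,
#'   `ref`, `alt`, `rna_depth`, `rna_alt`.
#' @return A tibble of per-patient, per-site RNA read counts.
#' @export
read_rna_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = "c", contig = "c", pos = "i", ref = "c", alt = "c",
      rna_depth = "i", rna_alt = "i"
    ),
    progress = FALSE
  )
  stop_cols(df, c("patient_id", "contig", "pos", "ref", "alt", "rna_depth", "rna_alt"),
    "RNA allele-count table")
  if (any(df$rna_alt > df$rna_depth | df$rna_alt < 0)) {
    abort("rna_alt must satisfy 0 <= rna_alt <= rna_depth")
  }
  as_tibble(df)
}
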