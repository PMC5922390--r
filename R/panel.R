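#' The 35-gene lung cancer panel
#'
#' The packaged panel mirrors a 35-gene panel used in clinical tumor-only
#' lung cancer testing: 25
#' genes implicated as somatic tumor drivers (`tumor_driver`) and 10 genes
#' affecting inherited cancer risk (`inherited_risk`). Each gene carries its
#' protein-coding sequence (CDS) length in bases and one or more genomic
#' intervals (GRCh37, 1-based closed) used to restrict variant input to the
#' panel footprint. CDS lengths and intervals come from canonical RefSeq
#' transcripts chosen by the package; they are plausible, not authoritative.
#'
#' @param path Optional path to a panel definition. Tab-separated files need
#'   columns `gene`, `panel_class`, `cds_length`, `contig`, `start`, `end`
#'   (one row per interval); `.yaml`/`.yml` files need a list of entries with
#'   fields `gene`, `class`, `cds_length` and `intervals` (each with `contig`,
#'   `start`, `end`). With `path = NULL` the packaged 35-gene panel is used.
#' @return An object of class `gene_panel`: a list with `genes` (one row per
#'   gene: `gene`, `panel_class`, `cds_length`) and `intervals` (one row per
#'   interval: `gene`, `contig`, `start`, `end`).
#' @examples
#' panel <- gene_panel()
#' dplyr::count(panel$genes, panel_class)
#' @export
gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "panel_grch37.tsv", package = "panelaudit")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    entries <- yaml::read_yaml(path)
    genes <- purrr::map_dfr(entries, function(e) {
      tibble(
        gene = e$gene,
        panel_class = e$class %||% e$panel_class,
        cds_length = as.integer(e$cds_length)
      )
    })
    intervals <- purrr::map_dfr(entries, function(e) {
      purrr::map_dfr(e$intervals, function(iv) {
        tibble(
          gene = e$gene, contig = as.character(iv$contig),
          start = as.integer(iv$start), end = as.integer(iv$end)
        )
      })
    })
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stop_cols(raw, c("gene", "panel_class", "cds_length", "contig", "start", "end"),
      "panel definition")
    genes <- distinct(raw, .data$gene, .data$panel_class, .data$cds_length)
    intervals <- select(raw, "gene", "contig", "start", "end") |>
      mutate(contig = as.character(.data$contig))
  }
  new_gene_panel(genes, intervals)
}

new_gene_panel <- function(genes, intervals) {
  if (anyDuplicated(genes$gene)) {
    abort("panel must contain exactly one entry per gene symbol")
  }
  if (!all(genes$panel_class %in% c("tumor_driver", "inherited_risk"))) {
    abort("panel_class must be 'tumor_driver' or 'inherited_risk'")
  }
  if (nrow(intervals) == 0 || any(intervals$start > intervals$end)) {
    abort("panel intervals must be non-empty with start <= end (1-based, closed)")
  }
  if (!all(intervals$gene %in% genes$gene)) {
    abort("interval rows refer to genes absent from the panel")
  }
  structure(
    list(genes = as_tibble(genes), intervals = as_tibble(intervals)),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf(
    "<gene_panel> %d genes (%d tumor_driver, %d inherited_risk), %d interval(s)\n",
    nrow(x$genes),
    sum(x$genes$panel_class == "tumor_driver"),
    sum(x$genes$panel_class == "inherited_risk"),
    nrow(x$intervals)
  ))
  invisible(x)
}

# GRanges view of the panel footprint, for interval overlap against VCF records.
panel_granges <- function(panel) {
  GenomicRanges::GRanges(
    seqnames = panel$intervals$contig,
    ranges = IRanges::IRanges(panel$intervals$start, panel$intervals$end),
    gene = panel$intervals$gene
  )
}

#' Map of drug-targetable panel genes to targeting drugs
#'
#' Twelve panel genes have FDA-approved drugs directed at their somatically
#' mutated forms; a false positive call in any of them can directly trigger
#' an ineffective (and potentially harmful) treatment. The packaged map joins
#' each gene to the drugs that target it.
#'
#' @param path Optional tab-separated file with columns `gene` and `drug`;
#'   defaults to the packaged 12-gene map.
#' @return A tibble with columns `gene`, `drug` (one row per pair).
#' @export
drug_target_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_targets.tsv", package = "panelaudit")
  }
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_cols(map, c("gene", "drug"), "drug target map")
  empty <- map$drug == "" | is.na(map$drug)
  if (any(empty)) abort("every mapped gene needs a non-empty drug name")
  as_tibble(map)
}

#' Published per-gene variant counts (reference cohort)
#'
#' Per-gene counts of unique SNV sites and of germline/somatic variant calls
#' from the reference tumor-normal study cohort (45 lung cancer patients; 621
#' patients across all cancer types), transcribed as a packaged fixture. These
#' counts let the reporting arithmetic be exercised and checked without access
#' to the unpublished per-patient data.
#'
#' @return A tibble with one row per panel gene: `gene`, `panel_class`,
#'   `unique_all`, `germline_all`, `somatic_all`, `unique_lung`,
#'   `germline_lung`, `somatic_lung`.
#' @seealso [reference_expression_counts()], [reference_cohort_variants()]
#' @export
reference_variant_counts <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "panelaudit")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published per-gene somatic expression counts (reference cohort)
#'
#' Per-gene counts of somatic SNVs assessable in tumor RNA, of those not
#' expressed, and of patients carrying a not-expressed somatic SNV, for the
#' reference cohort (all cancer types and the lung-only subset), transcribed
#' as a packaged fixture. Note the published "unique patients" totals (51
#' all-cancer, 6 lung) deduplicate across genes and are not column sums; they
#' are available from [reference_constants()].
#'
#' @return A tibble with one row per panel gene: `gene`, `assessed_all`,
#'   `not_expressed_all`, `patients_all`, `assessed_lung`,
#'   `not_expressed_lung`, `patients_lung`.
#' @export
reference_expression_counts <- function() {
  path <- system.file("extdata", "table3_expression.tsv", package = "panelaudit")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Headline constants of the reference study
#'
#' Published cohort-level constants that cannot be derived from the per-gene
#' fixtures: the raw number of protein-altering SNVs discovered in the lung
#' subset before restriction to the analyzed set (802 vs 746 analyzed; the
#' study does not explain the difference, so both are kept verbatim),
#' cross-gene-deduplicated patient counts for the expression tables, the
#' size of the RNA-assessable subsets, and germline expression totals.
#'
#' @return A named list of integers.
#' @export
reference_constants <- function() {
  list(
    lung_patients = 45L,
    all_patients = 621L,
    lung_snvs_discovered = 802L,
    lung_snvs_analyzed = 746L,
    expr_unique_patients_all = 51L,
    expr_unique_patients_lung = 6L,
    rna_patients_all = 378L,
    rna_patients_lung = 26L,
    germline_assessed_all = 3698L,
    germline_not_expressed_all = 337L,
    germline_assessed_lung = 215L,
    germline_not_expressed_lung = 23L
  )
}

#' Expand the reference per-gene counts to a synthetic per-variant table
#'
#' The reference study never published per-patient variant data, so exact
#' per-variant records cannot be reconstructed. This expansion fabricates a
#' variant table whose margins equal the published per-gene counts exactly:
#' each gene's variants are spread round-robin over exactly its published
#' number of unique sites (positions placed deterministically inside the
#' gene's panel interval), origins fill germline-first then somatic, patients
#' cycle through the roster, and read evidence is synthesized to be consistent
#' with the assigned origin (so the evidence-based classifier reproduces the
#' labels). Per-site and per-patient structure is therefore synthetic; only
#' the per-gene margins (and everything derived from margins alone) are real.
#'
#' @param scope `"lung"` (45 patients) or `"all"` (621 patients).
#' @param panel A [gene_panel()] used for interval placement.
#' @return A variant tibble in the layout of [read_variant_table()], with
#'   `origin` prefilled from the published labels (fixture mode).
#' @export
reference_cohort_variants <- function(scope = c("lung", "all"), panel = gene_panel()) {
  scope <- match.arg(scope)
  t1 <- reference_variant_counts()
  n_patients <- if (scope == "lung") 45L else 621L
  cols <- if (scope == "lung") {
    c(u = "unique_lung", g = "germline_lung", s = "somatic_lung")
  } else {
    c(u = "unique_all", g = "germline_all", s = "somatic_all")
  }
  rows <- purrr::pmap_dfr(
    list(t1$gene, t1[[cols["u"]]], t1[[cols["g"]]], t1[[cols["s"]]]),
    function(gene, n_unique, n_germ, n_som) {
      total <- n_germ + n_som
      if (total == 0) return(NULL)
      iv <- filter(panel$intervals, .data$gene == .env$gene)[1, ]
      step <- max((iv$end - iv$start) %/% (n_unique + 1L), 1L)
      site_pos <- iv$start + step * seq_len(n_unique)
      site_idx <- sort(rep_len(seq_len(n_unique), total))
      tibble(
        gene = gene,
        contig = iv$contig,
        pos = site_pos[site_idx],
        origin = rep(c("germline", "somatic"), c(n_germ, n_som))
      )
    }
  )
  rows |>
    mutate(
      patient_id = sprintf("P%03d", (row_number() - 1L) %% n_patients + 1L),
      ref = "G", alt = "A", consequence = "missense",
      tumor_depth = 60L, normal_depth = 30L,
      tumor_alt = if_else(.data$origin == "germline", 30L, 24L),
      normal_alt = if_else(.data$origin == "germline", 15L, 0L)
    ) |>
    select(dplyr::all_of(variant_cols))
}
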