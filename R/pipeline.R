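#' Run the full tumor-normal vs tumor-only audit
#'
#' End-to-end orchestration: classify variant origins (or trust fixture
#' labels), collapse unique sites and find cohort-common variants, apply each
#' tumor-only filter regime (an unfiltered baseline plus the three published
#' regimes by default), tally false positives/negatives at cohort, gene and
#' patient scope, quantify the impact on drug-targetable genes, and — when
#' RNA counts are supplied — assess variant expression. Returns everything as
#' one `panel_audit` object consumed by [write_report_tables()], [glance()]
#' and [tidy()].
#'
#' @param variants A variant tibble ([read_variant_table()],
#'   [read_paired_vcf()], or a simulated cohort's variants).
#' @param annotations Population annotation tibble; required whenever any
#'   regime other than the unfiltered baseline is requested.
#' @param rna_counts Optional RNA allele-count tibble.
#' @param panel A [gene_panel()].
#' @param patients Optional full patient roster (so zero-variant patients
#'   enter per-patient denominators); defaults to patients seen in
#'   `variants`.
#' @param cohort_size Cohort size for sample frequencies; defaults to the
#'   roster length.
#' @param thresholds A [classifier_thresholds()].
#' @param expr_thresholds An [expression_thresholds()].
#' @param regimes Named list of [filter_regime()]s.
#' @param common_threshold Strict cohort-frequency cut for "common in the
#'   sample" (default 0.02).
#' @param fixture_mode Trust the `origin` column instead of classifying.
#' @param drug_map A [drug_target_map()].
#' @return An object of class `panel_audit`; see Details.
#' @details The returned list holds: `labeled` (all variants with labels),
#'   `origin_counts`, `sites`, `common_sites`, `filtered` (per regime),
#'   `tallies` (cohort/gene/patient scope, per regime), `burden` and
#'   `burden_summaries` (per regime), `druggable`, `gene_counts`,
#'   `origin_table`, `size_cor`, `expression` (or `NULL`), `headline`, and
#'   the inputs' provenance (`cohort_size`, `patients`, `thresholds`).
#' @export
run_audit <- function(variants, annotations = NULL, rna_counts = NULL,
                      panel = gene_panel(), patients = NULL,
                      cohort_size = NULL,
                      thresholds = classifier_thresholds(),
                      expr_thresholds = expression_thresholds(),
                      regimes = tumor_only_regimes(include_baseline = TRUE),
                      common_threshold = 0.02,
                      fixture_mode = FALSE,
                      drug_map = drug_target_map()) {
  labeled <- classify_cohort(variants, thresholds, fixture_mode = fixture_mode)
  counts <- origin_counts(labeled)
  av <- auditable_variants(labeled)
  patients <- patients %||% sort(unique(variants$patient_id))
  cohort_size <- cohort_size %||% length(patients)
  sites <- collapse_sites(av, cohort_size)
  common <- cohort_common_variants(sites, common_threshold)

  needs_ann <- any(purrr::map_chr(regimes, "kind") != "no_filter")
  if (needs_ann && is.null(annotations)) {
    abort("filter stage: an annotation table is required for database/AF filter regimes")
  }
  if (is.null(annotations)) {
    annotations <- tibble(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), in_database = logical(), population_af = double()
    )
  }
  filtered <- purrr::map(regimes, function(rg) {
    apply_filter(av, annotations, rg, cohort_common_sites = common)
  })
  tallies <- purrr::imap_dfr(filtered, function(f, nm) {
    bind_rows(
      tally_confusion(f, "cohort"),
      tally_confusion(f, "gene"),
      tally_confusion(f, "patient")
    ) |>
      mutate(regime = nm) |>
      relocate("regime")
  })
  burden <- purrr::map(filtered, per_patient_burden, patients = patients)
  burden_summaries <- purrr::imap_dfr(burden, function(b, nm) {
    mutate(burden_summary(b), regime = nm) |> relocate("regime")
  })
  druggable <- druggable_impact(filtered, drug_map)

  expression <- NULL
  if (!is.null(rna_counts)) {
    calls <- call_expression(rna_counts, expr_thresholds)
    expression <- list(
      calls = calls,
      somatic = expression_summary(calls, labeled, "somatic", panel),
      germline = expression_summary(calls, labeled, "germline", panel),
      germline_fraction = tryCatch(
        germline_expression_fraction(calls, labeled),
        error = function(e) NULL
      )
    )
  }

  gene_counts <- gene_origin_counts(labeled, panel, cohort_size)
  origin_table <- gene_origin_table(gene_counts)
  size_cor <- tryCatch(size_correlation(gene_counts, panel),
    error = function(e) NULL)

  audit <- structure(
    list(
      labeled = labeled, origin_counts = counts, sites = sites,
      common_sites = common, filtered = filtered, tallies = tallies,
      burden = burden, burden_summaries = burden_summaries,
      druggable = druggable, gene_counts = gene_counts,
      origin_table = origin_table, size_cor = size_cor,
      expression = expression,
      patients = patients, cohort_size = cohort_size,
      thresholds = thresholds, common_threshold = common_threshold
    ),
    class = "panel_audit"
  )
  audit$headline <- headline_summary(audit)
  audit
}

#' Headline fractions of an audit
#'
#' Collects the cohort-level headline numbers: total variants and the
#' germline/somatic split (overall and by panel class), false positive rates
#' per regime under both denominators, the share of patients with at least
#' one (or only) false positives, and the expression dropout fractions when
#' RNA was assessed. Fractions are kept at full precision; rounding to
#' integer percent happens only at serialization in
#' [write_report_tables()].
#'
#' @param audit A `panel_audit` (all stages present; a missing stage is an
#'   error naming it).
#' @return A nested list.
#' @export
headline_summary <- function(audit) {
  for (stage in c("origin_counts", "tallies", "burden_summaries", "gene_counts")) {
    if (is.null(audit[[stage]])) {
      abort(sprintf("headline summary: missing stage '%s'", stage))
    }
  }
  oc <- setNames(audit$origin_counts$n, audit$origin_counts$origin)
  n_labeled <- oc[["germline"]] + oc[["somatic"]]
  by_class <- audit$gene_counts |>
    group_by(.data$panel_class) |>
    summarise(across(c("n_germline", "n_somatic"), sum), .groups = "drop") |>
    mutate(
      somatic_fraction = if_else(.data$n_germline + .data$n_somatic > 0,
        .data$n_somatic / (.data$n_germline + .data$n_somatic), NA_real_)
    )
  cohort_tallies <- filter(audit$tallies, .data$scope == "cohort")
  fp_rates <- purrr::map(split(cohort_tallies, cohort_tallies$regime), function(tt) {
    list(
      fp = tt$fp, tp = tt$tp, fn = tt$fn,
      fp_rate_retained = tryCatch(false_positive_rate(tt, "retained"),
        error = function(e) NA_real_),
      fp_rate_total = tryCatch(false_positive_rate(tt, "total"),
        error = function(e) NA_real_)
    )
  })
  out <- list(
    n_variants_labeled = unname(n_labeled),
    n_germline = unname(oc[["germline"]]),
    n_somatic = unname(oc[["somatic"]]),
    n_ambiguous = unname(oc[["ambiguous"]]),
    n_unassigned = unname(oc[["unassigned"]]),
    germline_fraction = if (n_labeled > 0) unname(oc[["germline"]] / n_labeled) else NA_real_,
    somatic_fraction_by_class = setNames(
      as.list(by_class$somatic_fraction), by_class$panel_class
    ),
    n_unique_sites = nrow(audit$sites),
    n_cohort_common = nrow(audit$common_sites),
    fp_by_regime = fp_rates,
    patients = purrr::map(
      split(audit$burden_summaries, audit$burden_summaries$regime),
      function(b) {
        list(
          prop_any_fp = b$prop_any_fp, prop_only_fp = b$prop_only_fp,
          mean_retained = b$mean_retained
        )
      }
    ),
    classifier_thresholds = unclass(audit$thresholds),
    cohort_size = audit$cohort_size
  )
  if (!is.null(audit$expression)) {
    som <- filter(audit$expression$somatic, .data$gene == "TOTAL")
    out$expression <- list(
      somatic_not_expressed_fraction = som$fraction,
      somatic_assessed = som$n_assessed,
      germline_not_expressed_fraction =
        audit$expression$germline_fraction$fraction %||% NA_real_
    )
  }
  out
}

#' @export
print.panel_audit <- function(x, ...) {
  h <- x$headline
  cat(sprintf(
    "<panel_audit> %d patients, %d labeled variants (%.0f%% germline), %d unique sites\n",
    x$cohort_size, h$n_variants_labeled, 100 * h$germline_fraction, h$n_unique_sites
  ))
  ct <- filter(x$tallies, .data$scope == "cohort")
  print(select(ct, "regime", "tp", "fp", "fn", "germline_removed"))
  invisible(x)
}

#' @exportS3Method
glance.panel_audit <- function(x, ...) {
  h <- x$headline
  tibble(
    n_patients = x$cohort_size,
    n_variants = h$n_variants_labeled,
    n_germline = h$n_germline,
    n_somatic = h$n_somatic,
    germline_fraction = h$germline_fraction,
    n_unique_sites = h$n_unique_sites,
    n_cohort_common = h$n_cohort_common,
    singleton_fraction = if (nrow(x$sites) > 0) singleton_fraction(x$sites) else NA_real_
  )
}

#' @exportS3Method
tidy.panel_audit <- function(x, scope = "cohort", ...) {
  filter(x$tallies, .data$scope == .env$scope)
}

#' Write the audit report tables
#'
#' Writes deterministic, byte-stable TSVs — per-gene origin table, confusion
#' tallies by regime (cohort and gene scope), per-patient burden per regime,
#' somatic expression summary, druggable-gene impact — plus a JSON summary of
#' the headline fractions. Writing the same audit twice yields identical
#' bytes.
#'
#' @param audit A `panel_audit` from [run_audit()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(audit, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory '%s'", out_dir))
  paths <- c(
    origin_table = file.path(out_dir, "gene_origin_table.tsv"),
    confusion = file.path(out_dir, "confusion_by_regime.tsv"),
    burden = file.path(out_dir, "patient_burden.tsv"),
    expression = file.path(out_dir, "expression_summary.tsv"),
    druggable = file.path(out_dir, "druggable_impact.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_tsv_stable(audit$origin_table, paths[["origin_table"]])
  write_tsv_stable(
    filter(audit$tallies, .data$scope %in% c("cohort", "gene")),
    paths[["confusion"]]
  )
  burden_all <- purrr::imap_dfr(audit$burden, function(b, nm) {
    mutate(b, regime = nm) |> relocate("regime")
  })
  write_tsv_stable(burden_all, paths[["burden"]])
  expr <- if (!is.null(audit$expression)) {
    mutate(audit$expression$somatic,
      pct_not_expressed = int_pct(.data$n_not_expressed, .data$n_assessed))
  } else {
    tibble(gene = character(), n_assessed = integer(), n_not_expressed = integer(),
      fraction = double(), n_patients_not_expressed = integer(),
      pct_not_expressed = double())
  }
  write_tsv_stable(expr, paths[["expression"]])
  write_tsv_stable(audit$druggable, paths[["druggable"]])
  jsonlite::write_json(audit$headline, paths[["summary"]],
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
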