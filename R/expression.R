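#' Thresholds for calling variant expression from RNA read counts
#'
#' A DNA variant is only a useful drug target if its alternate allele is
#' actually transcribed. The reference assay reports only performance (>95%
#' sensitivity, >99% specificity), not a decision rule, so conservative
#' pileup heuristics are used: a locus must reach a minimum RNA depth to be
#' assessable at all, and an assessable variant counts as expressed when its
#' alt-supporting reads clear both an absolute and a fractional floor.
#'
#' @param min_assessable_depth Minimum RNA depth for a call (below:
#'   `"not_assessable"`).
#' @param min_alt_reads,min_alt_fraction Minimum alt reads and alt fraction
#'   (both required) for `"expressed"`.
#' @return A list of class `expression_thresholds`.
#' @export
expression_thresholds <- function(min_assessable_depth = 10L,
                                  min_alt_reads = 3L,
                                  min_alt_fraction = 0.05) {
  if (min_assessable_depth < 0 || min_alt_reads < 0) {
    abort("read thresholds must be non-negative")
  }
  if (min_alt_fraction < 0 || min_alt_fraction > 1) {
    abort("min_alt_fraction must lie in [0, 1]")
  }
  structure(
    list(
      min_assessable_depth = min_assessable_depth,
      min_alt_reads = min_alt_reads,
      min_alt_fraction = min_alt_fraction
    ),
    class = "expression_thresholds"
  )
}

#' Call expression status at variant loci
#'
#' Pure function of the RNA counts and thresholds: `"not_assessable"` below
#' the depth floor, else `"expressed"` when alt reads clear both floors, else
#' `"not_expressed"`.
#'
#' @param rna_counts A tibble from [read_rna_table()] (or the simulator).
#' @param thresholds An [expression_thresholds()].
#' @return The input tibble with a `status` column appended.
#' @export
call_expression <- function(rna_counts, thresholds = expression_thresholds()) {
  if (any(rna_counts$rna_alt > rna_counts$rna_depth | rna_counts$rna_alt < 0)) {
    abort("rna_alt must satisfy 0 <= rna_alt <= rna_depth")
  }
  th <- thresholds
  frac <- if_else(rna_counts$rna_depth > 0,
    rna_counts$rna_alt / rna_counts$rna_depth, 0)
  status <- dplyr::case_when(
    rna_counts$rna_depth < th$min_assessable_depth ~ "not_assessable",
    rna_counts$rna_alt >= th$min_alt_reads & frac >= th$min_alt_fraction ~ "expressed",
    TRUE ~ "not_expressed"
  )
  mutate(rna_counts, status = status)
}

# Join expression calls onto labeled variants by patient and site identity.
# Variants with no RNA record at all are not assessable and never enter
# denominators (the study restricts to patients with tumor RNA data).
join_expression <- function(calls, variants) {
  variants |>
    left_join(
      select(calls, "patient_id", "contig", "pos", "ref", "alt", "status"),
      by = c("patient_id", "contig", "pos", "ref", "alt")
    ) |>
    mutate(status = if_else(is.na(.data$status), "not_assessable", .data$status))
}

#' Per-gene summary of variants not expressed in tumor RNA
#'
#' Joins expression calls to labeled variants, restricts to one origin, and
#' summarises per gene: variants assessed (assessable RNA coverage), variants
#' not expressed, the not-expressed fraction, and the number of distinct
#' patients with at least one not-expressed variant. A `"TOTAL"` row sums the
#' genes, with its patient count deduplicated across genes. Genes with no
#' assessable calls are still listed (fraction `NA`, rendered blank in
#' reports).
#'
#' @param calls Output of [call_expression()].
#' @param variants A labeled variant tibble.
#' @param origin `"somatic"` or `"germline"`.
#' @param panel Optional [gene_panel()] fixing the gene list and order.
#' @return A tibble: `gene`, `n_assessed`, `n_not_expressed`, `fraction`,
#'   `n_patients_not_expressed`.
#' @export
expression_summary <- function(calls, variants,
                               origin = c("somatic", "germline"),
                               panel = NULL) {
  origin <- match.arg(origin)
  joined <- join_expression(calls, auditable_variants(variants)) |>
    filter(.data$origin == .env$origin, .data$status != "not_assessable")
  per_gene <- joined |>
    group_by(.data$gene) |>
    summarise(
      n_assessed = n(),
      n_not_expressed = sum(.data$status == "not_expressed"),
      n_patients_not_expressed =
        n_distinct(.data$patient_id[.data$status == "not_expressed"]),
      .groups = "drop"
    )
  gene_list <- if (!is.null(panel)) panel$genes$gene else sort(unique(per_gene$gene))
  out <- tibble(gene = gene_list) |>
    left_join(per_gene, by = "gene") |>
    mutate(across(
      c("n_assessed", "n_not_expressed", "n_patients_not_expressed"),
      ~ if_else(is.na(.x), 0L, as.integer(.x))
    ))
  total <- tibble(
    gene = "TOTAL",
    n_assessed = sum(out$n_assessed),
    n_not_expressed = sum(out$n_not_expressed),
    n_patients_not_expressed =
      n_distinct(joined$patient_id[joined$status == "not_expressed"])
  )
  bind_rows(out, total) |>
    mutate(fraction = if_else(.data$n_assessed > 0,
      .data$n_not_expressed / .data$n_assessed, NA_real_)) |>
    relocate("gene", "n_assessed", "n_not_expressed", "fraction")
}

#' Cohort-level fraction of germline variants not expressed
#'
#' @param calls Output of [call_expression()].
#' @param variants A labeled variant tibble.
#' @return A one-row tibble: `n_assessed`, `n_not_expressed`, `fraction`.
#' @export
germline_expression_fraction <- function(calls, variants) {
  joined <- join_expression(calls, auditable_variants(variants)) |>
    filter(.data$origin == "germline", .data$status != "not_assessable")
  if (nrow(joined) == 0) {
    abort("no assessable germline variants; the fraction is undefined")
  }
  tibble(
    n_assessed = nrow(joined),
    n_not_expressed = sum(joined$status == "not_expressed"),
  ) |>
    mutate(fraction = .data$n_not_expressed / .data$n_assessed)
}
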