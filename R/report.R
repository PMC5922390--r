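#' Per-gene origin counts from labeled variants
#'
#' Reduces a labeled cohort to the per-gene counts that feed the gene origin
#' table: unique SNV sites, germline variant calls, somatic variant calls.
#'
#' @param variants A labeled variant tibble.
#' @param panel A [gene_panel()] fixing the gene list (genes with zero
#'   variants report zeros).
#' @param cohort_size Cohort size passed to [collapse_sites()].
#' @return A tibble: `gene`, `panel_class`, `unique_sites`, `n_germline`,
#'   `n_somatic`.
#' @export
gene_origin_counts <- function(variants, panel = gene_panel(), cohort_size) {
  av <- auditable_variants(variants)
  sites <- collapse_sites(av, cohort_size)
  per_gene <- av |>
    count(.data$gene, .data$origin) |>
    tidyr::pivot_wider(names_from = "origin", values_from = "n", values_fill = 0L)
  for (cc in c("germline", "somatic")) {
    if (!cc %in% names(per_gene)) per_gene[[cc]] <- 0L
  }
  panel$genes |>
    select("gene", "panel_class") |>
    left_join(count(sites, .data$gene, name = "unique_sites"), by = "gene") |>
    left_join(select(per_gene, "gene", n_germline = "germline", n_somatic = "somatic"),
      by = "gene") |>
    mutate(across(
      c("unique_sites", "n_germline", "n_somatic"),
      ~ if_else(is.na(.x), 0L, as.integer(.x))
    ))
}

#' Gene origin table with panel-class subtotals
#'
#' Renders per-gene counts in the published layout: unique sites, germline
#' calls with integer percentage, somatic calls with integer percentage, a
#' subtotal row per panel class and a grand total. Percentages are always
#' re-derived from the row's own counts (germline / (germline + somatic) and
#' complement, rounded half-up); a gene with no variants renders blank
#' percentages.
#'
#' @param counts A tibble with columns `gene`, `panel_class`, `unique_sites`,
#'   `n_germline`, `n_somatic` — from [gene_origin_counts()] or a published
#'   per-gene fixture.
#' @return A tibble with one row per gene plus `TOTAL tumor_driver`,
#'   `TOTAL inherited_risk` and `TOTAL` rows; columns `gene`, `panel_class`,
#'   `unique_sites`, `n_germline`, `pct_germline`, `n_somatic`,
#'   `pct_somatic`.
#' @export
gene_origin_table <- function(counts) {
  stop_cols(counts, c("gene", "panel_class", "unique_sites", "n_germline", "n_somatic"),
    "per-gene counts")
  class_totals <- counts |>
    group_by(.data$panel_class) |>
    summarise(across(c("unique_sites", "n_germline", "n_somatic"), sum),
      .groups = "drop") |>
    mutate(gene = paste("TOTAL", .data$panel_class))
  grand <- counts |>
    summarise(across(c("unique_sites", "n_germline", "n_somatic"), sum)) |>
    mutate(gene = "TOTAL", panel_class = "all")
  ordered <- bind_rows(
    filter(counts, .data$panel_class == "tumor_driver"),
    filter(class_totals, .data$panel_class == "tumor_driver"),
    filter(counts, .data$panel_class == "inherited_risk"),
    filter(class_totals, .data$panel_class == "inherited_risk"),
    grand
  )
  ordered |>
    mutate(
      total = .data$n_germline + .data$n_somatic,
      pct_germline = int_pct(.data$n_germline, .data$total),
      pct_somatic = int_pct(.data$n_somatic, .data$total)
    ) |>
    select("gene", "panel_class", "unique_sites",
      "n_germline", "pct_germline", "n_somatic", "pct_somatic")
}

#' Correlation between per-gene unique site counts and CDS length
#'
#' Pearson correlation between the number of unique SNV sites per gene and
#' the gene's protein-coding sequence length, with the two-sided p-value from
#' the standard t transform on n - 2 degrees of freedom. Larger coding
#' sequences present more mutable coding bases, so unique-site counts track
#' CDS length; raw variant counts do not, because they are dominated by a few
#' recurrent common variants.
#'
#' @param counts A per-gene tibble with a `gene` column and the count column
#'   named by `count_col`.
#' @param panel A [gene_panel()] providing `cds_length`.
#' @param count_col Name of the count column (default `"unique_sites"`).
#' @return An object of class `size_correlation` with fields `r`,
#'   `r_squared`, `p_value`, `n`; supports [tidy()] and [glance()].
#' @export
size_correlation <- function(counts, panel = gene_panel(),
                             count_col = "unique_sites") {
  df <- counts |>
    left_join(select(panel$genes, "gene", "cds_length"), by = "gene") |>
    filter(!is.na(.data$cds_length))
  if (nrow(df) < 3) abort("size correlation needs at least 3 genes")
  x <- df[[count_col]]
  y <- df$cds_length
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("size correlation is undefined when either vector has zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(
      r = unname(ct$estimate),
      r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value,
      n = nrow(df),
      count_col = count_col
    ),
    class = "size_correlation"
  )
}

#' @export
print.size_correlation <- function(x, ...) {
  cat(sprintf(
    "<size_correlation> %s vs CDS length: r = %.3f (R^2 = %.3f), p = %.3g, n = %d genes\n",
    x$count_col, x$r, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' @exportS3Method
tidy.size_correlation <- function(x, ...) {
  tibble(
    term = paste0(x$count_col, "_vs_cds_length"),
    estimate = x$r, r_squared = x$r_squared, p.value = x$p_value, n = x$n
  )
}

#' @exportS3Method
glance.size_correlation <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r_squared, p.value = x$p_value, n = x$n)
}

#' Histogram of per-patient true/false positive burden
#'
#' Bins patients with at least one retained call by their (true positive,
#' false positive) count pair; patients with a total retained burden above
#' `cap` are listed separately instead of binned (the published figure
#' excluded one patient with 39 somatic SNVs for presentation).
#'
#' @param burden Output of [per_patient_burden()].
#' @param cap Maximum total retained calls for inclusion in the histogram.
#' @return A list of class `burden_histogram`: `histogram` (tibble `n_tp`,
#'   `n_fp`, `n_patients`) and `excluded` (tibble `patient_id`, `n_tp`,
#'   `n_fp`).
#' @export
burden_histogram <- function(burden, cap = 30L) {
  shown <- filter(burden, .data$n_retained >= 1, .data$n_retained <= cap)
  excluded <- filter(burden, .data$n_retained > cap) |>
    select("patient_id", "n_tp", "n_fp")
  hist <- shown |>
    count(.data$n_tp, .data$n_fp, name = "n_patients") |>
    arrange(.data$n_tp, .data$n_fp)
  structure(list(histogram = hist, excluded = excluded), class = "burden_histogram")
}

#' @export
print.burden_histogram <- function(x, ...) {
  cat(sprintf(
    "<burden_histogram> %d bin(s), %d patient(s) excluded above cap\n",
    nrow(x$histogram), nrow(x$excluded)
  ))
  print(x$histogram)
  invisible(x)
}

#' @rdname burden_histogram
#' @param object A `burden_histogram`.
#' @param ... Ignored.
#' @exportS3Method
autoplot.burden_histogram <- function(object, ...) {
  df <- object$histogram |>
    tidyr::pivot_longer(c("n_tp", "n_fp"), names_to = "kind", values_to = "count") |>
    group_by(.data$kind, .data$count) |>
    summarise(n_patients = sum(.data$n_patients), .groups = "drop") |>
    mutate(kind = if_else(.data$kind == "n_tp", "true positive", "false positive"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$count, y = .data$n_patients, fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "retained SNVs per patient", y = "patients", fill = NULL,
      title = "True and false positive burden after tumor-only filtering"
    ) +
    ggplot2::theme_minimal()
}

#' Per-gene false positives by filter regime (plot)
#'
#' Bar chart of false positive counts per gene under each filter regime —
#' the per-gene companion to the cohort false positive rates.
#'
#' @param gene_tallies A tibble binding gene-scope [tally_confusion()]
#'   outputs with a `regime` column.
#' @return A ggplot object.
#' @export
plot_gene_fp <- function(gene_tallies) {
  stop_cols(gene_tallies, c("regime", "scope_id", "fp"), "gene tallies")
  ggplot2::ggplot(gene_tallies, ggplot2::aes(
    x = .data$scope_id, y = .data$fp, fill = .data$regime
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "false positive SNVs", fill = "filter") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
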