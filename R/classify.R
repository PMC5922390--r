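#' Evidence thresholds for germline/somatic origin assignment
#'
#' The reference study's tumor-vs-normal caller is proprietary, so origin
#' assignment here uses conventional paired-calling heuristics at the study's
#' stated depths (~30x normal, ~60x tumor). A variant must first clear tumor
#' evidence minima to be assignable at all; its origin then follows the
#' normal-sample evidence: strong normal support means the allele was
#' inherited (germline), while (near-)absent normal support means it arose in
#' the tumor (somatic). Normal evidence strictly between the two bands is
#' "ambiguous" and excluded from downstream tallies rather than forced.
#'
#' @param min_tumor_alt,min_tumor_vaf Minimum tumor alt reads and variant
#'   allele fraction (VAF) for a variant to be assignable; below either it is
#'   `"unassigned"`.
#' @param germline_min_normal_alt,germline_min_normal_vaf Normal-sample alt
#'   reads and VAF at or above which (both) the variant is `"germline"`.
#' @param somatic_max_normal_alt,somatic_max_normal_vaf The variant is
#'   `"somatic"` when normal alt reads are at or below
#'   `somatic_max_normal_alt` or normal VAF is below
#'   `somatic_max_normal_vaf`.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(min_tumor_alt = 4L, min_tumor_vaf = 0.05,
                                  germline_min_normal_alt = 4L,
                                  germline_min_normal_vaf = 0.20,
                                  somatic_max_normal_alt = 1L,
                                  somatic_max_normal_vaf = 0.02) {
  fr <- c(min_tumor_vaf, germline_min_normal_vaf, somatic_max_normal_vaf)
  if (any(fr < 0 | fr > 1)) abort("VAF thresholds must lie in [0, 1]")
  if (somatic_max_normal_vaf >= germline_min_normal_vaf) {
    abort("somatic_max_normal_vaf must be below germline_min_normal_vaf")
  }
  structure(
    list(
      min_tumor_alt = min_tumor_alt, min_tumor_vaf = min_tumor_vaf,
      germline_min_normal_alt = germline_min_normal_alt,
      germline_min_normal_vaf = germline_min_normal_vaf,
      somatic_max_normal_alt = somatic_max_normal_alt,
      somatic_max_normal_vaf = somatic_max_normal_vaf
    ),
    class = "classifier_thresholds"
  )
}

#' Assign germline/somatic origin from matched tumor/normal evidence
#'
#' Vectorized over the variant table; see [classifier_thresholds()] for the
#' decision bands. The function is total: every row receives exactly one of
#' `"germline"`, `"somatic"`, `"ambiguous"`, `"unassigned"`.
#'
#' @param variants A variant tibble (see [read_variant_table()]).
#' @param thresholds A [classifier_thresholds()].
#' @return The input tibble with `origin` replaced by the assigned labels.
#' @export
classify_origin <- function(variants, thresholds = classifier_thresholds()) {
  validate_variants(variants)
  th <- thresholds
  t_vaf <- if_else(variants$tumor_depth > 0,
    variants$tumor_alt / variants$tumor_depth, 0)
  n_vaf <- if_else(variants$normal_depth > 0,
    variants$normal_alt / variants$normal_depth, 0)
  assignable <- variants$tumor_alt >= th$min_tumor_alt & t_vaf >= th$min_tumor_vaf
  is_germline <- variants$normal_alt >= th$germline_min_normal_alt &
    n_vaf >= th$germline_min_normal_vaf
  is_somatic <- variants$normal_alt <= th$somatic_max_normal_alt |
    n_vaf < th$somatic_max_normal_vaf
  new_origin <- dplyr::case_when(
    !assignable ~ "unassigned",
    is_germline ~ "germline",
    is_somatic ~ "somatic",
    TRUE ~ "ambiguous"
  )
  mutate(variants, origin = .env$new_origin)
}

#' Classify a whole cohort, or consume trusted labels in fixture mode
#'
#' Labels every variant in the cohort. In fixture mode (published-table
#' transcriptions, synthetic truth) the existing `origin` column is trusted
#' and evidence-based classification is bypassed. Ambiguous and unassigned
#' variants stay in the returned table but are excluded by every downstream
#' tally; count them with [origin_counts()].
#'
#' @inheritParams classify_origin
#' @param fixture_mode If `TRUE`, keep the `origin` column as-is (it must
#'   contain only "germline"/"somatic").
#' @return The labeled variant tibble.
#' @export
classify_cohort <- function(variants, thresholds = classifier_thresholds(),
                            fixture_mode = FALSE) {
  if (fixture_mode) {
    bad <- !variants$origin %in% c("germline", "somatic")
    if (any(bad)) {
      abort(sprintf(
        "fixture mode requires trusted germline/somatic labels; %d row(s) carry other origins",
        sum(bad)
      ))
    }
    return(as_tibble(variants))
  }
  classify_origin(variants, thresholds)
}

#' Count variants by assigned origin
#'
#' @param variants A labeled variant tibble.
#' @return A tibble with columns `origin`, `n`, covering all four labels
#'   (zero-filled), so the partition germline + somatic + ambiguous +
#'   unassigned = total is visible.
#' @export
origin_counts <- function(variants) {
  lv <- c("germline", "somatic", "ambiguous", "unassigned")
  variants |>
    count(origin = factor(.data$origin, levels = lv), .drop = FALSE) |>
    mutate(origin = as.character(.data$origin))
}

# Variants that enter downstream accounting: confidently labeled and
# protein-altering (missense/nonsense), per the study's restriction.
auditable_variants <- function(variants) {
  filter(
    variants,
    .data$origin %in% c("germline", "somatic"),
    .data$consequence %in% c("missense", "nonsense")
  )
}

#' Collapse labeled variants to unique SNV sites
#'
#' Groups germline/somatic-labeled variants by site identity (contig,
#' position, ref, alt) and counts carriers per origin. A site carried as
#' germline by one patient and somatic by another is flagged dual-origin.
#' Cohort frequency is, by default, the carrier frequency: patients carrying
#' the site divided by cohort size (somatic variants have no diploid allele
#' count, so carriers/N is the interpretable sample frequency); set
#' `frequency_mode = "allelic"` to divide carrier counts by 2N instead.
#'
#' @param variants A labeled variant tibble (only germline/somatic rows with
#'   missense/nonsense consequence are used).
#' @param cohort_size Number of patients in the cohort (>= number of distinct
#'   patients observed; patients without variants count in the denominator).
#' @param frequency_mode `"carrier"` (carriers/N, default) or `"allelic"`
#'   (carriers/2N).
#' @return A site tibble: `contig`, `pos`, `ref`, `alt`, `gene`,
#'   `n_germline`, `n_somatic`, `dual_origin`, `cohort_frequency`.
#' @export
collapse_sites <- function(variants, cohort_size,
                           frequency_mode = c("carrier", "allelic")) {
  frequency_mode <- match.arg(frequency_mode)
  av <- auditable_variants(variants)
  multi_gene <- av |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt, .data$gene) |>
    count(.data$contig, .data$pos, .data$ref, .data$alt) |>
    filter(.data$n > 1)
  if (nrow(multi_gene) > 0) {
    abort(sprintf(
      "site(s) mapped to more than one gene (panel overlap misconfiguration): %s",
      paste(key_str(multi_gene$contig, multi_gene$pos, multi_gene$ref, multi_gene$alt),
        collapse = ", ")
    ))
  }
  denom <- if (frequency_mode == "carrier") cohort_size else 2 * cohort_size
  av |>
    group_by(.data$contig, .data$pos, .data$ref, .data$alt, .data$gene) |>
    summarise(
      n_germline = n_distinct(.data$patient_id[.data$origin == "germline"]),
      n_somatic = n_distinct(.data$patient_id[.data$origin == "somatic"]),
      .groups = "drop"
    ) |>
    mutate(
      dual_origin = .data$n_germline >= 1 & .data$n_somatic >= 1,
      cohort_frequency = (.data$n_germline + .data$n_somatic) / denom
    ) |>
    arrange(.data$gene, .data$contig, .data$pos, .data$ref, .data$alt)
}

#' Sites common in the cohort itself
#'
#' Returns sites whose cohort frequency strictly exceeds the threshold
#' (default 0.02, the study's cut for "common in the sample"). These feed the
#' rescue rule of the allele-frequency filter regimes.
#'
#' @param sites Output of [collapse_sites()].
#' @param threshold Strict lower bound on cohort frequency.
#' @return The subset of `sites` with `cohort_frequency > threshold`.
#' @export
cohort_common_variants <- function(sites, threshold = 0.02) {
  filter(sites, .data$cohort_frequency > threshold)
}

#' Fraction of unique sites observed exactly once
#'
#' A rare-variant-dominated spectrum shows a high singleton fraction (the
#' reference cohort: 70% of unique sites seen in a single patient).
#'
#' @param sites Output of [collapse_sites()].
#' @return A single fraction in \[0, 1\].
#' @export
singleton_fraction <- function(sites) {
  if (nrow(sites) == 0) abort("singleton fraction is undefined for an empty site list")
  mean(sites$n_germline + sites$n_somatic == 1)
}
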