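#' Define a tumor-only filter regime
#'
#' Tumor-only analysis cannot see the matched normal, so putative germline
#' variants are removed by population-database criteria. Two kinds are
#' supported: `database_membership` removes every variant catalogued in the
#' population database (dbSNP-style), and `af_threshold` removes variants
#' whose reported population allele frequency is at or above `af_cutoff`
#' (inclusive). Allele-frequency regimes optionally add a rescue rule
#' (default on): variants with no reported frequency are still removed when
#' they are catalogued in the database AND common among the cohort's own
#' germline carriers — mirroring the reference study, which removed three
#' such frequency-less common germline SNPs.
#'
#' @param kind `"database_membership"` or `"af_threshold"`.
#' @param af_cutoff Inclusive frequency cutoff in (0, 1]; required for
#'   `af_threshold` regimes.
#' @param rescue Apply the rescue rule (af regimes only).
#' @return A list of class `filter_regime` with a `label` used in reports.
#' @export
filter_regime <- function(kind = c("database_membership", "af_threshold"),
                          af_cutoff = NULL, rescue = TRUE) {
  kind <- match.arg(kind)
  if (kind == "af_threshold") {
    if (is.null(af_cutoff)) {
      abort("af_threshold regimes require an af_cutoff")
    }
    if (af_cutoff <= 0 || af_cutoff > 1) abort("af_cutoff must lie in (0, 1]")
  } else {
    af_cutoff <- NULL
  }
  label <- if (kind == "database_membership") "dbsnp" else {
    sprintf("af_%g", af_cutoff)
  }
  structure(
    list(kind = kind, af_cutoff = af_cutoff, rescue = rescue, label = label),
    class = "filter_regime"
  )
}

#' The three published filter regimes
#'
#' Database membership, allele frequency >= 0.01, and allele frequency
#' >= 0.001 (both AF regimes with the rescue rule enabled), plus an unfiltered
#' baseline when `include_baseline = TRUE`.
#'
#' @param include_baseline Prepend a `no_filter` regime that removes nothing.
#' @return A named list of [filter_regime()] objects.
#' @export
tumor_only_regimes <- function(include_baseline = FALSE) {
  regimes <- list(
    dbsnp = filter_regime("database_membership"),
    af_0.01 = filter_regime("af_threshold", af_cutoff = 0.01),
    af_0.001 = filter_regime("af_threshold", af_cutoff = 0.001)
  )
  if (include_baseline) {
    baseline <- structure(
      list(kind = "no_filter", af_cutoff = NULL, rescue = FALSE, label = "no_filter"),
      class = "filter_regime"
    )
    regimes <- c(list(no_filter = baseline), regimes)
  }
  regimes
}

#' Apply a tumor-only filter regime to labeled variants
#'
#' Evaluates the regime's removal rule against the population annotation of
#' each variant's site. Sites absent from the annotation table count as "not
#' in database, frequency absent" — and a variant with no frequency and no
#' database record is always retained by AF regimes (public frequency
#' estimates bottom out around 1e-4, so absence is uninformative, not zero).
#' The rescue rule only ever fires on sites with at least one germline
#' carrier in the cohort, so recurrent somatic hotspot sites are never
#' rescued away.
#'
#' @param variants A labeled variant tibble; every row must be germline or
#'   somatic (use [auditable_variants()] upstream).
#' @param annotations Annotation tibble from [read_annotation_table()] (or
#'   the simulator).
#' @param regime A [filter_regime()].
#' @param cohort_common_sites Site tibble from [cohort_common_variants()]
#'   (used by the rescue rule; `NULL` disables it).
#' @return The input tibble with logical `retained` and character
#'   `removal_reason` (`NA`, `"database_membership"`, `"af_threshold"`, or
#'   `"rescue_rule"`) columns appended; retained and removed rows partition
#'   the input.
#' @export
apply_filter <- function(variants, annotations, regime,
                         cohort_common_sites = NULL) {
  bad <- !variants$origin %in% c("germline", "somatic")
  if (any(bad)) {
    abort(sprintf(
      "apply_filter() needs germline/somatic labels only; %d row(s) carry other origins",
      sum(bad)
    ))
  }
  ann <- select(annotations, "contig", "pos", "ref", "alt", "in_database", "population_af")
  df <- variants |>
    left_join(ann, by = c("contig", "pos", "ref", "alt")) |>
    mutate(
      in_database = if_else(is.na(.data$in_database), FALSE, .data$in_database)
    )
  common_keys <- character(0)
  if (!is.null(cohort_common_sites) && nrow(cohort_common_sites) > 0) {
    germ_common <- filter(cohort_common_sites, .data$n_germline >= 1)
    common_keys <- key_str(germ_common$contig, germ_common$pos,
      germ_common$ref, germ_common$alt)
  }
  vkey <- key_str(df$contig, df$pos, df$ref, df$alt)
  reason <- rep(NA_character_, nrow(df))
  if (regime$kind == "database_membership") {
    reason[df$in_database] <- "database_membership"
  } else if (regime$kind == "af_threshold") {
    hit_af <- !is.na(df$population_af) & df$population_af >= regime$af_cutoff
    reason[hit_af] <- "af_threshold"
    if (isTRUE(regime$rescue)) {
      rescued <- is.na(df$population_af) & df$in_database & vkey %in% common_keys
      reason[rescued & !hit_af] <- "rescue_rule"
    }
  } # no_filter: nothing removed
  out <- df |>
    select(-"in_database", -"population_af") |>
    mutate(retained = is.na(reason), removal_reason = reason)
  attr(out, "regime") <- regime
  out
}

#' Confusion tally of a filtered cohort
#'
#' In the tumor-only framing, a germline variant that survives filtering is a
#' false positive (it would be reported as a somatic mutation) and a somatic
#' variant that is removed is a false negative (a real tumor mutation lost).
#' The tally is conservative by construction: `tp + fn` equals the somatic
#' input count and `fp + germline_removed` the germline input count at each
#' scope.
#'
#' @param filtered Output of [apply_filter()].
#' @param scope `"cohort"` (one row), `"gene"`, or `"patient"`.
#' @return A tibble with columns `scope`, `scope_id`, `tp`, `fp`, `fn`,
#'   `germline_removed`.
#' @export
tally_confusion <- function(filtered, scope = c("cohort", "gene", "patient")) {
  scope <- match.arg(scope)
  bad <- !filtered$origin %in% c("germline", "somatic")
  if (any(bad)) {
    abort("tally_confusion() requires germline/somatic origins only")
  }
  grp <- switch(scope,
    cohort = mutate(filtered, scope_id = "cohort"),
    gene = mutate(filtered, scope_id = .data$gene),
    patient = mutate(filtered, scope_id = .data$patient_id)
  )
  grp |>
    group_by(.data$scope_id) |>
    summarise(
      tp = sum(.data$origin == "somatic" & .data$retained),
      fp = sum(.data$origin == "germline" & .data$retained),
      fn = sum(.data$origin == "somatic" & !.data$retained),
      germline_removed = sum(.data$origin == "germline" & !.data$retained),
      .groups = "drop"
    ) |>
    mutate(scope = scope) |>
    relocate("scope", "scope_id") |>
    arrange(.data$scope_id)
}

#' False positive rate of a confusion tally
#'
#' Two denominators are in routine use: `"retained"` gives FP / (FP + TP),
#' the fraction of the reported (post-filter) variant list that is wrong;
#' `"total"` gives FP over all germline + somatic input variants, the
#' fraction of everything observed that becomes a false report. `n_total`
#' overrides the total denominator when the discovery count exceeds the
#' labeled input (the reference study quotes 41 false positives against 802
#' discovered SNVs while analyzing 746).
#'
#' @param tally A one-row cohort tally from [tally_confusion()].
#' @param denominator `"retained"` or `"total"`.
#' @param n_total Optional explicit total denominator.
#' @return A single fraction.
#' @export
false_positive_rate <- function(tally, denominator = c("retained", "total"),
                                n_total = NULL) {
  denominator <- match.arg(denominator)
  if (nrow(tally) != 1) abort("false_positive_rate() expects a single tally row")
  den <- if (denominator == "retained") {
    tally$fp + tally$tp
  } else {
    n_total %||% (tally$tp + tally$fp + tally$fn + tally$germline_removed)
  }
  if (den == 0) abort("false positive rate is undefined for a zero denominator")
  tally$fp / den
}

#' Per-patient burden of retained calls
#'
#' Counts retained true positives and false positives per patient over the
#' full roster, including patients whose variants were all removed (or who
#' never had any).
#'
#' @param filtered Output of [apply_filter()].
#' @param patients Character roster of all cohort patients; defaults to the
#'   patients present in `filtered` (supply the roster explicitly so
#'   zero-variant patients enter the denominators).
#' @return A tibble with one row per patient: `patient_id`, `n_tp`, `n_fp`,
#'   `n_retained`, `any_fp`, `only_fp`.
#' @export
per_patient_burden <- function(filtered, patients = NULL) {
  patients <- patients %||% sort(unique(filtered$patient_id))
  per <- filtered |>
    group_by(.data$patient_id) |>
    summarise(
      n_tp = sum(.data$origin == "somatic" & .data$retained),
      n_fp = sum(.data$origin == "germline" & .data$retained),
      .groups = "drop"
    )
  tibble(patient_id = patients) |>
    left_join(per, by = "patient_id") |>
    mutate(
      n_tp = if_else(is.na(.data$n_tp), 0L, as.integer(.data$n_tp)),
      n_fp = if_else(is.na(.data$n_fp), 0L, as.integer(.data$n_fp)),
      n_retained = .data$n_tp + .data$n_fp,
      any_fp = .data$n_fp >= 1,
      only_fp = .data$n_fp >= 1 & .data$n_tp == 0
    )
}

#' Cohort aggregates of the per-patient burden
#'
#' @param burden Output of [per_patient_burden()].
#' @return A one-row tibble: `n_patients`, `n_any_fp`, `prop_any_fp`,
#'   `n_only_fp`, `prop_only_fp`, `n_with_retained`, `mean_retained` (mean
#'   retained calls over patients with at least one retained call, matching
#'   the study's histogram denominator), and `mean_fp_per_patient` (over all
#'   patients).
#' @export
burden_summary <- function(burden) {
  with_retained <- filter(burden, .data$n_retained >= 1)
  tibble(
    n_patients = nrow(burden),
    n_any_fp = sum(burden$any_fp),
    prop_any_fp = mean(burden$any_fp),
    n_only_fp = sum(burden$only_fp),
    prop_only_fp = mean(burden$only_fp),
    n_with_retained = nrow(with_retained),
    mean_retained = if (nrow(with_retained) > 0) mean(with_retained$n_retained) else NA_real_,
    mean_fp_per_patient = mean(burden$n_fp)
  )
}

#' False positive impact on drug-targetable genes
#'
#' For each regime and each gene with a targeting drug, counts the patients
#' with at least one retained germline variant (false positive) in that gene
#' — a patient counts once per gene no matter how many false positives they
#' carry there. A per-regime `"ANY"` row gives the number of unique patients
#' with a false positive in any mapped gene (deduplicated across genes).
#'
#' @param filtered_by_regime A named list of [apply_filter()] outputs, one
#'   per regime.
#' @param drug_map A tibble from [drug_target_map()].
#' @return A tibble with columns `regime`, `gene`, `n_patients_fp`. Genes in
#'   the map with no false positives report 0; genes absent from the map are
#'   not reported.
#' @export
druggable_impact <- function(filtered_by_regime, drug_map = drug_target_map()) {
  genes <- sort(unique(drug_map$gene))
  purrr::imap_dfr(filtered_by_regime, function(filtered, regime_name) {
    fp <- filter(
      filtered,
      .data$origin == "germline", .data$retained, .data$gene %in% genes
    )
    per_gene <- fp |>
      distinct(.data$gene, .data$patient_id) |>
      count(.data$gene, name = "n_patients_fp")
    tibble(gene = genes) |>
      left_join(per_gene, by = "gene") |>
      mutate(
        n_patients_fp = if_else(is.na(.data$n_patients_fp), 0L,
          as.integer(.data$n_patients_fp))
      ) |>
      bind_rows(tibble(gene = "ANY", n_patients_fp = n_distinct(fp$patient_id))) |>
      mutate(regime = regime_name) |>
      relocate("regime")
  })
}
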