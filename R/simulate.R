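#' Configuration of a synthetic paired tumor/normal cohort
#'
#' Describes the population and assay the simulator emulates. The germline
#' spectrum has three tiers of fixed site pools per gene: common SNPs
#' (population AF above 0.02, carried under Hardy-Weinberg carrier
#' probability 1 - (1 - af)^2), low-frequency SNPs (AF between the lowest
#' filter cutoff and ~0.01, the tier that separates the AF >= 0.01 and
#' AF >= 0.001 regimes), and rare/private variants (AF below 0.001, placed
#' per patient at random positions — the irreducible false positive source).
#' Somatic events are drawn per patient, genes chosen proportionally to CDS
#' length with an enrichment multiplier for tumor-driver genes, and a
#' fraction of events recur at four fixed hotspot sites (two in KRAS, two in
#' PIK3CA, emulating the recurrent common somatic drivers of the reference
#' cohort). Database annotation is deliberately incomplete, and in-database
#' sites can lack a reported frequency, exercising the rescue-rule path.
#' Tier AFs are a fixed, evenly spaced grid over their range, so the
#' population (and hence every expectation in [expected_fractions()]) is
#' fully determined by the configuration, not by the seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param panel A [gene_panel()].
#' @param common_snp_count_per_gene,common_af_range Common-SNP pool size per
#'   gene and AF range (within (0.02, 0.5]).
#' @param low_snp_count_per_gene,low_af_range Low-frequency pool size per
#'   gene and AF range (between 0.001 and 0.02).
#' @param rare_snp_rate_per_kb,rare_af_range Expected rare/private variants
#'   per patient per kb of CDS, and their AF range (within (0, 0.001)).
#' @param somatic_rate_per_patient Mean somatic mutations per patient.
#' @param driver_enrichment Multiplier on the somatic gene-choice weight of
#'   tumor-driver genes.
#' @param hotspot_fraction Fraction of somatic events drawn from the fixed
#'   recurrent-site list.
#' @param db_annotation_completeness Probability a germline site is in the
#'   population database.
#' @param af_missing_given_in_db Probability an in-database germline site has
#'   no reported frequency.
#' @param somatic_in_db_rate Probability a somatic hotspot site is in the
#'   database (always with frequency absent).
#' @param expression_dropout_somatic,expression_dropout_germline Probability
#'   a variant is not expressed in tumor RNA (somatic mutations disrupt
#'   transcription more often than inherited variants: ~18% vs ~10%).
#' @param tumor_depth_mean,normal_depth_mean,rna_depth_mean Read depths
#'   (tumor ~60x, normal ~30x per the reference assay; RNA 50x).
#' @param nonsense_fraction Fraction of variants emitted as nonsense (rest
#'   missense).
#' @param sequencing_noise If `FALSE` (default) read evidence is
#'   deterministic given depth, so classification tests are exact; if `TRUE`,
#'   depths are Poisson and alt reads Binomial (normal-sample error rate
#'   0.001 at somatic sites).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          panel = gene_panel(),
                          common_snp_count_per_gene = 1L,
                          common_af_range = c(0.02, 0.50),
                          low_snp_count_per_gene = 3L,
                          low_af_range = c(0.001, 0.008),
                          rare_snp_rate_per_kb = 0.01,
                          rare_af_range = c(1e-5, 9e-4),
                          somatic_rate_per_patient = 0.9,
                          driver_enrichment = 3,
                          hotspot_fraction = 0.4,
                          db_annotation_completeness = 0.98,
                          af_missing_given_in_db = 0.05,
                          somatic_in_db_rate = 0.9,
                          expression_dropout_somatic = 0.18,
                          expression_dropout_germline = 0.10,
                          tumor_depth_mean = 60,
                          normal_depth_mean = 30,
                          rna_depth_mean = 50,
                          nonsense_fraction = 0.1,
                          sequencing_noise = FALSE,
                          seed = 1L) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (!inherits(panel, "gene_panel") || nrow(panel$genes) == 0) {
    abort("a non-empty gene_panel is required")
  }
  check_range <- function(r, lo, hi, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      abort(sprintf("%s must be an ordered interval within [%g, %g]", what, lo, hi))
    }
  }
  check_range(common_af_range, 0.02, 0.5, "common_af_range")
  check_range(low_af_range, 0.001, 0.02, "low_af_range")
  check_range(rare_af_range, 1e-8, 0.001, "rare_af_range")
  probs <- c(
    hotspot_fraction, db_annotation_completeness, af_missing_given_in_db,
    somatic_in_db_rate, expression_dropout_somatic, expression_dropout_germline,
    nonsense_fraction
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (rare_snp_rate_per_kb < 0 || somatic_rate_per_patient < 0) {
    abort("rates must be non-negative")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), panel = panel,
      common_snp_count_per_gene = as.integer(common_snp_count_per_gene),
      common_af_range = common_af_range,
      low_snp_count_per_gene = as.integer(low_snp_count_per_gene),
      low_af_range = low_af_range,
      rare_snp_rate_per_kb = rare_snp_rate_per_kb,
      rare_af_range = rare_af_range,
      somatic_rate_per_patient = somatic_rate_per_patient,
      driver_enrichment = driver_enrichment,
      hotspot_fraction = hotspot_fraction,
      db_annotation_completeness = db_annotation_completeness,
      af_missing_given_in_db = af_missing_given_in_db,
      somatic_in_db_rate = somatic_in_db_rate,
      expression_dropout_somatic = expression_dropout_somatic,
      expression_dropout_germline = expression_dropout_germline,
      tumor_depth_mean = tumor_depth_mean,
      normal_depth_mean = normal_depth_mean,
      rna_depth_mean = rna_depth_mean,
      nonsense_fraction = nonsense_fraction,
      sequencing_noise = isTRUE(sequencing_noise),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Configuration emulating the reference study's cohort structure
#'
#' The default [cohort_config()] values are tuned once to the reference
#' study's marginal structure — an expected germline:somatic variant mix of
#' ~95:5 (~17 germline and ~0.9 somatic variants per patient), a pool of
#' cohort-common SNPs above the 0.02 carrier threshold, recurrent somatic
#' hotspots carrying database records but no reported frequency (so the AF
#' regimes produce zero false negatives), and expression dropout of 18%
#' (somatic) / 10% (germline). This constructor just names that stated world.
#'
#' @param n_patients Cohort size (default 600, near the reference 621).
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
reference_config <- function(n_patients = 600L, seed = 1L) {
  cohort_config(n_patients = n_patients, seed = seed)
}

#' Analytic expectations implied by a cohort configuration
#'
#' Expected germline and somatic variant counts per patient and the expected
#' germline fraction, computed in closed form from the fixed site-pool AF
#' grids (carrier probability 1 - (1 - af)^2 per site) and the configured
#' rates. Used by parameter-recovery tests as the "configured" value that a
#' generated cohort must reproduce within binomial sampling error.
#'
#' @param config A [cohort_config()].
#' @return A one-row tibble: `germline_per_patient`, `somatic_per_patient`,
#'   `germline_fraction`.
#' @export
expected_fractions <- function(config) {
  pools <- germline_site_pool(config)
  e_pool <- sum(1 - (1 - pools$af)^2)
  e_rare <- config$rare_snp_rate_per_kb * sum(config$panel$genes$cds_length) / 1000
  e_g <- e_pool + e_rare
  e_s <- config$somatic_rate_per_patient
  tibble(
    germline_per_patient = e_g,
    somatic_per_patient = e_s,
    germline_fraction = e_g / (e_g + e_s)
  )
}

# Deterministic fixed site pools (common + low-frequency tiers). Positions
# are evenly spaced inside each gene's first interval; AFs are an evenly
# spaced grid over the tier range, assigned in gene order. Tiers use distinct
# ref/alt pairs so keys never collide across tiers.
germline_site_pool <- function(config) {
  panel <- config$panel
  iv <- panel$intervals[!duplicated(panel$intervals$gene), ]
  iv <- iv[match(panel$genes$gene, iv$gene), ]
  tier_pool <- function(count, af_range, frac_offset, ref, alt, tier) {
    if (count == 0) return(NULL)
    n_sites <- nrow(iv) * count
    afs <- if (n_sites == 1) mean(af_range) else {
      seq(af_range[1], af_range[2], length.out = n_sites)
    }
    k <- rep(seq_len(count), times = nrow(iv))
    g <- rep(seq_len(nrow(iv)), each = count)
    span <- iv$end[g] - iv$start[g]
    tibble(
      gene = iv$gene[g],
      contig = iv$contig[g],
      pos = as.integer(iv$start[g] + pmax(1L, floor(span * (k + frac_offset) / (count + 1)))),
      ref = ref, alt = alt, af = afs, tier = tier
    )
  }
  bind_rows(
    tier_pool(config$common_snp_count_per_gene, config$common_af_range,
      0, "G", "A", "common"),
    tier_pool(config$low_snp_count_per_gene, config$low_af_range,
      0.31, "T", "C", "low")
  )
}

# Fixed recurrent somatic hotspot sites: two in KRAS, two in PIK3CA.
hotspot_sites <- function(config) {
  panel <- config$panel
  hs_genes <- intersect(c("KRAS", "PIK3CA"), panel$genes$gene)
  if (length(hs_genes) == 0) hs_genes <- panel$genes$gene[1]
  purrr::map_dfr(hs_genes, function(g) {
    iv <- filter(panel$intervals, .data$gene == g)[1, ]
    span <- iv$end - iv$start
    tibble(
      gene = g, contig = iv$contig,
      pos = as.integer(iv$start + floor(span * c(0.21, 0.73))),
      ref = "G", alt = "T"
    )
  })
}

#' Generate a synthetic paired tumor/normal cohort with ground truth
#'
#' Draws a full cohort from the configured population: germline carriers from
#' the fixed site pools plus per-patient rare variants, somatic events with
#' driver enrichment and recurrent hotspots, matched tumor/normal read
#' evidence (germline normal VAF ~0.5; somatic normal alt 0), a population
#' annotation table with configurable incompleteness, and RNA allele counts
#' with origin-specific expression dropout (a dropped-out variant contributes
#' zero alt reads). Every emitted variant has exactly one truth record; truth
#' never leaks into the emitted inputs (use [truth_labeled_variants()]
#' explicitly for fixture mode).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `variants` (origin
#'   `"unassigned"`), `annotations`, `rna_counts`, `truth`, `site_pool`,
#'   `hotspots`, and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- config$panel
  genes <- panel$genes
  iv <- panel$intervals[!duplicated(panel$intervals$gene), ]
  iv <- iv[match(genes$gene, iv$gene), ]
  n_pat <- config$n_patients
  patients <- sprintf("P%04d", seq_len(n_pat))
  pool <- germline_site_pool(config)
  hs <- hotspot_sites(config)

  withr::with_seed(config$seed, {
    # --- germline: fixed-pool carriers -------------------------------------
    n_sites <- nrow(pool)
    carrier_p <- 1 - (1 - pool$af)^2
    draws <- rbinom(n_sites * n_pat, 1L, rep(carrier_p, times = n_pat))
    hit <- which(draws == 1L)
    site_i <- ((hit - 1L) %% n_sites) + 1L
    pat_i <- ((hit - 1L) %/% n_sites) + 1L
    pool_vars <- tibble(
      patient_id = patients[pat_i],
      contig = pool$contig[site_i], pos = pool$pos[site_i],
      ref = pool$ref[site_i], alt = pool$alt[site_i],
      gene = pool$gene[site_i],
      true_origin = "germline",
      population_af_true = pool$af[site_i]
    )
    # --- germline: rare/private variants -----------------------------------
    lambda <- config$rare_snp_rate_per_kb * genes$cds_length / 1000
    rc <- rpois(nrow(genes) * n_pat, rep(lambda, times = n_pat))
    nz <- which(rc > 0)
    gene_i <- rep(((nz - 1L) %% nrow(genes)) + 1L, rc[nz])
    rpat_i <- rep(((nz - 1L) %/% nrow(genes)) + 1L, rc[nz])
    span <- iv$end[gene_i] - iv$start[gene_i]
    rare_vars <- tibble(
      patient_id = patients[rpat_i],
      contig = iv$contig[gene_i],
      pos = as.integer(iv$start[gene_i] + floor(runif(length(gene_i)) * span)),
      ref = "C", alt = "T",
      gene = genes$gene[gene_i],
      true_origin = "germline",
      population_af_true = runif(length(gene_i),
        config$rare_af_range[1], config$rare_af_range[2])
    ) |>
      distinct(.data$patient_id, .data$contig, .data$pos, .data$ref, .data$alt,
        .keep_all = TRUE)
    # --- somatic events -----------------------------------------------------
    sc <- rpois(n_pat, config$somatic_rate_per_patient)
    spat_i <- rep(seq_len(n_pat), sc)
    n_som <- length(spat_i)
    som_vars <- NULL
    if (n_som > 0) {
      is_hot <- rbinom(n_som, 1L, config$hotspot_fraction) == 1L
      hs_idx <- sample.int(nrow(hs), n_som, replace = TRUE)
      w <- genes$cds_length *
        if_else(genes$panel_class == "tumor_driver", config$driver_enrichment, 1)
      g_idx <- sample.int(nrow(genes), n_som, replace = TRUE, prob = w / sum(w))
      span_s <- iv$end[g_idx] - iv$start[g_idx]
      rnd_pos <- as.integer(iv$start[g_idx] + floor(runif(n_som) * span_s))
      som_vars <- tibble(
        patient_id = patients[spat_i],
        contig = if_else(is_hot, hs$contig[hs_idx], iv$contig[g_idx]),
        pos = if_else(is_hot, hs$pos[hs_idx], rnd_pos),
        ref = if_else(is_hot, hs$ref[hs_idx], "A"),
        alt = if_else(is_hot, hs$alt[hs_idx], "T"),
        gene = if_else(is_hot, hs$gene[hs_idx], genes$gene[g_idx]),
        true_origin = "somatic",
        population_af_true = NA_real_
      ) |>
        distinct(.data$patient_id, .data$contig, .data$pos, .data$ref, .data$alt,
          .keep_all = TRUE)
    }
    all_vars <- bind_rows(pool_vars, rare_vars, som_vars) |>
      arrange(.data$patient_id, .data$gene, .data$contig, .data$pos, .data$alt)
    n_var <- nrow(all_vars)
    if (n_var == 0) abort("configuration generated an empty cohort")

    # --- read evidence ------------------------------------------------------
    is_germ <- all_vars$true_origin == "germline"
    t_vaf <- if_else(is_germ, 0.5, 0.4)
    if (config$sequencing_noise) {
      td <- rpois(n_var, config$tumor_depth_mean)
      nd <- rpois(n_var, config$normal_depth_mean)
      ta <- rbinom(n_var, td, t_vaf)
      na_ <- rbinom(n_var, nd, if_else(is_germ, 0.5, 0.001))
    } else {
      td <- rep(as.integer(round(config$tumor_depth_mean)), n_var)
      nd <- rep(as.integer(round(config$normal_depth_mean)), n_var)
      ta <- as.integer(round(td * t_vaf))
      na_ <- if_else(is_germ, as.integer(round(nd * 0.5)), 0L)
    }
    consequence <- if_else(
      rbinom(n_var, 1L, config$nonsense_fraction) == 1L, "nonsense", "missense"
    )
    variants <- all_vars |>
      mutate(
        consequence = consequence,
        tumor_depth = as.integer(td), tumor_alt = as.integer(ta),
        normal_depth = as.integer(nd), normal_alt = as.integer(na_),
        origin = "unassigned"
      ) |>
      select(dplyr::all_of(variant_cols))

    # --- population annotation table ---------------------------------------
    germ_sites <- bind_rows(
      select(pool, "contig", "pos", "ref", "alt", "af"),
      all_vars |>
        filter(.data$true_origin == "germline", .data$ref == "C") |>
        distinct(.data$contig, .data$pos, .data$ref, .data$alt,
          af = .data$population_af_true)
    )
    g_in_db <- rbinom(nrow(germ_sites), 1L, config$db_annotation_completeness) == 1L
    g_af_missing <- rbinom(nrow(germ_sites), 1L, config$af_missing_given_in_db) == 1L
    hs_in_db <- rbinom(nrow(hs), 1L, config$somatic_in_db_rate) == 1L
    annotations <- bind_rows(
      germ_sites |>
        mutate(
          in_database = g_in_db,
          population_af = if_else(g_in_db & !g_af_missing, .data$af, NA_real_)
        ) |>
        select(-"af"),
      hs |>
        mutate(in_database = hs_in_db, population_af = NA_real_) |>
        select("contig", "pos", "ref", "alt", "in_database", "population_af")
    ) |>
      distinct(.data$contig, .data$pos, .data$ref, .data$alt, .keep_all = TRUE) |>
      arrange(.data$contig, .data$pos, .data$ref, .data$alt)

    # --- RNA allele counts with expression dropout -------------------------
    dropout_p <- if_else(is_germ,
      config$expression_dropout_germline, config$expression_dropout_somatic)
    expressed <- rbinom(n_var, 1L, 1 - dropout_p) == 1L
    if (config$sequencing_noise) {
      rd <- rpois(n_var, config$rna_depth_mean)
      ra <- rbinom(n_var, rd, if_else(expressed, t_vaf, 0.001))
    } else {
      rd <- rep(as.integer(round(config$rna_depth_mean)), n_var)
      ra <- if_else(expressed, as.integer(round(rd * t_vaf)), 0L)
    }
    rna_counts <- all_vars |>
      select("patient_id", "contig", "pos", "ref", "alt") |>
      mutate(rna_depth = as.integer(rd), rna_alt = as.integer(ra))

    truth <- all_vars |>
      mutate(true_expressed = expressed) |>
      select("patient_id", "contig", "pos", "ref", "alt", "gene",
        "true_origin", "true_expressed", "population_af_true")
  })

  structure(
    list(
      variants = variants, annotations = annotations, rna_counts = rna_counts,
      truth = truth, site_pool = pool, hotspots = hs, config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d variants (%d germline, %d somatic), seed %d\n",
    x$config$n_patients, nrow(x$variants),
    sum(x$truth$true_origin == "germline"),
    sum(x$truth$true_origin == "somatic"),
    x$config$seed
  ))
  invisible(x)
}

#' Variants with trusted origin labels from synthetic truth
#'
#' Joins the ground-truth origin onto the emitted variant table for use in
#' fixture mode (`classify_cohort(..., fixture_mode = TRUE)`), keeping the
#' leak explicit.
#'
#' @param cohort A [generate_cohort()] result.
#' @return The variant tibble with `origin` set to the true origin.
#' @export
truth_labeled_variants <- function(cohort) {
  cohort$variants |>
    select(-"origin") |>
    left_join(
      select(cohort$truth, "patient_id", "contig", "pos", "ref", "alt",
        origin = "true_origin"),
      by = c("patient_id", "contig", "pos", "ref", "alt")
    )
}

#' Write a synthetic cohort to tab-separated files
#'
#' Emits `variants.tsv`, `annotations.tsv`, `rna_counts.tsv` and `truth.tsv`
#' in the formats read back by [read_variant_table()],
#' [read_annotation_table()] and [read_rna_table()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_stable(cohort$variants, file.path(dir, "variants.tsv"))
  ann <- mutate(cohort$annotations, in_database = as.integer(.data$in_database))
  write_tsv_stable(ann, file.path(dir, "annotations.tsv"))
  write_tsv_stable(cohort$rna_counts, file.path(dir, "rna_counts.tsv"))
  write_tsv_stable(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
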