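# Shared fixture builders: everything is constructed in code at test time.

# A minimal variant row with sane matched-pair evidence; override any field.
make_variant <- function(patient_id = "P1", contig = "7", pos = 55249071L,
                         ref = "C", alt = "T", gene = "EGFR",
                         consequence = "missense",
                         tumor_depth = 60L, tumor_alt = 24L,
                         normal_depth = 30L, normal_alt = 0L,
                         origin = "unassigned") {
  tibble::tibble(
    patient_id = patient_id, contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt, gene = gene, consequence = consequence,
    tumor_depth = as.integer(tumor_depth), tumor_alt = as.integer(tumor_alt),
    normal_depth = as.integer(normal_depth), normal_alt = as.integer(normal_alt),
    origin = origin
  )
}

make_annotation <- function(contig = "7", pos = 55249071L, ref = "C", alt = "T",
                            in_database = TRUE, population_af = NA_real_) {
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
    in_database = in_database, population_af = population_af
  )
}

# Write a small single-sample VCF as text; records = data.frame with
# chrom, pos, ref, alt (comma-joined for multi-allelic), ad (e.g. "40,20"),
# conseq.
write_mini_vcf <- function(path, records, sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CONSEQ,Number=1,Type=String,Description="Coding consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO", "FORMAT", sample), collapse = "\t"))
  )
  body <- apply(records, 1, function(r) {
    paste(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]], ".", "PASS",
      paste0("CONSEQ=", r[["conseq"]]), "GT:AD", paste0("0/1:", r[["ad"]]),
      sep = "\t")
  })
  writeLines(c(header, body), path)
  path
}

# Independent brute-force re-evaluation of a tumor-only filter: one explicit
# decision per variant, no set operations, no shared code with apply_filter().
oracle_removed <- function(variants, annotations, regime, common_sites) {
  germ_common <- character(0)
  if (!is.null(common_sites)) {
    for (i in seq_len(nrow(common_sites))) {
      if (common_sites$n_germline[i] >= 1) {
        germ_common <- c(germ_common, paste(common_sites$contig[i],
          common_sites$pos[i], common_sites$ref[i], common_sites$alt[i]))
      }
    }
  }
  removed <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    k <- paste(variants$contig[i], variants$pos[i], variants$ref[i], variants$alt[i])
    in_db <- FALSE
    af <- NA_real_
    for (j in seq_len(nrow(annotations))) {
      kj <- paste(annotations$contig[j], annotations$pos[j], annotations$ref[j],
        annotations$alt[j])
      if (kj == k) {
        in_db <- annotations$in_database[j]
        af <- annotations$population_af[j]
        break
      }
    }
    if (regime$kind == "database_membership") {
      removed[i] <- in_db
    } else if (regime$kind == "af_threshold") {
      if (!is.na(af) && af >= regime$af_cutoff) {
        removed[i] <- TRUE
      } else if (isTRUE(regime$rescue) && is.na(af) && in_db && k %in% germ_common) {
        removed[i] <- TRUE
      }
    }
  }
  removed
}

# Brute-force confusion counts from labeled variants + removal flags.
oracle_tally <- function(variants, removed) {
  tp <- fp <- fn <- gr <- 0L
  for (i in seq_len(nrow(variants))) {
    if (variants$origin[i] == "somatic") {
      if (removed[i]) fn <- fn + 1L else tp <- tp + 1L
    } else {
      if (removed[i]) gr <- gr + 1L else fp <- fp + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, germline_removed = gr)
}

# Random small labeled cohort + annotations + common-site list, for oracle
# equivalence tests. Annotation states cover: absent, in_db no AF, in_db with
# AF across the cutoffs.
random_small_cohort <- function(n_max = 50) {
  n <- sample(5:n_max, 1)
  genes <- c("EGFR", "KRAS", "RET", "APC")
  pos <- sample(1e6, n)
  variants <- tibble::tibble(
    patient_id = sprintf("P%d", sample(8, n, replace = TRUE)),
    contig = sample(c("1", "7"), n, replace = TRUE),
    pos = as.integer(pos), ref = "A", alt = "C",
    gene = sample(genes, n, replace = TRUE),
    consequence = "missense",
    tumor_depth = 60L, tumor_alt = 24L, normal_depth = 30L,
    normal_alt = 0L,
    origin = sample(c("germline", "somatic"), n, replace = TRUE, prob = c(.8, .2))
  )
  sites <- dplyr::distinct(variants, contig, pos, ref, alt)
  state <- sample(4, nrow(sites), replace = TRUE)
  annotations <- sites[state > 1, ]
  if (nrow(annotations) > 0) {
    st <- state[state > 1]
    annotations$in_database <- TRUE
    annotations$population_af <- dplyr::case_when(
      st == 2 ~ NA_real_,
      st == 3 ~ runif(length(st), 0.0002, 0.005),
      TRUE ~ runif(length(st), 0.02, 0.5)
    )
  } else {
    annotations <- make_annotation()[0, ]
  }
  common_sites <- variants |>
    dplyr::group_by(contig, pos, ref, alt) |>
    dplyr::summarise(
      n_germline = sum(origin == "germline"),
      n_somatic = sum(origin == "somatic"), .groups = "drop"
    ) |>
    dplyr::slice_sample(prop = 0.5)
  list(variants = variants, annotations = annotations, common_sites = common_sites)
}
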