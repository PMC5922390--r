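# Internal helpers shared across modules.

# Canonical string identity of an SNV site. Site identity for unique-site
# collapsing uses all four fields (contig, 1-based position, ref, alt).
key_str <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# Round half away from zero (the convention used for printed percentages in
# clinical report tables); base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Integer percent from a count pair; NA when the denominator is zero so a
# gene with no variants renders blank rather than 0%.
int_pct <- function(num, den) {
  if_else(den > 0, round_half_up(100 * num / den), NA_real_)
}

variant_cols <- c(
  "patient_id", "contig", "pos", "ref", "alt", "gene", "consequence",
  "tumor_depth", "tumor_alt", "normal_depth", "normal_alt", "origin"
)

stop_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
}

# Shared invariant checks for a variant table. SNVs only: ref and alt are
# single bases and differ; alt read support never exceeds depth.
validate_variants <- function(variants, panel = NULL) {
  stop_cols(variants, variant_cols, "variant table")
  bad_snv <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
    variants$ref == variants$alt
  if (any(bad_snv)) {
    abort(sprintf(
      "%d record(s) are not single-nucleotide variants (ref/alt must be single, differing bases)",
      sum(bad_snv)
    ))
  }
  if (any(variants$pos < 1)) abort("positions must be >= 1 (1-based coordinates)")
  bad_counts <- variants$tumor_alt > variants$tumor_depth |
    variants$normal_alt > variants$normal_depth |
    variants$tumor_alt < 0 | variants$normal_alt < 0
  if (any(bad_counts)) {
    abort(sprintf(
      "alt read counts exceed depth (or are negative) in row(s): %s",
      paste(head(which(bad_counts), 10), collapse = ", ")
    ))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(variants$gene), panel$genes$gene)
    if (length(unknown) > 0) {
      rows <- which(variants$gene %in% unknown)
      abort(sprintf(
        "gene symbol(s) not in panel: %s (row(s) %s)",
        paste(unknown, collapse = ", "),
        paste(head(rows, 10), collapse = ", ")
      ))
    }
  }
  invisible(variants)
}

# yaml::write_yaml / readr::write_tsv produce platform-stable bytes; all report
# writers funnel through here so output is byte-identical across runs.
write_tsv_stable <- function(df, path) {
  readr::write_tsv(df, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}
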