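#' Heuristic-genotype / Fisher exact caller configuration
#'
#' Mirrors the VarScan2-style design: each sample is genotyped
#' heuristically from its variant allele proportion, and where the two
#' genotypes disagree a one-tailed Fisher exact test on the 2x2 read
#' count table decides significance.
#'
#' @param min_var_freq minimum variant frequency for a variant genotype
#'   (default 0.20; variant proportions below it are homozygous
#'   reference).
#' @param hom_threshold proportion at or above which the genotype is
#'   homozygous variant (default 0.75).
#' @param min_base_quality base-quality cutoff for counted reads
#'   (default 15).
#' @param p_threshold Fisher p-value for inclusion (default 0.05).
#' @param min_variant_reads minimum supporting reads for a variant
#'   genotype (default 2).
#' @return a `varscan_config` list.
#' @export
varscan_config <- function(min_var_freq = 0.20, hom_threshold = 0.75,
                           min_base_quality = 15, p_threshold = 0.05,
                           min_variant_reads = 2L) {
  stopifnot(min_var_freq > 0, min_var_freq < hom_threshold,
            hom_threshold < 1, min_base_quality >= 0,
            p_threshold > 0, p_threshold <= 1, min_variant_reads >= 0)
  structure(list(min_var_freq = min_var_freq, hom_threshold = hom_threshold,
                 min_base_quality = min_base_quality,
                 p_threshold = p_threshold,
                 min_variant_reads = as.integer(min_variant_reads)),
            class = "varscan_config")
}

# One-tailed Fisher exact p that the "enriched" sample's variant count is
# at least as extreme as observed, given fixed margins: hypergeometric
# upper tail.
.fisher_one_tailed <- function(v_enriched, ref_enriched, v_other, ref_other) {
  V <- v_enriched + v_other
  N <- V + ref_enriched + ref_other
  k <- v_enriched + ref_enriched
  stats::phyper(v_enriched - 1L, V, N - V, k, lower.tail = FALSE)
}

.varscan_genotype <- function(cnt, cfg) {
  tot <- cnt$v + cnt$ref_count
  if (tot == 0L) return(NA_character_)
  vp <- cnt$v / tot
  if (vp >= cfg$min_var_freq && cnt$v >= cfg$min_variant_reads) {
    if (vp < cfg$hom_threshold) "AB" else "BB"
  } else "AA"
}

.varscan_core <- function(nr, tr, ref, cfg) {
  st <- summarize_alleles(tr, ref, cfg$min_base_quality)
  vb <- st$variant_base
  if (is.na(vb)) vb <- summarize_alleles(nr, ref, cfg$min_base_quality)$variant_base
  cn <- .count_base(nr, ref, vb, cfg$min_base_quality)
  ct <- .count_base(tr, ref, vb, cfg$min_base_quality)
  gN <- .varscan_genotype(cn, cfg)
  gT <- .varscan_genotype(ct, cfg)
  if (is.na(gN) || is.na(gT) || gN == gT) return(NULL)  # zero depth or match
  if (gN == "AA") {  # somatic direction: tumour variant enrichment
    p <- .fisher_one_tailed(ct$v, ct$ref_count, cn$v, cn$ref_count)
    class <- "somatic"
  } else {           # LOH direction: normal variant enrichment
    p <- .fisher_one_tailed(cn$v, cn$ref_count, ct$v, ct$ref_count)
    class <- if (gN == "AB") "LOH" else "unknown"
  }
  list(class = class, score = 1 - p, p = p, phred_score = NULL,
       normal_gt = gN, tumour_gt = gT, variant_base = vb, n = cn, t = ct)
}

#' Call one site with the heuristic-genotype / Fisher caller
#'
#' Each sample is genotyped from its variant proportion at the chosen
#' variant base (tumour's most common variant base, falling back to the
#' normal's): homozygous reference below `min_var_freq`, heterozygous up
#' to `hom_threshold`, homozygous variant above, requiring
#' `min_variant_reads` supporting reads. When the genotypes differ, a
#' one-tailed Fisher exact test on the (ref, variant) x (normal, tumour)
#' table gives p; the class is somatic if the normal is homozygous
#' reference, LOH if heterozygous, unknown if homozygous variant. The
#' score is 1 - p. Matching genotypes or a zero-depth sample yield no
#' call (`NULL`); `p_threshold` is applied by [run_all_callers()], not
#' here.
#'
#' @param site a [paired_site()].
#' @param cfg a [varscan_config()].
#' @return a one-row `candidate_calls` data.frame, or `NULL`.
#' @export
call_varscan <- function(site, cfg = varscan_config()) {
  res <- .varscan_core(.reads_as_list(site$normal), .reads_as_list(site$tumour),
                       site$ref, cfg)
  if (is.null(res)) return(NULL)
  .as_candidate_calls(.call_row(site$chrom, site$pos, "varscan", res$class,
                                res$score, res$phred_score, res$normal_gt,
                                res$tumour_gt, res$variant_base, res$n, res$t))
}
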