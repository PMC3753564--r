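BASES <- c("A", "C", "G", "T")

# row b, columns = the three bases that are not b
ALT_BASES <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                      "A", "C", "G"), nrow = 4, byrow = TRUE,
                    dimnames = list(BASES, NULL))

#' Summarize allele evidence at one site
#'
#' Selects the variant allele and counts supporting reads. The variant
#' base is the single most frequent non-reference base among observations
#' passing the base-quality cutoff, excluding `N` calls and reads whose
#' alignment deletes the site (a deleted base has no base call). Ties
#' between equally frequent candidate bases are broken by the fixed order
#' A < C < G < T, for determinism. Multi-allelic evidence beyond the top
#' variant base is ignored.
#'
#' @param reads a read-observation data.frame (see [paired_pileup()]), or
#'   the `normal`/`tumour` component of a `paired_site`.
#' @param ref reference base, one of A/C/G/T.
#' @param min_base_quality minimum phred base quality for an observation
#'   to contribute to allele counts (depth counts all observations).
#' @return an `allele_summary` list: `variant_base` (NA if no variant
#'   evidence), `v` (variant read count), `ref_count`, `v_forward`,
#'   `v_reverse`, `variant_proportion` = v / (v + ref_count) (0 when the
#'   denominator is 0), and `depth` (all observations, including `N` and
#'   spanning deletions).
#' @export
summarize_alleles <- function(reads, ref, min_base_quality = 0) {
  stopifnot(ref %in% BASES, min_base_quality >= 0)
  r <- if (is.data.frame(reads)) .reads_as_list(reads) else reads
  if (is.null(r) || length(r$base) == 0L)
    return(.allele_summary(NA_character_, 0L, 0L, 0L, 0L, 0L))
  ok <- !r$spans_deletion & r$base != "N" & r$baseq >= min_base_quality
  counts <- c(sum(ok & r$base == "A"), sum(ok & r$base == "C"),
              sum(ok & r$base == "G"), sum(ok & r$base == "T"))
  names(counts) <- BASES
  ref_count <- counts[[ref]]
  counts[ref] <- -1L  # exclude reference from the variant argmax
  vb <- BASES[which.max(counts)]  # first max = alphabetical tie-break
  v <- counts[[vb]]
  if (v <= 0L)
    return(.allele_summary(NA_character_, 0L, ref_count, 0L, 0L,
                           length(r$base)))
  is_v <- ok & r$base == vb
  .allele_summary(vb, v, ref_count, sum(is_v & r$strand == "+"),
                  sum(is_v & r$strand == "-"), length(r$base))
}

.allele_summary <- function(vb, v, ref_count, vf, vr, depth) {
  structure(list(
    variant_base = vb, v = as.integer(v), ref_count = as.integer(ref_count),
    v_forward = as.integer(vf), v_reverse = as.integer(vr),
    variant_proportion = if (v + ref_count > 0) v / (v + ref_count) else 0,
    depth = as.integer(depth)), class = "allele_summary")
}

#' @export
print.allele_summary <- function(x, ...) {
  cat(sprintf(
    "allele_summary: variant=%s v=%d (%d+/%d-) ref=%d vaf=%.4f depth=%d\n",
    ifelse(is.na(x$variant_base), ".", x$variant_base), x$v, x$v_forward,
    x$v_reverse, x$ref_count, x$variant_proportion, x$depth))
  invisible(x)
}

# Counts of one specific base vs the reference, used where two samples
# must be tallied against the same variant base (Fisher table, VCF AD).
.count_base <- function(r, ref, base, min_base_quality = 0) {
  if (is.null(r) || length(r$base) == 0L)
    return(list(ref_count = 0L, v = 0L, v_forward = 0L, v_reverse = 0L,
                depth = 0L))
  ok <- !r$spans_deletion & r$base != "N" & r$baseq >= min_base_quality
  is_v <- if (is.na(base)) rep(FALSE, length(r$base)) else ok & r$base == base
  list(ref_count = sum(ok & r$base == ref), v = sum(is_v),
       v_forward = sum(is_v & r$strand == "+"),
       v_reverse = sum(is_v & r$strand == "-"), depth = length(r$base))
}
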