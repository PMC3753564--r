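FILTER_RULES <- c("strand_bias", "mean_baseq", "max_baseq", "mean_mapq",
                  "max_mapq", "nearby_snvs", "spanning_deletion",
                  "adjacent_indel")

#' Post-calling filter thresholds
#'
#' The eight removal rules applied to raw candidates, evaluated on the
#' relevant sample's variant reads (tumour for somatic candidates,
#' normal for LOH): (1) all variant reads on one strand; (2) mean
#' variant base quality below `min_mean_baseq`; (3) no variant base
#' quality strictly over `min_max_baseq`; (4) mean variant mapping
#' quality below `min_mean_mapq`; (5) no variant mapping quality
#' strictly over `min_max_mapq`; (6) more than `max_nearby_snvs` other
#' candidate positions within `snv_window` bp either side; (7)
#' spanning-deletion reads above `max_spanning_deletion_fraction` of
#' overall depth in either sample; (8) adjacent-indel reads above
#' `max_adjacent_indel_fraction` of reads in either sample. "Over" and
#' "below" are strict inequalities.
#'
#' @param min_mean_baseq,min_max_baseq,min_mean_mapq,min_max_mapq phred
#'   thresholds (defaults 15, 30, 15, 40).
#' @param snv_window window half-width in bp (default 50, inclusive).
#' @param max_nearby_snvs allowed candidate neighbours (default 2).
#' @param max_spanning_deletion_fraction,max_adjacent_indel_fraction
#'   depth fractions (default 0.20).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_mean_baseq = 15, min_max_baseq = 30,
                          min_mean_mapq = 15, min_max_mapq = 40,
                          snv_window = 50L, max_nearby_snvs = 2L,
                          max_spanning_deletion_fraction = 0.20,
                          max_adjacent_indel_fraction = 0.20) {
  cfg <- list(min_mean_baseq = min_mean_baseq, min_max_baseq = min_max_baseq,
              min_mean_mapq = min_mean_mapq, min_max_mapq = min_max_mapq,
              snv_window = as.integer(snv_window),
              max_nearby_snvs = as.integer(max_nearby_snvs),
              max_spanning_deletion_fraction = max_spanning_deletion_fraction,
              max_adjacent_indel_fraction = max_adjacent_indel_fraction)
  stopifnot(all(unlist(cfg) >= 0))
  structure(cfg, class = "filter_config")
}

#' Apply the filter suite to one candidate call
#'
#' @param call a one-row candidate-call data.frame.
#' @param site the matching [paired_site()].
#' @param all_candidate_positions data.frame with columns `chrom`, `pos`:
#'   the union of raw candidate positions from every caller (used by the
#'   nearby-SNV rule; the call's own position is excluded).
#' @param cfg a [filter_config()].
#' @return a `filter_verdict`: one-row data.frame with, per rule, a
#'   `<rule>_pass` flag and a `<rule>_metric` value, plus `overall_pass`
#'   (the conjunction of all eight). A call with zero variant reads
#'   passes the strand and quality rules vacuously.
#' @export
apply_filters <- function(call, site, all_candidate_positions,
                          cfg = filter_config()) {
  stopifnot(nrow(call) == 1L)
  rel <- if (identical(call$class, "LOH")) site$normal else site$tumour
  oth <- if (identical(call$class, "LOH")) site$tumour else site$normal
  r <- .reads_as_list(rel); o <- .reads_as_list(oth)
  vb <- call$variant_base
  nearby <- .nearby_counts(call$chrom, call$pos, all_candidate_positions,
                           cfg$snv_window)
  .filter_verdict_row(call, r, o, vb, nearby, cfg)
}

.nearby_counts <- function(chrom, pos, cand, window) {
  if (is.null(cand) || nrow(cand) == 0L) return(rep(0L, length(pos)))
  vapply(seq_along(pos), function(i) {
    same <- cand$chrom == chrom[i] & cand$pos != pos[i]
    sum(same & abs(cand$pos - pos[i]) <= window)
  }, 0L)
}

.filter_verdict_row <- function(call, r, o, vb, nearby, cfg) {
  is_v <- if (is.null(r) || is.na(vb)) logical(0)
          else !r$spans_deletion & r$base == vb
  v <- sum(is_v)
  vf <- sum(is_v & r$strand == "+"); vr <- v - vf
  bq <- if (v) r$baseq[is_v] else numeric(0)
  mq <- if (v) r$mapq[is_v] else numeric(0)
  frac <- function(x, flag) {
    d <- if (is.null(x)) 0L else length(x$base)
    if (d == 0L) 0 else sum(x[[flag]]) / d
  }
  sd_rel <- frac(r, "spans_deletion"); sd_oth <- frac(o, "spans_deletion")
  ai_rel <- frac(r, "adjacent_indel"); ai_oth <- frac(o, "adjacent_indel")
  p <- list(
    strand_bias = v == 0L || (vf > 0L && vr > 0L),
    mean_baseq = v == 0L || mean(bq) >= cfg$min_mean_baseq,
    max_baseq = v == 0L || any(bq > cfg$min_max_baseq),
    mean_mapq = v == 0L || mean(mq) >= cfg$min_mean_mapq,
    max_mapq = v == 0L || any(mq > cfg$min_max_mapq),
    nearby_snvs = nearby <= cfg$max_nearby_snvs,
    spanning_deletion = max(sd_rel, sd_oth) <= cfg$max_spanning_deletion_fraction,
    adjacent_indel = max(ai_rel, ai_oth) <= cfg$max_adjacent_indel_fraction)
  structure(data.frame(
    chrom = call$chrom, pos = call$pos, caller = call$caller,
    class = call$class, v = v, v_forward = vf, v_reverse = vr,
    strand_bias_pass = p$strand_bias,
    mean_baseq_pass = p$mean_baseq,
    mean_baseq_metric = if (v) mean(bq) else NA_real_,
    max_baseq_pass = p$max_baseq,
    max_baseq_metric = if (v) max(bq) else NA_real_,
    mean_mapq_pass = p$mean_mapq,
    mean_mapq_metric = if (v) mean(mq) else NA_real_,
    max_mapq_pass = p$max_mapq,
    max_mapq_metric = if (v) max(mq) else NA_real_,
    nearby_snvs_pass = p$nearby_snvs, nearby_snvs_metric = nearby,
    spanning_deletion_pass = p$spanning_deletion,
    spanning_deletion_metric = max(sd_rel, sd_oth),
    adjacent_indel_pass = p$adjacent_indel,
    adjacent_indel_metric = max(ai_rel, ai_oth),
    overall_pass = all(unlist(p)), stringsAsFactors = FALSE),
    class = c("filter_verdict", "data.frame"))
}

#' Apply the filter suite to a full candidate set
#'
#' Vector version of [apply_filters()]: evaluates every call against the
#' pileup, using the pooled candidate positions of all callers for the
#' nearby-SNV rule.
#'
#' @param calls a `candidate_calls` data.frame.
#' @param pp the [paired_pileup()] the calls were made on.
#' @param cfg a [filter_config()].
#' @param all_candidate_positions optional data.frame `chrom`,`pos`;
#'   defaults to the distinct positions in `calls`.
#' @return a `filter_verdict` data.frame, one row per call.
#' @export
apply_filters_all <- function(calls, pp, cfg = filter_config(),
                              all_candidate_positions = NULL) {
  stopifnot(inherits(pp, "paired_pileup"))
  if (is.null(all_candidate_positions))
    all_candidate_positions <-
      unique(data.frame(chrom = calls$chrom, pos = calls$pos,
                        stringsAsFactors = FALSE))
  if (nrow(calls) == 0L)
    return(structure(data.frame(), class = c("filter_verdict", "data.frame")))
  key <- paste(pp$sites$chrom, pp$sites$pos)
  si <- match(paste(calls$chrom, calls$pos), key)
  if (anyNA(si)) stop("calls at positions absent from the pileup")
  n <- nrow(pp$sites)
  ncols <- .read_columns(pp$normal, n)
  tcols <- .read_columns(pp$tumour, n)
  nearby <- .nearby_counts(calls$chrom, calls$pos, all_candidate_positions,
                           cfg$snv_window)
  out <- vector("list", nrow(calls))
  for (k in seq_len(nrow(calls))) {
    i <- si[k]
    loh <- identical(calls$class[k], "LOH")
    r <- .slice(if (loh) ncols else tcols, i)
    o <- .slice(if (loh) tcols else ncols, i)
    out[[k]] <- .filter_verdict_row(calls[k, ], r, o, calls$variant_base[k],
                                    nearby[k], cfg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("filter_verdict", "data.frame"))
}

#' Strand-bias null probability
#'
#' Under fair per-read strand assignment, the chance that all `v` variant
#' reads at a site fall on one strand (either strand counts) is
#' 2 * (1/2)^v = (1/2)^(v-1).
#'
#' @param v positive integer count(s) of variant reads.
#' @return probability vector.
#' @export
strand_bias_null_probability <- function(v) {
  if (any(v < 1)) stop("v must be >= 1")
  0.5^(v - 1)
}

#' Expected versus observed fully strand-biased sites
#'
#' Sums the per-site null probabilities (1/2)^(v-1) over candidate calls
#' to get the number of 100%-strand-biased sites expected from random
#' strand sampling alone, and compares it with the observed count. An
#' observed count far above the expectation (the paper-style excess) is
#' the signature of systematic one-strand error.
#'
#' @param calls a `candidate_calls` data.frame; the relevant sample's
#'   variant counts (`t_*` for somatic/other, `n_*` for LOH) are used.
#'   Calls with zero variant reads are excluded and counted separately.
#' @return list with `expected`, `observed`, `ratio`
#'   (observed/expected), `sd` (Poisson-binomial standard deviation of
#'   the null count), `n_used` and `n_zero_variant`.
#' @export
expected_strand_bias_count <- function(calls) {
  loh <- calls$class == "LOH"
  v <- ifelse(loh, calls$n_v, calls$t_v)
  vf <- ifelse(loh, calls$n_v_fwd, calls$t_v_fwd)
  vr <- ifelse(loh, calls$n_v_rev, calls$t_v_rev)
  keep <- v >= 1L
  p <- strand_bias_null_probability(v[keep])
  observed <- sum(vf[keep] == 0L | vr[keep] == 0L)
  expected <- sum(p)
  list(expected = expected, observed = observed,
       ratio = if (expected > 0) observed / expected else NA_real_,
       sd = sqrt(sum(p * (1 - p))), n_used = sum(keep),
       n_zero_variant = sum(!keep))
}
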