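#' Site-by-caller comparison matrix
#'
#' Pivots a pooled candidate-call table into one row per distinct site
#' and one column per caller, holding each caller's probability score
#' (NA where the caller did not report the site) and call class. The
#' allele proportions of the first reporting caller are carried along
#' for characterization plots.
#'
#' @param calls a `candidate_calls` data.frame.
#' @return a `comparison_matrix`: list with `sites` (chrom, pos, t_vp,
#'   n_vp), `score` (sites x callers numeric matrix) and `class`
#'   (matching character matrix).
#' @export
comparison_matrix <- function(calls) {
  key <- paste(calls$chrom, calls$pos)
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- !duplicated(key)
  sites <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                      t_vp = calls$t_vp[first], n_vp = calls$n_vp[first],
                      stringsAsFactors = FALSE)
  score <- matrix(NA_real_, length(ukey), length(CALLERS),
                  dimnames = list(NULL, CALLERS))
  cls <- matrix(NA_character_, length(ukey), length(CALLERS),
                dimnames = list(NULL, CALLERS))
  ci <- match(calls$caller, CALLERS)
  score[cbind(idx, ci)] <- calls$score
  cls[cbind(idx, ci)] <- calls$class
  structure(list(sites = sites, score = score, class = cls),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("comparison_matrix: %d sites x %d callers (%d entries)\n",
              nrow(x$sites), ncol(x$score), sum(!is.na(x$score))))
  invisible(x)
}

.class_mask <- function(mat, class_filter) {
  if (is.null(class_filter)) !is.na(mat$score)
  else !is.na(mat$class) & mat$class == class_filter
}

#' Candidate-set overlaps between callers
#'
#' Partitions the distinct candidate sites by the exact subset of
#' callers reporting each site (at any score), i.e. the counts behind a
#' 4-set Venn diagram: 15 non-empty subsets whose counts sum to the
#' number of distinct sites.
#'
#' @param mat a [comparison_matrix()].
#' @param class_filter `"somatic"`, `"LOH"`, or NULL for any class.
#' @return named integer vector over the 15 subsets (names like
#'   `"varscan+strelka_like"`).
#' @export
overlap_counts <- function(mat, class_filter = "somatic") {
  m <- .class_mask(mat, class_filter)
  keep <- rowSums(m) > 0L
  m <- m[keep, , drop = FALSE]
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(CALLERS, k, paste, collapse = "+", simplify = FALSE)))
  out <- stats::setNames(integer(length(subsets)), subsets)
  if (nrow(m)) {
    lab <- apply(m, 1, function(row) paste(CALLERS[row], collapse = "+"))
    tab <- table(lab)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Pairwise score correlations over shared sites
#'
#' Pearson correlation of the probability scores for each of the six
#' caller pairs, over the sites where both callers report a score. Pairs
#' with fewer than 3 shared sites, or a zero-variance score vector, are
#' undefined (NA, with the reason flagged).
#'
#' @param mat a [comparison_matrix()].
#' @param class_filter class restriction as in [overlap_counts()].
#' @return data.frame with `caller1`, `caller2`, `n_shared`, `r`,
#'   `undefined_reason`.
#' @export
pairwise_score_correlation <- function(mat, class_filter = "somatic") {
  m <- .class_mask(mat, class_filter)
  sc <- mat$score
  pairs <- utils::combn(CALLERS, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    c1 <- pairs[1, i]; c2 <- pairs[2, i]
    sel <- m[, c1] & m[, c2]
    x <- sc[sel, c1]; y <- sc[sel, c2]
    r <- NA_real_; why <- NA_character_
    if (sum(sel) < 3L) why <- "fewer than 3 shared sites"
    else if (stats::sd(x) == 0 || stats::sd(y) == 0) why <- "zero variance"
    else r <- stats::cor(x, y)
    data.frame(caller1 = c1, caller2 = c2, n_shared = sum(sel), r = r,
               undefined_reason = why, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Threshold sweep: retention, multi-caller fraction, known-site fraction
#'
#' For each caller and ascending score threshold t, computes the number
#' of its candidate sites retained at score >= t, the fraction of those
#' found by at least one other caller at ANY score, and the fraction
#' present in a supplied known-site list (the dbSNP analog: a germline
#' truth position set on synthetic data).
#'
#' @param mat a [comparison_matrix()].
#' @param known_sites data.frame `chrom`,`pos` (or NULL for none).
#' @param thresholds ascending numeric grid in `[0, 1]` (default 101
#'   evenly spaced values).
#' @param class_filter class restriction as in [overlap_counts()].
#' @return data.frame `caller`, `threshold`, `n_retained`,
#'   `fraction_multicaller`, `fraction_known` (fractions NA where
#'   nothing is retained).
#' @export
threshold_sweep <- function(mat, known_sites = NULL,
                            thresholds = seq(0, 1, length.out = 101),
                            class_filter = "somatic") {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  m <- .class_mask(mat, class_filter)
  sc <- mat$score
  multi <- rowSums(m) >= 2L
  known <- if (is.null(known_sites) || nrow(known_sites) == 0L)
    rep(FALSE, nrow(mat$sites))
  else paste(mat$sites$chrom, mat$sites$pos) %in%
    paste(known_sites$chrom, known_sites$pos)
  out <- lapply(CALLERS, function(cl) {
    has <- m[, cl]
    res <- t(vapply(thresholds, function(th) {
      ret <- has & sc[, cl] >= th
      n <- sum(ret)
      c(n, if (n) mean(multi[ret]) else NA_real_,
        if (n) mean(known[ret]) else NA_real_)
    }, numeric(3)))
    data.frame(caller = cl, threshold = thresholds, n_retained = res[, 1],
               fraction_multicaller = res[, 2], fraction_known = res[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Allele-fraction profile of caller-unique candidates
#'
#' For the sites reported by exactly one caller, sorts each caller's
#' unique set by tumour variant proportion and returns the proportions
#' against a scaled index i/(n-1) in [0, 1] (0 for a single site), the
#' layout used to characterize what each caller uniquely finds: the
#' tumour curve is smooth and non-decreasing by construction while the
#' normal proportions ride along unsorted (the "jagged lines").
#'
#' @param mat a [comparison_matrix()].
#' @param class_filter class restriction as in [overlap_counts()].
#' @return data.frame `caller`, `scaled_index`,
#'   `tumour_variant_proportion`, `normal_variant_proportion`.
#' @export
vaf_profile <- function(mat, class_filter = "somatic") {
  m <- .class_mask(mat, class_filter)
  uniq <- rowSums(m) == 1L
  out <- lapply(CALLERS, function(cl) {
    sel <- which(uniq & m[, cl])
    if (!length(sel))
      return(data.frame(caller = character(), scaled_index = numeric(),
                        tumour_variant_proportion = numeric(),
                        normal_variant_proportion = numeric(),
                        stringsAsFactors = FALSE))
    o <- sel[order(mat$sites$t_vp[sel])]
    n <- length(o)
    data.frame(caller = cl,
               scaled_index = if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1),
               tumour_variant_proportion = mat$sites$t_vp[o],
               normal_variant_proportion = mat$sites$n_vp[o],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Filter pass-rate table with significance tests
#'
#' Per caller: percentage of candidates passing the strand-bias rule,
#' and percentage of the strand-bias SURVIVORS passing all seven other
#' rules combined (the survivors are the second column's denominator).
#' Pairwise column differences are tested with a two-proportion
#' chi-square test with continuity correction (or Fisher's exact test).
#'
#' @param verdicts a `filter_verdict` data.frame from
#'   [apply_filters_all()] (must carry the `caller` column).
#' @param test `"chisq"` (default) or `"fisher"`.
#' @param alpha significance level (default 0.05).
#' @return list with `table` (data.frame: caller, n, strand_bias_pass_pct,
#'   n_survivors, other_filters_pass_pct, percentages rounded to 1
#'   decimal; NA for a caller with no candidates) and `tests`
#'   (data.frame of pairwise p-values and significance per column).
#' @export
pass_rate_table <- function(verdicts, test = c("chisq", "fisher"),
                            alpha = 0.05) {
  test <- match.arg(test)
  other_rules <- paste0(setdiff(FILTER_RULES, "strand_bias"), "_pass")
  per <- lapply(CALLERS, function(cl) {
    v <- verdicts[verdicts$caller == cl, , drop = FALSE]
    n <- nrow(v)
    if (n == 0L)
      return(data.frame(caller = cl, n = 0L, sb_pass = NA_integer_,
                        strand_bias_pass_pct = NA_real_,
                        n_survivors = NA_integer_,
                        other_pass = NA_integer_,
                        other_filters_pass_pct = NA_real_,
                        stringsAsFactors = FALSE))
    sb <- v$strand_bias_pass
    surv <- v[sb, , drop = FALSE]
    op <- if (nrow(surv)) rowSums(as.matrix(surv[other_rules])) ==
      length(other_rules) else logical(0)
    data.frame(caller = cl, n = n, sb_pass = sum(sb),
               strand_bias_pass_pct = round(100 * mean(sb), 1),
               n_survivors = nrow(surv), other_pass = sum(op),
               other_filters_pass_pct = if (nrow(surv))
                 round(100 * mean(op), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  prop_p <- function(x1, n1, x2, n2) {
    if (any(is.na(c(x1, n1, x2, n2))) || n1 == 0 || n2 == 0)
      return(NA_real_)
    if (test == "fisher")
      stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
    else suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value)
  }
  pairs <- utils::combn(CALLERS, 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- tab[tab$caller == pairs[1, i], ]
    b <- tab[tab$caller == pairs[2, i], ]
    p_sb <- prop_p(a$sb_pass, a$n, b$sb_pass, b$n)
    p_ot <- prop_p(a$other_pass, a$n_survivors, b$other_pass, b$n_survivors)
    data.frame(caller1 = pairs[1, i], caller2 = pairs[2, i],
               strand_bias_p = p_sb,
               strand_bias_significant = !is.na(p_sb) & p_sb < alpha,
               other_filters_p = p_ot,
               other_filters_significant = !is.na(p_ot) & p_ot < alpha,
               stringsAsFactors = FALSE)
  })
  list(table = tab[, c("caller", "n", "strand_bias_pass_pct", "n_survivors",
                       "other_filters_pass_pct")],
       counts = tab, tests = do.call(rbind, tests))
}

#' Truth-based evaluation of caller output
#'
#' On simulated data, computes per caller and tumour-VAF bin the
#' sensitivity (fraction of true somatic sites called somatic at score
#' >= `score_threshold`) and, per caller, the germline leak (fraction
#' of its somatic calls sitting on germline truth — the dbSNP-proportion
#' analog) and the fraction of its somatic calls at sites with no
#' planted variant.
#'
#' @param mat a [comparison_matrix()] (somatic classes are evaluated).
#' @param truth a simulator truth data.frame (from [simulate_pair()]).
#' @param vaf_bins breaks for tumour true-VAF bins.
#' @param score_threshold somatic score for a positive call.
#' @return list with `sensitivity` (caller x bin data.frame; NA for
#'   empty bins) and `calls` (per caller: n_somatic_calls,
#'   germline_leak, none_fraction).
#' @export
evaluate_against_truth <- function(mat, truth,
                                   vaf_bins = c(0, 0.05, 0.1, 0.2, 0.5, 1),
                                   score_threshold = 0.95) {
  tkey <- paste(truth$chrom, truth$pos)
  skey <- paste(mat$sites$chrom, mat$sites$pos)
  som_truth <- truth[truth$truth_class %in%
                     c("somatic_clonal", "somatic_subclonal"), , drop = FALSE]
  bins <- cut(som_truth$true_vaf_tumour, vaf_bins, include.lowest = TRUE)
  m <- .class_mask(mat, "somatic")
  sens <- lapply(CALLERS, function(cl) {
    called_keys <- skey[m[, cl] & mat$score[, cl] >= score_threshold]
    hit <- paste(som_truth$chrom, som_truth$pos) %in% called_keys
    vapply(levels(bins), function(b) {
      in_b <- bins == b
      if (!sum(in_b)) NA_real_ else mean(hit[in_b])
    }, 0)
  })
  sens_df <- data.frame(caller = CALLERS, do.call(rbind, sens),
                        check.names = FALSE, stringsAsFactors = FALSE)
  calls_df <- do.call(rbind, lapply(CALLERS, function(cl) {
    sel <- which(m[, cl])
    tcls <- truth$truth_class[match(skey[sel], tkey)]
    n <- length(sel)
    data.frame(caller = cl, n_somatic_calls = n,
               germline_leak = if (n) mean(tcls %in% c("germline_het",
                                                       "germline_hom"),
                                           na.rm = TRUE) else NA_real_,
               none_fraction = if (n) mean(tcls == "none" |
                                           tcls == "systematic_error",
                                           na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(sensitivity = sens_df, calls = calls_df)
}
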