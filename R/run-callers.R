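#' Run all four callers over a paired pileup
#'
#' Drives the comparison: trains the joint mixture if no fit is supplied
#' (optionally on a fixed-seed subsample of sites), runs the four calling
#' models at every site, and keeps calls above each caller's inclusion
#' threshold. The default thresholds are deliberately low to generate
#' large candidate sets, mirroring the low-stringency raw output the
#' downstream filters and concordance statistics are designed for:
#' Fisher p <= 0.05, somatic score S >= 15, mixture somatic probability
#' >= 0.001, and phred score >= 1 for the marginalized-frequency caller.
#'
#' @param pp a [paired_pileup()].
#' @param varscan a [varscan_config()].
#' @param priors a [prior_config()].
#' @param model a [genotype_likelihood_model()].
#' @param jsm a `jsm_fit` or [jsm_params()]; if `NULL`, trained here with
#'   [train_jsm_em()].
#' @param jsm_mode `"jsm2"` or `"jsm1"`.
#' @param grid_step grid for [call_strelka_like()].
#' @param thresholds list with `varscan_p`, `somaticsniper_S`,
#'   `jointsnvmix_score`, `strelka_phred`.
#' @param train_fraction fraction of sites used for EM training
#'   (fixed-seed subsample; default 1).
#' @param train_seed seed for the training subsample.
#' @param max_iter EM iteration cap when training here.
#' @return a `candidate_calls` data.frame (all callers pooled), with the
#'   trained fit attached as attribute `jsm_fit`.
#' @export
run_all_callers <- function(pp, varscan = varscan_config(),
                            priors = prior_config(),
                            model = genotype_likelihood_model(),
                            jsm = NULL, jsm_mode = c("jsm2", "jsm1"),
                            grid_step = 0.01,
                            thresholds = list(varscan_p = 0.05,
                                              somaticsniper_S = 15,
                                              jointsnvmix_score = 0.001,
                                              strelka_phred = 1),
                            train_fraction = 1, train_seed = 1L,
                            max_iter = 50L) {
  stopifnot(inherits(pp, "paired_pileup"))
  jsm_mode <- match.arg(jsm_mode)
  if (is.null(jsm)) {
    cc <- .jsm_counts(pp)
    if (train_fraction < 1) {
      idx <- .with_seed(train_seed,
                        sample(nrow(cc), ceiling(train_fraction * nrow(cc))))
      cc <- cc[idx, , drop = FALSE]
    }
    jsm <- train_jsm_em(cc, max_iter = max_iter)
  }
  jp <- if (inherits(jsm, "jsm_fit")) jsm$params else jsm
  n <- nrow(pp$sites)
  ncols <- .read_columns(pp$normal, n)
  tcols <- .read_columns(pp$tumour, n)
  rows <- vector("list", 4L * 64L)
  nrows <- 0L
  push <- function(chrom, pos, caller, res) {
    nrows <<- nrows + 1L
    if (nrows > length(rows)) length(rows) <<- 2L * nrows  # grow
    rows[[nrows]] <<- .call_row(chrom, pos, caller, res$class, res$score,
                                res$phred_score, res$normal_gt,
                                res$tumour_gt, res$variant_base, res$n,
                                res$t)
  }
  for (i in seq_len(n)) {
    nr <- .slice(ncols, i)
    tr <- .slice(tcols, i)
    if (is.null(nr) && is.null(tr)) next
    ref <- pp$sites$ref[i]
    # fast path: a site with no variant base call in either sample can
    # only produce the no-signal outputs (S = 0, mixture score ~ 0,
    # marginal score ~ prior), all below the default thresholds
    any_var <- (!is.null(tr) &&
                any(tr$base != ref & tr$base != "N" & !tr$spans_deletion)) ||
               (!is.null(nr) &&
                any(nr$base != ref & nr$base != "N" & !nr$spans_deletion))
    if (!any_var) next
    chrom <- pp$sites$chrom[i]; pos <- pp$sites$pos[i]
    vs <- .varscan_core(nr, tr, ref, varscan)
    if (!is.null(vs) && vs$p <= thresholds$varscan_p)
      push(chrom, pos, "varscan", vs)
    ss <- .sniper_core(nr, tr, ref, priors, model)
    if (ss$S >= thresholds$somaticsniper_S)
      push(chrom, pos, "somaticsniper", ss)
    js <- .jsm_core(nr, tr, ref, jp, jsm_mode, model)
    if (js$score >= thresholds$jointsnvmix_score)
      push(chrom, pos, "jointsnvmix", js)
    st <- .strelka_core(nr, tr, ref, priors, model, grid_step)
    if (st$phred_score >= thresholds$strelka_phred)
      push(chrom, pos, "strelka_like", st)
  }
  calls <- if (nrows == 0L) .empty_calls()
           else do.call(rbind, rows[seq_len(nrows)])
  calls <- calls[order(calls$chrom, calls$pos, calls$caller), , drop = FALSE]
  rownames(calls) <- NULL
  calls <- .as_candidate_calls(calls)
  attr(calls, "jsm_fit") <- if (inherits(jsm, "jsm_fit")) jsm else NULL
  calls
}
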