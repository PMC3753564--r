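# Marginalized allele-frequency caller in the spirit of Strelka,
# deliberately simplified: the normal sample is modelled as a diploid
# genotype with the quality-aware noise kernel, and under the somatic
# hypothesis the tumour variant fraction s is marginalized uniformly over
# a grid rather than over the original tool's full continuous model (the
# original's realignment and inbuilt depth filters live in the filter
# suite instead).

.strelka_core <- function(nr, tr, ref, priors, model, grid_step = 0.01) {
  vb <- summarize_alleles(tr, ref)$variant_base
  if (is.na(vb)) vb <- summarize_alleles(nr, ref)$variant_base
  llN <- .genotype_logliks(nr, model, vb, ref)
  # tumour log-likelihood as a function of variant fraction s
  co <- if (is.null(tr) || length(tr$base) == 0L) NULL
        else .emission_coefs(tr, vb, ref)
  llT_at <- function(s) {
    if (is.null(co)) return(rep(0, length(s)))
    colSums(log(outer(co$B, s) + co$A))
  }
  sgrid <- seq(grid_step, 1, by = grid_step)
  ll_som <- .logsumexp(llT_at(sgrid)) - log(length(sgrid))
  ll_nonsom <- llT_at(1 - model$f)            # tumour at the normal fraction
  th <- priors$theta; mu <- priors$mu_somatic
  lpN <- log(c(AA = 1 - 1.5 * th, AB = th, BB = th / 2))
  l_ns <- lpN + llN + log(1 - mu) + ll_nonsom  # (g, non-somatic)
  l_s <- lpN + llN + log(mu) + ll_som          # (g, somatic)
  lz <- .logsumexp(c(l_ns, l_s))
  post_g <- exp(l_ns - lz) + exp(l_s - lz)
  g_hat <- GENOTYPES[which.max(post_g)]
  score <- exp(l_s[[g_hat]] - lz)
  phred <- if (score >= 1) 255L else min(255L, max(0L, round(-10 * log10(1 - score))))
  class <- if (score > 0.5) "somatic"
           else if (g_hat == "AA") "reference" else "germline"
  list(class = class, score = unname(score), phred_score = phred,
       normal_gt = g_hat, tumour_gt = NA_character_, variant_base = vb,
       n = .count_base(nr, ref, vb), t = .count_base(tr, ref, vb))
}

#' Call one site with the marginalized allele-frequency caller
#'
#' The normal sample's genotype posterior over AA/AB/BB is computed with
#' the quality-aware kernel and the [prior_config()] heterozygosity
#' prior. Under the non-somatic hypothesis the tumour reads are generated
#' at the normal genotype's allele fraction; under the somatic hypothesis
#' (prior `mu_somatic`) the tumour variant fraction is marginalized
#' uniformly over the grid `{grid_step, 2*grid_step, ..., 1}`, which is
#' what makes the caller sensitive to low-allelic-fraction (subclonal)
#' variants. The score is the posterior probability of (most likely
#' normal genotype, somatic); the phred score is -10 log10(1 - score),
#' rounded and capped at 255. With zero tumour depth the score reduces to
#' approximately the somatic prior.
#'
#' @param site a [paired_site()].
#' @param priors a [prior_config()].
#' @param model a [genotype_likelihood_model()].
#' @param grid_step grid resolution for the marginalized tumour variant
#'   fraction (default 0.01).
#' @return a one-row `candidate_calls` data.frame.
#' @export
call_strelka_like <- function(site, priors = prior_config(),
                              model = genotype_likelihood_model(),
                              grid_step = 0.01) {
  res <- .strelka_core(.reads_as_list(site$normal), .reads_as_list(site$tumour),
                       site$ref, priors, model, grid_step)
  .as_candidate_calls(.call_row(site$chrom, site$pos, "strelka_like",
                                res$class, res$score, res$phred_score,
                                res$normal_gt, res$tumour_gt,
                                res$variant_base, res$n, res$t))
}
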