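# Joint-genotype Bayesian caller in the style of SomaticSniper, reduced
# to the A/B genotype space. The posterior over the 9 joint genotypes is
# P(gN, gT | D) propto P(D_N | gN) P(D_T | gT) P(gN) P(gT | gN) with
# P(gN) = (1 - 3 theta / 2, theta, theta / 2) and a transition that keeps
# the tumour genotype with probability 1 - mu_somatic, splitting
# mu_somatic equally between the two non-matching genotypes. The somatic
# score S is the phred-scaled posterior probability that the genotypes
# are EQUAL, capped at 255.

.sniper_core <- function(nr, tr, ref, priors, model) {
  vb <- summarize_alleles(tr, ref)$variant_base
  if (is.na(vb)) vb <- summarize_alleles(nr, ref)$variant_base
  llN <- .genotype_logliks(nr, model, vb, ref)
  llT <- .genotype_logliks(tr, model, vb, ref)
  th <- priors$theta; mu <- priors$mu_somatic
  lpN <- log(c(1 - 1.5 * th, th, th / 2))
  ltrans <- matrix(log(mu / 2), 3, 3); diag(ltrans) <- log(1 - mu)
  lp <- outer(lpN + llN, llT, `+`) + ltrans   # [gN, gT]
  lz <- .logsumexp(lp)
  post <- exp(lp - lz)
  p_same <- sum(diag(post))
  S <- if (p_same <= 0) 255L else min(255L, max(0L, round(-10 * log10(p_same))))
  amax <- arrayInd(which.max(post), c(3L, 3L))
  gN <- GENOTYPES[amax[1]]; gT <- GENOTYPES[amax[2]]
  class <- if (gN == "AA" && gT != "AA") "somatic"
           else if (gN == "AB" && gT != "AB") "LOH"
           else if (gN == gT && gN == "AA") "reference"
           else if (gN == gT) "germline" else "unknown"
  list(class = class, score = 1 - 10^(-S / 10), S = S, phred_score = S,
       normal_gt = gN, tumour_gt = gT, variant_base = vb,
       posterior = post,
       n = .count_base(nr, ref, vb), t = .count_base(tr, ref, vb))
}

#' Call one site with the joint-genotype Bayesian caller
#'
#' Computes the posterior over the nine joint (normal, tumour) genotypes
#' in reduced A/B space, using the per-read quality-weighted emission
#' kernel of [read_likelihood()], the heterozygosity prior
#' `priors$theta` for the normal genotype and a somatic transition prior
#' `priors$mu_somatic`. The phred-scaled somatic score
#' S = -10 log10 P(gN = gT | D), capped at 255, is reported alongside
#' score = 1 - 10^(-S/10). The class follows the joint posterior argmax:
#' somatic when the normal is AA and the tumour is not, LOH when the
#' normal is AB and the tumour is not.
#'
#' @param site a [paired_site()].
#' @param priors a [prior_config()].
#' @param model a [genotype_likelihood_model()].
#' @return a one-row `candidate_calls` data.frame, or `NULL` when both
#'   samples have zero depth.
#' @export
call_somaticsniper <- function(site, priors = prior_config(),
                               model = genotype_likelihood_model()) {
  if (nrow(site$normal) == 0L && nrow(site$tumour) == 0L) return(NULL)
  res <- .sniper_core(.reads_as_list(site$normal), .reads_as_list(site$tumour),
                      site$ref, priors, model)
  .as_candidate_calls(.call_row(site$chrom, site$pos, "somaticsniper",
                                res$class, res$score, res$phred_score,
                                res$normal_gt, res$tumour_gt,
                                res$variant_base, res$n, res$t))
}
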