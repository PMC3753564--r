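#' Genotype likelihood model
#'
#' Per-genotype reference-allele fractions for the reduced
#' reference/variant (A/B) genotype space used by all Bayesian callers:
#' AA emits the reference with fraction 1 - epsilon, AB with 0.5, BB with
#' epsilon. Per-read evidence is weighted by base quality (error
#' probability e = 10^(-baseQ/10)) and mapping quality (confidence
#' m = 1 - 10^(-mapQ/10)); an unmapped read (m = 0) is uninformative and
#' emits any base with probability 1/4.
#'
#' @param epsilon residual variant emission of a homozygote (sequencing
#'   cannot distinguish a true fraction of exactly 0 or 1 from rare
#'   contamination); default 0.001.
#' @return a `genotype_likelihood_model` list with `f` (named vector of
#'   reference fractions for AA/AB/BB) and `epsilon`.
#' @export
genotype_likelihood_model <- function(epsilon = 0.001) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  structure(list(f = c(AA = 1 - epsilon, AB = 0.5, BB = epsilon),
                 epsilon = epsilon),
            class = "genotype_likelihood_model")
}

GENOTYPES <- c("AA", "AB", "BB")

#' Per-read likelihood under a genotype
#'
#' The shared emission kernel: P(read | g) = m * (f_g * P(b | ref) +
#' (1 - f_g) * P(b | variant)) + (1 - m) / 4, where P(b | a) = 1 - e if
#' b = a and e / 3 otherwise, e is the base-call error probability from
#' the read's base quality and m the mapping confidence from its mapping
#' quality. A base that is neither the reference nor the chosen variant
#' is generic error evidence (both conditional terms are e / 3). Reads
#' with base `N` or a spanning deletion carry no base call and get
#' likelihood 1.
#'
#' @param obs read observations: a data.frame (rows of a `paired_site`
#'   sample) or an equivalent list of vectors.
#' @param genotype one of `"AA"`, `"AB"`, `"BB"`.
#' @param model a [genotype_likelihood_model()].
#' @param variant_base the variant base B, or NA when no variant allele
#'   was identified.
#' @param ref the reference base A.
#' @return numeric vector of per-read probabilities in (0, 1).
#' @export
read_likelihood <- function(obs, genotype, model = genotype_likelihood_model(),
                            variant_base, ref) {
  genotype <- match.arg(genotype, GENOTYPES)
  r <- if (is.data.frame(obs)) .reads_as_list(obs) else obs
  .emission_f(r, model$f[[genotype]], variant_base, ref)
}

# Vector of per-read emission probabilities at reference fraction f.
.emission_f <- function(r, f, variant_base, ref) {
  e <- 10^(-r$baseq / 10)
  m <- 1 - 10^(-r$mapq / 10)
  p_ref <- ifelse(r$base == ref, 1 - e, e / 3)
  p_var <- if (is.na(variant_base)) e / 3
           else ifelse(r$base == variant_base, 1 - e, e / 3)
  out <- m * (f * p_ref + (1 - f) * p_var) + (1 - m) / 4
  out[r$spans_deletion | r$base == "N"] <- 1
  out
}

# Per-read linear coefficients so that emission at VARIANT fraction s is
# A + s * B; informative reads only (N / spanning deletions dropped).
.emission_coefs <- function(r, variant_base, ref) {
  keep <- !r$spans_deletion & r$base != "N"
  if (!any(keep)) return(NULL)
  base <- r$base[keep]
  e <- 10^(-r$baseq[keep] / 10)
  m <- 1 - 10^(-r$mapq[keep] / 10)
  p_ref <- ifelse(base == ref, 1 - e, e / 3)
  p_var <- if (is.na(variant_base)) e / 3
           else ifelse(base == variant_base, 1 - e, e / 3)
  list(A = m * p_ref + (1 - m) / 4, B = m * (p_var - p_ref))
}

# log-likelihood of one sample's reads under each of AA/AB/BB
.genotype_logliks <- function(r, model, variant_base, ref) {
  if (is.null(r) || length(r$base) == 0L)
    return(c(AA = 0, AB = 0, BB = 0))
  co <- .emission_coefs(r, variant_base, ref)
  if (is.null(co)) return(c(AA = 0, AB = 0, BB = 0))
  s <- 1 - model$f  # variant fraction per genotype
  c(AA = sum(log(co$A + s[[1]] * co$B)),
    AB = sum(log(co$A + s[[2]] * co$B)),
    BB = sum(log(co$A + s[[3]] * co$B)))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Joint genotype priors
#'
#' Population-level priors shared by the Bayesian callers: `theta` is the
#' population heterozygosity (prior for the normal genotype: AA gets
#' 1 - 3*theta/2, AB theta, BB theta/2), `mu_somatic` the prior
#' probability of a somatic event at a site, and `loh_prior` an analogous
#' prior for loss of heterozygosity. The paper cites the concepts without
#' values; these defaults are conventional and fully configurable.
#'
#' @param theta population heterozygosity prior, default 0.001.
#' @param mu_somatic somatic prior probability, default 1e-4.
#' @param loh_prior LOH prior probability, default 1e-4.
#' @return a `prior_config` list.
#' @export
prior_config <- function(theta = 0.001, mu_somatic = 1e-4,
                         loh_prior = 1e-4) {
  stopifnot(theta > 0, theta < 1, mu_somatic > 0, mu_somatic < 1,
            loh_prior > 0, loh_prior < 1,
            theta + mu_somatic + loh_prior < 1)
  structure(list(theta = theta, mu_somatic = mu_somatic,
                 loh_prior = loh_prior), class = "prior_config")
}
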