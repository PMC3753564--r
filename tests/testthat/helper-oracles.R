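# Independent oracle implementations: straightforward enumeration / loop
# code kept deliberately separate from the package's vectorized paths.

# One-tailed Fisher p by explicit hypergeometric enumeration with choose()
oracle_fisher_one_tailed <- function(v_enr, ref_enr, v_oth, ref_oth) {
  V <- v_enr + v_oth
  N <- V + ref_enr + ref_oth
  k <- v_enr + ref_enr           # draws from the enriched sample
  lo <- max(0L, k - (N - V)); hi <- min(V, k)
  ks <- lo:hi
  pmf <- choose(V, ks) * choose(N - V, k - ks) / choose(N, k)
  sum(pmf[ks >= v_enr])
}

# per-read emission, scalar loop version
oracle_emission <- function(base, baseq, mapq, f, vb, ref) {
  e <- 10^(-baseq / 10); m <- 1 - 10^(-mapq / 10)
  pb <- function(b, a) if (!is.na(a) && b == a) 1 - e else e / 3
  m * (f * pb(base, ref) + (1 - f) * pb(base, vb)) + (1 - m) / 4
}

# direct 9-term joint genotype posterior for the SomaticSniper-style model
oracle_sniper_posterior <- function(nr, tr, ref, vb, theta, mu_somatic,
                                    eps = 0.001) {
  f <- c(AA = 1 - eps, AB = 0.5, BB = eps)
  ll <- function(reads, g) {
    if (is.null(reads) || nrow(reads) == 0L) return(0)
    tot <- 0
    for (i in seq_len(nrow(reads))) {
      if (reads$spans_deletion[i] || reads$base[i] == "N") next
      tot <- tot + log(oracle_emission(reads$base[i], reads$baseq[i],
                                       reads$mapq[i], f[[g]], vb, ref))
    }
    tot
  }
  pN <- c(AA = 1 - 1.5 * theta, AB = theta, BB = theta / 2)
  post <- matrix(0, 3, 3, dimnames = list(names(f), names(f)))
  for (gn in names(f)) for (gt in names(f)) {
    trans <- if (gn == gt) 1 - mu_somatic else mu_somatic / 2
    post[gn, gt] <- pN[[gn]] * trans * exp(ll(nr, gn)) * exp(ll(tr, gt))
  }
  post / sum(post)
}

# direct 9-term joint mixture posterior from counts (jsm1 model)
oracle_jsm_posterior <- function(aN, dN, aT, dT, pi, muN, muT) {
  post <- matrix(0, 3, 3, dimnames = dimnames(pi))
  for (j in 1:3) for (k in 1:3)
    post[j, k] <- pi[j, k] * stats::dbinom(aN, dN, muN[j]) *
      stats::dbinom(aT, dT, muT[k])
  post / sum(post)
}

# penalized joint mixture log-likelihood, loop version
oracle_jsm_penloglik <- function(cc, pi, muN, muT, delta, alpha, beta) {
  tot <- 0
  for (i in seq_len(nrow(cc))) {
    s <- 0
    for (j in 1:3) for (k in 1:3)
      s <- s + pi[j, k] *
        stats::dbinom(cc$a_normal[i], cc$d_normal[i], muN[j]) *
        stats::dbinom(cc$a_tumour[i], cc$d_tumour[i], muT[k])
    tot <- tot + log(s)
  }
  tot + sum((delta - 1) * log(pi)) +
    sum((alpha - 1) * log(muN) + (beta - 1) * log(1 - muN)) +
    sum((alpha - 1) * log(muT) + (beta - 1) * log(1 - muT))
}

# exhaustive strand-assignment enumeration: probability all v reads land
# on one strand under fair assignment
oracle_one_strand_prob <- function(v) {
  hits <- 0L
  for (code in 0:(2^v - 1)) {
    bits <- as.integer(intToBits(code))[1:v]
    if (all(bits == 0L) || all(bits == 1L)) hits <- hits + 1L
  }
  hits / 2^v
}
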