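#' Joint binomial mixture parameters
#'
#' Parameters of the nine-state joint genotype mixture (JointSNVMix
#' style): `pi`, a 3x3 matrix of joint genotype probabilities (rows =
#' normal AA/AB/BB, columns = tumour); `delta`, the matching Dirichlet
#' pseudocounts; `mu_normal`/`mu_tumour`, the per-genotype probabilities
#' that a read supports the reference; and `alpha`/`beta`, per-genotype
#' Beta pseudocounts (applied to both samples) regularizing `mu`.
#'
#' Defaults concentrate the Dirichlet mass on (AA, AA) — almost every
#' genomic site is reference in both samples — with a small symmetric
#' mass of 2 elsewhere. Raising the off-diagonal mass reproduces the
#' over-confident somatic probabilities this mixture is known for; the
#' lever is deliberately exposed.
#'
#' @param mu_normal,mu_tumour length-3 reference-success probabilities
#'   for AA/AB/BB.
#' @param alpha,beta length-3 Beta pseudocounts per genotype.
#' @param delta 3x3 Dirichlet pseudocount matrix.
#' @param pi 3x3 joint genotype probability matrix; defaults to the
#'   normalized `delta`.
#' @return a `jsm_params` list.
#' @export
jsm_params <- function(mu_normal = c(0.99, 0.5, 0.01),
                       mu_tumour = c(0.99, 0.5, 0.01),
                       alpha = c(1000, 500, 10), beta = c(10, 500, 1000),
                       delta = NULL, pi = NULL) {
  if (is.null(delta)) {
    delta <- matrix(2, 3, 3)
    delta[1, 1] <- 1e6
  }
  dimnames(delta) <- list(GENOTYPES, GENOTYPES)
  if (is.null(pi)) pi <- delta / sum(delta)
  dimnames(pi) <- list(GENOTYPES, GENOTYPES)
  stopifnot(abs(sum(pi) - 1) < 1e-9, all(pi > 0),
            all(mu_normal > 0 & mu_normal < 1),
            all(mu_tumour > 0 & mu_tumour < 1),
            all(alpha > 0), all(beta > 0), all(delta > 0))
  structure(list(pi = pi, delta = delta,
                 mu_normal = stats::setNames(mu_normal, GENOTYPES),
                 mu_tumour = stats::setNames(mu_tumour, GENOTYPES),
                 alpha = stats::setNames(alpha, GENOTYPES),
                 beta = stats::setNames(beta, GENOTYPES)),
            class = "jsm_params")
}

# Reference-supporting read counts (a) and usable depths (d) per site per
# sample; N bases and spanning deletions carry no base call.
.jsm_counts <- function(pp, min_base_quality = 0) {
  n <- nrow(pp$sites)
  cnt <- function(reads) {
    ok <- !reads$spans_deletion & reads$base != "N" &
      reads$baseq >= min_base_quality
    d <- tabulate(reads$site[ok], nbins = n)
    a <- tabulate(reads$site[ok & reads$base == pp$sites$ref[reads$site]],
                  nbins = n)
    list(a = a, d = d)
  }
  cn <- cnt(pp$normal); ct <- cnt(pp$tumour)
  data.frame(a_normal = cn$a, d_normal = cn$d,
             a_tumour = ct$a, d_tumour = ct$d)
}

# n x 9 log joint weights: log pi_jk + log Bin(aN | dN, muN_j)
#                                    + log Bin(aT | dT, muT_k).
# Column order is row-major over (j = normal, k = tumour).
.jsm_logjoint <- function(cc, params) {
  lN <- sapply(params$mu_normal,
               function(mu) stats::dbinom(cc$a_normal, cc$d_normal, mu,
                                          log = TRUE))
  lT <- sapply(params$mu_tumour,
               function(mu) stats::dbinom(cc$a_tumour, cc$d_tumour, mu,
                                          log = TRUE))
  lp <- matrix(0, nrow(cc), 9L)
  col <- 0L
  for (j in 1:3) for (k in 1:3) {
    col <- col + 1L
    lp[, col] <- log(params$pi[j, k]) + lN[, j] + lT[, k]
  }
  lp
}

.jsm_penalty <- function(params) {
  sum((params$delta - 1) * log(params$pi)) +
    sum((params$alpha - 1) * log(params$mu_normal) +
        (params$beta - 1) * log(1 - params$mu_normal)) +
    sum((params$alpha - 1) * log(params$mu_tumour) +
        (params$beta - 1) * log(1 - params$mu_tumour))
}

.row_lse <- function(lp) {
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Fit the joint binomial mixture by MAP expectation-maximization
#'
#' E-step: site responsibilities over the nine joint genotypes from the
#' current `pi` and binomial likelihoods of the reference-supporting read
#' counts. M-step: Dirichlet-regularized update of `pi` and
#' Beta-regularized updates of the per-genotype reference-success
#' probabilities `mu` for each sample. Iterates until the penalized
#' log-posterior improves by less than `tol` or `max_iter` is reached;
#' the trace is non-decreasing (a property the tests assert).
#'
#' @param x a [paired_pileup()], or a data.frame of counts with columns
#'   `a_normal, d_normal, a_tumour, d_tumour`.
#' @param params0 starting [jsm_params()] (also the prior pseudocounts).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the penalized log-likelihood.
#' @param min_base_quality base-quality cutoff when counting from a
#'   pileup.
#' @return a `jsm_fit`: list with `params` (trained [jsm_params()]),
#'   `trace` (penalized log-likelihood per iteration), `iterations`, and
#'   `converged`. Has `print`, `coef` and `logLik` methods.
#' @export
train_jsm_em <- function(x, params0 = jsm_params(), max_iter = 100L,
                         tol = 1e-6, min_base_quality = 0) {
  cc <- if (inherits(x, "paired_pileup")) .jsm_counts(x, min_base_quality)
        else x
  stopifnot(nrow(cc) > 0L, max_iter >= 0L)
  params <- params0
  trace <- numeric(0)
  converged <- FALSE
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lp <- .jsm_logjoint(cc, params)
    lse <- .row_lse(lp)
    ll <- sum(lse) + .jsm_penalty(params)
    if (length(trace) && ll - trace[length(trace)] < tol) {
      trace <- c(trace, ll)
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    gam <- exp(lp - lse)                       # n x 9 responsibilities
    gsum <- colSums(gam)
    pi_num <- matrix(gsum, 3, 3, byrow = TRUE) + params$delta - 1
    if (any(pi_num <= 0)) {
      warning("degenerate Dirichlet pseudocounts; clamping pi")
      pi_num <- pmax(pi_num, 1e-6)
    }
    pi_new <- pi_num / (nrow(cc) + sum(params$delta) - 9)
    pi_new <- pi_new / sum(pi_new)
    dimnames(pi_new) <- dimnames(params$pi)
    wN <- gam[, c(1, 4, 7)] + gam[, c(2, 5, 8)] + gam[, c(3, 6, 9)]
    wT <- gam[, c(1, 2, 3)] + gam[, c(4, 5, 6)] + gam[, c(7, 8, 9)]
    upd <- function(w, a, d) {
      num <- colSums(w * a) + params$alpha - 1
      den <- colSums(w * d) + params$alpha + params$beta - 2
      if (any(num <= 0) || any(den <= num)) {
        warning("degenerate Beta pseudocounts; clamping mu")
      }
      clamp(num / pmax(den, 1e-12))
    }
    params$pi <- pi_new
    params$mu_normal <- upd(wN, cc$a_normal, cc$d_normal)
    params$mu_tumour <- upd(wT, cc$a_tumour, cc$d_tumour)
  }
  structure(list(params = params, trace = trace, iterations = iter,
                 converged = converged, n_sites = nrow(cc)),
            class = "jsm_fit")
}

#' @export
print.jsm_fit <- function(x, ...) {
  cat(sprintf("jsm_fit: %d sites, %d EM iterations (%s)\n", x$n_sites,
              x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  if (length(x$trace))
    cat(sprintf("penalized log-likelihood: %.4f\n", x$trace[length(x$trace)]))
  cat("mu_normal:", sprintf("%.4f", x$params$mu_normal), "\n")
  cat("mu_tumour:", sprintf("%.4f", x$params$mu_tumour), "\n")
  invisible(x)
}

#' @export
coef.jsm_fit <- function(object, ...) {
  list(pi = object$params$pi, mu_normal = object$params$mu_normal,
       mu_tumour = object$params$mu_tumour)
}

#' @export
logLik.jsm_fit <- function(object, ...) {
  val <- if (length(object$trace)) object$trace[length(object$trace)] else NA_real_
  structure(val, df = 8 + 3 + 3, class = "logLik")
}

.jsm_core <- function(nr, tr, ref, params, mode, model) {
  vb <- summarize_alleles(tr, ref)$variant_base
  if (is.na(vb)) vb <- summarize_alleles(nr, ref)$variant_base
  if (mode == "jsm1") {
    qual <- function(r) {
      if (is.null(r) || length(r$base) == 0L) return(c(a = 0L, d = 0L))
      ok <- !r$spans_deletion & r$base != "N"
      c(a = sum(ok & r$base == ref), d = sum(ok))
    }
    qn <- qual(nr); qt <- qual(tr)
    llN <- stats::dbinom(qn[["a"]], qn[["d"]], params$mu_normal, log = TRUE)
    llT <- stats::dbinom(qt[["a"]], qt[["d"]], params$mu_tumour, log = TRUE)
  } else {
    # per-read kernel with the genotype reference fraction replaced by mu
    lik <- function(r, mu) {
      if (is.null(r) || length(r$base) == 0L) return(c(0, 0, 0))
      co <- .emission_coefs(r, vb, ref)
      if (is.null(co)) return(c(0, 0, 0))
      vapply(mu, function(m) sum(log(co$A + (1 - m) * co$B)), 0)
    }
    llN <- lik(nr, params$mu_normal)
    llT <- lik(tr, params$mu_tumour)
  }
  lp <- log(params$pi) + outer(llN, llT, `+`)
  post <- exp(lp - .logsumexp(lp))
  score <- post["AA", "AB"] + post["AA", "BB"]
  loh <- post["AB", "AA"] + post["AB", "BB"]
  other <- 1 - score - loh
  amax <- arrayInd(which.max(post), c(3L, 3L))
  gN <- GENOTYPES[amax[1]]; gT <- GENOTYPES[amax[2]]
  class <- if (score >= loh && score >= other) "somatic"
           else if (loh > score && loh >= other) "LOH"
           else if (gN == gT && gN == "AA") "reference"
           else if (gN == gT) "germline" else "unknown"
  list(class = class, score = unname(score), loh_prob = unname(loh),
       phred_score = NULL, normal_gt = gN, tumour_gt = gT,
       variant_base = vb, posterior = post,
       n = .count_base(nr, ref, vb), t = .count_base(tr, ref, vb))
}

#' Call one site with the joint binomial mixture
#'
#' Computes the posterior over the nine joint genotypes from trained
#' mixture parameters. `jsm1` uses binomial likelihoods of the
#' reference-supporting counts (perfect base calls and alignment
#' assumed); `jsm2` weighs each read by base and mapping quality through
#' the shared emission kernel, with the genotype reference fraction
#' replaced by the trained `mu`. The somatic score is
#' P(AA,AB) + P(AA,BB); the LOH probability is P(AB,AA) + P(AB,BB). A
#' zero-depth sample contributes a uniform likelihood.
#'
#' @param site a [paired_site()].
#' @param params a [jsm_params()] or a `jsm_fit` from [train_jsm_em()].
#' @param mode `"jsm2"` (default) or `"jsm1"`.
#' @param model a [genotype_likelihood_model()] (kernel bounds only).
#' @return a one-row `candidate_calls` data.frame.
#' @export
call_jointsnvmix <- function(site, params, mode = c("jsm2", "jsm1"),
                             model = genotype_likelihood_model()) {
  mode <- match.arg(mode)
  if (inherits(params, "jsm_fit")) params <- params$params
  res <- .jsm_core(.reads_as_list(site$normal), .reads_as_list(site$tumour),
                   site$ref, params, mode, model)
  .as_candidate_calls(.call_row(site$chrom, site$pos, "jointsnvmix",
                                res$class, res$score, res$phred_score,
                                res$normal_gt, res$tumour_gt,
                                res$variant_base, res$n, res$t))
}
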