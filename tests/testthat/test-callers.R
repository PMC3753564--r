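test_that("read likelihood kernel reaches its analytic limits", {
  model <- genotype_likelihood_model()
  lk <- function(base, g, baseq = 93, mapq = 93)
    read_likelihood(mk_reads(base, baseq = baseq, mapq = mapq), g, model,
                    variant_base = "C", ref = "A")
  # noise-free reference read under AA: probability -> f_AA = 0.999
  expect_equal(lk("A", "AA"), 0.999, tolerance = 1e-6)
  # noise-free variant read under AB: either allele equally -> 0.5
  expect_equal(lk("C", "AB"), 0.5, tolerance = 1e-6)
  # unmapped read carries no information
  expect_equal(lk("A", "AA", mapq = 0), 0.25)
  expect_equal(lk("C", "BB", mapq = 0), 0.25)
  # monotone in base quality for a concordant read
  qs <- seq(5, 60, by = 5)
  vals <- vapply(qs, function(q) lk("A", "AA", baseq = q, mapq = 60), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("Fisher caller classifies somatic and LOH and matches enumeration", {
  cfg <- varscan_config()
  # clear somatic: normal 30 ref / 0 var, tumour 15 ref / 15 var
  s <- mk_site("A", mk_stack("A", "C", 30, 0), mk_stack("A", "C", 15, 15))
  call <- call_varscan(s, cfg)
  expect_equal(call$class, "somatic")
  expect_equal(call$normal_gt, "AA")
  expect_equal(call$tumour_gt, "AB")
  p <- 1 - call$score
  expect_lt(p, 0.001)
  expect_lt(abs(p - oracle_fisher_one_tailed(15, 15, 0, 30)), 1e-12)

  # tumour variant proportion below the 0.20 gate: no call
  s <- mk_site("A", mk_stack("A", "C", 81, 0), mk_stack("A", "C", 81, 19))
  expect_null(call_varscan(s, cfg))

  # LOH: normal het, tumour homozygous reference
  s <- mk_site("A", mk_stack("A", "C", 10, 10), mk_stack("A", "C", 20, 0))
  call <- call_varscan(s, cfg)
  expect_equal(call$class, "LOH")
  expect_equal(call$normal_gt, "AB")
  expect_lt(1 - call$score, 0.05)

  # zero-depth sample: no call
  s <- mk_site("A", mk_reads(character(0)), mk_stack("A", "C", 10, 10))
  expect_null(call_varscan(s, cfg))
})

test_that("one-tailed Fisher p equals hypergeometric enumeration and fisher.test", {
  set.seed(21)
  for (rep in 1:200) {
    tot <- sample(4:60, 1)
    v_t <- sample(0:tot, 1)
    rest <- tot - v_t
    r_t <- sample(0:rest, 1)
    rest <- rest - r_t
    v_n <- sample(0:rest, 1)
    r_n <- rest - v_n
    if (v_t + r_t == 0 || v_n + r_n == 0) next
    p <- snvcompare:::.fisher_one_tailed(v_t, r_t, v_n, r_n)
    expect_equal(p, oracle_fisher_one_tailed(v_t, r_t, v_n, r_n),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(v_t, r_t, v_n, r_n), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("joint-genotype posterior matches the direct 9-term oracle", {
  priors <- prior_config()
  model <- genotype_likelihood_model()
  set.seed(31)
  for (rep in 1:25) {
    dn <- sample(5:30, 1); dt <- sample(5:30, 1)
    vn <- rbinom(1, dn, 0.15); vt <- rbinom(1, dt, 0.4)
    nr <- mk_stack("A", "G", dn - vn, vn, baseq = sample(15:45, 1),
                   mapq = sample(c(20L, 40L, 60L), 1))
    tr <- mk_stack("A", "G", dt - vt, vt, baseq = sample(15:45, 1),
                   mapq = sample(c(20L, 40L, 60L), 1))
    core <- snvcompare:::.sniper_core(snvcompare:::.reads_as_list(nr),
                                      snvcompare:::.reads_as_list(tr),
                                      "A", priors, model)
    orc <- oracle_sniper_posterior(nr, tr, "A", core$variant_base,
                                   priors$theta, priors$mu_somatic)
    expect_equal(sum(core$posterior), 1, tolerance = 1e-9)
    expect_equal(unname(core$posterior), unname(orc), tolerance = 1e-9)
  }
})

test_that("somatic score behaves at the no-data, clear-somatic and symmetric limits", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  # no reads at all: posterior equals the prior, S ~ 0
  core <- snvcompare:::.sniper_core(NULL, NULL, "A", priors, model)
  expect_equal(core$S, 0L)
  prior_mat <- outer(c(1 - 1.5 * priors$theta, priors$theta,
                       priors$theta / 2),
                     rep(1, 3)) *
    (diag(3) * (1 - priors$mu_somatic) +
     (1 - diag(3)) * priors$mu_somatic / 2)
  expect_equal(unname(core$posterior), prior_mat / sum(prior_mat),
               tolerance = 1e-12)
  # the exported per-site caller declines a fully empty site
  expect_null(call_somaticsniper(mk_site("A")))

  # deep noise-free somatic site: argmax (AA, AB); S equals the phred of
  # the oracle's P(gN = gT) (the (AB, AB) term dominates that residue)
  nr <- mk_stack("A", "C", 50, 0, baseq = 93, mapq = 93)
  tr <- mk_stack("A", "C", 25, 25, baseq = 93, mapq = 93)
  s <- mk_site("A", nr, tr)
  call <- call_somaticsniper(s, priors, model)
  expect_equal(call$class, "somatic")
  expect_equal(call$normal_gt, "AA")
  expect_equal(call$tumour_gt, "AB")
  orc <- oracle_sniper_posterior(nr, tr, "A", "C", priors$theta,
                                 priors$mu_somatic)
  expect_equal(call$phred_score,
               as.integer(round(-10 * log10(sum(diag(orc))))))
  expect_gt(call$phred_score, 100L)
  # twice the depth drives P(gN = gT) below 10^-25.5: capped at 255
  s <- mk_site("A", mk_stack("A", "C", 100, 0, baseq = 93, mapq = 93),
               mk_stack("A", "C", 50, 50, baseq = 93, mapq = 93))
  expect_equal(call_somaticsniper(s, priors, model)$phred_score, 255L)

  # identical deep stacks: genotypes certainly equal, S = 0
  st <- mk_stack("A", "C", 25, 25, baseq = 93, mapq = 93)
  call <- call_somaticsniper(mk_site("A", st, st), priors, model)
  expect_equal(call$phred_score, 0L)
  expect_equal(call$score, 0)
})

test_that("EM returns params unchanged at max_iter 0 and is monotone on random data", {
  p0 <- jsm_params()
  cc <- data.frame(a_normal = c(10L, 5L, 0L), d_normal = c(10L, 10L, 4L),
                   a_tumour = c(10L, 6L, 1L), d_tumour = c(10L, 12L, 6L))
  fit0 <- train_jsm_em(cc, p0, max_iter = 0)
  expect_identical(fit0$params, p0)
  expect_length(fit0$trace, 0L)

  set.seed(41)
  for (rep in 1:20) {
    n <- 150
    d1 <- rpois(n, 25); d2 <- rpois(n, 25)
    truth <- sample(1:3, n, replace = TRUE, prob = c(0.9, 0.08, 0.02))
    mu <- c(0.99, 0.5, 0.01)
    cc <- data.frame(a_normal = rbinom(n, d1, mu[truth]), d_normal = d1,
                     a_tumour = rbinom(n, d2, mu[truth]), d_tumour = d2)
    fit <- train_jsm_em(cc, max_iter = 30)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("EM recovers the heterozygote reference-success rate", {
  set.seed(51)
  n <- 10000
  pi_true <- matrix(0, 3, 3); pi_true[1, 1] <- 0.96
  pi_true[2, 2] <- 0.02; pi_true[1, 2] <- 0.01; pi_true[3, 3] <- 0.01
  jt <- sample(1:9, n, replace = TRUE, prob = as.vector(t(pi_true)))
  j <- (jt - 1) %/% 3 + 1; k <- (jt - 1) %% 3 + 1
  mu <- c(0.99, 0.5, 0.01)
  dN <- rpois(n, 30); dT <- rpois(n, 30)
  cc <- data.frame(a_normal = rbinom(n, dN, mu[j]), d_normal = dN,
                   a_tumour = rbinom(n, dT, mu[k]), d_tumour = dT)
  fit <- train_jsm_em(cc, max_iter = 100)
  expect_lt(abs(fit$params$mu_normal[["AB"]] - 0.5), 0.02)
  expect_lt(abs(fit$params$mu_tumour[["AB"]] - 0.5), 0.02)
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("converged EM sits at a coordinate-wise penalized-likelihood maximum", {
  set.seed(61)
  n <- 60
  d <- rpois(n, 20) + 5
  truth <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  mu <- c(0.99, 0.5, 0.01)
  cc <- data.frame(a_normal = rbinom(n, d, mu[truth]), d_normal = d,
                   a_tumour = rbinom(n, d, mu[truth]), d_tumour = d)
  fit <- train_jsm_em(cc, max_iter = 500, tol = 1e-12)
  expect_true(fit$converged)
  pp <- fit$params
  base_ll <- oracle_jsm_penloglik(cc, pp$pi, pp$mu_normal, pp$mu_tumour,
                                  pp$delta, pp$alpha, pp$beta)
  # another EM step barely moves the parameters
  fit2 <- train_jsm_em(cc, pp, max_iter = 1)
  expect_lt(max(abs(fit2$params$mu_normal - pp$mu_normal)), 1e-5)
  expect_lt(max(abs(fit2$params$pi - pp$pi)), 1e-5)
  # 1-D slices through each mu coordinate peak at the converged value
  for (g in 1:3) {
    grid <- seq(max(1e-4, pp$mu_normal[g] - 0.05),
                min(1 - 1e-4, pp$mu_normal[g] + 0.05), length.out = 41)
    slice <- vapply(grid, function(v) {
      muN <- pp$mu_normal; muN[g] <- v
      oracle_jsm_penloglik(cc, pp$pi, muN, pp$mu_tumour, pp$delta,
                           pp$alpha, pp$beta)
    }, 0)
    expect_lt(abs(grid[which.max(slice)] - pp$mu_normal[g]),
              1.5 * diff(grid[1:2]))
    expect_gte(base_ll, max(slice) - 1e-6)
  }
})

test_that("joint mixture posterior is normalized and matches the 9-term oracle", {
  params <- jsm_params()
  model <- genotype_likelihood_model()
  set.seed(71)
  for (rep in 1:25) {
    dn <- sample(5:40, 1); dt <- sample(5:40, 1)
    vn <- rbinom(1, dn, 0.1); vt <- rbinom(1, dt, 0.5)
    s <- mk_site("A", mk_stack("A", "T", dn - vn, vn),
                 mk_stack("A", "T", dt - vt, vt))
    call <- call_jointsnvmix(s, params, mode = "jsm1", model = model)
    orc <- oracle_jsm_posterior(dn - vn, dn, dt - vt, dt, params$pi,
                                params$mu_normal, params$mu_tumour)
    expect_equal(call$score, orc["AA", "AB"] + orc["AA", "BB"],
                 tolerance = 1e-9)
  }
  # deep somatic site: score > 0.99
  s <- mk_site("A", mk_stack("A", "C", 100, 0), mk_stack("A", "C", 50, 50))
  expect_gt(call_jointsnvmix(s, params)$score, 0.99)
})

test_that("quality-weighted and count-based mixture modes agree at Q93", {
  params <- jsm_params(); model <- genotype_likelihood_model()
  set.seed(81)
  for (rep in 1:10) {
    dn <- sample(10:40, 1); dt <- sample(10:40, 1)
    vn <- rbinom(1, dn, 0.05); vt <- rbinom(1, dt, 0.3)
    s <- mk_site("A", mk_stack("A", "C", dn - vn, vn, baseq = 93, mapq = 93),
                 mk_stack("A", "C", dt - vt, vt, baseq = 93, mapq = 93))
    s1 <- call_jointsnvmix(s, params, "jsm1", model)$score
    s2 <- call_jointsnvmix(s, params, "jsm2", model)$score
    expect_equal(s1, s2, tolerance = 1e-6)
  }
})

test_that("marginalized-frequency caller scores the designed extremes", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  # tumour indistinguishable from a hom-ref normal: score near the prior
  s <- mk_site("A", mk_stack("A", "C", 60, 0, baseq = 93, mapq = 93),
               mk_stack("A", "C", 60, 0, baseq = 93, mapq = 93))
  call <- call_strelka_like(s, priors, model)
  expect_lt(call$score, priors$mu_somatic * 10)
  # ~5% VAF candidate on a clean deep pair is detectable
  s <- mk_site("A", mk_stack("A", "C", 200, 0, baseq = 40),
               mk_stack("A", "C", 190, 10, baseq = 40))
  call <- call_strelka_like(s, priors, model)
  expect_gt(call$score, 0.5)
  expect_equal(call$class, "somatic")
  # zero tumour depth: score collapses to ~ the somatic prior
  s <- mk_site("A", mk_stack("A", "C", 30, 0), mk_reads(character(0)))
  expect_lt(call_strelka_like(s, priors, model)$score,
            2 * priors$mu_somatic)
})

test_that("marginalized-frequency score is stable under grid refinement", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  set.seed(91)
  for (rep in 1:15) {
    dn <- sample(20:80, 1); dt <- sample(20:80, 1)
    vn <- rbinom(1, dn, 0.02); vt <- rbinom(1, dt, runif(1, 0, 0.4))
    s <- mk_site("A", mk_stack("A", "G", dn - vn, vn),
                 mk_stack("A", "G", dt - vt, vt))
    a <- call_strelka_like(s, priors, model, grid_step = 0.01)$score
    b <- call_strelka_like(s, priors, model, grid_step = 0.005)$score
    expect_lt(abs(a - b), 0.02)
  }
})

test_that("Bayesian caller scores are non-decreasing in tumour variant count", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  params <- jsm_params()
  nr <- mk_stack("A", "C", 40, 0)
  score3 <- vapply(0:20, function(v) {
    s <- mk_site("A", nr, mk_stack("A", "C", 40 - v, v))
    c(call_somaticsniper(s, priors, model)$score,
      call_jointsnvmix(s, params, "jsm2", model)$score,
      call_strelka_like(s, priors, model)$score)
  }, numeric(3))
  for (r in 1:3) expect_true(all(diff(score3[r, ]) >= -1e-9))
})

test_that("swapping the samples maps deep somatic calls to LOH-or-other", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  params <- jsm_params()
  nr <- mk_stack("A", "C", 60, 0, baseq = 93, mapq = 93)
  tr <- mk_stack("A", "C", 30, 30, baseq = 93, mapq = 93)
  fwd <- mk_site("A", nr, tr); rev <- mk_site("A", tr, nr)
  expect_equal(call_somaticsniper(fwd, priors, model)$class, "somatic")
  expect_equal(call_somaticsniper(rev, priors, model)$class, "LOH")
  expect_equal(call_jointsnvmix(fwd, params)$class, "somatic")
  expect_equal(call_jointsnvmix(rev, params)$class, "LOH")
})

test_that("run_all_callers: silence on the noise-free null, consensus on a clonal site", {
  cfg <- sim_config(n_sites = 400, seed = 17,
                    base_quality_distribution = list(values = 93, probs = 1),
                    map_quality_distribution = list(values = 93, probs = 1),
                    germline_het_rate = 0, germline_hom_rate = 0,
                    n_clonal_somatic = 0, n_subclonal_somatic = 0,
                    systematic_error_site_rate = 0,
                    spanning_deletion_rate = 0, adjacent_indel_rate = 0)
  calls <- run_all_callers(simulate_pair(cfg)$pileup)
  expect_equal(sum(calls$class == "somatic" & calls$score > 0.99), 0L)

  cfg2 <- cfg
  cfg2$n_clonal_somatic <- 1L
  cfg2$tumour_purity <- 1
  cfg2$mean_depth_normal <- 60; cfg2$mean_depth_tumour <- 60
  sim <- simulate_pair(cfg2)
  calls <- run_all_callers(sim$pileup)
  som <- calls[calls$class == "somatic", ]
  i <- which(sim$truth$truth_class == "somatic_clonal")
  expect_equal(sort(unique(som$caller)), sort(CALLERS <- c("jointsnvmix",
               "somaticsniper", "strelka_like", "varscan")))
  expect_true(all(som$pos == sim$truth$pos[i]))
  expect_true(all(som$score > 0.99))
})

test_that("a 10% VAF site is missed by the Fisher caller but found deep by the marginal one", {
  priors <- prior_config(); model <- genotype_likelihood_model()
  s <- mk_site("A", mk_stack("A", "C", 200, 0, baseq = 35),
               mk_stack("A", "C", 180, 20, baseq = 35))
  expect_null(call_varscan(s))   # 10% < the 0.20 minimum variant frequency
  st <- call_strelka_like(s, priors, model)
  expect_gt(st$score, 0.5)
  expect_gte(st$phred_score, 1L)
})

test_that("low-fraction sensitivity: marginal caller outscores the Fisher caller", {
  set.seed(101)
  priors <- prior_config(); model <- genotype_likelihood_model()
  n_rep <- 60
  sc_st <- sc_vs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    vaf <- runif(1, 0.05, 0.15)
    dt <- 100
    vt <- rbinom(1, dt, vaf)
    s <- mk_site("A", mk_stack("A", "C", 100, 0, baseq = 35),
                 mk_stack("A", "C", dt - vt, vt, baseq = 35))
    sc_st[r] <- call_strelka_like(s, priors, model)$score
    vs <- call_varscan(s)
    sc_vs[r] <- if (is.null(vs)) 0 else vs$score
  }
  expect_gt(mean(sc_st), mean(sc_vs))
})
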