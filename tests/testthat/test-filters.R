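test_that("each filter rule fails exactly at its planted site", {
  fx <- filter_fixture()
  v <- apply_filters_all(fx$calls, fx$pp, filter_config(),
                         all_candidate_positions = fx$cand)
  rules <- paste0(snvcompare:::FILTER_RULES, "_pass")
  fails <- lapply(1:12, function(i)
    snvcompare:::FILTER_RULES[!unlist(v[i, rules])])
  expect_equal(fails[[1]], "strand_bias")
  expect_equal(fails[[2]], "mean_baseq")
  expect_equal(fails[[3]], "max_baseq")
  expect_equal(fails[[4]], "mean_mapq")
  expect_equal(fails[[5]], "max_mapq")
  expect_equal(fails[[6]], "nearby_snvs")
  expect_equal(v$nearby_snvs_metric[6], 3L)
  expect_equal(fails[[7]], "spanning_deletion")
  expect_equal(fails[[8]], "adjacent_indel")
  expect_equal(fails[[9]], character(0))
  expect_equal(fails[[10]], character(0))   # v = 0: vacuous pass
  expect_equal(fails[[11]], character(0))   # LOH judged on the normal
  expect_equal(fails[[12]], character(0))
  expect_equal(v$overall_pass, c(rep(FALSE, 8), rep(TRUE, 4)))
  # metric spot checks
  expect_equal(v$mean_baseq_metric[2], 13.75)
  expect_equal(v$max_baseq_metric[3], 30)
  expect_equal(v$mean_mapq_metric[4], 11.25)
  expect_equal(v$spanning_deletion_metric[7], 0.25)
  expect_equal(v$adjacent_indel_metric[8], 0.25)
})

test_that("boundary semantics: Q30/Q40 maxima fail, passing needs strictly over", {
  # variant baseQs {30, 30}: mean 30 passes, "over 30" strictly fails
  r <- rbind(mk_reads(rep("A", 10), strand = rep(c("+", "-"), 5)),
             mk_reads(c("C", "C"), baseq = 30L, strand = c("+", "-")))
  s <- mk_site("A", mk_reads(rep("A", 10)), r, pos = 500L)
  call <- snvcompare:::.as_candidate_calls(snvcompare:::.call_row(
    "chr1", 500L, "varscan", "somatic", 0.9, NULL, "AA", "AB", "C",
    snvcompare:::.count_base(snvcompare:::.reads_as_list(s$normal), "A", "C"),
    snvcompare:::.count_base(snvcompare:::.reads_as_list(s$tumour), "A", "C")))
  v <- apply_filters(call, s, data.frame(chrom = "chr1", pos = 500L))
  expect_true(v$mean_baseq_pass)
  expect_false(v$max_baseq_pass)
  # one Q31 read rescues the rule
  r$baseq[nrow(r)] <- 31L
  s <- mk_site("A", mk_reads(rep("A", 10)), r, pos = 500L)
  v <- apply_filters(call, s, data.frame(chrom = "chr1", pos = 500L))
  expect_true(v$max_baseq_pass)
})

test_that("verdicts do not depend on call order or caller label", {
  fx <- filter_fixture()
  v1 <- apply_filters_all(fx$calls, fx$pp, filter_config(),
                          all_candidate_positions = fx$cand)
  perm <- sample(nrow(fx$calls))
  calls2 <- fx$calls[perm, ]
  calls2$caller <- "strelka_like"
  v2 <- apply_filters_all(snvcompare:::.as_candidate_calls(calls2), fx$pp,
                          filter_config(), all_candidate_positions = fx$cand)
  expect_equal(v2$overall_pass, v1$overall_pass[perm])
  expect_equal(v2$nearby_snvs_metric, v1$nearby_snvs_metric[perm])
})

test_that("any filtered-through site with v >= 2 has both strands represented", {
  fx <- filter_fixture()
  v <- apply_filters_all(fx$calls, fx$pp, filter_config(),
                         all_candidate_positions = fx$cand)
  ok <- v[v$overall_pass & v$v >= 2, ]
  expect_true(all(ok$v_forward >= 1 & ok$v_reverse >= 1))
})

test_that("strand-bias null probability matches exhaustive enumeration", {
  expect_equal(strand_bias_null_probability(1), 1.0)
  expect_equal(strand_bias_null_probability(2), 0.5)
  expect_equal(strand_bias_null_probability(5), 0.0625)
  expect_error(strand_bias_null_probability(0))
  for (v in 1:10)
    expect_equal(strand_bias_null_probability(v), oracle_one_strand_prob(v))
})

test_that("expected strand-bias count sums the per-site null probabilities", {
  mk <- function(v, vf) {
    n0 <- list(depth = 30L, ref_count = 30L, v = 0L, v_forward = 0L,
               v_reverse = 0L)
    do.call(rbind, lapply(seq_along(v), function(i)
      snvcompare:::.call_row("chr1", i, "varscan", "somatic", 0.9, NULL,
                             "AA", "AB", "C", n0,
                             list(depth = 30L, ref_count = 30L - v[i],
                                  v = v[i], v_forward = vf[i],
                                  v_reverse = v[i] - vf[i]))))
  }
  res <- expected_strand_bias_count(mk(c(1L, 2L, 3L), c(1L, 1L, 2L)))
  expect_equal(res$expected, 1.75)
  expect_equal(res$observed, 1L)  # only the single-read site is one-sided
  # all v = 1: always one-sided, expected = observed = n
  res <- expected_strand_bias_count(mk(rep(1L, 7), rep(1L, 7)))
  expect_equal(res$expected, 7)
  expect_equal(res$observed, 7L)
  # zero-variant calls are excluded and counted
  res <- expected_strand_bias_count(mk(c(0L, 1L), c(0L, 1L)))
  expect_equal(res$n_used, 1L)
  expect_equal(res$n_zero_variant, 1L)
})

test_that("fair strand assignment keeps the observed biased count inside 3 sigma", {
  set.seed(7)
  n <- 10000
  v <- pmax(1L, rpois(n, 3))
  vf <- rbinom(n, v, 0.5)
  n0 <- list(depth = 30L, ref_count = 30L, v = 0L, v_forward = 0L,
             v_reverse = 0L)
  calls <- do.call(rbind, lapply(seq_len(n), function(i)
    snvcompare:::.call_row("chr1", i, "varscan", "somatic", 0.9, NULL, "AA",
                           "AB", "C", n0,
                           list(depth = 30L, ref_count = 30L - v[i],
                                v = v[i], v_forward = vf[i],
                                v_reverse = v[i] - vf[i]))))
  res <- expected_strand_bias_count(calls)
  expect_lt(abs(res$observed - res$expected), 3 * res$sd)
})

test_that("systematic-error sites are fully strand biased; fair sites at the null rate", {
  cfg <- sim_config(n_sites = 4000, seed = 23,
                    base_quality_distribution = list(values = 93, probs = 1),
                    map_quality_distribution = list(values = 93, probs = 1),
                    germline_het_rate = 0, germline_hom_rate = 0,
                    n_clonal_somatic = 40, n_subclonal_somatic = 0,
                    tumour_purity = 0.8,
                    systematic_error_site_rate = 0.01,
                    systematic_error_read_rate = 0.2,
                    spanning_deletion_rate = 0, adjacent_indel_rate = 0)
  sim <- simulate_pair(cfg)
  pp <- sim$pileup
  sys <- which(sim$truth$truth_class == "systematic_error")
  som <- which(sim$truth$truth_class == "somatic_clonal")
  n_sys_with_var <- 0L
  for (i in sys) {
    s <- summarize_alleles(paired_site(pp, i)$tumour, pp$sites$ref[i])
    if (s$v > 0) {
      n_sys_with_var <- n_sys_with_var + 1L
      expect_true(s$v_forward == 0L || s$v_reverse == 0L)
    }
  }
  expect_gt(n_sys_with_var, 10L)
  # true mutations are one-sided only at ~ the null rate
  p <- obs <- numeric(0)
  for (i in som) {
    s <- summarize_alleles(paired_site(pp, i)$tumour, pp$sites$ref[i])
    if (s$v >= 1) {
      p <- c(p, strand_bias_null_probability(s$v))
      obs <- c(obs, s$v_forward == 0L || s$v_reverse == 0L)
    }
  }
  expect_lt(abs(sum(obs) - sum(p)), 3 * sqrt(sum(p * (1 - p))) + 1)
})

test_that("pass-rate table uses strand-bias survivors as the second denominator", {
  mkv <- function(caller, n, sb_pass, other_pass_among_survivors) {
    sb <- c(rep(TRUE, sb_pass), rep(FALSE, n - sb_pass))
    other <- rep(TRUE, n)
    other[seq_len(sb_pass)] <-
      seq_len(sb_pass) <= other_pass_among_survivors
    data.frame(caller = caller, strand_bias_pass = sb,
               mean_baseq_pass = other, max_baseq_pass = TRUE,
               mean_mapq_pass = TRUE, max_mapq_pass = TRUE,
               nearby_snvs_pass = TRUE, spanning_deletion_pass = TRUE,
               adjacent_indel_pass = TRUE,
               overall_pass = sb & other, stringsAsFactors = FALSE)
  }
  verdicts <- rbind(mkv("varscan", 100L, 50L, 25L),
                    mkv("somaticsniper", 100L, 70L, 35L),
                    mkv("jointsnvmix", 80L, 40L, 10L),
                    mkv("strelka_like", 60L, 60L, 60L))
  pr <- pass_rate_table(verdicts)
  tab <- pr$table
  expect_equal(tab$strand_bias_pass_pct[tab$caller == "varscan"], 50.0)
  expect_equal(tab$strand_bias_pass_pct[tab$caller == "somaticsniper"], 70.0)
  # second column computed over survivors only
  expect_equal(tab$n_survivors[tab$caller == "jointsnvmix"], 40L)
  expect_equal(tab$other_filters_pass_pct[tab$caller == "jointsnvmix"], 25.0)
  # 50/100 vs 70/100 is significant at 0.05 with the chi-square test
  t1 <- pr$tests[pr$tests$caller1 == "varscan" &
                 pr$tests$caller2 == "somaticsniper", ]
  expect_true(t1$strand_bias_significant)
  expect_equal(t1$strand_bias_p,
               prop.test(c(50, 70), c(100, 100))$p.value)
  # identical pass rates: not significant
  verdicts2 <- rbind(mkv("varscan", 100L, 100L, 100L),
                     mkv("somaticsniper", 100L, 100L, 100L),
                     mkv("jointsnvmix", 100L, 100L, 100L),
                     mkv("strelka_like", 100L, 100L, 100L))
  pr2 <- pass_rate_table(verdicts2)
  expect_true(all(pr2$table$strand_bias_pass_pct == 100.0))
  expect_false(any(pr2$tests$strand_bias_significant))
})
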