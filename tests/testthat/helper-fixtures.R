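# Build read-observation data.frames and paired sites in code.

mk_reads <- function(base, baseq = 40L, mapq = 60L, strand = "+",
                     spans_deletion = NULL, adjacent_indel = FALSE,
                     site = 1L) {
  n <- length(base)
  if (is.null(spans_deletion)) spans_deletion <- base == "*"
  data.frame(site = rep_len(site, n), base = base,
             baseq = rep_len(as.integer(baseq), n),
             mapq = rep_len(as.integer(mapq), n),
             strand = rep_len(strand, n),
             spans_deletion = rep_len(spans_deletion, n),
             adjacent_indel = rep_len(adjacent_indel, n),
             stringsAsFactors = FALSE)
}

mk_site <- function(ref = "A", normal = mk_reads(character(0)),
                    tumour = mk_reads(character(0)),
                    chrom = "chr1", pos = 100L) {
  pp <- paired_pileup(data.frame(chrom = chrom, pos = pos, ref = ref,
                                 stringsAsFactors = FALSE),
                      normal, tumour)
  paired_site(pp, 1L)
}

# depth-d stack with v variant reads; strand split for variant reads
mk_stack <- function(ref, var, n_ref, n_var, var_fwd = ceiling(n_var / 2),
                     baseq = 40L, mapq = 60L) {
  ref_strand <- rep(c("+", "-"), length.out = n_ref)
  var_strand <- c(rep("+", var_fwd), rep("-", n_var - var_fwd))
  mk_reads(c(rep(ref, n_ref), rep(var, n_var)), baseq = baseq, mapq = mapq,
           strand = c(ref_strand, var_strand))
}

random_calls <- function(n, seed = 42) {
  set.seed(seed)
  pos <- sort(sample.int(10 * n, n))
  cnt <- function() {
    v <- sample(0:30, n, replace = TRUE)
    vf <- vapply(v, function(k) sample(0:k, 1), 0L)
    list(v = v, vf = vf)
  }
  cn <- cnt(); ct <- cnt()
  n_ref <- sample(0:60, n, replace = TRUE)
  t_ref <- sample(0:60, n, replace = TRUE)
  phred <- ifelse(stats::runif(n) < 0.5, NA_integer_,
                  sample(0:255, n, replace = TRUE))
  score <- ifelse(is.na(phred), round(stats::runif(n), 6),
                  1 - 10^(-phred / 10))
  df <- data.frame(
    chrom = "chr1", pos = pos,
    caller = sample(c("varscan", "somaticsniper", "jointsnvmix",
                      "strelka_like"), n, replace = TRUE),
    class = sample(c("somatic", "LOH", "germline", "reference", "unknown"),
                   n, replace = TRUE),
    score = score, phred_score = phred,
    normal_gt = sample(c("AA", "AB", "BB", NA), n, replace = TRUE),
    tumour_gt = sample(c("AA", "AB", "BB", NA), n, replace = TRUE),
    variant_base = sample(c("C", "G", "T", NA), n, replace = TRUE),
    n_depth = n_ref + cn$v, n_ref = n_ref, n_v = cn$v, n_v_fwd = cn$vf,
    n_v_rev = cn$v - cn$vf,
    n_vp = ifelse(cn$v + n_ref > 0, cn$v / (cn$v + n_ref), 0),
    t_depth = t_ref + ct$v, t_ref = t_ref, t_v = ct$v, t_v_fwd = ct$vf,
    t_v_rev = ct$v - ct$vf,
    t_vp = ifelse(ct$v + t_ref > 0, ct$v / (ct$v + t_ref), 0),
    stringsAsFactors = FALSE)
  snvcompare:::.as_candidate_calls(df)
}

# A 12-site fixture in which each of the 8 rules fails in isolation,
# plus control sites: clean pass, zero-variant vacuous pass, an LOH call
# judged on the normal sample, and the window-arithmetic example.
filter_fixture <- function() {
  v_ok <- function(baseq = 40L, mapq = 60L)      # 2+/2- variant reads
    mk_reads(rep("C", 4), baseq = baseq, mapq = mapq,
             strand = c("+", "-", "+", "-"))
  ref_ok <- function(n = 16L) mk_reads(rep("A", n), strand = rep(c("+", "-"), n / 2))
  stack <- function(v = v_ok(), r = ref_ok()) rbind(r, v)

  tum <- list(
    s1 = stack(mk_reads(rep("C", 4), strand = "+")),              # strand bias
    s2 = stack(mk_reads(rep("C", 4), baseq = c(5L, 5L, 5L, 40L),
                        strand = c("+", "-", "+", "-"))),         # mean baseQ 13.75
    s3 = stack(mk_reads(rep("C", 2), baseq = 30L,
                        strand = c("+", "-"))),                   # none over 30
    s4 = stack(mk_reads(rep("C", 4), mapq = c(0L, 0L, 0L, 45L),
                        strand = c("+", "-", "+", "-"))),         # mean mapQ 11.25
    s5 = stack(mk_reads(rep("C", 2), mapq = 40L,
                        strand = c("+", "-"))),                   # none over 40
    s6 = stack(),                                                 # nearby SNVs
    s7 = stack(r = rbind(ref_ok(14), mk_reads(rep("*", 6)))),     # 6/24 deletions
    s8 = stack(r = rbind(ref_ok(14),
                         mk_reads(rep("A", 6), adjacent_indel = TRUE))), # 6/24
    s9 = stack(),                                                 # clean pass
    s10 = ref_ok(),                                               # v = 0
    s11 = mk_reads(rep("C", 4), strand = "+"),  # LOH: tumour one-sided is fine
    s12 = stack())
  nrm <- lapply(1:12, function(i) ref_ok())
  nrm[[11]] <- stack()                          # LOH site: normal carries C 2+/2-
  pos <- c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L, 8000L, 9000L,
           10000L, 11000L, 12000L)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A",
                      stringsAsFactors = FALSE)
  add_site <- function(lst) do.call(rbind, lapply(seq_along(lst), function(i) {
    d <- lst[[i]]; if (nrow(d)) d$site <- i; d
  }))
  pp <- paired_pileup(sites, add_site(nrm), add_site(tum))
  calls <- do.call(rbind, lapply(1:12, function(i) {
    smp <- if (i == 11) pp$normal else pp$tumour
    cnt <- snvcompare:::.count_base(
      snvcompare:::.reads_as_list(smp[smp$site == i, ]), "A", "C")
    ref_cnt <- snvcompare:::.count_base(
      snvcompare:::.reads_as_list(
        (if (i == 11) pp$tumour else pp$normal)[
          (if (i == 11) pp$tumour else pp$normal)$site == i, ]), "A", "C")
    n <- if (i == 11) cnt else ref_cnt
    t <- if (i == 11) ref_cnt else cnt
    snvcompare:::.call_row("chr1", pos[i], "varscan",
                           if (i == 11) "LOH" else "somatic", 0.99, NULL,
                           "AA", "AB", "C", n, t)
  }))
  # extra candidate positions around site 6: distances 10, 49, 50 count,
  # 51 does not
  cand <- rbind(data.frame(chrom = "chr1", pos = pos,
                           stringsAsFactors = FALSE),
                data.frame(chrom = "chr1", pos = 6000L + c(10L, -49L, 50L,
                                                           51L),
                           stringsAsFactors = FALSE))
  list(pp = pp, calls = snvcompare:::.as_candidate_calls(calls),
       cand = cand)
}
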