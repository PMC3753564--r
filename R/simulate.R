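#' Configuration for the paired-pileup simulator
#'
#' Describes the generative world for a matched cancer--normal exome-like
#' experiment: per-site sequencing depth, germline heterozygous and
#' homozygous variant rates, a fixed number of clonal somatic SNVs whose
#' tumour allele fraction is purity/2 (heterozygous mutation in a diploid
#' tumour; aneuploidy is not modelled), subclonal somatic SNVs with
#' tumour VAF drawn uniformly from `subclonal_vaf_range`, random
#' base-call error driven by each read's phred base quality, and
#' systematic error sites whose miscalls are confined to one randomly
#' chosen strand (the signature targeted by the strand-bias filter).
#'
#' @param n_sites number of simulated sites.
#' @param seed RNG seed; a fixed seed gives a byte-identical result.
#' @param mean_depth_normal,mean_depth_tumour mean per-site depths.
#' @param depth_model `"poisson"` or `"negative_binomial"`.
#' @param depth_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed); ignored for the Poisson model.
#' @param germline_het_rate,germline_hom_rate per-site probabilities of a
#'   germline heterozygote / homozygous-variant site.
#' @param n_clonal_somatic,n_subclonal_somatic exact counts of planted
#'   clonal and subclonal somatic SNV sites.
#' @param tumour_purity fraction of tumour-sample cells that are
#'   cancerous; clonal tumour VAF = purity/2.
#' @param subclonal_vaf_range interval within (0, 0.5] for subclonal
#'   tumour VAF.
#' @param systematic_error_site_rate per-site probability that a site is
#'   susceptible to one-strand systematic error (applies to both
#'   samples: susceptibility is a property of the locus).
#' @param systematic_error_read_rate per-read miscall probability on the
#'   affected strand at a susceptible site.
#' @param base_quality_distribution,map_quality_distribution lists with
#'   `values` (phred integers) and `probs`.
#' @param normal_contamination fraction of tumour cells contaminating the
#'   normal sample; somatic normal VAF = contamination * tumour VAF.
#' @param spanning_deletion_rate,adjacent_indel_rate per-read
#'   probabilities of the deletion / adjacent-indel context flags.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 10000L, seed = 1L,
                       mean_depth_normal = 50, mean_depth_tumour = 50,
                       depth_model = c("poisson", "negative_binomial"),
                       depth_dispersion = 10,
                       germline_het_rate = 1e-3, germline_hom_rate = 5e-4,
                       n_clonal_somatic = 10L, tumour_purity = 0.8,
                       n_subclonal_somatic = 10L,
                       subclonal_vaf_range = c(0.02, 0.20),
                       systematic_error_site_rate = 1e-3,
                       systematic_error_read_rate = 0.15,
                       base_quality_distribution = list(
                         values = c(20, 25, 30, 35, 40),
                         probs = c(0.05, 0.10, 0.20, 0.30, 0.35)),
                       map_quality_distribution = list(
                         values = c(0, 20, 40, 60),
                         probs = c(0.02, 0.03, 0.15, 0.80)),
                       normal_contamination = 0,
                       spanning_deletion_rate = 0.005,
                       adjacent_indel_rate = 0.005) {
  depth_model <- match.arg(depth_model)
  cfg <- list(n_sites = as.integer(n_sites), seed = as.integer(seed),
              mean_depth_normal = mean_depth_normal,
              mean_depth_tumour = mean_depth_tumour,
              depth_model = depth_model,
              depth_dispersion = depth_dispersion,
              germline_het_rate = germline_het_rate,
              germline_hom_rate = germline_hom_rate,
              n_clonal_somatic = as.integer(n_clonal_somatic),
              tumour_purity = tumour_purity,
              n_subclonal_somatic = as.integer(n_subclonal_somatic),
              subclonal_vaf_range = subclonal_vaf_range,
              systematic_error_site_rate = systematic_error_site_rate,
              systematic_error_read_rate = systematic_error_read_rate,
              base_quality_distribution = base_quality_distribution,
              map_quality_distribution = map_quality_distribution,
              normal_contamination = normal_contamination,
              spanning_deletion_rate = spanning_deletion_rate,
              adjacent_indel_rate = adjacent_indel_rate)
  rates <- c(cfg$germline_het_rate, cfg$germline_hom_rate,
             cfg$systematic_error_site_rate, cfg$systematic_error_read_rate,
             cfg$tumour_purity, cfg$normal_contamination,
             cfg$spanning_deletion_rate, cfg$adjacent_indel_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_sites < 1L) stop("n_sites must be positive")
  if (cfg$mean_depth_normal <= 0 || cfg$mean_depth_tumour <= 0)
    stop("mean depths must be positive")
  if (length(cfg$subclonal_vaf_range) != 2L ||
      cfg$subclonal_vaf_range[1] <= 0 || cfg$subclonal_vaf_range[2] > 0.5 ||
      diff(cfg$subclonal_vaf_range) < 0)
    stop("subclonal_vaf_range must be an interval within (0, 0.5]")
  expected_mut <- cfg$n_clonal_somatic + cfg$n_subclonal_somatic +
    cfg$n_sites * (cfg$germline_het_rate + cfg$germline_hom_rate)
  if (expected_mut > cfg$n_sites)
    stop("infeasible config: more mutation sites than n_sites")
  structure(cfg, class = "sim_config")
}

TRUTH_CLASSES <- c("none", "germline_het", "germline_hom", "somatic_clonal",
                   "somatic_subclonal", "systematic_error")

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (has) assign(".Random.seed", old, envir = .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

# Draw all reads for one sample over all sites at once. `vaf` is the
# per-site expected variant allele fraction, `var_base` the per-site
# variant (or systematic-error) base, `sys` marks susceptible sites and
# `sys_strand` their affected strand.
.gen_reads <- function(cfg, mean_depth, vaf, var_base, ref, sys, sys_strand) {
  n <- cfg$n_sites
  depth <- if (cfg$depth_model == "poisson") stats::rpois(n, mean_depth)
           else stats::rnbinom(n, mu = mean_depth, size = cfg$depth_dispersion)
  site <- rep.int(seq_len(n), depth)
  m <- length(site)
  strand <- c("+", "-")[1L + (stats::runif(m) < 0.5)]
  spans <- stats::runif(m) < cfg$spanning_deletion_rate
  adj <- stats::runif(m) < cfg$adjacent_indel_rate
  bqd <- cfg$base_quality_distribution
  mqd <- cfg$map_quality_distribution
  baseq <- bqd$values[sample.int(length(bqd$values), m, replace = TRUE,
                                 prob = bqd$probs)]
  mapq <- mqd$values[sample.int(length(mqd$values), m, replace = TRUE,
                                prob = mqd$probs)]
  true_var <- stats::runif(m) < vaf[site]
  base <- ifelse(true_var, var_base[site], ref[site])
  # random base-call error: phred-driven, uniform over the other 3 bases
  err <- stats::runif(m) < 10^(-baseq / 10)
  if (any(err))
    base[err] <- ALT_BASES[cbind(match(base[err], BASES),
                                 sample.int(3L, sum(err), replace = TRUE))]
  # systematic one-strand corruption at susceptible sites
  hit <- sys[site] & strand == sys_strand[site] &
    stats::runif(m) < cfg$systematic_error_read_rate
  if (any(hit)) base[hit] <- var_base[site[hit]]
  base[spans] <- "*"
  data.frame(site = site, base = base, baseq = as.integer(baseq),
             mapq = as.integer(mapq), strand = strand,
             spans_deletion = spans, adjacent_indel = adj,
             stringsAsFactors = FALSE)
}

# Site metadata shared by both simulate_pair and split_null: positions,
# reference bases, truth classes and expected VAFs.
.gen_sites <- function(cfg) {
  n <- cfg$n_sites
  pos <- cumsum(1L + stats::rpois(n, 149))  # mean spacing ~150 bp
  ref <- sample(BASES, n, replace = TRUE)
  truth <- rep("none", n)
  u <- stats::runif(n)
  truth[u < cfg$germline_het_rate] <- "germline_het"
  truth[u >= cfg$germline_het_rate &
        u < cfg$germline_het_rate + cfg$germline_hom_rate] <- "germline_hom"
  free <- which(truth == "none")
  n_som <- cfg$n_clonal_somatic + cfg$n_subclonal_somatic
  if (n_som > length(free)) stop("infeasible config: too few free sites")
  som <- if (n_som > 0L) sample(free, n_som) else integer()
  if (cfg$n_clonal_somatic > 0L)
    truth[som[seq_len(cfg$n_clonal_somatic)]] <- "somatic_clonal"
  if (cfg$n_subclonal_somatic > 0L)
    truth[som[cfg$n_clonal_somatic + seq_len(cfg$n_subclonal_somatic)]] <-
      "somatic_subclonal"
  free <- which(truth == "none")
  sys <- rep(FALSE, n)
  sys[free[stats::runif(length(free)) < cfg$systematic_error_site_rate]] <- TRUE
  truth[sys] <- "systematic_error"
  sys_strand <- rep(".", n)
  sys_strand[sys] <- c("+", "-")[1L + (stats::runif(sum(sys)) < 0.5)]
  # variant (or error) base: one fixed non-reference base per site
  var_base <- ALT_BASES[cbind(match(ref, BASES),
                              sample.int(3L, n, replace = TRUE))]
  vaf_t <- numeric(n); vaf_n <- numeric(n)
  vaf_t[truth == "germline_het"] <- 0.5
  vaf_n[truth == "germline_het"] <- 0.5
  vaf_t[truth == "germline_hom"] <- 1
  vaf_n[truth == "germline_hom"] <- 1
  cl <- truth == "somatic_clonal"
  vaf_t[cl] <- cfg$tumour_purity / 2
  vaf_n[cl] <- cfg$normal_contamination * cfg$tumour_purity / 2
  sub <- truth == "somatic_subclonal"
  vaf_t[sub] <- stats::runif(sum(sub), cfg$subclonal_vaf_range[1],
                             cfg$subclonal_vaf_range[2])
  vaf_n[sub] <- cfg$normal_contamination * vaf_t[sub]
  list(sites = data.frame(chrom = "sim1", pos = pos, ref = ref,
                          stringsAsFactors = FALSE),
       truth = data.frame(chrom = "sim1", pos = pos, truth_class = truth,
                          true_vaf_tumour = vaf_t, true_vaf_normal = vaf_n,
                          error_strand = sys_strand, variant_base = var_base,
                          stringsAsFactors = FALSE),
       sys = sys, sys_strand = sys_strand, var_base = var_base, ref = ref,
       vaf_t = vaf_t, vaf_n = vaf_n)
}

#' Simulate a matched cancer--normal paired pileup with ground truth
#'
#' @param config a [sim_config()].
#' @return a `sim_result`: list with `pileup` (a [paired_pileup()]) and
#'   `truth` (a data.frame aligned to the sites, with `truth_class`,
#'   expected VAFs in both samples, the affected `error_strand` for
#'   systematic-error sites and the planted `variant_base`).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    w <- .gen_sites(config)
    normal <- .gen_reads(config, config$mean_depth_normal, w$vaf_n,
                         w$var_base, w$ref, w$sys, w$sys_strand)
    tumour <- .gen_reads(config, config$mean_depth_tumour, w$vaf_t,
                         w$var_base, w$ref, w$sys, w$sys_strand)
    structure(list(pileup = paired_pileup(w$sites, normal, tumour),
                   truth = w$truth, config = config),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result\n")
  print(x$pileup)
  print(table(factor(x$truth$truth_class, levels = TRUTH_CLASSES)))
  invisible(x)
}

#' Normal--normal split null
#'
#' Simulates ONE non-cancer sample at twice the configured normal depth
#' (tumour and somatic fields of the config are ignored: no somatic truth
#' is planted), then assigns each read independently to a pseudo-normal
#' or pseudo-tumour half with a fair coin. Every somatic call made on the
#' pseudo-pair is a false positive by construction, which is the audit
#' the split null exists for.
#'
#' @param config a [sim_config()] describing the single normal sample.
#' @return a `split_null` list: `pair` (a `sim_result` whose truth holds
#'   no somatic records) and `parent` (the undivided sample as a
#'   [paired_pileup()] with an empty tumour slot, for audit).
#' @export
split_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$n_clonal_somatic <- 0L
  cfg$n_subclonal_somatic <- 0L
  cfg$normal_contamination <- 0
  .with_seed(config$seed, {
    w <- .gen_sites(cfg)
    parent_reads <- .gen_reads(cfg, 2 * cfg$mean_depth_normal, w$vaf_n,
                               w$var_base, w$ref, w$sys, w$sys_strand)
    coin <- stats::runif(nrow(parent_reads)) < 0.5
    pair <- paired_pileup(w$sites, parent_reads[coin, , drop = FALSE],
                          parent_reads[!coin, , drop = FALSE])
    truth <- w$truth
    truth$true_vaf_tumour <- truth$true_vaf_normal  # same underlying sample
    structure(list(
      pair = structure(list(pileup = pair, truth = truth, config = cfg),
                       class = "sim_result"),
      parent = paired_pileup(w$sites, parent_reads, NULL)),
      class = "split_null")
  })
}

#' Write / read simulator ground truth as TSV
#'
#' @param truth the `truth` data.frame of a `sim_result`.
#' @param file path or connection.
#' @export
write_truth <- function(truth, file) {
  out <- truth
  out$true_vaf_tumour <- sprintf("%.6f", out$true_vaf_tumour)
  out$true_vaf_normal <- sprintf("%.6f", out$true_vaf_normal)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
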