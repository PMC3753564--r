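CALLERS <- c("varscan", "somaticsniper", "jointsnvmix", "strelka_like")
CALL_CLASSES <- c("somatic", "LOH", "germline", "reference", "unknown")

# One candidate call = one row. Allele summaries for both samples travel
# with the call so filtering and characterization never need to re-read
# the pileup for proportions.
.call_row <- function(chrom, pos, caller, class, score, phred_score,
                      normal_gt, tumour_gt, variant_base, n, t) {
  data.frame(chrom = chrom, pos = as.integer(pos), caller = caller,
             class = class, score = score,
             phred_score = if (is.null(phred_score)) NA_integer_ else as.integer(phred_score),
             normal_gt = if (is.null(normal_gt)) NA_character_ else normal_gt,
             tumour_gt = if (is.null(tumour_gt)) NA_character_ else tumour_gt,
             variant_base = if (is.na(variant_base)) NA_character_ else variant_base,
             n_depth = n$depth, n_ref = n$ref_count, n_v = n$v,
             n_v_fwd = n$v_forward, n_v_rev = n$v_reverse,
             n_vp = if (n$v + n$ref_count > 0) n$v / (n$v + n$ref_count) else 0,
             t_depth = t$depth, t_ref = t$ref_count, t_v = t$v,
             t_v_fwd = t$v_forward, t_v_rev = t$v_reverse,
             t_vp = if (t$v + t$ref_count > 0) t$v / (t$v + t$ref_count) else 0,
             stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  .call_row("x", 1L, "varscan", "somatic", 0, NA_integer_, NA, NA,
            NA_character_,
            list(depth = 0L, ref_count = 0L, v = 0L, v_forward = 0L,
                 v_reverse = 0L),
            list(depth = 0L, ref_count = 0L, v = 0L, v_forward = 0L,
                 v_reverse = 0L))[0, ]
}

.as_candidate_calls <- function(df) {
  class(df) <- c("candidate_calls", "data.frame")
  df
}

#' @export
print.candidate_calls <- function(x, ...) {
  cat(sprintf("candidate_calls: %d calls at %d sites\n", nrow(x),
              length(unique(paste(x$chrom, x$pos)))))
  if (nrow(x)) print(table(caller = x$caller, class = x$class))
  invisible(x)
}

.gt_to_vcf <- c(AA = "0/0", AB = "0/1", BB = "1/1")

#' Write and read candidate calls
#'
#' Candidate calls are serialized either as a TSV mirroring every column
#' of the call table, or as VCF 4.2 with INFO keys `CALLER`, `CLASS`,
#' `SCORE` (6 decimal places) and `PHRED`, and per-sample
#' `GT:AD:ADF:ADR:DP` fields (AD = reference,variant counts; ADF/ADR the
#' variant strand split). Both formats round-trip through
#' `read_candidates` losslessly at 6 decimal places. Input must be sorted
#' by (chrom, pos).
#'
#' @param calls a candidate-call data.frame (from the callers or
#'   [run_all_callers()]).
#' @param file path or connection.
#' @param format `"tsv"` or `"vcf"`.
#' @return `write_candidates` returns `file` invisibly; `read_candidates`
#'   returns a `candidate_calls` data.frame.
#' @export
write_candidates <- function(calls, file, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  o <- order(calls$chrom, calls$pos)
  if (is.unsorted(o)) stop("calls must be sorted by (chrom, pos)")
  if (format == "tsv") {
    out <- calls
    out$score <- sprintf("%.6f", out$score)
    out$n_vp <- sprintf("%.6f", out$n_vp)
    out$t_vp <- sprintf("%.6f", out$t_vp)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(file))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling model\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Call class\">",
           "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Somatic probability\">",
           "##INFO=<ID=PHRED,Number=1,Type=Integer,Description=\"Phred-scaled score\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Ref,variant read counts\">",
           "##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=\"Variant reads, forward strand\">",
           "##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=\"Variant reads, reverse strand\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOUR")
  recs <- character(0)
  if (nrow(calls)) {
    gt <- function(g) ifelse(is.na(g), "./.", .gt_to_vcf[g])
    smp <- function(g, ref, v, vf, vr, dp)
      sprintf("%s:%d,%d:%d:%d:%d", gt(g), ref, v, vf, vr, dp)
    # REF is not stored on the call; emit N (calls are defined in reduced
    # reference/variant space). ALT "." when no variant base was found.
    recs <- sprintf(
      "%s\t%d\t.\tN\t%s\t%s\tPASS\tCALLER=%s;CLASS=%s;SCORE=%.6f%s\tGT:AD:ADF:ADR:DP\t%s\t%s",
      calls$chrom, calls$pos,
      ifelse(is.na(calls$variant_base), ".", calls$variant_base),
      ifelse(is.na(calls$phred_score), ".",
             as.character(calls$phred_score)),
      calls$caller, calls$class, calls$score,
      ifelse(is.na(calls$phred_score), "",
             sprintf(";PHRED=%d", calls$phred_score)),
      smp(calls$normal_gt, calls$n_ref, calls$n_v, calls$n_v_fwd,
          calls$n_v_rev, calls$n_depth),
      smp(calls$tumour_gt, calls$t_ref, calls$t_v, calls$t_v_fwd,
          calls$t_v_rev, calls$t_depth))
  }
  writeLines(c(hdr, recs), file)
  invisible(file)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(file, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           na.strings = "NA")
    d$chrom <- as.character(d$chrom)
    return(.as_candidate_calls(d))
  }
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(.as_candidate_calls(.empty_calls()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  info <- f[, 8]
  pick <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]*"), info))
    has <- grepl(paste0(key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(key, "="), "", m)
    out
  }
  vcf_to_gt <- c("0/0" = "AA", "0/1" = "AB", "1/1" = "BB", "./." = NA)
  parse_sample <- function(col) {
    p <- strsplit(col, ":", fixed = TRUE)
    ad <- strsplit(vapply(p, `[`, "", 2L), ",", fixed = TRUE)
    list(gt = unname(vcf_to_gt[vapply(p, `[`, "", 1L)]),
         ref = as.integer(vapply(ad, `[`, "", 1L)),
         v = as.integer(vapply(ad, `[`, "", 2L)),
         vf = as.integer(vapply(p, `[`, "", 3L)),
         vr = as.integer(vapply(p, `[`, "", 4L)),
         dp = as.integer(vapply(p, `[`, "", 5L)))
  }
  n <- parse_sample(f[, 10]); t <- parse_sample(f[, 11])
  phred <- suppressWarnings(as.integer(pick("PHRED")))
  d <- data.frame(
    chrom = f[, 1], pos = as.integer(f[, 2]), caller = pick("CALLER"),
    class = pick("CLASS"), score = as.numeric(pick("SCORE")),
    phred_score = phred, normal_gt = n$gt, tumour_gt = t$gt,
    variant_base = ifelse(f[, 5] == ".", NA_character_, f[, 5]),
    n_depth = n$dp, n_ref = n$ref, n_v = n$v, n_v_fwd = n$vf,
    n_v_rev = n$vr,
    n_vp = ifelse(n$v + n$ref > 0, n$v / (n$v + n$ref), 0),
    t_depth = t$dp, t_ref = t$ref, t_v = t$v, t_v_fwd = t$vf,
    t_v_rev = t$vr,
    t_vp = ifelse(t$v + t$ref > 0, t$v / (t$v + t$ref), 0),
    stringsAsFactors = FALSE)
  .as_candidate_calls(d)
}
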