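#' Read and write paired pileups as text
#'
#' Two dialects are supported. `internal_tsv` is the package's lossless
#' dump: one row per read observation with columns `chrom, pos, ref,
#' sample, base, baseq, mapq, strand, spans_deletion, adjacent_indel`
#' (`sample` is `normal` or `tumour`; a site with no reads in either
#' sample is kept with a single sentinel row `sample = "."`). `mpileup2`
#' is the samtools two-sample mpileup text produced with `-s` (mapping
#' quality column), 11 columns: chrom, pos, ref, then depth/bases/baseQ/
#' mapQ for each sample. The read-base string is decoded per mpileup
#' rules: `.`/`,` reference match on forward/reverse strand, letter case
#' gives the strand of mismatches, `^X`/`$` clip markers are consumed,
#' `+n`/`-n` indel runs set `adjacent_indel` on the preceding read, and
#' `*` marks a spanning deletion.
#'
#' @param file path or connection.
#' @param format `"internal_tsv"` or `"mpileup2"`.
#' @param pp a [paired_pileup()] (writer only; always internal_tsv).
#' @return `read_paired_pileup` returns a [paired_pileup()];
#'   `write_paired_pileup` returns `file` invisibly.
#' @export
read_paired_pileup <- function(file, format = c("internal_tsv", "mpileup2")) {
  format <- match.arg(format)
  if (format == "internal_tsv") .read_internal_tsv(file) else .read_mpileup2(file)
}

#' @rdname read_paired_pileup
#' @export
write_paired_pileup <- function(pp, file) {
  stopifnot(inherits(pp, "paired_pileup"))
  fmt <- function(reads, label) {
    if (nrow(reads) == 0L) return(NULL)
    data.frame(chrom = pp$sites$chrom[reads$site],
               pos = pp$sites$pos[reads$site],
               ref = pp$sites$ref[reads$site],
               sample = label, base = reads$base, baseq = reads$baseq,
               mapq = reads$mapq, strand = reads$strand,
               spans_deletion = as.integer(reads$spans_deletion),
               adjacent_indel = as.integer(reads$adjacent_indel),
               site = reads$site, stringsAsFactors = FALSE)
  }
  out <- rbind(fmt(pp$normal, "normal"), fmt(pp$tumour, "tumour"))
  covered <- if (is.null(out)) integer() else unique(out$site)
  bare <- setdiff(seq_len(nrow(pp$sites)), covered)
  if (length(bare)) {
    out <- rbind(out, data.frame(
      chrom = pp$sites$chrom[bare], pos = pp$sites$pos[bare],
      ref = pp$sites$ref[bare], sample = ".", base = ".", baseq = 0L,
      mapq = 0L, strand = "+", spans_deletion = 0L, adjacent_indel = 0L,
      site = bare, stringsAsFactors = FALSE))
  }
  out <- out[order(out$site, out$sample), , drop = FALSE]
  out$site <- NULL
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.read_internal_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "character", "character", "integer",
                                        "integer", "character", "integer",
                                        "integer"))
  key <- paste(d$chrom, d$pos)
  site <- match(key, unique(key))
  first <- !duplicated(site)
  sites <- data.frame(chrom = d$chrom[first], pos = d$pos[first],
                      ref = d$ref[first], stringsAsFactors = FALSE)
  mk <- function(label) {
    sel <- d$sample == label
    data.frame(site = site[sel], base = d$base[sel], baseq = d$baseq[sel],
               mapq = d$mapq[sel], strand = d$strand[sel],
               spans_deletion = d$spans_deletion[sel] == 1L,
               adjacent_indel = d$adjacent_indel[sel] == 1L,
               stringsAsFactors = FALSE)
  }
  paired_pileup(sites, mk("normal"), mk("tumour"))
}

# Decode one mpileup base string + quality strings into observations.
# `line` is only used for error messages.
.decode_mpileup_bases <- function(bases, quals, mapqs, ref, line) {
  ch <- strsplit(bases, "")[[1]]
  bq <- utf8ToInt(quals) - 33L
  mq <- utf8ToInt(mapqs) - 33L
  base <- character(0); strand <- character(0)
  spans <- logical(0); adj <- logical(0)
  i <- 1L; n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {            # read start: next char is encoded mapq
      i <- i + 2L; next
    }
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 == "+" || c0 == "-") {  # indel run attached to previous read
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- suppressWarnings(as.integer(paste(ch[(i + 1L):(j - 1L)],
                                               collapse = "")))
      if (is.na(len) || j + len - 1L > n)
        stop(sprintf("mpileup parse error at line %d: bad indel run", line))
      if (length(base) == 0L)
        stop(sprintf("mpileup parse error at line %d: leading indel", line))
      adj[length(adj)] <- TRUE
      i <- j + len; next
    }
    if (c0 %in% c(">", "<")) {  # reference skip: consumes a qual, no base
      base <- c(base, "N"); strand <- c(strand, "+")
      spans <- c(spans, FALSE); adj <- c(adj, FALSE)
      i <- i + 1L; next
    }
    if (c0 == "*") {
      base <- c(base, "*"); strand <- c(strand, "+")
      spans <- c(spans, TRUE); adj <- c(adj, FALSE)
      i <- i + 1L; next
    }
    if (c0 == ".") { b <- ref; s <- "+" }
    else if (c0 == ",") { b <- ref; s <- "-" }
    else if (c0 %in% c("A", "C", "G", "T", "N")) { b <- c0; s <- "+" }
    else if (c0 %in% c("a", "c", "g", "t", "n")) { b <- toupper(c0); s <- "-" }
    else stop(sprintf("mpileup parse error at line %d: unexpected '%s'",
                      line, c0))
    base <- c(base, b); strand <- c(strand, s)
    spans <- c(spans, FALSE); adj <- c(adj, FALSE)
    i <- i + 1L
  }
  if (length(base) != length(bq) || length(base) != length(mq))
    stop(sprintf(
      "mpileup parse error at line %d: %d bases vs %d base quals, %d map quals",
      line, length(base), length(bq), length(mq)))
  data.frame(base = base, baseq = bq, mapq = mq, strand = strand,
             spans_deletion = spans, adjacent_indel = adj,
             stringsAsFactors = FALSE)
}

.read_mpileup2 <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sites <- list(); nr <- list(); tr <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 11L)
      stop(sprintf("mpileup parse error at line %d: expected 11 columns, got %d",
                   k, length(f)))
    ref <- toupper(f[3])
    sites[[k]] <- data.frame(chrom = f[1], pos = as.integer(f[2]), ref = ref,
                             stringsAsFactors = FALSE)
    dec <- function(d, b, q, m) {
      if (as.integer(d) == 0L || b == "*") return(NULL)
      obs <- .decode_mpileup_bases(b, q, m, ref, k)
      if (nrow(obs)) obs$site <- k
      obs
    }
    nr[[k]] <- dec(f[4], f[5], f[6], f[7])
    tr[[k]] <- dec(f[8], f[9], f[10], f[11])
  }
  paired_pileup(do.call(rbind, sites),
                do.call(rbind, nr[!vapply(nr, is.null, TRUE)]),
                do.call(rbind, tr[!vapply(tr, is.null, TRUE)]))
}
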