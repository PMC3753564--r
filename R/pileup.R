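#' Paired pileup container
#'
#' A `paired_pileup` holds per-site read stacks for a matched normal and
#' tumour sample. Coordinates are 1-based and fully closed, following
#' pileup convention. Each read observation carries the called base
#' (`A/C/G/T/N`, or `*` for a read whose alignment deletes the base at
#' this site), a phred base quality, a phred mapping quality, the strand
#' (`+`/`-`), and two context flags: `spans_deletion` (base is `*`) and
#' `adjacent_indel` (the read has an indel immediately adjacent to the
#' site).
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (integer, >= 1) and `ref` (one of A/C/G/T).
#' @param normal,tumour data.frames of read observations with columns
#'   `site` (integer row index into `sites`), `base`, `baseq`, `mapq`,
#'   `strand`, `spans_deletion`, `adjacent_indel`.
#' @return an object of class `paired_pileup`.
#' @export
paired_pileup <- function(sites, normal, tumour) {
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  stopifnot(all(sites$pos >= 1L), all(sites$ref %in% c("A", "C", "G", "T")))
  normal <- .validate_reads(normal, nrow(sites))
  tumour <- .validate_reads(tumour, nrow(sites))
  structure(list(sites = sites, normal = normal, tumour = tumour),
            class = "paired_pileup")
}

.empty_reads <- function() {
  data.frame(site = integer(), base = character(), baseq = integer(),
             mapq = integer(), strand = character(),
             spans_deletion = logical(), adjacent_indel = logical(),
             stringsAsFactors = FALSE)
}

.validate_reads <- function(reads, n_sites) {
  if (is.null(reads) || nrow(reads) == 0L) return(.empty_reads())
  reads$site <- as.integer(reads$site)
  reads$base <- as.character(reads$base)
  reads$baseq <- as.integer(reads$baseq)
  reads$mapq <- as.integer(reads$mapq)
  reads$strand <- as.character(reads$strand)
  reads$spans_deletion <- as.logical(reads$spans_deletion)
  reads$adjacent_indel <- as.logical(reads$adjacent_indel)
  stopifnot(
    all(reads$site >= 1L & reads$site <= n_sites),
    all(reads$base %in% c("A", "C", "G", "T", "N", "*")),
    all(reads$baseq >= 0L & reads$baseq <= 93L),
    all(reads$mapq >= 0L & reads$mapq <= 254L),
    all(reads$strand %in% c("+", "-")),
    all(reads$spans_deletion == (reads$base == "*"))
  )
  reads <- reads[order(reads$site), , drop = FALSE]
  rownames(reads) <- NULL
  reads[, c("site", "base", "baseq", "mapq", "strand",
            "spans_deletion", "adjacent_indel")]
}

#' @export
length.paired_pileup <- function(x) nrow(x$sites)

#' @export
print.paired_pileup <- function(x, ...) {
  cat(sprintf(
    "paired_pileup: %d sites, %d normal reads (mean depth %.1f), %d tumour reads (mean depth %.1f)\n",
    nrow(x$sites), nrow(x$normal), nrow(x$normal) / max(1L, nrow(x$sites)),
    nrow(x$tumour), nrow(x$tumour) / max(1L, nrow(x$sites))))
  invisible(x)
}

#' Extract one site from a paired pileup
#'
#' @param pp a [paired_pileup()].
#' @param i site index (row of `pp$sites`).
#' @return a `paired_site`: list with `chrom`, `pos`, `ref` and the two
#'   read-observation data.frames `normal` and `tumour`.
#' @export
paired_site <- function(pp, i) {
  stopifnot(inherits(pp, "paired_pileup"), i >= 1L, i <= nrow(pp$sites))
  structure(list(
    chrom = pp$sites$chrom[i], pos = pp$sites$pos[i], ref = pp$sites$ref[i],
    normal = pp$normal[pp$normal$site == i, , drop = FALSE],
    tumour = pp$tumour[pp$tumour$site == i, , drop = FALSE]),
    class = "paired_site")
}

# Precompute column vectors plus per-site index ranges so the per-site
# caller loop can slice plain vectors instead of subsetting data.frames.
# Reads are already sorted by site; ptr[i]..(ptr[i+1]-1) is site i's range.
.read_columns <- function(reads, n_sites) {
  counts <- tabulate(reads$site, nbins = n_sites)
  ptr <- cumsum(c(1L, counts))
  list(base = reads$base, baseq = as.numeric(reads$baseq),
       mapq = as.numeric(reads$mapq), strand = reads$strand,
       spans_deletion = reads$spans_deletion,
       adjacent_indel = reads$adjacent_indel,
       ptr = ptr, counts = counts)
}

.slice <- function(cols, i) {
  lo <- cols$ptr[i]; hi <- cols$ptr[i + 1L] - 1L
  if (hi < lo) return(NULL)
  idx <- lo:hi
  list(base = cols$base[idx], baseq = cols$baseq[idx], mapq = cols$mapq[idx],
       strand = cols$strand[idx], spans_deletion = cols$spans_deletion[idx],
       adjacent_indel = cols$adjacent_indel[idx])
}

.reads_as_list <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0L) return(NULL)
  list(base = reads$base, baseq = as.numeric(reads$baseq),
       mapq = as.numeric(reads$mapq), strand = reads$strand,
       spans_deletion = reads$spans_deletion,
       adjacent_indel = reads$adjacent_indel)
}
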