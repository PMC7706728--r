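# Coordinate conventions
# ----------------------
# Interval containers are GRanges (1-based, closed), the Bioconductor native
# convention. Zero-based half-open formats (BED, BEDPE, bedGraph) are
# converted at the I/O boundary, and every scalar base-pair *position*
# carried in plain tables (TSS modes, dyads, track bin starts) is 0-based so
# that tables and browser tracks agree.

#' Extract sequences for a set of genomic intervals
#'
#' Pulls one uppercase DNA sequence per interval from an indexed FASTA file
#' or an in-memory genome. Minus-strand intervals are reverse-complemented
#' when `flip_minus` is set, so that anchored sequence sets share one
#' orientation (e.g. TSS-anchored promoter windows).
#'
#' @param genome Path to a FASTA file (a `.fai` index is created on the fly
#'   if missing) or a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param intervals `GRanges`. Intervals must lie within chromosome bounds.
#' @param flip_minus Logical; reverse-complement `-` strand intervals
#'   (default `TRUE`).
#' @return A [Biostrings::DNAStringSet] parallel to `intervals`, each
#'   sequence of length `width(intervals)`.
#' @examples
#' chr <- Biostrings::DNAStringSet(c(chrI = "ACGTACGTAA"))
#' gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(2, 5), strand = "-")
#' as.character(read_sequences(chr, gr))
#' @export
read_sequences <- function(genome, intervals, flip_minus = TRUE) {
  stopifnot(is(intervals, "GRanges"))
  if (is.character(genome)) {
    if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
    fa <- Rsamtools::FaFile(genome)
    lens <- seqlengths(seqinfo(fa))
    fetch <- function(gr) Biostrings::getSeq(fa, gr)
  } else if (is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("in-memory genome must have chromosome names")
    lens <- stats::setNames(width(genome), names(genome))
    fetch <- function(gr) {
      DNAStringSet(lapply(seq_along(gr), function(i) {
        subseq(genome[[as.character(seqnames(gr))[i]]],
               start = start(gr)[i], end = end(gr)[i])
      }))
    }
  } else {
    stop("genome must be a FASTA path or a DNAStringSet")
  }

  chroms <- as.character(seqnames(intervals))
  unknown <- !(chroms %in% names(lens))
  if (any(unknown)) {
    stop("unknown chromosome '", chroms[which(unknown)[1]], "'")
  }
  oob <- start(intervals) < 1L | end(intervals) > lens[chroms]
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf("interval %s:%d-%d out of chromosome bounds",
                 chroms[i], start(intervals)[i] - 1L, end(intervals)[i]))
  }

  unstranded <- intervals
  strand(unstranded) <- "*"
  seqs <- Biostrings::DNAStringSet(toupper(fetch(unstranded)))
  if (flip_minus) {
    flip <- as.character(strand(intervals)) == "-"
    if (any(flip)) seqs[flip] <- reverseComplement(seqs[flip])
  }
  names(seqs) <- names(intervals)
  seqs
}

#' Read paired-end fragments from BAM or BEDPE
#'
#' Produces one genomic span per sequenced fragment. For BAM input only
#' properly paired, primary, non-duplicate alignments are used, one fragment
#' per pair, defined by the leftmost mate start and the template length (the
#' standard ATAC-seq fragment definition). BEDPE rows are collapsed to the
#' union span of the two reads; coordinates are 0-based half-open on disk
#' and converted on read.
#'
#' @param path BAM or BEDPE file.
#' @param format `"auto"` (by extension), `"bam"` or `"bedpe"`.
#' @param length_range Keep fragments whose length lies in this closed
#'   interval, in bp. Default `c(30, 250)`, the span displayed by ATAC
#'   fragment-density plots.
#' @param verbose Report fragment counts before/after filtering.
#' @return `GRanges` of fragment spans (lengths are `width()`).
#' @seealso [fragment_midpoints()]
#' @export
read_fragments <- function(path, format = c("auto", "bam", "bedpe"),
                           length_range = c(30, 250), verbose = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bedpe"
  }
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2])

  if (format == "bam") {
    flag <- Rsamtools::scanBamFlag(
      isPaired = TRUE, isProperPair = TRUE, isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag,
                                     what = c("rname", "pos", "isize"))
    res <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(res$isize) & res$isize > 0L  # leftmost mate carries +TLEN
    frags <- GRanges(res$rname[keep],
                     IRanges(start = res$pos[keep], width = res$isize[keep]))
  } else {
    n_cols <- tryCatch(ncol(read.table(path, sep = "\t", nrows = 1)),
                       error = function(e) 0L)
    if (n_cols == 0L) {
      warning("no fragments in ", path)
      return(GRanges())
    }
    if (n_cols < 6L) stop("BEDPE requires at least 6 columns: ", path)
    bp <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    same <- bp[[1]] == bp[[4]]
    if (!all(same)) {
      warning(sum(!same), " inter-chromosomal BEDPE rows dropped")
      bp <- bp[same, , drop = FALSE]
    }
    start0 <- pmin(bp[[2]], bp[[5]])
    end0 <- pmax(bp[[3]], bp[[6]])
    frags <- GRanges(bp[[1]], IRanges(start = start0 + 1L, end = end0))
  }

  n_total <- length(frags)
  frags <- frags[width(frags) >= length_range[1] &
                 width(frags) <= length_range[2]]
  if (verbose) {
    message(sprintf("read %d fragments; %d within [%d, %d] bp",
                    n_total, length(frags), length_range[1], length_range[2]))
  }
  if (length(frags) == 0L) warning("zero fragments after length filtering")
  frags
}

#' Fragment midpoints (0-based)
#'
#' The midpoint of a fragment spanning `[start0, end0)` is
#' `floor((start0 + end0) / 2)`; even-length fragments take the floor of the
#' true center, making downstream counts reproducible.
#'
#' @param fragments `GRanges` of fragment spans.
#' @return Integer vector of 0-based midpoint positions.
#' @export
fragment_midpoints <- function(fragments) {
  as.integer(floor((start(fragments) - 1L + end(fragments)) / 2))
}

# center of an interval [start0, end0), 0-based
interval_centers0 <- function(gr) {
  as.integer(floor((start(gr) - 1L + end(gr)) / 2))
}

#' Build a single-base-pair signal track
#'
#' A signal track is a `GRanges` whose ranges are constant-width bins with a
#' numeric `score` column; this helper builds one from a value vector.
#'
#' @param chrom Chromosome name.
#' @param start0 0-based start of the first bin.
#' @param values Numeric vector, one value per bin.
#' @param step Bin width in bp (default 1).
#' @return `GRanges` with a `score` metadata column.
#' @export
signal_track <- function(chrom, start0, values, step = 1L) {
  stopifnot(all(is.finite(values)), start0 >= 0)
  n <- length(values)
  if (n == 0L) return(GRanges())
  starts0 <- start0 + step * (seq_len(n) - 1L)
  GRanges(chrom, IRanges(start = starts0 + 1L, width = step), score = values)
}

#' Per-base values of a signal track
#'
#' @param track `GRanges` with a `score` column.
#' @param chrom Chromosome name.
#' @param positions0 0-based positions to query.
#' @return Numeric vector; positions not covered by the track return 0.
#' @export
track_values <- function(track, chrom, positions0) {
  vals <- numeric(length(positions0))
  if (length(track) == 0L) return(vals)
  q <- GRanges(chrom, IRanges(start = positions0 + 1L, width = 1L))
  # chromosomes absent from the track legitimately return zeros
  ov <- suppressWarnings(findOverlaps(q, track))
  vals[queryHits(ov)] <- track$score[subjectHits(ov)]
  vals
}

#' Write a signal track to bedGraph or bigWig
#'
#' Round-tripping through either format preserves values to within 1e-6.
#' An empty track yields an empty bedGraph (no header line); writing an
#' empty bigWig requires sequence lengths and is refused.
#'
#' @param track `GRanges` with a finite `score` column.
#' @param path Output path; extension selects the format when
#'   `format = "auto"` (`.bw`/`.bigwig` for bigWig, anything else bedGraph).
#' @param format `"auto"`, `"bedgraph"` or `"bigwig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("auto", "bedgraph", "bigwig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigwig" else "bedgraph"
  }
  stopifnot(is(track, "GRanges"))
  if (length(track) == 0L) {
    # empty bedGraph: an empty file, no header line
    if (format == "bigwig") stop("cannot write an empty bigWig track")
    file.create(path)
    return(invisible(path))
  }
  stopifnot(!is.null(track$score), all(is.finite(track$score)))
  if (format == "bigwig") {
    if (any(is.na(seqlengths(track)))) {
      sl <- tapply(end(track), as.character(seqnames(track)), max)
      seqlengths(track) <- sl[seqlevels(track)]
    }
    rtracklayer::export(track, path, format = "BigWig")
  } else {
    rtracklayer::export(track, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read a signal track written by [write_track()]
#'
#' @param path bedGraph or bigWig file.
#' @return `GRanges` with a `score` column.
#' @export
read_track <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
    "BigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  gr
}

#' Read a promoter annotation table
#'
#' Tab-separated with header; required columns `chrom`, `start`, `end`
#' (0-based half-open interval) and optional `strand`, `center`, `tss_fwd`,
#' `tss_rev` (0-based positions; `NA` when undetermined) and `class`.
#' Divergent promoters are expected to satisfy `tss_rev < tss_fwd` on the
#' genome axis; violations are reported.
#'
#' @param path TSV file.
#' @return `data.frame` with the columns above.
#' @export
read_promoters <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop("promoter table must contain columns: ", paste(req, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("promoter intervals must satisfy start < end")
  if (all(c("tss_fwd", "tss_rev") %in% names(df))) {
    both <- !is.na(df$tss_fwd) & !is.na(df$tss_rev)
    bad <- both & df$tss_rev >= df$tss_fwd
    if (any(bad)) {
      warning(sum(bad), " promoters violate tss_rev < tss_fwd")
    }
  }
  df
}
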