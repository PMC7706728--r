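# +1/-1 nucleosome calling and promoter architecture metrics.
#
# Dyads are called as the maximum of a nucleosome occupancy probability
# track within a fixed search window beyond each TSS mode: downstream of the
# forward mode for the +1 nucleosome, upstream of the reverse mode for the
# -1 nucleosome. Edges are dyad +/- 73 bp (147-bp core particle). All
# positions are 0-based.

#' Call +1 and -1 nucleosomes at divergent promoters
#'
#' For each promoter the +1 dyad is the argmax of occupancy over
#' `(tss_fwd, tss_fwd + search]` and the -1 dyad the argmax over
#' `[tss_rev - search, tss_rev)`; the search windows are open at the TSS
#' itself and ties are broken toward the TSS. Promoters whose window is flat
#' zero get no call and are flagged.
#'
#' @param occupancy Signal track (`GRanges` with `score`), e.g. from
#'   [read_track()] or [gen_occupancy_track()].
#' @param promoters `data.frame` with columns `chrom`, `tss_fwd`, `tss_rev`
#'   (0-based positions; both required per promoter).
#' @param search Search window, bp (default 200).
#' @param half_width Half-width used to derive edges from dyads, bp
#'   (default 73; the 147-bp core particle).
#' @return `data.frame` with one row per promoter: dyad, 5'/3' edges and
#'   occupancy for both nucleosomes (`NA` plus `flagged = TRUE` where no
#'   call was possible).
#' @export
call_nucleosomes <- function(occupancy, promoters, search = 200L,
                             half_width = 73L) {
  req <- c("chrom", "tss_fwd", "tss_rev")
  stopifnot(all(req %in% names(promoters)))
  n <- nrow(promoters)
  out <- data.frame(
    plus1_dyad = rep(NA_integer_, n), plus1_occ = NA_real_,
    minus1_dyad = NA_integer_, minus1_occ = NA_real_,
    flagged = FALSE)

  for (i in seq_len(n)) {
    chrom <- promoters$chrom[i]
    tf <- promoters$tss_fwd[i]
    tr <- promoters$tss_rev[i]
    if (is.na(tf) || is.na(tr)) {
      out$flagged[i] <- TRUE
      next
    }
    # +1: (tss_fwd, tss_fwd + search]; which.max takes the first maximum,
    # i.e. the position closest to the TSS
    pos_f <- (tf + 1L):(tf + search)
    v_f <- track_values(occupancy, chrom, pos_f)
    # -1: [tss_rev - search, tss_rev); tie toward the TSS = largest position
    pos_r <- (tr - search):(tr - 1L)
    v_r <- track_values(occupancy, chrom, pos_r)
    # each side is called independently; a flat-zero window yields no call
    if (any(v_f > 0)) {
      jf <- which.max(v_f)
      out$plus1_dyad[i] <- pos_f[jf]
      out$plus1_occ[i] <- v_f[jf]
    }
    if (any(v_r > 0)) {
      jr <- length(v_r) + 1L - which.max(rev(v_r))
      out$minus1_dyad[i] <- pos_r[jr]
      out$minus1_occ[i] <- v_r[jr]
    }
    out$flagged[i] <- is.na(out$plus1_dyad[i]) || is.na(out$minus1_dyad[i])
  }
  out$plus1_edge5 <- out$plus1_dyad - half_width
  out$plus1_edge3 <- out$plus1_dyad + half_width
  out$minus1_edge5 <- out$minus1_dyad + half_width  # 5' on the reverse axis
  out$minus1_edge3 <- out$minus1_dyad - half_width
  out
}

#' Promoter architecture metrics d1, d2 and NDR width
#'
#' On the forward-transcription axis: `d1` is the distance from the forward
#' TSS mode to the +1 nucleosome 5' edge (`plus1_dyad - half_width -
#' tss_fwd`); `d2` the separation of the divergent TSS modes
#' (`tss_fwd - tss_rev`); `w` the NDR width, from the -1 nucleosome's
#' TSS-proximal edge to the +1 nucleosome's 5' edge
#' (`(plus1_dyad - half_width) - (minus1_dyad + half_width)`). Overlapping
#' calls give `w < 0` and are flagged.
#'
#' @param promoters As in [call_nucleosomes()].
#' @param calls The `data.frame` returned by [call_nucleosomes()].
#' @param half_width Edge offset, bp (default 73).
#' @return `data.frame` with columns `d1`, `d2`, `w`, `flagged`; metrics
#'   are `NA` where a call is missing.
#' @examples
#' prom <- data.frame(chrom = "chrI", tss_fwd = 1030, tss_rev = 970)
#' calls <- data.frame(plus1_dyad = 1095, minus1_dyad = 905)
#' architecture_metrics(prom, calls)  # d1 = -8, d2 = 60, w = 44
#' @export
architecture_metrics <- function(promoters, calls, half_width = 73L) {
  stopifnot(nrow(promoters) == nrow(calls))
  p1e5 <- calls$plus1_dyad - half_width
  m1e3 <- calls$minus1_dyad + half_width
  d1 <- p1e5 - promoters$tss_fwd
  d2 <- promoters$tss_fwd - promoters$tss_rev
  w <- p1e5 - m1e3
  data.frame(d1 = d1, d2 = d2, w = w,
             flagged = !is.na(w) & w < 0)
}

#' Periodicity of nucleosomal sequences by occupancy bin
#'
#' Sorts +1 nucleosome calls by occupancy, chunks them into bins of
#' `bin_size` calls, and scores the 10-bp dinucleotide periodicity of the
#' dyad-centered sequences in each bin, relating positioning strength to
#' sequence periodicity.
#'
#' @param calls `data.frame` with columns `chrom`, `dyad` (0-based),
#'   `occupancy`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param bin_size Calls per bin (default 20).
#' @param motif,period As in [get_periodicity()].
#' @param seq_width Width of the dyad-centered sequence, bp (default 200).
#' @return List with `table` (`data.frame`: `bin`, `mean_occupancy`,
#'   `psd_at_period`, `n`) and `r`, the Pearson correlation between bin mean
#'   occupancy and periodicity score (`NA` and `flagged = TRUE` if either
#'   side has zero variance).
#' @export
periodicity_by_occupancy_bins <- function(calls, genome, bin_size = 20L,
                                          motif = "WW", period = 10,
                                          seq_width = 200L) {
  stopifnot(all(c("chrom", "dyad", "occupancy") %in% names(calls)))
  n <- nrow(calls)
  if (n < 2L * bin_size) stop("need at least two bins of calls")
  ord <- order(calls$occupancy)
  calls <- calls[ord, , drop = FALSE]
  n_bins <- n %/% bin_size
  bin <- pmin(ceiling(seq_len(n) / bin_size), n_bins)

  half <- seq_width %/% 2L
  res <- lapply(seq_len(n_bins), function(b) {
    sub <- calls[bin == b, , drop = FALSE]
    gr <- GRanges(sub$chrom,
                  IRanges(start = sub$dyad - half + 1L, width = seq_width))
    seqs <- read_sequences(genome, gr, flip_minus = FALSE)
    p <- get_periodicity(seqs, motif, period = period, d_max = seq_width)
    data.frame(bin = b, mean_occupancy = mean(sub$occupancy),
               psd_at_period = p$psd_at_period, n = nrow(sub))
  })
  tab <- do.call(rbind, res)
  flagged <- sd(tab$psd_at_period) == 0 || sd(tab$mean_occupancy) == 0
  r <- if (flagged) NA_real_ else cor(tab$mean_occupancy, tab$psd_at_period)
  list(table = tab, r = r, flagged = flagged)
}

# Cross-correlation lag between a cluster profile and a reference profile:
# the lag l in [-max_lag, max_lag] maximizing the mean product of
# profile[t + l] and reference[t] over the overlap. Ties break toward the
# smallest |l| (then the negative one), so an autocorrelation yields 0.
profile_lag <- function(profile, reference, max_lag = 5L) {
  L <- length(profile)
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      mean(profile[(1 + l):L] * reference[1:(L - l)])
    } else {
      mean(profile[1:(L + l)] * reference[(1 - l):L])
    }
  }, numeric(1))
  best <- which(cc == max(cc))
  best <- best[order(abs(lags[best]), lags[best])][1]
  lags[best]
}

#' Phase nucleosomal sequences by k-means and lagged cross-correlation
#'
#' Builds the binary dinucleotide occurrence matrix (sequences x positions),
#' clusters the rows by k-means, estimates one lag per cluster as the
#' cross-correlation argmax (within `-max_lag..+max_lag`) between the
#' cluster mean profile and the global mean profile, and shifts each row by
#' its cluster's lag (positions shifted out of range are dropped). Aligning
#' clusters this way sharpens the summed periodic occurrence profile.
#'
#' @param sequences Character vector or `DNAStringSet`; all the same length
#'   (typically 400-bp dyad-centered windows).
#' @param motif As in [find_occurrences()].
#' @param k Number of k-means clusters (default 6).
#' @param max_lag Maximum rephasing shift, bp (default 5).
#' @param seed Integer seed for k-means (default 1).
#' @param nstart k-means restarts (default 10).
#' @return List with `cluster` (assignment per sequence), `lags` (per
#'   cluster), `shifted` (rephased occurrence matrix), `profile` (summed
#'   occurrences after phasing) and `profile_raw` (before phasing).
#' @export
phase_sequences <- function(sequences, motif = "WW", k = 6L, max_lag = 5L,
                            seed = 1L, nstart = 10L) {
  sequences <- as.character(sequences)
  n <- length(sequences)
  if (n == 0L) stop("empty sequence set")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must all have the same length")
  if (k < 1L || k > n) stop("k must be between 1 and the number of sequences")

  L <- lens - 1L  # dinucleotide start positions
  M <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    M[i, find_occurrences(sequences[i], motif) + 1L] <- 1L
  }

  # fewer distinct occurrence rows than clusters (e.g. identical sequences):
  # each distinct row forms its own cluster
  keys <- apply(M, 1, paste, collapse = "")
  n_distinct <- length(unique(keys))
  if (k == 1L) {
    cl <- rep(1L, n)
    k <- 1L
  } else if (n_distinct <= k) {
    cl <- match(keys, unique(keys))
    k <- n_distinct
  } else {
    set.seed(seed)
    cl <- kmeans(M, centers = k, nstart = nstart, iter.max = 50L)$cluster
  }

  global <- colMeans(M)
  lags <- vapply(seq_len(k), function(g) {
    profile_lag(colMeans(M[cl == g, , drop = FALSE]), global, max_lag)
  }, integer(1))

  shifted <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    l <- lags[cl[i]]
    src <- seq_len(L) + l
    ok <- src >= 1L & src <= L
    shifted[i, which(ok)] <- M[i, src[ok]]
  }
  list(cluster = cl, lags = lags, shifted = shifted,
       profile = colSums(shifted), profile_raw = colSums(M))
}
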