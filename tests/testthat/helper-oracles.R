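# Independent oracles and small fixture builders shared across tests.

# Naive O(L^2) DFT power spectrum: |sum_n x[n] e^{-2*pi*i*k*n/L}|^2 / L,
# independent of stats::fft.
naive_dft_psd <- function(x) {
  L <- length(x)
  ks <- 0:(L %/% 2)
  vapply(ks, function(k) {
    n <- 0:(L - 1)
    re <- sum(x * cos(-2 * pi * k * n / L))
    im <- sum(x * sin(-2 * pi * k * n / L))
    (re^2 + im^2) / L
  }, numeric(1))
}

# Brute-force pair count: occurrences found with Biostrings (independent of
# find_occurrences), distances accumulated by an explicit double loop.
brute_pair_hist <- function(sequences, members, d_max) {
  h <- integer(d_max)
  for (s in as.character(sequences)) {
    pos <- sort(unique(unlist(lapply(members, function(m) {
      Biostrings::start(Biostrings::matchPattern(m, Biostrings::DNAString(s)))
    })))) - 1L
    k <- length(pos)
    if (k < 2) next
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- pos[j] - pos[i]
        if (d <= d_max) h[d] <- h[d] + 1L
      }
    }
  }
  h
}

# Double-loop count of in-window (x, y) V-plot events.
brute_vplot_count <- function(fragments, anchors, x_range, y_range) {
  mids <- fragment_midpoints(fragments)
  lens <- IRanges::width(fragments)
  fchr <- as.character(GenomicRanges::seqnames(fragments))
  centers <- floor((IRanges::start(anchors) - 1 + IRanges::end(anchors)) / 2)
  achr <- as.character(GenomicRanges::seqnames(anchors))
  n <- 0L
  for (a in seq_along(anchors)) {
    for (f in seq_along(fragments)) {
      if (fchr[f] != achr[a]) next
      x <- mids[f] - centers[a]
      if (x >= x_range[1] && x <= x_range[2] &&
          lens[f] >= y_range[1] && lens[f] <= y_range[2]) {
        n <- n + 1L
      }
    }
  }
  n
}

# Circular right-shift of a sequence by l bases.
circular_shift <- function(s, l) {
  n <- nchar(s)
  l <- ((l %% n) + n) %% n
  if (l == 0) return(s)
  paste0(substr(s, n - l + 1, n), substr(s, 1, n - l))
}

# Majority-consensus phasing fixture: most sequences at the consensus phase,
# minorities circularly offset by the planted lags.
phasing_fixture <- function(shifts = c(-4L, -2L, 0L, 2L, 4L),
                            sizes = c(3L, 3L, 12L, 3L, 3L), seed = 6L) {
  tmpl <- as.character(
    gen_periodic_sequences(1, 400, seed = seed)$sequences[[1]])
  list(sequences = unlist(mapply(function(s, m) {
         rep(circular_shift(tmpl, s), m)
       }, shifts, sizes)),
       planted = rep(shifts, sizes), shifts = shifts)
}

# Five anchors on one synthetic chromosome, plus-strand.
toy_anchors <- function(n = 5L) {
  GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = 1L + (seq_len(n) - 1L) * 3000L, width = 2000L),
    strand = "+")
}

full_design <- function(reps = 1L) {
  rep(c(paste0("specific:", promarch_tissues()),
        "restricted:germline+neurons",
        "restricted:muscle+hypodermis+intestine",
        "ubiquitous-uniform", "ubiquitous-biased", "unclassified"), reps)
}
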