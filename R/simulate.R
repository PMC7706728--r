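# Seeded generators for every input the toolkit consumes, with ground
# truth, so all analyses can be exercised without external data. A single
# root seed fans out to per-generator child seeds through child_seed(), so
# individual fixtures are reproducible in isolation.

#' Derive a child seed from a root seed
#'
#' Deterministic fan-out: `(seed + 1000003 * index) mod (2^31 - 1)`. Using a
#' distinct index per generator keeps fixtures independent and individually
#' reproducible.
#'
#' @param seed Root integer seed.
#' @param index Generator index (non-negative integer).
#' @return Integer seed below 2^31.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

# provenance sidecar: parameters echoed next to every written fixture
write_provenance <- function(path, params) {
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate sequences with planted periodic WW dinucleotides
#'
#' Background sequences are i.i.d. with the stated GC content (default 0.36,
#' a worm-like genome). A `planted_fraction` of the sequences additionally
#' receive a W pair (`AA`/`AT`/`TA`/`TT`) at every `period` positions, each
#' site jittered uniformly within `round(jitter * period)` bp.
#'
#' @param n Number of sequences.
#' @param length Sequence length, bp.
#' @param period Planted period, bp (default 10).
#' @param planted_fraction Fraction of sequences carrying the signal
#'   (default 1).
#' @param jitter Site jitter as a fraction of the period (default 0.1).
#' @param gc Background GC content (default 0.36).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param fasta Optional path; when given, sequences are written as FASTA
#'   with a `.json` provenance sidecar and a `<fasta>.truth.tsv` table.
#' @return List with `sequences` (`DNAStringSet`) and `truth`
#'   (`data.frame`: `name`, `planted`).
#' @export
gen_periodic_sequences <- function(n, length, period = 10L,
                                   planted_fraction = 1, jitter = 0.1,
                                   gc = 0.36, seed = 1L, fasta = NULL) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  n_planted <- round(planted_fraction * n)
  j <- as.integer(round(jitter * period))
  seqs <- character(n)
  for (i in seq_len(n)) {
    ch <- sample(names(probs), length, replace = TRUE, prob = probs)
    if (i <= n_planted) {
      sites <- seq.int(1L, length - 1L, by = period)
      if (j > 0) {
        sites <- sites + sample.int(2L * j + 1L, length(sites),
                                    replace = TRUE) - j - 1L
        sites <- pmin(pmax(sites, 1L), length - 1L)
      }
      for (s in sites) ch[c(s, s + 1L)] <- sample(c("A", "T"), 2L,
                                                 replace = TRUE)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  names(seqs) <- sprintf("seq_%04d", seq_len(n))
  truth <- data.frame(name = names(seqs),
                      planted = seq_len(n) <= n_planted)
  dss <- DNAStringSet(seqs)
  if (!is.null(fasta)) {
    writeXStringSet(dss, fasta)
    write.table(truth, paste0(fasta, ".truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_provenance(fasta, list(generator = "gen_periodic_sequences",
                                 n = n, length = length, period = period,
                                 planted_fraction = planted_fraction,
                                 jitter = jitter, gc = gc, seed = seed))
  }
  list(sequences = dss, truth = truth)
}

#' Generate ATAC-like fragments around anchors
#'
#' Emulates the two promoter architectures seen in fragment V-plots. The
#' `germline` architecture has a narrow NDR (short fragments, midpoints
#' within ~55 bp of the center) flanked by positioned nucleosomes
#' (140-200-bp fragments centered near +/- `nuc_offset` bp). The `somatic`
#' architecture has a wide NDR and diffuse nucleosome-length fragments over
#' a +/- 200-bp band.
#'
#' @param anchors `GRanges` of anchor intervals (strand respected: offsets
#'   are mirrored for `-` anchors).
#' @param architecture `"germline"` or `"somatic"`.
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @param nuc_offset Planted nucleosome dyad offset from the anchor center,
#'   bp (default 110).
#' @param bg_fraction Fraction of fragments drawn from a diffuse uniform
#'   background (offsets within +/- 450 bp, lengths 30-250 bp), emulating
#'   the noise floor of real libraries (default 0.1).
#' @param bedpe Optional path; when given, fragments are written as BEDPE
#'   (two 50-bp reads at the fragment ends) with provenance and truth
#'   sidecars.
#' @return List with `fragments` (`GRanges`), `truth` (`data.frame`:
#'   `anchor`, `type`, `offset`, `length`).
#' @export
gen_fragments <- function(anchors, architecture = c("germline", "somatic"),
                          n = 10000L, seed = 1L, nuc_offset = 110L,
                          bg_fraction = 0.1, bedpe = NULL) {
  architecture <- match.arg(architecture)
  if (length(anchors) == 0L) stop("no anchors given")
  set.seed(seed)
  anchor <- sample.int(length(anchors), n, replace = TRUE)
  u <- runif(n)
  type <- ifelse(u < bg_fraction, "background",
                 ifelse(u < bg_fraction + (1 - bg_fraction) / 2,
                        "ndr", "nucleosome"))
  len <- integer(n)
  offset <- integer(n)

  bg <- type == "background"
  short <- type == "ndr"
  long <- type == "nucleosome"
  n_b <- sum(bg); n_s <- sum(short); n_l <- sum(long)
  len[bg] <- sample(30:250, n_b, replace = TRUE)
  offset[bg] <- as.integer(round(runif(n_b, -450, 450)))
  len[short] <- sample(40:99, n_s, replace = TRUE)
  len[long] <- sample(140:200, n_l, replace = TRUE)
  if (architecture == "germline") {
    offset[short] <- pmin(pmax(as.integer(round(rnorm(n_s, 0, 25))),
                               -55L), 55L)
    side <- sample(c(-1L, 1L), n_l, replace = TRUE)
    offset[long] <- side *
      pmin(pmax(as.integer(round(rnorm(n_l, nuc_offset, 8))), 60L), 180L)
  } else {
    offset[short] <- as.integer(round(runif(n_s, -140, 140)))
    offset[long] <- as.integer(round(runif(n_l, -200, 200)))
  }

  centers0 <- interval_centers0(anchors)[anchor]
  neg <- as.character(strand(anchors))[anchor] == "-"
  offset[neg] <- -offset[neg]
  mid0 <- centers0 + offset
  start0 <- mid0 - len %/% 2L
  frags <- GRanges(as.character(seqnames(anchors))[anchor],
                   IRanges(start = start0 + 1L, width = len))
  truth <- data.frame(anchor = anchor, type = type,
                      offset = offset, length = len)
  if (!is.null(bedpe)) {
    end0 <- start0 + len
    r <- pmin(50L, len)
    df <- data.frame(chrom1 = as.character(seqnames(frags)), start1 = start0,
                     end1 = start0 + r, chrom2 = as.character(seqnames(frags)),
                     start2 = end0 - r, end2 = end0)
    write.table(df, bedpe, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(truth, paste0(bedpe, ".truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_provenance(bedpe, list(generator = "gen_fragments",
                                 architecture = architecture, n = n,
                                 nuc_offset = nuc_offset, seed = seed))
  }
  list(fragments = frags, truth = truth)
}

#' Generate a nucleosome occupancy probability track
#'
#' Sums Gaussian bumps (one per dyad) over a region, optionally with
#' additive noise clamped at zero. With the default noiseless setting the
#' track argmax recovers each isolated dyad exactly.
#'
#' @param dyads `data.frame` with columns `chrom`, `pos` (0-based dyad) and
#'   optionally `amplitude` (default 1).
#' @param region List or `data.frame` row with `chrom`, `start`, `end`
#'   (0-based half-open) giving the track extent.
#' @param sigma Bump standard deviation, bp (default 20).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param bedgraph Optional output path (+ provenance and truth sidecars).
#' @return List with `track` (`GRanges` signal track, 1-bp bins) and
#'   `truth` (the dyad table).
#' @export
gen_occupancy_track <- function(dyads, region, sigma = 20, noise_sd = 0,
                                seed = 1L, bedgraph = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(dyads)))
  if (is.null(dyads$amplitude)) dyads$amplitude <- 1
  pos0 <- seq.int(region$start, region$end - 1L)
  vals <- numeric(length(pos0))
  on_chrom <- dyads$chrom == region$chrom
  for (i in which(on_chrom)) {
    # bumps are numerically zero beyond ~8 sigma; evaluate locally
    lo <- max(1L, as.integer(dyads$pos[i] - 8 * sigma - region$start + 1L))
    hi <- min(length(pos0),
              as.integer(dyads$pos[i] + 8 * sigma - region$start + 1L))
    if (lo > hi) next
    idx <- lo:hi
    vals[idx] <- vals[idx] + dyads$amplitude[i] *
      exp(-(pos0[idx] - dyads$pos[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- pmax(vals + rnorm(length(vals), 0, noise_sd), 0)
  }
  track <- signal_track(region$chrom, region$start, vals)
  if (!is.null(bedgraph)) {
    write_track(track, bedgraph, format = "bedgraph")
    write.table(dyads, paste0(bedgraph, ".truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_provenance(bedgraph, list(generator = "gen_occupancy_track",
                                    sigma = sigma, noise_sd = noise_sd,
                                    seed = seed))
  }
  list(track = track, truth = dyads)
}

# Design means per class label, scaled off the detection threshold. The
# effect parameter sets the planted specific/restricted contrast.
class_design_means <- function(label, detect_threshold, effect) {
  low <- detect_threshold * 0.6
  high <- low * effect
  m <- stats::setNames(rep(low, 5L), PROMARCH_TISSUES)
  if (startsWith(label, "specific:")) {
    m[sub("specific:", "", label)] <- high
  } else if (startsWith(label, "restricted:")) {
    m[strsplit(sub("restricted:", "", label), "+", fixed = TRUE)[[1]]] <- high
  } else if (label == "ubiquitous-uniform") {
    m[] <- high
  } else if (label == "ubiquitous-biased") {
    m[] <- detect_threshold * 1.75
    m[PROMARCH_TISSUES[1:2]] <- high
  } else if (label == "unclassified") {
    m[] <- detect_threshold * 0.5
  } else {
    stop("unknown design label: ", label)
  }
  m
}

#' Generate a signal matrix, differential table and truth labels
#'
#' Plants one of the specificity classes per ID at a chosen effect size and
#' multiplicative noise, then derives the pairwise differential table from
#' the design means: `fc` is the ratio of true means and `padj` is small
#' (1e-6) for contrasts whose true fold change exceeds 3, and 1 otherwise --
#' emulating well-powered upstream differential testing.
#'
#' @param design Character vector of planted labels, one per ID, in the
#'   label syntax of [classify_specificity()] (e.g. `"specific:germline"`,
#'   `"restricted:germline+neurons"`, `"ubiquitous-uniform"`).
#' @param detect_threshold 8 for site (RPM) designs, 5 for gene (TPM)
#'   designs.
#' @param effect Planted fold effect for specific/restricted classes
#'   (default 10).
#' @param noise_cv Multiplicative noise CV (default 0).
#' @param seed Integer seed.
#' @param prefix Optional path prefix; writes `<prefix>.matrix.tsv`,
#'   `<prefix>.diffs.tsv`, `<prefix>.truth.tsv` and a provenance sidecar.
#' @return List with `matrix`, `diffs`, `truth` (named label vector).
#' @export
gen_class_matrix <- function(design, detect_threshold = 8, effect = 10,
                             noise_cv = 0, seed = 1L, prefix = NULL) {
  n <- length(design)
  ids <- sprintf("id_%04d", seq_len(n))
  means <- t(vapply(design, class_design_means, numeric(5L),
                    detect_threshold = detect_threshold, effect = effect))
  dimnames(means) <- list(ids, PROMARCH_TISSUES)

  set.seed(seed)
  mat <- means
  if (noise_cv > 0) {
    mat <- means * (1 + matrix(rnorm(n * 5L, 0, noise_cv), n, 5L))
    mat[mat < 0] <- 0
  }

  pairs <- utils::combn(PROMARCH_TISSUES, 2L)
  diffs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    fc <- means[, a] / means[, b]
    data.frame(id = ids, tissue_a = a, tissue_b = b, fc = fc,
               padj = ifelse(pmax(fc, 1 / fc) > 3, 1e-6, 1),
               row.names = NULL)
  }))
  truth <- stats::setNames(design, ids)

  if (!is.null(prefix)) {
    write.table(data.frame(id = ids, mat, check.names = FALSE),
                paste0(prefix, ".matrix.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(diffs, paste0(prefix, ".diffs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(id = ids, label = design),
                paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_provenance(paste0(prefix, ".matrix.tsv"),
                     list(generator = "gen_class_matrix", n = n,
                          detect_threshold = detect_threshold,
                          effect = effect, noise_cv = noise_cv, seed = seed))
  }
  list(matrix = mat, diffs = diffs, truth = truth)
}

#' Generate nucleosome calls whose sequence periodicity tracks occupancy
#'
#' Builds one synthetic chromosome of consecutive 400-bp blocks, one block
#' per +1 nucleosome call. Each block's central 200 bp receives planted
#' 10-bp periodic WW sites with per-site retention probability equal to the
#' call's occupancy, so that sequence periodicity is monotonically coupled
#' to occupancy; this is the positive control for the occupancy-vs-
#' periodicity analysis.
#'
#' @param n Number of calls (default 400).
#' @param period Planted period (default 10).
#' @param gc Background GC content (default 0.36).
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`, one chromosome), `calls`
#'   (`data.frame`: `chrom`, `dyad`, `occupancy`).
#' @export
gen_coupled_nucleosomes <- function(n = 400L, period = 10L, gc = 0.36,
                                    seed = 1L) {
  set.seed(seed)
  block <- 400L
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  occupancy <- seq(0.05, 1, length.out = n)
  chrom <- character(n)
  for (i in seq_len(n)) {
    ch <- sample(names(probs), block, replace = TRUE, prob = probs)
    sites <- seq.int(101L, 299L, by = period) +
      sample(c(-1L, 0L, 1L), length(seq.int(101L, 299L, by = period)),
             replace = TRUE)
    sites <- sites[runif(length(sites)) < occupancy[i]]
    for (s in sites) ch[c(s, s + 1L)] <- sample(c("A", "T"), 2L,
                                                replace = TRUE)
    chrom[i] <- paste(ch, collapse = "")
  }
  genome <- DNAStringSet(stats::setNames(paste(chrom, collapse = ""), "chrS"))
  calls <- data.frame(chrom = "chrS",
                      dyad = (seq_len(n) - 1L) * block + 200L,
                      occupancy = occupancy)
  list(genome = genome, calls = calls)
}
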