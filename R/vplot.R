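# Fragment density V-plots.
#
# A V-plot is the 2D density of paired-end fragments around a set of anchors
# (promoter centers): x = fragment midpoint offset from the anchor center,
# y = fragment length. Promoters flanked by positioned -1/+1 nucleosomes
# show a central concentration of short (sub-nucleosomal) fragments over the
# NDR and clusters of nucleosome-length fragments ~100 bp on either side.

#' Compute a fragment-density V-plot
#'
#' Each fragment contributes one count at `(midpoint - anchor_center,
#' length)` for every anchor whose x-window contains its midpoint; the x
#' offset is sign-flipped for minus-strand anchors so that all anchors share
#' the transcription orientation. Raw counts are optionally scaled to
#' per-million-fragments per-anchor density:
#' `counts * 1e6 / (n_fragments * n_anchors)`.
#'
#' @param fragments `GRanges` of fragment spans ([read_fragments()]).
#' @param anchors `GRanges` of anchor intervals with strand; the anchor
#'   center is the floor midpoint of the interval.
#' @param x_range Midpoint-offset range, bp (default `c(-500, 500)`).
#' @param y_range Fragment-length range, bp (default `c(30, 250)`).
#' @param normalization `"per-million-per-anchor"` (default) or `"raw"`.
#' @return A `VplotMatrix`: list with `density` (length x offset matrix on
#'   the chosen scale), `raw` (integer counts), `x`, `y`, `n_fragments`,
#'   `n_anchors`, `normalization`. The raw matrix sum equals the number of
#'   in-range (x, y) fragment events.
#' @export
compute_vplot <- function(fragments, anchors,
                          x_range = c(-500L, 500L), y_range = c(30L, 250L),
                          normalization = c("per-million-per-anchor", "raw")) {
  normalization <- match.arg(normalization)
  if (length(anchors) == 0L) stop("no anchors given")
  stopifnot(x_range[1] < x_range[2], y_range[1] <= y_range[2])
  xs <- x_range[1]:x_range[2]
  ys <- y_range[1]:y_range[2]
  raw <- matrix(0L, nrow = length(ys), ncol = length(xs),
                dimnames = list(length = ys, offset = xs))
  n_frag <- length(fragments)

  lens <- width(fragments)
  inlen <- lens >= y_range[1] & lens <= y_range[2]
  if (!any(inlen)) {
    warning("no fragments within the length range")
  } else {
    fr <- fragments[inlen]
    mids0 <- fragment_midpoints(fr)
    centers0 <- interval_centers0(anchors)
    win <- GRanges(seqnames(anchors),
                   IRanges(start = centers0 + x_range[1] + 1L,
                           end = centers0 + x_range[2] + 1L))
    mp <- GRanges(seqnames(fr), IRanges(start = mids0 + 1L, width = 1L))
    ov <- findOverlaps(mp, win)
    if (length(ov) > 0L) {
      x <- mids0[queryHits(ov)] - centers0[subjectHits(ov)]
      neg <- as.character(strand(anchors))[subjectHits(ov)] == "-"
      x[neg] <- -x[neg]
      y <- width(fr)[queryHits(ov)]
      keep <- x >= x_range[1] & x <= x_range[2]
      x <- x[keep]; y <- y[keep]
      idx <- (match(x, xs) - 1L) * length(ys) + match(y, ys)
      counts <- tabulate(idx, nbins = length(xs) * length(ys))
      raw <- matrix(as.integer(counts), nrow = length(ys),
                    dimnames = dimnames(raw))
    } else {
      warning("no fragment midpoints within any anchor window")
    }
  }

  dens <- if (normalization == "raw") {
    raw
  } else {
    raw * 1e6 / (n_frag * length(anchors))
  }
  structure(list(density = dens, raw = raw, x = xs, y = ys,
                 n_fragments = n_frag, n_anchors = length(anchors),
                 normalization = normalization),
            class = "VplotMatrix")
}

#' @export
print.VplotMatrix <- function(x, ...) {
  cat(sprintf(
    "VplotMatrix: %d x %d (length %d..%d bp, offset %d..%d bp)\n  %d fragments, %d anchors, %d events, normalization: %s\n",
    nrow(x$density), ncol(x$density), min(x$y), max(x$y), min(x$x), max(x$x),
    x$n_fragments, x$n_anchors, sum(x$raw), x$normalization))
  invisible(x)
}

# mean density over a rectangular (x, y) box, both bounds inclusive
vplot_box_mean <- function(v, x_box, y_box) {
  xi <- v$x >= x_box[1] & v$x <= x_box[2]
  yi <- v$y >= y_box[1] & v$y <= y_box[2]
  if (!any(xi) || !any(yi)) stop("box outside the V-plot extent")
  mean(v$density[yi, xi])
}

#' Flanking-nucleosome enrichment score of a V-plot
#'
#' Ratio of the mean density over two flanking-nucleosome boxes (long
#' fragments at symmetric offsets on either side of the anchor) to the mean
#' density over matched background boxes further out. A uniform V-plot
#' scores exactly 1; positioned -1/+1 nucleosomes score above 1.
#'
#' @param v A `VplotMatrix`.
#' @param nuc_box_x Absolute offset range of the nucleosome boxes, bp;
#'   applied at both `+` and `-` offsets (default `c(70, 180)`).
#' @param nuc_box_y Fragment-length range of all boxes (default
#'   `c(150, 250)`).
#' @param bg_box_x Absolute offset range of the background boxes (default
#'   `c(250, 400)`).
#' @return A `FlankingScore`: list with `score` (NA and `flagged = TRUE`
#'   when the background density is zero) and `boxes`.
#' @export
flanking_enrichment <- function(v, nuc_box_x = c(70L, 180L),
                                nuc_box_y = c(150L, 250L),
                                bg_box_x = c(250L, 400L)) {
  stopifnot(inherits(v, "VplotMatrix"))
  nuc <- mean(c(vplot_box_mean(v, nuc_box_x, nuc_box_y),
                vplot_box_mean(v, -rev(nuc_box_x), nuc_box_y)))
  bg <- mean(c(vplot_box_mean(v, bg_box_x, nuc_box_y),
               vplot_box_mean(v, -rev(bg_box_x), nuc_box_y)))
  flagged <- bg == 0
  structure(list(score = if (flagged) NA_real_ else nuc / bg,
                 flagged = flagged,
                 boxes = list(nuc_x = nuc_box_x, bg_x = bg_box_x,
                              y = nuc_box_y)),
            class = "FlankingScore")
}

#' @export
print.FlankingScore <- function(x, ...) {
  cat(sprintf("FlankingScore: %s%s\n",
              format(x$score), if (x$flagged) " (flagged: zero background)" else ""))
  invisible(x)
}

#' Write a V-plot matrix as TSV
#'
#' Rows are fragment lengths, columns are midpoint offsets; dimnames are
#' written so the matrix round-trips.
#'
#' @param v A `VplotMatrix`.
#' @param path Output file.
#' @param what `"density"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_vplot <- function(v, path, what = c("density", "raw")) {
  what <- match.arg(what)
  m <- v[[what]]
  df <- data.frame(length = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
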