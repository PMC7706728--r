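# Tissue-specificity classification of accessible sites and genes.
#
# Inputs are a replicate-averaged signal matrix (RPM for sites, TPM for
# genes) over the five-tissue panel and a table of pairwise differential
# statistics (fold change + adjusted P-value) computed upstream. The
# classifier applies a fixed decision tree:
#   0. below the detection threshold in every tissue      -> unclassified
#   1. max tissue significant over every other tissue     -> specific(t)
#   2. detected set T of 2-4 tissues, every member
#      significant over every outsider, no member
#      significant over all other members                 -> restricted(T)
#   3. detected in all five, spread < fold-change
#      threshold and no significant pair                  -> ubiquitous-uniform
#   4. detected in all five otherwise                     -> ubiquitous-biased
#   5. anything else                                      -> unclassified
# Significance of a pair toward tissue a means FC > fc_threshold in a's
# favor with padj < padj_threshold.

format_specificity_label <- function(kind, tissues = NULL) {
  switch(kind,
         specific = paste0("specific:", tissues),
         restricted = paste0(
           "restricted:",
           paste(tissues[order(match(tissues, PROMARCH_TISSUES))],
                 collapse = "+")),
         kind)
}

# Per-ID 5x5 logical matrix S[a, b] = "a significantly above b".
build_sig_matrix <- function(d, fc_threshold, padj_threshold) {
  S <- matrix(FALSE, 5L, 5L,
              dimnames = list(PROMARCH_TISSUES, PROMARCH_TISSUES))
  sig <- d$padj < padj_threshold
  up <- sig & d$fc > fc_threshold
  dn <- sig & d$fc < 1 / fc_threshold
  S[cbind(d$tissue_a[up], d$tissue_b[up])] <- TRUE
  S[cbind(d$tissue_b[dn], d$tissue_a[dn])] <- TRUE
  S
}

classify_one <- function(v, S, detect_threshold, fc_threshold) {
  det <- v >= detect_threshold
  if (!any(det)) return("unclassified")
  tmax <- PROMARCH_TISSUES[which.max(v)]
  others <- setdiff(PROMARCH_TISSUES, tmax)
  if (all(S[tmax, others])) {
    return(format_specificity_label("specific", tmax))
  }
  Tset <- PROMARCH_TISSUES[det]
  if (length(Tset) >= 2L && length(Tset) <= 4L) {
    outside <- setdiff(PROMARCH_TISSUES, Tset)
    all_vs_out <- all(S[Tset, outside])
    dominator <- any(vapply(Tset, function(t) {
      all(S[t, setdiff(Tset, t)])
    }, logical(1)))
    if (all_vs_out && !dominator) {
      return(format_specificity_label("restricted", Tset))
    }
  }
  if (all(det)) {
    if (max(v) / min(v) < fc_threshold && !any(S)) {
      return("ubiquitous-uniform")
    }
    return("ubiquitous-biased")
  }
  "unclassified"
}

#' Classify accessible sites (or genes) by tissue specificity
#'
#' Applies the rule-based decision tree described in the package vignette to
#' a replicate-averaged signal matrix and a table of pairwise differential
#' statistics. Every ID receives exactly one label.
#'
#' @param mat Numeric matrix, rows = site/gene IDs (rownames required),
#'   columns = the five tissues of [promarch_tissues()] (any order).
#' @param diffs `data.frame` with columns `id`, `tissue_a`, `tissue_b`,
#'   `fc` (fold change, oriented `tissue_a / tissue_b`), `padj`. All ten
#'   unordered tissue pairs must be present for every ID detected above
#'   threshold; a missing pair is an error naming the ID.
#' @param detect_threshold Detection threshold: 8 RPM for sites
#'   ([classify_sites()]), 5 TPM for genes ([classify_genes()]).
#' @param fc_threshold Fold-change threshold (default 3).
#' @param padj_threshold Adjusted P-value threshold (default 0.01).
#' @return Named character vector of labels: `"specific:<tissue>"`,
#'   `"restricted:<t1>+<t2>..."`, `"ubiquitous-uniform"`,
#'   `"ubiquitous-biased"` or `"unclassified"`.
#' @export
classify_specificity <- function(mat, diffs, detect_threshold,
                                 fc_threshold = 3, padj_threshold = 0.01) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (!setequal(colnames(mat), PROMARCH_TISSUES)) {
    stop("matrix columns must be exactly: ",
         paste(PROMARCH_TISSUES, collapse = ", "))
  }
  mat <- mat[, PROMARCH_TISSUES, drop = FALSE]
  req <- c("id", "tissue_a", "tissue_b", "fc", "padj")
  stopifnot(all(req %in% names(diffs)))

  dsplit <- split(diffs, diffs$id)
  labels <- character(nrow(mat))
  names(labels) <- rownames(mat)
  for (id in rownames(mat)) {
    v <- mat[id, ]
    if (any(v >= detect_threshold)) {
      d <- dsplit[[id]]
      if (is.null(d)) {
        stop("differential table is missing tissue pairs for ID '", id, "'")
      }
      pairs <- unique(paste(pmin(d$tissue_a, d$tissue_b),
                            pmax(d$tissue_a, d$tissue_b), sep = "|"))
      if (length(pairs) < 10L) {
        stop("differential table is missing tissue pairs for ID '", id, "'")
      }
      S <- build_sig_matrix(d, fc_threshold, padj_threshold)
    } else {
      S <- matrix(FALSE, 5L, 5L,
                  dimnames = list(PROMARCH_TISSUES, PROMARCH_TISSUES))
    }
    labels[id] <- classify_one(v, S, detect_threshold, fc_threshold)
  }
  labels
}

#' @rdname classify_specificity
#' @param ... Passed to [classify_specificity()].
#' @export
classify_sites <- function(mat, diffs, detect_threshold = 8, ...) {
  classify_specificity(mat, diffs, detect_threshold = detect_threshold, ...)
}

#' @rdname classify_specificity
#' @export
classify_genes <- function(mat, diffs, detect_threshold = 5, ...) {
  classify_specificity(mat, diffs, detect_threshold = detect_threshold, ...)
}

#' Group genes by expression coefficient of variation
#'
#' Computes CV = sd/mean per gene across samples and splits genes into the
#' lowest-CV quantile (`broad`, broadly expressed), the highest-CV quantile
#' (`regulated`) and the remainder (`middle`). Cut points are rank-based so
#' a fraction `low_q` (resp. `high_q`) of genes lands in each extreme group
#' exactly (floor of `n * q`); ties are broken by gene order, stably.
#' Zero-mean genes have undefined CV and are excluded (returned in the
#' `excluded` attribute).
#'
#' @param expression Numeric matrix, genes x samples (>= 2 samples),
#'   rownames required.
#' @param low_q,high_q Quantile fractions (defaults 0.2 and 0.2).
#' @return `data.frame` with columns `gene`, `cv`, `group`; attribute
#'   `excluded` holds the zero-mean gene IDs.
#' @export
cv_groups <- function(expression, low_q = 0.2, high_q = 0.2) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2,
            !is.null(rownames(expression)))
  m <- rowMeans(expression)
  excluded <- rownames(expression)[m == 0]
  if (length(excluded)) {
    warning(length(excluded), " zero-mean genes excluded from CV grouping")
    expression <- expression[m != 0, , drop = FALSE]
    m <- m[m != 0]
  }
  s <- apply(expression, 1, sd)
  cv <- s / m
  n <- length(cv)
  ord <- order(cv)  # stable: ties keep input order
  group <- rep("middle", n)
  n_low <- floor(n * low_q)
  n_high <- floor(n * high_q)
  if (n_low > 0) group[ord[seq_len(n_low)]] <- "broad"
  if (n_high > 0) group[ord[seq.int(n - n_high + 1L, n)]] <- "regulated"
  structure(data.frame(gene = rownames(expression), cv = cv, group = group,
                       row.names = NULL),
            excluded = excluded)
}

#' Read a pairwise differential table
#'
#' Generic TSV adapter: columns `id`, `tissue_a`, `tissue_b`, `fc`, `padj`
#' with `fc` oriented `tissue_a / tissue_b`.
#'
#' @param path TSV file with header.
#' @return `data.frame` suitable for [classify_specificity()].
#' @export
read_diff_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("id", "tissue_a", "tissue_b", "fc", "padj")
  if (!all(req %in% names(df))) {
    stop("differential table must contain columns: ",
         paste(req, collapse = ", "))
  }
  df
}

#' Read a signal matrix (RPM or TPM) from TSV
#'
#' First column = ID, remaining columns = tissues.
#'
#' @param path TSV file with header.
#' @return Numeric matrix with ID rownames.
#' @export
read_signal_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Keep non-operon genes and first genes in operons
#'
#' Optional pre-filter for promoter-level analyses: operon-internal genes
#' share an upstream promoter and are removed.
#'
#' @param ids Character vector of gene IDs.
#' @param operons `data.frame` with columns `gene` and `position`
#'   (`"first"` or `"internal"`); genes absent from the table are treated as
#'   non-operon genes and kept.
#' @return Logical vector parallel to `ids`: keep or drop.
#' @export
operon_filter <- function(ids, operons) {
  stopifnot(all(c("gene", "position") %in% names(operons)))
  pos <- operons$position[match(ids, operons$gene)]
  is.na(pos) | pos == "first"
}
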