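#' Community relative-abundance table
#'
#' Samples x taxa matrix of relative abundances (rows sum to 1 within
#' 1e-6), with a group label per sample (e.g. rock vs control, or site).
#'
#' @param abundance Numeric matrix or data frame, samples in rows (named),
#'   taxa in columns (named); non-negative, rows summing to ~1.
#' @param groups Character vector of per-sample group labels (optional).
#' @param substrates Optional character vector mapping each sample to a
#'   substrate id in a [bulk_chemistry()] table.
#' @param check_rowsums If `FALSE`, skip the row-sum check (used internally
#'   after taxa filtering, which deliberately does not renormalize).
#' @return An object of class `community_table`.
#' @export
community_table <- function(abundance, groups = NULL, substrates = NULL,
                            check_rowsums = TRUE) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) && nrow(abundance))
    rownames(abundance) <- paste0("sample", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)) && ncol(abundance))
    colnames(abundance) <- paste0("taxon", seq_len(ncol(abundance)))
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (check_rowsums && nrow(abundance) &&
      any(abs(rowSums(abundance) - 1) > 1e-6))
    stop("rows must sum to 1 (relative abundances)")
  if (!is.null(groups)) stopifnot(length(groups) == nrow(abundance))
  if (!is.null(substrates)) stopifnot(length(substrates) == nrow(abundance))
  structure(list(abundance = abundance, groups = groups,
                 substrates = substrates, filtered = FALSE),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d samples x %d taxa%s\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$filtered) " (filtered, not renormalized)" else ""))
  invisible(x)
}

#' Bulk chemistry from replicate XEDS scans
#'
#' Element-wise arithmetic mean across replicate low-magnification scans of
#' one substrate (the study convention: 8 scans at 70x per rock unit).
#'
#' @param scans Data frame or matrix of per-scan element compositions
#'   (scans in rows, elements in columns, weight-%), or a list of named
#'   numeric vectors with identical element sets.
#' @return Named numeric vector: mean weight-% per element.
#' @export
bulk_chemistry <- function(scans) {
  if (is.list(scans) && !is.data.frame(scans)) {
    els <- names(scans[[1]])
    if (is.null(els)) stop("scans must have named elements")
    for (k in seq_along(scans))
      if (!identical(sort(names(scans[[k]])), sort(els)))
        stop(sprintf("scan %d has a different element set", k))
    scans <- do.call(rbind, lapply(scans, function(v) v[els]))
  }
  scans <- as.matrix(scans)
  stopifnot(nrow(scans) >= 1)
  if (any(scans < 0)) stop("weight-% must be non-negative")
  colMeans(scans)
}

#' Assemble a substrates x elements bulk-chemistry table
#'
#' @param rows Named list: substrate id -> named element vector (e.g. the
#'   output of [bulk_chemistry()] per substrate).
#' @return Matrix (substrates x elements) of class `bulk_chem`.
#' @export
bulk_chem_table <- function(rows) {
  stopifnot(is.list(rows), length(rows) >= 1, !is.null(names(rows)))
  els <- sort(unique(unlist(lapply(rows, names))))
  m <- t(vapply(rows, function(v) {
    out <- stats::setNames(numeric(length(els)), els)
    out[names(v)] <- v
    out
  }, numeric(length(els))))
  if (any(rowSums(m) > 100 + 1e-6))
    warning("per-substrate totals exceed 100 weight-%")
  structure(m, class = c("bulk_chem", "matrix"))
}

#' Filter taxa by abundance and prevalence
#'
#' Keeps taxa that reach at least `min_abundance` relative abundance in at
#' least one sample AND are present (> 0) in at least a `min_prevalence`
#' fraction of samples (the "at least 1% of a community and present in at
#' least half" rule). Abundances are deliberately NOT renormalized after
#' filtering, so retained values stay interpretable against the original
#' whole community; the result is flagged `filtered`.
#'
#' @param table A [community_table()].
#' @param min_abundance Minimum within-sample relative abundance
#'   (default 0.01).
#' @param min_prevalence Minimum fraction of samples with presence
#'   (default 0.5).
#' @return A filtered `community_table` (empty with a warning if no taxon
#'   passes). Idempotent.
#' @export
filter_taxa <- function(table, min_abundance = 0.01, min_prevalence = 0.5) {
  stopifnot(inherits(table, "community_table"))
  ab <- table$abundance
  if (!ncol(ab)) return(table)
  keep <- apply(ab, 2, max) >= min_abundance &
    colMeans(ab > 0) >= min_prevalence
  if (!any(keep)) warning("no taxa pass the abundance/prevalence filter")
  out <- community_table(ab[, keep, drop = FALSE], groups = table$groups,
                         substrates = table$substrates, check_rowsums = FALSE)
  out$filtered <- TRUE
  out
}

#' Correlation matrix between taxa and bulk rock chemistry
#'
#' Correlates each taxon's abundance with each element's weight-% across
#' samples (each sample carries the bulk chemistry of its substrate).
#' Zero-variance taxa or elements give `NA` entries ("undefined", distinct
#' from 0). Rows and columns are ordered by complete-linkage hierarchical
#' clustering of correlation distance (`1 - r`), reproducing the clade
#' structure of clustered-heatmap displays.
#'
#' @param table A [community_table()] with `substrates` set.
#' @param chem A [bulk_chem_table()] whose rownames cover the table's
#'   substrates.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform Optional abundance transform applied first (e.g.
#'   `function(x) log10(x + 1e-6)`); raw abundances by default.
#' @return Matrix (taxa x elements) of correlations, ordered by clustering;
#'   attributes `row_order`/`col_order` hold the dendrogram orders.
#' @export
taxa_chem_correlation <- function(table, chem, method = c("pearson", "spearman"),
                                  transform = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$substrates))
    stop("community table must map samples to substrates")
  chem <- as.matrix(chem)
  if (!all(table$substrates %in% rownames(chem)))
    stop("every sample's substrate must appear in the chemistry table")
  if (nrow(table$abundance) < 3)
    stop("correlation needs at least 3 samples")
  ab <- table$abundance
  if (!is.null(transform)) ab <- transform(ab)
  X <- chem[table$substrates, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(ab, X, method = method))
  ord_r <- seq_len(nrow(cm)); ord_c <- seq_len(ncol(cm))
  if (nrow(cm) > 2) {
    dmat <- 1 - cm
    dmat[!is.finite(dmat)] <- 1 # undefined correlations treated as neutral
    ord_r <- stats::hclust(stats::dist(dmat), method = "complete")$order
  }
  if (ncol(cm) > 2) {
    dmat <- 1 - t(cm)
    dmat[!is.finite(dmat)] <- 1
    ord_c <- stats::hclust(stats::dist(dmat), method = "complete")$order
  }
  out <- cm[ord_r, ord_c, drop = FALSE]
  attr(out, "row_order") <- ord_r
  attr(out, "col_order") <- ord_c
  out
}

#' Bray-Curtis dissimilarity matrix among samples
#'
#' `d(a, b) = sum |x_a - x_b| / sum (x_a + x_b)` over taxa, computed with
#' [vegan::vegdist()].
#'
#' @param table A [community_table()].
#' @return Symmetric samples x samples matrix with zero diagonal, entries
#'   in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (any(rowSums(table$abundance) == 0))
    stop("all-zero sample row(s): dissimilarity undefined")
  as.matrix(vegan::vegdist(table$abundance, method = "bray"))
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every between-group sample pair `(a, b)`, taxon `i` contributes
#' `|x_ai - x_bi| / sum_k (x_ak + x_bk)` to the pair's Bray-Curtis
#' dissimilarity; contributions are averaged over all between-group pairs.
#' They sum exactly to the average between-group Bray-Curtis dissimilarity.
#' Taxa are ranked by contribution and the selected set is the smallest
#' prefix reaching the cumulative `cutoff` (default 75%).
#'
#' @param table A [community_table()] with `groups` set.
#' @param groups Two group labels to contrast (default: the table's two
#'   unique labels).
#' @param cutoff Cumulative-share cutoff for the selected taxa set
#'   (default 0.75).
#' @return Object of class `simper_result`: `contributions` (data frame
#'   `taxon`, `average`, `cumulative_share`, ranked), `overall` (mean
#'   between-group dissimilarity), `selected` (character vector), `groups`.
#' @export
simper_contributions <- function(table, groups = NULL, cutoff = 0.75) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$groups)) stop("community table must carry group labels")
  if (is.null(groups)) {
    groups <- unique(table$groups)
    if (length(groups) != 2)
      stop("specify the two group labels to contrast")
  }
  ia <- which(table$groups == groups[1])
  ib <- which(table$groups == groups[2])
  if (!length(ia) || !length(ib))
    stop("both groups must have at least one sample")
  ab <- table$abundance
  pairs <- expand.grid(a = ia, b = ib)
  contrib <- matrix(0, nrow(pairs), ncol(ab))
  for (p in seq_len(nrow(pairs))) {
    xa <- ab[pairs$a[p], ]; xb <- ab[pairs$b[p], ]
    contrib[p, ] <- abs(xa - xb) / sum(xa + xb)
  }
  avg <- colMeans(contrib)
  names(avg) <- colnames(ab)
  ord <- order(avg, decreasing = TRUE)
  overall <- sum(avg)
  cum <- cumsum(avg[ord]) / overall
  n_sel <- if (overall > 0) which(cum >= cutoff)[1] else 0L
  structure(list(
    contributions = data.frame(taxon = names(avg)[ord], average = avg[ord],
                               cumulative_share = cum, row.names = NULL),
    overall = overall,
    selected = if (n_sel > 0) names(avg)[ord][seq_len(n_sel)] else character(0),
    groups = groups, cutoff = cutoff), class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat(sprintf("SIMPER %s vs %s: mean between-group dissimilarity %.4f\n",
              x$groups[1], x$groups[2], x$overall))
  cat(sprintf("  %d taxa reach the %.0f%% cumulative cutoff\n",
              length(x$selected), 100 * x$cutoff))
  print(utils::head(x$contributions, 5))
  invisible(x)
}
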