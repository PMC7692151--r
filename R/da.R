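#' Per-sample log-ratio matrix
#'
#' For every ordered pair of taxa (t, r) and every sample s, the natural-log
#' ratio `log((counts[s,t] + pseudocount) / (counts[s,r] + pseudocount))`.
#' Library size cancels in the ratio, so counts and relative abundances give
#' identical values up to the pseudocount.
#'
#' @param counts an [asv_count_table] (or numeric samples-by-taxa matrix)
#'   with at least two taxa.
#' @param pseudocount positive offset added to every count before the ratio;
#'   may be a scalar or one value per sample.
#' @return A 3-d array with dimensions sample x target taxon x reference
#'   taxon; the diagonal slices (t = r) are zero.
#' @export
logratio_matrix <- function(counts, pseudocount = 1) {
  m <- unclass(counts) * 1.0
  if (ncol(m) < 2) stop("need at least 2 taxa for log ratios")
  if (any(pseudocount <= 0)) stop("pseudocount must be > 0")
  if (!length(pseudocount) %in% c(1L, nrow(m)))
    stop("pseudocount must be a scalar or one value per sample")
  lc <- log(m + pseudocount)   # per-sample pseudocount recycles down columns
  out <- array(NA_real_, c(nrow(m), ncol(m), ncol(m)),
               dimnames = list(rownames(m), colnames(m), colnames(m)))
  for (r in seq_len(ncol(m))) out[, , r] <- lc - lc[, r]
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value, using the exact null distribution when both
#' groups have at most 25 observations and the pooled data is tie-free, and
#' the normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 25 && length(y) <= 25 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Two-sample Hodges-Lehmann estimator
#'
#' The median of all pairwise differences `y_j - x_i`: a robust estimate of
#' the location shift of `y` relative to `x`.
#'
#' @param x,y non-empty numeric vectors.
#' @return The median of the `length(x) * length(y)` differences.
#' @export
hodges_lehmann <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  stats::median(as.vector(outer(y, x, "-")))
}

#' Benjamini-Yekutieli adjustment with an FDR cap
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence
#' (the raw step ratios are inflated by the harmonic number
#' `c(m) = sum(1/(1:m))`), plus the significance mask at the given cap.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param cap FDR cap; adjusted p-values at or below it are flagged.
#' @return A list with `adjusted` (numeric vector) and `significant`
#'   (logical mask `adjusted <= cap`).
#' @export
by_adjust <- function(p, cap = 0.10) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BY")
  list(adjusted = adjusted, significant = adjusted <= cap)
}

#' Compositional differential-abundance test (ANCOM variant)
#'
#' Tests every taxon for differential abundance between two sample groups by
#' the pairwise log-ratio strategy of ANCOM: counts are aggregated to the
#' requested rank, a pseudocount is added, and for every pair of taxa the
#' per-sample log ratio is compared between the groups with a Wilcoxon
#' rank-sum test. The p-values are adjusted jointly across all taxon pairs
#' with the Benjamini-Yekutieli procedure capped at `thresholds$fdr_cap`.
#' A taxon's W statistic counts the reference taxa against which its ratio
#' shifts significantly; taxa with a W fraction at or above
#' `thresholds$w_fraction_cutoff` are flagged. Shifts are quantified with the
#' two-sample Hodges-Lehmann estimator of the between-group log-ratio
#' difference; a taxon's effect is its median over all references, positive
#' when the taxon is relatively more abundant in `group_a`.
#'
#' The default fixed pseudocount makes results only approximately invariant
#' to per-sample library size; with `scaled_pseudocount = TRUE` each
#' sample's pseudocount is `pseudocount * depth / reference_depth`, so a
#' sample's log ratios depend on its counts only through their proportions.
#' This gives exact invariance under integer rescaling of any sample
#' whenever `reference_depth` is fixed (by default it is the median depth of
#' the analysed samples, which itself moves if the rescaled sample straddles
#' the median).
#'
#' @param counts an [asv_count_table] at ASV level.
#' @param metadata a [sample_metadata] data.frame covering the samples.
#' @param group_a,group_b the two group labels to compare (effects are
#'   `group_a` minus `group_b` on the log-ratio scale).
#' @param rank taxonomic rank at which to test (`"genus"`, `"asv"`, ...).
#' @param taxonomy a [taxonomy_table]; required unless `rank = "asv"`.
#' @param thresholds a [vag_thresholds] object.
#' @param scaled_pseudocount logical; scale the pseudocount with sample
#'   depth (see Details).
#' @param reference_depth depth at which the scaled pseudocount equals
#'   `thresholds$pseudocount`; default the median depth of the analysed
#'   samples. Ignored unless `scaled_pseudocount = TRUE`.
#' @return An object of class `vag_da`: a list with the taxa, the symmetric
#'   raw and adjusted p-value matrices, the antisymmetric Hodges-Lehmann
#'   effect matrix, and a per-taxon `summary` data.frame with columns
#'   `taxon`, `w_count`, `w_fraction`, `significant`, `effect` (natural log),
#'   `effect_log10` and `direction`.
#' @seealso [summary.vag_da()], [coef.vag_da()], [plot.vag_da()]
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit <- da_test(cohort$counts, cohort$metadata, "AV", "NL",
#'                rank = "genus", taxonomy = cohort$taxonomy)
#' summary(fit)
#' @export
da_test <- function(counts, metadata, group_a, group_b, rank = "genus",
                    taxonomy = NULL, thresholds = vag_thresholds(),
                    scaled_pseudocount = FALSE, reference_depth = NULL) {
  if (!group_a %in% metadata$group) stop("unknown group label: ", group_a)
  if (!group_b %in% metadata$group) stop("unknown group label: ", group_b)
  if (!identical(rank, "asv") && is.null(taxonomy))
    stop("taxonomy required for rank ", rank)
  grp <- metadata$group[match(rownames(counts), metadata$sample_id)]
  in_a <- which(grp == group_a)
  in_b <- which(grp == group_b)
  if (length(in_a) < 2 || length(in_b) < 2)
    stop("need at least 2 samples per group (", group_a, ": ", length(in_a),
         ", ", group_b, ": ", length(in_b), ")")

  sub <- unclass(counts)[c(in_a, in_b), , drop = FALSE]
  sub <- asv_count_table(sub)
  if (!identical(rank, "asv")) sub <- aggregate_taxa(sub, taxonomy, rank)
  m <- unclass(sub)[, colSums(unclass(sub)) > 0, drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 taxa with non-zero counts at rank ", rank)
  taxa <- colnames(m)
  n_t <- length(taxa)
  is_a <- seq_len(nrow(m)) <= length(in_a)

  pc <- thresholds$pseudocount
  if (scaled_pseudocount) {
    depth <- rowSums(m)
    ref <- if (is.null(reference_depth)) stats::median(depth) else reference_depth
    pc <- pc * depth / ref
  }
  lc <- log(m + pc)

  p_mat <- matrix(NA_real_, n_t, n_t, dimnames = list(taxa, taxa))
  hl_mat <- matrix(NA_real_, n_t, n_t, dimnames = list(taxa, taxa))
  pairs <- which(upper.tri(p_mat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    t_i <- pairs[k, 1]; r_i <- pairs[k, 2]
    lr <- lc[, t_i] - lc[, r_i]
    p <- wilcoxon_rank_sum(lr[is_a], lr[!is_a])
    eff <- hodges_lehmann(lr[!is_a], lr[is_a])   # group_a minus group_b
    p_mat[t_i, r_i] <- p_mat[r_i, t_i] <- p
    hl_mat[t_i, r_i] <- eff
    hl_mat[r_i, t_i] <- -eff
  }

  # one BY family over the unordered pairs; the mirrored entries share a value
  adj <- by_adjust(p_mat[upper.tri(p_mat)], cap = thresholds$fdr_cap)
  adj_mat <- matrix(NA_real_, n_t, n_t, dimnames = list(taxa, taxa))
  adj_mat[upper.tri(adj_mat)] <- adj$adjusted
  adj_mat[lower.tri(adj_mat)] <- t(adj_mat)[lower.tri(adj_mat)]

  w_count <- vapply(seq_len(n_t), function(t_i)
    sum(adj_mat[t_i, -t_i] <= thresholds$fdr_cap), integer(1))
  effect <- vapply(seq_len(n_t), function(t_i)
    stats::median(hl_mat[t_i, -t_i]), numeric(1))
  summ <- data.frame(
    taxon = taxa,
    w_count = w_count,
    w_fraction = w_count / (n_t - 1),
    significant = w_count / (n_t - 1) >= thresholds$w_fraction_cutoff,
    effect = effect,
    effect_log10 = effect / log(10),
    direction = sign(effect),
    row.names = NULL)

  structure(list(taxa = taxa, groups = c(group_a, group_b),
                 n = c(length(in_a), length(in_b)), rank = rank,
                 p_values = p_mat, adjusted_p = adj_mat, hl_effects = hl_mat,
                 summary = summ, thresholds = thresholds,
                 scaled_pseudocount = scaled_pseudocount,
                 call = match.call()),
            class = "vag_da")
}

#' @export
print.vag_da <- function(x, ...) {
  cat("Compositional differential abundance (ANCOM variant)\n")
  cat("  ", x$groups[1], " (n = ", x$n[1], ") vs ", x$groups[2],
      " (n = ", x$n[2], ") at rank ", x$rank, ", ",
      length(x$taxa), " taxa\n", sep = "")
  cat("  FDR cap ", x$thresholds$fdr_cap, " (Benjamini-Yekutieli), W cutoff ",
      x$thresholds$w_fraction_cutoff, "\n", sep = "")
  sig <- x$summary$taxon[x$summary$significant]
  if (length(sig) == 0) {
    cat("  No taxa flagged.\n")
  } else {
    cat("  Flagged: ", paste(sig, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-taxon summary of a differential-abundance fit
#'
#' @param object a `vag_da` object from [da_test()].
#' @param ... unused.
#' @return The per-taxon summary data.frame, ordered by decreasing W count.
#' @export
summary.vag_da <- function(object, ...) {
  s <- object$summary
  s <- s[order(-s$w_count, -abs(s$effect)), ]
  rownames(s) <- NULL
  class(s) <- c("summary.vag_da", "data.frame")
  attr(s, "groups") <- object$groups
  s
}

#' @export
print.summary.vag_da <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Per-taxon W statistics and Hodges-Lehmann effects (",
      g[1], " vs ", g[2], "; effect > 0 means higher in ", g[1], ")\n",
      sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
coef.vag_da <- function(object, ...) {
  stats::setNames(object$summary$effect, object$summary$taxon)
}

#' @export
as.data.frame.vag_da <- function(x, ...) x$summary

#' Plot a differential-abundance fit
#'
#' W fraction against the Hodges-Lehmann effect per taxon, with the
#' significance cutoff drawn as a horizontal line.
#'
#' @param x a `vag_da` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vag_da <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$effect, s$w_fraction,
                 xlab = sprintf("Hodges-Lehmann effect (log scale, %s vs %s)",
                                x$groups[1], x$groups[2]),
                 ylab = "W fraction", ylim = c(0, 1),
                 pch = ifelse(s$significant, 19, 1), ...)
  graphics::abline(h = x$thresholds$w_fraction_cutoff, lty = 2)
  graphics::text(s$effect, s$w_fraction, s$taxon, pos = 3, cex = 0.6)
  invisible(x)
}
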