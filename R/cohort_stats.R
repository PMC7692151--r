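#' Dominance and prevalence profile
#'
#' Per taxon and group, the number of samples in which the taxon is present
#' (relative abundance strictly above `thresholds$present_cutoff`, default
#' 1%) and dominant (strictly above `thresholds$dominant_cutoff`, default
#' 50%).
#'
#' @param relab relative-abundance matrix from [relative_abundance()].
#' @param metadata a [sample_metadata] data.frame.
#' @param thresholds a [vag_thresholds] object.
#' @return A data.frame with columns `taxon`, `group`, `n_present`,
#'   `n_dominant`, `n_group`.
#' @export
dominance_profile <- function(relab, metadata, thresholds = vag_thresholds()) {
  grp <- metadata$group[match(rownames(relab), metadata$sample_id)]
  if (anyNA(grp))
    stop("sample(s) missing from metadata: ",
         paste(rownames(relab)[is.na(grp)], collapse = ", "))
  out <- expand.grid(taxon = colnames(relab), group = sort(unique(grp)),
                     stringsAsFactors = FALSE)
  out$n_present <- mapply(function(tx, g)
    sum(relab[grp == g, tx] > thresholds$present_cutoff), out$taxon, out$group)
  out$n_dominant <- mapply(function(tx, g)
    sum(relab[grp == g, tx] > thresholds$dominant_cutoff), out$taxon, out$group)
  out$n_group <- as.integer(table(grp)[out$group])
  out
}

#' Relative abundances of the top genera plus a residual
#'
#' Aggregates to genus, ranks genera by their total relative abundance over
#' all samples, keeps the `n` most abundant and pools the remaining mass
#' into a final `"residual"` column; rows still sum to one.
#'
#' @param counts an [asv_count_table].
#' @param taxonomy a [taxonomy_table].
#' @param n number of genera to keep (default 11).
#' @return A relative-abundance matrix over `n` genera plus `"residual"`.
#' @export
top_genus_table <- function(counts, taxonomy, n = 11) {
  stopifnot(n >= 1)
  relab <- relative_abundance(aggregate_taxa(counts, taxonomy, "genus"))
  rank_order <- order(colSums(relab), decreasing = TRUE)
  keep <- colnames(relab)[rank_order[seq_len(min(n, ncol(relab)))]]
  rest <- setdiff(colnames(relab), keep)
  residual <- if (length(rest) > 0)
    rowSums(relab[, rest, drop = FALSE]) else rep(0, nrow(relab))
  cbind(relab[, keep, drop = FALSE], residual = residual)
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical vectors,
#' 1 for disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return A dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("vectors must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(x, y)) / tot
}

bray_curtis_matrix <- function(relab) {
  n <- nrow(relab)
  d <- matrix(0, n, n, dimnames = list(rownames(relab), rownames(relab)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(relab[i, ], relab[j, ])
  d
}

path_length <- function(d, ord) {
  if (length(ord) < 2) return(0)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Order samples by Bray-Curtis similarity
#'
#' Finds an open-path ordering of the samples minimising the total
#' Bray-Curtis distance between neighbours. For up to 9 samples the optimum
#' is found by exhaustive search over all orderings; above that, a
#' best-of-all-starts nearest-neighbour construction refined by 2-opt moves
#' gives a deterministic, locally optimal path. Ties are broken by sample
#' identifier and the orientation is fixed by putting the lexicographically
#' smaller endpoint first.
#'
#' @param relab relative-abundance matrix (samples in rows).
#' @return Character vector of sample identifiers in seriated order.
#' @export
seriate_samples <- function(relab) {
  ids <- rownames(relab)
  n <- length(ids)
  if (n == 0) stop("need at least one sample")
  if (n == 1) return(ids)
  if (n == 2) return(sort(ids))
  d <- bray_curtis_matrix(relab)
  # work in identifier-sorted index space so all tie-breaks are by id
  o <- order(ids)
  d <- d[o, o]
  ids_s <- ids[o]

  best <- if (n <= 9) seriate_exhaustive(d) else seriate_heuristic(d)
  # orientation: lexicographically smaller endpoint first
  if (ids_s[best[1]] > ids_s[best[n]]) best <- rev(best)
  ids_s[best]
}

seriate_exhaustive <- function(d) {
  n <- nrow(d)
  perms <- all_perms(n)
  perms <- perms[perms[, 1] < perms[, n], , drop = FALSE]  # one orientation
  len <- rep(0, nrow(perms))
  for (i in seq_len(n - 1))
    len <- len + d[cbind(perms[, i], perms[, i + 1])]
  cand <- which(len <= min(len) + 1e-12)
  # deterministic among ties: lexicographically smallest index sequence
  best <- cand[do.call(order, as.data.frame(perms[cand, , drop = FALSE]))[1]]
  perms[best, ]
}

seriate_heuristic <- function(d) {
  n <- nrow(d)
  nn_path <- function(start) {
    ord <- integer(n); used <- rep(FALSE, n)
    ord[1] <- start; used[start] <- TRUE
    for (i in 2:n) {
      rem <- which(!used)
      nxt <- rem[which.min(d[ord[i - 1], rem])]  # which.min is tie-stable
      ord[i] <- nxt; used[nxt] <- TRUE
    }
    ord
  }
  candidates <- c(lapply(seq_len(n), nn_path), list(seq_len(n)))
  lens <- vapply(candidates, function(o) path_length(d, o), numeric(1))
  ord <- candidates[[which.min(lens)]]
  # 2-opt: reverse segments while the path shortens
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        new <- ord
        new[i:j] <- rev(new[i:j])
        if (path_length(d, new) < path_length(d, ord) - 1e-12) {
          ord <- new
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Correlation of a taxon's relative abundance with the AV score
#'
#' Pearson correlation (two-sided t-based p-value) between a taxon's
#' relative abundance and the composite AV score, over the samples with a
#' non-missing score.
#'
#' @param relab relative-abundance matrix.
#' @param taxon column of `relab` to correlate.
#' @param scores numeric AV scores aligned with `rownames(relab)` (NA =
#'   missing).
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_score_correlation <- function(relab, taxon, scores) {
  if (!taxon %in% colnames(relab)) stop("unknown taxon: ", taxon)
  keep <- !is.na(scores)
  if (sum(keep) < 3) stop("need at least 3 samples with scores")
  x <- relab[keep, taxon]
  y <- scores[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Pairwise Wilcoxon tests with Holm correction
#'
#' Wilcoxon rank-sum test (see [wilcoxon_rank_sum()]) for every pair of
#' groups, with Holm step-down adjustment across the pairs.
#'
#' @param values numeric vector named by (or aligned with) sample.
#' @param metadata a [sample_metadata] data.frame; `values` are matched to
#'   `metadata$sample_id` by name when named, by position otherwise.
#' @return A data.frame with columns `group_a`, `group_b`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_wilcoxon_holm <- function(values, metadata) {
  grp <- align_groups(values, metadata)
  tab <- table(grp)
  if (any(tab < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  gs <- sort(unique(grp))
  pairs <- utils::combn(gs, 2)
  p <- apply(pairs, 2, function(pr)
    wilcoxon_rank_sum(values[grp == pr[1]], values[grp == pr[2]]))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], p_value = p,
             p_adjusted = stats::p.adjust(p, method = "holm"))
}

#' Kruskal-Wallis test across the groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared p-value on k - 1
#' degrees of freedom.
#'
#' @inheritParams pairwise_wilcoxon_holm
#' @return A list with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(values, metadata) {
  grp <- align_groups(values, metadata)
  tab <- table(grp)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (length(unique(values)) == 1)
    stop("all values identical; tie-corrected statistic undefined")
  kt <- stats::kruskal.test(values, factor(grp))
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

align_groups <- function(values, metadata) {
  if (!is.null(names(values))) {
    grp <- metadata$group[match(names(values), metadata$sample_id)]
    if (anyNA(grp))
      stop("value sample(s) missing from metadata: ",
           paste(names(values)[is.na(grp)], collapse = ", "))
  } else {
    if (length(values) != nrow(metadata))
      stop("unnamed values must match metadata rows one-to-one")
    grp <- metadata$group
  }
  grp
}

#' Group comparison of reporter-assay responses
#'
#' Group medians of the raw absorbance responses plus Holm-adjusted pairwise
#' Wilcoxon tests. Blank absorbance is reported alongside, not subtracted,
#' unless `blank_subtract = TRUE`.
#'
#' @param table data.frame with columns `sample_id`, `response`,
#'   `blank_mean`, `assay` (see [simulate_assay_responses()]).
#' @param metadata a [sample_metadata] data.frame.
#' @param blank_subtract subtract the blank mean before comparing.
#' @return A list with `medians` (data.frame `group`, `n`, `median`),
#'   `tests` (from [pairwise_wilcoxon_holm()]), `blank_mean` and `assay`.
#' @export
assay_group_comparison <- function(table, metadata, blank_subtract = FALSE) {
  if (any(table$response < 0)) stop("responses must be >= 0")
  vals <- table$response
  if (blank_subtract) vals <- vals - table$blank_mean
  names(vals) <- table$sample_id
  grp <- align_groups(vals, metadata)
  med <- do.call(rbind, lapply(sort(unique(grp)), function(g)
    data.frame(group = g, n = sum(grp == g),
               median = stats::median(vals[grp == g]))))
  list(medians = med, tests = pairwise_wilcoxon_holm(vals, metadata),
       blank_mean = mean(table$blank_mean), assay = unique(table$assay))
}
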