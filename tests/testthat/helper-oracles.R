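# Independent brute-force / textbook oracles used to validate the package's
# statistical primitives. These deliberately share no code with R/.

# Hodges-Lehmann: explicit double loop over all pairwise differences.
hl_oracle <- function(x, y) {
  diffs <- numeric(0)
  for (i in seq_along(x)) for (j in seq_along(y))
    diffs <- c(diffs, y[j] - x[i])
  sort(diffs)[ceiling(length(diffs) / 2)] / 2 +
    sort(diffs)[floor(length(diffs) / 2) + 1] / 2
}

# Benjamini-Yekutieli step-up, written from the textbook definition:
# adjusted_(i) = min_{j >= i} ( m * c(m) * p_(j) / j ), clipped to 1.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- m * cm * p[o] / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  pmin(adj, 1)[order(o)]
}

# Holm step-down: adjusted_(i) = max_{j <= i} ( (m - j + 1) * p_(j) ), clipped.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- (m - seq_len(m) + 1) * p[o]
  adj <- cummax(raw)
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
# of the pooled (tie-free) data.
wilcoxon_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(n, nx)
  w_all <- apply(sets, 2, function(s) sum(r[s]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Bray-Curtis from its definition.
bc_oracle <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# Kruskal-Wallis H with tie correction, from the rank formula.
kw_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive open-path seriation over all orderings, with its own
# permutation generator (insert n into every slot of each (n-1)-permutation)
# and Bray-Curtis distances.
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_oracle(n - 1)) for (pos in 0:(n - 1))
    out[[length(out) + 1]] <- append(sub, n, after = pos)
  out
}

seriation_oracle_length <- function(relab) {
  n <- nrow(relab)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- bc_oracle(relab[i, ], relab[j, ])
  best <- Inf
  for (p in perms_oracle(n)) {
    len <- sum(d[cbind(p[-n], p[-1])])
    if (len < best) best <- len
  }
  best
}

# A small deterministic genus-level fixture: 6 samples, 5 ASVs, 4 genera.
make_fixture_tables <- function() {
  counts <- matrix(
    c(90, 5, 3, 2, 0,
      80, 10, 5, 5, 0,
      5, 60, 20, 10, 5,
      2, 70, 15, 8, 5,
      10, 10, 40, 30, 10,
      5, 15, 35, 35, 10),
    nrow = 6, byrow = TRUE,
    dimnames = list(c("NL01", "NL02", "BV01", "BV02", "AV01", "AV02"),
                    c("ASV1", "ASV2", "ASV3", "ASV4", "ASV5")))
  taxonomy <- taxonomy_table(data.frame(
    asv_id = paste0("ASV", 1:5),
    kingdom = "Bacteria",
    phylum = c("Firmicutes", "Actinobacteria", "Bacteroidetes", "Firmicutes",
               "Bacteroidetes"),
    class = c("Bacilli", "Actinobacteria", "Bacteroidia", "Bacilli",
              "Bacteroidia"),
    order = c("Lactobacillales", "Bifidobacteriales", "Bacteroidales",
              "Lactobacillales", "Bacteroidales"),
    family = c("Lactobacillaceae", "Bifidobacteriaceae", "Prevotellaceae",
               "Streptococcaceae", "Prevotellaceae"),
    genus = c("Lactobacillus", "Gardnerella", "Prevotella", "Streptococcus",
              "Prevotella"),
    species_hint = c("L. iners", "G. vaginalis", "P. bivia", "S. agalactiae",
                     "")))
  metadata <- sample_metadata(data.frame(
    sample_id = rownames(counts),
    group = c("NL", "NL", "BV", "BV", "AV", "AV"),
    av_score = c(NA, NA, NA, NA, 6L, 8L),
    lactobacillary_grade = c("I", "I", "III", "III", "IIb", "III")))
  list(counts = asv_count_table(counts), taxonomy = taxonomy,
       metadata = metadata)
}
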