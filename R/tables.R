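#' Construct an ASV count table
#'
#' The substrate of all compositional analysis: a samples-by-taxa matrix of
#' non-negative integer read counts. Row names are sample identifiers, column
#' names are ASV (or, after aggregation, taxon) identifiers.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns, with
#'   unique non-empty dimnames. All entries must be non-negative integers and
#'   every sample must have at least one non-zero count.
#' @return An integer matrix of class `asv_count_table`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("ASV1", "ASV2")))
#' asv_count_table(m)
#' @export
asv_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix (samples x ASVs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample row names and ASV column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero) > 0)
    stop("sample(s) with all-zero counts: ", paste(zero, collapse = ", "))
  storage.mode(counts) <- "integer"
  class(counts) <- c("asv_count_table", class(matrix()))
  counts
}

#' @export
print.asv_count_table <- function(x, ...) {
  cat("ASV count table: ", nrow(x), " samples x ", ncol(x), " taxa, ",
      format(sum(as.numeric(x)), big.mark = ","), " reads total\n", sep = "")
  invisible(x)
}

ranks_order <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomy table
#'
#' One row per ASV with the assigned ranks kingdom through genus plus an
#' optional sub-genus `species_hint` (possibly multi-species, e.g.
#' `"L. crispatus/acidophilus/gallinarum"`). Missing ranks are stored as the
#' explicit marker `"unclassified"`.
#'
#' @param df data.frame with columns `asv_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species_hint`. `NA` or empty rank cells are
#'   normalised to `"unclassified"`.
#' @return A data.frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  need <- c("asv_id", ranks_order, "species_hint")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$asv_id))
    stop("duplicate ASV identifiers in taxonomy: ",
         paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "))
  for (r in ranks_order) {
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- "unclassified"
    df[[r]] <- v
  }
  sh <- as.character(df$species_hint)
  sh[is.na(sh)] <- ""
  df$species_hint <- sh
  df$asv_id <- as.character(df$asv_id)
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

valid_groups <- c("AV", "BV", "NL")
valid_grades <- c("I", "IIa", "IIb", "III")

#' Construct sample metadata
#'
#' Per-sample clinical annotation: diagnostic group (AV, aerobic vaginitis;
#' BV, bacterial vaginosis; NL, Lactobacillus-dominated reference), the
#' composite AV score (0-10, microscopy-based) and the lactobacillary grade
#' (I, IIa, IIb, III). Score and grade may be missing; group is mandatory.
#'
#' @param df data.frame with columns `sample_id`, `group` and optionally
#'   `av_score`, `lactobacillary_grade`.
#' @return A data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata requires columns sample_id and group")
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifiers in metadata")
  grp <- as.character(df$group)
  bad <- unique(grp[!grp %in% valid_groups | is.na(grp)])
  if (length(bad) > 0)
    stop("invalid group label(s): ", paste(bad, collapse = ", "),
         " (must be AV, BV or NL)")
  df$group <- grp
  if (!"av_score" %in% names(df)) df$av_score <- NA_integer_
  sc <- suppressWarnings(as.integer(df$av_score))
  if (any(!is.na(sc) & (sc < 0 | sc > 10)))
    stop("av_score must be in 0..10 or missing")
  df$av_score <- sc
  if (!"lactobacillary_grade" %in% names(df)) df$lactobacillary_grade <- NA_character_
  lg <- as.character(df$lactobacillary_grade)
  lg[lg == ""] <- NA_character_
  badg <- unique(lg[!is.na(lg) & !lg %in% valid_grades])
  if (length(badg) > 0)
    stop("invalid lactobacillary grade(s): ", paste(badg, collapse = ", "))
  df$lactobacillary_grade <- lg
  df <- df[c("sample_id", "group", "av_score", "lactobacillary_grade")]
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read the three study tables
#'
#' Reads a count table (TSV with samples as rows, or BIOM-format JSON), a
#' taxonomy TSV and a sample-metadata TSV, and cross-validates their axes:
#' every sample in the counts must have metadata and every ASV must have a
#' taxonomy row. Input order is preserved.
#'
#' @param count_path path to a tab-separated count table whose first column
#'   holds sample identifiers, or a BIOM JSON file (detected by the `.biom`
#'   extension), in which case observations (taxa) are rows and are
#'   transposed on read.
#' @param taxonomy_path tab-separated taxonomy table with columns
#'   `asv_id`, `kingdom` ... `genus`, `species_hint`.
#' @param metadata_path tab-separated metadata with columns `sample_id`,
#'   `group`, `av_score`, `lactobacillary_grade`.
#' @return A list with elements `counts` ([asv_count_table]), `taxonomy`
#'   ([taxonomy_table]) and `metadata` ([sample_metadata]).
#' @export
read_study_tables <- function(count_path, taxonomy_path, metadata_path) {
  for (p in c(count_path, taxonomy_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  counts <- if (grepl("\\.biom$", count_path)) {
    read_counts_biom(count_path)
  } else {
    read_counts_tsv(count_path)
  }
  taxonomy <- taxonomy_table(utils::read.delim(taxonomy_path, check.names = FALSE,
                                               colClasses = "character"))
  metadata <- sample_metadata(utils::read.delim(metadata_path, check.names = FALSE))

  no_meta <- setdiff(rownames(counts), metadata$sample_id)
  if (length(no_meta) > 0)
    stop("sample(s) in counts without metadata: ", paste(no_meta, collapse = ", "))
  no_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(no_tax) > 0)
    stop("ASV(s) in counts without taxonomy: ", paste(no_tax, collapse = ", "))
  list(counts = counts, taxonomy = taxonomy, metadata = metadata)
}

read_counts_tsv <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs an identifier column plus taxa")
  ids <- raw[[1]]
  m <- as.matrix(raw[-1])
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  if (anyNA(num))
    stop("non-numeric count value(s), e.g. ", m[which(is.na(num))[1]])
  if (any(abs(num - round(num)) > 1e-8))
    stop("non-integer count value(s), e.g. ", m[which(abs(num - round(num)) > 1e-8)[1]])
  rownames(num) <- ids
  asv_count_table(num)
}

read_counts_biom <- function(path) {
  b <- biomformat::read_biom(path)
  m <- methods::as(biomformat::biom_data(b), "matrix")   # observations x samples
  asv_count_table(t(m))
}

#' Write the three study tables
#'
#' Writes TSV files in the dialect [read_study_tables()] reads back
#' losslessly.
#'
#' @param counts an [asv_count_table].
#' @param taxonomy a [taxonomy_table].
#' @param metadata a [sample_metadata] data.frame.
#' @param count_path,taxonomy_path,metadata_path output file paths.
#' @return Invisibly, the three paths.
#' @export
write_study_tables <- function(counts, taxonomy, metadata,
                               count_path, taxonomy_path, metadata_path) {
  df <- data.frame(sample_id = rownames(counts), unclass(counts),
                   check.names = FALSE)
  utils::write.table(df, count_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(count_path, taxonomy_path, metadata_path))
}

#' Relative abundance
#'
#' Normalises each sample's counts to fractions summing to one. Zero counts
#' map to zero fractions; no pseudocount is applied here.
#'
#' @param counts an [asv_count_table] or a numeric samples-by-taxa matrix.
#' @return A numeric matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  m <- unclass(counts)
  tot <- rowSums(m)
  zero <- rownames(m)[tot == 0]
  if (length(zero) > 0)
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  sweep(m * 1.0, 1, tot, "/")
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums ASV counts sharing the same label at the requested rank; per-sample
#' totals are conserved exactly. ASVs whose rank is `"unclassified"` are kept
#' apart as `"unclassified_<highest known rank>"` so unknowns are never
#' silently merged.
#'
#' @param counts an [asv_count_table].
#' @param taxonomy a [taxonomy_table] covering every column of `counts`.
#' @param rank one of `"kingdom"` ... `"genus"`, or `"asv"` (identity).
#' @return An [asv_count_table] with columns relabelled to taxa at `rank`.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank) {
  if (identical(rank, "asv")) return(counts)
  if (!rank %in% ranks_order)
    stop("unknown rank: ", rank, " (expected one of ",
         paste(c(ranks_order, "asv"), collapse = ", "), ")")
  no_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(no_tax) > 0)
    stop("ASV(s) without taxonomy: ", paste(no_tax, collapse = ", "))
  tax <- taxonomy[match(colnames(counts), taxonomy$asv_id), ]
  labels <- vapply(seq_len(nrow(tax)), function(i) {
    rank_label(unlist(tax[i, ranks_order]), rank)
  }, character(1))
  keep <- unique(labels)   # first-appearance order
  agg <- sapply(keep, function(lb)
    rowSums(unclass(counts)[, labels == lb, drop = FALSE]))
  if (nrow(counts) == 1) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(counts), keep))
  asv_count_table(agg)
}

# Label an ASV at `rank`; fall back to the deepest classified rank above it.
rank_label <- function(ranks, rank) {
  i <- match(rank, ranks_order)
  if (ranks[[i]] != "unclassified") return(ranks[[i]])
  above <- ranks[seq_len(i - 1)]
  known <- above[above != "unclassified"]
  if (length(known) == 0) return("unclassified")
  paste0("unclassified_", known[length(known)])
}
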