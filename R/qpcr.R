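#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(concentration) over a serial
#' dilution of a reference of known concentration. The amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 for perfect doubling, i.e. a slope
#' of -3.32 cycles per decade). A warning is issued when the efficiency
#' falls outside \[0.8, 1.2\].
#'
#' @param standards data.frame with columns `concentration` (> 0, at least
#'   3 distinct levels) and `ct`; replicate wells are individual rows.
#' @param assay assay label carried through to results (e.g. `"total_16S"`,
#'   `"human_cyc1"`, `"Lactobacillus"`).
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `assay`, `n` and `data`.
#' @examples
#' std <- data.frame(concentration = 10^(6:4), ct = c(15, 18.3219, 21.6438))
#' fit_standard_curve(std, assay = "total_16S")
#' @export
fit_standard_curve <- function(standards, assay = "assay") {
  if (!all(c("concentration", "ct") %in% names(standards)))
    stop("standards need columns `concentration` and `ct`")
  conc <- standards$concentration
  ct <- standards$ct
  if (any(conc <= 0)) stop("standard concentrations must be positive")
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct standard concentrations")
  fit <- stats::lm(ct ~ log10(conc))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    stop("standard curve slope is non-negative; Ct must decrease with concentration")
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency < 0.8 || efficiency > 1.2)
    warning(sprintf("amplification efficiency %.2f outside [0.8, 1.2] for assay %s",
                    efficiency, assay))
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = efficiency, assay = assay,
                 n = length(conc),
                 data = data.frame(concentration = conc, ct = ct),
                 call = match.call()),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve [%s]: Ct = %.4f %+.4f * log10(conc)\n",
              x$assay, x$intercept, x$slope))
  cat(sprintf("  efficiency = %.3f, R^2 = %.5f, %d standard wells\n",
              x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Convert between Ct and concentration with a standard curve
#'
#' With `ct` given, returns the back-calculated concentration
#' `10^((ct - intercept) / slope)`; with `concentration` given, returns the
#' predicted Ct.
#'
#' @param object a `standard_curve`.
#' @param ct numeric Ct values to invert (optional).
#' @param concentration numeric concentrations to project onto Ct (optional).
#' @param ... unused.
#' @export
predict.standard_curve <- function(object, ct = NULL, concentration = NULL, ...) {
  if (!is.null(ct) && !is.null(concentration))
    stop("supply `ct` or `concentration`, not both")
  if (!is.null(ct)) return(10^((ct - object$intercept) / object$slope))
  if (!is.null(concentration))
    return(object$intercept + object$slope * log10(concentration))
  stop("supply `ct` or `concentration`")
}

#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(log10(x$data$concentration), x$data$ct,
                 xlab = "log10 concentration", ylab = "Ct",
                 main = paste("Standard curve:", x$assay), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Absolute quantification of a duplicate Ct measurement
#'
#' Ct values above `ct_cutoff` (and missing values) are treated as
#' non-detects and excluded; the remaining duplicates are averaged and
#' back-calculated through the standard curve, then multiplied by the sample
#' dilution factor. With both duplicates censored the sample is reported as
#' not detected. Duplicate discordance `|dCt| > 1` is flagged but the sample
#' is not dropped.
#'
#' @param ct_pair numeric vector of replicate Ct values (`NA` = censored;
#'   usually length 2).
#' @param curve a `standard_curve`.
#' @param dilution_factor fold-dilution applied to the sample before qPCR.
#' @param ct_cutoff non-detect cutoff in cycles.
#' @param sample_id identifier carried into the result.
#' @return A one-row data.frame with columns `sample_id`, `assay`,
#'   `concentration` (`NA` when not detected), `detected`, `n_replicates`
#'   and `discordant`.
#' @export
quantify <- function(ct_pair, curve, dilution_factor = 1,
                     ct_cutoff = 38, sample_id = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"), ct_cutoff > 0,
            dilution_factor > 0)
  ct <- as.numeric(ct_pair)
  ct[!is.na(ct) & ct > ct_cutoff] <- NA
  usable <- ct[!is.na(ct)]
  discordant <- length(usable) >= 2 &&
    (max(usable) - min(usable)) > 1.0
  if (length(usable) == 0) {
    return(data.frame(sample_id = sample_id, assay = curve$assay,
                      concentration = NA_real_, detected = FALSE,
                      n_replicates = 0L, discordant = FALSE))
  }
  conc <- 10^((mean(usable) - curve$intercept) / curve$slope) * dilution_factor
  data.frame(sample_id = sample_id, assay = curve$assay,
             concentration = conc, detected = TRUE,
             n_replicates = length(usable), discordant = discordant)
}

#' Read a qPCR plate table
#'
#' Plate TSV dialect: columns `assay`, `well_type` (`standard` or `sample`),
#' `sample_id` (samples only), `concentration` (standards only), `ct` (empty
#' = censored well) and `dilution_factor`. One row per well; duplicates are
#' consecutive rows of the same sample.
#'
#' @param path path to the TSV file.
#' @return A list of class `qpcr_plate` with `assay`, `standards`
#'   (data.frame `concentration`, `ct`) and `samples` (data.frame
#'   `sample_id`, `ct`, `dilution_factor`, one row per well).
#' @export
read_qpcr_plate <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("assay", "well_type", "sample_id", "concentration", "ct",
            "dilution_factor")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("plate file missing column(s): ",
                             paste(miss, collapse = ", "))
  assay <- unique(df$assay)
  if (length(assay) != 1) stop("plate file must hold exactly one assay")
  std <- df[df$well_type == "standard", ]
  smp <- df[df$well_type == "sample", ]
  if (length(unique(std$concentration)) < 3)
    stop("plate needs >= 3 distinct standard concentrations")
  if (any(smp$dilution_factor <= 0)) stop("dilution_factor must be > 0")
  structure(list(assay = assay,
                 standards = data.frame(concentration = std$concentration,
                                        ct = as.numeric(std$ct)),
                 samples = data.frame(sample_id = as.character(smp$sample_id),
                                      ct = suppressWarnings(as.numeric(smp$ct)),
                                      dilution_factor = smp$dilution_factor)),
            class = "qpcr_plate")
}

#' Write a qPCR plate table
#'
#' Inverse of [read_qpcr_plate()].
#'
#' @param plate a `qpcr_plate` object.
#' @param path output TSV path.
#' @export
write_qpcr_plate <- function(plate, path) {
  std <- data.frame(assay = plate$assay, well_type = "standard",
                    sample_id = "", concentration = plate$standards$concentration,
                    ct = plate$standards$ct, dilution_factor = 1)
  smp <- data.frame(assay = plate$assay, well_type = "sample",
                    sample_id = plate$samples$sample_id, concentration = "",
                    ct = plate$samples$ct,
                    dilution_factor = plate$samples$dilution_factor)
  utils::write.table(rbind(std, smp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantify every sample on a plate
#'
#' Fits the standard curve from the plate's standard wells, then quantifies
#' each sample from its replicate wells.
#'
#' @param plate a `qpcr_plate` from [read_qpcr_plate()] or the simulator.
#' @param ct_cutoff non-detect cutoff in cycles.
#' @return A data.frame of per-sample quantification results (see
#'   [quantify()]), plus the fitted curve as attribute `"curve"`.
#' @export
quantify_plate <- function(plate, ct_cutoff = 38) {
  stopifnot(inherits(plate, "qpcr_plate"))
  curve <- fit_standard_curve(plate$standards, assay = plate$assay)
  ids <- unique(plate$samples$sample_id)
  res <- do.call(rbind, lapply(ids, function(sid) {
    rows <- plate$samples[plate$samples$sample_id == sid, ]
    quantify(rows$ct, curve, dilution_factor = rows$dilution_factor[1],
             ct_cutoff = ct_cutoff, sample_id = sid)
  }))
  attr(res, "curve") <- curve
  res
}

#' Bacteria-to-human load ratio
#'
#' Ratio of a bacterial concentration to the human-cell concentration from
#' the same sample; a dimensionless estimator of bacterial load that cancels
#' sampling-volume effects. A censored bacterial measurement gives a ratio
#' of 0 flagged `below_detection`; a censored human measurement is an error
#' (there is no denominator).
#'
#' @param bacteria,human one-row quantification results from [quantify()].
#' @return A one-row data.frame with `sample_id`, `ratio` and
#'   `below_detection`.
#' @export
load_ratio <- function(bacteria, human) {
  if (!isTRUE(human$detected))
    stop("human cells not detected; load ratio undefined")
  if (!isTRUE(bacteria$detected)) {
    return(data.frame(sample_id = bacteria$sample_id, ratio = 0,
                      below_detection = TRUE))
  }
  data.frame(sample_id = bacteria$sample_id,
             ratio = bacteria$concentration / human$concentration,
             below_detection = FALSE)
}

#' Per-sample load ratios for two quantification tables
#'
#' Applies [load_ratio()] across the samples shared by a bacterial and a
#' human quantification table. Samples whose human assay is censored are
#' dropped with a message rather than an error.
#'
#' @param quant_bacteria,quant_human data.frames from [quantify_plate()].
#' @return A data.frame with `sample_id`, `ratio`, `below_detection`.
#' @export
load_ratio_table <- function(quant_bacteria, quant_human) {
  shared <- intersect(quant_bacteria$sample_id, quant_human$sample_id)
  rows <- lapply(shared, function(sid) {
    b <- quant_bacteria[quant_bacteria$sample_id == sid, ][1, ]
    h <- quant_human[quant_human$sample_id == sid, ][1, ]
    if (!isTRUE(h$detected)) return(NULL)
    load_ratio(b, h)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " sample(s) dropped: human assay not detected")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Group medians of quantification results
#'
#' Per-group medians under a chosen non-detect policy: `"detected-only"`
#' takes the median over detected samples only (the default; group medians
#' are reported alongside detection counts), `"zero-impute"` counts
#' non-detects as zero concentration.
#'
#' @param results data.frame with `sample_id`, `concentration`, `detected`
#'   (from [quantify_plate()]), or any data.frame with a `sample_id` column
#'   plus a value column named by `value_col`.
#' @param metadata a [sample_metadata] data.frame.
#' @param policy `"detected-only"` or `"zero-impute"`.
#' @param value_col name of the value column (default `"concentration"`).
#' @return A data.frame with one row per group: `group`, `n`, `n_detected`,
#'   `median`.
#' @export
group_median_summary <- function(results, metadata,
                                 policy = c("detected-only", "zero-impute"),
                                 value_col = "concentration") {
  policy <- match.arg(policy)
  grp <- metadata$group[match(results$sample_id, metadata$sample_id)]
  if (anyNA(grp))
    stop("result sample(s) missing from metadata: ",
         paste(results$sample_id[is.na(grp)], collapse = ", "))
  detected <- if ("detected" %in% names(results)) results$detected else
    rep(TRUE, nrow(results))
  vals <- results[[value_col]]
  out <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    if (!any(sel)) stop("empty group: ", g)
    v <- vals[sel]
    d <- detected[sel]
    med <- if (policy == "detected-only") {
      if (!any(d)) NA_real_ else stats::median(v[d])
    } else {
      stats::median(ifelse(d, v, 0))
    }
    data.frame(group = g, n = sum(sel), n_detected = sum(d), median = med)
  })
  do.call(rbind, out)
}
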