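#' Analysis thresholds
#'
#' The tunable constants of the whole pipeline, gathered in one validated
#' object. Defaults follow the study design they implement: a pseudocount of
#' one before log ratios, a 10% false-discovery-rate cap, the conventional
#' ANCOM W-fraction cutoff of 0.7, a qPCR non-detect cutoff of Ct 38, strict
#' dominance (>50%) and presence (>1%) cutoffs on relative abundance, the 11
#' most abundant genera for display aggregation and a 20-fold sample dilution
#' before qPCR.
#'
#' @param pseudocount count added to each entry before log ratios (> 0).
#' @param fdr_cap false-discovery-rate cap for the Benjamini-Yekutieli
#'   adjustment, in (0,1).
#' @param w_fraction_cutoff fraction of reference taxa that must be
#'   significant for a per-taxon call, in (0,1).
#' @param ct_cutoff qPCR cycle threshold above which a reaction is treated
#'   as a non-detect, in (0,45).
#' @param dominant_cutoff relative abundance above which a taxon counts as
#'   dominant in a sample (strict inequality), in (0,1).
#' @param present_cutoff relative abundance above which a taxon counts as
#'   present (strict inequality), in (0,1).
#' @param top_n_genera number of genera shown individually before pooling
#'   the remainder into a residual.
#' @param sample_dilution_factor fold-dilution of sample DNA before qPCR.
#' @return A named list of class `vag_thresholds`.
#' @export
vag_thresholds <- function(pseudocount = 1, fdr_cap = 0.10,
                           w_fraction_cutoff = 0.7, ct_cutoff = 38,
                           dominant_cutoff = 0.50, present_cutoff = 0.01,
                           top_n_genera = 11, sample_dilution_factor = 20) {
  stopifnot(pseudocount > 0,
            fdr_cap > 0, fdr_cap < 1,
            w_fraction_cutoff > 0, w_fraction_cutoff < 1,
            ct_cutoff > 0, ct_cutoff < 45,
            dominant_cutoff > 0, dominant_cutoff < 1,
            present_cutoff > 0, present_cutoff < 1,
            top_n_genera >= 1,
            sample_dilution_factor > 0)
  structure(list(pseudocount = pseudocount, fdr_cap = fdr_cap,
                 w_fraction_cutoff = w_fraction_cutoff, ct_cutoff = ct_cutoff,
                 dominant_cutoff = dominant_cutoff,
                 present_cutoff = present_cutoff,
                 top_n_genera = top_n_genera,
                 sample_dilution_factor = sample_dilution_factor),
            class = "vag_thresholds")
}

#' @export
print.vag_thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
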