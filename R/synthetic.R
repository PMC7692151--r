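# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

default_taxa <- c("Lactobacillus", "Gardnerella", "Atopobium", "Prevotella",
                  "Sneathia", "Megasphaera", "Dialister", "Streptococcus",
                  "Anaerococcus", "Veillonella", "Streptobacillus",
                  "Escherichia_Shigella")

#' Default per-group community templates
#'
#' Dirichlet concentration weights over the default genus panel: an NL
#' template heavily weighted towards *Lactobacillus* (low total
#' concentration, so a minority of samples escape dominance), a BV template
#' mixing the typical anaerobes (*Gardnerella*, *Atopobium*, *Prevotella*,
#' *Sneathia*, *Megasphaera*, *Dialister*) and a flat AV base template on
#' which the per-sample dominance mechanism acts.
#'
#' @return Named list of weight vectors for groups `AV`, `BV`, `NL`.
#' @export
default_templates <- function() {
  base <- stats::setNames(rep(0.06, length(default_taxa)), default_taxa)
  nl <- base; nl["Lactobacillus"] <- 2.5
  bv <- stats::setNames(rep(0.05, length(default_taxa)), default_taxa)
  bv[c("Gardnerella", "Atopobium", "Prevotella", "Sneathia", "Megasphaera",
       "Dialister", "Lactobacillus", "Anaerococcus", "Veillonella")] <-
    c(1.2, 0.9, 0.9, 0.6, 0.6, 0.5, 0.8, 0.2, 0.2)
  av <- stats::setNames(rep(0.15, length(default_taxa)), default_taxa)
  list(AV = av, BV = bv, NL = nl)
}

#' Default absolute-load model
#'
#' Group-wise median loads (CFU/mL for bacterial assays, cells/mL for the
#' human *cyc1* assay, per mL of lavage fluid) with a common log10-normal
#' spread of 0.6. The medians encode the cohort structure the pipeline is
#' designed to recover: highest total bacterial load in BV, lowest in AV;
#' lactobacilli highest in NL; streptococci highest in AV.
#'
#' @return A list with `medians` (assay-by-group matrix) and `log10_sd`.
#' @export
default_load_model <- function() {
  medians <- rbind(
    total_16S          = c(AV = 1.1e7, BV = 2.2e9, NL = 9.6e7),
    human_cyc1         = c(AV = 2.7e6, BV = 1.4e6, NL = 7.4e5),
    Lactobacillus      = c(AV = 2.2e5, BV = 8.2e6, NL = 1.5e7),
    Streptococcus      = c(AV = 2.7e5, BV = 3.0e2, NL = 2.54e2),
    Enterobacteriaceae = c(AV = 1.2e3, BV = 4.2e2, NL = 5.4e2),
    Staphylococcus     = c(AV = 2.3e5, BV = 3.2e5, NL = 1.5e5))
  list(medians = medians, log10_sd = 0.6)
}

taxon_lineage <- rbind(
  Lactobacillus        = c("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae"),
  Gardnerella          = c("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae"),
  Atopobium            = c("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae"),
  Prevotella           = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae"),
  Sneathia             = c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Leptotrichiaceae"),
  Megasphaera          = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
  Dialister            = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
  Streptococcus        = c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae"),
  Anaerococcus         = c("Firmicutes", "Clostridia", "Clostridiales", "Peptoniphilaceae"),
  Veillonella          = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
  Streptobacillus      = c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Leptotrichiaceae"),
  Escherichia_Shigella = c("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae"))

species_hints <- list(
  Lactobacillus = c("L. iners", "L. crispatus/acidophilus/gallinarum"),
  Prevotella = c("P. bivia", "P. timonensis"),
  Gardnerella = "G. vaginalis", Atopobium = "A. vaginae",
  Streptococcus = "S. agalactiae", Dialister = "D. propionicifaciens")

#' Configuration of a synthetic cohort
#'
#' Collects every parameter of the generator: group sizes, per-group
#' Dirichlet community templates, the AV dominance scheme, optional spiked
#' effects, the absolute-load model, the sequencing-depth model, the qPCR
#' measurement model and the AV-score model. The defaults emulate the
#' cohort structure the analysis is designed for: an NL group dominated by
#' *Lactobacillus* with a minority of non-dominated samples, a BV group
#' mixing *Gardnerella*, *Atopobium*, *Prevotella*, *Sneathia*,
#' *Megasphaera* and *Dialister*, and an AV group where per-sample dominance
#' is drawn from \{Lactobacillus, Prevotella, Streptococcus, Gardnerella,
#' none\} with weights 5:5:2:1:7. Default load medians per group (CFU/mL;
#' human assay in cells/mL) are given by `default_load_model()` with a
#' log10-normal spread of 0.6.
#'
#' @param n_per_group named integer vector of group sizes (names among
#'   `"AV"`, `"BV"`, `"NL"`, each at least 2). Default `c(AV=20, BV=20,
#'   NL=18)`.
#' @param taxa_templates named list of per-group Dirichlet concentration
#'   weights over taxa (all weights > 0).
#' @param av_dominance named weights for the per-sample AV dominance
#'   category (including `"mixed"` for no dominant taxon), or `NULL` to
#'   disable the dominance mechanism.
#' @param av_dominant_weight Dirichlet weight given to the drawn dominant
#'   taxon in an AV sample.
#' @param spike_effects `NULL` or data.frame with columns `taxon`, `group`,
#'   `log_effect`: the taxon's template weight is multiplied by
#'   `exp(log_effect)` in that group.
#' @param load_model list with `medians` (assay-by-group matrix, > 0) and
#'   `log10_sd`.
#' @param depth_model list with `mean` and `dispersion` of the negative
#'   binomial sequencing depth.
#' @param qpcr_noise_sd Gaussian sd of replicate Ct values, in cycles.
#' @param curve_model list with `slope` and `intercept` of the underlying
#'   log-linear Ct response used for all simulated assays.
#' @param standard_concentrations concentrations of the simulated standard
#'   dilution series.
#' @param asv_split `NULL` or named list splitting a taxon's weight over
#'   several ASVs (shares summing to 1).
#' @param score_model list with `base`, `slope`, `noise_sd` and `floor`
#'   controlling the AV-score generator (see [generate_cohort()]).
#' @param seed integer seed making the cohort reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(AV = 20, BV = 20, NL = 18),
                          taxa_templates = default_templates(),
                          av_dominance = c(Lactobacillus = 5, Prevotella = 5,
                                           Streptococcus = 2, Gardnerella = 1,
                                           mixed = 7),
                          av_dominant_weight = 6,
                          spike_effects = NULL,
                          load_model = default_load_model(),
                          depth_model = list(mean = 20000, dispersion = 5),
                          qpcr_noise_sd = 0.15,
                          curve_model = list(slope = -3.3219, intercept = 38),
                          standard_concentrations = 10^(2:8),
                          asv_split = list(Lactobacillus = c(0.7, 0.3),
                                           Prevotella = c(0.8, 0.2)),
                          score_model = list(base = 5.5, slope = 2.2,
                                             noise_sd = 2.0, floor = 1e-3),
                          seed = 1) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% valid_groups))
    stop("n_per_group must be named with groups among AV, BV, NL")
  if (any(n_per_group < 2)) stop("all group sizes must be >= 2")
  groups <- names(n_per_group)
  miss <- setdiff(groups, names(taxa_templates))
  if (length(miss) > 0) stop("missing template(s) for group(s): ",
                             paste(miss, collapse = ", "))
  for (g in groups) {
    w <- taxa_templates[[g]]
    if (is.null(names(w)) || any(w <= 0))
      stop("template for ", g, " must be a named vector of positive weights")
  }
  if (!is.null(spike_effects) &&
      !all(c("taxon", "group", "log_effect") %in% names(spike_effects)))
    stop("spike_effects needs columns taxon, group, log_effect")
  if (any(load_model$medians <= 0)) stop("load medians must be > 0")
  if (qpcr_noise_sd < 0) stop("qpcr_noise_sd must be >= 0")
  if (depth_model$mean <= 0 || depth_model$dispersion <= 0)
    stop("depth model parameters must be > 0")
  structure(list(n_per_group = n_per_group, taxa_templates = taxa_templates,
                 av_dominance = av_dominance,
                 av_dominant_weight = av_dominant_weight,
                 spike_effects = spike_effects, load_model = load_model,
                 depth_model = depth_model, qpcr_noise_sd = qpcr_noise_sd,
                 curve_model = curve_model,
                 standard_concentrations = standard_concentrations,
                 asv_split = asv_split, score_model = score_model,
                 seed = seed),
            class = "cohort_config")
}

#' Null-cohort configuration
#'
#' A convenience configuration in which every group shares one symmetric
#' community template (anonymous taxa `T01`, `T02`, ...), with no AV
#' dominance mechanism and no ASV splitting, so that any between-group
#' difference is pure sampling noise unless `spike_effects` are supplied.
#'
#' @param n_per_group named group sizes (default two groups of 20).
#' @param n_taxa number of taxa in the flat template.
#' @param spike_effects optional spike table, as in [cohort_config()].
#' @param seed integer seed.
#' @param ... further arguments passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(n_per_group = c(AV = 20, NL = 20), n_taxa = 12,
                               spike_effects = NULL, seed = 1, ...) {
  taxa <- sprintf("T%02d", seq_len(n_taxa))
  flat <- stats::setNames(rep(1, n_taxa), taxa)
  templates <- stats::setNames(rep(list(flat), length(n_per_group)),
                               names(n_per_group))
  cohort_config(n_per_group = n_per_group, taxa_templates = templates,
                av_dominance = NULL, spike_effects = spike_effects,
                asv_split = NULL, seed = seed, ...)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_config()]: per sample, a community
#' composition from the group's (possibly spiked) Dirichlet template, a
#' sequencing depth from a negative binomial, read counts from a
#' multinomial, absolute bacterial/human loads from group-wise log10-normal
#' distributions, and simulated qPCR plates (standard dilution series plus
#' duplicate sample reactions) through the log-linear measurement model of
#' [simulate_qpcr()]. AV samples additionally receive a composite AV score
#' generated as a clamped, rounded linear function of the sample's
#' log-relative *Prevotella* abundance plus Gaussian noise, calibrated so
#' that score and *Prevotella* abundance correlate at roughly r = 0.6 under
#' the default configuration.
#'
#' All ground truth (true compositions, true loads, spiked taxa and their
#' log effects, depths) is returned for parameter-recovery testing. The
#' generation is deterministic given `config$seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `counts`
#'   ([asv_count_table]), `taxonomy` ([taxonomy_table]), `metadata`
#'   ([sample_metadata]), `qpcr_plates` (named list of `qpcr_plate`
#'   objects, one per assay), `truth` (list with `composition`, `loads`,
#'   `depth`, `spiked`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    groups <- names(config$n_per_group)
    sample_ids <- unlist(lapply(groups, function(g)
      sprintf("%s%02d", g, seq_len(config$n_per_group[[g]]))))
    group_of <- rep(groups, config$n_per_group)
    taxa <- names(config$taxa_templates[[1]])
    n_s <- length(sample_ids)

    # ASV layout: each taxon maps to >= 1 ASVs with weight shares
    split <- config$asv_split
    asv_taxon <- unlist(lapply(taxa, function(tx)
      rep(tx, if (!is.null(split) && tx %in% names(split)) length(split[[tx]]) else 1L)))
    asv_share <- unlist(lapply(taxa, function(tx)
      if (!is.null(split) && tx %in% names(split)) split[[tx]] else 1))
    asv_ids <- sprintf("ASV%02d", seq_along(asv_taxon))

    composition <- matrix(0, n_s, length(taxa),
                          dimnames = list(sample_ids, taxa))
    counts <- matrix(0L, n_s, length(asv_ids),
                     dimnames = list(sample_ids, asv_ids))
    depth <- pmax(stats::rnbinom(n_s, mu = config$depth_model$mean,
                                 size = config$depth_model$dispersion), 50L)
    dominance <- rep(NA_character_, n_s)

    for (i in seq_len(n_s)) {
      g <- group_of[i]
      w <- config$taxa_templates[[g]]
      if (g == "AV" && !is.null(config$av_dominance)) {
        cat_i <- sample(names(config$av_dominance), 1,
                        prob = config$av_dominance)
        dominance[i] <- cat_i
        if (cat_i != "mixed") w[cat_i] <- config$av_dominant_weight
      }
      sp <- config$spike_effects
      if (!is.null(sp)) {
        for (k in which(sp$group == g)) {
          if (!sp$taxon[k] %in% names(w))
            stop("spiked taxon not in template: ", sp$taxon[k])
          w[sp$taxon[k]] <- w[sp$taxon[k]] * exp(sp$log_effect[k])
        }
      }
      alpha <- w[asv_taxon] * asv_share
      comp_asv <- rdirichlet1(alpha)
      composition[i, ] <- as.vector(tapply(comp_asv, factor(asv_taxon, levels = taxa), sum))
      counts[i, ] <- stats::rmultinom(1, depth[i], comp_asv)[, 1]
    }

    lm_ <- config$load_model
    loads <- matrix(NA_real_, n_s, nrow(lm_$medians),
                    dimnames = list(sample_ids, rownames(lm_$medians)))
    for (a in rownames(lm_$medians)) {
      loads[, a] <- 10^stats::rnorm(n_s,
                                    mean = log10(lm_$medians[a, group_of]),
                                    sd = lm_$log10_sd)
    }

    # AV score: linear in standardized log10 relative Prevotella abundance
    av_score <- rep(NA_integer_, n_s)
    sm <- config$score_model
    is_av <- group_of == "AV"
    if (any(is_av) && "Prevotella" %in% taxa) {
      z <- log10(composition[is_av, "Prevotella"] + sm$floor)
      zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      latent <- sm$base + sm$slope * zs + stats::rnorm(sum(is_av), 0, sm$noise_sd)
      av_score[is_av] <- as.integer(pmin(10, pmax(0, round(latent))))
    }
    grade <- rep(NA_character_, n_s)
    grade[group_of == "NL"] <- sample(c("I", "IIa"), sum(group_of == "NL"),
                                      replace = TRUE, prob = c(0.7, 0.3))
    grade[group_of == "BV"] <- sample(c("IIb", "III"), sum(group_of == "BV"),
                                      replace = TRUE, prob = c(0.3, 0.7))
    grade[is_av] <- sample(c("IIa", "IIb", "III"), sum(is_av),
                           replace = TRUE, prob = c(0.2, 0.4, 0.4))

    metadata <- sample_metadata(data.frame(
      sample_id = sample_ids, group = group_of, av_score = av_score,
      lactobacillary_grade = grade))

    taxonomy <- if (all(asv_taxon %in% rownames(taxon_lineage))) {
      taxonomy_table(data.frame(
        asv_id = asv_ids, kingdom = "Bacteria",
        phylum = taxon_lineage[asv_taxon, 1], class = taxon_lineage[asv_taxon, 2],
        order = taxon_lineage[asv_taxon, 3], family = taxon_lineage[asv_taxon, 4],
        genus = asv_taxon,
        species_hint = vapply(seq_along(asv_ids), function(j) {
          hints <- species_hints[[asv_taxon[j]]]
          k <- sum(asv_taxon[seq_len(j)] == asv_taxon[j])
          if (is.null(hints) || k > length(hints)) "" else hints[k]
        }, character(1)),
        row.names = NULL))
    } else {
      # anonymous taxa (null configurations): minimal placeholder lineage
      taxonomy_table(data.frame(
        asv_id = asv_ids, kingdom = "Bacteria", phylum = "unclassified",
        class = "unclassified", order = "unclassified",
        family = "unclassified", genus = asv_taxon, species_hint = ""))
    }

    curve <- list(slope = config$curve_model$slope,
                  intercept = config$curve_model$intercept)
    thr <- vag_thresholds()
    plates <- lapply(rownames(lm_$medians), function(a) {
      concs <- rep(config$standard_concentrations, each = 2)
      std_ct <- curve$intercept + curve$slope * log10(concs) +
        stats::rnorm(length(concs), 0, config$qpcr_noise_sd)
      smp <- do.call(rbind, lapply(seq_len(n_s), function(i) {
        ct <- simulate_qpcr(loads[i, a], curve,
                            dilution_factor = thr$sample_dilution_factor,
                            noise_sd = config$qpcr_noise_sd,
                            ct_cutoff = thr$ct_cutoff)
        data.frame(sample_id = sample_ids[i], ct = ct,
                   dilution_factor = thr$sample_dilution_factor)
      }))
      structure(list(assay = a,
                     standards = data.frame(concentration = concs, ct = std_ct),
                     samples = smp),
                class = "qpcr_plate")
    })
    names(plates) <- rownames(lm_$medians)

    structure(list(counts = asv_count_table(counts), taxonomy = taxonomy,
                   metadata = metadata, qpcr_plates = plates,
                   truth = list(composition = composition, loads = loads,
                                depth = depth, dominance = dominance,
                                spiked = config$spike_effects),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$counts), " samples (",
      paste(sprintf("%s=%d", names(x$config$n_per_group),
                    x$config$n_per_group), collapse = ", "),
      "), ", ncol(x$counts), " ASVs, ", length(x$qpcr_plates),
      " qPCR assays\n", sep = "")
  invisible(x)
}

#' Simulate a duplicate qPCR measurement
#'
#' Log-linear measurement model: each replicate Ct equals
#' `intercept + slope * log10(true_conc / dilution_factor)` plus independent
#' Gaussian noise. Replicates falling above the non-detect cutoff — and all
#' replicates when `true_conc` is zero — are censored (`NA`).
#'
#' @param true_conc true concentration in the undiluted sample (>= 0).
#' @param curve a `standard_curve` or any list with `slope` and `intercept`.
#' @param dilution_factor fold-dilution before the reaction.
#' @param noise_sd Gaussian Ct noise, in cycles (>= 0).
#' @param ct_cutoff censoring cutoff in cycles.
#' @param n_replicates number of replicate reactions (default duplicate).
#' @param seed optional seed; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return Numeric vector of replicate Ct values with `NA` for censored
#'   reactions.
#' @export
simulate_qpcr <- function(true_conc, curve, dilution_factor = 20,
                          noise_sd = 0.15, ct_cutoff = 38,
                          n_replicates = 2, seed = NULL) {
  stopifnot(true_conc >= 0, dilution_factor > 0, noise_sd >= 0)
  with_seed(seed, {
    if (true_conc == 0) return(rep(NA_real_, n_replicates))
    ct <- curve$intercept + curve$slope * log10(true_conc / dilution_factor) +
      stats::rnorm(n_replicates, 0, noise_sd)
    ct[ct > ct_cutoff] <- NA
    ct
  })
}

#' Simulate reporter-assay responses
#'
#' Draws per-sample absorbance responses (405 nm, dimensionless) from
#' group-wise log10-normal distributions, emulating an NF-kB reporter-cell
#' readout of TLR stimulation. Default group medians are 1.99 (NL), 1.50
#' (BV) and 1.13 (AV).
#'
#' @param metadata a [sample_metadata] data.frame.
#' @param medians named group medians of the absorbance response.
#' @param log10_sd log10-scale spread of the response.
#' @param blank_mean mean blank absorbance, reported alongside.
#' @param assay assay label.
#' @param seed optional seed (see [simulate_qpcr()]).
#' @return A data.frame with columns `sample_id`, `response`, `blank_mean`,
#'   `assay`.
#' @export
simulate_assay_responses <- function(metadata,
                                     medians = c(NL = 1.99, BV = 1.50, AV = 1.13),
                                     log10_sd = 0.12, blank_mean = 0.155,
                                     assay = "TLR2/6", seed = NULL) {
  stopifnot(all(metadata$group %in% names(medians)))
  with_seed(seed, {
    resp <- 10^stats::rnorm(nrow(metadata),
                            mean = log10(medians[metadata$group]),
                            sd = log10_sd)
    data.frame(sample_id = metadata$sample_id, response = resp,
               blank_mean = blank_mean, assay = assay)
  })
}
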