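## Synthetic low-biomass amplicon study generator.
##
## The generator emulates a field study of ~90 individual gut specimens in
## 3 replicates (one extraction blank each), 3 treatments and 2 timepoints.
## Each specimen carries a true community drawn around its replicate's base
## composition, but its library is a mixture: a biomass-dependent weight
## w = B / (B + c0) of true-community reads and (1 - w) of a shared reagent
## contaminant pool, so contamination dominates exactly when biomass is
## low. Negative controls read from the pool, with a small fraction eps of
## cross-contamination leaking in from the replicate's specimens. Ground
## truth (origin labels, biomasses, mixture weights, planted effects) is
## returned for validation.

#' Simulation configuration for the synthetic study
#'
#' Defaults reproduce the emulated design: 3 replicates x 3 treatments x
#' 2 timepoints x 5 specimens = 90 specimens plus one extraction control
#' per replicate. Six designated "major" contaminant taxa dominate the
#' reagent pool so that, in expectation, they satisfy both major-contaminant
#' criteria; the remaining pool taxa are rare enough in specimens to
#' violate the prevalence criterion.
#'
#' @param n_replicates Number of replicates (each with its own base
#'   community and blank).
#' @param specimens_per_cell Specimens per replicate x treatment x
#'   timepoint cell.
#' @param n_controls_per_replicate Extraction negative controls per
#'   replicate.
#' @param treatments,timepoints Treatment and timepoint levels.
#' @param s_true Number of true-community taxa.
#' @param s_cont Number of contaminant-pool taxa.
#' @param n_major_contaminants Designated dominant pool taxa expected to be
#'   flagged by the major-contaminant rule.
#' @param major_pool_mass Total pool mass held by the designated major
#'   contaminants (the rest is spread over the minor pool taxa).
#' @param base_concentration Dirichlet concentration linking replicate base
#'   compositions to the global community profile.
#' @param individual_concentration Dirichlet concentration linking each
#'   specimen's composition to its replicate base.
#' @param biomass_meanlog,biomass_sdlog Log-normal specimen biomass
#'   parameters (arbitrary units relative to `c0`).
#' @param c0 Contaminant mass constant; the contaminant read share of a
#'   specimen with biomass B is `c0 / (B + c0)` in expectation.
#' @param cross_contamination_rate Fraction `eps` of control reads drawn
#'   from the replicate's mean specimen composition instead of the pool.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters.
#' @param planted_effects Data frame (`genus`, `treatment`, `timepoint`,
#'   `delta_log2`): the genus' proportion is multiplied by
#'   `2^-delta_log2` (before renormalization) in matching cells.
#' @param infection_effects Data frame (`genus`, `enrich_log2`): the genus'
#'   proportion is multiplied by `2^enrich_log2` in infected replicates.
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_replicates = 3,
                              specimens_per_cell = 5,
                              n_controls_per_replicate = 1,
                              treatments = c("control", "amox", "amox_clav"),
                              timepoints = c(24, 72),
                              s_true = 60,
                              s_cont = 40,
                              n_major_contaminants = 6,
                              major_pool_mass = 0.992,
                              base_concentration = 100,
                              individual_concentration = 50,
                              biomass_meanlog = log(4),
                              biomass_sdlog = 0.8,
                              c0 = 1,
                              cross_contamination_rate = 0.02,
                              depth_meanlog = log(2e4),
                              depth_sdlog = 0.3,
                              planted_effects = data.frame(
                                genus = "Elizabethkingia",
                                treatment = c("amox", "amox_clav"),
                                timepoint = 24,
                                delta_log2 = 2),
                              infection_effects = data.frame(
                                genus = "Asaia",
                                enrich_log2 = 1),
                              seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_replicates >= 1, specimens_per_cell >= 1,
            n_controls_per_replicate >= 0,
            s_true >= 1, s_cont >= 0,
            n_major_contaminants <= s_cont,
            major_pool_mass >= 0, major_pool_mass <= 1,
            c0 >= 0,
            cross_contamination_rate >= 0, cross_contamination_rate < 1)
  structure(as.list(environment()), class = "simulation_config")
}

## Community genus scaffold: four named dominant genera plus generic ones.
COMMUNITY_GENERA <- c("Elizabethkingia", "Wigglesworthia", "Asaia",
                      "Serratia", "Comamonas", "Aeromonas",
                      "Chryseobacterium", "Cedecea", "Enterobacter",
                      "Pseudomonas", "Acinetobacter", "Heliimonas")
CONTAMINANT_GENERA <- c("Ralstonia", "Bradyrhizobium", "Sphingomonas",
                        "Staphylococcus", "Rhizobium", "Cutibacterium",
                        "Methylobacterium", "Burkholderia")

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Generate a synthetic study with ground truth
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (feature table), `metadata`, `taxonomy`, and
#'   `truth` — itself a list with `taxon_origin` (per-taxon data frame,
#'   incl. `expected_major` for the designated pool dominants), `samples`
#'   (per-sample biomass, mixture weight, depth), `true_composition`
#'   (taxa x specimens expected mixture proportions), `pool` (contaminant
#'   pool proportions), and the planted effect tables.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)

  taxa_true <- sprintf("ASV_true_%03d", seq_len(cf$s_true))
  taxa_cont <- if (cf$s_cont > 0) sprintf("ASV_cont_%03d", seq_len(cf$s_cont))
               else character(0)
  taxa <- c(taxa_true, taxa_cont)
  s_all <- length(taxa)

  ## genus assignment: round-robin over the genus scaffolds
  genus_true <- COMMUNITY_GENERA[(seq_len(cf$s_true) - 1) %%
                                   length(COMMUNITY_GENERA) + 1]
  genus_cont <- if (cf$s_cont > 0) {
    CONTAMINANT_GENERA[(seq_len(cf$s_cont) - 1) %%
                         length(CONTAMINANT_GENERA) + 1]
  } else character(0)
  genus <- c(genus_true, genus_cont)
  taxonomy <- data.frame(
    taxon_id = taxa,
    lineage = paste("Bacteria", "SimPhylum", "SimClass", "SimOrder",
                    "SimFamily", genus, sep = ";"),
    stringsAsFactors = FALSE)

  ## planted-effect feasibility
  for (g in unique(c(cf$planted_effects$genus, cf$infection_effects$genus))) {
    if (!g %in% genus_true) {
      stop("planted effect on genus absent from the community pool: ", g)
    }
  }

  ## global community profile: geometric series gives a few dominant genera
  base_global <- 0.75^(seq_len(cf$s_true) - 1)
  base_global <- base_global / sum(base_global)

  ## contaminant pool: majors share major_pool_mass, minors the remainder
  n_major <- cf$n_major_contaminants
  pool <- numeric(cf$s_cont)
  if (cf$s_cont > 0) {
    if (n_major > 0) pool[seq_len(n_major)] <- cf$major_pool_mass / n_major
    n_minor <- cf$s_cont - n_major
    if (n_minor > 0) {
      pool[(n_major + 1):cf$s_cont] <- (1 - cf$major_pool_mass) / n_minor
    }
    pool <- pool / sum(pool)
  }
  pool_full <- c(numeric(cf$s_true), pool)

  replicates <- c("AP4", "BP3", "P10")[seq_len(min(cf$n_replicates, 3))]
  if (cf$n_replicates > 3) {
    replicates <- c(replicates,
                    sprintf("R%02d", seq(4, cf$n_replicates)))
  }
  infection_by_rep <- stats::setNames(
    rep(c("uninfected", "infected"), length.out = length(replicates)),
    replicates)
  species_pool <- c("gambiae", "coluzzii", "arabiensis", "ND")

  rep_base <- lapply(replicates, function(r) {
    rdirichlet(cf$base_concentration * cf$s_true * base_global /
                 sum(base_global))
  })
  names(rep_base) <- replicates

  design <- expand.grid(replicate = replicates,
                        treatment = cf$treatments,
                        timepoint_h = cf$timepoints,
                        unit = seq_len(cf$specimens_per_cell),
                        stringsAsFactors = FALSE)
  design <- design[order(design$replicate, design$treatment,
                         design$timepoint_h, design$unit), ]
  n_spec <- nrow(design)

  sample_id <- sprintf("S%03d", seq_len(n_spec))
  metadata <- data.frame(
    sample_id = sample_id,
    role = "specimen",
    replicate = design$replicate,
    treatment = design$treatment,
    timepoint_h = design$timepoint_h,
    infection = infection_by_rep[design$replicate],
    species = sample(species_pool, n_spec, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
    stringsAsFactors = FALSE)

  biomass <- stats::rlnorm(n_spec, cf$biomass_meanlog, cf$biomass_sdlog)
  w <- if (cf$c0 == 0) rep(1, n_spec) else biomass / (biomass + cf$c0)
  depth <- pmax(round(stats::rlnorm(n_spec, cf$depth_meanlog,
                                    cf$depth_sdlog)), 100)

  counts <- matrix(0L, nrow = s_all, ncol = n_spec,
                   dimnames = list(taxa, sample_id))
  true_comp <- matrix(0, nrow = s_all, ncol = n_spec,
                      dimnames = list(taxa, sample_id))
  for (j in seq_len(n_spec)) {
    comp <- rdirichlet(cf$individual_concentration * cf$s_true *
                         rep_base[[design$replicate[j]]])
    ## planted treatment x timepoint depletions
    pe <- cf$planted_effects
    if (nrow(pe) > 0) {
      for (r in seq_len(nrow(pe))) {
        if (design$treatment[j] == pe$treatment[r] &&
            design$timepoint_h[j] == pe$timepoint[r]) {
          hit <- genus_true == pe$genus[r]
          comp[hit] <- comp[hit] * 2^(-pe$delta_log2[r])
        }
      }
    }
    ## infection-associated enrichments
    ie <- cf$infection_effects
    if (nrow(ie) > 0 &&
        infection_by_rep[design$replicate[j]] == "infected") {
      for (r in seq_len(nrow(ie))) {
        hit <- genus_true == ie$genus[r]
        comp[hit] <- comp[hit] * 2^(ie$enrich_log2[r])
      }
    }
    comp <- comp / sum(comp)
    mix <- w[j] * c(comp, numeric(cf$s_cont)) + (1 - w[j]) * pool_full
    true_comp[, j] <- mix
    counts[, j] <- stats::rmultinom(1, depth[j], mix)[, 1]
  }

  ## extraction negative controls
  ctrl_meta <- NULL
  ctrl_counts <- NULL
  ctrl_depth <- integer(0)
  if (cf$n_controls_per_replicate > 0) {
    ctrl_rows <- expand.grid(replicate = replicates,
                             unit = seq_len(cf$n_controls_per_replicate),
                             stringsAsFactors = FALSE)
    ctrl_id <- sprintf("NC_%s_%d", ctrl_rows$replicate, ctrl_rows$unit)
    ctrl_depth <- pmax(round(stats::rlnorm(nrow(ctrl_rows),
                                           cf$depth_meanlog,
                                           cf$depth_sdlog)), 100)
    ctrl_counts <- matrix(0L, nrow = s_all, ncol = nrow(ctrl_rows),
                          dimnames = list(taxa, ctrl_id))
    for (j in seq_len(nrow(ctrl_rows))) {
      reps <- metadata$replicate == ctrl_rows$replicate[j]
      mean_spec <- rowMeans(true_comp[, reps, drop = FALSE])
      mix <- (1 - cf$cross_contamination_rate) * pool_full +
        cf$cross_contamination_rate * mean_spec
      if (sum(mix) == 0) next                     # no contamination sources
      mix <- mix / sum(mix)
      ctrl_counts[, j] <- stats::rmultinom(1, ctrl_depth[j], mix)[, 1]
    }
    ctrl_meta <- data.frame(
      sample_id = ctrl_id,
      role = "negative_control",
      replicate = ctrl_rows$replicate,
      treatment = "control",
      timepoint_h = cf$timepoints[1],
      infection = "uninfected",
      species = "ND",
      stringsAsFactors = FALSE)
  }

  counts_all <- cbind(counts, ctrl_counts)
  metadata_all <- rbind(metadata, ctrl_meta)

  truth <- list(
    taxon_origin = data.frame(
      taxon_id = taxa,
      genus = genus,
      origin = rep(c("community", "contaminant"),
                   c(cf$s_true, cf$s_cont)),
      expected_major = c(rep(FALSE, cf$s_true),
                         seq_len(cf$s_cont) <= n_major &
                           rep(TRUE, cf$s_cont)),
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = c(sample_id, if (!is.null(ctrl_meta)) ctrl_meta$sample_id),
      biomass = c(biomass, rep(0, length(ctrl_depth))),
      mixture_weight = c(w, rep(0, length(ctrl_depth))),
      depth = c(depth, ctrl_depth),
      stringsAsFactors = FALSE),
    true_composition = true_comp,
    pool = stats::setNames(pool_full, taxa),
    planted_effects = cf$planted_effects,
    infection_effects = cf$infection_effects)

  list(counts = validate_feature_table(counts_all),
       metadata = validate_sample_metadata(metadata_all, counts_all),
       taxonomy = taxonomy,
       truth = truth)
}

#' Generate survival records with exponential hazards
#'
#' Event times are exponential per group, rounded up to whole days to mimic
#' daily monitoring, with administrative censoring at `horizon`.
#'
#' @param hazards Named numeric vector of per-day hazard rates, one per
#'   group; all positive.
#' @param n_per_group Animals per group (recycled over groups).
#' @param horizon Censoring horizon in days.
#' @param seed Integer seed.
#' @return Data frame with `time`, `event` (`"death"`/`"censored"`),
#'   `group`.
#' @export
generate_survival <- function(hazards, n_per_group, horizon = 30,
                              seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (is.null(names(hazards))) {
    names(hazards) <- paste0("group", seq_along(hazards))
  }
  set.seed(seed)
  n_per_group <- rep_len(n_per_group, length(hazards))
  out <- do.call(rbind, lapply(seq_along(hazards), function(g) {
    raw <- ceiling(stats::rexp(n_per_group[g], rate = hazards[g]))
    died <- raw <= horizon
    data.frame(time = pmin(raw, horizon),
               event = ifelse(died, "death", "censored"),
               group = names(hazards)[g],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (all(out$event == "censored")) {
    warning("all observations censored before the horizon")
  }
  out
}
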