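# End-to-end conveniences tying the modules together, used by the CLI,
# the acceptance script and the longer tests.

#' Build the default synthetic discovery world
#'
#' The stated world of the parameter-recovery experiment: 10,000
#' regions with constant hypermethylated background (m_bg = 0.85),
#' 50 planted markers per (class, direction) cell (200 total) with
#' alternative component m_alt = 0.1 carried by phi = 0.3 of tumor
#' fragments; 30 tissue samples per subtype at purity 0.6 and depth 50;
#' 30 noncancer plasma samples at depth 20.
#'
#' @param seed integer seed.
#' @param n_regions default 10000.
#' @param n_per_cell planted markers per cell (default 50).
#' @param n_tissue tissue samples per subtype (default 30).
#' @param n_background noncancer plasma samples (default 30).
#' @param tissue_depth,plasma_depth mean fragments per region (50 / 20).
#' @param purity tissue purity (default 0.6).
#' @param m_bg,m_alt,phi marker geometry (defaults 0.85, 0.1, 0.3).
#' @return list `profiles`, `truth`, `luad`, `lusc`, `background`,
#'   `config_tissue`, `config_plasma`.
#' @export
synthetic_discovery_world <- function(seed, n_regions = 10000L,
                                      n_per_cell = 50L, n_tissue = 30L,
                                      n_background = 30L, tissue_depth = 50,
                                      plasma_depth = 20, purity = 0.6,
                                      m_bg = 0.85, m_alt = 0.1, phi = 0.3) {
  profiles <- generate_region_catalog(n_regions, seed = seed, m_bg = m_bg)
  planted <- plant_markers(profiles, n_per_cell, m_alt = m_alt, phi = phi,
                           seed = seed)
  cfg_t <- cohort_config(n_per_class = n_tissue, depth = tissue_depth,
                         purity = purity, seed = derive_seed(seed, "tissue"))
  cfg_p <- cohort_config(n_per_class = n_background, depth = plasma_depth,
                         seed = derive_seed(seed, "plasma"))
  list(profiles = planted$profiles, truth = planted$truth,
       luad = simulate_cohort(planted$profiles, cfg_t, "LUAD", "tissue"),
       lusc = simulate_cohort(planted$profiles, cfg_t, "LUSC", "tissue"),
       background = simulate_cohort(planted$profiles, cfg_p, "noncancer",
                                    "plasma", prefix = "NC"),
       config_tissue = cfg_t, config_plasma = cfg_p)
}

#' Precision and recall of discovered markers against a truth ledger
#'
#' A discovered marker is a true positive when its (region, class,
#' direction) triple appears in the ledger.
#'
#' @param markers marker data.frame from [discover_markers()].
#' @param truth ledger data.frame `region_id`, `target_class`,
#'   `direction` from [plant_markers()].
#' @return list `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
marker_recovery <- function(markers, truth) {
  key <- function(d) paste(d$region_id, d$target_class, d$direction)
  tp <- sum(key(markers) %in% key(truth))
  list(precision = if (nrow(markers)) tp / nrow(markers) else NA_real_,
       recall = tp / nrow(truth),
       tp = tp, fp = nrow(markers) - tp, fn = nrow(truth) - tp)
}

#' Simulate plasma cohorts and evaluate cfDNA subtype classification
#'
#' Simulates LUAD and LUSC plasma cohorts at tumor fraction `theta` over
#' the marker regions, builds merged-marker features and runs pooled
#' LOOCV with the L2 logistic model.
#'
#' @param world a [synthetic_discovery_world()].
#' @param merged a `merged_markers` object built from the world's
#'   discovery output.
#' @param theta plasma tumor fraction.
#' @param n_per_class plasma samples per subtype (default 30).
#' @param depth mean fragments per region (default 20).
#' @param seed integer seed.
#' @return a `roc_result` from [cross_validate()].
#' @export
evaluate_plasma_classification <- function(world, merged, theta,
                                           n_per_class = 30L, depth = 20,
                                           seed) {
  markers <- attr(merged, "markers")
  sub <- world$profiles[world$profiles$region_id %in% markers$region_id, ,
                        drop = FALSE]
  cfg <- cohort_config(n_per_class = n_per_class, depth = depth,
                       tumor_fraction = theta,
                       seed = derive_seed(seed, paste0("theta", theta)))
  total_regions <- nrow(world$profiles)
  luad <- simulate_cohort(sub, cfg, "LUAD", "plasma", prefix = "pLUAD",
                          total_regions = total_regions)
  lusc <- simulate_cohort(sub, cfg, "LUSC", "plasma", prefix = "pLUSC",
                          total_regions = total_regions)
  cohort <- c(luad, lusc)
  x <- build_feature_matrix(cohort, merged)
  cross_validate(x, cohort_labels(cohort), scheme = "loocv")
}
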