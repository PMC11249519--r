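# Seeded synthetic fragment-level methylomes.
#
# The generator states a world with the structure the analysis assumes:
#  - regions whose background methylation is stably high or low, with
#    per-fragment alpha drawn from a beta-binomial (CpGs on one molecule
#    are correlated, which is what makes alpha bimodal across fragments);
#  - planted subtype-specific markers: on a carrier fraction phi of tumor
#    fragments the methylation mean shifts to m_alt (hypo markers sit on
#    hypermethylated background; hyper markers are the mirror image);
#  - tissue samples as purity-pi mixtures of tumor and contaminating
#    normal cells; plasma as tumor-fraction-theta mixtures over a
#    noncancer background; noncancer plasma is pure background.
#
# All randomness flows from a single integer seed; per-sample substreams
# are derived deterministically so cohorts are reproducible piecewise.

#' Default cohort configuration for the synthetic world
#'
#' @param n_per_class samples per class (default 30).
#' @param depth mean fragments per region per sample (default 50 for
#'   tissue; 20 for plasma roughly matches a median ~22x fragment
#'   coverage over ~117 bp regions).
#' @param cpg_range integer min/max CpGs per fragment (default `c(5, 14)`,
#'   the CpG-dense regime MspI enrichment selects for).
#' @param purity tissue tumor purity pi in `[0,1]` (default 0.6).
#' @param tumor_fraction plasma tumor fraction theta in `[0,1]`.
#' @param seed mandatory integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = 30L, depth = 50, cpg_range = c(5L, 14L),
                          purity = 0.6, tumor_fraction = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_per_class >= 1L, depth > 0, length(cpg_range) == 2L,
            cpg_range[1L] >= 1L, cpg_range[2L] >= cpg_range[1L],
            purity >= 0, purity <= 1, tumor_fraction >= 0, tumor_fraction <= 1)
  structure(list(n_per_class = as.integer(n_per_class), depth = depth,
                 cpg_range = as.integer(cpg_range), purity = purity,
                 tumor_fraction = tumor_fraction, seed = as.integer(seed)),
            class = "cohort_config")
}

# derive a reproducible 31-bit child seed from a base seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_along(utf8ToInt(as.character(tag))) + 13))
  as.integer((as.double(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

#' Generate a synthetic region catalog with methylation profiles
#'
#' Region lengths are offset-exponential (20 + Exp(mean 115), resampled
#' above 349) so the catalog mean is ~117 bp. Background methylation
#' means are drawn from a mixture favouring the extremes (most of the
#' genome is stably hypo- or hypermethylated) unless a constant `m_bg`
#' is supplied. Per-region beta-binomial concentration is `kappa`.
#'
#' @param n_regions number of regions (>= 1).
#' @param seed integer seed.
#' @param m_bg `NULL` for the bimodal background mixture, or a constant
#'   background methylation mean in `[0,1]`.
#' @param kappa beta-binomial concentration (default 30).
#' @return a [region_catalog()] with extra profile columns `m_bg`,
#'   `kappa`, `planted`, `direction`, `target_class`, `m_alt`, `phi`.
#' @export
generate_region_catalog <- function(n_regions, seed, m_bg = NULL, kappa = 30) {
  if (n_regions < 1L) stop("n_regions must be >= 1")
  set.seed(derive_seed(seed, "regions"))
  len <- 20 + stats::rexp(n_regions, rate = 1 / 115)
  while (any(len > 349)) {
    i <- len > 349
    len[i] <- 20 + stats::rexp(sum(i), rate = 1 / 115)
  }
  len <- as.integer(round(len))
  gap <- as.integer(round(stats::rexp(n_regions, rate = 1 / 500)))
  start <- cumsum(c(0L, (len + gap)[-n_regions]))
  cat <- region_catalog(chrom = "chrS", start = start, end = start + len,
                        region_id = sprintf("r%05d", seq_len(n_regions)))
  if (is.null(m_bg)) {
    hi <- stats::runif(n_regions) < 0.6  # CpG-poor background skews methylated
    m <- ifelse(hi, stats::rbeta(n_regions, 16, 2), stats::rbeta(n_regions, 2, 16))
    cat$m_bg <- pmin(pmax(m, 0.02), 0.98)
  } else {
    stopifnot(m_bg >= 0, m_bg <= 1)
    cat$m_bg <- rep(as.double(m_bg), n_regions)
  }
  cat$kappa <- rep(as.double(kappa), n_regions)
  cat$planted <- FALSE
  cat$direction <- NA_character_
  cat$target_class <- NA_character_
  cat$m_alt <- NA_real_
  cat$phi <- NA_real_
  class(cat) <- c("region_catalog", "data.frame")
  cat
}

#' Plant subtype-specific markers into a region catalog
#'
#' Marks `n_per_class_per_direction` regions for each of the four cells
#' LUAD-hypo, LUAD-hyper, LUSC-hypo, LUSC-hyper. Hypo markers keep the
#' region's (hypermethylated) background and add an alternative tumor
#' component at mean `m_alt` carried by a fraction `phi` of tumor
#' fragments; hyper markers are the mirror image (background flipped to
#' `1 - m_bg`, alternative at `1 - m_alt`), since hypermethylation is
#' only observable on a hypomethylated background.
#'
#' @param profiles catalog from [generate_region_catalog()].
#' @param n_per_class_per_direction markers per (class, direction) cell.
#' @param m_alt alternative-component methylation mean for hypo markers
#'   (default 0.1); hyper markers use `1 - m_alt`.
#' @param phi carrier fraction of the alternative component within tumor
#'   fragments, in `(0, 1]` (default 0.3).
#' @param seed integer seed.
#' @return list `profiles` (updated catalog) and `truth` (data.frame
#'   `region_id`, `target_class`, `direction`).
#' @export
plant_markers <- function(profiles, n_per_class_per_direction, m_alt = 0.1,
                          phi = 0.3, seed) {
  if (!(phi > 0 && phi <= 1)) stop("phi must lie in (0, 1]")
  n_cell <- as.integer(n_per_class_per_direction)
  cells <- expand.grid(target_class = c("LUAD", "LUSC"),
                       direction = c("hypo", "hyper"),
                       stringsAsFactors = FALSE)
  need <- n_cell * nrow(cells)
  free <- which(!profiles$planted)
  if (length(free) < need) stop("not enough unplanted regions")
  set.seed(derive_seed(seed, "plant"))
  picked <- sample(free, need)
  idx <- split(picked, rep(seq_len(nrow(cells)), each = n_cell))
  for (j in seq_len(nrow(cells))) {
    i <- idx[[j]]
    profiles$planted[i] <- TRUE
    profiles$target_class[i] <- cells$target_class[j]
    profiles$direction[i] <- cells$direction[j]
    if (cells$direction[j] == "hypo") {
      profiles$m_alt[i] <- m_alt
    } else {
      profiles$m_bg[i] <- 1 - profiles$m_bg[i]
      profiles$m_alt[i] <- 1 - m_alt
    }
    profiles$phi[i] <- phi
  }
  truth <- data.frame(region_id = profiles$region_id[picked],
                      target_class = profiles$target_class[picked],
                      direction = profiles$direction[picked],
                      stringsAsFactors = FALSE)
  list(profiles = profiles, truth = truth)
}

# beta-binomial fragment methylation: p ~ Beta(m*kappa, (1-m)*kappa),
# n_methylated ~ Binom(n_cpgs, p)
rbetabinom <- function(n_cpgs, m, kappa) {
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  p <- stats::rbeta(length(n_cpgs), m * kappa, (1 - m) * kappa)
  stats::rbinom(length(n_cpgs), n_cpgs, p)
}

#' Simulate one sample's fragments
#'
#' Fragment counts per region are Poisson(`depth`). Each fragment is of
#' tumor origin with probability `purity` (tissue) or `tumor_fraction`
#' (plasma, 0 for noncancer); tumor fragments on a region planted for the
#' sample's own class come from the alternative component with
#' probability `phi`. `total_fragments` is set to a simulated genome-wide
#' total exceeding the stored on-region count.
#'
#' @param profiles planted catalog from [plant_markers()] (or a subset of
#'   its rows; see `total_regions`).
#' @param config a [cohort_config()]; `config$seed` is combined with
#'   `sample_id` so each sample has its own stream.
#' @param label `"LUAD"`, `"LUSC"` or `"noncancer"`.
#' @param material `"tissue"` or `"plasma"`.
#' @param sample_id sample identifier.
#' @param total_regions genome-wide region count used to scale
#'   `total_fragments` when `profiles` is a subset (default
#'   `nrow(profiles)`).
#' @return a [sample_fragments()].
#' @export
simulate_sample <- function(profiles, config, label, material, sample_id,
                            total_regions = nrow(profiles)) {
  label <- match.arg(label, SAMPLE_LABELS)
  material <- match.arg(material, SAMPLE_MATERIALS)
  if (label == "noncancer" && material != "plasma") {
    stop("noncancer samples are plasma-only")
  }
  tumor_p <- if (label == "noncancer") 0
             else if (material == "tissue") config$purity
             else config$tumor_fraction
  set.seed(derive_seed(config$seed, paste0("sample:", sample_id)))
  counts <- stats::rpois(nrow(profiles), config$depth)
  tot <- sum(counts)
  ridx <- rep(seq_len(nrow(profiles)), counts)
  n_cpgs <- sample(seq(config$cpg_range[1L], config$cpg_range[2L]),
                   tot, replace = TRUE)
  is_tumor <- stats::runif(tot) < tumor_p
  own_marker <- profiles$planted[ridx] &
    !is.na(profiles$target_class[ridx]) &
    profiles$target_class[ridx] == label
  is_alt <- is_tumor & own_marker &
    (stats::runif(tot) < ifelse(is.na(profiles$phi[ridx]), 0, profiles$phi[ridx]))
  m <- ifelse(is_alt, profiles$m_alt[ridx], profiles$m_bg[ridx])
  n_meth <- rbetabinom(n_cpgs, m, profiles$kappa[ridx])
  # genome-wide denominator: on-region depth over the full catalog plus
  # ~25% off-region fragments
  total_fragments <- max(tot, stats::rpois(1L, config$depth * total_regions * 1.25))
  sample_fragments(
    sample_id, label, material, total_fragments,
    data.frame(region_id = profiles$region_id[ridx], n_cpgs = n_cpgs,
               n_methylated = n_meth, stringsAsFactors = FALSE)
  )
}

#' Simulate a labeled cohort
#'
#' @param profiles planted catalog.
#' @param config a [cohort_config()].
#' @param label class label for every sample.
#' @param material `"tissue"` or `"plasma"`.
#' @param prefix sample-id prefix (default `label`).
#' @param n number of samples (default `config$n_per_class`).
#' @inheritParams simulate_sample
#' @return named list of [sample_fragments()].
#' @export
simulate_cohort <- function(profiles, config, label, material,
                            prefix = label, n = config$n_per_class,
                            total_regions = nrow(profiles)) {
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  cohort <- lapply(ids, function(id) {
    simulate_sample(profiles, config, label, material, id,
                    total_regions = total_regions)
  })
  names(cohort) <- ids
  cohort
}

#' Generate matched validation matrices (450K-style beta + TPM)
#'
#' Probes are placed inside a subset of regions (all planted regions plus
#' a random draw of unplanted ones). Per-sample region beta is the
#' class-expected methylation mean under purity `pi` with Gaussian noise,
#' clipped to `[0,1]`. Genes are created with promoters overlapping
#' planted markers (associated genes, whose expression is
#' anti-correlated with promoter methylation) and promoters elsewhere
#' (null genes).
#'
#' @param profiles planted catalog.
#' @param n_per_class samples per class in the matrices (default 50).
#' @param purity tissue purity applied to the class effect (default 0.6).
#' @param beta_sd Gaussian noise sd on beta (default 0.05).
#' @param n_null_regions unplanted regions receiving probes (default 200).
#' @param tpm_effect log-scale expression shift for associated genes
#'   (default 1).
#' @param n_null_genes genes with promoters off the markers (default 300).
#' @param seed integer seed.
#' @return list `beta` ([beta_matrix()]), `tpm` ([tpm_matrix()]),
#'   `promoters` (data.frame), `associated_genes` (character).
#' @export
generate_validation_matrices <- function(profiles, n_per_class = 50L,
                                         purity = 0.6, beta_sd = 0.05,
                                         n_null_regions = 200L,
                                         tpm_effect = 1, n_null_genes = 300L,
                                         seed) {
  set.seed(derive_seed(seed, "validation"))
  planted <- which(profiles$planted)
  nulls <- sample(which(!profiles$planted),
                  min(n_null_regions, sum(!profiles$planted)))
  ridx <- c(planted, nulls)
  samples <- c(sprintf("LUAD_T%02d", seq_len(n_per_class)),
               sprintf("LUSC_T%02d", seq_len(n_per_class)))
  labels <- stats::setNames(rep(c("LUAD", "LUSC"), each = n_per_class), samples)

  # expected region methylation per class: background, shifted toward
  # m_alt by purity * phi for the target class of a planted marker
  mean_for_class <- function(i, cls) {
    m <- profiles$m_bg[i]
    hit <- profiles$planted[i] & !is.na(profiles$target_class[i]) &
      profiles$target_class[i] == cls
    if (hit) {
      m <- (1 - purity) * m +
        purity * (profiles$phi[i] * profiles$m_alt[i] +
                  (1 - profiles$phi[i]) * m)
    }
    m
  }
  mu <- vapply(ridx, function(i) {
    c(mean_for_class(i, "LUAD"), mean_for_class(i, "LUSC"))
  }, numeric(2L))

  # 1-2 probes per chosen region
  n_probes <- sample(1:2, length(ridx), replace = TRUE)
  pidx <- rep(seq_along(ridx), n_probes)
  probe_region <- ridx[pidx]
  pos <- profiles$start[probe_region] +
    vapply(profiles$end[probe_region] - profiles$start[probe_region],
           function(w) sample.int(w, 1L) - 1L, integer(1L))
  probes <- data.frame(
    probe_id = sprintf("cg%06d", seq_along(probe_region)),
    chrom = profiles$chrom[probe_region], pos = pos,
    region_id = profiles$region_id[probe_region], stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow(probes), length(samples),
                 dimnames = list(probes$probe_id, samples))
  for (s in seq_along(samples)) {
    cls <- if (labels[s] == "LUAD") 1L else 2L
    vals[, s] <- pmin(pmax(mu[cls, pidx] +
                             stats::rnorm(nrow(probes), 0, beta_sd), 0), 1)
  }
  beta <- beta_matrix(vals, probes[, c("probe_id", "chrom", "pos")], labels)

  # genes: one per planted marker (promoter fully covering the marker,
  # so marker-fraction overlap is 1) plus null genes on open intervals
  assoc_idx <- planted
  assoc_genes <- sprintf("GENE_A%04d", seq_along(assoc_idx))
  null_genes <- sprintf("GENE_N%04d", seq_len(n_null_genes))
  genome_end <- max(profiles$end)
  promoters <- rbind(
    data.frame(gene_id = assoc_genes, chrom = profiles$chrom[assoc_idx],
               start = pmax(profiles$start[assoc_idx] - 100L, 0L),
               end = profiles$end[assoc_idx] + 100L, stringsAsFactors = FALSE),
    data.frame(gene_id = null_genes, chrom = "chrN",
               start = seq(genome_end + 10000L, by = 2000L,
                           length.out = n_null_genes),
               end = seq(genome_end + 10000L, by = 2000L,
                         length.out = n_null_genes) + 1000L,
               stringsAsFactors = FALSE))
  genes <- c(assoc_genes, null_genes)
  log_tpm <- matrix(stats::rnorm(length(genes) * length(samples), 3, 1),
                    nrow = length(genes),
                    dimnames = list(genes, samples))
  # methylation represses: hypo marker in target class -> expression up
  sign <- ifelse(profiles$direction[assoc_idx] == "hypo", +1, -1)
  for (s in seq_along(samples)) {
    hit <- profiles$target_class[assoc_idx] == labels[s]
    log_tpm[seq_along(assoc_idx)[hit], s] <-
      log_tpm[seq_along(assoc_idx)[hit], s] + sign[hit] * tpm_effect
  }
  tpm <- tpm_matrix(exp(log_tpm), promoters = promoters, labels = labels)
  list(beta = beta, tpm = tpm, promoters = promoters,
       associated_genes = assoc_genes)
}
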