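test_that("generate_region_catalog is deterministic with realistic lengths", {
  a <- generate_region_catalog(1000, seed = 7)
  b <- generate_region_catalog(1000, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_region_catalog(1000, seed = 8)))
  expect_true(all(a$end - a$start < 350))
  expect_error(generate_region_catalog(0, seed = 1), "n_regions")

  big <- generate_region_catalog(10000, seed = 3)
  expect_lt(abs(mean(big$end - big$start) - 117), 10)
  # background mixture favours the extremes
  expect_gt(mean(big$m_bg > 0.7 | big$m_bg < 0.3), 0.8)
  # constant-background option
  expect_true(all(generate_region_catalog(50, seed = 1, m_bg = 0.85)$m_bg == 0.85))
})

test_that("plant_markers builds a consistent truth ledger", {
  prof <- generate_region_catalog(10000, seed = 1, m_bg = 0.85)
  pl <- plant_markers(prof, 50, seed = 2)
  expect_equal(nrow(pl$truth), 200L)
  expect_equal(anyDuplicated(pl$truth$region_id), 0L)
  expect_equal(unname(table(pl$truth$target_class)), c(100L, 100L),
               ignore_attr = TRUE)
  p <- pl$profiles
  hypo <- p$planted & p$direction == "hypo"
  hyper <- p$planted & p$direction == "hyper"
  expect_true(all(p$m_alt[hypo] < p$m_bg[hypo], na.rm = TRUE))
  expect_true(all(p$m_alt[hyper] > p$m_bg[hyper], na.rm = TRUE))
  expect_error(plant_markers(prof, 50, phi = 0, seed = 1), "phi")
  expect_error(plant_markers(generate_region_catalog(10, seed = 1), 50, seed = 1),
               "not enough")
})

test_that("planted regions shift tumor fragment alpha toward m_alt", {
  prof <- generate_region_catalog(200, seed = 5, m_bg = 0.85)
  pl <- plant_markers(prof, 10, m_alt = 0.1, phi = 0.3, seed = 5)
  cfg <- cohort_config(n_per_class = 1, depth = 300, purity = 1, seed = 9)
  s <- simulate_sample(pl$profiles, cfg, "LUAD", "tissue", "T1")
  at <- s$fragments
  at$alpha <- at$n_methylated / at$n_cpgs
  luad_hypo <- pl$truth$region_id[pl$truth$target_class == "LUAD" &
                                    pl$truth$direction == "hypo"]
  bg <- pl$profiles$region_id[!pl$profiles$planted]
  m_marker <- mean(at$alpha[at$region_id %in% luad_hypo])
  m_bg <- mean(at$alpha[at$region_id %in% bg])
  # beta-binomial mixture mean: phi * m_alt + (1 - phi) * m_bg at purity 1
  expect_lt(abs(m_marker - (0.3 * 0.1 + 0.7 * 0.85)), 0.04)
  expect_lt(abs(m_bg - 0.85), 0.02)
})

test_that("simulate_sample is seeded, mixes by theta and validates labels", {
  prof <- plant_markers(generate_region_catalog(100, seed = 1, m_bg = 0.85),
                        5, seed = 1)$profiles
  cfg <- cohort_config(n_per_class = 1, depth = 20, seed = 33)
  a <- simulate_sample(prof, cfg, "LUAD", "plasma", "P1")
  b <- simulate_sample(prof, cfg, "LUAD", "plasma", "P1")
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$total_fragments, b$total_fragments)
  expect_gte(a$total_fragments, nrow(a$fragments))
  expect_error(simulate_sample(prof, cfg, "noncancer", "tissue", "X"),
               "plasma")

  # degenerate mixture: theta = 1, phi = 1 on a planted hypo region draws
  # everything from the m_alt component
  prof2 <- plant_markers(generate_region_catalog(30, seed = 2, m_bg = 0.9),
                         3, m_alt = 0.05, phi = 1, seed = 2)$profiles
  cfg2 <- cohort_config(n_per_class = 1, depth = 100, tumor_fraction = 1,
                        seed = 4)
  s2 <- simulate_sample(prof2, cfg2, "LUAD", "plasma", "P2")
  hypo_r <- prof2$region_id[prof2$planted & prof2$direction == "hypo" &
                              prof2$target_class == "LUAD"]
  al <- with(s2$fragments[s2$fragments$region_id %in% hypo_r, ],
             n_methylated / n_cpgs)
  expect_lt(mean(al), 0.15)
})

test_that("theta = 0 plasma is indistinguishable from noncancer background", {
  prof <- plant_markers(generate_region_catalog(150, seed = 6, m_bg = 0.85),
                        10, seed = 6)$profiles
  rejections <- 0L
  for (s in 1:20) {
    cfg <- cohort_config(n_per_class = 1, depth = 30, tumor_fraction = 0,
                         seed = 1000 + s)
    fake <- simulate_sample(prof, cfg, "LUAD", "plasma", paste0("F", s))
    nc <- simulate_sample(prof, cfg, "noncancer", "plasma", paste0("N", s))
    a1 <- fake$fragments$n_methylated / fake$fragments$n_cpgs
    a2 <- nc$fragments$n_methylated / nc$fragments$n_cpgs
    p <- suppressWarnings(stats::ks.test(a1, a2))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("validation matrices carry the planted structure", {
  prof <- plant_markers(generate_region_catalog(2000, seed = 8, m_bg = 0.85),
                        25, seed = 8)$profiles
  vm <- generate_validation_matrices(prof, n_per_class = 40, seed = 8)
  expect_true(all(vm$beta$values >= 0 & vm$beta$values <= 1))
  labels <- vm$beta$labels

  # probes in unplanted regions: class beta differences centred at 0
  asg <- map_probes_to_regions(vm$beta$probes, prof)
  unplanted <- asg$probe_id[asg$region_id %in% prof$region_id[!prof$planted]]
  d <- rowMeans(vm$beta$values[unplanted, labels == "LUAD"]) -
    rowMeans(vm$beta$values[unplanted, labels == "LUSC"])
  expect_lt(abs(mean(d)), 0.01)

  # genes on planted LUAD-hypo markers express higher in LUAD
  luad_hypo <- prof$region_id[prof$planted & !is.na(prof$direction) &
                                prof$direction == "hypo" &
                                prof$target_class == "LUAD"]
  am <- associate_genes(data.frame(region_id = luad_hypo), prof, vm$promoters)
  g <- intersect(unique(am$gene_id), rownames(vm$tpm$values))
  lt <- log(vm$tpm$values + 1)
  diff <- rowMeans(lt[g, labels == "LUAD"]) - rowMeans(lt[g, labels == "LUSC"])
  expect_gt(mean(diff > 0), 0.9)
})
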