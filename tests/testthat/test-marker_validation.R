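test_that("fold-change reproducibility uses pseudocounts and direction", {
  markers <- data.frame(region_id = c("r1", "r2", "r3"),
                        target_class = "LUAD", direction = "hypo",
                        threshold = 0.2, stringsAsFactors = FALSE)
  # LUAD samples carry hypo reads at r1 (strong) and r2 (weak); r3 empty
  luad <- lapply(1:3, function(i)
    make_sample(paste0("L", i), "LUAD", "tissue",
                c(alpha_frags("r1", rep(0.1, 6)), alpha_frags("r2", 0.1)),
                total_fragments = 1e9))
  lusc <- lapply(1:3, function(i)
    make_sample(paste0("S", i), "LUSC", "tissue",
                c(alpha_frags("r1", rep(0.1, 2)), alpha_frags("r2", 0.1)),
                total_fragments = 1e9))
  fc <- fold_change_reproducibility(markers, c(luad, lusc))
  per <- fc$per_marker
  expect_equal(per$fold_change[per$region_id == "r1"], 6.5 / 2.5)  # consistent
  expect_true(per$consistent[per$region_id == "r1"])
  expect_false(per$consistent[per$region_id == "r2"])  # FC 1
  # means 0 vs 0 -> pseudocount FC 1 -> inconsistent
  expect_equal(per$fold_change[per$region_id == "r3"], 1)
  expect_false(per$consistent[per$region_id == "r3"])
  expect_equal(fc$fraction_reproduced, 1 / 3)
  expect_error(fold_change_reproducibility(markers, luad), "both classes")
})

test_that("probe-to-region mapping is half-open", {
  regions <- region_catalog("chr1", 100L, 217L, "r1")
  probes <- data.frame(probe_id = c("in", "at_end", "at_start", "out"),
                       chrom = "chr1", pos = c(150L, 217L, 100L, 500L))
  asg <- map_probes_to_regions(probes, regions)
  expect_equal(asg$region_id, c("r1", NA, "r1", NA))
  # no regions -> all unassigned
  empty <- region_catalog(character(), integer(), integer())
  expect_true(all(is.na(map_probes_to_regions(probes, empty)$region_id)))
})

test_that("region_beta averages probes and stays within [0,1]", {
  v <- matrix(c(0.2, 0.4, 0.9, 0.25, 0.35, 0.8), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  bm <- beta_matrix(v, data.frame(probe_id = c("p1", "p2", "p3"),
                                  chrom = "c", pos = 1:3))
  asg <- data.frame(probe_id = c("p1", "p2", "p3"),
                    region_id = c("rA", "rA", "rB"), stringsAsFactors = FALSE)
  rb <- region_beta(bm, asg)
  expect_equal(rb["rA", ], c(s1 = 0.3, s2 = 0.3))
  expect_equal(rb["rB", ], c(s1 = 0.9, s2 = 0.8))  # single probe = identity
  expect_true(all(rb >= 0 & rb <= 1))
  # probe-order invariance; unassigned probes are dropped, empty regions omitted
  rb2 <- region_beta(bm, asg[c(3, 1, 2), ])
  expect_equal(rb2, rb)
  asg3 <- data.frame(probe_id = "p1", region_id = NA_character_)
  expect_equal(nrow(region_beta(bm, asg3)), 0L)
})

test_that("BH adjustment matches the step-up oracle exhaustively", {
  # textbook example: {0.01, 0.02, 0.04} -> {0.03, 0.03, 0.04}
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(12)
  for (i in 1:300) {
    p <- round(runif(sample(1:12, 1L)), 3)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("differential_test_450k detects planted effects with BH control", {
  set.seed(13)
  n <- 50
  labels <- stats::setNames(rep(c("LUAD", "LUSC"), each = n),
                            sprintf("s%03d", 1:(2 * n)))
  # 10 planted LUAD-hypo regions (delta beta = -0.4 in LUAD), 90 null
  rb <- rbind(
    matrix(c(stats::rnorm(10 * n, 0.3, 0.1), stats::rnorm(10 * n, 0.7, 0.1)),
           10, 2 * n, dimnames = list(sprintf("hit%02d", 1:10), names(labels))),
    matrix(stats::rnorm(90 * 2 * n, 0.5, 0.1), 90, 2 * n,
           dimnames = list(sprintf("null%02d", 1:90), names(labels))))
  rb <- pmin(pmax(rb, 0), 1)
  markers <- data.frame(region_id = rownames(rb), target_class = "LUAD",
                        direction = "hypo", stringsAsFactors = FALSE)
  res <- differential_test_450k(rb, labels, markers)
  per <- res$per_marker
  expect_true(all(per$consistent[grepl("hit", per$region_id)]))
  expect_lt(mean(per$consistent[grepl("null", per$region_id)]), 0.05)

  # identical group values -> degenerate rows get p = 1
  rb0 <- matrix(0.5, 2, 2 * n,
                dimnames = list(c("a", "b"), names(labels)))
  res0 <- differential_test_450k(rb0, labels,
                                 data.frame(region_id = c("a", "b"),
                                            target_class = "LUAD",
                                            direction = "hypo"))
  expect_equal(res0$per_marker$p, c(1, 1))
  expect_equal(res0$fraction_significant, 0)
})

test_that("gene association uses strict marker-fraction overlap", {
  regions <- region_catalog("chr1", 1000L, 1100L, "m1")  # length 100
  markers <- data.frame(region_id = "m1")
  prom <- function(s, e, g) data.frame(gene_id = g, chrom = "chr1",
                                       start = s, end = e)
  # 60% overlap -> associated
  expect_equal(associate_genes(markers, regions, prom(900L, 1060L, "g60"))$gene_id,
               "g60")
  # exactly 50% -> not associated (strict >)
  expect_equal(nrow(associate_genes(markers, regions, prom(950L, 1050L, "g50"))), 0L)
  # disjoint -> not associated
  expect_equal(nrow(associate_genes(markers, regions, prom(5000L, 6000L, "gx"))), 0L)
  # many-to-many allowed
  both <- rbind(prom(900L, 1100L, "gA"), prom(1000L, 1200L, "gB"))
  expect_equal(sort(associate_genes(markers, regions, both)$gene_id),
               c("gA", "gB"))
})

test_that("de_empirical_p ranks the observed DE fraction against random sets", {
  set.seed(14)
  n <- 40
  labels <- stats::setNames(rep(c("LUAD", "LUSC"), each = n),
                            sprintf("s%03d", 1:(2 * n)))
  genes <- sprintf("g%03d", 1:200)
  lt <- matrix(stats::rnorm(200 * 2 * n, 3, 1), 200, 2 * n,
               dimnames = list(genes, names(labels)))
  lt[1:20, labels == "LUAD"] <- lt[1:20, labels == "LUAD"] + 2  # DE genes
  tpm <- tpm_matrix(exp(lt), labels = labels)
  res <- de_empirical_p(tpm, labels, gene_set = genes[1:20], seed = 1)
  expect_equal(res$fraction_de, 1)
  expect_equal(res$empirical_p, 0)  # beats all 500 random sets

  # null gene set: empirical p roughly uniform (median-ish run)
  ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    gs <- sample(genes, 20)
    de_empirical_p(tpm, labels, gene_set = gs, seed = i)$empirical_p
  }, numeric(1L))
  expect_gte(sum(ps >= 0.05 & ps <= 0.95), 16L)
  expect_gte(stats::median(ps), 0.3)
  expect_lte(stats::median(ps), 0.7)

  expect_error(de_empirical_p(tpm, labels, character()), "empty")
  expect_error(de_empirical_p(tpm, labels, genes[1:5], n_random = 0), "n_random")
  # plus-one estimator never returns 0
  expect_gt(de_empirical_p(tpm, labels, genes[1:20], seed = 1,
                           plus_one = TRUE)$empirical_p, 0)
})
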