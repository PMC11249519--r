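test_that("alpha_value computes the methylated fraction and validates", {
  expect_equal(alpha_value(4, 2), 0.5)
  expect_equal(alpha_value(5, 5), 1.0)
  expect_equal(alpha_value(c(4, 5), c(2, 5)), c(0.5, 1.0))
  expect_error(alpha_value(0, 0), "n_cpgs")
  expect_error(alpha_value(3, 4), "n_methylated")
})

test_that("sample_qualifies uses inclusive comparisons", {
  s <- make_sample("S", "LUAD", "tissue", alpha_frags("r1", c(0.1, 0.2, 0.9)))
  expect_true(sample_qualifies(s, "r1", 0.2, "hypo"))
  expect_false(sample_qualifies(s, "r1", 0.05, "hypo"))
  expect_true(sample_qualifies(s, "r1", 0.9, "hyper"))
  s2 <- make_sample("S", "LUSC", "tissue", alpha_frags("r1", c(0.5, 0.75)))
  expect_false(sample_qualifies(s2, "r1", 0.8, "hyper"))
  # empty region and min_fragments behaviour
  expect_false(sample_qualifies(s, "r2", 0.5, "hypo"))
  expect_true(sample_qualifies(s, "r1", 0.2, "hypo", min_fragments = 2))
  expect_false(sample_qualifies(s, "r1", 0.1, "hypo", min_fragments = 2))
  # fragments below min_cpgs are invisible
  s3 <- make_sample("S", "LUAD", "tissue", list(list("r1", 2L, 0L)))
  expect_false(sample_qualifies(s3, "r1", 0.5, "hypo"))
})

test_that("scan_thresholds maximises n_target under the n_other < 2 rule", {
  targets <- lapply(1:5, function(i)
    make_sample(paste0("T", i), "LUAD", "tissue", alpha_frags("r", c(0.1, 0.9))))
  others <- lapply(1:4, function(i)
    make_sample(paste0("O", i), "LUSC", "tissue", alpha_frags("r", c(0.8, 0.9))))
  res <- scan_thresholds("r", targets, others, "hypo")
  expect_equal(res$threshold, 0.1)
  expect_equal(res$n_target, 5L)
  expect_equal(res$n_other, 0L)

  # two other-class samples at the target alpha kill every threshold
  others2 <- c(others[1:2], lapply(1:2, function(i)
    make_sample(paste0("O", i + 2), "LUSC", "tissue", alpha_frags("r", 0.1))))
  expect_null(scan_thresholds("r", targets, others2, "hypo"))

  # no hypomethylated target fragments -> none
  targets3 <- lapply(1:3, function(i)
    make_sample(paste0("T", i), "LUAD", "tissue", alpha_frags("r", 0.9)))
  others3 <- lapply(1:3, function(i)
    make_sample(paste0("O", i), "LUSC", "tissue", alpha_frags("r", 0.5)))
  expect_null(scan_thresholds("r", targets3, others3, "hypo"))

  expect_error(scan_thresholds("r", list(), others, "hypo"), "at least one")
})

test_that("scan_thresholds agrees with the 101-point grid oracle", {
  set.seed(11)
  n_checked <- 0L
  for (case in 1:1000) {
    n_t <- sample(2:5, 1L); n_o <- sample(2:5, 1L)
    # alpha support on the 0.05 grid so the 101-point grid is exhaustive
    mk <- function(n, who, lab) lapply(seq_len(n), function(i) {
      make_sample(paste0(who, i), lab, "tissue",
                  alpha_frags("r", sample(seq(0, 1, 0.05),
                                          sample(1:6, 1L), replace = TRUE)))
    })
    targets <- mk(n_t, "T", "LUAD"); others <- mk(n_o, "O", "LUSC")
    direction <- sample(c("hypo", "hyper"), 1L)
    got <- scan_thresholds("r", targets, others, direction)
    t_alpha <- lapply(targets, function(s)
      s$fragments$n_methylated / s$fragments$n_cpgs)
    o_alpha <- lapply(others, function(s)
      s$fragments$n_methylated / s$fragments$n_cpgs)
    want <- scan_oracle(t_alpha, o_alpha, direction)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_checked <- n_checked + 1L
      expect_equal(got$n_target, want$n_target)
      expect_equal(got$n_other, want$n_other)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-6)
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("background filter is strict at 20% and sets bg_fraction", {
  cand <- data.frame(region_id = "r", direction = "hypo", threshold = 0.1,
                     n_target = 5L, n_other = 0L, stringsAsFactors = FALSE)
  nc <- function(n_q, n = 30L) {
    lapply(seq_len(n), function(i) {
      a <- if (i <= n_q) 0.1 else 0.9
      make_sample(paste0("N", i), "noncancer", "plasma", alpha_frags("r", a))
    })
  }
  # 7/30 = 0.233 > 0.2 -> removed
  expect_equal(nrow(apply_background_filter(cand, nc(7))), 0L)
  # 6/30 = 0.2 -> kept (strict >)
  kept <- apply_background_filter(cand, nc(6))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$bg_fraction, 0.2)
  # 0/30 -> kept with bg_fraction 0
  expect_equal(apply_background_filter(cand, nc(0))$bg_fraction, 0)
  expect_error(apply_background_filter(cand, list()), "empty")
})

test_that("rank_and_select keeps ties at the cutoff deterministically", {
  cand <- data.frame(region_id = c("d", "c", "b", "a"),
                     n_target = c(9L, 8L, 8L, 7L), stringsAsFactors = FALSE)
  sel <- rank_and_select(cand, k = 2)
  expect_equal(nrow(sel), 3L)  # ties included
  expect_equal(sel$region_id, c("d", "b", "c"))
  expect_equal(sel$rank, 1:3)
  expect_equal(nrow(rank_and_select(cand, k = 10)), 4L)
  empty <- cand[0, , drop = FALSE]
  expect_equal(nrow(rank_and_select(empty)), 0L)
})

test_that("discover_markers is symmetric, order-invariant and monotone", {
  w <- small_world()
  mk <- w$markers
  expect_true(all(mk$n_other < 2))
  expect_true(all(mk$bg_fraction <= 0.2))

  # swapping cohorts swaps class labels exactly
  swapped <- discover_markers(w$lusc, w$luad, w$background, k = 15)
  relabel <- swapped
  relabel$target_class <- ifelse(swapped$target_class == "LUAD", "LUSC", "LUAD")
  key <- function(d) sort(paste(d$region_id, d$target_class, d$direction,
                                d$threshold, d$n_target))
  expect_equal(key(relabel), key(mk))

  # invariance to sample order and fragment order
  shuf <- function(cohort) {
    cohort <- rev(cohort)
    lapply(cohort, function(s) {
      s$fragments <- s$fragments[rev(seq_len(nrow(s$fragments))), ]
      s
    })
  }
  mk2 <- discover_markers(shuf(w$luad), shuf(w$lusc), shuf(w$background),
                          k = 15)
  expect_equal(key(mk2), key(mk))

  # k = 1 still yields >= 1 marker per non-empty cell
  mk1 <- discover_markers(w$luad, w$lusc, w$background, k = 1)
  expect_true(all(table(mk1$target_class, mk1$direction) >= 1))

  # monotonicity: adding a qualifying fragment to a target sample never
  # decreases n_target at the selected threshold
  m0 <- mk[mk$direction == "hypo" & mk$target_class == "LUAD", ][1L, ]
  luad2 <- w$luad
  extra <- data.frame(region_id = m0$region_id, n_cpgs = 20L,
                      n_methylated = 0L)
  for (i in seq_along(luad2)) {
    luad2[[i]]$fragments <- rbind(luad2[[i]]$fragments, extra)
  }
  mk3 <- discover_markers(luad2, w$lusc, w$background, k = 15)
  m3 <- mk3[mk3$region_id == m0$region_id & mk3$direction == "hypo" &
              mk3$target_class == "LUAD", ]
  expect_gte(m3$n_target[1L], m0$n_target)
})

test_that("marker tables round-trip through TSV", {
  mk <- small_world()$markers
  f <- tempfile(fileext = ".tsv")
  write_markers(mk, f)
  back <- read_markers(f)
  expect_equal(back$region_id, mk$region_id)
  expect_equal(back$threshold, mk$threshold, tolerance = 1e-12)
  expect_equal(back$n_target, mk$n_target)
})
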