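# Count filtering, CPM+1 normalization, fold changes, envelope calls,
# gene ranking and temporal tests.

# independent textbook Welch oracle used against package results
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  t <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("raw-count filter excludes below 40 and retains at 40", {
  raw <- matrix(c(39L, 40L, 0L, 1000L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  pass <- apply_count_filter(raw)
  expect_false(pass["g1", "s1"])  # 39 excluded
  expect_true(pass["g2", "s1"])   # 40 retained
  expect_identical(raw["g1", "s1"], 39L)  # counts never altered
})

test_that("all-zero samples are flagged with every guide excluded", {
  raw <- matrix(c(0L, 0L, 50L, 60L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_warning(pass <- apply_count_filter(raw), "all-zero")
  expect_true(all(!pass[, "s1"]))
})

test_that("CPM+1 normalization follows the formula and conserves mass", {
  raw <- matrix(c(250000L, 750000L), nrow = 2,
                dimnames = list(c("g1", "g2"), "s1"))
  norm <- normalize_cpm(raw)
  expect_equal(unname(norm["g1", "s1"]), 250001)
  raw0 <- matrix(c(0L, 10L), nrow = 2,
                 dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(normalize_cpm(raw0)["g1", "s1"]), 1)

  sim <- simulate_screen(small_screen_cfg(9))
  norm <- normalize_cpm(sim$counts)
  expect_true(all(norm >= 1))
  expect_equal(colSums(norm - 1), rep(1e6, ncol(norm)),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("normalization is invariant to per-sample depth scaling", {
  sim <- simulate_screen(small_screen_cfg(10))
  doubled <- sim$counts
  doubled[, 1] <- doubled[, 1] * 2L
  expect_equal(normalize_cpm(doubled)[, 1],
               normalize_cpm(sim$counts)[, 1], tolerance = 1e-12)
})

test_that("zero-total samples fail with the sample named", {
  raw <- matrix(c(0L, 0L, 5L, 5L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("bad", "ok")))
  expect_error(normalize_cpm(raw), "bad")
})

test_that("arm aggregation averages passing samples under the half rule", {
  sheet <- data.frame(
    sample_id = paste0("s", 1:8),
    genotype = rep(c("WT", "CD8KO"), each = 4),
    stage = "early",
    mouse_id = paste0("m", 1:8),
    barcode = c("AAAA", "CCCC", "GGGG", "TTTT",
                "AACC", "AAGG", "AATT", "CCGG"),
    stringsAsFactors = FALSE)
  norm <- matrix(101:108, nrow = 1,
                 dimnames = list("g1", sheet$sample_id))
  # pass in 2 of the first 2 WT samples only: mean over those two
  pass <- matrix(c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 4)), nrow = 1,
                 dimnames = dimnames(norm))
  arm <- aggregate_arm(norm, sheet, pass)
  expect_equal(unname(arm$means["g1", "WT"]), mean(c(101, 102)))
  expect_true(arm$usable["g1", "WT"])  # 2 = max(2, 4/2) passes
  # failing in 3 of 4 leaves only 1 pass -> unusable in that arm
  pass1 <- pass
  pass1[1, 2] <- FALSE
  arm1 <- aggregate_arm(norm, sheet, pass1)
  expect_false(arm1$usable["g1", "WT"])
  # failing in 1 of 4 -> mean over the remaining 3
  pass3 <- matrix(TRUE, 1, 8, dimnames = dimnames(norm))
  pass3[1, 4] <- FALSE
  arm3 <- aggregate_arm(norm, sheet, pass3)
  expect_equal(unname(arm3$means["g1", "WT"]), mean(101:103))
})

test_that("fold changes follow arm means with the both-below-5 rule", {
  lib <- data.frame(guide_id = c("g1", "g2", "g3"),
                    gene = c("A", "B", "C"),
                    protospacer = c("ACGTACGTACGTACGTACGT",
                                    "TTTTCCCCAAAAGGGGTTTT",
                                    "GGGGGGGGGGGGGGGGGGGG"),
                    is_ntc = FALSE, stringsAsFactors = FALSE)
  arm <- list(
    means = matrix(c(200, 100, 4.2, 100, 100, 3.1), ncol = 2,
                   dimnames = list(lib$guide_id, c("WT", "CD8KO"))),
    usable = matrix(TRUE, 3, 2,
                    dimnames = list(lib$guide_id, c("WT", "CD8KO"))))
  res <- guide_fold_changes(arm, lib)
  expect_equal(res$fc[1], 2)
  expect_equal(res$log2fc[1], 1)
  expect_equal(res$fc[2], 1)
  expect_equal(res$class[3], "unanalyzable")  # 4.2 and 3.1 both < 5
  # unusable arm -> low_count_excluded, which outranks unanalyzable
  arm$usable[1, "WT"] <- FALSE
  res2 <- guide_fold_changes(arm, lib)
  expect_equal(res2$class[1], "low_count_excluded")
  expect_true(is.na(res2$fc[1]))
})

test_that("envelope classification uses strict inequalities", {
  res <- data.frame(
    guide_id = c(paste0("n", 1:3), paste0("g", 1:3)),
    gene = c(rep("non-targeting", 3), "A", "B", "C"),
    is_ntc = rep(c(TRUE, FALSE), each = 3),
    fc = c(0.8, 1.0, 1.25, 1.3, 0.7, 1.25),
    log2fc = log2(c(0.8, 1.0, 1.25, 1.3, 0.7, 1.25)),
    class = "neutral", stringsAsFactors = FALSE)
  env <- ntc_envelope(res)
  expect_equal(env$max_ntc_fc, 1.25)
  expect_equal(env$min_ntc_fc, 0.8)
  out <- classify_by_ntc_envelope(res, env)
  expect_equal(out$class[out$guide_id == "g1"], "enriched")
  expect_equal(out$class[out$guide_id == "g2"], "depleted")
  expect_equal(out$class[out$guide_id == "g3"], "neutral")  # tie at max
  expect_true(all(out$class[out$is_ntc] == "neutral"))
})

test_that("envelope requires at least two usable controls", {
  res <- data.frame(guide_id = "n1", gene = "non-targeting",
                    is_ntc = TRUE, fc = 1, log2fc = 0,
                    class = "neutral", stringsAsFactors = FALSE)
  expect_error(ntc_envelope(res), "at least two")
})

test_that("a gene whose guides sit inside the envelope gets no calls", {
  res <- data.frame(
    guide_id = c("n1", "n2", "a1", "a2"),
    gene = c("non-targeting", "non-targeting", "A", "A"),
    is_ntc = c(TRUE, TRUE, FALSE, FALSE),
    fc = c(0.5, 2.0, 0.9, 1.1), log2fc = log2(c(0.5, 2, 0.9, 1.1)),
    class = "neutral", stringsAsFactors = FALSE)
  out <- classify_by_ntc_envelope(res)
  gs <- gene_summary(out)
  expect_equal(gs$n_depleted[gs$gene == "A"], 0)
  expect_equal(gs$n_enriched[gs$gene == "A"], 0)
  expect_equal(gs$depletion_rank[gs$gene == "A"], 1)
})

test_that("increasing a guide's WT counts strictly increases its fc", {
  base <- list(
    means = matrix(c(100, 50), ncol = 2,
                   dimnames = list("g1", c("WT", "CD8KO"))),
    usable = matrix(TRUE, 1, 2,
                    dimnames = list("g1", c("WT", "CD8KO"))))
  lib <- data.frame(guide_id = "g1", gene = "A",
                    protospacer = "ACGTACGTACGTACGTACGT",
                    is_ntc = FALSE, stringsAsFactors = FALSE)
  fc_at <- function(wt) {
    a <- base
    a$means["g1", "WT"] <- wt
    guide_fold_changes(a, lib)$fc
  }
  wt_grid <- c(60, 80, 100, 150, 300)
  fcs <- vapply(wt_grid, fc_at, numeric(1))
  expect_true(all(diff(fcs) > 0))
})

test_that("temporal Welch test matches the textbook oracle", {
  early <- c(10, 12, 9, 11)
  late <- c(3, 4, 2, 3)
  norm <- matrix(c(early, late), nrow = 1,
                 dimnames = list("A_g1", paste0("s", 1:8)))
  sheet <- data.frame(sample_id = paste0("s", 1:8), genotype = "WT",
                      stage = rep(c("early", "late"), each = 4),
                      mouse_id = paste0("m", 1:8),
                      barcode = c("AAAA", "CCCC", "GGGG", "TTTT",
                                  "AACC", "AAGG", "AATT", "CCGG"),
                      stringsAsFactors = FALSE)
  lib <- data.frame(guide_id = "A_g1", gene = "A",
                    protospacer = "ACGTACGTACGTACGTACGT",
                    is_ntc = FALSE, stringsAsFactors = FALSE)
  pass <- matrix(TRUE, 1, 8, dimnames = dimnames(norm))
  res <- temporal_selection_test(norm, sheet, pass, lib, "A", "WT")
  orc <- welch_oracle(early, late)
  expect_equal(res$t_statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$df, orc$df, tolerance = 1e-12)
  expect_equal(res$p_two_sided, orc$p, tolerance = 1e-12)
  expect_equal(res$direction, -1)

  # identical stages: t = 0, p = 1
  norm_eq <- matrix(rep(early, 2), nrow = 1, dimnames = dimnames(norm))
  res_eq <- temporal_selection_test(norm_eq, sheet, pass, lib, "A", "WT")
  expect_equal(res_eq$t_statistic, 0)
  expect_equal(res_eq$p_two_sided, 1)

  # constant but unequal stages: flagged underflow floor
  norm_c <- matrix(rep(c(5, 2), each = 4), nrow = 1,
                   dimnames = dimnames(norm))
  res_c <- temporal_selection_test(norm_c, sheet, pass, lib, "A", "WT")
  expect_true(res_c$p_underflow)
  expect_gt(res_c$p_two_sided, 0)
})

test_that("Welch t and p match the oracle on random small samples", {
  set.seed(404)
  for (i in 1:100) {
    x <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    orc <- welch_oracle(x, y)
    tt <- t.test(x, y)   # the gene_summary / temporal engine
    expect_equal(unname(tt$statistic), orc$t, tolerance = 1e-10)
    expect_equal(tt$p.value, orc$p, tolerance = 1e-10)
  }
})

test_that("library fold representation reproduces the printed coverages", {
  expect_equal(representation_coverage(200000, 12, 3000), 800L)
  expect_equal(representation_coverage(200000, 11, 3000), 733L)
  expect_equal(representation_coverage(200000, 0, 3000), 0L)
  expect_error(representation_coverage(200000, 11, 0), "n_guides")
})
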