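panel <- read_reference_panel()

make_ct <- function(effects, noise_sd = 0, seed = 1)
  generate_ct_table(effects, noise_sd = noise_sd, seed = seed)

test_that("relative expression implements 2^-ddCt against control mean", {
  # null effect -> ratio exactly 1
  eff0 <- data.frame(gene = "g", log2fc_tolerant = 0, log2fc_susceptible = 0)
  rel0 <- relative_expression(make_ct(eff0)$ct, "beta_actin")
  expect_equal(rel0$ratio, rep(1, nrow(rel0)))
  # ddCt of -1 doubles expression
  eff1 <- data.frame(gene = "g", log2fc_tolerant = 1, log2fc_susceptible = 1)
  rel1 <- relative_expression(make_ct(eff1)$ct, "beta_actin")
  expect_equal(rel1$ratio, rep(2, nrow(rel1)))
  # planted effect at zero noise gives every replicate the exact ratio
  eff <- data.frame(gene = "g", log2fc_tolerant = 2.62,
                    log2fc_susceptible = 2.62)
  rel <- relative_expression(make_ct(eff)$ct, "beta_actin")
  expect_equal(rel$ratio, rep(2^2.62, nrow(rel)), tolerance = 1e-12)
})

test_that("a missing reference Ct is an error naming the cell", {
  eff <- data.frame(gene = "g", log2fc_tolerant = 0, log2fc_susceptible = 0)
  ct <- make_ct(eff)$ct
  drop <- which(ct$gene == "beta_actin")[1]
  expect_error(relative_expression(ct[-drop, ], "beta_actin"),
               "beta_actin")
})

test_that("technical repeats are averaged before analysis", {
  eff <- data.frame(gene = "g", log2fc_tolerant = 1, log2fc_susceptible = 1)
  ct <- make_ct(eff)$ct
  # duplicate every row with +/- 0.5 cycles: means unchanged
  ct2 <- rbind(transform(ct, ct = ct + 0.5), transform(ct, ct = ct - 0.5))
  rel <- relative_expression(ct2, "beta_actin")
  expect_equal(rel$ratio, rep(2, nrow(rel)))
})

test_that("class fold change averages linear and log ratios separately", {
  ratios <- data.frame(
    gene = "g", class = "TOLERANT",
    genotype = rep(c("G1", "G2"), each = 3),
    replicate = rep(1:3, 2),
    ratio = c(4, 4, 4, 8, 8, 8),
    log2_ratio = c(2, 2, 2, 3, 3, 3))
  cfc <- class_fold_change(ratios)
  expect_equal(cfc$fc, 6)        # mean of genotype FCs {4, 8}
  expect_equal(cfc$log2fc, 2.5)  # mean replicate log2; FC != 2^Log2FC
  expect_error(class_fold_change(transform(ratios, ratio = c(-1, ratio[-1]))),
               "non-positive")
  # all-ones table
  ones <- transform(ratios, ratio = 1, log2_ratio = 0)
  expect_equal(class_fold_change(ones)$fc, 1)
  expect_equal(class_fold_change(ones)$log2fc, 0)
})

test_that("class Log2FC never exceeds log2 of class FC (AM-GM)", {
  set.seed(12)
  for (i in 1:20) {
    lr <- rnorm(6, 0, 2)
    ratios <- data.frame(gene = "g", class = "TOLERANT",
                         genotype = rep(c("G1", "G2"), each = 3),
                         replicate = rep(1:3, 2),
                         ratio = 2^lr, log2_ratio = lr)
    cfc <- class_fold_change(ratios)
    expect_lte(cfc$log2fc, log2(cfc$fc) + 1e-12)
  }
})

test_that("significance thresholds are inclusive at +/-1", {
  expect_equal(significance(c(2.62, -0.52, 1, -1, 0.99, -0.99)),
               c("UP", "NS", "UP", "DOWN", "NS", "NS"))
})

test_that("group assignment is sign-based with zero counting as up", {
  expect_equal(classify_group(0.07, -2.42), 1L)
  expect_equal(classify_group(1.91, 1.20), 2L)
  expect_equal(classify_group(-1.02, 2.20), 3L)
  expect_equal(classify_group(-1.15, -1.45), 4L)
  expect_equal(classify_group(0, 0), 2L)
  expect_equal(classify_group(0, -0.01), 1L)
})

test_that("trait rule reproduces the published panel and is total", {
  got <- classify_trait(panel$log2fc_tolerant, panel$log2fc_susceptible)
  expect_equal(got, panel$trait)
  # spot values
  expect_equal(classify_trait(2.62, -1.20), "highly heat-tolerant")
  expect_equal(classify_trait(-2.08, 1.71), "highly heat-susceptible")
  expect_equal(classify_trait(-1.02, 0.94),
               "moderately highly heat-susceptible")
  expect_equal(classify_trait(1.79, 1.56), "neutral")
  expect_equal(classify_trait(0.5, -0.5), "not-DE")
  # totality over a grid, exactly one known label each
  grid <- expand.grid(tol = seq(-2.5, 2.5, by = 0.5),
                      sus = seq(-2.5, 2.5, by = 0.5))
  labs <- classify_trait(grid$tol, grid$sus)
  expect_true(all(labs %in% gfam:::TRAIT_LEVELS))
  # symmetry: swapping classes swaps tolerant/susceptible categories
  expect_equal(classify_trait(-1.20, 2.62), "highly heat-susceptible")
})

test_that("regulation summary counts classes and the DEG union", {
  res <- expression_calls(data.frame(gene = "g", log2fc_tolerant = 2.62,
                                     log2fc_susceptible = -1.20))
  s <- summarize_regulation(res)
  expect_equal(s$up_tolerant, 1L)
  expect_equal(s$down_susceptible, 1L)
  expect_equal(s$n_deg, 1L)
  ns <- expression_calls(data.frame(gene = c("a", "b"),
                                    log2fc_tolerant = c(0.2, -0.3),
                                    log2fc_susceptible = c(0.5, 0)))
  s0 <- summarize_regulation(ns)
  expect_equal(s0$n_deg, 0L)
  expect_equal(s0$total_tolerant + s0$total_susceptible, 0L)
})

test_that("noise-free planted Ct tables are inverted exactly", {
  eff <- data.frame(gene = c("gA", "gB", "gC"),
                    log2fc_tolerant = c(2.62, -1.15, 0),
                    log2fc_susceptible = c(-1.20, -1.45, 0))
  res <- analyze_expression(make_ct(eff)$ct, "beta_actin")
  res <- res[match(eff$gene, res$gene), ]
  expect_equal(res$log2fc_tolerant, eff$log2fc_tolerant, tolerance = 1e-12)
  expect_equal(res$log2fc_susceptible, eff$log2fc_susceptible,
               tolerance = 1e-12)
  expect_equal(res$fc_tolerant, 2^eff$log2fc_tolerant, tolerance = 1e-12)
  expect_equal(res$trait[1], "highly heat-tolerant")
  expect_equal(res$trait[2], "neutral")
  expect_equal(res$trait[3], "not-DE")
})

test_that("noisy planted effects are recovered within sampling error", {
  eff <- data.frame(gene = c("g1", "g2", "g3"),
                    log2fc_tolerant = c(2.62, -1.2, 0),
                    log2fc_susceptible = c(2.62, -1.2, 0))
  n_tab <- 50; sd_noise <- 0.2
  est <- matrix(NA_real_, n_tab, 3)
  for (t in seq_len(n_tab)) {
    res <- analyze_expression(make_ct(eff, noise_sd = sd_noise,
                                      seed = 1000 + t)$ct, "beta_actin")
    est[t, ] <- res$log2fc_tolerant[match(eff$gene, res$gene)]
  }
  se_grand <- sd_noise / sqrt(6 * n_tab)
  expect_true(all(abs(colMeans(est) - eff$log2fc_tolerant) <= 3 * se_grand))
})
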