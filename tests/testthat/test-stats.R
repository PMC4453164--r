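# Screen statistics: replicate correlation, Z / dZ scores, hit calling,
# hit-rate and proportion arithmetic, interaction scores.

make_wells <- function(vals, background = "NS", replicate = 1,
                       role = "sample",
                       genes = paste0("G", seq_along(vals))) {
  data.frame(well = sprintf("A%02d", seq_along(vals)), gene = genes,
             background = background, replicate = replicate, role = role,
             pct_multipolar = vals, stringsAsFactors = FALSE)
}

test_that("replicate correlation hits the rank-formula oracle, ties included", {
  a <- make_wells(c(1, 2, 3, 4, 5))
  b <- make_wells(c(2, 4, 6, 8, 10), replicate = 2)
  r <- replicate_correlation(a, b, "pct_multipolar")
  expect_equal(r$rho, 1)
  expect_equal(r$p, 0)
  rev <- make_wells(c(10, 8, 6, 4, 2), replicate = 2)
  expect_equal(replicate_correlation(a, rev, "pct_multipolar")$rho, -1)
  # tied values: average-rank handling equals the brute-force oracle
  x <- c(3, 1, 4, 1, 5); y <- c(2, 7, 1, 8, 2)
  rt <- replicate_correlation(make_wells(x),
                              make_wells(y, replicate = 2),
                              "pct_multipolar")
  expect_equal(rt$rho, oracle_spearman(x, y))
  set.seed(8)
  for (i in 1:5) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    got <- replicate_correlation(make_wells(x),
                                 make_wells(y, replicate = 2),
                                 "pct_multipolar")$rho
    expect_equal(got, oracle_spearman(x, y))
  }
  expect_error(replicate_correlation(make_wells(1:2),
                                     make_wells(2:3, replicate = 2),
                                     "pct_multipolar"), ">= 3")
  # permutation p is sane on a strongly correlated pair
  rp <- replicate_correlation(a, b, "pct_multipolar",
                              method = "permutation", seed = 1)
  expect_lt(rp$p, 0.05)
})

zwells <- local({
  set.seed(42)
  genes <- paste0("G", 1:30)
  rows <- list()
  for (bg in c("NS", "chTOG")) for (rp in 1:2) {
    v <- rnorm(30, 10, 3)
    w <- make_wells(v, background = bg, replicate = rp, genes = genes)
    for (f in c("n_cells", "mitotic_index", "mean_poles",
                "pct_multinucleate"))
      w[[f]] <- rnorm(30, 5, 1)
    rows[[paste(bg, rp)]] <- w
  }
  do.call(rbind, rows)
})

test_that("Z scores standardize each plate and dZ is the exact background difference", {
  sc <- compute_zscores(zwells)
  pm <- sc[sc$feature == "pct_multipolar", ]
  expect_equal(pm$dz, pm$z_ns - pm$z_chtog)
  # normalization population: per plate mean 0, SD 1
  for (bg in c("NS", "chTOG")) for (rp in 1:2) {
    w <- zwells[zwells$background == bg & zwells$replicate == rp, ]
    z <- (w$pct_multipolar - mean(w$pct_multipolar)) / sd(w$pct_multipolar)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  # a gene at the plate mean in both replicates scores Z = 0 exactly
  small <- do.call(rbind, lapply(1:2, function(rp) {
    rbind(make_wells(c(10, 8, 12, 9, 11), background = "NS",
                     replicate = rp),
          make_wells(c(10, 6, 14, 8, 12), background = "chTOG",
                     replicate = rp))
  }))
  for (f in c("n_cells", "mitotic_index", "mean_poles",
              "pct_multinucleate"))
    small[[f]] <- rep(seq_len(10), 2)
  sc_small <- compute_zscores(small)
  g1s <- sc_small[sc_small$feature == "pct_multipolar" &
                    sc_small$gene == "G1", ]
  expect_equal(g1s$z_ns, 0)
  expect_equal(g1s$z_chtog, 0)
  expect_equal(g1s$dz, 0)
  # replicate handling: final Z is the mean of the per-plate Z values
  g1 <- pm[pm$gene == "G1", ]
  zz <- sapply(1:2, function(rp) {
    w <- zwells[zwells$background == "NS" & zwells$replicate == rp, ]
    (w$pct_multipolar[w$gene == "G1"] - mean(w$pct_multipolar)) /
      sd(w$pct_multipolar)
  })
  expect_equal(g1$z_ns, mean(zz))
})

test_that("dZ is antisymmetric under swapping the background labels", {
  sw <- zwells
  sw$background <- ifelse(sw$background == "NS", "chTOG", "NS")
  sc <- compute_zscores(zwells)
  sc_sw <- compute_zscores(sw)
  m <- merge(sc, sc_sw, by = c("gene", "feature"))
  expect_equal(m$dz.x, -m$dz.y)
})

test_that("degenerate features and arithmetic corner cases error clearly", {
  w <- zwells
  w$mean_poles <- 2
  expect_error(compute_zscores(w), "mean_poles")
  expect_error(proportion(1, 0), "positive")
})

test_that("hit calls follow the strict 1.5-SD rule around control wells", {
  ctrl <- make_wells(rep(c(8, 12), 3), role = "control",
                     genes = rep("CTRL_NT", 6))   # mu = 10, sd ~ 2.19
  mu <- 10; sig <- sd(rep(c(8, 12), 3))
  genes <- make_wells(c(mu + 1.5 * sig, mu + 1.5 * sig + 0.01,
                        mu - 1.5 * sig - 0.01, mu))
  wells <- rbind(ctrl, genes)
  h <- call_hits(wells, k = 1.5)
  expect_equal(h$class, c("none", "enhancer", "suppressor", "none"))
  # all genes at the control mean: zero hits
  flat <- rbind(ctrl, make_wells(rep(mu, 10)))
  hf <- call_hits(flat, k = 1.5)
  expect_true(all(hf$class == "none"))
  # missing controls error
  expect_error(call_hits(genes, k = 1.5), "control")
})

test_that("a null single-replicate screen flags about 13.4% of genes at k = 1.5", {
  lay <- make_layout(paste0("G", 1:240), replicates = 1)
  mod <- gene_effect_model(lay,
                           chtog = list(well_noise_sd = 0.06,
                                        cell_count_mean = 4000,
                                        mitotic_fraction = 0.3))
  rates <- vapply(1:4, function(s) {
    sim <- simulate_screen_tables(lay, mod, seed = 100 + s,
                                  plate_effect_sd = 0)
    h <- call_hits(sim$wells, lay, k = 1.5)
    mean(h$class[h$background == "chTOG"] != "none")
  }, numeric(1))
  expected <- 2 * pnorm(-1.5)   # 0.1336
  se <- sqrt(expected * (1 - expected) / (4 * 240))
  expect_lt(abs(mean(rates) - expected), 4 * se + 0.01)
})

test_that("simulated strong effects surface as the top |Z| and are recovered as hits", {
  lay <- make_layout(paste0("G", 1:60), n_controls = 12)
  mod <- gene_effect_model(lay)
  mod <- set_gene_effect(mod, "G7", "chTOG", multipolar_penetrance = 0.75)
  sim <- simulate_screen_tables(lay, mod, seed = 6)
  sc <- compute_zscores(sim$wells, lay)
  pm <- sc[sc$feature == "pct_multipolar", ]
  expect_equal(pm$gene[which.max(abs(pm$z_chtog))], "G7")
  h <- call_hits(sim$wells, lay)
  expect_equal(h$class[h$gene == "G7" & h$background == "chTOG"],
               "enhancer")
})

test_that("hit-rate and proportion arithmetic reproduce the screen's printed summaries", {
  expect_equal(summarize_hits(c(n_suppressors = 0, n_enhancers = 8),
                              240)$pct_hits, 3.3)
  expect_equal(summarize_hits(c(n_suppressors = 13, n_enhancers = 15),
                              240)$pct_hits, 11.7)
  expect_equal(summarize_hits(c(n_suppressors = 0, n_enhancers = 0),
                              999)$pct_hits, 0)
  expect_equal(proportion(11, 25), 44)
  expect_equal(proportion(0, 7), 0)
  expect_equal(proportion(7, 7), 100)
})

test_that("interaction scores follow the multiplicative expectation exactly", {
  # exact independence: w_AB = w_A * w_B
  r <- interaction_score(100, 50, 60, 30)
  expect_equal(r$epsilon, 0)
  expect_equal(r$classification, "none")
  # hand arithmetic: eps = 0.1 - 0.2 = -0.1
  r2 <- interaction_score(20, 10, 8, 2)
  expect_equal(r2$epsilon, 0.1 - 0.2)
  expect_equal(r2$classification, "none")   # |eps| < 0.25
  # null perturbations
  r3 <- interaction_score(20, 20, 20, 20)
  expect_equal(r3$epsilon, 0)
  # classification beyond the threshold, both conventions
  r4 <- interaction_score(50, 40, 40, 10)   # eps = 0.2 - 0.64 = -0.44
  expect_equal(r4$classification, "alleviating")
  r5 <- interaction_score(50, 40, 40, 10, convention = "rescue")
  expect_equal(r5$classification, "aggravating")
  # invariance to common rescaling of all four phenotypes
  r6 <- interaction_score(50 / 5, 40 / 5, 40 / 5, 10 / 5)
  expect_equal(r6$epsilon, r4$epsilon)
  expect_equal(r6$classification, r4$classification)
  expect_error(interaction_score(0, 1, 1, 1), "> 0")
})
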