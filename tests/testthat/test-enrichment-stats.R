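# Mean-variance trend, NB tail test, hit calling and the downstream
# classification rules.

sim_norm <- function(n_guides, n_ntc = 0, seed = 1, ...) {
  cfg <- screen_sim_config(seed = seed, include_baseline = FALSE, ...)
  sim <- simulate_screen_counts(make_generic_library(n_guides, n_ntc), cfg)
  list(nm = normalize_counts(sim$matrix), truth = sim$truth)
}

test_that("Poisson-simulated counts fit an essentially Poisson trend", {
  s <- sim_norm(10000, seed = 51, k = 0)
  fit <- fit_mean_variance(s$nm, "CXCR4neg")
  mu_bar <- mean(rowMeans(s$nm$counts))
  excess <- fit$k * mu_bar^fit$b
  expect_lt(abs(excess), 0.05 * mu_bar)
})

test_that("NB trend parameters are recovered within 15% at 20k guides", {
  s <- sim_norm(20000, seed = 52)  # truth k = 0.1, b = 1.5
  fit <- fit_mean_variance(s$nm, "CXCR4neg")
  expect_lt(abs(fit$k - 0.1) / 0.1, 0.15)
  expect_lt(abs(fit$b - 1.5) / 1.5, 0.15)
  expect_gt(fit$r_squared, 0.9)
})

test_that("a single reference replicate cannot support a variance fit", {
  counts <- matrix(rpois(200, 500), ncol = 2,
                   dimnames = list(sprintf("g%d", 1:100), c("a", "b")))
  cm <- count_matrix(counts, role = c("CXCR4neg", "CXCR4pos"),
                     replicate = c(1, 1))
  expect_error(fit_mean_variance(normalize_counts(cm), "CXCR4neg"),
               "variance undefined")
})

test_that("too few overdispersed guides is a hard error", {
  set.seed(3)
  counts <- matrix(rep(500L, 60 * 3), ncol = 3,
                   dimnames = list(sprintf("g%d", 1:60), c("a", "b", "c")))
  counts[, 2] <- 501L  # constant-ish, no usable variance signal
  cm <- count_matrix(counts, role = rep("CXCR4neg", 3), replicate = 1:3)
  expect_error(fit_mean_variance(normalize_counts(cm), "CXCR4neg"),
               "insufficient overdispersion")
})

test_that("observation at the null mean puts mass in both tails", {
  # treatment mean exactly equals control mean: both one-sided tail
  # probabilities contain the observed point, so they sum to >= 1 and
  # each is near 0.5 (the right-skewed discrete null puts its median
  # slightly below its mean, so exactly 0.5 is not guaranteed)
  tails <- m6ascreen:::nb_tails(obs = c(500, 50), mu = c(500, 50),
                                k = 0.1, b = 1.5, n_trt = 3, n_ctrl = 3)
  expect_true(all(tails$p_low >= 0.45))
  expect_true(all(tails$p_high >= 0.45))
  expect_true(all(tails$p_low + tails$p_high >= 1 - 1e-9))
  # zero-mean convention
  z <- m6ascreen:::nb_tails(obs = c(0, 7), mu = c(0, 0),
                            k = 0.1, b = 1.5, n_trt = 3, n_ctrl = 3)
  expect_equal(z$p_low, c(1, 1))
  expect_equal(z$p_high[1], 1)
  expect_lt(z$p_high[2], 1e-100)
})

test_that("a 10x enrichment at mu = 500 is overwhelmingly significant", {
  tails <- m6ascreen:::nb_tails(obs = 5000, mu = 500, k = 0.1, b = 1.5,
                                n_trt = 3, n_ctrl = 3)
  expect_lt(tails$p_high, 1e-6)
  expect_equal(tails$p_low, 1)
})

test_that("p_low + p_high >= 1 across a full simulated fit", {
  s <- sim_norm(3000, 300, seed = 53)
  fit <- screen_nb_test(s$nm)
  tab <- fit$table[!fit$table$low_count_removed, ]
  expect_true(all(tab$p_low + tab$p_high >= 1 - 1e-9))
  expect_true(all(tab$p_low > 0 & tab$p_low <= 1))
  expect_true(all(tab$p_high > 0 & tab$p_high <= 1))
})

test_that("type-I error of the NB test is calibrated at the null", {
  rates01 <- rates05 <- numeric(3)
  for (i in 1:3) {
    s <- sim_norm(10000, seed = 60 + i)
    fit <- screen_nb_test(s$nm)
    tab <- fit$table[!fit$table$low_count_removed, ]
    rates05[i] <- mean(tab$p_high < 0.05)
    rates01[i] <- mean(tab$p_high < 0.01)
  }
  expect_true(all(abs(rates05 - 0.05) <= 0.01))
  expect_true(all(abs(rates01 - 0.01) <= 0.005))
})

test_that("hit calling applies the joint p/LFC rule with exclusions", {
  base <- data.frame(
    sgRNA_id = sprintf("g%d", 1:6), gene = "G",
    site_id = sprintf("s%d", 1:6), is_nontargeting = FALSE,
    mean_ctrl = 500, mean_trt = 500,
    lfc_r1 = 0, median_lfc = c(0.7, 0.7, -2, 0.7, 1.4, 3),
    p_low = c(0.9, 0.9, 0.2, 0.9, 0.9, 0.9),
    p_high = c(0.01, 0.01, 0.9, 0.2, 0.01, 0.001),
    low_count_removed = FALSE, stringsAsFactors = FALSE)
  base$is_nontargeting[6] <- TRUE
  fit <- structure(list(table = base, treatment_role = "CXCR4pos",
                        control_role = "CXCR4neg"), class = "screen_nb")
  ann <- data.frame(sgRNA_id = sprintf("g%d", 1:6),
                    region = c("three_prime_UTR", "CDS", "CDS", "CDS",
                               "three_prime_UTR", "three_prime_UTR"),
                    coding_effect = c("none", "missense", "synonymous",
                                      "none", "none", "none"))
  res <- call_hits(fit, ann)
  # (p_high 0.01, lfc 0.7, 3'UTR): relaxed hit, not high-confidence
  expect_true(res$hit_CXCR4pos[1]); expect_false(res$highconf_CXCR4pos[1])
  # same numbers but missense: filtered out
  expect_false(res$hit_CXCR4pos[2]); expect_true(res$missense_excluded[2])
  # (p_low 0.2, lfc -2): p fails the conjunction
  expect_false(res$hit_CXCR4neg[3])
  # (p_high 0.2): not a hit
  expect_false(res$hit_CXCR4pos[4])
  # lfc 1.4 and significant: hit and high-confidence
  expect_true(res$hit_CXCR4pos[5] && res$highconf_CXCR4pos[5])
  # non-targeting guides are never hits, whatever their numbers
  expect_false(res$hit_CXCR4pos[6])
  # directions are mutually exclusive; highconf implies hit
  expect_false(any(res$hit_CXCR4pos & res$hit_CXCR4neg))
  expect_true(all(res$highconf_CXCR4pos <= res$hit_CXCR4pos))
  # disabling the missense filter restores guide 2
  res2 <- call_hits(fit, ann, exclude_missense = FALSE)
  expect_true(res2$hit_CXCR4pos[2])
  expect_error(call_hits(fit, ann, p_thresh = 0), "> 0")
})

test_that("hit calling is monotone in its thresholds", {
  s <- sim_norm(4000, 400, seed = 54,
                effects = data.frame(lfc = c(1, -1, 0.7, -0.7),
                                     fraction = rep(0.02, 4)))
  fit <- screen_nb_test(s$nm)
  tight <- call_hits(fit, p_thresh = 0.01, lfc_relaxed = 1)
  loose <- call_hits(fit, p_thresh = 0.05, lfc_relaxed = 0.58)
  for (fl in c("hit_CXCR4pos", "hit_CXCR4neg")) {
    expect_true(all(tight$sgRNA_id[tight[[fl]]] %in%
                      loose$sgRNA_id[loose[[fl]]]), label = fl)
  }
})

test_that("site collapse follows set semantics", {
  tab <- data.frame(
    sgRNA_id = sprintf("g%d", 1:6),
    site_id = c("sA", "sA", "sB", "sC", "sD", NA),
    is_nontargeting = c(rep(FALSE, 5), TRUE),
    hit_CXCR4neg = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    hit_CXCR4pos = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    highconf_CXCR4neg = FALSE, highconf_CXCR4pos = FALSE,
    stringsAsFactors = FALSE)
  out <- collapse_to_sites(tab)
  # two hit guides sharing a site -> 1 site, 2 guides
  expect_equal(out$n_sites[out$direction == "CXCR4neg"], 1L)
  expect_equal(out$n_sgrnas[out$direction == "CXCR4neg"], 2L)
  # three hit guides on three distinct sites -> 3 sites
  expect_equal(out$n_sites[out$direction == "CXCR4pos"], 3L)
  expect_true(all(out$n_sites <= out$n_sgrnas))
  expect_setequal(attr(out, "sites")$CXCR4neg, "sA")
})

test_that("non-targeting FPR is the fraction of controls passing the rule", {
  n <- 1000
  tab <- data.frame(
    sgRNA_id = sprintf("n%d", 1:n), is_nontargeting = TRUE,
    low_count_removed = FALSE,
    median_lfc = rep(0, n), p_low = rep(0.5, n), p_high = rep(0.5, n),
    stringsAsFactors = FALSE)
  # plant 19 passing in the negative direction, 17 in the positive
  tab$p_low[1:19] <- 0.01; tab$median_lfc[1:19] <- -1
  tab$p_high[21:37] <- 0.01; tab$median_lfc[21:37] <- 1
  fpr <- estimate_nontargeting_fpr(tab)
  expect_equal(unname(fpr), c(0.019, 0.017))
  expect_error(estimate_nontargeting_fpr(tab[0, ]), "no non-targeting")
})

test_that("baseline comparison classifies toxic and proliferative guides", {
  # single replicate, pc = 0: baseline 400 vs (150, 100) -> LFCs
  # (1.415, 2.0) -> toxic; 100 vs (100, 100) -> neither;
  # 250/100 = 2.5x vs 150/100 = 1.5x -> neither (AND rule);
  # 50 vs (250, 210) -> proliferative
  counts <- rbind(gT = c(400, 150, 100), gN = c(100, 100, 100),
                  gH = c(250, 100, 150), gP = c(50, 250, 210))
  counts <- balanced_counts(counts)
  colnames(counts) <- c("b1", "n1", "p1")
  cm <- count_matrix(counts,
                     role = c("baseline_d0", "CXCR4neg", "CXCR4pos"),
                     replicate = c(1, 1, 1))
  nm <- normalize_counts(cm)
  bl <- classify_baseline_effects(nm, pseudocount = 0)
  expect_equal(bl$toxic[bl$sgRNA_id %in% c("gT", "gN", "gH", "gP")],
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(bl$proliferative[bl$sgRNA_id %in% c("gT", "gN", "gH", "gP")],
               c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_baseline_effects(nm, baseline_role = "nope"),
               "missing baseline")
})

test_that("longitudinal calls threshold the day-N/day-0 LFC at 1", {
  counts <- rbind(gDown = c(1000, 100), gFlat = c(500, 500),
                  gUp = c(100, 900))
  counts <- balanced_counts(counts)
  colnames(counts) <- c("d0", "d30")
  cm <- count_matrix(counts, role = c("timepoint_d0", "timepoint_d30"),
                     replicate = c(1, 1))
  calls <- be3_longitudinal_calls(normalize_counts(cm), pseudocount = 0)
  expect_true(calls$depleted[calls$sgRNA_id == "gDown"])
  expect_equal(calls$lfc[calls$sgRNA_id == "gDown"], log2(100 / 1000))
  expect_false(calls$depleted[calls$sgRNA_id == "gFlat"] ||
                 calls$enriched[calls$sgRNA_id == "gFlat"])
  expect_true(calls$enriched[calls$sgRNA_id == "gUp"])
  expect_error(be3_longitudinal_calls(normalize_counts(
    count_matrix(counts, role = c("timepoint_d0", "x"),
                 replicate = c(1, 1))), pseudocount = 0),
    "missing timepoint")
})

test_that("power rises with effect size and depth", {
  recall_at <- function(lfc, depth, seed) {
    s <- sim_norm(3000, seed = seed, depth = depth,
                  effects = data.frame(lfc = lfc, fraction = 0.05))
    fit <- screen_nb_test(s$nm, low_count_threshold = 0)
    res <- call_hits(fit)
    hit <- if (lfc > 0) res$hit_CXCR4pos else res$hit_CXCR4neg
    mean(hit[s$truth$true_lfc != 0])
  }
  r_small <- recall_at(0.7, 750, 55)
  r_large <- recall_at(2.0, 750, 55)
  expect_gte(r_large, r_small)
  r_shallow <- recall_at(0.8, 150, 56)
  r_deep <- recall_at(0.8, 1500, 56)
  expect_gte(r_deep, r_shallow)
})

test_that("model methods expose the fit (print, coef, summary, simulate)", {
  s <- sim_norm(2000, 100, seed = 57)
  fit <- screen_nb_test(s$nm)
  expect_output(print(fit), "mean-variance trend")
  expect_named(coef(fit), c("k", "b"))
  expect_output(print(summary(fit)), "tested")
  nulls <- simulate(fit, nsim = 2, seed = 1)
  expect_length(nulls, 2)
  expect_equal(nrow(nulls[[1]]), sum(!fit$table$low_count_removed))
  expect_identical(simulate(fit, nsim = 1, seed = 9),
                   simulate(fit, nsim = 1, seed = 9))
})
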