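test_that("rank-sum p-values match wilcox.test on a small fixture", {
  set.seed(31)
  x <- matrix(c(rpois(8 * 12, 4), rep(2, 12)), 9, 12, byrow = FALSE)
  x <- rbind(x, matrix(rep(c(1, 2), 6), 1))   # heavy ties
  nm <- make_nm(log1p(x))
  a <- 1:6; b <- 7:12
  deg <- deg_wilcoxon(nm, a, b)
  for (g in seq_len(nrow(x))) {
    ref <- suppressWarnings(
      wilcox.test(log1p(x)[g, a], log1p(x)[g, b],
                  exact = FALSE, correct = TRUE)$p.value)
    expect_equal(deg$p_value[g], ref, tolerance = 1e-10)
  }
  # BH adjustment is monotone in the raw p order
  expect_true(all(diff(deg$adj_p[order(deg$p_value)]) >= -1e-12))
  expect_true(all(deg$adj_p >= deg$p_value - 1e-12))
})

test_that("identical groups yield no passing genes", {
  set.seed(32)
  nm <- make_nm(matrix(rpois(100 * 20, 3), 100, 20))
  deg <- deg_wilcoxon(nm, 1:10, 1:10)
  expect_equal(sum(deg$pass), 0L)
  expect_error(deg_wilcoxon(nm, 1:2, 3:20), ">= 3 cells")
})

test_that("spiked genes are recovered under the pass rule", {
  cfg <- sim_config(seed = 33, n_samples = 1, genes = 400,
                    cells_per_sample = c(malignant = 200,
                                         nonmalignant_B = 0, cd8_T = 0),
                    programs = list(program_spec(
                      sprintf("G%04d", 1:40), 1.5, 0.5, "S01",
                      name = "spike")))
  ch <- generate_cohort(cfg)
  nm <- normalize_log(ch$counts)
  act <- ch$truth$program_activity[, "spike"] == 1
  deg <- deg_wilcoxon(nm, which(act), which(!act))
  spiked <- deg$pass[deg$gene_id %in% sprintf("G%04d", 1:40)]
  expect_gte(mean(spiked), 0.9)
})

test_that("DEG runs identically on spliced and unspliced layers", {
  cfg <- sim_config(seed = 37, n_samples = 1, genes = 300,
                    cells_per_sample = c(malignant = 120,
                                         nonmalignant_B = 0, cd8_T = 0),
                    programs = list(program_spec(
                      sprintf("G%04d", 1:30), 1.5, 0.5, "S01",
                      name = "spike")),
                    emit_layers = TRUE)
  ch <- generate_cohort(cfg)
  expect_named(ch$layers, c("spliced", "unspliced"))
  expect_equal(dim(ch$layers$spliced$counts), dim(ch$counts$counts))
  act <- ch$truth$program_activity[, "spike"] == 1
  for (layer in ch$layers) {
    deg <- deg_wilcoxon(normalize_log(layer), which(act), which(!act))
    expect_gte(mean(deg$pass[deg$gene_id %in% sprintf("G%04d", 1:30)]),
               0.9)
  }
})

test_that("exhaustion scoring compares groups and tolerates singletons", {
  set.seed(34)
  g <- 120; n <- 60
  base <- matrix(rpois(g * n, 4) + 0.0, g, n)
  base[1:10, 1:30] <- base[1:10, 1:30] * 4    # shifted group
  nm <- make_nm(log1p(base))
  ex_set <- sprintf("g%03d", 1:10)
  groups <- rep(c("hot", "cold"), each = 30)
  res <- exhaustion_scores(nm, ex_set, groups, n_bins = 10,
                           ctrl_per_gene = 20, seed = 5)
  expect_equal(nrow(res$pairwise), 1L)
  expect_lt(res$pairwise$p_value, 1e-6)
  expect_gt(median(res$scores[groups == "hot"]),
            median(res$scores[groups == "cold"]))
  # a single usable group returns scores without tests
  res1 <- expect_warning(
    exhaustion_scores(nm, ex_set, c(rep("a", 58), "b", "c"),
                      n_bins = 10, ctrl_per_gene = 20, seed = 5),
    "excluding groups")
  expect_null(res1$pairwise)
})

test_that("log-rank statistic matches the hand-worked example", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1,
                  group = c("A", "A", "B", "B"))
  lr <- logrank_test(d$time, d$event, d$group == "A")
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 0.8333, tolerance = 1e-4)
  expect_equal(lr$variance, 0.4722, tolerance = 1e-4)
  expect_equal(lr$chisq, 2.882, tolerance = 1e-3)
  # identical arms: duplicated data split evenly
  d2 <- data.frame(time = rep(c(1, 2, 5), 2), event = 1,
                   group = rep(c("A", "B"), each = 3))
  lr2 <- logrank_test(d2$time, d2$event, d2$group == "A")
  expect_equal(lr2$chisq, 0)
  expect_equal(lr2$p_value, 1)
  # label swap leaves the chi-square unchanged
  expect_equal(logrank_test(d$time, d$event, d$group == "B")$chisq,
               lr$chisq)
})

test_that("log-rank agrees with survival::survdiff across random data", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    time <- rexp(n, 0.2)
    event <- rbinom(n, 1, 0.8)
    grp <- rbinom(n, 1, 0.5) == 1
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    mine <- logrank_test(time, event, grp)
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
  }
})

test_that("optimal cutpoint honors minprop and maximality", {
  set.seed(36)
  # exhaustive admissibility check on small n
  for (n in 5:15) {
    d <- data.frame(time = rexp(n, 0.3), event = rbinom(n, 1, 0.9),
                    score = runif(n))
    if (sum(d$event) == 0) d$event[1] <- 1
    cp <- try(optimal_cutpoint(d, minprop = 0.3), silent = TRUE)
    if (inherits(cp, "try-error")) next
    hi <- sum(d$score > cp$cutpoint)
    expect_gte(min(hi, n - hi) / n, 0.3)
    # the chosen statistic dominates every admissible candidate
    expect_true(all(cp$candidates$abs_z <= cp$statistic + 1e-12))
    s <- sort(unique(d$score))
    mids <- (s[-1] + s[-length(s)]) / 2
    inadmissible <- mids[vapply(mids, function(c) {
      h <- sum(d$score > c); min(h, n - h) / n < 0.3
    }, TRUE)]
    expect_false(cp$cutpoint %in% inadmissible)
  }
  # constant scores: no candidate exists
  dc <- data.frame(time = 1:4, event = 1, score = rep(2, 4))
  expect_error(optimal_cutpoint(dc), "constant|no candidate")
})

test_that("Kaplan-Meier curves reduce to the empirical survival", {
  d <- data.frame(time = c(1, 2, 3, 4, 6, 9), event = 1,
                  score = c(0, 0, 0, 1, 1, 1))
  km <- km_logrank(d, 0.5)
  s_low <- summary(km$fit)$surv[summary(km$fit)$strata == "arm=low"]
  expect_equal(s_low, c(2 / 3, 1 / 3, 0))      # empirical survival
  expect_true(all(diff(s_low) <= 0))
  d0 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                   score = c(0, 0, 1, 1))
  expect_warning(km_logrank(d0, 0.5), "zero events")
})
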