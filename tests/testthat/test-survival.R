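test_that("t-SNE stratification separates planted activity blobs exactly", {
  set.seed(17)
  n <- 20
  high <- matrix(rnorm(7 * n, mean = 2.5, sd = 0.5), 7)
  low <- matrix(rnorm(7 * n, mean = -2.5, sd = 0.5), 7)
  act <- cbind(high, low)
  dimnames(act) <- list(paste0("PW", 1:7), sprintf("S%02d", 1:(2 * n)))
  class(act) <- c("activity_matrix", "matrix", "array")
  attr(act, "level") <- "expression"
  st <- stratify(act, seed = 3)
  truth <- rep(c("high", "low"), each = n)
  expect_equal(as.character(st$group[sprintf("S%02d", 1:(2 * n))]), truth)
  # determinism under the same seed
  st2 <- stratify(act, seed = 3)
  expect_identical(st$group, st2$group)
  expect_identical(st$embedding, st2$embedding)
  # contract errors
  expect_error(stratify(act[, 1:4], seed = 1), ">= 6 samples")
  expect_error(stratify(act, seed = 1, perplexity = 20), "perplexity")
})

test_that("log-rank matches the hand-computed O-E table on a 4-patient toy", {
  # group A: events at days 1, 2; group B: censored at 3, 3
  # t=1: 4 at risk (2A), E_A = 1/2, V = 1*2*2*3/(4^2*3) = 1/4
  # t=2: 3 at risk (1A), E_A = 1/3, V = 1*1*2*2/(3^2*2) = 2/9
  # chisq = (2 - 5/6)^2 / (1/4 + 2/9) = 49/17
  cl <- make_clinical(c("A1", "A2", "B1", "B2"),
                      time = c(1, 2, 3, 3), event = c(1, 1, 0, 0))
  g <- setNames(c("A", "A", "B", "B"), cl$sample_id)
  res <- km_logrank(g, cl)
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(res$p, pchisq(49 / 17, 1, lower.tail = FALSE))
  # label swap leaves the statistic unchanged
  g2 <- setNames(c("B", "B", "A", "A"), cl$sample_id)
  expect_equal(km_logrank(g2, cl)$statistic, res$statistic)
})

test_that("log-rank degenerates gracefully for identical curves", {
  cl <- make_clinical(paste0("S", 1:8),
                      time = rep(c(5, 10, 15, 20), 2),
                      event = rep(c(1, 0, 1, 0), 2))
  g <- setNames(rep(c("A", "B"), each = 4),
                c("S1", "S2", "S3", "S4", "S5", "S6", "S7", "S8"))
  # same times/events in both groups: statistic 0
  res <- km_logrank(g, cl)
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)
  expect_error(km_logrank(setNames(rep("A", 8), cl$sample_id), cl),
               "two non-empty groups")
})

test_that("Cox fit matches a grid-search partial-likelihood oracle and
           inverts under label swap", {
  cl <- make_clinical(paste0("S", 1:6),
                      time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
  x <- c(1, 0, 1, 0, 1, 0)
  design <- data.frame(sample_id = cl$sample_id,
                       group = factor(ifelse(x == 1, "high", "low"),
                                      levels = c("low", "high")))
  fit <- cox_model(design, cl)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = cl$time_to_event, event = cl$event, x = x)
  expect_equal(log(fit$hr), grid[which.max(ll)], tolerance = 1e-3)

  design2 <- design
  design2$group <- factor(ifelse(x == 1, "low", "high"),
                          levels = c("low", "high"))
  fit2 <- cox_model(design2, cl)
  expect_equal(fit2$hr, 1 / fit$hr, tolerance = 1e-8)

  expect_error(cox_model(data.frame(sample_id = cl$sample_id,
                                    group = rep("high", 6)), cl),
               "constant")
})

test_that("null covariates give uniform Cox LR p-values", {
  set.seed(23)
  ps <- vapply(1:200, function(i) {
    n <- 30
    cl <- make_clinical(paste0("S", 1:n),
                        time = rexp(n, 1 / 300),
                        event = rbinom(n, 1, 0.8))
    g <- rnorm(n)
    cox_model(data.frame(sample_id = cl$sample_id, score = g), cl)$lr_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("signature covariate is the mean z-score of signature genes", {
  set.seed(31)
  x <- matrix(rnorm(50 * 6), 50,
              dimnames = list(sprintf("G%02d", 1:50), paste0("S", 1:6)))
  expr <- omics_matrix(x, "expression")
  one <- signature_covariate(expr, "G05")
  z <- (x["G05", ] - mean(x["G05", ])) / sd(x["G05", ])
  expect_equal(one, z)
  # constant shift of all signature genes in one sample moves the score
  x2 <- x; x2[c("G01", "G02"), 1] <- x2[c("G01", "G02"), 1] + 3
  s1 <- signature_covariate(expr, c("G01", "G02"))
  s2 <- signature_covariate(omics_matrix(x2, "expression"), c("G01", "G02"))
  expect_gt(s2[["S1"]], s1[["S1"]])
  expect_error(signature_covariate(expr, "NOPE"), "no signature gene")
})

test_that("random models apply the add-one empirical p formula", {
  set.seed(5)
  cl <- make_clinical(sprintf("S%02d", 1:20),
                      time = rexp(20, 1 / 300), event = rbinom(20, 1, 0.7))
  rm2 <- random_group_model(observed_p = 1e-6, n_per_group = c(10, 10),
                            clinical = cl, n_draws = 200, seed = 2)
  # observed smaller than every null -> p at the formula floor
  expect_equal(rm2$empirical_p, 1 / 201)
  rm2b <- random_group_model(observed_p = 1e-6, n_per_group = c(10, 10),
                             clinical = cl, n_draws = 200, seed = 2)
  expect_identical(rm2$null_ps, rm2b$null_ps)
  # direct formula evaluation on a constructed null set
  obs <- 0.02
  nulls <- c(rep(0.01, 30), rep(0.5, 9970))
  expect_equal((sum(nulls <= obs) + 1) / (length(nulls) + 1),
               31 / 10001)
  expect_equal(pathchemo:::empirical_p(obs, nulls), 31 / 10001)
})

test_that("random pathway model recomputes activity per draw", {
  set.seed(6)
  n_genes <- 120
  x <- matrix(rnorm(n_genes * 10), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes), sprintf("S%02d", 1:10)))
  z <- zscore_rows(omics_matrix(x, "expression"))
  col <- pathway_collection(split(sprintf("G%03d", 1:120),
                                  rep(1:12, each = 10)))
  names(col) <- paste0("PW", 1:12)
  cl <- make_clinical(sprintf("S%02d", 1:10),
                      time = rexp(10, 1 / 300), event = rep(1, 10))
  rm1 <- random_pathway_model(observed_p = 0.5, zscored = z, collection = col,
                              clinical = cl, k = 3, n_draws = 4,
                              n_perm = 120, seed = 8,
                              stratify_args = list(max_iter = 120))
  expect_length(rm1$null_ps, 4)
  expect_true(all(rm1$null_ps > 0 & rm1$null_ps <= 1))
  expect_gte(rm1$empirical_p, 1 / 5)
})

test_that("LOOCV risk separates planted outcomes and respects contracts", {
  set.seed(51)
  n <- 16
  act <- rbind(PW1 = c(rnorm(8, 5), rnorm(8, -5)),
               PW2 = rnorm(n))
  colnames(act) <- sprintf("S%02d", 1:n)
  outcome <- setNames(rep(c(1, 0), each = 8), colnames(act))
  res <- loocv_risk(act, outcome)
  expect_equal(res$accuracy, 1.0)
  # separation handled by the ridge fallback, flagged
  expect_true(length(res$flagged_folds) > 0)

  expect_error(loocv_risk(act[, 1:6], outcome[1:6]), ">= 8")
  expect_error(loocv_risk(act, setNames(rep(1, n), colnames(act))),
               "both outcome classes")
})

test_that("LOOCV accuracy is near chance for independent labels", {
  set.seed(52)
  accs <- vapply(1:20, function(i) {
    n <- 20
    act <- matrix(rnorm(3 * n), 3,
                  dimnames = list(paste0("PW", 1:3), sprintf("S%02d", 1:n)))
    outcome <- setNames(sample(rep(0:1, each = n / 2)), colnames(act))
    suppressWarnings(loocv_risk(act, outcome)$accuracy)
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.15)
})

test_that("AUROC follows the concordant-pair formulation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.7, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # invariant under strictly monotone transforms; matches pROC
  set.seed(61)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(sc), lb), a)
  expect_equal(roc_auc(rank(sc), lb), a)
  expect_equal(a, as.numeric(suppressMessages(pROC::auc(lb, sc))))
  expect_error(roc_auc(sc, rep(1, 40)), "both classes")
})
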