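toy_cohort <- function(expr, os_time = NULL, os_event = NULL) {
  n <- nrow(expr)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("PT%02d", seq_len(n))
  if (is.null(os_time)) os_time <- seq_len(n) * 10
  if (is.null(os_event)) os_event <- rep(1L, n)
  new_bulk_cohort(expr, data.frame(patient_id = rownames(expr),
                                   os_time = os_time, os_event = os_event,
                                   stringsAsFactors = FALSE))
}

test_that("median binarization uses >= with midpoint medians", {
  expr <- cbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(1, 1, 2, 9))
  cohort <- toy_cohort(expr)
  bin <- binarize_vs_median(cohort, c("g1", "g2", "g3"))
  expect_equal(unname(bin[, "g1"]), c(0L, 0L, 1L, 1L))  # median 2.5
  expect_equal(unname(bin[, "g2"]), c(1L, 1L, 1L, 1L))  # constant gene
  expect_equal(unname(bin[, "g3"]), c(0L, 0L, 1L, 1L))  # median 1.5

  # odd cohort: the patient exactly at the median scores 1
  expr5 <- cbind(g1 = c(1, 2, 3, 4, 5))
  bin5 <- binarize_vs_median(toy_cohort(expr5), "g1")
  expect_equal(unname(bin5[, 1]), c(0L, 0L, 1L, 1L, 1L))

  expect_warning(b <- binarize_vs_median(cohort, c("g1", "nope")), "absent")
  expect_equal(ncol(b), 1)
  expect_error(binarize_vs_median(cohort, "nope"), "no signature gene")
})

test_that("patient scores are row sums conserving the total mass", {
  set.seed(50)
  bin <- matrix(rbinom(80, 1, 0.5), nrow = 8,
                dimnames = list(sprintf("P%d", 1:8), sprintf("g%d", 1:10)))
  s <- score_patients(bin)
  expect_equal(unname(s), unname(rowSums(bin)))
  expect_equal(sum(s), sum(bin))
  expect_true(all(s >= 0 & s <= 10))
  # hand-built 4 x 3 check
  hand <- rbind(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1), c(0, 1, 0))
  rownames(hand) <- paste0("P", 1:4)
  expect_equal(unname(score_patients(hand)), c(2L, 0L, 3L, 1L))
})

test_that("quartile stratification takes ceiling(n/4) with inclusive ties", {
  s <- setNames(1:8, paste0("P", 1:8))
  g <- stratify_quartiles(s)
  expect_identical(unname(g[c("P7", "P8")]), c("high", "high"))
  expect_identical(unname(g[c("P1", "P2")]), c("low", "low"))
  expect_equal(sum(g == "excluded"), 4)

  # boundary tie pulls all tied patients into the adjacent group
  s2 <- setNames(c(1, 1, 1, 2, 3, 4, 5, 5), paste0("P", 1:8))
  g2 <- stratify_quartiles(s2)
  expect_equal(sum(g2 == "low"), 3)
  expect_equal(sum(g2 == "high"), 2)

  s3 <- setNames(sample(1:100), paste0("P", 1:100))
  g3 <- stratify_quartiles(s3)
  expect_equal(sum(g3 == "high"), 25)
  expect_equal(sum(g3 == "low"), 25)

  expect_error(stratify_quartiles(setNames(rep(2, 10), paste0("P", 1:10))),
               "identical")
  expect_error(stratify_quartiles(setNames(1:5, paste0("P", 1:5))),
               "at least 8")
})

test_that("stratification is invariant to monotone score transforms", {
  set.seed(51)
  s <- setNames(sample(0:20, 40, TRUE), paste0("P", 1:40))
  if (length(unique(s)) == 1) s[1] <- s[1] + 1
  g1 <- stratify_quartiles(s)
  g2 <- stratify_quartiles(s^3 + 2)
  expect_identical(g1, g2)
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # all events at 1, 2, 3
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored
  km0 <- kaplan_meier(c(5, 8, 2), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # 6-subject mixed fixture: times 1, 2+, 3, 4, 5+, 6
  km6 <- kaplan_meier(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(km6$survival,
               c(5 / 6, 5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3,
                 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_true(all(diff(km6$survival) <= 0))
  expect_error(kaplan_meier(numeric(), numeric()), "empty")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(52)
  t <- round(rexp(40, 0.1), 1)
  km <- kaplan_meier(t, rep(1, 40))
  emp <- sapply(km$time, function(u) mean(t > u))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed 6-subject fixture", {
  high <- list(times = c(1, 3, 5), events = c(1, 1, 0))
  low <- list(times = c(2, 4, 6), events = c(1, 1, 1))
  res <- logrank_hr(high, low)
  expect_equal(res$o_e$observed, c(2, 3))
  expect_equal(res$o_e$expected[1], 1.7333333333, tolerance = 1e-9)
  expect_equal(res$chi_square, 0.0739030023, tolerance = 1e-9)
  expect_equal(res$p_value, 0.7857365380, tolerance = 1e-9)
  expect_equal(res$hr, 1.2564102564, tolerance = 1e-9)
  expect_lt(res$ci95[1], res$hr)
  expect_gt(res$ci95[2], res$hr)
})

test_that("log-rank is symmetric: identical groups and label swaps", {
  g <- list(times = c(1, 2, 3, 4), events = c(1, 1, 0, 1))
  res <- logrank_hr(g, g)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$hr, 1)

  set.seed(53)
  a <- list(times = rexp(30), events = rbinom(30, 1, 0.8))
  b <- list(times = rexp(30, 2), events = rbinom(30, 1, 0.8))
  r1 <- logrank_hr(a, b)
  r2 <- logrank_hr(b, a)
  expect_equal(r1$hr, 1 / r2$hr, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(logrank_hr(list(times = 1, events = 0),
                          list(times = 2, events = 0)), "no events")
})

test_that("log-rank chi-square matches the reference on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(54)
  for (i in 1:100) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    t1 <- rexp(n1); e1 <- rbinom(n1, 1, 0.7)
    t2 <- rexp(n2, 1.5); e2 <- rbinom(n2, 1, 0.7)
    if (sum(e1) + sum(e2) == 0) next
    res <- logrank_hr(list(times = t1, events = e1),
                      list(times = t2, events = e2))
    ref <- survival::survdiff(
      survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(n1, n2)))
    expect_equal(res$chi_square, ref$chisq, tolerance = 1e-6)
  }
})

test_that("the Cox cross-check HR tracks the Mantel-Haenszel HR", {
  skip_if_not_installed("survival")
  set.seed(55)
  a <- list(times = rexp(60, 2), events = rbinom(60, 1, 0.8))
  b <- list(times = rexp(60, 1), events = rbinom(60, 1, 0.8))
  mh <- logrank_hr(a, b)
  cox <- logrank_hr(a, b, hr_method = "cox")
  expect_equal(log(mh$hr), log(cox$hr), tolerance = 0.2)
})

test_that("signature_survival composes the steps and exposes audit fields", {
  sim <- simulate_bulk(bulk_sim_config(n_patients = 120, seed = 56))
  sig <- bulk_sim_config()$signature_genes
  res <- signature_survival(sim$cohort, sig)
  expect_s3_class(res, "SurvivalResult")
  expect_length(res$scores, 120)
  expect_true(all(res$groups %in% c("high", "low", "excluded")))
  expect_true(all(res$scores >= 0 & res$scores <= length(sig)))
  # planted hazardous signature: high group fares worse
  expect_gt(res$hr, 1)
  # score conservation
  bin <- binarize_vs_median(sim$cohort, sig)
  expect_equal(sum(res$scores), sum(bin))
})

test_that("estimated hazard ratio is monotone in the planted effect", {
  med_hr <- sapply(c(0, 0.5, 1.0), function(beta) {
    hrs <- sapply(1:30, function(i) {
      sim <- simulate_bulk(bulk_sim_config(n_patients = 200, beta = beta,
                                           seed = 1000 * beta + i))
      signature_survival(sim$cohort, bulk_sim_config()$signature_genes)$hr
    })
    median(hrs)
  })
  expect_true(all(diff(med_hr) > 0))
})

test_that("detection power grows with cohort size and effect size", {
  reject <- function(n, beta, reps = 25) {
    mean(sapply(seq_len(reps), function(i) {
      sim <- simulate_bulk(bulk_sim_config(n_patients = n, beta = beta,
                                           seed = 7000 + 100 * n + i))
      signature_survival(sim$cohort,
                         bulk_sim_config()$signature_genes)$p_value < 0.05
    }))
  }
  grid <- c(small_null = reject(60, 0.2), small_eff = reject(60, 1.3),
            large_null = reject(240, 0.2), large_eff = reject(240, 1.3))
  expect_gt(grid["small_eff"], grid["small_null"])
  expect_gt(grid["large_eff"], grid["large_null"])
  expect_gte(grid["large_eff"], grid["small_eff"])
})
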