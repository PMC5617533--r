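test_that("Kaplan-Meier estimates match hand product-limit results", {
  # no censoring, half the events before t
  km <- km_estimate(c(1, 2, 10, 11), c(1, 1, 1, 1))
  expect_equal(survival_at(km, 5), 0.5, ignore_attr = TRUE)
  # all censored
  km <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_equal(survival_at(km, 9), 1, ignore_attr = TRUE)
  # times 1, 2, 3 all events: S(2) = (1 - 1/3)(1 - 1/2) = 1/3
  km <- km_estimate(1:3, rep(1, 3))
  expect_equal(survival_at(km, 2), 1 / 3, ignore_attr = TRUE)
  expect_equal(survival_at(km, 0), 1, ignore_attr = TRUE)
})

test_that("survival_at flags evaluation beyond the observed follow-up", {
  km <- km_estimate(c(12, 20, 40, 50), c(1, 1, 0, 1))
  expect_equal(as.numeric(survival_at(km, 36)), 0.5)
  expect_false(attr(survival_at(km, 36), "extrapolated"))
  expect_true(attr(survival_at(km, 60), "extrapolated"))
})

test_that("KM agrees with the brute-force estimator on exhaustive fixtures", {
  times <- c(1, 2, 2, 3, 4, 4)  # includes ties
  for (code in 1:63) {          # every event pattern with >= 1 event
    ev <- as.integer(intToBits(code)[1:6])
    km <- km_estimate(times, ev)
    for (t in c(0.5, 2, 3.5, 4))
      expect_equal(as.numeric(survival_at(km, t)), bf_km_at(times, ev, t),
                   tolerance = 1e-12)
  }
})

test_that("log-rank statistic equals the hand risk-table computation", {
  # identical groups: statistic 0, p 1
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  # textbook two-group fixture, computed from the O/E/V tables
  tm <- c(3, 5, 7, 9, 18, 2, 4, 6, 8, 10)
  ev <- c(1, 1, 0, 1, 1, 1, 1, 1, 1, 0)
  gr <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$chisq, bf_logrank2(tm, ev, gr), tolerance = 1e-10)
  expect_equal(lr$df, 1)
  # exhaustive small fixtures with ties
  times <- c(1, 1, 2, 3, 3, 4, 5, 6)
  grp <- c(1, 2, 1, 2, 1, 2, 1, 2)
  for (code in 1:255) {
    evv <- as.integer(intToBits(code)[1:8])
    if (sum(evv) == 0) next
    got <- logrank_test(times, evv, grp)
    want <- bf_logrank2(times, evv, grp)
    if (is.finite(want))
      expect_equal(got$chisq, want, tolerance = 1e-9)
  }
})

test_that("multi-group log-rank p-values are uniform under the null", {
  set.seed(55)
  pv <- replicate(60, {
    tm <- rexp(60, 0.05); ev <- as.integer(tm < 30)
    logrank_test(pmin(tm, 30), ev, sample(1:4, 60, TRUE))$p
  })
  expect_lt(mean(pv < 0.05), 0.2)
  expect_gt(mean(pv > 0.4), 0.3)
})

test_that("cutoff search returns the admissible log-rank argmax", {
  values <- 1:10
  times <- as.numeric(values)
  res <- find_cutoff(values, times, rep(1, 10), min_group_frac = 0.1)
  # the exhaustive scan puts the maximum at 3.5 (chisq 11.25), not at the
  # median split (chisq 9.70): early deaths carry the statistic
  expect_equal(res$cutoff, 3.5)
  expect_identical(res$direction, "le")  # low values die early
  # independent re-scan over every admissible midpoint
  sv <- sort(unique(values))
  cands <- (sv[-1] + sv[-length(sv)]) / 2
  stats <- vapply(cands, function(cut) {
    lo <- values <= cut
    if (sum(lo) < 1 || sum(!lo) < 1) return(NA_real_)
    bf_logrank2(times, rep(1, 10), lo)
  }, numeric(1))
  expect_equal(res$chisq, max(stats, na.rm = TRUE), tolerance = 1e-9)
  expect_equal(res$cutoff, cands[which.max(stats)])
  expect_error(find_cutoff(rep(2, 6), 1:6, rep(1, 6)), "constant")
})

test_that("cutoff search honours the minimum group-size guard", {
  set.seed(77)
  values <- rnorm(40)
  tm <- rexp(40, 0.1); ev <- rep(1, 40)
  res <- find_cutoff(values, tm, ev, min_group_frac = 0.25)
  expect_gte(res$n_low, 10)
  expect_gte(res$n_high, 10)
  # n = 2 with a 10% guard leaves exactly one admissible cutoff
  r2 <- find_cutoff(c(1, 2), c(5, 9), c(1, 1), min_group_frac = 0.1)
  expect_equal(r2$cutoff, 1.5)
})

test_that("selected cutoff p-values are optimistically biased under the null", {
  set.seed(202)
  pv <- replicate(40, {
    v <- rnorm(60); tm <- rexp(60, 0.05); ev <- as.integer(tm < 25)
    find_cutoff(v, pmin(tm, 25), ev)$p
  })
  # selection bias: far more small p than the nominal 5%
  expect_gt(mean(pv < 0.05), 0.1)
})

test_that("Cox regression matches a brute-force partial likelihood", {
  # six patients, one binary covariate, no ties
  tm <- c(2, 4, 6, 8, 10, 12)
  ev <- c(1, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- fit_cox(data.frame(x = x), tm, ev)
  # independent route: maximize the partial likelihood by direct search
  logpl <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      rs <- tm >= tm[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }
  bhat <- stats::optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$coef$log_hr, bhat, tolerance = 1e-4)
})

test_that("Cox estimates recover simulated effects within 3 SE", {
  set.seed(404)
  n <- 2000
  x <- rnorm(n)
  tm <- rexp(n, 0.05)                  # x has no effect
  ev <- as.integer(tm < 40)
  fit <- fit_cox(data.frame(x = x), pmin(tm, 40), ev)
  expect_lt(abs(fit$coef$log_hr), 3 * fit$coef$se)
  # true hazard ratio 2 on a binary covariate
  z <- rbinom(n, 1, 0.5)
  tm2 <- rexp(n, 0.03 * 2^z)
  ev2 <- as.integer(tm2 < 50)
  fit2 <- fit_cox(data.frame(z = z), pmin(tm2, 50), ev2)
  expect_lt(abs(fit2$coef$log_hr - log(2)), 3 * fit2$coef$se)
})

test_that("Cox guards reject degenerate inputs", {
  expect_error(fit_cox(data.frame(x = rep(1, 10)), rexp(10), rep(1, 10)),
               "constant")
  expect_error(fit_cox(data.frame(x = rnorm(10), y = rnorm(10)),
                       rexp(10), c(1, rep(0, 9))), "events")
})
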