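test_that("pooling reproduces concatenated raw-sample statistics exactly", {
  # identity on a single summary
  one <- pooled_mean_sd(data.frame(mean = 10, sd = 2, n = 5))
  expect_equal(one$mean, 10)
  expect_equal(one$sd, 2)
  expect_equal(one$n_total, 5)

  two <- pooled_mean_sd(data.frame(mean = c(10, 20), sd = c(0, 0), n = c(5, 5)))
  expect_equal(two$mean, 15)

  # concatenation oracle over 20 random groups
  set.seed(21)
  groups <- lapply(1:20, function(i) rnorm(sample(2:40, 1), mean = runif(1, 40, 80),
                                           sd = runif(1, 1, 12)))
  summaries <- data.frame(
    mean = vapply(groups, mean, 1), sd = vapply(groups, sd, 1),
    n = lengths(groups)
  )
  pooled <- pooled_mean_sd(summaries)
  raw <- unlist(groups)
  expect_equal(pooled$mean, mean(raw), tolerance = 1e-9)
  expect_equal(pooled$sd, sd(raw), tolerance = 1e-9)
  expect_equal(sum(pooled$weights[[1]]), 1, tolerance = 1e-12)

  # invariant to cohort order and to splitting a cohort in two
  expect_equal(pooled_mean_sd(summaries[sample(20), ])$sd, pooled$sd,
               tolerance = 1e-12)
  split_first <- rbind(
    data.frame(mean = mean(groups[[1]][1:2]), sd = sd(groups[[1]][1:2]), n = 2),
    data.frame(mean = mean(groups[[1]][-(1:2)]), sd = sd(groups[[1]][-(1:2)]),
               n = lengths(groups)[1] - 2),
    summaries[-1, ]
  )
  resplit <- pooled_mean_sd(split_first)
  expect_equal(resplit$mean, pooled$mean, tolerance = 1e-9)
  expect_equal(resplit$sd, pooled$sd, tolerance = 1e-9)

  expect_error(pooled_mean_sd(data.frame(mean = 1, sd = -1, n = 3)), "negative")
  expect_error(pooled_mean_sd(data.frame(mean = numeric(), sd = numeric(),
                                         n = integer())), "no summaries")
})

test_that("Gaussian onset/survival models behave as stated", {
  m <- fit_gaussian(59.19, 9.12, support = c(30, 100))
  expect_equal(m$mu, 59.19)
  expect_equal(ml_age(m), 59.19)
  expect_error(fit_gaussian(60, 0), "sd")

  # density integrates to >= 0.99 over +/- 4 sigma
  mass <- stats::integrate(function(x) dnorm(x, m$mu, m$sigma),
                           m$mu - 4 * m$sigma, m$mu + 4 * m$sigma)$value
  expect_gte(mass, 0.99)
  # support truncation zeroes the density outside
  expect_equal(model_density(m, 20), 0)

  surv <- fit_gaussian(7.19, 2.60, support = c(0, 30))
  expect_equal(survival_probability(surv, 7.19), 0.5)
  ts <- seq(0.5, 29.5, by = 1)
  expect_true(all(diff(survival_probability(surv, ts)) < 0))
  expect_gt(survival_probability(surv, 0.01), 0.99)
  expect_lt(survival_probability(surv, 29.9), 0.001)
  expect_error(survival_probability(surv, 31), "support")

  # Monte-Carlo oracle
  set.seed(99)
  draws <- rnorm(1e6, 7.19, 2.60)
  expect_equal(survival_probability(surv, 10), mean(draws > 10),
               tolerance = 0.003)
})

test_that("age-conditional priors normalise and weight correctly", {
  m1 <- fit_gaussian(60, 10)
  pr <- age_prior(55, list(A = m1, B = m1))
  expect_equal(pr$prior, c(0.5, 0.5))

  onset_models <- list(
    PD = fit_gaussian(62.75, 11.11), MSA = fit_gaussian(59.19, 9.12),
    PSP = fit_gaussian(65.60, 8.10), DLB = fit_gaussian(69.34, 10.46),
    CBD = fit_gaussian(62.64, 7.78)
  )
  pr45 <- age_prior(45, onset_models)
  expect_equal(pr45$disease[which.max(pr45$prior)], "MSA")
  expect_equal(sum(pr45$prior), 1, tolerance = 1e-12)
  # direct pdf-evaluation oracle
  dens <- vapply(onset_models, function(m) dnorm(45, m$mu, m$sigma), 1)
  expect_equal(pr45$prior, unname(dens / sum(dens)), tolerance = 1e-12)

  # scale invariance of weights
  w <- c(PD = 2, MSA = 1, PSP = 3, DLB = 1, CBD = 0.5)
  expect_equal(age_prior(45, onset_models, w)$prior,
               age_prior(45, onset_models, w * 1000)$prior, tolerance = 1e-12)
  expect_error(age_prior(45, onset_models, w * 0), "zero")
})

test_that("disease profiles pool cohorts and respect missing-is-not-zero", {
  c1 <- cohort_annotation("S:1", 2000L, "a", "PD", 20L,
                          phenotypes = tibble::tibble(term_id = "HP:0001337",
                                                      n_present = 10L,
                                                      n_assessed = 20L))
  c2 <- cohort_annotation("S:2", 2001L, "a", "PD", 30L,
                          phenotypes = tibble::tibble(term_id = "HP:0001337",
                                                      n_present = 5L,
                                                      n_assessed = 30L))
  c3 <- cohort_annotation("S:3", 2002L, "a", "PD", 40L)  # does not assess it
  prof <- build_profile(dplyr::bind_rows(c1, c2, c3), "PD")
  row <- prof$phenotype_table
  expect_equal(row$n_present, 15)
  expect_equal(row$n_assessed, 50)   # c3 contributes nothing
  expect_equal(prof$n_cases, 90)
  expect_error(build_profile(c1, "MSA"), "no cohorts")
})

test_that("propagation rolls counts up the is-a hierarchy conservatively", {
  g <- mini_graph()
  ann <- cohort_annotation(
    "S:4", 2000L, "a", "PD", 100L,
    phenotypes = tibble::tibble(
      term_id = c("HP:0002322", "HP:0002345"),  # resting + action tremor
      n_present = c(60L, 20L), n_assessed = c(100L, 80L))
  )
  prof <- build_profile(ann, "PD", graph = g, propagate = TRUE)
  tab <- prof$phenotype_table
  tremor <- tab[tab$term_id == "HP:0001337", ]
  expect_equal(tremor$n_present, 60)    # max mode: conservative lower bound
  expect_equal(tremor$n_assessed, 100)
  expect_true(tremor$propagated)
  prof2 <- build_profile(ann, "PD", graph = g, propagate = TRUE,
                         aggregate_mode = "capped_sum")
  tremor2 <- prof2$phenotype_table[prof2$phenotype_table$term_id == "HP:0001337", ]
  expect_equal(tremor2$n_present, 80)   # upper bound
})

test_that("profile estimates recover a planted frequency (binomial CI oracle)", {
  set.seed(31)
  n <- 400L
  anns <- dplyr::bind_rows(lapply(1:5, function(i) {
    k <- rbinom(1, n, 0.30)
    cohort_annotation(sprintf("S:%d", i), 2000L, "a", "PD", n,
                      phenotypes = tibble::tibble(term_id = "HP:0001337",
                                                  n_present = k,
                                                  n_assessed = n))
  }))
  prof <- build_profile(anns, "PD")
  tab <- prof$phenotype_table
  ci <- binom.test(tab$n_present, tab$n_assessed, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.30 && 0.30 <= ci[2])
})

test_that("rank-based group tests match exact references", {
  # identical groups: omnibus not significant, no pairwise tests run
  same <- data.frame(group = rep(c("a", "b"), each = 5),
                     value = rep(c(1, 3, 5, 7, 9), 2))
  gt <- group_tests(same)
  expect_gt(gt$omnibus$p_value, 0.05)
  expect_equal(nrow(gt$pairwise), 0L)
  # forcing the pairwise stage on identical groups gives p = 1
  gt_forced <- group_tests(same, alpha_omnibus = 1.01)
  expect_gte(gt_forced$pairwise$p_value, 0.99)

  # tiny separated groups: exact permutation p-value 2/choose(6,3) = 0.1
  sep <- data.frame(group = rep(c("lo", "hi"), each = 3),
                    value = c(1, 2, 3, 101, 102, 103))
  gt2 <- group_tests(sep, alpha_omnibus = 1.01)
  expect_equal(gt2$pairwise$p_value, 0.1, tolerance = 1e-12)
  expect_false(gt2$pairwise$significant)  # n far too small for 0.005

  # omnibus statistic against a hand rank computation (3 groups, no ties)
  d <- data.frame(group = rep(c("a", "b", "c"), times = c(4, 3, 5)),
                  value = c(12, 5, 9, 20, 1, 18, 3, 7, 15, 2, 11, 8))
  gt3 <- group_tests(d, alpha_omnibus = 1.01)
  r <- rank(d$value)
  n_tot <- nrow(d)
  h <- 12 / (n_tot * (n_tot + 1)) *
    sum(tapply(r, d$group, function(x) length(x) * mean(x)^2)) -
    3 * (n_tot + 1)
  expect_equal(gt3$omnibus$statistic, h, tolerance = 1e-9)

  expect_error(group_tests(data.frame(group = c("a", "a", "b"),
                                      value = c(1, 2, 3))), "n >= 2")
})
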