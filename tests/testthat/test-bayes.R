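test_that("probability/odds conversions are mutual inverses", {
  expect_equal(odds_to_prob(1), 0.5)
  expect_equal(prob_to_odds(0.5), 1)
  set.seed(71)
  p <- runif(50, 0.001, 0.999)
  expect_equal(odds_to_prob(prob_to_odds(p)), p, tolerance = 1e-12)
  expect_error(prob_to_odds(1), "inside")
  expect_error(prob_to_odds(0), "inside")
  expect_error(odds_to_prob(-0.1), ">= 0")
})

two_world <- function(fa, fb, n = 1000L) {
  list(PD = exact_profile("PD", fa, n = n),
       MSA = exact_profile("MSA", fb, n = n))
}

test_that("uninformative evidence returns the prior", {
  f <- c("HP:0001337" = 0.5)
  profs <- two_world(f, f)
  q <- diagnostic_query(
    findings = data.frame(term_id = "HP:0001337", status = "present"),
    differential = c("PD", "MSA"),
    prior_override = c(PD = 0.7, MSA = 0.3))
  res <- posterior(q, profs)
  expect_equal(res$diseases$total_lr, c(1, 1))
  expect_equal(res$diseases$probability, c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(res$diseases$posterior, c(0.7, 0.3), tolerance = 1e-12)
})

test_that("posterior equals enumeration Bayes on synthetic worlds", {
  # two diseases, four findings with asserted present/absent statuses
  fa <- c("HP:0000001" = 0.8, "HP:0000002" = 0.3, "HP:0000003" = 0.55,
          "HP:0000004" = 0.1)
  fb <- c("HP:0000001" = 0.25, "HP:0000002" = 0.6, "HP:0000003" = 0.5,
          "HP:0000004" = 0.45)
  profs <- two_world(fa, fb)
  status <- c("present", "absent", "present", "absent")
  pri <- c(PD = 0.6, MSA = 0.4)
  q <- diagnostic_query(
    findings = data.frame(term_id = names(fa), status = status),
    differential = c("PD", "MSA"), prior_override = pri)
  res <- posterior(q, profs)

  lik <- function(f) prod(ifelse(status == "present", f, 1 - f))
  exact <- c(pri["PD"] * lik(fa), pri["MSA"] * lik(fb))
  exact <- exact / sum(exact)
  expect_equal(res$diseases$posterior, unname(exact), tolerance = 1e-9)
  # with two diseases the one-vs-rest odds view is exact Bayes as well
  expect_equal(res$diseases$probability, unname(exact), tolerance = 1e-9)

  # three diseases, six binary findings
  set.seed(73)
  terms <- sprintf("HP:%07d", 1:6)
  fs <- lapply(1:3, function(i) setNames(round(runif(6, 0.1, 0.9), 3), terms))
  profs3 <- list(PD = exact_profile("PD", fs[[1]]),
                 MSA = exact_profile("MSA", fs[[2]]),
                 PSP = exact_profile("PSP", fs[[3]]))
  status3 <- sample(c("present", "absent"), 6, replace = TRUE)
  pri3 <- c(PD = 0.5, MSA = 0.3, PSP = 0.2)
  q3 <- diagnostic_query(
    findings = data.frame(term_id = terms, status = status3),
    differential = c("PD", "MSA", "PSP"), prior_override = pri3)
  res3 <- posterior(q3, profs3)
  lik3 <- function(f) prod(ifelse(status3 == "present", f, 1 - f))
  exact3 <- vapply(fs, lik3, 1) * pri3
  exact3 <- exact3 / sum(exact3)
  expect_equal(res3$diseases$posterior, unname(exact3), tolerance = 1e-9)
})

test_that("posteriors are order-invariant, monotone and deterministic", {
  fa <- c("HP:0000001" = 0.7, "HP:0000002" = 0.2)
  fb <- c("HP:0000001" = 0.3, "HP:0000002" = 0.4)
  profs <- two_world(fa, fb)
  pri <- c(PD = 0.5, MSA = 0.5)
  fwd <- posterior(diagnostic_query(
    findings = data.frame(term_id = names(fa), status = c("present", "absent")),
    differential = c("PD", "MSA"), prior_override = pri), profs)
  rev <- posterior(diagnostic_query(
    findings = data.frame(term_id = rev(names(fa)),
                          status = c("absent", "present")),
    differential = c("PD", "MSA"), prior_override = pri), profs)
  expect_equal(fwd$diseases, rev$diseases, tolerance = 1e-12)

  # raising a present finding's frequency never lowers that disease's posterior
  fa_up <- fa; fa_up["HP:0000001"] <- 0.9
  up <- posterior(diagnostic_query(
    findings = data.frame(term_id = "HP:0000001", status = "present"),
    differential = c("PD", "MSA"), prior_override = pri),
    two_world(fa_up, fb))
  base <- posterior(diagnostic_query(
    findings = data.frame(term_id = "HP:0000001", status = "present"),
    differential = c("PD", "MSA"), prior_override = pri), profs)
  expect_gte(up$diseases$posterior[1], base$diseases$posterior[1])
  expect_gte(up$diseases$probability[1], base$diseases$probability[1])

  # bit-identical serialisation for identical inputs
  again <- posterior(diagnostic_query(
    findings = data.frame(term_id = names(fa), status = c("present", "absent")),
    differential = c("PD", "MSA"), prior_override = pri), profs)
  expect_identical(jsonlite::toJSON(fwd$diseases, digits = NA),
                   jsonlite::toJSON(again$diseases, digits = NA))
})

test_that("external tests enter via LR machinery with contrast inversion", {
  f <- c("HP:0000001" = 0.5)
  profs <- two_world(f, f)
  nflc <- data.frame(name = "NFLC", sensitivity = 0.86, specificity = 0.85,
                     result = "positive")
  nflc$applies_to <- list("MSA")
  q <- diagnostic_query(findings = NULL, external_tests = nflc,
                        differential = c("PD", "MSA"),
                        prior_override = c(PD = 0.5, MSA = 0.5))
  res <- posterior(q, profs)
  d <- res$diseases
  # positive NFLC favours the atypical contrast it was validated on
  expect_gt(d$probability[d$disease == "MSA"], d$probability[d$disease == "PD"])
  # MSA vs REST(=PD) ratio is sens / inverted sens = 0.86 / 0.14
  msa_lr <- res$contrasts$lr[res$contrasts$disease_a == "MSA"]
  expect_equal(msa_lr, 0.86 / 0.14, tolerance = 1e-12)
})

test_that("pairwise mode reports per-contrast products", {
  fa <- c("HP:0000001" = 0.8, "HP:0000002" = 0.4)
  fb <- c("HP:0000001" = 0.2, "HP:0000002" = 0.5)
  profs <- two_world(fa, fb)
  q <- diagnostic_query(
    findings = data.frame(term_id = names(fa), status = "present"),
    differential = c("PD", "MSA"), prior_override = c(PD = 0.4, MSA = 0.6))
  res <- posterior(q, profs, mode = "pairwise")
  con <- res$contrasts
  pd_v_msa <- con[con$disease_a == "PD" & con$disease_b == "MSA", ]
  expect_equal(sort(pd_v_msa$lr), sort(c(0.8 / 0.2, 0.4 / 0.5)),
               tolerance = 1e-12)
  pd_row <- res$diseases[res$diseases$disease == "PD", ]
  expect_equal(pd_row$total_lr, (0.8 / 0.2) * (0.4 / 0.5), tolerance = 1e-12)
  expect_equal(pd_row$post_test_odds, (0.4 / 0.6) * pd_row$total_lr,
               tolerance = 1e-12)
})

test_that("diseases missing an assessed finding are dropped, not guessed", {
  pd <- exact_profile("PD", c("HP:0000001" = 0.5, "HP:0000002" = 0.4))
  msa <- exact_profile("MSA", c("HP:0000001" = 0.3, "HP:0000002" = 0.2))
  cbd <- exact_profile("CBD", c("HP:0000002" = 0.1))  # never assessed term 1
  q <- diagnostic_query(
    findings = data.frame(term_id = "HP:0000001", status = "present"),
    differential = c("PD", "MSA", "CBD"),
    prior_override = c(PD = 0.4, MSA = 0.4, CBD = 0.2))
  res <- posterior(q, list(PD = pd, MSA = msa, CBD = cbd))
  expect_false("CBD" %in% res$diseases$disease)
  expect_equal(res$dropped$disease, "CBD")
})

test_that("a zero-frequency finding zeroes the disease, matching exclusion rules", {
  pd <- exact_profile("PD", c("HP:0000001" = 0.5))
  psp <- exact_profile("PSP", c("HP:0000001" = 0))
  q <- diagnostic_query(
    findings = data.frame(term_id = "HP:0000001", status = "present"),
    differential = c("PD", "PSP"), prior_override = c(PD = 0.5, PSP = 0.5))
  res <- posterior(q, list(PD = pd, PSP = psp))
  psp_row <- res$diseases[res$diseases$disease == "PSP", ]
  expect_equal(psp_row$total_lr, 0)
  expect_equal(psp_row$probability, 0)
  expect_equal(psp_row$posterior, 0)
  # PD's ratio against a zero-frequency rest is unbounded: excluded by default
  expect_gt(nrow(res$excluded_evidence), 0)
  # with pathognomonic opt-in the ratio is capped, not dropped
  res_cap <- posterior(q, list(PD = pd, PSP = psp), pathognomonic = TRUE)
  pd_cap <- res_cap$diseases[res_cap$diseases$disease == "PD", ]
  expect_equal(pd_cap$total_lr, 1e3)
})

test_that("sequential updates equal recomputation on the enlarged query", {
  fa <- c("HP:0000001" = 0.8, "HP:0000002" = 0.3, "HP:0000003" = 0.6)
  fb <- c("HP:0000001" = 0.25, "HP:0000002" = 0.55, "HP:0000003" = 0.4)
  profs <- two_world(fa, fb)
  pri <- c(PD = 0.55, MSA = 0.45)
  q1 <- diagnostic_query(
    findings = data.frame(term_id = "HP:0000001", status = "present"),
    differential = c("PD", "MSA"), prior_override = pri)
  r1 <- posterior(q1, profs)
  r2 <- sequential_update(r1, finding = data.frame(term_id = "HP:0000002",
                                                   status = "absent"))
  full <- posterior(diagnostic_query(
    findings = data.frame(term_id = c("HP:0000001", "HP:0000002"),
                          status = c("present", "absent")),
    differential = c("PD", "MSA"), prior_override = pri), profs)
  expect_equal(r2$diseases, full$diseases, tolerance = 1e-12)

  # updating with uninformative evidence changes nothing
  flat <- two_world(c(fa, "HP:0000009" = 0.5), c(fb, "HP:0000009" = 0.5))
  r1f <- posterior(q1, flat)
  r3 <- sequential_update(r1f, finding = data.frame(term_id = "HP:0000009",
                                                    status = "present"))
  expect_equal(r3$diseases$post_test_odds, r1f$diseases$post_test_odds,
               tolerance = 1e-12)

  # adding then conceptually removing evidence restores the odds
  lr_added <- r2$diseases$post_test_odds / r1$diseases$post_test_odds
  expect_equal(r2$diseases$post_test_odds / lr_added,
               r1$diseases$post_test_odds, tolerance = 1e-12)

  expect_error(sequential_update(r1, finding = data.frame(
    term_id = "HP:0000001", status = "absent")), "duplicate")
  expect_error(sequential_update(r1), "finding or a test")
})

test_that("screening projections reproduce expected cell counts", {
  proj <- screening_projection(10000, 0.1, 0.98, 0.953)
  expect_equal(proj$TP, 980)
  expect_equal(proj$FP, 9000 * 0.047, tolerance = 1e-9)   # 423
  expect_equal(proj$ppv, 980 / (980 + 423), tolerance = 1e-9)
  expect_equal(proj$TP + proj$FN, proj$n * proj$prevalence)
  expect_equal(proj$TN + proj$FP, proj$n * (1 - proj$prevalence))
  # near-degenerate prevalence drives PPV towards 1
  expect_gt(screening_projection(10000, 1 - 1e-9, 0.98, 0.953)$ppv, 0.999)
  expect_error(screening_projection(100, 0, 0.9, 0.9))
})

test_that("the inverse query ranks candidate observations by information", {
  profs <- list(
    A = exact_profile("PD", c("HP:0000001" = 0.8, "HP:0000002" = 0.25,
                              "HP:0000003" = 0.3)),
    B = exact_profile("MSA", c("HP:0000001" = 0.2, "HP:0000002" = 0.2,
                               "HP:0000003" = 0.2))
  )
  nbo <- next_best_observation(profs, "A", "B")
  expect_equal(nbo$term_id[1], "HP:0000001")          # LR 4.0 most informative
  expect_true(all(diff(nbo$abs_log10_lr) <= 0))

  # LR 0.25 beats LR 1.5 on |log| informativeness
  profs2 <- list(
    A = exact_profile("PD", c("HP:0000001" = 0.1, "HP:0000002" = 0.3)),
    B = exact_profile("MSA", c("HP:0000001" = 0.4, "HP:0000002" = 0.2))
  )
  nbo2 <- next_best_observation(profs2, "A", "B")
  expect_equal(nbo2$term_id[1], "HP:0000001")
  expect_equal(nbo2$abs_log10_lr[1], abs(log10(0.25)), tolerance = 1e-12)
})
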