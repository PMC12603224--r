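test_that("contrast LRs follow the sensitivity/specificity formulas", {
  a <- exact_profile("PD", c("HP:0001337" = 0.5), n = 20L)
  b <- exact_profile("MSA", c("HP:0001337" = 0.2), n = 20L)
  lr <- contrast_lr(a, b, "HP:0001337")
  expect_equal(lr$sensitivity, 0.5)
  expect_equal(lr$specificity, 0.8)
  expect_equal(lr$lr_positive, 2.5)
  expect_equal(lr$lr_negative, 0.5 / 0.8)
  expect_true(lr$finite)

  # empty comparator observation: excluded by default, finite under haldane
  z <- exact_profile("MSA", c("HP:0001337" = 0), n = 20L)
  lr0 <- contrast_lr(a, z, "HP:0001337")
  expect_false(lr0$finite)
  expect_true(is.na(lr0$lr_positive))
  lr_h <- contrast_lr(a, z, "HP:0001337",
                      lr_config(zero_policy = "haldane"))
  expect_equal(lr_h$lr_positive, (10.5 / 21) / (0.5 / 21))  # = 21

  tiny <- exact_profile("MSA", c("HP:0001337" = 0.4), n = 5L)
  expect_error(contrast_lr(a, tiny, "HP:0001337"), "MSA")
  expect_error(contrast_lr(tiny, a, "HP:0001337"), "MSA")
})

test_that("one-vs-rest pools the remaining diseases by weight", {
  a <- exact_profile("PD", c("HP:0001337" = 0.5), n = 100L)
  b <- exact_profile("MSA", c("HP:0001337" = 0.2), n = 100L)
  c3 <- exact_profile("PSP", c("HP:0001337" = 0.4), n = 100L)

  # two-disease corpus: identical to the pairwise contrast
  two <- one_vs_rest_lr(list(PD = a, MSA = b), "PD", "HP:0001337")
  pair <- contrast_lr(a, b, "HP:0001337")
  expect_equal(two$lr_positive, pair$lr_positive)

  # equal weights, rest frequencies 0.2 and 0.4 -> rest frequency 0.3
  ovr <- one_vs_rest_lr(list(PD = a, MSA = b, PSP = c3), "PD", "HP:0001337",
                        rest_weights = c(MSA = 1, PSP = 1))
  expect_equal(ovr$specificity, 0.7, tolerance = 1e-12)
  expect_equal(ovr$lr_positive, 0.5 / 0.3, tolerance = 1e-12)

  # random profiles against brute-force weighted pooling
  set.seed(53)
  for (i in 1:10) {
    fr <- round(runif(3, 0.05, 0.9), 3)
    profs <- list(PD = exact_profile("PD", c("HP:0001337" = fr[1])),
                  MSA = exact_profile("MSA", c("HP:0001337" = fr[2])),
                  PSP = exact_profile("PSP", c("HP:0001337" = fr[3])))
    w <- runif(2, 0.1, 5)
    got <- one_vs_rest_lr(profs, "PD", "HP:0001337",
                          rest_weights = c(MSA = w[1], PSP = w[2]))
    rest <- sum(w / sum(w) * fr[2:3])
    expect_equal(got$lr_positive, fr[1] / rest, tolerance = 1e-9)
  }
  expect_error(one_vs_rest_lr(list(PD = a,
                                   MSA = exact_profile("MSA", c("HP:X" = 0.1))),
                              "PD", "HP:0001337"), "rest")
})

test_that("top discriminators rank by LR+ with deterministic ties", {
  profs <- list(
    PD = exact_profile("PD", c("HP:0001337" = 0.8, "HP:0001251" = 0.12,
                               "HP:0002067" = 0.3)),
    MSA = exact_profile("MSA", c("HP:0001337" = 0.2, "HP:0001251" = 0.1,
                                 "HP:0002067" = 0.25))
  )
  top <- top_discriminators(profs, "PD", "MSA")
  expect_equal(top$term_id[1], "HP:0001337")   # LR 4.0 first
  expect_true(all(diff(top$lr_positive) <= 0))

  # a term below the observation floor is excluded despite a huge LR
  small <- cohort_annotation("S:s", 2000L, "a", "PD", 8L,
                             phenotypes = tibble::tibble(
                               term_id = "HP:0010307", n_present = 8L,
                               n_assessed = 8L))
  base <- cohort_annotation("S:b", 2000L, "a", "PD", 100L,
                            phenotypes = tibble::tibble(
                              term_id = "HP:0001337", n_present = 80L,
                              n_assessed = 100L))
  pd2 <- build_profile(dplyr::bind_rows(small, base), "PD")
  msa2 <- exact_profile("MSA", c("HP:0001337" = 0.2, "HP:0010307" = 0.01))
  top2 <- top_discriminators(list(PD = pd2, MSA = msa2), "PD", "MSA")
  expect_false("HP:0010307" %in% top2$term_id)

  # planted best discriminator (0.8 vs 0.1) ranks first in a noisy screen
  set.seed(59)
  terms <- sprintf("HP:%07d", 1:12)
  fa <- setNames(round(runif(12, 0.2, 0.4), 2), terms)
  fb <- setNames(round(runif(12, 0.2, 0.4), 2), terms)
  fa["HP:0000001"] <- 0.8; fb["HP:0000001"] <- 0.1
  planted <- top_discriminators(list(A = exact_profile("PD", fa),
                                     B = exact_profile("MSA", fb)),
                                "A", "B")
  expect_equal(planted$term_id[1], "HP:0000001")
  expect_lte(nrow(planted), 5L)
})

test_that("external-test LRs and inversion follow the printed formulas", {
  nflc <- lr_from_test(0.86, 0.85)
  expect_equal(nflc$lr_positive, 0.86 / 0.15, tolerance = 1e-12)   # 5.7333
  expect_equal(round(nflc$lr_positive, 4), 5.7333)
  expect_equal(round(nflc$lr_negative, 4), 0.1647)

  flat <- lr_from_test(0.5, 0.5)
  expect_equal(flat$lr_positive, 1)
  expect_equal(flat$lr_negative, 1)

  rtquic <- lr_from_test(0.98, 0.953)
  expect_equal(rtquic$lr_positive, 0.98 / 0.047, tolerance = 1e-12) # 20.85
  expect_error(lr_from_test(0.9, 1), "unbounded")

  inv <- invert_test(0.86, 0.85)
  expect_equal(unname(inv), c(0.14, 0.15))
  expect_equal(unname(invert_test(inv[1], inv[2])), c(0.86, 0.85))  # involution
  expect_equal(unname(invert_test(1, 1)), c(0, 0))
})

test_that("sensitivity/specificity are recoverable from a finite LR pair", {
  set.seed(61)
  for (i in 1:25) {
    sens <- runif(1, 0.05, 0.95)
    spec <- runif(1, 0.05, 0.95)
    lr <- lr_from_test(sens, spec)
    # solve the two defining equations back
    spec_back <- (lr$lr_positive - 1) / (lr$lr_positive - lr$lr_negative)
    sens_back <- lr$lr_positive * (1 - spec_back)
    expect_equal(sens_back, sens, tolerance = 1e-12)
    expect_equal(spec_back, spec, tolerance = 1e-12)
  }
})

test_that("haldane-corrected LRs converge to uncorrected values with n", {
  freqs <- c(0.3, 0.1)
  gap <- vapply(c(1e3, 1e6), function(n) {
    a <- exact_profile("PD", c("HP:0001337" = freqs[1]), n = as.integer(n))
    b <- exact_profile("MSA", c("HP:0001337" = freqs[2]), n = as.integer(n))
    raw <- contrast_lr(a, b, "HP:0001337")$lr_positive
    hal <- contrast_lr(a, b, "HP:0001337",
                       lr_config(zero_policy = "haldane"))$lr_positive
    abs(hal - raw)
  }, 1)
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 1e-4)
})
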