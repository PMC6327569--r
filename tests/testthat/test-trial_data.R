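test_that("long-format files round-trip through load_trial", {
  tr <- toy_trial(n = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, f)
  tr2 <- load_trial(f)
  expect_equal(tr2$Y, tr$Y, ignore_attr = TRUE)
  expect_true(all(tr2$R == 1L))
  expect_equal(tr2$arm, tr$arm)

  # omitting a scheduled row yields a missing cell
  d <- utils::read.csv(f)
  d <- d[!(d$id == 2 & d$month == 3), ]
  utils::write.csv(d, f, row.names = FALSE)
  tr3 <- load_trial(f)
  i <- which(tr3$patient_id == 2)
  expect_identical(tr3$R[i, 4], 0L)
  expect_true(is.na(tr3$Y[i, 4]))
})

test_that("load_trial rejects duplicates and unknown months, and applies inclusion rules", {
  tr <- toy_trial(n = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, f)
  d <- utils::read.csv(f)
  utils::write.csv(rbind(d, d[1, ]), f, row.names = FALSE)
  expect_error(load_trial(f), "duplicate")

  d2 <- d
  d2$month[2] <- 2.5
  utils::write.csv(d2, f, row.names = FALSE)
  expect_error(load_trial(f), "schedule")

  # baseline missing -> excluded with a warning
  d3 <- d[!(d$id == 1 & d$month == 0), ]
  utils::write.csv(d3, f, row.names = FALSE)
  expect_warning(tr3 <- load_trial(f), "baseline")
  expect_false(1 %in% tr3$patient_id)

  # fewer than two observed visits -> excluded with a message
  d4 <- d[!(d$id == 2 & d$month > 0), ]
  utils::write.csv(d4, f, row.names = FALSE)
  expect_message(tr4 <- load_trial(f), "fewer than two")
  expect_false(2 %in% tr4$patient_id)
})

test_that("classify_patterns finds the single pattern of a complete cohort", {
  tr <- toy_trial(n = 20)
  pt <- classify_patterns(tr)
  expect_identical(nrow(pt$counts), 1L)
  expect_equal(unname(pt$proportions[1, ]), c(1, 1))
})

test_that("classify_patterns reproduces monotone dropout counts implied by remaining-at-visit tables", {
  # remaining placebo 64,64,57,53,44 => dropouts after visits 2,3,4 of
  # 7,4,9 and 44 completers
  tr <- make_monotone_trial(c("2" = 7, "3" = 4, "4" = 9, "5" = 44),
                            c("2" = 10, "3" = 12, "4" = 5, "5" = 46))
  pt <- classify_patterns(tr)
  expect_identical(nrow(pt$counts), 4L)
  # completers first, then later dropouts
  expect_equal(unname(pt$counts[, 1]), c(44, 9, 4, 7))
  expect_equal(unname(pt$counts[, 2]), c(46, 5, 12, 10))
  expect_true(all(colSums(pt$counts) == c(64, 73)))
  # all patterns monotone: ones then zeros
  mono <- apply(pt$patterns, 1, function(p) all(diff(p) <= 0))
  expect_true(all(mono))
})

test_that("deviation_time reports last visit, gaps and monotonicity", {
  Y <- rbind(c(1, 2, 3, 4, 5),
             c(1, 2, NA, NA, NA),
             c(1, NA, 3, 4, NA))
  tr <- longitudinal_trial(Y, arm = c(0, 0, 1),
                           visit_times = c(0, 0.5, 1, 3, 6))
  dv <- deviation_time(tr)
  expect_equal(dv$n_last, c(5, 2, 4))
  expect_equal(dv$intermittent, list(integer(0), integer(0), 2L))
  expect_equal(dv$is_monotone, c(TRUE, TRUE, FALSE))
})

test_that("pattern chi-squared matches the Pearson formula and drops empty patterns", {
  expect_equal(pattern_arm_chisq(cbind(c(10, 10), c(10, 10)))$statistic, 0)
  cs <- pattern_arm_chisq(cbind(c(20, 10), c(10, 20)))
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-12)

  # zero-total patterns dropped, df reflects kept rows
  counts <- cbind(c(5, 0, 7), c(3, 0, 9))
  cs2 <- pattern_arm_chisq(counts)
  expect_identical(cs2$df, 1L)
  expect_equal(cs2$statistic, chisq_brute(counts[c(1, 3), ]),
               tolerance = 1e-12)
  expect_error(pattern_arm_chisq(cbind(5, 3)), "at least 2")
})

test_that("pattern chi-squared equals a brute-force double loop on random tables", {
  set.seed(7)
  for (i in 1:50) {
    U <- sample(2:6, 1)
    counts <- matrix(rpois(2 * U, 20) + 5, U, 2)
    expect_equal(pattern_arm_chisq(counts)$statistic,
                 chisq_brute(counts), tolerance = 1e-10)
  }
})

test_that("pattern counts sum to arm sizes on random incomplete trials", {
  for (s in 1:5) {
    tr <- impose_dropout(toy_trial(n = 40, seed = s),
                         dropout_model("MCAR", intercept = -1),
                         seed = s)
    pt <- classify_patterns(tr)
    expect_equal(unname(colSums(pt$counts)),
                 unname(as.vector(table(tr$arm))))
    expect_equal(unname(colSums(pt$proportions)), c(1, 1))
    # monotone trial iff every pattern is ones then zeros
    dv <- deviation_time(tr)
    mono_patterns <- all(apply(pt$patterns, 1,
                               function(p) all(diff(p) <= 0)))
    expect_identical(all(dv$is_monotone), mono_patterns)
  }
})

test_that("summarize_patterns reports deviating fractions and visit means", {
  tr <- make_monotone_trial(c("2" = 7, "3" = 4, "4" = 9, "5" = 44),
                            c("2" = 10, "3" = 12, "4" = 5, "5" = 46))
  s <- summarize_patterns(tr)
  expect_equal(unique(s$deviating_pct[s$arm == 0]), 31)
  expect_equal(unique(s$deviating_pct[s$arm == 1]), 37)

  # single fully observed patient: deviating 0, means equal the data
  tr1 <- longitudinal_trial(matrix(1:5, 1), arm = 0,
                            visit_times = c(0, 0.5, 1, 3, 6))
  s1 <- summarize_patterns(tr1)
  expect_equal(s1$deviating_pct, 0)
  expect_equal(unname(unlist(s1[grep("mean_", names(s1))])), 1:5)
})
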