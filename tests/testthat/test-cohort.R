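test_that("cohort tables are reproducible and have the declared structure", {
  sp <- cohort_spec(seed = 123)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a, b)
  expect_equal(nrow(a), 296)
  expect_equal(sum(a$event == "+"), 34)
  expect_equal(sum(a$set == "training"), 148)
  expect_true(all(morphometric_features() %in% names(a)))
  expect_true(all(a[morphometric_features()] >= 0))
  d <- simulate_cohort(cohort_spec(seed = 124))
  expect_false(identical(a$`MPA bifurcation area`,
                         d$`MPA bifurcation area`))
})

test_that("replicated group means of the bifurcation area hit the targets", {
  # 200 replicates of the reference design; the mean of sample group means
  # must sit within 2 SE of the configured group means (1.32 / 0.57)
  m_pos <- m_neg <- numeric(200)
  for (r in 1:200) {
    co <- simulate_cohort(cohort_spec(seed = 1000 + r))
    m_pos[r] <- mean(co$`MPA bifurcation area`[co$event == "+"])
    m_neg[r] <- mean(co$`MPA bifurcation area`[co$event == "-"])
  }
  se_pos <- sd(m_pos) / sqrt(200)
  se_neg <- sd(m_neg) / sqrt(200)
  # the generator moment-matches the zero-truncated draws, so the group
  # means sit within 2 SE of the configured targets
  expect_lt(abs(mean(m_pos) - 1.32), 2 * se_pos)
  expect_lt(abs(mean(m_neg) - 0.57), 2 * se_neg)
})

test_that("moments converge to the spec moments as n grows", {
  big <- simulate_cohort(cohort_spec(n_total = 20000, seed = 5))
  pos <- big$event == "+"
  mom <- reference_cohort_moments()
  for (f in c("MPA outlet CSA", "MPA outlet hydraulic diameter")) {
    i <- match(f, mom$feature)
    expect_equal(mean(big[[f]][pos]), mom$mean_pos[i], tolerance = 0.02)
    expect_equal(sd(big[[f]][!pos]), mom$sd_neg[i], tolerance = 0.05)
  }
  expect_equal(mean(big$dilation[pos]), 13 / 34, tolerance = 0.1)
})

test_that("degenerate prevalence and the zero-noise limit behave as stated", {
  co0 <- simulate_cohort(cohort_spec(prevalence = 0, seed = 2))
  expect_true(all(co0$event == "-"))
  expect_error(cohort_group_tests(co0), "degenerate")

  mom <- reference_cohort_moments()
  mom$sd_pos[] <- 0; mom$sd_neg[] <- 0
  cz <- simulate_cohort(cohort_spec(moments = mom, seed = 3))
  pos <- cz$event == "+"
  for (i in seq_len(nrow(mom))) {
    f <- mom$feature[i]
    expect_true(all(cz[[f]][pos] == mom$mean_pos[i]))
    expect_true(all(cz[[f]][!pos] == mom$mean_neg[i]))
  }
})

test_that("infeasible correlation matrices fail by name", {
  k <- nrow(reference_cohort_moments())
  bad <- diag(k); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(cohort_spec(correlation = bad), "correlation matrix")
  lop <- matrix(0.5, k, k); diag(lop) <- 1; lop[1, 2] <- 0.9
  expect_error(cohort_spec(correlation = lop), "symmetric")
})

test_that("a supplied correlation structure is realized", {
  k <- nrow(reference_cohort_moments())
  cm <- diag(k)
  cm[1, 2] <- cm[2, 1] <- 0.8
  co <- simulate_cohort(cohort_spec(n_total = 4000, correlation = cm,
                                    seed = 9))
  neg <- co$event == "-"
  r <- cor(co$`MPA inlet CSA`[neg], co$`MPA outlet CSA`[neg])
  expect_equal(r, 0.8, tolerance = 0.05)
})

test_that("cohort CSV round-trips with the standard header labels", {
  co <- simulate_cohort(cohort_spec(seed = 4))
  tf <- tempfile(fileext = ".csv")
  write_cohort_csv(co, tf)
  hdr <- names(read.csv(tf, check.names = FALSE))
  expect_true("MPA bifurcation area (100 mm^2)" %in% hdr)
  expect_true("MPA outlet hydraulic diameter (10 mm)" %in% hdr)
  expect_true(all(c("event", "set") %in% hdr))
  back <- read_cohort_csv(tf)
  expect_equal(back$`MPA bifurcation area`, co$`MPA bifurcation area`)
  expect_identical(back$dilation, co$dilation)
})

test_that("group tests flag the engineered group differences", {
  co <- simulate_cohort(cohort_spec(seed = 21))
  gt <- cohort_group_tests(co)
  area <- gt[gt$feature == "MPA bifurcation area", ]
  expect_lt(area$p_value, 0.001)
  age <- gt[gt$feature == "age", ]
  expect_gt(age$p_value, 0.01)   # ages differ by < 1.4 years
})
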