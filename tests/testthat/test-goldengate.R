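test_that("the theta transform maps channel ratios onto [0, 1]", {
  expect_equal(theta_transform(4000, 0)$theta, 0)
  expect_equal(theta_transform(0, 4000)$theta, 1)
  expect_equal(theta_transform(1000, 1000)$theta, 0.5)
  expect_true(is.na(theta_transform(0, 0)$theta))
  expect_equal(theta_transform(300, 700)$normR, 1000)
  expect_error(theta_transform(-1, 5), "non-negative")
  # scale invariance and monotonicity
  set.seed(171)
  cy3 <- runif(50, 10, 5000); cy5 <- runif(50, 10, 5000)
  expect_equal(theta_transform(cy3, cy5)$theta,
               theta_transform(3.7 * cy3, 3.7 * cy5)$theta)
  th <- theta_transform(1000, c(100, 500, 1000, 3000))$theta
  expect_true(all(diff(th) > 0))
})

test_that("cluster fitting recovers planted group structures", {
  set.seed(172)
  three <- c(rnorm(30, 0.05, 0.01), rnorm(30, 0.5, 0.01),
             rnorm(30, 0.95, 0.01))
  m3 <- fit_clusters(three)
  expect_equal(m3$k, 3L)
  expect_equal(m3$centers, c(0.05, 0.5, 0.95), tolerance = 0.02)
  expect_true(all(diff(m3$centers) > 0))

  m1 <- fit_clusters(rnorm(40, 0.5, 0.01))
  expect_equal(m1$k, 1L)

  four <- c(rnorm(25, 0.05, 0.02), rnorm(25, 0.35, 0.02),
            rnorm(25, 0.65, 0.02), rnorm(25, 0.95, 0.02))
  expect_equal(fit_clusters(four)$k, 4L)

  # noise-free groups: exact centers, deterministic
  exact <- rep(c(0.1, 0.5, 0.9), times = c(10, 12, 9))
  me <- fit_clusters(exact)
  expect_equal(me$k, 3L)
  expect_equal(me$centers, c(0.1, 0.5, 0.9))
  expect_identical(fit_clusters(exact)$assignment, me$assignment)

  # NA theta points keep their slot but get no assignment
  with_na <- c(exact, NA)
  expect_true(is.na(fit_clusters(with_na)$assignment[length(with_na)]))
})

test_that("genotype calls apply the intensity floor and distance cutoff", {
  model <- fit_clusters(rep(c(0.1, 0.9), each = 10))
  out <- call_gg_genotypes(model, theta = c(0.1, 0.9, 0.5, 0.11),
                           normR = c(5000, 5000, 5000, 100))
  expect_equal(out$call, c(1L, 2L, NA, NA))  # 0.5 too far; low intensity
  expect_equal(out$call_rate, 0.5)
  # points at the centers are always called
  perfect <- call_gg_genotypes(model, rep(c(0.1, 0.9), 5), rep(4000, 10))
  expect_equal(perfect$call_rate, 1)
})

test_that("samples under the 0.8 call-rate floor are excluded", {
  calls <- data.table::rbindlist(list(
    data.table::data.table(sample = "good", assay = sprintf("a%02d", 1:96),
                           call = 1L),
    data.table::data.table(sample = "poor", assay = sprintf("a%02d", 1:96),
                           call = c(rep(1L, 70), rep(NA_integer_, 26)))))
  ex <- exclude_low_call_samples(calls)
  expect_identical(ex$excluded, "poor")   # 70/96 = 0.73 < 0.8
  expect_false("poor" %in% ex$kept$sample)
  expect_equal(ex$sample_rates$rate[ex$sample_rates$sample == "poor"],
               70 / 96)
})

test_that("segregation tests match the closed-form chi-squared", {
  r <- segregation_test(c(25, 25), "DH")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_false(r$distorted)

  r2 <- segregation_test(c(10, 20, 10), "F2")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  expect_equal(r2$df, 2)

  # DH 40:10 -> (15^2/25) * 2 = 18, p from the df-1 tail
  r3 <- segregation_test(c(40, 10), "DH")
  expect_equal(r3$statistic, 18)
  expect_equal(r3$p, stats::pchisq(18, 1, lower.tail = FALSE))
  expect_true(r3$distorted)

  # a heterozygote class in a DH design is dropped but flagged
  r4 <- segregation_test(c(20, 4, 24), "DH")
  expect_true(r4$inconsistent)
  expect_equal(r4$df, 1)
})

test_that("replicate call concordance follows the no-call rule", {
  expect_true(reproducibility_check(c(1L, 1L, 1L)))
  expect_false(reproducibility_check(c(1L, 1L, 2L)))
  expect_true(reproducibility_check(c(1L, NA, 1L)))
  expect_true(is.na(reproducibility_check(c(1L, NA, NA))))
})

test_that("designability scores are filtered and banded as specified", {
  d <- designability_filter(c(0.85, 0.86, 0.3, 0.5, 0.65, 0.99))
  expect_equal(d$kept, c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(d$class,
                   c("high", "high", "low", "moderate", "high", "high"))
  expect_error(designability_filter(c(1.2)))
})

test_that("hemi assays split into four pooled theta groups by construction", {
  cfg <- tiny_sim_config(seed = 181L)
  gg_cfg <- cfg$goldengate
  gg_cfg$sd <- 0   # noise-free enumeration of the genotype sums
  cfg$goldengate <- gg_cfg
  r <- generate_reference(cfg)
  gg <- simulate_goldengate(r$truth, cfg)
  expect_length(gg$truth$hemi_assays, 3L)
  ints <- gg$intensities
  th <- theta_transform(ints$Cy3, ints$Cy5)$theta
  for (a in gg$truth$hemi_assays) {
    vals <- unique(round(th[ints$assay == a], 6))
    expect_gte(length(vals), 4L)
  }
  simple <- setdiff(gg$assays$assay, gg$truth$hemi_assays)
  for (a in simple[1:10]) {
    vals <- unique(round(th[ints$assay == a], 6))
    expect_lte(length(vals), 3L)
  }
  # one DH sample is emitted in triplicate
  expect_equal(sum(gg$samples$role == "replicate"), 2L)
  expect_equal(unique(gg$samples$replicate_of[gg$samples$role ==
                                                "replicate"]), "DH_L01")
})

test_that("the full assay analysis recovers the planted structure", {
  cfg <- tiny_sim_config(seed = 182L)
  r <- generate_reference(cfg)
  gg <- simulate_goldengate(r$truth, cfg)
  res <- analyze_goldengate(gg)
  m <- merge(gg$assays[, c("assay", "hemi")], res$assays, by = "assay")
  expect_equal(mean((m$hemi_flag == "hemi") == m$hemi), 1)
  # call rates are high on clean simulated intensities
  expect_gt(mean(m$call_rate), 0.95)
  # replicate concordance holds for nearly all assays
  expect_gte(mean(m$reproducible, na.rm = TRUE), 0.95)
  # polymorphism flags match the planted parent genotypes
  truth_poly <- gg$assays$dh_p1 != gg$assays$dh_p2 |
    gg$assays$f2_p1 != gg$assays$f2_p2
  expect_gte(mean(m$polymorphic == truth_poly), 0.95)
  # fair Mendelian sampling passes the segregation tests most of the time
  dh_p <- m$seg_p_dh[!is.na(m$seg_p_dh)]
  expect_gt(length(dh_p), 5L)
  expect_gte(mean(dh_p > 0.05), 0.8)
})
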