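# analytics_reporting: replication statistics, r^2 verification, export.

test_that("summaries are exact under zero noise and permutation-invariant", {
  cfg <- tiny_config(noise_cv = 0, bw_initial_sd = 0, run_days = 40,
                     n_replications = 3)
  run <- run_replications(cfg)
  s <- summarize_replications(run)
  expect_true(all(s$sd == 0))
  expect_true(all(s$ci_low == s$mean & s$ci_high == s$mean))

  # shuffling record rows changes nothing
  run2 <- run_replications(tiny_config(run_days = 40, n_replications = 3))
  rec <- run2$records
  shuffled <- rec[sample(nrow(rec)), ]
  a <- summarize_replications(rec)
  b <- summarize_replications(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$ci_low <= a$mean & a$mean <= a$ci_high))
  expect_error(summarize_replications(rec[0, ]), "empty")
  expect_error(summarize_replications(rec, "no_such_var"), "unknown")
})

test_that("a single observation yields sd 0 and a degenerate interval", {
  one <- run_replications(herd_config(sexes = "gilt", n_pigs_per_sex = 1,
                                      n_replications = 1, run_days = 10))
  s <- summarize_replications(one, "bw")
  expect_true(all(s$n == 1))
  expect_true(all(s$sd == 0))
  expect_true(all(s$ci_low == s$mean))
})

test_that("r_squared matches the textbook computation and lm", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(20); y <- 2 * x + rnorm(20, sd = 0.5)
    v <- r_squared(y, x)
    expect_equal(v$r_squared, r2_oracle(y, x), tolerance = 1e-10)
    fit <- lm(y ~ x)
    expect_equal(v$slope, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(v$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  }
  z <- c(1, 2, 3, 4)
  ident <- r_squared(z, z)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  aff <- r_squared(2 * z + 3, z)
  expect_equal(aff$r_squared, 1)
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 3)
  expect_error(r_squared(z, rep(1, 4)), "variance")
  expect_error(r_squared(1:2, 1:2), "3")
})

test_that("confidence bands shrink like one over root replications", {
  base <- herd_config(sexes = "gilt", n_pigs_per_sex = 2, seed = 5L)
  hw <- vapply(c(125L, 500L), function(R) {
    run <- run_replications(base, n_replications = R)
    s <- summarize_replications(run, "bw")
    mean(s$ci_high[s$day >= 100] - s$ci_low[s$day >= 100])
  }, numeric(1))
  ratio <- hw[2] / hw[1]
  expect_lt(abs(ratio / 0.5 - 1), 0.2)
})

test_that("the deterministic path stays inside the stochastic 95% CI band", {
  cfg <- herd_config(sexes = "gilt", n_pigs_per_sex = 2,
                     n_replications = 500)
  s <- summarize_replications(run_replications(cfg), "bw")
  det <- deterministic_trajectory(cfg, "gilt")
  m <- merge(as.data.frame(det[, c("day", "bw")]), as.data.frame(s),
             by = "day")
  inside <- m$bw >= m$ci_low & m$bw <= m$ci_high
  expect_gte(mean(inside), 0.9)
})

test_that("verification r^2 is exact without noise and degrades with it", {
  exact <- verify_run(run_replications(
    herd_config(sexes = "gilt", n_pigs_per_sex = 2, n_replications = 2,
                noise_cv = 0, bw_initial_sd = 0)), variables = "bwg")
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(exact$slope, 1, tolerance = 1e-9)

  noisy <- verify_run(run_replications(
    herd_config(sexes = "gilt", n_pigs_per_sex = 1, n_replications = 10,
                bw_initial_sd = 0, noise_cv = 0.05)), variables = "bwg")
  expect_lt(noisy$r_squared, 1)
  expect_gt(noisy$r_squared, 0.5)
  # per-replication breakdown covers every replication
  per <- verify_run(run_replications(
    herd_config(sexes = "gilt", n_pigs_per_sex = 1, n_replications = 4,
                bw_initial_sd = 0)), variables = "bwg",
    by_replication = TRUE)
  expect_equal(sort(unique(per$replication)), 1:4)
})

test_that("the day-130 snapshot has the published report shape", {
  run <- run_replications(tiny_config(n_replications = 2))
  snap <- requirements_snapshot(run, day = 130)
  expect_true(all(c("gilt", "barrow", "boar") %in% names(snap)))
  expect_true(all(c("bw", "sid_lysine", "threonine", "valine", "sttd_p",
                    "total_ca", "sodium", "vitamin_b12") %in% snap$quantity))
  # internal consistency: Ca = 2.15 * STTD P, AA = ratio * lysine
  for (s in c("gilt", "barrow", "boar")) {
    expect_equal(snap[[s]][snap$quantity == "total_ca"],
                 2.15 * snap[[s]][snap$quantity == "sttd_p"])
    expect_equal(snap[[s]][snap$quantity == "threonine"],
                 0.603 * snap[[s]][snap$quantity == "sid_lysine"])
  }
  expect_error(requirements_snapshot(run, day = 999), "no records")
})

test_that("export writes deterministic, re-readable files", {
  run <- run_replications(tiny_config(run_days = 20, n_replications = 2))
  d1 <- file.path(tempdir(), "sns_out_a")
  d2 <- file.path(tempdir(), "sns_out_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  f1 <- export_results(run, d1, snapshot_day = 10)
  f2 <- export_results(run, d2, snapshot_day = 10)
  expect_true(all(file.exists(f1)))
  expect_setequal(basename(f1),
                  c("records.csv", "summary.csv", "verification.csv",
                    "requirements_day10.csv", "run_meta.json"))
  for (f in basename(f1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read.csv(file.path(d1, "records.csv"))
  expect_equal(nrow(back), nrow(run$records))
  expect_equal(back$bw, run$records$bw, tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(d1, "run_meta.json"))
  expect_equal(meta$config$me_content, 3300)
})

test_that("space_check flags crowded barn-days only", {
  run <- run_replications(tiny_config(run_days = 15, n_replications = 1))
  roomy <- space_check(run, barn_area = 1e6)
  expect_false(any(roomy$crowded))
  tight <- space_check(run, barn_area = 1e-6)
  expect_true(all(tight$crowded))
  expect_equal(sum(roomy$n_pigs), nrow(run$records))
})
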