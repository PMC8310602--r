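schema_demo <- list(
  id = c("patient_id", "facility_id"),
  event = "event", duration = "duration_days",
  covariates = c(k = "numeric", race = "categorical"))

demo_df <- data.frame(
  patient_id = c("P1", "P1", "P2"),
  facility_id = c("F1", "F2", "F1"),
  event = c(0, 1, 0),
  duration_days = c(10, 2.5, 1),
  k = c(4.0, 5.1, 3.2),
  race = c("b", "a", "b"))

test_that("CSV round trip preserves values, levels in first-appearance order", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(demo_df, f, row.names = FALSE, quote = FALSE)
  tab <- read_long_table(f, schema_demo)
  expect_s3_class(tab, "long_table")
  expect_equal(nrow(tab), 3)
  expect_equal(levels(tab$race), c("b", "a"))   # first appearance, not sorted
  expect_equal(tab$k, demo_df$k)
  f2 <- tempfile(fileext = ".csv")
  write_long_table(tab, f2)
  tab2 <- read_long_table(f2, schema_demo)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})

test_that("schema and parse violations are reported with the offending column", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(demo_df[setdiff(names(demo_df), "duration_days")], f,
                   row.names = FALSE)
  expect_error(read_long_table(f, schema_demo), "duration_days")

  bad <- demo_df; bad$k <- c("4.0", "oops", "3.2")
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f3, row.names = FALSE, quote = FALSE)
  expect_error(read_long_table(f3, schema_demo), "row 2")

  neg <- demo_df; neg$duration_days[2] <- 0
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(neg, f4, row.names = FALSE, quote = FALSE)
  expect_error(read_long_table(f4, schema_demo), "positive")
})

test_that("survival encoding produces 0-strings terminated by a death", {
  enc <- encode_survival_poisson(TRUE, 10)
  expect_equal(enc$event, 0L)
  expect_equal(enc$offset, log(10), tolerance = 1e-12)

  enc3 <- encode_survival_poisson(c(TRUE, TRUE, FALSE), c(5, 2, 10))
  expect_equal(enc3$event, c(0L, 0L, 1L))

  expect_error(encode_survival_poisson(c(TRUE, FALSE, TRUE), c(1, 1, 1)),
               "ordering")
  expect_error(encode_survival_poisson(TRUE, 0), "positive")
})

test_that("natural spline basis satisfies the natural (linear-tail) constraint", {
  x <- seq(0, 1, length.out = 100)
  b <- natural_spline_basis(x, df = 3)
  expect_equal(b$df, 3)
  expect_equal(ncol(b$matrix), 3)

  # beyond the boundary every basis function must be exactly linear:
  # second differences of evaluations vanish
  right <- eval_spline_basis(b, b$boundary[2] + c(0.5, 1.0, 1.5))
  expect_lt(max(abs(right[1, ] - 2 * right[2, ] + right[3, ])), 1e-10)
  left <- eval_spline_basis(b, b$boundary[1] - c(0.5, 1.0, 1.5))
  expect_lt(max(abs(left[1, ] - 2 * left[2, ] + left[3, ])), 1e-10)

  # second difference vanishes at and beyond the boundary knots
  h <- 1e-4
  for (s_ in c(1, -1)) {
    bk <- if (s_ > 0) b$boundary[2] else b$boundary[1]
    pts <- bk + s_ * h * (0:2)
    ev <- eval_spline_basis(b, pts)
    expect_lt(max(abs(ev[1, ] - 2 * ev[2, ] + ev[3, ])) / h^2, 1e-6)
  }
})

test_that("spline columns span the textbook natural-spline space", {
  x <- seq(0, 1, length.out = 200)
  b <- natural_spline_basis(x, df = 3, boundary = c(0.05, 0.95),
                            knots = c(0.35, 0.65))
  oracle <- truncated_power_natural_basis(x, c(0.05, 0.35, 0.65, 0.95))
  # every fitted-basis column must be exactly representable in the
  # truncated-power natural basis (and is not constant)
  for (j in seq_len(b$df)) {
    res <- stats::lm.fit(oracle, b$matrix[, j])$residuals
    expect_lt(max(abs(res)), 1e-8)
    expect_gt(stats::sd(b$matrix[, j]), 0)
  }
  # conversely the non-trivial oracle directions lie in span(1, basis)
  for (j in 2:4) {
    res <- stats::lm.fit(cbind(1, b$matrix), oracle[, j])$residuals
    expect_lt(max(abs(res)), 1e-8)
  }
  expect_error(natural_spline_basis(rep(1, 10), df = 3), "degenerate")
})

test_that("build_design assembles indicators, dummy coding and p = 18 clinical design", {
  tab <- data.frame(patient_id = c("P1", "P1", "P2", "P2"),
                    facility_id = c("F1", "F2", "F1", "F2"),
                    y = 1:4)
  d <- build_design(tab, list(family = "gaussian", response = "y",
                              fixed = list(), groups = c("patient_id",
                                                         "facility_id")))
  expect_equal(d$X, matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(dim(d$Z), c(4L, 4L))
  expect_equal(as.numeric(Matrix::rowSums(d$Z)), rep(2, 4))

  tab$arm <- c("c", "a", "b", "a")
  d2 <- build_design(tab, list(family = "gaussian", response = "y",
                               fixed = list(list(name = "arm",
                                                 type = "categorical")),
                               groups = "patient_id"))
  expect_equal(ncol(d2$X), 3L)  # intercept + 2 dummies (3 levels)

  # clinical model: intercept + 3x3-df splines + gender + 5 race dummies +
  # inpatient + comorbidity score = 18 columns
  set.seed(1)
  n <- 120
  clin <- data.frame(
    patient_id = sprintf("P%02d", sample(30, n, TRUE)),
    facility_id = sprintf("F%d", sample(4, n, TRUE)),
    event = rbinom(n, 1, 0.05),
    duration_days = rlnorm(n),
    k = runif(n, 3, 6), egfr = runif(n, 15, 120), age = runif(n, 20, 90),
    gender = sample(c("F", "M"), n, TRUE),
    race = sample(paste0("r", 1:6), n, TRUE),
    inpatient = rbinom(n, 1, 0.4), charlson = rpois(n, 2))
  dc <- build_design(clin, list(
    family = "poisson", response = "event", offset_from = "duration_days",
    fixed = list(list(name = "k", type = "spline", df = 3),
                 list(name = "egfr", type = "spline", df = 3),
                 list(name = "age", type = "spline", df = 3),
                 list(name = "gender", type = "categorical"),
                 list(name = "race", type = "categorical"),
                 list(name = "inpatient", type = "linear"),
                 list(name = "charlson", type = "linear")),
    groups = c("patient_id", "facility_id")))
  expect_equal(ncol(dc$X), 18L)
  expect_equal(dc$offset, log(clin$duration_days))
})

test_that("design construction is row-permutation equivariant", {
  set.seed(3)
  tab <- data.frame(patient_id = sprintf("P%d", sample(5, 20, TRUE)),
                    facility_id = sprintf("F%d", sample(3, 20, TRUE)),
                    y = rpois(20, 2), x = rnorm(20))
  cfg <- list(family = "poisson", response = "y",
              fixed = list(list(name = "x", type = "linear")),
              groups = c("patient_id", "facility_id"))
  d1 <- build_design(tab, cfg)
  perm <- sample(20)
  d2 <- build_design(tab[perm, ], cfg)
  expect_equal(d2$y, d1$y[perm])
  expect_equal(unname(d2$X), unname(d1$X[perm, ]))
  expect_equal(as.matrix(d2$Z), as.matrix(d1$Z)[perm, ])

  # per-patient encounter counts are recoverable from the Z block
  sizes <- group_sizes(d1)
  counts <- Matrix::colSums(d1$Z[, seq_len(sizes[1])])
  expect_equal(as.numeric(counts),
               as.numeric(table(tab$patient_id)[d1$groups$patient_id$levels]))
})

test_that("patient subsampling is deterministic and keeps patients whole", {
  set.seed(9)
  tab <- data.frame(patient_id = rep(sprintf("P%04d", 1:1000),
                                     times = sample(1:4, 1000, TRUE)))
  tab$y <- seq_len(nrow(tab))
  expect_identical(subsample_patients(tab, 1.0, seed = 5), tab)
  s1 <- subsample_patients(tab, 0.1, seed = 5)
  s2 <- subsample_patients(tab, 0.1, seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$patient_id)), 100L)
  # all rows of each kept patient are retained
  kept <- unique(s1$patient_id)
  expect_equal(nrow(s1), sum(tab$patient_id %in% kept))
  expect_error(subsample_patients(tab, 0, seed = 1), "fraction")
  expect_error(subsample_patients(tab, 1.2, seed = 1), "fraction")
})

test_that("a GLMM dataset survives the JSON serialization round trip", {
  d <- toy_crossed_data(n_pat = 3, n_fac = 2, rep = 2, seed = 14)
  path <- tempfile(fileext = ".json")
  write_glmm_data(d, path)
  d2 <- read_glmm_data(path)
  expect_equal(d2$y, d$y)
  expect_equal(d2$X, d$X)
  expect_equal(as.matrix(d2$Z), as.matrix(d$Z))
  expect_equal(d2$offset, d$offset)
  expect_equal(d2$family$name, d$family$name)
  expect_equal(lapply(d2$groups, `[`, c("name", "levels", "index")),
               lapply(d$groups, `[`, c("name", "levels", "index")))
})
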