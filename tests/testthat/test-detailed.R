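test_that("a single differing covariate receives the entire explained part", {
  X_u <- cbind("(Intercept)" = 1, x1 = c(1, 1, 1), x2 = c(0, 1, 2))
  X_r <- cbind("(Intercept)" = 1, x1 = c(0, 0, 0), x2 = c(2, 1, 0))
  b <- c("(Intercept)" = 0.1, x1 = 0.4, x2 = 0.2)
  fu <- manual_fit("urban", b)
  fr <- manual_fit("rural", b)
  det <- detailed_explained(fu, fr, X_u, X_r, omega = 0.5)
  tab <- det$table
  expect_equal(tab$contribution[tab$variable_group == "x1"], det$explained,
               tolerance = 1e-14)
  expect_equal(tab$contribution[tab$variable_group == "x2"], 0,
               tolerance = 1e-14)
  expect_equal(sum(tab$share), 1, tolerance = 1e-6)
})

test_that("linear-link contributions equal the direct endowment products", {
  set.seed(71)
  for (rep in 1:5) {
    p <- 4
    X_u <- cbind("(Intercept)" = 1,
                 matrix(rnorm(6 * p), 6, p,
                        dimnames = list(NULL, paste0("v", 1:p))))
    X_r <- cbind("(Intercept)" = 1,
                 matrix(rnorm(6 * p), 6, p,
                        dimnames = list(NULL, paste0("v", 1:p))))
    b_u <- c(0.3, runif(p, -0.5, 0.5))
    b_r <- c(0.1, runif(p, -0.5, 0.5))
    names(b_u) <- names(b_r) <- colnames(X_u)
    omega <- runif(1)
    fu <- manual_fit("urban", b_u)
    fr <- manual_fit("rural", b_r)
    det <- detailed_explained(fu, fr, X_u, X_r, omega)
    b_s <- omega * b_u + (1 - omega) * b_r
    brute <- (colMeans(X_u) - colMeans(X_r))[-1] * b_s[-1]
    expect_equal(det$table$contribution, unname(brute), tolerance = 1e-12)
    expect_equal(det$residual, 0, tolerance = 1e-10)
    expect_equal(sum(det$table$contribution) + det$residual, det$explained,
                 tolerance = 1e-10)
  }
})

test_that("dummies of one categorical variable are aggregated into one group", {
  tab <- generate_survey(compact_spec(), 3000, seed = 41)
  fit_u <- fit_group_model(tab, "urban", "logit")
  fit_r <- fit_group_model(tab, "rural", "logit")
  X <- build_design(tab, fit_u$design_meta$terms)
  X_u <- X[tab$residence == "urban", ]
  X_r <- X[tab$residence == "rural", ]
  det <- detailed_explained(fit_u, fit_r, X_u, X_r, 0.5)
  expect_setequal(det$table$variable_group,
                  c("education", "wealth_quintile", "parity",
                    "distance_barrier"))
  expect_equal(sum(det$table$contribution), det$explained, tolerance = 1e-10)
  # custom grouping must partition the columns
  expect_error(
    detailed_explained(fit_u, fit_r, X_u, X_r, 0.5,
                       variable_groups = list(a = "parity")),
    "partition")
})

test_that("the Mills ratio forms its own contribution group", {
  spec <- selection_spec(0.6)
  pop <- generate_population(spec, 8000, seed = 43)
  aug <- heckman_augment(pop, spec$selection_terms)
  tm <- c(spec$outcome_terms, "mills_ratio")
  fit_u <- fit_group_model(aug, "urban", "probit", tm)
  fit_r <- fit_group_model(aug, "rural", "probit", tm)
  X <- build_design(aug, tm)
  det <- detailed_explained(fit_u, fit_r, X[aug$residence == "urban", ],
                            X[aug$residence == "rural", ], 0.5)
  expect_true("mills_ratio" %in% det$table$variable_group)
})

test_that("no endowment differences yield zero contributions with a warning", {
  X <- cbind("(Intercept)" = 1, x = c(1, 2, 3))
  b_u <- c("(Intercept)" = 0.5, x = 0.2)
  b_r <- c("(Intercept)" = 0.1, x = 0.3)
  expect_warning(
    det <- detailed_explained(manual_fit("urban", b_u),
                              manual_fit("rural", b_r), X, X, 0.5),
    "zero|no endowment")
  expect_true(all(det$table$contribution == 0))
})

test_that("shares are contributions over the explained component", {
  expect_equal(explained_shares(c(0.161), 0.261), 0.161 / 0.261,
               tolerance = 1e-15)
  expect_true(all(is.na(explained_shares(c(0.1, 0.2), 0))))
})
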