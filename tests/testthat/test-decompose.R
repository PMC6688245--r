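test_that("counterfactual_mean matches closed forms and hand arithmetic", {
  X <- cbind("(Intercept)" = 1, a = c(1, 0, 2), b = c(0.5, -1, 0))
  # all-zero coefficients, logit: 0.5
  expect_equal(counterfactual_mean(c("(Intercept)" = 0, a = 0, b = 0), X,
                                   "logit"), 0.5)
  # intercept-only closed form
  expect_equal(counterfactual_mean(c("(Intercept)" = 1.3, a = 0, b = 0), X,
                                   "logit"), 1 / (1 + exp(-1.3)))
  # 3-row hand evaluation
  beta <- c("(Intercept)" = -0.2, a = 0.7, b = -1.1)
  hand <- mean(plogis(c(-0.2 + 0.7 * 1 - 1.1 * 0.5,
                        -0.2 + 0.7 * 0 - 1.1 * -1,
                        -0.2 + 0.7 * 2 - 1.1 * 0)))
  expect_equal(counterfactual_mean(beta, X, "logit"), hand, tolerance = 1e-15)
  # name mismatch is a schema error
  expect_error(counterfactual_mean(c("(Intercept)" = 0, z = 1), X, "logit"),
               "do not match")
})

test_that("three-fold components on a linear link equal hand matrix algebra", {
  # 6-row design, 2 covariates, known coefficients
  X_u <- cbind("(Intercept)" = 1, x1 = c(1, 2, 0), x2 = c(0, 1, 1))
  X_r <- cbind("(Intercept)" = 1, x1 = c(0, 1, 0), x2 = c(1, 0, 0))
  b_u <- c("(Intercept)" = 0.2, x1 = 0.3, x2 = 0.1)
  b_r <- c("(Intercept)" = 0.1, x1 = 0.15, x2 = 0.05)
  fu <- manual_fit("urban", b_u)
  fr <- manual_fit("rural", b_r)

  xbar_u <- colMeans(X_u)
  xbar_r <- colMeans(X_r)
  dx <- xbar_u - xbar_r
  db <- b_u - b_r

  res_u <- threefold(fu, fr, X_u, X_r, reference = "urban")
  expect_equal(res_u$components[["total"]],
               sum(xbar_u * b_u) - sum(xbar_r * b_r), tolerance = 1e-14)
  expect_equal(res_u$components[["explained"]], sum(dx * b_u),
               tolerance = 1e-14)
  expect_equal(res_u$components[["unexplained"]], sum(xbar_u * db),
               tolerance = 1e-14)
  expect_equal(res_u$components[["interaction"]], -sum(dx * db),
               tolerance = 1e-14)

  res_r <- threefold(fu, fr, X_u, X_r, reference = "rural")
  expect_equal(res_r$components[["explained"]], sum(dx * b_r),
               tolerance = 1e-14)
  expect_equal(res_r$components[["unexplained"]], sum(xbar_r * db),
               tolerance = 1e-14)
  expect_equal(res_r$components[["interaction"]], sum(dx * db),
               tolerance = 1e-14)

  # explained(urban ref) - explained(rural ref) = interaction(rural ref)
  expect_equal(res_u$components[["explained"]] - res_r$components[["explained"]],
               res_r$components[["interaction"]], tolerance = 1e-14)
})

test_that("identical coefficients put the whole gap in the explained part", {
  spec <- compact_spec()
  tab <- generate_survey(spec, 2000, seed = 17)
  fit_u <- fit_group_model(tab, "urban", "logit")
  fit_r <- fit_group_model(tab, "rural", "logit")
  fit_r2 <- fit_r
  fit_r2$coefficients <- fit_u$coefficients
  X <- build_design(tab, fit_u$design_meta$terms)
  X_u <- X[tab$residence == "urban", ]
  X_r <- X[tab$residence == "rural", ]
  res <- threefold(fit_u, fit_r2, X_u, X_r, "urban")
  expect_equal(res$components[["unexplained"]], 0, tolerance = 1e-14)
  expect_equal(res$components[["interaction"]], 0, tolerance = 1e-14)
  expect_equal(res$components[["explained"]], res$components[["total"]],
               tolerance = 1e-14)
  # two-fold: advantage = disadvantage = 0 for every omega
  for (w in c(0, 0.3, 1)) {
    tw <- twofold(fit_u, fit_r2, X_u, X_r, w)
    expect_equal(tw$components[["advantage"]], 0, tolerance = 1e-14)
    expect_equal(tw$components[["disadvantage"]], 0, tolerance = 1e-14)
  }
})

test_that("two-fold endpoints coincide with the reference three-folds", {
  tab <- generate_survey(compact_spec(), 2500, seed = 19)
  fit_u <- fit_group_model(tab, "urban", "logit")
  fit_r <- fit_group_model(tab, "rural", "logit")
  X <- build_design(tab, fit_u$design_meta$terms)
  X_u <- X[tab$residence == "urban", ]
  X_r <- X[tab$residence == "rural", ]

  t1 <- twofold(fit_u, fit_r, X_u, X_r, omega = 1)
  expect_equal(t1$components[["advantage"]], 0, tolerance = 1e-14)
  expect_equal(t1$components[["explained"]],
               threefold(fit_u, fit_r, X_u, X_r, "urban")$components[["explained"]],
               tolerance = 1e-14)

  t0 <- twofold(fit_u, fit_r, X_u, X_r, omega = 0)
  expect_equal(t0$components[["disadvantage"]], 0, tolerance = 1e-14)
  expect_equal(t0$components[["explained"]],
               threefold(fit_u, fit_r, X_u, X_r, "rural")$components[["explained"]],
               tolerance = 1e-14)

  expect_error(twofold(fit_u, fit_r, X_u, X_r, omega = 1.2), "omega")
})

test_that("with a linear link the Reimers explained is the mean of the two references", {
  tab <- hand_table()
  tab$parity <- c(2, 1, 3, 1, 4, 2, 5, 3)
  fit_u <- fit_group_model(tab, "urban", "linear", c("x", "parity"))
  fit_r <- fit_group_model(tab, "rural", "linear", c("x", "parity"))
  X <- build_design(tab, c("x", "parity"))
  X_u <- X[tab$residence == "urban", ]
  X_r <- X[tab$residence == "rural", ]
  e_u <- threefold(fit_u, fit_r, X_u, X_r, "urban")$components[["explained"]]
  e_r <- threefold(fit_u, fit_r, X_u, X_r, "rural")$components[["explained"]]
  e_half <- twofold(fit_u, fit_r, X_u, X_r, 0.5)$components[["explained"]]
  expect_equal(e_half, (e_u + e_r) / 2, tolerance = 1e-13)
})

test_that("scheme weights follow their definitions", {
  expect_identical(scheme_weight("oaxaca"), 1)
  expect_identical(scheme_weight("blinder"), 0)
  expect_identical(scheme_weight("reimers"), 0.5)
  w <- scheme_weight("cotton", n_u = 5672, n_r = 8130)
  expect_equal(as.numeric(w), 5672 / 13802, tolerance = 1e-12)
  expect_equal(attr(w, "rural_share"), 8130 / 13802, tolerance = 1e-12)
  expect_error(scheme_weight("fairlie"), "valid schemes")
  expect_error(scheme_weight("cotton"), "n_u")
})

test_that("all schemes share one total and components always add up", {
  spec <- compact_spec()
  for (seed in 1:5) {
    tab <- generate_survey(spec, 1200, seed = seed)
    fit_u <- fit_group_model(tab, "urban", "logit")
    fit_r <- fit_group_model(tab, "rural", "logit")
    X <- build_design(tab, fit_u$design_meta$terms)
    X_u <- X[tab$residence == "urban", ]
    X_r <- X[tab$residence == "rural", ]
    totals <- vapply(c("oaxaca", "blinder", "reimers", "cotton"),
                     function(sc) {
      res <- decompose_scheme(fit_u, fit_r, X_u, X_r, sc)
      expect_lt(abs(sum(res$components[-1]) - res$components[["total"]]),
                1e-10)
      expect_lt(abs(sum(res$percent[-1]) - 100), 1e-6)
      res$components[["total"]]
    }, numeric(1))
    expect_lt(max(totals) - min(totals), 1e-10)
    # logit: total equals the raw gap in observed outcome means exactly
    raw_gap <- mean(tab$outcome[tab$residence == "urban"]) -
      mean(tab$outcome[tab$residence == "rural"])
    expect_equal(unname(totals[1]), raw_gap, tolerance = 1e-8)
  }
})

test_that("swapping the group labels negates the decomposition", {
  tab <- generate_survey(compact_spec(), 1500, seed = 23)
  fit_u <- fit_group_model(tab, "urban", "logit")
  fit_r <- fit_group_model(tab, "rural", "logit")
  X <- build_design(tab, fit_u$design_meta$terms)
  X_u <- X[tab$residence == "urban", ]
  X_r <- X[tab$residence == "rural", ]
  fwd <- twofold(fit_u, fit_r, X_u, X_r, 0.4)
  rev <- twofold(fit_r, fit_u, X_r, X_u, 0.6)
  expect_equal(rev$components[["total"]], -fwd$components[["total"]],
               tolerance = 1e-14)
  expect_equal(rev$components[["explained"]], -fwd$components[["explained"]],
               tolerance = 1e-14)
  expect_equal(rev$components[["advantage"]], -fwd$components[["disadvantage"]],
               tolerance = 1e-14)
  expect_equal(rev$components[["disadvantage"]], -fwd$components[["advantage"]],
               tolerance = 1e-14)
})

test_that("mismatched links or term sets are contract errors", {
  tab <- generate_survey(compact_spec(), 1000, seed = 29)
  fit_u <- fit_group_model(tab, "urban", "logit")
  fit_p <- fit_group_model(tab, "urban", "probit")
  fit_r <- fit_group_model(tab, "rural", "logit")
  fit_small <- fit_group_model(tab, "rural", "logit", terms = "education")
  X <- build_design(tab, fit_u$design_meta$terms)
  expect_error(threefold(fit_p, fit_r, X, X, "urban"), "different links")
  expect_error(threefold(fit_u, fit_small, X, X, "urban"), "namespace")
})
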