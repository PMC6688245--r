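test_that("population_spec validation names the offending field", {
  spec <- compact_spec()
  bad <- spec
  bad$covariates$rural$education <- norm_probs(c(1, 1, 1, 1), "education") * 2
  expect_error(validate_population_spec(bad), "education.*sum")

  bad <- spec
  bad$group_share_rural <- 1.2
  expect_error(validate_population_spec(bad), "group_share_rural")

  bad <- spec
  names(bad$beta_urban)[2] <- "nonsense"
  expect_error(validate_population_spec(bad), "beta_urban")

  bad <- spec
  bad$covariates$urban$distance_barrier <- -0.1
  expect_error(validate_population_spec(bad), "distance_barrier")
})

test_that("generate_survey is bit-identical under a fixed seed", {
  spec <- compact_spec()
  a <- generate_survey(spec, 1000, seed = 7)
  b <- generate_survey(spec, 1000, seed = 7)
  expect_identical(a, b)
  c <- generate_survey(spec, 1000, seed = 8)
  expect_false(identical(a, c))
})

test_that("generated tables respect the requested size and outcome domain", {
  spec <- compact_spec()
  tab <- generate_survey(spec, 500, seed = 1)
  expect_equal(nrow(tab), 500)
  expect_true(all(tab$outcome %in% c(0, 1)))
  expect_true(all(tab$parity >= 1))
  expect_s3_class(tab$residence, "factor")
})

test_that("rural row count matches the binomial share at DHS scale", {
  spec <- default_ghana_spec()
  tab <- generate_survey(spec, 13802, seed = 11)
  n_rural <- sum(tab$residence == "rural")
  tol <- 3 * sqrt(13802 * 0.589 * (1 - 0.589))
  expect_lt(abs(n_rural - 8130), tol)
})

test_that("degenerate coefficients give a degenerate outcome", {
  spec <- compact_spec()
  spec$beta_urban[] <- 0
  spec$beta_urban[["(Intercept)"]] <- -50
  spec$beta_rural <- spec$beta_urban
  tab <- generate_survey(spec, 300, seed = 3)
  expect_true(all(tab$outcome == 0))
})

test_that("empirical covariate margins converge to the spec margins", {
  spec <- compact_spec()
  tab <- generate_survey(spec, 40000, seed = 5)
  for (grp in c("rural", "urban")) {
    sub <- tab[tab$residence == grp, ]
    want <- spec$covariates[[grp]]$education
    got <- prop.table(table(sub$education))
    tol <- 3 * sqrt(want * (1 - want) / nrow(sub))
    expect_true(all(abs(got - want) < pmax(tol, 1e-3)),
                label = paste("education margins,", grp))
    p <- spec$covariates[[grp]]$distance_barrier
    expect_lt(abs(mean(sub$distance_barrier) - p),
              3 * sqrt(p * (1 - p) / nrow(sub)))
  }
})

test_that("default Ghana preset validates and hits its outcome-rate targets", {
  spec <- default_ghana_spec()
  expect_s3_class(validate_population_spec(spec), "population_spec")
  tab <- generate_survey(spec, 50000, seed = 7)
  expect_lt(abs(mean(tab$outcome[tab$residence == "urban"]) - 0.8469), 0.02)
  expect_lt(abs(mean(tab$outcome[tab$residence == "rural"]) - 0.4310), 0.02)
})

test_that("spec config files round-trip through YAML", {
  for (spec in list(compact_spec(), selection_spec(0.4),
                    default_ghana_spec())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_spec_config(spec, path)
    back <- read_spec_config(path)
    expect_equal(back$beta_urban, spec$beta_urban)
    expect_equal(back$beta_rural, spec$beta_rural)
    expect_equal(back$gamma_selection, spec$gamma_selection)
    expect_equal(back$covariates, spec$covariates, tolerance = 1e-12)
    expect_identical(back$link, spec$link)
    expect_equal(back$rho_selection, spec$rho_selection)
  }
})

test_that("population components vanish when their source of difference does", {
  eq_beta <- compact_spec(beta_equal = TRUE)
  pc <- population_components(eq_beta, "oaxaca", n_mc = 20000, seed = 2)
  expect_lt(abs(pc$components[["unexplained"]]),
            3 * pc$se[["unexplained"]] + 1e-12)
  expect_lt(abs(pc$components[["interaction"]]),
            3 * (pc$se[["interaction"]] + 1e-12))

  eq_cov <- compact_spec(covariates_equal = TRUE)
  pc2 <- population_components(eq_cov, "oaxaca", n_mc = 20000, seed = 2)
  expect_lt(abs(pc2$components[["explained"]]), 3 * pc2$se[["explained"]])

  pc3 <- population_components(eq_cov, "reimers", n_mc = 20000, seed = 2)
  expect_lt(abs(pc3$components[["explained"]]), 3 * pc3$se[["explained"]])
})

test_that("population components match an independent brute-force average", {
  spec <- compact_spec()
  pc <- population_components(spec, "oaxaca", n_mc = 2e5, seed = 9)

  # brute force: fresh draws, direct evaluation of plogis at the true betas,
  # written without the package's oracle path
  set.seed(4242)
  n <- 1e6
  draw_group <- function(grp) {
    cv <- spec$covariates[[grp]]
    lv <- survey_levels()
    edu <- sample(lv$education, n, TRUE, prob = cv$education)
    wq <- sample(lv$wealth_quintile, n, TRUE, prob = cv$wealth_quintile)
    db <- rbinom(n, 1, cv$distance_barrier)
    par <- 1 + rpois(n, cv$parity - 1)
    idx <- function(beta) {
      beta[["(Intercept)"]] +
        ifelse(edu == "none", 0, beta[paste0("education", edu)]) +
        ifelse(wq == "Q1", 0, beta[paste0("wealth_quintile", wq)]) +
        beta[["distance_barrier"]] * db + beta[["parity"]] * par
    }
    list(idx = idx)
  }
  gu <- draw_group("urban")
  gr <- draw_group("rural")
  m_uu <- mean(plogis(gu$idx(spec$beta_urban)))
  m_ur <- mean(plogis(gr$idx(spec$beta_urban)))
  m_ru <- mean(plogis(gu$idx(spec$beta_rural)))
  m_rr <- mean(plogis(gr$idx(spec$beta_rural)))

  brute <- c(total = m_uu - m_rr, explained = m_uu - m_ur,
             unexplained = m_uu - m_ru)
  brute[["interaction"]] <- brute[["total"]] - brute[["explained"]] -
    brute[["unexplained"]]
  for (comp in names(brute)) {
    expect_lt(abs(pc$components[[comp]] - brute[[comp]]),
              3 * (pc$se[[comp]] + abs(brute[[comp]]) / sqrt(n) + 1e-4),
              label = paste("component", comp))
  }
})

test_that("population components sum to the total gap for every scheme", {
  spec <- compact_spec()
  for (sc in c("oaxaca", "blinder", "reimers", "cotton")) {
    pc <- population_components(spec, sc, n_mc = 5000, seed = 1)
    expect_lt(abs(sum(pc$components[-1]) - pc$components[["total"]]), 1e-12)
  }
})

test_that("selection generator reduces to the no-selection model at rho = 0", {
  spec <- selection_spec(0, link = "logit")
  pop <- generate_population(spec, 30000, seed = 21)
  births <- pop[pop$gave_birth == 1, ]
  # conditional outcome rates among mothers must match the unconditional
  # model probabilities when selection is ignorable
  pc <- population_components(spec, "oaxaca", n_mc = 1e5, seed = 3)
  for (grp in c("rural", "urban")) {
    sub <- births[births$residence == grp, ]
    X <- build_design(sub, spec$outcome_terms)
    beta <- if (grp == "urban") spec$beta_urban else spec$beta_rural
    expect_lt(abs(mean(sub$outcome) - mean(plogis(drop(X %*% beta)))),
              4 * sqrt(0.25 / nrow(sub)))
  }
})
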