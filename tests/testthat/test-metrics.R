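test_that("normalized likelihood matches hand computations", {
  # NL = P(e|1) / (prior P(e|1) + (1-prior) P(e|0))
  m <- one_var_model(0.1, 0.8, 0.2)
  expect_equal(normalized_likelihood(m, "x", "pos"), 0.8 / 0.26,
               tolerance = 1e-12)
  expect_equal(normalized_likelihood(m, "x", "neg"), 0.2 / 0.74,
               tolerance = 1e-12)
  m_null <- one_var_model(0.1, 0.5, 0.5)
  expect_equal(normalized_likelihood(m_null, "x", "pos"), 1, tolerance = 1e-12)
})

test_that("NL equals the single-item posterior-to-prior ratio", {
  set.seed(17)
  for (i in 1:25) {
    m <- random_model(n_vars = 3, max_states = 4)
    nm <- sample(names(m$variables), 1)
    s <- sample(m$variables[[nm]]$states, 1)
    post <- predict_risk(m, evidence_vector(stats::setNames(list(s), nm)))$posterior
    expect_equal(normalized_likelihood(m, nm, s), post / m$prior,
                 tolerance = 1e-12)
  }
})

test_that("posterior odds factorize into prior odds times likelihood ratios", {
  set.seed(19)
  for (i in 1:25) {
    m <- random_model(n_vars = 5, max_states = 3)
    ev <- random_evidence(m, n_obs = sample(1:5, 1))
    r <- predict_risk(m, ev)
    lr_prod <- prod(exp(vapply(names(ev$assignments), function(nm) {
      log_likelihood_ratio(m, nm, ev$assignments[[nm]])
    }, numeric(1))))
    odds <- function(p) p / (1 - p)
    expect_equal(odds(r$posterior), odds(m$prior) * lr_prod,
                 tolerance = 1e-9 * odds(r$posterior))
  }
})

test_that("impact reports sort by NL and label directions", {
  vars <- list(variable_spec("u", "binary", c("n", "y")),
               variable_spec("v", "binary", c("n", "y")),
               variable_spec("w", "binary", c("n", "y")))
  cpts <- list(u = cbind(p_event = c(0.2, 0.8), p_noevent = c(0.8, 0.2)),
               v = cbind(p_event = c(0.8, 0.2), p_noevent = c(0.2, 0.8)),
               w = cbind(p_event = c(0.5, 0.5), p_noevent = c(0.5, 0.5)))
  m <- nb_model(0.1, vars, cpts)
  rep <- impact_report(m, evidence_vector(u = "y", v = "y", w = "y"))
  expect_identical(rep$variable, c("u", "w", "v"))
  expect_identical(rep$direction, c("risk-increasing", "neutral", "protective"))
  expect_equal(rep$nl[1], 0.8 / 0.26, tolerance = 1e-12)
  expect_equal(rep$nl[3], 0.2 / 0.74, tolerance = 1e-12)
  expect_error(impact_report(m, evidence_vector()), "at least one")
})

test_that("VOI reproduces the closed-form binary-entropy case", {
  # prior 0.5, P(x=1|Y=1) = 0.9, P(x=1|Y=0) = 0.1: I(Y;X) = 1 - H2(0.9)
  m <- one_var_model(0.5, 0.9, 0.1)
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(value_of_information(m, candidate = "x"), 1 - h2(0.9),
               tolerance = 1e-12)
  expect_equal(1 - h2(0.9), 0.531, tolerance = 1e-3)
})

test_that("VOI is zero under conditional independence and for observed items", {
  m <- one_var_model(0.3, 0.4, 0.4)
  expect_equal(value_of_information(m, candidate = "x"), 0, tolerance = 1e-12)
  m2 <- toy_model()
  expect_message(
    v <- value_of_information(m2, evidence_vector(marker = "pos"), "marker"),
    "already observed")
  expect_identical(v, 0)
})

test_that("VOI equals brute-force conditional mutual information", {
  set.seed(23)
  for (i in 1:25) {
    m <- random_model(n_vars = sample(2:4, 1), max_states = 3)
    vnames <- names(m$variables)
    cand <- sample(vnames, 1)
    others <- setdiff(vnames, cand)
    n_obs <- sample(0:length(others), 1)
    asg <- character(0)
    if (n_obs > 0) {
      picked <- sample(others, n_obs)
      asg <- vapply(picked, function(nm) sample(m$variables[[nm]]$states, 1),
                    character(1))
    }
    ev <- evidence_vector(as.list(asg))
    expect_lt(abs(value_of_information(m, ev, cand) -
                  brute_force_voi(m, ev, cand)), 1e-12)
  }
})

test_that("VOI is non-negative across random models", {
  set.seed(29)
  for (i in 1:200) {
    m <- random_model(n_vars = 3, max_states = 3)
    cand <- sample(names(m$variables), 1)
    v <- value_of_information(m, evidence_vector(), cand)
    expect_gte(v, 0)
  }
})

test_that("indexed VOI normalizes per mode with identical ordering", {
  m <- example_model()
  ev <- case_study_fixture()$evidence
  r_max <- indexed_voi(m, ev, mode = "max")
  r_res <- indexed_voi(m, ev, mode = "residual-entropy")
  expect_equal(r_max$indexed_voi[1], 1, tolerance = 1e-12)
  expect_identical(r_max$variable, r_res$variable)
  expect_true(all(diff(r_max$voi_bits) <= 1e-15))
  expect_true(all(r_res$indexed_voi <= 1 + 1e-12))
  expect_identical(attr(r_res, "normalization_mode"), "residual-entropy")
  # observed candidates are dropped; all-observed gives an empty report
  empty <- indexed_voi(m, ev, candidates = names(ev$assignments))
  expect_identical(nrow(empty), 0L)
})

test_that("all-zero VOIs index to zero without dividing by zero", {
  vars <- list(variable_spec("u", "binary", c("n", "y")),
               variable_spec("v", "binary", c("n", "y")))
  cpts <- list(u = cbind(p_event = c(0.6, 0.4), p_noevent = c(0.6, 0.4)),
               v = cbind(p_event = c(0.3, 0.7), p_noevent = c(0.3, 0.7)))
  m <- nb_model(0.2, vars, cpts)
  rep <- indexed_voi(m, evidence_vector(), mode = "max")
  expect_equal(rep$voi_bits, c(0, 0), tolerance = 1e-12)
  expect_equal(rep$indexed_voi, c(0, 0))
})
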