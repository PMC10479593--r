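test_that("odds-ratio inversion reproduces closed-form cases", {
  # no association: conditionals equal the marginal
  ab <- or_to_conditionals(1, 0.1, 0.3)
  expect_equal(unname(ab), c(0.3, 0.3), tolerance = 1e-12)

  # symmetric case prior = q = 0.5, OR = 9 -> (0.75, 0.25)
  ab <- or_to_conditionals(9, 0.5, 0.5)
  expect_equal(unname(ab), c(0.75, 0.25), tolerance = 1e-10)

  # quadratic case 9 b^2 + 9 b - 2 = 0 -> b = (sqrt(153) - 9) / 18
  ab <- or_to_conditionals(2, 0.1, 0.2)
  b_expected <- (sqrt(153) - 9) / 18
  expect_equal(unname(ab[["p_noevent"]]), b_expected, tolerance = 1e-10)
  expect_equal(unname(ab[["p_event"]]), (0.2 - 0.9 * b_expected) / 0.1,
               tolerance = 1e-10)
})

test_that("risk-ratio inversion reproduces closed-form cases", {
  expect_equal(unname(rr_to_conditionals(1, 0.2, 0.4)), c(0.4, 0.4),
               tolerance = 1e-12)
  # symmetric 2x2: RR = 3 with prior = q = 0.5 -> (0.75, 0.25)
  ab <- rr_to_conditionals(3, 0.5, 0.5)
  expect_equal(unname(ab), c(0.75, 0.25), tolerance = 1e-10)
  # implied P(Y=1|E=1) > 1 is infeasible
  expect_error(rr_to_conditionals(10, 0.5, 0.1), "infeasible")
})

test_that("inversion round-trips the effect size and satisfies the margin", {
  set.seed(7)
  for (i in 1:1000) {
    tr <- random_or_triple()
    ab <- or_to_conditionals(tr[["or"]], tr[["prior"]], tr[["q"]])
    a <- ab[["p_event"]]; b <- ab[["p_noevent"]]
    or_back <- (a / (1 - a)) / (b / (1 - b))
    expect_lt(abs(log(or_back) - log(tr[["or"]])), 1e-9)
    margin <- tr[["prior"]] * a + (1 - tr[["prior"]]) * b
    expect_lt(abs(margin - tr[["q"]]), 1e-10)
  }
  for (i in 1:1000) {
    tr <- random_rr_triple()
    ab <- rr_to_conditionals(tr[["rr"]], tr[["prior"]], tr[["q"]])
    a <- ab[["p_event"]]; b <- ab[["p_noevent"]]
    p <- tr[["prior"]]; q <- tr[["q"]]
    risk1 <- p * a / q
    risk0 <- p * (1 - a) / (1 - q)
    expect_lt(abs(log(risk1 / risk0) - log(tr[["rr"]])), 1e-9)
    expect_lt(abs(p * a + (1 - p) * b - q), 1e-10)
  }
})

test_that("inversion agrees with an exhaustive grid search over 2x2 tables", {
  set.seed(11)
  bs <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  for (i in 1:50) {
    tr <- random_or_triple()
    p <- tr[["prior"]]; q <- tr[["q"]]; or <- tr[["or"]]
    a_grid <- (q - (1 - p) * bs) / p
    valid <- a_grid > 0 & a_grid < 1
    or_grid <- (a_grid / (1 - a_grid)) / (bs / (1 - bs))
    err <- suppressWarnings(abs(log(or_grid) - log(or)))
    err[!valid | !is.finite(err)] <- Inf
    b_star <- bs[which.min(err)]
    ab <- or_to_conditionals(or, p, q)
    expect_lt(abs(ab[["p_noevent"]] - b_star), 1e-3)
  }
})

test_that("hazard ratios are routed through the risk-ratio path", {
  expect_equal(effect_to_conditionals("HR", 2, 0.05, 0.3),
               rr_to_conditionals(2, 0.05, 0.3))
  expect_equal(effect_to_conditionals("OR", 2, 0.05, 0.3),
               or_to_conditionals(2, 0.05, 0.3))
})

test_that("a null effect yields identical CPT columns", {
  spec <- variable_spec("x", "binary", c("no", "yes"))
  ct <- conditional_table(
    spec,
    effects = list(yes = list(measure = "OR", pooled_effect = 1)),
    prevalences = c(yes = 0.2), outcome_prev = 0.1
  )
  expect_equal(ct$probs[, "p_event"], ct$probs[, "p_noevent"],
               tolerance = 1e-9)
})

test_that("a single-variable network carries the inverted conditionals", {
  spec <- variable_spec("x", "binary", c("no", "yes"))
  model <- build_network(
    prior = 0.1, variables = list(spec),
    effects = list(x = list(yes = list(measure = "OR", pooled_effect = 2))),
    prevalences = list(x = c(yes = 0.2))
  )
  b <- (sqrt(153) - 9) / 18
  a <- (0.2 - 0.9 * b) / 0.1
  # smoothing perturbs at most ~eps relative to the exact inversion
  expect_equal(unname(model$cpts$x$probs["yes", ]), c(a, b), tolerance = 1e-4)
  expect_equal(unname(model$cpts$x$probs["no", ]), c(1 - a, 1 - b),
               tolerance = 1e-4)
})

test_that("the full 31-variable build passes every model invariant", {
  model <- example_model()
  expect_s3_class(model, "calibra_model")
  expect_length(model$variables, 31L)
  expect_length(model$cpts, 31L)
  for (ct in model$cpts) {
    expect_equal(unname(colSums(ct$probs)), c(1, 1), tolerance = 1e-12)
    expect_true(all(ct$probs > 0 & ct$probs < 1))
  }
})

test_that("missing knowledge is reported by variable and state", {
  spec <- variable_spec("x", "categorical", c("a", "b", "c"))
  expect_error(
    conditional_table(spec,
                      effects = list(b = list(measure = "OR", pooled_effect = 2)),
                      prevalences = c(b = 0.2, c = 0.1), outcome_prev = 0.1),
    "incomplete knowledge.*'x'.*'c'"
  )
  expect_error(
    conditional_table(spec,
                      effects = list(b = list(measure = "OR", pooled_effect = 2),
                                     c = list(measure = "OR", pooled_effect = 3)),
                      prevalences = c(b = 0.2), outcome_prev = 0.1),
    "incomplete knowledge"
  )
})

test_that("model validation catches broken CPTs and priors", {
  m <- toy_model()
  bad <- m
  bad$prior <- 1.2
  expect_error(validate_model(bad), "prior")
  bad <- m
  bad$cpts$marker$probs[1, 1] <- 0.9  # column no longer sums to 1
  expect_error(validate_model(bad), "sum")
  bad <- m
  bad$cpts$marker <- NULL
  expect_error(validate_model(bad), "one CPT per variable")
})
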