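test_that("trapezoid and triangle membership follow the piecewise-linear form", {
  young <- fuzzy_set("young", "trapezoid", c(10, 15, 18, 22))
  expect_equal(membership(young, 16), 1)          # plateau
  expect_equal(membership(young, 9), 0)           # outside support
  expect_equal(membership(young, 20), 0.5)        # falling limb 1-(20-18)/4
  expect_equal(membership(young, c(10, 12.5, 15, 18, 22)),
               c(0, 0.5, 1, 1, 0))                # breakpoints exactly
  no <- fuzzy_set("no", "triangle", c(0, 0, 0.5)) # degenerate left edge
  expect_equal(membership(no, c(0, 0.25, 0.5, 1)), c(1, 0.5, 0, 0))
  tri <- fuzzy_set("t", "triangle", c(0, 1, 4))
  expect_equal(membership(tri, c(0, 0.5, 1, 2.5, 4)), c(0, 0.5, 1, 0.5, 0))
  expect_true(all(membership(tri, seq(-2, 6, by = 0.01)) >= 0))
  expect_true(all(membership(tri, seq(-2, 6, by = 0.01)) <= 1))
})

test_that("malformed set definitions are configuration errors", {
  expect_error(fuzzy_set("bad", "trapezoid", c(5, 3, 8, 9)), class = "agcdx_config_error")
  expect_error(fuzzy_set("bad", "triangle", c(1, 2, 3, 4)), class = "agcdx_config_error")
  expect_error(fuzzy_variable("v", c(0, 1),
                              list(fuzzy_set("s", "triangle", c(0, 1, 2)))),
               class = "agcdx_config_error")  # support exceeds universe
})

test_that("fuzzification returns one degree per set and clamps to the universe", {
  ps <- fuzzy_variable("PS", c(0, 20), list(
    fuzzy_set("few", "trapezoid", c(0, 2, 3, 4)),
    fuzzy_set("many", "trapezoid", c(3, 5, 9, 10)),
    fuzzy_set("unusual", "trapezoid", c(9, 15, 20, 20))))
  expect_equal(fuzzify(ps, 3), c(few = 1, many = 0, unusual = 0))
  ets <- fuzzy_variable("ETS", c(0, 1.5), list(
    fuzzy_set("no", "triangle", c(0, 0, 0.5)),
    fuzzy_set("yes", "triangle", c(0.51, 1, 1.5))))
  expect_equal(fuzzify(ets, 0), c(no = 1, yes = 0))
  expect_warning(d <- fuzzify(ets, -1), "clamped")
  expect_equal(d, c(no = 1, yes = 0))
})

test_that("hairline coverage gaps snap to the nearest support with a warning", {
  ng <- fuzzy_variable("NG", c(0, 18), list(
    fuzzy_set("null", "triangle", c(0, 0, 0.5)),
    fuzzy_set("few", "triangle", c(0.51, 4, 8)),
    fuzzy_set("many", "trapezoid", c(7, 8, 18, 18))))
  expect_warning(d <- fuzzify(ng, 0.505), "gap")
  expect_gt(sum(d), 0)
})

test_that("rule firing is the AND of antecedent degrees and honors disabling", {
  degrees <- list(A = c(hi = 1, lo = 0.2), B = c(hi = 1, lo = 0.7))
  rule <- list(A = "hi", B = "hi", consequent = "out", enabled = TRUE)
  expect_equal(fire_rule(rule, degrees), 1)
  rule2 <- list(A = "lo", B = "lo", consequent = "out", enabled = TRUE)
  expect_equal(fire_rule(rule2, degrees), 0.2)
  expect_equal(fire_rule(rule2, degrees, and_op = "prod"), 0.2 * 0.7)
  rule2$enabled <- FALSE
  expect_equal(fire_rule(rule2, degrees), 0)
  expect_error(fire_rule(list(A = "hi", C = "hi", enabled = TRUE), degrees),
               class = "agcdx_input_error")
})

test_that("centroid defuzzification matches closed-form centers of gravity", {
  res <- 10001L
  sym <- fuzzy_variable("o", c(0, 10),
                        list(fuzzy_set("s", "triangle", c(2, 5, 8))))
  expect_equal(defuzzify_centroid(sym, list(s = 1), res), 5, tolerance = 1e-6)
  rect <- fuzzy_variable("o", c(0, 10),
                         list(fuzzy_set("r", "trapezoid", c(2, 2, 8, 8))))
  expect_equal(defuzzify_centroid(rect, list(r = 1), res), 5, tolerance = 1e-6)
  # right triangle: centroid one third of the base from the right angle
  rt <- fuzzy_variable("o", c(0, 10),
                       list(fuzzy_set("r", "triangle", c(2, 8, 8))))
  expect_equal(defuzzify_centroid(rt, list(r = 1), res), 8 - 6 / 3,
               tolerance = 1e-3)
  expect_error(defuzzify_centroid(sym, list(s = 0), res),
               class = "agcdx_compute_error")
})

test_that("centroid agrees with an independent trapz integration oracle", {
  set.seed(42)
  for (i in 1:25) {
    case <- random_defuzz_case()
    got <- defuzzify_centroid(case$variable, case$activations,
                              resolution = 100001L)
    want <- oracle_centroid(case$variable, case$activations, n = 100001L)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("activation scaling leaves the centroid where theory says it must", {
  # min implication: clipping a symmetric set at any level keeps its center
  sym <- fuzzy_variable("o", c(0, 10),
                        list(fuzzy_set("s", "trapezoid", c(1, 4, 6, 9))))
  for (k in c(1, 0.6, 0.25, 0.05))
    expect_equal(defuzzify_centroid(sym, list(s = k), 20001L), 5,
                 tolerance = 1e-6)
  # prod implication: scaling the whole surface never moves the centroid,
  # symmetric or not
  asym <- fuzzy_variable("o", c(0, 10),
                         list(fuzzy_set("s", "triangle", c(0, 1, 9))))
  ref <- defuzzify_centroid(asym, list(s = 1), 20001L, implication = "prod")
  for (k in c(0.7, 0.3, 0.1))
    expect_equal(defuzzify_centroid(asym, list(s = k), 20001L,
                                    implication = "prod"),
                 ref, tolerance = 1e-9)
})

test_that("inference is deterministic and stays within the activated supports", {
  model <- injury_model_default()
  inputs <- list(DN = 7000, TN = 84, HN = 0.78, PN = 5, R = 1.2)
  a <- infer(model, inputs)
  b <- infer(model, inputs)
  expect_identical(a$score, b$score)
  expect_identical(a$label, b$label)
  # convex hull of activated output supports contains the crisp value
  act <- a$activations[a$activations > 0]
  sup <- sapply(names(act), function(lab)
    model$output$sets[[lab]]$params[c(1, length(model$output$sets[[lab]]$params))])
  expect_gte(a$score, min(sup))
  expect_lte(a$score, max(sup))
})

test_that("a single firing rule reduces inference to its clipped-set centroid", {
  v_in <- fuzzy_variable("x", c(0, 10), list(
    fuzzy_set("lo", "trapezoid", c(0, 0, 3, 5)),
    fuzzy_set("hi", "trapezoid", c(5, 7, 10, 10))))
  v_out <- fuzzy_variable("y", c(0, 100), list(
    fuzzy_set("a", "trapezoid", c(0, 0, 31, 41)),
    fuzzy_set("b", "trapezoid", c(58, 68, 100, 100))))
  rules <- data.frame(x = c("lo", "hi"), consequent = c("a", "b"))
  m <- mamdani_model(list(v_in), v_out, rules)
  res <- infer(m, list(x = 1))                    # only "lo" fires, degree 1
  expect_equal(res$activations, c(a = 1, b = 0))
  expect_equal(res$score, defuzzify_centroid(v_out, list(a = 1), 1001L))
  expect_equal(res$label, "a")
})

test_that("model construction validates rule references and variables", {
  v <- fuzzy_variable("x", c(0, 1), list(fuzzy_set("s", "triangle", c(0, 0.5, 1))))
  out <- fuzzy_variable("y", c(0, 1), list(fuzzy_set("o", "triangle", c(0, 0.5, 1))))
  expect_error(mamdani_model(list(v), out,
                             data.frame(x = "nope", consequent = "o")),
               class = "agcdx_config_error")
  expect_error(mamdani_model(list(v), out,
                             data.frame(x = "s", consequent = "nope")),
               class = "agcdx_config_error")
  m <- mamdani_model(list(v), out, data.frame(x = "s", consequent = "o"))
  expect_s3_class(m, "mamdani_model")
  expect_output(print(m), "Mamdani")
})
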