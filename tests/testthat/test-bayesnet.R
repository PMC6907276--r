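make_chain_bn <- function(p_a1 = 0.4, p_b1_a1 = 0.75, p_b1_a0 = 0.2) {
  g <- dag(c("A", "B"), tibble::tibble(parent = "A", child = "B"))
  variables <- list(A = c("a1", "a0"), B = c("b1", "b0"))
  cpts <- list(
    A = cpt("A", character(0),
            array(c(p_a1, 1 - p_a1), dim = 2, dimnames = list(A = c("a1", "a0")))),
    B = cpt("B", "A",
            array(c(p_b1_a1, 1 - p_b1_a1, p_b1_a0, 1 - p_b1_a0), dim = c(2, 2),
                  dimnames = list(B = c("b1", "b0"), A = c("a1", "a0"))))
  )
  bayesian_network(variables, g, cpts)
}

test_that("dag construction rejects cycles and undeclared nodes", {
  expect_error(dag(c("a", "b"),
                   tibble::tibble(parent = c("a", "b"), child = c("b", "a"))),
               "cycle")
  expect_error(dag("a", tibble::tibble(parent = "a", child = "z")),
               "undeclared")
  g <- dag(c("a", "b", "c"), tibble::tibble(parent = c("a", "b"),
                                            child = c("b", "c")))
  expect_s3_class(g, "vdt_dag")
})

test_that("maximum-likelihood CPT estimation matches hand counts", {
  g <- dag(c("A", "B"), tibble::tibble(parent = "A", child = "B"))
  rec <- tibble::tibble(A = c("a1", "a1", "a1", "a0"),
                        B = c("b1", "b1", "b0", "b0"))
  bn <- fit_mle(g, rec)
  expect_equal(bn$cpts$B$prob["b1", "a1"], 2 / 3)
  expect_equal(bn$cpts$B$prob["b1", "a0"], 0)
  expect_equal(unname(bn$cpts$A$prob[["a1"]]), 3 / 4)

  sm <- fit_mle(g, rec, smoothing = 1)
  expect_equal(sm$cpts$B$prob["b1", "a1"], (2 + 1) / (3 + 2))

  # unobserved parent combination with zero smoothing: uniform fallback
  rec2 <- tibble::tibble(A = c("a1", "a1"), B = c("b1", "b0"))
  bn2 <- fit_mle(g, rec2, states = list(A = c("a0", "a1"), B = c("b0", "b1")))
  expect_equal(unname(bn2$cpts$B$prob[, "a0"]), c(0.5, 0.5))

  expect_error(fit_mle(g, tibble::tibble(A = "a9", B = "b1"),
                       states = list(A = c("a0", "a1"), B = c("b0", "b1"))),
               "outside declared")
})

test_that("joint probability is the CPT product and normalizes", {
  bn <- make_chain_bn()
  expect_equal(joint_probability(bn, c(A = "a1", B = "b1")), 0.4 * 0.75)
  grid <- expand.grid(A = c("a1", "a0"), B = c("b1", "b0"),
                      stringsAsFactors = FALSE)
  total <- sum(vapply(seq_len(nrow(grid)), function(r) {
    joint_probability(bn, c(A = grid$A[[r]], B = grid$B[[r]]))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  expect_error(joint_probability(bn, c(A = "a1")), "missing")
})

test_that("posterior matches the enumeration oracle on hand and random nets", {
  bn <- make_chain_bn()
  # diagnostic direction, hand Bayes: P(a1 | b1) = .3 / (.3 + .12)
  expect_equal(unname(posterior(bn, "A", c(B = "b1"))[["a1"]]),
               0.3 / 0.42, tolerance = 1e-12)
  expect_equal(unname(posterior(bn, "A")), c(0.4, 0.6), tolerance = 1e-12)

  withr::with_seed(101, {
    for (rep in 1:25) {
      rbn <- random_binary_bn(sample(2:6, 1))
      nodes <- names(rbn$variables)
      q <- sample(nodes, 1)
      n_ev <- sample(0:min(2, length(nodes) - 1), 1)
      ev <- NULL
      if (n_ev > 0) {
        ev_vars <- sample(setdiff(nodes, q), n_ev)
        ev <- stats::setNames(sample(c("s0", "s1"), n_ev, replace = TRUE),
                              ev_vars)
      }
      expect_equal(unname(posterior(rbn, q, ev)),
                   unname(enum_posterior(rbn, q, ev)), tolerance = 1e-12)
    }
  })
})

test_that("impossible evidence raises a zero-probability error", {
  bn <- make_chain_bn(p_a1 = 1)
  expect_error(posterior(bn, "B", c(A = "a0")), "probability zero")
  expect_error(posterior(bn, "A", c(A = "a1")), "must not appear")
  expect_error(posterior(bn, "A", c(B = "nope")), "not a state")
})

test_that("the spec-parameterised naive network answers diagnostic queries exactly", {
  spec <- default_population_spec()
  bn <- naive_bn_from_spec(spec)
  post <- posterior(bn, "age_ge39", c(disorder = "musculoskeletal"))
  expect_equal(unname(post), c(0.7181, 0.2819), tolerance = 1e-12)

  prof_none <- diagnostic_profile(bn, "none")
  expect_equal(prof_none$probability[prof_none$attribute == "sleep"], 0.1673)
  prof_cv <- diagnostic_profile(bn, "cardiovascular")
  expect_equal(prof_cv$probability[prof_cv$attribute == "sex"], 0.8140)
  expect_true(all(prof_cv$probability >= 0 & prof_cv$probability <= 1))
  expect_error(diagnostic_profile(bn, "gibberish"), "unknown disorder state")
})

test_that("classification is MAP with declared-order tie-breaking", {
  # degenerate prior: first class always wins regardless of evidence
  g <- dag(c("T", "X"), tibble::tibble(parent = "T", child = "X"))
  variables <- list(T = c("t1", "t2"), X = c("x1", "x2"))
  cpts <- list(
    T = cpt("T", character(0), array(c(1, 0), 2, list(T = c("t1", "t2")))),
    X = cpt("X", "T", array(c(0.5, 0.5, 0.5, 0.5), c(2, 2),
                            list(X = c("x1", "x2"), T = c("t1", "t2"))))
  )
  bn <- bayesian_network(variables, g, cpts)
  expect_equal(classify(bn, c(X = "x1"), target = "T"), "t1")

  # symmetric parameters construct an exact posterior tie -> first state
  cpts$T <- cpt("T", character(0), array(c(0.5, 0.5), 2,
                                         list(T = c("t1", "t2"))))
  cpts$X <- cpt("X", "T", array(c(0.3, 0.7, 0.3, 0.7), c(2, 2),
                                list(X = c("x1", "x2"), T = c("t1", "t2"))))
  tie_bn <- bayesian_network(variables, g, cpts)
  expect_equal(classify(tie_bn, c(X = "x2"), target = "T"), "t1")

  # agreement with an independently implemented naive-Bayes oracle
  cohort <- generate_cohort(default_population_spec(), n = 5000, seed = 13)
  star <- learn_abn_structure(cohort, cmi_threshold = Inf)
  expect_equal(sum(star$arcs$parent != "disorder"), 0)
  bn_star <- fit_mle(star, cohort)
  withr::with_seed(14, {
    for (rep in 1:10) {
      ev <- vapply(exam_attribute_states(), function(pair) sample(pair, 1), "")
      expect_equal(classify(bn_star, ev),
                   naive_bayes_oracle(cohort, ev))
    }
  })
})

test_that("sensitivity analysis matches the two-node closed form", {
  bn <- make_chain_bn(p_a1 = 0.4, p_b1_a1 = 0.75, p_b1_a0 = 0.2)
  expect_identical(sensitivity(bn, "A", "a1", 0, "B", "b1"), 0)
  delta <- 0.1
  hand <- (0.5 * 0.75 + 0.5 * 0.2) - (0.4 * 0.75 + 0.6 * 0.2)
  expect_equal(sensitivity(bn, "A", "a1", delta, "B", "b1"), hand,
               tolerance = 1e-12)
  expect_error(sensitivity(bn, "A", "a1", 0.7, "B", "b1"), "outside")

  # disconnected components: no influence propagates
  g <- dag(c("A", "B"))
  variables <- list(A = c("a1", "a0"), B = c("b1", "b0"))
  cpts <- list(
    A = cpt("A", character(0), array(c(0.3, 0.7), 2, list(A = c("a1", "a0")))),
    B = cpt("B", character(0), array(c(0.6, 0.4), 2, list(B = c("b1", "b0"))))
  )
  disc <- bayesian_network(variables, g, cpts)
  expect_equal(sensitivity(disc, "A", "a1", 0.2, "B", "b1"), 0,
               tolerance = 1e-12)
})

test_that("CMI is non-negative, symmetric, and vanishes under conditional independence", {
  cohort <- generate_cohort(default_population_spec(), n = 4000, seed = 21)
  attrs <- names(exam_attribute_states())
  withr::with_seed(22, pick <- replicate(8, sample(attrs, 2), simplify = FALSE))
  for (pr in pick) {
    c1 <- conditional_mutual_information(cohort, pr[[1]], pr[[2]], "disorder")
    c2 <- conditional_mutual_information(cohort, pr[[2]], pr[[1]], "disorder")
    expect_gte(c1, 0)
    expect_equal(c1, c2, tolerance = 1e-12)
    expect_equal(c1, enum_cmi(cohort, pr[[1]], pr[[2]], "disorder"),
                 tolerance = 1e-12)
  }
})

test_that("ABN structure learning augments only where dependence exists", {
  spec <- default_population_spec()
  # conditionally independent attributes: naive star only
  indep <- generate_cohort(spec, n = 20000, seed = 31)
  g <- learn_abn_structure(indep, cmi_threshold = 0.01)
  expect_equal(sum(g$arcs$parent == "disorder"), 7)
  expect_equal(sum(g$arcs$parent != "disorder"), 0)

  # a deterministic copy has maximal CMI: the planted arc is recovered,
  # directed away from the lexicographically smaller attribute
  dep <- generate_cohort(spec, n = 20000, seed = 31,
                         couple = list(from = "smoker", to = "sleep",
                                       agreement = 1))
  g2 <- learn_abn_structure(dep, cmi_threshold = 0.01)
  aug <- g2$arcs[g2$arcs$parent != "disorder", ]
  expect_true(nrow(aug) >= 1)
  expect_true(any(aug$parent == "sleep" & aug$child == "smoker"))

  # structural contract: star present, forest augmentation, at most one
  # feature parent per feature, acyclic overall
  expect_lte(nrow(aug), 6)
  expect_lte(max(table(factor(aug$child, levels = names(exam_attribute_states())))), 1)
  expect_error(learn_abn_structure(indep, target = "nope"), "not present")
})

test_that("fitted parameters recover a known network within 3 SE", {
  spec <- default_population_spec()
  cohort <- generate_cohort(spec, n = 50000, seed = 41)
  star <- dag(c("disorder", names(exam_attribute_states())),
              tibble::tibble(parent = "disorder",
                             child = names(exam_attribute_states())))
  bn <- fit_mle(star, cohort)
  counts <- table(cohort$disorder)
  for (cl in disorder_classes()) {
    for (a in names(exam_attribute_states())) {
      p <- spec$conditionals[cl, a]
      est <- bn$cpts[[a]]$prob[exam_attribute_states()[[a]][[1]], cl]
      se <- sqrt(p * (1 - p) / counts[[cl]])
      expect_lt(abs(est - p), 3 * se + 1e-12)
    }
  }
})

test_that("networks round-trip through JSON serialization", {
  cohort <- generate_cohort(default_population_spec(), n = 2000, seed = 51)
  g <- learn_abn_structure(cohort)
  bn <- fit_mle(g, cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(bn, path)
  back <- read_network(path)
  expect_equal(back$variables, bn$variables)
  expect_equal(back$graph$arcs, bn$graph$arcs)
  for (v in names(bn$cpts)) {
    expect_equal(back$cpts[[v]]$prob, bn$cpts[[v]]$prob)
  }
  post_a <- posterior(bn, "disorder", c(smoker = "yes"))
  post_b <- posterior(back, "disorder", c(smoker = "yes"))
  expect_equal(post_a, post_b, tolerance = 1e-12)
})

test_that("tidy and glance summarise a network", {
  bn <- naive_bn_from_spec(default_population_spec())
  td <- tidy(bn)
  expect_true(all(c("node", "state", "parent_config", "probability") %in%
                    names(td)))
  expect_equal(sum(td$node == "disorder"), 6)
  expect_equal(td$probability[td$node == "age_ge39" & td$state == "yes" &
                                td$parent_config == "disorder=musculoskeletal"],
               0.7181)
  gl <- glance(bn)
  expect_equal(gl$n_nodes, 8)
  expect_equal(gl$n_arcs, 7)
  expect_equal(gl$n_augmentation_arcs, 0)
  p <- autoplot(bn)
  expect_s3_class(p, "ggplot")
})
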