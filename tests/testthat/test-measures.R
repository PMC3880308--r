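# expected values below were computed by hand from the closed-form
# definitions (2x2 contingency table with n_ab, n_a, n_b, N)

test_that("measures reproduce hand-evaluated values on the worked-example counts", {
  expect_equal(compute_measure("Jac", 15, 90, 30), 15 / 105, tolerance = 1e-12)
  expect_equal(compute_measure("Kulc", 10, 15, 30), 0.5)
  expect_equal(compute_measure("ACnf", 10, 15, 30), 1 / 3)
  expect_equal(compute_measure("Cos", 10, 15, 30), 0.4714045, tolerance = 1e-6)
  expect_equal(compute_measure("Lift", 15, 90, 30, 1000), 5.555556, tolerance = 1e-6)
  expect_equal(compute_measure("BF", 15, 90, 30, 1000), 10.11111, tolerance = 1e-5)
  expect_equal(compute_measure("Phi", 15, 90, 30, 1000), 0.2519513, tolerance = 1e-6)
  expect_equal(compute_measure("CCnf", 15, 90, 30, 1000), 15 / 90 - 30 / 1000)
  expect_equal(compute_measure("Sup", 15, 90, 30, 1000), 0.015)
  expect_equal(compute_measure("Cnf", 15, 90, 30), 15 / 90)
})

test_that("boundary cases behave as the closed forms dictate", {
  expect_equal(compute_measure("Jac", 0, 5, 7), 0)
  expect_equal(compute_measure("Jac", 4, 4, 4), 1)
  expect_identical(compute_measure("BF", 3, 10, 3, 100), Inf)
  expect_warning(out <- compute_measure("Phi", 5, 5, 5, 5), "phi undefined")
  expect_equal(out, 0)
  expect_error(compute_measure("Sup", 1, 2, 3), "needs the transaction total")
  expect_error(compute_measure("Jac", 5, 3, 4), "n_ab must lie")
})

test_that("measure values stay in their declared ranges", {
  set.seed(3)
  for (i in 1:200) {
    n_a <- sample(1:50, 1); n_b <- sample(1:50, 1)
    n_ab <- sample(0:min(n_a, n_b), 1)
    N <- max(n_a, n_b) + sample(0:100, 1)
    for (m in c("Sup", "Cnf", "Cos", "ACnf", "Kulc", "Jac")) {
      v <- compute_measure(m, n_ab, n_a, n_b, N)
      expect_gte(v, 0); expect_lte(v, 1)
    }
    expect_gte(compute_measure("Lift", n_ab, n_a, n_b, N), 0)
    suppressWarnings({
      expect_gte(compute_measure("BF", n_ab, n_a, n_b, N), 0)
      cc <- compute_measure("CCnf", n_ab, n_a, n_b, N)
      expect_gt(cc, -1); expect_lt(cc, 1)
      ph <- compute_measure("Phi", n_ab, n_a, n_b, N, phi_clamp = TRUE)
      expect_gte(ph, 0); expect_lte(ph, 1)
    })
  }
})

test_that("every measure is non-decreasing in the co-occurrence count", {
  n_a <- 20; n_b <- 30; N <- 200
  for (m in setdiff(measure_ids(), c("JacDif", "CosDif"))) {
    v <- compute_measure(m, 0:20, n_a, n_b, N)
    expect_true(all(diff(v) >= 0), info = m)
  }
})

test_that("null-invariant measures ignore N while the frequency-based ones do not", {
  inv <- c("Cnf", "Cos", "ACnf", "Kulc", "Jac")
  dep <- c("Sup", "Lift", "CCnf", "Phi")
  for (m in inv)
    expect_identical(compute_measure(m, 7, 20, 30, 100),
                     compute_measure(m, 7, 20, 30, 100 + 1e4))
  for (m in dep)
    expect_false(compute_measure(m, 7, 20, 30, 100) ==
                 compute_measure(m, 7, 20, 30, 100 + 1e4))
})

test_that("phi converges to cosine as the transaction total grows", {
  cos_val <- compute_measure("Cos", 15, 90, 30)
  gaps <- vapply(10^(3:6), function(N)
    abs(compute_measure("Phi", 15, 90, 30, N) - cos_val), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[[4]], 1e-3)
})

test_that("support expectation reproduces the worked example", {
  fx <- toy_clothing_fixture()
  sup <- count_pair_supports(fx$store, c("apparel", "footwear"))
  rules <- generate_rules(sup, fx$ontologies)
  hb <- rules[rules$consequent == "Hiking Boots"]
  exp_ant <- support_expectation(hb, fx$ontologies, sup, mode = "antecedent_only")
  names(exp_ant) <- hb$antecedent
  expect_equal(exp_ant[["Jackets"]], 18)        # 20 * 90 / 100
  expect_equal(exp_ant[["Travel Pants"]], 3)    # 20 * 15 / 100
  expect_equal(exp_ant[["Clothes"]], 150 * 30 / 1000)  # root: independence
})

test_that("expectation takes the minimum over multiple parents in a DAG", {
  dia <- diamond_ontology()
  oz <- flat_ontology("Z", "z")
  labels <- rbind(
    data.frame(object_id = "o1", ontology_id = c("dia", "Z"), category_id = c("D", "z")),
    data.frame(object_id = "o2", ontology_id = "dia", category_id = "D"),
    data.frame(object_id = c("o3", "o4", "o5"), ontology_id = "dia", category_id = "B"),
    data.frame(object_id = c("o3", "o4", "o5"), ontology_id = "Z", category_id = "z"),
    data.frame(object_id = "o6", ontology_id = "dia", category_id = "B"),
    data.frame(object_id = c("o7", "o8"), ontology_id = "dia", category_id = "C"))
  st <- ancestor_closure(annotation_store(labels, list(dia, oz)), list(dia, oz))
  sup <- count_pair_supports(st, c("dia", "Z"))
  rules <- generate_rules(sup, list(dia, oz))
  dz <- rules[rules$antecedent == "D" & rules$consequent == "z"]
  # candidates: via B 4*2/6 = 4/3, via C 1*2/4 = 1/2; minimum wins
  expect_equal(support_expectation(dz, list(dia, oz), sup, "antecedent_only"), 0.5)
  expect_equal(support_expectation(dz, list(dia, oz), sup, "both_sides_min"), 0.5)
  az <- rules[rules$antecedent == "A" & rules$consequent == "z"]
  expect_equal(support_expectation(az, list(dia, oz), sup, "antecedent_only"),
               az$n_a * az$n_b / az$N)
})

test_that("difference measures reproduce the worked example and obey their sign law", {
  # Jackets -> Hiking Boots: M = 15/105, E at expectation 18
  jd <- dif_measure("Jac", 15, 90, 30, 18)
  expect_equal(jd, (1 / 7) * (1 / 7 - 18 / 102))  # = -0.004802 to 6 decimals
  expect_equal(round(jd, 3), -0.005)
  # Travel Pants -> Hiking Boots: M = 10/35, E at expectation 3
  jd2 <- dif_measure("Jac", 10, 15, 30, 3)
  expect_equal(jd2, 0.06122449, tolerance = 1e-8)
  expect_equal(round(jd2, 2), 0.06)
  cd <- dif_measure("Cos", 15, 90, 30, 18)
  expect_equal(cd, -1 / 60, tolerance = 1e-9)  # = -0.016667

  expect_equal(dif_measure("Jac", 10, 15, 30, 10), 0)  # expectation met exactly
  expect_equal(dif_measure("Jac", 10, 15, 30, 3, form = "plain"),
               10 / 35 - 3 / 42)

  set.seed(5)
  for (i in 1:50) {
    n_a <- sample(2:40, 1); n_b <- sample(2:40, 1)
    n_ab <- sample(1:min(n_a, n_b), 1)
    e <- stats::runif(1, 0, min(n_a, n_b))
    m <- compute_measure("Jac", n_ab, n_a, n_b)
    d <- dif_measure("Jac", n_ab, n_a, n_b, e)
    expect_lte(d, m + 1e-12)
    expect_equal(d < 0, m < e / (n_a + n_b - e))
  }
})

test_that("a child distributed proportionally to its parent has zero difference score", {
  ch <- chain_ontology(1)  # r <- c1
  oz <- flat_ontology("Z", "z")
  labels <- rbind(
    data.frame(object_id = c("o1", "o2"), ontology_id = "chain", category_id = "c1"),
    data.frame(object_id = c("o1", "o2"), ontology_id = "Z", category_id = "z"),
    data.frame(object_id = c("o3", "o4", "o5"), ontology_id = "chain", category_id = "c1"),
    data.frame(object_id = c("o6", "o7"), ontology_id = "chain", category_id = "r"),
    data.frame(object_id = c("o6", "o7"), ontology_id = "Z", category_id = "z"),
    data.frame(object_id = c("o8", "o9", "o10"), ontology_id = "chain", category_id = "r"))
  st <- ancestor_closure(annotation_store(labels, list(ch, oz)), list(ch, oz))
  sup <- count_pair_supports(st, c("chain", "Z"))
  rules <- generate_rules(sup, list(ch, oz))
  rules <- annotate_measures(rules, c("JacDif", "CosDif"), sup, list(ch, oz),
                             expectation_mode = "antecedent_only")
  cz <- rules[rules$antecedent == "c1" & rules$consequent == "z"]
  # n(c1 -> z)/n(r -> z) = 2/4 = n_c1/n_r = 5/10: expectation met exactly
  expect_equal(cz$expectation, cz$n_ab)
  expect_equal(cz$JacDif, 0)
  expect_equal(cz$CosDif, 0)
})

test_that("annotate_measures attaches all requested columns or fails cleanly", {
  fx <- toy_clothing_fixture()
  sup <- count_pair_supports(fx$store, c("apparel", "footwear"))
  rules <- generate_rules(sup, fx$ontologies)
  out <- annotate_measures(rules, c("Jac", "JacDif"), sup, fx$ontologies)
  expect_true(all(c("Jac", "JacDif", "expectation") %in% names(out)))
  expect_identical(annotate_measures(rules, character(), sup), rules)
  expect_error(annotate_measures(rules, "Zap", sup), "unknown measure")
})
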