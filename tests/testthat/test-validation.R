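test_that("Gwet AC2 reproduces hand-computed reference values", {
  # full agreement: every rater gives each item the same category
  full <- cbind(c("A", "B", "A"), c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(gwet_ac2(full)$coefficient, 1)

  # 2 raters, 4 items: (A,A),(A,A),(A,B),(B,B)
  m <- rbind(c("A", "A"), c("A", "A"), c("A", "B"), c("B", "B"))
  res <- gwet_ac2(m)
  expect_equal(res$p_a, 0.75)
  expect_equal(res$p_e, 0.46875)
  expect_equal(res$coefficient, 0.28125 / 0.53125, tolerance = 1e-9)
  expect_equal(round(res$coefficient, 4), 0.5294)

  # always-disagree table
  d <- rbind(c("A", "B"), c("B", "A"), c("A", "B"), c("B", "A"))
  rd <- gwet_ac2(d)
  expect_equal(rd$p_a, 0)
  expect_equal(rd$p_e, 0.5)
  expect_equal(rd$coefficient, -1)
})

test_that("AC2 with identity weights equals an independent AC1 computation", {
  ac1_direct <- function(m, categories) {
    q <- length(categories)
    r_ik <- t(apply(m, 1, function(row)
      tabulate(match(row, categories), nbins = q)))
    r_i <- rowSums(r_ik)
    use <- r_i >= 2
    p_a <- mean((rowSums(r_ik * (r_ik - 1)) / (r_i * (r_i - 1)))[use])
    pi_k <- colMeans(r_ik / r_i)
    p_e <- sum(pi_k * (1 - pi_k)) / (q - 1)
    (p_a - p_e) / (1 - p_e)
  }
  for (seed in 1:15) {
    set.seed(seed)
    cats <- c("A", "B", "C")
    m <- matrix(sample(cats, 5 * 4, replace = TRUE), nrow = 5)
    expect_equal(gwet_ac2(m, categories = cats)$coefficient,
                 ac1_direct(m, cats), tolerance = 1e-12)
    # invariance to relabeling under identity weights
    relabeled <- matrix(c(A = "Z", B = "Y", C = "X")[m], nrow = 5)
    expect_equal(gwet_ac2(relabeled,
                          categories = c("X", "Y", "Z"))$coefficient,
                 gwet_ac2(m, categories = cats)$coefficient,
                 tolerance = 1e-12)
  }
})

test_that("AC2 handles missing ratings and degenerate tables", {
  m <- rbind(c("A", "A", NA), c("A", NA, NA), c("B", "B", "B"))
  res <- gwet_ac2(m, categories = c("A", "B"))
  expect_equal(res$n_used, 2L)  # single-rater item excluded from p_a
  expect_true(res$p_a >= 0 && res$p_a <= 1)

  single <- rbind(c("A", NA), c(NA, "B"))
  expect_error(gwet_ac2(single, categories = c("A", "B")), "undefined")
  expect_error(gwet_ac2(rbind(c("A", "A"))), "two categories")
})

test_that("Landis-Koch banding matches the published interpretation table", {
  expect_identical(landis_koch(0.34), "Fair")
  expect_identical(landis_koch(0.85), "Almost perfect")
  expect_identical(landis_koch(-0.1), "Poor")
  expect_identical(landis_koch(0.5), "Moderate")
  expect_identical(landis_koch(c(0, 0.2, 0.4, 0.6, 0.8, 1)),
                   c("Slight", "Slight", "Fair", "Moderate", "Substantial",
                     "Almost perfect"))
  expect_error(landis_koch(1.2), "exceed 1")
  # total and monotone over a fine grid
  grid <- seq(-0.5, 1, by = 0.01)
  bands <- landis_koch(grid)
  lv <- c("Poor", "Slight", "Fair", "Moderate", "Substantial",
          "Almost perfect")
  expect_true(all(bands %in% lv))
  expect_true(all(diff(match(bands, lv)) >= 0))
})

test_that("band summary reproduces the published 9/11 almost-perfect count", {
  co <- expert_agreement_coefficients()
  expect_length(co, 11)
  bs <- band_summary(co)
  expect_equal(bs$bands[["Almost perfect"]], 9L)
  expect_equal(bs$bands[["Substantial"]], 1L)
  expect_equal(bs$bands[["Fair"]], 1L)
  expect_identical(bs$labels$band[bs$labels$variable == "fracture"], "Fair")

  empty <- band_summary(numeric(0))
  expect_true(all(empty$bands == 0L))
  expect_equal(band_summary(c(x = 0.5))$bands[["Moderate"]], 1L)
})

test_that("containment check reproduces the published guideline comparison", {
  net <- build_default_network()
  ck <- containment_check(net)
  s <- ck$summary
  # nerve root: only 1 of the 7 national-guideline factors is linked
  expect_equal(s$n_contained[s$condition == "nerve_root_condition"], 1L)
  expect_equal(s$n_factors[s$condition == "nerve_root_condition"], 7L)
  # cauda equina: exactly the five published linked factors
  ces <- ck$table[ck$table$condition == "cauda_equina_syndrome", ]
  expect_setequal(ces$node[ces$contained],
                  c("bilateral_radicular_pain", "myotomal_weakness",
                    "bladder_function_change", "bowel_function_change",
                    "saddle_sensory_disturbance"))
  # computed containment agrees with every published mark
  expect_identical(ck$table$contained, ck$table$reported_contained)

  empty <- containment_check(net, guideline_factor_reference()[0, ])
  expect_equal(nrow(empty$table), 0L)
  expect_error(containment_check(net, data.frame(
    condition = "stress_fracture", factor_label = "x", node = "age")),
    "stress_fracture")
})

test_that("validation registry reports four of seven implementable domains", {
  reg <- validation_registry()
  expect_equal(nrow(reg), 7L)
  expect_equal(sum(reg$implementable), 4L)
  expect_setequal(reg$domain[!reg$implementable],
                  c("concurrent", "convergent", "discriminant"))
})

test_that("pair-counting AUC matches reference values and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(1, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  und <- roc_auc(c(0.2, 0.3), c(0, 0))
  expect_true(is.na(und$auc))
  expect_match(und$diagnostic, "single class")
  expect_error(roc_auc(c(0.1), c(1, 0)), "equal length")
})

test_that("pair counting equals trapezoidal ROC integration and pROC", {
  trapezoid <- function(curve) {
    o <- order(curve$fpr, curve$tpr)
    x <- curve$fpr[o]; y <- curve$tpr[o]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  skip_if_not_installed("pROC")
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, trapezoid(r$curve), tolerance = 1e-12)
    p <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
    expect_equal(r$auc, as.numeric(p), tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("sensitivity variations modify evidence but never labels", {
  net <- build_default_network()
  ces_signs <- intersect(node_names(net),
                         children_of(net, "cauda_equina_syndrome"))
  base <- case_record("c1",
                      evidence = c(bilateral_radicular_pain = "present"),
                      labels = c(cauda_equina_syndrome = 1L))
  hr <- apply_variation(base, "higher_risk", net)
  added <- setdiff(names(hr$evidence)[hr$evidence == "present"],
                   names(base$evidence))
  expect_length(added, 1)
  # first unset linked sign in canonical order
  expect_identical(added, setdiff(ces_signs, names(base$evidence))[1])
  expect_identical(hr$labels, base$labels)

  ca <- apply_variation(base, "add_cancer_symptoms", net)
  sol_signs <- children_of(net, "space_occupying_lesion")
  expect_true(all(ca$evidence[sol_signs] == "present"))
  expect_identical(ca$labels, base$labels)

  saturated <- case_record("c2",
                           evidence = stats::setNames(
                             rep("present", length(ces_signs)), ces_signs),
                           labels = c(cauda_equina_syndrome = 1L))
  expect_error(apply_variation(saturated, "higher_risk", net), "exhausted")
})

test_that("predictive validation scores cases per condition", {
  net <- build_default_network()
  pnet <- attach_parameters(net, default_parameterization(net, 31))
  # separable construction: one florid CES presentation, one empty
  ces_signs <- children_of(net, "cauda_equina_syndrome")
  pos <- case_record("pos",
                     stats::setNames(rep("present", length(ces_signs)),
                                     ces_signs),
                     labels = c(cauda_equina_syndrome = 1L, fracture = 0L))
  neg <- case_record("neg",
                     stats::setNames(rep("absent", length(ces_signs)),
                                     ces_signs),
                     labels = c(cauda_equina_syndrome = 0L, fracture = 0L))
  pv <- predictive_validation(pnet, list(pos, neg))
  expect_equal(pv$auc[["cauda_equina_syndrome"]], 1.0)
  # all-zero labels give an undefined AUC, not an error
  expect_true(is.na(pv$auc[["fracture"]]))
  expect_true(is.na(pv$auc[["inflammatory_condition"]]))  # no labels at all
  expect_error(predictive_validation(pnet, list()), "at least one")
})

test_that("case labels are restricted to the six predictable conditions", {
  expect_error(case_record("x", labels = c(stress = 1L)), "stress")
  expect_error(case_record("x", labels = c(fracture = 2L)), "0 or 1")
  ok <- case_record("x", labels = c(fracture = 1L))
  expect_s3_class(ok, "ssp_case")
})
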