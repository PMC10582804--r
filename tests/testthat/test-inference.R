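test_that("chain posteriors match the closed-form oracle values", {
  pn <- chain_pnet()   # P(r)=0.2, j: leak .05 link .5, s: leak .1 link .8
  # prior marginal: 0.2*0.525 + 0.8*0.05
  expect_equal(unname(posterior(pn, "j")[["present"]]), 0.145,
               tolerance = 1e-12)
  # Bayes update on s=present: 0.145*0.82 / (0.145*0.82 + 0.855*0.1)
  expected <- (0.145 * 0.82) / (0.145 * 0.82 + 0.855 * 0.1)
  expect_equal(unname(posterior(pn, "j", c(s = "present"))[["present"]]),
               expected, tolerance = 1e-9)
  expect_equal(round(expected, 3), 0.582)
})

test_that("empty evidence returns prior marginals for every judgment factor", {
  net <- build_default_network()
  pnet <- attach_parameters(net, default_parameterization(net, 21))
  rep_ <- posterior_judgments(pnet)
  for (j in layer_nodes(net, "judgment_factor"))
    expect_equal(rep_$posteriors[[j]],
                 unname(posterior(pnet, j)[["present"]]), tolerance = 1e-12)
  # posteriors are proper probabilities
  expect_true(all(rep_$posteriors >= 0 & rep_$posteriors <= 1))
})

test_that("variable elimination agrees with full-joint enumeration", {
  for (seed in 1:40) {
    pnet <- random_layered_pnet(seed)
    ev <- random_evidence(pnet, seed + 500)
    q <- layer_nodes(pnet$net, "judgment_factor")[1]
    ve <- posterior(pnet, q, ev)
    bf <- brute_force_posterior(pnet, q, ev)
    expect_lt(max(abs(unname(ve[names(bf)]) - unname(bf))), 1e-9)
  }
})

test_that("fully observed evidence matches the enumeration oracle", {
  pnet <- random_layered_pnet(7)
  layer <- stats::setNames(pnet$net$nodes$layer, node_names(pnet$net))
  pool <- node_names(pnet$net)[layer != "judgment_factor"]
  set.seed(99)
  ev <- vapply(pool, function(n) sample(pnet$states[[n]], 1), character(1))
  for (q in layer_nodes(pnet$net, "judgment_factor")) {
    ve <- posterior(pnet, q, ev)
    bf <- brute_force_posterior(pnet, q, ev)
    expect_lt(max(abs(unname(ve[names(bf)]) - unname(bf))), 1e-9)
  }
})

test_that("observing a sign with a positive link raises its parent's posterior", {
  for (seed in 1:10) {
    set.seed(seed)
    pn <- chain_pnet(prior_r = runif(1, 0.05, 0.5),
                     leak_j = runif(1, 0.01, 0.1),
                     link_rj = runif(1, 0.2, 0.9),
                     leak_s = runif(1, 0.01, 0.1),
                     link_js = runif(1, 0.1, 0.95))
    prior <- unname(posterior(pn, "j")[["present"]])
    post <- unname(posterior(pn, "j", c(s = "present"))[["present"]])
    expect_gt(post, prior)
  }
})

test_that("conditioning consistency: an observed node queries to certainty", {
  pnet <- random_layered_pnet(3)
  n <- layer_nodes(pnet$net, "sign_symptom")[1]
  d <- posterior(pnet, n, stats::setNames("present", n))
  expect_equal(unname(d[["present"]]), 1)
  expect_equal(unname(d[["absent"]]), 0)
})

test_that("posterior distributions normalize within tolerance", {
  pnet <- random_layered_pnet(11)
  ev <- random_evidence(pnet, 42)
  for (q in layer_nodes(pnet$net, "judgment_factor"))
    expect_equal(sum(posterior(pnet, q, ev)), 1, tolerance = 1e-9)
})

test_that("evidence is validated and judgment evidence is rejected in prediction", {
  pnet <- chain_pnet()
  expect_error(posterior(pnet, "j", c(zz = "present")), "zz")
  expect_error(posterior(pnet, "j", c(s = "maybe")), "maybe")
  expect_error(posterior_judgments(pnet, c(j = "present")),
               "judgment_factor")
  # but direct conditioning on a judgment node is allowed for posterior()
  expect_equal(unname(posterior(pnet, "s",
                                c(j = "present"))[["present"]]),
               0.82, tolerance = 1e-12)
})

test_that("brute force reads back priors and guards against large networks", {
  net <- network_definition(list(ssp_node("a", "risk_factor")))
  pnet <- attach_parameters(net, parameter_set(c(a = 0.3), list()))
  d <- brute_force_posterior(pnet, "a")
  expect_equal(unname(d), c(0.3, 0.7))

  nodes <- lapply(sprintf("n%02d", 1:21), ssp_node, layer = "risk_factor")
  big <- network_definition(nodes)
  pr <- stats::setNames(rep(0.5, 21), sprintf("n%02d", 1:21))
  pbig <- attach_parameters(big, parameter_set(pr, list()))
  expect_error(brute_force_posterior(pbig, "n01"), "at most 20")
})

test_that("elimination order diagnostics are recorded and deterministic", {
  pnet <- random_layered_pnet(5)
  q <- layer_nodes(pnet$net, "judgment_factor")[1]
  d1 <- attr(posterior(pnet, q), "elimination_order")
  d2 <- attr(posterior(pnet, q), "elimination_order")
  expect_identical(d1, d2)
})
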