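test_that("noisy-OR expansion follows the closed-form product rule", {
  net <- chain_network()
  # leak-only: no parents active
  tb <- noisy_or_table(noisy_or_spec("j", 0.1, c(r = 0.5)), net)
  off <- which(tb$combos$r == "absent")
  expect_equal(unname(tb$prob[off, "present"]), 0.1)

  # two active strengths 0.8 and 0.5 with leak 0.1: 1 - 0.9*0.2*0.5 = 0.91
  net2 <- network_definition(
    list(ssp_node("a", "risk_factor"), ssp_node("b", "risk_factor"),
         ssp_node("j", "judgment_factor")),
    list(ssp_edge("a", "j"), ssp_edge("b", "j")))
  tb2 <- noisy_or_table(noisy_or_spec("j", 0.1, c(a = 0.8, b = 0.5)), net2)
  both <- which(tb2$combos$a == "present" & tb2$combos$b == "present")
  expect_equal(unname(tb2$prob[both, "present"]), 0.91)

  # every row sums to one by complement construction
  expect_true(all(abs(rowSums(tb2$prob) - 1) < 1e-12))

  # expansion equals the closed form on every row, to 1e-12
  for (i in seq_len(nrow(tb2$combos))) {
    active <- c(a = 0.8, b = 0.5)[unlist(tb2$combos[i, ]) == "present"]
    expect_equal(unname(tb2$prob[i, "present"]),
                 1 - (1 - 0.1) * prod(1 - active), tolerance = 1e-12)
  }
})

test_that("noisy-OR is monotone in active parents and inert at strength zero", {
  net2 <- network_definition(
    list(ssp_node("a", "risk_factor"), ssp_node("b", "risk_factor"),
         ssp_node("j", "judgment_factor")),
    list(ssp_edge("a", "j"), ssp_edge("b", "j")))
  for (seed in 1:20) {
    set.seed(seed)
    leak <- runif(1, 0, 0.3)
    s <- runif(2, 0, 1)
    tb <- noisy_or_table(noisy_or_spec("j", leak, c(a = s[1], b = s[2])),
                         net2)
    p <- function(a, b) tb$prob[tb$combos$a == a & tb$combos$b == b,
                                "present"]
    expect_gte(p("present", "absent"), p("absent", "absent"))
    expect_gte(p("present", "present"), p("present", "absent"))
    expect_gte(p("present", "present"), p("absent", "present"))
  }
  tb0 <- noisy_or_table(noisy_or_spec("j", 0.2, c(a = 0, b = 0.7)), net2)
  p0 <- function(a, b) tb0$prob[tb0$combos$a == a & tb0$combos$b == b,
                                "present"]
  expect_equal(p0("present", "absent"), p0("absent", "absent"))
  expect_equal(p0("present", "present"), p0("absent", "present"))
})

test_that("noisy-OR specifications are checked against the parent set", {
  net <- chain_network()
  expect_error(noisy_or_table(noisy_or_spec("j", 0.1), net), "missing")
  expect_error(noisy_or_table(
    noisy_or_spec("j", 0.1, c(r = 0.5, zz = 0.2)), net), "non-parents")
  expect_error(noisy_or_spec("j", 1.0, c(r = 0.5)), "leak")
  expect_error(noisy_or_spec("j", 0.1, c(r = 1.5)), "strengths")
})

test_that("default parameterization is seeded, complete and rare at baseline", {
  net <- build_default_network()
  p1 <- default_parameterization(net, 11)
  p2 <- default_parameterization(net, 11)
  expect_identical(p1, p2)
  p3 <- default_parameterization(net, 12)
  expect_false(identical(p1, p3))

  roots <- Filter(function(n) length(parents_of(net, n)) == 0,
                  node_names(net))
  expect_setequal(names(p1$priors), roots)
  expect_setequal(names(p1$tables), setdiff(node_names(net), roots))

  pnet <- attach_parameters(net, p1)
  marg <- posterior_judgments(pnet)$posteriors
  expect_true(all(marg <= 0.1 + 1e-9))

  # all link strengths strictly positive on guideline-derived edges
  t3 <- net$edges[net$edges$provenance == "table3", ]
  for (i in seq_len(nrow(t3))) {
    tb <- p1$tables[[t3$child[i]]]
    expect_gt(tb$link_strength[[t3$parent[i]]], 0)
  }
})

test_that("elicited 0-3 strengths seed link probabilities via the fixed map", {
  net <- network_definition(
    list(ssp_node("a", "risk_factor"), ssp_node("b", "risk_factor"),
         ssp_node("j", "judgment_factor")),
    list(ssp_edge("a", "j", 3), ssp_edge("b", "j", 1)))
  p <- default_parameterization(net, 5, marginal_cap = Inf)
  expect_equal(unname(p$tables$j$link_strength["a"]), 0.85)
  expect_equal(unname(p$tables$j$link_strength["b"]), 0.3)
})

test_that("attach_parameters rejects incomplete or malformed parameter sets", {
  net <- chain_network()
  good <- parameter_set(
    c(r = 0.2),
    list(j = noisy_or_spec("j", 0.05, c(r = 0.5)),
         s = noisy_or_spec("s", 0.1, c(j = 0.8))))
  expect_s3_class(attach_parameters(net, good), "ssp_pnet")

  missing_prior <- good; missing_prior$priors <- numeric(0)
  expect_error(attach_parameters(net, missing_prior), "missing priors: r")

  missing_table <- good; missing_table$tables$s <- NULL
  expect_error(attach_parameters(net, missing_table), "missing tables: s")

  bad_rows <- good
  combos <- data.frame(r = c("present", "absent"))
  expect_error(
    cond_table("j", "r", combos,
               cbind(present = c(0.5, 0.05), absent = c(0.4, 0.95))),
    "sum to 1")
})

test_that("parameter serialization round-trips probabilities exactly", {
  net <- chain_network()
  params <- default_parameterization(net, 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(params, path)
  back <- read_params(path)
  expect_equal(back$priors, params$priors, tolerance = 1e-12)
  for (n in names(params$tables)) {
    expect_equal(back$tables[[n]]$leak, params$tables[[n]]$leak,
                 tolerance = 1e-12)
    expect_equal(back$tables[[n]]$link_strength,
                 params$tables[[n]]$link_strength, tolerance = 1e-12)
  }
  # expanded export: explicit tables whose rows match the closed form
  path2 <- withr::local_tempfile(fileext = ".json")
  write_params(params, path2, net = net)
  expanded <- read_params(path2)
  expect_s3_class(expanded$tables$j, "cond_table")
  direct <- noisy_or_table(params$tables$j, net)
  expect_equal(unname(expanded$tables$j$prob[, "present"]),
               unname(direct$prob[, "present"]), tolerance = 1e-12)
})
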