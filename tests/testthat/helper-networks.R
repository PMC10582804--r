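# Shared fixtures, built in code.

# Minimal risk -> judgment -> sign chain with known closed-form posteriors.
chain_network <- function() {
  network_definition(
    list(ssp_node("r", "risk_factor"),
         ssp_node("j", "judgment_factor"),
         ssp_node("s", "sign_symptom")),
    list(ssp_edge("r", "j"), ssp_edge("j", "s")))
}

chain_pnet <- function(prior_r = 0.2, leak_j = 0.05, link_rj = 0.5,
                       leak_s = 0.1, link_js = 0.8) {
  net <- chain_network()
  params <- parameter_set(
    c(r = prior_r),
    list(j = noisy_or_spec("j", leak_j, c(r = link_rj)),
         s = noisy_or_spec("s", leak_s, c(j = link_js))))
  attach_parameters(net, params)
}

# Random three-layer network with at most `max_nodes` binary nodes, plus a
# random parameterization; pure function of the seed.
random_layered_pnet <- function(seed, max_nodes = 12) {
  set.seed(seed)
  n_r <- sample(1:3, 1)
  n_j <- sample(1:3, 1)
  n_s <- sample(1:(max_nodes - n_r - n_j), 1)
  rs <- sprintf("r%d", seq_len(n_r))
  js <- sprintf("j%d", seq_len(n_j))
  ss <- sprintf("s%d", seq_len(n_s))
  nodes <- c(lapply(rs, ssp_node, layer = "risk_factor"),
             lapply(js, ssp_node, layer = "judgment_factor"),
             lapply(ss, ssp_node, layer = "sign_symptom"))
  edges <- list()
  for (j in js)
    for (r in rs)
      if (stats::runif(1) < 0.5) edges <- c(edges, list(ssp_edge(r, j)))
  for (s in ss)
    for (j in js)
      if (stats::runif(1) < 0.6) edges <- c(edges, list(ssp_edge(j, s)))
  net <- network_definition(nodes, edges)
  params <- default_parameterization(net, seed + 1000L,
                                     marginal_cap = Inf)
  attach_parameters(net, params)
}

# Random partial evidence over non-judgment nodes; pure function of the seed.
random_evidence <- function(pnet, seed, p_observe = 0.5) {
  set.seed(seed)
  layer <- stats::setNames(pnet$net$nodes$layer, node_names(pnet$net))
  pool <- node_names(pnet$net)[layer != "judgment_factor"]
  obs <- pool[stats::runif(length(pool)) < p_observe]
  ev <- vapply(obs, function(n)
    sample(pnet$states[[n]], 1), character(1))
  ev
}
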