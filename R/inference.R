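# ---- factor algebra ---------------------------------------------------------
# A factor is a list(vars, card, values): `values` is a numeric vector of
# length prod(card) laid out with vars[1] varying fastest (column-major).

new_factor <- function(vars, card, values) {
  list(vars = vars, card = card, values = values)
}

# Index vector mapping every assignment of `uvars` (sizes `ucard`) to the
# corresponding cell of a factor over `fvars` (a subset of uvars).
map_index <- function(uvars, ucard, fvars) {
  N <- prod(ucard)
  pos <- 0:(N - 1)
  idx <- rep(0, N)
  stride <- 1
  for (v in fvars) {
    k <- match(v, uvars)
    div <- if (k == 1L) 1 else prod(ucard[seq_len(k - 1L)])
    idx <- idx + ((pos %/% div) %% ucard[k]) * stride
    stride <- stride * ucard[k]
  }
  as.integer(idx) + 1L
}

f_mult <- function(f1, f2) {
  if (!length(f1$vars)) return(new_factor(f2$vars, f2$card,
                                          f1$values * f2$values))
  if (!length(f2$vars)) return(new_factor(f1$vars, f1$card,
                                          f1$values * f2$values))
  vars <- union(f1$vars, f2$vars)
  card <- c(f1$card, f2$card)[vars]
  v1 <- f1$values[map_index(vars, card, f1$vars)]
  v2 <- f2$values[map_index(vars, card, f2$vars)]
  new_factor(vars, card, v1 * v2)
}

# Sum a variable out of a factor.
f_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  d <- f$card
  if (length(d) == 1L)
    return(new_factor(character(0), integer(0), sum(f$values)))
  perm <- c(k, seq_along(d)[-k])
  arr <- aperm(array(f$values, dim = d), perm)
  vals <- colSums(matrix(arr, nrow = d[k]))
  new_factor(f$vars[-k], d[-k], as.numeric(vals))
}

# Fix a variable of a factor to one observed state (dropping that axis).
f_reduce <- function(f, var, state_idx) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  d <- f$card
  if (length(d) == 1L)
    return(new_factor(character(0), integer(0), f$values[state_idx]))
  perm <- c(k, seq_along(d)[-k])
  arr <- aperm(array(f$values, dim = d), perm)
  vals <- matrix(arr, nrow = d[k])[state_idx, ]
  new_factor(f$vars[-k], d[-k], as.numeric(vals))
}

node_factor <- function(pnet, node) {
  a <- pnet$cpt[[node]]
  vars <- names(dimnames(a))
  new_factor(vars, stats::setNames(dim(a), vars), as.numeric(a))
}

# ---- evidence ---------------------------------------------------------------

#' Check evidence against a parameterized network
#'
#' Evidence is a named character vector mapping node names to observed
#' states. A node with no entry is unknown and is marginalized during
#' inference, which is equivalent to falling back on its prior baseline.
#'
#' @param pnet an `ssp_pnet`.
#' @param evidence named character vector (possibly empty).
#' @param forbid_layers layers whose nodes may not carry evidence (used to
#'   keep judgment factors out of the evidence in prediction mode).
#' @return the evidence, invisibly, after validation.
#' @export
check_evidence <- function(pnet, evidence, forbid_layers = character(0)) {
  if (!length(evidence)) return(invisible(evidence))
  nm <- names(evidence)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("evidence must be a named character vector", call. = FALSE)
  unknown <- setdiff(nm, node_names(pnet$net))
  if (length(unknown))
    stop("evidence names unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (n in nm) {
    if (!evidence[[n]] %in% pnet$states[[n]])
      stop("evidence state '", evidence[[n]], "' is not a legal state of '",
           n, "'", call. = FALSE)
  }
  layer <- stats::setNames(pnet$net$nodes$layer, node_names(pnet$net))
  bad <- nm[layer[nm] %in% forbid_layers]
  if (length(bad))
    stop("evidence may not be set on ", paste(forbid_layers, collapse = "/"),
         " node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(evidence)
}

# ---- variable elimination ---------------------------------------------------

# Remove nodes irrelevant to query+evidence: a barren node (no retained
# children, neither queried nor observed) contributes a factor that sums to
# one, so it and its CPT can be dropped; iterate until a fixed point.
relevant_nodes <- function(pnet, query, evidence_nodes) {
  keep <- node_names(pnet$net)
  target <- union(query, evidence_nodes)
  repeat {
    barren <- keep[vapply(keep, function(n)
      !(n %in% target) && !any(children_of(pnet$net, n) %in% keep),
      logical(1))]
    if (!length(barren)) break
    keep <- setdiff(keep, barren)
  }
  keep
}

# Keep only the factors in the query's connected component of the factor
# interaction graph (post evidence reduction); scalar factors are dropped.
query_component <- function(factors, query) {
  scopes <- lapply(factors, `[[`, "vars")
  reached <- query
  repeat {
    hit <- vapply(scopes, function(sc) any(sc %in% reached), logical(1))
    new_vars <- unique(unlist(scopes[hit]))
    if (all(new_vars %in% reached)) return(factors[hit])
    reached <- union(reached, new_vars)
  }
}

# Min-fill elimination order with deterministic lexicographic tie-breaking.
min_fill_order <- function(scopes, to_eliminate) {
  adj <- list()
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  vars <- unique(unlist(scopes))
  for (v in vars) adj[[v]] <- character(0)
  for (sc in scopes) {
    sc <- unique(sc)
    if (length(sc) > 1L)
      for (i in seq_len(length(sc) - 1L))
        for (j in seq((i + 1L), length(sc))) link(sc[i], sc[j])
  }
  order_out <- character(0)
  remaining <- sort(intersect(to_eliminate, vars))
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- setdiff(adj[[v]], v)
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L))
        for (j in seq((i + 1L), length(nb)))
          if (!nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]  # remaining is sorted -> lexicographic tie
    nb <- setdiff(adj[[v]], v)
    if (length(nb) > 1L)
      for (i in seq_len(length(nb) - 1L))
        for (j in seq((i + 1L), length(nb))) link(nb[i], nb[j])
    for (u in nb) adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- character(0)
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  c(order_out, setdiff(to_eliminate, vars))
}

#' Exact posterior distribution of one node by variable elimination
#'
#' @param pnet an `ssp_pnet`.
#' @param query a node name.
#' @param evidence named character vector of observed states; nodes not
#'   mentioned are unknown and are marginalized.
#' @return named numeric vector over the query node's states, summing to 1;
#'   attribute `elimination_order` records the variable order used.
#' @export
posterior <- function(pnet, query, evidence = character(0)) {
  check_evidence(pnet, evidence)
  if (query %in% names(evidence)) {
    st <- pnet$states[[query]]
    out <- stats::setNames(as.numeric(st == evidence[[query]]), st)
    attr(out, "elimination_order") <- character(0)
    return(out)
  }
  keep <- relevant_nodes(pnet, query, names(evidence))
  factors <- if (is.null(pnet$factors)) lapply(keep, node_factor, pnet = pnet)
  else unname(pnet$factors[keep])
  for (n in intersect(names(evidence), keep)) {
    si <- match(evidence[[n]], pnet$states[[n]])
    factors <- lapply(factors, f_reduce, var = n, state_idx = si)
  }
  # factors disconnected from the query contribute only a multiplicative
  # constant that cancels on normalization; drop them so posteriors that are
  # analytically constant come out bit-identical across evidence sets
  factors <- query_component(factors, query)
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), query)
  ord <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
  for (v in ord) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(f_mult, factors[involved])
    # renormalize intermediate products; only the constant changes
    s <- sum(prod_f$values)
    if (s > 0) prod_f$values <- prod_f$values / s
    factors <- c(factors[!involved], list(f_marginalize(prod_f, v)))
  }
  final <- Reduce(f_mult, factors)
  vals <- final$values
  if (sum(vals) <= 0)
    stop("evidence has zero probability under the model", call. = FALSE)
  out <- stats::setNames(vals / sum(vals), pnet$states[[query]])
  attr(out, "elimination_order") <- ord
  out
}

#' Posteriors of all judgment factors given a patient presentation
#'
#' Computes the exact probability of `present` for each of the judgment
#' factors given partial evidence on risk factors and signs/symptoms.
#' Unknown nodes fall back on their prior baseline (marginalization);
#' judgment factors themselves may not be observed in prediction mode.
#'
#' @param pnet an `ssp_pnet`.
#' @param evidence named character vector of observed states.
#' @return a list of class `ssp_posterior_report`: `posteriors` (named
#'   numeric, probability of present per judgment factor), `evidence`
#'   (echo), `diagnostics` (per-node elimination orders).
#' @export
posterior_judgments <- function(pnet, evidence = character(0)) {
  check_evidence(pnet, evidence, forbid_layers = "judgment_factor")
  jn <- layer_nodes(pnet$net, "judgment_factor")
  diag <- list()
  post <- vapply(jn, function(n) {
    d <- posterior(pnet, n, evidence)
    diag[[n]] <<- attr(d, "elimination_order")
    unname(d[["present"]])
  }, numeric(1))
  structure(list(posteriors = post, evidence = evidence,
                 diagnostics = diag),
            class = "ssp_posterior_report")
}

#' @export
print.ssp_posterior_report <- function(x, ...) {
  cat("<posterior report> P(present) per judgment factor\n")
  for (n in names(x$posteriors))
    cat(sprintf("  %-28s %.6f\n", n, x$posteriors[[n]]))
  invisible(x)
}

#' Exact posterior by full-joint enumeration (reference oracle)
#'
#' Sums the full joint distribution over all state combinations. Written
#' independently of the variable-elimination path so the two can be compared
#' in tests; guarded to networks of at most 20 nodes.
#'
#' @param pnet an `ssp_pnet` with at most 20 nodes.
#' @param query node name to query.
#' @param evidence named character vector of observed states.
#' @return named numeric vector over the query node's states, summing to 1.
#' @export
brute_force_posterior <- function(pnet, query, evidence = character(0)) {
  nm <- node_names(pnet$net)
  if (length(nm) > 20L)
    stop("brute_force_posterior is limited to networks of at most 20 nodes",
         call. = FALSE)
  check_evidence(pnet, evidence)
  grid <- expand.grid(pnet$states[nm], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  names(grid) <- nm
  keep <- rep(TRUE, nrow(grid))
  for (n in names(evidence)) keep <- keep & grid[[n]] == evidence[[n]]
  grid <- grid[keep, , drop = FALSE]
  p <- rep(1, nrow(grid))
  for (n in nm) {
    a <- pnet$cpt[[n]]
    vars <- names(dimnames(a))
    idx <- lapply(vars, function(v) match(grid[[v]], pnet$states[[v]]))
    p <- p * a[do.call(cbind, idx)]
  }
  st <- pnet$states[[query]]
  tot <- vapply(st, function(s) sum(p[grid[[query]] == s]), numeric(1))
  if (sum(tot) <= 0)
    stop("evidence has zero probability under the model", call. = FALSE)
  stats::setNames(tot / sum(tot), st)
}
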