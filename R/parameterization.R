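# Mapping from elicited 0-3 relationship strengths to default link
# probabilities; preserves the elicited ordering and is overridable in any
# parameter file.
STRENGTH_MAP <- c(`0` = 0.0, `1` = 0.3, `2` = 0.6, `3` = 0.85)

#' Leaky noisy-OR specification for one child node
#'
#' Each active (present) parent independently triggers the child with its
#' link strength; a background leak captures all causes outside the model:
#' `P(child = present | active set A) = 1 - (1 - leak) * prod_{i in A} (1 - s_i)`.
#'
#' @param child child node name.
#' @param leak background probability of the child being present with all
#'   modeled causes absent; in `[0, 1)`.
#' @param link_strength named numeric vector, one entry in `[0, 1]` per
#'   parent of `child`.
#' @return a list of class `noisy_or_spec`.
#' @export
noisy_or_spec <- function(child, leak, link_strength = numeric(0)) {
  if (!is.numeric(leak) || length(leak) != 1L || leak < 0 || leak >= 1)
    stop("noisy-OR leak for '", child, "' must lie in [0, 1)", call. = FALSE)
  if (length(link_strength) &&
      (any(link_strength < 0) || any(link_strength > 1)))
    stop("noisy-OR link strengths for '", child,
         "' must lie in [0, 1]", call. = FALSE)
  structure(list(child = child, leak = leak,
                 link_strength = link_strength),
            class = "noisy_or_spec")
}

#' Explicit conditional probability table for one child node
#'
#' Rows enumerate all parent-state combinations in canonical order
#' (`expand.grid` over the parents' state sets, first parent varying
#' fastest); columns are the child's states.
#'
#' @param child child node name.
#' @param parents ordered character vector of parent names (may be empty).
#' @param combos data.frame of parent-state combinations, one column per
#'   parent.
#' @param prob numeric matrix, `nrow(combos)` x number of child states; each
#'   row sums to 1 within 1e-9.
#' @param states child state labels (matrix column names).
#' @return a list of class `cond_table`.
#' @export
cond_table <- function(child, parents, combos, prob,
                       states = colnames(prob)) {
  stopifnot(is.matrix(prob), nrow(prob) == nrow(combos))
  if (any(prob < 0))
    stop("conditional table for '", child, "' has negative entries",
         call. = FALSE)
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop("conditional table rows for '", child,
         "' must sum to 1 (within 1e-9)", call. = FALSE)
  colnames(prob) <- states
  structure(list(child = child, parents = parents, combos = combos,
                 prob = prob, states = states),
            class = "cond_table")
}

# Canonical parent-state combination grid for a child node.
parent_combos <- function(net, parents) {
  if (!length(parents))
    return(data.frame(row.names = 1L))
  g <- expand.grid(lapply(net$states[parents], identity),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(g) <- parents
  g
}

#' Expand a noisy-OR specification to an explicit conditional table
#'
#' @param spec a [noisy_or_spec()].
#' @param net the `ssp_network` providing the child's parent set.
#' @return a [cond_table()] whose rows follow the closed-form product rule.
#' @export
noisy_or_table <- function(spec, net) {
  pa <- parents_of(net, spec$child)
  missing <- setdiff(pa, names(spec$link_strength))
  extra <- setdiff(names(spec$link_strength), pa)
  if (length(missing))
    stop("noisy-OR spec for '", spec$child, "' missing link strengths for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra))
    stop("noisy-OR spec for '", spec$child, "' has strengths for non-parents: ",
         paste(extra, collapse = ", "), call. = FALSE)
  combos <- parent_combos(net, pa)
  p_present <- vapply(seq_len(nrow(combos)), function(i) {
    active <- pa[vapply(pa, function(p) combos[i, p] == "present",
                        logical(1))]
    1 - (1 - spec$leak) * prod(1 - spec$link_strength[active])
  }, numeric(1))
  if (!nrow(combos)) p_present <- spec$leak
  prob <- cbind(present = p_present, absent = 1 - p_present)
  cond_table(spec$child, pa, combos, prob)
}

#' A full parameter set for a network
#'
#' @param priors named numeric vector: probability of `present` for every
#'   root node, each in `(0, 1)`.
#' @param tables named list: for every non-root node, either a
#'   [noisy_or_spec()] or a [cond_table()].
#' @return a list of class `ssp_params`.
#' @export
parameter_set <- function(priors, tables) {
  structure(list(priors = priors, tables = tables), class = "ssp_params")
}

#' Draw a reproducible default parameterization
#'
#' The published elicitation did not release its probability values, so the
#' packaged default draws them from documented ranges: risk-factor priors
#' uniform on `[0.05, 0.4]`; judgment-factor leaks and root priors uniform
#' on `[0.001, 0.02]` (serious pathologies are rare); sign leaks uniform on
#' `[0.01, 0.05]`; link strengths uniform on `[0.2, 0.9]`, except that edges
#' carrying an elicited 0-3 strength are seeded through the fixed map
#' 0 -> 0, 1 -> 0.3, 2 -> 0.6, 3 -> 0.85. Each judgment factor's incoming
#' link strengths are then shrunk (single scale factor, solved exactly) so
#' that its no-evidence marginal probability of `present` stays at or below
#' `marginal_cap`, keeping the baseline rates rare.
#'
#' @param net an `ssp_network`.
#' @param seed integer seed; the draw is a pure function of it (Mersenne
#'   Twister).
#' @param risk_prior_range,judgment_leak_range,sign_leak_range,link_range
#'   uniform ranges used for the draws.
#' @param marginal_cap cap on each judgment factor's prior marginal of
#'   present; `Inf` disables the calibration.
#' @return an `ssp_params` covering `net` exactly.
#' @export
default_parameterization <- function(net, seed,
                                     risk_prior_range = c(0.05, 0.4),
                                     judgment_leak_range = c(0.001, 0.02),
                                     sign_leak_range = c(0.01, 0.05),
                                     link_range = c(0.2, 0.9),
                                     marginal_cap = 0.1) {
  rep_ <- validate_structure(net)
  if (!rep_$ok)
    stop("cannot parameterize an invalid network; run validate_structure()",
         call. = FALSE)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  nm <- node_names(net)
  layer <- stats::setNames(net$nodes$layer, nm)
  roots <- nm[vapply(nm, function(n) length(parents_of(net, n)) == 0L,
                     logical(1))]
  priors <- numeric(0)
  tables <- list()
  for (n in nm) {
    pa <- parents_of(net, n)
    if (!length(pa)) {
      priors[[n]] <- switch(layer[[n]],
        risk_factor = runif1(risk_prior_range),
        judgment_factor = runif1(judgment_leak_range),
        sign_symptom = runif1(risk_prior_range))
      next
    }
    leak <- switch(layer[[n]],
      judgment_factor = runif1(judgment_leak_range),
      sign_symptom = runif1(sign_leak_range),
      runif1(sign_leak_range))
    idx <- which(net$edges$child == n)
    s <- vapply(idx, function(i) {
      es <- net$edges$elicited_strength[i]
      if (!is.na(es)) unname(STRENGTH_MAP[as.character(es)])
      else runif1(link_range)
    }, numeric(1))
    names(s) <- net$edges$parent[idx]
    if (layer[[n]] == "judgment_factor" && is.finite(marginal_cap)) {
      # Roots are independent, so the prior marginal has the closed form
      # 1 - (1-leak) * prod(1 - P(parent present) * s_i); shrink all links by
      # a common factor until it meets the cap.
      pp <- vapply(names(s), function(p) priors[[p]], numeric(1))
      marg <- function(lam) 1 - (1 - leak) * prod(1 - pp * lam * s)
      if (marg(1) > marginal_cap) {
        lam <- stats::uniroot(function(l) marg(l) - marginal_cap,
                              c(0, 1), tol = 1e-12)$root
        s <- s * lam
      }
    }
    tables[[n]] <- noisy_or_spec(n, leak, s)
  }
  parameter_set(priors, tables)
}

# Save/restore the global RNG state so seeded draws do not perturb callers.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Attach parameters to a network for querying
#'
#' Expands every noisy-OR specification to an explicit table and stores each
#' node's conditional distribution as an array indexed by (child state,
#' parent states...), ready for exact inference.
#'
#' @param net an `ssp_network`.
#' @param params an `ssp_params` covering `net` exactly.
#' @return an object of class `ssp_pnet` with components `net`, `states`,
#'   `parents`, `cpt` (named list of arrays) and `order` (a topological
#'   ordering of the nodes).
#' @export
attach_parameters <- function(net, params) {
  nm <- node_names(net)
  roots <- nm[vapply(nm, function(n) length(parents_of(net, n)) == 0L,
                     logical(1))]
  nonroots <- setdiff(nm, roots)
  missing_priors <- setdiff(roots, names(params$priors))
  extra_priors <- setdiff(names(params$priors), roots)
  missing_tables <- setdiff(nonroots, names(params$tables))
  extra_tables <- setdiff(names(params$tables), nonroots)
  problems <- c(
    if (length(missing_priors))
      paste("missing priors:", paste(missing_priors, collapse = ", ")),
    if (length(extra_priors))
      paste("priors for non-root nodes:",
            paste(extra_priors, collapse = ", ")),
    if (length(missing_tables))
      paste("missing tables:", paste(missing_tables, collapse = ", ")),
    if (length(extra_tables))
      paste("tables for unknown/root nodes:",
            paste(extra_tables, collapse = ", ")))
  if (length(problems))
    stop("parameter set does not cover the network exactly; ",
         paste(problems, collapse = "; "), call. = FALSE)
  if (any(params$priors <= 0 | params$priors >= 1))
    stop("root priors must lie strictly inside (0, 1)", call. = FALSE)

  cpt <- list()
  for (n in roots) {
    p <- params$priors[[n]]
    st <- net$states[[n]]
    v <- stats::setNames(c(p, rep((1 - p) / (length(st) - 1),
                                  length(st) - 1)), st)
    cpt[[n]] <- array(v, dim = length(st),
                      dimnames = stats::setNames(list(st), n))
  }
  for (n in nonroots) {
    tb <- params$tables[[n]]
    if (inherits(tb, "noisy_or_spec")) tb <- noisy_or_table(tb, net)
    if (!inherits(tb, "cond_table"))
      stop("table for '", n, "' is neither a noisy_or_spec nor a cond_table",
           call. = FALSE)
    pa <- parents_of(net, n)
    if (!identical(sort(tb$parents), sort(pa)))
      stop("table for '", n, "' does not match the network parent set",
           call. = FALSE)
    tb <- reorder_cond_table(tb, pa, net)
    st <- net$states[[n]]
    dims <- c(length(st), vapply(pa, function(p) length(net$states[[p]]),
                                 integer(1)))
    dn <- c(list(st), lapply(pa, function(p) net$states[[p]]))
    names(dn) <- c(n, pa)
    # combos enumerate parents with the first parent fastest, matching the
    # column-major layout of the array after the child dimension.
    cpt[[n]] <- array(as.numeric(t(tb$prob[, st, drop = FALSE])),
                      dim = dims, dimnames = dn)
  }
  pnet <- structure(list(net = net, states = net$states,
                         parents = stats::setNames(
                           lapply(nm, parents_of, net = net), nm)[nm],
                         cpt = cpt, order = topological_order(net)),
                    class = "ssp_pnet")
  # cache each node's CPT in factor form; inference reuses these per query
  pnet$factors <- stats::setNames(lapply(nm, node_factor, pnet = pnet), nm)
  pnet
}

# Bring a cond_table's rows into canonical combo order for a parent ordering.
reorder_cond_table <- function(tb, pa, net) {
  canon <- parent_combos(net, pa)
  if (!length(pa)) return(tb)
  key <- function(df) do.call(paste, c(df[pa], sep = "\r"))
  idx <- match(key(canon), key(tb$combos))
  if (anyNA(idx))
    stop("conditional table for '", tb$child,
         "' does not cover all parent-state combinations", call. = FALSE)
  if (any(duplicated(tb$combos[pa])))
    stop("conditional table for '", tb$child,
         "' has duplicate parent-state rows", call. = FALSE)
  cond_table(tb$child, pa, canon, tb$prob[idx, , drop = FALSE], tb$states)
}

topological_order <- function(net) {
  nm <- node_names(net)
  indeg <- vapply(nm, function(n) length(parents_of(net, n)), integer(1))
  out <- character(0)
  remaining <- nm
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) stop("network is cyclic", call. = FALSE)
    n <- ready[1]  # canonical order preserved among ready nodes
    out <- c(out, n)
    remaining <- setdiff(remaining, n)
    for (k in children_of(net, n)) indeg[[k]] <- indeg[[k]] - 1L
  }
  out
}

#' @export
print.ssp_pnet <- function(x, ...) {
  cat("<ssp_pnet> parameterized network over", length(x$cpt), "nodes\n")
  invisible(x)
}

#' @export
print.ssp_params <- function(x, ...) {
  cat("<ssp_params>", length(x$priors), "root priors,",
      length(x$tables), "conditional tables/specs\n")
  invisible(x)
}
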