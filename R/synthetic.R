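# Seeded generators that stand in for unpublished clinical inputs: labeled
# patient cases (ancestral sampling from the network), panel rating matrices
# at controlled concordance, and categorical agreement tables at controlled
# agreement. Every generator is a pure function of (arguments, seed) under
# R's default Mersenne-Twister generator.

#' Forward-sample labeled cases from a parameterized network
#'
#' Ancestral sampling in topological order. Sampled judgment-factor states
#' are hidden into 0/1 labels (for the six predictable conditions); the
#' returned evidence contains only risk-factor and sign/symptom nodes, so
#' the cases can be scored blind by [predictive_validation()].
#'
#' @param pnet an `ssp_pnet`.
#' @param n number of cases (>= 1).
#' @param seed integer seed.
#' @return list of `ssp_case` records with `source = "synthetic"`.
#' @export
forward_sample <- function(pnet, n, seed) {
  stopifnot(n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  nm <- pnet$order
  layer <- stats::setNames(pnet$net$nodes$layer, node_names(pnet$net))
  lab_nodes <- intersect(predictable_conditions(),
                         layer_nodes(pnet$net, "judgment_factor"))
  # sample column-wise over cases for speed
  samp <- matrix(NA_integer_, nrow = n, ncol = length(nm),
                 dimnames = list(NULL, nm))
  for (node in nm) {
    a <- pnet$cpt[[node]]
    pa <- pnet$parents[[node]]
    st <- pnet$states[[node]]
    if (!length(pa)) {
      p <- as.numeric(a)
      samp[, node] <- sample.int(length(st), n, replace = TRUE, prob = p)
    } else {
      # index of each case's parent configuration into the cpt array
      dims <- dim(a)
      stride <- dims[1]
      offset <- rep(0L, n)
      for (j in seq_along(pa)) {
        offset <- offset + (samp[, pa[j]] - 1L) * stride
        stride <- stride * dims[j + 1L]
      }
      u <- stats::runif(n)
      # binary-or-more states: walk the cumulative distribution
      cum <- rep(0, n)
      chosen <- rep(length(st), n)
      undecided <- rep(TRUE, n)
      for (s in seq_len(length(st) - 1L)) {
        pr <- as.numeric(a)[offset + s]
        cum <- cum + pr
        hit <- undecided & (u <= cum)
        chosen[hit] <- s
        undecided <- undecided & !hit
      }
      samp[, node] <- chosen
    }
  }
  obs_nodes <- nm[layer[nm] != "judgment_factor"]
  lapply(seq_len(n), function(i) {
    ev <- vapply(obs_nodes, function(node)
      pnet$states[[node]][samp[i, node]], character(1))
    labels <- vapply(lab_nodes, function(node)
      as.integer(pnet$states[[node]][samp[i, node]] == "present"),
      integer(1))
    case_record(sprintf("sim_%05d", i), ev, labels, source = "synthetic")
  })
}

#' Synthesize a panel rating matrix at controlled concordance
#'
#' Each item carries a designated 0-3 score. With probability `concordance`
#' a rater reports that score; otherwise the rating is uniform over 0-3.
#'
#' @param n_raters,n_items dimensions.
#' @param concordance mixing probability in `[0, 1]`.
#' @param seed integer seed.
#' @param designated optional integer vector of per-item designated scores
#'   (recycled); drawn uniformly when omitted.
#' @return integer matrix items x raters with attribute `designated`.
#' @export
synth_rating_matrix <- function(n_raters, n_items, concordance, seed,
                                designated = NULL) {
  stopifnot(n_raters >= 1, n_items >= 1,
            concordance >= 0, concordance <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(designated))
    designated <- sample(0:3, n_items, replace = TRUE)
  designated <- rep_len(as.integer(designated), n_items)
  m <- matrix(0L, nrow = n_items, ncol = n_raters,
              dimnames = list(paste0("item_", seq_len(n_items)),
                              paste0("rater_", seq_len(n_raters))))
  for (i in seq_len(n_items)) {
    concordant <- stats::runif(n_raters) < concordance
    noise <- sample(0:3, n_raters, replace = TRUE)
    m[i, ] <- ifelse(concordant, designated[i], noise)
  }
  attr(m, "designated") <- designated
  m
}

#' Synthesize a categorical agreement table at a target agreement level
#'
#' Each item carries a designated category; every rating matches it with
#' probability `target_agreement` and otherwise flips to a uniformly chosen
#' other category.
#'
#' @param n_raters,n_items dimensions.
#' @param target_agreement probability in `[0, 1]`.
#' @param seed integer seed.
#' @param categories category labels (default binary `c("agree",
#'   "disagree")`).
#' @param designated optional per-item designated categories (recycled).
#' @return character matrix items x raters with attributes `designated` and
#'   `categories`.
#' @export
synth_agreement_table <- function(n_raters, n_items, target_agreement, seed,
                                  categories = c("agree", "disagree"),
                                  designated = NULL) {
  stopifnot(n_raters >= 1, n_items >= 1, length(categories) >= 2,
            target_agreement >= 0, target_agreement <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(designated))
    designated <- sample(categories, n_items, replace = TRUE)
  designated <- rep_len(designated, n_items)
  m <- matrix(NA_character_, nrow = n_items, ncol = n_raters,
              dimnames = list(paste0("item_", seq_len(n_items)),
                              paste0("rater_", seq_len(n_raters))))
  for (i in seq_len(n_items)) {
    keep <- stats::runif(n_raters) < target_agreement
    others <- setdiff(categories, designated[i])
    flips <- sample(others, n_raters, replace = TRUE)
    m[i, ] <- ifelse(keep, designated[i], flips)
  }
  attr(m, "designated") <- designated
  attr(m, "categories") <- categories
  m
}

#' AUC recovery experiment: sample labeled cases, then score them back
#'
#' Forward-samples `n` labeled cases from the network and runs
#' [predictive_validation()] on them, measuring how well posterior scores
#' recover the sampled condition states. Under a strong parameterization
#' (high link strengths, small leaks) the AUC should approach 1; with a
#' condition's outgoing links all zero it should sit at chance.
#'
#' @param pnet an `ssp_pnet`.
#' @param n number of sampled cases.
#' @param seed integer seed.
#' @return a list of class `ssp_auc_recovery`: `auc` (named numeric per
#'   condition, `NA` when a condition's sample is single-class),
#'   `class_counts` (data.frame `condition`, `n_pos`, `n_neg`), `n`, `seed`.
#' @export
auc_recovery_experiment <- function(pnet, n, seed) {
  cases <- forward_sample(pnet, n, seed)
  pv <- predictive_validation(pnet, cases)
  cc <- do.call(rbind, lapply(names(pv$results), function(cd)
    data.frame(condition = cd, n_pos = pv$results[[cd]]$n_pos,
               n_neg = pv$results[[cd]]$n_neg, stringsAsFactors = FALSE)))
  structure(list(auc = pv$auc, class_counts = cc, n = n, seed = seed,
                 validation = pv),
            class = "ssp_auc_recovery")
}

#' @export
print.ssp_auc_recovery <- function(x, ...) {
  cat("<auc recovery> n =", x$n, " seed =", x$seed, "\n")
  for (cd in names(x$auc))
    cat(sprintf("  %-28s AUC %s\n", cd,
                if (is.na(x$auc[[cd]])) "undefined (single class)"
                else sprintf("%.4f", x$auc[[cd]])))
  invisible(x)
}

#' Zero out a condition's outgoing link strengths
#'
#' Test device for null-signal experiments: sets every noisy-OR link
#' strength on edges leaving `condition` to zero, so its signs carry no
#' information about it.
#'
#' @param params an `ssp_params` whose sign tables are noisy-OR specs.
#' @param condition a judgment-factor name.
#' @param net the `ssp_network`.
#' @return modified `ssp_params`.
#' @export
zero_condition_links <- function(params, condition, net) {
  for (s in children_of(net, condition)) {
    tb <- params$tables[[s]]
    if (!inherits(tb, "noisy_or_spec"))
      stop("zero_condition_links requires noisy-OR tables; '", s,
           "' is explicit", call. = FALSE)
    tb$link_strength[[condition]] <- 0
    params$tables[[s]] <- tb
  }
  params
}
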