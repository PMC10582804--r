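# ---- inter-rater agreement --------------------------------------------------

#' Weight schemes for weighted agreement
#'
#' `identity_weights` treats categories as nominal (AC2 reduces to AC1);
#' `linear_weights` and `quadratic_weights` are the usual ordinal schemes.
#'
#' @param categories character vector of category labels (length q >= 2).
#' @return a q x q numeric matrix with unit diagonal, symmetric, entries in
#'   `[0, 1]`, dimnames = categories.
#' @export
identity_weights <- function(categories) {
  q <- length(categories)
  w <- diag(q)
  dimnames(w) <- list(categories, categories)
  w
}

#' @rdname identity_weights
#' @export
linear_weights <- function(categories) {
  q <- length(categories)
  idx <- seq_len(q)
  w <- 1 - abs(outer(idx, idx, "-")) / (q - 1)
  dimnames(w) <- list(categories, categories)
  w
}

#' @rdname identity_weights
#' @export
quadratic_weights <- function(categories) {
  q <- length(categories)
  idx <- seq_len(q)
  w <- 1 - (outer(idx, idx, "-") / (q - 1))^2
  dimnames(w) <- list(categories, categories)
  w
}

#' Gwet's AC2 chance-corrected weighted agreement coefficient
#'
#' For ratings of items by raters over q categories with weights `w_kl`:
#' with `r_ik` raters placing item i in category k, `r_i` raters for item i,
#' and `r*_ik = sum_l w_kl r_il`, observed agreement is the mean over items
#' with at least two raters of `sum_k r_ik (r*_ik - 1) / (r_i (r_i - 1))`;
#' chance agreement is `p_e = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)`
#' with `pi_k` the mean over all items of `r_ik / r_i` and `T_w` the sum of
#' all weights. The coefficient is `(p_a - p_e) / (1 - p_e)`. With identity
#' weights this is Gwet's AC1.
#'
#' @param ratings matrix or data.frame, items x raters, of category labels;
#'   `NA` marks a missing rating.
#' @param categories category labels; defaults to the sorted set observed.
#'   Supply explicitly when some categories are never used.
#' @param weights q x q weight matrix (see [identity_weights()]).
#' @return a list of class `ssp_agreement`: `p_a`, `p_e`, `coefficient`,
#'   `interpretation` (Landis-Koch band), `n_items`, `n_used` (items with
#'   >= 2 raters), `categories`.
#' @export
gwet_ac2 <- function(ratings, categories = NULL, weights = NULL) {
  ratings <- as.matrix(ratings)
  if (is.null(categories))
    categories <- sort(unique(stats::na.omit(as.vector(ratings))))
  q <- length(categories)
  if (q < 2L)
    stop("gwet_ac2: at least two categories are required", call. = FALSE)
  bad <- setdiff(stats::na.omit(as.vector(ratings)), categories)
  if (length(bad))
    stop("gwet_ac2: ratings outside the declared categories: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- identity_weights(categories)
  weights <- as.matrix(weights)
  if (!all(dim(weights) == q))
    stop("gwet_ac2: weight matrix does not match the number of categories",
         call. = FALSE)
  if (any(abs(diag(weights) - 1) > 1e-12) ||
      any(abs(weights - t(weights)) > 1e-12) ||
      any(weights < 0 | weights > 1))
    stop("gwet_ac2: weights must be symmetric, in [0,1], with unit diagonal",
         call. = FALSE)

  n <- nrow(ratings)
  r_ik <- t(apply(ratings, 1, function(row)
    tabulate(match(row, categories), nbins = q)))
  if (n == 1L) r_ik <- matrix(r_ik, nrow = 1L)
  r_i <- rowSums(r_ik)
  if (all(r_i < 2L))
    stop("gwet_ac2: agreement is undefined (every item has fewer than two ",
         "raters)", call. = FALSE)
  use <- r_i >= 2L
  rs_ik <- r_ik %*% t(weights)              # r*_ik = sum_l w_kl r_il
  pa_items <- rowSums(r_ik * (rs_ik - 1))[use] / (r_i[use] * (r_i[use] - 1))
  p_a <- mean(pa_items)
  pi_k <- colMeans(r_ik[r_i > 0, , drop = FALSE] / r_i[r_i > 0])
  T_w <- sum(weights)
  p_e <- T_w / (q * (q - 1)) * sum(pi_k * (1 - pi_k))
  coefficient <- (p_a - p_e) / (1 - p_e)
  structure(list(p_a = p_a, p_e = p_e, coefficient = coefficient,
                 interpretation = landis_koch(coefficient),
                 n_items = n, n_used = sum(use), categories = categories),
            class = "ssp_agreement")
}

#' @export
print.ssp_agreement <- function(x, ...) {
  cat(sprintf("<agreement> AC2 = %.4f (p_a %.4f, p_e %.4f) - %s\n",
              x$coefficient, x$p_a, x$p_e, x$interpretation))
  invisible(x)
}

#' Landis-Koch interpretation band of an agreement coefficient
#'
#' Bands: below 0 "Poor"; 0-0.2 "Slight"; above 0.2 to 0.4 "Fair"; above
#' 0.4 to 0.6 "Moderate"; above 0.6 to 0.8 "Substantial"; above 0.8 to 1
#' "Almost perfect". Published band edges leave printed gaps (0.2 vs 0.21);
#' half-open intervals make the function total, consistent with the printed
#' examples.
#'
#' @param coefficient numeric value(s), each at most 1.
#' @return character vector of band labels.
#' @export
landis_koch <- function(coefficient) {
  if (any(coefficient > 1 + 1e-12))
    stop("landis_koch: agreement coefficients cannot exceed 1", call. = FALSE)
  vapply(coefficient, function(k) {
    if (k < 0) "Poor"
    else if (k <= 0.2) "Slight"
    else if (k <= 0.4) "Fair"
    else if (k <= 0.6) "Moderate"
    else if (k <= 0.8) "Substantial"
    else "Almost perfect"
  }, character(1))
}

#' Count agreement coefficients per interpretation band
#'
#' @param coefficients named numeric vector (variable -> coefficient).
#' @return a list of class `ssp_band_summary`: `bands` (named integer counts
#'   over all six bands) and `labels` (data.frame `variable`, `coefficient`,
#'   `band`).
#' @export
band_summary <- function(coefficients) {
  lv <- c("Poor", "Slight", "Fair", "Moderate", "Substantial",
          "Almost perfect")
  if (!length(coefficients)) {
    return(structure(list(
      bands = stats::setNames(integer(length(lv)), lv),
      labels = data.frame(variable = character(0), coefficient = numeric(0),
                          band = character(0), stringsAsFactors = FALSE)),
      class = "ssp_band_summary"))
  }
  bands <- landis_koch(coefficients)
  labels <- data.frame(
    variable = if (is.null(names(coefficients)))
      as.character(seq_along(coefficients)) else names(coefficients),
    coefficient = unname(coefficients), band = bands,
    stringsAsFactors = FALSE)
  structure(list(
    bands = stats::setNames(as.integer(table(factor(bands, levels = lv))),
                            lv),
    labels = labels),
    class = "ssp_band_summary")
}

#' @export
print.ssp_band_summary <- function(x, ...) {
  cat("<band summary>\n")
  for (b in names(x$bands))
    if (x$bands[[b]] > 0) cat(sprintf("  %-15s %d\n", b, x$bands[[b]]))
  invisible(x)
}

#' Published expert agreement coefficients for the 11 judgment factors
#'
#' The agreement (Gwet AC2) between the elicitation panel and the
#' independent spinal experts, per judgment factor, as published. These are
#' inputs for [band_summary()]; the underlying rating instrument is not
#' recomputable.
#'
#' @return named numeric vector of 11 coefficients.
#' @export
expert_agreement_coefficients <- function() {
  path <- system.file("extdata", "expert_agreement_coefficients.csv",
                      package = "sspbn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$coefficient, df$variable)
}

# ---- nomological containment ------------------------------------------------

#' Published guideline factor lists for the six predictable conditions
#'
#' The reference map of condition-to-factor associations drawn from the
#' red-flag consensus statement (cauda equina syndrome, malignancy,
#' fracture, spinal infection), the inflammatory-condition review and the
#' national nerve-root guideline. `node` gives the canonical network node
#' that corresponds to each published factor label (`NA` when no such node
#' exists); `reported_contained` records the published containment mark.
#'
#' @return data.frame with columns `condition`, `factor_label`, `node`,
#'   `reported_contained`.
#' @export
guideline_factor_reference <- function() {
  path <- system.file("extdata", "guideline_factor_reference.csv",
                      package = "sspbn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$node[df$node == ""] <- NA_character_
  df$reported_contained <- as.logical(df$reported_contained)
  df
}

#' Nomological containment check of a network against a factor reference
#'
#' For each (condition, factor) pair of the reference, a factor is contained
#' when its corresponding node exists in the network and is linked to the
#' condition's judgment node by an edge (in either causal direction).
#'
#' @param net an `ssp_network`.
#' @param reference data.frame as returned by
#'   [guideline_factor_reference()]; must have columns `condition`,
#'   `factor_label`, `node`.
#' @return a list of class `ssp_containment`: `table` (the reference plus a
#'   logical `contained` column) and `summary` (per condition: `n_factors`,
#'   `n_contained`, `pct_contained`).
#' @export
containment_check <- function(net, reference = guideline_factor_reference()) {
  stopifnot(all(c("condition", "factor_label", "node") %in% names(reference)))
  judgments <- layer_nodes(net, "judgment_factor")
  unknown <- setdiff(unique(reference$condition), judgments)
  if (length(unknown))
    stop("containment_check: condition(s) not judgment factors of the ",
         "network: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!nrow(reference)) {
    return(structure(list(
      table = cbind(reference,
                    contained = logical(0)),
      summary = data.frame(condition = character(0), n_factors = integer(0),
                           n_contained = integer(0),
                           pct_contained = numeric(0),
                           stringsAsFactors = FALSE)),
      class = "ssp_containment"))
  }
  linked <- function(cond, node) {
    if (is.na(node) || !node %in% node_names(net)) return(FALSE)
    any(net$edges$parent == cond & net$edges$child == node) ||
      any(net$edges$parent == node & net$edges$child == cond)
  }
  contained <- mapply(linked, reference$condition, reference$node)
  tab <- cbind(reference, contained = unname(contained))
  agg <- do.call(rbind, lapply(split(tab, tab$condition), function(d)
    data.frame(condition = d$condition[1], n_factors = nrow(d),
               n_contained = sum(d$contained),
               pct_contained = 100 * mean(d$contained),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(table = tab, summary = agg), class = "ssp_containment")
}

#' @export
print.ssp_containment <- function(x, ...) {
  cat("<containment check>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- validation framework registry ------------------------------------------

#' Registry of validation domains and their status in this package
#'
#' Seven validation domains make up the framework used to test the network;
#' the three comparator-based domains (concurrent, convergent, discriminant)
#' require an independent model of the same construct, which does not exist,
#' and are deferred.
#'
#' @return data.frame `domain`, `summary`, `method`, `implementable`
#'   (logical); attribute `n_implementable` gives the count.
#' @export
validation_registry <- function() {
  df <- data.frame(
    domain = c("nomological", "face", "content", "predictive",
               "concurrent", "convergent", "discriminant"),
    summary = c(
      "Does the model fit its context in the literature?",
      "Does the structure look right to independent experts?",
      "Does the structure contain all and only the relevant elements?",
      "Does the model predict known case outcomes?",
      "Does the model act like a network of a related construct?",
      "How similar is the model to nomologically proximal models?",
      "How different is the model from nomologically distant models?"),
    method = c(
      "containment_check() against published factor lists",
      "gwet_ac2() on expert review ratings",
      "gwet_ac2() + band_summary() on expert review ratings",
      "predictive_validation(): case ROC/AUC with sensitivity variations",
      "deferred: no comparator model available",
      "deferred: no comparator model available",
      "deferred: no comparator model available"),
    implementable = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  attr(df, "n_implementable") <- sum(df$implementable)
  df
}

# ---- ROC / AUC --------------------------------------------------------------

#' ROC curve and AUC by rank-sum pair counting
#'
#' The AUC is the probability that a randomly chosen positive case scores
#' above a randomly chosen negative one, with ties counting one half. Curve
#' points are the tie-grouped (FPR, TPR) pairs obtained by sweeping the
#' decision threshold through the distinct scores.
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @param condition optional label carried through to the result.
#' @return a list of class `ssp_roc`: `condition`, `auc` (`NA` with a
#'   `diagnostic` when labels contain a single class), `curve` (data.frame
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, condition = NA_character_) {
  if (length(scores) != length(labels))
    stop("roc_auc: scores and labels must have equal length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("roc_auc: labels must be 0 or 1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    return(structure(list(
      condition = condition, auc = NA_real_,
      diagnostic = "AUC undefined: labels contain a single class",
      curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
      n_pos = n_pos, n_neg = n_neg), class = "ssp_roc"))
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg),
                 numeric(1))
  auc <- sum(wins) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(neg >= t) / n_neg, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(condition = condition, auc = auc, diagnostic = NULL,
                 curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "ssp_roc")
}

#' @export
print.ssp_roc <- function(x, ...) {
  cat(sprintf("<roc> %s AUC = %s (%d pos / %d neg)\n",
              if (is.na(x$condition)) "" else x$condition,
              if (is.na(x$auc)) "undefined" else sprintf("%.4f", x$auc),
              x$n_pos, x$n_neg))
  invisible(x)
}

# ---- case records and sensitivity variations --------------------------------

#' Construct a patient case record
#'
#' @param id case identifier.
#' @param evidence named character vector of observed states over risk and
#'   sign nodes; unknown nodes are simply absent.
#' @param labels named 0/1 vector over (a subset of) the six predictable
#'   conditions (see [predictable_conditions()]).
#' @param source free-text provenance tag (e.g. `"literature"`, `"real"`,
#'   `"variation:higher_risk"`, `"synthetic"`).
#' @return a list of class `ssp_case`.
#' @export
case_record <- function(id, evidence = character(0), labels = integer(0),
                        source = "unspecified") {
  if (length(labels)) {
    bad <- setdiff(names(labels), predictable_conditions())
    if (length(bad))
      stop("case '", id, "': labels allowed only for the six predictable ",
           "conditions; offending: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!all(labels %in% c(0L, 1L)))
      stop("case '", id, "': labels must be 0 or 1", call. = FALSE)
  }
  structure(list(id = as.character(id), evidence = evidence,
                 labels = labels, source = source), class = "ssp_case")
}

#' Apply a sensitivity variation to a case
#'
#' The three variations used in the published sensitivity analysis:
#' `"higher_risk"` switches on one additional sign linked to the case's
#' labeled condition (the first, in canonical node order, not already
#' present); `"add_cancer_symptoms"` and `"add_inflammatory_symptoms"`
#' switch on every sign linked to the space-occupying lesion/cancer or
#' inflammatory condition respectively. Labels are never changed.
#'
#' @param case an `ssp_case`.
#' @param variation one of `"higher_risk"`, `"add_cancer_symptoms"`,
#'   `"add_inflammatory_symptoms"`.
#' @param net the `ssp_network` supplying condition-sign links.
#' @param condition for `"higher_risk"`: the target condition; defaults to
#'   the case's (unique) positively labeled condition.
#' @return a new `ssp_case` with modified evidence and a `source` tag
#'   recording the variation.
#' @export
apply_variation <- function(case, variation, net, condition = NULL) {
  variation <- match.arg(variation, c("higher_risk", "add_cancer_symptoms",
                                      "add_inflammatory_symptoms"))
  signs_of <- function(cond) {
    kids <- children_of(net, cond)
    # canonical node order
    intersect(node_names(net), kids)
  }
  ev <- case$evidence
  if (variation == "higher_risk") {
    if (is.null(condition)) {
      pos <- names(case$labels)[case$labels == 1L]
      if (length(pos) != 1L)
        stop("higher_risk: target condition is ambiguous; pass `condition`",
             call. = FALSE)
      condition <- pos
    }
    candidates <- signs_of(condition)
    unset <- candidates[vapply(candidates, function(s)
      !(s %in% names(ev)) || ev[[s]] != "present", logical(1))]
    if (!length(unset))
      stop("higher_risk: every sign linked to '", condition,
           "' is already present; variation exhausted", call. = FALSE)
    ev[unset[1]] <- "present"
  } else {
    cond <- if (variation == "add_cancer_symptoms")
      "space_occupying_lesion" else "inflammatory_condition"
    for (s in signs_of(cond)) ev[s] <- "present"
  }
  case_record(case$id, ev, case$labels,
              source = paste0(case$source, "+", variation))
}

#' Case-based predictive validation
#'
#' Scores every case with the exact posterior probability of each
#' predictable condition given the case's evidence, then compares scores
#' against the 0/1 labels with [roc_auc()], per condition. Conditions whose
#' labels contain a single class are reported with an undefined AUC rather
#' than an error.
#'
#' @param pnet an `ssp_pnet`.
#' @param cases list of `ssp_case` records (each must carry labels).
#' @param conditions conditions to evaluate; defaults to all six.
#' @return a list of class `ssp_predictive_validation`: `results` (named
#'   list of `ssp_roc` per condition), `auc` (named numeric, `NA` when
#'   undefined), `scores` (cases x conditions matrix), `labels` (matrix).
#' @export
predictive_validation <- function(pnet, cases,
                                  conditions = predictable_conditions()) {
  if (!length(cases))
    stop("predictive_validation: at least one case is required",
         call. = FALSE)
  scores <- matrix(NA_real_, nrow = length(cases),
                   ncol = length(conditions),
                   dimnames = list(vapply(cases, `[[`, character(1), "id"),
                                   conditions))
  labels <- scores
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    rep_ <- tryCatch(posterior_judgments(pnet, cs$evidence),
                     error = function(e)
                       stop("case '", cs$id, "': ", conditionMessage(e),
                            call. = FALSE))
    scores[i, ] <- rep_$posteriors[conditions]
    labels[i, ] <- vapply(conditions, function(cd)
      if (cd %in% names(cs$labels)) as.numeric(cs$labels[[cd]]) else NA_real_,
      numeric(1))
  }
  results <- lapply(conditions, function(cd) {
    ok <- !is.na(labels[, cd])
    roc_auc(scores[ok, cd], labels[ok, cd], condition = cd)
  })
  names(results) <- conditions
  structure(list(
    results = results,
    auc = vapply(results, `[[`, numeric(1), "auc"),
    scores = scores, labels = labels),
    class = "ssp_predictive_validation")
}

#' @export
print.ssp_predictive_validation <- function(x, ...) {
  cat("<predictive validation>\n")
  for (cd in names(x$auc))
    cat(sprintf("  %-28s AUC %s\n", cd,
                if (is.na(x$auc[[cd]])) "undefined"
                else sprintf("%.4f", x$auc[[cd]])))
  invisible(x)
}
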