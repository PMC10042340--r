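# Statistical evaluation: Mann-Whitney U comparison of ambiguity indices
# between normal and diseased groups, and ROC/AUC for discrimination, per
# layer and overall. Higher ambiguity index => predicted diseased.

#' Mann-Whitney U test (rank-sum with midranks, normal approximation)
#'
#' U is computed from the rank sum of `group_a` with midrank tie handling
#' (`U = R_a - n1(n1+1)/2`, the number of (a, b) pairs with `a > b`, ties
#' counting one half). The two-sided p-value uses the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return An object of class `mwu_result`: list with `U`, `p_value`, `n1`,
#'   `n2`, `z`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_octamb("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- if (v <= 0) 0 else {
    num <- U - mu
    (num - sign(num) * 0.5) / sqrt(v)
  }
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(U = U, p_value = p, n1 = n1, n2 = n2, z = z),
            class = "mwu_result")
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique scores (higher score predicts the positive
#' class); the curve starts at (0, 0), ends at (1, 1), and AUC is the
#' trapezoidal integral, which equals the tie-adjusted probability that a
#' positive outranks a negative.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive (diseased).
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame fpr/tpr/threshold), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_octamb("scores and labels must be complete and of equal length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop_octamb("both classes must be present to build a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1L))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                      threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Check the AUC / Mann-Whitney U duality
#'
#' Asserts that the trapezoidal AUC equals `U' / (n1 * n2)`, where `U'`
#' counts (positive > negative) pairs with ties as one half.
#'
#' @inheritParams roc_curve
#' @param tol Agreement tolerance.
#' @return `TRUE`/`FALSE`, with attributes `auc` and `u_normalized`.
#' @export
auc_equivalence_check <- function(scores, labels, tol = 1e-10) {
  labels <- as.logical(labels)
  auc <- roc_curve(scores, labels)$auc
  pos <- scores[labels]; neg <- scores[!labels]
  uprime <- mann_whitney_u(pos, neg)$U     # (pos > neg) pairs, ties as 1/2
  un <- uprime / (length(pos) * length(neg))
  structure(abs(auc - un) <= tol, auc = auc, u_normalized = un)
}

#' Run the full cohort study
#'
#' Segments every sample with the trained model, computes per-layer and
#' overall ambiguity indices, and evaluates discrimination: overall Amb-I
#' against the global abnormality label, and each layer's Amb-I against
#' that layer's label, via ROC/AUC and the Mann-Whitney U test. Layers
#' whose label is constant across the cohort get `NA` results.
#'
#' @param samples List of labelled `bscan_sample` (e.g. [generate_cohort()]).
#' @param model A trained `octamb_model`.
#' @param mask Optional A-scan mask (e.g. [fovea_mask()]) applied to every
#'   index computation.
#' @param log_base Entropy log base.
#' @return An object of class `cohort_study`: list with `table`
#'   (data.frame: id, label, overall plus per-layer Amb-I and labels),
#'   `overall` (list with `roc`, `mwu`), `per_layer` (list of 6, each with
#'   `roc`, `mwu`, `auc`).
#' @export
run_cohort_study <- function(samples, model, mask = NULL, log_base = exp(1)) {
  stopifnot(inherits(model, "octamb_model"))
  if (!isTRUE(model$trained))
    stop_octamb("model has not been trained; run train_model() first")
  if (length(samples) == 0L) stop_octamb("empty cohort")
  nL <- model$config$n_boundaries
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pv <- predict_probabilities(model, s)
    ep <- ascan_entropy(pv, log_base = log_base)
    ai <- overall_ambiguity_index(ep, mask)
    c(list(id = if (!is.null(s$id)) s$id else sprintf("sample_%03d", i),
           label = s$global_label, overall = ai$overall),
      stats::setNames(as.list(ai$per_layer), paste0("amb_", seq_len(nL))),
      stats::setNames(as.list(s$layer_labels), paste0("label_", seq_len(nL))))
  })
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (length(unique(tab$label)) < 2L)
    stop_octamb("cohort contains a single class; cannot evaluate")
  overall <- list(
    roc = roc_curve(tab$overall, tab$label),
    mwu = mann_whitney_u(tab$overall[tab$label], tab$overall[!tab$label])
  )
  per_layer <- lapply(seq_len(nL), function(l) {
    sc <- tab[[paste0("amb_", l)]]
    lb <- tab[[paste0("label_", l)]]
    if (length(unique(lb)) < 2L)
      return(list(roc = NULL, mwu = NULL, auc = NA_real_))
    r <- roc_curve(sc, lb)
    list(roc = r, mwu = mann_whitney_u(sc[lb], sc[!lb]), auc = r$auc)
  })
  names(per_layer) <- boundary_names()[seq_len(nL)]
  structure(list(table = tab, overall = overall, per_layer = per_layer),
            class = "cohort_study")
}
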