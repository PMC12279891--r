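#' Intra/juxta neighborhood views for colocalization modelling
#'
#' The intra view is each bead's own abundance row; the juxta view is the
#' unweighted mean abundance of the bead's `k_view` nearest neighboring
#' beads, self excluded (ties broken by bead index). Together they let the
#' neighborhood abundance of predictor cell types explain a target type's
#' local abundance.
#'
#' @param spatial A `spatial_map`.
#' @param k_view Neighbors per bead in the juxta view (default 20).
#' @return A `neighborhood_view`: list with `intra`, `juxta`, `k_view`.
#' @export
build_views <- function(spatial, k_view = 20L) {
  stopifnot(inherits(spatial, "spatial_map"))
  k_view <- as.integer(k_view)
  if (k_view < 1) stop("k_view must be >= 1", call. = FALSE)
  n <- nrow(spatial$abundance)
  if (n < k_view + 1) {
    stop(sprintf("need at least k_view+1 = %d beads, got %d", k_view + 1, n),
         call. = FALSE)
  }
  nn <- knn_index_matrix(spatial$coords, k_view)
  juxta <- matrix(0, n, ncol(spatial$abundance),
                  dimnames = dimnames(spatial$abundance))
  for (j in seq_len(k_view)) juxta <- juxta + spatial$abundance[nn[, j], , drop = FALSE]
  juxta <- juxta / k_view
  rownames(juxta) <- spatial$bead_ids
  structure(list(intra = spatial$abundance, juxta = juxta, k_view = k_view),
            class = "neighborhood_view")
}

#' Predictor-to-target spatial colocalization importance
#'
#' For each target cell type, regresses its intra-view abundance on the
#' juxta-view abundances of all other cell types (self-prediction masked),
#' both z-scored, with ridge regularization; the importance of predictor p
#' for target t is the absolute standardized ridge coefficient. Per-target
#' in-sample R-squared is recorded. Zero-variance predictors get
#' importance 0 with a warning; a zero-variance target yields an NA
#' column.
#'
#' @param view A `neighborhood_view` from [build_views()].
#' @param group Optional tissue-group label carried in the result.
#' @param ridge_lambda Ridge penalty (default 1).
#' @return An `importance_matrix`: list with `importance` (predictor types
#'   x target types, NA diagonal), `model_r2` per target, `group`.
#' @export
fit_importance <- function(view, group = NA_character_, ridge_lambda = 1) {
  stopifnot(inherits(view, "neighborhood_view"))
  n <- nrow(view$intra)
  types <- colnames(view$intra)
  if (n < 10) stop("need at least 10 beads", call. = FALSE)
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0", call. = FALSE)
  imp <- matrix(NA_real_, length(types), length(types),
                dimnames = list(predictor = types, target = types))
  r2 <- stats::setNames(rep(NA_real_, length(types)), types)
  zsc <- function(m) {
    s <- apply(m, 2, stats::sd)
    centered <- sweep(m, 2, colMeans(m))
    sweep(centered, 2, ifelse(s > 0, s, 1), "/")
  }
  juxta_sd <- apply(view$juxta, 2, stats::sd)
  Z <- zsc(view$juxta)
  for (t in types) {
    y <- view$intra[, t]
    if (stats::sd(y) == 0) next  # target carries no signal: NA column
    y <- (y - mean(y)) / stats::sd(y)
    preds <- setdiff(types, t)
    live <- preds[juxta_sd[preds] > 0]
    if (length(live) < length(preds)) {
      warning("zero-variance predictor(s) set to importance 0 for target ", t)
      imp[setdiff(preds, live), t] <- 0
    }
    if (length(live) == 0) { r2[t] <- 0; next }
    X <- Z[, live, drop = FALSE]
    XtX <- crossprod(X)
    beta <- solve(XtX + diag(ridge_lambda, ncol(X)), crossprod(X, y))
    fit <- X %*% beta
    imp[live, t] <- abs(beta[, 1])
    r2[t] <- 1 - sum((y - fit)^2) / sum(y^2)
  }
  structure(list(importance = imp, model_r2 = r2, group = group,
                 ridge_lambda = ridge_lambda),
            class = "importance_matrix")
}

#' Difference of importance matrices between two groups
#'
#' @param a,b `importance_matrix` objects over the same cell types in the
#'   same order (e.g. tumor and healthy).
#' @return Signed matrix `a$importance - b$importance`; NA where either
#'   side is undefined.
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "importance_matrix"), inherits(b, "importance_matrix"))
  if (!identical(dimnames(a$importance), dimnames(b$importance))) {
    stop("importance matrices have mismatched cell-type sets", call. = FALSE)
  }
  a$importance - b$importance
}
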