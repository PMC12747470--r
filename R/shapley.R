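# Shapley-value feature attributions for model predictions. The coalition
# value is the model evaluated with coalition features taken from the
# instance and all other features replaced by background averages, so the
# base value is the model at the background mean and efficiency
# (base + sum(phi) = f(x)) holds exactly - also for the permutation
# estimator, whose per-permutation contributions telescope.

#' Shapley-value explanation of a single prediction
#'
#' Features identical to the background mean are inactive and receive zero
#' attribution. The remaining `d` active features are attributed by exact
#' enumeration of all `2^d` coalitions when `d <= exact_limit` (default
#' 12), weighting marginal contributions by `|S|! (d-|S|-1)! / d!`;
#' otherwise by seeded permutation sampling with a Monte-Carlo standard
#' error per feature.
#'
#' @param f Model as a function taking a numeric feature matrix (one row
#'   per evaluation) and returning a numeric vector. For a
#'   `toxicity_model` use e.g.
#'   `function(X) predict_toxicity(model, X)$probabilities[, "safe"]`.
#' @param x Numeric feature vector of the instance to explain.
#' @param background Numeric matrix of background rows (same columns as
#'   `x`); its column means define the "feature missing" replacement.
#' @param method `"exact"`, `"sampled"`, or `"auto"` (exact when feasible).
#' @param n_permutations Permutations for the sampled estimator.
#' @param seed RNG seed for the sampled estimator.
#' @param exact_limit Maximum active dimension for exact enumeration
#'   (hard cap 30, above which the request is refused).
#' @return Object of class `shapley_explanation`: `attributions` (named,
#'   length of `x`), `base_value`, `prediction`, `method`, and `se`
#'   (per-feature MC standard errors; zeros for exact).
#' @export
shapley_explain <- function(f, x, background,
                            method = c("auto", "exact", "sampled"),
                            n_permutations = 2000L, seed = 1L,
                            exact_limit = 12L) {
  method <- match.arg(method)
  background <- as.matrix(background)
  if (!nrow(background)) stop("background set is empty", call. = FALSE)
  x <- as.numeric(x)
  stopifnot(length(x) == ncol(background))
  mu <- colMeans(background)
  active <- which(abs(x - mu) > 1e-12)
  d <- length(active)
  phi <- stats::setNames(numeric(length(x)),
                         colnames(background) %||% paste0("f", seq_along(x)))
  se <- phi
  eval_row <- function(mask) {
    z <- mu
    z[active[mask]] <- x[active[mask]]
    z
  }
  base_value <- as.numeric(f(rbind(mu)))
  prediction <- as.numeric(f(rbind(x)))
  if (d == 0L) {
    return(structure(list(attributions = phi, base_value = base_value,
                          prediction = prediction, method = "exact", se = se),
                     class = "shapley_explanation"))
  }
  if (method == "auto") method <- if (d <= exact_limit) "exact" else "sampled"
  if (method == "exact") {
    if (d > 30L) {
      stop("exact Shapley enumeration refused for d > 30 active features",
           call. = FALSE)
    }
    if (d > exact_limit) {
      stop(sprintf("exact enumeration requested for d = %d > exact_limit = %d",
                   d, exact_limit), call. = FALSE)
    }
    # evaluate all 2^d coalition values in one batched model call
    n_coal <- 2^d
    masks <- matrix(FALSE, n_coal, d)
    for (k in seq_len(d)) {
      masks[, k] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, k - 1L)) > 0L
    }
    Z <- t(apply(masks, 1, eval_row))
    v <- as.numeric(f(Z))
    sizes <- rowSums(masks)
    lw <- lgamma(sizes + 1) + lgamma(d - sizes) - lgamma(d + 1)  # |S|!(d-|S|-1)!/d!
    for (k in seq_len(d)) {
      without <- which(!masks[, k])
      with_k <- without + bitwShiftL(1L, k - 1L)
      phi[active[k]] <- sum(exp(lw[without]) * (v[with_k] - v[without]))
    }
    mc_se <- rep(0, length(x))
  } else {
    set.seed(seed)
    contrib <- matrix(0, n_permutations, d)
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(d)
      mask <- rep(FALSE, d)
      rows <- matrix(0, d + 1L, length(x))
      rows[1, ] <- eval_row(mask)
      for (k in seq_len(d)) {
        mask[perm[k]] <- TRUE
        rows[k + 1L, ] <- eval_row(mask)
      }
      vv <- as.numeric(f(rows))
      contrib[p, perm] <- diff(vv)
    }
    phi[active] <- colMeans(contrib)
    mc_se <- rep(0, length(x))
    mc_se[active] <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  }
  se[] <- mc_se
  structure(list(attributions = phi, base_value = base_value,
                 prediction = prediction, method = method,
                 n_permutations = if (method == "sampled") n_permutations else NA_integer_,
                 seed = if (method == "sampled") seed else NA_integer_,
                 se = se),
            class = "shapley_explanation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("shapley_explanation (%s): base %.4f -> prediction %.4f\n",
              x$method, x$base_value, x$prediction))
  top <- sort(abs(x$attributions), decreasing = TRUE)
  show <- names(utils::head(top[top > 0], 8))
  if (length(show)) print(round(x$attributions[show], 4))
  invisible(x)
}
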