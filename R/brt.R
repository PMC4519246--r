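#' Boosting hyperparameters
#'
#' Defaults follow the conventions established for boosted regression trees
#' in species-distribution modelling (small learning rate, shallow trees,
#' 75% bagging).
#'
#' @param learning_rate shrinkage applied to every tree's contribution.
#' @param tree_complexity maximum interior splits per tree (>= 1).
#' @param bag_fraction fraction of training rows drawn (without replacement)
#'   for each tree, in (0, 1].
#' @param max_trees maximum boosting iterations.
#' @param holdout_fraction fraction of rows held out for early stopping; set
#'   to 0 to fit exactly `max_trees` trees.
#' @param patience iterations without holdout-deviance improvement before
#'   stopping.
#' @param min_obs minimum observations per leaf.
#' @param seed integer seed driving holdout and bag draws.
#' @return an object of class `pod_brt_params`.
#' @export
brt_params <- function(learning_rate = 0.01, tree_complexity = 5L,
                       bag_fraction = 0.75, max_trees = 1000L,
                       holdout_fraction = 0.2, patience = 10L,
                       min_obs = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, tree_complexity >= 1L,
            bag_fraction > 0, bag_fraction <= 1,
            max_trees >= 1L, holdout_fraction >= 0, holdout_fraction < 1,
            patience >= 1L, min_obs >= 1L)
  structure(
    list(learning_rate = learning_rate,
         tree_complexity = as.integer(tree_complexity),
         bag_fraction = bag_fraction, max_trees = as.integer(max_trees),
         holdout_fraction = holdout_fraction, patience = as.integer(patience),
         min_obs = as.integer(min_obs), seed = as.integer(seed)),
    class = "pod_brt_params"
  )
}

# best least-squares split of `rows`; candidates are midpoints between
# consecutive distinct values; ties broken by (column index, threshold) order
best_split <- function(X, r, rows, min_obs) {
  n <- length(rows)
  if (n < 2L * min_obs) return(NULL)
  rr <- r[rows]
  S <- sum(rr)
  base <- S^2 / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    o <- order(x, method = "radix")
    xs <- x[o]
    cum <- cumsum(rr[o])
    k <- seq_len(n - 1L)
    valid <- k >= min_obs & k <= n - min_obs & xs[k] < xs[k + 1L]
    if (!any(valid)) next
    k <- k[valid]
    gain <- cum[k]^2 / k + (S - cum[k])^2 / (n - k) - base
    i <- which.max(gain)
    if (is.null(best) || gain[i] > best$gain + 1e-12) {
      kk <- k[i]
      best <- list(gain = gain[i], var = j,
                   split = (xs[kk] + xs[kk + 1L]) / 2,
                   left = rows[o[seq_len(kk)]],
                   right = rows[o[(kk + 1L):n]])
    }
  }
  best
}

#' Fit a single regression tree on a working response
#'
#' Greedy best-first CART-style least-squares splitting, used as the base
#' learner of the boosting loop: at each step the frontier leaf whose best
#' split yields the largest squared-error reduction is expanded, up to
#' `tree_complexity` interior splits, with at least `min_obs` observations
#' per leaf. Terminal values are Bernoulli Newton steps
#' `sum(residual) / sum(p(1-p))` over the rows reaching the leaf, capped at
#' |value| <= 4 to guard pure leaves.
#'
#' @param X numeric matrix of covariates (the in-bag rows).
#' @param residual working response (gradient residuals y - p).
#' @param hessian per-row curvature p(1-p) for the Newton step.
#' @param tree_complexity maximum interior splits.
#' @param min_obs minimum rows per leaf.
#' @return a `pod_tree`: a node table with columns `var` (0 for leaves),
#'   `split`, `left`, `right`, `value`, `n`, `improvement`.
#' @export
fit_tree <- function(X, residual, hessian, tree_complexity = 5L, min_obs = 5L) {
  stopifnot(nrow(X) >= 2L, all(is.finite(residual)))
  nodes <- list(list(rows = seq_len(nrow(X)), var = 0L, split = NA_real_,
                     left = 0L, right = 0L, improvement = 0))
  cand <- list(`1` = best_split(X, residual, nodes[[1]]$rows, min_obs))
  n_splits <- 0L
  while (n_splits < tree_complexity) {
    gains <- vapply(cand, function(s) if (is.null(s)) -Inf else s$gain, numeric(1))
    if (!length(gains) || all(gains <= 1e-12)) break
    pick <- as.integer(names(cand)[which.max(gains)])
    s <- cand[[as.character(pick)]]
    li <- length(nodes) + 1L
    ri <- length(nodes) + 2L
    nodes[[pick]]$var <- s$var
    nodes[[pick]]$split <- s$split
    nodes[[pick]]$left <- li
    nodes[[pick]]$right <- ri
    nodes[[pick]]$improvement <- s$gain
    nodes[[li]] <- list(rows = s$left, var = 0L, split = NA_real_,
                        left = 0L, right = 0L, improvement = 0)
    nodes[[ri]] <- list(rows = s$right, var = 0L, split = NA_real_,
                        left = 0L, right = 0L, improvement = 0)
    cand[[as.character(pick)]] <- NULL
    cand[[as.character(li)]] <- best_split(X, residual, s$left, min_obs)
    cand[[as.character(ri)]] <- best_split(X, residual, s$right, min_obs)
    n_splits <- n_splits + 1L
  }
  value <- vapply(nodes, function(nd) {
    if (nd$var != 0L) return(0)
    num <- sum(residual[nd$rows])
    den <- sum(hessian[nd$rows])
    v <- num / max(den, 1e-10)
    max(min(v, 4), -4)
  }, numeric(1))
  tab <- cbind(
    var = vapply(nodes, `[[`, integer(1), "var"),
    split = vapply(nodes, `[[`, numeric(1), "split"),
    left = vapply(nodes, `[[`, numeric(1), "left"),
    right = vapply(nodes, `[[`, numeric(1), "right"),
    value = value,
    n = vapply(nodes, function(nd) length(nd$rows), numeric(1)),
    improvement = vapply(nodes, `[[`, numeric(1), "improvement")
  )
  structure(tab, class = "pod_tree")
}

# vectorised tree traversal; children always follow their parent, so a single
# forward pass over nodes routes every row
predict_tree <- function(tree, X) {
  node_of <- rep.int(1L, nrow(X))
  out <- numeric(nrow(X))
  for (k in seq_len(nrow(tree))) {
    at <- node_of == k
    if (!any(at)) next
    if (tree[k, "var"] == 0) {
      out[at] <- tree[k, "value"]
    } else {
      goes_left <- X[, tree[k, "var"]] <= tree[k, "split"]
      node_of[at & goes_left] <- as.integer(tree[k, "left"])
      node_of[at & !goes_left] <- as.integer(tree[k, "right"])
    }
  }
  out
}

bernoulli_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a boosted regression tree model for binary occurrence
#'
#' Stagewise gradient boosting on the Bernoulli deviance: the model starts
#' at the empirical log-odds, and each iteration fits a least-squares
#' regression tree (see [fit_tree()]) to the gradient residuals `y - p` on a
#' seeded bag of training rows, then shrinks its Newton-step leaf values
#' into the additive logit predictor. With a positive `holdout_fraction`
#' a seeded holdout set stops boosting once its deviance has not improved
#' for `patience` iterations, and the model is trimmed back to the best
#' iteration.
#'
#' @param X data frame or matrix of numeric covariates.
#' @param y 0/1 presence labels (both classes required).
#' @param params a [brt_params()].
#' @return an object of class `pod_brt` with elements `intercept`, `trees`,
#'   `learning_rate`, `covariates`, `n_trees`, `train_deviance`,
#'   `holdout_deviance`, `holdout_idx`, `params`, `data` (the training
#'   matrix, kept for partial-dependence averaging).
#' @export
fit_brt <- function(X, y, params = brt_params()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("degenerate response: only one class present", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  intercept <- stats::qlogis(mean(y))

  with_pod_seed(params$seed, {
    if (params$holdout_fraction > 0) {
      ho <- sort(sample.int(n, max(1L, round(params$holdout_fraction * n))))
      tr <- setdiff(seq_len(n), ho)
    } else {
      ho <- integer(0)
      tr <- seq_len(n)
    }
    bag_n <- max(2L, round(params$bag_fraction * length(tr)))
    f <- rep(intercept, n)
    trees <- vector("list", params$max_trees)
    dev_tr <- numeric(params$max_trees)
    dev_ho <- numeric(params$max_trees)
    best_dev <- Inf
    best_iter <- 0L
    m <- 0L
    while (m < params$max_trees) {
      m <- m + 1L
      p <- stats::plogis(f)
      bag <- if (bag_n < length(tr)) tr[sample.int(length(tr), bag_n)] else tr
      r <- y[bag] - p[bag]
      h <- p[bag] * (1 - p[bag])
      tree <- fit_tree(X[bag, , drop = FALSE], r, h,
                       params$tree_complexity, params$min_obs)
      f <- f + params$learning_rate * predict_tree(tree, X)
      trees[[m]] <- tree
      pnew <- stats::plogis(f)
      dev_tr[m] <- bernoulli_deviance(y[tr], pnew[tr])
      if (length(ho)) {
        dev_ho[m] <- bernoulli_deviance(y[ho], pnew[ho])
        if (dev_ho[m] < best_dev - 1e-10) {
          best_dev <- dev_ho[m]
          best_iter <- m
        } else if (m - best_iter >= params$patience) {
          break
        }
      } else {
        best_iter <- m
      }
    }
  })
  n_used <- max(best_iter, 1L)
  structure(
    list(intercept = intercept,
         trees = trees[seq_len(n_used)],
         learning_rate = params$learning_rate,
         covariates = colnames(X),
         n_trees = n_used,
         train_deviance = dev_tr[seq_len(n_used)],
         holdout_deviance = if (length(ho)) dev_ho[seq_len(n_used)] else NULL,
         holdout_idx = ho,
         params = params,
         data = X),
    class = "pod_brt"
  )
}

#' @export
print.pod_brt <- function(x, ...) {
  cat(sprintf(
    "<pod_brt> %d trees (lr %g, complexity %d), %d covariates, intercept %.3f\n",
    x$n_trees, x$learning_rate, x$params$tree_complexity,
    length(x$covariates), x$intercept
  ))
  cat(sprintf("  final training deviance: %.2f\n", utils::tail(x$train_deviance, 1)))
  if (!is.null(x$holdout_deviance)) {
    cat(sprintf("  final holdout deviance : %.2f (%d holdout rows)\n",
                utils::tail(x$holdout_deviance, 1), length(x$holdout_idx)))
  }
  invisible(x)
}

#' Predict from a fitted BRT model
#'
#' @param object a `pod_brt`.
#' @param newdata data frame or matrix containing the model's covariates.
#' @param scale `"probability"` (inverse-logit) or `"logit"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pod_brt <- function(object, newdata, scale = c("probability", "logit"), ...) {
  scale <- match.arg(scale)
  newdata <- as.data.frame(newdata)
  missing_cov <- setdiff(object$covariates, names(newdata))
  if (length(missing_cov)) {
    stop("newdata is missing covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  newdata <- as.matrix(newdata[, object$covariates, drop = FALSE])
  storage.mode(newdata) <- "double"
  f <- rep(object$intercept, nrow(newdata))
  for (tree in object$trees) {
    f <- f + object$learning_rate * predict_tree(tree, newdata)
  }
  if (scale == "probability") stats::plogis(f) else f
}

#' Relative influence of each covariate
#'
#' Accumulates, over every split in every tree, the squared-error
#' improvement attributed to the split variable, and scales the per-variable
#' totals to sum to 100. Variables the model never splits on get 0.
#'
#' @param model a `pod_brt`.
#' @return a tibble with columns `covariate`, `influence`, sorted decreasing.
#' @export
relative_influence <- function(model) {
  totals <- stats::setNames(numeric(length(model$covariates)), model$covariates)
  any_split <- FALSE
  for (tree in model$trees) {
    interior <- tree[, "var"] != 0
    if (any(interior)) {
      any_split <- TRUE
      v <- model$covariates[tree[interior, "var"]]
      imp <- tree[interior, "improvement"]
      for (i in seq_along(v)) totals[v[i]] <- totals[v[i]] + imp[i]
    }
  }
  if (!any_split) stop("model contains no splits", call. = FALSE)
  tibble::tibble(
    covariate = names(totals),
    influence = unname(100 * totals / sum(totals))
  ) |>
    dplyr::arrange(dplyr::desc(.data$influence))
}

#' Partial-dependence (marginal effect) curve
#'
#' For each grid value v, the covariate is set to v in every training row
#' and the model's logit predictions are averaged — the definitional
#' brute-force computation, vectorised over the grid.
#'
#' @param model a `pod_brt`.
#' @param covariate covariate name.
#' @param grid numeric grid of values; default `n_grid` evenly spaced points
#'   over the training range of the covariate.
#' @param n_grid grid size when `grid` is NULL.
#' @return a tibble with columns `covariate`, `value`, `logit`.
#' @export
partial_dependence <- function(model, covariate, grid = NULL, n_grid = 100L) {
  if (!covariate %in% model$covariates) {
    stop("covariate '", covariate, "' is not in the model", call. = FALSE)
  }
  X <- model$data
  if (is.null(grid)) {
    rng <- range(X[, covariate])
    grid <- seq(rng[1], rng[2], length.out = n_grid)
  }
  n <- nrow(X)
  Xrep <- X[rep(seq_len(n), times = length(grid)), , drop = FALSE]
  Xrep[, covariate] <- rep(grid, each = n)
  f <- predict.pod_brt(model, Xrep, scale = "logit")
  # per-grid-value mean() so the result is bit-identical to the defining
  # row-by-row averaging
  tibble::tibble(
    covariate = covariate,
    value = grid,
    logit = vapply(seq_along(grid),
                   function(g) mean(f[((g - 1L) * n + 1L):(g * n)]),
                   numeric(1))
  )
}

#' Serialize a BRT model to JSON and back
#'
#' Full-precision JSON round trip: predictions from the reloaded model are
#' bit-identical to the original's.
#'
#' @param model a `pod_brt`.
#' @param path JSON file path.
#' @return `write_brt()` returns `path` invisibly; `read_brt()` a `pod_brt`.
#' @export
write_brt <- function(model, path) {
  doc <- list(
    intercept = model$intercept,
    learning_rate = model$learning_rate,
    covariates = model$covariates,
    n_trees = model$n_trees,
    params = unclass(model$params),
    trees = lapply(model$trees, function(t) as.data.frame(unclass(t))),
    train_deviance = model$train_deviance,
    holdout_deviance = model$holdout_deviance,
    holdout_idx = model$holdout_idx,
    boot_idx = model$boot_idx,
    oob_idx = model$oob_idx,
    data = as.data.frame(model$data)
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_brt
#' @export
read_brt <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(doc$n_trees), function(i) {
    t <- as.matrix(doc$trees[[i]])
    storage.mode(t) <- "double"
    structure(t, class = "pod_tree")
  })
  X <- as.matrix(doc$data)
  storage.mode(X) <- "double"
  extra <- list(boot_idx = doc$boot_idx, oob_idx = doc$oob_idx)
  structure(
    c(list(intercept = doc$intercept, trees = trees,
         learning_rate = doc$learning_rate,
         covariates = doc$covariates, n_trees = doc$n_trees,
         train_deviance = doc$train_deviance,
         holdout_deviance = doc$holdout_deviance,
         holdout_idx = if (length(doc$holdout_idx)) doc$holdout_idx else integer(0),
         params = do.call(brt_params, doc$params),
         data = X),
      extra[!vapply(extra, is.null, logical(1))]),
    class = "pod_brt"
  )
}
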