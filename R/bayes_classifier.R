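#' Train a naive-Bayes activity classifier
#'
#' Fits the star-structured Bayes network in which the class node is the sole
#' parent of every feature node.  With the default Gaussian likelihood each
#' feature gets a per-class normal density (the natural choice for continuous
#' IMU features); with `likelihood = "discrete"` features are first
#' discretized by equal-frequency binning and modelled by smoothed
#' conditional probability tables, exactly as in [train_bayes_network()] with
#' no feature-to-feature edges.
#'
#' Class priors are estimated with additive smoothing
#' `(n_c + alpha) / (n + alpha K)` so every prior is strictly positive.
#'
#' @param x Numeric matrix of training instances (rows) by features (named
#'   columns).
#' @param y Class label per row; at least 2 classes and 2 instances per
#'   class.
#' @param likelihood `"gaussian"` (default) or `"discrete"`.
#' @param bins Number of equal-frequency bins for the discrete likelihood.
#' @param alpha Additive (Laplace) smoothing pseudo-count, default 0.5.
#' @return An object of class `bayes_net_model`.
#' @export
train_naive_bayes <- function(x, y, likelihood = c("gaussian", "discrete"),
                              bins = 10L, alpha = 0.5) {
  likelihood <- match.arg(likelihood)
  x <- as.matrix(x)
  y <- as.character(y)
  check_training_set(x, y)
  if (likelihood == "discrete") {
    return(train_bayes_network(x, y, max_parents = 0L, bins = bins,
                               alpha = alpha))
  }
  classes <- sort(unique(y))
  feats <- colnames(x)
  mu <- sdev <- matrix(0, length(classes), length(feats),
                       dimnames = list(classes, feats))
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(xc)
    s <- apply(xc, 2, stats::sd)
    # variance floor keeps degenerate (constant) features from producing
    # infinite densities
    sdev[cl, ] <- pmax(s, 1e-6)
  }
  structure(list(type = "gaussian",
                 classes = classes,
                 features = feats,
                 priors = smoothed_priors(y, classes, alpha),
                 mu = mu, sd = sdev,
                 parents = stats::setNames(rep(list(character(0)), length(feats)),
                                           feats),
                 alpha = alpha),
            class = "bayes_net_model")
}

#' Train a Bayes-network activity classifier
#'
#' Learns a class-augmented Bayes network `B = <G, Theta>` over discretized
#' features.  The class node is forced as a root parent of every feature
#' node; up to `max_parents` additional feature-to-feature edges per node are
#' added by greedy hill-climbing, scored by the decomposable Bayesian
#' (Dirichlet-marginal, K2-style with pseudo-count `alpha`) score, rejecting
#' edges that would create a directed cycle.  Conditional probability tables
#' are smoothed maximum-likelihood estimates with pseudo-count `alpha`; the
#' joint then factorises as `P(X_1..X_n, C) = P(C) * prod_i P(X_i | pa(X_i))`.
#'
#' Continuous features are discretized by per-feature equal-frequency binning
#' (bin edges from training quantiles); at prediction time, values outside
#' the training range fall into the nearest edge bin, so no instance ever
#' receives zero probability.
#'
#' @inheritParams train_naive_bayes
#' @param max_parents Maximum feature parents per feature node (class parent
#'   excluded); 0 reduces to discretized naive Bayes.  Must be >= 0.
#' @return An object of class `bayes_net_model` with fields `parents` (the
#'   learned feature-parent map), `breaks` (per-feature bin edges), `cpt`
#'   (per-feature tables) and `priors`.
#' @export
train_bayes_network <- function(x, y, max_parents = 1L, bins = 10L,
                                alpha = 0.5) {
  x <- as.matrix(x)
  y <- as.character(y)
  check_training_set(x, y)
  if (max_parents < 0) stop("invalid config: max_parents must be >= 0")
  if (bins < 2) stop("invalid config: bins must be >= 2")
  classes <- sort(unique(y))
  feats <- colnames(x)
  ci <- match(y, classes)
  K <- length(classes)

  breaks <- lapply(feats, function(f) equal_frequency_breaks(x[, f], bins))
  names(breaks) <- feats
  binned <- sapply(feats, function(f) bin_values(x[, f], breaks[[f]]))
  nbins <- vapply(breaks, function(b) length(b) + 1L, integer(1))

  parents <- stats::setNames(rep(list(character(0)), length(feats)), feats)
  node_score <- function(f, par) {
    pc <- parent_config(binned, par, nbins)
    bn_family_score(binned[, f], nbins[[f]], ci, K, pc$idx, pc$size, alpha)
  }
  if (max_parents > 0 && length(feats) > 1) {
    scores <- vapply(feats, function(f) node_score(f, character(0)), numeric(1))
    repeat {
      best <- NULL
      best_gain <- 1e-9
      for (i in feats) {
        if (length(parents[[i]]) >= max_parents) next
        for (j in setdiff(feats, c(i, parents[[i]]))) {
          if (creates_cycle(parents, from = j, to = i)) next
          gain <- node_score(i, c(parents[[i]], j)) - scores[[i]]
          if (gain > best_gain) {
            best <- c(i, j)
            best_gain <- gain
          }
        }
      }
      if (is.null(best)) break
      i <- best[1L]; j <- best[2L]
      parents[[i]] <- c(parents[[i]], j)
      scores[[i]] <- node_score(i, parents[[i]])
    }
  }

  # CPT for node f: array [bin_f, class, parent config], smoothed ML
  cpt <- lapply(feats, function(f) {
    par <- parents[[f]]
    pc <- parent_config(binned, par, nbins)
    r <- nbins[[f]]
    counts <- table(factor(binned[, f], levels = seq_len(r)),
                    factor(ci, levels = seq_len(K)),
                    factor(pc$idx, levels = seq_len(pc$size)))
    counts <- unclass(counts)
    tot <- apply(counts, c(2, 3), sum)
    p <- counts + alpha
    for (k in seq_len(K)) for (b in seq_len(pc$size)) {
      p[, k, b] <- p[, k, b] / (tot[k, b] + alpha * r)
    }
    p
  })
  names(cpt) <- feats

  structure(list(type = "discrete",
                 classes = classes,
                 features = feats,
                 priors = smoothed_priors(y, classes, alpha),
                 breaks = breaks,
                 nbins = nbins,
                 parents = parents,
                 cpt = cpt,
                 alpha = alpha,
                 bins = bins),
            class = "bayes_net_model")
}

#' @export
print.bayes_net_model <- function(x, ...) {
  edges <- sum(lengths(x$parents))
  cat(sprintf("<bayes_net_model> %s, %d classes, %d features, %d feature edge%s\n",
              if (x$type == "gaussian") "Gaussian naive Bayes"
              else "discretized Bayes network",
              length(x$classes), length(x$features), edges,
              if (edges == 1) "" else "s"))
  invisible(x)
}

#' Log joint probabilities for a batch of instances
#'
#' Returns the unnormalised per-class log joint
#' `log P(class) + sum_i log P(x_i | pa(x_i))` for each row of `x`; the
#' posterior of a row is the softmax of its log joints.  Computation is in
#' log space throughout -- a 200-sample window in the 9-feature set
#' multiplies 1800 factors, far beyond double-precision underflow in linear
#' space.
#'
#' @param model A `bayes_net_model`.
#' @param x Numeric matrix (or single named vector) of instances; columns
#'   must include all model features.
#' @return Numeric matrix, rows as in `x`, one named column per class.
#' @export
log_joint <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) {
    stop(sprintf("schema error: instance is missing feature(s) %s",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(x)
  K <- length(model$classes)
  lp <- matrix(rep(log(model$priors), each = n), n, K,
               dimnames = list(NULL, model$classes))
  if (model$type == "gaussian") {
    for (f in model$features) {
      for (k in seq_len(K)) {
        lp[, k] <- lp[, k] + stats::dnorm(x[, f], model$mu[k, f],
                                          model$sd[k, f], log = TRUE)
      }
    }
  } else {
    binned <- sapply(model$features,
                     function(f) bin_values(x[, f], model$breaks[[f]]))
    if (n == 1L) binned <- matrix(binned, nrow = 1,
                                  dimnames = list(NULL, model$features))
    for (f in model$features) {
      tab <- log(model$cpt[[f]])
      pc <- parent_config(binned, model$parents[[f]], model$nbins)
      for (k in seq_len(K)) {
        lp[, k] <- lp[, k] + tab[cbind(binned[, f], k, pc$idx)]
      }
    }
  }
  lp
}

#' Posterior class probabilities for one instance
#'
#' Normalised posterior over the activity classes for a single feature
#' vector, computed in log space from the model's factorised joint.
#'
#' @param model A `bayes_net_model`.
#' @param v Named numeric feature vector whose names cover the model's
#'   features.
#' @return Named numeric vector of posterior probabilities summing to 1.
#' @export
classify_instance <- function(model, v) {
  lp <- log_joint(model, v)[1L, ]
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Classify a sliding window
#'
#' Aggregates per-sample evidence over one fixed-width window into a single
#' activity label.  Two rules are provided:
#' * `"mean_log_posterior"` (default): argmax of the window-averaged
#'   per-class log joint -- the decision of a model that treats the window's
#'   samples as repeated evidence;
#' * `"majority"`: modal per-sample argmax label.
#'
#' All ties break towards a fall class first (in a safety application a tie
#' must alarm), then lexicographically.
#'
#' @param model A `bayes_net_model`.
#' @param window An `imu_window` from [slide()], or a bare feature matrix.
#' @param rule Aggregation rule.
#' @return A single class label.
#' @export
classify_window <- function(model, window,
                            rule = c("mean_log_posterior", "majority")) {
  rule <- match.arg(rule)
  m <- if (inherits(window, "imu_window")) window$elements else as.matrix(window)
  if (is.null(m) || nrow(m) == 0L) stop("empty window: nothing to classify")
  lp <- log_joint(model, m)
  if (rule == "mean_log_posterior") {
    argmax_label(colMeans(lp))
  } else {
    votes <- apply(lp, 1L, argmax_label)
    counts <- table(votes)
    argmax_label(stats::setNames(as.numeric(counts), names(counts)))
  }
}

#' @export
predict.bayes_net_model <- function(object, newdata,
                                    type = c("class", "posterior", "log"),
                                    ...) {
  type <- match.arg(type)
  lp <- log_joint(object, newdata)
  switch(type,
         log = lp,
         posterior = t(apply(lp, 1L, function(r) {
           p <- exp(r - max(r)); p / sum(p)
         })),
         class = apply(lp, 1L, argmax_label))
}

#' Serialise / load a classifier model
#'
#' Writes a `bayes_net_model` as versioned structured YAML text (graph, bin
#' edges, CPTs, priors) and reads it back.
#'
#' @param model A `bayes_net_model`.
#' @param path File path.
#' @return `write_bayes_model()` returns `path` invisibly;
#'   `read_bayes_model()` returns the model.
#' @export
write_bayes_model <- function(model, path) {
  obj <- unclass(model)
  obj$format <- "imufall-bayes-model"
  obj$version <- 1L
  if (!is.null(obj$mu)) obj$mu <- matrix_to_list(obj$mu)
  if (!is.null(obj$sd)) obj$sd <- matrix_to_list(obj$sd)
  if (!is.null(obj$cpt)) {
    obj$cpt <- lapply(obj$cpt, function(a) {
      list(dim = dim(a), values = as.numeric(a))
    })
  }
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_bayes_model
#' @export
read_bayes_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "imufall-bayes-model")) {
    stop("not an imufall model file")
  }
  obj$format <- NULL; obj$version <- NULL
  obj$classes <- as.character(obj$classes)
  obj$features <- as.character(obj$features)
  obj$priors <- stats::setNames(as.numeric(obj$priors), obj$classes)
  obj$parents <- lapply(obj$parents, as.character)
  if (!is.null(obj$mu)) obj$mu <- list_to_matrix(obj$mu, obj$classes, obj$features)
  if (!is.null(obj$sd)) obj$sd <- list_to_matrix(obj$sd, obj$classes, obj$features)
  if (!is.null(obj$breaks)) obj$breaks <- lapply(obj$breaks, as.numeric)
  if (!is.null(obj$nbins)) {
    obj$nbins <- stats::setNames(as.integer(obj$nbins), obj$features)
  }
  if (!is.null(obj$cpt)) {
    obj$cpt <- lapply(obj$cpt, function(e) {
      array(as.numeric(e$values), dim = as.integer(e$dim))
    })
  }
  structure(obj, class = "bayes_net_model")
}

# ---- internal helpers -------------------------------------------------------

check_training_set <- function(x, y) {
  if (is.null(colnames(x))) stop("training matrix must have named feature columns")
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  tab <- table(y)
  if (length(tab) < 2L) {
    stop("degenerate training set: at least 2 classes are required")
  }
  if (any(tab < 2L)) {
    stop("degenerate training set: every class needs at least 2 instances")
  }
  invisible(NULL)
}

smoothed_priors <- function(y, classes, alpha) {
  n <- table(factor(y, levels = classes))
  p <- (as.numeric(n) + alpha) / (length(y) + alpha * length(classes))
  stats::setNames(p, classes)
}

# Equal-frequency bin edges: inner break points from training quantiles.
# Ties can merge bins; at least one break always remains for non-constant
# input (constant features collapse to a single bin).
equal_frequency_breaks <- function(v, bins) {
  qs <- stats::quantile(v, probs = seq_len(bins - 1L) / bins,
                        names = FALSE, type = 7)
  unique(qs)
}

# Bin assignment in 1..(length(breaks) + 1); out-of-range values land in the
# nearest edge bin by construction of findInterval.
bin_values <- function(v, breaks) {
  findInterval(v, breaks) + 1L
}

# Combined 1-based parent-configuration index over zero or more discretized
# feature parents; `size` is the number of joint parent configurations.
parent_config <- function(binned, par, nbins) {
  n <- if (is.null(dim(binned))) length(binned) else nrow(binned)
  idx <- rep(1L, n)
  size <- 1L
  for (p in par) {
    idx <- idx + size * (binned[, p] - 1L)
    size <- size * nbins[[p]]
  }
  list(idx = idx, size = size)
}

# Decomposable Bayesian (Dirichlet-marginal) family score for one feature
# node given the class index and a combined feature-parent configuration.
bn_family_score <- function(child, r, class_index, K, parent_idx, pr, alpha) {
  config <- class_index + K * (parent_idx - 1L)
  n_config <- K * pr
  cell <- child + r * (config - 1L)
  N <- tabulate(cell, nbins = r * n_config)
  Nc <- tabulate(config, nbins = n_config)
  sum(lgamma(r * alpha) - lgamma(Nc + r * alpha)) +
    sum(lgamma(N + alpha) - lgamma(alpha))
}

# Would adding edge from -> to create a directed cycle among feature nodes?
creates_cycle <- function(parents, from, to) {
  # cycle iff `to` is already an ancestor of `from`
  seen <- character(0)
  frontier <- from
  while (length(frontier)) {
    node <- frontier[1L]
    frontier <- frontier[-1L]
    if (node == to) return(TRUE)
    if (node %in% seen) next
    seen <- c(seen, node)
    frontier <- c(frontier, parents[[node]])
  }
  FALSE
}

# Argmax with deterministic safety-first tie-breaking: fall classes win ties,
# then lexicographic order.
argmax_label <- function(scores) {
  labs <- names(scores)
  top <- labs[scores >= max(scores) - 1e-12]
  falls <- intersect(sort(top), fall_classes())
  if (length(falls)) falls[1L] else sort(top)[1L]
}

matrix_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = as.numeric(m))
}

list_to_matrix <- function(l, rows, cols) {
  matrix(as.numeric(l$values), nrow = length(rows),
         dimnames = list(rows, cols))
}
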