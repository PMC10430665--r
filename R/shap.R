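## Shapley additive attributions for the random-forest classifier.
##
## Implements the polynomial-time TreeSHAP recursion (path-dependent
## feature perturbation). Node covers are the bootstrap (in-bag) training
## weights routed through each tree, so the conditional expectations match
## the data each tree was grown on. Local accuracy holds by construction:
## base_value + sum(attributions) equals the model's predicted class
## probability for every sample.

# ---- tree extraction -------------------------------------------------------

# Convert one randomForest tree into parallel arrays with covers and
# 0/1 leaf values for the requested class.
extract_tree <- function(model, k, class = "agonist") {
  rf <- model$forest
  tr <- randomForest::getTree(rf, k, labelVar = FALSE)
  cls_ix <- match(class, model$classes)
  leaf <- tr[, "status"] == -1
  value <- ifelse(leaf, as.numeric(tr[, "prediction"] == cls_ix), 0)
  x <- model$training$x
  w <- rf$inbag[, k]
  cover <- numeric(nrow(tr))
  feat <- tr[, "split var"]
  thr <- tr[, "split point"]
  left <- tr[, "left daughter"]; right <- tr[, "right daughter"]
  for (r in which(w > 0)) {
    node <- 1L
    repeat {
      cover[node] <- cover[node] + w[r]
      if (leaf[node]) break
      node <- if (x[r, feat[node]] <= thr[node]) left[node] else right[node]
    }
  }
  list(left = left, right = right, feature = feat, threshold = thr,
       leaf = leaf, value = value, cover = cover)
}

# ---- the TreeSHAP recursion ------------------------------------------------

shap_extend <- function(m, pz, po, pi) {
  l <- length(m$w)
  m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0) 1 else 0)
  if (l > 0) for (i in l:1) {
    m$w[i + 1] <- m$w[i + 1] + po * m$w[i] * i / (l + 1)
    m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
  }
  m
}

shap_unwind <- function(m, i) {
  l <- length(m$w)
  n <- m$w[l]
  oi <- m$o[i]; zi <- m$z[i]
  for (j in (l - 1):1) {
    if (oi != 0) {
      t <- m$w[j]
      m$w[j] <- n * l / (j * oi)
      n <- t - m$w[j] * zi * (l - j) / l
    } else {
      m$w[j] <- m$w[j] * l / (zi * (l - j))
    }
  }
  keep <- setdiff(seq_len(l), i)
  # entry i leaves the path; weights stay positional by depth
  m$d <- m$d[keep]; m$z <- m$z[keep]; m$o <- m$o[keep]
  m$w <- m$w[seq_len(l - 1)]
  m
}

tree_shap_one <- function(tree, x, n_features) {
  phi <- numeric(n_features)
  recurse <- function(j, m, pz, po, pi) {
    m <- shap_extend(m, pz, po, pi)
    if (tree$leaf[j]) {
      l <- length(m$w)
      if (l >= 2) for (i in 2:l) {
        um <- shap_unwind(m, i)
        phi[m$d[i]] <<- phi[m$d[i]] + sum(um$w) * (m$o[i] - m$z[i]) * tree$value[j]
      }
    } else {
      f <- tree$feature[j]
      goleft <- x[f] <= tree$threshold[j]
      hot <- if (goleft) tree$left[j] else tree$right[j]
      cold <- if (goleft) tree$right[j] else tree$left[j]
      iz <- 1; io <- 1
      k <- match(f, m$d[-1])
      if (!is.na(k)) {
        k <- k + 1L
        iz <- m$z[k]; io <- m$o[k]
        m <- shap_unwind(m, k)
      }
      rj <- tree$cover[j]
      recurse(hot, m, iz * tree$cover[hot] / rj, io, f)
      recurse(cold, m, iz * tree$cover[cold] / rj, 0, f)
    }
  }
  recurse(1L, list(d = numeric(0), z = numeric(0), o = numeric(0), w = numeric(0)),
          1, 1, 0)
  phi
}

tree_expected_value <- function(tree) {
  lv <- which(tree$leaf)
  sum(tree$value[lv] * tree$cover[lv]) / sum(tree$cover[lv])
}

# ---- public surface --------------------------------------------------------

#' TreeSHAP feature attributions for the forest
#'
#' Per-sample signed attributions toward the predicted probability of
#' `class` (default `"agonist"`, matching the convention of plotting the
#' impact toward the agonist call). For every sample,
#' `base_value + sum(attributions)` reproduces the model probability to
#' machine precision.
#'
#' @param model a trained [train_rf()] classifier (tree ensembles only).
#' @param samples feature matrix of the samples to explain.
#' @param class class whose probability is attributed.
#' @return list of class `attribution_report`: `attributions`
#'   (samples x features), `base_value`, `feature_names`, `prediction`.
#' @export
shap_attributions <- function(model, samples, class = "agonist") {
  if (!inherits(model, "rf_ligand_classifier"))
    stop_fmt("unsupported model: SHAP attribution requires a tree ensemble")
  samples <- as.matrix(samples)
  if (ncol(samples) != length(model$feature_names))
    stop_fmt("feature length mismatch: model has %d, data has %d",
             length(model$feature_names), ncol(samples))
  p <- ncol(samples)
  ntree <- model$forest$ntree
  trees <- lapply(seq_len(ntree), function(k) extract_tree(model, k, class))
  base <- mean(vapply(trees, tree_expected_value, 0))
  phi <- matrix(0, nrow(samples), p,
                dimnames = list(rownames(samples), model$feature_names))
  for (s in seq_len(nrow(samples))) {
    acc <- numeric(p)
    for (tk in trees) acc <- acc + tree_shap_one(tk, samples[s, ], p)
    phi[s, ] <- acc / ntree
  }
  structure(list(attributions = phi, base_value = base,
                 feature_names = model$feature_names,
                 prediction = predict(model, samples, class = class),
                 class = class),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d samples x %d features toward '%s' (base %.4f)\n",
              nrow(x$attributions), ncol(x$attributions), x$class, x$base_value))
  invisible(x)
}

#' Global attribution summary
#'
#' @param object an `attribution_report`.
#' @param ... unused.
#' @return data.frame ranked by mean absolute attribution, with the
#'   fraction of samples sharing the majority attribution sign.
#' @export
summary.attribution_report <- function(object, ...) {
  a <- object$attributions
  mean_abs <- colMeans(abs(a))
  sign_consistency <- apply(a, 2, function(v) {
    nz <- v[v != 0]
    if (!length(nz)) return(1)
    max(mean(nz > 0), mean(nz < 0))
  })
  out <- data.frame(feature = colnames(a), mean_abs_attribution = mean_abs,
                    sign_consistency = sign_consistency, row.names = NULL)
  out[order(-out$mean_abs_attribution), ]
}
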