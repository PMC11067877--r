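# Three-hidden-layer feed-forward classifier over intron classes
# (NCI / CIR / LIR), with pairwise AUROC/AUPRC evaluation and permutation
# feature importance.

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(y, classes) {
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), match(y, classes))] <- 1
  m
}

# stratified train/val/test indices
stratified_split <- function(y, split) {
  idx <- list(train = integer(), val = integer(), test = integer())
  for (cl in unique(y)) {
    rows <- sample(which(y == cl))
    n <- length(rows)
    n_tr <- round(split[1] * n)
    n_va <- round(split[2] * n)
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$val <- c(idx$val, rows[n_tr + seq_len(min(n_va, n - n_tr))])
    idx$test <- c(idx$test, rows[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  idx
}

#' Train the intron-class neural network
#'
#' Feed-forward network with three hidden layers (default 64/32/16,
#' rectified-linear activations) and a softmax output over the classes,
#' trained with mini-batch Adam on a weighted cross-entropy loss
#' (inverse-class-frequency weights). Features are standardised with the
#' training-split mean and standard deviation only. Given the same seed and
#' data the fit is bit-identical.
#'
#' @param data Tibble with a `label` column plus numeric feature columns
#'   (non-numeric columns other than `label` are ignored).
#' @param hidden Hidden layer sizes (default `c(64, 32, 16)`).
#' @param epochs Training epochs (default 150).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param l2 L2 penalty on weights (default 1e-4).
#' @param split Train/validation/test fractions, stratified by class
#'   (default `c(0.7, 0.15, 0.15)`).
#' @param seed RNG seed controlling split, initialisation and batching.
#' @return Object of class `eicir_nn`: weights, standardisation parameters,
#'   classes, the three data splits and the training history.
#' @export
train_classifier <- function(data, hidden = c(64L, 32L, 16L), epochs = 150L,
                             lr = 1e-3, batch_size = 64L, l2 = 1e-4,
                             split = c(0.7, 0.15, 0.15), seed = 1L) {
  if (!"label" %in% names(data)) abort("data needs a 'label' column")
  classes <- sort(unique(as.character(data$label)))
  if (length(classes) < 2) abort("need at least 2 classes to train")
  feat_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  feat_cols <- setdiff(feat_cols, "label")
  if (length(feat_cols) == 0) abort("no numeric feature columns")
  if (anyNA(data[feat_cols])) abort("missing feature values")

  set.seed(seed)
  y <- as.character(data$label)
  idx <- stratified_split(y, split)
  X <- as.matrix(data[feat_cols])
  mu <- colMeans(X[idx$train, , drop = FALSE])
  sdev <- apply(X[idx$train, , drop = FALSE], 2, sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  std <- function(m) sweep(sweep(m, 2, mu), 2, sdev, "/")

  Xtr <- std(X[idx$train, , drop = FALSE])
  ytr <- y[idx$train]
  Ytr <- one_hot(ytr, classes)
  freq <- table(factor(ytr, levels = classes))
  cw <- as.numeric(length(ytr) / (length(classes) * freq))
  wtr <- cw[match(ytr, classes)]

  sizes <- c(ncol(Xtr), hidden, length(classes))
  W <- map(seq_len(length(sizes) - 1), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])
  })
  b <- map(seq_len(length(sizes) - 1), ~ rep(0, sizes[.x + 1]))
  mW <- map(W, ~ .x * 0); vW <- map(W, ~ .x * 0)
  mb <- map(b, ~ .x * 0); vb <- map(b, ~ .x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  L <- length(W)
  n <- nrow(Xtr)
  t_step <- 0
  history <- numeric(epochs)

  forward <- function(Xb) {
    A <- vector("list", L + 1)
    A[[1]] <- Xb
    for (l in seq_len(L - 1)) A[[l + 1]] <- relu(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
    A[[L + 1]] <- softmax(sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+"))
    A
  }

  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (s in seq(1, n, by = batch_size)) {
      rows <- ord[s:min(s + batch_size - 1, n)]
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- Ytr[rows, , drop = FALSE]
      wb <- wtr[rows]
      A <- forward(Xb)
      P <- A[[L + 1]]
      delta <- (P - Yb) * wb / length(rows)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t_step)) /
          (sqrt(vW[[l]] / (1 - beta2^t_step)) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t_step)) /
          (sqrt(vb[[l]] / (1 - beta2^t_step)) + eps)
      }
    }
    P <- forward(Xtr)[[L + 1]]
    history[ep] <- -mean(wtr * log(P[cbind(seq_len(n), match(ytr, classes))] + 1e-12))
  }

  structure(
    list(W = W, b = b, classes = classes, features = feat_cols,
         mu = mu, sd = sdev, hidden = hidden, seed = seed,
         history = history,
         data = list(train = data[idx$train, ], val = data[idx$val, ],
                     test = data[idx$test, ])),
    class = "eicir_nn"
  )
}

#' Predict class probabilities
#'
#' @param object An `eicir_nn` model.
#' @param newdata Tibble with the model's feature columns.
#' @param ... Unused.
#' @return Matrix of softmax probabilities (columns = classes).
#' @export
predict.eicir_nn <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  X <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  A <- X
  L <- length(object$W)
  for (l in seq_len(L - 1)) {
    A <- relu(sweep(A %*% object$W[[l]], 2, object$b[[l]], "+"))
  }
  P <- softmax(sweep(A %*% object$W[[L]], 2, object$b[[L]], "+"))
  colnames(P) <- object$classes
  P
}

#' @export
print.eicir_nn <- function(x, ...) {
  cat(sprintf("<eicir_nn> %d features -> %s -> %d classes (%s); %d train rows\n",
              length(x$features), paste(x$hidden, collapse = "/"),
              length(x$classes), paste(x$classes, collapse = ","),
              nrow(x$data$train)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param score Numeric classifier scores.
#' @param label Logical or 0/1 vector, `TRUE` = positive.
#' @return AUROC in `[0, 1]`, `NA` if a class is absent.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: precision summed at each positive in decreasing-score
#' order, divided by the number of positives.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, `NA` if no positives.
#' @export
auprc <- function(score, label) {
  label <- as.logical(label)
  if (sum(label) == 0 || sum(!label) == 0) return(NA_real_)
  ord <- order(-score, label)  # ties: negatives first (conservative)
  lab <- label[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

pair_score <- function(P, pos, neg) {
  P[, pos] / (P[, pos] + P[, neg])
}

#' Evaluate the intron classifier
#'
#' Pairwise one-vs-one AUROC and AUPRC on held-out data for every class
#' pair, using the renormalised softmax score of the positive (second)
#' class, plus permutation feature importance: the mean AUROC drop over
#' `n_permutations` shuffles of each feature, signed by the point-biserial
#' correlation between the feature and the positive class.
#'
#' @param model An `eicir_nn` model.
#' @param data Evaluation tibble with `label`; defaults to the model's
#'   held-out test split.
#' @param n_permutations Shuffles per feature (default 20).
#' @param seed RNG seed for the shuffles.
#' @return Object of class `eicir_eval`: tibbles `pairwise` (pair, auroc,
#'   auprc, n), `importance` (pair, feature, auroc_drop, sign,
#'   association) and `curves` (ROC/PR points for plotting).
#' @export
evaluate <- function(model, data = NULL, n_permutations = 20L, seed = 1L) {
  data <- data %||% model$data$test
  y <- as.character(data$label)
  cls <- model$classes
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  set.seed(seed)
  pw <- list(); imp <- list(); curves <- list()
  for (p in pairs) {
    neg <- p[1]; pos <- p[2]
    pair_name <- paste0(neg, "_vs_", pos)
    rows <- which(y %in% p)
    if (sum(y[rows] == pos) < 2 || sum(y[rows] == neg) < 2) {
      pw[[pair_name]] <- tibble(pair = pair_name, positive = pos,
                                auroc = NA_real_, auprc = NA_real_,
                                n = length(rows))
      next
    }
    sub <- data[rows, ]
    lab <- y[rows] == pos
    sc <- pair_score(predict(model, sub), pos, neg)
    pw[[pair_name]] <- tibble(pair = pair_name, positive = pos,
                              auroc = auroc(sc, lab), auprc = auprc(sc, lab),
                              n = length(rows))
    ord <- order(-sc)
    curves[[pair_name]] <- tibble(
      pair = pair_name,
      fpr = cumsum(!lab[ord]) / sum(!lab),
      tpr = cumsum(lab[ord]) / sum(lab),
      precision = cumsum(lab[ord]) / seq_along(ord),
      recall = cumsum(lab[ord]) / sum(lab)
    )
    base <- auroc(sc, lab)
    imp[[pair_name]] <- bind_rows(map(model$features, function(f) {
      drops <- map_dbl(seq_len(n_permutations), function(k) {
        shuf <- sub
        shuf[[f]] <- sample(shuf[[f]])
        base - auroc(pair_score(predict(model, shuf), pos, neg), lab)
      })
      assoc <- suppressWarnings(cor(sub[[f]], as.numeric(lab)))
      tibble(pair = pair_name, feature = f, auroc_drop = mean(drops),
             sign = ifelse(is.na(assoc), 0, sign(assoc)),
             association = assoc)
    }))
  }
  structure(list(pairwise = bind_rows(pw), importance = bind_rows(imp),
                 curves = bind_rows(curves)),
            class = "eicir_eval")
}

#' @export
print.eicir_eval <- function(x, ...) {
  cat("<eicir_eval> pairwise performance:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' Tidy a classifier evaluation
#'
#' @param x An `eicir_eval` object.
#' @param ... Unused.
#' @return The pairwise AUROC/AUPRC tibble.
#' @export
tidy.eicir_eval <- function(x, ...) x$pairwise

#' Tidy an intron-class neural network
#'
#' @param x An `eicir_nn` model.
#' @param ... Unused.
#' @return One row per feature with the standardisation parameters and the
#'   L2 norm of the feature's first-layer weights.
#' @export
tidy.eicir_nn <- function(x, ...) {
  tibble(feature = x$features, mean = unname(x$mu), sd = unname(x$sd),
         input_weight_norm = sqrt(rowSums(x$W[[1]]^2)))
}

#' Glance at an intron-class neural network
#'
#' @param x An `eicir_nn` model.
#' @param ... Unused.
#' @return One-row tibble with data sizes, architecture and final training
#'   loss.
#' @export
glance.eicir_nn <- function(x, ...) {
  tibble(n_train = nrow(x$data$train), n_val = nrow(x$data$val),
         n_test = nrow(x$data$test), n_features = length(x$features),
         n_classes = length(x$classes),
         hidden = paste(x$hidden, collapse = "/"),
         epochs = length(x$history),
         final_loss = tail(x$history, 1), seed = x$seed)
}

#' Serialise a trained classifier to a portable JSON file
#'
#' @param model An `eicir_nn` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  payload <- list(
    format = "eicir_nn", version = 1L,
    classes = model$classes, features = model$features,
    hidden = model$hidden, seed = model$seed,
    mu = unname(model$mu), sd = unname(model$sd),
    W = map(model$W, ~ unname(as.matrix(.x))), b = map(model$b, unname)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier written by [write_classifier()]
#'
#' @param path Path to the JSON model file.
#' @return An `eicir_nn` model (without training-data splits).
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "eicir_nn")) abort("not an eicir_nn model file")
  structure(
    list(W = map(p$W, as.matrix), b = map(p$b, as.numeric),
         classes = p$classes, features = p$features,
         mu = setNames(p$mu, p$features), sd = setNames(p$sd, p$features),
         hidden = p$hidden, seed = p$seed, history = numeric(),
         data = list(train = tibble(), val = tibble(), test = tibble())),
    class = "eicir_nn"
  )
}
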