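# Shallow-network regression of per-SE mean community size on the feature
# table, with replicate training rounds and feature-subset ablation. The
# network is deliberately small -- one hidden layer of 10 logistic units,
# linear output, mild L2 -- to avoid overtraining on a few hundred rows;
# it is trained by BFGS with analytic gradients (no external NN dependency).

#' Predictor configuration
#'
#' @param hidden_nodes hidden-layer width, default 10.
#' @param n_replicates replicate training rounds (fresh random split each),
#'   default 100.
#' @param holdout_fraction fraction of rows held out per replicate,
#'   default 0.25.
#' @param standardize center/scale features using training rows only,
#'   default TRUE.
#' @param seed base RNG seed; replicate k uses `seed + k`.
#' @param l2 L2 penalty on non-bias weights, default 1e-4.
#' @param maxit BFGS iteration cap per fit, default 400.
#' @return list of class `predictor_config`.
#' @export
predictor_config <- function(hidden_nodes = 10L, n_replicates = 100L,
                             holdout_fraction = 0.25, standardize = TRUE,
                             seed = 1L, l2 = 1e-4, maxit = 400L) {
  stopifnot(hidden_nodes >= 1, holdout_fraction > 0, holdout_fraction < 1)
  structure(as.list(environment()), class = "predictor_config")
}

# one network fit: returns a predict() closure
.mlp_train <- function(X, y, hidden, l2, maxit) {
  n <- nrow(X); p <- ncol(X)
  n_w1 <- (p + 1L) * hidden
  n_w2 <- hidden + 1L
  unpack <- function(theta) {
    list(W1 = matrix(theta[seq_len(n_w1)], p + 1L, hidden),
         w2 = theta[n_w1 + seq_len(n_w2)])
  }
  Xb <- cbind(1, X)
  obj <- function(theta) {
    w <- unpack(theta)
    A <- plogis(Xb %*% w$W1)
    yhat <- cbind(1, A) %*% w$w2
    pen <- l2 * 0.5 * (sum(w$W1[-1, ]^2) + sum(w$w2[-1]^2))
    0.5 * mean((yhat - y)^2) + pen
  }
  grad <- function(theta) {
    w <- unpack(theta)
    A <- plogis(Xb %*% w$W1)
    Ab <- cbind(1, A)
    e <- (Ab %*% w$w2 - y) / n
    g2 <- as.numeric(crossprod(Ab, e))
    g2[-1] <- g2[-1] + l2 * w$w2[-1]
    dA <- (e %*% t(w$w2[-1])) * A * (1 - A)
    G1 <- crossprod(Xb, dA)
    G1[-1, ] <- G1[-1, ] + l2 * w$W1[-1, ]
    c(as.numeric(G1), g2)
  }
  theta0 <- rnorm(n_w1 + n_w2, sd = 0.5)
  fit <- optim(theta0, obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  w <- unpack(fit$par)
  function(Xnew) as.numeric(cbind(1, plogis(cbind(1, Xnew) %*% w$W1)) %*% w$w2)
}

.as_feature_matrix <- function(features, columns = NULL) {
  ft <- as.data.table(features)
  num <- names(ft)[vapply(ft, is.numeric, TRUE)]
  if (is.null(columns)) columns <- num
  unknown <- setdiff(columns, names(ft))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  not_num <- setdiff(columns, num)
  if (length(not_num))
    stop("non-numeric feature(s): ", paste(not_num, collapse = ", "))
  m <- as.matrix(ft[, ..columns])
  if (anyNA(m)) stop("missing feature values; impute before training")
  m
}

#' Train the community-size regressor with replicate rounds
#'
#' Per replicate: a fresh random 75/25 train/holdout split, feature
#' standardization fit on the training rows only, one shallow-network fit,
#' and held-out Pearson r and RMSE. The report averages across replicates;
#' everything is reproducible from the config seed.
#'
#' @param features per-row feature table (numeric columns are used; pass
#'   `columns` to restrict).
#' @param target numeric response (e.g. per-SE mean community size, in SEs
#'   per community), one per row.
#' @param config `predictor_config`.
#' @param columns optional character vector of feature columns.
#' @return list of class `prediction_report`: `replicates` (data.table
#'   replicate, r, rmse), `mean_r`, `mean_rmse`, `sd_r`, `sd_rmse`,
#'   `features`.
#' @export
train_predictor <- function(features, target, config = predictor_config(),
                            columns = NULL) {
  X <- .as_feature_matrix(features, columns)
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 40L) stop("need at least 40 rows")
  if (sd(y) == 0) stop("constant target: correlation undefined")
  n <- nrow(X)
  n_hold <- max(1L, floor(config$holdout_fraction * n))
  res <- vector("list", config$n_replicates)
  for (k in seq_len(config$n_replicates)) {
    set.seed(config$seed + k)
    hold <- sample.int(n, n_hold)
    tr <- setdiff(seq_len(n), hold)
    Xtr <- X[tr, , drop = FALSE]; Xho <- X[hold, , drop = FALSE]
    if (config$standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2L, sd); sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sg, "/")
      Xho <- sweep(sweep(Xho, 2L, mu), 2L, sg, "/")
    }
    predict_fn <- .mlp_train(Xtr, y[tr], config$hidden_nodes, config$l2,
                             config$maxit)
    yhat <- predict_fn(Xho)
    r <- if (sd(yhat) == 0) 0 else cor(yhat, y[hold])
    res[[k]] <- data.table(replicate = k, r = r,
                           rmse = sqrt(mean((yhat - y[hold])^2)))
  }
  reps <- rbindlist(res)
  structure(list(replicates = reps[], mean_r = mean(reps$r),
                 mean_rmse = mean(reps$rmse), sd_r = sd(reps$r),
                 sd_rmse = sd(reps$rmse),
                 features = colnames(X)), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d replicates, %d features: mean r = %.3f (sd %.3f), mean RMSE = %.3f (sd %.3f)\n",
              nrow(x$replicates), length(x$features), x$mean_r, x$sd_r,
              x$mean_rmse, x$sd_rmse))
  invisible(x)
}

#' Feature-subset ablation
#'
#' Trains identical networks on named feature subsets with the same
#' protocol (and seed), quantifying the contribution of each predictor
#' group. Typical subsets: general transcription machinery (pol2 + med1),
#' pluripotency TFs (oct4 + sox2 + nanog), nuclear positioning
#' (speckle + LAD), linear genome separation (n_se_1mb + inv_dist_sum),
#' and all features.
#'
#' @param features feature table.
#' @param target numeric response per row.
#' @param subsets named list of character vectors of feature columns.
#' @param config `predictor_config`.
#' @return named list of `prediction_report`s.
#' @export
ablation <- function(features, target, subsets, config = predictor_config()) {
  stopifnot(length(subsets) > 0, !is.null(names(subsets)))
  if (any(lengths(subsets) == 0)) stop("empty feature subset")
  lapply(subsets, function(cols)
    train_predictor(features, target, config, columns = cols))
}
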