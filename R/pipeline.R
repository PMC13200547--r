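#' Read a genotype matrix from delimited text
#'
#' Expects comma- or tab-delimited text (the separator is sniffed from the
#' header line): a header row of marker ids, a first column of sample ids,
#' and numeric cells in `[0, 2]` (hard genotype calls 0/1/2 or imputed
#' dosages). Empty cells are resolved by `missing_policy`: `"error"`
#' (default) aborts, `"mean_impute"` substitutes the column mean computed
#' once from the observed values.
#'
#' @param path File path.
#' @param missing_policy `"error"` or `"mean_impute"`.
#' @return Numeric matrix with sample-id rownames and marker-id colnames.
#' @export
read_genotypes <- function(path, missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = 1L, colClasses = NA,
                          na.strings = c("", "NA"))
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric genotype cells in ", path)
  if (anyDuplicated(rownames(M))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(M))) stop("duplicate marker ids")
  if (anyNA(M)) {
    if (missing_policy == "error")
      stop("missing genotype cells (missing_policy = \"error\"); ",
           "first at row ", which(rowSums(is.na(M)) > 0)[1L])
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2L]]
  }
  bad <- which(M < 0 | M > 2, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("genotype value out of [0, 2] at row `", rownames(M)[bad[1L, 1L]],
         "`, column `", colnames(M)[bad[1L, 2L]], "`")
  M
}

#' Write a genotype matrix as delimited text
#'
#' @param G Matrix with sample-id rownames and marker-id colnames.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_genotypes <- function(G, path, sep = ",") {
  df <- data.frame(sample_id = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with a first column of sample ids and one column per
#' trait.
#'
#' @param path File path.
#' @return Numeric matrix (samples x traits) with sample-id rownames.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = 1L, na.strings = c("", "NA"))
  as.matrix(df)
}

#' Fit a leakage-safe standardizer on training data
#'
#' Per-feature means and sample standard deviations are estimated on the
#' training portion only; [apply_standardizer()] then applies the same
#' transform to any split. Zero-variance features are mapped to 0 (with a
#' warning at fit time).
#'
#' @param X Training matrix (samples x features).
#' @return An object of class `"standardizer"` with `center` and `scale`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    warning(sum(scl == 0), " zero-variance feature(s) mapped to 0")
    scl[scl == 0] <- Inf   # (x - mean) / Inf = 0
  }
  structure(list(center = ctr, scale = scl), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param sz A [fit_standardizer()] object.
#' @param X Matrix with the same feature count.
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(sz, X) {
  stopifnot(inherits(sz, "standardizer"))
  X <- as.matrix(X)
  if (ncol(X) != length(sz$center)) stop("feature count mismatch")
  sweep(sweep(X, 2L, sz$center), 2L, sz$scale, "/")
}

#' Cross-validation plan: repeated test split plus folds
#'
#' For each of `n_reps` repetitions (seeded `master_seed + r`), holds out
#' `test_frac` of the individuals as a test set and partitions the remaining
#' training individuals into `n_folds` folds of sizes differing by at most
#' one. Splits are always over individuals (rows), never over markers, and
#' the plan is deterministic given `(n, master_seed)` so that every method
#' and regularizer sees identical partitions within a repetition.
#'
#' @param n Number of individuals.
#' @param n_reps Number of repetitions (default 10).
#' @param n_folds Number of CV folds (default 5).
#' @param test_frac Held-out test fraction (default 0.2).
#' @param master_seed Integer master seed.
#' @return Object of class `"cv_plan"`: a list of repetitions, each with
#'   `seed`, `test` (indices), `train` (indices), and `folds` (list of
#'   index vectors partitioning `train`).
#' @export
make_cv_plan <- function(n, n_reps = 10L, n_folds = 5L, test_frac = 0.2,
                         master_seed = 1L) {
  n <- as.integer(n)
  n_test <- floor(n * test_frac)
  n_train <- n - n_test
  if (n_train < n_folds)
    stop("n too small: ", n_train, " training samples for ", n_folds, " folds")
  reps <- lapply(seq_len(n_reps), function(r) {
    seed_r <- as.integer(master_seed) + r
    with_seed(seed_r, {
      perm <- sample.int(n)
      test <- sort(perm[seq_len(n_test)])
      train <- sort(perm[(n_test + 1L):n])
      fold_id <- rep(seq_len(n_folds), length.out = n_train)
      fold_id <- sample(fold_id)
      folds <- lapply(seq_len(n_folds), function(f) train[fold_id == f])
      list(seed = seed_r, test = test, train = train, folds = folds)
    })
  })
  structure(list(n = n, n_reps = as.integer(n_reps),
                 n_folds = as.integer(n_folds), test_frac = test_frac,
                 master_seed = as.integer(master_seed), reps = reps),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("CV plan: ", x$n_reps, " repetitions, ", x$n_folds, " folds, ",
      sprintf("%.0f%%", 100 * x$test_frac), " test split of n = ", x$n,
      " (master seed ", x$master_seed, ")\n", sep = "")
  invisible(x)
}

#' Hyperparameter search space
#'
#' Defaults follow the protocol used throughout the package: learning rate
#' log-uniform on `[1e-4, 1e-2]`, penalty strength lambda log-uniform on
#' `[1e-3, 1e2]`, batch size from \{32, 64, 128\}, at most `max_evals`
#' evaluations, and early stopping once the improvement in the best
#' validation MSE is below `early_stop_tol` for `early_stop_rounds`
#' consecutive evaluations.
#'
#' @param lr_range,lambda_range Positive (low, high) intervals.
#' @param batch_sizes Integer vector of candidate batch sizes.
#' @param max_evals Maximum number of evaluations (default 100).
#' @param early_stop_tol Improvement threshold (default 1e-5).
#' @param early_stop_rounds Consecutive non-improving evaluations before
#'   stopping (default 5).
#' @return Object of class `"search_space"`.
#' @export
search_space <- function(lr_range = c(1e-4, 1e-2),
                         lambda_range = c(1e-3, 1e2),
                         batch_sizes = c(32L, 64L, 128L),
                         max_evals = 100L, early_stop_tol = 1e-5,
                         early_stop_rounds = 5L) {
  stopifnot(all(lr_range > 0), lr_range[1L] < lr_range[2L],
            all(lambda_range > 0), lambda_range[1L] < lambda_range[2L],
            max_evals >= 1L)
  structure(list(lr_range = lr_range, lambda_range = lambda_range,
                 batch_sizes = as.integer(batch_sizes),
                 max_evals = as.integer(max_evals),
                 early_stop_tol = early_stop_tol,
                 early_stop_rounds = as.integer(early_stop_rounds)),
            class = "search_space")
}

#' Hyperparameter search
#'
#' Minimizes `objective(config)` over the search space. The native backend
#' is seeded random search: learning rate and lambda are drawn log-uniformly
#' and the batch size uniformly from its candidate set. Evaluations stop at
#' `max_evals` or when the early-stop rule fires, whichever comes first. An
#' objective returning `NaN`/`NA` is recorded as `+Inf` and the search
#' continues. Alternative strategies (e.g. Bayesian optimization by a
#' tree-structured Parzen estimator) plug in through `backend` as a function
#' `function(space, objective, seed)` returning the same structure.
#'
#' @param space A [search_space()].
#' @param objective Function taking `list(lr =, lambda =, batch_size =)` and
#'   returning a validation MSE.
#' @param backend `"random"`, or a function implementing the same contract.
#' @param seed Integer seed making the search deterministic.
#' @return List with `best` (config), `best_score`, and `history`
#'   (data.frame of every evaluation).
#' @export
search_hyperparams <- function(space, objective, backend = "random",
                               seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (is.function(backend)) return(backend(space, objective, seed))
  if (identical(backend, "tpe"))
    stop("no TPE implementation is registered; pass a backend function ",
         "with signature function(space, objective, seed)")
  if (!identical(backend, "random")) stop("unknown backend")
  with_seed(seed, {
    history <- data.frame(eval = integer(0), lr = numeric(0),
                          lambda = numeric(0), batch_size = integer(0),
                          score = numeric(0))
    best_score <- Inf
    best <- NULL
    stall <- 0L
    for (i in seq_len(space$max_evals)) {
      cfg <- list(
        lr = exp(stats::runif(1, log(space$lr_range[1L]),
                              log(space$lr_range[2L]))),
        lambda = exp(stats::runif(1, log(space$lambda_range[1L]),
                                  log(space$lambda_range[2L]))),
        batch_size = sample(space$batch_sizes, 1L))
      sc <- objective(cfg)
      if (!is.finite(sc)) sc <- Inf
      history <- rbind(history,
                       data.frame(eval = i, lr = cfg$lr, lambda = cfg$lambda,
                                  batch_size = cfg$batch_size, score = sc))
      if (sc < best_score - space$early_stop_tol) {
        best_score <- sc
        best <- cfg
        stall <- 0L
      } else {
        if (sc < best_score) { best_score <- sc; best <- cfg }
        stall <- stall + 1L
        if (stall >= space$early_stop_rounds) break
      }
    }
    list(best = best, best_score = best_score, history = history)
  })
}

#' Run the full evaluation protocol on one dataset
#'
#' For every repetition of the CV plan and every requested method/penalty
#' combination: tunes hyperparameters on the CV folds (averaged validation
#' MSE), retrains on the full training split with the best configuration,
#' and evaluates test MSE, test distance correlation, and penalized-weight
#' sparsity. Standardization of markers (and the phenotype) is fit on each
#' repetition's training split only and applied to its test split. Each
#' regularized variant is compared against the unregularized baseline by the
#' exact Wilcoxon signed-rank test on the paired per-repetition test MSEs.
#'
#' This is the desk-scale reproduction harness of the full protocol; its
#' defaults (small `max_evals`, few epochs) keep it tractable on one CPU and
#' are all overridable.
#'
#' @param G Genotype matrix (samples x markers).
#' @param y Phenotype vector.
#' @param methods Subset of `"resnet"`, `"resnet_unregularized"`, `"pgdlm"`.
#' @param penalties Character vector of penalty kinds for the regularized
#'   methods.
#' @param depth ResNet depth.
#' @param plan A [make_cv_plan()]; defaults to a plan over `nrow(G)`.
#' @param space A [search_space()].
#' @param epochs Training epochs for network fits.
#' @param pgdlm_epochs Epochs for linear-model fits.
#' @param max_evals Search evaluations per tuning run (overrides `space`).
#' @param tune_folds How many of the folds to use while tuning (all by
#'   default; fewer is faster).
#' @param verbose Print per-stage progress to stderr.
#' @return Object of class `"genoprox_result"`: long-format `results`
#'   data.frame (one row per repetition x method x penalty), `wilcoxon`
#'   comparisons, and the aggregated `table`.
#' @export
run_experiment <- function(G, y, methods = c("resnet", "resnet_unregularized"),
                           penalties = "l1/2", depth = 5L, plan = NULL,
                           space = search_space(), epochs = 15L,
                           pgdlm_epochs = 200L, max_evals = 5L,
                           tune_folds = NULL, verbose = FALSE) {
  G <- as.matrix(G); y <- as.numeric(y)
  stopifnot(nrow(G) == length(y))
  if (stats::sd(y) == 0) stop("zero-variance phenotype")
  methods <- match.arg(methods, c("resnet", "resnet_unregularized", "pgdlm"),
                       several.ok = TRUE)
  if (is.null(plan)) plan <- make_cv_plan(nrow(G))
  space$max_evals <- as.integer(max_evals)
  rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  fit_eval <- function(method, pen_kind, rep_idx, rp) {
    sz <- fit_standardizer(G[rp$train, , drop = FALSE])
    Xtr <- apply_standardizer(sz, G[rp$train, , drop = FALSE])
    Xte <- apply_standardizer(sz, G[rp$test, , drop = FALSE])
    ysz <- fit_standardizer(matrix(y[rp$train], ncol = 1L))
    ytr <- as.vector(apply_standardizer(ysz, matrix(y[rp$train], ncol = 1L)))
    yte <- as.vector(apply_standardizer(ysz, matrix(y[rp$test], ncol = 1L)))
    row_of <- function(idx) match(idx, rp$train)
    folds <- if (is.null(tune_folds)) rp$folds
             else rp$folds[seq_len(min(tune_folds, length(rp$folds)))]
    tuned <- search_hyperparams(space, function(cfg) {
      val <- vapply(folds, function(fold) {
        tr <- setdiff(rp$train, fold)
        if (method == "pgdlm") {
          f <- pgdlm(Xtr[row_of(tr), , drop = FALSE], ytr[row_of(tr)],
                     penalty = pen_kind, lambda = cfg$lambda,
                     epochs = pgdlm_epochs)
          mse(ytr[row_of(fold)],
              predict(f, Xtr[row_of(fold), , drop = FALSE]))
        } else {
          f <- resnet1d(Xtr[row_of(tr), , drop = FALSE], ytr[row_of(tr)],
                        depth = depth,
                        penalty = if (method == "resnet") pen_kind else NULL,
                        lambda = if (method == "resnet") cfg$lambda else 0,
                        epochs = epochs, batch_size = cfg$batch_size,
                        alpha = cfg$lr, seed = rp$seed)
          mse(ytr[row_of(fold)],
              predict(f, Xtr[row_of(fold), , drop = FALSE]))
        }
      }, numeric(1L))
      mean(val)
    }, seed = rp$seed)
    cfg <- tuned$best
    if (method == "pgdlm") {
      fit <- pgdlm(Xtr, ytr, penalty = pen_kind, lambda = cfg$lambda,
                   epochs = pgdlm_epochs)
      pred <- predict(fit, Xte)
      zf <- sparsity(coef(fit))$zero_fraction
    } else {
      fit <- resnet1d(Xtr, ytr, depth = depth,
                      penalty = if (method == "resnet") pen_kind else NULL,
                      lambda = if (method == "resnet") cfg$lambda else 0,
                      epochs = epochs, batch_size = cfg$batch_size,
                      alpha = cfg$lr, seed = rp$seed)
      pred <- predict(fit, Xte)
      zf <- fit$zero_fraction
    }
    data.frame(rep = rep_idx, method = method,
               penalty = if (method == "resnet_unregularized") "-"
                         else pen_kind,
               test_mse = mse(yte, pred), test_dcor = dcor(pred, yte),
               zero_fraction = zf,
               lr = if (is.null(cfg$lr)) NA_real_ else cfg$lr,
               lambda = if (method == "resnet_unregularized") NA_real_
                        else cfg$lambda,
               batch_size = if (method == "pgdlm") NA_integer_
                            else cfg$batch_size)
  }

  for (r in seq_along(plan$reps)) {
    rp <- plan$reps[[r]]
    for (method in methods) {
      pens <- if (method == "resnet_unregularized") "-" else penalties
      for (pen in pens) {
        say("rep %d, %s, %s", r, method, pen)
        rows[[length(rows) + 1L]] <- fit_eval(method, pen, r, rp)
      }
    }
  }
  results <- do.call(rbind, rows)

  wil <- NULL
  if ("resnet_unregularized" %in% methods) {
    base <- results[results$method == "resnet_unregularized", ]
    base <- base[order(base$rep), ]
    cmp <- results[results$method != "resnet_unregularized", ]
    if (nrow(base) >= 2L && nrow(cmp) > 0L) {
      combos <- unique(cmp[, c("method", "penalty")])
      wil <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        sub <- cmp[cmp$method == combos$method[i] &
                   cmp$penalty == combos$penalty[i], ]
        sub <- sub[order(sub$rep), ]
        if (nrow(sub) != nrow(base) || !any(sub$test_mse != base$test_mse))
          return(NULL)
        wt <- wilcoxon_signed_rank_exact(sub$test_mse, base$test_mse)
        data.frame(method = combos$method[i], penalty = combos$penalty[i],
                   W = wt$statistic, p_value = wt$p_value, n = wt$n_used)
      }))
    }
  }

  agg_key <- interaction(results$method, results$penalty, drop = TRUE)
  tab <- do.call(rbind, lapply(split(results, agg_key), function(d) {
    data.frame(method = d$method[1L], penalty = d$penalty[1L],
               mse = format_mean_std(d$test_mse),
               dcor = format_mean_std(d$test_dcor),
               sparsity_pct = sprintf("%.2f", 100 * mean(d$zero_fraction)),
               n_reps = nrow(d))
  }))
  rownames(tab) <- NULL
  structure(list(results = results, wilcoxon = wil, table = tab,
                 plan = plan),
            class = "genoprox_result")
}

#' @export
print.genoprox_result <- function(x, ...) {
  cat("Evaluation over", x$plan$n_reps, "repetitions\n\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("\nExact Wilcoxon signed-rank vs unregularized baseline",
        "(paired test MSEs):\n")
    print(x$wilcoxon, row.names = FALSE)
  }
  invisible(x)
}

#' Write experiment reports to CSV
#'
#' Emits the per-repetition results, the aggregated mean (sd) table, and,
#' when present, the Wilcoxon comparisons as CSV files under `dir`.
#'
#' @param result A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "genoprox_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "results.csv"), file.path(dir, "summary.csv"))
  utils::write.csv(result$results, paths[1L], row.names = FALSE)
  utils::write.csv(result$table, paths[2L], row.names = FALSE)
  if (!is.null(result$wilcoxon)) {
    paths <- c(paths, file.path(dir, "wilcoxon.csv"))
    utils::write.csv(result$wilcoxon, paths[3L], row.names = FALSE)
  }
  invisible(paths)
}
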