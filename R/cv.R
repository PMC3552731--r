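#' Repeated k-fold cross-validation plan over genotypes
#'
#' Randomly partitions the lines into `n_folds` disjoint, balanced folds
#' (sizes differ by at most one), independently for each of `n_repeats`
#' repeats. Fold assignment is by genotype, so a line is never split between
#' training and validation. Deterministic given the seed.
#'
#' @param line_ids Character vector of line ids.
#' @param n_folds Number of folds (default 5).
#' @param n_repeats Number of repeats (default 20, giving 100 runs).
#' @param seed Integer seed.
#' @return A tibble of class `cv_plan` with columns `repeat_id`, `fold`,
#'   `line_id` and attributes `n_folds`, `n_repeats`, `seed`.
#' @export
make_cv_plan <- function(line_ids, n_folds = 5, n_repeats = 20, seed = 1) {
  n <- length(line_ids)
  if (n < n_folds) abort("fewer lines than folds.")
  set.seed(seed)
  plan <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    tibble(
      repeat_id = r,
      fold = sample(rep(seq_len(n_folds), length.out = n)),
      line_id = line_ids
    )
  })
  structure(plan, class = c("cv_plan", class(plan)),
            n_folds = n_folds, n_repeats = n_repeats, seed = seed)
}

# model registry: name -> fitting closure(train_panel, trait_train, ...)
fit_model_by_name <- function(model, train_panel, trait_train, settings) {
  std <- impute_and_standardize(train_panel, drop_monomorphic = TRUE)
  switch(
    model,
    rrblup = do.call(fit_rrblup, c(list(std, trait_train), settings)),
    lasso = do.call(fit_lasso, c(list(std, trait_train), settings)),
    elastic_net = do.call(fit_elastic_net, c(list(std, trait_train), settings)),
    rkhs = do.call(fit_rkhs, c(list(train_panel, trait_train), settings)),
    bayesb = do.call(fit_bayesb, c(list(std, trait_train), settings)),
    abort(sprintf("unknown model '%s'.", model))
  )
}

#' Run the cross-validation protocol for one model
#'
#' For every (repeat, fold) run the model is fitted on the other folds —
#' including imputation, standardization, and any hyperparameter selection,
#' so no statistic ever sees the held-out lines — and scored on the held-out
#' fold by the Pearson correlation `r(y, yhat)` (the predictive ability).
#' The prediction accuracy, the correlation with the unobserved true genetic
#' values, is estimated as `mean(r) / h` with `h` the square root of the
#' trait heritability (line-mean heritability or repeatability). A fold with
#' constant predictions scores a correlation of zero with a warning, so all
#' models are compared on the same set of runs.
#'
#' @param panel A QC'd [genotype_panel()].
#' @param trait Trait tibble (`line_id`, `trait`, `value`, `h2`).
#' @param model One of `"rrblup"`, `"lasso"`, `"elastic_net"`, `"rkhs"`,
#'   `"bayesb"`, or a function `(train_panel, trait_train, ...)` returning
#'   an object with a `predict(fit, test_panel)` method.
#' @param plan A [make_cv_plan()] over the panel's lines.
#' @param h2 Heritability override (defaults to the trait table's `h2`).
#' @param ... Model settings forwarded to the fitting function (e.g.
#'   `alpha_grid`, `theta_grid`, `n_iter`).
#' @return Object of class `cv_result`: per-run predictive abilities,
#'   their mean and sd, `h`, and the accuracy `mean(r)/h`.
#' @export
run_cv <- function(panel, trait, model, plan, h2 = NULL, ...) {
  settings <- list(...)
  if (is.numeric(trait) && is.null(names(trait))) {
    stopifnot(length(trait) == nrow(panel$dosages))
    names(trait) <- rownames(panel$dosages)
  }
  h2 <- trait_h2(trait, h2)
  if (h2 <= 0) abort("trait heritability must be positive.")
  model_name <- if (is.function(model)) "custom" else model
  trait_name <- if (is.data.frame(trait) && "trait" %in% names(trait)) {
    trait$trait[1]
  } else "trait"
  seed0 <- attr(plan, "seed") %||% 0

  runs <- dplyr::distinct(as_tibble(plan)[c("repeat_id", "fold")])
  res <- purrr::pmap_dfr(runs, function(repeat_id, fold) {
    test_ids <- plan$line_id[plan$repeat_id == repeat_id & plan$fold == fold]
    train_ids <- setdiff(rownames(panel$dosages), test_ids)
    train_panel <- subset_panel(panel, lines = train_ids)
    test_panel <- subset_panel(panel, lines = test_ids)
    # the fitting routine only ever sees the training slice of the trait
    trait_train <- if (is.data.frame(trait)) {
      trait[trait$line_id %in% train_ids, , drop = FALSE]
    } else {
      align_trait(trait, train_ids)
    }
    # per-run seed so stochastic fits (inner CV folds, MCMC) are reproducible
    set.seed((seed0 + 7919 * (repeat_id * 100 + fold)) %% .Machine$integer.max)

    fit <- if (is.function(model)) {
      do.call(model, c(list(train_panel, trait_train), settings))
    } else {
      fit_model_by_name(model, train_panel, trait_train, settings)
    }
    yhat <- predict(fit, test_panel)
    y_test <- align_trait(trait, test_ids)
    r <- if (sd(yhat) == 0 || sd(y_test) == 0) {
      warn(sprintf("constant predictions in repeat %d fold %d; r set to 0.",
                   repeat_id, fold))
      0
    } else {
      cor(y_test, yhat[test_ids])
    }
    tibble(repeat_id = repeat_id, fold = fold, model = model_name,
           trait = trait_name, r = r, n_test = length(test_ids))
  })

  h <- sqrt(h2)
  structure(
    list(
      per_run = res,
      mean_r = mean(res$r),
      sd_r = sd(res$r),
      h = h,
      h2 = h2,
      accuracy = mean(res$r) / h,
      model = model_name,
      trait = trait_name
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s / %s: %d runs\n  predictive ability r = %.3f (sd %.3f), h2 = %.3f, accuracy r(g,ghat) = %.3f\n",
    x$model, x$trait, nrow(x$per_run), x$mean_r, x$sd_r, x$h^2, x$accuracy
  ))
  invisible(x)
}

#' @describeIn run_cv Per-run tibble of predictive abilities.
#' @param x A `cv_result`.
#' @export
tidy.cv_result <- function(x, ...) x$per_run

#' @describeIn run_cv One-row summary (accuracy, sd, heritability).
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    trait = x$trait, h2 = x$h2, model = x$model,
    mean_r = x$mean_r, sd_r = x$sd_r,
    accuracy = x$accuracy, sd_accuracy = x$sd_r / x$h,
    n_runs = nrow(x$per_run)
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$per_run, ggplot2::aes(x = .data$model, y = .data$r)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(y = "predictive ability r(y, yhat)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Compare cross-validated accuracies across models and traits
#'
#' One row per (trait, model) with the accuracy and its standard deviation
#' over runs, plus the max-min accuracy gap among models of the same trait
#' (the headline robustness statistic). Rows are sorted canonically by
#' trait then model.
#'
#' @param results List of `cv_result` objects.
#' @return Tibble with columns `trait`, `h2`, `model`, `accuracy`,
#'   `sd_accuracy`, `n_runs`, `trait_gap`.
#' @export
summarize_comparison <- function(results) {
  stopifnot(length(results) >= 1)
  tbl <- purrr::map_dfr(results, glance)
  tbl <- dplyr::arrange(tbl, .data$trait, .data$model)
  gaps <- dplyr::summarise(
    dplyr::group_by(tbl, .data$trait),
    trait_gap = max(.data$accuracy) - min(.data$accuracy)
  )
  dplyr::select(
    dplyr::left_join(tbl, gaps, by = "trait"),
    "trait", "h2", "model", "accuracy", "sd_accuracy", "mean_r", "sd_r",
    "n_runs", "trait_gap"
  )
}
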