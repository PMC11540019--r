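#' Leave-one-out cross-validation of a shared-parameter model
#'
#' For each held-out trial, a single parameter set is fitted to all other
#' trials by minimizing the pooled RMSE (equivalently the summed RSS across
#' training trials), then the held-out trial's AIC is computed with those
#' parameters. Event times may differ across trials; `spec_for_trial` builds
#' the per-trial predictor, but every spec must expose the same free
#' parameters.
#'
#' @param trials List of >= 3 [photometry_trial()] objects (or numeric
#'   vectors).
#' @param spec_for_trial `function(trial)` returning the trial's
#'   [model_spec()].
#' @param n_starts,seed,maxit Passed to the multi-start optimizer.
#' @return A list with `per_trial` (tibble of held-out AICs) and `mean_aic`.
#' @export
loo_cv <- function(trials, spec_for_trial, n_starts = 10, seed = 1,
                   maxit = 200) {
  if (length(trials) < 3) {
    abort("LOO-CV needs at least 3 trials.", class = "needmot_input_error")
  }
  specs <- lapply(trials, spec_for_trial)
  nm <- names(specs[[1]]$lower)
  if (!all(vapply(specs, function(s) identical(names(s$lower), nm),
                  logical(1)))) {
    abort("All per-trial specs must share the same free parameters.",
          class = "needmot_config_error")
  }
  obs <- lapply(seq_along(trials),
                function(i) specs[[i]]$response(trials[[i]]))
  test_aic <- vapply(seq_along(trials), function(i) {
    train <- setdiff(seq_along(trials), i)
    pooled <- model_spec(
      name = specs[[1]]$name,
      predict = function(par) {
        unlist(lapply(train, function(j) specs[[j]]$predict(par)))
      },
      lower = specs[[1]]$lower, upper = specs[[1]]$upper,
      response = function(x) unlist(obs[train]),
      k = specs[[1]]$k)
    fit <- fit_model(NULL, pooled, n_starts = n_starts, seed = seed,
                     maxit = maxit)
    pred <- specs[[i]]$predict(fit$params)
    rss <- sum((pred - obs[[i]])^2)
    suppressWarnings(aic_rss(rss, length(obs[[i]]), specs[[i]]$k))
  }, numeric(1))
  list(per_trial = tibble(trial = seq_along(trials), aic = test_aic),
       mean_aic = mean(test_aic))
}

split_blocks <- function(n, n_parts) {
  size <- ceiling(n / n_parts)
  split(seq_len(n), rep(seq_len(n_parts), each = size, length.out = n))
}

#' Block-permutation test of a model fit
#'
#' Verifies that a model fits the observed time series better than
#' structure-destroyed surrogates. The trace is divided into `n_parts`
#' contiguous blocks; each surrogate concatenates the blocks in a random
#' order (sampling without replacement, preserving size), the model is
#' refitted, and the observed AIC is ranked in the surrogate AIC null
#' distribution. The empirical p is the fraction of surrogates with AIC at
#' or below the observed AIC (a rank of zero is reported as 0 and should be
#' read as p < 1/`n_perm`).
#'
#' @param data Observed series (numeric or [photometry_trial()]).
#' @param spec A [model_spec()].
#' @param n_parts Number of contiguous blocks (default 20).
#' @param n_perm Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @param n_starts,maxit Optimizer settings per surrogate fit.
#' @return A list: `p`, `observed_aic`, `null_aic` (length `n_perm`).
#' @export
permutation_test <- function(data, spec, n_parts = 20, n_perm = 1000,
                             seed = 1, n_starts = 5, maxit = 200) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.",
                        class = "needmot_input_error")
  obs <- spec$response(data)
  observed <- fit_model(obs, spec, n_starts = n_starts, seed = seed,
                        maxit = maxit)$aic
  blocks <- split_blocks(length(obs), n_parts)
  pieces <- lapply(blocks, function(i) obs[i])
  # draw all block orders up front: the fitter reseeds the RNG internally
  set.seed(seed + 1L)
  orders <- lapply(seq_len(n_perm),
                   function(i) sample(length(pieces)))
  null_aic <- vapply(orders, function(ord) {
    surrogate <- unlist(pieces[ord], use.names = FALSE)
    fit_model(surrogate, spec, n_starts = n_starts, seed = seed,
              maxit = maxit)$aic
  }, numeric(1))
  list(p = mean(null_aic <= observed), observed_aic = observed,
       null_aic = null_aic)
}

friedman_statistic <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  colsums <- colSums(ranks)
  num <- 12 * sum((colsums - n * (k + 1) / 2)^2)
  if (num == 0) return(0)
  # tie correction as in the classical rank test
  ties <- apply(ranks, 1, function(r) {
    tab <- table(r)
    sum(tab^3 - tab)
  })
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  num / den
}

friedman_exact_p <- function(stat, n, k) {
  # DP over the joint distribution of column rank sums; each subject
  # contributes an independent uniformly random permutation of 1..k
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  pp <- perms(seq_len(k))
  keys <- vapply(pp, function(p) paste(p[-k], collapse = ","), character(1))
  dist <- new.env(hash = TRUE)
  assign(paste(rep(0, k - 1), collapse = ","), 1, envir = dist)
  for (subject in seq_len(n)) {
    nxt <- new.env(hash = TRUE)
    for (key in ls(dist)) {
      base <- as.numeric(strsplit(key, ",")[[1]])
      w <- get(key, envir = dist)
      for (j in seq_along(pp)) {
        newsum <- base + pp[[j]][-k]
        nk <- paste(newsum, collapse = ",")
        assign(nk, (if (exists(nk, envir = nxt))
          get(nk, envir = nxt) else 0) + w, envir = nxt)
      }
    }
    dist <- nxt
  }
  total <- factorial(k)^n
  tot_rank <- n * k * (k + 1) / 2
  p_ge <- 0
  for (key in ls(dist)) {
    cs <- as.numeric(strsplit(key, ",")[[1]])
    cs <- c(cs, tot_rank - sum(cs))
    q <- 12 / (n * k * (k + 1)) * sum((cs - n * (k + 1) / 2)^2)
    if (q >= stat - 1e-9) p_ge <- p_ge + get(key, envir = dist)
  }
  p_ge / total
}

#' Friedman rank test on an AIC matrix
#'
#' Compares candidate models across subjects by ranking each subject's AIC
#' values. Ties get mid-ranks; an exact permutation p (enumerating all
#' within-subject rank orders) is used for small untied designs
#' (models <= 3, subjects <= 8), otherwise the chi-square approximation.
#'
#' @param aic_matrix Numeric matrix, subjects x models, no missing cells.
#' @return A list: `statistic`, `p`, `method`, `ranks`.
#' @export
friedman_on_aic <- function(aic_matrix) {
  m <- as.matrix(aic_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Need >= 2 subjects and >= 2 models.",
          class = "needmot_input_error")
  }
  if (any(!is.finite(m))) {
    abort("AIC matrix has missing or non-finite cells.",
          class = "needmot_input_error")
  }
  all_equal_rows <- apply(m, 1, function(r) diff(range(r)) == 0)
  if (any(all_equal_rows)) {
    warn(sprintf("%d subject row(s) have all-equal AICs (pure ties).",
                 sum(all_equal_rows)))
  }
  ranks <- t(apply(m, 1, rank))
  stat <- friedman_statistic(ranks)
  n <- nrow(m); k <- ncol(m)
  has_ties <- any(apply(m, 1, function(r) anyDuplicated(r) > 0))
  if (!has_ties && k <= 3 && n <= 8) {
    p <- friedman_exact_p(stat, n, k)
    method <- "exact"
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = stat, p = p, method = method, ranks = ranks)
}
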