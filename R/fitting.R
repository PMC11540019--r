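#' Root mean square error
#'
#' @param pred,data Equal-length numeric vectors.
#' @return `sqrt(mean((pred - data)^2))`.
#' @export
rmse <- function(pred, data) {
  if (length(pred) != length(data) || length(pred) < 1) {
    abort("`pred` and `data` must have equal length >= 1.",
          class = "needmot_input_error")
  }
  sqrt(mean((pred - data)^2))
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = N * ln(RSS / N) + 2 * K`, the Gaussian-likelihood form used to
#' compare need/motivation model fits. `N` is the number of samples, `RSS`
#' the residual sum of squares and `K` the number of free parameters.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of samples (>= 1).
#' @param k Number of free parameters.
#' @return The AIC value; `-Inf` with a warning for a degenerate perfect fit
#'   (`rss == 0`).
#' @examples
#' aic_rss(100, 100, 2) # 4: n*log(1) + 2*2
#' @export
aic_rss <- function(rss, n, k) {
  if (n < 1) abort("`n` must be >= 1.", class = "needmot_input_error")
  if (rss < 0) abort("`rss` must be non-negative.",
                     class = "needmot_input_error")
  if (rss == 0) {
    warn("RSS is 0: perfect fit, AIC is -Inf.")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Generic model specification for curve fitting
#'
#' A model spec bundles everything [fit_model()] needs: a predictor mapping
#' a named parameter vector to a predicted series, box bounds for each free
#' parameter, and a response extractor that pulls the comparable series out
#' of the data object.
#'
#' @param name Model name.
#' @param predict `function(par)` returning the predicted numeric series.
#' @param lower,upper Named numeric vectors of box bounds (equal names).
#' @param response `function(x)` extracting the observed series; the default
#'   accepts a numeric vector or any data frame with a `value` column.
#' @param k Free-parameter count for AIC; defaults to `length(lower)`.
#' @return An object of class `"needmot_model_spec"`.
#' @export
model_spec <- function(name, predict, lower, upper,
                       response = default_response, k = length(lower)) {
  if (length(lower) != length(upper) ||
      !identical(names(lower), names(upper))) {
    abort("`lower` and `upper` must share names and length.",
          class = "needmot_config_error")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("Every free parameter needs finite bounds.",
          class = "needmot_config_error")
  }
  structure(list(name = name, predict = predict, lower = lower,
                 upper = upper, response = response, k = k),
            class = "needmot_model_spec")
}

default_response <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x) && "value" %in% names(x)) return(x$value)
  abort("Cannot extract a response series from this object.",
        class = "needmot_input_error")
}

#' Candidate latent-model specifications for photometry fitting
#'
#' Builds a [model_spec()] whose predictor constructs the per-test latent
#' ([build_test_model()]), convolves it with the calcium kernel and adds a
#' free offset ([predict_signal()]). Free parameters and default bounds:
#' baselines in `[-5, 5]`, step magnitudes in `[0, 10]` z-units (signs
#' applied by event kind), `a` and `leak` in `[0, 10]`, offset in `[-5, 5]`.
#' For motivation-family models the loss steps do not enter (predicted loss
#' leaves motivation unchanged), so only gain-event magnitudes are free.
#'
#' @inheritParams build_test_model
#' @param kernel Kernel vector from [gcamp_kernel()] at `rate`.
#' @param mode Boundary handling passed to [predict_signal()].
#' @param fixed Named list of parameters to fix (removed from the free set);
#'   may include `n0`, `steps` (full signed step vector), `m0`, `a`, `leak`,
#'   `offset`.
#' @param bounds Optional named list overriding default bounds, each entry
#'   `c(lower, upper)`.
#' @return A `"needmot_model_spec"`.
#' @export
latent_model_spec <- function(test_id, model, schedule, kernel, rate = 100,
                              mode = c("pad_mean", "crop_last5s", "none"),
                              delay_s = 0, fixed = list(), bounds = list()) {
  mode <- match.arg(mode)
  model <- match.arg(model, MODEL_NAMES)
  test_id <- match.arg(test_id, TEST_IDS)
  check_test_vocabulary(test_id, schedule)
  sev <- step_events(schedule)
  signs <- ifelse(sev$kind == "gain", 1, -1)
  need_family <- model %in% c("need", "inverted_need")
  free_step <- if (need_family) rep(TRUE, nrow(sev)) else sev$kind == "gain"
  step_names <- paste0("R", seq_len(nrow(sev)))

  b <- function(nm, dflt) {
    if (!is.null(bounds[[nm]])) bounds[[nm]] else dflt
  }
  lower <- c(); upper <- c()
  add_par <- function(nm, rng) {
    lower[[nm]] <<- rng[1]; upper[[nm]] <<- rng[2]
  }
  if (need_family) {
    if (is.null(fixed$n0)) add_par("n0", b("n0", c(-5, 5)))
  } else {
    if (is.null(fixed$m0)) add_par("m0", b("m0", c(-5, 5)))
    if (is.null(fixed$a)) add_par("a", b("a", c(0, 10)))
    if (is.null(fixed$leak)) add_par("leak", b("leak", c(0, 10)))
  }
  if (is.null(fixed$steps)) {
    for (i in which(free_step)) add_par(step_names[i], b("steps", c(0, 10)))
  }
  if (is.null(fixed$offset)) add_par("offset", b("offset", c(-5, 5)))
  lower <- unlist(lower); upper <- unlist(upper)

  assemble <- function(par) {
    get_par <- function(nm, dflt) {
      if (nm %in% names(par)) par[[nm]] else fixed[[nm]] %||% dflt
    }
    steps <- if (!is.null(fixed$steps)) fixed$steps else {
      mag <- numeric(nrow(sev))
      mag[free_step] <- par[step_names[free_step]]
      mag * signs
    }
    params <- if (need_family) {
      list(n0 = get_par("n0", 1), steps = steps,
           clip_floor = fixed$clip_floor)
    } else {
      list(n0 = fixed$n0 %||% 1, m0 = get_par("m0", 0),
           a = get_par("a", 1), leak = get_par("leak", 0), steps = steps)
    }
    list(params = params, offset = get_par("offset", 0))
  }

  # the predicted signal is linear in a small set of convolved basis
  # functions (indicator steps for need, accumulation ramps for
  # motivation), so the design matrix is precomputed once and every
  # objective evaluation is a matrix product; build_test_model() remains
  # the reference path and the two agree to numerical precision
  sched_d <- if (delay_s != 0) shift_consumption_end(schedule, delay_s)
    else schedule
  w <- schedule_window(sched_d)
  t_grid <- sample_grid(w, rate)
  conv_col <- function(b) {
    predict_signal(latent_trace(b, rate = rate, t_start = w[1]), kernel,
                   offset = 0, mode = mode)
  }
  sev_d <- step_events(sched_d)
  abn <- sched_d$time_s[sched_d$kind == "abandon"]
  t_abandon <- if (length(abn) > 0) abn[1] else Inf
  inv <- model %in% c("inverted_need", "inverted_motivation")
  flip <- if (inv) -1 else 1
  if (need_family) {
    cols <- c(list(n0 = conv_col(rep(1, length(t_grid)))),
              lapply(setNames(seq_len(nrow(sev_d)), step_names),
                     function(i) {
                       conv_col(as.numeric(t_grid >= sev_d$time_s[i] &
                                             t_grid < t_abandon))
                     }))
    X <- cbind(do.call(cbind, cols), offset = 1)
    weight_fun <- function(ap) {
      st <- ap$params$steps
      c(ap$params$n0, -flip * st, ap$offset)
    }
  } else {
    acc <- sched_d$time_s[sched_d$kind == "accessibility"]
    t0 <- if (length(acc) > 0) acc[1] else NA_real_
    ce <- sched_d$time_s[sched_d$kind == "consumption_end"]
    t_acc_end <- if (length(ce) > 0) ce[1] else w[2]
    ramp <- function(from) {
      r <- pmax(0, pmin(t_grid, t_acc_end) - from)
      r[t_grid >= t_abandon] <- 0
      r
    }
    if (is.na(t0)) {
      # no accessibility moment: accumulation never starts, flat latent
      g0 <- rep(0, length(t_grid))
      gi <- lapply(seq_len(nrow(sev_d)), function(i) g0)
      lk <- g0
    } else {
      g0 <- ramp(t0)
      gi <- lapply(seq_len(nrow(sev_d)),
                   function(i) ramp(max(sev_d$time_s[i], t0)))
      lk <- pmax(0, t_grid - t0)
      lk[t_grid >= t_abandon] <- 0
    }
    cols <- c(list(m0 = conv_col(rep(1, length(t_grid))),
                   g0 = conv_col(g0)),
              lapply(setNames(gi, step_names), conv_col),
              list(lk = conv_col(lk)))
    X <- cbind(do.call(cbind, cols), offset = 1)
    weight_fun <- function(ap) {
      p <- ap$params
      st <- p$steps
      st[sev_d$kind == "loss"] <- 0  # predicted loss leaves motivation flat
      c(p$m0, flip * p$a * p$n0, -flip * p$a * st,
        -flip * p$leak, ap$offset)
    }
  }
  predict_fun <- function(par) {
    drop(X %*% weight_fun(assemble(par)))
  }
  clamp <- function(x, nm) {
    if (!nm %in% names(lower)) return(NULL)
    max(lower[[nm]], min(upper[[nm]], x))
  }
  # least-squares solution in basis-coefficient space, mapped back to the
  # natural parameters (and clamped into the bounds) as a warm start for
  # the multi-start optimizer
  smart_start <- function(obs) {
    fit <- stats::lm.fit(X, obs)
    wcoef <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    par <- list()
    if (need_family) {
      par$n0 <- clamp(wcoef[["n0"]], "n0")
      for (i in which(free_step)) {
        par[[step_names[i]]] <-
          clamp(-flip * wcoef[[step_names[i]]] * signs[i], step_names[i])
      }
    } else {
      a_hat <- flip * wcoef[["g0"]] / (fixed$n0 %||% 1)
      par$m0 <- clamp(wcoef[["m0"]], "m0")
      par$a <- clamp(a_hat, "a")
      par$leak <- clamp(-flip * wcoef[["lk"]], "leak")
      a_div <- max(abs(a_hat), 1e-6)
      for (i in which(free_step)) {
        par[[step_names[i]]] <-
          clamp(-flip * wcoef[[step_names[i]]] / a_div, step_names[i])
      }
    }
    par$offset <- clamp(wcoef[["offset"]], "offset")
    unlist(par[names(lower)])
  }
  reference_predict <- function(par) {
    ap <- assemble(par)
    latent <- build_test_model(test_id, schedule, model, ap$params,
                               rate = rate, delay_s = delay_s)
    predict_signal(latent, kernel, offset = ap$offset, mode = mode)
  }
  response_fun <- function(x) {
    v <- default_response(x)
    if (mode == "crop_last5s") v <- v[-seq_len(round(5 * rate))] else v
  }
  out <- model_spec(name = model, predict = predict_fun, lower = lower,
                    upper = upper, response = response_fun)
  out$reference_predict <- reference_predict
  out$smart_start <- smart_start
  out
}

new_fit_result <- function(spec, par, obs, pred, n_starts, seed, converged,
                           extra_k = 0) {
  rmse_v <- rmse(pred, obs)
  n <- length(obs)
  rss <- rmse_v^2 * n
  k <- spec$k + extra_k
  structure(
    list(model_name = spec$name, params = par, rmse = rmse_v, rss = rss,
         n = n, k = k,
         aic = suppressWarnings(aic_rss(rss, n, k)),
         n_starts = n_starts, seed = seed, converged = converged,
         observed = obs, fitted = pred),
    class = "needmot_fit")
}

#' @export
print.needmot_fit <- function(x, ...) {
  cat(sprintf("<needmot_fit> model '%s': RMSE %.4g, AIC %.4g (n = %d, k = %d)\n",
              x$model_name, x$rmse, x$aic, x$n, x$k))
  cat("params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Fit a model specification to a trace by multi-start RMSE minimization
#'
#' Runs `n_starts` bounded quasi-Newton (L-BFGS-B) optimizations. The first
#' start is deterministic (the spec's least-squares warm start when
#' available, otherwise the bound-box midpoint); the rest are drawn
#' uniformly within the bounds under `seed`, so the same
#' `(data, spec, n_starts, seed)` always returns an identical fit. The best
#' (lowest-RMSE) start wins.
#'
#' @param data A [photometry_trial()], numeric vector, or anything the
#'   spec's response extractor understands.
#' @param spec A [model_spec()] / [latent_model_spec()].
#' @param n_starts Number of random starts (default 100, matching the
#'   standard multi-start protocol).
#' @param seed Integer seed for the start draws.
#' @param maxit Iteration cap per start.
#' @return A `"needmot_fit"` object: fitted parameters, `rmse`, `rss`, `n`,
#'   `k`, `aic`, bookkeeping, plus the observed and fitted series.
#' @export
fit_model <- function(data, spec, n_starts = 100, seed = 1, maxit = 200) {
  obs <- spec$response(data)
  par0 <- if (!is.null(spec$smart_start)) {
    tryCatch(spec$smart_start(obs),
             error = function(e) (spec$lower + spec$upper) / 2)
  } else {
    (spec$lower + spec$upper) / 2
  }
  objective <- function(p) {
    names(p) <- names(spec$lower)
    rmse(spec$predict(p), obs)
  }
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- par0
  if (n_starts > 1) {
    for (i in 2:n_starts) {
      starts[[i]] <- runif(length(par0), spec$lower, spec$upper)
    }
  }
  best <- NULL
  any_ok <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = spec$lower,
            upper = spec$upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    any_ok <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!any_ok) {
    abort("All optimization starts failed.",
          class = "needmot_convergence_error")
  }
  par <- setNames(best$par, names(spec$lower))
  new_fit_result(spec, par, obs, spec$predict(par), n_starts, seed,
                 converged = best$convergence == 0)
}

#' Fit with a consumption-end delay grid
#'
#' Refits the model at each candidate delay of the measured consumption-end
#' event (default 0-8 s in 1-s steps, compensating for residual food in the
#' mouth) and returns the best fit by AIC. The chosen delay is recorded as a
#' parameter `delay_s` and counted as one extra free parameter.
#'
#' @inheritParams fit_model
#' @param spec_builder `function(delay_s)` returning the [model_spec()] at
#'   that delay (see [latent_model_spec()]'s `delay_s` argument).
#' @param delay_grid Numeric vector of candidate delays in seconds.
#' @return The best `"needmot_fit"` across the grid, with `$params["delay_s"]`
#'   set and `k` incremented by one.
#' @export
fit_with_delay <- function(data, spec_builder, delay_grid = 0:8,
                           n_starts = 100, seed = 1, maxit = 200) {
  if (length(delay_grid) < 1) {
    abort("`delay_grid` must be non-empty.", class = "needmot_config_error")
  }
  fits <- lapply(delay_grid, function(d) {
    f <- fit_model(data, spec_builder(d), n_starts = n_starts, seed = seed,
                   maxit = maxit)
    f$params <- c(f$params, delay_s = d)
    f$k <- f$k + 1
    f$aic <- suppressWarnings(aic_rss(f$rss, f$n, f$k))
    f
  })
  fits[[which.min(vapply(fits, function(f) f$aic, numeric(1)))]]
}

#' Compare fitted models by AIC
#'
#' @param fits A named or unnamed list of `"needmot_fit"` objects for the
#'   same data.
#' @return A `"needmot_comparison"`: the fits, the winning model (minimal
#'   AIC) and the AIC gap to the runner-up.
#' @export
compare_fits <- function(fits) {
  if (length(fits) < 2) {
    abort("Need at least two fitted models to compare.",
          class = "needmot_config_error")
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  nm <- vapply(fits, function(f) f$model_name, character(1))
  ord <- order(aics)
  structure(list(fits = fits, winner = unname(nm[ord[1]]),
                 delta_aic = aics[ord[2]] - aics[ord[1]],
                 aic = setNames(aics, nm)),
            class = "needmot_comparison")
}

#' @export
print.needmot_comparison <- function(x, ...) {
  cat(sprintf("<needmot_comparison> winner '%s' (delta AIC %.3g)\n",
              x$winner, x$delta_aic))
  print(sort(x$aic))
  invisible(x)
}
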