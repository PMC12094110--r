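# One replay of the history assembling the sufficient structures for the
# likelihood: stacked per-interval design rows with exposure weights
# (survival of every supported endogenous event), the column sums of the
# observed events' design rows, and the response multinomial blocks.
build_rem_data <- function(events, model, roster) {
  events <- lek_events(as.data.frame(events))
  if (!nrow(events)) stop("empty event history")
  model <- .with_solicit_ids(model, events)
  k <- length(model$par_names)
  state <- lek_state(roster, day = events$day[1])
  t_prev <- 0
  Xs <- vector("list", nrow(events))
  ws <- vector("list", nrow(events))
  obs_sum <- numeric(k)
  resp_X <- list()
  resp_chosen <- integer(0)
  n_endog <- 0L
  prev_day <- events$day[1]
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]; t <- events$time_s[i]; day <- events$day[i]
    if (day != prev_day) {
      state <- state_begin_day(state, roster, day)
      prev_day <- day
      t_prev <- 0
    }
    dt <- t - t_prev
    if (dt < 0) stop("numeric error: negative waiting time at row ", i)
    des <- candidate_design(state, model)
    if (!is.null(state$pending) && dt > 0)
      stop("validation error: response to the attack at day ", day,
           " t=", state$pending$time, " is not immediate")
    if (dt > 0 && nrow(des$X)) {
      Xs[[i]] <- des$X
      ws[[i]] <- rep(dt, nrow(des$X))
    }
    if (kind %in% .ek$response) {
      ri <- match(kind, .ek$response)
      if (is.null(state$pending))
        stop("validation error: response with no pending attack at row ", i)
      resp_X[[length(resp_X) + 1L]] <- des$X
      resp_chosen <- c(resp_chosen, ri)
      n_endog <- n_endog + 1L
    } else if (kind %in% .ek$endogenous) {
      s <- match(events$sender[i], state$ids)
      r <- match(events$receiver[i], state$ids)
      hit <- which(des$ct$kind == kind &
                     (is.na(des$ct$sender) | des$ct$sender == s) &
                     (is.na(des$ct$receiver) | is.na(r) |
                        des$ct$receiver == r))
      if (!length(hit))
        stop("validation error: observed ", kind, " at day ", day, " t=", t,
             " is not in the model's support set")
      obs_sum <- obs_sum + des$X[hit[1], ]
      n_endog <- n_endog + 1L
    }
    state <- apply_event(state, list(kind = kind, time = t, day = day,
                                     sender = events$sender[i],
                                     receiver = events$receiver[i]))
    t_prev <- t
  }
  keep <- !vapply(Xs, is.null, logical(1))
  X <- if (any(keep)) do.call(rbind, Xs[keep]) else
    matrix(0, 0, k, dimnames = list(NULL, model$par_names))
  w <- if (any(keep)) unlist(ws[keep]) else numeric(0)
  RX <- if (length(resp_X)) do.call(rbind, resp_X) else
    matrix(0, 0, k, dimnames = list(NULL, model$par_names))
  list(X = X, w = w, obs_sum = obs_sum, resp_X = RX,
       resp_chosen = resp_chosen, n_endog = n_endog, model = model)
}

.rem_ll_parts <- function(theta, dat) {
  eta <- as.numeric(dat$X %*% theta)
  surv <- sum(dat$w * exp(eta))
  obs <- sum(dat$obs_sum * theta)
  ll_resp <- 0
  if (length(dat$resp_chosen)) {
    etaR <- matrix(dat$resp_X %*% theta, ncol = 3, byrow = TRUE)
    m <- apply(etaR, 1, max)
    lse <- m + log(rowSums(exp(etaR - m)))
    chosen <- etaR[cbind(seq_along(dat$resp_chosen), dat$resp_chosen)]
    ll_resp <- sum(chosen - lse)
  }
  list(ll = obs - surv + ll_resp, eta = eta)
}

#' Log-likelihood of an event history under the model
#'
#' The piecewise-constant hazard process implies that every inter-event
#' interval of length dt contributes the survival term
#' `-dt * sum(hazards of all supported endogenous events)`, and each
#' observed endogenous event contributes the log of its own hazard.
#' Responses are zero-duration: they contribute the log probability of the
#' chosen fight kind under a competing-risks multinomial and no waiting
#' time. Exogenous events terminate intervals (survival only).
#'
#' @param events a [lek_events()] history including exogenous events.
#' @param model a [lek_model()].
#' @param theta named parameter vector aligned to `model$par_names`.
#' @param roster the roster.
#' @return log-likelihood (scalar).
#' @export
rem_loglik <- function(events, model, theta, roster) {
  dat <- build_rem_data(events, model, roster)
  theta <- .align_theta(theta, dat$model)
  out <- .rem_ll_parts(theta, dat)$ll
  if (!is.finite(out)) stop("numeric error: non-finite log-likelihood")
  out
}

.align_theta <- function(theta, model) {
  pn <- model$par_names
  if (is.null(names(theta))) {
    if (length(theta) != length(pn)) stop("alignment error: theta length")
    return(stats::setNames(as.numeric(theta), pn))
  }
  miss <- setdiff(pn, names(theta))
  if (length(miss))
    stop("alignment error: theta lacks parameter(s): ",
         paste(miss, collapse = ", "))
  stats::setNames(as.numeric(theta[pn]), pn)
}

#' Posterior-mode fit of the relational event model
#'
#' Maximises the log-likelihood plus an independent Gaussian log-prior
#' (mean 0, SD `prior_sd`) on every coefficient by quasi-Newton (BFGS) with
#' analytic gradients. Standard errors come from the inverse of the
#' observed information (negative Hessian of the log-posterior) at the
#' mode; a pseudo-inverse with a warning is used if the information matrix
#' is near-singular. BIC uses `k * log(n) - 2 * logLik` with n the number
#' of observed endogenous events (responses included).
#'
#' @param events,model,roster as in [rem_loglik()].
#' @param prior_sd prior standard deviation (default 10).
#' @param init initial parameter vector (default all zero).
#' @param control passed to [stats::optim()] (maxit defaults to 500).
#' @return object of class `lek_fit`: `theta` (posterior mode), `se`,
#'   `logLik` (unpenalised, at the mode), `bic`, `k`, `n_events`,
#'   `convergence` (optim code and gradient norm), `model`.
#' @export
fit_rem <- function(events, model, roster, prior_sd = 10, init = NULL,
                    control = list()) {
  dat <- build_rem_data(events, model, roster)
  model <- dat$model
  k <- length(model$par_names)
  # identifiability: every column must vary somewhere in the design
  seen <- colSums(abs(dat$X)) + abs(dat$obs_sum) + colSums(abs(dat$resp_X))
  if (any(seen == 0))
    stop("identifiability error: degenerate design column(s): ",
         paste(model$par_names[seen == 0], collapse = ", "))
  if (is.null(init)) init <- numeric(k)
  npll <- function(th) {
    val <- -.rem_ll_parts(th, dat)$ll + sum(th^2) / (2 * prior_sd^2)
    if (!is.finite(val)) 1e10 else val
  }
  grad <- function(th) {
    e <- exp(as.numeric(dat$X %*% th))
    g <- -dat$obs_sum + as.numeric(crossprod(dat$X, dat$w * e)) +
      th / prior_sd^2
    if (length(dat$resp_chosen)) {
      etaR <- matrix(dat$resp_X %*% th, ncol = 3, byrow = TRUE)
      p <- exp(etaR - apply(etaR, 1, max))
      p <- p / rowSums(p)
      chosen_rows <- 3 * (seq_along(dat$resp_chosen) - 1) + dat$resp_chosen
      g <- g - colSums(dat$resp_X[chosen_rows, , drop = FALSE]) +
        as.numeric(crossprod(dat$resp_X, as.numeric(t(p))))
    }
    g
  }
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(init, npll, grad, method = "BFGS", control = ctl)
  th <- stats::setNames(opt$par, model$par_names)
  gn <- sqrt(sum(grad(opt$par)^2))
  H <- .rem_hessian(opt$par, dat, prior_sd)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) {
    warning("information matrix near-singular; using pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    Hi <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    sqrt(pmax(diag(Hi), 0))
  })
  ll <- .rem_ll_parts(opt$par, dat)$ll
  fit <- list(theta = th, se = stats::setNames(se, model$par_names),
              logLik = ll, bic = k * log(max(dat$n_endog, 1L)) - 2 * ll,
              k = k,
              n_events = dat$n_endog,
              convergence = list(code = opt$convergence, grad_norm = gn,
                                 counts = opt$counts),
              prior_sd = prior_sd, model = model)
  class(fit) <- "lek_fit"
  fit
}

.rem_hessian <- function(th, dat, prior_sd) {
  e <- exp(as.numeric(dat$X %*% th))
  H <- crossprod(dat$X * sqrt(dat$w * e))
  if (length(dat$resp_chosen)) {
    etaR <- matrix(dat$resp_X %*% th, ncol = 3, byrow = TRUE)
    p <- exp(etaR - apply(etaR, 1, max))
    p <- p / rowSums(p)
    for (b in seq_along(dat$resp_chosen)) {
      Xb <- dat$resp_X[3 * (b - 1) + 1:3, , drop = FALSE]
      mb <- as.numeric(crossprod(Xb, p[b, ]))
      H <- H + crossprod(Xb * sqrt(p[b, ])) - tcrossprod(mb)
    }
  }
  H + diag(1 / prior_sd^2, length(th))
}

#' @export
print.lek_fit <- function(x, ...) {
  cat("lek_fit:", x$k, "parameters,", x$n_events, "endogenous events\n")
  cat("  logLik =", format(x$logLik, digits = 8),
      " BIC =", format(x$bic, digits = 8),
      " grad norm =", format(x$convergence$grad_norm, digits = 3), "\n")
  print(data.frame(estimate = round(x$theta, 4),
                   posterior_se = round(x$se, 4)))
  invisible(x)
}

#' Bayesian information criterion of a fit
#'
#' `k * log(n) - 2 * logLik`, with n the number of observed endogenous
#' events (responses counted) and k the number of parameters.
#'
#' @param fit a `lek_fit`.
#' @return BIC (smaller is better).
#' @export
rem_bic <- function(fit) {
  stopifnot(inherits(fit, "lek_fit"))
  fit$bic
}

#' Coefficient table of a fit
#' @param fit a `lek_fit`.
#' @return data.frame with name, estimate, posterior_se.
#' @export
coef_table <- function(fit) {
  data.frame(name = names(fit$theta), estimate = unname(fit$theta),
             posterior_se = unname(fit$se))
}

#' Greedy BIC model selection over predictor statistics
#'
#' Starting from a base model, candidate statistics are added one at a time
#' (each step adding the statistic that most lowers BIC), then pruned
#' backwards; ties are broken toward the smaller model (a statistic is kept
#' only if it strictly lowers BIC). When several base models are supplied
#' (e.g. the two solicitation schemes), the search runs within each and the
#' overall BIC minimiser is returned.
#'
#' @param events,roster as in [fit_rem()].
#' @param base_models a [lek_model()] or list of them.
#' @param candidate_stats a [stat_catalog()] of statistics to consider
#'   adding (on top of each base model's own set).
#' @param prior_sd prior SD passed to [fit_rem()].
#' @param quiet suppress progress output?
#' @return list with `model`, `fit`, and a `trace` data.frame of every
#'   step's BIC.
#' @export
select_rem <- function(events, roster, base_models,
                       candidate_stats = NULL, prior_sd = 10,
                       quiet = TRUE) {
  if (inherits(base_models, "lek_model")) base_models <- list(base_models)
  if (!length(base_models)) stop("selection error: no candidate models")
  best <- NULL
  trace <- list()
  for (bi in seq_along(base_models)) {
    base <- base_models[[bi]]
    fit <- tryCatch(fit_rem(events, base, roster, prior_sd = prior_sd),
                    error = function(e) NULL)
    if (is.null(fit)) next
    trace[[length(trace) + 1L]] <-
      data.frame(base = bi, action = "base", name = NA, bic = fit$bic)
    cur_model <- fit$model
    # forward additions
    remaining <- candidate_stats
    repeat {
      if (is.null(remaining) || !nrow(remaining)) break
      gains <- vapply(seq_len(nrow(remaining)), function(j) {
        m2 <- cur_model
        m2$statistics <- rbind(m2$statistics, remaining[j, ])
        m2 <- .refresh_model(m2)
        f2 <- tryCatch(fit_rem(events, m2, roster, prior_sd = prior_sd),
                       error = function(e) NULL)
        if (is.null(f2)) Inf else f2$bic
      }, numeric(1))
      jbest <- which.min(gains)
      if (!is.finite(gains[jbest]) || gains[jbest] >= fit$bic) break
      cur_model$statistics <- rbind(cur_model$statistics,
                                    remaining[jbest, ])
      cur_model <- .refresh_model(cur_model)
      fit <- fit_rem(events, cur_model, roster, prior_sd = prior_sd)
      trace[[length(trace) + 1L]] <-
        data.frame(base = bi, action = "add",
                   name = remaining$name[jbest], bic = fit$bic)
      if (!quiet) message("add ", remaining$name[jbest], " BIC ", fit$bic)
      remaining <- remaining[-jbest, ]
    }
    # backward pruning over the statistic set
    repeat {
      if (!nrow(cur_model$statistics)) break
      drops <- vapply(seq_len(nrow(cur_model$statistics)), function(j) {
        m2 <- cur_model
        m2$statistics <- m2$statistics[-j, ]
        m2 <- .refresh_model(m2)
        f2 <- tryCatch(fit_rem(events, m2, roster, prior_sd = prior_sd),
                       error = function(e) NULL)
        if (is.null(f2)) Inf else f2$bic
      }, numeric(1))
      jbest <- which.min(drops)
      if (!is.finite(drops[jbest]) || drops[jbest] > fit$bic) break
      dropped <- cur_model$statistics$name[jbest]
      cur_model$statistics <- cur_model$statistics[-jbest, ]
      cur_model <- .refresh_model(cur_model)
      fit <- fit_rem(events, cur_model, roster, prior_sd = prior_sd)
      trace[[length(trace) + 1L]] <-
        data.frame(base = bi, action = "drop", name = dropped,
                   bic = fit$bic)
    }
    if (is.null(best) || fit$bic < best$fit$bic)
      best <- list(model = cur_model, fit = fit)
  }
  if (is.null(best)) stop("selection error: no candidate model converged")
  best$trace <- do.call(rbind, trace)
  best
}
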