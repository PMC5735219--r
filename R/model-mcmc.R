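# draw x ~ N(Q^{-1} b, Q^{-1}) from a dense precision matrix
draw_gaussian_canonical <- function(Q, b) {
  R <- chol(Q)
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  as.numeric(mu + backsolve(R, rnorm(length(b))))
}

# one RW2 unit: precision kappa*K + diag(dw), canonical mean db, then
# conditioning-by-kriging onto the constraints Cmat %*% u = 0. Precision is
# made full-rank by adding mass along the constraint directions, which leaves
# the constrained law unchanged.
sample_rw_unit <- function(kappa, K, Cmat, dw, db) {
  T <- nrow(K)
  lam <- kappa + mean(dw) + 1
  Q <- kappa * K + diag(dw, T) + lam * crossprod(Cmat)
  R <- chol(Q)
  mu <- backsolve(R, backsolve(R, db, transpose = TRUE))
  x <- mu + backsolve(R, rnorm(T))
  V <- backsolve(R, backsolve(R, t(Cmat), transpose = TRUE))
  x <- x - V %*% solve(Cmat %*% V, Cmat %*% x)
  as.numeric(x)
}

# adaptive random-walk Metropolis step on log(sd); returns c(value, accepted)
mh_log_sd <- function(value, step, target) {
  prop <- value * exp(rnorm(1, 0, step))
  la <- target(prop) + log(prop) - target(value) - log(value)
  if (is.finite(la) && log(runif(1)) < la) c(prop, 1) else c(value, 0)
}

#' Fit the hierarchical model by MCMC
#'
#' Blocked Gibbs sampling for the Gaussian components (hierarchical
#' intercepts/slopes and fixed effects jointly; each level's RW2 path from
#' its sparse Gaussian Markov full conditional with sum-to-zero and
#' zero-mean-slope constraints imposed by conditioning; spline coefficients;
#' study random effects), conjugate Gamma updates for the RW2 precisions,
#' and adaptive random-walk Metropolis on the log scale for every SD
#' component, with step sizes frozen at the end of burn-in to preserve
#' detailed balance. Deterministic given `seed`.
#'
#' @param ws A [build_model()] workspace.
#' @param iterations,burn_in,thin Override the schedule in the spec.
#' @param seed Integer seed for the sampler.
#' @param progress Print progress every `progress` iterations (0 = quiet).
#' @return An object of class `bmi_fit` with retained parameter draws,
#'   convergence diagnostics (split-chain scale reduction and effective
#'   sample size for monitored scalars), acceptance rates and the workspace.
#' @export
run_mcmc <- function(ws, iterations = NULL, burn_in = NULL, thin = NULL,
                     seed = 1L, progress = 0L) {
  spec <- ws$spec
  iterations <- iterations %||% spec$iterations
  burn_in <- burn_in %||% spec$burn_in
  thin <- thin %||% spec$thin
  if (iterations <= burn_in) {
    stop_bad_arg("iterations must exceed burn_in.", "bmitrends_config_error")
  }
  set.seed(as.integer(seed))
  t_start <- Sys.time()

  state <- init_state(ws)
  lp0 <- log_posterior(state, ws)
  if (!is.finite(lp0)) {
    parts <- log_posterior(state, ws, terms = TRUE)
    stop_bad_arg(sprintf(
      "Non-finite posterior at initialisation (likelihood %.3g, prior %.3g).",
      parts$likelihood, parts$prior), "bmitrends_numeric_error")
  }

  n <- ws$n; T <- ws$T; k <- ws$k_spline
  comp <- spec$components
  pr <- spec$priors
  X <- ws$X
  g <- ws$col_group
  levels_rw <- c("global", "superregion", "region", "country")
  n_units <- c(global = 1L, superregion = ws$S, region = ws$R,
               country = ws$C)

  # which sd parameters are sampled
  fit_v <- spec$fit_variances
  sd_names <- c(paste0("alpha_", names(pr$sd_alpha_scale)),
                paste0("beta_", names(pr$sd_beta_scale)),
                if (k > 0) paste0("gamma_", names(pr$sd_gamma_scale)),
                if (comp$study_re) paste0("phi_", COVERAGE_LEVELS),
                paste0("tau_", COVERAGE_LEVELS))
  steps <- setNames(rep(0.3, length(sd_names)), sd_names)
  acc_n <- setNames(numeric(length(sd_names)), sd_names)
  acc_d <- acc_n

  D <- (iterations - burn_in) %/% thin
  draws <- list(
    theta = matrix(NA_real_, D, ncol(X),
                   dimnames = list(NULL, colnames(X))),
    u = lapply(n_units, function(m) array(NA_real_, dim = c(D, m, T))),
    gamma_g = matrix(NA_real_, D, max(k, 1)),
    gamma_c = array(NA_real_, dim = c(D, max(k, 1), ws$C)),
    sds = matrix(NA_real_, D, length(sd_names),
                 dimnames = list(NULL, sd_names)),
    kappa = matrix(NA_real_, D, 4,
                   dimnames = list(NULL, levels_rw)),
    phi_e_sd = numeric(D),
    lp = numeric(D))

  # running linear-predictor pieces
  eta_A <- as.numeric(X %*% state$theta)
  eta_rw <- numeric(n)
  eta_sp <- numeric(n)
  if (k > 0) {
    eta_sp <- as.numeric(ws$B_obs %*% state$gamma_g) +
      rowSums(ws$B_obs * t(state$gamma_c)[ws$ct_i, , drop = FALSE])
  }
  eta_e <- numeric(n)

  d <- 0L
  for (it in seq_len(iterations)) {
    adapting <- it <= burn_in
    W <- 1 / (ws$v + state$sds$tau[ws$class_i]^2)

    # --- block A: hierarchical intercepts/slopes and fixed effects,
    # jointly with the study random effects (they are strongly correlated
    # with the coverage/urbanicity effects, so a joint Gaussian draw is
    # needed for the sampler to mix)
    if (comp$study_re) {
      r <- ws$y - eta_rw - eta_sp
      XW <- X * W
      Qaa <- crossprod(X, XW) + diag(prior_precision_A(ws, state$sds),
                                     ncol(X))
      cross <- rowsum(cbind(XW, W, W * r), ws$study_i)  # by study
      Ewx <- cross[, seq_len(ncol(X)), drop = FALSE]    # E'WX
      ewe <- cross[, ncol(X) + 1L]                      # diag(E'WE)
      ewr <- cross[, ncol(X) + 2L]                      # E'Wr
      Q <- rbind(cbind(Qaa, t(Ewx)),
                 cbind(Ewx, diag(ewe +
                                   1 / state$sds$phi[ws$study_class_i]^2,
                                 ws$n_study)))
      b <- c(crossprod(X, W * r), ewr)
      joint <- draw_gaussian_canonical(Q, b)
      state$theta <- setNames(joint[seq_len(ncol(X))], colnames(X))
      state$e <- joint[ncol(X) + seq_len(ws$n_study)]
      eta_A <- as.numeric(X %*% state$theta)
      eta_e <- state$e[ws$study_i]
    } else {
      r <- ws$y - eta_rw - eta_sp - eta_e
      Q <- crossprod(X, X * W) + diag(prior_precision_A(ws, state$sds),
                                      ncol(X))
      b <- crossprod(X, W * r)
      state$theta <- setNames(draw_gaussian_canonical(Q, b), colnames(X))
      eta_A <- as.numeric(X %*% state$theta)
    }

    # --- RW2 paths, level by level, unit by unit
    if (comp$rw2) {
      resid_base <- ws$y - eta_A - eta_sp - eta_e
      for (lev in levels_rw) {
        kap <- state$kappa[[lev]]
        for (j in seq_len(n_units[[lev]])) {
          rows <- ws$unit_rows[[lev]][[j]]
          dw <- numeric(T); db <- numeric(T)
          old <- state$u[[lev]][j, ]
          if (length(rows) > 0) {
            tt <- ws$t_i[rows]
            r_u <- resid_base[rows] - eta_rw[rows] + old[tt]
            m <- rowsum(cbind(W[rows], W[rows] * r_u), tt)
            ti <- as.integer(rownames(m))
            dw[ti] <- m[, 1]; db[ti] <- m[, 2]
          }
          new <- sample_rw_unit(kap, ws$K, ws$Cmat, dw, db)
          if (length(rows) > 0) {
            tt <- ws$t_i[rows]
            eta_rw[rows] <- eta_rw[rows] - old[tt] + new[tt]
          }
          state$u[[lev]][j, ] <- new
        }
      }
    }

    # --- age-spline coefficients: global, then per-country deviations
    if (k > 0) {
      resid_base <- ws$y - eta_A - eta_rw - eta_e
      eta_sp_c <- rowSums(ws$B_obs * t(state$gamma_c)[ws$ct_i, ,
                                                      drop = FALSE])
      r <- resid_base - eta_sp_c
      Q <- crossprod(ws$B_obs, ws$B_obs * W) +
        diag(1 / state$sds$gamma[["global"]]^2, k)
      state$gamma_g <- draw_gaussian_canonical(Q, crossprod(ws$B_obs, W * r))
      eta_sp_g <- as.numeric(ws$B_obs %*% state$gamma_g)
      prec_c <- 1 / state$sds$gamma[["country"]]^2
      for (c in seq_len(ws$C)) {
        rows <- ws$unit_rows$country[[c]]
        if (length(rows) == 0) {
          state$gamma_c[, c] <- rnorm(k, 0, state$sds$gamma[["country"]])
        } else {
          Bc <- ws$B_obs[rows, , drop = FALSE]
          rc <- resid_base[rows] - eta_sp_g[rows]
          Qc <- crossprod(Bc, Bc * W[rows]) + diag(prec_c, k)
          state$gamma_c[, c] <-
            draw_gaussian_canonical(Qc, crossprod(Bc, W[rows] * rc))
        }
      }
      eta_sp <- eta_sp_g +
        rowSums(ws$B_obs * t(state$gamma_c)[ws$ct_i, , drop = FALSE])
    }

    # --- variance components
    if (comp$rw2) {
      rank <- T - 2
      for (lev in levels_rw) {
        uu <- state$u[[lev]]
        quad <- sum(vapply(seq_len(nrow(uu)), function(jj)
          sum(uu[jj, ] * (ws$K %*% uu[jj, ])), numeric(1)))
        if (fit_v) {
          state$kappa[[lev]] <- rgamma(
            1, pr$rw2_shape + nrow(uu) * rank / 2,
            pr$rw2_rate + quad / 2)
        }
      }
    }
    if (fit_v) {
      gauss_target <- function(dev, scale) {
        m <- length(dev); ssq <- sum(dev^2)
        function(s) -m * log(s) - ssq / (2 * s^2) + dhalfnorm_log(s, scale)
      }
      upd <- function(name, value, target) {
        out <- mh_log_sd(value, steps[[name]], target)
        acc_n[[name]] <<- acc_n[[name]] + out[2]
        acc_d[[name]] <<- acc_d[[name]] + 1
        if (adapting) {
          steps[[name]] <<- steps[[name]] *
            exp(min(0.1, 1 / sqrt(it)) * (out[2] - 0.44))
        }
        out[1]
      }
      for (lv in names(pr$sd_alpha_scale)) {
        state$sds$alpha[[lv]] <- upd(
          paste0("alpha_", lv), state$sds$alpha[[lv]],
          gauss_target(state$theta[g == paste0("a_", abbrev_level(lv))],
                       pr$sd_alpha_scale[[lv]]))
        state$sds$beta[[lv]] <- upd(
          paste0("beta_", lv), state$sds$beta[[lv]],
          gauss_target(state$theta[g == paste0("b_", abbrev_level(lv))],
                       pr$sd_beta_scale[[lv]]))
      }
      if (k > 0) {
        state$sds$gamma[["global"]] <- upd(
          "gamma_global", state$sds$gamma[["global"]],
          gauss_target(state$gamma_g, pr$sd_gamma_scale[["global"]]))
        state$sds$gamma[["country"]] <- upd(
          "gamma_country", state$sds$gamma[["country"]],
          gauss_target(as.numeric(state$gamma_c),
                       pr$sd_gamma_scale[["country"]]))
      }
      if (comp$study_re) {
        for (ki in seq_along(COVERAGE_LEVELS)) {
          cl <- COVERAGE_LEVELS[ki]
          state$sds$phi[[cl]] <- upd(
            paste0("phi_", cl), state$sds$phi[[cl]],
            gauss_target(state$e[ws$study_class_i == ki],
                         pr$phi_scale[[cl]]))
        }
      }
      eta_full <- eta_A + eta_rw + eta_sp + eta_e
      for (ki in seq_along(COVERAGE_LEVELS)) {
        cl <- COVERAGE_LEVELS[ki]
        rows <- which(ws$class_i == ki)
        yk <- ws$y[rows]; ek <- eta_full[rows]; vk <- ws$v[rows]
        scale_k <- pr$tau_scale[[cl]]
        tau_target <- function(s) {
          sum(dnorm(yk, ek, sqrt(vk + s^2), log = TRUE)) +
            dhalfnorm_log(s, scale_k)
        }
        state$sds$tau[[cl]] <- upd(paste0("tau_", cl),
                                   state$sds$tau[[cl]], tau_target)
      }
    }

    # --- retain
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      d <- d + 1L
      draws$theta[d, ] <- state$theta
      for (lev in levels_rw) draws$u[[lev]][d, , ] <- state$u[[lev]]
      if (k > 0) {
        draws$gamma_g[d, ] <- state$gamma_g
        draws$gamma_c[d, , ] <- state$gamma_c
      }
      draws$sds[d, ] <- unlist(state$sds)[
        c(paste0("alpha.", names(pr$sd_alpha_scale)),
          paste0("beta.", names(pr$sd_beta_scale)),
          if (k > 0) paste0("gamma.", names(pr$sd_gamma_scale)),
          if (comp$study_re) paste0("phi.", COVERAGE_LEVELS),
          paste0("tau.", COVERAGE_LEVELS))]
      draws$kappa[d, ] <- unlist(state$kappa[levels_rw])
      draws$phi_e_sd[d] <- if (comp$study_re) sd(state$e) else 0
      draws$lp[d] <- log_posterior(state, ws)
    }
    if (progress > 0 && it %% progress == 0L) {
      message(sprintf("iteration %d/%d", it, iterations))
    }
  }

  monitored <- cbind(
    intercept = draws$theta[, which(g == "icpt")],
    slope = draws$theta[, which(g == "slope")],
    lp = draws$lp)
  diagnostics <- tibble(
    parameter = colnames(monitored),
    rhat = apply(monitored, 2, split_rhat),
    ess = apply(monitored, 2, ess_basic))
  runtime <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))

  structure(list(
    draws = draws, workspace = ws, spec = spec,
    seed = as.integer(seed), n_draws = D,
    iterations = iterations, burn_in = burn_in, thin = thin,
    diagnostics = diagnostics,
    accept = ifelse(acc_d > 0, acc_n / acc_d, NA_real_),
    runtime = runtime),
    class = "bmi_fit")
}

abbrev_level <- function(lv) {
  c(superregion = "sr", region = "reg", country = "ctry")[[lv]]
}

#' @export
print.bmi_fit <- function(x, ...) {
  cat(sprintf(
    "<bmi_fit: %s, %d draws (of %d iterations, %d burn-in), %d obs, %.1fs>\n",
    x$spec$outcome, x$n_draws, x$iterations, x$burn_in, x$workspace$n,
    x$runtime))
  print(x$diagnostics)
  invisible(x)
}
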