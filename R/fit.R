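#' Constrained model specifications and maximum-likelihood fitting
#'
#' A `model_spec` says which omega classes are active in each parameter
#' group. The foreground partitions (role `FG`) share one group; each
#' background partition keeps its own unconstrained group so foreground
#' constraints do not bias it.
#'
#' @param scheme A `partition_scheme` with roles set
#'   ([set_partition_roles()]).
#' @param fg_classes Classes active on the foreground: `"w2"` (neutral-only
#'   null), `c("w1", "w2")` (purifying + neutral), or all three.
#' @param bg_classes Classes on each background partition (default: full
#'   three-class mixture, unconstrained).
#' @return A `model_spec` object.
#' @export
model_spec <- function(scheme, fg_classes = c("w1", "w2", "w3"),
                       bg_classes = c("w1", "w2", "w3")) {
  stopifnot(inherits(scheme, "partition_scheme"))
  if (is.null(scheme$roles)) stop("scheme needs roles; call set_partition_roles()")
  roles <- scheme$roles
  fg_parts <- names(roles)[roles == "FG"]
  bg_parts <- names(roles)[roles != "FG"]
  partition_group <- c(stats::setNames(rep("FG", length(fg_parts)), fg_parts),
                       stats::setNames(bg_parts, bg_parts))
  group_classes <- c(list(FG = sort(fg_classes)),
                     stats::setNames(rep(list(sort(bg_classes)), length(bg_parts)),
                                     bg_parts))
  structure(list(partition_group = partition_group,
                 group_classes = group_classes),
            class = "model_spec")
}

# ---- parameter transforms -------------------------------------------------
# omega1 via logit, omega3 via shifted log, weights via (multinomial) logit,
# exchangeabilities via log. Branch lengths are handled by coordinate
# sweeps, not by the global optimizer.

n_group_pars <- function(classes) {
  has1 <- "w1" %in% classes; has3 <- "w3" %in% classes
  (if (has1) 2L else 0L) + (if (has3) 2L else 0L)
}

pack_group <- function(g) {
  th <- numeric(0)
  if ("w1" %in% g$classes) {
    th <- c(th, stats::qlogis(clamp01(g$omega1)))
  }
  if ("w3" %in% g$classes) {
    th <- c(th, log(max(g$omega3 - 1, 1e-8)))
  }
  has1 <- "w1" %in% g$classes; has3 <- "w3" %in% g$classes
  if (has1 && has3) {
    p3 <- max(1 - g$p1 - g$p2, 1e-8)
    th <- c(th, log(max(g$p1, 1e-8) / p3), log(max(g$p2, 1e-8) / p3))
  } else if (has1) {
    th <- c(th, stats::qlogis(clamp01(g$p1)))
  } else if (has3) {
    th <- c(th, stats::qlogis(clamp01(g$p2)))
  }
  th
}

unpack_group <- function(classes, th) {
  g <- list(classes = classes)
  i <- 1L
  has1 <- "w1" %in% classes; has3 <- "w3" %in% classes
  if (has1) { g$omega1 <- stats::plogis(th[i]); i <- i + 1L }
  if (has3) { g$omega3 <- 1 + exp(th[i]); i <- i + 1L }
  if (has1 && has3) {
    e1 <- exp(th[i]); e2 <- exp(th[i + 1L]); s <- 1 + e1 + e2
    g$p1 <- e1 / s; g$p2 <- e2 / s
  } else if (has1) {
    g$p1 <- stats::plogis(th[i]); g$p2 <- 1 - g$p1
  } else if (has3) {
    g$p2 <- stats::plogis(th[i]); g$p1 <- 0
  } else {
    g$p1 <- 0; g$p2 <- 1
  }
  validate_group(g)
}

clamp01 <- function(x) min(max(x, 1e-8), 1 - 1e-8)

pack_theta <- function(params, spec, fix_exch) {
  th <- if (fix_exch) numeric(0) else log(unname(params$exch))
  for (gn in names(spec$group_classes)) th <- c(th, pack_group(params$groups[[gn]]))
  th
}

unpack_theta <- function(th, spec, template, fix_exch) {
  i <- 1L
  if (!fix_exch) { template$exch <- validate_exchangeabilities(exp(th[1:5])); i <- 6L }
  groups <- list()
  for (gn in names(spec$group_classes)) {
    cls <- spec$group_classes[[gn]]
    np <- n_group_pars(cls)
    groups[[gn]] <- unpack_group(cls, th[seq.int(i, length.out = np)])
    i <- i + np
  }
  template$groups <- groups
  template$partition_group <- spec$partition_group
  template
}

default_start_group <- function(classes) {
  validate_group(list(classes = classes, omega1 = 0.3, omega3 = 2,
                      p1 = if ("w3" %in% classes) 0.4 else 0.5,
                      p2 = if ("w3" %in% classes) 0.4 else NULL))
}

#' Fit the partitioned codon mixture model by maximum likelihood
#'
#' Multi-start quasi-Newton optimization on transformed parameters
#' (logit for `omega1` and weights, shifted log for `omega3`, log for
#' exchangeabilities), with optional coordinate sweeps over branch lengths
#' between global rounds. The run is deterministic given `seed`.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` tree.
#' @param scheme A `partition_scheme` with roles.
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling the random restarts.
#' @param init Optional `model_parameters` used as a warm start.
#' @param control List of optimizer settings: `restarts` (random restarts in
#'   addition to the heuristic start; default 3), `maxit`, `optimize_branch_lengths`,
#'   `branch_rounds`, `freqs` (`"empirical"` plug-in CF3x4 or `"mle"`),
#'   `fix_exch`.
#' @return A `fit_result`: maximized log-likelihood, estimates, diagnostics.
#' @export
fit_model <- function(aln, tree, scheme, spec, seed = 1, init = NULL,
                      control = list()) {
  ctl <- utils::modifyList(list(restarts = 3L, maxit = 400L,
                                optimize_branch_lengths = TRUE,
                                branch_rounds = 2L, freqs = "empirical",
                                fix_exch = FALSE, rel_tol = 1e-10,
                                lnl_tol = 1e-6), control)
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  plan <- likelihood_plan(aln, tree, scheme)

  # plug-in CF3x4 start; in "mle" mode the 9 positional parameters join the
  # free parameters below (the corrected estimator)
  pf0 <- empirical_positional_frequencies(aln)
  template <- model_parameters(
    exch = if (!is.null(init)) init$exch else rep(1, 5),
    pos_freqs = if (!is.null(init)) init$pos_freqs else pf0,
    groups = lapply(spec$group_classes, default_start_group),
    partition_group = spec$partition_group)

  lens <- plan$edges$length
  n_eval <- 0L

  # positional-frequency packing for the corrected (ML) CF3x4 mode
  use_mle_freqs <- identical(ctl$freqs, "mle")
  pack_pf <- function(pf) as.vector(t(log(pf[, 1:3] / pf[, 4])))
  unpack_pf <- function(v) {
    m <- matrix(v, 3, 3, byrow = TRUE)
    e <- cbind(exp(m), 1)
    positional_frequencies(e / rowSums(e))
  }

  build_params <- function(th) {
    npf <- if (use_mle_freqs) 9L else 0L
    if (npf > 0L) {
      template$pos_freqs <- unpack_pf(th[seq_len(npf)])
      th <- th[-seq_len(npf)]
    }
    unpack_theta(th, spec, template, ctl$fix_exch)
  }
  objective <- function(th) {
    p <- tryCatch(build_params(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    n_eval <<- n_eval + 1L
    ll <- tryCatch(eval_core(plan, p, lens)$loglik, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start_theta <- function(perturb) {
    # per-group warm start: reuse init values for classes present in both
    # the init and the requested structure; newly freed classes start at
    # the interior heuristic rather than the boundary
    base_groups <- lapply(names(spec$group_classes), function(gn) {
      cls <- spec$group_classes[[gn]]
      g <- default_start_group(cls)
      gi <- if (!is.null(init)) init$groups[[gn]] else NULL
      if (!is.null(gi)) {
        if ("w1" %in% cls && "w1" %in% gi$classes) {
          g$omega1 <- gi$omega1; g$p1 <- gi$p1
        }
        if ("w3" %in% cls && "w3" %in% gi$classes) {
          g$omega3 <- gi$omega3; g$p2 <- gi$p2
        }
        if (!"w3" %in% cls) g$p2 <- 1 - g$p1
        if (g$p1 + g$p2 > 1) g$p2 <- (1 - g$p1) / 2
      }
      validate_group(g)
    })
    names(base_groups) <- names(spec$group_classes)
    tm <- template
    tm$groups <- base_groups
    if (!is.null(init)) tm$exch <- init$exch
    th <- pack_theta(tm, spec, ctl$fix_exch)
    if (use_mle_freqs) th <- c(pack_pf(tm$pos_freqs), th)
    if (perturb) th <- th + stats::rnorm(length(th), 0, 0.75)
    th
  }

  run_nlminb <- function(th0) {
    stats::nlminb(th0, objective,
                  control = list(iter.max = ctl$maxit, eval.max = 4L * ctl$maxit,
                                 rel.tol = ctl$rel_tol))
  }

  starts <- c(list(start_theta(FALSE)),
              lapply(seq_len(ctl$restarts), function(i) start_theta(TRUE)))
  fits <- lapply(starts, run_nlminb)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]

  conv <- best$convergence == 0
  # coordinate rounds: alternate branch-length sweeps with global polish
  if (ctl$optimize_branch_lengths && ctl$branch_rounds > 0L) {
    for (r in seq_len(ctl$branch_rounds)) {
      ll_before <- -best$objective
      pr <- build_params(best$par)
      for (k in seq_along(lens)) {
        f <- function(x) {
          l2 <- lens; l2[k] <- x
          n_eval <<- n_eval + 1L
          -eval_core(plan, pr, l2)$loglik
        }
        hi <- max(1, 5 * max(lens[k], 0.05))
        cur <- f(lens[k])
        opt <- stats::optimize(f, c(0, hi), tol = 1e-5)
        if (opt$objective < cur) lens[k] <- opt$minimum
      }
      best <- run_nlminb(best$par)
      if (abs(-best$objective - ll_before) < ctl$lnl_tol) break
    }
    conv <- best$convergence == 0
  }

  est <- build_params(best$par)
  est$lengths <- stats::setNames(lens, plan$edges$id)
  structure(list(
    loglik = -best$objective,
    params = est,
    groups = est$groups,
    lengths = stats::setNames(lens, plan$edges$id),
    converged = conv,
    restarts = ctl$restarts,
    n_eval = n_eval,
    spec = spec,
    seed = seed
  ), class = "fit_result")
}

# single entry point used by both the public functions and the optimizer
eval_core <- function(plan, params, lens = NULL) {
  if (!is.null(lens)) {
    params$lengths <- NULL
    plan$edges$length <- lens
  }
  eval_loglik(plan, params)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Partitioned codon-model fit: lnL = %.4f (%sconverged, %d evals)\n",
              x$loglik, if (x$converged) "" else "NOT ", x$n_eval))
  for (gn in names(x$groups)) {
    g <- x$groups[[gn]]
    cat(sprintf("  %s [%s]: omega1=%s p1=%.3f  omega3=%s p2=%.3f\n", gn,
                paste(g$classes, collapse = ","),
                if (is.null(g$omega1)) "-" else sprintf("%.3f", g$omega1),
                g$p1,
                if (is.null(g$omega3)) "-" else sprintf("%.3f", g$omega3),
                g$p2))
  }
  invisible(x)
}
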