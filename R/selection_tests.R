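#' Likelihood-ratio tests for selection on foreground partitions
#'
#' Both tests constrain only the foreground partition(s); every background
#' partition keeps its full, unconstrained three-category mixture so the
#' foreground test is not biased by background misspecification.
#'
#' * Purifying: null = foreground neutral-only (`omega2 = 1`); alternative
#'   adds a purifying class (`omega1 < 1` with weight `p1`).
#' * Positive: null = foreground purifying + neutral; alternative adds a
#'   positive class (`omega3 > 1`).
#'
#' Each alternative has two additional parameters (a rate ratio and its
#' weight), so p-values come from a chi-squared distribution with two
#' degrees of freedom — expected to be conservative because the null lies
#' on the boundary of the alternative's parameter space.
#'
#' @name selection_tests
NULL

#' Chi-squared (df = 2) p-value for a nested likelihood-ratio test
#'
#' @param lnl_null,lnl_alt Maximized log-likelihoods of the nested fits.
#' @param df Degrees of freedom (default 2: one rate ratio + one weight).
#' @param tol Negative slack tolerated before erroring; tiny negative
#'   statistics from optimizer noise are clamped to 0 with a warning.
#' @return List with `lr`, `df`, `p`.
#' @export
lrt_pvalue <- function(lnl_null, lnl_alt, df = 2, tol = 1e-4) {
  lr <- 2 * (lnl_alt - lnl_null)
  if (lr < -tol) {
    stop("fit ordering violated: lnL_alt < lnL_null by ",
         format(-lr / 2), " (refit with more restarts)")
  }
  if (lr < 0) {
    warning("small negative LR statistic (", format(lr), ") clamped to 0")
    lr <- 0
  }
  list(lr = lr, df = df, p = stats::pchisq(lr, df = df, lower.tail = FALSE))
}

run_selection_test <- function(test, aln, tree, scheme, roles, seed, control) {
  if (!is.null(roles)) scheme <- set_partition_roles(scheme, roles)
  if (is.null(scheme$roles)) stop("foreground roles required: pass `roles` or set them on the scheme")
  classes <- switch(test,
    purifying = list(null = "w2", alt = c("w1", "w2")),
    positive  = list(null = c("w1", "w2"), alt = c("w1", "w2", "w3")))
  spec_null <- model_spec(scheme, fg_classes = classes$null)
  spec_alt <- model_spec(scheme, fg_classes = classes$alt)

  control <- as.list(control)
  stage_shared <- control$stage_shared %||% TRUE
  control$stage_shared <- NULL
  fit_null <- fit_model(aln, tree, scheme, spec_null, seed = seed,
                        control = control)
  # Warm-start the alternative at the null solution (the null sits on the
  # boundary of the alternative, so this also keeps lnL_alt >= lnL_null).
  # With stage_shared the nucleotide exchangeabilities are estimated once,
  # under the null, and held there for the alternative: both fits then use
  # identical shared parameters and the LRT compares only selection
  # parameters, which is what the chi-squared df counts.
  ctl_alt <- if (stage_shared) utils::modifyList(control, list(fix_exch = TRUE))
             else control
  fit_alt <- fit_model(aln, tree, scheme, spec_alt, seed = seed + 1,
                       init = fit_null$params, control = ctl_alt)
  if (fit_alt$loglik < fit_null$loglik - 1e-4) {
    ctl2 <- utils::modifyList(ctl_alt,
                              list(restarts = max(6L, 2L * (control$restarts %||% 3L))))
    fit_alt2 <- fit_model(aln, tree, scheme, spec_alt, seed = seed + 2,
                          init = fit_null$params, control = ctl2)
    if (fit_alt2$loglik > fit_alt$loglik) fit_alt <- fit_alt2
  }
  lrt <- lrt_pvalue(fit_null$loglik, fit_alt$loglik)
  fg <- fit_alt$groups[["FG"]]
  structure(list(
    test = test,
    roles = scheme$roles,
    lnl_null = fit_null$loglik,
    lnl_alt = fit_alt$loglik,
    lr = lrt$lr, df = lrt$df, p = lrt$p,
    fg_omega1 = fg$omega1 %||% NA_real_,
    fg_p1 = fg$p1,
    fg_omega3 = fg$omega3 %||% NA_real_,
    fg_p3 = max(0, 1 - fg$p1 - fg$p2),
    fit_null = fit_null,
    fit_alt = fit_alt,
    diagnostics = list(converged = fit_null$converged && fit_alt$converged,
                       n_eval = fit_null$n_eval + fit_alt$n_eval,
                       seed = seed)
  ), class = "selection_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test a foreground partition for purifying selection
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` tree.
#' @param scheme A `partition_scheme`; roles may be supplied here or via
#'   `roles`. Multiple partitions given role `FG` share one foreground
#'   parameter set (a merged foreground).
#' @param roles Optional named role vector (values `FG`, `BG1`, `BG2`).
#' @param seed Integer seed (restarts are seeded deterministically).
#' @param control Optimizer control list, as in [fit_model()].
#' @return A `selection_test` with `lnl_null`, `lnl_alt`, `lr`, `df`, `p`,
#'   and foreground estimates `fg_omega1`, `fg_p1` under the alternative.
#' @export
purifying_selection_test <- function(aln, tree, scheme, roles = NULL,
                                     seed = 1, control = list()) {
  run_selection_test("purifying", aln, tree, scheme, roles, seed, control)
}

#' Test a foreground partition for positive selection
#'
#' @inheritParams purifying_selection_test
#' @export
positive_selection_test <- function(aln, tree, scheme, roles = NULL,
                                    seed = 1, control = list()) {
  run_selection_test("positive", aln, tree, scheme, roles, seed, control)
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("%s-selection LRT: LR = %.4f (df = %d), p = %.4g\n",
              x$test, x$lr, x$df, x$p))
  cat(sprintf("  lnL null = %.4f, lnL alt = %.4f\n", x$lnl_null, x$lnl_alt))
  cat(sprintf("  foreground: omega1 = %s, p1 = %.3f\n",
              if (is.na(x$fg_omega1)) "-" else sprintf("%.3f", x$fg_omega1),
              x$fg_p1))
  invisible(x)
}

#' Write a selection-test report
#'
#' JSON for machines; TSV mirroring the selection-results table layout
#' (one row per test: partition roles, p, omega1, P1).
#'
#' @param results A `selection_test` or list of them.
#' @param json_file,tsv_file Output paths (either may be `NULL`).
#' @export
write_test_report <- function(results, json_file = NULL, tsv_file = NULL) {
  if (inherits(results, "selection_test")) results <- list(results)
  rows <- lapply(results, function(x) {
    c(as.list(stats::setNames(unname(x$roles), names(x$roles))),
      list(test = x$test, lnL_null = x$lnl_null, lnL_alt = x$lnl_alt,
           LR = x$lr, df = x$df, p = x$p,
           omega1 = x$fg_omega1, P1 = x$fg_p1))
  })
  if (!is.null(json_file)) {
    payload <- lapply(results, function(x) list(
      test = x$test, foreground = names(x$roles)[x$roles == "FG"],
      roles = as.list(x$roles), lnL_null = x$lnl_null, lnL_alt = x$lnl_alt,
      LR = x$lr, df = x$df, p = x$p, omega1 = x$fg_omega1, P1 = x$fg_p1,
      diagnostics = x$diagnostics))
    jsonlite::write_json(payload, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_file)) {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    utils::write.table(df, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(results)
}
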