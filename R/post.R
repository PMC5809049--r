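# Posterior decision layer: differential-selection effects D with posterior
# probabilities, site/condition dN/dS summaries, pp-thresholded site calls,
# the unified site report, and logo-matrix export.

# pool post-burn-in random-effect draws across one fit or a list of fits
.collect_draws <- function(fit, what = c("F_draws", "omega_draws")) {
  what <- match.arg(what)
  fits <- if (inherits(fit, "codon_fit")) list(fit) else fit
  ok_model <- if (what == "F_draws") "DS" else "OM"
  draws <- lapply(fits, function(f) {
    if (!inherits(f, "codon_fit")) {
      stop("expected a codon_fit or list of codon_fit objects", call. = FALSE)
    }
    if (f$model != ok_model) {
      stop("this post-analysis needs a ", ok_model, " fit, got ", f$model,
           call. = FALSE)
    }
    keep <- f$ef_iters > f$config$burnin
    if (what == "F_draws") {
      f$F_draws[keep, , , , drop = FALSE]
    } else {
      f$omega_draws[keep, , , drop = FALSE]
    }
  })
  ref <- fits[[1]]
  list(draws = do.call(abind_first, draws), K = ref$K, nsites = ref$nsites)
}

# bind arrays along the first (draw) dimension without an extra dependency
abind_first <- function(...) {
  args <- list(...)
  if (length(args) == 1L) return(args[[1]])
  d <- dim(args[[1]])
  n <- sum(vapply(args, function(a) dim(a)[1], 0))
  out <- array(NA_real_, c(n, d[-1]))
  at <- 0L
  for (a in args) {
    idx <- at + seq_len(dim(a)[1])
    if (length(d) == 4L) out[idx, , , ] <- a else out[idx, , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Posterior differential-selection effects between two conditions
#'
#' For every site and amino acid, computes the differential selection effect
#' `D = log(F[cond_to] / F[cond_from])` in each posterior draw, and reports
#' the posterior mean together with the posterior probabilities that D is
#' positive or negative. An amino acid is called `+` at a site when
#' `pp(D > 0)` exceeds the threshold (its fitness is credibly higher under
#' `cond_to`, e.g. C4) and `-` when `pp(D < 0)` exceeds it.
#'
#' @param fit a DS `codon_fit`, or a list of them (draws are pooled, e.g. two
#'   independent chains).
#' @param cond_from,cond_to 0-based condition indices contrasted (defaults:
#'   conditions 1 vs 2 when K = 3 — the C3 and C4 clades — and 0 vs 1 when
#'   K = 2).
#' @param threshold posterior-probability cutoff for a direction call
#'   (default 0.90).
#' @param offset added to the 1-based alignment column to produce reported
#'   site coordinates (e.g. 21 when the alignment starts at residue 22).
#' @return a `ds_effects` tibble: `site`, `aa`, `mean_D`, `pp_pos`,
#'   `pp_neg`, `call` (`"+"`, `"-"` or `""`).
#' @export
differential_effects <- function(fit, cond_from = NULL, cond_to = NULL,
                                 threshold = 0.9, offset = 0) {
  cd <- .collect_draws(fit, "F_draws")
  K <- cd$K
  if (is.null(cond_from)) cond_from <- if (K >= 3) 1L else 0L
  if (is.null(cond_to)) cond_to <- if (K >= 3) 2L else 1L
  if (cond_from >= K || cond_to >= K || cond_from < 0 || cond_to < 0) {
    stop("conditions must lie in 0:(K-1)", call. = FALSE)
  }
  D <- log(cd$draws[, , cond_to + 1L, , drop = FALSE] /
             cd$draws[, , cond_from + 1L, , drop = FALSE])
  D <- array(D, dim(D)[c(1, 2, 4)])  # draws x sites x 20
  mean_D <- apply(D, c(2, 3), mean)
  pp_pos <- apply(D > 0, c(2, 3), mean)
  pp_neg <- apply(D < 0, c(2, 3), mean)
  out <- tidyr::expand_grid(site = seq_len(cd$nsites) + offset,
                            aa = aa_alphabet())
  ord <- cbind(rep(seq_len(cd$nsites), each = 20), rep(1:20, cd$nsites))
  out$mean_D <- mean_D[ord]
  out$pp_pos <- pp_pos[ord]
  out$pp_neg <- pp_neg[ord]
  out$call <- dplyr::case_when(out$pp_pos > threshold ~ "+",
                               out$pp_neg > threshold ~ "-",
                               TRUE ~ "")
  attr(out, "threshold") <- threshold
  attr(out, "offset") <- offset
  attr(out, "conditions") <- c(from = cond_from, to = cond_to)
  class(out) <- c("ds_effects", class(out))
  out
}

#' Posterior site/condition dN/dS summaries and positive-selection calls
#'
#' Reports the posterior mean dN/dS and the posterior probability that
#' omega exceeds 1 for every site (OM1) or site x condition (OM3); a site is
#' flagged under positive selection in a condition when that probability
#' exceeds the threshold.
#'
#' @param fit an OM `codon_fit`, or a list of them (pooled draws).
#' @inheritParams differential_effects
#' @return a `site_omega` tibble: `site`, `condition`, `mean_omega`,
#'   `pp_gt1`, `call` (logical).
#' @export
omega_site_calls <- function(fit, threshold = 0.9, offset = 0) {
  cd <- .collect_draws(fit, "omega_draws")
  out <- tidyr::expand_grid(site = seq_len(cd$nsites) + offset,
                            condition = seq_len(cd$K) - 1L)
  ord <- cbind(rep(seq_len(cd$nsites), each = cd$K),
               rep(seq_len(cd$K), cd$nsites))
  mean_om <- apply(cd$draws, c(2, 3), mean)
  pp <- apply(cd$draws > 1, c(2, 3), mean)
  out$mean_omega <- mean_om[ord]
  out$pp_gt1 <- pp[ord]
  out$call <- out$pp_gt1 > threshold
  attr(out, "threshold") <- threshold
  attr(out, "offset") <- offset
  class(out) <- c("site_omega", class(out))
  out
}

#' Unified site report across DS and OM analyses
#'
#' Builds a table in the style of a model-comparison site inventory: the
#' union of sites with any posterior-probability call in any supplied
#' analysis, with the OM1 omega, the OM3 per-condition omegas and their
#' `pp(omega > 1)`, and the DS direction calls with their pps, sorted by
#' site.
#'
#' @param ds a `ds_effects` table (or NULL).
#' @param om1,om3 `site_omega` tables (or NULL).
#' @return a tibble with one row per reported site.
#' @export
site_report <- function(ds = NULL, om1 = NULL, om3 = NULL) {
  inputs <- list(ds = ds, om1 = om1, om3 = om3)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  if (!length(inputs)) stop("supply at least one analysis", call. = FALSE)
  offs <- vapply(inputs, function(x) as.numeric(attr(x, "offset")), 0)
  if (length(unique(offs)) != 1L) {
    stop("analyses use different site-coordinate offsets", call. = FALSE)
  }
  called <- sort(unique(c(
    if (!is.null(ds)) ds$site[ds$call != ""],
    if (!is.null(om1)) om1$site[om1$call],
    if (!is.null(om3)) om3$site[om3$call]
  )))
  out <- tibble::tibble(site = called)
  if (!is.null(om1)) {
    m <- om1[match(called, om1$site), ]
    out$omega_om1 <- round(m$mean_omega, 2)
    out$pp_om1 <- round(m$pp_gt1, 2)
  }
  if (!is.null(om3)) {
    for (k in sort(unique(om3$condition))) {
      mk <- om3[om3$condition == k, ]
      m <- mk[match(called, mk$site), ]
      out[[paste0("omega_om3_c", k)]] <- round(m$mean_omega, 2)
      out[[paste0("pp_om3_c", k)]] <- round(m$pp_gt1, 2)
    }
  }
  if (!is.null(ds)) {
    calls <- vapply(called, function(s) {
      rows <- ds[ds$site == s & ds$call != "", ]
      if (!nrow(rows)) return("-")
      rows <- rows[order(-pmax(rows$pp_pos, rows$pp_neg)), ]
      paste0(rows$call, rows$aa, collapse = ", ")
    }, "")
    pps <- vapply(called, function(s) {
      rows <- ds[ds$site == s & ds$call != "", ]
      if (!nrow(rows)) return("-")
      rows <- rows[order(-pmax(rows$pp_pos, rows$pp_neg)), ]
      paste(round(pmax(rows$pp_pos, rows$pp_neg), 2), collapse = ", ")
    }, "")
    out$ds_calls <- calls
    out$ds_pp <- pps
  }
  out
}

#' Absolute and differential logo matrices
#'
#' Exports the per-site 20-vectors that sequence-logo tools render: the
#' *absolute* matrix is the posterior mean fitness profile of a reference
#' condition (letter heights proportional to fitness); the *differential*
#' matrix is the posterior mean of `D = log(F[cond_to]/F[cond_from])` per
#' amino acid (letters above/below the baseline for fitness increased or
#' decreased relative to the reference condition).
#'
#' @inheritParams differential_effects
#' @param ref_cond 0-based condition for the absolute matrix (default
#'   `cond_from`).
#' @return list of two tibbles, `absolute` and `differential`, each with a
#'   `site` column plus one column per amino acid.
#' @export
logo_matrices <- function(fit, cond_from = NULL, cond_to = NULL,
                          ref_cond = NULL, offset = 0) {
  cd <- .collect_draws(fit, "F_draws")
  K <- cd$K
  if (is.null(cond_from)) cond_from <- if (K >= 3) 1L else 0L
  if (is.null(cond_to)) cond_to <- if (K >= 3) 2L else 1L
  if (is.null(ref_cond)) ref_cond <- cond_from
  absmat <- apply(cd$draws[, , ref_cond + 1L, , drop = FALSE], c(2, 4), mean)
  D <- log(cd$draws[, , cond_to + 1L, , drop = FALSE] /
             cd$draws[, , cond_from + 1L, , drop = FALSE])
  diffmat <- apply(array(D, dim(D)[c(1, 2, 4)]), c(2, 3), mean)
  site <- seq_len(cd$nsites) + offset
  mk <- function(m) {
    colnames(m) <- aa_alphabet()
    dplyr::bind_cols(tibble::tibble(site = site), tibble::as_tibble(m))
  }
  list(absolute = mk(absmat), differential = mk(diffmat))
}

#' Write a logo matrix (or any site table) as TSV
#'
#' @param x a tibble with a `site` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a codon model fit
#'
#' For a DS fit, the per-site per-amino-acid differential effects (see
#' [differential_effects()]); for an OM fit, the per-site dN/dS summaries
#' (see [omega_site_calls()]).
#'
#' @param x a `codon_fit`.
#' @param ... passed to the underlying summary function.
#' @return a tibble.
#' @export
tidy.codon_fit <- function(x, ...) {
  if (x$model == "DS") differential_effects(x, ...) else omega_site_calls(x, ...)
}

#' One-row summary of a codon model fit
#'
#' @param x a `codon_fit`.
#' @param ... unused.
#' @return a one-row tibble with the model family, dimensions, sweep counts,
#'   post-burn-in mean log-likelihood and the minimum effective sample size
#'   across scalar trace statistics.
#' @export
glance.codon_fit <- function(x, ...) {
  tr <- x$trace[x$trace$iter > x$config$burnin, ]
  ess <- vapply(setdiff(names(tr), "iter"), function(s) trace_ess(tr[[s]]), 0)
  tibble::tibble(
    model = x$model, K = x$K, n_sites = x$nsites,
    n_iter = x$config$n_iter, burnin = x$config$burnin,
    mean_loglik = mean(tr$loglik), min_ess = min(ess)
  )
}

#' Plot the differential-selection profile along the sequence
#'
#' A differential-logo-style bar chart: for every site, signed posterior
#' mean effects of the amino acids whose direction call passed the
#' threshold (or the strongest effects when nothing is called).
#'
#' @param object a `ds_effects` table.
#' @param called_only show only sites with at least one call.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ds_effects <- function(object, called_only = TRUE, ...) {
  d <- object
  if (called_only) {
    keep_sites <- unique(d$site[d$call != ""])
    d <- d[d$site %in% keep_sites & d$call != "", ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$site), y = .data$mean_D,
                                  fill = .data$aa)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "site", y = "posterior mean D",
                  fill = "amino acid") +
    ggplot2::theme_minimal()
}

#' Plot site dN/dS with positive-selection calls
#'
#' @param object a `site_omega` table.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.site_omega <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$site, y = .data$mean_omega,
                               colour = .data$pp_gt1)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~condition, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_gradient(low = "grey70", high = "red3") +
    ggplot2::labs(x = "site", y = "posterior mean dN/dS",
                  colour = "pp(ω > 1)") +
    ggplot2::theme_minimal()
}

#' Trace plot of scalar MCMC statistics
#'
#' @param fit a `codon_fit`, or list of fits (chains overlaid).
#' @param stats character vector of trace columns to show (default all).
#' @return a ggplot object.
#' @export
plot_trace <- function(fit, stats = NULL) {
  fits <- if (inherits(fit, "codon_fit")) list(fit) else fit
  d <- purrr::imap_dfr(fits, function(f, i) {
    dplyr::mutate(f$trace, chain = factor(i))
  })
  if (is.null(stats)) stats <- setdiff(names(fits[[1]]$trace), "iter")
  long <- tidyr::pivot_longer(d, dplyr::all_of(stats),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::theme_minimal()
}
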