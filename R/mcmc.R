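# MCMC driver: alternation of stochastic substitution mapping (C++ core)
# with Metropolis-Hastings updates of all global parameters and all
# site/condition random effects, conditional on the mapping.

# genetic-code tables in the 0-based layout the C++ core expects
.code_for_cpp <- function() {
  if (!is.null(.codonDS_cache$cpp_code)) return(.codonDS_cache$cpp_code)
  gc <- genetic_code()
  p <- gc$pairs
  out <- list(
    from = p$from - 1L, to = p$to - 1L, n1 = p$n1 - 1L, n2 = p$n2 - 1L,
    syn = as.integer(p$syn), aa_from = p$aa_from - 1L, aa_to = p$aa_to - 1L,
    aa = gc$aa_index - 1L, codon_nuc = gc$codon_nuc - 1L
  )
  .codonDS_cache$cpp_code <- out
  out
}

# postorder edge arrays for a conditioned tree; conditions are re-aligned to
# the postorder edge ordering
.tree_arrays <- function(ct) {
  tr <- ct$tree
  po <- ape::reorder.phylo(tr, "postorder")
  key <- paste(tr$edge[, 1], tr$edge[, 2])
  key_po <- paste(po$edge[, 1], po$edge[, 2])
  idx <- match(key_po, key)
  list(edge = po$edge, elen = po$edge.length,
       econd = as.integer(ct$condition[idx]),
       ntip = ape::Ntip(tr), order = idx)
}

# alignment as the 0-based/-1-masked integer matrix used by the C++ core,
# rows in tip order
.tips_for_cpp <- function(aln, ct) {
  tips <- aln[ct$tree$tip.label, , drop = FALSE]
  tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"
  tips <- tips - 1L
  tips[tips < 0L] <- -1L
  tips
}

.rdirichlet1 <- function(n) {
  g <- stats::rgamma(n, 1, 1)
  g / sum(g)
}

#' Draw a model state from the prior
#'
#' Samples every parameter of a DS or OM model from its prior: branch
#' lengths iid Exponential with mean `lambda`, `lambda` Exponential with mean
#' 0.1, the six mutational exchangeabilities iid Exponential with mean 1, the
#' mutational nucleotide frequencies uniform Dirichlet, fitness profiles
#' uniform Dirichlet over the 20 amino acids (DS), and site/condition dN/dS
#' values Gamma with shape `alpha[k]` and scale `beta[k]`, the
#' hyperparameters themselves Exponential with mean 1 (OM).
#'
#' @param ct a `conditioned_tree` (supplies the number of branches and K).
#' @param nsites number of codon sites.
#' @param model `"DS"` or `"OM"`.
#' @param seed optional integer seed.
#' @return a named list (`lambda`, `elen`, `exch`, `pi`, and `F` or
#'   `omega`/`alpha`/`beta`) — one prior draw of the full model state.
#' @export
sample_prior <- function(ct, nsites, model = c("DS", "OM"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  E <- nrow(ct$tree$edge)
  K <- ct$K
  lambda <- stats::rexp(1, rate = 1 / 0.1)
  st <- list(
    lambda = lambda,
    elen = stats::rexp(E, rate = 1 / lambda),
    exch = stats::rexp(6, 1),
    pi = .rdirichlet1(4)
  )
  if (model == "DS") {
    F <- array(stats::rgamma(nsites * K * 20, 1, 1), c(nsites, K, 20))
    st$F <- sweep_normalize_profiles(F)
  } else {
    st$alpha <- stats::rexp(K, 1)
    st$beta <- stats::rexp(K, 1)
    st$omega <- matrix(
      stats::rgamma(nsites * K, shape = rep(st$alpha, each = nsites),
                    scale = rep(st$beta, each = nsites)),
      nsites, K)
  }
  st
}

# default proposal-tuning control; adapted during burn-in only
.default_ctrl <- function() {
  list(nrep_re = 5L, delta_hi = 500, delta_lo = 50, sigma_om = 0.6,
       sd_len = 0.6, sd_lambda = 0.6, sd_exch = 0.4, delta_pi = 300,
       sd_ab = 0.5, n_mut_rep = 6L, n_len_rep = 2L, n_lambda_rep = 3L,
       map_every = 2L)
}

# one full cycle of global-parameter MH updates given mapping aggregates;
# returns the updated state plus per-block acceptance counts
.update_globals <- function(state, sw, model, ctrl, nsites, do_root_terms) {
  E <- length(state$elen)
  acc <- c(len = 0, len_try = 0, lambda = 0, lambda_try = 0,
           exch = 0, exch_try = 0, pi = 0, pi_try = 0,
           ab = 0, ab_try = 0)
  nb <- sw$nb
  ebmat <- sw$ebmat
  n12 <- sw$n12
  gcc <- genetic_code()

  # weight vector aligned with ebmat columns (0-based index 4*n1 + n2)
  j <- 0:15
  qv <- state$q4[cbind(j %/% 4 + 1L, j %% 4 + 1L)]

  # ---- branch lengths: independent targets given the mapping ----
  for (r in seq_len(ctrl$n_len_rep)) {
    ew <- as.vector(ebmat %*% qv)
    z <- stats::rnorm(E, 0, ctrl$sd_len)
    tnew <- state$elen * exp(z)
    logr <- nb * log(tnew / state$elen) - (tnew / state$elen - 1) * ew -
      (tnew - state$elen) / state$lambda + z
    logr[!is.finite(logr)] <- -Inf  # guards zero-length edges
    ok <- log(stats::runif(E)) < logr
    acc["len"] <- acc["len"] + sum(ok); acc["len_try"] <- acc["len_try"] + E
    ebmat[ok, ] <- ebmat[ok, , drop = FALSE] * (tnew[ok] / state$elen[ok])
    state$elen[ok] <- tnew[ok]
  }

  # ---- lambda ----
  for (r in seq_len(ctrl$n_lambda_rep)) {
    z <- stats::rnorm(1, 0, ctrl$sd_lambda)
    ln <- state$lambda * exp(z)
    logr <- (-E * log(ln) - sum(state$elen) / ln - ln / 0.1) -
      (-E * log(state$lambda) - sum(state$elen) / state$lambda -
         state$lambda / 0.1) + z
    acc["lambda_try"] <- acc["lambda_try"] + 1
    if (log(stats::runif(1)) < logr) {
      state$lambda <- ln
      acc["lambda"] <- acc["lambda"] + 1
    }
  }

  # ---- mutation model (exchangeabilities + frequencies) ----
  A12 <- matrix(colSums(ebmat), 4, 4, byrow = TRUE)  # A12[n1, n2]
  off <- which(row(A12) != col(A12))
  root_codon <- sw$rootstate + 1L
  have_root <- do_root_terms && length(root_codon) && all(root_codon > 0)
  if (model == "DS" && have_root) {
    # site x codon fitness of the encoded amino acid under the root condition
    Fc <- matrix(state$F[, state$root_cond + 1L, ], nsites, 20)[, gcc$aa_index]
  }
  loglik_mut <- function(exch, pi) {
    m <- mutation_model(exch, pi)
    ll <- sum(n12[off] * log(m$Q[off])) - sum(m$Q[off] * A12[off])
    if (have_root) {
      piprod <- pi[gcc$codon_nuc[, 1]] * pi[gcc$codon_nuc[, 2]] *
        pi[gcc$codon_nuc[, 3]]
      ll <- ll + sum(log(piprod[root_codon]))
      if (model == "DS") {
        ll <- ll - sum(log(as.vector(Fc %*% piprod)))
      } else {
        ll <- ll - length(root_codon) * log(sum(piprod))
      }
    }
    ll
  }
  cur_ll <- loglik_mut(state$exch, state$pi)
  for (r in seq_len(ctrl$n_mut_rep)) {
    for (j in 1:6) {
      z <- stats::rnorm(1, 0, ctrl$sd_exch)
      ex <- state$exch
      ex[j] <- ex[j] * exp(z)
      ll <- loglik_mut(ex, state$pi)
      logr <- ll - cur_ll - (ex[j] - state$exch[j]) + z
      acc["exch_try"] <- acc["exch_try"] + 1
      if (log(stats::runif(1)) < logr) {
        state$exch <- ex; cur_ll <- ll
        acc["exch"] <- acc["exch"] + 1
      }
    }
    dp <- ctrl$delta_pi
    prop <- stats::rgamma(4, shape = dp * state$pi, rate = 1)
    if (all(prop > 0) && all(is.finite(prop))) {
      prop <- prop / sum(prop)
      if (min(prop) > 1e-10) {
        lq_f <- sum((dp * state$pi - 1) * log(prop) - lgamma(dp * state$pi))
        lq_r <- sum((dp * prop - 1) * log(state$pi) - lgamma(dp * prop))
        ll <- loglik_mut(state$exch, prop)
        logr <- ll - cur_ll + lq_r - lq_f
        acc["pi_try"] <- acc["pi_try"] + 1
        if (log(stats::runif(1)) < logr) {
          state$pi <- prop; cur_ll <- ll
          acc["pi"] <- acc["pi"] + 1
        }
      }
    }
  }
  state$q4 <- mutation_model(state$exch, state$pi)$Q

  # ---- OM hyperparameters ----
  if (model == "OM") {
    K <- ncol(state$omega)
    for (k in seq_len(K)) {
      om <- state$omega[, k]
      lp <- function(a, b) {
        sum(stats::dgamma(om, shape = a, scale = b, log = TRUE)) - a - b
      }
      cur <- lp(state$alpha[k], state$beta[k])
      for (nm in c("alpha", "beta")) {
        z <- stats::rnorm(1, 0, ctrl$sd_ab)
        a <- state$alpha[k]; b <- state$beta[k]
        if (nm == "alpha") a <- a * exp(z) else b <- b * exp(z)
        new <- lp(a, b)
        logr <- new - cur + z
        acc["ab_try"] <- acc["ab_try"] + 1
        if (log(stats::runif(1)) < logr) {
          state$alpha[k] <- a; state$beta[k] <- b; cur <- new
          acc["ab"] <- acc["ab"] + 1
        }
      }
    }
  }
  list(state = state, acc = acc)
}

#' Run one MCMC chain of a DS or OM codon model
#'
#' Alternates one stochastic-mapping refresh of the complete substitution
#' history (conditional on tip codons and current parameters) with
#' Metropolis-Hastings updates of all random effects (fitness profiles or
#' site/condition dN/dS) and all global parameters (branch lengths, their
#' hyperparameter lambda, mutational exchangeabilities and frequencies, and
#' the gamma hyperparameters of the OM models), conditional on the mapping.
#' Proposal scales are adapted during burn-in only, targeting 20-50 percent
#' acceptance. Seeded runs are bit-reproducible.
#'
#' @param aln a `codon_alignment` (see [read_alignment()]); all tips of the
#'   tree must be present as rows.
#' @param ct a `conditioned_tree` giving the topology, branch lengths used
#'   for initialization, and the per-branch conditions.
#' @param model `"DS"` (fitness-profile mutation-selection) or `"OM"`
#'   (site/condition dN/dS).
#' @param n_iter total number of MCMC points (default 6000).
#' @param burnin number of initial points discarded by the post-analysis
#'   functions and during which proposals adapt (default 400).
#' @param thin trace thinning interval for scalar statistics.
#' @param ef_thin thinning interval for the stored random-effect draws
#'   (fitness profiles / omega fields); these arrays dominate memory.
#' @param seed integer seed.
#' @param root_cond condition index (0-based) whose stationary distribution
#'   is the root-state prior; defaults to 0.
#' @param ctrl optional list overriding proposal-tuning defaults.
#' @param progress print a progress line every 500 sweeps.
#' @return a `codon_fit` object: list with `trace` (tibble of scalar
#'   statistics per kept sweep), `F_draws` (draws x sites x K x 20, DS) or
#'   `omega_draws` (draws x sites x K, OM) at `ef_thin` cadence together with
#'   `ef_iters`, final `state`, `acceptance` rates, and the run
#'   configuration.
#' @export
run_chain <- function(aln, ct, model = c("DS", "OM"), n_iter = 6000,
                      burnin = 400, thin = 1, ef_thin = 10, seed = 1,
                      root_cond = 0L, ctrl = list(), progress = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(ct, "conditioned_tree"))
  if (burnin >= n_iter) stop("`burnin` must be smaller than `n_iter`",
                             call. = FALSE)
  check_taxa(aln, ct)
  set.seed(as.integer(seed))
  ta <- .tree_arrays(ct)
  tips <- .tips_for_cpp(aln, ct)
  nsites <- ncol(aln)
  K <- ct$K
  code <- .code_for_cpp()
  control <- utils::modifyList(.default_ctrl(), ctrl)

  # initial state: data-tree branch lengths, flat mutation model, prior
  # draws for the random effects
  prior0 <- sample_prior(ct, nsites, model)
  state <- list(lambda = max(mean(ta$elen), 1e-3), elen = ta$elen,
                exch = rep(1, 6), pi = rep(0.25, 4),
                root_cond = as.integer(root_cond))
  state$q4 <- mutation_model(state$exch, state$pi)$Q
  if (model == "DS") {
    state$F <- prior0$F
  } else {
    state$alpha <- prior0$alpha; state$beta <- prior0$beta
    state$omega <- prior0$omega
  }
  mode <- if (model == "DS") 0L else 1L
  dummyF <- array(1, c(1, 1, 20))
  dummyO <- matrix(1, 1, 1)

  keep <- seq(thin, n_iter, by = thin)
  stats_names <- c("iter", "loglik", "lambda", "tree_length",
                   paste0("pi_", nuc_alphabet()),
                   if (model == "OM") paste0("mean_omega_", seq_len(K) - 1L)
                   else paste0("profile_max_", seq_len(K) - 1L))
  tracem <- matrix(NA_real_, length(keep), length(stats_names),
                   dimnames = list(NULL, stats_names))
  ef_keep <- seq(ef_thin, n_iter, by = ef_thin)
  if (model == "DS") {
    F_draws <- array(NA_real_, c(length(ef_keep), nsites, K, 20))
  } else {
    omega_draws <- array(NA_real_, c(length(ef_keep), nsites, K))
  }
  acc_tot <- NULL
  acc_win <- NULL
  win_f <- c(0, 0); win_o <- c(0, 0)

  krow <- 0L; erow <- 0L
  ws <- cpp_map_ws()
  last_ll <- NA_real_
  for (it in seq_len(n_iter)) {
    # refresh the stochastic mapping every map_every-th sweep; in between,
    # Metropolis-Hastings rounds condition on the stored mapping
    map_mode <- if ((it - 1L) %% control$map_every == 0L) 1L else 2L
    sw <- cpp_sweep(ta$edge, state$elen, ta$econd, ta$ntip, tips, code,
                    state$q4, state$pi, mode,
                    if (model == "DS") state$F else dummyF,
                    if (model == "OM") state$omega else dummyO,
                    if (model == "OM") state$alpha else 1,
                    if (model == "OM") state$beta else 1,
                    state$root_cond, ws, map_mode, control$nrep_re,
                    control$delta_hi, control$delta_lo, control$sigma_om,
                    FALSE)
    if (map_mode == 1L) last_ll <- sum(sw$loglik)
    if (model == "DS") state$F <- sw$F else state$omega <- sw$omega
    up <- .update_globals(state, sw, model, control, nsites,
                          do_root_terms = TRUE)
    state <- up$state
    acc_tot <- if (is.null(acc_tot)) up$acc else acc_tot + up$acc
    acc_win <- if (is.null(acc_win)) up$acc else acc_win + up$acc
    win_f <- win_f + c(sw$acc_f, sw$try_f)
    win_o <- win_o + c(sw$acc_o, sw$try_o)

    # adapt proposal scales during burn-in only
    if (it <= burnin && it %% 50 == 0) {
      rate <- function(a, b) if (b > 0) a / b else 0.35
      adj <- function(cur, r, lo = 1e-4, hi = 1e6) {
        if (r < 0.2) cur / 1.3 else if (r > 0.5) cur * 1.3 else cur
      }
      control$sd_len <- adj(control$sd_len, rate(acc_win["len"], acc_win["len_try"]))
      control$sd_lambda <- adj(control$sd_lambda, rate(acc_win["lambda"], acc_win["lambda_try"]))
      control$sd_exch <- adj(control$sd_exch, rate(acc_win["exch"], acc_win["exch_try"]))
      control$sigma_om <- adj(control$sigma_om, rate(win_o[1], win_o[2]))
      control$sd_ab <- adj(control$sd_ab, rate(acc_win["ab"], acc_win["ab_try"]))
      # Dirichlet concentrations move opposite to scale parameters
      rpi <- rate(acc_win["pi"], acc_win["pi_try"])
      if (rpi < 0.2) control$delta_pi <- control$delta_pi * 1.3
      if (rpi > 0.5) control$delta_pi <- control$delta_pi / 1.3
      rf <- rate(win_f[1], win_f[2])
      if (rf < 0.2) {
        control$delta_hi <- control$delta_hi * 1.3
        control$delta_lo <- control$delta_lo * 1.3
      }
      if (rf > 0.5) {
        control$delta_hi <- control$delta_hi / 1.3
        control$delta_lo <- control$delta_lo / 1.3
      }
      acc_win <- NULL; win_f <- c(0, 0); win_o <- c(0, 0)
    }

    if (it %% thin == 0) {
      krow <- krow + 1L
      row <- c(it, last_ll, state$lambda, sum(state$elen), state$pi)
      if (model == "OM") {
        row <- c(row, colMeans(state$omega))
      } else {
        row <- c(row, vapply(seq_len(K), function(k)
          mean(apply(matrix(state$F[, k, ], nsites, 20), 1, max)), 0))
      }
      tracem[krow, ] <- row
    }
    if (it %% ef_thin == 0) {
      erow <- erow + 1L
      if (model == "DS") F_draws[erow, , , ] <- state$F
      else omega_draws[erow, , ] <- state$omega
    }
    if (progress && it %% 500 == 0) {
      message(sprintf("sweep %d / %d, loglik %.2f", it, n_iter, last_ll))
    }
  }

  out <- list(
    model = model, K = K, nsites = nsites, ct = ct,
    trace = tibble::as_tibble(as.data.frame(tracem)),
    ef_iters = ef_keep,
    state = state,
    config = list(n_iter = n_iter, burnin = burnin, thin = thin,
                  ef_thin = ef_thin, seed = seed, root_cond = root_cond),
    acceptance = acc_tot, control = control
  )
  if (model == "DS") out$F_draws <- F_draws else out$omega_draws <- omega_draws
  class(out) <- "codon_fit"
  out
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("%s codon model fit: %d sites, K = %d, %d sweeps (burn-in %d)\n",
              x$model, x$nsites, x$K, x$config$n_iter, x$config$burnin))
  cat(sprintf("  mean post-burn-in loglik: %.2f\n",
              mean(x$trace$loglik[x$trace$iter > x$config$burnin])))
  invisible(x)
}

#' One full MCMC sweep on an explicit model state
#'
#' Refreshes the stochastic mapping and performs one cycle of
#' Metropolis-Hastings updates of all random effects and global parameters.
#' Exposed mainly for testing and for building custom samplers; [run_chain()]
#' is the user-facing loop.
#'
#' @inheritParams run_chain
#' @param state a model state as stored in a `codon_fit` (`lambda`, `elen`
#'   in postorder, `exch`, `pi`, `q4`, `root_cond`, and `F` or
#'   `omega`/`alpha`/`beta`).
#' @return list with the updated `state` and the sweep's mapping aggregates.
#' @export
mh_sweep <- function(state, aln, ct, model = c("DS", "OM"), ctrl = list()) {
  model <- match.arg(model)
  ta <- .tree_arrays(ct)
  tips <- .tips_for_cpp(aln, ct)
  control <- utils::modifyList(.default_ctrl(), ctrl)
  mode <- if (model == "DS") 0L else 1L
  sw <- cpp_sweep(ta$edge, state$elen, ta$econd, ta$ntip, tips,
                  .code_for_cpp(), state$q4, state$pi, mode,
                  if (model == "DS") state$F else array(1, c(1, 1, 20)),
                  if (model == "OM") state$omega else matrix(1, 1, 1),
                  if (model == "OM") state$alpha else 1,
                  if (model == "OM") state$beta else 1,
                  state$root_cond, cpp_map_ws(), 1L, control$nrep_re,
                  control$delta_hi, control$delta_lo, control$sigma_om, FALSE)
  if (model == "DS") state$F <- sw$F else state$omega <- sw$omega
  up <- .update_globals(state, sw, model, control, ncol(aln),
                        do_root_terms = TRUE)
  list(state = up$state, sweep = sw)
}

#' Sample one stochastic mapping of substitution histories
#'
#' Draws a complete substitution history (per-branch dwell segments and
#' substitution events, for every site) from its conditional distribution
#' given tip codons and the model parameters, by uniformization-based
#' endpoint-conditioned path sampling.
#'
#' @inheritParams run_chain
#' @param mut a [mutation_model()].
#' @param field a [fitness_field()] (DS) or [omega_field()] (OM).
#' @return list with `segments` (site, edge, state, dwell), `events` (site,
#'   edge, from, to), `nodestate` (nodes x sites codon indices), `loglik`
#'   (per-site pruning log-likelihoods) and `condwait` (total mapped time per
#'   condition).
#' @export
stochastic_map <- function(aln, ct, mut, field, root_cond = 0L) {
  ta <- .tree_arrays(ct)
  tips <- .tips_for_cpp(aln, ct)
  is_ds <- inherits(field, "fitness_field")
  sw <- cpp_sweep(ta$edge, ta$elen, ta$econd, ta$ntip, tips, .code_for_cpp(),
                  mut$Q, mut$pi, if (is_ds) 0L else 1L,
                  if (is_ds) unclass(field) else array(1, c(1, 1, 20)),
                  if (is_ds) matrix(1, 1, 1) else field$omega,
                  1, 1, as.integer(root_cond), cpp_map_ws(), 1L, 0L,
                  500, 50, 0.5, TRUE)
  list(segments = tibble::as_tibble(sw$segments),
       events = tibble::as_tibble(sw$events),
       nodestate = sw$nodestate, loglik = sw$loglik,
       condwait = sw$condwait, edge = ta$edge, elen = ta$elen,
       econd = ta$econd)
}

#' Pruning log-likelihood of an alignment under fixed parameters
#'
#' @inheritParams stochastic_map
#' @return numeric vector of per-site log-likelihoods.
#' @export
site_loglik <- function(aln, ct, mut, field, root_cond = 0L) {
  ta <- .tree_arrays(ct)
  tips <- .tips_for_cpp(aln, ct)
  is_ds <- inherits(field, "fitness_field")
  sw <- cpp_sweep(ta$edge, ta$elen, ta$econd, ta$ntip, tips, .code_for_cpp(),
                  mut$Q, mut$pi, if (is_ds) 0L else 1L,
                  if (is_ds) unclass(field) else array(1, c(1, 1, 20)),
                  if (is_ds) matrix(1, 1, 1) else field$omega,
                  1, 1, as.integer(root_cond), cpp_map_ws(), 0L, 0L,
                  500, 50, 0.5, FALSE)
  sw$loglik
}
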