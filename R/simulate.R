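# Forward simulation of codon alignments along a conditioned tree, by exact
# event-driven (Gillespie) simulation of the DS or OM substitution process.
# Full histories are kept so that counting statistics (realized dN/dS,
# per-branch substitution counts) can be computed from the same run.

#' Simulate a codon alignment under a DS or OM process
#'
#' Draws the root codon of every site from the stationary distribution of the
#' root condition's generator, then simulates the substitution process
#' branch by branch (each branch using the generator of its condition) with
#' an exact event-driven algorithm, so the full substitution history is
#' available, not just the tip states.
#'
#' @param ct a `conditioned_tree` carrying topology, branch lengths and
#'   per-branch conditions.
#' @param mut a [mutation_model()].
#' @param field a [fitness_field()] (DS process) or [omega_field()] (OM
#'   process); its site dimension sets the number of simulated sites.
#' @param seed optional integer seed.
#' @param root_cond condition (0-based) whose stationary distribution is
#'   used at the root.
#' @param return_events keep the full event list (site, edge, time, from,
#'   to codon) — needed for history-level tests, off by default.
#' @return a `codon_sim` object: list with `aln` (a `codon_alignment` of the
#'   tips), `rootstate`, per-condition substitution counts (`nsyn`,
#'   `nnonsyn`) and neutral opportunity integrals (`syn_opp`, `ns_opp`),
#'   `edge_subs` (substitutions per branch), and optionally `events`.
#' @export
simulate_alignment <- function(ct, mut, field, seed = NULL, root_cond = 0L,
                               return_events = FALSE) {
  stopifnot(inherits(ct, "conditioned_tree"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  is_ds <- inherits(field, "fitness_field")
  if (!is_ds && !inherits(field, "omega_field")) {
    stop("`field` must be a fitness_field or omega_field", call. = FALSE)
  }
  K_field <- if (is_ds) dim(field)[2] else ncol(field$omega)
  if (K_field < ct$K) {
    stop("field has fewer conditions than the tree", call. = FALSE)
  }
  ta <- .tree_arrays(ct)
  sim <- cpp_simulate(ta$edge, ta$elen, ta$econd, ta$ntip, .code_for_cpp(),
                      mut$Q, mut$pi, if (is_ds) 0L else 1L,
                      if (is_ds) unclass(field) else array(1, c(1, 1, 20)),
                      if (is_ds) matrix(1, 1, 1) else field$omega,
                      as.integer(root_cond), return_events)
  gc <- genetic_code()
  tips <- sim$tips
  rownames(tips) <- ct$tree$tip.label
  aln <- structure(tips, n_nuc = 3L * ncol(tips),
                   class = c("codon_alignment", "matrix", "array"))
  out <- list(aln = aln, rootstate = sim$rootstate,
              nsyn = sim$nsyn, nnonsyn = sim$nnonsyn,
              syn_opp = sim$syn_opp, ns_opp = sim$ns_opp,
              edge_subs = sim$edge_subs, ct = ct, mut = mut, field = field,
              root_cond = as.integer(root_cond))
  if (return_events) out$events <- tibble::as_tibble(sim$events)
  class(out) <- "codon_sim"
  out
}

#' Counting-based realized dN/dS of a simulated history
#'
#' The ratio of the observed non-synonymous substitution count to its
#' expectation under the neutral mutation process (given the occupied states
#' and dwell times of the history), divided by the same ratio for synonymous
#' substitutions. Under a neutral process this converges to 1; an OM process
#' with constant omega converges to omega; a single-condition DS process at
#' stationarity stays below 1.
#'
#' @param sim a `codon_sim` from [simulate_alignment()].
#' @param condition optional condition index (0-based) to restrict the
#'   counting to; default pools all conditions.
#' @return numeric scalar; `NA` with a warning when there is no synonymous
#'   opportunity or no synonymous substitution to normalize by.
#' @export
realized_dnds <- function(sim, condition = NULL) {
  stopifnot(inherits(sim, "codon_sim"))
  idx <- if (is.null(condition)) seq_along(sim$nsyn) else condition + 1L
  ns <- sum(sim$nnonsyn[idx]); s <- sum(sim$nsyn[idx])
  ns_opp <- sum(sim$ns_opp[idx]); s_opp <- sum(sim$syn_opp[idx])
  if (s_opp <= 0 || s == 0) {
    warning("no synonymous substitutions/opportunity; dN/dS undefined")
    return(NA_real_)
  }
  (ns / ns_opp) / (s / s_opp)
}

# fixed mutation model used by all benchmark fixtures: transition bias 2,
# uniform base composition (keeps codon-multiplicity effects symmetric)
.fixture_mutation <- function() {
  mutation_model(c(1, 2, 1, 1, 2, 1), rep(0.25, 4))
}

# 20-taxon fixture topology: a caterpillar backbone of interior branches
# with alternating C3 and C4 terminal lineages, so each terminal branch is
# its own maximal phenotype-pure clade -- ten independent origins of each
# condition, the extreme form of repeated convergent transitions; terminal
# branches are long enough for each lineage to approach its condition's
# mutation-selection balance
.fixture_tree <- function(terminal = 3.5, backbone = 0.15) {
  tips <- as.vector(rbind(paste0("C3_", 1:10), paste0("C4_", 1:10)))
  txt <- sprintf("(%s:%.2f,%s:%.2f)", tips[1], terminal, tips[2], terminal)
  for (t in tips[-(1:2)]) {
    txt <- sprintf("(%s:%.2f,%s:%.2f)", txt, backbone, t, terminal)
  }
  ape::read.tree(text = paste0(txt, ";"))
}

.fixture_phenotypes <- function(tree) {
  stats::setNames(ifelse(grepl("^C4", tree$tip.label), "C4", "C3"),
                  tree$tip.label)
}

# injected differential effects of the "ds3-small" preset: at each listed
# site the up amino acid's fitness is 4x higher under C4 than C3 and the
# down amino acid's 4x lower (|D| = log 4), on an otherwise flat background
# all pairs are transition-coupled single-nucleotide neighbours with
# (nearly) balanced codon counts (T/A, K/E, N/D, H/Y), so the two states
# exchange fast and neither is favoured by codon multiplicity
.ds3_small_truth <- function() {
  tibble::tibble(
    site = c(10L, 35L, 60L, 85L),
    aa_down = c("T", "K", "N", "H"),
    aa_up   = c("A", "E", "D", "Y"),
    D = log(4)
  )
}

.inject_profile <- function(aa_hi, aa_lo, p_hi = 0.7992, p_lo = 0.1998) {
  f <- rep((1 - p_hi - p_lo) / 18, 20)
  f[match(aa_hi, aa_alphabet())] <- p_hi
  f[match(aa_lo, aa_alphabet())] <- p_lo
  f
}

#' Generate a self-contained benchmark fixture on disk
#'
#' Simulates a codon alignment with known parameters and writes the four
#' files an end-to-end analysis consumes: `alignment.fasta`, `tree.nwk`,
#' `phenotypes.tsv`, and a `truth.json` sidecar recording the generating
#' parameters. Presets:
#'
#' * `"ds3-small"`: 20 taxa (ten independent C3 and ten independent C4
#'   terminal lineages on an interior backbone), 100 codon sites under the
#'   DS3 process; 96 null sites share one strongly concentrated profile
#'   across all conditions (emulating the near-invariance of most positions
#'   of a conserved protein), and 4 sites carry injected differential
#'   effects of magnitude `|D| = log 4` between C3 and C4 (listed in the
#'   sidecar).
#' * `"om1-small"`: same tree, single condition, OM process with omega 0.2
#'   at 95 sites and omega 4 at 5 positively selected sites.
#' * `"neutral"`: same tree, single condition, omega 1 at all 100 sites
#'   (false-positive control).
#'
#' @param preset `"ds3-small"`, `"om1-small"` or `"neutral"`.
#' @param dir output directory (created if missing).
#' @param seed integer seed; the same preset and seed give byte-identical
#'   files.
#' @return invisibly, a list with the file `paths`, the `truth` parameters
#'   (including the full fitness/omega fields), the `ct` used, and the
#'   simulated `sim` object.
#' @export
make_benchmark_fixture <- function(preset = c("ds3-small", "om1-small", "neutral"),
                                   dir, seed = 1) {
  preset <- match.arg(preset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(as.integer(seed))
  # the DS benchmark needs deep condition branches (amino-acid preference
  # contrasts build up slowly); the omega benchmarks need moderate
  # divergence, because dN/dS likelihoods flatten once branches saturate
  tree <- if (preset == "ds3-small") .fixture_tree(3.5) else .fixture_tree(0.4)
  phen <- .fixture_phenotypes(tree)
  mut <- .fixture_mutation()
  nsites <- 100L

  if (preset == "ds3-small") {
    ct <- allocate_conditions(tree, phen, "ds3")
    truth_tab <- .ds3_small_truth()
    # null sites share one concentrated profile across all conditions,
    # emulating the strong per-site conservation of a slowly evolving
    # protein (one amino acid overwhelmingly favoured at most positions)
    F <- array(NA_real_, c(nsites, 3, 20))
    for (i in seq_len(nsites)) {
      g <- stats::rgamma(20, shape = 0.02, rate = 1)
      base <- pmax(g, 1e-8) / sum(pmax(g, 1e-8))
      for (k in 1:3) F[i, k, ] <- base
    }
    for (r in seq_len(nrow(truth_tab))) {
      i <- truth_tab$site[r]
      c3 <- .inject_profile(truth_tab$aa_down[r], truth_tab$aa_up[r])
      c4 <- .inject_profile(truth_tab$aa_up[r], truth_tab$aa_down[r])
      F[i, 1, ] <- c3  # ancestral condition matches C3
      F[i, 2, ] <- c3
      F[i, 3, ] <- c4
    }
    field <- fitness_field(F)
    truth <- list(preset = preset, seed = seed, model = "DS", K = 3,
                  injected = as.list(truth_tab),
                  exchangeabilities = mut$exchangeabilities, pi = mut$pi)
  } else {
    ct <- conditioned_tree(tree, rep(0L, nrow(tree$edge)), K = 1L)
    omega <- if (preset == "neutral") {
      matrix(1, nsites, 1)
    } else {
      w <- rep(0.2, nsites)
      w[c(12L, 30L, 48L, 66L, 90L)] <- 4
      matrix(w, ncol = 1)
    }
    field <- omega_field(omega)
    truth <- list(preset = preset, seed = seed, model = "OM", K = 1,
                  omega = as.vector(omega),
                  positive_sites = if (preset == "om1-small")
                    c(12L, 30L, 48L, 66L, 90L) else integer(0),
                  exchangeabilities = mut$exchangeabilities, pi = mut$pi)
  }

  sim <- simulate_alignment(ct, mut, field, root_cond = 0L)
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_alignment_fasta(sim$aln, paths$alignment)
  ape::write.tree(tree, paths$tree)
  utils::write.table(
    data.frame(taxon = names(phen), phenotype = unname(phen)),
    paths$phenotypes, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, ct = ct, mut = mut,
                 field = field, sim = sim))
}
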