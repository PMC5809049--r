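#' End-to-end analysis: two chains, diagnostics, and the site report
#'
#' The standard pipeline for one model family on one dataset: validates that
#' alignment, tree and phenotypes name the same taxa, builds the
#' branch-condition partition implied by the model (DS3/OM3 use the
#' three-condition scheme, DS2 the two-condition scheme, OM1 a single
#' condition), runs two independent MCMC chains with seeds `seed` and
#' `seed + 1`, computes cross-chain convergence diagnostics and the
#' posterior decision tables from the pooled post-burn-in draws, and
#' (optionally) writes every table to an output directory with a manifest.
#'
#' @param alignment a `codon_alignment` or path to a FASTA/PHYLIP file.
#' @param tree an [ape::phylo], a `conditioned_tree`, or path to a Newick
#'   file.
#' @param phenotypes named character vector or path to a two-column TSV;
#'   required for DS2/DS3/OM3.
#' @param model `"DS3"`, `"DS2"`, `"OM1"` or `"OM3"`.
#' @param n_iter,burnin chain length and burn-in (defaults 6000 / 400).
#' @param seed integer; the chains use `seed` and `seed + 1`.
#' @param pp_threshold posterior-probability cutoff for site calls.
#' @param offset added to alignment columns for reported coordinates.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @param derived,ancestral phenotype labels (see [allocate_conditions()]).
#' @param ... further arguments to [run_chain()] (`thin`, `ef_thin`,
#'   `ctrl`, `progress`).
#' @return a `codonDS_run` list: `fits` (two `codon_fit`s), `diagnostics`,
#'   `effects` (DS) or `calls` (OM), `report`, `logos` (DS),
#'   `chain_agreement` (per-effect posterior means chain 1 vs chain 2), and
#'   the configuration.
#' @export
run_analysis <- function(alignment, tree, phenotypes = NULL,
                         model = c("DS3", "DS2", "OM1", "OM3"),
                         n_iter = 6000, burnin = 400, seed = 1,
                         pp_threshold = 0.9, offset = 0, outdir = NULL,
                         derived = "C4", ancestral = "C3", ...) {
  model <- match.arg(model)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(tree) && length(tree) == 1L) tree <- read_newick(tree)
  # a length-1 unnamed character is a file path; a named vector is the map
  if (is.character(phenotypes) && length(phenotypes) == 1L &&
      is.null(names(phenotypes))) {
    phenotypes <- read_phenotypes(phenotypes)
  }

  ct <- if (inherits(tree, "conditioned_tree")) {
    tree
  } else if (model == "OM1") {
    conditioned_tree(tree, rep(0L, nrow(tree$edge)), K = 1L)
  } else {
    if (is.null(phenotypes)) {
      stop("model ", model, " needs tip phenotypes", call. = FALSE)
    }
    allocate_conditions(tree, phenotypes,
                        scheme = if (model == "DS2") "ds2" else "ds3",
                        derived = derived, ancestral = ancestral)
  }
  check_taxa(alignment, ct, phenotypes)
  family <- if (startsWith(model, "DS")) "DS" else "OM"

  fits <- lapply(c(seed, seed + 1L), function(s) {
    run_chain(alignment, ct, model = family, n_iter = n_iter,
              burnin = burnin, seed = s, ...)
  })
  diag <- diagnostics(fits[[1]], fits[[2]])

  out <- list(model = model, ct = ct, fits = fits, diagnostics = diag,
              config = list(model = model, n_iter = n_iter, burnin = burnin,
                            seed = seed, pp_threshold = pp_threshold,
                            offset = offset))
  if (family == "DS") {
    out$effects <- differential_effects(fits, threshold = pp_threshold,
                                        offset = offset)
    out$logos <- logo_matrices(fits, offset = offset)
    out$report <- site_report(ds = out$effects)
    e1 <- differential_effects(fits[[1]], threshold = pp_threshold,
                               offset = offset)
    e2 <- differential_effects(fits[[2]], threshold = pp_threshold,
                               offset = offset)
    out$chain_agreement <- tibble::tibble(
      site = e1$site, aa = e1$aa,
      mean_D_chain1 = e1$mean_D, mean_D_chain2 = e2$mean_D)
  } else {
    out$calls <- omega_site_calls(fits, threshold = pp_threshold,
                                  offset = offset)
    out$report <- if (model == "OM1") {
      site_report(om1 = out$calls)
    } else {
      site_report(om3 = out$calls)
    }
    c1 <- omega_site_calls(fits[[1]], threshold = pp_threshold, offset = offset)
    c2 <- omega_site_calls(fits[[2]], threshold = pp_threshold, offset = offset)
    out$chain_agreement <- tibble::tibble(
      site = c1$site, condition = c1$condition,
      mean_omega_chain1 = c1$mean_omega, mean_omega_chain2 = c2$mean_omega)
  }
  class(out) <- "codonDS_run"

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    wr <- function(x, nm) write_site_tsv(x, file.path(outdir, nm))
    wr(fits[[1]]$trace, "trace_chain1.tsv")
    wr(fits[[2]]$trace, "trace_chain2.tsv")
    wr(diag, "diagnostics.tsv")
    wr(out$report, "site_report.tsv")
    wr(out$chain_agreement, "chain_agreement.tsv")
    if (family == "DS") {
      wr(out$effects, "differential_effects.tsv")
      wr(out$logos$absolute, "logo_absolute.tsv")
      wr(out$logos$differential, "logo_differential.tsv")
    } else {
      wr(out$calls, "omega_site_calls.tsv")
    }
    manifest <- list(model = model, n_iter = n_iter, burnin = burnin,
                     seed = seed, pp_threshold = pp_threshold,
                     offset = offset,
                     n_taxa = nrow(alignment), n_sites = ncol(alignment),
                     files = list.files(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.codonDS_run <- function(x, ...) {
  cat(sprintf("%s analysis: %d sites, 2 chains x %d sweeps (burn-in %d)\n",
              x$model, x$fits[[1]]$nsites, x$config$n_iter, x$config$burnin))
  cat(sprintf("  max cross-chain discrepancy: %.3f; min ESS: %.0f\n",
              max(x$diagnostics$discrepancy), min(x$diagnostics$min_ess)))
  cat(sprintf("  sites reported at pp > %.2f: %d\n",
              x$config$pp_threshold, nrow(x$report)))
  invisible(x)
}
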