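# One-call pipeline: structure -> elastic network -> essential modes ->
# per-protein curves -> correlation tables -> per-filter cooperativity
# counts, with optional persisted intermediates (TSV) and a JSON report.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis.  Exactly one of `pdb` (a file
#' path) or `structure` (a `mol_structure`) must be given; `pairs` may
#' override [make_pairs()] with explicit `pair_spec`s (e.g. to analyse two
#' identical pairs as a control).
#'
#' @param pdb Path to the input PDB file, or `NULL`.
#' @param structure A `mol_structure`, or `NULL`.
#' @param sox_chain Chain id of the HMG (Sox) protein.
#' @param split A [subunit_split()] for the POU chain.
#' @param cutoff,gamma,granularity,mass_weighted Elastic-network parameters
#'   (see [build_network()]); mass weighting defaults off.
#' @param n_essential Number of essential modes (default 10).
#' @param p_grid Length fractions (default `1.0, 0.9, ..., 0.5`).
#' @param filters Filter methods to apply (default all four).
#' @param curve_family `"magnitude"`, `"angle-pc1"` or `"angle-fourier"`.
#' @param angle_representative `"centroid"` or `"c-alpha"` (angle curves).
#' @param angle_amplitude Deformation scale for angle curves: the eigenvector
#'   is scaled so the maximum per-atom displacement equals this many
#'   Angstrom (default 1).
#' @param search Segment search strategy (see [best_segment_pair()]).
#' @param seed Integer seed (recorded in the report; the analysis itself is
#'   deterministic).
#' @param output_dir Directory for the report and intermediates, or `NULL`
#'   to skip writing.
#' @param pairs Optional list(pair1, pair2) of `pair_spec`s.
#' @param verbose Emit stage log messages (default `FALSE`).
#' @return A `run_config`.
#' @export
pipeline_config <- function(pdb = NULL, structure = NULL, sox_chain = "B",
                            split = NULL, cutoff = 10, gamma = 1,
                            granularity = "all-atom", mass_weighted = FALSE,
                            n_essential = 10,
                            p_grid = seq(1, 0.5, by = -0.1),
                            filters = c("median", "tertile", "quartile", "mean"),
                            curve_family = c("magnitude", "angle-pc1", "angle-fourier"),
                            angle_representative = c("centroid", "c-alpha"),
                            angle_amplitude = 1.0,
                            search = c("all", "shift"),
                            seed = 1, output_dir = NULL, pairs = NULL,
                            verbose = FALSE) {
  curve_family <- match.arg(curve_family)
  angle_representative <- match.arg(angle_representative)
  search <- match.arg(search)
  stopifnot(all(p_grid > 0), all(p_grid <= 1), n_essential >= 1,
            cutoff > 0, gamma > 0, angle_amplitude > 0)
  filters <- match.arg(filters, c("median", "tertile", "quartile", "mean"),
                       several.ok = TRUE)
  if (is.null(pdb) && is.null(structure))
    stop("one of `pdb` or `structure` is required")
  structure(list(pdb = pdb, structure = structure, sox_chain = sox_chain,
                 split = split, cutoff = cutoff, gamma = gamma,
                 granularity = granularity, mass_weighted = mass_weighted,
                 n_essential = n_essential, p_grid = p_grid, filters = filters,
                 curve_family = curve_family,
                 angle_representative = angle_representative,
                 angle_amplitude = angle_amplitude, search = search,
                 seed = as.integer(seed), output_dir = output_dir,
                 pairs = pairs, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror [pipeline_config()] arguments; the subunit split is
#' given as `split: {chain: A, pou_s: [1, 25], pou_hd: [30, 60]}`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$split))
    y$split <- subunit_split(y$split$chain, unlist(y$split$pou_s),
                             unlist(y$split$pou_hd))
  if (!is.null(y$p_grid)) y$p_grid <- as.numeric(unlist(y$p_grid))
  if (!is.null(y$filters)) y$filters <- as.character(unlist(y$filters))
  do.call(pipeline_config, y)
}

#' Run the full cooperativity pipeline
#'
#' Executes structure reading, elastic-network construction,
#' diagonalisation, curve extraction for the four proteins (two pairs),
#' correlation-table assembly and per-filter S1/S2/D counting.  For
#' `curve_family = "angle-pc1"` each protein's angle curves are first
#' condensed to one curve and a single per-p correlation column is produced
#' per pair; for `"angle-fourier"` the magnitude spectra of the angle curves
#' replace the curves and the full p-by-mode machinery runs.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, the report: configuration echo, essential eigenvalues,
#'   correlation tables, per-p medians, per-filter counts and per-row
#'   significant-entry diagnostics.  Written as JSON + TSV when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(fmt, ...) {
    if (config$verbose) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
                                sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_stage(name, conditionMessage(e)))
    log_msg("%s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  st <- stage("structure", {
    if (!is.null(config$structure)) config$structure else read_pdb(config$pdb)
  })
  prs <- stage("pairs", {
    if (!is.null(config$pairs)) config$pairs
    else {
      split <- config$split %||% attr(st, "split")
      if (is.null(split)) stop("no subunit split configured")
      make_pairs(st, config$sox_chain, split)
    }
  })
  net <- stage("network", build_network(st, config$cutoff, config$gamma,
                                        config$granularity))
  modes <- stage("modes", {
    H <- build_anm_hessian(net)
    if (config$mass_weighted) H <- mass_weight(H, net$masses)
    compute_modes(H, config$n_essential, network = net)
  })

  proteins <- list(pair1_a = prs$pair1$protein_a, pair1_b = prs$pair1$protein_b,
                   pair2_a = prs$pair2$protein_a, pair2_b = prs$pair2$protein_b)
  family <- config$curve_family
  curves <- stage("curves", {
    lapply(proteins, function(prot) {
      cl <- lapply(modes$mode_numbers, function(k) {
        disp <- mode_displacements(modes, net, k, amplitude = 1)
        if (family == "magnitude") {
          magnitude_curve(disp, st, prot, mode_number = k)
        } else {
          scale <- config$angle_amplitude / max(sqrt(rowSums(disp^2)))
          rotation_angle_curve(st, deform(st, scale * disp), prot,
                               representative = config$angle_representative,
                               mode_number = k,
                               amplitude_used = config$angle_amplitude)
        }
      })
      names(cl) <- modes$mode_numbers
      if (family == "angle-fourier") {
        cl <- lapply(cl, fourier_magnitude)
        names(cl) <- modes$mode_numbers
      }
      cl
    })
  })

  tables <- stage("correlate", {
    if (family == "angle-pc1") {
      cond <- lapply(curves, pc1_condense)
      mk <- function(a, b, id) correlation_table(list(cond[[a]]), list(cond[[b]]),
                                                 p_grid = config$p_grid,
                                                 mode_numbers = "pc1",
                                                 pair_id = id,
                                                 search = config$search)
      list(pair1 = mk("pair1_a", "pair1_b", 1L),
           pair2 = mk("pair2_a", "pair2_b", 2L))
    } else {
      list(pair1 = correlation_table(curves$pair1_a, curves$pair1_b,
                                     p_grid = config$p_grid,
                                     mode_numbers = modes$mode_numbers,
                                     pair_id = 1L, search = config$search),
           pair2 = correlation_table(curves$pair2_a, curves$pair2_b,
                                     p_grid = config$p_grid,
                                     mode_numbers = modes$mode_numbers,
                                     pair_id = 2L, search = config$search))
    }
  })

  stats <- stage("stats", {
    out <- list()
    for (f in config$filters) {
      lp1 <- logic_pair(tables$pair1, f)
      lp2 <- logic_pair(tables$pair2, f)
      cc <- coop_counts(lp1, lp2)
      out[[f]] <- list(counts = unclass(cc),
                       n_sig_per_row = list(pair1 = unname(lp1$n_sig_per_row),
                                            pair2 = unname(lp2$n_sig_per_row)),
                       thresholds = list(pair1 = unname(lp1$thresholds),
                                         pair2 = unname(lp2$thresholds)))
    }
    out
  })
  medians <- summarize_medians(tables$pair1, tables$pair2)

  report <- list(
    config = list(pdb = config$pdb, sox_chain = config$sox_chain,
                  cutoff = config$cutoff, gamma = config$gamma,
                  granularity = config$granularity,
                  mass_weighted = config$mass_weighted,
                  n_essential = config$n_essential, p_grid = config$p_grid,
                  filters = config$filters, curve_family = config$curve_family,
                  angle_representative = config$angle_representative,
                  angle_amplitude = config$angle_amplitude,
                  search = config$search, seed = config$seed),
    n_atoms = n_atoms(st), n_residues = n_residues(st),
    proteins = lapply(proteins, function(p)
      list(label = p$label, chain = p$chain, n_residues = length(p$rows))),
    essential_modes = list(numbers = modes$mode_numbers,
                           eigenvalues = modes$values[modes$mode_numbers]),
    lambdas = list(pair1 = tables$pair1$lambdas, pair2 = tables$pair2$lambdas),
    tables = list(pair1 = unname(apply(tables$pair1$values, 1, identity,
                                       simplify = FALSE)),
                  pair2 = unname(apply(tables$pair2$values, 1, identity,
                                       simplify = FALSE))),
    medians = medians,
    filters = stats)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_correlation_tsv(tables$pair1, file.path(config$output_dir, "table_pair1.tsv"))
    write_correlation_tsv(tables$pair2, file.path(config$output_dir, "table_pair2.tsv"))
    write.table(medians, file.path(config$output_dir, "medians.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("report written to %s", config$output_dir)
  }
  invisible(report)
}
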