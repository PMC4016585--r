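#' Run the full module-detection pipeline
#'
#' Orchestrates every stage: input acquisition (simulation, homologous
#' structures through an alignment, or a trajectory), per-dimension
#' correlations with Fisher filtering, `Xi` aggregation and graph
#' construction, fast-greedy community detection, permutation-test
#' refinement, power summary and bootstrap support.  One master seed
#' deterministically derives the per-stage seeds (simulation, permutation,
#' bootstrap), so re-running with the same configuration reproduces every
#' output bit-identically.
#'
#' @param mode `"simulate"`, `"homologs"` or `"trajectory"`.
#' @param blocks,n_noise,dims,n_obs simulation design (see
#'   [sample_ensemble()]); defaults reproduce the standard one-module
#'   validation setup: one 30-landmark block at correlation 0.35 over 70
#'   noise landmarks, two dimensions, 85 observations.
#' @param pdb_paths PDB file paths (homologs: one per structure;
#'   trajectory: a single multi-model file).
#' @param alignment aligned FASTA path (homologs mode).
#' @param ensemble optionally, a ready-made [coord_ensemble()]; skips input
#'   acquisition (contacts may still be supplied via `contacts`).
#' @param contacts optional pre-computed contact map (simulate mode treats
#'   all pairs as in contact when `NULL`).
#' @param contact_cutoff,consensus contact definition (see
#'   [compute_contacts()]).
#' @param alpha significance level shared by the Fisher filter, the
#'   refinement and the power summary.
#' @param power target power for the resolvable-correlation computation.
#' @param B_perm permutations per refinement test in the main run.
#' @param B_boot bootstrap replicates (0 skips the bootstrap).
#' @param boot_B_perm permutations per refinement test inside bootstrap
#'   replicates.
#' @param refine_in_boot rerun the refinement inside replicates.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, write `membership.csv`, `modules.tsv`,
#'   `edges.tsv`, `contacts.tsv` (structural modes) and `manifest.json`
#'   there.
#' @param quiet suppress progress messages.
#' @return An object of class `module_report`: list with `modules` (a
#'   data.frame with one row per final cluster: `module`, `size`,
#'   `p_adj_max`, `significant`, `rho_res`, `pvp`, `boot_support`,
#'   `members`), `refined`, `partition`, `graph`, `stack`, `ensemble`,
#'   `contacts` and `config`.
#' @export
run_pipeline <- function(mode = c("simulate", "homologs", "trajectory"),
                         blocks = list(c(30, 0.35)), n_noise = 70L,
                         dims = 2L, n_obs = 85L,
                         pdb_paths = NULL, alignment = NULL,
                         ensemble = NULL, contacts = NULL,
                         contact_cutoff = 4.5, consensus = 0.5,
                         alpha = 0.05, power = 0.8,
                         B_perm = 999L, B_boot = 100L, boot_B_perm = 199L,
                         refine_in_boot = TRUE,
                         seed = 1L, out_dir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, 3L)
  # -- input stage -----------------------------------------------------
  if (is.null(ensemble)) {
    if (mode == "simulate") {
      msg("simulate: drawing ", n_obs, " observations", quiet = quiet)
      ensemble <- sample_ensemble(blocks, n_noise = n_noise, dims = dims,
                                  n_obs = n_obs, seed = seeds[[1L]])
    } else {
      if (is.null(pdb_paths) || length(pdb_paths) == 0L)
        stop("no structures found")
      msg("structures: reading ", length(pdb_paths), " path(s)",
          quiet = quiet)
      records <- read_structures(pdb_paths, mode = mode)
      map <- if (mode == "homologs") {
        if (is.null(alignment)) stop("homologs mode requires an alignment")
        alignment_map(alignment, records)
      } else identity_map(records)
      ensemble <- compute_landmarks(records, map)
      if (is.null(contacts)) {
        struct_idx <- if (mode == "trajectory") 1L else seq_along(records)
        contacts <- compute_contacts(records, map, cutoff = contact_cutoff,
                                     consensus = consensus,
                                     structures = struct_idx)
      }
    }
  }
  # -- correlation graph -----------------------------------------------
  msg("corrgraph: ", length(ensemble$landmark_ids), " landmarks x ",
      ensemble$dims, " dims", quiet = quiet)
  stack <- fisher_filter(per_dimension_correlations(ensemble), alpha = alpha)
  graph <- build_graph(xi_aggregate(stack), contacts,
                       landmark_ids = ensemble$landmark_ids)
  # -- community detection + refinement --------------------------------
  partition <- fast_greedy_partition(graph)
  msg(sprintf("community: %d clusters, Q = %.3f",
              length(partition$clusters), partition$q), quiet = quiet)
  refined <- refine_partition(partition, stack, alpha = alpha,
                              B_perm = B_perm, seed = seeds[[2L]])
  msg(sprintf("sigtest: %d cluster(s) after %d iteration(s)",
              length(refined$clusters), refined$n_iterations), quiet = quiet)
  # -- power -----------------------------------------------------------
  rho_res <- resolvable_correlation(ensemble$n_obs, alpha = alpha,
                                    power = power)
  pvp <- vapply(refined$clusters, function(m)
    suppressWarnings(cluster_pvp(m, stack, rho_res)), 0)
  # -- bootstrap -------------------------------------------------------
  support <- if (B_boot >= 1L) {
    msg("bootstrap: ", B_boot, " replicates", quiet = quiet)
    bootstrap_support(ensemble, refined$clusters, contacts = contacts,
                      B_boot = B_boot, seed = seeds[[3L]],
                      refine = refine_in_boot, alpha = alpha,
                      B_perm = boot_B_perm)
  } else setNames(rep(NA_real_, length(refined$clusters)),
                  names(refined$clusters))
  # -- report ----------------------------------------------------------
  modules <- data.frame(
    module = names(refined$clusters),
    size = lengths(refined$clusters),
    p_adj_max = refined$significance[names(refined$clusters)],
    significant = !is.na(refined$significance[names(refined$clusters)]) &
      refined$significance[names(refined$clusters)] <= alpha,
    rho_res = rho_res,
    pvp = pvp[names(refined$clusters)],
    boot_support = as.numeric(support[names(refined$clusters)]),
    members = vapply(refined$clusters, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  config <- list(mode = mode, alpha = alpha, power = power,
                 B_perm = B_perm, B_boot = B_boot,
                 boot_B_perm = boot_B_perm, refine_in_boot = refine_in_boot,
                 contact_cutoff = contact_cutoff, consensus = consensus,
                 seed = seed, n_obs = ensemble$n_obs,
                 n_landmarks = length(ensemble$landmark_ids),
                 dims = ensemble$dims,
                 blocks = if (mode == "simulate") blocks else NULL,
                 n_noise = if (mode == "simulate") n_noise else NULL,
                 package_version = as.character(utils::packageVersion("modulyzer")))
  report <- structure(list(modules = modules, refined = refined,
                           partition = partition, graph = graph,
                           stack = stack, ensemble = ensemble,
                           contacts = contacts, config = config),
                      class = "module_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.module_report <- function(x, ...) {
  cat("module_report\n")
  df <- x$modules
  df$members <- NULL
  print(df, digits = 3)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `membership.csv` (landmark, cluster), `modules.tsv` (the module
#' table), `edges.tsv` (the weighted edge list), `tests.tsv` (every
#' refinement test) and `manifest.json` (full configuration, for exact
#' reruns).
#'
#' @param report a `module_report` from [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "module_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  memb <- data.frame(landmark = names(report$refined$membership),
                     cluster = as.vector(report$refined$membership))
  write.csv(memb, file.path(out_dir, "membership.csv"), row.names = FALSE)
  write.table(report$modules, file.path(out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(graph_edges(report$graph), file.path(out_dir, "edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$refined$tests, file.path(out_dir, "tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$contacts))
    write_contact_tsv(report$contacts, report$graph$landmark_ids,
                      file.path(out_dir, "contacts.tsv"))
  jsonlite::write_json(report$config, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
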