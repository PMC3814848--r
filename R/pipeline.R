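#' Configuration of the full analysis pipeline
#'
#' @param cohort A `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]); alternatively `input_dir` names a cohort directory.
#' @param input_dir Directory holding a cohort written by [write_cohort()].
#' @param fn_threshold Minimum fiber count for a connection (default 10).
#' @param backbone_alpha Sign-test level before Bonferroni (default 0.05).
#' @param n_null_networks Null-ensemble size for small-worldness
#'   (default 1000).
#' @param null_seed Seed for the null ensembles.
#' @param fdr_q FDR level for nodal comparisons (default 0.05).
#' @param group_order Optional explicit developmental ordering of group
#'   labels; defaults to the cohort's own order.
#' @param match_sparsity_groups If `TRUE`, backbones are additionally
#'   re-analyzed after trimming all groups to the smallest group backbone
#'   sparsity, and modularity is reported both raw and sparsity-matched.
#' @param output_dir Where report CSVs and the run manifest are written;
#'   `NULL` keeps everything in memory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            fn_threshold = 10, backbone_alpha = 0.05,
                            n_null_networks = 1000, null_seed = 1L,
                            fdr_q = 0.05, group_order = NULL,
                            match_sparsity_groups = TRUE,
                            output_dir = NULL) {
  if (is.null(cohort) && is.null(input_dir))
    stop("provide a cohort object or an input directory")
  if (fn_threshold < 1) stop("fn_threshold must be >= 1")
  if (backbone_alpha <= 0 || backbone_alpha > 1)
    stop("backbone_alpha must lie in (0, 1]")
  if (fdr_q <= 0 || fdr_q > 1) stop("fdr_q must lie in (0, 1]")
  if (n_null_networks < 1) stop("n_null_networks must be >= 1")
  structure(
    list(cohort = cohort, input_dir = input_dir, fn_threshold = fn_threshold,
         backbone_alpha = backbone_alpha, n_null_networks = n_null_networks,
         null_seed = as.integer(null_seed), fdr_q = fdr_q,
         group_order = group_order,
         match_sparsity_groups = match_sparsity_groups,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full developmental network analysis
#'
#' Executes, in order: per-subject network construction (fiber-count
#' threshold, FN*FA/volume weighting, mean-weight normalization),
#' per-subject global and nodal metrics, per-group backbone extraction,
#' small-worldness of each backbone against a degree-preserving null
#' ensemble, greedy module detection with participation coefficients and
#' hub classification per backbone, an optional sparsity-matched
#' re-analysis of backbone modularity, and adjacent-group statistics with
#' age and sex covariates. When `output_dir` is set, every table is written
#' as CSV/TSV together with a JSON manifest recording the configuration and
#' seeds; runs are deterministic given identical configuration and seeds.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print one progress line per stage and group.
#' @return A list of class `pipeline_result` with elements
#'   `subject_networks`, `global_metrics`, `nodal_metrics`, `backbones`,
#'   `small_world`, `modularity`, `group_stats`, `group_order` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- read_cohort(config$input_dir)
  group_order <- config$group_order
  if (is.null(group_order)) group_order <- cohort$group_order
  demo <- cohort$demographics

  say("stage 1/6: building %d subject networks (FN >= %d)",
      length(cohort$subjects), config$fn_threshold)
  nets <- lapply(cohort$subjects, function(s)
    normalize_by_mean_weight(build_network(s, config$fn_threshold)))
  names(nets) <- demo$subject_id

  say("stage 2/6: per-subject global and nodal metrics")
  per_subject <- lapply(seq_along(nets), function(i) {
    net <- nets[[i]]
    d <- shortest_path_distances(net)
    eg <- global_efficiency(net, d)
    part <- greedy_modularity(net)
    en <- nodal_efficiency(net, d)
    pc <- participation_coefficients(net, part)
    meta <- demo[i, c("subject_id", "group", "age", "sex")]
    list(
      global = cbind(meta, data.frame(
        S = total_strength(net), CC = weighted_clustering(net)$mean,
        L = if (eg > 0) 1 / eg else NA_real_, E_glob = eg,
        E_loc = local_efficiency(net), Q = part$Q), row.names = NULL),
      nodal = data.frame(
        subject_id = meta$subject_id, group = meta$group, age = meta$age,
        sex = meta$sex, region = rep(net$node_labels, 2),
        metric = rep(c("E_nodal", "PC"), each = net$N),
        value = c(en, pc), row.names = NULL))
  })
  gm <- do.call(rbind, lapply(per_subject, `[[`, "global"))
  nm_long <- do.call(rbind, lapply(per_subject, `[[`, "nodal"))

  say("stage 3/6: group backbones (sign test, alpha = %g, Bonferroni)",
      config$backbone_alpha)
  backbones <- lapply(group_order, function(g) {
    bb <- build_backbone(nets[demo$group == g], alpha = config$backbone_alpha)
    say("  %s: %d subjects, %d edges retained, sparsity %.4f", g,
        bb$n_subjects, bb$network$K, sparsity(bb$network))
    bb
  })
  names(backbones) <- group_order

  say("stage 4/6: small-worldness (%d nulls per group)",
      config$n_null_networks)
  sw <- do.call(rbind, lapply(seq_along(group_order), function(gi) {
    g <- group_order[gi]
    res <- small_worldness(backbones[[g]]$network,
                           n_networks = config$n_null_networks,
                           seed = config$null_seed + 1000L * gi)
    data.frame(group = g, CC = res$CC, L = res$L, CC_rand = res$CC_rand,
               L_rand = res$L_rand, gamma = res$gamma, lambda = res$lambda,
               sigma = res$sigma, n_nulls = res$n_networks, seed = res$seed)
  }))

  say("stage 5/6: backbone modularity, participation and hubs")
  bb_sparsities <- vapply(backbones, function(b) sparsity(b$network),
                          numeric(1))
  min_sparsity <- min(bb_sparsities)
  modularity_rows <- list()
  partitions <- list()
  nodal_tables <- list()
  for (g in group_order) {
    net <- backbones[[g]]$network
    part <- greedy_modularity(net)
    partitions[[g]] <- part
    nodal_tables[[g]] <- cbind(group = g, nodal_metrics(net, part))
    q_matched <- NA_real_
    if (config$match_sparsity_groups) {
      matched <- match_sparsity(net, min_sparsity)
      q_matched <- greedy_modularity(matched)$Q
    }
    say("  %s: %d modules, Q = %.3f%s", g, part$N_M, part$Q,
        if (is.na(q_matched)) "" else sprintf(" (sparsity-matched Q = %.3f)",
                                              q_matched))
    modularity_rows[[g]] <- data.frame(
      group = g, n_modules = part$N_M, Q = part$Q,
      Q_sparsity_matched = q_matched, sparsity = bb_sparsities[[g]],
      target_sparsity = min_sparsity)
  }
  modularity_tab <- do.call(rbind, modularity_rows)
  rownames(modularity_tab) <- NULL
  backbone_nodal <- do.call(rbind, nodal_tables)
  rownames(backbone_nodal) <- NULL

  say("stage 6/6: adjacent-group statistics (FDR q = %g for nodal maps)",
      config$fdr_q)
  stats_tab <- compare_adjacent_groups(
    gm[, c("subject_id", "group", "age", "sex", "S", "CC", "L", "E_glob",
           "E_loc", "Q")],
    nm_long, group_order, q = config$fdr_q)

  manifest <- list(
    fn_threshold = config$fn_threshold,
    backbone_alpha = config$backbone_alpha,
    n_null_networks = config$n_null_networks,
    null_seed = config$null_seed,
    fdr_q = config$fdr_q,
    group_order = group_order,
    match_sparsity_groups = config$match_sparsity_groups,
    cohort_seed = if (!is.null(cohort$spec)) cohort$spec$seed else NA,
    n_subjects = length(cohort$subjects),
    package_version = as.character(utils::packageVersion("devconnectome")),
    backbone_sparsities = as.list(bb_sparsities),
    min_backbone_sparsity = min_sparsity
  )

  result <- structure(
    list(subject_networks = nets, global_metrics = gm,
         nodal_metrics = nm_long, backbones = backbones, small_world = sw,
         modularity = modularity_tab, backbone_nodal = backbone_nodal,
         partitions = partitions, group_stats = stats_tab,
         group_order = group_order, manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

# Write every pipeline table plus the JSON run manifest.
write_pipeline_outputs <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$global_metrics,
                   file.path(dir, "global_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$nodal_metrics,
                   file.path(dir, "nodal_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$small_world, file.path(dir, "small_world.csv"),
                   row.names = FALSE)
  utils::write.csv(result$modularity, file.path(dir, "modularity.csv"),
                   row.names = FALSE)
  utils::write.csv(result$backbone_nodal,
                   file.path(dir, "backbone_nodal_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$group_stats, file.path(dir, "group_stats.csv"),
                   row.names = FALSE)
  for (g in result$group_order) {
    write_network_csv(result$backbones[[g]]$network,
                      file.path(dir, sprintf("backbone_%s.csv", g)))
    backbone_edge_report(result$backbones[[g]],
                         file.path(dir, sprintf("backbone_%s_edges.tsv", g)))
    part <- result$partitions[[g]]
    utils::write.table(
      data.frame(node_label = names(part$assignment),
                 module_id = part$assignment),
      file.path(dir, sprintf("modules_%s.tsv", g)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Developmental network analysis\n")
  cat(sprintf("  %d subjects, groups: %s\n", nrow(x$global_metrics),
              paste(x$group_order, collapse = " -> ")))
  cat("  backbone sparsity by group:",
      paste(sprintf("%.4f", vapply(x$backbones, function(b)
        sparsity(b$network), numeric(1))), collapse = ", "), "\n")
  cat("  small-world sigma by group:",
      paste(sprintf("%.2f", x$small_world$sigma), collapse = ", "), "\n")
  cat("  backbone Q by group:",
      paste(sprintf("%.3f", x$modularity$Q), collapse = ", "), "\n")
  sig <- x$group_stats[is.na(x$group_stats$region) & x$group_stats$significant, ]
  if (nrow(sig))
    cat("  significant global transitions:",
        paste(sprintf("%s (%s)", sig$metric, sig$transition), collapse = "; "),
        "\n")
  invisible(x)
}
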