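# TSV writer with '# key=value' metadata header and 10-significant-digit
# numeric serialization; deterministic (no timestamps), so identical runs
# produce byte-identical files.
write_stage_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

default_config <- function() {
  list(
    table = NULL, metadata = NULL, tree = NULL, responses = NULL,
    outdir = "microstab_out", seed = 1,
    rarefy = list(enabled = TRUE, depth = NULL),   # NULL depth = min sample total
    network = list(rho_threshold = 0.6, q_threshold = 0.01,
                   min_prevalence = 0.2, method = "spearman"),
    cohesion = list(iterations = 200, method = "pearson"),
    stability = list(fraction = 0.5, repetitions = 100, hub_count = 5),
    ncm = list(bootstrap = 1000),
    consentrait = list(share_threshold = 0.9, permutations = 1000,
                       reference_group = NULL, treatment_group = NULL),
    mantel = list(permutations = 999, n_classes = NULL),
    pcoa_axes = 2
  )
}

merge_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(def[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad)) stopf("unknown config key(s) under '%s': %s", k, paste(bad, collapse = ", "))
      def[[k]][names(config[[k]])] <- config[[k]]
    } else {
      def[[k]] <- config[[k]]
    }
  }
  def
}

#' Run the full community-stability pipeline
#'
#' Executes rarefaction, alpha/beta diversity, per-group co-occurrence
#' networks with topology, modularity and hubs, cohesion, robustness and
#' vulnerability, the neutral community model, phylogenetic response tests
#' (when a tree is available), and Levins niche overlap. Every output file
#' carries its stage parameters and seed in a `#`-prefixed header, and a
#' JSON manifest lists all artifacts. One global seed fans out to per-stage
#' child seeds via a counter scheme ([child_seed()]), so adding a stage does
#' not shift another stage's random stream.
#'
#' @param config Named list (see `microstab:::default_config()` for keys and
#'   defaults) or path to a YAML/JSON file with the same structure. Required:
#'   `table` and `metadata` paths. Optional: `tree` (Newick; phylogenetic
#'   stages are skipped with a warning when absent) and `responses` (TSV of
#'   per-taxon log2-fold ratios; computed internally when absent and the
#'   consenTRAIT group pair is configured).
#' @return Invisibly, the manifest (named list of artifact paths, plus
#'   headline statistics per group).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  if (is.null(cfg$table) || is.null(cfg$metadata))
    stopf("config must provide 'table' and 'metadata' paths")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.yaml"))
  manifest <- list(config = file.path(cfg$outdir, "config.yaml"))
  out <- function(name) file.path(cfg$outdir, name)
  seed_of <- function(i) child_seed(cfg$seed, i)

  counts <- read_asv_table(cfg$table)
  meta <- read_sample_metadata(cfg$metadata, counts)
  tree <- if (!is.null(cfg$tree) && file.exists(cfg$tree)) {
    read_tree(cfg$tree)
  } else {
    if (!is.null(cfg$tree)) warnf("tree file '%s' not found; skipping phylogenetic stages", cfg$tree)
    NULL
  }

  # stage 1: rarefaction
  depth <- cfg$rarefy$depth
  if (isTRUE(cfg$rarefy$enabled)) {
    if (is.null(depth)) depth <- min(colSums(counts))
    counts <- rarefy(counts, depth, seed = seed_of(1))
    meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  }
  groups <- levels(droplevels(meta$group))
  by_group <- lapply(groups, function(g)
    counts[, meta$sample_id[meta$group == g], drop = FALSE])
  names(by_group) <- groups

  # stage 2: diversity
  alpha <- alpha_diversity(counts)
  alpha$group <- meta$group[match(alpha$sample_id, meta$sample_id)]
  manifest$alpha <- write_stage_tsv(alpha, out("alpha_diversity.tsv"),
                                    list(stage = "diversity", rarefy_depth = depth))
  bc <- bray_curtis(counts)
  manifest$bray_curtis <- write_stage_tsv(
    data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
    out("bray_curtis.tsv"), list(stage = "diversity"))
  ord <- pcoa(bc, k = cfg$pcoa_axes)
  manifest$pcoa <- write_stage_tsv(
    data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
               check.names = FALSE),
    out("pcoa.tsv"),
    list(stage = "diversity",
         proportion_explained = paste(fmt_num(ord$proportion_explained), collapse = ",")))

  summary_stats <- list()
  for (g in groups) {
    tab <- by_group[[g]]
    gstat <- list()
    # stage 3: network + topology + modules
    net <- tryCatch(co_network(tab, cfg$network$rho_threshold, cfg$network$q_threshold,
                               cfg$network$min_prevalence, cfg$network$method),
                    error = function(e) { warnf("group %s: %s", g, conditionMessage(e)); NULL })
    if (!is.null(net)) {
      mods <- detect_modules(net, seed = seed_of(2))
      net <- mods$network
      hubs <- module_hubs(net, n_hubs = cfg$stability$hub_count)
      topo <- topology_metrics(net)
      node_tab <- merge(topo, hubs[, c("node", "module", "z", "is_hub")], by = "node")
      manifest[[paste0("nodes_", g)]] <- write_stage_tsv(
        node_tab, out(sprintf("network_nodes_%s.tsv", g)),
        list(stage = "network", group = g, modularity = fmt_num(mods$modularity),
             rho_threshold = cfg$network$rho_threshold,
             q_threshold = cfg$network$q_threshold, seed = seed_of(2)))
      ed <- igraph::as_data_frame(net, what = "edges")
      manifest[[paste0("edges_", g)]] <- write_stage_tsv(
        data.frame(taxon_a = ed$from, taxon_b = ed$to, rho = ed$weight, q = ed$q),
        out(sprintf("network_edges_%s.tsv", g)),
        list(stage = "network", group = g))
      gstat$n_nodes <- igraph::gorder(net)
      gstat$n_edges <- igraph::gsize(net)
      gstat$modularity <- mods$modularity
      # stage 5: robustness + vulnerability
      rob <- robustness(net, "random", f = cfg$stability$fraction,
                        repetitions = cfg$stability$repetitions, seed = seed_of(3))
      hubrob <- robustness(net, "module_hubs", hub_count = cfg$stability$hub_count)
      vul <- tryCatch(vulnerability(net), error = function(e) {
        warnf("group %s vulnerability: %s", g, conditionMessage(e))
        list(global_efficiency = NA_real_, network_vulnerability = NA_real_)
      })
      gstat$robustness_mean <- rob$mean
      gstat$robustness_sd <- rob$sd
      gstat$robustness_hub_removal <- hubrob$proportions
      gstat$vulnerability <- vul$network_vulnerability
      manifest[[paste0("stability_", g)]] <- write_stage_json(
        list(group = g, random = rob[c("mean", "sd", "proportions", "f", "seed")],
             module_hubs = hubrob[c("proportions", "hub_count")],
             global_efficiency = vul$global_efficiency,
             network_vulnerability = vul$network_vulnerability),
        out(sprintf("stability_%s.json", g)))
    }
    # stage 4: cohesion
    coh <- cohesion(tab, iterations = cfg$cohesion$iterations, seed = seed_of(4),
                    method = cfg$cohesion$method)
    coh$samples$group <- g
    manifest[[paste0("cohesion_", g)]] <- write_stage_tsv(
      coh$samples, out(sprintf("cohesion_%s.tsv", g)),
      list(stage = "cohesion", group = g, iterations = cfg$cohesion$iterations,
           seed = seed_of(4)))
    gstat$cohesion_ratio_median <- coh$ratio_median
    # stage 6: neutral community model
    ncm <- tryCatch(fit_ncm(occurrence_stats(tab), N = sum(tab[, 1]),
                            bootstrap = cfg$ncm$bootstrap, seed = seed_of(5)),
                    error = function(e) { warnf("group %s NCM: %s", g, conditionMessage(e)); NULL })
    if (!is.null(ncm)) {
      manifest[[paste0("ncm_", g)]] <- write_stage_json(
        list(group = g, m = ncm$m, Nm = ncm$Nm, R2 = ncm$R2, d = ncm$d, N = ncm$N,
             ci95_m = ncm$ci95_m, bootstrap = ncm$bootstrap, seed = seed_of(5),
             partition = as.list(table(ncm$per_asv$partition))),
        out(sprintf("ncm_%s.json", g)))
      gstat$ncm_m <- ncm$m
      gstat$ncm_R2 <- ncm$R2
    }
    # stage 8: niche overlap
    nic <- niche_metrics(tab)
    manifest[[paste0("niche_", g)]] <- write_stage_tsv(
      nic$breadth, out(sprintf("niche_breadth_%s.tsv", g)),
      list(stage = "niche", group = g,
           mean_overlap = fmt_num(nic$mean_overlap),
           states = "group samples"))
    gstat$mean_niche_overlap <- nic$mean_overlap
    summary_stats[[g]] <- gstat
  }

  # stage 7: phylogenetic response conservation
  if (!is.null(tree)) {
    cs <- cfg$consentrait
    responses <- NULL
    if (!is.null(cfg$responses) && file.exists(cfg$responses)) {
      responses <- utils::read.table(cfg$responses, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
    } else if (!is.null(cs$reference_group) && !is.null(cs$treatment_group)) {
      responses <- log2_fold_response(counts, meta, cs$reference_group, cs$treatment_group)
    }
    if (!is.null(responses)) {
      shared <- intersect(tree$tip.label, responses$taxon)
      if (length(shared) >= 10) {
        tr <- ape::keep.tip(tree, shared)
        resp <- responses[match(tr$tip.label, responses$taxon), ]
        for (dir in c("positive", "negative")) {
          trait <- stats::setNames(as.numeric(
            if (dir == "positive") resp$log2_fold_ratio > 0 else resp$log2_fold_ratio < 0),
            resp$taxon)
          if (sum(trait) == 0) next
          ct <- consentrait(tr, trait, share_threshold = cs$share_threshold,
                            permutations = cs$permutations, seed = seed_of(6))
          manifest[[paste0("consentrait_", dir)]] <- write_stage_json(
            list(direction = dir, tau_D = ct$tau_D, p_value = ct$p_value,
                 n_clades = nrow(ct$clades), n_singletons = ct$n_singletons,
                 permutations = ct$n_permutations, seed = seed_of(6)),
            out(sprintf("consentrait_%s.json", dir)))
          summary_stats[[paste0("consentrait_", dir)]] <-
            list(tau_D = ct$tau_D, p_value = ct$p_value)
        }
        mg <- mantel_correlogram(stats::cophenetic(tr),
                                 response_diff_matrix(
                                   stats::setNames(abs(resp$log2_fold_ratio), resp$taxon)),
                                 n_classes = cfg$mantel$n_classes,
                                 permutations = cfg$mantel$permutations,
                                 seed = seed_of(7))
        manifest$mantel <- write_stage_tsv(
          mg$classes, out("mantel_correlogram.tsv"),
          list(stage = "phylo_response", permutations = mg$n_permutations,
               seed = seed_of(7)))
      } else {
        warnf("fewer than 10 taxa shared between tree and response table; skipping phylo stages")
      }
    }
  }

  manifest$summary <- write_stage_json(summary_stats, out("summary.json"))
  # manifest records artifact file names relative to the output directory, so
  # identical runs into different directories stay byte-identical
  write_stage_json(lapply(manifest, function(p) basename(as.character(p))),
                   out("manifest.json"))
  invisible(c(manifest, list(stats = summary_stats)))
}
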