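default_config <- function() {
  list(
    input = NULL,            # path to a TSV profile; NULL -> synthetic
    synthetic = list(tara_like = TRUE, seed = 1, n_taxa = 1200),
    drop_taxa = character(0),
    rarefy_depth = NULL,
    min_samples = 0,
    max_samples = Inf,
    policies = c(1, 3, 5),
    methods = "spearman",
    min_overlap = 30,
    pseudo_value = 0.01,
    knn_k = 10,
    r_cutoff = 0.6,
    p_cutoff = 0.001,
    hub_top_k = 10,
    seed = 1
  )
}

#' Read a pipeline run configuration
#'
#' A flat YAML document mirroring the fields of [run_pipeline()]'s
#' configuration; unspecified keys take the documented defaults.
#'
#' @param path YAML file path.
#' @return Named configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  if (is.character(cfg$max_samples)) cfg$max_samples <- Inf
  cfg
}

#' Run the full filtering / correlation / network pipeline
#'
#' Orchestrates the whole workflow: load (or synthesise) a count profile,
#' optionally drop taxa and rarefy, frequency-filter, then for every
#' configured policy x method combination compute the pair correlations,
#' build co-occurrence and co-exclusive networks, collect topology
#' metrics, and take consensus networks and pairwise overlaps across the
#' combinations. All outputs are written under `out_dir` as TSV/GraphML
#' plus a YAML provenance record sufficient to reproduce the run.
#'
#' @param config configuration list (see [read_run_config()]) or a path to
#'   a YAML config file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the treated profiles, correlation
#'   tibbles, networks, the metrics table and the overlap tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$input)) {
    profile <- read_profile(cfg$input)
  } else {
    spec <- if (isTRUE(cfg$synthetic$tara_like)) {
      tara_like_spec(
        seed = cfg$synthetic$seed %||% cfg$seed,
        n_taxa = cfg$synthetic$n_taxa %||% 1200
      )
    } else {
      do.call(synthetic_spec, cfg$synthetic[setdiff(names(cfg$synthetic), "tara_like")])
    }
    profile <- generate_profile(spec)$profile
  }
  for (lab in cfg$drop_taxa) profile <- drop_taxon(profile, lab, strict = FALSE)
  if (!is.null(cfg$rarefy_depth)) {
    profile <- rarefy(profile, cfg$rarefy_depth, seed = cfg$seed)
  }
  profile <- frequency_filter(profile, cfg$min_samples, cfg$max_samples)
  inform(sprintf(
    "pipeline profile: %d taxa x %d samples, zero fraction %.3f",
    nrow(profile), ncol(profile) - 1, zero_fraction(profile)
  ))

  policies <- as.integer(cfg$policies)
  methods <- cfg$methods
  treated <- list()
  results <- list()
  networks <- list()
  metric_rows <- list()
  for (pol in policies) {
    prof_p <- if (pol %in% 1:3) {
      treat_profile(profile, pol, pseudo_value = cfg$pseudo_value, k = cfg$knn_k)
    } else {
      profile
    }
    treated[[as.character(pol)]] <- prof_p
    if (pol %in% 2:3) {
      write_profile(prof_p, file.path(out_dir, sprintf("profile_policy%d.tsv", pol)))
    }
    for (method in methods) {
      key <- sprintf("%s_policy%d", method, pol)
      res <- correlate_all(prof_p,
        method = method, policy = pol,
        min_overlap = cfg$min_overlap, pseudo_value = cfg$pseudo_value
      )
      results[[key]] <- res
      write_edge_list(res, file.path(out_dir, sprintf("edges_%s.tsv", key)))
      for (kind in c("co_occurrence", "co_exclusive")) {
        net <- build_network(res,
          r_cutoff = cfg$r_cutoff, p_cutoff = cfg$p_cutoff, kind = kind
        )
        networks[[paste(key, kind, sep = "_")]] <- net
        export_network(net,
          file.path(out_dir, sprintf("network_%s_%s.tsv", key, kind)),
          format = "edge_tsv"
        )
        metric_rows[[paste(key, kind, sep = "_")]] <- dplyr::bind_cols(
          tibble::tibble(method = method, policy = pol, kind = kind),
          compute_metrics(net)
        )
      }
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  readr::write_tsv(metrics, file.path(out_dir, "network_metrics.tsv"), progress = FALSE)

  overlaps <- list()
  for (kind in c("co_occurrence", "co_exclusive")) {
    nets <- networks[grepl(paste0(kind, "$"), names(networks))]
    if (length(nets) >= 1) {
      cons <- consensus_network(nets)
      export_network(cons,
        file.path(out_dir, sprintf("consensus_%s.tsv", kind)),
        format = "edge_tsv"
      )
      networks[[paste0("consensus_", kind)]] <- cons
    }
    if (length(nets) >= 2) {
      grid <- expand.grid(a = names(nets), b = names(nets), stringsAsFactors = FALSE)
      ov <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(t) {
        dplyr::bind_cols(
          tibble::tibble(net_a = grid$a[t], net_b = grid$b[t]),
          overlap_counts(nets[[grid$a[t]]], nets[[grid$b[t]]])
        )
      }))
      overlaps[[kind]] <- ov
      readr::write_tsv(ov, file.path(out_dir, sprintf("overlap_%s.tsv", kind)),
        progress = FALSE
      )
    }
  }

  provenance <- list(
    config = lapply(cfg, function(v) if (identical(v, Inf)) "Inf" else v),
    package_version = as.character(packageVersion("zeronet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))

  invisible(list(
    profile = profile, treated = treated, results = results,
    networks = networks, metrics = metrics, overlaps = overlaps
  ))
}
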