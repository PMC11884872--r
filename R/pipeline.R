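#' Run the full simulate -> run -> analyze pipeline
#'
#' Simulates a cohort, drives every session through the closed-loop engine
#' (feedback group in feedback mode, control group in control mode),
#' counts reaches per paw, computes normalized reach ratios and the group
#' statistics, and clusters the feedback group's aligned reach
#' trajectories (PCA features, GMM with BIC model selection). The whole
#' run is deterministic given the master seed: per-session seeds derive
#' from it, and repeated runs write byte-identical outputs.
#'
#' @param seed master seed; overrides `config$seed` when given.
#' @param config a `run_config` (see [default_run_config()],
#'   [load_config()]).
#' @param out_dir optional output directory; when given, the effective
#'   configuration (`config.yaml`), per-mouse/day ratios (`ratios.csv`),
#'   session summaries (`sessions.csv`), cluster assignments
#'   (`clusters.csv`) and the statistics report (`stats.json`) are
#'   written there.
#' @param traj_per_session at most this many reach trajectories per
#'   session enter the clustering (the earliest ones, deterministically).
#' @param T_samples resampled trajectory length.
#' @param K_range candidate cluster counts for the GMM.
#' @param run_tsne also compute the 2-D t-SNE embedding of the clustered
#'   trajectories (visualization only; off by default).
#' @return An object of class `pipeline_report`: `sessions` (per-session
#'   counts and event tallies), `ratios` (a `cohort_result`), `stats` (a
#'   `stats_result`), `clusters` (a `cluster_result`), `trajectory_meta`,
#'   `tsne` (or `NULL`), `config`, `paths`.
#' @export
pipeline_end_to_end <- function(seed = NULL, config = default_run_config(),
                                out_dir = NULL, traj_per_session = 20,
                                T_samples = 100, K_range = 1:4,
                                run_tsne = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  design <- config$design
  tab <- cohort_session_table(design, config$seed)

  sessions <- NULL
  traj_rows <- list(); traj_meta <- NULL
  for (i in seq_len(nrow(tab))) {
    sim <- simulate_session(tab$mouse[i], tab$day[i], tab$group[i],
                            config$learning, design, seed = tab$seed[i],
                            target_offset = config$trial$target_offset)
    mode <- if (tab$group[i] == design$groups[1]) "feedback" else "control"
    rec <- run_session(sim$stream, sim$calibration, config$trial,
                       config$sonification, mode = mode,
                       meta = list(mouse = tab$mouse[i], day = tab$day[i],
                                   group = tab$group[i], seed = tab$seed[i]))
    counts <- session_reach_counts(rec)
    sessions <- rbind(sessions, data.frame(
      mouse = tab$mouse[i], group = tab$group[i], day = tab$day[i],
      seed = tab$seed[i], mode = mode,
      left = counts[["left"]], right = counts[["right"]],
      planted_left = unname(sim$counts["left"]),
      planted_right = unname(sim$counts["right"]),
      successes = success_count(rec),
      rewards = sum(rec$events$kind == "reward"),
      reward_ul = sum(rec$events$payload[rec$events$kind == "reward"]),
      tone_commands = nrow(rec$tones)))
    if (mode == "feedback") {
      reaches <- detect_reaches(rec$kinematics, config$trial, "left")
      take <- seq_len(min(traj_per_session, n_reaches(reaches)))
      long_enough <- which(reaches$segments$n_samples >= 2)
      take <- intersect(take, long_enough)
      if (length(take)) {
        traj_rows <- c(traj_rows, reaches$samples[take])
        traj_meta <- rbind(traj_meta, data.frame(
          mouse = tab$mouse[i], day = tab$day[i], reach = take))
      }
    }
  }

  ratios <- reach_ratio(sessions[, c("mouse", "group", "day", "left", "right")])
  stats <- group_stats(ratios)

  clusters <- NULL; embedding <- NULL; pca <- NULL
  if (length(traj_rows) >= max(K_range)) {
    tm <- suppressWarnings(align_and_resample(traj_rows, T_samples,
                                              meta = traj_meta))
    pca <- pca_embed(tm, k = min(dim(tm$mat)))
    k90 <- choose_pca_k(pca$variance_explained, 0.9)
    feats <- pca$scores[, seq_len(k90), drop = FALSE]
    clusters <- gmm_cluster(feats, K_range, seed = config$seed)
    if (run_tsne && nrow(feats) >= 3 * 10)
      embedding <- tsne_embed(feats, perplexity = 10, seed = config$seed)
    traj_meta <- tm$meta
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(config = file.path(out_dir, "config.yaml"),
                  sessions = file.path(out_dir, "sessions.csv"),
                  ratios = file.path(out_dir, "ratios.csv"),
                  stats = file.path(out_dir, "stats.json"),
                  clusters = file.path(out_dir, "clusters.csv"))
    dump_config(config, paths$config)
    write.csv(sessions, paths$sessions, row.names = FALSE)
    write.csv(as.data.frame(ratios), paths$ratios, row.names = FALSE)
    jsonlite::write_json(
      list(groups = stats$groups, per_day = stats$per_day,
           anova = stats$anova, master_seed = config$seed),
      paths$stats, auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(clusters)) {
      ca <- cbind(traj_meta, cluster = clusters$labels)
      if (!is.null(embedding)) {
        ca$tsne1 <- embedding[, 1]; ca$tsne2 <- embedding[, 2]
      }
      write.csv(ca, paths$clusters, row.names = FALSE)
    }
  }

  structure(list(sessions = sessions, ratios = ratios, stats = stats,
                 clusters = clusters, pca = pca, trajectory_meta = traj_meta,
                 tsne = embedding, config = config, paths = paths),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sessions (%d mice x %d days), seed %d\n",
              nrow(x$sessions), length(unique(x$sessions$mouse)),
              length(unique(x$sessions$day)), x$config$seed))
  d4 <- x$ratios[x$ratios$day == max(x$ratios$day), ]
  for (g in unique(d4$group))
    cat(sprintf("  final-day mean normalized reach ratio, %s: %.3f\n",
                g, mean(d4$norm_ratio[d4$group == g])))
  if (!is.null(x$clusters))
    cat(sprintf("  trajectory clusters: K = %d (BIC)\n", x$clusters$K))
  invisible(x)
}
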